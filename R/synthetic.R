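# Synthetic multitrait-multimethod Likert data with a known latent structure.
#
# The generating model is the one the CFA stage assumes: every item loads on
# exactly one trait-by-method factor, factors are jointly multivariate normal
# with correlation matrix Phi, items are discretised by fixed thresholds, and
# external criteria are linear in the factor scores plus independent noise.

#' Build and validate an MTMM generating model
#'
#' @param traits character vector of trait labels (>= 1).
#' @param methods named list; each element a list with `n_items` (items per
#'   trait), `categories` (K >= 2 response options).
#' @param loadings numeric vector, one standardized loading in [0, 1) per
#'   item, ordered method-major then trait then item. NULL uses
#'   `default_loadings` ranges.
#' @param phi factor correlation matrix over the trait-by-method factors
#'   (order: method 1 traits, then method 2 traits, ...). Must be symmetric
#'   positive definite with unit diagonal.
#' @param thresholds list of strictly increasing numeric vectors (length
#'   K-1), one per item; NULL builds shifted equiprobable normal cuts.
#' @param threshold_shift scalar added to the default normal quantile cuts;
#'   a positive shift yields the mild right skew typical of dark-trait items
#'   in community samples (default 0.3, well inside the +/-2 screen).
#' @param criteria data frame describing external criteria: columns
#'   `criterion`, `set`, and one weight column per factor (or per trait, see
#'   [criterion_weights_from_traits]), plus optional `residual_sd`. NULL for
#'   none.
#' @param shared_traits if TRUE both methods' items load on the same trait
#'   factors (a literally method-equivalent world, used to verify that the
#'   consistency metrics reach their ideal values); default FALSE gives one
#'   factor per trait-by-method cell.
#' @return object of class `mtmm_spec` with fields `traits`, `methods`,
#'   `factors` (labels trait.method), `assignment` (item -> factor), `items`
#'   (labels), `loadings`, `phi`, `thresholds`, `categories` (per item),
#'   `criteria`.
#' @export
mtmm_model_spec <- function(traits, methods, loadings = NULL, phi = NULL,
                            thresholds = NULL, threshold_shift = 0.3,
                            criteria = NULL, shared_traits = FALSE) {
  stopifnot(length(traits) >= 1L, length(methods) >= 1L,
            !is.null(names(methods)))
  factors <- if (shared_traits) traits else
    unlist(lapply(names(methods), function(m) paste(traits, m, sep = ".")))
  q <- length(factors)
  item_rows <- do.call(rbind, lapply(names(methods), function(m) {
    mm <- methods[[m]]
    do.call(rbind, lapply(traits, function(tr) {
      data.frame(item = paste(m, tr, seq_len(mm$n_items), sep = "_"),
                 factor = if (shared_traits) tr else paste(tr, m, sep = "."),
                 trait = tr, method = m,
                 categories = mm$categories, stringsAsFactors = FALSE)
    }))
  }))
  p <- nrow(item_rows)
  if (is.null(phi)) phi <- diag(q)
  phi <- as.matrix(phi)
  dimnames(phi) <- list(factors, factors)
  if (!is_corr_matrix(phi)) {
    stop("phi must be a correlation matrix (symmetric, unit diagonal, ",
         "entries in [-1, 1])", call. = FALSE)
  }
  check_pd(phi, "factor correlation matrix phi")
  if (is.null(loadings)) {
    loadings <- rep(0.6, p)
  }
  if (length(loadings) != p || any(loadings < 0) || any(loadings >= 1)) {
    stop("need one loading in [0, 1) per item", call. = FALSE)
  }
  if (is.null(thresholds)) {
    thresholds <- lapply(item_rows$categories, function(K) {
      stats::qnorm(seq_len(K - 1L) / K) + threshold_shift
    })
  }
  if (length(thresholds) != p) stop("need one threshold vector per item",
                                    call. = FALSE)
  for (i in seq_len(p)) {
    tau <- thresholds[[i]]
    if (length(tau) != item_rows$categories[i] - 1L ||
        any(diff(tau) <= 0)) {
      stop(sprintf("thresholds for item '%s' must be strictly increasing ",
                   item_rows$item[i]), call. = FALSE)
    }
  }
  if (!is.null(criteria)) criteria <- validate_criteria(criteria, factors, traits)
  structure(list(traits = traits, methods = methods, factors = factors,
                 items = item_rows$item, assignment = item_rows$factor,
                 item_table = item_rows, loadings = loadings, phi = phi,
                 thresholds = thresholds,
                 categories = item_rows$categories, criteria = criteria),
            class = "mtmm_spec")
}

validate_criteria <- function(criteria, factors, traits) {
  stopifnot(is.data.frame(criteria),
            all(c("criterion", "set") %in% names(criteria)))
  wcols <- paste0("w.", factors)
  if (!all(wcols %in% names(criteria))) {
    stop("criteria must carry weight columns: ",
         paste(setdiff(wcols, names(criteria)), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(criteria$residual_sd)) criteria$residual_sd <- NA_real_
  if (any(!is.na(criteria$residual_sd) & criteria$residual_sd < 0)) {
    stop("residual_sd must be nonnegative", call. = FALSE)
  }
  criteria
}

#' Expand per-trait criterion weights onto a reference method's factors
#'
#' Criteria are linear in factor scores; the usual configuration puts each
#' criterion's per-trait weights on one reference method's factors ("the
#' chosen reference scale") and zero elsewhere. Supplying `method_b` and
#' `weights_b` splits the weights 50/50 across the two methods' factors,
#' which makes the two inventories' criterion profiles diverge wherever the
#' two weight sets differ.
#'
#' @param criterion,set labels (vectors of equal length).
#' @param weights matrix (criteria x traits) of standardized weights.
#' @param traits trait labels (column order of `weights`).
#' @param factors full factor label vector of the spec.
#' @param method reference method name.
#' @param method_b,weights_b optional second method and weight matrix.
#' @return data frame suitable for the `criteria` field of [mtmm_model_spec].
#' @export
criterion_weights_from_traits <- function(criterion, set, weights, traits,
                                          factors, method,
                                          method_b = NULL, weights_b = NULL) {
  weights <- as.matrix(weights)
  stopifnot(length(criterion) == nrow(weights),
            ncol(weights) == length(traits))
  W <- matrix(0, nrow(weights), length(factors),
              dimnames = list(NULL, factors))
  fa <- paste(traits, method, sep = ".")
  if (is.null(method_b)) {
    W[, fa] <- weights
  } else {
    fb <- paste(traits, method_b, sep = ".")
    W[, fa] <- weights / 2
    W[, fb] <- as.matrix(weights_b) / 2
  }
  out <- data.frame(criterion = criterion, set = set,
                    stringsAsFactors = FALSE)
  colnames(W) <- paste0("w.", factors)
  cbind(out, as.data.frame(W), residual_sd = NA_real_)
}

#' Simulate latent factor scores
#'
#' Multivariate-normal factor scores with correlation `spec$phi`,
#' deterministic under (`spec`, `n`, `seed`).
#'
#' @param spec an `mtmm_spec`.
#' @param n number of persons (>= 2).
#' @param seed integer seed.
#' @return numeric matrix n x factors.
#' @export
simulate_latent_scores <- function(spec, n, seed) {
  stopifnot(inherits(spec, "mtmm_spec"))
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  set.seed(derive_seed(seed, "latent"))
  Z <- matrix(stats::rnorm(n * length(spec$factors)), n)
  F <- Z %*% chol(spec$phi)
  colnames(F) <- spec$factors
  F
}

#' Discretise latent item values into Likert categories
#'
#' Category c is assigned iff the value falls in (tau_{c-1}, tau_c], with
#' tau_0 = -Inf and tau_K = +Inf, so marginal category proportions converge
#' to consecutive differences of the standard normal CDF at the thresholds.
#'
#' @param values numeric matrix (persons x items) of latent item values.
#' @param thresholds list of strictly increasing cut-point vectors, one per
#'   column of `values`.
#' @return integer matrix of responses in 1..K (per item).
#' @export
discretize_to_likert <- function(values, thresholds) {
  values <- as.matrix(values)
  stopifnot(length(thresholds) == ncol(values))
  out <- matrix(NA_integer_, nrow(values), ncol(values),
                dimnames = dimnames(values))
  for (j in seq_len(ncol(values))) {
    tau <- thresholds[[j]]
    if (any(diff(tau) <= 0)) stop("thresholds must be strictly increasing",
                                  call. = FALSE)
    out[, j] <- findInterval(values[, j], tau, left.open = TRUE) + 1L
  }
  out
}

#' Simulate criterion scores from latent factor scores
#'
#' Each criterion is `y = F w + e` with `e ~ N(0, residual_sd^2)`
#' independent across persons and criteria. Where `residual_sd` is NA the
#' residual variance is set to `max(1 - w' Phi w, 0.05)` so criteria are
#' near unit variance; with standardized uncorrelated factors and unit
#' variance the population R-squared is `sum(w^2)`.
#'
#' @param factor_scores matrix (persons x factors).
#' @param spec an `mtmm_spec` whose `criteria` field is non-NULL.
#' @param seed integer seed.
#' @return data frame of criterion columns.
#' @export
simulate_criterion_scores <- function(factor_scores, spec, seed) {
  stopifnot(inherits(spec, "mtmm_spec"), !is.null(spec$criteria))
  cr <- spec$criteria
  W <- as.matrix(cr[, paste0("w.", spec$factors), drop = FALSE])
  set.seed(derive_seed(seed, "criteria"))
  n <- nrow(factor_scores)
  out <- matrix(NA_real_, n, nrow(cr),
                dimnames = list(NULL, cr$criterion))
  for (i in seq_len(nrow(cr))) {
    w <- W[i, ]
    s <- cr$residual_sd[i]
    if (is.na(s)) {
      expl <- drop(t(w) %*% spec$phi %*% w)
      s <- sqrt(max(1 - expl, 0.05))
    }
    out[, i] <- drop(factor_scores %*% w) + stats::rnorm(n, sd = s)
  }
  as.data.frame(out)
}

#' Model-implied item correlation matrix of a generating spec
#'
#' @param spec an `mtmm_spec`.
#' @return plain correlation matrix lambda_i Phi_ab lambda_j off diagonal.
#' @export
implied_item_corr <- function(spec) {
  model_implied_corr(spec$loadings, spec$phi,
                     match(spec$assignment, spec$factors),
                     labels = spec$items)
}

#' Simulate a complete MTMM dataset
#'
#' Runs the full generative chain (latent scores -> item discretisation ->
#' criteria) and returns the dataset together with its ground truth.
#'
#' @param spec an `mtmm_spec`.
#' @param n persons.
#' @param seed integer master seed; all sub-streams derive from it.
#' @return list with `items` (integer data frame), `criteria` (data frame or
#'   NULL), `latent` (factor scores), `codebook` (see [build_codebook]),
#'   `spec`, `seed`.
#' @export
simulate_mtmm <- function(spec, n, seed) {
  F <- simulate_latent_scores(spec, n, seed)
  lam <- spec$loadings
  fidx <- match(spec$assignment, spec$factors)
  set.seed(derive_seed(seed, "uniqueness"))
  E <- matrix(stats::rnorm(n * length(lam)), n)
  latent_items <- F[, fidx, drop = FALSE] %*% diag(lam) +
    E %*% diag(sqrt(1 - lam^2))
  colnames(latent_items) <- spec$items
  items <- discretize_to_likert(latent_items, spec$thresholds)
  criteria <- if (!is.null(spec$criteria)) {
    simulate_criterion_scores(F, spec, seed)
  }
  list(items = as.data.frame(items), criteria = criteria, latent = F,
       codebook = build_codebook(spec), spec = spec, seed = seed)
}
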