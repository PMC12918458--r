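#' Labelled correlation matrix container
#'
#' Light S3 container shared by the Pearson and polychoric estimators and by
#' the CFA stage. Construction validates symmetry, unit diagonal and range.
#'
#' @param values symmetric numeric matrix with unit diagonal.
#' @param kind "pearson" or "polychoric".
#' @param n sample size the matrix was estimated from.
#' @param labels optional character labels (defaults to colnames).
#' @return object of class `corr_matrix` with fields `values`, `kind`, `n`,
#'   `labels`.
#' @export
corr_matrix <- function(values, kind = c("pearson", "polychoric"), n = NA,
                        labels = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  labels <- labels %||% colnames(values) %||%
    paste0("v", seq_len(ncol(values)))
  dimnames(values) <- list(labels, labels)
  if (!is_corr_matrix(values)) {
    stop("not a valid correlation matrix (symmetry/diagonal/range)",
         call. = FALSE)
  }
  structure(list(values = values, kind = kind, n = n, labels = labels),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("%s correlation matrix, %d variables, n = %s\n", x$kind,
              length(x$labels), format(x$n)))
  print(round(x$values, 3))
  invisible(x)
}

#' Pearson correlation matrix
#'
#' @param data data frame or matrix of numeric columns.
#' @param use missing-data policy: "listwise" (default) or "pairwise".
#' @return a [corr_matrix]; correlations involving zero-variance columns are
#'   set to NA and the column names are recorded in attribute `"undefined"`.
#' @export
pearson_matrix <- function(data, use = c("listwise", "pairwise")) {
  use <- match.arg(use)
  X <- as.matrix(data)
  if (use == "listwise") X <- X[stats::complete.cases(X), , drop = FALSE]
  policy <- if (use == "listwise") "everything" else "pairwise.complete.obs"
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  bad <- colnames(X)[!is.finite(sds) | sds == 0]
  R <- suppressWarnings(stats::cor(X, use = policy))
  R[!is.finite(R)] <- NA_real_
  diag(R) <- 1
  n_eff <- if (use == "listwise") nrow(X) else max(colSums(!is.na(X)))
  ok <- !(rownames(R) %in% bad)
  if (any(!ok)) R[!ok, ] <- R[, !ok] <- NA_real_
  diag(R) <- 1
  out <- corr_matrix(replace(R, is.na(R), 0), kind = "pearson", n = n_eff)
  out$values[is.na(R)] <- NA_real_
  attr(out, "undefined") <- bad
  out
}

#' Fisher's z transform and inverse
#'
#' `fisher_z` is `atanh(r)`; `fisher_z_inv` is `tanh(z)`. The transform
#' variance-stabilises correlation coefficients and underlies both the
#' pairwise correlation tests and the profile-difference statistics.
#'
#' @param r correlation(s), each with |r| < 1.
#' @param z Fisher z value(s).
#' @return transformed numeric vector.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("fisher_z requires |r| < 1", call. = FALSE)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

# ---------------------------------------------------------------------------
# Polychoric correlation: two-step estimator. Thresholds come from the
# inverse-normal cumulative marginals; rho maximises the bivariate-normal
# likelihood of the contingency table by 1-D search on (-0.999, 0.999).

ordinal_thresholds <- function(x) {
  tab <- table(factor(x))
  cum <- cumsum(tab) / sum(tab)
  stats::qnorm(cum[-length(cum)])
}

polychoric_loglik <- function(rho, counts, tau_x, tau_y) {
  ax <- c(-Inf, tau_x, Inf)
  ay <- c(-Inf, tau_y, Inf)
  kx <- length(ax) - 1L
  ky <- length(ay) - 1L
  ij <- expand.grid(i = seq_len(kx), j = seq_len(ky))
  pr <- bvn_rect_prob(ax[ij$i], ax[ij$i + 1L], ay[ij$j], ay[ij$j + 1L], rho)
  pr <- pmax(pr, 1e-300)
  sum(as.vector(counts) * log(pr))
}

#' Polychoric correlation of two ordinal variables
#'
#' Two-step maximum-likelihood estimate of the correlation of the latent
#' bivariate-normal variables assumed to underlie two ordinal items:
#' thresholds are fixed at the inverse-normal cumulative marginal
#' proportions, then rho maximises the contingency-table likelihood over
#' (-0.999, 0.999).
#'
#' @param x,y integer/ordinal vectors (each with >= 2 observed categories).
#' @param names optional length-2 labels used in error messages.
#' @return list with `rho`, `tau_x`, `tau_y`, `n`, `loglik`, and `var`
#'   (estimated asymptotic sampling variance of rho from the observed
#'   information of the profile likelihood; used as the DWLS weight).
#' @export
polychoric_corr <- function(x, y, names = c("x", "y")) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2L) {
    stop(sprintf("variable '%s' has a single observed category", names[1L]),
         call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop(sprintf("variable '%s' has a single observed category", names[2L]),
         call. = FALSE)
  }
  counts <- table(factor(x), factor(y))
  tau_x <- ordinal_thresholds(x)
  tau_y <- ordinal_thresholds(y)
  nll <- function(r) -polychoric_loglik(r, counts, tau_x, tau_y)
  opt <- stats::optimize(nll, interval = c(-0.999, 0.999), tol = 1e-7)
  rho <- opt$minimum
  obj <- opt$objective
  # optimize() cannot land exactly on the clip; take a boundary if better
  for (bnd in c(-0.999, 0.999)) {
    vb <- nll(bnd)
    if (vb < obj) { rho <- bnd; obj <- vb }
  }
  # observed information by central second difference of the log-likelihood
  h <- 1e-3
  if (abs(rho) > 0.995) {
    v <- NA_real_   # boundary estimate: curvature unreliable
  } else {
    ll <- function(r) polychoric_loglik(r, counts, tau_x, tau_y)
    info <- -(ll(rho + h) - 2 * ll(rho) + ll(rho - h)) / h^2
    v <- if (is.finite(info) && info > 0) 1 / info else NA_real_
  }
  list(rho = rho, tau_x = tau_x, tau_y = tau_y, n = length(x),
       loglik = -obj, var = v)
}

#' Pairwise polychoric correlation matrix
#'
#' Assembles all pairwise polychoric estimates, smooths the result to the
#' nearest positive-semidefinite correlation matrix (eigenvalue clipping and
#' rescaling to unit diagonal), and retains the per-element asymptotic
#' variances for use as diagonal weights in DWLS.
#'
#' @param data data frame/matrix of ordinal item columns.
#' @return a [corr_matrix] of kind "polychoric" with attribute
#'   `"asymp_var"`: a symmetric matrix of estimated sampling variances
#'   (NA variances are replaced by the median of the finite ones).
#' @export
polychoric_matrix <- function(data) {
  X <- as.matrix(data)
  p <- ncol(X)
  labels <- colnames(X) %||% paste0("v", seq_len(p))
  R <- diag(p)
  V <- matrix(NA_real_, p, p)
  for (j in seq_len(p - 1L)) {
    for (k in seq((j + 1L), p)) {
      est <- polychoric_corr(X[, j], X[, k], names = labels[c(j, k)])
      R[j, k] <- R[k, j] <- est$rho
      V[j, k] <- V[k, j] <- est$var
    }
  }
  med <- stats::median(V[lower.tri(V)], na.rm = TRUE)
  V[!is.finite(V)] <- if (is.finite(med)) med else 1 / nrow(X)
  dimnames(R) <- dimnames(V) <- list(labels, labels)
  R <- smooth_psd(R)
  out <- corr_matrix(R, kind = "polychoric", n = nrow(X))
  attr(out, "asymp_var") <- V
  out
}

#' Standardized OLS regression from a correlation matrix
#'
#' Computes standardized coefficients `beta = Rxx^{-1} rxy`, the model
#' R-squared `rxy' beta`, and t-based p-values at sample size `n` — the
#' regression summaries the prediction-consistency framework consumes.
#'
#' @param corr [corr_matrix] (or plain labelled correlation matrix) covering
#'   criterion and predictors.
#' @param criterion criterion label.
#' @param predictors character vector of predictor labels.
#' @param n sample size.
#' @return object of class `nomo_regression`: list with `criterion`,
#'   `predictors`, `beta`, `r_squared`, `p_values`, `n`.
#' @export
standardized_ols <- function(corr, criterion, predictors, n) {
  R <- if (inherits(corr, "corr_matrix")) corr$values else corr
  labs <- c(criterion, predictors)
  missing_labs <- setdiff(labs, colnames(R))
  if (length(missing_labs)) {
    stop("unknown labels: ", paste(missing_labs, collapse = ", "),
         call. = FALSE)
  }
  k <- length(predictors)
  if (n <= k + 1) stop("n must exceed #predictors + 1", call. = FALSE)
  Rxx <- R[predictors, predictors, drop = FALSE]
  rxy <- R[predictors, criterion]
  if (rcond(Rxx) < 1e-12) {
    stop("singular predictor correlation block: ",
         paste(predictors, collapse = ", "), call. = FALSE)
  }
  beta <- drop(solve(Rxx, rxy))
  r2 <- drop(crossprod(rxy, beta))
  r2 <- min(max(r2, 0), 1)
  Cjj <- diag(solve(Rxx))
  se <- sqrt(pmax(1 - r2, 1e-12) / (n - k - 1) * Cjj)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - k - 1)
  structure(list(criterion = criterion, predictors = predictors,
                 beta = stats::setNames(beta, predictors),
                 r_squared = r2,
                 p_values = stats::setNames(pval, predictors), n = n),
            class = "nomo_regression")
}
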