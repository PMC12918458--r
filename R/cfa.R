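# Multitrait-multimethod CFA fitted by (diagonally) weighted least squares
# on a polychoric correlation matrix.
#
# The model is simple-structure: each item loads on exactly one
# trait-by-method factor, factor variances are fixed at 1, and all loadings
# and factor correlations are free unless a correlation is fixed by
# constraint. The discrepancy minimised is
#   F(theta) = sum_{i<j} w_ij^{-1} (s_ij - lambda_i lambda_j phi_{f(i)f(j)})^2
# with w_ij the estimated asymptotic variances of the polychoric
# correlations (unit weights give a ULS fallback). The reported test
# statistic is the naive T = (N-1) F_min; mean/variance-scaled robust
# statistics are deliberately not reproduced.

#' Define a CFA measurement model
#'
#' @param assignment character vector: for each item, its factor label.
#' @param items item labels (defaults to names of `assignment`).
#' @param fixed_corr optional data frame with columns `f1`, `f2`, `value`
#'   fixing specific factor correlations (used by the nested
#'   constrained-correlation tests, where a same-trait cross-method
#'   correlation is fixed at 1).
#' @return object of class `cfa_spec` with fields `items`, `factors`,
#'   `assignment_idx`, `fixed_corr`, `n_free`.
#' @export
cfa_model_spec <- function(assignment, items = NULL, fixed_corr = NULL) {
  items <- items %||% names(assignment) %||%
    paste0("item", seq_along(assignment))
  factors <- unique(assignment)
  q <- length(factors)
  p <- length(items)
  pairs <- lower_tri_pairs(q)
  fixed <- matrix(NA_real_, q, q, dimnames = list(factors, factors))
  if (!is.null(fixed_corr)) {
    stopifnot(all(c("f1", "f2", "value") %in% names(fixed_corr)))
    for (i in seq_len(nrow(fixed_corr))) {
      a <- fixed_corr$f1[i]; b <- fixed_corr$f2[i]
      if (!all(c(a, b) %in% factors)) {
        stop("fixed_corr names unknown factors", call. = FALSE)
      }
      fixed[a, b] <- fixed[b, a] <- fixed_corr$value[i]
    }
  }
  free_pair <- is.na(fixed[cbind(pairs[, 1L], pairs[, 2L])])
  n_free <- p + sum(free_pair)
  structure(list(items = items, factors = factors,
                 assignment_idx = match(assignment, factors),
                 assignment = assignment, fixed = fixed,
                 pairs = pairs, free_pair = free_pair, n_free = n_free),
            class = "cfa_spec")
}

#' Degrees of freedom of a CFA model on correlation input
#' @param spec a `cfa_spec`.
#' @return integer df = p(p-1)/2 - #free parameters.
#' @export
cfa_df <- function(spec) {
  p <- length(spec$items)
  as.integer(p * (p - 1) / 2 - spec$n_free)
}

#' Model-implied item correlation matrix
#'
#' @param loadings standardized loading per item (|lambda| < 1).
#' @param phi factor correlation matrix.
#' @param assignment_idx integer factor index per item.
#' @param labels optional item labels.
#' @return correlation matrix with entries lambda_i phi_ab lambda_j off the
#'   diagonal and 1 on the diagonal.
#' @export
model_implied_corr <- function(loadings, phi, assignment_idx, labels = NULL) {
  stopifnot(all(abs(loadings) < 1), length(assignment_idx) == length(loadings))
  phi_items <- phi[assignment_idx, assignment_idx, drop = FALSE]
  R <- tcrossprod(loadings) * phi_items
  diag(R) <- 1
  if (!is.null(labels)) dimnames(R) <- list(labels, labels)
  R
}

phi_from_par <- function(par_phi, spec) {
  q <- length(spec$factors)
  phi <- spec$fixed
  phi[is.na(phi)] <- 0
  diag(phi) <- 1
  free_idx <- spec$pairs[spec$free_pair, , drop = FALSE]
  phi[cbind(free_idx[, 1L], free_idx[, 2L])] <- par_phi
  phi[cbind(free_idx[, 2L], free_idx[, 1L])] <- par_phi
  phi
}

dwls_objective <- function(par, S, Winv, spec) {
  p <- length(spec$items)
  lam <- par[seq_len(p)]
  phi <- phi_from_par(par[-seq_len(p)], spec)
  Imp <- model_implied_corr(lam, phi, spec$assignment_idx)
  Res <- S - Imp
  diag(Res) <- 0
  sum(Winv * Res^2) / 2
}

dwls_gradient <- function(par, S, Winv, spec) {
  p <- length(spec$items)
  lam <- par[seq_len(p)]
  phi <- phi_from_par(par[-seq_len(p)], spec)
  phi_items <- phi[spec$assignment_idx, spec$assignment_idx, drop = FALSE]
  Imp <- tcrossprod(lam) * phi_items
  diag(Imp) <- 1
  G <- Winv * (S - Imp)
  diag(G) <- 0
  dlam <- -2 * drop((G * phi_items) %*% lam)
  M <- outer(spec$assignment_idx, seq_along(spec$factors), `==`) + 0
  dphi_full <- -2 * t(M) %*% (G * tcrossprod(lam)) %*% M
  free_idx <- spec$pairs[spec$free_pair, , drop = FALSE]
  c(dlam, dphi_full[cbind(free_idx[, 1L], free_idx[, 2L])])
}

#' Fit a CFA by (diagonally) weighted least squares
#'
#' @param poly a [corr_matrix] (typically polychoric) covering the model's
#'   items; its `"asymp_var"` attribute supplies the DWLS weights.
#' @param spec a `cfa_spec`.
#' @param N sample size used for the test statistic.
#' @param weights "dwls" (asymptotic-variance weights, the default) or
#'   "uls" (unit weights).
#' @param start deterministic start values: loadings 0.5, correlations 0.3.
#'   On optimizer failure up to 3 jittered restarts are attempted (seeded).
#' @param seed seed for the restart jitter.
#' @return object of class `cfa_fit`: list with `loadings`, `phi`, `F_min`,
#'   `chi_square` (= (N-1) F_min), `df`, `N`, `converged`, `sample_corr`,
#'   `implied`, `spec`, `weights`.
#' @export
fit_dwls <- function(poly, spec, N, weights = c("dwls", "uls"),
                     start = NULL, seed = 1L) {
  weights <- match.arg(weights)
  stopifnot(inherits(spec, "cfa_spec"))
  S <- if (inherits(poly, "corr_matrix")) poly$values else as.matrix(poly)
  if (!all(spec$items %in% colnames(S))) {
    stop("correlation matrix does not cover all model items", call. = FALSE)
  }
  S <- S[spec$items, spec$items]
  p <- length(spec$items)
  if (weights == "dwls") {
    V <- attr(poly, "asymp_var")
    if (is.null(V)) {
      stop("no asymptotic variances on input; use weights = 'uls' or a ",
           "polychoric_matrix() result", call. = FALSE)
    }
    # stored variances are for rho_hat (O(1/n)); the discrepancy uses the
    # asymptotic variance of sqrt(n)(s - sigma), so rescale by the
    # estimation sample size to keep T = (N-1) F_min on the chi-square scale
    n_est <- if (inherits(poly, "corr_matrix") && is.finite(poly$n)) poly$n
             else N
    V <- V[spec$items, spec$items] * n_est
    Winv <- 1 / V
  } else {
    Winv <- matrix(1, p, p)
  }
  diag(Winv) <- 0
  n_phi <- sum(spec$free_pair)
  par0 <- start %||% c(rep(0.5, p), rep(0.3, n_phi))
  lower <- rep(-0.999, p + n_phi)
  upper <- rep(0.999, p + n_phi)
  fit <- NULL
  set.seed(derive_seed(seed, "dwls_restarts"))
  for (attempt in 0:3) {
    par_try <- if (attempt == 0) par0 else
      pmin(pmax(par0 + stats::runif(length(par0), -0.1, 0.1), -0.9), 0.9)
    res <- try(stats::optim(par_try, dwls_objective, dwls_gradient,
                            S = S, Winv = Winv, spec = spec,
                            method = "L-BFGS-B", lower = lower,
                            upper = upper,
                            control = list(maxit = 2000, factr = 1e4)),
               silent = TRUE)
    if (!inherits(res, "try-error") && res$convergence == 0) {
      fit <- res
      break
    }
    if (!inherits(res, "try-error") && is.null(fit)) fit <- res
  }
  converged <- !is.null(fit) && fit$convergence == 0
  if (is.null(fit)) {
    return(structure(list(converged = FALSE, spec = spec, N = N),
                     class = "cfa_fit"))
  }
  lam <- stats::setNames(fit$par[seq_len(p)], spec$items)
  phi <- phi_from_par(fit$par[-seq_len(p)], spec)
  F_min <- fit$value  # objective already sums unordered pairs once
  implied <- model_implied_corr(lam, phi, spec$assignment_idx,
                                labels = spec$items)
  structure(list(loadings = lam, phi = phi, F_min = F_min,
                 chi_square = (N - 1) * F_min, df = cfa_df(spec), N = N,
                 converged = converged, sample_corr = S, implied = implied,
                 spec = spec, weights = weights),
            class = "cfa_fit")
}

#' @export
print.cfa_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("CFA fit: NOT converged\n")
    return(invisible(x))
  }
  cat(sprintf("CFA fit by %s: chi-square(%d, N = %d) = %.2f, F_min = %.5g\n",
              toupper(x$weights), x$df, x$N, x$chi_square, x$F_min))
  invisible(x)
}

#' Independence (baseline) model fit
#'
#' The baseline constrains all correlations to zero (thresholds only), so
#' its discrepancy has the closed form `sum w_ij^{-1} s_ij^2` with
#' df = p(p-1)/2. Used by the incremental fit indices.
#'
#' @inheritParams fit_dwls
#' @return a `cfa_fit` with zero loadings.
#' @export
fit_baseline <- function(poly, spec, N, weights = c("dwls", "uls")) {
  weights <- match.arg(weights)
  S <- if (inherits(poly, "corr_matrix")) poly$values else as.matrix(poly)
  S <- S[spec$items, spec$items]
  p <- length(spec$items)
  if (weights == "dwls") {
    n_est <- if (inherits(poly, "corr_matrix") && is.finite(poly$n)) poly$n
             else N
    V <- attr(poly, "asymp_var")[spec$items, spec$items] * n_est
    Winv <- 1 / V
  } else Winv <- matrix(1, p, p)
  diag(Winv) <- 0
  F_min <- sum(Winv * S^2) / 2
  structure(list(loadings = stats::setNames(rep(0, p), spec$items),
                 phi = diag(length(spec$factors)), F_min = F_min,
                 chi_square = (N - 1) * F_min,
                 df = as.integer(p * (p - 1) / 2), N = N, converged = TRUE,
                 sample_corr = S,
                 implied = diag(p), spec = spec, weights = weights),
            class = "cfa_fit")
}

#' Fit indices from a fitted and a baseline model
#'
#' CFI, TLI, RMSEA (naive, from T = (N-1) F_min) and SRMR (root mean square
#' of the off-diagonal residual correlations).
#'
#' @param fit,baseline `cfa_fit` objects from the same estimator.
#' @param N sample size (defaults to `fit$N`).
#' @return list with `cfi`, `tli`, `rmsea`, `srmr`.
#' @export
fit_indices <- function(fit, baseline, N = fit$N) {
  Tm <- fit$chi_square; dfm <- fit$df
  Tb <- baseline$chi_square; dfb <- baseline$df
  cfi <- 1 - max(Tm - dfm, 0) / max(Tb - dfb, Tm - dfm, 0)
  tli <- ((Tb / dfb) - (Tm / dfm)) / ((Tb / dfb) - 1)
  rmsea <- if (dfm == 0) NA_real_ else
    sqrt(max(Tm - dfm, 0) / (dfm * (N - 1)))
  res <- fit$sample_corr - fit$implied
  srmr <- sqrt(mean(res[lower.tri(res)]^2))
  list(cfi = cfi, tli = tli, rmsea = rmsea, srmr = srmr)
}

#' Nested model comparison (constrained vs free correlations)
#'
#' @param fit_free unconstrained `cfa_fit`.
#' @param fit_constrained `cfa_fit` with one or more factor correlations
#'   fixed (must nest in the free model: larger df).
#' @param baseline optional baseline fit for index differences.
#' @return list with `delta_chi_square`, `delta_df`, `p_value`, `anomaly`
#'   (TRUE when the constrained statistic is smaller than the free one,
#'   a non-monotone estimation artefact), and `delta_indices` when a
#'   baseline is supplied.
#' @export
compare_nested <- function(fit_free, fit_constrained, baseline = NULL) {
  if (fit_constrained$df <= fit_free$df) {
    stop("constrained model must have more df than the free model",
         call. = FALSE)
  }
  d_chi <- fit_constrained$chi_square - fit_free$chi_square
  d_df <- fit_constrained$df - fit_free$df
  anomaly <- d_chi < 0
  p <- if (anomaly) NA_real_ else
    stats::pchisq(d_chi, df = d_df, lower.tail = FALSE)
  out <- list(delta_chi_square = d_chi, delta_df = d_df, p_value = p,
              anomaly = anomaly)
  if (!is.null(baseline)) {
    fi_f <- fit_indices(fit_free, baseline)
    fi_c <- fit_indices(fit_constrained, baseline)
    out$delta_indices <- list(cfi = fi_c$cfi - fi_f$cfi,
                              tli = fi_c$tli - fi_f$tli,
                              rmsea = fi_c$rmsea - fi_f$rmsea,
                              srmr = fi_c$srmr - fi_f$srmr)
  }
  out
}
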