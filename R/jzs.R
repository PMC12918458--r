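# Zellner-Siow (JZS) Bayes factors for linear regression, computed from the
# R-squared summary, which is sufficient under the standardized g-prior
# formulation. The Bayes factor of a p-predictor model against the
# intercept-only model is the one-dimensional integral over the mixing
# parameter g of
#   (1+g)^((n-p-1)/2) * (1 + g (1-R^2))^(-(n-1)/2)
# against an inverse-gamma(1/2, n r^2 / 2) density. All work is done on the
# log scale with a change of variables t = g/(1+g) onto (0, 1) and
# deterministic adaptive quadrature; no Monte Carlo is involved.

jzs_log_integrand <- function(g, r2, n, p, b) {
  # b = n * r_scale^2 / 2 ; inverse-gamma(1/2, b) log-density included
  0.5 * (n - p - 1) * log1p(g) -
    0.5 * (n - 1) * log1p(g * (1 - r2)) +
    0.5 * log(b) - lgamma(0.5) - 1.5 * log(g) - b / g
}

#' JZS Bayes factor of a regression model against the intercept-only model
#'
#' @param r2 coefficient of determination of the model (0 <= r2 < 1).
#' @param n sample size (> p + 1).
#' @param p number of predictors (p = 0 returns BF = 1 by convention).
#' @param r_scale prior scale of the Zellner-Siow Cauchy prior on the
#'   standardized effects; default `sqrt(2)/4`, the common "medium" prior
#'   for regression.
#' @return list with `bf10`, `log_bf10`, `error` (quadrature error estimate
#'   on the linear scale), `n`, `p`, `r_scale`.
#' @export
jzs_bf10 <- function(r2, n, p, r_scale = sqrt(2) / 4) {
  if (p == 0) {
    return(list(bf10 = 1, log_bf10 = 0, error = 0, n = n, p = 0L,
                r_scale = r_scale))
  }
  if (!is.finite(r2) || r2 < 0 || r2 >= 1) {
    stop("r2 must lie in [0, 1)", call. = FALSE)
  }
  if (n <= p + 1) stop("need n > p + 1", call. = FALSE)
  if (r_scale <= 0) stop("r_scale must be positive", call. = FALSE)
  b <- n * r_scale^2 / 2
  # locate the mode on the log(g) scale for stable shifting
  opt <- stats::optimize(function(u) jzs_log_integrand(exp(u), r2, n, p, b),
                         interval = c(-30, 30), maximum = TRUE)
  shift <- opt$objective
  f <- function(t) {
    g <- t / (1 - t)
    exp(jzs_log_integrand(g, r2, n, p, b) - shift) / (1 - t)^2
  }
  quad <- stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 0,
                           subdivisions = 500L)
  log_bf <- shift + log(quad$value)
  list(bf10 = exp(log_bf), log_bf10 = log_bf,
       error = exp(shift) * quad$abs.error, n = n, p = as.integer(p),
       r_scale = r_scale)
}

#' Omitted-predictor BF01
#'
#' Bayes factor of the reduced model (one predictor omitted) relative to the
#' full model: `BF01 = BF10(reduced) / BF10(full)`. Low values mark the
#' omitted predictor as important for that criterion.
#'
#' @param r2_full,r2_reduced model R-squared values; a reduced value
#'   slightly above the full one (rounding in printed tables) is clipped
#'   with a warning attribute rather than rejected.
#' @param n sample size.
#' @param p_full number of predictors in the full model (>= 2).
#' @param r_scale prior scale, as in [jzs_bf10].
#' @return list with `bf01`, `log_bf01`, `bf10_full`, `bf10_reduced`, and
#'   `r2_violation` (TRUE when r2_reduced exceeded r2_full).
#' @export
bf01_omitted <- function(r2_full, r2_reduced, n, p_full,
                         r_scale = sqrt(2) / 4) {
  if (p_full < 2) stop("full model needs >= 2 predictors", call. = FALSE)
  if (any(!is.finite(c(r2_full, r2_reduced))) ||
      r2_full < 0 || r2_full >= 1 || r2_reduced < 0 || r2_reduced >= 1) {
    stop("R-squared values must lie in [0, 1)", call. = FALSE)
  }
  violation <- r2_reduced > r2_full
  if (violation) r2_reduced <- r2_full
  full <- jzs_bf10(r2_full, n, p_full, r_scale)
  red <- jzs_bf10(r2_reduced, n, p_full - 1L, r_scale)
  log_bf01 <- red$log_bf10 - full$log_bf10
  list(bf01 = exp(log_bf01), log_bf01 = log_bf01,
       bf10_full = full$bf10, bf10_reduced = red$bf10,
       r2_violation = violation)
}

#' Three-category evidence classification of a BF01
#'
#' `BF01 >= 3` favors omitting the predictor, `BF01 <= 1/3` favors keeping
#' it, anything strictly between is inconclusive. Boundaries are closed
#' exactly as stated.
#'
#' @param bf01 positive Bayes factor(s).
#' @return character vector over {"favors-omission", "inconclusive",
#'   "favors-inclusion"}.
#' @export
classify_evidence <- function(bf01) {
  if (any(!is.finite(bf01)) || any(bf01 <= 0)) {
    stop("BF01 must be positive", call. = FALSE)
  }
  out <- rep("inconclusive", length(bf01))
  out[bf01 >= 3] <- "favors-omission"
  out[bf01 <= 1 / 3] <- "favors-inclusion"
  out
}

#' Omitted-predictor evidence table from regression summaries
#'
#' @param regressions data frame with columns `set`, `criterion`, `method`,
#'   `r2`, plus `r2_omit_<trait>` columns of reduced-model R-squared values.
#' @param traits trait labels (suffixes of the `r2_omit_` columns).
#' @param n sample size.
#' @param r_scale prior scale.
#' @return data frame of class `bf_evidence_table`: one row per
#'   (set, criterion, method, omitted trait) with `bf01` and `category`.
#' @export
bf_evidence_table <- function(regressions, traits, n,
                              r_scale = sqrt(2) / 4) {
  rows <- list()
  for (i in seq_len(nrow(regressions))) {
    for (tr in traits) {
      r2r <- regressions[[paste0("r2_omit_", tr)]][i]
      bf <- bf01_omitted(regressions$r2[i], r2r, n,
                         p_full = length(traits), r_scale = r_scale)
      # exp() underflows for decisive inclusion at large n; keep it positive
      bf01 <- max(bf$bf01, .Machine$double.xmin)
      rows[[length(rows) + 1L]] <- data.frame(
        set = regressions$set[i], criterion = regressions$criterion[i],
        method = regressions$method[i], omitted = tr, bf01 = bf01,
        log_bf01 = bf$log_bf01,
        category = classify_evidence(bf01), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bf_evidence_table", class(out))
  out
}
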