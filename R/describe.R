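#' Descriptive statistics with the +/-2 normality screen
#'
#' Computes the usual scale-screening descriptives: valid N, mean, standard
#' deviation, and the sample-adjusted skewness and excess kurtosis (Fisher's
#' G1 and G2, the SPSS/Excel convention). A flag records whether both shape
#' statistics fall inside the conventional +/-2 acceptability band used when
#' screening Likert scale scores for gross non-normality.
#'
#' @param values numeric vector; non-finite entries are dropped.
#' @return an object of class `nomo_descriptives`: a list with `n_valid`,
#'   `mean`, `sd`, `skewness`, `kurtosis` (excess), `undefined_moments`
#'   (TRUE when the input is constant so shape is undefined), and
#'   `in_range` (|skewness| <= 2 and |kurtosis| <= 2).
#' @examples
#' describe(c(1, 2, 3, 4, 5))
#' @export
describe <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 3L) stop("describe() needs at least 3 finite values", call. = FALSE)
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) {
    out <- list(n_valid = n, mean = m, sd = 0, skewness = NA_real_,
                kurtosis = NA_real_, undefined_moments = TRUE,
                in_range = NA)
    class(out) <- "nomo_descriptives"
    return(out)
  }
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  G1 <- b1 * sqrt(n * (n - 1)) / (n - 2)
  G2 <- ((n + 1) * (b2 - 3) + 6) * (n - 1) / ((n - 2) * (n - 3))
  out <- list(n_valid = n, mean = m, sd = s, skewness = G1, kurtosis = G2,
              undefined_moments = FALSE,
              in_range = abs(G1) <= 2 && abs(G2) <= 2)
  class(out) <- "nomo_descriptives"
  out
}

#' @export
print.nomo_descriptives <- function(x, ...) {
  cat(sprintf(
    "n = %d, mean = %.3f, sd = %.3f, skew = %.3f, kurtosis = %.3f (%s)\n",
    x$n_valid, x$mean, x$sd, x$skewness, x$kurtosis,
    if (isTRUE(x$in_range)) "within +/-2" else "outside +/-2 or undefined"))
  invisible(x)
}

#' Descriptives table for a dataset
#'
#' @param data data frame of numeric columns.
#' @return data frame with one row per column (n, mean, sd, skewness,
#'   kurtosis, in_range).
#' @export
describe_all <- function(data) {
  rows <- lapply(names(data), function(nm) {
    d <- describe(data[[nm]])
    data.frame(variable = nm, n = d$n_valid, mean = d$mean, sd = d$sd,
               skewness = d$skewness, kurtosis = d$kurtosis,
               in_range = isTRUE(d$in_range), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Standardized (ordinal) Cronbach's alpha from a correlation matrix
#'
#' Computes alpha as `k * rbar / (1 + (k - 1) * rbar)` where `rbar` is the
#' mean off-diagonal inter-item correlation of the selected items. Applied
#' to a Pearson matrix this is standardized alpha; applied to a polychoric
#' matrix it is the ordinal alpha commonly reported for Likert items.
#'
#' @param corr a [corr_matrix] object or plain correlation matrix with
#'   dimnames.
#' @param items character vector of item labels (>= 2), or NULL for all.
#' @return list with `alpha`, `k`, `rbar`, and `undefined` (TRUE when
#'   `rbar <= -1/(k-1)` so the formula has no meaningful value).
#' @export
cronbach_alpha <- function(corr, items = NULL) {
  R <- if (inherits(corr, "corr_matrix")) corr$values else corr
  if (is.null(items)) items <- colnames(R)
  if (length(items) < 2L) stop("alpha needs >= 2 items", call. = FALSE)
  missing_items <- setdiff(items, colnames(R))
  if (length(missing_items)) {
    stop("unknown items: ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  }
  Rs <- R[items, items, drop = FALSE]
  k <- length(items)
  rbar <- mean(Rs[lower.tri(Rs)])
  if (rbar <= -1 / (k - 1)) {
    return(list(alpha = NA_real_, k = k, rbar = rbar, undefined = TRUE))
  }
  list(alpha = k * rbar / (1 + (k - 1) * rbar), k = k, rbar = rbar,
       undefined = FALSE)
}
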