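# Convergent/discriminant validity statistics computed from a fitted MTMM
# CFA and the item correlation matrix.

#' Average variance extracted
#'
#' Mean squared standardized loading of one factor's items.
#'
#' @param loadings numeric vector of the factor's standardized loadings.
#' @return AVE, a value between 0 and 1.
#' @export
compute_ave <- function(loadings) {
  if (!length(loadings)) stop("need >= 1 loading", call. = FALSE)
  mean(loadings^2)
}

#' Fornell-Larcker discriminant-validity check
#'
#' A factor passes when the square root of its AVE strictly exceeds the
#' absolute value of its correlation with every other factor (ties fail).
#'
#' @param ave named vector of AVE values per factor.
#' @param phi factor correlation matrix over the same factors.
#' @return list with `pass` (named logical per factor), `sqrt_ave`, and
#'   `pairs`: data frame (f1, f2, sqrt_ave_f1, abs_corr, ok).
#' @export
fornell_larcker <- function(ave, phi) {
  factors <- names(ave)
  stopifnot(!is.null(factors), all(factors %in% colnames(phi)))
  phi <- phi[factors, factors]
  sq <- sqrt(ave)
  rows <- list()
  pass <- stats::setNames(rep(TRUE, length(factors)), factors)
  for (a in factors) {
    for (b in setdiff(factors, a)) {
      ok <- sq[a] > abs(phi[a, b])
      pass[a] <- pass[a] && ok
      rows[[length(rows) + 1L]] <- data.frame(
        f1 = a, f2 = b, sqrt_ave_f1 = unname(sq[a]),
        abs_corr = abs(phi[a, b]), ok = ok, stringsAsFactors = FALSE)
    }
  }
  list(pass = pass, sqrt_ave = sq, pairs = do.call(rbind, rows))
}

#' Heterotrait-monotrait (HTMT) ratio for a factor pair
#'
#' Ratio of the mean correlation between the two factors' item sets to a
#' within-set denominator. Two denominator conventions are exposed:
#' `"arithmetic"` (mean of the two within-set mean inter-item correlations)
#' and `"geometric"` (their geometric mean, the Henseler convention).
#'
#' @param item_corr [corr_matrix] (or plain matrix) over the items.
#' @param items_a,items_b item labels of the two factors (>= 2 each).
#' @param denominator "arithmetic" (default) or "geometric".
#' @return list with `htmt`, `between_mean`, `within_a`, `within_b`,
#'   `denominator`, and `undefined` (TRUE when the denominator is not
#'   positive, in which case `htmt` is NA).
#' @export
htmt <- function(item_corr, items_a, items_b,
                 denominator = c("arithmetic", "geometric")) {
  denominator <- match.arg(denominator)
  R <- if (inherits(item_corr, "corr_matrix")) item_corr$values else
    as.matrix(item_corr)
  if (length(items_a) < 2L || length(items_b) < 2L) {
    stop("both factors need >= 2 items", call. = FALSE)
  }
  missing_items <- setdiff(c(items_a, items_b), colnames(R))
  if (length(missing_items)) {
    stop("items not in correlation matrix: ",
         paste(missing_items, collapse = ", "), call. = FALSE)
  }
  between <- mean(R[items_a, items_b])
  wa <- R[items_a, items_a]; wa <- mean(wa[lower.tri(wa)])
  wb <- R[items_b, items_b]; wb <- mean(wb[lower.tri(wb)])
  den <- if (denominator == "arithmetic") (wa + wb) / 2 else {
    if (wa > 0 && wb > 0) sqrt(wa * wb) else -1
  }
  if (!is.finite(den) || den <= 0) {
    return(list(htmt = NA_real_, between_mean = between, within_a = wa,
                within_b = wb, denominator = denominator, undefined = TRUE))
  }
  list(htmt = between / den, between_mean = between, within_a = wa,
       within_b = wb, denominator = denominator, undefined = FALSE)
}

#' Validity table for a fitted MTMM CFA
#'
#' Per factor: AVE, sqrt(AVE), ordinal alpha (alpha on the polychoric item
#' matrix) and the Fornell-Larcker verdict; per same-trait cross-method
#' factor pair: the HTMT ratio and the .85 verdict.
#'
#' @param fit converged `cfa_fit`.
#' @param item_corr the polychoric [corr_matrix] the model was fitted to.
#' @param item_table data frame with columns `item`, `trait`, `method`
#'   (e.g. `spec$item_table` of the generating `mtmm_spec`).
#' @param htmt_denominator passed to [htmt].
#' @param htmt_threshold overlap threshold (default 0.85).
#' @return list of class `validity_table` with `factors` (data frame:
#'   factor, ave, sqrt_ave, alpha, fl_pass), `fornell_larcker_pairs`, and
#'   `htmt` (data frame: trait, method_a, method_b, htmt, overlapping).
#' @export
validity_table <- function(fit, item_corr, item_table,
                           htmt_denominator = "arithmetic",
                           htmt_threshold = 0.85) {
  stopifnot(isTRUE(fit$converged))
  spec <- fit$spec
  factors <- spec$factors
  ave <- vapply(factors, function(f) {
    compute_ave(fit$loadings[spec$assignment == f])
  }, numeric(1))
  alpha <- vapply(factors, function(f) {
    cronbach_alpha(item_corr, spec$items[spec$assignment == f])$alpha
  }, numeric(1))
  fl <- fornell_larcker(ave, fit$phi)
  traits <- unique(item_table$trait)
  methods <- unique(item_table$method)
  hrows <- list()
  if (length(methods) >= 2L) {
    for (tr in traits) {
      combs <- utils::combn(methods, 2L)
      for (k in seq_len(ncol(combs))) {
        ia <- item_table$item[item_table$trait == tr &
                                item_table$method == combs[1L, k]]
        ib <- item_table$item[item_table$trait == tr &
                                item_table$method == combs[2L, k]]
        h <- htmt(item_corr, ia, ib, denominator = htmt_denominator)
        hrows[[length(hrows) + 1L]] <- data.frame(
          trait = tr, method_a = combs[1L, k], method_b = combs[2L, k],
          htmt = h$htmt, overlapping = !is.na(h$htmt) &&
            h$htmt >= htmt_threshold, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(
    factors = data.frame(factor = factors, ave = unname(ave),
                         sqrt_ave = unname(sqrt(ave)),
                         alpha = unname(alpha),
                         fl_pass = unname(fl$pass), stringsAsFactors = FALSE),
    fornell_larcker_pairs = fl$pairs,
    htmt = if (length(hrows)) do.call(rbind, hrows) else NULL),
    class = "validity_table")
}
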