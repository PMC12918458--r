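# The three-step consistency framework: correlation-profile differences,
# explained-variance differences, profile intraclass correlations, pairwise
# Fisher z tests, and agreement of Bayes-factor conclusions, each judged
# against its stated cutoff.

#' Trait-criterion correlation profile
#'
#' @param trait,method labels.
#' @param criteria ordered criterion labels.
#' @param r correlations of the trait score with each criterion (|r| < 1).
#' @param n sample size.
#' @return object of class `corr_profile`.
#' @export
corr_profile <- function(trait, method, criteria, r, n) {
  stopifnot(length(criteria) == length(r), all(abs(r) < 1))
  structure(list(trait = trait, method = method, criteria = criteria,
                 r = stats::setNames(r, criteria), n = n),
            class = "corr_profile")
}

match_profiles <- function(a, b) {
  stopifnot(inherits(a, "corr_profile"), inherits(b, "corr_profile"))
  if (length(a$criteria) != length(b$criteria) ||
      !all(a$criteria == b$criteria)) {
    stop("profiles must cover identical criteria in identical order",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Mean absolute correlation difference of two profiles
#'
#' Default rule `"fisher"`: mean over criteria of the absolute difference of
#' Fisher z values, back-transformed by `tanh` onto the correlation metric
#' (where the .10 cutoff lives). Rule `"raw"`: mean absolute difference of
#' the raw correlations.
#'
#' @param a,b matched [corr_profile]s.
#' @param rule "fisher" (default) or "raw".
#' @return list with `delta_r_bar` and `rule`.
#' @export
delta_r_bar <- function(a, b, rule = c("fisher", "raw")) {
  rule <- match.arg(rule)
  match_profiles(a, b)
  d <- if (rule == "fisher") {
    tanh(mean(abs(atanh(a$r) - atanh(b$r))))
  } else {
    mean(abs(a$r - b$r))
  }
  list(delta_r_bar = unname(d), rule = rule)
}

#' Absolute difference of mean R-squared values
#'
#' `|mean(r2_a) - mean(r2_b)|` — the difference of the two means, not the
#' mean of per-criterion differences; this convention exactly reproduces
#' the bundled reference table's printed values.
#'
#' @param r2_a,r2_b equal-length vectors of model R-squared values.
#' @return scalar difference.
#' @export
delta_R2_bar <- function(r2_a, r2_b) {
  if (!length(r2_a) || length(r2_a) != length(r2_b)) {
    stop("need two non-empty equal-length R-squared vectors", call. = FALSE)
  }
  abs(mean(r2_a) - mean(r2_b))
}

#' Profile intraclass correlation
#'
#' Default rule `"double-entry"`: the Pearson correlation over the
#' double-entered pair vectors `[(a, b); (b, a)]`, computed on Fisher-z
#' transformed correlations (option `fisher = FALSE` uses raw r). A
#' two-way absolute-agreement single-measure ICC (`rule = "icc_a1"`) is
#' also available.
#'
#' @param a,b matched [corr_profile]s (>= 2 criteria).
#' @param rule "double-entry" (default) or "icc_a1".
#' @param fisher transform to Fisher z before computing (default TRUE).
#' @return list with `icc`, `rule`, `fisher`, and `undefined` (TRUE when
#'   the double-entered vectors have zero variance).
#' @export
profile_icc <- function(a, b, rule = c("double-entry", "icc_a1"),
                        fisher = TRUE) {
  rule <- match.arg(rule)
  match_profiles(a, b)
  if (length(a$criteria) < 2L) stop("need >= 2 criteria", call. = FALSE)
  x <- unname(a$r); y <- unname(b$r)
  if (fisher) { x <- atanh(x); y <- atanh(y) }
  if (rule == "double-entry") {
    u <- c(x, y); v <- c(y, x)
    if (stats::sd(u) == 0 || stats::sd(v) == 0) {
      return(list(icc = NA_real_, rule = rule, fisher = fisher,
                  undefined = TRUE))
    }
    icc <- stats::cor(u, v)
  } else {
    # two-way absolute agreement, single measures (criteria as rows,
    # profiles as the two raters)
    M <- cbind(x, y)
    n <- nrow(M); k <- 2
    ms_r <- k * stats::var(rowMeans(M))
    ms_c <- n * stats::var(colMeans(M))
    tot <- sum((M - mean(M))^2)
    ms_e <- (tot - ms_r * (n - 1) - ms_c * (k - 1)) / ((n - 1) * (k - 1))
    icc <- (ms_r - ms_e) /
      (ms_r + (k - 1) * ms_e + k / n * (ms_c - ms_e))
    if (!is.finite(icc)) {
      return(list(icc = NA_real_, rule = rule, fisher = fisher,
                  undefined = TRUE))
    }
  }
  list(icc = icc, rule = rule, fisher = fisher, undefined = FALSE)
}

#' Fisher z test comparing two correlations
#'
#' Independent-samples test: `z = (atanh(r_a) - atanh(r_b)) /
#' sqrt(1/(n_a-3) + 1/(n_b-3))` with a two-sided normal p-value. (Used for
#' replication even when both correlations come from one sample, where it
#' is conservative; a dependent-samples variant is out of scope here.)
#'
#' @param r_a,r_b correlations (|r| < 1).
#' @param n_a,n_b sample sizes (> 3).
#' @return list with `z` and `p_value`.
#' @export
compare_correlation_pair <- function(r_a, n_a, r_b, n_b) {
  if (any(abs(c(r_a, r_b)) >= 1)) stop("|r| must be < 1", call. = FALSE)
  if (n_a <= 3 || n_b <= 3) stop("need n > 3", call. = FALSE)
  z <- (atanh(r_a) - atanh(r_b)) / sqrt(1 / (n_a - 3) + 1 / (n_b - 3))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Steiger test for two dependent correlations sharing one variable
#'
#' Compares r(j,k) with r(j,h) measured on one sample of size n, where the
#' correlation r(k,h) between the two non-shared variables captures the
#' dependence (Steiger's Case A). Provided as the statistically appropriate
#' alternative to [compare_correlation_pair] for within-sample profile
#' comparisons; the replication output uses the independent test.
#'
#' @param r_jk,r_jh the two correlations being compared (|r| < 1).
#' @param r_kh correlation between the two non-shared variables.
#' @param n sample size (> 3).
#' @return list with `z` and `p_value`.
#' @export
compare_correlation_pair_dependent <- function(r_jk, r_jh, r_kh, n) {
  if (any(abs(c(r_jk, r_jh, r_kh)) >= 1)) stop("|r| must be < 1",
                                               call. = FALSE)
  if (n <= 3) stop("need n > 3", call. = FALSE)
  det_r <- 1 - r_jk^2 - r_jh^2 - r_kh^2 + 2 * r_jk * r_jh * r_kh
  cov_num <- r_kh * (1 - r_jk^2 - r_jh^2) -
    0.5 * r_jk * r_jh * (1 - r_jk^2 - r_jh^2 - r_kh^2)
  c_jkjh <- cov_num / ((1 - r_jk^2) * (1 - r_jh^2))
  if (det_r < 0) warning("correlations are not jointly consistent")
  z <- sqrt(n - 3) * (atanh(r_jk) - atanh(r_jh)) / sqrt(2 - 2 * c_jkjh)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Agreement percentage of two categorical conclusion sequences
#'
#' @param categories_a,categories_b equal-length vectors over the same
#'   (trait x criterion) cells.
#' @return percentage (0-100) of cells with identical categories.
#' @export
agreement_percentage <- function(categories_a, categories_b) {
  if (length(categories_a) != length(categories_b)) {
    stop("category sequences must have equal length", call. = FALSE)
  }
  if (!length(categories_a)) stop("empty category sequences", call. = FALSE)
  100 * mean(categories_a == categories_b)
}

#' Benchmark a criterion set against the consistency cutoffs
#'
#' Applies the five cutoffs with closed inequalities: `delta_r_bar <= .10`,
#' `delta_R2_bar <= .05`, every per-trait `icc >= .80`, every pairwise
#' z-test `p >= .05`, and `agreement >= 80`. A missing component yields a
#' `not-evaluable` flag, never a silent pass; the set-level verdict is the
#' conjunction of the evaluable flags and is NA if any flag is
#' not-evaluable.
#'
#' @param set criterion-set label.
#' @param delta_r named or plain scalar (or NULL if unavailable).
#' @param delta_R2 scalar or NULL.
#' @param icc named vector of per-trait profile ICCs or NULL.
#' @param z_p vector of pairwise z-test p-values or NULL.
#' @param agreement agreement percentage or NULL.
#' @return object of class `consistency_benchmark`: list with the inputs,
#'   per-metric `flags` (TRUE/FALSE/NA), and `overall`.
#' @export
evaluate_benchmarks <- function(set, delta_r = NULL, delta_R2 = NULL,
                                icc = NULL, z_p = NULL, agreement = NULL) {
  flag <- function(x, f) if (is.null(x) || anyNA(x)) NA else f(x)
  flags <- c(
    delta_r = flag(delta_r, function(x) x <= 0.10),
    delta_R2 = flag(delta_R2, function(x) x <= 0.05),
    icc = flag(icc, function(x) all(x >= 0.80)),
    z_tests = flag(z_p, function(x) all(x >= 0.05)),
    agreement = flag(agreement, function(x) x >= 80))
  overall <- if (anyNA(flags)) NA else all(flags)
  structure(list(set = set, delta_r = delta_r, delta_R2 = delta_R2,
                 icc = icc, z_p = z_p, agreement = agreement,
                 flags = flags, overall = overall),
            class = "consistency_benchmark")
}

#' @export
print.consistency_benchmark <- function(x, ...) {
  cat(sprintf("Consistency benchmarks for set '%s':\n", x$set))
  lab <- c(delta_r = "mean |delta r| <= .10",
           delta_R2 = "delta mean R^2 <= .05",
           icc = "profile ICC >= .80",
           z_tests = "all z-test p >= .05",
           agreement = "BF agreement >= 80%")
  for (nm in names(x$flags)) {
    v <- x$flags[[nm]]
    cat(sprintf("  %-24s %s\n", lab[[nm]],
                if (is.na(v)) "not-evaluable" else if (v) "pass" else "FAIL"))
  }
  invisible(x)
}

#' Consistency summary from published-style summary tables
#'
#' Fixture execution mode: starting from a regression summary table
#' (per criterion and method: standardized betas and R-squared) and an
#' omitted-predictor BF01 table, computes per-set `delta_R2_bar` and the
#' cross-method agreement percentage of BF conclusions. The raw-data-only
#' statistics (profile differences, ICCs, z tests) are marked
#' not-evaluable.
#'
#' @param regressions reference regression table
#'   (see [read_reference_regressions]).
#' @param bf01 reference BF01 table (see [read_reference_bf01]).
#' @param methods length-2 method labels, in (A, B) order.
#' @param traits trait labels; BF01 columns must be named
#'   `<method>_<trait>`.
#' @return list with `delta_R2` (named per set), `agreement` (named per
#'   set), and `benchmarks` (per-set [evaluate_benchmarks] results).
#' @export
consistency_from_tables <- function(regressions, bf01,
                                    methods = c("SD3", "DD"),
                                    traits = c("mach", "nar", "psych")) {
  sets <- unique(regressions$set)
  delta_R2 <- stats::setNames(numeric(length(sets)), sets)
  agreement <- stats::setNames(numeric(length(sets)), sets)
  for (s in sets) {
    ra <- regressions[regressions$set == s &
                        regressions$method == methods[1L], ]
    rb <- regressions[regressions$set == s &
                        regressions$method == methods[2L], ]
    rb <- rb[match(ra$criterion, rb$criterion), ]
    delta_R2[s] <- delta_R2_bar(ra$r2, rb$r2)
    bset <- bf01[bf01$set == s, ]
    ca <- cb <- character(0)
    for (tr in traits) {
      ca <- c(ca, classify_evidence(bset[[paste0(methods[1L], "_", tr)]]))
      cb <- c(cb, classify_evidence(bset[[paste0(methods[2L], "_", tr)]]))
    }
    agreement[s] <- agreement_percentage(ca, cb)
  }
  benchmarks <- lapply(sets, function(s) {
    evaluate_benchmarks(s, delta_R2 = delta_R2[[s]],
                        agreement = agreement[[s]])
  })
  names(benchmarks) <- sets
  list(delta_R2 = delta_R2, agreement = agreement, benchmarks = benchmarks)
}
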