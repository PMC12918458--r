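# Bundled reference tables: the published regression summaries
# (standardized betas and R-squared per criterion and method) and the
# published omitted-predictor BF01 table for the same criterion battery.
# The raw participant data behind them were never deposited, so these
# printed summaries are the only exact worked examples available; they feed
# the fixture execution mode and the generator's default criterion weights.

#' Read the bundled reference regression table
#'
#' @param path optional override; defaults to the installed copy.
#' @return data frame with columns set, criterion, method, beta_mach,
#'   beta_nar, beta_psych, r2.
#' @export
read_reference_regressions <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table1_regressions.tsv",
                                package = "nomoscan", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read the bundled reference BF01 table
#'
#' Censored entries printed as "<0.001" are parsed as 0.0005 (any value
#' below 0.001 classifies identically against the 1/3 and 3 thresholds);
#' the `censored_` columns record which cells were censored.
#'
#' @param path optional override; defaults to the installed copy.
#' @return data frame with columns set, criterion and one numeric BF01
#'   column per (method x omitted trait): SD3_mach .. DD_psych.
#' @export
read_reference_bf01 <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table3_bf01.tsv",
                                package = "nomoscan", mustWork = TRUE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  cols <- setdiff(names(raw), c("set", "criterion"))
  out <- raw[c("set", "criterion")]
  for (cc in cols) {
    cens <- raw[[cc]] == "<0.001"
    val <- suppressWarnings(as.numeric(raw[[cc]]))
    val[cens] <- 0.0005
    if (anyNA(val)) stop("unparseable BF01 cell in column ", cc,
                         call. = FALSE)
    out[[cc]] <- val
    out[[paste0("censored_", cc)]] <- cens
  }
  out
}
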