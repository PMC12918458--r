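# Dataset + codebook loading, scale scoring, orchestration of the full
# analysis, and report serialization.

#' Analysis configuration
#'
#' Collects every tunable rule in one validated object that is embedded
#' verbatim in reports for provenance.
#'
#' @param seed master integer seed.
#' @param missing "listwise" or "pairwise".
#' @param delta_rule rule for [delta_r_bar]: "fisher" or "raw".
#' @param icc_rule rule for [profile_icc]: "double-entry" or "icc_a1".
#' @param htmt_denominator "arithmetic" or "geometric".
#' @param bf_r_scale JZS prior scale.
#' @param run_cfa fit the MTMM CFA stage (the slowest stage); the
#'   consistency stages do not depend on it.
#' @param precision decimal places used in TSV output.
#' @return list of class `nomo_config`.
#' @export
analysis_config <- function(seed = 1L, missing = c("listwise", "pairwise"),
                            delta_rule = c("fisher", "raw"),
                            icc_rule = c("double-entry", "icc_a1"),
                            htmt_denominator = c("arithmetic", "geometric"),
                            bf_r_scale = sqrt(2) / 4, run_cfa = TRUE,
                            precision = 3L) {
  structure(list(seed = as.integer(seed), missing = match.arg(missing),
                 delta_rule = match.arg(delta_rule),
                 icc_rule = match.arg(icc_rule),
                 htmt_denominator = match.arg(htmt_denominator),
                 bf_r_scale = bf_r_scale, run_cfa = isTRUE(run_cfa),
                 precision = as.integer(precision)),
            class = "nomo_config")
}

#' Read a codebook (JSON or YAML)
#'
#' The codebook declares, per item column: scale, trait, method, response
#' range and reverse-coding flag; and per criterion column: its set label.
#'
#' @param path file ending in .json (read with jsonlite) or .yaml/.yml
#'   (requires the yaml package).
#' @return a `nomo_codebook` (see [build_codebook]).
#' @export
load_codebook <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML codebooks requires the 'yaml' package; ",
           "use JSON instead", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  items <- as.data.frame(raw$items, stringsAsFactors = FALSE)
  criteria <- as.data.frame(raw$criteria, stringsAsFactors = FALSE)
  need <- c("column", "scale", "trait", "method", "min", "max", "reverse")
  if (!all(need %in% names(items))) {
    stop("codebook items need fields: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(items$column)) {
    stop("duplicate item assignment: ",
         paste(unique(items$column[duplicated(items$column)]),
               collapse = ", "), call. = FALSE)
  }
  structure(list(items = items, criteria = criteria),
            class = "nomo_codebook")
}

#' Write a codebook next to a dataset
#'
#' @param codebook a `nomo_codebook`.
#' @param path output path (.json or .yaml).
#' @export
write_codebook <- function(codebook, path) {
  obj <- list(items = codebook$items, criteria = codebook$criteria)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("writing YAML requires the 'yaml' package", call. = FALSE)
    }
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Load a person x variable dataset with its codebook
#'
#' Items are coerced to integers, reverse-coded where flagged
#' (`min + max - x`), and out-of-range cells are set missing with a logged
#' count. Criterion columns are taken as numeric.
#'
#' @param data_path CSV of persons x item columns (criterion columns may
#'   also live here).
#' @param codebook_path codebook file (or a `nomo_codebook` object).
#' @param criteria_path optional CSV holding the criterion columns when they
#'   are stored separately from the items.
#' @return list with `items` (integer data frame), `criteria` (numeric data
#'   frame), `codebook`, `n`, `n_out_of_range`.
#' @export
load_dataset <- function(data_path, codebook_path, criteria_path = NULL) {
  cb <- if (inherits(codebook_path, "nomo_codebook")) codebook_path else
    load_codebook(codebook_path)
  dat <- utils::read.csv(data_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!is.null(criteria_path)) {
    cdat <- utils::read.csv(criteria_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    if (nrow(cdat) != nrow(dat)) {
      stop("criteria file has ", nrow(cdat), " rows but data has ",
           nrow(dat), call. = FALSE)
    }
    dat <- cbind(dat, cdat[setdiff(names(cdat), names(dat))])
  }
  missing_cols <- setdiff(cb$items$column, names(dat))
  if (length(missing_cols)) {
    stop("codebook references missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  missing_crit <- setdiff(cb$criteria$column, names(dat))
  if (length(missing_crit)) {
    stop("criterion columns not found (supply criteria_path?): ",
         paste(missing_crit, collapse = ", "), call. = FALSE)
  }
  n_oor <- 0L
  items <- as.data.frame(
    lapply(seq_len(nrow(cb$items)), function(i) {
      row <- cb$items[i, ]
      x <- dat[[row$column]]
      xi <- suppressWarnings(as.integer(x))
      if (any(is.na(xi) & !is.na(x))) {
        bad <- which(is.na(xi) & !is.na(x))[1L]
        stop(sprintf("unparseable cell at row %d, column '%s'", bad,
                     row$column), call. = FALSE)
      }
      oor <- !is.na(xi) & (xi < row$min | xi > row$max)
      n_oor <<- n_oor + sum(oor)
      xi[oor] <- NA_integer_
      if (isTRUE(row$reverse)) xi <- row$min + row$max - xi
      xi
    }), col.names = cb$items$column, check.names = FALSE)
  criteria <- dat[, cb$criteria$column, drop = FALSE]
  criteria[] <- lapply(criteria, as.numeric)
  list(items = items, criteria = criteria, codebook = cb, n = nrow(dat),
       n_out_of_range = n_oor)
}

#' Score scales as means of their items
#'
#' @param items integer item data frame (already reverse-coded).
#' @param codebook a `nomo_codebook`.
#' @return data frame with one column per scale (named `<method>_<trait>`),
#'   plus attributes `"trait"`/`"method"` vectors.
#' @export
score_scales <- function(items, codebook) {
  cbi <- codebook$items
  scales <- unique(cbi$scale)
  out <- as.data.frame(lapply(scales, function(s) {
    cols <- cbi$column[cbi$scale == s]
    rowMeans(items[, cols, drop = FALSE], na.rm = FALSE)
  }), col.names = scales, check.names = FALSE)
  attr(out, "trait") <- cbi$trait[match(scales, cbi$scale)]
  attr(out, "method") <- cbi$method[match(scales, cbi$scale)]
  out
}

#' Run the full measurement-equivalence analysis
#'
#' Stages run in order: descriptives -> scale scores and correlations ->
#' MTMM CFA and validity (optional) -> per-method regressions ->
#' omitted-predictor Bayes factors -> consistency benchmarks. The result is
#' deterministic given (dataset, config).
#'
#' @param dataset list with `items`, `criteria`, `codebook` (as produced by
#'   [load_dataset] or assembled from [simulate_mtmm] output).
#' @param config an [analysis_config].
#' @return list of class `nomo_analysis` with elements `config`,
#'   `descriptives`, `scales`, `cfa` (fit, baseline, indices, validity,
#'   nested; NULL when skipped), `profiles`, `regressions`, `bf_table`,
#'   `consistency`, `n`.
#' @export
run_full_analysis <- function(dataset, config = analysis_config()) {
  cb <- dataset$codebook
  items <- dataset$items
  criteria <- dataset$criteria
  n <- nrow(items)
  traits <- unique(cb$items$trait)
  methods <- unique(cb$items$method)
  if (length(methods) < 2L) {
    stop("analysis stage 'design': need >= 2 methods", call. = FALSE)
  }
  scales <- score_scales(items, cb)
  desc <- describe_all(cbind(scales, criteria))

  cfa_out <- NULL
  if (config$run_cfa) {
    cfa_out <- tryCatch(
      run_mtmm_cfa(items, cb, config),
      error = function(e) stop("analysis stage 'cfa' failed: ",
                               conditionMessage(e), call. = FALSE))
  }

  sets <- unique(cb$criteria$set)
  scale_names <- names(scales)
  sc_trait <- attr(scales, "trait")
  sc_method <- attr(scales, "method")
  analysis_data <- cbind(scales, criteria)
  if (config$missing == "listwise") {
    analysis_data <- analysis_data[stats::complete.cases(analysis_data), ,
                                   drop = FALSE]
  }
  pm <- pearson_matrix(analysis_data, use = config$missing)
  n_eff <- pm$n

  profiles <- list()
  for (m in methods) for (tr in traits) {
    sname <- scale_names[sc_trait == tr & sc_method == m]
    for (s in sets) {
      crit <- cb$criteria$column[cb$criteria$set == s]
      key <- paste(m, tr, s, sep = "|")
      profiles[[key]] <- corr_profile(
        tr, m, crit, pm$values[sname, crit], n_eff)
    }
  }

  regressions <- list()
  for (m in methods) {
    preds <- scale_names[sc_method == m]
    pred_traits <- sc_trait[sc_method == m]
    preds <- preds[match(traits, pred_traits)]  # predictors in trait order
    for (i in seq_len(nrow(cb$criteria))) {
      crit <- cb$criteria$column[i]
      full <- standardized_ols(pm, crit, preds, n_eff)
      omit_r2 <- vapply(seq_along(preds), function(j) {
        standardized_ols(pm, crit, preds[-j], n_eff)$r_squared
      }, numeric(1))
      regressions[[paste(m, crit, sep = "|")]] <- c(
        list(set = cb$criteria$set[i], method = m, fit = full),
        stats::setNames(as.list(omit_r2), paste0("r2_omit_", traits)))
    }
  }
  reg_df <- do.call(rbind, lapply(regressions, function(r) {
    row <- data.frame(set = r$set, criterion = r$fit$criterion,
                      method = r$method, r2 = r$fit$r_squared,
                      stringsAsFactors = FALSE)
    for (tr in traits) row[[paste0("r2_omit_", tr)]] <- r[[paste0("r2_omit_", tr)]]
    bet <- r$fit$beta
    for (j in seq_along(bet)) row[[paste0("beta_", traits[j])]] <- bet[[j]]
    row
  }))
  rownames(reg_df) <- NULL

  bf_table <- bf_evidence_table(reg_df, traits, n_eff,
                                r_scale = config$bf_r_scale)

  m1 <- methods[1L]; m2 <- methods[2L]
  consistency <- list()
  for (s in sets) {
    r_a <- unlist(lapply(traits, function(tr)
      profiles[[paste(m1, tr, s, sep = "|")]]$r))
    r_b <- unlist(lapply(traits, function(tr)
      profiles[[paste(m2, tr, s, sep = "|")]]$r))
    crit_all <- unlist(lapply(traits, function(tr)
      profiles[[paste(m1, tr, s, sep = "|")]]$criteria))
    pa <- corr_profile("all", m1, paste(seq_along(r_a)), r_a, n_eff)
    pb <- corr_profile("all", m2, paste(seq_along(r_b)), r_b, n_eff)
    dr <- delta_r_bar(pa, pb, rule = config$delta_rule)$delta_r_bar
    icc <- vapply(traits, function(tr) {
      # sets with a single criterion have no profile to correlate
      tryCatch(profile_icc(profiles[[paste(m1, tr, s, sep = "|")]],
                           profiles[[paste(m2, tr, s, sep = "|")]],
                           rule = config$icc_rule)$icc,
               error = function(e) NA_real_)
    }, numeric(1))
    zp <- mapply(function(ra, rb) {
      compare_correlation_pair(ra, n_eff, rb, n_eff)$p_value
    }, r_a, r_b)
    d_r2 <- delta_R2_bar(reg_df$r2[reg_df$set == s & reg_df$method == m1],
                         reg_df$r2[reg_df$set == s & reg_df$method == m2])
    cat_a <- bf_table$category[bf_table$set == s & bf_table$method == m1]
    cat_b <- bf_table$category[bf_table$set == s & bf_table$method == m2]
    agree <- agreement_percentage(cat_a, cat_b)
    consistency[[s]] <- list(
      benchmark = evaluate_benchmarks(s, delta_r = dr, delta_R2 = d_r2,
                                      icc = icc, z_p = zp,
                                      agreement = agree),
      z_cells = data.frame(cell = crit_all, p = zp,
                           stringsAsFactors = FALSE))
  }

  structure(list(config = config, descriptives = desc, scales = scales,
                 cfa = cfa_out, profiles = profiles, regressions = reg_df,
                 bf_table = bf_table, consistency = consistency, n = n_eff),
            class = "nomo_analysis")
}

run_mtmm_cfa <- function(items, cb, config) {
  keep <- stats::complete.cases(items)
  X <- items[keep, , drop = FALSE]
  poly <- polychoric_matrix(X)
  assignment <- stats::setNames(
    paste(cb$items$trait, cb$items$method, sep = "."), cb$items$column)
  spec <- cfa_model_spec(assignment)
  N <- nrow(X)
  fit <- fit_dwls(poly, spec, N, seed = config$seed)
  if (!isTRUE(fit$converged)) {
    stop("DWLS estimation did not converge", call. = FALSE)
  }
  base <- fit_baseline(poly, spec, N)
  idx <- fit_indices(fit, base)
  it <- data.frame(item = cb$items$column, trait = cb$items$trait,
                   method = cb$items$method, stringsAsFactors = FALSE)
  validity <- validity_table(fit, poly, it,
                             htmt_denominator = config$htmt_denominator)
  traits <- unique(cb$items$trait)
  methods <- unique(cb$items$method)
  nested <- list()
  if (length(methods) >= 2L) {
    for (tr in traits) {
      fixed <- data.frame(f1 = paste(tr, methods[1L], sep = "."),
                          f2 = paste(tr, methods[2L], sep = "."),
                          value = 1)
      spec_c <- cfa_model_spec(assignment, fixed_corr = fixed)
      fit_c <- fit_dwls(poly, spec_c, N, seed = config$seed)
      nested[[tr]] <- if (isTRUE(fit_c$converged)) {
        compare_nested(fit, fit_c, baseline = base)
      } else list(converged = FALSE)
    }
  }
  list(poly = poly, fit = fit, baseline = base, indices = idx,
       validity = validity, nested = nested)
}

#' Serialize an analysis bundle
#'
#' Writes `report.json` (full precision, stable key order) plus
#' human-readable TSV tables (`regressions.tsv`, `bf_table.tsv`,
#' `consistency.tsv`, `descriptives.tsv`) rounded to the configured
#' precision. The config and seed are embedded for provenance.
#'
#' @param analysis a `nomo_analysis`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pr <- analysis$config$precision
  cons_rows <- do.call(rbind, lapply(names(analysis$consistency), function(s) {
    b <- analysis$consistency[[s]]$benchmark
    data.frame(set = s, delta_r_bar = b$delta_r %||% NA_real_,
               delta_R2_bar = b$delta_R2 %||% NA_real_,
               min_icc = if (is.null(b$icc)) NA_real_ else min(b$icc),
               n_sig_z = if (is.null(b$z_p)) NA_integer_ else
                 sum(b$z_p < 0.05),
               agreement = b$agreement %||% NA_real_,
               overall = b$overall, stringsAsFactors = FALSE)
  }))
  report <- list(
    config = unclass(analysis$config),
    n = analysis$n,
    fit_indices = analysis$cfa$indices,
    chi_square = analysis$cfa$fit$chi_square,
    df = analysis$cfa$fit$df,
    validity = if (!is.null(analysis$cfa)) {
      list(factors = analysis$cfa$validity$factors,
           htmt = analysis$cfa$validity$htmt)
    },
    nested = analysis$cfa$nested,
    regressions = analysis$regressions,
    bf_table = as.data.frame(analysis$bf_table),
    consistency = cons_rows)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report, json_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  write_tsv <- function(df, name) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, pr)
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(json_path,
             write_tsv(analysis$regressions, "regressions.tsv"),
             write_tsv(as.data.frame(analysis$bf_table), "bf_table.tsv"),
             write_tsv(cons_rows, "consistency.tsv"),
             write_tsv(analysis$descriptives, "descriptives.tsv"))
  invisible(paths)
}
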