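# Ready-made generating models. The "sd3dd" preset mirrors the published
# two-inventory design: a 27-item five-point inventory (9 items per trait)
# and a 12-item seven-point inventory (4 items per trait), three correlated
# dark traits per method, cross-method same-trait latent correlations of
# .927 / .718 / .876, and standardized loadings spread over the printed
# per-subscale ranges. Heterotrait correlations are not printed in full and
# are set once to field-realistic values (higher within the 27-item method,
# whose discriminant validity is known to be weaker).

sd3dd_phi <- function() {
  traits <- c("mach", "nar", "psych")
  f <- c(paste0(traits, ".SD3"), paste0(traits, ".DD"))
  phi <- matrix(0.50, 6, 6, dimnames = list(f, f))
  phi[1:3, 1:3] <- 0.65
  phi[4:6, 4:6] <- 0.45
  cross <- c(mach = 0.927, nar = 0.718, psych = 0.876)
  for (i in 1:3) phi[i, i + 3] <- phi[i + 3, i] <- cross[i]
  diag(phi) <- 1
  phi
}

sd3dd_loadings <- function(strong = FALSE) {
  rng <- list(
    SD3 = list(mach = c(0.433, 0.810), nar = c(0.217, 0.642),
               psych = c(0.238, 0.731)),
    DD = list(mach = c(0.778, 0.850), nar = c(0.502, 0.819),
              psych = c(0.373, 0.786)))
  if (strong) {
    rng <- lapply(rng, function(m) lapply(m, function(x) c(0.60, 0.85)))
  }
  n_items <- c(SD3 = 9L, DD = 4L)
  unlist(lapply(names(rng), function(m) {
    unlist(lapply(rng[[m]], function(r) {
      seq(r[1], r[2], length.out = n_items[[m]])
    }))
  }), use.names = FALSE)
}

# Per-trait criterion weights taken from the bundled reference regression
# table (standardized betas of the named method), so the generator's
# criterion network reproduces a realistic published pattern.
reference_criterion_weights <- function(method = "SD3") {
  t1 <- read_reference_regressions()
  t1 <- t1[t1$method == method, ]
  list(criterion = t1$criterion, set = t1$set,
       weights = as.matrix(t1[, c("beta_mach", "beta_nar", "beta_psych")]))
}

#' Preset MTMM generating models
#'
#' * `"sd3dd"` — the two-inventory dark-triad design described above, with
#'   criteria weighted by the first method's reference betas on the first
#'   method's factors, plus a social-desirability criterion treated as an
#'   ordinary negatively-related external variable.
#' * `"sd3dd_divergent"` — same latent structure, but each criterion mixes
#'   the two methods' reference beta sets (half weight each on the two
#'   methods' factors), so criterion profiles diverge wherever the published
#'   betas diverge.
#' * `"equivalent"` — a method-equivalent world: both methods' items load on
#'   the same three trait factors with identical loadings, item counts and
#'   response formats, so every consistency metric has its ideal population
#'   value.
#' * `"strong"` — the sd3dd layout with uniformly strong loadings
#'   (.60-.85), used for parameter-recovery checks.
#'
#' @param preset preset name.
#' @param include_criteria attach the criterion network (default TRUE).
#' @return an `mtmm_spec`.
#' @export
default_mtmm_spec <- function(preset = c("sd3dd", "sd3dd_divergent",
                                         "equivalent", "strong"),
                              include_criteria = TRUE) {
  preset <- match.arg(preset)
  traits <- c("mach", "nar", "psych")
  if (preset == "equivalent") {
    methods <- list(SD3 = list(n_items = 6L, categories = 5L),
                    DD = list(n_items = 6L, categories = 5L))
    phi <- matrix(c(1, 0.45, 0.55, 0.45, 1, 0.35, 0.55, 0.35, 1), 3, 3,
                  dimnames = list(traits, traits))
    criteria <- NULL
    if (include_criteria) {
      rw <- reference_criterion_weights("SD3")
      W <- matrix(0, length(rw$criterion), 3,
                  dimnames = list(NULL, traits))
      W[, ] <- rw$weights
      colnames(W) <- paste0("w.", traits)
      criteria <- cbind(
        data.frame(criterion = rw$criterion, set = rw$set,
                   stringsAsFactors = FALSE),
        as.data.frame(W), residual_sd = NA_real_)
    }
    return(mtmm_model_spec(traits, methods, loadings = rep(0.7, 36),
                           phi = phi, criteria = criteria,
                           shared_traits = TRUE))
  }
  methods <- list(SD3 = list(n_items = 9L, categories = 5L),
                  DD = list(n_items = 4L, categories = 7L))
  phi <- sd3dd_phi()
  loadings <- sd3dd_loadings(strong = preset == "strong")
  factors <- c(paste0(traits, ".SD3"), paste0(traits, ".DD"))
  criteria <- NULL
  if (include_criteria) {
    rw <- reference_criterion_weights("SD3")
    if (preset == "sd3dd_divergent") {
      rwb <- reference_criterion_weights("DD")
      criteria <- criterion_weights_from_traits(
        rw$criterion, rw$set, rw$weights, traits, factors, "SD3",
        method_b = "DD", weights_b = rwb$weights)
    } else {
      criteria <- criterion_weights_from_traits(
        rw$criterion, rw$set, rw$weights, traits, factors, "SD3")
    }
    # social desirability as an ordinary correlated criterion
    mc <- criterion_weights_from_traits(
      "MC", "desirability", matrix(c(-0.25, -0.10, -0.25), 1), traits,
      factors, "SD3")
    criteria <- rbind(criteria, mc)
  }
  mtmm_model_spec(traits, methods, loadings = loadings, phi = phi,
                  criteria = criteria)
}

#' Codebook for a generated dataset
#'
#' @param spec an `mtmm_spec`.
#' @return list of class `nomo_codebook` with `items` (column, scale, trait,
#'   method, min, max, reverse) and `criteria` (column, set) data frames.
#' @export
build_codebook <- function(spec) {
  it <- spec$item_table
  items <- data.frame(column = it$item,
                      scale = paste(it$method, it$trait, sep = "_"),
                      trait = it$trait, method = it$method,
                      min = 1L, max = it$categories, reverse = FALSE,
                      stringsAsFactors = FALSE)
  criteria <- if (!is.null(spec$criteria)) {
    data.frame(column = spec$criteria$criterion, set = spec$criteria$set,
               stringsAsFactors = FALSE)
  } else {
    data.frame(column = character(), set = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(items = items, criteria = criteria),
            class = "nomo_codebook")
}
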