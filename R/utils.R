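#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed for a named random stream. One global integer seed
# per run; every operation that consumes randomness derives its own stream so
# that adding a stage never perturbs the draws of another.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (cc in utf8ToInt(stream)) h <- (h * 131 + cc) %% 2147480009
  as.integer((as.numeric(seed) %% 2147480009 * 48271 + h) %% 2147480009)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Nearest-PSD smoothing by eigenvalue clipping, rescaled back to unit
# diagonal. Pairwise-assembled polychoric matrices need not be jointly PSD.
smooth_psd <- function(mat, eps = 1e-8) {
  stopifnot(isSymmetric(unname(mat), tol = 1e-8))
  ee <- eigen(mat, symmetric = TRUE)
  if (min(ee$values) >= 0) return(mat)
  vals <- pmax(ee$values, eps)
  out <- ee$vectors %*% (vals * t(ee$vectors))
  out <- stats::cov2cor(out)
  dimnames(out) <- dimnames(mat)
  out
}

is_corr_matrix <- function(mat, tol = 1e-6) {
  is.matrix(mat) && nrow(mat) == ncol(mat) &&
    isSymmetric(unname(mat), tol = tol) &&
    all(abs(diag(mat) - 1) < tol) &&
    all(mat >= -1 - tol & mat <= 1 + tol)
}

check_pd <- function(mat, what = "matrix") {
  ev <- eigen(mat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf("%s is not positive definite (smallest eigenvalue %.3g)",
                 what, min(ev)), call. = FALSE)
  }
  invisible(min(ev))
}

lower_tri_pairs <- function(p) {
  idx <- which(lower.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
}
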