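# Small internal helpers shared across modules.

# Population (divide-by-n) standard deviation; the z-scoring convention used
# throughout the package (documented in the methods vignette).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Z-score a vector with the population SD convention.
zscore_vec <- function(x, label = "value") {
  s <- pop_sd(x)
  if (!is.finite(s) || s < .Machine$double.eps * max(1, abs(mean(x)))) {
    stop("degenerate input: '", label, "' has zero variance", call. = FALSE)
  }
  (x - mean(x)) / s
}

# Column-wise z-scoring of a matrix, population SD.
zscore_cols <- function(m, what = "column") {
  for (j in seq_len(ncol(m))) {
    lbl <- if (!is.null(colnames(m))) colnames(m)[j] else paste(what, j)
    m[, j] <- zscore_vec(m[, j], label = lbl)
  }
  m
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Derive a stream of child seeds from one integer seed, all below 2^31.
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Principal angles between two subspaces
#'
#' The principal angles (degrees) between the column spaces of two matrices
#' with the same number of rows, via the SVD of the product of their
#' orthonormal bases. Useful for comparing recovered latent axes with
#' planted ones.
#'
#' @param a,b Numeric matrices with equal row count.
#' @return Numeric vector of angles in degrees, one per paired dimension.
#' @export
principal_angles <- function(a, b) {
  qa <- qr.Q(qr(as.matrix(a)))
  qb <- qr.Q(qr(as.matrix(b)))
  d <- svd(crossprod(qa, qb))$d
  acos(pmin(1, pmax(-1, d))) * 180 / pi
}
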