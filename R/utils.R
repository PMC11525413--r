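`%||%` <- function(a, b) if (is.null(a)) b else a

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a replication seed from a base seed
#'
#' Deterministic integer hash used by the Monte-Carlo engine so that every
#' replication (and every redraw after a non-converged replication) gets its
#' own reproducible stream. Stays within the 32-bit integer range.
#'
#' @param base integer base seed.
#' @param rep replication index.
#' @param redraw redraw counter (0 for the first attempt).
#' @return a single integer seed.
#' @export
derive_seed <- function(base, rep, redraw = 0L) {
  h <- (as.double(base) %% 2147483647) * 48271 +
    as.double(rep) * 16807 + as.double(redraw) * 69621
  as.integer(h %% 2147483647) + 1L
}

## row-normalised unit-lower-triangle parameterization of a correlation
## matrix (matches the objective template exactly)
tr_to_cor <- function(x, p) {
  L <- diag(p)
  idx <- 1L
  if (p >= 2) {
    for (i in 2:p) {
      for (j in seq_len(i - 1)) {
        L[i, j] <- x[idx]
        idx <- idx + 1L
      }
      L[i, ] <- L[i, ] / sqrt(sum(L[i, seq_len(i)]^2))
    }
  }
  L %*% t(L)
}

cor_to_tr <- function(R) {
  p <- nrow(R)
  if (p < 2) return(numeric(0))
  L <- t(chol(R))
  x <- numeric(0)
  for (i in 2:p) {
    for (j in seq_len(i - 1)) x <- c(x, L[i, j] / L[i, i])
  }
  x
}
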