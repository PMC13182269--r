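# Internal numeric helpers shared across modules.

#' Log-sum-exp of the rows of a matrix
#'
#' Stable computation of `log(rowSums(exp(m)))`; rows that are entirely
#' `-Inf` return `-Inf` rather than `NaN`.
#' @param m numeric matrix.
#' @return numeric vector, one value per row.
#' @keywords internal
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

#' Central-difference Hessian of a scalar function
#'
#' @param fn scalar-valued function of a numeric vector.
#' @param x evaluation point.
#' @param eps relative step size.
#' @return symmetric numeric matrix.
#' @keywords internal
num_hessian <- function(fn, x, eps = 1e-4) {
  p <- length(x)
  h <- pmax(abs(x), 1) * eps
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    ei <- rep(0, p); ei[i] <- h[i]
    fpp <- fn(x + ei); fmm <- fn(x - ei)
    H[i, i] <- (fpp - 2 * f0 + fmm) / h[i]^2
    if (i < p) {
      for (j in seq.int(i + 1L, p)) {
        ej <- rep(0, p); ej[j] <- h[j]
        f1 <- fn(x + ei + ej); f2 <- fn(x + ei - ej)
        f3 <- fn(x - ei + ej); f4 <- fn(x - ei - ej)
        H[i, j] <- H[j, i] <- (f1 - f2 - f3 + f4) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

# Deterministic per-unit substream seed derived from a master seed, so the
# i-th subject's draws do not depend on how many other subjects are simulated.
substream_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
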