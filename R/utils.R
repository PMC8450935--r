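#' @useDynLib hydroshell, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cor.test lm coef rpois runif rnorm sd quantile setNames dist
#' @importFrom utils read.delim write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Minimum-image displacement
#'
#' Wraps displacement components into `[-L/2, L/2)` for an orthorhombic box.
#' Components with a non-positive box length are returned unchanged (no
#' periodicity in that direction).
#'
#' @param d numeric vector or matrix of displacements (nm).
#' @param box box lengths (nm), recycled across columns of `d`.
#' @return object shaped like `d`.
#' @keywords internal
min_image <- function(d, box) {
  if (is.matrix(d)) {
    for (k in seq_len(ncol(d))) {
      if (box[k] > 0) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    }
    d
  } else {
    ifelse(box > 0, d - box * round(d / box), d)
  }
}

# Shift coordinates so `center` sits at the box center, then wrap into [0, box).
wrap_about <- function(xyz, box, center) {
  shift <- box / 2 - center
  out <- sweep(xyz, 2, shift, "+")
  for (k in 1:3) out[, k] <- out[, k] %% box[k]
  out
}

#' Halton low-discrepancy sequence
#'
#' @param n number of points.
#' @param dim dimension (uses the first `dim` primes as bases).
#' @param skip number of initial points to drop.
#' @return an `n` x `dim` matrix in the unit cube.
#' @keywords internal
halton <- function(n, dim = 3, skip = 0) {
  primes <- c(2, 3, 5, 7, 11, 13)
  idx <- (skip + 1):(skip + n)
  out <- matrix(0, n, dim)
  for (d in seq_len(dim)) {
    b <- primes[d]
    i <- idx
    f <- 1
    h <- numeric(n)
    repeat {
      f <- f / b
      h <- h + f * (i %% b)
      i <- i %/% b
      if (all(i == 0)) break
    }
    out[, d] <- h
  }
  out
}

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch.
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = rev(e$values), weights = rev(2 * e$vectors[1, ]^2))
}

# Fibonacci (golden-spiral) unit sphere points: deterministic, near-uniform.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}
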