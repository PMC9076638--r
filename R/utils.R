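# Shared small helpers: angle wrapping, circular moments, seeded RNG streams.

#' Wrap angles to (-pi, pi]
#'
#' @param theta Numeric vector of angles in radians.
#' @return Angles wrapped to the half-open interval (-pi, pi].
#' @export
wrap_pi <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  # %% maps exact multiples of 2*pi to -pi; the convention here is (-pi, pi]
  out[out == -pi] <- pi
  out
}

#' Unwrap a phase time course
#'
#' Removes 2*pi jumps from a sampled phase series so it becomes continuous.
#'
#' @param theta Wrapped phase series, radians.
#' @return Unwrapped series starting at `theta[1]`.
#' @export
unwrap_phase <- function(theta) {
  if (length(theta) < 2) return(theta)
  theta[1] + c(0, cumsum(wrap_pi(diff(theta))))
}

# Resultant vector of a set of angles: complex mean of unit vectors.
circ_resultant <- function(theta, w = NULL) {
  if (is.null(w)) {
    mean(exp(1i * theta))
  } else {
    sum(w * exp(1i * theta)) / sum(w)
  }
}

#' Circular mean direction
#'
#' @param theta Angles in radians.
#' @param w Optional non-negative weights.
#' @return Mean direction in (-pi, pi]; `NA` when the resultant length is 0.
#' @export
circ_mean <- function(theta, w = NULL) {
  r <- circ_resultant(theta, w)
  if (Mod(r) < .Machine$double.eps^0.5) return(NA_real_)
  wrap_pi(Arg(r))
}

#' Mean resultant length
#'
#' @param theta Angles in radians.
#' @param w Optional non-negative weights.
#' @return Resultant length in `[0, 1]`.
#' @export
circ_r <- function(theta, w = NULL) Mod(circ_resultant(theta, w))

# Maximum-likelihood-ish kappa estimate from a resultant length
# (Fisher 1993 piecewise approximation).
circ_kappa <- function(rbar) {
  if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    r <- min(rbar, 1 - 1e-8)
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); kappa = 0 falls
# back to the uniform distribution. Uses the session RNG stream.
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(wrap_pi(runif(n, -pi, pi)))
  if (kappa > 1e6) return(rep(wrap_pi(mu), n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_pi(mu + out)
}

# Derive a reproducible child seed from a master seed and a stream label.
# Keeps results independent across stages while fully determined by the
# master seed. Result is always a valid 32-bit integer seed.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- substr(rlang::hash(key), 1, 7)
  as.integer(strtoi(h, base = 16L) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_invalid <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "ispcmed_invalid_argument")
}
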