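# Internal helpers: local RNG scoping, seed derivation, circular statistics.

# Run code under a fixed seed without touching the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed for a named generator stage; stays inside 32-bit
# range (the multiply stays exact in doubles: 2^31 * 48271 < 2^53).
derive_seed <- function(seed, salt) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + salt) %% 2147483647)
}

stop_param <- function(msg, call. = FALSE) stop(msg, call. = call.)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_param(sprintf("`%s` must be a single positive finite number (got %s)",
                       name, paste(format(x), collapse = ",")))
  invisible(x)
}

#' Circular-statistics helpers
#'
#' Small utilities used throughout the phase analyses: [wrap_pi()] wraps
#' angles to (-pi, pi], [circ_mean()] is the mean direction, [circ_r()] the
#' mean resultant length (the quantity ITPC reports), and [circ_dist()] the
#' smallest absolute angular difference.
#'
#' @param x,theta,a,b angles in radians.
#' @return numeric vector (or scalar for the summaries).
#' @export
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' @rdname wrap_pi
#' @export
circ_mean <- function(theta) {
  Arg(mean(exp(1i * theta)))
}

#' @rdname wrap_pi
#' @export
circ_r <- function(theta) {
  Mod(mean(exp(1i * theta)))
}

#' @rdname wrap_pi
#' @export
circ_dist <- function(a, b) abs(wrap_pi(a - b))

# von Mises sampler via inverse-CDF interpolation on a fine grid; vectorised,
# one uniform draw per sample (keeps draw counts deterministic).
rvonmises <- function(n, mu, kappa, ngrid = 8192L) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  th <- seq(-pi, pi, length.out = ngrid)
  dens <- exp(kappa * (cos(th - mu) - 1))
  cdf <- cumsum(dens)
  cdf <- (cdf - cdf[1]) / (cdf[ngrid] - cdf[1])
  u <- runif(n)
  wrap_pi(stats::approx(cdf, th, xout = u, ties = "ordered")$y)
}

# 1/f ("pink") noise of unit standard deviation via spectral shaping of white noise.
pink_noise <- function(n) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- c(1, seq_len(n - 1))            # guard DC
  k <- pmin(k, n - k + 1)              # symmetric frequency index
  s <- 1 / sqrt(k)
  s[1] <- 0
  y <- Re(stats::fft(X * s, inverse = TRUE)) / n
  y / stats::sd(y)
}
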