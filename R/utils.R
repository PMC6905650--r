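# internal numerical helpers

# clip into [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# time grid from t0 to at least tmax with step h (last point exactly tmax)
time_grid <- function(t0, tmax, h) {
  if (tmax <= t0) return(c(t0, t0))
  g <- seq(t0, tmax, by = h)
  if (g[length(g)] < tmax) g <- c(g, tmax)
  g
}

# cumulative composite Simpson integral of y sampled on a uniform grid x;
# returns the integral from x[1] to each x[i] (O(h^4), fully vectorised).
# Odd grid points carry exact composite Simpson sums over panel pairs; even
# points add a backward quadratic half-panel from the preceding odd point.
cum_simpson <- function(x, y) {
  n <- length(x)
  out <- numeric(n)
  if (n < 2) return(out)
  h <- x[2] - x[1]
  if (n == 2) return(c(0, h * (y[1] + y[2]) / 2))
  odd <- seq(3, n, by = 2)
  out[odd] <- cumsum(h / 3 * (y[odd - 2] + 4 * y[odd - 1] + y[odd]))
  ev <- seq(2, n, by = 2)
  if (length(ev) > 0) {
    half <- h / 12 * (-y[pmax(ev - 2, 1)] + 8 * y[ev - 1] + 5 * y[ev])
    half[1] <- h / 12 * (5 * y[1] + 8 * y[2] - y[3])
    out[ev] <- out[ev - 1] + half
    out[2] <- half[1]
  }
  out
}

# Gauss-Legendre nodes/weights on [0, 1], cached
gl_unit <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      gl <- pracma::gaussLegendre(n, 0, 1)
      cache[[key]] <<- gl
    }
    cache[[key]]
  }
})

# format a number to k significant figures as numeric
signif_sf <- function(x, k = 2) signif(x, k)

`%||%` <- function(a, b) if (is.null(a)) b else a
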