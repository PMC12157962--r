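#' Scrambled Halton draws for simulated likelihood
#'
#' Standard-normal quasi-random draws used to simulate the mixing
#' distribution of the random coefficients: one Halton sequence per random
#' dimension (consecutive primes as bases, first 100 points discarded),
#' randomised by a seeded uniform shift modulo 1 (Tuffin scrambling), then
#' mapped through the normal quantile function. Each respondent receives a
#' contiguous block of `R` draws that is held fixed across likelihood
#' evaluations.
#'
#' @param n_resp number of respondents.
#' @param R draws per respondent.
#' @param q number of random dimensions.
#' @param seed integer seed for the shifts.
#' @param scramble apply the random shift (default TRUE); without it the
#'   draws are the raw Halton points.
#' @param antithetic pair every draw with its negation (default TRUE), so
#'   the draw set is symmetric: the simulated likelihood is then exactly
#'   invariant to the sign of any heterogeneity SD, and variance is reduced.
#'   With an odd `R` the final draw of each respondent is unpaired.
#' @return array of dimension `c(q, R, n_resp)`.
#' @export
halton_normal_draws <- function(n_resp, R, q, seed = 1, scramble = TRUE,
                                antithetic = TRUE) {
  if (R < 1) stop("need at least one draw per respondent", call. = FALSE)
  if (q < 1) stop("need at least one random dimension", call. = FALSE)
  burn <- 100L
  Rh <- if (antithetic) ceiling(R / 2) else R
  n <- n_resp * Rh
  bases <- first_primes(q)
  shifts <- if (scramble) with_seed(seed, stats::runif(q)) else rep(0, q)
  out <- array(0, dim = c(q, R, n_resp))
  for (k in seq_len(q)) {
    u <- (halton_sequence(n + burn, bases[k])[(burn + 1L):(burn + n)] + shifts[k]) %% 1
    # guard the tails before the normal quantile map
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    z <- matrix(stats::qnorm(u), nrow = Rh)           # Rh x n_resp
    if (antithetic) {
      zz <- matrix(0, 2 * Rh, n_resp)
      zz[seq(1, 2 * Rh, by = 2), ] <- z
      zz[seq(2, 2 * Rh, by = 2), ] <- -z
      out[k, , ] <- zz[seq_len(R), ]
    } else {
      out[k, , ] <- z
    }
  }
  out
}

# radical-inverse (van der Corput) sequence in the given base, points 1..n
halton_sequence <- function(n, base) {
  h <- numeric(n)
  i <- seq_len(n)
  f <- 1 / base
  while (any(i > 0)) {
    h <- h + (i %% base) * f
    i <- i %/% base
    f <- f / base
  }
  h
}

first_primes <- function(q) {
  p <- integer(0)
  x <- 2L
  while (length(p) < q) {
    if (all(x %% p != 0L)) p <- c(p, x)
    x <- x + 1L
  }
  p
}
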