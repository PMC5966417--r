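## Deterministic analytic test processes: every analysis stage can be
## verified against closed forms without running long simulations.

#' Generate a coupled pair of symbol series
#'
#' Known-dependence processes over the 5-symbol alphabet `0:4`:
#' \describe{
#'   \item{`iid_uniform`}{`x` and `y` independent i.i.d. uniform; analytic
#'     transfer entropy is 0 in both directions.}
#'   \item{`lag1_copy`}{`y_t = x_{t-1}` (first `y` uniform); analytic
#'     `T_{x -> y} = log2(5)` bits, `T_{y -> x} = 0`.}
#'   \item{`coupled_markov`}{`y_{t+1}` copies `x_t` with probability
#'     `1 - eps`, else uniform; analytic
#'     `T_{x -> y} = log2(5) - H(channel)` (see
#'     [analytic_te_coupled_markov()]). `eps = 1` reduces to `iid_uniform`.}
#' }
#'
#' @param kind One of `"iid_uniform"`, `"lag1_copy"`, `"coupled_markov"`.
#' @param length Series length (>= 2).
#' @param seed Optional seed; if `NULL`, uses the current RNG state.
#' @param eps Noise level for `coupled_markov` (in `[0, 1]`).
#' @param alphabet Alphabet size (default 5).
#' @return A list with integer vectors `x` and `y`.
#' @export
make_pair <- function(kind = c("iid_uniform", "lag1_copy", "coupled_markov"),
                      length, seed = NULL, eps = 0.1, alphabet = 5L) {
  kind <- match.arg(kind)
  stopifnot(length >= 2, eps >= 0, eps <= 1)
  if (!is.null(seed)) set.seed(seed)
  runit <- function(n) sample.int(alphabet, n, replace = TRUE) - 1L
  x <- runit(length)
  y <- switch(kind,
    iid_uniform = runit(length),
    lag1_copy = c(runit(1L), x[-length]),
    coupled_markov = {
      noise <- stats::runif(length) < eps
      y <- c(x[1], x[-length])  # lag-1 copy backbone
      y[noise] <- runit(sum(noise))
      y[1] <- runit(1L)
      y
    })
  list(x = x, y = y)
}

#' Analytic transfer entropy of the noisy lag-1 copy channel
#'
#' For `y_{t+1} = x_t` with probability `1 - eps` and uniform otherwise,
#' on an alphabet of size `k`, the channel distribution puts mass
#' `1 - eps + eps/k` on the copied symbol and `eps/k` on each other symbol,
#' so `T_{x -> y} = log2(k) - H(channel)` bits.
#'
#' @param eps Noise level in `[0, 1]`.
#' @param alphabet Alphabet size (default 5).
#' @return Transfer entropy in bits.
#' @export
analytic_te_coupled_markov <- function(eps, alphabet = 5L) {
  k <- alphabet
  p_hit <- 1 - eps + eps / k
  p_miss <- eps / k
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  h_channel <- -(plogp(p_hit) + (k - 1) * plogp(p_miss))
  log2(k) - h_channel
}

#' Generate an analytic trend series
#'
#' Real-valued series with closed-form darwin rates:
#' \describe{
#'   \item{`exp_trend`}{`v_t = v0 * exp(r * t)`: rate exactly `r` at every
#'     measurement interval (the directional regime).}
#'   \item{`alternating`}{`a, b, a, b, ...`: rate magnitude
#'     `|ln(b/a)| / dt` at odd intervals, 0 at even ones (the fluctuation
#'     regime, inversely proportional to the interval).}
#'   \item{`constant`}{all values `c`: every rate 0.}
#' }
#'
#' @param kind One of `"exp_trend"`, `"alternating"`, `"constant"`.
#' @param length Series length (>= 2).
#' @param r Growth rate per generation (`exp_trend`).
#' @param v0 Initial value (`exp_trend`).
#' @param a,b Alternating values.
#' @param c Constant value.
#' @return A numeric vector.
#' @export
make_trend <- function(kind = c("exp_trend", "alternating", "constant"),
                       length, r = 0.01, v0 = 1, a = 1, b = exp(1), c = 1) {
  kind <- match.arg(kind)
  stopifnot(length >= 2)
  switch(kind,
    exp_trend = v0 * exp(r * (seq_len(length) - 1)),
    alternating = rep_len(c(a, b), length),
    constant = rep.int(c, length))
}
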