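#' Draw Polya-Gamma random variates
#'
#' Samples from the Polya-Gamma distribution PG(b, c), the auxiliary-variable
#' law that renders logistic and negative-binomial likelihoods conditionally
#' Gaussian. The default sampler is a hybrid: exact Devroye-type rejection for
#' unit shapes (summed for integer shapes up to 12), a two-moment gamma match
#' for fractional remainders and intermediate shapes, and a normal
#' approximation for shapes above 170. `method = "series"` instead uses a
#' truncated sum-of-gammas representation (with an exact mean correction for
#' the dropped tail), useful as an independent cross-check.
#'
#' @param n number of draws.
#' @param b shape parameter(s), positive real (recycled).
#' @param c tilt parameter(s) (recycled); the distribution is symmetric in `c`.
#' @param method `"hybrid"` (default) or `"series"`.
#' @param nterms number of series terms when `method = "series"`.
#' @return numeric vector of `n` positive draws.
#' @examples
#' set.seed(1)
#' mean(rpolyagamma(1e4, 1, 0)) # close to 1/4
#' @export
rpolyagamma <- function(n, b = 1, c = 0, method = c("hybrid", "series"),
                        nterms = 200L) {
  method <- match.arg(method)
  .assert(is.numeric(b) && all(is.finite(b)) && all(b > 0),
          "'b' must be positive and finite")
  .assert(is.numeric(c) && all(is.finite(c)), "'c' must be finite")
  b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n)
  if (method == "hybrid") .rpg_hybrid(b, c) else .rpg_series(b, c, nterms)
}

#' Polya-Gamma moments
#'
#' Closed-form mean `b/(2c) tanh(c/2)` (limit `b/4` at `c = 0`) and variance
#' `b (sinh(c) - c) / (4 c^3 cosh^2(c/2))` (limit `b/24`).
#'
#' @param b,c distribution parameters (recycled).
#' @return for `pg_mean`/`pg_var`, a numeric vector.
#' @export
pg_mean <- function(b, c = 0) {
  k <- max(length(b), length(c))
  .pg_moments(rep_len(as.numeric(b), k), rep_len(as.numeric(c), k))[, 1]
}

#' @rdname pg_mean
#' @export
pg_var <- function(b, c = 0) {
  k <- max(length(b), length(c))
  .pg_moments(rep_len(as.numeric(b), k), rep_len(as.numeric(c), k))[, 2]
}
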