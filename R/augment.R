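#' Transform a mixed-type response to its conditionally Gaussian pseudo-data
#'
#' Given a Polya-Gamma auxiliary draw `psi`, maps an outcome to the
#' transformed response used by the factor-model likelihood: continuous
#' outcomes are returned unchanged; a binary outcome becomes
#' `(y - 0.5) / psi`; a count outcome becomes `(y - 0.5 (y + r)) / psi`,
#' i.e. `(y - r) / (2 psi)`, the standard negative-binomial pseudo-response.
#' The pseudo-datum has conditional precision `psi` for discrete outcomes.
#'
#' @param y outcome value(s).
#' @param outcome_type one of `"continuous"`, `"binary"`, `"count"`.
#' @param psi positive Polya-Gamma draw(s); required for discrete types.
#' @param r negative-binomial dispersion (successes); required for counts.
#' @return transformed response, same length as `y`.
#' @examples
#' augment_response(1, "binary", psi = 0.5) # (1 - 0.5) / 0.5 = 1
#' @export
augment_response <- function(y, outcome_type = c("continuous", "binary", "count"),
                             psi = NULL, r = NULL) {
  outcome_type <- match.arg(outcome_type)
  .assert(is.numeric(y) && all(is.finite(y)), "'y' must be finite numeric")
  if (outcome_type == "continuous") return(y)
  .assert(!is.null(psi) && all(psi > 0), "'psi' must be positive for discrete outcomes")
  psi <- rep_len(psi, length(y))
  if (outcome_type == "binary") {
    .assert(all(y %in% c(0, 1)), "binary outcome must be coded 0/1")
    return((y - 0.5) / psi)
  }
  .assert(all(y >= 0) && all(y == round(y)), "count outcome must be a non-negative integer")
  .assert(!is.null(r) && all(r > 0), "'r' must be positive for count outcomes")
  xi <- y + rep_len(r, length(y))
  (y - 0.5 * xi) / psi
}

#' Gibbs update of the negative-binomial dispersion
#'
#' One draw of the dispersion `r` (number of successes) of a
#' negative-binomial outcome column with logit-scale linear predictor
#' `linear_pred`, via Chinese-restaurant-table latent counts and a conjugate
#' gamma prior: `r | l ~ Gamma(shape + sum(l), rate + sum(log(1 + e^eta)))`.
#' The Polya-Gamma auxiliaries are marginalized in this conditional, so the
#' draw must be followed by a fresh `psi` draw (the joint sampler does this).
#'
#' @param y_col non-negative integer counts.
#' @param linear_pred logit-scale linear predictor, same length as `y_col`.
#' @param r_current current dispersion value (returned unchanged when `fixed`).
#' @param prior `c(shape, rate)` of the gamma prior; default `c(1, 0.01)`.
#' @param fixed if `TRUE`, return `r_current` without sampling.
#' @return a positive scalar draw.
#' @export
update_r <- function(y_col, linear_pred, r_current, prior = c(1, 0.01),
                     fixed = FALSE) {
  .assert(all(y_col >= 0) && all(y_col == round(y_col)),
          "'y_col' must be non-negative integers")
  .assert(length(linear_pred) == length(y_col), "length mismatch")
  .assert(is.finite(r_current) && r_current > 0, "'r_current' must be positive")
  if (fixed) return(r_current)
  l <- vapply(seq_along(y_col), function(i) {
    yi <- y_col[i]
    if (yi == 0) return(0L)
    t <- seq_len(yi)
    sum(runif(yi) < r_current / (r_current + t - 1))
  }, integer(1))
  softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmax(x, -30))))
  rate <- prior[2] + sum(softplus(linear_pred))
  max(rgamma(1, shape = prior[1] + sum(l), rate = rate), 1e-3)
}
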