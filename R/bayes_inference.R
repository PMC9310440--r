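# Bayesian machinery: Uniform(0, a) likelihood, its Pareto(b, K) conjugate
# prior with the closed-form posterior update, discrete posterior
# normalisation, and Monte-Carlo conditional-probability estimation with
# binomial Monte-Carlo error.
#
# The published description invokes MCMC by name but specifies only direct
# Monte-Carlo counting over the simulated cohort; estimate_conditional()
# implements exactly that (no Markov chain).

#' Pareto prior parameters
#'
#' Scale/shape pair (b, K) of the Pareto conjugate prior for the upper
#' bound of a Uniform(0, a) likelihood.
#'
#' @param b Positive scale (support lower bound).
#' @param k Positive shape.
#' @return An object of class `pareto_params`.
#' @export
pareto_params <- function(b, k) {
  if (!is.numeric(b) || b <= 0 || !is.numeric(k) || k <= 0) {
    stop("Pareto parameters require b > 0 and k > 0", call. = FALSE)
  }
  structure(list(b = b, k = k), class = "pareto_params")
}

#' @export
print.pareto_params <- function(x, ...) {
  cat(sprintf("Pareto(b = %g, K = %g)\n", x$b, x$k))
  invisible(x)
}

#' Uniform(0, a) density
#'
#' `1/a` on `[0, a]`, zero elsewhere.
#'
#' @param x Evaluation points (vectorised).
#' @param a Positive upper support bound.
#' @return Density values.
#' @export
uniform_pdf <- function(x, a) {
  if (!is.numeric(a) || length(a) != 1L || a <= 0) {
    stop("uniform upper bound a must be > 0", call. = FALSE)
  }
  ifelse(x >= 0 & x <= a, 1 / a, 0)
}

#' Uniform likelihood of an i.i.d. sample
#'
#' Product of [uniform_pdf()] over all observations: `a^(-n)` when every
#' observation lies in `[0, a]`, zero otherwise; 1 for an empty sample.
#'
#' @param y Numeric vector of observations.
#' @param a Positive upper support bound.
#' @return Likelihood value.
#' @export
likelihood <- function(y, a) {
  prod(uniform_pdf(y, a))
}

#' Pareto(b, K) density
#'
#' `K b^K / a^(K+1)` for `a >= b`, zero otherwise.
#'
#' @param a Evaluation points (vectorised).
#' @param prior A [pareto_params()].
#' @return Density values.
#' @export
pareto_pdf <- function(a, prior) {
  stopifnot(inherits(prior, "pareto_params"))
  ifelse(a >= prior$b, prior$k * prior$b^prior$k / a^(prior$k + 1), 0)
}

#' Conjugate posterior update for the uniform upper bound
#'
#' With a Pareto(b, K) prior on the Uniform(0, a) upper bound and n
#' nonnegative observations y, the posterior is
#' Pareto(max(b, max(y)), K + n). An empty sample returns the prior.
#'
#' @param prior A [pareto_params()].
#' @param y Numeric vector of observations, all >= 0.
#' @return A [pareto_params()] holding the posterior.
#' @export
#' @examples
#' pareto_posterior_update(pareto_params(1, 2), c(0.5, 0.8))  # Pareto(1, 4)
pareto_posterior_update <- function(prior, y) {
  stopifnot(inherits(prior, "pareto_params"))
  if (length(y) == 0L) return(prior)
  if (anyNA(y) || any(y < 0)) {
    stop("observations must be nonnegative", call. = FALSE)
  }
  pareto_params(max(prior$b, max(y)), prior$k + length(y))
}

#' Discrete posterior from prior and likelihood
#'
#' Normalised elementwise product over a finite hypothesis space
#' (the model's nodes are binary, so discrete spaces suffice).
#'
#' @param prior Named numeric vector of prior probabilities, summing to 1.
#' @param lik Named numeric vector of nonnegative likelihood values over the
#'   same hypotheses.
#' @return Named numeric vector of posterior probabilities, summing to 1.
#' @export
posterior_from_likelihood <- function(prior, lik) {
  if (length(prior) != length(lik)) {
    stop("prior and likelihood must cover the same hypotheses",
         call. = FALSE)
  }
  if (!is.null(names(prior)) && !is.null(names(lik))) {
    if (!setequal(names(prior), names(lik))) {
      stop("prior and likelihood hypothesis names disagree", call. = FALSE)
    }
    lik <- lik[names(prior)]
  }
  .check_prob(prior, "prior")
  if (abs(sum(prior) - 1) > 1e-8) {
    stop("prior probabilities must sum to 1", call. = FALSE)
  }
  if (any(lik < 0)) stop("likelihood values must be nonnegative",
                         call. = FALSE)
  w <- prior * lik
  if (sum(w) <= 0) {
    stop("degenerate evidence: all prior x likelihood products are zero",
         call. = FALSE)
  }
  w / sum(w)
}

#' Monte-Carlo error of an estimated proportion
#'
#' The binomial standard error `sqrt(p (1 - p) / n)` of a probability
#' estimated by counting over n simulated samples.
#'
#' @param p Estimated probability.
#' @param n Number of samples (>= 1).
#' @return Nonnegative real.
#' @export
monte_carlo_error <- function(p, n) {
  .check_prob(p, "p")
  if (!is.numeric(n) || any(n < 1) || any(n != round(n))) {
    stop("n must be a positive integer", call. = FALSE)
  }
  sqrt(p * (1 - p) / n)
}

#' Conditional probability estimate from a simulated cohort
#'
#' Empirical estimate of P(outcome | evidence) by direct counting:
#' the fraction of cohort records satisfying the evidence that also satisfy
#' the outcome, with its Monte-Carlo (binomial) error.
#'
#' @param cohort A `cohort_table` (or any data frame with its columns).
#' @param evidence,outcome Predicates: functions mapping the cohort data
#'   frame to a logical vector of length `nrow(cohort)`.
#' @return An object of class `conditional_estimate`: list with fields
#'   `estimate`, `n_evidence`, `mc_error`.
#' @export
#' @examples
#' cohort <- simulate_cohort(500, seed = 1)
#' estimate_conditional(cohort,
#'   evidence = function(d) d$diet == "HL",
#'   outcome  = function(d) d$fission == 1)
estimate_conditional <- function(cohort, evidence, outcome) {
  stopifnot(is.data.frame(cohort), is.function(evidence),
            is.function(outcome))
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  ev <- evidence(cohort)
  out <- outcome(cohort)
  stopifnot(is.logical(ev), length(ev) == nrow(cohort),
            is.logical(out), length(out) == nrow(cohort))
  n_ev <- sum(ev)
  if (n_ev == 0L) {
    stop("no records match evidence", call. = FALSE)
  }
  p <- sum(ev & out) / n_ev
  structure(list(estimate = p, n_evidence = n_ev,
                 mc_error = monte_carlo_error(p, n_ev)),
            class = "conditional_estimate")
}

#' @export
print.conditional_estimate <- function(x, ...) {
  cat(sprintf("P(outcome | evidence) = %.4f  (n = %d, MC error = %.4f)\n",
              x$estimate, x$n_evidence, x$mc_error))
  invisible(x)
}
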