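#' Beta distribution shape parameters
#'
#' Constructor for the conjugate prior/posterior of a binomial response rate.
#' Fractional shapes are allowed: power-prior weighting produces non-integer
#' pseudo-counts and these are carried through all downstream computations
#' without rounding.
#'
#' @param alpha,beta Positive shape parameters.
#' @return An object of class `beta_params` with elements `alpha` and `beta`.
#' @examples
#' beta_params(1, 1)            # non-informative prior
#' beta_params(20.5, 28.75)     # a power prior with fractional pseudo-counts
#' @export
beta_params <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta),
            length(alpha) == 1L, length(beta) == 1L)
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0)
    stop("'alpha' and 'beta' must be finite and strictly positive", call. = FALSE)
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "beta_params")
}

#' @export
print.beta_params <- function(x, ...) {
  cat(sprintf("Beta(%g, %g)  mean %.4f\n",
              x$alpha, x$beta, x$alpha / (x$alpha + x$beta)))
  invisible(x)
}

#' @rdname beta_params
#' @param x Object to test or print.
#' @export
is.beta_params <- function(x) inherits(x, "beta_params")

#' Posterior mean of a `beta_params` object
#'
#' @param x A `beta_params` object.
#' @param ... Unused.
#' @return The mean `alpha / (alpha + beta)`.
#' @export
mean.beta_params <- function(x, ...) x$alpha / (x$alpha + x$beta)

#' Aggregate binomial outcome for one arm
#'
#' @param responders Number of responders (non-negative integer).
#' @param total Number of patients (non-negative integer, at least `responders`).
#' @return An object of class `binom_outcome`.
#' @examples
#' binom_outcome(26, 63)
#' @export
binom_outcome <- function(responders, total) {
  stopifnot(is.numeric(responders), is.numeric(total),
            length(responders) == 1L, length(total) == 1L)
  if (is.na(responders) || is.na(total) ||
      responders < 0 || total < 0 ||
      responders != round(responders) || total != round(total))
    stop("'responders' and 'total' must be non-negative integers", call. = FALSE)
  if (responders > total)
    stop("'responders' exceeds 'total' (", responders, " > ", total,
         "): corrupt outcome data", call. = FALSE)
  structure(list(responders = as.integer(responders), total = as.integer(total)),
            class = "binom_outcome")
}

#' @export
print.binom_outcome <- function(x, ...) {
  cat(sprintf("%d/%d responders", x$responders, x$total))
  if (x$total > 0) cat(sprintf(" (%.1f%%)", 100 * x$responders / x$total))
  cat("\n")
  invisible(x)
}

#' Historical outcome with a power-prior borrowing weight
#'
#' Pairs a historical control dataset with the exponent applied to its
#' likelihood in the power prior: weight 1 means each historical patient
#' counts fully in the subsequent analysis, weight 0 means the data are
#' discarded.
#'
#' @param outcome A [binom_outcome()] (or a `responders` count when `total`
#'   is supplied).
#' @param weight Borrowing weight in `[0, 1]`.
#' @param total Optional; when given, `outcome` is taken as the responder
#'   count and a `binom_outcome` is built from `(outcome, total)`.
#' @return An object of class `weighted_outcome`.
#' @examples
#' weighted_outcome(binom_outcome(26, 63), weight = 0.75)
#' weighted_outcome(26, 0.75, total = 63)
#' @export
weighted_outcome <- function(outcome, weight, total = NULL) {
  if (!is.null(total)) outcome <- binom_outcome(outcome, total)
  if (!inherits(outcome, "binom_outcome"))
    stop("'outcome' must be a binom_outcome", call. = FALSE)
  stopifnot(is.numeric(weight), length(weight) == 1L)
  if (is.na(weight) || weight < 0 || weight > 1)
    stop("borrowing 'weight' must lie in [0, 1], got ", weight, call. = FALSE)
  structure(list(outcome = outcome, weight = as.numeric(weight)),
            class = "weighted_outcome")
}

#' @export
print.weighted_outcome <- function(x, ...) {
  cat(sprintf("%d/%d responders, borrowing weight %g\n",
              x$outcome$responders, x$outcome$total, x$weight))
  invisible(x)
}

#' Posterior success rule for the primary comparison
#'
#' The experimental arm is declared successful when the posterior probability
#' that its true response rate exceeds the control rate by at least `margin`
#' reaches the `certainty` level. The boundary counts as success: a posterior
#' probability exactly equal to `certainty` declares success.
#'
#' @param margin Clinically meaningful rate difference, in `[-1, 1]`
#'   (default 0.15, i.e. a 15-point improvement).
#' @param certainty Required posterior probability, in `[0, 1]` (default 0.60).
#' @return An object of class `decision_rule`.
#' @export
decision_rule <- function(margin = 0.15, certainty = 0.60) {
  stopifnot(is.numeric(margin), is.numeric(certainty),
            length(margin) == 1L, length(certainty) == 1L)
  if (is.na(margin) || margin < -1 || margin > 1)
    stop("'margin' must lie in [-1, 1]", call. = FALSE)
  if (is.na(certainty) || certainty < 0 || certainty > 1)
    stop("'certainty' must lie in [0, 1]", call. = FALSE)
  structure(list(margin = as.numeric(margin), certainty = as.numeric(certainty)),
            class = "decision_rule")
}

#' @export
print.decision_rule <- function(x, ...) {
  cat(sprintf("Success if P(p_e - p_c >= %g) >= %g\n", x$margin, x$certainty))
  invisible(x)
}

#' Conjugate Beta-Binomial posterior update
#'
#' @param prior A [beta_params()] prior.
#' @param data A [binom_outcome()].
#' @return The posterior `beta_params`:
#'   `Beta(alpha + responders, beta + total - responders)`.
#' @examples
#' beta_posterior(beta_params(1, 1), binom_outcome(26, 63))  # Beta(27, 38)
#' @export
beta_posterior <- function(prior, data) {
  stopifnot(is.beta_params(prior), inherits(data, "binom_outcome"))
  beta_params(prior$alpha + data$responders,
              prior$beta + data$total - data$responders)
}

#' Fixed power prior from weighted historical outcomes
#'
#' Raises each historical binomial likelihood to its borrowing weight and
#' multiplies by the initial prior. For binomial data with a Beta initial
#' prior this stays in the Beta family with weighted pseudo-counts:
#' `Beta(alpha0 + sum(w_i * s_i), beta0 + sum(w_i * (n_i - s_i)))`.
#'
#' @param initial The initial [beta_params()] prior (default `Beta(1, 1)`).
#' @param history A list of [weighted_outcome()] objects (a single
#'   `weighted_outcome` is accepted).
#' @return The power prior as a `beta_params` object.
#' @examples
#' power_prior(history = list(weighted_outcome(26, 0.75, total = 63)))
#' # Beta(1 + 0.75*26, 1 + 0.75*37) = Beta(20.5, 28.75)
#' @export
power_prior <- function(initial = beta_params(1, 1), history = list()) {
  stopifnot(is.beta_params(initial))
  if (inherits(history, "weighted_outcome")) history <- list(history)
  if (!is.list(history) || !all(vapply(history, inherits, TRUE, "weighted_outcome")))
    stop("'history' must be a list of weighted_outcome objects", call. = FALSE)
  a <- initial$alpha
  b <- initial$beta
  for (h in history) {
    a <- a + h$weight * h$outcome$responders
    b <- b + h$weight * (h$outcome$total - h$outcome$responders)
  }
  beta_params(a, b)
}

#' Posterior probability that the rate difference meets a margin
#'
#' Computes `P(p_e - p_c >= margin)` for independent `p_c ~ Beta(control)`
#' and `p_e ~ Beta(experimental)` by adaptive one-dimensional quadrature of
#' `integral f_c(p) * (1 - F_e(p + margin)) dp` over the admissible range,
#' to absolute accuracy better than 1e-8.
#'
#' @param control,experimental [beta_params()] posteriors for the two arms.
#' @param margin Rate difference in `[-1, 1]`.
#' @return The posterior tail probability, a number in `[0, 1]`.
#' @examples
#' # difference of two independent uniforms: P(U2 - U1 >= 0.15) = 0.85^2 / 2
#' prob_diff_at_least(beta_params(1, 1), beta_params(1, 1), 0.15)
#' @export
prob_diff_at_least <- function(control, experimental, margin) {
  stopifnot(is.beta_params(control), is.beta_params(experimental),
            is.numeric(margin), length(margin) == 1L)
  if (is.na(margin) || margin < -1 || margin > 1)
    stop("'margin' must lie in [-1, 1]", call. = FALSE)
  if (margin <= -1) return(1)
  if (margin >= 1) return(0)
  ac <- control$alpha; bc <- control$beta
  ae <- experimental$alpha; be <- experimental$beta
  # P(p_e >= p_c + margin) contributes only where p_c + margin is in [0, 1];
  # below that range the inner probability is 1, above it 0.
  lo <- max(0, -margin)
  hi <- min(1, 1 - margin)
  f <- function(x) stats::dbeta(x, ac, bc) *
    stats::pbeta(x + margin, ae, be, lower.tail = FALSE)
  val <- stats::integrate(f, lo, hi, abs.tol = 1e-10, rel.tol = 1e-10,
                          subdivisions = 1000L, stop.on.error = FALSE)$value
  if (margin < 0) val <- val + stats::pbeta(lo, ac, bc)
  min(max(val, 0), 1)
}

#' Apply the posterior success rule
#'
#' @param prob A posterior probability in `[0, 1]`.
#' @param rule A [decision_rule()].
#' @return `TRUE` iff `prob >= rule$certainty` (boundary counts as success).
#' @export
decide_success <- function(prob, rule) {
  stopifnot(is.numeric(prob), length(prob) == 1L, inherits(rule, "decision_rule"))
  if (is.na(prob) || prob < 0 || prob > 1)
    stop("'prob' must lie in [0, 1]", call. = FALSE)
  prob >= rule$certainty
}

#' Effective sample size of a control arm with borrowing
#'
#' The concurrent control count plus the weight-scaled borrowed counts:
#' `n_current + sum(w_i * n_i)`. The exact fractional value is returned; a
#' companion value rounded to the nearest whole patient is attached because
#' design summaries conventionally report whole patients.
#'
#' @param n_current Concurrent control-arm sample size.
#' @param history A list of [weighted_outcome()] objects (or a single one).
#' @return A classed numeric (`ess`) holding the fractional effective sample
#'   size, with attribute `rounded` giving the nearest-patient value.
#' @examples
#' effective_sample_size(16, list(weighted_outcome(26, 0.75, total = 63)))
#' # 63.25, reported as 63 patients
#' @export
effective_sample_size <- function(n_current, history = list()) {
  stopifnot(is.numeric(n_current), length(n_current) == 1L, n_current >= 0)
  if (inherits(history, "weighted_outcome")) history <- list(history)
  if (!is.list(history) || !all(vapply(history, inherits, TRUE, "weighted_outcome")))
    stop("'history' must be a list of weighted_outcome objects", call. = FALSE)
  ess <- n_current + sum(vapply(history, function(h) h$weight * h$outcome$total, 0))
  structure(ess, rounded = as.integer(round(ess)), class = "ess")
}

#' @export
print.ess <- function(x, ...) {
  cat(sprintf("Effective sample size: %g (%d patients to the nearest patient)\n",
              unclass(x), attr(x, "rounded")))
  invisible(x)
}
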