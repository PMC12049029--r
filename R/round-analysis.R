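#' Bayesian primary-outcome analysis of one treatment round
#'
#' Fits the conjugate Beta-Binomial model to one round's concurrent arms,
#' with the control prior built as a fixed power prior over weighted
#' historical control data, and evaluates the posterior success rule
#' `P(p_e - p_c >= margin) >= certainty`. This is the per-round primary
#' analysis: the returned object carries both posteriors, posterior mean
#' rates with central credible intervals, the posterior tail probability,
#' the success decision, and the control arm's effective sample size.
#'
#' @param control_data,experimental_data [binom_outcome()] objects for the
#'   concurrent arms; both must have at least one patient.
#' @param history List of [weighted_outcome()] objects: earlier rounds'
#'   control arms with their borrowing weights (empty for the first round).
#' @param rule The [decision_rule()] (default margin 0.15, certainty 0.60).
#' @param prior_control,prior_experimental Initial [beta_params()] priors;
#'   both default to the non-informative `Beta(1, 1)`. Only the control arm
#'   borrows: historical data never enter the experimental prior.
#' @param level Credible-interval level (default 0.95, equal-tailed).
#' @return An object of class `round_analysis`; see [summary.round_analysis()].
#' @examples
#' fit <- round_analysis(binom_outcome(26, 63), binom_outcome(41, 63))
#' fit
#' coef(fit)
#' confint(fit)
#' @export
round_analysis <- function(control_data, experimental_data, history = list(),
                           rule = decision_rule(),
                           prior_control = beta_params(1, 1),
                           prior_experimental = beta_params(1, 1),
                           level = 0.95) {
  stopifnot(inherits(control_data, "binom_outcome"),
            inherits(experimental_data, "binom_outcome"),
            inherits(rule, "decision_rule"),
            is.numeric(level), length(level) == 1L, level > 0, level < 1)
  if (control_data$total == 0L || experimental_data$total == 0L)
    stop("both concurrent arms must contain at least one patient", call. = FALSE)
  if (inherits(history, "weighted_outcome")) history <- list(history)
  ctrl_prior <- power_prior(prior_control, history)
  post_c <- beta_posterior(ctrl_prior, control_data)
  post_e <- beta_posterior(prior_experimental, experimental_data)
  prob <- prob_diff_at_least(post_c, post_e, rule$margin)
  a2 <- (1 - level) / 2
  ci <- function(p) stats::qbeta(c(a2, 1 - a2), p$alpha, p$beta)
  structure(list(
    control_data = control_data,
    experimental_data = experimental_data,
    history = history,
    rule = rule,
    level = level,
    prior_control = ctrl_prior,
    prior_experimental = prior_experimental,
    posterior_control = post_c,
    posterior_experimental = post_e,
    mean_control = mean(post_c),
    mean_experimental = mean(post_e),
    interval_control = ci(post_c),
    interval_experimental = ci(post_e),
    prob = prob,
    success = decide_success(prob, rule),
    ess_control = effective_sample_size(control_data$total, history)),
    class = "round_analysis")
}

#' @export
print.round_analysis <- function(x, digits = 3, ...) {
  cat("Beta-Binomial round analysis with power-prior borrowing\n\n")
  cat(sprintf("Control:      %d/%d observed; posterior Beta(%g, %g), mean %.*f\n",
              x$control_data$responders, x$control_data$total,
              x$posterior_control$alpha, x$posterior_control$beta,
              digits, x$mean_control))
  cat(sprintf("Experimental: %d/%d observed; posterior Beta(%g, %g), mean %.*f\n",
              x$experimental_data$responders, x$experimental_data$total,
              x$posterior_experimental$alpha, x$posterior_experimental$beta,
              digits, x$mean_experimental))
  cat(sprintf("\nP(p_e - p_c >= %g) = %.*f  =>  %s (threshold %g)\n",
              x$rule$margin, digits, x$prob,
              if (x$success) "SUCCESS" else "no success", x$rule$certainty))
  invisible(x)
}

#' Summarise a round analysis
#'
#' @param object A [round_analysis()] fit.
#' @param ... Unused.
#' @return The fit, classed `summary.round_analysis`, printed with borrowing
#'   details, credible intervals and the effective sample size.
#' @export
summary.round_analysis <- function(object, ...) {
  structure(object, class = c("summary.round_analysis", "round_analysis"))
}

#' @export
print.summary.round_analysis <- function(x, digits = 3, ...) {
  print.round_analysis(x, digits = digits, ...)
  lvl <- 100 * x$level
  cat(sprintf("\n%g%% credible intervals (equal-tailed):\n", lvl))
  cat(sprintf("  control      [%.*f, %.*f]\n", digits, x$interval_control[1],
              digits, x$interval_control[2]))
  cat(sprintf("  experimental [%.*f, %.*f]\n", digits,
              x$interval_experimental[1], digits, x$interval_experimental[2]))
  if (length(x$history)) {
    cat("\nBorrowed control data:\n")
    for (h in x$history)
      cat(sprintf("  %d/%d at weight %g\n", h$outcome$responders,
                  h$outcome$total, h$weight))
  }
  print(x$ess_control)
  invisible(x)
}

#' Posterior mean response rates
#'
#' @param object A [round_analysis()] fit.
#' @param ... Unused.
#' @return Named vector: posterior mean control and experimental rates and
#'   their difference.
#' @export
coef.round_analysis <- function(object, ...) {
  c(control = object$mean_control,
    experimental = object$mean_experimental,
    difference = object$mean_experimental - object$mean_control)
}

#' Central posterior credible intervals for the arm rates
#'
#' @param object A [round_analysis()] fit.
#' @param parm Which rates: any of `"control"`, `"experimental"`.
#' @param level Interval level (defaults to the level stored in the fit).
#' @param ... Unused.
#' @return A matrix with one row per rate and lower/upper columns.
#' @export
confint.round_analysis <- function(object, parm = c("control", "experimental"),
                                   level = NULL, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  if (is.null(level)) level <- object$level
  a2 <- (1 - level) / 2
  post <- list(control = object$posterior_control,
               experimental = object$posterior_experimental)
  out <- t(vapply(post[parm], function(p)
    stats::qbeta(c(a2, 1 - a2), p$alpha, p$beta), numeric(2)))
  colnames(out) <- paste0(100 * c(a2, 1 - a2), " %")
  out
}

#' Draw from the joint posterior of the two response rates
#'
#' @param object A [round_analysis()] fit.
#' @param nsim Number of posterior draws.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A `data.frame` with columns `control`, `experimental`,
#'   `difference`, one row per draw.
#' @export
simulate.round_analysis <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pc <- stats::rbeta(nsim, object$posterior_control$alpha,
                     object$posterior_control$beta)
  pe <- stats::rbeta(nsim, object$posterior_experimental$alpha,
                     object$posterior_experimental$beta)
  data.frame(control = pc, experimental = pe, difference = pe - pc)
}

# plain-list view used for JSON serialisation (CLI `analyze`)
analysis_record <- function(x) {
  stopifnot(inherits(x, "round_analysis"))
  list(
    control = list(responders = x$control_data$responders,
                   total = x$control_data$total,
                   prior = list(alpha = x$prior_control$alpha,
                                beta = x$prior_control$beta),
                   posterior = list(alpha = x$posterior_control$alpha,
                                    beta = x$posterior_control$beta),
                   mean = x$mean_control,
                   interval = x$interval_control),
    experimental = list(responders = x$experimental_data$responders,
                        total = x$experimental_data$total,
                        posterior = list(alpha = x$posterior_experimental$alpha,
                                         beta = x$posterior_experimental$beta),
                        mean = x$mean_experimental,
                        interval = x$interval_experimental),
    history = lapply(x$history, function(h)
      list(responders = h$outcome$responders, total = h$outcome$total,
           weight = h$weight)),
    rule = list(margin = x$rule$margin, certainty = x$rule$certainty),
    level = x$level,
    prob_diff_at_least_margin = x$prob,
    success = x$success,
    ess_control = as.numeric(x$ess_control),
    ess_control_rounded = attr(x$ess_control, "rounded"))
}
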