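#' Control-arm summary for side-by-side DMC review
#'
#' Bundles one round's control-arm response data, its posterior response
#' rate under a Beta prior, and baseline covariate summaries, in the form
#' the drift report compares across rounds.
#'
#' @param round_id Round label.
#' @param outcome A [binom_outcome()] for the control arm.
#' @param covariates Named list of covariate summaries. A continuous
#'   covariate is `list(type = "continuous", mean =, sd =)`; a categorical
#'   covariate is `list(type = "categorical", proportions = <named numeric
#'   summing to 1>)`.
#' @param prior [beta_params()] prior for the posterior rate (default
#'   `Beta(1, 1)`).
#' @param level Credible-interval level for the posterior rate.
#' @return An object of class `control_summary`.
#' @export
control_summary <- function(round_id, outcome, covariates = list(),
                            prior = beta_params(1, 1), level = 0.95) {
  stopifnot(length(round_id) == 1L, inherits(outcome, "binom_outcome"),
            is.beta_params(prior), is.list(covariates))
  if (length(covariates) && is.null(names(covariates)))
    stop("'covariates' must be a named list", call. = FALSE)
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    if (!is.list(cv) || is.null(cv$type) ||
        !cv$type %in% c("continuous", "categorical"))
      stop("covariate '", nm, "' must declare type 'continuous' or ",
           "'categorical'", call. = FALSE)
    if (cv$type == "continuous") {
      if (!is.numeric(cv$mean) || !is.numeric(cv$sd) || cv$sd < 0)
        stop("continuous covariate '", nm, "' needs numeric mean and sd >= 0",
             call. = FALSE)
    } else {
      p <- cv$proportions
      if (!is.numeric(p) || is.null(names(p)) || any(p < 0) ||
          abs(sum(p) - 1) > 1e-8)
        stop("categorical covariate '", nm, "' needs named proportions ",
             "summing to 1", call. = FALSE)
    }
  }
  post <- beta_posterior(prior, outcome)
  a2 <- (1 - level) / 2
  structure(list(round_id = as.character(round_id), outcome = outcome,
                 posterior = post, posterior_rate = mean(post),
                 interval = stats::qbeta(c(a2, 1 - a2), post$alpha, post$beta),
                 level = level, covariates = covariates),
            class = "control_summary")
}

#' @export
print.control_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Control arm %s: %d/%d responders; posterior rate %.*f [%.*f, %.*f]\n",
              x$round_id, x$outcome$responders, x$outcome$total,
              digits, x$posterior_rate, digits, x$interval[1],
              digits, x$interval[2]))
  invisible(x)
}

# absolute standardized difference for one covariate between two summaries;
# categorical covariates report the largest per-level standardized difference
std_diff <- function(cv1, cv2) {
  if (cv1$type == "continuous") {
    pooled <- sqrt((cv1$sd^2 + cv2$sd^2) / 2)
    if (pooled == 0) return(if (cv1$mean == cv2$mean) 0 else Inf)
    abs(cv1$mean - cv2$mean) / pooled
  } else {
    lev <- union(names(cv1$proportions), names(cv2$proportions))
    p1 <- ifelse(lev %in% names(cv1$proportions), cv1$proportions[lev], 0)
    p2 <- ifelse(lev %in% names(cv2$proportions), cv2$proportions[lev], 0)
    denom <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
    d <- abs(p1 - p2) / ifelse(denom == 0, NA, denom)
    d[denom == 0 & abs(p1 - p2) == 0] <- 0
    d[denom == 0 & abs(p1 - p2) > 0] <- Inf
    max(d)
  }
}

#' Control-drift report across rounds
#'
#' Descriptive side-by-side comparison of the control arms of two or more
#' rounds, as reviewed by a data monitoring committee before a weighting
#' decision: pairwise differences in posterior mean response rates and
#' per-covariate absolute standardized differences, with flags where a
#' configurable threshold is exceeded. No hypothesis tests are performed.
#'
#' @param summaries List of two or more [control_summary()] objects with
#'   identical covariate schemas.
#' @param flag_threshold Non-negative drift threshold applied to both the
#'   absolute rate differences and the covariate standardized differences
#'   (default 0.2, the conventional imbalance cutoff).
#' @return An object of class `drift_report`: a list with data.frames
#'   `rates` (pairwise rate differences) and `covariates` (pairwise
#'   standardized differences), each with a logical `flag` column.
#' @examples
#' s1 <- control_summary("R1", binom_outcome(26, 63))
#' s2 <- control_summary("R2", binom_outcome(7, 16))
#' drift_report(list(s1, s2), flag_threshold = 0.10)
#' @export
drift_report <- function(summaries, flag_threshold = 0.2) {
  if (inherits(summaries, "control_summary")) summaries <- list(summaries)
  stopifnot(all(vapply(summaries, inherits, TRUE, "control_summary")),
            is.numeric(flag_threshold), length(flag_threshold) == 1L,
            flag_threshold >= 0)
  if (length(summaries) < 2L)
    stop("drift reporting needs at least two control summaries", call. = FALSE)
  schema <- lapply(summaries, function(s) {
    types <- lapply(s$covariates, `[[`, "type")
    if (length(types)) types[order(names(types))] else types
  })
  for (i in seq_along(schema)[-1])
    if (!identical(schema[[i]], schema[[1]]))
      stop("control summaries have mismatched covariate schemas (round ",
           summaries[[i]]$round_id, " vs ", summaries[[1]]$round_id, ")",
           call. = FALSE)
  pairs <- utils::combn(length(summaries), 2)
  rate_rows <- cov_rows <- list()
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    si <- summaries[[i]]; sj <- summaries[[j]]
    diff <- sj$posterior_rate - si$posterior_rate
    rate_rows[[p]] <- data.frame(
      round_a = si$round_id, round_b = sj$round_id,
      rate_a = si$posterior_rate, rate_b = sj$posterior_rate,
      difference = diff, abs_difference = abs(diff),
      flag = abs(diff) > flag_threshold, stringsAsFactors = FALSE)
    for (nm in names(si$covariates)) {
      sd_val <- std_diff(si$covariates[[nm]], sj$covariates[[nm]])
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        round_a = si$round_id, round_b = sj$round_id, covariate = nm,
        std_difference = sd_val, flag = sd_val > flag_threshold,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(
    rates = do.call(rbind, rate_rows),
    covariates = if (length(cov_rows)) do.call(rbind, cov_rows) else
      data.frame(round_a = character(), round_b = character(),
                 covariate = character(), std_difference = numeric(),
                 flag = logical(), stringsAsFactors = FALSE),
    flag_threshold = flag_threshold,
    any_flag = any(vapply(rate_rows, function(r) r$flag, TRUE)) ||
      any(vapply(cov_rows, function(r) r$flag, logical(1)))),
    class = "drift_report")
}

#' @export
print.drift_report <- function(x, digits = 3, ...) {
  cat(sprintf("Control-drift report (flag threshold %g)\n\nResponse rates:\n",
              x$flag_threshold))
  print.data.frame(x$rates, digits = digits, row.names = FALSE)
  if (nrow(x$covariates)) {
    cat("\nCovariate standardized differences:\n")
    print.data.frame(x$covariates, digits = digits, row.names = FALSE)
  }
  cat(if (x$any_flag) "\nDrift threshold exceeded: weight review indicated.\n"
      else "\nNo drift flags raised.\n")
  invisible(x)
}

#' Predefined borrowing-weight sensitivity reanalysis
#'
#' Re-runs the round's primary analysis across a grid of borrowing weights
#' applied uniformly to all historical control sources: the sensitivity
#' table mandated around the prespecified weight (reanalysis with lower
#' weights when a high weight was used, and vice versa).
#'
#' @param control_data,experimental_data Concurrent-arm [binom_outcome()]s.
#' @param history List of historical control [binom_outcome()] objects
#'   (unweighted; the grid supplies the weights).
#' @param weights Non-empty numeric vector of weights in `[0, 1]`.
#' @param rule The [decision_rule()].
#' @param prior_control,prior_experimental Initial [beta_params()] priors.
#' @return A `data.frame` of class `weight_sensitivity`, one row per weight
#'   in increasing order: power-prior and posterior parameters, posterior
#'   mean rates, the posterior tail probability at the rule margin, and the
#'   success decision.
#' @examples
#' weight_sensitivity(binom_outcome(7, 16), binom_outcome(41, 63),
#'                    history = list(binom_outcome(26, 63)),
#'                    weights = c(0, 0.25, 0.5, 0.75, 1))
#' @export
weight_sensitivity <- function(control_data, experimental_data, history,
                               weights, rule = decision_rule(),
                               prior_control = beta_params(1, 1),
                               prior_experimental = beta_params(1, 1)) {
  if (inherits(history, "binom_outcome")) history <- list(history)
  stopifnot(all(vapply(history, inherits, TRUE, "binom_outcome")))
  if (!is.numeric(weights) || length(weights) == 0L)
    stop("'weights' must be a non-empty numeric vector", call. = FALSE)
  if (any(is.na(weights) | weights < 0 | weights > 1))
    stop("all weights must lie in [0, 1]", call. = FALSE)
  weights <- sort(unique(weights))
  rows <- lapply(weights, function(w) {
    wh <- lapply(history, weighted_outcome, weight = w)
    fit <- round_analysis(control_data, experimental_data, history = wh,
                          rule = rule, prior_control = prior_control,
                          prior_experimental = prior_experimental)
    data.frame(weight = w,
               prior_alpha = fit$prior_control$alpha,
               prior_beta = fit$prior_control$beta,
               post_alpha = fit$posterior_control$alpha,
               post_beta = fit$posterior_control$beta,
               mean_control = fit$mean_control,
               mean_experimental = fit$mean_experimental,
               prob = fit$prob,
               success = fit$success,
               ess_control = as.numeric(fit$ess_control))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("weight_sensitivity", "data.frame")
  out
}

#' @export
print.weight_sensitivity <- function(x, digits = 4, ...) {
  cat("Borrowing-weight sensitivity reanalysis\n")
  print.data.frame(x, digits = digits, row.names = FALSE, ...)
  invisible(x)
}

#' Weighting decision record for DMC/TSC review
#'
#' Bundles the evidence behind a borrowing-weight decision into a
#' serialisable record: the drift report, the chosen weight, the
#' justification, any change to standard of care, and the recruitment gap
#' between rounds. The decision itself is made by the monitoring and
#' steering committees; this record never adjusts weights.
#'
#' @param report A [drift_report()].
#' @param chosen_weight The weight selected for the analysis, in `[0, 1]`.
#' @param rationale Non-empty justification text.
#' @param care_change_note Description of any change to standard of care.
#' @param recruitment_gap_months Time between closure of the previous
#'   round's recruitment and the current round's, in months.
#' @return An object of class `weighting_decision_record`.
#' @export
weighting_decision_record <- function(report, chosen_weight, rationale,
                                      care_change_note = "none",
                                      recruitment_gap_months = NA_real_) {
  stopifnot(inherits(report, "drift_report"))
  if (!is.numeric(chosen_weight) || length(chosen_weight) != 1L ||
      is.na(chosen_weight) || chosen_weight < 0 || chosen_weight > 1)
    stop("'chosen_weight' must lie in [0, 1]", call. = FALSE)
  if (!is.character(rationale) || length(rationale) != 1L ||
      !nzchar(trimws(rationale)))
    stop("a non-empty 'rationale' is required", call. = FALSE)
  structure(list(report = report, chosen_weight = as.numeric(chosen_weight),
                 rationale = rationale,
                 care_change_note = as.character(care_change_note),
                 recruitment_gap_months = as.numeric(recruitment_gap_months)),
            class = "weighting_decision_record")
}

#' @export
print.weighting_decision_record <- function(x, ...) {
  cat(sprintf("Weighting decision: weight %g\nRationale: %s\n",
              x$chosen_weight, x$rationale))
  cat(sprintf("Standard-of-care change: %s\nRecruitment gap: %s months\n",
              x$care_change_note,
              if (is.na(x$recruitment_gap_months)) "not stated"
              else format(x$recruitment_gap_months)))
  print(x$report)
  invisible(x)
}

#' Serialise a weighting decision record to JSON
#'
#' @param record A [weighting_decision_record()].
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON string, invisibly when written to `path`.
#' @export
decision_record_json <- function(record, path = NULL) {
  stopifnot(inherits(record, "weighting_decision_record"))
  payload <- list(
    chosen_weight = record$chosen_weight,
    rationale = record$rationale,
    care_change_note = record$care_change_note,
    recruitment_gap_months = record$recruitment_gap_months,
    drift = list(flag_threshold = record$report$flag_threshold,
                 any_flag = record$report$any_flag,
                 rates = record$report$rates,
                 covariates = record$report$covariates))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
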