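#' Operating-characteristic result
#'
#' @param prob_success Estimated probability of declaring success.
#' @param reps Number of Monte-Carlo replicates (for exact enumeration the
#'   count of outcome cells evaluated).
#' @param mc_se Monte-Carlo standard error `sqrt(p(1-p)/reps)`; 0 for exact
#'   enumeration.
#' @param method `"simulation"` or `"exact_enumeration"`.
#' @return An object of class `oc_result`.
#' @keywords internal
oc_result <- function(prob_success, reps, mc_se, method) {
  structure(list(prob_success = prob_success, reps = as.integer(reps),
                 mc_se = mc_se, method = method),
            class = "oc_result")
}

#' @export
print.oc_result <- function(x, ...) {
  cat(sprintf("P(declare success) = %.4f", x$prob_success))
  if (x$method == "simulation")
    cat(sprintf("  (simulation, %d reps, MC se %.4f)\n", x$reps, x$mc_se))
  else
    cat("  (exact enumeration)\n")
  invisible(x)
}

# Control-arm power prior implied by a scenario's fixed historical counts.
scenario_control_prior <- function(sc, initial = beta_params(1, 1)) {
  hist <- mapply(function(h, o) weighted_outcome(o, h$weight),
                 sc$design$history, sc$historical_counts, SIMPLIFY = FALSE)
  power_prior(initial, hist)
}

# Smallest experimental responder count meeting the rule for a fixed control
# posterior. Uses that the posterior tail probability is non-decreasing in
# the experimental responder count (likelihood-ratio ordering of the
# Beta posteriors). Returns ne + 1 when no count qualifies.
success_threshold <- function(control_post, ne, prior_e, rule) {
  pr <- function(se) prob_diff_at_least(
    control_post,
    beta_params(prior_e$alpha + se, prior_e$beta + ne - se),
    rule$margin)
  if (pr(ne) < rule$certainty) return(ne + 1L)
  if (pr(0L) >= rule$certainty) return(0L)
  lo <- 0L; hi <- ne
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pr(mid) >= rule$certainty) hi <- mid else lo <- mid
  }
  hi
}

#' Exact operating characteristics by outcome-grid enumeration
#'
#' Sums binomial probability masses over every concurrent outcome pair
#' `(s_c, s_e)` whose posterior analysis meets the success rule, with the
#' historical control data held fixed at the scenario's counts. For each
#' control count the minimal successful experimental count is located by
#' bisection (the posterior tail probability is monotone in the
#' experimental responders), so the result is deterministic and exact up to
#' quadrature accuracy.
#'
#' @param scenario An [scenario()] object.
#' @param prior_control,prior_experimental Initial [beta_params()] priors
#'   (default non-informative `Beta(1, 1)`; the control prior is combined
#'   with the weighted historical data).
#' @param max_cells Refuse enumeration beyond this many outcome cells.
#' @return An [oc_result] with `method = "exact_enumeration"` and `mc_se = 0`.
#' @examples
#' d <- three_round_design()$R1
#' exact_oc(scenario(d, 0.40, 0.65))
#' @export
exact_oc <- function(scenario, prior_control = beta_params(1, 1),
                     prior_experimental = beta_params(1, 1),
                     max_cells = 1e6) {
  stopifnot(inherits(scenario, "oc_scenario"))
  nc <- scenario$design$n_control
  ne <- scenario$design$n_experimental
  cells <- (nc + 1) * (ne + 1)
  if (cells > max_cells)
    stop("outcome grid has ", cells, " cells, above the enumeration bound ",
         max_cells, call. = FALSE)
  ctrl_prior <- scenario_control_prior(scenario, prior_control)
  pc <- scenario$true_control_rate
  pe <- scenario$true_experimental_rate
  total <- 0
  for (s_c in 0:nc) {
    ctrl_post <- beta_params(ctrl_prior$alpha + s_c, ctrl_prior$beta + nc - s_c)
    thr <- success_threshold(ctrl_post, ne, prior_experimental, scenario$rule)
    p_succ <- if (thr > ne) 0 else
      stats::pbinom(thr - 1, ne, pe, lower.tail = FALSE)
    total <- total + stats::dbinom(s_c, nc, pc) * p_succ
  }
  oc_result(min(max(total, 0), 1), cells, 0, "exact_enumeration")
}

#' Operating characteristics by Monte-Carlo simulation
#'
#' For each replicate, draws concurrent control responders from
#' `Binomial(n_control, true_control_rate)` and experimental responders from
#' `Binomial(n_experimental, true_experimental_rate)` (control drawn first),
#' forms the control power prior from the weighted historical counts,
#' updates both arms, and applies the success rule to the posterior tail
#' probability. Posterior probabilities are memoised per distinct outcome
#' pair, so large replicate counts cost little beyond the binomial draws.
#'
#' By default the historical control data are held fixed at the scenario's
#' counts across replicates. With `resample_history = TRUE` each replicate
#' also re-draws every historical source from
#' `Binomial(n_i, historical_rate_i)` (after the two concurrent arms, in
#' source order), propagating historical sampling variability into the
#' operating characteristics.
#'
#' @inheritParams exact_oc
#' @param reps Number of replicates (at least 1).
#' @param seed Optional integer seed; identical seeds give identical results.
#' @param resample_history Re-draw historical control data each replicate
#'   instead of holding it fixed.
#' @return An [oc_result] with `method = "simulation"`.
#' @examples
#' d <- three_round_design()$R1
#' simulate_oc(scenario(d, 0.40, 0.65), reps = 1000, seed = 1)
#' @export
simulate_oc <- function(scenario, reps = 10000, seed = NULL,
                        resample_history = FALSE,
                        prior_control = beta_params(1, 1),
                        prior_experimental = beta_params(1, 1)) {
  stopifnot(inherits(scenario, "oc_scenario"))
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1)
    stop("'reps' must be at least 1", call. = FALSE)
  reps <- as.integer(reps)
  if (!is.null(seed)) set.seed(seed)
  nc <- scenario$design$n_control
  ne <- scenario$design$n_experimental
  rule <- scenario$rule
  s_c <- stats::rbinom(reps, nc, scenario$true_control_rate)
  s_e <- stats::rbinom(reps, ne, scenario$true_experimental_rate)

  if (!resample_history || length(scenario$historical_counts) == 0L) {
    ctrl_prior <- scenario_control_prior(scenario, prior_control)
    # memoise the success decision per distinct control count via the
    # minimal successful experimental count
    thr <- new.env(parent = emptyenv())
    success <- logical(reps)
    for (v in unique(s_c)) {
      post_c <- beta_params(ctrl_prior$alpha + v, ctrl_prior$beta + nc - v)
      assign(as.character(v),
             success_threshold(post_c, ne, prior_experimental, rule),
             envir = thr)
    }
    for (i in seq_len(reps))
      success[i] <- s_e[i] >= get(as.character(s_c[i]), envir = thr)
  } else {
    k <- length(scenario$historical_counts)
    hdraw <- matrix(0L, nrow = reps, ncol = k)
    for (j in seq_len(k))
      hdraw[, j] <- stats::rbinom(reps, scenario$design$history[[j]]$n,
                                  scenario$historical_rates[j])
    key <- apply(cbind(hdraw, s_c), 1L, paste, collapse = ",")
    thr <- new.env(parent = emptyenv())
    success <- logical(reps)
    for (i in seq_len(reps)) {
      if (!exists(key[i], envir = thr, inherits = FALSE)) {
        hist <- lapply(seq_len(k), function(j)
          weighted_outcome(hdraw[i, j], scenario$design$history[[j]]$weight,
                           total = scenario$design$history[[j]]$n))
        post_c <- beta_posterior(power_prior(prior_control, hist),
                                 binom_outcome(s_c[i], nc))
        assign(key[i],
               success_threshold(post_c, ne, prior_experimental, rule),
               envir = thr)
      }
      success[i] <- s_e[i] >= get(key[i], envir = thr)
    }
  }
  p <- mean(success)
  oc_result(p, reps, sqrt(p * (1 - p) / reps), "simulation")
}

#' Tabulate operating characteristics over a scenario grid
#'
#' Runs [simulate_oc()] (or [exact_oc()]) for every scenario and returns one
#' row per scenario with its descriptors and the estimated probability of
#' declaring success. A single master seed spawns one derived seed per
#' scenario, so the table is reproducible as a whole and row-by-row.
#'
#' @param grid A non-empty list of scenarios from [build_scenario_grid()]
#'   (or built by hand with [scenario()]).
#' @param reps Replicates per scenario (simulation method).
#' @param seed Master integer seed.
#' @param method `"simulation"` or `"exact"`.
#' @param resample_history Passed to [simulate_oc()].
#' @return A `data.frame` of class `oc_table` with columns `round`,
#'   `hist_rates`, `hist_counts`, `true_control_rate`, `true_exp_rate`,
#'   `difference`, `weight`, `margin`, `certainty`, `reps`, `seed`,
#'   `method`, `prob_success`, `mc_se`.
#' @export
oc_table <- function(grid, reps = 10000, seed = 1,
                     method = c("simulation", "exact"),
                     resample_history = FALSE) {
  method <- match.arg(method)
  if (inherits(grid, "oc_scenario")) grid <- list(grid)
  if (length(grid) == 0L) stop("'grid' must be non-empty", call. = FALSE)
  stopifnot(all(vapply(grid, inherits, TRUE, "oc_scenario")))
  # per-scenario substreams derived once from the master seed
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, length(grid))
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    sc <- grid[[i]]
    res <- tryCatch(
      if (method == "exact") exact_oc(sc)
      else simulate_oc(sc, reps = reps, seed = sub_seeds[i],
                       resample_history = resample_history),
      error = function(e)
        stop("scenario ", i, " [", sc$design$round_id, ", control ",
             sc$true_control_rate, " vs experimental ",
             sc$true_experimental_rate, "]: ", conditionMessage(e),
             call. = FALSE))
    w <- attr(sc, "weight")
    if (is.null(w))
      w <- if (length(sc$design$history)) sc$design$history[[1]]$weight
      else NA_real_
    rows[[i]] <- data.frame(
      round = sc$design$round_id,
      hist_rates = paste(sc$historical_rates, collapse = ";"),
      hist_counts = paste(vapply(sc$historical_counts, function(o)
        sprintf("%d/%d", o$responders, o$total), ""), collapse = ";"),
      true_control_rate = sc$true_control_rate,
      true_exp_rate = sc$true_experimental_rate,
      difference = sc$true_experimental_rate - sc$true_control_rate,
      weight = w,
      margin = sc$rule$margin,
      certainty = sc$rule$certainty,
      reps = res$reps,
      seed = if (method == "exact") NA_integer_ else sub_seeds[i],
      method = res$method,
      prob_success = res$prob_success,
      mc_se = res$mc_se,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("oc_table", "data.frame")
  out
}

#' @export
print.oc_table <- function(x, digits = 4, ...) {
  cat(sprintf("Operating characteristics (%d scenarios, method: %s)\n",
              nrow(x), paste(unique(x$method), collapse = ", ")))
  print.data.frame(x, digits = digits, row.names = FALSE, ...)
  invisible(x)
}
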