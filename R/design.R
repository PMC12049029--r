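#' Borrowing source specification within a round design
#'
#' Identifies an earlier round's control arm to borrow from, its size, and
#' the power-prior weight applied to it.
#'
#' @param from_round Label of the source round.
#' @param n Control-arm size of the source round.
#' @param weight Borrowing weight in `[0, 1]`.
#' @return An object of class `borrow_spec`.
#' @export
borrow_spec <- function(from_round, n, weight) {
  stopifnot(length(from_round) == 1L, is.numeric(n), length(n) == 1L, n >= 0,
            is.numeric(weight), length(weight) == 1L)
  if (is.na(weight) || weight < 0 || weight > 1)
    stop("borrowing 'weight' must lie in [0, 1]", call. = FALSE)
  structure(list(from_round = as.character(from_round), n = as.integer(n),
                 weight = as.numeric(weight)),
            class = "borrow_spec")
}

#' Per-round trial design
#'
#' Arm sizes, allocation ratio and borrowing sources for one treatment round
#' of a sequential platform trial. The allocation ratio is design metadata:
#' simulation and analysis use the per-arm sample sizes directly.
#'
#' @param round_id Round label, e.g. `"R1"`.
#' @param n_control,n_experimental Per-arm sample sizes.
#' @param allocation Length-2 numeric `c(control, experimental)` ratio,
#'   e.g. `c(1, 1)` or `c(1, 4)`.
#' @param history List of [borrow_spec()] entries referencing earlier rounds'
#'   control arms (empty for the first round).
#' @return An object of class `round_design`.
#' @examples
#' round_design("R2", 16, 63, c(1, 4),
#'              history = list(borrow_spec("R1", 63, 0.75)))
#' @export
round_design <- function(round_id, n_control, n_experimental,
                         allocation = c(1, 1), history = list()) {
  stopifnot(length(round_id) == 1L,
            is.numeric(n_control), n_control >= 0,
            is.numeric(n_experimental), n_experimental >= 0,
            is.numeric(allocation), length(allocation) == 2L, all(allocation > 0))
  if (inherits(history, "borrow_spec")) history <- list(history)
  if (!all(vapply(history, inherits, TRUE, "borrow_spec")))
    stop("'history' must be a list of borrow_spec objects", call. = FALSE)
  structure(list(round_id = as.character(round_id),
                 n_control = as.integer(n_control),
                 n_experimental = as.integer(n_experimental),
                 allocation = as.numeric(allocation),
                 history = history),
            class = "round_design")
}

#' @export
print.round_design <- function(x, ...) {
  cat(sprintf("Round %s: %d control / %d experimental (%g:%g allocation)\n",
              x$round_id, x$n_control, x$n_experimental,
              x$allocation[1], x$allocation[2]))
  for (h in x$history)
    cat(sprintf("  borrows %s control arm (n=%d) at weight %g\n",
                h$from_round, h$n, h$weight))
  invisible(x)
}

#' The default three-round platform design
#'
#' Round 1 randomises 63 patients per arm 1:1 with no borrowing; Rounds 2
#' and 3 randomise 16 control and 63 experimental patients 1:4, borrowing
#' every earlier round's control arm at a common prespecified weight
#' (0.75 by default). The totals are 284 patients: 95 control and 189
#' experimental.
#'
#' @param weight Common borrowing weight for Rounds 2 and 3.
#' @return A named list of three [round_design()] objects (`R1`, `R2`, `R3`).
#' @export
three_round_design <- function(weight = 0.75) {
  r1 <- round_design("R1", 63, 63, c(1, 1))
  r2 <- round_design("R2", 16, 63, c(1, 4),
                     history = list(borrow_spec("R1", 63, weight)))
  r3 <- round_design("R3", 16, 63, c(1, 4),
                     history = list(borrow_spec("R1", 63, weight),
                                    borrow_spec("R2", 16, weight)))
  list(R1 = r1, R2 = r2, R3 = r3)
}

#' Deterministic responder count at a nominal rate
#'
#' Converts a nominal response rate into its fixed responder-count
#' realisation: the smallest responder count whose observed rate is at
#' least the nominal rate, i.e. `ceiling(n * rate)` (guarded against
#' floating-point representation error). This is the convention behind the
#' design's fixed historical realisations — 63 patients at a 40% rate give
#' 26/63 (25.2 rounds up) and 16 patients at 40% give 7/16 (6.4 rounds up);
#' half-up rounding would disagree with both.
#'
#' @param n Number of patients.
#' @param rate Response rate in `[0, 1]`.
#' @return A [binom_outcome()] with `responders = ceiling(n * rate)`.
#' @examples
#' historical_counts_for_rate(63, 0.40)  # 26/63
#' historical_counts_for_rate(16, 0.40)  # 7/16
#' @export
historical_counts_for_rate <- function(n, rate) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0, n == round(n),
            is.numeric(rate), length(rate) == 1L)
  if (is.na(rate) || rate < 0 || rate > 1)
    stop("'rate' must lie in [0, 1]", call. = FALSE)
  binom_outcome(ceiling(n * rate - 1e-9), n)
}

#' Simulation scenario: a design plus true rates and the decision rule
#'
#' The unit of the operating-characteristics study. Historical control data
#' are held fixed at their nominal realisations (via
#' [historical_counts_for_rate()]) unless explicit counts are supplied;
#' the simulator can instead re-draw them each replicate (see
#' [simulate_oc()]).
#'
#' @param design A [round_design()].
#' @param true_control_rate,true_experimental_rate True response rates in
#'   `[0, 1]` for the concurrent arms.
#' @param rule A [decision_rule()].
#' @param historical_rates Numeric vector of true/nominal control rates for
#'   the design's borrowing sources, aligned one-to-one with
#'   `design$history`. Required when the design borrows.
#' @param historical_counts Optional list of [binom_outcome()] objects
#'   overriding the nominal realisations derived from `historical_rates`.
#' @return An object of class `oc_scenario`.
#' @export
scenario <- function(design, true_control_rate, true_experimental_rate,
                     rule = decision_rule(), historical_rates = numeric(),
                     historical_counts = NULL) {
  stopifnot(inherits(design, "round_design"), inherits(rule, "decision_rule"))
  for (r in c(true_control_rate, true_experimental_rate, historical_rates))
    if (is.na(r) || r < 0 || r > 1)
      stop("response rates must lie in [0, 1], got ", r, call. = FALSE)
  nh <- length(design$history)
  if (length(historical_rates) != nh)
    stop("'historical_rates' must align one-to-one with the design's ",
         nh, " borrowing source(s)", call. = FALSE)
  if (is.null(historical_counts)) {
    historical_counts <- vector("list", nh)
    for (i in seq_len(nh))
      historical_counts[[i]] <-
        historical_counts_for_rate(design$history[[i]]$n, historical_rates[i])
  } else {
    if (length(historical_counts) != nh ||
        !all(vapply(historical_counts, inherits, TRUE, "binom_outcome")))
      stop("'historical_counts' must be a list of binom_outcome aligned ",
           "with the design's borrowing sources", call. = FALSE)
  }
  structure(list(design = design,
                 true_control_rate = as.numeric(true_control_rate),
                 true_experimental_rate = as.numeric(true_experimental_rate),
                 historical_rates = as.numeric(historical_rates),
                 historical_counts = historical_counts,
                 rule = rule),
            class = "oc_scenario")
}

#' @export
print.oc_scenario <- function(x, ...) {
  cat(sprintf("Scenario [%s]: true rates %.0f%% control vs %.0f%% experimental\n",
              x$design$round_id, 100 * x$true_control_rate,
              100 * x$true_experimental_rate))
  for (i in seq_along(x$historical_counts)) {
    h <- x$design$history[[i]]
    o <- x$historical_counts[[i]]
    cat(sprintf("  history %s: %d/%d fixed (nominal %.0f%%), weight %g\n",
                h$from_round, o$responders, o$total,
                100 * x$historical_rates[i], h$weight))
  }
  print(x$rule)
  invisible(x)
}

# replace the weight of every borrowing source in a design
set_design_weight <- function(design, weight) {
  design$history <- lapply(design$history, function(h) {
    h$weight <- weight
    h
  })
  design
}

#' Build a Cartesian scenario grid
#'
#' Crosses control rates, rate differences, certainty levels, borrowing
#' weights and designs into the full grid of simulation scenarios. For a
#' design that borrows from k earlier rounds, every permutation of the k + 1
#' control rates (each earlier round's nominal rate and the concurrent
#' round's true rate) is generated. Combinations whose implied experimental
#' rate `control + difference` falls outside `[0, 1]` are dropped. For a
#' design without borrowing the weight dimension is collapsed (recorded as
#' `NA`), since the weight has no effect there.
#'
#' @param control_rates Numeric vector of control response rates.
#' @param differences Numeric vector of experimental-minus-control rate
#'   differences in `[-1, 1]`.
#' @param certainties Numeric vector of certainty thresholds.
#' @param weights Numeric vector of borrowing weights applied uniformly to
#'   all of a design's sources. Ignored for designs without history.
#' @param designs A [round_design()] or list of them.
#' @param margin Decision-rule margin shared by all scenarios.
#' @return A list of `oc_scenario` objects; each carries attributes
#'   `weight` and `certainty` recording its grid coordinates.
#' @examples
#' g <- build_scenario_grid(c(0.40, 0.60), c(-0.10, 0, 0.15, 0.25),
#'                          certainties = 0.60, weights = NA,
#'                          designs = three_round_design()$R1)
#' length(g)  # 8
#' @export
build_scenario_grid <- function(control_rates, differences,
                                certainties = 0.60, weights = 0.75,
                                designs, margin = 0.15) {
  if (inherits(designs, "round_design")) designs <- list(designs)
  stopifnot(length(designs) >= 1L,
            all(vapply(designs, inherits, TRUE, "round_design")))
  for (r in control_rates)
    if (is.na(r) || r < 0 || r > 1)
      stop("control rates must lie in [0, 1]", call. = FALSE)
  for (d in differences)
    if (is.na(d) || d < -1 || d > 1)
      stop("differences must lie in [-1, 1]", call. = FALSE)
  for (ct in certainties[!is.na(certainties)])
    if (ct < 0 || ct > 1) stop("certainties must lie in [0, 1]", call. = FALSE)
  out <- list()
  for (design in designs) {
    k <- length(design$history)
    w_grid <- if (k == 0L) NA_real_ else weights
    rate_slots <- rep(list(control_rates), k + 1L)
    rate_perms <- if (length(differences) == 0L || length(control_rates) == 0L)
      data.frame() else expand.grid(rate_slots, KEEP.OUT.ATTRS = FALSE)
    for (w in w_grid) {
      d_w <- if (k > 0L && !is.na(w)) set_design_weight(design, w) else design
      for (ct in certainties) {
        rule <- decision_rule(margin = margin, certainty = ct)
        for (diff in differences) {
          for (p in seq_len(nrow(rate_perms))) {
            perm <- as.numeric(rate_perms[p, ])
            ctrl <- perm[k + 1L]
            expr <- ctrl + diff
            if (expr < 0 || expr > 1) next
            sc <- scenario(d_w, ctrl, expr, rule = rule,
                           historical_rates = if (k > 0L) perm[seq_len(k)]
                           else numeric())
            attr(sc, "weight") <- w
            attr(sc, "certainty") <- ct
            out[[length(out) + 1L]] <- sc
          }
        }
      }
    }
  }
  out
}
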