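#' Default covariate specification for synthetic trial data
#'
#' One age-like continuous covariate and one categorical covariate counting
#' prior lines of therapy, enough to exercise baseline drift reporting.
#'
#' @return Named list of covariate generator specifications.
#' @export
default_covariate_spec <- function() {
  list(
    age = list(type = "continuous", mean = 62, sd = 11),
    prior_lines = list(type = "categorical",
                       proportions = c(`2` = 0.45, `3` = 0.35, `4+` = 0.20)))
}

check_covariate_spec <- function(spec) {
  if (!is.list(spec) || (length(spec) && is.null(names(spec))))
    stop("'covariate_spec' must be a named list", call. = FALSE)
  for (nm in names(spec)) {
    cv <- spec[[nm]]
    if (!is.list(cv) || is.null(cv$type))
      stop("covariate spec '", nm, "' must declare a type", call. = FALSE)
    if (cv$type == "continuous") {
      if (!is.numeric(cv$mean) || !is.numeric(cv$sd) || cv$sd < 0)
        stop("continuous covariate spec '", nm, "' needs mean and sd >= 0",
             call. = FALSE)
    } else if (cv$type == "categorical") {
      p <- cv$proportions
      if (!is.numeric(p) || is.null(names(p)) || any(p < 0) ||
          abs(sum(p) - 1) > 1e-8)
        stop("categorical covariate spec '", nm, "' needs named proportions ",
             "summing to 1", call. = FALSE)
    } else stop("covariate spec '", nm, "' has unknown type '", cv$type, "'",
                call. = FALSE)
  }
  invisible(spec)
}

#' Generate synthetic patient-level trial data for one round
#'
#' Draws exactly `n_control + n_experimental` patient records with per-arm
#' Bernoulli responses at the stated true rates and baseline covariates
#' from the covariate specification (normal for continuous, multinomial for
#' categorical). Control-arm patients are generated first; draws are
#' reproducible under a seed.
#'
#' @param design A [round_design()].
#' @param true_control_rate,true_experimental_rate True response rates.
#' @param covariate_spec Named generator list, see
#'   [default_covariate_spec()]; use `list()` for no covariates.
#' @param seed Optional integer seed.
#' @return A `data.frame` with columns `patient_id`, `round_id`, `arm`,
#'   `response`, then one column per covariate.
#' @examples
#' head(generate_trial_data(three_round_design()$R1, 0.40, 0.65, seed = 1))
#' @export
generate_trial_data <- function(design, true_control_rate,
                                true_experimental_rate,
                                covariate_spec = default_covariate_spec(),
                                seed = NULL) {
  stopifnot(inherits(design, "round_design"))
  for (r in c(true_control_rate, true_experimental_rate))
    if (is.na(r) || r < 0 || r > 1)
      stop("response rates must lie in [0, 1]", call. = FALSE)
  check_covariate_spec(covariate_spec)
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_control + design$n_experimental
  arm <- rep(c("control", "experimental"),
             c(design$n_control, design$n_experimental))
  rate <- ifelse(arm == "control", true_control_rate, true_experimental_rate)
  out <- data.frame(
    patient_id = sprintf("%s-%04d", design$round_id, seq_len(n)),
    round_id = design$round_id,
    arm = arm,
    response = stats::rbinom(n, 1L, rate),
    stringsAsFactors = FALSE)
  for (nm in names(covariate_spec)) {
    cv <- covariate_spec[[nm]]
    out[[nm]] <- if (cv$type == "continuous")
      stats::rnorm(n, cv$mean, cv$sd)
    else
      sample(names(cv$proportions), n, replace = TRUE, prob = cv$proportions)
  }
  out
}

#' Aggregate patient-level records to arm-level outcomes
#'
#' Counts responders per arm per round and builds the per-round control
#' summaries (posterior response rate plus covariate summaries) consumed by
#' the drift report.
#'
#' @param records A `data.frame` as produced by [generate_trial_data()]
#'   (columns `patient_id`, `round_id`, `arm`, `response`, then covariates).
#' @param prior [beta_params()] prior for the control summaries.
#' @return A list of class `trial_aggregate` with elements `arms` (a
#'   `data.frame` of `round_id`, `arm`, `responders`, `total`), `outcomes`
#'   (nested list `outcomes[[round]][[arm]]` of [binom_outcome()]s) and
#'   `control_summaries` (list of [control_summary()]s, one per round).
#' @export
aggregate_trial_data <- function(records, prior = beta_params(1, 1)) {
  req <- c("patient_id", "round_id", "arm", "response")
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a non-empty data.frame", call. = FALSE)
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop("'records' is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(records$patient_id))
    stop("duplicate patient_id values in 'records'", call. = FALSE)
  if (!all(records$arm %in% c("control", "experimental")))
    stop("'arm' must be 'control' or 'experimental'", call. = FALSE)
  if (!all(records$response %in% c(0L, 1L)))
    stop("'response' must be coded 0/1", call. = FALSE)
  cov_cols <- setdiff(names(records), req)
  rounds <- unique(records$round_id)
  arm_rows <- list(); outcomes <- list(); summaries <- list()
  for (rid in rounds) {
    rd <- records[records$round_id == rid, , drop = FALSE]
    outcomes[[rid]] <- list()
    for (a in c("control", "experimental")) {
      sub <- rd[rd$arm == a, , drop = FALSE]
      if (nrow(sub) == 0L)
        stop("round ", rid, " has an empty ", a, " arm", call. = FALSE)
      o <- binom_outcome(sum(sub$response), nrow(sub))
      outcomes[[rid]][[a]] <- o
      arm_rows[[length(arm_rows) + 1L]] <- data.frame(
        round_id = rid, arm = a, responders = o$responders, total = o$total,
        stringsAsFactors = FALSE)
    }
    ctrl <- rd[rd$arm == "control", , drop = FALSE]
    covs <- list()
    for (nm in cov_cols) {
      v <- ctrl[[nm]]
      covs[[nm]] <- if (is.numeric(v))
        list(type = "continuous", mean = mean(v), sd = stats::sd(v))
      else {
        tab <- table(v)
        list(type = "categorical",
             proportions = stats::setNames(as.numeric(tab) / sum(tab),
                                           names(tab)))
      }
    }
    summaries[[rid]] <- control_summary(rid, outcomes[[rid]]$control,
                                        covariates = covs, prior = prior)
  }
  structure(list(arms = do.call(rbind, arm_rows), outcomes = outcomes,
                 control_summaries = summaries),
            class = "trial_aggregate")
}

#' @export
print.trial_aggregate <- function(x, ...) {
  cat("Aggregated trial data\n")
  print.data.frame(x$arms, row.names = FALSE)
  invisible(x)
}
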