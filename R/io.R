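#' Read a trial design configuration
#'
#' Parses a YAML or JSON configuration describing the rounds, the decision
#' rule, the simulation grid and the simulation settings:
#'
#' ```yaml
#' rounds:
#'   - id: R1
#'     n_control: 63
#'     n_experimental: 63
#'     allocation: [1, 1]
#'     borrow: []
#'   - id: R2
#'     n_control: 16
#'     n_experimental: 63
#'     allocation: [1, 4]
#'     borrow: [{from_round: R1, weight: 0.75}]
#' rule: {margin: 0.15, certainty: 0.60}
#' grid:
#'   control_rates: [0.40, 0.50, 0.60]
#'   differences: [-0.10, 0.0, 0.15, 0.25]
#'   certainties: [0.60]
#'   weights: [0.75]
#' sim: {reps: 10000, seed: 20230701}
#' ```
#'
#' Borrowing sources are resolved against earlier rounds in the same file
#' (the source round's control-arm size is taken from its definition).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `trial_config` with elements `designs` (named
#'   list of [round_design()]s), `rule` ([decision_rule()]), `grid` and
#'   `sim`.
#' @export
read_trial_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  if (is.null(raw$rounds) || length(raw$rounds) == 0L)
    stop("config must define at least one round", call. = FALSE)
  sizes <- list()
  designs <- list()
  for (rd in raw$rounds) {
    if (is.null(rd$id) || is.null(rd$n_control) || is.null(rd$n_experimental))
      stop("each round needs id, n_control and n_experimental", call. = FALSE)
    borrow <- list()
    for (b in rd$borrow %||% list()) {
      src_n <- sizes[[as.character(b$from_round)]]
      if (is.null(src_n))
        stop("round ", rd$id, " borrows from undefined earlier round '",
             b$from_round, "'", call. = FALSE)
      borrow[[length(borrow) + 1L]] <-
        borrow_spec(b$from_round, src_n, b$weight)
    }
    designs[[rd$id]] <- round_design(
      rd$id, rd$n_control, rd$n_experimental,
      allocation = as.numeric(rd$allocation %||% c(1, 1)),
      history = borrow)
    sizes[[rd$id]] <- rd$n_control
  }
  rule <- decision_rule(margin = raw$rule$margin %||% 0.15,
                        certainty = raw$rule$certainty %||% 0.60)
  structure(list(designs = designs, rule = rule,
                 grid = raw$grid %||% list(),
                 sim = raw$sim %||% list(reps = 10000, seed = 1)),
            class = "trial_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the scenario grid described by a configuration
#'
#' @param config A [read_trial_config()] result.
#' @param rounds Optional character vector restricting to some round ids.
#' @return A list of scenarios, as from [build_scenario_grid()].
#' @export
config_to_grid <- function(config, rounds = NULL) {
  stopifnot(inherits(config, "trial_config"))
  designs <- config$designs
  if (!is.null(rounds)) {
    missing_r <- setdiff(rounds, names(designs))
    if (length(missing_r))
      stop("config defines no round(s): ", paste(missing_r, collapse = ", "),
           call. = FALSE)
    designs <- designs[rounds]
  }
  g <- config$grid
  if (is.null(g$control_rates))
    stop("config grid must define control_rates", call. = FALSE)
  build_scenario_grid(
    control_rates = as.numeric(g$control_rates),
    differences = as.numeric(g$differences %||% 0),
    certainties = as.numeric(g$certainties %||% config$rule$certainty),
    weights = as.numeric(g$weights %||% 0.75),
    designs = designs,
    margin = config$rule$margin)
}

#' Write / read an operating-characteristics table as CSV
#'
#' Deterministic column order, UTF-8, dot decimal separator; the reader
#' restores the `oc_table` class so tables round-trip exactly.
#'
#' @param x An [oc_table()] result.
#' @param path Output / input CSV path.
#' @return `write_oc_csv` returns `path` invisibly; `read_oc_csv` the table.
#' @export
write_oc_csv <- function(x, path) {
  stopifnot(inherits(x, "data.frame"))
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_oc_csv
#' @export
read_oc_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8",
                         colClasses = c(round = "character",
                                        hist_rates = "character",
                                        hist_counts = "character"))
  class(out) <- c("oc_table", "data.frame")
  out
}

#' Write / read patient-level records as CSV
#'
#' @param records A patient-level `data.frame` (see [generate_trial_data()]).
#' @param path CSV path.
#' @return `write_patient_csv` returns `path` invisibly; `read_patient_csv`
#'   the records.
#' @export
write_patient_csv <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_patient_csv
#' @export
read_patient_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                  colClasses = c(patient_id = "character",
                                 round_id = "character",
                                 arm = "character"))
}

# "26/63" -> binom_outcome; "26/63:0.75" -> weighted_outcome
parse_outcome <- function(s) {
  m <- regmatches(s, regexec("^\\s*(\\d+)\\s*/\\s*(\\d+)\\s*$", s))[[1]]
  if (length(m) != 3L)
    stop("cannot parse outcome '", s, "' (expected 'responders/total')",
         call. = FALSE)
  binom_outcome(as.integer(m[2]), as.integer(m[3]))
}

parse_weighted_outcome <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("cannot parse weighted outcome '", s,
         "' (expected 'responders/total:weight')", call. = FALSE)
  weighted_outcome(parse_outcome(parts[1]), as.numeric(parts[2]))
}
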