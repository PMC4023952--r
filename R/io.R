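#' Read and write stimulus sequences as CSV
#'
#' The on-disk schema is one row per presented value with columns
#' `value`, `order_index`, `half` (A/B), `condition` (UB/BU/UN) and
#' `decile` (1--10), plus `participant_id` when several sequences are
#' stored in one file.
#'
#' @param x a stimulus-set tibble (single sequence or long table).
#' @param path file path.
#' @export
write_stimuli <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimuli
#' @return `read_stimuli` returns a tibble with the schema above.
#' @export
read_stimuli <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("value", "order_index", "half", "condition")
  if (!all(need %in% names(d))) {
    stop("stimulus CSV must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"decile" %in% names(d)) d$decile <- decile_of(d$value)
  tibble::as_tibble(d)
}

#' Read and write simulated response tables as CSV
#'
#' One row per participant, test time and task (sampling-task trials one
#' row per matrix), with `bin_1`...`bin_10` for production frequencies,
#' `choice` for the identification pick, `selected` as a
#' semicolon-joined value list for the sampling task, and
#' `est_mean`/`est_median`/`est_mad` for the descriptive task.
#'
#' @param x a responses tibble from [run_experiment()].
#' @param path file path.
#' @export
write_responses <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "condition", "test_time", "task")
  if (!all(need %in% names(d))) {
    stop("response CSV must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(d)
}

#' Split a semicolon-joined selection field
#'
#' @param selected character vector as stored in the `selected` column.
#' @return list of numeric vectors.
#' @export
parse_selected <- function(selected) {
  lapply(strsplit(selected, ";", fixed = TRUE), as.numeric)
}

#' Read an experiment configuration from a YAML file
#'
#' Recognized keys: `experiment`, `n_per_condition`, `seed`, `alpha`
#' (or `beta_alpha`), `conditions`, `anchor_weight`, and the sampling
#' scheme keys `policy`, `decay`, `k`, `k_jitter`, `n_pools`,
#' `with_replacement`, `response_noise_sd`. Missing keys take the
#' package defaults.
#'
#' @param path YAML file path.
#' @return an [experiment_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(key, default) if (!is.null(y[[key]])) y[[key]] else default
  scheme_defaults <- sampling_scheme()
  scheme <- sampling_scheme(
    policy = pick("policy", scheme_defaults$policy),
    decay = pick("decay", scheme_defaults$decay),
    k = pick("k", scheme_defaults$k),
    k_jitter = pick("k_jitter", scheme_defaults$k_jitter),
    n_pools = pick("n_pools", scheme_defaults$n_pools),
    with_replacement = pick("with_replacement", scheme_defaults$with_replacement),
    response_noise_sd = pick("response_noise_sd", scheme_defaults$response_noise_sd)
  )
  experiment_config(
    experiment = pick("experiment", 1),
    n_per_condition = pick("n_per_condition", NULL),
    scheme = scheme,
    seed = pick("seed", 1),
    alpha = pick("alpha", pick("beta_alpha", 2.4)),
    conditions = pick("conditions", c("UB", "BU", "UN")),
    anchor_weight = pick("anchor_weight", 0)
  )
}

#' Write the tables and analyses of a simulated experiment
#'
#' Writes `stimuli.csv`, `responses.csv`, `scored.csv`,
#' `deviations.csv`, `analysis.json` and a plain-text `run_log.txt`
#' (config echo and package version) under `dir`.
#'
#' @param result a [run_experiment()] result.
#' @param dir output directory, created if needed.
#' @return the directory path, invisibly.
#' @export
write_experiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stimuli(result$stimuli, file.path(dir, "stimuli.csv"))
  write_responses(result$responses, file.path(dir, "responses.csv"))
  utils::write.csv(as.data.frame(result$scored), file.path(dir, "scored.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$deviations),
                   file.path(dir, "deviations.csv"), row.names = FALSE)
  analysis <- lapply(result$analysis, function(tab) {
    lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, ]))
  })
  writeLines(to_json(analysis), file.path(dir, "analysis.json"))
  cfg <- result$config
  log_lines <- c(
    paste0("lazystat ", as.character(utils::packageVersion("lazystat"))),
    paste0("experiment: ", cfg$experiment),
    paste0("n_per_condition: ", cfg$n_per_condition),
    paste0("conditions: ", paste(cfg$conditions, collapse = ",")),
    paste0("policy: ", cfg$scheme$policy, " decay: ", cfg$scheme$decay,
           " k: ", cfg$scheme$k, " n_pools: ", cfg$scheme$n_pools),
    paste0("seed: ", cfg$seed)
  )
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

# Minimal JSON serializer for nested lists of scalars (keeps jsonlite a
# soft dependency).
to_json <- function(x) {
  if (is.list(x)) {
    if (is.null(names(x)) || any(names(x) == "")) {
      paste0("[", paste(vapply(x, to_json, character(1)), collapse = ","), "]")
    } else {
      paste0("{", paste(sprintf('"%s":%s', names(x),
                                vapply(x, to_json, character(1))), collapse = ","), "}")
    }
  } else if (is.character(x)) {
    sprintf('"%s"', x)
  } else if (is.na(x)) {
    "null"
  } else {
    format(x, digits = 15, scientific = FALSE)
  }
}
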