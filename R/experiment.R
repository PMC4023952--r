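#' Configuration of an in-silico replication
#'
#' Describes one full simulated experiment. Design 1 is a single test
#' phase after all 120 values (n = 16 per condition); design 2 interrupts
#' exposure after 60 values with an intermediate production test and then
#' tests again on the full 120 (n = 14 per condition), with final
#' judgments based on all experienced values.
#'
#' @param experiment 1 or 2.
#' @param n_per_condition participants per condition; defaults to 16 for
#'   design 1 and 14 for design 2.
#' @param scheme a [sampling_scheme()] shared by all simulants.
#' @param seed master seed; every participant gets an independent stream
#'   derived from it.
#' @param alpha shape parameter of the unimodal half (default 2.4).
#' @param conditions presentation-order conditions to run.
#' @param anchor_weight w in \[0, 1\]: design-2 final production blends
#'   w x intermediate profile with (1 - w) x fresh profile. The default
#'   0 means no anchoring; positive w expresses an anchor-and-adjust
#'   strategy.
#' @param task_order_counterbalance recorded label only; the simulant
#'   has no task carry-over, so counterbalancing cannot affect results.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(experiment = 1, n_per_condition = NULL,
                              scheme = sampling_scheme(), seed = 1,
                              alpha = 2.4, conditions = c("UB", "BU", "UN"),
                              anchor_weight = 0,
                              task_order_counterbalance = TRUE) {
  if (!experiment %in% c(1, 2)) stop("experiment must be 1 or 2", call. = FALSE)
  if (is.null(n_per_condition)) n_per_condition <- if (experiment == 1) 16 else 14
  if (anchor_weight < 0 || anchor_weight > 1) {
    stop("anchor_weight must be in [0, 1]", call. = FALSE)
  }
  structure(list(
    experiment = experiment, n_per_condition = as.integer(n_per_condition),
    scheme = scheme, seed = as.integer(seed), alpha = alpha,
    conditions = vapply(conditions, canonical_condition, character(1),
                        USE.NAMES = FALSE),
    anchor_weight = anchor_weight,
    task_order_counterbalance = isTRUE(task_order_counterbalance)
  ), class = "experiment_config")
}

#' Run a full in-silico experiment
#'
#' Generates the materials (exposure set E, withheld set T, the
#' unimodal/bimodal partition, the eight sampling matrices and the seven
#' prototypes), assigns `n_per_condition` simulated participants to each
#' condition, gives each an independent presentation order, encodes the
#' sequence into exemplar memory, simulates the four tasks under the
#' configured retrieval scheme, scores every response (Shape Index and
#' deviation measures) and runs the standard mixed ANOVAs. Fully
#' reproducible from the config seed.
#'
#' @param config an [experiment_config()].
#' @return list with elements `stimuli` (long per-participant
#'   sequences), `responses` (long response table), `scored` (Shape
#'   Index per participant, test time, task and provenance),
#'   `deviations` (signed/absolute deviation per measurement),
#'   `analysis` (named list of [mixed_anova()] tables), `normative`
#'   (true mean/median/MAD of E), `materials`, and the `config`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed
  E <- generate_uniform_set(seed = derive_seed(seed, 1))
  T_set <- generate_uniform_set(seed = derive_seed(seed, 2), exclude = E$value)
  part <- partition_unimodal_bimodal(E, alpha = config$alpha,
                                     seed = derive_seed(seed, 3))
  matrices <- generate_matrices(E, T_set, seed = derive_seed(seed, 4))
  prototypes <- generate_prototypes()
  norm_stats <- estimate_descriptives(E$value)

  stim_rows <- list(); resp_rows <- list(); score_rows <- list(); dev_rows <- list()
  counter <- 0L
  for (cond in config$conditions) {
    for (j in seq_len(config$n_per_condition)) {
      counter <- counter + 1L
      pid <- sprintf("p%03d", counter)
      pseed <- derive_seed(seed, 1000L + counter)
      sim <- simulate_participant(pid, cond, part, matrices, prototypes,
                                  norm_stats, config, pseed)
      stim_rows[[counter]] <- sim$stimuli
      resp_rows[[counter]] <- sim$responses
      score_rows[[counter]] <- sim$scored
      dev_rows[[counter]] <- sim$deviations
    }
  }
  stimuli <- do.call(rbind, stim_rows)
  responses <- do.call(rbind, resp_rows)
  scored <- do.call(rbind, score_rows)
  deviations <- do.call(rbind, dev_rows)
  analysis <- analyze_experiment(scored, deviations, config)
  list(stimuli = stimuli, responses = responses, scored = scored,
       deviations = deviations, analysis = analysis,
       normative = norm_stats,
       materials = list(E = E, T = T_set, partition = part,
                        matrices = matrices, prototypes = prototypes),
       config = config)
}

simulate_participant <- function(pid, cond, part, matrices, prototypes,
                                 norm_stats, config, pseed) {
  scheme <- config$scheme
  sequence <- order_by_condition(part$E_a, part$E_b, cond,
                                 seed = derive_seed(pseed, 1))
  stim <- tibble::as_tibble(sequence)
  stim <- tibble::add_column(stim, participant_id = pid, .before = 1)

  with_seed(derive_seed(pseed, 2), {
    memory <- encode(sequence)
    n_total <- length(memory$value)
    resp <- list(); sc <- list()

    intermediate_profile <- NULL
    if (config$experiment == 2) {
      half_mem <- encode(sequence$value[sequence$order_index <= n_total / 2])
      inter_total <- n_total / 2
      inter_counts <- simulate_production(half_mem, scheme, total = inter_total)
      intermediate_profile <- inter_counts / inter_total
      resp[["inter"]] <- response_row(pid, cond, "intermediate", "production",
                                      bins = inter_counts)
      sc[["inter"]] <- score_row(pid, cond, "intermediate", "production", "all",
                                 si_from_production(inter_counts, inter_total)$si)
    }

    prod_counts <- simulate_production(memory, scheme, total = n_total)
    if (!is.null(intermediate_profile) && config$anchor_weight > 0) {
      blended <- config$anchor_weight * intermediate_profile +
        (1 - config$anchor_weight) * prod_counts / n_total
      prod_counts <- largest_remainder(blended, n_total)
    }
    resp[["prod"]] <- response_row(pid, cond, "final", "production", bins = prod_counts)
    sc[["prod"]] <- score_row(pid, cond, "final", "production", "all",
                              si_from_production(prod_counts, n_total)$si)

    choice <- simulate_identification(memory, scheme, prototypes)
    resp[["ident"]] <- response_row(pid, cond, "final", "identification", choice = choice)
    sc[["ident"]] <- score_row(pid, cond, "final", "identification", "all",
                               si_from_identification(choice, prototypes)$si)

    sel_by_prov <- list(old = numeric(0), new = numeric(0))
    trial_ids <- sort(unique(matrices$trial_index))
    samp_rows <- lapply(trial_ids, function(tr) {
      m <- matrices[matrices$trial_index == tr, ]
      sel <- simulate_sampling_task(memory, scheme, m$value)
      prov <- m$provenance[1]
      sel_by_prov[[prov]] <<- c(sel_by_prov[[prov]], sel)
      response_row(pid, cond, "final", "sample", trial_index = tr,
                   provenance = prov,
                   selected = paste(sel, collapse = ";"))
    })
    resp[["samp"]] <- do.call(rbind, samp_rows)
    all_sel <- c(sel_by_prov$old, sel_by_prov$new)
    sc[["samp"]] <- rbind(
      score_row(pid, cond, "final", "sample", "all", si_from_sample(all_sel)$si),
      score_row(pid, cond, "final", "sample", "old", si_from_sample(sel_by_prov$old)$si),
      score_row(pid, cond, "final", "sample", "new", si_from_sample(sel_by_prov$new)$si)
    )

    # descriptive task: each statistic from its own independent retrieval
    noise <- function() {
      if (scheme$response_noise_sd > 0) stats::rnorm(1, 0, scheme$response_noise_sd) else 0
    }
    est_mean <- mean(draw_sample(memory, scheme)) + noise()
    est_median <- stats::median(draw_sample(memory, scheme)) + noise()
    s <- draw_sample(memory, scheme)
    est_mad <- mean(abs(s - mean(s))) + noise()
    resp[["desc"]] <- response_row(pid, cond, "final", "descriptive",
                                   est_mean = est_mean, est_median = est_median,
                                   est_mad = est_mad)
    dev_ct <- collapse_central_tendency(
      deviation(est_mean, norm_stats$mean),
      deviation(est_median, norm_stats$median)
    )
    dev_var <- deviation(est_mad, norm_stats$mad, "variability")
    deviations <- tibble::tibble(
      participant_id = pid, condition = cond,
      measurement = c("central_tendency", "variability"),
      signed = c(dev_ct$signed, dev_var$signed),
      absolute = c(dev_ct$absolute, dev_var$absolute)
    )

    list(stimuli = stim, responses = do.call(rbind, resp),
         scored = do.call(rbind, sc), deviations = deviations)
  })
}

response_row <- function(pid, cond, test_time, task, bins = NULL, choice = NA,
                         trial_index = NA, provenance = NA, selected = NA,
                         est_mean = NA, est_median = NA, est_mad = NA) {
  row <- tibble::tibble(
    participant_id = pid, condition = cond, test_time = test_time, task = task,
    choice = as.integer(choice), trial_index = as.integer(trial_index),
    provenance = as.character(provenance), selected = as.character(selected),
    est_mean = as.numeric(est_mean), est_median = as.numeric(est_median),
    est_mad = as.numeric(est_mad)
  )
  b <- matrix(NA_integer_, nrow = nrow(row), ncol = 10,
              dimnames = list(NULL, paste0("bin_", 1:10)))
  if (!is.null(bins)) b[1, ] <- bins
  cbind(row, tibble::as_tibble(b))
}

score_row <- function(pid, cond, test_time, task, provenance, si) {
  tibble::tibble(participant_id = pid, condition = cond, test_time = test_time,
                 task = task, provenance = provenance, si = si)
}

analyze_experiment <- function(scored, deviations, config) {
  # degenerate designs (e.g. a single participant per condition leave no
  # between-subjects error df) keep the simulation output but drop the test
  try_anova <- function(...) {
    tryCatch(mixed_anova(...), error = function(e) {
      warning("ANOVA skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
  }
  analysis <- list()
  final <- scored[scored$test_time == "final" & scored$provenance == "all", ]
  analysis$si_by_task <- try_anova(final, "si", "condition", "task")
  analysis$deviation_absolute <-
    try_anova(deviations, "absolute", "condition", "measurement")
  analysis$deviation_signed <-
    try_anova(deviations, "signed", "condition", "measurement")
  oldnew <- scored[scored$task == "sample" & scored$provenance %in% c("old", "new"), ]
  analysis$old_new <- try_anova(oldnew, "si", "condition", "provenance")
  if (config$experiment == 2) {
    prod <- scored[scored$task == "production" & scored$provenance == "all", ]
    analysis$production_by_test_time <-
      try_anova(prod, "si", "condition", "test_time")
  }
  analysis
}

#' Old versus new Shape Index in the sampling task
#'
#' Summarizes the sampling-task Shape Index separately for matrices
#' built from exposed (old) and withheld (new) values. Because the
#' simulant's selections depend only on the remembered profile, old and
#' new differ only by sampling noise — the constructive analogue of the
#' no-difference finding for human selections.
#'
#' @param scored a scored table from [run_experiment()] (or any table
#'   with columns `task`, `provenance`, `si`).
#' @return tibble with one row per provenance: `provenance`, `mean_si`,
#'   `sd_si`, `n`. Warns if a provenance is absent.
#' @export
old_new_comparison <- function(scored) {
  s <- scored[scored$task == "sample" & scored$provenance %in% c("old", "new"), ]
  present <- unique(s$provenance)
  missing <- setdiff(c("old", "new"), present)
  if (length(missing)) {
    warning("no '", paste(missing, collapse = "', '"),
            "' sampling trials in the scored table", call. = FALSE)
  }
  out <- lapply(present, function(pv) {
    si <- s$si[s$provenance == pv]
    tibble::tibble(provenance = pv, mean_si = mean(si),
                   sd_si = stats::sd(si), n = length(si))
  })
  do.call(rbind, out)
}
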