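#' Task design specification
#'
#' Describes the trial/run structure of a delayed match-to-sample working
#' memory session: runs manipulating memory load (high vs. low) and runs
#' manipulating the motor response (respond vs. abstain). Defaults reproduce
#' a 4-run session of 16 trials of 30.7 s each at TR = 2 s, where each trial
#' is sample (3.5 s, followed by a 0.2 s mask), delay (13 s), response window
#' (4.2 s) and inter-trial interval (10 s). Runs start with a pre-trial
#' lead-in so that a 16-trial run lasts 504 s (252 scans).
#'
#' @param n_runs_load,n_runs_motor number of load- and motor-manipulation
#'   runs.
#' @param trials_per_run trials per run (must be even).
#' @param trial_duration_s trial length in seconds.
#' @param sample_s,delay_s,response_window_s,iti_s durations of the trial
#'   components, in seconds; they must sum to `trial_duration_s`.
#' @param mask_s duration of the post-sample visual mask; part of the
#'   encoding window for signal injection but not of the duration identity.
#' @param max_consecutive_same longest permitted streak of identical
#'   conditions within a run.
#' @param tr_s repetition time in seconds.
#' @param lead_in_s pre-trial lead-in at the start of each run, seconds.
#' @param baseline_s post-trial tail appended after the last trial, seconds
#'   (0 by default; the lead-in already covers the run-length difference).
#'
#' @return An object of class `design_spec` (a list of the validated fields,
#'   plus `run_length_s` and `n_scans`).
#' @export
design_spec <- function(n_runs_load = 2L, n_runs_motor = 2L,
                        trials_per_run = 16L, trial_duration_s = 30.7,
                        sample_s = 3.5, delay_s = 13, response_window_s = 4.2,
                        iti_s = 10, mask_s = 0.2,
                        max_consecutive_same = 3L, tr_s = 2.0,
                        lead_in_s = 12.8, baseline_s = 0) {
  trials_per_run <- check_count(trials_per_run, "trials_per_run", lower = 2L)
  if (trials_per_run %% 2L != 0L) {
    stop_ld("`trials_per_run` must be even (two counterbalanced conditions)")
  }
  max_consecutive_same <- check_count(max_consecutive_same,
                                      "max_consecutive_same", lower = 1L)
  check_number(trial_duration_s, "trial_duration_s", lower = 1e-9)
  check_number(tr_s, "tr_s", lower = 1e-9)
  check_number(lead_in_s, "lead_in_s", lower = 0)
  component_sum <- sample_s + delay_s + response_window_s + iti_s
  if (abs(component_sum - trial_duration_s) > 1e-9) {
    stop_ld(sprintf(
      "trial components (sample %g + delay %g + response %g + iti %g = %g s) must sum to trial_duration_s = %g s",
      sample_s, delay_s, response_window_s, iti_s, component_sum,
      trial_duration_s))
  }
  run_length_s <- lead_in_s + trials_per_run * trial_duration_s + baseline_s
  spec <- list(
    n_runs_load = check_count(n_runs_load, "n_runs_load"),
    n_runs_motor = check_count(n_runs_motor, "n_runs_motor"),
    trials_per_run = trials_per_run,
    trial_duration_s = trial_duration_s,
    sample_s = sample_s, delay_s = delay_s, mask_s = mask_s,
    response_window_s = response_window_s, iti_s = iti_s,
    max_consecutive_same = max_consecutive_same,
    tr_s = tr_s, lead_in_s = lead_in_s, baseline_s = baseline_s,
    run_length_s = run_length_s,
    n_scans = as.integer(ceiling(run_length_s / tr_s))
  )
  class(spec) <- "design_spec"
  spec
}

run_conditions <- function(run_type) {
  switch(run_type,
         load = c("high", "low"),
         motor = c("response", "abstain"),
         stop_ld(sprintf("unknown run type '%s'", run_type)))
}

#' Generate pseudorandomized event tables for one session
#'
#' Draws a counterbalanced, pseudorandomized condition sequence for every run:
#' each run has exactly `trials_per_run / 2` trials per condition and no
#' streak longer than `max_consecutive_same`. Trial onsets follow the fixed
#' trial clock (`lead_in_s + (k - 1) * trial_duration_s`), which is not
#' TR-locked when the trial duration is not a TR multiple.
#'
#' @param spec a [design_spec()].
#' @param seed integer seed; identical seeds give identical designs.
#' @param max_tries bounded number of resampling attempts per run before the
#'   streak constraint is declared infeasible.
#'
#' @return A list of event tables (class `event_table`, a data.frame with
#'   columns `onset_s`, `duration_s`, `condition`, `run`, `run_type`,
#'   `trial_index`, `prev_condition`), one per run; load runs first.
#'   `prev_condition` is `NA` for the first trial of each run (see
#'   [fill_prev_across_runs()]).
#' @export
generate_design <- function(spec, seed = NULL, max_tries = 1000L) {
  stopifnot(inherits(spec, "design_spec"))
  with_local_seed(seed, {
    run_types <- c(rep("load", spec$n_runs_load),
                   rep("motor", spec$n_runs_motor))
    lapply(seq_along(run_types), function(r) {
      conds <- run_conditions(run_types[r])
      base <- rep(conds, each = spec$trials_per_run / 2L)
      seq_ok <- NULL
      for (i in seq_len(max_tries)) {
        cand <- sample(base)
        if (max_streak(cand) <= spec$max_consecutive_same) {
          seq_ok <- cand
          break
        }
      }
      if (is.null(seq_ok)) {
        stop_ld(sprintf(
          "could not satisfy max_consecutive_same = %d within %d tries",
          spec$max_consecutive_same, max_tries))
      }
      k <- seq_len(spec$trials_per_run)
      ev <- data.frame(
        onset_s = spec$lead_in_s + (k - 1L) * spec$trial_duration_s,
        duration_s = spec$trial_duration_s,
        condition = seq_ok,
        run = r,
        run_type = run_types[r],
        trial_index = k,
        prev_condition = c(NA_character_, seq_ok[-length(seq_ok)]),
        stringsAsFactors = FALSE
      )
      class(ev) <- c("event_table", "data.frame")
      ev
    })
  })
}

#' Fill first-trial previous conditions across runs
#'
#' The first trial of a run has no within-run predecessor; for
#' transition-balanced decoding its previous condition is taken from the last
#' trial of the preceding run of the same run type. The first run of each
#' type keeps `NA` (such trials may be tested on but never trained on).
#'
#' @param events list of event tables from [generate_design()].
#' @return The list with `prev_condition` filled where a preceding same-type
#'   run exists.
#' @export
fill_prev_across_runs <- function(events) {
  last_of_type <- list()
  for (i in seq_along(events)) {
    ev <- events[[i]]
    ty <- ev$run_type[1L]
    if (!is.null(last_of_type[[ty]]) && is.na(ev$prev_condition[1L])) {
      ev$prev_condition[1L] <- last_of_type[[ty]]
      events[[i]] <- ev
    }
    last_of_type[[ty]] <- ev$condition[nrow(ev)]
  }
  events
}

#' Check that every trial-transition subtype occurs in a session
#'
#' Transition-balanced decoding needs trials of all four current x previous
#' condition subtypes per run type; short runs can by chance miss one.
#'
#' @param events list of event tables with previous conditions filled
#'   (see [fill_prev_across_runs()]).
#' @return TRUE if, for every run type present, all four subtypes occur
#'   among trials with a known previous condition.
#' @export
all_transitions_present <- function(events) {
  ev <- do.call(rbind, events)
  for (ty in unique(ev$run_type)) {
    sub <- ev[ev$run_type == ty & !is.na(ev$prev_condition), ]
    conds <- run_conditions(ty)
    need <- as.vector(outer(conds, conds, paste, sep = "<-"))
    have <- unique(paste(sub$condition, sub$prev_condition, sep = "<-"))
    if (!all(need %in% have)) return(FALSE)
  }
  TRUE
}

#' Simulate behavioral responses
#'
#' Draws per-trial correctness as Bernoulli with condition-specific rates and
#' response times from a lognormal around condition-specific means. Abstain
#' trials are "correct" when the response is withheld and carry no RT.
#'
#' @param events an event table or list of event tables.
#' @param acc_by_condition named vector of accuracy rates in `[0, 1]`; must
#'   cover every condition present. Defaults follow typical performance:
#'   high load 0.743, low load 0.955, response 0.993, abstain 0.979.
#' @param rt_by_condition named vector of mean RTs in seconds for responding
#'   conditions.
#' @param rt_sdlog lognormal sdlog for RT dispersion.
#' @param seed integer seed.
#'
#' @return data.frame with columns `run`, `trial_index`, `condition`,
#'   `correct` (logical), `rt_s` (NA for abstain trials).
#' @export
simulate_behavior <- function(events,
                              acc_by_condition = c(high = 0.743, low = 0.955,
                                                   response = 0.993,
                                                   abstain = 0.979),
                              rt_by_condition = c(high = 1.6, low = 1.1,
                                                  response = 1.3),
                              rt_sdlog = 0.2, seed = NULL) {
  if (is.data.frame(events)) events <- list(events)
  ev <- do.call(rbind, events)
  if (any(acc_by_condition < 0 | acc_by_condition > 1)) {
    stop_ld("accuracies must be in [0, 1]")
  }
  missing_cond <- setdiff(unique(ev$condition), names(acc_by_condition))
  if (length(missing_cond)) {
    stop_ld("no accuracy rate for condition(s): ",
            paste(missing_cond, collapse = ", "))
  }
  with_local_seed(seed, {
    correct <- stats::runif(nrow(ev)) < acc_by_condition[ev$condition]
    rt <- rep(NA_real_, nrow(ev))
    responds <- ev$condition != "abstain"
    if (any(responds)) {
      mu <- rt_by_condition[ev$condition[responds]]
      if (anyNA(mu)) stop_ld("no RT mean for a responding condition")
      rt[responds] <- stats::rlnorm(sum(responds),
                                    meanlog = log(mu) - rt_sdlog^2 / 2,
                                    sdlog = rt_sdlog)
    }
    data.frame(run = ev$run, trial_index = ev$trial_index,
               condition = ev$condition, correct = unname(correct),
               rt_s = rt, stringsAsFactors = FALSE)
  })
}
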