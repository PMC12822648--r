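COMBOS <- c("A30", "A90", "B30", "B90")

combo_shape <- function(cond) {
  ifelse(cond %in% c("A30", "B90"), "wide",
         ifelse(cond %in% c("A90", "B30"), "narrow", NA_character_))
}

combo_background <- function(cond) {
  ifelse(grepl("30$", cond), "30", ifelse(grepl("90$", cond), "90",
                                          NA_character_))
}

#' Design parameters for a synthetic experiment
#'
#' Encodes the trial and run structure of the two event-related designs.
#' Experiment 1: seven main-task runs of 48 trials each, 75% of which end
#' with a scene-congruent object orientation, plus three classifier-training
#' runs of orientation-by-rotation mini-blocks. Experiment 2: eight
#' main-task runs of 40 trials whose final occlusion period is modelled as a
#' boxcar, 12.5% catch trials on which the object reappears, plus three
#' training runs of wide/narrow mini-blocks without a scene background.
#' Both experiments include two functional localizer runs.
#'
#' Trials are laid on a fixed within-run grid (one trial every
#' `trial_period_s` seconds after a 15 s lead-in) and the critical event --
#' object reappearance (Experiment 1, impulse) or the occluded final period
#' (Experiment 2, boxcar) -- carries a uniformly jittered onset, mirroring
#' the jittered final-view duration of the task.
#'
#' @param experiment 1 or 2.
#' @param ... overrides for any field listed below.
#' @return object of class `design_params` with fields `experiment`,
#'   `n_runs_main`, `trials_per_run`, `p_congruent`, `conditions`,
#'   `n_runs_training`, `miniblocks_per_training_run`, `n_runs_localizer`,
#'   `miniblocks_per_localizer_run`, `catch_fraction`, `catch_range`,
#'   `tr_seconds`, `run_length_volumes` (named: main, training, localizer),
#'   `trial_period_s`, `n_splits`.
#' @export
design_params <- function(experiment = 1, ...) {
  stopifnot(experiment %in% c(1, 2))
  p <- if (experiment == 1) {
    list(experiment = 1L, n_runs_main = 7L, trials_per_run = 48L,
         p_congruent = 0.75, conditions = COMBOS,
         n_runs_training = 3L, miniblocks_per_training_run = 20L,
         n_runs_localizer = 2L, miniblocks_per_localizer_run = 16L,
         catch_fraction = 0, catch_range = c(0L, 0L),
         tr_seconds = 1,
         run_length_volumes = c(main = 404L, training = 333L,
                                localizer = 318L),
         trial_period_s = 7.5, n_splits = 3L)
  } else {
    list(experiment = 2L, n_runs_main = 8L, trials_per_run = 40L,
         p_congruent = NA_real_, conditions = COMBOS,
         n_runs_training = 3L, miniblocks_per_training_run = 40L,
         n_runs_localizer = 2L, miniblocks_per_localizer_run = 16L,
         catch_fraction = 0.125, catch_range = c(2L, 10L),
         tr_seconds = 1,
         run_length_volumes = c(main = 315L, training = 333L,
                                localizer = 318L),
         trial_period_s = 7.0, n_splits = NA_integer_)
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown design parameter(s): ", paste(unknown, collapse = ", "))
  p <- modifyList(p, dots)
  p <- validate_design_params(p)
  class(p) <- "design_params"
  p
}

validate_design_params <- function(p) {
  if (p$experiment == 1) {
    n_cong <- p$p_congruent * p$trials_per_run
    n_inc <- p$trials_per_run - n_cong
    if (p$p_congruent < 0 || p$p_congruent > 1)
      stop("configuration error: p_congruent must lie in [0, 1]")
    if (n_cong != round(n_cong))
      stop("configuration error: p_congruent * trials_per_run is not ",
           "an integer trial count")
    if (n_cong %% 4 != 0 || n_inc %% 4 != 0)
      stop("configuration error: trials are not divisible evenly across ",
           "the 4 conditions within each congruency cell")
    if (n_inc > 0 && n_cong %% n_inc != 0)
      stop("configuration error: congruent trials cannot be split into ",
           "subsets matching the incongruent trial count")
    p$n_splits <- if (n_inc > 0) as.integer(n_cong / n_inc) else 1L
    if (p$n_splits > 1 && (n_cong / 4) %% p$n_splits != 0)
      stop("configuration error: congruent trials per condition (",
           n_cong / 4, ") are not divisible into ", p$n_splits, " splits")
  } else {
    if (p$trials_per_run %% 4 != 0)
      stop("configuration error: trials are not divisible evenly across ",
           "the 4 conditions")
    n_catch <- p$catch_fraction * p$trials_per_run * p$n_runs_main
    if (n_catch != round(n_catch))
      stop("configuration error: catch_fraction does not yield an integer ",
           "number of catch trials")
  }
  # events (plus a 15 s response tail) must fit in the run
  main_end <- 15 + (p$trials_per_run - 1) * p$trial_period_s + 6
  if (main_end + 15 > p$run_length_volumes[["main"]] * p$tr_seconds)
    stop("configuration error: main-task events (last ends at ", main_end,
         " s plus 15 s tail) exceed run_length_volumes")
  mb <- p$miniblocks_per_training_run
  per_series <- if (p$experiment == 1) 4L else 8L
  mb_dur <- if (p$experiment == 1) 13.5 else 6.75
  tr_end <- 15 + (mb - 1) * mb_dur + floor((mb - 1) / per_series) * 6.75 +
    mb_dur
  if (tr_end + 15 > p$run_length_volumes[["training"]] * p$tr_seconds)
    stop("configuration error: training mini-blocks (last ends at ", tr_end,
         " s plus 15 s tail) exceed run_length_volumes")
  p
}

event_attrs <- function(df, params, run_type, run) {
  attr(df, "experiment") <- params$experiment
  attr(df, "run_type") <- run_type
  attr(df, "n_volumes") <-
    as.integer(params$run_length_volumes[[run_type]])
  attr(df, "tr_seconds") <- params$tr_seconds
  attr(df, "run") <- run
  class(df) <- c("event_table", "data.frame")
  df
}

new_events <- function(onset, duration, condition, shape, background,
                       congruency, split_id, miniblock, catch, sim_label,
                       glm_label, run) {
  data.frame(onset = onset, duration = duration, condition = condition,
             shape = shape, background = background, congruency = congruency,
             split_id = split_id, miniblock = miniblock, catch = catch,
             sim_label = sim_label, glm_label = glm_label, run = run,
             stringsAsFactors = FALSE)
}

make_main_run_exp1 <- function(params, run, seed) {
  t_per <- params$trials_per_run
  n_cong <- as.integer(params$p_congruent * t_per)
  n_inc <- t_per - n_cong
  with_seed(seed, {
    congr <- sample(rep(c("congruent", "incongruent"), c(n_cong, n_inc)))
    cond <- character(t_per)
    cond[congr == "congruent"] <- sample(rep(params$conditions, n_cong / 4))
    cond[congr == "incongruent"] <- sample(rep(params$conditions, n_inc / 4))
    split <- rep(NA_integer_, t_per)
    # splits balanced within condition so every condition-by-split cell is
    # populated (9 congruent trials per condition -> 3 per split)
    for (cd in params$conditions) {
      sel <- which(congr == "congruent" & cond == cd)
      split[sel] <- sample(rep(seq_len(params$n_splits),
                               length(sel) / params$n_splits))
    }
    jit <- runif(t_per, 0, 0.5)
  })
  start <- 15 + (seq_len(t_per) - 1) * params$trial_period_s
  onset <- start + 5.5 + jit
  lab <- paste0(cond, ".", congr,
                ifelse(is.na(split), "", paste0(".s", split)))
  df <- new_events(onset, 0, cond, combo_shape(cond),
                   combo_background(cond), congr, split, NA_integer_,
                   FALSE, lab, lab, run)
  df$fir_label <- paste(df$shape, df$congruency, sep = ".")
  event_attrs(df, params, "main", run)
}

make_main_run_exp2 <- function(params, run, n_catch_run, seed) {
  t_per <- params$trials_per_run
  with_seed(seed, {
    cond <- sample(rep(params$conditions, t_per / 4))
    catch <- seq_len(t_per) %in% sample.int(t_per, n_catch_run)
    dur <- 1.5 + runif(t_per, 0, 0.5)
  })
  start <- 15 + (seq_len(t_per) - 1) * params$trial_period_s
  onset <- start + 4.0
  shape <- combo_shape(cond)
  df <- new_events(onset, dur, cond, shape, combo_background(cond),
                   "n/a", NA_integer_, NA_integer_, catch,
                   paste0("occl.", cond),
                   ifelse(catch, "catch", shape), run)
  if (any(catch)) {
    ci <- which(catch)
    reap <- new_events(onset[ci] + dur[ci], 0, cond[ci], shape[ci],
                       combo_background(cond[ci]), "n/a", NA_integer_,
                       NA_integer_, TRUE, paste0("reapp.", cond[ci]),
                       "reappearance", run)
    df <- rbind(df, reap)
    df <- df[order(df$onset), , drop = FALSE]
    rownames(df) <- NULL
  }
  event_attrs(df, params, "main", run)
}

make_training_run <- function(params, run, seed) {
  mb <- params$miniblocks_per_training_run
  if (params$experiment == 1) {
    per_series <- 4L; mb_dur <- 13.5
    # each series of four mini-blocks holds the four combinations once
    stopifnot(mb %% 4 == 0)
    with_seed(seed, {
      cond <- as.vector(vapply(seq_len(mb / 4),
                               function(i) sample(params$conditions),
                               character(4)))
    })
    shape <- combo_shape(cond)
  } else {
    per_series <- 8L; mb_dur <- 6.75
    stopifnot(mb %% 2 == 0)
    # wide/narrow balanced within each series of eight
    with_seed(seed, {
      cond <- rep(NA_character_, mb)
      shape <- as.vector(vapply(seq_len(mb / 8), function(i)
        sample(rep(c("wide", "narrow"), 4)), character(8)))
    })
  }
  k <- seq_len(mb)
  onset <- 15 + (k - 1) * mb_dur + floor((k - 1) / per_series) * 6.75
  lab <- if (params$experiment == 1) paste0(cond, ".mb", k)
         else paste0(shape, ".mb", k)
  df <- new_events(onset, mb_dur, cond, shape,
                   if (params$experiment == 1) combo_background(cond)
                   else "none",
                   "n/a", NA_integer_, k, FALSE, lab, lab, run)
  event_attrs(df, params, "training", run)
}

make_localizer_run <- function(params, run, seed) {
  cats <- c("objects", "scrambled", "faces", "scenes")
  mb <- params$miniblocks_per_localizer_run
  stopifnot(mb %% 4 == 0)
  with_seed(seed, {
    cond <- as.vector(vapply(seq_len(mb / 4), function(i) sample(cats),
                             character(4)))
  })
  k <- seq_len(mb)
  onset <- 15 + (k - 1) * 15 + floor((k - 1) / 4) * 12
  df <- new_events(onset, 15, cond, NA_character_, NA_character_, "n/a",
                   NA_integer_, k, FALSE, cond, cond, run)
  event_attrs(df, params, "localizer", run)
}

#' Generate the event tables for one synthetic subject
#'
#' Builds randomized trial/mini-block event tables for the main-task,
#' classifier-training, and functional-localizer runs of the configured
#' experiment. Condition counts are exact by construction: in Experiment 1
#' every run carries 36 congruent and 12 incongruent trials (at the default
#' 48 trials, 75% congruent), balanced across the four
#' orientation-by-rotation combinations within each congruency cell, and
#' the congruent trials of each run are partitioned into three splits the
#' size of the incongruent cell. In Experiment 2, 12.5% of trials across
#' the session are catch trials on which the object reappears; these are
#' flagged for exclusion (between 2 and 10 per run).
#'
#' @param params a [design_params()] object.
#' @param seed integer seed; identical `(params, seed)` pairs reproduce
#'   identical tables.
#' @return object of class `experiment_design`: list with elements `main`,
#'   `training`, `localizer` (each a list of event tables), plus `params`
#'   and `seed`.
#' @export
make_design <- function(params, seed) {
  stopifnot(inherits(params, "design_params"))
  n_catch_run <- integer(params$n_runs_main)
  if (params$experiment == 2 && params$catch_fraction > 0) {
    total <- as.integer(params$catch_fraction * params$trials_per_run *
                          params$n_runs_main)
    n_catch_run <- with_seed(derive_seed(seed, 3), {
      repeat {
        k <- as.vector(rmultinom(1, total, rep(1, params$n_runs_main)))
        if (all(k >= params$catch_range[1] & k <= params$catch_range[2]))
          break
      }
      k
    })
  }
  main <- lapply(seq_len(params$n_runs_main), function(r) {
    s <- derive_seed(seed, 1, r)
    if (params$experiment == 1) make_main_run_exp1(params, r, s)
    else make_main_run_exp2(params, r, n_catch_run[r], s)
  })
  training <- lapply(seq_len(params$n_runs_training), function(r)
    make_training_run(params, r, derive_seed(seed, 2, r)))
  localizer <- lapply(seq_len(params$n_runs_localizer), function(r)
    make_localizer_run(params, r, derive_seed(seed, 4, r)))
  structure(list(main = main, training = training, localizer = localizer,
                 params = params, seed = seed),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  p <- x$params
  cat("Synthetic experiment design (Experiment ", p$experiment, ")\n",
      "  main: ", p$n_runs_main, " runs x ", p$trials_per_run, " trials\n",
      "  training: ", p$n_runs_training, " runs x ",
      p$miniblocks_per_training_run, " mini-blocks\n",
      "  localizer: ", p$n_runs_localizer, " runs\n", sep = "")
  invisible(x)
}
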