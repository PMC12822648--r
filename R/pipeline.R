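#' Pipeline configuration
#'
#' Assembles and validates the full configuration of a synthetic-cohort
#' analysis: design and generative parameters, voxel budgets, decoding
#' options, and group-statistics options. Unknown keys are rejected. Every
#' default is serialized into the run manifest, so a results bundle always
#' records the active value of each analysis choice.
#'
#' @param experiment 1 or 2.
#' @param n_subjects cohort size (default 34).
#' @param seed base integer seed for the whole pipeline.
#' @param voxels_per_roi named vector, voxels per ROI per hemisphere.
#' @param n_other additional non-visual voxels for whole-brain maps.
#' @param subroi_counts voxel-inclusion grid for the sub-ROI sweep.
#' @param rois ROIs to decode.
#' @param design named list of [design_params()] overrides.
#' @param truth named list of [truth_params()] overrides.
#' @param decode list: `cost`, `pooling` ("pooled"/"within_run"),
#'   `measure` ("information"/"accuracy"), `direction` (summary direction).
#' @param stats list: `E`, `H`, `dh`, `n_permutations`, `alpha`,
#'   `cluster_min`, `tfce_null_mode` ("max"/"pointwise"), `fisher_z`.
#' @param coupling list: `enabled`, `settings`, `n_bins`, `seed_roi`.
#' @param univariate run the univariate analyses (Experiment 1).
#' @param tmap_source `"meta"` (use the generator's localizer statistic)
#'   or `"localizer"` (simulate localizer runs and estimate the t map).
#' @param attention_sd report-noise SD of attentive subjects (Exp 2).
#' @param n_inattentive number of injected inattentive subjects (Exp 2).
#' @param inattentive_sd report-noise SD of inattentive subjects.
#' @param out_dir optional output directory for tidy CSV results.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(experiment = 1, n_subjects = 34, seed = 1,
                            voxels_per_roi = c(EVC = 1500, LVC = 1500),
                            n_other = 0,
                            subroi_counts = seq(100, 1500, by = 100),
                            rois = c("EVC", "LVC"),
                            design = list(), truth = list(),
                            decode = list(), stats = list(),
                            coupling = list(), univariate = TRUE,
                            tmap_source = c("meta", "localizer"),
                            attention_sd = 0.5, n_inattentive = 0,
                            inattentive_sd = 20, out_dir = NULL) {
  tmap_source <- match.arg(tmap_source)
  decode_def <- list(cost = 1, pooling = "pooled", measure = "information",
                     direction = "average")
  stats_def <- list(E = 0.5, H = 2, dh = NULL, n_permutations = 10000,
                    alpha = 0.001, cluster_min = 10,
                    tfce_null_mode = "max", fisher_z = FALSE)
  coupling_def <- list(enabled = FALSE, settings = seq(500, 1000, by = 100),
                       n_bins = 10, seed_roi = "EVC")
  check_keys <- function(given, def, what) {
    unk <- setdiff(names(given), names(def))
    if (length(unk))
      stop("unknown ", what, " option(s): ", paste(unk, collapse = ", "))
    modifyList(def, given)
  }
  cfg <- list(experiment = as.integer(experiment),
              n_subjects = as.integer(n_subjects),
              seed = as.integer(seed),
              voxels_per_roi = voxels_per_roi, n_other = as.integer(n_other),
              subroi_counts = subroi_counts, rois = rois,
              design = design, truth = truth,
              decode = check_keys(decode, decode_def, "decode"),
              stats = check_keys(stats, stats_def, "stats"),
              coupling = check_keys(coupling, coupling_def, "coupling"),
              univariate = isTRUE(univariate), tmap_source = tmap_source,
              attention_sd = attention_sd,
              n_inattentive = as.integer(n_inattentive),
              inattentive_sd = inattentive_sd, out_dir = out_dir)
  if (!all(rois %in% names(voxels_per_roi)))
    stop("rois must be named in voxels_per_roi")
  if (max(subroi_counts) > max(voxels_per_roi[rois]))
    stop("configuration error: requested sub-ROI maximum (",
         max(subroi_counts), ") exceeds the per-hemisphere voxel budget (",
         max(voxels_per_roi[rois]), ")")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys must match [pipeline_config()] arguments; unknown keys
#' are rejected.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a `pipeline_config` object.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  allowed <- names(formals(pipeline_config))
  unk <- setdiff(names(raw), allowed)
  if (length(unk))
    stop("unknown configuration key(s): ", paste(unk, collapse = ", "))
  if (!is.null(raw$voxels_per_roi))
    raw$voxels_per_roi <- unlist(raw$voxels_per_roi)
  do.call(pipeline_config, raw)
}

config_hash <- function(cfg) {
  txt <- paste(deparse(unclass(cfg)), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(txt)) h <- ((bitwXor(as.integer(h %% 2^31), b)) *
                                    16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

make_params_from_config <- function(config) {
  list(params = do.call(design_params,
                        c(list(experiment = config$experiment),
                          config$design)),
       tparams = do.call(truth_params,
                         c(list(experiment = config$experiment),
                           config$truth)))
}

subject_subrois <- function(config, truth, training_seed_runs = NULL) {
  tmap <- if (config$tmap_source == "meta") truth$voxel_meta$localizer_t
  else localizer_tmap(training_seed_runs)
  make_subrois(tmap, truth$voxel_meta, counts = config$subroi_counts,
               rois = config$rois)
}

# simulate and analyze one Experiment 1 subject; heavy run data are
# discarded run-by-run
subject_pipeline_exp1 <- function(config, params, tparams, subj_seed,
                                  decode_only = FALSE) {
  design <- make_design(params, derive_seed(subj_seed, 1))
  truth <- make_subject(params, tparams, derive_seed(subj_seed, 2),
                        voxels_per_roi = config$voxels_per_roi,
                        n_other = config$n_other)
  run_seed <- derive_seed(subj_seed, 3)
  training_betas <- lapply(seq_along(design$training), function(r) {
    vts <- simulate_run(design$training[[r]], truth,
                        derive_seed(run_seed, 2, r))
    fit_glm(vts, vts$design)
  })
  do_univ <- config$univariate && !decode_only
  do_coup <- isTRUE(config$coupling$enabled) && !decode_only
  decode_betas <- vector("list", length(design$main))
  univ_betas <- if (do_univ) vector("list", length(design$main))
  fir_betas <- if (do_coup) vector("list", length(design$main))
  for (r in seq_along(design$main)) {
    ev <- design$main[[r]]
    vts <- simulate_run(ev, truth, derive_seed(run_seed, 1, r))
    decode_betas[[r]] <- fit_glm(vts, vts$design)
    if (do_univ) {
      dm <- build_design_matrix(ev, condition_by = "congruency")
      univ_betas[[r]] <- fit_glm(vts, dm)
    }
    if (do_coup)
      fir_betas[[r]] <- fit_fir(vts, ev, n_bins = config$coupling$n_bins,
                                condition_by = "fir_label")
    rm(vts)
  }
  loc_betas <- NULL
  if (config$tmap_source == "localizer") {
    loc_betas <- lapply(seq_along(design$localizer), function(r) {
      vts <- simulate_run(design$localizer[[r]], truth,
                          derive_seed(run_seed, 3, r))
      fit_glm(vts, vts$design)
    })
  }
  subrois <- subject_subrois(config, truth, loc_betas)
  train <- stack_betas(training_betas)
  main <- stack_betas(decode_betas)
  curve <- cross_decode_exp1(train, main, subrois,
                             cost = config$decode$cost,
                             pooling = config$decode$pooling,
                             measure = config$decode$measure)
  out <- list(curve = curve, truth_gains = c(
    congruent = unname(truth$gain_congruent[1]),
    incongruent = unname(truth$gain_incongruent[1])))
  if (do_univ) {
    ub <- stack_betas(univ_betas)
    out$univariate <- univariate_roi(ub, subrois,
                                     condition_col = "congruency")
    cong <- ub$labels$congruency == "congruent"
    out$wb_diff <- colMeans(ub$mat[cong, , drop = FALSE]) -
      colMeans(ub$mat[!cong, , drop = FALSE])
    out$coords <- as.matrix(truth$voxel_meta[, c("x", "y", "z")])
  }
  if (do_coup) {
    out$coupling <- coupling_pipeline(train, fir_betas, truth$voxel_meta,
                                      seed_roi = config$coupling$seed_roi,
                                      voxel_count_settings =
                                        config$coupling$settings,
                                      n_bins = config$coupling$n_bins,
                                      cost = config$decode$cost)
    out$coords <- as.matrix(truth$voxel_meta[, c("x", "y", "z")])
  }
  out
}

subject_pipeline_exp2 <- function(config, params, tparams, subj_seed,
                                  attention_sd) {
  design <- make_design(params, derive_seed(subj_seed, 1))
  truth <- make_subject(params, tparams, derive_seed(subj_seed, 2),
                        voxels_per_roi = config$voxels_per_roi,
                        n_other = config$n_other)
  run_seed <- derive_seed(subj_seed, 3)
  training_betas <- lapply(seq_along(design$training), function(r) {
    vts <- simulate_run(design$training[[r]], truth,
                        derive_seed(run_seed, 2, r))
    fit_glm(vts, vts$design)
  })
  main_betas <- lapply(seq_along(design$main), function(r) {
    ev <- design$main[[r]]
    vts <- simulate_run(ev, truth, derive_seed(run_seed, 1, r))
    dm <- build_design_matrix(ev, condition_by = "glm_label")
    fit_glm(vts, dm)
  })
  subrois <- subject_subrois(config, truth)
  curve <- cross_decode_exp2(stack_betas(training_betas),
                             stack_betas(main_betas), subrois,
                             cost = config$decode$cost,
                             pooling = config$decode$pooling,
                             measure = config$decode$measure)
  reports <- simulate_reports(design, attention_sd,
                              derive_seed(subj_seed, 4))
  rcor <- suppressWarnings(cor(reports$true_count, reports$reported_count))
  if (is.na(rcor)) rcor <- 0
  list(curve = curve, reports = reports, report_correlation = rcor)
}

# subjects x points matrix of per-subject curves (mean over hemispheres),
# one point per voxel count, for one ROI
difference_curves <- function(curves, roi, direction = "average",
                              conditions = c("congruent", "incongruent")) {
  t(vapply(curves, function(cv) {
    d <- cv[cv$roi == roi & cv$direction == direction, , drop = FALSE]
    ns <- sort(unique(d$n_voxels))
    vapply(ns, function(n) {
      if (length(conditions) == 2) {
        mean(d$info[d$n_voxels == n & d$condition == conditions[1]]) -
          mean(d$info[d$n_voxels == n & d$condition == conditions[2]])
      } else {
        mean(d$info[d$n_voxels == n & d$condition == conditions[1]])
      }
    }, numeric(1))
  }, numeric(length(unique(curves[[1]]$n_voxels[curves[[1]]$roi == roi])))))
}

#' Run the full Experiment 1 analysis on a synthetic cohort
#'
#' Simulates (or re-derives from seed) each subject's runs, estimates the
#' GLMs, builds sub-ROIs, performs the background-matched bidirectional
#' cross-decoding, and runs the group stage: per-ROI paired t tests of
#' congruent versus incongruent classifier information, the 2x2
#' congruency-by-ROI interaction, TFCE sign-flip tests along the sub-ROI
#' sweep, the within-ROI univariate comparison, the whole-brain
#' congruency cluster contrast, and (optionally) the information-
#' activation coupling contrast. Writes tidy CSVs plus a JSON manifest
#' when `out_dir` is set.
#'
#' @param config a [pipeline_config()] with `experiment = 1`.
#' @return object of class `mvpa_results`.
#' @export
run_experiment1 <- function(config) {
  stopifnot(inherits(config, "pipeline_config"), config$experiment == 1)
  pp <- make_params_from_config(config)
  subj <- lapply(seq_len(config$n_subjects), function(s)
    subject_pipeline_exp1(config, pp$params, pp$tparams,
                          derive_seed(config$seed, 100, s)))
  curves <- lapply(subj, `[[`, "curve")

  summaries <- do.call(rbind, lapply(seq_along(curves), function(s) {
    sm <- summarize_curve(curves[[s]], config$decode$direction)
    sm$subject <- s
    sm
  }))

  tests <- list()
  for (r in config$rois) {
    a <- summaries$info[summaries$roi == r &
                          summaries$condition == "congruent"]
    b <- summaries$info[summaries$roi == r &
                          summaries$condition == "incongruent"]
    tests[[paste0(r, "_congruent_vs_incongruent")]] <- paired_t(a, b)
    tests[[paste0(r, "_overall_vs_zero")]] <- one_sample_t((a + b) / 2)
  }
  anova <- NULL
  if (all(c("EVC", "LVC") %in% config$rois)) {
    arr <- array(NA_real_, c(config$n_subjects, 2, 2))
    for (s in seq_len(config$n_subjects)) for (ci in 1:2) for (ri in 1:2) {
      cond <- c("congruent", "incongruent")[ci]
      roi <- c("EVC", "LVC")[ri]
      arr[s, ci, ri] <- summaries$info[summaries$subject == s &
                                         summaries$roi == roi &
                                         summaries$condition == cond]
    }
    anova <- interaction_anova_2x2(arr)
  }

  tfce <- list()
  for (r in config$rois) {
    cm <- difference_curves(curves, r, config$decode$direction)
    tfce[[r]] <- tfce_signflip_test(
      cm, n_permutations = config$stats$n_permutations,
      E = config$stats$E, H = config$stats$H, dh = config$stats$dh,
      seed = derive_seed(config$seed, 777, match(r, config$rois)),
      null_mode = config$stats$tfce_null_mode)
  }

  univariate <- wholebrain <- NULL
  if (config$univariate) {
    univ <- do.call(rbind, lapply(seq_along(subj), function(s) {
      u <- subj[[s]]$univariate
      u$subject <- s
      u
    }))
    univariate <- list(table = univ, tests = list())
    for (r in config$rois) {
      agg <- stats::aggregate(value ~ subject + condition,
                              data = univ[univ$roi == r, ], FUN = mean)
      a <- agg$value[agg$condition == "congruent"]
      b <- agg$value[agg$condition == "incongruent"]
      univariate$tests[[r]] <- paired_t(a, b)
    }
    maps <- do.call(rbind, lapply(subj, `[[`, "wb_diff"))
    wholebrain <- whole_brain_contrast(maps, subj[[1]]$coords,
                                       alpha = config$stats$alpha,
                                       cluster_min = config$stats$cluster_min,
                                       sided = "two")
  }

  coupling <- NULL
  if (isTRUE(config$coupling$enabled)) {
    coupling <- coupling_contrast(lapply(subj, `[[`, "coupling"),
                                  subj[[1]]$coords,
                                  alpha = config$stats$alpha,
                                  cluster_min = config$stats$cluster_min,
                                  fisher_z = config$stats$fisher_z)
  }

  res <- structure(list(experiment = 1, config = config, curves = curves,
                        summaries = summaries, tests = tests, anova = anova,
                        tfce = tfce, univariate = univariate,
                        wholebrain = wholebrain, coupling = coupling),
                   class = "mvpa_results")
  if (!is.null(config$out_dir)) write_results(res, config$out_dir)
  res
}

#' Run the full Experiment 2 analysis on a synthetic cohort
#'
#' Simulates each subject (including end-of-run reappearance reports),
#' applies the interquartile-range attention exclusion, cross-decodes the
#' occluded final period from the background-free benchmark patterns, and
#' runs the group stage: per-ROI one-sample t tests of classifier
#' information against zero, the EVC-versus-LVC paired comparison, and
#' per-ROI TFCE sign-flip tests. Catch trials are modelled as separate
#' regressors and never enter the test set.
#'
#' @param config a [pipeline_config()] with `experiment = 2`.
#' @return object of class `mvpa_results`.
#' @export
run_experiment2 <- function(config) {
  stopifnot(inherits(config, "pipeline_config"), config$experiment == 2)
  pp <- make_params_from_config(config)
  att <- rep(config$attention_sd, config$n_subjects)
  if (config$n_inattentive > 0)
    att[seq_len(config$n_inattentive)] <- config$inattentive_sd
  subj <- lapply(seq_len(config$n_subjects), function(s)
    subject_pipeline_exp2(config, pp$params, pp$tparams,
                          derive_seed(config$seed, 100, s), att[s]))
  rcors <- vapply(subj, `[[`, numeric(1), "report_correlation")
  keep <- exclude_inattentive(rcors)
  kept <- which(keep)
  curves <- lapply(subj[kept], `[[`, "curve")

  summaries <- do.call(rbind, lapply(seq_along(curves), function(i) {
    sm <- summarize_curve(curves[[i]], config$decode$direction)
    sm$subject <- kept[i]
    sm
  }))

  tests <- list()
  for (r in config$rois) {
    v <- summaries$info[summaries$roi == r]
    tests[[paste0(r, "_vs_zero")]] <- one_sample_t(v)
  }
  if (all(c("EVC", "LVC") %in% config$rois)) {
    tests$EVC_vs_LVC <- paired_t(summaries$info[summaries$roi == "EVC"],
                                 summaries$info[summaries$roi == "LVC"])
  }
  tfce <- list()
  for (r in config$rois) {
    cm <- difference_curves(curves, r, config$decode$direction,
                            conditions = "occluded")
    tfce[[r]] <- tfce_signflip_test(
      cm, n_permutations = config$stats$n_permutations,
      E = config$stats$E, H = config$stats$H, dh = config$stats$dh,
      seed = derive_seed(config$seed, 777, match(r, config$rois)),
      null_mode = config$stats$tfce_null_mode)
  }
  res <- structure(list(experiment = 2, config = config, curves = curves,
                        summaries = summaries, tests = tests, tfce = tfce,
                        report_correlations = rcors, keep = keep),
                   class = "mvpa_results")
  if (!is.null(config$out_dir)) write_results(res, config$out_dir)
  res
}

#' @export
print.mvpa_results <- function(x, ...) {
  cat("MVPA synthetic-cohort results (Experiment ", x$experiment, ", ",
      length(x$curves), " subjects)\n", sep = "")
  agg <- stats::aggregate(info ~ roi + condition, data = x$summaries,
                          FUN = mean)
  cat("Mean classifier information:\n")
  print(agg, row.names = FALSE)
  for (nm in names(x$tests)) {
    cat(nm, ": ", sep = "")
    print(x$tests[[nm]])
  }
  if (!is.null(x$anova))
    cat(sprintf("Congruency x ROI interaction: F(1,%d) = %.2f, p = %.4g, pes = %.3f\n",
                x$anova$dof[2], x$anova$F, x$anova$p, x$anova$partial_eta_sq))
  for (r in names(x$tfce)) {
    cat("TFCE [", r, "]: ", sep = "")
    print(x$tfce[[r]])
  }
  invisible(x)
}

#' Monte-Carlo calibration of the pipeline's group tests
#'
#' Repeatedly simulates and analyzes full cohorts under the configured
#' generative state and tabulates, per replicate, the decisions of the
#' group tests: for Experiment 1 the congruency TFCE test (any point
#' significant at FWE 0.05) and the paired t test per ROI; for
#' Experiment 2 the one-sample TFCE and t tests of occluded decoding. Under
#' a null configuration (equal gains / zero occluded gain) the tabulated
#' rates estimate the type-I error; under an effect configuration they
#' estimate power.
#'
#' @param config a [pipeline_config()].
#' @param n_replicates number of replicate cohorts.
#' @param seed base seed (replicate r uses a derived child seed).
#' @return object of class `calibration_result`: list with `table` (one
#'   row per replicate x ROI) and `rates` (per ROI: fraction of replicates
#'   with TFCE FWE significance and with paired-t significance in the
#'   positive direction).
#' @export
run_calibration <- function(config, n_replicates, seed = config$seed) {
  pp <- make_params_from_config(config)
  rows <- list()
  k <- 0
  for (rep_i in seq_len(n_replicates)) {
    rep_seed <- derive_seed(seed, 9000, rep_i)
    if (config$experiment == 1) {
      subj <- lapply(seq_len(config$n_subjects), function(s)
        subject_pipeline_exp1(config, pp$params, pp$tparams,
                              derive_seed(rep_seed, 100, s),
                              decode_only = TRUE))
      curves <- lapply(subj, `[[`, "curve")
      for (r in config$rois) {
        cm <- difference_curves(curves, r, config$decode$direction)
        tf <- tfce_signflip_test(
          cm, n_permutations = config$stats$n_permutations,
          E = config$stats$E, H = config$stats$H, dh = config$stats$dh,
          seed = derive_seed(rep_seed, 777, match(r, config$rois)),
          null_mode = config$stats$tfce_null_mode)
        pv <- rowMeans(cm)
        tt <- one_sample_t(pv)
        tg <- one_sample_t(pv, sided = "greater")
        k <- k + 1
        rows[[k]] <- data.frame(replicate = rep_i, roi = r,
                                tfce_min_p = min(tf$p_fwe),
                                tfce_sig = any(tf$p_fwe < 0.05),
                                t_p = tt$p,
                                mean_diff = mean(pv),
                                t_sig_pos = tt$p < 0.05 &&
                                  tt$statistic > 0,
                                t_sig_greater = tg$p < 0.05)
      }
    } else {
      subj <- lapply(seq_len(config$n_subjects), function(s)
        subject_pipeline_exp2(config, pp$params, pp$tparams,
                              derive_seed(rep_seed, 100, s),
                              config$attention_sd))
      curves <- lapply(subj, `[[`, "curve")
      for (r in config$rois) {
        cm <- difference_curves(curves, r, config$decode$direction,
                                conditions = "occluded")
        tf <- tfce_signflip_test(
          cm, n_permutations = config$stats$n_permutations,
          E = config$stats$E, H = config$stats$H, dh = config$stats$dh,
          seed = derive_seed(rep_seed, 777, match(r, config$rois)),
          null_mode = config$stats$tfce_null_mode)
        pv <- rowMeans(cm)
        tt <- one_sample_t(pv)
        tg <- one_sample_t(pv, sided = "greater")
        k <- k + 1
        rows[[k]] <- data.frame(replicate = rep_i, roi = r,
                                tfce_min_p = min(tf$p_fwe),
                                tfce_sig = any(tf$p_fwe < 0.05),
                                t_p = tt$p,
                                mean_diff = mean(pv),
                                t_sig_pos = tt$p < 0.05 &&
                                  tt$statistic > 0,
                                t_sig_greater = tg$p < 0.05)
      }
    }
  }
  tab <- do.call(rbind, rows)
  rates <- stats::aggregate(cbind(tfce_sig, t_sig_pos, t_sig_greater) ~ roi,
                            data = tab,
                            FUN = mean)
  structure(list(table = tab, rates = rates,
                 n_replicates = n_replicates, seed = seed),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration over", x$n_replicates, "replicate cohorts\n")
  print(x$rates, row.names = FALSE)
  invisible(x)
}
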