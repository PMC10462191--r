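#' Full run configuration
#'
#' Aggregates every paradigm, preprocessing and statistics constant with the
#' study defaults: 450/900/1800 ms SOAs, 100/180 ms tones, 85/15%
#' standard/deviant split, 512 Hz acquisition decimated to 128 Hz, 1-40 Hz
#' band-pass, +-150 uV then 2-SD rejection, -100..800 ms epochs, 200-240 ms
#' measurement window at F3/Fz/F4, T7/T8 reference, 2000 permutations,
#' JZS scale 0.707, 1000 bootstrap resamples. Serializes round-trip
#' identically through JSON.
#'
#' @param seed top-level seed.
#' @param n_td,n_cln3 cohort sizes.
#' @param block_plan paradigm block plan data.frame.
#' @param cohort cohort effect-map configuration ([cohort_config()]).
#' @param fs acquisition sampling rate (Hz); `fs / decim` is the analysis rate.
#' @param decim,low,high,abs_uv,sd_mult preprocessing settings.
#' @param n_perm,bf_scale,n_boot statistics settings.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1, n_td = 41, n_cln3 = 21,
                            block_plan = oddball_block_plan(),
                            cohort = cohort_config(),
                            fs = 512, decim = 4, low = 1, high = 40,
                            abs_uv = 150, sd_mult = 2,
                            n_perm = 2000, bf_scale = 0.707, n_boot = 1000) {
  structure(list(seed = seed, n_td = n_td, n_cln3 = n_cln3,
                 block_plan = block_plan, cohort = unclass(cohort),
                 fs = fs, decim = decim, low = low, high = high,
                 abs_uv = abs_uv, sd_mult = sd_mult, n_perm = n_perm,
                 bf_scale = bf_scale, n_boot = n_boot),
            class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' @param config a `run_config`.
#' @param path JSON path.
#' @return `read_run_config` returns the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$block_plan <- as.data.frame(raw$block_plan)
  ## JSON arrays drop the per-SOA names of the effect-map vectors
  for (nm in c("td_mean", "cln3_mean")) {
    raw$cohort[[nm]] <- stats::setNames(raw$cohort[[nm]],
                                        c("450", "900", "1800"))
  }
  structure(raw, class = "run_config")
}

#' Simulate, preprocess and measure one subject
#'
#' @param sp a `subject_params`.
#' @param config a `run_config`.
#' @param montage montage object.
#' @param block_plan block plan (defaults to the config's).
#' @return list with `measurements` (data.frame), `report`, `bad_channels`,
#'   `reference`.
#' @export
process_subject <- function(sp, config = pipeline_config(),
                            montage = default_montage(),
                            block_plan = NULL) {
  plan <- block_plan %||% config$block_plan
  sched <- build_session_schedule(plan, seed = derive_seed(sp$seed, "schedule"))
  eeg <- simulate_continuous_eeg(sched, sp, montage, fs = config$fs %||% 512)
  pre <- preprocess_subject(eeg, decim = config$decim, low = config$low,
                            high = config$high, abs_uv = config$abs_uv,
                            sd_mult = config$sd_mult)
  meas <- measure_subject(pre$epochs, subject_id = sp$subject_id)
  meas$group <- sp$group
  meas$age <- sp$age
  meas$stage <- sp$cln3_stage
  list(measurements = meas, report = pre$report,
       bad_channels = pre$bad_channels, reference = pre$reference)
}

#' Long-format amplitude table for the LME harness
#'
#' Pivots a measurement table (one row per subject x SOA with `amp_dev`,
#' `amp_std`) to one row per subject x SOA x tone condition.
#'
#' @param measurements data.frame from [process_subject()] /
#'   [measure_subject()] with group/age/stage columns.
#' @return data.frame with columns `subject_id`, `group`, `age`, `stage`,
#'   `soa`, `condition`, `amplitude`.
#' @export
amplitude_long_table <- function(measurements) {
  base <- measurements[, intersect(c("subject_id", "group", "age", "stage", "soa"),
                                   names(measurements))]
  rbind(
    cbind(base, condition = "DEV", amplitude = measurements$amp_dev),
    cbind(base, condition = "STD", amplitude = measurements$amp_std)
  )
}

#' Run the full study pipeline
#'
#' Simulate a cohort, preprocess and measure every subject, then run the
#' statistical battery: the group LME, planned DEV-vs-STD contrasts and JZS
#' Bayes factors per group and SOA, age correlations per group, and (on the
#' generator's subject-ERP sampling path) cluster permutation tests per group
#' and SOA. Writes tables under `out_dir` with a provenance manifest.
#'
#' @param config a `run_config`.
#' @param out_dir output directory (created if missing).
#' @param erp_cluster if TRUE run the cluster permutation stage.
#' @return list with `measurements`, `lme`, `contrasts`, `bayes`,
#'   `correlations`, `clusters`, `manifest` (invisibly written to disk).
#' @export
run_study <- function(config = pipeline_config(), out_dir = NULL,
                      erp_cluster = TRUE) {
  cohort <- generate_cohort(config$n_td, config$n_cln3,
                            structure(config$cohort, class = "cohort_config"),
                            seed = config$seed)
  meas_list <- lapply(cohort$params, process_subject, config = config)
  measurements <- do.call(rbind, lapply(meas_list, `[[`, "measurements"))
  rownames(measurements) <- NULL

  lme <- fit_mmn_lme(amplitude_long_table(measurements), covariate = "group")

  combos <- expand.grid(group = c("TD", "CLN3"), soa = c(450, 900, 1800),
                        stringsAsFactors = FALSE)
  contrasts <- lapply(seq_len(nrow(combos)), function(i) {
    ct <- planned_mmn_contrast(measurements, combos$group[i], combos$soa[i])
    cbind(combos[i, ], t = ct$t, df = ct$df, p = ct$p, mean_diff = ct$mean_diff)
  })
  contrasts <- do.call(rbind, contrasts)

  bayes <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- measurements$group == combos$group[i] &
      measurements$soa == combos$soa[i]
    bf <- jzs_bayes_ttest(measurements$amp_dev[sel], measurements$amp_std[sel],
                          scale = config$bf_scale,
                          seed = derive_seed(config$seed, "bf", i))
    cbind(combos[i, ], bf10 = bf$bf10, t = bf$t_stat, n = bf$n)
  })
  bayes <- do.call(rbind, bayes)

  correlations <- lapply(c("TD", "CLN3"), function(g) {
    sel <- measurements$group == g
    r <- robust_spearman_bootstrap(measurements$age[sel],
                                   measurements$mmn[sel],
                                   n_boot = config$n_boot,
                                   seed = derive_seed(config$seed, "corr", g))
    data.frame(group = g, rs = r$rs, ci_lo = r$ci95[1], ci_hi = r$ci95[2],
               p = r$p, significant = r$significant, n = r$n)
  })
  correlations <- do.call(rbind, correlations)

  clusters <- NULL
  if (erp_cluster) {
    montage <- default_montage()
    adj <- channel_adjacency(montage)
    subj <- cohort$subjects
    clusters <- lapply(seq_len(nrow(combos)), function(i) {
      g <- combos$group[i]; soa <- combos$soa[i]
      amps <- subj[subj$group == g, paste0("mmn_", soa)]
      erps <- simulate_cohort_erps(
        amps, montage = montage,
        seed = derive_seed(config$seed, "erps", g, soa))
      res <- cluster_permutation_test(erps$dev, erps$std, adj,
                                      n_perm = config$n_perm,
                                      seed = derive_seed(config$seed, "perm", g, soa))
      cbind(combos[i, ],
            significant_negative = has_significant_cluster(res, "negative"),
            n_clusters = nrow(res$clusters))
    })
    clusters <- do.call(rbind, clusters)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("oddballmmn")),
    seed = config$seed, n_td = config$n_td, n_cln3 = config$n_cln3,
    n_measurement_rows = nrow(measurements),
    n_contrast_rows = nrow(contrasts),
    timestamp = format(Sys.time(), tz = "UTC"))

  out <- list(measurements = measurements, lme = lme, contrasts = contrasts,
              bayes = bayes, correlations = correlations, clusters = clusters,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(measurements, file.path(out_dir, "measurements.csv"),
                     row.names = FALSE)
    utils::write.csv(lme$coefficients, file.path(out_dir, "lme_fixed_effects.csv"),
                     row.names = FALSE)
    utils::write.csv(contrasts, file.path(out_dir, "planned_contrasts.csv"),
                     row.names = FALSE)
    utils::write.csv(bayes, file.path(out_dir, "bayes_factors.csv"),
                     row.names = FALSE)
    utils::write.csv(correlations, file.path(out_dir, "age_correlations.csv"),
                     row.names = FALSE)
    if (!is.null(clusters)) {
      utils::write.csv(clusters, file.path(out_dir, "cluster_summary.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

#' Small named test datasets with ground truth
#'
#' * `"noiseless"` — one subject, no noise/blinks/bad channels, short session.
#' * `"null"` — a cohort whose injected MMN is 0 everywhere.
#' * `"effect"` — a cohort with the default effect map.
#' * `"artifact"` — a noisy recording with blinks and one bad channel.
#'
#' @param kind fixture name.
#' @param seed integer seed.
#' @return list with the simulated objects plus a `ground_truth` list.
#' @export
make_fixtures <- function(kind = c("noiseless", "null", "effect", "artifact"),
                          seed = 1) {
  kind <- match.arg(kind)
  montage <- default_montage()
  plan <- data.frame(soa = c(450L, 900L, 1800L), n_trials = c(60L, 40L, 30L))
  switch(kind,
    noiseless = {
      sp <- subject_params("fx_noiseless", group = "TD", age = 12,
                           mmn_amplitude_by_soa = list(`450` = -1, `900` = -1.5,
                                                       `1800` = -0.5),
                           noise_sd = 0, blink_rate = 0, seed = seed)
      sched <- build_session_schedule(plan, seed = seed)
      eeg <- simulate_continuous_eeg(sched, sp, montage, fs = 512)
      list(eeg = eeg, schedule = sched, subject = sp,
           ground_truth = list(mmn = sp$mmn_amplitude_by_soa))
    },
    null = {
      cfg <- cohort_config(td_mean = c(`450` = 0, `900` = 0, `1800` = 0),
                           cln3_mean = c(`450` = 0, `900` = 0, `1800` = 0),
                           td_age_slope = 0, cln3_age_slope = 0,
                           stage_slope = 0, between_sd = 0)
      cohort <- generate_cohort(8, 0, cfg, seed = seed)
      list(cohort = cohort, ground_truth = list(mmn = 0))
    },
    effect = {
      cfg <- cohort_config()
      cohort <- generate_cohort(10, 6, cfg, seed = seed)
      list(cohort = cohort,
           ground_truth = list(td_mean = cfg$td_mean, cln3_mean = cfg$cln3_mean,
                               injected = cohort$subjects))
    },
    artifact = {
      sp <- subject_params("fx_artifact", group = "TD", age = 15,
                           mmn_amplitude_by_soa = list(`450` = -1, `900` = -1,
                                                       `1800` = -1),
                           noise_sd = 5, blink_rate = 10,
                           bad_channels = "PO3", seed = seed)
      sched <- build_session_schedule(plan, seed = seed)
      eeg <- simulate_continuous_eeg(sched, sp, montage, fs = 512)
      list(eeg = eeg, schedule = sched, subject = sp,
           ground_truth = list(mmn = sp$mmn_amplitude_by_soa,
                               bad_channels = "PO3"))
    })
}
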