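## Shared fixture builders. Everything is generated in code at test time.

## Wrap a channels x samples matrix as a continuous_eeg on (a subset of) the
## default montage.
mk_eeg <- function(data, fs = 128, montage = default_montage(),
                   events = data.frame()) {
  stopifnot(nrow(data) == length(montage$labels))
  rownames(data) <- montage$labels
  structure(list(data = data, fs = fs, montage = montage, events = events,
                 t0_ms = 0), class = "continuous_eeg")
}

## Wrap a trials x channels x time array as an epoch_set.
mk_epochs <- function(data, time_ms, labels, trials = NULL, fs = 128) {
  n <- dim(data)[1]
  if (is.null(trials)) {
    trials <- data.frame(onset_ms = seq_len(n) * 1000, kind = "STD",
                         soa = 900, block = 1)
  }
  structure(list(data = data, time_ms = time_ms, labels = labels,
                 trials = trials, accepted = rep(TRUE, n), fs = fs,
                 reference_label = NA_character_), class = "epoch_set")
}

## Measurement-level cohort: per-subject window amplitudes drawn around the
## injected ground truth, skipping the signal chain. `meas_sd` is the
## measurement noise of a window amplitude.
mk_measurement_cohort <- function(n_td = 20, n_cln3 = 20, seed = 1,
                                  config = cohort_config(), meas_sd = 0.2) {
  cohort <- generate_cohort(n_td, n_cln3, config, seed = seed)
  subj <- cohort$subjects
  set.seed(seed + 1)
  rows <- lapply(seq_len(nrow(subj)), function(i) {
    s <- subj[i, ]
    do.call(rbind, lapply(c(450, 900, 1800), function(soa) {
      amp_std <- stats::rnorm(1, 0, meas_sd)
      amp_dev <- amp_std + s[[paste0("mmn_", soa)]] + stats::rnorm(1, 0, meas_sd)
      data.frame(subject_id = s$subject_id, group = s$group, age = s$age,
                 stage = s$stage, soa = soa, amp_dev = amp_dev,
                 amp_std = amp_std, mmn = amp_dev - amp_std)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(measurements = out, subjects = subj)
}

## Reduced 12-channel montage (frontal composite kept) used by the
## calibration studies.
mk_small_montage <- function(n_channels = 12) {
  m <- default_montage()
  subset_montage(m, unique(c("F3", "Fz", "F4", m$labels))[seq_len(n_channels)])
}
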