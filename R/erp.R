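#' Average accepted epochs of one condition
#'
#' Arithmetic mean over accepted trials of the given tone kind and SOA.
#'
#' @param epochs an `epoch_set`.
#' @param kind "STD" or "DEV".
#' @param soa SOA condition (450, 900 or 1800).
#' @return object of class `erp`: list with `data` (channels x time, uV),
#'   `time_ms`, `labels`, `n_trials`, `condition`.
#' @export
average_condition <- function(epochs, kind, soa) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- epochs$trials$kind == kind & epochs$trials$soa == soa & epochs$accepted
  if (!any(sel)) {
    stop("no accepted trials for condition ", kind, " / SOA ", soa)
  }
  idx <- which(sel)
  nch <- dim(epochs$data)[2]; nt <- dim(epochs$data)[3]
  acc <- matrix(0, nch, nt)
  for (i in idx) acc <- acc + epochs$data[i, , ]
  erp <- acc / length(idx)
  rownames(erp) <- epochs$labels
  structure(list(data = erp, time_ms = epochs$time_ms, labels = epochs$labels,
                 n_trials = length(idx), condition = list(kind = kind, soa = soa)),
            class = "erp")
}

#' Deviant-minus-standard difference wave
#'
#' Elementwise DEV - STD. (The source study's text once writes "STD-DEV" but
#' reports and plots the canonical negative-going deviant-minus-standard
#' wave; DEV - STD is used throughout here.)
#'
#' @param dev,std `erp` objects (or plain channels x time matrices) on the
#'   same grid.
#' @return channels x time matrix.
#' @export
difference_wave <- function(dev, std) {
  d <- if (inherits(dev, "erp")) dev$data else dev
  s <- if (inherits(std, "erp")) std$data else std
  stopifnot(all(dim(d) == dim(s)))
  d - s
}

#' Frontal-composite MMN amplitude
#'
#' Mean of the difference wave over channels F3, Fz, F4 and over samples with
#' 200 <= t <= 240 ms (endpoints inclusive on the sample grid).
#'
#' @param diff_wave channels x time matrix (rows named by channel).
#' @param time_ms time axis in ms (defaults to rownames-compatible attr).
#' @param window measurement window in ms.
#' @param composite channels entering the composite.
#' @return numeric scalar (uV), with attributes `window` and `composite`.
#' @export
mmn_amplitude <- function(diff_wave, time_ms, window = c(200, 240),
                          composite = c("F3", "Fz", "F4")) {
  if (!all(composite %in% rownames(diff_wave))) {
    stop("missing composite channel(s): ",
         paste(setdiff(composite, rownames(diff_wave)), collapse = ", "))
  }
  in_win <- time_ms >= window[1] & time_ms <= window[2]
  if (!any(in_win)) stop("no samples inside the measurement window")
  val <- mean(colMeans(diff_wave[composite, in_win, drop = FALSE]))
  structure(val, window = window, composite = composite)
}

#' Grand average of subject ERPs
#'
#' Unweighted mean across subjects: each subject contributes equally
#' regardless of accepted-trial counts (standard ERP group analysis).
#'
#' @param erps list of `erp` objects (or channels x time matrices) on the
#'   same grid.
#' @return `erp`-like list with `data`, `time_ms`, `labels`, `n_subjects`.
#' @export
grand_average <- function(erps) {
  stopifnot(length(erps) >= 1)
  mats <- lapply(erps, function(e) if (inherits(e, "erp")) e$data else e)
  acc <- Reduce(`+`, mats) / length(mats)
  first <- erps[[1]]
  structure(list(data = acc,
                 time_ms = if (inherits(first, "erp")) first$time_ms else NULL,
                 labels = rownames(acc), n_subjects = length(mats)),
            class = "erp")
}

#' Subject inclusion decision
#'
#' A subject is included if they retain at least `min_trials` accepted trials
#' in every condition, or — the retention exception — if their composite
#' waveform lies within `band_sd` between-subject SDs of the group mean
#' waveform at every time point.
#'
#' @param n_accepted named/plain numeric vector of accepted trial counts per
#'   condition.
#' @param subject_wave subject's composite waveform (numeric vector).
#' @param group_mean,group_sd pointwise group mean and between-subject SD of
#'   the same waveform (same length as `subject_wave`).
#' @param min_trials minimum accepted trials per condition.
#' @param band_sd width of the retention band in SD units.
#' @return list with `include` (logical), `exception` (logical: retained via
#'   the waveform band), `reason` (character).
#' @export
subject_inclusion <- function(n_accepted, subject_wave = NULL,
                              group_mean = NULL, group_sd = NULL,
                              min_trials = 50, band_sd = 3) {
  if (min(n_accepted) >= min_trials) {
    return(list(include = TRUE, exception = FALSE,
                reason = sprintf("min accepted trials %d >= %d",
                                 min(n_accepted), min_trials)))
  }
  if (is.null(subject_wave) || is.null(group_mean) || is.null(group_sd)) {
    return(list(include = FALSE, exception = FALSE,
                reason = sprintf("min accepted trials %d < %d; no waveform given",
                                 min(n_accepted), min_trials)))
  }
  inside <- abs(subject_wave - group_mean) <= band_sd * group_sd
  if (all(inside)) {
    list(include = TRUE, exception = TRUE,
         reason = sprintf("retained: waveform within %g SD of group mean", band_sd))
  } else {
    list(include = FALSE, exception = FALSE,
         reason = sprintf("excluded: waveform outside %g SD band at %d point(s)",
                          band_sd, sum(!inside)))
  }
}

#' Measure per-condition window amplitudes for one subject
#'
#' For each SOA condition, averages accepted DEV and STD epochs, takes the
#' frontal-composite mean amplitude in the 200-240 ms window for each kind
#' and for the difference wave.
#'
#' @param epochs a preprocessed `epoch_set`.
#' @param subject_id id carried into the table.
#' @param window,composite as in [mmn_amplitude()].
#' @return data.frame with one row per SOA: `subject_id`, `soa`, `amp_dev`,
#'   `amp_std`, `mmn` (= dev - std), `n_dev`, `n_std`.
#' @export
measure_subject <- function(epochs, subject_id = "s", window = c(200, 240),
                            composite = c("F3", "Fz", "F4")) {
  soas <- sort(unique(epochs$trials$soa))
  rows <- lapply(soas, function(soa) {
    dev <- average_condition(epochs, "DEV", soa)
    std <- average_condition(epochs, "STD", soa)
    dw <- difference_wave(dev, std)
    data.frame(
      subject_id = subject_id, soa = soa,
      amp_dev = as.numeric(mmn_amplitude(dev$data, epochs$time_ms, window, composite)),
      amp_std = as.numeric(mmn_amplitude(std$data, epochs$time_ms, window, composite)),
      mmn = as.numeric(mmn_amplitude(dw, epochs$time_ms, window, composite)),
      n_dev = dev$n_trials, n_std = std$n_trials)
  })
  do.call(rbind, rows)
}

#' Composite waveform (mean over F3/Fz/F4) of an ERP matrix
#'
#' @param erp `erp` object or channels x time matrix with named rows.
#' @param composite channel labels.
#' @return numeric vector over time.
#' @export
composite_waveform <- function(erp, composite = c("F3", "Fz", "F4")) {
  m <- if (inherits(erp, "erp")) erp$data else erp
  colMeans(m[composite, , drop = FALSE])
}
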