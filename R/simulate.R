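#' Subject-level simulation parameters
#'
#' Houses the simulated analogue of group, age, disease stage, and SOA: the
#' injected per-SOA MMN amplitude (negative = canonical MMN), the obligatory
#' ERP component parameters, noise level, blink rate and bad channels.
#'
#' @param subject_id character id.
#' @param group "TD" or "CLN3".
#' @param age years.
#' @param mmn_amplitude_by_soa named numeric (names "450","900","1800"), uV.
#' @param cln3_stage integer 0..3 for CLN3 subjects, NA for TD.
#' @param erp_kernel_params an [erp_kernel_params()].
#' @param noise_sd pink-noise SD per sample, uV.
#' @param blink_rate blink events per minute.
#' @param blink_amp_uv blink peak amplitude at the fronto-polar sites.
#' @param bad_channels labels of channels replaced by white-noise traces.
#' @param seed per-subject seed.
#' @return list of class `subject_params`.
#' @export
subject_params <- function(subject_id, group = c("TD", "CLN3"), age,
                           mmn_amplitude_by_soa,
                           cln3_stage = NA_integer_,
                           erp_kernel_params = oddballmmn::erp_kernel_params(),
                           noise_sd = 5, blink_rate = 0, blink_amp_uv = 90,
                           bad_channels = character(0), seed = 1L) {
  group <- match.arg(group)
  if (group == "TD" && !is.na(cln3_stage)) {
    stop("TD subjects do not carry a CLN3 stage")
  }
  if (!all(is.finite(unlist(mmn_amplitude_by_soa)))) {
    stop("MMN amplitudes must be finite")
  }
  structure(list(subject_id = subject_id, group = group, age = age,
                 cln3_stage = cln3_stage,
                 mmn_amplitude_by_soa = mmn_amplitude_by_soa,
                 erp_kernel_params = erp_kernel_params,
                 noise_sd = noise_sd, blink_rate = blink_rate,
                 blink_amp_uv = blink_amp_uv,
                 bad_channels = bad_channels, seed = as.integer(seed)),
            class = "subject_params")
}

#' 1/f ("pink") noise via spectral shaping
#'
#' White Gaussian noise is shaped in the frequency domain with amplitude
#' proportional to f^(-alpha/2) (power ~ 1/f^alpha) and rescaled to the
#' requested standard deviation.
#'
#' @param n number of samples.
#' @param sd target standard deviation.
#' @param alpha spectral exponent of the power spectrum (default 1).
#' @return numeric vector.
#' @export
pink_noise <- function(n, sd = 1, alpha = 1) {
  if (sd == 0 || n == 0) return(numeric(n))
  ## FFT on a highly composite length (truncate afterwards): raw recording
  ## lengths routinely contain large prime factors that make the mixed-radix
  ## FFT orders of magnitude slower
  nfft <- stats::nextn(n, c(2, 3, 5))
  x <- stats::rnorm(nfft)
  f <- c(0, seq_len(nfft - 1))
  f <- pmin(f, nfft - f)                   # two-sided frequency index
  scale <- c(0, f[-1]^(-alpha / 2))        # kill DC
  y <- Re(stats::fft(stats::fft(x) * scale, inverse = TRUE))[seq_len(n)] / nfft
  y * sd / stats::sd(y)
}

## Raised-cosine blink transient, `dur_s` long, unit peak.
blink_shape <- function(fs, dur_s = 0.4) {
  n <- round(dur_s * fs)
  0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
}

## Blink scalp weighting: strongest at the fronto-polar midline, decaying
## with angular distance.
blink_weights <- function(montage) {
  p <- montage$positions
  anchor <- colMeans(p[intersect(c("Fp1", "Fp2"), montage$labels), , drop = FALSE])
  anchor <- anchor / sqrt(sum(anchor^2))
  ang <- acos(pmin(1, pmax(-1, p %*% anchor)))
  w <- exp(-(ang / 0.6)^2)
  stats::setNames(as.numeric(w), montage$labels)
}

#' Simulate a continuous oddball EEG recording
#'
#' Superposes the subject's event kernels (projected through the fixed scalp
#' template) on 1/f background noise, adds seeded blink transients at frontal
#' channels, and replaces any declared bad channels by white-noise-dominated
#' traces. Event markers are preserved sample-accurately (onsets are stored in
#' ms and snapped to the sample grid at epoching).
#'
#' @param schedule a `session_schedule`.
#' @param subject a `subject_params`.
#' @param montage an `mmn_montage`.
#' @param fs sampling rate, Hz (>= 256).
#' @param pad_s silent padding before the first and after the last event.
#' @return object of class `continuous_eeg`: list with `data` (channels x
#'   samples, uV), `fs`, `montage`, `events`, `t0_ms`.
#' @export
simulate_continuous_eeg <- function(schedule, subject, montage = default_montage(),
                                    fs = 512, pad_s = 2) {
  stopifnot(inherits(schedule, "session_schedule"), fs >= 256)
  ev <- schedule$events
  with_seed(subject$seed, {
    dur_s <- (max(ev$onset_ms) + 1000) / 1000 + pad_s
    n <- ceiling(dur_s * fs)
    n_ch <- length(montage$labels)

    ## single-source event train per SOA (kernels differ by SOA through the
    ## subject's amplitude map), then one projection for all channels
    kern_t <- seq(0, 0.8 * fs - 1) / fs * 1000   # kernel support 0..800 ms
    source <- numeric(n)
    for (soa in unique(ev$soa)) {
      ks <- standard_kernel(kern_t, subject$erp_kernel_params)
      kd <- ks + subject$mmn_amplitude_by_soa[[as.character(soa)]] *
        mmn_deflection(kern_t, subject$erp_kernel_params)
      for (kind in c("STD", "DEV")) {
        kk <- if (kind == "STD") ks else kd
        onsets <- ev$onset_ms[ev$soa == soa & ev$kind == kind]
        s0 <- round(onsets / 1000 * fs) + 1
        for (s in s0) {
          idx <- s:(s + length(kk) - 1)
          keep <- idx <= n
          source[idx[keep]] <- source[idx[keep]] + kk[keep]
        }
      }
    }
    ## generation weights: the MMN-topography template rescaled so the frontal
    ## composite carries the source amplitude as-is (frontal-positive for the
    ## obligatory components; the injected negative MMN amplitude then yields
    ## frontal negativity and mastoid positivity in the difference wave)
    w <- scalp_projection(montage)
    v <- w / mean(w[c("F3", "Fz", "F4")])
    data <- outer(unname(v), source)

    if (subject$noise_sd > 0) {
      ## spatially correlated background: per-channel pink noise mixed through
      ## a Gaussian spatial kernel (volume conduction correlates neighbours);
      ## rows are L2-normalized so each channel keeps SD = noise_sd
      noise <- matrix(0, n_ch, n)
      for (i in seq_len(n_ch)) noise[i, ] <- pink_noise(n, subject$noise_sd)
      smix <- exp(-(channel_distances(montage) / 0.8)^2)
      smix <- smix / sqrt(rowSums(smix^2))
      data <- data + smix %*% noise
    }

    if (subject$blink_rate > 0) {
      n_blinks <- stats::rpois(1, subject$blink_rate * dur_s / 60)
      if (n_blinks > 0) {
        bs <- blink_shape(fs) * subject$blink_amp_uv
        bw <- blink_weights(montage)
        bt <- sort(stats::runif(n_blinks, 0, dur_s - 0.5))
        btrain <- numeric(n)
        for (t0 in bt) {
          s <- round(t0 * fs) + 1
          idx <- s:(s + length(bs) - 1)
          keep <- idx <= n
          btrain[idx[keep]] <- btrain[idx[keep]] + bs[keep]
        }
        data <- data + outer(unname(bw), btrain)
      }
    }

    for (bc in subject$bad_channels) {
      i <- match(bc, montage$labels)
      if (is.na(i)) stop("bad channel not in montage: ", bc)
      data[i, ] <- stats::rnorm(n, sd = max(20 * subject$noise_sd, 100))
    }

    rownames(data) <- montage$labels
    structure(list(data = data, fs = fs, montage = montage,
                   events = ev, t0_ms = 0),
              class = "continuous_eeg")
  })
}

#' Cohort-level generative configuration (the effect map)
#'
#' Group-mean injected MMN amplitudes per SOA follow the study's qualitative
#' pattern: robust negative MMN in TD at all rates; in CLN3 a robust MMN at
#' the 900 ms SOA, a marginal one at 450 ms, and none (0 uV) at 1800 ms.
#' Age trends have opposite signs per group (TD: MMN strengthens, i.e. grows
#' more negative, with age; CLN3: amplitudes drift back toward zero), and
#' CLN3 amplitudes weaken with disease stage.
#'
#' @param td_mean,cln3_mean named numeric, group-mean amplitude per SOA (uV).
#' @param between_sd between-subject SD of the injected amplitude (uV).
#' @param td_age_slope,cln3_age_slope uV per year, applied to age centred at
#'   the group mean age.
#' @param stage_slope uV per CLN3 stage unit (centred at stage 2).
#' @param age_range_td,age_range_cln3 uniform age ranges (years).
#' @param stage_probs sampling probabilities of CLN3 stages 1..3.
#' @param noise_sd,blink_rate recording-level noise parameters passed to each
#'   subject.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(td_mean = c(`450` = -1.05, `900` = -1.11, `1800` = -1.12),
                          cln3_mean = c(`450` = -0.45, `900` = -1.00, `1800` = 0),
                          between_sd = 1.0,
                          td_age_slope = -0.033, cln3_age_slope = 0.047,
                          stage_slope = 0.45,
                          age_range_td = c(6, 26), age_range_cln3 = c(6, 28),
                          stage_probs = c(9, 10, 6) / 25,
                          noise_sd = 5, blink_rate = 0) {
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a simulated cohort with ground-truth annotations
#'
#' Draws per-subject ages, stages (CLN3 only) and injected MMN amplitudes
#' under the cohort effect map, returning both a subject table (ground truth)
#' and the per-subject simulation parameter objects. Recordings themselves
#' are simulated on demand with [simulate_continuous_eeg()].
#'
#' @param n_td,n_cln3 group sizes (defaults: the study's 41 TD and 21 CLN3).
#' @param config a [cohort_config()].
#' @param seed top-level seed; per-subject seeds are derived from it.
#' @return list with `subjects` (data.frame: subject_id, group, age, stage,
#'   and injected amplitudes `mmn_450`, `mmn_900`, `mmn_1800`) and `params`
#'   (list of `subject_params`).
#' @export
generate_cohort <- function(n_td = 41, n_cln3 = 21, config = cohort_config(),
                            seed = 1) {
  if (n_td < 0 || n_cln3 < 0) stop("cohort sizes must be non-negative")
  soas <- c("450", "900", "1800")
  with_seed(seed, {
    rows <- list(); params <- list()
    mk <- function(i, group) {
      id <- sprintf("%s%02d", tolower(group), i)
      if (group == "TD") {
        age <- stats::runif(1, config$age_range_td[1], config$age_range_td[2])
        stage <- NA_integer_
        mu <- config$td_mean +
          config$td_age_slope * (age - mean(config$age_range_td))
      } else {
        age <- stats::runif(1, config$age_range_cln3[1], config$age_range_cln3[2])
        stage <- sample(1:3, 1, prob = config$stage_probs)
        mu <- config$cln3_mean +
          config$cln3_age_slope * (age - mean(config$age_range_cln3)) +
          config$stage_slope * (stage - 2)
      }
      amps <- stats::setNames(mu + stats::rnorm(3, 0, config$between_sd), soas)
      sp <- subject_params(id, group = group, age = age,
                           mmn_amplitude_by_soa = as.list(amps),
                           cln3_stage = stage,
                           noise_sd = config$noise_sd,
                           blink_rate = config$blink_rate,
                           seed = derive_seed(seed, "subject", id))
      list(row = data.frame(subject_id = id, group = group, age = age,
                            stage = stage, mmn_450 = amps[["450"]],
                            mmn_900 = amps[["900"]], mmn_1800 = amps[["1800"]]),
           sp = sp)
    }
    k <- 0
    for (i in seq_len(n_td)) {
      k <- k + 1; out <- mk(i, "TD"); rows[[k]] <- out$row; params[[k]] <- out$sp
    }
    for (i in seq_len(n_cln3)) {
      k <- k + 1; out <- mk(i, "CLN3"); rows[[k]] <- out$row; params[[k]] <- out$sp
    }
    subjects <- if (k) do.call(rbind, rows) else
      data.frame(subject_id = character(0), group = character(0),
                 age = numeric(0), stage = integer(0), mmn_450 = numeric(0),
                 mmn_900 = numeric(0), mmn_1800 = numeric(0))
    rownames(subjects) <- NULL
    names(params) <- subjects$subject_id
    list(subjects = subjects, params = params)
  })
}

#' Simulate subject-level ERPs directly (scaled-down path)
#'
#' Draws each subject's per-condition ERP as the projected kernel plus
#' temporally smoothed Gaussian residual noise with SD `erp_noise_sd`
#' (the sampling noise left after averaging ~n trials, i.e. trial noise /
#' sqrt(n_trials)). Used for statistical calibration and pattern-recovery
#' studies where simulating and preprocessing full continuous sessions would
#' add nothing but runtime.
#'
#' @param amplitudes numeric vector of injected MMN amplitudes, one per subject.
#' @param montage an `mmn_montage`.
#' @param fs analysis sampling rate (Hz).
#' @param erp_noise_sd residual ERP noise SD per channel-sample (uV).
#' @param kernel_params an [erp_kernel_params()].
#' @param smooth_len moving-average length (samples) applied to the noise.
#' @param seed integer seed.
#' @return list with arrays `dev`, `std` (subjects x channels x time),
#'   `time_ms`, and `labels`.
#' @export
simulate_cohort_erps <- function(amplitudes, montage = default_montage(),
                                 fs = 128, erp_noise_sd = 0.4,
                                 kernel_params = erp_kernel_params(),
                                 smooth_len = 3, seed = 1) {
  n <- length(amplitudes)
  time_ms <- epoch_time_axis(fs)
  nt <- length(time_ms)
  w <- scalp_projection(montage)
  v <- w / mean(w[c("F3", "Fz", "F4")])   # generation weights (see simulator)
  nch <- length(v)
  ks <- standard_kernel(time_ms, kernel_params)
  gd <- mmn_deflection(time_ms, kernel_params)
  base_std <- outer(unname(v), ks)
  noise_mat <- function() {
    m <- matrix(stats::rnorm(nch * nt, 0, erp_noise_sd), nch, nt)
    if (smooth_len > 1) {
      ## circular moving average along time, then rescale to the nominal SD
      acc <- m * 0
      for (s in seq_len(smooth_len) - (smooth_len + 1) %/% 2) {
        idx <- ((seq_len(nt) - 1 + s) %% nt) + 1
        acc <- acc + m[, idx, drop = FALSE]
      }
      m <- acc / sqrt(smooth_len)   # restores the per-sample SD exactly
    }
    m
  }
  dev <- array(0, c(n, nch, nt)); std <- array(0, c(n, nch, nt))
  with_seed(seed, {
    for (i in seq_len(n)) {
      std[i, , ] <- base_std + noise_mat()
      dev[i, , ] <- base_std + outer(unname(v), amplitudes[i] * gd) + noise_mat()
    }
  })
  list(dev = dev, std = std, time_ms = time_ms, labels = montage$labels)
}

#' Simulate a label-exchangeable null cohort
#'
#' Deviant and standard ERPs share an identical generative distribution
#' (injected MMN amplitude 0 for every subject), so any significant cluster
#' is a false positive. Used for family-wise error calibration.
#'
#' @param n_subjects subjects per cohort.
#' @param montage montage (subset to `n_channels` first channels if given).
#' @param n_channels optional channel count.
#' @param fs sampling rate (time points follow the -100..800 ms grid).
#' @param erp_noise_sd residual ERP noise SD (uV).
#' @param seed integer seed.
#' @return as [simulate_cohort_erps()].
#' @export
simulate_null_cohort <- function(n_subjects = 15, montage = default_montage(),
                                 n_channels = NULL, fs = 128,
                                 erp_noise_sd = 0.4, seed = 1) {
  if (!is.null(n_channels)) {
    keep <- unique(c("F3", "Fz", "F4", montage$labels))[seq_len(n_channels)]
    montage <- subset_montage(montage, keep)
  }
  simulate_cohort_erps(rep(0, n_subjects), montage = montage, fs = fs,
                       erp_noise_sd = erp_noise_sd, seed = seed)
}
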