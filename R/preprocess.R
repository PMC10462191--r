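## Preprocessing chain: decimate -> band-pass -> bad-channel detection and
## spherical spline interpolation -> epoching -> two-stage rejection ->
## baseline correction -> T7/T8 re-reference -> ocular template regression.

## Zero-phase filtering with odd-reflection end padding, so constants pass
## unchanged and filter start-up transients never reach the data.
filtfilt_padded <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  xe <- c(head_pad, x, tail_pad)
  y <- signal::filter(filt, xe)
  y <- rev(signal::filter(filt, rev(y)))
  y[(pad + 1):(pad + n)]
}

apply_filtfilt <- function(data, filt, fs) {
  pad <- round(10 * fs)
  out <- t(apply(data, 1, function(x) filtfilt_padded(filt, x, pad)))
  dimnames(out) <- dimnames(data)
  out
}

#' Decimate a continuous recording
#'
#' Anti-alias filters with an 8th-order Chebyshev Type I low-pass (0.05 dB
#' passband ripple, cutoff at 0.8x the new Nyquist — the classic `decimate`
#' design) applied forward-backward (zero phase), then keeps every
#' `factor`-th sample. Event onsets are stored in ms and re-snapped to the
#' new grid at epoching.
#'
#' @param eeg a `continuous_eeg`.
#' @param factor integer decimation factor; the new rate must stay >= 80 Hz
#'   (2x the 40 Hz band edge).
#' @return a `continuous_eeg` at `fs / factor`.
#' @export
resample_decimate <- function(eeg, factor = 4) {
  stopifnot(inherits(eeg, "continuous_eeg"))
  if (factor <= 0 || factor != round(factor)) stop("factor must be a positive integer")
  new_fs <- eeg$fs / factor
  if (new_fs < 2 * 40) stop("decimated rate must remain at least 80 Hz")
  if (factor == 1) return(eeg)
  filt <- signal::cheby1(8, 0.05, 0.8 / factor)
  ## even-order Chebyshev I sits at the ripple trough at DC; renormalize to
  ## unity DC gain so constants (and slow ERP content) pass unscaled
  filt$b <- filt$b / (sum(filt$b) / sum(filt$a))
  data <- apply_filtfilt(eeg$data, filt, eeg$fs)
  keep <- seq(1, ncol(data), by = factor)
  eeg$data <- data[, keep, drop = FALSE]
  eeg$fs <- new_fs
  eeg
}

#' Band-pass filter (Chebyshev Type II, zero phase)
#'
#' 4th-order Chebyshev Type II design with 40 dB stopband attenuation,
#' applied forward-backward. The stopband corners are placed at `low / 2`
#' and `1.3 * high` so the 1-40 Hz band itself lies in the flat passband.
#'
#' @param eeg a `continuous_eeg`.
#' @param low,high band edges in Hz.
#' @param order filter order of the prototype.
#' @param rs stopband attenuation in dB.
#' @return filtered `continuous_eeg`.
#' @export
bandpass_chebyshev2 <- function(eeg, low = 1, high = 40, order = 4, rs = 40) {
  stopifnot(inherits(eeg, "continuous_eeg"))
  nyq <- eeg$fs / 2
  if (high >= nyq) stop("upper band edge must be below Nyquist")
  w_stop <- c(low / 2, min(1.3 * high, 0.95 * nyq)) / nyq
  filt <- signal::cheby2(order, rs, w_stop, type = "pass")
  eeg$data <- apply_filtfilt(eeg$data, filt, eeg$fs)
  eeg
}

#' Detect bad channels
#'
#' A channel is flagged if its robust (MAD-based) SD exceeds `k_sd` times the
#' median channel SD (or falls below `1/k_sd` of it), or if its mean absolute
#' correlation with its `n_neighbors` nearest montage neighbours falls below
#' `r_min`. Deterministic.
#'
#' @param eeg a `continuous_eeg`.
#' @param n_neighbors neighbours per channel, between 3 and 7.
#' @param k_sd SD ratio threshold.
#' @param r_min minimum mean absolute neighbour correlation.
#' @return character vector of flagged labels.
#' @export
detect_bad_channels <- function(eeg, n_neighbors = 5, k_sd = 5, r_min = 0.4) {
  stopifnot(inherits(eeg, "continuous_eeg"))
  if (n_neighbors < 3 || n_neighbors > 7) stop("n_neighbors must be in 3..7")
  if (is.null(eeg$montage$positions)) stop("montage lacks positions")
  labs <- eeg$montage$labels
  sds <- apply(eeg$data, 1, stats::mad)
  med <- stats::median(sds)
  flag_sd <- sds > k_sd * med | sds < med / k_sd
  nb <- nearest_neighbors(eeg$montage, n_neighbors)
  cors <- suppressWarnings(stats::cor(t(eeg$data)))
  cors[!is.finite(cors)] <- 0
  flag_cor <- vapply(labs, function(l) {
    mean(abs(cors[l, nb[[l]]])) < r_min
  }, logical(1))
  ## identical channels: correlation of a channel with itself-like copies is 1
  labs[flag_sd | flag_cor]
}

## Legendre polynomials P_1..P_lmax evaluated at x (vector), plain recurrence.
legendre_series <- function(x, lmax) {
  out <- matrix(0, length(x), lmax)
  p_prev <- rep(1, length(x))   # P_0
  p_cur <- x                    # P_1
  out[, 1] <- p_cur
  if (lmax >= 2) {
    for (l in 2:lmax) {
      p_next <- ((2 * l - 1) * x * p_cur - (l - 1) * p_prev) / l
      out[, l] <- p_next
      p_prev <- p_cur
      p_cur <- p_next
    }
  }
  out
}

## Perrin spherical-spline kernel g(cos angle) with order m and lmax terms.
## Preserves the shape of `cosang` (matrix in, matrix out).
spline_g <- function(cosang, m = 4, lmax = 7) {
  d <- dim(cosang)
  x <- pmin(pmax(as.numeric(cosang), -1), 1)
  P <- legendre_series(x, lmax)
  l <- seq_len(lmax)
  coef <- (2 * l + 1) / (l * (l + 1))^m
  out <- as.numeric(P %*% coef) / (4 * pi)
  if (!is.null(d)) dim(out) <- d
  out
}

#' Spherical spline interpolation of bad channels
#'
#' Replaces flagged channel traces by Perrin-style spherical spline estimates
#' computed from the good channels (spline order m = 4, 7-term Legendre
#' truncation, ridge regularization lambda = 1e-5). Good channels are left
#' untouched. Refuses if 25% or more of the montage is bad.
#'
#' @param eeg a `continuous_eeg`.
#' @param bad_labels channels to re-estimate.
#' @param m spline order.
#' @param lmax Legendre truncation.
#' @param lambda ridge regularization added to the kernel matrix diagonal.
#' @return `continuous_eeg` with interpolated traces.
#' @export
interpolate_spherical_spline <- function(eeg, bad_labels, m = 4, lmax = 7,
                                         lambda = 1e-5) {
  stopifnot(inherits(eeg, "continuous_eeg"))
  if (length(bad_labels) == 0) return(eeg)
  labs <- eeg$montage$labels
  if (!all(bad_labels %in% labs)) stop("unknown bad channel label")
  if (length(bad_labels) >= 0.25 * length(labs)) {
    stop("refusing to interpolate: ", length(bad_labels), " of ", length(labs),
         " channels flagged bad (>= 25%)")
  }
  good <- setdiff(labs, bad_labels)
  pos <- eeg$montage$positions
  cos_gg <- tcrossprod(pos[good, , drop = FALSE])
  cos_bg <- pos[bad_labels, , drop = FALSE] %*% t(pos[good, , drop = FALSE])
  G <- spline_g(cos_gg, m, lmax)
  Gb <- spline_g(cos_bg, m, lmax)
  ng <- length(good)
  A <- rbind(cbind(G + lambda * diag(ng), rep(1, ng)),
             c(rep(1, ng), 0))
  rhs <- rbind(eeg$data[good, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  c_coef <- sol[seq_len(ng), , drop = FALSE]
  d_coef <- sol[ng + 1, ]
  est <- Gb %*% c_coef + matrix(d_coef, nrow = length(bad_labels),
                                ncol = ncol(eeg$data), byrow = TRUE)
  eeg$data[bad_labels, ] <- est
  eeg
}

#' Extract epochs around event onsets
#'
#' Epoch window is half-open `[-100, 800)` ms on the recording's sample grid
#' (115 samples at 128 Hz); onsets are snapped to the nearest sample. Events
#' whose window falls outside the recording are dropped with a message.
#'
#' @param eeg a `continuous_eeg` (its `events` are used unless overridden).
#' @param events optional events data.frame (`onset_ms`, `kind`, `soa`, `block`).
#' @return object of class `epoch_set`: list with `data` (trials x channels x
#'   time, uV), `time_ms`, `labels` (channel labels), `trials` (data.frame),
#'   `accepted` (logical), `fs`, `reference_label`.
#' @export
extract_epochs <- function(eeg, events = NULL) {
  stopifnot(inherits(eeg, "continuous_eeg"))
  ev <- events %||% eeg$events
  fs <- eeg$fs
  time_ms <- epoch_time_axis(fs)
  k <- round(time_ms / 1000 * fs)     # sample offsets relative to onset
  n_samp <- ncol(eeg$data)
  if (nrow(ev) == 0) {
    return(structure(list(
      data = array(0, c(0, nrow(eeg$data), length(k))), time_ms = time_ms,
      labels = eeg$montage$labels, trials = ev,
      accepted = logical(0), fs = fs, reference_label = NA_character_),
      class = "epoch_set"))
  }
  s0 <- round(ev$onset_ms / 1000 * fs) + 1
  ok <- s0 + k[1] >= 1 & s0 + k[length(k)] <= n_samp
  if (any(!ok)) {
    message(sum(!ok), " event(s) too close to the recording edge; dropped")
  }
  ev <- ev[ok, , drop = FALSE]
  s0 <- s0[ok]
  dat <- array(0, c(nrow(ev), nrow(eeg$data), length(k)))
  for (i in seq_len(nrow(ev))) dat[i, , ] <- eeg$data[, s0[i] + k]
  rownames(ev) <- NULL
  structure(list(data = dat, time_ms = time_ms, labels = eeg$montage$labels,
                 trials = ev, accepted = rep(TRUE, nrow(ev)), fs = fs,
                 reference_label = NA_character_),
            class = "epoch_set")
}

#' Two-stage amplitude-based epoch rejection
#'
#' Stage 1 flags any epoch containing a sample with `|V| > abs_uv` on any
#' channel. Stage 2, computed per condition (SOA x tone kind) over stage-1
#' survivors, takes each epoch's largest absolute value across channels in
#' the first `stat_window` ms post-onset (m_i) and flags epochs with
#' m_i > mean(m) + `sd_mult` * SD(m) (strict). Decisions are scale-free in
#' stage 2.
#'
#' @param epochs an `epoch_set`.
#' @param abs_uv absolute-amplitude threshold (uV).
#' @param sd_mult SD multiplier for stage 2.
#' @param stat_window window (ms) for the stage-2 statistic.
#' @return list with `epochs` (accepted mask updated) and `report`
#'   (class `rejection_report`: per-trial flags, per-condition thresholds,
#'   accepted counts).
#' @export
reject_epochs <- function(epochs, abs_uv = 150, sd_mult = 2,
                          stat_window = c(0, 500)) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- dim(epochs$data)[1]
  if (n == 0) {
    rep0 <- structure(list(
      trial_flags = data.frame(stage1 = logical(0), stage2 = logical(0)),
      thresholds = data.frame(soa = integer(0), kind = character(0),
                              mean_max = numeric(0), sd_max = numeric(0),
                              threshold = numeric(0)),
      n_accepted = data.frame(soa = integer(0), kind = character(0),
                              n = integer(0))), class = "rejection_report")
    return(list(epochs = epochs, report = rep0))
  }
  stage1 <- vapply(seq_len(n), function(i) {
    max(abs(epochs$data[i, , ])) > abs_uv
  }, logical(1))
  in_win <- epochs$time_ms >= stat_window[1] & epochs$time_ms <= stat_window[2]
  m <- vapply(seq_len(n), function(i) {
    max(abs(epochs$data[i, , in_win]))
  }, numeric(1))
  stage2 <- rep(FALSE, n)
  conds <- unique(epochs$trials[, c("soa", "kind")])
  thr_rows <- list()
  for (j in seq_len(nrow(conds))) {
    sel <- epochs$trials$soa == conds$soa[j] &
      epochs$trials$kind == conds$kind[j] & !stage1
    if (!any(sel)) {
      thr_rows[[j]] <- data.frame(soa = conds$soa[j], kind = conds$kind[j],
                                  mean_max = NA_real_, sd_max = NA_real_,
                                  threshold = NA_real_)
      next
    }
    mu <- mean(m[sel]); s <- stats::sd(m[sel])
    if (is.na(s)) s <- 0
    thr <- mu + sd_mult * s
    stage2[sel] <- m[sel] > thr
    thr_rows[[j]] <- data.frame(soa = conds$soa[j], kind = conds$kind[j],
                                mean_max = mu, sd_max = s, threshold = thr)
  }
  epochs$accepted <- !stage1 & !stage2
  acc <- stats::aggregate(list(n = epochs$accepted),
                          by = epochs$trials[, c("soa", "kind")], FUN = sum)
  report <- structure(list(
    trial_flags = data.frame(stage1 = stage1, stage2 = stage2),
    thresholds = do.call(rbind, thr_rows),
    n_accepted = acc), class = "rejection_report")
  list(epochs = epochs, report = report)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the pre-stimulus interval
#' `[-100, 0)` ms.
#'
#' @param epochs an `epoch_set`.
#' @return baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  base <- epochs$time_ms < 0
  if (!any(base)) stop("no baseline samples in the epoch window")
  n <- dim(epochs$data)[1]
  for (i in seq_len(n)) {
    mu <- rowMeans(matrix(epochs$data[i, , base], dim(epochs$data)[2]))
    epochs$data[i, , ] <- epochs$data[i, , ] - mu
  }
  epochs
}

#' Re-reference epochs to a temporal scalp site
#'
#' Subtracts the reference channel's trace from every channel, per trial.
#' The reference is `primary` (T7) unless it was flagged as a bad channel, in
#' which case `fallback` (T8) is used; if both are bad the call errors.
#'
#' @param epochs an `epoch_set`.
#' @param primary,fallback reference channel labels.
#' @param bad_labels channels flagged bad on the continuous data.
#' @return re-referenced `epoch_set` with `reference_label` recorded.
#' @export
rereference <- function(epochs, primary = "T7", fallback = "T8",
                        bad_labels = character(0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  ref <- if (primary %in% bad_labels) fallback else primary
  if (ref %in% bad_labels) {
    stop("both reference candidates (", primary, ", ", fallback,
         ") were flagged bad; cannot re-reference")
  }
  ri <- match(ref, epochs$labels)
  if (is.na(ri)) stop("reference channel ", ref, " not in montage")
  n <- dim(epochs$data)[1]
  for (i in seq_len(n)) {
    reftrace <- epochs$data[i, ri, ]
    epochs$data[i, , ] <- sweep(epochs$data[i, , , drop = TRUE],
                                2, reftrace, "-")
  }
  epochs$reference_label <- ref
  epochs
}

## Core ocular regression on a channels x samples matrix.
ocular_regress_matrix <- function(data, labels, min_blink_uv, mad_mult,
                                  dilate_samples) {
  frontal <- intersect(c("Fp1", "Fp2", "AF3", "AF4"), labels)
  if (length(frontal) == 0) stop("no frontal channels to build a blink template")
  eog <- colMeans(data[match(frontal, labels), , drop = FALSE])
  med <- stats::median(eog)
  madv <- stats::mad(eog)
  thr <- max(med + mad_mult * madv, min_blink_uv)
  mask <- eog > thr
  if (!any(mask)) return(list(data = data, n_templates = 0L))
  ## dilate so the full blink transient (not only its tip) is modelled
  idx <- which(mask)
  for (d in seq_len(dilate_samples)) {
    idx <- unique(c(idx, pmax(idx - 1, 1), pmin(idx + 1, length(eog))))
  }
  mask <- logical(length(eog)); mask[idx] <- TRUE
  r <- numeric(length(eog))
  r[mask] <- eog[mask] - med
  denom <- sum(r^2)
  beta <- as.numeric(data %*% r) / denom
  list(data = data - outer(beta, r), n_templates = 1L)
}

#' Remove ocular (blink) artifacts by deterministic template regression
#'
#' Builds a virtual EOG trace from fronto-polar channels, detects blink
#' intervals where it exceeds both a robust (median + 4 MAD) and an absolute
#' (`min_blink_uv`) threshold, and regresses the blink time course out of
#' every channel (a single spatial template; at most one removed, mirroring
#' the practice of removing one or two ocular components). Blink-free data
#' pass through essentially unchanged.
#'
#' @param x a `continuous_eeg` or `epoch_set`.
#' @param min_blink_uv absolute minimum blink amplitude on the virtual EOG.
#' @param mad_mult robust threshold multiplier.
#' @param dilate_ms half-width (ms) by which detected blink samples are dilated.
#' @return same class as `x`.
#' @export
remove_ocular_artifacts <- function(x, min_blink_uv = 40, mad_mult = 4,
                                    dilate_ms = 150) {
  if (inherits(x, "continuous_eeg")) {
    res <- ocular_regress_matrix(x$data, x$montage$labels, min_blink_uv,
                                 mad_mult, round(dilate_ms / 1000 * x$fs))
    x$data <- res$data
    return(x)
  }
  if (inherits(x, "epoch_set")) {
    dims <- dim(x$data)
    if (dims[1] == 0) return(x)
    ## concatenate trials along time so blinks spanning epochs are one event
    flat <- matrix(aperm(x$data, c(2, 3, 1)), nrow = dims[2])
    rownames(flat) <- x$labels
    res <- ocular_regress_matrix(flat, x$labels, min_blink_uv, mad_mult,
                                 round(dilate_ms / 1000 * x$fs))
    x$data <- aperm(array(res$data, c(dims[2], dims[3], dims[1])), c(3, 1, 2))
    return(x)
  }
  stop("x must be a continuous_eeg or epoch_set")
}

#' Run the full preprocessing chain on one recording
#'
#' Order: decimate, band-pass, bad-channel detection + spherical spline
#' interpolation, epoching, two-stage rejection, baseline correction, T7/T8
#' re-reference, ocular template regression.
#'
#' @param eeg a `continuous_eeg` (raw, e.g. 512 Hz).
#' @param decim decimation factor (4: 512 -> 128 Hz).
#' @param low,high band-pass edges (Hz).
#' @param abs_uv,sd_mult rejection parameters.
#' @param n_neighbors,k_sd,r_min bad-channel parameters.
#' @param skip_filters if TRUE, skip decimation and band-pass (the exactly
#'   amplitude-preserving path used for noiseless ground-truth checks).
#' @param detect_bad if FALSE, skip bad-channel detection/interpolation
#'   (noise-free data make relative-SD screening meaningless).
#' @return list with `epochs`, `report`, `bad_channels`, `reference`.
#' @export
preprocess_subject <- function(eeg, decim = 4, low = 1, high = 40,
                               abs_uv = 150, sd_mult = 2, n_neighbors = 5,
                               k_sd = 5, r_min = 0.4, skip_filters = FALSE,
                               detect_bad = TRUE) {
  if (!skip_filters) {
    eeg <- resample_decimate(eeg, decim)
    eeg <- bandpass_chebyshev2(eeg, low, high)
  }
  bad <- if (detect_bad) {
    detect_bad_channels(eeg, n_neighbors = n_neighbors, k_sd = k_sd,
                        r_min = r_min)
  } else character(0)
  if (length(bad)) eeg <- interpolate_spherical_spline(eeg, bad)
  epochs <- extract_epochs(eeg)
  rej <- reject_epochs(epochs, abs_uv = abs_uv, sd_mult = sd_mult)
  epochs <- baseline_correct(rej$epochs)
  epochs <- rereference(epochs, bad_labels = bad)
  epochs <- remove_ocular_artifacts(epochs)
  list(epochs = epochs, report = rej$report, bad_channels = bad,
       reference = epochs$reference_label)
}
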