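#' Default ERP kernel parameters
#'
#' The single-source event-related response is modelled as a sum of Gaussian
#' deflections: the obligatory P1/N1/P2 auditory components, shared by
#' standards and deviants, plus (deviants only) an MMN deflection centred at
#' 220 ms. Gaussians are smooth and analytically integrable, which keeps the
#' window-mean ground truth available in closed form.
#'
#' @param p1,n1,p2 lists with `amp` (uV), `lat` (ms), `sigma` (ms).
#' @param mmn_latency_ms centre of the MMN deflection.
#' @param mmn_sigma_ms Gaussian half-width of the MMN deflection.
#' @return list of class `erp_kernel_params`.
#' @export
erp_kernel_params <- function(p1 = list(amp = 2.0, lat = 60, sigma = 15),
                              n1 = list(amp = -3.0, lat = 110, sigma = 20),
                              p2 = list(amp = 2.0, lat = 190, sigma = 25),
                              mmn_latency_ms = 220,
                              mmn_sigma_ms = 30) {
  structure(list(p1 = p1, n1 = n1, p2 = p2,
                 mmn_latency_ms = mmn_latency_ms,
                 mmn_sigma_ms = mmn_sigma_ms),
            class = "erp_kernel_params")
}

## Gaussian deflection, compactly supported at +-4 sigma (the truncation is a
## 3e-4 relative edge step; it keeps event kernels from bleeding into the
## next trial's baseline at the fastest presentation rate).
gauss_bump <- function(t_ms, amp, lat, sigma) {
  z <- (t_ms - lat) / sigma
  amp * exp(-0.5 * z^2) * (abs(z) <= 4)
}

#' Evaluate the standard-tone kernel on a time axis
#'
#' Zero over the baseline (t < 0) by convention, so baseline correction is
#' exact on noiseless data.
#'
#' @param t_ms numeric vector of times in ms relative to tone onset.
#' @param params an `erp_kernel_params`.
#' @return numeric vector (uV).
#' @keywords internal
standard_kernel <- function(t_ms, params = erp_kernel_params()) {
  k <- gauss_bump(t_ms, params$p1$amp, params$p1$lat, params$p1$sigma) +
    gauss_bump(t_ms, params$n1$amp, params$n1$lat, params$n1$sigma) +
    gauss_bump(t_ms, params$p2$amp, params$p2$lat, params$p2$sigma)
  k[t_ms < 0] <- 0
  k
}

#' Unit MMN deflection
#'
#' Gaussian centred at `mmn_latency_ms`, unit peak, zero over the baseline.
#' @inheritParams standard_kernel
#' @keywords internal
mmn_deflection <- function(t_ms, params = erp_kernel_params()) {
  g <- gauss_bump(t_ms, 1, params$mmn_latency_ms, params$mmn_sigma_ms)
  g[t_ms < 0] <- 0
  g
}

#' Synthesize standard and deviant single-source kernels for one subject
#'
#' The deviant kernel is the standard kernel plus a Gaussian MMN deflection
#' centred at 220 ms, scaled so its peak equals the subject's injected MMN
#' amplitude for the given SOA condition (negative for a canonical MMN).
#'
#' @param subject a [subject_params()] object.
#' @param soa SOA condition, one of 450, 900, 1800.
#' @param fs sampling rate of the returned time axis (Hz).
#' @param t_range time range in ms (default -100..800, the epoch window).
#' @return list with `time_ms`, `std`, `dev` (uV).
#' @export
#' @examples
#' s <- subject_params("s1", group = "TD", age = 12,
#'                     mmn_amplitude_by_soa = c(`450` = -1, `900` = -1, `1800` = -1))
#' k <- synthesize_erp_kernels(s, 900)
#' range(k$dev - k$std)
synthesize_erp_kernels <- function(subject, soa, fs = 512,
                                   t_range = c(-100, 800)) {
  soa <- as.character(soa)
  if (!soa %in% c("450", "900", "1800")) stop("unknown SOA condition: ", soa)
  amp <- subject$mmn_amplitude_by_soa[[soa]]
  if (is.null(amp) || !is.finite(amp)) stop("no finite MMN amplitude for SOA ", soa)
  time_ms <- epoch_time_axis(fs, t_range)
  params <- subject$erp_kernel_params
  std <- standard_kernel(time_ms, params)
  dev <- std + amp * mmn_deflection(time_ms, params)
  list(time_ms = time_ms, std = std, dev = dev)
}

#' Sample grid for the epoch window
#'
#' Half-open window convention: samples at integer multiples k/fs with
#' t in `[t_range[1], t_range[2])` ms. At 128 Hz and -100..800 ms this yields
#' 115 samples.
#'
#' @param fs sampling rate (Hz).
#' @param t_range window in ms.
#' @return numeric vector of sample times in ms.
#' @export
epoch_time_axis <- function(fs, t_range = c(-100, 800)) {
  k0 <- ceiling(t_range[1] / 1000 * fs - 1e-9)
  k1 <- ceiling(t_range[2] / 1000 * fs - 1e-9) - 1
  (k0:k1) / fs * 1000
}

#' Fixed scalp projection template
#'
#' Deterministic topography used to project the single-source kernel to the
#' scalp: a frontal negative lobe centred on Fz (so Fz carries the most
#' negative weight), equal positive weights at the two mastoids (the MMN's
#' polarity inversion), and exactly zero weight at the reference candidates
#' T7/T8 so that measured frontal amplitudes are invariant to the temporal
#' re-reference. Weights are normalized so the F3/Fz/F4 composite mean is -1,
#' hence an injected MMN amplitude is recovered as-is at the composite.
#'
#' @param montage an `mmn_montage`.
#' @param frontal_sigma width (radians) of the frontal lobe.
#' @param mastoid_weight unnormalized positive weight at M1/M2.
#' @param zero_mean if TRUE, subtract the across-channel mean so the template
#'   sums to zero (a reference-free variant).
#' @return named numeric vector of per-channel weights.
#' @export
scalp_projection <- function(montage, frontal_sigma = 0.9,
                             mastoid_weight = 0.35, zero_mean = FALSE) {
  labs <- montage$labels
  need <- c("Fz", "F3", "F4")
  if (!all(need %in% labs)) stop("montage must contain F3, Fz, F4")
  d <- channel_distances(montage)
  w <- -exp(-(d["Fz", ] / frontal_sigma)^2)
  mast <- intersect(c("M1", "M2"), labs)
  w[mast] <- mastoid_weight
  w[intersect(c("T7", "T8"), labs)] <- 0
  w <- w / (-mean(w[c("F3", "Fz", "F4")]))
  if (zero_mean) w <- w - mean(w)
  w
}

#' Project a source value to scalp channels
#'
#' @param kernel_value numeric scalar or vector (source time course, uV).
#' @param montage an `mmn_montage`.
#' @param weights optional precomputed template from [scalp_projection()].
#' @return matrix channels x length(kernel_value).
#' @export
project_to_scalp <- function(kernel_value, montage, weights = NULL) {
  w <- weights %||% scalp_projection(montage)
  if (length(w) != length(montage$labels)) stop("channel count mismatch")
  out <- outer(unname(w), kernel_value)
  rownames(out) <- montage$labels
  out
}
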