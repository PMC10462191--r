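short_plan <- data.frame(soa = c(450L, 900L), n_trials = c(40L, 20L))

noiseless_subject <- function(seed = 1, amp = -1) {
  subject_params("sim1", group = "TD", age = 10,
                 mmn_amplitude_by_soa = list(`450` = amp, `900` = amp,
                                             `1800` = amp),
                 noise_sd = 0, blink_rate = 0, seed = seed)
}

test_that("same seed gives bit-identical recordings", {
  sched <- build_session_schedule(short_plan, seed = 2)
  sp <- subject_params("s", group = "TD", age = 9,
                       mmn_amplitude_by_soa = list(`450` = -1, `900` = -1,
                                                   `1800` = -1),
                       noise_sd = 3, blink_rate = 5, seed = 77)
  e1 <- simulate_continuous_eeg(sched, sp)
  e2 <- simulate_continuous_eeg(sched, sp)
  expect_identical(e1$data, e2$data)
})

test_that("noiseless epoch average equals the projected kernel", {
  sched <- build_session_schedule(short_plan, seed = 3)
  sp <- noiseless_subject()
  eeg <- simulate_continuous_eeg(sched, sp, fs = 512)
  epochs <- suppressMessages(extract_epochs(eeg))
  erp <- average_condition(epochs, "STD", 900)
  k <- synthesize_erp_kernels(sp, 900, fs = 512)
  w <- scalp_projection(eeg$montage)
  v <- w / mean(w[c("F3", "Fz", "F4")])
  expected <- outer(unname(v), k$std)
  post <- epochs$time_ms >= 0
  expect_lt(max(abs(erp$data[, post] - expected[, post])), 1e-9)
})

test_that("doubling kernel amplitudes doubles the noiseless signal", {
  sched <- build_session_schedule(data.frame(soa = 900L, n_trials = 10L), seed = 4)
  p1 <- erp_kernel_params()
  p2 <- erp_kernel_params(p1 = list(amp = 4, lat = 60, sigma = 15),
                          n1 = list(amp = -6, lat = 110, sigma = 20),
                          p2 = list(amp = 4, lat = 190, sigma = 25))
  mk <- function(kp, amp) {
    subject_params("s", group = "TD", age = 10,
                   mmn_amplitude_by_soa = list(`450` = amp, `900` = amp,
                                               `1800` = amp),
                   erp_kernel_params = kp, noise_sd = 0, seed = 5)
  }
  e1 <- simulate_continuous_eeg(sched, mk(p1, -1))
  e2 <- simulate_continuous_eeg(sched, mk(p2, -2))
  expect_equal(e2$data, 2 * e1$data, tolerance = 1e-12)
})

test_that("noisy simulation recovers the injected amplitude within 2 SE", {
  ## moderate trial count; the standard error budget comes from the empirical
  ## spread of per-epoch window amplitudes
  plan <- data.frame(soa = 900L, n_trials = 300L)
  sched <- build_session_schedule(plan, seed = 6)
  sp <- subject_params("s", group = "TD", age = 10,
                       mmn_amplitude_by_soa = list(`450` = -1, `900` = -1,
                                                   `1800` = -1),
                       noise_sd = 5, seed = 8)
  eeg <- simulate_continuous_eeg(sched, sp, fs = 512)
  epochs <- suppressMessages(extract_epochs(eeg))
  epochs <- baseline_correct(epochs)
  meas <- measure_subject(epochs)
  k <- synthesize_erp_kernels(sp, 900, fs = 512)
  win <- k$time_ms >= 200 & k$time_ms <= 240
  injected_window_mean <- mean((k$dev - k$std)[win])
  ## SE of the difference of two condition means of composite window values
  win_amp <- function(kind) {
    idx <- which(epochs$trials$kind == kind)
    vapply(idx, function(i) {
      mmn_amplitude(`rownames<-`(epochs$data[i, , ], epochs$labels),
                    epochs$time_ms)
    }, numeric(1))
  }
  a_dev <- win_amp("DEV"); a_std <- win_amp("STD")
  se <- sqrt(stats::var(a_dev) / length(a_dev) + stats::var(a_std) / length(a_std))
  expect_lt(abs(meas$mmn[meas$soa == 900] - injected_window_mean), 2 * se)
})

test_that("cohort generation reproduces sizes, ranges and the effect map", {
  cohort <- generate_cohort(41, 21, seed = 9)
  subj <- cohort$subjects
  expect_equal(sum(subj$group == "TD"), 41)
  expect_equal(sum(subj$group == "CLN3"), 21)
  expect_true(all(subj$age[subj$group == "TD"] >= 6 &
                    subj$age[subj$group == "TD"] <= 26))
  expect_true(all(subj$age[subj$group == "CLN3"] >= 6 &
                    subj$age[subj$group == "CLN3"] <= 28))
  expect_true(all(is.na(subj$stage[subj$group == "TD"])))
  expect_true(all(subj$stage[subj$group == "CLN3"] %in% 1:3))
  ## configuration contract: CLN3 group-mean injected MMN at 1800 ms is 0
  expect_equal(unname(cohort_config()$cln3_mean[["1800"]]), 0)
  ## age-trend signs in the effect map mirror the reported directions
  cfg <- cohort_config()
  expect_lt(cfg$td_age_slope, 0)
  expect_gt(cfg$cln3_age_slope, 0)
})

test_that("empty CLN3 cohort yields a TD-only table and negatives error", {
  cohort <- generate_cohort(5, 0, seed = 10)
  expect_true(all(cohort$subjects$group == "TD"))
  expect_error(generate_cohort(-1, 5), "non-negative")
})

test_that("pink noise has the requested scale and no DC", {
  set.seed(1)
  x <- pink_noise(8192, sd = 3)
  expect_equal(stats::sd(x), 3, tolerance = 1e-9)
  expect_lt(abs(mean(x)), 0.5)
})
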