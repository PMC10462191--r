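#' Tone specification for the duration-oddball paradigm
#'
#' Standards are 100 ms, deviants 180 ms, both 1000 Hz pure tones with 10 ms
#' rise/fall, presented at a nominal 75 dB SPL (the level is carried as a
#' label; no acoustics are rendered).
#'
#' @param frequency_hz tone frequency in Hz.
#' @param duration_ms tone duration in ms.
#' @param rise_fall_ms rise and fall time in ms.
#' @param level_label nominal presentation level.
#' @return list of class `tone_spec`.
#' @export
tone_spec <- function(frequency_hz = 1000, duration_ms = 100,
                      rise_fall_ms = 10, level_label = "75 dB SPL") {
  if (frequency_hz <= 0) stop("frequency must be positive")
  if (duration_ms <= 2 * rise_fall_ms) {
    stop("duration must exceed twice the rise/fall time")
  }
  structure(list(frequency_hz = frequency_hz, duration_ms = duration_ms,
                 rise_fall_ms = rise_fall_ms, level_label = level_label),
            class = "tone_spec")
}

#' Default oddball block plan
#'
#' 14 blocks in total: 2 blocks of 500 trials at the 450 ms SOA, 4 blocks of
#' 250 trials at 900 ms, and 8 blocks of 125 trials at 1800 ms, giving 1000
#' trials per SOA condition.
#'
#' @return data.frame with columns `soa` (ms) and `n_trials`.
#' @export
oddball_block_plan <- function() {
  data.frame(
    soa = c(rep(450L, 2), rep(900L, 4), rep(1800L, 8)),
    n_trials = c(rep(500L, 2), rep(250L, 4), rep(125L, 8))
  )
}

## Uniformly sample k deviant positions among trials 2..n with no two adjacent,
## via the classic bijection between non-adjacent k-subsets of {1..m} and
## k-subsets of {1..m-k+1}.
sample_deviant_positions <- function(n_trials, n_dev) {
  if (n_dev == 0L) return(integer(0))
  m <- n_trials - 1L             # candidate slots are trials 2..n
  if (m - n_dev + 1L < n_dev) {
    stop("cannot place ", n_dev, " non-adjacent deviants in ", n_trials, " trials")
  }
  y <- sort(sample.int(m - n_dev + 1L, n_dev))
  y + seq_len(n_dev) - 1L + 1L   # spread, then shift from slot 1 -> trial 2
}

#' Build a randomized oddball session schedule
#'
#' Generates the ordered stimulus events for one recording session: blocks are
#' shuffled, and within each block exactly `round(0.15 * n_trials)` deviants
#' are placed uniformly at random subject to two conventions of oddball
#' practice: the first trial of a block is a standard, and no two deviants are
#' adjacent. Within a block successive onsets differ by exactly the block SOA.
#'
#' @param block_plan data.frame with columns `soa` and `n_trials`; defaults to
#'   [oddball_block_plan()].
#' @param seed integer seed controlling block order and deviant placement.
#' @param deviant_prop deviant proportion (default 0.15).
#' @param inter_block_gap_ms silent gap inserted between blocks.
#' @return object of class `session_schedule`: list with `events` (data.frame
#'   `onset_ms`, `kind`, `soa`, `block`) and `block_plan` (shuffled order).
#' @export
#' @examples
#' sched <- build_session_schedule(seed = 1)
#' table(sched$events$soa)
build_session_schedule <- function(block_plan = oddball_block_plan(), seed = 1,
                                   deviant_prop = 0.15,
                                   inter_block_gap_ms = 2000) {
  stopifnot(is.data.frame(block_plan), nrow(block_plan) >= 1,
            all(c("soa", "n_trials") %in% names(block_plan)))
  if (any(block_plan$n_trials <= 0)) stop("invalid block plan: non-positive trial count")
  if (!all(block_plan$soa %in% c(450L, 900L, 1800L))) {
    stop("invalid block plan: unknown SOA condition")
  }
  with_seed(seed, {
    ord <- sample.int(nrow(block_plan))
    plan <- block_plan[ord, , drop = FALSE]
    t_cursor <- 0
    ev <- vector("list", nrow(plan))
    for (b in seq_len(nrow(plan))) {
      n <- plan$n_trials[b]
      soa <- plan$soa[b]
      n_dev <- round(deviant_prop * n)
      kind <- rep("STD", n)
      kind[sample_deviant_positions(n, n_dev)] <- "DEV"
      onset <- t_cursor + soa * (seq_len(n) - 1)
      ev[[b]] <- data.frame(onset_ms = onset, kind = kind,
                            soa = soa, block = b)
      t_cursor <- onset[n] + soa + inter_block_gap_ms
    }
    events <- do.call(rbind, ev)
    rownames(events) <- NULL
    structure(list(events = events, block_plan = plan),
              class = "session_schedule")
  })
}

#' Write schedule events as a tab-separated file
#'
#' @param schedule a `session_schedule`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(schedule, path) {
  utils::write.table(schedule$events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read schedule events from a tab-separated file
#'
#' @param path TSV produced by [write_events_tsv()].
#' @return data.frame of events.
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
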