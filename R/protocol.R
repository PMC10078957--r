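#' Stimulation protocol configuration
#'
#' Describes the block/sub-block structure and timing of the electrotactile
#' stimulation session. The defaults reproduce the experimental protocol:
#' 6 blocks of 300 stimuli each, every block split into 5 sub-blocks in which
#' each of the two forearm sites (D = dorsal/radial, V = volar/median)
#' receives between 25 and 35 pulses (60 per sub-block in total), 700 ms
#' inter-stimulus interval, 10 s pauses between sub-blocks, and no more than
#' 3 consecutive pulses at the same site. The attended (target) location
#' alternates between blocks.
#'
#' @param n_blocks number of blocks.
#' @param stimuli_per_block stimuli delivered in one block (must be even and
#'   divisible by `sub_blocks_per_block`).
#' @param sub_blocks_per_block sub-blocks per block.
#' @param per_site_range length-2 integer vector: admissible per-site stimulus
#'   count within one sub-block.
#' @param isi_ms inter-stimulus interval in milliseconds (>= 500 so that
#'   500 ms epochs never overlap).
#' @param pause_s pause between sub-blocks in seconds.
#' @param max_run_length maximum number of consecutive same-site stimuli.
#' @param start_target attended location of block 1: "D", "V" or
#'   "randomized" (drawn from the seed).
#' @param warmup_s silent lead-in before the first stimulus, seconds; must
#'   leave room for the first epoch's baseline.
#' @param rate_hz sampling rate of the acquisition clock.
#' @param seed integer seed making the schedule deterministic.
#' @return object of class `protocol_config`.
#' @export
protocol_config <- function(n_blocks = 6L,
                            stimuli_per_block = 300L,
                            sub_blocks_per_block = 5L,
                            per_site_range = c(25L, 35L),
                            isi_ms = 700,
                            pause_s = 10,
                            max_run_length = 3L,
                            start_target = c("randomized", "D", "V"),
                            warmup_s = 2,
                            rate_hz = RATE_HZ,
                            seed = NULL) {
  start_target <- match.arg(start_target)
  n_blocks <- as.integer(n_blocks)
  stimuli_per_block <- as.integer(stimuli_per_block)
  sub_blocks_per_block <- as.integer(sub_blocks_per_block)
  per_site_range <- as.integer(per_site_range)

  if (n_blocks < 1L) stop("protocol config: n_blocks must be >= 1")
  if (stimuli_per_block %% sub_blocks_per_block != 0L)
    stop("protocol config: stimuli_per_block must be divisible by sub_blocks_per_block")
  if (stimuli_per_block %% 2L != 0L)
    stop("protocol config: stimuli_per_block must be even (per-location balance)")
  sub_total <- stimuli_per_block %/% sub_blocks_per_block
  lo <- per_site_range[1]; hi <- per_site_range[2]
  if (lo > hi || lo < 0L)
    stop("protocol config: per_site_range must be a non-decreasing pair of non-negative counts")
  # a per-site count d is feasible iff d and sub_total - d are both in range
  if (max(lo, sub_total - hi) > min(hi, sub_total - lo))
    stop(sprintf(paste0("protocol config: per_site_range [%d, %d] cannot sum to the ",
                        "sub-block total %d"), lo, hi, sub_total))
  if (isi_ms < 500)
    stop("protocol config: isi_ms must be >= 500 ms so that 500 ms epochs never overlap")
  if (warmup_s * rate_hz < EPOCH_PRE)
    stop("protocol config: warmup_s too short for the first epoch's 100 ms baseline")

  structure(list(n_blocks = n_blocks,
                 stimuli_per_block = stimuli_per_block,
                 sub_blocks_per_block = sub_blocks_per_block,
                 per_site_range = per_site_range,
                 isi_ms = isi_ms,
                 pause_s = pause_s,
                 max_run_length = as.integer(max_run_length),
                 start_target = start_target,
                 warmup_s = warmup_s,
                 rate_hz = as.integer(rate_hz),
                 seed = seed),
            class = "protocol_config")
}

# longest run in a location sequence, given a carried-in run from the
# previous sub-block (loc/len); returns max run length of the joined sequence
max_run_with_carry <- function(x, carry_loc, carry_len) {
  r <- rle(x)
  m <- max(r$lengths)
  if (!is.null(carry_loc) && r$values[1] == carry_loc)
    m <- max(m, r$lengths[1] + carry_len)
  m
}

# draw one sub-block site sequence satisfying the run constraint, by
# rejection sampling over shuffles of the fixed multiset
draw_subblock_sequence <- function(n_d, n_v, carry_loc, carry_len, max_run,
                                   max_attempts = 10000L) {
  pool <- c(rep("D", n_d), rep("V", n_v))
  for (i in seq_len(max_attempts)) {
    s <- sample(pool)
    if (max_run_with_carry(s, carry_loc, carry_len) <= max_run) return(s)
  }
  stop("generate_schedule: could not satisfy the run-length constraint; ",
       "max_run_length too small for the requested site counts")
}

# draw per-sub-block D counts for one block: each in [lo, hi], summing to
# half the block total so every block is site-balanced
draw_site_counts <- function(n_sub, lo, hi, block_half, max_attempts = 100000L) {
  if (n_sub * lo > block_half || n_sub * hi < block_half)
    stop(sprintf(paste0("generate_schedule: per-site range [%d, %d] cannot give ",
                        "%d stimuli per site per block"), lo, hi, block_half))
  for (i in seq_len(max_attempts)) {
    d <- sample(seq.int(lo, hi), n_sub, replace = TRUE)
    if (sum(d) == block_half) return(d)
  }
  stop("generate_schedule: site-count rejection sampling failed")
}

#' Generate a pseudo-randomized stimulus schedule
#'
#' Produces the ordered event list of one session: within every sub-block the
#' two sites receive a randomized number of stimuli (within
#' `per_site_range`, site-balanced over each block) in shuffled order with no
#' more than `max_run_length` consecutive same-site stimuli (enforced across
#' sub-block boundaries as well). Stimuli within a sub-block are spaced by
#' `isi_ms`; consecutive sub-blocks are separated by `pause_s`. The attended
#' location alternates across blocks.
#'
#' @param config a [protocol_config()].
#' @return object of class `stim_schedule`: list with `events` (data.frame
#'   with columns onset_sample (0-based), location, block, sub_block,
#'   attended_location) and `config`.
#' @export
generate_schedule <- function(config = protocol_config()) {
  stopifnot(inherits(config, "protocol_config"))
  with_seed(config$seed, {
    lo <- config$per_site_range[1]; hi <- config$per_site_range[2]
    n_sub <- config$sub_blocks_per_block
    block_half <- config$stimuli_per_block %/% 2L
    isi_smp <- as.integer(round(config$isi_ms / 1000 * config$rate_hz))
    pause_smp <- as.integer(round(config$pause_s * config$rate_hz))

    start <- if (config$start_target == "randomized")
      sample(c("D", "V"), 1L) else config$start_target
    attended <- rep(c(start, setdiff(c("D", "V"), start)),
                    length.out = config$n_blocks)

    rows <- vector("list", config$n_blocks * n_sub)
    t <- as.integer(round(config$warmup_s * config$rate_hz))
    carry_loc <- NULL; carry_len <- 0L
    k <- 0L
    for (b in seq_len(config$n_blocks)) {
      d_counts <- draw_site_counts(n_sub, lo, hi, block_half)
      for (s in seq_len(n_sub)) {
        n_d <- d_counts[s]
        n_v <- config$stimuli_per_block %/% n_sub - n_d
        locs <- draw_subblock_sequence(n_d, n_v, carry_loc, carry_len,
                                       config$max_run_length)
        n <- length(locs)
        onsets <- t + isi_smp * (seq_len(n) - 1L)
        k <- k + 1L
        rows[[k]] <- data.frame(onset_sample = onsets,
                                location = locs,
                                block = b,
                                sub_block = s,
                                attended_location = attended[b],
                                stringsAsFactors = FALSE)
        t <- onsets[n] + isi_smp + pause_smp
        tail_run <- rle(locs)
        carry_new <- tail(tail_run$values, 1)
        carry_new_len <- tail(tail_run$lengths, 1)
        if (!is.null(carry_loc) && identical(carry_new, carry_loc) &&
            carry_new_len == n) {
          carry_len <- carry_len + carry_new_len
        } else {
          carry_loc <- carry_new
          carry_len <- carry_new_len
        }
      }
    }
    structure(list(events = do.call(rbind, rows), config = config),
              class = "stim_schedule")
  })
}

#' @export
print.stim_schedule <- function(x, ...) {
  ev <- x$events
  cat(sprintf("<stim_schedule> %d events, %d blocks; D: %d, V: %d\n",
              nrow(ev), length(unique(ev$block)),
              sum(ev$location == "D"), sum(ev$location == "V")))
  invisible(x)
}

check_row <- function(check, pass, first_violation = NA_integer_,
                      detail = "") {
  data.frame(check = check, pass = pass,
             first_violation = first_violation, detail = detail,
             stringsAsFactors = FALSE)
}

#' Validate a stimulus schedule against the protocol invariants
#'
#' Runs every structural check (event totals, per-location balance, run
#' length, per-sub-block site counts, onset monotonicity and spacing,
#' attended-location structure) and reports pass/fail per check with the
#' first violating event index (1-based) where applicable. Validation never
#' throws.
#'
#' @param schedule a `stim_schedule`.
#' @return data.frame of class `schedule_validation` with columns check,
#'   pass, first_violation, detail.
#' @export
validate_schedule <- function(schedule) {
  cfg <- schedule$config
  ev <- schedule$events
  out <- list()

  n_expect <- cfg$n_blocks * cfg$stimuli_per_block
  out$total <- check_row("total_events", nrow(ev) == n_expect,
                         detail = sprintf("%d of %d", nrow(ev), n_expect))

  n_d <- sum(ev$location == "D"); n_v <- sum(ev$location == "V")
  out$balance <- check_row("location_balance", n_d == n_v,
                           detail = sprintf("D=%d V=%d", n_d, n_v))

  r <- rle(ev$location)
  bad <- which(r$lengths > cfg$max_run_length)
  first <- if (length(bad)) sum(r$lengths[seq_len(bad[1] - 1)]) + 1L else NA_integer_
  out$run <- check_row("max_run_length", length(bad) == 0L, first,
                       detail = sprintf("longest run %d (max %d)",
                                        max(r$lengths), cfg$max_run_length))

  lo <- cfg$per_site_range[1]; hi <- cfg$per_site_range[2]
  counts <- table(ev$block, ev$sub_block, ev$location)
  in_range <- counts >= lo & counts <= hi
  out$sub <- check_row("sub_block_site_counts", all(in_range),
                       detail = sprintf("counts in [%d, %d]", lo, hi))

  incr <- all(diff(ev$onset_sample) > 0)
  first_bad <- if (incr) NA_integer_ else which(diff(ev$onset_sample) <= 0)[1] + 1L
  out$onset <- check_row("onsets_increasing", incr, first_bad)

  isi_smp <- round(cfg$isi_ms / 1000 * cfg$rate_hz)
  spacing_ok <- TRUE; first_sp <- NA_integer_
  sub_id <- interaction(ev$block, ev$sub_block, drop = TRUE)
  for (g in split(seq_len(nrow(ev)), sub_id)) {
    d <- diff(ev$onset_sample[g])
    if (length(d) && any(d != isi_smp)) {
      spacing_ok <- FALSE
      first_sp <- g[which(d != isi_smp)[1] + 1L]
      break
    }
  }
  out$isi <- check_row("isi_spacing", spacing_ok, first_sp,
                       detail = sprintf("%d samples", isi_smp))

  att_const <- all(tapply(ev$attended_location, ev$block,
                          function(a) length(unique(a)) == 1L))
  out$attc <- check_row("attended_constant_within_block", att_const)

  blocks <- unique(ev$block)
  att_by_block <- vapply(blocks, function(b)
    ev$attended_location[ev$block == b][1], character(1))
  alt <- length(blocks) < 2L || all(att_by_block[-1] != att_by_block[-length(att_by_block)])
  out$alt <- check_row("attended_alternates_across_blocks", alt)

  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("schedule_validation", "data.frame")
  res
}

#' Write / read a schedule event table as TSV
#'
#' @param x a `stim_schedule` or its events data.frame.
#' @param path file path.
#' @return `read_events` returns the events data.frame.
#' @export
write_events <- function(x, path) {
  ev <- if (inherits(x, "stim_schedule")) x$events else x
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset_sample", "location", "block", "sub_block",
            "attended_location")
  missing <- setdiff(need, names(ev))
  if (length(missing))
    stop("event table missing columns: ", paste(missing, collapse = ", "))
  ev
}
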