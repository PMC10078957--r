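# Shared fixtures, built in code.

# small session: 2 blocks x 60 stimuli in one sub-block each (30 per
# cluster), enough for SEP3 grouping
small_config <- function(seed = 1, n_blocks = 2, stimuli_per_block = 60,
                         sub_blocks_per_block = 1, ...) {
  protocol_config(n_blocks = n_blocks, stimuli_per_block = stimuli_per_block,
                  sub_blocks_per_block = sub_blocks_per_block, seed = seed,
                  ...)
}

# deterministic noise-free subject (no blinks) with a given attention gain
clean_subject <- function(gain = 1, seed = 1, ...) {
  subject_model(attention_gain = gain, noise_sd_uV = 0, blink_rate_hz = 0,
                seed = seed, ...)
}

# full preprocessing chain; filtering optional so that noise-free algebraic
# identities can be checked exactly
preprocessed_epochs <- function(schedule, subject, filter = TRUE) {
  rec <- simulate_recording(schedule, subject)
  if (filter) rec <- bandpass_filter(rec)
  reject_artifacts(baseline_correct(epoch_recording(rec)))
}

# per-group sERP matrices straight from a seed, for classifier tests
quick_serps <- function(seed = 1, gain = 1.5, noise = 10, n_avg = 3,
                        channel = "C3", cfg = small_config(seed),
                        filter = TRUE, max_groups = NULL) {
  sch <- generate_schedule(cfg)
  sub <- subject_model(attention_gain = gain, noise_sd_uV = noise,
                       blink_rate_hz = 0, seed = seed + 500)
  ep <- preprocessed_epochs(sch, sub, filter = filter)
  grouped <- balance_and_group(assign_clusters(ep), n_avg, max_groups)
  cluster_serps(grouped, channel)
}

# synthetic serp_set built directly (no simulation): class separation
# injected on chosen samples of the D-stim cluster means
direct_serps <- function(m = 10, p = 60, effect = 1, support = 21:35,
                         noise = 0.5, seed = 42, n_avg = 3,
                         channel = "C3") {
  set.seed(seed)
  base <- function() matrix(rnorm(m * p, 0, noise), m, p)
  bump <- numeric(p); bump[support] <- effect
  serps <- list(ADSD = base() + rep(bump, each = m), ADSV = base(),
                AVSD = base(), AVSV = base() + rep(bump, each = m))
  structure(c(serps, list(m = m, n_avg = n_avg, channel = channel)),
            class = "serp_set")
}
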