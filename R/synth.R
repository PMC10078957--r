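#' Somatosensory evoked potential template
#'
#' Parametric single-trial SEP shape: a sum of Gaussian-windowed component
#' lobes (P1/N1/P3-like) on the post-stimulus axis, plus a per-channel gain
#' map describing how strongly the response projects onto each scalp
#' channel. Default amplitudes/latencies give the canonical morphology of a
#' contralateral somatosensory response to right-forearm stimulation: P1
#' +2 uV at 50 ms, N1 -4 uV at 120 ms, P3 +3 uV at 280 ms, with
#' contralateral (C3/CP3) dominance. Fp1 carries no SEP.
#'
#' @param components data.frame with columns label, latency_ms (0-400),
#'   width_ms (> 0, Gaussian sd), amplitude_uV (signed).
#' @param gains named numeric vector over the scalp channels.
#' @return object of class `sep_template`.
#' @export
sep_template <- function(components = data.frame(
                           label = c("P1", "N1", "P3"),
                           latency_ms = c(50, 120, 280),
                           width_ms = c(15, 25, 60),
                           amplitude_uV = c(2, -4, 3)),
                         gains = c(C3 = 1, Cz = 0.8, C4 = 0.4,
                                   CP3 = 1, Pz = 0.6)) {
  if (nrow(components) > 0) {
    if (any(components$width_ms <= 0))
      stop("sep_template: component widths must be > 0")
    if (any(components$latency_ms < 0 | components$latency_ms > 400))
      stop("sep_template: component latencies must lie in 0-400 ms")
  }
  if (!all(SCALP_CHANNELS %in% names(gains)))
    stop("sep_template: gains must cover all scalp channels")
  structure(list(components = components, gains = gains[SCALP_CHANNELS]),
            class = "sep_template")
}

#' Evaluate a SEP template on a time axis
#'
#' Sums the Gaussian component lobes at their latencies; the waveform is
#' identically zero before stimulus onset (t < 0).
#'
#' @param template a [sep_template()].
#' @param times time axis in seconds (0 = stimulus onset), e.g.
#'   [epoch_times()].
#' @return numeric waveform in microvolts, same length as `times`.
#' @export
render_template <- function(template, times = epoch_times()) {
  w <- numeric(length(times))
  comps <- template$components
  for (i in seq_len(nrow(comps))) {
    lat <- comps$latency_ms[i] / 1000
    sig <- comps$width_ms[i] / 1000
    w <- w + comps$amplitude_uV[i] * exp(-(times - lat)^2 / (2 * sig^2))
  }
  w[times < 0] <- 0
  w
}

#' Synthetic subject model
#'
#' Generative model of one subject's continuous EEG: location-specific SEP
#' templates, a multiplicative attention gain applied to responses at the
#' attended location, 1/f background noise, and Poisson blink artifacts
#' dominant on Fp1. `attention_gain = 1` makes the attended and unattended
#' conditions statistically exchangeable (the null).
#'
#' @param template_D,template_V [sep_template()] objects for the dorsal
#'   (radial-nerve) and volar (median-nerve) stimulation sites. The default
#'   V template is slightly smaller and later than the D template.
#' @param attention_gain multiplicative gain (>= 1) on the attended
#'   location's response amplitude.
#' @param noise_sd_uV standard deviation of the background noise, microvolts.
#' @param pink_exponent spectral exponent of the noise (1 = pink, 0 = white).
#' @param blink_rate_hz Poisson rate of blink artifacts.
#' @param blink_amp_uV peak blink amplitude on Fp1.
#' @param seed integer seed for all stochastic elements.
#' @return object of class `subject_model`.
#' @export
subject_model <- function(template_D = sep_template(),
                          template_V = sep_template(
                            components = data.frame(
                              label = c("P1", "N1", "P3"),
                              latency_ms = c(55, 125, 285),
                              width_ms = c(15, 25, 60),
                              amplitude_uV = c(1.6, -3.4, 2.5))),
                          attention_gain = 1.5,
                          noise_sd_uV = 20,
                          pink_exponent = 1,
                          blink_rate_hz = 0.1,
                          blink_amp_uV = 120,
                          seed = NULL) {
  if (attention_gain < 1) stop("subject_model: attention_gain must be >= 1")
  if (noise_sd_uV < 0 || blink_rate_hz < 0)
    stop("subject_model: noise_sd_uV and blink_rate_hz must be non-negative")
  structure(list(template_D = template_D, template_V = template_V,
                 attention_gain = attention_gain,
                 noise_sd_uV = noise_sd_uV,
                 pink_exponent = pink_exponent,
                 blink_rate_hz = blink_rate_hz,
                 blink_amp_uV = blink_amp_uV,
                 seed = seed),
            class = "subject_model")
}

#' 1/f-shaped Gaussian noise
#'
#' Spectrally shaped noise: white Gaussian noise whose Fourier amplitudes are
#' scaled by f^(-exponent/2), rescaled to the requested standard deviation.
#' Uses the current RNG stream.
#'
#' @param n number of samples.
#' @param sd target standard deviation.
#' @param exponent spectral exponent (power ~ 1/f^exponent); 0 gives white
#'   noise.
#' @return numeric vector of length `n`.
#' @export
pink_noise <- function(n, sd = 1, exponent = 1) {
  if (sd == 0) return(numeric(n))
  w <- rnorm(n)
  if (exponent == 0) return(w * sd / stats::sd(w))
  f <- seq_len(n) - 1
  f <- pmin(f, n - f)             # two-sided frequency index, symmetric
  scale <- ifelse(f == 0, 0, f^(-exponent / 2))
  x <- Re(fft(fft(w) * scale, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

# raised-cosine blink lobe, ~300 ms, peak 1
blink_shape <- function(rate_hz = RATE_HZ, dur_s = 0.3) {
  n <- round(dur_s * rate_hz)
  sin(pi * (seq_len(n) - 1) / (n - 1))^2
}

# fixed scalp propagation of the ocular artifact (fraction of Fp1 amplitude)
BLINK_PROP <- c(C3 = 0.18, Cz = 0.20, C4 = 0.18, CP3 = 0.12, Pz = 0.08,
                Fp1 = 1)

#' Inject blink artifacts into a recording
#'
#' Adds smooth ~300 ms positive deflections at Poisson-distributed times,
#' with full amplitude on Fp1 and fixed fractional copies on the scalp
#' channels (frontal-to-posterior fall-off).
#'
#' @param recording an `eeg_recording`.
#' @param rate_hz blink rate (Poisson, events per second).
#' @param amp_uV peak amplitude on Fp1.
#' @param seed integer seed, or NULL to use the current stream.
#' @return the recording with blinks added and a `blink_onsets` element
#'   (0-based sample indices of blink starts).
#' @export
inject_blinks <- function(recording, rate_hz, amp_uV, seed = NULL) {
  if (amp_uV <= 0) stop("inject_blinks: amp_uV must be > 0")
  if (rate_hz == 0) {
    recording$blink_onsets <- integer(0)
    return(recording)
  }
  with_seed(seed, {
    n <- ncol(recording$data)
    dur_s <- n / recording$rate_hz
    shape <- blink_shape(recording$rate_hz)
    len <- length(shape)
    n_blinks <- rpois(1, rate_hz * dur_s)
    onsets <- sort(floor(runif(n_blinks, 0, n - len)))
    for (s in onsets) {
      idx <- (s + 1):(s + len)
      for (ch in recording$channels)
        recording$data[ch, idx] <- recording$data[ch, idx] +
          BLINK_PROP[ch] * amp_uV * shape
    }
    recording$blink_onsets <- as.integer(onsets)
    recording
  })
}

#' Simulate a continuous EEG recording for a stimulus schedule
#'
#' Renders, for every scheduled stimulus, the corresponding location's SEP
#' template onto the five scalp channels (scaled by the template's channel
#' gains, and by `attention_gain` when the stimulated location is the
#' attended one), then adds 1/f background noise to all channels and blink
#' artifacts at Poisson times. Deterministic given the subject seed.
#'
#' @param schedule a `stim_schedule`.
#' @param subject a [subject_model()].
#' @param seed overrides `subject$seed` when given.
#' @return object of class `eeg_recording`: list with `data` (channels x
#'   samples matrix, microvolts), `rate_hz`, `channels`, `events`, and
#'   bookkeeping fields.
#' @export
simulate_recording <- function(schedule, subject, seed = subject$seed) {
  stopifnot(inherits(schedule, "stim_schedule"),
            inherits(subject, "subject_model"))
  ev <- schedule$events
  rate <- schedule$config$rate_hz
  n <- max(ev$onset_sample) + EPOCH_POST + rate   # 1 s tail margin
  with_seed(seed, {
    data <- matrix(0, nrow = length(ALL_CHANNELS), ncol = n,
                   dimnames = list(ALL_CHANNELS, NULL))
    post_t <- (seq_len(EPOCH_POST) - 1) / rate
    w_D <- render_template(subject$template_D, post_t)
    w_V <- render_template(subject$template_V, post_t)
    for (i in seq_len(nrow(ev))) {
      w <- if (ev$location[i] == "D") w_D else w_V
      g <- if (ev$location[i] == ev$attended_location[i])
        subject$attention_gain else 1
      gains <- if (ev$location[i] == "D") subject$template_D$gains
               else subject$template_V$gains
      idx <- (ev$onset_sample[i] + 1):(ev$onset_sample[i] + EPOCH_POST)
      for (ch in SCALP_CHANNELS)
        data[ch, idx] <- data[ch, idx] + g * gains[ch] * w
    }
    rec <- structure(list(data = data, rate_hz = rate,
                          channels = ALL_CHANNELS, events = ev,
                          unit = "uV", provenance = list()),
                     class = "eeg_recording")
    if (subject$noise_sd_uV > 0)
      for (ch in ALL_CHANNELS)
        rec$data[ch, ] <- rec$data[ch, ] +
          pink_noise(n, subject$noise_sd_uV, subject$pink_exponent)
    if (subject$blink_rate_hz > 0)
      rec <- inject_blinks(rec, subject$blink_rate_hz, subject$blink_amp_uV)
    rec
  })
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %d Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$rate_hz,
              ncol(x$data) / x$rate_hz, nrow(x$events)))
  invisible(x)
}
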