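# Seeded synthetic maneuver generator.
#
# Real recordings of airway-protective maneuvers are not publicly
# distributable, so the pipeline is validated against synthetic waveforms
# that emulate the acoustic structure reported for each class:
#
# - voluntary cough: burst-like onset (broadband noise with sub-800 Hz
#   oscillation), decaying frication noise, and a non-mandatory voiced coda
#   -- so the amplitude contour is high at onset, decays, and may re-rise
#   (convex).
# - throat clearing: weak onset and one sustained low-frequency
#   amplitude-modulated oscillatory fragment that rises and falls -- so the
#   amplitude contour is concave and energy concentrates below 800 Hz.
# - induced reflexive cough: a very short, strong onset pulse followed by
#   frication extending well above 800 Hz -- so kurtosis at onset and
#   high-band energy exceed the voluntary cough's.
#
# The generator is deterministic given its seed, uses Mersenne-Twister
# (R's default RNG) throughout, and shapes all noise with the same DCT
# filter bank used for analysis.

class_defaults <- list(
  voluntary_cough = list(
    duration_s = 0.39,
    onset_pulse = list(length_s = 0.06, gain = 1.0, decay_tau_s = 0.025),
    frication = list(lo_hz = 400, hi_hz = 2500, gain = 0.32, decay_rate = 8),
    low_freq_oscillation = list(f0_hz = 300, gain = 0.45, am_depth = 0.2),
    voiced_coda = list(probability = 0.5, f0_hz = 140, length_s = 0.08,
                       gain = 0.30)
  ),
  throat_clearing = list(
    duration_s = 0.46,
    onset_pulse = list(length_s = 0.03, gain = 0.25, decay_tau_s = 0.012),
    frication = list(lo_hz = 400, hi_hz = 1500, gain = 0.12, decay_rate = 0),
    low_freq_oscillation = list(f0_hz = 180, gain = 1.0, am_depth = 0.5),
    voiced_coda = list(probability = 0, f0_hz = 140, length_s = 0,
                       gain = 0)
  ),
  reflexive_cough = list(
    duration_s = 0.31,
    onset_pulse = list(length_s = 0.012, gain = 2.8, decay_tau_s = 0.004),
    frication = list(lo_hz = 800, hi_hz = 9000, gain = 0.5, decay_rate = 6),
    low_freq_oscillation = list(f0_hz = 280, gain = 0.25, am_depth = 0.2),
    voiced_coda = list(probability = 0.3, f0_hz = 150, length_s = 0.06,
                       gain = 0.22)
  )
)

#' Specification of one synthetic maneuver
#'
#' Returns the class defaults, optionally overridden field by field. The
#' default durations (voluntary cough 0.39 s, throat clearing 0.46 s,
#' reflexive cough 0.31 s) target the typical median durations of the three
#' maneuver classes.
#'
#' @param class one of `"voluntary_cough"`, `"throat_clearing"`,
#'   `"reflexive_cough"`.
#' @param seed integer seed making [generate_maneuver()] deterministic.
#' @param ... named overrides of the class defaults (`duration_s`,
#'   `onset_pulse`, `frication`, `low_freq_oscillation`, `voiced_coda`,
#'   `silence_s`, `gain`).
#' @return list of class `maneuver_spec`.
#' @export
maneuver_spec <- function(class = names(class_defaults), seed = 0L, ...) {
  class <- match.arg(class)
  spec <- class_defaults[[class]]
  spec$class <- class
  spec$seed <- as.integer(seed)
  spec$silence_s <- 0.15
  spec$gain <- 1.0
  over <- list(...)
  bad <- setdiff(names(over), c(names(spec)))
  if (length(bad)) stop("unknown maneuver_spec fields: ",
                        paste(bad, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(spec[[nm]]) && is.list(over[[nm]]))
      spec[[nm]] <- utils::modifyList(spec[[nm]], over[[nm]])
    else spec[[nm]] <- over[[nm]]
  }
  if (spec$duration_s <= spec$onset_pulse$length_s +
        spec$voiced_coda$length_s * (spec$voiced_coda$probability > 0))
    stop("duration_s must exceed onset plus coda length")
  if (spec$onset_pulse$gain < 0 || spec$frication$gain < 0 ||
        spec$low_freq_oscillation$gain < 0 || spec$voiced_coda$gain < 0)
    stop("gains must be >= 0")
  if (spec$voiced_coda$probability < 0 || spec$voiced_coda$probability > 1)
    stop("coda probability must be in [0, 1]")
  structure(spec, class = c("maneuver_spec", "list"))
}

# Band-shaped Gaussian noise of n samples, unit RMS before gain.
shaped_noise <- function(n, rate, lo, hi) {
  x <- dct_bandpass(stats::rnorm(n), rate, lo, min(hi, rate / 2 * 0.999))
  s <- sqrt(mean(x^2))
  if (s > 0) x / s else x
}

#' Generate one synthetic maneuver waveform
#'
#' Deterministic given `spec$seed`. The waveform is flanked by
#' `spec$silence_s` of near-silence (noise floor 70 dB below the maneuver)
#' so that envelope trimming has something to do. The returned annotation
#' gives the ground-truth fragment layout: 0-based half-open sample ranges
#' for `silence_pre`, `onset`, `body`, `coda` (possibly empty), and
#' `silence_post`, partitioning `[0, N)`.
#'
#' @param spec a [maneuver_spec()].
#' @param rate sampling rate (Hz), default 44100.
#' @return list with `waveform` ([waveform()]), `annotation` (data.frame
#'   `fragment`, `start`, `end`), `spec`.
#' @export
generate_maneuver <- function(spec, rate = 44100) {
  stopifnot(inherits(spec, "maneuver_spec"))
  local_seed(spec$seed, {
    on_len <- max(32L, round(spec$onset_pulse$length_s * rate))
    has_coda <- spec$voiced_coda$probability > 0 &&
      stats::runif(1) < spec$voiced_coda$probability
    coda_len <- if (has_coda) max(32L, round(spec$voiced_coda$length_s * rate)) else 0L
    total <- round(spec$duration_s * rate)
    body_len <- max(64L, total - on_len - coda_len)
    sil_len <- round(spec$silence_s * rate)
    t_on <- (seq_len(on_len) - 1) / rate
    t_body <- (seq_len(body_len) - 1) / rate

    lfo <- spec$low_freq_oscillation
    f0 <- lfo$f0_hz * stats::rlnorm(1, 0, 0.05)

    if (spec$class == "throat_clearing") {
      # weak noise onset, then one sustained AM oscillatory fragment whose
      # envelope rises and falls (concave amplitude contour)
      onset <- spec$onset_pulse$gain *
        exp(-t_on / spec$onset_pulse$decay_tau_s) *
        shaped_noise(on_len, rate, 100, 2000)
      env <- sin(pi * seq(0.05, 0.95, length.out = body_len))^0.75
      am <- 1 - lfo$am_depth / 2 +
        lfo$am_depth / 2 * sin(2 * pi * 25 * t_body + stats::runif(1, 0, 2 * pi))
      osc <- lfo$gain * env * am *
        (sin(2 * pi * f0 * t_body + stats::runif(1, 0, 2 * pi)) +
           0.35 * sin(2 * pi * 2 * f0 * t_body + stats::runif(1, 0, 2 * pi)))
      fric <- spec$frication$gain * env *
        shaped_noise(body_len, rate, spec$frication$lo_hz, spec$frication$hi_hz)
      body <- osc + fric
      coda <- numeric(0)
    } else {
      # burst-like onset: broadband noise under a sharply decaying envelope,
      # overlaid with low-frequency oscillation below 800 Hz
      burst_env <- exp(-t_on / spec$onset_pulse$decay_tau_s)
      attack <- pmin(1, t_on / 0.002)
      onset <- spec$onset_pulse$gain * attack * burst_env *
        (shaped_noise(on_len, rate, 200, 8000) +
           lfo$gain * sin(2 * pi * f0 * t_on + stats::runif(1, 0, 2 * pi)))
      fric_env <- if (spec$frication$decay_rate > 0)
        exp(-spec$frication$decay_rate * t_body) else rep(1, body_len)
      body <- spec$frication$gain * fric_env *
        shaped_noise(body_len, rate, spec$frication$lo_hz, spec$frication$hi_hz)
      if (has_coda) {
        t_coda <- (seq_len(coda_len) - 1) / rate
        cf0 <- spec$voiced_coda$f0_hz * stats::rlnorm(1, 0, 0.05)
        cenv <- sin(pi * seq(0.02, 0.98, length.out = coda_len))
        coda <- spec$voiced_coda$gain * cenv *
          (sin(2 * pi * cf0 * t_coda + stats::runif(1, 0, 2 * pi)) +
             0.3 * sin(2 * pi * 2 * cf0 * t_coda + stats::runif(1, 0, 2 * pi)) +
             0.15 * shaped_noise(coda_len, rate, 100, 1200))
      } else coda <- numeric(0)
    }

    maneuver <- spec$gain * c(onset, body, coda)
    floor_amp <- sqrt(mean(maneuver^2)) * 10^(-70 / 20)
    silence <- function(n) floor_amp * stats::rnorm(n)
    x <- c(silence(sil_len), maneuver, silence(sil_len))

    bounds <- cumsum(c(sil_len, length(onset), length(body), length(coda),
                       sil_len))
    annotation <- data.frame(
      fragment = c("silence_pre", "onset", "body", "coda", "silence_post"),
      start = c(0L, bounds[-5L]),
      end = bounds,
      stringsAsFactors = FALSE
    )
    list(waveform = waveform(x, rate), annotation = annotation, spec = spec)
  })
}

#' Microphone channel model
#'
#' `free_standing` is the identity. `skin_contact` emulates the attenuation
#' of high-frequency components propagating through neck tissue: a
#' zero-phase Butterworth low-pass (order `order`, applied forward and
#' backward) with default cutoff 1.5 kHz, giving well over 40 dB of
#' stop-band attenuation an octave above the cutoff.
#'
#' @param kind `"free_standing"` or `"skin_contact"`.
#' @param cutoff_hz low-pass cutoff for the skin-contact channel (Hz).
#' @param order Butterworth order (per pass).
#' @return list of class `channel_model`.
#' @export
channel_model <- function(kind = c("free_standing", "skin_contact"),
                          cutoff_hz = 1500, order = 6L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, cutoff_hz = cutoff_hz, order = as.integer(order)),
            class = "channel_model")
}

#' Apply a microphone channel model to a waveform
#'
#' @param w a [waveform()].
#' @param ch a [channel_model()].
#' @return A [waveform()]; identical to `w` for a free-standing channel.
#'   No re-normalization is performed here -- segments are energy-normalized
#'   downstream.
#' @export
apply_channel <- function(w, ch) {
  stopifnot(is_waveform(w), inherits(ch, "channel_model"))
  if (ch$kind == "free_standing") return(w)
  if (ch$cutoff_hz >= w$rate / 2)
    stop("skin-contact cutoff must be below the Nyquist frequency")
  bf <- signal::butter(ch$order, ch$cutoff_hz / (w$rate / 2), type = "low")
  waveform(signal::filtfilt(bf, w$samples), w$rate)
}

#' Generate a labeled synthetic cohort
#'
#' Emulates a study design in which every subject produces several tokens
#' of each maneuver class. Subject-level random effects (lognormal gain and
#' duration multipliers, sigma = 0.15) are drawn once per subject and
#' applied to all of that subject's tokens, so durations are correlated
#' within subject; token-level jitter (sigma = 0.05) is added on top. For
#' the reflexive class, the first half of the subjects are labeled
#' `urge_to_cough` and the rest `suppressed`; the generator parameters are
#' identical for both, so that contrast is a true null.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param tokens_per_class tokens per subject and class.
#' @param classes character vector of maneuver classes to generate.
#' @param channel a [channel_model()] applied to every waveform.
#' @param seed integer master seed; all randomness derives from it.
#' @param rate sampling rate (Hz).
#' @param dir if non-NULL, write one WAV per token (float32), a
#'   `cohort.csv`, and a `ground_truth.json` of annotations into `dir`, and
#'   return file paths instead of in-memory waveforms.
#' @return list with `cohort` (a [cohort_table()] including a `duration_s`
#'   column of realized maneuver durations), and either `waveforms` (named
#'   list of [waveform()]) plus `annotations`, or `files` (named vector of
#'   WAV paths) when `dir` is given.
#' @export
generate_cohort <- function(n_subjects = 40L, tokens_per_class = 5L,
                            classes = c("voluntary_cough", "throat_clearing"),
                            channel = channel_model("free_standing"),
                            seed = 0L, rate = 44100, dir = NULL) {
  if (n_subjects < 2L) stop("need n_subjects >= 2")
  stopifnot(all(classes %in% maneuver_classes))
  mic <- channel$kind

  grid <- expand.grid(token = seq_len(tokens_per_class),
                      class = classes,
                      subject = seq_len(n_subjects),
                      stringsAsFactors = FALSE)
  n_tok <- nrow(grid)

  draws <- local_seed(seed, {
    list(gain_mult = stats::rlnorm(n_subjects, 0, 0.15),
         dur_mult = stats::rlnorm(n_subjects, 0, 0.15),
         tok_jitter = stats::rlnorm(n_tok, 0, 0.05),
         tok_seed = sample.int(.Machine$integer.max - 1L, n_tok))
  })

  urge_subjects <- seq_len(n_subjects %/% 2L)
  rows <- vector("list", n_tok)
  waves <- vector("list", n_tok)
  annos <- vector("list", n_tok)
  for (i in seq_len(n_tok)) {
    s <- grid$subject[i]
    cl <- grid$class[i]
    dur <- class_defaults[[cl]]$duration_s * draws$dur_mult[s] *
      draws$tok_jitter[i]
    sp <- maneuver_spec(cl, seed = draws$tok_seed[i],
                        duration_s = dur,
                        gain = draws$gain_mult[s])
    g <- generate_maneuver(sp, rate)
    w <- apply_channel(g$waveform, channel)
    fid <- sprintf("s%02d_%s_t%d", s, cl, grid$token[i])
    rows[[i]] <- data.frame(
      file_id = fid, subject = s, class = cl, microphone = mic,
      induction = if (cl == "reflexive_cough") {
        if (s %in% urge_subjects) "urge_to_cough" else "suppressed"
      } else "none",
      token = grid$token[i], duration_s = dur,
      stringsAsFactors = FALSE
    )
    waves[[i]] <- w
    annos[[i]] <- g$annotation
  }
  ct <- cohort_table(do.call(rbind, rows))
  names(waves) <- names(annos) <- ct$file_id

  if (is.null(dir))
    return(list(cohort = ct, waveforms = waves, annotations = annos))

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(ct$file_id, function(fid) {
    p <- file.path(dir, paste0(fid, ".wav"))
    write_wav(waves[[fid]], p, encoding = "float32")
    p
  }, character(1))
  write_cohort_table(ct, file.path(dir, "cohort.csv"))
  jsonlite::write_json(annos, file.path(dir, "ground_truth.json"),
                       dataframe = "columns")
  list(cohort = ct, files = files)
}
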