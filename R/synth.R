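# Seeded synthetic soundscape generator. The categories emulate the
# structure of a balanced multi-label natural-sound corpus: a music
# super-category (harmonic, beat-aligned, phrase-repeating sound with
# long-range temporal organization), a speech-like category (syllable-rate
# amplitude-modulated formant trains), and environmental categories
# (stationary textures, impulsive event trains, machinery hum, chirps).

# Evaluate an expression under a temporary RNG state so generators are
# deterministic by seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Synthetic dataset configuration
#'
#' Defines the category inventory and global generation settings. The
#' default inventory has nine categories: two music-related (`music`,
#' `singing`), one speech-like (`speech`), and six environmental ones. The
#' music and speech subsets must be disjoint subsets of the inventory.
#'
#' @param sample_rate Waveform rate in Hz.
#' @param clip_duration Clip length in seconds.
#' @param categories Character vector of category names.
#' @param music_categories Subset of `categories` forming the music
#'   super-category.
#' @param speech_categories Subset forming the speech group.
#' @param clips_per_category Number of label appearances per category.
#' @param mixed_fraction Fraction of clips containing one music plus one
#'   non-music event, in `[0, 1]`.
#' @param overlay_fraction Fraction of clips containing two distinct
#'   non-music events overlaid at equal RMS (multi-label, group
#'   `non-music`). Natural field recordings routinely contain co-occurring
#'   events, and these clips keep the detection task away from ceiling.
#' @param rms_range Per-clip target RMS amplitude band; targets are drawn
#'   uniformly from it.
#' @param noise_floor_db Level of the ambient pink-noise bed added to every
#'   clip, in dB below the clip's signal RMS. Natural recordings always
#'   carry a background noise floor; without one, event-sparse categories
#'   would contain digital silence and the log-Mel representation would
#'   swing to its floor, letting overall energy dominate every analysis.
#' @param channel_eq_db Amplitude (dB) of a smooth random per-clip spectral
#'   tilt (a low-order Chebyshev EQ curve) emulating recording-channel
#'   variation between clips -- every field recording has its own
#'   microphone and channel coloration. Set to 0 to disable.
#' @param seed Integer seed; the same configuration (including seed) yields
#'   a bit-identical dataset.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(sample_rate = 22050, clip_duration = 10,
                         categories = c("music", "singing", "speech", "water",
                                        "wind", "barks", "ticks", "machinery",
                                        "chirps", "bells"),
                         music_categories = c("music", "singing"),
                         speech_categories = "speech",
                         clips_per_category = 30, mixed_fraction = 0.05,
                         overlay_fraction = 0.15,
                         rms_range = c(0.03, 0.09), noise_floor_db = 25,
                         channel_eq_db = 4, seed = 1L) {
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (clip_duration <= 0) stop("clip_duration must be positive")
  if (!all(music_categories %in% categories))
    stop("music_categories must be a subset of the inventory")
  if (!all(speech_categories %in% categories))
    stop("speech_categories must be a subset of the inventory")
  if (length(intersect(music_categories, speech_categories)) > 0L)
    stop("music and speech subsets must be disjoint")
  if (mixed_fraction < 0 || mixed_fraction > 1)
    stop("mixed_fraction must be in [0, 1]")
  if (overlay_fraction < 0 || overlay_fraction > 1)
    stop("overlay_fraction must be in [0, 1]")
  if (length(rms_range) != 2L || any(rms_range <= 0) ||
      rms_range[1] > rms_range[2])
    stop("rms_range must be an increasing positive pair")
  structure(list(sample_rate = sample_rate, clip_duration = clip_duration,
                 categories = categories,
                 music_categories = music_categories,
                 speech_categories = speech_categories,
                 clips_per_category = clips_per_category,
                 mixed_fraction = mixed_fraction,
                 overlay_fraction = overlay_fraction,
                 rms_range = rms_range,
                 noise_floor_db = noise_floor_db,
                 channel_eq_db = channel_eq_db,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Music generator settings
#'
#' The music generator is harmonic additive synthesis over a pentatonic
#' scale with a seeded random-walk melody on a fixed beat grid; the melody
#' (and the metric accent pattern) repeats exactly at the phrase scale,
#' which gives the clips controllable temporal structure across the
#' 50 ms--1600 ms range probed by sound quilting.
#'
#' Several parameters accept a *range* (or a choice set for `beat_s`) from
#' which a concrete value is drawn per clip; natural sound categories have
#' large within-category diversity (different pitches, tempi, timbres
#' across recordings), and the generator emulates that by default. Passing
#' a scalar fixes the value.
#'
#' @param beat_s Beat period in seconds: a scalar, or a set of choices (the
#'   defaults all divide the phrase length exactly).
#' @param phrase_s Phrase length in seconds (>= 2 s); must be a multiple of
#'   every beat-period choice.
#' @param root_hz Root frequency of the scale (scalar or range).
#' @param scale_steps Scale degrees in semitones relative to the root;
#'   extended over `octaves` octaves.
#' @param octaves Number of octaves available to the melody.
#' @param n_partials Number of harmonic partials per note (scalar or
#'   integer range, >= 1); partial `h` has amplitude `1/h^a` with the
#'   timbre exponent `a` drawn from `partial_decay`.
#' @param partial_decay Timbre brightness exponent (scalar or range);
#'   larger values give duller notes.
#' @param scales Optional list of scale-step vectors; one scale is drawn
#'   per clip (pentatonic, major, natural minor by default). Set to `NULL`
#'   to always use `scale_steps`.
#' @param contour `"walk"` for a seeded random-walk melody or `"flat"` for a
#'   single repeated pitch.
#' @param accent_period Beats per metric accent.
#' @param decay_frac Note envelope level remaining at the end of a beat
#'   (exponential decay; scalar or range); keeps every 50 ms window
#'   energized.
#' @param percussion Relative level of the percussion layer (scalar or
#'   range; 0 disables): a low drum thump on accented beats and a
#'   high-frequency noise tick on every beat, locked to the beat grid.
#'   Most real music carries percussive broadband energy alongside the
#'   harmonic content.
#' @param vibrato_hz,vibrato_depth Sinusoidal pitch vibrato (depth as a
#'   proportion of the note frequency); used by the `singing` voice.
#' @param formants Optional two-element list of formant center frequencies
#'   in Hz; when set, the summed waveform is passed through Gaussian formant
#'   bumps (the `singing` timbre).
#' @return A list of class `music_params`.
#' @export
music_params <- function(beat_s = c(0.25, 1 / 3, 0.4, 0.5), phrase_s = 2,
                         root_hz = c(160, 320),
                         scale_steps = c(0, 2, 4, 7, 9), octaves = 2,
                         n_partials = c(4, 10), partial_decay = c(0.7, 1.6),
                         scales = list(c(0, 2, 4, 7, 9),
                                       c(0, 2, 4, 5, 7, 9, 11),
                                       c(0, 2, 3, 5, 7, 8, 10)),
                         contour = c("walk", "flat"),
                         accent_period = 4, decay_frac = c(0.15, 0.35),
                         percussion = c(0.2, 0.9),
                         vibrato_hz = 0, vibrato_depth = 0,
                         formants = NULL) {
  contour <- match.arg(contour)
  if (any(beat_s <= 0)) stop("beat_s must be positive")
  if (phrase_s < 2) stop("phrase length must be at least 2 s")
  if (any(abs(phrase_s / beat_s - round(phrase_s / beat_s)) > 1e-9))
    stop("phrase_s must be a multiple of every beat_s choice")
  if (any(n_partials < 1)) stop("n_partials must be at least 1")
  structure(list(beat_s = beat_s, phrase_s = phrase_s, root_hz = root_hz,
                 scale_steps = scale_steps, octaves = octaves,
                 n_partials = n_partials, partial_decay = partial_decay,
                 scales = scales, contour = contour,
                 percussion = percussion,
                 accent_period = accent_period, decay_frac = decay_frac,
                 vibrato_hz = vibrato_hz, vibrato_depth = vibrato_depth,
                 formants = formants),
            class = "music_params")
}

# Shape the spectrum of a waveform with a gain function of frequency (Hz).
fft_shape <- function(x, gain_fn, sample_rate) {
  n <- length(x)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1L) / n * sample_rate
  freqs <- pmin(freqs, sample_rate - freqs)   # fold to [0, sr/2]
  Re(stats::fft(X * gain_fn(freqs), inverse = TRUE)) / n
}

gaussian_band <- function(center, width) {
  function(f) exp(-0.5 * ((f - center) / width)^2)
}

finalize_clip <- function(x, config, target_rms, id) {
  r <- sqrt(mean(x^2))
  if (r == 0) stop("generator produced silence")
  eq <- config$channel_eq_db
  if (!is.null(eq) && eq > 0) {
    co <- stats::runif(3, -eq, eq)
    sr <- config$sample_rate
    x <- fft_shape(x, function(f) {
      l <- 2 * (log1p(f) - log1p(20)) / (log1p(sr / 2) - log1p(20)) - 1
      l <- pmin(1, pmax(-1, l))
      10^((co[1] * l + co[2] * (2 * l^2 - 1) + co[3] * (4 * l^3 - 3 * l)) / 20)
    }, sr)
    r <- sqrt(mean(x^2))
  }
  nf <- config$noise_floor_db
  if (!is.null(nf) && is.finite(nf)) {
    bed <- fft_shape(stats::rnorm(length(x)),
                     function(f) 1 / sqrt(f + 30), config$sample_rate)
    bed <- bed / sqrt(mean(bed^2)) * r * 10^(-nf / 20)
    x <- x + bed
    r <- sqrt(mean(x^2))
  }
  x <- x * (target_rms / r)
  peak <- max(abs(x))
  if (peak > 0.99) x <- x * (0.99 / peak)
  audio_clip(x, config$sample_rate, id = id)
}

#' Generate a synthetic music clip
#'
#' Harmonic note events on a beat grid with a phrase-repeating melodic
#' contour; see [music_params()]. Deterministic given `seed`.
#'
#' @param params A [music_params()] object.
#' @param seed Integer seed for the melody walk and amplitude target.
#' @param config A [synth_config()].
#' @param id Clip identifier.
#' @return An [audio_clip()] of the configured duration.
#' @export
generate_music_clip <- function(params = music_params(), seed = 1L,
                                config = synth_config(), id = "music") {
  stopifnot(inherits(params, "music_params"), inherits(config, "synth_config"))
  with_seed(seed, {
    sr <- config$sample_rate
    dur <- config$clip_duration
    # draw concrete per-clip values from ranges / choice sets
    beat_s <- if (length(params$beat_s) > 1L)
      sample(params$beat_s, 1L) else params$beat_s
    root_hz <- if (length(params$root_hz) > 1L)
      stats::runif(1, params$root_hz[1], params$root_hz[2])
      else params$root_hz
    n_partials <- if (length(params$n_partials) > 1L)
      sample(params$n_partials[1]:params$n_partials[2], 1L)
      else params$n_partials
    decay_frac <- if (length(params$decay_frac) > 1L)
      stats::runif(1, params$decay_frac[1], params$decay_frac[2])
      else params$decay_frac
    alpha <- if (length(params$partial_decay) > 1L)
      stats::runif(1, params$partial_decay[1], params$partial_decay[2])
      else params$partial_decay
    scale_steps <- if (is.null(params$scales)) params$scale_steps
      else params$scales[[sample.int(length(params$scales), 1L)]]
    beat_n <- round(beat_s * sr)
    n_beats <- floor(dur * sr / beat_n)
    phrase_beats <- round(params$phrase_s / beat_s)
    # pitch inventory over the configured octaves
    degrees <- as.vector(outer(scale_steps,
                               12 * (seq_len(params$octaves) - 1L), "+"))
    if (params$contour == "flat") {
      melody_idx <- rep(ceiling(length(degrees) / 2), phrase_beats)
    } else {
      melody_idx <- numeric(phrase_beats)
      pos <- sample.int(length(degrees), 1L)
      for (i in seq_len(phrase_beats)) {
        melody_idx[i] <- pos
        pos <- pos + sample(c(-2L, -1L, 1L, 2L), 1L)
        pos <- min(max(pos, 1L), length(degrees))
      }
    }
    melody_idx <- rep_len(melody_idx, n_beats)
    accents <- rep_len(c(1, rep(0.65, params$accent_period - 1L)), n_beats)
    tau <- beat_s / log(1 / decay_frac)
    t_note <- (seq_len(beat_n) - 1L) / sr
    attack <- pmin(1, t_note / 0.01)
    env <- attack * exp(-t_note / tau)
    x <- numeric(n_beats * beat_n)
    for (i in seq_len(n_beats)) {
      f0 <- root_hz * 2^(degrees[melody_idx[i]] / 12)
      if (params$vibrato_depth > 0) {
        f_inst <- f0 * (1 + params$vibrato_depth *
                          sin(2 * pi * params$vibrato_hz * t_note))
        phase <- 2 * pi * cumsum(f_inst) / sr
      } else {
        phase <- 2 * pi * f0 * t_note
      }
      note <- numeric(beat_n)
      for (h in seq_len(n_partials)) {
        if (h * f0 > sr / 2 * 0.95) break
        note <- note + sin(h * phase) / h^alpha
      }
      idx <- (i - 1L) * beat_n + seq_len(beat_n)
      x[idx] <- x[idx] + accents[i] * env * note
    }
    perc_level <- draw_range(params$percussion)
    if (perc_level > 0) {
      perc <- numeric(length(x))
      thump_f <- stats::runif(1, 70, 140)
      thump_n <- round(0.12 * sr)
      tt <- (seq_len(thump_n) - 1L) / sr
      thump <- sin(2 * pi * thump_f * tt * (1 - 0.3 * tt / 0.12)) *
        exp(-tt / 0.04)
      tick_n <- round(0.03 * sr)
      tick <- fft_shape(stats::rnorm(tick_n),
                        gaussian_band(stats::runif(1, 5000, 8000), 2000), sr)
      tick <- tick / max(abs(tick)) *
        exp(-(seq_len(tick_n) - 1L) / sr / 0.008)
      for (i in seq_len(n_beats)) {
        onset <- (i - 1L) * beat_n + 1L
        if (accents[i] == 1) {
          idx <- onset + seq_len(thump_n) - 1L
          keep <- idx <= length(perc)
          perc[idx[keep]] <- perc[idx[keep]] + thump[keep]
        }
        idx <- onset + seq_len(tick_n) - 1L
        keep <- idx <= length(perc)
        perc[idx[keep]] <- perc[idx[keep]] + 0.5 * tick[keep]
      }
      perc_rms <- sqrt(mean(perc^2))
      if (perc_rms > 0)
        x <- x + perc / perc_rms * sqrt(mean(x^2)) * perc_level
    }
    x <- c(x, numeric(round(dur * sr) - length(x)))
    if (!is.null(params$formants)) {
      f1 <- params$formants[[1]]; f2 <- params$formants[[2]]
      x <- fft_shape(x, function(f) {
        0.15 + gaussian_band(f1, 150)(f) + 0.8 * gaussian_band(f2, 250)(f)
      }, sr)
    }
    finalize_clip(x, config, stats::runif(1, config$rms_range[1],
                                          config$rms_range[2]), id)
  })
}

#' Default settings of the non-music generators
#'
#' @param category One of the non-music categories of the default inventory.
#' @return A list of generator settings; notably `rate` (events per second)
#'   for the impulsive categories and `syllable_rate` for speech.
#' @export
nonmusic_params <- function(category) {
  switch(category,
    speech = list(syllable_rate = c(3, 5.5), voiced_prob = 0.8,
                  f0_range = c(110, 200)),
    water = list(band_hi = c(4000, 8000), tilt = c(0.3, 0.8)),
    wind = list(am_hz = c(0.05, 0.25), am_depth = 0.3,
                cutoff = c(20, 80)),
    barks = list(rate = 2, burst_s = c(0.12, 0.24), f0 = c(100, 200)),
    ticks = list(rate = 8, click_s = 0.006, band_center = c(3000, 6000)),
    machinery = list(f0_range = c(85, 130), am_hz = c(15, 40),
                     n_harmonics = c(5, 10)),
    chirps = list(interval_s = 0.8, sweep_s = c(0.15, 0.4)),
    bells = list(strike_rate = c(0.8, 1.4), f0 = c(200, 550),
                 decay_s = c(0.8, 2)),
    stop("unknown category: ", category)
  )
}

# draw a concrete per-clip value from a scalar or range
draw_range <- function(p) if (length(p) > 1L) stats::runif(1, p[1], p[2]) else p

#' Generate a synthetic non-music clip
#'
#' Category-specific generators: `water` (stationary filtered-noise
#' texture), `wind` (low-frequency noise with slow amplitude modulation),
#' `barks` (jittered impulsive event train of band-limited bursts), `ticks`
#' (high-rate click train), `speech` (syllable-rate amplitude-modulated
#' formant train over a harmonic glottal source), `machinery` (inharmonic
#' hum with fast AM), `chirps` (repeated frequency sweeps), and `bells`
#' (slowly decaying inharmonic strikes at random times -- spectrally
#' music-like, but with no beat grid or phrase repetition). Event onsets are
#' jittered within their grid cells or drawn at random, so no non-music
#' category carries phrase-scale periodic structure.
#'
#' @param category Category name from the inventory (not in the music
#'   subset).
#' @param seed Integer seed.
#' @param config A [synth_config()].
#' @param params Generator settings, defaulting to
#'   [nonmusic_params()]`(category)`.
#' @param id Clip identifier.
#' @return An [audio_clip()].
#' @export
generate_nonmusic_clip <- function(category, seed = 1L,
                                   config = synth_config(),
                                   params = nonmusic_params(category),
                                   id = category) {
  stopifnot(inherits(config, "synth_config"))
  if (!category %in% config$categories)
    stop("unknown category: ", category)
  if (category %in% config$music_categories)
    stop("'", category, "' is in the music subset; use generate_music_clip()")
  with_seed(seed, {
    sr <- config$sample_rate
    n <- round(config$clip_duration * sr)
    t <- (seq_len(n) - 1L) / sr
    x <- switch(category,
      water = {
        hi <- draw_range(params$band_hi)
        tilt <- draw_range(params$tilt)
        z <- stats::rnorm(n)
        fft_shape(z, function(f) {
          edge <- pmin(1, pmax(0, (f - 80) / 60)) *
            pmin(1, pmax(0, (hi - f) / 500))
          edge / (f + 200)^tilt
        }, sr)
      },
      wind = {
        cutoff <- draw_range(params$cutoff)
        am_hz <- draw_range(params$am_hz)
        z <- stats::rnorm(n)
        base <- fft_shape(z, function(f) 1 / (f + cutoff), sr)
        base * (1 + params$am_depth *
                  sin(2 * pi * am_hz * t + stats::runif(1, 0, 2 * pi)))
      },
      barks = {
        n_events <- round(params$rate * config$clip_duration)
        cell <- n / n_events
        burst_n <- round(draw_range(params$burst_s) * sr)
        f0_base <- draw_range(params$f0)
        tb <- (seq_len(burst_n) - 1L) / sr
        env <- (tb / 0.02) * exp(-tb / 0.03)
        env <- env / max(env)
        out <- numeric(n)
        for (i in seq_len(n_events)) {
          onset <- floor((i - 1 + stats::runif(1, 0.15, 0.55)) * cell) + 1L
          f0 <- f0_base * 2^stats::runif(1, -0.15, 0.15)
          growl <- sin(2 * pi * f0 * tb) + 0.5 * sin(2 * pi * 2 * f0 * tb) +
            0.25 * sin(2 * pi * 3 * f0 * tb)
          noise <- fft_shape(stats::rnorm(burst_n),
                             gaussian_band(900, 600), sr)
          noise <- noise / max(abs(noise))
          burst <- env * (0.6 * growl / 1.75 + 0.8 * noise)
          idx <- onset + seq_len(burst_n) - 1L
          keep <- idx <= n
          out[idx[keep]] <- out[idx[keep]] + burst[keep]
        }
        out
      },
      ticks = {
        n_events <- round(params$rate * config$clip_duration)
        cell <- n / n_events
        click_n <- round(params$click_s * sr)
        center <- draw_range(params$band_center)
        tb <- (seq_len(click_n) - 1L) / sr
        env <- exp(-tb / 0.0015)
        out <- numeric(n)
        for (i in seq_len(n_events)) {
          onset <- floor((i - 1 + stats::runif(1, 0.1, 0.5)) * cell) + 1L
          click <- env * fft_shape(stats::rnorm(click_n),
                                   gaussian_band(center, 1500), sr)
          idx <- onset + seq_len(click_n) - 1L
          keep <- idx <= n
          out[idx[keep]] <- out[idx[keep]] + click[keep]
        }
        out
      },
      speech = {
        # syllable durations jitter around the nominal rate: real speech has
        # irregular syllable timing, so the envelope is amplitude-modulated
        # at the syllable rate without long-range periodicity
        base_syl <- sr / draw_range(params$syllable_rate)
        f0_base <- stats::runif(1, params$f0_range[1], params$f0_range[2])
        out <- numeric(n)
        pos <- 1L
        while (pos <= n) {
          syl_n <- max(400L, round(base_syl * stats::runif(1, 0.65, 1.45)))
          ts <- (seq_len(syl_n) - 1L) / sr
          env <- sin(pi * pmin(1, ts / (0.9 * syl_n / sr)))^1.5
          voiced <- stats::runif(1) < params$voiced_prob
          if (voiced) {
            f0 <- f0_base * 2^stats::runif(1, -0.25, 0.25)
            n_h <- floor(4000 / f0)
            syl <- numeric(syl_n)
            for (h in seq_len(n_h)) syl <- syl + sin(2 * pi * h * f0 * ts) / h
            F1 <- stats::runif(1, 300, 900)
            F2 <- stats::runif(1, 1000, 2500)
            syl <- fft_shape(syl, function(f) {
              0.1 + gaussian_band(F1, 120)(f) + 0.7 * gaussian_band(F2, 200)(f)
            }, sr)
          } else {
            syl <- fft_shape(stats::rnorm(syl_n), gaussian_band(3000, 1200), sr)
            syl <- syl * 0.4
          }
          idx <- pos + seq_len(syl_n) - 1L
          keep <- idx <= n
          out[idx[keep]] <- out[idx[keep]] + (env * syl)[keep]
          pos <- pos + syl_n
        }
        out
      },
      machinery = {
        f0 <- stats::runif(1, params$f0_range[1], params$f0_range[2])
        n_h <- if (length(params$n_harmonics) > 1L)
          sample(params$n_harmonics[1]:params$n_harmonics[2], 1L)
          else params$n_harmonics
        am_hz <- draw_range(params$am_hz)
        amps <- stats::runif(n_h, 0.5, 1) / seq_len(n_h)
        out <- numeric(n)
        for (h in seq_len(n_h))
          out <- out + amps[h] * sin(2 * pi * h * f0 * t +
                                       stats::runif(1, 0, 2 * pi))
        out <- out * (1 + 0.25 * sin(2 * pi * am_hz * t))
        hiss <- fft_shape(stats::rnorm(n), function(f) 1 / sqrt(f + 500), sr)
        out + 0.1 * hiss / sqrt(mean(hiss^2)) * sqrt(mean(out^2))
      },
      chirps = {
        n_events <- floor(config$clip_duration / params$interval_s)
        cell <- n / n_events
        sweep_n <- round(draw_range(params$sweep_s) * sr)
        ts <- (seq_len(sweep_n) - 1L) / sr
        env <- sin(pi * ts / (sweep_n / sr))^2
        out <- numeric(n)
        for (i in seq_len(n_events)) {
          onset <- floor((i - 1 + stats::runif(1, 0.1, 0.5)) * cell) + 1L
          f1 <- stats::runif(1, 600, 1200)
          f2 <- f1 * stats::runif(1, 2, 3.5)
          if (stats::runif(1) < 0.5) { tmp <- f1; f1 <- f2; f2 <- tmp }
          f_inst <- f1 + (f2 - f1) * ts / (sweep_n / sr)
          sweep <- env * sin(2 * pi * cumsum(f_inst) / sr)
          idx <- onset + seq_len(sweep_n) - 1L
          keep <- idx <= n
          out[idx[keep]] <- out[idx[keep]] + sweep[keep]
        }
        out
      },
      bells = {
        # inharmonic partial stacks with long decays, struck at random
        # (non-grid) times; partial ratios typical of struck idiophones
        n_strikes <- round(draw_range(params$strike_rate) *
                             config$clip_duration)
        f0_base <- draw_range(params$f0)
        ratios <- c(1, 2.76, 5.40, 8.93) * 2^stats::runif(4, -0.03, 0.03)
        onsets <- sort(stats::runif(n_strikes, 0, 0.92)) * n
        out <- numeric(n)
        for (i in seq_len(n_strikes)) {
          decay <- draw_range(params$decay_s)
          strike_n <- min(round(2.5 * decay * sr), n)
          tb <- (seq_len(strike_n) - 1L) / sr
          f0 <- f0_base * 2^stats::runif(1, -0.3, 0.3)
          strike <- numeric(strike_n)
          for (k in seq_along(ratios)) {
            if (ratios[k] * f0 > sr / 2 * 0.9) break
            strike <- strike + sin(2 * pi * ratios[k] * f0 * tb +
                                     stats::runif(1, 0, 2 * pi)) *
              exp(-tb / (decay / k)) / k
          }
          strike <- strike * pmin(1, tb / 0.003)
          idx <- floor(onsets[i]) + seq_len(strike_n)
          keep <- idx <= n
          out[idx[keep]] <- out[idx[keep]] + strike[keep]
        }
        out
      },
      stop("unknown category: ", category)
    )
    finalize_clip(x, config, stats::runif(1, config$rms_range[1],
                                          config$rms_range[2]), id)
  })
}

assign_group <- function(label_list, music_categories) {
  vapply(label_list, function(labs) {
    n_music <- sum(labs %in% music_categories)
    if (n_music == length(labs)) "music"
    else if (n_music == 0L) "non-music"
    else "mixed"
  }, character(1))
}

#' Split a semicolon-joined label string into a label set
#' @param labels Character vector of `;`-joined labels.
#' @return A list of character vectors.
#' @export
split_labels <- function(labels) strsplit(labels, ";", fixed = TRUE)

#' Generate a labeled synthetic dataset
#'
#' Produces `clips_per_category` label appearances per category. A fraction
#' `mixed_fraction` of the clips are mixed: one music-subset event and one
#' non-music event overlaid at equal RMS before the final amplitude
#' normalization, labeled with both categories. A further
#' `overlay_fraction` of the clips overlay two distinct non-music events
#' the same way (multi-label rows of group `non-music`). Every clip is assigned to a
#' train or test split, 50/50 and stratified by category (disjoint by
#' `clip_id`). Identical configurations (including the seed) produce
#' bit-identical datasets.
#'
#' @param config A [synth_config()].
#' @param dir Output directory for WAV files and the manifest (CSV and
#'   JSON); when `NULL` (default) the clips are kept in memory.
#' @return An object of class `sound_dataset`: a list with `manifest` (a
#'   data frame with columns `clip_id`, `path`, `labels` (semicolon-joined),
#'   `group`, `rms`, `split`, `clip_seed`), `clips` (named list of
#'   [audio_clip()]s, or `NULL` when written to disk), and `config`.
#' @export
generate_dataset <- function(config = synth_config(), dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  n_total <- length(config$categories) * config$clips_per_category
  n_mixed <- round(config$mixed_fraction * n_total)
  n_overlay <- round(config$overlay_fraction * n_total)
  nm_cats <- setdiff(config$categories, config$music_categories)
  if ((n_mixed > 0L || n_overlay > 0L) && length(nm_cats) == 0L)
    stop("mixed/overlay clips require at least one non-music category")
  if (n_overlay > 0L && length(nm_cats) < 2L)
    stop("overlay clips require at least two non-music categories")
  # Mixed clips consume one appearance from a music category and one from a
  # non-music category; overlay clips consume two non-music appearances.
  # Both are distributed as evenly as possible.
  mix_music <- rep_len(config$music_categories, n_mixed)
  mix_nonmusic <- rep_len(nm_cats, n_mixed)
  m <- length(nm_cats)
  ov_a <- ov_b <- character(n_overlay)
  for (i in seq_len(n_overlay)) {
    a <- (i - 1L) %% m
    off <- 1L + ((i - 1L) %/% m) %% (m - 1L)
    ov_a[i] <- nm_cats[a + 1L]
    ov_b[i] <- nm_cats[(a + off) %% m + 1L]
  }
  appearances <- table(factor(c(mix_music, mix_nonmusic, ov_a, ov_b),
                              levels = config$categories))
  pure_counts <- config$clips_per_category - as.integer(appearances)
  names(pure_counts) <- config$categories
  if (any(pure_counts < 0L))
    stop("mixed/overlay fractions too large: more label appearances ",
         "consumed than clips_per_category provides")
  if (any(pure_counts < 2L))
    warning("fewer than 2 pure clips remain for some category; ",
            "selectivity analyses need at least 2 per split")
  rows <- list(); clips <- list()
  clip_seeds <- with_seed(config$seed,
                          sample.int(.Machine$integer.max - 1L,
                                     n_total + n_mixed + n_overlay))
  k <- 0L
  gen_one <- function(category, seed, id) {
    if (category %in% config$music_categories) {
      if (category == "singing")
        generate_music_clip(music_params(n_partials = 10, vibrato_hz = 5.5,
                                         vibrato_depth = 0.012,
                                         formants = list(600, 1600)),
                            seed, config, id = id)
      else generate_music_clip(music_params(), seed, config, id = id)
    } else {
      generate_nonmusic_clip(category, seed, config, id = id)
    }
  }
  for (cat in config$categories) {
    for (i in seq_len(pure_counts[[cat]])) {
      k <- k + 1L
      id <- sprintf("%s_%03d", cat, i)
      clip <- gen_one(cat, clip_seeds[k], id)
      rows[[length(rows) + 1L]] <- data.frame(
        clip_id = id, path = NA_character_, labels = cat,
        group = NA_character_, rms = rms(clip), split = NA_character_,
        clip_seed = clip_seeds[k], stringsAsFactors = FALSE)
      clips[[id]] <- clip
    }
  }
  for (i in seq_len(n_mixed)) {
    k <- k + 1L
    id <- sprintf("mixed_%03d", i)
    mcat <- mix_music[i]; ncat <- mix_nonmusic[i]
    m_clip <- gen_one(mcat, clip_seeds[k], id)
    nm_clip <- gen_one(ncat, clip_seeds[k] + 1L, id)
    # overlay at equal RMS, then renormalize to the music clip's target;
    # finalization draws (EQ, noise bed) from the clip's own seeded stream
    nm_clip <- normalize_rms(nm_clip, rms(m_clip))
    mix <- m_clip$samples + nm_clip$samples
    clip <- with_seed(clip_seeds[k] + 2L,
                      finalize_clip(mix, config, rms(m_clip), id))
    rows[[length(rows) + 1L]] <- data.frame(
      clip_id = id, path = NA_character_,
      labels = paste(mcat, ncat, sep = ";"), group = NA_character_,
      rms = rms(clip), split = NA_character_, clip_seed = clip_seeds[k],
      stringsAsFactors = FALSE)
    clips[[id]] <- clip
  }
  for (i in seq_len(n_overlay)) {
    k <- k + 1L
    id <- sprintf("multi_%03d", i)
    a_clip <- gen_one(ov_a[i], clip_seeds[k], id)
    b_clip <- gen_one(ov_b[i], clip_seeds[k] + 1L, id)
    b_clip <- normalize_rms(b_clip, rms(a_clip))
    clip <- with_seed(clip_seeds[k] + 2L,
                      finalize_clip(a_clip$samples + b_clip$samples, config,
                                    rms(a_clip), id))
    rows[[length(rows) + 1L]] <- data.frame(
      clip_id = id, path = NA_character_,
      labels = paste(ov_a[i], ov_b[i], sep = ";"), group = NA_character_,
      rms = rms(clip), split = NA_character_, clip_seed = clip_seeds[k],
      stringsAsFactors = FALSE)
    clips[[id]] <- clip
  }
  manifest <- do.call(rbind, rows)
  manifest$group <- assign_group(split_labels(manifest$labels),
                                 config$music_categories)
  # stratified 50/50 split, disjoint by clip id
  strata <- ifelse(manifest$group == "mixed", "mixed",
                   vapply(split_labels(manifest$labels), `[`, "", 1L))
  manifest$split <- NA_character_
  with_seed(config$seed + 1L, {
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      n_train <- ceiling(length(idx) / 2)
      manifest$split[idx[seq_len(n_train)]] <- "train"
      manifest$split[idx[-seq_len(n_train)]] <- "test"
    }
  })
  dataset <- structure(list(manifest = manifest, clips = clips,
                            config = config),
                       class = "sound_dataset")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(nrow(manifest))) {
      p <- file.path(dir, paste0(manifest$clip_id[i], ".wav"))
      ok <- tryCatch(write_wav(clips[[manifest$clip_id[i]]], p),
                     error = function(e)
                       stop("failed to write ", p, ": ", conditionMessage(e)))
      dataset$manifest$path[i] <- p
    }
    write_manifest(dataset$manifest, file.path(dir, "manifest.csv"))
    jsonlite::write_json(dataset$manifest,
                         file.path(dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  dataset
}

#' @export
print.sound_dataset <- function(x, ...) {
  cat(sprintf("<sound_dataset: %d clips (%s)>\n", nrow(x$manifest),
              paste(sprintf("%s: %d", names(table(x$manifest$group)),
                            table(x$manifest$group)), collapse = ", ")))
  invisible(x)
}

#' Write or read a clip manifest as CSV
#' @param manifest Manifest data frame.
#' @param path CSV file path.
#' @return `path` (write) or the manifest data frame (read).
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Randomize the label assignments of a manifest
#'
#' Permutes the label sets across clips (a uniform random permutation), so
#' the multiset of label sets is preserved while the association between
#' audio content and labels is destroyed -- the memorization control. The
#' `group` column is recomputed from the permuted labels.
#'
#' @param x A `sound_dataset` or a manifest data frame.
#' @param seed Integer seed; the same seed yields the same permutation.
#' @param split Optional split name (e.g. `"train"`) to restrict the
#'   permutation to; labels in other splits are untouched.
#' @param music_categories Music subset used to recompute `group`; taken
#'   from the dataset config when `x` is a `sound_dataset`.
#' @return An object of the same type as `x` with permuted labels.
#' @export
randomize_labels <- function(x, seed = 1L, split = NULL,
                             music_categories = c("music", "singing")) {
  is_dataset <- inherits(x, "sound_dataset")
  manifest <- if (is_dataset) x$manifest else x
  if (nrow(manifest) == 0L) stop("empty manifest")
  if (is_dataset) music_categories <- x$config$music_categories
  rows <- if (is.null(split)) seq_len(nrow(manifest))
          else which(manifest$split == split)
  perm <- with_seed(seed, sample(length(rows)))
  manifest$labels[rows] <- manifest$labels[rows][perm]
  manifest$group[rows] <- assign_group(split_labels(manifest$labels[rows]),
                                       music_categories)
  if (is_dataset) { x$manifest <- manifest; x } else manifest
}

#' Drop training clips carrying given labels
#'
#' Removes from the chosen split every clip whose label set intersects
#' `labels` -- the "trained without music" (or "without speech") condition.
#' Other splits are untouched.
#'
#' @param dataset A `sound_dataset`.
#' @param labels Character vector of labels to exclude.
#' @param split Split to filter (default `"train"`).
#' @return The filtered `sound_dataset`.
#' @export
exclude_labels <- function(dataset, labels, split = "train") {
  stopifnot(inherits(dataset, "sound_dataset"))
  hit <- vapply(split_labels(dataset$manifest$labels),
                function(l) any(l %in% labels), logical(1))
  drop <- hit & dataset$manifest$split == split
  dataset$manifest <- dataset$manifest[!drop, , drop = FALSE]
  dataset$clips <- dataset$clips[dataset$manifest$clip_id]
  dataset
}

#' Frame-level RMS envelope of a clip
#'
#' @param clip An [audio_clip()].
#' @param frame_s Frame length in seconds (default 50 ms, the shortest
#'   quilting segment).
#' @return Numeric vector of per-frame RMS values.
#' @export
clip_envelope <- function(clip, frame_s = 0.05) {
  stopifnot(inherits(clip, "audio_clip"))
  fn <- round(frame_s * clip$sample_rate)
  n_frames <- floor(length(clip$samples) / fn)
  x <- clip$samples[seq_len(n_frames * fn)]
  dim(x) <- c(fn, n_frames)
  sqrt(colMeans(x^2))
}

#' Normalized envelope autocorrelation at a lag
#'
#' Pearson correlation between the envelope and its copy shifted by
#' `lag` frames; the long-range structure statistic used to separate music
#' (phrase repetition) from the other categories.
#'
#' @param env Envelope vector (e.g. from [clip_envelope()]).
#' @param lag Lag in frames.
#' @return Correlation in `[-1, 1]`.
#' @export
envelope_autocorr <- function(env, lag) {
  n <- length(env)
  if (lag <= 0 || lag >= n - 2) stop("lag out of range")
  stats::cor(env[seq_len(n - lag)], env[(lag + 1):n])
}

#' Long-range structure index of a clip
#'
#' Envelope autocorrelation at the phrase lag; high for phrase-repeating
#' music, low for aperiodic or jittered sound, and destroyed by short-
#' segment quilting.
#'
#' @param clip An [audio_clip()].
#' @param phrase_s Phrase length in seconds.
#' @param frame_s Envelope frame in seconds.
#' @return Correlation in `[-1, 1]`.
#' @export
long_range_index <- function(clip, phrase_s = 2, frame_s = 0.05) {
  env <- clip_envelope(clip, frame_s)
  envelope_autocorr(env, round(phrase_s / frame_s))
}
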