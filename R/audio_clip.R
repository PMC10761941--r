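#' Construct an audio clip
#'
#' An `audio_clip` is the universal carrier of sound in this package: a mono
#' waveform stored as a numeric vector in `[-1, 1]` together with its sample
#' rate and an optional clip identifier.
#'
#' @param samples Numeric vector of waveform samples.
#' @param sample_rate Sampling rate in Hz (default 22050).
#' @param id Optional clip identifier (character scalar).
#' @return An object of class `audio_clip`.
#' @examples
#' t <- seq(0, 1, length.out = 22050)
#' clip <- audio_clip(sin(2 * pi * 440 * t), 22050, id = "a440")
#' clip_duration(clip)
#' @export
audio_clip <- function(samples, sample_rate = 22050L, id = NULL) {
  if (!is.numeric(samples)) stop("'samples' must be numeric")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("'sample_rate' must be a single positive number")
  structure(
    list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate),
         id = if (is.null(id)) NA_character_ else as.character(id)),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip %s: %.3f s @ %g Hz, rms = %.4g>\n",
              x$id, clip_duration(x), x$sample_rate, rms(x)))
  invisible(x)
}

#' Duration of a clip in seconds
#' @param clip An `audio_clip`.
#' @return Duration in seconds.
#' @export
clip_duration <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  length(clip$samples) / clip$sample_rate
}

#' Resample a clip by linear interpolation
#'
#' Simple linear-interpolation resampler used to bring external material to
#' the pipeline's working rate. Adequate for the band-limited synthetic
#' stimuli used here; not an anti-aliased polyphase resampler.
#'
#' @param clip An `audio_clip`.
#' @param sample_rate Target rate in Hz.
#' @return An `audio_clip` at the target rate.
#' @export
resample_clip <- function(clip, sample_rate) {
  stopifnot(inherits(clip, "audio_clip"))
  if (clip$sample_rate == sample_rate) return(clip)
  n_out <- round(length(clip$samples) * sample_rate / clip$sample_rate)
  t_in <- seq(0, 1, length.out = length(clip$samples))
  t_out <- seq(0, 1, length.out = n_out)
  audio_clip(stats::approx(t_in, clip$samples, xout = t_out)$y,
             sample_rate, id = clip$id)
}
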