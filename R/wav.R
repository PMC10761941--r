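# Minimal RIFF/WAVE I/O (16-bit PCM, mono). Implemented here because no
# installed package provides WAV reading/writing; the format subset is fixed
# by the dataset contract (mono PCM16).

#' Write a clip as a 16-bit PCM mono WAV file
#'
#' Samples are clamped to `[-1, 1]` and quantized to signed 16-bit integers.
#'
#' @param clip An [audio_clip()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- pmin(1, pmax(-1, clip$samples))
  pcm <- as.integer(round(x * 32767))
  sr <- as.integer(round(clip$sample_rate))
  n <- length(pcm)
  data_bytes <- 2L * n
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")      # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path Path to a RIFF/WAVE file written by [write_wav()] or any
#'   conforming 16-bit PCM mono writer.
#' @param id Clip id to attach; defaults to the file name without extension.
#' @return An [audio_clip()] with samples in `[-1, 1]`.
#' @export
read_wav <- function(path, id = NULL) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  riff <- readChar(con, 4)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path)
  sr <- NULL; n_channels <- NULL; bits <- NULL; samples <- NULL
  repeat {
    tag <- readChar(con, 4)
    if (length(tag) == 0L || nchar(tag) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(tag, "fmt ")) {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      n_channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt != 1L) stop("only PCM WAV is supported (fmt = ", fmt, ")")
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (identical(tag, "data")) {
      samples <- readBin(con, "integer", size / 2L, size = 2,
                         endian = "little", signed = TRUE)
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  if (is.null(sr) || is.null(samples)) stop("malformed WAV file: ", path)
  if (n_channels != 1L) stop("only mono WAV is supported")
  if (bits != 16L) stop("only 16-bit PCM WAV is supported")
  if (is.null(id)) id <- sub("\\.wav$", "", basename(path), ignore.case = TRUE)
  audio_clip(samples / 32767, sr, id = id)
}
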