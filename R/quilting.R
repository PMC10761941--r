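# Sound quilting: a source clip is cut into equal segments which are
# reordered so that the segment-to-segment change in the log-Mel
# spectrogram of the quilt tracks that of the original; junctions are
# phase-aligned and cross-faded. Short-timescale structure (within a
# segment) is preserved while long-timescale structure (melodic phrases,
# metric organization) is destroyed, increasingly so for shorter segments.

#' Cut a clip into equal-length segments
#'
#' @param clip An [audio_clip()].
#' @param segment_ms Segment length in milliseconds.
#' @return A list of class `clip_segments`: `segments` (list of sample
#'   vectors), `segment_ms`, `segment_n` (samples per segment) and the
#'   sample rate. The trailing remainder shorter than one segment is
#'   discarded.
#' @export
segment_clip <- function(clip, segment_ms) {
  stopifnot(inherits(clip, "audio_clip"))
  seg_n <- round(segment_ms / 1000 * clip$sample_rate)
  n_seg <- floor(length(clip$samples) / seg_n)
  if (n_seg < 2L)
    stop("clip too short: need at least 2 segments of ", segment_ms, " ms")
  segments <- lapply(seq_len(n_seg), function(i)
    clip$samples[((i - 1L) * seg_n + 1L):(i * seg_n)])
  structure(list(segments = segments, segment_ms = segment_ms,
                 segment_n = seg_n, sample_rate = clip$sample_rate,
                 clip_id = clip$id),
            class = "clip_segments")
}

# Edge feature vectors of each segment in the original log-Mel spectrogram:
# the first and last frame fully inside the segment.
segment_edges <- function(segs, spec) {
  hop <- spec$config$hop
  win <- spec$config$window
  n_frames <- ncol(spec$values)
  first_frame <- function(start_sample) {
    f <- ceiling((start_sample - 1) / hop) + 1L
    min(max(f, 1L), n_frames)
  }
  last_frame <- function(end_sample) {
    f <- floor((end_sample - win) / hop) + 1L
    min(max(f, 1L), n_frames)
  }
  n <- length(segs$segments)
  starts <- (seq_len(n) - 1L) * segs$segment_n + 1L
  ends <- seq_len(n) * segs$segment_n
  list(e_in = lapply(starts, function(s) spec$values[, first_frame(s)]),
       e_out = lapply(ends, function(e) spec$values[, last_frame(e)]))
}

#' Plan a quilt: choose a segment reordering
#'
#' Greedy boundary matching: starting from a seeded random segment, each
#' step appends the unused segment whose junction change (entry-edge log-Mel
#' vector minus the current segment's exit edge) is closest, in squared
#' Euclidean norm, to the original sound's segment-to-segment change at that
#' position. The segment that originally followed the current one is
#' excluded from the candidates (while other candidates remain), which
#' forces a genuine reordering; with two segments the only non-identity
#' permutation is returned. The summed matching cost is recorded.
#'
#' @param segs A [segment_clip()] result.
#' @param spec The log-Mel spectrogram of the *original* clip.
#' @param seed Integer seed for the starting segment.
#' @return A list of class `quilt_plan`: `order` (a permutation of segment
#'   indices, never the identity for 3+ segments), `cost`, `segment_ms`,
#'   `seed`.
#' @export
plan_quilt <- function(segs, spec, seed = 1L) {
  stopifnot(inherits(segs, "clip_segments"), inherits(spec, "log_mel"))
  n <- length(segs$segments)
  if (n < 2L) stop("need at least 2 segments")
  if (n == 2L)
    return(structure(list(order = c(2L, 1L), cost = 0, n_segments = 2L,
                          segment_ms = segs$segment_ms, seed = seed,
                          clip_id = segs$clip_id),
                     class = "quilt_plan"))
  edges <- segment_edges(segs, spec)
  d_orig <- lapply(seq_len(n - 1L), function(i)
    edges$e_in[[i + 1L]] - edges$e_out[[i]])
  order_out <- integer(n)
  used <- logical(n)
  cur <- with_seed(seed, sample.int(n, 1L))
  order_out[1L] <- cur; used[cur] <- TRUE
  cost <- 0
  for (t in seq_len(n - 1L)) {
    cands <- which(!used)
    succ <- if (cur < n) cur + 1L else 0L  # original successor
    if (succ %in% cands && length(cands) > 1L)
      cands <- setdiff(cands, succ)
    costs <- vapply(cands, function(b) {
      sum(((edges$e_in[[b]] - edges$e_out[[cur]]) - d_orig[[t]])^2)
    }, numeric(1))
    best <- cands[which.min(costs)]  # ties: lowest index
    cost <- cost + min(costs)
    order_out[t + 1L] <- best; used[best] <- TRUE
    cur <- best
  }
  structure(list(order = order_out, cost = cost, n_segments = n,
                 segment_ms = segs$segment_ms, seed = seed,
                 clip_id = segs$clip_id),
            class = "quilt_plan")
}

#' Render a quilt from a plan
#'
#' Concatenates the segments in plan order. At each junction the start of
#' the incoming segment is phase-aligned by searching the best
#' cross-correlation lag within `align_ms`, and the joint is smoothed with
#' an equal-power cross-fade of `junction_ms` (both zero disable the
#' processing and give plain concatenation). The windows are kept short --
#' 2 ms by default, well under the shortest 50 ms segment -- because the
#' junction processing exists to minimize boundary artifacts, not to blur
#' segment content. The content is then cut to
#' `content_s` seconds and zero-padded to `duration_s`, so every quilt is a
#' fixed-length clip with a fixed amount of sound content.
#'
#' @param segs A [segment_clip()] result.
#' @param plan A [plan_quilt()] result for the same segmentation.
#' @param junction_ms Cross-fade length in milliseconds.
#' @param align_ms Maximum phase-alignment lag in milliseconds.
#' @param content_s Sound content length in seconds (default 8).
#' @param duration_s Total output duration in seconds (default 10; the tail
#'   is exactly zero).
#' @return An [audio_clip()].
#' @export
render_quilt <- function(segs, plan, junction_ms = 2, align_ms = 5,
                         content_s = 8, duration_s = 10) {
  stopifnot(inherits(segs, "clip_segments"), inherits(plan, "quilt_plan"))
  if (plan$n_segments != length(segs$segments) ||
      !setequal(plan$order, seq_along(segs$segments)))
    stop("plan does not match the segmentation")
  sr <- segs$sample_rate
  w <- round(junction_ms / 1000 * sr)
  max_lag <- round(align_ms / 1000 * sr)
  out <- segs$segments[[plan$order[1L]]]
  for (i in seq_along(plan$order)[-1L]) {
    nxt <- segs$segments[[plan$order[i]]]
    if (w > 0 && length(out) > w && length(nxt) > w + max_lag) {
      tail_w <- out[(length(out) - w + 1L):length(out)]
      # pick the entry lag into the next segment with maximal correlation
      lags <- 0:max_lag
      score <- vapply(lags, function(l)
        sum(tail_w * nxt[(l + 1L):(l + w)]), numeric(1))
      l <- lags[which.max(score)]
      head_w <- nxt[(l + 1L):(l + w)]
      fade <- seq(0, 1, length.out = w)
      joint <- tail_w * sqrt(1 - fade) + head_w * sqrt(fade)
      out <- c(out[seq_len(length(out) - w)], joint,
               nxt[(l + w + 1L):length(nxt)])
    } else {
      out <- c(out, nxt)
    }
  }
  n_content <- round(content_s * sr)
  n_total <- round(duration_s * sr)
  if (length(out) >= n_content) out <- out[seq_len(n_content)]
  out <- c(out, numeric(n_total - length(out)))
  audio_clip(out, sr, id = paste0(segs$clip_id, "_quilt",
                                  segs$segment_ms, "ms"))
}

#' Quilt a clip end to end
#'
#' Convenience wrapper: segment, plan against the clip's own log-Mel
#' spectrogram, render.
#'
#' @param clip An [audio_clip()].
#' @param segment_ms Segment length in milliseconds.
#' @param seed Integer seed for the plan.
#' @param frontend A [frontend_config()].
#' @param ... Passed to [render_quilt()].
#' @return An [audio_clip()].
#' @export
quilt_clip <- function(clip, segment_ms, seed = 1L,
                       frontend = frontend_config(), ...) {
  segs <- segment_clip(clip, segment_ms)
  plan <- plan_quilt(segs, to_log_mel(clip, frontend), seed = seed)
  render_quilt(segs, plan, ...)
}

#' Unit-group response versus quilt segment length
#'
#' For each segment length, renders one quilt per source clip, records the
#' mean response of the unit group, and normalizes by the mean group
#' response to the original sounds (so the original condition is exactly 1).
#' For comparability with the fixed-content quilts, the originals are also
#' truncated to the quilts' content length and zero-padded.
#'
#' @param model A `tagger_model`.
#' @param group A `unit_group` (identified on data independent of the
#'   quilting sources).
#' @param sources List of [audio_clip()]s to quilt (e.g. music clips from
#'   the split not used to identify the group).
#' @param segment_lengths Segment lengths in ms (default the octave range
#'   50--1600).
#' @param seed Integer seed; source `i` at each length uses `seed + i`.
#' @param frontend A [frontend_config()].
#' @param time_pool Time-pooling factor matching the model's inputs.
#' @param which Weight set, as in [extract_features()].
#' @param content_s,duration_s Quilt content and total durations.
#' @return Data frame of class `quilt_curve`: rows for each segment length
#'   plus an `original` row, with columns `segment_ms` (`NA` for the
#'   original), `response` (normalized mean), `sd` (dispersion over
#'   sources).
#' @export
quilt_response_curve <- function(model, group, sources,
                                 segment_lengths = c(50, 100, 200, 400, 800,
                                                     1600),
                                 seed = 1L, frontend = frontend_config(),
                                 time_pool = 1L, which = "best",
                                 content_s = 8, duration_s = 10) {
  stopifnot(inherits(model, "tagger_model"), length(sources) > 0L)
  group_mean <- function(clips) {
    x <- stack_spectrograms(lapply(clips, to_log_mel, config = frontend),
                            time_pool = time_pool)
    feats <- extract_features(model, x, which = which)
    rowMeans(feats[, group, drop = FALSE])
  }
  originals <- lapply(sources, function(cl) {
    n_content <- round(content_s * cl$sample_rate)
    n_total <- round(duration_s * cl$sample_rate)
    x <- cl$samples[seq_len(min(n_content, length(cl$samples)))]
    audio_clip(c(x, numeric(n_total - length(x))), cl$sample_rate, cl$id)
  })
  orig_resp <- group_mean(originals)
  base <- mean(orig_resp)
  rows <- lapply(segment_lengths, function(ms) {
    quilts <- lapply(seq_along(sources), function(i)
      quilt_clip(sources[[i]], ms, seed = seed + i, frontend = frontend,
                 content_s = content_s, duration_s = duration_s))
    r <- group_mean(quilts) / base
    data.frame(segment_ms = ms, response = mean(r), sd = stats::sd(r))
  })
  out <- rbind(do.call(rbind, rows),
               data.frame(segment_ms = NA_real_,
                          response = mean(orig_resp / base),
                          sd = stats::sd(orig_resp / base)))
  class(out) <- c("quilt_curve", "data.frame")
  out
}
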