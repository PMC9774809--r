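#' Construct a video prediction stream
#'
#' A video stream holds per-frame class-posterior vectors over the
#' procedural phases, sampled at a fixed frame rate. Time is continuous in
#' seconds from procedure start; frames are instants at `t = t0, t0 + 1/fps,
#' ...` and each frame is taken to occupy the `1/fps` seconds starting at
#' its timestamp.
#'
#' @param probs Numeric matrix, one row per frame, one column per procedural
#'   phase (column names, if present, must equal `phase_set$phases` in
#'   order). Rows must be probability vectors; rows within `1e-9` of unit
#'   mass are renormalized on ingest.
#' @param fps Frames per second (> 0).
#' @param timestamps Optional frame times in seconds; defaults to a regular
#'   grid `t0 + (0:(n-1))/fps`. Must be strictly increasing with spacing
#'   `1/fps` within `1e-6`.
#' @param t0 Start time of the first frame when `timestamps` is omitted.
#' @param phase_set A [phase_set()].
#' @return An object of class `video_stream` with fields `fps`,
#'   `timestamps`, `probs` and `phase_set`.
#' @seealso [audio_stream()], [validate_stream()]
#' @export
video_stream <- function(probs, fps, timestamps = NULL, t0 = 0,
                         phase_set = surgflow::phase_set()) {
  probs <- as.matrix(probs)
  if (is.null(timestamps))
    timestamps <- t0 + (seq_len(nrow(probs)) - 1L) / fps
  colnames(probs) <- phase_set$phases
  x <- structure(list(fps = fps, timestamps = as.numeric(timestamps),
                      probs = probs, phase_set = phase_set),
                 class = "video_stream")
  validate_stream(x)
}

#' Construct a speech (audio) prediction stream
#'
#' A speech stream holds class-posterior vectors for speech fragments:
#' half-open time intervals `[start, end)` obtained by cutting the audio at
#' silences. Each vector spans the procedural phases plus, as its last
#' entry, the pseudo-phase that absorbs off-task speech.
#'
#' @param start,end Fragment interval bounds in seconds (`start < end`);
#'   fragments must be sorted by start and pairwise non-overlapping.
#' @param probs Numeric matrix, one row per fragment, `n_phases + 1`
#'   columns (pseudo-phase last). Rows within `1e-9` of unit mass are
#'   renormalized on ingest.
#' @param phase_set A [phase_set()].
#' @return An object of class `audio_stream` with fields `start`, `end`,
#'   `probs` and `phase_set`. Zero fragments is allowed (silent procedure).
#' @export
audio_stream <- function(start, end, probs, phase_set = surgflow::phase_set()) {
  probs <- as.matrix(probs)
  if (length(start) == 0L && nrow(probs) == 0L)
    probs <- matrix(numeric(0), 0L, n_phases(phase_set) + 1L)
  colnames(probs) <- c(phase_set$phases, phase_set$pseudo_phase)
  x <- structure(list(start = as.numeric(start), end = as.numeric(end),
                      probs = probs, phase_set = phase_set),
                 class = "audio_stream")
  validate_stream(x)
}

#' Validate a prediction stream
#'
#' Checks every structural invariant of a stream and returns it unchanged if
#' all hold; otherwise stops with a message naming the first violated
#' invariant and the offending frame/fragment index.
#'
#' For video streams: `fps > 0`, strictly increasing timestamps with
#' inter-frame spacing `1/fps` within `1e-6`, probability rows of unit mass
#' within `1e-9` over the procedural phases. For audio streams: `start <
#' end` per fragment, fragments sorted and pairwise non-overlapping
#' (fragment `k` must end at or before fragment `k+1` starts), probability
#' rows over phases plus pseudo-phase.
#'
#' @param stream A `video_stream` or `audio_stream`.
#' @return The validated stream, invisibly usable in pipelines.
#' @export
validate_stream <- function(stream) UseMethod("validate_stream")

#' @export
validate_stream.video_stream <- function(stream) {
  if (!is.numeric(stream$fps) || length(stream$fps) != 1L || stream$fps <= 0)
    stop("video stream: fps must be a single positive number")
  n <- nrow(stream$probs)
  if (length(stream$timestamps) != n)
    stop("video stream: ", length(stream$timestamps), " timestamps for ",
         n, " probability rows")
  if (ncol(stream$probs) != n_phases(stream$phase_set))
    stop("video stream: expected ", n_phases(stream$phase_set),
         " phase columns, got ", ncol(stream$probs))
  if (n > 0L) {
    if (any(stream$timestamps < 0))
      stop("video stream: negative timestamp at frame ",
           which(stream$timestamps < 0)[1L])
    if (n > 1L) {
      d <- diff(stream$timestamps)
      if (any(d <= 0))
        stop("video stream: non-increasing timestamp at frame ",
             which(d <= 0)[1L] + 1L)
      off <- which(abs(d - 1 / stream$fps) > 1e-6)
      if (length(off))
        stop("video stream: frame spacing ", format(d[off[1L]], digits = 8),
             " at frame ", off[1L] + 1L, " != 1/fps = ",
             format(1 / stream$fps, digits = 8))
    }
    stream$probs <- normalize_probs(stream$probs, what = "video stream")
  }
  stream
}

#' @export
validate_stream.audio_stream <- function(stream) {
  k <- length(stream$start)
  if (length(stream$end) != k || nrow(stream$probs) != k)
    stop("audio stream: start/end/probs lengths differ")
  if (ncol(stream$probs) != n_phases(stream$phase_set) + 1L)
    stop("audio stream: expected ", n_phases(stream$phase_set) + 1L,
         " class columns (phases + pseudo), got ", ncol(stream$probs))
  if (k > 0L) {
    if (any(stream$start < 0))
      stop("audio stream: negative start at fragment ",
           which(stream$start < 0)[1L])
    bad <- which(stream$start >= stream$end)
    if (length(bad))
      stop("audio stream: empty or inverted interval at fragment ", bad[1L])
    if (k > 1L) {
      if (any(diff(stream$start) < 0))
        stop("audio stream: fragments not sorted by start at fragment ",
             which(diff(stream$start) < 0)[1L] + 1L)
      ov <- which(stream$end[-k] > stream$start[-1L] + 1e-12)
      if (length(ov))
        stop("audio stream: overlap at fragment ", ov[1L] + 1L)
    }
    stream$probs <- normalize_probs(stream$probs, what = "audio stream")
  }
  stream
}

#' @export
print.video_stream <- function(x, ...) {
  n <- nrow(x$probs)
  cat("Video prediction stream: ", n, " frames at ", x$fps, " fps",
      if (n) sprintf(" (t = %.3f .. %.3f s)", x$timestamps[1L],
                     x$timestamps[n]), "\n", sep = "")
  invisible(x)
}

#' @export
print.audio_stream <- function(x, ...) {
  k <- length(x$start)
  cat("Speech prediction stream: ", k, " fragments",
      if (k) sprintf(" (%.3f .. %.3f s, %.1f s speech)", x$start[1L],
                     x$end[k], sum(x$end - x$start)), "\n", sep = "")
  invisible(x)
}

#' Number of frames or fragments in a stream
#' @param stream A `video_stream` or `audio_stream`.
#' @return Integer count.
#' @export
stream_length <- function(stream) {
  if (inherits(stream, "video_stream")) return(nrow(stream$probs))
  if (inherits(stream, "audio_stream")) return(length(stream$start))
  stop("not a stream")
}
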