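#' Fusion configuration
#'
#' Controls the late-fusion rule that combines speech and video phase
#' posteriors. By default both modalities receive equal weight (50% speech,
#' 50% video); within one speech fragment the video share is split equally
#' over all frames the fragment covers.
#'
#' @param audio_weight Fraction of the fused posterior contributed by the
#'   speech fragment, in `[0, 1]`. The video side receives
#'   `1 - audio_weight`, divided equally among covered frames.
#' @param tie_rule Deterministic argmax tie-breaking policy; only
#'   `"lowest"` (lowest phase index wins) is provided.
#' @param pseudo_policy What to do with a speech fragment whose predicted
#'   class (argmax) is the pseudo-phase. `"eliminate"` (default) drops the
#'   whole fragment from the analysis so its frames fall back to the video
#'   prediction; `"renormalize"` never eliminates and instead always strips
#'   the pseudo entry and renormalizes the procedural mass.
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(audio_weight = 0.5,
                          tie_rule = c("lowest"),
                          pseudo_policy = c("eliminate", "renormalize")) {
  if (!is.numeric(audio_weight) || length(audio_weight) != 1L ||
      audio_weight < 0 || audio_weight > 1)
    stop("'audio_weight' must be a single number in [0, 1]")
  structure(list(audio_weight = audio_weight,
                 tie_rule = match.arg(tie_rule),
                 pseudo_policy = match.arg(pseudo_policy)),
            class = "fusion_config")
}

#' Deterministic argmax label of a probability vector
#'
#' Returns the index of the maximum entry; exact ties are resolved
#' deterministically by the tie rule (default: the lowest phase index).
#'
#' @param probs Numeric probability vector.
#' @param tie_rule Tie-breaking policy (see [fusion_config()]).
#' @return Integer class index (1-based).
#' @export
#' @examples
#' argmax_label(c(0.1, 0.7, 0.2))  # 2
#' argmax_label(c(0.5, 0.5, 0))    # 1 (lowest index wins)
argmax_label <- function(probs, tie_rule = "lowest") {
  if (!length(probs)) stop("empty probability vector")
  # which.max returns the first maximum: the lowest-index rule.
  which.max(probs)
}

#' Remove the pseudo-phase entry from a speech posterior
#'
#' Speech posteriors carry an extra final entry for the pseudo-phase. When
#' the fragment's predicted class is the pseudo-phase the fragment is
#' off-task talk and is eliminated from the analysis (returns `NULL`);
#' otherwise the pseudo entry is dropped and the remaining procedural mass
#' renormalized to 1.
#'
#' @param probs Numeric vector of length `n_phases + 1` (pseudo-phase last).
#' @param config A [fusion_config()].
#' @return Numeric procedural probability vector of length `n_phases`, or
#'   `NULL` when the fragment is eliminated.
#' @export
#' @examples
#' strip_pseudo(c(0.05, 0.05, 0, 0, 0, 0, 0, 0.9))   # NULL: eliminated
#' strip_pseudo(c(0.5, 0.3, 0, 0, 0, 0, 0, 0.2))     # renormalized to 0.625/0.375
strip_pseudo <- function(probs, config = fusion_config()) {
  n1 <- length(probs)
  if (n1 < 2L) stop("speech posterior must have at least 2 entries")
  if (config$pseudo_policy == "eliminate" &&
      argmax_label(probs, config$tie_rule) == n1)
    return(NULL)
  v <- probs[-n1]
  s <- sum(v)
  if (s <= 0)
    stop("fragment has zero procedural mass and cannot be renormalized")
  v / s
}

#' Synchronize speech fragments with the video frames they cover
#'
#' Frame `i` (an instant at `t_i`) is covered by fragment `f` iff
#' `f$start <= t_i < f$end` (half-open convention, so a frame exactly at a
#' fragment's end is not covered). Because fragments are non-overlapping,
#' every frame is covered by at most one fragment.
#'
#' @param video A validated [video_stream()].
#' @param audio A validated [audio_stream()] over the same phase set.
#' @return A list with `windows` — one element per fragment, each a list
#'   with `fragment` (index) and `frames` (integer indices of covered
#'   frames, possibly empty) — and `uncovered`, the indices of frames
#'   covered by no fragment.
#' @export
synchronize <- function(video, audio) {
  t <- video$timestamps
  k <- length(audio$start)
  covered_by <- rep.int(NA_integer_, length(t))
  if (k > 0L && length(t) > 0L) {
    # candidate fragment: last fragment starting at or before t
    cand <- findInterval(t, audio$start)
    ok <- cand >= 1L & cand <= k
    ok[ok] <- t[ok] < audio$end[cand[ok]]
    covered_by[ok] <- cand[ok]
  }
  windows <- lapply(seq_len(k), function(j)
    list(fragment = j, frames = which(covered_by == j)))
  list(windows = windows, uncovered = which(is.na(covered_by)))
}

#' Fuse one speech fragment with its covered frames
#'
#' The fused posterior is the convex combination
#' `audio_weight * fragment + sum_i ((1 - audio_weight)/k) * frame_i`
#' over the `k` frames the fragment covers, so the video share is split
#' equally among the frames.
#'
#' @param fragment_probs Procedural posterior of the fragment (pseudo-phase
#'   already stripped).
#' @param frame_probs Numeric matrix of `k >= 1` frame posteriors (rows).
#' @param config A [fusion_config()].
#' @return Fused procedural probability vector.
#' @export
fuse_window <- function(fragment_probs, frame_probs, config = fusion_config()) {
  frame_probs <- rbind(frame_probs)
  k <- nrow(frame_probs)
  if (k == 0L)
    stop("fragment covers no frames; nothing to fuse")
  if (ncol(frame_probs) != length(fragment_probs))
    stop("fragment and frame posteriors span different class counts")
  w <- config$audio_weight
  w * fragment_probs + (1 - w) * colMeans(frame_probs)
}

#' Fuse a video stream with a speech stream into a per-frame timeline
#'
#' Applies the full late-fusion rule: each speech fragment is synchronized
#' with the frames it covers; its posterior (pseudo-phase stripped) is
#' combined with those frames' posteriors by [fuse_window()] and the single
#' fused distribution is assigned to every frame in the window. Fragments
#' whose predicted class is the pseudo-phase are eliminated — their frames,
#' like frames under no fragment (no speech captured), keep the video
#' posterior alone. Each frame's provenance records which branch fired.
#'
#' Degenerate weights: with `audio_weight = 1` every covered frame takes
#' the fragment's posterior; with `audio_weight = 0` the fragment carries
#' no mass and fusion is the identity on the video frames, so labels equal
#' the video-only labels frame by frame.
#'
#' @param video A validated [video_stream()] (must be non-empty).
#' @param audio A validated [audio_stream()] over the same phase set.
#' @param config A [fusion_config()].
#' @return An object of class `fused_timeline` with fields `fps`,
#'   `timestamps`, `probs` (fused per-frame posteriors), `labels` (tie-ruled
#'   argmax per frame), `provenance` (factor: `video_only`, `fused`,
#'   `audio_eliminated`) and `phase_set`. Frame count and timestamps equal
#'   the input video stream's.
#' @export
fuse_streams <- function(video, audio, config = fusion_config()) {
  video <- validate_stream(video)
  audio <- validate_stream(audio)
  if (nrow(video$probs) == 0L)
    stop("empty video stream: nothing to fuse")
  if (!identical(video$phase_set$phases, audio$phase_set$phases))
    stop("video and audio streams use different phase sets")

  sync <- synchronize(video, audio)
  probs <- video$probs
  provenance <- rep.int("video_only", nrow(probs))
  n_empty <- 0L
  for (w in sync$windows) {
    if (length(w$frames) == 0L) { n_empty <- n_empty + 1L; next }
    frag <- strip_pseudo(audio$probs[w$fragment, ], config)
    if (is.null(frag)) {
      provenance[w$frames] <- "audio_eliminated"
      next
    }
    if (config$audio_weight > 0) {
      fused <- fuse_window(frag, video$probs[w$frames, , drop = FALSE], config)
      probs[w$frames, ] <- rep(fused, each = length(w$frames))
    }
    # at audio_weight 0 the fragment carries no mass, so fusion degenerates
    # to the identity on the frames (labels equal the video-only labels)
    provenance[w$frames] <- "fused"
  }
  if (n_empty > 0L)
    warning(n_empty, " fragment(s) shorter than one frame period cover no ",
            "frame and were ignored")
  fused_timeline(
    probs = probs, fps = video$fps, timestamps = video$timestamps,
    provenance = provenance, phase_set = video$phase_set,
    tie_rule = config$tie_rule)
}

#' Construct a fused per-frame timeline
#'
#' Usually produced by [fuse_streams()]; the constructor is exported so
#' timelines can be rebuilt from serialized form. Labels are always the
#' tie-ruled argmax of the per-frame posteriors.
#'
#' @param probs Per-frame procedural posteriors (rows renormalized within
#'   `1e-9`).
#' @param fps Frames per second.
#' @param timestamps Frame times (regular grid, spacing `1/fps`).
#' @param provenance Per-frame branch: `video_only`, `fused` or
#'   `audio_eliminated`.
#' @param phase_set A [phase_set()].
#' @param tie_rule Argmax tie rule (see [fusion_config()]).
#' @return An object of class `fused_timeline`.
#' @export
fused_timeline <- function(probs, fps, timestamps = NULL,
                           provenance = rep("video_only", nrow(probs)),
                           phase_set = surgflow::phase_set(),
                           tie_rule = "lowest") {
  probs <- as.matrix(probs)
  if (nrow(probs) == 0L) stop("empty timeline")
  if (is.null(timestamps)) timestamps <- (seq_len(nrow(probs)) - 1L) / fps
  lev <- c("video_only", "fused", "audio_eliminated")
  if (!all(provenance %in% lev))
    stop("unknown provenance value(s): ",
         paste(setdiff(provenance, lev), collapse = ", "))
  probs <- normalize_probs(probs, what = "fused timeline")
  colnames(probs) <- phase_set$phases
  labels <- max.col(probs, ties.method = "first")  # lowest-index tie rule
  structure(list(fps = fps, timestamps = as.numeric(timestamps),
                 probs = probs, labels = labels,
                 provenance = factor(provenance, levels = lev),
                 phase_set = phase_set),
            class = "fused_timeline")
}

#' @export
print.fused_timeline <- function(x, ...) {
  n <- length(x$labels)
  tab <- table(x$provenance)
  cat("Fused phase timeline: ", n, " frames at ", x$fps, " fps (",
      round(n / x$fps, 1), " s)\n", sep = "")
  cat(sprintf("  provenance: %d video-only, %d fused, %d audio-eliminated\n",
              tab[["video_only"]], tab[["fused"]], tab[["audio_eliminated"]]))
  invisible(x)
}
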