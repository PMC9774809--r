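#' Default reference workflow for laparoscopic cholecystectomy
#'
#' An embedded-chain workflow over the seven canonical phases reflecting
#' the usual course of the procedure: a forward chain from preparation to
#' extraction, with the two loops commonly seen in practice — dissection
#' briefly interrupted by additional clipping, and packaging interleaved
#' with cleaning/coagulation when the anatomical surface needs attention.
#' Gallbladder extraction is terminal.
#'
#' @param phase_set A [phase_set()] with the seven canonical phases.
#' @return A [workflow_model()].
#' @export
default_lc_workflow <- function(phase_set = surgflow::phase_set()) {
  n <- n_phases(phase_set)
  stopifnot(n == 7L)
  m <- matrix(0, n, n)
  m[1, 2] <- 1                      # preparation -> Calot dissection
  m[2, 3] <- 1                      # -> clipping & cutting
  m[3, 4] <- 1                      # -> gallbladder dissection
  m[4, 3] <- 0.15; m[4, 5] <- 0.85  # dissection occasionally re-clips
  m[5, 6] <- 1                      # packaging -> cleaning/coagulation
  m[6, 5] <- 0.25; m[6, 7] <- 0.75  # cleaning may return to packaging
  workflow_model(m, phase_set)
}

#' Symmetric confusion matrix
#'
#' Row-stochastic confusion with a constant diagonal and the remaining mass
#' spread equally over the other classes — the standard symmetric-noise
#' model for a classifier whose per-class accuracy is `accuracy`.
#'
#' @param n Number of classes.
#' @param accuracy Diagonal value in `(0, 1]`.
#' @return `n x n` row-stochastic matrix.
#' @export
symmetric_confusion <- function(n, accuracy) {
  stopifnot(n >= 2, accuracy > 0, accuracy <= 1)
  m <- matrix((1 - accuracy) / (n - 1), n, n)
  diag(m) <- accuracy
  m
}

#' Simulation configuration
#'
#' Parameters of the synthetic procedure and classifier simulator. The
#' generative model is: a phase sequence sampled from the embedded Markov
#' chain `reference_workflow`, lognormal dwell time per visit, a frame grid
#' at `fps`, speech fragments from a renewal process (silence gaps between
#' fragments, occasional off-task fragments whose true class is the
#' pseudo-phase), and per-modality classifier noise driven by confusion
#' matrices.
#'
#' Defaults emulate a narrated teaching laparoscopic cholecystectomy:
#' dwell means of 60/180/90/180/60/90/45 s across the seven phases
#' (coefficient of variation 0.5), 1 frame per second, about eight speech
#' fragments per minute of roughly 4 s each separated by at least 1 s of
#' silence, and 10% off-task fragments. Default confusion matrices are the
#' identity (noise-free classifiers).
#'
#' @param reference_workflow A [workflow_model()] generating the phase
#'   sequence.
#' @param initial_phase Starting phase index (default 1, preparation).
#' @param dwell_mean,dwell_sd Per-phase mean and standard deviation of the
#'   lognormal dwell time, in seconds (recycled to `n_phases`). `dwell_sd =
#'   0` gives deterministic dwells equal to `dwell_mean`.
#' @param fps Video frame rate, frames/second.
#' @param speech_rate Expected speech fragments per minute; `0` disables
#'   speech.
#' @param fragment_duration_mean,fragment_duration_sd Fragment duration in
#'   seconds (normal, truncated below at 0.25 s).
#' @param silence_min Minimum silent gap between fragments, seconds.
#' @param offtask_prob Probability that a fragment is off-task talk (its
#'   true class is the pseudo-phase).
#' @param video_confusion `n x n` row-stochastic confusion matrix of the
#'   video classifier (truth rows).
#' @param audio_confusion `(n+1) x (n+1)` row-stochastic confusion matrix
#'   of the speech classifier over phases plus pseudo-phase.
#' @param concentration Sharpness (>= 1) of emitted posteriors around the
#'   sampled predicted class; larger is sharper. The emitted vector is
#'   `(1-s) * delta_pred + s * z` with `s` uniform on
#'   `(0, 1/(1+concentration))`, so the argmax always equals the class drawn
#'   from the confusion row and each modality's per-class argmax accuracy is
#'   exactly the confusion diagonal. The default (1) emits top-1
#'   probabilities between 0.5 and 1, typical of a moderately confident
#'   classifier.
#' @param truth_lean Informativeness (>= 0) of the residual posterior mass:
#'   `z` is Dirichlet with unit weights except `1 + truth_lean` at the true
#'   class, so even a mis-ranked posterior assigns above-chance mass to the
#'   true phase — real classifiers' top-2 accuracy exceeds their top-1
#'   accuracy, and it is this graded evidence that late fusion pools. `0`
#'   makes the residual uninformative flat noise.
#' @param max_transitions Hard stop on the number of embedded jumps.
#' @param seed Integer seed; every stream derived from a config is
#'   bit-reproducible given the seed.
#' @param phase_set A [phase_set()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(reference_workflow = default_lc_workflow(phase_set),
                              initial_phase = 1L,
                              dwell_mean = c(60, 180, 90, 180, 60, 90, 45),
                              dwell_sd = dwell_mean / 2,
                              fps = 1,
                              speech_rate = 8,
                              fragment_duration_mean = 4,
                              fragment_duration_sd = 1.5,
                              silence_min = 1,
                              offtask_prob = 0.1,
                              video_confusion = NULL,
                              audio_confusion = NULL,
                              concentration = 1,
                              truth_lean = 3,
                              max_transitions = 100L,
                              seed = 1L,
                              phase_set = surgflow::phase_set()) {
  n <- n_phases(phase_set)
  dwell_mean <- rep_len(dwell_mean, n)
  dwell_sd <- rep_len(dwell_sd, n)
  if (is.null(video_confusion)) video_confusion <- diag(n)
  if (is.null(audio_confusion)) audio_confusion <- diag(n + 1L)
  stopifnot(fps > 0, all(dwell_mean > 0), all(dwell_sd >= 0),
            speech_rate >= 0, fragment_duration_mean > 0, silence_min >= 0,
            offtask_prob >= 0, offtask_prob <= 1, concentration >= 1,
            truth_lean >= 0, initial_phase >= 1, initial_phase <= n)
  check_rows <- function(m, d, what) {
    m <- as.matrix(m)
    if (!all(dim(m) == d)) stop(what, " must be ", d, "x", d)
    normalize_probs(m, what = what)
  }
  video_confusion <- check_rows(video_confusion, n, "video_confusion")
  audio_confusion <- check_rows(audio_confusion, n + 1L, "audio_confusion")
  if (length(reference_workflow$terminal_phases) == 0L &&
      (is.null(max_transitions) || !is.finite(max_transitions)))
    stop("reference workflow has no terminal phase and no max_transitions: ",
         "the simulated procedure would never end")
  structure(list(reference_workflow = reference_workflow,
                 initial_phase = as.integer(initial_phase),
                 dwell_mean = dwell_mean, dwell_sd = dwell_sd, fps = fps,
                 speech_rate = speech_rate,
                 fragment_duration_mean = fragment_duration_mean,
                 fragment_duration_sd = fragment_duration_sd,
                 silence_min = silence_min, offtask_prob = offtask_prob,
                 video_confusion = video_confusion,
                 audio_confusion = audio_confusion,
                 concentration = concentration, truth_lean = truth_lean,
                 max_transitions = as.integer(max_transitions),
                 seed = as.integer(seed), phase_set = phase_set),
            class = "simulation_config")
}

# Lognormal parameterized by its own mean/sd (method of moments); sd = 0
# degenerates to the constant `mean`.
rdwell <- function(k, mean, sd) {
  if (sd == 0) return(rep.int(mean, k))
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(k, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a ground-truth procedure
#'
#' Samples a procedure from the embedded Markov chain of
#' `config$reference_workflow`: starting at `initial_phase`, jumps are drawn
#' from the transition rows until a terminal phase's dwell completes or
#' `max_transitions` is reached; each visit's dwell is lognormal with the
#' per-phase mean/sd. The frame grid and the speech-fragment schedule
#' (onsets from a renewal process with mean rate `speech_rate`, gaps of at
#' least `silence_min`, off-task fragments with probability `offtask_prob`)
#' are part of the ground truth; classifier noise is added later by the
#' render functions. A candidate fragment that would cross a phase
#' transition is truncated at the boundary — narration about a phase stops
#' when the phase changes — so every fragment lies within a single true
#' phase and its class is unambiguous. Deterministic given `config$seed`: the generator is
#' seeded once and consumed in fixed order (phase jumps, dwells, fragment
#' schedule).
#'
#' @param config A [simulation_config()].
#' @return An object of class `ground_truth`: a list with `segments` (a
#'   [phase_segments()] data frame from `t = 0`), `total_time`,
#'   `frame_times` and `frame_labels` (true phase per frame), and
#'   `fragments` (data frame `start`, `end`, `true_class` where
#'   `true_class` is a phase index or `n_phases + 1` for the pseudo-phase).
#' @export
simulate_procedure <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ps <- config$phase_set
  n <- n_phases(ps)
  M <- config$reference_workflow$matrix
  terminal <- rowSums(M) == 0
  withr_seed <- config$seed
  set.seed(withr_seed)

  # phase jumps
  seq_ph <- config$initial_phase
  cur <- config$initial_phase
  while (!terminal[cur] && length(seq_ph) <= config$max_transitions) {
    cur <- sample.int(n, 1L, prob = M[cur, ])
    seq_ph <- c(seq_ph, cur)
  }
  # dwells
  dw <- vapply(seq_ph, function(p)
    rdwell(1L, config$dwell_mean[p], config$dwell_sd[p]), numeric(1))
  ends <- cumsum(dw)
  starts <- c(0, ends[-length(ends)])
  segments <- phase_segments(data.frame(
    phase = phase_name(ps, seq_ph), phase_idx = seq_ph,
    start = starts, end = ends, stringsAsFactors = FALSE), ps)
  total <- ends[length(ends)]

  frame_times <- seq(0, by = 1 / config$fps,
                     length.out = floor(total * config$fps))
  frame_labels <- seq_ph[findInterval(frame_times, starts)]

  # fragment schedule: renewal of (gap, duration) pairs
  frag <- list(start = numeric(0), end = numeric(0), cls = integer(0))
  if (config$speech_rate > 0) {
    period <- 60 / config$speech_rate
    gap_mean <- max(period - config$fragment_duration_mean -
                      config$silence_min, 0.1)
    t <- config$silence_min + stats::rexp(1L, 1 / gap_mean)
    while (t < total) {
      d <- stats::rnorm(1L, config$fragment_duration_mean,
                        config$fragment_duration_sd)
      while (d < 0.25)
        d <- stats::rnorm(1L, config$fragment_duration_mean,
                          config$fragment_duration_sd)
      # narration about a phase stops at the phase transition: a candidate
      # fragment is truncated at the end of the segment it starts in, so
      # every fragment lies within a single true phase
      seg_end <- ends[findInterval(t, starts)]
      e <- min(t + d, seg_end, total)
      if (e - t >= 0.25) {
        mid <- (t + e) / 2
        cls <- seq_ph[findInterval(mid, starts)]
        if (stats::runif(1L) < config$offtask_prob) cls <- n + 1L
        frag$start <- c(frag$start, t)
        frag$end <- c(frag$end, e)
        frag$cls <- c(frag$cls, cls)
      }
      t <- e + config$silence_min + stats::rexp(1L, 1 / gap_mean)
    }
  }
  if (length(frag$start) == 0L && config$speech_rate > 0)
    warning("no speech fragment fits the procedure; audio stream will be empty")

  structure(list(segments = segments, total_time = total,
                 frame_times = frame_times, frame_labels = frame_labels,
                 fragments = data.frame(start = frag$start, end = frag$end,
                                        true_class = frag$cls),
                 config = config),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("Synthetic procedure: %.1f s, %d segments, %d frames, ",
                     "%d speech fragments\n"),
              x$total_time, nrow(x$segments), length(x$frame_labels),
              nrow(x$fragments)))
  invisible(x)
}

# Emit noisy posteriors. For each sample the predicted class is drawn from
# the confusion row of the true class, then the vector
#   (1 - s) * delta_pred + s * z
# is emitted, with s ~ U(0, 1/(1+concentration)) < 1/2 (so the argmax always
# equals the sampled prediction and per-class argmax accuracy is exactly the
# confusion diagonal) and z ~ Dirichlet(1, ..., 1 + truth_lean at the true
# class): the residual mass leans toward the true class, emulating a
# classifier whose ranked posterior is more informative than its top-1.
emit_posteriors <- function(true_cls, confusion, concentration, truth_lean) {
  n <- ncol(confusion)
  k <- length(true_cls)
  probs <- matrix(0, k, n)
  if (k == 0L) return(probs)
  pred <- vapply(true_cls, function(tc)
    sample.int(n, 1L, prob = confusion[tc, ]), integer(1))
  s <- stats::runif(k, 0, 1 / (1 + concentration))
  g <- matrix(stats::rgamma(k * n, shape = 1), k, n)
  g[cbind(seq_len(k), true_cls)] <-
    stats::rgamma(k, shape = 1 + truth_lean)
  z <- g / rowSums(g)
  probs <- s * z
  probs[cbind(seq_len(k), pred)] <- probs[cbind(seq_len(k), pred)] + (1 - s)
  probs
}

#' Render the noisy video prediction stream of a simulated procedure
#'
#' Emits one posterior per frame on the truth's frame grid. The predicted
#' class of each frame is drawn from the `video_confusion` row of the true
#' phase, and the emitted vector peaks at that class with sharpness
#' `concentration`, so the empirical per-class argmax accuracy matches the
#' confusion diagonal. With the identity confusion every frame's argmax is
#' the true phase. Deterministic given `config$seed` (video emissions use
#' the seed offset by 1, so the stream does not depend on whether the audio
#' stream was rendered first).
#'
#' @param truth A [simulate_procedure()] result.
#' @param config The same [simulation_config()].
#' @return A validated [video_stream()].
#' @export
render_video_stream <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(config$seed + 1L)
  probs <- emit_posteriors(truth$frame_labels, config$video_confusion,
                           config$concentration, config$truth_lean)
  video_stream(probs, fps = config$fps, timestamps = truth$frame_times,
               phase_set = config$phase_set)
}

#' Render the noisy speech prediction stream of a simulated procedure
#'
#' Emits one posterior (over phases plus pseudo-phase) per scheduled speech
#' fragment, drawing each fragment's predicted class from the
#' `audio_confusion` row of its true class. Fragment intervals and true
#' classes come from the ground truth; this function only adds classifier
#' noise. Deterministic given `config$seed` (audio emissions use the seed
#' offset by 2).
#'
#' @param truth A [simulate_procedure()] result.
#' @param config The same [simulation_config()].
#' @return A validated [audio_stream()] (possibly empty).
#' @export
render_audio_stream <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(config$seed + 2L)
  probs <- emit_posteriors(truth$fragments$true_class, config$audio_confusion,
                           config$concentration, config$truth_lean)
  audio_stream(truth$fragments$start, truth$fragments$end, probs,
               phase_set = config$phase_set)
}

#' Simulate a complete multimodal run
#'
#' Convenience wrapper: [simulate_procedure()] plus both render functions.
#'
#' @param config A [simulation_config()].
#' @return List with `truth`, `video` and `audio`.
#' @export
simulate_run <- function(config) {
  truth <- simulate_procedure(config)
  list(truth = truth,
       video = render_video_stream(truth, config),
       audio = render_audio_stream(truth, config))
}
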