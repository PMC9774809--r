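# Shared fixtures and independent oracles, built in code.

ps7 <- phase_set()

# delta distribution on index i over n classes
delta_on <- function(i, n = 7L) {
  v <- numeric(n); v[i] <- 1; v
}

# random probability vector over n classes
rand_probs <- function(n) {
  v <- rexp(n)
  v / sum(v)
}

# random valid video stream
rand_video <- function(n_frames = 10L, fps = 2, phase_set = ps7) {
  video_stream(t(replicate(n_frames, rand_probs(n_phases(phase_set)))),
               fps = fps, phase_set = phase_set)
}

# random valid audio stream on [0, t_max): alternating gaps and fragments
rand_audio <- function(n_frag = 4L, t_max = 10, phase_set = ps7) {
  cuts <- sort(runif(2L * n_frag, 0, t_max))
  start <- cuts[seq(1L, by = 2L, length.out = n_frag)]
  end <- cuts[seq(2L, by = 2L, length.out = n_frag)]
  keep <- end - start > 1e-3
  audio_stream(start[keep], end[keep],
               t(sapply(seq_len(sum(keep)),
                        function(i) rand_probs(n_phases(phase_set) + 1L))),
               phase_set = phase_set)
}

# random contiguous maximal-run segment list from t = 0
rand_segments <- function(n_seg = 6L, phase_set = ps7) {
  n <- n_phases(phase_set)
  idx <- integer(n_seg)
  idx[1L] <- sample.int(n, 1L)
  for (k in seq_len(n_seg - 1L))
    idx[k + 1L] <- sample(setdiff(seq_len(n), idx[k]), 1L)
  dur <- runif(n_seg, 0.5, 30)
  ends <- cumsum(dur)
  phase_segments(data.frame(phase = phase_name(phase_set, idx),
                            start = c(0, ends[-n_seg]), end = ends),
                 phase_set)
}

# random embedded-chain workflow model with at least one non-terminal row
rand_workflow <- function(phase_set = ps7, p_terminal = 0.2) {
  n <- n_phases(phase_set)
  m <- matrix(0, n, n)
  repeat {
    terminal <- runif(n) < p_terminal
    if (!all(terminal)) break
  }
  for (i in which(!terminal)) {
    w <- rexp(n - 1L)
    m[i, -i] <- w / sum(w)
  }
  workflow_model(m, phase_set)
}

# Independent Wasserstein oracle: monotone (north-west-corner) transport.
# Walks both distributions in index order, always shipping the smallest
# pending mass; the monotone coupling is optimal for convex 1-D costs.
# Shares no code with the CDF-sum implementation.
oracle_wasserstein <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  i <- 1L; j <- 1L; cost <- 0
  pi <- p[1L]; qj <- q[1L]
  while (i <= length(p) && j <= length(q)) {
    m <- min(pi, qj)
    cost <- cost + m * abs(i - j)
    pi <- pi - m; qj <- qj - m
    if (pi <= 1e-15) { i <- i + 1L; if (i <= length(p)) pi <- p[i] }
    if (qj <= 1e-15) { j <- j + 1L; if (j <= length(q)) qj <- q[j] }
  }
  cost
}

# Independent confusion-matrix metric oracle (loops and explicit counts,
# no table()/factor machinery shared with the implementation).
oracle_eval <- function(predicted, truth, n) {
  cm <- matrix(0L, n, n)
  for (t in seq_along(truth))
    cm[truth[t], predicted[t]] <- cm[truth[t], predicted[t]] + 1L
  prec <- rec <- f1 <- jac <- numeric(n)
  for (c in seq_len(n)) {
    tp <- cm[c, c]; fn <- sum(cm[c, ]) - tp; fp <- sum(cm[, c]) - tp
    rec[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
    prec[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1[c] <- if (prec[c] + rec[c] > 0)
      2 * prec[c] * rec[c] / (prec[c] + rec[c]) else 0
    jac[c] <- if (tp + fn + fp > 0) tp / (tp + fn + fp) else 0
  }
  present <- rowSums(cm) > 0
  list(accuracy = sum(diag(cm)) / length(truth),
       precision = mean(prec[present]), recall = mean(rec[present]),
       f1 = mean(f1[present]), jaccard = mean(jac[present]),
       avg_error_per_phase_pct = 100 * mean(1 - rec[present]),
       avg_error_pct = 100 * (1 - sum(diag(cm)) / length(truth)),
       confusion = cm)
}

# symmetric-noise config used by the fusion-benefit experiments
noisy_config <- function(seed, accuracy = 0.8) {
  simulation_config(seed = seed,
                    video_confusion = symmetric_confusion(7, accuracy),
                    audio_confusion = symmetric_confusion(8, accuracy))
}
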