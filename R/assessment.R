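#' Run-length encode a fused timeline into phase segments
#'
#' Collapses maximal runs of equal frame labels into contiguous segments.
#' Every frame occupies `1/fps` seconds starting at its timestamp, so a run
#' of `m` frames beginning at time `t` becomes the segment `[t, t + m/fps)`
#' and the segment list spans exactly `n_frames / fps` seconds.
#'
#' @param timeline A [fused_timeline()].
#' @return A data frame of class `phase_segments` with columns `phase`
#'   (name), `phase_idx`, `start` and `end` (seconds); consecutive segments
#'   are contiguous and carry different phases.
#' @export
segments_from_timeline <- function(timeline) {
  if (!inherits(timeline, "fused_timeline")) stop("not a fused_timeline")
  labs <- timeline$labels
  if (!length(labs)) stop("empty timeline")
  r <- rle(labs)
  ends <- timeline$timestamps[1L] + cumsum(r$lengths) / timeline$fps
  starts <- c(timeline$timestamps[1L], ends[-length(ends)])
  phase_segments(data.frame(
    phase = phase_name(timeline$phase_set, r$values),
    phase_idx = r$values, start = starts, end = ends,
    stringsAsFactors = FALSE), timeline$phase_set)
}

#' Construct/validate a phase segment list
#'
#' Segments are the timeline representation of a procedure: ordered,
#' contiguous half-open intervals, each labelled with one phase, adjacent
#' segments always differing in phase (maximal runs).
#'
#' @param segments Data frame with columns `phase`, `start`, `end` (and
#'   optionally `phase_idx`).
#' @param phase_set A [phase_set()].
#' @param tol Contiguity tolerance in seconds.
#' @return The validated data frame, classed `phase_segments`.
#' @export
phase_segments <- function(segments, phase_set = surgflow::phase_set(),
                           tol = 1e-9) {
  segments <- as.data.frame(segments)
  if (!all(c("phase", "start", "end") %in% names(segments)))
    stop("segments need columns phase, start, end")
  if (nrow(segments) == 0L) stop("empty segment list")
  if (is.null(segments$phase_idx))
    segments$phase_idx <- phase_index(phase_set, segments$phase)
  if (any(segments$start >= segments$end))
    stop("segment ", which(segments$start >= segments$end)[1L],
         " has start >= end")
  if (nrow(segments) > 1L) {
    gap <- segments$start[-1L] - segments$end[-nrow(segments)]
    if (any(abs(gap) > tol))
      stop("segments not contiguous at segment ",
           which(abs(gap) > tol)[1L] + 1L)
    if (any(diff(segments$phase_idx) == 0L))
      stop("adjacent segments share a phase at segment ",
           which(diff(segments$phase_idx) == 0L)[1L] + 1L,
           "; runs must be maximal")
  }
  structure(segments, class = c("phase_segments", "data.frame"),
            phase_set = phase_set)
}

#' Timewise assessment metrics of a procedure
#'
#' Computes the metric battery used to characterize a procedure in a
#' timewise way: total time spent in surgery, time spent in each phase,
#' occupancy percentage per phase, the number of occurrences of each phase
#' and — meaningful whenever a phase occurs more than once — the minimal,
#' maximal and mean duration of its occurrences. Phases never visited
#' report zero time and zero occurrences.
#'
#' @param segments A [phase_segments()] data frame.
#' @param phase_set A [phase_set()]; defaults to the one attached to
#'   `segments`.
#' @return An object of class `metrics_report`: a list with `total_time`
#'   (seconds) and `per_phase`, a data frame with one row per procedural
#'   phase and columns `total_time`, `occupancy_pct`, `n_occurrences`,
#'   `min_duration`, `max_duration`, `mean_duration`.
#' @export
compute_metrics <- function(segments, phase_set = attr(segments, "phase_set")) {
  if (is.null(phase_set)) phase_set <- surgflow::phase_set()
  segments <- phase_segments(segments, phase_set)
  dur <- segments$end - segments$start
  total <- sum(dur)
  ph <- factor(segments$phase, levels = phase_set$phases)
  zero_or <- function(x, f, default = 0) {
    out <- rep.int(default, n_phases(phase_set))
    v <- tapply(x, ph, f)
    hit <- !is.na(v)
    out[hit] <- v[hit]
    out
  }
  per <- data.frame(
    phase = phase_set$phases,
    total_time = zero_or(dur, sum),
    n_occurrences = as.integer(table(ph)),
    min_duration = zero_or(dur, min),
    max_duration = zero_or(dur, max),
    mean_duration = zero_or(dur, mean),
    stringsAsFactors = FALSE)
  per$occupancy_pct <- 100 * per$total_time / total
  per <- per[, c("phase", "total_time", "occupancy_pct", "n_occurrences",
                 "min_duration", "max_duration", "mean_duration")]
  structure(list(total_time = total, per_phase = per, phase_set = phase_set),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Procedure metrics: total time %.1f s\n", x$total_time))
  p <- x$per_phase
  p[-1L] <- lapply(p[-1L], function(v) round(v, 2))
  print(p, row.names = FALSE)
  invisible(x)
}

#' Collapse consecutive duplicate labels
#'
#' Removes self-transitions from a phase sequence, leaving the embedded
#' sequence of distinct-phase jumps: consecutive duplicates are merged, the
#' first element is preserved and no two adjacent outputs are equal. Apply
#' before [estimate_transition_matrix()].
#'
#' @param labels Vector of phase labels (indices or names).
#' @return Vector of the same type with runs collapsed.
#' @export
#' @examples
#' collapse_runs(c(1, 1, 2, 2, 3))  # 1 2 3
collapse_runs <- function(labels) {
  if (!length(labels)) stop("empty label sequence")
  rle(labels)$values
}

#' Construct/validate an embedded-chain workflow model
#'
#' A workflow model is the row-stochastic transition matrix of the embedded
#' Markov chain of a procedure: only jumps between distinct phases carry
#' probability (the diagonal is identically zero, since the probability of
#' remaining in a phase is not modelled). Phases with no outgoing
#' transition are terminal and carry an all-zero row.
#'
#' @param matrix Square numeric matrix over the procedural phases.
#' @param phase_set A [phase_set()].
#' @param tol Row-sum tolerance.
#' @return An object of class `workflow_model` with fields `matrix`,
#'   `terminal_phases` (character) and `phase_set`.
#' @export
workflow_model <- function(matrix, phase_set = surgflow::phase_set(),
                           tol = 1e-9) {
  matrix <- as.matrix(matrix)
  n <- n_phases(phase_set)
  if (!all(dim(matrix) == n))
    stop("workflow matrix must be ", n, "x", n)
  if (any(matrix < 0)) stop("negative transition probability")
  if (any(abs(diag(matrix)) > 0))
    stop("self-transition forbidden: nonzero diagonal at phase ",
         phase_set$phases[which(abs(diag(matrix)) > 0)[1L]])
  rs <- rowSums(matrix)
  terminal <- rs == 0
  if (any(!terminal & abs(rs - 1) > tol))
    stop("non-terminal row for phase ",
         phase_set$phases[which(!terminal & abs(rs - 1) > tol)[1L]],
         " sums to ", format(rs[which(!terminal & abs(rs - 1) > tol)[1L]],
                             digits = 10))
  matrix[!terminal, ] <- matrix[!terminal, , drop = FALSE] / rs[!terminal]
  dimnames(matrix) <- list(phase_set$phases, phase_set$phases)
  structure(list(matrix = matrix,
                 terminal_phases = phase_set$phases[terminal],
                 phase_set = phase_set),
            class = "workflow_model")
}

#' @export
print.workflow_model <- function(x, ...) {
  cat("Embedded-chain workflow model over", n_phases(x$phase_set), "phases\n")
  print(round(x$matrix, 3))
  if (length(x$terminal_phases))
    cat("terminal:", paste(x$terminal_phases, collapse = ", "), "\n")
  invisible(x)
}

#' Estimate the embedded transition matrix from phase sequences
#'
#' Maximum-likelihood estimate of the embedded Markov chain from one or
#' more phase sequences: entry `(i, j)` is the number of observed `i -> j`
#' jumps, pooled across sequences, divided by the total jumps out of `i`.
#' Sequences must already have self-transitions removed (use
#' [collapse_runs()]); an averaged-per-sequence alternative is available
#' for building a reference workflow from several procedures.
#'
#' @param sequences A single vector or a list of vectors of phase labels
#'   (indices or names), each with no adjacent duplicates.
#' @param phase_set A [phase_set()].
#' @param method `"pool"` (default) pools jump counts across sequences;
#'   `"average"` estimates one matrix per sequence and averages rows over
#'   the sequences where the phase is non-terminal.
#' @return A [workflow_model()]. Phases with no outgoing jump are terminal.
#' @export
estimate_transition_matrix <- function(sequences,
                                       phase_set = surgflow::phase_set(),
                                       method = c("pool", "average")) {
  method <- match.arg(method)
  if (!is.list(sequences)) sequences <- list(sequences)
  if (!length(sequences)) stop("no sequences supplied")
  n <- n_phases(phase_set)
  as_idx <- function(s) {
    if (is.character(s)) s <- phase_index(phase_set, s)
    s <- as.integer(s)
    if (any(s < 1L | s > n)) stop("phase index out of range")
    if (length(s) > 1L && any(diff(s) == 0L))
      stop("sequence contains adjacent duplicate phases; ",
           "apply collapse_runs() first")
    s
  }
  sequences <- lapply(sequences, as_idx)
  count_one <- function(s) {
    cnt <- matrix(0, n, n)
    if (length(s) > 1L) {
      from <- s[-length(s)]; to <- s[-1L]
      for (t in seq_along(from)) cnt[from[t], to[t]] <- cnt[from[t], to[t]] + 1
    }
    cnt
  }
  if (method == "pool") {
    cnt <- Reduce(`+`, lapply(sequences, count_one))
    rs <- rowSums(cnt)
    mat <- cnt
    mat[rs > 0, ] <- cnt[rs > 0, , drop = FALSE] / rs[rs > 0]
  } else {
    mats <- lapply(sequences, function(s) {
      cnt <- count_one(s)
      rs <- rowSums(cnt)
      cnt[rs > 0, ] <- cnt[rs > 0, , drop = FALSE] / rs[rs > 0]
      list(mat = cnt, active = rs > 0)
    })
    mat <- matrix(0, n, n)
    n_active <- rep.int(0L, n)
    for (m in mats) {
      mat[m$active, ] <- mat[m$active, , drop = FALSE] +
        m$mat[m$active, , drop = FALSE]
      n_active <- n_active + m$active
    }
    mat[n_active > 0, ] <- mat[n_active > 0, , drop = FALSE] /
      n_active[n_active > 0]
  }
  workflow_model(mat, phase_set)
}

#' First-order Wasserstein distance between categorical distributions
#'
#' Earth mover's distance between two distributions over the same ordered
#' support of phase indices, with unit spacing between adjacent indices as
#' the ground metric. On such a 1-D support the minimum-cost transport has
#' the closed form `sum_{k=1}^{n-1} |CDF_p(k) - CDF_q(k)|`.
#'
#' @param p,q Probability vectors over the same ordered support.
#' @param tol Ingest tolerance on the unit-mass check.
#' @return Non-negative distance; 0 iff `p == q`.
#' @export
#' @examples
#' wasserstein_categorical(c(0, 1, 0, 0), c(0, 0, 0, 1))  # 2
wasserstein_categorical <- function(p, q, tol = 1e-9) {
  if (length(p) != length(q))
    stop("distributions have different support sizes (", length(p), " vs ",
         length(q), ")")
  p <- normalize_probs(p, tol)
  q <- normalize_probs(q, tol)
  d <- cumsum(p - q)
  sum(abs(d[-length(d)]))
}

#' Compare a trainee workflow against a reference workflow
#'
#' For every phase that is non-terminal in both models, computes the
#' Wasserstein distance between the reference's and the trainee's outgoing
#' transition distributions for that phase; the overall score is the
#' arithmetic mean over the included phases. Phases terminal (or absent) in
#' either model carry an all-zero row, which is not a probability
#' distribution, so they are excluded and reported rather than silently
#' dropped.
#'
#' @param reference,student [workflow_model()] objects over the same phase
#'   set (reference is typically the average workflow pooled from a
#'   clinician-validated video database).
#' @return An object of class `workflow_comparison`: a list with
#'   `per_phase_distance` (named numeric over included phases),
#'   `excluded_phases` and `average_distance`.
#' @export
compare_workflows <- function(reference, student) {
  stopifnot(inherits(reference, "workflow_model"),
            inherits(student, "workflow_model"))
  if (!identical(reference$phase_set$phases, student$phase_set$phases))
    stop("workflows use different phase sets")
  phases <- reference$phase_set$phases
  excluded <- union(reference$terminal_phases, student$terminal_phases)
  included <- setdiff(phases, excluded)
  if (!length(included))
    stop("no comparable rows: every phase is terminal in one of the models")
  d <- vapply(included, function(ph)
    wasserstein_categorical(reference$matrix[ph, ], student$matrix[ph, ]),
    numeric(1))
  structure(list(per_phase_distance = d,
                 excluded_phases = excluded,
                 average_distance = mean(d)),
            class = "workflow_comparison")
}

#' @export
print.workflow_comparison <- function(x, ...) {
  cat("Workflow comparison (Wasserstein distance per phase)\n")
  print(round(x$per_phase_distance, 4))
  if (length(x$excluded_phases))
    cat("excluded (terminal in a model):",
        paste(x$excluded_phases, collapse = ", "), "\n")
  cat(sprintf("average distance: %.4f\n", x$average_distance))
  invisible(x)
}

#' Frame-wise evaluation of predicted phases against ground truth
#'
#' Builds the per-class confusion matrix and the standard phase-recognition
#' scores: precision, recall, F1 (the harmonic mean of precision and
#' recall), accuracy and the Jaccard index. Per-class scores are
#' macro-averaged (unweighted) over the classes present in the ground
#' truth, so absent classes never contribute undefined recalls. Two
#' aggregate error rates are also reported: `avg_error_per_phase_pct`, the
#' mean over truth-present classes of `100 * (1 - recall)`, and
#' `avg_error_pct = 100 * (1 - accuracy)`.
#'
#' @param predicted,truth Equal-length label vectors (indices or names)
#'   over the procedural phases.
#' @param phase_set A [phase_set()].
#' @return An object of class `evaluation_report`: a list with the macro
#'   scores `f1`, `precision`, `recall`, `accuracy`, `jaccard`, the two
#'   error percentages, `confusion` (truth rows x predicted columns) and
#'   `per_class` (data frame of per-class scores for truth-present classes).
#' @export
evaluate_predictions <- function(predicted, truth,
                                 phase_set = surgflow::phase_set()) {
  if (length(predicted) != length(truth))
    stop("predicted (", length(predicted), ") and truth (", length(truth),
         ") label sequences differ in length")
  if (!length(truth)) stop("empty label sequences")
  to_name <- function(x)
    if (is.character(x)) x else phase_name(phase_set, x)
  predicted <- factor(to_name(predicted), levels = phase_set$phases)
  truth <- factor(to_name(truth), levels = phase_set$phases)
  cm <- table(truth = truth, predicted = predicted)
  tp <- diag(cm)
  truth_n <- rowSums(cm)
  pred_n <- colSums(cm)
  present <- truth_n > 0
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  recall <- safe(tp, truth_n)
  precision <- safe(tp, pred_n)
  f1 <- safe(2 * precision * recall, precision + recall)
  jaccard <- safe(tp, truth_n + pred_n - tp)
  accuracy <- sum(tp) / length(truth)
  per_class <- data.frame(
    phase = phase_set$phases[present],
    support = as.integer(truth_n[present]),
    precision = precision[present], recall = recall[present],
    f1 = f1[present], jaccard = jaccard[present],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    f1 = mean(f1[present]), precision = mean(precision[present]),
    recall = mean(recall[present]), accuracy = accuracy,
    jaccard = mean(jaccard[present]),
    avg_error_per_phase_pct = 100 * mean(1 - recall[present]),
    avg_error_pct = 100 * (1 - accuracy),
    confusion = cm, per_class = per_class, phase_set = phase_set),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("Evaluation: F1 %.3f | precision %.3f | recall %.3f | ",
                     "accuracy %.3f | Jaccard %.3f\n"),
              x$f1, x$precision, x$recall, x$accuracy, x$jaccard))
  cat(sprintf("avg error/phase %.2f%% | avg error %.2f%%\n",
              x$avg_error_per_phase_pct, x$avg_error_pct))
  invisible(x)
}
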