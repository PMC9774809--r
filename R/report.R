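#' Assemble the assessment report for a fused timeline
#'
#' Runs the full assessment battery on a fused per-frame timeline: segments
#' the timeline, computes the timewise metrics, estimates the trainee's
#' embedded workflow, and — when a reference workflow is supplied —
#' compares the two via the per-phase Wasserstein distances. The report
#' also summarizes fusion provenance (which fraction of frames was fused,
#' video-only, or under an eliminated off-task fragment), the numbers a
#' trainer would sanity-check first.
#'
#' @param timeline A [fused_timeline()].
#' @param reference Optional reference [workflow_model()] (the average
#'   workflow of the procedure).
#' @param config The [fusion_config()] used to produce the timeline
#'   (echoed into the report).
#' @return An object of class `assessment_report`: a list with `metrics`,
#'   `segments`, `student_workflow`, `comparison` (`NULL` without a
#'   reference), `provenance_summary`, `config` and `version`.
#' @export
assess_timeline <- function(timeline, reference = NULL,
                            config = fusion_config()) {
  stopifnot(inherits(timeline, "fused_timeline"))
  segments <- segments_from_timeline(timeline)
  metrics <- compute_metrics(segments, timeline$phase_set)
  student <- estimate_transition_matrix(collapse_runs(timeline$labels),
                                        timeline$phase_set)
  comparison <- if (!is.null(reference)) compare_workflows(reference, student)
  prov <- table(timeline$provenance) / length(timeline$labels)
  structure(list(
    metrics = metrics, segments = segments, student_workflow = student,
    comparison = comparison,
    provenance_summary = as.list(as.numeric(prov)) |>
      stats::setNames(names(prov)),
    config = list(audio_weight = config$audio_weight,
                  tie_rule = config$tie_rule,
                  pseudo_policy = config$pseudo_policy),
    version = as.character(utils::packageVersion("surgflow")),
    phase_set = timeline$phase_set),
    class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("== Surgical workflow assessment report (surgflow ", x$version,
      ") ==\n", sep = "")
  print(x$metrics)
  cat(sprintf("provenance: %.1f%% video-only, %.1f%% fused, %.1f%% off-task eliminated\n",
              100 * x$provenance_summary$video_only,
              100 * x$provenance_summary$fused,
              100 * x$provenance_summary$audio_eliminated))
  print(x$student_workflow)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' Read and write assessment reports
#'
#' The report serializes to a single JSON document (sorted structure,
#' full-precision numerics); re-parsing reproduces every numeric field to
#' `1e-9`.
#'
#' @param report An [assess_timeline()] result.
#' @param path File path.
#' @param phase_set A [phase_set()].
#' @return The report (reader) or `path` (writer).
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "assessment_report"))
  wf <- function(m) list(
    phases = m$phase_set$phases,
    matrix = unname(lapply(seq_len(nrow(m$matrix)),
                           function(i) as.numeric(m$matrix[i, ]))),
    terminal_phases = m$terminal_phases)
  obj <- list(
    version = report$version,
    config = report$config,
    metrics = list(total_time = report$metrics$total_time,
                   per_phase = report$metrics$per_phase),
    timeline = data.frame(phase = report$segments$phase,
                          start_s = report$segments$start,
                          end_s = report$segments$end),
    student_workflow = wf(report$student_workflow),
    provenance_summary = report$provenance_summary)
  if (!is.null(report$comparison))
    obj$comparison <- list(
      per_phase_distance = as.list(report$comparison$per_phase_distance),
      excluded_phases = report$comparison$excluded_phases,
      average_distance = report$comparison$average_distance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, phase_set = surgflow::phase_set()) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  segments <- phase_segments(data.frame(phase = obj$timeline$phase,
                                        start = obj$timeline$start_s,
                                        end = obj$timeline$end_s),
                             phase_set)
  metrics <- list(total_time = obj$metrics$total_time,
                  per_phase = as.data.frame(obj$metrics$per_phase),
                  phase_set = phase_set)
  class(metrics) <- "metrics_report"
  m <- obj$student_workflow$matrix
  if (is.list(m)) m <- do.call(rbind, m)
  student <- workflow_model(m, phase_set)
  comparison <- NULL
  if (!is.null(obj$comparison)) {
    comparison <- structure(list(
      per_phase_distance = unlist(obj$comparison$per_phase_distance),
      excluded_phases = as.character(obj$comparison$excluded_phases),
      average_distance = obj$comparison$average_distance),
      class = "workflow_comparison")
  }
  structure(list(metrics = metrics, segments = segments,
                 student_workflow = student, comparison = comparison,
                 provenance_summary = obj$provenance_summary,
                 config = obj$config, version = obj$version,
                 phase_set = phase_set),
            class = "assessment_report")
}
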