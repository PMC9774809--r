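# Serialization. One CSV layout serves both modality streams:
#   t_start,t_end,<phase names...>[,<pseudo>]
# video rows are instants (t_end == t_start), audio rows intervals
# (t_end > t_start). Workflows, reports and comparisons are JSON. All
# writes are deterministic: fixed column order, 12-decimal fixed-point
# floats (so probability rows survive a round trip within the 1e-9 ingest
# tolerance and numerics within 1e-9 overall).

fmt_num <- function(x) {
  out <- sprintf("%.12f", x)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

write_stream_csv <- function(t_start, t_end, probs, path) {
  df <- data.frame(t_start = fmt_num(t_start), t_end = fmt_num(t_end),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(probs))) df[[colnames(probs)[j]]] <- fmt_num(probs[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_stream_csv <- function(path, expected_cols, what) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "numeric"),
    error = function(e) stop("cannot parse ", what, " file '", path, "': ",
                             conditionMessage(e)))
  if (!identical(names(df), c("t_start", "t_end", expected_cols)))
    stop(what, " file '", path, "': phase order mismatch; header must be ",
         paste(c("t_start", "t_end", expected_cols), collapse = ","))
  df
}

#' Read and write prediction streams
#'
#' Streams are stored as UTF-8 CSV with header
#' `t_start,t_end,<phase names...>` (video) or
#' `t_start,t_end,<phase names...>,<pseudo>` (speech): one probability
#' column per class, `.` decimal separator. Video rows are instants
#' (`t_end == t_start`); speech rows are half-open intervals. The header's
#' phase names must match the configured phase set exactly and in order.
#'
#' @param path File path.
#' @param stream Stream object to write.
#' @param fps Frame rate for [read_video_stream()]; if `NULL`, inferred
#'   from the spacing of the first two frames (a single-frame file then
#'   needs an explicit `fps`).
#' @param phase_set A [phase_set()].
#' @return The stream (readers) or `path`, invisibly (writers).
#' @export
read_video_stream <- function(path, fps = NULL,
                              phase_set = surgflow::phase_set()) {
  df <- read_stream_csv(path, phase_set$phases, "video stream")
  if (nrow(df) && any(abs(df$t_end - df$t_start) > 1e-9))
    stop("video stream file '", path, "': row ",
         which(abs(df$t_end - df$t_start) > 1e-9)[1L],
         " is an interval, expected instants (t_end == t_start)")
  if (is.null(fps)) {
    if (nrow(df) < 2L)
      stop("cannot infer fps from ", nrow(df), " frame(s); pass fps=")
    fps <- 1 / (df$t_start[2L] - df$t_start[1L])
  }
  video_stream(as.matrix(df[phase_set$phases]), fps = fps,
               timestamps = df$t_start, phase_set = phase_set)
}

#' @rdname read_video_stream
#' @export
write_video_stream <- function(stream, path) {
  stopifnot(inherits(stream, "video_stream"))
  write_stream_csv(stream$timestamps, stream$timestamps, stream$probs, path)
}

#' @rdname read_video_stream
#' @export
read_audio_stream <- function(path, phase_set = surgflow::phase_set()) {
  cols <- c(phase_set$phases, phase_set$pseudo_phase)
  df <- read_stream_csv(path, cols, "audio stream")
  audio_stream(df$t_start, df$t_end, as.matrix(df[cols]),
               phase_set = phase_set)
}

#' @rdname read_video_stream
#' @export
write_audio_stream <- function(stream, path) {
  stopifnot(inherits(stream, "audio_stream"))
  write_stream_csv(stream$start, stream$end, stream$probs, path)
}

#' Read and write fused timelines
#'
#' Same CSV layout as a video stream plus trailing `label` and
#' `provenance` columns.
#'
#' @param timeline A [fused_timeline()].
#' @param path File path.
#' @param fps,phase_set As in [read_video_stream()].
#' @return The timeline (reader) or `path` (writer).
#' @export
write_fused_timeline <- function(timeline, path) {
  stopifnot(inherits(timeline, "fused_timeline"))
  df <- data.frame(t_start = fmt_num(timeline$timestamps),
                   t_end = fmt_num(timeline$timestamps),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(timeline$probs)))
    df[[colnames(timeline$probs)[j]]] <- fmt_num(timeline$probs[, j])
  df$label <- phase_name(timeline$phase_set, timeline$labels)
  df$provenance <- as.character(timeline$provenance)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fused_timeline
#' @export
read_fused_timeline <- function(path, fps = NULL,
                                phase_set = surgflow::phase_set()) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop("cannot parse fused timeline '",
                                          path, "': ", conditionMessage(e)))
  need <- c("t_start", "t_end", phase_set$phases, "label", "provenance")
  if (!identical(names(df), need))
    stop("fused timeline '", path, "': phase order mismatch; header must be ",
         paste(need, collapse = ","))
  if (is.null(fps)) {
    if (nrow(df) < 2L)
      stop("cannot infer fps from ", nrow(df), " frame(s); pass fps=")
    fps <- 1 / (df$t_start[2L] - df$t_start[1L])
  }
  tl <- fused_timeline(as.matrix(df[phase_set$phases]), fps = fps,
                       timestamps = df$t_start, provenance = df$provenance,
                       phase_set = phase_set)
  relabelled <- phase_name(phase_set, tl$labels) != df$label
  if (any(relabelled))
    stop("fused timeline '", path, "': row ", which(relabelled)[1L],
         " label does not match the argmax of its probabilities")
  tl
}

#' Read and write workflow models
#'
#' A workflow model is stored as JSON with the ordered phase names, the
#' row-stochastic embedded transition matrix (zero diagonal) and the
#' terminal phases. All invariants are re-validated on read.
#'
#' @param model A [workflow_model()].
#' @param path File path.
#' @param phase_set A [phase_set()]; the file's phase names must match it
#'   exactly, order-sensitive.
#' @return The model (reader) or `path` (writer).
#' @export
write_workflow <- function(model, path) {
  stopifnot(inherits(model, "workflow_model"))
  obj <- list(phases = model$phase_set$phases,
              matrix = unname(apply(model$matrix, 1L, as.numeric,
                                    simplify = FALSE)),
              terminal_phases = model$terminal_phases)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_workflow
#' @export
read_workflow <- function(path, phase_set = surgflow::phase_set()) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse workflow '", path,
                                           "': ", conditionMessage(e)))
  if (!identical(as.character(obj$phases), phase_set$phases))
    stop("workflow '", path, "': phase order mismatch")
  m <- obj$matrix
  if (is.list(m)) m <- do.call(rbind, m)
  model <- workflow_model(m, phase_set)
  declared <- sort(as.character(obj$terminal_phases %||% character(0)))
  if (!identical(declared, sort(model$terminal_phases)))
    stop("workflow '", path, "': declared terminal phases disagree with ",
         "the all-zero rows of the matrix")
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a segment list as CSV
#'
#' Columns `phase,start_s,end_s`, one row per segment.
#'
#' @param segments A [phase_segments()] data frame.
#' @param path File path.
#' @param phase_set A [phase_set()] for the reader.
#' @return The segments (reader) or `path` (writer).
#' @export
write_segments <- function(segments, path) {
  df <- data.frame(phase = segments$phase, start_s = fmt_num(segments$start),
                   end_s = fmt_num(segments$end), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path, phase_set = surgflow::phase_set()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("phase", "start_s", "end_s")))
    stop("segments file '", path, "': header must be phase,start_s,end_s")
  phase_segments(data.frame(phase = df$phase, start = df$start_s,
                            end = df$end_s, stringsAsFactors = FALSE),
                 phase_set)
}

#' Read a label sequence from CSV
#'
#' A single `label` column of phase names (one frame per row), as written
#' by [write_labels()].
#'
#' @param path File path.
#' @param labels Character or integer labels to write.
#' @param phase_set A [phase_set()].
#' @return Character vector of labels (reader) or `path` (writer).
#' @export
read_labels <- function(path, phase_set = surgflow::phase_set()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), "label"))
    stop("label file '", path, "': header must be a single 'label' column")
  phase_index(phase_set, df$label)  # validates names
  df$label
}

#' @rdname read_labels
#' @export
write_labels <- function(labels, path, phase_set = surgflow::phase_set()) {
  if (is.numeric(labels)) labels <- phase_name(phase_set, labels)
  utils::write.csv(data.frame(label = labels), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Any field of [simulation_config()] may be given; missing fields take
#' the defaults. `reference_workflow` may be a matrix (list of rows) or the
#' path of a workflow JSON file (resolved relative to the config file).
#' Confusion matrices may be given as matrices or as a single scalar
#' `accuracy`, expanded with [symmetric_confusion()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @param phase_set A [phase_set()].
#' @param seed Optional seed overriding the file's.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path, phase_set = surgflow::phase_set(),
                                   seed = NULL) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  n <- n_phases(phase_set)
  as_mat <- function(x) {
    if (is.list(x))
      x <- do.call(rbind, lapply(x, function(r) as.numeric(unlist(r))))
    as.matrix(x)
  }
  if (!is.null(raw$reference_workflow)) {
    raw$reference_workflow <- if (is.character(raw$reference_workflow)) {
      p <- raw$reference_workflow
      if (!file.exists(p)) p <- file.path(dirname(path), p)
      read_workflow(p, phase_set)
    } else workflow_model(as_mat(raw$reference_workflow), phase_set)
  }
  expand_conf <- function(x, d) {
    if (is.null(x)) return(NULL)
    if (length(x) == 1L && is.numeric(x)) symmetric_confusion(d, x)
    else as_mat(x)
  }
  raw$video_confusion <- expand_conf(raw$video_confusion, n)
  raw$audio_confusion <- expand_conf(raw$audio_confusion, n + 1L)
  if (!is.null(seed)) raw$seed <- seed
  known <- setdiff(names(formals(simulation_config)), "phase_set")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("config '", path, "': unknown field(s): ",
         paste(unknown, collapse = ", "))
  raw <- raw[!vapply(raw, is.null, logical(1))]
  do.call(simulation_config, c(raw, list(phase_set = phase_set)))
}
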