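#' Canonical laparoscopic cholecystectomy phase names
#'
#' The seven procedural phases of a laparoscopic cholecystectomy in their
#' canonical order, from patient preparation to gallbladder extraction.
#'
#' @return Character vector of length 7.
#' @export
#' @examples
#' lc_phases()
lc_phases <- function() {
  c("preparation",
    "calot_triangle_dissection",
    "clipping_cutting",
    "gallbladder_dissection",
    "gallbladder_packaging",
    "cleaning_coagulation",
    "gallbladder_extraction")
}

#' Construct a phase set
#'
#' A phase set is the ordered collection of procedural phase names together
#' with the name reserved for the speech-only pseudo-phase (off-task talk in
#' the operating room, e.g. casual conversation, that belongs to no
#' procedural phase). The pseudo-phase is carried only by speech probability
#' vectors, always as the last entry, and is consumed during fusion: it
#' never appears in segments, metrics, workflow models or evaluation.
#'
#' @param phases Ordered character vector of unique procedural phase names
#'   (default: the seven canonical LC phases, [lc_phases()]).
#' @param pseudo_phase Name of the reserved off-task class. Must not be a
#'   procedural phase name.
#' @return An object of class `phase_set`.
#' @export
#' @examples
#' ps <- phase_set()
#' n_phases(ps)
phase_set <- function(phases = lc_phases(), pseudo_phase = "__pseudo__") {
  if (!is.character(phases) || length(phases) < 2L)
    stop("'phases' must be a character vector with at least 2 names")
  if (anyDuplicated(phases))
    stop("phase names must be unique; duplicated: ",
         paste(unique(phases[duplicated(phases)]), collapse = ", "))
  if (!is.character(pseudo_phase) || length(pseudo_phase) != 1L || !nzchar(pseudo_phase))
    stop("'pseudo_phase' must be a single non-empty name")
  if (pseudo_phase %in% phases)
    stop("pseudo-phase '", pseudo_phase, "' must not be a procedural phase")
  structure(list(phases = phases, pseudo_phase = pseudo_phase),
            class = "phase_set")
}

#' Number of procedural phases in a phase set
#'
#' @param phase_set A [phase_set()].
#' @return Integer count of procedural phases (the pseudo-phase not included).
#' @export
n_phases <- function(phase_set) {
  stopifnot(inherits(phase_set, "phase_set"))
  length(phase_set$phases)
}

#' Map phase names to indices and back
#'
#' Phases are index-addressable in canonical order (1-based). The mapping
#' between names and indices is a bijection.
#'
#' @param phase_set A [phase_set()].
#' @param x Phase names (for `phase_index`) or indices (for `phase_name`).
#' @return Integer indices, or character names.
#' @export
phase_index <- function(phase_set, x) {
  stopifnot(inherits(phase_set, "phase_set"))
  idx <- match(x, phase_set$phases)
  if (anyNA(idx))
    stop("unknown phase name(s): ", paste(x[is.na(idx)], collapse = ", "))
  idx
}

#' @rdname phase_index
#' @export
phase_name <- function(phase_set, x) {
  stopifnot(inherits(phase_set, "phase_set"))
  x <- as.integer(x)
  if (any(x < 1L | x > length(phase_set$phases)))
    stop("phase index out of range 1..", length(phase_set$phases))
  phase_set$phases[x]
}

#' @export
print.phase_set <- function(x, ...) {
  cat("Phase set (", length(x$phases), " procedural phases + pseudo-phase)\n",
      sep = "")
  cat(paste0("  ", seq_along(x$phases), ". ", x$phases, collapse = "\n"), "\n")
  cat("  pseudo-phase: ", x$pseudo_phase, "\n", sep = "")
  invisible(x)
}

# Validate and renormalize one probability vector (or each row of a matrix).
# Entries must be >= 0 and sum to 1 within `tol`; values within tolerance are
# renormalized exactly, so downstream arithmetic sees unit mass.
normalize_probs <- function(x, tol = 1e-9, what = "probability vector") {
  if (is.matrix(x)) {
    if (nrow(x) == 0L) return(x)
    if (any(x < 0))
      stop(what, ": negative probability at row ",
           which(apply(x < 0, 1L, any))[1L])
    s <- rowSums(x)
    bad <- which(abs(s - 1) > tol)
    if (length(bad))
      stop(what, " at row ", bad[1L], ": probability mass ",
           format(s[bad[1L]], digits = 10), " != 1")
    return(x / s)
  }
  if (any(x < 0)) stop(what, ": negative probability")
  s <- sum(x)
  if (abs(s - 1) > tol)
    stop(what, ": probability mass ", format(s, digits = 10), " != 1")
  x / s
}
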