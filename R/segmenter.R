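#' The fixed 10-s segment grid of a recording
#'
#' Segments are half-open, 0-based: segment `i` spans `[10i, 10i + 10)`
#' seconds, anchored at the recording start. A trailing partial segment is
#' dropped.
#'
#' @param duration_s recording length in seconds (>= 10).
#' @param step_s grid step in seconds.
#' @return list with `n_segments`, `step_s` and `starts_s`.
#' @export
segment_grid <- function(duration_s, step_s = 10) {
  stopifnot(duration_s >= step_s)
  n <- floor(duration_s / step_s)
  list(n_segments = as.integer(n), step_s = step_s,
       starts_s = (seq_len(n) - 1) * step_s)
}

# Map free-text annotation kinds onto the binary task's two classes.
# Obstructive/central/mixed apnea variants all count as "apnea"; unknown
# kinds are dropped with a warning.
normalize_event_kinds <- function(events) {
  k <- tolower(trimws(events$kind))
  is_hyp <- grepl("hypopnea", k, fixed = TRUE)
  is_apn <- !is_hyp & grepl("apnea", k, fixed = TRUE)
  unknown <- !(is_hyp | is_apn)
  if (any(unknown)) {
    warning("ignoring ", sum(unknown), " annotation(s) of unrecognised kind: ",
            paste(unique(events$kind[unknown]), collapse = ", "))
    events <- events[!unknown, , drop = FALSE]
    is_hyp <- is_hyp[!unknown]
  }
  events$kind <- ifelse(is_hyp, "hypopnea", "apnea")
  events
}

#' Strict-enclosure segment labeling
#'
#' Labels segment `i` positive iff it is *entirely* contained in one
#' annotated event: there exists an event with `start_s <= 10 i` and
#' `10 i + 10 <= start_s + duration_s`. Apnea and hypopnea both count
#' (binary task); events shorter than 10 s can never enclose a segment.
#'
#' @param events an `annotation_events` table (overlaps are an error).
#' @param duration_s recording length in seconds.
#' @param by_kind if `TRUE`, also return the enclosing event's class per
#'   segment.
#' @return integer 0/1 vector of length `floor(duration_s / 10)`; with
#'   `by_kind = TRUE`, a list with `labels` and `kinds` (`"none"`,
#'   `"apnea"`, `"hypopnea"`).
#' @export
label_segments <- function(events, duration_s, by_kind = FALSE) {
  grid <- segment_grid(duration_s)
  n <- grid$n_segments
  labels <- integer(n)
  kinds <- rep("none", n)
  if (nrow(events) > 0L) {
    events <- normalize_event_kinds(events)
    events <- events[order(events$start_s), , drop = FALSE]
    ends <- events$start_s + events$duration_s
    if (any(events$start_s < 0)) stop("annotation corrupt: negative start")
    if (nrow(events) > 1L &&
        any(events$start_s[-1L] < ends[-nrow(events)] - 1e-9)) {
      stop("annotation corrupt: overlapping events")
    }
    for (i in seq_len(nrow(events))) {
      s <- events$start_s[i]
      e <- s + events$duration_s[i]
      i0 <- ceiling(s / 10)           # first segment starting at/after s
      i1 <- floor(e / 10) - 1         # last segment ending at/before e
      i0 <- max(i0, 0)
      i1 <- min(i1, n - 1)
      if (i1 >= i0) {
        idx <- (i0:i1) + 1L
        labels[idx] <- 1L
        kinds[idx] <- events$kind[i]
      }
    }
  }
  if (by_kind) list(labels = labels, kinds = kinds) else labels
}

#' Context-window extents for a 10-s segment
#'
#' Segment `t` (0-based) is extended by the preceding and following 25 s to
#' a 1-min window, and that window is paired with its two preceding and two
#' succeeding 1-min windows to span 5 min. Consecutive steps therefore slide
#' both windows by exactly 10 s; the 5-min label is the central 1-min
#' segment's label.
#'
#' @param t 0-based segment index.
#' @return list with `min1 = c(10t - 25, 10t + 35)` and
#'   `min5 = c(10t - 145, 10t + 155)` in seconds.
#' @export
window_extent <- function(t) {
  stopifnot(all(t >= 0))
  list(min1 = c(10 * t - 25, 10 * t + 35),
       min5 = c(10 * t - 145, 10 * t + 155))
}

#' Assemble the overlapped per-recording sequence dataset
#'
#' For every recording: preprocess (unless already an `ecg_prep`), build one
#' RRI/RPA window pair per 10-s grid segment, and attach strict-enclosure
#' labels from the matching annotation. The result is the sequence dataset
#' the scorer trains on.
#'
#' @param recordings named list of `ecg_recording` or `ecg_prep` objects.
#' @param annotations named list of `annotation_events` tables, keyed by
#'   record id; every recording must have one.
#' @param manifest optional named character vector record_id -> patient_id
#'   (defaults to each recording's own patient id).
#' @param verbose print progress.
#' @return an object of class `apnea_dataset`: list of per-recording
#'   sequences, each with `record_id`, `patient_id`, `n`, `r1` (2x180xN),
#'   `r5` (2x900xN), `labels`, `kinds`, `flags`, `duration_s`.
#' @export
build_sequences <- function(recordings, annotations, manifest = NULL,
                            verbose = FALSE) {
  ids <- names(recordings)
  if (is.null(ids)) stop("recordings must be a named list")
  missing_ann <- setdiff(ids, names(annotations))
  if (length(missing_ann)) {
    stop("missing annotation for record(s): ",
         paste(missing_ann, collapse = ", "))
  }
  seqs <- vector("list", length(ids))
  names(seqs) <- ids
  for (rid in ids) {
    rec <- recordings[[rid]]
    prep <- if (inherits(rec, "ecg_prep")) rec else preprocess_recording(rec)
    grid <- segment_grid(prep$duration_s)
    lab <- label_segments(annotations[[rid]], prep$duration_s, by_kind = TRUE)
    win <- build_all_windows(prep, grid$n_segments)
    pid <- if (!is.null(manifest) && rid %in% names(manifest)) {
      manifest[[rid]]
    } else {
      prep$patient_id %||% rid
    }
    seqs[[rid]] <- list(
      record_id = rid, patient_id = pid, n = grid$n_segments,
      r1 = win$r1, r5 = win$r5,
      labels = lab$labels, kinds = lab$kinds, flags = win$flags,
      duration_s = prep$duration_s
    )
    if (verbose) message("built ", rid, ": ", grid$n_segments, " steps")
  }
  structure(seqs, class = "apnea_dataset")
}

#' @export
`[.apnea_dataset` <- function(x, i) {
  structure(unclass(x)[i], class = "apnea_dataset")
}

#' @export
print.apnea_dataset <- function(x, ...) {
  n_steps <- sum(vapply(x, function(s) s$n, integer(1)))
  n_pos <- sum(vapply(x, function(s) sum(s$labels), numeric(1)))
  cat(sprintf("<apnea_dataset> %d recordings, %d segments (%.1f%% positive)\n",
              length(x), n_steps, 100 * n_pos / max(1, n_steps)))
  invisible(x)
}
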