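#' Collapse consecutive positive segments into events
#'
#' Counts maximal runs of 1s in a binary segment track. Because one
#' sleep-breathing event longer than 20 s encloses several consecutive 10-s
#' segments, runs -- not positive segments -- are the event count.
#'
#' @param track integer/logical vector of 0/1 segment labels or predictions.
#' @return number of maximal runs of 1s.
#' @export
collapse_events <- function(track) {
  track <- as.integer(track)
  stopifnot(all(track %in% c(0L, 1L)))
  if (length(track) == 0L) return(0L)
  sum(diff(c(0L, track)) == 1L)
}

#' Segment-derived AHI of a binary track
#'
#' Events are counted by [collapse_events()]; total sleep time is inferred
#' from the segment count (`n * 10` seconds). Applied to ground-truth labels
#' this yields the *target* AHI (a perfect classifier's ceiling); applied to
#' thresholded model scores it yields the *predicted* AHI.
#'
#' @param track binary segment track (nonempty).
#' @param step_s segment duration in seconds.
#' @return events per hour.
#' @export
segment_ahi <- function(track, step_s = 10) {
  if (length(track) == 0L) stop("empty segment track")
  collapse_events(track) / (length(track) * step_s / 3600)
}

#' Annotation-derived (true) AHI
#'
#' Apnea plus hypopnea events divided by the recording duration in hours
#' (the simulated recording stands in for total sleep time).
#'
#' @param events an `annotation_events` table.
#' @param duration_s recording length in seconds.
#' @return events per hour.
#' @export
true_ahi <- function(events, duration_s) {
  stopifnot(duration_s > 0)
  nrow(events) / (duration_s / 3600)
}

#' Per-segment confusion counts
#'
#' @param labels binary ground-truth labels.
#' @param scores model scores (or hard 0/1 predictions).
#' @param threshold scores at or above the threshold are positive.
#' @return list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) {
    stop("labels and scores differ in length")
  }
  pred <- as.integer(scores >= threshold)
  labels <- as.integer(labels)
  list(tp = sum(pred == 1L & labels == 1L),
       tn = sum(pred == 0L & labels == 0L),
       fp = sum(pred == 1L & labels == 0L),
       fn = sum(pred == 0L & labels == 1L))
}

#' Accuracy, sensitivity, specificity and F1 from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP). F1 defaults to the standard precision-recall harmonic mean
#' `2 TP / (2 TP + FP + FN)`; `f1 = "sens_spec"` instead returns the
#' harmonic mean of sensitivity and specificity for comparison. Ratios with
#' zero denominators are returned as `NA` (undefined), never as 0.
#'
#' @param counts output of [confusion_counts()].
#' @param f1 which F1 variant to report.
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `f1`.
#' @export
classification_metrics <- function(counts, f1 = c("precision_recall",
                                                  "sens_spec")) {
  f1 <- match.arg(f1)
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("no scored segments")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  f1v <- if (f1 == "precision_recall") {
    ratio(2 * tp, 2 * tp + fp + fn)
  } else if (is.na(sens) || is.na(spec) || sens + spec == 0) {
    NA_real_
  } else {
    2 * sens * spec / (sens + spec)
  }
  c(accuracy = (tp + tn) / total, sensitivity = sens,
    specificity = spec, f1 = f1v)
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic: the fraction of
#' (positive, negative) pairs the scores rank correctly, ties counting 1/2.
#'
#' @param labels binary labels containing both classes.
#' @param scores numeric scores.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) {
    stop("labels and scores differ in length")
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC undefined: both classes must be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Pearson correlation, MAE and RMSE between two AHI vectors
#'
#' @param x,y numeric vectors of equal length >= 2 (e.g. true and predicted
#'   AHI across recordings).
#' @return named vector `r`, `mae`, `rmse`; `r` is `NA` when either input
#'   has zero variance.
#' @export
agreement_metrics <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  r <- if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  c(r = r, mae = mean(abs(y - x)), rmse = sqrt(mean((y - x)^2)))
}

#' Per-segment and per-recording performance report
#'
#' Pools test segments for the classification metrics and computes the
#' true/target/predicted AHI triple per recording, with agreement metrics
#' for the three pairings (true-target, target-predicted, true-predicted).
#' The apnea-only variant drops segments whose enclosing event is a
#' hypopnea from the confusion counts, mirroring an evaluation restricted to
#' normal and apnea segments.
#'
#' @param dataset an `apnea_dataset` (provides labels, kinds, durations).
#' @param scores named list of per-recording score vectors aligned with the
#'   dataset's segment grids.
#' @param annotations named list of `annotation_events` per recording.
#' @param threshold classification threshold for predicted labels.
#' @return list of class `apnea_report` with elements `segment`
#'   (all-events and apnea-only metrics), `ahi` (per-recording data frame),
#'   and `agreement` (3-row data frame of r/MAE/RMSE).
#' @export
performance_report <- function(dataset, scores, annotations,
                               threshold = 0.5) {
  ids <- names(dataset)
  missing_ann <- setdiff(ids, names(annotations))
  if (length(missing_ann)) {
    stop("missing annotation for record(s): ",
         paste(missing_ann, collapse = ", "))
  }
  all_lab <- unlist(lapply(dataset, `[[`, "labels"), use.names = FALSE)
  all_kind <- unlist(lapply(dataset, `[[`, "kinds"), use.names = FALSE)
  all_sc <- unlist(scores[ids], use.names = FALSE)
  if (length(all_sc) != length(all_lab)) {
    stop("scores are not aligned with the dataset segments")
  }
  seg_all <- c(classification_metrics(confusion_counts(all_lab, all_sc,
                                                       threshold)),
               auroc = auroc(all_lab, all_sc))
  keep <- all_kind != "hypopnea"
  seg_apnea <- if (sum(all_lab[keep]) > 0 && sum(1 - all_lab[keep]) > 0) {
    c(classification_metrics(confusion_counts(all_lab[keep], all_sc[keep],
                                              threshold)),
      auroc = auroc(all_lab[keep], all_sc[keep]))
  } else {
    NULL
  }
  ahi <- do.call(rbind, lapply(ids, function(rid) {
    s <- dataset[[rid]]
    data.frame(
      record_id = rid,
      true_ahi = true_ahi(annotations[[rid]], s$duration_s),
      target_ahi = segment_ahi(s$labels),
      predicted_ahi = segment_ahi(as.integer(scores[[rid]] >= threshold)),
      stringsAsFactors = FALSE
    )
  }))
  agree <- function(x, y) {
    if (length(x) >= 2L) return(agreement_metrics(x, y))
    c(r = NA_real_, mae = mean(abs(y - x)), rmse = sqrt(mean((y - x)^2)))
  }
  pairs <- rbind(
    data.frame(pair = "true-target",
               t(agree(ahi$true_ahi, ahi$target_ahi))),
    data.frame(pair = "target-predicted",
               t(agree(ahi$target_ahi, ahi$predicted_ahi))),
    data.frame(pair = "true-predicted",
               t(agree(ahi$true_ahi, ahi$predicted_ahi)))
  )
  structure(list(segment = list(all_events = seg_all,
                                apnea_only = seg_apnea),
                 ahi = ahi, agreement = pairs),
            class = "apnea_report")
}

#' @export
print.apnea_report <- function(x, digits = 3, ...) {
  cat("Per-segment metrics (pooled", nrow(x$ahi), "recordings):\n")
  print(round(x$segment$all_events, digits))
  if (!is.null(x$segment$apnea_only)) {
    cat("Apnea-only (hypopnea segments excluded):\n")
    print(round(x$segment$apnea_only, digits))
  }
  cat("\nAHI agreement across recordings:\n")
  pr <- x$agreement
  pr[, -1] <- round(pr[, -1], digits)
  print(pr, row.names = FALSE)
  invisible(x)
}
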