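# Shared fixtures and independent oracles used across the suite.

events_df <- function(start_s, duration_s,
                      kind = rep("apnea", length(start_s))) {
  df <- data.frame(kind = kind, start_s = start_s, duration_s = duration_s,
                   stringsAsFactors = FALSE)
  class(df) <- c("annotation_events", "data.frame")
  df
}

# Brute-force strict-enclosure labeling: scan every segment against every
# event independently of the vectorised implementation.
oracle_label_segments <- function(events, duration_s) {
  n <- floor(duration_s / 10)
  out <- integer(n)
  for (i in seq_len(n)) {
    a <- 10 * (i - 1)
    b <- a + 10
    for (j in seq_len(nrow(events))) {
      s <- events$start_s[j]
      e <- s + events$duration_s[j]
      if (s <= a && b <= e) {
        out[i] <- 1L
        break
      }
    }
  }
  out
}

# Random non-overlapping schedule for the labeling oracle; durations may be
# below 10 s on purpose.
random_schedule <- function(duration_s, n_events, dur_range = c(5, 60)) {
  starts <- numeric(0)
  durs <- numeric(0)
  t <- runif(1, 0, 30)
  for (i in seq_len(n_events)) {
    d <- runif(1, dur_range[1], dur_range[2])
    if (t + d >= duration_s) break
    starts <- c(starts, t)
    durs <- c(durs, d)
    t <- t + d + runif(1, 0.5, 40)
  }
  events_df(starts, durs)
}

# Pairwise-counting AUROC oracle (all positive-negative pairs).
oracle_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Trapezoidal integration of the empirical ROC curve.
trapezoid_auroc <- function(labels, scores) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- fpr <- numeric(length(th))
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  for (i in seq_along(th)) {
    pred <- scores >= th[i]
    tpr[i] <- sum(pred & labels == 1) / np
    fpr[i] <- sum(pred & labels == 0) / nn
  }
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Tiny architecture for fast model tests.
tiny_model_config <- function(...) {
  model_config(fd_channels = c(4L, 6L), fd_kernel = 3L,
               fs_channels = c(4L, 6L), fs_kernel = 5L, fs_pool = 4L,
               se_reduction = 2L, feature_dim = 8L, gru_hidden = 7L,
               dropout = 0, ...)
}

random_sequence <- function(n, seed = NULL, p_pos = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  list(n = as.integer(n),
       r1 = array(rnorm(2 * 180 * n), c(2, 180, n)),
       r5 = array(rnorm(2 * 900 * n), c(2, 900, n)),
       labels = rbinom(n, 1, p_pos))
}

# A small annotated corpus built once per test file when needed.
make_corpus <- function(n, duration_s, seed = 77, ...) {
  cfg <- sim_config(n_recordings = n, duration_s = duration_s, seed = seed,
                    ...)
  recs <- list()
  anns <- list()
  for (i in seq_len(n)) {
    s <- simulate_recording(cfg, i)
    recs[[s$record_id]] <- s$ecg
    anns[[s$record_id]] <- s$events
  }
  list(cfg = cfg, recordings = recs, annotations = anns)
}
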