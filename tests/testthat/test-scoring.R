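test_that("event collapsing counts maximal runs of ones", {
  expect_equal(collapse_events(c(0, 0, 0)), 0L)
  expect_equal(collapse_events(c(0, 1, 1, 1, 0, 1, 0)), 2L)
  expect_equal(collapse_events(c(1, 1, 0, 0, 1)), 2L)
  expect_equal(collapse_events(integer(0)), 0L)

  # exhaustive: all 2^10 tracks of length 10 against a run-length oracle
  for (code in 0:1023) {
    track <- as.integer(intToBits(code))[1:10]
    r <- rle(track)
    expect_identical(collapse_events(track),
                     sum(r$values == 1L))
  }
})

test_that("segment AHI divides collapsed events by inferred sleep time", {
  track <- c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0)  # 12 segments, 1 run
  expect_equal(segment_ahi(track), 30)
  expect_equal(segment_ahi(rep(0, 100)), 0)
  # 8 h of segments with 160 isolated events -> 20/h
  track <- rep(0L, 2880)
  track[seq(1, by = 18, length.out = 160)] <- 1L
  expect_equal(segment_ahi(track), 20)
  expect_error(segment_ahi(integer(0)), "empty")
})

test_that("appending empty segments dilutes AHI only through the denominator", {
  track <- c(1, 1, 0, 1, 0, 0)
  a0 <- segment_ahi(track)
  a1 <- segment_ahi(c(track, rep(0, 6)))
  expect_equal(collapse_events(c(track, rep(0, 6))), collapse_events(track))
  expect_equal(a1, a0 / 2)
})

test_that("true AHI is the annotated event count per hour", {
  expect_equal(true_ahi(events_df(numeric(0), numeric(0)), 3600), 0)
  ev <- events_df(seq(0, by = 100, length.out = 45), rep(15, 45))
  expect_equal(true_ahi(ev, 1.5 * 3600), 30)
  ev5 <- events_df(seq(0, by = 1000, length.out = 5), rep(20, 5))
  expect_equal(true_ahi(ev5, 7200), 2.5)
})

test_that("one long event spans several segments but counts once", {
  for (k in 1:5) {
    ev <- events_df(10, 10 * k + 2)
    lab <- label_segments(ev, 200)
    expect_equal(sum(lab), k)
    expect_equal(collapse_events(lab), 1L)
  }
})

test_that("events separated by under 20 s can merge into one counted run", {
  # two annotated events, but their labeled segments are adjacent
  ev <- events_df(c(0, 20), c(20, 20))
  lab <- label_segments(ev, 60)
  expect_equal(sum(lab), 4)
  expect_equal(collapse_events(lab), 1L)  # documented undercount
})

test_that("confusion counts follow the four definitions", {
  cc <- confusion_counts(c(1, 0, 1, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(cc, list(tp = 1L, tn = 1L, fp = 1L, fn = 1L))
  cc <- confusion_counts(c(1, 1, 0), c(1, 1, 0))
  expect_equal(cc$fp + cc$fn, 0L)
  cc <- confusion_counts(rep(0, 7), rep(0.6, 7))
  expect_equal(cc$fp, 7L)
  expect_error(confusion_counts(c(1, 0), 0.5), "length")
})

test_that("classification metrics match their closed forms", {
  m <- classification_metrics(list(tp = 50, tn = 50, fp = 0, fn = 0))
  expect_equal(unname(m), c(1, 1, 1, 1))
  m <- classification_metrics(list(tp = 1, tn = 1, fp = 1, fn = 1))
  expect_equal(unname(m), c(0.5, 0.5, 0.5, 0.5))
  # undefined ratios surface as NA, not 0
  m <- classification_metrics(list(tp = 0, tn = 5, fp = 0, fn = 0))
  expect_true(is.na(m[["sensitivity"]]))
  expect_equal(m[["specificity"]], 1)
  # literal sensitivity/specificity harmonic-mean variant
  m <- classification_metrics(list(tp = 30, tn = 60, fp = 20, fn = 10),
                              f1 = "sens_spec")
  sens <- 30 / 40; spec <- 60 / 80
  expect_equal(m[["f1"]], 2 * sens * spec / (sens + spec))
})

test_that("AUROC equals pairwise counting and trapezoidal integration", {
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auroc(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)), 0.75)
  expect_error(auroc(c(1, 1), c(0.2, 0.4)), "both classes")

  set.seed(11)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    scores <- round(rnorm(n), sample(c(1, 2, 8), 1))  # force some ties
    a <- auroc(labels, scores)
    expect_equal(a, oracle_auroc(labels, scores), tolerance = 1e-12)
    expect_equal(a, trapezoid_auroc(labels, scores), tolerance = 1e-12)
  }
})

test_that("agreement metrics match direct covariance formulas", {
  x <- c(3, 7, 1)
  m <- agreement_metrics(x, x)
  expect_equal(unname(m), c(1, 0, 0))
  m <- agreement_metrics(c(0, 1, 2), c(1, 2, 3))
  expect_equal(unname(m), c(1, 1, 1))
  m <- agreement_metrics(c(0, 0, 3), c(0, 0, 0))
  expect_equal(m[["mae"]], 1)
  expect_equal(m[["rmse"]], sqrt(3))
  expect_true(is.na(agreement_metrics(c(1, 1), c(0, 2))[["r"]]))

  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    m <- agreement_metrics(x, y)
    expect_equal(m[["r"]], cov(x, y) / (sd(x) * sd(y)), tolerance = 1e-12)
    expect_equal(m[["mae"]], sum(abs(y - x)) / 30, tolerance = 1e-12)
    expect_equal(m[["rmse"]], sqrt(sum((y - x)^2) / 30), tolerance = 1e-12)
  }
})

test_that("the report reproduces a perfect predictor and the table layout", {
  corpus <- make_corpus(3, 240, seed = 14, event_rate_per_h = c(30, 60))
  ds <- build_sequences(corpus$recordings, corpus$annotations)
  scores <- lapply(ds, function(s) as.numeric(s$labels))
  rep <- performance_report(ds, scores, corpus$annotations)
  expect_equal(rep$ahi$predicted_ahi, rep$ahi$target_ahi)
  ag <- rep$agreement
  expect_equal(ag$pair,
               c("true-target", "target-predicted", "true-predicted"))
  expect_equal(ag$r[ag$pair == "target-predicted"], 1)
  expect_equal(ag$mae[ag$pair == "target-predicted"], 0)
  expect_named(ag, c("pair", "r", "mae", "rmse"))
  expect_equal(rep$segment$all_events[["accuracy"]], 1)
})

test_that("the apnea-only variant excludes hypopnea-labeled segments", {
  s1 <- list(record_id = "a", n = 6L,
             labels = c(0L, 1L, 1L, 0L, 1L, 0L),
             kinds = c("none", "apnea", "hypopnea", "none", "apnea", "none"),
             duration_s = 60)
  ds <- structure(list(a = s1), class = "apnea_dataset")
  scores <- list(a = c(0.1, 0.9, 0.2, 0.3, 0.8, 0.4))
  ann <- list(a = events_df(c(10, 40), c(12, 15),
                            kind = c("apnea", "hypopnea")))
  rep <- performance_report(ds, scores, ann)
  keep <- s1$kinds != "hypopnea"
  cc <- confusion_counts(s1$labels[keep], scores$a[keep])
  expect_equal(rep$segment$apnea_only[["accuracy"]],
               classification_metrics(cc)[["accuracy"]])
  expect_equal(rep$segment$apnea_only[["auroc"]],
               auroc(s1$labels[keep], scores$a[keep]))
})
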