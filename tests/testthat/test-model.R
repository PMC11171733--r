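test_that("feature extraction returns finite 128-vectors of fixed length", {
  m <- apnea_model(seed = 2)
  r1 <- matrix(rnorm(2 * 180), 2, 180)
  r5 <- matrix(rnorm(2 * 900), 2, 900)
  h <- extract_features(m, r1, r5)
  expect_length(h, 128L)
  expect_true(all(is.finite(h)))

  # zero inputs: still finite (numerical sanity)
  h0 <- extract_features(m, matrix(0, 2, 180), matrix(0, 2, 900))
  expect_true(all(is.finite(h0)))

  expect_error(extract_features(m, matrix(0, 2, 100), r5), "shapes")
  expect_error(extract_features(m, r1 * NA, r5), "finite")
})

test_that("batched feature extraction is independent across the batch", {
  m <- apnea_model(seed = 3)
  set.seed(3)
  r1 <- array(rnorm(2 * 180), c(2, 180, 1))
  r5 <- array(rnorm(2 * 900), c(2, 900, 1))
  h1 <- extract_features(m, r1[, , 1], r5[, , 1])
  r1b <- array(r1, c(2, 180, 4))
  r5b <- array(r5, c(2, 900, 4))
  hb <- extract_features(m, r1b, r5b)
  expect_equal(dim(hb), c(128L, 4L))
  for (j in 1:4) expect_equal(hb[, j], h1, tolerance = 1e-14)
})

test_that("sequence scoring emits one in-range score per step", {
  m <- apnea_model(tiny_model_config(), seed = 4)
  H <- matrix(rnorm(8), 8, 1)
  out <- score_sequence(m, H)
  expect_length(out$scores, 1L)
  expect_true(out$scores > 0 && out$scores < 1)

  H <- matrix(rnorm(8 * 25), 8, 25)
  out <- score_sequence(m, H)
  expect_length(out$scores, 25L)
  expect_true(all(out$scores > 0 & out$scores < 1))
  expect_error(score_sequence(m, matrix(numeric(0), 8, 0)), "empty")
})

test_that("unidirectional scoring is causal under truncation", {
  m <- apnea_model(tiny_model_config(), seed = 5)
  H <- matrix(rnorm(8 * 30), 8, 30)
  full <- score_sequence(m, H)$scores
  half <- score_sequence(m, H[, 1:14])$scores
  expect_equal(half, full[1:14], tolerance = 1e-14)
})

test_that("permuting two distant steps only changes later outputs", {
  m <- apnea_model(tiny_model_config(), seed = 6)
  H <- matrix(rnorm(8 * 30), 8, 30)
  Hp <- H
  Hp[, c(10, 22)] <- H[, c(22, 10)]
  s0 <- score_sequence(m, H)$scores
  s1 <- score_sequence(m, Hp)$scores
  expect_equal(s1[1:9], s0[1:9], tolerance = 1e-14)
  expect_gt(max(abs(s1[10:30] - s0[10:30])), 0)
})

test_that("whole-recording forward equals the two-stage composition", {
  m <- apnea_model(seed = 7)
  set.seed(7)
  s <- random_sequence(12)
  ds <- structure(list(rec = c(s, record_id = "rec")),
                  class = "apnea_dataset")
  p1 <- predict(m, ds)$rec
  expect_length(p1, 12L)
  nx <- sleepahi:::normalize_inputs(m, s$r1, s$r5)
  H <- sleepahi:::extractor_forward(m$params, m$bn_state, m$config,
                                    nx$r1, nx$r5)$H
  p2 <- score_sequence(m, H)$scores
  expect_equal(p1, p2, tolerance = 1e-14)
  # eval-mode determinism: bitwise identical repeat
  expect_identical(p1, predict(m, ds)$rec)
})

test_that("analytic gradients match finite differences in both modes", {
  set.seed(8)
  cfg <- tiny_model_config()
  m <- apnea_model(cfg, seed = 8)
  seqs <- list(random_sequence(4), random_sequence(3))
  get_in <- function(tree, path) {
    for (k in path) tree <- tree[[k]]
    tree
  }
  set_in <- function(tree, path, i, val) {
    if (length(path) == 1) {
      tree[[path[[1]]]][i] <- val
      return(tree)
    }
    tree[[path[[1]]]] <- set_in(tree[[path[[1]]]], path[-1], i, val)
    tree
  }
  paths <- list(list("fd", 1, "W"), list("fd", 2, "gamma"),
                list("fs", 1, "W"), list("fs", 2, "beta"),
                list("se", "W1"), list("fc1", "W"),
                list("gru", "Wx"), list("gru", "Wh"),
                list("fc2", "W"))
  for (train in c(TRUE, FALSE)) {
    bl <- sleepahi:::batch_loss(m, seqs, w_pos = 2, chunk = 5L,
                                train = train, grad = TRUE)
    for (pp in paths) {
      p <- get_in(m$params, pp)
      g <- get_in(bl$grads, pp)
      i <- sample(length(p), 1)
      eps <- 1e-6
      f <- function(d) {
        mm <- m
        mm$params <- set_in(mm$params, pp, i, p[i] + d)
        sleepahi:::batch_loss(mm, seqs, w_pos = 2, chunk = 5L,
                              train = train, grad = FALSE)$loss
      }
      gn <- (f(eps) - f(-eps)) / (2 * eps)
      expect_equal(g[i], gn, tolerance = 1e-4)
    }
  }
})

test_that("bidirectional mode produces valid scores and gradients", {
  set.seed(9)
  cfg <- tiny_model_config(bidirectional = TRUE)
  m <- apnea_model(cfg, seed = 9)
  s <- random_sequence(6)
  out <- score_sequence(m, matrix(rnorm(8 * 6), 8, 6))
  expect_length(out$scores, 6L)
  bl <- sleepahi:::batch_loss(m, list(s), w_pos = 1, chunk = 6L,
                              train = TRUE, grad = TRUE)
  expect_true(is.finite(bl$loss))
  expect_named(bl$grads, c("fd", "fs", "se", "fc1", "gru", "fc2", "gru_rev"))
  # spot-check one reverse-GRU gradient numerically
  p <- m$params$gru_rev$Wx
  i <- 5L
  eps <- 1e-6
  f <- function(d) {
    mm <- m
    mm$params$gru_rev$Wx[i] <- p[i] + d
    sleepahi:::batch_loss(mm, list(s), w_pos = 1, chunk = 6L,
                          train = TRUE, grad = FALSE)$loss
  }
  expect_equal(bl$grads$gru_rev$Wx[i], (f(eps) - f(-eps)) / (2 * eps),
               tolerance = 1e-4)
})

test_that("a strongly modulated toy corpus is overfit within 200 steps", {
  corpus <- make_corpus(4, 300, seed = 55,
                        event_rate_per_h = c(40, 60),
                        modulation_depth_apnea = 0.5,
                        modulation_depth_hypopnea = 0.25,
                        noise_sd = 0.02)
  ds <- build_sequences(corpus$recordings, corpus$annotations)
  m <- apnea_model(seed = 1)
  m$norm <- sleepahi:::compute_norm_stats(ds)
  nd <- ds
  labs <- unlist(lapply(ds, `[[`, "labels"))
  expect_gt(sum(labs), 5)
  w_pos <- sum(labs == 0) / sum(labs == 1)
  adam <- sleepahi:::adam_init(m$params)
  set.seed(1)
  best_acc <- 0
  for (step in 1:200) {
    bl <- sleepahi:::batch_loss(m, nd, w_pos = w_pos, chunk = 256L,
                                train = TRUE, grad = TRUE)
    m$bn_state <- bl$bn_state
    up <- sleepahi:::adam_step(m$params, bl$grads, adam, 3e-3)
    m$params <- up$params
    adam <- up$state
    if (step %% 10 == 0) {
      sc <- unlist(predict(m, ds))
      acc <- mean((sc >= 0.5) == (labs == 1))
      best_acc <- max(best_acc, acc)
      if (best_acc >= 0.97) break
    }
  }
  expect_gte(best_acc, 0.95)
})
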