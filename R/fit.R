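#' Training protocol settings
#'
#' Defaults follow the reference optimisation protocol: Adam with betas
#' (0.9, 0.999), initial learning rate 1e-4, batches of 16 whole recordings,
#' up to 1000 epochs with a 10-epoch warmup during which neither the
#' learning-rate schedule nor early stopping may trigger, plateau scheduling
#' with factor 0.1 and patience 10, and early stopping on the monitored
#' validation loss with patience 30.
#'
#' @param max_epochs,warmup_epochs epoch budget and warmup length.
#' @param batch_recordings recordings per optimisation step (padded+masked).
#' @param lr initial learning rate.
#' @param adam_betas length-2 Adam moment decay rates.
#' @param sched_factor,sched_patience plateau learning-rate schedule.
#' @param early_stop_patience epochs without improvement before stopping.
#' @param k_folds default fold count for cross-validation utilities.
#' @param pos_weight positive-class loss weight; `NULL` computes
#'   negatives/positives on the training labels.
#' @param chunk windows per feature-extractor chunk (memory/speed knob).
#' @param monitor checkpoint/early-stop criterion.
#' @param seed RNG seed for shuffling, dropout and initialisation.
#' @return an object of class `train_control`.
#' @export
train_control <- function(max_epochs = 1000L, warmup_epochs = 10L,
                          batch_recordings = 16L, lr = 1e-4,
                          adam_betas = c(0.9, 0.999),
                          sched_factor = 0.1, sched_patience = 10L,
                          early_stop_patience = 30L, k_folds = 5L,
                          pos_weight = NULL, chunk = 512L,
                          monitor = c("loss", "auroc"), seed = 1L) {
  stopifnot(warmup_epochs < max_epochs, sched_factor > 0, sched_factor < 1,
            batch_recordings >= 1, lr > 0, length(adam_betas) == 2L)
  structure(list(max_epochs = as.integer(max_epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 batch_recordings = as.integer(batch_recordings),
                 lr = lr, adam_betas = adam_betas,
                 sched_factor = sched_factor,
                 sched_patience = as.integer(sched_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 k_folds = as.integer(k_folds), pos_weight = pos_weight,
                 chunk = as.integer(chunk),
                 monitor = match.arg(monitor), seed = as.integer(seed)),
            class = "train_control")
}

#' Patient-grouped train/test split
#'
#' Assigns whole patients to the test side until roughly `test_fraction` of
#' the recordings are held out, so no patient contributes to both sides.
#'
#' @param manifest named character vector record_id -> patient_id.
#' @param test_fraction target fraction of recordings in the test set
#'   (default mirrors a 245/1465 hold-out, about one sixth).
#' @param seed RNG seed for the patient shuffle.
#' @return list with character vectors `train` and `test` of record ids.
#' @export
split_train_test <- function(manifest, test_fraction = 245 / 1465,
                             seed = 1L) {
  patients <- unique(manifest)
  if (length(patients) < 2L) {
    stop("cannot split: corpus contains a single patient")
  }
  set.seed(derive_seed(seed, 303L))
  patients <- sample(patients)
  target <- round(length(manifest) * test_fraction)
  test_pat <- character(0)
  n_test <- 0L
  for (p in patients) {
    if (n_test >= target) break
    test_pat <- c(test_pat, p)
    n_test <- n_test + sum(manifest == p)
  }
  test <- names(manifest)[manifest %in% test_pat]
  train <- setdiff(names(manifest), test)
  if (length(train) == 0L) stop("test fraction leaves no training recordings")
  list(train = train, test = test)
}

#' Patient-disjoint cross-validation folds
#'
#' Partitions the patients of the training pool into `k` near-equal groups;
#' each fold's validation set is one group's recordings and its training set
#' is the rest. Folds are disjoint by patient and partition the pool.
#'
#' @param train_pool named character vector record_id -> patient_id.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return list of `k` lists with `train` and `validation` record ids.
#' @export
make_folds <- function(train_pool, k = 5L, seed = 1L) {
  patients <- unique(train_pool)
  if (length(patients) < k) stop("fewer patients than folds")
  set.seed(derive_seed(seed, 404L))
  patients <- sample(patients)
  grp <- rep(seq_len(k), length.out = length(patients))
  folds <- lapply(seq_len(k), function(f) {
    val_pat <- patients[grp == f]
    val <- names(train_pool)[train_pool %in% val_pat]
    list(train = setdiff(names(train_pool), val), validation = val)
  })
  assert_patient_disjoint(folds, train_pool)
  folds
}

assert_patient_disjoint <- function(folds, manifest) {
  for (f in folds) {
    shared <- intersect(unique(manifest[f$train]),
                        unique(manifest[f$validation]))
    if (length(shared)) {
      stop("fold not patient-disjoint: ", paste(shared, collapse = ", "))
    }
  }
  invisible(TRUE)
}

# ---- plateau schedule / early stopping (pure helpers) -------------------

plateau_init <- function(lr) list(lr = lr, best = Inf, wait = 0L)

# One epoch's scheduler update; `active` is FALSE during warmup.
plateau_step <- function(state, value, factor, patience, active = TRUE,
                         eps = 1e-8) {
  if (value < state$best - eps) {
    state$best <- value
    state$wait <- 0L
  } else if (active) {
    state$wait <- state$wait + 1L
    if (state$wait >= patience) {
      state$lr <- state$lr * factor
      state$wait <- 0L
    }
  }
  state
}

early_stop_init <- function() list(best = Inf, wait = 0L, stop = FALSE)

early_stop_step <- function(state, value, patience, active = TRUE,
                            eps = 1e-8) {
  if (value < state$best - eps) {
    state$best <- value
    state$wait <- 0L
  } else if (active) {
    state$wait <- state$wait + 1L
    if (state$wait >= patience) state$stop <- TRUE
  }
  state
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, betas = c(0.9, 0.999),
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  state$m <- tree_map(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) b2 * v + (1 - b2) * g * g, state$v, grads)
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  params <- tree_map(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                     params, state$m, state$v)
  list(params = params, state = state)
}

# ---- batched loss / gradients -------------------------------------------

stable_bce <- function(o, y) {
  pmax(o, 0) - o * y + log1p(exp(-abs(o)))
}

# Concatenate the (already normalised) windows of a batch of sequences.
concat_windows <- function(seqs) {
  Ts <- vapply(seqs, `[[`, integer(1), "n")
  Mtot <- sum(Ts)
  X1 <- array(0, dim = c(2L, 180L, Mtot))
  X5 <- array(0, dim = c(2L, 900L, Mtot))
  off <- 0L
  for (s in seqs) {
    X1[, , off + seq_len(s$n)] <- s$r1
    X5[, , off + seq_len(s$n)] <- s$r5
    off <- off + s$n
  }
  list(X1 = X1, X5 = X5, Ts = Ts, Mtot = Mtot)
}

# Forward (and optionally backward) pass over a batch of whole recordings.
# Channel normalisation is applied to the concatenated batch copy, so the
# dataset itself is never duplicated. Returns the masked weighted BCE and,
# with grad = TRUE, the full gradient tree (aligned with params) and the
# updated batch-norm running stats.
batch_loss <- function(model, seqs, w_pos = 1, chunk = 512L,
                       train = FALSE, grad = FALSE) {
  params <- model$params
  cfg <- model$config
  bn <- model$bn_state
  cw <- concat_windows(seqs)
  nx <- normalize_inputs(model, cw$X1, cw$X5)
  cw$X1 <- nx$r1
  cw$X5 <- nx$r5
  Ts <- cw$Ts; B <- length(seqs); Tmax <- max(Ts); Mtot <- cw$Mtot
  fdim <- cfg$feature_dim

  H_all <- matrix(0, fdim, Mtot)
  for (i0 in seq(1L, Mtot, by = chunk)) {
    i1 <- min(Mtot, i0 + chunk - 1L)
    ef <- extractor_forward(params, bn, cfg,
                            cw$X1[, , i0:i1, drop = FALSE],
                            cw$X5[, , i0:i1, drop = FALSE],
                            train = train, cache = FALSE)
    H_all[, i0:i1] <- ef$H
    if (train) bn <- ef$bn_state
  }

  Hseq <- array(0, dim = c(fdim, Tmax, B))
  y <- matrix(0, Tmax, B)
  mask <- matrix(0, Tmax, B)
  off <- 0L
  for (b in seq_len(B)) {
    n <- Ts[b]
    Hseq[, seq_len(n), b] <- H_all[, off + seq_len(n)]
    y[seq_len(n), b] <- seqs[[b]]$labels
    mask[seq_len(n), b] <- 1
    off <- off + n
  }

  seqf <- sequence_forward(params, cfg, Hseq, cache = grad)
  G <- seqf$G
  hidG <- dim(G)[1]
  dmask <- NULL
  if (train && cfg$dropout > 0) {
    dmask <- array(rbinom(length(G), 1L, 1 - cfg$dropout) / (1 - cfg$dropout),
                   dim = dim(G))
    G <- G * dmask
  }
  Gm <- matrix(G, nrow = hidG)
  o <- matrix(params$fc2$W %*% Gm + params$fc2$b, Tmax, B)
  w <- mask * (1 + (w_pos - 1) * y)
  wsum <- sum(w)
  loss <- sum(w * stable_bce(o, y)) / wsum
  scores <- sigmoid(o)
  out <- list(loss = loss, scores = scores, mask = mask, y = y, Ts = Ts)
  if (!grad) return(out)

  do <- w * (scores - y) / wsum
  dov <- matrix(as.numeric(do), nrow = 1L)
  g_fc2 <- list(W = tcrossprod(dov, Gm), b = sum(do))
  dG <- crossprod(params$fc2$W, dov)
  dim(dG) <- dim(G)
  if (!is.null(dmask)) dG <- dG * dmask

  hid <- cfg$gru_hidden
  if (cfg$bidirectional) {
    rev_idx <- rev(seq_len(Tmax))
    g1 <- gru_backward(dG[seq_len(hid), , , drop = FALSE], Hseq,
                       params$gru, seqf$fw$cache)
    dGb <- dG[hid + seq_len(hid), rev_idx, , drop = FALSE]
    g2 <- gru_backward(dGb, Hseq[, rev_idx, , drop = FALSE],
                       params$gru_rev, seqf$bw$cache)
    dHseq <- g1$dX + g2$dX[, rev_idx, , drop = FALSE]
    g_gru <- g1$grads
    g_gru_rev <- g2$grads
  } else {
    g1 <- gru_backward(dG, Hseq, params$gru, seqf$fw$cache)
    dHseq <- g1$dX
    g_gru <- g1$grads
    g_gru_rev <- NULL
  }

  dH_all <- matrix(0, fdim, Mtot)
  off <- 0L
  for (b in seq_len(B)) {
    n <- Ts[b]
    dH_all[, off + seq_len(n)] <- dHseq[, seq_len(n), b]
    off <- off + n
  }

  g_ext <- NULL
  for (i0 in seq(1L, Mtot, by = chunk)) {
    i1 <- min(Mtot, i0 + chunk - 1L)
    ef <- extractor_forward(params, model$bn_state, cfg,
                            cw$X1[, , i0:i1, drop = FALSE],
                            cw$X5[, , i0:i1, drop = FALSE],
                            train = train, cache = TRUE)
    gb <- extractor_backward(params, cfg, ef$cache,
                             dH_all[, i0:i1, drop = FALSE])
    g_ext <- if (is.null(g_ext)) gb else tree_map(`+`, g_ext, gb)
  }

  grads <- list(fd = g_ext$fd, fs = g_ext$fs, se = g_ext$se,
                fc1 = g_ext$fc1, gru = g_gru, fc2 = g_fc2)
  if (cfg$bidirectional) grads$gru_rev <- g_gru_rev
  out$grads <- grads
  out$bn_state <- bn
  out
}

# Channel-wise normalisation statistics over a set of sequences.
compute_norm_stats <- function(seqs) {
  acc <- function(get) {
    s <- 0; s2 <- 0; n <- 0
    for (q in seqs) {
      v <- get(q)
      s <- s + sum(v); s2 <- s2 + sum(v^2); n <- n + length(v)
    }
    m <- s / n
    list(mean = m, sd = max(sqrt(pmax(s2 / n - m^2, 0)), 1e-6))
  }
  a <- acc(function(q) q$r1[1L, , ])
  b <- acc(function(q) q$r1[2L, , ])
  cc <- acc(function(q) q$r5[1L, , ])
  d <- acc(function(q) q$r5[2L, , ])
  list(mean = c(r1_rri = a$mean, r1_rpa = b$mean,
                r5_rri = cc$mean, r5_rpa = d$mean),
       sd = c(r1_rri = a$sd, r1_rpa = b$sd, r5_rri = cc$sd, r5_rpa = d$sd))
}

#' Fit the apnea segment scorer
#'
#' Trains the dual-path CNN + GRU sequence model on an [build_sequences()]
#' dataset with masked, class-weighted binary cross-entropy over batches of
#' whole recordings (padded to the batch maximum). After the warmup the
#' learning rate drops by `sched_factor` whenever the monitored loss stalls
#' for `sched_patience` epochs, and training stops early after
#' `early_stop_patience` stalled epochs. The returned object holds the
#' best-monitor checkpoint.
#'
#' @param data an `apnea_dataset` used for training.
#' @param val optional `apnea_dataset` monitored for scheduling, early
#'   stopping and checkpoint selection (training loss is monitored when
#'   absent).
#' @param config a [model_config()].
#' @param control a [train_control()].
#' @param verbose print per-epoch progress.
#' @return an object of class `apnea_scorer`: list with `model` (the best
#'   checkpoint, an `apnea_model`), `history` (per-epoch data frame),
#'   `control`, `pos_weight` and `call`.
#' @export
apnea_scorer <- function(data, val = NULL, config = model_config(),
                         control = train_control(), verbose = FALSE) {
  stopifnot(inherits(data, "apnea_dataset"), length(data) >= 1L)
  set.seed(derive_seed(control$seed, 202L))
  model <- apnea_model(config, seed = control$seed)
  model$norm <- compute_norm_stats(data)
  nd <- data
  nv <- val

  labs <- unlist(lapply(data, `[[`, "labels"), use.names = FALSE)
  n_pos <- sum(labs == 1L)
  n_neg <- sum(labs == 0L)
  w_pos <- control$pos_weight %||%
    if (n_pos > 0) n_neg / n_pos else 1
  adam <- adam_init(model$params)
  sched <- plateau_init(control$lr)
  es <- early_stop_init()
  best <- list(value = Inf, params = model$params, bn = model$bn_state,
               epoch = 0L)
  hist <- list()

  for (epoch in seq_len(control$max_epochs)) {
    ord <- sample(length(nd))
    ep_loss <- 0
    ep_n <- 0
    for (i0 in seq(1L, length(ord), by = control$batch_recordings)) {
      idx <- ord[i0:min(length(ord), i0 + control$batch_recordings - 1L)]
      bl <- batch_loss(model, nd[idx], w_pos = w_pos,
                       chunk = control$chunk, train = TRUE, grad = TRUE)
      if (!is.finite(bl$loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      }
      model$bn_state <- bl$bn_state
      up <- adam_step(model$params, bl$grads, adam, sched$lr,
                      control$adam_betas)
      model$params <- up$params
      adam <- up$state
      ep_loss <- ep_loss + bl$loss * length(idx)
      ep_n <- ep_n + length(idx)
    }
    train_loss <- ep_loss / ep_n
    val_loss <- NA_real_
    if (!is.null(nv)) {
      vl <- batch_loss(model, nv, w_pos = w_pos, chunk = control$chunk,
                       train = FALSE, grad = FALSE)
      val_loss <- vl$loss
    }
    monitor <- if (!is.null(nv)) val_loss else train_loss
    warm_done <- epoch > control$warmup_epochs
    sched <- plateau_step(sched, monitor, control$sched_factor,
                          control$sched_patience, active = warm_done)
    es <- early_stop_step(es, monitor, control$early_stop_patience,
                          active = warm_done)
    if (monitor < best$value) {
      best <- list(value = monitor, params = model$params,
                   bn = model$bn_state, epoch = epoch)
    }
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                val_loss = val_loss, lr = sched$lr)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %s  lr %.2e", epoch,
                      train_loss,
                      if (is.na(val_loss)) "-" else sprintf("%.4f", val_loss),
                      sched$lr))
    }
    if (es$stop) break
  }

  model$params <- best$params
  model$bn_state <- best$bn
  model$trained <- TRUE
  structure(list(model = model, history = do.call(rbind, hist),
                 control = control, pos_weight = w_pos,
                 best_epoch = best$epoch, call = match.call()),
            class = "apnea_scorer")
}

#' @export
print.apnea_scorer <- function(x, ...) {
  cat("Apnea segment scorer (CNN feature extractor + GRU)\n")
  cat(sprintf("  trained %d epoch(s), best monitored loss %.4f at epoch %d\n",
              nrow(x$history), min(x$history$val_loss, x$history$train_loss,
                                   na.rm = TRUE), x$best_epoch))
  cat(sprintf("  positive-class weight %.2f, final lr %.2e\n",
              x$pos_weight, tail(x$history$lr, 1)))
  print(x$model)
  invisible(x)
}

#' @export
summary.apnea_scorer <- function(object, ...) {
  h <- object$history
  cat("Training history (", nrow(h), " epochs):\n", sep = "")
  print(h[unique(pmin(nrow(h), c(1, seq(5, nrow(h), by = 5), nrow(h)))), ],
        row.names = FALSE)
  invisible(object)
}

#' @export
predict.apnea_scorer <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' @export
coef.apnea_scorer <- function(object, ...) {
  unlist(object$model$params)
}

#' @export
plot.apnea_scorer <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = "training curve", ...)
  if (any(!is.na(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = c(1, 2),
                     bty = "n")
  }
  invisible(x)
}

#' Evaluate fold checkpoints on a held-out test set
#'
#' Applies each fitted fold model to the test recordings, computes pooled
#' per-segment metrics and AHI agreement via [performance_report()], and
#' appends mean and standard-deviation rows across folds.
#'
#' @param fits list of `apnea_scorer` (or `apnea_model`) objects.
#' @param test_data an `apnea_dataset` of test recordings.
#' @param annotations named list of `annotation_events` for the test set.
#' @param threshold classification threshold.
#' @return data frame with one row per fold plus `mean` and `sd` rows.
#' @export
evaluate_folds <- function(fits, test_data, annotations, threshold = 0.5) {
  stopifnot(length(fits) >= 1L)
  if (length(test_data) == 0L) stop("empty test set")
  rows <- lapply(seq_along(fits), function(i) {
    sc <- predict(fits[[i]], test_data)
    rep <- performance_report(test_data, sc, annotations, threshold)
    data.frame(fold = i,
               accuracy = rep$segment$all_events[["accuracy"]],
               sensitivity = rep$segment$all_events[["sensitivity"]],
               specificity = rep$segment$all_events[["specificity"]],
               f1 = rep$segment$all_events[["f1"]],
               auroc = rep$segment$all_events[["auroc"]],
               ahi_r = rep$agreement$r[rep$agreement$pair == "true-predicted"])
  })
  tab <- do.call(rbind, rows)
  num <- tab[, -1, drop = FALSE]
  rbind(tab,
        cbind(fold = "mean", as.data.frame(t(colMeans(num)))),
        cbind(fold = "sd", as.data.frame(t(apply(num, 2, sd)))))
}
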