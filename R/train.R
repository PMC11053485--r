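# Training, evaluation and ablation orchestration.
#
# Labels are standardized (z-scored on the training set) before entering
# the losses; omega and sigma_l are, by default, set to 10% and 25% of
# the training-label standard deviation (i.e. 0.1 and 0.25 in
# standardized units) at run start and frozen. Predictions are mapped
# back to grams for all reported metrics. Optimization is Adam with
# per-epoch cosine annealing of the learning rate.

#' Training configuration
#'
#' @param epochs number of epochs (default 80; desk-scale runs use 10).
#' @param batch_size samples per step (>= 2; each yields two views).
#' @param lr,lr_min cosine-annealed Adam learning-rate bounds.
#' @param seed master seed controlling initialization, shuffling and
#'   augmentation; identical seeds give identical runs.
#' @param model a [bioumixer_config()].
#' @param loss an [scdr_config()].
#' @param toggles ablation toggles forwarded to [bioumixer()].
#' @param augment a [transform_spec()]; `NULL` derives one from the model
#'   input size.
#' @param val_fraction held-out fraction used for best-MAE checkpointing.
#' @param loss_auto_scale set `omega`/`sigma_l` from training-label
#'   statistics (10% / 25% of the label SD) at run start.
#' @param verbose print per-epoch progress.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 80L, batch_size = 16L, lr = 1e-3,
                         lr_min = 1e-5, seed = 1L,
                         model = bioumixer_config(), loss = scdr_config(),
                         toggles = NULL, augment = NULL,
                         val_fraction = 0.2, loss_auto_scale = TRUE,
                         verbose = FALSE) {
  if (epochs < 1) stop_config("`epochs` must be >= 1")
  if (batch_size < 2) stop_config("`batch_size` must be >= 2 (pairing needs non-sibling views)")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_min = lr_min, seed = as.integer(seed),
                 model = model, loss = loss, toggles = toggles,
                 augment = augment, val_fraction = val_fraction,
                 loss_auto_scale = isTRUE(loss_auto_scale),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

adam_init <- function() list(m = new.env(parent = emptyenv()),
                             v = new.env(parent = emptyenv()), t = 0L)

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in model$trainable) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- state$m[[nm]] %||% 0
    v <- state$v[[nm]] %||% 0
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    model$params[[nm]] <- model$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

cosine_lr <- function(epoch, epochs, lr, lr_min) {
  if (epochs <= 1) return(lr)
  lr_min + 0.5 * (lr - lr_min) * (1 + cos(pi * (epoch - 1) / (epochs - 1)))
}

channel_stats <- function(samples, max_images = 64L) {
  idx <- seq_len(min(length(samples), max_images))
  acc <- matrix(0, length(idx), 3)
  acc2 <- matrix(0, length(idx), 3)
  for (i in seq_along(idx)) {
    img <- samples[[idx[i]]]$image
    for (ch in 1:3) {
      acc[i, ch] <- mean(img[, , ch])
      acc2[i, ch] <- mean(img[, , ch]^2)
    }
  }
  mu <- colMeans(acc)
  sd <- sqrt(pmax(colMeans(acc2) - mu^2, 1e-6))
  list(mean = mu, sd = pmax(sd, 0.05))
}

# eval-time preprocessing: center crop to square, resize, standardize
prep_eval_images <- function(samples, input_size, cstats) {
  B <- length(samples)
  out <- array(0, c(B, input_size, input_size, 3))
  for (i in seq_len(B)) {
    img <- samples[[i]]$image
    d <- dim(img)
    side <- min(d[1], d[2])
    oy <- (d[1] - side) %/% 2L; ox <- (d[2] - side) %/% 2L
    v <- img[(oy + 1L):(oy + side), (ox + 1L):(ox + side), , drop = FALSE]
    if (side != input_size) v <- resize_nearest(v, input_size, input_size)
    m <- input_size * input_size
    out[i, , , ] <- (v - bcast(cstats$mean, m)) / bcast(cstats$sd, m)
  }
  out
}

#' Train a BioUMixer model with the SCDR total loss
#'
#' Each step augments a sampled batch into two views per sample, runs the
#' network, and minimizes `alpha * L_reg + beta * L_scdr` with Adam under
#' per-epoch cosine annealing. The model state with the best validation
#' MAE is kept. Fully reproducible from `config$seed`.
#'
#' @param config a [train_config()].
#' @param dataset list of samples (`list(image, label, ...)`), e.g. from
#'   [load_dataset()]; samples carrying `split == "test"` are ignored.
#' @param checkpoint_path optional path; when given, the best model is
#'   saved there with [save_checkpoint()].
#' @return list of class `scdr_fit`: `model` (best weights), `meta`
#'   (label/channel statistics, resolved loss config), `log` (one row per
#'   epoch: losses, validation metrics, anchor fraction, timestamp),
#'   `best_epoch`, `val_mae`.
#' @export
scdr_train <- function(config, dataset, checkpoint_path = NULL) {
  stopifnot(inherits(config, "train_config"))
  dataset <- Filter(function(s) !identical(s$split, "test"), dataset)
  if (length(dataset) < 2 * config$batch_size) {
    stop_invalid("dataset must hold at least 2 * batch_size training samples")
  }
  if (any(vapply(dataset, function(s) s$label, 0) <= 0)) {
    stop_invalid("biomass labels must be positive")
  }
  seeds <- derive_seeds(config$seed, 6, salt = 7L)

  # validation split
  n <- length(dataset)
  val_idx <- with_seed(seeds[1], sample(n, max(1L, round(config$val_fraction * n))))
  tr_idx <- setdiff(seq_len(n), val_idx)
  train_set <- dataset[tr_idx]
  val_set <- dataset[val_idx]

  labels_raw <- vapply(train_set, function(s) s$label, 0)
  center <- mean(labels_raw)
  scale <- stats::sd(labels_raw)
  if (!is.finite(scale) || scale == 0) scale <- 1
  cstats <- channel_stats(train_set)

  loss_cfg <- config$loss
  if (config$loss_auto_scale) {
    loss_cfg$omega <- 0.10    # 10% of the (unit) standardized label SD
    loss_cfg$sigma_l <- 0.25  # 25%
  } else {
    loss_cfg$omega <- loss_cfg$omega / scale
    loss_cfg$sigma_l <- loss_cfg$sigma_l / scale
  }

  spec <- config$augment %||% transform_spec(out_size = config$model$input_size)
  spec$channel_mean <- cstats$mean
  spec$channel_sd <- cstats$sd

  model <- bioumixer(config$model, toggles = config$toggles, seed = seeds[2])
  opt <- adam_init()
  val_images <- prep_eval_images(val_set, config$model$input_size, cstats)
  val_labels <- vapply(val_set, function(s) s$label, 0)

  n_tr <- length(train_set)
  steps_per_epoch <- ceiling(n_tr / config$batch_size)
  log_rows <- vector("list", config$epochs)
  best <- list(mae = Inf, params = NULL, epoch = NA_integer_)
  batch_seeds <- derive_seeds(config$seed, config$epochs * steps_per_epoch, salt = 13L)

  for (epoch in seq_len(config$epochs)) {
    lr_t <- cosine_lr(epoch, config$epochs, config$lr, config$lr_min)
    perm <- with_seed(seeds[3] + epoch, sample(n_tr))
    ep_reg <- ep_scdr <- ep_sum <- ep_anch <- 0
    for (step in seq_len(steps_per_epoch)) {
      lo <- (step - 1L) * config$batch_size + 1L
      hi <- min(step * config$batch_size, n_tr)
      batch <- train_set[perm[lo:hi]]
      bseed <- batch_seeds[(epoch - 1L) * steps_per_epoch + step]
      ab <- make_augmented_batch(batch, spec, bseed)
      y_std <- (ab$labels - center) / scale

      G <- new.env(parent = emptyenv())
      fwd <- with_seed(bseed + 1, bioumixer_forward(model, ab$views,
                                                    train = TRUE, grads = G))
      reg <- regression_loss(fwd$prediction, y_std, loss_cfg$regression_kind,
                             loss_cfg$focal_gamma, loss_cfg$focal_p,
                             want_grad = TRUE)
      use_contrast <- loss_cfg$beta > 0
      sc <- scdr_batch_loss(fwd$embedding, y_std, fwd$prediction, loss_cfg,
                            want_grad = use_contrast)
      l_sum <- total_loss(reg$loss, sc$l_scdr, loss_cfg$alpha, loss_cfg$beta)
      if (!is.finite(l_sum)) {
        stop(sprintf(paste0("non-finite loss at epoch %d step %d ",
                            "(l_reg=%g, l_scdr=%g); offending batch labels: %s"),
                     epoch, step, reg$loss, sc$l_scdr,
                     paste(signif(ab$labels, 4), collapse = ", ")))
      }
      d_pred <- loss_cfg$alpha * reg$grad
      d_emb <- if (use_contrast) loss_cfg$beta * sc$grad else
        matrix(0, nrow(fwd$embedding), ncol(fwd$embedding))
      fwd$backward(d_emb, d_pred)
      opt <- adam_step(model, G, opt, lr_t)
      ep_reg <- ep_reg + reg$loss
      ep_scdr <- ep_scdr + sc$l_scdr
      ep_sum <- ep_sum + l_sum
      ep_anch <- ep_anch + sc$anchor_fraction
    }
    # validation in grams
    vp <- predict_images(model, val_images)
    val_pred <- center + scale * vp$prediction
    vm <- compute_metrics(val_labels, val_pred)
    if (vm$mae < best$mae) {
      best <- list(mae = vm$mae, params = snapshot_params(model), epoch = epoch)
    }
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, lr = lr_t,
      l_reg = ep_reg / steps_per_epoch, l_scdr = ep_scdr / steps_per_epoch,
      l_sum = ep_sum / steps_per_epoch,
      anchor_fraction = ep_anch / steps_per_epoch,
      val_rmse = vm$rmse, val_mae = vm$mae, val_mape = vm$mape,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    log_msg("epoch %3d  lr %.2e  l_reg %.4f  l_scdr %.4f  val MAE %.2f",
            epoch, lr_t, ep_reg / steps_per_epoch, ep_scdr / steps_per_epoch,
            vm$mae, verbose = config$verbose)
  }
  restore_params(model, best$params)
  meta <- list(label_center = center, label_scale = scale,
               channel_stats = cstats, loss = loss_cfg,
               train = config[c("epochs", "batch_size", "lr", "lr_min",
                                "seed", "val_fraction")])
  fit <- structure(list(model = model, meta = meta,
                        log = do.call(rbind, log_rows),
                        best_epoch = best$epoch, val_mae = best$mae),
                   class = "scdr_fit")
  if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path, meta)
  fit
}

# eval-mode forward in mini-batches; returns embeddings and predictions
predict_images <- function(model, images, batch_size = 64L) {
  B <- dim(images)[1]
  emb <- NULL; pred <- numeric(B)
  for (lo in seq(1L, B, batch_size)) {
    hi <- min(lo + batch_size - 1L, B)
    out <- bioumixer_forward(model, images[lo:hi, , , , drop = FALSE],
                             train = FALSE)
    if (is.null(emb)) emb <- matrix(0, B, ncol(out$embedding))
    emb[lo:hi, ] <- out$embedding
    pred[lo:hi] <- out$prediction
  }
  list(embedding = emb, prediction = pred)
}

#' Predict biomass for a set of samples
#'
#' @param fit an `scdr_fit` (from [scdr_train()]) or the list returned by
#'   [load_checkpoint()].
#' @param samples list of samples with `image` entries.
#' @return list with `prediction` (grams) and `embedding` (matrix).
#' @export
scdr_predict <- function(fit, samples) {
  model <- fit$model
  meta <- fit$meta
  imgs <- prep_eval_images(samples, model$config$input_size, meta$channel_stats)
  out <- predict_images(model, imgs)
  out$prediction <- meta$label_center + meta$label_scale * out$prediction
  out
}

#' Evaluate a trained model on a dataset
#'
#' Runs an eval-mode forward pass over the samples and reports
#' RMSE/MAE/MAPE in label units (grams), plus per-sample residuals.
#'
#' @param fit an `scdr_fit` or [load_checkpoint()] result (or a
#'   checkpoint file path).
#' @param dataset list of samples; samples carrying `split == "train"`
#'   are kept too -- filter beforehand to evaluate held-out data only.
#' @return list of class `scdr_eval`: `metrics` ([compute_metrics()]
#'   report), `residuals` data frame, `predictions`, `embeddings`.
#' @export
scdr_evaluate <- function(fit, dataset) {
  if (is.character(fit)) fit <- load_checkpoint(fit)
  if (length(dataset) == 0) stop_invalid("empty evaluation dataset")
  out <- scdr_predict(fit, dataset)
  labels <- vapply(dataset, function(s) s$label, 0)
  metrics <- compute_metrics(labels, out$prediction)
  residuals <- data.frame(
    filename = vapply(dataset, function(s) s$filename %||% NA_character_, ""),
    label = labels, prediction = out$prediction,
    residual = out$prediction - labels)
  structure(list(metrics = metrics, residuals = residuals,
                 predictions = out$prediction, embeddings = out$embedding),
            class = "scdr_eval")
}

#' Module-ablation cases
#'
#' The five canonical toggle combinations: main module only; without the
#' U-like skips; without FeatureBlocks; without BioBlocks; full model.
#'
#' @return named list of toggle lists.
#' @export
ablation_cases <- function() {
  list(case1 = list(skips = FALSE, feature_block = FALSE, bio_block = FALSE),
       case2 = list(skips = FALSE, feature_block = TRUE, bio_block = TRUE),
       case3 = list(skips = TRUE, feature_block = FALSE, bio_block = TRUE),
       case4 = list(skips = TRUE, feature_block = TRUE, bio_block = FALSE),
       case5 = list(skips = TRUE, feature_block = TRUE, bio_block = TRUE))
}

#' Run the module-ablation harness
#'
#' Trains and evaluates every requested toggle case end-to-end with a
#' shared seed and shared data, and tabulates RMSE/MAE/MAPE and the
#' parameter count per case.
#'
#' @param config a [train_config()] (its `toggles` field is overridden
#'   per case).
#' @param train_set,test_set sample lists.
#' @param cases subset of `names(ablation_cases())`.
#' @return data frame with one row per case.
#' @export
scdr_ablate <- function(config, train_set, test_set,
                        cases = names(ablation_cases())) {
  all_cases <- ablation_cases()
  unknown <- setdiff(cases, names(all_cases))
  if (length(unknown)) {
    stop_config(paste0("unknown ablation case(s): ", paste(unknown, collapse = ", ")))
  }
  rows <- lapply(cases, function(cs) {
    cfg <- config
    cfg$toggles <- all_cases[[cs]]
    fit <- scdr_train(cfg, train_set)
    ev <- scdr_evaluate(fit, test_set)
    data.frame(case = cs,
               skips = all_cases[[cs]]$skips,
               feature_block = all_cases[[cs]]$feature_block,
               bio_block = all_cases[[cs]]$bio_block,
               n_params = n_parameters(fit$model),
               rmse = ev$metrics$rmse, mae = ev$metrics$mae,
               mape = ev$metrics$mape)
  })
  do.call(rbind, rows)
}
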