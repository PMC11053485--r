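# Shared fixtures and numeric helpers.

# central finite differences of a scalar function of an array
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

# a sibling-structured random batch: labels duplicated pairwise, as
# produced by two-view augmentation
random_view_batch <- function(n_samples, d_emb, seed,
                              label_range = c(1, 100)) {
  set.seed(seed)
  y0 <- runif(n_samples, label_range[1], label_range[2])
  labels <- rep(y0, each = 2)
  predictions <- labels + rnorm(2 * n_samples, 0, diff(label_range) / 4)
  emb <- matrix(rnorm(2 * n_samples * d_emb), 2 * n_samples, d_emb)
  list(labels = labels, predictions = predictions, embeddings = emb)
}

# small square model config for fast structural tests
small_model_config <- function(input_size = 32, widths = c(6, 8, 10)) {
  bioumixer_config(input_size = input_size, stage_widths = widths,
                   embedding_dim = 8, mixer_token_hidden = 5,
                   mixer_channel_hidden = 9, head_hidden = 6)
}

# in-memory random samples (images already at model input size)
random_samples <- function(n, size = 32, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    list(image = array(runif(size * size * 3), c(size, size, 3)),
         label = runif(1, 200, 4000),
         filename = sprintf("mem_%03d", i), split = "train")
  })
}

# one shared small synthetic dataset on disk per test session
synthetic_dataset_dir <- local({
  dir <- NULL
  function(n = 250, seed = 11) {
    if (is.null(dir)) {
      d <- file.path(tempdir(), sprintf("scdr_ds_%d_%d", n, seed))
      if (!dir.exists(d)) generate_dataset(n, scene_params(), seed, d)
      dir <<- d
    }
    dir
  }
})

load_synthetic_split <- function(split = c("train", "test")) {
  split <- match.arg(split)
  d <- synthetic_dataset_dir()
  samples <- load_dataset(file.path(d, "manifest.csv"), d)
  Filter(function(s) identical(s$split, split), samples)
}

# untrained counterpart of a fit (same architecture, fresh random init)
untrained_fit <- function(fit, seed = 999) {
  list(model = bioumixer(fit$model$config, fit$model$toggles, seed = seed),
       meta = fit$meta)
}
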