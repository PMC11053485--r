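# Two-view augmentation: every sample contributes two independently
# transformed views with unchanged labels (views 2k-1 and 2k share
# source index k). Transform set: random cropping, horizontal/vertical
# flipping, color-contrast jitter, and per-channel standardization.

#' Augmentation transform specification
#'
#' @param out_size output side in pixels (model input size).
#' @param crop_scale range of the random crop side, as a fraction of the
#'   shorter image side.
#' @param flip_h,flip_v enable random horizontal / vertical flips (p = 0.5).
#' @param contrast multiplicative contrast-jitter range around the image
#'   mean; `c(1, 1)` disables jitter.
#' @param channel_mean,channel_sd optional per-channel statistics for
#'   standardization (length-3); `NULL` leaves values in `[0, 1]`.
#' @return list of class `transform_spec`.
#' @export
transform_spec <- function(out_size = 64L, crop_scale = c(0.7, 1),
                           flip_h = TRUE, flip_v = TRUE,
                           contrast = c(0.8, 1.25),
                           channel_mean = NULL, channel_sd = NULL) {
  if (crop_scale[1] <= 0 || crop_scale[2] > 1 || crop_scale[1] > crop_scale[2]) {
    stop_config("`crop_scale` must satisfy 0 < lo <= hi <= 1")
  }
  structure(list(out_size = as.integer(out_size), crop_scale = crop_scale,
                 flip_h = isTRUE(flip_h), flip_v = isTRUE(flip_v),
                 contrast = contrast,
                 channel_mean = channel_mean, channel_sd = channel_sd),
            class = "transform_spec")
}

resize_nearest <- function(img, out_h, out_w) {
  d <- dim(img)
  hi <- pmin(d[1], pmax(1L, ceiling(seq_len(out_h) * d[1] / out_h)))
  wi <- pmin(d[2], pmax(1L, ceiling(seq_len(out_w) * d[2] / out_w)))
  img[hi, wi, , drop = FALSE]
}

augment_one <- function(img, spec) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  if (min(H, W) < spec$out_size) {
    stop_invalid(sprintf("image (%dx%d) smaller than output size %d",
                         H, W, spec$out_size))
  }
  s <- stats::runif(1, spec$crop_scale[1], spec$crop_scale[2])
  side <- max(2L, round(s * min(H, W)))
  oy <- sample.int(H - side + 1L, 1L)
  ox <- sample.int(W - side + 1L, 1L)
  v <- img[oy:(oy + side - 1L), ox:(ox + side - 1L), , drop = FALSE]
  v <- resize_nearest(v, spec$out_size, spec$out_size)
  if (spec$flip_h && stats::runif(1) < 0.5) v <- v[, rev(seq_len(dim(v)[2])), , drop = FALSE]
  if (spec$flip_v && stats::runif(1) < 0.5) v <- v[rev(seq_len(dim(v)[1])), , , drop = FALSE]
  if (spec$contrast[1] != 1 || spec$contrast[2] != 1) {
    cf <- stats::runif(1, spec$contrast[1], spec$contrast[2])
    mx <- mean(v)
    v <- pmin(pmax((v - mx) * cf + mx, 0), 1)
  }
  if (!is.null(spec$channel_mean)) {
    m <- dim(v)[1] * dim(v)[2]
    v <- (v - bcast(spec$channel_mean, m)) / bcast(spec$channel_sd, m)
  }
  v
}

#' Build a two-view augmented batch
#'
#' Each input sample `k` yields views `2k-1` and `2k` under two
#' independently sampled transforms; labels are duplicated unchanged.
#' Deterministic for a fixed `rng_seed`.
#'
#' @param samples non-empty list of samples, each
#'   `list(image = (H, W, 3) array in [0, 1], label = positive number)`.
#' @param spec a [transform_spec()].
#' @param rng_seed integer seed.
#' @return list of class `augmented_batch`: `views` array
#'   (2N, out, out, 3), `labels` (length 2N), `source_index` (length 2N,
#'   1-based sample of origin).
#' @export
make_augmented_batch <- function(samples, spec, rng_seed) {
  if (length(samples) == 0) stop_invalid("empty sample list")
  n <- length(samples)
  with_seed(rng_seed, {
    views <- array(0, c(2L * n, spec$out_size, spec$out_size, 3L))
    labels <- numeric(2L * n)
    src <- integer(2L * n)
    for (k in seq_len(n)) {
      for (r in 1:2) {
        idx <- 2L * (k - 1L) + r
        views[idx, , , ] <- augment_one(samples[[k]]$image, spec)
        labels[idx] <- samples[[k]]$label
        src[idx] <- k
      }
    }
    structure(list(views = views, labels = labels, source_index = src),
              class = "augmented_batch")
  })
}
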