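# Synthetic canopy-scene generator.
#
# Emulates the structure of plot-level crop biomass datasets: RGB scenes
# of green foliage over brown soil with red fruits and mutual occlusion,
# one positive continuous label per image whose magnitude scales with
# visible vegetation and fruit area plus measurement noise. Scene realism
# is deliberately minimal -- the point is a learnable, monotone
# pixel-to-biomass signal with a right-skewed label distribution, not
# photorealism.

#' Synthetic scene parameters
#'
#' Defaults target plot-scale labels of order 500-4000 g on 64x64 scenes.
#'
#' @param image_size square scene side in pixels (>= 16).
#' @param n_plants integer range `c(lo, hi)` of plant blobs per scene.
#' @param foliage_coverage range of the foliage area fraction; coverage
#'   is drawn from a right-skewed Beta(1.3, 2.6) rescaled to this range,
#'   which makes the label distribution continuous and right-skewed.
#' @param fruit_count integer range of fruits per plant.
#' @param a_veg grams of biomass per visible foliage pixel.
#' @param a_fruit grams per fruit pixel.
#' @param noise_sigma Gaussian label noise, grams.
#' @param background soil RGB triplet in `[0, 1]`.
#' @param label_floor minimum label, grams (> 0).
#' @return list of class `scene_params`.
#' @export
scene_params <- function(image_size = 64L, n_plants = c(1L, 6L),
                         foliage_coverage = c(0.06, 0.72),
                         fruit_count = c(0L, 6L),
                         a_veg = 1.5, a_fruit = 2, noise_sigma = 25,
                         background = c(0.42, 0.30, 0.18),
                         label_floor = 50) {
  if (image_size < 16) stop_invalid("`image_size` must be >= 16")
  check_number(a_veg, "a_veg", lower = 0)
  check_number(a_fruit, "a_fruit", lower = 0)
  check_number(noise_sigma, "noise_sigma", lower = 0)
  check_number(label_floor, "label_floor", lower = 0, strict_lower = TRUE)
  if (foliage_coverage[1] <= 0 || foliage_coverage[2] >= 1 ||
      foliage_coverage[1] > foliage_coverage[2]) {
    stop_config("`foliage_coverage` must satisfy 0 < lo <= hi < 1")
  }
  structure(list(image_size = as.integer(image_size),
                 n_plants = as.integer(n_plants),
                 foliage_coverage = foliage_coverage,
                 fruit_count = as.integer(fruit_count),
                 a_veg = a_veg, a_fruit = a_fruit,
                 noise_sigma = noise_sigma,
                 background = background, label_floor = label_floor),
            class = "scene_params")
}

#' Render one synthetic canopy scene
#'
#' Foliage is the thresholded superposition of Gaussian bumps (one per
#' plant), thresholded at the quantile matching the drawn coverage
#' fraction, which yields organic merged/occluded blob shapes; fruits are
#' small ellipses placed on foliage and occluding it. The label is
#' `a_veg * (visible foliage pixels) + a_fruit * (fruit pixels) +
#' N(0, noise_sigma)`, floored at `label_floor`.
#'
#' @param params a [scene_params()].
#' @param rng_seed integer seed; rendering is deterministic given the seed.
#' @return list: `image` (size x size x 3 array in `[0, 1]`), `biomass`
#'   (grams), `masks` (logical matrices `foliage` (visible) and `fruit`),
#'   `counts` (pixel counts used for the label).
#' @export
render_scene <- function(params, rng_seed) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(rng_seed, {
    n <- params$image_size
    xs <- matrix(rep(seq_len(n), each = n), n, n)   # column coords
    ys <- matrix(rep(seq_len(n), times = n), n, n)  # row coords
    np <- if (params$n_plants[1] == params$n_plants[2]) params$n_plants[1] else
      sample(seq(params$n_plants[1], params$n_plants[2]), 1)
    cov_raw <- stats::rbeta(1, 1.3, 2.6)
    coverage <- params$foliage_coverage[1] +
      cov_raw * diff(params$foliage_coverage)
    field <- matrix(0, n, n)
    for (p in seq_len(np)) {
      cy <- stats::runif(1, 0.15 * n, 0.85 * n)
      cx <- stats::runif(1, 0.15 * n, 0.85 * n)
      r <- stats::runif(1, 0.10 * n, 0.30 * n)
      field <- field + exp(-((ys - cy)^2 + (xs - cx)^2) / (2 * r^2))
    }
    field <- field + matrix(stats::runif(n * n, 0, 0.02), n, n)  # break ties
    thr <- stats::quantile(field, 1 - coverage)
    foliage <- field >= thr

    img <- array(0, c(n, n, 3))
    soil_noise <- matrix(stats::runif(n * n, -0.05, 0.05), n, n)
    for (ch in 1:3) img[, , ch] <- params$background[ch] + soil_noise
    green_var <- matrix(stats::runif(n * n, -0.06, 0.06), n, n)
    gcol <- c(0.16, 0.42, 0.14)
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[foliage] <- gcol[ch] + green_var[foliage]
      img[, , ch] <- pl
    }

    fruit <- matrix(FALSE, n, n)
    nf <- 0L
    if (params$fruit_count[2] > 0 && any(foliage)) {
      nf <- sum(sample(seq(params$fruit_count[1], params$fruit_count[2]),
                       np, replace = TRUE))
      fol_idx <- which(foliage)
      if (nf > 0) {
        centers <- sample(fol_idx, min(nf, length(fol_idx)),
                          replace = length(fol_idx) < nf)
        for (ci in centers) {
          fy <- (ci - 1L) %% n + 1L
          fx <- (ci - 1L) %/% n + 1L
          ry <- stats::runif(1, 1.2, 2.6); rx <- stats::runif(1, 1.2, 2.6)
          fruit <- fruit | (((ys - fy) / ry)^2 + ((xs - fx) / rx)^2 <= 1)
        }
      }
    }
    fcol <- c(0.78, 0.16, 0.10)
    fruit_var <- matrix(stats::runif(n * n, -0.05, 0.05), n, n)
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[fruit] <- fcol[ch] + fruit_var[fruit]
      img[, , ch] <- pl
    }
    img <- pmin(pmax(img, 0), 1)

    visible_fol <- foliage & !fruit
    n_fol <- sum(visible_fol)
    n_fruit <- sum(fruit)
    noise <- if (params$noise_sigma > 0) stats::rnorm(1, 0, params$noise_sigma) else 0
    biomass <- max(params$a_veg * n_fol + params$a_fruit * n_fruit + noise,
                   params$label_floor)
    list(image = img, biomass = biomass,
         masks = list(foliage = visible_fol, fruit = fruit),
         counts = c(foliage = n_fol, fruit = n_fruit))
  })
}

#' Generate an on-disk synthetic dataset
#'
#' Writes `n_images` PNG scenes plus `manifest.csv` (filename, biomass,
#' split) and a `params.json` sidecar. The train/test split is 80/20,
#' stratified by label quartile. Fully reproducible from `seed`.
#'
#' @param n_images number of scenes (>= 2).
#' @param params a [scene_params()].
#' @param seed integer master seed.
#' @param out_dir output directory (created if missing).
#' @param test_fraction held-out fraction (default 0.2).
#' @return The manifest as a data frame (invisibly written to disk).
#' @export
generate_dataset <- function(n_images, params = scene_params(), seed = 1,
                             out_dir, test_fraction = 0.2) {
  if (n_images < 2) stop_invalid("`n_images` must be >= 2")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, n_images)
  fn <- sprintf("scene_%05d.png", seq_len(n_images))
  biomass <- numeric(n_images)
  for (i in seq_len(n_images)) {
    sc <- render_scene(params, seeds[i])
    png::writePNG(sc$image, file.path(out_dir, fn[i]))
    biomass[i] <- sc$biomass
  }
  # stratified split by label quartile
  qs <- stats::quantile(biomass, c(0.25, 0.5, 0.75))
  stratum <- findInterval(biomass, qs)
  split <- rep("train", n_images)
  with_seed(seed + 104729, {
    for (s in unique(stratum)) {
      idx <- which(stratum == s)
      n_test <- round(length(idx) * test_fraction)
      if (n_test > 0) split[sample(idx, n_test)] <- "test"
    }
  })
  manifest <- data.frame(filename = fn, biomass = biomass, split = split,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(params), file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Load a dataset of images and biomass labels
#'
#' Reads a CSV manifest mapping image files to continuous labels and
#' decodes the images. Column names are configurable so user-supplied
#' dataset layouts can be mapped onto the expected schema. Unreadable
#' images are skipped with a warning in lenient mode (`strict = FALSE`)
#' or raise an error in strict mode.
#'
#' @param manifest_path CSV path.
#' @param images_dir directory holding the image files.
#' @param columns named character vector mapping the roles `filename`,
#'   `biomass` and (optionally) `split` to manifest column names.
#' @param strict error (rather than skip) on unreadable images.
#' @return list of samples `list(image, label, filename, split)`.
#' @export
load_dataset <- function(manifest_path, images_dir,
                         columns = c(filename = "filename",
                                     biomass = "biomass", split = "split"),
                         strict = FALSE) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (nrow(man) == 0) stop_invalid("empty manifest")
  for (role in c("filename", "biomass")) {
    if (!columns[[role]] %in% names(man)) {
      stop_invalid(sprintf("manifest lacks column '%s' for role '%s'",
                           columns[[role]], role))
    }
  }
  labels <- man[[columns[["biomass"]]]]
  if (!is.numeric(labels)) {
    labels <- suppressWarnings(as.numeric(labels))
    if (any(is.na(labels))) stop_invalid("non-numeric biomass label in manifest")
  }
  has_split <- !is.na(columns["split"]) && columns[["split"]] %in% names(man)
  samples <- vector("list", nrow(man))
  keep <- logical(nrow(man))
  for (i in seq_len(nrow(man))) {
    path <- file.path(images_dir, man[[columns[["filename"]]]][i])
    img <- tryCatch(png::readPNG(path), error = function(e) NULL)
    if (is.null(img)) {
      msg <- sprintf("skipping unreadable image '%s'", path)
      if (strict) stop_invalid(msg) else warning(msg, call. = FALSE)
      next
    }
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
    samples[[i]] <- list(image = img, label = labels[i],
                         filename = man[[columns[["filename"]]]][i],
                         split = if (has_split) man[[columns[["split"]]]][i] else "train")
    keep[i] <- TRUE
  }
  samples[keep]
}
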