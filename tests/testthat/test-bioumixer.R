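# Network structure: shapes, toggles, determinism, skips, checkpoints.

test_that("patch embedding has the contracted shape and bias behaviour", {
  set.seed(1)
  W <- matrix(rnorm(4 * 4 * 3 * 8), 48, 8)
  b <- rnorm(8)
  x <- array(rnorm(2 * 64 * 64 * 3), c(2, 64, 64, 3))
  out <- scdr:::op_convdown(x, W, b, 4L)
  expect_equal(dim(out$y), c(2, 16, 16, 8))
  # constant-zero image maps to the bias everywhere
  z <- scdr:::op_convdown(array(0, c(1, 8, 8, 3)), W, b, 4L)$y
  for (c_ in 1:8) expect_equal(as.vector(z[1, , , c_]), rep(b[c_], 4))
})

test_that("forward pass yields per-image embeddings and predictions", {
  cfg <- small_model_config()
  model <- bioumixer(cfg, seed = 2)
  set.seed(3)
  x <- array(rnorm(4 * 32 * 32 * 3), c(4, 32, 32, 3))
  out <- bioumixer_forward(model, x)
  expect_equal(dim(out$embedding), c(4, cfg$embedding_dim))
  expect_length(out$prediction, 4)
  expect_true(all(is.finite(out$embedding)) && all(is.finite(out$prediction)))
  expect_error(bioumixer_forward(model, x[, 1:16, , , drop = FALSE]),
               class = "scdr_invalid_input")
})

test_that("images in a batch are processed independently", {
  model <- bioumixer(small_model_config(), seed = 4)
  set.seed(5)
  x <- array(rnorm(3 * 32 * 32 * 3), c(3, 32, 32, 3))
  base <- bioumixer_forward(model, x)
  x2 <- x
  x2[2, , , ] <- x2[2, , , ] + rnorm(32 * 32 * 3)
  pert <- bioumixer_forward(model, x2)
  expect_equal(base$prediction[c(1, 3)], pert$prediction[c(1, 3)])
  expect_equal(base$embedding[c(1, 3), ], pert$embedding[c(1, 3), ])
  expect_false(isTRUE(all.equal(base$prediction[2], pert$prediction[2])))
})

test_that("eval-mode forward is deterministic, duplicates map identically", {
  model <- bioumixer(small_model_config(), seed = 6)
  set.seed(7)
  img <- array(rnorm(32 * 32 * 3), c(1, 32, 32, 3))
  x <- array(0, c(2, 32, 32, 3))
  x[1, , , ] <- img[1, , , ]; x[2, , , ] <- img[1, , , ]
  o1 <- bioumixer_forward(model, x)
  o2 <- bioumixer_forward(model, x)
  expect_identical(o1$prediction, o2$prediction)
  expect_equal(o1$prediction[1], o1$prediction[2], tolerance = 1e-12)
  expect_equal(o1$embedding[1, ], o1$embedding[2, ], tolerance = 1e-12)
})

test_that("all five ablation cases run and parameters grow with each module", {
  cfg <- small_model_config()
  set.seed(8)
  x <- array(rnorm(2 * 32 * 32 * 3), c(2, 32, 32, 3))
  counts <- vapply(ablation_cases(), function(tg) {
    m <- bioumixer(cfg, toggles = tg, seed = 9)
    out <- bioumixer_forward(m, x)
    expect_true(all(is.finite(out$prediction)))
    n_parameters(m)
  }, 0)
  expect_equal(length(counts), 5)
  # enabling any single module on top of the bare network adds parameters
  expect_true(all(counts[2:5] > counts[1]))
  # the full model dominates every partial configuration
  expect_true(all(counts[5] > counts[2:4]))
})

test_that("enabling each module separately increases the parameter count", {
  cfg <- small_model_config()
  base <- n_parameters(bioumixer(cfg, toggles = ablation_cases()$case1, seed = 1))
  for (mod in c("skips", "feature_block", "bio_block")) {
    tg <- ablation_cases()$case1
    tg[[mod]] <- TRUE
    expect_gt(n_parameters(bioumixer(cfg, toggles = tg, seed = 1)), base)
  }
  expect_error(bioumixer(cfg, toggles = list(bogus = TRUE)),
               class = "scdr_invalid_config")
})

test_that("residual blocks preserve shape and reduce to identity at zero weights", {
  cfg <- small_model_config()
  model <- bioumixer(cfg, seed = 10)
  P <- model$params
  set.seed(11)
  x <- array(rnorm(2 * 8 * 8 * cfg$stage_widths[1]), c(2, 8, 8, cfg$stage_widths[1]))
  fb <- scdr:::fwd_feature_block(x, P, "s1.fb1", train = FALSE, G = NULL, cfg)
  expect_equal(dim(fb$y), dim(x))
  bb <- scdr:::fwd_bio_block(x, P, "s1.bb1", train = FALSE, G = NULL, cfg)
  expect_equal(dim(bb$y), dim(x))
  # zero the FeatureBlock branch: BN gamma/beta = 0 kills the branch
  P[["s1.fb1.bn.gamma"]][] <- 0
  P[["s1.fb1.bn.beta"]][] <- 0
  P[["s1.fb1.down.b"]][] <- 0
  fb0 <- scdr:::fwd_feature_block(x, P, "s1.fb1", train = FALSE, G = NULL, cfg)
  expect_equal(fb0$y, x, tolerance = 1e-9)
  # zero the BioBlock sub-layer output weights: block becomes identity
  for (nm in c("s1.bb1.f1b.W", "s1.bb1.f1b.b", "s1.bb1.f2b.W", "s1.bb1.f2b.b",
               "s1.bb1.mx.w", "s1.bb1.mx.b")) P[[nm]][] <- 0
  bb0 <- scdr:::fwd_bio_block(x, P, "s1.bb1", train = FALSE, G = NULL, cfg)
  expect_equal(bb0$y, x, tolerance = 1e-9)
})

test_that("u_skip_fuse fuses additively with pooling and projection", {
  set.seed(12)
  late <- array(rnorm(2 * 4 * 4 * 6), c(2, 4, 4, 6))
  early_same <- array(rnorm(2 * 4 * 4 * 6), c(2, 4, 4, 6))
  # identity mode with matching shapes: plain elementwise sum
  f <- u_skip_fuse(early_same, late)
  expect_equal(f$y, early_same + late, tolerance = 1e-12)
  # zero early map leaves late untouched
  f0 <- u_skip_fuse(array(0, dim(early_same)), late)
  expect_equal(f0$y, late)
  # larger early map is average-pooled, channels projected
  early_big <- array(rnorm(2 * 8 * 8 * 3), c(2, 8, 8, 3))
  W <- matrix(rnorm(18), 3, 6); b <- rnorm(6)
  fp <- u_skip_fuse(early_big, late, W, b)
  expect_equal(dim(fp$y), dim(late))
  pooled <- scdr:::op_avgpool(early_big, 2)$y
  manual <- late + scdr:::as_map(scdr:::as_mat(pooled) %*% W +
                                   scdr:::bcast(b, 32), dim(late))
  expect_equal(fp$y, manual, tolerance = 1e-12)
  # channel mismatch without a projection is a config error
  expect_error(u_skip_fuse(early_big, late), class = "scdr_invalid_config")
})

test_that("whole-model parameter gradients match finite differences", {
  cfg <- small_model_config()
  model <- bioumixer(cfg, seed = 13)
  set.seed(14)
  x <- array(rnorm(2 * 32 * 32 * 3), c(2, 32, 32, 3))
  de <- matrix(rnorm(2 * cfg$embedding_dim), 2, cfg$embedding_dim)
  dp <- rnorm(2)
  G <- new.env()
  fw <- bioumixer_forward(model, x, train = TRUE, grads = G)
  fw$backward(de, dp)
  loss_of <- function() {
    out <- bioumixer_forward(model, x, train = TRUE)
    sum(out$embedding * de) + sum(out$prediction * dp)
  }
  eps <- 1e-5
  set.seed(15)
  for (nm in sample(model$trainable, 12)) {
    i <- sample(length(model$params[[nm]]), 1)
    orig <- model$params[[nm]][i]
    model$params[[nm]][i] <- orig + eps; lp <- loss_of()
    model$params[[nm]][i] <- orig - eps; lm <- loss_of()
    model$params[[nm]][i] <- orig
    gn <- (lp - lm) / (2 * eps)
    ga <- G[[nm]][i]
    expect_lt(abs(gn - ga) / max(1e-4, abs(gn), abs(ga)), 1e-3)
  }
})

test_that("checkpoints round-trip the model exactly", {
  model <- bioumixer(small_model_config(), seed = 16)
  set.seed(17)
  x <- array(rnorm(2 * 32 * 32 * 3), c(2, 32, 32, 3))
  before <- bioumixer_forward(model, x)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path, meta = list(note = "test"))
  back <- load_checkpoint(path)
  after <- bioumixer_forward(back$model, x)
  expect_identical(before$prediction, after$prediction)
  expect_identical(before$embedding, after$embedding)
  expect_identical(back$meta$note, "test")
  expect_identical(sort(back$model$trainable), sort(model$trainable))
})

test_that("config validation rejects incompatible geometry", {
  expect_error(bioumixer_config(input_size = 60), class = "scdr_invalid_config")
  expect_error(bioumixer_config(input_size = 16, stage_widths = c(4, 8, 16)),
               class = "scdr_invalid_config")
  expect_error(bioumixer_config(drop_path_rate = 1), class = "scdr_invalid_config")
  expect_error(bioumixer_config(simam_lambda = 0), class = "scdr_invalid_config")
})

test_that("finite outputs across many seeded random inputs", {
  cfg <- small_model_config()
  model <- bioumixer(cfg, seed = 18)
  for (seed in 1:25) {
    set.seed(seed)
    x <- array(rnorm(2 * 32 * 32 * 3, sd = 3), c(2, 32, 32, 3))
    out <- bioumixer_forward(model, x)
    expect_true(all(is.finite(out$prediction)) && all(is.finite(out$embedding)))
  }
})
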