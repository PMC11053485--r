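# Pair selection, similarities, thrust, and the contrastive loss.

test_that("pair classification applies the label/prediction threshold rules", {
  # sibling views with identical labels are always positive
  p <- classify_pairs(c(10, 10), c(3, 80), omega = 1)
  expect_equal(p$status[1, 2], "positive")
  expect_equal(p$status[2, 1], "positive")
  expect_false(any(p$anchor_flags))

  # distant labels, close predictions -> negative pair, both anchors
  p <- classify_pairs(c(0, 100), c(50, 52), omega = 5)
  expect_equal(p$status[1, 2], "negative")
  expect_true(all(p$anchor_flags))

  # distant labels and distant predictions -> unpaired, no anchors
  p <- classify_pairs(c(0, 100), c(0, 100), omega = 5)
  expect_equal(p$status[1, 2], "unpaired")
  expect_false(any(p$anchor_flags))
  emb <- matrix(rnorm(4), 2, 2)
  out <- scdr_batch_loss(emb, c(0, 100), c(0, 100), scdr_config(omega = 5))
  expect_identical(out$l_scdr, 0)

  # structural invariants on a larger random batch
  b <- random_view_batch(8, 4, seed = 3)
  p <- classify_pairs(b$labels, b$predictions, omega = 10)
  expect_identical(p$status, t(p$status))
  expect_true(all(diag(p$status) == "self"))
  expect_true(all(p$n_pos >= 1))                      # sibling guarantee
  expect_true(all(p$anchor_flags == (p$n_neg > 0)))
  expect_true(all(!(p$pos_mask & p$neg_mask)))        # P+ and P- disjoint
})

test_that("pair classification rejects invalid input", {
  expect_error(classify_pairs(c(1, 2, 3), c(1, 2, 3), 1), class = "scdr_invalid_input")
  expect_error(classify_pairs(c(1, NaN), c(1, 2), 1), class = "scdr_invalid_input")
  expect_error(classify_pairs(c(1, 2), c(1, 2, 3), 1), class = "scdr_invalid_input")
})

test_that("label similarity kernel has the right shape and limits", {
  expect_identical(label_similarity(5, 5, 2), 1)
  expect_equal(label_similarity(0, 2.5, 2.5), exp(-1), tolerance = 1e-12)
  expect_equal(label_similarity(0, 100, 1e12), 1, tolerance = 1e-9)
  d <- seq(0, 10, by = 0.5)
  v <- label_similarity(0, d, 3)
  expect_true(all(diff(v) < 0) && all(v > 0))
  expect_error(label_similarity(1, 2, 0), class = "scdr_invalid_config")
})

test_that("feature similarity is floored cosine mapped to [0, 1]", {
  expect_equal(feature_similarity(c(1, 2), c(2, 4), 0.05), 1)
  expect_equal(feature_similarity(c(1, 0), c(0, 1), 0.05), 0.5)
  expect_equal(feature_similarity(c(1, 1), c(-1, -1), 0.05), 0.05)
  expect_equal(feature_similarity(c(1, 3), c(2, -1), 0.1),
               feature_similarity(c(2, -1), c(1, 3), 0.1))
  expect_error(feature_similarity(c(0, 0), c(1, 1), 0.05), class = "scdr_invalid_input")
})

test_that("thrust weight is proportional to eta, inverse in similarities, capped", {
  expect_identical(thrust_weight(0, 1, 1), 0)
  expect_equal(thrust_weight(0.01, 1, 1), 0.01)
  expect_equal(thrust_weight(0.01, 0.5, 0.5), 0.04)
  expect_equal(thrust_weight(5, 0.01, 0.01, s_max = 100), 100)
  s <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(thrust_weight(0.01, s, 0.5)) <= 0))
  expect_true(all(diff(thrust_weight(0.01, 0.5, s)) <= 0))
  expect_error(thrust_weight(0.01, 1.5, 1), class = "scdr_invalid_input")
})

test_that("per-anchor loss matches hand-computed closed forms", {
  # non-anchor contributes exactly zero
  pairs <- classify_pairs(c(1, 1), c(1, 1), omega = 1)
  emb <- matrix(rnorm(8), 2, 4)
  expect_identical(scdr_anchor_loss(1, emb, pairs, matrix(0, 2, 2), tau = 1), 0)

  # one positive, one negative with zero thrust: loss collapses to 0.
  # view 4 is unpaired with view 1 (distant label and prediction)
  labels <- c(0, 0, 100, 100); preds <- c(1, 2, 1, 200)
  pairs <- classify_pairs(labels, preds, omega = 5)
  expect_equal(pairs$status[1, ], c("self", "positive", "negative", "unpaired"))
  # embeddings with known dot products (no normalization)
  z <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, -1))
  S0 <- matrix(0, 4, 4)
  expect_equal(scdr_anchor_loss(1, z, pairs, S0, tau = 1, normalize = FALSE), 0)

  # tau = 1, positive dot 1, negative dot 0, S = 1: -log(e / (e + 1))
  S1 <- matrix(0, 4, 4); S1[1, 3] <- 1
  expect_equal(scdr_anchor_loss(1, z, pairs, S1, tau = 1, normalize = FALSE),
               -log(exp(1) / (exp(1) + 1)), tolerance = 1e-9)
})

test_that("vectorized batch loss equals the nested-loop oracle", {
  cfg <- scdr_config(omega = 10, tau = 0.2, eta = 0.01, sigma_l = 25)
  for (seed in 1:50) {
    n <- sample(2:16, 1)
    d <- sample(2:32, 1)
    b <- random_view_batch(n, d, seed = seed)
    got <- scdr_batch_loss(b$embeddings, b$labels, b$predictions, cfg)
    ref <- oracle_scdr_cfg(b$embeddings, b$labels, b$predictions, cfg)
    expect_equal(got$per_anchor, ref$per_anchor, tolerance = 1e-6)
    denom <- max(1e-8, abs(ref$l_scdr))
    expect_lt(abs(got$l_scdr - ref$l_scdr) / denom, 1e-6)
    expect_equal(got$l_scdr, mean(got$per_anchor))   # Eq.-(3) identity
    expect_true(all(got$per_anchor >= 0))
    expect_true(all(got$per_anchor[!got$anchor_flags] == 0))
  }
})

test_that("zero-anchor law: labels within omega give exactly zero loss", {
  set.seed(4)
  labels <- rep(50, 12) + runif(12, -0.4, 0.4)   # all within omega = 1
  preds <- runif(12, 0, 100)
  emb <- matrix(rnorm(12 * 8), 12, 8)
  out <- scdr_batch_loss(emb, labels, preds, scdr_config(omega = 1))
  expect_identical(out$l_scdr, 0)
  expect_identical(out$per_anchor, numeric(12))
})

test_that("eta = 0 makes the loss independent of negative embeddings", {
  cfg <- scdr_config(omega = 5, eta = 0, sigma_l = 10)
  b <- random_view_batch(6, 8, seed = 9, label_range = c(1, 200))
  out1 <- scdr_batch_loss(b$embeddings, b$labels, b$predictions, cfg)
  # perturb embeddings of views that are negatives of some anchor
  neg_idx <- which(colSums(out1$pairs$neg_mask) > 0)
  expect_gt(length(neg_idx), 0)
  # with eta = 0 the denominator holds positives only: per-anchor losses
  # must be unchanged when a pure-negative partner's embedding changes
  anchors_only <- which(out1$anchor_flags)
  pure_neg <- setdiff(neg_idx, unlist(out1$pairs$positives[anchors_only]))
  expect_gt(length(pure_neg), 0)
  emb2 <- b$embeddings
  emb2[pure_neg[1], ] <- rnorm(ncol(emb2)) * 10
  out3 <- scdr_batch_loss(emb2, b$labels, b$predictions, cfg)
  others <- setdiff(seq_along(b$labels), pure_neg[1])
  expect_equal(out1$per_anchor[others], out3$per_anchor[others])
})

test_that("increasing a thrust entry never decreases the anchor loss", {
  b <- random_view_batch(6, 8, seed = 21)
  pairs <- classify_pairs(b$labels, b$predictions, omega = 20)
  anchors <- which(pairs$anchor_flags)
  expect_gt(length(anchors), 0)
  j <- anchors[1]
  q <- pairs$negatives[[j]][1]
  S <- matrix(0, length(b$labels), length(b$labels))
  losses <- vapply(c(0, 0.1, 1, 10, 100), function(s) {
    S[j, q] <- s
    scdr_anchor_loss(j, b$embeddings, pairs, S, tau = 0.5)
  }, 0)
  expect_true(all(diff(losses) >= 0))
})

test_that("analytic embedding gradient matches finite differences", {
  cfg <- scdr_config(omega = 10, tau = 0.5, eta = 0.05, sigma_l = 20)
  b <- random_view_batch(4, 5, seed = 33)
  out <- scdr_batch_loss(b$embeddings, b$labels, b$predictions, cfg,
                         want_grad = TRUE)
  # thrust and pair structure are treated as constants (stop-gradient),
  # so compare against numeric differentiation with both frozen
  pairs <- classify_pairs(b$labels, b$predictions, cfg$omega)
  S <- thrust_matrix(b$labels, b$embeddings, pairs, cfg)
  loss_frozen <- function(e) {
    mean(vapply(seq_along(b$labels), function(j) {
      scdr_anchor_loss(j, e, pairs, S, cfg$tau)
    }, 0))
  }
  gn <- num_grad(loss_frozen, b$embeddings, eps = 1e-6)
  expect_lt(max_rel_err(out$grad, gn), 1e-5)
})

test_that("a gradient step pulls positives together and pushes negatives apart", {
  # 4-view toy batch: views 1-2 siblings (label 10), views 3-4 siblings
  # (label 100); predictions all close so cross pairs are negatives
  labels <- c(10, 10, 100, 100)
  preds <- c(50, 51, 52, 50)
  cfg <- scdr_config(omega = 5, tau = 0.5, eta = 0.5, sigma_l = 50)
  set.seed(5)
  emb <- matrix(rnorm(4 * 6), 4, 6)
  out <- scdr_batch_loss(emb, labels, preds, cfg, want_grad = TRUE)
  expect_true(out$anchor_flags[1])
  expect_gt(out$S[1, 3], 0)
  step <- emb - 0.1 * out$grad
  cossim <- function(m, a, b) sum(m[a, ] * m[b, ]) /
    sqrt(sum(m[a, ]^2) * sum(m[b, ]^2))
  expect_gt(cossim(step, 1, 2), cossim(emb, 1, 2))   # positive pair closer
  expect_lt(cossim(step, 1, 3), cossim(emb, 1, 3))   # thrusted negative apart
})

test_that("regression losses behave per definition", {
  expect_identical(regression_loss(c(1, 2), c(1, 2), "l1"), 0)
  expect_identical(regression_loss(c(1, 2), c(1, 2), "focal_l1"), 0)
  expect_equal(regression_loss(c(12, 18), c(10, 20), "l1"), 2)
  # focal/l1 ratio is non-decreasing in |e| (sigmoid weight grows)
  es <- seq(0.1, 5, by = 0.1)
  ratio <- vapply(es, function(e) {
    regression_loss(e, 0, "focal_l1") / regression_loss(e, 0, "l1")
  }, 0)
  expect_true(all(diff(ratio) >= 0))
  expect_true(all(ratio >= 0.5 & ratio <= 1))
  # analytic gradient vs finite differences
  set.seed(8)
  p <- rnorm(6); y <- rnorm(6)
  g <- regression_loss(p, y, "focal_l1", want_grad = TRUE)
  gn <- num_grad(function(pp) regression_loss(pp, y, "focal_l1"), p)
  expect_lt(max_rel_err(g$grad, gn), 1e-6)
  expect_error(regression_loss(1, c(1, 2), "l1"), class = "scdr_invalid_input")
  expect_error(regression_loss(1, 1, "huber"))
})

test_that("total loss is the weighted sum with valid weights", {
  expect_identical(total_loss(2, 0.5, alpha = 1, beta = 0), 2)
  expect_identical(total_loss(2, 0.5, alpha = 1, beta = 3), 3.5)
  expect_error(total_loss(1, 1, alpha = -1, beta = 1), class = "scdr_invalid_config")
})

test_that("config constructor enforces parameter ranges", {
  expect_error(scdr_config(tau = 0), class = "scdr_invalid_config")
  expect_error(scdr_config(eta = -1), class = "scdr_invalid_config")
  expect_error(scdr_config(eps_f = 1), class = "scdr_invalid_config")
  expect_error(scdr_config(sigma_l = 0), class = "scdr_invalid_config")
  d <- scdr_config()
  expect_equal(c(d$tau, d$eta, d$alpha, d$beta), c(0.2, 0.01, 1, 3))
})
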