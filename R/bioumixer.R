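# BioUMixer: U-like hierarchical residual fusion network.
#
# Layout: patch embedding -> stages of (FeatureBlock+, BioBlock+) with
# SimAM attention at every stage transition and a strided-convolution
# downsample -> long-range U-like skips pairing same-kind block groups
# across the depth (stage s feeds stage n_stages+1-s, fused additively
# after average pooling and an optional 1x1 projection) -> MixerBlock and
# MLP head producing the image embedding v and the scalar biomass
# prediction.
#
# The model is a list(config, toggles, params, trainable); `params` is an
# environment of named arrays (BatchNorm running statistics live there
# too but are not trainable). Forward passes return a backward closure
# that accumulates parameter gradients into a caller-supplied
# environment, so the training loop owns the optimizer state.

acc_grad <- function(G, name, val) {
  if (is.null(G)) return(invisible(NULL))
  cur <- G[[name]]
  G[[name]] <- if (is.null(cur)) val else cur + val
  invisible(NULL)
}

init_param <- function(P, trainable, name, dims, sd) {
  P[[name]] <- array(stats::rnorm(prod(dims), 0, sd), as.integer(dims))
  c(trainable, name)
}

init_const <- function(P, trainable, name, dims, value, train = TRUE) {
  P[[name]] <- array(value, as.integer(dims))
  if (train) c(trainable, name) else trainable
}

## ---- block parameter initialisation -----------------------------------

init_feature_block <- function(P, tr, pre, C) {
  tr <- init_param(P, tr, paste0(pre, ".dw.w"), c(3, 3, C), sqrt(2 / 9))
  tr <- init_const(P, tr, paste0(pre, ".dw.b"), C, 0)
  tr <- init_const(P, tr, paste0(pre, ".bn.gamma"), C, 1)
  tr <- init_const(P, tr, paste0(pre, ".bn.beta"), C, 0)
  tr <- init_const(P, tr, paste0(pre, ".bn.rm"), C, 0, train = FALSE)
  tr <- init_const(P, tr, paste0(pre, ".bn.rv"), C, 1, train = FALSE)
  tr <- init_param(P, tr, paste0(pre, ".up.W"), c(C, 4 * C), sqrt(2 / C))
  tr <- init_const(P, tr, paste0(pre, ".up.b"), 4 * C, 0)
  tr <- init_const(P, tr, paste0(pre, ".grn.gamma"), 4 * C, 0)
  tr <- init_const(P, tr, paste0(pre, ".grn.beta"), 4 * C, 0)
  tr <- init_param(P, tr, paste0(pre, ".down.W"), c(4 * C, C), sqrt(2 / (4 * C)))
  tr <- init_const(P, tr, paste0(pre, ".down.b"), C, 0)
  tr
}

init_bio_block <- function(P, tr, pre, C) {
  for (ffn in c("f1", "f2")) {
    tr <- init_param(P, tr, paste0(pre, ".", ffn, "a.W"), c(C, 2 * C), sqrt(2 / C))
    tr <- init_const(P, tr, paste0(pre, ".", ffn, "a.b"), 2 * C, 0)
    tr <- init_param(P, tr, paste0(pre, ".", ffn, "b.W"), c(2 * C, C), sqrt(2 / (2 * C)))
    tr <- init_const(P, tr, paste0(pre, ".", ffn, "b.b"), C, 0)
  }
  tr <- init_param(P, tr, paste0(pre, ".mx.w"), c(3, 3, C), sqrt(2 / 9))
  tr <- init_const(P, tr, paste0(pre, ".mx.b"), C, 0)
  tr
}

#' Construct a BioUMixer model
#'
#' @param config a [bioumixer_config()].
#' @param toggles named list of ablation switches (`skips`,
#'   `feature_block`, `bio_block`); missing entries default to `TRUE`
#'   (full model). Disabled modules are replaced by the identity.
#' @param seed optional integer; when given, parameter initialization is
#'   reproducible and the caller's RNG state is untouched.
#' @return A model object (list with class `bioumixer`).
#' @export
bioumixer <- function(config = bioumixer_config(), toggles = NULL, seed = NULL) {
  stopifnot(inherits(config, "bioumixer_config"))
  toggles <- default_toggles(toggles)
  build <- function() {
    P <- new.env(parent = emptyenv())
    tr <- character(0)
    widths <- config$stage_widths
    n_st <- length(widths)
    ps <- config$patch_size
    tr <- init_param(P, tr, "patch.W", c(ps * ps * 3, widths[1]),
                     sqrt(2 / (ps * ps * 3)))
    tr <- init_const(P, tr, "patch.b", widths[1], 0)
    for (s in seq_len(n_st)) {
      C <- widths[s]
      for (b in seq_len(config$blocks_per_stage[s])) {
        if (toggles$feature_block) {
          tr <- init_feature_block(P, tr, sprintf("s%d.fb%d", s, b), C)
        }
        if (toggles$bio_block) {
          tr <- init_bio_block(P, tr, sprintf("s%d.bb%d", s, b), C)
        }
      }
      if (s < n_st) {
        tr <- init_param(P, tr, sprintf("t%d.W", s), c(4 * C, widths[s + 1]),
                         sqrt(2 / (4 * C)))
        tr <- init_const(P, tr, sprintf("t%d.b", s), widths[s + 1], 0)
      }
    }
    if (toggles$skips) {
      for (s in seq_len(floor(n_st / 2))) {
        s_to <- n_st + 1L - s
        cin <- widths[s]; cout <- widths[s_to]
        if (config$skip_projection == "conv1x1" || cin != cout) {
          for (kind in c("f", "b")) {
            tr <- init_param(P, tr, sprintf("skip%s%d.W", kind, s),
                             c(cin, cout), sqrt(1 / cin))
            tr <- init_const(P, tr, sprintf("skip%s%d.b", kind, s), cout, 0)
          }
        }
      }
    }
    # mixer head
    Cf <- widths[n_st]
    side <- config$input_size %/% (ps * 2^(n_st - 1L))
    Tn <- side * side
    tr <- init_const(P, tr, "head.ln1.gamma", Cf, 1)
    tr <- init_const(P, tr, "head.ln1.beta", Cf, 0)
    tr <- init_param(P, tr, "head.tok1.W", c(Tn, config$mixer_token_hidden),
                     sqrt(2 / Tn))
    tr <- init_const(P, tr, "head.tok1.b", config$mixer_token_hidden, 0)
    tr <- init_param(P, tr, "head.tok2.W", c(config$mixer_token_hidden, Tn),
                     sqrt(2 / config$mixer_token_hidden))
    tr <- init_const(P, tr, "head.tok2.b", Tn, 0)
    tr <- init_const(P, tr, "head.ln2.gamma", Cf, 1)
    tr <- init_const(P, tr, "head.ln2.beta", Cf, 0)
    tr <- init_param(P, tr, "head.ch1.W", c(Cf, config$mixer_channel_hidden),
                     sqrt(2 / Cf))
    tr <- init_const(P, tr, "head.ch1.b", config$mixer_channel_hidden, 0)
    tr <- init_param(P, tr, "head.ch2.W", c(config$mixer_channel_hidden, Cf),
                     sqrt(2 / config$mixer_channel_hidden))
    tr <- init_const(P, tr, "head.ch2.b", Cf, 0)
    tr <- init_param(P, tr, "head.emb.W", c(Cf, config$embedding_dim),
                     sqrt(2 / Cf))
    tr <- init_const(P, tr, "head.emb.b", config$embedding_dim, 0)
    tr <- init_param(P, tr, "head.mlp1.W", c(config$embedding_dim, config$head_hidden),
                     sqrt(2 / config$embedding_dim))
    tr <- init_const(P, tr, "head.mlp1.b", config$head_hidden, 0)
    tr <- init_param(P, tr, "head.mlp2.W", c(config$head_hidden, 1), 0.01)
    tr <- init_const(P, tr, "head.mlp2.b", 1, 0)
    structure(list(config = config, toggles = toggles, params = P,
                   trainable = tr), class = "bioumixer")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Count trainable parameters of a model
#' @param model a [bioumixer()] model.
#' @return integer scalar.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$trainable, function(nm) length(model$params[[nm]]), 0))
}

#' @export
print.bioumixer <- function(x, ...) {
  on <- names(Filter(isTRUE, x$toggles))
  cat(sprintf("BioUMixer (%s preset): %s parameters; modules on: %s\n",
              x$config$preset, format(n_parameters(x), big.mark = ","),
              if (length(on)) paste(on, collapse = ", ") else "main module only"))
  invisible(x)
}

## ---- composite block forward passes -----------------------------------

fwd_feature_block <- function(x, P, pre, train, G, cfg) {
  d <- dim(x)
  o1 <- op_dwconv3(x, P[[paste0(pre, ".dw.w")]], P[[paste0(pre, ".dw.b")]])
  o2 <- op_batchnorm(as_mat(o1$y), P[[paste0(pre, ".bn.gamma")]],
                     P[[paste0(pre, ".bn.beta")]], P,
                     paste0(pre, ".bn.rm"), paste0(pre, ".bn.rv"), train)
  o3 <- op_linear(o2$y, P[[paste0(pre, ".up.W")]], P[[paste0(pre, ".up.b")]])
  o4 <- op_gelu(o3$y)
  o5 <- op_grn(as_map(o4$y, c(d[1:3], 4L * d[4])),
               P[[paste0(pre, ".grn.gamma")]], P[[paste0(pre, ".grn.beta")]])
  o6 <- op_linear(as_mat(o5$y), P[[paste0(pre, ".down.W")]],
                  P[[paste0(pre, ".down.b")]])
  o7 <- op_droppath(as_map(o6$y, d), cfg$drop_path_rate, train)
  list(y = x + o7$y, bw = function(dy) {
    g7 <- o7$bw(dy)
    g6 <- o6$bw(as_mat(g7$dx))
    acc_grad(G, paste0(pre, ".down.W"), g6$dW)
    acc_grad(G, paste0(pre, ".down.b"), g6$db)
    g5 <- o5$bw(as_map(g6$dx, c(d[1:3], 4L * d[4])))
    acc_grad(G, paste0(pre, ".grn.gamma"), g5$dgamma)
    acc_grad(G, paste0(pre, ".grn.beta"), g5$dbeta)
    g4 <- o4$bw(as_mat(g5$dx))
    g3 <- o3$bw(g4$dx)
    acc_grad(G, paste0(pre, ".up.W"), g3$dW)
    acc_grad(G, paste0(pre, ".up.b"), g3$db)
    g2 <- o2$bw(g3$dx)
    acc_grad(G, paste0(pre, ".bn.gamma"), g2$dgamma)
    acc_grad(G, paste0(pre, ".bn.beta"), g2$dbeta)
    g1 <- o1$bw(as_map(g2$dx, d))
    acc_grad(G, paste0(pre, ".dw.w"), g1$dw)
    acc_grad(G, paste0(pre, ".dw.b"), g1$db)
    g1$dx + dy
  })
}

fwd_ffn <- function(x, P, pre, train, G, cfg) {
  # residual pointwise FFN with ReLU (sandwich-layout sub-layer)
  d <- dim(x)
  o1 <- op_linear(as_mat(x), P[[paste0(pre, "a.W")]], P[[paste0(pre, "a.b")]])
  o2 <- op_relu(o1$y)
  o3 <- op_linear(o2$y, P[[paste0(pre, "b.W")]], P[[paste0(pre, "b.b")]])
  o4 <- op_droppath(as_map(o3$y, d), cfg$drop_path_rate, train)
  list(y = x + o4$y, bw = function(dy) {
    g4 <- o4$bw(dy)
    g3 <- o3$bw(as_mat(g4$dx))
    acc_grad(G, paste0(pre, "b.W"), g3$dW)
    acc_grad(G, paste0(pre, "b.b"), g3$db)
    g2 <- o2$bw(g3$dx)
    g1 <- o1$bw(g2$dx)
    acc_grad(G, paste0(pre, "a.W"), g1$dW)
    acc_grad(G, paste0(pre, "a.b"), g1$db)
    as_map(g1$dx, d) + dy
  })
}

fwd_bio_block <- function(x, P, pre, train, G, cfg, use_simam = TRUE) {
  f1 <- fwd_ffn(x, P, paste0(pre, ".f1"), train, G, cfg)
  o1 <- op_dwconv3(f1$y, P[[paste0(pre, ".mx.w")]], P[[paste0(pre, ".mx.b")]])
  o2 <- if (use_simam) op_simam(o1$y, cfg$simam_lambda) else
    list(y = o1$y, bw = function(dy) list(dx = dy))
  o3 <- op_droppath(o2$y, cfg$drop_path_rate, train)
  mix <- f1$y + o3$y
  f2 <- fwd_ffn(mix, P, paste0(pre, ".f2"), train, G, cfg)
  list(y = f2$y, bw = function(dy) {
    dmix <- f2$bw(dy)
    g3 <- o3$bw(dmix)
    g2 <- o2$bw(g3$dx)
    g1 <- o1$bw(g2$dx)
    acc_grad(G, paste0(pre, ".mx.w"), g1$dw)
    acc_grad(G, paste0(pre, ".mx.b"), g1$db)
    f1$bw(g1$dx + dmix)
  })
}

fwd_transition <- function(x, P, s, train, G, cfg) {
  a <- op_simam(x, cfg$simam_lambda)
  dwn <- op_convdown(a$y, P[[sprintf("t%d.W", s)]], P[[sprintf("t%d.b", s)]], 2L)
  list(y = dwn$y, bw = function(dy) {
    g <- dwn$bw(dy)
    acc_grad(G, sprintf("t%d.W", s), g$dW)
    acc_grad(G, sprintf("t%d.b", s), g$db)
    a$bw(g$dx)$dx
  })
}

#' Fuse a U-like skip connection
#'
#' Additively fuses an early feature map into a later one:
#' `fused = late + project(pool(early))`. Spatial dimensions are
#' reconciled by average pooling (early larger) or nearest-neighbour
#' upsampling (early smaller); channels by a 1x1 projection when they
#' differ (or always, under `skip_projection = "conv1x1"`).
#'
#' @param early,late feature maps (B, H, W, C arrays).
#' @param proj_W,proj_b optional 1x1 projection parameters; `NULL` for
#'   identity fusion (requires matching channel counts).
#' @return list(y, bw); `bw(dy)` returns `list(d_early, d_late, dW, db)`.
#' @export
u_skip_fuse <- function(early, late, proj_W = NULL, proj_b = NULL) {
  de <- dim(early); dl <- dim(late)
  if (de[2] %% dl[2] != 0 && dl[2] %% de[2] != 0) {
    stop_config("skip spatial dimensions are not integer multiples")
  }
  resamp <- if (de[2] >= dl[2]) op_avgpool(early, de[2] %/% dl[2])
            else op_upsample_nearest(early, dl[2] %/% de[2])
  if (is.null(proj_W)) {
    if (de[4] != dl[4]) stop_config("identity skip requires matching channels")
    proj <- list(y = resamp$y, bw = function(dy) list(dx = dy))
  } else {
    lin <- op_linear(as_mat(resamp$y), proj_W, proj_b)
    proj <- list(y = as_map(lin$y, dl), bw = function(dy) {
      g <- lin$bw(as_mat(dy))
      list(dx = as_map(g$dx, dim(resamp$y)), dW = g$dW, db = g$db)
    })
  }
  list(y = late + proj$y, bw = function(dy) {
    gp <- proj$bw(dy)
    list(d_early = resamp$bw(gp$dx)$dx, d_late = dy,
         dW = gp$dW, db = gp$db)
  })
}

fwd_skip <- function(early, late, P, kind, s, G, toggles, cfg) {
  nm <- sprintf("skip%s%d", kind, s)
  W <- P[[paste0(nm, ".W")]]; b <- P[[paste0(nm, ".b")]]
  fuse <- u_skip_fuse(early, late, W, b)
  list(y = fuse$y, bw = function(dy) {
    g <- fuse$bw(dy)
    if (!is.null(g$dW)) {
      acc_grad(G, paste0(nm, ".W"), g$dW)
      acc_grad(G, paste0(nm, ".b"), g$db)
    }
    g
  })
}

fwd_mixer_head <- function(x, P, train, G, cfg) {
  d <- dim(x); B <- d[1]; Tn <- d[2] * d[3]; C <- d[4]
  xt <- as_map(x, c(B, Tn, C))
  # token mixing
  ln1 <- op_layernorm(matrix(xt, B * Tn, C), P[["head.ln1.gamma"]], P[["head.ln1.beta"]])
  h <- aperm(as_map(ln1$y, c(B, Tn, C)), c(1, 3, 2))    # (B, C, T)
  hm <- matrix(h, B * C, Tn)
  t1 <- op_linear(hm, P[["head.tok1.W"]], P[["head.tok1.b"]])
  t1a <- op_gelu(t1$y)
  t2 <- op_linear(t1a$y, P[["head.tok2.W"]], P[["head.tok2.b"]])
  tokmix <- aperm(as_map(t2$y, c(B, C, Tn)), c(1, 3, 2))
  x2 <- xt + tokmix
  # channel mixing
  ln2 <- op_layernorm(matrix(x2, B * Tn, C), P[["head.ln2.gamma"]], P[["head.ln2.beta"]])
  c1 <- op_linear(ln2$y, P[["head.ch1.W"]], P[["head.ch1.b"]])
  c1a <- op_gelu(c1$y)
  c2 <- op_linear(c1a$y, P[["head.ch2.W"]], P[["head.ch2.b"]])
  x3 <- x2 + as_map(c2$y, c(B, Tn, C))
  # pool -> embedding -> prediction MLP
  gp <- op_global_mean_tokens(x3)
  eb <- op_linear(gp$y, P[["head.emb.W"]], P[["head.emb.b"]])
  m1 <- op_linear(eb$y, P[["head.mlp1.W"]], P[["head.mlp1.b"]])
  m1a <- op_relu(m1$y)
  m2 <- op_linear(m1a$y, P[["head.mlp2.W"]], P[["head.mlp2.b"]])
  list(embedding = eb$y, prediction = as.vector(m2$y),
       bw = function(d_emb, d_pred) {
    gm2 <- m2$bw(matrix(d_pred, B, 1))
    acc_grad(G, "head.mlp2.W", gm2$dW); acc_grad(G, "head.mlp2.b", gm2$db)
    gm1a <- m1a$bw(gm2$dx)
    gm1 <- m1$bw(gm1a$dx)
    acc_grad(G, "head.mlp1.W", gm1$dW); acc_grad(G, "head.mlp1.b", gm1$db)
    demb <- gm1$dx + d_emb
    geb <- eb$bw(demb)
    acc_grad(G, "head.emb.W", geb$dW); acc_grad(G, "head.emb.b", geb$db)
    ggp <- gp$bw(geb$dx)
    dx3 <- ggp$dx
    gc2 <- c2$bw(matrix(dx3, B * Tn, C))
    acc_grad(G, "head.ch2.W", gc2$dW); acc_grad(G, "head.ch2.b", gc2$db)
    gc1a <- c1a$bw(gc2$dx)
    gc1 <- c1$bw(gc1a$dx)
    acc_grad(G, "head.ch1.W", gc1$dW); acc_grad(G, "head.ch1.b", gc1$db)
    gln2 <- ln2$bw(gc1$dx)
    acc_grad(G, "head.ln2.gamma", gln2$dgamma)
    acc_grad(G, "head.ln2.beta", gln2$dbeta)
    dx2 <- dx3 + as_map(gln2$dx, c(B, Tn, C))
    dtok <- aperm(dx2, c(1, 3, 2))                      # (B, C, T)
    gt2 <- t2$bw(matrix(dtok, B * C, Tn))
    acc_grad(G, "head.tok2.W", gt2$dW); acc_grad(G, "head.tok2.b", gt2$db)
    gt1a <- t1a$bw(gt2$dx)
    gt1 <- t1$bw(gt1a$dx)
    acc_grad(G, "head.tok1.W", gt1$dW); acc_grad(G, "head.tok1.b", gt1$db)
    gln1 <- ln1$bw(matrix(aperm(as_map(gt1$dx, c(B, C, Tn)), c(1, 3, 2)), B * Tn, C))
    acc_grad(G, "head.ln1.gamma", gln1$dgamma)
    acc_grad(G, "head.ln1.beta", gln1$dbeta)
    dxt <- dx2 + as_map(gln1$dx, c(B, Tn, C))
    as_map(dxt, d)
  })
}

## ---- full network ------------------------------------------------------

#' Run the BioUMixer forward pass
#'
#' @param model a [bioumixer()] model.
#' @param images array (B, H, W, 3) of standardized image tensors.
#' @param train logical; training mode enables BatchNorm batch statistics
#'   and DropPath.
#' @param grads optional environment; when supplied, the returned
#'   `backward(d_embedding, d_prediction)` closure accumulates parameter
#'   gradients into it (named like the parameters).
#' @return list with `embedding` (B x d_emb matrix), `prediction`
#'   (length-B vector) and `backward` closure.
#' @export
bioumixer_forward <- function(model, images, train = FALSE, grads = NULL) {
  cfg <- model$config; P <- model$params; G <- grads
  tg <- model$toggles
  d <- dim(images)
  if (length(d) != 4 || d[4] != 3 || d[2] != cfg$input_size || d[3] != cfg$input_size) {
    stop_invalid(sprintf("images must be (B, %d, %d, 3)", cfg$input_size, cfg$input_size))
  }
  if (any(!is.finite(images))) stop_invalid("non-finite values in input images")
  widths <- cfg$stage_widths; n_st <- length(widths)
  tape <- list()
  push <- function(bw) tape[[length(tape) + 1L]] <<- bw  # linear chain segments

  pe <- op_convdown(images, P[["patch.W"]], P[["patch.b"]], cfg$patch_size)
  x <- pe$y
  # per-stage saved outputs for U-like skips: group outputs per kind
  saved <- list()
  skip_pairs <- if (tg$skips && n_st >= 2) {
    lapply(seq_len(floor(n_st / 2)), function(s) c(from = s, to = n_st + 1L - s))
  } else list()
  skip_to <- vapply(skip_pairs, function(p) p[["to"]], 0L)

  # we build an explicit list of (closure) steps to reverse later
  steps <- list()   # each: list(kind, bw, extra)
  for (s in seq_len(n_st)) {
    # incoming skip fusion for this stage (feature-kind before the
    # FeatureBlock group, bio-kind before the BioBlock group)
    src <- if (length(skip_to)) match(s, skip_to) else NA_integer_
    if (!is.na(src)) {
      from <- skip_pairs[[src]][["from"]]
      fs <- fwd_skip(saved[[sprintf("f%d", from)]], x, P, "f", from, G, tg, cfg)
      steps[[length(steps) + 1L]] <- list(kind = "skip", bw = fs$bw,
                                          save = sprintf("f%d", from))
      x <- fs$y
    }
    if (tg$feature_block) {
      for (b in seq_len(cfg$blocks_per_stage[s])) {
        fb <- fwd_feature_block(x, P, sprintf("s%d.fb%d", s, b), train, G, cfg)
        steps[[length(steps) + 1L]] <- list(kind = "chain", bw = fb$bw)
        x <- fb$y
      }
    }
    if (!is.na(src)) {
      from <- skip_pairs[[src]][["from"]]
      bs <- fwd_skip(saved[[sprintf("b%d", from)]], x, P, "b", from, G, tg, cfg)
      steps[[length(steps) + 1L]] <- list(kind = "skip", bw = bs$bw,
                                          save = sprintf("b%d", from))
      x <- bs$y
    }
    # remember group outputs (and the step index that produced them) so
    # skip gradients can be injected at the right point of the reverse sweep
    saved[[sprintf("f%d", s)]] <- x           # feature-kind group output
    saved[[sprintf("f%d.step", s)]] <- length(steps)
    if (tg$bio_block) {
      for (b in seq_len(cfg$blocks_per_stage[s])) {
        bb <- fwd_bio_block(x, P, sprintf("s%d.bb%d", s, b), train, G, cfg)
        steps[[length(steps) + 1L]] <- list(kind = "chain", bw = bb$bw)
        x <- bb$y
      }
    }
    saved[[sprintf("b%d", s)]] <- x           # bio-kind group output
    saved[[sprintf("b%d.step", s)]] <- length(steps)
    if (s < n_st) {
      trn <- fwd_transition(x, P, s, train, G, cfg)
      steps[[length(steps) + 1L]] <- list(kind = "chain", bw = trn$bw)
      x <- trn$y
    }
  }
  head <- fwd_mixer_head(x, P, train, G, cfg)
  if (any(!is.finite(head$prediction))) {
    stop("non-finite prediction encountered in forward pass; check inputs/learning rate")
  }

  backward <- function(d_embedding, d_prediction) {
    dy <- head$bw(d_embedding, d_prediction)
    # pending gradients for saved maps, keyed by the step index after
    # which they must be added (i.e. where the map was produced)
    pending <- list()
    for (i in rev(seq_along(steps))) {
      key <- as.character(i)
      if (!is.null(pending[[key]])) {
        dy <- dy + pending[[key]]
        pending[[key]] <- NULL
      }
      st <- steps[[i]]
      if (st$kind == "chain") {
        dy <- st$bw(dy)
      } else {  # skip fusion
        g <- st$bw(dy)
        dy <- g$d_late
        at <- as.character(saved[[paste0(st$save, ".step")]])
        pending[[at]] <- if (is.null(pending[[at]])) g$d_early else pending[[at]] + g$d_early
      }
    }
    if (!is.null(pending[["0"]])) dy <- dy + pending[["0"]]
    gpe <- pe$bw(dy)
    acc_grad(G, "patch.W", gpe$dW)
    acc_grad(G, "patch.b", gpe$db)
    invisible(gpe$dx)
  }
  list(embedding = head$embedding, prediction = head$prediction,
       backward = backward)
}

## ---- checkpoints --------------------------------------------------------

#' Save / load model checkpoints
#'
#' A checkpoint is a single-file snapshot (versioned schema) holding the
#' architecture config, ablation toggles, all parameter arrays, and any
#' pipeline metadata (label standardization, channel statistics, loss
#' config) the training run attached.
#'
#' @param model a [bioumixer()] model.
#' @param path file path (`.rds`).
#' @param meta named list of extra metadata to store.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a list with `model` and `meta`.
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  obj <- list(schema = "scdr-checkpoint-1",
              config = model$config,
              toggles = model$toggles,
              params = as.list(model$params),
              trainable = model$trainable,
              meta = meta)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "scdr-checkpoint-1")) {
    stop_invalid("unrecognized checkpoint schema")
  }
  P <- new.env(parent = emptyenv())
  for (nm in names(obj$params)) P[[nm]] <- obj$params[[nm]]
  model <- structure(list(config = obj$config, toggles = obj$toggles,
                          params = P, trainable = obj$trainable),
                     class = "bioumixer")
  list(model = model, meta = obj$meta)
}

# deep-copy a model's parameters (used for best-checkpoint tracking)
snapshot_params <- function(model) as.list(model$params)

restore_params <- function(model, snap) {
  for (nm in names(snap)) model$params[[nm]] <- snap[[nm]]
  invisible(model)
}
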