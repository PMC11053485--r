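# Supervised contrastive loss for deep regression (SCDR).
#
# For a batch of 2N augmented views with labels y~ and model predictions
# y^, pairs (i, j) are classified on label and prediction proximity:
#   positive  : |y~_i - y~_j| <= omega
#   negative  : |y~_i - y~_j| >  omega  and |y^_i - y^_j| <= omega
#   unpaired  : otherwise.
# Views with at least one negative are anchors. The per-anchor loss is
#   L_j = -log[ (1/N+_j) sum_{i in P+} e^{v_j.v_i/tau} /
#               ( sum_{p in P+} e^{v_j.v_p/tau}
#                 + sum_{q in P-} S_{j,q} e^{v_j.v_q/tau} ) ]
# and the batch loss is the mean of L_j over all 2N views (non-anchors
# contribute exactly zero). The thrust S_{j,q} down-weights the push on
# negatives whose labels or features are similar to the anchor's:
#   S = min(eta / (Sim_l * Sim_f), S_max),
#   Sim_l = exp(-|dy| / sigma_l), Sim_f = max((1 + cos(v_j, v_q))/2, eps_f).

#' SCDR loss configuration
#'
#' @param omega label-similarity threshold, in label units. Two views are
#'   a positive pair when their labels differ by at most `omega`; a
#'   negative pair when their labels differ by more but their predictions
#'   differ by at most `omega`.
#' @param tau softmax temperature (> 0); default 0.2.
#' @param eta thrust weight coefficient (>= 0); default 0.01. `eta = 0`
#'   removes all negative-pair terms.
#' @param alpha,beta weights of the regression and contrastive terms in
#'   the total loss; defaults 1 and 3.
#' @param sigma_l label-kernel scale (> 0, label units) of the label
#'   similarity `exp(-|dy|/sigma_l)`.
#' @param eps_f feature-similarity floor in (0, 1).
#' @param s_max thrust clip ceiling (> 0).
#' @param normalize_embeddings L2-normalize embeddings before dot
#'   products (default `TRUE`).
#' @param regression_kind `"focal_l1"` (default) or `"l1"`.
#' @param focal_gamma,focal_p focal-L1 parameters.
#' @return An object of class `scdr_config`.
#' @export
scdr_config <- function(omega = 1, tau = 0.2, eta = 0.01, alpha = 1, beta = 3,
                        sigma_l = 2.5, eps_f = 0.05, s_max = 100,
                        normalize_embeddings = TRUE,
                        regression_kind = c("focal_l1", "l1"),
                        focal_gamma = 1, focal_p = 1) {
  check_number(omega, "omega", lower = 0)
  check_number(tau, "tau", lower = 0, strict_lower = TRUE)
  check_number(eta, "eta", lower = 0)
  check_number(alpha, "alpha", lower = 0)
  check_number(beta, "beta", lower = 0)
  check_number(sigma_l, "sigma_l", lower = 0, strict_lower = TRUE)
  check_number(eps_f, "eps_f", lower = 0, upper = 1)
  if (eps_f <= 0 || eps_f >= 1) stop_config("`eps_f` must be in (0, 1)")
  check_number(s_max, "s_max", lower = 0, strict_lower = TRUE)
  structure(list(omega = omega, tau = tau, eta = eta, alpha = alpha,
                 beta = beta, sigma_l = sigma_l, eps_f = eps_f, s_max = s_max,
                 normalize_embeddings = isTRUE(normalize_embeddings),
                 regression_kind = match.arg(regression_kind),
                 focal_gamma = focal_gamma, focal_p = focal_p),
            class = "scdr_config")
}

#' Classify view pairs into positive / negative / unpaired
#'
#' @param labels,predictions numeric vectors of equal even length (2N
#'   augmented views).
#' @param omega similarity threshold in label units.
#' @return An object of class `pair_assignment`: list with `status`
#'   (2N x 2N matrix over `"positive"`, `"negative"`, `"unpaired"`,
#'   `"self"`), `positives` / `negatives` (per-view index lists),
#'   `anchor_flags`, and counts `n_pos` / `n_neg`.
#' @export
classify_pairs <- function(labels, predictions, omega) {
  n <- length(labels)
  if (n == 0 || n %% 2L != 0L) stop_invalid("need an even, positive number of views")
  if (length(predictions) != n) stop_invalid("labels and predictions differ in length")
  if (any(!is.finite(labels)) || any(!is.finite(predictions))) {
    stop_invalid("labels/predictions must be finite (no NaN)")
  }
  check_number(omega, "omega", lower = 0)
  dl <- abs(outer(labels, labels, "-"))
  dp <- abs(outer(predictions, predictions, "-"))
  pos <- dl <= omega
  neg <- (!pos) & (dp <= omega)
  status <- matrix("unpaired", n, n)
  status[pos] <- "positive"
  status[neg] <- "negative"
  diag(status) <- "self"
  diag(pos) <- FALSE
  diag(neg) <- FALSE
  positives <- lapply(seq_len(n), function(j) which(pos[j, ]))
  negatives <- lapply(seq_len(n), function(j) which(neg[j, ]))
  n_neg <- rowSums(neg)
  structure(list(status = status,
                 pos_mask = pos, neg_mask = neg,
                 positives = positives, negatives = negatives,
                 anchor_flags = n_neg > 0,
                 n_pos = rowSums(pos), n_neg = n_neg),
            class = "pair_assignment")
}

#' Label similarity kernel
#'
#' `exp(-|y_a - y_b| / sigma_l)`: equals 1 at zero label distance and
#' decreases strictly with distance, staying positive.
#'
#' @param y_a,y_b label values (vectorized).
#' @param sigma_l kernel scale in label units (> 0).
#' @return similarity in (0, 1].
#' @export
label_similarity <- function(y_a, y_b, sigma_l) {
  if (!is.numeric(sigma_l) || length(sigma_l) != 1 || !is.finite(sigma_l) || sigma_l <= 0) {
    stop_config("`sigma_l` must be a positive number")
  }
  exp(-abs(y_a - y_b) / sigma_l)
}

#' Feature similarity
#'
#' Cosine similarity mapped to `[0, 1]` and floored:
#' `max((1 + cos(u, v)) / 2, eps_f)`.
#'
#' @param u,v non-zero numeric vectors of equal length.
#' @param eps_f floor in (0, 1).
#' @return similarity in `[eps_f, 1]`.
#' @export
feature_similarity <- function(u, v, eps_f) {
  if (eps_f <= 0 || eps_f >= 1) stop_config("`eps_f` must be in (0, 1)")
  if (length(u) != length(v)) stop_invalid("vectors differ in length")
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) stop_invalid("zero vector has no direction")
  cosv <- sum(u * v) / (nu * nv)
  max((1 + cosv) / 2, eps_f)
}

#' Thrust weight for a negative pair
#'
#' `S = min(eta / (sim_l * sim_f), s_max)`: proportional to `eta`,
#' non-increasing in both similarities (a negative whose label or
#' features already resemble the anchor's is pushed less, which damps the
#' effect of mislabelled pairs), and clipped at `s_max`.
#'
#' @param eta weight coefficient (>= 0).
#' @param sim_l,sim_f label and feature similarities in (0, 1].
#' @param s_max clip ceiling (> 0).
#' @return thrust in `[0, s_max]`.
#' @export
thrust_weight <- function(eta, sim_l, sim_f, s_max = 100) {
  check_number(eta, "eta", lower = 0)
  check_number(s_max, "s_max", lower = 0, strict_lower = TRUE)
  if (any(sim_l <= 0 | sim_l > 1) || any(sim_f <= 0 | sim_f > 1)) {
    stop_invalid("similarities must lie in (0, 1]")
  }
  pmin(eta / (sim_l * sim_f), s_max)
}

# L2-normalize rows; guards zero rows
l2_normalize_rows <- function(v) {
  nrm <- sqrt(rowSums(v * v))
  if (any(nrm == 0)) stop_invalid("zero embedding vector cannot be normalized")
  v / nrm
}

#' Thrust matrix for a batch
#'
#' Computes `S[j, q] = min(eta / (Sim_l(y_j, y_q) * Sim_f(v_j, v_q)),
#' s_max)` for every negative pair and 0 elsewhere.
#'
#' @param labels length-2N label vector.
#' @param embeddings 2N x d matrix (normalized or not; cosine is
#'   scale-invariant).
#' @param pairs a [classify_pairs()] result.
#' @param config an [scdr_config()].
#' @return 2N x 2N matrix.
#' @export
thrust_matrix <- function(labels, embeddings, pairs, config) {
  n <- length(labels)
  S <- matrix(0, n, n)
  if (config$eta == 0 || !any(pairs$neg_mask)) return(S)
  z <- l2_normalize_rows(embeddings)
  cosm <- tcrossprod(z)
  simf <- pmax((1 + cosm) / 2, config$eps_f)
  siml <- exp(-abs(outer(labels, labels, "-")) / config$sigma_l)
  Sfull <- pmin(config$eta / (siml * simf), config$s_max)
  S[pairs$neg_mask] <- Sfull[pairs$neg_mask]
  S
}

#' Per-anchor SCDR loss
#'
#' Direct (readable) evaluation of the per-anchor loss for view `j`.
#' Returns 0 for non-anchor views. Used mainly for inspection; the batch
#' path is vectorized in [scdr_batch_loss()].
#'
#' @param j view index (1-based).
#' @param embeddings 2N x d matrix of view embeddings.
#' @param pairs a [classify_pairs()] result.
#' @param thrust 2N x 2N thrust matrix (see [thrust_matrix()]).
#' @param tau temperature (> 0).
#' @param normalize L2-normalize embeddings first (default `TRUE`).
#' @return non-negative scalar.
#' @export
scdr_anchor_loss <- function(j, embeddings, pairs, thrust, tau,
                             normalize = TRUE) {
  check_number(tau, "tau", lower = 0, strict_lower = TRUE)
  if (!pairs$anchor_flags[j]) return(0)
  pj <- pairs$positives[[j]]
  qj <- pairs$negatives[[j]]
  if (length(pj) == 0) stop_invalid("anchor with no positive pair violates the sibling rule")
  z <- if (normalize) l2_normalize_rows(embeddings) else embeddings
  ep <- exp(drop(z[pj, , drop = FALSE] %*% z[j, ]) / tau)
  eq <- exp(drop(z[qj, , drop = FALSE] %*% z[j, ]) / tau)
  num <- mean(ep)
  den <- sum(ep) + sum(thrust[j, qj] * eq)
  -log(num / den)
}

#' Batch SCDR loss (and gradient)
#'
#' Vectorized evaluation of the contrastive loss over all 2N views:
#' classifies pairs, computes the thrust matrix, and returns the loss
#' breakdown. When `want_grad = TRUE` the gradient of `l_scdr` with
#' respect to the (raw, pre-normalization) embeddings is returned; thrust
#' weights and pair assignments are treated as constants (stop-gradient),
#' so the gradient flows only through the dot-product logits.
#'
#' @param embeddings 2N x d matrix of view embeddings.
#' @param labels,predictions length-2N vectors.
#' @param config an [scdr_config()].
#' @param want_grad also compute `d l_scdr / d embeddings`.
#' @return list of class `scdr_loss`: `l_scdr`, `per_anchor` (length 2N;
#'   0 for non-anchors), `anchor_flags`, `anchor_fraction`, `pairs`, `S`,
#'   and optionally `grad` (2N x d).
#' @export
scdr_batch_loss <- function(embeddings, labels, predictions, config,
                            want_grad = FALSE) {
  n <- length(labels)
  if (!is.matrix(embeddings) || nrow(embeddings) != n) {
    stop_invalid("`embeddings` must be a 2N x d matrix aligned with labels")
  }
  pairs <- classify_pairs(labels, predictions, config$omega)
  S <- thrust_matrix(labels, embeddings, pairs, config)
  z <- if (config$normalize_embeddings) l2_normalize_rows(embeddings) else embeddings
  per_anchor <- numeric(n)
  grad_z <- if (want_grad) matrix(0, n, ncol(embeddings)) else NULL
  anchors <- which(pairs$anchor_flags)
  if (length(anchors)) {
    logits <- tcrossprod(z) / config$tau
    E <- exp(logits)
    ep_sum <- rowSums(E * pairs$pos_mask)
    eq_sum <- rowSums(E * S * pairs$neg_mask)
    den <- ep_sum + eq_sum
    la <- log(den[anchors]) - log(ep_sum[anchors]) + log(pairs$n_pos[anchors])
    per_anchor[anchors] <- la
    if (want_grad) {
      # dL_j/ds_{ji} for anchors: positives e/den - e/ep_sum; negatives S e/den
      Wm <- matrix(0, n, n)
      Wm[anchors, ] <-
        (E * pairs$pos_mask * (1 / den - 1 / ep_sum))[anchors, , drop = FALSE] +
        (E * S * pairs$neg_mask / den)[anchors, , drop = FALSE]
      Wm <- Wm / (n * config$tau)          # mean over 2N and d logits/dz
      sym <- Wm + t(Wm)                    # s_{ji} depends on z_j and z_i
      grad_z <- sym %*% z
      if (config$normalize_embeddings) {
        nrm <- sqrt(rowSums(embeddings^2))
        dotzg <- rowSums(z * grad_z)
        grad_z <- (grad_z - z * dotzg) / nrm
      }
    }
  } else if (want_grad) {
    grad_z <- matrix(0, n, ncol(embeddings))
  }
  structure(list(l_scdr = mean(per_anchor), per_anchor = per_anchor,
                 anchor_flags = pairs$anchor_flags,
                 anchor_fraction = mean(pairs$anchor_flags),
                 pairs = pairs, S = S, grad = grad_z),
            class = "scdr_loss")
}

#' Regression loss (L1 or focal L1)
#'
#' `l1` is the mean absolute error. `focal_l1` re-weights each absolute
#' error by `sigmoid(gamma * |e|)^p`, emphasising larger errors.
#'
#' @param predictions,labels numeric vectors of equal length.
#' @param kind `"l1"` or `"focal_l1"`.
#' @param focal_gamma,focal_p focal parameters (defaults 1, 1).
#' @param want_grad also return the gradient with respect to predictions.
#' @return scalar loss, or list(loss, grad) when `want_grad`.
#' @export
regression_loss <- function(predictions, labels, kind = c("focal_l1", "l1"),
                            focal_gamma = 1, focal_p = 1, want_grad = FALSE) {
  kind <- match.arg(kind)
  if (length(predictions) != length(labels)) stop_invalid("length mismatch")
  e <- predictions - labels
  ae <- abs(e)
  m <- length(e)
  if (kind == "l1") {
    loss <- mean(ae)
    if (!want_grad) return(loss)
    return(list(loss = loss, grad = sign(e) / m))
  }
  sg <- sigmoid(focal_gamma * ae)
  w <- sg^focal_p
  loss <- mean(w * ae)
  if (!want_grad) return(loss)
  dw <- focal_p * sg^(focal_p - 1) * sg * (1 - sg) * focal_gamma
  grad <- sign(e) * (w + ae * dw) / m
  list(loss = loss, grad = grad)
}

#' Total training loss
#'
#' `L_sum = alpha * L_reg + beta * L_scdr`.
#'
#' @param l_reg,l_scdr component losses.
#' @param alpha,beta non-negative weights.
#' @return scalar.
#' @export
total_loss <- function(l_reg, l_scdr, alpha = 1, beta = 3) {
  check_number(alpha, "alpha", lower = 0)
  check_number(beta, "beta", lower = 0)
  alpha * l_reg + beta * l_scdr
}
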