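# Independent nested-loop reference implementation of the contrastive
# loss: classifies pairs, builds thrust weights and evaluates every
# per-anchor term with explicit loops and scalar arithmetic. Kept free of
# any code shared with the package's vectorized path.
oracle_scdr <- function(embeddings, labels, predictions, omega, tau, eta,
                        sigma_l, eps_f, s_max, normalize = TRUE) {
  n <- length(labels)
  z <- embeddings
  if (normalize) {
    for (i in seq_len(n)) z[i, ] <- z[i, ] / sqrt(sum(z[i, ]^2))
  }
  per <- numeric(n)
  for (j in seq_len(n)) {
    pos <- integer(0); neg <- integer(0)
    for (i in seq_len(n)) {
      if (i == j) next
      if (abs(labels[i] - labels[j]) <= omega) {
        pos <- c(pos, i)
      } else if (abs(predictions[i] - predictions[j]) <= omega) {
        neg <- c(neg, i)
      }
    }
    if (length(neg) == 0) next   # not an anchor: contributes exactly 0
    num <- 0; den <- 0
    for (p in pos) {
      e <- exp(sum(z[j, ] * z[p, ]) / tau)
      num <- num + e / length(pos)
      den <- den + e
    }
    for (q in neg) {
      sim_l <- exp(-abs(labels[j] - labels[q]) / sigma_l)
      cosv <- sum(z[j, ] * z[q, ]) /
        (sqrt(sum(z[j, ]^2)) * sqrt(sum(z[q, ]^2)))
      sim_f <- max((1 + cosv) / 2, eps_f)
      S <- min(eta / (sim_l * sim_f), s_max)
      den <- den + S * exp(sum(z[j, ] * z[q, ]) / tau)
    }
    per[j] <- -log(num / den)
  }
  list(per_anchor = per, l_scdr = mean(per))
}

oracle_scdr_cfg <- function(embeddings, labels, predictions, cfg) {
  oracle_scdr(embeddings, labels, predictions, cfg$omega, cfg$tau, cfg$eta,
              cfg$sigma_l, cfg$eps_f, cfg$s_max, cfg$normalize_embeddings)
}
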