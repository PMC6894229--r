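# Independent oracles used to pin down expected values.  These are written
# as direct transcriptions of the defining formulas (dense solves, explicit
# enumeration) and never call the package's own code paths.

# dense direct solve of the weighted penalized baseline system
# min_z sum(w (y - z)^2) + lam * sum(diff(z, d = 2)^2)
dense_als_solve <- function(y, w, lam) {
  n <- length(y)
  d2 <- diff(diag(n), differences = 2)
  a <- diag(w) + lam * t(d2) %*% d2
  as.numeric(solve(a, w * y))
}

# plain-loop NIPALS transcription for a single response
nipals_reference <- function(x, y, a_max) {
  w_list <- list(); p_list <- list(); t_list <- list(); q_list <- list()
  for (a in seq_len(a_max)) {
    w <- as.numeric(t(x) %*% y)
    w <- w / sqrt(sum(w^2))
    tt <- as.numeric(x %*% w)
    p <- as.numeric(t(x) %*% tt) / sum(tt^2)
    q <- sum(y * tt) / sum(tt^2)
    x <- x - outer(tt, p)
    y <- y - q * tt
    w_list[[a]] <- w; p_list[[a]] <- p; t_list[[a]] <- tt; q_list[[a]] <- q
  }
  list(w = do.call(cbind, w_list), p = do.call(cbind, p_list),
       t = do.call(cbind, t_list), q = unlist(q_list))
}

# brute-force Benjamini-Hochberg: evaluate the min-over-suffix definition
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (k in seq_len(m)) {
    adj_sorted[k] <- min(1, min(p[o][k:m] * m / (k:m)))
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Mann-Whitney AUC by brute-force pair counting (ties count 1/2)
auc_mannwhitney <- function(score, y) {
  pos <- score[y == 1]; neg <- score[y == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# Breslow partial log-likelihood for a single covariate, no ties assumed
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# two-stage grid maximization of the Breslow partial likelihood
cox_grid_oracle <- function(time, event, x, lo = -8, hi = 8) {
  g1 <- seq(lo, hi, length.out = 401)
  v1 <- vapply(g1, breslow_loglik, numeric(1), time = time, event = event,
               x = x)
  b1 <- g1[which.max(v1)]
  g2 <- seq(b1 - 0.05, b1 + 0.05, length.out = 2001)
  v2 <- vapply(g2, breslow_loglik, numeric(1), time = time, event = event,
               x = x)
  g2[which.max(v2)]
}

# exact two-sided Fisher p by enumerating all tables with the observed
# margins and summing probabilities no larger than the observed one
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# the 14 serum metabolites printed as differential in the published table
differential_serum_panel <- function() {
  c("3-Hydroxybutyrate", "Acetate", "Acetoacetate", "Glutamine",
    "Isoleucine", "Isopropyl alcohol", "Lactate", "Leucine", "Lysine",
    "N-acetylated groups", "Phenylalanine", "Propylene Glycol",
    "Pyruvate", "Valine")
}

# small serum-like config for fast cohort tests
fast_serum_config <- function(...) {
  cohort_config(axis_points = 2048, ...)
}
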