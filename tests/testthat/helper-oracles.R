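## Independent brute-force oracles, deliberately naive implementations.

# AUC by exhaustive pair enumeration, ties counted one half.
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    if (p > n) wins <- wins + 1
    else if (p == n) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# Benjamini-Hochberg step-up by its definition: q_(i) = min_{j>=i} m p_(j)/j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# NormFinder-style stability from the variance-component equations, all
# loops, no vectorisation shared with the implementation.
oracle_normfinder <- function(m, group) {
  n <- nrow(m)
  z <- m
  for (j in seq_len(ncol(m))) z[, j] <- m[, j] - mean(m[, j])
  for (i in seq_len(n)) z[i, ] <- z[i, ] - mean(z[i, ])
  glev <- unique(group)
  G <- length(glev)
  d <- s2 <- matrix(0, n, G)
  sizes <- numeric(G)
  for (gi in seq_along(glev)) {
    cols <- which(group == glev[gi])
    sizes[gi] <- length(cols)
    for (i in seq_len(n)) {
      d[i, gi] <- mean(z[i, cols])
      s2[i, gi] <- var(z[i, cols])
    }
  }
  sig2 <- matrix(0, n, G)
  for (gi in seq_len(G)) {
    tot <- sum(s2[, gi])
    for (i in seq_len(n))
      sig2[i, gi] <- max(0, (s2[i, gi] - tot / (n * (n - 1))) / (1 - 2 / n))
  }
  samp <- sweep(sig2, 2, sizes, `/`)
  gamma2 <- max(0, sum(d^2) / ((n - 1) * (G - 1)) - mean(samp))
  rho <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (gi in seq_len(G)) {
      sh <- if (gamma2 + samp[i, gi] > 0) gamma2 / (gamma2 + samp[i, gi]) else 0
      acc <- acc + abs(d[i, gi] * sh) + sqrt(samp[i, gi])
    }
    rho[i] <- acc / G
  }
  rho
}

# Build a long-format well table from a merged Ct matrix (one replicate
# per cell, perfect quality).
wells_from_matrix <- function(m, quality = 1) {
  data.frame(
    sample_id = rep(colnames(m), each = nrow(m)),
    assay_id = rep(rownames(m), times = ncol(m)),
    replicate = 1L,
    ct = as.vector(m),
    quality = quality,
    stringsAsFactors = FALSE
  )
}

# Small simulated study config for fast tests.
tiny_config <- function(...) {
  defaults <- list(n_per_group = c(NSCLC = 12L, COPD = 6L, control = 6L),
                   n_assays = 30L, n_planted = 5L, effect_size = 2,
                   baseline_range = c(12, 22), dropout_base = 0.01,
                   seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# Annotation data frame from a label vector.
ann <- function(ids, groups) {
  data.frame(sample_id = ids, group = groups, stringsAsFactors = FALSE)
}
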