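# Independent oracles, coded as naive step-by-step procedures so they
# share no code path with the package implementation.

# Brute-force running-sum enrichment score: walk the ranked list one gene
# at a time, incrementing by |stat|^p (normalized over hits) at hits and
# decrementing by 1/(N-k) at misses; return the extremum of largest
# magnitude (positive wins exact ties).
brute_es <- function(stats_sorted, hit, p = 0) {
  N <- length(hit)
  k <- sum(hit)
  if (p == 0) {
    # walk with integer numerators (denominator k(N-k)) so that exact
    # magnitude ties between the extrema are detected reliably; a tie
    # means the direction is ambiguous and the score is 0
    run <- 0L
    hi <- 0L
    lo <- 0L
    for (i in seq_len(N)) {
      run <- if (hit[i]) run + (N - k) else run - k
      if (run > hi) hi <- run
      if (run < lo) lo <- run
    }
    if (hi == -lo) return(0)
    return(if (hi > -lo) hi / (k * (N - k)) else lo / (k * (N - k)))
  }
  w <- abs(stats_sorted)^p
  sw <- sum(w[hit])
  run <- 0
  hi <- 0
  lo <- 0
  for (i in seq_len(N)) {
    run <- if (hit[i]) run + w[i] / sw else run - 1 / (N - k)
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  if (abs(hi + lo) <= 1e-12 * max(hi, -lo)) return(0)
  if (hi > -lo) hi else lo
}

# Lamb-convention two-set connectivity score via the brute-force ES.
brute_ks_connectivity <- function(profile_sorted_names, up, dn) {
  N <- length(profile_sorted_names)
  eu <- brute_es(rep(1, N), profile_sorted_names %in% up, p = 0)
  ed <- brute_es(rep(1, N), profile_sorted_names %in% dn, p = 0)
  if (sign(eu) != sign(ed)) (eu - ed) / 2 else 0
}

# Direct-formula moderated t, scalar arithmetic per gene. The trigamma
# inversion comes from limma (an implementation the package does not
# share); everything else is written out longhand.
oracle_moderated_t <- function(logFC, s2, d, se_unscaled) {
  x <- pmax(s2, 1e-5 * median(s2))
  z <- log(x)
  ev <- sum((z - mean(z))^2) / (length(z) - 1)
  excess <- ev - trigamma(d / 2)
  if (excess <= 0) {
    d0 <- Inf
    s0 <- mean(x)
  } else {
    d0 <- 2 * limma::trigammaInverse(excess)
    s0 <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                digamma(d0 / 2) - log(d0 / 2))
  }
  t <- numeric(length(s2))
  for (g in seq_along(s2)) {
    sp <- if (is.finite(d0)) (d0 * s0 + d * s2[g]) / (d0 + d) else s0
    t[g] <- logFC[g] / (sqrt(sp) * se_unscaled)
  }
  list(t = t, d0 = d0, s0_2 = s0)
}

# Hand-rolled weighted Pearson correlation of two rank vectors.
oracle_weighted_rank_cor <- function(x, y, w) {
  rx <- rank(x); ry <- rank(y)
  mx <- sum(w * rx) / sum(w); my <- sum(w * ry) / sum(w)
  num <- 0; vx <- 0; vy <- 0
  for (i in seq_along(w)) {
    num <- num + w[i] * (rx[i] - mx) * (ry[i] - my)
    vx <- vx + w[i] * (rx[i] - mx)^2
    vy <- vy + w[i] * (ry[i] - my)^2
  }
  unname(num / sqrt(vx * vy))
}

# All permutations of 1..n (n small), for exhaustive permutation nulls.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- cbind(i, sub + (sub >= i))
    out <- rbind(out, rest)
  }
  out
}

# Mean silhouette width for a labelled embedding (euclidean distances).
mean_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(unique(labels[!own]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Simulation conditions used throughout: the generator defaults that
# emulate the study's two-group microarray design.
default_sim <- function(seed, n_genes = 2000, n_per_group = 5, n_de = 200,
                        effect = 2, sigma = 0.5) {
  simulate_expression(n_genes, n_per_group, n_de, effect, sigma, seed = seed)
}
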