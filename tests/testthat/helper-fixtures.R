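# Shared fixtures, built in code at test time.

# Planted checkerboard whose row-shift patterns remain distinct after
# per-row centering and scaling (patterns must not be proportional once
# centered, or row normalization genuinely merges the clusters).
make_checkerboard <- function(N = 120, D = 60, shift = 5, noise = 1,
                              seed = 11) {
  set.seed(seed)
  M <- shift / 5 * matrix(c(5, 0, -5,
                            -5, 5, 0,
                            0, -5, 5,
                            5, -5, 5), 4, 3, byrow = TRUE)
  rb <- sample(1:4, N, replace = TRUE)
  cb <- sample(1:3, D, replace = TRUE)
  X <- M[cbind(rep(rb, D), rep(cb, each = N))] +
    stats::rnorm(N * D, sd = noise)
  dim(X) <- c(N, D)
  list(X = X, rb = rb, cb = cb, M = M)
}

# Two well-separated subject clusters expressed through the generator's
# own block model (normalization-safe shift patterns).
two_cluster_config <- function(n = 200, shift = 5, noise_sd = 1, seed = 1) {
  synthetic_config(
    n_per_group = c(PD = round(0.6 * n), HC = round(0.25 * n),
                    SWEDD = n - round(0.6 * n) - round(0.25 * n)),
    row_clusters = list(k = 2, prop = c(0.5, 0.5),
                        M = shift / 5 * matrix(c(5, 0, -5,
                                                 -5, 5, 0), 2, 3,
                                               byrow = TRUE)),
    pathway_effects = list(),
    noise_sd = noise_sd, seed = seed)
}

fast_ctl <- function(seed = 1, ...) {
  srvcc_control(pretrain_epochs = 20, epochs = 40, warmup = 15, lr = 3e-3,
                seed = seed, ...)
}

# Brute-force pair-counting adjusted Rand oracle.
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / denom
}

# Step-up FDR oracle, independent of p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# Exhaustive-pair Cliff's delta oracle.
cliffs_oracle <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + sign(x - y)
  s / (length(a) * length(b))
}
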