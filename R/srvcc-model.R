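#' Variational co-clustering primitives
#'
#' The co-clustering model pairs two variational autoencoders -- a row
#' model on the subject-by-feature matrix X and a column model on its
#' transpose -- each with a learnable Gaussian-mixture latent prior.  Soft
#' cluster assignments are the mixture responsibilities of the encoder
#' means, and the two partitions are coupled through a mutual-information
#' penalty on their data-weighted cross-tabulation.
#'
#' @name srvcc
NULL

#' Gaussian-mixture prior parameters
#'
#' @param K number of components.
#' @param d latent dimension.
#' @param log_weights,means,log_vars optional initial values.
#' @return object of class `gmm_params` (`log_weights` length K, `means`
#'   and `log_vars` K x d).
#' @export
gmm_params <- function(K, d, log_weights = rep(0, K),
                       means = matrix(0, K, d),
                       log_vars = matrix(0, K, d)) {
  stopifnot(length(log_weights) == K, nrow(means) == K, ncol(means) == d,
            nrow(log_vars) == K, ncol(log_vars) == d)
  structure(list(K = K, d = d, log_weights = log_weights, means = means,
                 log_vars = log_vars),
            class = "gmm_params")
}

gmm_log_weights_norm <- function(prior) {
  prior$log_weights - logsumexp(prior$log_weights)
}

# K-column matrix of per-component diagonal-Gaussian log densities for the
# rows of z, plus the (normalized) log mixture weights.
gmm_component_logliks <- function(z, prior) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  stopifnot(ncol(z) == prior$d, all(is.finite(z)))
  lw <- gmm_log_weights_norm(prior)
  out <- matrix(0, nrow(z), prior$K)
  for (k in seq_len(prior$K)) {
    v <- exp(prior$log_vars[k, ])
    out[, k] <- lw[k] - 0.5 * sum(log(2 * pi) + prior$log_vars[k, ]) -
      0.5 * colSums((t(z) - prior$means[k, ])^2 / v)
  }
  out
}

#' Log density of a Gaussian-mixture prior
#'
#' `log p(z) = logsumexp_k [log pi_k + log N(z | mu_k, diag sigma_k^2)]`,
#' evaluated stably in log space.
#'
#' @param z latent vector, or matrix with one sample per row.
#' @param prior a [gmm_params()].
#' @return log density (one value per sample).
#' @export
gmm_log_density <- function(z, prior) {
  ll <- gmm_component_logliks(z, prior)
  as.numeric(logsumexp(ll))
}

#' Mixture responsibilities
#'
#' Posterior component probabilities `gamma_k proportional to
#' pi_k N(z | mu_k, diag sigma_k^2)`, normalized in log space so that
#' underflow can never produce `NaN`.
#'
#' @inheritParams gmm_log_density
#' @return vector (or matrix, one row per sample) summing to 1.
#' @export
responsibilities <- function(z, prior) {
  ll <- gmm_component_logliks(z, prior)
  g <- exp(ll - logsumexp(ll))
  if (nrow(g) == 1 && is.null(dim(z))) as.numeric(g) else g
}

#' Hard cluster labels from soft assignments
#'
#' Per row, the index of the maximum responsibility; exact ties break to
#' the lowest index so the reduction is deterministic.
#'
#' @param gamma row-stochastic assignment matrix.
#' @return integer labels in `1..K`.
#' @export
hard_assign <- function(gamma) {
  if (is.null(dim(gamma))) gamma <- matrix(gamma, nrow = 1)
  max.col(gamma, ties.method = "first")
}

one_hot <- function(labels, K) {
  m <- matrix(0, length(labels), K)
  m[cbind(seq_along(labels), labels)] <- 1
  m
}

#' Data-weighted cross-tabulation of two soft partitions
#'
#' `T = Gamma_r' W Gamma_c` normalized by its grand sum, a Kr x Kc joint
#' distribution over (row cluster, column cluster) mass.  The weight
#' matrix carries the data through the coupling; the default used in
#' training is `W_ij = |x_ij|` on the normalized matrix, which reduces to
#' the plain partition product when W is the identity.
#'
#' @param gamma_rows N x Kr row-stochastic matrix.
#' @param gamma_cols D x Kc row-stochastic matrix.
#' @param weight_matrix N x D nonnegative matrix with positive sum.
#' @param kind `"soft"` or `"reduced"` (bookkeeping tag).
#' @return object of class `cross_tab` with fields `table` and `kind`.
#' @export
cross_tab <- function(gamma_rows, gamma_cols, weight_matrix,
                      kind = "soft") {
  stopifnot(nrow(gamma_rows) == nrow(weight_matrix),
            nrow(gamma_cols) == ncol(weight_matrix),
            all(weight_matrix >= 0))
  s <- sum(weight_matrix)
  if (s <= 0) stop("weight matrix sums to zero; cross-tabulation undefined")
  raw <- crossprod(gamma_rows, weight_matrix %*% gamma_cols)
  structure(list(table = raw / sum(raw), kind = kind), class = "cross_tab")
}

#' Mutual information of a joint cluster table (nats)
#'
#' `MI(T) = sum_ab T_ab log(T_ab / (T_a. T_.b))` with the `0 log 0 = 0`
#' convention; nonnegative, and at most `min(log Kr, log Kc)`.
#'
#' @param t a `cross_tab` or a nonnegative matrix summing to 1.
#' @export
mutual_information <- function(t) {
  tab <- if (inherits(t, "cross_tab")) t$table else t
  stopifnot(all(tab >= 0), abs(sum(tab) - 1) < 1e-6)
  pr <- rowSums(tab); pc <- colSums(tab)
  pos <- tab > 0
  sum(tab[pos] * log(tab[pos] / outer(pr, pc)[pos]))
}

#' Mutual-information coupling penalty
#'
#' `L_MI = lambda log(1 + (1 - MI(T_red)/MI(T_org)))`, where `T_org` is the
#' soft cross-tabulation and `T_red` its hard-assignment reduction: the
#' penalty is exactly zero when hardening loses no association, and grows
#' as hard labels discard soft co-structure.  The MI ratio is clamped to
#' `[0, 2 - 1e-6]`; a degenerate `MI(T_org)` below tolerance yields a zero
#' penalty with a warning.
#'
#' @inheritParams cross_tab
#' @param lambda_mi nonnegative coupling weight.
#' @export
mi_coupling_loss <- function(gamma_rows, gamma_cols, weight_matrix,
                             lambda_mi = 1) {
  stopifnot(lambda_mi >= 0)
  if (lambda_mi == 0) return(0)
  torg <- cross_tab(gamma_rows, gamma_cols, weight_matrix, "soft")
  hr <- one_hot(hard_assign(gamma_rows), ncol(gamma_rows))
  hc <- one_hot(hard_assign(gamma_cols), ncol(gamma_cols))
  tred <- cross_tab(hr, hc, weight_matrix, "reduced")
  mi_org <- mutual_information(torg)
  mi_red <- mutual_information(tred)
  if (mi_org <= 1e-9) {
    warning("MI(T_org) is degenerate; coupling penalty set to 0",
            call. = FALSE)
    return(0)
  }
  ratio <- min(max(mi_red / mi_org, 0), 2 - 1e-6)
  lambda_mi * log(1 + (1 - ratio))
}
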