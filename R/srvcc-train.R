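#' Training the variational co-clustering model
#'
#' Each side (rows = subjects, columns = features) is a small
#' fully-connected variational autoencoder (two tanh hidden layers, widths
#' 64 and 32, latent dimension 10 by default) whose latent prior is a
#' learnable diagonal Gaussian mixture.  The per-side objective is
#' `sum_i ||x_i - xhat_i||^2 + beta KL(q(z|x) || p(z))`, the KL estimated
#' by a single reparameterized sample (`log q - log p`); reconstruction is
#' summed over features and averaged over the batch.  Training is staged:
#' reconstruction-only pretraining, k-means initialization of the mixture
#' on the encoder means, then joint Adam optimization under a linear KL
#' warm-up, with a full-batch mutual-information coupling step each epoch.
#' Gradients are derived analytically (no autodiff dependency).
#'
#' @name srvcc_training
NULL

#' Training control parameters
#'
#' @param pretrain_epochs reconstruction-only epochs before the mixture
#'   prior is attached.
#' @param epochs joint-training epochs.
#' @param warmup epochs over which the KL weight beta rises linearly to 1.
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param lambda_mi weight of the mutual-information coupling.
#' @param val_frac fraction of subjects held out for validation
#'   reconstruction error.
#' @param latent_dim,hidden latent dimension and hidden-layer widths.
#' @param seed RNG seed; training is deterministic given seed and config.
#' @param verbose print per-epoch losses.
#' @export
srvcc_control <- function(pretrain_epochs = 20, epochs = 100, warmup = 30,
                          lr = 1e-3, batch_size = 64, lambda_mi = 1,
                          val_frac = 0.2, latent_dim = 10,
                          hidden = c(64, 32), seed = 1, verbose = FALSE) {
  stopifnot(lambda_mi >= 0, val_frac >= 0, val_frac < 1)
  list(pretrain_epochs = pretrain_epochs, epochs = epochs, warmup = warmup,
       lr = lr, batch_size = batch_size, lambda_mi = lambda_mi,
       val_frac = val_frac, latent_dim = latent_dim, hidden = hidden,
       seed = seed, verbose = verbose)
}

net_init <- function(input_dim, hidden, latent_dim) {
  rmat <- function(r, c) matrix(stats::rnorm(r * c, sd = sqrt(1 / c)), r, c)
  list(
    W1 = rmat(hidden[1], input_dim), b1 = numeric(hidden[1]),
    W2 = rmat(hidden[2], hidden[1]), b2 = numeric(hidden[2]),
    Wmu = rmat(latent_dim, hidden[2]), bmu = numeric(latent_dim),
    Wlv = rmat(latent_dim, hidden[2]), blv = numeric(latent_dim),
    V1 = rmat(hidden[2], latent_dim), c1 = numeric(hidden[2]),
    V2 = rmat(hidden[1], hidden[2]), c2 = numeric(hidden[1]),
    V3 = rmat(input_dim, hidden[1]), c3 = numeric(input_dim)
  )
}

addrow <- function(m, v) sweep(m, 2L, v, "+")

encode <- function(net, X) {
  H1 <- tanh(addrow(X %*% t(net$W1), net$b1))
  H2 <- tanh(addrow(H1 %*% t(net$W2), net$b2))
  MU <- addrow(H2 %*% t(net$Wmu), net$bmu)
  LV <- pmin(pmax(addrow(H2 %*% t(net$Wlv), net$blv), -10), 10)
  list(H1 = H1, H2 = H2, MU = MU, LV = LV)
}

decode <- function(net, Z) {
  G1 <- tanh(addrow(Z %*% t(net$V1), net$c1))
  G2 <- tanh(addrow(G1 %*% t(net$V2), net$c2))
  XH <- addrow(G2 %*% t(net$V3), net$c3)
  list(G1 = G1, G2 = G2, XH = XH)
}

#' Evidence-lower-bound loss for one side
#'
#' @param batch matrix of samples (rows).
#' @param side_model list with elements `net` and `prior` (`NULL` prior
#'   means a standard-normal prior, as in pretraining).
#' @param beta KL weight in `[0, 1]`.
#' @param eps optional fixed noise matrix for the reparameterized sample
#'   (matching `batch` rows x latent dim); drawn from the RNG when absent.
#' @param sample if `FALSE`, use `z = mu` (deterministic evaluation).
#' @return list with `recon_mse` (sum over features, mean over batch),
#'   `kl_estimate` (mean single-sample `log q - log p`) and
#'   `total = recon_mse + beta * kl_estimate`.
#' @export
elbo_loss <- function(batch, side_model, beta, eps = NULL, sample = TRUE) {
  stopifnot(beta >= 0, beta <= 1)
  if (!all(is.finite(batch))) stop("non-finite values in batch")
  net <- side_model$net
  enc <- encode(net, batch)
  d <- ncol(enc$MU)
  E <- if (!sample) matrix(0, nrow(batch), d) else
    eps %||% matrix(stats::rnorm(nrow(batch) * d), nrow(batch), d)
  Z <- enc$MU + exp(enc$LV / 2) * E
  dec <- decode(net, Z)
  recon <- mean(rowSums((batch - dec$XH)^2))
  log_q <- rowSums(-0.5 * log(2 * pi) - 0.5 * enc$LV - 0.5 * E^2)
  prior <- side_model$prior %||% gmm_params(1, d)
  log_p <- gmm_log_density(Z, prior)
  kl <- mean(log_q - log_p)
  list(recon_mse = recon, kl_estimate = kl, total = recon + beta * kl)
}

# Analytic gradients of the per-batch objective recon + beta * kl with a
# reparameterized sample.  Returns gradients named like the net fields,
# plus prior gradients when beta > 0.
elbo_grads <- function(batch, net, prior, beta, E) {
  B <- nrow(batch)
  enc <- encode(net, batch)
  SIG <- exp(enc$LV / 2)
  Z <- enc$MU + SIG * E
  dec <- decode(net, Z)

  g <- list()
  dXH <- 2 * (dec$XH - batch) / B
  g$V3 <- crossprod(dXH, dec$G2); g$c3 <- colSums(dXH)
  dG2 <- (dXH %*% net$V3) * (1 - dec$G2^2)
  g$V2 <- crossprod(dG2, dec$G1); g$c2 <- colSums(dG2)
  dG1 <- (dG2 %*% net$V2) * (1 - dec$G1^2)
  g$V1 <- crossprod(dG1, Z); g$c1 <- colSums(dG1)
  dZ <- dG1 %*% net$V1

  dLV <- matrix(0, B, ncol(Z))
  gp <- NULL
  if (beta > 0) {
    ll <- gmm_component_logliks(Z, prior)
    gam <- exp(ll - logsumexp(ll))
    # d(-log p)/dZ accumulated over components
    dlogp_dZ <- matrix(0, B, ncol(Z))
    K <- prior$K
    gp <- list(log_weights = numeric(K),
               means = matrix(0, K, ncol(Z)),
               log_vars = matrix(0, K, ncol(Z)))
    pik <- exp(gmm_log_weights_norm(prior))
    for (k in seq_len(K)) {
      v <- exp(prior$log_vars[k, ])
      dev <- sweep(Z, 2L, prior$means[k, ])
      dlogp_dZ <- dlogp_dZ - gam[, k] * sweep(dev, 2L, v, "/")
      gp$means[k, ] <- -(beta / B) * colSums(gam[, k] * sweep(dev, 2L, v, "/"))
      gp$log_vars[k, ] <- -(beta / B) *
        colSums(gam[, k] * 0.5 * (sweep(dev^2, 2L, v, "/") - 1))
    }
    gp$log_weights <- -(beta / B) * (colSums(gam) - B * pik)
    dZ <- dZ - (beta / B) * dlogp_dZ
    dLV <- dLV - (beta / B) * 0.5   # d log q / d LV = -1/2
  }
  dMU <- dZ
  dLV <- dLV + dZ * 0.5 * SIG * E   # z = mu + exp(lv/2) eps

  dH2 <- dMU %*% net$Wmu + dLV %*% net$Wlv
  g$Wmu <- crossprod(dMU, enc$H2); g$bmu <- colSums(dMU)
  g$Wlv <- crossprod(dLV, enc$H2); g$blv <- colSums(dLV)
  dA2 <- dH2 * (1 - enc$H2^2)
  g$W2 <- crossprod(dA2, enc$H1); g$b2 <- colSums(dA2)
  dA1 <- (dA2 %*% net$W2) * (1 - enc$H1^2)
  g$W1 <- crossprod(dA1, batch); g$b1 <- colSums(dA1)
  list(net = g, prior = gp)
}

adam_new <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    if (is.null(grads[[nm]])) next
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * grads[[nm]]
    st$v <- beta2 * st$v + (1 - beta2) * grads[[nm]]^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

# Full-batch gradients of the MI coupling penalty with respect to both
# encoders (via their latent means) and both priors.  T_red is piecewise
# constant in the parameters, so gradient flows through T_org only.
mi_grads <- function(Xr, Xc, W, row, col, lambda_mi) {
  enc_r <- encode(row$net, Xr); enc_c <- encode(col$net, Xc)
  llr <- gmm_component_logliks(enc_r$MU, row$prior)
  llc <- gmm_component_logliks(enc_c$MU, col$prior)
  Gr <- exp(llr - logsumexp(llr)); Gc <- exp(llc - logsumexp(llc))

  Sr <- crossprod(Gr, W %*% Gc); s <- sum(Sr); Torg <- Sr / s
  Hr <- one_hot(hard_assign(Gr), ncol(Gr))
  Hc <- one_hot(hard_assign(Gc), ncol(Gc))
  Sred <- crossprod(Hr, W %*% Hc); Tred <- Sred / sum(Sred)
  mi_org <- mutual_information(Torg); mi_red <- mutual_information(Tred)
  if (mi_org <= 1e-8)
    return(list(loss = 0, mi_org = mi_org, mi_red = mi_red, grads = NULL))
  ratio_raw <- mi_red / mi_org
  ratio <- min(max(ratio_raw, 0), 2 - 1e-6)
  loss <- lambda_mi * log(1 + (1 - ratio))
  if (ratio != ratio_raw)  # clamp saturated: zero subgradient
    return(list(loss = loss, mi_org = mi_org, mi_red = mi_red,
                grads = NULL))
  dmi_org <- lambda_mi * (-1 / (2 - ratio)) * (-mi_red / mi_org^2)
  pr <- rowSums(Torg); pc <- colSums(Torg)
  gT <- matrix(0, nrow(Torg), ncol(Torg))
  pos <- Torg > 0
  gT[pos] <- log(Torg[pos] / outer(pr, pc)[pos]) - 1
  gS <- dmi_org * (gT - sum(Torg * gT)) / s

  grad_Gr <- W %*% Gc %*% t(gS)          # N x Kr
  grad_Gc <- crossprod(W, Gr) %*% gS     # D x Kc

  side_grads <- function(Gam, grad_Gam, enc, side, X) {
    dl <- Gam * (grad_Gam - rowSums(Gam * grad_Gam))  # softmax jacobian
    prior <- side$prior
    K <- prior$K
    dMU <- matrix(0, nrow(Gam), ncol(enc$MU))
    gp <- list(log_weights = numeric(K),
               means = matrix(0, K, ncol(enc$MU)),
               log_vars = matrix(0, K, ncol(enc$MU)))
    for (k in seq_len(K)) {
      v <- exp(prior$log_vars[k, ])
      dev <- sweep(enc$MU, 2L, prior$means[k, ])
      devv <- sweep(dev, 2L, v, "/")
      dMU <- dMU - dl[, k] * devv
      gp$means[k, ] <- colSums(dl[, k] * devv)
      gp$log_vars[k, ] <- colSums(dl[, k] * 0.5 * (dev * devv - 1))
    }
    pik <- exp(gmm_log_weights_norm(prior))
    gp$log_weights <- colSums(dl) - sum(dl) * pik
    # encoder backprop (means path only; assignments use means)
    g <- list()
    dH2 <- dMU %*% side$net$Wmu
    g$Wmu <- crossprod(dMU, enc$H2); g$bmu <- colSums(dMU)
    dA2 <- dH2 * (1 - enc$H2^2)
    g$W2 <- crossprod(dA2, enc$H1); g$b2 <- colSums(dA2)
    dA1 <- (dA2 %*% side$net$W2) * (1 - enc$H1^2)
    g$W1 <- crossprod(dA1, X); g$b1 <- colSums(dA1)
    list(net = g, prior = gp)
  }
  list(loss = loss, mi_org = mi_org, mi_red = mi_red,
       grads = list(row = side_grads(Gr, grad_Gr, enc_r, row, Xr),
                    col = side_grads(Gc, grad_Gc, enc_c, col, Xc)))
}

# One closed-form EM step for the mixture prior on the full-batch encoder
# means: responsibility-weighted component weights, means and variances
# (floored).  Anchoring the prior to the current latent layout this way is
# far more stable than stochastic-gradient prior updates, which let
# components wander off their clusters.
em_update_prior <- function(MU, prior, var_floor = 0.05) {
  gam <- responsibilities(MU, prior)
  if (is.null(dim(gam))) gam <- matrix(gam, nrow = 1)
  nk <- pmax(colSums(gam), 1e-8)
  means <- crossprod(gam, MU) / nk
  lv <- prior$log_vars
  for (k in seq_len(prior$K)) {
    dev2 <- sweep(MU, 2L, means[k, ])^2
    lv[k, ] <- log(pmax(colSums(gam[, k] * dev2) / nk[k], var_floor))
  }
  gmm_params(prior$K, prior$d,
             log_weights = log(pmax(nk / nrow(MU), 1e-8)),
             means = means, log_vars = lv)
}

init_prior_kmeans <- function(MU, K, var_floor = 0.05) {
  K <- min(K, nrow(unique(MU)), nrow(MU))
  km <- if (K == nrow(MU)) {
    # every sample its own component; k-means is degenerate here
    list(cluster = seq_len(K), centers = MU)
  } else {
    stats::kmeans(MU, centers = K, nstart = 10, iter.max = 50)
  }
  lv <- matrix(0, K, ncol(MU))
  for (k in seq_len(K)) {
    idx <- which(km$cluster == k)
    v <- if (length(idx) > 1) apply(MU[idx, , drop = FALSE], 2L, stats::var)
    else rep(var_floor, ncol(MU))
    lv[k, ] <- log(pmax(v, var_floor))
  }
  gmm_params(K, ncol(MU),
             log_weights = log(pmax(tabulate(km$cluster, K) / nrow(MU),
                                    1e-6)),
             means = km$centers, log_vars = lv)
}

#' Train the variational co-clustering model
#'
#' @param fm a standardized `feature_matrix` or a plain numeric matrix;
#'   per-row/per-column normalization is applied internally before
#'   training (see [row_col_normalize()]).
#' @param kr,kc requested numbers of row (subject) and column (feature)
#'   clusters; capped at the available sample/feature counts with a
#'   warning.
#' @param control a [srvcc_control()].
#' @param cohort_labels optional factor of cohort labels; when supplied,
#'   mini-batches are sampled with inverse-frequency weights to mitigate
#'   cohort imbalance (labels never enter the loss).
#' @return list with `model` (both sides' networks and priors, the
#'   coupling weight and dimensions), `assignments` (soft `gamma_rows`,
#'   `gamma_cols` and hard labels), `log` (per-epoch losses) and
#'   `val_recon` (held-out per-entry reconstruction MSE).
#' @export
train_srvcc <- function(fm, kr, kc, control = srvcc_control(),
                        cohort_labels = NULL) {
  X <- if (inherits(fm, "feature_matrix")) {
    row_col_normalize(fm)$values
  } else {
    rcn <- row_col_normalize(new_feature_matrix(
      as.matrix(fm), rownames(fm) %||% as.character(seq_len(nrow(fm))),
      data.frame(name = colnames(fm) %||%
                   paste0("f", seq_len(ncol(fm))),
                 stringsAsFactors = FALSE)))
    rcn$values
  }
  N <- nrow(X); D <- ncol(X)
  if (kr > N) { warning("kr capped at N = ", N); kr <- N }
  if (kc > D) { warning("kc capped at D = ", D); kc <- D }
  set.seed(control$seed)

  val_n <- floor(control$val_frac * N)
  val_idx <- if (val_n > 0) sort(sample.int(N, val_n)) else integer(0)
  train_idx <- setdiff(seq_len(N), val_idx)
  Xtr <- X[train_idx, , drop = FALSE]
  Xc <- t(X)                       # column side trains on all subjects
  W <- abs(X)

  d <- control$latent_dim
  row <- list(net = net_init(D, control$hidden, d), prior = NULL)
  col <- list(net = net_init(N, control$hidden, d), prior = NULL)
  st_row <- adam_new(row$net); st_col <- adam_new(col$net)
  t_row <- 0L; t_col <- 0L

  batches <- function(n, bs) {
    ord <- sample.int(n)
    split(ord, ceiling(seq_along(ord) / bs))
  }
  batch_weights <- NULL
  if (!is.null(cohort_labels)) {
    tab <- table(cohort_labels[train_idx])
    batch_weights <- as.numeric(1 / tab[as.character(cohort_labels[train_idx])])
  }
  wbatches <- function(n, bs, w) {
    ord <- sample.int(n, n, replace = TRUE, prob = w)
    split(ord, ceiling(seq_along(ord) / bs))
  }

  run_epoch <- function(Xside, side, state, t0, beta, bs, w = NULL) {
    bl <- if (is.null(w)) batches(nrow(Xside), bs)
    else wbatches(nrow(Xside), bs, w)
    for (b in bl) {
      xb <- Xside[b, , drop = FALSE]
      E <- matrix(stats::rnorm(length(b) * d), length(b), d)
      gr <- elbo_grads(xb, side$net, side$prior, beta, E)
      t0 <- t0 + 1L
      up <- adam_step(side$net, gr$net, state, control$lr, t0)
      side$net <- up$params; state <- up$state
    }
    list(side = side, state = state, t = t0)
  }

  eval_side <- function(Xside, side, beta) {
    el <- elbo_loss(Xside, side, beta, sample = FALSE)
    el$total
  }

  # stage 1: reconstruction-only pretraining (beta = 0, z = mu)
  pre_log <- numeric(control$pretrain_epochs)
  for (ep in seq_len(control$pretrain_epochs)) {
    res <- run_epoch(Xtr, row, st_row, t_row, 0, control$batch_size,
                     batch_weights)
    row <- res$side; st_row <- res$state; t_row <- res$t
    res <- run_epoch(Xc, col, st_col, t_col, 0, control$batch_size)
    col <- res$side; st_col <- res$state; t_col <- res$t
    pre_log[ep] <- eval_side(Xtr, row, 0)
  }

  # stage 2: k-means initialization of the mixture priors
  row$prior <- init_prior_kmeans(encode(row$net, Xtr)$MU, kr)
  col$prior <- init_prior_kmeans(encode(col$net, Xc)$MU, kc)

  # stage 3: joint optimization with KL warm-up and MI coupling
  log <- data.frame(epoch = integer(), beta = numeric(), l_row = numeric(),
                    l_col = numeric(), l_mi = numeric(), total = numeric(),
                    val_recon = numeric())
  for (ep in seq_len(control$epochs)) {
    beta <- if (control$warmup > 0) min(1, ep / control$warmup) else 1
    res <- run_epoch(Xtr, row, st_row, t_row, beta, control$batch_size,
                     batch_weights)
    row <- res$side; st_row <- res$state; t_row <- res$t
    res <- run_epoch(Xc, col, st_col, t_col, beta, control$batch_size)
    col <- res$side; st_col <- res$state; t_col <- res$t
    row$prior <- em_update_prior(encode(row$net, Xtr)$MU, row$prior)
    col$prior <- em_update_prior(encode(col$net, Xc)$MU, col$prior)

    l_mi <- 0
    if (control$lambda_mi > 0) {
      mg <- mi_grads(X, Xc, W, row, col, control$lambda_mi)
      l_mi <- mg$loss
      if (!is.null(mg$grads)) {
        t_row <- t_row + 1L
        up <- adam_step(row$net, mg$grads$row$net, st_row, control$lr, t_row)
        row$net <- up$params; st_row <- up$state
        t_col <- t_col + 1L
        up <- adam_step(col$net, mg$grads$col$net, st_col, control$lr, t_col)
        col$net <- up$params; st_col <- up$state
      }
    }
    l_row <- eval_side(Xtr, row, beta)
    l_col <- eval_side(Xc, col, beta)
    if (!is.finite(l_row + l_col + l_mi))
      stop(sprintf("training diverged at epoch %d (l_row=%g l_col=%g l_mi=%g)",
                   ep, l_row, l_col, l_mi))
    # held-out reconstruction through the prior-quantized latent: encode,
    # soft-assign, decode from the responsibility-weighted component
    # means.  This measures how well the cluster-level representation
    # reconstructs unseen subjects (and, symmetrically, features), so it
    # degrades when the component count understates the block structure.
    quant_recon <- function(side, Xs) {
      gam <- responsibilities(encode(side$net, Xs)$MU, side$prior)
      if (is.null(dim(gam))) gam <- matrix(gam, nrow = nrow(Xs))
      mean((Xs - decode(side$net, gam %*% side$prior$means)$XH)^2)
    }
    val_recon <- if (length(val_idx) > 0) {
      (quant_recon(row, X[val_idx, , drop = FALSE]) +
         quant_recon(col, Xc)) / 2
    } else quant_recon(col, Xc)
    log <- rbind(log, data.frame(epoch = ep, beta = beta, l_row = l_row,
                                 l_col = l_col, l_mi = l_mi,
                                 total = l_row + l_col + l_mi,
                                 val_recon = val_recon))
    if (control$verbose)
      cat(sprintf("epoch %3d beta %.2f L %.4f (row %.4f col %.4f mi %.4f)\n",
                  ep, beta, l_row + l_col + l_mi, l_row, l_col, l_mi))
  }

  gamma_rows <- responsibilities(encode(row$net, X)$MU, row$prior)
  gamma_cols <- responsibilities(encode(col$net, Xc)$MU, col$prior)
  torg <- cross_tab(gamma_rows, gamma_cols, W, "soft")
  hr <- one_hot(hard_assign(gamma_rows), ncol(gamma_rows))
  hc <- one_hot(hard_assign(gamma_cols), ncol(gamma_cols))
  tred <- cross_tab(hr, hc, W, "reduced")

  # components that end up essentially empty are logged, not merged
  resp_mass <- colSums(gamma_rows)
  if (any(resp_mass < 1e-3 * N))
    message(sum(resp_mass < 1e-3 * N),
            " row mixture component(s) have near-zero responsibility mass")

  list(
    model = list(row = row, col = col, kr = ncol(gamma_rows),
                 kc = ncol(gamma_cols), lambda_mi = control$lambda_mi,
                 control = control),
    assignments = list(gamma_rows = gamma_rows, gamma_cols = gamma_cols,
                       row_labels = hard_assign(gamma_rows),
                       col_labels = hard_assign(gamma_cols)),
    log = log, pretrain_recon = pre_log,
    mi_org = mutual_information(torg), mi_red = mutual_information(tred),
    val_recon = if (nrow(log) > 0) log$val_recon[nrow(log)] else NA_real_,
    final_loss = if (nrow(log) > 0) log$total[nrow(log)] else NA_real_
  )
}
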