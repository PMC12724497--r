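test_that("mixture log density matches hand-computed values", {
  p1 <- gmm_params(1, 1)
  expect_equal(gmm_log_density(0, p1), -0.5 * log(2 * pi), tolerance = 1e-9)
  # two identical components collapse to one
  p2 <- gmm_params(2, 1)
  expect_equal(gmm_log_density(0.7, p2), gmm_log_density(0.7, p1),
               tolerance = 1e-12)
  # separated symmetric mixture at the midpoint
  p3 <- gmm_params(2, 1, means = matrix(c(-1, 1), 2, 1))
  expect_equal(gmm_log_density(0, p3), log(0.5 * dnorm(1) + 0.5 * dnorm(-1)),
               tolerance = 1e-9)
  expect_equal(gmm_log_density(0, p3), -1.418939, tolerance = 1e-6)
  expect_error(gmm_log_density(NaN, p1), "finite")
})

test_that("responsibilities are normalized posteriors, robust to underflow", {
  p1 <- gmm_params(1, 1)
  expect_equal(responsibilities(0.3, p1), 1)
  p3 <- gmm_params(2, 1, means = matrix(c(-1, 1), 2, 1))
  expect_equal(responsibilities(0, p3), c(0.5, 0.5))
  g <- responsibilities(1, p3)
  expect_equal(g[2], 1 / (1 + exp(-2)), tolerance = 1e-9)
  expect_equal(g[2], 0.880797, tolerance = 1e-6)
  # extreme z: log-space normalization never yields NaN
  far <- responsibilities(1e4, p3)
  expect_false(anyNA(far))
  expect_equal(sum(far), 1)
})

test_that("hard assignment takes the argmax with deterministic ties", {
  expect_equal(hard_assign(diag(3)), 1:3)
  expect_equal(hard_assign(matrix(c(0.5, 0.5), 1)), 1L)
  expect_equal(hard_assign(matrix(c(0.2, 0.5, 0.3), 1)), 2L)
})

test_that("cross-tabulation is a normalized joint distribution", {
  W <- diag(2)
  ct <- cross_tab(diag(2), diag(2), W)
  expect_equal(ct$table, matrix(c(0.5, 0, 0, 0.5), 2), ignore_attr = TRUE)
  # uniform assignments give the uniform table
  gr <- matrix(1 / 3, 9, 3); gc <- matrix(1 / 2, 6, 2)
  Wu <- matrix(1, 9, 6)
  expect_equal(cross_tab(gr, gc, Wu)$table, matrix(1 / 6, 3, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  # grand sum is always 1
  set.seed(1)
  grr <- matrix(runif(20), 5, 4); grr <- grr / rowSums(grr)
  gcc <- matrix(runif(9), 3, 3); gcc <- gcc / rowSums(gcc)
  expect_equal(sum(cross_tab(grr, gcc, matrix(runif(15), 5, 3))$table), 1)
  expect_error(cross_tab(diag(2), diag(2), matrix(0, 2, 2)), "zero")
})

test_that("mutual information matches hand computation and its bounds", {
  expect_equal(mutual_information(matrix(c(0.5, 0, 0, 0.5), 2)), log(2))
  marg <- outer(c(0.3, 0.7), c(0.4, 0.6))
  expect_equal(mutual_information(marg), 0, tolerance = 1e-12)
  expect_equal(mutual_information(matrix(c(0.4, 0.1, 0.1, 0.4), 2)),
               0.1927448, tolerance = 1e-6)
  set.seed(2)
  for (i in 1:20) {
    t <- matrix(rexp(12), 3, 4); t <- t / sum(t)
    mi <- mutual_information(t)
    expect_gte(mi, 0)
    expect_lte(mi, min(log(3), log(4)) + 1e-12)
  }
})

test_that("the coupling penalty vanishes under lossless hardening", {
  W <- matrix(runif(12) + 0.1, 4, 3)
  gr <- pathwaycc:::one_hot(c(1, 2, 1, 2), 2)
  gc <- pathwaycc:::one_hot(c(1, 2, 2), 2)
  expect_equal(mi_coupling_loss(gr, gc, W, lambda_mi = 1), 0)
  expect_equal(mi_coupling_loss(gr, gc, W, lambda_mi = 0), 0)
  # soft assignments: penalty equals the independently composed formula
  # (near-one-hot soft partitions with genuine block structure, so the
  # soft cross-tabulation carries nonzero mutual information)
  grs <- 0.96 * pathwaycc:::one_hot(c(1, 1, 2, 2), 2) + 0.02
  gcs <- 0.9 * pathwaycc:::one_hot(c(1, 2, 2), 2) + 0.05
  W <- matrix(1, 4, 3)
  W[1:2, 1] <- 5; W[3:4, 2:3] <- 5
  torg <- cross_tab(grs, gcs, W)
  tred <- cross_tab(pathwaycc:::one_hot(hard_assign(grs), 2),
                    pathwaycc:::one_hot(hard_assign(gcs), 2), W)
  ratio <- mutual_information(tred) / mutual_information(torg)
  expect_lt(ratio, 2)  # fixture stays inside the clamp range
  expected <- log(1 + (1 - ratio))
  expect_equal(mi_coupling_loss(grs, gcs, W, lambda_mi = 1), expected,
               tolerance = 1e-12)
  expect_error(mi_coupling_loss(grs, gcs, W, lambda_mi = -1), "lambda")
})

test_that("the ELBO reduces to reconstruction error at beta = 0", {
  set.seed(5)
  net <- pathwaycc:::net_init(6, c(5, 4), 3)
  side <- list(net = net, prior = gmm_params(1, 3))
  X <- matrix(rnorm(24), 4, 6)
  el <- elbo_loss(X, side, beta = 0, sample = FALSE)
  expect_identical(el$total, el$recon_mse)
  xh <- pathwaycc:::decode(net, pathwaycc:::encode(net, X)$MU)$XH
  expect_equal(el$recon_mse, mean(rowSums((X - xh)^2)), tolerance = 1e-12)
})

test_that("the single-sample KL estimate equals log q - log p at the fixed sample", {
  set.seed(6)
  net <- pathwaycc:::net_init(5, c(4, 3), 2)
  prior <- gmm_params(2, 2, log_weights = c(0.2, -0.1),
                      means = matrix(rnorm(4), 2, 2),
                      log_vars = matrix(rnorm(4, sd = 0.2), 2, 2))
  side <- list(net = net, prior = prior)
  X <- matrix(rnorm(15), 3, 5)
  E <- matrix(rnorm(6), 3, 2)
  el <- elbo_loss(X, side, beta = 1, eps = E)
  enc <- pathwaycc:::encode(net, X)
  Z <- enc$MU + exp(enc$LV / 2) * E
  log_q <- rowSums(dnorm(E, log = TRUE) - enc$LV / 2)
  log_p <- gmm_log_density(Z, prior)
  expect_equal(el$kl_estimate, mean(log_q - log_p), tolerance = 1e-9)
  expect_equal(el$total, el$recon_mse + el$kl_estimate, tolerance = 1e-12)
})

test_that("analytic ELBO gradients agree with finite differences", {
  set.seed(7)
  D <- 5; d <- 2
  net <- pathwaycc:::net_init(D, c(4, 3), d)
  prior <- gmm_params(2, d, log_weights = c(0.3, -0.2),
                      means = matrix(rnorm(4), 2, d),
                      log_vars = matrix(rnorm(4, sd = 0.3), 2, d))
  X <- matrix(rnorm(3 * D), 3, D)
  E <- matrix(rnorm(3 * d), 3, d)
  beta <- 0.6
  loss_fn <- function(net, prior)
    elbo_loss(X, list(net = net, prior = prior), beta, eps = E)$total
  g <- pathwaycc:::elbo_grads(X, net, prior, beta, E)
  h <- 1e-6
  for (nm in names(net)) {
    idx <- seq_len(min(4, length(net[[nm]])))
    for (i in idx) {
      n2 <- net; n2[[nm]][i] <- n2[[nm]][i] + h
      n3 <- net; n3[[nm]][i] <- n3[[nm]][i] - h
      expect_equal(g$net[[nm]][i],
                   (loss_fn(n2, prior) - loss_fn(n3, prior)) / (2 * h),
                   tolerance = 1e-4)
    }
  }
  for (nm in c("log_weights", "means", "log_vars")) {
    for (i in seq_along(prior[[nm]])) {
      p2 <- prior; p2[[nm]][i] <- p2[[nm]][i] + h
      p3 <- prior; p3[[nm]][i] <- p3[[nm]][i] - h
      expect_equal(g$prior[[nm]][i],
                   (loss_fn(net, p2) - loss_fn(net, p3)) / (2 * h),
                   tolerance = 1e-4)
    }
  }
})

test_that("training recovers a planted checkerboard and is seed-deterministic", {
  cb <- make_checkerboard(N = 120, D = 60, shift = 5, noise = 1, seed = 11)
  for (s in 1:3) {
    fit <- suppressMessages(train_srvcc(cb$X, 4, 3, fast_ctl(seed = s)))
    expect_equal(ari(fit$assignments$row_labels, cb$rb), 1)
    expect_equal(ari(fit$assignments$col_labels, cb$cb), 1)
  }
  fit1 <- suppressMessages(train_srvcc(cb$X, 4, 3, fast_ctl(seed = 1)))
  fit2 <- suppressMessages(train_srvcc(cb$X, 4, 3, fast_ctl(seed = 1)))
  expect_identical(fit1$assignments$row_labels, fit2$assignments$row_labels)
  expect_identical(fit1$log, fit2$log)
})

test_that("training invariants hold: stochastic gammas, loss decomposition, descent", {
  cb <- make_checkerboard(N = 80, D = 40, seed = 12)
  fit <- suppressMessages(train_srvcc(cb$X, 3, 2, fast_ctl(seed = 2)))
  expect_true(all(abs(rowSums(fit$assignments$gamma_rows) - 1) < 1e-6))
  expect_true(all(abs(rowSums(fit$assignments$gamma_cols) - 1) < 1e-6))
  expect_true(all(fit$assignments$gamma_rows >= 0 &
                    fit$assignments$gamma_rows <= 1))
  # reported total equals the sum of its parts at every epoch
  expect_true(all(abs(fit$log$total -
                        (fit$log$l_row + fit$log$l_col + fit$log$l_mi))
                  < 1e-6))
  # beta warms up to 1
  expect_equal(max(fit$log$beta), 1)
  # pretraining reduces reconstruction error
  expect_lte(tail(fit$pretrain_recon, 1), fit$pretrain_recon[1] + 1e-8)
})

test_that("degenerate cluster counts are handled", {
  cb <- make_checkerboard(N = 40, D = 20, seed = 13)
  ctl <- srvcc_control(pretrain_epochs = 3, epochs = 5, seed = 1)
  fit1 <- suppressMessages(train_srvcc(cb$X, 1, 2, ctl))
  expect_true(all(fit1$assignments$gamma_rows == 1))
  expect_warning(fit2 <- suppressMessages(train_srvcc(cb$X, 50, 2, ctl)),
                 "capped")
  expect_lte(max(fit2$assignments$row_labels), 40)
})
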