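test_that("zero-contrast stimuli are pure observation noise", {
  gsm <- small_net()$gsm
  set.seed(1)
  xs <- replicate(300, sample_stimulus(gsm, 0)$x)
  expect_equal(mean(xs), 0, tolerance = 0.01)
  expect_equal(mean(xs^2), gsm$sigma_x_sq, tolerance = 0.01)
})

test_that("filter projections of unit-contrast stimuli are white at scale A'A", {
  # Cov(A'x) = A'(ACA' + sigma_x^2 I)A = A'A when C = (1-sigma_x^2)(A'A)^-1
  gsm <- small_net()$gsm
  set.seed(2)
  proj <- t(replicate(4000, crossprod(gsm$A, sample_stimulus(gsm, 1)$x)[, 1]))
  emp <- cov(proj)
  expect_equal(emp, gsm$gram, tolerance = 0.12)
})

test_that("stimulus draws are reproducible under a seed", {
  gsm <- small_net()$gsm
  s1 <- sample_stimulus(gsm, 1, seed = 11)
  s2 <- sample_stimulus(gsm, 1, seed = 11)
  expect_identical(s1$x, s2$x)
  expect_identical(s1$u_gen, s2$u_gen)
})

test_that("the conditional posterior matches hand-computed values", {
  gsm1 <- gsm_model(matrix(1), sigma_x_sq = 0.1)
  post <- posterior_u(gsm1, x = 1, z = 1)
  expect_equal(post$cov[1, 1], 0.09, tolerance = 1e-12)
  expect_equal(post$mean, 0.9, tolerance = 1e-12)
  # zero evidence: posterior = prior
  p0 <- posterior_u(gsm1, x = 1, z = 0)
  expect_equal(p0$cov[1, 1], 0.9)
  expect_equal(p0$mean, 0)
})

test_that("posterior covariance shrinks with contrast (Loewner order)", {
  gsm <- default_net()$gsm
  x <- sample_stimulus(gsm, 1, seed = 3)$x
  S1 <- posterior_u(gsm, x, 1)$cov
  S2 <- posterior_u(gsm, x, 2)$cov
  ev <- eigen(S1 - S2, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
})

test_that("the general posterior agrees with its collapsed whitened form", {
  gsm <- default_net()$gsm
  x <- sample_stimulus(gsm, 1, seed = 4)$x
  z <- 1.3
  post <- posterior_u(gsm, x, z)
  scale <- z^2 / gsm$sigma_x_sq + 1 / gsm$K
  u_bar_collapsed <- (z / gsm$sigma_x_sq) / scale *
    solve(gsm$gram, crossprod(gsm$A, x))[, 1]
  expect_equal(post$mean, u_bar_collapsed, tolerance = 1e-9)
  expect_equal(post$cov, solve(gsm$gram) / scale, tolerance = 1e-9)
})

test_that("input current is the posterior-precision-weighted pull to the mean", {
  gsm <- small_net()$gsm
  x <- sample_stimulus(gsm, 1, seed = 5)$x
  post <- posterior_u(gsm, x, 1)
  expect_equal(input_current(gsm, post$mean, 1, x), rep(0, gsm$n_features),
               tolerance = 1e-9)
  set.seed(6)
  for (k in 1:5) {
    u <- rnorm(gsm$n_features)
    expect_equal(input_current(gsm, u, 1, x),
                 drop(post$precision %*% (post$mean - u)), tolerance = 1e-9)
  }
  # zero contrast: pure prior pull
  u <- rnorm(gsm$n_features)
  expect_equal(input_current(gsm, u, 0, x), -drop(gsm$C_inv %*% u),
               tolerance = 1e-12)
  # 1-D worked value: A = 1, sigma_x^2 = 0.1, z = 1, x = 1, u = 0 -> 10
  gsm1 <- gsm_model(matrix(1), 0.1)
  expect_equal(input_current(gsm1, 0, 1, 1), 10)
})

test_that("contrast input current matches its closed form and a finite difference", {
  gsm1 <- gsm_model(matrix(1), 0.1)
  expect_equal(z_input_current(gsm1, u = 1, z = 1, x = 1), -1)
  expect_equal(z_input_current(gsm1, u = 1, z = 0, x = 0), 0)
  gsm <- small_net()$gsm
  x <- sample_stimulus(gsm, 1, seed = 7)$x
  set.seed(8)
  for (k in 1:5) {
    u <- rnorm(gsm$n_features)
    z <- runif(1, 0.2, 2)
    logp <- function(zz) {
      -sum((x - zz * gsm$A %*% u)^2) / (2 * gsm$sigma_x_sq) - zz^2 / 2
    }
    h <- 1e-6
    expect_equal(z_input_current(gsm, u, z, x),
                 (logp(z + h) - logp(z - h)) / (2 * h), tolerance = 1e-4)
  }
})

test_that("the joint log-density has the gradients the network implements", {
  net <- small_net()
  gsm <- net$gsm
  x <- sample_stimulus(gsm, 1, seed = 9)$x
  post <- posterior_u(gsm, x, 1)
  n <- gsm$n_features
  # stationary point at (u_bar, B u_bar)
  e0 <- log_joint(net, post$mean, post$mean, 1, x)
  set.seed(10)
  for (k in 1:5) {
    d <- rnorm(2 * n, sd = 1e-4)
    e <- log_joint(net, post$mean + d[1:n], post$mean + d[(n + 1):(2 * n)],
                   1, x)
    expect_lt(e, e0 + 1e-10)
  }
  # finite-difference gradients match input_current and the v-coupling
  u <- rnorm(n)
  v <- rnorm(n)
  h <- 1e-6
  num_grad <- function(f, w) {
    vapply(seq_along(w), function(i) {
      wp <- w; wm <- w
      wp[i] <- wp[i] + h
      wm[i] <- wm[i] - h
      (f(wp) - f(wm)) / (2 * h)
    }, numeric(1))
  }
  gu <- num_grad(function(w) log_joint(net, w, v, 1, x), u)
  gv <- num_grad(function(w) log_joint(net, u, w, 1, x), v)
  expect_equal(gu,
               input_current(gsm, u, 1, x) +
                 drop(crossprod(net$B, net$M %*% (v - net$B %*% u))),
               tolerance = 1e-5)
  expect_equal(gv, -drop(net$M %*% (v - net$B %*% u)), tolerance = 1e-5)
  # shifting the image leaves the v-gradient untouched
  gv2 <- num_grad(function(w) log_joint(net, u, w, 1, x + 0.5), v)
  expect_equal(gv, gv2, tolerance = 1e-5)
})

test_that("the average posterior approaches the prior over generative draws", {
  gsm <- small_net()$gsm
  set.seed(11)
  n <- gsm$n_features
  acc <- matrix(0, n, n)
  n_draws <- 400
  for (k in seq_len(n_draws)) {
    z <- abs(rnorm(1))
    st <- sample_stimulus(gsm, z)
    post <- posterior_u(gsm, st$x, z)
    acc <- acc + post$cov + tcrossprod(post$mean)
  }
  avg <- acc / n_draws
  expect_equal(avg, gsm$C, tolerance = 0.2)
})

test_that("offsetting the prior mean shifts inference but not the image law", {
  gsm <- small_net()$gsm
  b <- c(1, 2, -0.5)
  gsm_b <- apply_offset(gsm, b)
  expect_identical(apply_offset(gsm, rep(0, 3))$b, gsm$b)
  # same seed: identical images with and without the offset
  s0 <- sample_stimulus(gsm, 1, seed = 12)
  sb <- sample_stimulus(gsm_b, 1, seed = 12)
  expect_identical(s0$x, sb$x)
  expect_equal(sb$u_gen, s0$u_gen + b)
  # posterior mean translates by exactly b
  p0 <- posterior_u(gsm, s0$x, 1)
  pb <- posterior_u(gsm_b, sb$x, 1)
  expect_equal(pb$mean, p0$mean + b, tolerance = 1e-12)
  expect_equal(pb$cov, p0$cov, tolerance = 1e-12)
})
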