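test_that("the noise-free drifts vanish at their fixed points", {
  net <- small_net()
  gsm <- net$gsm
  x <- sample_stimulus(gsm, 1, seed = 20)$x
  u_bar <- posterior_u(gsm, x, 1)$mean
  st <- list(u = u_bar, v = drop(net$B %*% u_bar), z = 1, v_z = 1)
  d <- drift_hamiltonian(st, net, x)
  expect_equal(d$du, rep(0, net$n), tolerance = 1e-9)
  expect_equal(d$dv, rep(0, net$n), tolerance = 1e-9)
  expect_equal(drift_langevin(st, net, x), rep(0, net$n), tolerance = 1e-9)
  # contrast subsystem: balance point of the z input current
  u <- c(0.5, -0.2, 1)
  Au <- drop(gsm$A %*% u)
  z_star <- sum(Au * x) / (sum(Au^2) + gsm$sigma_x_sq)
  st_z <- list(u = u, v = u, z = z_star, v_z = z_star)
  expect_equal(z_input_current(gsm, u, z_star, x), 0, tolerance = 1e-9)
  dz <- drift_z(st_z, net, x)
  expect_equal(unname(dz$dz), 0, tolerance = 1e-9)
  expect_equal(unname(dz$dv_z), 0, tolerance = 1e-9)
})

test_that("the conservative Hamiltonian component conserves the joint log-density", {
  net <- small_net()
  gsm <- net$gsm
  x <- sample_stimulus(gsm, 1, seed = 21)$x
  u_bar <- posterior_u(gsm, x, 1)$mean
  drift_of_energy <- function(dt) {
    st <- list(u = u_bar + c(1, -0.5, 0.3), v = u_bar, z = 1)
    e0 <- log_joint(net, st$u, st$v, st$z, x)
    for (i in seq_len(round(0.05 / dt))) {
      d <- drift_hamiltonian(st, net, x, conservative = TRUE)
      st$u <- st$u + d$du * dt
      st$v <- st$v + d$dv * dt
    }
    abs(log_joint(net, st$u, st$v, st$z, x) - e0)
  }
  drifts <- vapply(c(4e-5, 1e-5, 2.5e-6), drift_of_energy, numeric(1))
  # first-order integrator: energy error shrinks linearly with the step
  expect_lt(drifts[2], drifts[1] / 2)
  expect_lt(drifts[3], drifts[2] / 2)
  expect_lt(drifts[3], 0.05 * abs(log_joint(net, u_bar + 1, u_bar, 1, x)))
})

test_that("simulation is bit-reproducible under the protocol seed", {
  net <- small_net()
  pr <- simulation_protocol(t_pre = 0.05, t_post = 0.05, z_gen = 1, seed = 5)
  t1 <- simulate(net, protocol = pr)
  t2 <- simulate(net, protocol = pr)
  expect_identical(t1$u, t2$u)
  expect_identical(t1$z, t2$z)
  t3 <- simulate(net, protocol = pr, seed = 6)
  expect_false(identical(t1$u, t3$u))
})

test_that("the contrast variable stays nonnegative under reflection", {
  net <- small_net()
  traj <- simulate(net, protocol = simulation_protocol(
    t_pre = 0.5, t_post = 0.5, z_gen = 0.2, seed = 7))
  expect_true(all(traj$z >= 0))
  expect_true(all(is.finite(traj$u)))
})

test_that("too coarse a step is reported as an integration blow-up", {
  net <- small_net()
  expect_error(
    simulate(net, protocol = simulation_protocol(
      t_pre = 0.5, t_post = 0.5, z_gen = 1, dt = 0.02, seed = 1)),
    "blew up"
  )
})

test_that("a prior-mean offset translates trajectories without changing dynamics", {
  net <- small_net()
  b <- c(2, 1, 3)
  net_b <- ei_network(apply_offset(net$gsm, b), tau = net$tau,
                      tau_L = net$tau_L)
  pr <- simulation_protocol(t_pre = 0.05, t_post = 0.1, z_gen = 1, seed = 9)
  t0 <- simulate(net, protocol = pr)
  tb <- simulate(net_b, protocol = pr)
  expect_identical(t0$stimulus$x, tb$stimulus$x) # image law unchanged
  expect_equal(tb$u, t0$u + rep(b, each = nrow(t0$u)))
  expect_identical(tb$z, t0$z)
})

test_that("fixed-contrast stationary covariance solves the Lyapunov equation", {
  # Both the analytic block target [[S, S], [S, M^-1 + S]] and the empirical
  # covariance of the (u, v) process must agree with a brute-force solve of
  # J P + P J' + Q = 0 for the linearised SDE.
  net <- small_net()
  gsm <- net$gsm
  n <- net$n
  z <- 1
  stim <- sample_stimulus(gsm, z, seed = 30)
  post <- posterior_u(gsm, stim$x, z)
  S_inv <- post$precision
  J <- rbind(
    cbind(net$W_uu / net$tau - S_inv / net$tau_L, -net$W_uv / net$tau),
    cbind(net$W_vu / net$tau + S_inv / net$tau, -net$W_vv / net$tau)
  )
  Q <- diag(2 * n) * (2 / net$tau_L)
  P <- matrix(solve(diag(2 * n) %x% J + J %x% diag(2 * n), -as.vector(Q)),
              2 * n, 2 * n)
  target <- rbind(
    cbind(post$cov, post$cov),
    cbind(post$cov, net$M_inv + post$cov)
  )
  expect_equal(P, target, tolerance = 1e-8)

  # dt below the default: the Euler-Maruyama second-moment bias is O(dt) and
  # must sit well inside the Monte-Carlo error for a 3-standard-error check
  reps <- lapply(1:4, function(k) {
    traj <- simulate(net, protocol = simulation_protocol(
      t_pre = 0.5, t_post = 5, z_gen = z, mode = "hamiltonian_fixed_z",
      seed = 100 + k, dt = 2e-5, thin = 10L), stimulus = stim)
    keep <- traj$times > 0
    cov(cbind(traj$u[keep, ], traj$v[keep, ]))
  })
  emp <- Reduce(`+`, reps) / length(reps)
  se <- apply(simplify2array(reps), c(1, 2), sd) / sqrt(length(reps))
  tol <- pmax(3 * se, 0.02 * max(abs(target)))
  expect_true(all(abs(emp - target) <= tol))
})

test_that("the Langevin sampler has the exact conditional posterior as stationary law", {
  net <- small_net()
  gsm <- net$gsm
  stim <- sample_stimulus(gsm, 1, seed = 31)
  post <- posterior_u(gsm, stim$x, 1)
  reps <- lapply(1:2, function(k) {
    traj <- simulate(net, protocol = simulation_protocol(
      t_pre = 0.5, t_post = 6, z_gen = 1, mode = "langevin", z_fixed = 1,
      seed = 200 + k, thin = 4L), stimulus = stim)
    traj$u[traj$times > 0, ]
  })
  u <- do.call(rbind, reps)
  expect_equal(colMeans(u), post$mean, tolerance = 0.12)
  expect_equal(apply(u, 2, var), diag(post$cov), tolerance = 0.2)
})

test_that("the inferred contrast concentrates on the grid-integrated posterior mean", {
  net <- small_net()
  gsm <- net$gsm
  stim <- sample_stimulus(gsm, 1, seed = 32)
  # brute-force oracle: P(z | x) on a dense grid, u marginalised analytically
  z_grid <- seq(1e-4, 4, length.out = 80)
  log_post <- vapply(z_grid, function(z) {
    S_x <- z^2 * gsm$A %*% gsm$C %*% t(gsm$A) + gsm$sigma_x_sq * diag(gsm$n_pixels)
    ch <- chol(S_x)
    -sum(log(diag(ch))) -
      0.5 * sum(backsolve(ch, stim$x, transpose = TRUE)^2) - z^2 / 2
  }, numeric(1))
  w <- exp(log_post - max(log_post))
  z_mean_oracle <- sum(z_grid * w) / sum(w)
  z_samples <- unlist(lapply(1:2, function(k) {
    traj <- simulate(net, protocol = simulation_protocol(
      t_pre = 1, t_post = 6, z_gen = 1, seed = 300 + k, thin = 4L),
      stimulus = stim)
    traj$z[traj$times > 0]
  }))
  expect_equal(mean(z_samples), z_mean_oracle, tolerance = 0.1)
})
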