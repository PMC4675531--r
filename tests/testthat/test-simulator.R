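test_that("local_dynamics matches the normal form", {
  expect_equal(local_dynamics(0, 0.5), 0 + 0i)
  expect_equal(local_dynamics(1, 0.5, 15), 0.5 + 15i)
  # the stable-cycle radius is a root of the radial part
  for (lam in c(0.2, 0.5, 0.8)) {
    r <- sqrt(1 + sqrt(lam))
    expect_equal(Re(local_dynamics(r, lam, 15)), 0, tolerance = 1e-12)
    # the unstable cycle too
    ru <- sqrt(1 - sqrt(lam))
    expect_equal(Re(local_dynamics(ru, lam, 15)), 0, tolerance = 1e-12)
  }
})

test_that("noiseless subthreshold systems never escape", {
  p <- model_parameters(alpha = 0, max_time = 5)
  m <- make_model(c(0.5, 0.8, 0.3), params = p)
  r <- simulate_subject(m, seed = 1)
  expect_true(all(r$censored))
  expect_true(all(r$kth_censored))
  expect_equal(r$kth_escape_times, rep(5, 3))
})

test_that("a node initialized on the seizure attractor escapes at time 0", {
  p <- model_parameters(alpha = 0, max_time = 2)
  lam <- c(0.5, 0.5, 0.5)
  m <- make_model(lam, params = p)
  z0 <- c(sqrt(1 + sqrt(0.5)) + 0i, 0, 0)
  r <- simulate_subject(m, seed = 1, z0 = z0)
  expect_equal(r$escape_time[1], 0)
  expect_false(r$censored[1])
  expect_true(all(r$censored[2:3]))
  expect_equal(r$escape_order, 1L)
  # and it stays on the attractor (Euler fixed radius at omega = 0)
  p0 <- model_parameters(alpha = 0, omega = 0, max_time = 2)
  m0 <- make_model(lam, params = p0)
  r0 <- simulate_subject(m0, seed = 1, z0 = z0)
  expect_equal(abs(r0$z_final[1]), sqrt(1 + sqrt(0.5)), tolerance = 1e-9)
})

test_that("bistable basins behave as the radial analysis predicts (omega 0)", {
  # with the rotation switched off, the explicit-Euler fixed radius solves
  # the radial equation exactly, so the analytic basins are recovered
  p <- model_parameters(alpha = 0, omega = 0, dt = 1e-3, max_time = 50)
  for (lam in c(0.2, 0.5, 0.8)) {
    m <- make_model(lam, params = p)
    r_u <- sqrt(1 - sqrt(lam))
    r_s <- sqrt(1 + sqrt(lam))
    inside <- simulate_subject(m, 1, z0 = 0.5 * r_u + 0i)
    expect_lt(abs(inside$z_final), 1e-3)
    outside <- simulate_subject(m, 1, z0 = 1.05 * r_u + 0i)
    expect_equal(abs(outside$z_final), r_s, tolerance = 1e-3)
  }
})

test_that("single-node high-excitability runs always escape", {
  # lambda = 0.9, alpha = 0.05: near-monostable regime
  p <- model_parameters(max_time = 200)
  m <- make_model(0.9, params = p)
  times <- vapply(1:50, function(s) {
    r <- simulate_subject(m, s)
    expect_false(r$censored[1])
    r$escape_time[1]
  }, numeric(1))
  expect_true(all(times < 200))
})

test_that("simulations are seed-deterministic", {
  coh <- tiny_cohort()
  ctl <- coh$connectomes[coh$manifest$group == "control"]
  m <- build_subject_model(coh$connectomes$patient01, ctl,
                           model_parameters(max_time = 20))
  a <- simulate_subject(m, 123)
  b <- simulate_subject(m, 123)
  expect_identical(a$escape_time, b$escape_time)
  expect_identical(a$z_final, b$z_final)
  c2 <- simulate_subject(m, 124)
  expect_false(identical(a$z_final, c2$z_final))
})

test_that("run_iterations reproduces ordered seed blocks", {
  m <- make_model(0.9, params = model_parameters(max_time = 50))
  res <- run_iterations(m, 5, base_seed = 10)
  expect_equal(vapply(res, `[[`, 0, "seed"), 10:14)
  res2 <- run_iterations(m, 5, base_seed = 10)
  expect_identical(lapply(res, `[[`, "escape_time"),
                   lapply(res2, `[[`, "escape_time"))
  expect_error(run_iterations(m, 0), "n_iter")
})

test_that("kth escape accessors follow the censoring policy", {
  r <- fake_result(order = c(5L, 9L, 2L), times = c(3.1, 4.0, 4.2))
  expect_equal(third_escape_time(r), 4.2)
  expect_equal(kth_escape_time(r, 1), 3.1)
  r2 <- fake_result(order = c(5L, 9L), times = c(3.1, 4.0))
  expect_equal(third_escape_time(r2), 200)
  expect_true(r2$kth_censored[3])
  r3 <- fake_result(order = 7L, times = 1.5, k = 1L)
  expect_equal(kth_escape_time(r3), 1.5)   # criterion k = 1: first escape
})

test_that("compiled integrator matches the naive oracle exactly", {
  set.seed(99)
  n <- 3L
  M <- matrix(0, n, n)
  M[1, 2] <- M[2, 1] <- 0.8
  M[2, 3] <- M[3, 2] <- 0.5
  M[1, 3] <- M[3, 1] <- 0.3
  delays <- matrix(0L, n, n)
  delays[1, 2] <- delays[2, 1] <- 3L
  delays[2, 3] <- delays[3, 2] <- 7L
  delays[1, 3] <- delays[3, 1] <- 1L
  lam <- c(0.4, 0.55, 0.3)
  n_steps <- 2000L
  p <- model_parameters(dt = 0.0025, max_time = n_steps * 0.0025,
                        n_escapes_for_seizure = 82L)
  noise <- matrix(rnorm(n_steps * 2 * n), n_steps, 2 * n)
  m <- make_model(lam, M = M, delay_steps = delays, params = p)
  got <- simulate_subject(m, seed = 0, noise = noise)
  Z <- naive_integrate(M, lam, delays, p$beta, p$alpha, p$omega, p$dt,
                       n_steps, noise)
  expect_lt(max(abs(got$z_final - Z[n_steps + 1L, ])), 1e-10)
})

test_that("masked nodes are equivalent to physically deleted nodes", {
  set.seed(5)
  n <- 4L
  M <- matrix(runif(n * n, 0.2, 1), n, n)
  M <- (M + t(M)) / 2; diag(M) <- 0
  lam <- c(0.5, 0.6, 0.55, 0.45)
  n_steps <- 1500L
  p <- model_parameters(max_time = n_steps * 0.0025)
  noise <- matrix(rnorm(n_steps * 2 * n), n_steps, 2 * n)

  # mask node 3
  masked <- make_model(lam, M = M, params = p,
                       active = c(TRUE, TRUE, FALSE, TRUE))
  rm3 <- simulate_subject(masked, 0, noise = noise)

  keep <- c(1L, 2L, 4L)
  deleted <- make_model(lam[keep], M = M[keep, keep], params = p)
  cols <- as.vector(rbind(2 * keep - 1L, 2 * keep))
  rd <- simulate_subject(deleted, 0, noise = noise[, cols])

  expect_equal(rm3$z_final[keep], rd$z_final, tolerance = 1e-12)
  expect_equal(rm3$escape_time[keep], rd$escape_time)
  expect_true(is.na(rm3$censored[3]))
  expect_false(3L %in% rm3$escape_order)
})

test_that("escape slows down when dt shrinks (documented solver property)", {
  # explicit Euler dilates radial amplitude at rate omega^2 dt / 2; halving
  # dt raises the effective threshold, so escapes get slower, not equal
  mean_escape <- function(dt) {
    m <- make_model(0.7, params = model_parameters(dt = dt, max_time = 150))
    mean(vapply(1:25, function(s) simulate_subject(m, s)$escape_time[1],
                numeric(1)))
  }
  expect_gt(mean_escape(0.00125), mean_escape(0.0025))
})

test_that("state blow-up is reported with step and node", {
  p <- model_parameters(alpha = 0, max_time = 1)
  m <- make_model(0.5, params = p)
  expect_error(simulate_subject(m, 1, z0 = 1e7 + 0i), "blow-up.*node 1")
})

test_that("escape tables are tidy and omit resected nodes", {
  p <- model_parameters(max_time = 5)
  m <- make_model(c(0.9, 0.5, 0.9), params = p,
                  active = c(TRUE, FALSE, TRUE))
  tab <- escape_table(run_iterations(m, 2, 1), "subj")
  expect_equal(sort(unique(tab$node)), c(1L, 3L))
  expect_equal(nrow(tab), 4L)
  expect_true(all(c("subject_id", "seed", "node", "escape_time",
                    "censored") %in% names(tab)))
})
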