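# Shared test fixtures and independent oracles.

# Construct a subject_model directly (bypasses connectome plumbing) for
# small dynamical test systems. n is taken from length(lambda).
make_model <- function(lambda, M = NULL, delay_steps = NULL,
                       params = model_parameters(), active = NULL,
                       subject_id = "test", group = "control") {
  n <- length(lambda)
  if (is.null(M)) M <- matrix(0, n, n)
  if (is.null(delay_steps)) delay_steps <- matrix(0L, n, n)
  if (is.null(active)) active <- rep(TRUE, n)
  structure(
    list(M = M, lambda = lambda, delay_steps = delay_steps,
         D = rep(0, n), active_mask = active, params = params,
         subject_id = subject_id, group = group),
    class = "subject_model"
  )
}

# Straight-line re-implementation of the Euler-Maruyama update, kept
# deliberately naive (full trajectory, nested loops) as an independent
# oracle for the compiled integrator. Returns the state after each step;
# row k+1 is the state after k steps.
naive_integrate <- function(M, lambda, delay_steps, beta, alpha, omega,
                            dt, n_steps, noise, z0 = NULL) {
  n <- length(lambda)
  Z <- matrix(0 + 0i, n_steps + 1L, n)
  if (!is.null(z0)) Z[1L, ] <- z0
  init <- Z[1L, ]
  for (step in seq_len(n_steps)) {
    for (i in seq_len(n)) {
      zi <- Z[step, i]
      f <- (lambda[i] - 1 + 1i * omega) * zi +
        2 * zi * abs(zi)^2 - zi * abs(zi)^4
      coup <- 0 + 0i
      for (j in seq_len(n)) {
        if (j == i || M[j, i] == 0) next
        d <- delay_steps[j, i]
        zj <- if (step - d >= 1L) Z[step - d, j] else init[j]
        coup <- coup + M[j, i] * (zj - zi)
      }
      Z[step + 1L, i] <- zi + (f + beta * coup) * dt +
        alpha * sqrt(dt) * (noise[step, 2 * i - 1L] + 1i * noise[step, 2 * i])
    }
  }
  Z
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments
# (valid for tie-free samples; mirrors the 2 * min-tail convention).
enumerate_mw_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  N <- length(pooled)
  idx <- utils::combn(N, n1)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_all <- apply(idx, 2L, function(sel) {
    xs <- pooled[sel]; ys <- pooled[-sel]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  })
  mu <- n1 * (N - n1) / 2
  if (u_obs > mu) {
    min(1, 2 * mean(u_all >= u_obs))
  } else {
    min(1, 2 * mean(u_all <= u_obs))
  }
}

# Fake sim_result with a prescribed escape order/times (for ranking and
# summary tests that do not need real dynamics).
fake_result <- function(order, times, n = 82L, max_time = 200,
                        seed = 0L, k = 3L) {
  escape_time <- rep(max_time, n)
  escape_time[order] <- times
  censored <- rep(TRUE, n)
  censored[order] <- FALSE
  kth <- rep(max_time, k)
  kth_cens <- rep(TRUE, k)
  kk <- seq_len(min(k, length(order)))
  kth[kk] <- sort(times)[kk]
  kth_cens[kk] <- FALSE
  structure(
    list(seed = seed, escape_time = escape_time, censored = censored,
         escape_order = order, kth_escape_times = kth,
         kth_censored = kth_cens, n_steps = 0L),
    class = "sim_result"
  )
}

# Small reusable cohort (generated once per test run).
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(
        cohort_spec(n_patients = 2L, n_controls = 4L, seed = 42L))
    }
    cache
  }
})
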