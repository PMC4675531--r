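#' Local node dynamics of the bistable normal form
#'
#' The deterministic per-node vector field
#' `f(z) = (lambda - 1 + i*omega) z + 2 z |z|^2 - z |z|^4` (z complex).
#' For `0 < lambda < 1` the radial part has a stable fixed point at 0 (the
#' background state), an unstable limit cycle at radius `sqrt(1 - sqrt(lambda))`
#' and a stable limit cycle at radius `sqrt(1 + sqrt(lambda))` (the
#' seizure-like state).
#'
#' @param z complex state (vectorized).
#' @param lambda excitability in (0, 1).
#' @param omega angular frequency.
#' @return Complex rate of change.
#' @examples
#' local_dynamics(0, 0.5)          # 0: the background state is a fixed point
#' local_dynamics(1, 0.5)          # 0.5 + 15i
#' @export
local_dynamics <- function(z, lambda, omega = 15) {
  (lambda - 1 + 1i * omega) * z + 2 * z * abs(z)^2 - z * abs(z)^4
}

#' Simulate one noise realization of a subject model
#'
#' Integrates the coupled stochastic delay system with a fixed-step
#' Euler-Maruyama scheme from the all-background initial condition
#' (`z = 0`, zero-valued delay history) and records, for every active node,
#' the first time its modulus exceeds the escape threshold. Escaped nodes
#' keep evolving (on the seizure attractor) and continue to drive their
#' neighbours. Integration stops once `n_escapes_for_seizure` distinct
#' active nodes have escaped, or at `max_time`; nodes that have not escaped
#' by then are censored at `max_time`.
#'
#' A given `seed` always yields the same realization. Noise is drawn per
#' node per step in fixed node order (inactive nodes consume their draws),
#' so the same seed exposes active nodes to the same streams under any
#' resection mask.
#'
#' @param model a `subject_model`.
#' @param seed non-negative integer noise seed.
#' @param noise optional pre-drawn noise matrix (`n_steps` x `2n`, columns
#'   alternating real/imaginary standard normals per node); overrides
#'   `seed`-driven generation. Intended for integrator cross-checks.
#' @param z0 optional complex initial state (length 82); intended for
#'   deterministic trajectory tests.
#' @return An object of class `sim_result`: `seed`, `escape_time` (82,
#'   `max_time` where censored), `censored` (logical 82), `escape_order`
#'   (indices of escaped active nodes, in escape order),
#'   `kth_escape_times` / `kth_censored` (length `n_escapes_for_seizure`),
#'   `n_steps`.
#' @export
simulate_subject <- function(model, seed, noise = NULL, z0 = NULL) {
  stopifnot(inherits(model, "subject_model"))
  p <- model$params
  if (is.null(noise) && (length(seed) != 1L || seed < 0)) {
    stop("seed must be a single non-negative integer")
  }
  n_steps <- as.integer(round(p$max_time / p$dt))
  res <- .sim_core(model$M, model$lambda, model$delay_steps,
                   model$active_mask, p$beta, p$alpha, p$omega, p$dt,
                   n_steps, p$n_escapes_for_seizure, p$escape_threshold,
                   as.double(seed), noise, z0)
  esc_step <- res$escape_step
  escaped <- which(!is.na(esc_step))
  escape_time <- rep(p$max_time, length(model$lambda))
  escape_time[escaped] <- esc_step[escaped] * p$dt
  censored <- is.na(esc_step)
  censored[!model$active_mask] <- NA    # resected: no escape is defined
  ord <- escaped[order(esc_step[escaped], escaped)]
  k <- p$n_escapes_for_seizure
  kth <- rep(p$max_time, k)
  kth_cens <- rep(TRUE, k)
  if (length(ord) > 0L) {
    kk <- seq_len(min(k, length(ord)))
    kth[kk] <- esc_step[ord][kk] * p$dt
    kth_cens[kk] <- FALSE
  }
  structure(
    list(seed = seed, escape_time = escape_time, censored = censored,
         escape_order = ord, kth_escape_times = kth, kth_censored = kth_cens,
         n_steps = res$n_steps_done, z_final = res$z_final),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  k <- length(x$kth_escape_times)
  cat("<sim_result> seed", x$seed, "-", sum(!is.na(x$censored) & !x$censored),
      "node(s) escaped in", x$n_steps, "steps\n")
  cat("  kth escape times:",
      paste(signif(x$kth_escape_times, 4),
            ifelse(x$kth_censored, "(censored)", ""), collapse = ", "), "\n")
  invisible(x)
}

#' Repeat a simulation over consecutive noise seeds
#'
#' Runs [simulate_subject()] with seeds `base_seed + 0 ... base_seed +
#' n_iter - 1`. Results are order-stable and reproducible.
#'
#' @param model a `subject_model`.
#' @param n_iter number of iterations (>= 1).
#' @param base_seed first noise seed.
#' @return List of `sim_result`, one per seed.
#' @export
run_iterations <- function(model, n_iter = 100L, base_seed = 0L) {
  if (n_iter < 1L) stop("n_iter must be >= 1")
  lapply(seq_len(n_iter) - 1L, function(k) {
    simulate_subject(model, base_seed + k)
  })
}

#' k-th escape time of a simulation result
#'
#' @param result a `sim_result`.
#' @param k which escape (defaults to the configured seizure criterion,
#'   i.e. the last recorded one).
#' @return The time at which the k-th distinct active node escaped
#'   (`max_time` if censored).
#' @export
kth_escape_time <- function(result, k = length(result$kth_escape_times)) {
  stopifnot(k >= 1L, k <= length(result$kth_escape_times))
  result$kth_escape_times[k]
}

#' @rdname kth_escape_time
#' @export
third_escape_time <- function(result) {
  kth_escape_time(result, min(3L, length(result$kth_escape_times)))
}

#' Tidy long-format table of escape times
#'
#' @param results list of `sim_result` (e.g. from [run_iterations()]).
#' @param subject_id optional id column value.
#' @return data.frame with columns `subject_id`, `seed`, `node`,
#'   `escape_time`, `censored` (resected nodes are omitted).
#' @export
escape_table <- function(results, subject_id = NA_character_) {
  do.call(rbind, lapply(results, function(r) {
    keep <- which(!is.na(r$censored))
    data.frame(subject_id = subject_id, seed = r$seed, node = keep,
               escape_time = r$escape_time[keep],
               censored = r$censored[keep], row.names = NULL)
  }))
}
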