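#' Model parameters of the bistable network simulation
#'
#' All quantities are in model time units unless noted. Defaults follow the
#' source model: coupling scale `beta = 0.01`, noise scale `alpha = 0.05`,
#' angular frequency `omega = 15`, excitability spread `psi = 15`, axonal
#' conduction speed 7 m/s, escape threshold 1, and a three-node escape
#' criterion for seizure onset.
#'
#' The solver step `dt` deserves care: the explicit Euler-Maruyama update of
#' a rotation with angular frequency `omega` dilates radial amplitude at
#' rate `omega^2 * dt / 2` per time unit, which shifts the effective
#' bistability threshold of a node from `lambda = 1` down to
#' `lambda* = 1 - omega^2 * dt / 2`. The default `dt = 0.0025` puts
#' `lambda*` at about 0.72, above the excitability attainable by control
#' regions, so the background state is metastable for every physiological
#' region while strongly atrophic regions approach criticality. See the
#' package vignette for the full analysis.
#'
#' @param beta coupling scale multiplying the connectivity matrix.
#' @param alpha noise amplitude; each complex component receives an
#'   independent `alpha * sqrt(dt)` normal increment per step.
#' @param omega angular frequency of the node oscillation (rad per time
#'   unit).
#' @param psi spread constant mapping surface-area deviation to
#'   excitability.
#' @param conduction_speed axonal propagation speed in m/s used to turn
#'   fibre lengths into delays.
#' @param dt solver step.
#' @param max_time censoring horizon.
#' @param escape_threshold radius defining the seizure state; fixed at 1.
#' @param n_escapes_for_seizure number of distinct escaped nodes at which a
#'   simulation stops (the seizure-onset criterion).
#' @param time_unit_seconds seconds per model time unit, used only for the
#'   fibre-length-to-delay conversion.
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(beta = 0.01, alpha = 0.05, omega = 15,
                             psi = 15, conduction_speed = 7, dt = 0.0025,
                             max_time = 200, escape_threshold = 1,
                             n_escapes_for_seizure = 3L,
                             time_unit_seconds = 1) {
  stopifnot(dt > 0, max_time > 0, conduction_speed > 0, psi > 0,
            alpha >= 0, time_unit_seconds > 0)
  if (escape_threshold != 1) {
    stop("escape_threshold is fixed at 1 (the unstable-cycle ceiling of ",
         "the normal form)")
  }
  if (n_escapes_for_seizure < 1L || n_escapes_for_seizure > 82L) {
    stop("n_escapes_for_seizure must be in 1..82")
  }
  structure(
    list(beta = beta, alpha = alpha, omega = omega, psi = psi,
         conduction_speed = conduction_speed, dt = dt, max_time = max_time,
         escape_threshold = 1, n_escapes_for_seizure =
           as.integer(n_escapes_for_seizure),
         time_unit_seconds = time_unit_seconds),
    class = "model_parameters"
  )
}

#' Normalize streamline counts into coupling weights
#'
#' Applies the log normalization `M = log(S) / max(log(S))` entrywise.
#' Entries with `S <= 1` map to weight 0: a zero count is an absent edge,
#' and a single-streamline edge is below tractography noise (and `log 1 = 0`
#' would not survive the normalization anyway). The result is symmetric,
#' zero-diagonal, with entries in [0, 1] and maximum exactly 1.
#'
#' @param S symmetric matrix of non-negative integer streamline counts.
#' @return The coupling matrix `M`.
#' @export
normalize_connectivity <- function(S) {
  if (!isSymmetric(unname(S))) stop("S must be symmetric")
  if (any(S < 0)) stop("S must be non-negative")
  M <- matrix(0, nrow(S), ncol(S), dimnames = dimnames(S))
  keep <- S > 1
  if (!any(keep)) stop("empty network: no edge with more than one streamline")
  M[keep] <- log(S[keep])
  M / max(M)
}

#' Surface-area deviation scores
#'
#' Quantifies how far each regional surface area lies from the control
#' distribution, in standard-deviation-like units. Two scores are provided:
#'
#' \describe{
#'   \item{`"pooled"` (default)}{an allometric parametric standard score
#'     on the log scale. Each subject's log areas are first centred by a
#'     robust (median) per-subject offset relative to the reference means,
#'     removing the shared brain-size factor; the score is then the
#'     centred deviation from the per-region reference means divided by a
#'     single residual standard deviation pooled across all regions.
#'     Regional areas vary multiplicatively with similar relative spread
#'     everywhere, so pooling is variance-stabilizing and keeps the score
#'     well-resolved even for small control cohorts (the same small-sample
#'     logic as pooled-variance moderated statistics in gene-expression
#'     analysis); the robust offset keeps focal atrophy from biasing the
#'     subject's own normalization.}
#'   \item{`"rank"`}{a nonparametric placement score with tie adjustment and
#'     continuity correction: `D = qnorm((n_below + 0.5 * n_ties + 0.5) /
#'     (n_ref + 1))`. Robust, but it saturates at
#'     `qnorm(0.5 / (n_ref + 1))` -- about +/-1.69 for 10 references --
#'     which erases genuine extreme atrophy in small cohorts; prefer it only
#'     when the reference cohort is large (tens of controls).}
#' }
#'
#' Scores are clipped to `+/- clip` (default 6, i.e. lambda within
#' \[0.1, 0.9\] at psi = 15) so downstream excitabilities stay inside the
#' bistable range; a message is emitted when clipping occurs. The bound is
#' deliberately wide: sclerotic mesial-temporal structures genuinely sit
#' many standard deviations below controls, and a tight clip would assign
#' them the same excitability as an ordinary sampling extreme.
#'
#' @param subject_areas numeric vector of the subject's surface areas (one
#'   per region), or a scalar when `control_areas` is a vector.
#' @param control_areas matrix of control surface areas (subjects in rows,
#'   regions in columns), or a vector of one region's control areas.
#' @param method `"pooled"` or `"rank"`.
#' @param exclude optional row index or rowname to drop from
#'   `control_areas` first (leave-one-out scoring for control subjects).
#' @param clip symmetric clipping bound for the returned scores.
#' @return Numeric vector of deviation scores `D` (negative = smaller area
#'   than controls).
#' @export
surface_area_deviation <- function(subject_areas, control_areas,
                                   method = c("pooled", "rank"),
                                   exclude = NULL, clip = 6) {
  method <- match.arg(method)
  if (is.vector(control_areas)) {
    control_areas <- matrix(control_areas, ncol = length(subject_areas))
  }
  if (!is.null(exclude)) {
    if (is.character(exclude)) exclude <- match(exclude, rownames(control_areas))
    if (is.na(exclude) || exclude < 1 || exclude > nrow(control_areas)) {
      stop("exclude does not identify a control row")
    }
    control_areas <- control_areas[-exclude, , drop = FALSE]
  }
  n_ref <- nrow(control_areas)
  if (n_ref < 2L) stop("need at least 2 control references per region")
  if (ncol(control_areas) != length(subject_areas)) {
    stop("control_areas must have one column per subject region")
  }

  if (method == "pooled") {
    lg <- log(control_areas)
    mu0 <- colMeans(lg)
    offsets <- apply(sweep(lg, 2L, mu0), 1L, stats::median)
    lgc <- lg - offsets                 # allometrically centred references
    mu <- colMeans(lgc)
    resid <- sweep(lgc, 2L, mu)
    s_pool <- sqrt(sum(resid^2) / (length(resid) - ncol(resid)))
    subj <- log(subject_areas)
    subj_off <- stats::median(subj - mu)
    D <- (subj - subj_off - mu) / s_pool
  } else {
    D <- vapply(seq_along(subject_areas), function(i) {
      ref <- control_areas[, i]
      p_tilde <- (sum(ref < subject_areas[i]) +
                    0.5 * sum(ref == subject_areas[i]) + 0.5) / (n_ref + 1)
      qnorm(p_tilde)
    }, numeric(1))
  }
  if (any(abs(D) > clip)) {
    message(sum(abs(D) > clip), " deviation score(s) clipped to +/-", clip)
    D <- pmin(pmax(D, -clip), clip)
  }
  unname(D)
}

#' Excitability from surface-area deviation
#'
#' `lambda = -D / psi + 0.5`, clamped to `[0.001, 0.999]` so the node
#' normal form keeps both attractors (`0 < lambda < 1`). A region exactly at
#' the control centre (`D = 0`) has `lambda = 0.5`; reduced surface area
#' (negative `D`) raises excitability.
#'
#' @param D deviation scores from [surface_area_deviation()].
#' @param psi spread constant (> 0), default 15.
#' @return Excitability vector with entries in (0, 1).
#' @export
compute_lambda <- function(D, psi = 15) {
  stopifnot(psi > 0)
  pmin(pmax(-D / psi + 0.5, 1e-3), 1 - 1e-3)
}

#' Integer-step conduction delays from fibre lengths
#'
#' Converts mean fibre lengths (mm) into integer solver-step delays:
#' `tau = (L / 1000) / speed` seconds, divided by `time_unit_seconds`, then
#' binned to the nearest multiple of `dt` (a fixed-step solver can only
#' realize such delays; this is the delay "binning"). Absent edges keep
#' delay 0.
#'
#' @param L matrix of fibre lengths (mm), 0 where no edge.
#' @param conduction_speed m/s.
#' @param time_unit_seconds seconds per model time unit.
#' @param dt solver step (model time units).
#' @return Integer matrix of delays in solver steps.
#' @export
compute_delays <- function(L, conduction_speed = 7, time_unit_seconds = 1,
                           dt = 0.0025) {
  if (any(L < 0)) stop("negative fibre length")
  stopifnot(conduction_speed > 0, dt > 0, time_unit_seconds > 0)
  tau <- (L / 1000) / conduction_speed / time_unit_seconds
  steps <- matrix(as.integer(round(tau / dt)), nrow(L), ncol(L),
                  dimnames = dimnames(L))
  steps[L == 0] <- 0L
  steps
}

#' Build a subject model from a connectome and a control cohort
#'
#' Composes [normalize_connectivity()], [surface_area_deviation()] /
#' [compute_lambda()] and [compute_delays()] into the quantities entering
#' the dynamics. For control subjects that are themselves part of
#' `control_cohort`, the deviation score uses leave-one-out referencing
#' (the subject is removed from the reference sample first).
#'
#' @param conn a `connectome`.
#' @param control_cohort list of control `connectome`s (>= 3).
#' @param params a [model_parameters()] object.
#' @param deviation_method passed to [surface_area_deviation()].
#' @return An object of class `subject_model` with elements `M`, `lambda`,
#'   `delay_steps`, `D`, `active_mask`, `params`, `subject_id`, `group`.
#' @export
build_subject_model <- function(conn, control_cohort,
                                params = model_parameters(),
                                deviation_method = c("pooled", "rank")) {
  deviation_method <- match.arg(deviation_method)
  stopifnot(inherits(conn, "connectome"),
            inherits(params, "model_parameters"))
  if (length(control_cohort) < 3L) {
    stop("control_cohort must contain at least 3 control subjects")
  }
  groups <- vapply(control_cohort, `[[`, "", "group")
  if (any(groups != "control")) {
    stop("control_cohort must contain controls only")
  }
  ctrl_areas <- do.call(rbind, lapply(control_cohort, `[[`, "areas"))
  rownames(ctrl_areas) <- vapply(control_cohort, `[[`, "", "subject_id")

  exclude <- NULL
  if (conn$group == "control" && conn$subject_id %in% rownames(ctrl_areas)) {
    exclude <- conn$subject_id
  }
  D <- surface_area_deviation(conn$areas, ctrl_areas,
                              method = deviation_method, exclude = exclude)
  lam <- compute_lambda(D, params$psi)
  M <- normalize_connectivity(conn$S)
  delay_steps <- compute_delays(conn$L, params$conduction_speed,
                                params$time_unit_seconds, params$dt)
  structure(
    list(M = M, lambda = lam, delay_steps = delay_steps, D = D,
         active_mask = rep(TRUE, nrow(M)), params = params,
         subject_id = conn$subject_id, group = conn$group),
    class = "subject_model"
  )
}

#' @export
print.subject_model <- function(x, ...) {
  cat("<subject_model>", x$subject_id, "(", x$group, ")\n")
  cat("  lambda range:", paste(signif(range(x$lambda), 4), collapse = " - "),
      "\n")
  cat("  active nodes:", sum(x$active_mask), "/", length(x$active_mask), "\n")
  cat("  max delay steps:", max(x$delay_steps), "\n")
  invisible(x)
}

#' Serialize a subject model for inspection
#'
#' Writes `M.tsv`, `lambda.tsv`, `delays.tsv` and a parameter echo under
#' `dir_path`.
#'
#' @param model a `subject_model`.
#' @param dir_path output directory.
#' @return `dir_path`, invisibly.
#' @export
write_subject_model <- function(model, dir_path) {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  wm <- function(m, file) {
    df <- cbind(region = rownames(m), as.data.frame(m))
    write.table(df, file.path(dir_path, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wm(model$M, "M.tsv")
  wm(model$delay_steps, "delays.tsv")
  lam <- data.frame(region = rownames(model$M), lambda = model$lambda,
                    D = model$D, active = model$active_mask)
  write.table(lam, file.path(dir_path, "lambda.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  pars <- data.frame(key = names(model$params),
                     value = unlist(model$params))
  write.table(pars, file.path(dir_path, "params.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir_path)
}
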