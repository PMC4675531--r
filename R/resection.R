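#' Resection plans
#'
#' A resection plan names a strategy and exactly three distinct atlas
#' indices to remove. Three strategies mirror the in-silico surgery
#' conditions: `random` (a random seed node plus its two strongest
#' above-average neighbours), `clinical` (the amygdalohippocampectomy
#' targets: ipsilateral hippocampus, amygdala, parahippocampal gyrus) and
#' `patient_specific` (the three fastest-escaping nodes of the unresected
#' baseline).
#'
#' @param strategy one of `"random"`, `"clinical"`, `"patient_specific"`.
#' @param nodes integer vector of exactly 3 distinct atlas indices.
#' @param seed seed used by the random strategy (NA otherwise).
#' @return An object of class `resection_plan`.
#' @export
resection_plan <- function(strategy = c("random", "clinical",
                                        "patient_specific"),
                           nodes, seed = NA_integer_) {
  strategy <- match.arg(strategy)
  nodes <- as.integer(nodes)
  if (length(nodes) != 3L || anyDuplicated(nodes) ||
      any(nodes < 1L | nodes > 82L)) {
    stop("a resection plan must name exactly 3 distinct atlas indices in 1..82")
  }
  structure(list(strategy = strategy, nodes = nodes, seed = seed),
            class = "resection_plan")
}

#' @export
print.resection_plan <- function(x, ...) {
  cat("<resection_plan>", x$strategy, "- nodes:",
      paste(x$nodes, collapse = ", "),
      if (!is.na(x$seed)) paste0("(seed ", x$seed, ")"), "\n")
  invisible(x)
}

#' Clinical resection plan (amygdalohippocampectomy)
#'
#' Returns the three regions most commonly removed in a standard
#' amygdalohippocampectomy on the given side: hippocampus, amygdala and
#' parahippocampal gyrus.
#'
#' @param atlas atlas table.
#' @param side `"left"` or `"right"`.
#' @return A `resection_plan` with strategy `"clinical"`.
#' @export
plan_clinical <- function(atlas = load_atlas(), side = c("left", "right")) {
  side <- match.arg(side)
  nodes <- atlas$index[atlas$clinical_target & atlas$hemisphere == side]
  resection_plan("clinical", nodes)
}

#' Random resection plan
#'
#' Draws a uniformly random seed node among the currently active nodes,
#' then adds its two strongest-coupled neighbours whose connection weight
#' exceeds the mean nonzero weight of `M` ("nearest neighbours with
#' connection weights greater than the average"). If the drawn node has
#' fewer than two qualifying neighbours, a bounded number of redraws is
#' attempted before failing.
#'
#' @param model a `subject_model`.
#' @param seed integer seed making the draw reproducible.
#' @param max_redraws redraw budget before giving up.
#' @return A `resection_plan` with strategy `"random"`.
#' @export
plan_random <- function(model, seed, max_redraws = 82L) {
  stopifnot(inherits(model, "subject_model"))
  M <- model$M
  act <- which(model$active_mask)
  wbar <- mean(M[M > 0])
  with_seed(seed, {
    for (try in seq_len(max_redraws)) {
      centre <- act[sample.int(length(act), 1L)]
      w <- M[, centre]
      w[!model$active_mask] <- 0
      qual <- which(w > wbar)
      if (length(qual) >= 2L) {
        nbrs <- qual[order(-w[qual], qual)][1:2]
        return(resection_plan("random", c(centre, nbrs), seed = seed))
      }
    }
    stop("no seed node with two neighbours above the mean nonzero weight ",
         "was found in ", max_redraws, " draws")
  })
}

#' Patient-specific resection plan from baseline simulations
#'
#' Ranks nodes by the number of appearances among the first three escapers
#' across baseline (unresected) iterations; ties are broken by smaller mean
#' escape time (over the iterations in which the node escaped), then by
#' lower atlas index. The top `n_top` nodes form the plan.
#'
#' @param baseline_results list of `sim_result` from the unresected model.
#' @param n_top number of nodes to remove (3, per the surgical analogy).
#' @return A `resection_plan` with strategy `"patient_specific"`.
#' @export
plan_patient_specific <- function(baseline_results, n_top = 3L) {
  stopifnot(length(baseline_results) >= 1L)
  n <- length(baseline_results[[1L]]$escape_time)
  appearances <- numeric(n)
  time_sum <- numeric(n)
  time_cnt <- numeric(n)
  for (r in baseline_results) {
    first3 <- utils::head(r$escape_order, 3L)
    appearances[first3] <- appearances[first3] + 1
    esc <- r$escape_order
    time_sum[esc] <- time_sum[esc] + r$escape_time[esc]
    time_cnt[esc] <- time_cnt[esc] + 1
  }
  candidates <- which(appearances > 0)
  if (length(candidates) < n_top) {
    stop("only ", length(candidates), " node(s) ever appeared among the ",
         "first three escapers; need ", n_top)
  }
  mean_time <- ifelse(time_cnt > 0, time_sum / pmax(time_cnt, 1), Inf)
  ord <- candidates[order(-appearances[candidates], mean_time[candidates],
                          candidates)]
  resection_plan("patient_specific", ord[seq_len(n_top)])
}

#' Apply a resection to a subject model
#'
#' Simulates surgery by setting all inputs and outputs of the resected
#' nodes to zero (rows and columns of `M`) and marking them inactive, which
#' freezes them at the background state and excludes them from escape
#' detection. The original model is not modified. Applying the same plan
#' twice is an error (a node cannot be resected again); disjoint plans
#' commute.
#'
#' @param model a `subject_model`.
#' @param plan a `resection_plan`.
#' @return A new `subject_model` with the plan applied.
#' @export
apply_resection <- function(model, plan) {
  stopifnot(inherits(model, "subject_model"),
            inherits(plan, "resection_plan"))
  if (any(!model$active_mask[plan$nodes])) {
    stop("node(s) ",
         paste(plan$nodes[!model$active_mask[plan$nodes]], collapse = ", "),
         " are already resected")
  }
  out <- model
  out$M[plan$nodes, ] <- 0
  out$M[, plan$nodes] <- 0
  out$delay_steps[plan$nodes, ] <- 0L
  out$delay_steps[, plan$nodes] <- 0L
  out$active_mask[plan$nodes] <- FALSE
  out
}

#' Serialize resection plans
#'
#' @param plans list of `resection_plan` (or a single one).
#' @param file output TSV path.
#' @param atlas atlas table used to attach region labels.
#' @return The written data.frame, invisibly.
#' @export
write_plans <- function(plans, file, atlas = load_atlas()) {
  if (inherits(plans, "resection_plan")) plans <- list(plans)
  df <- do.call(rbind, lapply(plans, function(p) {
    data.frame(strategy = p$strategy,
               nodes = paste(p$nodes, collapse = ","),
               labels = paste(atlas$label[p$nodes], collapse = ","),
               seed = p$seed, row.names = NULL)
  }))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
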