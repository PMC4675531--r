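#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two samples, reporting the U statistic for the
#' first sample, a normal-approximation z score (tie-corrected, with
#' continuity correction) and a two-sided p value. The p value is exact
#' (via the null U distribution) when there are no ties and both samples
#' have at most 50 observations, matching common practice; otherwise the
#' normal approximation is used. Positive `z` means the first sample tends
#' to be larger.
#'
#' @param x,y numeric samples.
#' @return List with `U`, `z`, `p`, `n1`, `n2`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nt <- table(c(x, y))
  N <- n1 + n2
  tie_term <- sum(nt^3 - nt) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    warning("degenerate samples (all values tied); p = 1")
    return(list(U = U, z = 0, p = 1, n1 = n1, n2 = n2))
  }
  cc <- sign(U - mu) * 0.5
  z <- (U - mu - cc) / sqrt(sigma2)
  has_ties <- any(nt > 1)
  if (!has_ties && n1 <= 50L && n2 <= 50L) {
    p <- if (U > mu) {
      2 * (1 - stats::pwilcox(U - 1, n1, n2))
    } else {
      2 * stats::pwilcox(U, n1, n2)
    }
    p <- min(1, p)
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = U, z = z, p = p, n1 = n1, n2 = n2)
}

# Appearance ranking of first-three escapers across iterations: returns
# candidate node indices ordered by (appearances desc, mean escape time asc,
# index asc).
rank_first_three <- function(results) {
  n <- length(results[[1L]]$escape_time)
  appearances <- numeric(n)
  time_sum <- numeric(n)
  time_cnt <- numeric(n)
  for (r in results) {
    first3 <- utils::head(r$escape_order, 3L)
    appearances[first3] <- appearances[first3] + 1
    esc <- r$escape_order
    time_sum[esc] <- time_sum[esc] + r$escape_time[esc]
    time_cnt[esc] <- time_cnt[esc] + 1
  }
  candidates <- which(appearances > 0)
  mean_time <- ifelse(time_cnt > 0, time_sum / pmax(time_cnt, 1), Inf)
  list(order = candidates[order(-appearances[candidates],
                                mean_time[candidates], candidates)],
       appearances = appearances)
}

#' Summarize one subject's simulations
#'
#' Means over iterations of the k-th escape times (censored runs contribute
#' `max_time`, so all iterations stay comparable), the subject's top-3
#' fastest-escaping nodes by appearance ranking, and the fraction of
#' iterations censored before the seizure criterion was met.
#'
#' @param results list of `sim_result` from [run_iterations()].
#' @param subject_id,group metadata carried into the summary.
#' @return An object of class `subject_summary`.
#' @export
summarize_subject <- function(results, subject_id = NA_character_,
                              group = NA_character_) {
  stopifnot(length(results) >= 1L)
  kth <- do.call(rbind, lapply(results, `[[`, "kth_escape_times"))
  kcens <- do.call(rbind, lapply(results, `[[`, "kth_censored"))
  rk <- rank_first_three(results)
  structure(
    list(subject_id = subject_id, group = group,
         mean_kth_escape = colMeans(kth),
         top3_nodes = utils::head(rk$order, 3L),
         appearances = rk$appearances,
         censored_fraction = mean(kcens[, ncol(kcens)]),
         n_iterations = length(results)),
    class = "subject_summary"
  )
}

#' Compare escape times between subject groups
#'
#' Two-sided Mann-Whitney U test on subject-level mean k-th escape times,
#' reporting the statistics plotted in the validation figure: group means,
#' standard errors, U, z and p.
#'
#' @param patient_summaries,control_summaries lists of `subject_summary`.
#' @param k which escape time to compare (default 3, the seizure criterion).
#' @return List with the test report.
#' @export
compare_groups <- function(patient_summaries, control_summaries, k = 3L) {
  stopifnot(length(patient_summaries) >= 2L, length(control_summaries) >= 2L)
  gx <- vapply(patient_summaries, function(s) s$mean_kth_escape[k], 0)
  gy <- vapply(control_summaries, function(s) s$mean_kth_escape[k], 0)
  mw <- mann_whitney(gx, gy)
  list(k = k, U = mw$U, z = mw$z, p = mw$p,
       patient_mean = mean(gx), patient_se = sd(gx) / sqrt(length(gx)),
       control_mean = mean(gy), control_se = sd(gy) / sqrt(length(gy)),
       n_patients = length(gx), n_controls = length(gy),
       patient_values = gx, control_values = gy)
}

#' Population-level tally of top escaping nodes
#'
#' Counts how often each node appears among the subjects' top-3
#' fastest-escaping nodes and returns the `n` most frequent, ties broken by
#' lower atlas index.
#'
#' @param subject_summaries list of `subject_summary`.
#' @param n how many nodes to return.
#' @param atlas atlas table for labels.
#' @return data.frame with `node`, `label`, `count`.
#' @export
population_top_nodes <- function(subject_summaries, n = 10L,
                                 atlas = load_atlas()) {
  stopifnot(length(subject_summaries) >= 1L)
  tally <- numeric(nrow(atlas))
  for (s in subject_summaries) tally[s$top3_nodes] <- tally[s$top3_nodes] + 1
  ord <- order(-tally, seq_along(tally))
  keep <- utils::head(ord[tally[ord] > 0], n)
  data.frame(node = keep, label = atlas$label[keep], count = tally[keep],
             row.names = NULL)
}

#' Consistency of early escape locations
#'
#' Percentage of realized (subject, iteration, first-three-slot) escape
#' occurrences that fall inside `top_set`. Slots censored before a third
#' escape are excluded from the denominator, so the score reads "of all
#' observed early escapes, how many were in the top set".
#'
#' @param results_by_subject list (one element per subject) of lists of
#'   `sim_result`.
#' @param top_set integer vector of node indices (e.g. from
#'   [population_top_nodes()]).
#' @return Percentage in \[0, 100\].
#' @export
consistency_score <- function(results_by_subject, top_set) {
  stopifnot(length(top_set) >= 1L)
  hits <- 0L; total <- 0L
  for (results in results_by_subject) {
    for (r in results) {
      first3 <- utils::head(r$escape_order, 3L)
      hits <- hits + sum(first3 %in% top_set)
      total <- total + length(first3)
    }
  }
  if (total == 0L) return(0)
  100 * hits / total
}

#' Pre/post resection improvement record for one subject
#'
#' Per-iteration percentage improvement in the third-escape time,
#' `100 * (T_post - T_pre) / T_pre`, iterations paired by seed index, with
#' a paired t-test across iterations. `success` requires both p < 0.05 and
#' a positive mean improvement (longer post-surgery escape times).
#'
#' @param pre_results,post_results equal-length lists of `sim_result` with
#'   matched seeds.
#' @param subject_id,strategy metadata carried into the record.
#' @param require_matched_seeds verify that pre and post used identical
#'   seed sequences (the pipeline's pairing guarantee). Disable only for
#'   designs that pair independent replicate blocks by position, e.g. null
#'   calibration experiments.
#' @return An object of class `improvement_record`.
#' @export
improvement_table <- function(pre_results, post_results,
                              subject_id = NA_character_,
                              strategy = NA_character_,
                              require_matched_seeds = TRUE) {
  if (length(pre_results) != length(post_results)) {
    stop("pre and post must have equal iteration counts")
  }
  seeds_pre <- vapply(pre_results, `[[`, 0, "seed")
  seeds_post <- vapply(post_results, `[[`, 0, "seed")
  if (require_matched_seeds && !identical(seeds_pre, seeds_post)) {
    stop("pre/post iterations must be paired by seed")
  }
  t_pre <- vapply(pre_results, third_escape_time, 0)
  t_post <- vapply(post_results, third_escape_time, 0)
  if (any(t_pre == 0)) stop("zero pre-resection escape time")
  impr <- 100 * (t_post - t_pre) / t_pre
  if (sd(t_post - t_pre) == 0) {
    p <- if (all(t_post == t_pre)) 1 else 0
  } else {
    p <- t.test(t_post, t_pre, paired = TRUE)$p.value
  }
  structure(
    list(subject_id = subject_id, strategy = strategy,
         improvement = impr, mean_improvement = mean(impr),
         p_value = p, success = p < 0.05 && mean(t_post) > mean(t_pre)),
    class = "improvement_record"
  )
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Omnibus and pairwise comparison of resection strategies
#'
#' Kruskal-Wallis test across the strategies' improvement distributions;
#' pairwise two-sided Mann-Whitney U tests with Bonferroni-adjusted p
#' values are run only when the omnibus test is significant at 0.05.
#' Star levels: * p < 0.05, ** p < 0.01, *** p < 0.001 (on adjusted p).
#'
#' @param improvements_by_strategy named list of numeric vectors (one per
#'   strategy) of improvement percentages.
#' @return List with `omnibus_p`, `pairwise` (data.frame or NULL) and
#'   `n_comparisons`.
#' @export
compare_strategies <- function(improvements_by_strategy) {
  stopifnot(length(improvements_by_strategy) >= 2L,
            all(lengths(improvements_by_strategy) >= 2L))
  vals <- unlist(improvements_by_strategy, use.names = FALSE)
  grp <- factor(rep(names(improvements_by_strategy),
                    lengths(improvements_by_strategy)))
  omnibus_p <- if (stats::var(vals) == 0) 1 else
    kruskal.test(vals, grp)$p.value
  pairwise <- NULL
  pairs <- utils::combn(names(improvements_by_strategy), 2L)
  n_comp <- ncol(pairs)
  if (omnibus_p < 0.05) {
    pairwise <- do.call(rbind, lapply(seq_len(n_comp), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      mw <- mann_whitney(improvements_by_strategy[[a]],
                         improvements_by_strategy[[b]])
      data.frame(strategy_a = a, strategy_b = b, U = mw$U, z = mw$z,
                 p_adjusted = min(1, mw$p * n_comp), row.names = NULL)
    }))
    pairwise$stars <- significance_stars(pairwise$p_adjusted)
  }
  list(omnibus_p = omnibus_p, pairwise = pairwise, n_comparisons = n_comp)
}

#' Cohort surgery success rates per strategy
#'
#' Percentage of subjects whose `improvement_record` is a success
#' (significant paired improvement), per strategy.
#'
#' @param records list of `improvement_record`.
#' @return data.frame with `strategy`, `n`, `n_success`, `success_rate`
#'   (percent).
#' @export
cohort_success_rate <- function(records) {
  stopifnot(length(records) >= 1L)
  strategies <- vapply(records, `[[`, "", "strategy")
  success <- vapply(records, `[[`, TRUE, "success")
  out <- do.call(rbind, lapply(split(success, strategies), function(s) {
    data.frame(n = length(s), n_success = sum(s),
               success_rate = 100 * mean(s))
  }))
  out <- cbind(strategy = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Weighted network measures per node
#'
#' Degree (nonzero neighbours), node strength (sum of incident weights),
#' weighted clustering coefficient (geometric mean of triangle weights,
#' weights normalized by the matrix maximum), and eigenvector centrality
#' (principal eigenvector, normalized to unit maximum). On a disconnected
#' graph the centrality is computed on the largest connected component,
#' other nodes receive 0, with a warning.
#'
#' @param M symmetric non-negative weight matrix.
#' @return data.frame with `node`, `degree`, `strength`, `clustering`,
#'   `eigencentrality`.
#' @export
network_measures <- function(M) {
  if (!isSymmetric(unname(M)) || any(M < 0)) {
    stop("M must be symmetric and non-negative")
  }
  n <- nrow(M)
  A <- (M > 0) * 1
  degree <- rowSums(A)
  strength <- rowSums(M)

  W <- M / max(M)
  W3 <- W^(1 / 3)
  cyc <- diag(W3 %*% W3 %*% W3)      # sum over ordered triangle pairs
  clustering <- ifelse(degree >= 2, cyc / (degree * (degree - 1)), 0)

  comp <- integer(n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (comp[v] != 0L) next
    cid <- cid + 1L
    queue <- v
    comp[v] <- cid
    while (length(queue) > 0L) {
      u <- queue[1L]; queue <- queue[-1L]
      nb <- which(A[u, ] > 0 & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  eigencentrality <- numeric(n)
  main <- which(comp == which.max(tabulate(comp)))
  if (length(main) < n) {
    warning("graph is disconnected; eigenvector centrality computed on the ",
            "largest component (", length(main), " nodes), others set to 0")
  }
  if (length(main) >= 2L) {
    ev <- eigen(M[main, main, drop = FALSE], symmetric = TRUE)
    v1 <- ev$vectors[, 1L]
    if (sum(v1) < 0) v1 <- -v1
    v1 <- pmax(v1, 0)                # Perron vector is non-negative
    eigencentrality[main] <- v1 / max(v1)
  }
  data.frame(node = seq_len(n), degree = degree, strength = strength,
             clustering = clustering, eigencentrality = eigencentrality,
             row.names = NULL)
}

#' Group z scores of network measures per node
#'
#' For each requested node and measure, the normal-approximation z of a
#' two-sided Mann-Whitney U test comparing the patient values against the
#' control values. Positive z means the measure is higher in patients.
#'
#' @param patient_tables,control_tables lists of per-subject data.frames
#'   from [network_measures()].
#' @param nodes integer vector of node indices to compare.
#' @param measures character vector of measure column names.
#' @return Matrix of z scores, `length(nodes)` x `length(measures)`.
#' @export
node_measure_group_z <- function(patient_tables, control_tables,
                                 nodes,
                                 measures = c("degree", "strength",
                                              "clustering",
                                              "eigencentrality")) {
  stopifnot(length(patient_tables) >= 2L, length(control_tables) >= 2L)
  z <- matrix(NA_real_, length(nodes), length(measures),
              dimnames = list(nodes, measures))
  for (i in seq_along(nodes)) {
    for (m in measures) {
      px <- vapply(patient_tables, function(tb) tb[[m]][nodes[i]], 0)
      cx <- vapply(control_tables, function(tb) tb[[m]][nodes[i]], 0)
      z[i, m] <- mann_whitney(px, cx)$z
    }
  }
  z
}
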