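test_that("mann_whitney agrees with exhaustive enumeration (n <= 4)", {
  set.seed(17)
  for (rep in 1:20) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    x <- round(runif(n1, 0, 100), 6); y <- round(runif(n2, 0, 100), 6)
    if (anyDuplicated(c(x, y))) next
    mw <- mann_whitney(x, y)
    expect_equal(mw$U, sum(outer(x, y, ">")))
    expect_equal(mw$p, enumerate_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("mann_whitney handles the worked separation example", {
  # patients {1,2,3} vs controls {10,11,12}: U = 0, the minimal p for 3 v 3
  mw <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 2 / choose(6, 3))   # 0.1: the 3v3 floor
  expect_lt(mw$z, 0)
})

test_that("mann_whitney symmetry and degenerate cases", {
  x <- c(5, 8, 1, 9); y <- c(2, 3, 7, 11)
  a <- mann_whitney(x, y); b <- mann_whitney(y, x)
  expect_equal(a$p, b$p)
  expect_equal(a$z, -b$z, tolerance = 1e-12)
  expect_warning(deg <- mann_whitney(rep(4, 3), rep(4, 5)), "degenerate")
  expect_equal(deg$p, 1)
  expect_equal(deg$z, 0)
})

test_that("summarize_subject means match direct recomputation", {
  set.seed(3)
  res <- lapply(1:40, function(s) {
    ord <- sample(82L, sample(2:5, 1))
    fake_result(ord, sort(runif(length(ord), 1, 150)), seed = s)
  })
  s <- summarize_subject(res, "subjX", "patient")
  kth <- t(vapply(res, `[[`, numeric(3), "kth_escape_times"))
  expect_equal(s$mean_kth_escape, colMeans(kth))
  expect_true(all(diff(s$mean_kth_escape) >= 0))   # order statistics
  expect_equal(s$censored_fraction,
               mean(vapply(res, function(r) r$kth_censored[3], TRUE)))
  expect_length(s$top3_nodes, 3L)
})

test_that("compare_groups reports the plotted quantities", {
  mk_sum <- function(m3) {
    structure(list(subject_id = "s", group = "g",
                   mean_kth_escape = c(m3 - 2, m3 - 1, m3),
                   top3_nodes = 1:3, censored_fraction = 0),
              class = "subject_summary")
  }
  pat <- lapply(c(10, 11, 12), mk_sum)
  ctl <- lapply(c(30, 31, 33), mk_sum)
  cg <- compare_groups(pat, ctl, k = 3)
  expect_equal(cg$U, 0)
  expect_equal(cg$patient_mean, 11)
  expect_equal(cg$control_mean, mean(c(30, 31, 33)))
  expect_equal(cg$patient_se, sd(c(10, 11, 12)) / sqrt(3))
  # identical groups: p near 1
  cg0 <- suppressWarnings(compare_groups(pat, pat, k = 3))
  expect_gt(cg0$p, 0.9)
})

test_that("population_top_nodes tallies and tie-breaks deterministically", {
  mk_sum <- function(top3) {
    structure(list(top3_nodes = top3), class = "subject_summary")
  }
  subs <- lapply(1:3, function(i) mk_sum(c(5L, 9L, 2L)))
  tally <- population_top_nodes(subs, n = 10)
  expect_equal(tally$count, c(3, 3, 3))
  expect_equal(tally$node, c(2L, 5L, 9L))    # tie-break by lower index

  # brute-force recount on a random fixture
  set.seed(11)
  tops <- lapply(1:20, function(i) sample(82L, 3L))
  subs <- lapply(tops, mk_sum)
  tally <- population_top_nodes(subs, n = 82)
  manual <- table(factor(unlist(tops), levels = 1:82))
  for (i in seq_len(nrow(tally))) {
    expect_equal(tally$count[i], unname(manual[tally$node[i]]))
  }
  expect_true(all(diff(tally$count) <= 0))

  # disjoint top sets: every count 1, ordered by index
  subs <- lapply(list(c(4L, 5L, 6L), c(1L, 2L, 3L)), mk_sum)
  tally <- population_top_nodes(subs, n = 6)
  expect_equal(tally$node, 1:6)
  expect_equal(tally$count, rep(1, 6))
})

test_that("consistency_score counts first-three occurrences in the top set", {
  r1 <- fake_result(c(5L, 9L, 2L), c(1, 2, 3))
  r2 <- fake_result(c(5L, 7L, 8L), c(1, 2, 3))
  r3 <- fake_result(c(9L, 5L, 3L), c(1, 2, 3))
  r4 <- fake_result(c(1L, 5L, 9L), c(1, 2, 3))
  by_subject <- list(list(r1, r2), list(r3, r4))
  # top set {5, 9}: hits = 2 + 1 + 2 + 2 = 7 of 12 slots
  expect_equal(consistency_score(by_subject, c(5L, 9L)), 100 * 7 / 12)
  expect_equal(consistency_score(by_subject, 1:82), 100)
  expect_equal(consistency_score(by_subject, c(60L, 61L)), 0)
  # censored slots leave the denominator
  r5 <- fake_result(c(5L, 9L), c(1, 2))
  expect_equal(consistency_score(list(list(r5)), c(5L, 9L)), 100)
})

test_that("improvement records follow the paired design", {
  pre <- lapply(1:30, function(s) fake_result(1:3, c(8, 9, 10), seed = s))
  post <- lapply(1:30, function(s) fake_result(1:3, c(12, 13, 15), seed = s))
  rec <- improvement_table(pre, post, "p1", "clinical")
  expect_equal(rec$mean_improvement, 50)
  expect_true(rec$success)

  # unchanged escape times: no improvement, no success
  same <- improvement_table(pre, pre, "p1", "clinical")
  expect_equal(same$mean_improvement, 0)
  expect_false(same$success)

  # constructed positive shift across iterations is detected
  set.seed(6)
  post2 <- lapply(1:100, function(s)
    fake_result(1:3, c(8, 9, 10 + rnorm(1, 1, 0.1)), seed = s))
  pre2 <- lapply(1:100, function(s) fake_result(1:3, c(8, 9, 10), seed = s))
  expect_true(improvement_table(pre2, post2)$success)
  # a significant *worsening* is not a success
  expect_false(improvement_table(post2, pre2)$success)

  expect_error(improvement_table(pre[1:5], post[1:6]), "equal iteration")
  badseed <- post; badseed[[1]]$seed <- 999L
  expect_error(improvement_table(pre, badseed), "paired by seed")
  zero <- lapply(1:30, function(s) {
    r <- fake_result(1:3, c(0, 1, 2), seed = s)
    r$kth_escape_times <- c(0, 1, 0)  # zero third-escape
    r
  })
  expect_error(improvement_table(zero, post), "zero pre-resection")
})

test_that("strategy comparison gates pairwise tests on the omnibus", {
  same <- list(a = rep(1, 10), b = rep(1, 10), c = rep(1, 10))
  out <- compare_strategies(same)
  expect_gt(out$omnibus_p, 0.05)
  expect_null(out$pairwise)
  expect_equal(out$n_comparisons, 3L)

  sep <- list(random = rep(0, 10), clinical = rep(50, 10),
              patient_specific = rep(100, 10))
  out <- compare_strategies(sep)
  expect_lt(out$omnibus_p, 0.05)
  expect_equal(nrow(out$pairwise), 3L)
  expect_true(all(out$pairwise$p_adjusted < 0.05))
  expect_true(all(out$pairwise$stars != ""))
  # Bonferroni factor equals the number of comparisons performed
  raw <- suppressWarnings(mann_whitney(sep$random, sep$clinical)$p)
  expect_equal(out$pairwise$p_adjusted[1], min(1, raw * 3))
})

test_that("cohort success rates reproduce the headline arithmetic", {
  mk_rec <- function(success, strategy = "clinical") {
    structure(list(subject_id = "s", strategy = strategy,
                   mean_improvement = 10, p_value = 0.01,
                   success = success), class = "improvement_record")
  }
  recs <- c(lapply(1:16, function(i) mk_rec(TRUE)),
            lapply(1:6, function(i) mk_rec(FALSE)))
  out <- cohort_success_rate(recs)
  expect_equal(out$success_rate, 72.7, tolerance = 1e-2)  # 16 of 22
  expect_equal(out$n, 22L)

  recs <- c(recs, lapply(1:5, function(i) mk_rec(TRUE, "patient_specific")))
  out <- cohort_success_rate(recs)
  expect_equal(out$success_rate[out$strategy == "patient_specific"], 100)
  out0 <- cohort_success_rate(lapply(1:4, function(i) mk_rec(FALSE)))
  expect_equal(out0$success_rate, 0)
})

test_that("network measures match closed forms on canonical graphs", {
  # unweighted K4: clustering 1, uniform centrality
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  nm <- network_measures(K4)
  expect_equal(nm$degree, rep(3, 4))
  expect_equal(nm$strength, rep(3, 4))
  expect_equal(nm$clustering, rep(1, 4))
  expect_equal(nm$eigencentrality, rep(1, 4))

  # star: centre dominates, no triangles anywhere
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 0.7
  nm <- network_measures(star)
  expect_equal(which.max(nm$strength), 1L)
  expect_equal(nm$degree[1], 4)
  expect_equal(nm$clustering, rep(0, 5))
  expect_equal(which.max(nm$eigencentrality), 1L)
})

test_that("network measures match igraph and a brute-force triangle oracle", {
  skip_if_not_installed("igraph")
  set.seed(23)
  n <- 10
  W <- matrix(runif(n * n), n, n) * (matrix(runif(n * n), n, n) < 0.6)
  W <- (W + t(W)) / 2; diag(W) <- 0
  nm <- network_measures(W)

  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  expect_equal(nm$degree, unname(igraph::degree(g)))
  expect_equal(nm$strength, unname(igraph::strength(g)), tolerance = 1e-12)
  ec <- igraph::eigen_centrality(g, weights = igraph::E(g)$weight)$vector
  expect_equal(nm$eigencentrality, unname(ec), tolerance = 1e-6)

  # geometric-mean triangle clustering, naive triple loop
  Wn <- W / max(W)
  for (i in 1:n) {
    k <- sum(W[i, ] > 0)
    acc <- 0
    for (j in 1:n) for (h in 1:n) {
      if (j != i && h != i && j != h) {
        acc <- acc + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
      }
    }
    expect_equal(nm$clustering[i],
                 if (k >= 2) acc / (k * (k - 1)) else 0, tolerance = 1e-12)
  }
})

test_that("disconnected graphs warn and zero the minor component", {
  W <- matrix(0, 5, 5)
  W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 1
  W[4, 5] <- W[5, 4] <- 1
  expect_warning(nm <- network_measures(W), "disconnected")
  expect_equal(nm$eigencentrality[4:5], c(0, 0))
  expect_equal(max(nm$eigencentrality[1:3]), 1)
})

test_that("group z scores carry the patients-higher-positive convention", {
  mk_tab <- function(vals) data.frame(node = 1:3, degree = vals,
                                      strength = vals, clustering = vals,
                                      eigencentrality = vals)
  pat <- lapply(c(5, 6, 7), function(v) mk_tab(rep(v, 3)))
  ctl <- lapply(c(1, 2, 3), function(v) mk_tab(rep(v, 3)))
  z <- node_measure_group_z(pat, ctl, nodes = 1:2)
  expect_true(all(z > 0))
  # hand-computed 3v3 complete separation: U = 9, continuity-corrected
  z_hand <- (9 - 4.5 - 0.5) / sqrt(9 * 7 / 12)
  expect_equal(unname(z[1, "degree"]), z_hand, tolerance = 1e-12)
  # swap: sign flips
  z2 <- node_measure_group_z(ctl, pat, nodes = 1L)
  expect_equal(unname(z2[1, ]), -unname(z[1, ]), tolerance = 1e-12)
  # identical groups: z = 0 under the tie-degenerate convention
  z0 <- suppressWarnings(node_measure_group_z(pat, pat, nodes = 1L))
  expect_true(all(z0 == 0))
})
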