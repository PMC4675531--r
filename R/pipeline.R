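#' End-to-end experiment configuration
#'
#' Bundles everything a full experiment needs: the synthetic cohort
#' specification, the model parameters, the iteration count, the surgery
#' strategies, and the simulation base seed. All randomness flows from
#' exactly two seeds: `cohort$seed` (connectome sampling) and `base_seed`
#' (noise streams), both echoed into every report.
#'
#' @param cohort a [cohort_spec()].
#' @param model a [model_parameters()] object.
#' @param n_iterations noise iterations per subject (>= 1).
#' @param strategies subset of `c("random", "clinical", "patient_specific")`.
#' @param base_seed first noise seed.
#' @param deviation_method passed to [build_subject_model()].
#' @param output_dir optional report directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), model = model_parameters(),
                       n_iterations = 100L,
                       strategies = c("random", "clinical",
                                      "patient_specific"),
                       base_seed = 1000L,
                       deviation_method = c("pooled", "rank"),
                       output_dir = NULL) {
  deviation_method <- match.arg(deviation_method)
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  bad <- setdiff(strategies, c("random", "clinical", "patient_specific"))
  if (length(bad) > 0L) {
    stop("invalid strategy name(s): ", paste(bad, collapse = ", "))
  }
  if (length(strategies) == 0L) stop("strategies must be non-empty")
  structure(
    list(cohort = cohort, model = model,
         n_iterations = as.integer(n_iterations), strategies = strategies,
         base_seed = as.integer(base_seed),
         deviation_method = deviation_method, output_dir = output_dir),
    class = "run_config"
  )
}

# Build all subject models for a cohort list (controls are the reference).
build_cohort_models <- function(cons, manifest, config) {
  controls <- cons[manifest$subject_id[manifest$group == "control"]]
  lapply(cons, function(x) {
    build_subject_model(x, controls, config$model, config$deviation_method)
  })
}

# All subjects share one seed block (common random numbers): between-subject
# rank comparisons then reflect model differences, not noise-draw luck, and
# under the null of identical models the comparison is exactly tied --
# conservative. Pre/post surgery pairing uses the same block, so improvement
# stays seed-matched.
subject_base_seed <- function(config, subject_index) {
  config$base_seed
}

write_report <- function(df, output_dir, file) {
  if (is.null(output_dir)) return(invisible(NULL))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write.table(df, file.path(output_dir, file), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(NULL)
}

run_info <- function(config) {
  data.frame(key = c("cohort_seed", "base_seed", "n_iterations",
                     "n_patients", "n_controls", "deviation_method",
                     "dt", "alpha", "beta", "omega", "psi"),
             value = c(config$cohort$seed, config$base_seed,
                       config$n_iterations, config$cohort$n_patients,
                       config$cohort$n_controls, config$deviation_method,
                       config$model$dt, config$model$alpha,
                       config$model$beta, config$model$omega,
                       config$model$psi))
}

#' Run the model-validation experiment
#'
#' Generates (or accepts) a cohort, builds subject models, simulates every
#' subject over `n_iterations` noise seeds, and produces the validation
#' analyses: patient-vs-control comparison of mean 1st/2nd/3rd escape
#' times, population top-ten escape locations per group, and consistency
#' scores. Fully reproducible from the two seeds in the config.
#'
#' @param config a [run_config()].
#' @param cohort optionally, a pre-generated cohort list (as returned by
#'   [generate_cohort()]); by default one is generated from
#'   `config$cohort`.
#' @return List with `models`, `baseline_results`, `summaries`,
#'   `group_comparison` (one row per k), `top_nodes`, `consistency`, and
#'   the `config`.
#' @export
run_validation <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (config$n_iterations == 1L) {
    warning("n_iterations = 1: subject means will have very wide variance")
  }
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)
  cons <- cohort$connectomes
  manifest <- cohort$manifest
  models <- build_cohort_models(cons, manifest, config)
  baseline <- lapply(seq_along(models), function(i) {
    run_iterations(models[[i]], config$n_iterations,
                   subject_base_seed(config, i))
  })
  names(baseline) <- names(models)
  summaries <- lapply(names(models), function(id) {
    summarize_subject(baseline[[id]], id,
                      manifest$group[manifest$subject_id == id])
  })
  names(summaries) <- names(models)
  grp <- vapply(summaries, `[[`, "", "group")
  pat <- summaries[grp == "patient"]
  ctl <- summaries[grp == "control"]

  comparison <- do.call(rbind, lapply(1:3, function(k) {
    cg <- compare_groups(pat, ctl, k = k)
    data.frame(k = k, U = cg$U, z = cg$z, p = cg$p,
               patient_mean = cg$patient_mean, patient_se = cg$patient_se,
               control_mean = cg$control_mean, control_se = cg$control_se)
  }))
  top_pat <- population_top_nodes(pat)
  top_ctl <- population_top_nodes(ctl)
  tag <- function(df, g) cbind(group = rep(g, nrow(df)), df)
  top_nodes <- rbind(tag(top_pat, "patient"), tag(top_ctl, "control"))
  safe_consistency <- function(results, top) {
    if (length(top) == 0L) return(NA_real_)   # no escapes observed at all
    consistency_score(results, top)
  }
  consistency <- data.frame(
    group = c("patient", "control"),
    consistency = c(
      safe_consistency(baseline[grp == "patient"], top_pat$node),
      safe_consistency(baseline[grp == "control"], top_ctl$node)
    )
  )

  write_report(run_info(config), config$output_dir, "run_info.tsv")
  write_report(comparison, config$output_dir, "group_comparison.tsv")
  write_report(top_nodes, config$output_dir, "top_nodes.tsv")
  write_report(consistency, config$output_dir, "consistency.tsv")
  sumdf <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(subject_id = s$subject_id, group = s$group,
               mean_first = s$mean_kth_escape[1],
               mean_second = s$mean_kth_escape[min(
                 2L, length(s$mean_kth_escape))],
               mean_third = s$mean_kth_escape[min(
                 3L, length(s$mean_kth_escape))],
               censored_fraction = s$censored_fraction,
               top3 = paste(s$top3_nodes, collapse = ","), row.names = NULL)
  }))
  write_report(sumdf, config$output_dir, "subject_summaries.tsv")

  list(config = config, cohort = cohort, models = models,
       baseline_results = baseline, summaries = summaries,
       group_comparison = comparison, top_nodes = top_nodes,
       consistency = consistency)
}

#' Run the in-silico surgery experiment
#'
#' For every patient and every configured strategy: construct the resection
#' plan, apply it, re-simulate with the same seed sequence as the baseline,
#' and compute the paired improvement record. Produces the strategy
#' comparison (Kruskal-Wallis + Bonferroni pairwise) on per-patient mean
#' improvements, and cohort success rates.
#'
#' @param config a [run_config()].
#' @param validation optionally, the result of [run_validation()] for this
#'   config (recomputed otherwise); baseline simulations are shared so
#'   pre/post pairs are seed-matched.
#' @return List with `records` (one `improvement_record` per patient x
#'   strategy), `plans`, `strategy_comparison`, `success_rates`.
#' @export
run_surgery <- function(config, validation = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(validation)) validation <- run_validation(config)
  models <- validation$models
  baseline <- validation$baseline_results
  manifest <- validation$cohort$manifest
  patients <- manifest$subject_id[manifest$group == "patient"]

  records <- list()
  plans <- list()
  for (pid in patients) {
    i <- match(pid, names(models))
    model <- models[[pid]]
    for (strat in config$strategies) {
      plan <- switch(strat,
        clinical = plan_clinical(side = "left"),
        random = plan_random(model, seed = config$base_seed + i),
        patient_specific = plan_patient_specific(baseline[[pid]])
      )
      post_model <- apply_resection(model, plan)
      post <- run_iterations(post_model, config$n_iterations,
                             subject_base_seed(config, i))
      rec <- improvement_table(baseline[[pid]], post, pid, strat)
      records[[paste(pid, strat, sep = ".")]] <- rec
      plans[[paste(pid, strat, sep = ".")]] <- plan
    }
  }

  by_strat <- lapply(split(
    vapply(records, `[[`, 0, "mean_improvement"),
    vapply(records, `[[`, "", "strategy")
  ), unname)
  strategy_comparison <- if (length(by_strat) >= 2L) {
    compare_strategies(by_strat)
  } else NULL
  success <- cohort_success_rate(records)

  imp <- do.call(rbind, lapply(records, function(r) {
    data.frame(subject_id = r$subject_id, strategy = r$strategy,
               mean_improvement = r$mean_improvement, p = r$p_value,
               success = r$success, row.names = NULL)
  }))
  write_report(imp, config$output_dir, "improvements.tsv")
  write_report(success, config$output_dir, "success_rates.tsv")
  if (!is.null(config$output_dir)) {
    write_plans(plans, file.path(config$output_dir, "plans.tsv"))
    if (!is.null(strategy_comparison)) {
      sc <- data.frame(omnibus_p = strategy_comparison$omnibus_p)
      write_report(sc, config$output_dir, "strategy_omnibus.tsv")
      if (!is.null(strategy_comparison$pairwise)) {
        write_report(strategy_comparison$pairwise, config$output_dir,
                     "strategy_pairwise.tsv")
      }
    }
  }
  list(config = config, records = records, plans = plans,
       strategy_comparison = strategy_comparison, success_rates = success,
       validation = validation)
}

# ---------------------------------------------------------------------------
# Command-line interface

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  positional <- character()
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      if (i == length(args)) stop("flag ", a, " needs a value")
      flags[[substring(a, 3L)]] <- args[i + 1L]
      i <- i + 2L
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  list(flags = flags, positional = positional)
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("key", "value") %in% names(df))) {
    stop("config file must be a TSV with columns 'key' and 'value'")
  }
  setNames(as.list(df$value), df$key)
}

config_from_flags <- function(flags) {
  cfgf <- list()
  if (!is.null(flags$config)) cfgf <- read_config_file(flags$config)
  getval <- function(key, default) {
    if (!is.null(flags[[key]])) return(flags[[key]])
    if (!is.null(cfgf[[key]])) return(cfgf[[key]])
    default
  }
  strategies <- strsplit(getval("strategies",
                                "random,clinical,patient_specific"),
                         ",")[[1]]
  run_config(
    cohort = cohort_spec(
      n_patients = as.integer(getval("patients", 10L)),
      n_controls = as.integer(getval("controls", 10L)),
      seed = as.integer(getval("cohort-seed", 1L)),
      atrophy_effect_sd = as.numeric(getval("atrophy-sd", 2.0))
    ),
    model = model_parameters(),
    n_iterations = as.integer(getval("iterations", 100L)),
    strategies = strategies,
    base_seed = as.integer(getval("seed", 1000L)),
    output_dir = getval("out", NULL)
  )
}

#' Command-line entry point
#'
#' Subcommands: `generate-cohort`, `full-run`, `validate`, `surgery`,
#' `analyze`. Options may come from a `--config` TSV (columns `key`,
#' `value`) and are overridden by flags: `--patients`, `--controls`,
#' `--cohort-seed`, `--seed`, `--iterations`, `--strategies`
#' (comma-separated), `--atrophy-sd`, `--out`.
#'
#' `analyze` recomputes the group-comparison report from a previously
#' written `subject_summaries.tsv` without re-simulation.
#'
#' Run from a shell as
#' `Rscript -e 'ictalnet::ictalnet_cli()' full-run --out reports`.
#'
#' @param args character vector of CLI arguments (default: the command
#'   line).
#' @return The subcommand's result, invisibly.
#' @export
ictalnet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    stop("usage: ictalnet_cli <generate-cohort|validate|surgery|full-run|",
         "analyze> [--flags]")
  }
  cmd <- args[1L]
  parsed <- parse_cli_flags(args[-1L])
  flags <- parsed$flags

  if (cmd == "analyze") {
    if (is.null(flags$out)) stop("analyze needs --out <dir> with stored reports")
    f <- file.path(flags$out, "subject_summaries.tsv")
    if (!file.exists(f)) stop("missing stored summaries: ", f)
    df <- read.delim(f, stringsAsFactors = FALSE)
    mk <- function(g, col) df[[col]][df$group == g]
    comparison <- do.call(rbind, lapply(
      c(mean_first = 1, mean_second = 2, mean_third = 3), function(k) {
        col <- c("mean_first", "mean_second", "mean_third")[k]
        mw <- mann_whitney(mk("patient", col), mk("control", col))
        data.frame(k = k, U = mw$U, z = mw$z, p = mw$p,
                   patient_mean = mean(mk("patient", col)),
                   patient_se = sd(mk("patient", col)) /
                     sqrt(sum(df$group == "patient")),
                   control_mean = mean(mk("control", col)),
                   control_se = sd(mk("control", col)) /
                     sqrt(sum(df$group == "control")))
      }))
    write.table(comparison, file.path(flags$out, "group_comparison.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(comparison))
  }

  config <- config_from_flags(flags)
  out <- switch(cmd,
    "generate-cohort" = {
      if (is.null(config$output_dir)) stop("generate-cohort needs --out")
      generate_cohort(config$cohort, dir = config$output_dir)
    },
    "validate" = run_validation(config),
    "surgery" = run_surgery(config),
    "full-run" = {
      val <- run_validation(config)
      run_surgery(config, val)
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(out)
}
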