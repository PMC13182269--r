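# Benchmark driver: scenario grid -> fits -> AUROC table, with per-cell
# resumability and paired cross-method comparisons, plus a small CLI.

#' Run the scenario benchmark
#'
#' For every scenario in `scenarios` simulates a train/test pair, evaluates
#' the requested methods at each follow-up length, and collects one row per
#' (scenario, method, follow-up) with AUROC, confidence bounds, convergence
#' flag and wall time.  Completed cells found in `out_dir` are not refit
#' (resumability: each scenario's rows are written atomically to
#' `cell_<id>.csv` as soon as it finishes); pass `out_dir = NULL` to keep
#' everything in memory.  Paired Wilcoxon signed-rank comparisons between
#' methods, across scenario x follow-up cells, are attached as attribute
#' `"comparisons"`.  Every non-convergence is reported via `message()` with
#' the scenario id and method.
#'
#' @param scenarios list of [scenario_config()]s (e.g. from
#'   [build_scenario_grid()]).
#' @param methods subset of `c("jm", "lcmm", "pccox", "cox")`.
#' @param followups follow-up lengths in years.
#' @param horizon prediction horizon in years.
#' @param out_dir optional results directory for resumable runs.
#' @param seed master seed; scenario i uses `seed + i - 1` unless the
#'   scenario config carries its own seed.
#' @return data.frame of results with attribute `"comparisons"`.
#' @export
run_benchmark <- function(scenarios, methods = c("jm", "pccox", "cox"),
                          followups = c(5, 10, 15), horizon = 20,
                          out_dir = NULL, seed = NULL) {
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  all_rows <- list()
  for (i in seq_along(scenarios)) {
    cfg <- scenarios[[i]]
    if (!is.null(seed)) cfg$seed <- as.integer(seed + i - 1L)
    id <- scenario_id(cfg)
    cell_file <- if (!is.null(out_dir))
      file.path(out_dir, paste0("cell_", id, ".csv")) else NULL
    if (!is.null(cell_file) && file.exists(cell_file)) {
      all_rows[[id]] <- utils::read.csv(cell_file)
      next
    }
    pair <- simulate_scenario_pair(cfg)
    t0 <- proc.time()[["elapsed"]]
    res <- try(evaluate_scenario(pair$train, pair$test, methods = methods,
                                 followups = followups, horizon = horizon,
                                 seed = cfg$seed), silent = TRUE)
    if (inherits(res, "try-error")) {
      message("scenario ", id, ": evaluation failed: ",
              attr(res, "condition")$message)
      next
    }
    res$scenario <- id
    res$wall_time <- proc.time()[["elapsed"]] - t0
    bad <- res[!res$converged & !duplicated(res$method), , drop = FALSE]
    for (j in seq_len(nrow(bad)))
      message("scenario ", id, ": method ", bad$method[j],
              " did not converge (", bad$reason[j], ")")
    if (!is.null(cell_file)) {
      tmp <- paste0(cell_file, ".tmp")
      utils::write.csv(res, tmp, row.names = FALSE)
      file.rename(tmp, cell_file)   # atomic publish of the finished cell
    }
    all_rows[[id]] <- res
  }
  out <- do.call(rbind, all_rows)
  rownames(out) <- NULL
  attr(out, "comparisons") <- .benchmark_comparisons(out)
  out
}

# Paired Wilcoxon signed-rank p-values between each pair of methods over the
# scenario x followup cells where both produced an AUROC.
.benchmark_comparisons <- function(res) {
  methods <- unique(res$method)
  if (length(methods) < 2) return(NULL)
  key <- interaction(res$scenario, res$followup, drop = TRUE)
  cmp <- list()
  for (a in seq_along(methods)) for (b in seq_along(methods)) {
    if (a >= b) next
    xa <- res$auroc[res$method == methods[a]][order(key[res$method == methods[a]])]
    xb <- res$auroc[res$method == methods[b]][order(key[res$method == methods[b]])]
    ok <- !is.na(xa) & !is.na(xb)
    p <- if (sum(ok) >= 5) compare_methods(xa[ok], xb[ok]) else NA_real_
    cmp[[length(cmp) + 1L]] <- data.frame(
      method_a = methods[a], method_b = methods[b], n_pairs = sum(ok),
      mean_diff = mean(xa[ok] - xb[ok]), p = p)
  }
  do.call(rbind, cmp)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (scenario grid or a single default scenario to
#' CSV directories), `benchmark` (reduced or full grid to a results table),
#' `screen` (simulated cohort screening to `screen_results.csv`,
#' `consensus.csv`), `loocv` (cross-validated AUROCs to `loocv.csv`).  Every
#' run writes its resolved configuration to `run_config.json` next to its
#' outputs when the jsonlite package is available.  Invoke from a shell as
#' `Rscript -e 'jmscreen::jmscreen_cli()' <subcommand> --seed N --out DIR`.
#'
#' @param args character vector of arguments (defaults to
#'   [base::commandArgs()]).
#' @return invisibly, the result object of the subcommand.
#' @export
jmscreen_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: jmscreen <simulate|benchmark|screen|loocv> [options]",
    "  --seed N        master seed (default 1)",
    "  --out DIR       output directory (default 'jmscreen_out')",
    "  --scenario-grid use the full 45-cell grid (simulate/benchmark)",
    "  --config FILE   JSON file of scenario_config fields (simulate)",
    "  --methods M,M   method list (default jm,pccox,cox)", sep = "\n")
  if (!length(args)) { cat(usage, "\n"); return(invisible(NULL)) }
  cmd <- args[1]
  getopt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  seed <- as.integer(getopt("--seed", "1"))
  out <- getopt("--out", "jmscreen_out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  full_grid <- "--scenario-grid" %in% args
  methods <- strsplit(getopt("--methods", "jm,pccox,cox"), ",")[[1]]

  resolved <- list(command = cmd, seed = seed, out = out,
                   scenario_grid = full_grid, methods = methods)
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(resolved, file.path(out, "run_config.json"),
                         auto_unbox = TRUE, pretty = TRUE)

  result <- switch(cmd,
    simulate = {
      config_file <- getopt("--config", NA)
      scen <- if (!is.na(config_file)) {
        fields <- jsonlite::read_json(config_file, simplifyVector = TRUE)
        fields$seed <- fields$seed %||% seed
        list(do.call(scenario_config, fields))
      } else if (full_grid) build_scenario_grid(base_seed = seed) else
        list(scenario_config(seed = seed))
      for (cfg in scen)
        write_dataset(simulate_dataset(cfg),
                      file.path(out, scenario_id(cfg)))
      invisible(scen)
    },
    benchmark = {
      scen <- if (full_grid) build_scenario_grid(base_seed = seed) else
        build_scenario_grid(variance_levels = c(0.5, 1.5),
                            slope_levels = c(0, 0.1),
                            group_sizes = 50, base_seed = seed)
      res <- run_benchmark(scen, methods = methods, out_dir = out)
      utils::write.csv(res, file.path(out, "benchmark_results.csv"),
                       row.names = FALSE)
      res
    },
    screen = {
      cohort <- simulate_cohort(n_features = 200, seed = seed)
      cfg <- screen_config()
      rows <- screen_cohort(cohort, methods = intersect(methods,
                                                        c("jm", "pccox", "lcmm")),
                            config = cfg, seed = seed)
      utils::write.csv(rows, file.path(out, "screen_results.csv"),
                       row.names = FALSE)
      utils::write.csv(consensus(rows, cfg), file.path(out, "consensus.csv"),
                       row.names = FALSE)
      rows
    },
    loocv = {
      cohort <- simulate_cohort(n_features = 50, seed = seed)
      cfg <- screen_config()
      cv <- loocv_screen(cohort, attr(cohort, "planted"), "pccox", cfg,
                         seed = seed)
      utils::write.csv(cv, file.path(out, "loocv.csv"), row.names = FALSE)
      cv
    },
    { cat(usage, "\n"); stop("unknown subcommand: ", cmd) })
  invisible(result)
}
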