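#' Default pipeline configuration
#'
#' Assembles the run configuration consumed by [run_pipeline()]. Either
#' `scan_csv` + `roster_csv` + `agonistic_csv` point at input files, or
#' `synthetic = TRUE` generates a study internally.
#'
#' @param out_dir output directory (created if absent).
#' @param seed global seed recorded in every output.
#' @param synthetic generate inputs with [gen_study()]?
#' @param scan_csv,roster_csv,agonistic_csv input paths (ignored when
#'   `synthetic`).
#' @param n,n_waves synthetic study size.
#' @param mutuality_rule how many behaviors must exceed threshold for a tie
#'   (the two-of-three rule).
#' @param simx_covariates,rate_covariates candidate covariates for
#'   stepwise selection.
#' @param gof_n_sims Monte Carlo replicates for the fit assessment.
#' @param estimation passed to [estimation_options()].
#' @return a named list (class `run_config`).
#' @export
run_config <- function(out_dir, seed = 1L, synthetic = TRUE,
                       scan_csv = NULL, roster_csv = NULL,
                       agonistic_csv = NULL, n = 30, n_waves = 8,
                       mutuality_rule = 2,
                       simx_covariates = c("sex"),
                       rate_covariates = c("sex"),
                       gof_n_sims = 100,
                       estimation = estimation_options()) {
  structure(as.list(environment()), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Lists every violated constraint without running anything.
#'
#' @param config a [run_config()] (or plain list).
#' @return character vector of problems; empty when the config is valid.
#' @export
validate_config <- function(config) {
  problems <- character()
  need <- c("out_dir", "seed", "synthetic", "mutuality_rule",
            "simx_covariates", "rate_covariates", "gof_n_sims",
            "estimation")
  miss <- setdiff(need, names(config))
  if (length(miss))
    problems <- c(problems, paste0("missing field: ", miss))
  if (!is.null(config$gof_n_sims) &&
      (!is.numeric(config$gof_n_sims) || config$gof_n_sims < 20))
    problems <- c(problems, "gof_n_sims must be a number >= 20")
  if (!is.null(config$mutuality_rule) &&
      !config$mutuality_rule %in% 1:3)
    problems <- c(problems, "mutuality_rule must be 1, 2 or 3")
  if (!is.null(config$seed) && (!is.numeric(config$seed)))
    problems <- c(problems, "seed must be an integer")
  if (isFALSE(config$synthetic)) {
    for (f in c("scan_csv", "roster_csv", "agonistic_csv")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]]))
        problems <- c(problems,
                      paste0(f, " must point at an existing file"))
    }
  }
  if (!is.null(config$n_waves) && config$n_waves < 2)
    problems <- c(problems, "n_waves must be at least 2")
  problems
}

#' Run the full analysis pipeline
#'
#' Orchestrates ingest, binarization, dominance ranking, stepwise SAOM
#' fitting and goodness of fit from one configuration, writing per-wave
#' networks, the ranking, a results table, the selection trace, the GOF
#' report and a run log into the output directory. All randomness flows
#' from `config$seed`, so identical configurations reproduce identical
#' outputs.
#'
#' @param config a [run_config()].
#' @return the output directory path, invisibly; side effect: files
#'   written.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  log_line <- function(...) cat(..., "\n", file = logf, append = TRUE,
                                sep = "")
  cat("", file = logf)
  log_line("saomnet ", as.character(utils::packageVersion("saomnet")),
           " seed=", config$seed)
  set.seed(config$seed)

  stage <- function(name, expr) {
    log_line("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- ingest / simulate
  inputs <- stage("ingest", {
    if (isTRUE(config$synthetic)) {
      study <- gen_study(n = config$n, n_waves = config$n_waves)
      list(scan_counts = study$scan_counts, roster = study$roster,
           covariates = study$covariates, agonistic = study$agonistic,
           latent = study$latent_order)
    } else {
      rec <- read_scan_records(config$scan_csv)
      ros <- read.csv(config$roster_csv, stringsAsFactors = FALSE)
      ago <- read_agonistic_matrix(config$agonistic_csv)
      periods <- sort(unique(rec$period))
      counts <- lapply(periods, function(p)
        build_behavior_matrices(rec, ros$actor, p))
      cv_cols <- setdiff(names(ros), "actor")
      cv <- covariate_table(ros)
      list(scan_counts = counts, roster = ros$actor, covariates = cv,
           agonistic = ago, latent = NULL)
    }
  })
  if (length(inputs$scan_counts) < 2)
    stop("pipeline stage 'binarize' failed: need at least 2 waves of ",
         "scan data", call. = FALSE)

  # ---- binarize
  waves <- stage("binarize", {
    lapply(seq_along(inputs$scan_counts), function(m) {
      cc <- inputs$scan_counts[[m]]
      wn <- binarize_wave(cc$groom, cc$prox1m, cc$prox5m, period = m,
                          min_behaviors = config$mutuality_rule)
      thr <- attr(wn, "thresholds")
      log_line(sprintf("wave %d thresholds: groom=%.3f prox1m=%.3f ",
                       m, thr[["groom"]], thr[["prox1m"]]),
               sprintf("prox5m=%.3f ties=%d", thr[["prox5m"]],
                       sum(wn$adjacency) / 2))
      write_wave_network(
        wn, file.path(config$out_dir, sprintf("wave%02d_adjacency.csv", m)),
        file.path(config$out_dir, sprintf("wave%02d_edges.csv", m)))
      wn
    })
  })

  # ---- dominance ranking
  ranking <- stage("rank", {
    rk <- isi_rank(inputs$agonistic)
    write_ranking(rk, file.path(config$out_dir, "ranking.csv"))
    rk
  })
  # refresh the rank covariate from the recovered hierarchy
  cv <- inputs$covariates
  if ("rank" %in% names(cv)) {
    rk_pos <- match(cv$actor, ranking$order)
    if (!anyNA(rk_pos)) cv$rank <- rk_pos
  }

  # ---- stepwise fit
  sel <- stage("fit", {
    cands <- default_candidates(
      simx_covariates = config$simx_covariates,
      rate_covariates = config$rate_covariates)
    sel <- forward_select(waves, cands, cv, opts = config$estimation)
    write_fit_csv(sel$fit, file.path(config$out_dir, "results.csv"),
                  seed = config$seed)
    write.csv(sel$trace, file.path(config$out_dir, "selection_trace.csv"),
              row.names = FALSE)
    sel
  })

  # ---- goodness of fit
  stage("gof", {
    gof <- mhd_test(sel$fit, waves, cv, n_sims = config$gof_n_sims)
    write.csv(data.frame(statistic = "pooled", MHD = gof$mhd, p = gof$p,
                         n_sims = gof$n_sims, seed = config$seed),
              file.path(config$out_dir, "gof.csv"), row.names = FALSE)
    write.csv(gof_long_table(gof),
              file.path(config$out_dir, "gof_long.csv"), row.names = FALSE)
    log_line(sprintf("gof: MHD=%.2f p=%.3f", gof$mhd, gof$p))
  })
  log_line("done")
  invisible(config$out_dir)
}
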