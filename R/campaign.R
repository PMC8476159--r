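# End-to-end pipeline drivers: simulate -> infer -> posterior predictive
# check -> tree metrics, per grid cell, producing the tabular substrate for
# the power and worth analyses.

#' Campaign configuration
#'
#' Everything needed to run (and re-run, reproducibly) a full
#' simulate/infer/diagnose campaign: the simulation grid, tree, generating
#' parameters, inference settings, replicate counts, convergence thresholds
#' and the master seed (per-cell seeds are derived by counter hashing, so
#' any cell can be regenerated on its own).
#'
#' @param spec A [grid_spec()].
#' @param tree Simulation tree (`ape::phylo`).
#' @param params Generating `"epi_params"` (its `d` is overridden per cell).
#' @param mcmc An [mcmc_config()] for the misspecified GTR+G inference.
#' @param m_reps Posterior predictive replicates per cell.
#' @param alpha Test level for two-tailed significance.
#' @param asdsf_max,psrf_max Convergence thresholds.
#' @return A list of class `"campaign_config"`.
#' @export
campaign_config <- function(spec, tree, params, mcmc = mcmc_config(),
                            m_reps = 100L, alpha = 0.05,
                            asdsf_max = 0.05, psrf_max = 1.1) {
  structure(list(spec = spec, tree = tree, params = params, mcmc = mcmc,
                 m_reps = as.integer(m_reps), alpha = alpha,
                 asdsf_max = asdsf_max, psrf_max = psrf_max),
            class = "campaign_config")
}

#' Analyze one observed alignment
#'
#' The per-cell pipeline: two-chain misspecified GTR+G MCMC, convergence
#' report, posterior predictive check of the three adequacy statistics
#' (replicates drawn from the pooled chains), and accuracy/precision
#' summaries of the pooled posterior tree sample against the true tree.
#'
#' @param aln `"paired_alignment"` (the observed alignment).
#' @param truth True tree.
#' @param config A `"campaign_config"` (its `spec` is unused here).
#' @param seed Integer seed for inference and replicates.
#' @return One-row data.frame of cell results.
#' @export
analyze_alignment <- function(aln, truth, config, seed = 1L) {
  two <- run_two_chains(aln, config$mcmc, seed = derive_seed(seed, 101L),
                        asdsf_max = config$asdsf_max,
                        psrf_max = config$psrf_max)
  pooled <- pool_traces(two$chains)
  pp <- pp_check(aln, pooled, m = config$m_reps, alpha = config$alpha,
                 seed = derive_seed(seed, 202L))
  ps <- posterior_summaries(pooled$trees, truth)
  data.frame(
    d = aln$d, ni = aln$ni, ne = aln$ne, seed = as.integer(seed),
    asdsf = two$report$asdsf, psrf = two$report$psrf,
    converged = two$report$pass,
    obs_g93 = pp$observed[["g93"]], p_g93 = pp$p[["g93"]],
    sig_g93 = pp$significant[["g93"]],
    obs_mimax = pp$observed[["mimax"]], p_mimax = pp$p[["mimax"]],
    sig_mimax = pp$significant[["mimax"]],
    obs_mikurt = pp$observed[["mikurt"]], p_mikurt = pp$p[["mikurt"]],
    sig_mikurt = pp$significant[["mikurt"]],
    rf_mean = ps$accuracy[["rf_mean"]], rf_median = ps$accuracy[["rf_median"]],
    rf_min = ps$accuracy[["rf_min"]], rf_max = ps$accuracy[["rf_max"]],
    mrc_error = ps$accuracy[["mrc_error"]],
    resolution = ps$precision[["resolution"]],
    rf_ci_width = ps$precision[["rf_ci_width"]])
}

#' Pool posterior traces
#'
#' Concatenates the samples of several chains (used after convergence
#' filtering; the retained chains are pooled before summarization).
#'
#' @param chains List of `"posterior_trace"` objects over the same taxa.
#' @return A pooled `"posterior_trace"`.
#' @export
pool_traces <- function(chains) {
  stopifnot(length(chains) >= 1L)
  trees <- do.call(c, lapply(chains, function(x) unclass(x$trees)))
  class(trees) <- "multiPhylo"
  structure(list(trees = trees,
                 pars = do.call(rbind, lapply(chains, `[[`, "pars")),
                 acceptance = chains[[1L]]$acceptance,
                 config = chains[[1L]]$config, seed = chains[[1L]]$seed,
                 taxa = chains[[1L]]$taxa),
            class = "posterior_trace")
}

#' Run a simulation-and-diagnosis campaign
#'
#' Executes the full pipeline for every cell of the grid: simulate the
#' observed alignment, infer under the misspecified site-iid model with two
#' chains, run the posterior predictive check, and summarize tree accuracy
#' and precision.  Per-cell failures are caught, logged and marked with NA
#' rather than aborting the campaign.  If `out_csv` is given the result
#' table is written after every cell and already-completed cells are skipped
#' on re-runs (cells are individually reproducible from the master seed).
#'
#' @param config A `"campaign_config"`.
#' @param out_csv Optional path for incremental results.
#' @param verbose Print one line per cell.
#' @return Data frame with one row per grid cell (see [analyze_alignment()]).
#' @export
run_campaign <- function(config, out_csv = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "campaign_config"))
  cells <- config$spec$cells
  done <- NULL
  if (!is.null(out_csv) && file.exists(out_csv)) {
    done <- utils::read.csv(out_csv)
  }
  rows <- list()
  ctx_cache <- list()
  for (i in seq_len(nrow(cells))) {
    key <- sprintf("%g_%d_%d", cells$d[i], cells$ni[i], cells$ne[i])
    if (!is.null(done) &&
        any(done$d == cells$d[i] & done$ni == cells$ni[i] &
            done$ne == cells$ne[i])) {
      rows[[key]] <- done[done$d == cells$d[i] & done$ni == cells$ni[i] &
                            done$ne == cells$ne[i], , drop = FALSE][1, ]
      next
    }
    dkey <- as.character(cells$d[i])
    if (is.null(ctx_cache[[dkey]])) {
      p <- config$params
      p$d <- cells$d[i]
      ctx_cache[[dkey]] <- simulation_context(config$tree, p, pairs = TRUE)
    }
    row <- tryCatch({
      aln <- simulate_from_context(ctx_cache[[dkey]], cells$ni[i],
                                   cells$ne[i], seed = cells$seed[i])
      analyze_alignment(aln, config$tree, config, seed = cells$seed[i])
    }, error = function(e) {
      warning(sprintf("cell (d=%g, ni=%d, ne=%d) failed: %s",
                      cells$d[i], cells$ni[i], cells$ne[i],
                      conditionMessage(e)))
      out <- data.frame(d = cells$d[i], ni = cells$ni[i], ne = cells$ne[i],
                        seed = cells$seed[i])
      out
    })
    rows[[key]] <- row
    if (verbose)
      cat(sprintf("[%d/%d] d=%g ni=%d ne=%d done\n", i, nrow(cells),
                  cells$d[i], cells$ni[i], cells$ne[i]))
    if (!is.null(out_csv)) {
      tab <- rbind_fill(rows)
      utils::write.csv(tab, out_csv, row.names = FALSE)
    }
  }
  rbind_fill(rows)
}

# rbind data.frames with possibly missing columns (failure rows)
rbind_fill <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  do.call(rbind, lapply(rows, function(r) {
    for (cn in setdiff(cols, names(r))) r[[cn]] <- NA
    r[, cols, drop = FALSE]
  }))
}
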