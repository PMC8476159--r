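# The reduced simulate -> infer -> diagnose campaign shared by the
# pipeline-level acceptance tests.  One fixed design, computed once and
# cached for the whole acceptance file:
#
#   * 12 taxa, well-separated synthetic tree of length 4.58
#   * worth grid: ni, ne in {0, 32, 64, 128} for d in {0.5, 1000}
#     (origin excluded; the d-independent ne = 0 column run once),
#     two chains of 15,000 iterations each, ASDSF/PSRF filtering.
#     The site range 32..256 is where both the accuracy response (mean
#     posterior RF) and the precision response (MRC resolution) retain
#     dynamic range on a 12-taxon tree; larger cells saturate resolution
#     while costing the most inference time.
#   * null strip: 60 purely independent alignments (ne = 0,
#     ni = 20, 22, ..., 138), single chain, no convergence filter,
#     giving the false-positive rate of the posterior predictive tests
#   * 50 posterior predictive replicates per cell at alpha = 0.05

campaign_master_seed <- 20240917L

campaign_tree <- function() synthetic_tree(12, 4.58, seed = 301,
                                           shape = "separated")

campaign_mcmc <- function() mcmc_config(
  n_iter = 15000L, n_samples = 500L, burnin_frac = 0.3,
  move_weights = c(topology = 4, spr = 2, branch = 5, treelength = 2,
                   pi = 1, exch = 1, alpha = 1))

.campaign_cache <- new.env(parent = emptyenv())

reduced_campaign <- function() {
  if (!is.null(.campaign_cache$out)) return(.campaign_cache$out)
  tr <- campaign_tree()
  prm <- stem_params(alpha = 0.45)

  spec <- grid_spec(d_values = c(0.5, 1000),
                    n_values = c(0L, 32L, 64L, 128L),
                    seed = campaign_master_seed)
  # the ne = 0 column is d-independent: run it under one d only
  spec$cells <- spec$cells[!(spec$cells$d == 1000 & spec$cells$ne == 0L), ]
  cfg <- campaign_config(spec, tr, prm, mcmc = campaign_mcmc(),
                         m_reps = 50L, alpha = 0.05)
  worth_cells <- run_campaign(cfg)

  # null strip: data truly from the inference model, single chain
  null_ni <- seq(20L, 138L, by = 2L)
  nctx <- epiworth:::simulation_context(tr, prm, pairs = FALSE)
  ncfg <- mcmc_config(n_iter = 6000L, n_samples = 300L, burnin_frac = 0.3,
                      move_weights = campaign_mcmc()$move_weights)
  nulls <- do.call(rbind, lapply(null_ni, function(ni) {
    sd <- epiworth:::derive_seed(campaign_master_seed, 9L, ni)
    aln <- epiworth:::simulate_from_context(nctx, ni, 0L, seed = sd)
    trace <- run_mcmc(aln, ncfg, seed = epiworth:::derive_seed(sd, 1L))
    pp <- pp_check(aln, trace, m = 50L, alpha = 0.05,
                   seed = epiworth:::derive_seed(sd, 2L))
    data.frame(d = 0.5, ni = ni, ne = 0L, seed = sd,
               asdsf = NA_real_, psrf = NA_real_, converged = NA,
               sig_g93 = pp$significant[["g93"]],
               sig_mimax = pp$significant[["mimax"]],
               sig_mikurt = pp$significant[["mikurt"]])
  }))

  worth_fit_for <- function(dv, col, tf) {
    sub <- worth_cells[worth_cells$converged &
                         (worth_cells$d == dv | worth_cells$ne == 0L), ]
    worth_fit(data.frame(ni = sub$ni, ne = sub$ne, y = sub[[col]]),
              transform = tf, n_knots = 2L)
  }

  .campaign_cache$out <- list(
    tree = tr, cells = worth_cells, nulls = nulls,
    worth_fit_for = worth_fit_for)
  .campaign_cache$out
}
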