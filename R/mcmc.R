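# Metropolis-Hastings sampler for deliberately misspecified site-independent
# GTR+G inference: tree topology (stochastic NNI), branch lengths (single- and
# whole-tree multipliers), exchangeability and base-frequency simplices
# (Dirichlet-centered proposals), and the gamma shape (multiplier).
#
# Priors (RevBayes-conventional defaults): uniform over unrooted topologies,
# iid Exponential(10) branch lengths, flat Dirichlet on both simplices,
# Exponential(1) on alpha.

#' MCMC configuration
#'
#' @param n_iter Total iterations (one single-move update each).
#' @param n_samples Number of retained posterior samples after burn-in.
#' @param burnin_frac Fraction of iterations discarded as burn-in.
#' @param gamma_categories Discrete-gamma categories of the inference model.
#' @param prior_only If `TRUE`, the likelihood is switched off and the
#'   sampler targets the prior (a standard sampler-correctness check).
#' @param bl_rate Exponential prior rate on branch lengths.
#' @param alpha_rate Exponential prior rate on the gamma shape.
#' @param tune_bl,tune_tl,tune_alpha Log-scale window of the multiplier
#'   proposals (branch, tree-length, alpha).
#' @param conc_pi,conc_exch Concentration of the Dirichlet-centered proposals.
#' @param move_weights Relative weights of the move types `topology` (NNI),
#'   `spr`, `branch`, `treelength`, `pi`, `exch`, `alpha`.
#' @return A list of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_iter = 4000L, n_samples = 200L, burnin_frac = 0.25,
                        gamma_categories = 4L, prior_only = FALSE,
                        bl_rate = 10, alpha_rate = 1,
                        tune_bl = 1.2, tune_tl = 0.5, tune_alpha = 0.8,
                        conc_pi = 60, conc_exch = 60,
                        move_weights = c(topology = 3, spr = 1, branch = 4,
                                         treelength = 1, pi = 1, exch = 1,
                                         alpha = 1)) {
  structure(list(n_iter = as.integer(n_iter), n_samples = as.integer(n_samples),
                 burnin_frac = burnin_frac,
                 gamma_categories = as.integer(gamma_categories),
                 prior_only = prior_only, bl_rate = bl_rate,
                 alpha_rate = alpha_rate, tune_bl = tune_bl, tune_tl = tune_tl,
                 tune_alpha = tune_alpha, conc_pi = conc_pi,
                 conc_exch = conc_exch, move_weights = move_weights),
            class = "mcmc_config")
}

rdirichlet1 <- function(a) {
  g <- stats::rgamma(length(a), shape = a, rate = 1)
  g / sum(g)
}

ddirichlet_log <- function(x, a) {
  sum((a - 1) * log(x)) + lgamma(sum(a)) - sum(lgamma(a))
}

# log prior of a sampler state
log_prior <- function(state, config) {
  sum(stats::dexp(state$tree$edge.length, config$bl_rate, log = TRUE)) +
    stats::dexp(state$alpha, config$alpha_rate, log = TRUE)
  # flat Dirichlet terms and the uniform topology prior are constant
}

# log likelihood of the compressed data under the current GTR+G state;
# data$tipL holds precomputed tip partials keyed by taxon label.
# The compiled pruning kernel carries the per-iteration load; set
# engine = "r" to run the reference R implementation instead.
gtr_loglik <- function(state, data, config, engine = "cpp") {
  if (config$prior_only || is.null(data)) return(0)
  Q <- iid_rate_matrix(state$exch, state$pi)
  asrv <- discretize_gamma(state$alpha, config$gamma_categories)
  po <- postorder_edges(state$tree)
  tipL <- data$tipL[po$tree$tip.label]
  if (engine == "cpp") {
    ed <- rate_eigen(Q)
    return(.cpp_pruning_loglik(po$edge, po$len, po$ntip,
                               po$ntip + po$tree$Nnode, po$root, tipL,
                               data$weights, ed$values, ed$right, ed$left,
                               Q$freq, asrv$rates))
  }
  ll <- pattern_logliks(po, NULL, rate_eigen(Q), asrv, Q$freq, tipL = tipL)
  sum(ll * data$weights)
}

# --- proposals: each returns list(state, log_hastings) -----------------------

propose_nni <- function(state, config) {
  tr <- phangorn::rNNI(state$tree, moves = 1L)
  # rNNI can return tip labels reordered; edge lengths travel with edges.
  # Keep the state tree in postorder so the likelihood can skip reordering.
  state$tree <- ape::reorder.phylo(tr, "postorder")
  list(state = state, log_hastings = 0)  # NNI neighborhoods have equal size
}

propose_spr <- function(state, config) {
  # subtree prune-and-regraft: larger topology jumps than NNI, improving
  # mixing on diffuse posteriors; the unrooted SPR neighborhood size is
  # constant for binary trees, so the proposal is symmetric
  tr <- phangorn::rSPR(state$tree, moves = 1L)
  tr$edge.length[is.na(tr$edge.length)] <- stats::rexp(
    sum(is.na(tr$edge.length)), config$bl_rate)
  state$tree <- ape::reorder.phylo(tr, "postorder")
  list(state = state, log_hastings = 0)
}

propose_branch <- function(state, config) {
  e <- sample.int(nrow(state$tree$edge), 1L)
  m <- exp(config$tune_bl * (stats::runif(1L) - 0.5))
  state$tree$edge.length[e] <- state$tree$edge.length[e] * m
  list(state = state, log_hastings = log(m))
}

propose_treelength <- function(state, config) {
  m <- exp(config$tune_tl * (stats::runif(1L) - 0.5))
  state$tree$edge.length <- state$tree$edge.length * m
  list(state = state, log_hastings = nrow(state$tree$edge) * log(m))
}

propose_simplex <- function(x, conc) {
  a_fwd <- conc * x
  x2 <- rdirichlet1(a_fwd)
  x2 <- pmax(x2, 1e-10); x2 <- x2 / sum(x2)
  lh <- ddirichlet_log(x, conc * x2) - ddirichlet_log(x2, a_fwd)
  list(x = x2, log_hastings = lh)
}

propose_pi <- function(state, config) {
  pr <- propose_simplex(state$pi, config$conc_pi)
  state$pi <- pr$x
  list(state = state, log_hastings = pr$log_hastings)
}

propose_exch <- function(state, config) {
  pr <- propose_simplex(state$exch, config$conc_exch)
  state$exch <- pr$x
  list(state = state, log_hastings = pr$log_hastings)
}

propose_alpha <- function(state, config) {
  m <- exp(config$tune_alpha * (stats::runif(1L) - 0.5))
  state$alpha <- state$alpha * m
  list(state = state, log_hastings = log(m))
}

MOVES <- list(topology = propose_nni, spr = propose_spr,
              branch = propose_branch, treelength = propose_treelength,
              pi = propose_pi, exch = propose_exch, alpha = propose_alpha)

#' Run one MCMC chain
#'
#' Samples tree topology, branch lengths, GTR exchangeabilities, base
#' frequencies and the gamma shape for an alignment under the site-iid
#' GTR+G model (one single-parameter-block Metropolis-Hastings update per
#' iteration).  The epistatic structure of the data, if any, is deliberately
#' ignored: this is the misspecified inference model.  Deterministic given
#' `seed`.
#'
#' @param aln A `"paired_alignment"`, character matrix, or `NULL` for a
#'   prior-only run.
#' @param config An [mcmc_config()].
#' @param seed Integer seed.
#' @param taxa Taxon labels (required when `aln` is `NULL`).
#' @return A `"posterior_trace"`: `trees` (multiPhylo of sampled topologies
#'   with branch lengths), `pars` (data.frame of sampled parameters,
#'   tree length and log densities), `acceptance` (per-move rates), `config`,
#'   `seed`.
#' @export
run_mcmc <- function(aln, config = mcmc_config(), seed = 1L, taxa = NULL) {
  data <- NULL
  if (!is.null(aln)) {
    m <- as_char_alignment(aln)
    if (nrow(m) < 4L) stop("need at least 4 taxa for nontrivial topology")
    taxa <- rownames(m)
    if (is.null(taxa)) stop("alignment must have taxon rownames")
    codes <- aln_codes(m)
    cp <- compress_patterns(codes)
    if (ncol(cp$patterns) == 1L)
      warning("alignment has a single site pattern; posterior will track the prior")
    tipL <- tip_partial_list(cp$patterns, 4L)
    names(tipL) <- taxa
    data <- list(weights = cp$weights, tipL = tipL)
  }
  if (is.null(taxa) || length(taxa) < 4L)
    stop("need taxon labels (>= 4) for a prior-only run")
  if (config$prior_only) data <- NULL
  ntaxa <- length(taxa)

  with_seed(seed, {
    state <- list(
      tree = {
        tr <- ape::unroot(ape::rtree(ntaxa, tip.label = sample(taxa)))
        tr$edge.length <- stats::rexp(nrow(tr$edge), config$bl_rate)
        ape::reorder.phylo(tr, "postorder")
      },
      pi = rdirichlet1(rep(1, 4)),
      exch = rdirichlet1(rep(1, 6)),
      alpha = stats::rexp(1L, config$alpha_rate)
    )
    names(state$pi) <- NUC
    names(state$exch) <- EXCH_NAMES
    ll <- gtr_loglik(state, data, config)
    lp <- log_prior(state, config)

    n_iter <- config$n_iter
    burn <- floor(config$burnin_frac * n_iter)
    keep_at <- unique(round(seq(burn + 1L, n_iter,
                                length.out = config$n_samples)))
    wts <- config$move_weights[names(MOVES)]
    wts[is.na(wts)] <- 0  # moves absent from move_weights are disabled
    names(wts) <- names(MOVES)
    att <- acc <- stats::setNames(numeric(length(MOVES)), names(MOVES))

    trees <- vector("list", length(keep_at))
    pars <- vector("list", length(keep_at))
    ki <- 0L
    for (it in seq_len(n_iter)) {
      mv <- sample(names(MOVES), 1L, prob = wts)
      prop <- MOVES[[mv]](state, config)
      ll2 <- gtr_loglik(prop$state, data, config)
      lp2 <- log_prior(prop$state, config)
      att[mv] <- att[mv] + 1
      if (log(stats::runif(1L)) < (ll2 + lp2) - (ll + lp) + prop$log_hastings) {
        state <- prop$state; ll <- ll2; lp <- lp2
        acc[mv] <- acc[mv] + 1
      }
      if (ki < length(keep_at) && it == keep_at[ki + 1L]) {
        ki <- ki + 1L
        trees[[ki]] <- state$tree
        pars[[ki]] <- c(iter = it, lnL = ll, lnPrior = lp,
                        tree_length = sum(state$tree$edge.length),
                        alpha = state$alpha,
                        stats::setNames(state$pi, paste0("pi_", NUC)),
                        stats::setNames(state$exch, paste0("er_", EXCH_NAMES)))
      }
    }
    class(trees) <- "multiPhylo"
    structure(list(trees = trees,
                   pars = as.data.frame(do.call(rbind, pars)),
                   acceptance = ifelse(att > 0, acc / att, NA_real_),
                   config = config, seed = as.integer(seed),
                   taxa = taxa),
              class = "posterior_trace")
  })
}

#' @export
print.posterior_trace <- function(x, ...) {
  cat(sprintf("Posterior trace: %d samples, %d taxa (seed %d)\n",
              length(x$trees), length(x$taxa), x$seed))
  cat("  acceptance:", paste(sprintf("%s=%.2f", names(x$acceptance),
                                     x$acceptance), collapse = " "), "\n")
  invisible(x)
}

#' Run two independent chains with convergence checking
#'
#' The two-chain protocol: independent seeds, then topological convergence is
#' assessed with the average standard deviation of split frequencies (ASDSF)
#' and branch-length convergence with the potential scale reduction factor
#' (PSRF) of the tree-length series.
#'
#' @inheritParams run_mcmc
#' @param asdsf_max,psrf_max Convergence thresholds; an analysis fails if
#'   `ASDSF > asdsf_max` or `PSRF > psrf_max`.
#' @return A list with `chains` (two `"posterior_trace"`s) and `report`
#'   (a `"convergence_report"`).
#' @export
run_two_chains <- function(aln, config = mcmc_config(), seed = 1L,
                           asdsf_max = 0.05, psrf_max = 1.1, taxa = NULL) {
  c1 <- run_mcmc(aln, config, seed = derive_seed(seed, 1L), taxa = taxa)
  c2 <- run_mcmc(aln, config, seed = derive_seed(seed, 2L), taxa = taxa)
  rep <- convergence_report(c1, c2, asdsf_max = asdsf_max, psrf_max = psrf_max)
  list(chains = list(c1, c2), report = rep)
}
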