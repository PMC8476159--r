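# The misspecified GTR+G sampler: determinism, prior-sampling validation,
# detailed-balance of the proposal Hastings ratios, posterior consistency,
# and the ASDSF / PSRF convergence machinery.

test_that("identical seed and config give identical traces", {
  tr <- synthetic_tree(6, 3, seed = 2)
  a <- simulate_alignment(tr, fix_params(d = 0), 60, 0, seed = 5)
  cfg <- mcmc_config(n_iter = 400, n_samples = 40)
  r1 <- run_mcmc(a, cfg, seed = 9)
  r2 <- run_mcmc(a, cfg, seed = 9)
  expect_identical(r1$pars, r2$pars)
  expect_equal(vapply(r1$trees, function(t) sum(t$edge.length), numeric(1)),
               vapply(r2$trees, function(t) sum(t$edge.length), numeric(1)))
  expect_false(identical(r1$pars$lnL, run_mcmc(a, cfg, seed = 10)$pars$lnL))
})

test_that("prior-only sampling reproduces the prior moments", {
  cfg <- mcmc_config(n_iter = 40000, n_samples = 3000, prior_only = TRUE,
                     burnin_frac = 0.2,
                     move_weights = c(topology = 1, branch = 3, treelength = 1,
                                      pi = 3, exch = 3, alpha = 2))
  tr <- run_mcmc(NULL, cfg, seed = 77, taxa = paste0("t", 1:6))
  mc_close <- function(x, target, floor = 0.01) {
    expect_lt(abs(mean(x) - target),
              4 * sd(x) / sqrt(effective_n(x)) + floor)
  }
  # branch lengths iid Exponential(10): mean tree length = n_edges / 10
  mc_close(tr$pars$tree_length, (2 * 6 - 3) / 10)
  # alpha Exponential(1)
  mc_close(tr$pars$alpha, 1, floor = 0.05)
  # base frequencies flat Dirichlet(1,1,1,1): component means 1/4
  for (nm in paste0("pi_", c("A", "C", "G", "T")))
    mc_close(tr$pars[[nm]], 0.25)
  # exchangeabilities flat Dirichlet: component means 1/6
  for (nm in grep("^er_", names(tr$pars), value = TRUE))
    mc_close(tr$pars[[nm]], 1 / 6)
})

test_that("proposal Hastings ratios are correct on frozen states", {
  # multiplier proposals: the log Hastings ratio equals log(multiplier)
  # (and n_edges * log m for the whole-tree scaler); verified by inverting
  # the move: q(x -> y) * HR(x -> y) must equal q(y -> x) in density.
  cfg <- mcmc_config()
  st <- list(tree = tree5(), pi = rep(0.25, 4),
             exch = rep(1 / 6, 6), alpha = 1)
  set.seed(4)
  pr <- epiworth:::propose_branch(st, cfg)
  e_changed <- which(pr$state$tree$edge.length != st$tree$edge.length)
  m <- pr$state$tree$edge.length[e_changed] / st$tree$edge.length[e_changed]
  expect_equal(pr$log_hastings, log(m), tolerance = 1e-12)
  pr2 <- epiworth:::propose_treelength(st, cfg)
  m2 <- sum(pr2$state$tree$edge.length) / sum(st$tree$edge.length)
  expect_equal(pr2$log_hastings, nrow(st$tree$edge) * log(m2),
               tolerance = 1e-9)
  # Dirichlet-centered simplex proposal: HR = dDir(x | c y) - dDir(y | c x)
  set.seed(5)
  prs <- epiworth:::propose_simplex(c(0.4, 0.3, 0.2, 0.1), 150)
  hand <- epiworth:::ddirichlet_log(c(0.4, 0.3, 0.2, 0.1), 150 * prs$x) -
    epiworth:::ddirichlet_log(prs$x, 150 * c(0.4, 0.3, 0.2, 0.1))
  expect_equal(prs$log_hastings, hand, tolerance = 1e-10)
})

test_that("strong signal recovers the true topology and improves with length", {
  # a well-separated topology: every internal edge is long enough to resolve
  tr <- ape::read.tree(text = paste0(
    "((a:0.25,b:0.3):0.2,(c:0.28,d:0.22):0.18,(e:0.3,f:0.26):0.15);"))
  p <- fix_params(d = 0, alpha = 1)
  cfg <- mcmc_config(n_iter = 2500, n_samples = 150)
  rf_at <- function(n, seed) {
    a <- simulate_alignment(tr, p, n, 0, seed = seed)
    res <- run_mcmc(a, cfg, seed = seed + 1)
    ps <- posterior_summaries(res$trees, tr)
    ps$accuracy[["rf_mean"]]
  }
  long <- rf_at(1600, 7)
  short <- rf_at(100, 8)
  expect_lte(long, short + 0.25)   # consistency, with Monte-Carlo slack
  expect_lt(long, 0.5)             # long alignments pin the true topology
})

test_that("ASDSF follows the worked two-chain example and its conventions", {
  x <- ape::read.tree(text = "((a,b),(c,d),e);")
  y <- ape::read.tree(text = "((a,c),(b,d),e);")
  chainX <- rep(list(x), 20)
  chainY <- rep(list(y), 20)
  # no shared nontrivial splits: every qualifying split has frequencies
  # (1, 0); two-point sample sd = 1/sqrt(2)
  expect_equal(asdsf(chainX, chainY), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(asdsf(chainX, chainX), 0)
  # qualification floor: splits below 10% in both chains are ignored
  mixed <- c(rep(list(x), 19), list(y))  # y's splits at 5%
  expect_equal(asdsf(mixed, mixed), 0)
})

test_that("PSRF distinguishes mixed from separated chains", {
  set.seed(6)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(abs(psrf(a, b) - 1), 0.05)
  expect_gt(psrf(rnorm(1000), rnorm(1000, 10)), 1.1)
  expect_warning(p1 <- psrf(rep(2, 50), rep(2, 50)), "degenerate")
  expect_equal(p1, 1)
  expect_error(psrf(1:5, 1:5), "too short")
})

test_that("convergence filtering implements the either/or discard rule", {
  mk <- function(a, p) structure(list(asdsf = a, psrf = p),
                                 class = "convergence_report")
  reports <- list(mk(0.01, 1.01), mk(0.06, 1.0), mk(0.04, 1.2), mk(0.05, 1.1))
  keep <- filter_converged(reports, asdsf_max = 0.05, psrf_max = 1.1)
  expect_identical(keep, c(TRUE, FALSE, FALSE, TRUE))
  # thresholds are configurable (the sensitivity knob)
  expect_identical(filter_converged(reports, 0.10, 1.5), rep(TRUE, 4))
  expect_error(filter_converged(reports, 0, 1.1), "positive")
})

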