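# Pruning likelihoods against brute-force enumeration oracles, pattern-space
# normalization, root invariance and additivity.

test_that("two-taxon column likelihood matches the closed-form sum", {
  tr <- ape::read.tree(text = "(a:0.3,b:0.5);")
  p <- random_params(3)
  Q <- iid_rate_matrix(p$exchangeabilities, p$base_freqs)
  P1 <- transition_probabilities(Q, 0.3)
  P2 <- transition_probabilities(Q, 0.5)
  for (pair in list(c("A", "G"), c("C", "C"), c("T", "A"))) {
    col <- matrix(pair, 2, 1, dimnames = list(c("a", "b"), NULL))
    bf <- log(sum(Q$freq * P1[, pair[1]] * P2[, pair[2]]))
    expect_equal(column_loglik_iid(col, tr, Q), bf, tolerance = 1e-10)
  }
})

test_that("three-taxon likelihoods match brute-force internal-state sums", {
  tr <- tree3()
  p <- random_params(5)
  Q <- iid_rate_matrix(p$exchangeabilities, p$base_freqs)
  P <- lapply(c(a = 0.2, b = 0.4, c = 0.1), function(t)
    transition_probabilities(Q, t))
  col <- matrix(c("G", "T", "A"), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  bf <- log(sum(Q$freq * P$a[, "G"] * P$b[, "T"] * P$c[, "A"]))
  expect_equal(column_loglik_iid(col, tr, Q), bf, tolerance = 1e-10)

  # 16-state version
  Qe <- doublet_rate_matrix(p$exchangeabilities, p$doublet_freqs, p$d)
  Pe <- lapply(c(a = 0.2, b = 0.4, c = 0.1), function(t)
    transition_probabilities(Qe, t))
  dbl <- c(a = "AT", b = "GC", c = "AT")
  bfe <- log(sum(Qe$freq * Pe$a[, dbl["a"]] * Pe$b[, dbl["b"]] *
                   Pe$c[, dbl["c"]]))
  c5 <- matrix(substr(dbl, 1, 1), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  c3 <- matrix(substr(dbl, 2, 2), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(pair_loglik(c5, c3, tr, Qe), bfe, tolerance = 1e-10)
})

test_that("zero-length star tree with identical characters returns the stationary mass", {
  tr <- tree3(); tr$edge.length[] <- 0
  p <- fix_params()
  Q <- iid_rate_matrix(p$exchangeabilities, p$base_freqs)
  col <- matrix("C", 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(exp(column_loglik_iid(col, tr, Q)),
               unname(Q$freq["C"]), tolerance = 1e-12)
  Qe <- doublet_rate_matrix(p$exchangeabilities, p$doublet_freqs, 3)
  expect_equal(exp(pair_loglik(matrix("C", 3, 1, dimnames = list(c("a","b","c"), NULL)),
                               matrix("G", 3, 1, dimnames = list(c("a","b","c"), NULL)),
                               tr, Qe)),
               unname(Qe$freq["CG"]), tolerance = 1e-12)
})

test_that("pattern likelihoods sum to one over the full pattern space (t=3)", {
  tr <- tree3()
  p <- random_params(7)
  asrv <- discretize_gamma(p$alpha, 4)
  Q <- iid_rate_matrix(p$exchangeabilities, p$base_freqs)
  pats <- t(as.matrix(expand.grid(a = NUC, b = NUC, c = NUC,
                                  stringsAsFactors = FALSE)))
  expect_equal(sum(exp(column_loglik_iid(pats, tr, Q, asrv))), 1,
               tolerance = 1e-10)
  Qe <- doublet_rate_matrix(p$exchangeabilities, p$doublet_freqs, p$d)
  ds <- doublet_states()
  idx <- as.matrix(expand.grid(a = 1:16, b = 1:16, c = 1:16))
  c5 <- t(matrix(substr(ds[idx], 1, 1), ncol = 3))
  c3 <- t(matrix(substr(ds[idx], 2, 2), ncol = 3))
  rownames(c5) <- rownames(c3) <- c("a", "b", "c")
  expect_equal(sum(exp(pair_loglik(c5, c3, tr, Qe, asrv))), 1,
               tolerance = 1e-9)
})

test_that("likelihood is invariant to the rooting of a reversible model", {
  p <- random_params(9)
  Q <- iid_rate_matrix(p$exchangeabilities, p$base_freqs)
  asrv <- discretize_gamma(p$alpha, 4)
  tr <- tree5()
  a <- simulate_alignment(tr, p, 30, 0, seed = 6)
  base <- sum(column_loglik_iid(a$aln, tr, Q, asrv))
  for (og in tr$tip.label) {
    rerooted <- ape::unroot(ape::root(tr, outgroup = og, resolve.root = TRUE))
    expect_equal(sum(column_loglik_iid(a$aln, rerooted, Q, asrv)), base,
                 tolerance = 1e-8)
  }
})

test_that("uniform-frequency pair likelihood at d=0 splits into two iid columns", {
  s <- c(1.3, 0.8, 1.1, 0.9, 2.2, 0.7)
  Qe <- doublet_rate_matrix(s, rep(1 / 16, 16), 0)
  Qi <- iid_rate_matrix(s, rep(0.25, 4))
  tr <- tree5()
  set.seed(2)
  c5 <- matrix(sample(NUC, 10, TRUE), 5, 2, dimnames = list(tr$tip.label, NULL))
  c3 <- matrix(sample(NUC, 10, TRUE), 5, 2, dimnames = list(tr$tip.label, NULL))
  expect_equal(pair_loglik(c5, c3, tr, Qe),
               column_loglik_iid(c5, tr, Qi) + column_loglik_iid(c3, tr, Qi),
               tolerance = 1e-9)
})

test_that("alignment likelihood is additive and finite across a parameter sweep", {
  tr <- tree5()
  p <- fix_params(d = 2)
  a <- simulate_alignment(tr, p, 15, 10, seed = 14)
  ll <- alignment_loglik(a, tr, p)
  expect_equal(ll$total, ll$independent + ll$paired)
  Q <- iid_rate_matrix(p$exchangeabilities, p$base_freqs)
  asrv <- discretize_gamma(p$alpha, p$gamma_categories)
  expect_equal(ll$independent,
               sum(column_loglik_iid(a$aln[, a$map$independent + 1], tr, Q,
                                     asrv)))
  # no NaN/-Inf over a wide sweep of d and alpha
  for (d in c(0, 0.5, 8, 1000)) for (al in c(0.1, 1, 10)) {
    p2 <- fix_params(d = d, alpha = al)
    v <- alignment_loglik(a, tr, p2)$total
    expect_true(is.finite(v))
  }
  # ambiguous characters marginalize instead of failing
  a$aln[1, 1] <- "N"; a$aln[2, 3] <- "-"
  expect_true(is.finite(alignment_loglik(a, tr, p)$total))
})

test_that("true parameters dominate perturbed ones on long simulated data", {
  tr <- synthetic_tree(6, 4.58, seed = 30)
  p <- fix_params(d = 2)
  a <- simulate_alignment(tr, p, 1000, 1000, seed = 31)
  ll_true <- alignment_loglik(a, tr, p)$total
  worse <- fix_params(d = 30)        # wrong epistasis strength
  worse$base_freqs <- rep(0.25, 4)   # and wrong frequencies
  ll_bad <- alignment_loglik(a, tr, worse)$total
  expect_gt(ll_true, ll_bad)
  shrunk <- tr; shrunk$edge.length <- shrunk$edge.length * 0.3
  expect_gt(ll_true, alignment_loglik(a, shrunk, p)$total)
})
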