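# Alignment simulator: determinism, degenerate trees, stationarity of
# simulated columns, grid enumeration, and agreement between the
# matrix-exponential and exact (Gillespie) simulators.

test_that("simulation is deterministic and respects basic contracts", {
  tr <- synthetic_tree(6, 3, seed = 5)
  p <- fix_params(d = 2)
  a1 <- simulate_alignment(tr, p, 12, 8, seed = 99)
  a2 <- simulate_alignment(tr, p, 12, 8, seed = 99)
  expect_identical(a1$aln, a2$aln)
  expect_equal(ncol(a1$aln), 20)
  expect_equal(a1$ni, 12); expect_equal(a1$ne, 8)
  expect_true(all(a1$aln %in% c("A", "C", "G", "T")))
  expect_error(simulate_alignment(tr, p, 4, 3, seed = 1), "even")
  expect_error(simulate_alignment(tr, p, -1, 0, seed = 1), "nonnegative")
})

test_that("zero-length branches copy the root state to every taxon", {
  tr <- synthetic_tree(5, 3, seed = 2)
  tr$edge.length[] <- 0
  a <- simulate_alignment(tr, fix_params(d = 8), 6, 4, seed = 3)
  expect_equal(ncol(a$aln), 10)
  for (j in seq_len(ncol(a$aln)))
    expect_length(unique(a$aln[, j]), 1L)
})

test_that("simulated column frequencies converge to the stationary laws", {
  tr <- synthetic_tree(10, 6, seed = 8)
  p <- fix_params(d = 2)
  a <- simulate_alignment(tr, p, 4000, 4000, seed = 17)
  nsamp <- 10 * 4000
  ind <- a$aln[, a$map$independent + 1]
  for (k in seq_along(NUC)) {
    f <- mean(ind == NUC[k])
    se <- sqrt(p$base_freqs[k] * (1 - p$base_freqs[k]) / nsamp)
    # correlated draws along the tree inflate the standard error; the x10
    # factor is a loose envelope that still detects wrong stationary laws
    expect_lt(abs(f - p$base_freqs[k]), 10 * se + 0.01)
  }
  # 5' marginal of the doublet law
  p5 <- rowSums(matrix(p$doublet_freqs, 4, 4, byrow = TRUE))
  fives <- a$aln[, a$map$pairs[, 1] + 1]
  for (k in seq_along(NUC))
    expect_lt(abs(mean(fives == NUC[k]) - p5[k]), 0.02)
})

test_that("grid enumeration matches the published design counts", {
  spec <- grid_spec()  # defaults: 5 d values, 0..400 step 16
  expect_equal(nrow(spec$cells), 3375)
  expect_equal(sum(spec$cells$d == 0.5), 675)
  n <- spec$cells$ni + spec$cells$ne
  expect_equal(range(n), c(16, 800))
  expect_false(any(spec$cells$ni == 0 & spec$cells$ne == 0))
  # toy 2 x 2 grid: 4 cells minus the excluded origin
  spec2 <- grid_spec(d_values = 1, n_values = c(0L, 16L))
  expect_equal(nrow(spec2$cells), 3)
  expect_error(grid_spec(n_values = c(0L, 15L)), "even")
})

test_that("simulate_grid is reproducible and honors the reducer", {
  tr <- synthetic_tree(5, 2, seed = 4)
  spec <- grid_spec(d_values = c(0, 8), n_values = c(0L, 10L), seed = 33)
  g1 <- simulate_grid(spec, tr, fix_params(), fun = g93)
  g2 <- simulate_grid(spec, tr, fix_params())
  expect_equal(unlist(g1$results),
               vapply(g2$results, g93, numeric(1)))
  g3 <- simulate_grid(spec, tr, fix_params())
  expect_identical(lapply(g2$results, `[[`, "aln"),
                   lapply(g3$results, `[[`, "aln"))
})

test_that("event simulation: no doubles at d=0, event rate matches tree length", {
  tr <- synthetic_tree(6, 4, seed = 9)
  ev0 <- simulate_with_events(tr, fix_params(d = 0, alpha = 100), ni = 30,
                              ne = 20, seed = 12)
  expect_equal(sum(ev0$events$double), 0)
  # iid sites: expected events per site equals the tree length
  ev <- simulate_with_events(tr, fix_params(d = 0, alpha = 1000), ni = 400,
                             ne = 0, seed = 13)
  rate <- nrow(ev$events) / 400
  expect_lt(abs(rate - tree_length(tr)) / tree_length(tr), 0.15)
})

test_that("realized double-event fraction matches the analytic p(d)", {
  p <- fix_params(d = 8, alpha = 1000)  # ~constant rates isolate the ratio
  long <- ape::read.tree(text = "(a:4,b:4);")
  ev <- simulate_with_events(long, p, ni = 0, ne = 600, seed = 21)
  pe <- ev$events[ev$events$type == "pair", ]
  phat <- mean(pe$double)
  p_true <- doublet_substitution_fraction(p$exchangeabilities,
                                          p$doublet_freqs, 8)
  se <- sqrt(p_true * (1 - p_true) / nrow(pe))
  expect_lt(abs(phat - p_true), 3 * se)
})

test_that("matrix-exponential and Gillespie simulators agree on end states", {
  # one branch, 4-state chain: chi-square goodness of fit of tip states
  p <- fix_params(d = 0, alpha = 1000)
  br <- ape::read.tree(text = "(a:0.8,b:0.0001);")
  n <- 4000
  a <- simulate_alignment(br, p, n, 0, seed = 41)
  ev <- simulate_with_events(br, p, ni = n, ne = 0, seed = 42)
  # condition on the near-root taxon state, compare the other taxon's law
  ta <- table(factor(a$aln["a", ], NUC))
  tg <- table(factor(NUC[ev$tips_iid[match("a", ev$tip_labels), ]], NUC))
  expect_gt(suppressWarnings(
    chisq.test(rbind(ta, tg))$p.value), 0.001)
})

test_that("rooting is immaterial for simulation distributions (pulley principle)", {
  # same seed protocols on differently-rooted versions of one tree give
  # statistically indistinguishable pattern frequencies
  p <- fix_params(d = 0, alpha = 1000)
  tr <- synthetic_tree(5, 2.5, seed = 77)
  tr2 <- ape::unroot(ape::root(tr, outgroup = tr$tip.label[3],
                               resolve.root = TRUE))
  a1 <- simulate_alignment(tr, p, 3000, 0, seed = 1)
  a2 <- simulate_alignment(tr2, p, 3000, 0, seed = 2)
  f1 <- table(factor(a1$aln["t1", ], NUC))
  f2 <- table(factor(a2$aln["t1", ], NUC))
  expect_gt(suppressWarnings(chisq.test(rbind(f1, f2))$p.value), 0.001)
  # and pairwise identity proportions between two fixed taxa agree
  id1 <- mean(a1$aln["t1", ] == a1$aln["t4", ])
  id2 <- mean(a2$aln["t1", ] == a2$aln["t4", ])
  expect_lt(abs(id1 - id2), 3 * sqrt(0.25 / 3000) * 2)
})
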