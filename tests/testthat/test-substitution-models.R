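# The 4-state GTR generator, the 16-state doublet generator, gamma rate
# discretization, and transition probabilities.

test_that("iid generator matches the defining elements and normalization", {
  # uniform everything: all off-diagonals equal, rows sum to zero
  Q <- iid_rate_matrix(rep(1, 6), rep(0.25, 4))
  off <- Q$Q[row(Q$Q) != col(Q$Q)]
  expect_equal(max(off) - min(off), 0)
  expect_lt(max(abs(rowSums(Q$Q))), 1e-10)

  # hand evaluation: pi = (.4,.3,.2,.1), S = 1 -> Q(A,C)/Q(A,G) = .3/.2
  Q2 <- iid_rate_matrix(rep(1, 6), c(0.4, 0.3, 0.2, 0.1))
  expect_equal(Q2$Q["A", "C"] / Q2$Q["A", "G"], 0.3 / 0.2)

  # expected rate is one substitution per site, for arbitrary valid inputs
  for (seed in 1:5) {
    p <- random_params(seed)
    Q3 <- iid_rate_matrix(p$exchangeabilities, p$base_freqs)
    expect_equal(-sum(Q3$freq * diag(Q3$Q)), 1, tolerance = 1e-10)
    expect_lt(max(abs(Q3$freq %*% Q3$Q)), 1e-8)       # stationarity
    db <- Q3$freq * Q3$Q
    expect_lt(max(abs(db - t(db))), 1e-10)            # detailed balance
  }

  expect_error(iid_rate_matrix(rep(1, 6), c(0.5, 0.5, 0.2, 0.1)), "sum to 1")
  expect_error(iid_rate_matrix(c(-1, 1, 1, 1, 1, 1), rep(0.25, 4)), "positive")
})

test_that("doublet generator implements single, double and forbidden entries", {
  s <- 1.7; d <- 2.5
  Q <- doublet_rate_matrix(rep(s, 6), rep(1 / 16, 16), d)
  st <- doublet_states()
  # hand evaluation: rate(AT -> TA) / rate(AT -> CT) = s * d
  expect_equal(Q$Q["AT", "TA"] / Q$Q["AT", "CT"], s * d)
  # non-Watson-Crick double changes are forbidden
  expect_equal(Q$Q["AA", "CC"], 0)
  expect_equal(Q$Q["AT", "GG"], 0)
  # d = 0 kills every double change
  Q0 <- doublet_rate_matrix(rep(1, 6), rep(1 / 16, 16), 0)
  i1 <- substr(st, 1, 1)[row(Q0$Q)]; i2 <- substr(st, 2, 2)[row(Q0$Q)]
  j1 <- substr(st, 1, 1)[col(Q0$Q)]; j2 <- substr(st, 2, 2)[col(Q0$Q)]
  expect_true(all(Q0$Q[i1 != j1 & i2 != j2] == 0))

  for (seed in 1:5) {
    p <- random_params(seed)
    Qe <- doublet_rate_matrix(p$exchangeabilities, p$doublet_freqs, p$d)
    expect_lt(max(abs(rowSums(Qe$Q))), 1e-10)
    expect_true(all(Qe$Q[row(Qe$Q) != col(Qe$Q)] >= 0))
    db <- Qe$freq * Qe$Q
    expect_lt(max(abs(db - t(db))), 1e-10)            # reversibility
    expect_lt(max(abs(Qe$freq %*% Qe$Q)), 1e-8)
  }
})

test_that("site-change and event normalizations differ as expected", {
  p <- fix_params(d = 4)
  Qs <- doublet_rate_matrix(p$exchangeabilities, p$doublet_freqs, 4,
                            normalization = "site")
  Qe <- doublet_rate_matrix(p$exchangeabilities, p$doublet_freqs, 4,
                            normalization = "event")
  # site normalization: singles + 2 * doubles = 2 per pair
  flux <- function(Q) {
    f <- Q$freq * Q$Q; diag(f) <- 0
    c(s = sum(f[!Q$double]), d = sum(f[Q$double]))
  }
  fs <- flux(Qs); fe <- flux(Qe)
  expect_equal(unname(fs["s"] + 2 * fs["d"]), 2, tolerance = 1e-10)
  expect_equal(unname(fe["s"] + fe["d"]), 2, tolerance = 1e-10)
  # at d = 0 they coincide
  expect_equal(
    doublet_rate_matrix(p$exchangeabilities, p$doublet_freqs, 0, "site")$Q,
    doublet_rate_matrix(p$exchangeabilities, p$doublet_freqs, 0, "event")$Q)
})

test_that("doublet substitution fraction is 0 at d=0, sigmoid in log d, and -> 1", {
  p <- fix_params()
  pfrac <- function(d) doublet_substitution_fraction(p$exchangeabilities,
                                                     p$doublet_freqs, d)
  expect_identical(pfrac(0), 0)
  # strictly increasing in d
  ds <- c(0.1, 0.5, 2, 8, 50, 1000)
  ps <- vapply(ds, pfrac, numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_gt(doublet_substitution_fraction(rep(1, 6), rep(1 / 16, 16), 1e6),
            0.999)
  # p = k d / (k d + 1): logit(p) is linear in log d (sigmoid property)
  lg <- log(ps / (1 - ps)) - log(ds)
  expect_lt(max(lg) - min(lg), 1e-8)
})

test_that("calibrated stem parameters reproduce the printed doublet fractions", {
  p <- fix_params()
  pfrac <- function(d) doublet_substitution_fraction(p$exchangeabilities,
                                                     p$doublet_freqs, d)
  expect_equal(pfrac(0.5), 0.112, tolerance = 1e-3)
  expect_equal(pfrac(2), 0.336, tolerance = 2e-3)
  expect_equal(pfrac(8), 0.669, tolerance = 1e-3)
  expect_equal(pfrac(1000), 0.996, tolerance = 1e-3)
})

test_that("gamma discretization has mean-one nondecreasing categories", {
  expect_equal(discretize_gamma(0.73, 1)$rates, 1)
  # large alpha concentrates at the mean
  expect_lt(max(abs(discretize_gamma(5000, 4)$rates - 1)), 0.05)
  # alpha = 0.5, K = 4 vs direct numerical integration of the category means
  alpha <- 0.5; K <- 4
  g <- discretize_gamma(alpha, K)
  q <- qgamma(seq(0, 1, length.out = K + 1), alpha, rate = alpha)
  oracle <- vapply(seq_len(K), function(j)
    integrate(function(x) x * dgamma(x, alpha, rate = alpha),
              q[j], q[j + 1])$value * K, numeric(1))
  expect_equal(g$rates, oracle, tolerance = 1e-6)
  expect_true(all(diff(g$rates) > 0))
  expect_equal(mean(g$rates), 1, tolerance = 1e-12)
  expect_error(discretize_gamma(-1, 4), "positive")
})

test_that("transition probabilities are stochastic and match limits", {
  p <- random_params(11)
  Q <- iid_rate_matrix(p$exchangeabilities, p$base_freqs)
  expect_equal(transition_probabilities(Q, 0), diag(4),
               ignore_attr = TRUE, tolerance = 1e-12)
  # long branch: every row approaches the stationary distribution
  Pinf <- transition_probabilities(Q, 500)
  expect_lt(max(abs(sweep(Pinf, 2, Q$freq))), 1e-8)
  # small t: P = I + Qt + O(t^2) against the truncated series
  t0 <- 1e-4
  P <- transition_probabilities(Q, t0)
  expect_lt(max(abs(P - (diag(4) + Q$Q * t0))), 10 * t0^2)
  # rows sum to one for the 16-state generator too
  Qe <- doublet_rate_matrix(p$exchangeabilities, p$doublet_freqs, p$d)
  Pe <- transition_probabilities(Qe, 0.37, rate = 1.4)
  expect_lt(max(abs(rowSums(Pe) - 1)), 1e-10)
  expect_true(all(Pe >= 0 & Pe <= 1))
  expect_error(transition_probabilities(Q, -1), "nonnegative")
})

test_that("uniform-frequency doublet chain at d=0 is the product of two GTR chains", {
  s <- c(1.2, 0.7, 1.5, 0.9, 2.1, 0.8)
  Qe <- doublet_rate_matrix(s, rep(1 / 16, 16), 0)
  Qi <- iid_rate_matrix(s, rep(0.25, 4))
  for (tt in c(0.05, 0.4, 2)) {
    P4 <- transition_probabilities(Qi, tt)
    P16 <- transition_probabilities(Qe, tt)
    expect_equal(unname(P16), unname(kronecker(P4, P4)), tolerance = 1e-9)
  }
})

test_that("collapse at d=0 with product frequencies is only approximate when frequencies are non-uniform", {
  # single-site rates under the doublet model carry a partner-frequency
  # factor, so the 16-state chain at d=0 with pie = pi (x) pi is NOT the
  # exact product of two iid chains unless pi is uniform
  pi <- c(0.4, 0.3, 0.2, 0.1)
  s <- rep(1, 6)
  pie <- as.vector(t(outer(pi, pi)))
  Qe <- doublet_rate_matrix(s, pie, 0)
  Qi <- iid_rate_matrix(s, pi)
  dev_at <- function(tt) max(abs(
    transition_probabilities(Qe, tt) -
      kronecker(transition_probabilities(Qi, tt),
                transition_probabilities(Qi, tt))))
  expect_gt(dev_at(0.3), 1e-3)           # a real, documented deviation
  expect_lt(dev_at(0.003), dev_at(0.3))  # vanishing with branch length
})
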