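# Shared fixtures, built in code.

fix_params <- function(d = 0, alpha = 0.45, K = 4L)
  stem_params(d = d, alpha = alpha, gamma_categories = K)

# a small asymmetric but valid parameter set for property tests
random_params <- function(seed, d = stats::runif(1, 0, 5)) {
  with_fixed_seed(seed, {
    s <- stats::rgamma(6, 2, 1)
    pi <- as.numeric(stats::rgamma(4, 5, 1)); pi <- pi / sum(pi)
    pie <- as.numeric(stats::rgamma(16, 5, 1)); pie <- pie / sum(pie)
    model_params(s, pi, pie, d = d, alpha = stats::runif(1, 0.2, 2))
  })
}

with_fixed_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

tree5 <- function() ape::read.tree(
  text = "((a:0.12,b:0.3):0.08,(c:0.25,d:0.06):0.11,e:0.2);")

tree3 <- function() ape::read.tree(text = "(a:0.2,b:0.4,c:0.1);")

# all 15 unrooted binary topologies on 5 taxa, with unit branch lengths
all_topologies5 <- function() {
  trs <- phangorn::allTrees(5, rooted = FALSE, tip.label = paste0("t", 1:5))
  lapply(trs, function(t) {
    t$edge.length <- rep(0.1, nrow(t$edge))
    t
  })
}

effective_n <- function(x) {
  # crude ESS from lag-1 autocorrelation, for Monte-Carlo error envelopes
  r <- suppressWarnings(stats::cor(x[-1], x[-length(x)]))
  if (!is.finite(r) || r < 0) return(length(x))
  length(x) * (1 - r) / (1 + r)
}

# synthetic worth-regression dataset on the published grid geometry
synthetic_worth_data <- function(r, noise = 0.02, seed = 1,
                                 n_values = seq(0, 400, 16)) {
  cells <- expand.grid(ni = n_values, ne = n_values)
  cells <- cells[!(cells$ni == 0 & cells$ne == 0), ]
  neff <- cells$ni + r * cells$ne
  set.seed(seed)
  # an error-like response (like mean posterior RF): decreasing in neff
  y <- 10 * exp(-neff / 150) + rnorm(nrow(cells), 0, noise)
  data.frame(ni = cells$ni, ne = cells$ne, y = pmax(y, 0))
}
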