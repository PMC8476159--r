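# Rate matrices for the site-independent GTR model (4 states) and the
# epistatic doublet model (16 states), plus discrete-gamma rate variation
# and transition probabilities.

exch_matrix <- function(s) {
  s <- check_exchangeabilities(s)
  S <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  S["A", "C"] <- s["AC"]; S["A", "G"] <- s["AG"]; S["A", "T"] <- s["AT"]
  S["C", "G"] <- s["CG"]; S["C", "T"] <- s["CT"]; S["G", "T"] <- s["GT"]
  S + t(S)
}

new_rate_matrix <- function(Q, freq, scaling) {
  structure(list(Q = Q, freq = freq, scaling = scaling),
            class = "epi_rate_matrix")
}

#' @export
print.epi_rate_matrix <- function(x, ...) {
  cat(sprintf("%d-state reversible rate matrix (scaling %.6g)\n",
              nrow(x$Q), x$scaling))
  print(round(x$Q, 4))
  invisible(x)
}

#' Site-independent GTR rate matrix
#'
#' Builds the 4x4 generator with off-diagonal entries
#' `Q[x, y] = nu * pi[y] * S[x, y]`, diagonal set to minus the row sum, and
#' the scaling factor `nu` chosen so that the expected substitution rate at
#' stationarity, `-sum(pi * diag(Q))`, equals one substitution per site.
#'
#' @param exchangeabilities Six positive GTR exchange rates
#'   (order AC, AG, AT, CG, CT, GT).
#' @param base_freqs Nucleotide stationary frequencies (A, C, G, T).
#' @return An `"epi_rate_matrix"` with elements `Q` (the generator), `freq`
#'   (the stationary distribution) and `scaling` (`nu`).
#' @export
iid_rate_matrix <- function(exchangeabilities, base_freqs) {
  S <- exch_matrix(exchangeabilities)
  pi <- stats::setNames(check_simplex(base_freqs, 4L, "base_freqs"), NUC)
  Q <- S * rep(pi, each = 4L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  nu <- 1 / sum(pi * -diag(Q))
  new_rate_matrix(Q * nu, pi, nu)
}

#' Epistatic doublet rate matrix
#'
#' Builds the 16x16 generator of the doublet model on the lexicographic state
#' space of [doublet_states()].  Off-diagonal rates from doublet
#' `x = (x1, x2)` to `y = (y1, y2)` are
#' `pie[y] * S[x1, y1]` (single change at the 5' site),
#' `pie[y] * S[x2, y2]` (single change at the 3' site),
#' `pie[y] * S[x1, y1] * S[x2, y2] * d` when both sites change and both `x`
#' and `y` are Watson-Crick doublets, and zero for any other double change.
#'
#' The scaling factor `xi` normalizes the generator for branch-length
#' comparability with independent sites.  With
#' `normalization = "site"` (the default) `xi` is chosen so the expected
#' number of *site* changes per single site is one, counting a double
#' substitution as two site changes across the two sites of the pair, i.e.
#' `(r_s + 2 r_d) / 2 = 1` at stationarity.  With `normalization = "event"`
#' the expected number of substitution *events* per pair is two
#' (`r_s + r_d = 2`), counting a double substitution as a single event.
#'
#' @param exchangeabilities Six positive GTR exchange rates shared with the
#'   independent sites.
#' @param doublet_freqs Stationary frequencies of the 16 ordered doublets.
#' @param d Nonnegative relative rate of double to single substitutions.
#' @param normalization `"site"` or `"event"`; see Details.
#' @return An `"epi_rate_matrix"` with `Q`, `freq` and `scaling` (`xi`),
#'   plus a logical matrix `double` marking double-substitution entries.
#' @export
doublet_rate_matrix <- function(exchangeabilities, doublet_freqs, d,
                                normalization = c("site", "event")) {
  normalization <- match.arg(normalization)
  if (!is.finite(d) || d < 0) stop("d must be finite and nonnegative")
  S <- exch_matrix(exchangeabilities)
  states <- doublet_states()
  pie <- stats::setNames(check_simplex(doublet_freqs, 16L, "doublet_freqs"), states)
  i1 <- rep(1:4, each = 4L)   # 5' nucleotide index of each doublet
  i2 <- rep(1:4, times = 4L)  # 3' nucleotide index
  wc <- states %in% watson_crick_set()

  Q <- matrix(0, 16, 16, dimnames = list(states, states))
  dbl <- matrix(FALSE, 16, 16, dimnames = list(states, states))
  for (x in 1:16) for (y in 1:16) {
    if (x == y) next
    c5 <- i1[x] != i1[y]
    c3 <- i2[x] != i2[y]
    if (c5 && c3) {
      if (wc[x] && wc[y]) {
        Q[x, y] <- pie[y] * S[i1[x], i1[y]] * S[i2[x], i2[y]] * d
        dbl[x, y] <- TRUE
      }
    } else if (c5) {
      Q[x, y] <- pie[y] * S[i1[x], i1[y]]
    } else {
      Q[x, y] <- pie[y] * S[i2[x], i2[y]]
    }
  }
  flux <- pie * Q  # pie[x] * Q[x, y], x in rows
  rd <- sum(flux[dbl])
  rs <- sum(flux) - rd
  xi <- if (normalization == "site") 2 / (rs + 2 * rd) else 2 / (rs + rd)
  Q <- Q * xi
  diag(Q) <- -rowSums(Q)
  out <- new_rate_matrix(Q, pie, xi)
  out$double <- dbl
  out
}

#' Expected doublet-substitution fraction
#'
#' The expected fraction p of substitution events at a pair of epistatic
#' sites that are double (both-site) substitutions, `p = rd / (rd + rs)`,
#' where `rd` sums the stationary flux `pie[x] * Q[x, y]` over
#' double-substitution entries and `rs` over single-substitution entries.
#' The normalization factor xi cancels in the ratio, so p depends only on
#' the exchangeabilities, the doublet frequencies and d.  At `d = 0`, p = 0;
#' p is increasing in d and tends to 1 as d grows; as a function of log d it
#' is a sigmoid.
#'
#' @inheritParams doublet_rate_matrix
#' @return A probability in `[0, 1]`.
#' @export
doublet_substitution_fraction <- function(exchangeabilities, doublet_freqs, d) {
  M <- doublet_rate_matrix(exchangeabilities, doublet_freqs, d)
  flux <- M$freq * M$Q
  diag(flux) <- 0
  rd <- sum(flux[M$double])
  rs <- sum(flux) - rd
  rd / (rd + rs)
}

#' Discrete-gamma rate categories
#'
#' Discretizes the mean-one gamma distribution with shape (and rate) `alpha`
#' into `K` equal-probability categories, each represented by its conditional
#' mean.  The category means average exactly to one.
#'
#' @param alpha Positive gamma shape.
#' @param K Number of categories (>= 1).
#' @return A list of class `"epi_asrv"` with `alpha`, `K` and `rates`
#'   (nondecreasing multipliers of mean 1).
#' @export
discretize_gamma <- function(alpha, K = 4L) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K == 1L) {
    rates <- 1
  } else {
    # conditional mean of Gamma(alpha, alpha) on each inter-quantile slab:
    # E[X | q_{j-1} < X <= q_j] * (1/K) = F_{alpha+1}(q_j) - F_{alpha+1}(q_{j-1})
    q <- stats::qgamma(seq(0, 1, length.out = K + 1L), shape = alpha, rate = alpha)
    cdf1 <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
    rates <- diff(cdf1) * K
    rates <- rates / mean(rates)
  }
  structure(list(alpha = alpha, K = K, rates = rates), class = "epi_asrv")
}

#' Transition probability matrix
#'
#' Computes `P = exp(Q * t * rate)` for a reversible generator.  The
#' exponential uses the eigendecomposition of the symmetrized generator
#' `diag(sqrt(pi)) Q diag(1/sqrt(pi))`, which is numerically stable for
#' reversible chains; non-reversible generators fall back to a dense scaling
#' and squaring via `Matrix`-free Pade-like series is not needed here because
#' all model generators are reversible.
#'
#' @param Q An `"epi_rate_matrix"` (or a plain generator matrix together with
#'   its stationary `freq` attribute).
#' @param t Branch length, expected substitutions per site; `t >= 0`.
#' @param rate Nonnegative rate multiplier (e.g. a gamma category rate).
#' @return A stochastic matrix of the same dimension as `Q`.
#' @export
transition_probabilities <- function(Q, t, rate = 1) {
  if (!is.finite(t) || t < 0) stop("branch length t must be nonnegative")
  if (!is.finite(rate) || rate < 0) stop("rate must be nonnegative")
  ed <- rate_eigen(Q)
  prob_from_eigen(ed, t * rate)
}

# Eigendecomposition of a reversible generator, reusable across branch lengths.
rate_eigen <- function(Q) {
  if (inherits(Q, "epi_rate_matrix")) {
    pi <- Q$freq
    Qm <- Q$Q
  } else stop("Q must be an epi_rate_matrix")
  sp <- sqrt(pi)
  B <- Qm * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2  # symmetric up to round-off for reversible Q
  ed <- eigen(B, symmetric = TRUE)
  list(values = ed$values,
       right = ed$vectors / sp,     # rows scaled:  diag(1/sp) %*% U
       left = t(ed$vectors * sp),   # t(diag(sp) %*% U)
       dim = nrow(Qm), states = rownames(Qm))
}

prob_from_eigen <- function(ed, tt) {
  P <- ed$right %*% (exp(ed$values * tt) * ed$left)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(ed$states, ed$states)
  P
}
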