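# Felsenstein pruning likelihoods under the 4-state GTR+G model and the
# 16-state doublet model, with per-pattern log scaling for long trees.
# Natural-log convention throughout.

# Compile an alignment (integer codes, NA = fully ambiguous) into unique
# patterns with weights.  codes: taxa x columns.
compress_patterns <- function(codes) {
  key <- apply(codes, 2L, paste, collapse = ".")
  f <- factor(key, levels = unique(key))
  w <- tabulate(f)
  list(patterns = codes[, !duplicated(key), drop = FALSE], weights = w,
       index = as.integer(f))
}

# Tip partial likelihood vectors for `nstate` states.  `state_of_tip` is an
# integer matrix (tips x patterns); NA marginalizes over all states.
tip_partials <- function(states, nstate) {
  L <- matrix(0, nstate, length(states))
  ok <- !is.na(states)
  L[cbind(states[ok], which(ok))] <- 1
  L[, !ok] <- 1
  L
}

# Tip partial-likelihood matrices for a pattern block, one per tip row.
tip_partial_list <- function(patterns, nstate) {
  lapply(seq_len(nrow(patterns)), function(i)
    tip_partials(patterns[i, ], nstate))
}

# Pruning over compressed patterns for one rate multiplier.  `tipL` is a
# list of nstate x npat tip partial matrices indexed like po's tips.
# Returns list(site_lik, log_scale): column likelihood =
# site_lik * exp(log_scale).
prune_once <- function(po, tipL, ed, rate, freq) {
  nstate <- length(freq)
  npat <- ncol(tipL[[1L]])
  ntip <- po$ntip
  nnode <- ntip + po$tree$Nnode
  partial <- vector("list", nnode)
  partial[seq_len(ntip)] <- tipL
  logscale <- rep(0, npat)
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; child <- po$edge[e, 2L]
    contrib <- prob_from_eigen(ed, po$len[e] * rate) %*% partial[[child]]
    pp <- if (is.null(partial[[par]])) contrib else partial[[par]] * contrib
    # cheap underflow guard: column sums bound the column max within nstate x
    cs <- .colSums(pp, nstate, npat)
    small <- cs < 1e-180
    if (any(small)) {
      sc <- cs[small]
      sc[sc <= 0] <- 1
      pp[, small] <- pp[, small, drop = FALSE] / rep(sc, each = nstate)
      logscale[small] <- logscale[small] + log(sc)
    }
    partial[[par]] <- pp
  }
  root <- partial[[po$root]]
  list(site_lik = as.vector(freq %*% root), log_scale = logscale)
}

# ASRV-averaged per-pattern log-likelihoods.
pattern_logliks <- function(po, patterns, ed, asrv, freq,
                            tipL = tip_partial_list(patterns, length(freq))) {
  npat <- ncol(tipL[[1L]])
  acc <- matrix(0, asrv$K, npat)
  sc <- matrix(0, asrv$K, npat)
  for (k in seq_len(asrv$K)) {
    pr <- prune_once(po, tipL, ed, asrv$rates[k], freq)
    acc[k, ] <- pr$site_lik
    sc[k, ] <- pr$log_scale
  }
  # log(mean_k lik_k * exp(sc_k)) computed stably
  lg <- log(pmax(acc, .Machine$double.xmin)) + sc
  mx <- apply(lg, 2L, max)
  mx + log(colMeans(exp(sweep(lg, 2L, mx))))
}

#' Log-likelihood of independent alignment columns
#'
#' ASRV-averaged Felsenstein pruning log-likelihood of one or more 4-state
#' columns under a GTR+G model.  The likelihood is invariant to where the
#' (reversible) model is rooted.  Characters outside A/C/G/T are treated as
#' fully ambiguous (marginalized).
#'
#' @param columns Character matrix (taxa x columns) or vector (one column);
#'   row order must match `tree$tip.label`.
#' @param tree `ape::phylo` with branch lengths.
#' @param Q An `"epi_rate_matrix"` from [iid_rate_matrix()].
#' @param asrv An `"epi_asrv"` from [discretize_gamma()].
#' @return Numeric vector of per-column log-likelihoods (nats).
#' @export
column_loglik_iid <- function(columns, tree, Q, asrv = discretize_gamma(1, 1)) {
  if (!is.matrix(columns)) columns <- matrix(columns, ncol = 1L)
  po <- postorder_edges(tree)
  columns <- columns[match(po$tree$tip.label, rownames(columns) %||%
                             po$tree$tip.label), , drop = FALSE]
  if (nrow(columns) != po$ntip) stop("column length must equal taxon count")
  codes <- aln_codes(columns)
  cp <- compress_patterns(codes)
  ll <- pattern_logliks(po, cp$patterns, rate_eigen(Q), asrv, Q$freq)
  ll[cp$index]
}

#' Log-likelihood of epistatic column pairs
#'
#' Pruning log-likelihood of column pairs under the 16-state doublet model;
#' each leaf doublet is the ordered pair of observed nucleotides at the
#' pair's (5', 3') columns.  One gamma rate multiplier applies to the pair
#' as a unit.
#'
#' @param col5,col3 Character matrices (taxa x pairs) or vectors giving the
#'   5' and 3' member columns of each pair.
#' @param tree `ape::phylo` with branch lengths.
#' @param Q An `"epi_rate_matrix"` from [doublet_rate_matrix()].
#' @param asrv An `"epi_asrv"`.
#' @return Numeric vector of per-pair log-likelihoods (nats).
#' @export
pair_loglik <- function(col5, col3, tree, Q, asrv = discretize_gamma(1, 1)) {
  if (!is.matrix(col5)) col5 <- matrix(col5, ncol = 1L)
  if (!is.matrix(col3)) col3 <- matrix(col3, ncol = 1L)
  po <- postorder_edges(tree)
  ord <- match(po$tree$tip.label, rownames(col5) %||% po$tree$tip.label)
  col5 <- col5[ord, , drop = FALSE]; col3 <- col3[ord, , drop = FALSE]
  if (nrow(col5) != po$ntip) stop("column length must equal taxon count")
  c5 <- aln_codes(col5); c3 <- aln_codes(col3)
  codes <- (c5 - 1L) * 4L + c3  # lexicographic doublet index, NA propagates
  cp <- compress_patterns(codes)
  ll <- pattern_logliks(po, cp$patterns, rate_eigen(Q), asrv, Q$freq)
  ll[cp$index]
}

#' Factorized log-likelihood of a paired alignment
#'
#' Total log-likelihood of a `"paired_alignment"` under the generating
#' model: independent columns contribute GTR+G pruning likelihoods, column
#' pairs contribute doublet-model pruning likelihoods, and the total is the
#' sum (the only site-to-site dependencies are those inside a pair).
#'
#' @param aln A `"paired_alignment"` (alignment plus pairing map).
#' @param tree `ape::phylo` with branch lengths.
#' @param params An `"epi_params"`.
#' @return A list with `total`, `independent` and `paired` log-likelihood
#'   components (nats).
#' @export
alignment_loglik <- function(aln, tree, params) {
  stopifnot(inherits(aln, "paired_alignment"), inherits(params, "epi_params"))
  map <- aln$map
  if (max(c(map$independent, map$pairs, -1L)) + 1L > ncol(aln$aln))
    stop("pairing map indices exceed alignment width")
  asrv <- discretize_gamma(params$alpha, params$gamma_categories)
  ll_i <- 0
  if (length(map$independent)) {
    Qi <- iid_rate_matrix(params$exchangeabilities, params$base_freqs)
    ll_i <- sum(column_loglik_iid(aln$aln[, map$independent + 1L, drop = FALSE],
                                  tree, Qi, asrv))
  }
  ll_e <- 0
  if (nrow(map$pairs)) {
    Qe <- doublet_rate_matrix(params$exchangeabilities, params$doublet_freqs,
                              params$d)
    ll_e <- sum(pair_loglik(aln$aln[, map$pairs[, 1L] + 1L, drop = FALSE],
                            aln$aln[, map$pairs[, 2L] + 1L, drop = FALSE],
                            tree, Qe, asrv))
  }
  list(total = ll_i + ll_e, independent = ll_i, paired = ll_e)
}
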