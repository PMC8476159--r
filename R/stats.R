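# Alignment-only test statistics for adequacy checking: the multinomial
# likelihood statistic (G93) and the pairwise mutual-information family.

as_char_alignment <- function(aln) {
  if (inherits(aln, "paired_alignment")) aln <- aln$aln
  if (!is.matrix(aln) || !is.character(aln))
    stop("alignment must be a character matrix (taxa x columns)")
  aln
}

#' Multinomial likelihood statistic (G93)
#'
#' Treats the alignment as n draws from a multinomial distribution on site
#' patterns, plugs in the maximum-likelihood pattern probabilities
#' `s_i / n`, and returns the log-likelihood
#' `L = sum_i s_i log(s_i) - n log(n)` in nats.  L is 0 when all columns
#' share one pattern and `-n log n` when all patterns are distinct; it is a
#' general-purpose diagnostic for substitution-model misspecification and is
#' strongly (negatively) driven by alignment length.
#'
#' @param aln A `"paired_alignment"` or a character matrix (taxa x columns).
#' @return Scalar statistic in nats.
#' @export
g93 <- function(aln) {
  m <- as_char_alignment(aln)
  n <- ncol(m)
  if (n < 1L) stop("alignment has no columns")
  pat <- apply(m, 2L, paste0, collapse = "")
  s <- tabulate(factor(pat))
  sum(s * log(s)) - n * log(n)
}

# integer-coded copy of the alignment (A=1, C=2, G=3, T=4); other symbols NA
aln_codes <- function(m) {
  codes <- match(m, NUC)
  dim(codes) <- dim(m)
  codes
}

#' Pairwise mutual information matrix
#'
#' Mutual information between every pair of alignment columns, computed from
#' empirical (relative) character frequencies over taxa in nats, with the
#' convention `0 log 0 = 0`.  `MI[i, j] <= min(H(i), H(j))`.  Characters
#' outside A/C/G/T (gaps, ambiguities: possible in user data, never in
#' simulated data) are dropped pairwise-complete per column pair.
#'
#' @param aln A `"paired_alignment"` or character matrix.
#' @return Symmetric n x n matrix with zero diagonal.
#' @export
mi_matrix <- function(aln) {
  m <- as_char_alignment(aln)
  n <- ncol(m)
  if (n < 2L) stop("mutual information needs at least 2 columns")
  codes <- aln_codes(m)
  if (anyNA(codes)) return(mi_matrix_slow(codes))
  t_ <- nrow(m)
  ind <- lapply(1:4, function(a) (codes == a) * 1)
  # joint counts for all column pairs at once: t(Ia) %*% Ib
  MI <- matrix(0, n, n)
  marg <- vapply(ind, colSums, numeric(n)) / t_  # n x 4 marginal freqs
  for (a in 1:4) {
    for (b in 1:4) {
      F <- crossprod(ind[[a]], ind[[b]]) / t_      # f_ij(a, b), n x n
      E <- marg[, a] %o% marg[, b]                 # f_i(a) f_j(b)
      nz <- F > 0
      MI[nz] <- MI[nz] + F[nz] * log(F[nz] / E[nz])
    }
  }
  diag(MI) <- 0
  MI[MI < 0] <- 0  # clip tiny negative round-off
  MI
}

# pairwise-complete fallback for alignments containing gaps/ambiguities
mi_matrix_slow <- function(codes) {
  n <- ncol(codes)
  MI <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(codes[, i]) & !is.na(codes[, j])
    if (sum(ok) < 2L) next
    F <- table(factor(codes[ok, i], 1:4), factor(codes[ok, j], 1:4)) / sum(ok)
    fa <- rowSums(F); fb <- colSums(F)
    E <- fa %o% fb
    nz <- F > 0
    MI[i, j] <- MI[j, i] <- sum(F[nz] * log(F[nz] / E[nz]))
  }
  MI[MI < 0] <- 0
  MI
}

upper_mi <- function(aln) {
  MI <- if (is.matrix(aln) && is.numeric(aln) && isSymmetric(unname(aln)))
    aln else mi_matrix(aln)
  MI[upper.tri(MI)]
}

#' Maximum pairwise mutual information (MImax)
#'
#' The maximum over all column pairs of the pairwise mutual information.
#' Epistatic coupling inflates the upper tail of the MI distribution, so the
#' maximum is sensitive to the presence of even a few strongly interacting
#' pairs, largely independent of what fraction of the alignment they occupy.
#'
#' @param aln A `"paired_alignment"`, character matrix, or a precomputed
#'   [mi_matrix()].
#' @return Scalar MImax in nats.
#' @export
mi_max <- function(aln) max(upper_mi(aln))

#' Kurtosis of the pairwise mutual information distribution (MIkurt)
#'
#' The fourth standardized moment (population form, non-excess) of the vector
#' of all pairwise MI values.  A heavy right tail -- many or strong epistatic
#' pairs -- raises the kurtosis.  Undefined (NA with a warning) when the MI
#' values have zero variance.
#'
#' @inheritParams mi_max
#' @return Scalar kurtosis, or `NA` if the MI vector is degenerate.
#' @export
mi_kurtosis <- function(aln) {
  v <- upper_mi(aln)
  if (length(v) < 2L) stop("kurtosis needs at least 2 pairwise MI values")
  m2 <- mean((v - mean(v))^2)
  if (m2 <= .Machine$double.eps * max(1, mean(v)^2)) {
    warning("pairwise MI values have zero variance; kurtosis undefined")
    return(NA_real_)
  }
  mean((v - mean(v))^4) / m2^2
}

#' All three adequacy statistics at once
#'
#' @inheritParams g93
#' @return Named numeric vector `c(g93, mimax, mikurt)`.
#' @export
alignment_statistics <- function(aln) {
  MI <- mi_matrix(aln)
  c(g93 = g93(aln), mimax = mi_max(MI), mikurt = mi_kurtosis(MI))
}
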