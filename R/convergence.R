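# Convergence diagnostics for the two-chain protocol: ASDSF on topologies
# and the Gelman-Rubin PSRF on the tree-length series.

#' Average standard deviation of split frequencies
#'
#' For every nontrivial split reaching frequency >= `min_freq` in at least
#' one chain (the MrBayes qualification convention), the standard deviation
#' of the split's frequency across the two chains is computed and averaged.
#' For two chains the per-split standard deviation is the two-point sample
#' (n-1 denominator) form, so a split fixed in one chain and absent from the
#' other contributes `|1 - 0| / sqrt(2) = 0.7071`.
#'
#' @param traceA,traceB `"posterior_trace"` objects (or lists/multiPhylo of
#'   trees) over the same taxa.
#' @param min_freq Qualification floor (default 0.10).
#' @return Scalar ASDSF (0 when the chains agree exactly; 0 when no split
#'   qualifies).
#' @export
asdsf <- function(traceA, traceB, min_freq = 0.10) {
  ta <- if (inherits(traceA, "posterior_trace")) traceA$trees else traceA
  tb <- if (inherits(traceB, "posterior_trace")) traceB$trees else traceB
  if (!setequal(ta[[1L]]$tip.label, tb[[1L]]$tip.label))
    stop("chains must share the same taxon set")
  fa <- split_frequencies(ta)
  fb <- split_frequencies(tb)
  keys <- union(names(fa), names(fb))
  if (!length(keys)) return(0)
  f1 <- ifelse(keys %in% names(fa), fa[keys], 0)
  f2 <- ifelse(keys %in% names(fb), fb[keys], 0)
  qual <- pmax(f1, f2) >= min_freq
  if (!any(qual)) return(0)
  mean(abs(f1[qual] - f2[qual]) / sqrt(2))
}

#' Potential scale reduction factor (two chains)
#'
#' The Gelman-Rubin statistic on a scalar series from two chains of equal
#' length: `sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-chain
#' variance and `B` the between-chain variance.  Applied here to the
#' tree-length series.  Two identical constant series have zero variance;
#' the statistic is then defined as 1 with a warning.
#'
#' @param seriesA,seriesB Numeric series of equal length >= 10.
#' @return Scalar PSRF (approximately 1 at convergence).
#' @export
psrf <- function(seriesA, seriesB) {
  n <- length(seriesA)
  if (length(seriesB) != n) stop("series must have equal length")
  if (n < 10L) stop("series too short for a meaningful PSRF")
  W <- (stats::var(seriesA) + stats::var(seriesB)) / 2
  B <- n * stats::var(c(mean(seriesA), mean(seriesB)))
  if (W <= .Machine$double.eps) {
    warning("degenerate zero-variance series; PSRF defined as 1")
    return(1)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence report for a two-chain analysis
#'
#' @param traceA,traceB `"posterior_trace"` objects.
#' @param asdsf_max,psrf_max Thresholds; the analysis passes only if
#'   `ASDSF <= asdsf_max` **and** `PSRF <= psrf_max`.
#' @return A list of class `"convergence_report"` with `asdsf`, `psrf`,
#'   `pass_asdsf`, `pass_psrf`, `pass`.
#' @export
convergence_report <- function(traceA, traceB, asdsf_max = 0.05,
                               psrf_max = 1.1) {
  a <- asdsf(traceA, traceB)
  p <- suppressWarnings(psrf(traceA$pars$tree_length, traceB$pars$tree_length))
  structure(list(asdsf = a, psrf = p,
                 pass_asdsf = a <= asdsf_max, pass_psrf = p <= psrf_max,
                 pass = a <= asdsf_max && p <= psrf_max,
                 asdsf_max = asdsf_max, psrf_max = psrf_max),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("ASDSF = %.4f (max %.3g, %s); PSRF = %.4f (max %.3g, %s) -> %s\n",
              x$asdsf, x$asdsf_max, if (x$pass_asdsf) "pass" else "fail",
              x$psrf, x$psrf_max, if (x$pass_psrf) "pass" else "fail",
              if (x$pass) "retained" else "discarded"))
  invisible(x)
}

#' Filter analyses by convergence
#'
#' Keeps exactly the analyses whose report passes both the ASDSF and the
#' PSRF test at the given thresholds (an analysis failing either test is
#' discarded).
#'
#' @param reports List of `"convergence_report"` objects.
#' @param asdsf_max,psrf_max Thresholds (re-applied to the stored values, so
#'   the strictness can be varied after the fact).
#' @return Logical vector: `TRUE` for retained analyses.
#' @export
filter_converged <- function(reports, asdsf_max = 0.05, psrf_max = 1.1) {
  if (asdsf_max <= 0 || psrf_max <= 0) stop("thresholds must be positive")
  vapply(reports, function(r)
    r$asdsf <= asdsf_max && r$psrf <= psrf_max, logical(1))
}
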