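# Posterior-predictive replicate simulation under the inferred site-iid
# model, p-values, two-tailed decisions, and power aggregation.

#' Simulate posterior-predictive replicate alignments
#'
#' Draws `m` posterior samples from a trace (without replacement when
#' possible, with replacement -- flagged by a warning -- when `m` exceeds the
#' trace length) and simulates one GTR+G alignment of `n_sites` iid columns
#' per draw, at that draw's tree, branch lengths, exchangeabilities, base
#' frequencies and gamma shape.  Replicates carry no pairing structure: the
#' inference model is site-iid.
#'
#' @param trace A `"posterior_trace"`.
#' @param n_sites Number of columns per replicate (the observed alignment's
#'   site count).
#' @param m Number of replicates.
#' @param seed Integer seed.
#' @return List of character matrices (taxa x n_sites).
#' @export
simulate_replicates <- function(trace, n_sites, m = 100L, seed = 1L) {
  stopifnot(inherits(trace, "posterior_trace"))
  nt <- length(trace$trees)
  if (nt < 1L) stop("empty trace")
  with_seed(seed, {
    idx <- if (m <= nt) sample.int(nt, m) else {
      warning("more replicates than posterior samples; sampling draws with replacement")
      sample.int(nt, m, replace = TRUE)
    }
    lapply(idx, function(i) {
      p <- trace$pars[i, ]
      pars <- model_params(
        exchangeabilities = as.numeric(p[paste0("er_", EXCH_NAMES)]),
        base_freqs = as.numeric(p[paste0("pi_", NUC)]),
        doublet_freqs = rep(1 / 16, 16),  # unused: replicates have no pairs
        d = 0, alpha = p$alpha,
        gamma_categories = trace$config$gamma_categories)
      simulate_alignment(trace$trees[[i]], pars, ni = n_sites, ne = 0L,
                         seed = stats::runif(1L, 1, 2^31 - 2))$aln
    })
  })
}

#' Posterior predictive p-value
#'
#' The proportion of replicate statistic values below the observed value,
#' counting ties with half weight.
#'
#' @param observed Observed statistic value.
#' @param replicates Numeric vector of replicate statistic values.
#' @return p in `[0, 1]`.
#' @export
ppp_value <- function(observed, replicates) {
  if (!length(replicates)) stop("need at least one replicate")
  (sum(replicates < observed) + 0.5 * sum(replicates == observed)) /
    length(replicates)
}

#' Two-tailed significance decision
#'
#' A posterior predictive p-value signals misfit in either tail:
#' significant iff `p < alpha / 2` or `p > 1 - alpha / 2`.
#'
#' @param p Posterior predictive p-value.
#' @param alpha Test level in (0, 1).
#' @return Logical.
#' @export
two_tailed_significant <- function(p, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  p < alpha / 2 | p > 1 - alpha / 2
}

#' Posterior predictive check of one alignment
#'
#' Computes the observed G93 / MImax / MIkurt statistics, simulates `m`
#' posterior-predictive replicates from the trace, and returns the
#' per-statistic p-values and two-tailed decisions.
#'
#' @param aln Observed alignment (`"paired_alignment"` or matrix).
#' @param trace A `"posterior_trace"` fitted to that alignment.
#' @param m Replicate count.
#' @param alpha Test level.
#' @param seed Integer seed.
#' @return A list of class `"pp_result"`: `observed`, `replicates` (m x 3
#'   matrix), `p`, `significant`.
#' @export
pp_check <- function(aln, trace, m = 100L, alpha = 0.05, seed = 1L) {
  obs <- alignment_statistics(aln)
  n_sites <- ncol(as_char_alignment(aln))
  reps <- simulate_replicates(trace, n_sites, m = m, seed = seed)
  repstats <- t(vapply(reps, alignment_statistics, numeric(3)))
  p <- vapply(names(obs), function(s) ppp_value(obs[[s]], repstats[, s]),
              numeric(1))
  structure(list(observed = obs, replicates = repstats, p = p,
                 significant = two_tailed_significant(p, alpha),
                 alpha = alpha, m = m),
            class = "pp_result")
}

#' @export
print.pp_result <- function(x, ...) {
  for (s in names(x$observed))
    cat(sprintf("  %-7s obs = %10.4f  p = %.3f  %s\n", s, x$observed[[s]],
                x$p[[s]], if (x$significant[[s]]) "SIGNIFICANT" else ""))
  invisible(x)
}

#' Power table over the simulation grid
#'
#' Aggregates two-tailed significance decisions into power per epistasis
#' strength `d` and per window of the proportion of epistatic sites
#' `ne / (ni + ne)` (default 10% windows).  Cells with `ne = 0` are the null
#' set: data truly generated from the inference model; their aggregate is
#' the empirical false-positive rate.  (Cells with `d = 0` but `ne > 0` are
#' *not* null: the doublet stationary frequencies still misspecify the
#' model.)
#'
#' @param results Data frame with columns `d`, `ni`, `ne` and one logical
#'   column per statistic named `sig_<stat>` (as produced by
#'   [run_campaign()]).
#' @param window Window width on the epistatic proportion (default 0.1).
#' @return A list with `power` (data.frame: d, window, n, per-statistic
#'   power) and `fpr` (named vector of per-statistic false-positive rates
#'   over null cells).
#' @export
power_table <- function(results, window = 0.1) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  sig_cols <- grep("^sig_", names(results), value = TRUE)
  if (!length(sig_cols)) stop("no sig_* columns in results")
  prop <- with(results, ifelse(ni + ne > 0, ne / (ni + ne), 0))
  null_set <- results$ne == 0
  fpr <- vapply(sig_cols, function(s)
    mean(results[[s]][null_set], na.rm = TRUE), numeric(1))
  names(fpr) <- sub("^sig_", "", sig_cols)

  epi <- results[!null_set, , drop = FALSE]
  eprop <- prop[!null_set]
  breaks <- seq(0, 1, by = window)
  win <- cut(eprop, breaks, include.lowest = TRUE)
  rows <- list()
  for (dv in sort(unique(epi$d))) for (wv in levels(win)) {
    sel <- epi$d == dv & win == wv
    if (!any(sel)) next
    pw <- vapply(sig_cols, function(s) mean(epi[[s]][sel], na.rm = TRUE),
                 numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      d = dv, window = wv, n = sum(sel), t(pw))
  }
  power <- do.call(rbind, rows)
  names(power) <- sub("^sig_", "power_", names(power))
  list(power = power, fpr = fpr)
}
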