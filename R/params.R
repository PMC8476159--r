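#' @keywords internal
"_PACKAGE"

NUC <- c("A", "C", "G", "T")

#' Doublet state labels
#'
#' The 16 ordered nucleotide doublets in lexicographic order
#' (A,A), (A,C), ..., (T,T), indexed 0--15.  The first nucleotide of a
#' doublet is the more 5' member of the pair.
#'
#' @return Character vector of length 16, e.g. `"AA"`, `"AC"`, ...
#' @export
doublet_states <- function() {
  as.vector(t(outer(NUC, NUC, paste0)))
}

#' Watson-Crick doublets
#'
#' The set W of Watson-Crick pairs between which simultaneous (double)
#' substitutions are permitted under the doublet model.
#'
#' @return Character vector `c("AT", "CG", "GC", "TA")`.
#' @export
watson_crick_set <- function() c("AT", "CG", "GC", "TA")

EXCH_NAMES <- c("AC", "AG", "AT", "CG", "CT", "GT")

check_exchangeabilities <- function(s) {
  s <- as.numeric(s)
  if (length(s) != 6L || anyNA(s) || any(s <= 0))
    stop("exchangeabilities must be 6 strictly positive rates (order AC, AG, AT, CG, CT, GT)")
  names(s) <- EXCH_NAMES
  s
}

check_simplex <- function(p, n, what, tol = 1e-8) {
  p <- as.numeric(p)
  if (length(p) != n || anyNA(p) || any(p <= 0))
    stop(sprintf("%s must be %d strictly positive values", what, n))
  if (abs(sum(p) - 1) > tol)
    stop(sprintf("%s must sum to 1 (got %.10f)", what, sum(p)))
  p / sum(p)
}

#' Bundle model parameters
#'
#' Collects the parameters shared by the site-independent GTR+G model and the
#' 16-state epistatic doublet model: GTR exchangeabilities `S` (shared between
#' the two models), nucleotide stationary frequencies `pi` (independent
#' sites), doublet stationary frequencies `pie` (paired sites), the epistasis
#' strength `d` (relative rate of double to single substitutions between
#' Watson-Crick doublets), and the discrete-gamma rate heterogeneity shape
#' `alpha` with `gamma_categories` categories.
#'
#' @param exchangeabilities Six positive relative rates, order AC, AG, AT, CG,
#'   CT, GT.
#' @param base_freqs Nucleotide frequencies (A, C, G, T), a probability vector.
#' @param doublet_freqs Doublet frequencies over the 16 ordered doublets in
#'   lexicographic order, a probability vector.
#' @param d Nonnegative epistasis strength; `d = 0` disables double
#'   substitutions.
#' @param alpha Positive gamma shape for among-site rate variation.
#' @param gamma_categories Number of equal-probability discrete gamma
#'   categories (default 4).
#' @return An object of class `"epi_params"`.
#' @export
model_params <- function(exchangeabilities, base_freqs, doublet_freqs,
                         d = 0, alpha = 1, gamma_categories = 4L) {
  if (!is.finite(d) || d < 0) stop("d must be finite and nonnegative")
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  gamma_categories <- as.integer(gamma_categories)
  if (gamma_categories < 1L) stop("gamma_categories must be >= 1")
  out <- list(
    exchangeabilities = check_exchangeabilities(exchangeabilities),
    base_freqs = stats::setNames(check_simplex(base_freqs, 4L, "base_freqs"), NUC),
    doublet_freqs = stats::setNames(
      check_simplex(doublet_freqs, 16L, "doublet_freqs"), doublet_states()),
    d = as.numeric(d),
    alpha = as.numeric(alpha),
    gamma_categories = gamma_categories
  )
  class(out) <- "epi_params"
  out
}

#' @export
print.epi_params <- function(x, ...) {
  cat("Epistatic doublet model parameters\n")
  cat("  exchangeabilities:", paste(sprintf("%s=%.3g", names(x$exchangeabilities),
                                            x$exchangeabilities), collapse = " "), "\n")
  cat("  base freqs:       ", paste(sprintf("%.3f", x$base_freqs), collapse = " "), "\n")
  cat("  WC doublet mass:  ",
      sprintf("%.3f", sum(x$doublet_freqs[watson_crick_set()])), "\n")
  cat("  d =", x$d, " alpha =", x$alpha,
      " gamma categories =", x$gamma_categories, "\n")
  invisible(x)
}

#' Synthetic stem-site parameter set
#'
#' A synthetic parameter set emulating an rRNA gene with paired stem sites:
#' moderately transition-enriched GTR exchange rates, slightly GC-skewed base
#' frequencies, and doublet frequencies enriched for Watson-Crick pairs.  The
#' Watson-Crick enrichment was calibrated once (a single scalar mixing weight)
#' so that the expected doublet-substitution fraction satisfies
#' p(0.5) = 11.2%, which under the p = kd/(kd+1) form places the whole curve
#' at p(2) = 33.5%, p(8) = 66.9% and p(1000) = 99.6%.  This is a synthetic
#' stand-in for parameters fitted to a real stem/loop alignment, not an
#' empirical estimate.
#'
#' @param d Epistasis strength (default 0).
#' @param alpha Gamma shape (default 0.45, a typical rRNA-like value).
#' @param gamma_categories Number of discrete gamma categories.
#' @return An `"epi_params"` object.
#' @export
stem_params <- function(d = 0, alpha = 0.45, gamma_categories = 4L) {
  pie <- c(0.060367, 0.060367, 0.060367, 0.067192,
           0.060367, 0.060367, 0.070604, 0.060367,
           0.060367, 0.070604, 0.060367, 0.060367,
           0.067192, 0.060367, 0.060367, 0.060367)
  model_params(
    exchangeabilities = c(AC = 1.0, AG = 2.0, AT = 1.5, CG = 0.9, CT = 2.4, GT = 1.0),
    base_freqs = c(A = 0.25, C = 0.21, G = 0.27, T = 0.27),
    doublet_freqs = pie / sum(pie),
    d = d, alpha = alpha, gamma_categories = gamma_categories
  )
}

#' Read or write a model parameter file
#'
#' Flat key-value files holding the fields of [model_params()]:
#' `exchangeabilities` (6 values, order AC, AG, AT, CG, CT, GT),
#' `base_frequencies` (A, C, G, T), `doublet_frequencies` (16 values,
#' lexicographic), `d`, `alpha`, `gamma_categories`.  JSON is used for paths
#' ending in `.json`; YAML otherwise (requires the yaml package).
#'
#' @param path File path.
#' @param params An `"epi_params"` object (for writing).
#' @return `read_params()` returns an `"epi_params"` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML parameter files requires the yaml package")
    yaml::read_yaml(path)
  }
  model_params(
    exchangeabilities = unlist(raw$exchangeabilities),
    base_freqs = unlist(raw$base_frequencies),
    doublet_freqs = unlist(raw$doublet_frequencies),
    d = raw$d %||% 0,
    alpha = raw$alpha %||% 1,
    gamma_categories = raw$gamma_categories %||% 4L
  )
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "epi_params"))
  obj <- list(
    exchangeabilities = unname(params$exchangeabilities),
    base_frequencies = unname(params$base_freqs),
    doublet_frequencies = unname(params$doublet_freqs),
    d = params$d,
    alpha = params$alpha,
    gamma_categories = params$gamma_categories
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("writing YAML parameter files requires the yaml package")
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
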