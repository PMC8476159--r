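# Monotone semiparametric regression for the relative worth r(d) of an
# epistatic site: E[y'] = g(ni + r * ne) with g an I-spline with nonnegative
# coefficients (plus a free intercept), fitted by profiled least squares
# over r, with a nonparametric bootstrap for uncertainty.

#' I-spline basis
#'
#' Integrated M-spline (I-spline) basis of the given degree with `n_knots`
#' interior knots placed at equally spaced quantiles of `x` (boundary knots
#' at the range of `x`).  Computed as tail sums of a B-spline partition of
#' unity one degree higher, so each basis function is nondecreasing, 0 at
#' the left boundary and 1 at the right.  Nonnegative-coefficient
#' combinations of the columns are monotone nondecreasing functions.
#'
#' @param x Evaluation points.
#' @param degree Spline degree (default 3, cubic).
#' @param n_knots Number of interior knots (default 5).
#' @param knots Optional explicit interior knots (overrides `n_knots`).
#' @param boundary Optional boundary knots (length 2).
#' @return Matrix with `length(x)` rows; attributes `knots`, `boundary`,
#'   `degree` allow re-evaluation at new points via [ispline_eval()].
#' @export
ispline_basis <- function(x, degree = 3L, n_knots = 5L, knots = NULL,
                          boundary = NULL) {
  if (!length(x)) stop("x is empty")
  if (is.null(boundary)) boundary <- range(x)
  if (boundary[1] >= boundary[2]) stop("degenerate x: all values equal")
  if (is.null(knots)) {
    probs <- seq_len(n_knots) / (n_knots + 1)
    knots <- unique(stats::quantile(x, probs, names = FALSE, type = 7))
    knots <- knots[knots > boundary[1] & knots < boundary[2]]
  }
  B <- ispline_eval_raw(x, degree, knots, boundary)
  attr(B, "degree") <- degree
  attr(B, "knots") <- knots
  attr(B, "boundary") <- boundary
  B
}

ispline_eval_raw <- function(x, degree, knots, boundary) {
  ord <- degree + 2L  # B-spline order one higher than the I-spline degree
  aug <- c(rep(boundary[1], ord), knots, rep(boundary[2], ord))
  xc <- pmin(pmax(x, boundary[1]), boundary[2])
  Bs <- splines::splineDesign(aug, xc, ord = ord, outer.ok = TRUE)
  nb <- ncol(Bs)
  # tail sums of the partition of unity; drop the constant (j = 1) term
  I <- t(apply(Bs, 1L, function(r) rev(cumsum(rev(r)))))
  I <- I[, -1L, drop = FALSE]
  colnames(I) <- paste0("I", seq_len(nb - 1L))
  I
}

#' Evaluate an I-spline basis at new points
#'
#' @param basis A basis from [ispline_basis()].
#' @param x New evaluation points (clamped to the boundary).
#' @return Matrix of basis values.
#' @export
ispline_eval <- function(basis, x) {
  ispline_eval_raw(x, attr(basis, "degree"), attr(basis, "knots"),
                   attr(basis, "boundary"))
}

#' Response transforms for worth regression
#'
#' Maps a bounded or one-signed summary measure to an unbounded response
#' that increases with inference quality, so the monotone spline applies:
#' `"neglog"` for nonnegative error-like measures (posterior RF summaries),
#' `y' = -log(y + eps)` with `eps = 0.5` (half the smallest possible
#' nonzero RF step); `"logit"` for proportions that increase with quality
#' (MRC resolution), clamped away from 0/1; `"neglogit"` for proportions
#' that decrease with quality (MRC error); `"identity"` passes through.
#'
#' @param y Numeric summary values.
#' @param transform One of `"neglog"`, `"logit"`, `"neglogit"`, `"identity"`.
#' @param eps Clamping constant; default 0.5 for `"neglog"`, `1 / (2 * 200)`
#'   for the logit family.
#' @return Transformed numeric vector.
#' @export
worth_transform <- function(y, transform = c("neglog", "logit", "neglogit",
                                             "identity"),
                            eps = NULL) {
  transform <- match.arg(transform)
  switch(transform,
    neglog = -log(y + (eps %||% 0.5)),
    logit = {
      e <- eps %||% (1 / 400)
      yc <- pmin(pmax(y, e), 1 - e)
      log(yc / (1 - yc))
    },
    neglogit = {
      e <- eps %||% (1 / 400)
      yc <- pmin(pmax(y, e), 1 - e)
      -log(yc / (1 - yc))
    },
    identity = y)
}

# nonnegative least squares with a free intercept: project out the constant
# column, solve NNLS on the centered system, recover the intercept.
nnls_with_intercept <- function(B, y) {
  Bc <- scale(B, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  fit <- pracma::lsqnonneg(Bc, yc)
  beta <- fit$x
  intercept <- mean(y) - sum(colMeans(B) * beta)
  fitted <- as.vector(B %*% beta) + intercept
  list(beta = beta, intercept = intercept, fitted = fitted,
       rss = sum((y - fitted)^2))
}

worth_rss <- function(r, ni, ne, yt, degree, n_knots) {
  neff <- ni + r * ne
  if (diff(range(neff)) < .Machine$double.eps) return(Inf)
  B <- ispline_basis(neff, degree = degree, n_knots = n_knots)
  nnls_with_intercept(B, yt)$rss
}

#' Fit the relative worth of an epistatic site
#'
#' Fits the semiparametric model `E[y'] = g(ni + r * ne)` where `y'` is the
#' transformed summary measure and `g` a monotone I-spline with nonnegative
#' coefficients and a free intercept.  The worth `r` is profiled: a coarse
#' grid over `r_bounds` followed by golden-section refinement, minimizing the
#' residual sum of squares; the spline basis (knots at quantiles of the
#' candidate effective lengths `neff = ni + r * ne`) is rebuilt for every
#' candidate.  `r < 0` is the catastrophic regime and is kept inside the
#' default search interval so it can be detected rather than assumed away.
#'
#' @param data Data frame with columns `ni`, `ne` and the response; one
#'   summary measure for one value of d per fit.
#' @param response Name of the response column (default `"y"`).
#' @param transform Response transform (see [worth_transform()]); use
#'   `"identity"` if `data[[response]]` is already unbounded-increasing.
#' @param r_bounds Search interval for r (default `c(-2, 2)`).
#' @param degree,n_knots I-spline settings (defaults 3 and 5).
#' @param grid_step Coarse profile step (default 0.05).
#' @param tol Golden-section tolerance on r (default 1e-3).
#' @param eps Transform clamping constant (see [worth_transform()]).
#' @return An object of class `"worth_fit"` with components `r` (the
#'   estimate), `coefficients` (intercept + nonnegative spline
#'   coefficients), `basis`, `fitted`, `residuals`, `rss`, `profile`
#'   (the coarse grid), and the call metadata.
#' @export
worth_fit <- function(data, response = "y",
                      transform = c("neglog", "logit", "neglogit", "identity"),
                      r_bounds = c(-2, 2), degree = 3L, n_knots = 5L,
                      grid_step = 0.05, tol = 1e-3, eps = NULL) {
  transform <- match.arg(transform)
  stopifnot(is.data.frame(data), all(c("ni", "ne") %in% names(data)),
            response %in% names(data))
  ni <- as.numeric(data$ni); ne <- as.numeric(data$ne)
  y <- as.numeric(data[[response]])
  ok <- is.finite(y)
  ni <- ni[ok]; ne <- ne[ok]; y <- y[ok]
  if (!any(ne > 0)) stop("worth is unidentifiable: no rows with ne > 0")
  if (!any(ne == 0)) warning("no ne = 0 rows: g() is anchored only through epistatic cells")
  yt <- worth_transform(y, transform, eps)

  rss_of <- function(r) worth_rss(r, ni, ne, yt, degree, n_knots)
  grid <- seq(r_bounds[1], r_bounds[2], by = grid_step)
  prof <- vapply(grid, rss_of, numeric(1))
  i0 <- which.min(prof)
  lo <- grid[max(1L, i0 - 1L)]; hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(rss_of, c(lo, hi), tol = tol)
  r_hat <- opt$minimum
  if (rss_of(grid[i0]) < opt$objective) r_hat <- grid[i0]
  if (min(abs(r_hat - r_bounds)) < 2 * tol)
    warning("worth estimate at the search boundary; widen r_bounds")

  neff <- ni + r_hat * ne
  B <- ispline_basis(neff, degree = degree, n_knots = n_knots)
  fit <- nnls_with_intercept(B, yt)
  structure(list(r = r_hat,
                 coefficients = c(intercept = fit$intercept,
                                  stats::setNames(fit$beta, colnames(B))),
                 basis = B, fitted = fit$fitted, residuals = yt - fit$fitted,
                 rss = fit$rss, profile = data.frame(r = grid, rss = prof),
                 data = data.frame(ni = ni, ne = ne, y = y, yt = yt),
                 transform = transform, response = response,
                 degree = degree, n_knots = n_knots, r_bounds = r_bounds,
                 eps = eps),
            class = "worth_fit")
}

#' @export
print.worth_fit <- function(x, digits = 3, ...) {
  cat("Relative worth of an epistatic site (monotone I-spline regression)\n")
  cat(sprintf("  r-hat = %.*f   (%s)\n", digits, x$r, worth_scenario(x$r)))
  cat(sprintf("  response: %s (%s transform), %d cells, RSS = %.4g\n",
              x$response, x$transform, nrow(x$data), x$rss))
  invisible(x)
}

#' @export
summary.worth_fit <- function(object, ...) {
  out <- list(r = object$r, scenario = worth_scenario(object$r),
              coefficients = object$coefficients, rss = object$rss,
              n = nrow(object$data), transform = object$transform,
              sigma = sqrt(object$rss /
                             max(1, nrow(object$data) -
                                   sum(object$coefficients[-1] > 0) - 2)))
  class(out) <- "summary.worth_fit"
  out
}

#' @export
print.summary.worth_fit <- function(x, ...) {
  cat(sprintf("r-hat = %.4f (%s scenario), n = %d cells\n", x$r, x$scenario, x$n))
  cat(sprintf("residual scale = %.4g on the %s-transformed response\n",
              x$sigma, x$transform))
  cat("spline coefficients (nonnegative; intercept free):\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.worth_fit <- function(object, ...) {
  c(r = object$r, object$coefficients)
}

#' @export
residuals.worth_fit <- function(object, ...) object$residuals

#' @export
fitted.worth_fit <- function(object, ...) object$fitted

#' Predict the transformed summary measure at new cells
#'
#' Evaluates the fitted monotone curve `g` at `neff = ni + r-hat * ne` for
#' new cells.
#'
#' @param object A `"worth_fit"`.
#' @param newdata Data frame with columns `ni`, `ne` (defaults to the
#'   training cells).
#' @param ... Unused.
#' @return Numeric vector on the transformed-response scale.
#' @export
predict.worth_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  neff <- as.numeric(newdata$ni) + object$r * as.numeric(newdata$ne)
  B <- ispline_eval(object$basis, neff)
  as.vector(B %*% object$coefficients[-1]) + object$coefficients[["intercept"]]
}

#' @export
plot.worth_fit <- function(x, ...) {
  neff <- x$data$ni + x$r * x$data$ne
  ord <- order(neff)
  graphics::plot(neff, x$data$yt, xlab = "effective sequence length",
                 ylab = sprintf("%s (%s)", x$response, x$transform),
                 main = sprintf("r-hat = %.3f", x$r), ...)
  graphics::lines(neff[ord], x$fitted[ord], col = 2, lwd = 2)
  invisible(x)
}

#' Nonparametric bootstrap of the worth estimate
#'
#' Resamples grid-cell rows with replacement, refits, and collects the
#' bootstrap distribution of r-hat.  Deterministic given `seed`; fit
#' failures on degenerate resamples are counted and reported.
#'
#' @param data As in [worth_fit()].
#' @param B Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param ... Passed to [worth_fit()].
#' @return An object of class `"worth_boot"`: `r` (vector of length <= B),
#'   `failures`, `seed`.
#' @export
bootstrap_worth <- function(data, B = 100L, seed = 1L, ...) {
  if (B < 1L) stop("B must be >= 1")
  with_seed(seed, {
    rs <- rep(NA_real_, B)
    fail <- 0L
    for (b in seq_len(B)) {
      idx <- sample.int(nrow(data), replace = TRUE)
      rs[b] <- tryCatch(
        suppressWarnings(worth_fit(data[idx, , drop = FALSE], ...)$r),
        error = function(e) NA_real_)
      if (is.na(rs[b])) fail <- fail + 1L
    }
    structure(list(r = rs[!is.na(rs)], failures = fail, B = as.integer(B),
                   seed = as.integer(seed)),
              class = "worth_boot")
  })
}

#' @export
print.worth_boot <- function(x, ...) {
  q <- stats::quantile(x$r, c(0.05, 0.5, 0.95))
  cat(sprintf("Bootstrap worth: %d/%d successful refits; r-hat median %.3f (90%% interval %.3f..%.3f)\n",
              length(x$r), x$B, q[2], q[1], q[3]))
  invisible(x)
}

worth_scenario <- function(r) {
  if (r < 0) "catastrophic" else if (r <= 1) "best-case" else "super-efficient"
}

#' Classify and order a set of worth fits
#'
#' Labels each fit by misspecification scenario -- best-case
#' (`0 <= r <= 1`: epistatic sites still help, just less than independent
#' ones), catastrophic (`r < 0`: they actively hurt), or super-efficient
#' (`r > 1`, flagged as suspect) -- and reports the ordering of r-hat
#' across d.
#'
#' @param fits Named list of `"worth_fit"` objects (names = d values) or a
#'   named numeric vector of r-hat values.
#' @return A data.frame (d, r, scenario) sorted by decreasing r, with the
#'   ordering string as attribute `"ordering"`.
#' @export
worth_report <- function(fits) {
  if (!length(fits)) stop("need at least one fit")
  r <- if (is.numeric(fits)) fits else
    vapply(fits, function(f) f$r, numeric(1))
  out <- data.frame(d = names(r) %||% as.character(seq_along(r)), r = as.numeric(r),
                    scenario = vapply(as.numeric(r), worth_scenario, character(1)))
  out <- out[order(-out$r), ]
  rownames(out) <- NULL
  attr(out, "ordering") <- paste(
    sprintf("r(%s)", out$d), collapse = " >= ")
  out
}
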