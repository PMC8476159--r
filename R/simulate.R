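# Simulation of alignments mixing independent (GTR+G) sites and
# epistatically paired (doublet model) sites along a fixed tree.

#' Pairing map
#'
#' Describes which alignment columns form epistatic doublets and which are
#' independent.  All column indices are 0-based, matching the on-disk
#' tab-separated pairing format; column `j` in the map is column `j + 1` of
#' the R alignment matrix.
#'
#' @param pairs Integer matrix with two columns (5' index, 3' index), one row
#'   per doublet, or `NULL` for no pairs.
#' @param independent Integer vector of independent column indices.
#' @return An object of class `"pairing_map"`.
#' @export
pairing_map <- function(pairs = NULL, independent = integer()) {
  if (is.null(pairs)) pairs <- matrix(integer(), 0L, 2L)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  independent <- as.integer(independent)
  idx <- c(as.vector(pairs), independent)
  if (anyDuplicated(idx)) stop("pairing map indices overlap")
  if (length(idx) && (min(idx) < 0L || !setequal(idx, seq_len(length(idx)) - 1L)))
    stop("pairing map must cover exactly the alignment columns 0..n-1")
  structure(list(pairs = pairs, independent = independent),
            class = "pairing_map")
}

default_pairing_map <- function(ni, ne) {
  np <- ne %/% 2L
  pairs <- if (np > 0L) cbind(ni + 2L * (seq_len(np) - 1L),
                              ni + 2L * (seq_len(np) - 1L) + 1L) else NULL
  pairing_map(pairs = pairs, independent = seq_len(ni) - 1L)
}

#' @export
print.pairing_map <- function(x, ...) {
  cat(sprintf("Pairing map: %d independent columns, %d pairs (0-based indices)\n",
              length(x$independent), nrow(x$pairs)))
  invisible(x)
}

new_paired_alignment <- function(aln, map, d, seed) {
  structure(list(aln = aln, map = map, d = d,
                 ni = length(map$independent), ne = 2L * nrow(map$pairs),
                 seed = seed),
            class = "paired_alignment")
}

#' @export
print.paired_alignment <- function(x, ...) {
  cat(sprintf("Paired alignment: %d taxa x %d columns (ni = %d, ne = %d, d = %g)\n",
              nrow(x$aln), ncol(x$aln), x$ni, x$ne, x$d))
  invisible(x)
}

# sample next states given current states (integer vector) and a row-wise
# cumulative transition matrix CP, by inverse-CDF lookup; vectorized over sites.
evolve_states <- function(states, CP) {
  if (!length(states)) return(states)
  u <- stats::runif(length(states))
  1L + rowSums(u > CP[states, , drop = FALSE])
}

row_cdf <- function(P) {
  CP <- t(apply(P, 1L, cumsum))
  CP[, ncol(CP)] <- 1
  CP
}

# Precompute per-edge, per-category transition CDFs for a (tree, params)
# combination so that many alignments can be simulated cheaply on one tree.
simulation_context <- function(tree, params, pairs = TRUE) {
  po <- postorder_edges(tree)
  asrv <- discretize_gamma(params$alpha, params$gamma_categories)
  edQ <- rate_eigen(iid_rate_matrix(params$exchangeabilities, params$base_freqs))
  edE <- if (pairs)
    rate_eigen(doublet_rate_matrix(params$exchangeabilities,
                                   params$doublet_freqs, params$d)) else NULL
  ne <- nrow(po$edge)
  cdf_i <- vector("list", ne)
  cdf_e <- if (pairs) vector("list", ne) else NULL
  for (e in seq_len(ne)) {
    cdf_i[[e]] <- lapply(asrv$rates, function(r)
      row_cdf(prob_from_eigen(edQ, po$len[e] * r)))
    if (pairs)
      cdf_e[[e]] <- lapply(asrv$rates, function(r)
        row_cdf(prob_from_eigen(edE, po$len[e] * r)))
  }
  list(po = po, asrv = asrv, params = params, cdf_i = cdf_i, cdf_e = cdf_e)
}

simulate_from_context <- function(ctx, ni, ne, seed, map = NULL) {
  params <- ctx$params
  ni <- as.integer(ni); ne <- as.integer(ne)
  np <- ne %/% 2L
  if (np > 0L && is.null(ctx$cdf_e)) stop("context was built without pair support")
  if (is.null(map)) map <- default_pairing_map(ni, ne)
  po <- ctx$po; asrv <- ctx$asrv
  ntip <- po$ntip
  nnode <- ntip + po$tree$Nnode

  sim <- with_seed(seed, {
    cat_i <- sample.int(asrv$K, ni, replace = TRUE)
    cat_e <- sample.int(asrv$K, np, replace = TRUE)
    si <- matrix(NA_integer_, nnode, ni)
    se <- matrix(NA_integer_, nnode, np)
    if (ni) si[po$root, ] <- sample.int(4L, ni, replace = TRUE,
                                        prob = params$base_freqs)
    if (np) se[po$root, ] <- sample.int(16L, np, replace = TRUE,
                                        prob = params$doublet_freqs)
    for (e in rev(seq_len(nrow(po$edge)))) {  # preorder: root towards tips
      par <- po$edge[e, 1L]; child <- po$edge[e, 2L]
      for (k in seq_len(asrv$K)) {
        ii <- which(cat_i == k)
        if (length(ii))
          si[child, ii] <- evolve_states(si[par, ii], ctx$cdf_i[[e]][[k]])
        ie <- which(cat_e == k)
        if (length(ie))
          se[child, ie] <- evolve_states(se[par, ie], ctx$cdf_e[[e]][[k]])
      }
    }
    list(si = si[seq_len(ntip), , drop = FALSE],
         se = se[seq_len(ntip), , drop = FALSE])
  })

  n <- ni + ne
  aln <- matrix(NA_character_, ntip, n,
                dimnames = list(po$tree$tip.label, NULL))
  if (ni) aln[, map$independent + 1L] <- NUC[sim$si]
  if (np) {
    nuc1 <- (sim$se - 1L) %/% 4L + 1L
    nuc2 <- (sim$se - 1L) %% 4L + 1L
    aln[, map$pairs[, 1L] + 1L] <- NUC[nuc1]
    aln[, map$pairs[, 2L] + 1L] <- NUC[nuc2]
  }
  new_paired_alignment(aln, map, params$d, as.integer(seed))
}

#' Simulate a paired alignment along a tree
#'
#' Simulates `ni` independent columns under GTR+G and `ne / 2` column pairs
#' under the epistatic doublet model along `tree`.  Root states are drawn
#' from the respective stationary distributions; states then evolve along
#' each branch using matrix-exponential transition probabilities.  Each
#' independent site and each pair draws one discrete-gamma rate multiplier
#' (a pair evolves as a single unit under the doublet generator).  By default
#' pairs occupy adjacent columns after the independent block; pass `map` for
#' any other layout.
#'
#' @param tree `ape::phylo` with branch lengths (expected substitutions per
#'   site).
#' @param params An `"epi_params"` object; `params$d` sets the epistasis
#'   strength.
#' @param ni Number of independent columns.
#' @param ne Number of epistatic columns (even; `ne / 2` pairs).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param map Optional `"pairing_map"` fixing the column layout.
#' @return A `"paired_alignment"`: character matrix `aln` (taxa x columns,
#'   characters A/C/G/T), the `"pairing_map"`, and provenance (`d`, `ni`,
#'   `ne`, `seed`).
#' @export
simulate_alignment <- function(tree, params, ni, ne, seed = 1L, map = NULL) {
  stopifnot(inherits(params, "epi_params"))
  ni <- as.integer(ni); ne <- as.integer(ne)
  if (ni < 0L || ne < 0L) stop("ni and ne must be nonnegative")
  if (ne %% 2L != 0L) stop("ne must be even (epistatic sites come in pairs)")
  if (ni + ne == 0L) stop("alignment must have at least one column")
  ctx <- simulation_context(tree, params, pairs = ne > 0L)
  simulate_from_context(ctx, ni, ne, seed, map)
}

#' Grid specification for a simulation campaign
#'
#' The 3-D simulation grid: every combination of epistasis strength `d`,
#' number of independent sites `ni` and number of epistatic sites `ne`
#' (both ranging over `n_values`), excluding the empty cell
#' `ni = ne = 0`.  The published design uses
#' `d in {0, 0.5, 2, 8, 1000}` and `n_values = seq(0, 400, by = 16)`
#' (a 26 x 26 grid per d, 675 alignments per d, 3,375 in total).
#'
#' @param d_values Epistasis strengths.
#' @param n_values Site counts used for both `ni` and `ne`; must be even
#'   (values are also used as `ne`).
#' @param seed Master seed; per-cell seeds are derived from it.
#' @return An object of class `"grid_spec"` whose `cells` element is a
#'   data.frame with columns `d`, `ni`, `ne`, `seed`.
#' @export
grid_spec <- function(d_values = c(0, 0.5, 2, 8, 1000),
                      n_values = seq(0L, 400L, by = 16L),
                      seed = 1L) {
  n_values <- as.integer(n_values)
  if (any(n_values %% 2L != 0L)) stop("n_values must be even (they are used as ne)")
  cells <- expand.grid(ni = n_values, ne = n_values, d = d_values,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[!(cells$ni == 0L & cells$ne == 0L), c("d", "ni", "ne")]
  rownames(cells) <- NULL
  cells$seed <- vapply(seq_len(nrow(cells)), function(i)
    derive_seed(seed, match(cells$d[i], d_values), cells$ni[i], cells$ne[i]),
    integer(1))
  structure(list(d_values = d_values, n_values = n_values,
                 seed = as.integer(seed), cells = cells),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Simulation grid: %d d-values x (%d x %d site grid minus origin) = %d cells\n",
              length(x$d_values), length(x$n_values), length(x$n_values),
              nrow(x$cells)))
  invisible(x)
}

#' Simulate every cell of a grid
#'
#' Simulates one alignment per `(d, ni, ne)` cell of `spec` on a fixed tree.
#' To keep memory bounded on large grids, `fun` may be supplied to reduce
#' each alignment to a summary immediately (e.g. a test statistic); otherwise
#' the alignments themselves are returned.
#'
#' @param spec A `"grid_spec"`.
#' @param tree Simulation tree.
#' @param params An `"epi_params"`; its `d` is overridden per cell.
#' @param fun Optional function applied to each `"paired_alignment"`.
#' @return A list with `cells` (the spec's cell table) and `results`
#'   (list of alignments, or of `fun` values).
#' @export
simulate_grid <- function(spec, tree, params, fun = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  cells <- spec$cells
  results <- vector("list", nrow(cells))
  for (dv in unique(cells$d)) {
    p <- params
    p$d <- dv
    idx <- which(cells$d == dv)
    ctx <- simulation_context(tree, p, pairs = any(cells$ne[idx] > 0L))
    for (i in idx) {
      a <- simulate_from_context(ctx, cells$ni[i], cells$ne[i],
                                 seed = cells$seed[i])
      results[[i]] <- if (is.null(fun)) a else fun(a)
    }
  }
  list(cells = cells, results = results)
}

#' Exact event-recording simulation (Gillespie)
#'
#' Stochastic simulation of the substitution process along every branch,
#' recording each substitution event and whether it was a single- or
#' double-site change.  Used to validate the matrix-exponential simulator and
#' the expected doublet-substitution fraction against realized event counts.
#'
#' @inheritParams simulate_alignment
#' @return A list with `events` (data.frame: unit, type `"iid"`/`"pair"`,
#'   edge, from, to, double flag) and `tips` (tip states, integer codes).
#' @export
simulate_with_events <- function(tree, params, ni = 0L, ne = 0L, seed = 1L) {
  stopifnot(inherits(params, "epi_params"))
  ni <- as.integer(ni); ne <- as.integer(ne)
  if (ne %% 2L != 0L) stop("ne must be even")
  np <- ne %/% 2L
  Qi <- iid_rate_matrix(params$exchangeabilities, params$base_freqs)
  Qe <- if (np) doublet_rate_matrix(params$exchangeabilities,
                                    params$doublet_freqs, params$d) else NULL
  asrv <- discretize_gamma(params$alpha, params$gamma_categories)
  po <- postorder_edges(tree)
  ntip <- po$ntip
  nnode <- ntip + po$tree$Nnode

  gillespie_unit <- function(Q, dbl, root_state, rate, unit, type, rec) {
    s <- integer(nnode); s[po$root] <- root_state
    for (e in rev(seq_len(nrow(po$edge)))) {
      par <- po$edge[e, 1L]; child <- po$edge[e, 2L]
      x <- s[par]; remain <- po$len[e] * rate
      repeat {
        out <- -Q[x, x]
        if (out <= 0) break
        w <- stats::rexp(1L, out)
        if (w > remain) break
        remain <- remain - w
        y <- sample.int(nrow(Q), 1L, prob = pmax(Q[x, ], 0) * (seq_len(nrow(Q)) != x))
        rec$events[[length(rec$events) + 1L]] <-
          list(unit = unit, type = type, edge = e, from = x, to = y,
               double = if (is.null(dbl)) FALSE else dbl[x, y])
        x <- y
      }
      s[child] <- x
    }
    s[seq_len(ntip)]
  }

  with_seed(seed, {
    rec <- new.env(); rec$events <- list()
    tips_i <- matrix(NA_integer_, ntip, ni)
    tips_e <- matrix(NA_integer_, ntip, np)
    for (j in seq_len(ni)) {
      r <- asrv$rates[sample.int(asrv$K, 1L)]
      root <- sample.int(4L, 1L, prob = params$base_freqs)
      tips_i[, j] <- gillespie_unit(Qi$Q, NULL, root, r, j, "iid", rec)
    }
    for (j in seq_len(np)) {
      r <- asrv$rates[sample.int(asrv$K, 1L)]
      root <- sample.int(16L, 1L, prob = params$doublet_freqs)
      tips_e[, j] <- gillespie_unit(Qe$Q, Qe$double, root, r, j, "pair", rec)
    }
    ev <- if (length(rec$events))
      do.call(rbind, lapply(rec$events, as.data.frame)) else
      data.frame(unit = integer(), type = character(), edge = integer(),
                 from = integer(), to = integer(), double = logical())
    list(events = ev, tips_iid = tips_i, tips_pair = tips_e,
         tip_labels = po$tree$tip.label)
  })
}
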