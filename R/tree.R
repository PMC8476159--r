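# Tree plumbing: synthetic simulation trees, Newick round trips, and small
# helpers shared by the simulator and the MCMC sampler.

#' Seeded synthetic simulation tree
#'
#' Generates a random coalescent-shaped tree and rescales its branch lengths
#' to a target tree length (sum of branch lengths).  The default target of
#' 4.58 expected substitutions gives, on average, about 4.58 substitutions
#' at each alignment column, a tree length typical of a moderately divergent
#' rRNA alignment.  This synthetic tree stands in for an empirically
#' estimated simulation tree.
#'
#' @param ntaxa Number of taxa (>= 4).
#' @param tree_length Target sum of branch lengths.
#' @param seed Integer seed; the tree is deterministic given the seed.
#' @param shape `"coalescent"` draws a random coalescent tree (realistic
#'   shape, but internal edges can be arbitrarily short); `"separated"`
#'   draws a random topology with edge lengths bounded away from zero, so
#'   every split is resolvable -- the shape used for small-taxon pipeline
#'   studies where topological mixing must not be dominated by effectively
#'   unresolvable edges.
#' @return An unrooted `ape::phylo` tree with taxon labels `t1 ... t<ntaxa>`.
#' @export
synthetic_tree <- function(ntaxa, tree_length = 4.58, seed = 1L,
                           shape = c("coalescent", "separated")) {
  if (ntaxa < 4L) stop("need at least 4 taxa")
  shape <- match.arg(shape)
  tr <- with_seed(seed, {
    if (shape == "coalescent") {
      ape::unroot(ape::rcoal(ntaxa, tip.label = paste0("t", seq_len(ntaxa))))
    } else {
      tr <- ape::unroot(ape::rtree(ntaxa, tip.label = paste0("t", seq_len(ntaxa))))
      internal <- tr$edge[, 2] > ntaxa
      tr$edge.length[internal] <- stats::runif(sum(internal), 0.5, 1.2)
      tr$edge.length[!internal] <- stats::runif(sum(!internal), 0.5, 1.5)
      tr
    }
  })
  tr$edge.length <- tr$edge.length * tree_length / sum(tr$edge.length)
  tr
}

#' Tree length
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return Sum of branch lengths.
#' @export
tree_length <- function(tree) sum(tree$edge.length)

#' Read and write Newick trees
#'
#' Thin wrappers over `ape` keeping branch lengths and polytomies intact.
#' `read_tree()` rejects negative branch lengths.
#'
#' @param path File path.
#' @param tree An `ape::phylo` tree.
#' @return `read_tree()` returns a `phylo`; `write_tree()` returns `path`
#'   invisibly.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("unparseable Newick file: ", path)
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch lengths in ", path)
  tr
}

#' @rdname read_tree
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# Run code with a local RNG state seeded from `seed`, restoring the caller's
# RNG afterwards.  All stochastic entry points funnel through this.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a stream of child seeds from a master seed by counter hashing;
# keeps cells of a campaign independently reproducible.  Values stay in
# [0, 2^31 - 2].
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + (as.double(k) + 1) * 65537) %% 2147483647
  }
  as.integer(h)
}

# Root an unrooted binary phylo at an internal node and return a postorder
# edge traversal; reversibility makes the rooting immaterial.
postorder_edges <- function(tree) {
  tr <- if (identical(attr(tree, "order"), "postorder")) tree
        else ape::reorder.phylo(tree, "postorder")
  list(tree = tr, edge = tr$edge, len = tr$edge.length,
       ntip = length(tr$tip.label),
       root = tr$edge[nrow(tr$edge), 1])
}
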