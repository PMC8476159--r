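# Split (bipartition) machinery and the accuracy / precision summaries of
# posterior tree samples: Robinson-Foulds distances, majority-rule consensus,
# resolution, and MRC error.

#' Nontrivial splits of a tree
#'
#' The set of bipartitions of the taxon set induced by the internal edges of
#' an (unrooted) tree.  Each split is canonicalized as the sorted set of
#' taxon labels on the side *not* containing the alphabetically first taxon,
#' so representations are comparable across trees with the same taxa.
#' Trivial splits (single taxon vs rest) are dropped.
#'
#' @param tree `ape::phylo`.
#' @return Character vector of canonical split keys (possibly empty).
#' @export
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 4L) return(character())
  anchor <- sort(tree$tip.label)[1L]
  po <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + po$Nnode
  desc <- vector("list", nnode)
  for (i in seq_len(ntip)) desc[[i]] <- po$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; child <- po$edge[e, 2L]
    desc[[par]] <- c(desc[[par]], desc[[child]])
  }
  keys <- character()
  for (e in seq_len(nrow(po$edge))) {
    child <- po$edge[e, 2L]
    if (child <= ntip) next                       # trivial
    side <- desc[[child]]
    if (anchor %in% side) side <- setdiff(po$tip.label, side)
    if (length(side) < 2L || length(side) > ntip - 2L) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

check_same_taxa <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share the same taxon set")
}

#' Robinson-Foulds distance
#'
#' The size of the symmetric difference of the nontrivial split sets of two
#' trees on the same taxa (raw, unnormalized count).  Two binary trees on t
#' taxa sharing no nontrivial split are at distance `2 * (t - 3)`.
#'
#' @param t1,t2 `ape::phylo` trees on the same taxon set.
#' @return Integer distance.
#' @export
rf_distance <- function(t1, t2) {
  check_same_taxa(t1, t2)
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

split_frequencies <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  ntree <- length(trees)
  if (ntree < 1L) stop("need at least one tree")
  all_keys <- unlist(lapply(trees, tree_splits))
  if (!length(all_keys))
    return(stats::setNames(numeric(), character()))
  tab <- table(all_keys) / ntree
  stats::setNames(as.numeric(tab), names(tab))
}

#' Majority-rule consensus tree
#'
#' The tree containing exactly the nontrivial splits occurring in strictly
#' more than half of the input trees (ties at exactly 50% are excluded).
#' Strict-majority splits are mutually compatible, so the tree always
#' exists; with no majority split it is the star tree.
#'
#' @param trees A list / `multiPhylo` of trees on the same taxa.
#' @return `ape::phylo` consensus tree (without branch lengths).
#' @export
mrc_tree <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  ntree <- length(trees)
  if (ntree < 1L) stop("need at least one tree")
  labels <- sort(trees[[1L]]$tip.label)
  freqs <- split_frequencies(trees)
  keep <- names(freqs)[freqs > 0.5]
  build_tree_from_splits(labels, keep)
}

# Assemble an unrooted tree from mutually compatible canonical split keys.
build_tree_from_splits <- function(labels, keys) {
  ntip <- length(labels)
  sets <- lapply(keys, function(k) strsplit(k, "|", fixed = TRUE)[[1L]])
  if (length(sets) > 1L) {
    for (i in seq_len(length(sets) - 1L)) for (j in (i + 1L):length(sets)) {
      a <- sets[[i]]; b <- sets[[j]]
      # canonical sets exclude the anchor taxon, so compatibility means
      # nested or disjoint
      if (length(intersect(a, b)) && !all(a %in% b) && !all(b %in% a))
        stop("internal error: incompatible majority splits")
    }
  }
  # resolve smallest splits first so larger splits group whole clusters
  ord <- order(vapply(sets, length, integer(1)))
  sets <- sets[ord]
  clusters <- stats::setNames(as.list(labels), labels)  # id -> tip members
  children <- stats::setNames(as.list(labels), labels)  # id -> newick piece
  active <- labels
  k <- 0L
  for (s in sets) {
    members <- active[vapply(active, function(id)
      all(clusters[[id]] %in% s), logical(1))]
    covered <- sort(unname(unlist(clusters[members])))
    if (!identical(covered, sort(s))) next  # incompatible leftovers guard
    k <- k + 1L
    id <- paste0("__c", k)
    clusters[[id]] <- unlist(clusters[members])
    children[[id]] <- paste0("(", paste(unlist(children[members]), collapse = ","), ")")
    active <- c(setdiff(active, members), id)
  }
  nwk <- paste0("(", paste(unlist(children[active]), collapse = ","), ");")
  tr <- ape::read.tree(text = nwk)
  ape::unroot(tr)
}

#' Resolution of a consensus tree
#'
#' The number of nontrivial splits in the tree divided by `t - 3`, the
#' maximum possible for t taxa: 0 for a star tree, 1 for a fully resolved
#' binary tree.
#'
#' @param mrc `ape::phylo` (typically from [mrc_tree()]).
#' @return Proportion in `[0, 1]`.
#' @export
resolution <- function(mrc) {
  t_ <- length(mrc$tip.label)
  if (t_ < 4L) stop("resolution needs at least 4 taxa")
  length(tree_splits(mrc)) / (t_ - 3L)
}

#' Proportion of erroneous splits in a consensus tree
#'
#' The proportion of nontrivial splits of `mrc` absent from the true tree.
#' For a star consensus (no splits) the error is defined as 0, with a
#' warning.
#'
#' @param mrc Consensus tree.
#' @param truth True tree (same taxa).
#' @return Proportion in `[0, 1]`.
#' @export
mrc_error <- function(mrc, truth) {
  check_same_taxa(mrc, truth)
  sm <- tree_splits(mrc)
  if (!length(sm)) {
    warning("star consensus tree: MRC error defined as 0")
    return(0)
  }
  st <- tree_splits(truth)
  length(setdiff(sm, st)) / length(sm)
}

#' Accuracy and precision summaries of a posterior tree sample
#'
#' Computes the RF distance of every sampled tree to the true tree and
#' summarizes the resulting distribution (mean, median, min, max, and the
#' width of the equal-tailed 95% interval using nearest-rank quantiles), plus
#' the majority-rule consensus tree's resolution and error proportion.
#'
#' @param trees Posterior tree sample (list / `multiPhylo`), possibly pooled
#'   across retained chains.
#' @param truth True tree.
#' @return A list with `rf` (vector of distances), `accuracy`
#'   (mean/median/min/max and `mrc_error`) and `precision`
#'   (`resolution`, `rf_ci_width`).
#' @export
posterior_summaries <- function(trees, truth) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("empty tree sample")
  ts <- tree_splits(truth)
  rf <- vapply(trees, function(tr) {
    s <- tree_splits(tr)
    length(setdiff(s, ts)) + length(setdiff(ts, s))
  }, numeric(1))
  mrc <- mrc_tree(trees)
  err <- withCallingHandlers(mrc_error(mrc, truth),
                             warning = function(w) invokeRestart("muffleWarning"))
  q <- stats::quantile(rf, c(0.025, 0.975), type = 1, names = FALSE)
  list(
    rf = rf,
    mrc = mrc,
    accuracy = c(rf_mean = mean(rf), rf_median = stats::median(rf),
                 rf_min = min(rf), rf_max = max(rf), mrc_error = err),
    precision = c(resolution = resolution(mrc), rf_ci_width = q[2] - q[1])
  )
}
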