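# Tree operations on ape "phylo" objects: Newick I/O, split arithmetic,
# strict consensus with collapsed-branch counting, binary-resolution
# counting, constraint-topology construction, fast-taxon pruning, UPGMA.

#' Read a Newick tree
#'
#' @param x a Newick string (contains parentheses) or a file path.
#' @return An ape \code{phylo} object.
#' @export
read_newick <- function(x) {
  tr <- if (grepl("(", x[1], fixed = TRUE))
    tryCatch(ape::read.tree(text = x), error = function(e) NULL,
             warning = function(w) NULL)
  else {
    if (!file.exists(x)) stop("file not found: ", x)
    tryCatch(ape::read.tree(x), error = function(e) NULL,
             warning = function(w) NULL)
  }
  if (is.null(tr)) stop("malformed Newick input")
  if (inherits(tr, "phylo") && anyDuplicated(tr$tip.label))
    stop("duplicate tip labels")
  tr
}

#' Write a tree (or list of trees) as Newick
#' @param tree a \code{phylo} or \code{multiPhylo}.
#' @param path optional output file; if missing, the string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}

# Canonical bitmask splits of an unrooted tree over sorted tip labels.
# Each non-trivial bipartition is a 0/1 string over sort(tip.label),
# normalized so the side containing the alphabetically first label is
# coded 0.  Trivial splits (singleton | rest) are excluded.
tree_splits <- function(tree, labels = NULL) {
  tree <- ape::unroot(tree)
  if (is.null(labels)) labels <- sort(tree$tip.label)
  ntip <- length(tree$tip.label)
  if (ntip < 4) return(character(0))
  bp <- ape::prop.part(tree)   # clades of the (arbitrarily) rooted form
  out <- character(0)
  for (cl in bp) {
    if (length(cl) <= 1 || length(cl) >= ntip - 1) next
    mask <- labels %in% tree$tip.label[cl]
    if (mask[1]) mask <- !mask
    if (sum(mask) < 2 || sum(!mask) < 2) next
    out <- c(out, paste(as.integer(mask), collapse = ""))
  }
  unique(out)
}

#' Strict consensus of two trees
#'
#' The consensus contains exactly the non-trivial bipartitions shared
#' by both (unrooted) trees.  \code{collapsed_count} is the number of
#' internal branches of the more resolved input that are lost in the
#' consensus; for two binary unrooted trees on n taxa it equals
#' (n - 3) - number of shared splits.
#'
#' @param treeA,treeB \code{phylo} objects on identical leaf sets.
#' @return A \code{consensus_result}: list with \code{tree},
#'   \code{shared_splits}, \code{collapsed_count}, \code{inputs_binary}.
#' @export
strict_consensus <- function(treeA, treeB) {
  la <- sort(treeA$tip.label)
  lb <- sort(treeB$tip.label)
  if (!identical(la, lb)) {
    d <- c(setdiff(la, lb), setdiff(lb, la))
    stop("leaf sets differ; symmetric difference: ",
         paste(d, collapse = ", "))
  }
  treeA <- ape::unroot(treeA)
  treeB <- ape::unroot(treeB)
  sa <- tree_splits(treeA, la)
  sb <- tree_splits(treeB, la)
  shared <- intersect(sa, sb)
  n <- length(la)
  binA <- length(sa) == n - 3
  binB <- length(sb) == n - 3
  collapsed <- max(length(sa), length(sb)) - length(shared)
  cons <- ape::consensus(treeA, treeB, p = 1, rooted = FALSE)
  structure(list(tree = cons, shared_splits = shared,
                 collapsed_count = collapsed,
                 inputs_binary = binA && binB),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Strict consensus:", length(x$shared_splits), "shared splits,",
      x$collapsed_count, "branches collapsed",
      if (!x$inputs_binary) "(multifurcating input)" else "", "\n")
  invisible(x)
}

double_factorial_odd <- function(x) {
  # (x)!! for odd x >= -1; (-1)!! = 1!! = 1
  if (x <= 1) return(1)
  prod(seq(1, x, by = 2))
}

#' Number of fully binary trees compatible with a multifurcating tree
#'
#' Product over internal nodes of degree d >= 4 of (2d - 5)!!; equals 1
#' for binary trees.  This is the size of the set of fully resolved
#' trees compatible with a strict consensus tree, used by the
#' Bonferroni correction of the topology chi-squared test.
#'
#' @param tree an unrooted \code{phylo} (rooted input is unrooted
#'   first).
#' @return Integer count (as double, since counts grow fast).
#' @export
count_binary_resolutions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  deg <- tabulate(tree$edge, nbins = ntip + tree$Nnode)
  internal <- deg[(ntip + 1):(ntip + tree$Nnode)]
  prod(vapply(internal[internal >= 4],
              function(d) double_factorial_odd(2 * d - 5), numeric(1)))
}

flat_clade <- function(members) paste0("(", paste(members, collapse = ","), ")")

#' Build the six leptophyte placement constraint topologies
#'
#' Three candidate placements of the leptophyte clade within the
#' cryptophyte-haptophyte-leptophyte (CHL) group -- sister to
#' haptophytes+cryptophytes (HC-sister), sister to haptophytes only
#' (H-sister), sister to cryptophytes only (C-sister) -- crossed with
#' two treatments of the remaining red-complex lineages: complex
#' plastids constrained monophyletic, or left unconstrained.  Group
#' interiors are unresolved (multifurcating) so only the named
#' relationships are constrained.
#'
#' @param leptophytes,haptophytes,cryptophytes,other_red_complex,red_algae
#'   disjoint, non-empty character vectors of taxon labels.
#' @return Named list of six multifurcating \code{phylo} constraint
#'   trees: HC_sister/H_sister/C_sister x mono/free.
#' @export
build_constraint_set <- function(leptophytes, haptophytes, cryptophytes,
                                 other_red_complex, red_algae) {
  groups <- list(leptophytes = leptophytes, haptophytes = haptophytes,
                 cryptophytes = cryptophytes,
                 other_red_complex = other_red_complex,
                 red_algae = red_algae)
  if (any(lengths(groups) == 0))
    stop("all five groups must be non-empty (missing: ",
         paste(names(groups)[lengths(groups) == 0], collapse = ", "), ")")
  all_labs <- unlist(groups)
  if (anyDuplicated(all_labs))
    stop("groups overlap: ",
         paste(unique(all_labs[duplicated(all_labs)]), collapse = ", "))
  L <- flat_clade(leptophytes)
  H <- flat_clade(haptophytes)
  C <- flat_clade(cryptophytes)
  chl <- c(
    HC_sister = paste0("(", L, ",(", H, ",", C, "))"),
    H_sister  = paste0("((", L, ",", H, "),", C, ")"),
    C_sister  = paste0("((", L, ",", C, "),", H, ")"))
  O <- paste(other_red_complex, collapse = ",")
  R <- paste(red_algae, collapse = ",")
  out <- list()
  for (pl in names(chl)) {
    out[[paste0(pl, "_mono")]] <-
      read_newick(paste0("((", chl[[pl]], ",", O, "),", R, ");"))
    out[[paste0(pl, "_free")]] <-
      read_newick(paste0("(", chl[[pl]], ",", O, ",", R, ");"))
  }
  for (nm in names(out))
    stopifnot(is_compatible(out[[nm]], out[[nm]]))
  out
}

#' Is a tree compatible with a constraint topology?
#'
#' TRUE iff every non-trivial split of the constraint, restricted to
#' the shared leaf set, is a split of the tree.
#'
#' @param tree a \code{phylo}; its leaf set must contain the
#'   constraint's.
#' @param constraint a (possibly multifurcating) \code{phylo}.
#' @return Logical.
#' @export
is_compatible <- function(tree, constraint) {
  extra <- setdiff(constraint$tip.label, tree$tip.label)
  if (length(extra))
    stop("constraint leaves missing from tree: ",
         paste(extra, collapse = ", "))
  labs <- sort(constraint$tip.label)
  sub <- if (length(setdiff(tree$tip.label, labs)))
    ape::keep.tip(tree, constraint$tip.label) else tree
  cs <- tree_splits(constraint, labs)
  if (length(cs) == 0) return(TRUE)
  all(cs %in% tree_splits(sub, labs))
}

#' Remove the fastest-evolving leaves by root-to-tip distance
#'
#' @param tree a rooted \code{phylo} with branch lengths.
#' @param n number of leaves to remove (ties broken by label order).
#' @return List with \code{tree} (pruned, degree-2 nodes suppressed)
#'   and \code{removed} (labels, in removal order).
#' @export
remove_fastest_taxa <- function(tree, n) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ntip <- length(tree$tip.label)
  if (n >= ntip) stop("cannot remove ", n, " of ", ntip, " leaves")
  if (n == 0) return(list(tree = tree, removed = character(0)))
  depth <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
  ord <- order(-depth, tree$tip.label)
  removed <- tree$tip.label[ord[seq_len(n)]]
  list(tree = ape::drop.tip(tree, removed), removed = removed)
}

#' UPGMA clustering
#'
#' Average-linkage agglomeration of a symmetric distance matrix; node
#' heights are half the merge distance, so the output is rooted and
#' ultrametric.
#'
#' @param d symmetric non-negative matrix with zero diagonal (or a
#'   \code{dist}).
#' @param labels optional labels overriding the matrix dimnames.
#' @return A rooted ultrametric \code{phylo}.
#' @export
upgma <- function(d, labels = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (any(d < 0)) stop("distances must be non-negative")
  if (!is.null(labels)) dimnames(d) <- list(labels, labels)
  if (is.null(rownames(d)))
    dimnames(d) <- list(paste0("t", seq_len(nrow(d))),
                        paste0("t", seq_len(nrow(d))))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  tr <- ape::as.phylo(hc)
  # as.phylo.hclust puts tips at depth h/2 below each merge: ultrametric
  tr
}

#' The two clades under the root of a rooted tree
#' @param tree rooted \code{phylo} whose root has exactly two children.
#' @return List of two character vectors of tip labels.
#' @export
root_split <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  if (length(kids) != 2) stop("root is not bifurcating")
  clade_tips <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    ape::extract.clade(tree, node)$tip.label
  }
  lapply(kids, clade_tips)
}
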