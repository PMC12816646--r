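# Gene presence/absence matrix construction, UPGMA clustering of taxa
# and genes, and Dollo-parsimony loss counting under alternative
# host-tree scenarios.

#' Build a gene presence/absence matrix from an ortholog table
#'
#' Presence = copy count >= 1; genes present in fewer than
#' \code{min_taxa} taxa are dropped (logged in the \code{dropped}
#' attribute).
#'
#' @param ortholog_table data frame with columns gene, taxon, count.
#' @param min_taxa minimum taxa a gene must occur in (default 3).
#' @return A \code{gene_matrix}: list with \code{taxa}, \code{genes},
#'   \code{matrix} (binary taxa x genes), \code{dropped}.
#' @export
build_matrix <- function(ortholog_table, min_taxa = 3) {
  stopifnot(all(c("gene", "taxon", "count") %in% names(ortholog_table)))
  taxa <- sort(unique(ortholog_table$taxon))
  genes <- sort(unique(ortholog_table$gene))
  m <- matrix(0L, length(taxa), length(genes),
              dimnames = list(taxa, genes))
  pres <- ortholog_table[ortholog_table$count >= 1, ]
  m[cbind(match(pres$taxon, taxa), match(pres$gene, genes))] <- 1L
  keep <- colSums(m) >= min_taxa
  structure(list(taxa = taxa, genes = genes[keep],
                 matrix = m[, keep, drop = FALSE],
                 dropped = genes[!keep]),
            class = "gene_matrix")
}

#' Construct a gene matrix directly from a binary matrix
#' @param m binary matrix taxa x genes with dimnames.
#' @return A \code{gene_matrix}.
#' @export
gene_matrix <- function(m) {
  stopifnot(is.matrix(m), all(m %in% c(0, 1)),
            !is.null(rownames(m)), !is.null(colnames(m)))
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("duplicate taxon or gene names")
  structure(list(taxa = rownames(m), genes = colnames(m),
                 matrix = m, dropped = character(0)),
            class = "gene_matrix")
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat("Gene matrix:", length(x$taxa), "taxa x", length(x$genes), "genes\n")
  invisible(x)
}

#' UPGMA clustering of a gene matrix axis
#'
#' Pairwise distances between the binary vectors of the chosen axis
#' (euclidean, or jaccard = |symmetric difference| / |union|), then
#' UPGMA.
#'
#' @param gm a \code{gene_matrix}.
#' @param axis \code{"taxa"} or \code{"genes"}.
#' @param metric \code{"euclidean"} or \code{"jaccard"}.
#' @return A rooted ultrametric \code{phylo}.
#' @export
cluster_matrix <- function(gm, axis = c("taxa", "genes"),
                           metric = c("euclidean", "jaccard")) {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  m <- if (axis == "taxa") gm$matrix else t(gm$matrix)
  if (nrow(m) < 2) stop("need at least 2 items on axis ", axis)
  d <- if (metric == "euclidean") stats::dist(m)
       else stats::dist(m, method = "binary")
  upgma(as.matrix(d))
}

# All-absent clades: for one gene's presence vector over tree tips,
# minimum Dollo losses = number of maximal subtrees whose leaves all
# lack the gene.
count_dollo_losses <- function(tree, present) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  absent <- rep(NA, ntip + tree$Nnode)
  absent[seq_len(ntip)] <- !present[tree$tip.label]
  tre <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tre$edge))) {
    par <- tre$edge[e, 1]; chi <- tre$edge[e, 2]
    if (is.na(absent[par])) absent[par] <- TRUE
    absent[par] <- absent[par] && absent[chi]
  }
  if (absent[root]) return(list(losses = 1L, everywhere_absent = TRUE))
  parent <- integer(ntip + tree$Nnode)
  parent[tre$edge[, 2]] <- tre$edge[, 1]
  maximal <- which(absent & !absent[pmax(parent, 1L)] &
                   seq_along(absent) != root)
  list(losses = length(maximal), everywhere_absent = FALSE)
}

#' Dollo-parsimony gene losses on a host tree
#'
#' Assumes every gene present at the origin (root of the scenario
#' tree) with no regain; the minimum loss count per gene is the number
#' of maximal clades whose leaves all lack the gene.  Genes absent
#' from every taxon score one loss at the origin and are flagged.
#'
#' @param gm a \code{gene_matrix}.
#' @param host_tree rooted \code{phylo}; its leaves must include all
#'   matrix taxa (extra leaves are pruned).
#' @return A \code{loss_report}: list with \code{per_gene} (named
#'   integer vector), \code{total}, \code{flagged_absent} (genes
#'   absent everywhere), \code{tree}.
#' @export
dollo_losses <- function(gm, host_tree) {
  missing <- setdiff(gm$taxa, host_tree$tip.label)
  if (length(missing))
    stop("matrix taxa missing from tree: ", paste(missing, collapse = ", "))
  tree <- if (length(setdiff(host_tree$tip.label, gm$taxa)))
    ape::keep.tip(host_tree, gm$taxa) else host_tree
  per_gene <- integer(length(gm$genes))
  names(per_gene) <- gm$genes
  flagged <- character(0)
  for (g in gm$genes) {
    present <- stats::setNames(gm$matrix[, g] == 1, gm$taxa)
    res <- count_dollo_losses(tree, present)
    per_gene[g] <- res$losses
    if (res$everywhere_absent) flagged <- c(flagged, g)
  }
  structure(list(per_gene = per_gene, total = sum(per_gene),
                 flagged_absent = flagged, tree = tree),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat("Dollo losses:", x$total, "total over", length(x$per_gene), "genes\n")
  invisible(x)
}

#' Compare Dollo loss totals under two host-tree scenarios
#'
#' @param gm a \code{gene_matrix}.
#' @param scenarioA,scenarioB rooted \code{phylo} scenario trees.
#' @return List with \code{totalA}, \code{totalB}, and a per-gene data
#'   frame of losses and their difference (A - B).
#' @export
compare_scenarios <- function(gm, scenarioA, scenarioB) {
  ra <- dollo_losses(gm, scenarioA)
  rb <- dollo_losses(gm, scenarioB)
  list(totalA = ra$total, totalB = rb$total,
       per_gene = data.frame(gene = gm$genes,
                             lossesA = unname(ra$per_gene),
                             lossesB = unname(rb$per_gene),
                             diff = unname(ra$per_gene - rb$per_gene),
                             stringsAsFactors = FALSE))
}
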