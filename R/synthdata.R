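# Seeded generators for every input the pipeline consumes, with ground
# truth recorded so all stages are testable without external data.

truth_record <- function(generator, seed, ...) {
  structure(list(generator = generator, seed = seed, params = list(...)),
            class = "truth_record")
}

#' Write a truth record as a plain-text key-value file
#' @param truth a \code{truth_record}.
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  fmt <- function(v) paste(format(unlist(v), digits = 12), collapse = ",")
  lines <- c(paste0("generator=", truth$generator),
             paste0("seed=", truth$seed),
             vapply(names(truth$params), function(n)
               paste0(n, "=", fmt(truth$params[[n]])), character(1)))
  writeLines(lines, path)
  invisible(path)
}

# Descendant node set (incl. the mrca) of a clade given by tip labels.
clade_nodes <- function(tree, tips) {
  ntip <- length(tree$tip.label)
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("clade tips not in tree")
  if (length(idx) == 1) return(idx)
  mrca <- ape::getMRCA(tree, idx)
  nodes <- mrca
  repeat {
    kids <- tree$edge[tree$edge[, 1] %in% nodes, 2]
    new <- setdiff(kids, nodes)
    if (length(new) == 0) break
    nodes <- c(nodes, new)
  }
  nodes
}

#' Simulate an alignment on a known tree
#'
#' Root states are drawn from the model's equilibrium frequencies and
#' evolved along each branch by P(t r) with a discrete-gamma rate r
#' per site.  An optional compositional shift substitutes, on every
#' branch inside a named clade (including its stem), the rate matrix
#' built from the displaced frequencies pi' proportional to
#' pi exp(delta), so the shifted clade remains a proper Markov
#' process.
#'
#' @param tree rooted or unrooted \code{phylo} with branch lengths.
#' @param model a \code{subst_model}.
#' @param n_sites number of sites.
#' @param seed RNG seed.
#' @param shift optional list(clade = tip labels, delta = length-k
#'   displacement vector).
#' @return List with \code{alignment} and \code{truth}.
#' @export
sim_alignment <- function(tree, model, n_sites, seed, shift = NULL) {
  set.seed(seed)
  k <- model$k
  states <- if (is.null(model$states)) as.character(seq_len(k)) else
    model$states
  ntip <- length(tree$tip.label)
  if (n_sites == 0) {
    aln <- alignment(matrix(character(0), ntip, 0,
                            dimnames = list(tree$tip.label, NULL)),
                     alphabet = states)
    return(list(alignment = aln,
                truth = truth_record("sim_alignment", seed, n_sites = 0)))
  }
  shifted_model <- NULL
  shift_nodes <- integer(0)
  if (!is.null(shift)) {
    delta <- shift$delta
    if (length(delta) != k) stop("delta must have length k")
    pi2 <- model$freqs * exp(delta)
    if (any(pi2 <= 0) || !all(is.finite(pi2)))
      stop("invalid delta: displaced frequencies leave the simplex")
    pi2 <- pi2 / sum(pi2)
    shifted_model <- subst_model(model$S, pi2, alpha = model$alpha,
                                 m = model$m,
                                 name = paste0(model$name, "+shift"))
    shift_nodes <- clade_nodes(tree, shift$clade)
  }
  cat_id <- sample.int(model$m, n_sites, replace = TRUE)
  rates <- model$rates[cat_id]
  root <- ntip + 1L
  state <- matrix(NA_integer_, ntip + tree$Nnode, n_sites)
  state[root, ] <- sample.int(k, n_sites, replace = TRUE,
                              prob = model$freqs)
  tre <- ape::reorder.phylo(tree, "postorder")
  edges <- nrow(tre$edge):1   # preorder = reverse postorder
  for (e in edges) {
    par <- tre$edge[e, 1]; chi <- tre$edge[e, 2]
    mod <- if (chi %in% shift_nodes) shifted_model else model
    t0 <- tre$edge.length[e]
    for (cat in unique(cat_id)) {
      sel <- cat_id == cat
      Pm <- transition_probs(mod, t0 * model$rates[cat])
      from <- state[par, sel]
      to <- integer(sum(sel))
      for (s in unique(from)) {
        n_s <- sum(from == s)
        to[from == s] <- sample.int(k, n_s, replace = TRUE, prob = Pm[s, ])
      }
      state[chi, sel] <- to
    }
  }
  m <- matrix(states[state[seq_len(ntip), , drop = FALSE]], nrow = ntip,
              dimnames = list(tree$tip.label, NULL))
  aln <- alignment(m, alphabet = states)
  list(alignment = aln,
       truth = truth_record("sim_alignment", seed, n_sites = n_sites,
                            model = model$name,
                            tree = write_newick(tree),
                            shift_clade = if (is.null(shift)) NA else
                              paste(shift$clade, collapse = ","),
                            shift_delta = if (is.null(shift)) NA else
                              shift$delta))
}

#' Simulate an organelle gene complement with planted QC truth
#'
#' Samples round(completeness_frac * size) marker genes as present and
#' duplicates round(redundancy_frac * size) of them, so the QC
#' estimator recovers the planted fractions exactly.
#'
#' @param markers a \code{marker_set}.
#' @param completeness_frac,redundancy_frac fractions in [0, 1]
#'   (redundant copies are drawn from the present genes, so
#'   redundancy_frac <= completeness_frac).
#' @param seed RNG seed.
#' @return List with \code{genes} (multiset as character vector) and
#'   \code{truth}.
#' @export
sim_genome_complement <- function(markers, completeness_frac,
                                  redundancy_frac, seed) {
  stopifnot(completeness_frac >= 0, completeness_frac <= 1,
            redundancy_frac >= 0, redundancy_frac <= 1)
  set.seed(seed)
  n_pres <- round(completeness_frac * markers$size)
  n_dup <- round(redundancy_frac * markers$size)
  if (n_dup > n_pres)
    stop("redundancy_frac implies more duplicates than present genes")
  present <- sample(markers$genes, n_pres)
  dups <- if (n_dup > 0) sample(present, n_dup) else character(0)
  list(genes = sort(c(present, dups)),
       truth = truth_record("sim_genome_complement", seed,
                            completeness = 100 * n_pres / markers$size,
                            redundancy = 100 * n_dup / markers$size))
}

#' Simulate a coverage table with planted correlated organelle pairs
#'
#' Per-genome log-coverage across samples is Gaussian; each planted
#' pair (i, j, rho) shares a latent factor achieving correlation rho on
#' the log scale.  Detection increases with coverage (noisy saturating
#' curve) and random dropouts force detection below 0.25.
#'
#' @param n_genomes,n_samples table dimensions.
#' @param linked_pairs data frame with columns i, j, rho (genome
#'   indices) or NULL.
#' @param meanlog,sdlog log-normal coverage parameters.
#' @param dropout_rate per-cell probability of a detection dropout.
#' @param seed RNG seed.
#' @return List with \code{coverage} (data frame genome, sample,
#'   mean_coverage, detection) and \code{truth}.
#' @export
sim_coverage <- function(n_genomes, n_samples, linked_pairs = NULL,
                         meanlog = 1, sdlog = 1, dropout_rate = 0.1,
                         seed = 1) {
  set.seed(seed)
  z <- matrix(stats::rnorm(n_genomes * n_samples), n_genomes, n_samples)
  if (!is.null(linked_pairs)) {
    for (q in seq_len(nrow(linked_pairs))) {
      i <- linked_pairs$i[q]; j <- linked_pairs$j[q]
      rho <- linked_pairs$rho[q]
      stopifnot(rho >= -1, rho <= 1)
      z[j, ] <- rho * z[i, ] + sqrt(1 - rho^2) * z[j, ]
    }
  }
  cov <- exp(meanlog + sdlog * z)
  det <- 1 - exp(-cov / 2)
  det <- pmin(1, pmax(0, det + stats::rnorm(length(det), 0, 0.03)))
  drop <- matrix(stats::runif(length(det)) < dropout_rate,
                 n_genomes, n_samples)
  det[drop] <- stats::runif(sum(drop), 0, 0.25)
  gid <- paste0("G", formatC(seq_len(n_genomes), width = 3, flag = "0"))
  sid <- paste0("S", formatC(seq_len(n_samples), width = 3, flag = "0"))
  df <- data.frame(genome = rep(gid, times = n_samples),
                   sample = rep(sid, each = n_genomes),
                   mean_coverage = as.vector(cov),
                   detection = as.vector(det),
                   stringsAsFactors = FALSE)
  list(coverage = df,
       truth = truth_record("sim_coverage", seed,
                            n_genomes = n_genomes, n_samples = n_samples,
                            meanlog = meanlog, sdlog = sdlog,
                            dropout_rate = dropout_rate,
                            linked = if (is.null(linked_pairs)) NA else
                              apply(linked_pairs, 1, paste, collapse = ":")))
}

#' Simulate gene presence/absence by Dollo loss on a tree
#'
#' Every gene is present at the root; loss events occur as Poisson
#' events on branches (rate per unit branch length); all descendants
#' of a loss lack the gene.
#'
#' @param host_tree rooted \code{phylo} with branch lengths.
#' @param n_genes number of genes.
#' @param loss_rate Poisson loss rate per unit branch length.
#' @param seed RNG seed.
#' @return List with \code{gene_matrix}, \code{truth} (per-gene event
#'   counts in \code{params$events}).
#' @export
sim_dollo <- function(host_tree, n_genes, loss_rate, seed) {
  stopifnot(loss_rate >= 0)
  set.seed(seed)
  ntip <- length(host_tree$tip.label)
  tre <- ape::reorder.phylo(host_tree, "postorder")
  edges <- nrow(tre$edge):1   # preorder
  m <- matrix(1L, ntip, n_genes,
              dimnames = list(host_tree$tip.label,
                              paste0("g", formatC(seq_len(n_genes),
                                                  width = 3, flag = "0"))))
  events <- integer(n_genes)
  for (g in seq_len(n_genes)) {
    lost <- rep(FALSE, ntip + host_tree$Nnode)
    for (e in edges) {
      par <- tre$edge[e, 1]; chi <- tre$edge[e, 2]
      if (lost[par]) { lost[chi] <- TRUE; next }
      hit <- stats::rpois(1, loss_rate * tre$edge.length[e]) > 0
      if (hit) {
        events[g] <- events[g] + 1L
        lost[chi] <- TRUE
      }
    }
    m[, g] <- as.integer(!lost[seq_len(ntip)])
  }
  list(gene_matrix = gene_matrix(m),
       truth = truth_record("sim_dollo", seed, n_genes = n_genes,
                            loss_rate = loss_rate, events = events))
}
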