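# Desk-scale fixed-topology likelihood engine: Felsenstein pruning with
# discrete-gamma rates, optional fixed site-frequency profiles, simple
# coordinate-wise branch-length optimization, and site-lnL table I/O.

# Encode alignment columns as integer patterns ordered like tree tips.
# Returns list(codes = k-coded taxa x sites matrix rows ordered as
# tip.label, pattern_id = site -> pattern, patterns = matrix of unique
# pattern columns, weights).
compress_patterns <- function(aln, tree, extra_key = NULL) {
  if (!setequal(tree$tip.label, aln$taxa))
    stop("tree leaves and alignment taxa differ: ",
         paste(c(setdiff(tree$tip.label, aln$taxa),
                 setdiff(aln$taxa, tree$tip.label)), collapse = ", "))
  codes <- encode_states(aln)[tree$tip.label, , drop = FALSE]
  key <- apply(codes, 2, paste, collapse = ",")
  if (!is.null(extra_key)) key <- paste(key, extra_key)
  uid <- match(key, unique(key))
  first <- !duplicated(uid)
  list(patterns = codes[, first, drop = FALSE],
       pattern_id = uid, weights = tabulate(uid))
}

# Build a pruning closure for fixed patterns/topology/model.  The
# returned function maps a branch-length vector (in the postorder edge
# order of its `tree` element) to per-pattern log-likelihoods.
# patterns: ntip x P integer matrix (0 = missing), rows ordered like
# tree$tip.label.  Categories averaged with equal weights.
make_pruner <- function(patterns, tree, model) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  P <- ncol(patterns)
  k <- model$k
  tre <- ape::reorder.phylo(tree, "postorder")
  edge <- tre$edge
  root <- ntip + 1L
  leaves <- lapply(seq_len(ntip), function(i) {
    L <- matrix(0, k, P)
    s <- patterns[i, ]
    miss <- s == 0L
    L[cbind(s[!miss], which(!miss))] <- 1
    L[, miss] <- 1
    L
  })
  # fast path: no per-node rescaling (safe at desk scale); columns that
  # underflow to exactly zero are redone with log-scaling
  eval_cat <- function(elen, r, scale) {
    partial <- vector("list", ntip + nnode)
    logscale <- if (scale) numeric(P) else NULL
    for (e in seq_len(nrow(edge))) {
      par <- edge[e, 1]; chi <- edge[e, 2]
      Lc <- if (chi <= ntip) leaves[[chi]] else partial[[chi]]
      contrib <- transition_probs(model, elen[e] * r) %*% Lc
      partial[[par]] <- if (is.null(partial[[par]])) contrib
                        else partial[[par]] * contrib
      if (scale) {
        pp <- partial[[par]]
        mx <- pp[1, ]
        for (row in 2:k) mx <- pmax(mx, pp[row, ])
        pos <- mx > 0
        sc <- ifelse(pos, mx, 1)
        partial[[par]] <- pp / rep(sc, each = k)
        logscale <- logscale + ifelse(pos, log(mx), -Inf)
      }
    }
    lik <- .colSums(model$freqs * partial[[root]], k, P)
    if (scale) ifelse(lik > 0, log(lik) + logscale, -Inf)
    else ifelse(lik > 0, log(lik), NA_real_)   # NA = underflow or impossible
  }
  fn <- function(elen) {
    if (P == 0) return(numeric(0))
    if (any(elen < 0)) stop("negative branch lengths")
    percat <- matrix(NA_real_, model$m, P)
    for (cat in seq_len(model$m)) {
      r <- model$rates[cat]
      v <- eval_cat(elen, r, scale = FALSE)
      if (anyNA(v)) v <- eval_cat(elen, r, scale = TRUE)
      percat[cat, ] <- v
    }
    if (model$m == 1) return(percat[1, ])
    mx <- apply(percat, 2, max)
    ifelse(is.finite(mx),
           mx + log(colMeans(exp(sweep(percat, 2, mx, `-`)))),
           -Inf)
  }
  list(fn = fn, tree = tre)
}

# Per-pattern log-likelihood (one-shot convenience over make_pruner).
prune_loglik <- function(patterns, tree, model) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  pr <- make_pruner(patterns, tree, model)
  pr$fn(pr$tree$edge.length)
}

#' Per-site log-likelihoods on a fixed tree
#'
#' Felsenstein pruning under a reversible model with discrete-gamma
#' rates.  Gaps and ambiguities are missing data (partial likelihood 1
#' in every state).  With \code{profiles}, each site uses its assigned
#' fixed frequency profile in place of the model frequencies (PMSF
#' style), keeping the shared exchangeabilities.
#'
#' @param aln an \code{alignment} whose taxa equal the tree's leaves.
#' @param tree a \code{phylo} with branch lengths (rooting
#'   irrelevant for reversible models).
#' @param model a \code{subst_model}.
#' @param profiles optional \code{site_profiles}.
#' @return Numeric vector of per-site log-likelihoods (-Inf for
#'   impossible patterns, with a warning).
#' @export
site_log_likelihoods <- function(aln, tree, model, profiles = NULL) {
  if (is.null(profiles)) {
    cp <- compress_patterns(aln, tree)
    lnl_pat <- prune_loglik(cp$patterns, tree, model)
    out <- lnl_pat[cp$pattern_id]
  } else {
    if (length(profiles$assignment) != n_sites(aln))
      stop("profile assignment length != number of sites")
    cp <- compress_patterns(aln, tree, extra_key = profiles$assignment)
    pat_class <- profiles$assignment[!duplicated(cp$pattern_id)]
    lnl_pat <- numeric(ncol(cp$patterns))
    for (cl in unique(pat_class)) {
      mod_cl <- subst_model(model$S, profiles$profiles[cl, ],
                            alpha = model$alpha, m = model$m,
                            name = paste0(model$name, "/profile", cl))
      sel <- pat_class == cl
      lnl_pat[sel] <- prune_loglik(cp$patterns[, sel, drop = FALSE],
                                   tree, mod_cl)
    }
    out <- lnl_pat[cp$pattern_id]
  }
  if (any(!is.finite(out)))
    warning("impossible site pattern(s): -Inf log-likelihood")
  out
}

#' Total log-likelihood (sum over sites)
#' @inheritParams site_log_likelihoods
#' @return Scalar log-likelihood.
#' @export
total_log_likelihood <- function(aln, tree, model, profiles = NULL) {
  if (n_sites(aln) == 0) return(0)
  sum(site_log_likelihoods(aln, tree, model, profiles))
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate-wise bracketed scalar optimization of each branch length
#' on [0, 10], sweeping until the total log-likelihood improves by less
#' than \code{tol} or \code{max_sweeps} is reached.  The log-likelihood
#' is non-decreasing across sweeps.
#'
#' @param aln an \code{alignment}.
#' @param topology a \code{phylo}; any existing branch lengths are
#'   discarded and all branches start at 0.1.
#' @param model a \code{subst_model}.
#' @param profiles optional \code{site_profiles}.
#' @param tol sweep-level convergence tolerance on the log-likelihood.
#' @param max_sweeps maximum number of sweeps.
#' @return List with \code{tree} (branch lengths filled in),
#'   \code{lnL}, and \code{sweeps}.
#' @export
optimize_branch_lengths <- function(aln, topology, model, profiles = NULL,
                                    tol = 1e-4, max_sweeps = 100) {
  tree <- topology
  tree$edge.length <- rep(0.1, nrow(tree$edge))
  cp <- compress_patterns(aln, tree,
                          extra_key = if (is.null(profiles)) NULL
                                      else profiles$assignment)
  pat_class <- if (is.null(profiles)) NULL
               else profiles$assignment[!duplicated(cp$pattern_id)]
  if (is.null(profiles)) {
    pruners <- list(make_pruner(cp$patterns, tree, model))
    weights <- list(cp$weights)
  } else {
    classes <- sort(unique(pat_class))
    pruners <- lapply(classes, function(cl)
      make_pruner(cp$patterns[, pat_class == cl, drop = FALSE], tree,
                  subst_model(model$S, profiles$profiles[cl, ],
                              alpha = model$alpha, m = model$m,
                              name = model$name)))
    weights <- lapply(classes, function(cl) cp$weights[pat_class == cl])
  }
  tre <- pruners[[1]]$tree          # shared postorder topology
  elen <- tre$edge.length
  lnl_of <- function(el) {
    tot <- 0
    for (q in seq_along(pruners))
      tot <- tot + sum(weights[[q]] * pruners[[q]]$fn(el))
    tot
  }
  cur <- lnl_of(elen)
  if (!is.finite(cur)) stop("non-finite log-likelihood at initial lengths")
  for (sweep in seq_len(max_sweeps)) {
    prev <- cur
    for (e in seq_along(elen)) {
      f <- function(t) {
        el <- elen
        el[e] <- t
        lnl_of(el)
      }
      opt <- stats::optimize(f, c(0, 10), maximum = TRUE, tol = 1e-6)
      # consider the boundary 0 explicitly: optimize never returns an edge
      val0 <- f(0)
      if (val0 >= opt$objective) {
        cand <- 0; obj <- val0
      } else {
        cand <- opt$maximum; obj <- opt$objective
      }
      if (obj >= cur) {
        elen[e] <- cand
        cur <- obj
      }
    }
    if (cur - prev < tol) break
  }
  tre$edge.length <- elen
  list(tree = tre, lnL = cur, sweeps = sweep)
}

#' Read a site log-likelihood table
#'
#' Dialect: line 1 is \code{"<K> <N>"}; then K lines of
#' \code{"<label> v1 ... vN"}, whitespace-delimited.
#'
#' @param path input file.
#' @return Numeric matrix topologies x sites with topology labels as
#'   row names.
#' @export
read_sitelh <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || any(is.na(hdr)))
    stop("malformed site-lnL header: ", lines[1])
  K <- hdr[1]; N <- hdr[2]
  if (length(lines) != K + 1)
    stop("expected ", K, " rows, found ", length(lines) - 1)
  out <- matrix(NA_real_, K, N)
  labs <- character(K)
  for (i in seq_len(K)) {
    tok <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(tok) != N + 1)
      stop("row ", i, " has ", length(tok) - 1, " values, expected ", N)
    labs[i] <- tok[1]
    out[i, ] <- as.numeric(tok[-1])
  }
  if (anyNA(out)) stop("non-numeric site log-likelihood values")
  rownames(out) <- labs
  out
}

#' Write a site log-likelihood table
#' @param m numeric matrix topologies x sites with row names.
#' @param path output file.
#' @export
write_sitelh <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(m), ncol(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(rownames(m)[i],
                     paste(formatC(m[i, ], format = "g", digits = 10),
                           collapse = " ")), con)
  invisible(path)
}
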