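# Stuart's test of marginal homogeneity between aligned sequence pairs,
# and the greedy stationarity-based column trimmer built on it.

# Integer-code an alignment: 0 = gap/missing, 1..k = alphabet states.
encode_states <- function(aln) {
  codes <- match(aln$matrix, aln$alphabet)
  codes[is.na(codes)] <- 0L
  matrix(codes, nrow = n_taxa(aln), dimnames = dimnames(aln$matrix))
}

# Core Stuart statistic from a k x k contingency table of paired states.
# d_u = rowsum_u - colsum_u (u = 1..k-1); V_uu = rowsum_u + colsum_u -
# 2 N_uu, V_uv = -(N_uv + N_vu); W = d' V^- d with a Moore-Penrose
# pseudo-inverse when V is singular (df = numerical rank).
stuart_statistic <- function(N) {
  k <- nrow(N)
  rs <- rowSums(N)
  cs <- colSums(N)
  d <- (rs - cs)[-k]
  S <- N + t(N)
  V <- -S[-k, -k, drop = FALSE]
  diag(V) <- (rs + cs - 2 * diag(N))[-k]
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-10 * max(abs(ev), 1)
  rank <- sum(ev > tol)
  singular <- rank < (k - 1)
  if (rank == 0L) {
    W <- 0
  } else if (!singular) {
    W <- as.numeric(crossprod(d, solve(V, d)))
  } else {
    W <- as.numeric(crossprod(d, MASS::ginv(V, tol = 1e-10) %*% d))
  }
  W <- max(W, 0)
  p <- if (rank == 0L || W <= 1e-12) 1 else
    stats::pchisq(W, df = rank, lower.tail = FALSE)
  list(W = W, df = rank, p = p, d = d, V = V, singular = singular)
}

#' Stuart's test of marginal homogeneity for a pair of taxa
#'
#' Builds the k x k table of paired states over sites where both taxa
#' are ungapped and tests whether the two marginal state distributions
#' are equal.  A significant result indicates non-stationary
#' composition between the two sequences.
#'
#' @param aln an \code{alignment}.
#' @param taxonA,taxonB taxon labels.
#' @return A \code{stuart_result}: list with \code{pair}, \code{table},
#'   \code{d}, \code{V}, \code{W}, \code{df}, \code{p},
#'   \code{singular}.
#' @export
stuart_test <- function(aln, taxonA, taxonB) {
  ia <- match_taxon(aln, taxonA)
  ib <- match_taxon(aln, taxonB)
  codes <- encode_states(aln)
  a <- codes[ia, ]
  b <- codes[ib, ]
  both <- a > 0L & b > 0L
  if (!any(both))
    stop("no sites where both ", taxonA, " and ", taxonB, " are ungapped")
  k <- length(aln$alphabet)
  N <- matrix(0, k, k, dimnames = list(aln$alphabet, aln$alphabet))
  tab <- table(factor(a[both], levels = 1:k), factor(b[both], levels = 1:k))
  N[] <- as.numeric(tab)
  st <- stuart_statistic(N)
  structure(list(pair = c(taxonA, taxonB), table = N, d = st$d, V = st$V,
                 W = st$W, df = st$df, p = st$p, singular = st$singular),
            class = "stuart_result")
}

#' @export
print.stuart_result <- function(x, ...) {
  cat(sprintf("Stuart test %s vs %s: W = %.4g, df = %d, p = %.4g%s\n",
              x$pair[1], x$pair[2], x$W, x$df, x$p,
              if (x$singular) " (singular V, pseudo-inverse)" else ""))
  invisible(x)
}

# All pairwise Stuart W/p on integer-coded states (columns `cols`).
# Returns list of pair index matrix, W vector, p vector.
pairwise_stuart <- function(codes, k, cols) {
  nt <- nrow(codes)
  pairs <- utils::combn(nt, 2)
  W <- numeric(ncol(pairs))
  p <- numeric(ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    a <- codes[pairs[1, q], cols]
    b <- codes[pairs[2, q], cols]
    both <- a > 0L & b > 0L
    N <- matrix(0, k, k)
    if (any(both)) {
      tab <- table(factor(a[both], levels = 1:k),
                   factor(b[both], levels = 1:k))
      N[] <- as.numeric(tab)
    }
    st <- stuart_statistic(N)
    W[q] <- st$W
    p[q] <- st$p
  }
  list(pairs = pairs, W = W, p = p)
}

#' Stationarity-based alignment trimming (Stuart criterion)
#'
#' Greedy column remover: while any taxon pair fails Stuart's test of
#' marginal homogeneity at \code{alpha} and fewer than
#' \code{max_removed_fraction} of the original columns have been
#' removed, delete the single column whose removal maximally reduces
#' the summed Stuart W over the currently significant pairs (ties
#' broken by lowest column index), then retest.
#'
#' @param aln an \code{alignment} with at least 3 taxa.
#' @param alpha per-pair significance level (no multiple-testing
#'   correction across pairs).
#' @param max_removed_fraction cap on the removed fraction of columns.
#' @return A \code{trim_result}; \code{log} records one row per round
#'   (round, site_index, n_significant_pairs, objective_before,
#'   objective_after), sites in 0-based original coordinates.
#' @export
stationary_trim <- function(aln, alpha = 0.05, max_removed_fraction = 0.5) {
  stopifnot(n_taxa(aln) >= 3, alpha > 0, alpha < 1,
            max_removed_fraction >= 0, max_removed_fraction <= 1)
  codes <- encode_states(aln)
  k <- length(aln$alphabet)
  S <- n_sites(aln)
  kept <- seq_len(S)           # 1-based original coords while working
  removed <- integer(0)
  log <- data.frame(round = integer(0), site_index = integer(0),
                    n_significant_pairs = integer(0),
                    objective_before = numeric(0),
                    objective_after = numeric(0))
  round <- 0L
  repeat {
    pw <- pairwise_stuart(codes, k, kept)
    sig <- which(pw$p < alpha)
    if (length(sig) == 0L || length(removed) >= max_removed_fraction * S ||
        length(kept) <= 1L)
      break
    round <- round + 1L
    obj_before <- sum(pw$W[sig])
    # For each candidate column, the summed W over significant pairs
    # after removing it.  Columns only affect a pair's table through
    # their (stateA, stateB) cell, so group columns by cell per pair.
    obj_after_col <- rep(obj_before, length(kept))
    for (q in sig) {
      ia <- pw$pairs[1, q]; ib <- pw$pairs[2, q]
      a <- codes[ia, kept]; b <- codes[ib, kept]
      both <- a > 0L & b > 0L
      N <- matrix(0, k, k)
      if (any(both)) {
        tab <- table(factor(a[both], levels = 1:k),
                     factor(b[both], levels = 1:k))
        N[] <- as.numeric(tab)
      }
      W0 <- pw$W[q]
      if (!any(both)) next
      cells <- paste(a[both], b[both])
      for (cell in unique(cells)) {
        uv <- as.integer(strsplit(cell, " ", fixed = TRUE)[[1]])
        N1 <- N
        N1[uv[1], uv[2]] <- N1[uv[1], uv[2]] - 1
        W1 <- stuart_statistic(N1)$W
        idx <- which(both)[cells == cell]
        obj_after_col[idx] <- obj_after_col[idx] - W0 + W1
      }
    }
    drop_local <- which.min(obj_after_col)   # ties: lowest index
    site <- kept[drop_local]
    log <- rbind(log, data.frame(
      round = round, site_index = site - 1L,
      n_significant_pairs = length(sig),
      objective_before = obj_before,
      objective_after = obj_after_col[drop_local]))
    removed <- c(removed, site)
    kept <- kept[-drop_local]
  }
  trimmed <- alignment(aln$matrix[, kept, drop = FALSE],
                       alphabet = aln$alphabet, gap = aln$gap)
  trim_result(trimmed, kept = kept - 1L, removed = removed - 1L, log = log)
}
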