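# Amino-acid compositional-bias classification: chi-squared residuals
# on per-taxon residue counts, UPGMA split of taxa, per-residue
# binomial scoring, and enriched/depleted/other classification for
# branch-specific frequency-shift models (GFmix input).

#' Chi-squared residual table of residue counts
#'
#' Expected counts from the row/column marginals (independence model);
#' Pearson residuals r = (O - E)/sqrt(E); chi2 = sum r^2 with
#' df = (T - 1)(K - 1).
#'
#' @param counts non-negative integer matrix taxa x residues (e.g.
#'   from \code{\link{residue_counts}}).
#' @return A \code{residual_table}: list with \code{observed},
#'   \code{expected}, \code{residuals}, \code{chi2}, \code{df},
#'   \code{p}.
#' @export
residual_table <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  zr <- rowSums(counts) == 0
  zc <- colSums(counts) == 0
  if (any(zr)) stop("all-zero row(s): ",
                    paste(rownames(counts)[zr], collapse = ", "))
  if (any(zc)) stop("all-zero column(s): ",
                    paste(colnames(counts)[zc], collapse = ", "))
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  R <- (counts - E) / sqrt(E)
  chi2 <- sum(R^2)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  structure(list(observed = counts, expected = E, residuals = R,
                 chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "residual_table")
}

#' @export
print.residual_table <- function(x, ...) {
  cat(sprintf("Composition chi-squared: chi2 = %.4g, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Split taxa into two compositional groups
#'
#' Euclidean distances between the taxa's Pearson-residual rows are
#' clustered by UPGMA and the tree is cut at the root into its two
#' child clades.  Group 1 is the clade containing the alphabetically
#' first taxon label, so orientation is deterministic.
#'
#' @param rt a \code{residual_table}.
#' @return A \code{group_split}: list with \code{group1},
#'   \code{group2}, \code{tree}, \code{no_signal} (TRUE when all
#'   residual rows are identical).
#' @export
split_taxa <- function(rt) {
  R <- rt$residuals
  if (nrow(R) < 2) stop("need at least 2 taxa")
  if (nrow(R) == 2) {
    g <- rownames(R)[order(rownames(R))]
    return(structure(list(group1 = g[1], group2 = g[2], tree = NULL,
                          no_signal = sum(stats::dist(R)) < 1e-12),
                     class = "group_split"))
  }
  d <- stats::dist(R)
  tr <- upgma(as.matrix(d))
  halves <- root_split(tr)
  first <- min(rownames(R))
  if (first %in% halves[[2]]) halves <- rev(halves)
  structure(list(group1 = sort(halves[[1]]), group2 = sort(halves[[2]]),
                 tree = tr, no_signal = max(d) < 1e-12),
            class = "group_split")
}

#' @export
print.group_split <- function(x, ...) {
  cat("Group 1 (", length(x$group1), " taxa): ",
      paste(x$group1, collapse = ", "), "\n", sep = "")
  cat("Group 2 (", length(x$group2), " taxa): ",
      paste(x$group2, collapse = ", "), "\n", sep = "")
  if (x$no_signal) cat("(no compositional signal; split is arbitrary)\n")
  invisible(x)
}

#' Classify residues as enriched, depleted, or other
#'
#' For each residue, a two-sided exact binomial test of its group-1
#' count among the pooled count, with success probability equal to
#' group 1's share of the total residue count.  The score is
#' sign(freq1 - freq2) * (-log10 p); residues with score >=
#' \code{threshold} are "enriched" (in group 1), <= -threshold
#' "depleted", the rest "other".
#'
#' @param counts taxa x residues count matrix.
#' @param split a \code{group_split} covering the count-table taxa.
#' @param threshold absolute score cutoff (default 2, i.e. p <= 0.01).
#' @return A \code{composition_classes}: list with \code{scores},
#'   \code{p}, \code{enriched}, \code{depleted}, \code{other},
#'   \code{threshold}.  Sign convention: positive = relatively more
#'   frequent in group 1.
#' @export
classify_residues <- function(counts, split, threshold = 2) {
  g1 <- intersect(rownames(counts), split$group1)
  g2 <- intersect(rownames(counts), split$group2)
  if (length(g1) == 0 || length(g2) == 0)
    stop("both groups must contain taxa present in the count table")
  x1 <- colSums(counts[g1, , drop = FALSE])
  x2 <- colSums(counts[g2, , drop = FALSE])
  N1 <- sum(x1); N2 <- sum(x2)
  pr <- N1 / (N1 + N2)
  res <- colnames(counts)
  pv <- vapply(seq_along(res), function(a) {
    n <- x1[a] + x2[a]
    if (n == 0) return(1)
    stats::binom.test(x1[a], n, p = pr)$p.value
  }, numeric(1))
  sgn <- sign(x1 / N1 - x2 / N2)
  score <- sgn * (-log10(pmax(pv, 1e-300)))
  names(score) <- names(pv) <- res
  enriched <- sort(res[score >= threshold])
  depleted <- sort(res[score <= -threshold])
  structure(list(scores = score, p = pv,
                 enriched = enriched, depleted = depleted,
                 other = sort(setdiff(res, c(enriched, depleted))),
                 threshold = threshold),
            class = "composition_classes")
}

#' @export
print.composition_classes <- function(x, ...) {
  cat("Enriched:", paste(x$enriched, collapse = ""), "\n")
  cat("Depleted:", paste(x$depleted, collapse = ""), "\n")
  cat("Other:   ", paste(x$other, collapse = ""), "\n")
  invisible(x)
}

#' Write enriched/depleted classes in GFmix format
#'
#' Line 1: enriched residues as single letters, no separators,
#' alphabetical; line 2: depleted residues likewise.
#'
#' @param classes a \code{composition_classes}.
#' @param path output file.
#' @export
write_gfmix_classes <- function(classes, path) {
  if (length(classes$enriched) == 0)
    warning("enriched set is empty")
  if (length(classes$depleted) == 0)
    warning("depleted set is empty")
  writeLines(c(paste(sort(classes$enriched), collapse = ""),
               paste(sort(classes$depleted), collapse = "")), path)
  invisible(path)
}

#' Read a GFmix class file
#' @param path file written by \code{\link{write_gfmix_classes}}.
#' @return List with \code{enriched} and \code{depleted} residue sets.
#' @export
read_gfmix_classes <- function(path) {
  lines <- readLines(path)
  split1 <- function(s) if (nchar(s) == 0) character(0) else
    strsplit(s, "", fixed = TRUE)[[1]]
  list(enriched = split1(lines[1]), depleted = split1(lines[2]))
}

#' End-to-end compositional-bias classification of an alignment
#'
#' Runs the five-step procedure: residue counts, chi-squared residuals,
#' UPGMA taxon split, binomial scoring, classification.
#'
#' @param aln an \code{alignment}.
#' @param threshold score cutoff, see \code{\link{classify_residues}}.
#' @return List with \code{counts}, \code{residuals}, \code{split},
#'   \code{classes}.
#' @export
compbias <- function(aln, threshold = 2) {
  counts <- residue_counts(aln)
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  rt <- residual_table(counts)
  sp <- split_taxa(rt)
  cl <- classify_residues(counts, sp, threshold = threshold)
  list(counts = counts, residuals = rt, split = sp, classes = cl)
}
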