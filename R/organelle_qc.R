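# Organelle MAG quality control: marker-based completeness/redundancy,
# mitochondrial contamination screening, ANI dereplication with
# representative selection, detection/coverage rules, and
# coverage-correlation linking of organellar genomes.

#' Marker gene set
#'
#' Built-ins: \code{"plastid_core"} (44 plastid single-copy core genes
#' used for ptMAG completeness/redundancy) and \code{"mito_screen"}
#' (25 canonical mitochondrion-encoded genes used as a contamination
#' screen).  Both ship as editable plain-text defaults; pass a file
#' path or character vector to override.
#'
#' @param x built-in name, file path (one gene per line, \code{#}
#'   comments), or character vector of gene names.
#' @param name label for the set.
#' @return A \code{marker_set}: list with \code{name}, \code{genes},
#'   \code{size}.
#' @export
marker_set <- function(x = c("plastid_core", "mito_screen"),
                       name = NULL) {
  if (length(x) == 1 && x %in% c("plastid_core", "mito_screen")) {
    path <- system.file("extdata", paste0(x, "_genes.txt"),
                        package = "leptokit")
    genes <- readLines(path)
    genes <- trimws(genes[!startsWith(trimws(genes), "#")])
    genes <- genes[nzchar(genes)]
    if (is.null(name)) name <- x
  } else if (length(x) == 1 && file.exists(x)) {
    genes <- readLines(x)
    genes <- trimws(genes[!startsWith(trimws(genes), "#")])
    genes <- genes[nzchar(genes)]
    if (is.null(name)) name <- basename(x)
  } else {
    genes <- as.character(x)
    if (is.null(name)) name <- "custom"
  }
  if (anyDuplicated(genes)) stop("duplicate marker genes")
  if (length(genes) < 1) stop("empty marker set")
  structure(list(name = name, genes = genes, size = length(genes)),
            class = "marker_set")
}

#' Marker-based completeness and redundancy of a genome
#'
#' Completeness = percent of markers present at least once; redundancy
#' = percent of extra marker copies (sum over markers of copies beyond
#' the first, relative to the set size).  A 44-marker genome is deemed
#' near complete when at least \code{near_complete_min} markers are
#' present.
#'
#' @param gene_copies named integer vector gene -> copy count (genes
#'   absent from the names have count 0; names not in the marker set
#'   are ignored with a warning).
#' @param markers a \code{marker_set}.
#' @param near_complete_min marker-presence threshold for the
#'   near-complete flag (default 40, the convention for the 44-gene
#'   plastid core set).
#' @return A \code{qc_report}: list with \code{completeness},
#'   \code{redundancy} (percent), \code{n_present},
#'   \code{near_complete}, \code{copy_counts}.
#' @export
completeness_redundancy <- function(gene_copies, markers,
                                    near_complete_min = 40) {
  stopifnot(all(gene_copies >= 0))
  unknown <- setdiff(names(gene_copies), markers$genes)
  if (length(unknown))
    warning("ignoring genes not in marker set: ",
            paste(unknown, collapse = ", "))
  cc <- stats::setNames(rep(0L, markers$size), markers$genes)
  hits <- intersect(names(gene_copies), markers$genes)
  cc[hits] <- as.integer(gene_copies[hits])
  n_present <- sum(cc >= 1)
  structure(list(
    completeness = 100 * n_present / markers$size,
    redundancy = 100 * sum(pmax(0L, cc - 1L)) / markers$size,
    n_present = n_present,
    near_complete = n_present >= near_complete_min,
    copy_counts = cc), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Completeness %.1f%%, redundancy %.1f%% (%d markers present%s)\n",
              x$completeness, x$redundancy, x$n_present,
              if (x$near_complete) "; near complete" else ""))
  invisible(x)
}

#' Screen gene annotations for contaminating markers
#'
#' Case-insensitive intersection of a genome's gene names with a
#' screen set (e.g. mitochondrial genes inside a plastid MAG).
#'
#' @param gene_names character vector of annotated gene names.
#' @param screen a \code{marker_set}.
#' @return Character vector of flagged gene names (empty = clean).
#' @export
contamination_screen <- function(gene_names, screen) {
  gene_names[tolower(gene_names) %in% tolower(screen$genes)]
}

#' Dereplicate genomes by pairwise ANI
#'
#' Genomes are redundant when ANI > \code{ani_threshold} with aligned
#' fraction of the smaller genome > \code{min_align}; clusters are the
#' connected components of the redundancy graph (single linkage).  The
#' representative of a cluster is a reference genome when one is
#' present (the longest reference, ties by id), otherwise the longest
#' genome (ties by id).
#'
#' @param records data frame with columns genomeA, genomeB, ani,
#'   aligned_fraction (percent scales).
#' @param genomes data frame with columns id, is_reference, length.
#' @param ani_threshold,min_align thresholds in (0, 100], strict
#'   greater-than.
#' @return List with \code{clusters} (data frame id, cluster,
#'   representative, is_representative) and \code{representatives}.
#' @export
dereplicate <- function(records, genomes, ani_threshold = 98,
                        min_align = 25) {
  stopifnot(ani_threshold > 0, ani_threshold <= 100,
            min_align > 0, min_align <= 100)
  ids <- genomes$id
  bad <- setdiff(unique(c(records$genomeA, records$genomeB)), ids)
  if (length(bad))
    stop("unknown genome id(s) in ANI records: ", paste(bad, collapse = ", "))
  # union-find over genomes
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  edges <- records$ani > ani_threshold & records$aligned_fraction > min_align
  for (e in which(edges)) {
    ra <- find(match(records$genomeA[e], ids))
    rb <- find(match(records$genomeB[e], ids))
    if (ra != rb) parent[rb] <- ra
  }
  comp <- vapply(seq_along(ids), find, numeric(1))
  cluster <- match(comp, unique(comp))
  rep_of <- character(max(cluster))
  for (cl in seq_len(max(cluster))) {
    members <- which(cluster == cl)
    refs <- members[genomes$is_reference[members]]
    pool <- if (length(refs)) refs else members
    pool <- pool[order(-genomes$length[pool], genomes$id[pool])]
    rep_of[cl] <- genomes$id[pool[1]]
  }
  df <- data.frame(id = ids, cluster = cluster,
                   representative = rep_of[cluster],
                   is_representative = ids == rep_of[cluster],
                   stringsAsFactors = FALSE)
  list(clusters = df, representatives = rep_of)
}

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "",
                     fixed = TRUE)[[1]]), collapse = "")
}

#' Approximate ANI from canonical k-mer sharing
#'
#' Jaccard similarity J of the canonical k-mer sets is converted to a
#' per-base distance D = -(1/k) ln(2J/(1+J)) (the Mash distance) and
#' reported as ANI = 100 (1 - D).  The aligned fraction is approximated
#' by the shared-k-mer fraction of the smaller sequence's k-mer set.
#'
#' @param seqA,seqB DNA sequences as character strings (length >= k).
#' @param k k-mer size.
#' @return List with \code{ani}, \code{aligned_fraction} (percent),
#'   \code{jaccard}, \code{no_overlap} flag.
#' @export
kmer_ani <- function(seqA, seqB, k = 21) {
  canon_kmers <- function(s) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) stop("sequence shorter than k")
    starts <- 1:(n - k + 1)
    fwd <- substring(s, starts, starts + k - 1)
    rc <- revcomp(s)
    rcv <- substring(rc, n - k + 2 - starts, n - starts + 1)
    unique(pmin(fwd, rcv))
  }
  A <- canon_kmers(seqA)
  B <- canon_kmers(seqB)
  inter <- length(intersect(A, B))
  J <- inter / length(union(A, B))
  smaller <- min(length(A), length(B))
  af <- 100 * inter / smaller
  if (J == 0)
    return(list(ani = 0, aligned_fraction = 0, jaccard = 0,
                no_overlap = TRUE))
  D <- -(1 / k) * log(2 * J / (1 + J))
  list(ani = max(0, min(100, 100 * (1 - D))),
       aligned_fraction = af, jaccard = J, no_overlap = FALSE)
}

#' Apply the detection rule to a raw coverage table
#'
#' A genome counts as detected in a sample only when more than 25\% of
#' its length is covered; mean coverage is zeroed wherever detection
#' <= \code{min_detection} (strict greater-than rule).  Idempotent.
#'
#' @param raw data frame with columns genome, sample, mean_coverage,
#'   detection (fraction in [0, 1]).
#' @param min_detection detection cutoff (default 0.25).
#' @return The table with the zeroing rule applied.
#' @export
apply_detection_rule <- function(raw, min_detection = 0.25) {
  stopifnot(all(raw$detection >= 0), all(raw$detection <= 1),
            all(raw$mean_coverage >= 0))
  raw$mean_coverage[raw$detection <= min_detection] <- 0
  raw
}

#' Coverage-correlation link between two organelle genomes
#'
#' Ordinary least squares of \code{covB} on \code{covA} across samples;
#' reports the Pearson correlation, R^2, and the two-sided t-test of
#' the regression slope (H0: slope = 0, df = n - 2).
#'
#' @param covA,covB equal-length coverage vectors (n >= 3).
#' @return A \code{link_result}: list with \code{n}, \code{slope},
#'   \code{intercept}, \code{r}, \code{r_squared}, \code{t}, \code{p}.
#' @export
link_organelles <- function(covA, covB) {
  stopifnot(length(covA) == length(covB), length(covA) >= 3)
  if (stats::sd(covA) == 0 || stats::sd(covB) == 0)
    stop("degenerate coverage vector (zero variance)")
  fit <- stats::lm(covB ~ covA)
  sm <- summary(fit)
  r <- stats::cor(covA, covB)
  structure(list(n = length(covA),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = r, r_squared = r^2,
                 t = sm$coefficients[2, "t value"],
                 p = sm$coefficients[2, "Pr(>|t|)"]),
            class = "link_result")
}

#' @export
print.link_result <- function(x, ...) {
  cat(sprintf("Coverage link: n = %d, slope = %.3g, R^2 = %.3f, p = %.3g\n",
              x$n, x$slope, x$r_squared, x$p))
  invisible(x)
}

#' Rank candidate genomes by coverage correlation with a target
#'
#' Every candidate is linked to the target twice: without the detection
#' rule (raw coverages) and with it (coverage zeroed at detection <=
#' 0.25).  Candidates are sorted by the rule-off R^2 (the variant the
#' correlation is reported from).
#'
#' @param raw coverage table (genome, sample, mean_coverage,
#'   detection).
#' @param target target genome id (e.g. a plastid MAG).
#' @param candidates candidate genome ids; default all non-target
#'   genomes in the table.
#' @return Data frame sorted by \code{r_squared_raw} descending, one
#'   row per candidate, with both variants' slope, R^2 and p.
#' @export
rank_link_candidates <- function(raw, target, candidates = NULL) {
  genomes <- unique(raw$genome)
  if (!target %in% genomes) stop("target not in coverage table: ", target)
  if (is.null(candidates)) candidates <- setdiff(genomes, target)
  if (length(candidates) < 1) stop("no candidates")
  ruled <- apply_detection_rule(raw)
  vec <- function(tab, g) {
    sub <- tab[tab$genome == g, ]
    stats::setNames(sub$mean_coverage, sub$sample)[sort(unique(raw$sample))]
  }
  tgt_raw <- vec(raw, target)
  tgt_rule <- vec(ruled, target)
  one <- function(g) {
    lr_raw <- tryCatch(link_organelles(tgt_raw, vec(raw, g)),
                       error = function(e) NULL)
    lr_rule <- tryCatch(link_organelles(tgt_rule, vec(ruled, g)),
                        error = function(e) NULL)
    data.frame(candidate = g,
               r_squared_raw = if (is.null(lr_raw)) NA else lr_raw$r_squared,
               slope_raw = if (is.null(lr_raw)) NA else lr_raw$slope,
               p_raw = if (is.null(lr_raw)) NA else lr_raw$p,
               r_squared_detected = if (is.null(lr_rule)) NA else
                 lr_rule$r_squared,
               slope_detected = if (is.null(lr_rule)) NA else lr_rule$slope,
               p_detected = if (is.null(lr_rule)) NA else lr_rule$p,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(candidates, one))
  out <- out[order(-out$r_squared_raw), ]
  rownames(out) <- NULL
  out
}
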