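# Alignment container and basic treatments: FASTA I/O, residue counting,
# SR4 recoding, gap-threshold trimming.

#' The 20 amino acids (one-letter codes, PAML order)
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Ambiguity/unknown codes treated as missing data throughout.
AA_AMBIGUOUS <- c("B", "Z", "X", "J", "U", "O", "?", ".", "*")

#' Construct an alignment object
#'
#' An alignment is a taxa x sites character matrix over a declared
#' alphabet with a single gap symbol.  Ambiguity codes (B, Z, X, J, U,
#' O) are normalized to the gap symbol on construction and treated as
#' missing data everywhere downstream.
#'
#' @param matrix character matrix (taxa in rows, sites in columns) or a
#'   named character vector of equal-length sequence strings.
#' @param alphabet symbol set; defaults to the 20 amino acids.
#' @param gap gap symbol, default \code{"-"}.
#' @return An object of class \code{"alignment"} with fields
#'   \code{taxa}, \code{matrix}, \code{alphabet}, \code{gap}.
#' @export
alignment <- function(matrix, alphabet = AA_ALPHABET, gap = "-") {
  if (is.character(matrix) && is.null(dim(matrix))) {
    seqs <- toupper(matrix)
    lens <- nchar(seqs)
    if (length(seqs) == 0L) stop("alignment is empty")
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: sequence lengths differ (",
           paste(unique(lens), collapse = ", "), ")")
    labs <- names(seqs)
    if (is.null(labs)) labs <- paste0("t", seq_along(seqs))
    matrix <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    if (lens[1] == 0L) matrix <- base::matrix("", length(seqs), 0L)
    rownames(matrix) <- labs
  }
  if (!is.matrix(matrix)) stop("matrix must be a character matrix")
  matrix[] <- toupper(matrix)
  taxa <- rownames(matrix)
  if (is.null(taxa)) stop("alignment rows must be named by taxon")
  if (anyDuplicated(taxa))
    stop("duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  matrix[matrix %in% AA_AMBIGUOUS] <- gap
  bad <- setdiff(unique(as.vector(matrix)), c(alphabet, gap))
  if (length(bad))
    stop("characters outside alphabet: ", paste(bad, collapse = ", "))
  structure(list(taxa = taxa, matrix = matrix,
                 alphabet = alphabet, gap = gap),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("Alignment:", length(x$taxa), "taxa x", ncol(x$matrix), "sites;",
      "alphabet size", length(x$alphabet), "\n")
  invisible(x)
}

#' @export
dim.alignment <- function(x) dim(x$matrix)

n_sites <- function(aln) ncol(aln$matrix)
n_taxa <- function(aln) nrow(aln$matrix)

#' Read an alignment from a FASTA file
#'
#' Sequences are uppercased; ragged record lengths or duplicate labels
#' are errors.
#'
#' @param path path to a FASTA file.
#' @param alphabet,gap passed to \code{\link{alignment}}.
#' @return An \code{alignment}.
#' @export
read_fasta <- function(path, alphabet = AA_ALPHABET, gap = "-") {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  alignment(seqs, alphabet = alphabet, gap = gap)
}

#' Write an alignment to FASTA (wrapped at 60 columns)
#'
#' @param aln an \code{alignment}.
#' @param path output path.
#' @export
write_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_taxa(aln))) {
    writeLines(paste0(">", aln$taxa[i]), con)
    s <- paste(aln$matrix[i, ], collapse = "")
    if (nchar(s) == 0L) { writeLines("", con); next }
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' SR4 recoding scheme
#'
#' The four-class amino-acid reduction used to damp compositional
#' heterogeneity and saturation: AGNPST / CHWY / DEKQR / FILMV, rendered
#' as class symbols '1'..'4'.
#'
#' @return A recoding scheme: list with \code{name} and \code{classes}
#'   (named character vector residue -> class symbol).
#' @export
sr4_scheme <- function() {
  classes <- c(A = "1", G = "1", N = "1", P = "1", S = "1", T = "1",
               C = "2", H = "2", W = "2", Y = "2",
               D = "3", E = "3", K = "3", Q = "3", R = "3",
               F = "4", I = "4", L = "4", M = "4", V = "4")
  structure(list(name = "SR4", classes = classes,
                 target_alphabet = c("1", "2", "3", "4")),
            class = "recoding_scheme")
}

#' Identity recoding scheme over an alphabet
#' @param alphabet symbol set.
#' @return A recoding scheme mapping every symbol to itself.
#' @export
identity_scheme <- function(alphabet = AA_ALPHABET) {
  classes <- stats::setNames(alphabet, alphabet)
  structure(list(name = "identity", classes = classes,
                 target_alphabet = unique(unname(classes))),
            class = "recoding_scheme")
}

#' Recode an alignment under a reduction scheme
#'
#' Gaps pass through unchanged; any non-gap residue not covered by the
#' scheme is an error naming the residue and position.
#'
#' @param aln an \code{alignment}.
#' @param scheme a recoding scheme, e.g. \code{\link{sr4_scheme}()}.
#' @return The recoded \code{alignment} (same shape, class alphabet).
#' @export
recode <- function(aln, scheme = sr4_scheme()) {
  m <- aln$matrix
  is_gap <- m == aln$gap
  covered <- m %in% names(scheme$classes) | is_gap
  if (!all(covered)) {
    idx <- which(!covered, arr.ind = TRUE)[1, ]
    stop("residue '", m[idx[1], idx[2]], "' at taxon ", aln$taxa[idx[1]],
         ", site ", idx[2], " not covered by scheme ", scheme$name)
  }
  out <- m
  out[!is_gap] <- scheme$classes[m[!is_gap]]
  alignment(out, alphabet = scheme$target_alphabet, gap = aln$gap)
}

#' Per-taxon residue counts
#'
#' Tabulates non-gap characters per taxon; row sums equal each taxon's
#' ungapped length.
#'
#' @param aln an \code{alignment}.
#' @return Integer matrix taxa x alphabet.
#' @export
residue_counts <- function(aln) {
  out <- matrix(0L, n_taxa(aln), length(aln$alphabet),
                dimnames = list(aln$taxa, aln$alphabet))
  for (i in seq_len(n_taxa(aln))) {
    tab <- table(factor(aln$matrix[i, ], levels = aln$alphabet))
    out[i, ] <- as.integer(tab)
  }
  out
}

trim_result <- function(aln, kept, removed, log = NULL) {
  structure(list(kept = sort(kept), removed = sort(removed),
                 alignment = aln, log = log),
            class = "trim_result")
}

#' @export
print.trim_result <- function(x, ...) {
  cat("Trim result:", length(x$kept), "sites kept,",
      length(x$removed), "removed\n")
  invisible(x)
}

#' Gap-threshold column trimming
#'
#' Keeps columns whose fraction of non-gap characters is at least
#' \code{gap_threshold} (the trimAl convention: threshold 0.8 keeps
#' columns with >= 80\% residues).
#'
#' @param aln an \code{alignment}.
#' @param gap_threshold required non-gap fraction in [0, 1].
#' @return A \code{trim_result}; site indices are 0-based original
#'   coordinates.
#' @export
gap_trim <- function(aln, gap_threshold = 0.8) {
  stopifnot(gap_threshold >= 0, gap_threshold <= 1)
  nongap <- colMeans(aln$matrix != aln$gap)
  keep <- nongap >= gap_threshold
  trimmed <- alignment(aln$matrix[, keep, drop = FALSE],
                       alphabet = aln$alphabet, gap = aln$gap)
  trim_result(trimmed, kept = which(keep) - 1L, removed = which(!keep) - 1L)
}

#' Select alignment columns by 0-based index
#' @param aln an \code{alignment}.
#' @param kept0 0-based column indices to keep.
#' @return The column-subset \code{alignment}.
#' @export
subset_sites <- function(aln, kept0) {
  alignment(aln$matrix[, kept0 + 1L, drop = FALSE],
            alphabet = aln$alphabet, gap = aln$gap)
}

#' Percent identity of two aligned sequences
#'
#' Computed over columns where both sequences are ungapped.
#'
#' @param aln an \code{alignment}.
#' @param taxonA,taxonB taxon labels.
#' @return Percent identity in [0, 100].
#' @export
percent_identity <- function(aln, taxonA, taxonB) {
  a <- aln$matrix[match_taxon(aln, taxonA), ]
  b <- aln$matrix[match_taxon(aln, taxonB), ]
  both <- a != aln$gap & b != aln$gap
  if (!any(both)) stop("no co-ungapped sites between ", taxonA, " and ", taxonB)
  100 * mean(a[both] == b[both])
}

match_taxon <- function(aln, label) {
  i <- match(label, aln$taxa)
  if (is.na(i)) stop("taxon not in alignment: ", label)
  i
}

#' Write a trim result as TSV
#'
#' Columns: site_index (0-based original coordinate), action
#' (kept/removed), round (removal round, NA for kept sites or
#' single-pass trimmers).
#'
#' @param tr a \code{trim_result}.
#' @param path output path.
#' @export
write_trim_tsv <- function(tr, path) {
  rounds <- rep(NA_integer_, length(tr$removed))
  if (!is.null(tr$log) && nrow(tr$log) > 0)
    rounds <- tr$log$round[match(tr$removed, tr$log$site_index)]
  df <- rbind(
    data.frame(site_index = tr$kept,
               action = rep("kept", length(tr$kept)),
               round = rep(NA_integer_, length(tr$kept))),
    data.frame(site_index = tr$removed,
               action = rep("removed", length(tr$removed)),
               round = rounds))
  df <- df[order(df$site_index), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
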