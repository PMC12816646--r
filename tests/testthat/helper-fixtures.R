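# Shared fixtures built in code.

# small DNA-like 4-state model for fast engine tests
dna4_model <- function(m = 1, alpha = 1)
  poisson_model(states = c("A", "C", "G", "T"), m = m, alpha = alpha)

# random resolved tree with moderate branch lengths, fixed seed
fixture_tree <- function(n, seed = 1, scale = 0.4, min_len = 0.05) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- pmax(tr$edge.length * scale, min_len)
  tr
}

# write a temporary FASTA from named sequences
write_tmp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  for (nm in names(seqs)) writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  close(con)
  path
}

# random DNA string
random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# point-mutate a DNA string at the given per-base rate
mutate_dna <- function(s, rate, seed) {
  set.seed(seed)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  v[hit] <- vapply(v[hit], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(v, collapse = "")
}

# non-trivial splits of a tree as sorted label-set strings, computed
# through ape::prop.part only (independent of the package's canonical
# bitmask representation)
oracle_splits <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  labs <- sort(tree$tip.label)
  out <- character(0)
  for (cl in ape::prop.part(tree)) {
    if (length(cl) <= 1 || length(cl) >= ntip - 1) next
    side <- sort(tree$tip.label[cl])
    if (labs[1] %in% side) side <- setdiff(labs, side)
    out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}
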