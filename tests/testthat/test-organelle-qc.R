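test_that("completeness and redundancy follow the marker-counting formulas", {
  mk <- marker_set("plastid_core")
  expect_equal(mk$size, 44L)

  all_once <- setNames(rep(1L, 44), mk$genes)
  qc <- completeness_redundancy(all_once, mk)
  expect_equal(qc$completeness, 100)
  expect_equal(qc$redundancy, 0)
  expect_true(qc$near_complete)

  half <- setNames(rep(1L, 22), mk$genes[1:22])
  qc2 <- completeness_redundancy(half, mk)
  expect_equal(qc2$completeness, 50)
  expect_equal(qc2$redundancy, 0)
  expect_false(qc2$near_complete)

  dup <- setNames(rep(1L, 44), mk$genes)
  dup[1:11] <- 2L
  qc3 <- completeness_redundancy(dup, mk)
  expect_equal(qc3$completeness, 100)
  expect_equal(qc3$redundancy, 25)

  expect_warning(
    completeness_redundancy(c(setNames(1L, mk$genes[1]), nifH = 3L), mk),
    "nifH")
})

test_that("QC is exact on synthetic complements", {
  mk <- marker_set("plastid_core")
  for (s in 1:8) {
    cf <- sample(seq(0.2, 1, by = 0.1), 1)
    rf <- sample(seq(0, 0.2, by = 0.05), 1)
    sim <- sim_genome_complement(mk, cf, rf, seed = 300 + s)
    qc <- completeness_redundancy(table(sim$genes), mk)
    expect_equal(qc$completeness, sim$truth$params$completeness)
    expect_equal(qc$redundancy, sim$truth$params$redundancy)
  }
})

test_that("the mitochondrial contamination screen matches case-insensitively", {
  screen <- marker_set("mito_screen")
  expect_equal(screen$size, 25L)
  expect_equal(contamination_screen(c("psbA", "rbcL"), screen),
               character(0))
  expect_equal(contamination_screen(c("psbA", "cox3"), screen), "cox3")
  expect_equal(contamination_screen(c("COX3", "AtpA"), screen), "COX3")
})

test_that("ANI dereplication: single linkage, reference preference, ties", {
  genomes <- data.frame(
    id = c("refA", "mag1", "mag2", "mag3", "refB"),
    is_reference = c(TRUE, FALSE, FALSE, FALSE, TRUE),
    length = c(60000, 120000, 90000, 80000, 50000))
  # no edges above threshold: everyone their own representative
  rec0 <- data.frame(genomeA = "mag1", genomeB = "mag2",
                     ani = 95, aligned_fraction = 80)
  d0 <- dereplicate(rec0, genomes)
  expect_true(all(d0$clusters$is_representative))

  # chain A-B, B-C redundant; A-C below: one cluster by transitivity
  rec <- data.frame(
    genomeA = c("mag1", "mag2", "mag1", "refA"),
    genomeB = c("mag2", "mag3", "mag3", "mag1"),
    ani = c(99, 99, 90, 99),
    aligned_fraction = c(60, 60, 60, 30))
  d1 <- dereplicate(rec, genomes)
  cl <- d1$clusters
  expect_equal(length(unique(cl$cluster[cl$id %in%
    c("refA", "mag1", "mag2", "mag3")])), 1L)
  # the reference wins over a longer MAG
  expect_equal(unique(cl$representative[cl$id %in%
    c("refA", "mag1", "mag2", "mag3")]), "refA")
  # every genome maps to exactly one cluster
  expect_equal(nrow(cl), nrow(genomes))
  expect_true(all(cl$representative %in% genomes$id))

  # MAG-only cluster: the longest is chosen
  rec2 <- data.frame(genomeA = "mag1", genomeB = "mag2",
                     ani = 99, aligned_fraction = 50)
  d2 <- dereplicate(rec2, genomes)
  expect_equal(d2$clusters$representative[d2$clusters$id == "mag1"],
               "mag1")  # 120 kb > 90 kb

  # boundary semantics: ani exactly at the threshold is NOT redundant
  rec3 <- data.frame(genomeA = "mag1", genomeB = "mag2",
                     ani = 98, aligned_fraction = 50)
  d3 <- dereplicate(rec3, genomes)
  expect_true(all(d3$clusters$is_representative))

  expect_error(
    dereplicate(data.frame(genomeA = "zz", genomeB = "mag1", ani = 99,
                           aligned_fraction = 50), genomes), "unknown")
})

test_that("k-mer ANI: identity, disjointness, and mutated-sequence band", {
  s <- random_dna(20000, seed = 61)
  self <- kmer_ani(s, s)
  expect_equal(self$ani, 100)
  expect_equal(self$jaccard, 1)

  # reverse complement is the same molecule for canonical k-mers
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
              collapse = "")
  expect_equal(kmer_ani(s, rc)$ani, 100)

  disjoint <- kmer_ani(paste(rep("A", 100), collapse = ""),
                       paste(rep("C", 100), collapse = ""))
  expect_true(disjoint$no_overlap)
  expect_equal(disjoint$ani, 0)

  # ~3% point mutations land in the expected ANI band
  for (sd in 1:10) {
    mut <- mutate_dna(s, 0.03, seed = 700 + sd)
    r <- kmer_ani(s, mut)
    expect_gt(r$ani, 95.5)
    expect_lt(r$ani, 98.5)
  }
})

test_that("the detection rule zeroes coverage at or below 25% detection", {
  raw <- data.frame(genome = "g", sample = paste0("s", 1:3),
                    mean_coverage = c(10, 10, 10),
                    detection = c(0.24, 0.25, 0.26))
  out <- apply_detection_rule(raw)
  expect_equal(out$mean_coverage, c(0, 0, 10))
  # idempotent
  expect_equal(apply_detection_rule(out), out)
})

test_that("coverage linking reproduces closed-form OLS and is affine-invariant", {
  # exact linearity (lm warns about the perfect fit; that is the point)
  x <- 1:10
  lr <- suppressWarnings(link_organelles(x, 2 * x))
  expect_equal(lr$r_squared, 1)
  expect_lt(lr$p, 1e-10)

  # hand-computed three-point case
  lr3 <- link_organelles(c(0, 1, 2), c(0, 1, 3))
  expect_equal(lr3$slope, 1.5)
  expect_equal(lr3$r_squared, 27 / 28, tolerance = 1e-12)

  # independent noise: no correlation
  set.seed(71)
  a <- rlnorm(1000); b <- rlnorm(1000)
  expect_lt(link_organelles(a, b)$r_squared, 0.01)

  # R^2 invariant to affine rescaling of either vector
  set.seed(72)
  u <- rlnorm(50); v <- 0.8 * u + rlnorm(50, 0, 0.2)
  base <- link_organelles(u, v)$r_squared
  expect_equal(link_organelles(3 * u + 7, v)$r_squared, base,
               tolerance = 1e-12)
  expect_equal(link_organelles(u, 0.1 * v - 2)$r_squared, base,
               tolerance = 1e-12)

  expect_error(link_organelles(rep(2, 5), 1:5), "degenerate")
})

test_that("candidate ranking recovers a planted correlated pair among decoys", {
  sim <- sim_coverage(n_genomes = 35, n_samples = 100,
                      linked_pairs = data.frame(i = 1, j = 2, rho = 0.98),
                      dropout_rate = 0.1, seed = 81)
  ranked <- rank_link_candidates(sim$coverage, target = "G001")
  expect_equal(nrow(ranked), 34L)
  expect_equal(ranked$candidate[1], "G002")
  # both variants reported for every candidate
  expect_true(all(!is.na(ranked$r_squared_raw)))
  expect_true(all(c("r_squared_detected", "p_detected") %in% names(ranked)))

  single <- rank_link_candidates(sim$coverage, target = "G001",
                                 candidates = "G002")
  expect_equal(nrow(single), 1L)
})
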