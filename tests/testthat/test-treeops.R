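test_that("Newick I/O round-trips and rejects malformed input", {
  tr <- read_newick("((A,B),(C,D));")
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B", "C", "D"))
  star <- read_newick("(A,B,C,D);")
  expect_equal(star$Nnode, 1L)
  expect_error(read_newick("((A,B);"), "malformed")
  # round trip with branch lengths
  t2 <- read_newick("((A:0.123456789,B:1):0.5,(C:2,D:3):0.25);")
  s <- write_newick(t2)
  t3 <- read_newick(s)
  expect_equal(sort(t3$tip.label), sort(t2$tip.label))
  expect_equal(sort(t3$edge.length), sort(t2$edge.length), tolerance = 1e-9)
})

test_that("strict consensus: identity, NNI neighbours, disjoint quartets", {
  t1 <- read_newick("((A,B),((C,D),E));")
  same <- strict_consensus(t1, t1)
  expect_equal(same$collapsed_count, 0L)
  expect_equal(length(same$shared_splits), 2L)  # n-3 = 2

  # one NNI step: one branch collapsed, consensus has one polytomy
  t2 <- read_newick("((A,C),((B,D),E));")
  nn <- strict_consensus(t1, t2)
  expect_equal(nn$collapsed_count, 2L - length(nn$shared_splits))

  q1 <- read_newick("((A,B),(C,D));")
  q2 <- read_newick("((A,C),(B,D));")
  dj <- strict_consensus(q1, q2)
  expect_equal(dj$collapsed_count, 1L)
  expect_equal(length(dj$shared_splits), 0L)
  expect_equal(dj$tree$Nnode, 1L)  # star on 4

  # commutative
  expect_equal(strict_consensus(t2, t1)$collapsed_count, nn$collapsed_count)
  expect_setequal(strict_consensus(t2, t1)$shared_splits, nn$shared_splits)

  expect_error(strict_consensus(q1, read_newick("((A,B),(C,E));")),
               "symmetric difference")
})

test_that("consensus oracle: collapsed counts match RF distance on all 5- and 6-taxon tree pairs", {
  skip_if_not_installed("phangorn")
  for (n in c(5, 6)) {
    trees <- phangorn::allTrees(n, rooted = FALSE,
                                tip.label = LETTERS[1:n])
    set.seed(n)
    idx <- t(utils::combn(length(trees), 2))
    # full enumeration is quadratic; sample a fixed subset for n = 6
    if (n == 6) idx <- idx[sample(nrow(idx), 300), , drop = FALSE]
    for (r in seq_len(nrow(idx))) {
      ta <- trees[[idx[r, 1]]]
      tb <- trees[[idx[r, 2]]]
      cons <- strict_consensus(ta, tb)
      # binary trees: collapsed = RF/2 (independent oracle)
      rf <- phangorn::RF.dist(ta, tb)
      expect_equal(cons$collapsed_count, rf / 2)
      expect_equal(length(cons$shared_splits), (n - 3) - rf / 2)
    }
  }
})

test_that("consensus splits are contained in each input's splits", {
  set.seed(17)
  for (rep in 1:10) {
    ta <- ape::rtree(7)
    tb <- ape::rtree(7)
    tb$tip.label <- sample(ta$tip.label)
    cons <- strict_consensus(ta, tb)
    oa <- oracle_splits(ta)
    ob <- oracle_splits(tb)
    oc <- oracle_splits(cons$tree)
    expect_true(all(oc %in% oa))
    expect_true(all(oc %in% ob))
  }
})

test_that("binary-resolution counts match exhaustive enumeration", {
  skip_if_not_installed("phangorn")
  expect_equal(count_binary_resolutions(read_newick("((A,B),(C,D),E);")), 1)
  expect_equal(count_binary_resolutions(read_newick("(A,B,C,D);")), 3)
  expect_equal(count_binary_resolutions(read_newick("(A,B,C,D,E);")), 15)
  expect_equal(count_binary_resolutions(read_newick("(A,B,C,D,E,F);")), 105)
  # enumeration oracle on random multifurcating trees with <= 6 leaves:
  # count binary trees whose splits contain the constraint's splits
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:6, 1)
    # random partially-resolved tree: strict consensus of two random
    # binary trees on the same labels
    ta <- ape::rtree(n, rooted = FALSE)
    tb <- ape::rtree(n, rooted = FALSE)
    tb$tip.label <- sample(ta$tip.label)
    poly <- strict_consensus(ta, tb)$tree
    all_bin <- phangorn::allTrees(n, rooted = FALSE,
                                  tip.label = sort(poly$tip.label))
    want <- oracle_splits(poly)
    n_compat <- sum(vapply(all_bin, function(b)
      all(want %in% oracle_splits(b)), logical(1)))
    expect_equal(count_binary_resolutions(poly), n_compat)
  }
})

test_that("the constraint set has six topologies with the named placements", {
  L <- paste0("L", 1:3); H <- paste0("H", 1:3); C <- paste0("C", 1:3)
  O <- paste0("O", 1:4); R <- paste0("R", 1:2)
  cs <- build_constraint_set(L, H, C, O, R)
  expect_length(cs, 6L)
  expect_setequal(names(cs),
                  c("HC_sister_mono", "HC_sister_free", "H_sister_mono",
                    "H_sister_free", "C_sister_mono", "C_sister_free"))
  # H-sister trees contain the split (leptophytes + haptophytes | rest)
  for (nm in c("H_sister_mono", "H_sister_free")) {
    lh_side <- sort(c(L, H))
    expect_true(paste(lh_side, collapse = "|") %in%
                oracle_splits(cs[[nm]]) ||
                paste(sort(setdiff(c(L, H, C, O, R), lh_side)),
                      collapse = "|") %in% oracle_splits(cs[[nm]]))
  }
  # monophyly variants contain the complex-plastid split
  cp <- sort(c(L, H, C, O))
  for (nm in c("HC_sister_mono", "H_sister_mono", "C_sister_mono")) {
    spl <- oracle_splits(cs[[nm]])
    expect_true(paste(cp, collapse = "|") %in% spl ||
                paste(sort(R), collapse = "|") %in% spl)
  }
  expect_error(build_constraint_set(L, H, c(C, L[1]), O, R), "overlap")
  expect_error(build_constraint_set(character(0), H, C, O, R), "non-empty")
})

test_that("compatibility follows split containment", {
  tr <- read_newick("((A,B),((C,D),E));")
  expect_true(is_compatible(tr, read_newick("(A,B,C,D,E);")))  # star
  expect_true(is_compatible(tr, tr))
  expect_false(is_compatible(read_newick("((A,B),(C,D));"),
                             read_newick("((A,C),(B,D));")))
  # constraint on a leaf subset
  expect_true(is_compatible(tr, read_newick("((A,B),(C,E));")))
  expect_error(is_compatible(tr, read_newick("((A,B),(C,Z));")), "missing")
})

test_that("fast-taxon removal ranks leaves by root-to-tip distance", {
  tr <- read_newick("((A:1,B:2):0.5,C:3);")
  tr <- ape::root(tr, outgroup = "C", resolve.root = TRUE)
  out <- remove_fastest_taxa(tr, 0)
  expect_equal(out$removed, character(0))
  tr2 <- read_newick("(A:1,(B:1.5,C:2.5):0.5);")
  got <- remove_fastest_taxa(tr2, 1)
  expect_equal(got$removed, "C")
  expect_equal(sort(got$tree$tip.label), c("A", "B"))
  # tie rule: equal distances, lexicographically first removed
  tie <- read_newick("(A:1,(B:0.5,C:0.5):0.5);")
  expect_equal(remove_fastest_taxa(tie, 1)$removed, "A")
  expect_error(remove_fastest_taxa(tr2, 3), "cannot remove")
})

test_that("UPGMA reproduces closed forms and ultrametric generators", {
  d2 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("A", "B"),
                                                    c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(unname(ape::node.depth.edgelength(t2)[1:2]), c(2, 2))

  labs <- c("A", "B", "C")
  d3 <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
               dimnames = list(labs, labs))
  t3 <- upgma(d3)
  expect_equal(unname(ape::node.depth.edgelength(t3)[1:3]), rep(3, 3))
  halves <- root_split(t3)
  expect_true(setequal(halves[[1]], c("A", "B")) ||
              setequal(halves[[2]], c("A", "B")))

  # ultrametric input: cophenetic distances reproduced exactly
  set.seed(12)
  gen <- ape::rcoal(6)
  dm <- ape::cophenetic.phylo(gen)
  rebuilt <- upgma(dm)
  expect_equal(ape::cophenetic.phylo(rebuilt)[rownames(dm), colnames(dm)],
               dm, tolerance = 1e-9)
  # ultrametric within 1e-9
  depths <- ape::node.depth.edgelength(rebuilt)[1:6]
  expect_lt(diff(range(depths)), 1e-9)

  expect_error(upgma(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})
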