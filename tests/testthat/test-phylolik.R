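test_that("transition matrices are stochastic, reversible, identity at t = 0", {
  for (mod in list(load_model("LG", alpha = 0.8, m = 4),
                   load_model("cpREV"),
                   dna4_model())) {
    expect_equal(transition_probs(mod, 0), diag(mod$k))
    for (t in c(0.01, 0.3, 2)) {
      P <- transition_probs(mod, t)
      expect_equal(rowSums(P), rep(1, mod$k), tolerance = 1e-10)
      # detailed balance pi_i P_ij = pi_j P_ji
      flux <- mod$freqs * P
      expect_equal(flux, t(flux), tolerance = 1e-10)
    }
  }
})

test_that("discrete-gamma rates average to one", {
  for (alpha in c(0.2, 0.7, 1, 5, 50))
    for (m in c(1, 2, 4, 8))
      expect_equal(mean(discrete_gamma_rates(alpha, m)), 1,
                   tolerance = 1e-12)
  # stronger rate variation at smaller alpha
  expect_gt(diff(range(discrete_gamma_rates(0.3, 4))),
            diff(range(discrete_gamma_rates(2, 4))))
})

test_that("two-leaf boundary cases: identical at t = 0 gives -ln k, conflict gives -Inf", {
  mod <- dna4_model()
  tr <- read_newick("(X:0,Y:0);")
  same <- alignment(c(X = "A", Y = "A"), alphabet = mod$states)
  expect_equal(site_log_likelihoods(same, tr, mod), -log(4))
  diff <- alignment(c(X = "A", Y = "C"), alphabet = mod$states)
  expect_warning(lnl <- site_log_likelihoods(diff, tr, mod), "impossible")
  expect_identical(lnl, -Inf)
})

test_that("pruning equals exhaustive internal-state summation on 3 taxa", {
  # brute force over internal node states with transition matrices
  # cross-validated against an independent matrix exponential
  mod <- load_model("LG", alpha = 0.9, m = 2)
  t_root_a <- 0.2; t_root_b <- 0.35; t_root_c <- 0.6
  tr <- read_newick(sprintf("(A:%g,B:%g,C:%g);", t_root_a, t_root_b,
                            t_root_c))
  aln <- alignment(c(A = "MW", B = "MW", C = "MF"))
  mine <- site_log_likelihoods(aln, tr, mod)
  k <- mod$k
  codes <- match(aln$matrix[c("A", "B", "C"), ], mod$states)
  dim(codes) <- c(3, 2)
  brute <- numeric(2)
  for (s in 1:2) {
    tot <- 0
    for (cat in 1:mod$m) {
      r <- mod$rates[cat]
      Pa <- as.matrix(Matrix::expm(mod$Q * t_root_a * r))
      Pb <- as.matrix(Matrix::expm(mod$Q * t_root_b * r))
      Pc <- as.matrix(Matrix::expm(mod$Q * t_root_c * r))
      L <- 0
      for (root in 1:k)
        L <- L + mod$freqs[root] * Pa[root, codes[1, s]] *
          Pb[root, codes[2, s]] * Pc[root, codes[3, s]]
      tot <- tot + L / mod$m
    }
    brute[s] <- log(tot)
  }
  expect_equal(mine, brute, tolerance = 1e-8)
})

test_that("pruning matches an independent implementation on random trees up to 5 leaves", {
  skip_if_not_installed("phangorn")
  mod <- load_model("LG", alpha = 0.7, m = 4)
  for (seed in 1:4) {
    n <- 3 + (seed %% 3)
    tr <- fixture_tree(n, seed = 100 + seed)
    sim <- sim_alignment(tr, mod, 40, seed = 200 + seed)
    mine <- sum(site_log_likelihoods(sim$alignment, tr, mod))
    pd <- phangorn::phyDat(sim$alignment$matrix, type = "AA")
    fit <- phangorn::pml(tr, pd, model = "LG", k = 4, shape = 0.7)
    expect_equal(mine, fit$logLik, tolerance = 1e-6)
  }
})

test_that("likelihood is invariant to re-rooting (pulley principle)", {
  mod <- dna4_model(m = 2, alpha = 0.5)
  tr <- fixture_tree(6, seed = 41)
  sim <- sim_alignment(tr, mod, 60, seed = 42)
  base <- sum(site_log_likelihoods(sim$alignment, ape::unroot(tr), mod))
  for (og in tr$tip.label[1:3]) {
    rerooted <- ape::root(ape::unroot(tr), outgroup = og,
                          resolve.root = TRUE)
    expect_equal(sum(site_log_likelihoods(sim$alignment, rerooted, mod)),
                 base, tolerance = 1e-8)
  }
})

test_that("site-profile likelihoods mix fixed frequency profiles per site", {
  mod <- dna4_model()
  tr <- fixture_tree(4, seed = 55)
  sim <- sim_alignment(tr, mod, 20, seed = 56)
  prof <- site_profiles(rbind(c(0.7, 0.1, 0.1, 0.1),
                              c(0.25, 0.25, 0.25, 0.25)),
                        rep(c(1L, 2L), each = 10))
  mixed <- site_log_likelihoods(sim$alignment, tr, mod, prof)
  # profile 2 is uniform = the base model
  plain <- site_log_likelihoods(sim$alignment, tr, mod)
  expect_equal(mixed[11:20], plain[11:20], tolerance = 1e-10)
  expect_false(isTRUE(all.equal(mixed[1:10], plain[1:10])))
})

test_that("total log-likelihood is additive over sites", {
  mod <- dna4_model()
  tr <- fixture_tree(5, seed = 61)
  sim <- sim_alignment(tr, mod, 30, seed = 62)
  per_site <- site_log_likelihoods(sim$alignment, tr, mod)
  expect_equal(total_log_likelihood(sim$alignment, tr, mod), sum(per_site))
  empty <- alignment(matrix(character(0), 5, 0,
                            dimnames = list(tr$tip.label, NULL)),
                     alphabet = mod$states)
  expect_equal(total_log_likelihood(empty, tr, mod), 0)
})

test_that("branch-length optimization improves lnL and recovers simulated lengths", {
  mod <- dna4_model()
  # identical two-leaf sequences: optimum at the zero boundary
  two <- read_newick("(X:1,Y:1);")
  same <- alignment(c(X = paste(rep("A", 30), collapse = ""),
                      Y = paste(rep("A", 30), collapse = "")),
                    alphabet = mod$states)
  fit0 <- optimize_branch_lengths(same, two, mod)
  expect_equal(sum(fit0$tree$edge.length), 0)

  tr <- fixture_tree(6, seed = 71, scale = 1, min_len = 0.08)
  sim <- sim_alignment(tr, mod, 2000, seed = 72)
  init_lnl <- {
    t0 <- ape::unroot(tr)
    t0$edge.length <- rep(0.1, nrow(t0$edge))
    total_log_likelihood(sim$alignment, t0, mod)
  }
  fit <- optimize_branch_lengths(sim$alignment, ape::unroot(tr), mod)
  expect_gte(fit$lnL, init_lnl)
  # recovered lengths close to truth (median relative error)
  tru <- ape::unroot(tr)
  match_edges <- function(a, b) {
    # compare sorted branch lengths of identical topologies
    sort(a$edge.length)
  }
  rel_err <- abs(sort(fit$tree$edge.length) - sort(tru$edge.length)) /
    sort(tru$edge.length)
  expect_lt(median(rel_err), 0.15)
})

test_that("site-lnL tables round-trip and reject inconsistent rows", {
  m <- matrix(c(-1.25, -2.5, -3.75, -4.0625,
                -11.1, -2.2e-3, -3.3e+2, -4.4), 2, 4, byrow = TRUE,
              dimnames = list(c("topoA", "topoB"), NULL))
  path <- tempfile(fileext = ".sitelh")
  write_sitelh(m, path)
  back <- read_sitelh(path)
  expect_equal(back, m, tolerance = 1e-9)
  lines <- readLines(path)
  expect_equal(lines[1], "2 4")
  writeLines(c("2 4", "a -1 -2 -3 -4", "b -1 -2 -3"), path)
  expect_error(read_sitelh(path), "expected 4")
  writeLines(c("2 4", "a -1 -2 -3 -4"), path)
  expect_error(read_sitelh(path), "rows")
})
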