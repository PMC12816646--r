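# Topology test battery: likelihood-ratio chi-squared test with
# consensus-derived degrees of freedom, Bonferroni correction over the
# trees compatible with the strict consensus, and the approximately
# unbiased (AU) test via RELL multiscale bootstrap.

#' Likelihood-ratio chi-squared test between two topologies
#'
#' LRS = 2 |lnL_a - lnL_b|; degrees of freedom = number of branches
#' collapsed in the strict consensus of the two trees; p = upper tail
#' of chi-squared(df) at LRS.
#'
#' @param lnL_a,lnL_b maximized log-likelihoods of the two topologies
#'   under the same model.
#' @param tree_a,tree_b the corresponding \code{phylo} topologies.
#' @return List with \code{LRS}, \code{df}, \code{p}.
#' @export
lrs_chisq_test <- function(lnL_a, lnL_b, tree_a, tree_b) {
  stopifnot(is.finite(lnL_a), is.finite(lnL_b))
  LRS <- 2 * abs(lnL_a - lnL_b)
  df <- strict_consensus(tree_a, tree_b)$collapsed_count
  if (df == 0) {
    if (LRS > 1e-8)
      stop("identical topologies with different maximized log-likelihoods ",
           "(LRS = ", format(LRS), "); check the inputs")
    return(list(LRS = 0, df = 0L, p = 1))
  }
  list(LRS = LRS, df = df,
       p = stats::pchisq(LRS, df = df, lower.tail = FALSE))
}

#' Bonferroni correction over consensus-compatible trees
#'
#' Corrected p = 1 - (1 - p)^A, where A is the number of fully binary
#' trees compatible with the strict consensus of the pair under test.
#'
#' @param p raw p-value in [0, 1].
#' @param A number of compatible trees (>= 1).
#' @return Corrected p-value.
#' @export
bonferroni_correct <- function(p, A) {
  stopifnot(p >= 0, p <= 1)
  if (A < 1) stop("A must be >= 1")
  1 - (1 - p)^A
}

#' Approximately unbiased (AU) test from site log-likelihoods
#'
#' RELL multiscale bootstrap: for each scale r, B multinomial resamples
#' of size round(r N) over sites; BP_r is the fraction of replicates in
#' which the focal topology attains the maximal resampled
#' log-likelihood sum (exact ties split uniformly among the tied
#' topologies).  probit(1 - BP_r) is regressed on d sqrt(r) + c/sqrt(r)
#' by weighted least squares over non-degenerate scales, and
#' p_AU = 1 - Phi(d - c).
#'
#' @param sitelh matrix topologies x sites of per-site log-likelihoods
#'   (row names label topologies).
#' @param scales bootstrap scale factors.
#' @param B replicates per scale.
#' @param seed RNG seed.
#' @return Data frame, one row per topology: \code{topology},
#'   \code{p_AU}, \code{d}, \code{c}, \code{degenerate}, plus the BP
#'   matrix as attribute \code{"BP"} (topologies x scales).
#' @export
au_test <- function(sitelh, scales = seq(0.5, 1.4, by = 0.1), B = 10000,
                    seed = 1) {
  stopifnot(is.matrix(sitelh), nrow(sitelh) >= 1)
  N <- ncol(sitelh)
  if (N < 10) stop("need at least 10 sites")
  K <- nrow(sitelh)
  labs <- rownames(sitelh)
  if (is.null(labs)) labs <- paste0("T", seq_len(K))
  set.seed(seed)
  BP <- matrix(0, K, length(scales), dimnames = list(labs, scales))
  chunk <- 1000L
  for (si in seq_along(scales)) {
    n_r <- max(1L, round(scales[si] * N))
    done <- 0L
    wins <- numeric(K)
    while (done < B) {
      b <- min(chunk, B - done)
      wmat <- stats::rmultinom(b, n_r, rep(1 / N, N))   # N x b
      res <- sitelh %*% wmat                            # K x b
      mx <- apply(res, 2, max)
      tied <- res >= rep(mx, each = K) - 1e-9
      wins <- wins + rowSums(sweep(tied, 2, colSums(tied), `/`))
      done <- done + b
    }
    BP[, si] <- wins / B
  }
  out <- data.frame(topology = labs, p_AU = NA_real_, d = NA_real_,
                    c = NA_real_, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(K)) {
    bp <- BP[i, ]
    use <- bp > 0 & bp < 1
    if (sum(use) < 2) {
      out$degenerate[i] <- TRUE
      out$p_AU[i] <- if (mean(bp) >= 0.5) 1 else 0
      next
    }
    z <- stats::qnorm(1 - bp[use])
    r <- scales[use]
    X <- cbind(sqrt(r), 1 / sqrt(r))
    w <- B * stats::dnorm(z)^2 / (bp[use] * (1 - bp[use]))
    fit <- stats::lm.wfit(X, z, w)
    d <- fit$coefficients[1]; cc <- fit$coefficients[2]
    out$d[i] <- d; out$c[i] <- cc
    out$p_AU[i] <- stats::pnorm(d - cc, lower.tail = FALSE)
  }
  attr(out, "BP") <- BP
  out
}

#' Run the full topology-test battery
#'
#' Given candidate topologies and either an alignment (branch lengths
#' are optimized per topology under \code{model}) or an externally
#' computed site log-likelihood table, identifies the best-scoring
#' topology and, for each alternative, reports the likelihood-ratio
#' chi-squared test with consensus-derived degrees of freedom, its
#' Bonferroni correction over the A consensus-compatible binary trees,
#' and the AU test.
#'
#' @param trees named list of \code{phylo} topologies on a common leaf
#'   set.
#' @param aln optional \code{alignment} (required unless
#'   \code{sitelh} is given).
#' @param model \code{subst_model} used when optimizing from
#'   \code{aln}.
#' @param sitelh optional matrix topologies x sites of site
#'   log-likelihoods; row names must match \code{names(trees)}.
#' @param profiles optional \code{site_profiles} for the engine.
#' @param alpha rejection level for the flag columns.
#' @param scales,B,seed AU test controls.
#' @return Data frame sorted by \code{delta_lnL} with columns topology,
#'   lnL, delta_lnL, df, A, p_chisq, p_bonferroni, p_AU,
#'   rejected_chisq, rejected_AU.  Optimized trees (alignment route)
#'   are attached as attribute \code{"trees"}.
#' @export
run_battery <- function(trees, aln = NULL, model = NULL, sitelh = NULL,
                        profiles = NULL, alpha = 0.05,
                        scales = seq(0.5, 1.4, by = 0.1), B = 10000,
                        seed = 1) {
  stopifnot(length(trees) >= 2)
  if (is.null(names(trees)))
    names(trees) <- paste0("T", seq_along(trees))
  labs <- names(trees)
  fitted <- NULL
  if (is.null(sitelh)) {
    if (is.null(aln) || is.null(model))
      stop("supply either sitelh or aln + model")
    fitted <- lapply(trees, function(tr)
      optimize_branch_lengths(aln, tr, model, profiles))
    sitelh <- do.call(rbind, lapply(fitted, function(f)
      site_log_likelihoods(aln, f$tree, model, profiles)))
    rownames(sitelh) <- labs
  } else {
    if (!setequal(rownames(sitelh), labs))
      stop("sitelh row names must match tree names")
    sitelh <- sitelh[labs, , drop = FALSE]
  }
  lnL <- rowSums(sitelh)
  best <- which.max(lnL)
  au <- au_test(sitelh, scales = scales, B = B, seed = seed)
  out <- data.frame(topology = labs, lnL = lnL,
                    delta_lnL = lnL[best] - lnL,
                    df = NA_integer_, A = NA_real_,
                    p_chisq = NA_real_, p_bonferroni = NA_real_,
                    p_AU = au$p_AU[match(labs, au$topology)],
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_along(labs)) {
    if (i == best) {
      out$df[i] <- 0L; out$A[i] <- 1
      out$p_chisq[i] <- 1; out$p_bonferroni[i] <- 1
      next
    }
    cons <- strict_consensus(trees[[best]], trees[[i]])
    ct <- lrs_chisq_test(lnL[best], lnL[i], trees[[best]], trees[[i]])
    out$df[i] <- ct$df
    out$A[i] <- count_binary_resolutions(cons$tree)
    out$p_chisq[i] <- ct$p
    out$p_bonferroni[i] <- bonferroni_correct(ct$p, out$A[i])
  }
  out$rejected_chisq <- !is.na(out$p_bonferroni) & out$p_bonferroni < alpha &
    seq_along(labs) != best
  out$rejected_AU <- !is.na(out$p_AU) & out$p_AU < alpha &
    seq_along(labs) != best
  out <- out[order(out$delta_lnL), ]
  rownames(out) <- NULL
  if (!is.null(fitted)) attr(out, "trees") <- lapply(fitted, `[[`, "tree")
  attr(out, "sitelh") <- sitelh
  out
}

#' Write a battery report as TSV
#' @param report data frame from \code{\link{run_battery}}.
#' @param path output file.
#' @export
write_battery_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
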