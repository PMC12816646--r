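# Substitution models: empirical amino-acid exchangeabilities with
# equilibrium frequencies, discrete-gamma rate variation, and
# transition probabilities via symmetric eigendecomposition.

#' Construct a substitution model
#'
#' A reversible k-state model Q = S diag(pi), scaled so the expected
#' rate at equilibrium is 1 substitution/site, with m equal-weight
#' discrete-gamma rate categories of shape \code{alpha}.
#'
#' @param S symmetric exchangeability matrix (off-diagonal positive;
#'   diagonal ignored).
#' @param freqs equilibrium frequencies (normalized to sum to 1).
#' @param alpha gamma shape (> 0); ignored when \code{m = 1}.
#' @param m number of rate categories (>= 1).
#' @param name model label.
#' @return A \code{subst_model}: list with \code{k}, \code{S},
#'   \code{freqs}, \code{Q}, \code{alpha}, \code{m}, \code{rates},
#'   \code{name}, and cached eigendecomposition.
#' @export
subst_model <- function(S, freqs, alpha = 1, m = 4, name = "custom") {
  k <- length(freqs)
  stopifnot(nrow(S) == k, ncol(S) == k, all(freqs > 0), alpha > 0, m >= 1)
  if (max(abs(S - t(S))) > 1e-8) stop("exchangeabilities must be symmetric")
  freqs <- freqs / sum(freqs)
  Q <- build_q(S, freqs)
  eig <- q_eigen(Q, freqs)
  structure(list(k = k, S = S, freqs = freqs, Q = Q,
                 alpha = alpha, m = as.integer(m),
                 rates = discrete_gamma_rates(alpha, m),
                 eig = eig, name = name,
                 states = colnames(S)),
            class = "subst_model")
}

# Scaled rate matrix from exchangeabilities and frequencies.
build_q <- function(S, freqs) {
  Q <- S %*% diag(freqs)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(freqs * diag(Q))
  Q / rate
}

# Symmetric eigendecomposition of diag(sqrt(pi)) Q diag(1/sqrt(pi)).
q_eigen <- function(Q, freqs) {
  sp <- sqrt(freqs)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       right = diag(1 / sp) %*% e$vectors,   # columns: right eigenvectors of Q
       left = t(e$vectors) %*% diag(sp))
}

#' Discrete-gamma category rates
#'
#' m equal-probability categories; each category rate is the mean of
#' its quantile bin of the Gamma(alpha, alpha) distribution, then the
#' set is normalized to mean exactly 1.
#'
#' @param alpha gamma shape.
#' @param m number of categories.
#' @return Numeric vector of m rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, m) {
  if (m == 1) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = m + 1), shape = alpha,
                     rate = alpha)
  # mean of Gamma(alpha, alpha) over [b_i, b_{i+1}] times m
  cum <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  r <- m * diff(cum)
  r / mean(r)
}

#' Transition probability matrix P(t) = exp(Qt)
#' @param model a \code{subst_model}.
#' @param t branch length (expected substitutions/site) >= 0.
#' @return k x k stochastic matrix.
#' @export
transition_probs <- function(model, t) {
  stopifnot(t >= 0)
  if (t == 0) return(diag(model$k))
  P <- model$eig$right %*% (exp(model$eig$values * t) * model$eig$left)
  P[P < 0] <- 0
  P
}

read_model_file <- function(path, alpha = 1, m = 4, name) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  states <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  k <- length(states)
  S <- matrix(0, k, k, dimnames = list(states, states))
  for (i in 2:k) {
    vals <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
    S[i, 1:(i - 1)] <- vals
    S[1:(i - 1), i] <- vals
  }
  freqs <- as.numeric(strsplit(trimws(lines[k + 1]), "\\s+")[[1]])
  names(freqs) <- states
  subst_model(S, freqs, alpha = alpha, m = m, name = name)
}

#' Load a bundled empirical amino-acid model
#'
#' Standard published exchangeability/frequency tables shipped as
#' plain-text files: \code{"LG"} (general nuclear/organellar proteins)
#' and \code{"cpREV"} (chloroplast-encoded proteins).
#'
#' @param name \code{"LG"} or \code{"cpREV"}.
#' @param alpha gamma shape.
#' @param m number of rate categories (e.g. 4 for the usual +G4).
#' @param freqs optional replacement equilibrium frequencies (the +F
#'   case: observed alignment frequencies).
#' @return A \code{subst_model}.
#' @export
load_model <- function(name = c("LG", "cpREV"), alpha = 1, m = 4,
                       freqs = NULL) {
  name <- match.arg(name)
  file <- c(LG = "lg.txt", cpREV = "cprev.txt")[[name]]
  path <- system.file("extdata", file, package = "leptokit")
  if (path == "") stop("bundled model file missing: ", file)
  mod <- read_model_file(path, alpha = alpha, m = m, name = name)
  if (!is.null(freqs)) mod <- subst_model(mod$S, freqs, alpha = alpha,
                                          m = m, name = paste0(name, "+F"))
  mod
}

#' Equal-rates (Poisson-type) model on an arbitrary alphabet
#'
#' All exchangeabilities equal, uniform frequencies by default; handy
#' for recoded alphabets and toy examples.
#'
#' @param states state labels (e.g. the 20 amino acids or
#'   \code{c("1","2","3","4")}).
#' @param freqs optional frequencies.
#' @param alpha,m gamma parameters.
#' @return A \code{subst_model}.
#' @export
poisson_model <- function(states = AA_ALPHABET, freqs = NULL,
                          alpha = 1, m = 1) {
  k <- length(states)
  S <- matrix(1, k, k, dimnames = list(states, states))
  diag(S) <- 0
  if (is.null(freqs)) freqs <- rep(1 / k, k)
  subst_model(S, freqs, alpha = alpha, m = m, name = "Poisson")
}

#' Site-profile set (PMSF-style fixed frequency profiles)
#'
#' @param profiles matrix (classes x states), each row a frequency
#'   vector summing to 1.
#' @param assignment integer vector mapping each site to a profile row.
#' @return A \code{site_profiles} object.
#' @export
site_profiles <- function(profiles, assignment) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  stopifnot(all(abs(rowSums(profiles) - 1) < 1e-9),
            all(assignment >= 1), all(assignment <= nrow(profiles)))
  structure(list(profiles = profiles, assignment = as.integer(assignment)),
            class = "site_profiles")
}
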