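# Reversible amino-acid substitution models: Q = S diag(pi) with symmetric
# exchangeabilities S, rows summing to zero, normalized to one expected
# substitution per site at relative rate 1. Across-site rate variation by
# discrete gamma (category means, equal weights) plus a proportion of
# invariant sites handled as a separate mixture component.

#' Construct a reversible substitution model
#'
#' @param exchangeabilities symmetric non-negative matrix (diagonal ignored);
#'   default all ones (Poisson / proteins-JC).
#' @param frequencies stationary frequencies summing to 1; default uniform.
#' @param gamma_shape shape alpha of the discrete-gamma across-site rate
#'   model, or `NULL` for homogeneous rates.
#' @param n_categories number of gamma categories (default 4).
#' @param prop_invariant proportion of invariant sites in `[0, 1)`.
#' @param alphabet state labels; default the 20 amino acids (PAML order).
#' @return an object of class `subst_model`.
#' @export
subst_model <- function(exchangeabilities = NULL, frequencies = NULL,
                        gamma_shape = NULL, n_categories = 4L,
                        prop_invariant = 0, alphabet = aa_alphabet()) {
  ns <- length(alphabet)
  if (is.null(exchangeabilities)) {
    exchangeabilities <- matrix(1, ns, ns)
  }
  S <- as.matrix(exchangeabilities)
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-10)) || any(S[upper.tri(S)] < 0))
    stop_invalid("exchangeabilities must be a symmetric non-negative matrix")
  if (is.null(frequencies)) frequencies <- rep(1 / ns, ns)
  pi <- as.numeric(frequencies)
  if (length(pi) != ns || any(pi <= 0))
    stop_invalid("frequencies must be positive and match the alphabet")
  if (abs(sum(pi) - 1) > 1e-8)
    stop_invalid("frequencies must sum to 1")
  pi <- pi / sum(pi)
  if (!is.null(gamma_shape) && gamma_shape <= 0)
    stop_invalid("gamma_shape must be positive")
  if (prop_invariant < 0 || prop_invariant >= 1)
    stop_invalid("prop_invariant must lie in [0, 1)")
  n_categories <- as.integer(n_categories)
  if (n_categories < 1L) stop_invalid("n_categories must be >= 1")

  diag(S) <- 0
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop_invalid("degenerate model: zero substitution rate")
  Q <- Q / scale

  m <- structure(list(alphabet = alphabet, exchangeabilities = S,
                      frequencies = pi, Q = Q, gamma_shape = gamma_shape,
                      n_categories = n_categories,
                      prop_invariant = prop_invariant),
                 class = "subst_model")
  # detailed balance must hold by construction; verify defensively
  DB <- diag(pi) %*% Q
  if (max(abs(DB - t(DB))) > 1e-9)
    stop_invalid("model violates detailed balance")
  m
}

#' Poisson (equal-rates) amino-acid model
#'
#' @inheritParams subst_model
#' @return a `subst_model` with uniform exchangeabilities and (by default)
#'   uniform frequencies.
#' @export
poisson_model <- function(gamma_shape = NULL, n_categories = 4L,
                          prop_invariant = 0, frequencies = NULL) {
  subst_model(NULL, frequencies, gamma_shape, n_categories, prop_invariant)
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("<subst_model> %d states, %s%s\n", length(x$alphabet),
              if (is.null(x$gamma_shape)) "homogeneous rates"
              else sprintf("+G (alpha=%.3g, k=%d)", x$gamma_shape, x$n_categories),
              if (x$prop_invariant > 0)
                sprintf(" +I (p=%.3g)", x$prop_invariant) else ""))
  invisible(x)
}

#' Read a PAML-format empirical exchangeability matrix
#'
#' Parses the standard `.dat` layout: 190 lower-triangle exchangeabilities
#' (rows for states 2..20) followed by 20 stationary frequencies.
#'
#' @param path path to the `.dat` file.
#' @param ... passed to [subst_model()] (rate model settings).
#' @return a `subst_model`.
#' @export
read_paml_dat <- function(path, ...) {
  txt <- readLines(path, warn = FALSE)
  nums <- as.numeric(unlist(regmatches(txt, gregexpr(
    "[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?", txt))))
  nums <- nums[!is.na(nums)]
  if (length(nums) < 210)
    stop_invalid("PAML .dat file must contain 190 exchangeabilities + 20 frequencies")
  S <- matrix(0, 20, 20)
  k <- 1
  for (i in 2:20) for (j in 1:(i - 1)) {
    S[i, j] <- S[j, i] <- nums[k]
    k <- k + 1
  }
  freqs <- nums[k:(k + 19)]
  subst_model(S, freqs / sum(freqs), ...)
}

#' Discrete-gamma category rates (mean method)
#'
#' Category rates are the means of `k` equal-probability slices of a
#' Gamma(alpha, alpha) distribution, rescaled to mean exactly 1.
#'
#' @param alpha gamma shape.
#' @param k number of categories.
#' @return numeric vector of `k` relative rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  k <- as.integer(k)
  if (k == 1L) return(1)
  b <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  # E[X; a<X<b] for Gamma(alpha, alpha) via the shape+1 cdf
  cum <- pgamma(b, shape = alpha + 1, rate = alpha)
  r <- k * diff(cum)
  r / mean(r) * 1  # exact mean 1 against tail round-off
}

model_rates <- function(model) {
  if (is.null(model$gamma_shape)) return(1)
  discrete_gamma_rates(model$gamma_shape, model$n_categories)
}

# Spectral factors of the reversible generator: with D = diag(sqrt(pi)),
# B0 = D Q D^-1 is symmetric; P(t) = A diag(exp(lambda t)) B with
# A = D^-1 U, B = U' D.
model_eigen <- function(model) {
  pi <- model$frequencies
  d <- sqrt(pi)
  B0 <- diag(d) %*% model$Q %*% diag(1 / d)
  B0 <- (B0 + t(B0)) / 2
  e <- eigen(B0, symmetric = TRUE)
  list(lambda = e$values,
       A = diag(1 / d) %*% e$vectors,
       B = t(e$vectors) %*% diag(d))
}

# Transition matrix exp(Q t) from cached spectral factors.
prob_matrix <- function(eg, t) {
  P <- eg$A %*% (exp(eg$lambda * t) * eg$B)
  P[P < 0] <- 0
  P
}
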