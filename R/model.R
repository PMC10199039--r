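## Empirical amino-acid substitution model machinery.
##
## The JTT exchangeability matrix (Jones, Taylor & Thornton 1992) and its
## stationary frequencies are standard published model data; the 190
## lower-triangle exchangeabilities are stored column-wise in the order
## A R N D C Q E G H I L K M F P S T W Y V.

.aa_states <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.jtt_exch <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
  11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64,
  126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232,
  8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46,
  31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26,
  597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18,
  5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47,
  16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40,
  245, 9, 32, 961, 14, 388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47,
  103, 10, 8, 14, 43, 16, 29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62,
  285, 118, 6, 10, 23, 477, 35, 63, 38, 12, 21, 112, 71, 25, 16)

.jtt_freqs <- c(
  0.076748, 0.051691, 0.042645, 0.051544, 0.019803, 0.040752, 0.061830,
  0.073152, 0.022944, 0.053761, 0.091904, 0.058676, 0.023826, 0.040126,
  0.050901, 0.068765, 0.058565, 0.014261, 0.032102, 0.066005)

#' Build a reversible rate matrix from exchangeabilities and frequencies
#'
#' Assembles the instantaneous rate matrix `Q = S diag(pi)` from a symmetric
#' exchangeability matrix (given as its lower triangle, column-wise) and
#' stationary frequencies, normalized to one expected substitution per unit
#' branch length, and eigendecomposes it for fast transition probabilities.
#'
#' @param exch numeric vector, lower triangle of the symmetric
#'   exchangeability matrix (column-wise).
#' @param freqs stationary state frequencies (will be renormalized).
#' @param states character vector of state names.
#' @return an object of class `subst_model`: list with `states`, `freqs`,
#'   and the eigendecomposition used by [transition_matrix()].
#' @export
subst_model <- function(exch = .jtt_exch, freqs = .jtt_freqs,
                        states = .aa_states) {
  k <- length(states)
  stopifnot(length(freqs) == k, length(exch) == k * (k - 1) / 2)
  pi <- freqs / sum(freqs)
  S <- matrix(0, k, k)
  S[lower.tri(S)] <- exch
  S <- S + t(S)
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))            # expected rate at stationarity
  Q <- Q / mu
  ## symmetrize: B = D^1/2 Q D^-1/2 with D = diag(pi)
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(states = states, freqs = pi,
                 values = eig$values,
                 U = diag(1 / d) %*% eig$vectors,     # right transform
                 W = t(eig$vectors) %*% diag(d)),     # left transform
            class = "subst_model")
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a [subst_model()].
#' @param t branch length (expected substitutions per site), `t >= 0`.
#' @return k x k stochastic matrix.
#' @export
transition_matrix <- function(model, t) {
  P <- model$U %*% (exp(model$values * t) * model$W)
  ## clip tiny negative values from numerical error
  P[P < 0] <- 0
  P
}

#' Discrete-gamma rate categories
#'
#' Mean rates of `k` equal-probability categories of a gamma distribution
#' with shape `alpha` and mean 1 (delegated to [phangorn::discrete.gamma()]).
#'
#' @param alpha gamma shape parameter.
#' @param k number of categories (default 4).
#' @return numeric vector of `k` rates with mean 1.
#' @export
gamma_rates <- function(alpha, k = 4) {
  phangorn::discrete.gamma(alpha, k)
}

## encode an alignment matrix into state indices; NA = gap/ambiguous
encode_states <- function(m, states) {
  idx <- match(m, states)
  matrix(idx, nrow(m), ncol(m), dimnames = dimnames(m))
}
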