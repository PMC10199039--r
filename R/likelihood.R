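## Per-site likelihoods of the three unrooted quartet topologies under an
## empirical amino-acid model with discrete-gamma rate variation.

#' The three unrooted topologies of a focal quartet
#'
#' Given the four tip labels (two per species), returns the three possible
#' unrooted quartet topologies as central splits, labelled by their
#' category type: the same-species split is `PostSpecType`, the two
#' mixed-species splits are `PreSpecType`.
#'
#' @param labels character vector of 4 tip labels (`"Species|gene"`).
#' @param species optional named species vector (else parsed from labels).
#' @return named list of three topologies; each is a list with `pair1`,
#'   `pair2` (two tip labels each) and `type`.
#' @export
quartet_topologies <- function(labels, species = NULL) {
  if (is.null(species)) species <- quartet_species(labels)
  check_two_per_species(species, labels)
  sps <- sort(unique(species[labels]))
  s_tips <- labels[species[labels] == sps[1]]
  p_tips <- labels[species[labels] == sps[2]]
  tops <- list(
    PostSpecType = list(pair1 = s_tips, pair2 = p_tips,
                        type = "PostSpecType"),
    PreSpecType1 = list(pair1 = c(s_tips[1], p_tips[1]),
                        pair2 = c(s_tips[2], p_tips[2]),
                        type = "PreSpecType"),
    PreSpecType2 = list(pair1 = c(s_tips[1], p_tips[2]),
                        pair2 = c(s_tips[2], p_tips[1]),
                        type = "PreSpecType"))
  tops
}

#' Per-site log-likelihoods of a quartet topology
#'
#' Computes, by the pruning algorithm, the per-site natural-log likelihoods
#' of a 4-taxon alignment on a given unrooted quartet topology under an
#' empirical exchangeability model with `k` equal-probability discrete
#' gamma categories (mean rate 1). The five branch lengths are optimized
#' numerically by coordinate-wise bounded scalar optimization (default two
#' sweeps, lower bound 1e-6). Columns gapped in all four sequences are
#' skipped and recorded in the `skipped` attribute.
#'
#' @param aln alignment (character matrix or named strings) with the four
#'   quartet sequences.
#' @param topology a topology from [quartet_topologies()] (list with
#'   `pair1`, `pair2`).
#' @param model a [subst_model()] (default JTT).
#' @param alpha gamma shape (default 1).
#' @param k number of gamma categories (default 4).
#' @param optimize_branches optimize the five branch lengths (default TRUE);
#'   otherwise `branch_lengths` are used as given.
#' @param branch_lengths initial (or fixed) branch lengths: tips of
#'   `pair1`, tips of `pair2`, internal.
#' @param sweeps number of coordinate-optimization sweeps.
#' @return numeric vector of per-site log-likelihoods over the retained
#'   columns, with attributes `skipped` (indices of all-gap columns),
#'   `branch_lengths` and `logLik`.
#' @export
site_log_likelihoods <- function(aln, topology, model = subst_model(),
                                 alpha = 1, k = 4,
                                 optimize_branches = TRUE,
                                 branch_lengths = rep(0.1, 5),
                                 sweeps = 2) {
  m <- as_aln_matrix(aln)
  if (nrow(m) != 4) stop("need exactly four sequences")
  tips <- c(topology$pair1, topology$pair2)
  if (!all(tips %in% rownames(m))) stop("alignment rows must match topology tips")
  enc <- encode_states(m[tips, , drop = FALSE], model$states)
  allgap <- colSums(!is.na(enc)) == 0
  skipped <- which(allgap)
  enc <- enc[, !allgap, drop = FALSE]
  if (ncol(enc) < 1) stop("no non-gap column in the alignment")
  rates <- gamma_rates(alpha, k)

  ## pattern compression
  key <- apply(enc, 2, paste, collapse = ",")
  upat <- !duplicated(key)
  pat <- enc[, upat, drop = FALSE]
  w <- as.vector(table(factor(key, levels = key[upat])))
  map <- match(key, key[upat])
  np <- ncol(pat)
  nstate <- length(model$states)

  tipcond <- function(P, states) {
    ## conditional likelihood k x np for one tip; gap -> 1
    out <- matrix(1, nstate, np)
    ok <- !is.na(states)
    out[, ok] <- P[, states[ok]]
    out
  }
  pat_loglik <- function(b) {
    sl <- numeric(np)
    for (r in rates) {
      P1 <- transition_matrix(model, b[1] * r)
      P2 <- transition_matrix(model, b[2] * r)
      P3 <- transition_matrix(model, b[3] * r)
      P4 <- transition_matrix(model, b[4] * r)
      Pi <- transition_matrix(model, b[5] * r)
      Lu <- tipcond(P1, pat[1, ]) * tipcond(P2, pat[2, ])
      Lv <- tipcond(P3, pat[3, ]) * tipcond(P4, pat[4, ])
      sl <- sl + colSums(model$freqs * Lu * (Pi %*% Lv)) / length(rates)
    }
    log(sl)
  }
  total <- function(b) sum(w * pat_loglik(b))

  b <- branch_lengths
  if (optimize_branches) {
    for (s in seq_len(sweeps)) {
      for (i in seq_along(b)) {
        f <- function(x) { bb <- b; bb[i] <- x; -total(bb) }
        opt <- optimize(f, interval = c(1e-6, 5), tol = 1e-4)
        b[i] <- opt$minimum
      }
    }
  }
  per_pat <- pat_loglik(b)
  out <- per_pat[map]
  attr(out, "skipped") <- skipped
  attr(out, "branch_lengths") <- b
  attr(out, "logLik") <- sum(w * per_pat)
  out
}

## 1-D estimate of the gamma shape on a fixed topology, branches
## re-optimized lightly inside; used once on the best topology.
estimate_gamma_shape <- function(aln, topology, model = subst_model(),
                                 k = 4, interval = c(0.1, 20)) {
  f <- function(a) {
    sll <- site_log_likelihoods(aln, topology, model, alpha = a, k = k,
                                sweeps = 1)
    -attr(sll, "logLik")
  }
  optimize(f, interval = interval, tol = 0.05)$minimum
}

#' Site log-likelihood matrix for all three quartet topologies
#'
#' Convenience wrapper: fits the three unrooted topologies of a focal
#' quartet alignment (branch lengths re-optimized per topology), optionally
#' estimating the gamma shape once on the provisionally best topology and
#' reusing it for all three.
#'
#' @inheritParams site_log_likelihoods
#' @param estimate_alpha if `TRUE`, estimate the gamma shape on the best
#'   topology under `alpha = 1`, then refit all topologies with it.
#' @return matrix (sites x 3) of per-site log-likelihoods, with attributes
#'   `alpha`, `logLik` (per-topology totals) and `types` (unrooted type of
#'   each column).
#' @export
quartet_site_likelihoods <- function(aln, model = subst_model(),
                                     alpha = 1, k = 4,
                                     estimate_alpha = FALSE, sweeps = 2) {
  m <- as_aln_matrix(aln)
  tops <- quartet_topologies(rownames(m))
  fit_all <- function(a) {
    lapply(tops, function(tp)
      site_log_likelihoods(m, tp, model, alpha = a, k = k, sweeps = sweeps))
  }
  fits <- fit_all(alpha)
  if (estimate_alpha) {
    tot <- vapply(fits, attr, numeric(1), which = "logLik")
    best <- tops[[which.max(tot)]]
    alpha <- estimate_gamma_shape(m, best, model, k = k)
    fits <- fit_all(alpha)
  }
  sll <- do.call(cbind, lapply(fits, as.numeric))
  colnames(sll) <- names(tops)
  attr(sll, "alpha") <- alpha
  attr(sll, "logLik") <- vapply(fits, attr, numeric(1), which = "logLik")
  attr(sll, "types") <- vapply(tops, `[[`, "", "type")
  sll
}
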