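## Approximately Unbiased (AU) topology test via multiscale RELL bootstrap
## of per-site log-likelihoods (multiscale bootstrap with probit
## extrapolation of bootstrap proportions).

#' Approximately Unbiased test from a site log-likelihood matrix
#'
#' For each scale factor `r`, draws `B` RELL resamples of `ceil(r * L)`
#' sites with replacement and records the proportion of resamples in which
#' each topology attains the highest total log-likelihood (ties split
#' fractionally among co-best topologies, so topologies with identical
#' site-likelihood vectors receive identical p-values). The bootstrap
#' proportions are probit-transformed and `z(r) = d * sqrt(r) + c / sqrt(r)`
#' is fitted by weighted least squares over the scales with proportions
#' strictly inside (0, 1); the AU p-value is `1 - Phi(d - c)`. If fewer
#' than two informative scales remain, the p-value degenerates to 0 or 1
#' according to the proportions. If all topologies have identical
#' site-likelihood vectors, nothing is distinguishable and all p-values
#' are 1.
#'
#' @param sll numeric matrix, sites x topologies, of per-site
#'   log-likelihoods (natural log), e.g. from
#'   [quartet_site_likelihoods()].
#' @param scales numeric vector of bootstrap scale factors.
#' @param B replicates per scale.
#' @param seed optional integer seed for the resampling.
#' @return object of class `au_result`: data.frame with columns
#'   `topology`, `p_au`, `best` plus attributes `scales`, `B`, `seed`,
#'   `bp` (scales x topologies matrix of bootstrap proportions).
#' @references Shimodaira (2002) Syst. Biol. 51:492-508.
#' @export
au_test <- function(sll, scales = seq(0.5, 1.4, by = 0.1), B = 1000,
                    seed = NULL) {
  sll <- as.matrix(sll)
  L <- nrow(sll); ntop <- ncol(sll)
  if (ntop < 2) stop("need at least two topologies")
  if (L < 10) stop("need at least 10 sites")
  if (is.null(colnames(sll))) colnames(sll) <- paste0("T", seq_len(ntop))
  if (!is.null(seed)) set.seed(seed)
  tot0 <- colSums(sll)
  all_equal <- all(vapply(seq_len(ntop), function(j)
    isTRUE(all.equal(sll[, j], sll[, 1], check.attributes = FALSE)),
    logical(1)))
  if (all_equal) {
    res <- data.frame(topology = colnames(sll), p_au = rep(1, ntop),
                      best = seq_len(ntop) == which.max(tot0))
    return(structure(res, class = c("au_result", "data.frame"),
                     scales = scales, B = B, seed = seed, bp = NULL))
  }
  bp <- matrix(0, length(scales), ntop,
               dimnames = list(NULL, colnames(sll)))
  for (si in seq_along(scales)) {
    nr <- as.integer(ceiling(scales[si] * L))
    idx <- sample.int(L, nr * B, replace = TRUE)
    tot <- vapply(seq_len(ntop), function(j)
      colSums(matrix(sll[idx, j], nr, B)), numeric(B))
    mx <- apply(tot, 1, max)
    isb <- tot >= mx - 1e-10
    bp[si, ] <- colMeans(isb / rowSums(isb))
  }
  p <- vapply(seq_len(ntop), function(j)
    au_p_from_bp(bp[, j], scales, B), numeric(1))
  res <- data.frame(topology = colnames(sll), p_au = p,
                    best = seq_len(ntop) == which.max(tot0))
  structure(res, class = c("au_result", "data.frame"),
            scales = scales, B = B, seed = seed, bp = bp)
}

## probit-extrapolation fit for a single topology's bootstrap proportions
au_p_from_bp <- function(bp, scales, B) {
  ok <- bp > 0 & bp < 1
  if (sum(ok) < 2) return(if (mean(bp) > 0.5) 1 else 0)
  r <- scales[ok]
  z <- qnorm(1 - bp[ok])
  X <- cbind(sqrt(r), 1 / sqrt(r))
  wt <- B * dnorm(qnorm(bp[ok]))^2 / (bp[ok] * (1 - bp[ok]))
  beta <- tryCatch(solve(crossprod(X, wt * X), crossprod(X, wt * z)),
                   error = function(e) NULL)
  if (is.null(beta)) return(if (mean(bp) > 0.5) 1 else 0)
  d <- beta[1]; cc <- beta[2]
  unname(pnorm(d - cc, lower.tail = FALSE))
}

#' AU test of the three unrooted topologies of a focal quartet
#'
#' Computes per-site log-likelihoods for the three unrooted quartet
#' topologies of a four-sequence subalignment and runs the AU test,
#' additionally reporting a type-level p-value per unrooted category
#' (`PostSpecType`: its single topology; `PreSpecType`: the larger of its
#' two topologies' p-values, since rejecting the type means rejecting both).
#'
#' @inheritParams quartet_site_likelihoods
#' @inheritParams au_test
#' @return list with `au` (the `au_result`), `type_p` (named numeric:
#'   `PreSpecType`, `PostSpecType`), `best_type`, `alpha`.
#' @export
au_quartet <- function(aln, model = subst_model(), alpha = 1, k = 4,
                       estimate_alpha = FALSE,
                       scales = seq(0.5, 1.4, by = 0.1), B = 1000,
                       seed = NULL) {
  sll <- quartet_site_likelihoods(aln, model, alpha = alpha, k = k,
                                  estimate_alpha = estimate_alpha)
  res <- au_test(sll, scales = scales, B = B, seed = seed)
  types <- attr(sll, "types")
  type_p <- c(
    PreSpecType = max(res$p_au[types == "PreSpecType"]),
    PostSpecType = max(res$p_au[types == "PostSpecType"]))
  tot <- attr(sll, "logLik")
  list(au = res, type_p = type_p,
       best_type = unname(types[which.max(tot)]),
       alpha = attr(sll, "alpha"))
}

#' Per-category AU rejection frequencies
#'
#' Summarizes AU results grouped by rooted topology category: the fraction
#' of families in which the alternative unrooted type is decisively
#' rejected (`p < alpha`), and the fraction in which the matching type is
#' rejected.
#'
#' @param results data.frame with columns `rooted_category`,
#'   `p_prespec_type`, `p_postspec_type` (one row per family).
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `rooted_category`, `n`,
#'   `reject_alternative`, `reject_matching`.
#' @export
summarize_rejections <- function(results, alpha = 0.05) {
  stopifnot(all(c("rooted_category", "p_prespec_type", "p_postspec_type")
                %in% names(results)))
  cats <- unique(results$rooted_category)
  out <- lapply(cats, function(cat) {
    d <- results[results$rooted_category == cat, ]
    matching <- category_to_type(cat)
    p_match <- if (matching == "PreSpecType") d$p_prespec_type else
      d$p_postspec_type
    p_alt <- if (matching == "PreSpecType") d$p_postspec_type else
      d$p_prespec_type
    data.frame(rooted_category = cat, n = nrow(d),
               reject_alternative = mean(p_alt < alpha),
               reject_matching = mean(p_match < alpha))
  })
  do.call(rbind, out)
}
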