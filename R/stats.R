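## Alignment- and tree-level diagnostics used to compare topology
## categories for signs of limited signal or systematic error.

.gap_chars <- c("-", ".", "?", "X", "x", "*")

as_aln_matrix <- function(aln) {
  if (is.matrix(aln)) {
    m <- toupper(aln)
  } else if (is.list(aln) || is.character(aln)) {
    seqs <- if (is.list(aln)) vapply(aln, paste0, "", collapse = "") else aln
    if (length(unique(nchar(seqs))) > 1) stop("ragged alignment")
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
  } else stop("unsupported alignment representation")
  m
}

#' Alignment summary statistics
#'
#' Computes the diagnostics used to compare gene families across topology
#' categories: alignment length, average pairwise percentage identity
#' (averaged over all unordered sequence pairs, with positions gapped in
#' both members of a pair excluded and positions gapped in exactly one
#' member counted as mismatches), the number of variable sites (at least
#' two distinct non-gap residues) and of parsimony-informative sites (at
#' least two residues each present in at least two sequences).
#'
#' @param aln alignment: character matrix (rows = sequences) or a named
#'   character vector/list of equal-length strings.
#' @return list with `length`, `avg_pairwise_identity` (percent),
#'   `n_variable_sites`, `n_parsimony_informative`.
#' @export
alignment_stats <- function(aln) {
  m <- as_aln_matrix(aln)
  if (nrow(m) < 2) stop("need at least two sequences")
  L <- ncol(m)
  gap <- matrix(m %in% .gap_chars, nrow(m), L)
  ids <- combn(nrow(m), 2, function(ij) {
    a <- m[ij[1], ]; b <- m[ij[2], ]
    both_gap <- gap[ij[1], ] & gap[ij[2], ]
    cmp <- !both_gap
    if (!any(cmp)) return(NA_real_)
    match <- a == b & !gap[ij[1], ] & !gap[ij[2], ]
    100 * sum(match[cmp]) / sum(cmp)
  })
  n_var <- 0L; n_pis <- 0L
  for (j in seq_len(L)) {
    res <- m[!gap[, j], j]
    if (length(res) == 0) next
    tab <- table(res)
    if (length(tab) >= 2) n_var <- n_var + 1L
    if (sum(tab >= 2) >= 2) n_pis <- n_pis + 1L
  }
  list(length = L,
       avg_pairwise_identity = mean(ids, na.rm = TRUE),
       n_variable_sites = n_var,
       n_parsimony_informative = n_pis)
}

#' Tree- and composition-level diagnostics
#'
#' Computes, for a gene tree with branch lengths and its alignment: the
#' evolutionary rate (total tree length / number of leaves), treeness (sum
#' of internal branch lengths / total tree length), relative compositional
#' variability (RCV; mean absolute deviation of per-taxon residue counts
#' from the across-taxa mean, divided by taxa times alignment length),
#' treeness/RCV, and the saturation statistic (slope, through the origin,
#' of uncorrected pairwise distance regressed on patristic distance; values
#' well below 1 indicate saturation).
#'
#' @param tree `phylo` with branch lengths; tip labels must match the
#'   alignment rows.
#' @param aln alignment accepted by [alignment_stats()].
#' @return list with `evolutionary_rate`, `treeness`, `rcv`,
#'   `treeness_over_rcv`, `saturation`.
#' @export
tree_stats <- function(tree, aln) {
  m <- as_aln_matrix(aln)
  if (!all(tree$tip.label %in% rownames(m)))
    stop("alignment rows do not cover the tree leaves")
  m <- m[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  bl <- tree$edge.length
  if (is.null(bl)) stop("tree has no branch lengths")
  total <- sum(bl)
  if (total <= 0) stop("zero total tree length: treeness undefined")
  internal <- tree$edge[, 2] > ntip
  treeness <- sum(bl[internal]) / total
  ## RCV on non-gap residue counts
  gap <- matrix(m %in% .gap_chars, nrow(m), ncol(m))
  states <- sort(unique(m[!gap]))
  cnt <- t(apply(m, 1, function(row)
    table(factor(row[!(row %in% .gap_chars)], levels = states))))
  mean_cnt <- colMeans(cnt)
  rcv <- sum(abs(sweep(cnt, 2, mean_cnt))) / (ntip * ncol(m))
  ## saturation: uncorrected p-distance vs patristic distance, slope thru 0
  pat <- ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]
  pd <- matrix(0, ntip, ntip)
  for (i in seq_len(ntip - 1)) for (j in (i + 1):ntip) {
    ok <- !gap[i, ] & !gap[j, ]
    pd[i, j] <- pd[j, i] <-
      if (any(ok)) sum(m[i, ok] != m[j, ok]) / sum(ok) else NA_real_
  }
  x <- pat[upper.tri(pat)]; y <- pd[upper.tri(pd)]
  ok <- is.finite(x) & is.finite(y) & x > 0
  saturation <- if (any(ok)) sum(x[ok] * y[ok]) / sum(x[ok]^2) else NA_real_
  list(evolutionary_rate = total / ntip,
       treeness = treeness,
       rcv = rcv,
       treeness_over_rcv = if (rcv > 0) treeness / rcv else NA_real_,
       saturation = saturation)
}

#' Pairwise group comparisons with Bonferroni correction
#'
#' Compares a numeric statistic between every pair of topology categories
#' by the two-sided Wilcoxon rank-sum test, adjusting p-values by
#' Bonferroni across the comparisons.
#'
#' @param values numeric vector of the statistic per family.
#' @param groups factor/character of topology category per family.
#' @return data.frame with columns `group1`, `group2`, `p_value`,
#'   `p_adjusted`.
#' @export
group_stat_comparisons <- function(values, groups) {
  groups <- as.character(groups)
  gs <- sort(unique(groups))
  if (length(gs) < 2) stop("need at least two groups")
  pairs <- combn(gs, 2)
  p <- apply(pairs, 2, function(gp) {
    suppressWarnings(wilcox.test(values[groups == gp[1]],
                                 values[groups == gp[2]],
                                 alternative = "two.sided"))$p.value
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             p_value = p, p_adjusted = p.adjust(p, method = "bonferroni"))
}
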