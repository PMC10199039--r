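## End-to-end classification of gene family trees into rooted quartet
## categories, with support bookkeeping and the UFBoot cut-off sweep.

#' Classify a set of gene family trees
#'
#' For each family tree: roots on the most distant outgroup sequence,
#' verifies the focal quartet forms a clan, extracts the rooted quartet
#' subtree with its two internal supports, and assigns the rooted category
#' and its unrooted type. Families that cannot be classified (no outgroup,
#' quartet not a clan, wrong copy number) receive `NA` with a reason in
#' `note`; polytomic quartets are `"unresolved"`.
#'
#' @param trees named list of `phylo` gene trees (names = family ids).
#' @param sp_tree rooted species tree covering all leaf species.
#' @param ingroup the two focal species tags.
#' @return data.frame with columns `family_id`, `rooted_category`,
#'   `unrooted_type`, `support_1`, `support_2`, `support_min`,
#'   `support_missing`, `note`.
#' @export
classify_families <- function(trees, sp_tree = default_species_tree(),
                              ingroup = .default_ingroup) {
  ranking <- species_ranking(sp_tree, ingroup)
  rows <- lapply(names(trees), function(fid) {
    tr <- trees[[fid]]
    base <- data.frame(family_id = fid, rooted_category = NA_character_,
                       unrooted_type = NA_character_,
                       support_1 = NA_real_, support_2 = NA_real_,
                       support_min = NA_real_, support_missing = FALSE,
                       note = "")
    sp <- leaf_species(tr$tip.label)
    if (sum(sp == ingroup[1]) != 2 || sum(sp == ingroup[2]) != 2) {
      base$note <- "wrong_copy_number"; return(base)
    }
    focal <- tr$tip.label[sp %in% ingroup]
    if (length(focal) < length(tr$tip.label)) {
      if (!is_clan(tr, focal)) { base$note <- "not_clan"; return(base) }
      rooted <- tryCatch(root_by_most_distant_outgroup(tr, ranking),
                         error = function(e) NULL)
      if (is.null(rooted)) { base$note <- "no_outgroup"; return(base) }
    } else {
      if (!ape::is.rooted(tr)) { base$note <- "no_outgroup"; return(base) }
      rooted <- tr
    }
    qs <- quartet_subtree(rooted, ingroup)
    cat <- classify_rooted_quartet(qs$subtree)
    supports <- qs$supports
    missing <- anyNA(supports)
    supports[is.na(supports)] <- 0
    base$rooted_category <- cat
    base$unrooted_type <- if (cat == "unresolved") NA_character_ else
      category_to_type(cat)
    base$support_1 <- supports[1]
    base$support_2 <- if (length(supports) > 1) supports[2] else NA_real_
    base$support_min <- min(supports)
    base$support_missing <- missing
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Category counts at a support cut-off
#'
#' Counts the three top-level rooted categories among classified families
#' whose quartet passes the support filter at the cut-off. Unresolved
#' quartets are counted separately and excluded from the total used for
#' percentages and fold deviations.
#'
#' @param classification data.frame from [classify_families()].
#' @param cutoff UFBoot percentage cut-off (both supports must reach it).
#' @return list with `counts` (named: PostSpec, PreSpec, Other), `total`,
#'   `unresolved`, `cutoff`.
#' @export
category_counts <- function(classification, cutoff = 0) {
  d <- classification[!is.na(classification$rooted_category), ]
  keep <- d$support_min >= cutoff
  d <- d[keep, ]
  cat3 <- ifelse(d$rooted_category %in% c("PreSpecLike", "PostSpecLike"),
                 "Other", d$rooted_category)
  counts <- c(PostSpec = sum(cat3 == "PostSpec"),
              PreSpec = sum(cat3 == "PreSpec"),
              Other = sum(cat3 == "Other"))
  list(counts = counts, total = sum(counts),
       unresolved = sum(cat3 == "unresolved"), cutoff = cutoff)
}

#' Sweep of support cut-offs with percentages and fold deviations
#'
#' Reproduces the stringency analysis: counts, percentages and fold
#' deviations from the uniform-topology expectation for each category,
#' at each cut-off (default 0 to 100 by 5).
#'
#' @param classification data.frame from [classify_families()].
#' @param cutoffs numeric vector of cut-offs.
#' @return data.frame, one row per cut-off: `cutoff`, `n_postspec`,
#'   `n_prespec`, `n_other`, `n_unresolved`, `total`, `pct_*`, `fold_*`.
#' @export
cutoff_sweep <- function(classification, cutoffs = seq(0, 100, by = 5)) {
  rows <- lapply(cutoffs, function(co) {
    cc <- category_counts(classification, co)
    n <- cc$counts; tot <- cc$total
    fd <- if (tot > 0) fold_deviation(n) else
      c(PostSpec = NA_real_, PreSpec = NA_real_, Other = NA_real_)
    data.frame(cutoff = co,
               n_postspec = n[["PostSpec"]], n_prespec = n[["PreSpec"]],
               n_other = n[["Other"]], n_unresolved = cc$unresolved,
               total = tot,
               pct_postspec = if (tot > 0) 100 * n[["PostSpec"]] / tot else NA,
               pct_prespec = if (tot > 0) 100 * n[["PreSpec"]] / tot else NA,
               pct_other = if (tot > 0) 100 * n[["Other"]] / tot else NA,
               fold_postspec = fd[["PostSpec"]],
               fold_prespec = fd[["PreSpec"]],
               fold_other = fd[["Other"]])
  })
  do.call(rbind, rows)
}

#' Extract the ortholog pairing of a classified family
#'
#' Returns the gene identifiers of a family's quartet in the `s1/s2/p1/p2`
#' convention where (`s1`,`p1`) and (`s2`,`p2`) are the two ortholog pairs
#' implied by the quartet subtree: for a PreSpec tree these are its two
#' mixed-species cherries; otherwise pairing is by index order.
#'
#' @param tree rooted gene tree (`phylo`).
#' @param ingroup the two focal species tags.
#' @return named character vector `s1`, `s2`, `p1`, `p2` (gene ids).
#' @export
quartet_gene_roles <- function(tree, ingroup = .default_ingroup) {
  sp <- leaf_species(tree$tip.label)
  s_tips <- sort(tree$tip.label[sp == ingroup[1]])
  p_tips <- sort(tree$tip.label[sp == ingroup[2]])
  if (length(s_tips) != 2 || length(p_tips) != 2)
    stop("tree does not contain a 2+2 focal quartet")
  qs <- quartet_subtree(tree, ingroup)$subtree
  ch <- cherry_tip_sets(qs)
  mixed <- Filter(function(tp) length(unique(leaf_species(tp))) == 2, ch)
  if (length(mixed) == 2) {
    m1 <- mixed[[1]]; m2 <- mixed[[2]]
    s1 <- m1[leaf_species(m1) == ingroup[1]]
    p1 <- m1[leaf_species(m1) == ingroup[2]]
    s2 <- m2[leaf_species(m2) == ingroup[1]]
    p2 <- m2[leaf_species(m2) == ingroup[2]]
  } else {
    s1 <- s_tips[1]; s2 <- s_tips[2]; p1 <- p_tips[1]; p2 <- p_tips[2]
  }
  c(s1 = leaf_gene(s1), s2 = leaf_gene(s2),
    p1 = leaf_gene(p1), p2 = leaf_gene(p2))
}
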