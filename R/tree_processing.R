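#' Root a gene family tree on its most distant outgroup sequence
#'
#' Places the root on the terminal branch of the single leaf whose species
#' is the most distantly related to the focal pair according to a species
#' ranking (see [species_ranking()]). Ties among equally ranked species are
#' broken by the lexicographically smallest gene identifier (then by full
#' label). If the tree is already rooted on that leaf it is returned
#' unchanged.
#'
#' @param tree `phylo`; leaves labelled `"Species|gene"`.
#' @param ranking named numeric vector from [species_ranking()] (smaller =
#'   more distant; focal species `Inf`).
#' @return rooted `phylo`.
#' @export
root_by_most_distant_outgroup <- function(tree, ranking) {
  sp <- leaf_species(tree$tip.label)
  known <- sp %in% names(ranking)
  if (!all(known)) stop("species missing from ranking: ",
                        paste(unique(sp[!known]), collapse = ", "))
  r <- ranking[sp]
  if (all(!is.finite(r) | r == Inf)) stop("no outgroup leaf present")
  cand <- which(r == min(r))
  ord <- order(leaf_gene(tree$tip.label[cand]), tree$tip.label[cand])
  og <- tree$tip.label[cand[ord[1]]]
  ## already rooted on that leaf?
  if (ape::is.rooted(tree)) {
    root <- length(tree$tip.label) + 1L
    ch <- tree$edge[tree$edge[, 1] == root, 2]
    if (any(ch <= length(tree$tip.label) & tree$tip.label[ch] == og))
      return(tree)
  }
  ape::root(tree, outgroup = og, resolve.root = TRUE)
}

#' Test whether a leaf set forms a clan
#'
#' A clan is the unrooted analogue of a monophyletic group: a set of leaves
#' separable from all remaining leaves by cutting a single edge of the
#' unrooted tree.
#'
#' @param tree `phylo` (rooted or unrooted).
#' @param leaf_set character vector of tip labels (or logical/integer index).
#' @return `TRUE` or `FALSE`.
#' @export
is_clan <- function(tree, leaf_set) {
  tips <- tree$tip.label
  if (is.character(leaf_set)) {
    if (!all(leaf_set %in% tips)) stop("leaf_set contains unknown tips")
    idx <- match(leaf_set, tips)
  } else idx <- which(leaf_set) %||% leaf_set
  n <- length(tips)
  if (length(idx) == 0 || length(idx) >= n)
    stop("leaf_set must be a non-empty proper subset of the leaves")
  ## every pendant edge isolates its tip (and, unrooted, its complement)
  if (length(idx) %in% c(1L, n - 1L)) return(TRUE)
  target <- sort(unique(idx))
  cl <- node_clades(tree)
  for (nd in (n + 1L):(n + tree$Nnode)) {
    s <- sort(cl[[nd]])
    if (identical(s, target)) return(TRUE)
    if (length(s) == n - length(target) &&
        identical(sort(setdiff(seq_len(n), s)), target)) return(TRUE)
  }
  FALSE
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Strict gene-tree / species-tree reconciliation
#'
#' Maps every internal node of a rooted gene tree to the most recent common
#' ancestor, in the species tree, of the species under it, and labels the
#' node a `duplication` if the species sets of its two children intersect
#' (strict LCA rule), otherwise a `speciation`.
#'
#' @param tree rooted `phylo` gene tree with `"Species|gene"` leaves.
#' @param sp_tree rooted species tree containing every leaf species.
#' @return a list of class `reconciled_tree` with elements `tree`,
#'   `event` (character vector indexed by internal node number) and
#'   `sp_node` (species-tree node each internal node maps to).
#' @export
reconcile <- function(tree, sp_tree) {
  sp <- leaf_species(tree$tip.label)
  if (!all(sp %in% sp_tree$tip.label))
    stop("species missing from species tree: ",
         paste(setdiff(unique(sp), sp_tree$tip.label), collapse = ", "))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  sp_cl <- node_clades(sp_tree)
  sp_sets <- lapply(sp_cl, function(i) sort(sp_tree$tip.label[i]))
  ## species LCA = smallest species-tree clade containing the set
  sp_lca <- function(species) {
    sizes <- lengths(sp_sets)
    ok <- vapply(sp_sets, function(s) all(species %in% s), logical(1))
    which(ok)[which.min(sizes[ok])]
  }
  cl <- node_clades(tree)
  event <- rep(NA_character_, nnode)
  sp_node <- rep(NA_integer_, nnode)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  for (nd in (ntip + 1L):nnode) {
    this_sp <- unique(sp[cl[[nd]]])
    sp_node[nd] <- sp_lca(this_sp)
    ch <- kids[[as.character(nd)]]
    sets <- lapply(ch, function(c) unique(sp[cl[[c]]]))
    dup <- FALSE
    if (length(sets) >= 2) {
      for (i in seq_along(sets)[-1]) for (j in seq_len(i - 1))
        if (length(intersect(sets[[i]], sets[[j]])) > 0) dup <- TRUE
    }
    event[nd] <- if (dup) "duplication" else "speciation"
  }
  structure(list(tree = tree, event = event, sp_node = sp_node),
            class = "reconciled_tree")
}

#' Extract the maximal orthogroup around a focal ohnolog quartet
#'
#' Starting from each clade containing exactly two sequences of each focal
#' species, walks rootward as long as the ancestor's subtree still contains
#' no additional focal-species sequence, and returns the leaf set of the
#' highest such ancestor. This maximizes included outgroup species while
#' excluding extra focal-species paralogs; a family whose tree carries two
#' such quartet clades (e.g. a deeper duplication retaining 2+2 in both
#' copies) yields two disjoint sets.
#'
#' @param tree rooted `phylo` with `"Species|gene"` leaves.
#' @param ingroup the two focal species tags.
#' @return a list of character vectors of tip labels (usually length 1).
#' @export
extract_phog_quartet <- function(tree, ingroup = .default_ingroup) {
  sp <- leaf_species(tree$tip.label)
  ntip <- length(tree$tip.label)
  if (sum(sp == ingroup[1]) < 2 || sum(sp == ingroup[2]) < 2)
    stop("tree must contain at least two leaves of each focal species")
  cl <- node_clades(tree)
  counts <- function(nd) table(factor(sp[cl[[nd]]], levels = ingroup))
  is_quartet <- vapply((ntip + 1L):(ntip + tree$Nnode), function(nd)
    all(counts(nd) == 2L), logical(1))
  qnodes <- ((ntip + 1L):(ntip + tree$Nnode))[is_quartet]
  if (length(qnodes) == 0)
    stop("no clade with exactly two sequences of each focal species")
  ## keep only minimal quartet nodes (the quartet MRCAs)
  minimal <- qnodes[vapply(qnodes, function(nd) {
    others <- setdiff(qnodes, nd)
    !any(vapply(others, function(o) all(cl[[o]] %in% cl[[nd]]) &&
                  length(cl[[o]]) < length(cl[[nd]]), logical(1)))
  }, logical(1))]
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  out <- lapply(minimal, function(nd) {
    best <- nd
    while (best != root) {
      up <- parent[best]
      if (up == 0) break
      if (all(counts(up) == 2L)) best <- up else break
    }
    sort(tree$tip.label[cl[[best]]])
  })
  unique(out)
}

#' Apply the ohnolog-family inclusion filters
#'
#' Checks a gene family against the inclusion rules for the ohnolog-pair
#' dataset: exactly two sequences of each focal species
#' (`wrong_copy_number`); the two copies of a focal species on different
#' chromosomes (`same_chromosome`); every focal gene on a placed chromosome
#' (`unplaced_scaffold`); at least one outgroup sequence to allow rooting
#' (`no_outgroup`); and the four focal sequences forming a clan
#' (`not_clan`). Reasons are assessed independently; the family passes iff
#' none is triggered.
#'
#' @param family_id identifier string.
#' @param tree gene family tree (`phylo`, rooted or not).
#' @param coords data.frame with columns `gene_id`, `species`, `chrom`,
#'   `start`, `end` (0-based half-open) covering all focal genes.
#' @param placed named list of character vectors: placed chromosome names
#'   per focal species.
#' @param ingroup the two focal species tags.
#' @return a list with `family_id`, `pass` (flag) and `reasons`
#'   (character vector, empty when passing).
#' @export
apply_family_filters <- function(family_id, tree, coords, placed,
                                 ingroup = .default_ingroup) {
  sp <- leaf_species(tree$tip.label)
  reasons <- character(0)
  n_in <- vapply(ingroup, function(s) sum(sp == s), integer(1))
  if (any(n_in != 2L)) reasons <- c(reasons, "wrong_copy_number")
  focal <- tree$tip.label[sp %in% ingroup]
  genes <- leaf_gene(focal)
  rec <- coords[match(genes, coords$gene_id), , drop = FALSE]
  if (anyNA(rec$chrom))
    stop("missing coordinate record for: ",
         paste(genes[is.na(rec$chrom)], collapse = ", "))
  for (s in ingroup) {
    ch <- rec$chrom[leaf_species(focal) == s]
    if (length(ch) == 2 && ch[1] == ch[2])
      reasons <- c(reasons, "same_chromosome")
    pl <- placed[[s]]
    if (!is.null(pl) && any(!(ch %in% pl)))
      reasons <- c(reasons, "unplaced_scaffold")
  }
  reasons <- unique(reasons)
  if (!any(!(sp %in% ingroup))) reasons <- c(reasons, "no_outgroup")
  if (all(n_in == 2L) && length(focal) < length(tree$tip.label) &&
      !is_clan(tree, focal))
    reasons <- c(reasons, "not_clan")
  list(family_id = family_id, pass = length(reasons) == 0, reasons = reasons)
}

#' Extract the rooted focal quartet subtree and its internal supports
#'
#' Restricts a rooted gene tree to the four focal leaves (preserving the
#' induced rooted topology and node support labels) and reads the supports
#' of the two internal edges interior to the quartet subtree, i.e. the two
#' non-root internal nodes.
#'
#' @param tree rooted `phylo` with node labels holding integer supports.
#' @param ingroup the two focal species tags.
#' @return list with `subtree` (`phylo`, 4 tips) and `supports` (numeric,
#'   length 2; `NA` where a label was absent or non-numeric).
#' @export
quartet_subtree <- function(tree, ingroup = .default_ingroup) {
  sp <- leaf_species(tree$tip.label)
  focal <- tree$tip.label[sp %in% ingroup]
  if (length(focal) != 4) stop("tree does not contain a 2+2 focal quartet")
  sub <- ape::keep.tip(tree, focal)
  supports <- rep(NA_real_, 2)
  if (!is.null(sub$node.label) && sub$Nnode == 3) {
    ## node labels are in node-number order; node 1 is the subtree root
    supports <- suppressWarnings(as.numeric(sub$node.label[-1]))
  } else if (!is.null(sub$node.label) && sub$Nnode > 1) {
    supports <- suppressWarnings(as.numeric(sub$node.label[-1]))
  }
  list(subtree = sub, supports = supports)
}

#' Minimum-support filter for a quartet subtree
#'
#' A subtree is retained at a cut-off iff both internal supports are
#' greater than or equal to the cut-off.
#'
#' @param supports numeric vector of the two internal supports (0-100).
#' @param cutoff numeric cut-off percentage.
#' @param na_action `"zero"` treats missing supports as 0 (conservative,
#'   with a warning); `"error"` raises an error.
#' @return `TRUE` or `FALSE`.
#' @export
support_filter <- function(supports, cutoff, na_action = c("zero", "error")) {
  na_action <- match.arg(na_action)
  if (anyNA(supports)) {
    if (na_action == "error") stop("missing support value")
    supports[is.na(supports)] <- 0
  }
  min(supports) >= cutoff
}

#' Fold deviation of category counts from the uniform-topology null
#'
#' Compares observed frequencies of the three top-level rooted categories
#' with the expectation if each of the 15 rooted quartet topologies were
#' recovered equally often: PostSpec 1/15, PreSpec 2/15, Other 12/15.
#'
#' @param counts named numeric vector with entries `PostSpec`, `PreSpec`,
#'   `Other` (unresolved trees excluded beforehand).
#' @return named numeric vector of per-category ratios
#'   (observed frequency / expected frequency).
#' @export
fold_deviation <- function(counts) {
  e <- c(PostSpec = 1 / 15, PreSpec = 2 / 15, Other = 12 / 15)
  counts <- counts[names(e)]
  total <- sum(counts)
  if (is.na(total) || total <= 0) stop("total count must be positive")
  (counts / total) / e
}

#' Check recovery of a reference clade in a gene tree
#'
#' Returns `TRUE` if at least one sequence is present for every species of
#' the clade and those sequences together form a clan, `FALSE` if they do
#' not, and `NA` (not evaluable) if any clade species is absent from the
#' tree (which may reflect gene loss rather than error).
#'
#' @param tree `phylo` with `"Species|gene"` leaves.
#' @param clade_species character vector of species tags defining the clade.
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
clade_recovery <- function(tree, clade_species) {
  sp <- leaf_species(tree$tip.label)
  if (!all(clade_species %in% sp)) return(NA)
  members <- tree$tip.label[sp %in% clade_species]
  if (length(members) == length(tree$tip.label)) return(TRUE)
  is_clan(tree, members)
}

#' Paired comparison of focal-species branch lengths
#'
#' Tests for a rate difference between the two focal lineages by a
#' two-sided paired Wilcoxon signed-rank test on per-family terminal branch
#' lengths, after removing extreme outlier pairs in which either branch
#' length reaches `max_len`.
#'
#' @param sturgeon,paddlefish numeric vectors of paired branch lengths
#'   (substitutions/site).
#' @param max_len exclusion threshold; pairs with either value `>= max_len`
#'   are dropped (default 0.15).
#' @return list with `statistic`, `p_value`, `medians` (named, per input)
#'   and `n_used`.
#' @export
compare_paired_branch_lengths <- function(sturgeon, paddlefish,
                                          max_len = 0.15) {
  stopifnot(length(sturgeon) == length(paddlefish))
  keep <- sturgeon < max_len & paddlefish < max_len
  s <- sturgeon[keep]; p <- paddlefish[keep]
  if (length(s) == 0) stop("all pairs removed by the branch-length filter")
  if (all(s == p)) {
    return(list(statistic = NA_real_, p_value = 1,
                medians = c(sturgeon = median(s), paddlefish = median(p)),
                n_used = length(s)))
  }
  w <- suppressWarnings(wilcox.test(s, p, paired = TRUE,
                                    alternative = "two.sided"))
  list(statistic = unname(w$statistic), p_value = w$p.value,
       medians = c(sturgeon = median(s), paddlefish = median(p)),
       n_used = length(s))
}
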