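#' Enumerate all rooted, binary, leaf-labelled topologies
#'
#' Generates every distinct rooted bifurcating tree over the given tip
#' labels by recursive leaf insertion: the k-th leaf can be attached to any
#' of the `2k - 3` edges of a (k-1)-leaf tree or above its root, which
#' yields each topology exactly once. The number of topologies is the
#' double factorial `(2n - 3)!!` (1, 3, 15, 105 for n = 2..5).
#'
#' @param labels character vector of 2 to 6 distinct tip labels.
#' @return a list of `phylo` objects (class `multiPhylo`).
#' @examples
#' length(enumerate_rooted_topologies(c("a", "b", "c", "d")))  # 15
#' @export
enumerate_rooted_topologies <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2) stop("need at least 2 labels")
  if (length(labels) > 6) stop("more than 6 labels not supported")
  if (anyDuplicated(labels)) stop("labels must be distinct")
  trees <- list(list(labels[1], labels[2]))
  for (x in labels[-(1:2)]) {
    trees <- unlist(lapply(trees, insert_leaf_everywhere, x = x),
                    recursive = FALSE)
  }
  out <- lapply(trees, function(t)
    ape::read.tree(text = paste0(nested_to_newick(t), ";")))
  class(out) <- "multiPhylo"
  out
}

## all ways of inserting leaf x into tree t: above the root, or into the
## edge above any node of either subtree (recursively)
insert_leaf_everywhere <- function(t, x) {
  res <- list(list(t, x))                 # new root above old root
  if (is.list(t)) {
    for (i in 1:2) {
      for (s in insert_leaf_everywhere(t[[i]], x)) {
        tt <- t
        tt[[i]] <- s
        res <- c(res, list(tt))
      }
    }
  }
  res
}

nested_to_newick <- function(t) {
  if (!is.list(t)) return(t)
  paste0("(", nested_to_newick(t[[1]]), ",", nested_to_newick(t[[2]]), ")")
}

#' Classify a rooted four-tip ohnolog subtree
#'
#' Assigns one of the four rooted-topology categories used to place the
#' ohnolog duplication node relative to speciation. With two tips per
#' species, the 15 rooted quartets fall into: `PostSpec` (1 topology; the
#' balanced tree with two same-species cherries, i.e. independent
#' duplication nodes), `PreSpec` (2 topologies; balanced with two
#' mixed-species cherries, i.e. a shared duplication node), and 12 'Other'
#' caterpillar topologies subdivided by their single cherry:
#' `PostSpecLike` (same-species cherry, 4 topologies) and `PreSpecLike`
#' (mixed cherry, 8 topologies). Polytomies return `"unresolved"`.
#'
#' @param tree rooted `phylo` with exactly four tips.
#' @param species named character vector mapping tip labels to species tags;
#'   by default parsed from the labels with [leaf_species()]. Exactly two
#'   tips per species are required.
#' @return a single character string: `"PreSpec"`, `"PostSpec"`,
#'   `"PreSpecLike"`, `"PostSpecLike"`, or `"unresolved"`.
#' @examples
#' tr <- ape::read.tree(text = "((S|a,P|a),(S|b,P|b));")
#' classify_rooted_quartet(tr)  # "PreSpec"
#' @export
classify_rooted_quartet <- function(tree, species = NULL) {
  if (length(tree$tip.label) != 4)
    stop("quartet classification needs exactly 4 tips")
  if (is.null(species)) species <- quartet_species(tree$tip.label)
  check_two_per_species(species, tree$tip.label)
  if (tree$Nnode < 3) return("unresolved")
  if (tree$Nnode > 3) stop("tree is not a valid rooted binary quartet")
  cherries <- cherry_tip_sets(tree)
  same <- vapply(cherries, function(tips)
    length(unique(species[tips])) == 1L, logical(1))
  if (length(cherries) == 2L) {            # balanced shape
    if (all(same)) "PostSpec" else "PreSpec"
  } else {                                 # caterpillar shape
    if (same[1]) "PostSpecLike" else "PreSpecLike"
  }
}

#' Classify an unrooted four-tip ohnolog subtree
#'
#' The unrooted quartet is determined solely by its central split: the split
#' separating the two same-species pairs is `PostSpecType`; either of the
#' two mixed-species splits is `PreSpecType`. A star (unresolved) quartet
#' raises an error.
#'
#' @inheritParams classify_rooted_quartet
#' @param tree unrooted `phylo` with four tips.
#' @return `"PostSpecType"` or `"PreSpecType"`.
#' @examples
#' tr <- ape::unroot(ape::read.tree(text = "((S|a,S|b),(P|a,P|b));"))
#' classify_unrooted_quartet(tr)  # "PostSpecType"
#' @export
classify_unrooted_quartet <- function(tree, species = NULL) {
  if (length(tree$tip.label) != 4)
    stop("quartet classification needs exactly 4 tips")
  if (is.null(species)) species <- quartet_species(tree$tip.label)
  check_two_per_species(species, tree$tip.label)
  tree <- ape::unroot(tree)
  if (tree$Nnode < 2) stop("unresolved (star) quartet")
  ## the non-basal internal node subtends one side of the central split
  ntip <- 4L
  inner <- setdiff(unique(tree$edge[, 1]), ntip + 1L)
  side <- tree$tip.label[unlist(node_clades(tree)[inner])]
  if (length(side) != 2) stop("malformed quartet")
  if (length(unique(species[side])) == 1L) "PostSpecType" else "PreSpecType"
}

#' Classify a rooted three-tip subtree (single-copy second species)
#'
#' For families where one focal species retains both ohnologs and the other
#' only a single gene, the three-tip rooted subtree takes one of three
#' topologies: the one whose cherry unites the two same-species copies is
#' `PostSpecType`; the two others are `PreSpecType`.
#'
#' @param tree rooted binary `phylo` with three tips, two from one species
#'   and one from another.
#' @inheritParams classify_rooted_quartet
#' @return `"PostSpecType"` or `"PreSpecType"`.
#' @examples
#' tr <- ape::read.tree(text = "((S|a,S|b),P|c);")
#' classify_rooted_triplet(tr)  # "PostSpecType"
#' @export
classify_rooted_triplet <- function(tree, species = NULL) {
  if (length(tree$tip.label) != 3 || tree$Nnode != 2)
    stop("need a rooted binary 3-tip tree")
  if (is.null(species)) {
    species <- leaf_species(tree$tip.label)
    names(species) <- tree$tip.label
  }
  tab <- table(species[tree$tip.label])
  if (length(tab) != 2 || !all(sort(as.integer(tab)) == c(1L, 2L)))
    stop("triplet must have two tips of one species and one of another")
  cherry <- cherry_tip_sets(tree)[[1]]
  if (length(unique(species[cherry])) == 1L) "PostSpecType" else "PreSpecType"
}

#' Map a rooted category to its unrooted type
#'
#' `PreSpec`/`PreSpecLike` unroot to `PreSpecType`; `PostSpec`/`PostSpecLike`
#' to `PostSpecType`.
#'
#' @param category character vector of rooted categories.
#' @return character vector of unrooted types (`NA` for `"unresolved"`).
#' @export
category_to_type <- function(category) {
  map <- c(PreSpec = "PreSpecType", PreSpecLike = "PreSpecType",
           PostSpec = "PostSpecType", PostSpecLike = "PostSpecType")
  unname(map[category])
}

## tip label sets of all cherries (internal nodes whose children are both tips)
cherry_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  out <- list()
  for (nd in unique(tree$edge[, 1])) {
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    if (length(ch) == 2 && all(ch <= ntip))
      out <- c(out, list(tree$tip.label[ch]))
  }
  out
}

quartet_species <- function(labels) {
  sp <- leaf_species(labels)
  names(sp) <- labels
  sp
}

check_two_per_species <- function(species, labels) {
  tab <- table(species[labels])
  if (length(tab) != 2 || any(tab != 2))
    stop("quartet must contain exactly two tips from each of two species")
  invisible(TRUE)
}
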