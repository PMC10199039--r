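#' Reference species tree for the jawed-vertebrate study set
#'
#' Returns the fixed rooted species topology over the 13 study species
#' (two chondrichthyans, four sarcopterygians, bichir, the two focal
#' acipenseriforms, and four neopterygians). The focal sister pair
#' (sturgeon, paddlefish) is nested inside Actinopterygii.
#'
#' @return an object of class `phylo` (no branch lengths).
#' @examples
#' sp <- default_species_tree()
#' sp$tip.label
#' @export
default_species_tree <- function() {
  ape::read.tree(text = paste0(
    "((GhostShark,WhaleShark),((Coelacanth,(Frog,(Human,Chicken))),",
    "(Bichir,((Paddlefish,Sturgeon),((Zebrafish,Fugu),(SpottedGar,Bowfin))))));"
  ))
}

#' Rank species by phylogenetic distance from the focal pair
#'
#' Derives, from a rooted species tree, an ordering of species by how
#' distantly they are related to the focal ingroup: the rank of a species is
#' the depth (edges from the root) of its most recent common ancestor with
#' the ingroup clade. Smaller rank means more distantly related; the ingroup
#' species themselves receive rank `Inf`.
#'
#' @param sp_tree rooted species tree (`phylo`).
#' @param ingroup character vector of the two focal species tags.
#' @return named numeric vector, one entry per species tip, smaller =
#'   more distant from the ingroup.
#' @examples
#' species_ranking(default_species_tree())
#' @export
species_ranking <- function(sp_tree, ingroup = .default_ingroup) {
  if (!all(ingroup %in% sp_tree$tip.label))
    stop("ingroup species missing from species tree")
  ntip <- length(sp_tree$tip.label)
  root <- ntip + 1L
  depth <- node_depths(sp_tree)
  in_mrca <- ape::getMRCA(sp_tree, ingroup)
  rank <- numeric(ntip)
  names(rank) <- sp_tree$tip.label
  for (i in seq_len(ntip)) {
    sp <- sp_tree$tip.label[i]
    if (sp %in% ingroup) {
      rank[i] <- Inf
    } else {
      m <- ape::getMRCA(sp_tree, c(sp, ingroup))
      rank[i] <- depth[m]
    }
  }
  rank
}

## depth (edge count from root) of every node in a rooted phylo
node_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  depth <- rep(NA_real_, nnode)
  root <- ntip + 1L
  depth[root] <- 0
  ## edges in preorder: reorder guarantees parents before children
  eo <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(eo$edge))) {
    depth[eo$edge[k, 2]] <- depth[eo$edge[k, 1]] + 1
  }
  depth
}

## tip numbers descending from each node (list indexed by node id)
node_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  cl <- vector("list", nnode)
  for (i in seq_len(ntip)) cl[[i]] <- i
  eo <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    cl[[p]] <- c(cl[[p]], cl[[ch]])
  }
  cl
}
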