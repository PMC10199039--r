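## Chromosomal layout of classified ohnolog pairs: circos-style link
## tables, contiguous same-category block detection, and a permutation
## test for non-random clustering of categories along chromosomes.

#' Build a synteny link table from classified quartets
#'
#' In `intra` mode every classified family contributes one link per focal
#' species connecting its two ohnologs; in `inter` mode every PreSpec
#' family contributes two between-species ortholog links (one per ohnolog
#' copy); `combined` mixes the two: PostSpec families as intra-species
#' links, PreSpec families as inter-species links. Link anchors are gene
#' midpoints.
#'
#' @param quartets data.frame with columns `family_id`, `rooted_category`,
#'   `s1`, `s2`, `p1`, `p2` (ortholog pairing (`s1`,`p1`)/(`s2`,`p2`)).
#' @param coords data.frame with `gene_id`, `species`, `chrom`, `start`,
#'   `end`.
#' @param mode `"intra"`, `"inter"` or `"combined"`.
#' @param species_names species tags of the `s` and `p` genes.
#' @return data.frame with columns `family_id`, `category`, `scope`,
#'   `species_a`, `chrom_a`, `pos_a`, `gene_a`, `species_b`, `chrom_b`,
#'   `pos_b`, `gene_b`.
#' @export
build_links <- function(quartets, coords,
                        mode = c("intra", "inter", "combined"),
                        species_names = .default_ingroup) {
  mode <- match.arg(mode)
  mid <- function(g) {
    i <- match(g, coords$gene_id)
    if (anyNA(i)) stop("missing coordinates for: ",
                       paste(g[is.na(i)], collapse = ", "))
    list(species = coords$species[i], chrom = coords$chrom[i],
         pos = (coords$start[i] + coords$end[i]) / 2)
  }
  rows <- list()
  link <- function(fid, cat, scope, ga, gb) {
    a <- mid(ga); b <- mid(gb)
    rows[[length(rows) + 1L]] <<- data.frame(
      family_id = fid, category = cat, scope = scope,
      species_a = a$species, chrom_a = a$chrom, pos_a = a$pos, gene_a = ga,
      species_b = b$species, chrom_b = b$chrom, pos_b = b$pos, gene_b = gb)
  }
  for (i in seq_len(nrow(quartets))) {
    q <- quartets[i, ]
    cat <- q$rooted_category
    if (is.na(cat) || cat == "unresolved") next
    intra_ok <- mode == "intra" ||
      (mode == "combined" && cat != "PreSpec")
    inter_ok <- cat == "PreSpec" && mode %in% c("inter", "combined")
    if (intra_ok) {
      link(q$family_id, cat, "intra", q$s1, q$s2)
      link(q$family_id, cat, "intra", q$p1, q$p2)
    }
    if (inter_ok) {
      link(q$family_id, cat, "inter", q$s1, q$p1)
      link(q$family_id, cat, "inter", q$s2, q$p2)
    }
  }
  if (length(rows) == 0)
    return(data.frame(family_id = character(0), category = character(0),
                      scope = character(0), species_a = character(0),
                      chrom_a = character(0), pos_a = numeric(0),
                      gene_a = character(0), species_b = character(0),
                      chrom_b = character(0), pos_b = numeric(0),
                      gene_b = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect contiguous same-category synteny blocks
#'
#' Groups links by (species pair, chromosome pair), orders them along the
#' first chromosome, and reports maximal runs of links sharing a category,
#' tolerating up to `max_gap` interleaved links of other categories; runs
#' with at least `min_genes` links become blocks. Input order is
#' irrelevant (links are sorted internally).
#'
#' @param links data.frame from [build_links()].
#' @param min_genes minimal number of links per block (default 3).
#' @param max_gap maximal number of consecutive other-category links
#'   tolerated inside a block (default 1).
#' @return data.frame with one row per block: `species_a`, `chrom_a`,
#'   `species_b`, `chrom_b`, `category`, `n_genes`, `start_a`, `end_a`,
#'   `start_b`, `end_b`.
#' @export
detect_blocks <- function(links, min_genes = 3, max_gap = 1) {
  if (nrow(links) == 0) return(empty_blocks())
  ## canonical chromosome-pair orientation
  flip <- links$chrom_b < links$chrom_a |
    (links$chrom_a == links$chrom_b & links$species_b < links$species_a)
  l <- links
  l[flip, c("species_a", "chrom_a", "pos_a", "gene_a",
            "species_b", "chrom_b", "pos_b", "gene_b")] <-
    links[flip, c("species_b", "chrom_b", "pos_b", "gene_b",
                  "species_a", "chrom_a", "pos_a", "gene_a")]
  key <- paste(l$species_a, l$chrom_a, l$species_b, l$chrom_b, sep = "\r")
  out <- list()
  for (kk in unique(key)) {
    g <- l[key == kk, ]
    g <- g[order(g$pos_a, g$pos_b, g$gene_a), ]
    for (cat in unique(g$category)) {
      pos <- which(g$category == cat)
      if (length(pos) == 0) next
      run_start <- 1L
      i <- 1L
      while (i <= length(pos)) {
        if (i == length(pos) ||
            (pos[i + 1] - pos[i] - 1L) > max_gap) {
          members <- pos[run_start:i]
          if (length(members) >= min_genes) {
            b <- g[members, ]
            out[[length(out) + 1L]] <- data.frame(
              species_a = b$species_a[1], chrom_a = b$chrom_a[1],
              species_b = b$species_b[1], chrom_b = b$chrom_b[1],
              category = cat, n_genes = nrow(b),
              start_a = min(b$pos_a), end_a = max(b$pos_a),
              start_b = min(b$pos_b), end_b = max(b$pos_b))
          }
          run_start <- i + 1L
        }
        i <- i + 1L
      }
    }
  }
  if (length(out) == 0) return(empty_blocks())
  res <- do.call(rbind, out)
  res <- res[order(res$species_a, res$chrom_a, res$start_a, res$category), ]
  rownames(res) <- NULL
  res
}

empty_blocks <- function() {
  data.frame(species_a = character(0), chrom_a = character(0),
             species_b = character(0), chrom_b = character(0),
             category = character(0), n_genes = integer(0),
             start_a = numeric(0), end_a = numeric(0),
             start_b = numeric(0), end_b = numeric(0))
}

#' Permutation test for clustering of categories along a chromosome
#'
#' Tests whether same-category genes are more contiguous along a
#' chromosome than expected if the category labels were randomly ordered.
#' The statistic is the number of adjacent same-category pairs in gene
#' order; the null distribution is obtained by permuting labels, and
#' `p = (1 + #\{perm >= obs\}) / (1 + n_perm)`. A single gene, or a single
#' label value, is degenerate and returns `p = 1`.
#'
#' @param labels character/factor vector of category labels in gene order.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional seed for reproducibility.
#' @return list with `observed_statistic` and `p_value`.
#' @export
clustering_permutation_test <- function(labels, n_perm = 1000, seed = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  stat <- function(x) sum(x[-1] == x[-length(x)])
  if (n < 2 || length(unique(labels)) < 2)
    return(list(observed_statistic = if (n < 2) 0L else stat(labels),
                p_value = 1))
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  obs <- stat(labels)
  ge <- 0L
  for (i in seq_len(n_perm))
    if (stat(sample(labels)) >= obs) ge <- ge + 1L
  list(observed_statistic = obs, p_value = (1 + ge) / (1 + n_perm))
}

#' Write circos-format link and karyotype files
#'
#' Emits the standard circos link file (`chrom start end chrom start end
#' options`) with a colour option per category, and a karyotype file for
#' the chromosomes present, for direct rendering with external plotting
#' tools.
#'
#' @param links data.frame from [build_links()].
#' @param link_file,karyotype_file output paths.
#' @param colors named character vector of colours per category.
#' @param half_width half-width of each link anchor in bases (default 5e3).
#' @return invisibly, the paths written.
#' @export
write_circos <- function(links, link_file, karyotype_file = NULL,
                         colors = c(PreSpec = "blue", PostSpec = "red",
                                    PreSpecLike = "lblue",
                                    PostSpecLike = "lred"),
                         half_width = 5000) {
  chrom_tag <- function(sp, ch) paste0(sp, "_", ch)
  col <- unname(colors[links$category])
  col[is.na(col)] <- "grey"
  lines <- sprintf("%s %d %d %s %d %d color=%s",
                   chrom_tag(links$species_a, links$chrom_a),
                   pmax(0, round(links$pos_a - half_width)),
                   round(links$pos_a + half_width),
                   chrom_tag(links$species_b, links$chrom_b),
                   pmax(0, round(links$pos_b - half_width)),
                   round(links$pos_b + half_width),
                   col)
  writeLines(lines, link_file)
  if (!is.null(karyotype_file)) {
    tags <- unique(c(chrom_tag(links$species_a, links$chrom_a),
                     chrom_tag(links$species_b, links$chrom_b)))
    ends <- vapply(tags, function(tg) {
      m <- c(links$pos_a[chrom_tag(links$species_a, links$chrom_a) == tg],
             links$pos_b[chrom_tag(links$species_b, links$chrom_b) == tg])
      max(m) + 10 * half_width
    }, numeric(1))
    writeLines(sprintf("chr - %s %s 0 %d grey", tags, tags, round(ends)),
               karyotype_file)
  }
  invisible(c(link_file, karyotype_file))
}
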