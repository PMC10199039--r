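## Read-depth detection of collapsed (double-depth) duplicate regions.
## Consumes per-gene mean depth tables (one average value per gene, as
## produced by mosdepth-style region summaries upstream).

#' Modal sequencing depth of a gene set
#'
#' The main peak of the per-gene read-depth distribution, located as the
#' argmax of a Gaussian kernel density on a fixed grid. The mode of the
#' two-copy ohnolog-pair gene set serves as the single-copy reference
#' depth.
#'
#' @param depths numeric vector of per-gene mean depths (n >= 10).
#' @param grid_n number of density grid points (default 512).
#' @return the modal depth (single numeric).
#' @export
modal_depth <- function(depths, grid_n = 512) {
  depths <- depths[is.finite(depths)]
  if (length(depths) < 10) stop("need at least 10 depth values")
  if (sd(depths) == 0) return(depths[1])
  d <- density(depths, bw = "nrd0", n = grid_n, from = 0,
               to = max(depths) * 1.05)
  d$x[which.max(d$y)]
}

#' Classify genes as single- or double-depth (collapsed)
#'
#' A gene is labelled `double` iff its depth exceeds `threshold_factor`
#' times the single-copy reference mode. Collapsed assembly regions (or
#' residual tetrasomy) attract the reads of two loci and sit near twice
#' the reference depth; the default factor 1.5 is the midpoint of the two
#' expectations.
#'
#' @param depths numeric vector of per-gene mean depths.
#' @param reference_mode positive single-copy reference depth (typically
#'   [modal_depth()] of the two-copy ohnolog gene set).
#' @param threshold_factor multiplier on the reference (default 1.5).
#' @return list with `labels` (character vector `"single"`/`"double"`)
#'   and `double_fraction`.
#' @export
classify_collapsed <- function(depths, reference_mode,
                               threshold_factor = 1.5) {
  if (!is.finite(reference_mode) || reference_mode <= 0)
    stop("reference mode must be positive")
  lab <- ifelse(depths > threshold_factor * reference_mode,
                "double", "single")
  list(labels = lab, double_fraction = mean(lab == "double"))
}

#' Per-dataset collapsed-gene analysis
#'
#' Runs the full depth analysis on a per-gene depth table: the reference
#' mode is estimated from the two-copy ohnolog pair genes, then each
#' dataset's genes are classified and per-dataset double fractions
#' reported.
#'
#' @param depth_table data.frame with columns `gene_id`, `dataset`
#'   (`"two_copy_pair"`, `"single_copy_PostSpecType"`,
#'   `"single_copy_PreSpecType"`, ...) and `depth`.
#' @param threshold_factor multiplier on the reference mode (default 1.5).
#' @return list with `reference_mode`, `calls` (the table plus a `label`
#'   column) and `double_fraction` (named per dataset).
#' @export
coverage_analysis <- function(depth_table, threshold_factor = 1.5) {
  stopifnot(all(c("gene_id", "dataset", "depth") %in% names(depth_table)))
  ref <- modal_depth(depth_table$depth[depth_table$dataset ==
                                         "two_copy_pair"])
  cl <- classify_collapsed(depth_table$depth, ref, threshold_factor)
  depth_table$label <- cl$labels
  frac <- vapply(split(depth_table$label, depth_table$dataset),
                 function(l) mean(l == "double"), numeric(1))
  list(reference_mode = ref, calls = depth_table, double_fraction = frac)
}
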