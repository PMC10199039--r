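## Pairwise synonymous-distance (Ks) estimation and the category-stratified
## distribution summaries used to corroborate asynchronous rediploidization.

#' NG86 synonymous and nonsynonymous distances
#'
#' Counting estimator of synonymous (Ks) and nonsynonymous (Ka) distances
#' between two aligned coding sequences (Nei & Gojobori 1986): synonymous
#' and nonsynonymous site counts are averaged over the two sequences,
#' multi-hit codon pairs are averaged over their minimal substitution
#' pathways (stop-crossing pathways excluded when avoidable), and the
#' proportions are corrected for multiple hits with the Jukes-Cantor
#' transform `-(3/4) log(1 - 4p/3)`. Codons containing gaps, ambiguity
#' codes or a stop in either sequence are skipped pairwise. Proportions
#' `>= 3/4` are non-computable and flagged.
#'
#' @param seq_a,seq_b coding sequences (character strings or vectors of
#'   single characters), equal lengths divisible by 3, same reading frame.
#' @return list with `Ks`, `Ka` (NA if non-computable), `S_sites`,
#'   `N_sites`, `n_codons_used`, and `flags` (character vector, possibly
#'   empty: `"ks_noncomputable"`, `"ka_noncomputable"`, `"no_codons"`).
#' @export
ks_ng86 <- function(seq_a, seq_b) {
  a <- to_codon_vector(seq_a)
  b <- to_codon_vector(seq_b)
  if (length(a) != length(b))
    stop("sequences must have equal lengths")
  usable <- a %in% .sense_codons & b %in% .sense_codons
  a <- a[usable]; b <- b[usable]
  if (length(a) == 0)
    return(list(Ks = NA_real_, Ka = NA_real_, S_sites = 0, N_sites = 0,
                n_codons_used = 0L, flags = "no_codons"))
  s_a <- .syn_sites_table[a]; s_b <- .syn_sites_table[b]
  S <- (sum(s_a) + sum(s_b)) / 2
  N <- 3 * length(a) - S
  Sd <- 0; Nd <- 0
  for (i in seq_along(a)) {
    if (a[i] == b[i]) next
    cnt <- codon_path_counts(a[i], b[i])
    Sd <- Sd + cnt["syn"]; Nd <- Nd + cnt["nonsyn"]
  }
  ps <- Sd / S; pn <- Nd / N
  flags <- character(0)
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  if (is.finite(ps) && ps < 0.75) Ks <- jc(ps) else {
    Ks <- NA_real_; flags <- c(flags, "ks_noncomputable")
  }
  if (is.finite(pn) && pn < 0.75) Ka <- jc(pn) else {
    Ka <- NA_real_; flags <- c(flags, "ka_noncomputable")
  }
  list(Ks = unname(Ks), Ka = unname(Ka), S_sites = unname(S),
       N_sites = unname(N), n_codons_used = length(a), flags = flags)
}

to_codon_vector <- function(s) {
  if (length(s) > 1) s <- paste(s, collapse = "")
  s <- toupper(s)
  n <- nchar(s)
  if (n %% 3 != 0) stop("sequence length not divisible by 3")
  substring(s, seq(1, n, 3), seq(3, n, 3))
}

#' Build the Ks record table for classified families
#'
#' Emits one intra-species ohnolog-pair Ks record per focal species per
#' family (labelled by species and rooted category), and, for each family
#' classified `PreSpec`, the two inter-species ortholog pairs defined by
#' the mixed-species cherries of its quartet subtree. An optional set of
#' single-copy orthogroup pairs is appended as its own dataset. Records
#' whose Ks estimate is flagged are removed; the remaining records with
#' `Ks >= max_ks` are kept but marked excluded.
#'
#' @param quartets data.frame with one row per family: columns `family_id`,
#'   `rooted_category`, and gene identifiers `s1`, `s2`, `p1`, `p2` where
#'   (`s1`,`p1`) and (`s2`,`p2`) are the ortholog pairings given by the
#'   quartet subtree cherries (only used for PreSpec families).
#' @param cds named list (or character vector) of coding sequences indexed
#'   by gene identifier.
#' @param species_names character length-2: species tags for the `s` and
#'   `p` genes.
#' @param single_copy_pairs optional data.frame with columns `gene_a`,
#'   `gene_b` (one sturgeon-paddlefish pair per single-copy orthogroup).
#' @param max_ks exclusion threshold (default 0.3): records at or above it
#'   are flagged `excluded`.
#' @return data.frame with columns `family_id`, `dataset`, `gene_a`,
#'   `gene_b`, `Ks`, `Ka`, `excluded`. Missing sequences are skipped with
#'   a message.
#' @export
build_ks_datasets <- function(quartets, cds,
                              species_names = .default_ingroup,
                              single_copy_pairs = NULL, max_ks = 0.3) {
  get_seq <- function(g) if (g %in% names(cds)) cds[[g]] else NULL
  rows <- list()
  add_pair <- function(fid, dataset, ga, gb) {
    sa <- get_seq(ga); sb <- get_seq(gb)
    if (is.null(sa) || is.null(sb)) {
      message("skipping pair with missing coding sequence: ", ga, " / ", gb)
      return(invisible(NULL))
    }
    k <- ks_ng86(sa, sb)
    if (length(k$flags) > 0) return(invisible(NULL))  # flagged pair removed
    rows[[length(rows) + 1L]] <<- data.frame(
      family_id = fid, dataset = dataset, gene_a = ga, gene_b = gb,
      Ks = k$Ks, Ka = k$Ka, excluded = k$Ks >= max_ks)
  }
  for (i in seq_len(nrow(quartets))) {
    q <- quartets[i, ]
    cat <- q$rooted_category
    if (is.na(cat) || cat == "unresolved") next
    add_pair(q$family_id, paste0(species_names[1], "_", cat), q$s1, q$s2)
    add_pair(q$family_id, paste0(species_names[2], "_", cat), q$p1, q$p2)
    if (cat == "PreSpec") {
      add_pair(q$family_id, "PreSpec_ortholog", q$s1, q$p1)
      add_pair(q$family_id, "PreSpec_ortholog", q$s2, q$p2)
    }
  }
  if (!is.null(single_copy_pairs)) {
    for (i in seq_len(nrow(single_copy_pairs)))
      add_pair(NA_character_, "SingleCopy_ortholog",
               single_copy_pairs$gene_a[i], single_copy_pairs$gene_b[i])
  }
  if (length(rows) == 0)
    return(data.frame(family_id = character(0), dataset = character(0),
                      gene_a = character(0), gene_b = character(0),
                      Ks = numeric(0), Ka = numeric(0),
                      excluded = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a Ks distribution per dataset
#'
#' Quartiles by linear interpolation, a Gaussian kernel density with
#' Silverman's rule-of-thumb bandwidth evaluated on a fixed grid, and the
#' density mode, per dataset, using only non-excluded records.
#'
#' @param records data.frame from [build_ks_datasets()].
#' @param grid_n number of density grid points (default 512).
#' @param grid_max upper end of the density grid (default 0.3, the
#'   exclusion threshold).
#' @return named list (per dataset) of lists with `n`, `quartiles`,
#'   `mode`, `density` (a `density` object, or NULL when `n = 0`).
#' @export
ks_summary <- function(records, grid_n = 512, grid_max = 0.3) {
  out <- list()
  for (ds in unique(records$dataset)) {
    x <- records$Ks[records$dataset == ds & !records$excluded]
    x <- x[is.finite(x)]
    if (length(x) == 0) {
      out[[ds]] <- list(n = 0L, quartiles = NULL, mode = NA_real_,
                        density = NULL)
      next
    }
    q <- quantile(x, probs = c(0.25, 0.5, 0.75), type = 7)
    if (length(x) >= 2 && sd(x) > 0) {
      d <- density(x, bw = "nrd0", n = grid_n, from = 0, to = grid_max)
      mode <- d$x[which.max(d$y)]
    } else {
      d <- NULL; mode <- x[1]
    }
    out[[ds]] <- list(n = length(x), quartiles = q, mode = mode,
                      density = d)
  }
  out
}

#' Detect multimodality of a Ks distribution
#'
#' Finds local maxima of the Gaussian kernel density whose topographic
#' prominence (height above the highest saddle separating the peak from
#' any higher peak) exceeds a fraction of the global maximum. A clearly
#' bimodal ohnolog Ks distribution at strict support filtering is the
#' signature of distinct early and late rediploidization cohorts.
#'
#' @param x numeric vector of Ks values (n >= 20).
#' @param prominence minimal prominence as a fraction of the density
#'   maximum (default 0.1).
#' @param grid_n,grid_max density grid (defaults 512 points over
#'   `[0, grid_max]`; `grid_max` defaults to `max(x)`).
#' @return list with `n_modes` and `mode_positions` (sorted).
#' @export
bimodality_check <- function(x, prominence = 0.1, grid_n = 512,
                             grid_max = NULL) {
  x <- x[is.finite(x)]
  if (length(x) < 20) stop("need at least 20 values")
  if (is.null(grid_max)) grid_max <- max(x)
  d <- density(x, bw = "nrd0", n = grid_n, from = 0, to = grid_max)
  y <- d$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1L
  if (y[1] > y[2]) locmax <- c(1L, locmax)
  if (y[grid_n] > y[grid_n - 1]) locmax <- c(locmax, grid_n)
  if (length(locmax) == 0) return(list(n_modes = 0L,
                                       mode_positions = numeric(0)))
  keep <- logical(length(locmax))
  for (i in seq_along(locmax)) {
    pk <- locmax[i]
    higher <- locmax[y[locmax] > y[pk]]
    if (length(higher) == 0) { keep[i] <- TRUE; next }   # global max
    saddle <- -Inf
    for (h in higher) {
      rng <- if (h < pk) y[h:pk] else y[pk:h]
      saddle <- max(saddle, min(rng))
    }
    keep[i] <- (y[pk] - saddle) >= prominence * max(y)
  }
  pos <- sort(d$x[locmax[keep]])
  list(n_modes = sum(keep), mode_positions = pos)
}
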