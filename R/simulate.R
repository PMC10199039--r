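## Synthetic-data generator: desk-scale datasets under the three WGD /
## rediploidization scenarios, with per-family ground truth for every
## downstream module. Scenario 1 (independent-looking duplications) and
## Scenario 2 (fully shared) are the two degenerate ends of Scenario 3
## (shared WGD, block-wise rediploidization straddling speciation) and are
## obtained by pinning the rediploidization-time distribution.

#' Simulation configuration
#'
#' Assembles and validates the full parameterization of the WGD +
#' rediploidization simulator. Times are in Ma before present with
#' `t_root > max(outgroup) > t_wgd > t_spec > 0`; rates are in expected
#' substitutions per site per Ma.
#'
#' @param t_wgd time of the shared whole-genome duplication (default 250).
#' @param t_spec time of the focal speciation (default 170).
#' @param outgroup_times named numeric: divergence time of each successive
#'   outgroup lineage (default Gar 368, Shark 465; the last is the root).
#' @param n_blocks number of rediploidization blocks (default 30).
#' @param genes_per_block integer range `c(min, max)` of families per
#'   block (default 4-10).
#' @param prespec_fraction optional design fraction of blocks that
#'   rediploidize before speciation (assigned exactly, randomly placed);
#'   `NULL` (default) draws the ancestral candidate time uniformly on
#'   `(0, t_wgd)`, giving the expected fraction
#'   `(t_wgd - t_spec) / t_wgd`.
#' @param rate_ingroup named amino-acid rates for the two focal lineages
#'   (default sturgeon 5e-4, paddlefish 6e-4 - a 1.2x faster paddlefish).
#' @param rate_ancestral,rate_outgroup amino-acid rates on ancestral and
#'   outgroup branches (default 5e-4).
#' @param syn_rate_ingroup named synonymous rates for Ks emulation
#'   (defaults equal to the amino-acid rates).
#' @param syn_rate_ancestral ancestral synonymous rate (default 5e-4).
#' @param p_loss probability that a family loses one paddlefish ohnolog
#'   (default 0.05).
#' @param p_collapse probability that an eligible recently-rediploidized
#'   PostSpec family has its paddlefish copies collapsed into a single
#'   assembly sequence at double depth (default 0.15).
#' @param collapse_recency fraction of `t_spec` below which a PostSpec
#'   paddlefish rediploidization time makes the family collapse-eligible
#'   (default 0.35).
#' @param p_nni maximal probability of one topology-noise NNI inside the
#'   quartet subtree (default 0.1); the realized probability decays as
#'   `p_nni * exp(-b_min / nni_scale)` with the shortest internal branch.
#' @param nni_scale decay scale of the NNI probability, in substitutions
#'   per site (default 0.005).
#' @param support_scale saturation scale of the heuristic branch-support
#'   model `100 * (1 - exp(-b / support_scale))` (default 0.0015).
#' @param support_noise standard deviation of Gaussian noise added to
#'   supports (default 1.5).
#' @param depth_mean,depth_cv read-depth model: single-copy mean and
#'   coefficient of variation (defaults 30, 0.1).
#' @param n_chrom_pairs chromosome pairs per species (default 5).
#' @param gene_span,gene_gap gene length and intergenic spacing in bp
#'   (defaults 10 kb, 15 kb).
#' @param aln_length amino-acid alignment length (default 300).
#' @param n_codons coding-sequence length in codons (default 300).
#' @param alpha_gamma gamma shape of among-site rate variation (default 1).
#' @param omega relative nonsynonymous rate of the codon simulator
#'   (default 0.2).
#' @param n_single_copy number of extra single-copy orthogroup pairs for
#'   the ortholog Ks comparison set (default 40).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(t_wgd = 250, t_spec = 170,
                       outgroup_times = c(Gar = 368, Shark = 465),
                       n_blocks = 30, genes_per_block = c(4, 10),
                       prespec_fraction = NULL,
                       rate_ingroup = c(Sturgeon = 5e-4, Paddlefish = 6e-4),
                       rate_ancestral = 5e-4, rate_outgroup = 5e-4,
                       syn_rate_ingroup = c(Sturgeon = 5e-4,
                                            Paddlefish = 6e-4),
                       syn_rate_ancestral = 5e-4,
                       p_loss = 0.05, p_collapse = 0.15,
                       collapse_recency = 0.35,
                       p_nni = 0.1, nni_scale = 0.005,
                       support_scale = 0.0015, support_noise = 1.5,
                       depth_mean = 30, depth_cv = 0.1,
                       n_chrom_pairs = 5, gene_span = 1e4, gene_gap = 1.5e4,
                       aln_length = 300, n_codons = 300,
                       alpha_gamma = 1, omega = 0.2,
                       n_single_copy = 40) {
  cfg <- as.list(environment())
  ot <- sort(outgroup_times)
  if (!(t_wgd > t_spec && t_spec > 0)) stop("need t_wgd > t_spec > 0")
  if (ot[1] <= t_wgd) stop("outgroup divergences must predate the WGD")
  probs <- c(p_loss, p_collapse, p_nni)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(c(rate_ingroup, rate_ancestral, rate_outgroup) <= 0))
    stop("rates must be positive")
  cfg$outgroup_times <- ot
  cfg$ingroup <- names(rate_ingroup)
  class(cfg) <- "sim_config"
  cfg
}

#' Species tree implied by a simulation configuration
#'
#' @param cfg a [sim_config()].
#' @return rooted `phylo` over the two focal species and the outgroups.
#' @export
sim_species_tree <- function(cfg) {
  nwk <- sprintf("(%s,%s)", cfg$ingroup[1], cfg$ingroup[2])
  for (og in names(cfg$outgroup_times))
    nwk <- sprintf("(%s,%s)", nwk, og)
  ape::read.tree(text = paste0(nwk, ";"))
}

#' Simulate rediploidization blocks and the family layout
#'
#' Each block draws one ancestral candidate rediploidization time `u`: if
#' `u > t_spec` the whole block rediploidized before speciation and is
#' `PreSpec` with shared time `r = u`; otherwise rediploidization completed
#' independently in each lineage and the block is `PostSpec` with
#' lineage-specific times drawn uniformly on `(0, t_spec)`. Families
#' inherit their block's category and times, and genes are laid out
#' contiguously in block order on the block's chromosome pair (the two
#' ohnolog copies sit on the two chromosomes of the pair, collinearly in
#' both species).
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed.
#' @return a list of class `sim_truth` with data.frames `blocks`,
#'   `families` (per-family true category and times) and `coords`
#'   (per-gene chromosome coordinates).
#' @export
simulate_blocks <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nb <- cfg$n_blocks
  u <- if (is.null(cfg$prespec_fraction)) {
    runif(nb, 0, cfg$t_wgd)
  } else {
    ## design fraction: exactly round(f * n_blocks) early-rediploidizing
    ## blocks, randomly placed, times still stochastic within each regime
    n_pre <- round(cfg$prespec_fraction * nb)
    pre <- sample(rep(c(TRUE, FALSE), c(n_pre, nb - n_pre)))
    ifelse(pre, runif(nb, cfg$t_spec, cfg$t_wgd), runif(nb, 0, cfg$t_spec))
  }
  pre <- u > cfg$t_spec
  blocks <- data.frame(
    block_id = sprintf("blk%03d", seq_len(nb)),
    category = ifelse(pre, "PreSpec", "PostSpec"),
    r_shared = ifelse(pre, u, NA_real_),
    r_s = ifelse(pre, NA_real_, runif(nb, 0, cfg$t_spec)),
    r_p = ifelse(pre, NA_real_, runif(nb, 0, cfg$t_spec)),
    n_genes = {
      rng <- cfg$genes_per_block[1]:cfg$genes_per_block[2]
      rng[sample.int(length(rng), nb, replace = TRUE)]
    },
    chrom_pair = ((seq_len(nb) - 1L) %% cfg$n_chrom_pairs) + 1L)
  fam <- list(); coords <- list()
  fam_i <- 0L
  gene_cursor <- integer(cfg$n_chrom_pairs)   # genes already placed per pair
  step <- cfg$gene_span + cfg$gene_gap
  for (b in seq_len(nb)) {
    for (g in seq_len(blocks$n_genes[b])) {
      fam_i <- fam_i + 1L
      fid <- sprintf("fam%04d", fam_i)
      pair <- blocks$chrom_pair[b]
      slot <- gene_cursor[pair]
      gene_cursor[pair] <- slot + 1L
      start <- slot * step
      fam[[fam_i]] <- data.frame(
        family_id = fid, block_id = blocks$block_id[b],
        category = blocks$category[b],
        r_shared = blocks$r_shared[b], r_s = blocks$r_s[b],
        r_p = blocks$r_p[b],
        s1 = paste0(fid, "_S1"), s2 = paste0(fid, "_S2"),
        p1 = paste0(fid, "_P1"), p2 = paste0(fid, "_P2"))
      chromA <- sprintf("chr%02d", 2L * pair - 1L)
      chromB <- sprintf("chr%02d", 2L * pair)
      coords[[fam_i]] <- data.frame(
        gene_id = paste0(fid, c("_S1", "_S2", "_P1", "_P2")),
        species = rep(cfg$ingroup, each = 2)[c(1, 2, 3, 4)],
        chrom = c(chromA, chromB, chromA, chromB),
        start = rep(start, 4), end = rep(start + cfg$gene_span, 4))
    }
  }
  structure(list(blocks = blocks,
                 families = do.call(rbind, fam),
                 coords = do.call(rbind, coords)),
            class = "sim_truth")
}

## label helpers for simulated genes
sim_lab <- function(cfg, which, gene) make_leaf_label(
  switch(which, s = cfg$ingroup[1], p = cfg$ingroup[2], which), gene)

#' Simulate one gene family tree with branch lengths and supports
#'
#' Builds the true rooted gene tree of a family: a PreSpec family has a
#' duplication node at its shared rediploidization time with two
#' mixed-species speciation cherries at `t_spec`; a PostSpec family has a
#' speciation node at `t_spec` over two same-species duplication cherries
#' at the lineage-specific times. Outgroup lineages attach per the species
#' tree; branch lengths are lineage rate x time span. With probability
#' `p_nni * exp(-b_min / nni_scale)` (shrinking when the shortest internal
#' branch is long) one NNI is applied inside the quartet, producing an
#' 'Other' topology with low supports. Supports on unperturbed quartet
#' edges follow a saturating function of the internal branch length plus
#' noise, reaching 95-100 for long branches.
#'
#' @param family one row of the `families` table of [simulate_blocks()].
#' @param cfg a [sim_config()].
#' @return list with `tree` (amino-acid-scaled `phylo`, rooted, support
#'   node labels), `ks_tree` (same topology, synonymous-rate branch
#'   lengths, quartet only), `flipped` (was an NNI applied),
#'   `category_true`.
#' @export
simulate_gene_tree <- function(family, cfg) {
  ing <- cfg$ingroup
  rS <- cfg$rate_ingroup[[1]]; rP <- cfg$rate_ingroup[[2]]
  rA <- cfg$rate_ancestral
  kS <- cfg$syn_rate_ingroup[[1]]; kP <- cfg$syn_rate_ingroup[[2]]
  kA <- cfg$syn_rate_ancestral
  S1 <- sim_lab(cfg, "s", family$s1); S2 <- sim_lab(cfg, "s", family$s2)
  P1 <- sim_lab(cfg, "p", family$p1); P2 <- sim_lab(cfg, "p", family$p2)
  pre <- family$category == "PreSpec"
  ## true internal branch lengths (amino-acid scale) of the quartet
  if (pre) {
    bint <- rep(rA * (family$r_shared - cfg$t_spec), 2)
    t_qroot <- family$r_shared
  } else {
    bint <- c(rS * (cfg$t_spec - family$r_s), rP * (cfg$t_spec - family$r_p))
    t_qroot <- cfg$t_spec
  }
  p_flip <- cfg$p_nni * exp(-min(bint) / cfg$nni_scale)
  flipped <- runif(1) < p_flip
  supp_fun <- function(b) {
    s <- round(100 * (1 - exp(-b / cfg$support_scale)) +
                 rnorm(length(b), 0, cfg$support_noise))
    pmin(100L, pmax(0L, as.integer(s)))
  }
  fmt <- function(x) sprintf("%.8f", pmax(x, 0))
  if (!flipped) {
    supports <- supp_fun(bint)
    if (pre) {
      q_aa <- sprintf("((%s:%s,%s:%s)%d:%s,(%s:%s,%s:%s)%d:%s)",
                      S1, fmt(rS * cfg$t_spec), P1, fmt(rP * cfg$t_spec),
                      supports[1], fmt(bint[1]),
                      S2, fmt(rS * cfg$t_spec), P2, fmt(rP * cfg$t_spec),
                      supports[2], fmt(bint[2]))
      q_ks <- sprintf("((%s:%s,%s:%s):%s,(%s:%s,%s:%s):%s)",
                      S1, fmt(kS * cfg$t_spec), P1, fmt(kP * cfg$t_spec),
                      fmt(kA * (family$r_shared - cfg$t_spec)),
                      S2, fmt(kS * cfg$t_spec), P2, fmt(kP * cfg$t_spec),
                      fmt(kA * (family$r_shared - cfg$t_spec)))
    } else {
      q_aa <- sprintf("((%s:%s,%s:%s)%d:%s,(%s:%s,%s:%s)%d:%s)",
                      S1, fmt(rS * family$r_s), S2, fmt(rS * family$r_s),
                      supports[1], fmt(bint[1]),
                      P1, fmt(rP * family$r_p), P2, fmt(rP * family$r_p),
                      supports[2], fmt(bint[2]))
      q_ks <- sprintf("((%s:%s,%s:%s):%s,(%s:%s,%s:%s):%s)",
                      S1, fmt(kS * family$r_s), S2, fmt(kS * family$r_s),
                      fmt(kS * (cfg$t_spec - family$r_s)),
                      P1, fmt(kP * family$r_p), P2, fmt(kP * family$r_p),
                      fmt(kP * (cfg$t_spec - family$r_p)))
    }
  } else {
    ## topology noise: a random rooted caterpillar over the four tips,
    ## node times at fixed fractions of the true quartet root time
    supports <- as.integer(round(runif(2, 40, 90)))
    tips <- sample(c(S1, S2, P1, P2))
    rate_of <- function(lab) if (leaf_species(lab) == ing[1]) rS else rP
    krate_of <- function(lab) if (leaf_species(lab) == ing[1]) kS else kP
    tt <- c(0.4, 0.7, 1) * t_qroot
    q_aa <- sprintf("(((%s:%s,%s:%s)%d:%s,%s:%s)%d:%s,%s:%s)",
                    tips[1], fmt(rate_of(tips[1]) * tt[1]),
                    tips[2], fmt(rate_of(tips[2]) * tt[1]),
                    supports[1], fmt(rA * (tt[2] - tt[1])),
                    tips[3], fmt(rate_of(tips[3]) * tt[2]),
                    supports[2], fmt(rA * (tt[3] - tt[2])),
                    tips[4], fmt(rate_of(tips[4]) * tt[3]))
    q_ks <- sprintf("(((%s:%s,%s:%s):%s,%s:%s):%s,%s:%s)",
                    tips[1], fmt(krate_of(tips[1]) * tt[1]),
                    tips[2], fmt(krate_of(tips[2]) * tt[1]),
                    fmt(kA * (tt[2] - tt[1])),
                    tips[3], fmt(krate_of(tips[3]) * tt[2]),
                    fmt(kA * (tt[3] - tt[2])),
                    tips[4], fmt(krate_of(tips[4]) * tt[3]))
  }
  ## wrap with the outgroup ladder (ascending divergence times)
  cur <- q_aa; t_cur <- t_qroot
  for (og in names(cfg$outgroup_times)) {
    t_og <- cfg$outgroup_times[[og]]
    oglab <- make_leaf_label(og, paste0(family$family_id, "_", og))
    cur <- sprintf("(%s:%s,%s:%s)100", cur, fmt(rA * (t_og - t_cur)),
                   oglab, fmt(cfg$rate_outgroup * t_og))
    t_cur <- t_og
  }
  tree <- ape::read.tree(text = paste0(cur, ";"))
  ks_tree <- ape::read.tree(text = paste0(q_ks, ";"))
  list(tree = tree, ks_tree = ks_tree, flipped = flipped,
       category_true = family$category)
}

#' Simulate sequences along a tree
#'
#' Evolves sequences from a stationary root along the tree's branches
#' under a reversible substitution model with discrete-gamma among-site
#' rate variation. In `"aa"` mode the model is the empirical amino-acid
#' model and branch lengths are substitutions/site; in `"codon"` mode the
#' model is the two-rate synonymous/nonsynonymous codon chain of
#' [codon_model()] and branch lengths are on the Ks scale, so the realized
#' synonymous distance of a pair tracks the sum of its branch lengths.
#'
#' @param tree `phylo` with branch lengths in model units.
#' @param length number of sites (amino acids or codons).
#' @param type `"aa"` or `"codon"`.
#' @param model optional pre-built [subst_model()] (re-using one across
#'   families avoids repeated eigendecompositions).
#' @param alpha gamma shape (default 1); `Inf` disables rate variation.
#' @param k number of gamma categories (default 4).
#' @param seed optional integer seed.
#' @return `"aa"`: character matrix (tips x sites); `"codon"`: named
#'   character vector of nucleotide strings.
#' @export
simulate_sequences <- function(tree, length, type = c("aa", "codon"),
                               model = NULL, alpha = 1, k = 4,
                               seed = NULL) {
  type <- match.arg(type)
  if (length < 1) stop("length must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(model))
    model <- if (type == "aa") subst_model() else codon_model()
  nstate <- base::length(model$states)
  rates <- if (is.finite(alpha)) gamma_rates(alpha, k) else 1
  site_cat <- sample.int(base::length(rates), length, replace = TRUE)
  ntip <- base::length(tree$tip.label)
  root <- ntip + 1L
  nnode <- ntip + tree$Nnode
  states <- matrix(NA_integer_, nnode, length)
  states[root, ] <- sample.int(nstate, length, replace = TRUE,
                               prob = model$freqs)
  eo <- ape::reorder.phylo(tree, "cladewise")
  el <- eo$edge.length
  if (is.null(el)) stop("tree has no branch lengths")
  for (e in seq_len(nrow(eo$edge))) {
    par <- eo$edge[e, 1]; ch <- eo$edge[e, 2]
    for (cat in seq_along(rates)) {
      sites <- which(site_cat == cat)
      if (base::length(sites) == 0) next
      P <- transition_matrix(model, el[e] * rates[cat])
      ps <- states[par, sites]
      for (s in unique(ps)) {
        at <- sites[ps == s]
        states[ch, at] <- sample.int(nstate, base::length(at),
                                     replace = TRUE, prob = P[s, ])
      }
    }
  }
  tipstates <- states[seq_len(ntip), , drop = FALSE]
  if (type == "aa") {
    m <- matrix(model$states[tipstates], ntip, length)
    rownames(m) <- tree$tip.label
    m
  } else {
    setNames(apply(tipstates, 1, function(row)
      paste(model$states[row], collapse = "")), tree$tip.label)
  }
}

#' Simulate the observable layers: coordinates, depth, loss and collapse
#'
#' Applies paddlefish ohnolog loss (one copy deleted; the family becomes a
#' three-gene triplet at single depth) and assembly collapse (recently
#' rediploidized PostSpec paddlefish copies merged into one gene carrying
#' the reads of two loci, i.e. double depth); all remaining genes receive
#' single-copy depths with Gaussian noise. Depth-dataset labels follow the
#' family's true category mapped to its unrooted type.
#'
#' @param truth a `sim_truth` from [simulate_blocks()].
#' @param cfg a [sim_config()].
#' @param seed optional integer seed.
#' @return list with `depth` (data.frame `gene_id`, `dataset`, `depth`),
#'   `status` (per family: `"quartet"`, `"lost"` or `"collapsed"`), and
#'   `coords` (updated: deleted genes removed).
#' @export
simulate_observables <- function(truth, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fam <- truth$families
  n <- nrow(fam)
  lost <- runif(n) < cfg$p_loss
  eligible <- fam$category == "PostSpec" &
    !is.na(fam$r_p) & fam$r_p < cfg$collapse_recency * cfg$t_spec
  collapsed <- !lost & eligible & runif(n) < cfg$p_collapse
  status <- ifelse(lost, "lost", ifelse(collapsed, "collapsed", "quartet"))
  type_of <- category_to_type(fam$category)
  rows <- list(); drop_genes <- character(0)
  rdepth <- function(mult, m) rnorm(m, mult * cfg$depth_mean,
                                    cfg$depth_cv * cfg$depth_mean)
  for (i in seq_len(n)) {
    p_genes <- c(fam$p1[i], fam$p2[i])
    if (status[i] == "lost") {
      gone <- sample(p_genes, 1)
      keep <- setdiff(p_genes, gone)
      drop_genes <- c(drop_genes, gone)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = keep, dataset = paste0("single_copy_", type_of[i]),
        depth = rdepth(1, 1))
    } else if (status[i] == "collapsed") {
      drop_genes <- c(drop_genes, fam$p2[i])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = fam$p1[i], dataset = paste0("single_copy_", type_of[i]),
        depth = rdepth(2, 1))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = p_genes, dataset = "two_copy_pair", depth = rdepth(1, 2))
    }
  }
  depth <- do.call(rbind, rows)
  depth$depth <- pmax(depth$depth, 0)
  coords <- truth$coords[!(truth$coords$gene_id %in% drop_genes), ]
  list(depth = depth,
       status = setNames(status, fam$family_id),
       coords = coords)
}

#' Simulate a complete desk-scale dataset
#'
#' Master wrapper: draws the block structure, one gene tree per family,
#' and the observable layers, optionally simulating amino-acid alignments
#' and/or coding sequences. All randomness flows from the single seed via
#' sequential draws, so the same (config, seed) reproduces the dataset
#' exactly.
#'
#' @param cfg a [sim_config()].
#' @param seed integer master seed.
#' @param aa_families families for which to simulate amino-acid
#'   alignments: `TRUE` (all), `FALSE`/`NULL` (none), or a vector of
#'   family ids.
#' @param codon_families likewise for coding sequences (quartet genes
#'   only).
#' @return list with `cfg`, `truth`, `trees`, `ks_trees`, `flipped`,
#'   `observables`, and (when requested) `alignments` (named list of
#'   amino-acid matrices), `cds` (named character vector of coding
#'   sequences) and `single_copy_pairs` (ortholog comparison set,
#'   codon mode only).
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = 1,
                             aa_families = NULL, codon_families = NULL) {
  set.seed(seed)
  truth <- simulate_blocks(cfg)
  fam <- truth$families
  sims <- lapply(seq_len(nrow(fam)),
                 function(i) simulate_gene_tree(fam[i, ], cfg))
  names(sims) <- fam$family_id
  trees <- lapply(sims, `[[`, "tree")
  ks_trees <- lapply(sims, `[[`, "ks_tree")
  flipped <- vapply(sims, `[[`, logical(1), "flipped")
  obs <- simulate_observables(truth, cfg)
  out <- list(cfg = cfg, truth = truth, trees = trees, ks_trees = ks_trees,
              flipped = flipped, observables = obs)
  pick <- function(which) {
    if (isTRUE(which)) fam$family_id
    else if (is.character(which)) intersect(which, fam$family_id)
    else character(0)
  }
  aa_ids <- pick(aa_families)
  if (length(aa_ids) > 0) {
    aam <- subst_model()
    out$alignments <- lapply(trees[aa_ids], simulate_sequences,
                             length = cfg$aln_length, type = "aa",
                             model = aam, alpha = cfg$alpha_gamma)
  }
  codon_ids <- pick(codon_families)
  if (length(codon_ids) > 0) {
    cm <- codon_model(cfg$omega)
    cds <- list()
    for (fid in codon_ids) {
      seqs <- simulate_sequences(ks_trees[[fid]], length = cfg$n_codons,
                                 type = "codon", model = cm,
                                 alpha = cfg$alpha_gamma)
      names(seqs) <- leaf_gene(names(seqs))
      cds <- c(cds, as.list(seqs))
    }
    ## extra single-copy orthogroup pairs diverging at speciation
    sco <- list()
    if (cfg$n_single_copy > 0) {
      kS <- cfg$syn_rate_ingroup[[1]]; kP <- cfg$syn_rate_ingroup[[2]]
      two <- ape::read.tree(text = sprintf(
        "(%s:%0.8f,%s:%0.8f);", "a", kS * cfg$t_spec, "b",
        kP * cfg$t_spec))
      for (j in seq_len(cfg$n_single_copy)) {
        sid <- sprintf("sco%03d", j)
        seqs <- simulate_sequences(two, length = cfg$n_codons,
                                   type = "codon", model = cm,
                                   alpha = cfg$alpha_gamma)
        cds[[paste0(sid, "_S")]] <- unname(seqs["a"])
        cds[[paste0(sid, "_P")]] <- unname(seqs["b"])
        sco[[j]] <- data.frame(gene_a = paste0(sid, "_S"),
                               gene_b = paste0(sid, "_P"))
      }
      out$single_copy_pairs <- do.call(rbind, sco)
    }
    out$cds <- cds
  }
  out
}
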