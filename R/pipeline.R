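## End-to-end orchestration: simulate (or accept) a dataset, classify it,
## and run the corroborating analyses, emitting one structured report.

#' Run the full analysis pipeline on a simulated dataset
#'
#' Executes the stages in fixed order - simulate, family filters,
#' classification, support-cut-off sweep with fold deviations, synteny
#' links/blocks/clustering, read-depth collapse analysis, Ks distributions
#' (when coding sequences are simulated), AU tests (on a configurable
#' number of families), and dating-family selection with supermatrix
#' construction - and returns a single structured report. All randomness
#' derives from the master seed.
#'
#' @param cfg a [sim_config()].
#' @param seed master integer seed.
#' @param n_au number of families (taken in id order) to subject to the AU
#'   test; 0 disables the stage (it is by far the most expensive).
#' @param ks run the Ks stage (simulates coding sequences; default FALSE).
#' @param out_dir optional directory; when given, per-stage TSV artifacts
#'   and a JSON report are written there.
#' @param au_B,au_scales AU-test resampling parameters.
#' @return a list of class `run_report`; see the elements `classification`,
#'   `cutoffs`, `filters`, `synteny`, `coverage`, `ks`, `au`,
#'   `supermatrix`, `config`.
#' @export
run_pipeline <- function(cfg = sim_config(), seed = 1, n_au = 0,
                         ks = FALSE, out_dir = NULL,
                         au_B = 500, au_scales = seq(0.5, 1.4, by = 0.1)) {
  sim <- simulate_dataset(cfg, seed = seed,
                          codon_families = if (ks) TRUE else NULL)
  sp_tree <- sim_species_tree(cfg)
  fam <- sim$truth$families
  obs <- sim$observables
  quartet_ok <- names(obs$status)[obs$status == "quartet"]
  trees <- sim$trees[quartet_ok]

  ## family filters (placed chromosomes: all simulated ones)
  placed <- setNames(rep(list(sprintf("chr%02d",
                                      seq_len(2 * cfg$n_chrom_pairs))),
                         2), cfg$ingroup)
  filters <- lapply(quartet_ok, function(fid)
    apply_family_filters(fid, trees[[fid]], obs$coords, placed,
                         ingroup = cfg$ingroup))
  pass <- vapply(filters, `[[`, logical(1), "pass")
  kept <- quartet_ok[pass]

  classification <- classify_families(trees[kept], sp_tree,
                                      ingroup = cfg$ingroup)
  sweep <- cutoff_sweep(classification)

  ## quartet gene roles for downstream tables
  roles <- t(vapply(kept, function(fid)
    quartet_gene_roles(trees[[fid]], cfg$ingroup), character(4)))
  quartets <- data.frame(family_id = kept,
                         rooted_category = classification$rooted_category,
                         s1 = roles[, "s1"], s2 = roles[, "s2"],
                         p1 = roles[, "p1"], p2 = roles[, "p2"])

  links <- build_links(quartets, obs$coords, mode = "intra",
                       species_names = cfg$ingroup)
  blocks <- detect_blocks(links)
  ## clustering test per sturgeon chromosome (gene order = link order)
  sl <- links[links$species_a == cfg$ingroup[1], ]
  clus <- lapply(split(sl, sl$chrom_a), function(g) {
    g <- g[order(g$pos_a), ]
    clustering_permutation_test(g$category, n_perm = 1000)
  })
  clustering <- data.frame(
    chrom = names(clus),
    observed = vapply(clus, `[[`, numeric(1), "observed_statistic"),
    p_value = vapply(clus, `[[`, numeric(1), "p_value"))

  coverage <- coverage_analysis(obs$depth)

  ks_res <- NULL
  if (ks) {
    ks_records <- build_ks_datasets(quartets, sim$cds,
                                    species_names = cfg$ingroup,
                                    single_copy_pairs = sim$single_copy_pairs)
    ks_res <- list(records = ks_records, summary = ks_summary(ks_records))
  }

  au_res <- NULL
  if (n_au > 0) {
    ids <- head(kept, n_au)
    aam <- subst_model()
    sim_aln <- simulate_dataset(cfg, seed = seed, aa_families = ids)
    au_rows <- lapply(ids, function(fid) {
      qs <- quartet_subtree(trees[[fid]], cfg$ingroup)
      aln <- sim_aln$alignments[[fid]][qs$subtree$tip.label, , drop = FALSE]
      a <- au_quartet(aln, model = aam, alpha = cfg$alpha_gamma,
                      scales = au_scales, B = au_B)
      data.frame(family_id = fid,
                 rooted_category = classification$rooted_category[
                   classification$family_id == fid],
                 p_prespec_type = a$type_p[["PreSpecType"]],
                 p_postspec_type = a$type_p[["PostSpecType"]],
                 best_type = a$best_type)
    })
    au_tab <- do.call(rbind, au_rows)
    au_res <- list(results = au_tab,
                   rejections = summarize_rejections(au_tab))
  }

  dating <- select_dating_families(classification, trees,
                                   ingroup = cfg$ingroup)

  report <- structure(list(
    config = cfg, seed = seed,
    truth = sim$truth, status = obs$status,
    filters = data.frame(
      family_id = quartet_ok, pass = pass,
      reasons = vapply(filters, function(f)
        paste(f$reasons, collapse = ","), "")),
    classification = classification,
    cutoffs = sweep,
    synteny = list(links = links, blocks = blocks,
                   clustering = clustering),
    coverage = coverage,
    ks = ks_res,
    au = au_res,
    dating_families = dating), class = "run_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write the pipeline report artifacts
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, `out_dir`.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  write_tsv(report$classification, fp("classification.tsv"))
  write_tsv(report$cutoffs, fp("cutoff_sweep.tsv"))
  write_tsv(report$filters, fp("filters.tsv"))
  write_tsv(report$synteny$links, fp("synteny_links.tsv"))
  write_tsv(report$synteny$blocks, fp("synteny_blocks.tsv"))
  write_tsv(report$synteny$clustering, fp("synteny_clustering.tsv"))
  write_tsv(report$coverage$calls, fp("coverage_calls.tsv"))
  if (!is.null(report$ks)) write_tsv(report$ks$records, fp("ks_records.tsv"))
  if (!is.null(report$au)) {
    write_tsv(report$au$results, fp("au_results.tsv"))
    write_tsv(report$au$rejections, fp("au_rejections.tsv"))
  }
  summary <- list(
    seed = report$seed,
    n_families = nrow(report$truth$families),
    n_classified = sum(!is.na(report$classification$rooted_category)),
    counts_cutoff0 = as.list(category_counts(report$classification, 0)$counts),
    fold_cutoff0 = as.list(fold_deviation(
      category_counts(report$classification, 0)$counts)),
    coverage_reference_mode = report$coverage$reference_mode,
    double_fraction = as.list(report$coverage$double_fraction),
    n_dating_families = length(report$dating_families))
  jsonlite::write_json(summary, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
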