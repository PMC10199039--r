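## Preparation of phylogenomic dating inputs: selection of maximally
## supported shared-duplication families, random A/B ohnolog assignment,
## concatenation, and no-gaps column trimming. The Bayesian dating run
## itself is external.

#' Select families for divergence dating
#'
#' Keeps families classified `PreSpec` whose two quartet-internal supports
#' both equal 100 and whose trees contain no duplicate gene in any
#' non-focal species (otherwise single copy).
#'
#' @param classification data.frame with columns `family_id`,
#'   `rooted_category`, `support_min` (and optionally `support_both_100`).
#' @param trees named list of `phylo` gene trees (by `family_id`).
#' @param ingroup the two focal species tags.
#' @return character vector of selected `family_id`s.
#' @export
select_dating_families <- function(classification, trees,
                                   ingroup = .default_ingroup) {
  keep <- classification$rooted_category == "PreSpec" &
    !is.na(classification$support_min) & classification$support_min >= 100
  ids <- classification$family_id[keep %in% TRUE]
  ok <- vapply(ids, function(fid) {
    tr <- trees[[fid]]
    if (is.null(tr)) return(FALSE)
    sp <- leaf_species(tr$tip.label)
    out_sp <- sp[!(sp %in% ingroup)]
    length(out_sp) == 0 || max(table(out_sp)) <= 1
  }, logical(1))
  ids[ok]
}

#' Randomly assign ohnolog copies and concatenate supermatrices
#'
#' For each replicate, a seeded fair coin decides per family which of the
#' two ohnolog units (each unit = one sturgeon + one paddlefish ortholog
#' pair) is labelled the A copy; rows `<Species>A`/`<Species>B` plus one
#' row per outgroup species are concatenated across families (families
#' missing a required focal sequence are dropped with a message; outgroup
#' species missing from a family are padded with gaps). Replicates differ
#' only in the A/B assignment.
#'
#' @param families named list (by family id); each element a list with
#'   `unit1`, `unit2` (each a named character vector of aligned sequences
#'   keyed `"Sturgeon"`, `"Paddlefish"`) and optionally `outgroups` (named
#'   character vector keyed by species).
#' @param n_replicates number of alternative concatenations (default 5).
#' @param seed integer seed governing all assignments.
#' @param ingroup the two focal species tags.
#' @return list of replicates; each is a list with `matrix` (named
#'   character vector of concatenated sequences), `record` (a
#'   `concatenation_record`: replicate id, seed, per-family assignment,
#'   partition table, columns before/after no-gaps trimming) and
#'   `trimmed` (the no-gaps-trimmed matrix).
#' @export
shuffle_concat <- function(families, n_replicates = 5, seed = 1,
                           ingroup = .default_ingroup) {
  stopifnot(length(families) > 0)
  fam_ok <- vapply(families, function(f) {
    all(ingroup %in% names(f$unit1)) && all(ingroup %in% names(f$unit2)) &&
      nchar(f$unit1[[1]]) > 0
  }, logical(1))
  if (any(!fam_ok))
    message("dropping families with missing focal sequences: ",
            paste(names(families)[!fam_ok], collapse = ", "))
  families <- families[fam_ok]
  out_species <- sort(unique(unlist(lapply(families, function(f)
    names(f$outgroups)))))
  taxa <- c(paste0(ingroup, "A"), paste0(ingroup, "B"), out_species)
  set.seed(seed)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    flip <- setNames(sample(c(TRUE, FALSE), length(families),
                            replace = TRUE), names(families))
    mats <- setNames(rep(list(character(0)), length(taxa)), taxa)
    parts <- data.frame(family_id = character(0), start = integer(0),
                        end = integer(0))
    col <- 0L
    for (fid in names(families)) {
      f <- families[[fid]]
      a <- if (flip[fid]) f$unit2 else f$unit1
      b <- if (flip[fid]) f$unit1 else f$unit2
      L <- nchar(a[[ingroup[1]]])
      gaprow <- strrep("-", L)
      for (sp in ingroup) {
        mats[[paste0(sp, "A")]] <- c(mats[[paste0(sp, "A")]], a[[sp]])
        mats[[paste0(sp, "B")]] <- c(mats[[paste0(sp, "B")]], b[[sp]])
      }
      for (sp in out_species) {
        has <- !is.null(f$outgroups) && sp %in% names(f$outgroups)
        mats[[sp]] <- c(mats[[sp]], if (has) f$outgroups[[sp]] else gaprow)
      }
      parts <- rbind(parts, data.frame(family_id = fid, start = col,
                                       end = col + L))
      col <- col + L
    }
    mat <- vapply(mats, paste0, "", collapse = "")
    trimmed <- trim_gapped_columns(mat)
    record <- structure(list(
      replicate = r, seed = seed,
      assignment = ifelse(flip, "unit2=A", "unit1=A"),
      partitions = parts,
      columns_before = col,
      columns_after = nchar(trimmed[[1]])),
      class = "concatenation_record")
    reps[[r]] <- list(matrix = mat, record = record, trimmed = trimmed)
  }
  reps
}

#' Remove every alignment column containing a gap
#'
#' trimAl-style `-nogaps` filtering: drops each column in which any
#' sequence carries a gap or missing character (`-`, `.`, `?`, `X`, `*`).
#' Idempotent; warns when nothing survives.
#'
#' @param aln alignment (character matrix or named equal-length strings).
#' @return alignment in the input representation, gap-free.
#' @export
trim_gapped_columns <- function(aln) {
  was_strings <- !is.matrix(aln)
  m <- as_aln_matrix(aln)
  bad <- apply(m, 2, function(cl) any(cl %in% .gap_chars))
  m2 <- m[, !bad, drop = FALSE]
  if (ncol(m2) == 0) warning("all columns removed by no-gaps trimming")
  if (was_strings) {
    out <- apply(m2, 1, paste0, collapse = "")
    if (ncol(m2) == 0) out <- setNames(rep("", nrow(m2)), rownames(m2))
    return(out)
  }
  m2
}

#' Write a supermatrix in relaxed PHYLIP and FASTA formats
#'
#' @param mat named character vector of equal-length sequences.
#' @param phylip_file,fasta_file,partitions_file output paths (`NULL` to
#'   skip).
#' @param record optional `concatenation_record` supplying the partition
#'   table.
#' @return invisibly, the paths written.
#' @export
write_supermatrix <- function(mat, phylip_file = NULL, fasta_file = NULL,
                              partitions_file = NULL, record = NULL) {
  if (!is.null(phylip_file)) {
    writeLines(c(paste(length(mat), nchar(mat[[1]])),
                 paste(format(names(mat), width = 12), mat)),
               phylip_file)
  }
  if (!is.null(fasta_file)) {
    writeLines(as.vector(rbind(paste0(">", names(mat)), mat)), fasta_file)
  }
  if (!is.null(partitions_file) && !is.null(record)) {
    write.table(record$partitions, partitions_file, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(c(phylip_file, fasta_file, partitions_file))
}
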