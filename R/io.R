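## Readers and writers for the external formats the pipeline consumes and
## produces: Newick with support labels (IQ-TREE dialect), FASTA
## alignments, BED-like coordinate and depth TSVs, and deterministic
## output tables.

#' Read gene family trees from Newick files
#'
#' Reads one or many Newick files (support values as internal node
#' labels); multi-tree files are expanded with an index suffix.
#'
#' @param paths character vector of file paths; family ids default to the
#'   file base names.
#' @return named list of `phylo` objects.
#' @export
read_gene_trees <- function(paths) {
  out <- list()
  for (p in paths) {
    tr <- ape::read.tree(p)
    fid <- sub("\\.[^.]*$", "", basename(p))
    if (inherits(tr, "multiPhylo")) {
      for (i in seq_along(tr)) out[[paste0(fid, "_", i)]] <- tr[[i]]
    } else out[[fid]] <- tr
  }
  out
}

#' Read an alignment from a FASTA file
#'
#' @param path FASTA file (amino acid or nucleotide).
#' @return character matrix, rows named by sequence.
#' @export
read_fasta_alignment <- function(path) {
  lines <- readLines(path)
  hd <- grep("^>", lines)
  if (length(hd) == 0) stop("no FASTA records in ", path)
  ends <- c(hd[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hd), function(i)
    paste0(lines[(hd[i] + 1L):ends[i]], collapse = ""), "")
  names(seqs) <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hd]))
  as_aln_matrix(seqs)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences, or a character matrix.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (is.matrix(seqs)) seqs <- apply(seqs, 1, paste0, collapse = "")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  invisible(path)
}

#' Read a BED-like gene coordinate TSV
#'
#' Expects the columns `gene_id`, `species`, `chrom`, `start`, `end`
#' (0-based half-open).
#'
#' @param path TSV file with header.
#' @return data.frame.
#' @export
read_coords <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "species", "chrom", "start", "end")
  if (!all(need %in% names(d)))
    stop("coordinate table must have columns: ", paste(need, collapse = ", "))
  d
}

#' Read a per-gene depth TSV (mosdepth-regions-like)
#'
#' Expects columns `gene_id`, `dataset`, `depth`.
#'
#' @param path TSV file with header.
#' @return data.frame.
#' @export
read_depth_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "dataset", "depth")
  if (!all(need %in% names(d)))
    stop("depth table must have columns: ", paste(need, collapse = ", "))
  d
}

#' Write a deterministic TSV
#'
#' Fixed options (tab separator, no quoting, no row names, `NA` as empty)
#' so identical inputs yield byte-identical files.
#'
#' @param d data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
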