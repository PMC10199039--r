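## Standard genetic code and codon-level utilities shared by the Ks
## estimator and the codon-mode sequence simulator.

.nt <- c("A", "C", "G", "T")

.genetic_code <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

.sense_codons <- names(.genetic_code)[.genetic_code != "*"]

translate_codon <- function(codon) unname(.genetic_code[codon])

## single-nucleotide mutational neighbours of a codon (9 codons incl. stops)
codon_neighbors <- function(codon) {
  s <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) for (b in setdiff(.nt, s[pos])) {
    x <- s; x[pos] <- b
    out <- c(out, paste(x, collapse = ""))
  }
  out
}

## NG86 synonymous site count of a codon: over the 3 positions, the
## fraction of the 3 possible single-nucleotide changes that are
## synonymous; changes creating a stop codon count as nonsynonymous.
syn_sites_codon <- function(codon) {
  aa <- .genetic_code[codon]
  if (is.na(aa) || aa == "*") return(NA_real_)
  nb <- codon_neighbors(codon)
  syn <- .genetic_code[nb] == aa       # stop neighbours are non-synonymous
  sum(syn) / 3
}

.syn_sites_table <- vapply(.sense_codons, syn_sites_codon, numeric(1))

## average syn/nonsyn substitution counts between two codons over all
## minimal substitution pathways; pathways passing through a stop codon
## are excluded (falling back to all pathways if none is stop-free).
codon_path_counts <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
  diffpos <- which(a != b)
  k <- length(diffpos)
  if (k == 0) return(c(syn = 0, nonsyn = 0))
  perms <- permutations_of(diffpos)
  paths <- matrix(0, nrow = length(perms), ncol = 2)
  valid <- rep(TRUE, length(perms))
  for (pi in seq_along(perms)) {
    cur <- a; s <- 0; n <- 0
    for (pos in perms[[pi]]) {
      nxt <- cur; nxt[pos] <- b[pos]
      aa1 <- .genetic_code[paste(cur, collapse = "")]
      aa2 <- .genetic_code[paste(nxt, collapse = "")]
      if (aa2 == "*") valid[pi] <- FALSE
      if (identical(unname(aa1), unname(aa2))) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    paths[pi, ] <- c(s, n)
  }
  ok <- if (any(valid)) valid else rep(TRUE, length(perms))
  c(syn = mean(paths[ok, 1]), nonsyn = mean(paths[ok, 2]))
}

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(permutations_of(x[-i]), function(p) c(x[i], p)))
  out
}

#' Codon substitution model for synonymous-distance simulation
#'
#' Builds a 61-state (sense codons, standard code) reversible substitution
#' model in which single-nucleotide synonymous changes occur at relative
#' rate 1 and nonsynonymous changes at relative rate `omega`, with uniform
#' codon frequencies. The generator is scaled so that one unit of branch
#' length corresponds to one expected synonymous substitution per
#' synonymous (NG86-counted) site, i.e. branch lengths are on the Ks scale.
#'
#' @param omega relative nonsynonymous rate (default 0.2).
#' @return a `subst_model` over the 61 sense codons.
#' @export
codon_model <- function(omega = 0.2) {
  cods <- .sense_codons
  k <- length(cods)
  R <- matrix(0, k, k, dimnames = list(cods, cods))
  for (i in seq_len(k)) {
    nb <- codon_neighbors(cods[i])
    nb <- nb[nb %in% cods]
    for (cb in nb) {
      j <- match(cb, cods)
      R[i, j] <- if (.genetic_code[cods[i]] == .genetic_code[cb]) 1 else omega
    }
  }
  pi <- rep(1 / k, k)
  Q <- R
  diag(Q) <- -rowSums(Q)
  ## synonymous flux per codon vs synonymous sites per codon
  syn_mask <- outer(.genetic_code[cods], .genetic_code[cods], "==")
  syn_rate <- mean(rowSums(R * syn_mask))
  syn_sites <- mean(.syn_sites_table)
  Q <- Q * (syn_sites / syn_rate)
  eig <- eigen((Q + t(Q)) / 2, symmetric = TRUE)
  structure(list(states = cods, freqs = pi,
                 values = eig$values,
                 U = eig$vectors, W = t(eig$vectors)),
            class = "subst_model")
}
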