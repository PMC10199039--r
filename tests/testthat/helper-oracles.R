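## Independent brute-force oracles shared across test files.

## independent brute-force NG86 oracle (recursive pathway enumeration,
## written without reference to the package internals)
oracle_ng86 <- function(a, b) {
  code <- c(TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L",
            CTC = "L", CTA = "L", CTG = "L", ATT = "I", ATC = "I",
            ATA = "I", ATG = "M", GTT = "V", GTC = "V", GTA = "V",
            GTG = "V", TCT = "S", TCC = "S", TCA = "S", TCG = "S",
            CCT = "P", CCC = "P", CCA = "P", CCG = "P", ACT = "T",
            ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
            GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*",
            TAG = "*", CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
            AAT = "N", AAC = "N", AAA = "K", AAG = "K", GAT = "D",
            GAC = "D", GAA = "E", GAG = "E", TGT = "C", TGC = "C",
            TGA = "*", TGG = "W", CGT = "R", CGC = "R", CGA = "R",
            CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
            GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  nts <- c("A", "C", "G", "T")
  syn_sites <- function(cod) {
    s <- strsplit(cod, "")[[1]]; cnt <- 0
    for (p in 1:3) for (n in setdiff(nts, s[p])) {
      x <- s; x[p] <- n
      if (code[paste(x, collapse = "")] == code[cod]) cnt <- cnt + 1
    }
    cnt / 3
  }
  walk <- function(cur, target) {
    dp <- which(cur != target)
    if (length(dp) == 0) return(list(c(0, 0, TRUE)))
    out <- list()
    for (p in dp) {
      nxt <- cur; nxt[p] <- target[p]
      c1 <- code[paste(cur, collapse = "")]
      c2 <- code[paste(nxt, collapse = "")]
      step_s <- as.integer(c1 == c2)
      ok <- c2 != "*"
      for (rest in walk(nxt, target))
        out[[length(out) + 1]] <- c(step_s + rest[1],
                                    (1 - step_s) + rest[2],
                                    ok && rest[3])
    }
    out
  }
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  keep <- code[ca] != "*" & code[cb] != "*" & !is.na(code[ca]) &
    !is.na(code[cb])
  ca <- ca[keep]; cb <- cb[keep]
  S <- (sum(sapply(ca, syn_sites)) + sum(sapply(cb, syn_sites))) / 2
  N <- 3 * length(ca) - S
  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    paths <- walk(strsplit(ca[i], "")[[1]], strsplit(cb[i], "")[[1]])
    pm <- do.call(rbind, paths)
    use <- if (any(pm[, 3] == 1)) pm[pm[, 3] == 1, , drop = FALSE] else pm
    Sd <- Sd + mean(use[, 1]); Nd <- Nd + mean(use[, 2])
  }
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  list(Ks = jc(Sd / S), Ka = jc(Nd / N), S = S, N = N)
}

rand_codon <- function(n) {
  cods <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            c("A", "C", "G", "T")), 1, paste0,
                collapse = "")
  cods <- cods[!cods %in% c("TAA", "TAG", "TGA")]
  paste(sample(cods, n, replace = TRUE), collapse = "")
}

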