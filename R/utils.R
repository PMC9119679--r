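#' @importFrom rlang .data
#' @importFrom stats median optim pnorm qnorm rbinom rexp rnorm rpois runif
#'   sd var weighted.mean plogis predict setNames complete.cases quantile
#' @importFrom utils head tail
NULL

# Amino-acid alphabet; "*" is the stop state and is a legal genotype symbol.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "*")

NT_ALPHABET <- c("A", "C", "G", "T")

# Standard genetic code, codon -> single-letter amino acid.
GENETIC_CODE_1 <- c(
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

# Constant regions flanking barcodes in simulated reads.
MISEQ_CONSTANT <- "GTCAGGTCAG"
HISEQ_CONSTANT <- "ACGGTCTAGC"

#' Translate a coding nucleotide sequence
#'
#' Standard-code translation of an in-frame CDS; stop codons translate to
#' `"*"`.
#'
#' @param cds Nucleotide string whose length is a multiple of 3.
#' @return Amino-acid string (may contain `"*"`).
#' @export
translate_cds <- function(cds) {
  stopifnot(nchar(cds) %% 3 == 0)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- GENETIC_CODE_1[codons]
  if (anyNA(aa)) stop("invalid codon in CDS: ", codons[which(is.na(aa))[1]])
  paste(aa, collapse = "")
}

reverse_complement <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n, width) {
  vapply(seq_len(n), function(i) {
    paste(sample(NT_ALPHABET, width, replace = TRUE), collapse = "")
  }, character(1))
}

# n unique random DNA barcodes; collisions are regenerated, never merged.
unique_barcodes <- function(n, width) {
  bc <- random_dna(n, width)
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- random_dna(length(dup), width)
  }
  bc
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Parse a mutation-set string
#'
#' Mutation sets are written `"A12T:K45E"`: reference state, 1-based
#' position, alternative state, colon-separated and ordered by position.
#' The empty string denotes the unmutated (wildtype) sequence.
#'
#' @param muts Character vector of mutation-set strings.
#' @return List of data frames with columns `site`, `ref`, `alt`.
#' @export
parse_mutations <- function(muts) {
  lapply(muts, function(m) {
    if (is.na(m) || m == "") {
      return(data.frame(site = integer(), ref = character(),
                        alt = character()))
    }
    parts <- strsplit(m, ":", fixed = TRUE)[[1]]
    ok <- grepl("^[A-Z*]\\d+[A-Z*]$", parts)
    if (!all(ok)) stop("malformed mutation token: ", parts[!ok][1])
    data.frame(
      site = as.integer(gsub("[^0-9]", "", parts)),
      ref = substr(parts, 1, 1),
      alt = substring(parts, nchar(parts)))
  })
}

format_mutations <- function(site, ref, alt) {
  if (length(site) == 0) return("")
  o <- order(site)
  paste0(ref[o], site[o], alt[o], collapse = ":")
}

#' Apply a mutation set to a wildtype protein
#'
#' @param wildtype Wildtype amino-acid string.
#' @param muts Character vector of mutation-set strings
#'   (see [parse_mutations()]).
#' @return Character vector of mutated protein sequences.
#' @export
mutate_protein <- function(wildtype, muts) {
  wt <- strsplit(wildtype, "")[[1]]
  parsed <- parse_mutations(muts)
  vapply(parsed, function(p) {
    s <- wt
    if (nrow(p) > 0) {
      bad <- p$site < 1 | p$site > length(wt)
      if (any(bad)) stop("mutation site out of range: ", p$site[bad][1])
      s[p$site] <- p$alt
    }
    paste(s, collapse = "")
  }, character(1))
}

#' Mutation set of a protein relative to a wildtype
#'
#' @param wildtype Wildtype amino-acid string.
#' @param protein Character vector of same-length protein sequences.
#' @return Character vector of mutation-set strings.
#' @export
protein_mutations <- function(wildtype, protein) {
  wt <- strsplit(wildtype, "")[[1]]
  vapply(strsplit(protein, ""), function(p) {
    if (length(p) != length(wt)) stop("protein length differs from wildtype")
    d <- which(p != wt)
    format_mutations(d, wt[d], p[d])
  }, character(1))
}

# Hamming distance between two mutation sets (both relative to the same
# wildtype): number of positions at which the encoded proteins differ.
mutation_set_distance <- function(muts, origin) {
  po <- parse_mutations(origin)[[1]]
  pset <- parse_mutations(muts)
  vapply(pset, function(p) {
    all_sites <- union(p$site, po$site)
    state_a <- setNames(p$alt, p$site)
    state_b <- setNames(po$alt, po$site)
    a <- ifelse(is.na(state_a[as.character(all_sites)]), "",
                state_a[as.character(all_sites)])
    b <- ifelse(is.na(state_b[as.character(all_sites)]), "",
                state_b[as.character(all_sites)])
    sum(a != b)
  }, integer(1))
}

#' Size of protein genotype space at a fixed mutational distance
#'
#' Number of genotypes exactly `distance` substitutions away from a
#' reference of `n_sites` residues, on a log10 scale:
#' `log10(choose(n_sites, distance)) + distance * log10(n_states)`.
#' For a 222-residue protein at distance 48 this evaluates to ~110, the
#' scale of the search space faced when designing distant variants.
#'
#' @param n_sites Number of mutable residues.
#' @param distance Number of substitutions.
#' @param n_states Alternative states per site (default 19).
#' @return log10 of the number of genotypes.
#' @export
genotype_space_log10 <- function(n_sites, distance, n_states = 19) {
  lchoose(n_sites, distance) / log(10) + distance * log10(n_states)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
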