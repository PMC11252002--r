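# Standard genetic code lookups shared by every module. All codon tables are
# keyed by the 61 sense codons; stop codons never enter content denominators.

.GC <- Biostrings::GENETIC_CODE

STOP_CODONS <- names(.GC)[.GC == "*"]
SENSE_CODONS <- names(.GC)[.GC != "*"]

AA_1TO3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val"
)

# three-letter amino acid of each sense codon
CODON_AA <- unname(AA_1TO3[.GC[SENSE_CODONS]])
names(CODON_AA) <- SENSE_CODONS

AMINO_ACIDS <- sort(unique(CODON_AA))

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 sense codons, alphabetical.
#' @export
sense_codons <- function() SENSE_CODONS

#' Stop codons of the standard genetic code
#'
#' @return Character vector `c("TAA", "TAG", "TGA")`.
#' @export
stop_codons <- function() STOP_CODONS

#' Amino acids (three-letter codes)
#'
#' @return Character vector of the 20 amino acids, alphabetical.
#' @export
amino_acids <- function() AMINO_ACIDS

#' Translate sense codons to amino acids
#'
#' @param codon Character vector of codons (ACGT alphabet, length 3).
#' @return Three-letter amino-acid codes; `NA` for stop codons.
#' @export
#' @examples
#' codon_to_aa(c("GTG", "ATG"))
codon_to_aa <- function(codon) {
  unname(CODON_AA[toupper(codon)])
}

#' Map codons to the anticodon of the decoding tRNA
#'
#' Strict Watson-Crick pairing: the anticodon is the reverse complement of
#' the codon (GTG -> CAC). Wobble decoding rules are deliberately not
#' applied; isoacceptor concordance is assessed against the exact cognate
#' anticodon only.
#'
#' @param codon Character vector of codons.
#' @return Character vector of anticodons, read 5' to 3'.
#' @export
#' @examples
#' codon_to_anticodon("GTG") # "CAC"
codon_to_anticodon <- function(codon) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(toupper(codon), ""), function(x) {
    paste(rev(unname(comp[x])), collapse = "")
  }, character(1))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Derive independent per-unit seeds from one top-level seed so that results
# do not depend on iteration order. Kept below 2^31.
split_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
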