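## Genetic-code tables and codon utilities shared by the Ka/Ks, codon-model
## and physicochemical modules.

BASES <- c("T", "C", "A", "G")

.codon_order <- function() {
  # 64 codons, first base slowest, in T,C,A,G order
  paste0(rep(BASES, each = 16), rep(rep(BASES, each = 4), 4), rep(BASES, 16))
}

# standard code in TCAG order
.STD_AA <- strsplit(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", ""
)[[1]]

#' Genetic-code table
#'
#' Returns a named character vector mapping the 64 DNA codons to one-letter
#' amino acids, with `*` marking stop codons.
#'
#' @param code `"vertebrate_mito"` (NCBI translation table 2, the default for
#'   mitogenome work) or `"standard"` (table 1).
#' @return Named character vector of length 64.
#' @export
#' @examples
#' genetic_code("vertebrate_mito")[["TGA"]]  # "W"
genetic_code <- function(code = c("vertebrate_mito", "standard")) {
  code <- match.arg(code)
  aa <- .STD_AA
  names(aa) <- .codon_order()
  if (code == "vertebrate_mito") {
    aa[["ATA"]] <- "M"
    aa[["TGA"]] <- "W"
    aa[["AGA"]] <- "*"
    aa[["AGG"]] <- "*"
  }
  aa
}

#' Sense codons of a genetic code
#' @param code_table output of [genetic_code()]
#' @return character vector of codons whose translation is not `*`
#' @export
sense_codons <- function(code_table) names(code_table)[code_table != "*"]

#' Translate codons
#' @param codons character vector of 3-letter DNA codons (T alphabet)
#' @param code_table output of [genetic_code()]
#' @return amino acids; `NA` for codons containing gaps or ambiguity codes
#' @export
translate_codons <- function(codons, code_table = genetic_code()) {
  out <- unname(code_table[codons])
  out
}

.is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

#' Single-nucleotide codon neighbors
#'
#' All codons reachable from `codon` by one nucleotide change.
#'
#' @param codon 3-letter codon
#' @return data.frame with columns `to`, `pos` (1-3), `from_nt`, `to_nt`,
#'   `transition` (logical)
#' @keywords internal
codon_neighbors <- function(codon) {
  nts <- strsplit(codon, "")[[1]]
  out <- vector("list", 9L)
  k <- 0L
  for (pos in 1:3) {
    for (b in BASES) {
      if (b == nts[pos]) next
      alt <- nts
      alt[pos] <- b
      k <- k + 1L
      out[[k]] <- data.frame(
        to = paste(alt, collapse = ""), pos = pos,
        from_nt = nts[pos], to_nt = b,
        transition = .is_transition(nts[pos], b),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' All single-step nonsynonymous neighbor pairs of a genetic code
#'
#' Unordered pairs of sense codons one nucleotide apart whose translations
#' differ. This is the neutral mutational opportunity set used as the
#' expectation in the physicochemical z-tests.
#'
#' @param code_table output of [genetic_code()]
#' @return data.frame with columns `from`, `to`, `aa_from`, `aa_to`
#' @export
nonsyn_neighbor_pairs <- function(code_table = genetic_code()) {
  sense <- sense_codons(code_table)
  rows <- list()
  for (cd in sense) {
    nb <- codon_neighbors(cd)
    nb <- nb[nb$to %in% sense & cd < nb$to, , drop = FALSE]
    if (!nrow(nb)) next
    keep <- code_table[cd] != code_table[nb$to]
    nb <- nb[keep, , drop = FALSE]
    if (!nrow(nb)) next
    rows[[cd]] <- data.frame(
      from = cd, to = nb$to,
      aa_from = unname(code_table[cd]), aa_to = unname(code_table[nb$to]),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

REV_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-", U = "A")

#' Reverse complement of a DNA string
#' @param x character scalar over A,C,G,T,N,-
#' @return reverse complement
#' @export
rev_comp <- function(x) {
  chars <- strsplit(x, "")[[1]]
  paste(rev(unname(REV_COMP[chars])), collapse = "")
}
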