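## Alignment IO and coordinate plumbing. Coordinates are 0-based half-open
## internally; all user-facing reports are 1-based inclusive.

#' Construct a multiple alignment
#'
#' @param seqs named character vector of equal-length sequences (names are
#'   sequence ids) over the alphabet `A,C,G,T,N,-`. Lower case and `U` are
#'   normalized to upper case and `T`.
#' @param metadata optional named list of per-sequence annotations (e.g. a
#'   `region` character vector aligned with `ids`).
#' @return object of class `mito_aln` with fields `ids`, `seqs`, `length`,
#'   `metadata`.
#' @export
new_alignment <- function(seqs, metadata = list()) {
  if (length(seqs) == 0) stop("empty alignment: no sequences", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids) || any(ids == "")) stop("all sequences must be named", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: row lengths differ (", paste(unique(lens), collapse = ", "),
         ")", call. = FALSE)
  }
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    stop("sequence(s) contain characters outside {A,C,G,T,N,-}: ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  structure(
    list(ids = unname(ids), seqs = setNames(unname(seqs), ids),
         length = unname(lens[1]), metadata = metadata),
    class = "mito_aln"
  )
}

#' @export
print.mito_aln <- function(x, ...) {
  cat(sprintf("<mito_aln> %d sequences x %d columns\n", length(x$ids), x$length))
  invisible(x)
}

#' Alignment as a character matrix
#' @param aln a `mito_aln`
#' @return character matrix, rows = sequences (named), columns = positions
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- aln$ids
  m
}

#' Character matrix back to alignment
#' @param m character matrix with rownames
#' @param metadata optional metadata list
#' @return `mito_aln`
#' @export
aln_from_matrix <- function(m, metadata = list()) {
  seqs <- apply(m, 1, paste, collapse = "")
  names(seqs) <- rownames(m)
  new_alignment(seqs, metadata)
}

#' Read an aligned FASTA file
#'
#' Records are case-folded to upper case and `U` mapped to `T`. Empty files,
#' duplicate ids and ragged row lengths raise distinct errors.
#'
#' @param path FASTA file
#' @return a [new_alignment()] object
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty file: no FASTA records in ", path, call. = FALSE)
  seqs <- as.character(set)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  new_alignment(seqs)
}

#' Write an alignment as FASTA
#' @param aln a `mito_aln`
#' @param path output path
#' @param width line width
#' @return `path`, invisibly
#' @export
write_fasta <- function(aln, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in aln$ids) {
    writeLines(paste0(">", id), con)
    s <- aln$seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a gene partition table
#'
#' TSV with header `name start end strand frame`; `start`/`end` are 0-based
#' half-open on the alignment, `strand` is `+`/`-`, `frame` the 0-based frame
#' offset for protein-coding entries.
#'
#' @param path TSV file
#' @param aln_length optional alignment length to validate spans against
#' @return data.frame of class `gene_partition_table`
#' @export
read_partition_table <- function(path, aln_length = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("name", "start", "end", "strand", "frame")
  missing <- setdiff(required, names(tab))
  if (length(missing)) stop("partition table missing column(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  validate_partition_table(tab, aln_length)
}

#' Validate a partition table
#' @param tab data.frame with columns name,start,end,strand,frame
#' @param aln_length optional alignment length
#' @return the table, classed `gene_partition_table`
#' @export
validate_partition_table <- function(tab, aln_length = NULL) {
  if (anyDuplicated(tab$name)) stop("duplicate partition name(s)", call. = FALSE)
  if (any(tab$start < 0) || any(tab$start >= tab$end)) {
    stop("partition spans must satisfy 0 <= start < end", call. = FALSE)
  }
  if (!is.null(aln_length) && any(tab$end > aln_length)) {
    stop("partition end beyond alignment length", call. = FALSE)
  }
  if (!all(tab$strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
  class(tab) <- c("gene_partition_table", "data.frame")
  tab
}

#' Slice one partition out of an alignment
#'
#' Returns the columns `[start, end)` of the named entry, reverse-complemented
#' when the entry is on the `-` strand.
#'
#' @param aln a `mito_aln`
#' @param part a partition table (see [read_partition_table()])
#' @param name partition name
#' @return a `mito_aln` over the sliced columns
#' @export
slice_partition <- function(aln, part, name) {
  i <- match(name, part$name)
  if (is.na(i)) stop("unknown partition: ", name, call. = FALSE)
  start <- part$start[i]; end <- part$end[i]
  if (end > aln$length) stop("partition '", name, "' extends beyond alignment", call. = FALSE)
  sub <- substring(aln$seqs, start + 1L, end)
  if (part$strand[i] == "-") sub <- vapply(sub, rev_comp, character(1))
  names(sub) <- aln$ids
  new_alignment(sub, aln$metadata)
}

#' Codon-partition view of an alignment
#'
#' Splits an in-frame alignment into codon columns with per-codon amino-acid
#' translation. Codons containing `-` or `N` are flagged ambiguous (NA
#' translation). A terminal stop codon shared by all rows is trimmed when
#' `trim_stop = TRUE`.
#'
#' @param aln in-frame `mito_aln` (apply the partition's frame offset first)
#' @param code_table genetic code, default vertebrate mitochondrial
#' @param trim_stop drop a terminal all-row stop codon
#' @return object of class `codon_aln`: list with `ids`, `codons` (n x
#'   n_codons character matrix), `aa` (translations, NA when ambiguous),
#'   `n_codons`, `code_table`
#' @export
to_codon_alignment <- function(aln, code_table = genetic_code(), trim_stop = TRUE) {
  if (aln$length %% 3 != 0) {
    stop("alignment length ", aln$length, " is not divisible by 3", call. = FALSE)
  }
  m <- aln_matrix(aln)
  nc <- aln$length %/% 3
  codons <- matrix("", nrow = nrow(m), ncol = nc, dimnames = list(aln$ids, NULL))
  for (j in seq_len(nc)) {
    codons[, j] <- paste0(m[, 3 * j - 2], m[, 3 * j - 1], m[, 3 * j])
  }
  if (trim_stop && nc > 0) {
    last <- codons[, nc]
    tr <- code_table[last]
    if (all(!is.na(tr) & tr == "*")) {
      codons <- codons[, -nc, drop = FALSE]
      nc <- nc - 1L
    }
  }
  aa <- matrix(code_table[codons], nrow = nrow(codons), dimnames = dimnames(codons))
  aa[grepl("[N-]", codons)] <- NA_character_
  structure(
    list(ids = aln$ids, codons = codons, aa = aa, n_codons = nc,
         code_table = code_table, metadata = aln$metadata),
    class = "codon_aln"
  )
}

#' @export
print.codon_aln <- function(x, ...) {
  cat(sprintf("<codon_aln> %d sequences x %d codons\n", length(x$ids), x$n_codons))
  invisible(x)
}

#' Flatten a codon alignment back to nucleotides
#' @param caln a `codon_aln`
#' @return a `mito_aln`
#' @export
codon_to_nucleotide <- function(caln) {
  seqs <- apply(caln$codons, 1, paste, collapse = "")
  names(seqs) <- caln$ids
  new_alignment(seqs, caln$metadata)
}

#' Read a Newick tree
#' @param path Newick file
#' @return an `ape::phylo`
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Check that tree leaves and alignment ids agree
#' @param tree `ape::phylo`
#' @param ids character vector of alignment ids
#' @return TRUE invisibly; error otherwise
#' @export
check_tree_matches <- function(tree, ids) {
  if (!setequal(tree$tip.label, ids)) {
    stop("tree leaf set does not match alignment ids; missing from tree: ",
         paste(setdiff(ids, tree$tip.label), collapse = ", "),
         "; extra in tree: ",
         paste(setdiff(tree$tip.label, ids), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
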