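## Non-coding control-region analysis: tandem-repeat detection and Type 1/2/3
## classification, TAS/CSB/poly-A motif localization, secondary-structure
## folding (pair-maximization oracle and energy-minimization DP), and
## paired-vs-unpaired conservation statistics. All reported coordinates are
## 1-based inclusive.

#' Load the motif configuration
#' @param path TSV (`name`, `pattern`, `max_mismatch`); default the packaged
#'   template config
#' @return data.frame
#' @export
read_motif_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "motifs_default.tsv", package = "mitoscan")
  }
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Load a repeat-unit catalog
#' @param path FASTA of consensus units; default the packaged synthetic catalog
#' @return named character vector
#' @export
read_unit_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "unit_catalog_synthetic.fasta",
                        package = "mitoscan")
  }
  set <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

## ---- tandem repeats ------------------------------------------------------

# identity of a candidate unit against a consensus, aligned at offset 0 over
# the shorter length
.unit_identity <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  l <- min(la, lb)
  if (l == 0) return(0)
  xa <- strsplit(substr(a, 1, l), "")[[1]]
  xb <- strsplit(substr(b, 1, l), "")[[1]]
  mean(xa == xb) * l / max(la, lb)
}

#' Detect tandem repeats in a sequence
#'
#' De-novo detection by period-restricted self-comparison: for each lag `p`
#' in `[min_period, max_period]` the sequence is compared with itself shifted
#' by `p`; runs where the windowed identity reaches `min_identity` with at
#' least one full extra copy are reported, with partial terminal copies
#' extended base by base. Single-copy units carry no self-evidence and are
#' found only by scanning a consensus-unit catalog at `catalog_identity`.
#'
#' @param seq character scalar (DNA)
#' @param min_period,max_period period range in bp (defaults 36-42)
#' @param min_identity unit-vs-unit identity to accept a de-novo hit (0.8)
#' @param catalog optional named vector of consensus units for single-copy
#'   detection
#' @param catalog_identity identity threshold for catalog hits (0.85)
#' @return data.frame: start, end (1-based inclusive), period, copies
#'   (possibly fractional), unit (consensus), identity, source
#' @export
detect_tandem_repeats <- function(seq, min_period = 36, max_period = 42,
                                  min_identity = 0.8, catalog = NULL,
                                  catalog_identity = 0.85) {
  seq <- toupper(seq)
  x <- strsplit(seq, "")[[1]]
  L <- length(x)
  cands <- list()
  if (L >= 2 * min_period) {
    for (p in min_period:min(max_period, floor(L / 2))) {
      v <- x[seq_len(L - p)] == x[(p + 1):L]
      nw <- L - 2 * p + 1
      if (nw < 1) next
      cs <- c(0, cumsum(v))
      idw <- (cs[(p + 1):(L - p + 1)] - cs[1:nw]) / p
      hit <- idw >= min_identity
      if (!any(hit)) next
      # merge runs of passing windows
      r <- rle(hit)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        s0 <- starts[k]; e0 <- ends[k]
        span_s <- s0
        nfull0 <- max(1, floor((e0 - s0 + 2 * p) / p))
        seg0 <- matrix(x[span_s:min(span_s + nfull0 * p - 1, L)], nrow = p)
        cons <- apply(seg0, 1, function(col) names(which.max(table(col))))
        # refine: anchor the first copy on the consensus, then count
        # consecutive near-matching copies plus a partial terminal copy
        offs <- max(1, s0 - p):min(L - p + 1, s0 + p)
        ids <- vapply(offs, function(o) mean(x[o:(o + p - 1)] == cons),
                      numeric(1))
        s_best <- offs[which.max(ids)]
        while (s_best - p >= 1 &&
               mean(x[(s_best - p):(s_best - 1)] == cons) >= min_identity) {
          s_best <- s_best - p
        }
        nfull <- 0L; pos <- s_best
        while (pos + p - 1 <= L &&
               mean(x[pos:(pos + p - 1)] == cons) >= min_identity) {
          nfull <- nfull + 1L; pos <- pos + p
        }
        if (nfull == 0) next
        partial <- 0L
        while (pos + partial <= L && partial < p &&
               x[pos + partial] == cons[partial + 1]) {
          partial <- partial + 1L
        }
        span_s <- s_best
        span_e <- pos + partial - 1L
        copies <- nfull + partial / p
        seg <- matrix(x[span_s:(span_s + nfull * p - 1)], nrow = p)
        cons <- apply(seg, 1, function(col) names(which.max(table(col))))
        unit <- paste(cons, collapse = "")
        idty <- mean(vapply(seq_len(nfull), function(ci) {
          mean(seg[, ci] == cons)
        }, numeric(1)))
        cands[[length(cands) + 1]] <- data.frame(
          start = span_s, end = span_e, period = p, copies = round(copies, 2),
          unit = unit, identity = idty, source = "denovo",
          stringsAsFactors = FALSE)
      }
    }
  }
  # catalog scan for single-copy units
  if (!is.null(catalog)) {
    for (uname in names(catalog)) {
      u <- strsplit(toupper(catalog[[uname]]), "")[[1]]
      lu <- length(u)
      if (L < lu) next
      best <- NULL
      for (off in 0:(L - lu)) {
        idty <- mean(x[(off + 1):(off + lu)] == u)
        if (idty >= catalog_identity &&
            (is.null(best) || idty > best$identity)) {
          best <- data.frame(
            start = off + 1, end = off + lu, period = lu, copies = 1,
            unit = paste(x[(off + 1):(off + lu)], collapse = ""),
            identity = idty, source = paste0("catalog:", uname),
            stringsAsFactors = FALSE)
        }
      }
      if (!is.null(best)) cands[[length(cands) + 1]] <- best
    }
  }
  if (!length(cands)) {
    return(data.frame(start = integer(0), end = integer(0), period = integer(0),
                      copies = numeric(0), unit = character(0),
                      identity = numeric(0), source = character(0)))
  }
  all <- do.call(rbind, cands)
  # greedy selection of non-overlapping annotations, best-supported first;
  # de-novo multi-copy evidence beats a single-copy catalog hit on overlap
  score <- (all$end - all$start + 1) * all$identity
  all <- all[order(-score), , drop = FALSE]
  keep <- rep(FALSE, nrow(all))
  occupied <- rep(FALSE, L)
  for (i in seq_len(nrow(all))) {
    span <- all$start[i]:all$end[i]
    if (mean(occupied[span]) < 0.2) {
      keep[i] <- TRUE
      occupied[span] <- TRUE
    }
  }
  out <- all[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a repeat annotation into copy-number types
#'
#' Type label is the copy number rounded half-down (1 -> "Type 1", ...);
#' copies above 3.5 yield "Type >3 (unclassified)". The subtype is the
#' nearest catalog unit at >= 85% identity, else "novel".
#'
#' @param annotation one row of [detect_tandem_repeats()] output
#' @param unit_catalog named vector of consensus units
#' @return list: type, subtype, copies, partial_copy (note flag)
#' @export
classify_repeat_type <- function(annotation, unit_catalog = read_unit_catalog()) {
  copies <- annotation$copies
  n <- ceiling(copies - 0.5) # round half-down
  n <- max(n, 1)
  type <- if (n > 3) "Type >3 (unclassified)" else paste("Type", n)
  # a tandem array has no canonical phase: match the unit over all rotations
  u <- annotation$unit
  rots <- vapply(seq_len(nchar(u)), function(r) {
    paste0(substr(u, r, nchar(u)), substr(u, 1, r - 1))
  }, character(1))
  ids <- vapply(unit_catalog, function(cu) {
    max(vapply(rots, .unit_identity, numeric(1), b = cu))
  }, numeric(1))
  subtype <- if (length(ids) && max(ids) >= 0.85) names(unit_catalog)[which.max(ids)]
  else "novel"
  list(type = type, subtype = subtype, copies = copies,
       partial_copy = abs(copies - n) > 0.1)
}

## ---- motifs --------------------------------------------------------------

#' Annotate conserved motifs and the poly-A tract
#'
#' Each configured IUPAC motif is searched at increasing mismatch counts up
#' to its `max_mismatch`; the leftmost hit at the smallest count wins. The
#' poly-A tract is the longest A-homopolymer of at least `polya_min` bases.
#'
#' @param seq character scalar (DNA)
#' @param motif_config data.frame from [read_motif_config()]
#' @param polya_min minimum poly-A length (default 6)
#' @return data.frame: name, start, end (1-based; NA when not found),
#'   mismatches, found
#' @export
annotate_motifs <- function(seq, motif_config = read_motif_config(),
                            polya_min = 6) {
  seq <- toupper(seq)
  subject <- Biostrings::DNAString(seq)
  rows <- list()
  for (i in seq_len(nrow(motif_config))) {
    nm <- motif_config$name[i]
    pat <- motif_config$pattern[i]
    mm_max <- motif_config$max_mismatch[i]
    hit <- NULL
    for (mm in 0:mm_max) {
      m <- Biostrings::matchPattern(pat, subject, max.mismatch = mm,
                                    fixed = FALSE)
      if (length(m) > 0) {
        hit <- data.frame(name = nm, start = Biostrings::start(m)[1],
                          end = Biostrings::end(m)[1], mismatches = mm,
                          found = TRUE, stringsAsFactors = FALSE)
        break
      }
    }
    if (is.null(hit)) {
      hit <- data.frame(name = nm, start = NA_integer_, end = NA_integer_,
                        mismatches = NA_integer_, found = FALSE,
                        stringsAsFactors = FALSE)
    }
    rows[[i]] <- hit
  }
  # poly-A: longest A homopolymer >= threshold (leftmost on ties)
  runs <- gregexpr(paste0("A{", polya_min, ",}"), seq)[[1]]
  if (runs[1] != -1) {
    lens <- attr(runs, "match.length")
    j <- which.max(lens)
    rows[[length(rows) + 1]] <- data.frame(
      name = "poly_A", start = runs[j], end = runs[j] + lens[j] - 1,
      mismatches = 0L, found = TRUE, stringsAsFactors = FALSE)
  } else {
    rows[[length(rows) + 1]] <- data.frame(
      name = "poly_A", start = NA_integer_, end = NA_integer_,
      mismatches = NA_integer_, found = FALSE, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

## ---- secondary structure -------------------------------------------------

.check_foldable <- function(seq) {
  s <- chartr("Tt", "Uu", toupper(seq))
  if (grepl("[^ACGU]", s)) {
    stop("sequence contains non-ACGU characters after T->U mapping",
         call. = FALSE)
  }
  s
}

.dot_bracket <- function(pairs) {
  db <- rep(".", length(pairs))
  paired <- which(!is.na(pairs))
  db[paired[pairs[paired] > paired]] <- "("
  db[paired[pairs[paired] < paired]] <- ")"
  paste(db, collapse = "")
}

.structure_obj <- function(seq, pairs0, energy) {
  pairs <- ifelse(pairs0 < 0, NA_integer_, pairs0 + 1L)
  structure(
    list(structure = .dot_bracket(pairs), pairs = pairs,
         n_pairs = sum(!is.na(pairs)) / 2, energy = energy,
         length = nchar(seq), seq = seq,
         dG_per_length = if (nchar(seq) > 0) energy / nchar(seq) else 0),
    class = "secondary_structure"
  )
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(x$seq, "\n", x$structure, "\n", sep = "")
  cat(sprintf("pairs=%d dG=%.2f kcal/mol dG/length=%.4f\n",
              x$n_pairs, x$energy, x$dG_per_length))
  invisible(x)
}

#' Pair-maximization folding (Nussinov)
#'
#' Maximizes Watson-Crick + GU pairs with a minimum hairpin loop of 3,
#' deterministic traceback (smallest pairing index first). Serves as the
#' combinatorial oracle for the energy folder.
#'
#' @param seq DNA/RNA string
#' @return `secondary_structure` (energy field NA)
#' @export
fold_nussinov <- function(seq) {
  s <- .check_foldable(seq)
  res <- .nussinov_cpp(s)
  out <- .structure_obj(s, res$pairs, NA_real_)
  out$dG_per_length <- NA_real_
  out
}

#' Load folding energy parameters
#' @param type `"rna"` or `"dna"`, or a path to a parameter TSV
#' @return list: `stack` (3x3 matrix over GC/AU/GU pair types), `hairpin`,
#'   `bulge`, `internal` (penalty by loop size, log-extrapolated beyond the
#'   tabulated sizes), `multibranch` (a, b, c)
#' @export
load_energy_params <- function(type = c("rna", "dna")) {
  path <- if (file.exists(type[1])) type[1] else {
    type <- match.arg(type)
    system.file("extdata", paste0("energy_params_", type, ".tsv"),
                package = "mitoscan")
  }
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character",
                                   "numeric"))
  types <- c("GC", "AU", "GU")
  stack <- matrix(NA_real_, 3, 3, dimnames = list(types, types))
  st <- tab[tab$type == "stack", ]
  for (i in seq_len(nrow(st))) {
    stack[st$key1[i], st$key2[i]] <- st$value[i]
    stack[st$key2[i], st$key1[i]] <- st$value[i]
  }
  lxc <- tab$value[tab$type == "lxc"][1]
  grab <- function(kind, min_size, max_size = 300) {
    sub <- tab[tab$type == kind, ]
    sizes <- as.integer(sub$key1)
    v <- rep(NA_real_, max_size + 1) # index = size + 1 in R, size in C++
    v[sizes + 1] <- sub$value
    mx <- max(sizes)
    for (s in (mx + 1):max_size) v[s + 1] <- v[mx + 1] + lxc * log(s / mx)
    # fill any gaps below by interpolation
    for (s in min_size:max_size) if (is.na(v[s + 1])) v[s + 1] <- v[s]
    v[seq_len(min_size)] <- 1e9 # impossible sizes
    v
  }
  list(stack = stack, hairpin = grab("hairpin", 3),
       bulge = grab("bulge", 1), internal = grab("internal", 2),
       multibranch = setNames(
         tab$value[tab$type == "multibranch"][match(c("a", "b", "c"),
           tab$key1[tab$type == "multibranch"])], c("a", "b", "c")))
}

#' Minimum-free-energy folding
#'
#' Zuker-style dynamic program over hairpins, stacks, bounded internal/bulge
#' loops (<= 30 unpaired) and affine multibranch loops, using the packaged
#' simplified nearest-neighbour parameters. Returns 0 (open chain) when no
#' negative-energy structure exists.
#'
#' @param seq DNA/RNA string (T mapped to U)
#' @param params parameter list from [load_energy_params()], or `"rna"` /
#'   `"dna"`
#' @return `secondary_structure` with `energy` (kcal/mol) and `dG_per_length`
#' @export
fold_min_energy <- function(seq, params = "rna") {
  s <- .check_foldable(seq)
  if (is.character(params)) params <- load_energy_params(params)
  res <- .zuker_cpp(s, params)
  .structure_obj(s, res$pairs, res$energy)
}

#' Score a fixed structure under the energy model
#' @param seq sequence
#' @param pairs 1-based partner vector (NA = unpaired)
#' @param params energy parameters
#' @return total free energy (kcal/mol)
#' @export
score_structure <- function(seq, pairs, params = "rna") {
  s <- .check_foldable(seq)
  if (is.character(params)) params <- load_energy_params(params)
  p0 <- ifelse(is.na(pairs), -1L, as.integer(pairs) - 1L)
  .score_structure_cpp(s, p0, params)
}

#' Length-normalized folding free energy
#' @param struct a `secondary_structure`
#' @return dG / length (kcal/mol/nt)
#' @export
relative_free_energy <- function(struct) {
  if (struct$length == 0) stop("empty sequence", call. = FALSE)
  struct$energy / struct$length
}

#' Substitution rates at paired vs unpaired sites
#'
#' Partitions alignment columns by the paired/unpaired status of a reference
#' row's structure and compares per-site substitution rates (distinct valid
#' states minus one per column) with a two-proportion test on the
#' variable-column fractions.
#'
#' @param aln a `mito_aln` over the folded region
#' @param struct `secondary_structure` of the reference row (ungapped
#'   coordinates of that row)
#' @param ref the reference row id or index (default 1)
#' @return list: rate_paired, rate_unpaired, ratio, n_paired, n_unpaired,
#'   p_value
#' @export
paired_site_conservation <- function(aln, struct, ref = 1) {
  m <- aln_matrix(aln)
  if (is.character(ref)) ref <- match(ref, aln$ids)
  refseq <- m[ref, ]
  ref_pos <- which(refseq != "-")
  if (length(ref_pos) != struct$length) {
    stop("structure length (", struct$length,
         ") does not match ungapped reference length (", length(ref_pos), ")",
         call. = FALSE)
  }
  paired <- !is.na(struct$pairs)
  changes <- apply(m[, ref_pos, drop = FALSE], 2, function(col) {
    max(length(unique(col[col %in% VALID_NT])) - 1, 0)
  })
  n_p <- sum(paired); n_u <- sum(!paired)
  ch_p <- sum(changes[paired]); ch_u <- sum(changes[!paired])
  rate_p <- if (n_p > 0) ch_p / n_p else 0
  rate_u <- if (n_u > 0) ch_u / n_u else 0
  pv <- NA_real_
  var_p <- sum(changes[paired] > 0); var_u <- sum(changes[!paired] > 0)
  if (n_p > 0 && n_u > 0) {
    pv <- suppressWarnings(prop.test(c(var_p, var_u), c(n_p, n_u))$p.value)
  }
  list(rate_paired = rate_p, rate_unpaired = rate_u,
       ratio = if (rate_u > 0) rate_p / rate_u else NA_real_,
       n_paired = n_p, n_unpaired = n_u, p_value = pv)
}

#' Tajima's D over window spans of an alignment
#'
#' Delegates to [tajimas_d()] on column slices (e.g. the TAS span, CSB spans,
#' the repeat span, the whole region).
#'
#' @param aln a `mito_aln`
#' @param spans data.frame with `name`, `start`, `end` (0-based half-open)
#' @param policy deletion policy
#' @return data.frame: name, start, end, S, D, label
#' @export
region_tajima_d <- function(aln, spans, policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  rows <- lapply(seq_len(nrow(spans)), function(i) {
    s <- spans$start[i]; e <- spans$end[i]
    if (s < 0 || e > aln$length || s >= e) {
      stop("span '", spans$name[i], "' outside alignment", call. = FALSE)
    }
    sub <- substring(aln$seqs, s + 1L, e)
    names(sub) <- aln$ids
    td <- tajimas_d(new_alignment(sub), policy)
    data.frame(name = spans$name[i], start = s + 1L, end = e, S = td$S,
               D = td$D, label = if (is.null(td$label)) NA else td$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
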