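## Physicochemical-shift analysis of inferred amino-acid replacements:
## parsimony ancestral reconstruction, 8-bin magnitude classification per
## property, and z-tests against the genetic code's single-step mutational
## expectation.

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Load an amino-acid property table
#'
#' The packaged default ships 31 physicochemical scales (one row per amino
#' acid); see the file header for per-column provenance.
#'
#' @param path TSV path; default the packaged table
#' @return data.frame with rownames = one-letter amino acids, one numeric
#'   column per property
#' @export
read_aa_properties <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_properties.tsv", package = "mitoscan")
  }
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"aa" %in% names(tab)) stop("property table needs an 'aa' column", call. = FALSE)
  rownames(tab) <- tab$aa
  tab$aa <- NULL
  missing <- setdiff(AA_LETTERS, rownames(tab))
  if (length(missing)) {
    stop("property table missing amino acid(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab[AA_LETTERS, , drop = FALSE]
}

#' Magnitude category of an amino-acid replacement
#'
#' |delta property| mapped onto 8 equal-width bins spanning the property's
#' maximum achievable |delta| over all residue pairs; category 1 is the most
#' conservative, 8 the most radical. Symmetric in its arguments.
#'
#' @param props property table from [read_aa_properties()]
#' @param from_aa,to_aa one-letter amino acids
#' @param property column name in `props`
#' @return integer category in 1..8
#' @export
categorize_change <- function(props, from_aa, to_aa, property) {
  if (!property %in% names(props)) stop("unknown property: ", property, call. = FALSE)
  v <- props[[property]]
  names(v) <- rownames(props)
  if (!from_aa %in% names(v) || !to_aa %in% names(v)) {
    stop("unknown residue: ", from_aa, " or ", to_aa, call. = FALSE)
  }
  maxd <- diff(range(v))
  if (maxd == 0) return(1L)
  d <- abs(v[from_aa] - v[to_aa])
  cat <- ceiling(d / maxd * 8)
  as.integer(min(max(cat, 1L), 8L))
}

## ---- Fitch parsimony ----------------------------------------------------

# root an (possibly unrooted) tree on the first tip's edge so the topology is
# binary-rooted; parsimony change counts are invariant to root placement
.rooted_binary <- function(tree) {
  tr <- tree
  if (!ape::is.rooted(tr)) {
    tr <- ape::root(tr, outgroup = tr$tip.label[1], resolve.root = TRUE)
  }
  if (!ape::is.binary(tr)) tr <- ape::multi2di(tr)
  tr
}

#' Fitch-parsimony ancestral replacements
#'
#' Down-pass/up-pass Fitch parsimony per site on an amino-acid alignment;
#' ties in the minimum-change assignment are resolved deterministically
#' (lexicographically smallest amino acid) and recorded. Ambiguous leaves
#' (NA) are treated as missing per site.
#'
#' @param tree `ape::phylo`; leaf labels must match `rownames(aa_mat)`
#' @param aa_mat character matrix of amino acids (rows = sequences, columns =
#'   sites); NA for ambiguous residues
#' @return list of class `fitch_changes`: `changes` data.frame (site, edge,
#'   parent_node, child_node, from, to), `n_changes` per-site minimum change
#'   counts, `ties` per-site tie indicator, `tree` (the rooted copy used)
#' @export
fitch_ancestral_changes <- function(tree, aa_mat) {
  if (!setequal(tree$tip.label, rownames(aa_mat))) {
    stop("tree leaves do not match alignment rows", call. = FALSE)
  }
  tr <- .rooted_binary(tree)
  po <- stats::reorder(tr, "postorder")
  ntip <- length(po$tip.label)
  nn <- ntip + po$Nnode
  aa_mat <- aa_mat[po$tip.label, , drop = FALSE]
  nsites <- ncol(aa_mat)

  changes <- list()
  n_changes <- integer(nsites)
  ties <- logical(nsites)

  for (s in seq_len(nsites)) {
    col <- aa_mat[, s]
    lv <- sort(unique(col[!is.na(col)]))
    if (length(lv) <= 1) next
    k <- length(lv)
    sets <- matrix(FALSE, nrow = nn, ncol = k)
    for (i in seq_len(ntip)) {
      if (is.na(col[i])) sets[i, ] <- TRUE else sets[i, match(col[i], lv)] <- TRUE
    }
    seen <- logical(nn)
    cnt <- 0L
    tie <- FALSE
    # down-pass (postorder): binary nodes combine children by
    # intersection-else-union
    for (e in seq_len(nrow(po$edge))) {
      parent <- po$edge[e, 1]; child <- po$edge[e, 2]
      cs <- sets[child, ]
      if (!seen[parent]) {
        sets[parent, ] <- cs
        seen[parent] <- TRUE
      } else {
        inter <- sets[parent, ] & cs
        if (any(inter)) {
          sets[parent, ] <- inter
        } else {
          sets[parent, ] <- sets[parent, ] | cs
          cnt <- cnt + 1L
        }
      }
    }
    n_changes[s] <- cnt
    # up-pass assignment, deterministic lexicographic tie-break
    root <- ntip + 1L
    state <- integer(nn)
    rs <- which(sets[root, ])
    if (length(rs) > 1) tie <- TRUE
    state[root] <- rs[1]
    for (e in rev(seq_len(nrow(po$edge)))) { # preorder
      parent <- po$edge[e, 1]; child <- po$edge[e, 2]
      cs <- which(sets[child, ])
      if (state[parent] %in% cs) {
        state[child] <- state[parent]
      } else {
        if (length(cs) > 1) tie <- TRUE
        state[child] <- cs[1]
      }
      if (state[child] != state[parent]) {
        changes[[length(changes) + 1]] <- data.frame(
          site = s, edge = e, parent_node = parent, child_node = child,
          from = lv[state[parent]], to = lv[state[child]],
          stringsAsFactors = FALSE
        )
      }
    }
    ties[s] <- tie
  }
  ch <- if (length(changes)) do.call(rbind, changes) else
    data.frame(site = integer(0), edge = integer(0), parent_node = integer(0),
               child_node = integer(0), from = character(0), to = character(0))
  structure(list(changes = ch, n_changes = n_changes, ties = ties, tree = po),
            class = "fitch_changes")
}

## ---- z-tests against the mutational expectation -------------------------

#' Expected magnitude-category distribution under neutrality
#'
#' For each property, categorizes every single-nucleotide nonsynonymous
#' neighbor pair of the genetic code (equal mutation weights) and returns the
#' expected category frequencies.
#'
#' @param props property table
#' @param code_table genetic code
#' @return matrix properties x 8 of expected frequencies
#' @export
neutral_category_expectation <- function(props, code_table = genetic_code()) {
  pairs <- nonsyn_neighbor_pairs(code_table)
  out <- matrix(0, nrow = ncol(props), ncol = 8,
                dimnames = list(names(props), paste0("cat", 1:8)))
  for (p in names(props)) {
    cats <- mapply(function(a, b) categorize_change(props, a, b, p),
                   pairs$aa_from, pairs$aa_to)
    tab <- tabulate(cats, nbins = 8)
    out[p, ] <- tab / sum(tab)
  }
  out
}

#' Z-tests of observed replacement categories against neutrality
#'
#' For each property and magnitude category, compares the observed count of
#' inferred replacements falling in that category with the expectation from
#' the genetic code's single-step nonsynonymous neighbor graph:
#' `z = (obs - N p) / sqrt(N p (1 - p))`, two-sided p-values. Cells with
#' category >= `min_category`, positive z and `p < p_threshold` are flagged
#' "positive-destabilizing".
#'
#' @param changes data.frame with columns `from`, `to` (one replacement per
#'   row, e.g. `fitch_ancestral_changes()$changes`)
#' @param props property table
#' @param code_table genetic code (for the neutral expectation)
#' @param min_category smallest radical category to flag (default 6)
#' @param p_threshold significance level (default 0.001)
#' @return data.frame of class `physchem_z`: property, category, expected_p,
#'   observed, z, p, flagged, note
#' @export
property_z_test <- function(changes, props, code_table = genetic_code(),
                            min_category = 6, p_threshold = 0.001) {
  if (nrow(changes) == 0) stop("no inferred changes to test", call. = FALSE)
  expect <- neutral_category_expectation(props, code_table)
  N <- nrow(changes)
  rows <- list()
  for (p in names(props)) {
    cats <- mapply(function(a, b) categorize_change(props, a, b, p),
                   changes$from, changes$to)
    obs <- tabulate(cats, nbins = 8)
    for (k in 1:8) {
      pe <- expect[p, k]
      if (pe == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          property = p, category = k, expected_p = 0, observed = obs[k],
          z = NA_real_, p = NA_real_, flagged = FALSE,
          note = "zero expected frequency; skipped",
          stringsAsFactors = FALSE)
        next
      }
      z <- (obs[k] - N * pe) / sqrt(N * pe * (1 - pe))
      pv <- 2 * pnorm(-abs(z))
      rows[[length(rows) + 1]] <- data.frame(
        property = p, category = k, expected_p = pe, observed = obs[k],
        z = z, p = pv,
        flagged = (k >= min_category && z > 0 && pv < p_threshold),
        note = "", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("physchem_z", "data.frame")
  out
}

#' Site-level physicochemical scan of a codon alignment
#'
#' Translates the alignment, infers replacements by Fitch parsimony on the
#' tree, runs the property z-tests, and reports per-site calls: a site is
#' called when one of its inferred replacements falls in a flagged
#' (category >= `min_category`, z > 0, p < `p_threshold`) property cell.
#'
#' @param caln a `codon_aln`
#' @param tree `ape::phylo` matching the alignment ids
#' @param props property table (default packaged)
#' @param min_category,p_threshold flag thresholds (defaults 6 and 0.001)
#' @return list of class `physchem_scan`: `sites` (called site indices),
#'   `site_properties` data.frame (site, from, to, property, category),
#'   `z_table`, `changes`
#' @export
physchem_scan <- function(caln, tree, props = read_aa_properties(),
                          min_category = 6, p_threshold = 0.001) {
  aa_mat <- caln$aa
  rownames(aa_mat) <- caln$ids
  aa_mat[aa_mat == "*"] <- NA
  fit <- fitch_ancestral_changes(tree, aa_mat)
  if (nrow(fit$changes) == 0) {
    return(structure(list(sites = integer(0),
                          site_properties = data.frame(),
                          z_table = NULL, changes = fit$changes),
                     class = "physchem_scan"))
  }
  zt <- property_z_test(fit$changes, props, caln$code_table,
                        min_category = min_category, p_threshold = p_threshold)
  flagged_cells <- zt[zt$flagged, c("property", "category")]
  site_props <- list()
  for (i in seq_len(nrow(fit$changes))) {
    ch <- fit$changes[i, ]
    for (p in names(props)) {
      k <- categorize_change(props, ch$from, ch$to, p)
      if (k >= min_category &&
          any(flagged_cells$property == p & flagged_cells$category == k)) {
        site_props[[length(site_props) + 1]] <- data.frame(
          site = ch$site, from = ch$from, to = ch$to, property = p,
          category = k, stringsAsFactors = FALSE)
      }
    }
  }
  sp <- if (length(site_props)) unique(do.call(rbind, site_props)) else
    data.frame(site = integer(0), from = character(0), to = character(0),
               property = character(0), category = integer(0))
  structure(list(sites = sort(unique(sp$site)), site_properties = sp,
                 z_table = zt, changes = fit$changes),
            class = "physchem_scan")
}
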