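## Seeded synthetic-data generators emulating the statistical structure the
## analysis assumes: neutral coalescent mitogenome-like alignments (low pi,
## excess of unique haplotypes), codon alignments with heterogeneous omega
## (including a planted positively-selected minority), control regions with
## 38-40 bp tandem repeats in 1-3 copies and stem/loop mutation-rate
## contrast, and region-labelled carrier tables driven by environmental
## covariates. Every generator is a pure function of (seed, parameters).

#' Simulate a random genealogy
#'
#' Standard coalescent (branch lengths in coalescent units, so the depth of
#' an n = 2 tree is Exp(1)) or a Yule tree, optionally rescaled to a target
#' root-to-tip height.
#'
#' @param n_taxa number of tips (>= 2)
#' @param model `"coalescent"` or `"yule"`
#' @param seed RNG seed
#' @param target_height optional height to rescale to
#' @return `ape::phylo` with tip labels `t1..tn`
#' @export
simulate_tree <- function(n_taxa, model = c("coalescent", "yule"), seed = 1,
                          target_height = NULL) {
  model <- match.arg(model)
  stopifnot(n_taxa >= 2)
  set.seed(seed)
  tr <- if (model == "coalescent") {
    ape::rcoal(n_taxa, tip.label = paste0("t", seq_len(n_taxa)))
  } else {
    t0 <- ape::rphylo(n_taxa, birth = 1, death = 0)
    t0$tip.label <- paste0("t", seq_len(n_taxa))
    t0
  }
  if (!is.null(target_height)) {
    h <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * target_height / h
  }
  tr
}

# evolve finite-sites nucleotide sequences down a tree: per-edge Poisson
# mutation counts, uniform target site, uniform different base
.evolve_nucleotides <- function(tree, L, rate_per_site) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nn <- ntip + tree$Nnode
  seqs <- vector("list", nn)
  seqs[[root]] <- sample(VALID_NT, L, replace = TRUE)
  # preorder = reverse postorder
  po <- stats::reorder(tree, "postorder")
  for (e in rev(seq_len(nrow(po$edge)))) {
    parent <- po$edge[e, 1]; child <- po$edge[e, 2]
    s <- seqs[[parent]]
    nmut <- rpois(1, po$edge.length[e] * rate_per_site * L)
    if (nmut > 0) {
      pos <- sample.int(L, nmut, replace = TRUE)
      for (p in pos) {
        s[p] <- sample(setdiff(VALID_NT, s[p]), 1)
      }
    }
    seqs[[child]] <- s
  }
  m <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(m) <- po$tip.label[seq_len(ntip)]
  # reorder rows to original tip order
  m[tree$tip.label, , drop = FALSE]
}

#' Simulate a coalescent genealogy under exponential growth
#'
#' Backward-in-time coalescent with population size `N(t) = N0 exp(-g t)`:
#' intercoalescent waits are drawn by the standard time transformation
#' `w = log(exp(g s) + g E) / g - s` with `E ~ Exp(k(k-1)/2)`. `growth = 0`
#' recovers the standard coalescent; large `growth` gives the star-like
#' genealogies of an expanding population (excess of rare variants).
#'
#' @param n sample size
#' @param growth exponential growth rate (coalescent units)
#' @return `ape::phylo` with tips `t1..tn`
#' @export
coalescent_growth_tree <- function(n, growth = 0) {
  # grow subtree newick strings as lineages merge
  sub <- paste0("t", seq_len(n))
  times <- rep(0, n)
  s <- 0
  while (length(sub) > 1) {
    k <- length(sub)
    E <- rexp(1, k * (k - 1) / 2)
    w <- if (growth > 0) {
      log(exp(growth * s) + growth * E) / growth - s
    } else E
    s <- s + w
    pair <- sample(k, 2)
    merged <- sprintf("(%s:%g,%s:%g)", sub[pair[1]], s - times[pair[1]],
                      sub[pair[2]], s - times[pair[2]])
    sub <- c(sub[-pair], merged)
    times <- c(times[-pair], s)
  }
  ape::read.tree(text = paste0(sub, ";"))
}

#' Simulate a neutral alignment on a coalescent genealogy
#'
#' Mutations fall on the genealogy at locus-wide rate `theta / 2` per unit
#' coalescent time, so the expected mean pairwise difference K equals
#' `theta` (per locus).
#'
#' @param n sample size
#' @param theta locus-wide scaled mutation rate
#' @param L number of sites (large L approximates the infinite-sites model)
#' @param seed RNG seed
#' @param growth exponential growth rate (0 = standard coalescent)
#' @return a `mito_aln`
#' @export
simulate_neutral_alignment <- function(n, theta, L = 5000, seed = 1,
                                       growth = 0) {
  set.seed(seed)
  tr <- if (growth > 0) coalescent_growth_tree(n, growth)
  else ape::rcoal(n, tip.label = paste0("t", seq_len(n)))
  m <- .evolve_nucleotides(tr, L, theta / 2 / L)
  aln_from_matrix(m)
}

#' Simulate a mitogenome-like alignment
#'
#' A coalescent alignment at the diversity regime typical of a large,
#' recently expanded marine fish population: per-site diversity around `pi`
#' (default 0.006) on a ~16.6 kb locus under a star-like expansion genealogy
#' (`growth`, default 20), which produces the excess of rare variants and
#' unique haplotypes (negative Tajima's D / Fu's Fs) characteristic of such
#' populations.
#'
#' @param n sample size (default 45)
#' @param L alignment length (default 16600)
#' @param pi target per-site nucleotide diversity (default 0.006)
#' @param growth expansion rate of the genealogy (default 20)
#' @param seed RNG seed
#' @return a `mito_aln` with a `region` metadata vector cycling NAS/SEAS/BoB
#' @export
simulate_mitogenome_alignment <- function(n = 45, L = 16600, pi = 0.006,
                                          growth = 20, seed = 1) {
  set.seed(seed)
  tr <- if (growth > 0) coalescent_growth_tree(n, growth)
  else ape::rcoal(n, tip.label = paste0("t", seq_len(n)))
  # pad terminal branches (individuals sampled from a very large population
  # carry private variation even when their lineages are close), then scale
  # so the mean pairwise path length is 1 and mutate at `pi` per site
  height <- max(ape::node.depth.edgelength(tr))
  term <- tr$edge[, 2] <= n
  tr$edge.length[term] <- tr$edge.length[term] + 0.05 * height
  mp <- mean(ape::cophenetic.phylo(tr)[upper.tri(diag(n))])
  tr$edge.length <- tr$edge.length / mp
  m <- .evolve_nucleotides(tr, L, pi)
  aln <- aln_from_matrix(m)
  aln$metadata$region <- setNames(
    rep(c("NAS", "SEAS", "BoB"), length.out = n), aln$ids)
  aln
}

#' Simulate a codon alignment with heterogeneous omega
#'
#' Gillespie-style evolution along the tree under the same MG94 x HKY85
#' matrix used by the selection scans, with a per-site omega profile.
#'
#' @param tree `ape::phylo` with branch lengths (expected substitutions per
#'   codon site at omega = 1)
#' @param L_codons number of codon sites
#' @param kappa transition/transversion ratio
#' @param omega_profile data.frame with columns `omega` and `prob` (site
#'   class mixture), or a numeric vector of per-site omegas of length
#'   `L_codons`
#' @param seed RNG seed
#' @param pi_pos optional 3 x 4 position-specific nucleotide frequencies
#'   (default uniform)
#' @param code_table genetic code
#' @param episodic optional episodic burst: `list(tip =, sites =, omega =)`
#'   or `list(child_node =, sites =, omega =)` makes the listed sites evolve
#'   at the given omega on the single branch leading to that tip / internal
#'   node (an episodic, branch-restricted selection event; internal branches
#'   carry the detectable kind of burst, since the whole subtree inherits it)
#' @return list: `caln` (a `codon_aln`), `truth` (per-site omega, tree, seed)
#' @export
simulate_codon_alignment <- function(tree, L_codons, kappa = 2,
                                     omega_profile = data.frame(
                                       omega = c(0.1, 1, 5),
                                       prob = c(0.9, 0.07, 0.03)),
                                     seed = 1, pi_pos = NULL,
                                     code_table = genetic_code(),
                                     episodic = NULL) {
  set.seed(seed)
  if (is.null(pi_pos)) {
    pi_pos <- matrix(0.25, 3, 4, dimnames = list(NULL, BASES))
  }
  model <- mg94_model(pi_pos, kappa = kappa, code_table = code_table)
  m <- length(model$codons)
  if (is.data.frame(omega_profile)) {
    stopifnot(abs(sum(omega_profile$prob) - 1) < 1e-8)
    site_omega <- sample(omega_profile$omega, L_codons, replace = TRUE,
                         prob = omega_profile$prob)
  } else {
    stopifnot(length(omega_profile) == L_codons)
    site_omega <- omega_profile
  }
  omegas <- sort(unique(c(site_omega, if (!is.null(episodic)) episodic$omega)))
  # per-class generator: rates and jump distributions
  gens <- lapply(omegas, function(w) {
    Q <- mg94_q(model, 1, w)
    rates <- -diag(Q)
    J <- Q; diag(J) <- 0
    J <- J / ifelse(rates > 0, rates, 1)
    list(rates = rates, J = J)
  })
  names(gens) <- as.character(omegas)

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nn <- ntip + tree$Nnode
  states <- vector("list", nn)
  states[[root]] <- sample.int(m, L_codons, replace = TRUE, prob = model$pi)
  po <- stats::reorder(tree, "postorder")
  n_events <- 0L
  for (e in rev(seq_len(nrow(po$edge)))) {
    parent <- po$edge[e, 1]; child <- po$edge[e, 2]
    st <- states[[parent]]
    tlen <- po$edge.length[e]
    is_burst_edge <- !is.null(episodic) &&
      ((!is.null(episodic$tip) && child <= ntip &&
          po$tip.label[child] == episodic$tip) ||
         (!is.null(episodic$child_node) && child %in% episodic$child_node))
    if (tlen > 0) {
      for (s in seq_len(L_codons)) {
        w_here <- if (is_burst_edge && s %in% episodic$sites) episodic$omega
        else site_omega[s]
        g <- gens[[as.character(w_here)]]
        t_left <- tlen
        repeat {
          r <- g$rates[st[s]]
          if (r <= 0) break
          dt <- rexp(1, r)
          if (dt > t_left) break
          t_left <- t_left - dt
          st[s] <- sample.int(m, 1, prob = g$J[st[s], ])
          n_events <- n_events + 1L
        }
      }
    }
    states[[child]] <- st
  }
  cm <- do.call(rbind, lapply(seq_len(ntip), function(i) {
    model$codons[states[[i]]]
  }))
  rownames(cm) <- po$tip.label[seq_len(ntip)]
  cm <- cm[tree$tip.label, , drop = FALSE]
  seqs <- apply(cm, 1, paste, collapse = "")
  names(seqs) <- rownames(cm)
  caln <- to_codon_alignment(new_alignment(seqs), code_table = code_table,
                             trim_stop = FALSE)
  list(caln = caln,
       truth = list(site_omega = site_omega, tree = tree, seed = seed,
                    n_events = n_events, model = model))
}

#' Simulate control-region sequences with tandem repeats
#'
#' Builds a reference control region (5' domain, TAS, tandem repeat block,
#' poly-A, CSB blocks, 3' tail) around a 38-40 bp unit, then draws a copy
#' number per individual from `copy_dist`, applies slipped-strand copy-number
#' changes with probability `slip_prob`, and sprinkles point mutations with
#' stem columns of the unit's reference structure mutated at
#' `stem_loop_ratio` times the loop rate.
#'
#' @param n individuals
#' @param unit repeat unit (default the packaged 38 bp consensus)
#' @param copy_dist named probabilities over copy numbers (default
#'   `c("1" = 0.8, "2" = 0.15, "3" = 0.05)`, the Type-1-dominant regime)
#' @param point_mu per-base point mutation probability in loops (default 0.01)
#' @param slip_prob probability of one extra slip event (+/- 1 copy, floor 1)
#' @param stem_loop_ratio stem-to-loop mutation rate ratio (default 1)
#' @param seed RNG seed
#' @return list: `seqs` (named character vector), `truth` (copies, unit, stem
#'   positions within unit, region spans of the reference), `regions`
#'   (NAS/SEAS/BoB labels cycling)
#' @export
simulate_control_regions <- function(n, unit = NULL,
                                     copy_dist = c("1" = 0.8, "2" = 0.15,
                                                   "3" = 0.05),
                                     point_mu = 0.01, slip_prob = 0,
                                     stem_loop_ratio = 1, seed = 1) {
  set.seed(seed)
  if (is.null(unit)) unit <- unname(read_unit_catalog()[["unit38_type1"]])
  unit <- toupper(unit)
  p <- nchar(unit)
  motifs <- read_motif_config()
  pat <- setNames(motifs$pattern, motifs$name)
  rand_seq <- function(l) paste(sample(VALID_NT, l, replace = TRUE), collapse = "")
  flank5 <- rand_seq(120)
  spacer1 <- rand_seq(25)
  spacer2 <- rand_seq(30)
  spacer3 <- rand_seq(20)
  spacer4 <- rand_seq(15)
  spacer5 <- rand_seq(15)
  tail3 <- rand_seq(80)
  polyA <- strrep("A", 12)
  # stem positions of the unit's reference fold
  ref_fold <- fold_min_energy(unit, "rna")
  stem_in_unit <- which(!is.na(ref_fold$pairs))

  copies_drawn <- as.integer(names(copy_dist))[
    sample.int(length(copy_dist), n, replace = TRUE, prob = copy_dist)]
  seqs <- character(n)
  copies_final <- integer(n)
  for (i in seq_len(n)) {
    k <- copies_drawn[i]
    if (slip_prob > 0 && runif(1) < slip_prob) {
      k <- max(1L, k + sample(c(-1L, 1L), 1))
    }
    copies_final[i] <- k
    pre <- paste0(flank5, pat[["TAS"]], spacer1)
    repblock <- strrep(unit, k)
    post <- paste0(polyA, spacer2, pat[["CSB_D"]], spacer3, pat[["CSB1"]],
                   spacer4, pat[["CSB2"]], spacer5, pat[["CSB3"]],
                   tail3)
    x <- strsplit(paste0(pre, repblock, post), "")[[1]]
    # per-position mutation rates: stems in repeat units at ratio * point_mu
    rates <- rep(point_mu, length(x))
    rep_start <- nchar(pre)
    if (length(stem_in_unit)) {
      stem_pos <- as.vector(outer(stem_in_unit, (0:(k - 1)) * p, `+`)) + rep_start
      rates[stem_pos] <- point_mu * stem_loop_ratio
    }
    mut <- runif(length(x)) < rates
    for (j in which(mut)) x[j] <- sample(setdiff(VALID_NT, x[j]), 1)
    seqs[i] <- paste(x, collapse = "")
  }
  names(seqs) <- paste0("cr", seq_len(n))
  regions <- setNames(rep(c("NAS", "SEAS", "BoB"), length.out = n), names(seqs))
  list(seqs = seqs,
       truth = list(copies = setNames(copies_final, names(seqs)), unit = unit,
                    period = p, stem_in_unit = stem_in_unit,
                    rep_start = nchar(flank5) + nchar(pat[["TAS"]]) +
                      nchar(spacer1) + 1L,
                    seed = seed),
       regions = regions)
}

#' Simulate a region-labelled carrier dataset for the environment GLM
#'
#' Carrier status is drawn per individual from
#' `logit(p) = intercept + effect_size * covariate(region)` with the
#' covariate standardized across regions.
#'
#' @param effect_size slope on the logit scale
#' @param n_per_region individuals per region
#' @param covariate named numeric vector per region; default the annual SST
#'   SD of the packaged climatology
#' @param intercept logit-scale intercept (default -1)
#' @param seed RNG seed
#' @return list: `individuals` data.frame (id, region, carrier), `covariate`
#'   (standardized), `truth`
#' @export
simulate_env_glm_dataset <- function(effect_size, n_per_region = 50,
                                     covariate = NULL, intercept = -1,
                                     seed = 1) {
  set.seed(seed)
  if (is.null(covariate)) {
    cs <- seasonal_summaries(read_climatology())
    sub <- cs[cs$variable == "SST" & cs$season == "Annual", ]
    covariate <- setNames(sub$sd, sub$region)
  }
  z <- (covariate - mean(covariate)) / sd(covariate)
  regions <- rep(names(z), each = n_per_region)
  pr <- stats::plogis(intercept + effect_size * z[regions])
  carrier <- rbinom(length(regions), 1, pr)
  ids <- paste0("ind", seq_along(regions))
  list(individuals = data.frame(id = ids, region = regions, carrier = carrier,
                                stringsAsFactors = FALSE),
       covariate = z,
       truth = list(effect_size = effect_size, intercept = intercept,
                    seed = seed))
}

#' Deterministic tRNA-like cloverleaf sequences
#'
#' Synthetic reference set for the folding-potential comparison: cloverleaf
#' sequences built from random stems with exact reverse complements (acceptor
#' stem plus three stem-loop arms), so each folds into a stable structure.
#'
#' @param n how many sequences
#' @param seed RNG seed
#' @return named character vector (~70 nt each)
#' @export
simulate_trna_like <- function(n = 5, seed = 1) {
  set.seed(seed)
  mk_stem <- function(l) paste(sample(c("G", "C", "G", "C", "A", "T"), l,
                                      replace = TRUE), collapse = "")
  out <- character(n)
  for (i in seq_len(n)) {
    acc <- mk_stem(7)
    d_stem <- mk_stem(4); d_loop <- paste(sample(VALID_NT, 8, TRUE), collapse = "")
    a_stem <- mk_stem(5); a_loop <- paste(sample(VALID_NT, 7, TRUE), collapse = "")
    t_stem <- mk_stem(5); t_loop <- paste(sample(VALID_NT, 7, TRUE), collapse = "")
    out[i] <- paste0(
      acc, "T",
      d_stem, d_loop, rev_comp(d_stem), "A",
      a_stem, a_loop, rev_comp(a_stem), "AG",
      t_stem, t_loop, rev_comp(t_stem),
      rev_comp(acc), "CCA"
    )
  }
  names(out) <- paste0("trna_like_", seq_len(n))
  out
}
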