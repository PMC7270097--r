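## MG94 x HKY85 codon substitution model and Felsenstein-pruning likelihood
## engine shared by the pervasive (rate-grid) and episodic (mixed-effects)
## selection scans, and reused by the synthetic codon-alignment generator.

#' Position-specific nucleotide frequencies (F3x4)
#'
#' Observed nucleotide frequencies at each codon position, with a 0.5
#' pseudocount per nucleotide so no frequency is exactly zero.
#'
#' @param caln a `codon_aln`
#' @return 3 x 4 matrix (positions x T,C,A,G), rows summing to 1
#' @export
f3x4_frequencies <- function(caln) {
  cm <- caln$codons[!grepl("[N-]", caln$codons)]
  out <- matrix(0.5, nrow = 3, ncol = 4, dimnames = list(NULL, BASES))
  for (pos in 1:3) {
    nts <- substr(cm, pos, pos)
    ct <- table(factor(nts, levels = BASES))
    out[pos, ] <- out[pos, ] + as.numeric(ct)
  }
  out / rowSums(out)
}

#' Build an MG94 x HKY85 codon model
#'
#' Off-diagonal rates between sense codons one nucleotide apart are
#' `kappa^[transition] * pi_target(position)`, multiplied by the synonymous
#' rate alpha or nonsynonymous rate beta. The model is returned in the
#' decomposed form `Q(alpha, beta) = alpha * A + beta * B`, scaled so the
#' expected substitution rate at `alpha = beta = 1` is one substitution per
#' codon site per unit branch length.
#'
#' @param pi_pos 3 x 4 position-specific nucleotide frequencies (F3x4)
#' @param kappa transition/transversion rate ratio (> 0)
#' @param code_table genetic code
#' @return list of class `mg94_model`: `codons`, `pi` (stationary codon
#'   frequencies), `A`, `B` (syn / nonsyn off-diagonal rate parts), `kappa`
#' @export
mg94_model <- function(pi_pos, kappa = 2, code_table = genetic_code()) {
  stopifnot(kappa > 0)
  codons <- sense_codons(code_table)
  m <- length(codons)
  idx <- setNames(seq_len(m), codons)
  pi_cod <- vapply(codons, function(cd) {
    prod(vapply(1:3, function(p) pi_pos[p, substr(cd, p, p)], numeric(1)))
  }, numeric(1))
  pi_cod <- pi_cod / sum(pi_cod)

  A <- matrix(0, m, m, dimnames = list(codons, codons))
  B <- matrix(0, m, m, dimnames = list(codons, codons))
  for (cd in codons) {
    nb <- codon_neighbors(cd)
    nb <- nb[nb$to %in% codons, , drop = FALSE]
    for (r in seq_len(nrow(nb))) {
      rate <- pi_pos[nb$pos[r], nb$to_nt[r]] * if (nb$transition[r]) kappa else 1
      if (code_table[cd] == code_table[nb$to[r]]) {
        A[idx[cd], idx[nb$to[r]]] <- rate
      } else {
        B[idx[cd], idx[nb$to[r]]] <- rate
      }
    }
  }
  # scale: expected rate at alpha = beta = 1 equals 1
  scale <- sum(pi_cod * rowSums(A + B))
  A <- A / scale
  B <- B / scale
  structure(list(codons = codons, pi = pi_cod, A = A, B = B, kappa = kappa,
                 code_table = code_table),
            class = "mg94_model")
}

#' MG94 model fitted to a codon alignment
#' @param caln a `codon_aln`
#' @param kappa transition/transversion ratio
#' @return `mg94_model` with F3x4 frequencies taken from `caln`
#' @export
mg94_from_alignment <- function(caln, kappa = 2) {
  mg94_model(f3x4_frequencies(caln), kappa = kappa, code_table = caln$code_table)
}

#' Generator matrix at given site rates
#' @param model an `mg94_model`
#' @param alpha synonymous rate (>= 0)
#' @param beta nonsynonymous rate (>= 0)
#' @return rate matrix Q with rows summing to zero
#' @export
mg94_q <- function(model, alpha, beta) {
  Q <- alpha * model$A + beta * model$B
  diag(Q) <- -rowSums(Q)
  Q
}

# eigendecomposition of a reversible Q via symmetrization; returns closure
# P(t). Clamps tiny negative probabilities from roundoff.
.q_eigen <- function(Q, pi) {
  d <- sqrt(pi)
  Sy <- (d * Q) %*% diag(1 / d)
  Sy <- (Sy + t(Sy)) / 2
  ev <- eigen(Sy, symmetric = TRUE)
  U <- ev$vectors
  left <- (1 / d) * U          # D^{-1/2} U
  right <- t(U) %*% diag(d)    # U^T D^{1/2}
  lam <- ev$values
  function(t) {
    P <- left %*% (exp(lam * t) * right)
    P[P < 0] <- 0
    P
  }
}

#' Transition-probability matrices for a set of branch lengths
#' @param model `mg94_model`
#' @param alpha synonymous rate
#' @param beta nonsynonymous rate
#' @param times branch lengths (expected substitutions per codon site at
#'   alpha = beta = 1)
#' @return list of probability matrices, one per element of `times`
#' @export
mg94_transition_probs <- function(model, alpha, beta, times) {
  Pfun <- .q_eigen(mg94_q(model, alpha, beta), model$pi)
  lapply(times, Pfun)
}

#' Integer codon states for the likelihood engine
#' @param caln a `codon_aln`
#' @param model `mg94_model`
#' @return n x n_codons integer matrix of state indices; NA marks ambiguous
#'   codons (gap/N/stop), treated as missing data
#' @export
codon_states <- function(caln, model) {
  st <- matrix(match(caln$codons, model$codons), nrow = nrow(caln$codons),
               dimnames = list(caln$ids, NULL))
  st
}

# postorder edge traversal bookkeeping for an ape::phylo
.tree_postorder <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  list(tree = tr, edge = tr$edge, len = tr$edge.length,
       ntip = length(tr$tip.label), root = length(tr$tip.label) + 1L)
}

#' Per-site log-likelihood under fixed per-edge transition matrices
#'
#' Felsenstein pruning over all sites at once, with per-column rescaling to
#' avoid underflow. Missing states (NA) contribute a vector of ones.
#'
#' @param states integer matrix (rows named by tip label) from [codon_states()]
#' @param tree `ape::phylo` with branch lengths
#' @param Plist list of transition matrices, one per row of the postorder
#'   `tree$edge` (see [mg94_transition_probs()]; caller must order them to the
#'   postorder edge ordering)
#' @param pi stationary distribution
#' @return numeric vector of per-site log-likelihoods
#' @export
pruning_loglik <- function(states, tree, Plist, pi) {
  po <- .tree_postorder(tree)
  tr <- po$tree
  m <- length(pi)
  C <- ncol(states)
  states <- states[tr$tip.label, , drop = FALSE]
  nn <- po$ntip + tr$Nnode
  partial <- vector("list", nn)
  logscale <- numeric(C)

  tip_partial <- function(i) {
    M <- matrix(0, m, C)
    s <- states[i, ]
    obs <- !is.na(s)
    M[cbind(s[obs], which(obs))] <- 1
    if (any(!obs)) M[, which(!obs)] <- 1
    M
  }

  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]; child <- po$edge[e, 2]
    cp <- if (child <= po$ntip) tip_partial(child) else partial[[child]]
    contrib <- Plist[[e]] %*% cp
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- contrib
    } else {
      partial[[parent]] <- partial[[parent]] * contrib
      mx <- apply(partial[[parent]], 2, max)
      mx[mx == 0] <- 1
      partial[[parent]] <- sweep(partial[[parent]], 2, mx, "/")
      logscale <- logscale + log(mx)
    }
  }
  lik <- colSums(pi * partial[[po$root]])
  log(lik) + logscale
}

#' Per-site log-likelihood at given site rates
#'
#' @param caln a `codon_aln`
#' @param tree `ape::phylo`; leaf labels must match `caln$ids`
#' @param alpha synonymous rate
#' @param beta nonsynonymous rate
#' @param model optional prebuilt `mg94_model` (default F3x4 from `caln`)
#' @param sites optional site subset (1-based codon indices)
#' @return numeric vector of log-likelihoods (one per site)
#' @export
codon_site_loglik <- function(caln, tree, alpha, beta, model = NULL,
                              sites = NULL) {
  check_tree_matches(tree, caln$ids)
  if (is.null(model)) model <- mg94_from_alignment(caln)
  states <- codon_states(caln, model)
  if (!is.null(sites)) states <- states[, sites, drop = FALSE]
  po <- .tree_postorder(tree)
  Plist <- mg94_transition_probs(model, alpha, beta, po$len)
  pruning_loglik(states, po$tree, Plist, model$pi)
}

# total log-likelihood of the alignment under a homogeneous (alpha=1,
# beta=omega) model with a global branch-length scale; used to calibrate the
# tree before site-wise scans.
.homogeneous_loglik <- function(states, tree, model, scale, omega) {
  po <- .tree_postorder(tree)
  Plist <- mg94_transition_probs(model, 1, omega, po$len * scale)
  sum(pruning_loglik(states, po$tree, Plist, model$pi))
}

#' Calibrate branch lengths and global omega
#'
#' Two-phase convention: fit a site-homogeneous MG94 model (one global
#' branch-length scale and one omega) by maximum likelihood, then hold the
#' scaled branch lengths fixed for the site-wise scans.
#'
#' @param caln a `codon_aln`
#' @param tree `ape::phylo` with branch lengths
#' @param model optional `mg94_model`
#' @return list with `tree` (rescaled), `omega`, `scale`, `loglik`
#' @export
fit_global_codon_model <- function(caln, tree, model = NULL) {
  if (is.null(model)) model <- mg94_from_alignment(caln)
  states <- codon_states(caln, model)
  obj <- function(par) {
    -.homogeneous_loglik(states, tree, model, exp(par[1]), exp(par[2]))
  }
  fit <- optim(c(0, log(0.5)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-6, maxit = 300))
  scale <- exp(fit$par[1]); omega <- exp(fit$par[2])
  tr <- tree
  tr$edge.length <- tr$edge.length * scale
  list(tree = tr, omega = omega, scale = scale, loglik = -fit$value)
}
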