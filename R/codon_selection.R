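## Site-wise selection scans: an empirical-Bayes rate-grid scan for pervasive
## selection (FUBAR-style posteriors P(beta > alpha)) and a mixed-effects
## likelihood-ratio scan for episodic selection (MEME-style), combined by a
## two-method consensus rule.

#' Neighbor-joining fallback tree
#'
#' NJ on Kimura two-parameter distances with deterministic input ordering
#' (tips sorted lexicographically) and negative branch lengths clamped to 0.
#'
#' @param aln a `mito_aln` (nucleotide); codon alignments should be flattened
#'   with [codon_to_nucleotide()] first
#' @return an unrooted `ape::phylo`
#' @export
nj_fallback_tree <- function(aln) {
  if (length(aln$ids) < 3) stop("NJ needs at least 3 sequences", call. = FALSE)
  ord <- order(aln$ids)
  m <- aln_matrix(aln)[ord, , drop = FALSE]
  bin <- ape::as.DNAbin(tolower(m))
  d <- ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE)
  dm <- as.matrix(d)
  bad <- which(!is.finite(dm), arr.ind = TRUE)
  bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
  if (nrow(bad)) {
    stop("saturated/undefined K2P distance between ",
         rownames(dm)[bad[1, 1]], " and ", colnames(dm)[bad[1, 2]],
         call. = FALSE)
  }
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# crude per-site rate estimates (distinct non-ambiguous codons - 1 over tree
# length), used only to set the default grid span
.crude_site_rates <- function(caln, tree) {
  tl <- sum(tree$edge.length)
  apply(caln$codons, 2, function(col) {
    col <- col[!grepl("[N-]", col)]
    max(length(unique(col)) - 1, 0) / max(tl, 1e-8)
  })
}

#' Pervasive-selection scan on a rate grid
#'
#' Evaluates every site's likelihood on a fixed 2-D grid of synonymous (alpha)
#' and nonsynonymous (beta) rates, fits grid weights by Dirichlet-smoothed EM
#' across sites (empirical Bayes), and reports each site's posterior
#' probability of beta > alpha (positive selection) and beta < alpha
#' (purifying selection).
#'
#' @param caln a `codon_aln` (>= 3 sequences)
#' @param tree optional `ape::phylo`; when NULL an NJ tree is built from the
#'   alignment ([nj_fallback_tree()])
#' @param grid_size points per axis (default 20); grid points are spaced
#'   quadratically (denser at low rates, where site rates concentrate under
#'   purifying selection)
#' @param prior symmetric Dirichlet smoothing added to the EM weight counts
#'   (default 0.5)
#' @param pos_threshold posterior probability to flag a site (default 0.9)
#' @param gmax upper end of both rate axes; default twice the largest crude
#'   empirical site rate (at least 2)
#' @param kappa transition/transversion ratio for the codon model
#' @return list of class `grid_scan`: data.frame `sites` (site, posterior_pos,
#'   posterior_neg, flagged_positive, flagged_purifying), `grid` (alpha, beta,
#'   weight), `excluded` (degenerate all-missing sites), `tree`
#' @export
grid_bayes_scan <- function(caln, tree = NULL, grid_size = 20, prior = 0.5,
                            pos_threshold = 0.9, gmax = NULL, kappa = 2) {
  if (length(caln$ids) < 3) stop("need at least 3 sequences", call. = FALSE)
  if (is.null(tree)) tree <- nj_fallback_tree(codon_to_nucleotide(caln))
  check_tree_matches(tree, caln$ids)
  model <- mg94_from_alignment(caln, kappa = kappa)
  states <- codon_states(caln, model)

  excluded <- which(colSums(!is.na(states)) == 0)
  use_sites <- setdiff(seq_len(ncol(states)), excluded)

  cal <- fit_global_codon_model(caln, tree, model)
  tr <- cal$tree
  if (is.null(gmax)) {
    gmax <- 2 * max(1, max(.crude_site_rates(caln, tr)))
  }
  vals <- seq(0, 1, length.out = grid_size)^2 * gmax
  grid <- expand.grid(alpha = vals, beta = vals)

  po <- .tree_postorder(tr)
  st <- states[, use_sites, drop = FALSE]
  nS <- ncol(st)
  logL <- matrix(NA_real_, nrow = nS, ncol = nrow(grid))
  for (g in seq_len(nrow(grid))) {
    Plist <- mg94_transition_probs(model, grid$alpha[g], grid$beta[g], po$len)
    logL[, g] <- pruning_loglik(st, po$tree, Plist, model$pi)
  }

  # EM over grid weights with Dirichlet smoothing
  nG <- nrow(grid)
  w <- rep(1 / nG, nG)
  prev_ll <- -Inf
  for (it in seq_len(500)) {
    lw <- sweep(logL, 2, log(w), "+")
    mx <- apply(lw, 1, max)
    r <- exp(lw - mx)
    rs <- rowSums(r)
    ll <- sum(mx + log(rs))
    r <- r / rs
    w <- (colSums(r) + prior)
    w <- w / sum(w)
    if (is.finite(prev_ll) && ll - prev_ll < 1e-8 * abs(ll)) break
    prev_ll <- ll
  }
  post <- r # site x grid responsibilities at convergence

  pos_mask <- grid$beta > grid$alpha
  neg_mask <- grid$beta < grid$alpha
  posterior_pos <- as.numeric(post %*% pos_mask)
  posterior_neg <- as.numeric(post %*% neg_mask)

  sites <- data.frame(
    site = use_sites,
    posterior_pos = posterior_pos,
    posterior_neg = posterior_neg,
    flagged_positive = posterior_pos > pos_threshold,
    flagged_purifying = posterior_neg > pos_threshold
  )
  structure(list(sites = sites, grid = cbind(grid, weight = w),
                 excluded = excluded, tree = tr, omega_global = cal$omega,
                 threshold = pos_threshold),
            class = "grid_scan")
}

## ---- episodic (mixed-effects) scan --------------------------------------

# single-site log-likelihood under the branch-level mixture: each branch's
# transition matrix is q * P(alpha, beta_plus) + (1 - q) * P(alpha, beta_minus)
# (exact marginalization since branch classes are drawn independently).
# The symmetrized generator parts SA, SB are precomputed once per scan and
# the evaluation itself runs in compiled code.

# symmetrized generator parts D^{1/2} (A + diag(-rowSums A)) D^{-1/2}
.sym_parts <- function(model) {
  d <- sqrt(model$pi)
  sym <- function(M) {
    Mfull <- M
    diag(Mfull) <- -rowSums(M)
    S <- (d * Mfull) %*% diag(1 / d)
    (S + t(S)) / 2
  }
  list(SA = sym(model$A), SB = sym(model$B), pi = model$pi)
}

.fit_site_mixture <- function(svec, po, sym, null_model, starts = 3,
                              max_iter = 500) {
  # parameterization: log alpha, logit delta (beta_minus = alpha*delta),
  # logit q, and (alternative only) log beta_plus
  obj <- function(par) {
    alpha <- exp(par[1])
    delta <- 1 / (1 + exp(-par[2]))
    q <- 1 / (1 + exp(-par[3]))
    bp <- if (null_model) alpha else exp(par[4])
    -.mix_site_loglik_cpp(svec, po$edge, po$len, sym$pi, sym$SA, sym$SB,
                          alpha, alpha * delta, bp, q)
  }
  base <- list(c(0, 0, 1), c(log(0.5), -1, 0), c(log(2), 1, -1))
  best <- NULL
  conv <- FALSE
  for (s in seq_len(starts)) {
    p0 <- base[[((s - 1) %% length(base)) + 1]]
    if (!null_model) p0 <- c(p0, log(2) + (s - 1) * 0.7)
    fit <- tryCatch(
      optim(p0, obj, method = "Nelder-Mead",
            control = list(reltol = 1e-6, maxit = max_iter)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (fit$convergence == 0) conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(list(loglik = NA_real_, converged = FALSE))
  alpha <- exp(best$par[1])
  delta <- 1 / (1 + exp(-best$par[2]))
  q <- 1 / (1 + exp(-best$par[3]))
  list(loglik = -best$value, converged = conv, alpha = alpha,
       beta_minus = alpha * delta,
       beta_plus = if (null_model) alpha else exp(best$par[4]), q = q)
}

#' Episodic-selection scan (per-site mixed-effects LRT)
#'
#' Per site, fits a null model in which the nonsynonymous rate is bounded by
#' the synonymous rate on all branches against an alternative with a second,
#' unconstrained nonsynonymous rate class mixed over branches, and reports a
#' likelihood-ratio p-value against the boundary mixture
#' 1/3 chi2_0 + 1/3 chi2_1 + 1/3 chi2_2.
#'
#' @param caln a `codon_aln`
#' @param tree optional `ape::phylo` (NJ fallback when NULL)
#' @param p_threshold call threshold (default 0.05)
#' @param sites optional subset of codon sites to scan
#' @param starts number of optimizer starts per site per model (default 3)
#' @param kappa transition/transversion ratio
#' @return data.frame of class `episodic_scan`: site, lrt, p, flagged,
#'   status ("ok", "invariant", "not_converged", "missing")
#' @export
episodic_scan <- function(caln, tree = NULL, p_threshold = 0.05, sites = NULL,
                          starts = 3, kappa = 2) {
  if (length(caln$ids) < 3) stop("need at least 3 sequences", call. = FALSE)
  if (is.null(tree)) tree <- nj_fallback_tree(codon_to_nucleotide(caln))
  check_tree_matches(tree, caln$ids)
  model <- mg94_from_alignment(caln, kappa = kappa)
  states <- codon_states(caln, model)
  cal <- fit_global_codon_model(caln, tree, model)
  po <- .tree_postorder(cal$tree)
  states <- states[po$tree$tip.label, , drop = FALSE]
  sym <- .sym_parts(model)
  if (is.null(sites)) sites <- seq_len(ncol(states))

  res <- data.frame(site = sites, lrt = NA_real_, p = NA_real_,
                    flagged = FALSE, status = "ok",
                    stringsAsFactors = FALSE)
  for (i in seq_along(sites)) {
    s <- sites[i]
    col <- states[, s]
    obs <- col[!is.na(col)]
    if (!length(obs)) {
      res$status[i] <- "missing"; next
    }
    if (length(unique(obs)) <= 1) {
      res$lrt[i] <- 0; res$p[i] <- 1; res$status[i] <- "invariant"; next
    }
    null_fit <- .fit_site_mixture(col, po, sym, null_model = TRUE,
                                  starts = starts)
    alt_fit <- .fit_site_mixture(col, po, sym, null_model = FALSE,
                                 starts = starts)
    if (is.na(null_fit$loglik) || is.na(alt_fit$loglik)) {
      res$status[i] <- "not_converged"; next
    }
    if (!null_fit$converged || !alt_fit$converged) res$status[i] <- "not_converged"
    lrt <- max(2 * (alt_fit$loglik - null_fit$loglik), 0)
    p <- (lrt <= 1e-9) / 3 +
      pchisq(lrt, df = 1, lower.tail = FALSE) / 3 +
      pchisq(lrt, df = 2, lower.tail = FALSE) / 3
    res$lrt[i] <- lrt
    res$p[i] <- p
    res$flagged[i] <- is.finite(p) && p < p_threshold
  }
  class(res) <- c("episodic_scan", "data.frame")
  attr(res, "threshold") <- p_threshold
  res
}

#' Two-method consensus of selection calls
#'
#' A site is consensus-positive when at least `min_methods` of the three
#' scans (rate-grid posterior, episodic LRT, physicochemical z-test) call it.
#'
#' @param grid_res `grid_scan` result (or its `$sites` data.frame)
#' @param episodic_res `episodic_scan` data.frame
#' @param physchem_sites integer vector of codon sites called by the
#'   physicochemical analysis (may be empty)
#' @param n_sites total codon sites in the shared coordinate space
#' @param min_methods consensus rule (default 2)
#' @return data.frame: site, posterior_pos, episodic_p, methods (comma list),
#'   n_methods, consensus_positive
#' @export
consensus_positive_sites <- function(grid_res, episodic_res,
                                     physchem_sites = integer(0),
                                     n_sites = NULL, min_methods = 2) {
  gs <- if (inherits(grid_res, "grid_scan")) grid_res$sites else grid_res
  es <- episodic_res
  if (is.null(n_sites)) n_sites <- max(gs$site, es$site, physchem_sites, 0)
  if (any(gs$site > n_sites) || any(es$site > n_sites) ||
      (length(physchem_sites) && any(physchem_sites > n_sites))) {
    stop("site indices exceed the shared coordinate space", call. = FALSE)
  }
  out <- data.frame(site = seq_len(n_sites),
                    posterior_pos = NA_real_, episodic_p = NA_real_)
  out$posterior_pos[gs$site] <- gs$posterior_pos
  out$episodic_p[es$site] <- es$p
  called_grid <- logical(n_sites); called_grid[gs$site[gs$flagged_positive]] <- TRUE
  called_epi <- logical(n_sites); called_epi[es$site[es$flagged]] <- TRUE
  called_phys <- logical(n_sites); called_phys[physchem_sites] <- TRUE
  nm <- called_grid + called_epi + called_phys
  out$methods <- vapply(seq_len(n_sites), function(s) {
    paste(c(if (called_grid[s]) "grid-bayes", if (called_epi[s]) "episodic",
            if (called_phys[s]) "physchem"), collapse = ",")
  }, character(1))
  out$n_methods <- nm
  out$consensus_positive <- nm >= min_methods
  out
}
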