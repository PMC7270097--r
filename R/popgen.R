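## Per-partition diversity and neutrality statistics: S, pi, Hd, K, Watterson
## theta, Tajima's D, Fu & Li's D*/F*, Fu's Fs, Nei-Gojobori Ka/Ks, and the
## relative mutation rate. Follows the usual DnaSP-style conventions; the
## gap/N column policy is explicit ("complete" deletion by default).

VALID_NT <- c("A", "C", "G", "T")

.retained_columns <- function(m, policy) {
  if (policy == "complete") {
    keep <- colSums(!matrix(m %in% VALID_NT, nrow = nrow(m))) == 0
    which(keep)
  } else {
    seq_len(ncol(m))
  }
}

.check_policy <- function(policy) {
  if (!policy %in% c("complete", "pairwise")) {
    stop("deletion policy must be 'complete' or 'pairwise'", call. = FALSE)
  }
  policy
}

# per-column state counts over valid nucleotides
.column_counts <- function(m) {
  apply(m, 2, function(col) table(col[col %in% VALID_NT]))
}

#' Diversity statistics for an alignment
#'
#' Computes the segregating-site count S, mean pairwise differences K,
#' per-site nucleotide diversity pi, haplotype count and haplotype diversity
#' Hd (with Nei's sampling SD), Watterson's theta, and the mutation counts
#' eta (total) and eta_s (singletons) used by the Fu & Li tests.
#'
#' @param aln a `mito_aln`
#' @param policy `"complete"` (drop columns containing `-` or `N`; default) or
#'   `"pairwise"` (per-pair deletion)
#' @return list of class `diversity_stats`
#' @export
diversity_stats <- function(aln, policy = c("complete", "pairwise")) {
  policy <- .check_policy(match.arg(policy))
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)

  if (policy == "complete") {
    keep <- .retained_columns(m, "complete")
    mm <- m[, keep, drop = FALSE]
    L <- length(keep)
    counts <- lapply(seq_len(L), function(j) {
      tabulate(match(mm[, j], VALID_NT), nbins = 4L)
    })
    kstates <- vapply(counts, function(ct) sum(ct > 0L), integer(1))
    S <- sum(kstates >= 2L)
    eta <- sum(pmax(kstates - 1L, 0L))
    eta_s <- sum(vapply(counts, function(ct) {
      k <- sum(ct > 0L)
      if (k < 2L) return(0L)
      min(sum(ct == 1L), k - 1L)
    }, integer(1)))
    # mean pairwise differences via column allele counts
    npairs <- n * (n - 1) / 2
    diff_pairs <- vapply(counts, function(ct) (n^2 - sum(ct^2)) / 2, numeric(1))
    K <- sum(diff_pairs) / npairs
    pi <- if (L > 0) K / L else 0
    haps <- apply(mm, 1, paste, collapse = "")
  } else {
    L <- ncol(m)
    valid <- matrix(m %in% VALID_NT, nrow = n)
    kstates <- vapply(seq_len(L), function(j) {
      length(unique(m[valid[, j], j]))
    }, integer(1))
    S <- sum(kstates >= 2L)
    eta <- sum(pmax(kstates - 1L, 0L))
    eta_s <- sum(vapply(seq_len(L), function(j) {
      col <- m[valid[, j], j]
      ct <- table(col)
      k <- length(ct)
      if (k < 2L) return(0L)
      min(sum(ct == 1L), k - 1L)
    }, integer(1)))
    pairs <- combn(n, 2)
    diffs <- numeric(ncol(pairs)); props <- numeric(ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      ok <- valid[i, ] & valid[j, ]
      d <- sum(m[i, ok] != m[j, ok])
      diffs[p] <- d
      props[p] <- if (any(ok)) d / sum(ok) else 0
    }
    K <- mean(diffs)
    pi <- mean(props)
    haps <- apply(m, 1, paste, collapse = "")
  }

  hap_counts <- table(haps)
  n_hap <- length(hap_counts)
  p_i <- as.numeric(hap_counts) / n
  sum_p2 <- sum(p_i^2)
  Hd <- n / (n - 1) * (1 - sum_p2)
  # Nei (1987) sampling variance of haplotype diversity
  var_hd <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p_i^3) - sum_p2^2) + sum_p2 - sum_p2^2)
  hd_sd <- sqrt(max(var_hd, 0))

  theta_w <- watterson_theta(S, n, max(L, 1L))
  structure(
    list(n = n, L = L, S = S, K = K, pi = pi, n_hap = n_hap,
         Hd = Hd, Hd_sd = hd_sd, theta_w = theta_w,
         eta = eta, eta_s = eta_s, policy = policy),
    class = "diversity_stats"
  )
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("n=%d L=%d S=%d pi=%.5f K=%.3f haplotypes=%d Hd=%.3f (%.3f) theta=%.5f\n",
              x$n, x$L, x$S, x$pi, x$K, x$n_hap, x$Hd, x$Hd_sd, x$theta_w))
  invisible(x)
}

.harmonic <- function(n) sum(1 / seq_len(n))

#' Watterson's theta per site
#' @param S segregating-site count
#' @param n sample size (>= 2)
#' @param L sites used
#' @return theta per site, `S / (a1 * L)`
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2) stop("need n >= 2", call. = FALSE)
  if (L <= 0) stop("need L > 0", call. = FALSE)
  a1 <- .harmonic(n - 1)
  S / (a1 * L)
}

# conventional interval labels, Table-1 style
.p_label <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "P < 0.001"
  else if (p < 0.01) "P < 0.01"
  else if (p < 0.02) "P < 0.02"
  else if (p < 0.05) "P < 0.05"
  else if (p < 0.10) "0.10 > P > 0.05"
  else "not significant"
}

.tajima_coeffs <- function(n) {
  a1 <- .harmonic(n - 1)
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' `D = (K - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the standard coefficient
#' chain. The significance label comes from Tajima's beta-distribution
#' approximation, reported as a conventional interval label.
#'
#' @param aln a `mito_aln`
#' @param policy deletion policy
#' @return list with `D`, `S`, `p`, `label`, `defined`
#' @export
tajimas_d <- function(aln, policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  ds <- diversity_stats(aln, policy)
  tajimas_d_from_stats(ds$S, ds$K, ds$n)
}

#' Tajima's D from summary statistics
#' @param S segregating sites
#' @param K mean pairwise differences
#' @param n sample size
#' @return as [tajimas_d()]
#' @export
tajimas_d_from_stats <- function(S, K, n) {
  if (n < 4) stop("Tajima's D needs n >= 4", call. = FALSE)
  if (S < 1) {
    return(list(D = NA_real_, S = S, p = NA_real_, label = NA_character_,
                defined = FALSE))
  }
  cf <- .tajima_coeffs(n)
  D <- (K - S / cf$a1) / sqrt(cf$e1 * S + cf$e2 * S * (S - 1))
  # beta approximation (Tajima 1989)
  dmin <- (2 / n - 1 / cf$a1) / sqrt(cf$e2)
  dmax <- (n / (2 * (n - 1)) - 1 / cf$a1) / sqrt(cf$e2)
  alpha <- -(1 + dmin * dmax) * dmax / (dmax - dmin)
  beta <- (1 + dmin * dmax) * dmin / (dmax - dmin)
  p <- NA_real_
  if (alpha > 0 && beta > 0) {
    x <- (D - dmin) / (dmax - dmin)
    x <- min(max(x, 0), 1)
    cdf <- stats::pbeta(x, beta, alpha)
    p <- 2 * min(cdf, 1 - cdf)
  }
  list(D = D, S = S, p = p, label = .p_label(p), defined = TRUE)
}

#' Fu & Li's D* and F* (no-outgroup star variants)
#'
#' Uses the total mutation count eta and singleton count eta_s with the
#' corrected star-variant coefficients (the convention followed by standard
#' population-genetics software).
#'
#' @param aln a `mito_aln`
#' @param policy deletion policy
#' @return list with `D_star`, `F_star`, `eta`, `eta_s`, `defined`
#' @export
fu_li_star_tests <- function(aln, policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  ds <- diversity_stats(aln, policy)
  fu_li_star_from_stats(ds$eta, ds$eta_s, ds$K, ds$n)
}

#' Fu & Li's D*/F* from summary statistics
#' @param eta total mutations
#' @param eta_s singleton mutations
#' @param K mean pairwise differences
#' @param n sample size (>= 4)
#' @return as [fu_li_star_tests()]
#' @export
fu_li_star_from_stats <- function(eta, eta_s, K, n) {
  if (n < 4) stop("Fu & Li's tests need n >= 4", call. = FALSE)
  if (eta < 1) {
    return(list(D_star = NA_real_, F_star = NA_real_, eta = eta, eta_s = eta_s,
                defined = FALSE))
  }
  an <- .harmonic(n - 1)
  bn <- sum(1 / seq_len(n - 1)^2)
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  v_D <- ((n / (n - 1))^2 * bn + an^2 * dn -
            2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  u_D <- (n / (n - 1)) * (an - n / (n - 1)) - v_D
  D_star <- ((n / (n - 1)) * eta - an * eta_s) /
    sqrt(u_D * eta + v_D * eta^2)

  v_F <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
            (2 * (n - 1) * an) / n^2 - 8 * bn / n) / (an^2 + bn)
  u_F <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
            (3 * n * (n - 1))) / an - v_F
  F_star <- (K - ((n - 1) / n) * eta_s) / sqrt(u_F * eta + v_F * eta^2)

  list(D_star = D_star, F_star = F_star, eta = eta, eta_s = eta_s,
       defined = TRUE)
}

# log unsigned Stirling numbers of the first kind, |s(n, 1..n)|
.log_stirling1 <- function(n) {
  logs <- 0 # |s(1,1)| = 1
  for (m in 2:n) {
    prev <- logs
    cur <- numeric(m)
    # |s(m,k)| = |s(m-1,k-1)| + (m-1)|s(m-1,k)|
    for (k in 1:m) {
      terms <- c(
        if (k >= 2) prev[k - 1] else NULL,
        if (k <= m - 1) log(m - 1) + prev[k] else NULL
      )
      mx <- max(terms)
      cur[k] <- mx + log(sum(exp(terms - mx)))
    }
    logs <- cur
  }
  logs
}

#' Ewens haplotype-count probabilities
#'
#' `P(k haplotypes | theta, n)` under the Ewens sampling formula, computed in
#' log space with unsigned Stirling numbers of the first kind.
#'
#' @param n sample size
#' @param theta scaled mutation rate (here estimated by K)
#' @return numeric vector of probabilities for k = 1..n
#' @export
ewens_k_probs <- function(n, theta) {
  if (theta <= 0) stop("theta must be > 0", call. = FALSE)
  ls <- .log_stirling1(n)
  log_rising <- sum(log(theta + 0:(n - 1)))
  lp <- ls + (1:n) * log(theta) - log_rising
  exp(lp)
}

#' Fu's Fs
#'
#' `S' = P(k >= k_obs | theta = K)` under the Ewens sampling formula;
#' `Fs = ln(S' / (1 - S'))`. Undefined (with `defined = FALSE`) when all
#' sequences are identical or K = 0.
#'
#' @param aln a `mito_aln`
#' @param policy deletion policy
#' @return list with `Fs`, `S_prime`, `k_obs`, `theta`, `defined`
#' @export
fu_fs <- function(aln, policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  ds <- diversity_stats(aln, policy)
  fu_fs_from_stats(ds$K, ds$n_hap, ds$n)
}

#' Fu's Fs from summary statistics
#' @param K mean pairwise differences (theta estimate)
#' @param k_obs observed haplotype count
#' @param n sample size
#' @return as [fu_fs()]
#' @export
fu_fs_from_stats <- function(K, k_obs, n) {
  if (n < 3) stop("Fu's Fs needs n >= 3", call. = FALSE)
  if (k_obs <= 1 || K <= 0) {
    return(list(Fs = NA_real_, S_prime = NA_real_, k_obs = k_obs,
                theta = K, defined = FALSE))
  }
  probs <- ewens_k_probs(n, K)
  S_prime <- sum(probs[k_obs:n])
  S_prime <- min(max(S_prime, .Machine$double.xmin), 1 - 1e-15)
  list(Fs = log(S_prime / (1 - S_prime)), S_prime = S_prime,
       k_obs = k_obs, theta = K, defined = TRUE)
}

## ---- Nei-Gojobori Ka/Ks -------------------------------------------------

# expected synonymous site count of one codon: sum over positions of the
# fraction of the 3 single-nucleotide changes that are synonymous. Changes to
# stop codons count as nonsynonymous.
.syn_sites_codon <- function(codon, code_table) {
  aa <- code_table[codon]
  if (is.na(aa) || aa == "*") return(NA_real_)
  nb <- codon_neighbors(codon)
  to_aa <- code_table[nb$to]
  syn <- !is.na(to_aa) & to_aa == aa & to_aa != "*"
  sum(syn) / 3
}

# syn/nonsyn difference counts between two codons, averaged over all minimal
# mutational pathways that avoid stop codons (all pathways used if every one
# passes through a stop).
.codon_pair_diffs <- function(c1, c2, code_table) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(syn = 0, nonsyn = 0))
  perms <- if (nd == 1) list(pos) else {
    idx <- seq_len(nd)
    ords <- if (nd == 2) list(c(1, 2), c(2, 1)) else {
      out <- list(); k <- 0
      for (i in 1:3) for (j in setdiff(1:3, i)) {
        k <- k + 1; out[[k]] <- c(i, j, setdiff(1:3, c(i, j)))
      }
      out
    }
    lapply(ords, function(o) pos[o])
  }
  path_counts <- list()
  for (pw in perms) {
    cur <- strsplit(c1, "")[[1]]
    tgt <- strsplit(c2, "")[[1]]
    sy <- 0; ns <- 0; ok <- TRUE
    for (p in pw) {
      nxt <- cur
      nxt[p] <- tgt[p]
      aa_cur <- code_table[paste(cur, collapse = "")]
      aa_nxt <- code_table[paste(nxt, collapse = "")]
      if (aa_nxt == "*") { ok <- FALSE; break }
      if (aa_cur == aa_nxt) sy <- sy + 1 else ns <- ns + 1
      cur <- nxt
    }
    if (ok) path_counts[[length(path_counts) + 1]] <- c(sy, ns)
  }
  if (!length(path_counts)) { # all pathways blocked by stops: use them anyway
    for (pw in perms) {
      cur <- strsplit(c1, "")[[1]]
      tgt <- strsplit(c2, "")[[1]]
      sy <- 0; ns <- 0
      for (p in pw) {
        nxt <- cur
        nxt[p] <- tgt[p]
        aa_cur <- code_table[paste(cur, collapse = "")]
        aa_nxt <- code_table[paste(nxt, collapse = "")]
        if (!is.na(aa_cur) && !is.na(aa_nxt) && aa_cur == aa_nxt &&
            aa_nxt != "*") sy <- sy + 1 else ns <- ns + 1
        cur <- nxt
      }
      path_counts[[length(path_counts) + 1]] <- c(sy, ns)
    }
  }
  avg <- Reduce(`+`, path_counts) / length(path_counts)
  c(syn = avg[1], nonsyn = avg[2])
}

#' Nei-Gojobori Ka/Ks
#'
#' Expected synonymous/nonsynonymous site counts per codon by the 1/3-weighted
#' single-step rule; multi-step codon differences averaged over all minimal
#' mutational pathways; proportions Jukes-Cantor corrected
#' `d = -(3/4) ln(1 - (4/3) p)`; pairwise values averaged over all pairs.
#' Codons containing gaps, Ns or stops are skipped pairwise.
#'
#' @param caln a `codon_aln`
#' @return list of class `kaks_result`: `syn_sites`, `nonsyn_sites` (mean
#'   expected site counts), `syn_count`, `nonsyn_count` (observed substitution
#'   tallies per codon column, pathway-averaged against the majority codon),
#'   `Ks`, `Ka`, `ratio`, `n_pairs`, `undefined_pairs`
#' @export
nei_gojobori <- function(caln) {
  code_table <- caln$code_table
  cm <- caln$codons
  n <- nrow(cm)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  ok <- !grepl("[N-]", cm)
  aa <- matrix(code_table[cm], nrow = n)
  ok <- ok & !is.na(aa) & aa != "*"

  # cache per-codon expected syn sites and pairwise diff classifications
  syn_site_cache <- new.env(parent = emptyenv())
  get_ss <- function(cd) {
    v <- syn_site_cache[[cd]]
    if (is.null(v)) {
      v <- .syn_sites_codon(cd, code_table)
      syn_site_cache[[cd]] <- v
    }
    v
  }
  diff_cache <- new.env(parent = emptyenv())
  get_diff <- function(c1, c2) {
    key <- paste0(c1, c2)
    v <- diff_cache[[key]]
    if (is.null(v)) {
      v <- .codon_pair_diffs(c1, c2, code_table)
      diff_cache[[key]] <- v
    }
    v
  }

  pairs <- combn(n, 2)
  Ka_v <- Ks_v <- S_v <- N_v <- rep(NA_real_, ncol(pairs))
  undef <- 0L
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    use <- ok[i, ] & ok[j, ]
    if (!any(use)) next
    ci <- cm[i, use]; cj <- cm[j, use]
    Si <- sum(vapply(ci, get_ss, numeric(1)))
    Sj <- sum(vapply(cj, get_ss, numeric(1)))
    S <- (Si + Sj) / 2
    N <- 3 * sum(use) - S
    dsum <- c(syn = 0, nonsyn = 0)
    dif <- which(ci != cj)
    for (k in dif) dsum <- dsum + get_diff(ci[k], cj[k])
    ps <- if (S > 0) dsum[["syn"]] / S else 0
    pn <- if (N > 0) dsum[["nonsyn"]] / N else 0
    S_v[p] <- S; N_v[p] <- N
    if (ps >= 3 / 4 || pn >= 3 / 4) { undef <- undef + 1L; next }
    Ks_v[p] <- -3 / 4 * log(1 - 4 / 3 * ps)
    Ka_v[p] <- -3 / 4 * log(1 - 4 / 3 * pn)
  }

  # observed substitution tallies per codon column (minor variants vs the
  # column majority codon, pathway-averaged)
  syn_count <- 0; nonsyn_count <- 0
  for (j in seq_len(ncol(cm))) {
    col <- cm[ok[, j], j]
    if (!length(col)) next
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) < 2) next
    major <- names(tab)[1]
    for (v in names(tab)[-1]) {
      d <- get_diff(major, v)
      syn_count <- syn_count + d[["syn"]]
      nonsyn_count <- nonsyn_count + d[["nonsyn"]]
    }
  }

  Ks <- mean(Ks_v, na.rm = TRUE)
  Ka <- mean(Ka_v, na.rm = TRUE)
  if (is.nan(Ks)) Ks <- NA_real_
  if (is.nan(Ka)) Ka <- NA_real_
  structure(
    list(syn_sites = mean(S_v, na.rm = TRUE),
         nonsyn_sites = mean(N_v, na.rm = TRUE),
         syn_count = round(syn_count), nonsyn_count = round(nonsyn_count),
         Ks = Ks, Ka = Ka,
         ratio = kaks_ratio(Ka, Ks),
         n_pairs = ncol(pairs), undefined_pairs = undef),
    class = "kaks_result"
  )
}

#' Ka/Ks ratio
#' @param Ka nonsynonymous rate
#' @param Ks synonymous rate
#' @return Ka/Ks; `NA` when Ks is 0 or missing
#' @export
kaks_ratio <- function(Ka, Ks) {
  if (is.na(Ka) || is.na(Ks) || Ks == 0) return(NA_real_)
  Ka / Ks
}

#' Relative mutation rate of a gene
#'
#' The per-gene rate relative to the whole-mitogenome rate, computed as
#' `theta_gene / theta_genome` and truncated (not rounded) to 2 decimals, the
#' form consistent with published per-gene relative-rate tables.
#'
#' @param theta_gene Watterson's theta of the gene (per site)
#' @param theta_genome Watterson's theta of the whole alignment (per site)
#' @return unitless ratio, truncated to 2 decimals
#' @export
relative_mutation_rate <- function(theta_gene, theta_genome) {
  if (theta_genome <= 0) stop("theta_genome must be > 0", call. = FALSE)
  floor(theta_gene / theta_genome * 100 + 1e-9) / 100
}

#' Neutrality-test summary for an alignment
#'
#' Convenience wrapper returning Tajima's D, Fu & Li's D*/F* and Fu's Fs with
#' interval-style significance labels for D.
#'
#' @param aln a `mito_aln`
#' @param policy deletion policy
#' @return list of class `neutrality_result`
#' @export
neutrality_tests <- function(aln, policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  ds <- diversity_stats(aln, policy)
  td <- tajimas_d_from_stats(ds$S, ds$K, ds$n)
  fl <- fu_li_star_from_stats(ds$eta, ds$eta_s, ds$K, ds$n)
  fs <- fu_fs_from_stats(ds$K, ds$n_hap, ds$n)
  structure(
    list(tajima_d = td$D, tajima_label = td$label,
         fu_li_d_star = fl$D_star, fu_li_f_star = fl$F_star,
         fu_fs = fs$Fs, stats = ds),
    class = "neutrality_result"
  )
}
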