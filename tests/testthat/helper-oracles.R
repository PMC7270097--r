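# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own algorithms: plain enumeration and direct arithmetic.

# all set partitions of 1..n (for the Ewens sampling oracle)
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in set_partitions(n - 1L)) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# exact P(k haplotypes >= k_obs) by summing the Ewens probability of every
# set partition
ewens_tail_oracle <- function(n, theta, k_obs) {
  ps <- set_partitions(n)
  pr <- vapply(ps, function(p) {
    k <- length(p)
    theta^k * prod(vapply(p, function(b) factorial(length(b) - 1), numeric(1))) /
      prod(theta + 0:(n - 1))
  }, numeric(1))
  ks <- vapply(ps, length, integer(1))
  sum(pr[ks >= k_obs])
}

# maximum number of non-crossing pairs (min hairpin 3) by recursion
can_pair_rna <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}
max_pairs_oracle <- function(x, i = 1, j = length(x)) {
  if (j - i < 4) return(0L)
  best <- max_pairs_oracle(x, i, j - 1)
  for (k in i:(j - 4)) {
    if (!can_pair_rna(x[k], x[j])) next
    v <- 1L + (if (k > i) max_pairs_oracle(x, i, k - 1) else 0L) +
      max_pairs_oracle(x, k + 1, j - 1)
    if (v > best) best <- v
  }
  best
}

# exhaustive Fitch minimum: minimize changes over all internal labelings
fitch_min_oracle <- function(tree, tip_states) {
  states <- sort(unique(tip_states[!is.na(tip_states)]))
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  tip_states <- tip_states[tree$tip.label]
  grid <- as.matrix(expand.grid(rep(list(seq_along(states)), nint)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    lab <- c(match(tip_states, states), grid[g, ])
    cost <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      a <- lab[tree$edge[e, 1]]; b <- lab[tree$edge[e, 2]]
      if (!is.na(a) && !is.na(b) && a != b) cost <- cost + 1L
    }
    if (cost < best) best <- cost
  }
  best
}

# random small nucleotide alignment
random_alignment <- function(n, L, seed) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), nrow = n)
  rownames(m) <- paste0("s", seq_len(n))
  aln_from_matrix(m)
}

random_dna <- function(L, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}
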