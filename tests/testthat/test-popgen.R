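test_that("diversity statistics match hand-enumerated pairwise counts", {
  # 4 identical sequences
  a0 <- new_alignment(setNames(rep("ACGTACGT", 4), paste0("s", 1:4)))
  d0 <- diversity_stats(a0)
  expect_equal(d0$S, 0)
  expect_equal(d0$K, 0)
  expect_equal(d0$n_hap, 1)
  expect_equal(d0$Hd, 0)

  # n = 4, one column A/A/A/T: 3 of 6 pairs differ -> K = 0.5;
  # Hd = (4/3)(1 - (9/16 + 1/16)) = 0.5
  a1 <- new_alignment(c(s1 = "AACC", s2 = "AACC", s3 = "AACC", s4 = "TACC"))
  d1 <- diversity_stats(a1)
  expect_equal(d1$S, 1)
  expect_equal(d1$K, 0.5)
  expect_equal(d1$n_hap, 2)
  expect_equal(d1$Hd, 0.5)
  expect_equal(d1$pi * d1$L, d1$K)

  expect_error(diversity_stats(new_alignment(c(x = "ACGT"))), "at least 2")
})

test_that("pi * L = K holds exactly under complete deletion on random alignments", {
  for (seed in 1:6) {
    aln <- random_alignment(n = 5 + seed, L = 120, seed = seed)
    ds <- diversity_stats(aln, "complete")
    expect_equal(ds$pi * ds$L, ds$K, tolerance = 1e-12)
  }
})

test_that("statistics are invariant under sequence reordering and relabeling", {
  aln <- random_alignment(8, 200, seed = 31)
  perm <- sample(seq_along(aln$ids))
  seqs2 <- aln$seqs[perm]
  names(seqs2) <- paste0("x", seq_along(seqs2))
  aln2 <- new_alignment(seqs2)
  d1 <- diversity_stats(aln); d2 <- diversity_stats(aln2)
  expect_equal(d1[c("S", "K", "pi", "n_hap", "Hd", "theta_w", "eta", "eta_s")],
               d2[c("S", "K", "pi", "n_hap", "Hd", "theta_w", "eta", "eta_s")])
  expect_equal(tajimas_d(aln)$D, tajimas_d(aln2)$D)
  expect_equal(fu_fs(aln)$Fs, fu_fs(aln2)$Fs)
})

test_that("Watterson's theta matches the harmonic-sum arithmetic", {
  expect_equal(watterson_theta(0, 10, 100), 0)
  expect_equal(watterson_theta(4, 5, 1), 4 / (1 + 1/2 + 1/3 + 1/4))
  expect_error(watterson_theta(1, 1, 10), "n >= 2")
  expect_error(watterson_theta(1, 5, 0), "L > 0")
})

test_that("Tajima's D equals an independent evaluation of the coefficient chain", {
  aln <- new_alignment(c(a = "AAAA", b = "AAAT", c = "AAGT", d = "AAAA",
                         e = "AAAA"))
  ds <- diversity_stats(aln)
  # independent arithmetic: n = 5, S = 2, K from the 10 pairs by hand
  n <- 5; S <- 2
  # pairwise differences by hand: ab=1 ac=2 ad=0 ae=0 bc=1 bd=1 be=1 cd=2 ce=2 de=0
  K <- (1 + 2 + 0 + 0 + 1 + 1 + 1 + 2 + 2 + 0) / 10
  a1 <- sum(1 / 1:4); a2 <- sum(1 / (1:4)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D_hand <- (K - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(tajimas_d(aln)$D, D_hand, tolerance = 1e-12)
  expect_equal(ds$K, K)
})

test_that("undefined neutrality statistics are explicit, never silent zeros", {
  mono <- new_alignment(setNames(rep("ACGTAC", 5), paste0("s", 1:5)))
  td <- tajimas_d(mono)
  expect_false(td$defined)
  expect_true(is.na(td$D))
  fl <- fu_li_star_tests(mono)
  expect_false(fl$defined)
  fs <- fu_fs(mono)
  expect_false(fs$defined)
})

test_that("Fu & Li's D* is strongly negative when every variant is a singleton", {
  # 6 sequences, 8 variable columns, each variant in exactly one sequence
  base <- strrep("A", 24)
  seqs <- vapply(1:6, function(i) {
    x <- strsplit(base, "")[[1]]
    x[(3 * i - 2):(3 * i)] <- "T" # each sequence's variants are its own
    paste(x, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", 1:6)
  aln <- new_alignment(seqs)
  ds <- diversity_stats(aln)
  expect_equal(ds$eta, ds$eta_s) # all singletons by construction
  fl <- fu_li_star_tests(aln)
  expect_lt(fl$D_star, 0)
})

test_that("Fu's Fs is negative with many unique haplotypes and small K", {
  # 8 haplotypes each differing from a base sequence at its own single site
  base <- strrep("ACGT", 10)
  seqs <- vapply(1:8, function(i) {
    x <- strsplit(base, "")[[1]]
    x[i * 4] <- setdiff(c("A", "C", "G", "T"), x[i * 4])[1]
    paste(x, collapse = "")
  }, character(1))
  names(seqs) <- paste0("h", 1:8)
  fs <- fu_fs(new_alignment(seqs))
  expect_true(fs$defined)
  expect_lt(fs$Fs, 0)
})

test_that("Nei-Gojobori matches single-step enumeration on toy codons", {
  code <- genetic_code("standard")
  # TTT (Phe): only TTC at position 3 is synonymous -> 1/3 synonymous site
  expect_equal(mitoscan:::.syn_sites_codon("TTT", code), 1 / 3)
  caln <- to_codon_alignment(new_alignment(c(x = "TTT", y = "TTA")), code,
                             trim_stop = FALSE)
  ng <- nei_gojobori(caln)
  # pairwise expected sites: (s(TTT) + s(TTA)) / 2 = (1/3 + 2/3) / 2
  expect_equal(ng$syn_sites, 0.5)
  expect_equal(ng$nonsyn_count, 1) # Phe -> Leu is nonsynonymous
  expect_equal(ng$syn_count, 0)
  expect_gt(ng$Ka, 0)
  expect_equal(ng$Ks, 0)

  ident <- to_codon_alignment(new_alignment(c(x = "ATGAAA", y = "ATGAAA")),
                              code, trim_stop = FALSE)
  ng0 <- nei_gojobori(ident)
  expect_equal(ng0$Ka, 0)
  expect_equal(ng0$Ks, 0)
})

test_that("Nei-Gojobori site counts sum to 3 x codons for gap-free input", {
  set.seed(12)
  tree <- simulate_tree(5, "coalescent", seed = 12, target_height = 0.4)
  sim <- simulate_codon_alignment(tree, 25, omega_profile = rep(0.5, 25),
                                  seed = 13)
  ng <- nei_gojobori(sim$caln)
  expect_equal(ng$syn_sites + ng$nonsyn_sites, 3 * sim$caln$n_codons,
               tolerance = 1e-9)
})

test_that("relative mutation rate truncates theta ratios to two decimals", {
  expect_equal(relative_mutation_rate(0.00611, 0.00611), 1.00)
  expect_equal(relative_mutation_rate(0.00898, 0.00611), 1.46)
  expect_equal(relative_mutation_rate(0.00392, 0.00611), 0.64)
  expect_error(relative_mutation_rate(0.1, 0), "theta_genome")
})

test_that("Ewens haplotype-count probabilities sum to one", {
  for (theta in c(0.5, 1, 3, 10)) {
    p <- ewens_k_probs(12, theta)
    expect_equal(sum(p), 1, tolerance = 1e-10)
    expect_true(all(p >= 0))
  }
})
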