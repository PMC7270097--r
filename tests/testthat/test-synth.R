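test_that("generators are pure functions of seed and parameters", {
  t1 <- simulate_tree(10, "coalescent", seed = 5)
  t2 <- simulate_tree(10, "coalescent", seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_false(identical(ape::write.tree(t1),
                         ape::write.tree(simulate_tree(10, "coalescent", 6))))

  s1 <- simulate_codon_alignment(t1, 20, seed = 7)
  s2 <- simulate_codon_alignment(t1, 20, seed = 7)
  expect_identical(s1$caln$codons, s2$caln$codons)

  c1 <- simulate_control_regions(6, seed = 8)
  c2 <- simulate_control_regions(6, seed = 8)
  expect_identical(c1$seqs, c2$seqs)

  e1 <- simulate_env_glm_dataset(1, 10, seed = 9)
  e2 <- simulate_env_glm_dataset(1, 10, seed = 9)
  expect_identical(e1$individuals, e2$individuals)
})

test_that("a coalescent tree has the right shape", {
  tr <- simulate_tree(45, "coalescent", seed = 2)
  expect_equal(ape::Ntip(tr), 45)
  expect_equal(tr$Nnode, 44) # 44 coalescences
  expect_true(ape::is.binary(tr))
})

test_that("n = 2 coalescent depth follows Exp(1)", {
  depths <- vapply(1:600, function(s) {
    tr <- simulate_tree(2, "coalescent", seed = s)
    tr$edge.length[1]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(depths, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("omega = 0 forbids nonsynonymous change; zero-length trees copy the root", {
  tr <- simulate_tree(6, "coalescent", seed = 3, target_height = 1)
  sim0 <- simulate_codon_alignment(tr, 30, omega_profile = rep(0, 30), seed = 4)
  aa <- sim0$caln$aa
  expect_true(all(apply(aa, 2, function(col) length(unique(col)) == 1)))

  tr0 <- tr; tr0$edge.length[] <- 0
  simz <- simulate_codon_alignment(tr0, 10, seed = 5)
  expect_true(all(apply(simz$caln$codons, 2,
                        function(col) length(unique(col)) == 1)))
})

test_that("at omega = 1 the observed N/S change ratio matches the code's opportunity ratio", {
  # shallow tree so parsimony counting is a faithful event count
  tr <- simulate_tree(12, "coalescent", seed = 6, target_height = 0.25)
  sim <- simulate_codon_alignment(tr, 800, omega_profile = rep(1, 800), seed = 7)
  model <- sim$truth$model
  # expected ratio of nonsyn to syn flux at stationarity (independent of the
  # simulation path: computed from the generator parts)
  exp_ratio <- sum(model$pi * rowSums(model$B)) / sum(model$pi * rowSums(model$A))
  # observed: classify parsimony changes on the alignment
  aa_mat <- sim$caln$aa; rownames(aa_mat) <- sim$caln$ids
  cod <- sim$caln$codons; rownames(cod) <- sim$caln$ids
  fit_aa <- fitch_ancestral_changes(tr, aa_mat)
  fit_cod <- fitch_ancestral_changes(tr, cod)
  n_total <- sum(fit_cod$n_changes)
  n_nonsyn <- sum(fit_aa$n_changes)
  obs_ratio <- n_nonsyn / (n_total - n_nonsyn)
  expect_lt(abs(obs_ratio / exp_ratio - 1), 0.10)
})

test_that("mitogenome-like alignments live in the published diversity regime", {
  aln <- simulate_mitogenome_alignment(n = 45, L = 16600, pi = 0.006, seed = 11)
  ds <- diversity_stats(aln)
  expect_gt(ds$pi, 0.003)
  expect_lt(ds$pi, 0.01)
  expect_equal(ds$n_hap, 45) # every haplotype unique at this depth
  expect_setequal(unique(aln$metadata$region), c("NAS", "SEAS", "BoB"))
  # the expansion genealogy leaves the expected excess of rare variants
  expect_lt(tajimas_d_from_stats(ds$S, ds$K, ds$n)$D, -1)
})

test_that("control-region generator honors copy distribution and slippage off", {
  cr <- simulate_control_regions(30, copy_dist = c("2" = 1), point_mu = 0,
                                 slip_prob = 0, seed = 12)
  expect_true(all(cr$truth$copies == 2))
  expect_equal(length(unique(cr$seqs)), 1) # no mutation, all identical
  # detector-recovered type frequencies match the draw within binomial noise
  cr2 <- simulate_control_regions(60, copy_dist = c("1" = 0.8, "2" = 0.15,
                                                    "3" = 0.05),
                                  point_mu = 0.005, seed = 13)
  catalog <- read_unit_catalog()
  rec <- vapply(cr2$seqs, function(s) {
    ann <- detect_tandem_repeats(s, catalog = catalog)
    if (nrow(ann) == 0) return(NA_real_)
    classify_repeat_type(ann[1, ], catalog)$copies
  }, numeric(1))
  expect_equal(unname(round(rec)), unname(cr2$truth$copies))
})

test_that("tRNA-like cloverleaves fold with strongly negative dG/length", {
  tr <- simulate_trna_like(4, seed = 14)
  rel <- vapply(tr, function(s) relative_free_energy(fold_min_energy(s, "rna")),
                numeric(1))
  expect_true(all(rel < -0.05))
})
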