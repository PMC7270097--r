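test_that("NJ fallback recovers an additive 4-taxon tree", {
  # build sequences whose K2P distances are approximately additive on
  # ((a,b),(c,d)): a-b close, c-d close, cross pairs distant
  set.seed(8)
  L <- 3000
  root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mutate <- function(x, k) {
    pos <- sample.int(L, k)
    x[pos] <- vapply(x[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                     character(1))
    x
  }
  anc1 <- mutate(root, 150); anc2 <- mutate(root, 150)
  m <- rbind(a = mutate(anc1, 30), b = mutate(anc1, 30),
             c = mutate(anc2, 30), d = mutate(anc2, 30))
  aln <- aln_from_matrix(m)
  tr <- nj_fallback_tree(aln)
  expect_s3_class(tr, "phylo")
  expect_true(all(tr$edge.length >= 0))
  # topology: a,b form a cherry
  pair <- ape::prop.part(tr)
  expect_true(ape::is.monophyletic(tr, c("a", "b")) ||
                ape::is.monophyletic(tr, c("c", "d")))
})

test_that("NJ fallback on 3 taxa and identical sequences behaves as forced", {
  aln3 <- simulate_neutral_alignment(3, theta = 6, L = 400, seed = 2)
  tr3 <- nj_fallback_tree(aln3)
  expect_equal(ape::Ntip(tr3), 3)
  ident <- new_alignment(setNames(rep(strrep("ACGT", 30), 4), paste0("s", 1:4)))
  tr0 <- nj_fallback_tree(ident)
  expect_equal(sum(tr0$edge.length), 0)
  # saturated distances raise an error naming the offending pair
  expect_error(nj_fallback_tree(random_alignment(3, 200, seed = 2)),
               "saturated")
})

test_that("grid posteriors are proper probabilities partitioned by the diagonal", {
  tree <- simulate_tree(8, "coalescent", seed = 3, target_height = 0.8)
  sim <- simulate_codon_alignment(tree, 30, omega_profile = rep(0.5, 30),
                                  seed = 4)
  gs <- grid_bayes_scan(sim$caln, tree)
  expect_true(all(gs$sites$posterior_pos >= 0 & gs$sites$posterior_pos <= 1))
  expect_true(all(gs$sites$posterior_pos + gs$sites$posterior_neg <= 1 + 1e-9))
  expect_equal(sum(gs$grid$weight), 1, tolerance = 1e-9)
})

test_that("invariant columns never reach the positive-selection threshold", {
  tree <- simulate_tree(8, "coalescent", seed = 3, target_height = 0.8)
  sim <- simulate_codon_alignment(tree, 30, omega_profile = rep(0.3, 30),
                                  seed = 5)
  inv <- which(apply(sim$caln$codons, 2, function(z) length(unique(z)) == 1))
  gs <- grid_bayes_scan(sim$caln, tree)
  if (length(inv)) {
    expect_true(all(gs$sites$posterior_pos[gs$sites$site %in% inv] < 0.9))
  }
  es <- episodic_scan(sim$caln, tree, sites = inv[seq_len(min(3, length(inv)))])
  expect_true(all(es$p == 1))
  expect_true(all(es$status == "invariant"))
})

test_that("episodic scan detects multi-branch bursts and stays calibrated", {
  # burst on ~37% of branches at omega = 20 (the regime where a per-site
  # branch-mixture LRT is informative), tree height 2, 20 taxa
  tree <- simulate_tree(20, "coalescent", seed = 21, target_height = 2)
  set.seed(77)
  burst_nodes <- sample(tree$edge[, 2], 14)
  sim <- simulate_codon_alignment(
    tree, 24, omega_profile = rep(0.2, 24), seed = 22,
    episodic = list(child_node = burst_nodes, sites = 1:12, omega = 20))
  es <- episodic_scan(sim$caln, tree, sites = 1:24)
  expect_gte(sum(es$flagged[1:12]), 6)        # power >= 0.5
  expect_lte(sum(es$flagged[13:24]), 1)       # approximate type-I control
  expect_true(all(es$p >= 0 & es$p <= 1))
})

test_that("consensus rule requires two of three methods and is monotone", {
  gs <- data.frame(site = 1:5, posterior_pos = c(0.95, 0.5, 0.92, 0.2, 0.99),
                   flagged_positive = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  es <- data.frame(site = 1:5, p = c(0.03, 0.02, 0.5, 0.7, 0.01),
                   flagged = c(TRUE, TRUE, FALSE, FALSE, TRUE))
  cons <- consensus_positive_sites(gs, es, physchem_sites = c(3L),
                                   n_sites = 5)
  expect_true(cons$consensus_positive[1])   # grid + episodic
  expect_false(cons$consensus_positive[2])  # episodic only
  expect_true(cons$consensus_positive[3])   # grid + physchem
  expect_false(cons$consensus_positive[4])
  # >=2-method set is a subset of the >=1-method set
  cons1 <- consensus_positive_sites(gs, es, physchem_sites = c(3L),
                                    n_sites = 5, min_methods = 1)
  expect_true(all(cons$site[cons$consensus_positive] %in%
                    cons1$site[cons1$consensus_positive]))
  expect_error(consensus_positive_sites(gs, es, physchem_sites = 9L,
                                        n_sites = 5), "coordinate")
})
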