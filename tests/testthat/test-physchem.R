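props <- read_aa_properties()

test_that("the packaged property table covers all residues and 31 scales", {
  expect_equal(nrow(props), 20)
  expect_equal(ncol(props), 31)
  expect_true(all(c("polarity", "hydropathy", "isoelectric_point",
                    "chromatographic_index", "molecular_volume") %in%
                    names(props)))
  expect_false(any(is.na(props)))
})

test_that("magnitude categories are symmetric with the forced edge cases", {
  for (p in c("polarity", "hydropathy", "molecular_volume")) {
    expect_equal(categorize_change(props, "A", "A", p), 1L)
    # the extreme pair for the property is category 8 by construction
    v <- props[[p]]
    lo <- rownames(props)[which.min(v)]; hi <- rownames(props)[which.max(v)]
    expect_equal(categorize_change(props, lo, hi, p), 8L)
    # symmetry on random pairs
    set.seed(3)
    for (k in 1:10) {
      ab <- sample(rownames(props), 2)
      expect_equal(categorize_change(props, ab[1], ab[2], p),
                   categorize_change(props, ab[2], ab[1], p))
    }
  }
  expect_error(categorize_change(props, "A", "Z", "polarity"), "unknown residue")
  expect_error(categorize_change(props, "A", "V", "nope"), "unknown property")
})

test_that("Glu to Leu is a radical hydropathy shift", {
  expect_gte(categorize_change(props, "E", "L", "hydropathy"), 6L)
})

test_that("Fitch counts match hand enumeration on a 4-leaf split", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  aa <- matrix(c("A", "A", "V", "V"), ncol = 1,
               dimnames = list(c("a", "b", "c", "d"), NULL))
  fit <- fitch_ancestral_changes(tr, aa)
  expect_equal(fit$n_changes, 1L)
  expect_equal(nrow(fit$changes), 1L)
  expect_setequal(c(fit$changes$from, fit$changes$to), c("A", "V"))

  # invariant site
  aa2 <- matrix("A", nrow = 4, ncol = 1, dimnames = list(letters[1:4], NULL))
  expect_equal(fitch_ancestral_changes(tr, aa2)$n_changes, 0L)
})

test_that("Fitch counts equal the exhaustive minimum on random 5-leaf instances", {
  set.seed(17)
  for (rep in 1:25) {
    tr <- ape::rtree(5)
    tr$tip.label <- letters[1:5]
    states <- sample(c("A", "V", "L", "S"), 5, replace = TRUE)
    names(states) <- letters[1:5]
    aa <- matrix(states, ncol = 1, dimnames = list(letters[1:5], NULL))
    fit <- fitch_ancestral_changes(tr, aa)
    oracle <- fitch_min_oracle(tr, states)
    expect_equal(fit$n_changes[1], oracle)
    # the emitted labeling realizes the minimum
    expect_equal(nrow(fit$changes), oracle)
  }
})

test_that("Fitch change counts are invariant to re-rooting", {
  set.seed(23)
  tr <- ape::rtree(7)
  states <- sample(c("A", "V", "L"), 7, replace = TRUE)
  names(states) <- tr$tip.label
  aa <- matrix(states, ncol = 1, dimnames = list(tr$tip.label, NULL))
  n1 <- fitch_ancestral_changes(tr, aa)$n_changes
  tr2 <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[4],
                   resolve.root = TRUE)
  n2 <- fitch_ancestral_changes(tr2, aa)$n_changes
  expect_equal(n1, n2)
})

test_that("z-test flags a planted excess in one radical category", {
  # plant all observed changes in polarity's most radical achievable cell
  v <- props$polarity; names(v) <- rownames(props)
  lo <- names(v)[which.min(v)]; hi <- names(v)[which.max(v)]
  changes <- data.frame(from = rep(lo, 30), to = rep(hi, 30))
  zt <- property_z_test(changes, props["polarity"], genetic_code())
  k <- categorize_change(props, lo, hi, "polarity")
  cell <- zt[zt$property == "polarity" & zt$category == k, ]
  if (cell$expected_p > 0) {
    expect_gt(cell$z, 0)
    expect_lt(cell$p, 0.001)
    expect_true(cell$flagged || k < 6)
  } else {
    expect_match(cell$note, "zero expected")
  }
  expect_error(property_z_test(changes[0, ], props), "no inferred changes")
})

test_that("under neutral sampling, significant cells are rare", {
  # draw changes from the neutral expectation itself and check calibration
  pairs <- nonsyn_neighbor_pairs(genetic_code())
  set.seed(99)
  idx <- sample(nrow(pairs), 400, replace = TRUE)
  changes <- data.frame(from = pairs$aa_from[idx], to = pairs$aa_to[idx])
  zt <- property_z_test(changes, props)
  tested <- zt[!is.na(zt$p), ]
  frac <- mean(tested$p < 0.001)
  expect_lt(frac, 0.01)
})

test_that("physchem_scan ties parsimony changes to flagged property cells", {
  tree <- simulate_tree(8, "coalescent", seed = 41, target_height = 1)
  sim <- simulate_codon_alignment(tree, 30, omega_profile = rep(1, 30),
                                  seed = 42)
  ps <- physchem_scan(sim$caln, tree)
  expect_true(all(ps$sites %in% seq_len(sim$caln$n_codons)))
  if (nrow(ps$site_properties)) {
    expect_true(all(ps$site_properties$category >= 6))
  }
})
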