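catalog <- read_unit_catalog()

test_that("planted tandem repeats are recovered with period and copies", {
  set.seed(3)
  unit <- catalog[["unit38_type1"]]
  for (k in 1:3) {
    s <- paste0(random_dna(200), strrep(unit, k), random_dna(200))
    ann <- detect_tandem_repeats(s, catalog = catalog)
    expect_equal(nrow(ann), 1)
    expect_equal(ann$period, 38)
    cl <- classify_repeat_type(ann[1, ], catalog)
    expect_equal(cl$type, paste("Type", k))
  }
})

test_that("single-copy units need the catalog; de-novo alone misses them", {
  set.seed(4)
  s <- paste0(random_dna(150), catalog[["unit38_type1"]], random_dna(150))
  expect_equal(nrow(detect_tandem_repeats(s)), 0)
  ann <- detect_tandem_repeats(s, catalog = catalog)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$copies, 1)
  expect_match(ann$source, "catalog")
})

test_that("random sequences yield no repeat annotations (quick screen)", {
  set.seed(5)
  hits <- sum(vapply(1:40, function(i) {
    nrow(detect_tandem_repeats(random_dna(1000))) > 0
  }, logical(1)))
  expect_lte(hits, 2)
})

test_that("fractional copies round half-down with a partial-copy note", {
  ann <- data.frame(start = 1, end = 95, period = 38, copies = 2.5,
                    unit = catalog[["unit38_type1"]], identity = 1,
                    source = "denovo")
  cl <- classify_repeat_type(ann, catalog)
  expect_equal(cl$type, "Type 2")
  expect_true(cl$partial_copy)
  ann$copies <- 4.2
  expect_match(classify_repeat_type(ann, catalog)$type, ">3")
})

test_that("motif annotation reports exact hits, poly-A, and absences", {
  cfg <- read_motif_config()
  set.seed(6)
  s <- paste0(random_dna(50), cfg$pattern[cfg$name == "CSB2"],
              random_dna(20), "AAAAAAA", random_dna(30))
  mt <- annotate_motifs(s, cfg)
  csb2 <- mt[mt$name == "CSB2", ]
  expect_true(csb2$found)
  expect_equal(csb2$mismatches, 0)
  expect_equal(csb2$start, 51)
  pa <- mt[mt$name == "poly_A", ]
  expect_true(pa$found)
  expect_gte(pa$end - pa$start + 1, 7)
  # pattern absent everywhere -> "not found", never fabricated
  strict <- data.frame(name = "X", pattern = "GGGGGGGGGGGGGGGGGGGG",
                       max_mismatch = 0)
  mt2 <- annotate_motifs(paste(rep("ACT", 60), collapse = ""), strict)
  expect_false(mt2$found[mt2$name == "X"])
})

test_that("Nussinov pair counts equal exhaustive enumeration (length <= 12)", {
  f <- fold_nussinov("GGGAAAACCC")
  expect_equal(f$n_pairs, 3)
  expect_equal(fold_nussinov("AAAA")$n_pairs, 0)
  set.seed(7)
  for (r in 1:60) {
    L <- sample(5:12, 1)
    s <- random_dna(L, alphabet = c("A", "C", "G", "U"))
    x <- strsplit(s, "")[[1]]
    expect_equal(fold_nussinov(s)$n_pairs, max_pairs_oracle(x), info = s)
  }
})

test_that("dot-bracket strings are balanced and pairs non-crossing", {
  set.seed(8)
  for (r in 1:20) {
    s <- random_dna(sample(20:60, 1))
    f <- fold_min_energy(s, "rna")
    db <- strsplit(f$structure, "")[[1]]
    expect_equal(sum(db == "("), sum(db == ")"))
    depth <- cumsum((db == "(") - (db == ")"))
    expect_true(all(depth >= 0))
    # non-crossing: partners are properly nested
    pr <- f$pairs
    op <- which(!is.na(pr) & pr > seq_along(pr))
    for (i in op) {
      inside <- (i + 1):(pr[i] - 1)
      expect_true(all(is.na(pr[inside]) |
                        (pr[inside] >= i & pr[inside] <= pr[i])))
    }
  }
})

test_that("minimum energy respects hand-summed parameters and bounds", {
  par <- load_energy_params("rna")
  # perfect 6-bp GC hairpin with a 4-nt loop: 5 GC/GC stacks + hairpin(4)
  f <- fold_min_energy("GGGGGGAAAACCCCCC", "rna")
  expect_equal(f$energy, 5 * par$stack["GC", "GC"] + par$hairpin[5],
               tolerance = 1e-9)
  expect_equal(fold_min_energy("AAAAAAAAAA")$energy, 0)
  expect_error(fold_min_energy("ACGX"), "non-ACGU")

  # MFE lower-bounds the energy of any Nussinov-derived structure
  set.seed(9)
  for (r in 1:25) {
    s <- random_dna(sample(8:12, 1), alphabet = c("A", "C", "G", "U"))
    fz <- fold_min_energy(s, par)
    fn <- fold_nussinov(s)
    sc <- score_structure(s, fn$pairs, par)
    if (!is.na(sc)) expect_lte(fz$energy, sc + 1e-9)
  }
})

test_that("relative free energy is dG per nucleotide", {
  f <- fold_min_energy("GGGGGGAAAACCCCCC", "rna")
  expect_equal(relative_free_energy(f), f$energy / 16)
  open <- fold_min_energy("AAAAAAAAAA")
  expect_equal(relative_free_energy(open), 0)
})

test_that("paired sites evolve slower when stems are constrained", {
  cr <- simulate_control_regions(40, point_mu = 0.02, stem_loop_ratio = 0.2,
                                 seed = 9)
  ids1 <- names(cr$truth$copies)[cr$truth$copies == 1]
  us <- cr$truth$rep_start
  sub <- new_alignment(setNames(
    substring(cr$seqs[ids1], us, us + cr$truth$period - 1), ids1))
  ref_fold <- fold_min_energy(cr$truth$unit, "rna")
  pc <- paired_site_conservation(sub, ref_fold, ref = 1)
  expect_lt(pc$ratio, 1)
  # variation only at loop columns -> paired rate 0 (constructed case)
  unit <- cr$truth$unit
  loop_pos <- which(is.na(ref_fold$pairs))[1]
  v1 <- unit
  substr(v1, loop_pos, loop_pos) <- setdiff(c("A", "C", "G", "T"),
                                            substr(unit, loop_pos, loop_pos))[1]
  aln2 <- new_alignment(c(r1 = unit, r2 = v1, r3 = unit))
  pc2 <- paired_site_conservation(aln2, ref_fold, ref = 1)
  expect_equal(pc2$rate_paired, 0)
  expect_gt(pc2$rate_unpaired, 0)
  # invariant alignment -> both rates 0
  aln3 <- new_alignment(c(r1 = unit, r2 = unit))
  pc3 <- paired_site_conservation(aln3, ref_fold, ref = 1)
  expect_equal(pc3$rate_paired, 0)
  expect_equal(pc3$rate_unpaired, 0)
})

test_that("windowed Tajima's D delegates to the popgen statistic", {
  aln <- simulate_neutral_alignment(10, theta = 4, L = 300, seed = 13)
  spans <- data.frame(name = c("whole", "left"), start = c(0, 0),
                      end = c(300, 150))
  rd <- region_tajima_d(aln, spans)
  expect_equal(rd$D[1], tajimas_d(aln)$D)
  expect_error(region_tajima_d(aln, data.frame(name = "bad", start = 0,
                                               end = 999)), "outside")
})
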