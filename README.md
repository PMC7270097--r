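# mitoscan

Selection scans and control-region analysis for population samples of
mitochondrial genomes.

When a few dozen complete mitogenomes are sampled from one species across
contrasting habitats — the motivating case is a small pelagic fish sampled
from three Indian Ocean eco-regions (Northern Arabian Sea, South Eastern
Arabian Sea, Bay of Bengal) — the questions are: which OXPHOS genes and
codon sites show signatures of positive or purifying selection, is the
non-coding control region under comparable functional constraint, and do the
carriers of selected variants track environmental gradients? mitoscan
implements that whole analysis as a tested R package:

* **Diversity & neutrality statistics** per partition: segregating sites S,
  nucleotide diversity π, haplotype diversity Hd, mean pairwise differences
  K, Watterson's θ, Tajima's D, Fu & Li's D\*/F\*, Fu's Fs (Ewens sampling
  formula, exact in log space), Nei–Gojobori Ka/Ks with Jukes–Cantor
  correction, and per-gene relative mutation rates θ_gene/θ_genome.
* **Site-wise selection scans** on a codon alignment + tree under an
  MG94×HKY85 model: a FUBAR-style empirical-Bayes rate-grid scan giving
  per-site P(β>α), a MEME-style mixed-effects likelihood-ratio scan for
  episodic selection, and a TreeSAAP-style physicochemical analysis (Fitch
  ancestral replacements, 8 magnitude categories over 31 packaged property
  scales, z-tests against the genetic code's mutational expectation) —
  combined by a two-method consensus rule.
* **Control region tools**: de-novo tandem-repeat detection and Type 1/2/3
  classification (38–40 bp units), TAS/CSB/poly-A motif annotation,
  secondary-structure folding (Nussinov oracle and a Zuker-style
  minimum-free-energy DP in C++) with ΔG/length as the folding-potential
  statistic, paired-vs-unpaired substitution-rate contrasts, and windowed
  Tajima's D.
* **Environmental association**: seasonal climatology summaries (JFM/AMJ/
  JAS/OND means and annual SDs) and binomial GLMs of selected-site carrier
  counts per region on one covariate at a time.
* **Seeded synthetic-data generators** for every stage (coalescent and
  expansion genealogies, Gillespie codon evolution with planted ω classes
  and episodic bursts, tandem-repeat control regions with stem/loop
  mutation contrast, carrier tables with planted logit effects), so the
  whole pipeline is testable at desk scale.

## Worked example

```r
library(mitoscan)

# a mitogenome-like cohort: 45 haplotypes, ~16.6 kb, pi ~ 0.006,
# expansion genealogy (excess of rare variants)
aln <- simulate_mitogenome_alignment(n = 45, L = 16600, pi = 0.006, seed = 1)
nt  <- neutrality_tests(aln)
nt$stats
#> n=45 L=16600 S=796 pi=0.00586 K=97.249 haplotypes=45 Hd=1.000 (0.005) theta=0.01097
round(c(D = nt$tajima_d, Dstar = nt$fu_li_d_star,
        Fstar = nt$fu_li_f_star, Fs = nt$fu_fs), 3)
#>      D  Dstar  Fstar     Fs
#> -1.723 -2.819 -2.895 -8.907
```

All 45 haplotypes are unique, π is at the target, and the strongly negative
Tajima's D / Fu's Fs are the expansion signature the generator plants —
the same qualitative regime seen in real pelagic-fish mitogenome cohorts.

```r
# selection scan with ten planted positive sites
tree <- simulate_tree(20, "coalescent", seed = 101, target_height = 1)
om <- rep(0.1, 300); om[1:10] <- 5
sim <- simulate_codon_alignment(tree, 300, omega_profile = om, seed = 202)
gs <- grid_bayes_scan(sim$caln, tree)
sum(gs$sites$flagged_positive[gs$sites$site %in% 1:10])
#> [1] 6
```

```r
# relative mutation rates from a published per-gene theta table
ref <- read.delim(system.file("extdata", "sardinella_reference_stats.tsv",
                              package = "mitoscan"), comment.char = "#")
relative_mutation_rate(ref$theta[ref$partition == "ND5"],
                       ref$theta[ref$partition == "Genome"])
#> [1] 1.46
```

The full pipeline (stats → tree → scans → consensus → regional frequencies →
control region → environment GLM) runs from one config:

```r
res <- run_pipeline(pipeline_config(list(seed = 5)))
list.files(res$out_dir)
#> [1] "config.json" "control_region.tsv" "control_region_motifs.tsv"
#> [4] "diversity_stats.tsv" "env_glm.tsv" "manifest.json"
#> [7] "selected_sites.tsv" "site_frequencies.tsv"
```

A thin command-line front-end ships in `inst/scripts/mitoscan`
(`mitoscan run <config>`, `mitoscan stats <fasta>`,
`mitoscan simulate {codon|dloop|env}`).

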