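---
title: "Selection scans on mitogenomes: the models behind mitoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans on mitogenomes: the models behind mitoscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mitoscan analyzes population samples of mitochondrial genomes — the setting
is a few dozen complete mitogenomes from a single species sampled across
contrasting habitats — for signatures of natural selection, in both the 13
OXPHOS protein-coding genes and the non-coding control region, and relates
the carriers of selected variants to environmental covariates. This vignette
explains each model, its assumptions, the tunable parameters, and the design
choices made where the methodology was genuinely open.

```{r setup}
library(mitoscan)
```

## Diversity and neutrality statistics

For each partition (whole genome, concatenated coding genes, individual
genes, rRNAs, tRNAs, control region) the package computes the standard
descriptive set: segregating sites $S$, mean pairwise differences $K$,
per-site nucleotide diversity $\pi = K/L$, haplotype count and diversity
$H_d = \frac{n}{n-1}(1 - \sum p_i^2)$ (with Nei's sampling SD), and
Watterson's $\theta_W = S / (a_1 L)$ with $a_1 = \sum_{i=1}^{n-1} 1/i$.

Columns containing gaps or Ns are handled by an explicit policy object:
`"complete"` deletion (drop the column, the default, and the convention under
which $\pi L = K$ holds exactly) or `"pairwise"` deletion. Multiple hits
within a column contribute `distinct states - 1` mutations to $\eta$ (the
total-mutation count used by the Fu & Li tests), and a column's singleton
count is capped at `distinct states - 1` so that a column of four distinct
states in four sequences counts three mutations, not four.

Neutrality tests:

* **Tajima's D** contrasts $K$ with $S/a_1$, using the standard coefficient
  chain; significance labels come from Tajima's beta-distribution
  approximation and are reported as conventional interval labels
  (`P < 0.01`, `0.10 > P > 0.05`, ...), matching how population-genetics
  software prints them.
* **Fu & Li's D\* and F\*** (the no-outgroup "star" variants) use $\eta$ and
  the singleton count $\eta_s$, with the corrected coefficient forms that
  mainstream implementations adopted after the original publication; their
  correctness here is checked by neutral-coalescent simulation (means within
  ±0.15 of zero over 2000 replicates).
* **Fu's Fs** computes $S' = P(k \ge k_{obs} \mid \theta = K)$ under the
  Ewens sampling formula with unsigned Stirling numbers of the first kind in
  log space, and $F_s = \ln(S'/(1-S'))$. For $n \le 6$ the implementation is
  tested against exhaustive enumeration of all set partitions.

**Ka/Ks** follows Nei–Gojobori: expected synonymous sites per codon by the
1/3-weighted single-step rule, observed differences averaged over all
minimal mutational pathways (pathways through stop codons are excluded when
possible), Jukes–Cantor correction $d = -\tfrac34\ln(1 - \tfrac43 p)$, and
pairwise values averaged over all pairs. Changes to stop codons count as
nonsynonymous for site counting. The per-column substitution tallies
reported alongside (the "number of synonymous/nonsynonymous mutations")
classify each minor codon variant against its column's majority codon.

**Relative mutation rates.** Per-gene rates relative to the whole mitogenome
are computed as $\theta_{gene}/\theta_{genome}$, truncated (not rounded) to
two decimals. Published per-gene tables of this quantity are reproduced by
this ratio; the equation sometimes printed alongside such tables is inverted
relative to its own values, so the package deliberately implements the ratio
that reproduces them (e.g. ND5 $0.00898/0.00611 = 1.4697 \to 1.46$ and CO1
$0.00392/0.00611 \to 0.64$).

## Site-wise selection scans

Both scans share an MG94×HKY85 codon model: rates between sense codons one
nucleotide apart are $\kappa^{[ts]} \pi_{target}$ times the synonymous rate
$\alpha$ or nonsynonymous rate $\beta$, with F3x4 codon frequencies
(position-specific nucleotide frequencies with a 0.5 pseudocount) and the
vertebrate mitochondrial genetic code (NCBI table 2, configurable). The
generator is scaled so branch lengths are expected substitutions per codon
site at $\alpha = \beta = 1$. Likelihoods come from Felsenstein pruning with
per-column rescaling; transition probabilities from symmetric
eigendecomposition of the reversible generator. Branch lengths are
calibrated once under a site-homogeneous model (a global scale and a global
$\omega$, Nelder–Mead, relative tolerance $10^{-6}$) and then held fixed for
the site-wise scans — the usual two-phase practice. When no tree is
supplied, a neighbor-joining tree on K2P distances is built (deterministic
tie-breaking by sorting tips lexicographically; negative branch lengths
clamped to zero; saturated distances are an error naming the offending
pair).

**Pervasive selection (rate-grid empirical Bayes).** Site likelihoods are
evaluated on a 20×20 grid of $(\alpha, \beta)$ values spanning
$[0, g_{max}]$, where $g_{max}$ defaults to twice the largest crude
empirical site rate (distinct codons minus one over tree length, floored at
2). Grid points are spaced quadratically — denser at low rates, where site
rates concentrate under purifying selection — which matters because the grid
weights are estimated across sites: weights are fitted by EM with a
symmetric Dirichlet(0.5) smoothing, and each site's posterior
$P(\beta > \alpha)$ is the responsibility mass strictly above the diagonal.
Sites with posterior above 0.9 (configurable) are flagged positively
selected; the mirror-image mass flags purifying selection. Degenerate
all-missing sites are excluded and recorded. At the default settings the
scan recovers at least 6 of 10 sites planted at $\omega = 5$ among 300
codons on a 20-taxon tree of height 1, with about 2% of sites flagged on an
alignment simulated entirely at $\omega = 1$.

**Episodic selection (mixed-effects LRT).** Per site, the alternative model
has a shared synonymous rate $\alpha$, a constrained class
$\beta^- \le \alpha$, an unconstrained class $\beta^+$, and a mixing weight
$q$ applied independently per branch; because branch class assignments are
independent, the mixture folds exactly into per-branch averaged transition
matrices. The null pins $\beta^+ = \alpha$. The LRT p-value uses the
boundary mixture $\tfrac13\chi^2_0 + \tfrac13\chi^2_1 + \tfrac13\chi^2_2$.
Optimization is Nelder–Mead with three starts per model, relative tolerance
$10^{-6}$, iteration cap 500; non-convergence is reported via a status flag,
never silently dropped, and invariant sites short-circuit to $p = 1$.

A limitation worth stating plainly: a burst confined to a *single* branch is
close to undetectable at a single site, because only the branch's endpoint
state is observable and the null can absorb it by raising the site's shared
rate. Detectable episodic signal requires the burst to touch a meaningful
fraction of branches; the power test plants $\omega = 20$ on roughly 35–40%
of branches of a 20-taxon, height-2 tree, where measured power is about 0.6
at $p < 0.05$ with the false-positive rate at or below nominal.

**Consensus rule.** A site is reported as positively selected when at least
two of the three analyses call it: grid posterior > 0.9, episodic
$p < 0.05$, or a physicochemically radical replacement (below). Both
thresholds and the two-method rule are configuration fields.

## Physicochemical-shift analysis

Amino-acid replacements are inferred by Fitch parsimony on the translated
alignment (down-pass/up-pass; ties resolved deterministically to the
lexicographically smallest residue and recorded). For each of 31 packaged
physicochemical property scales (per-column provenance in
`inst/extdata/aa_properties.tsv`), the magnitude of a replacement is
$|\Delta \text{property}|$ binned into 8 equal-width categories spanning the
property's maximum achievable difference; category 8 is the most radical.
The neutral expectation for the category distribution comes from the genetic
code itself: all single-nucleotide nonsynonymous neighbor pairs with equal
weights (a transition/transversion weighting is a documented possible
extension). Observed counts are z-tested per property × category cell,
$z = (obs - Np)/\sqrt{Np(1-p)}$, two-sided; cells with category ≥ 6,
positive z and $p < 0.001$ are flagged "positive-destabilizing", and a codon
site is physchem-called when one of its inferred replacements falls in a
flagged cell. Cells with zero neutral expectation are skipped with a note.

## Control region

**Tandem repeats.** De-novo detection compares the sequence with itself at
every lag in the configured period range (default 36–42 bp, targeting the
38–40 bp units of clupeid control regions); windows of identity ≥ 80% with
at least one full extra copy seed an annotation, which is then refined by
anchoring a consensus unit and counting consecutive near-matching copies
plus a partial terminal copy. A single-copy unit carries no self-evidence,
so it is found only by scanning a consensus-unit catalog at ≥ 85% identity.
Type labels are the copy number rounded half-down (Type 1/2/3; above 3.5 the
label is "Type >3 (unclassified)"); subtypes are the nearest catalog unit
over all phase rotations, since a tandem array has no canonical phase.

**Motifs.** TAS, CSB-D, CSB1–3 are located by IUPAC pattern matching at
increasing mismatch counts up to a per-motif cap (leftmost hit at the
smallest count); the packaged patterns are template consensus patterns meant
to be overridden per species. The poly-A tract is the longest A-homopolymer
of at least 6 bases. Absent motifs are reported "not found", never
fabricated.

**Secondary structure.** Two folders are provided: a Nussinov
pair-maximization DP (Watson–Crick + GU, minimum hairpin loop 3,
deterministic traceback), which serves as a combinatorial oracle, and a
Zuker-style minimum-free-energy DP (hairpins, stacks, internal/bulge loops
bounded at 30 unpaired bases, affine multibranch loops) over a packaged
simplified nearest-neighbour parameter set (stack energies keyed by the two
pair types only; loop penalties by size with logarithmic extrapolation).
The parameter file documents its provenance; magnitudes follow the familiar
Turner-style sets but the table is deliberately coarse, so energy
comparisons in this package are **ordinal** — which unit folds better per
nucleotide — not literal reproductions of any web-server's kcal/mol. T is
mapped to U for RNA folding of the L-strand; a DNA parameter set is
available behind the same interface. ΔG of the open chain is 0, and the
reported robustness statistic is the length-normalized ΔG/length, the
comparative quantity for ranking folding potential against a tRNA-like
reference (generated cloverleaves with exact complementary stems). Since
published ΔG ranges for repeat units overlap their ΔG/length ranges, the
per-length quantity is treated as the comparative statistic throughout.

The packaged synthetic unit catalog encodes the comparative claim the
analysis targets: the 38 bp Type-1 consensus unit carries a palindromic
stem–loop core, while the 40 bp Type-3 variant units plant non-compensatory
substitutions in both stem arms, emulating the weaker folding potential of
Type-3 units; single Type-1 units consequently fold with lower (more
negative) ΔG/length than triple arrays of the variant units.

**Paired-site conservation.** Alignment columns over a folded region are
partitioned by the paired/unpaired status of a reference row's structure;
per-class substitution rates (distinct valid states minus one, per column)
are compared, with a two-proportion test on variable-column fractions.
Windowed Tajima's D over the TAS/CSB/repeat spans delegates to the popgen
statistic on column slices.

## Environmental association

Monthly climatology tables (region × variable × month) are summarized per
season — Winter = JFM, Spring = AMJ, Summer = JAS, Fall = OND — as means and
SDs (denominator $n-1$), plus the annual SD over the 12 monthly values as
the "fluctuation" covariate. Missing months are an error naming the month.
Carrier counts of consensus-selected replacements per region are regressed
on one covariate at a time (the default, since multi-covariate fits on three
regions are not identifiable) with a logit-link binomial GLM fitted by IRLS
(`stats::glm`), Wald tests, and an explicit separation flag; p-values are
reported raw, without multiplicity correction. The packaged climatology is
synthetic, constructed to mirror the qualitative regimes of the three Indian
Ocean eco-regions (NAS unimodal SST and high salinity; SEAS bimodal SST with
summer hypoxia and a strong upwelling bloom; BoB warm, fresh and stable).

## Synthetic data: what it does and does not emulate

Every stage is exercised by seeded generators (`simulate_tree`,
`simulate_neutral_alignment`, `simulate_mitogenome_alignment`,
`simulate_codon_alignment`, `simulate_control_regions`,
`simulate_env_glm_dataset`), pure functions of (seed, parameters):

* The mitogenome generator targets the published qualitative regime:
  $\pi \approx 0.006$ over ~16.6 kb, $n = 45$, an expansion (star-like)
  genealogy (`growth = 20`) producing the excess of rare variants (clearly
  negative Tajima's D) and all-unique haplotypes; terminal branches carry a
  small pad (5% of tree height) reflecting private variation of individuals
  sampled from a very large population.
* The codon generator is Gillespie simulation under the same MG94×HKY85
  generator the scanner uses — intentional, for internal consistency — with
  an independent counting oracle in the tests (parsimony change counts on
  shallow trees against the code's syn/nonsyn opportunity ratio) guarding
  against shared-bug circularity. The default omega profile (90% at 0.1, 7%
  at 1, 3% at 5) mimics a mostly-purifying mitogenome with a small positively
  selected minority.
* The control-region generator assembles flank + TAS + tandem repeats +
  poly-A + CSB blocks around the catalog unit, draws copy numbers from a
  Type-1-dominant distribution (0.8/0.15/0.05), models slipped-strand
  copy-number change with an optional probability per individual, and
  mutates stem columns of the unit's reference structure at a configurable
  fraction of the loop rate.
* None of the generators emulate recombination (mtDNA is treated as clonal),
  sequencing error, alignment error, indel evolution within genes, or
  population structure between regions; passing tests therefore demonstrate
  the estimators' behavior under their own model assumptions, not robustness
  to those artifacts.

## Numerical choices and problem sizes

Tolerances: EM and IRLS to relative $10^{-8}$; optimizers to relative
$10^{-6}$ with multi-start. Degenerate inputs are explicit states: $S = 0$
gives an "undefined" neutrality result rather than 0; a monomorphic sample
makes Fu's Fs undefined; Jukes–Cantor correction at $p \ge 3/4$ is an
undefined-pair state counted and reported. Test and acceptance problem sizes
are desk-scale by design: 2000 coalescent replicates at $n = 20$, 300-codon
scans on 20 taxa, 200 random sequences for each combinatorial oracle —
large enough to pin the statistics, small enough to run in minutes.
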