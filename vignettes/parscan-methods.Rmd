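---
title: "Methods: scanning a young pseudoautosomal region for sexually antagonistic selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning a young pseudoautosomal region for sexually antagonistic selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parscan)
```

## The problem

Sexually antagonistic selection (SAS) — an allele good for one sex and bad
for the other — is the leading hypothesis for why recombination shuts down
on sex chromosomes, yet it is notoriously hard to detect. The
pseudoautosomal region (PAR) of a *young* neo-sex chromosome is the one
place where the signal should be strong: the PAR still recombines between
X and Y, but its linkage to the adjacent non-recombining sex-determining
region (SDR) lets allele-frequency differences between X-linked and
Y-linked copies accumulate over generations. A locus under SAS should
therefore show a localized peak of X–Y differentiation
(F~ST~), a few ρ wide, where ρ = 4N~e~r is the population-scaled
recombination distance to the SDR.

parscan implements the whole search as a tested pipeline: trio-based
phasing of paternal X and Y haplotypes from interspecies pedigree crosses,
windowed X/Y statistics, a model-free permutation scan with
q-value FDR control, and a structured-coalescent null (with the Y's
founding sweep and demographic history) that calibrates how skeptical one
should be of those peaks.

## Phasing and filtering

Crosses pair a focal-species father (XY) with a sister-species mother
(XX); one son and one daughter per cross are sequenced. With parents from
diverged species, many offspring-heterozygous sites have parents fixed for
alternate alleles, which gives the trio rule its power: *the paternal
allele is the child allele present in the father and absent in the
mother*. Sites where all three are heterozygous are unphasable; a child
homozygous for an allele no parent can donate is a Mendelian error
(dropped for that trio only); a homozygous child trivially received its
allele from the father (flagged separately in provenance). One literal
consequence, kept deliberately: a heterozygous child of a homozygous
father and heterozygous mother is coded unphasable even though the father
could only have donated one allele — such sites are maternal-side
polymorphisms that contribute nothing to the paternal X/Y panel.

Hard filters precede phasing, with VCFtools-like semantics: site QUAL ≥
999 (the mpileup cap), genotypes with GQ < 20 set missing, across-sample
mean depth ≥ 10×, a paralog guard at 1.5× the chromosome median of site
mean depths (median over sites surviving the other filters), biallelic
SNPs only, and — after phasing — removal of sites with more than five
offspring missing a phased call across all families. The "mean depth"
open question is resolved as the across-sample site mean (the
VCFtools `--min-meanDP` reading), noted here because per-sample minima
would filter differently.

## Windowed statistics

All statistics tile the chromosome from position 1 in half-open
`[start, start + size)` windows (10 kb default; 100 kb for gene trees),
with 1-based positions matching VCF coordinates.

* **F~ST~ (Hudson)**: per site, 1 − H~w~/H~b~ with H~w~ the mean of the
  two within-group heterozygosities (unbiased, from mean pairwise
  differences) and H~b~ the between-group mean pairwise difference;
  windows aggregate as a ratio of averages (sum of numerators over sum of
  denominators), which is robust to low SNP counts. Negative site values
  are clamped at zero only for *reporting*; window sums use unclamped
  components to avoid truncation bias. The estimator is not named in the
  protocol this package reimplements; Hudson's is the field default for
  haplotype-level two-group comparison, and no second estimator
  (e.g. Weir–Cockerham) is offered — one tested code path beats two
  half-used ones.
* **π and K (Dxy)**: mean pairwise difference counts, within and between
  panels, per window-length bp (a callable-sites denominator is the
  documented alternative; window length is the default because the
  synthetic world has no callability mask). Note that K between two
  panels that share polymorphism is bounded below by that shared
  diversity; only fixed differences push it above the within-species
  level.
* **Tajima's D**: (π − S/a₁)/√(e₁S + e₂S(S−1)) with the standard 1989
  constants; undefined when S = 0 or n < 4. With missing calls the
  constants use the median per-site sample size.
* **Read-depth ratio**: son/daughter mean depths, each individual first
  normalized by its genome-wide mean (library size). A fully degenerate
  Y gives ≈ 0.5; a stratum whose Y retains a fraction *f* of coverage
  gives (1 + f)/2.
* **XY gene-tree consistency**: neighbour-joining on Hamming distances in
  100 kb windows; a window is "consistent" iff the X|Y bipartition exists
  in the unrooted tree (tested by rooting at an X tip and asking whether
  the Y tips are monophyletic). The tree method is a package choice; NJ
  on Hamming distances is deterministic here and only the bipartition is
  consumed.
* **SDR/PAR boundary**: single binary-segmentation change point
  (maximum within-segment SSE reduction) on any ordered window series —
  consistency, K, or π~Y~ — reported as the start of the first
  right-segment window.
* **dN/dS**: Nei–Gojobori codon counting with equal-weight pathway
  averaging and Jukes–Cantor correction below the 3/4 saturation;
  mutations to stop codons count as nonsynonymous, pathways through
  stops are not excluded, and the ratio is undefined when d~S~ = 0 or a
  proportion saturates.

## The model-free scan

Within a focal interval (default 7.5–11.5 Mb: far enough from the SDR
that linkage alone should not inflate F~ST~, near enough to retain power
and limit multiple testing), each 10 kb window with enough SNPs
(default ≥ 10; a strict `>` flag exists because the protocol's own text
uses both readings) gets an empirical p-value: the proportion of balanced
X/Y label randomizations whose window F~ST~ is **greater than or equal
to** the observed value. Defaults follow the published protocol
(10⁶ permutations at full scale; desk-scale 10⁴). Three numerical
choices matter:

* Ties count toward the numerator, matching the quoted definition. On a
  discrete F~ST~ null this makes p-values mildly *conservative*: across
  ~5,000 neutral synthetic windows the mean null p is ≈ 0.52 rather than
  0.50, a shift invisible to a 500-window KS test (the scale at which
  uniformity is asserted) but detectable when thousands of p-values are
  pooled. The optional add-one variant `(b+1)/(B+1)` is stricter still.
* No add-one correction by default — the plain proportion is what the
  protocol defines; `add_one = TRUE` is available for conservative use.
* Each window's permutation stream is seeded from the global seed and the
  window's start coordinate, so p-values are reproducible to the last
  digit and independent of scan extent or window order.

Multiple testing uses Storey q-values: π₀ estimated on a λ grid
(0.05…0.95) with a df-3 smoothing spline evaluated at λ = 0.95, falling
back to π₀ = 1 (Benjamini–Hochberg, the conservative limit) below 100
tests, where the smoother is unstable at typical scan sizes (~178
windows). Windows with q ≤ 0.2 are called significant; 0.2 is the
protocol's deliberate choice for a setting with few expected outliers.

## The structured-coalescent null

High F~ST~ near the SDR needs no selection: linkage plus the Y's own
history can produce it. The calibrator models one PAR window as a
non-recombining locus in a two-deme coalescent, time in units of 2N~e~
generations:

* **Demes**: Y-linked copies (relative size 1/4 — one copy per male) and
  X-linked copies (3/4). Coalescence at rate C(k,2)/(f·s(τ)) within each
  deme, with s(τ) the epoch size factor.
* **Migration is male-meiosis recombination**: backward in time a
  Y-linked copy moves to the X deme at ρ/2 per 2N~e~ generations, an
  X-linked copy to the Y deme at ρ/6 (only the third of X copies in males
  can have come off a Y). Female meiosis never switches linkage state and
  is ignored.
* **Sweep**: at t_sweep (default 306,000 generations — the species-split
  age, just after which the neo-Y arose) all lineages in the Y deme merge
  instantaneously and the process continues panmictic (the locus was
  autosomal before the fusion). A sweep *trajectory* is deliberately not
  modelled; the instantaneous merge is its zero-duration limit and the
  protocol supplies no trajectory to copy.
* **Demography**: stepwise epochs rescale both demes. The default —
  ancestral size 0.2·N~e~ before half a sweep-time ago — is an explicitly
  arbitrary placeholder for a recent ~5× expansion; anything quantitative
  should set `demography` from real estimates.
* **Mutation**: infinite sites at θ/2 per unit branch length, so a
  panmictic constant-size control has E[π] = θ. Default θ = 2.5 per
  10 kb window Watterson-matches the observed ~10 SNPs per window in a
  sample of 30. Summaries (F~ST~, π by label, S, D, Y-monophyly,
  T~MRCA~) are computed directly from per-branch descendant counts; the
  haplotype matrix and Newick genealogy are emitted on request and the
  two routes are cross-checked in the tests.

ρ units convert to physical distance through an explicit constant:
the working convention is 1 cM/Mb and 0.01 cM per ρ, i.e. 1 ρ ≙ 10 kb.
Plugging N~e~ = 10⁵ into 4N~e~r directly gives 40 ρ per 10 kb instead —
the two conventions are inconsistent in the source material, so the
scaling lives in `rho_scaling()` where it is an auditable choice rather
than a buried assumption.

Whole-scan calibration simulates many null scans (1000 at protocol
scale), reduces each to its minimum window p, and sets p\* to the largest
observed threshold at which at most 20% of null scans would yield any
call. Comparing q-value calls against p\* calls (`compare_calls()`)
reproduces the protocol's sobering comparison: a demographically honest
null can absorb peaks that the exchangeability null flags.

## The synthetic world

`simulate_sex_panels()` is a parametric mosaic, not an
ancestral-recombination-graph simulation — downstream tests need exact,
controlled truth, and model-faithful nulls are the coalescent module's
job. It emulates: 15 X + 15 Y focal haplotypes and 26 sister-species X
haplotypes; polymorphic sites as a Poisson process (10 per 10 kb
default) with derived counts from a neutral-like 1/i spectrum; fixed
interspecies differences at 5 × 10⁻⁴ per bp (a few-hundred-thousand-
generation split); an SDR in which fixed X–Y differences are injected
per stratum and polymorphism is mostly X-private (the Y sweep's
signature), with per-stratum Y depth factors; and planted SAS windows
whose X–Y frequency differential is set to δ at every site of the window
— a SAS polymorphism maintains LD across its ~1 ρ window, so the
coherent multi-site signal is the realistic planting (single-site
planting is available). `simulate_crosses()` transmits haplotypes
through the 15-cross/13-mother/58-individual design (one mother used
three times), then applies the observation model: per-haplotype
negative-binomial depth around 28× (Y haplotypes thinned by the stratum
factor in males), GQ, allele miscalls (0.002) and missingness (0.02),
all *after* truth is recorded. One seed drives everything and is echoed
in every output header.

What the generator does **not** emulate — so a green test does not
establish robustness to it: linked genealogies along the chromosome
(sites are exchangeable given their class), mapping artifacts and
paralogy (depth caricature only), indels and multi-allelic sites,
ancestral-strata dating, shared ancestral polymorphism between the
species. On that last point: with any polymorphism, between-species K
cannot be exactly zero even at zero divergence (shared diversity floors
the all-pairs Dxy), so "zero divergence" is asserted on the fixed-
difference component, not on raw K.

## Known limitations

* The coalescent treats windows independently; inter-window correlation
  in real data makes the familywise calibration slightly conservative.
* π and K are per window-length bp; with real callability masks, supply
  the callable length.
* The Storey smoother needs a few hundred tests to beat BH; at scan sizes
  near 178 the BH fallback usually governs.
* The permutation p's tie conservativeness (above) means reported p's are
  upper bounds at discrete nulls; power claims in the tests already
  absorb this.
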