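---
title: "Appraising ancestral haplotype reconstruction by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Appraising ancestral haplotype reconstruction by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplomosaic)
```

# Why simulate the truth

In a multiparent cross, each progeny chromosome is a mosaic of founder
segments. Many analyses (QTL mapping, recombination studies, genomic
prediction) start from a *haplotype map*: per marker and per homologue, the
founder each allele descends from. Reconstruction from sparse, error-prone
genotyping is statistically delicate, and with real data its accuracy is
unknowable, because the truth is unobserved. The approach implemented here
is to simulate a population whose origins are known by construction, pass
it through the same corruption + imputation + reconstruction stack a real
study would use, and score the result. The appraisal is of the *pipeline
under a design*, not of a particular data set: the output tells you what
accuracy to expect before you genotype anything.

# Simulation model

**Map.** `sim_genetic_map()` places markers on chromosomes with pinned
endpoints and either uniform-random or even cM spacing; bp positions are
carried at a constant expansion (default 1 Mb/cM) for VCF output. The cM
coordinate is the computational one throughout.

**Founders.** Founders are fully inbred: one haplotype each, biallelic
markers, allele frequencies drawn from a configurable interval (default
0.2–0.5 so markers are reasonably informative). Identity-by-state between
a founder pair can be planted either as a random fraction of markers or as
an explicit marker window (`ibs_markers`), which is how the regional
appraisal experiments are built.

**Meiosis.** `sim_gamete()` draws a crossover count per chromosome from
Poisson(length in Morgans) and breakpoint positions uniformly on the cM
interval — the Haldane model, i.e. no crossover interference. The starting
homologue is fair-coin. Origin labels and alleles travel together, so the
invariant *allele = founder allele at the labelled origin* holds at every
marker of every simulated individual. `sim_pedigree()` provides a circular
outcross design of configurable depth and a biparental-F1 design;
`sim_population()` walks any pedigree whose founders are in the panel.

**Corruption.** `induce_errors()` flips each non-missing call with the
global error probability, replacing it by one of the other two genotype
states uniformly — the least-informative substitution, symmetric with the
decoder's emission model. `induce_missing()` masks calls with per-locus
probabilities, either constant or from a Beta-distributed profile
(`sim_missingness()`), mimicking the strong per-locus heterogeneity of
reduced-representation sequencing. Errors are injected before missingness,
and realized per-locus error frequencies are recorded *pre-masking*: a
flipped-then-masked call still counts as an induced error even though it is
unobservable downstream. Realized rates are first-class outputs because
the realized corruption, not the nominal one, is what the reconstruction
actually faced.

# Imputation

`impute_genotypes()` treats each individual as an ordered pair of mosaic
copies of the founder haplotypes (a Li–Stephens-style model) and reuses the
same joint-pair HMM engine as origin decoding, with switch intensity `rho`
per Morgan per copy. Missing calls are replaced by the posterior-maximal
genotype (ties towards the smaller dosage, deterministically); observed
calls are never modified. Dosages are posterior expectations of the
allele-1 count, clamped to [0, 2].

Per-marker quality is the ratio-of-variances R²:
`Var_i(dosage) / (2 p (1 - p))` at the dosage-based allele frequency,
defined as 0 at monomorphic markers. Two calibration facts matter when
choosing a threshold (default 0.8):

- the estimator is *noisy* at small sample sizes even for perfect data
  (it is a variance ratio across individuals and can exceed 1);
- it centres *below* 1 on crossing designs, because related progeny carry
  excess heterozygosity relative to the Hardy–Weinberg denominator
  (measured mean ratio ≈ 0.93 with 4 founders, ≈ 0.97 with 8, on fully
  observed error-free data).

`filter_markers()` applies the threshold and refuses to leave any
chromosome empty, since decoding is chromosome-wise.

# Origin reconstruction

The state space is all ordered founder pairs, enumerated lexicographically
(`state = (i−1)P + j`). Per homologue over `d` Morgans,
`P(stay) = e^{-Rd} + (1-e^{-Rd}) π_same` and
`P(switch to j) = (1-e^{-Rd}) π_j`; the joint transition is the Kronecker
product of the two homologue chains, and the first marker of each
chromosome uses the prior `π ⊗ π`. Emissions compare the state's implied
genotype with the observed call under error rate `ε`; missing calls have
likelihood 1 in every state.

Decoding is exact: log-space Viterbi for the path (ties broken towards the
lowest state index, so results are reproducible), scaled forward–backward
for posteriors. Both are implemented in C++ and are verified in the test
suite against an exhaustive enumeration oracle that scores every one of the
`P^{2L}` paths of small instances, to 1e-10.

**Choosing `R`.** `R` is the expected number of origin switches per Morgan
per homologue. Junction-density reasoning gives the default
`max(1, generations − 1)`: a progeny homologue of a two-generation outcross
is the product of one recombinant meiosis acting on non-recombinant founder
chromosomes, hence about one switch per Morgan; each additional generation
adds roughly one. Decoding is fairly robust to moderate mis-specification
of `R`, much less so to a mis-specified `ε` when data are clean — the
acceptance suite decodes error-free data with `ε = 1e-4` rather than the
pipeline default 0.006 precisely because the matched value is near zero.

**Parent certainty.** The per-marker founder distribution pools the two
homologues, `q(f) = (P(hom₀=f) + P(hom₁=f))/2`, and certainty is the gap
between its two largest values. This pooled form (chosen and documented,
since per-homologue certainty is an equally defensible reading) has a
consequence worth knowing: at a site where the two homologues confidently
carry two different founders, the top two founders tie at 0.5 and certainty
is ≈ 0 — low certainty does *not* necessarily mean low accuracy. It also
means a planted IBS window does not reduce mean pooled certainty (the tie
is broken upward at heterozygous-origin sites, offsetting the drop at
homozygous ones); one acceptance assertion records this outcome as a
deliberate red rather than silently switching definitions.

# Metrics

AAA uses the unordered (multiset) origin-pair comparison per marker,
because Viterbi phase labels are arbitrary relative to maternal/paternal
labels; no global homologue alignment is needed. GAA scores the genotype
implied by the inferred origins against the true genotype, so IBS founders
make GAA exceed AAA — the gap is itself a diagnostic of founder
relatedness. PAA needs a homologue correspondence; per chromosome the
orientation maximizing origin agreement is used (identity wins ties), and
concordance of consecutive evaluation sites (truly heterozygous, genotype
correctly inferred) is counted. CCC is the Pearson correlation of
per-individual total crossover counts with the standard t-based p-value;
means and SDs are reported alongside because marker-resolution inferred
counts are systematically *downward*-biased in sparse regimes (short
double-crossover segments fall between markers), which correlation cannot
see.

```{r example, eval = FALSE}
map        <- sim_genetic_map(n_chrom = 2, n_markers = 150,
                              length_cM = 120, seed = 101)
founders   <- sim_founders(map, n_founders = 4, seed = 102)
population <- sim_population(sim_pedigree(4, 40), founders, map,
                             seed = 103)
observed   <- induce_missing(induce_errors(population, 0.006, seed = 104),
                             0.1, seed = 105)
imputed    <- impute_genotypes(observed, founders)
keep       <- retained_markers(filter_markers(imputed, 0.8))
decoding   <- decode_origins(subset_markers(imputed, keep), founders,
                             R = 1, error_rate = 0.006)
metrics    <- evaluate_reconstruction(subset_markers(population, keep),
                                      decoding,
                                      subset_markers(founders, keep))
glance(metrics)
autoplot(metrics)
```

# Pipeline, files and reproducibility

`run_pipeline()` chains the five stages in a run directory, persisting
every intermediate: map/pedigree/missingness tables, founder TSV + phased
VCF, known and observed VCFs, origin TSVs, imputation quality, posterior
and path-probability tables, metrics JSON/TSVs, and a JSON manifest
recording package version, config, per-stage seeds and marker bookkeeping
(total = retained + filtered). Each stochastic stage derives its own seed
from the master seed by a fixed formula, so re-running a late stage never
perturbs earlier draws, and a full run is byte-for-byte reproducible from
one integer. The stages are also exported individually and as a CLI
(`exec/haplomosaic`).

Default problem sizes (1–3 chromosomes of 150 cM, 100–200 markers each,
4–8 founders, 100–200 progeny) are the package's own desk-scale choices:
large enough for stable metric estimates, small enough that a full run
takes seconds.

# Known limitations

- The origin prior is homogeneous along the genome and across individuals;
  the exact pedigree-conditioned junction process (and founder-genotype
  uncertainty, X-chromosome inheritance) is out of scope — `R` and `π` are
  user parameters with pedigree-depth defaults.
- No crossover interference (Haldane); realized counts are Poisson.
- Founders must be inbred and markers biallelic.
- The variance-ratio R² is a population-level proxy; with few, related
  individuals it prunes markers aggressively (see the calibration notes
  above).
- Inferred crossover counts are marker-resolution and downward-biased in
  sparse maps; CCC should be read together with the reported means.
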