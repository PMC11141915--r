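---
title: "Methods: multiregion clonal-evolution inference for chromophobe RCC"
author: "chromoevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiregion clonal-evolution inference for chromophobe RCC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoevo)
```

## The problem

Chromophobe renal cell carcinoma (ChRCC) of the classic subtype is
characteristically *hypodiploid*: tumors recurrently lose one copy of
chromosomes 1, 2, 6, 10, 13, 17 and 21 (chromosome 21 less consistently).
A small fraction of tumors progress through focal dedifferentiation to an
aggressive, metastasis-prone state whose genomic hallmark is whole-genome
doubling (WGD) of the remaining chromosomes, typically after hemizygous
mutation of a TP53-like driver on monosomic chromosome 17 and a PTEN-like
driver on chromosome 10.

This package implements the inference chain needed to reconstruct that
trajectory from multiregion tumor/normal sequencing read counts:

1. allele-specific copy-number (ASCN) inference with joint purity/ploidy
   estimation (`fit_ascn()`),
2. WGD, chromosome-arm and gene-level copy-number calls,
3. somatic mutation multiplicity, zygosity and timing relative to WGD,
4. per-patient driver phylogenies from binary mutation presence patterns,
5. closed-form IHC and expression scores.

Because the corresponding patient-level sequencing data are access
controlled, the package ships a forward simulator (`chrcc_scenario()`,
`simulate_scenario()`) that emits multiregion observations with full
generating truth; every inference stage is validated against it.

## The simulator

A scenario is a rooted clone tree whose edges carry ordered events:
monosomies, driver mutations, WGD, arm gains, and Poisson passenger
mutation rates. Genotypes are arm-level maternal/paternal integer copy
numbers. Within an edge, copy losses precede mutations; mutations placed
before a WGD on the same edge double their multiplicity, exactly the
zygosity signal the timing rules exploit.

Observations follow the standard purity-mixture emission model. At a
germline-heterozygous SNP with B-allele copy number $c_B$ and total $c_T$
in the tumor mixture at purity $p$:

$$\mathrm{BAF} = \frac{p\,c_B + (1-p)}{p\,c_T + 2(1-p)},$$

and at a somatic variant of multiplicity $m$:

$$\mathrm{VAF} = \frac{p\,m}{p\,c_T + 2(1-p)}.$$

Tumor depth is Poisson with mean proportional to local mixed copy number,
normalised by the sample mean so library sizes stay comparable; allele
counts are binomial. There is no sequencing-error term by default
(`error_rate` adds one symmetrically).

The default scenario *is* the study condition used everywhere in the
validation suite: purity 0.7 (varied over 0.4–0.8 in the recovery studies),
coverage 100×, 500 SNP sites per chromosome on a 22-autosome genome with
scaled hg38 arm lengths; a classic clone with the canonical monosomies
(chromosome 21 lost with probability 0.5 per run, configurable) and a
hemizygous TP53-like driver; a dedifferentiated clone with a PTEN-like
driver followed by WGD and a post-WGD 1q gain (tumors with gains beyond two
copies, e.g. chromosome 1q, are part of the reported spectrum — and the
odd-copy state usefully pins the absolute copy-number scale, see below).
Passenger rates (trunk 23, classic branch 4, dedifferentiated branch 15,
plus the drivers) give expected nonsynonymous burdens of 28 and 40 per
classic and dedifferentiated sample, matching the published medians by
construction; the validation suite treats these as approximate, not as
assertions of truth.

What the simulator does **not** emulate: read-level artifacts (mapping,
GC, FFPE damage), subclonal copy number within a region, kataegis/signature
structure, germline CNVs, and real SNP spacing. Passing recovery tests
therefore demonstrate correctness of the inference logic under the stated
emission model, not robustness to every artifact of real WES data.

Determinism: all randomness derives from one master seed; per-region and
per-stage streams are derived by a stable string hash (`derive_seed()`), so
adding a region to a scenario never perturbs the draws of existing regions,
and identical seeds give bit-identical datasets.

## Site statistics and segmentation

`site_stats()` computes, per germline-het site, the library-size normalised
depth log-ratio `logR` and the Haldane-corrected allelic log odds ratio
`logOR` (natural log), plus a per-site binomial variance estimate for the
logOR. Sites with normal depth below 10 are dropped.

`segment_genome()` performs recursive binary segmentation per chromosome on
the bivariate series (logR, |logOR|): each candidate split is scored by the
sum of the two squared pooled-variance t statistics, the best split is
accepted if its score exceeds a critical value, and both halves are then
re-examined (minimum 5 sites per segment). The |logOR| channel is folded
because allele phase is unobserved. The two-pass design is preserved from
standard ASCN practice: a coarse pass (critical 35) feeds the purity/ploidy
fit; a fine pass (critical 20) yields the final segments. These critical
values were calibrated once on flat-noise null series (500 sites): the null
99th percentile of the maximum split score is ≈18, so 20 holds the
per-chromosome false-split rate under 5% while a logR step of one copy at
purity 0.4+ scores in the hundreds. t statistics are scale-free, so the
calibration does not depend on the noise level.

## The purity/ploidy/ASCN fit

`fit_purity_ploidy()` grid-searches purity (0.05–1.00, step 0.01) jointly
with a diploid-logR offset. For each candidate, every segment is assigned
the integer (major, minor) pair (total ≤ 8) minimising the squared distance
between its observed (mean logR, mean |logOR|) and the model expectation;
the candidate minimising the total genome-length-weighted residual wins.
Three numerical choices matter:

* **Folded-normal correction.** The observed mean |logOR| of a balanced
  segment is biased upward by noise ($E|X| > |EX|$). The fit therefore
  compares it with the folded-normal mean
  $E|N(\mu,\sigma)|$ at the segment's estimated per-site $\sigma$, rather
  than with $|\ln(b/(1-b))|$ directly. Without this, balanced segments
  drift toward spuriously imbalanced states.

* **Offset refinement.** Candidate offsets are seeded from a ploidy grid
  (0.8–6, step 0.05), but after each assignment the offset is reset to its
  closed-form optimum for that assignment. This removes the grid-resolution
  penalty on candidates whose implied ploidy falls between grid points and
  makes noise-free recovery exact.

* **Scale degeneracy and the near-tie rule.** A genome of (1,0)/(1,1)
  states at purity $p$ has *identical* expected logR and folded logOR to a
  genome of (2,0)/(2,2) states at purity $p/(2-p)$ — the classic
  diploid/tetraploid ambiguity. Under noise, scaled-up solutions even fit
  slightly better (more integer states absorb noise), while genuinely wrong
  scaled-*down* solutions misfit odd-copy segments (such as the post-WGD
  1q at three copies) by an order of magnitude. Measured residual
  landscapes across purities 0.4–0.8 and both genotypes show the true
  solution always within ~2.5× of the optimum and wrong down-scalings at
  ≥18×. The fit therefore collects all candidates within a factor 5 of the
  best residual, keeps the lowest-ploidy cluster (within 0.5 of the
  cluster minimum), and takes the smallest residual there, breaking exact
  ties toward higher purity — the most parsimonious genome consistent with
  the data.

Flat, balanced profiles (e.g. a pure normal) carry no purity signal; the
fit warns and flags such samples low-confidence. Fitted purity below 0.3
flags the sample excluded-by-default, mirroring the conventional exclusion
of unreliable low-purity fits; the flag is advisory and can be overridden
downstream.

Sample ploidy is reported as the genome-length-weighted mean total copy
number of the final assignment (how the published ploidies were summarised
is not specified; this convention is labelled in the output).

## Genome-level calls

* `call_wgd()`: WGD iff ≥ 50% of the autosomal genome (by length) has
  major-allele copy number ≥ 2 — the boundary counts as doubled.
* `call_arms()`: an arm is gained/lost iff strictly more than 50% of its
  length is above/below total copy number 2. The baseline is absolute CN 2
  regardless of sample ploidy, so hypodiploid monosomies count as losses
  (matching how the published arm-level oncoplot treats them); whether
  "gain" should instead be relative to sample ploidy is undefined in the
  source and documented here as a deliberate choice.
* `gene_copy_number()`: genes inherit (total, major, minor) from the
  fine-pass segment containing them; genes spanning a breakpoint take the
  larger-overlap segment, exact ties the more aberrant one. The rule used
  is recorded per gene.
* `differential_gene_cn()`: per gene, a paired two-tailed t test of integer
  copy number across patients with Benjamini–Hochberg adjustment;
  significant iff adjusted p ≤ 0.05 and fold change ≥ 2. A gene whose
  paired differences have zero variance has no t statistic: if the constant
  difference is zero it is flagged not-testable; if nonzero the groups are
  perfectly separated and p is reported as 0 (the planted 4-vs-2 case).

## Multiplicity, zygosity and timing

Multiplicity inverts the VAF model:
$\hat m = \mathrm{VAF}\,(p\,c_T + 2(1-p))/p$, rounded and clamped to
$[1, c_T]$; $\hat m < 0.75$ marks the call subclonal (drivers in this
disease are treated as clonal, so the guard mainly protects simulated edge
cases). Zygosity: hemizygous (LOH) iff $c_T = 1$; homozygous iff minor CN
is 0 and $m = c_T \ge 2$; heterozygous otherwise; subclonal overrides;
indeterminate without copy-number context.

Event ordering per driver mutation (matched across samples by locus):

* **before duplication** — hemizygous in a non-WGD sample *and* homozygous
  in a WGD sample; or homozygous ($m = c_T \ge 2$, minor 0) in a WGD
  sample even when absent pre-WGD (the PTEN-like configuration).
  Homozygosity at $c_T > 2$ is accepted but flagged extrapolated.
* **after duplication** — multiplicity 1 on a $c_T \ge 2$ segment in a WGD
  sample.
* **unordered** otherwise; contradictory evidence across samples yields
  unordered with a conflict note.

The mutation logOR, $\ln((\mathrm{alt}+0.5)/(\mathrm{ref}+0.5))$, is
attached for overlay on B-allele plots under the assumption that the
mutation occupies every major-allele copy. The numeric form of the
"manually calculated" published quantity is not stated; the Haldane-corrected
natural-log odds is this package's declared convention.

## Driver phylogenies

Filtered mutations (VAF ≥ 0.15, nonsynonymous — exactly the calling
filter; no rescue of low-VAF shared mutations) define per-patient binary
presence patterns over samples. A laminar pattern family admits a
containment (Hasse) tree: branches are patterns, branch length is the
pattern's mutation count, samples attach under the smallest containing
pattern, and the all-sample pattern is the MRCA trunk (created with length
0 if absent). The published trees were assembled manually; the containment
construction is this package's formalisation.

Crossing patterns (the two-gamete violation) are resolved by the greedy
`drop-min` policy: repeatedly remove the conflicting pattern with the
fewest mutations (ties to the smaller, then lexically first pattern),
logging removals. Greedy removal equals the exhaustive minimum whenever
conflicts are disjoint (verified exhaustively on small families); with
chained conflicts it is an upper bound, which the validation suite checks
as such. Branch lengths are conserved exactly: their sum equals the number
of distinct filtered mutations minus those dropped.

Sample-level events annotate branches: driver labels ride their pattern's
branch; copy-number events and WGD are placed on the branch whose clade
equals the event's sample set, falling back (with a warning) to the deepest
branch whose clade is contained in it. Trees export to Newick (attributes
in a JSON sidecar so any reader can parse the Newick); the trunk survives
re-import as the root edge.

## Scores

H-score = integer intensity (0–3) × percent positive cells (0–100), range
0–300; fractional intensities are rejected. p53 positivity is strict
H > 10. `logcpm()` uses the voom convention
$\log_2((\mathrm{count}+0.5)/(\mathrm{lib}+1)\times 10^6)$; the T effector
score is the mean logCPM over the signature genes present (the signature
itself is a required user input — the published gene list is external and
is not invented here; tests use a placeholder list).

## Validation sizes and reproduction

The validation suite and `scripts/acceptance.R` run the same studies at
the same sizes, chosen to pin each statistic well below its pass margin:
50 simulated patients across purities {0.4, 0.6, 0.8} for zygosity/timing
recovery; 10 seeds × 3 purities × both genotypes (60 fits) for ASCN
recovery; 100 null + 50 step series for segmentation; 10 four-region
patients for phylogeny; 20 runs × 1000 genes for differential copy number;
25 simulated pairs for the burden medians. Zygosity errors concentrate at
purity 0.4, where one multiplicity-rounding misstep costs a homozygous
call — the accuracy stays above 95% overall.

## Known limitations

* Arm-level genotypes only: focal events inside arms are detectable by the
  fine segmentation pass but the simulator never generates them, so
  sub-arm recovery is untested.
* No subclonal (fractional) copy number; mixtures of clones within a
  region are supported by the simulator but the fit reports the dominant
  integer state.
* X and Y are out of scope throughout (the WGD rule is autosomal).
* The purity grid floor (0.05) and the low-confidence heuristic mean
  near-flat genomes return an arbitrary low purity with a warning rather
  than an estimate.
* Timing verdicts are point rules, as in the source narrative; no
  confidence measure is attached.
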