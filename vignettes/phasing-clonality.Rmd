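---
title: "Deciding the clonal origin of synchronous tumors by copy-number phasing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding the clonal origin of synchronous tumors by copy-number phasing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnaphase)
```

## The problem

A patient with several synchronous liver tumors may have multi-centric
disease — independent primary tumors arising from distinct transformed
clones — or a single primary with intrahepatic metastases. The two differ
profoundly in prognosis and management, yet pathology often cannot separate
them. Molecular reasoning helps: clonally related tumors share somatic
mutations, so the *recall rate* (the fraction of one region's somatic SNVs
also detected in another region or tumor) is high within a tumor and between
clonally related tumors, and low between independent primaries.

Recall alone can mislead. Chromosome-arm gains and losses recur so often in
hepatocellular carcinoma that two independent tumors frequently carry what
looks like *the same* copy-number alteration (CNA). If such a shared CNA is
identical by descent it is strong evidence of shared clonal origin even when
few SNVs are shared (for instance when most SNVs are subclonal and poorly
recalled). `cnaphase` implements a test of that identity-by-descent
hypothesis using only standard tumor/normal sequencing data.

## The phasing test

Consider a heterozygous germline site inside a one-copy loss. The normal
tissue shows allele fraction (AF) near 0.5. In the tumor, the ALT allele
sits on one specific parental homolog: if that homolog was lost, the AF
falls; if the other was lost, it rises. The *direction* of the AF shift
therefore reveals the phase of the site relative to the event, and all
sites shifting the same way belong to one haplotype.

For a tumor sample with purity $\rho$ (tumor-cell fraction), a site whose
ALT-carrying homolog has tumor copy number $c_{alt}$ inside a segment of
total tumor copy number $c_A + c_B$ has expected allele fraction

$$\mathrm{AF} \;=\; \frac{\rho\, c_{alt} + (1-\rho)}
{\rho\,(c_A + c_B) + 2(1-\rho)} .$$

At purity 0.8, a one-copy loss moves heterozygous sites from 0.5 to
0.167 or 0.833 depending on phase — a signal far above binomial counting
noise at depth 100 (standard error about 0.04).

Two tumors sharing a CNA identical by descent lost (or gained) the *same*
homolog, so sites shift the same way in both. Two independent events hit a
homolog at random, and on a different homolog every informative site's
shift reverses sign. The test:

1. **Select polymorphic sites**: heterozygous in the matched normal
   (AF within `het_band`, default $[0.35, 0.65]$; depth $\ge$ `min_depth`,
   default 10) inside the candidate CNA.
2. **Compute deltas** per tumor: pooled tumor AF minus normal AF.
3. **Group haplotypes** by the delta sign in a reference tumor:
   H1 ($\delta > +$`min_shift`), H2 ($\delta < -$`min_shift`), the rest
   uninformative. `min_shift` defaults to 0.05, just above the counting
   noise at typical exome depth.
4. **Welch two-sample t-test** at the H1 sites informative in both tumors:
   the reference tumor's AF values against the other tumor's AF values at
   the same sites, with Welch–Satterthwaite degrees of freedom. The test is
   run in both directions (each tumor once as reference) so the decision
   cannot depend on tumor order.
5. **Verdict**: the null hypothesis is that both tumors altered the same
   homolog. `different_homolog` requires both directional tests to reject
   at `alpha` (default 0.05) *and* the matched sites' mean deltas to have
   opposite signs in the two tumors; `same_homolog` requires concordant
   signs and no rejection; everything else — including fewer than
   `min_informative_sites` (default 10) matched sites — is `inconclusive`.

### Why the Welch test compares AF values, not deltas

Haplotype grouping uses deltas because the *sign* of the shift is the
phase signal. For the Welch comparison itself the package defaults to the
tumors' raw AF values at the matched sites. Both tumors' deltas at one site
subtract the *same* realization of the normal's AF, so deltas from the two
tumors are positively correlated; feeding them to an unpaired two-sample
test overstates the variance of the mean difference and makes the test
conservative (null p-values pile up near 1, costing power and calibration).
Raw tumor AFs are independent across tumors, and under the same-homolog
null with matched purities the directional p-values are uniform — which the
test suite verifies by simulation (Kolmogorov–Smirnov on 400 null
replicates). Delta mode remains available via
`phasing_config(welch_values = "delta")`.

### The sign guard

A significant t-test alone does not imply different homologs: two tumors
that lost the *same* homolog at different purities show same-sign deltas of
different magnitude, which a mean comparison happily rejects. Requiring
opposite mean-delta signs for a `different_homolog` call closes this false
rejection mode; a significant test with concordant signs lands in
`inconclusive`, never in `different_homolog`.

## Breakpoint concordance

Phasing cannot distinguish two independent events that happened to hit the
same homolog (probability 1/2 per event pair). Breakpoints can: a CNA
inherited from a common ancestral clone has the same boundaries in both
tumors, while independent events rarely break in the same place. Candidate
shared CNAs are segment pairs on the same chromosome with equal state and
reciprocal overlap $|a \cap b| / \max(|a|, |b|) \ge 0.5$; a pair is
`concordant` when both starts and both ends agree within `tolerance`
(default 1 Mb — array and exome segmentation is coarse; boundary
inclusive), with ends at which both segments reach the chromosome boundary
exempted (a shared telomere carries no breakpoint information). The classic
pattern of two terminal q-arm losses with proximal breakpoints 10 Mb apart
is `discordant`: independent events, whatever the phasing verdict.

Only segments longer than 50 kb (strict) with at least 21 supporting
probes enter the analysis, mirroring standard segmentation quality
thresholds.

## Somatic filtering and recall

Somatic candidates are called against the matched normal (germline iff any
variant read in the normal) and pass through non-short-circuiting exclusion
filters: segmental-duplication membership; any variant read in the normal;
normal depth < 10; tumor depth < 8; tumor variant reads < 3; tumor VAF
< 3%; population-database frequency strictly above 2%; local-cohort
frequency at or above 5%. Every failing variant records all reasons that
apply. Boundary semantics are deliberate: VAF exactly 3% passes, population
frequency exactly 2% passes, cohort frequency exactly 5% fails.

Recall between regions is directional, $|A \cap B| / |A|$ over ordered
pairs (the symmetric Jaccard index is available as an alternative metric);
within-tumor and cross-tumor averages exclude undefined pairs rather than
zero-filling them.

## The origin call

Per tumor pair, evidence is combined as: `common_origin` if cross-tumor
recall $\ge$ 0.5 or any shared CNA is same-homolog *and*
breakpoint-concordant; `independent_origin` if cross-tumor recall $\le$
0.15 and every candidate shared CNA is explained as an independent event
(different homolog or discordant breakpoints); otherwise `indeterminate`.
There is no sharp recall threshold in nature; the defaults separate the
regimes seen in multi-region hepatocellular data (within-tumor recall of
65–85% versus cross-tumor recall around 7–11% for independent primaries)
and are configurable in `classify_config()`.

## The synthetic-data generator

Because patient-level sequencing data of this kind are shareable only on
request, every stage is validated against a generator with full ground
truth. It emulates exactly the statistical structure the test assumes:

- germline heterozygous sites, Poisson-placed at `het_site_density` per Mb,
  each assigned to parental homolog A or B by a fair coin (the truth the
  phasing must recover);
- chromosome-scale CNAs assigned to a labelled homolog
  (`cna_spec(..., affected_homolog, homolog_copies)`); the expected AF
  follows the purity-mixture formula above;
- purity mixing (default 0.8, matching the pathology requirement that
  sampled tumor tissue contain at least 80% tumor cells);
- read counts as Poisson depth (mean 118 by default, the typical average
  WES depth for this design; truncated at one read) with binomial allele
  sampling — no separate sequencing-error term by default, which keeps
  every moment analytically checkable (an `error_rate` flag folds a
  symmetric error into the expected AF if wanted);
- somatic SNVs with truncal/private/cross-tumor-shared structure; truncal
  and shared mutations are detected per region with probability
  `trunk_detection_prob` (default 0.8, reproducing the observed
  within-tumor recall regime), true VAFs drawn from a beta distribution
  (mean 0.2 by default, mimicking the predominantly low allelic
  frequencies of these tumors). Position pools are disjoint by
  construction, so mutations are shared across tumors only by design
  (`cross_tumor_shared > 0`), never by collision.

The generator does **not** emulate mapping artifacts, strand bias,
caller-specific errors, subclonal copy number, or allele-specific states
beyond single gains/losses of one homolog. Passing tests therefore
demonstrate the statistical correctness of the inference under its stated
model, not robustness to every artifact of real pipelines — which is why
the filtering stage's thresholds exist and are configurable.

## Numerical and design choices

- `welch_t_test()` defines its degenerate cases instead of erroring: two
  constant samples with equal means give $t = 0, p = 1$; constant samples
  with unequal means give $p = 0$ with a warning; fewer than two
  observations per side is an error. With equal sample sizes and equal
  variances it reduces exactly to the pooled Student t.
- Coordinates are 0-based half-open internally; VCF positions and SEG
  tables convert at the I/O boundary only (SEG is 1-based inclusive).
- Multi-region tumors are pooled by summing read counts before computing a
  tumor's AF, weighting regions by their evidence.
- No multiple-testing correction is applied across candidate CNAs by
  default: decisions are reported per CNA at `alpha`, as is conventional
  when each CNA is reviewed individually.
- Verdicts are invariant under relabelling homologs A/B and under swapping
  the two tumors (both verified by tests).

## Problem sizes used in the validation suite

Simulation-based checks run at the study's conditions: purity 0.8, mean
depth 100, about 50 heterozygous sites per candidate segment. Calibration
uses 1,000 same-homolog replicates (type-I error), power 500
different-homolog replicates (≥ 95% detection), and noise-free recovery
100 replicates at purity 1 and depth 10,000. The end-to-end demo simulates
three tumors on the four chromosomes that carry the candidate events
(6, 8, 17, 21), with tumors 1 and 2 sharing losses of 17p-, 8q- and
21q-like segments on *different* homologs and a terminal 6q-like loss on
the same homolog with proximal breakpoints 10 Mb apart — the configuration
in which recall is silent, phasing resolves three events, and breakpoints
resolve the fourth.

## A worked example

```{r example, eval = FALSE}
cfg <- list(simulation = list(
  seed = 99, tumors_per_patient = 3, regions_per_tumor = 2,
  purity_per_region = 0.8, mean_depth = 100, het_site_density = 2,
  genome = list("6" = 171115067, "8" = 146364022,
                "17" = 81195210, "21" = 48129895),
  cna_specs = list(
    list(tumor_id = 1, chrom = "17", start = 0, end = 22e6,
         affected_homolog = "A", homolog_copies = 0),
    list(tumor_id = 2, chrom = "17", start = 0, end = 22e6,
         affected_homolog = "B", homolog_copies = 0)),
  somatic_params = list(trunk_mutations_per_tumor = 30,
                        private_mutations_per_region = 8,
                        trunk_detection_prob = 0.8,
                        cross_tumor_shared = 0,
                        vaf_mean = 0.25, vaf_dispersion = 0.1)))
report <- run_pipeline(cfg, out_dir = "demo_out")
report$origin_calls
report$patients[[1]]$phasing_table
```

## Known limitations

- Pairwise tests only; more than two tumors are handled as iterated pairs.
- Single-homolog gains/losses only; no subclonal CNA fractions or complex
  allele-specific states.
- The phasing test needs enough informative heterozygous sites inside the
  candidate CNA (exome data on a short segment may yield too few, giving
  `inconclusive`).
- Population-scale reference phasing (haplotype panels) is out of scope;
  phase is inferred from the CNA itself.
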