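---
title: "Whole-genome reconstruction of preimplantation embryos: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome reconstruction of preimplantation embryos: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(wgr)
```

## The problem

An IVF embryo biopsy yields a handful of cells. Genotyping that material on
a SNP array produces sparse, noisy, unphased calls at a few hundred thousand
sites — far from the dense diploid genome one would need to screen for a
rare pathogenic variant or to compute a polygenic risk score (PRS). The
insight exploited here is that the embryo's genome is not new information:
every allele it carries is present in one of its parents. If the parents are
whole-genome sequenced and *phased* — their variants assigned to physical
chromosome copies (haplotypes) — then reconstructing the embryo's genome
reduces to a much smaller inference problem: **which parental haplotype did
the embryo inherit along each chromosome, and where did meiotic
recombination switch it?** Once that transmission path is known, every
phased parental variant, including rare ones the array never measures, can
be read off onto the embryo.

`wgr` implements this program as the two-step *parental support* method:

1. **Parental phasing from sibling embryos** (`phase_parent()`,
   `phase_parents()`): sibling embryos co-inherit long haplotype stretches,
   so their array calls collectively reveal which parental alleles travel
   together.
2. **Transmitted-haplotype decoding** (`decode_transmission()`): a hidden
   Markov model (HMM) per embryo infers the inherited haplotype pair along
   each chromosome and calls recombination breakpoints; `fill_genome()`
   then propagates phased parental alleles across the inferred segments.

On top of the reconstructed genome sit the risk layers: PRS computation
with ancestry centering (`raw_prs()`, `center_and_standardize()`,
`or_from_prs()`), carrier-stratified integration of monogenic and polygenic
risk (`combined_or()`), and simulation of the PRS distribution of a
couple's potential embryos (`simulate_prs_cohort()`).

Everything is testable without clinical data because the package ships a
ground-truthed generator (`simulate_family()`) that emulates the whole
study design, including the "born child" whose true genome serves as
evaluation truth.

## The generative model

### Meiosis

Crossovers are placed as a Poisson process on the genetic-map (centimorgan)
scale: one expected crossover per 100 cM, no interference. A gamete copies
alternately from the parent's two haplotypes at the crossover boundaries,
starting from a uniformly chosen haplotype. Between two loci separated by
$d$ cM, the probability that the transmitted haplotype differs is the
Haldane map function

$$r(d) = \tfrac{1}{2}\left(1 - e^{-2d/100}\right),$$

which is exactly the marginal of the interference-free Poisson model, so
the simulator and the HMM transition kernel agree by construction. Chi-square
goodness-of-fit of simulated crossover counts against Poisson is part of the
test suite. Interference models (chi-square, Housworth–Stahl) are out of
scope; with array marker spacing well below 1 cM the practical effect of
interference on decoding is negligible.

### Biopsy noise

Few-cell genotyping after whole-genome amplification fails in characteristic
ways, decomposed in `noise_profile()` as:

* **allele dropout (ADO)** — one allele of a heterozygous site fails to
  amplify and the call collapses to a homozygote (either one, uniformly).
  Dropout of one allele of a homozygote is observationally silent, so it is
  folded into the miscall rate;
* **random miscalls** — probability `error`, spread uniformly over the two
  wrong calls;
* **no-calls** — probability `missing`, independent of the true genotype,
  mapped to a distinct missing state (never to hom-ref).

`emission_matrix()` is the exact channel matrix of this process and is used
both to corrupt simulated observations and as the HMM emission model, so
decoding is exactly matched to the generator. The presets
(`day5`: ADO 0.02, miscall 0.005, no-call 0.02; `day3`: ADO 0.10,
miscall 0.01, no-call 0.05) encode the expectation that single-cell day-3
blastomere biopsies genotype less reliably than multi-cell day-5
trophectoderm biopsies. True platform-specific rates are not published;
these are package calibration constants chosen to be plausible for amplified
few-cell SNP-array data, and users can override them freely.

## The transmitted-haplotype HMM

For one embryo and one chromosome, the hidden state at informative array
site $t$ (a site heterozygous in at least one parent) is the pair
$s_t = (m_t, p_t) \in \{1,2\}^2$ of transmitted parental haplotype indices.
Because the two meioses are independent, the transition kernel factorizes:

$$P(s_{t+1} \mid s_t) = T_{r}(m_t, m_{t+1})\; T_{r}(p_t, p_{t+1}),
\qquad T_r = \begin{pmatrix}1-r & r\\ r & 1-r\end{pmatrix},$$

with $r = r(d_t)$ for the inter-site map distance $d_t$. The emission is
the probability of the observed call given the genotype implied by the
state (the sum of the two transmitted alleles), under the noise profile.
The initial distribution is uniform.

`decode_transmission()` returns both decodings:

* the **Viterbi path** (jointly most likely), from which haplotype
  segments and breakpoints are derived — segment structure should be a
  coherent path, not a sequence of pointwise argmaxes;
* **forward–backward posteriors**, which supply per-site confidence and
  the posterior mixture reported inside breakpoint intervals.

Both are checked against exhaustive enumeration over all $4^n$ state paths
on small chromosomes (log-space agreement to $10^{-9}$), across hundreds of
random noise/parameter draws.

Numerical choices: the forward–backward pass uses per-site scaling (no log
underflow), Viterbi runs in log space, and Viterbi ties are broken toward
the lowest state index, deterministically.

### Breakpoints are intervals

A crossover is localized no better than the gap between the flanking sites
informative *for that parent* — only sites heterozygous in a parent carry
signal about that parent's transmission. Segments and breakpoints are
therefore bounded per parent by that parent's heterozygous informative
sites; the reported breakpoint is the whole interval, and in the noiseless
limit it provably contains the true crossover. Two consequences are made
explicit rather than hidden:

* sites inside a breakpoint interval are emitted with the flanking
  posterior mixture as confidence, never dropped (`fill_genome()`);
* some true crossovers are *undetectable by any marker-based method*:
  those outside the span of parent-informative markers, and even-parity
  multiples within one inter-marker interval (they cancel).
  `breakpoint_accuracy()` classifies these and scores detection on the
  detectable ones; `determined_sites_mask()` and (with synthetic truth)
  `truth_determined_mask()` delimit the sites whose genotype the data
  actually determine. On noiseless synthetic families, reconstruction is
  exact at 100% of determined sites — the residual genome-wide gap
  (~0.1% under the default site densities) is entirely the undetermined
  regions, an information limit, not an algorithmic one.

No minimum segment length is imposed; spurious single-site switches are
suppressed only by the transition prior, which keeps the decoder free of
hidden heuristics and testable against the enumeration oracle.

## Parental phasing from sibling embryos

Phasing chooses, for each pair of adjacent heterozygous parental sites,
whether their alternate alleles lie on the same haplotype (coupling) or
opposite ones (repulsion). The likelihood model is the same transmission
HMM: a phase configuration fixes the parental haplotype allele sequences,
and the likelihood of all embryos' calls follows.

The estimator chains left to right. At each heterozygous site the two
relative phases against the scaffold built so far are compared by the
likelihood of every embryo's observations, conditioned on all data to the
left through a per-embryo forward filter over the joint state
(this parent's transmitted haplotype, the other parent's). Refinement
sweeps then revisit each decision with full left-and-right conditioning
(forward–backward), flipping assignments the full-data likelihood
disfavors; this resolves decisions that were ties at first pass but are
disambiguated by later sites. On small noiseless instances the chained
result attains the global maximum-likelihood phase found by brute-force
enumeration over all $2^{k-1}$ configurations — a property in the test
suite.

The other parent enters in one of two ways:

* **phase unknown** (first pass): its transmitted allele is marginalized
  independently per site with a uniform prior over its alleles — with an
  unphased partner this is the only well-defined form of the
  haplotype-sum;
* **phase known** (second pass, against the partner's first-pass
  scaffold): the likelihood sums over the partner's transmitted haplotype
  proper. The partner's scaffold may itself contain errors, so its
  orientation across each step is trusted only with the product of its
  step confidences — an orientation error behaves exactly like an extra
  switch of its haplotype labels and is folded into its transition
  probability. `phase_parents()` runs two passes; more change little.

Decisions aggregate per-embryo log-likelihood ratios by summing them in
sorted order, which makes the scaffold invariant under permutation of the
embryos (a floating-point subtlety: naive summation order could flip
knife-edge ties). Exact ties are broken toward coupling, deterministically.
The reported confidence is the posterior probability of the chosen
relative phase given both flanks; calibration is checked on synthetic
data. With a single embryo the relative phase is unidentifiable — every
configuration explains the data equally — and the operation refuses.

Measured on synthetic families (6 sibling embryos, ~1,000 heterozygous
sites per parent, day-5 noise) the scaffold switch-error rate averages
below 1%, with family-to-family spread up to a few percent where one
parent's heterozygosity shadows the other's informative sites.

### Anchoring external phase

Dense phasing of the parents' full WGS variant set is expected from an
upstream reference-panel tool; the embryo-derived scaffold then fixes the
labeling of the physically transmitted chromosomes.
`merge_with_truth_phase()` records, at every site shared between scaffold
and external phase, whether their orientations agree; orientation blocks
between flips are re-labeled so the output agrees with the scaffold at
scaffold sites while external sites keep their panel phase relative to the
anchors. A sample-swap heuristic warns when orientation *flips* at more
than 40% of adjacent shared sites — a swapped or unrelated sample flips at
~50% of steps, whereas genuine block relabeling flips rarely (the
minority-orientation fraction would be the wrong statistic: legitimate
long blocks can hold any fraction of sites). Rare variants absent from
panels are attached from direct physical evidence via
`attach_rare_variants()`: an explicit haplotype index, or a linked anchor
site whose alternate-allele haplotype the rare allele inherits.

## Polygenic risk

The raw PRS is the weighted sum of effect-allele dosages,
$S = \sum_i w_i d_i$, with weights in log-odds units taken from each
model's source publication. Effect-allele orientation is resolved against
the site's ref/alt at scoring time (scoring files mix orientations); when a
model site cannot be predicted — unmeasured, or on an aneuploid-flagged
chromosome — it contributes its population expectation $2\,w_i\,\mathrm{AF}_i$
rather than silently dropping out, and the site accounting reports both
counts.

Raw scores are not comparable across ancestries, so they are centered and
standardized: ordinary least squares of the raw score on the first four
reference principal components, fitted on control individuals, is
subtracted, and the centered score is divided by the standard deviation of
the centered score in the reference population most closely related to the
individual (nearest population centroid in PC1–4 when no label is given).
We use the SD of the *centered* scores within the population — the
centered scale is the one the score is reported on, and on that scale the
controls have mean ~0 and SD ~1 by construction. The PC model itself
(`fit_pc_model()`) standardizes panel genotypes by $\sqrt{2p(1-p)}$ before
the SVD, and projection mean-imputes missing panel sites at the panel
frequency (requiring ≥80% coverage), which makes projecting a panel
individual reproduce its own panel score exactly.

The standardized score converts to an odds ratio as
$\mathrm{OR} = e^{\beta \cdot \mathrm{PRS}}$ with $\beta$ the per-SD log
odds ratio; OR(0) = 1 and OR(−x)·OR(x) = 1.

### Model quality gates

`validate_model()` applies three gates on a case/control cohort: ROC AUC at
least 0.6, increasing odds ratio across score deciles, and top-vs-bottom
decile OR at least 2. Decile ORs use the pooled middle deciles (5–6) as
reference with a Haldane–Anscombe correction so empty cells stay finite.
The increase-per-decile gate is assessed as a significantly positive
weighted trend of log decile OR on decile index (one-sided p < 0.05): at
the cohort sizes this package targets (thousands, not biobank hundreds of
thousands), literal pairwise non-decrease is rejected by per-decile
sampling noise even for genuinely strong scores, so the trend test is the
decile gate; the strict pairwise indicator is also reported for
transparency. The per-SD effect size is estimated by logistic regression
of status on the SD-scaled score and is recovered within a few percent on
synthetic cohorts with a known generating effect.

## Monogenic + polygenic integration

Carrier status for panel variants is read off the reconstructed genome:
carrier if the predicted pathogenic-allele dosage is ≥1, `"unknown"` — not
non-carrier — when the site is unpredicted (e.g. an aneuploid chromosome).
The combined risk is the carrier-stratified logistic form

$$\mathrm{OR} = \exp\!\left(\alpha\,\mathbf{1}[\text{carrier}] +
\beta_{\text{stratum}}\cdot \mathrm{PRS}\right),$$

with separate per-SD slopes for carriers and non-carriers (for breast
cancer the published per-SD ORs are 1.3 in carriers and 1.6 in
non-carriers — the carrier line is the shallower one on the log-OR scale)
and $\alpha$ the carrier main effect at PRS = 0. No interaction beyond the
stratum-specific slopes is modeled — the two-line form implies stratified
slopes. $\alpha$ must be supplied in the panel file: it is a fitted
quantity from cohort data that the package has no basis to default, so
example configurations carry a clearly marked synthetic placeholder.
Absolute-risk conversion is out of scope: baseline prevalences per age and
sex are not part of the inputs, so only odds ratios are reported.
`family_report()` summarizes a family: OR extremes and their fold
difference, embryos ranked by OR, and a flag for the inadvertent-transfer
scenario — embryos below the family's 50th PRS percentile that nevertheless
carry a pathogenic variant, the case where PRS-only screening would look
favorable while missing the monogenic risk.

## Simulating a couple's embryos

Two modes generate the distribution of PRS among potential embryos of a
couple (default 500 replicates):

* **linkage**: one simulated meiosis per parent on the genetic map,
  gametes united into a diploid genome — preserves linkage between
  neighboring model variants;
* **unlinked**: one allele drawn independently from each parent at every
  site.

Both have the same expected score — the midparent mean, which Mendelian
segregation makes the expected offspring value — but different variances
when model weights sit on linked same-sign variants (linkage preserves
their positive covariance). Crossovers reuse the same Poisson/Haldane
machinery as the family simulator rather than shelling out to an external
pedigree simulator, keeping the package self-contained; map files in the
public 3-column convention are accepted as input. Simulated scores can be
standardized through the same PC model as real embryos so the distributions
share a scale; whether to display raw-centered or standardized scores is a
presentation choice — we standardize.

## Evaluation conventions

Genotype accuracy compares unordered diploid genotypes (phase errors are
not genotype errors), stratified by the truth genotype class (heterozygous
sites are the harder class — both dropout and transmission errors show up
there) and by rarity (population allele frequency strictly below 0.1%, or
absence from the frequency table, is "rare"). Half-called or unpredicted
sites inside the comparison mask count as discordant, not excluded —
conservative and stated in the report. Stratified accuracies aggregate
exactly to the overall figure as a site-count-weighted mean, which is
checked in the tests. Embryo-vs-truth score concordance is the squared
Pearson correlation of paired centered scores pooled over conditions
(sign-invariant by construction, and undefined — a typed error — when
either vector is constant).

## Problem sizes and what passing tests show

The test-suite study conditions are scaled-down but structurally faithful:
families of 6 sibling embryos, 2 chromosomes of 100 Mb at 1 cM/Mb,
4,000 parental variant sites of which 1,500 are on the array, with the
day-3/day-5 presets above. Under these conditions the full pipeline
(embryo-based phasing included) shows mean genome-wide accuracies near
99.0% (noiseless), 98.4% (day-5) and 97.3% (day-3) — the same ordering,
and similar magnitudes, as clinical-scale reports, though the numbers are
not comparable in detail because array content, noise rates and genome
size all differ. The synthetic generator does not emulate: mosaicism or
segmental aneuploidy (whole-chromosome flags only), sex chromosomes,
intensity/B-allele-frequency channels (genotype calls only), crossover
interference, population LD structure in the parental haplotypes, or
platform-specific site ascertainment. Accuracy claims from these tests are
claims about the inference machinery under the stated noise model, not
about any particular clinical platform.

## Known limitations

* Phasing quality degrades for couples with few embryos; with one embryo
  it is impossible (and refused), with two it is weak.
* Regions where one parent is densely heterozygous while the embryos'
  calls are mostly ambiguous for the other parent phase poorly; errors
  cluster there (reported confidence drops accordingly).
* The emission model uses genotype calls only; platforms exposing
  continuous allele intensities carry extra information the HMM does not
  use.
* Aneuploidy is consumed as per-chromosome flags from an upstream caller;
  nothing is predicted on flagged chromosomes.
* The X chromosome is not modeled by default; autosomes only.
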