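---
title: "Detecting and assigning cacao ancient DNA in ceramic residues"
author: "paleocacao"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and assigning cacao ancient DNA in ceramic residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleocacao)
```

## The problem

Food residues adsorbed on archaeological ceramics can preserve traces of the
plants once prepared in them. For *Theobroma cacao*, two independent signals
are informative: methylxanthines (theobromine, theophylline, caffeine -
alkaloids abundant in cacao seeds) measured by mass spectrometry, and ancient
DNA (aDNA) surviving in the residue. Both signals are faint and easily
confounded - methylxanthines by ambient museum contamination, aDNA by the
overwhelming excess of microbial and other non-target DNA and by post-mortem
chemical damage.

`paleocacao` implements the full inference chain from raw paired-end reads to
ancestry assignments, together with a synthetic generator for every input, so
that each stage can be exercised and calibrated without any external data:

1. **simulate** - reference SNP panels, admixed genotypes, damaged aDNA
   libraries with per-base truth, methylxanthine measurement tables;
2. **readproc** - adapter/quality trimming, pair merging, exact
   deduplication, windowed entropy filtering;
3. **taxassign** - focal-genome prefilter, Smith-Waterman best-hit
   classification over a labelled multi-taxon reference, and the
   five-distinct-sequence presence call;
4. **damage** - mis-incorporation profiles, end base composition,
   fragment-length statistics, amplifiable-fraction curves, and a composite
   authenticity verdict;
5. **snpcall** - unique-mapping rule, damage-aware terminal SNP exclusion,
   biallelic-match filter, per-item genotype aggregation;
6. **popgen** - supervised admixture by EM, Nei (1978) distances,
   allele-sharing dissimilarity, neighbor-joining trees with locus
   bootstrap;
7. **chem** - methylxanthine positivity calls, background break-point
   estimation, chemistry/aDNA concordance tables.

## The damage model

A sequenced aDNA fragment is modelled by four ingredients.

**Fragment length.** Only a mean fragment length (81.65 bp) is established
for this material, so the length law is a modelling choice: we use a
log-normal truncated to `[30, L]`, matching the right-skewed shape typical of
ancient libraries, with `sdlog` defaulting to 0.35. The log-scale location is
calibrated numerically (by `uniroot` on the closed-form truncated-log-normal
mean) so that the *truncated* mean equals `length_mean` exactly; the sample
mean of a simulated library is therefore an unbiased estimate of the model
mean, and recovery tests need no fudge term.

**Deamination.** Post-mortem cytosine deamination is read as C→T at 5'
fragment ends and (after amplification) G→A at 3' ends. A cytosine at
0-based 5' distance $i$ converts with probability
$\delta_0 \lambda^i$; guanines mirror this from the 3' end. The geometric
decay is the standard single-strand-overhang approximation: two parameters,
and a directly testable ratio property (successive positions decay by
$\lambda$). Defaults are $\delta_0 = 0.05$ - inside the 4-5.5% terminal
range observed in ceramic-residue cacao libraries - and $\lambda = 0.7$,
a choice that keeps interior rates measurable in libraries of a few
thousand fragments; no decay constant is published for this material, so
$\lambda$ is a free parameter recovered from simulations only.

**Depurination.** Strand breaks preferentially follow purines, so the
genomic base immediately 5' of a fragment start is purine-enriched. The
generator weights candidate break points by `depurination_bias` (default 4)
in the orientation the fragment will be sequenced: for minus-strand
fragments the bias acts at the genomic *end* flank, which is a purine on
the minus strand when the plus-strand base is a pyrimidine. The enrichment
at offset −1 of the 5' end then has the closed form
$bg/(bg + 1 - g)$ for background purine fraction $g$, which the
`end_composition` operation recovers.

**Library rendering.** Reads are 2 × 150 with a constant Q37 quality; when
the insert is shorter than the read, the read runs through into a fixed
33-mer adapter (the sequence is arbitrary but constant, keeping trimming
tests deterministic). Contaminant read pairs are drawn from non-target
genomes at `contamination_fraction`.

What the generator does *not* emulate: sequencing miscalls beyond
deamination, indels, capture-bait enrichment bias, and the extreme
target-to-background ratios of real residues (the study mapped 0.0045% of
reads to cacao). Passing tests therefore demonstrate correctness of the
inference chain under its stated model, not end-to-end power on real
ceramics.

## Read processing

The chain is trim → merge → dedup → entropy, mirroring standard ancient-DNA
practice, with each stage pinned to an explicit, testable rule rather than a
tool's internal heuristic:

* quality trimming removes bases below Q20 from both ends inward (a
  transparent end-trimming rule, not a sum heuristic), discarding reads
  shorter than 30 bp;
* adapters are removed by full-occurrence match or exact terminal overlap
  (≥ 3 bases), longest match first;
* pairs merge at the best inner overlap of ≥ 10 bases with mismatch density
  ≤ 0.25 (the defaults of common merge tools); overlapping bases resolve to
  the higher-quality call, so a read-through pair reconstructs its fragment
  exactly;
* deduplication is exact-sequence (zero mismatches), stable-order;
* the entropy filter computes Shannon entropy of 5-mer counts in sliding
  50-base windows, normalized by the log of the number of 5-mer slots per
  window, removing a read when any window falls below 0.7.

Unmerged pairs are kept as two single-end sequences by default
(`keep_unmerged`), maximizing usable aDNA; whether the original pipeline
kept them is not documented, so this is a config switch. Stage accounting
counts sequences, so a merged pair appears as two reads in and one out of
the merge stage; merging is not a loss.

## Taxonomic assignment

Instead of a remote database search, assignment is a self-contained
Smith-Waterman best hit over a user-supplied labelled FASTA. The compiled
kernel (affine gaps: a gap of length $L$ costs
`gap_open + (L-1) * gap_extend`; `N` matches nothing) reports *all* tied
optimal locations by origin-tracking in the DP, which both the
unique-mapping rule and the tie handling need. Exact score ties between
taxa make a read *ambiguous* and it supports no taxon - the conservative
reading of a "first hit" rule, since database-order-dependent tie-breaking
is not reproducible.

The focal prefilter retains a read when its best score reaches 0.9 x read
length on either strand: high enough to exclude random 80-mers against
kilobase references with near-certainty, low enough to tolerate terminal
deamination (each C→T costs 2 score units; expected damage per read at
$\delta_0 = 0.05, \lambda = 0.7$ is well under one event per end).

A taxon is present in an item when at least **five distinct** first-hit
sequences support it - distinct by exact sequence identity after
deduplication, so PCR duplicates cannot vote twice. Negative controls must
stay below the threshold; the suite checks this across 20 seeds.

## Damage authentication

`damage_profile` aggregates three classic lines of evidence over the 25
terminal positions of each end: the C→T rate by 5' distance (and G→A by 3'
distance), base composition at offsets −2..+1 around each terminus, and the
fragment-length distribution. `authenticate` formalizes what is usually a
visual inspection into a reproducible three-criterion rule - terminal C→T
elevation over the interior median ≥ 3, purine enrichment at −1 ≥ 1.1, and
mean length ≤ 120 bp - with every threshold overridable and the evidence
always reported. When a criterion cannot be evaluated (for example, no
substitutions at all in an undamaged library), it is flagged inconclusive
rather than passed. `amplifiable_fraction` gives the companion qPCR
prediction: the fraction of template at least as long as each amplicon
(66/197/290/543 bp by default), and a predicted Ct shift of
$-\log_2$ of the fraction ratio under perfect doubling - a deliberate
simplification of amplification efficiency.

## SNP extraction

Allele observations are taken only from fragments mapping to a single
optimal location (both strands pooled; tied optimal starts closer than one
fragment length collapse into one location). Within the first five bases of
either read end, an observation is excluded **only** when it matches the
damage signature there - an observed T at a C/T locus near the 5' end, or an
observed A at a G/A locus near the 3' end, evaluated in read space - so a
terminal G at an A/G locus is kept. Observations matching neither panel
allele are discarded and their fraction reported (a few percent is expected
from residual interior damage). Because the terminal rule drops only
observations *inside* the allele pair and the biallelic rule drops only
observations *outside* it, the two filters commute.

Conflicting reads at a locus are resolved to a three-level dosage: 0 (all
reference), 1 (all alternate), 0.5 (both observed). This is the simplest
representation that still exposes heterozygosity to the admixture model;
the source pipeline does not document its resolution rule. Items with fewer
than 20 loci are flagged ineligible for ancestry analysis.

Note one consequence of the terminal rule worth knowing: a *genuine*
terminal T allele at a C/T locus is indistinguishable from damage and is
removed too. The filter's removal rate is therefore zero in undamaged data
only when no damage-mimicking allele is actually carried; the test suite
exercises exactly that regime.

## Ancestry inference

**Supervised admixture.** With labelled reference groups, the quantity of
interest - the membership proportion vector $q$ - is the maximizer of
$$\ell(q) = \sum_{\text{allele copies}} \log \sum_k q_k\, p_{k,l}(\text{allele}),$$
where $p_{k,l}$ is group $k$'s allele frequency at locus $l$. This replaces
an unsupervised MCMC clustering run: the target estimand is identical, but
EM on this concave likelihood is deterministic, fast, and testable (the
log-likelihood increases at every iteration, and the optimum is independent
of initialization). The K-sweep of the unsupervised approach becomes
unnecessary. Frequencies are clipped to $[\varepsilon_k, 1-\varepsilon_k]$
with $\varepsilon_k = 1/(2n_k+1)$, preventing private alleles in small
groups (n = 4 for two of the eleven cacao groups) from producing infinite
log-likelihoods. Two groups are flagged *ambiguous* when swapping their
fitted proportions changes the log-likelihood by less than 2 units - the
operational form of "cannot distinguish these two ancestries with this SNP
set", as arises for closely related groups; both attributions should then
be reported.

**Distances and trees.** Nei's 1978 distance uses the unbiased
within-population identities $(2n\sum p^2 - 1)/(2n-1)$ - the small-sample
adaptation - with small negative results clamped to zero and flagged. An
archaeological item enters as a population of one pseudo-individual (its
dosages as frequencies, n = 1); which exact estimator the original
distance software applies to that case is undocumented, so ours is stated
precisely instead. Individual-level trees use allele-sharing dissimilarity
$d(i,j) = \overline{|g_i - g_j|}/2$ and Saitou-Nei neighbor joining (via
`ape::nj`, negative branches clamped and counted), with locus bootstrap
(default 500 replicates, all driven by one seed) writing percent support
into node labels. On additive matrices NJ recovery is exact, which the
suite verifies against randomly generated trees.

The per-item report combines both analyses: admixture argmax, the two
nearest groups by Nei distance, a concordance flag, ambiguity pairs, and a
separate list of items failing the 20-SNP rule.

## Chemistry

Positivity is a strict `value > 700` pg/sample per analyte (700 itself is
negative), with sub-threshold values reported as 0, matching the survey
convention. The threshold is applied per analyte independently - the
natural reading, though not explicitly documented. The background break
that motivates the threshold is estimated as the largest gap between
consecutive log10 values below the 95th percentile (geometric midpoint
reported); a gap must exceed 0.5 decades - a three-fold jump - to count,
otherwise the break is *undefined* rather than invented. Concordance
tables are 2x2 per analyte over items analyzed by both methods, with
percentages in both directions sharing the same both-positive cell.
Percentages round half-up to integers (64.58 → 65, 80.77 → 81), with one
decimal carried alongside for cases where published tables truncated
instead.

The methylxanthine generator draws background amounts log-normal around 50
pg truncated below 200 pg (the ambient-contamination mode) and positives
log-normal around 5000 pg truncated above 700 pg; conditional on an item
being truly positive, caffeine is elevated with probability 0.85 and
theophylline 0.25, approximating their relative abundance in cacao. The
default 326 items and 0.37 positive fraction mirror the survey scale.

## Numerical choices and problem sizes

* All randomness flows through a single integer seed per operation
  (`withr::with_seed`), giving byte-identical reruns without disturbing the
  caller's RNG.
* Coordinates are 0-based half-open internally; file formats convert at the
  boundary (panel TSVs store 1-based positions).
* EM converges at a log-likelihood increase below 1e-8 (cap 1000
  iterations); alignment score ties use a 1e-9 band.
* The test suite and the acceptance script size their simulations to run in
  minutes on one core: 20,000 fragments for damage-parameter recovery
  (terminal rate within ±0.01), 50 admixed items over an 11-group,
  500-locus panel at divergence 0.15 for ancestry recovery (mean absolute
  error ≤ 0.08 per component), 500-replicate bootstraps on the 76-accession
  design, and 20-seed negative-control batches. Smith-Waterman work uses
  kilobase-scale references; the kernel is exact DP, so scores do not
  depend on reference size, only runtime does.

## Known limitations

* The best-hit classifier is exhaustive DP over the supplied FASTA; it is
  meant for curated multi-taxon references, not for NT-scale databases.
* Genotype dosages are point calls, not likelihoods; contamination-aware
  genotype models and imputation are out of scope.
* The authenticity verdict is a fixed-threshold rule on three summary
  statistics; it does not produce per-read damage posteriors.
* Linkage between loci is ignored throughout, as in the underlying
  admixture model.
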