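---
title: "Methods: from AP-MS spectra counts to binding-region maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from AP-MS spectra counts to binding-region maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppikit)
```

This vignette explains the models and procedures the package implements,
the assumptions behind them, the tunable parameters, what the synthetic
generator does and does not emulate, and the design choices made where
the procedure left genuine latitude. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. Peptide filtering and emPAI abundance

A Mascot ion score is $-10 \log_{10} P$, where $P$ is the probability
that a peptide-spectrum match is a random event; the conventional
identity threshold of 40 corresponds to $P = 10^{-4}$. `filter_psms()`
removes rows strictly below the threshold (score exactly 40 is kept),
and the operation is idempotent.

Protein abundance uses the exponentially modified protein abundance
index,

$$\mathrm{emPAI} = 10^{N_\mathrm{obs}/N_\mathrm{obsbl}} - 1,$$

where $N_\mathrm{obs}$ counts **distinct** peptide sequences passing the
score filter (per protein, per experiment) and $N_\mathrm{obsbl}$ is the
theoretical number of observable peptides for the protein. Three
decisions deserve note:

- *Distinct peptides.* emPAI is defined on unique observed peptides;
  repeated spectra of one peptide do not raise it.
- *Averaging.* The mean across experiments treats non-detection as
  emPAI 0, so a protein seen in one of two purifications gets half its
  single-experiment value. This penalizes non-replicated hits, which is
  the conservative reading of "averaged across experiments".
- *Observable counts are inputs.* In-silico digestion depends on
  protease rules and the instrument's preferred mass range, which are
  not part of this package's scope; `n_observable` is a column the user
  (or the generator) supplies.

Ranks sort by mean emPAI descending with lexicographic tie-break, so
output is reproducible under row permutation. Proteins with mean
emPAI > 1 carry a high-abundance flag.

## 2. The filtering funnel

The funnel is purely set-logical — detection, not enrichment:

1. **Known contaminants** (packaged list: keratins, bovine serum
   proteins, trypsin) are removed.
2. **Control subtraction** removes any protein detected in the matched
   control purification, regardless of abundance.
3. **CRAPome exclusion** removes proteins occurring in more than
   `max_occurrence = 1` of the negative-control experiments (30 by
   default). Proteins absent from the matrix count as occurrence 0.
   Selecting *which* controls match the experimental conditions is a
   manual database query, out of computational scope; the matrix is an
   input.
4. **Replicate intersection** keeps proteins found in every independent
   purification.

Stages 1 and 2 are pure set differences and commute; the order used
(contaminants first) follows the published description. Every stage is
idempotent and monotone (output ⊆ input), and stage reports chain so a
funnel figure can be re-rendered: per replicate, counts in/out and the
half-up integer percentage of the original hit list.

Percentages throughout the package round half-up
(`floor(100k/n + 0.5)`): published category tables use this convention
(52 of 248 prints as 21%), whereas banker's rounding would disagree at
exact halves.

## 3. Network construction and MCODE

`build_graph()` keeps edges with combined confidence score ≥ 0.700
**and** at least one evidence channel among {experimental, database} —
the "high confidence, no text-mining" regime used for published
interactome figures. Self-loops, duplicate edges and edges touching
unknown proteins are dropped with logged counts; listed proteins with no
surviving edges remain as isolated nodes.

MCODE is implemented from scratch (igraph supplies only the graph
container, coreness and traversal):

- **Vertex weight**: the highest k-core of the vertex's closed
  neighborhood is found; the weight is its order $k$ times its edge
  density. Vertices below the degree cutoff (default 2) weigh 0.
- **Expansion**: complexes seed from the unvisited highest-weight vertex
  and grow breadth-first, admitting a neighbor when its weight is at
  least $(1 - \mathrm{VWP})$ of the seed weight (VWP default 0.2), to a
  maximum depth of 100. Each vertex joins at most one complex.
- **Post-processing**: *haircut* (default on) takes the 2-core of the
  complex — iterative removal of singly-connected members, so a bare
  path yields no complex at all; *fluff* (default off) adds boundary
  neighbors whose closed-neighborhood density exceeds a threshold;
  complexes without a k-core of order ≥ 2 are discarded.
- **Determinism**: all orderings are (weight descending, name
  ascending), so results are independent of input row order.

Parameter defaults (degree cutoff 2, VWP 0.2, k-core 2, depth 100,
haircut on, fluff off) are the published defaults of the algorithm;
none are printed in the study this package models, so they are exposed
as `mcode_params()` arguments.

One behavior is worth stating explicitly because it is easy to
mispredict: **two 6-cliques joined by a single bridge edge merge into
one complex.** Every vertex of either clique — including the bridge
endpoints — has weight 5 (its closed neighborhood contains a 5-core of
density 1), so the expansion rule crosses the bridge. Separating such
structures is the job of a densest-subgraph objective, not of MCODE's
seeded expansion; the test suite asserts the merged behavior against a
by-hand trace, and verifies equivalence with an exhaustive
densest-subgraph oracle only on fixtures whose planted cliques are
disconnected, where the two notions provably coincide.

Cluster scores are density × size; the analysis of the large component
only (the published choice) is available via `largest_component()`.

## 4. Annotation and candidate prioritization

Gene sets are read from standard GMT files; symbols are canonicalized
by uppercasing only — no alias resolution, because the consumed lists
are symbol-based. When ASD and ID sets are present, a derived
ASD-or-ID flag supports the neurodevelopmental-disorder (NDD) pool.

`prioritize_candidates()` assembles the validation list in three
stages: (1) NDD-annotated interactome proteins ranked by mean emPAI
descending, top `top_n` (default 10); (2) proteins known to interact
with established partner TFs of the bait, if present in the interactome
and not already chosen; (3) paralogs of stage-2 picks, supplied as an
explicit two-column map and appended even when they failed replicate
intersection (their support is homology, not spectra). The ordering
question the source leaves open — ranking before or after removing
already-known interactors — is resolved as "rank the full NDD pool";
ties at the cut break lexicographically.

The single-cell expression filter keeps proteins at ≥ 1 transcript per
million (inclusive boundary) in a reference cell type; missing proteins
count as 0 TPM and are logged.

## 5. BRET analysis

Each plate carries experimental wells (donor-acceptor pairs),
donor-only control wells, and untransfected wells. The analysis is:

1. **Background**: subtract the per-channel mean of untransfected wells
   from every other well; floor negatives at 0 (negative luminescence
   is not propagated; the count of floored readings is logged).
2. **Corrected ratio**: per well,
   $\mathrm{Green1}/\mathrm{Blue1}$ minus the *plate mean* of the
   donor-only wells' ratio. Per-well pairing of control wells is not
   used — the control ratio is a plate-level property. Wells with zero
   donor signal are excluded with a warning.
3. **Testing**: one-way ANOVA across all construct groups on the plate,
   with Tukey HSD (Tukey–Kramer for unbalanced groups) post-hoc
   p-values from the studentized range distribution. Significance tiers
   use strict inequalities (`*` < 0.05, `**` < 0.01, `***` < 0.001) and
   the headline "positive interaction" flag requires adjusted
   p < 0.001 *and* a mean above the control's.

**Variant classification.** The trichotomy is never formally defined in
the source narrative; the rule adopted is: *abolished* when not
significantly above the acceptor-dead control (α = 0.05); *reduced*
when significant versus control but also significantly below wild type;
*retained* otherwise. Under this rule a variant that keeps a clear but
weakened signal (significantly below WT) is classified "reduced" even
where a narrative might say "retained interaction with decreased
signal" — the mapping is deliberate and documented here.

A statistically consequential choice: `variant_call_matrix()` fits
**one** plate-wide ANOVA and reads both post-hoc contrasts
(variant-vs-control, variant-vs-WT) from that single model, rather than
a separate three-group model per variant. With triplicate wells, a
per-triple model has 6 error degrees of freedom and its control
contrast is at the mercy of the three control wells' draw; the
plate-wide model pools the error variance (30 df on a 15-group plate)
and is the design the published figure captions describe. The control
fusion differs between assays (screen vs variant panels), so the
control label is a parameter, not a constant.

## 6. The synthetic generator: what it emulates, and what not

`synth_config()` defaults are the study-scale stated world: 248 true
interactors present in both purifications; per-replicate extras sized
(239, 27) so the replicated set is ~43% / ~68% of per-replicate hits;
60 bait-and-control contaminants; 25 CRAPome-frequent proteins; 5
injected known contaminants; a 30-experiment occurrence matrix; Mascot
scores gamma-distributed above the threshold with a 20% sub-threshold
peptide fraction (every detected protein keeps one passing peptide, so
detection is score-filter-invariant by construction); observable
peptide counts uniform on [8, 30].

BRET plates: donor counts are lognormal (median 5×10⁴ counts), the
acceptor channel is donor × (base ratio + transfer efficiency) with
multiplicative Gaussian noise (CV default 0.05, a realistic
plate-reader figure), plus a constant instrument background emitted as
untransfected wells — so zero-noise plates invert exactly through the
analysis. The donor-only base ratio defaults to 0.35 (typical
luciferase bleed-through into the acceptor filter). The screen truth
places five candidates at transfer 0.18–0.25, two marginal signals at
0.02–0.025, and eight at 0; the wild-type transfer in variant assays
defaults to 0.4 with "reduced" planted at half of it — the scale at
which class separations are uniformly clean at triplicate precision,
matching the qualitative pattern of the published calls. These defaults
were fixed from that pattern, not adjusted against test outcomes.

Randomness derives per-stage stream seeds from one root seed, so any
stage can be regenerated independently; identical configurations give
byte-identical files.

Not emulated: raw spectra and chromatograms (generation starts at the
identified-peptide level), protein inference from shared peptides
(synthetic peptides map uniquely), enrichment-based filtering, plate
position effects, and luminescence kinetics. A green test on synthetic
data therefore establishes the *logic* of the pipeline — thresholds,
set operations, statistics, determinism — not robustness to the many
upstream pathologies of real MS or plate data.

## 7. Binding-region inference

Variant nomenclature maps to intact intervals: `p.X*` keeps residues
$[1, X-1]$; `p.Xfs*N` likewise (the aberrant tail is ignored for
interval logic and flagged); missense keeps full length with a point
annotation. Named regions default to the T-box DNA-binding domain
(residues 213–393) and the C-terminal region (394–567; the source
prints both 568 and 567 as the right edge — the package uses one
residue short of the distal truncation point and documents the
discrepancy).

For each interactor, every pair (retaining truncation R, losing
truncation L) with intact(L) ⊂ intact(R) bounds the binding determinant
inside intact(R) \ intact(L); intervals from multiple pairs intersect.
Three rules refine this:

- *Reduced counts as retaining* for the required-interval set logic,
  but a reduced truncation paired with a longer fully-retained one
  contributes its differential segment as **involved** (partial)
  evidence — this is how a partially-lost interaction implicates both
  regions.
- *Missense losses never bound intervals*; a single residue change
  cannot delimit a binding surface, so they only mark their containing
  named region as involved. A missense loss inside a region that
  truncation evidence shows to be dispensable is reported as
  involvement all the same — an unexplained case, not resolved.
- *Dispensable regions* are those wholly absent from some
  fully-retained truncation.

`consistency_check()` flags the impossible pattern — a strictly shorter
intact prefix retained while a longer one is lost — for truncations
only. Inference is monotone: adding a retaining variant can only narrow
required intervals.

## 8. Numerical and degenerate-input choices

- Tukey p-values come from `stats::ptukey` on the Tukey–Kramer
  statistic; zero within-group variance yields p = 0 for any nonzero
  difference and p = 1 for identical groups.
- Background subtraction floors at zero rather than propagating
  negative counts.
- Empty protein lists report 0% with a warning; an empty denominator
  never divides.
- All set-returning operations sort their output; all rankings break
  ties lexicographically — nothing in the package depends on input
  order or hash order.

## 9. Known limitations

- The funnel is presence/absence; spectral-count enrichment tests
  (e.g. SAINT-style scoring) are out of scope by design.
- MCODE parameters are the algorithm's defaults, not values fitted to
  any particular network; on bridged dense regions MCODE merges
  complexes (see §3).
- The ANOVA assumes homoscedastic groups; the generator's
  multiplicative noise makes high-signal groups noisier, which the
  plate-wide pooling absorbs at the simulated scales but which a real
  analysis might address with a variance-stabilizing transform.
- Symbol matching is exact-uppercase; users with legacy aliases must
  resolve them upstream.
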