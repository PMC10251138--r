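---
title: "Methods behind paleohexkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind paleohexkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`paleohexkit` reconstructs paleopolyploidy histories from gene orders and
protein homology hits. This vignette records the models each stage
implements, the tunable parameters and their defaults, the numerical
conventions, and the choices made where the methodology is genuinely open —
so that results can be interpreted, and deviations from other pipelines
diagnosed, without reading the source.

## Data model and coordinates

A `genome` is an ordered collection of genes on named chromosomes. The
coordinate that matters downstream is not the base-pair position but the
`order_index`: the 0-based rank of a gene along its chromosome. Synteny
chaining, the alignment table, retention windows and loss runs all operate
on gene ranks, which makes the analyses insensitive to assembly-scale
differences in intergenic content. Internally coordinates are 0-based
half-open; GFF3 is read and written 1-based inclusive and BED 0-based
half-open, so files round-trip in their native convention.

Gene `family_size` is computed as one plus the number of distinct homology
partners of a gene in the E-value-screened hit graph, pooled across all
genomes. Whether family size should be counted within one genome or across
all is ambiguous in common practice; pooling is the default because
polyploid paralog clusters and cross-genome ortholog groups both inflate
spurious collinearity, and a `within_genome` flag restricts the count when
wanted. E-value/score screening is applied before the family-size cap, and
the family sizes themselves are computed on the E-value-screened graph.

## Synteny chaining

Filtered hits (defaults: E-value strictly below 1e-5, bit score strictly
above 100, both genes in families of fewer than 50 members) are chained per
chromosome pair by dynamic programming: the longest chain of hits strictly
monotone in both genomes' order indices, with at most `max_gap = 50`
intervening genes between consecutive anchors on either genome, searched
separately for the two diagonal directions. Chains are extracted greedily
by anchor count without anchor reuse within a chromosome pair, until no
chain of `min_anchors = 5` remains. `min_anchors` is a conventional floor
for calling a block rather than a principled constant; it is configurable.
The chainer is a clean-room re-specification of the max-gap collinearity
idea used by the established block detectors; it does not reproduce any
particular tool's scoring, which is why block boundaries may differ at the
margins from other software.

Orthology depth ratios are modal block-coverage counts: for each gene the
number of blocks whose anchor span covers its rank, summarized by the mode
over covered genes on each side. A genome triplicated relative to the
reference gives 1:3 under no loss, and the mode keeps the statistic robust
to partial fragmentation.

## Nei–Gojobori Ka/Ks

Potential synonymous sites per codon are the sums over the three positions
of the fraction of the three possible single-nucleotide mutations that are
synonymous; mutations creating stop codons count as nonsynonymous, so
`S + N = 3 × n_codons` exactly. Observed differences at codons differing at
2 or 3 positions average all orderings of the minimal mutational pathways
with equal weight, excluding pathways through stop codons (if every pathway
is excluded, all are used). Proportions are corrected with Jukes–Cantor,
`d = -(3/4) ln(1 - (4/3) p)`, undefined at `p ≥ 3/4` ("saturated", reported
as a missing value with a status rather than a number). Codons containing
ambiguity characters or alignment gaps are dropped pairwise; a terminal
stop codon is trimmed; only the universal genetic code is supported.
Pathway-weighting conventions differ slightly among historic
implementations; the convention here (equal weights, stop-path exclusion)
is asserted in the tests against an independent brute-force enumeration
oracle rather than against any external binary.

Block Ks medians are taken over anchors with defined Ks; a block whose
anchors are all saturated is flagged instead of dated.

## Ks peaks, rate correction and dating

Ks values (defaults: restricted to 0.05–3, the upper bound a saturation
guard) are smoothed with a Gaussian kernel of bandwidth 0.05 — chosen on
the Ks scale where polyploidy peaks are typically 0.05–0.15 wide — and the
density curve is fitted with a sum of Gaussians by bounded least squares.
The number of components is the smallest achieving R² ≥ 0.95 against the
curve (configurable); when raw values are available, component means and
standard deviations are refined by maximum likelihood on the values
hard-assigned to their most probable component. If the target R² is not
reachable at the allowed component count the best fit is returned flagged,
never silently.

Lineage-rate correction runs in two rounds. Round 1 uses peaks of each
lineage's divergence from the common outgroup reference. Under a normal
model for the divergence distribution, only the ingroup branch differs
between lineages, so aligning lineage *i* to the slowest lineage *s*
(smallest peak) through the branch average gives
`(1 + λᵢ)/2 · μᵢ = μₛ`, i.e. `λᵢ = 2 μₛ/μᵢ − 1`, and the corrected
distribution is rescaled as `X ~ (λμ, λ²σ²)`. These two identities are in
tension: the rescaled peak `λμᵢ` equals `μₛ` only when `λ = 1`. Both
quantities are therefore exposed (`corrected_mu` and `aligned_mu`) rather
than silently reconciling them; users dating events should state which
they use. Round 2 uses the shared-hexaploidy paralog peaks: both branches
of a paralog pair lie in the same lineage, so the full factor
`λ² = μₛ/μᵢ` applies, after which all lineages' paralog peaks coincide by
construction. A coefficient `λ ≤ 0` (benchmark more than twice slower) is
rejected as inconsistent.

Dating is linear in Ks against a user-supplied calibration
(`T = μ_corrected × T_cal / μ_cal`), applied to both endpoints of an
interval calibration. No absolute substitution rate is assumed.

## Event classification and the alignment table

A block is assigned to the event whose expected corrected Ks peak is
nearest its Ks median, within that event's tolerance; equidistant peaks
(within 1e-9) flag the block as an unresolvable tie rather than picking a
side.

The multigenome alignment table anchors everything to one reference gene
per row. The reference's own hexaploid history gives three panels; each
aligned genome receives `m = 3·2^N` slot columns per panel, `N` its number
of later tetraploidies, for `3·(1 + Σ m)` columns in total. Slot identity
is assigned region-wise, not gene-wise: blocks overlapping on the
reference are clustered into region groups and ranked by anchor count, the
most-retained region taking slot 1. This keeps the LF/MF1/MF2 reading of
slots stable along a region and means neighbouring genes of one block
always share a slot; the cost is that slot numbers are comparable within a
region group, not across chromosomes. Cells with no supporting anchor are
dots; a dot conflates "ortholog absent" with "ortholog translocated away",
and a side analysis of hits without synteny is needed to separate them.
Region groups with more distinct orthologous regions than slots are
flagged and the extras reported, never silently dropped.

## Fractionation statistics

Retention is profiled in sliding windows over reference gene ranks
(defaults: window 50 genes, step 25 — half-overlapping windows trade
resolution against noise; a chromosome shorter than one window yields a
single truncated, flagged window). Runs of consecutively lost genes are
maximal dot runs, broken at chromosome boundaries, and are fitted by the
one-parameter geometric model `f(k|p) = (1−p)^(k−1) p` via least squares
on the empirical length frequencies, reported with R² and the regression
F-test against the constant-mean model; the closed-form maximum-likelihood
estimate `1/mean` is always reported alongside as a cross-check, and is
the fallback for degenerate single-length data (all runs of length 1 give
`p = 1`).

Subgenome labels rank the copies of each homologous region triplet by
retained ortholog count: LF (least fractionated), MF1, MF2. Ties break by
total retention on the harbouring chromosome, then lexicographically, and
are flagged. Because window-level counts under clustered (run-length) loss
are noisy, region labels should be stitched along shared chromosome
context — the modal label over the windows of one subgenome copy of a
chromosome — which is how the genome-wide subgenome assembly is meant to
be read; the tests validate the stitched labels.

The retention-divergence test is a chi-square goodness-of-fit against
equal retention across copies (df = copies − 1), replaced by the exact
multinomial tail probability (flagged) when any expected count drops
below 5.

The P-index summarizes windowed retention asymmetry between two subgenome
copies: per chromosome, each divergent window contributes the sign of
`A − B`; the signed sum is divided by the count of non-tied windows and
its absolute value weighted by the chromosome's share of windows. The
divergence indicator is 1 for any nonzero difference by default
(`min_diff` configurable); tied windows contribute nothing and leave the
denominator; a chromosome with only ties is excluded and the weights
renormalized; with more than two copies the index is averaged over copy
pairs. The index lives in [0, 1], is invariant to relabelling the copies
and to chromosome order, and the conventional decision threshold is 0.3:
above it, biased loss of the allopolyploid kind; below, balanced
autopolyploid-like loss. The inherited symbol semantics of the windowed
formula (what exactly counts as a divergent window, and how the tie count
enters the denominator) are not fully standardized; the choices here are
the simplest consistent reading and are parameterized.

## Karyotype algebra and ancestral reconstruction

Chromosomes are ordered lists of signed segments; a chromosome read
backwards is the same chromosome. Events: EEJ (end-to-end joining,
count −1), NCF (nested fusion — a whole chromosome into an internal
breakpoint, count −1; a terminal breakpoint is rejected as being an EEJ),
RCT (reciprocal exchange of terminal portions, count unchanged), NCT (a
segment run moved into another chromosome, count unchanged), fission
(count +1), WGD/WGT (copy-suffixed duplication/triplication). The segment
multiset is conserved by everything except WGD/WGT.

Ancestral inference is junction-based. A junction is the oriented
adjacency of two signed segments, canonicalized under chromosome reversal.
By Dollo-style parsimony, a junction present in every descendant but
absent from the outgroup is assigned to the descendants' common ancestor;
convergent independent fusions are thereby ruled out by assumption, which
matches how shared connection patterns are normally argued but will
over-assign in the (rare) case of genuinely convergent joins. The
ancestral karyotype is assembled by chaining the derived shared junctions
plus the outgroup junctions retained in at least one descendant; each
segment end takes one adjacency (conflicts resolved by descendant support,
then lexicographically), cycles are broken at the weakest junction with a
warning, and junctions with conflicting orientations across descendants
are excluded and reported. Derived junctions are classified EEJ / NCF /
RCT / NCT against the outgroup structure (two chromosome ends → EEJ; a
whole chromosome at a broken adjacency → one NCF; reciprocal breaks of the
same two chromosomes → one RCT; the rest NCT). Segments shorter than a
configurable gene count (default 10) can be dropped before junction
analysis, which is how small inversions and minor deletions are ignored.
Equally parsimonious alternative chainings are reported as ties, not
resolved.

Two-step hexaploidy ordering uses connection patterns of an adjacent
region pair (A, B): per homologous copy, `(A)-(B)`, `(A)-(-B)` (B
inverted), or `unlinked` (different chromosomes). If exactly two of the
three subgenome copies share a state derived relative to the outgroup,
those two passed through the first-step tetraploid together; zero, one or
three derived copies, or an unlinked outgroup, are uninformative.

## The simulator

`simulate_paleogenomes()` generates the study conditions every test runs
under: an ancestral gene order (defaults 7 chromosomes × 200 genes, split
into 4 segments per chromosome as rearrangement granularity), an outgroup
reference lineage kept structurally conservative, a shared triplication
(default Ks peak 0.95, σ 0.08) with per-subgenome biased loss (default
rates 0.2/0.35/0.5 — retention ratio 2:1.5:1 — with geometric run
parameter 0.29), optional ingroup speciation (default peak 0.56) and a
lineage tetraploidization, rearrangements applied through the karyotype
module (explicit planted events or randomly drawn counts per branch), and
per-pair Ks drawn from the event node's truncated normal, scaled by
lineage rate multipliers (cross-lineage pairs use the mean of the two
rates; optional per-subgenome additive offsets emulate allopolyploid
subgenome age differences). Homology hits cover all surviving homolog
pairs, plus a configurable fraction (default 2%) of sub-threshold noise
hits that the filter stage must remove. CDS pairs are generated on demand
by `emit_cds()`, which places synonymous third-position substitutions
until the package's own Nei–Gojobori measurement hits the target Ks
(within about 0.02 at 300 codons) plus nonsynonymous changes at a
configurable Ka/Ks (default 0.2); targets requiring `pS` within 0.01 of
the Jukes–Cantor pole at 3/4 are rejected as saturated. A single seed
fixes every output bit-for-bit.

What the simulator does not emulate: nucleotide-level neutral evolution
(sequences are constructed to hit a pairwise Ks, not evolved along a
tree), intergenic DNA and transposons, tandem duplication, gene
conversion between paralogs, and annotation error. Tests passing on
simulated data therefore validate the inference machinery under the
stated models, not robustness to the full messiness of real genome
projects.

Loss runs are placed uniformly without overlap (resampled up to 100
times, then an error — which is also how a loss rate high enough to empty
a chromosome surfaces before emission).

## Pipeline and reproducibility

`run_pipeline()` executes load → filter → synteny → Ks → peaks /
correction / dating → classification → table → fractionation / P-index →
karyotype from one YAML config, writes stage outputs and a JSON report
with a manifest, halts naming the failing stage, skips stages whose
inputs are not configured (with a notice), and reuses the cached result
when rerun with an identical config. All stated thresholds (max gap 50,
family cap 50, E-value 1e-5, score 100, bandwidth 0.05, R² 0.95, window
50, Ks range 0.05–1.8 for retention-feeding blocks, P-index threshold
0.3) are surfaced as config defaults. Numeric report output uses 6
significant digits.

Test problem sizes are chosen to exercise every code path at desk scale:
unit fixtures of tens to hundreds of genes, mixture recovery at 5000
values, geometric recovery at 10⁴ runs, oracle equivalence on 100
100-codon pairs, and one end-to-end scenario on a 7 × 200-gene ancestor
with a triplication, a speciation, a lineage tetraploidization, planted
ancestral fusions and 2:1.5:1 retention bias.

## Known limitations

* The chainer's greedy extraction is order-dependent among equal-length
  chains; block boundaries can differ between equally valid decompositions.
* Dot cells conflate loss with translocation; separating them requires the
  hit graph, not just the table.
* The two printed forms of the round-1 correction (branch-average
  alignment versus full rescaling) are both exposed; downstream dates
  depend on which is used.
* Ancestral reconstruction assumes no convergent fusions and reports, but
  does not resolve, equally parsimonious chainings.
* Only the universal genetic code is supported, and Ks saturates near the
  Jukes–Cantor pole; pairs beyond Ks ≈ 3 are excluded rather than modelled.
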