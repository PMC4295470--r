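---
title: "Methods: kinase-domain candidate analysis with rlkscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinase-domain candidate analysis with rlkscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlkscan)
```

# The problem

Domain-targeted gene-family surveys isolate members of a large family — here
plant receptor-like kinases (RLK/Pelle) — from a genome without a reference
sequence, by degenerate PCR against conserved stretches of the kinase
catalytic domain. The resulting data are *partial* coding fragments
(individual fragments start and end at different kinase subdomains),
organised in clades, contaminated by frameshifted pseudogene copies, and
only classifiable by comparison with reference subfamilies. rlkscan
implements each analysis stage of such a survey as a tested function, and a
codon-evolution simulator that generates data with exactly this structure so
the full workflow is validated end to end without any external data.

# Models and procedures

## In-silico PCR and ORF screening

Degenerate primers are IUPAC strings. Matching is deliberately *asymmetric*:
a primer code matches any of its expansions, while the only template
ambiguity honoured is N (matches anything) — this mirrors how a degenerate
oligo anneals to an uncertain base call, rather than set-intersection
semantics. A reverse primer is written 5'→3' on the antisense strand and
matched through its reverse complement. Products are constrained by a
per-primer mismatch budget and a product-length window; `start`/`end`
always delimit the full primer-to-primer product (0-based half-open
internally; reports print 1-based coordinates), and `trim_primers = TRUE`
(default, matching the usual practice of trimming primer sequence before
analysis) returns the inner insert.

ORF screening translates from a frame offset up to the last complete codon;
any internal stop marks the fragment `interrupted`, with the stop's codon
index reported. Codons containing N or another ambiguity code translate to X
rather than erroring.

## Kinase subdomain annotation, RD/non-RD, activation segment

Because fragments start at different subdomains, subdomains are located by
*ordered anchor-motif matching*, not fixed offsets. The default anchors are
permissive regular-expression contexts for the canonical invariant motifs:

```{r}
default_anchor_profile()
```

Anchors are searched left-to-right in subdomain order; spans run
anchor-to-anchor (the boundary convention when no precise definition is
available). The anchor patterns are kept *looser* than the invariant
residues they contain, so that a mutated invariant (e.g. DFG→DFA) still
anchors but is reported by the separate invariant audit — a fragment is
**atypical** iff at least one invariant mismatches; invariants in unmatched
subdomains are "not spanned", not mismatches. A fragment matching fewer than
`min_anchors = 3` anchors is rejected as "not a kinase fragment"; with the
default patterns this rejects random 200-residue sequences ≥99% of the time
while accepting fragments that begin or end mid-domain.

The **RD/non-RD** call inspects the residue immediately N-terminal to the
catalytic Asp of the subdomain-VIB anchor (the HxD context, which the
default pattern requires to be followed by the catalytic-loop Lys/Arg/Asn
context): Arg → RD; anything else → non-RD with the substituent reported
(Cys being the biologically prominent case in pattern-recognition-receptor
clades); VIB absent → undetermined. `{RD, nonRD, undetermined}` is a
partition and the substituent is never R.

The **activation segment** spans the DFG anchor to the end of the APE
anchor. Consensus comparison uses editable tables of (offset from DFG,
allowed residues); the shipped defaults are reduced, implementer-transcribed
motifs limited to the functionally characterised T-loop phospho-positions of
the Pto and BRI1 activation segments. The BRI1 motif carries one serine more
than the Pto motif; by default the *second* serine is treated as an
insertion so the two phospho-threonines occupy corresponding positions —
the documented alternative (first serine as insertion) is a config switch
(`bri1_insertion = "S1042"`). Insertion positions belong to the motif, not
the query, and are skipped in matching; non-consensus residues are masked
as X in reports.

## Phylogenetic classification

Amino-acid distances use the Poisson correction with rate uniformity:
for each pair, *p* = differing / compared positions and *d* = −ln(1 − *p*)
substitutions per site. *p* ≥ 1 is undefined and raises an error naming the
pair. Gap handling defaults to **pairwise deletion** because fragments span
different subdomain ranges — complete deletion would discard most columns —
but complete deletion is available to mirror tools that default to it.

Trees are built by neighbor-joining (the standard Saitou–Nei agglomeration,
via ape); negative branch-length estimates are clamped to zero for display
with the raw minimum kept as an attribute. Bootstrap resamples alignment
columns with replacement; each replicate rebuilds the Poisson+NJ tree, and
every internal bipartition of the point-estimate tree is annotated with the
percentage of replicates containing it. Replicates with an undefined
distance are dropped and counted; more than 10% dropped is an error.

Subfamily assignment: a query receives subfamily S iff the *smallest*
supported clade (bipartition side with support ≥ `min_support`, default
70%) containing the query contains reference leaves of S only; mixed or
unsupported neighbourhoods give "uncertain". The 70% default is a
conventional "well-supported" cutoff; it is a config parameter, not a claim.

## Ka/Ks estimation (NG86 and a κ-weighted variant)

The default estimator is Nei–Gojobori counting, chosen because it is fully
specifiable and oracle-testable:

* **Sites**: each codon position contributes the fraction of its three
  possible changes that are synonymous; mutations *to stop codons count as
  non-synonymous*, so N + S = 3 exactly for every sense codon (the package
  verifies this identity against brute-force enumeration for all 61×61
  sense-codon pairs).
* **Differences**: for codons differing at k positions, syn/non-syn step
  counts are averaged over all k! minimal mutational pathways, with
  pathways passing through a stop codon discarded (uniform weights over the
  survivors). If every pathway is blocked, the codon pair is skipped and
  logged.
* **Correction**: Jukes–Cantor, d = −(3/4)·ln(1 − (4/3)p), applied to the
  synonymous and non-synonymous proportions separately; p ≥ 3/4 flags the
  estimate "saturated".
* **Sentinels**: Ks = 0 with Ka > 0 → ω = +inf ("undefined_inf");
  Ka = Ks = 0 → ω = NA ("undefined_na").

The `"YN-approx"` method applies the same pathway machinery with
transition/transversion weighting: sites and pathway weights are scaled by
κ on transition steps, with κ estimated from third positions of four-fold
degenerate codons shared by the pair (expected ts:tv ratio κ:2; estimate
clamped to [0.5, 20]). This is a documented approximation of
maximum-likelihood pairwise estimators that model the transition bias; it is
*not* a reimplementation of them, and outputs carry a method tag so reports
remain comparable only within one method.

Codon columns with a gap or ambiguity in either row are skipped and
counted. All counts are precomputed as 61×61 lookup tables per (code, κ), so
window profiling reduces to range sums.

## Sliding windows and tests

Windows are 75 nt (25 codons) advancing by 15 nt in *alignment coordinates*
(gap columns count toward the window): an alignment of L nt yields
⌊(L−75)/15⌋+1 windows. Within a window, ω is estimated for every unordered
pair of group members; pairs with fewer than 10 comparable codons in the
window, and pairs whose ratio is undefined or saturated there, are
*excluded* from the window mean and SEM, with exclusion counts reported.
Exclusion (rather than capping) was chosen because any cap value would
dominate small-window means arbitrarily.

Between-group comparison is a two-sided rank-sum test per window on the
per-pair ω lists, flagged significant iff p < α (default 10⁻⁴) *and* the
fold change of window means exceeds `fold_min` (default 2). The same
machinery compares a group's highest window against its lowest. The
neutrality check is a one-sided signed-rank test of a window's ω list
against 1 (H1: median > 1, default α = 0.05); zero differences are dropped,
and a window of ratios all exactly 1 degenerately returns p = 1.

Small samples use **exact enumeration over midranks** (all subsets for the
rank-sum, all sign flips for the signed-rank) whenever each side has ≤ 10
observations — valid under ties, and verified against independent
enumeration in the tests; larger samples use the tie-corrected normal
approximation. With complete separation at n = 20 vs 20 the exact two-sided
tail is 2/C(40,20) ≈ 1.4·10⁻¹¹, comfortably past the 10⁻⁴ rule; with ten
ratios above 1 the one-sided signed-rank p is exactly 1/1024.

## Non-synonymous position maps

A codon column is non-synonymously variable *within a group* iff ≥ 2
distinct amino acids are encoded among the group's gap-free members there
(a stricter pairwise codon-level mode is a flag). "Excluding gaps" is
operationalised as: a column is analysed iff at least one group has ≥ 2
gap-free members there, and a group participates at a column only under the
same condition. Sharing classes nest (shared-by-all ⊆ shared-by-2+), and
exclusives plus shared positions account for all variable positions.
Because both candidate denominators are defensible, sharing percentages are
reported against the variable-position count *and* the shared-position
count.

# The simulator: what it emulates, and what it does not

`simulate_family()` draws a random sense-codon ancestor, writes the anchor
motifs at fixed codon offsets (subdomain VIB in its RD or non-RD variant per
group), and evolves each clade by per-branch Gillespie event sampling on the
codon chain: relative rates are 0 into stop codons, κ on transitions, and an
ω multiplier on non-synonymous changes taken from a region map that tiles
the fragment. Anchor codons are frozen. Rates are normalised so a branch
length is the expected number of substitutions per nucleotide site under
neutrality; a cherry with terminal branches 0.15 therefore diverges at
roughly Ks ≈ 0.3. Event sampling was preferred over matrix exponentiation
because it is simple, exact for this model, and yields a complete *truth
map* — every realised substitution with position, codon change and syn/nonsyn
label — against which classification and variability analyses are validated
exactly.

Defaults mirror the scale of a kinase-domain survey: 4 groups × 8 members,
165 codons (495 nt, a typical fragment floor), κ = 2, within-group terminal
branches 0.15, group stems 0.4, relaxed regions (ω = 1) over the subdomain
I–II, V–VIA and VII–VIII analogs and ω = 0.1 elsewhere, and one non-RD
(Cys) clade. The ancestor is redrawn (up to 50 times) until the annotation
machinery finds the anchors exactly at their planted offsets, so chance
anchor-context matches elsewhere in the ancestor are excluded; descendants
diverge little enough that spurious matches remain rare, though not
impossible in principle.

Two deliberate simplifications:

* **Gapless by default.** The alignment is the true homology, so
  codon-alignment invariants hold trivially; indel evolution and alignment
  error are *not* emulated. Passing tests therefore demonstrate correctness
  of the counting, classification and testing machinery — not robustness to
  misalignment, codon-usage bias, heterotachy or recombination, which real
  amplicon data may contain.
* **Pseudogene copies** are made by inserting/deleting 1–2 nt at random
  positions restricted to the first 75% of the sequence
  (`max_rel_pos = 0.75`): a frameshift in the terminal stretch leaves too
  little downstream sequence for a stop codon to surface, and such copies
  would be indistinguishable from intact genes by any ORF screen — they are
  not informative "degraded" cases.

# Validation design and problem sizes

The acceptance-grade checks run entirely on simulator output and exact
oracles: NG86 site and pathway counts against brute-force enumeration over
all 61×61 sense-codon pairs; NJ against 50 random additive matrices (5–12
taxa, exact topology and branch lengths); ω recovery on 100-codon pairs at
ω ∈ {0.1, 0.5, 1.0} and Ks ≈ 0.3 (50 replicates each, mean within ±0.1);
relaxed-region detection (top window mean inside a planted ω = 1 region in
≥ 19 of 20 seeded runs); and full recovery of planted RD/non-RD labels and
clade memberships plus exact-enumeration agreement of the rank tests.

The ω-recovery experiment simulates at **κ = 1**, the rate symmetry NG86
itself assumes: it isolates the counting and correction machinery. The
estimator's behaviour under transition bias is exercised separately (κ = 2
at ω = 0.2, where the NG86 bias is well within the ±0.1 band); under strong
bias and high ω, plain NG86 is expected to underestimate ω — that is a
property of the method, and the reason results carry a method tag.

Bootstrap replicate counts in tests and the acceptance script are 30–200
(1000 in the `analysis/` drivers, the conventional choice for reporting);
simulated families in tests use 2–4 groups of 3–8 members. These sizes were
chosen to exercise every code path at comfortable desk scale.

# Known limitations

* Subdomain boundaries are anchor-to-anchor by convention; published
  figures sometimes use slightly different conventions, so span strings are
  comparable in structure, not guaranteed to match residue-for-residue.
* The default activation-segment consensus tables are reduced to the
  main-text-documented phospho-positions; a full consensus should be
  supplied by the user as a config table.
* `"YN-approx"` is an approximation (see above); for publication-grade
  maximum-likelihood pairwise estimates, export the codon alignment and run
  a dedicated ML tool, then compare method-tagged outputs.
* Maximum-likelihood tree inference and site-model tests (M7/M8-style) are
  intentionally out of scope; the NJ path is the classification backbone.
* Group comparison assumes profiles share window geometry; alignments of
  different lengths must be compared on a common alignment.
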