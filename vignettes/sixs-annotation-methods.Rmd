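---
title: "Annotating 6S RNA loci: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating 6S RNA loci: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sixsanno)
```

## The problem

6S RNA (gene *ssrS*) is an abundant bacterial small non-coding RNA that
mimics an open promoter and sequesters the housekeeping-sigma RNA polymerase
holoenzyme, globally dampening transcription during stationary phase. The
polymerase can use the bound 6S RNA itself as a template, synthesizing short
product RNAs (pRNAs, roughly 8–16 nt); once a pRNA:6S duplex grows long
enough the polymerase is released. In lactic acid bacteria the *ssrS* gene
sits in a conserved neighborhood between *rarA* (upstream) and *uspA*
(downstream), is typically followed by a Rho-independent terminator, and its
promoter region can carry catabolite-responsive elements (cre) bound by
CcpA.

`sixsanno` packages the computational stages needed to annotate such loci
across many genomes: homology search with analytic significance, a
synteny-constrained second search iteration, redundancy reduction to
representative consensus sequences, terminator calling with an empirical
shuffled-genome threshold, cre motif scanning with exact p-values under a
dinucleotide background, and projection of pRNA start sites through a
multiple alignment. A synthetic-cohort generator plants all of these
elements with known coordinates, so every stage can be validated against
ground truth.

## Homology search and its significance model

The search engine is deliberately simple and fully specified: exact
`seed_len`-mer matches between query and target (both strands) are extended
without gaps in both directions until the running score drops `x_drop` below
its maximum; the reported hit is the maximal-scoring extension. With
match/mismatch scores $s_{ij}$ and background base frequencies $p_i$ whose
expected per-position score is negative, ungapped local alignment scores
obey Karlin–Altschul statistics: the scale $\lambda$ is the unique positive
root of

$$\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1,$$

solved here by bracketed root-finding to ~1e-12 relative precision (for
match +1 / mismatch −1 and uniform background the equation reduces to a
quadratic with $e^\lambda = 3$). E-values are $K m n e^{-\lambda S}$ with
$K$ a configured constant (default 0.1): since $K$ rescales every e-value
by the same factor, its exact value only shifts thresholds, which are
themselves configurable.

Choosing an ungapped engine is a deliberate trade: gapped engines have no
exact analytic significance, whereas this one can be verified against a
brute-force maximal-segment scanner (the test suite does exactly that).
Sensitivity across indels is recovered by transitively joining overlapping
co-linear hits. The e-value tiers (1e-30 for annotated references, 1e-8 for
the relaxed pass, 0.1 for the rescue iteration, 1e-40 for anchor genes) are
a calibration onto this engine's e-value scale, not an equivalence claim
with any other search tool's scale.

Per genome, the best hit (smallest e-value; ties broken by higher raw
score, then leftmost start, then + strand — the tie order is a package
choice) is accepted under the assumption that each genome encodes at least
one 6S RNA; genomes without an acceptable hit proceed to the rescue stage.

## Synteny-constrained rescue

Anchor genes are located with the same engine at the strict 1e-40 tier;
each anchor interval is extended by `anchor_window_nt` (default 2000 nt) on
both sides, clipped and merged, and the second search iteration runs only
inside these windows, with exhaustive settings (seed length 4, no x-drop)
and the relaxed 0.1 threshold. A window from either anchor suffices; both
are used when present. Distances are measured from anchor boundaries, not
midpoints. Rescue hits overlapping first-pass hits are suppressed to avoid
double reporting. By construction no rescue hit can fall outside a window,
which is what makes the equally diverged out-of-window decoys in the
synthetic cohort a meaningful negative control.

## Redundancy reduction

Identical sequences are collapsed first (representative: smallest id).
Near-identical sequences are then clustered by Levenshtein distance at a
cutoff of 10: the package interprets "merge at distance ≤ 10" as
single-linkage (connected components of the ≤-cutoff graph), the only
parameter-free reading; chaining is observable through logged cluster
diameters. Each cluster is replaced by a majority consensus of its multiple
alignment: per column the most frequent symbol wins, columns whose strict
majority is the gap are dropped, and base ties resolve in the fixed order
A < C < G < T (a base beats a tied gap). Consensus is computed per cluster,
not from one global alignment of all sequences.

## Multiple alignment and coordinate maps

Pairwise alignment is Needleman–Wunsch with a linear gap penalty (defaults
match 2 / mismatch −1 / gap −2) and deterministic tie-breaking (diagonal,
then gap in the second sequence, then gap in the first). The progressive
stage builds a neighbor-joining guide tree on 1 − identity distances and
merges profiles leaf-to-root, scoring column pairs by average substitution
score ("once a gap, always a gap"). This sequence-only alignment replaces a
structure-aware aligner and is the package's single largest simplification:
for the ≥70%-identity sequence sets the pipeline targets, sequence
alignment suffices for coordinate projection, but where sequence and
structural alignments disagree, projected starts may differ.

Every alignment carries bidirectional maps between ungapped positions and
alignment columns; the inverse map resolves gap columns to the nearest
residue on the left and flags the result as inexact.

## Terminator calling with the shuffled-genome threshold

The hairpin scorer enumerates, on both strands, every inverted repeat with
a maximal stem of ≥ 4 pairs (G–C = 3, A–T = 2, G–T wobble = 1) around a
3–10 nt loop, scoring stem pairing − 0.5 per loop nucleotide beyond 3 +
the number of T in the 8 nt downstream. It is intentionally minimal — the
statistical rule around it is the interesting part — and its weights are
configurable.

Significance is empirical: the genome is shuffled ten times preserving the
exact mono- and dinucleotide composition (uniform Eulerian-path sampling
with fixed terminal characters), candidates are rescored on every shuffle,
and the threshold is the smallest observed candidate score $t$ such that
the mean number of shuffled hits with score ≥ $t$ is at most 5% of the
original hits with score ≥ $t$ — e.g. 100 original hits above 90 tolerate
an average of at most 5 shuffled hits above 90. "Above" includes ties, and
restricting candidate thresholds to observed score values loses nothing
(any intermediate $t$ yields identical hit sets). If no threshold
qualifies, the result is $+\infty$ and the genome gets no calls; this is
the expected outcome on featureless backgrounds and gives the procedure
its ~5% per-genome false-call behavior. Thresholding is applied per genome
sequence, and accepted overlapping candidates are merged keeping the
highest-scoring representative.

## cre motif scanning with exact p-values

The motif is a PWM with pseudocount 0.5 built from a site list. The
packaged list is a synthetic stand-in (pseudo-palindromic 14-mers; see
`inst/extdata/cre_sites_synthetic.txt`) because no training matrix is
bundled; users supply experimentally derived sites for biological work.
The background is the genome's own first-order (dinucleotide) Markov chain,
smoothed to keep all transitions positive. Window scores are log-odds in
bits, with the first position conditioned on the actual preceding genomic
base where available — closer to a true dinucleotide background than a
stationary initialization.

P-values are exact, not asymptotic: a dynamic program over (position, last
base, discretized score) yields the full score distribution under the
chain, with the preceding base drawn from the initial distribution.
Per-position score increments are rounded *down* to multiples of the
resolution (default 1e-3 bits), and the lookup compensates by the maximal
total rounding loss, so reported p-values are never smaller than the exact
tail and deviate by at most about `width × resolution` in score units. The
test suite verifies both properties against exhaustive $4^w$ enumeration
for widths 4–8.

Both strands are scanned (cre sites are pseudo-palindromic), each with its
own p-value table since the background chain is not strand-symmetric.
Scanning covers the gene plus 100 nt upstream in the gene's frame; hits at
negative offsets are classified `upstream`, others `internal`. Because a
single locus makes sequence-level e-values degenerate, the external
e-value-style gate becomes a best-N cap (default 5 hits per locus) on top
of the 1e-5 p-value threshold; overlapping same-strand hits are first
reduced to the best p-value.

## pRNA projection, shift correction and the pRNA tree

Reference start positions (supplied as inputs, not hard-coded) are mapped
to alignment columns; the modal column (ties: smallest) is mapped back to
each target. The pRNA is the antisense product read off the 6S template:
the default `toward_5prime` orientation returns the reverse complement of
the 16-nt window ending at the start position, with the start base pairing
the pRNA 5' nucleotide; the orientation is a configuration switch since
either convention is defensible. A motif (column frequencies and
information content 2 − H bits, no small-sample correction) is built from
the extracted pRNAs, and each start may then shift by up to ±3 nt to the
best motif log-likelihood (pseudocount 0.5 avoids −∞; ties prefer the
smaller absolute, then negative shift; one pass, no iteration). The shift
is implemented as signed — "up to three nucleotides" is read as either
direction. Finally, pRNAs trimmed to positions 1–15 plus their consensus
enter a Saitou–Nei neighbor-joining tree on Hamming distance / 15
(Hamming is an assumption; the choice of distance for short
near-identical sequences has little leverage).

## The synthetic cohort: what it emulates and what it does not

Each synthetic genome is a stationary first-order chain (default uniform
dinucleotides, length 10 000 nt) into which the generator overwrites: a
rarA marker, a 6S gene copy mutated from a packaged 188-nt seed sequence
(default 10% substitutions, no indels), a hairpin/U-tract terminator
immediately downstream, a uspA marker — all within the 2000-nt anchor
window — plus a cre site sampled from the training PWM in the 100-nt
upstream region, and one equally diverged decoy copy placed farther than
the window from any anchor. Anchors are synthetic nucleotide markers
(360 nt), not real protein genes: the rescue stage only needs locatable
anchors, and markers keep the fixture self-contained. The seed 6S sequence
is likewise a constructed fixture with the canonical architecture (closing
stem arms around a weakly paired central bubble, where the pRNA template
position sits); its exact identity carries no biological claim.
Substitutions are uniform over the three alternative bases; indel lengths
are uniform on {1, 2, 3}.

What the cohort does **not** model: real gene structure and codon bias,
phylogenetically correlated divergence, rearranged or partially conserved
synteny, multi-replicon genomes, and non-canonical 6S variants. Passing
tests therefore demonstrate the correctness of the algorithms under
controlled conditions, not field performance on real genome corpora.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open internally; GFF3 output is 1-based
  inclusive; the round trip is the identity.
- U and lowercase are normalized to T/uppercase; other characters are
  rejected in strict mode or replaced by a seeded random base in lenient
  mode.
- All randomness flows through per-stage child seeds derived from one
  configured seed; every run is bit-reproducible and the resolved
  configuration is logged.
- Root-finding for $\lambda$ brackets the positive root away from the
  trivial root at 0 and polishes with one Newton step.
- The adaptive terminator threshold returns $+\infty$ (no calls) rather
  than inventing a threshold when no candidate qualifies.
- Alignment traceback uses a 1e-9 tolerance when comparing profile scores,
  with the fixed diagonal/up/left preference.
- The p-value DP clamps −∞ log-odds increments (zero motif probability)
  far below the lowest finite path so that impossible windows never
  contaminate finite-score tails.

## Problem sizes used in the shipped tests

The test suite validates each stage at sizes chosen to give stable
statistics while keeping a full run lightweight: 1000 random sequences
(lengths 2–2000) for the shuffle invariants, 100 random query/target pairs
against the brute-force search oracle, exhaustive enumeration up to motif
width 8, a 50-genome cohort at 15% divergence for rescue sensitivity
(observed ≥ 95% with zero decoy calls), 40 targets at 10% divergence for
pRNA projection and shift correction, and 50 terminator-free 2-kb
backgrounds for the false-call rate. These sizes are the package's own
validation choices; all of them regenerate their data programmatically.

## Known limitations

- Sequence-only alignment in place of structural alignment (see above).
- The hairpin scorer ignores thermodynamics (no nearest-neighbor ΔG); it
  is a stand-in whose job is to feed the adaptive threshold.
- One search engine with one e-value scale replaces several external tools
  whose scales are incomparable; threshold tiers are re-calibrations.
- Whether genomes should be pooled per species rather than thresholded per
  sequence for terminator calling is left per-sequence.
- cre site lists bundled with the package are synthetic stand-ins.
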