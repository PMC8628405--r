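---
title: "Methods: site profiling, clade assignment and simulation in opsintools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: site profiling, clade assignment and simulation in opsintools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opsintools)
```

## The scientific problem

Opsins of the photoisomerase family (retinochromes, RGRs, peropsins)
differ from signaling visual pigments in two sequence-level respects
that can be read off an alignment against bovine rhodopsin, the
numbering standard of the GPCR literature. First, monostable visual
pigments carry a negatively charged counterion at position 113 that
stabilizes the protonated retinal Schiff base, whereas bistable
pigments — which re-isomerize retinal with a second photon rather than
releasing it — carry an uncharged residue there. Second, G-protein
activation depends on four interacting residue pairs (D83/N302,
R135/Y223, K231/E247, Y306/F313) and the NPXXY motif at 302–306;
photoisomerases have lost several of these and are therefore poor
candidates for phototransduction despite binding retinal. A parallel
question arises for CRAL_TRIO retinoid-binding proteins: ten residues
of RLBP1/CRALBP (W166, Y180, F198, C199, M209, Q211, M223, V224, M226,
W245) are critical for retinoid binding, and the number conserved in a
candidate sequence is a direct, interpretable measure of likely
binding competence.

opsintools turns these observations into a reusable pipeline: map
reference-numbered sites onto query sequences, classify counterion
state and signaling competence, tally the ten RLBP1-critical residues,
and place queries into labeled clades (retinochrome, RGR, peropsin,
…) on a distance tree with bootstrap support. A sequence simulator
with planted, clade-constrained sites supplies ground truth so that
every stage is testable without downloading data.

## Coordinate mapping by global alignment

All site calls rest on a single primitive: a global pairwise alignment
of the query against the scheme reference, computed by the
Needleman–Wunsch/Gotoh three-state dynamic program. Conventions, all
of which matter for exactness and are therefore fixed rather than
left to a library default:

* **Affine gaps.** A gap of length $k$ costs
  $g_{\mathrm{open}} + k\,g_{\mathrm{ext}}$ — the opening column is
  charged both terms. Defaults $g_{\mathrm{open}} = 11$,
  $g_{\mathrm{ext}} = 1$ with BLOSUM62, the standard protein setting;
  both are arguments everywhere since no single setting suits all
  divergences.
* **Terminal gaps are penalized** like internal ones. Site mapping
  needs end-to-end coordinates; free end gaps would let a divergent
  terminus float and silently shift the numbering.
* **Deterministic tie-breaks.** Where optima tie, the traceback
  prefers an aligned column, then a gap in the query, then a gap in
  the reference, both at the final cell and at every predecessor. Two
  runs on the same input are byte-identical.
* **`X` scores 0 against everything** and never counts as a site
  match: ambiguous residues are common in translated transcriptome
  data, and ambiguity is evidence of nothing.

The aligner is validated against exhaustive enumeration of every
global alignment of short sequences (200 random pairs of length ≤ 6
per run), which is feasible because the affine cost of a path can be
accumulated move by move.

The progressive multiple alignment (used only for trees, never for
site mapping — pairwise mapping is order-independent and reproducible
per query) merges profiles along a neighbor-joining guide tree built
from pairwise p-distances, scoring profile columns by the mean
pairwise substitution score and never removing a gap once inserted.
Manual alignment curation is replaced by a reproducible column filter:
columns with non-gap occupancy below `min_occupancy` (default 0.5) are
dropped before distances are computed.

## Site calls and classifications

A *reference scheme* is a reference sequence plus named sites
(1-based positions in that sequence), pair rules and motif rules.
"Conserved" means identity with the site's expected residue set, which
defaults to the single reference residue; the figures this mimics use
identity, and a biochemical-similarity mode can be expressed later by
widening the expected sets in the scheme config. Classification rules:

* **Counterion**: observed E or D at the counterion site → `charged` →
  `monostable-like` (D is the only other negatively charged residue);
  any other residue → `uncharged` → `bistable-like`; a gap or `X` →
  `indeterminate`.
* **Pairs**: `intact` iff both members match; `indeterminate` iff both
  members are unaligned; otherwise `broken` — in particular, one
  member missing while the other is informative is a deviation (the
  chordate-RGR pattern, where E247 is absent altogether), not missing
  data.
* **Motif**: `intact` iff every anchored residue (N302, P303, Y306 for
  NPXXY) matches; wildcard positions are unconstrained.
* **`signaling_intact_count`** is the number of intact pairs plus
  intact motifs, 0–5 for the packaged opsin scheme. `indeterminate`
  never contributes.
* **RLBP1 score** is the number of matches among the ten
  `rlbp1_critical` sites; unaligned counts as non-match, so a
  truncated protein scores low rather than dropping out.

Two schemes ship with the package. The opsin scheme is built on the
bovine rhodopsin sequence (UniProt P02699, 348 aa). The RLBP1 scheme
carries the ten critical residues at their literature positions but
embeds them in a **synthetic** 317-aa background (a deterministic
random draw), clearly labeled as such; to reproduce literature
numbering on real CRAL_TRIO data, build a scheme on the genuine human
RLBP1 (UniProt P12271) and pass its config path. Conservation tallies
against the synthetic background are positionally faithful only at the
ten critical sites.

## Trees, rooting and clade assignment

Tree inference is deliberately desk-scale: Poisson-corrected distances
$d = -\ln(1 - p)$ over shared non-gap columns, neighbor joining
(Saitou–Nei criterion, Studier–Keppler updates), and plain
nonparametric bootstrap over alignment columns. Every report labels
the method ("NJ + Poisson distance, nonparametric bootstrap") so its
supports cannot be mistaken for ML bootstrap proportions or Bayesian
posteriors from heavier machinery. Numerical choices:

* $p$ is capped at 0.95 before correction (the correction diverges as
  $p \to 1$); capped entries are counted and reported. Saturated
  distances are a warning sign in their own right — beyond the cap the
  matrix carries little tree signal.
* Ties in the NJ criterion are broken lexicographically on the pair of
  node keys (a node's key is the smallest leaf label it subtends), so
  degenerate matrices resolve deterministically.
* Negative NJ branch lengths are clamped to zero with the deficit
  moved to the sister branch, preserving the joined pair's distance.
* Rooting uses the outgroup MRCA edge. On bootstrap replicates where
  the outgroup is not recovered as a clean split, the root goes on the
  edge maximizing (outgroup minus non-outgroup leaves) on the outgroup
  side, ties broken by sorted label order — a rule that behaves
  sensibly on noisy replicates instead of failing.
* A query is assigned clade $C$ iff the smallest rooted clade
  containing it and at least one reference contains only references of
  $C$ besides the query; anything mixed is `unassigned`. The bootstrap
  assignment is the modal label over successful replicates (ties →
  `unassigned`), its support the modal fraction. Replicates in which
  some pair shares no sampled column are excluded and counted.

## What the simulator emulates — and what it does not

The simulator evolves a uniform-random root sequence along a rooted
tree under an equal-exchangeability 20-state process with uniform
stationary frequencies, for which the per-branch substitution
probability has the closed form
$p_{\mathrm{diff}}(t) = \tfrac{19}{20}\left(1 - e^{-\frac{20}{19}t}\right)$.
Clade-diagnostic sites are planted: on the stem branch of an annotated
clade the site is set to that clade's residue and held invariant
below, mimicking a counterion state or a conserved binding residue
fixed within a clade. The closed form makes calibration exactly
testable (observed mismatch fractions are checked within 3 standard
errors at 10,000 sites for $t \in \{0.1, 0.3, 1.0\}$).

Deliberate simplifications, and what they mean for interpreting green
tests: there is **no indel process** (the true alignment is the leaf
sequences, so ground-truth coordinates are exact), **no rate
heterogeneity, no empirical exchangeabilities, no compositional
bias**. Passing recovery tests therefore demonstrate that the
pipeline's logic is correct under a clean generative model — they do
not certify performance on real opsins, where alignment error,
heterotachy and saturation are all worse. The pipeline itself never
assumes the generative model.

## The recovery experiment

The standard validation scenario (`recovery_config()`) is four clades
of three references plus one held-out query each, and a two-leaf
outgroup, radiating from the root as a star of five stem branches of
0.3 substitutions/site with 0.1 terminal branches and 200 sites. The
star shape is a deliberate choice: every internal branch is the 0.3 of
the scenario description, and root-to-leaf divergence stays at 0.4
(~70% identity), where global alignment maps planted sites reliably;
a deeper nested backbone would push queries to ~40% identity against
the profiling reference, where occasional one-column gap shifts make
single-site calls — and thus exactness guarantees — impossible for any
identity-based method. Clade separation (≥ 0.8 expected
substitutions/site between clades) still makes placement non-trivial.

Planted truth: position 113 carries E in clades A and C, F in B, D and
the outgroup; ten binding-style sites carry the root residue in
clade-specific subsets of sizes 10, 8, 6 and 3 (echoing the spread of
tallies seen across real CRAL_TRIO proteins). Each trial simulates a
dataset, profiles the four queries against a scheme built on the known
root sequence, aligns all leaves, filters columns, and places each
query by bootstrap (100 replicates). With 50 trials (the problem size
used throughout the package's own validation; one run takes a few
minutes on one CPU) the experiment checks: clade-assignment accuracy,
counterion classification accuracy, and exact recovery of every
planted tally.

## Degenerate inputs and edge cases

Empty-vs-empty alignment is an error; empty-vs-sequence is a single
forced gap run costing $g_{\mathrm{open}} + L\,g_{\mathrm{ext}}$.
Rows sharing no residue column have no defined p-distance and raise an
error naming the pair; during bootstrap such replicates are dropped
and counted rather than aborting the run. Fewer than three labels
cannot form an unrooted tree. Scheme configs are validated on read:
positions must lie in the reference, the reference must carry an
expected residue at every site, pair members must exist, motif anchors
must sit on defined sites. Output directories refuse to overwrite
prior results unless forced, and every command writes a provenance
record (input checksums, parameters, seed, package version, method
label).

## Known limitations

Identity-based conservation cannot distinguish conservative
substitutions (an E↔D swap at a pair member is "broken" even though
both are acidic) — widen the expected set in a custom scheme where
that is wrong for your question. Pairwise site mapping degrades below
roughly 50% identity to the reference, as any alignment-based
numbering must. NJ on Poisson distances is a placement tool, not a
phylogenomic analysis: use it to ask "which labeled group does this
sequence fall into and how stable is that under resampling", not to
estimate deep topology. The packaged RLBP1 scheme's background is
synthetic; absolute positions outside the ten critical sites carry no
biological meaning.
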