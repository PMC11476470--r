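---
title: "Designing and scoring split-intein dual-AAV constructs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and scoring split-intein dual-AAV constructs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midisplit)
```

## The design problem

A dual-AAV protein-trans-splicing (PTS) strategy expresses a large
protein as two halves, each fused to one half of a split intein, from two
vectors. After co-expression the intein halves associate and splice the
flanking exteins into the intact protein. Whether splicing works at
useful efficiency depends on (i) a chemically valid junction, (ii) both
cassettes fitting the vector, and (iii) the two halves actually
associating. `midisplit` covers the sequence-level design rules for (i)
and (ii) and a structure-confidence score for (iii) computed from
AlphaFold3 (AF3) outputs.

## Construct assembly and split placement

A construct is an ordered list of domain segments on a reference protein,
each optionally trimmed (`keep_start`/`keep_end`, domain-local 1-based
inclusive coordinates). All residue indexing in the package is 1-based
with inclusive ranges; there is no zero-based convention anywhere.
Trimming targets the intrinsically disordered hinge regions because they
tolerate shortening without disrupting the folded repeats;
`hinge_reduction_stats()` reports `100 * (1 - kept/original)` per hinge to
two decimals. A 96-residue hinge with its first 54 residues removed is a
56.25% reduction — the kind of edit that buys cassette space.

Split sites are enumerated as every position whose *following* residue is
serine, because for GP41-1 the first C-extein residue is the
catalytically essential nucleophile, and the remaining native junction
residues (SGY/SSS) are dispensable. This makes split placement traceless:
no foreign residues remain in the spliced product. `build_halves()`
composes `N-extein + IntN (+ tag)` and `IntC + C-extein` and refuses a
non-serine junction outright rather than warning, since such a design
cannot splice.

### Mass bookkeeping

`molecular_weight()` uses average residue masses (Expasy-style table)
plus one water, free termini, no PTMs — the convention under which
intact-protein masses are quoted on Western blots. This gives an exact
additivity identity, used as a design cross-check: the two expressed
halves outweigh the full construct by exactly the mass of the joined
intein halves (plus tag, if present). For GP41-1 (88 + 37 aa) that
excised mass is ~14.2 kDa, and the split designs here carry no tag on the
halves by default (an HA tag is an explicit option for reporter work).

### Cassette accounting

`cassette_size()` computes `3*(aa + 1)` nt of coding sequence (one stop
per cassette) plus element lengths. The regulatory element sizes are
user-configurable inputs with documented typical defaults (CK8-style
muscle promoter 436 nt, SV40 late polyA 135 nt, two ITRs of 145 nt)
because real cloning designs vary; the capacity default is 4700 nt.
Oversize payloads return `"warn"`, not an error: packaging beyond ~4.7 kb
degrades gracefully rather than failing absolutely, and a designer may
knowingly accept it where no smaller split exists.

## Confidence metrics

An AF3 confidence bundle holds per-residue pLDDT (atom values averaged
per residue, since the scores of interest are regional), the token-pair
PAE matrix, the optional contact-probability matrix and the optional
global pTM. The PAE matrix is stored exactly as downloaded — rows are the
aligned (conditioning) residue — and is never silently transposed.

For two disjoint regions A and B, `interface_metrics()` pools **both**
off-diagonal blocks, `PAE[a, b]` and `PAE[b, a]`, for `2·|A|·|B|` ordered
pairs. PAE is asymmetric and nothing in the quantity "pairwise
inter-domain PAE" privileges one direction, so the pooled definition was
chosen: it is symmetric in (A, B) by construction, and the package
exposes no option to use a single block (one less knob to misreport).
The qualifying test is strict `PAE < threshold`, threshold default 10 Å.
The conditional contact mean is computed over the same qualifying pooled
pairs; when no pair qualifies (or the bundle has no contact matrix) the
field is `NA` rather than 0 — a zero would fabricate a confidence
statement where there is none.

pLDDT bands follow the conventional coloring: `[0,50)`, `[50,60)`,
`[60,80)`, `[80,90]`, `(90,100]`; exactly 90 falls in the high (not very
high) band. pTM values are tabulated and differenced only — no
significance test is attached, because with a handful of predictions per
comparison any p-value would be decoration.

## Superposition

`kabsch()` is the closed-form least-squares fit: SVD of the cross
covariance with sign correction so the rotation is always proper
(det = +1); mirrored inputs therefore superpose with a large residual
instead of an unphysical reflection. Collinear point sets are rejected
(the rotation about the line is undetermined). The residual identity —
applying the returned transform reproduces the reported RMSD to 1e-9 —
is asserted in the tests.

`refine_superpose()` adds PyMOL-`align`-style outlier rejection: after
each fit, pairs whose residual exceeds `reject_sigma` times the current
RMS residual are dropped and the remainder refit, up to `max_cycles`
(defaults 2.0 and 5, chosen to emulate PyMOL's defaults; `max_cycles = 0`
is plain Kabsch). The cutoff is a multiple of the RMS residual about
zero, not of the standard deviation of residual norms about their mean:
residual norms of a well-fit structure follow a Maxwell-like
distribution whose mean exceeds its spread, so a mean-centred rule would
discard the bulk of perfectly good pairs. With exact input (RMSD 0) the
cutoff is 0 and nothing is dropped.

Residue pairing (`pair_by_sequence()`) matches chains in order of
appearance, residues by number, and drops name mismatches with a message;
at least 3 pairs are required. CA-only superposition is deliberate — the
comparisons of interest are backbone conformations of the same sequence
predicted in two contexts.

## Design evaluation and ranking

`evaluate_design()` aggregates: mean pLDDT over the two intein-half
regions, mean intein-to-intein PAE, optional RMSD of the complex-context
intein against an isolated-intein prediction, and the extein-extein
interface metrics over the two extein windows (default window 200
residues each side of the junction). `rank_designs()` sorts by extein
`%PAE<threshold` descending, then conditional contact mean, then name — a
stable, input-order-independent order.

The favorable/unfavorable call applies a cutoff (default 10%) to the
extein `%PAE<threshold`. This is a documented heuristic separating
strongly and weakly interacting extein pairs from non-interacting ones,
not a validated classifier — it is config-exposed and reported alongside
the raw numbers. Intein-region confidence is deliberately **not** part of
the call: the intein halves associate avidly in essentially every design
(pLDDT near 90, low mutual PAE), so it carries no discriminating
information between designs, only a sanity check that the intein itself
folded.

## What the synthetic generator does and does not emulate

`generate_bundle()` plants an exact number
`round(f · 2·n_A·n_B)` of qualifying cross pairs, drawing qualifying PAE
uniformly from 3–8 Å and non-qualifying from 15–31 Å (strictly either
side of the 10 Å threshold), contact probabilities high (0.5–0.95) on
qualifying pairs and low (0–0.05) elsewhere, symmetric with one draw per
unordered pair, and pLDDT as clipped Gaussians (defaults mean 85, sd 8).
Within-chain PAE is uniformly low. Values stay inside the AF3 ranges
(PAE ≤ 31.75 Å, pLDDT ≤ 100, probabilities in [0, 1]).

This emulates exactly what the interface statistics consume — threshold
side membership and magnitudes — and nothing more. Real AF3 error
surfaces are spatially correlated (domain-shaped blocks, distance decay);
the generator's are i.i.d. Passing the planted-recovery tests therefore
demonstrates the metrics, ranking and I/O are computed correctly, not
that AF3 confidence predicts splicing efficiency — that association is an
empirical claim about real predictions, outside what synthetic data can
establish.

`generate_structure_pair()` builds an ideal poly-CA α-helix (rise 1.5 Å,
100°/residue, radius 2.3 Å) or a 3.8 Å-step random coil, applies a known
random proper rotation and translation, optional isotropic Gaussian noise
and planted outliers of fixed magnitude in random directions. Under noise
σ per coordinate the expected post-fit RMSD is σ√3, which is what the
calibration tests check (within 10% at n = 500). Every generator takes an
explicit seed and touches no global state beyond `set.seed()` at entry.

The synthetic dystrophin-like example (`synthetic_dystrophin_example()`)
uses a random reference sequence with a dystrophin-shaped domain table
(96-aa hinge 1, 109-aa repeats). It is labelled synthetic everywhere: its
purpose is end-to-end exercise of assembly, split placement in named
domains (R11, R17, hinge 3), mass and cassette accounting at realistic
sizes — not reproduction of any real protein's numbers.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in about a minute: interface oracles on 100
random bundles of up to 60 tokens, 1,000 random sequences for split-site
enumeration, 100-seed calibrations at n = 500 for superposition noise and
n = 100 with 5 planted 10 Å outliers for rejection, and 100 ranking
replicates on 60-token bundles. Exact-equality checks (planted fraction
recovery, mass additivity) use tolerances of 1e-6 kDa or tighter;
geometric identities use 1e-9.

Known limitations: no ligand/glycan tokens (explicit error), no
insertion codes, CA-only superposition, no sequence-alignment-based
pairing of divergent sequences, and no attempt to model AF3's true error
distribution. Confidence metrics from regenerated AF3 outputs will drift
with server model versions; comparisons against previously reported
values should expect ordering and magnitude agreement rather than exact
reproduction.
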