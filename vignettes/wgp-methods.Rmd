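---
title: "Whole-genome parameters: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome parameters: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgp)
```

## The model

The package treats a closed bacterial genome as a one-dimensional signal.
Each residue is mapped to the phase of a complex number assigned by
projecting the nucleotide tetrahedron onto the complex plane: A = π/4,
C = −3π/4, G = 3π/4, T = −π/4, with the two-fold ambiguity codes on the
axes (R = π/2, Y = −π/2, S = π, W = 0) and all unresolved codes at 0. Two
conventions are ours: W is taken as 0 rather than 2π so every phase lies in
(−π, π] and the running sum acquires no spurious 2π jumps, and the codes
B/D/H/V — not covered by the tetrahedron projection — are treated like N.
The map is invertible on unambiguous symbols, so no information is lost.

The *cumulated phase* is the running sum of the phase signal. Its
per-position increment has expectation π/4·(3(g−c) + (a−t)) in the local
base probabilities, so the curve is an integrated strand-skew profile: on a
typical chromosome it rises from the replication origin to a maximum near
the terminus and falls back. This "arrow" gives every genome an intrinsic
coordinate system, which the rearrangement step exploits.

Four descriptors summarise the genome:

* `diff_p`, the summed absolute differences of adjacent phases divided by
  the signal length L. The divisor is L even though there are L−1 adjacent
  pairs; that convention is what makes the reference values for the 6-mers
  AAAGGG (π/2/6 ≈ 0.26) and AGAGAG (5π/2/6 ≈ 1.31) come out as they do,
  and the package reproduces it exactly.
* `tr_0` and `tr_cg`, the fractions (out of L−1) of adjacent pairs that
  cross zero or that both lie on the C/G phases. On A/C/G/T sequences these
  are exactly the dinucleotide fractions {AC, AT, CA, CG, GC, GT, TA, TG}
  and {CC, CG, GC, GG}, which the test suite checks against literal
  dinucleotide counting. Pairs involving a zero phase (W, N, …) count as no
  transition: that preserves the dinucleotide equivalence on A/C/G/T input
  and extends conservatively elsewhere.
* `a_cp`, the average growth angle of the anchored cumulated phase:
  the mean of atan(c_i/i) at N sampled positions i = round(k·i_max/N),
  k = 1…N, where i_max is the position of the signal's maximum. The
  formula mixes radians and base-pair counts; we implement it literally,
  with no rescaling, because the descriptor is defined by the formula. The
  sampling index is rounded (and clamped to [1, i_max]) so the last sample
  lands exactly on the maximum; N defaults to 10, a compromise between
  smoothing the locally uneven rise and computing cost. Signals whose
  maximum sits before position N are rejected with advice to lower N —
  only degenerate, sub-100-bp inputs ever trigger this.

## Origin anchoring

A deposited record starts wherever sequencing happened to close the
circle, so descriptors computed from the raw record would inherit that
arbitrariness (and the first value of the cumulated phase may sit in a
false minimum). The rearrangement makes the start canonical in three
steps: compute the cumulated phase; rotate to begin at its global maximum;
locate the global minimum of the rotated signal, rotate again to begin
there, and subtract the minimum so the signal starts at 0.

One numerical subtlety deserves record. When a rotation moves the front
part of the signal behind the back, the moved values must be offset by the
walk's *full-circle increment* — for a from-zero running sum this is
precisely "the last signal value", and carrying it keeps every rotation an
exact contiguous window of the circularly extended walk. Two tempting
alternatives fail: re-deriving the running sum from the rotated sequence
re-zeroes the walk at the new start and shifts the moved segment by the
genome's net phase sum, which can relocate the minimum away from position
1; and carrying the literal last value of the *already-offset* intermediate
signal elevates the moved tail by a constant that depends on the original
record start, which perturbs the signal maximum and hence `a_cp` between
rotations of the same genome. With the full-circle carry, the anchor is a
property of the circular genome: the test suite checks that two random
rotations of the same genome anchor to the identical sequence and yield
identical `a_cp` to machine precision.

Extremum ties are broken by first occurrence, which is deterministic and,
because tied candidates form a contiguous arc away from the window
boundary, rotation-stable. If a genome's walk closes at a negative value
(net phase sum < 0), the far tail of the anchored window can dip slightly
below the start; the first value is still 0. Near-flat signals (no arrow)
are anchored anyway — the procedure does not detect them, and descriptors
of such genomes should be interpreted with care. Linear contigs are
rotated as if circular, with a warning.

## Delineation and validation

For a dataset of parameter tables, each parameter's pairwise absolute
differences are normalised by the parameter's range (max − min) over the
dataset — which equals the largest pairwise difference, so the two
plausible readings of "range" coincide. A parameter with zero range
contributes distance 0 rather than 0/0: identical values carry no
discriminative signal. The average distance over a subset (presets
s̄₂ = {tr_cg, diff_p}, s̄₃ = + tr_0, s̄₄ = all four) becomes a percentage
similarity s = 100·(1 − d̄), and a pair is called conspecific when s
exceeds the threshold (default 96). The comparison is strict (`>`): the
boundary case is called *different*, the conservative choice against false
positives, and `strict = FALSE` is exposed for the other convention.
Normalisation makes similarities explicitly dataset-dependent — adding a
genome can change existing similarities — which is why the persistent
artifact is the parameter table, not a similarity matrix.

Validation against species labels counts, over all unordered pairs, true
and false positives and negatives; sensitivity and specificity are left
`NA` (never silently 0 or 100) when a dataset has no intra- or no
inter-species pairs. The threshold sweep runs 90–98% in steps of 0.5
(17 points, built by integer stepping to avoid floating accumulation), and
by construction sensitivity is non-increasing and specificity
non-decreasing in the threshold.

## What the simulator emulates — and what it does not

The descriptors are composition statistics, dinucleotide fractions and a
skew-curve angle, so the simulator controls exactly those levers and
nothing more:

* per-species base composition (G+C spread over 0.32–0.62 by default, the
  realistic bacterial range);
* replichore strand skew: the leading half is enriched in G over C
  (`gc_skew`, default 0.02–0.08 across species) and in T over A
  (`at_skew`), with both biases mirrored in the lagging half. The lagging
  replichore is generated as a shuffled complement of the leading one, so
  strand parity holds exactly and the cumulated phase closes at 0 — as in
  real closed chromosomes, where this closure is what makes the origin
  anchor well-defined. An early version drew the two halves independently;
  the resulting √L-scale net drift broke the arrow shape for weakly skewed
  profiles and made anchoring unstable, which is a property of unrealistic
  input, not of the method;
* strain-level divergence: uniform substitutions at a configurable rate
  (default 1%), optionally followed by a random rotation of the record to
  exercise the anchoring; no indels, recombination or horizontal transfer;
* optionally, first-order Markov generation to move dinucleotide fractions
  independently of marginal composition.

The default study conditions — 7 species × 5 strains of 200 kb at 1%
substitution — are a scaled-down stand-in for a labelled multi-species
validation set; at that scale the full simulate → parameters → similarity
→ ROC pipeline runs in about a second, and the suite also computes
parameters for 30 genomes of 2 Mb to confirm the intended scale is
unproblematic. Passing tests on this fixture show that the pipeline
separates composition- and skew-distinct species robustly and that the
machinery (anchoring, normalisation, sweep) is correct. They do *not* show
that real species are delineated at any particular sensitivity: real
genomes differ by rearrangements, repeats, mobile elements and much subtler
composition contrasts than the simulated profiles, and closely related taxa
with near-identical composition (the classic enterobacterial problem
cases) can legitimately exceed an inter-species similarity of 96%. The
fixture with two species sharing their G+C content — where `tr_cg` alone
produces false positives but the four-parameter average restores
specificity — probes exactly this failure mode at small scale.

## Practical notes

* Genomes must be single closed records; multi-record FASTA is rejected
  unless concatenation is forced, because descriptor values depend on
  scaffold order and the method is not meant for draft assemblies.
* Parameter tables serialise numerics at 17 significant digits and carry a
  provenance line (package version, `n_acp`, rearrangement flag); merging
  tables with different `n_acp` warns, since `a_cp` values are then not
  comparable.
* All generators accept a seed and restore the caller's RNG state; the
  whole fixture → ROC pipeline is bit-reproducible for a fixed seed.
* `compute_parameters(..., rearrange = FALSE)` exposes the un-anchored
  variant for ablation studies only.
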