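---
title: "Programming M13 phage ssDNA and quantifying antigen display"
author: "phageDesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Programming M13 phage ssDNA and quantifying antigen display}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phageDesign)
```

# The platform

M13 is a filamentous bacteriophage: a ~7 nm-wide protein tube whose
length tracks the size of the single-stranded DNA it packages and whose
surface is a lattice of ~2700 copies of the major coat protein pVIII.
Three properties make it a programmable nanovaccine chassis:

1. **Adjuvanticity** — unmethylated CG dinucleotides in the ssDNA are
   TLR9 agonists, and embedding them in canonical murine hexamer
   contexts (AACGTT, GACGTT) strengthens the stimulation;
2. **Geometry** — filament length is proportional to ssDNA length, so a
   phagemid insert sets the particle size;
3. **Antigen density** — when a helper plasmid supplies both wild-type
   and antigen-fused pVIII, the assembled capsid is a mosaic whose
   antigen fraction (the *display ratio*) is set by the expression
   configuration.

This package implements the computational layer: sequence design and
repair, display-ratio estimation from chromatograms, and the supporting
mass and length calculators.

# The ssDNA programming algorithm

## Definitions and design rules

A design is specified by a target length $L$, a *dimer-based* CG
fraction $f$ (the fraction of nucleotides belonging to placed CG
dimers, $f = 2N_{CG}/L$, so $N_{CG} = \mathrm{round}(fL/2)$), an
optional hexamer-conversion fraction, and a seed. The dimer-based
reading reproduces the published design points exactly: a 1415-nt
insert at 27% carries 191 dimers; at 9%, 64 dimers. (The alternative
reading — mononucleotide C+G content — cannot be reconciled with those
integer censuses and is not used.)

Three constraint families define a *clean* design:

* **Boundary rules.** The flank between dimers is drawn from
  {A,C,G,T}, may not start with C after a dimer, may not end with G
  before a dimer, and contains no internal CG — so the realized dimer
  census is exactly the placed count. (The stated boundary rule alone
  does not prevent stray CG dimers inside flanks; the no-internal-CG
  rule closes that gap.)
* **Direct repeats.** No 9-mer may occur twice. Scanning at exactly
  $k = 9$ is complete: any repeated stretch of length ≥ 9 contains a
  repeated 9-mer.
* **Hairpins.** No 13-nt window may equal the reverse complement of
  another ("longer than 12 bases", exact complementarity, no minimum
  loop separation — a conservative superset of foldable hairpins;
  thermodynamic folding is out of scope).

Repairs are restricted to A↔T transversions at unprotected positions,
which conserves the C count, G count and dimer census structurally.
Placed dimers and installed hexamers are protected by a position mask.

## Scaffold construction

Dimers are spread evenly with seeded jitter: the $N_{CG}+1$ gap lengths
are drawn within ±25% of the mean gap and rescaled to the exact total
(largest-remainder apportionment), which hits the census exactly while
avoiding the periodicity that uniform spacing would imprint.

Flanks are generated by **rejection sampling against the growing
sequence**: candidate chunks (≤ 24 nt) that would duplicate any 9-mer
already present are redrawn, up to 40 tries. This choice is load-bearing
at scale. At the densest published design point (6261 nt at 26%, 814
dimers ~5.7 nt apart) thousands of 9-windows span two CG dimers; their
C/G positions are frozen under A/T-only repair, and we found (and
verified by long random-walk traces) that no sequence of legal repair
moves can make them pairwise distinct once generated carelessly —
neither with uniform flanks (frozen skeletons collide) nor with
A/T-rich flanks (the per-window alphabet collapses to $2^{gap}$ values).
Avoiding repeats at construction sidesteps the problem: repair passes
then handle only the few residual and insertion-induced cases (typically
< 10 mutations per design; every design point from 721 to 6261 nt
finishes clean in well under a second).

## Repair

Each sweep rescans the sequence and fixes every open repeat family and
hairpin pair once: a *seeded-random* unprotected A/T in the first
(leftmost) instance is flipped, falling back to later instances when
the first is fully protected. Two details differ deliberately from the
obvious implementation:

* *Randomized pick within the window.* A strictly leftmost pick cycles:
  flipping a base can spawn a new repeat family whose deterministic fix
  flips the same base back (we observed 2000+ mutations without
  progress on a 1415-nt scaffold). The randomized pick is a random walk
  that escapes such 2-cycles; it remains fully reproducible because all
  randomness flows from the design seed.
* *One mutation per family per sweep.* Attacking only the lowest-offset
  family can hammer a near-frozen window indefinitely while the rest of
  the sequence waits, and rescanning after every single mutation makes
  the pass quadratic. Sweeping spreads progress and keeps the rescan
  count proportional to the number of sweeps.

A family with no unprotected A/T in any instance can never be fixed by
a legal move and raises an `unresolvable` condition immediately; a
stall (30 sweeps without reducing the open-hit minimum) does the same.
The pipeline then restarts from a fresh scaffold (seed advanced by one,
up to 5 restarts) before surfacing the error. The mutation cap is 10×
the sequence length per pass.

## Hexamer conversion

`round(fraction · N_CG)` dimers, chosen uniformly at random (seeded),
are each replaced by a 6-nt hexamer — net +4 nt per site, so the CpG40
recipe (1415 nt, 191 dimers, 40% conversion) yields 1719 nt with 76
cassettes. The insertion mode reflects the observation that converted
phages are longer than their parents (≈ 220 vs ≈ 200 nm); an in-place
mode (rewrite the 6-nt window centered on the dimer, length preserved)
is available as a switch. Motifs alternate AACGTT/GACGTT from a
seed-determined start to limit repeat creation, with one override: a
motif may not form a CG across its junction (a C-ending flank followed
by G-initial GACGTT would add a dimer), so such sites receive a
junction-safe motif or are swapped for another dimer.

Two subtleties surfaced during implementation and are resolved as
follows:

* **Motif-induced repeats are features, not defects.** Installing the
  same 6-mer at ~38 sites necessarily repeats it, and every 9-window
  containing a cassette has only 3 free flanking bases — with all six
  cassette positions protected, exact 9-mer uniqueness is
  combinatorially unreachable (~230 repeat instances persist no matter
  how many legal mutations are applied). Repeat families whose *every*
  instance overlaps an installed cassette are therefore classified
  motif-induced, skipped by repair, excluded from the clean flag, and
  reported separately (`motifRepeats` in the `ConstraintReport`).
  Families with at least one cassette-free instance are still
  eliminated, and the insertion stage audits its site choice, swapping
  out any site that would leave such a family with no mutable base.
  Hairpins are never exempted: complementarity between cassette flanks
  is coincidental, hence repairable.
* **The hexamer census is a controlled variable.** A dimer whose flanks
  happen to spell AACGTT/GACGTT (about one per design by chance) would
  shift the measured motif content, so chance contexts are scrubbed by
  the same CG-conserving A/T flips at every conversion fraction. The
  validator census therefore equals exactly the installed cassette
  count: 76/191 = 39.79% for CpG40, 0 for the CG series.

## What the validator reports

`validateDesign()` recomputes everything by scanning: length, dimer
census, realized fraction (raw and nearest-integer percent), hexamer
embedding, repeat families (split into genuine and motif-induced),
hairpin pairs, and boundary violations. `clean` requires empty genuine
repeats, hairpins and boundary violations. All report coordinates are
0-based half-open.

# Double-Gaussian HPLC deconvolution

## Model

The capsid chromatogram window holds two overlapping peaks: wild-type
pVIII (main, apex near 51.3 min) and antigen pVIII (trailing shoulder,
default +0.6 min). Each peak is an asymmetric sum of two Gaussians;
with a linear baseline the full model has 14 parameters. Peak areas are
closed-form, and the display ratio is the antigen share of the total
area. Raw areas are compared without an extinction-coefficient
correction between the two species (a correction hook would multiply
one area); the two peaks are ordered by area-weighted effective center,
antigen trailing.

Within a peak the two components are interchangeable (swap symmetry),
so nothing is asserted about individual components — only per-peak
areas and the ratio; the narrower component is listed first as a pure
tie-break.

## Fitting protocol

Initialization is deterministic: the dominant maximum of the lightly
smoothed, edge-baseline-subtracted trace anchors one peak; secondary
structure is sought as a local maximum on *either* side (at high
display ratios the antigen is the dominant peak and the wild type sits
to its left), then as a trough of the smoothed second derivative, then
falls back to a small peak one shoulder offset to the right. Widths
come from the nearer half-maximum crossing (a twin peak can hold the
trace above half maximum across the whole valley, so the nearer side is
the honest one).

The fit is staged. Stage one fits two *single* Gaussians plus baseline
from three center layouts (detected pair; antigen-dominant; wild-type-
dominant). Stage two fits the full 14-parameter model from three
partitions of the stage-one result: each Gaussian split 0.75/0.25 into
one peak slot; both Gaussians in the wild-type slot with a near-zero
shoulder; both in the antigen slot with a near-zero leading peak. The
latter two matter because a peak's own tail component is exactly
degenerate with a small adjacent peak on a clean trace: among
residual-equivalent solutions the smaller antigen share is preferred
(ambiguous mass belongs to the main peak). Optimization is bounded
Levenberg–Marquardt (`minpack.lm`), amplitudes ≥ 0, widths > 0, centers
inside the window, cost tolerance 10⁻¹²; a fit whose residual stays
above the noise floor (MAD of second differences) is retried from
deterministically jittered starts. Non-convergence is reported in the
`converged` flag, never silently.

On noiseless synthetic traces this recovers every generative ratio in
{0, 0.05, …, 0.9} to < 10⁻⁶, at shoulder offsets 0.6 and 1.2 min. At
0.3 min separation the two peaks are no longer identifiable as distinct
shapes and recovery degrades to roughly ±13 percentage points — the
documented failure mode of the overlap stress grid.

## Noise and the scaled-copy estimator

With 1% additive noise the free 14-parameter partition is not
identifiable: the wild-type tail and the antigen shoulder trade area
along a nearly flat residual valley (per-fit scatter ~10 percentage
points, biased toward ½). For noisy traces the package provides
`shape = "scaled"`: the antigen peak is constrained to a scaled,
shifted copy of the wild-type peak (10 parameters). Both species are
near-identical proteins eluting on the same column, so sharing the peak
shape is physically justified — and it is exactly how the simulator
builds its traces. The scaled estimator recovers noisy ratios to within
~1 percentage point in the mean over 20 seeds; the free fit remains
the default (and is exact on clean traces).

## The simulator

`simulateChromatogram()` generates each peak from a shared shape
(leading σ = 0.18 min, trailing σ = 0.45 min at +0.25 min carrying 35%
of the area — a moderately tailing peak), places the wild-type apex at
51.3 min and the shoulder at +0.6 min, samples at 0.01 min over a
[−3, +4] min window, and scales amplitudes so the antigen share of the
closed-form total area equals the requested fraction exactly. Optional
linear drift and seeded Gaussian noise complete the trace. It emulates
peak overlap, asymmetry, baseline and noise; it does not emulate
retention-time drift between runs, non-Gaussian fronting, detector
saturation or co-eluting contaminants — recovery on these fixtures
demonstrates estimator correctness under the stated model, not
instrument-grade robustness.

# Mass and length calculators

Protein masses are residue-table sums (standard IUPAC average and
monoisotopic tables) plus one water; the MALDI prediction is the singly
protonated ion of the *average* mass, [M+H]⁺ = M + 1.00728 Da, as
appropriate for linear positive mode where isotopes are unresolved.
This reconciles the canonical 50-residue mature wild-type pVIII
(average ≈ 5238.0 Da) with the observed 5239 Da peak. Recombinant
fusion sequences are user-supplied.

Filament length is calibrated by least squares through the origin on
the four published (nt, nm) pairs {(721, 100), (1447, 200), (3241, 400),
(6261, 800)}, giving 0.1274 nm/nt. The calibration residuals (up to
~16 nm) correspond to a ±20% accuracy band; predictions outside
721–6261 nt are extrapolations.

```{r example}
d <- designSsDNA(DesignSpec(1415, 0.27, hexamerFraction = 0.4, seed = 1))
d$report
phageLengthFromSsdna(nchar(d$sequence))
```

# Numerical choices and limitations

* Problem sizes: designs are validated at 721–6261 nt; the acceptance
  analyses use the published design points (1415 nt CG series, 1719 nt
  CpG40, 6261 nt length series) and 701-sample chromatogram windows.
* All randomness (gap jitter, flank sampling, mutation picks, hexamer
  sites, simulated noise) flows from one seeded generator per run;
  identical spec + seed gives byte-identical sequences.
* Degenerate inputs: empty sequences, non-ACGT characters, non-monotone
  chromatogram time axes and flat traces raise typed conditions
  (`phageDesign_io`, `phageDesign_nopeak`, `phageDesign_infeasible`,
  `phageDesign_unresolvable`), which the CLI maps to distinct exit
  codes (5, 4, 2, 3; usage errors 64).
* The repeat/hairpin definitions are exact string matches; biophysical
  secondary-structure prediction, codon-level design, vector assembly
  and synthesis-vendor screens are out of scope.
* The display-ratio estimator assumes two analytes in the window;
  multi-antigen mosaics would need a wider mixture model.
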