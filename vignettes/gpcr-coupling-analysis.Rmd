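---
title: "Analysing GPCR-transducer trajectories with gpcrtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing GPCR-transducer trajectories with gpcrtraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrtraj)
```

## The problem

When a G protein-coupled receptor engages an intracellular partner — a G
protein or an arrestin — the receptor's conformation, the buried
receptor–partner surface, and the specific residue contacts all depend on
which partner is bound. Comparative molecular dynamics of several
receptor–partner complexes is the standard way to probe this, and the
analysis layer is remarkably uniform across studies: decide which part of
each trajectory is equilibrated, compute a small battery of
activation-state geometries, compare torsion ensembles between systems,
track the buried-surface interface per residue, and classify contacts
with occupancy statistics. `gpcrtraj` implements that layer as a tested,
reusable package, together with a synthetic-trajectory generator that
gives every stage a known right answer.

Structures come in as PDB or GRO files, trajectories as multi-model PDB
or DCD, and residue annotations — generic numbers
(Ballesteros–Weinstein `3.50`-style for receptors, CGN-style `H5.23` for
Gα, strand-loop names for arrestin) and substructure labels — as a TSV
the user supplies, since helix boundaries are a per-receptor judgement
call the package deliberately does not guess. Coordinates are stored in
nm throughout; Å inputs (PDB, DCD) are converted on load so no factor of
ten can leak between stages.

## Equilibration

Six diagnostics are computed per frame: receptor helicity, the
receptor–membrane centre-of-mass z offset, the box *xy* area, Cα RMSD of
receptor and of partner against the initial frame (Kabsch superposition
first), and per-residue RMSF. Helicity is defined by a dihedral window —
φ ∈ [−100°, −30°], ψ ∈ [−67°, −7°] — rather than hydrogen-bond pattern
assignment; for a stationarity diagnostic the window definition is
equally sensitive and has no external dependencies, and the bounds are
arguments.

The decision rule is the part such studies usually leave implicit, so
here it is explicit and configurable: the discard time is the earliest
time from which, for every metric, the mean of each subsequent window of
width `window` (default 50 ns) stays within `k` (default 2) noise
standard deviations of the final-half mean. The noise scale is estimated
from first differences of the final half (`sd(diff(x))/sqrt(2)`), so a
final half that still drifts slowly does not widen its own acceptance
band; a never-converging ramp therefore correctly reports "no onset"
(discard = full length, flagged) instead of passing. Because the
reference mean is re-estimated from a finite noisy tail, the onset is a
windowed estimate: appending more stationary data can shift it by a grid
step (about a tenth of a window in our property tests), which is the
precision one should attach to it. A fixed cut (`discard = 200`)
reproduces the fixed-window workflow common in the literature, and the
cut is applied per replica by default since replicas relax
independently.

## Activation metrics

The eight standard read-outs are implemented over annotated selectors so
the same call works on any class-A receptor: TM3–TM6 and TM3–TM7 Cα
distances, TM3–TM7 side-chain packing, NPxxY backbone RMSD against a
user-supplied inactive reference (superpose on receptor TM Cα, then RMSD
over N/CA/C/O of 7.49–7.53 without re-fitting — the reference structure
is required input because no single choice is canonical), the two
transmission-switch distances, the Na⁺-pocket and hydrophobic-lock
triangle areas, the closest Na⁺ ion, and the hydration count within 8 Å.

Two conventions deserve a note. Triangle "areas" are defined by the three
pairwise side-chain centre-of-mass distances and evaluated with Heron's
formula (the degenerate, triangle-inequality-violating case returns 0);
the tests cross-check every evaluated frame against the independent
½|AB×AC| formula. The water count takes the most inclusive reading of
"within 8 Å of a residue": distance to *any* heavy atom of the residue,
configurable to Cα or side-chain COM. Glycine side-chain COMs fall back
to Cα. All distances apply the minimum-image convention when box vectors
are present.

Summaries everywhere follow one convention: the mean of per-replica
means, ± the standard error of that mean (sample SD over replica means,
n−1 denominator, divided by √n). With a single replica the SEM is
reported as NA rather than 0.

## Ensemble comparison by Jensen–Shannon distance

Backbone (φ, ψ) and side-chain (χ₁–χ₅, standard atom quadruples bundled
per residue type) torsions are extracted per residue and frame, pooling
all replicas of a system after the equilibration cut. Each shared
feature is histogrammed on 36 equal circular bins over [−180°, 180°) and
two systems are compared with

$$\mathrm{JSD}(p,q) = \sqrt{\tfrac12 D_{KL}(p\|m) + \tfrac12 D_{KL}(q\|m)},
\qquad m = \tfrac{p+q}{2},$$

with base-2 logarithms, so the distance lives in [0, 1]. Zero-count bins
use the 0·log 0 ≡ 0 convention with no pseudocounts — every KL term is
well defined because m ≥ p/2 wherever p > 0. The density estimator is a
design choice (histogram vs kernel) that such analyses rarely document;
36 bins (10°) is the default and an argument, and since coarser nested
binnings can only merge probability mass, halving the bin count can only
lower a JSD — a property the tests assert. Per residue we report the
maximum over its backbone angles and over its side-chain angles
separately, and `select_high_jsd()` applies the conventional 0.6 display
threshold. At 2000 frames and 36 bins, two independent draws from the
same torsion distribution stay below JSD 0.15 for every feature
(finite-sample null), while a 120° rotamer shift at tight concentration
saturates to 1 — the contrast the method is meant to detect.

## Interface protocol

The solvent-accessible surface area is computed with Shrake–Rupley point
sampling: per atom, the fraction of points on the probe-expanded sphere
(radius r + 0.14 nm) not inside any other included atom's expanded
sphere, times the expanded-sphere area. The point set is a deterministic
golden-spiral lattice (960 points/atom by default), so results are
reproducible and converge at about the 1 % level — doubling the point
count moves per-residue values by under 1 % on our fixtures, and an
isolated atom reproduces 4π(r+probe)² to machine precision of the
fraction. Probe radius, point count and the Bondi-style element radii
are all parameters. The C++ kernel is cross-checked in the test suite
against a 10⁴-point brute-force R implementation; per-residue buried
areas on a 50-residue dimer agree within 2 %.

Per frame, each residue's ΔSASA is its SASA with only its own chain
group present minus its SASA with both groups present; water, ions and
membrane are excluded from both, since the contrast of interest is
monomer vs complex. The interface area is the mean of the two sides'
summed ΔSASA. Membership follows the literal rule set: original
interface residues have ΔSASA > 0 at the first retained frame, minus
those excluded by the *conjunction* of ΔSASA < 0.05 nm² and normalised
ΔSASA < 10 % (normalisation by the bundled Gly-X-Gly theoretical maximal
accessibility of the residue type; the table is replaceable). We read
the exclusion as a conjunction because that is what the protocol text
states; a disjunction mode exists behind a flag for sensitivity
analysis. Presence is the percentage of retained frames with ΔSASA above
a noise floor ε (default 0, matching "higher than 0"); residues outside
the original set with presence above 50 % are additional members. Which
frame defines "the beginning" is ambiguous in fixed-cut workflows; we
use the first *retained* frame, configurable.

## Contacts

Interactions are classified geometrically from a bundled residue
chemistry table (charged groups, donors, acceptors, aromatic rings,
apolar carbons). The thresholds mirror widely used interaction-
fingerprint conventions — ionic N/O pairs ≤ 0.40 nm; hydrogen bonds at
donor–acceptor heavy distance ≤ 0.35 nm with a ≥ 110° donor–H–acceptor
angle when hydrogens exist and a heavy-atom fallback when they do not
(toy fixtures and many deposited structures lack hydrogens); salt
bridges as ionic pairs that also meet hydrogen-bond geometry; π-cation
at ≤ 0.60 nm and ≤ 60° off-axis; π-stacking at ≤ 0.70 nm with ring
normals within 30°; T-stacking with normals at 60–90°; hydrophobic
apolar-carbon pairs ≤ 0.45 nm; van der Waals at r₁+r₂+0.05 nm. Exact
thresholds vary between published fingerprint tools, so every one of
them lives in `contact_criteria()` and is echoed into output metadata.
Van der Waals is the residual class: it is suppressed for a residue pair
whenever a more specific category fires, which keeps it meaningful as
the "weakest interaction" label. Production detection is asserted
identical to an independent nested-loop oracle on every fixture.

Occupancy — the fraction of retained frames a (pair, category) is
present — is computed per replica and averaged unweighted across
replicas; pairs averaging under 30 % are excluded, with the boundary
value kept ("less than" excluded). The substructure-pair contact matrix
uses a separate 50 % display threshold applied to the averaged
occupancy.

## The synthetic generator: what it emulates, and what it does not

Deposited trajectories are rarely available, so the package's test bed
is a generator whose defaults encode the statistical structure the
analyses assume: inter-residue distances as independent Gaussian series
(realised exactly, by rigid displacement of the second residue along the
pair axis); torsions as von Mises mixtures (Best–Fisher sampling,
applied exactly by rotating the dependent atoms); burial as a scripted
blocker group covering a residue in exactly `round(f·n)` seeded frames
(the first retained frame stays exposed so scheduled residues exercise
the *additional*-member rule); contacts placed strictly inside or
outside their geometric criterion in the scheduled frames; solvent as
rigid three-site waters on shells; initial relaxation as an exponential
drift segment with configurable time constant; and optional isotropic
per-atom Gaussian jitter as the stationary noise floor. Everything is a
deterministic function of the spec including its seed, and the realised
draws, masks and schedules are recorded as ground truth so tests compare
detector output to what was actually generated.

What the toys do *not* have: a force field, a membrane with lipids,
correlated collective motions, realistic side-chain rotamer coupling, or
water dynamics. Passing tests therefore demonstrate that the
*computations* are correct and the *decision rules* behave as specified
on data with known structure — not that any biological conclusion about
a real receptor would follow. On real trajectories the statistical
caveats (autocorrelation inflating effective sample size, SASA point
noise near the membership thresholds) are the user's to weigh; the
per-frame tables the package returns are designed to make that easy.

## Numerical choices and degenerate inputs

Internally: nm everywhere; minimum image for all distances; Kabsch
superposition via SVD with a determinant guard against reflections, and
an explicit conditioning error for collinear fit selections; Heron areas
clamped at 0 for degenerate triangles; torsion histograms on the
half-open interval so ±180° land in one bin; JSD clamped to [0, 1]
against rounding. The bundled two-system study (`demo_two_system_config()`)
uses 60 stationary frames per replica, two replicas per system and
240 SASA points in its pipeline configuration — sizes chosen so a full
end-to-end run with all stages completes in well under a minute on a
laptop while every recovery check still has comfortable margin; the
focused recovery analyses in `scripts/acceptance.R` use 400–2000 frames
per quantity for tighter sampling error.

## A complete run

```{r, eval = FALSE}
dir <- tempfile("study")
cfg <- demo_two_system_config(dir, seed = 1)
bundle <- run_pipeline(cfg)

bundle$summary$interface_area          # mean ± SEM per system
glance(bundle$systems$Gq$metrics$tm3_tm6_ca)
select_high_jsd(bundle$comparisons[["Gq vs Gi"]])
autoplot(bundle$systems$Gq$interface)  # area traces per replica
```

For file-based runs, `run_config()` accepts a YAML with `systems`
(label, structure, trajectories, annotation, chain roles), `comparisons`,
the discard rule, and every threshold of the protocol — presence 50 %,
occupancy 30 %, matrix display 50 %, JSD display 0.6, ΔSASA exclusion
0.05 nm² and 10 %, water shell 8 Å — defaulted to the conventional
values and recorded in the run manifest, never hard-coded.

## Known limitations

XTC trajectories are not supported (no R reader exists); convert to DCD
or multi-model PDB. GRO files carry no chain identifiers, so multi-chain
GRO input needs explicit chain roles. The hydrogen-bond angle criterion
engages only when hydrogens are present. The equilibration onset is a
windowed estimate with the grid precision discussed above. SASA point
sampling makes ΔSASA near 0 noisy at low point counts; the membership
noise filter exists precisely for that regime, and ε > 0 is available
for presence when needed.
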