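---
title: "The coarse-grained SWISH model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The coarse-grained SWISH model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swishmc)
```

## What the package models

The N-terminal 17-19 residues of huntingtin (sequence
`MATLEKLMKAFESLKSFQQ`) are intrinsically disordered in water but have a
latent amphipathic-helix propensity, and phosphorylation of Thr3 or
acetylation of Lys6 measurably shifts their helical content. `swishmc`
implements the two ingredients needed to study this computationally at desk
scale:

1. **SWISH Hamiltonian replica exchange** (Sampling Water Interfaces
   through Scaled Hamiltonians): several replicas of the system run in
   parallel, identical except that the dispersion interaction between
   solvent and the peptide's apolar atoms is multiplied by a per-replica
   coefficient $\lambda$. Rungs with $\lambda > 1$ over-stabilise solvated,
   extended conformations; rungs with $\lambda < 1$ favour hydrophobic
   collapse. Periodic swap attempts between adjacent rungs let
   conformations diffuse across the ladder, and only the unscaled rung
   ($\lambda = 1$) is reported as the physical ensemble.
2. **The trajectory observables** used for disordered helical peptides:
   Kabsch-Sander backbone hydrogen-bond energies and DSSP-style
   alpha/3-10 assignment, geometric hydrogen-bond statistics, salt
   bridges, radius of gyration, Ramachandran histograms, and Aurora-Rose
   helix N-capping motif classification.

Because explicit-solvent all-atom molecular dynamics is far outside a
single-CPU budget, the sampler operates on a coarse-grained peptide model
built for the purpose. The model is a vehicle for exercising the SWISH
machinery and the analysis stack with the correct statistics, not a
quantitative force field; its defaults are calibrated only to qualitative
regimes (see *Calibration* below).

## The coarse-grained model

Each residue carries backbone atoms N, H, CA, C, O with ideal internal
geometry (N-CA 1.458 Å, CA-C 1.525 Å, C-N 1.329 Å, C=O 1.231 Å, N-H
1.0 Å, standard sp² angles, $\omega$ fixed at 180°) plus a single
side-chain bead (written as CB in PDB output) whose distance from CA grows
with side-chain size. The only degrees of freedom are the backbone
dihedrals $(\phi_i, \psi_i)$; conformations are rebuilt deterministically
from internal coordinates with the first residue in a canonical frame.
$\phi_1$ has no geometric effect (there is no preceding carbonyl) but is
retained as a coordinate so every residue carries the torsion prior;
$\psi_L$ orients the terminal carbonyl. Amide hydrogens are placed 1 Å
from N opposing the preceding carbonyl — the same reconstruction used when
external trajectories arrive without hydrogens — and residue 1 has no amide
hydrogen, so it can never act as a backbone donor.

The energy is

$$U(\lambda) = U_0 + \lambda W$$

with four terms, all in kcal/mol:

* **Torsion** (in $U_0$): two 2-D Gaussian wells per residue, a helical
  basin at $(-57, -47)$ (width 25°, depth 3.0) and an extended basin at
  $(-135, 135)$ (width 35°, depth 1.4). Depths were chosen so that the
  unmodified peptide at 300 K is mostly coil with transient helix; the
  wider, shallower extended basin gives the coil state its entropy.
* **Bead Lennard-Jones** (in $U_0$): between CA and side-chain beads of
  residues at least two apart; hydrophobic-class side chains attract more
  strongly ($\varepsilon$ 0.12 vs 0.06; CA 0.05). This provides mild
  compaction pressure and excluded volume. Bead overlaps closer than the
  hard-core distance (1.8 Å between non-adjacent residues) make
  $U_0 = +\infty$; the sampler simply rejects such moves, no exception is
  raised.
* **Screened electrostatics** (in $U_0$): Debye-Hückel interactions
  between formal charges, $332\, q_i q_j e^{-r/\lambda_D} / (\epsilon r)$,
  with $\epsilon = 78.5$ and $\lambda_D = 9.6$ Å, the Debye length of
  100 mM monovalent salt at 300 K. Charges sit on side-chain beads
  (Asp/Glu $-1$, Lys/Arg $+1$, phosphorylated Ser/Thr $-2$ by default) and
  on the termini (free N-terminus $+1$ on the first N, free C-terminus
  $-1$ on the last C). This term carries the mechanism of interest: in
  helical conformations the phosphate bead of pThr3 sits within a Debye
  length of the Lys6 amine and the N-terminus, and acetylation deletes the
  partner charge.
* **Solvent dispersion $W$** (the $\lambda$-coupled term): for every
  apolar bead — CA and C of all residues, side-chain beads of
  hydrophobic-class residues, the coarse-grained mirror of "all carbon and
  sulfur atoms" — count heavy atoms of residues at least two away within
  6.5 Å; the bead's exposure is $\max(0, 8 - n_{\text{contacts}})$ and
  $W = -s \sum \text{exposure}$ with $s = 0.03$. $W$ is the analogue of the
  *attractive* water-apolar Lennard-Jones energy, so it is negative and
  more negative the more exposed the chain: multiplying it by
  $\lambda > 1$ lowers the energy of solvated extended states, and
  $\lambda < 1$ favours collapse. (Only non-local contacts count as
  burial; bonded neighbours would otherwise saturate the counter and make
  $W$ conformation-independent.)

All constants live in one versioned parameter file
(`system.file("params", "cg_default_v1.tsv", package = "swishmc")`),
loadable and writable with `read_energy_params()` /
`write_energy_params()`.

### Sequence chemistry

`parse_modified_sequence()` supports phosphorylation of Ser/Thr
(side-chain charge set to the configured phosphate charge, $-2$ at
physiological pH, $-1$ selectable), side-chain acetylation of Lys (charge
zeroed) and N-terminal acetylation (`acNterm`, or spelled with the first
residue as in `acMet1`; terminal charge zeroed). Modifications also
slightly enlarge the bead (mass and CA-bead distance). Terminal charge
states are configuration, not inference: the experimental peptides'
terminal chemistry is not always known, so amidated or capped termini are
expressed by setting `nterm_charge`/`cterm_charge` to zero.

The Aurora-Rose capping alphabet used by the motif matcher is
`h = {A,V,L,I,M,F,W,Y,C} ∪ {K,R}` and `p = {S,T,N,Q,D,E,H} ∪ {K,R}`: Lys
and Arg belong to both classes because their alkyl chains are hydrophobic
while the charged heads are polar. Phosphorylated Ser/Thr stay polar;
acetylated Lys keeps its alkyl h-membership. Class membership is a pure
function of residue code and modification state — never of position.

## The sampler

Moves are single-dihedral perturbations, uniform within
$\pm\delta_{\max}$ (default 25°), applied in a systematic pass over all
$\phi/\psi$ angles; the proposal is symmetric, so plain Metropolis
acceptance $\min(1, e^{-\Delta U/k_B T})$ holds detailed balance
($k_B T = 0.5961$ kcal/mol at 300 K).

Exchange is attempted every `swap_interval` sweeps (default 10) — the
sweep-space analogue of the all-atom protocol's 5 ps interval, documented
as an analogue, not a simulated time. Adjacent pairs alternate between
even and odd phases deterministically. Under the linear decomposition the
general same-temperature Hamiltonian-exchange exponent collapses to

$$\Delta = \frac{(\lambda_m - \lambda_n)(W_n - W_m)}{k_B T},$$

so the acceptance test needs only the cached $W$ of the two replicas. The
four-energy formula is retained behind `exponent_method = "full"` as a
verification path, and the package's tests confirm both that the two
paths agree to floating-point precision and — the stronger property —
that every rung of a SWISH run on an exhaustively enumerable toy system
reproduces its own Boltzmann distribution, not just the $\lambda = 1$
rung. That chi-square check against direct enumeration is the package's
substitute for trusting the acceptance criterion on authority.

Each replica owns an independent L'Ecuyer-CMRG random-number stream keyed
to its permanent identity, and the exchange phase has its own stream;
swaps therefore never touch RNG state and runs are bit-reproducible from
(seed, configuration). Frames are recorded per rung; `demux()` replays the
exchange log from the identity mapping to recover replica-continuous
(walker) trajectories, and errors on the first inconsistent step rather
than guessing.

By default the first 10% of recorded frames are discarded as
equilibration when computing helicity (`equilibration_fraction = 0.1`,
exposed everywhere); whether the reference analyses used all frames or
post-relaxation frames is not knowable from the outside, so the choice is
a visible parameter rather than a constant.

## Observables

* **Kabsch-Sander bonds**: $E = 0.084 \cdot 332 \,(1/r_{ON} + 1/r_{CH} -
  1/r_{OH} - 1/r_{CN})$, bond iff $E < -0.5$ kcal/mol. Distances below
  0.5 Å are rejected as malformed geometry.
* **Helical assignment**: an $n$-turn at $i$ is a bond
  $CO(i) \to NH(i+n)$, $n \in \{3, 4\}$; two consecutive 4-turns make
  residues $i..i+3$ H, two consecutive 3-turns make residues $i..i+2$ G
  unless already H (alpha priority, the DSSP convention); single turns
  mark their interior T; everything else C. Sheet and pi classes are
  deliberately out of scope — the observable of record counts only alpha
  or 3-10 helicity — so labels other than H/G are cosmetic.
* **Helicity**: per residue, the fraction of frames labelled H or G; the
  overall helicity is the mean over residues, identical to the mean over
  frames of the per-frame helical fraction (both orders are exposed and
  tested equal).
* **Geometric hydrogen bonds**: two electronegative heavy atoms, one
  carrying a hydrogen, with heavy-heavy distance $\le 3.5$ Å (inclusive)
  and heavy-H-heavy angle $> 120°$ (exclusive) — the boundary semantics
  follow the rule's wording exactly and are pinned by tests on both the
  predicate and constructed geometries. Side-chain donors get a virtual
  hydrogen 1 Å beyond the bead along the CA-bead direction, a necessity of
  single-bead resolution. Acetylated Lys is not a donor; phosphorylated
  Ser/Thr become acceptors only.
* **Backbone bond matrices**: cell $(i, k)$ is the fraction of frames with
  a $CO(i) \to NH(i+k)$ bond, $k = 1..4$; per-frame indicator semantics (a
  frame counts once however many atom pairs qualify), the natural pooling
  for group statistics such as phosphate oxygens. Group frequencies via
  `pair_hbond_frequency()` use the same any-pair union rule.
* **Salt bridges**: opposite-sign charged beads within 4.0 Å — the
  conventional heavy-atom criterion, configurable because the underlying
  literature rarely states one.
* **Capping motifs**: patterns `Ia = h-xpxhx`, `Ib = h-xpxph`,
  `IIa = hp-xpxhx` over the h/p/x alphabet with `-` the helix boundary.
  Characters before `-` describe residues immediately preceding the N-cap;
  the first character after `-` is the N-cap itself. This alignment is the
  unique convention consistent with all three worked matches on the
  unmodified sequence (Ib at Ala2, IIa at Leu4, Ia at Phe11) and is
  recorded as derived, not assumed. Note the patterns are necessary, not
  sufficient: other positions can pattern-match by chance; the N-cap
  position itself comes from structure.

## Calibration and what the tests do (and do not) show

The model's defaults were fixed by two qualitative requirements stated in
advance: the unmodified peptide at 300 K should be mostly coil with
transient helix (single-digit percent helicity), and the solvent term
should be comparable to — not dominant over — the intra-chain terms, so
that the $\lambda$ ladder tilts the compact/extended balance by a few
$k_B T$ across its range. With those defaults the model reproduces,
direction-only, the modification phenomenology: phosphorylation of Thr3
raises helicity in the N-terminal half of the peptide, and acetylating
Lys6 on top of it removes most of the increase, because the
phosphate-amine contact is deleted. The package asserts exactly this
ordering, averaged over several seeds, and nothing more. All-atom
helicity percentages (and the associated hydrogen-bond percentages)
require an explicit-solvent force field and are explicitly not
reproduction targets of the coarse-grained model.

What the generator does *not* emulate: explicit water, side-chain
rotamers, proline/glycine irregularity (absent from these sequences),
helix macrodipole effects beyond the terminal charges, and any quantitative
free-energy scale. A passing test suite therefore certifies the
statistical machinery (Metropolis and exchange correctness, estimator
arithmetic, assignment rules, file formats) — not force-field accuracy on
real peptides.

Problem sizes used by the shipped tests and the acceptance script: the
replica-statistics oracle runs 3 residues x 3 states (27 microstates,
exactly enumerable, energy tables spread over $\pm 0.5$ kcal/mol so the
worst single-site trap is about $4\,k_BT$ and microstates mix quickly) for
$10^5$ sweeps on a 4-rung ladder, thinned to every 25th sweep so the
goodness-of-fit draws are effectively independent; peptide checks
use the 19-mer with 4000-8000 sweeps per replica, 6-rung production
ladder, and 4-5 seeds for seed-averaged comparisons.

## Numerical notes

* The $\lambda$-linearity of the energy is exact by construction and
  tested by recovering $(U_0, W)$ from evaluations at the ladder ends.
* Exposure counts are integers, so two conformations can have *exactly*
  equal $W$; the exchange exponent is then exactly zero via the shortcut
  while the four-energy path returns pure cancellation noise. Comparisons
  of the two paths therefore use a relative error with an absolute floor
  of one.
* Ladders are validated, never truncated: bounds not commensurate with
  the step raise an error. A ladder without $\lambda = 1$ runs, but warns
  that there is no physical reporting stream.
* Multi-model PDB is the only trajectory format; coordinates round-trip
  to the format's 10^-3 Å precision. 1-based residue numbering is used
  throughout; angles are degrees, energies kcal/mol, lengths Ångström.

## Known limitations

* Rigid side chains and a single bead per side chain: no rotamer
  entropy, no explicit phosphate oxygens (group statistics pool over the
  one bead).
* The torsion prior is sequence-independent; helix propensity differences
  between residues enter only through bead classes and charges.
* Plain Metropolis single-angle moves mix slowly through the helix
  nucleation barrier; seed-averaged comparisons are used where single
  trajectories would be noisy.
* The exposure proxy is a contact count, not a surface area.
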