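---
title: "Peptaibol folding landscapes: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptaibol folding landscapes: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptaifold)
```

# Scope

`peptaifold` implements two connected analysis chains for peptaibols —
fungal, membrane-active peptides with an acetylated N-terminus, a C-terminal
amino alcohol and a high content of the helix-promoting residue Aib
(alpha-aminoisobutyric acid):

1. **Sequence and mass-spectrometric bookkeeping**: parsing three-letter-code
   sequences with non-standard residues, nominal b/y fragment-ion masses for
   the labile Aib-Pro amide bond, classification into sequence groups A and B
   by the four-residue motif preceding that bond, and aggregation of strain
   production profiles.
2. **Folding-dynamics analysis** of accelerated-MD (aMD) trajectories:
   dihedral principal component analysis (dPCA), boost-potential reweighting,
   free-energy landscape (FEL) construction, and density-peak conformational
   clustering with exact occupancy accounting.

Because microsecond aMD trajectories of these systems are GPU-scale and are
not redistributable, the package ships a seeded synthetic generator of
Markov-switching metastable dihedral dynamics with a state-dependent boost
series. Every downstream stage is tested against the generator's known
ground truth.

# Sequence model and ion conventions

A peptaibol sequence is an ordered list of three-letter residue codes with
positions R1..RL, an acetylation flag and an amino-alcohol terminal flag.
The mass-spectrometric ambiguity codes `Lxx` (Leu/Ile) and `Vxx` (Val/Iva)
are isobaric at nominal resolution; they are resolved to Leu and Val at
parse time — the convention supported by residue abundances at these
positions in the peptaibiotics literature — and the original token is
retained as metadata.

Nominal **integer** masses are the canonical output because the reference
ion tables print integers; the residue table (`residue_masses()`) carries
residue masses (monomer minus water), with amino-alcohol codes at the full
molecular mass of the free alcohol (Pheol = 151 Da).

For cleavage after position $n$ of an acetylated, alcohol-terminated L-mer:

$$b_n = \sum_{i=1}^{n} m_i + 43, \qquad
  y_{L-n} = \sum_{i=n+1}^{L-1} m_i + m_\mathrm{alcohol} + 1$$

i.e. the b ion is the acetyl-capped acylium (+43 for the acetyl cap) and the
y ion is the protonated amine with the amino alcohol counted whole (+1 for
the proton). This convention was chosen because it reproduces every
published (b13, y7p) pair of the twelve reference sequences exactly; an
immediate corollary, tested as a property, is that
$b_n + y_{L-n} = \sum_i m_i + 44$ independently of $n$.

The **labile bond** is the first Aib followed by Pro (R13–R14 in all twelve
reference sequences). The **group rule** inspects the four residues ending
at that Pro: `Gly-Leu-Aib-Pro` is group A, `Gly-Aib-Aib-Pro` is group B,
anything else — including sequences without an Aib-Pro pair — is `unknown`.

# Dihedral features and dPCA

Backbone dihedrals are handled in degrees (matching MD tool output), wrapped
to $(-180, 180]$ with $-180 \mapsto +180$; one convention, stated and
tested. Radians appear only transiently inside trig calls. The dPCA
embedding maps each angle $\theta$ to $(\cos\theta, \sin\theta)$, removing
the periodic discontinuity; columns are ordered cos-then-sin per angle.

`dpca()` eigendecomposes the mean-centred sample covariance
($1/(N-1)$ normalisation — the choice does not affect eigenvectors or
variance fractions). Components are sorted by descending eigenvalue, and
each eigenvector's sign is fixed so its largest-magnitude entry is positive.
The sign convention costs nothing and makes projections, landscapes and
cluster labels identical run to run, which matters because cluster numbering
feeds the reporting layer.

The module is agnostic about *which* angles the table contains: terminal
residues with undefined $\phi$ or $\psi$ are simply absent, and nothing
assumes a fixed residue count.

# Boost reweighting

aMD adds a non-negative boost $\Delta V$ to the potential wherever it falls
below a threshold, flattening barriers. Unbiased expectations are recovered
by weighting frame $i$ by $e^{\Delta V_i / k_B T}$. Two estimators are
provided:

- **exponential** — the exact factor, computed with a max-shift so large
  boosts cannot overflow. Statistically exact but high-variance when
  $\Delta V$ fluctuates by many $k_BT$.
- **maclaurin** — the truncated series
  $\sum_{j=0}^{k} (\Delta V_i/k_BT)^j / j!$, the standard variance-robust
  approximation; order 2 is the default.

The default is `maclaurin` order 2 for realistic boost series, because the
series estimator degrades gracefully under boost noise; the exponential
estimator is what the synthetic-recovery tests use, since the generator is
constructed so that exponential reweighting exactly targets the planted
populations. $k_BT$ defaults to $0.0019872 \times 300 = 0.59616$ kcal/mol
(300 K); it is overridable everywhere it appears. Under dual boost both the
dihedral and total terms are biased, so the total boost feeds the weights by
default, with a switch for the dihedral component.

Reweighting is applied at the **histogram stage**, never inside the PCA fit:
the landscape is reweighted, the coordinate system is not.

# Landscapes and clustering

A d-dimensional histogram over the leading PCs uses equal-width bins
spanning the data range per dimension, with the last bin right-closed so
maximal frames are counted; 100 bins/dimension is the 2-D plotting default.
The landscape is $\mu = -k_BT \ln P$, shifted so the minimum occupied bin is
0. Empty bins are `NA` in the data output and are filled at
$\max\mu + k_BT$ for plotting only. $\mu$ *differences* are invariant to
rescaling $P$, so normalisation conventions cannot change barrier heights —
a tested property.

**Clustering** operates on a raw frame-count density map (default $d = 3$,
24 bins/dimension; 12 bins/dimension is the sensible choice at $d = 5$ to
bound grid memory), because occupancy bookkeeping is defined in frames.
A weighted map is available for sensitivity analysis. A bin is a **peak**
when its count is at least every count in its full Moore neighbourhood and
exceeds `threshold_fraction` (default 0.10) of the maximum bin count; on
ties a bin qualifies only if strictly greater than every tied neighbour of
lower linear index, so a plateau yields exactly one peak rather than one per
bin. Peaks are ranked by descending density; under this rule raising the
threshold can never increase the peak count, and the global maximum always
survives, so an empty peak set cannot arise from thresholding alone.

Frames join the nearest peak in Euclidean PC distance (ties to the denser
peak); occupancy is exactly $100 \cdot \mathrm{count}/\mathrm{total}$, and
each cluster's representative frame is the assigned frame nearest the peak
centre. Cluster *numbering* is by density rank; published cluster numberings
are not always occupancy-ordered, so label-for-label agreement with any
particular table is not a goal — occupancies and counts are.

The **saddle estimate** between the two deepest wells is computed by a
flooding search: occupied bins are added in order of increasing $\mu$ and
merged with added Moore neighbours; the level at which the two wells first
connect is the minimal over paths of the maximal $\mu$ en route. If the
wells share no occupied corridor the saddle is reported as `NA` rather than
invented.

# The synthetic generator

The generator emulates the *statistical* structure the analysis chain
assumes — metastable basins plus a non-negative bias — not any engine's
boost functional form, whose threshold energies are system-specific and
unpublished. Its pieces:

- **Templates**: per-angle mean vectors; shipped presets are the helical
  basin $(\phi, \psi) = (-63.8, -38.3)$, the extended/C5 basin
  $(-157.2, 161.9)$, and a hairpin mixing the two along the chain. Defaults
  use 18 residue pairs, the interior of a 20-mer.
- **States**: a Markov chain from a row-stochastic transition matrix,
  started from its stationary distribution. The default chain is sticky
  (self-transition 0.995), giving dwells of ~200 frames — long enough that
  basins are metastable on the trajectory scale, short enough that a
  100,000-frame run contains hundreds of transitions.
- **Angles**: template plus independent Gaussian noise (default sd 8°, small
  against the ≥60° inter-template separations), wrapped. Independence keeps
  the ground truth analytic.
- **Boost**: $\Delta V_i = \max(0, \mathcal N(\mu_{s_i}, \sigma))$ with
  state means solved from
  $p_b(s)\, e^{\mu_s / k_BT} \propto \pi(s)$, where $p_b$ is the chain's
  stationary distribution and $\pi$ the target unbiased populations, then
  shifted so the smallest mean is zero (the shift cancels in normalised
  weights and keeps the boost non-negative). Exponential reweighting of the
  emitted frames therefore provably targets $\pi$; with default
  $\sigma = 0.05$ kcal/mol the truncation bias of the max(0, ·) is
  negligible.

One seed governs each draw; `simulate_trajectory()` derives sub-seeds
deterministically, and outputs are bit-for-bit reproducible.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: angular correlations along the chain, gradual
transition paths (switching is instantaneous, so synthetic FELs have *empty*
corridors between basins and the saddle estimate is legitimately `NA`
there), solvent effects, and realistic boost autocorrelation. Tests that
need a connected landscape therefore construct the density grid directly.

# Test problem sizes and tolerances

Statistical recovery tests run at $10^5$ frames — large enough that the
3-standard-error bands are a few tenths of a percentage point, small enough
that the whole suite runs in seconds. For the reweighting-recovery check the
frames are serially correlated, so the standard error is computed from the
number of metastable dwell segments (the effectively independent blocks),
not the frame count. Equivalence with dense-eigensolver and exhaustive-scan
oracles is asserted at 1e-10 and exactly, respectively; exact reference
values (ion masses, occupancy percentages, production totals) are asserted
as integers or to printed precision.

# Known limitations

- Dihedral tables are the input boundary: computing dihedrals from Cartesian
  trajectory formats is out of scope (any standard trajectory tool can
  produce the table).
- Detected cluster counts depend on the binning and threshold wherever
  basins are broad or overlapping; they are faithful to the definitions
  here, not to any unpublished parameter choice.
- The group comparison in `build_report()` is descriptive (means, minima,
  maxima per group); no statistical association between folding metrics and
  bioactivity annotations is claimed or computed.
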