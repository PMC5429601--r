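---
title: "proteoMSI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{proteoMSI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Ultra-high-resolution MALDI imaging of intact proteins (FTICR, 15 T
class instruments) resolves the full isotopologue envelope of every
protein ion between roughly 3.5 and 16 kDa.  That resolution is what
makes the data interpretable: envelopes of distinct proteoforms that a
linear TOF amalgamates into one broad hump appear as separate combs,
proteins of equal nominal mass interleave ("isobaric isotopomers") yet
remain separable, and a single isotopologue can be imaged with true
molecular specificity.  But none of the peaks carry an identity.
Identities come from bottom-up LC-MS/MS of microdissected tissue, and
the bridge between the two experiments is purely computational: exact
isotope-envelope theory plus accurate mass.

`proteoMSI` implements that bridge end to end:

1. exact nominal-mass isotopologue envelopes for any CHNOPS(+Na,K)
   composition;
2. enumeration of candidate proteoforms (PTM stacks, chemical
   modifications, adducts, charge states 1-3) from identification
   lists, restricted per region of interest;
3. envelope extraction from profile ROI-average spectra and two-gate
   matching (|ppm| < 10 on the apex isotopologue, Pearson r >= 0.95 on
   envelope shape);
4. internal verification across charge states;
5. label-free-quantification concordance between MSI intensities and
   summed tryptic-peptide areas;
6. metabolite elemental-formula assignment from accurate mass and
   isotope pattern;
7. a fully seeded FTICR-like simulator that provides ground truth for
   every one of those stages.

# Isotope envelope theory

Envelopes are computed on the nominal-mass (neutron-shift) grid:
isotopologues that differ only in which atoms carry the extra neutrons
are aggregated into one bin whose centroid is the abundance-weighted
mean mass of its fine structure.  At the resolving powers this package
targets (R ~ 50,000 at m/z 16,000), isotopologue fine structure of
intact proteins is unresolved, so the aggregated representation is the
physically observable one.

The engine convolves per-element distributions by repeated squaring
with per-step pruning at 1e-10 relative abundance; a brute-force
atom-at-a-time expansion (no pruning, no squaring) lives in the test
suite as an independent oracle and agrees to better than 1e-9 absolute
abundance for molecules up to 60 atoms.  The isotope masses and
abundances are vendored as a pinned table (`isotopeTable()`, stamped
`CIAAW-2013` in every report) rather than taken from any library
default, so results are reproducible across environments.

Three masses are reported for every composition (`massTriple()`):
monoisotopic, average, and most-abundant-isotopologue.  Printed m/z
values in the literature rarely say which convention they use; the
package always reports all three and never guesses.

Ionization arithmetic includes the electron mass in the carrier (a
proton weighs 1.007276 Da); `m/z = (M + n m_carrier)/z`, deprotonation
subtracts a proton.  Whether a molecule actually has enough exchangeable
hydrogens for a requested deprotonation count is documented as
unchecked.

# The candidate search space

From each identification record the package enumerates: chain variants
(full, initiator-Met removed when the sequence starts with M) x
modification count vectors (methyl <= 3, acetyl <= 2, oxidation <= 2,
deamidation <= 1, disulfide <= 1, at most 4 in total — all
configurable) x adducts (protonated; +Na-H and +K-H salt exchange;
a matrix adduct defaulting to sinapinic acid minus water, +C11H10O4,
fully configurable because matrix-adduct composition is preparation
dependent) x charges 1-3, filtered to the neutral-mass acquisition
window.  N-terminal acetylation is expressed through the acetyl counter
(mass-identical to a separate chain variant, and assignment is by mass
only).  Cysteines are free thiols unless a disulfide count is applied.

Compositions are exact — no averagine approximation anywhere — and
candidate envelopes are computed lazily with memoization, because only
the narrow mono-mass window below an observed apex ever needs them.

# Matching: gates, ranking, and honest ambiguity

The two acceptance gates follow standard practice for this data type:
mass accuracy within 10 ppm measured on the apex (most abundant)
isotopologue — the monoisotopic peak of a 5-16 kDa protein is weak or
absent at realistic SNR — and Pearson r >= 0.95 between max-normalized
theoretical abundances (members >= 5% of apex) and the experimental
heights at those positions, with missing members contributing zero so
that incomplete envelopes are penalized rather than silently trimmed.
Both the height readout (default) and the member-pairing tolerance are
configurable; an area mode is available.

Two refinements matter in practice and are the package's own design
choices:

**Apex-position correction.**  When the top two theoretical bins are
nearly degenerate (neighbor >= 70% of apex), envelope noise can flip the
experimental argmax by one bin.  Measured apex-to-apex this looks like
a ~1 Da error and a spurious rejection; the package measures the mass
error against the member the experimental apex actually corresponds to
whenever that member is a near-degenerate neighbor of the theoretical
apex, and flags the result (`apexShifted`).

**Mass-indistinguishability clusters.**  Many modification stacks
differ by the CH4-vs-O unit (36.4 mDa): trimethyl vs acetyl, methyl vs
oxidation+disulfide.  At 5-16 kDa that is 2-7 ppm — inside the mass
gate — and empirically neither the ppm error (dominated by the
per-dataset calibration offset) nor the envelope correlation
(differences of ~2e-5, below noise) separates such candidates reliably;
which one scores better flips with the random seed.  Pretending
otherwise would be silent misassignment.  Accepted candidates whose
theoretical apex masses lie within a configurable window (5 ppm, with a
0.04 Da floor covering the CH4/O class) therefore form one ambiguity
cluster that is reported as a set of co-assignments.  Within a cluster
the ordering is by parsimony — the number of departures from the plain
protonated full chain (each modification, a non-proton adduct, a
truncation) — then by the rank score `r x (1 - |ppm|/tol)`, which also
orders mass-distinguishable candidates against each other.  The
parsimony rule is how a practitioner annotates: prefer the simplest
explanation, list the indistinguishable alternatives.

**Charge corroboration.**  Assignments sharing a proteoform at
different charge states are grouped; the neutral mass recomputed from
each charge state must agree (dispersion below the ppm tolerance; on
clean simulations it is under 1 ppm).  Detecting the same proteoform at
z = 1, 2, 3 with consistent neutral mass is internal verification of
the assignment.

**Decoys.**  False-assignment behavior is estimated competitively:
decoy identification lists are built by pooling all target residues,
permuting the pool, and re-splitting at the original lengths (a
per-protein shuffle would preserve each exact composition and make
every decoy a guaranteed self-match; reversal is equally useless for
mass-only matching).  Decoy candidates are enumerated under the
identical search space and pooled with the targets.  Two rates are
reported: the accepted decoy *pair* rate (how often any decoy passes
both gates anywhere — with the full modification space this is
substantial, typically 15-40% of envelopes, which is precisely the
false-positive risk that motivates region restriction), and the decoy
*primary* rate — the fraction of envelopes whose top-ranked assignment
is a decoy, i.e. how often the pipeline would actually report a false
identity.  On the standard benchmark the primary rate is well under 2%.

# Quantification concordance

Protein-level label-free quantification is the sum of tryptic peptide
areas per replicate, then mean +/- sd across replicates within each
region; shared peptides count for every parent by default (flagged),
or are dropped in unique-only mode.  MSI region intensities are read as
apex peak heights from the picked ROI-average spectrum: at FTICR
resolving power neighboring species are separate peaks, so the peak
readout is more interference-robust than an ion-image m/z window that
can clip a resolved neighbor's tail.  When a protein is detected at
several charge states, the benchmark uses the charge state whose fold
change is the median — a charge state whose comb happens to coincide
with another protein's comb reads contaminated (inflated) heights, so
"use the strongest ion" would prefer exactly the corrupted readout.
Fold changes are stabilized with a pseudo-count of half the smallest
nonzero value, one-sided detections are flagged, and proteins with a
negligible planted/measured effect are excluded from the headline
agreement fraction (direction agreement for a true fold change of 1 is
a coin flip).

# Metabolite formula assignment

Formula candidates are generated by exhaustive CHNOPS enumeration
within element bounds (defaults C<=40, H<=80, N<=10, O<=30, P<=4,
S<=3), solving the hydrogen count directly from the residual mass, then
filtering by ppm tolerance (default 2 ppm — the package's declared
default for accurate-mass work, deliberately not attributed to any
instrument), RDBE >= 0 and integer-valued (a neutral closed-shell
molecule), element-ratio windows (H/C, N/C, O/C, P/C, S/C), and a
phosphate-chemistry rule (at least 3 oxygens per phosphorus, as
biological phosphorus occurs as phosphate; configurable).

Pattern scoring is a Pearson correlation over M, M+1, M+2 — but a
three-point correlation is apex-dominated and barely reacts to a
deleted M+1 on its own, so a missing member predicted at >= 1%
abundance additionally deducts 0.05 from the score, and candidate
*ranking* uses a pattern deviation (summed absolute difference of
normalized heights) as the primary key with |ppm| as the tie-break.
Structural isomers (glucose 6-phosphate / fructose 6-phosphate) are
never disambiguated: annotation is to the formula, and all names of a
mass-class are reported together.

Amine-metabolite charge-tagging (pyrylium-type derivatization) is
modeled purely as a configurable mass delta with **no default**: the
delta depends on the reagent chemistry and must be stated explicitly in
the configuration.  The simulator's own test configuration uses a
synthetic delta, labelled as such.

# The simulator

The generator exists to provide ground truth, and its defaults are the
study conditions, not tuning knobs:

* **Instrument.**  FTICR mode with R = 50,000 at m/z 16,000 scaling as
  1/(m/z) — the minimal resolving power consistent with full isotopic
  resolution of singly charged ions up to m/z 16,000; acquisition
  window 3,500-16,500 (the isotopically resolved regime); Gaussian
  peaks (analytic apex math; Lorentzian available); profile axis
  uniform in 1/(m/z) (the FT frequency domain) at 4 samples per FWHM.
  The TOF-emulation mode uses a constant R = 1,000 for contrast
  experiments; no baseline is added in FTICR mode (metastable chemical
  background does not survive the FT time scale) and an optional
  baseline exists only for TOF emulation.
* **Errors.**  One mass-calibration offset per dataset (s.d. 1.5 ppm,
  truncated at 2 s.d. — typical external-calibration FTICR
  performance), 0.2 ppm per-peak jitter, per-pixel log-normal abundance
  variation (CV 0.25), additive Gaussian detector noise (s.d. 1
  intensity unit against planted abundances of 50-500).
* **Biology.**  Random sequences at vertebrate-average residue
  frequencies (realistic C/H/N/O/S ratios and hence envelope shapes);
  a fraction of proteins exclusive to one region, the rest shared with
  planted log2 fold changes; 20% of proteins carry histone-like PTM
  ladders (mono/di/tri-methyl, acetyl) emitted at charges 1-3; tryptic
  tables with up to 2 missed cleavages, per-peptide log-normal
  ionization factors shared across replicates, and replicate CV 0.2
  over 3 replicates per region (one per consecutive section).
* **Presets.**  `presetIsobaricPair()` builds two region-exclusive
  proteins of identical length and nominal residue composition
  differing by eleven Gln->Lys substitutions (+0.400 Da monoisotopic,
  +0.48 Da average): their isotopologue combs interleave on the shared
  nominal grid and are only separable at full isotopic resolution.
  (Eleven substitutions also keep the interleaving offset away from the
  1.00235/3 Th charge-3 spacing, so extraction cannot misread the two
  z = 1 combs as one z = 3 series.)  `presetHistoneLadder()` emits one
  ~11.3 kDa backbone as five proteoforms at three charge states each,
  with acetylation up-regulated in the first region.

Everything is driven by one explicit seed (seeds are mandatory, never
implicit), and regeneration is byte-identical — the imzML writer emits
no timestamps and derives its file UUID from the seed.

**What the simulator does not emulate** — and therefore what passing
tests do and do not show about real data: absorption-mode FT line
shapes, space-charge frequency shifts and coalescence of close peaks,
MALDI shot-to-shot and matrix-crystal heterogeneity beyond a log-normal
factor, chemical background and in-source decay, chromatographic and
search-engine behavior behind the identification tables (their *output*
is simulated directly), and histology registration (ROIs enter as
coordinate masks).  Passing the benchmarks shows the computational
bridge is correct and well-behaved under realistic noise, calibration
error and spectral interference; it does not certify performance on any
particular instrument's artifacts.

# Benchmark scales and known limitations

The standard benchmarks use 50 proteins (3.5-16 kDa, PTM stacks,
charges 1-3, noise on) on a 4 x 4 pixel grid for recovery/decoys, and
100 proteins with planted |log2 FC| >= 1 for concordance — sizes chosen
so every stage, including full profile rendering at FTICR sampling
density (~700k points per pixel), runs comfortably on a desktop.

Known limitations, all visible in the benchmarks at honest settings:

* Proteoform pairs differing by ~36 mDa are reported as ambiguity
  clusters, never resolved — no mass measurement at these masses can.
* Two random proteins landing within ~0.1 Da of each other at every
  charge state contaminate each other's single-isotope readouts; with
  100 proteins over the 3.5-16 kDa range this happens in a few percent
  of datasets and can flip one protein's apparent fold-change
  direction.
* The accepted decoy *pair* rate at the default gates is large by
  construction of the modification search space; it is the competitive
  primary rate that is controlled.  Region restriction is load-bearing:
  it halves the candidate (and decoy) density per ROI.
* m/z recalibration is deliberately out of scope; the mass gate must
  absorb the calibration offset.
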