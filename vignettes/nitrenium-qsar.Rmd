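---
title: "Nitrenium-ion stability as a local QSAR for aromatic amine mutagenicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nitrenium-ion stability as a local QSAR for aromatic amine mutagenicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Primary aromatic amines (ArNH2) are mutagenic through metabolic activation:
N-hydroxylation by CYP enzymes, conjugation or hydrolysis, and finally
heterolysis to a nitrenium ion (ArNH+) that attacks DNA. The more the
aromatic system stabilizes the nitrenium ion, the easier that final step is,
so thermodynamic nitrenium stability is a mechanistically grounded,
training-set-free predictor of Ames mutagenicity. This package scores each
amine by the relative stabilization energy, in kcal/mol,

$$
\Delta\Delta E \;=\; \Delta E_{ArNH^+} + \Delta E_{PhNH_2}
              \;-\; \Delta E_{ArNH_2} - \Delta E_{PhNH^+},
$$

where the four terms are AM1 heats of formation of geometry-optimized
species and the Ph pair is aniline, which therefore sits at exactly
0 kcal/mol by construction. Negative values mean the substituents stabilize
the cation more than in aniline (electron donors: methyl, para/ortho
methoxy), which correlates with Ames-positive amines; positive values mean
destabilization (sulfonate, sulfonamide, trifluoromethyl, ring-deactivating
groups), which correlates with Ames-negative amines. The default decision
rule is the sign of $\Delta\Delta E$: negative is called mutagenic, zero or
positive nonmutagenic (the boundary goes to nonmutagenic because aniline
itself is Ames-negative). Accuracy on an 85-compound industrial benchmark
peaks near a cutoff of +2.5 kcal/mol; that alternative cutoff is available
as `cutoff = 2.5` but is never applied silently. Scores within roughly
±5 kcal/mol of the cutoff separate the classes poorly and deserve expert
review; the optional `equivocal_band` argument can label that zone
explicitly instead of forcing a binary call.

## The computational protocol

For each compound the pipeline is:

1. **Parsing and normalization** (`parse_structures()`, `parse_smiles()`).
   Structures come in as SMILES or SDF; explicit hydrogens are added and
   aromaticity perceived through Open Babel. Multi-fragment inputs keep
   only the largest carbon-containing fragment, so salts such as aniline
   hydrochloride are scored as the free base. Unparsable entries become
   rows with a `parse error` remark; a batch run never aborts.

2. **Eligibility** (`check_eligibility()`). The six curation criteria of
   the local-QSAR domain: (i) no net formal charge, (ii) molecular weight
   under 500 Da, (iii) at most one potential tetrahedral stereocenter,
   (iv) fewer than 10 rotatable bonds, (v) exactly one primary aromatic
   amine site — a trivalent, uncharged N with two hydrogens bonded to one
   aromatic carbon — and (vi) no aromatic nitro group. All failures are
   reported together. The criteria sources do not pin down operational
   definitions of "rotatable bond" or "stereocenter", so this package
   declares them: rotatable means a single acyclic bond between two
   non-terminal heavy atoms excluding amide C–N; stereocenters are counted
   as potential ones (sp3 carbons with four topologically distinct
   branches), assigned or not. Ineligible compounds are not scored unless
   `force = TRUE`, and even then the failed criteria stay in the remark.

3. **Conformers** (`enumerate_conformers()`). The neutral amine is embedded
   by seeded stochastic distance geometry (RDKit ETKDGv3 through a bundled
   Python helper); the number of trials grows with the rotatable-bond count
   (minimum 20, maximum 300). Every trial is minimized with MMFF94,
   members more than 7 kcal/mol above the minimum are discarded, and
   duplicates below 0.5 Å heavy-atom RMSD (after optimal superposition)
   are removed. The same seed yields a bit-identical ensemble, which is
   what makes the aniline reference cancel to exactly zero. The window is
   deliberately generous: the force-field ranking only has to hand the AM1
   stage every basin that might contain the true minimum.

4. **AM1 refinement** (`engine_am1()`, `optimize_species()`). Every
   windowed conformer is geometry-optimized with the bundled AM1 engine
   and the most stable conformer — lowest heat of formation, not lowest
   force-field energy — defines $\Delta E_{ArNH_2}$.

5. **Nitrenium construction** (`build_nitrenium_candidates()`). From each
   retained neutral geometry, one cation start structure per amine
   hydrogen is made by deleting that hydrogen (the portable equivalent of
   replacing it with a non-interacting dummy atom) and setting the total
   charge to +1; no pre-relaxation. Each candidate is AM1-optimized and
   the lowest result defines $\Delta E_{ArNH^+}$. By default cations are
   seeded from **all** retained neutral conformers
   (`cation_from_all_conformers = TRUE`): "the lowest value is adopted" is
   ambiguous between lowest-over-hydrogens and lowest-over-conformers, and
   the all-conformer minimum contains the single-conformer answer as a
   special case, so it is the more robust reading. The flag restores the
   narrower protocol.

6. **Guard rails.** A species whose SCF or geometry optimization fails is
   dropped; if nothing survives the compound is reported `NaN`. After each
   optimization, connectivity is re-perceived from the final geometry
   (bonded when the distance is under 1.25 times the sum of covalent
   radii); if an aromatic ring bond of the input topology is gone, the
   species is discarded and the compound reported `aromatic ring opening`
   when that is what exhausted the candidates. Remarks form a closed
   vocabulary — `""`, `NaN`, `aromatic ring opening`, `no aromatic amine`,
   `ineligible:<criteria>`, `parse error` — so downstream tools can filter
   mechanically. Failures never raise errors in batch runs.

## The bundled AM1 engine

No external quantum-chemistry program is required: the package ships its
own implementation of the AM1 model (Dewar, Zoebisch, Healy & Stewart,
*J. Am. Chem. Soc.* 1985, with the published halogen and sulfur
parameter extensions) as compiled code — a closed-shell restricted
Hartree–Fock SCF over the NDDO integral approximation. Slater-orbital
overlaps are evaluated analytically in prolate-spheroidal coordinates;
two-electron integrals use the standard point-charge multipole
configurations with Klopman additive terms, computed in the local diatomic
frame and rotated tensorially (the energy is rotation- and
translation-invariant to numerical precision, which the tests assert).
Isolated-atom energies are derived from the one-center parameters and
Hund's-rule occupations rather than tabulated. Geometry optimization is
BFGS on Cartesian coordinates with pairwise central-difference gradients
evaluated at frozen converged density — exact at SCF stationarity — to a
default gradient norm of 0.5 kcal/mol/Å. SCF uses DIIS with early-iteration
damping. Nitrenium cations are even-electron species and are treated as
closed-shell singlets. Supported elements: H, C, N, O, F, S, Cl, Br.

The implementation is validated two ways. First, against published AM1
heats of formation of small molecules (methane −8.79, ammonia −7.3, water
−59.2, ethane −17.4, benzene 22.0, methanol −57.0 kcal/mol), reproduced to
about 0.1 kcal/mol; the computed isolated-atom energies match the published
AM1 values to 10⁻⁴ eV for all eight elements. Second, against the printed
$\Delta\Delta E$ values of the bundled 23-compound panel (below). Residual
differences from historical AM1 builds (integral conventions, optimizer
thresholds) largely cancel in the double difference and stay well inside
the ±1 kcal/mol acceptance tolerance used in the tests.

`engine_mopac()` drives an external MOPAC-dialect program instead, for
users who have one; `engine_mock()` substitutes scripted energies so every
layer above the engine can be tested without quantum chemistry. AM1 is the
reference Hamiltonian of this QSAR — scores from anything else are not
comparable to the published scale.

## The reference panel and the synthetic generator

`reference_set()` returns the 23-compound panel used throughout the tests:
aniline (as its hydrochloride, which doubles as the salt-stripping test),
seven methylated and three methoxylated anilines, three sulfonic acids,
two sulfonamides, and seven expert-review case-study amines, with CAS
numbers, Ames calls, printed $\Delta\Delta E$ values, and the commercial
QSAR tool calls as uninterpreted annotation strings. SMILES were resolved
from the printed CAS numbers and names once, at authoring time. The
package's regression suite recomputes all 23 values end-to-end and checks
them against the printed column (±1 kcal/mol on the benchmark members,
rank correlation ≥ 0.95, sign agreement).

`synthetic_scores()` draws Gaussian ddE values for labelled classes. Its
defaults emulate the published benchmark composition — 51 mutagens and 34
nonmutagens — with class means ±8 kcal/mol and a common 5 kcal/mol spread,
the separation scale seen in the real score distribution. It exists to
exercise the metric and cutoff-sweep machinery at arbitrary sample sizes;
it reproduces class imbalance and score overlap, but not the heavy tails,
multimodality, or structure-correlated errors of real chemistry, so
passing sweep tests on synthetic scores says nothing about accuracy on new
compounds.

## Benchmarking layer

`confusion_counts()` tallies TP/FP/TN/FN with mutagenic as the positive
class; inconclusive and out-of-domain calls are excluded from the matrix
and surface only through coverage, which is the only reading under which a
tool can report partial coverage alongside well-defined accuracy.
`compute_metrics()` returns accuracy, sensitivity, specificity, positive
and negative prediction values, Matthews correlation coefficient, and
coverage; any statistic with a zero denominator is `NA` ("not
applicable"), never 0. Values are kept at full precision; displays round
half-up to one decimal. `cutoff_sweep()` scans a grid (default −10 to
+10 kcal/mol in 2.5 steps) and reports the best cutoff by accuracy, ties
broken by larger MCC and then by smaller |cutoff| — the tie-break is this
package's convention, declared here because the sweep definition alone
does not determine one.

The published performance table for the method (69.4% accuracy, 74.5%
sensitivity, 61.8% specificity, MCC 0.4, 100% coverage) was measured on an
85-compound in-house industrial set that is **undisclosed**; it cannot be
recomputed end-to-end here. The suite therefore covers it as a formula
worked example: with 51 mutagens and 34 nonmutagens, those percentages
imply TP = 38, FP = 13, FN = 13, TN = 21, and `compute_metrics()` must map
those counts back to every printed value after rounding. The same applies
to the published cutoff-sweep table.

## Numerical choices and limitations

* Problem sizes: the regression suite optimizes roughly 130 AM1 species of
  up to 24 atoms (the full panel) in a few minutes on one core; per-species
  optimization is seconds. The acceptance script recomputes the benchmark
  subset of the panel from scratch.
* Determinism: embedding is seeded, the rotor search over trials is
  exhaustive within its budget, SCF and BFGS are deterministic, so a fixed
  seed reproduces every number bit-for-bit on the same platform.
* Degenerate inputs: empty files warn and return empty; unparsable records,
  embedding failures, SCF failures, and ring ruptures map to the remark
  vocabulary; ties in conformer energy resolve to the first-generated
  member.
* Ionizable groups (sulfonic, anthranilic acids) are scored as neutral
  species, consistent with the no-formal-charge domain criterion and with
  how the panel's sulfonic acids were scored.
* The score is thermodynamic only. Bulky substituents that sterically block
  CYP activation, or strong resonance effects on the activation step
  itself, are invisible to it and are known sources of false positives.
  There is no applicability-domain model beyond the six criteria and no
  probability calibration; the tool is meant to support expert review with
  a quantitative, mechanism-based indicator, not to replace it.
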