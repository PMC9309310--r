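---
title: "Spectral inference for salmonid visual photopigments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral inference for salmonid visual photopigments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salmopsin)
```

## The inference problem

A visual photopigment is an opsin protein covalently bound to an 11-*cis*
retinal chromophore through a Schiff base at lysine 296 (bovine rod-opsin
numbering). Its wavelength of peak absorbance, $\lambda_{max}$, is set by the
residues lining the chromophore pocket. Salmonids carry an unusually rich
opsin repertoire — after the salmonid-specific fourth whole-genome
duplication, Atlantic salmon retains eleven full-length visual opsins across
the five vertebrate classes (SWS1, SWS2, RH2, LWS, RH1) plus several
pseudogenized copies — and the spectral diversity within the RH2 and LWS
classes is functionally important during the fish's anadromous life history.

`salmopsin` implements the desk-scale half of characterizing such a
repertoire: everything downstream of sequence acquisition and molecular
dynamics production runs. Genome mining, phylogenetics, homology modelling,
and the MD simulations themselves are out of scope; the package *consumes*
sequences, trajectories, descriptor tables, and count tables.

## Rule-based spectral tuning

For SWS1, LWS, and RH1 pigments, $\lambda_{max}$ can be assigned by
interrogating known spectral tuning sites after mapping the query onto
bovine rod-opsin numbering.

**Numbering.** `map_to_bovine_numbering()` globally aligns the query protein
against the 348-residue bovine rhodopsin (NP_001014890) with BLOSUM62 and
affine gaps (open 10, extend 0.5, end gaps penalized). Opsins are
full-length, globally alignable GPCRs, so a global alignment is the right
model; the gap parameters are conventional protein-alignment defaults and
are exposed as arguments. No alignment recipe is canonical for this mapping
— published tuning-site work does the interrogation manually — so the choice
is ours and is validated by planted-site recovery tests rather than by
matching a published alignment.

**SWS1.** Phenylalanine at site 86 marks an ultraviolet pigment with
$\lambda_{max} = 360$ nm; any other residue marks a violet-shifted pigment,
for which the rule assigns no number.

**LWS.** The additive five-sites rule starts from 560 nm for the ancestral
state S164/H181/Y261/T269/A292 and applies per-site blue shifts for S164A
(−7), H181Y (−28), Y261F (−8), T269A (−15), A292S (−27 nm). The shift values
come from the classical LWS mutagenesis literature — they are registered in
a packaged, overridable rule table (`tuning_rule_table()`) rather than
hard-coded — and they reproduce the published salmonid outputs: 560 nm for
the ancestral profile and 553 nm after the single substitution S164A.
Profiles whose residues match neither state are skipped with a warning;
unalignable sites make the prediction `"incomplete"` but it is still
computed from the remaining sites. Predictions below 500 or above 575 nm
carry an `out_of_class_range` flag instead of being clipped: the additive
rule extrapolates linearly, and heavily substituted profiles can leave the
range in which the rule was characterized.

**RH2.** Site 122 acts as a green/blue switch: E122 pigments sit above
~495 nm, Q122 pigments below, the substitution alone accounting for roughly
15 nm. `classify_rh2_e122q()` returns the qualitative call; numeric RH2
values come from the regression route below.

**RH1.** Twenty-seven rod-opsin sites are interrogated and annotated
(D83N, E122Q, A164S, F261Y, A269T, A292S with their shift directions). No
complete additive rule set over all 27 sites exists in the literature, so
the numeric estimate (500 nm base plus registered shifts) is always flagged
`"approximate"`; the report, not the number, is the deliverable.

## Chromophore descriptors from trajectories

For SWS2 and RH2 pigments, sequence rules are unreliable and
$\lambda_{max}$ is instead predicted from the conformation and flexibility
of the chromophore observed in molecular dynamics. `compute_descriptors()`
extracts five quantities from a trajectory of the retinal + lysine moiety:

| descriptor | definition | units |
|---|---|---|
| Torsion 15 | median dihedral C7–C6–C5–C18 | degrees |
| Angle 3    | median geometric angle C3–C7–C8 (vertex C7) | degrees |
| Torsion 3  | median dihedral C15–C14–C13–C20 | degrees |
| Torsion 12 | median dihedral C19–C9–C8–C7 | degrees |
| RMSF(LYS+RET) | area under the per-atom RMSF curve | Å·atom index |

Numerical choices, all of which matter at the precision the regression
models need:

* **Dihedral sign.** The standard atan2-of-plane-normals construction, with
  the sign fixed by the frozen case
  `dihedral((0,0,0),(1,0,0),(1,1,0),(1,1,1)) = -90°`. Values live in
  (−180°, 180°]; reversing the atom order preserves the value, mirroring
  the coordinates negates it.
* **Circular medians.** Per-frame dihedral series are re-branched around
  their circular mean before the ordinary median is taken, so distributions
  straddling ±180° (frames alternating +179°/−179° must give 180°, not 0°)
  are handled deterministically. Whether published medians were
  circular-aware is unstated in the sources; for the near-planar torsions
  involved here the two conventions agree, and the circular version is
  strictly safer. Geometric angles live in [0°, 180°] and use plain
  medians.
* **Angle 3 is taken literally.** Its named atoms (C3, C7, C8) are not
  mutually bonded; the operation computes the geometric angle with vertex
  C7 as written, since no alternative atom triple is documented.
* **Superposition.** RMSF requires removing global rigid-body motion.
  Frames are least-squares fitted (Kabsch, via bio3d) to the mean structure
  of the selected atoms themselves, iterated twice from the first frame.
  The fitting reference is not specified by the sources, which superpose
  within whole-protein simulations; chromophore-only trajectories are what
  this package ingests, so the selection's own mean is the only reference
  available, and a user-supplied reference frame is accepted as an
  argument. Static and rigid-motion-only trajectories give exactly zero
  RMSF after the fit, which the tests assert.
* **RMSF area.** Trapezoidal rule at unit atom-index spacing over the fixed
  LYS+RET atom order. The integration scheme is not documented in the
  sources; trapezoidal-at-unit-spacing is the simplest convention
  consistent with the published magnitudes (~0.76–1.12 over a short atom
  series).

## The regression models

Two published coefficient sets map descriptors to $\lambda_{max}$:

$$\lambda_{max}^{RH2} = 475.628 - 8.720\,T_{15} + 34.925\,\mathrm{RMSF}_{LYS+RET}$$

$$\lambda_{max}^{SWS2} = 2677.5348 - 17.052\,A_{3} + 5.1634\,T_{3} + 2.3642\,T_{12}$$

The SWS2 model is stored in sign-resolved form. The source prints its first
term as "minus a negative product"; evaluated literally that yields
≈ 4933 nm for the model's own example inputs, which is physically
impossible, while the form above reproduces the published example output
(420.04 nm) to hundredths of a nanometre. The resolution is hard-verified
in the test suite. Model evaluation is affine and unclipped: raw outputs
outside 300–650 nm are returned with an `out_of_range` flag, because the
models are only valid near their training descriptor ranges — intercepts
evaluated at zero descriptors are meaningless extrapolations and should
look that way.

Replaying the published descriptor table through `predict_rh2()` gives
471.48, 475.49, 511.17, and 506.72 nm for the four RH2 pigments (printed:
471.5, 475.5, 511.2, 506.4 — the fourth deviates ~0.3 nm because the table
prints descriptors rounded to ≤2 decimals) and 420.036 nm for SWS2. The
RH2 span, 39.7 nm, reproduces the "almost 40 nm" spread that makes this
class the most spectrally diverse in the repertoire.

## Template spectra

`govardovskii_template()` turns a $\lambda_{max}$ into a full normalized A1
dark spectrum using the standard empirical template: the alpha band

$$S_\alpha(\lambda) = \left[e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D\right]^{-1},
\quad x = \lambda_{max}/\lambda$$

with the published constants $A=69.7$, $B=28$, $b=0.922$, $C=-14.9$,
$c=1.104$, $D=0.674$ and
$a = 0.8795 + 0.0459\,e^{-(\lambda_{max}-300)^2/11940}$, plus the beta
(cis) band $0.26\,e^{-((\lambda-\lambda_{m\beta})/b_\beta)^2}$ with
$\lambda_{m\beta} = 189 + 0.315\,\lambda_{max}$ and
$b_\beta = -40.5 + 0.195\,\lambda_{max}$, the sum normalized to peak 1.

One property of the full template is worth stating plainly, because a naive
shape check will trip over it: **the template is not unimodal**. For mid-
and long-wave pigments the beta band is a genuine secondary bump near
350–370 nm (relative height up to ~0.26), and for an ultraviolet pigment
the beta band overlaps the main band closely enough to pull the composite
maximum about 1 nm short of the nominal $\lambda_{max}$. Both behaviours
are properties of the published formula — the implementation agrees with an
independent re-implementation to 10⁻⁹ — not artifacts. `beta_band = FALSE`
yields the bare alpha band, which is unimodal and peaks exactly on the grid
point nearest $\lambda_{max}$. The test suite asserts the alpha-band
properties and the existence (and bounded size) of the cis bump.

## ORF integrity and pseudogene calling

`evaluate_orf()` reproduces the evaluation logic used on salmonid opsin
gene copies: codon-aware comparison of a candidate CDS against an intact
paralogue, classifying lesions and assigning a verdict.

* Indels are located by global nucleotide alignment and classified by
  length mod 3; any frameshifting indel, or any premature stop codon in the
  translation, makes the verdict `pseudogene` (the archetype: a 6 bp
  deletion plus a premature stop, truncating the would-be protein).
* An in-frame deletion of ≥ 30 nt — the threshold generalizes a published
  33 bp case and is an argument, not a constant — makes the verdict
  `nonfunctional_suspect`, with `tm3_disruption` set when the deletion
  overlaps an annotated transmembrane helix. Helix annotations default to
  the approximate bovine rod-opsin topology mapped through the reference's
  own bovine numbering.
* Queries shorter than half the reference are truncation pseudogenes
  outright; the 50% floor is our choice, since the sources exclude
  "partial sequences" without stating a cutoff.
* No indel count threshold is used: "several indels" is operationalized as
  ≥ 1 frameshift or ≥ 1 premature stop, which is the weakest rule
  consistent with the published verdicts.

One recoverability limit is inherent: downstream of a frameshift the
reference reading frame is lost, so engineered stops planted after a
frameshifting lesion are not locatable in reference codons (the verdict is
already `pseudogene` by then). The generator's ground truth and the tests
respect this.

## Expression normalization

The developmental expression module reproduces the simplest defensible
normalization: `normalize_to_min_depth()` scales every library to the
lowest-depth sample (preserving within-sample proportions exactly), and
`log_heatmap_matrix()` builds the heatmap matrix. "Log-fold" reporting of
normalized counts is ambiguous between two readings, so both are
implemented and documented: the default is `log2(normalized count + 1)`;
`mode = "logfc"` gives `log2((c+1)/(c_ref+1))` against a reference stage
(default: the earliest). The pseudocount of 1 is the conventional guard for
zero counts at the integer count scales involved. Full precision is kept
internally; rounding is a rendering concern.

## The synthetic-data generator

Every pipeline input can be generated with recorded ground truth, which is
what makes the package testable without downloads.

**Trajectories** (`make_trajectory()`) are built from an idealized 29-atom
LYS+RET scaffold. Each targeted angle is set exactly, per frame, by
rotating a single mobile leaf atom (C18, C20, C19, or C3) about its bond
axis to a value drawn wrapped-normal around the recipe location; isotropic
Gaussian jitter and optional random rigid motion are then applied. Only the
statistics the descriptors measure are controlled — no force field, no
chemistry. Wrapped-normal sampling was chosen deliberately to exercise the
circular-median branch. Defaults are 5000 frames (the sampling one would
take from a 100 ns production run), angular spreads of a few degrees as
seen in chromophore torsion distributions, and jitter sized to an RMSF
area of order 0.8 over 29 atoms.

The recorded RMSF ground truth uses the fact that least-squares
superposition removes six rigid-body degrees of freedom: isotropic jitter
$\sigma$ per axis over $N$ atoms yields expected per-atom RMSF
$\sigma\sqrt{3(1-2/N)}$, hence an exact expected curve area for spread-free
recipes (`jitter_for_auc()` inverts this). With nonzero angular spreads the
mobile atoms acquire additional tangential variance
$r^2(1-e^{-s^2})$ at lever arm $r$; that contribution interacts with the
rigid fit, so the recorded area is flagged approximate and parameter
recovery is asserted on spread-free recipes.

**Sequences** (`make_sequence()`) copy an intact reference — by default a
synthetic one: the bovine rhodopsin protein reverse-translated with
canonical codons, which makes bovine site *k* equal protein position *k*
and planted-site bookkeeping exact. Requested residues are planted by codon
replacement, lesions applied right-to-left in reference coordinates, and
the expected `evaluate_orf()` verdict recorded. The synthetic reference is
labelled as such; it is a numbering-faithful stand-in, not a salmonid gene.

**Count tables** (`make_counts()`) draw negative-binomial counts over a
4-stage × 4-replicate design (the stand-in replicate structure for a
16-sample developmental series whose exact replicate assignment is not
published) with lognormal gene baselines, gene-specific stage trends,
uniform library depths in a configurable range, and dispersion 0.1 —
typical biological variability for bulk RNA counts. A planted fold change
is recorded as the composition-corrected log2 ratio of proportions, which
is what depth normalization can actually recover (a 30-fold abundance
increase is *not* a 30-fold proportion increase once it moves the library
total). At the default dispersion, single-table recovery scatters by a few
tenths of a log2 unit; the tight recovery test therefore runs at low
dispersion, where the pipeline, not biological noise, is what is being
tested.

## What passing tests do and do not show

The generator controls exactly the statistics the estimators measure, so
green tests demonstrate correctness of the computational chain — geometry,
circular statistics, superposition, alignment bookkeeping, normalization
algebra — under known ground truth, including published-value replays at
the tolerances the printed precision supports (±0.5 nm for the RH2 table
replay, ±0.05 nm for SWS2). They do not validate the regression
coefficients themselves (training data lives in prior work), do not test
robustness to force-field artifacts, alignment ambiguity in highly
divergent sequences, or real RNA-seq biases, and say nothing about A2
chromophore usage, which the package deliberately does not model
(`chromophore` is fixed to `"A1"` throughout).

## Problem sizes

The shipped tests and the acceptance script run at the scales the methods
need, not larger: 5000-frame trajectories for descriptor recovery
(seconds per trajectory), 348-residue alignments, 11 × 16 count tables,
and 1 nm spectral grids over 300–700 nm.
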