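---
title: "Methods: geometry, rotation measurement and frameshift quantification in riboframe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, rotation measurement and frameshift quantification in riboframe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboframe)
```

`riboframe` turns two questions into reproducible computations: *what is the
geometric relationship between 16S rRNA base A1503 and the mRNA in a given
70S ribosome structure*, and *what conformational state is that ribosome
in*. A companion module reduces -1 programmed-frameshifting gel assays to
comparable numbers. This vignette records the models, the tunable
parameters, the numerical choices, and what the synthetic fixtures do and do
not demonstrate.

## The contact model

A nucleobase is summarised by the unweighted centroid of its canonical ring
atoms (purines N1, C2, N3, C4, C5, C6, N7, C8, N9; pyrimidines N1–C6) and by
the least-squares base plane, taken as the smallest-variance axis of the
ring-atom scatter (the third right singular vector of the centred
coordinates). A residue with fewer than five of its ring atoms is
unresolvable and propagates an `unresolved` call rather than a guess; this
also covers abasic and heavily modified positions.

For a query base `q` and each candidate mRNA base `j`, three quantities are
computed:

- `d_j`, the centroid–centroid distance (Å);
- `alpha_j`, the acute angle between the two base planes (degrees);
- `omega_j`, the acute angle between the centroid–centroid vector and the
  query base normal (degrees).

Base `j` is a *stacking partner* when `d_j <= d_stack`,
`alpha_j <= alpha_max` and `omega_j <= omega_max`. The `omega` criterion is
what makes the contact face-on: a base touching the query edge-on can pass
the distance and coplanarity tests but sits near `omega = 90°`. Whether an
edge contact should have counted as "stacked" in a by-eye survey is
genuinely ambiguous; this package decides it in favour of face-on geometry
and records the thresholds in every output, so the decision is inspectable.

The call is then:

- **intercalated** — exactly two partners at consecutive mRNA positions and
  the query centroid lies *between* their planes (its signed projections
  onto the mean partner normal have opposite signs). The between-ness test
  uses the mean normal of the two partners, which tolerates partner-plane
  disagreement up to `alpha_max`.
- **stacked** — exactly one partner. Two partners at non-consecutive
  positions also yield `stacked` (on the nearer, flagged
  `nonconsecutive_partners`), because intercalation is by definition
  insertion between adjacent bases. A consecutive pair that fails
  between-ness is likewise stacked, flagged `partners_same_side`.
- **retracted** — no partner at all.
- **unresolved** — the query or the whole mRNA window lacks usable geometry.

Defaults are `d_stack = 4.5` Å, `alpha_max = 30°`, `omega_max = 40°`,
`d_retract = 6.0` Å — standard aromatic-stacking geometry ranges. The
original screen this codifies combined a centroid-distance scan with visual
inspection and printed no numeric cutoffs, so these values are declared
choices, not reproductions; every survey report embeds them, making any
count reproducible from the report alone. Partner ties within 0.01 Å
resolve deterministically toward the more 5′ position.

The mRNA is addressed in the standard register convention: position +1 is the
first base of the P-site codon, negative positions run 5′ (E-site side), and
there is no position 0. The register is anchored by locating the mRNA
triplet whose three bases each make a Watson–Crick-edge heavy-atom contact
within 3.5 Å (a canonical H-bond distance) of the anticodon bases 34–36 of
a tRNA, antiparallel. When several tRNAs qualify — chimeric states blur site
labels — the codon nearest the 5′ end is taken as the P codon; in rotated
intermediates where even that rule is doubtful, an explicit per-structure
`p_codon_start` override is the supported path. A structure whose register
cannot be anchored is reported `unresolved`, never silently guessed.

## The rotation model

Rotation is measured against a classical-state reference structure with one
phosphorus atom per residue (robust to base disorder) in three rigid
superpositions, each an SVD-based least-squares fit constrained to a proper
rotation:

1. the 23S rRNA core of the structure is superposed onto the reference,
   fixing the frame. The core excludes the mobile L1 stalk (residues
   2093–2196) and A-site finger (880–898);
2. the residual rotation of the 16S *body* atoms gives the intersubunit
   (body) angle;
3. after aligning body frames, the residual rotation of the 16S *head*
   (residues 930–1381, E. coli numbering) gives the head swivel — head
   rotation is measured relative to the body, not the 50S, which is the
   convention behind the state windows.

Angles come from the axis–angle (Euler–Rodrigues) decomposition
`theta = arccos((tr(R) - 1)/2)`, with the axis taken from the
skew-symmetric part and dedicated branches near 0° and 180° where that
expression degenerates. Angles are reported as unsigned magnitudes with a
sign flag relative to a user-declared forward axis, because the state
windows are magnitude windows.

The head/body boundary and the 23S core mask are the community-standard
choices, but they are deliberately configurable
(`domain_definition()`): published rotation values depend on the exact
masks, and reproducing a particular survey requires matching its masks, not
trusting defaults. If a structure lacks a 23S chain the body is used as the
frame (flagged); the body angle is then unmeasurable and is reported `NA`.

State assignment uses inclusive magnitude windows with precedence
chimeric-hybrid > hybrid > classical:

| state | window | default |
|---|---|---|
| chimeric-hybrid | head rotation | 15–21° |
| hybrid | body rotation | 6–10° |
| classical | body and head below | 3° / 6° |

Anything outside all windows — e.g. a 4° body rotation, which sits in the
gap between "non-rotated" and the hybrid window — is `unassigned` rather
than forced into a state. The classical bounds are declared values: the
source classification says only "non-rotated", so the 3°/6° caps are this
package's quantification of that phrase, stamped into outputs.

## The survey pipeline and the confidence filter

`run_survey()` maps each accession through read → chain identification →
register → contact call (A1503 against positions −6…+3; optionally C1397
against +6…+11) → rotation → state. Chains are identified by RNA length
(16S 1400–1700 residues, 23S 2700–3100, tRNA 55–110, mRNA < 200 and nearest
the decoding region), with explicit hints overriding everything; ambiguity
is an error listing candidates, not a guess. Per-structure failures produce
a failed record with a reason and never abort the batch, and identical
inputs yield byte-identical reports.

The original screen kept structures "in which the relative positions could
be placed with reasonable confidence, based on local resolution and/or map
quality" — a partly subjective, per-map judgement that a coordinates-only
pipeline cannot replay. The package substitutes a declared filter: reported
resolution ≤ 4.0 Å, at least five ring atoms at the query base and at each
mRNA position −4…+1, and a resolved register. Counts from this pipeline on
real depositions are therefore expected to *approximate* published ones,
with every inclusion decision auditable in `records.tsv`; exact
reproduction of a visually-curated set is explicitly not claimed.

Aggregation reports, per state, the total and the
intercalated/stacked/retracted counts and percentages plus the modal
intercalation position pair; unresolved contacts and unassigned states are
tallied separately so that `total = intercalated + stacked + retracted`
holds for every row. Percentages are kept at full precision internally and
rounded only in the written `table1.tsv`, where the convention is percent of
the row total rounded to integers.

## Synthetic fixtures: what they are and are not

Two generators make every stage testable without downloads, with truth
labels fixed by construction, never by the classifier under test.

**Contact scenes** build an idealised 8-base single-strand stack (planar
ring templates, rise 3.4 Å, optional twist) and insert an adenine query:
midway in a gap widened to twice the rise (intercalated), face-on under the
5′-terminal base (stacked), or displaced laterally beyond stacking range
(retracted). After optional isotropic Gaussian coordinate noise, the
construction margins — partner distances at least 0.5 Å inside `d_stack`,
non-partners 0.5 Å outside, partner plane/approach angles 5° inside the
angular cutoffs, retracted distances 0.5 Å beyond `d_retract` — are
re-checked from raw coordinates and the scene is resampled if violated. The
labels are therefore geometric guarantees, and 100% classifier agreement on
them is an oracle-equivalence check, not a statistical one.

**Rotated subunits** draw three uniform point clouds (16S body, 16S head,
23S core; one "phosphorus" per residue, ≥ 50 per domain), rotate the whole
16S about a declared intersubunit axis, then the head about an axis through
its centroid, optionally apply a random global rigid motion (so the frame
stage does real work), and add per-atom Gaussian noise. All full synthetic
ribosomes share one fixed cloud architecture — as real ribosomes share a
fold — so any of them can serve as the measurement reference for any other.

These fixtures emulate the *geometry* of the problem, not its biology: no
backbone connectivity, no base-pair constraints beyond the constructed
anticodon pairing, no correlated disorder, no partial occupancy, no
modelling bias from map fitting. Passing on them demonstrates that the
geometric computations are correct and noise-stable at the stated levels
(recovery within 0.01° noise-free and 0.5° at σ = 0.3 Å on 0–25°
injections; 100% label agreement with ≥ 0.5 Å margins). It does not
demonstrate that the thresholds match any particular curator's visual
judgement on real maps — that calibration is exactly what the embedded
threshold provenance in the reports is for.

Problem sizes in the shipped tests and acceptance script — 36 noise-free
grid points plus 200 noisy trials of 450–550-point subunits, 600 scenes,
a 25-structure survey batch — were chosen as the smallest sets that
exercise the full parameter ranges with stable statistics.

## Frameshift quantification

The assay translates a reporter mRNA carrying an internal Shine–Dalgarno
sequence and the slippery heptamer (GAAAAAAG variant); a -1 slip yields a
premature-termination product (16 kDa) alongside the full-length protein
(27 kDa). With [35S]-methionine labelling, band intensity is proportional
to the product amount times its methionine count, so intensities are
normalised by the number of *internal* methionines of each predicted
product before comparison. "Internal" excludes position 1 only: whether the
initiator (formyl)methionine is retained or cleaved, it is shared by both
products, and excluding just the initiator is the convention adopted and
documented here. `fs_products()` predicts both product sequences from the
mRNA (0-frame to the stop; -1 frame re-reading the last slippery base), so
methionine counts can be derived rather than typed in.

Per replicate, `percent = 100·fs/(fs + full)` and `ratio = fs/full`; the
identity `ratio = percent/(100 − percent)` holds exactly per replicate.
Replicate summaries are arithmetic means with SEM = sd/√N (N ≥ 2 required).
The mean of per-replicate ratios is *not* the ratio implied by the mean
percent — the package averages per-replicate values, and the test suite
carries a constructed counterexample so the distinction cannot regress.
Translation activity is the methionine-normalised total product as a
fraction of the control lane's total, matched within replicate. Background
subtraction is upstream of this module: inputs are assumed
background-corrected, since no subtraction scheme is part of the assay
definition. Display rounding (two decimals for ratios and activities, one
for percents) is applied only in `fs_format_table()`; full precision is
retained everywhere else.

## Numerical choices and degenerate inputs

- Superposition rejects fewer than three points or (near-)collinear sets
  (`riboframe_degenerate_fit`) instead of returning an ill-conditioned fit;
  the proper-rotation constraint (det = +1) is enforced via the standard
  sign correction of the SVD solution.
- `axis_angle()` validates orthogonality and determinant to 1e-6; near 0°
  the axis is undefined and reported as a fixed convention with θ = 0; near
  180° the axis is recovered from `(R + I)/2`, keeping reconstruction error
  below 1e-6. Self-measurement returns angles of ~1e-6 degrees, the
  precision floor of `arccos` near 1.
- Insertion codes are treated as distinct residues ordered after their base
  number; residues with insertion codes do not participate in the register.
- 16S numbering is assumed E. coli-aligned (true for most bacterial 70S
  depositions); a per-structure integer offset covers other numberings. No
  sequence alignment is performed — remapping by alignment is out of scope.
- File model selection happens before parsing; requesting a missing model
  is an explicit error, as is an unparseable file.

## Known limitations

- Chain identification is length-heuristic; unusual constructs (fused
  rRNAs, long reporter mRNAs) need explicit hints.
- The confidence filter sees coordinates only; it cannot use local
  resolution maps, so it is a declared proxy, not a re-implementation of
  per-map curation.
- Rotation values depend on the domain masks; comparisons across surveys
  require matching masks.
- The contact classifier is purely geometric — no stacking energetics, no
  solvent, no tertiary base-pair detection.
- The synthetic generators produce idealised geometry (see above); they
  validate the algorithms, not the thresholds' biological calibration.
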