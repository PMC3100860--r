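---
title: "Periodontal risk assessment: coding, classification and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Periodontal risk assessment: coding, classification and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, message=FALSE}
library(periorisk)
library(dplyr)
```

## The model

Periodontal risk assessment (PRA) models summarise a patient's risk of
(recurrent) periodontitis by scoring several clinical parameters on a common
0–5 axis scale and reading the resulting radar-chart polygon against
concentric low/moderate/high zones. `periorisk` implements two such models
over a single coding system:

* the eight-parameter **modified** model: bleeding on probing, deep pockets
  (>5 mm), tooth loss, smoking, attachment-loss/age ratio, glycemic
  (diabetic) status, dental-status–systemic-factors interplay, and a
  socioeconomic/stress background axis;
* the six-parameter **Lang–Tonetti (2003)** comparison model over the shared
  clinical axes.

The model is retrospective: it grades current risk burden from current and
historical findings, and makes no claim to predict future attachment loss.

## The coding system and its gap closure

Each scoring function is a banded lookup. The published bands have small
gaps between adjacent rows (e.g. BOP "<4" followed by "5–9", pocket counts
"7–8" followed by ">9"). We close each gap by treating a band's upper edge
as inclusive and extending it to the next band's floor, so the BOP bands
become 0, (0,4], (4,9], (9,16], (16,25], >25 and the count band ">9" is
read as ≥9. This keeps every printed anchor value on its printed score and
makes every lookup total, single-valued and monotone — properties the test
suite verifies by exhaustive integer sweeps (counts 0–40) and 0.01-step
grids over the continuous ranges.

Interpretive conventions, each isolated in one function so it can be
swapped:

* **BOP** is a percentage of bleeding sites (the Lang–Tonetti lineage uses
  percentages); "generalized bleeding on probing" is encoded as
  `bop_extent > 25`, i.e. axis score 5.
* **Diabetic status** bands (<102 … >133) are read as a glycemic
  measurement in mg/dL. The package accepts any consistently banded
  glycemic value; no HbA1c conversion is attempted. Values falling between
  the printed integer band edges (e.g. 109.5) take the lower band.
* **AL/age** is accepted as a precomputed ratio; when attachment loss and
  age are held separately their direct quotient is the input. The unit of
  the numerator is the caller's responsibility.
* **Background axis**: no coding table for socioeconomic status and stress
  was published. The package's convention maps Kuppuswamy class I–V to
  0–4 and adds 1 for a high-stress indicator, capped at 5: class is the
  dominant, slowly-varying determinant and stress a one-step modifier.
  Stress is folded into this axis (keeping eight parameters total) rather
  than given a ninth axis.
* **Dental–systemic interplay** is carried as its ordinal 0–5 code
  directly; deriving it from free-text history is out of scope.
* Record invariants: age in [30, 60] (the study inclusion window) and
  `teeth_lost <= 12`, i.e. at least 20 functional teeth against a 32-tooth
  baseline dentition (the exclusion criterion).

## Risk zones and the classification rules

Scores 0–1 lie in the low zone, 2–3 moderate, 4–5 high — the even
three-way split of the 0–5 scale, fixed in `risk_zone()` and drawn in the
diagram as annuli with boundaries at radii 1.5 and 3.5 so each integer
score sits strictly inside its zone.

The published rule table gives three clauses: low — "all parameters in low
risk areas, or at most 2 parameters in moderate and high risk area";
moderate — "3 in moderate one in high risk"; high — "2 parameters in high
risk category". As printed the clauses are neither exhaustive nor mutually
exclusive (a vector with exactly two high axes satisfies both the low and
the high clause). `periorisk` uses the deterministic completion with
precedence high ≻ low ≻ moderate: with $m$ moderate-zone and $h$ high-zone
axes,

$$\text{category} = \begin{cases}
\text{high} & h \ge 2\\
\text{low} & h < 2,\ m + h \le 2\\
\text{moderate} & \text{otherwise.}
\end{cases}$$

This honours every printed clause ("at most 2 in moderate and high" is read
as a bound on the combined count), is total and deterministic, and is
monotone: raising any single axis score never lowers the category. The
Lang–Tonetti rule is not reprinted alongside the modified model; the
package adopts the classic form of the cited model, identical except that
the low clause is $m + h \le 1$ (at most one axis outside the low zone).
Both are property-tested by enumeration — exhaustively over all $6^6$
six-axis vectors and all $6^8 \approx 1.68\times 10^6$ eight-axis vectors
(vectorised zone counting), with the classifier spot-checked against an
independently written plain-R oracle, plus monotonicity and
permutation-invariance checks on seeded random vectors.

## Polygon geometry

Axis $k$ of $n$ points at angle $2\pi k/n$ from vertical, proceeding
clockwise; the vertex sits at radius equal to the raw score (no offset),
and the closed polygon's area comes from the shoelace formula. A uniform
score $r$ gives the regular-polygon closed form $(n/2)r^2\sin(2\pi/n)$,
which the tests match to $10^{-6}$ relative; coordinate-wise monotonicity
is checked on $10^4$ seeded perturbation pairs. The published description
ties categories to "the area of polygon" but provides no thresholds or
normalisation, so the area is computed and reported as a diagnostic only;
categorisation uses the counting rules above. Note the area is
order-dependent in general, which is why each model fixes a canonical axis
order.

## The synthetic cohort generator

No per-patient data were published, so the generator emulates the
evaluated cohort's printed marginals and is the package's test bed. The
defaults are the study conditions: $n = 30$ diabetic adults aged 30–60,
all with generalized bleeding on probing; 12 current and 4 former smokers
(printed counts win over the printed percentages, which are inconsistent
with $n = 30$: 46% of 30 is not 12); 50% with deep pockets at 7–8 areas
(15 patients) and 35% at 5–6 areas (rounded to 10); 47% with attachment
loss of 3–5 mm and 10% above 5 mm, mapped onto the model's AL/age input as
14 patients in (0.25, 0.75] and 3 above 1 (an interpretive bridge: the
ratio, not raw millimetres, is the axis input); 35% with 7–8 missing teeth
(10 patients); socioeconomic status massed on Kuppuswamy classes IV and V
(weights 0.02/0.05/0.13/0.45/0.35). "Confirmed diabetics" is encoded as
glycemic values of at least 110 mg/dL — an established banded elevation
(axis score ≥ 2) rather than mere borderline values.

Mechanics: each banded marginal is met *exactly* by constructing the band
labels deterministically and shuffling them with the seeded RNG; values
within a band (BOP percent, glycemic value, within-band counts, ages) are
uniform draws over the band's valid range, rounded to the precision the
CSV carries so cohorts round-trip identically. Marginals are assigned
independently of one another — the source reports no joint structure, so
none is invented; the overlap between, say, the severe-attachment-loss and
high-pocket groups is whatever the seeded shuffle produces. Two marginals
are unstated and fixed once as package defaults: 40% high-stress
prevalence (psychosocial stress is common but not universal in such
outpatient cohorts) and dental–systemic codes drawn from 0–3 with weights
0.35/0.3/0.2/0.15 (most patients have at most general modifying problems;
the severe codes 4–5 describe states that would dominate the clinical
picture and are left to explicit configuration). The default seed is 42.
The generator is a pure function of its configuration: identical config
and seed give byte-identical CSV output, and the caller's RNG stream is
left undisturbed.

What passing tests on synthetic cohorts do **not** show: the generator
reproduces marginal counts, not the unpublished joint distribution, so the
published headline category splits (13/10/7 under the modified model,
20/5/5 under Lang–Tonetti) are not reproducible and are not targeted. The
pipeline instead validates the *shape* of that comparison — both
distributions always sum to the cohort size, and the cross-model
contingency margins agree with the per-model counts. Indeed, because every
default synthetic patient carries a high-zone BOP axis and a
moderate-or-worse glycemic axis, the default cohort classifies far more
pessimistically than the published one; that is a property of the stated
marginals under independent assignment, not a defect of the rules.

## Numerical and design choices

* Band edges are closed intervals on the printed anchors; scoring is by
  `findInterval`, so ties at an edge always take the lower band's score
  deterministically.
* Classification depends only on zone counts, hence is exactly integer
  arithmetic; there are no tolerances anywhere in the decision path.
* The SVG renderer writes plain SVG 1.1 text with fixed three-decimal
  coordinates and no timestamps, so rendering is byte-reproducible;
  rendering is a pure output stage and never alters classification state.
* Degenerate inputs: an all-zero vector is a zero-area polygon at the
  centre and classifies low; an empty cohort, duplicate patient ids, a
  current smoker without a cigarettes/day count, or any out-of-band value
  abort with the patient id, field and offending value (no silent drops).
* Enumeration sizes used by the test suite: exhaustive $6^6$ and $6^8$
  sweeps for the rules, 0.01-step grids for the continuous bands, $10^4$
  perturbation pairs for area monotonicity, and $10^5$ sampled eight-axis
  vectors in the acceptance-style checks.

## Limitations

* The background-axis coding and the generator's stress and
  dental–systemic defaults are package conventions, clearly isolated, not
  published facts.
* Pocket and attachment-loss inputs are site/area counts and a
  dimensionless ratio; the package does not model sextant-level CPI
  bookkeeping or probing technique.
* The models are retrospective classifiers; no prospective risk prediction
  or hypothesis testing between models is offered.
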