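---
title: "Detecting drug class effects on adverse events with PCR, C-PRR and class-level chi-squared"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting drug class effects on adverse events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeclass)
```

## The problem

Pharmacovigilance works mostly drug by drug, but many adverse events (AEs)
are properties of whole pharmacological classes: every
angiotensin-converting enzyme inhibitor is associated with cough, every
statin with myalgia. A drug **class effect** on an AE is the condition in
which *every* drug ingredient in a defined class — a chemical-ingredient
class or a mechanism-of-action (MoA) class in a reference terminology such
as NDF-RT — is associated with the same AE. Class effects matter clinically
(switching within a class will not avoid the AE) and mechanistically (they
point at the shared target or pathway).

This package scores candidate class effects from a curated drug–AE
association table (the kind of table produced by systematic curation of
package inserts) and two rooted is-a hierarchies: a drug classification
(ingredient classes or MoA classes, with ingredients as leaves) and an AE
ontology (OAE-like). Everything is computed at the **ingredient** level: an
ingredient is associated with an AE as soon as at least one marketed
product containing it reports the AE, because different dosage forms of one
ingredient report different AE profiles and any positive form establishes
the ingredient-level association (`collapse_to_ingredients()`).

## The statistics

For a drug class $C$ with members resolved through the classification
hierarchy and an AE $e$, the **proportional class level ratio** is

$$\mathrm{PCR}(C, e) \;=\; \frac{\#\{\text{ingredients in } C
\text{ associated with } e\}}{\#\{\text{ingredients in } C\}},$$

so $\mathrm{PCR} = 1$ is exactly the class-effect condition. A PCR of 1 in
a small class is weak evidence on its own, so three further criteria are
applied, adapted from classical spontaneous-report signal detection but
counting drug ingredients over a classification universe instead of case
reports. With the 2×2 table

|            | in class | out of class |
|------------|----------|--------------|
| has AE     | $a$      | $b$          |
| lacks AE   | $c$      | $d$          |

the class-level proportional reporting ratio is
$\mathrm{C\text{-}PRR} = \dfrac{a/(a+c)}{b/(b+d)}$ with the conventional
signal cutoff of 2, the class-level chi-squared statistic is Pearson's
$\chi^2$ on the same table with cutoff $>4$ (roughly $p<0.05$ on 1 df),
and a minimum of 3 ingredients in the class is required (the analogue of
minimal case-count filtering). `detect_class_effects()` reports all four
flags and their conjunction per (class, AE) pair.

The **universe** behind $b$ and $d$ is the set of ingredients mapped into
the classification scheme under analysis, not every drug ever curated —
ingredient-class and MoA analyses legitimately use different universes. It
is an explicit argument because an ingredient whose products report no AE
cannot appear in the association table at all (records are (product, AE)
pairs) yet still belongs in the denominator.

## Hierarchy propagation

AE associations are recorded at specific terms (e.g. *diarrhea*) but class
effects are often visible only at AE classes (e.g. *digestive system AE*).
`propagate_ae()` closes each ingredient's AE set upward through the AE
ontology with union semantics over multiple parents, so a pair can be
scored at any ontology level. Two numerical choices:

* the global AE root is excluded from propagation — a PCR against the
  universal root is 1 for every drug with any AE and carries no
  information;
* propagation only ever adds associations (monotone) and is idempotent,
  which the test suite asserts property-style.

Records lacking an AE ontology id are retained for product/AE counting and
`rank_top_aes()` but are excluded, with a logged count, from
hierarchy-propagated statistics.

## The PCR heatmap

`pcr_matrix()` evaluates PCR on a drug-class × AE-class grid and
`cluster_matrix()` orders both axes by agglomerative clustering (default
Euclidean distance, average linkage — both configurable; no authoritative
convention exists for this display, so the defaults are the most common
neutral choice). Leaf orders are made canonical by weight-reordering the
dendrograms with row/column means, so the ordering is invariant to how the
input rows were permuted. The exported TSV prints cells at full precision
(`%.17g`) and round-trips bit-exactly; the rendered image
(`plot_pcr_heatmap()`, via pheatmap) is presentation only. The AE-class
level for the columns is a deliberate explicit argument: different
ontologies put different semantics at "level 2", so the caller names the
AE class ids rather than the package inferring a depth.

## The synthetic generator

`generate_synthetic()` exists so every stage is testable without any
external download. It emulates the statistical structure of a real
curation: ingredients dealt into classes of configured sizes (overlap
allowed), a balanced AE ontology of configured depth, independent
background (ingredient, leaf AE) associations at rate `p_bg`, and
**planted class effects** — (class, leaf AE) pairs where every member is
made positive. Background associations are drawn at the ingredient level
and then attached to one randomly chosen product of the ingredient, the
direction the collapse rule undoes; planting at leaf AEs means detection
at ancestor AE classes genuinely exercises propagation.

Defaults mirror the scale of a real cardiovascular-drug curation: 180
ingredients in 36 classes of 5, 736 leaf AEs in a depth-3 ontology, 1–3
products per ingredient, and `p_bg = 0.03`, i.e. about 22 reported AEs per
ingredient — a typical package-insert AE count. What the generator does
*not* model: AE co-reporting correlation, class-AE confounding, unequal
class sizes, or curation noise. Passing tests therefore demonstrate the
statistical machinery is correct and calibrated under independence, not
that real spontaneous-report data meet those assumptions.

`estimate_operating_characteristics()` Monte-Carlos the filter: replicate
$r$ uses seed `seed + r`, and reports planted-pair recovery and the
false-positive rate over non-planted pairs with standard errors. At
`p_bg = 0` the significant set equals the planted set (for classes at or
above the minimum size) by construction; under noise the false-positive
rate stays below about 1% at the default cutoffs in the configurations the
test suite runs (for example 20 classes of 4 over 30 leaf AEs at
`p_bg = 0.3`). The suite uses problem sizes of tens of ingredients and
50–100 replicates, which characterises these rates to Monte-Carlo noise of
a few tenths of a percent.

## Degenerate inputs and tie-breaks

* `c_prr()`: $a = 0$ returns 0; $b = 0$ with $a > 0$ returns `Inf`, which
  *passes* the cutoff but is flagged `zero_background` in results —
  disproportionality is maximal, but the consumer should see the
  degeneracy. An empty class or empty background is an error; inside a
  full scan a class spanning the whole universe yields `NA` rather than
  aborting the other pairs.
* `c_chi2()`: a zero marginal returns 0 with a `degenerate` attribute.
  The default is uncorrected Pearson with a Yates flag
  (`class_effect_cutoffs(chi2_correction = TRUE)`); published analyses of
  this kind rarely state the variant, so both are first-class and results
  should quote which was used.
* Result rows are sorted by (class id, AE id); `rank_top_aes()` breaks
  count ties lexicographically by AE key.
* No multiplicity adjustment is applied beyond the three-criterion rule —
  pairs are scored independently even for overlapping classes — but
  `n_pairs_tested` is emitted so users can apply their own correction.

## A worked run

```{r example, message = FALSE, warning = FALSE}
cfg <- synthetic_config(
  n_ingredients = 40, class_sizes = rep(5L, 8), n_leaf_aes = 20,
  p_bg = 0.10, planted_effects = list(c(2L, 7L)), seed = 42)
g <- generate_synthetic(cfg)

res <- detect_class_effects(
  g$table, g$class_hierarchy, g$ae_hierarchy,
  class_ids = g$class_ids, ae_ids = g$leaf_ae_ids,
  universe = g$ingredients)
res[res$significant,
    c("class_id", "ae_id", "class_size", "a", "b", "pcr", "c_prr", "chi2")]
```

The planted pair is recovered; its C-PRR is the ratio between an in-class
AE rate of 1 and the background rate, and the chi-squared statistic is far
above the cutoff. The full pipeline (`run_pipeline()`) adds the clustered
PCR matrix, the heatmap, and a machine-readable run report.

## Known limitations

* Curation quality bounds everything: the statistics see only what the
  association table asserts, and package-insert AE sections are themselves
  heterogeneous.
* The chi-squared approximation is poor in the small cells typical of
  class-level counts; the cutoff of 4 is a convention, not a calibrated
  test, and the Yates variant can be materially smaller.
* `Inf` C-PRR (no out-of-class reporter of the AE) is common in small
  universes; treat `zero_background` rows with care.
* Class membership is resolved purely through the supplied hierarchy;
  errors or omissions in the classification propagate directly into the
  member sets and hence into every statistic.
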