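---
title: "Anatomic region alerting and terminology utility classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomic region alerting and terminology utility classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sanops)
```

## The problem

When a clinician orders a CT exam, a health-information-exchange (HIE) wide
alerting system can surface relevant prior imaging: the *same* exam (same
exam-name code, e.g. the same LOINC code), a *similar* exam (different code,
same body region — head CT with vs without contrast), or an anatomically
*proximate* exam (adjacent body region — a prior neck CT when a head CT is
ordered). Same-exam alerts only need exam-name standardization. Similar and
proximate alerts additionally need every exam mapped to body regions in some
anatomic terminology, and that terminology must actually connect the exam's
anatomic focus ("kidney", "temporal bone", "esophagus") to a body-region
concept. Real anatomic terminologies — FMA, SNOMED CT, RadLex, LOINC's
anatomic hierarchy, and the LOINC/RSNA Radiology Playbook — differ sharply
in whether and how they do this, which is what this package models and
measures.

## The SANOPS reference model

`sanops_regions()` defines 17 body regions: the midline chain head, neck,
chest, abdomen, pelvis (codes 1–5) and, for each of the four extremities,
proximal/mid/distal thirds split at the midshafts of the long bones (6a–6c,
7a–7c, 8a–8c, 9a–9c). The extremity thirds roughly correspond to the large
joints plus adjacent shaft; partitioning this way is what prevents a prior
right-foot CT (9c) from alerting on a right-hip CT order (9a).

`sanops_adjacency()` is the symmetric, irreflexive adjacency relation:
the midline path 1–2–3–4–5, girdle attachments (chest–6a, chest–7a,
pelvis–8a, pelvis–9a), and within-limb chains Xa–Xb–Xc. The source material
for this model states only examples (neck adjacent to head and chest; foot
*not* adjacent to hip), so the full table is a design decision of this
package: anatomic contiguity, no cross-limb adjacency, and no
proximal–distal shortcut. It ships as CSV data
(`inst/extdata/sanops/adjacency.csv`) and is overridable, so a deployment
wanting e.g. neck–7a adjacency can supply its own table without code
changes.

The alert rule (`alert_relation()`) has precedence same > similar >
proximate > none: *same* iff exam codes are equal; *similar* iff the region
assignments intersect (any shared region suffices — an abdomen+pelvis CT
and a lumbar-spine CT, both assigned {4, 5}, are similar); *proximate* iff
the assignments are disjoint but contain an adjacent pair.

## Terminology graphs and path semantics

A terminology is a typed directed graph over concepts, with five relation
types. Four are "rootward", asserted child/part → parent/whole: `is_a`,
`part_of`, `regional_part_of`, `constitutional_part_of`. The fifth,
`has_part`, is asserted whole → part ("leafward"). A connecting walk
(`find_paths()`) traverses every edge in its asserted direction only; this
single rule reproduces the structures that matter here:

* a uniform `is_a` or `part_of` chain from focus to region — the easy case
  expressible as a lookup table;
* a polyhierarchy where the focus *also* has rootward walks reaching a root
  while never visiting the region (`rootward_closure_avoiding()`) — the
  bypass case, where a naive ancestor query can come back with "skeletal
  system" instead of "head";
* a mixed-relation detour — in the FMA fixture, esophagus reaches chest
  only by going *down* a `has_part` edge to the thoracic esophagus and back
  *up* `part_of`, so every connecting walk mixes relation types.

The rootward subgraph must be acyclic (validated at load, with the cycle
reported); `has_part` may close directed cycles with `part_of`, so walk
enumeration is restricted to simple walks (no repeated concept), which
guarantees termination. The default walk-length bound `max_length = 15` is
far beyond the depth of any fixture (≤ 3) and exists to bound generated
graphs; results on the fixtures are identical for any bound ≥ 3.

## The utility scale

`classify()` scores one exam mapping in one terminology on an ordinal 1–5
scale — an approximation of how much machinery beyond a plain SANOPS lookup
the terminology needs before the alert can fire. Criteria are evaluated in
order, first match wins:

1. an attribute concept of the exam (body-region attribute, or the focus
   itself) carries a SANOPS correspondence marker — a region code, a
   `JOINT:` marker (major joints stand in for the extremity thirds), or a
   `WHOLE_EXTREMITY:` marker (expands to all three regions of the limb);
2. a uniform-relation walk connects the focus to the region concept, and no
   rootward walk bypasses it;
3. a uniform walk exists but bypassing rootward walks exist too;
4. the region is reachable only through mixed relation types;
5. the region is unreachable.

Three readings were genuinely open and are resolved as follows. First,
"nested directly under … via uniform relationships" (class 2) is read as a
uniform chain of *any* length with no bypass, not strictly one hop: the
contrast the scale draws between classes 2 and 3 is the bypass, and chain
length is never part of it. Second, the target region R is resolved from
the exam's named region(s) (carried on the mapping as `target_regions`)
via the correspondence table; when an exam names two regions, each is
scored and the *worst* class is reported (with per-region detail retained),
the conservative aggregate for a mapping evaluated as a whole. Third, a
region-grade attribute wins over a pathological focus path (criterion 1 is
checked first): the Playbook's sinus exam carries a "head" region-imaged
attribute and is class 1 even though its focus concept has no usable path.
When no attribute carries a marker *and* no named region resolves to a
marked concept, `classify()` raises a distinct "no target region" error
rather than guessing class 5: unreachability and unresolvability are
different defects.

Joint and whole-extremity markers are data in the correspondence table, not
inferred from labels — that "right knee" corresponds to the mid right lower
extremity is a modeling fact, not derivable from the graph.

`classify_oracle()` is a deliberately independent implementation of the
same criteria (igraph simple-path enumeration with parallel typed edges
expanded, no shared traversal code) used by the test suite; the two agree
on hundreds of generated graphs per run.

## The alert engine and the "unaltered state"

`resolve_regions(backend, code, max_class)` returns the SANOPS regions an
exam can reach at utility class ≤ `max_class`: marker-carried regions at
class 1, path-derived regions at their path class. `max_class = 1` is a
terminology's *unaltered state* — only region-grade information available
without extra computing steps; 2–3 model lookup-table remedies; 4 models a
custom traversal algorithm. Class-5 regions never resolve. An exam that
resolves to nothing yields alert `none` (a missed alert, not an error).
This threshold semantics makes the firing matrix of `run_scenarios()`
reproduce the seven-scenario narrative exactly at `max_class = 1`, and
gives the monotonicity property the tests verify: raising `max_class` never
shrinks a region set and never downgrades an alert.

`alert_history()` ranks one decision per prior exam by alert precedence,
ties broken most-recent-first. A lookback window is available but unlimited
by default — the alerting use case as modeled sets no time horizon.
Patient identity matching across sites is assumed done upstream (an HIE
concern, out of scope).

## Fixtures: encoded facts, deliberate absences

The six fixture bundles (`build_fixture()`) are *minimal*: they contain
exactly the concepts and edges needed to realize the cited structural facts
— every edge carries a provenance note, and the tests enforce one note per
edge. They are not excerpts of the real terminology releases; concept ids
are synthetic. Structural facts not stated in the source narrative are
simply absent, and absence reads as class 5 / no alert — which is exactly
how every blank cell of the firing matrix is explained. All exam codes are
flagged synthetic placeholders except Liver CT (24815-3), the one printed
code. The `sanops` fixture is the framework as its own backend (identity
correspondence); it fires an appropriate alert in all seven scenarios,
which is what makes it the reference defining "appropriate".

## Synthetic data: what it emulates, what it does not

`random_terminology()` plants exactly one of the five structural conditions
around a focus F and marked region R (chain lengths 1–3, relation sampled
from the palette, decoys wired so they cannot alter the planted class), so
generator intent is ground truth for classifier recovery; recovery is 100%
over 100 seeds × 5 classes and the construction makes that provable, not
lucky. An infeasible palette (class 4 without `has_part`) is an error.
`random_class_sample()` draws iid ordinal classes per terminology from
stated categorical distributions. Neither emulates: real terminology scale
(10⁴–10⁵ concepts), label semantics, SEP-triplet conventions beyond plain
`is_a` encoding, or correlation of classes across exams within one
terminology (real samples score the *same* 100 codes in all five
terminologies; the generator draws groups independently). A green
statistical test therefore establishes calibration and qualitative
behavior of the comparison machinery, not population values for any real
terminology.

Null-simulation distributions for the type-I-error checks use class
probabilities (0.40, 0.25, 0.15, 0.10, 0.10) — unimodal at class 1 with a
long tail, the shape the published descriptives suggest; the two-low /
three-high pattern simulations use means 1.45 and 2.35, inside the stated
1.4–1.5 and 2.2–2.6 bands. These were chosen once, before any measurement.

## Statistics

`describe_classes()` reports median, mode (ties broken toward the smaller
class — determinism; a tie never occurs in the reported data), mean, and
*sample* standard deviation (the printed "standard deviation of mean"
values, e.g. 1.85 at n = 100, are consistent with sample SD, not standard
error), plus Kruskal–Wallis mean ranks on pooled mid-ranks.
`kruskal_wallis()` uses the tie-corrected H with a χ² reference on k − 1
df; `wilcoxon_pairwise()` uses the two-sided normal approximation with
continuity and tie correction — appropriate for samples of ~100 heavily
tied ordinal values, where exact enumeration is pointless. **No
multiple-testing correction is applied**, mirroring the analysis being
reproduced; the report header says so. Exact published descriptive values
are *not* reproduced or asserted anywhere: they depend on 200 unpublished
HIE exam-code mappings, so the statistics module is accepted on calibration
and qualitative-pattern grounds only.

One acceptance check is knife-edge by construction and is left red rather
than adjusted: requiring the full significance pattern (six low-vs-high
pairs significant *and* the two identically distributed low groups not
significant) in ≥ 95% of 200 datasets sets the threshold exactly at the
expected success rate, since the low-vs-low comparison is falsely
significant with probability ≈ α = .05 per dataset. With the pre-chosen
fixed seeds the suite measures 189/200 = 0.945; every failure is that false
positive (power was 200/200). The decisions ledger carries the analysis.

## Numerical and degenerate-input choices

* Edge direction is the only traversal rule; there is no bidirectional
  search. A start concept that is itself a rootward root vacuously bypasses
  any forbidden concept other than itself.
* `find_paths(start, start)` returns no walks (a simple walk of length ≥ 1
  cannot return to its start); classify never hits this case because a
  focus equal to the marked region concept is class 1 by criterion order.
* Serialization is stable (concepts by id, edges by source/target/relation),
  so saved graphs are byte-comparable and CLI runs are byte-identical for
  identical invocations.
* Empty batches, empty prior histories, and all-`none` histories are valid
  inputs returning empty/complete results, never errors; per-row
  classification errors are collected, not fatal.
* The CLI config file is JSON (not YAML) — a deliberate substitution: the
  deployment environment carries no YAML parser, and config/flag layering
  semantics are unchanged.

## Known limitations

Fixtures encode cited structure only; they cannot answer questions about
the real terminologies beyond those facts. The utility scale is ordinal and
criterion-ordered: it does not grade *how many* bypassing paths exist or
their depth. Adjacency is binary; no dose accumulation, no modalities
beyond CT, no description-logic reasoning, and no parsing of native
OWL/RF2/LOINC release formats.
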