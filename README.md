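# sanops

Anatomic region alerting and terminology utility classification for prior
CT imaging.

## What this is for

Health information exchanges (HIEs) can reduce avoidable CT imaging by
alerting the ordering clinician when a relevant prior study exists anywhere
in the exchange — not just the **same** exam (identical exam-name code),
but a **similar** exam (different code, same body region) or an
anatomically **proximate** exam (adjacent body region). Same-exam alerts
need only exam-name standardization (e.g. LOINC); similar/proximate alerts
additionally need every exam mapped to body regions, and the anatomic
terminology doing that mapping must actually connect each exam's anatomic
focus to a body-region concept.

This package is for clinical informaticists evaluating whether an anatomic
terminology can support that use case. It provides:

* **SANOPS**, a 17-region anatomic framework (head, neck, chest, abdomen,
  pelvis, plus proximal/mid/distal thirds of each extremity) with a region
  adjacency relation and the same/similar/proximate alert rules;
* a typed-edge **terminology graph** model (`is_a`, `part_of`,
  `regional_part_of`, `constitutional_part_of` rootward; `has_part`
  leafward) with path enumeration and polyhierarchy bypass detection;
* an ordinal 1–5 **terminology utility classifier** scoring how much
  machinery beyond a plain SANOPS lookup a terminology needs for one exam
  mapping (1 = usable as-is … 5 = region unreachable);
* an **alert engine** deciding same/similar/proximate over exam pairs and
  histories at a chosen utility-class threshold (`max_class = 1` models a
  terminology's unaltered state);
* **fixture mini-terminologies** (FMA/SNOMED CT/RadLex/LOINC/Playbook
  style) encoding the structural facts behind seven reference alerting
  scenarios, plus random generators with planted utility classes;
* nonparametric **comparison statistics** (Kruskal–Wallis, pairwise
  Wilcoxon rank-sum, α = .05, no multiple-testing correction) over
  utility-class samples.

The model in brief: an exam pair with different codes gets alert
`similar` iff its region assignments intersect, `proximate` iff they are
disjoint but contain an adjacent pair, else `none`. The classifier's
criteria, evaluated in order: (1) an exam attribute carries a SANOPS
region/joint/whole-extremity marker; (2) a uniform-relation walk focus → R
exists and no rootward walk bypasses R; (3) a uniform walk exists but
bypassing walks exist too; (4) R reachable only via mixed relation types;
(5) R unreachable.

## Worked example

```r
library(sanops)

# Why FMA cannot fire an esophagus/chest alert unmodified:
fma <- build_fixture("fma")$backend
classify(fma$graph, fma$mappings[["X0010-2"]], fma$correspondence)
#> utility class 4: SANOPS region reachable only through mixed relation types
#>   witness: FMA:Esophagus -[has_part]-> FMA:ThoracicEsophagus -[part_of]-> FMA:Chest
```

Class 4 means the only route from esophagus to chest travels *down* a
`has_part` edge and back *up* `part_of` — a custom traversal, not a lookup.

```r
# SNOMED's sinus exam resolves to head only once a class-3 lookup is paid for:
snomed <- build_fixture("snomed")$backend
resolve_regions(snomed, "X0006-0", max_class = 1)   # character(0) -> no alert
resolve_regions(snomed, "X0006-0", max_class = 3)   # "1" (head)

# RadLex fires a similar alert for kidney-after-liver (both carry the
# abdomen body-region attribute):
decide_alert(build_fixture("radlex")$backend,
             exam_record("p1", "siteA", "X0008-6", "2016-02-01T09:00:00"),
             exam_record("p1", "siteB", "24815-3", "2016-01-10T14:00:00"))
#> [radlex] SIMILAR: current X0008-6 {4} vs prior 24815-3 {4} (max_class=1)
```

The seven-scenario firing matrix across all five terminology fixtures in
their unaltered state (`-` = no alert fires):

```r
run_scenarios()[, c("scenario", "loinc", "loinc_rsna", "radlex", "fma", "snomed")]
#>   scenario     loinc loinc_rsna    radlex       fma    snomed
#> 1        1   similar    similar   similar   similar   similar
#> 2        2 proximate  proximate proximate proximate proximate
#> 3        3 proximate  proximate proximate proximate proximate
#> 4        4         -    similar   similar         -         -
#> 5        5         -          -   similar         -         -
#> 6        6         -          -         -         -         -
#> 7        7         -          -         -         -         -
```

Rows 1–3 (head w/wo contrast; head/neck; bilateral elbow/right shoulder)
fire everywhere; row 4 (head / paranasal sinuses) fires only where "head"
is an exam attribute; row 5 (liver / kidney) only in RadLex; rows 6–7
(cervical spine / neck, esophagus / chest) fire nowhere unmodified.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "sanops-alert", package = "sanops"))')
Rscript "$CLI" scenarios --out matrix.csv
Rscript "$CLI" classify --backend fma --exam "Esophagus CT"
Rscript "$CLI" alert --backend radlex --current X0003-7 --priors priors.csv
Rscript "$CLI" compare --in classes.csv --alpha 0.05 --out report.csv
Rscript "$CLI" fixtures --name fma --out fma_mini.json
```

Subcommands accept `--config file.json` (flags override) and `--seed`.

## Layout

* `R/` — graph model (`terminology_graph.R`), SANOPS (`sanops_model.R`),
  classifier (`utility_classifier.R`), alert engine (`alert_engine.R`),
  fixtures (`fixtures.R`), generators (`generators.R`), statistics
  (`stats_compare.R`), CLI (`cli.R`)
* `inst/extdata/sanops/` — region and adjacency tables (CSV, overridable)
* `vignettes/anatomic-alerting.Rmd` — the methods vignette: model
  assumptions, design decisions, what the synthetic data does and does not
  establish, known limitations
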