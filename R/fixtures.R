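# Minimal fixture terminologies. Each fixture encodes only the structural
# facts the alerting scenarios and worked classification examples depend on
# (every edge carries a provenance note saying which fact it encodes);
# everything else is deliberately absent, and absence reads as utility class
# 5 / no alert. Concept ids are synthetic; they are not excerpts of the real
# FMA / SNOMED CT / RadLex / LOINC releases. All exam codes except Liver CT
# (24815-3, the one code printed in the source material) are synthetic
# placeholders in the X####-# format.

#' Names of the available fixture terminologies
#'
#' @return Character vector: the five standard-terminology fixtures plus the
#'   SANOPS reference itself.
#' @export
fixture_names <- function() {
  c("loinc", "loinc_rsna", "radlex", "fma", "snomed", "sanops")
}

# Shared exam roster: key, code, long name, SANOPS target regions.
.fixture_exam_defs <- function() {
  out <- data.frame(
    key = c("head_iv", "head_noiv", "neck", "chest", "elbow_bilat",
            "shoulder_r", "sinus", "liver", "kidney", "cspine", "esoph",
            "angio_abd", "abd_pelvis", "rknee", "neck_angio", "temporal"),
    code = c("X0001-1", "X0002-9", "X0003-7", "X0011-0", "X0004-5",
             "X0005-2", "X0006-0", "24815-3", "X0008-6", "X0009-4",
             "X0010-2", "X0012-8", "X0013-6", "X0014-4", "X0015-1",
             "X0016-9"),
    name = c("Head CT with IV contrast", "Head CT without IV contrast",
             "Neck CT without IV contrast", "Chest CT",
             "Elbow-bilateral CT without contrast",
             "Shoulder-right CT with IV contrast",
             "Paranasal sinuses CT without IV contrast", "Liver CT",
             "Kidney CT without and with IV contrast", "Cervical spine CT",
             "Esophagus CT", "CT angio abdomen", "Abdomen and Pelvis CT",
             "Right Knee CT", "Neck vessel CT angio", "Temporal bone CT"),
    regions = c("1", "1", "2", "3", "6b;7b", "7a", "1", "4", "4", "2", "3",
                "4", "4;5", "9b", "2", "1"),
    synthetic_code = c(rep(TRUE, 7), FALSE, rep(TRUE, 8)),
    stringsAsFactors = FALSE)
  out
}

#' The shared fixture exam roster
#'
#' The CT exams used across all fixtures: scenario exams plus the worked
#' classification examples. Codes flagged `synthetic_code` are placeholders
#' (only Liver CT carries its real printed code).
#'
#' @return `data.frame` with columns `key`, `code`, `name`, `regions`
#'   (semicolon-separated SANOPS codes), `synthetic_code`.
#' @export
fixture_exams <- function() .fixture_exam_defs()

# --- internal assembly helpers ---------------------------------------------

# concepts: named character vector short_name -> label.
# edges: data.frame(source, target, relation, note) in short names.
# joints: short names of the standard joint concepts (knee/elbows/shoulder).
# exam attrs: list key -> list(region =, focus =) in short names.
.assemble_fixture <- function(term, prefix, concepts, edges, markers, attrs) {
  qual <- function(x) paste0(prefix, ":", x)
  cdf <- data.frame(id = qual(names(concepts)), label = unname(concepts),
                    stringsAsFactors = FALSE)
  if (is.null(edges) || !nrow(edges)) {
    edf <- data.frame(source = character(), target = character(),
                      relation = character(), note = character(),
                      stringsAsFactors = FALSE)
  } else {
    edf <- data.frame(source = qual(edges$source), target = qual(edges$target),
                      relation = edges$relation, note = edges$note,
                      stringsAsFactors = FALSE)
  }
  graph <- terminology_graph(term, cdf, edf[, c("source", "target", "relation")])
  corr <- correspondence_table(data.frame(
    terminology = term, concept_id = qual(names(markers)),
    marker = unname(markers), stringsAsFactors = FALSE))
  defs <- .fixture_exam_defs()
  mappings <- list()
  for (i in seq_len(nrow(defs))) {
    key <- defs$key[i]
    a <- attrs[[key]]
    if (is.null(a)) next
    mappings[[defs$code[i]]] <- exam_mapping(
      exam_code = defs$code[i], exam_name = defs$name[i], terminology = term,
      region_attribute = if (!is.null(a$region)) qual(a$region),
      focus_attribute = if (!is.null(a$focus)) qual(a$focus),
      target_regions = strsplit(defs$regions[i], ";")[[1L]])
  }
  backend <- terminology_backend(graph, mappings, corr)
  structure(list(name = term, backend = backend, provenance = edf),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle '%s': %d concepts, %d edges, %d exam mappings>\n",
              x$name, nrow(x$backend$graph$concepts),
              nrow(x$backend$graph$edges), length(x$backend$mappings)))
  invisible(x)
}

# Region + joint concept roster common to the five standard fixtures
# (labels are overridden per terminology where naming style differs).
.std_markers <- function(region_names) {
  c(stats::setNames(c("1", "2", "3", "4", "5"), region_names),
    RightKnee = "JOINT:9b", LeftElbow = "JOINT:6b", RightElbow = "JOINT:7b",
    RightShoulder = "JOINT:7a")
}

.fixture_loinc <- function() {
  concepts <- c(
    Head = "Head", Neck = "Neck", Chest = "Chest", Abdomen = "Abdomen",
    Pelvis = "Pelvis", RightKnee = "Knee - right", LeftElbow = "Elbow - left",
    RightElbow = "Elbow - right", RightShoulder = "Shoulder - right",
    SkeletalSystem = "Skeletal system", ParanasalSinuses = "Paranasal sinuses",
    CervicalSpine = "Cervical spine", Liver = "Liver", Kidney = "Kidney",
    Esophagus = "Esophagus", AbdominalVessels = "Abdominal vessels",
    TemporalBone = "Temporal bone", NeckVessels = "Neck vessels")
  edges <- data.frame(stringsAsFactors = FALSE, rbind(
    c("ParanasalSinuses", "SkeletalSystem", "is_a",
      "paranasal sinuses nested under skeletal system, bypassing head (scenario 4)"),
    c("CervicalSpine", "SkeletalSystem", "is_a",
      "cervical spine nested skeletally; no link to neck (scenario 6)"),
    c("TemporalBone", "SkeletalSystem", "is_a",
      "temporal bone under skeletal system; no head link stated for LOINC"),
    c("Liver", "Abdomen", "is_a",
      "liver linked under abdomen (Abdomen>Liver system attribute; scenario 5)"),
    c("AbdominalVessels", "Abdomen", "is_a",
      "abdominal vessels nested directly under abdomen (class-2 worked example)")))
  names(edges) <- c("source", "target", "relation", "note")
  # LOINC's system attribute behaves like an anatomic focus, not a separate
  # body-region attribute, so every exam maps through `focus`.
  attrs <- list(
    head_iv = list(focus = "Head"), head_noiv = list(focus = "Head"),
    neck = list(focus = "Neck"), chest = list(focus = "Chest"),
    elbow_bilat = list(focus = c("LeftElbow", "RightElbow")),
    shoulder_r = list(focus = "RightShoulder"),
    sinus = list(focus = "ParanasalSinuses"), liver = list(focus = "Liver"),
    kidney = list(focus = "Kidney"), cspine = list(focus = "CervicalSpine"),
    esoph = list(focus = "Esophagus"), angio_abd = list(focus = "AbdominalVessels"),
    abd_pelvis = list(focus = c("Abdomen", "Pelvis")),
    rknee = list(focus = "RightKnee"), neck_angio = list(focus = "NeckVessels"),
    temporal = list(focus = "TemporalBone"))
  .assemble_fixture("loinc", "LOINC", concepts, edges,
                    .std_markers(c("Head", "Neck", "Chest", "Abdomen", "Pelvis")),
                    attrs)
}

.fixture_loinc_rsna <- function() {
  concepts <- c(
    Head = "Head", Neck = "Neck", Chest = "Chest", Abdomen = "Abdomen",
    Pelvis = "Pelvis", RightKnee = "Right knee", LeftElbow = "Left elbow",
    RightElbow = "Right elbow", RightShoulder = "Right shoulder",
    ParanasalSinuses = "Paranasal sinuses", CervicalSpine = "Cervical spine",
    Liver = "Liver", Kidney = "Kidney", Esophagus = "Esophagus",
    AbdominalVessels = "Abdominal vessels", TemporalBone = "Temporal bone",
    NeckVessels = "Neck vessels")
  edges <- data.frame(stringsAsFactors = FALSE, rbind(
    c("Liver", "Abdomen", "is_a",
      "liver linked to abdomen in the Playbook hierarchy (scenario 5: liver yes, kidney no)")))
  names(edges) <- c("source", "target", "relation", "note")
  attrs <- list(
    head_iv = list(region = "Head"), head_noiv = list(region = "Head"),
    neck = list(region = "Neck"), chest = list(region = "Chest"),
    elbow_bilat = list(focus = c("LeftElbow", "RightElbow")),
    shoulder_r = list(focus = "RightShoulder"),
    # scenario 4: head is the region-imaged attribute of the sinus exam
    sinus = list(region = "Head", focus = "ParanasalSinuses"),
    liver = list(focus = "Liver"), kidney = list(focus = "Kidney"),
    # scenario 6: the region attribute is cervical spine, not neck
    cspine = list(region = "CervicalSpine", focus = "CervicalSpine"),
    esoph = list(focus = "Esophagus"),
    angio_abd = list(region = "Abdomen", focus = "AbdominalVessels"),
    abd_pelvis = list(region = c("Abdomen", "Pelvis")),
    rknee = list(focus = "RightKnee"),
    # class-1 worked example: neck specified as region attribute
    neck_angio = list(region = "Neck", focus = "NeckVessels"),
    temporal = list(focus = "TemporalBone"))
  .assemble_fixture("loinc_rsna", "PLAYBOOK", concepts, edges,
                    .std_markers(c("Head", "Neck", "Chest", "Abdomen", "Pelvis")),
                    attrs)
}

.fixture_radlex <- function() {
  concepts <- c(
    Head = "Head", Neck = "Neck", Chest = "Chest", Abdomen = "Abdomen",
    Pelvis = "Pelvis", RightKnee = "Right knee", LeftElbow = "Left elbow",
    RightElbow = "Right elbow", RightShoulder = "Right shoulder",
    ParanasalSinuses = "Paranasal sinus", CervicalSpine = "Cervical spine",
    Liver = "Liver", Kidney = "Kidney", Esophagus = "Esophagus",
    AbdominalVessels = "Abdominal vasculature", TemporalBone = "Temporal bone",
    NeckVessels = "Neck vasculature")
  edges <- NULL  # every RadLex fact used is an exam attribute, not an edge
  attrs <- list(
    head_iv = list(region = "Head"), head_noiv = list(region = "Head"),
    neck = list(region = "Neck"), chest = list(region = "Chest"),
    elbow_bilat = list(focus = c("LeftElbow", "RightElbow")),
    shoulder_r = list(focus = "RightShoulder"),
    # scenario 4: head is the body-region attribute of the sinus exam
    sinus = list(region = "Head", focus = "ParanasalSinuses"),
    # scenario 5: abdomen is the body-region attribute of BOTH liver and kidney
    liver = list(region = "Abdomen", focus = "Liver"),
    kidney = list(region = "Abdomen", focus = "Kidney"),
    cspine = list(region = "CervicalSpine", focus = "CervicalSpine"),
    esoph = list(focus = "Esophagus"),
    angio_abd = list(region = "Abdomen", focus = "AbdominalVessels"),
    abd_pelvis = list(region = c("Abdomen", "Pelvis")),
    rknee = list(focus = "RightKnee"),
    neck_angio = list(region = "Neck", focus = "NeckVessels"),
    temporal = list(focus = "TemporalBone"))
  .assemble_fixture("radlex", "RADLEX", concepts, edges,
                    .std_markers(c("Head", "Neck", "Chest", "Abdomen", "Pelvis")),
                    attrs)
}

.fixture_fma <- function() {
  concepts <- c(
    Head = "Head", Neck = "Neck", Chest = "Chest", Abdomen = "Abdomen",
    Pelvis = "Pelvis", RightKnee = "Right knee", LeftElbow = "Left elbow",
    RightElbow = "Right elbow", RightShoulder = "Right shoulder",
    ParanasalSinuses = "Paranasal sinus", AnatomicSpaces = "Anatomical spaces",
    CervicalSpine = "Cervical vertebral column",
    VertebralColumn = "Vertebral column", Liver = "Liver", Kidney = "Kidney",
    Esophagus = "Esophagus", ThoracicEsophagus = "Thoracic part of esophagus",
    AbdominalVessels = "Abdominal vasculature", TemporalBone = "Temporal bone",
    NeckVessels = "Vasculature of neck")
  edges <- data.frame(stringsAsFactors = FALSE, rbind(
    c("ParanasalSinuses", "AnatomicSpaces", "is_a",
      "paranasal sinuses nested under anatomic spaces, bypassing head (scenario 4)"),
    c("Liver", "Abdomen", "part_of",
      "liver related to abdomen by homogeneous part_of (scenario 5: liver yes, kidney no)"),
    c("CervicalSpine", "Neck", "regional_part_of",
      "cervical spine linked to neck region (scenario 6: link exists ...)"),
    c("CervicalSpine", "VertebralColumn", "regional_part_of",
      "... but alternative partonomy path bypasses neck (scenario 6)"),
    c("Esophagus", "ThoracicEsophagus", "has_part",
      "reaching chest requires traveling down has_part to thoracic esophagus (class-4 example)"),
    c("ThoracicEsophagus", "Chest", "part_of",
      "... and back through part_of to arrive at chest (class-4 example)")))
  names(edges) <- c("source", "target", "relation", "note")
  attrs <- list(
    head_iv = list(focus = "Head"), head_noiv = list(focus = "Head"),
    neck = list(focus = "Neck"), chest = list(focus = "Chest"),
    elbow_bilat = list(focus = c("LeftElbow", "RightElbow")),
    shoulder_r = list(focus = "RightShoulder"),
    sinus = list(focus = "ParanasalSinuses"), liver = list(focus = "Liver"),
    kidney = list(focus = "Kidney"), cspine = list(focus = "CervicalSpine"),
    esoph = list(focus = "Esophagus"), angio_abd = list(focus = "AbdominalVessels"),
    abd_pelvis = list(focus = c("Abdomen", "Pelvis")),
    rknee = list(focus = "RightKnee"), neck_angio = list(focus = "NeckVessels"),
    temporal = list(focus = "TemporalBone"))
  .assemble_fixture("fma", "FMA", concepts, edges,
                    .std_markers(c("Head", "Neck", "Chest", "Abdomen", "Pelvis")),
                    attrs)
}

.fixture_snomed <- function() {
  concepts <- c(
    Head = "Head structure", HeadPart = "Head part", Neck = "Neck structure",
    Chest = "Thoracic structure", Abdomen = "Abdominal structure",
    Pelvis = "Pelvic structure", RightKnee = "Structure of right knee",
    LeftElbow = "Structure of left elbow",
    RightElbow = "Structure of right elbow",
    RightShoulder = "Structure of right shoulder",
    SkeletalSystem = "Skeletal system structure",
    DigestiveSystem = "Digestive system structure",
    UrinarySystem = "Urinary system structure",
    VertebralColumn = "Vertebral column structure",
    ParanasalSinuses = "Paranasal sinus structure",
    CervicalSpine = "Cervical spine structure", Liver = "Liver structure",
    Kidney = "Kidney structure", Esophagus = "Esophageal structure",
    TemporalBone = "Temporal bone structure",
    AbdominalVessels = "Abdominal vascular structure",
    NeckVessels = "Neck vascular structure")
  # SEP-style modeling: partonomy expressed via is_a through "part" concepts.
  edges <- data.frame(stringsAsFactors = FALSE, rbind(
    c("TemporalBone", "HeadPart", "is_a",
      "temporal bone reaches head through uniform is_a (SEP; class-3 example)"),
    c("HeadPart", "Head", "is_a",
      "SEP triplet: head part is_a head structure"),
    c("TemporalBone", "SkeletalSystem", "is_a",
      "... but other is_a paths link to the skeletal system, bypassing head (class-3 example)"),
    c("ParanasalSinuses", "HeadPart", "is_a",
      "paranasal sinuses nested under head in some hierarchies (scenario 4)"),
    c("ParanasalSinuses", "SkeletalSystem", "is_a",
      "... but bypass head in others (scenario 4)"),
    c("Liver", "Abdomen", "is_a",
      "liver linked to abdomen (scenario 5)"),
    c("Liver", "DigestiveSystem", "is_a",
      "... with divergent links bypassing abdomen (scenario 5)"),
    c("Kidney", "Abdomen", "is_a",
      "kidney linked to abdomen (scenario 5)"),
    c("Kidney", "UrinarySystem", "is_a",
      "... with divergent links bypassing abdomen (scenario 5)"),
    c("CervicalSpine", "Neck", "is_a",
      "cervical spine linked to neck (scenario 6)"),
    c("CervicalSpine", "VertebralColumn", "is_a",
      "... plus links bypassing neck (scenario 6)"),
    c("Esophagus", "Chest", "is_a",
      "esophagus linked to chest (scenario 7)"),
    c("Esophagus", "DigestiveSystem", "is_a",
      "... plus edge links bypassing chest (scenario 7)")))
  names(edges) <- c("source", "target", "relation", "note")
  attrs <- list(
    head_iv = list(focus = "Head"), head_noiv = list(focus = "Head"),
    neck = list(focus = "Neck"), chest = list(focus = "Chest"),
    elbow_bilat = list(focus = c("LeftElbow", "RightElbow")),
    shoulder_r = list(focus = "RightShoulder"),
    sinus = list(focus = "ParanasalSinuses"), liver = list(focus = "Liver"),
    kidney = list(focus = "Kidney"), cspine = list(focus = "CervicalSpine"),
    esoph = list(focus = "Esophagus"), angio_abd = list(focus = "AbdominalVessels"),
    abd_pelvis = list(focus = c("Abdomen", "Pelvis")),
    rknee = list(focus = "RightKnee"), neck_angio = list(focus = "NeckVessels"),
    temporal = list(focus = "TemporalBone"))
  .assemble_fixture("snomed", "SNOMED", concepts, edges,
                    .std_markers(c("Head", "Neck", "Chest", "Abdomen", "Pelvis")),
                    attrs)
}

.fixture_sanops <- function() {
  reg <- sanops_regions()
  concepts <- stats::setNames(reg$label, reg$code)
  markers <- stats::setNames(reg$code, reg$code)  # identity correspondence
  defs <- .fixture_exam_defs()
  attrs <- stats::setNames(lapply(seq_len(nrow(defs)), function(i) {
    list(focus = strsplit(defs$regions[i], ";")[[1L]])
  }), defs$key)
  .assemble_fixture("sanops", "SANOPS", concepts, NULL, markers, attrs)
}

#' Build a fixture terminology bundle
#'
#' Each bundle contains the terminology graph, the exam mappings for the
#' full fixture exam roster, the SANOPS correspondence table, and a per-edge
#' provenance table stating which structural fact the edge encodes.
#'
#' @param name One of [fixture_names()].
#' @return A `fixture_bundle`: list with `name`, `backend`
#'   (a [terminology_backend()]), `provenance` (`data.frame` with one row
#'   per graph edge and a `note` column).
#' @export
build_fixture <- function(name) {
  switch(match.arg(name, fixture_names()),
         loinc = .fixture_loinc(),
         loinc_rsna = .fixture_loinc_rsna(),
         radlex = .fixture_radlex(),
         fma = .fixture_fma(),
         snomed = .fixture_snomed(),
         sanops = .fixture_sanops())
}

#' The seven hypothetical alerting scenarios
#'
#' Exam pairs for which a similar or proximate alert should be issued on
#' anatomic grounds, with the expected firing pattern per terminology in its
#' unaltered state: scenarios 1-3 fire everywhere, scenario 4 fires only for
#' the Playbook and RadLex (similar), scenario 5 only for RadLex (similar),
#' scenarios 6-7 nowhere. `type` is the appropriate alert type where stated
#' (`NA` for the never-firing rows).
#'
#' @return `data.frame` with columns `scenario`, `prior_code`, `prior_name`,
#'   `current_code`, `current_name`, the five expected-firing logical
#'   columns `loinc`, `loinc_rsna`, `radlex`, `fma`, `snomed`, and `type`.
#' @export
scenario_table <- function() {
  defs <- .fixture_exam_defs()
  code <- function(k) defs$code[defs$key == k]
  nm <- function(k) defs$name[defs$key == k]
  pairs <- rbind(
    data.frame(scenario = 1L, prior = "head_iv", current = "head_noiv",
               type = "similar"),
    data.frame(scenario = 2L, prior = "head_iv", current = "neck",
               type = "proximate"),
    data.frame(scenario = 3L, prior = "elbow_bilat", current = "shoulder_r",
               type = "proximate"),
    data.frame(scenario = 4L, prior = "head_iv", current = "sinus",
               type = "similar"),
    data.frame(scenario = 5L, prior = "liver", current = "kidney",
               type = "similar"),
    data.frame(scenario = 6L, prior = "cspine", current = "neck",
               type = NA_character_),
    data.frame(scenario = 7L, prior = "esoph", current = "chest",
               type = NA_character_))
  fired <- rbind(
    c(TRUE, TRUE, TRUE, TRUE, TRUE),
    c(TRUE, TRUE, TRUE, TRUE, TRUE),
    c(TRUE, TRUE, TRUE, TRUE, TRUE),
    c(FALSE, TRUE, TRUE, FALSE, FALSE),
    c(FALSE, FALSE, TRUE, FALSE, FALSE),
    c(FALSE, FALSE, FALSE, FALSE, FALSE),
    c(FALSE, FALSE, FALSE, FALSE, FALSE))
  colnames(fired) <- c("loinc", "loinc_rsna", "radlex", "fma", "snomed")
  out <- data.frame(scenario = pairs$scenario,
                    prior_code = vapply(pairs$prior, code, character(1)),
                    prior_name = vapply(pairs$prior, nm, character(1)),
                    current_code = vapply(pairs$current, code, character(1)),
                    current_name = vapply(pairs$current, nm, character(1)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(fired), type = pairs$type)
  rownames(out) <- NULL
  out
}
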