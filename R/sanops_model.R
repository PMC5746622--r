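# The SANOPS framework: 17 body regions, the region adjacency relation, and
# the same/similar/proximate alert rules defined over region assignments.

#' Alert classes, in precedence order
#'
#' `same` means the two exams carry the identical exam-name code; `similar`
#' means different codes whose anatomic assignments share at least one body
#' region; `proximate` means disjoint assignments with at least one adjacent
#' region pair; `none` means no alert.
#'
#' @return `c("same", "similar", "proximate", "none")`, strongest first.
#' @export
alert_classes <- function() c("same", "similar", "proximate", "none")

.sanops_extdata <- function(file) {
  system.file("extdata", "sanops", file, package = "sanops", mustWork = TRUE)
}

#' The 17 SANOPS body regions
#'
#' SANOPS divides the body into five midline regions (head, neck, chest,
#' abdomen, pelvis; codes 1-5) and, per extremity, proximal/mid/distal
#' thirds separated at the midshafts of the long bones (codes 6a-6c left
#' upper, 7a-7c right upper, 8a-8c left lower, 9a-9c right lower). The
#' extremity thirds roughly correspond to the large joints plus adjacent
#' shaft, which is what keeps a foot CT from alerting on a hip CT order.
#'
#' @param path Optional override: a CSV with columns `code`, `label`.
#' @return `data.frame` with columns `code`, `label`, in code order.
#' @export
sanops_regions <- function(path = NULL) {
  if (is.null(path)) path <- .sanops_extdata("regions.csv")
  reg <- utils::read.csv(path, colClasses = "character")
  stopifnot(all(c("code", "label") %in% names(reg)))
  if (anyDuplicated(reg$code)) stop("duplicate region codes", call. = FALSE)
  reg[order(match(reg$code, reg$code)), c("code", "label")]
}

#' The SANOPS region adjacency table
#'
#' Symmetric, irreflexive adjacency between body regions: the midline chain
#' head-neck-chest-abdomen-pelvis, the girdle attachments (chest to each
#' proximal upper-extremity region, pelvis to each proximal lower-extremity
#' region), and the within-limb chains proximal-mid-distal. There is no
#' cross-limb adjacency and, deliberately, no proximal-distal shortcut
#' within a limb. The table is data, not code, and can be overridden.
#'
#' @param path Optional override: a CSV with columns `code_a`, `code_b`
#'   (one row per unordered pair).
#' @param regions Region table the pairs must draw codes from.
#' @return An object of class `sanops_adjacency`: a `data.frame` of
#'   unordered pairs with both orientations expanded.
#' @export
sanops_adjacency <- function(path = NULL, regions = sanops_regions()) {
  if (is.null(path)) path <- .sanops_extdata("adjacency.csv")
  adj <- utils::read.csv(path, colClasses = "character")
  stopifnot(all(c("code_a", "code_b") %in% names(adj)))
  bad <- setdiff(c(adj$code_a, adj$code_b), regions$code)
  if (length(bad)) {
    stop("adjacency references unknown region code(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  if (any(adj$code_a == adj$code_b)) {
    stop("adjacency must be irreflexive", call. = FALSE)
  }
  both <- rbind(adj[, c("code_a", "code_b")],
                data.frame(code_a = adj$code_b, code_b = adj$code_a))
  both <- both[!duplicated(both), , drop = FALSE]
  rownames(both) <- NULL
  structure(both, class = c("sanops_adjacency", "data.frame"))
}

#' Are two SANOPS regions adjacent?
#'
#' @param table A `sanops_adjacency` table.
#' @param a,b Region codes.
#' @return `TRUE` or `FALSE` (`FALSE` when `a == b`; adjacency is
#'   irreflexive).
#' @export
regions_adjacent <- function(table, a, b) {
  stopifnot(inherits(table, "sanops_adjacency"))
  any(table$code_a == a & table$code_b == b)
}

#' Region codes of a whole extremity
#'
#' @param limb One of `"LUE"`, `"RUE"`, `"LLE"`, `"RLE"` (left/right,
#'   upper/lower extremity).
#' @return The three region codes of that limb, proximal to distal.
#' @export
limb_regions <- function(limb) {
  prefix <- unname(c(LUE = "6", RUE = "7", LLE = "8", RLE = "9")[toupper(limb)])
  if (is.na(prefix)) stop("unknown limb: ", limb, call. = FALSE)
  paste0(prefix, c("a", "b", "c"))
}

.check_region_codes <- function(codes, regions = sanops_regions()) {
  bad <- setdiff(codes, regions$code)
  if (length(bad)) {
    stop("unknown SANOPS region code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(codes)
}

#' Alert relation between two region assignments
#'
#' The core SANOPS alert rule. Given the body-region assignments of two
#' exams: the alert is `same` when the exam codes are identical; otherwise
#' `similar` when the assignments share at least one region ("mapped to the
#' same body regions"); otherwise `proximate` when some region of one is
#' adjacent to some region of the other; otherwise `none`. Exams spanning
#' several regions carry multi-region assignments, so an abdomen+pelvis exam
#' and a lumbar spine exam (both assigned `{4, 5}`) are similar.
#'
#' @param regions_a,regions_b Non-empty character vectors of region codes.
#' @param same_code `TRUE` when both exams map to the identical exam-name
#'   terminology code.
#' @param table Adjacency table (default [sanops_adjacency()]).
#' @return One of [alert_classes()]. Symmetric in its two assignments for
#'   non-`same` outcomes.
#' @export
alert_relation <- function(regions_a, regions_b, same_code,
                           table = sanops_adjacency()) {
  if (length(regions_a) == 0L || length(regions_b) == 0L) {
    stop("region assignments must be non-empty", call. = FALSE)
  }
  .check_region_codes(c(regions_a, regions_b))
  if (isTRUE(same_code)) return("same")
  if (length(intersect(regions_a, regions_b))) return("similar")
  for (r in regions_a) {
    for (s in regions_b) {
      if (regions_adjacent(table, r, s)) return("proximate")
    }
  }
  "none"
}
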