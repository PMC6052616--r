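# Machine-readable TRIPOD checklist: items, elements, applicability,
# conditionality, and the applicability queries everything downstream uses.

STUDY_TYPES <- c(
  "development", "external_validation",
  "incremental_value", "development_and_validation"
)

JUDGEMENT_LEVELS <- c(
  "reported", "not_reported", "not_applicable", "reported_by_reference"
)

#' Study types of prediction model studies
#'
#' The four study types a model extraction can carry: development of a new
#' model, external validation of an existing model, incremental value of
#' adding a predictor to an existing model, and combined development and
#' external validation of the same model.
#'
#' @return character vector of the four study-type labels.
#' @export
study_types <- function() STUDY_TYPES

# ---- construction & validation ---------------------------------------------

#' Construct a checklist object
#'
#' Builds a `tripod_checklist` from a list of item records. Used by
#' [load_checklist()] and by tests that need miniature checklists; most users
#' want [tripod_checklist()], the bundled default.
#'
#' @param version version string of the definition.
#' @param items list of item records. Each record is a list with fields
#'   `item_id`, `main_item`, `applicability` (one of `"D"`, `"V"`, `"DV"`),
#'   `conditional`, `reference_acceptable`, `excluded_from_scores`,
#'   `either_type_suffices` (logicals) and `elements`, an ordered list of
#'   `list(id =, description =)` pairs.
#' @param incremental_value_excluded item ids structurally inapplicable to
#'   incremental-value studies (default item 17).
#' @param partial_applicability named list (by study type) of item ids whose
#'   applicability is decided per record by an explicit flag even though they
#'   are not "if done" items (e.g. 10c, 12, 19a for incremental value).
#' @param strict if `TRUE`, enforce the full TRIPOD structure (exactly the 37
#'   canonical subitems with their annotations); if `FALSE`, only generic
#'   consistency (unique ids, >= 1 element each). Miniature test checklists
#'   use `strict = FALSE`.
#' @return object of class `tripod_checklist`.
#' @export
new_checklist <- function(version, items,
                          incremental_value_excluded = character(),
                          partial_applicability = list(),
                          strict = TRUE) {
  cl <- structure(
    list(
      version = version,
      incremental_value_excluded = incremental_value_excluded,
      partial_applicability = partial_applicability,
      items = items
    ),
    class = "tripod_checklist"
  )
  problems <- validate_checklist(cl, strict = strict)
  if (length(problems) > 0) {
    stop_tripod(
      paste0("invalid checklist definition:\n", paste("-", problems, collapse = "\n")),
      "tripod_checklist_error"
    )
  }
  cl$element_table <- build_element_table(cl)
  cl
}

# The canonical TRIPOD structure (Box 1 of the statement): 22 main items,
# items 3,4,6,7,14,15,19 split in two, 5 and 13 in three, 10 in five.
tripod_structure <- function() {
  list(
    item_ids = c(
      "1", "2", "3a", "3b", "4a", "4b", "5a", "5b", "5c", "6a", "6b",
      "7a", "7b", "8", "9", "10a", "10b", "10c", "10d", "10e", "11", "12",
      "13a", "13b", "13c", "14a", "14b", "15a", "15b", "16", "17", "18",
      "19a", "19b", "20", "21", "22"
    ),
    development_only = c("10a", "10b", "14a", "14b", "15a", "15b"),
    validation_only = c("10c", "10e", "12", "13c", "17", "19a"),
    conditional = c("5c", "10e", "11", "14b", "17"),
    reference_acceptable = c("4b", "5a", "6a", "7a"),
    excluded_from_scores = "21",
    either_type_suffices = c("3a", "18", "19a", "19b", "20"),
    element_counts = c("1" = 4L, "2" = 12L, "4b" = 3L)
  )
}

validate_checklist <- function(cl, strict = TRUE) {
  problems <- character()
  items <- cl$items
  ids <- vapply(items, function(it) as.character(it$item_id %||% NA_character_), "")
  if (anyNA(ids)) problems <- c(problems, "every item needs an item_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    problems <- c(problems, paste0("duplicate item_id: ", paste(dup, collapse = ", ")))
  }
  for (it in items) {
    id <- as.character(it$item_id)
    if (!is.list(it$elements) || length(it$elements) < 1) {
      problems <- c(problems, paste0("item ", id, " has no elements"))
    }
    if (!(it$applicability %in% c("D", "V", "DV"))) {
      problems <- c(problems, paste0("item ", id, ": applicability must be D, V or DV"))
    }
    for (fld in c("conditional", "reference_acceptable", "excluded_from_scores",
                  "either_type_suffices")) {
      if (!is.logical(it[[fld]]) || length(it[[fld]]) != 1 || is.na(it[[fld]])) {
        problems <- c(problems, paste0("item ", id, ": ", fld, " must be TRUE/FALSE"))
      }
    }
  }
  el_ids <- unlist(lapply(items, function(it) {
    vapply(it$elements, function(e) as.character(e$id %||% NA_character_), "")
  }))
  dup_el <- unique(el_ids[duplicated(el_ids)])
  if (length(dup_el) > 0) {
    problems <- c(problems, paste0("duplicate element id: ", paste(dup_el, collapse = ", ")))
  }
  if (length(problems) > 0 || !strict) return(problems)

  ts <- tripod_structure()
  extra <- setdiff(ids, ts$item_ids)
  missing <- setdiff(ts$item_ids, ids)
  if (length(extra) > 0) {
    problems <- c(problems, paste0("unknown TRIPOD item: ", paste(extra, collapse = ", ")))
  }
  if (length(missing) > 0) {
    problems <- c(problems, paste0("missing TRIPOD item: ", paste(missing, collapse = ", ")))
  }
  if (length(problems) > 0) return(problems)

  flag_sets <- list(
    conditional = ts$conditional,
    reference_acceptable = ts$reference_acceptable,
    excluded_from_scores = ts$excluded_from_scores,
    either_type_suffices = ts$either_type_suffices
  )
  for (it in items) {
    id <- as.character(it$item_id)
    expected_app <- if (id %in% ts$development_only) "D"
      else if (id %in% ts$validation_only) "V" else "DV"
    if (it$applicability != expected_app) {
      problems <- c(problems, paste0("item ", id, ": applicability must be ", expected_app))
    }
    for (fld in names(flag_sets)) {
      want <- id %in% flag_sets[[fld]]
      if (!identical(it[[fld]], want)) {
        problems <- c(problems, paste0("item ", id, ": ", fld, " must be ", want))
      }
    }
    if (id %in% names(ts$element_counts) &&
        length(it$elements) != ts$element_counts[[id]]) {
      problems <- c(problems, paste0(
        "item ", id, " must have ", ts$element_counts[[id]], " elements"
      ))
    }
    if (!identical(as.integer(it$main_item), main_item_of(id))) {
      problems <- c(problems, paste0("item ", id, ": main_item inconsistent with item_id"))
    }
  }
  problems
}

main_item_of <- function(item_id) as.integer(sub("[a-z]+$", "", item_id))

# ---- default definition ----------------------------------------------------

the <- new.env(parent = emptyenv())

#' The bundled TRIPOD checklist
#'
#' Loads (and caches) the default checklist definition shipped with the
#' package: the 22 main TRIPOD items decomposed into 37 scored subitems with
#' their development/validation applicability, conditionality, reference
#' acceptance, and element lists.
#'
#' @return a `tripod_checklist`.
#' @examples
#' cl <- tripod_checklist()
#' length(cl$items)
#' @export
tripod_checklist <- function() {
  if (is.null(the$default_checklist)) {
    path <- system.file("extdata", "tripod_checklist_v1.0.yaml",
                        package = "tripodscore", mustWork = TRUE)
    the$default_checklist <- load_checklist(path)
  }
  the$default_checklist
}

#' Load a checklist definition file
#'
#' Reads a YAML checklist definition and validates it. The default
#' definition enforces the full TRIPOD structure; pass `strict = FALSE` for
#' reduced custom checklists (used e.g. in exhaustive-enumeration tests).
#'
#' @param path path to a YAML definition, or `NULL` for the bundled default.
#' @param strict enforce the canonical 37-item TRIPOD structure.
#' @return a `tripod_checklist`.
#' @export
load_checklist <- function(path = NULL, strict = TRUE) {
  if (is.null(path)) return(tripod_checklist())
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      stop_tripod(paste0("cannot parse checklist file '", path, "': ",
                         conditionMessage(e)), "tripod_parse_error")
    }
  )
  for (fld in c("version", "items")) {
    if (is.null(raw[[fld]])) {
      stop_tripod(paste0("checklist file '", path, "' lacks field '", fld, "'"),
                  "tripod_parse_error")
    }
  }
  items <- lapply(raw$items, function(it) {
    it$item_id <- as.character(it$item_id)
    it$elements <- lapply(it$elements, function(e) {
      list(id = as.character(e$id), description = as.character(e$description))
    })
    it
  })
  new_checklist(
    version = as.character(raw$version),
    items = items,
    incremental_value_excluded = as.character(raw$incremental_value_excluded %||% character()),
    partial_applicability = lapply(raw$partial_applicability %||% list(), as.character),
    strict = strict
  )
}

#' Write a checklist definition file
#'
#' Serialises a checklist to canonical YAML. Writing the result of
#' [load_checklist()] reproduces the input file byte for byte, so definitions
#' can be round-tripped through edits safely.
#'
#' @param checklist a `tripod_checklist`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_checklist <- function(checklist, path) {
  stopifnot(inherits(checklist, "tripod_checklist"))
  doc <- list(
    version = checklist$version,
    incremental_value_excluded = as.list(checklist$incremental_value_excluded),
    partial_applicability = lapply(checklist$partial_applicability, as.list),
    items = lapply(checklist$items, function(it) {
      list(
        item_id = it$item_id,
        main_item = as.integer(it$main_item),
        applicability = it$applicability,
        conditional = it$conditional,
        reference_acceptable = it$reference_acceptable,
        excluded_from_scores = it$excluded_from_scores,
        either_type_suffices = it$either_type_suffices,
        elements = lapply(it$elements, function(e) {
          list(id = e$id, description = e$description)
        })
      )
    })
  )
  txt <- yaml::as.yaml(doc, indent.mapping.sequence = TRUE)
  writeLines(txt, path, sep = "")
  invisible(path)
}

# ---- queries ----------------------------------------------------------------

cl_item <- function(checklist, item_id) {
  for (it in checklist$items) if (it$item_id == item_id) return(it)
  stop_tripod(paste0("unknown checklist item '", item_id, "'"), "tripod_lookup_error")
}

cl_item_ids <- function(checklist) {
  vapply(checklist$items, `[[`, "", "item_id")
}

#' Items applicable to a study type
#'
#' Returns the item ids relevant to one study type: development and external
#' validation each combine the shared items with their six type-specific
#' items (31 each); combined development and validation uses all 37; and
#' incremental value uses all items except the structural exclusion (item 17
#' in the default definition, 36 items). The returned set still includes
#' item 21 and the conditional items; scoring removes those.
#'
#' @param checklist a `tripod_checklist`.
#' @param study_type one of [study_types()].
#' @return character vector of item ids, in checklist order.
#' @examples
#' length(applicable_item_set(tripod_checklist(), "development"))
#' @export
applicable_item_set <- function(checklist, study_type) {
  stopifnot(inherits(checklist, "tripod_checklist"))
  study_type <- match.arg(study_type, STUDY_TYPES)
  ids <- cl_item_ids(checklist)
  app <- vapply(checklist$items, `[[`, "", "applicability")
  switch(study_type,
    development = ids[app %in% c("D", "DV")],
    external_validation = ids[app %in% c("V", "DV")],
    development_and_validation = ids,
    incremental_value = setdiff(ids, checklist$incremental_value_excluded)
  )
}

#' Number of extraction elements of an item
#'
#' @param checklist a `tripod_checklist`.
#' @param item_id item label such as `"4b"`.
#' @return integer element count.
#' @examples
#' element_count(tripod_checklist(), "4b")
#' @export
element_count <- function(checklist, item_id) {
  length(cl_item(checklist, item_id)$elements)
}

# element ids of one item, in order
cl_element_ids <- function(checklist, item_id) {
  vapply(cl_item(checklist, item_id)$elements, `[[`, "", "id")
}

# full element table in checklist order, cached on the checklist object
build_element_table <- function(checklist) {
  rows <- lapply(checklist$items, function(it) {
    ids <- vapply(it$elements, `[[`, "", "id")
    tibble::tibble(
      item_id = it$item_id,
      element_id = ids,
      ordinal = seq_along(ids),
      n_elements = length(ids)
    )
  })
  do.call(rbind, rows)
}

# long table of all elements of the given items, in checklist order
cl_element_table <- function(checklist, item_ids = cl_item_ids(checklist)) {
  tab <- checklist$element_table %||% build_element_table(checklist)
  tab[tab$item_id %in% item_ids, , drop = FALSE]
}

# items whose applicability is decided per record by an explicit flag
flaggable_items <- function(checklist, study_type) {
  cond <- cl_item_ids(checklist)[vapply(checklist$items, `[[`, TRUE, "conditional")]
  partial <- checklist$partial_applicability[[study_type]] %||% character()
  intersect(
    cl_item_ids(checklist),
    union(intersect(cond, applicable_item_set(checklist, study_type)), partial)
  )
}

#' Summarise checklist items as a tibble
#'
#' @param checklist a `tripod_checklist`.
#' @return tibble with one row per item: id, main item, applicability code,
#'   flags, and element count.
#' @export
checklist_items <- function(checklist) {
  stopifnot(inherits(checklist, "tripod_checklist"))
  tibble::tibble(
    item_id = cl_item_ids(checklist),
    main_item = vapply(checklist$items, function(it) as.integer(it$main_item), 1L),
    applicability = vapply(checklist$items, `[[`, "", "applicability"),
    conditional = vapply(checklist$items, `[[`, TRUE, "conditional"),
    reference_acceptable = vapply(checklist$items, `[[`, TRUE, "reference_acceptable"),
    excluded_from_scores = vapply(checklist$items, `[[`, TRUE, "excluded_from_scores"),
    either_type_suffices = vapply(checklist$items, `[[`, TRUE, "either_type_suffices"),
    n_elements = vapply(checklist$items, function(it) length(it$elements), 1L)
  )
}

#' @export
print.tripod_checklist <- function(x, ...) {
  cat("<tripod_checklist> version ", x$version, ": ", length(x$items),
      " items, ", sum(checklist_items(x)$n_elements), " elements\n", sep = "")
  invisible(x)
}
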