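# Element-level extraction records: construction, validation, interchange
# (long CSV and JSON), and merging development/validation parts of one model.

#' Construct a model extraction record
#'
#' One prediction model in one publication: a judgement for every element of
#' every item applicable to the model's study type, explicit applicability
#' flags for conditional ("if done") and partially applicable items, and the
#' model metadata extracted alongside.
#'
#' @param model_id,publication_id opaque identifiers.
#' @param study_type one of [study_types()].
#' @param judgements named character vector, `element_id -> judgement`, with
#'   judgements among `reported`, `not_reported`, `not_applicable`,
#'   `reported_by_reference`.
#' @param applicability named logical vector over the flaggable items for
#'   this study type (conditional items, plus e.g. 10c/12/19a for
#'   incremental value). Missing flags default to applicable.
#' @param clinical_domain,purpose,outcome metadata; `purpose` is
#'   `"diagnostic"` or `"prognostic"`.
#' @param sample_size,n_predictors participant and final-model predictor
#'   counts.
#' @param checklist checklist the record is judged against.
#' @param validate validate on construction (default `TRUE`).
#' @return object of class `model_extraction`.
#' @export
model_extraction <- function(model_id, publication_id, study_type, judgements,
                             applicability = NULL,
                             clinical_domain = NA_character_,
                             purpose = "prognostic",
                             sample_size = NA_integer_,
                             n_predictors = NA_integer_,
                             outcome = NA_character_,
                             checklist = tripod_checklist(),
                             validate = TRUE) {
  m <- structure(
    list(
      model_id = as.character(model_id),
      publication_id = as.character(publication_id),
      study_type = study_type,
      judgements = judgements,
      applicability = applicability %||% logical(),
      clinical_domain = clinical_domain,
      purpose = purpose,
      sample_size = sample_size,
      n_predictors = n_predictors,
      outcome = outcome
    ),
    class = "model_extraction"
  )
  if (validate) {
    problems <- validate_model_extraction(m, checklist)
    if (length(problems) > 0) {
      stop_tripod(
        paste0("invalid model extraction:\n", paste("-", problems, collapse = "\n")),
        "tripod_validation_error"
      )
    }
  }
  m
}

#' Construct a publication extraction record
#'
#' @param publication_id identifier.
#' @param journal_impact_factor positive real (2012 JCR scale in the study
#'   the defaults emulate).
#' @param prospective_design logical.
#' @param models list of [model_extraction()] records, one per study type
#'   present (each study type at most once).
#' @param validate validate on construction.
#' @return object of class `publication_extraction`.
#' @export
publication_extraction <- function(publication_id, journal_impact_factor,
                                   prospective_design, models,
                                   validate = TRUE) {
  p <- structure(
    list(
      publication_id = as.character(publication_id),
      journal_impact_factor = journal_impact_factor,
      prospective_design = prospective_design,
      models = models
    ),
    class = "publication_extraction"
  )
  if (validate) {
    problems <- validate_publication_shell(p)
    if (length(problems) > 0) {
      stop_tripod(
        paste0("invalid publication extraction:\n",
               paste("-", problems, collapse = "\n")),
        "tripod_validation_error"
      )
    }
  }
  p
}

# publication-level checks that do not need the checklist
validate_publication_shell <- function(pub) {
  problems <- character()
  where <- paste0("publication ", pub$publication_id)
  if (length(pub$models) < 1) {
    problems <- c(problems, paste0(where, ": needs at least one model"))
  }
  types <- vapply(pub$models, `[[`, "", "study_type")
  if (anyDuplicated(types)) {
    problems <- c(problems, paste0(
      where, ": duplicated study_type ",
      paste(unique(types[duplicated(types)]), collapse = ", ")
    ))
  }
  jif <- pub$journal_impact_factor
  if (!is.numeric(jif) || length(jif) != 1 || is.na(jif) || jif <= 0) {
    problems <- c(problems, paste0(where, ": journal_impact_factor must be a positive number"))
  }
  if (!is.logical(pub$prospective_design) || length(pub$prospective_design) != 1 ||
      is.na(pub$prospective_design)) {
    problems <- c(problems, paste0(where, ": prospective_design must be TRUE/FALSE"))
  }
  problems
}

validate_model_extraction <- function(model, checklist = tripod_checklist()) {
  problems <- character()
  where <- paste0("publication ", model$publication_id, ", model ", model$model_id)
  if (!(model$study_type %in% STUDY_TYPES)) {
    return(paste0(where, ": unknown study_type '", model$study_type, "'"))
  }
  item_set <- applicable_item_set(checklist, model$study_type)
  el_tab <- cl_element_table(checklist, item_set)
  expected <- el_tab$element_id

  j <- model$judgements
  if (is.null(names(j)) || any(names(j) == "")) {
    return(paste0(where, ": judgements must be a named vector of element ids"))
  }
  miss <- setdiff(expected, names(j))
  if (length(miss) > 0) {
    problems <- c(problems, paste0(
      where, ": missing judgement for element ", paste(miss, collapse = ", ")
    ))
  }
  extra <- setdiff(names(j), expected)
  if (length(extra) > 0) {
    problems <- c(problems, paste0(
      where, ": judgement for element outside the applicable item set: ",
      paste(extra, collapse = ", ")
    ))
  }
  bad <- names(j)[!(j %in% JUDGEMENT_LEVELS)]
  if (length(bad) > 0) {
    problems <- c(problems, paste0(
      where, ": invalid judgement value at ", paste(bad, collapse = ", ")
    ))
  }
  ref_items <- cl_item_ids(checklist)[
    vapply(checklist$items, `[[`, TRUE, "reference_acceptable")
  ]
  ref_ok <- el_tab$element_id[el_tab$item_id %in% ref_items]
  by_ref <- names(j)[j == "reported_by_reference"]
  bad_ref <- setdiff(intersect(by_ref, expected), ref_ok)
  if (length(bad_ref) > 0) {
    problems <- c(problems, paste0(
      where, ": reported_by_reference not allowed for element ",
      paste(bad_ref, collapse = ", "), " (item does not accept references)"
    ))
  }
  allowed_flags <- flaggable_items(checklist, model$study_type)
  flags <- model$applicability
  if (length(flags) > 0) {
    if (is.null(names(flags)) || !is.logical(flags) || anyNA(flags)) {
      problems <- c(problems, paste0(where, ": applicability must be a named logical vector"))
    } else {
      bad_keys <- setdiff(names(flags), allowed_flags)
      if (length(bad_keys) > 0) {
        problems <- c(problems, paste0(
          where, ": applicability flag for non-flaggable item ",
          paste(bad_keys, collapse = ", ")
        ))
      }
    }
  }
  if (!is.na(model$sample_size) && model$sample_size < 1) {
    problems <- c(problems, paste0(where, ": sample_size must be >= 1"))
  }
  dev_like <- model$study_type %in% c("development", "development_and_validation")
  if (dev_like && (is.na(model$n_predictors) || model$n_predictors < 1)) {
    problems <- c(problems, paste0(
      where, ": n_predictors must be >= 1 for development studies"
    ))
  }
  if (!(model$purpose %in% c("diagnostic", "prognostic"))) {
    problems <- c(problems, paste0(where, ": purpose must be diagnostic or prognostic"))
  }
  problems
}

#' Validate a list of publication extractions
#'
#' Runs all structural and checklist-level checks and returns every
#' violation with its publication/model coordinates.
#'
#' @param records list of [publication_extraction()] records.
#' @param checklist checklist to validate against.
#' @return tibble with columns `publication_id`, `model_id`, `message`;
#'   zero rows when everything is valid.
#' @export
validate_records <- function(records, checklist = tripod_checklist()) {
  rows <- list()
  seen_pub <- character()
  for (pub in records) {
    if (pub$publication_id %in% seen_pub) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        publication_id = pub$publication_id, model_id = NA_character_,
        message = paste0("duplicate publication_id ", pub$publication_id)
      )
    }
    seen_pub <- c(seen_pub, pub$publication_id)
    for (msg in validate_publication_shell(pub)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        publication_id = pub$publication_id, model_id = NA_character_, message = msg
      )
    }
    for (m in pub$models) {
      if (!identical(m$publication_id, pub$publication_id)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          publication_id = pub$publication_id, model_id = m$model_id,
          message = "model publication_id does not match its publication"
        )
      }
      for (msg in validate_model_extraction(m, checklist)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          publication_id = pub$publication_id, model_id = m$model_id, message = msg
        )
      }
    }
  }
  if (length(rows) == 0) {
    tibble::tibble(publication_id = character(), model_id = character(),
                   message = character())
  } else {
    do.call(rbind, rows)
  }
}

stop_on_violations <- function(violations) {
  if (nrow(violations) == 0) return(invisible(NULL))
  shown <- utils::head(violations$message, 20)
  more <- nrow(violations) - length(shown)
  stop_tripod(
    paste0(
      nrow(violations), " record validation failure(s):\n",
      paste("-", shown, collapse = "\n"),
      if (more > 0) paste0("\n... and ", more, " more")
    ),
    "tripod_validation_error"
  )
}

# ---- interchange ------------------------------------------------------------

canonical_records <- function(records, checklist) {
  records <- records[order(vapply(records, `[[`, "", "publication_id"))]
  lapply(records, function(pub) {
    pub$models <- pub$models[order(vapply(pub$models, `[[`, "", "model_id"))]
    pub$models <- lapply(pub$models, function(m) {
      ord <- cl_element_table(checklist, applicable_item_set(checklist, m$study_type))
      m$judgements <- m$judgements[ord$element_id]
      m$applicability <- m$applicability[
        intersect(cl_item_ids(checklist), names(m$applicability))
      ]
      m
    })
    pub
  })
}

records_paths <- function(path, format) {
  if (format == "csv_long") {
    list(
      judgements = paste0(path, ".judgements.csv"),
      models = paste0(path, ".models.csv"),
      publications = paste0(path, ".publications.csv")
    )
  } else {
    list(json = path)
  }
}

#' Write extraction records
#'
#' Serialises records deterministically in canonical order (publication id,
#' model id, checklist item order, element ordinal). The long-CSV dialect
#' writes three files next to `path`: `<path>.judgements.csv` (one row per
#' element judgement), `<path>.models.csv` (model metadata plus the items
#' flagged inapplicable), and `<path>.publications.csv` (publication
#' covariates). The JSON dialect writes a single file mirroring the record
#' structure.
#'
#' @param records list of [publication_extraction()] records.
#' @param path output path (CSV: path stem; JSON: file path).
#' @param format `"csv_long"` or `"json"`.
#' @param checklist checklist used for validation and canonical ordering.
#' @return the written file path(s), invisibly.
#' @export
write_records <- function(records, path, format = c("csv_long", "json"),
                          checklist = tripod_checklist()) {
  format <- match.arg(format)
  stop_on_violations(validate_records(records, checklist))
  records <- canonical_records(records, checklist)
  paths <- records_paths(path, format)

  pub_tab <- tibble::tibble(
    publication_id = vapply(records, `[[`, "", "publication_id"),
    journal_impact_factor = vapply(records, `[[`, 1, "journal_impact_factor"),
    prospective_design = vapply(records, `[[`, TRUE, "prospective_design")
  )
  model_rows <- list(); jud_rows <- list()
  for (pub in records) {
    for (m in pub$models) {
      inapp <- names(m$applicability)[!m$applicability]
      model_rows[[length(model_rows) + 1]] <- tibble::tibble(
        publication_id = pub$publication_id,
        model_id = m$model_id,
        study_type = m$study_type,
        clinical_domain = m$clinical_domain,
        purpose = m$purpose,
        sample_size = as.integer(m$sample_size),
        n_predictors = as.integer(m$n_predictors),
        outcome = m$outcome,
        inapplicable_items = paste(inapp, collapse = ";")
      )
      ord <- cl_element_table(checklist, applicable_item_set(checklist, m$study_type))
      jud_rows[[length(jud_rows) + 1]] <- tibble::tibble(
        publication_id = pub$publication_id,
        model_id = m$model_id,
        study_type = m$study_type,
        item_id = ord$item_id,
        element_id = ord$element_id,
        judgement = unname(m$judgements[ord$element_id])
      )
    }
  }
  empty_models <- tibble::tibble(
    publication_id = character(), model_id = character(), study_type = character(),
    clinical_domain = character(), purpose = character(),
    sample_size = integer(), n_predictors = integer(), outcome = character(),
    inapplicable_items = character()
  )
  empty_jud <- tibble::tibble(
    publication_id = character(), model_id = character(), study_type = character(),
    item_id = character(), element_id = character(), judgement = character()
  )
  model_tab <- if (length(model_rows)) do.call(rbind, model_rows) else empty_models
  jud_tab <- if (length(jud_rows)) do.call(rbind, jud_rows) else empty_jud

  if (format == "csv_long") {
    readr::write_csv(jud_tab, paths$judgements)
    readr::write_csv(model_tab, paths$models)
    readr::write_csv(pub_tab, paths$publications)
  } else {
    doc <- list(publications = lapply(records, function(pub) {
      list(
        publication_id = pub$publication_id,
        journal_impact_factor = pub$journal_impact_factor,
        prospective_design = pub$prospective_design,
        models = lapply(pub$models, function(m) {
          list(
            model_id = m$model_id,
            study_type = m$study_type,
            clinical_domain = m$clinical_domain,
            purpose = m$purpose,
            sample_size = m$sample_size,
            n_predictors = m$n_predictors,
            outcome = m$outcome,
            inapplicable_items = as.list(names(m$applicability)[!m$applicability]),
            judgements = as.list(m$judgements)
          )
        })
      )
    }))
    jsonlite::write_json(doc, paths$json, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, na = "null")
  }
  invisible(unlist(paths))
}

parse_flags <- function(inapplicable_items, checklist, study_type) {
  ids <- if (is.null(inapplicable_items) || is.na(inapplicable_items) ||
             !nzchar(inapplicable_items)) {
    character()
  } else if (is.character(inapplicable_items) && length(inapplicable_items) == 1) {
    strsplit(inapplicable_items, ";", fixed = TRUE)[[1]]
  } else {
    as.character(inapplicable_items)
  }
  flags <- rep(TRUE, length(flaggable_items(checklist, study_type)))
  names(flags) <- flaggable_items(checklist, study_type)
  extra <- setdiff(ids, names(flags))
  flags[intersect(ids, names(flags))] <- FALSE
  if (length(extra) > 0) {
    # keep the bad key so validation reports it with coordinates
    bad <- rep(FALSE, length(extra)); names(bad) <- extra
    flags <- c(flags, bad)
  }
  flags
}

#' Read extraction records
#'
#' Parses and validates records written by [write_records()]; any violation
#' is reported with publication/model coordinates and aborts the read.
#'
#' @param path CSV path stem or JSON file path.
#' @param format `"csv_long"` or `"json"`.
#' @param checklist checklist to validate against.
#' @param validate abort on validation failures (default). With
#'   `validate = FALSE` the parsed records are returned as-is so callers can
#'   collect diagnostics with [validate_records()] themselves.
#' @return list of [publication_extraction()] records in canonical order.
#' @export
read_records <- function(path, format = c("csv_long", "json"),
                         checklist = tripod_checklist(), validate = TRUE) {
  format <- match.arg(format)
  paths <- records_paths(path, format)
  if (format == "csv_long") {
    for (p in paths) {
      if (!file.exists(p)) {
        stop_tripod(paste0("missing record file '", p, "'"), "tripod_io_error")
      }
    }
    jud <- readr::read_csv(paths$judgements, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
    mod <- readr::read_csv(paths$models, show_col_types = FALSE,
                           col_types = readr::cols(
                             sample_size = readr::col_integer(),
                             n_predictors = readr::col_integer(),
                             .default = readr::col_character()
                           ))
    pubs <- readr::read_csv(paths$publications, show_col_types = FALSE,
                            col_types = readr::cols(
                              publication_id = readr::col_character(),
                              journal_impact_factor = readr::col_double(),
                              prospective_design = readr::col_logical()
                            ))
    bad_type <- setdiff(unique(mod$study_type), STUDY_TYPES)
    if (length(bad_type) > 0) {
      stop_tripod(paste0("unknown study_type in '", paths$models, "': ",
                         paste(bad_type, collapse = ", ")), "tripod_parse_error")
    }
    records <- lapply(seq_len(nrow(pubs)), function(i) {
      pid <- pubs$publication_id[i]
      mrows <- mod[mod$publication_id == pid, , drop = FALSE]
      models <- lapply(seq_len(nrow(mrows)), function(k) {
        mid <- mrows$model_id[k]
        jr <- jud[jud$publication_id == pid & jud$model_id == mid, , drop = FALSE]
        judgements <- stats::setNames(jr$judgement, jr$element_id)
        model_extraction(
          model_id = mid, publication_id = pid,
          study_type = mrows$study_type[k],
          judgements = judgements,
          applicability = parse_flags(mrows$inapplicable_items[k], checklist,
                                      mrows$study_type[k]),
          clinical_domain = mrows$clinical_domain[k],
          purpose = mrows$purpose[k],
          sample_size = mrows$sample_size[k],
          n_predictors = mrows$n_predictors[k],
          outcome = mrows$outcome[k],
          checklist = checklist, validate = FALSE
        )
      })
      publication_extraction(
        publication_id = pid,
        journal_impact_factor = pubs$journal_impact_factor[i],
        prospective_design = pubs$prospective_design[i],
        models = models, validate = FALSE
      )
    })
  } else {
    if (!file.exists(paths$json)) {
      stop_tripod(paste0("missing record file '", paths$json, "'"), "tripod_io_error")
    }
    doc <- jsonlite::fromJSON(paths$json, simplifyVector = FALSE)
    records <- lapply(doc$publications, function(p) {
      models <- lapply(p$models, function(m) {
        if (!(m$study_type %in% STUDY_TYPES)) {
          stop_tripod(paste0("unknown study_type '", m$study_type, "' in '",
                             paths$json, "'"), "tripod_parse_error")
        }
        model_extraction(
          model_id = m$model_id, publication_id = p$publication_id,
          study_type = m$study_type,
          judgements = unlist(m$judgements) %||% stats::setNames(character(), character()),
          applicability = parse_flags(
            paste(unlist(m$inapplicable_items), collapse = ";"),
            checklist, m$study_type
          ),
          clinical_domain = m$clinical_domain %||% NA_character_,
          purpose = m$purpose %||% "prognostic",
          sample_size = m$sample_size %||% NA_integer_,
          n_predictors = m$n_predictors %||% NA_integer_,
          outcome = m$outcome %||% NA_character_,
          checklist = checklist, validate = FALSE
        )
      })
      publication_extraction(
        publication_id = p$publication_id,
        journal_impact_factor = p$journal_impact_factor,
        prospective_design = p$prospective_design,
        models = models, validate = FALSE
      )
    })
  }
  if (!validate) return(records)
  stop_on_violations(validate_records(records, checklist))
  canonical_records(records, checklist)
}

# ---- merging ----------------------------------------------------------------

JUDGEMENT_RANK <- c(
  not_reported = 1L, not_applicable = 2L,
  reported_by_reference = 3L, reported = 4L
)

#' Merge development and validation parts of the same model
#'
#' When one publication develops and externally validates the same model,
#' the two parts are extracted separately and then combined element by
#' element into a single combined-study record covering all 37 items. In
#' `"favourable"` mode (default) a shared element counts as the best of the
#' two judgements (reported > reported_by_reference > not_applicable >
#' not_reported) — information reported anywhere in the publication counts.
#' `"strict"` mode takes the worst of the two instead.
#'
#' @param dev_part development-part [model_extraction()].
#' @param val_part external-validation-part [model_extraction()] of the same
#'   model.
#' @param checklist checklist in use.
#' @param mode `"favourable"` or `"strict"`.
#' @return a `model_extraction` with study type
#'   `development_and_validation`.
#' @export
merge_model_parts <- function(dev_part, val_part,
                              checklist = tripod_checklist(),
                              mode = c("favourable", "strict")) {
  mode <- match.arg(mode)
  if (!identical(dev_part$model_id, val_part$model_id)) {
    stop_tripod(
      paste0("cannot merge different models ('", dev_part$model_id, "' vs '",
             val_part$model_id, "')"),
      "tripod_merge_error"
    )
  }
  if (dev_part$study_type != "development" ||
      val_part$study_type != "external_validation") {
    stop_tripod("merge needs a development part and an external_validation part",
                "tripod_merge_error")
  }
  dev_set <- applicable_item_set(checklist, "development")
  val_set <- applicable_item_set(checklist, "external_validation")
  shared <- intersect(dev_set, val_set)
  shared_el <- cl_element_table(checklist, shared)$element_id
  pick <- if (mode == "favourable") pmax else pmin
  merged_shared <- names(JUDGEMENT_RANK)[pick(
    JUDGEMENT_RANK[dev_part$judgements[shared_el]],
    JUDGEMENT_RANK[val_part$judgements[shared_el]]
  )]
  names(merged_shared) <- shared_el
  dev_only_el <- cl_element_table(checklist, setdiff(dev_set, shared))$element_id
  val_only_el <- cl_element_table(checklist, setdiff(val_set, shared))$element_id
  judgements <- c(merged_shared,
                  dev_part$judgements[dev_only_el],
                  val_part$judgements[val_only_el])

  flags <- rep(TRUE, length(flaggable_items(checklist, "development_and_validation")))
  names(flags) <- flaggable_items(checklist, "development_and_validation")
  for (id in names(flags)) {
    d <- dev_part$applicability[id]; v <- val_part$applicability[id]
    d <- if (is.na(d)) NA else unname(d); v <- if (is.na(v)) NA else unname(v)
    flags[id] <- if (id %in% shared) {
      # missing flag means applicable; "if done" in either part means the
      # combined report should cover it
      !isFALSE(d) || !isFALSE(v)
    } else if (id %in% dev_set) {
      !isFALSE(d)
    } else {
      !isFALSE(v)
    }
  }
  model_extraction(
    model_id = dev_part$model_id,
    publication_id = dev_part$publication_id,
    study_type = "development_and_validation",
    judgements = judgements,
    applicability = flags,
    clinical_domain = dev_part$clinical_domain,
    purpose = dev_part$purpose,
    sample_size = max(dev_part$sample_size, val_part$sample_size, na.rm = TRUE),
    n_predictors = dev_part$n_predictors,
    outcome = dev_part$outcome,
    checklist = checklist
  )
}

#' @export
print.model_extraction <- function(x, ...) {
  cat("<model_extraction> ", x$model_id, " (", x$study_type, ") in publication ",
      x$publication_id, ": ", length(x$judgements), " element judgements\n", sep = "")
  invisible(x)
}

#' @export
print.publication_extraction <- function(x, ...) {
  cat("<publication_extraction> ", x$publication_id, ": ",
      length(x$models), " model(s) [",
      paste(vapply(x$models, `[[`, "", "study_type"), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}
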