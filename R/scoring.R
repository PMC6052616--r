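# The three scoring levels: item completeness, per-model adherence,
# per-publication adherence, and per-item adherence across models.
#
# Scores are kept as exact integer numerator/denominator pairs; rounding to
# whole percentages happens only when rendering.

new_adherence_score <- function(numerator, denominator) {
  structure(
    list(
      numerator = as.integer(numerator),
      denominator = as.integer(denominator),
      fraction = numerator / denominator
    ),
    class = "adherence_score"
  )
}

#' @export
print.adherence_score <- function(x, ...) {
  cat("<adherence_score> ", x$numerator, "/", x$denominator, " = ",
      format_percent(x$numerator, x$denominator), "%\n", sep = "")
  invisible(x)
}

# is `item_id` applicable to this model (study-type set + explicit flag)?
item_applicable <- function(model, item_id, checklist) {
  if (!(item_id %in% applicable_item_set(checklist, model$study_type))) {
    return(FALSE)
  }
  flag <- model$applicability[item_id]
  !isFALSE(unname(flag))
}

#' Is a TRIPOD item completely reported in a model?
#'
#' An item is complete when every one of its elements is reported (or not
#' applicable, which counts as reported; or reported by reference, for the
#' items where a citation to another article is acceptable: 4b, 5a, 6a, 7a
#' in the default checklist).
#'
#' Querying an item that is not applicable to the model — outside its study
#' type's item set, or flagged "not done" — is an error, so extraction
#' mistakes surface early.
#'
#' @param model a [model_extraction()].
#' @param item_id item label.
#' @param checklist checklist in use.
#' @return `TRUE` or `FALSE`.
#' @export
item_complete <- function(model, item_id, checklist = tripod_checklist()) {
  it <- cl_item(checklist, item_id)
  if (!item_applicable(model, item_id, checklist)) {
    stop_tripod(
      paste0("item ", item_id, " is not applicable to model ", model$model_id,
             " (study type ", model$study_type, ")"),
      "tripod_applicability_error"
    )
  }
  ok <- c("reported", "not_applicable",
          if (it$reference_acceptable) "reported_by_reference")
  el <- cl_element_ids(checklist, item_id)
  all(model$judgements[el] %in% ok)
}

#' Items entering a model's adherence score
#'
#' The study type's applicable items, minus the items excluded from all
#' score calculations (item 21), minus conditional or partially applicable
#' items the record flags as not applicable.
#'
#' @inheritParams item_complete
#' @return character vector of item ids in checklist order.
#' @export
scored_item_set <- function(model, checklist = tripod_checklist()) {
  ids <- applicable_item_set(checklist, model$study_type)
  excluded <- cl_item_ids(checklist)[
    vapply(checklist$items, `[[`, TRUE, "excluded_from_scores")
  ]
  flagged_off <- names(model$applicability)[!model$applicability]
  setdiff(ids, union(excluded, flagged_off))
}

# named logical over the scored item set: complete or not
model_item_status <- function(model, checklist) {
  ids <- scored_item_set(model, checklist)
  status <- vapply(ids, function(id) item_complete(model, id, checklist), TRUE)
  names(status) <- ids
  status
}

#' Overall completeness of reporting of one model
#'
#' Number of completely reported scored items over the number of scored
#' items for that model's study type (31, 36 or 37 before the item-21 and
#' conditional-item exclusions).
#'
#' @inheritParams item_complete
#' @return an `adherence_score` with fields `numerator`, `denominator`,
#'   `fraction`.
#' @export
model_adherence <- function(model, checklist = tripod_checklist()) {
  status <- model_item_status(model, checklist)
  if (length(status) == 0) {
    stop_tripod(paste0("model ", model$model_id, " has an empty scored item set"),
                "tripod_degenerate_error")
  }
  new_adherence_score(sum(status), length(status))
}

#' Overall completeness of reporting of one publication
#'
#' For a single-model publication this equals [model_adherence()]. When a
#' publication contains several study types, the item universe is the union
#' of the member models' scored sets; an item counts complete only if it is
#' complete in every member model where it is scored — except the items for
#' which complete reporting in either type suffices (3a, 18, 19a, 19b, 20 in
#' the default checklist), which count complete if any member reports them
#' completely.
#'
#' @param pub a [publication_extraction()].
#' @param checklist checklist in use.
#' @return an `adherence_score`.
#' @export
publication_adherence <- function(pub, checklist = tripod_checklist()) {
  statuses <- lapply(pub$models, model_item_status, checklist = checklist)
  if (length(statuses) == 1) {
    status <- statuses[[1]]
    if (length(status) == 0) {
      stop_tripod(paste0("publication ", pub$publication_id,
                         " has an empty scored item set"),
                  "tripod_degenerate_error")
    }
    return(new_adherence_score(sum(status), length(status)))
  }
  universe <- intersect(
    cl_item_ids(checklist),
    Reduce(union, lapply(statuses, names))
  )
  either <- cl_item_ids(checklist)[
    vapply(checklist$items, `[[`, TRUE, "either_type_suffices")
  ]
  complete <- vapply(universe, function(id) {
    per_model <- unlist(lapply(statuses, function(s) s[id]))
    per_model <- per_model[!is.na(per_model)]
    if (id %in% either) any(per_model) else all(per_model)
  }, TRUE)
  if (length(complete) == 0) {
    stop_tripod(paste0("publication ", pub$publication_id,
                       " has an empty scored item set"),
                "tripod_degenerate_error")
  }
  new_adherence_score(sum(complete), length(complete))
}

#' Completeness of one item across a cohort of models
#'
#' Divides the number of models completely reporting the item by the number
#' of models in which the item was applicable (its scored-set membership).
#' The item excluded from score calculations (item 21) is special-cased: its
#' denominator is the total number of models, since the set of models where
#' it truly applied is unknowable from reports.
#'
#' @param models list of [model_extraction()] records.
#' @param item_id item label.
#' @param checklist checklist in use.
#' @return tibble with one row: `item_id`, `n_complete`, `n_applicable`,
#'   `percent` (`NA` when the item is never applicable in the cohort).
#' @export
item_adherence <- function(models, item_id, checklist = tripod_checklist()) {
  stopifnot(length(models) > 0)
  it <- cl_item(checklist, item_id)
  if (it$excluded_from_scores) {
    applicable <- vapply(models, function(m) {
      item_id %in% applicable_item_set(checklist, m$study_type)
    }, TRUE)
    n_complete <- sum(vapply(models[applicable], item_complete, TRUE,
                             item_id = item_id, checklist = checklist))
    n_applicable <- length(models)
  } else {
    in_scored <- vapply(models, function(m) {
      item_id %in% scored_item_set(m, checklist)
    }, TRUE)
    n_complete <- sum(vapply(models[in_scored], item_complete, TRUE,
                             item_id = item_id, checklist = checklist))
    n_applicable <- sum(in_scored)
  }
  tibble::tibble(
    item_id = item_id,
    n_complete = as.integer(n_complete),
    n_applicable = as.integer(n_applicable),
    percent = if (n_applicable > 0) 100 * n_complete / n_applicable else NA_real_
  )
}

#' Per-item adherence for every checklist item
#'
#' @param models list of [model_extraction()] records.
#' @param checklist checklist in use.
#' @return tibble with one row per item (see [item_adherence()]). Items
#'   never applicable in the cohort get `percent = NA` and a warning.
#' @export
adherence_table <- function(models, checklist = tripod_checklist()) {
  stopifnot(length(models) > 0)
  # one status pass per model, then tally per item
  ids <- cl_item_ids(checklist)
  tallies <- matrix(0L, nrow = length(ids), ncol = 2,
                    dimnames = list(ids, c("complete", "applicable")))
  excluded <- ids[vapply(checklist$items, `[[`, TRUE, "excluded_from_scores")]
  for (m in models) {
    status <- model_item_status(m, checklist)
    tallies[names(status), "applicable"] <- tallies[names(status), "applicable"] + 1L
    tallies[names(status), "complete"] <-
      tallies[names(status), "complete"] + as.integer(status)
    for (id in intersect(excluded, applicable_item_set(checklist, m$study_type))) {
      tallies[id, "applicable"] <- tallies[id, "applicable"] + 1L
      tallies[id, "complete"] <- tallies[id, "complete"] +
        as.integer(item_complete(m, id, checklist))
    }
  }
  out <- tibble::tibble(
    item_id = ids,
    n_complete = unname(tallies[, "complete"]),
    n_applicable = unname(tallies[, "applicable"]),
    percent = ifelse(tallies[, "applicable"] > 0,
                     100 * tallies[, "complete"] / tallies[, "applicable"],
                     NA_real_)
  )
  never <- out$item_id[out$n_applicable == 0]
  if (length(never) > 0) {
    warning("item(s) never applicable in this cohort: ",
            paste(never, collapse = ", "), call. = FALSE)
  }
  out
}

#' Score every model in a cohort
#'
#' @param publications list of [publication_extraction()] records.
#' @param checklist checklist in use.
#' @return tibble with one row per model: identifiers, study type,
#'   numerator, denominator, and adherence fraction.
#' @export
score_models <- function(publications, checklist = tripod_checklist()) {
  rows <- lapply(publications, function(pub) {
    do.call(rbind, lapply(pub$models, function(m) {
      sc <- model_adherence(m, checklist)
      tibble::tibble(
        publication_id = pub$publication_id,
        model_id = m$model_id,
        study_type = m$study_type,
        purpose = m$purpose,
        numerator = sc$numerator,
        denominator = sc$denominator,
        fraction = sc$fraction
      )
    }))
  })
  do.call(rbind, rows)
}

#' Score every publication in a cohort
#'
#' @inheritParams score_models
#' @return tibble with one row per publication: identifiers, number of
#'   member models, numerator, denominator, adherence fraction, and the
#'   publication covariates carried by the records.
#' @export
score_publications <- function(publications, checklist = tripod_checklist()) {
  rows <- lapply(publications, function(pub) {
    sc <- publication_adherence(pub, checklist)
    # covariates for downstream summaries/regression: purpose of the first
    # model; size covariates from the member model with the largest sample
    sizes <- vapply(pub$models, function(m) {
      if (is.na(m$sample_size)) -Inf else as.numeric(m$sample_size)
    }, 1)
    primary <- pub$models[[which.max(sizes)]]
    tibble::tibble(
      publication_id = pub$publication_id,
      n_models = length(pub$models),
      purpose = pub$models[[1]]$purpose,
      journal_impact_factor = pub$journal_impact_factor,
      prospective_design = pub$prospective_design,
      sample_size = primary$sample_size,
      n_predictors = primary$n_predictors,
      numerator = sc$numerator,
      denominator = sc$denominator,
      fraction = sc$fraction
    )
  })
  do.call(rbind, rows)
}
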