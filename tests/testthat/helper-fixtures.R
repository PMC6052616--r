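# Shared fixtures: fully reported / fully unreported models, models with a
# chosen number of complete items, a miniature checklist for exhaustive
# enumeration, and a brute-force scoring oracle written directly from the
# scoring definitions (independent of the engine).

CL <- tripod_checklist()

element_ids_of <- function(checklist, item_ids) {
  unlist(lapply(item_ids, function(id) {
    vapply(tripodscore:::cl_item(checklist, id)$elements, `[[`, "", "id")
  }))
}

# a valid model with every applicable element set to `fill`
make_model <- function(study_type = "development", fill = "reported",
                       flags = NULL, model_id = "M1", publication_id = "P1",
                       sample_size = 100L, n_predictors = 5L,
                       checklist = CL, ...) {
  items <- applicable_item_set(checklist, study_type)
  els <- element_ids_of(checklist, items)
  judgements <- stats::setNames(rep(fill, length(els)), els)
  fl <- rep(TRUE, length(tripodscore:::flaggable_items(checklist, study_type)))
  names(fl) <- tripodscore:::flaggable_items(checklist, study_type)
  if (!is.null(flags)) fl[names(flags)] <- flags
  model_extraction(
    model_id = model_id, publication_id = publication_id,
    study_type = study_type, judgements = judgements, applicability = fl,
    sample_size = sample_size, n_predictors = n_predictors,
    checklist = checklist, ...
  )
}

# set all elements of the given items to `value` in an existing model
set_items <- function(model, item_ids, value, checklist = CL) {
  els <- element_ids_of(checklist, item_ids)
  model$judgements[intersect(els, names(model$judgements))] <- value
  model
}

# development model whose scored numerator is exactly k (of 30):
# the first k scored items fully reported, the rest not reported
make_dev_model_with_numerator <- function(k, model_id = "M1",
                                          publication_id = "P1",
                                          n_predictors = 5L,
                                          sample_size = 100L) {
  m <- make_model("development", fill = "not_reported",
                  model_id = model_id, publication_id = publication_id)
  m$sample_size <- as.integer(sample_size)
  m$n_predictors <- as.integer(n_predictors)
  scored <- scored_item_set(m, CL)
  set_items(m, utils::head(scored, k), "reported")
}

make_publication <- function(models, publication_id = "P1", jif = 5,
                             prospective = TRUE) {
  models <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    m$publication_id <- publication_id
    m$model_id <- paste0(publication_id, "_M", i)
    m
  })
  publication_extraction(publication_id, jif, prospective, models)
}

# ---- miniature checklist for exhaustive enumeration ------------------------

mini_item <- function(item_id, applicability, n_el, conditional = FALSE,
                      reference_acceptable = FALSE, excluded = FALSE,
                      either = FALSE) {
  list(
    item_id = item_id, main_item = tripodscore:::main_item_of(item_id),
    applicability = applicability, conditional = conditional,
    reference_acceptable = reference_acceptable,
    excluded_from_scores = excluded, either_type_suffices = either,
    elements = lapply(seq_len(n_el), function(i) {
      list(id = paste0(item_id, ".", i), description = paste0("element ", i))
    })
  )
}

# 3 items: a shared 2-element item, a conditional development-only item,
# and a reference-acceptable validation-only item
mini_checklist <- function() {
  new_checklist(
    version = "mini-1",
    items = list(
      mini_item("1", "DV", 2, either = TRUE),
      mini_item("2", "D", 1, conditional = TRUE),
      mini_item("3", "V", 1, reference_acceptable = TRUE)
    ),
    strict = FALSE
  )
}

# ---- brute-force oracle ----------------------------------------------------
# Direct transcription of the scoring rules, structured nothing like the
# engine: plain loops over checklist fields.

oracle_applicable <- function(cl, study_type) {
  out <- character()
  for (it in cl$items) {
    keep <- switch(study_type,
      development = it$applicability %in% c("D", "DV"),
      external_validation = it$applicability %in% c("V", "DV"),
      development_and_validation = TRUE,
      incremental_value = !(it$item_id %in% cl$incremental_value_excluded)
    )
    if (keep) out <- c(out, it$item_id)
  }
  out
}

oracle_item_complete <- function(cl, model, item_id) {
  for (it in cl$items) {
    if (it$item_id != item_id) next
    for (e in it$elements) {
      j <- model$judgements[[e$id]]
      good <- j == "reported" || j == "not_applicable" ||
        (j == "reported_by_reference" && it$reference_acceptable)
      if (!good) return(FALSE)
    }
    return(TRUE)
  }
  stop("unknown item")
}

oracle_scored_set <- function(cl, model) {
  out <- character()
  for (id in oracle_applicable(cl, model$study_type)) {
    it <- tripodscore:::cl_item(cl, id)
    if (it$excluded_from_scores) next
    flag <- model$applicability[id]
    if (!is.na(flag) && !flag) next
    out <- c(out, id)
  }
  out
}

oracle_model_adherence <- function(cl, model) {
  scored <- oracle_scored_set(cl, model)
  num <- 0L
  for (id in scored) num <- num + oracle_item_complete(cl, model, id)
  c(numerator = num, denominator = length(scored))
}

oracle_publication_adherence <- function(cl, pub) {
  per_model <- lapply(pub$models, function(m) {
    ids <- oracle_scored_set(cl, m)
    stats::setNames(
      vapply(ids, function(id) oracle_item_complete(cl, m, id), TRUE), ids
    )
  })
  universe <- unique(unlist(lapply(per_model, names)))
  num <- 0L
  for (id in universe) {
    vals <- logical()
    for (s in per_model) if (id %in% names(s)) vals <- c(vals, s[[id]])
    either <- tripodscore:::cl_item(cl, id)$either_type_suffices
    if (if (either) any(vals) else all(vals)) num <- num + 1L
  }
  c(numerator = num, denominator = length(universe))
}
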