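# Synthetic cohort generator calibrated to the published pre-TRIPOD cohort:
# 146 publications / ~170 models, study-type mix 43/25/19/12%, per-item
# completeness anchored to the printed item percentages, conditional-item
# applicability frequencies from the published per-type counts, and
# right-skewed covariates matching the printed medians and IQRs.

# Per-item probability that the item is completely reported. 24 of the 37
# values are printed cohort percentages; the 13 others (4b, 5a, 5c, 6a, 8,
# 10c, 10e, 13a, 13c, 14a, 14b, 15b, 19a) are package defaults chosen in the
# 25-75% band (the printed "extreme" tables exhaust the items outside it).
default_item_probability <- function() {
  c(
    "1" = 0.05, "2" = 0.02, "3a" = 0.81, "3b" = 0.63, "4a" = 0.95,
    "4b" = 0.55, "5a" = 0.60, "5b" = 0.79, "5c" = 0.70, "6a" = 0.65,
    "6b" = 0.28, "7a" = 0.25, "7b" = 0.06, "8" = 0.30, "9" = 0.39,
    "10a" = 0.29, "10b" = 0.24, "10c" = 0.40, "10d" = 0.21, "10e" = 0.35,
    "11" = 0.90, "12" = 0.11, "13a" = 0.50, "13b" = 0.21, "13c" = 0.30,
    "14a" = 0.45, "14b" = 0.50, "15a" = 0.17, "15b" = 0.30, "16" = 0.14,
    "17" = 0.14, "18" = 0.88, "19a" = 0.60, "19b" = 0.96, "20" = 0.59,
    "21" = 0.55, "22" = 0.27
  )
}

# Probability that a conditional ("if done") or partially applicable item is
# applicable to a model, per study type; published applicability counts over
# the per-type model totals (73/43/33/21). Items not listed are always
# applicable.
default_conditional_probability <- function() {
  list(
    development = c("5c" = 72 / 73, "11" = 22 / 73, "14b" = 55 / 73),
    external_validation = c("10e" = 8 / 43, "11" = 15 / 43, "17" = 4 / 43),
    incremental_value = c(
      "10c" = 20 / 33, "10e" = 11 / 33, "11" = 20 / 33,
      "12" = 17 / 33, "14b" = 25 / 33, "19a" = 29 / 33
    ),
    development_and_validation = c(
      "10e" = 4 / 21, "11" = 13 / 21, "14b" = 14 / 21,
      "17" = 3 / 21, "19a" = 20 / 21
    )
  )
}

lognormal_from_quartiles <- function(median, p25, p75) {
  c(meanlog = log(median),
    sdlog = (log(p75) - log(p25)) / (2 * stats::qnorm(0.75)))
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the published pre-TRIPOD assessment cohort: 146
#' publications carrying about 170 models; model-level study-type mix
#' 0.43/0.25/0.19/0.12 over development / external validation / incremental
#' value / combined; 84% prognostic; journal impact factor lognormal with
#' median 5.3 (IQR 4.0–7.1); sample size lognormal with median 450 (IQR
#' 200–2005); predictor count a discretised lognormal with median 5 (IQR
#' 3–8); per-item completeness probabilities anchored to the printed item
#' percentages; and conditional-item applicability frequencies from the
#' published per-type counts.
#'
#' @param n_publications number of publications (default 146).
#' @param type_mix named model-level study-type probabilities (renormalised).
#' @param multi_type_rate probability a publication carries a second model
#'   of a different study type (default 24/146, reproducing 170 models from
#'   146 publications on average).
#' @param item_probability named per-item completeness probabilities
#'   covering every checklist item.
#' @param conditional_probability list (per study type) of named
#'   applicability probabilities for conditional/partially applicable items.
#' @param purpose_mix probability a publication is prognostic (default
#'   0.84).
#' @param jif,sample_size,n_predictors `c(meanlog=, sdlog=)` lognormal
#'   parameters; sample size and predictor count are rounded to integers
#'   (minimum 1).
#' @param prospective_rate probability of a prospective design.
#' @param domain_mix named clinical-domain probabilities.
#' @param all_cause_mortality_rate probability the predicted outcome is
#'   all-cause mortality (drawn per publication).
#' @param na_element_rate named per-element probabilities of a
#'   not-applicable judgement (defaults: end of follow-up `4b.3` and outcome
#'   blinding `6b.1`, both 0.16). The reporting probability of the remaining
#'   channel is solved so the item-level completeness still matches
#'   `item_probability` (clamped at 0 when the target sits below the
#'   not-applicable floor).
#' @param reference_rate probability that a complete element of a
#'   reference-acceptable item is recorded as `reported_by_reference`.
#' @param seed integer seed; identical configurations generate byte-identical
#'   cohorts.
#' @param checklist checklist the cohort is generated against.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_publications = 146,
                             type_mix = c(development = 0.43,
                                          external_validation = 0.25,
                                          incremental_value = 0.19,
                                          development_and_validation = 0.12),
                             multi_type_rate = 24 / 146,
                             item_probability = default_item_probability(),
                             conditional_probability = default_conditional_probability(),
                             purpose_mix = 0.84,
                             jif = lognormal_from_quartiles(5.3, 4.0, 7.1),
                             sample_size = lognormal_from_quartiles(450, 200, 2005),
                             n_predictors = lognormal_from_quartiles(5, 3, 8),
                             prospective_rate = 0.6,
                             domain_mix = c("critical care medicine" = 0.11,
                                            "obstetrics and gynaecology" = 0.09,
                                            "gastroenterology and hepatology" = 0.07,
                                            "other" = 0.73),
                             all_cause_mortality_rate = 0.16,
                             na_element_rate = c("4b.3" = 0.16, "6b.1" = 0.16),
                             reference_rate = 0.1,
                             seed = 1L,
                             checklist = tripod_checklist()) {
  stopifnot(
    n_publications >= 1,
    all(type_mix >= 0), sum(type_mix) > 0,
    setequal(names(type_mix), STUDY_TYPES),
    multi_type_rate >= 0, multi_type_rate <= 1,
    all(item_probability >= 0), all(item_probability <= 1),
    purpose_mix >= 0, purpose_mix <= 1,
    prospective_rate >= 0, prospective_rate <= 1,
    all_cause_mortality_rate >= 0, all_cause_mortality_rate <= 1,
    length(na_element_rate) == 0 ||
      (all(na_element_rate >= 0) && all(na_element_rate <= 1)),
    reference_rate >= 0, reference_rate <= 1
  )
  miss <- setdiff(cl_item_ids(checklist), names(item_probability))
  if (length(miss) > 0) {
    stop_tripod(paste0("item_probability lacks item(s): ",
                       paste(miss, collapse = ", ")), "tripod_config_error")
  }
  for (st in names(conditional_probability)) {
    p <- conditional_probability[[st]]
    stopifnot(all(p >= 0), all(p <= 1))
    bad <- setdiff(names(p), flaggable_items(checklist, st))
    if (length(bad) > 0) {
      stop_tripod(paste0("conditional_probability[", st, "] has non-flaggable item(s): ",
                         paste(bad, collapse = ", ")), "tripod_config_error")
    }
  }
  structure(
    list(
      n_publications = as.integer(n_publications),
      type_mix = type_mix[STUDY_TYPES] / sum(type_mix),
      multi_type_rate = multi_type_rate,
      item_probability = item_probability,
      conditional_probability = conditional_probability,
      purpose_mix = purpose_mix,
      jif = jif, sample_size = sample_size, n_predictors = n_predictors,
      prospective_rate = prospective_rate,
      domain_mix = domain_mix / sum(domain_mix),
      all_cause_mortality_rate = all_cause_mortality_rate,
      na_element_rate = na_element_rate,
      reference_rate = reference_rate,
      seed = as.integer(seed),
      checklist = checklist
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config> ", x$n_publications, " publications, seed ", x$seed,
      ", checklist ", x$checklist$version, "\n", sep = "")
  invisible(x)
}

# Element judgements for one model. `p_item` is the (possibly tilted) item
# completeness target; elements are drawn independently with
# p_element = p_item^(1/k) so the product reproduces the item target.
sim_model_judgements <- function(cfg, study_type, flags) {
  cl <- cfg$checklist
  el <- cl_element_table(cl, applicable_item_set(cl, study_type))
  p_item <- cfg$item_probability[el$item_id]
  p_el <- p_item^(1 / el$n_elements)
  r <- rep(0, nrow(el))
  na_ids <- intersect(el$element_id, names(cfg$na_element_rate))
  r[match(na_ids, el$element_id)] <- cfg$na_element_rate[na_ids]
  # reporting probability of the non-NA channel, solved so that
  # r + (1 - r) q = p_el; clamped when the target sits below the NA floor
  q <- ifelse(r > 0, pmax(0, pmin(1, (p_el - r) / (1 - r))), p_el)
  u <- stats::runif(nrow(el))
  j <- ifelse(u < r, "not_applicable",
              ifelse(u < r + (1 - r) * q, "reported", "not_reported"))
  ref_items <- cl_item_ids(cl)[
    vapply(cl$items, `[[`, TRUE, "reference_acceptable")
  ]
  is_ref <- el$item_id %in% ref_items & j == "reported"
  if (any(is_ref) && cfg$reference_rate > 0) {
    flip <- stats::runif(sum(is_ref)) < cfg$reference_rate
    j[which(is_ref)[flip]] <- "reported_by_reference"
  }
  # items flagged "not done" carry no reporting
  off <- names(flags)[!flags]
  j[el$item_id %in% off] <- "not_reported"
  stats::setNames(j, el$element_id)
}

# tilt item probabilities so the model's expected adherence shifts by
# `delta` (fraction scale) while staying inside [0, 1]: positive shifts are
# distributed proportional to headroom (1 - p), negative ones proportional
# to p
tilt_probabilities <- function(p, scored_ids, delta) {
  if (delta == 0) return(p)
  ps <- p[scored_ids]
  if (delta > 0) {
    head <- mean(1 - ps)
    if (delta > head + 1e-12) {
      stop_tripod(sprintf(
        "planted effect infeasible: required mean adherence shift %+.1f points exceeds headroom %.1f",
        100 * delta, 100 * head), "tripod_range_error")
    }
    p[scored_ids] <- ps + delta * (1 - ps) / head
  } else {
    room <- mean(ps)
    if (-delta > room + 1e-12) {
      stop_tripod(sprintf(
        "planted effect infeasible: required mean adherence shift %+.1f points exceeds headroom %.1f",
        100 * delta, -100 * room), "tripod_range_error")
    }
    p[scored_ids] <- ps + delta * ps / room
  }
  pmin(pmax(p, 0), 1)
}

sim_cohort <- function(cfg, slopes, reference) {
  cl <- cfg$checklist
  n <- cfg$n_publications
  pub_ids <- sprintf("P%03d", seq_len(n))

  # study types: pre-drawn pool so the model-level mix stays calibrated
  n_second <- stats::rbinom(1, n, cfg$multi_type_rate)
  pool <- sample(STUDY_TYPES, n + n_second, replace = TRUE, prob = cfg$type_mix)
  first_type <- pool[seq_len(n)]
  second_of <- if (n_second > 0) sort(sample.int(n, n_second)) else integer()
  second_type <- pool[n + seq_len(n_second)]
  for (k in seq_along(second_of)) {
    while (second_type[k] == first_type[second_of[k]]) {
      second_type[k] <- sample(STUDY_TYPES, 1, prob = cfg$type_mix)
    }
  }

  pubs <- vector("list", n)
  for (i in seq_len(n)) {
    jif <- stats::rlnorm(1, cfg$jif["meanlog"], cfg$jif["sdlog"])
    prospective <- stats::runif(1) < cfg$prospective_rate
    purpose <- if (stats::runif(1) < cfg$purpose_mix) "prognostic" else "diagnostic"
    domain <- sample(names(cfg$domain_mix), 1, prob = cfg$domain_mix)
    outcome <- if (stats::runif(1) < cfg$all_cause_mortality_rate) {
      "all-cause mortality"
    } else "domain-specific outcome"

    types <- first_type[i]
    if (i %in% second_of) types <- c(types, second_type[match(i, second_of)])

    meta <- lapply(seq_along(types), function(k) {
      list(
        sample_size = max(1L, as.integer(round(stats::rlnorm(
          1, cfg$sample_size["meanlog"], cfg$sample_size["sdlog"]
        )))),
        n_predictors = max(1L, as.integer(round(stats::rlnorm(
          1, cfg$n_predictors["meanlog"], cfg$n_predictors["sdlog"]
        ))))
      )
    })

    # planted linear effect on expected adherence (percentage points),
    # computed from publication covariates and the primary (largest-sample)
    # model's size covariates
    primary <- which.max(vapply(meta, `[[`, 1L, "sample_size"))
    delta <- (
      slopes["jif"] * (jif - reference$jif) +
      slopes["sample_size"] * (meta[[primary]]$sample_size - reference$sample_size) +
      slopes["n_predictors"] * (meta[[primary]]$n_predictors - reference$n_predictors) +
      slopes["prospective"] * (as.numeric(prospective) - reference$prospective)
    ) / 100

    models <- lapply(seq_along(types), function(k) {
      st <- types[k]
      flaggable <- flaggable_items(cl, st)
      p_app <- rep(1, length(flaggable)); names(p_app) <- flaggable
      given <- cfg$conditional_probability[[st]]
      p_app[intersect(names(given), flaggable)] <-
        given[intersect(names(given), flaggable)]
      flags <- stats::runif(length(flaggable)) < p_app
      names(flags) <- flaggable

      cfg_m <- cfg
      if (delta != 0) {
        fake <- structure(list(study_type = st, applicability = flags),
                          class = "model_extraction")
        cfg_m$item_probability <- tilt_probabilities(
          cfg$item_probability, scored_item_set(fake, cl), delta
        )
      }
      model_extraction(
        model_id = sprintf("%s_M%d", pub_ids[i], k),
        publication_id = pub_ids[i],
        study_type = st,
        judgements = sim_model_judgements(cfg_m, st, flags),
        applicability = flags,
        clinical_domain = domain,
        purpose = purpose,
        sample_size = meta[[k]]$sample_size,
        n_predictors = meta[[k]]$n_predictors,
        outcome = outcome,
        checklist = cl, validate = FALSE
      )
    })
    pubs[[i]] <- publication_extraction(
      publication_id = pub_ids[i],
      journal_impact_factor = jif,
      prospective_design = prospective,
      models = models, validate = FALSE
    )
  }
  pubs
}

#' Generate a synthetic extraction cohort
#'
#' Draws a fully valid cohort of publication/model extraction records under
#' the configured study conditions. Element judgements are independent
#' across elements and items, with per-element reporting probabilities
#' solved so each item's completeness matches its configured target.
#' Identical configurations (including seed) generate identical cohorts.
#'
#' @param config a [generator_config()].
#' @return list of [publication_extraction()] records.
#' @examples
#' cohort <- generate_cohort(generator_config(n_publications = 5, seed = 7))
#' length(cohort)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  zero <- c(jif = 0, sample_size = 0, n_predictors = 0, prospective = 0)
  local_seed(config$seed, sim_cohort(
    config, zero,
    list(jif = 5.3, sample_size = 450, n_predictors = 5, prospective = 0)
  ))
}

#' Generate a cohort with planted covariate effects
#'
#' Like [generate_cohort()], but the expected publication adherence depends
#' linearly on the covariates: a slope of 1.5 for `jif` means each unit of
#' journal impact factor above the reference shifts expected adherence by
#' +1.5 percentage points. The shift is realised by tilting the per-item
#' reporting probabilities (proportionally to their headroom), and an
#' infeasible shift — one that would push expected adherence outside
#' \[0, 100\] — raises a range error. With all slopes zero the output is
#' identical to [generate_cohort()].
#'
#' @param config a [generator_config()].
#' @param slopes named numeric: percentage points of adherence per unit of
#'   `jif`, `sample_size`, `n_predictors`, `prospective`.
#' @param reference covariate reference values at which the tilt is zero
#'   (defaults: the calibrated medians).
#' @return list of [publication_extraction()] records.
#' @export
planted_effect_cohort <- function(config,
                                  slopes = c(jif = 0, sample_size = 0,
                                             n_predictors = 0, prospective = 0),
                                  reference = list(jif = 5.3, sample_size = 450,
                                                   n_predictors = 5,
                                                   prospective = 0)) {
  stopifnot(inherits(config, "generator_config"))
  full <- c(jif = 0, sample_size = 0, n_predictors = 0, prospective = 0)
  stopifnot(all(names(slopes) %in% names(full)))
  full[names(slopes)] <- slopes
  local_seed(config$seed, sim_cohort(config, full, reference))
}
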