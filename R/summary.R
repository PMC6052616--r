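# Cohort-level summaries: adherence distributions, per-item classification,
# the adherence regression, and deterministic report rendering.

#' Summarise adherence distributions
#'
#' Computes n, median, 25th/75th percentiles, min and max of adherence (in
#' percent) for the requested strata. `"overall"` and `"purpose"`
#' (diagnostic vs prognostic) summarise publication-level adherence;
#' `"study_type"` summarises model-level adherence per study type, matching
#' how per-type completeness is conventionally tabulated (models, not
#' publications, are the unit there).
#'
#' @param publications list of [publication_extraction()] records.
#' @param stratifier one or more of `"overall"`, `"purpose"`,
#'   `"study_type"`.
#' @param checklist checklist in use.
#' @param percentile_type quantile interpolation mode, passed to
#'   [stats::quantile()]'s `type` (default 7, linear interpolation between
#'   order statistics).
#' @return tibble with columns `stratum`, `n`, `median`, `p25`, `p75`,
#'   `min`, `max`, all percentages on a 0–100 scale.
#' @export
summarize_adherence <- function(publications,
                                stratifier = c("overall", "purpose", "study_type"),
                                checklist = tripod_checklist(),
                                percentile_type = 7) {
  stratifier <- match.arg(stratifier, several.ok = TRUE)
  stopifnot(length(publications) > 0)
  pub_scores <- score_publications(publications, checklist)
  rows <- list()
  one <- function(label, fracs) {
    if (length(fracs) == 0) {
      warning("empty stratum '", label, "' omitted", call. = FALSE)
      return(NULL)
    }
    pct <- 100 * fracs
    q <- stats::quantile(pct, c(0.25, 0.5, 0.75), type = percentile_type,
                         names = FALSE)
    tibble::tibble(
      stratum = label, n = length(pct),
      median = q[2], p25 = q[1], p75 = q[3],
      min = min(pct), max = max(pct)
    )
  }
  if ("overall" %in% stratifier) {
    rows <- c(rows, list(one("overall", pub_scores$fraction)))
  }
  if ("purpose" %in% stratifier) {
    for (p in c("prognostic", "diagnostic")) {
      rows <- c(rows, list(one(p, pub_scores$fraction[pub_scores$purpose == p])))
    }
  }
  if ("study_type" %in% stratifier) {
    model_scores <- score_models(publications, checklist)
    for (st in STUDY_TYPES) {
      rows <- c(rows, list(
        one(st, model_scores$fraction[model_scores$study_type == st])
      ))
    }
  }
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Classify items by adherence level
#'
#' Partitions per-item adherence statistics into well-reported items
#' (percent at or above `high`), poorly reported items (percent below
#' `low`), and the middle band, each sorted by percent descending. With the
#' default thresholds this reproduces the conventional ">= 75% / < 25%"
#' two-column table.
#'
#' @param item_stats tibble as returned by [adherence_table()].
#' @param high,low thresholds in percent, `0 < low < high < 100`.
#' @return list with tibbles `high`, `middle`, `low`.
#' @export
classify_items <- function(item_stats, high = 75, low = 25) {
  stopifnot(0 < low, low < high, high < 100)
  s <- item_stats[!is.na(item_stats$percent), , drop = FALSE]
  s <- s[order(-s$percent, s$item_id), , drop = FALSE]
  list(
    high = s[s$percent >= high, , drop = FALSE],
    middle = s[s$percent < high & s$percent >= low, , drop = FALSE],
    low = s[s$percent < low, , drop = FALSE]
  )
}

#' Regress publication adherence on study covariates
#'
#' Ordinary least-squares fit of publication-level adherence (percent) on
#' sample size, journal impact factor, number of predictors in the final
#' model, and prospective design (0/1), over complete-case publications.
#'
#' @param publications list of [publication_extraction()] records.
#' @param covariates covariate names among `"sample_size"`, `"jif"`,
#'   `"n_predictors"`, `"prospective"`.
#' @param checklist checklist in use.
#' @param log_sample_size fit `log(sample_size)` instead of the raw count.
#' @return object of class `adherence_regression`: a list with
#'   `coefficients` (tibble: term, estimate, std_error, statistic, p_value,
#'   intercept first), `n` (complete-case publications), and the underlying
#'   `fit`.
#' @export
regress_adherence <- function(publications,
                              covariates = c("sample_size", "jif",
                                             "n_predictors", "prospective"),
                              checklist = tripod_checklist(),
                              log_sample_size = FALSE) {
  covariates <- match.arg(covariates, several.ok = TRUE)
  scores <- score_publications(publications, checklist)
  dat <- data.frame(
    adherence = 100 * scores$fraction,
    sample_size = as.numeric(scores$sample_size),
    jif = scores$journal_impact_factor,
    n_predictors = as.numeric(scores$n_predictors),
    prospective = as.numeric(scores$prospective_design)
  )
  if (log_sample_size) dat$sample_size <- log(dat$sample_size)
  dat <- dat[, c("adherence", covariates), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < length(covariates) + 2) {
    stop_tripod("too few complete-case publications for the regression",
                "tripod_degenerate_error")
  }
  fit <- stats::lm(adherence ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_tripod(
      paste0("collinear covariate(s): ", paste(bad, collapse = ", ")),
      "tripod_singular_error"
    )
  }
  sm <- summary(fit)$coefficients
  structure(
    list(
      coefficients = tibble::tibble(
        term = rownames(sm),
        estimate = unname(sm[, "Estimate"]),
        std_error = unname(sm[, "Std. Error"]),
        statistic = unname(sm[, "t value"]),
        p_value = unname(sm[, "Pr(>|t|)"])
      ),
      n = nrow(dat),
      fit = fit
    ),
    class = "adherence_regression"
  )
}

#' @export
print.adherence_regression <- function(x, ...) {
  cat("<adherence_regression> n =", x$n, "complete-case publications\n")
  print(x$coefficients)
  invisible(x)
}

#' Write summary report files
#'
#' Renders deterministic, locale-independent report artifacts into a
#' directory: `adherence_summary.csv`, `item_adherence.csv`, `table1.md`
#' (the high/low adherence table, whole percentages rounded half away from
#' zero), and `regression.csv` when a regression result is supplied.
#'
#' @param out_dir output directory (created if needed).
#' @param summaries tibble from [summarize_adherence()].
#' @param item_stats tibble from [adherence_table()].
#' @param regression optional [regress_adherence()] result.
#' @param high,low classification thresholds for the table.
#' @return character vector of written paths, invisibly.
#' @export
render_tables <- function(out_dir, summaries, item_stats, regression = NULL,
                          high = 75, low = 25) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  s <- summaries
  for (col in c("median", "p25", "p75", "min", "max")) {
    s[[col]] <- round_half_away(s[[col]], 1)
  }
  p <- file.path(out_dir, "adherence_summary.csv")
  readr::write_csv(s, p); paths <- c(paths, p)

  it <- item_stats
  it$percent_rendered <- ifelse(
    is.na(it$percent), NA_character_,
    format_percent(it$n_complete, pmax(it$n_applicable, 1L))
  )
  p <- file.path(out_dir, "item_adherence.csv")
  readr::write_csv(it, p); paths <- c(paths, p)

  cls <- classify_items(item_stats, high = high, low = low)
  fmt_rows <- function(tab) {
    if (nrow(tab) == 0) return("| (none) | |")
    paste0("| ", tab$item_id, " | ",
           format_percent(tab$n_complete, pmax(tab$n_applicable, 1L)), " |")
  }
  lines <- c(
    paste0("# Items reported completely in >= ", high,
           "% or < ", low, "% of models"),
    "",
    paste0("## Complete reporting for >= ", high, "% of the models"),
    "",
    "| TRIPOD item | % |", "|---|---|",
    fmt_rows(cls$high),
    "",
    paste0("## Complete reporting for < ", low, "% of the models"),
    "",
    "| TRIPOD item | % |", "|---|---|",
    fmt_rows(cls$low),
    ""
  )
  p <- file.path(out_dir, "table1.md")
  writeLines(lines, p); paths <- c(paths, p)

  if (!is.null(regression)) {
    p <- file.path(out_dir, "regression.csv")
    reg <- regression$coefficients
    reg$n <- regression$n
    readr::write_csv(reg, p); paths <- c(paths, p)
  }
  invisible(paths)
}
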