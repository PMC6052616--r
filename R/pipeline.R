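# One entry point wiring the pipeline stages: validate -> score ->
# summarize -> report, plus simulate. A JSON run manifest (configuration
# echo, checklist version, seed) accompanies every output so artifacts are
# reproducible from the manifest alone.

write_manifest <- function(out_dir, command, options) {
  manifest <- list(
    command = command,
    package = "tripodscore",
    package_version = as.character(utils::packageVersion("tripodscore")),
    options = options
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  path
}

#' Run a pipeline command
#'
#' Commands:
#' \describe{
#'   \item{`validate`}{read records, write `violations.csv` (empty when
#'     valid); invalid records do not abort this command.}
#'   \item{`score`}{read + validate records, write `model_scores.csv`,
#'     `publication_scores.csv`, `item_adherence.csv`.}
#'   \item{`summarize`}{score plus `adherence_summary.csv`.}
#'   \item{`report`}{everything: scores, summaries, `table1.md`,
#'     `regression.csv`.}
#'   \item{`simulate`}{generate a synthetic cohort and write it as a record
#'     set consumable by the other commands.}
#' }
#'
#' @param command one of `validate`, `score`, `summarize`, `simulate`,
#'   `report`.
#' @param input record path (CSV stem or JSON file); unused by `simulate`.
#' @param out_dir output directory, created if needed.
#' @param format record format, `"csv_long"` or `"json"`.
#' @param checklist_path optional path to a checklist definition (default:
#'   the bundled checklist).
#' @param seed seed for `simulate` (overrides `config$seed` when given).
#' @param config [generator_config()] for `simulate`.
#' @param percentile_type quantile interpolation mode for summaries.
#' @param high,low item classification thresholds in percent.
#' @return invisibly, a list with the written `paths` and the `manifest`
#'   path.
#' @export
run_pipeline <- function(command = c("validate", "score", "summarize",
                                     "simulate", "report"),
                         input = NULL, out_dir,
                         format = c("csv_long", "json"),
                         checklist_path = NULL,
                         seed = NULL, config = NULL,
                         percentile_type = 7, high = 75, low = 25) {
  command <- match.arg(command)
  format <- match.arg(format)
  checklist <- load_checklist(checklist_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  if (command == "simulate") {
    config <- config %||% generator_config(checklist = checklist)
    if (!is.null(seed)) config$seed <- as.integer(seed)
    cohort <- generate_cohort(config)
    stem <- if (format == "csv_long") file.path(out_dir, "cohort") else
      file.path(out_dir, "cohort.json")
    paths <- write_records(cohort, stem, format = format, checklist = checklist)
    manifest <- write_manifest(out_dir, command, list(
      checklist_version = checklist$version,
      format = format,
      seed = config$seed,
      n_publications = config$n_publications,
      type_mix = as.list(config$type_mix),
      multi_type_rate = config$multi_type_rate,
      purpose_mix = config$purpose_mix,
      prospective_rate = config$prospective_rate,
      item_probability = as.list(config$item_probability)
    ))
    return(invisible(list(paths = paths, manifest = manifest)))
  }

  if (is.null(input)) {
    stop_tripod(paste0("command '", command, "' needs an --input record set"),
                "tripod_io_error")
  }
  options <- list(checklist_version = checklist$version, input = input,
                  format = format, percentile_type = percentile_type,
                  high = high, low = low)

  if (command == "validate") {
    violations <- tryCatch(
      validate_records(
        read_records(input, format = format, checklist = checklist,
                     validate = FALSE),
        checklist
      ),
      tripod_error = function(e) {
        tibble::tibble(publication_id = NA_character_,
                       model_id = NA_character_,
                       message = conditionMessage(e))
      }
    )
    p <- file.path(out_dir, "violations.csv")
    readr::write_csv(violations, p)
    manifest <- write_manifest(out_dir, command, options)
    return(invisible(list(paths = p, manifest = manifest,
                          n_violations = nrow(violations))))
  }

  records <- read_records(input, format = format, checklist = checklist)
  if (length(records) == 0) {
    stop_tripod("record set is empty; nothing to score", "tripod_validation_error")
  }
  model_scores <- score_models(records, checklist)
  pub_scores <- score_publications(records, checklist)
  item_stats <- suppressWarnings(
    adherence_table(unlist(lapply(records, `[[`, "models"), recursive = FALSE),
                    checklist)
  )
  item_stats$percent_rendered <- ifelse(
    is.na(item_stats$percent), NA_character_,
    format_percent(item_stats$n_complete, pmax(item_stats$n_applicable, 1L))
  )
  p <- file.path(out_dir, "model_scores.csv")
  readr::write_csv(model_scores, p); paths <- c(paths, p)
  p <- file.path(out_dir, "publication_scores.csv")
  readr::write_csv(pub_scores, p); paths <- c(paths, p)
  p <- file.path(out_dir, "item_adherence.csv")
  readr::write_csv(item_stats, p); paths <- c(paths, p)

  if (command %in% c("summarize", "report")) {
    summaries <- suppressWarnings(summarize_adherence(
      records, c("overall", "purpose", "study_type"),
      checklist = checklist, percentile_type = percentile_type
    ))
    s <- summaries
    for (col in c("median", "p25", "p75", "min", "max")) {
      s[[col]] <- round_half_away(s[[col]], 1)
    }
    p <- file.path(out_dir, "adherence_summary.csv")
    readr::write_csv(s, p); paths <- c(paths, p)
  }
  if (command == "report") {
    regression <- tryCatch(regress_adherence(records, checklist = checklist),
                           tripod_error = function(e) NULL)
    more <- render_tables(out_dir, summaries, item_stats, regression,
                          high = high, low = low)
    paths <- unique(c(paths, more))
  }
  manifest <- write_manifest(out_dir, command, options)
  invisible(list(paths = paths, manifest = manifest))
}
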