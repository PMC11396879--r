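#' Read and validate a subject/metabolite panel CSV
#'
#' Strict reader for the flat per-subject table: comma-separated, UTF-8,
#' `.` decimal, header row mandatory, missing values as empty cells only.
#' Checks the schema (required columns, numeric parseability, unique
#' `subject_id`, reporting offending row numbers), recomputes BMI as
#' weight / height² when `height_m` and `weight_kg` columns are present,
#' derives the obesity flag (BMI >= 30 kg/m²), and warns — without
#' modifying values — when concentrations fall outside configurable
#' physiological bounds.
#'
#' @param path CSV file path.
#' @param required columns that must be present beyond `subject_id`.
#' @param bounds named list of `c(lower, upper)` physiological plausibility
#'   ranges (µmol/L) used for warnings.
#' @return validated data frame; attribute `n_out_of_bounds` counts warned
#'   values per analyte.
#' @export
read_panel_csv <- function(path,
                           required = c("valine", "leucine", "isoleucine",
                                        "alanine", "citrate", "glyca", "shdlp"),
                           bounds = panel_bounds()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", na.strings = "")
  if (!"subject_id" %in% names(raw)) {
    stop("missing required column: subject_id", call. = FALSE)
  }
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(raw$subject_id) | duplicated(raw$subject_id, fromLast = TRUE)
  if (any(dup)) {
    stop("duplicate subject_id '", raw$subject_id[dup][1L], "' at rows ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  }
  numeric_cols <- intersect(
    c(required, "age", "bmi", "height_m", "weight_kg", "edss", "t25fw",
      mri_measures()),
    names(raw))
  for (col in numeric_cols) {
    if (is.character(raw[[col]])) {
      parsed <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(!is.na(raw[[col]]) & is.na(parsed))
      if (length(bad) > 0L) {
        stop(sprintf("column '%s' has unparseable numeric values at rows %s",
                     col, paste(bad, collapse = ", ")), call. = FALSE)
      }
      raw[[col]] <- parsed
    }
    raw[[col]] <- as.double(raw[[col]])
  }
  if (all(c("height_m", "weight_kg") %in% names(raw))) {
    raw$bmi <- raw$weight_kg / raw$height_m^2
  }
  if ("bmi" %in% names(raw)) raw$obese <- !is.na(raw$bmi) & raw$bmi >= 30
  n_oob <- integer(0)
  for (a in intersect(names(bounds), names(raw))) {
    b <- bounds[[a]]
    oob <- sum(!is.na(raw[[a]]) & (raw[[a]] < b[1L] | raw[[a]] > b[2L]))
    if (oob > 0L) {
      warning(sprintf("%d value(s) of '%s' outside plausible range [%g, %g] µmol/L",
                      oob, a, b[1L], b[2L]), call. = FALSE)
    }
    n_oob[a] <- oob
  }
  attr(raw, "n_out_of_bounds") <- n_oob
  raw
}

#' @rdname read_panel_csv
#' @export
panel_bounds <- function() {
  list(valine = c(50, 600), leucine = c(30, 400), isoleucine = c(10, 250),
       alanine = c(100, 900), citrate = c(20, 400), glyca = c(100, 1200),
       shdlp = c(1, 60))
}

write_result_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  path
}

#' Run the whole pipeline: simulate, score, analyze, report
#'
#' Executes the end-to-end workflow under a single root seed and writes all
#' artifacts to `outdir`: `cohort.csv` (simulated subjects with metabolite
#' panel and MRI volumetrics), `scores.csv` (panel plus the seven score
#' columns), the three association tables (`table_group.csv`,
#' `table_disability.csv`, `table_mri.csv`), and `manifest.json` — the run
#' manifest with the config snapshot, root seed, package version, per-file
#' MD5 digests, and per-stage row/warning counts. Re-running with the same
#' config and seed reproduces byte-identical CSVs (and hence digests).
#'
#' @param config a [cohort_config()].
#' @param seed integer root seed.
#' @param outdir output directory (created if absent).
#' @param anchors score anchors.
#' @return invisibly, the manifest list.
#' @export
end_to_end <- function(config = cohort_config(), seed = 1L,
                       outdir = "metavulx_run", anchors = default_anchors()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  manifest <- tryCatch({
    demo <- generate_demographics(config, seed)
    panel <- generate_metabolites(demo, config, seed)
    panel <- generate_mri(panel, config, seed)
    cohort_path <- write_result_csv(panel, file.path(outdir, "cohort.csv"))

    stage <- "score"
    scored <- score_panel(panel, anchors)
    scores_path <- write_result_csv(scored, file.path(outdir, "scores.csv"))

    stage <- "analyze"
    res <- run_full_association_suite(scored)
    paths <- c(
      cohort_path, scores_path,
      write_result_csv(res$group, file.path(outdir, "table_group.csv")),
      write_result_csv(res$disability, file.path(outdir, "table_disability.csv")),
      write_result_csv(res$mri, file.path(outdir, "table_mri.csv"))
    )

    stage <- "report"
    man <- list(
      package = "metavulx",
      version = as.character(utils::packageVersion("metavulx")),
      seed = as.integer(seed),
      rng = "Mersenne-Twister (per-stage child streams)",
      config = unclass_config(config),
      anchors = lapply(unclass(anchors), unlist),
      rows = list(cohort = nrow(panel), ms = sum(panel$group != "HC")),
      warnings = list(
        metabolite_floored = as.list(attr(panel, "n_floored") %||% integer(0)),
        mri_floored = attr(panel, "n_floored_mri") %||% 0L
      ),
      digests = as.list(tools::md5sum(paths))
    )
    jsonlite::write_json(man, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unclass_config <- function(config) {
  cfg <- unclass(config)
  cfg$n <- as.list(cfg$n)
  cfg$demographics <- lapply(cfg$demographics, function(d) lapply(d, as.list))
  cfg
}
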