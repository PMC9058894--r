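#' Read a patient manifest into cohorts
#'
#' Accepts CSV or TSV with required columns `patient_id`, `cohort_id`,
#' `label`, `slide_path` (an optional `microns_per_pixel` column
#' overrides image metadata). Labels are encoded 1 = MSI/dMMR,
#' 0 = MSS/pMMR. Rows with a missing label -- and, when `check_files` is
#' `TRUE`, rows whose slide image does not exist -- are excluded and
#' counted in a consort-style exclusion table rather than silently
#' dropped. Duplicate patient ids (within or across cohorts) are a hard
#' error.
#'
#' @param path manifest path (`.csv` or `.tsv`).
#' @param check_files verify that every `slide_path` exists (default
#'   `TRUE`).
#' @return List: `cohorts` (named list of per-cohort data frames),
#'   `exclusions` (data frame `patient_id`, `reason`), `n_input`,
#'   `n_kept`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character"))
  required <- c("patient_id", "cohort_id", "label", "slide_path")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id in manifest: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]),
               collapse = ", "), call. = FALSE)

  reason <- rep(NA_character_, nrow(df))
  bad_label <- is.na(df$label) | !(as.character(df$label) %in% c("0", "1"))
  reason[bad_label] <- "missing MSI/dMMR label"
  if (check_files) {
    no_img <- !bad_label & !file.exists(df$slide_path)
    reason[no_img] <- "missing whole-slide image"
  }
  excl <- data.frame(patient_id = df$patient_id[!is.na(reason)],
                     reason = reason[!is.na(reason)],
                     stringsAsFactors = FALSE)
  kept <- df[is.na(reason), , drop = FALSE]
  kept$label <- as.integer(kept$label)
  cohorts <- split(kept, kept$cohort_id)
  list(cohorts = cohorts, exclusions = excl,
       n_input = nrow(df), n_kept = nrow(kept))
}

# small deterministic rolling hash of an R object's deparsed form,
# embedded in outputs so runs are auditable
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a results bundle to disk
#'
#' Emits the standard outputs of an evaluation run: a metrics CSV (one
#' row per cohort x policy, formatted like a multi-cohort triage table),
#' a per-cohort AUROC CSV, a per-patient score CSV, policy YAMLs, and a
#' JSON summary embedding the config hash and seed. Files are written
#' atomically (temp file + rename), so an identical re-run overwrites
#' byte-identically.
#'
#' @param result a `loco_result` (or a list with compatible `metrics`,
#'   `auroc`, `patient_scores`, `policies`, `seed` elements).
#' @param out_dir output directory (created if missing).
#' @param config optional run configuration recorded in the summary.
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(result, out_dir, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0)
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  hash <- config_hash(list(config = config, seed = result$seed))
  atomically <- function(name, writer) {
    final <- file.path(out_dir, name)
    tmp <- paste0(final, ".tmp")
    writer(tmp)
    file.rename(tmp, final)
    final
  }
  paths <- c(
    atomically("metrics.csv", function(p)
      utils::write.csv(result$metrics, p, row.names = FALSE)),
    atomically("auroc.csv", function(p)
      utils::write.csv(result$auroc, p, row.names = FALSE)),
    atomically("patient_scores.csv", function(p)
      utils::write.csv(result$patient_scores, p, row.names = FALSE)),
    atomically("policies.yaml", function(p)
      write_policies(unlist(unname(result$policies), recursive = FALSE), p)),
    atomically("summary.json", function(p)
      jsonlite::write_json(list(
        config_hash = hash, seed = result$seed,
        n_patients = nrow(result$patient_scores),
        n_cohorts = nrow(result$auroc),
        auroc = result$auroc), p, auto_unbox = TRUE, digits = NA,
        dataframe = "rows", na = "null")))
  log_line <- sprintf("run %s seed %s: %d patients, %d cohorts",
                      hash, result$seed, nrow(result$patient_scores),
                      nrow(result$auroc))
  writeLines(log_line, file.path(out_dir, "run.log"))
  invisible(c(paths, file.path(out_dir, "run.log")))
}

#' Read a run configuration YAML
#'
#' Fills unspecified fields with package defaults: 256 um / 512 px
#' tiling, QC threshold 4, tile threshold 0.5, target sensitivity 0.95,
#' fixed thresholds 0.25/0.50/0.75, 1000 bootstrap resamples at the 95%
#' level, tile cap 500, seed 1.
#'
#' @param path YAML path, or `NULL` for pure defaults.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    tile_edge_um = 256, out_edge_px = 512, qc_threshold = 4,
    tile_threshold = 0.5, tile_cap = 500,
    target_sensitivity = 0.95, fixed_thresholds = c(0.25, 0.50, 0.75),
    n_boot = 1000, level = 0.95, seed = 1L,
    normalization_target = NULL, out_dir = "results")
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  utils::modifyList(defaults, user)
}

#' Score a manifest of slides end to end
#'
#' Convenience driver used by the command-line interface and tests:
#' reads slides for each patient, tessellates, applies QC, optionally
#' Macenko-normalizes to a target context, caps tiles per patient,
#' scores them, and aggregates to patient level. Patients whose tiles
#' are all removed by QC are recorded as unevaluable exclusions.
#'
#' @param cohort data frame with `patient_id`, `cohort_id`, `label`,
#'   `slide_path` and optional `microns_per_pixel`.
#' @param scorer a scorer accepted by [score_tiles()].
#' @param config run configuration list, see [read_run_config()].
#' @param target_context optional [stain_context()] for normalization.
#' @return List: `scores` (patient-level data frame), `exclusions`.
#' @export
score_manifest_cohort <- function(cohort, scorer,
                                  config = read_run_config(),
                                  target_context = NULL) {
  rows <- list(); excl <- list()
  for (i in seq_len(nrow(cohort))) {
    pat <- cohort[i, ]
    mpp <- if ("microns_per_pixel" %in% names(pat)) pat$microns_per_pixel
           else NULL
    tiles <- unlist(lapply(strsplit(pat$slide_path, ";")[[1]], function(sp) {
      slide <- read_slide(sp, microns_per_pixel = mpp,
                          patient_id = pat$patient_id)
      tl <- tessellate(slide, config$tile_edge_um, config$out_edge_px)
      qc <- qc_filter(tl, threshold = config$qc_threshold)
      qc$kept
    }), recursive = FALSE)
    if (length(tiles) == 0L) {
      excl[[length(excl) + 1L]] <- data.frame(
        patient_id = pat$patient_id,
        reason = "no tiles passed quality control",
        stringsAsFactors = FALSE)
      next
    }
    if (!is.null(target_context)) {
      src <- estimate_stain_matrix(do.call(rbind, lapply(tiles, function(t)
        flatten_rgb(t$pixels))))
      tiles <- lapply(tiles, macenko_normalize, source = src,
                      target = target_context)
    }
    tiles <- sample_patient_tiles(tiles, cap = config$tile_cap,
                                  seed = config$seed + i)
    p <- score_tiles(scorer, tiles)
    rows[[length(rows) + 1L]] <- aggregate_patient(
      p, tile_threshold = config$tile_threshold,
      patient_id = pat$patient_id, cohort_id = pat$cohort_id,
      label = pat$label)
  }
  list(scores = do.call(rbind, rows),
       exclusions = if (length(excl)) do.call(rbind, excl)
                    else data.frame(patient_id = character(),
                                    reason = character()))
}
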