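# Pipeline orchestration: per-eye processing (threshold -> metrics), study
# runs over many eyes, run configuration, and structured provenance logging.

#' Run configuration
#'
#' Collects every tunable of the per-eye pipeline and the statistics layer.
#' Values default to the published protocol: 3 mm field, full-range unit-step
#' threshold sweep, 10-point minimum fit segments, fit window capped at 0.9
#' of the intensity maximum, 1-3 mm parafoveal annulus, FDR 0.05.
#'
#' @param fov_mm field of view in mm.
#' @param t_min lower sweep bound.
#' @param t_max upper sweep bound (`NULL` = `2^bit_depth - 2`).
#' @param min_segment minimum points per regression segment.
#' @param fit_upper_frac upper fit-window bound as a fraction of the
#'   intensity maximum.
#' @param annulus an [annulus_spec()].
#' @param fdr false discovery rate for post-hoc tests.
#' @param seed integer seed for anything stochastic.
#' @param out_dir output directory for study runs.
#' @return list of class `octa_config`.
#' @export
octa_config <- function(fov_mm = 3.0, t_min = 1L, t_max = NULL,
                        min_segment = 10L, fit_upper_frac = 0.9,
                        annulus = annulus_spec(), fdr = 0.05, seed = 1L,
                        out_dir = ".") {
  structure(list(fov_mm = fov_mm, t_min = as.integer(t_min),
                 t_max = if (!is.null(t_max)) as.integer(t_max),
                 min_segment = as.integer(min_segment),
                 fit_upper_frac = fit_upper_frac, annulus = annulus,
                 fdr = fdr, seed = as.integer(seed), out_dir = out_dir),
            class = "octa_config")
}

#' Read / write a run configuration as JSON
#'
#' @param path JSON file.
#' @return an [octa_config()].
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ann <- annulus_spec(
    outer_diameter_mm = x$annulus$outer_diameter_mm %||% 3.0,
    inner_diameter_mm = x$annulus$inner_diameter_mm %||% 1.0,
    center_px = x$annulus$center_px)
  octa_config(fov_mm = x$fov_mm %||% 3.0, t_min = x$t_min %||% 1L,
              t_max = x$t_max, min_segment = x$min_segment %||% 10L,
              fit_upper_frac = x$fit_upper_frac %||% 0.9, annulus = ann,
              fdr = x$fdr %||% 0.05, seed = x$seed %||% 1L,
              out_dir = x$out_dir %||% ".")
}

#' @rdname read_config
#' @param config an [octa_config()].
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(x, unclass_deep) else x
}

config_hash <- function(config) {
  # cheap stable digest: sum of byte values of the serialized config
  s <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = NA,
                        null = "null")
  raw <- charToRaw(as.character(s))
  sprintf("%08x", sum(as.numeric(raw) * seq_along(raw)) %% 2^31)
}

#' Process one eye: DCP threshold then metric set
#'
#' Computes the VLD-based threshold from the DCP slab, applies it to every
#' layer, and returns the metric set plus full fit diagnostics.  If
#' `qc = list(q_score=, ssi=, sex=, cmt_um=)` is supplied the eye must pass
#' [qc_eligible()].
#'
#' @param images named list of [enface_image()]s (`SCP`, `MCP`, `DCP`,
#'   optional `RETINA`).
#' @param config an [octa_config()].
#' @param faz_mask optional traced FAZ mask.
#' @param faz_seed optional assisted-mode seed `c(x, y)`.
#' @param qc optional QC record.
#' @param eye_id identifier used in error messages and logs.
#' @return list with `metrics` (a `metric_set`), `threshold_result`, and
#'   `log` (one structured provenance record).
#' @export
run_eye <- function(images, config = octa_config(), faz_mask = NULL,
                    faz_seed = NULL, qc = NULL, eye_id = "eye") {
  if (!"DCP" %in% names(images))
    stop("eye ", eye_id, ": missing required plexus slab DCP")
  if (!is.null(qc)) {
    elig <- qc_eligible(qc)
    if (!elig$eligible)
      stop("eye ", eye_id, ": fails QC (",
           paste(elig$failed, collapse = ", "), ")")
  }
  tr <- tryCatch(
    compute_vld_threshold(images$DCP, t_min = config$t_min,
                          t_max = config$t_max,
                          min_segment = config$min_segment,
                          fit_upper_frac = config$fit_upper_frac),
    error = function(e) stop("eye ", eye_id, ": ", conditionMessage(e),
                             call. = FALSE))
  ms <- tryCatch(
    compute_metricset(images, spec = config$annulus, result = tr,
                      faz_mask = faz_mask, faz_seed = faz_seed),
    error = function(e) stop("eye ", eye_id, ": ", conditionMessage(e),
                             call. = FALSE))
  log <- list(eye_id = eye_id, threshold = tr$threshold,
              intersection_x = tr$fit$intersection_x,
              breakpoint = tr$fit$breakpoint, fit_sse = tr$fit$total_sse,
              config_hash = config_hash(config),
              qc = if (!is.null(qc)) qc_eligible(qc)$eligible else NA)
  list(metrics = ms, threshold_result = tr, log = log)
}

metricset_row <- function(eye_id, ms) {
  row <- data.frame(eye_id = eye_id,
                    SCP_VD = ms$vd_pct[["SCP"]], MCP_VD = ms$vd_pct[["MCP"]],
                    DCP_VD = ms$vd_pct[["DCP"]],
                    SCP_VLD = ms$vld_per_mm[["SCP"]],
                    SCP_AFI = ms$afi[["SCP"]], MCP_AFI = ms$afi[["MCP"]],
                    DCP_AFI = ms$afi[["DCP"]], FAZ = ms$faz_mm2,
                    THRESHOLD = ms$threshold_used,
                    stringsAsFactors = FALSE)
  row
}

#' Run a full study: images per eye, then cohort statistics
#'
#' Two entry modes.  Image mode: `eye_table` has one row per eye plus an
#' `image_dir` containing `<eye_id>_SCP.png`, `<eye_id>_MCP.png`,
#' `<eye_id>_DCP.png` (and optionally `<eye_id>_RETINA.png`); each eye is
#' processed with [run_eye()] and the computed parameters joined onto the
#' table.  Statistics mode (`image_dir = NULL`): `eye_table` already carries
#' parameter columns.  Per-eye failures never abort the study; failed eyes
#' are dropped from the report and recorded in `failures`.
#'
#' @param eye_table eye data.frame (see [load_parameter_table()]).
#' @param config an [octa_config()].
#' @param image_dir directory of per-eye slabs, or `NULL`.
#' @param params parameters to analyze (default: the computed OCTA set).
#' @return list with `per_eye` (augmented table), `report`
#'   (a `cohort_report`), `failures` (named character), `logs`.
#' @export
run_study <- function(eye_table, config = octa_config(), image_dir = NULL,
                      params = c("SCP_VD", "MCP_VD", "DCP_VD", "SCP_VLD",
                                 "SCP_AFI", "MCP_AFI", "DCP_AFI")) {
  validate_eye_table(eye_table)
  failures <- character(0)
  logs <- list()
  if (!is.null(image_dir)) {
    rows <- list()
    for (i in seq_len(nrow(eye_table))) {
      id <- eye_table$eye_id[i]
      res <- tryCatch({
        images <- load_eye_images(image_dir, id, config$fov_mm)
        run_eye(images, config, qc = eye_table[i, ], eye_id = id)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[id] <- conditionMessage(res)
        next
      }
      logs[[id]] <- res$log
      rows[[id]] <- metricset_row(id, res$metrics)
    }
    if (!length(rows)) stop("no eye processed successfully")
    per_eye <- merge(eye_table, do.call(rbind, rows), by = "eye_id")
  } else {
    per_eye <- eye_table
  }
  params <- intersect(params, names(per_eye))
  if (!length(params)) stop("no analyzable parameter columns present")
  report <- run_cohort_report(per_eye, params, fdr = config$fdr)
  list(per_eye = per_eye, report = report, failures = failures, logs = logs)
}

load_eye_images <- function(dir, eye_id, fov_mm) {
  find1 <- function(plexus) {
    for (ext in c("png", "tif", "tiff")) {
      p <- file.path(dir, sprintf("%s_%s.%s", eye_id, plexus, ext))
      if (file.exists(p)) return(p)
    }
    NULL
  }
  out <- list()
  for (p in c("SCP", "MCP", "DCP", "RETINA")) {
    f <- find1(p)
    if (!is.null(f)) out[[p]] <- load_enface(f, p, fov_mm)
  }
  need <- setdiff(c("SCP", "MCP", "DCP"), names(out))
  if (length(need))
    stop("missing plexus slab(s) for ", eye_id, ": ",
         paste(need, collapse = ", "))
  out
}

#' Append structured provenance records to a JSON-lines log
#'
#' @param logs list of per-eye log records (from [run_eye()]).
#' @param path output file; one JSON object per line.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(logs, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (rec in logs)
    writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                             digits = NA, null = "null")),
               con)
  invisible(path)
}
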