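#' Read a treatment plan
#'
#' Dispatches on content: files starting with the DICOM magic (128-byte
#' preamble + `DICM`) are parsed as DICOM RT Plan objects, anything else as
#' the package's JSON plan dialect (see [write_plan_json()]).
#'
#' Setup / non-treatment beams in DICOM plans are skipped. The reader
#' enforces the control-point invariants and fails with `"corrupt control
#' points"` (non-monotone cumulative weight), `"invalid meterset"` (zero
#' beam MU) or `"unsupported plan"` (no MLC sequence).
#'
#' @param path file path.
#' @return A [plan_record()].
#' @export
read_rtplan <- function(path) {
  if (!file.exists(path)) stopf("read_rtplan: no such file: %s", path)
  plan <- if (is_dicom_file(path)) dicom_read_rtplan(path) else read_plan_json(path)
  check_plan_on_read(plan)
  plan
}

#' Write a treatment plan
#'
#' @param plan a [plan_record()].
#' @param path output path.
#' @param format `"json"` for the plain-text dialect, `"dicom"` for a
#'   DICOM RT Plan Storage object (explicit VR little endian).
#' @return `path`, invisibly.
#' @export
write_rtplan <- function(plan, path, format = c("json", "dicom")) {
  format <- match.arg(format)
  if (format == "json") write_plan_json(plan, path) else dicom_write_rtplan(plan, path)
  invisible(path)
}

is_dicom_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 132L)
  length(hdr) == 132L && rawToChar(hdr[129:132]) == "DICM"
}

check_plan_on_read <- function(plan) {
  v <- validate_plan(plan)
  if (length(v) == 0) {
    return(invisible(plan))
  }
  if (any(grepl("cum_weight decreases|first cum_weight|last cum_weight", v))) {
    stopf("corrupt control points: %s", v[grep("cum_weight", v)[1]])
  }
  if (any(grepl("invalid meterset", v))) {
    stopf("invalid meterset: %s", v[grep("invalid meterset", v)[1]])
  }
  stopf("invalid plan: %s", v[1])
}

# --- JSON plan dialect -------------------------------------------------------
#
# One JSON document mirroring plan_record:
# {
#   "format": "vmatqa-plan/1",
#   "plan_id": ..., "fraction_dose_gy": ..., "n_fractions": ...,
#   "beams": [ { "beam_id", "total_mu", "energy_label", "site_label",
#                "geometry": {"boundaries": [...]},
#                "control_points": [ {"index", "cum_weight", "gantry_deg",
#                                     "jaw_x": [x1,x2], "jaw_y": [y1,y2],
#                                     "left": [...], "right": [...]} ] } ]
# }

#' Write the JSON plan dialect
#' @param plan a [plan_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan_json <- function(plan, path) {
  doc <- list(
    format = "vmatqa-plan/1",
    plan_id = plan$plan_id,
    fraction_dose_gy = plan$fraction_dose_gy,
    n_fractions = plan$n_fractions,
    beams = lapply(plan$beams, function(b) {
      list(
        beam_id = b$beam_id,
        total_mu = b$total_mu,
        energy_label = b$energy_label,
        site_label = b$site_label,
        geometry = list(boundaries = b$geometry$boundaries),
        control_points = lapply(b$cps, function(cp) {
          list(
            index = cp$index, cum_weight = cp$cum_weight,
            gantry_deg = cp$gantry_deg,
            jaw_x = cp$jaw_x, jaw_y = cp$jaw_y,
            left = cp$left, right = cp$right
          )
        })
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read the JSON plan dialect
#' @param path file path.
#' @return A [plan_record()].
#' @export
read_plan_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(doc$format, "vmatqa-plan/1")) {
    stopf("unsupported plan: not a vmatqa-plan/1 document")
  }
  beams <- lapply(doc$beams, function(b) {
    geom <- mlc_geometry(b$geometry$boundaries)
    cps <- lapply(b$control_points, function(cp) {
      control_point(
        index = cp$index, cum_weight = cp$cum_weight,
        left = cp$left, right = cp$right,
        jaw_x = cp$jaw_x, jaw_y = cp$jaw_y,
        gantry_deg = cp$gantry_deg %||% 0
      )
    })
    beam_record(
      beam_id = b$beam_id, total_mu = b$total_mu, cps = cps, geometry = geom,
      energy_label = b$energy_label %||% "6X-FFF",
      site_label = b$site_label %||% NA_character_
    )
  })
  plan_record(doc$plan_id, beams, doc$fraction_dose_gy, doc$n_fractions %||% 1L)
}

# --- QA / metrics tables -----------------------------------------------------

#' Fixed metric column order of the 27-metric vector
#'
#' @return Character vector of the 27 metric names in their canonical CSV
#'   order.
#' @export
metric_names <- function() {
  c(
    "TotalMU", "PMU", "NumSegments", "AvgLeafGap", "AAJA", "MAXJ",
    "JawTrackingPct", "M", "LSV", "AAV", "MCS", "MCSv", "LT", "LTMCS",
    "BA", "BI", "BM", "EM", "EAM", "MAD", "UnionArea",
    "SAS2", "SAS5", "SAS10", "SAS20", "APV", "LAAM"
  )
}

#' Read a QA results table
#'
#' Expects a CSV with header `plan_id, beam_id, site, gpr_percent, criterion`
#' (`site`/`criterion` optional). Every `gpr_percent` must be in `[0, 100]`.
#'
#' @param path CSV path.
#' @return A `data.frame` of QA records, one row per beam.
#' @export
read_qa_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plan_id", "beam_id", "gpr_percent")
  if (!all(need %in% names(df))) {
    stopf("QA table must have columns %s", paste(need, collapse = ", "))
  }
  df$gpr_percent <- as.numeric(df$gpr_percent)
  bad <- which(!is.finite(df$gpr_percent) | df$gpr_percent < 0 | df$gpr_percent > 100)
  if (length(bad)) {
    stopf(
      "invalid GPR: row %d has gpr_percent = %s", bad[1],
      format(df$gpr_percent[bad[1]])
    )
  }
  if (is.null(df$site)) df$site <- NA_character_
  if (is.null(df$criterion)) df$criterion <- NA_character_
  df[, c("plan_id", "beam_id", "site", "gpr_percent", "criterion")]
}

#' Write a QA results table
#' @param qa data.frame as returned by [read_qa_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_qa_table <- function(qa, path) {
  write.csv(qa, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write / read the metrics table
#'
#' Columns are `plan_id`, `beam_id` then exactly the 27 metrics of
#' [metric_names()] in order. Writing then reading is the identity (to
#' double precision round-trip).
#'
#' @param metrics data.frame with columns `plan_id`, `beam_id` and the 27
#'   metric columns.
#' @param path CSV path.
#' @return `path` (write) / the data.frame (read).
#' @export
write_metrics_csv <- function(metrics, path) {
  cols <- c("plan_id", "beam_id", metric_names())
  missing <- setdiff(cols, names(metrics))
  if (length(missing)) {
    stopf("metrics table lacks columns: %s", paste(missing, collapse = ", "))
  }
  out <- metrics[, cols]
  for (m in metric_names()) {
    out[[m]] <- formatC(out[[m]], digits = 17, format = "g")
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  cols <- c("plan_id", "beam_id", metric_names())
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stopf("metrics table lacks columns: %s", paste(missing, collapse = ", "))
  }
  for (m in metric_names()) df[[m]] <- as.numeric(df[[m]])
  df[, cols]
}

#' Join metrics and QA tables on (plan_id, beam_id)
#'
#' @param metrics metrics data.frame ([read_metrics_csv()]).
#' @param qa QA data.frame ([read_qa_table()]).
#' @return Merged data.frame, one row per matched beam.
#' @export
join_metrics_qa <- function(metrics, qa) {
  key_m <- paste(metrics$plan_id, metrics$beam_id, sep = "\r")
  key_q <- paste(qa$plan_id, qa$beam_id, sep = "\r")
  unmatched <- setdiff(key_q, key_m)
  if (length(unmatched)) {
    stopf(
      "unmatched record: %s", paste(gsub("\r", "/", head(unmatched, 5)),
      collapse = ", ")
    )
  }
  merged <- merge(metrics, qa, by = c("plan_id", "beam_id"), sort = FALSE)
  merged[order(match(paste(merged$plan_id, merged$beam_id, sep = "\r"), key_m)), ]
}
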