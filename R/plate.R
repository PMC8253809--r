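# Plate-level data handling: layout/read I/O, log2 transform, % activity
# normalization against DMSO / staurosporine controls, and z' quality control.

.roles <- c("negative_control", "positive_control", "compound", "empty")

#' Read a plate layout file
#'
#' Layout files are comma-separated with header
#' `plate_id,row,col,role,compound_id,concentration_M`. Rows and columns are
#' 1-based; `role` is one of `negative_control`, `positive_control`,
#' `compound`, `empty`. Compound wells must carry a compound identifier and a
#' positive molar concentration; control and empty wells carry neither.
#'
#' @param path path to the layout CSV.
#' @return a validated layout `data.frame`.
#' @export
read_plate_layout <- function(path) {
  layout <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(plate_id = "character",
                                           compound_id = "character"))
  layout$compound_id[!is.na(layout$compound_id) &
                       layout$compound_id == ""] <- NA_character_
  validate_layout(layout)
}

#' Read a plate luminescence file
#'
#' Read files are comma-separated with header
#' `plate_id,cell_line,row,col,rlu`, one row per measured well. RLU values
#' must be positive.
#'
#' @param path path to the reads CSV.
#' @return a reads `data.frame`.
#' @export
read_plate_reads <- function(path) {
  reads <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(plate_id = "character",
                                          cell_line = "character"))
  validate_reads(reads)
}

#' Validate a plate layout table
#'
#' Checks the layout invariants: known roles, unique `(plate_id, row, col)`
#' keys, compound wells with compound ID and positive concentration, and
#' control/empty wells with neither.
#'
#' @param layout layout `data.frame`.
#' @return the layout, invisibly usable downstream.
#' @export
validate_layout <- function(layout) {
  need <- c("plate_id", "row", "col", "role", "compound_id", "concentration_M")
  missing_cols <- setdiff(need, names(layout))
  if (length(missing_cols) > 0) {
    stopf("layout is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  bad_role <- setdiff(unique(layout$role), .roles)
  if (length(bad_role) > 0) {
    stopf("unknown well role(s): %s", paste(bad_role, collapse = ", "))
  }
  key <- paste(layout$plate_id, layout$row, layout$col)
  if (anyDuplicated(key)) {
    stopf("duplicate (plate_id, row, col) entries in layout")
  }
  cmp <- layout$role == "compound"
  if (any(cmp & (is.na(layout$compound_id) |
                 is.na(layout$concentration_M) |
                 layout$concentration_M <= 0))) {
    stopf("compound wells must have a compound_id and concentration_M > 0")
  }
  if (any(!cmp & (!is.na(layout$compound_id) | !is.na(layout$concentration_M)))) {
    stopf("control/empty wells must not carry compound_id or concentration_M")
  }
  layout
}

validate_reads <- function(reads) {
  need <- c("plate_id", "cell_line", "row", "col", "rlu")
  missing_cols <- setdiff(need, names(reads))
  if (length(missing_cols) > 0) {
    stopf("reads table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(reads$rlu)) || any(reads$rlu <= 0)) {
    stopf("all RLU values must be finite and positive")
  }
  reads
}

#' Transform plate reads to the analysis scale
#'
#' Single-agent screens are analysed on the log2 RLU scale; combination
#' screens on the linear RLU scale. The transformed value is added as a
#' `value` column and the scale recorded in `scale_used`.
#'
#' @param reads reads `data.frame` (see [read_plate_reads()]).
#' @param scale `"log2"` or `"linear"`.
#' @return the reads with `value` and `scale_used` columns.
#' @export
transform_plate <- function(reads, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  validate_reads(reads)
  if (scale == "log2") {
    reads$value <- log2(reads$rlu)
  } else {
    reads$value <- reads$rlu
  }
  reads$scale_used <- scale
  reads
}

# Join transformed reads to the layout on (plate_id, row, col); every read
# well must exist in the layout.
.join_layout <- function(plate, layout) {
  if (is.null(plate$value)) {
    stopf("plate reads must be passed through transform_plate() first")
  }
  idx <- match(paste(plate$plate_id, plate$row, plate$col),
               paste(layout$plate_id, layout$row, layout$col))
  if (anyNA(idx)) {
    stopf("%d read well(s) are absent from the layout", sum(is.na(idx)))
  }
  plate$role <- layout$role[idx]
  plate$compound_id <- layout$compound_id[idx]
  plate$concentration_M <- layout$concentration_M[idx]
  plate
}

.control_means <- function(df, plate_id) {
  neg <- df$value[df$role == "negative_control"]
  pos <- df$value[df$role == "positive_control"]
  if (length(neg) < 2 || length(pos) < 2) {
    stopf("plate %s needs >= 2 negative and >= 2 positive control wells",
          plate_id)
  }
  list(neg = neg, pos = pos,
       mean_neg = mean(neg), mean_pos = mean(pos))
}

#' Normalize a transformed plate to percent activity
#'
#' Converts each compound well to % activity relative to the plate's own
#' controls: `100 * (mean(neg) - value) / (mean(neg) - mean(pos))`, computed
#' on the transformed scale. 0% corresponds to the negative (vehicle) control
#' level and 100% to the positive (cytotoxic) control level; values are not
#' clamped, so over- and under-shoot are carried into curve fitting.
#'
#' @param plate transformed reads (one or more plates), from
#'   [transform_plate()].
#' @param layout validated layout covering every read well.
#' @return a `data.frame` with one row per compound well:
#'   `plate_id, cell_line, row, col, compound_id, concentration_M,
#'   activity_pct, scale_used`.
#' @export
percent_activity <- function(plate, layout) {
  layout <- validate_layout(layout)
  plate <- .join_layout(plate, layout)
  pieces <- lapply(split(plate, plate$plate_id), function(df) {
    ctrl <- .control_means(df, df$plate_id[1])
    denom <- ctrl$mean_neg - ctrl$mean_pos
    if (denom == 0) {
      stopf("plate %s: negative and positive control means coincide; %s",
            df$plate_id[1], "normalization is undefined")
    }
    cmp <- df[df$role == "compound", , drop = FALSE]
    cmp$activity_pct <- 100 * (ctrl$mean_neg - cmp$value) / denom
    cmp[, c("plate_id", "cell_line", "row", "col", "compound_id",
            "concentration_M", "activity_pct", "scale_used")]
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Compute the z-prime quality-control statistic per plate
#'
#' z' = 1 - (3*sd(neg) + 3*sd(pos)) / |mean(neg) - mean(pos)|, computed on
#' the transformed scale with the sample (n-1) standard deviation. z' is at
#' most 1; values near 0.5 and above indicate a robust assay window. Plates
#' whose control means coincide get `zprime = NA` with an error note.
#'
#' @param plate transformed reads, from [transform_plate()].
#' @param layout validated layout.
#' @return a `data.frame` with columns
#'   `plate_id, zprime, n_neg, n_pos, error`.
#' @export
zprime <- function(plate, layout) {
  layout <- validate_layout(layout)
  plate <- .join_layout(plate, layout)
  pieces <- lapply(split(plate, plate$plate_id), function(df) {
    ctrl <- .control_means(df, df$plate_id[1])
    sep <- abs(ctrl$mean_neg - ctrl$mean_pos)
    z <- if (sep == 0) NA_real_ else {
      1 - (3 * stats::sd(ctrl$neg) + 3 * stats::sd(ctrl$pos)) / sep
    }
    data.frame(
      plate_id = df$plate_id[1],
      zprime = z,
      n_neg = length(ctrl$neg),
      n_pos = length(ctrl$pos),
      error = if (sep == 0) "degenerate controls: equal means" else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Partition plates by a z-prime threshold
#'
#' Splits QC records into passing and failing plate IDs. Plates with an
#' undefined z' (degenerate controls) always fail. Failed plates should be
#' excluded from downstream pooling.
#'
#' @param records QC `data.frame` from [zprime()].
#' @param threshold minimum acceptable z' (must be < 1); default 0.5, the
#'   classical screening convention.
#' @return a list with `records` (with a logical `passed` column added),
#'   `passed` and `failed` (character vectors of plate IDs).
#' @export
qc_filter <- function(records, threshold = 0.5) {
  if (!is.numeric(threshold) || threshold >= 1) {
    stopf("`threshold` must be a number < 1")
  }
  if (nrow(records) == 0) {
    records$passed <- logical(0)
    return(list(records = records, passed = character(0),
                failed = character(0)))
  }
  records$passed <- !is.na(records$zprime) & records$zprime >= threshold
  list(
    records = records,
    passed = records$plate_id[records$passed],
    failed = records$plate_id[!records$passed]
  )
}

#' Normalize a set of plates with quality control
#'
#' Convenience wrapper running the full plate stage: transform, per-plate z'
#' QC, exclusion of failing plates, and % activity normalization of the
#' remainder.
#'
#' @param reads raw reads `data.frame`.
#' @param layout layout `data.frame`.
#' @param scale analysis scale, `"log2"` (single-agent default) or `"linear"`.
#' @param qc_threshold minimum z' for a plate to enter normalization.
#' @return list with `activities` (normalized compound wells of passing
#'   plates), `qc` (QC records with `passed`), and `failed` plate IDs.
#' @export
normalize_plates <- function(reads, layout, scale = "log2",
                             qc_threshold = 0.5) {
  plate <- transform_plate(reads, scale)
  qc <- qc_filter(zprime(plate, layout), qc_threshold)
  keep <- plate$plate_id %in% qc$passed
  activities <- if (any(keep)) {
    percent_activity(plate[keep, , drop = FALSE], layout)
  } else {
    NULL
  }
  list(activities = activities, qc = qc$records, failed = qc$failed)
}
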