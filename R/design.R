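#' Sample design for a chase experiment
#'
#' A sample design maps every quantified sample column to an experimental
#' condition (e.g. \code{CON}, \code{CHX}, \code{CHX_PROTAC}, \code{PROTAC},
#' \code{BORT_PROTAC}), a chase timepoint in hours and a replicate number.
#' The vehicle control at time zero (\code{CON}, \code{timepoint_h == 0})
#' provides the baseline against which protein fraction remaining is
#' expressed, so at least one such sample must exist.
#'
#' @param sample_id character vector of unique sample identifiers matching
#'   the intensity columns of the protein-groups table.
#' @param condition character vector of condition labels. The label set is
#'   open-ended; \code{CON} is reserved for the vehicle control.
#' @param timepoint_h numeric vector of chase timepoints in hours (>= 0).
#' @param replicate positive integer vector of replicate numbers.
#' @return A \code{sample_design} data frame with one row per sample.
#' @examples
#' sample_design(
#'   sample_id   = c("CON_0h_r1", "CHX_8h_r1"),
#'   condition   = c("CON", "CHX"),
#'   timepoint_h = c(0, 8),
#'   replicate   = c(1, 1)
#' )
#' @seealso [read_design()] to load a design from a delimited file.
#' @export
sample_design <- function(sample_id, condition, timepoint_h, replicate) {
  d <- data.frame(
    sample_id   = as.character(sample_id),
    condition   = as.character(condition),
    timepoint_h = as.numeric(timepoint_h),
    replicate   = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  validate_design(d)
}

validate_design <- function(d) {
  required <- c("sample_id", "condition", "timepoint_h", "replicate")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    stopf("design is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  d <- d[required]
  if (anyNA(d$timepoint_h)) stopf("design has non-numeric or missing timepoint_h")
  if (any(d$timepoint_h < 0)) stopf("timepoint_h must be >= 0")
  if (anyNA(d$replicate) || any(d$replicate < 1)) {
    stopf("replicate must be a positive integer")
  }
  if (anyNA(d$sample_id) || any(d$sample_id == "")) stopf("empty sample_id")
  if (anyDuplicated(d$sample_id)) {
    stopf("duplicate sample_id: %s",
          paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  }
  key <- paste(d$condition, d$timepoint_h, d$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- d[duplicated(key), , drop = FALSE]
    stopf("duplicate (condition, timepoint_h, replicate) triple: (%s, %s, %s)",
          dup$condition[1], dup$timepoint_h[1], dup$replicate[1])
  }
  if (!any(d$condition == "CON" & d$timepoint_h == 0)) {
    stopf("no baseline: design must contain at least one CON sample at timepoint 0")
  }
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Read a sample-design table
#'
#' Reads a tab- or comma-delimited table with columns \code{sample_id},
#' \code{condition}, \code{timepoint_h} and \code{replicate} and validates it:
#' (condition, timepoint, replicate) triples must be unique, timepoints must
#' be non-negative numbers and a \code{CON} baseline sample at time 0 must be
#' present.
#'
#' @param path path to the design file. The delimiter is taken from the file
#'   extension (.csv means comma, anything else tab).
#' @return A validated [sample_design()] data frame.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stopf("design file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                         colClasses = "character", check.names = FALSE,
                         stringsAsFactors = FALSE, comment.char = "")
  required <- c("sample_id", "condition", "timepoint_h", "replicate")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    stopf("design file lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  tp <- suppressWarnings(as.numeric(d$timepoint_h))
  if (anyNA(tp)) {
    bad <- d$timepoint_h[is.na(tp)]
    stopf("non-numeric timepoint_h: %s", paste(unique(bad), collapse = ", "))
  }
  rep_n <- suppressWarnings(as.integer(d$replicate))
  if (anyNA(rep_n)) stopf("non-integer replicate value in design file")
  sample_design(d$sample_id, d$condition, tp, rep_n)
}

#' @export
print.sample_design <- function(x, ...) {
  tab <- table(x$condition)
  cat(sprintf("Sample design: %d samples, %d condition(s)\n", nrow(x), length(tab)))
  for (cond in names(tab)) {
    tps <- sort(unique(x$timepoint_h[x$condition == cond]))
    cat(sprintf("  %-12s %2d samples at t = {%s} h\n",
                cond, tab[[cond]], paste(tps, collapse = ", ")))
  }
  invisible(x)
}

# Sample ids of a condition, optionally restricted to one timepoint.
design_samples <- function(design, condition, timepoint_h = NULL) {
  keep <- design$condition == condition
  if (!is.null(timepoint_h)) keep <- keep & design$timepoint_h == timepoint_h
  design$sample_id[keep]
}

# Ascending chase grid (timepoints > 0) of a condition.
chase_timepoints <- function(design, condition) {
  sort(unique(design$timepoint_h[design$condition == condition &
                                   design$timepoint_h > 0]))
}
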