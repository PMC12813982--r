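#' Read a MaxQuant-style protein-groups table
#'
#' Parses a tab-delimited protein-groups table (the \code{proteinGroups.txt}
#' dialect) into an [lfq_matrix()]. For every sample in the design the
#' intensity column is located as \code{"LFQ intensity <sample_id>"}
#' (case-sensitive), falling back to a bare \code{<sample_id>} column. Zero
#' and empty intensity cells become missing values: an LFQ zero encodes
#' non-detection, not a measurement. The decoy/contaminant annotation columns
#' \code{"Reverse"}, \code{"Potential contaminant"} and
#' \code{"Only identified by site"} (marker \code{"+"}) are parsed into
#' logical flags; absent columns default to \code{FALSE}.
#'
#' Proteins are keyed by the first entry of \code{"Majority protein IDs"}
#' when that column exists, otherwise by \code{"Protein IDs"} or a
#' \code{protein_id} column. Gene symbols (\code{"Gene names"} or
#' \code{gene_symbol}) are carried as annotation only.
#'
#' @param path path to the tab-delimited table.
#' @param design a [sample_design()]; one intensity column per design sample
#'   must be present.
#' @return A linear-scale [lfq_matrix()].
#' @export
read_protein_groups <- function(path, design) {
  if (!file.exists(path)) stopf("protein-groups file not found: %s", path)
  design <- validate_design(as.data.frame(design))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "")

  ids <- extract_protein_ids(tab)
  if (anyDuplicated(ids)) {
    stopf("duplicate protein_id: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }

  vals <- matrix(NA_real_, nrow = nrow(tab), ncol = nrow(design),
                 dimnames = list(ids, design$sample_id))
  for (s in design$sample_id) {
    col <- paste("LFQ intensity", s)
    if (!col %in% names(tab)) col <- s
    if (!col %in% names(tab)) {
      stopf("no intensity column for design sample '%s'", s)
    }
    v <- suppressWarnings(as.numeric(tab[[col]]))
    v[tab[[col]] %in% c("", "NA", "NaN")] <- NA_real_
    vals[, s] <- v
  }

  flag_col <- function(name) {
    if (name %in% names(tab)) tab[[name]] == "+" else logical(nrow(tab))
  }
  flags <- data.frame(
    reverse      = flag_col("Reverse"),
    contaminant  = flag_col("Potential contaminant"),
    only_by_site = flag_col("Only identified by site")
  )

  gene <- NULL
  for (gc in c("Gene names", "gene_symbol")) {
    if (gc %in% names(tab)) { gene <- tab[[gc]]; break }
  }

  lfq_matrix(vals, design, gene_symbol = gene, flags = flags,
             scale = "linear", imputed = FALSE)
}

extract_protein_ids <- function(tab) {
  for (col in c("Majority protein IDs", "Protein IDs", "protein_id")) {
    if (col %in% names(tab)) {
      ids <- vapply(strsplit(tab[[col]], ";", fixed = TRUE),
                    function(p) p[1], character(1))
      return(ids)
    }
  }
  stopf("no protein identifier column found (expected 'Majority protein IDs', 'Protein IDs' or 'protein_id')")
}

#' Write a result table as TSV
#'
#' Writes a data frame as a tab-separated UTF-8 file. Missing cells are
#' written as empty strings and numeric values with enough digits (\code{\%.15g})
#' that the table round-trips through [read_result_table()] bit-faithfully
#' for strings and integers and to better than 1e-12 relative error for
#' reals.
#'
#' @param rows a data frame with a stable column order.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  out <- rows
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.double(col)) {
      txt <- sprintf("%.15g", col)
      txt[is.na(col)] <- ""
      out[[j]] <- txt
    } else {
      txt <- as.character(col)
      txt[is.na(col)] <- ""
      out[[j]] <- txt
    }
  }
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e) stopf("cannot write to '%s': %s",
                                            path, conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a TSV result table
#'
#' Counterpart of [write_table()]: empty cells become \code{NA}; columns
#' that parse fully as numbers are returned numeric.
#'
#' @param path path to a TSV written by [write_table()].
#' @return A data frame.
#' @export
read_result_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "",
                           na.strings = "")
  for (j in seq_along(tab)) {
    col <- tab[[j]]
    num <- suppressWarnings(as.numeric(col))
    if (!any(is.na(num) & !is.na(col))) {
      # prefer integer when exactly representable
      if (length(num) && all(is.na(num) | num == trunc(num)) &&
          all(abs(num) < .Machine$integer.max, na.rm = TRUE) &&
          !any(grepl("[.eE]", col[!is.na(col)]))) {
        tab[[j]] <- as.integer(num)
      } else {
        tab[[j]] <- num
      }
    } else if (all(is.na(col) | col %in% c("TRUE", "FALSE"))) {
      tab[[j]] <- as.logical(col)
    }
  }
  tab
}
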