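#' Construct an LFQ intensity matrix
#'
#' The central container of the package: a proteins x samples matrix of
#' label-free quantification (LFQ) intensities, where \code{NA} encodes a
#' missing (not detected) value — distinct from zero, which never occurs on
#' the linear scale. Decoy/contaminant annotation travels with the matrix,
#' as does the scale flag (\code{linear} or \code{log2}) and an
#' \code{imputed} flag used to keep imputed values out of the kinetics
#' branch of the pipeline.
#'
#' @param values numeric matrix, proteins in rows (rownames = protein
#'   accessions), samples in columns (colnames = sample ids from the design).
#'   \code{NA} means missing; on the linear scale all present values must be
#'   positive (zeros are converted to \code{NA}).
#' @param design a [sample_design()] covering every value column.
#' @param gene_symbol optional character vector of gene symbols, one per
#'   protein (annotation only; proteins are keyed by accession).
#' @param flags optional data frame with logical columns \code{reverse},
#'   \code{contaminant}, \code{only_by_site}; defaults to all-\code{FALSE}.
#' @param scale \code{"linear"} or \code{"log2"}.
#' @param imputed logical; whether missing values have been imputed.
#' @return An object of class \code{lfq_matrix}.
#' @export
lfq_matrix <- function(values, design, gene_symbol = NULL, flags = NULL,
                       scale = c("linear", "log2"), imputed = FALSE) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("'values' must be a numeric matrix")
  }
  if (nrow(values) > 0 && is.null(rownames(values))) {
    stopf("'values' must have protein ids as rownames")
  }
  if (ncol(values) > 0 && is.null(colnames(values))) {
    stopf("'values' must have sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stopf("duplicate protein_id: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]),
                collapse = ", "))
  }
  design <- validate_design(as.data.frame(design))
  undeclared <- setdiff(colnames(values), design$sample_id)
  if (length(undeclared)) {
    stopf("value column(s) not declared in design: %s",
          paste(undeclared, collapse = ", "))
  }
  if (scale == "linear") {
    values[!is.na(values) & values == 0] <- NA_real_
    if (any(values < 0, na.rm = TRUE)) {
      stopf("negative intensities on linear scale")
    }
  }
  n <- nrow(values)
  if (is.null(flags)) {
    flags <- data.frame(reverse = logical(n), contaminant = logical(n),
                        only_by_site = logical(n))
  }
  stopifnot(nrow(flags) == n)
  rownames(flags) <- rownames(values)
  if (!is.null(gene_symbol)) {
    stopifnot(length(gene_symbol) == n)
    gene_symbol <- as.character(gene_symbol)
    names(gene_symbol) <- rownames(values)
  }
  structure(
    list(values = values, design = design, gene_symbol = gene_symbol,
         flags = flags, scale = scale, imputed = imputed),
    class = "lfq_matrix"
  )
}

#' @export
print.lfq_matrix <- function(x, ...) {
  nm <- sum(is.na(x$values))
  cat(sprintf("LFQ matrix: %d proteins x %d samples (%s scale%s)\n",
              nrow(x$values), ncol(x$values), x$scale,
              if (x$imputed) ", imputed" else ""))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nm,
              100 * nm / length(x$values)))
  fl <- x$flags
  cat(sprintf("  flagged: %d reverse, %d contaminant, %d only-by-site\n",
              sum(fl$reverse), sum(fl$contaminant), sum(fl$only_by_site)))
  invisible(x)
}

#' @export
dim.lfq_matrix <- function(x) dim(x$values)

#' Protein accessions of an LFQ matrix
#' @param x an \code{lfq_matrix}.
#' @return Character vector of protein ids (row key).
#' @export
protein_ids <- function(x) rownames(x$values)

# Row/column subsetting that keeps annotation in sync.
subset_lfq <- function(x, proteins = NULL, samples = NULL) {
  if (!is.null(proteins)) {
    idx <- match(proteins, rownames(x$values))
    if (anyNA(idx)) stopf("unknown protein id(s): %s",
                          paste(proteins[is.na(idx)], collapse = ", "))
    x$values <- x$values[idx, , drop = FALSE]
    x$flags <- x$flags[idx, , drop = FALSE]
    if (!is.null(x$gene_symbol)) x$gene_symbol <- x$gene_symbol[idx]
  }
  if (!is.null(samples)) {
    idx <- match(samples, colnames(x$values))
    if (anyNA(idx)) stopf("unknown sample id(s): %s",
                          paste(samples[is.na(idx)], collapse = ", "))
    x$values <- x$values[, idx, drop = FALSE]
  }
  x
}
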