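#' Contact matrix for one cell and one chromosome
#'
#' A `ContactMatrix` holds the binned, symmetric, nonnegative contact counts of
#' a single chromosome in a single cell, together with the bin size.  Raw
#' matrices are integer counts; enhanced or normalized matrices are real.
#'
#' @param counts Square numeric matrix, symmetric and nonnegative.
#' @param resolution_bp Bin size in base pairs.
#' @param cell_id Cell identifier string.
#' @param chrom Chromosome name.
#' @return An object of class `ContactMatrix`: a list with elements
#'   `cell_id`, `chrom`, `resolution_bp`, `n_bins`, `counts`.
#' @examples
#' m <- contact_matrix(matrix(c(2, 1, 1, 3), 2), resolution_bp = 1e6)
#' m$n_bins
#' @export
contact_matrix <- function(counts, resolution_bp, cell_id = "cell", chrom = "chr1") {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (nrow(counts) < 2L) stop("a contact matrix needs n_bins >= 2")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be nonnegative and finite")
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(abs(counts)))) {
    stop("counts must be symmetric")
  }
  if (!is.numeric(resolution_bp) || length(resolution_bp) != 1L || resolution_bp <= 0) {
    stop("resolution_bp must be a positive scalar")
  }
  structure(
    list(cell_id = as.character(cell_id), chrom = as.character(chrom),
         resolution_bp = as.integer(resolution_bp), n_bins = nrow(counts),
         counts = unname(counts)),
    class = "ContactMatrix"
  )
}

#' @export
print.ContactMatrix <- function(x, ...) {
  nz <- sum(x$counts[upper.tri(x$counts, diag = TRUE)] > 0)
  cat(sprintf(
    "ContactMatrix %s %s: %d bins @ %d bp, %d non-zero upper-triangle entries, total %.6g\n",
    x$cell_id, x$chrom, x$n_bins, x$resolution_bp, nz,
    sum(x$counts[upper.tri(x$counts, diag = TRUE)])
  ))
  invisible(x)
}

is_contact_matrix <- function(x) inherits(x, "ContactMatrix")

stopifnot_cm <- function(m, what = "m") {
  if (!is_contact_matrix(m)) stop(sprintf("%s must be a ContactMatrix", what))
  invisible(m)
}
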