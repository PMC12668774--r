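#' Read a sparse upper-triangle triplet file
#'
#' The triplet format is one line per non-zero upper-triangle entry,
#' `bin_i<TAB>bin_j<TAB>count` with 0-based bins and `i <= j`, an optional
#' header line, and optional leading `#` comment lines.  Files compressed with
#' gzip are read transparently.  Duplicate `(i, j)` pairs are summed.
#'
#' @param path Path to a triplet file (plain or `.gz`).
#' @param n_bins Number of bins of the full matrix.
#' @param resolution_bp Bin size in base pairs.
#' @param cell_id,chrom Metadata; `cell_id` defaults to the file name.
#' @return A `ContactMatrix`.
#' @export
read_triplets <- function(path, n_bins, resolution_bp,
                          cell_id = NULL, chrom = "chr1") {
  if (is.null(cell_id)) cell_id <- sub("\\.(txt|tsv)(\\.gz)?$", "", basename(path))
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) > 0L && grepl("[A-Za-z]", lines[1L])) lines <- lines[-1L]
  m <- matrix(0, n_bins, n_bins)
  if (length(lines) > 0L) {
    parts <- strsplit(lines, "[\t ]+")
    for (ln in seq_along(parts)) {
      p <- parts[[ln]]
      if (length(p) < 3L) stop(sprintf("malformed triplet line %d in %s", ln, path))
      i <- as.integer(p[1L]); j <- as.integer(p[2L]); v <- as.numeric(p[3L])
      if (is.na(i) || is.na(j) || is.na(v)) {
        stop(sprintf("non-numeric triplet line %d in %s", ln, path))
      }
      if (i < 0L || j < 0L || i >= n_bins || j >= n_bins) {
        stop(sprintf("bin index out of range [0,%d) at line %d in %s", n_bins, ln, path))
      }
      if (v < 0) stop(sprintf("negative count at line %d in %s", ln, path))
      m[i + 1L, j + 1L] <- m[i + 1L, j + 1L] + v
    }
  }
  m <- mirror_upper(m)
  contact_matrix(m, resolution_bp, cell_id = cell_id, chrom = chrom)
}

#' Write a contact matrix as a sparse upper-triangle triplet file
#'
#' Writes only the non-zero entries with `i <= j` (0-based), after a header
#' line and an optional `#` provenance comment.  For integer matrices,
#' `read_triplets(write_triplets(m))` reproduces `m` exactly.
#'
#' @param m A `ContactMatrix`.
#' @param path Output path (a `.gz` suffix triggers gzip compression).
#' @param comment Optional provenance string written as a leading `#` line.
#' @return Invisibly, `path`.
#' @export
write_triplets <- function(m, path, comment = NULL) {
  stopifnot_cm(m)
  idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0, arr.ind = TRUE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("bin_i\tbin_j\tcount", con)
  if (nrow(idx) > 0L) {
    ord <- order(idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]
    vals <- m$counts[idx]
    fmt <- ifelse(vals == round(vals), format(vals, scientific = FALSE, trim = TRUE),
                  sprintf("%.10g", vals))
    writeLines(sprintf("%d\t%d\t%s", idx[, 1] - 1L, idx[, 2] - 1L, fmt), con)
  }
  invisible(path)
}

#' Log-scale normalization of contact counts
#'
#' Maps counts into `[0, 1]` via `min(log1p(x), cap) / cap`; the inverse maps
#' back via `expm1(y * cap)` clipped at 0.  The round trip is exact for counts
#' with `log1p(x) <= cap`.
#'
#' @param m A `ContactMatrix` (or bare numeric matrix/array).
#' @param cap Positive normalization cap on the `log1p` scale; see
#'   [estimate_cap()].
#' @return Same shape as the input, normalized (or denormalized) values.
#' @export
normalize_counts <- function(m, cap) {
  if (cap <= 0) stop("cap must be positive")
  f <- function(x) pmin(log1p(x), cap) / cap
  if (is_contact_matrix(m)) {
    out <- m
    out$counts <- f(m$counts)
    out
  } else f(m)
}

#' @rdname normalize_counts
#' @export
denormalize_counts <- function(m, cap) {
  if (cap <= 0) stop("cap must be positive")
  f <- function(y) pmax(expm1(y * cap), 0)
  if (is_contact_matrix(m)) {
    out <- m
    out$counts <- f(m$counts)
    out
  } else f(m)
}

#' Estimate the cohort normalization cap
#'
#' `log1p` of the 99.9th percentile of the non-zero counts pooled over the
#' training cohort.  Stored in the model checkpoint so that training and
#' prediction use the identical scale.
#'
#' @param cells List of `ContactMatrix`.
#' @param probs Quantile of the non-zero counts (default 0.999).
#' @return Positive scalar cap.
#' @export
estimate_cap <- function(cells, probs = 0.999) {
  nz <- unlist(lapply(cells, function(m) {
    v <- m$counts[upper.tri(m$counts, diag = TRUE)]
    v[v > 0]
  }))
  if (length(nz) == 0L) return(log1p(1))
  max(log1p(stats::quantile(nz, probs, names = FALSE)), log1p(1))
}

#' Tile a contact matrix into diagonal-band submatrices
#'
#' Cuts `w x w` windows along the diagonal with stride `k` so that the central
#' `k x k` block of the tile anchored at bin `a` covers diagonal bins
#' `[a, a + k)`; each window carries `(w - k)/2` bins of flanking context on
#' each side.  Out-of-range rows/columns are zero-padded and the valid extent
#' recorded, so the tiling covers any matrix size.
#'
#' @param m A `ContactMatrix` (typically normalized).
#' @param w Window size in bins.
#' @param k Central (enhanced) size in bins, `k < w`, `(w - k)` even.
#' @param cap Normalization cap recorded in the batch (bookkeeping only).
#' @param offset First anchor (0-based, `0 <= offset < k`); a half-stride
#'   offset pass lets [enhance()] assemble a seam-free diagonal band.
#' @return A `SubmatrixBatch`: list with `outer_tiles`, `anchors` (0-based),
#'   `window`, `central_size`, `pad`, `valid` (per-tile 1-based valid row/col
#'   range within the tile), `source_n_bins`, `normalization_cap`, `source`.
#' @export
extract_submatrices <- function(m, w = 40L, k = 28L, cap = NA_real_, offset = 0L) {
  stopifnot_cm(m)
  w <- as.integer(w); k <- as.integer(k); offset <- as.integer(offset)
  if (k <= 0L || w <= k) stop("need 0 < k < w")
  if ((w - k) %% 2L != 0L) stop("(w - k) must be even")
  if (offset < 0L || offset >= k) stop("need 0 <= offset < k")
  n <- m$n_bins
  p <- (w - k) %/% 2L
  anchors <- seq(offset, max(offset, n - 1L), by = k)
  anchors <- anchors[anchors < n]
  tiles <- vector("list", length(anchors))
  valid <- vector("list", length(anchors))
  for (t in seq_along(anchors)) {
    a <- anchors[t]
    lo <- a - p                       # 0-based first row of the window
    rows <- lo + 0:(w - 1L)
    ok <- rows >= 0L & rows < n
    tile <- matrix(0, w, w)
    tile[which(ok), which(ok)] <- m$counts[rows[ok] + 1L, rows[ok] + 1L]
    tiles[[t]] <- tile
    valid[[t]] <- range(which(ok))
  }
  structure(
    list(outer_tiles = tiles, anchors = anchors, window = w, central_size = k,
         pad = p, valid = valid, source_n_bins = n,
         normalization_cap = cap, source = m),
    class = "SubmatrixBatch"
  )
}

# Central k x k crop of an outer tile (rows/cols pad+1 .. pad+k).
central_crop <- function(tile, p, k) tile[p + seq_len(k), p + seq_len(k), drop = FALSE]

#' Merge enhanced central tiles back into a full matrix
#'
#' Writes only the central `k x k` block of each enhanced tile at its anchor;
#' those blocks are disjoint, so every assembled entry is written exactly once.
#' Entries outside the assembled diagonal blocks are copied from the original
#' source matrix, and the result is symmetrized as `(M + t(M))/2`.
#'
#' @param batch A `SubmatrixBatch` from [extract_submatrices()].
#' @param enhanced_tiles List of `k x k` matrices aligned 1:1 with
#'   `batch$anchors`.
#' @return A `ContactMatrix` with real values on the scale of the tiles.
#' @export
merge_submatrices <- function(batch, enhanced_tiles) {
  if (!inherits(batch, "SubmatrixBatch")) stop("batch must be a SubmatrixBatch")
  if (length(enhanced_tiles) != length(batch$anchors)) {
    stop(sprintf("tile count mismatch: %d enhanced vs %d anchors",
                 length(enhanced_tiles), length(batch$anchors)))
  }
  k <- batch$central_size
  n <- batch$source_n_bins
  out <- batch$source$counts
  for (t in seq_along(batch$anchors)) {
    a <- batch$anchors[t]
    et <- enhanced_tiles[[t]]
    if (!all(dim(et) == c(k, k))) stop("enhanced tiles must be k x k")
    nb <- min(k, n - a)               # bins of this central block inside the matrix
    if (nb <= 0L) next
    out[a + seq_len(nb), a + seq_len(nb)] <- et[seq_len(nb), seq_len(nb)]
  }
  out <- symmetrize(out)
  contact_matrix(out, batch$source$resolution_bp,
                 cell_id = batch$source$cell_id, chrom = batch$source$chrom)
}
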