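# Evaluation suite: pixel-wise, Hi-C-specific, and structural metrics.

as_counts <- function(x) if (is_contact_matrix(x)) x$counts else as.matrix(x)

check_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("matrices must have the same shape")
}

#' Mean absolute error between two matrices
#'
#' @param pred,truth Same-shape numeric matrices (or `ContactMatrix`).
#' @return Mean of `|pred - truth|` over all entries.
#' @export
mae <- function(pred, truth) {
  p <- as_counts(pred); t <- as_counts(truth)
  check_same_shape(p, t)
  mean(abs(p - t))
}

#' Binarized macro F1 (over-smoothing diagnostic)
#'
#' Both matrices are binarized at the smallest non-zero value of the ground
#' truth (inclusive, so the truth binarized against itself reproduces its own
#' support); the macro F1 is the unweighted mean of the positive-class and
#' negative-class F1 scores.  Over-smoothed predictions flood the background
#' with values above the threshold and are penalized through the
#' positive-class precision.
#'
#' @param pred,truth Same-shape matrices; `truth` must have a non-zero entry.
#' @return Macro F1 in `[0, 1]`; a class with precision + recall = 0
#'   contributes an F1 of 0.
#' @export
binarized_macro_f1 <- function(pred, truth) {
  p <- as_counts(pred); t <- as_counts(truth)
  check_same_shape(p, t)
  nz <- t[t > 0]
  if (length(nz) == 0L) stop("all-zero truth: binarization threshold undefined")
  tau <- min(nz)
  pp <- p >= tau
  tp_ <- t >= tau
  macro_f1_from_labels(pp, tp_)
}

macro_f1_from_labels <- function(pred_pos, true_pos) {
  tp <- sum(pred_pos & true_pos)
  fp <- sum(pred_pos & !true_pos)
  fn <- sum(!pred_pos & true_pos)
  tn <- sum(!pred_pos & !true_pos)
  mean(c(f1_class(tp, fp, fn), f1_class(tn, fn, fp)))
}

f1_class <- function(tp, fp, fn) {
  # a class absent from both prediction and truth is in perfect agreement
  if (tp + fp + fn == 0) return(1)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# Box mean filter with window (2h+1)^2, truncated at the matrix edges.
box_mean <- function(m, h) {
  if (h == 0L) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  cs <- matrix(0, n1 + 1L, n2 + 1L)
  cs[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- pmax(seq_len(n1) - h, 1L); r2 <- pmin(seq_len(n1) + h, n1)
  c1 <- pmax(seq_len(n2) - h, 1L); c2 <- pmin(seq_len(n2) + h, n2)
  sums <- cs[r2 + 1L, c2 + 1L] - cs[r1, c2 + 1L] - cs[r2 + 1L, c1] + cs[r1, c1]
  cnts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / cnts
}

#' Stratum-adjusted correlation coefficient (SCC)
#'
#' HiCRep-style similarity: both matrices are smoothed with a mean filter of
#' span `2h + 1`, entries are stratified by genomic distance, and the
#' per-stratum Pearson correlations are combined with weights
#' `N_d * sd(rank(a_d)) * sd(rank(b_d))`.  Strata whose entries are constant
#' in either matrix are skipped.
#'
#' @param a,b Same-shape symmetric matrices (or `ContactMatrix`).
#' @param h Smoothing half-span in bins (0 disables smoothing); the package
#'   default is 1 at 1-Mb resolution and 3 at <= 100 kb.
#' @param max_distance_bins Largest diagonal stratum used (default
#'   `n_bins - 1`).
#' @return SCC in `[-1, 1]`.
#' @export
stratum_adjusted_correlation <- function(a, b, h = 1L, max_distance_bins = NULL) {
  am <- as_counts(a); bm <- as_counts(b)
  check_same_shape(am, bm)
  n <- nrow(am)
  D <- if (is.null(max_distance_bins)) n - 1L else min(max_distance_bins, n - 1L)
  if (D < 0L) stop("max_distance_bins must be >= 0")
  as_ <- box_mean(am, h); bs_ <- box_mean(bm, h)
  num <- 0; den <- 0; informative <- FALSE
  for (d in 0:D) {
    i <- seq_len(n - d)
    av <- as_[cbind(i, i + d)]
    bv <- bs_[cbind(i, i + d)]
    if (length(av) < 2L) next
    if (stats::sd(av) == 0 || stats::sd(bv) == 0) next
    r <- stats::cor(av, bv)
    wgt <- length(av) * stats::sd(rank(av)) * stats::sd(rank(bv))
    num <- num + wgt * r
    den <- den + wgt
    informative <- TRUE
  }
  if (!informative) stop("no informative strata")
  num / den
}

#' Random-walk graph concordance
#'
#' GenomeDISCO-style similarity: each matrix is row-normalized into a
#' transition matrix (all-zero rows stay zero), raised to the `t`-th power,
#' and the score is `1 - sum(|A^t - B^t|) / mean(nnz nodes)`, where a node
#' counts as non-empty if its bin has any contact.  Perfect agreement scores
#' 1; the score is unbounded below but <= 1.
#'
#' @param a,b Same-shape symmetric matrices.
#' @param steps Number of random-walk steps `t >= 1` (default 3, the
#'   published default of the original tool).
#' @return Concordance score <= 1.
#' @export
random_walk_concordance <- function(a, b, steps = 3L) {
  am <- as_counts(a); bm <- as_counts(b)
  check_same_shape(am, bm)
  if (steps < 1L) stop("steps must be >= 1")
  nnz_a <- sum(rowSums(am) > 0)
  nnz_b <- sum(rowSums(bm) > 0)
  if (nnz_a + nnz_b == 0L) stop("both matrices are empty")
  pa <- row_normalize(am); pb <- row_normalize(bm)
  Aa <- pa; Bb <- pb
  if (steps > 1L) for (s in 2:steps) { Aa <- Aa %*% pa; Bb <- Bb %*% pb }
  d <- sum(abs(Aa - Bb)) / ((nnz_a + nnz_b) / 2)
  1 - d
}

row_normalize <- function(m) {
  rs <- rowSums(m)
  rs[rs == 0] <- 1
  m / rs
}

#' One-to-one bin matching with a flexible shift threshold
#'
#' Matches predicted to true bins when their distance is at most `shift`,
#' greedily by increasing distance (ties broken by predicted index), each bin
#' used at most once.  Matched pairs are TP, unmatched predictions FP,
#' unmatched truths FN; the negative class is evaluated over the `n_bins`
#' universe, giving a macro F1 comparable across shift thresholds.
#'
#' @param pred_bins,true_bins Integer vectors of 0-based bins (sets).
#' @param shift Maximum allowed offset in bins (the study sweeps 1..6).
#' @param n_bins Size of the bin universe.
#' @return List with `precision`, `recall`, `macro_f1`, `tp`, `fp`, `fn`.
#' @export
flexible_match_prf <- function(pred_bins, true_bins, shift, n_bins) {
  if (shift < 0) stop("shift must be >= 0")
  pred <- sort(unique(as.integer(pred_bins)))
  tru <- sort(unique(as.integer(true_bins)))
  tp <- 0L
  if (length(pred) > 0L && length(tru) > 0L) {
    cand <- expand.grid(p = seq_along(pred), t = seq_along(tru))
    cand$d <- abs(pred[cand$p] - tru[cand$t])
    cand <- cand[cand$d <= shift, , drop = FALSE]
    cand <- cand[order(cand$d, cand$p, cand$t), , drop = FALSE]
    used_p <- logical(length(pred)); used_t <- logical(length(tru))
    for (r in seq_len(nrow(cand))) {
      if (!used_p[cand$p[r]] && !used_t[cand$t[r]]) {
        used_p[cand$p[r]] <- TRUE; used_t[cand$t[r]] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- length(pred) - tp
  fn <- length(tru) - tp
  tn <- max(n_bins - tp - fp - fn, 0L)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1p <- f1_class(tp, fp, fn)
  f1n <- f1_class(tn, fn, fp)
  list(precision = prec, recall = rec, macro_f1 = mean(c(f1p, f1n)),
       tp = tp, fp = fp, fn = fn)
}

#' Loop set
#'
#' @param anchors Two-column matrix (or list of pairs) of 0-based `(bin_i,
#'   bin_j)` with `bin_i < bin_j`; duplicates are dropped.
#' @param resolution_bp Bin size in base pairs.
#' @return A `LoopSet`.
#' @export
loop_set <- function(anchors, resolution_bp = NA_integer_) {
  if (is.list(anchors) && !is.data.frame(anchors)) {
    anchors <- do.call(rbind, lapply(anchors, function(x) as.integer(x[1:2])))
  }
  anchors <- unique(matrix(as.integer(as.matrix(anchors)), ncol = 2L))
  if (nrow(anchors) > 0L && any(anchors[, 1] >= anchors[, 2])) {
    stop("loop anchors need bin_i < bin_j")
  }
  structure(list(anchors = anchors, resolution_bp = resolution_bp),
            class = "LoopSet")
}

#' Match two loop sets allowing a pixel shift
#'
#' Two-dimensional analogue of [flexible_match_prf()]: loops match when their
#' anchors are within Chebyshev distance `pixel_shift` (the study allows a
#' single-pixel shift), matched one-to-one greedily by increasing distance.
#' Also reports the number of exact (zero-shift) matches.
#'
#' @param pred,true `LoopSet` objects (or 2-column anchor matrices).
#' @param pixel_shift Maximum Chebyshev distance (default 1).
#' @param n_bins Optional bin universe for the negative class of the macro F1;
#'   defaults to 1 + the largest anchor seen.
#' @return List with `precision`, `recall`, `macro_f1`, `n_exact`, `tp`.
#' @export
match_loops <- function(pred, true, pixel_shift = 1L, n_bins = NULL) {
  pa <- if (inherits(pred, "LoopSet")) pred$anchors else matrix(as.integer(as.matrix(pred)), ncol = 2L)
  ta <- if (inherits(true, "LoopSet")) true$anchors else matrix(as.integer(as.matrix(true)), ncol = 2L)
  if (pixel_shift < 0) stop("pixel_shift must be >= 0")
  if (is.null(n_bins)) n_bins <- max(c(pa, ta, 0L)) + 1L
  tp <- 0L; n_exact <- 0L
  if (nrow(pa) > 0L && nrow(ta) > 0L) {
    cand <- expand.grid(p = seq_len(nrow(pa)), t = seq_len(nrow(ta)))
    cand$d <- pmax(abs(pa[cand$p, 1] - ta[cand$t, 1]),
                   abs(pa[cand$p, 2] - ta[cand$t, 2]))
    cand <- cand[cand$d <= pixel_shift, , drop = FALSE]
    cand <- cand[order(cand$d, cand$p, cand$t), , drop = FALSE]
    used_p <- logical(nrow(pa)); used_t <- logical(nrow(ta))
    for (r in seq_len(nrow(cand))) {
      if (!used_p[cand$p[r]] && !used_t[cand$t[r]]) {
        used_p[cand$p[r]] <- TRUE; used_t[cand$t[r]] <- TRUE
        tp <- tp + 1L
        if (cand$d[r] == 0L) n_exact <- n_exact + 1L
      }
    }
  }
  fp <- nrow(pa) - tp
  fn <- nrow(ta) - tp
  universe <- n_bins * (n_bins - 1L) / 2
  tn <- max(universe - tp - fp - fn, 0)
  list(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0,
       macro_f1 = mean(c(f1_class(tp, fp, fn), f1_class(tn, fn, fp))),
       n_exact = n_exact, tp = tp)
}

#' Full similarity report for one prediction/truth pair
#'
#' Computes the four matrix-level metrics on a shared normalized scale.
#'
#' @param pred,truth `ContactMatrix` objects on the count scale.
#' @param cap Normalization cap (default estimated from the truth).
#' @param h,steps Passed to [stratum_adjusted_correlation()] and
#'   [random_walk_concordance()].
#' @param count_scale If TRUE, MAE and macro F1 are computed on raw counts
#'   instead of the normalized scale.
#' @return A `MetricReport` list: `mae`, `macro_f1`, `scc`, `disco`.
#' @export
metric_report <- function(pred, truth, cap = NULL, h = 1L, steps = 3L,
                          count_scale = FALSE) {
  stopifnot_cm(pred, "pred"); stopifnot_cm(truth, "truth")
  if (is.null(cap)) cap <- estimate_cap(list(truth))
  if (count_scale) {
    p <- pred$counts; t <- truth$counts
  } else {
    p <- normalize_counts(pred$counts, cap)
    t <- normalize_counts(truth$counts, cap)
  }
  structure(
    list(mae = mae(p, t),
         macro_f1 = binarized_macro_f1(p, t),
         scc = stratum_adjusted_correlation(pred$counts, truth$counts, h = h),
         disco = random_walk_concordance(pred$counts, truth$counts, steps = steps)),
    class = "MetricReport"
  )
}

#' Mean (pseudo-bulk) aggregate of a cohort
#'
#' @param cells List of `ContactMatrix` with identical dimensions.
#' @return A `ContactMatrix` of entrywise means.
#' @export
aggregate_mean <- function(cells) {
  if (length(cells) == 0L) stop("empty cell list")
  acc <- Reduce(`+`, lapply(cells, function(m) m$counts)) / length(cells)
  contact_matrix(acc, cells[[1]]$resolution_bp, cell_id = "pseudo_bulk",
                 chrom = cells[[1]]$chrom)
}

#' Gaussian-blur baseline enhancer
#'
#' Convolves the counts with a truncated 2-D Gaussian kernel and rescales by
#' `gain`.  This is the canonical over-smoothing comparator: it can match a
#' learned enhancer's MAE while flooding the background with false-positive
#' pixels.
#'
#' @param m A `ContactMatrix`.
#' @param sigma Gaussian standard deviation in bins.
#' @param gain Multiplicative rescaling applied after blurring (e.g. the
#'   downsampling ratio).
#' @return A `ContactMatrix` of real values.
#' @export
blur_baseline <- function(m, sigma = 1, gain = 1) {
  stopifnot_cm(m)
  r <- max(1L, ceiling(2 * sigma))
  g <- stats::dnorm(-r:r, sd = sigma)
  ker <- outer(g, g)
  ker <- ker / sum(ker)
  n <- m$n_bins
  padded <- matrix(0, n + 2L * r, n + 2L * r)
  padded[r + seq_len(n), r + seq_len(n)] <- m$counts
  out <- matrix(0, n, n)
  for (di in -r:r) for (dj in -r:r) {
    out <- out + ker[di + r + 1L, dj + r + 1L] *
      padded[r + di + seq_len(n), r + dj + seq_len(n)]
  }
  contact_matrix(symmetrize(out * gain), m$resolution_bp,
                 cell_id = m$cell_id, chrom = m$chrom)
}
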