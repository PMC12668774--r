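# Downstream structure callers: A/B compartments and insulation-score
# TAD-like boundaries.  These are used to evaluate enhancement, not to make
# biological claims: the compartment caller is the classical leading-
# eigenvector method on the O/E correlation matrix (a documented stand-in for
# hypergraph-based single-cell callers), and the boundary caller is a sliding
# diamond insulation score restricted to a genomic-distance band.

#' Observed/expected transformation
#'
#' Divides every entry by the mean of its genomic-distance stratum; strata
#' with zero mean map to 0.
#'
#' @param m A `ContactMatrix` or symmetric numeric matrix.
#' @return A symmetric numeric matrix of O/E ratios.
#' @export
observed_expected <- function(m) {
  x <- as_counts(m)
  n <- nrow(x)
  d <- distance_matrix(n)
  means <- vapply(0:(n - 1L), function(dd) mean(x[d == dd]), numeric(1))
  expected <- matrix(means[d + 1L], n, n)
  out <- ifelse(expected > 0, x / expected, 0)
  symmetrize(out)
}

#' Single-matrix A/B compartment profile
#'
#' Computes the O/E matrix, its row-wise Pearson correlation matrix, and the
#' leading eigenvector; the sign of each bin's loading gives its compartment
#' label.  The global sign is flipped to maximize agreement with
#' `orientation_ref` when provided (typically the pseudo-bulk profile), since
#' the eigenvector sign is arbitrary.  Bins with all-zero or constant rows
#' are labeled 0 (undetermined).
#'
#' @param m A `ContactMatrix` with `n_bins >= 4`.
#' @param orientation_ref Optional vector of +/-1 used to orient the sign.
#' @param pseudocount Constant added to the O/E matrix before correlation
#'   (guards degenerate all-equal rows; Pearson correlation is shift
#'   invariant, so the value is otherwise immaterial).
#' @return A `CompartmentProfile`: list with `labels` (+1 = A, -1 = B, 0 =
#'   undetermined) and `eigen_values` (per-bin scores, NA where undetermined).
#' @export
compartment_profile <- function(m, orientation_ref = NULL, pseudocount = 0.0) {
  x <- as_counts(m)
  n <- nrow(x)
  if (n < 4L) stop("compartment calling needs n_bins >= 4")
  oe <- observed_expected(x) + pseudocount
  informative <- rowSums(as_counts(m)) > 0 & apply(oe, 1L, stats::sd) > 0
  labels <- numeric(n)
  scores <- rep(NA_real_, n)
  if (sum(informative) >= 2L) {
    sub <- oe[informative, informative, drop = FALSE]
    cc <- suppressWarnings(stats::cor(t(sub)))
    bad <- !is.finite(diag(cc))
    if (any(bad)) {
      warning("degenerate correlation rows labeled 0")
      keep <- which(informative)[!bad]
    } else keep <- which(informative)
    if (length(keep) >= 2L) {
      cc <- suppressWarnings(stats::cor(t(oe[keep, keep, drop = FALSE])))
      cc[!is.finite(cc)] <- 0
      ev <- eigen(cc, symmetric = TRUE)
      v <- ev$vectors[, 1L]
      if (!is.null(orientation_ref)) {
        ref <- orientation_ref[keep]
        if (sum(sign(v) == sign(ref)) < sum(sign(-v) == sign(ref))) v <- -v
      } else if (sum(v) < 0 || (sum(v) == 0 && v[1] < 0)) {
        v <- -v  # deterministic sign convention when no reference is given
      }
      scores[keep] <- v
      labels[keep] <- sign(v)
    }
  }
  structure(list(labels = labels, eigen_values = scores),
            class = "CompartmentProfile")
}

#' Insulation score track
#'
#' For each bin `i`, the score is `log2` of the mean contact in the `W x W`
#' diamond spanning the `W` bins upstream and the `W` bins downstream of `i`
#' (using only entries within `band_bins` of the diagonal), divided by the
#' chromosome-wide mean diamond value.  Bins closer than `W` to either end
#' are missing (NA).  Dips in the track mark domain boundaries.
#'
#' @param m A `ContactMatrix`.
#' @param window_bins Diamond half-size `W` (default 10, i.e. a 1-Mb diamond
#'   at 100-kb resolution).
#' @param band_bins Genomic-distance band `B >= W` (default 20, the 2-Mb band
#'   at 100-kb resolution).
#' @return An `InsulationTrack`: list with `scores` (length `n_bins`, NA at
#'   the edges) and `window_bins`.
#' @export
insulation_score <- function(m, window_bins = 10L, band_bins = 20L) {
  x <- as_counts(m)
  n <- nrow(x)
  W <- as.integer(window_bins); B <- as.integer(band_bins)
  if (W < 1L || W > B) stop("need 1 <= window_bins <= band_bins")
  if (W > n / 2) stop("window_bins larger than half the matrix")
  d <- distance_matrix(n)
  diamonds <- rep(NA_real_, n)
  for (i in seq(W, n - W - 1L)) {         # 0-based bin index
    rows <- (i - W + 1L):i + 1L           # 1-based rows i-W .. i-1 (0-based)
    cols <- (i + 1L):(i + W) + 1L
    sel <- d[rows, cols, drop = FALSE] <= B
    vals <- x[rows, cols, drop = FALSE][sel]
    diamonds[i + 1L] <- if (length(vals) > 0L) mean(vals) else NA_real_
  }
  gmean <- mean(diamonds, na.rm = TRUE)
  scores <- log2(diamonds / gmean)
  structure(list(scores = scores, window_bins = W), class = "InsulationTrack")
}

#' Boundary calls from an insulation track
#'
#' Boundaries are local minima of the insulation score whose prominence (the
#' smaller of the rises to the nearest higher flanking local maxima) is at
#' least `delta_threshold`.  Plateau minima yield one boundary at the plateau
#' center; missing-score regions cannot host boundaries.
#'
#' @param track An `InsulationTrack` (or bare numeric vector with NAs for
#'   missing bins).
#' @param delta_threshold Minimum prominence (default 0.1).
#' @return A `BoundarySet`: list with sorted unique 0-based `boundary_bins`.
#' @export
call_boundaries <- function(track, delta_threshold = 0.1) {
  if (delta_threshold < 0) stop("delta_threshold must be >= 0")
  s <- if (inherits(track, "InsulationTrack")) track$scores else as.numeric(track)
  n <- length(s)
  bounds <- integer()
  # process each contiguous run of defined scores independently
  defined <- !is.na(s)
  runs <- rle(defined)
  pos <- cumsum(c(1L, runs$lengths))
  for (r in seq_along(runs$lengths)) {
    if (!runs$values[r]) next
    lo <- pos[r]; hi <- pos[r + 1L] - 1L
    seg <- s[lo:hi]
    bounds <- c(bounds, lo - 1L + find_prominent_minima(seg, delta_threshold))
  }
  structure(list(boundary_bins = sort(unique(bounds)) - 1L), class = "BoundarySet")
}

# 1-based indices of plateau-aware local minima with prominence >= delta.
# A run j of equal values is a minimum if both neighboring runs are strictly
# higher; its per-side prominence is the climb to the nearest flanking local
# maximum (the first run where the outward path stops rising; segment edges
# count as maxima).
find_prominent_minima <- function(seg, delta) {
  if (length(seg) < 3L) return(integer())
  r <- rle(seg)
  rv <- r$values
  k <- length(rv)
  starts <- cumsum(c(1L, r$lengths))[seq_len(k)]
  out <- integer()
  for (j in seq_len(k)) {
    if (j == 1L || j == k) next                 # edge plateaus are not minima
    if (!(rv[j - 1L] > rv[j] && rv[j + 1L] > rv[j])) next
    t <- j - 1L
    while (t > 1L && rv[t - 1L] > rv[t]) t <- t - 1L
    left_h <- rv[t]
    t <- j + 1L
    while (t < k && rv[t + 1L] > rv[t]) t <- t + 1L
    right_h <- rv[t]
    prom <- min(left_h, right_h) - rv[j]
    if (prom > 0 && prom >= delta) {
      out <- c(out, starts[j] + (r$lengths[j] - 1L) %/% 2L)
    }
  }
  out
}

#' Bin-level agreement between two compartment profiles
#'
#' Fraction of bins labeled (non-zero) in both profiles whose labels agree.
#'
#' @param a,b `CompartmentProfile` objects or +/-1/0 vectors.
#' @return Agreement fraction in `[0, 1]` (NA if no bin is informative in both).
#' @export
compartment_agreement <- function(a, b) {
  la <- if (inherits(a, "CompartmentProfile")) a$labels else as.numeric(a)
  lb <- if (inherits(b, "CompartmentProfile")) b$labels else as.numeric(b)
  both <- la != 0 & lb != 0
  if (!any(both)) return(NA_real_)
  mean(la[both] == lb[both])
}
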