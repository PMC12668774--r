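#' Specification of a synthetic scHi-C cohort
#'
#' Describes the planted ground truth used by the simulator: a power-law
#' distance decay, an A/B compartment checkerboard, TAD blocks, focal loops,
#' and a per-cell sequencing depth.  The defaults describe a 12-Mb region at
#' 100-kb resolution with realistic relative enrichments: a 2-fold
#' within-TAD enrichment, a 0.6 compartment strength (about 1.6-fold
#' checkerboard contrast), and 4-fold focal loop enrichment.
#'
#' @param n_bins Number of genomic bins.
#' @param resolution_bp Bin size in base pairs.
#' @param decay_exponent Power-law exponent alpha of the distance decay
#'   `(1 + d)^-alpha`.
#' @param compartment_profile Vector of +1/-1 per bin (A/B).  Default:
#'   alternating blocks of 15 bins.
#' @param compartment_strength Nonnegative multiplier `c`; same-compartment
#'   pairs are enriched by `1 + c`.
#' @param tad_blocks List of half-open 0-based `c(start, end)` bin intervals,
#'   pairwise disjoint.  Default: an irregular tiling of the region.
#' @param tad_strength Nonnegative multiplier `t`; within-block pairs are
#'   enriched by `1 + t`.
#' @param loops List of `c(bin_i, bin_j, strength)` with `bin_i < bin_j`.
#' @param depth_per_cell Expected total upper-triangle contacts per cell.
#' @param n_cells Number of cells in the cohort.
#' @param seed Integer seed for cohort simulation.
#' @return A `SyntheticSpec` object.
#' @examples
#' sp <- synthetic_spec(n_bins = 40, depth_per_cell = 1000, n_cells = 3)
#' length(sp$compartment_profile)
#' @export
synthetic_spec <- function(n_bins = 120L,
                           resolution_bp = 100000L,
                           decay_exponent = 1.0,
                           compartment_profile = NULL,
                           compartment_strength = 0.6,
                           tad_blocks = NULL,
                           tad_strength = 1.0,
                           loops = NULL,
                           depth_per_cell = 30000L,
                           n_cells = 60L,
                           seed = 1L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (decay_exponent <= 0) stop("decay_exponent must be positive")
  if (compartment_strength < 0 || tad_strength < 0) {
    stop("compartment_strength and tad_strength must be nonnegative")
  }
  if (depth_per_cell < 0) stop("depth_per_cell must be nonnegative")

  if (is.null(compartment_profile)) {
    compartment_profile <- rep(rep(c(1, -1), length.out = ceiling(n_bins / 15)),
                               each = 15)[seq_len(n_bins)]
  }
  if (length(compartment_profile) != n_bins ||
      !all(compartment_profile %in% c(-1, 1))) {
    stop("compartment_profile must have length n_bins with values in {-1, +1}")
  }

  if (is.null(tad_blocks)) {
    sizes <- c(10L, 14L, 8L, 12L, 16L, 10L, 13L, 9L, 11L, 17L)
    tad_blocks <- list()
    pos <- 0L
    i <- 1L
    while (pos < n_bins) {
      sz <- sizes[(i - 1L) %% length(sizes) + 1L]
      end <- min(pos + sz, n_bins)
      tad_blocks[[i]] <- c(pos, end)
      pos <- end
      i <- i + 1L
    }
  }
  validate_tad_blocks(tad_blocks, n_bins)

  if (is.null(loops)) {
    anchors <- list(c(8L, 22L), c(30L, 55L), c(62L, 80L), c(90L, 110L))
    loops <- lapply(anchors[vapply(anchors, function(a) a[2] < n_bins, TRUE)],
                    function(a) c(a[1], a[2], 4.0))
  }
  for (lp in loops) {
    if (length(lp) != 3L || lp[1] >= lp[2] || lp[1] < 0 || lp[2] >= n_bins) {
      stop("each loop must be c(bin_i, bin_j, strength) with 0 <= bin_i < bin_j < n_bins")
    }
  }

  structure(
    list(n_bins = n_bins, resolution_bp = as.integer(resolution_bp),
         decay_exponent = decay_exponent,
         compartment_profile = as.numeric(compartment_profile),
         compartment_strength = compartment_strength,
         tad_blocks = tad_blocks, tad_strength = tad_strength,
         loops = loops, depth_per_cell = as.integer(depth_per_cell),
         n_cells = as.integer(n_cells), seed = as.integer(seed)),
    class = "SyntheticSpec"
  )
}

validate_tad_blocks <- function(tad_blocks, n_bins) {
  if (length(tad_blocks) == 0L) return(invisible(TRUE))
  iv <- do.call(rbind, lapply(tad_blocks, function(b) as.integer(b[1:2])))
  if (any(iv[, 1] >= iv[, 2]) || any(iv[, 1] < 0) || any(iv[, 2] > n_bins)) {
    stop("invalid spec: tad_blocks must be non-empty [start,end) within [0, n_bins)")
  }
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (nrow(iv) > 1L && any(iv[-1, 1] < iv[-nrow(iv), 2])) {
    stop("invalid spec: overlapping TAD blocks")
  }
  invisible(TRUE)
}

#' Build the expected-intensity matrix of a synthetic spec
#'
#' Combines distance decay, compartment checkerboard, TAD blocks and loop
#' bumps multiplicatively:
#' \deqn{\Lambda_{ij} = (1+|i-j|)^{-\alpha}\,(1 + c\,[\mathrm{same\ compartment}])
#'   \,(1 + t\,[\mathrm{same\ TAD}])\,(1 + \sum_\ell s_\ell K_\ell(i,j))}
#' where each loop kernel `K` is a unit plateau of radius 1 bin around the
#' anchor (so that 2x downsampling does not erase planted loops).  The result
#' is symmetric and normalized to sum 1 over the upper triangle including the
#' diagonal.
#'
#' @param spec A [synthetic_spec()].
#' @return An `IntensityMatrix`: list with `values` (n x n) and `spec`.
#' @export
build_intensity <- function(spec) {
  if (!inherits(spec, "SyntheticSpec")) stop("spec must be a SyntheticSpec")
  validate_tad_blocks(spec$tad_blocks, spec$n_bins)
  n <- spec$n_bins
  lam <- (1 + distance_matrix(n))^(-spec$decay_exponent)

  same_comp <- outer(spec$compartment_profile, spec$compartment_profile) > 0
  lam <- lam * (1 + spec$compartment_strength * same_comp)

  if (length(spec$tad_blocks) > 0L && spec$tad_strength > 0) {
    in_tad <- matrix(FALSE, n, n)
    for (b in spec$tad_blocks) {
      idx <- (b[1] + 1L):b[2]
      in_tad[idx, idx] <- TRUE
    }
    lam <- lam * (1 + spec$tad_strength * in_tad)
  }

  if (length(spec$loops) > 0L) {
    bump <- matrix(0, n, n)
    for (lp in spec$loops) {
      ri <- intersect((lp[1] + 1L) + (-1:1), seq_len(n))
      ci <- intersect((lp[2] + 1L) + (-1:1), seq_len(n))
      bump[ri, ci] <- bump[ri, ci] + lp[3]
      bump[ci, ri] <- bump[ci, ri] + lp[3]
    }
    lam <- lam * (1 + bump)
  }

  lam <- symmetrize(lam)
  lam <- lam / sum(lam[upper.tri(lam, diag = TRUE)])
  structure(list(values = lam, spec = spec), class = "IntensityMatrix")
}

#' Sample one cell from an intensity matrix
#'
#' Draws a Poisson-distributed total number of upper-triangle contacts with
#' mean `depth` and assigns them multinomially to upper-triangle cells with
#' probabilities proportional to the intensity, then mirrors to a symmetric
#' integer matrix.  `fixed_total = TRUE` skips the Poisson randomization and
#' uses exactly `depth` contacts.
#'
#' @param intensity An `IntensityMatrix` from [build_intensity()].
#' @param depth Expected total number of upper-triangle contacts (>= 0; 0 is
#'   the degenerate all-zero cell).
#' @param seed Integer seed; the same seed yields an identical cell.
#' @param cell_id,chrom Metadata for the resulting [contact_matrix()].
#' @param fixed_total If TRUE, the total is exactly `depth`.
#' @return A `ContactMatrix` with integer counts.
#' @export
sample_cell <- function(intensity, depth, seed, cell_id = "cell", chrom = "chr1",
                        fixed_total = FALSE) {
  if (!inherits(intensity, "IntensityMatrix")) stop("intensity must be an IntensityMatrix")
  if (depth < 0) stop("depth must be >= 0")
  lam <- intensity$values
  n <- nrow(lam)
  up <- which(upper.tri(lam, diag = TRUE))
  p <- lam[up]
  p <- p / sum(p)
  counts <- with_seed(seed, {
    total <- if (fixed_total) as.integer(depth) else stats::rpois(1L, depth)
    if (total == 0L) integer(length(up)) else
      as.integer(stats::rmultinom(1L, total, p))
  })
  m <- matrix(0, n, n)
  m[up] <- counts
  m <- mirror_upper(m)
  contact_matrix(m, intensity$spec$resolution_bp, cell_id = cell_id, chrom = chrom)
}

#' Binomial downsampling of a contact matrix
#'
#' Thins each upper-triangle count `c` to `Binomial(c, 1/ratio)` and mirrors,
#' emulating a sequencing depth reduced by `ratio`.  `ratio = 1` returns the
#' input unchanged.
#'
#' @param m A `ContactMatrix` with integer counts.
#' @param ratio Downsampling ratio >= 1 (the study design uses 2, 4, 9, 16, 36).
#' @param seed Integer seed.
#' @return A `ContactMatrix` with entrywise counts <= the input's.
#' @export
downsample <- function(m, ratio, seed) {
  stopifnot_cm(m)
  if (ratio < 1) stop("ratio must be >= 1")
  if (any(m$counts != round(m$counts))) stop("downsample needs integer counts")
  if (ratio == 1) return(m)
  up <- which(upper.tri(m$counts, diag = TRUE))
  cnt <- as.integer(round(m$counts[up]))
  thinned <- with_seed(seed, stats::rbinom(length(cnt), cnt, 1 / ratio))
  out <- matrix(0, m$n_bins, m$n_bins)
  out[up] <- thinned
  out <- mirror_upper(out)
  contact_matrix(out, m$resolution_bp, cell_id = m$cell_id, chrom = m$chrom)
}

#' Simulate a cohort of synthetic cells
#'
#' @param spec A [synthetic_spec()].
#' @return List of `ContactMatrix`, one per cell; per-cell seeds are derived
#'   from `spec$seed` so the cohort is reproducible as a whole.
#' @export
simulate_cohort <- function(spec) {
  intensity <- build_intensity(spec)
  lapply(seq_len(spec$n_cells), function(i) {
    sample_cell(intensity, spec$depth_per_cell,
                seed = derive_seed(spec$seed, paste0("cell", i)),
                cell_id = sprintf("cell_%03d", i), chrom = "chrS")
  })
}

# Ground-truth sidecar describing the planted structure, written next to
# simulated cohorts and consumed by evaluation code.
spec_ground_truth <- function(spec) {
  list(
    n_bins = spec$n_bins,
    resolution_bp = spec$resolution_bp,
    seed = spec$seed,
    compartment_profile = spec$compartment_profile,
    tad_boundaries = tad_junctions(spec),
    loops = lapply(spec$loops, function(lp) list(bin_i = lp[1], bin_j = lp[2], strength = lp[3]))
  )
}

# Internal junctions between adjacent TAD blocks (0-based bin of the first bin
# of the downstream block); these are the boundaries a caller should recover.
tad_junctions <- function(spec) {
  if (length(spec$tad_blocks) < 2L) return(integer())
  iv <- do.call(rbind, lapply(spec$tad_blocks, function(b) as.integer(b[1:2])))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  starts <- iv[-1, 1]
  ends <- iv[-nrow(iv), 2]
  sort(unique(starts[starts == ends]))
}
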