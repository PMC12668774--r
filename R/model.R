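# The dual-branch enhancement network.
#
# Each branch processes one submatrix (the w x w context window or its k x k
# central crop): a two-conv stem expands the single-channel map into feature
# channels, a squeeze-and-excitation (SE) block recalibrates them, an n x 1
# convolution collapses one spatial axis into per-channel rank-one vectors
# which two 1-D convolutions refine, and weighted outer products v v^T
# reconstruct exactly symmetric feature maps; a 1x1-projected additive skip
# from the stem preserves information around the rank-one bottleneck.  The
# branch stacks are cropped/aligned to k x k, concatenated, fused by two 1x1
# convolutions, symmetrized and passed through a clamped softplus.

#' Generator configuration
#'
#' @param window Outer submatrix size `w` in bins.
#' @param central Central (enhanced) size `k < w`, with `w - k` even.
#' @param channels Stem channel widths (two 3x3 convolutions).
#' @param se_reduction SE bottleneck reduction `r`; must divide the stem
#'   output width.
#' @param n_rank_one_channels Number of rank-one channels per branch.
#' @param activation Stem nonlinearity (`"relu"` only, kept for provenance).
#' @param final_cap Upper clamp of the output softplus (default 1.2, so
#'   denormalized counts are nonnegative without hard saturation at 1).
#' @param se_bypass If TRUE all SE gates are forced to exactly 1 (identity);
#'   a testing aid, since exact sigmoid saturation is unreachable.
#' @return A `GeneratorConfig`.
#' @export
generator_config <- function(window = 40L, central = 28L, channels = c(16L, 32L),
                             se_reduction = 4L, n_rank_one_channels = 16L,
                             activation = "relu", final_cap = 1.2,
                             se_bypass = FALSE) {
  window <- as.integer(window); central <- as.integer(central)
  if (central <= 0L || window <= central) stop("need 0 < central < window")
  if ((window - central) %% 2L != 0L) stop("(window - central) must be even")
  if (length(channels) != 2L || any(channels <= 0L)) stop("channels must be two positive widths")
  if (channels[2] %% se_reduction != 0L) stop("se_reduction must divide the stem output width")
  if (n_rank_one_channels < 1L) stop("need at least one rank-one channel")
  structure(list(window = window, central = central,
                 channels = as.integer(channels),
                 se_reduction = as.integer(se_reduction),
                 n_rank_one_channels = as.integer(n_rank_one_channels),
                 activation = activation, final_cap = final_cap,
                 se_bypass = isTRUE(se_bypass)),
            class = "GeneratorConfig")
}

#' Discriminator configuration
#'
#' @param channels Widths of the two strided convolution stages.
#' @param patch_output If TRUE, return the patch realness grid instead of its
#'   mean.
#' @return A `DiscriminatorConfig`.
#' @export
discriminator_config <- function(channels = c(8L, 16L), patch_output = FALSE) {
  if (any(channels <= 0L)) stop("channels must be positive")
  structure(list(channels = as.integer(channels), patch_output = isTRUE(patch_output)),
            class = "DiscriminatorConfig")
}

he_init <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)

# raw value whose softplus is 1, used to start rank-one channel weights at 1
.softplus_inv_1 <- log(expm1(1))

init_branch_params <- function(n, cfg) {
  c1 <- cfg$channels[1]; c2 <- cfg$channels[2]
  cr <- cfg$n_rank_one_channels
  rr <- cfg$se_reduction
  list(
    conv1W = he_init(9L, c1, 9),        conv1b = numeric(c1),
    conv2W = he_init(9L * c1, c2, 9 * c1), conv2b = numeric(c2),
    seW1 = he_init(c2, c2 %/% rr, c2),  seb1 = numeric(c2 %/% rr),
    seW2 = he_init(c2 %/% rr, c2, c2 %/% rr), seb2 = numeric(c2),
    nx1W = he_init(n * c2, cr, n * c2), nx1b = numeric(cr),
    r1aW = he_init(3L * cr, cr, 3 * cr), r1ab = numeric(cr),
    r1bW = he_init(3L * cr, cr, 3 * cr), r1bb = numeric(cr),
    wraw = rep(.softplus_inv_1, cr),
    skipW = he_init(c2, cr, c2),        skipb = numeric(cr)
  )
}

#' Initialize generator parameters
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed for the (He-normal) initialization.
#' @return Flat named list of parameter arrays; branch parameters are
#'   prefixed `outer.` / `central.`.
#' @export
init_generator_params <- function(cfg, seed = 1L) {
  with_seed(seed, {
    cr <- cfg$n_rank_one_channels
    f1 <- 16L
    po <- init_branch_params(cfg$window, cfg)
    pc <- init_branch_params(cfg$central, cfg)
    flat <- c(stats::setNames(po, paste0("outer.", names(po))),
              stats::setNames(pc, paste0("central.", names(pc))),
              list(fuse1W = he_init(2L * cr, f1, 2 * cr), fuse1b = numeric(f1),
                   fuse2W = he_init(f1, 1L, f1), fuse2b = -2))
    flat
  })
}

#' Initialize discriminator parameters
#'
#' @param cfg A [discriminator_config()].
#' @param seed Integer seed.
#' @return Flat named list of parameter arrays.
#' @export
init_discriminator_params <- function(cfg, seed = 1L) {
  with_seed(seed, {
    d1 <- cfg$channels[1]; d2 <- cfg$channels[2]
    list(conv1W = he_init(9L, d1, 9), conv1b = numeric(d1),
         conv2W = he_init(9L * d1, d2, 9 * d1), conv2b = numeric(d2),
         headW = he_init(d2, 1L, d2), headb = numeric(1L))
  })
}

#' Number of parameters in a flat parameter list
#' @param params Flat named list of arrays.
#' @return Integer total count.
#' @export
n_params <- function(params) sum(vapply(params, length, integer(1)))

params_to_nodes <- function(tape, params, trainable = TRUE) {
  lapply(params, function(p) if (trainable) ad_param(tape, p) else ad_const(tape, p))
}

# SE block: global average pool -> C -> C/r -> C -> sigmoid gates.
se_fwd <- function(tape, x, P, prefix, cfg) {
  if (cfg$se_bypass) return(x)
  z <- ad_gap(tape, x)
  hmid <- ad_relu(tape, ad_dense(tape, z, P[[paste0(prefix, "seW1")]], P[[paste0(prefix, "seb1")]]))
  s <- ad_sigmoid(tape, ad_dense(tape, hmid, P[[paste0(prefix, "seW2")]], P[[paste0(prefix, "seb2")]]))
  ad_scale_channels(tape, x, s)
}

branch_fwd <- function(tape, P, prefix, x_arr, cfg) {
  g <- function(nm) P[[paste0(prefix, nm)]]
  n <- dim(x_arr)[1]
  x <- ad_const(tape, x_arr)
  x <- ad_sym3(tape, x)                       # enforce symmetric branch input
  h1 <- ad_relu(tape, ad_conv2d(tape, x, g("conv1W"), g("conv1b")))
  stem <- ad_relu(tape, ad_conv2d(tape, h1, g("conv2W"), g("conv2b")))
  stem <- se_fwd(tape, stem, P, prefix, cfg)
  vecs <- ad_conv_nx1(tape, stem, g("nx1W"), g("nx1b"))
  v1 <- ad_relu(tape, ad_conv1d(tape, vecs, g("r1aW"), g("r1ab")))
  v2 <- ad_conv1d(tape, v1, g("r1bW"), g("r1bb"))
  wts <- ad_softplus_vec(tape, g("wraw"))
  recon <- ad_outer_bundle(tape, v2, wts)
  skip <- ad_conv1x1(tape, stem, g("skipW"), g("skipb"))
  ad_add(tape, recon, skip)
}

# Full generator graph; returns the (k, k, 1) output node.
generator_graph <- function(tape, P, outer_arr, central_arr, cfg) {
  k <- cfg$central
  p <- (cfg$window - k) %/% 2L
  a_out <- branch_fwd(tape, P, "outer.", outer_arr, cfg)
  b_out <- branch_fwd(tape, P, "central.", central_arr, cfg)
  a_cropped <- ad_crop(tape, a_out, p + seq_len(k), p + seq_len(k))
  fused <- ad_concat_channels(tape, a_cropped, b_out)
  fused <- ad_relu(tape, ad_conv1x1(tape, fused, P$fuse1W, P$fuse1b))
  fused <- ad_conv1x1(tape, fused, P$fuse2W, P$fuse2b)
  fused <- ad_sym3(tape, fused)
  ad_softplus_clamp(tape, fused, cfg$final_cap)
}

#' Generator forward pass
#'
#' @param outer_tile `w x w` matrix (normalized to `[0, 1]`).
#' @param central_tile `k x k` matrix (normalized).
#' @param params Flat parameter list from [init_generator_params()].
#' @param cfg The matching [generator_config()].
#' @return Enhanced `k x k` matrix, exactly symmetric, values in
#'   `[0, final_cap]`.
#' @export
generator_forward <- function(outer_tile, central_tile, params, cfg) {
  outer_tile <- as.matrix(outer_tile); central_tile <- as.matrix(central_tile)
  if (!all(is.finite(outer_tile)) || !all(is.finite(central_tile))) {
    stop("non-finite generator input")
  }
  if (!all(dim(outer_tile) == cfg$window) || !all(dim(central_tile) == cfg$central)) {
    stop("tile shapes do not match the generator configuration")
  }
  tape <- ad_tape()
  P <- params_to_nodes(tape, params, trainable = FALSE)
  out <- generator_graph(tape, P,
                         array(outer_tile, c(cfg$window, cfg$window, 1L)),
                         array(central_tile, c(cfg$central, cfg$central, 1L)),
                         cfg)
  matrix(out$value, cfg$central, cfg$central)
}

# Discriminator graph on a (k, k, 1) constant input.
discriminator_graph <- function(tape, P, tile_arr, cfg) {
  x <- ad_const(tape, tile_arr)
  h <- ad_lrelu(tape, ad_conv2d(tape, x, P$conv1W, P$conv1b))
  h <- ad_stride2(tape, h)
  h <- ad_lrelu(tape, ad_conv2d(tape, h, P$conv2W, P$conv2b))
  h <- ad_stride2(tape, h)
  ad_conv1x1(tape, h, P$headW, P$headb)     # patch realness grid
}

#' Discriminator forward pass
#'
#' @param tile `k x k` matrix (normalized).
#' @param params Flat parameter list from [init_discriminator_params()].
#' @param cfg The matching [discriminator_config()].
#' @return Scalar realness score, or the patch grid when
#'   `cfg$patch_output` is TRUE.
#' @export
discriminator_forward <- function(tile, params, cfg) {
  tile <- as.matrix(tile)
  if (!all(is.finite(tile))) stop("non-finite discriminator input")
  tape <- ad_tape()
  P <- params_to_nodes(tape, params, trainable = FALSE)
  out <- discriminator_graph(tape, P, array(tile, c(dim(tile), 1L)), cfg)
  if (cfg$patch_output) out$value[, , 1L] else mean(out$value)
}

# --- public rank-one / SE operations on plain arrays -----------------------

#' Parameters for a stand-alone rank-one extraction module
#'
#' @param n Spatial size of the input feature maps.
#' @param c_in Number of input channels.
#' @param channels Number of rank-one channels `C`.
#' @param seed Integer seed (ignored when `identity_refine = TRUE` weights
#'   are requested for the 1-D refinements).
#' @param identity_refine If TRUE the two 1-D convolutions are initialized to
#'   the identity (center tap 1) with zero bias, so the refined vectors equal
#'   the raw `n x 1` convolution output.
#' @return Parameter list consumed by [rank_one_extract()].
#' @export
rank_one_params <- function(n, c_in, channels, seed = 1L, identity_refine = FALSE) {
  with_seed(seed, {
    p <- list(nx1W = he_init(n * c_in, channels, n * c_in), nx1b = numeric(channels),
              r1aW = he_init(3L * channels, channels, 3 * channels), r1ab = numeric(channels),
              r1bW = he_init(3L * channels, channels, 3 * channels), r1bb = numeric(channels),
              wraw = rep(.softplus_inv_1, channels))
    if (identity_refine) {
      idw <- matrix(0, 3L * channels, channels)
      idw[channels + seq_len(channels), ] <- diag(channels)   # center tap
      p$r1aW <- idw; p$r1bW <- idw
      p$r1ab <- numeric(channels); p$r1bb <- numeric(channels)
    }
    p
  })
}

#' Rank-one feature extraction
#'
#' Collapses one spatial axis of an `n x n x C_in` feature stack with an
#' `n x 1` convolution, then refines each of the `C` resulting length-`n`
#' vectors with two 1-D convolutions (kernel 3, padding 1, ReLU between).
#'
#' @param x `n x n x C_in` array (a matrix is treated as `C_in = 1`).
#' @param params From [rank_one_params()] (fields `nx1W`, `nx1b`, `r1aW`,
#'   `r1ab`, `r1bW`, `r1bb`, `wraw`).
#' @return A `RankOneBundle`: list with `vectors` (`n x C`) and
#'   `channel_weights` (softplus of `wraw`, hence nonnegative).
#' @export
rank_one_extract <- function(x, params) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  n <- dim(x)[1]
  if (dim(x)[2] != n) stop("rank-one extraction needs square spatial input")
  if (nrow(params$nx1W) != n * dim(x)[3]) stop("spatial size mismatch with params")
  tape <- ad_tape()
  P <- params_to_nodes(tape, params, trainable = FALSE)
  xn <- ad_const(tape, x)
  vecs <- ad_conv_nx1(tape, xn, P$nx1W, P$nx1b)
  v1 <- ad_relu(tape, ad_conv1d(tape, vecs, P$r1aW, P$r1ab))
  v2 <- ad_conv1d(tape, v1, P$r1bW, P$r1bb)
  structure(list(vectors = v2$value,
                 channel_weights = ifelse(params$wraw > 30, params$wraw,
                                          log1p(exp(pmin(params$wraw, 30))))),
            class = "RankOneBundle")
}

#' Rank-one symmetric reconstruction
#'
#' Channel `c` of the output is `channel_weights[c] * v_c v_c^T`, which is
#' exactly (bitwise) symmetric and has numerical rank at most 1.
#'
#' @param bundle A `RankOneBundle` (or list with `vectors`, `channel_weights`).
#' @return `n x n x C` array of symmetric feature maps.
#' @export
rank_one_reconstruct <- function(bundle) {
  v <- bundle$vectors
  wts <- bundle$channel_weights
  if (any(wts < 0)) stop("channel_weights must be nonnegative")
  n <- nrow(v); C <- ncol(v)
  out <- array(0, c(n, n, C))
  for (c in seq_len(C)) out[, , c] <- wts[c] * tcrossprod(v[, c])
  out
}

#' Squeeze-and-excitation channel recalibration
#'
#' Global-average-pools each channel, passes the pooled vector through a
#' two-layer perceptron with a sigmoid output, and scales each channel by its
#' gate in `(0, 1)`.  Symmetric inputs stay symmetric (per-channel scalar
#' scaling).
#'
#' @param x `n x n x C` array.
#' @param params List with `seW1` (`C x C/r`), `seb1`, `seW2` (`C/r x C`),
#'   `seb2`.
#' @param bypass If TRUE, all gates are forced to exactly 1.
#' @return Recalibrated array of the same shape.
#' @export
se_recalibrate <- function(x, params, bypass = FALSE) {
  C <- dim(x)[3]
  if (nrow(params$seW1) != C) stop("channel count does not match SE params")
  if (bypass) return(x)
  z <- colMeans(matrix(x, prod(dim(x)[1:2]), C))
  hmid <- pmax(drop(z %*% params$seW1) + params$seb1, 0)
  s <- 1 / (1 + exp(-(drop(hmid %*% params$seW2) + params$seb2)))
  x * array(rep(s, each = prod(dim(x)[1:2])), dim(x))
}

#' Parameters for a stand-alone SE module
#' @param channels Number of channels `C`.
#' @param reduction Bottleneck reduction `r` (must divide `C`).
#' @param seed Integer seed.
#' @return Parameter list for [se_recalibrate()].
#' @export
se_params <- function(channels, reduction = 4L, seed = 1L) {
  if (channels %% reduction != 0L) stop("reduction must divide the channel count")
  with_seed(seed, list(
    seW1 = he_init(channels, channels %/% reduction, channels),
    seb1 = numeric(channels %/% reduction),
    seW2 = he_init(channels %/% reduction, channels, channels %/% reduction),
    seb2 = numeric(channels)
  ))
}
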