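# GAN training: pairing by downsampling, alternating least-squares GAN
# updates, and whole-matrix enhancement.

#' Training configuration
#'
#' @param epochs Number of passes over the training tiles.
#' @param batch_size Tiles per optimizer step.
#' @param lr_g,lr_d Adam learning rates for generator and discriminator.
#' @param lambda_rec,lambda_adv Loss weights: total generator loss is
#'   `lambda_rec * L1(generated, target) + lambda_adv * LSGAN`.  With
#'   `lambda_adv = 0` training reduces to supervised L1 regression.
#' @param downsample_ratio Depth reduction used to build training pairs
#'   (the study uses 2, 4, 9, 16 or 36).
#' @param seed Seed governing initialization, pairing and shuffling.
#' @param validation_fraction Fraction of cells (never tiles) held out for
#'   validation.
#' @return A `TrainConfig`.
#' @export
train_config <- function(epochs = 30L, batch_size = 4L, lr_g = 1e-3, lr_d = 1e-3,
                         lambda_rec = 10, lambda_adv = 1, downsample_ratio = 9,
                         seed = 1L, validation_fraction = 1 / 6) {
  if (lambda_rec <= 0) stop("lambda_rec must be > 0")
  if (lambda_adv < 0) stop("lambda_adv must be >= 0")
  if (validation_fraction < 0 || validation_fraction >= 1) {
    stop("validation_fraction must be in [0, 1)")
  }
  if (downsample_ratio < 1) stop("downsample_ratio must be >= 1")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_g = lr_g, lr_d = lr_d, lambda_rec = lambda_rec,
                 lambda_adv = lambda_adv, downsample_ratio = downsample_ratio,
                 seed = as.integer(seed), validation_fraction = validation_fraction),
            class = "TrainConfig")
}

#' Build (input, target) training pairs by downsampling
#'
#' Each cell is binomially downsampled, both versions are normalized with a
#' shared cap, the downsampled copy is tiled with [extract_submatrices()],
#' and the targets are the corresponding central `k x k` tiles of the
#' normalized original.
#'
#' @param cells List of `ContactMatrix` (raw counts).
#' @param ratio Downsampling ratio >= 1.
#' @param seed Integer seed (per-cell thinning seeds are derived from it).
#' @param w,k Window and central tile sizes.
#' @param cap Normalization cap; estimated from `cells` when NULL.
#' @return A `PairSet`: list with `pairs` (each `list(outer, central, target,
#'   cell)`), `cap`, `w`, `k`, `ratio`, `n_cells`, `cells_downsampled`.
#' @export
make_pairs <- function(cells, ratio, seed = 1L, w = 40L, k = 28L, cap = NULL) {
  if (length(cells) == 0L) stop("empty cell list")
  if (ratio < 1) stop("ratio must be >= 1")
  if (is.null(cap)) cap <- estimate_cap(cells)
  pairs <- list()
  ds_cells <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    ds <- downsample(cells[[i]], ratio, seed = derive_seed(seed, paste0("pair_ds", i)))
    ds_cells[[i]] <- ds
    dn <- normalize_counts(ds, cap)
    on <- normalize_counts(cells[[i]], cap)
    bd <- extract_submatrices(dn, w = w, k = k, cap = cap)
    bt <- extract_submatrices(on, w = w, k = k, cap = cap)
    p <- bd$pad
    for (t in seq_along(bd$outer_tiles)) {
      pairs[[length(pairs) + 1L]] <- list(
        outer = bd$outer_tiles[[t]],
        central = central_crop(bd$outer_tiles[[t]], p, bd$central_size),
        target = central_crop(bt$outer_tiles[[t]], p, bt$central_size),
        cell = i)
    }
  }
  structure(list(pairs = pairs, cap = cap, w = as.integer(w), k = as.integer(k),
                 ratio = ratio, n_cells = length(cells),
                 cells_downsampled = ds_cells),
            class = "PairSet")
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

collect_grads <- function(nodes) lapply(nodes, function(n) n$grad)

#' Train the enhancement GAN
#'
#' Alternating updates: the generator minimizes `lambda_rec * L1 +
#' lambda_adv * (D(fake) - 1)^2`, the discriminator minimizes the
#' least-squares GAN objective on (target = real, generated = fake) tiles.
#' Validation splits by whole cells, never by tiles.  A fixed seed gives a
#' reproducible history (single-threaded BLAS assumed for bitwise identity).
#'
#' @param pairset A `PairSet` from [make_pairs()].
#' @param gcfg,dcfg Network configurations.
#' @param tcfg A [train_config()].
#' @param init Optional checkpoint to continue training from.
#' @param verbose Print one line per epoch.
#' @return List with `checkpoint` (class `schic_checkpoint`) and `history`
#'   (data.frame: epoch, g_loss, d_loss, val_mae).
#' @export
train_gan <- function(pairset, gcfg = generator_config(), dcfg = discriminator_config(),
                      tcfg = train_config(), init = NULL, verbose = FALSE) {
  if (!inherits(pairset, "PairSet")) stop("pairset must come from make_pairs()")
  if (length(pairset$pairs) < 1L) stop("need at least one training pair")
  if (pairset$w != gcfg$window || pairset$k != gcfg$central) {
    stop("pair tile sizes do not match the generator configuration")
  }
  k <- gcfg$central

  cell_ids <- vapply(pairset$pairs, function(p) p$cell, integer(1))
  ucells <- sort(unique(cell_ids))
  n_val_cells <- floor(length(ucells) * tcfg$validation_fraction)
  val_cells <- if (n_val_cells > 0L) utils::tail(ucells, n_val_cells) else integer()
  train_idx <- which(!(cell_ids %in% val_cells))
  val_idx <- which(cell_ids %in% val_cells)
  if (length(train_idx) == 0L) stop("validation split left no training tiles")

  gparams <- if (!is.null(init)) init$gparams else init_generator_params(gcfg, derive_seed(tcfg$seed, "ginit"))
  dparams <- if (!is.null(init)) init$dparams else init_discriminator_params(dcfg, derive_seed(tcfg$seed, "dinit"))
  gstate <- adam_state(gparams)
  dstate <- adam_state(dparams)

  history <- data.frame(epoch = integer(), g_loss = numeric(),
                        d_loss = numeric(), val_mae = numeric())
  if (tcfg$epochs > 0L) {
    for (ep in seq_len(tcfg$epochs)) {
      ord <- with_seed(derive_seed(tcfg$seed, paste0("shuffle", ep)),
                       sample(train_idx))
      batches <- split(ord, ceiling(seq_along(ord) / tcfg$batch_size))
      ep_g <- 0; ep_d <- 0; nb <- 0L
      for (bi in seq_along(batches)) {
        b <- batches[[bi]]
        # --- generator step -------------------------------------------------
        tape <- ad_tape()
        P <- params_to_nodes(tape, gparams, trainable = TRUE)
        D <- params_to_nodes(tape, dparams, trainable = FALSE)
        fake_vals <- vector("list", length(b))
        loss <- NULL
        for (j in seq_along(b)) {
          pr <- pairset$pairs[[b[j]]]
          out <- generator_graph(tape, P,
                                 array(pr$outer, c(gcfg$window, gcfg$window, 1L)),
                                 array(pr$central, c(k, k, 1L)), gcfg)
          fake_vals[[j]] <- out$value
          lrec <- ad_scale(tape, ad_l1_loss(tape, out, array(pr$target, c(k, k, 1L))),
                           tcfg$lambda_rec)
          ltile <- lrec
          if (tcfg$lambda_adv > 0) {
            dsc <- discriminator_graph_node(tape, D, out, dcfg)
            ladv <- ad_scale(tape, ad_mse_loss(tape, dsc, 1), tcfg$lambda_adv)
            ltile <- ad_add(tape, lrec, ladv)
          }
          loss <- if (is.null(loss)) ltile else ad_add(tape, loss, ltile)
        }
        loss <- ad_scale(tape, loss, 1 / length(b))
        if (!is.finite(loss$value)) {
          stop(sprintf("non-finite generator loss in epoch %d, batch %d", ep, bi))
        }
        ad_backward(tape, loss)
        upd <- adam_step(gparams, collect_grads(P), gstate, tcfg$lr_g)
        gparams <- upd$params; gstate <- upd$state
        ep_g <- ep_g + loss$value

        # --- discriminator step --------------------------------------------
        if (tcfg$lambda_adv > 0) {
          tape2 <- ad_tape()
          Dp <- params_to_nodes(tape2, dparams, trainable = TRUE)
          dloss <- NULL
          for (j in seq_along(b)) {
            pr <- pairset$pairs[[b[j]]]
            real <- discriminator_graph(tape2, Dp, array(pr$target, c(k, k, 1L)), dcfg)
            fake <- discriminator_graph(tape2, Dp, fake_vals[[j]], dcfg)
            lj <- ad_add(tape2,
                         ad_mse_loss(tape2, real, 1),
                         ad_mse_loss(tape2, fake, 0))
            dloss <- if (is.null(dloss)) lj else ad_add(tape2, dloss, lj)
          }
          dloss <- ad_scale(tape2, dloss, 0.5 / length(b))
          if (!is.finite(dloss$value)) {
            stop(sprintf("non-finite discriminator loss in epoch %d, batch %d", ep, bi))
          }
          ad_backward(tape2, dloss)
          updd <- adam_step(dparams, collect_grads(Dp), dstate, tcfg$lr_d)
          dparams <- updd$params; dstate <- updd$state
          ep_d <- ep_d + dloss$value
        }
        nb <- nb + 1L
      }
      val_mae <- if (length(val_idx) > 0L) {
        mean(vapply(val_idx, function(i) {
          pr <- pairset$pairs[[i]]
          out <- generator_forward(pr$outer, pr$central, gparams, gcfg)
          mean(abs(out - pr$target))
        }, numeric(1)))
      } else NA_real_
      history <- rbind(history, data.frame(epoch = ep, g_loss = ep_g / nb,
                                           d_loss = if (tcfg$lambda_adv > 0) ep_d / nb else NA_real_,
                                           val_mae = val_mae))
      if (verbose) {
        message(sprintf("epoch %3d  g_loss %.5f  d_loss %s  val_mae %s",
                        ep, ep_g / nb,
                        ifelse(tcfg$lambda_adv > 0, sprintf("%.5f", ep_d / nb), "-"),
                        ifelse(is.na(val_mae), "-", sprintf("%.5f", val_mae))))
      }
    }
  }

  checkpoint <- structure(
    list(gparams = gparams, dparams = dparams, gcfg = gcfg, dcfg = dcfg,
         cap = pairset$cap, seed = tcfg$seed, ratio = pairset$ratio,
         val_cells = val_cells),
    class = "schic_checkpoint")
  list(checkpoint = checkpoint, history = history)
}

# discriminator graph taking an existing node as input (for the adversarial
# term inside the generator's tape)
discriminator_graph_node <- function(tape, P, xnode, cfg) {
  h <- ad_lrelu(tape, ad_conv2d(tape, xnode, P$conv1W, P$conv1b))
  h <- ad_stride2(tape, h)
  h <- ad_lrelu(tape, ad_conv2d(tape, h, P$conv2W, P$conv2b))
  h <- ad_stride2(tape, h)
  ad_conv1x1(tape, h, P$headW, P$headb)
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles generator and discriminator parameters, both
#' configurations, the normalization cap and the training seed — everything
#' [enhance()] needs.
#'
#' @param checkpoint A `schic_checkpoint`.
#' @param path File path.
#' @return `load_checkpoint` returns the checkpoint; `save_checkpoint`
#'   returns `path` invisibly.
#' @export
save_checkpoint <- function(checkpoint, path) {
  if (!inherits(checkpoint, "schic_checkpoint")) stop("not a checkpoint")
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "schic_checkpoint")) stop("file is not a model checkpoint")
  ck
}

block_mask <- function(n, k, anchors) {
  mask <- matrix(FALSE, n, n)
  for (a in anchors) {
    nb <- min(k, n - a)
    if (nb > 0L) mask[a + seq_len(nb), a + seq_len(nb)] <- TRUE
  }
  mask
}

#' Mask of entries written by whole-matrix enhancement
#'
#' The primary pass writes disjoint `k x k` diagonal blocks at anchors
#' `0, k, 2k, ...`; a second pass offset by `k/2` covers the cross-block
#' rectangles between consecutive blocks, so the union is a seam-free
#' diagonal band.
#'
#' @param n_bins Matrix size.
#' @param k Central tile size.
#' @return Logical `n x n` matrix, TRUE where [enhance()] writes values.
#' @export
enhanced_band_mask <- function(n_bins, k) {
  m1 <- block_mask(n_bins, k, seq(0L, n_bins - 1L, by = k))
  off <- k %/% 2L
  if (off > 0L && off < n_bins) {
    m1 | block_mask(n_bins, k, seq(off, n_bins - 1L, by = k))
  } else m1
}

run_generator_pass <- function(nm, checkpoint, offset) {
  gcfg <- checkpoint$gcfg
  batch <- extract_submatrices(nm, w = gcfg$window, k = gcfg$central,
                               cap = checkpoint$cap, offset = offset)
  p <- batch$pad
  enhanced <- lapply(batch$outer_tiles, function(tile) {
    generator_forward(tile, central_crop(tile, p, gcfg$central),
                      checkpoint$gparams, gcfg)
  })
  list(merged = merge_submatrices(batch, enhanced), anchors = batch$anchors)
}

#' Enhance a whole contact matrix
#'
#' Normalizes with the checkpoint's stored cap, tiles, runs the generator on
#' every tile and merges the central blocks.  A second generator pass with
#' anchors offset by `k/2` fills the cross-block rectangles between
#' consecutive central blocks, so the assembled region is a seam-free
#' diagonal band (see [enhanced_band_mask()]).  Entries outside that band
#' are copied verbatim from the input: the network never saw those genomic
#' distances, so inventing values there would be unsupported extrapolation.
#'
#' @param checkpoint A `schic_checkpoint`.
#' @param m A `ContactMatrix` on the count scale with `n_bins >= k`.
#' @return A `ContactMatrix` of real, nonnegative, symmetric enhanced values.
#' @export
enhance <- function(checkpoint, m) {
  if (!inherits(checkpoint, "schic_checkpoint")) stop("not a checkpoint")
  stopifnot_cm(m)
  gcfg <- checkpoint$gcfg
  k <- gcfg$central
  n <- m$n_bins
  if (n < k) stop("matrix smaller than the enhancement tile")
  cap <- checkpoint$cap
  nm <- normalize_counts(m, cap)

  pass1 <- run_generator_pass(nm, checkpoint, offset = 0L)
  mask1 <- block_mask(n, k, pass1$anchors)
  vals <- pass1$merged$counts

  off <- k %/% 2L
  if (off > 0L && off < n) {
    pass2 <- run_generator_pass(nm, checkpoint, offset = off)
    mask2 <- block_mask(n, k, pass2$anchors)
    fill <- mask2 & !mask1
    vals[fill] <- pass2$merged$counts[fill]
  }

  out <- denormalize_counts(vals, cap)
  band <- enhanced_band_mask(n, k)
  out[!band] <- m$counts[!band]
  out <- pmax(symmetrize(out), 0)
  contact_matrix(out, m$resolution_bp, cell_id = m$cell_id, chrom = m$chrom)
}
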