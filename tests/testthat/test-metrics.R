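test_that("MAE matches direct elementwise means and is symmetric in arguments", {
  expect_equal(mae(matrix(1, 3, 3), matrix(1, 3, 3)), 0)
  expect_equal(mae(matrix(c(0, 1, 1, 0), 2), matrix(1, 2, 2)), 0.5)
  a <- rand_sym(6, 1); b <- rand_sym(6, 2)
  expect_equal(mae(a, b), mae(b, a))
  expect_error(mae(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("binarized macro F1 matches the confusion-matrix oracle", {
  t1 <- matrix(c(0, 1, 1, 3), 2)
  expect_equal(binarized_macro_f1(t1, t1), 1)
  expect_equal(binarized_macro_f1(matrix(c(2, 0, 0, 0), 2), t1), 0)
  expect_error(binarized_macro_f1(t1, matrix(0, 2, 2)), "all-zero")

  # fully over-smoothed prediction on a 4x4 case, oracle enumerated
  set.seed(7)
  truth <- rand_sym(4, seed = 7, scale = 0.8)
  truth[truth > 0 & truth < 1] <- 1
  tau <- min(truth[truth > 0])
  pred <- truth + tau * (truth == 0)
  expect_equal(binarized_macro_f1(pred, truth), oracle_macro_f1(pred, truth))
  expect_lt(binarized_macro_f1(pred, truth), 1)

  for (seed in 1:5) {
    p <- rand_sym(8, seed, scale = 2)
    t_ <- rand_sym(8, seed + 50, scale = 2)
    expect_equal(binarized_macro_f1(p, t_), oracle_macro_f1(p, t_))
  }
})

test_that("SCC attains 1 on self and affine copies, -1 on per-stratum negation", {
  a <- rand_sym(10, seed = 3, scale = 4)
  expect_equal(stratum_adjusted_correlation(a, a, h = 1), 1)
  expect_equal(stratum_adjusted_correlation(a, 2 * a + 5, h = 1), 1)

  # b = -a after mean-centering within strata (h = 0 so smoothing is off)
  n <- 10L
  b <- a * 0
  for (d in 0:(n - 1)) {
    idx <- cbind(seq_len(n - d), seq_len(n - d) + d)
    v <- a[idx]
    b[idx] <- -(v - mean(v))
    b[idx[, 2:1, drop = FALSE]] <- b[idx]
  }
  expect_equal(stratum_adjusted_correlation(a, b, h = 0), -1)
  expect_error(stratum_adjusted_correlation(matrix(1, 4, 4), matrix(1, 4, 4), h = 0),
               "no informative strata")
})

test_that("random-walk concordance matches a brute-force matrix-power oracle", {
  a <- rand_sym(6, seed = 11, scale = 3)
  b <- rand_sym(6, seed = 12, scale = 3)
  expect_equal(random_walk_concordance(a, a), 1)
  expect_equal(random_walk_concordance(a, b), random_walk_concordance(b, a))

  oracle <- function(x, y, t) {
    rn <- function(m) { rs <- rowSums(m); rs[rs == 0] <- 1; m / rs }
    px <- rn(x); py <- rn(y)
    ax <- px; ay <- py
    if (t > 1) for (s in 2:t) { ax <- ax %*% px; ay <- ay %*% py }
    1 - sum(abs(ax - ay)) / ((sum(rowSums(x) > 0) + sum(rowSums(y) > 0)) / 2)
  }
  expect_equal(random_walk_concordance(a, b, steps = 1), oracle(a, b, 1))
  expect_equal(random_walk_concordance(a, b, steps = 3), oracle(a, b, 3))
  expect_error(random_walk_concordance(matrix(0, 3, 3), matrix(0, 3, 3)), "empty")
})

test_that("flexible bin matching follows the greedy one-to-one rule", {
  r <- flexible_match_prf(c(3L, 9L), c(3L, 9L), shift = 0, n_bins = 20L)
  expect_equal(c(r$precision, r$recall), c(1, 1))

  expect_equal(flexible_match_prf(5L, 7L, shift = 1, n_bins = 20L)$tp, 0L)
  expect_equal(flexible_match_prf(5L, 7L, shift = 2, n_bins = 20L)$tp, 1L)

  r <- flexible_match_prf(c(3L, 4L), 4L, shift = 3, n_bins = 20L)
  expect_equal(r$tp, 1L)
  expect_equal(r$fp, 1L)
  expect_error(flexible_match_prf(1L, 1L, shift = -1, n_bins = 10L), "shift")
})

test_that("loop matching uses Chebyshev distance with one-to-one pairing", {
  ls <- loop_set(rbind(c(10L, 20L), c(30L, 44L)))
  r <- match_loops(ls, ls, pixel_shift = 1)
  expect_equal(c(r$precision, r$recall, r$n_exact), c(1, 1, 2))

  r <- match_loops(loop_set(rbind(c(10L, 20L))), loop_set(rbind(c(11L, 21L))), 1)
  expect_equal(c(r$tp, r$n_exact), c(1L, 0L))
  r <- match_loops(loop_set(rbind(c(10L, 20L))), loop_set(rbind(c(12L, 22L))), 1)
  expect_equal(r$tp, 0L)
})

test_that("every metric attains its perfect value on self-comparison", {
  for (seed in 1:3) {
    a <- rand_sym(15, seed, scale = 2)
    expect_equal(mae(a, a), 0)
    expect_equal(binarized_macro_f1(a, a), 1)
    expect_equal(stratum_adjusted_correlation(a, a), 1)
    expect_equal(random_walk_concordance(a, a), 1)
  }
})

test_that("increasing noise monotonically degrades SCC and concordance", {
  base <- tiny_cohort(n_cells = 1L, n_bins = 40L, depth = 20000L, seed = 2L)$cells[[1]]$counts
  deg <- function(amp) {
    mean(vapply(1:20, function(s) {
      set.seed(s)
      noise <- matrix(stats::rpois(1600, amp), 40)
      noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
      b <- base + noise
      c(stratum_adjusted_correlation(base, b),
        random_walk_concordance(base, b))
    }, numeric(2)) |> rowMeans() |> mean())
  }
  d <- vapply(c(1, 8, 40), deg, numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("macro F1 flags over-smoothing: dense prediction scores below support", {
  truth <- tiny_cohort(n_cells = 1L, n_bins = 40L, depth = 3000L, seed = 3L)$cells[[1]]$counts
  tau <- min(truth[truth > 0])
  dense <- truth + tau * (truth == 0)        # every pixel pushed above threshold
  support <- (truth >= tau) * tau            # exactly the truth support
  expect_lt(binarized_macro_f1(dense, truth), binarized_macro_f1(support, truth))
})

test_that("metric_report and cohort evaluation wire the metrics together", {
  co <- tiny_cohort(n_cells = 3L, n_bins = 40L, depth = 5000L, seed = 8L)
  rep <- metric_report(co$cells[[1]], co$cells[[1]])
  expect_equal(c(rep$mae, rep$macro_f1, rep$scc, rep$disco), c(0, 1, 1, 1))
  df <- evaluate_cohort(co$cells, co$cells)
  expect_equal(nrow(df), 4L)
  expect_equal(df$mae[4], 0)
  dfm <- evaluate_cohort(co$cells, co$cells, mode = "merged")
  expect_equal(dfm$macro_f1, 1)
  bulk <- aggregate_mean(co$cells)
  expect_equal(bulk$counts, (co$cells[[1]]$counts + co$cells[[2]]$counts +
                               co$cells[[3]]$counts) / 3)
})
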