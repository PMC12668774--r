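# Shared fixtures, all generated in code.

# random symmetric nonnegative matrix
rand_sym <- function(n, seed = 1L, scale = 5) {
  set.seed(seed)
  m <- matrix(stats::rpois(n * n, scale), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

rand_sym_cm <- function(n, seed = 1L, scale = 5, res = 100000L) {
  contact_matrix(rand_sym(n, seed, scale), res)
}

# tiny cohort memo so several test files can share one simulation
.fixture_env <- new.env(parent = emptyenv())

tiny_cohort <- function(n_cells = 6L, n_bins = 40L, depth = 5000L, seed = 11L) {
  key <- paste("cohort", n_cells, n_bins, depth, seed, sep = "_")
  got <- .fixture_env[[key]]
  if (!is.null(got)) return(got)
  sp <- synthetic_spec(n_bins = n_bins, depth_per_cell = depth,
                       n_cells = n_cells, seed = seed)
  out <- list(spec = sp, cells = simulate_cohort(sp))
  .fixture_env[[key]] <- out
  out
}

# independent confusion-matrix oracle for binarized macro F1
oracle_macro_f1 <- function(pred, truth) {
  tau <- min(truth[truth > 0])
  pp <- pred >= tau
  tp_ <- truth >= tau
  tp <- sum(pp & tp_); fp <- sum(pp & !tp_); fn <- sum(!pp & tp_); tn <- sum(!pp & !tp_)
  f1 <- function(a, b, c) {
    if (a + b + c == 0) return(1)            # class absent on both sides
    pr <- if (a + b > 0) a / (a + b) else 0
    rc <- if (a + c > 0) a / (a + c) else 0
    if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  }
  mean(c(f1(tp, fp, fn), f1(tn, fn, fp)))
}
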