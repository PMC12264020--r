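# Shared fixtures. Everything is generated in code; nothing is read from
# disk except files the tests themselves write to tempdirs.

# A small, fast 2-class / d=4 two-domain sequence for engine-level tests.
tiny_specs <- function(seed = 42, n_train = 30, n_test = 20) {
  means <- rbind(c(0, 0, 0, 0), c(3, 3, 0, 0))
  list(
    domain_spec("A", n_train, n_test, means, c(0.5, 0.5), seed = seed),
    domain_spec("B", n_train, n_test, means, c(0.5, 0.5),
                shift_vector = c(6, -6, 0, 0), seed = seed + 1))
}

tiny_cfg <- function(strategy = "naive", ...) {
  args <- utils::modifyList(
    list(strategy = strategy, hidden_widths = c(16L, 8L), epochs = 5L,
         batch_size = 16L, n_repeats = 1L),
    list(...))
  do.call(run_config, args)
}

# Two well-separated isotropic blobs in d dimensions.
two_blobs <- function(n_per = 50, d = 2, sep = 10, sd = 0.5, seed = 7) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d, sd = sd), n_per, d),
             matrix(rnorm(n_per * d, sd = sd), n_per, d) + sep)
  list(x = x, means = rbind(colMeans(x[1:n_per, , drop = FALSE]),
                            colMeans(x[-(1:n_per), , drop = FALSE])))
}

# Brute-force CL metric oracles: literal loops over the printed formulas,
# independent of the vectorised implementations they check.
oracle_acc <- function(P) {
  T_ <- nrow(P); s <- 0
  for (j in 1:T_) s <- s + P[T_, j]
  s / T_
}
oracle_bwt <- function(P) {
  T_ <- nrow(P); outer_sum <- 0
  for (j in 1:(T_ - 1)) {
    inner <- 0; cnt <- 0
    for (i in 1:T_) if (i > j) { inner <- inner + (P[i, j] - P[j, j]); cnt <- cnt + 1 }
    outer_sum <- outer_sum + inner / cnt
  }
  outer_sum / (T_ - 1)
}
oracle_ilm <- function(P) {
  T_ <- nrow(P); s <- 0
  for (i in 1:T_) for (j in 1:T_) if (j <= i) s <- s + P[i, j]
  2 * s / (T_ * (T_ + 1))
}

# One-sample Kolmogorov-Smirnov distance against an analytic CDF.
ks_distance <- function(samples, cdf) {
  x <- sort(samples); n <- length(x)
  Fx <- cdf(x)
  max(abs((1:n) / n - Fx), abs((0:(n - 1)) / n - Fx))
}

# The default 4-domain benchmark runs are expensive, so they are computed
# once per test session on first use and shared by every block that needs
# them (forgetting-mitigation and ablation properties).
benchmark_cache <- new.env(parent = emptyenv())

benchmark_results <- function() {
  if (!is.null(benchmark_cache$res)) return(benchmark_cache$res)
  seq4 <- make_sequence(default_benchmark_specs())
  strategies <- c("naive", "proposed", "joint", "dst_only", "glr_only")
  res <- lapply(strategies, function(s)
    run_experiment(seq4, run_config(strategy = s, n_repeats = 3L,
                                    base_seed = 101L)))
  names(res) <- strategies
  benchmark_cache$res <- res
  res
}
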