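#' Compress latents to K cluster centers
#'
#' K-means summarisation of one task's latent vectors. Only the resulting
#' centers are kept downstream, which is what makes the replay generator
#' privacy-preserving: raw training vectors are discarded (a center equals
#' a raw vector only when its cluster is a singleton).
#'
#' If the latents contain fewer than `K` distinct rows, `K` is clamped to
#' the number of distinct rows with a warning.
#'
#' @param latents Numeric `n x d` matrix.
#' @param K Number of clusters, `1 <= K <= n`.
#' @param seed Integer seed; the fit is deterministic given it.
#' @param nstart Random restarts (best fit kept).
#' @return `K x d` matrix of cluster centers; every center is the mean of a
#'   non-empty cluster.
#' @export
fit_kmeans <- function(latents, K, seed = 0L, nstart = 10L) {
  latents <- as.matrix(latents)
  n <- nrow(latents)
  abort_if(!is_count(K) || K < 1, "K must be a positive integer")
  abort_if(K > n, "K = ", K, " exceeds the number of rows (", n, ")")
  n_distinct <- nrow(unique(latents))
  if (K > n_distinct) {
    warning("K = ", K, " exceeds the ", n_distinct,
            " distinct rows; clamping K to ", n_distinct, call. = FALSE)
    K <- n_distinct
  }
  if (K == 1L) return(matrix(colMeans(latents), 1L, ncol(latents),
                             dimnames = list(NULL, colnames(latents))))
  if (K == n) return(latents[order(latents[, 1L]), , drop = FALSE])
  fit <- with_seed(derive_seed(seed, "kmeans"),
                   stats::kmeans(latents, centers = K, nstart = nstart,
                                 iter.max = 100L))
  fit$centers
}

# BIC of a K-means solution under a spherical-Gaussian mixture reading:
# one pooled per-dimension variance for the whole model, parameter count
# p = K*d (means) + K (mixing weights) + 1 (variance).
kmeans_bic <- function(latents, centers, assignment) {
  n <- nrow(latents); d <- ncol(latents); K <- nrow(centers)
  resid <- latents - centers[assignment, , drop = FALSE]
  ss <- sum(resid^2)
  v <- ss / (d * max(n - K, 1L))
  v <- max(v, 1e-12)
  nk <- tabulate(assignment, nbins = K)
  nk <- nk[nk > 0]
  loglik <- sum(nk * log(nk / n)) - n * d / 2 * log(2 * pi * v) -
    ss / (2 * v)
  p <- K * d + K + 1
  p * log(n) - 2 * loglik
}

#' Choose the cluster count by BIC
#'
#' Scores each candidate `K` with the Bayesian Information Criterion under
#' a spherical-Gaussian reading of the K-means solution (pooled variance,
#' `K*d + K + 1` parameters) and returns the candidate with the smallest
#' BIC; ties break toward smaller `K`.
#'
#' @param latents Numeric `n x d` matrix.
#' @param k_candidates Non-empty vector of positive integers, all `<= n`.
#' @param seed Integer seed shared by all candidate fits.
#' @return The chosen `K` (integer). The BIC values are attached as
#'   attribute `"bic"`.
#' @export
select_k_bic <- function(latents, k_candidates, seed = 0L) {
  latents <- as.matrix(latents)
  abort_if(length(k_candidates) < 1L, "k_candidates must be non-empty")
  abort_if(any(k_candidates < 1) || any(k_candidates != as.integer(k_candidates)),
           "k_candidates must be positive integers")
  abort_if(any(k_candidates > nrow(latents)),
           "all candidates must be <= n = ", nrow(latents))
  k_candidates <- as.integer(k_candidates)
  bics <- vapply(k_candidates, function(K) {
    centers <- fit_kmeans(latents, K, seed = seed)
    assignment <- nearest_support(latents, centers)
    kmeans_bic(latents, centers, assignment)
  }, numeric(1))
  ord <- order(bics, k_candidates)  # ties toward smaller K
  structure(k_candidates[ord[1L]], bic = stats::setNames(bics, k_candidates))
}

# Index of the nearest row of `centers` for each row of `x`.
nearest_support <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  max.col(-d2, ties.method = "first")
}

#' Silverman's rule-of-thumb bandwidth, per dimension
#'
#' For `m` points in `d` dimensions the diagonal Gaussian-kernel bandwidth
#' is `h_j = sigma_j * (4 / ((d + 2) * m))^(1 / (d + 4))`, with `sigma_j`
#' the sample standard deviation of column `j`. Entries are floored at
#' `floor_eps` so zero-variance columns still yield a usable kernel.
#'
#' @param points Numeric `m x d` matrix, `m >= 2`.
#' @param floor_eps Lower bound for each bandwidth entry.
#' @param pooled_sigma If `TRUE`, use a single pooled standard deviation
#'   (mean of the per-column ones) in every dimension.
#' @return Length-`d` vector of positive bandwidths.
#' @export
silverman_bandwidth <- function(points, floor_eps = 1e-6, pooled_sigma = FALSE) {
  points <- as.matrix(points)
  m <- nrow(points); d <- ncol(points)
  abort_if(m < 2, "bandwidth is undefined for fewer than 2 points")
  sds <- apply(points, 2L, stats::sd)
  if (pooled_sigma) sds <- rep(mean(sds), d)
  h <- sds * (4 / ((d + 2) * m))^(1 / (d + 4))
  pmax(h, floor_eps)
}

#' Create or update the replay generator
#'
#' `generator_state()` builds an empty state; `update_generator()` appends
#' a task's cluster centers to the retained support set and recomputes the
#' KDE bandwidth over the combined set. The state holds only `sum(K_t)`
#' center vectors regardless of the training-set sizes, which is the
#' privacy/compression property of the method.
#'
#' @param kind `"kde"` (default) or `"gmm"`.
#' @return An object of class `generator_state` with fields
#'   `support_points` (`m x d`), `per_task_counts`, `bandwidth`
#'   (`d`-vector, `NULL` until `m >= 2`), `kind`, and for GMM states a
#'   `gmm` list of per-task mixtures.
#' @export
generator_state <- function(kind = c("kde", "gmm")) {
  kind <- match.arg(kind)
  structure(list(support_points = NULL, per_task_counts = integer(0),
                 bandwidth = NULL, kind = kind, gmm = list()),
            class = "generator_state")
}

#' @export
print.generator_state <- function(x, ...) {
  m <- n_support(x)
  cat(sprintf("<generator_state kind=%s> m=%d support points over %d task(s)\n",
              x$kind, m, length(x$per_task_counts)))
  invisible(x)
}

n_support <- function(state) {
  if (is.null(state$support_points)) 0L else nrow(state$support_points)
}

#' @rdname generator_state
#' @param prev A `generator_state` (possibly empty) of kind `"kde"`.
#' @param new_centers `K x d` matrix of the new task's cluster centers.
#' @param floor_eps Bandwidth floor passed to [silverman_bandwidth()].
#' @export
update_generator <- function(prev = generator_state(), new_centers,
                             floor_eps = 1e-6) {
  abort_if(!inherits(prev, "generator_state"), "prev must be a generator_state")
  abort_if(prev$kind != "kde", "update_generator applies to KDE states")
  new_centers <- as.matrix(new_centers)
  if (!is.null(prev$support_points))
    abort_if(ncol(prev$support_points) != ncol(new_centers),
             "dimension mismatch: state has d = ", ncol(prev$support_points),
             ", new centers have d = ", ncol(new_centers))
  support <- rbind(prev$support_points, new_centers)
  state <- prev
  state$support_points <- support
  state$per_task_counts <- c(prev$per_task_counts, nrow(new_centers))
  state$bandwidth <- if (nrow(support) >= 2L)
    silverman_bandwidth(support, floor_eps = floor_eps) else NULL
  state
}

#' Sample synthetic latents from the generator
#'
#' KDE states draw a uniformly chosen support point plus diagonal Gaussian
#' noise with the per-dimension Silverman bandwidths; GMM states draw a
#' seen task uniformly, then a component by its mixture weight. The labels
#' of these synthetic latents are assigned downstream by the teacher model
#' ([pseudo_label()]), never stored here.
#'
#' @param state A non-empty `generator_state` (`m >= 2` for KDE so the
#'   bandwidth exists).
#' @param n Number of rows to draw (`n = 0` gives an empty matrix).
#' @param seed Integer seed; sampling is deterministic given it.
#' @return `n x d` numeric matrix.
#' @export
sample_generator <- function(state, n, seed = 0L) {
  abort_if(!inherits(state, "generator_state"), "state must be a generator_state")
  abort_if(!is_count(n) || n < 0, "n must be a non-negative integer")
  if (state$kind == "kde") {
    m <- n_support(state)
    abort_if(m < 1L, "cannot sample from an empty generator")
    abort_if(m < 2L, "KDE sampling needs at least 2 support points")
    d <- ncol(state$support_points)
    if (n == 0L) return(matrix(numeric(0), 0L, d))
    with_seed(derive_seed(seed, "kde-sample"), {
      idx <- sample.int(m, n, replace = TRUE)
      noise <- matrix(stats::rnorm(n * d), n, d)
      state$support_points[idx, , drop = FALSE] +
        sweep(noise, 2L, state$bandwidth, "*")
    })
  } else {
    abort_if(length(state$gmm) < 1L, "cannot sample from an empty generator")
    d <- ncol(state$gmm[[1]]$means)
    if (n == 0L) return(matrix(numeric(0), 0L, d))
    with_seed(derive_seed(seed, "gmm-sample"), {
      task <- sample.int(length(state$gmm), n, replace = TRUE)
      out <- matrix(NA_real_, n, d)
      for (i in seq_len(n)) {
        g <- state$gmm[[task[i]]]
        k <- sample.int(length(g$weights), 1L, prob = g$weights)
        out[i, ] <- g$means[k, ] + stats::rnorm(d) * sqrt(g$variances[k, ])
      }
      out
    })
  }
}

#' Fit the GMM alternative generator
#'
#' Fits one diagonal-covariance Gaussian mixture per seen task (the
#' replay variant that assumes Gaussian-distributed latents, in contrast
#' to the non-parametric KDE). Fitting is delegated to `mclust`; model
#' "VVI" (diagonal, varying volume and shape) is tried first, falling back
#' to "EEI" then "EII" when a fit degenerates.
#'
#' @param latents_per_task List of `n_t x d` matrices, one per seen task.
#' @param n_components Components per task mixture (the comparison setting
#'   uses 10); clamped per task when `n_t` is too small.
#' @param seed Integer seed (mclust initialisation is deterministic; the
#'   seed guards the stochastic EM paths).
#' @return A `generator_state` of kind `"gmm"`; component means are also
#'   exposed as `support_points` for inspection.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_gmm_generator <- function(latents_per_task, n_components = 10L, seed = 0L) {
  abort_if(!is.list(latents_per_task) || length(latents_per_task) < 1L,
           "latents_per_task must be a non-empty list of matrices")
  abort_if(!is_count(n_components) || n_components < 1,
           "n_components must be a positive integer")
  state <- generator_state("gmm")
  fits <- with_seed(derive_seed(seed, "gmm-fit"), lapply(latents_per_task, function(x) {
    x <- as.matrix(x)
    abort_if(n_components > nrow(x),
             "n_components = ", n_components, " exceeds the task's ", nrow(x),
             " rows")
    G <- min(n_components, nrow(unique(x)))
    fit <- NULL
    for (model in c("VVI", "EEI", "EII")) {
      fit <- suppressWarnings(
        Mclust(x, G = G, modelNames = model, verbose = FALSE))
      if (!is.null(fit)) break
    }
    abort_if(is.null(fit), "GMM fit failed for a task")
    means <- t(fit$parameters$mean)                      # G x d
    sig <- fit$parameters$variance$sigma                 # d x d x G
    vars <- t(apply(sig, 3L, diag))
    if (nrow(vars) != nrow(means)) vars <- matrix(vars, nrow(means),
                                                  ncol(means), byrow = TRUE)
    list(weights = fit$parameters$pro, means = means,
         variances = pmax(vars, 1e-12))
  }))
  state$gmm <- fits
  state$support_points <- do.call(rbind, lapply(fits, `[[`, "means"))
  state$per_task_counts <- vapply(fits, function(g) nrow(g$means), integer(1))
  state
}

#' Serialize / load a generator state
#'
#' The support points go to a delimited-text matrix and the remaining
#' fields (per-task counts, bandwidth, kind, GMM parameters) to a YAML
#' sidecar, so the retained state is human-inspectable: one can audit that
#' only cluster centers, never raw training vectors, are persisted.
#'
#' @param state A `generator_state`.
#' @param path Base path; `<path>.tsv` and `<path>.yaml` are written.
#' @return `write_generator` invisibly returns `path`; `read_generator`
#'   returns the state.
#' @export
write_generator <- function(state, path) {
  abort_if(!inherits(state, "generator_state"), "state must be a generator_state")
  sp <- state$support_points
  if (is.null(sp)) sp <- matrix(numeric(0), 0L, 0L)
  utils::write.table(sp, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  side <- list(kind = state$kind,
               per_task_counts = as.list(state$per_task_counts),
               bandwidth = as.list(state$bandwidth))
  if (state$kind == "gmm")
    side$gmm <- lapply(state$gmm, function(g)
      list(weights = as.list(g$weights),
           means = apply(g$means, 1L, as.list, simplify = FALSE),
           variances = apply(g$variances, 1L, as.list, simplify = FALSE)))
  yaml::write_yaml(side, paste0(path, ".yaml"), precision = 15L)
  invisible(path)
}

#' @rdname write_generator
#' @export
read_generator <- function(path) {
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  state <- generator_state(side$kind)
  tsv <- paste0(path, ".tsv")
  if (file.size(tsv) > 0) {
    sp <- as.matrix(utils::read.table(tsv, sep = "\t", header = FALSE))
    dimnames(sp) <- NULL
    state$support_points <- sp
  }
  state$per_task_counts <- as.integer(unlist(side$per_task_counts))
  if (length(side$bandwidth)) state$bandwidth <- as.numeric(unlist(side$bandwidth))
  if (identical(side$kind, "gmm"))
    state$gmm <- lapply(side$gmm, function(g)
      list(weights = as.numeric(unlist(g$weights)),
           means = do.call(rbind, lapply(g$means, as.numeric)),
           variances = do.call(rbind, lapply(g$variances, as.numeric))))
  state
}
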