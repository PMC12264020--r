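#' Continual-learning metrics from the train-test matrix
#'
#' All three metrics consume a `T x T` accuracy matrix `P` on the 0-100
#' scale, where `P[i, j]` is the accuracy on task `j` after completing
#' training session `i` (the paper-style 1-based cell `p_{ij}` maps to the
#' R index `P[i, j]`; this is the only place the index convention lives).
#'
#' * `cl_acc`: average accuracy after the last session, the mean of the
#'   last row, `(1/T) * sum_j P[T, j]`.
#' * `cl_bwt`: backward transfer, the double average
#'   `(1/(T-1)) * sum_{j=1}^{T-1} mean_{i > j} (P[i, j] - P[j, j])`;
#'   negative values quantify forgetting.
#' * `cl_ilm`: incremental-learning metric, the mean over the lower
#'   triangle including the diagonal,
#'   `(2/(T*(T+1))) * sum_{j <= i} P[i, j]`.
#'
#' @param P Numeric `T x T` matrix of accuracies in percent.
#' @return A scalar, in percent (`cl_bwt` is signed).
#' @name cl_metrics_ops
NULL

check_P <- function(P, min_T = 1L) {
  P <- as.matrix(P)
  abort_if(nrow(P) == 0L || ncol(P) == 0L, "P must be non-empty")
  abort_if(nrow(P) != ncol(P), "P must be square, got ",
           nrow(P), " x ", ncol(P))
  abort_if(nrow(P) < min_T, "this metric needs T >= ", min_T,
           " (got T = ", nrow(P), ")")
  abort_if(any(!is.finite(P)), "P must contain finite accuracies")
  P
}

#' @rdname cl_metrics_ops
#' @export
cl_acc <- function(P) {
  P <- check_P(P)
  mean(P[nrow(P), ])
}

#' @rdname cl_metrics_ops
#' @export
cl_bwt <- function(P) {
  P <- check_P(P, min_T = 2L)
  T_ <- nrow(P)
  inner <- vapply(seq_len(T_ - 1L), function(j)
    mean(P[(j + 1L):T_, j] - P[j, j]), numeric(1))
  mean(inner)
}

#' @rdname cl_metrics_ops
#' @export
cl_ilm <- function(P) {
  P <- check_P(P)
  mean(P[lower.tri(P, diag = TRUE)])
}

#' All three CL metrics at once
#'
#' @param P Numeric `T x T` accuracy matrix in percent.
#' @return A list with `acc`, `bwt` (`NA` when `T = 1`), `ilm` and `T`.
#' @export
cl_metrics <- function(P) {
  P <- check_P(P)
  list(acc = cl_acc(P),
       bwt = if (nrow(P) >= 2L) cl_bwt(P) else NA_real_,
       ilm = cl_ilm(P), T = nrow(P))
}

#' Aggregate metrics across repetitions
#'
#' Arithmetic mean and sample (n-1) standard deviation per metric; the
#' standard deviation of a single value is 0.
#'
#' @param metrics_list Non-empty list of [cl_metrics()] results.
#' @return A data frame with one row per metric (`acc`, `bwt`, `ilm`) and
#'   columns `mean`, `sd`, `n`.
#' @export
aggregate_metrics <- function(metrics_list) {
  abort_if(!is.list(metrics_list) || length(metrics_list) < 1L,
           "metrics_list must be non-empty")
  one <- function(name) {
    x <- vapply(metrics_list, function(m) as.numeric(m[[name]]), numeric(1))
    x <- x[!is.na(x)]
    data.frame(metric = name,
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1L) stats::sd(x)
                    else if (length(x) == 1L) 0 else NA_real_,
               n = length(x))
  }
  do.call(rbind, lapply(c("acc", "bwt", "ilm"), one))
}

#' Write / read a train-test matrix as TSV
#'
#' Plain tab-separated numbers, one row of `P` per line, no header.
#'
#' @param P Numeric matrix.
#' @param path File path.
#' @export
write_matrix_tsv <- function(P, path) {
  utils::write.table(P, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  abort_if(!file.exists(path), "no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(lines, "[\t,]")
  lens <- lengths(rows)
  abort_if(length(unique(lens)) != 1L,
           "ragged matrix in ", path, ": row lengths ",
           paste(unique(lens), collapse = ", "))
  vals <- suppressWarnings(vapply(rows, as.numeric, numeric(lens[1])))
  abort_if(any(!is.finite(vals)), "non-numeric cell in ", path)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(rows))
  else vals <- t(vals)
  vals
}
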