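#' Specify one synthetic latent domain
#'
#' A domain is a class-conditional Gaussian model in latent space: class `c`
#' is an isotropic Gaussian centered at `class_means[c, ] + shift_vector`,
#' with standard deviation `class_scales[c]`, rotated by `rotation_angle`
#' radians in the first two latent coordinates. Domains sharing the same
#' class set but different shift/scale/rotation emulate the heterogeneous
#' distribution shifts seen between staining protocols, scanners and sample
#' sources in single-cell image collections.
#'
#' @param domain_id Short identifier string.
#' @param n_train_per_class,n_test_per_class Positive integers; rows drawn
#'   per class for the train and test split.
#' @param class_means Numeric `C x d` matrix of class centers (C >= 2,
#'   d >= 2).
#' @param class_scales Length-`C` vector of strictly positive isotropic
#'   standard deviations.
#' @param shift_vector Length-`d` translation applied to every class mean
#'   (the domain shift); defaults to zero.
#' @param rotation_angle Rotation in radians applied in latent coordinates
#'   1 and 2 after the shift; defaults to 0.
#' @param seed Non-negative integer; all randomness of this domain flows
#'   from it through named sub-streams, so train and test draws are
#'   independent.
#' @return An object of class `domain_spec`.
#' @seealso [make_domain()], [make_sequence()]
#' @export
domain_spec <- function(domain_id, n_train_per_class, n_test_per_class,
                        class_means, class_scales,
                        shift_vector = NULL, rotation_angle = 0, seed = 0L) {
  abort_if(!is.character(domain_id) || length(domain_id) != 1L || !nzchar(domain_id),
           "domain_id must be a non-empty string")
  abort_if(!is_count(n_train_per_class) || n_train_per_class < 1,
           "n_train_per_class must be a positive integer")
  abort_if(!is_count(n_test_per_class) || n_test_per_class < 1,
           "n_test_per_class must be a positive integer")
  class_means <- as.matrix(class_means)
  C <- nrow(class_means); d <- ncol(class_means)
  abort_if(C < 2, "at least 2 classes are required")
  abort_if(d < 2, "latent dimension must be >= 2")
  abort_if(length(class_scales) != C || any(!is.finite(class_scales)) ||
             any(class_scales <= 0),
           "class_scales must be ", C, " strictly positive finite values")
  if (is.null(shift_vector)) shift_vector <- numeric(d)
  abort_if(length(shift_vector) != d || any(!is.finite(shift_vector)),
           "shift_vector must be a finite vector of length ", d)
  abort_if(!is.numeric(rotation_angle) || length(rotation_angle) != 1L ||
             !is.finite(rotation_angle), "rotation_angle must be a finite scalar")
  abort_if(!is_count(seed) || seed < 0, "seed must be a non-negative integer")
  structure(list(domain_id = domain_id,
                 n_train_per_class = as.integer(n_train_per_class),
                 n_test_per_class = as.integer(n_test_per_class),
                 class_means = class_means,
                 class_scales = as.numeric(class_scales),
                 shift_vector = as.numeric(shift_vector),
                 rotation_angle = as.numeric(rotation_angle),
                 seed = as.integer(seed)),
            class = "domain_spec")
}

#' Construct a labeled latent dataset
#'
#' Container for one split of one domain: an `n x d` matrix of latent
#' feature vectors and integer class labels in `0..C-1`.
#'
#' @param features Numeric `n x d` matrix of finite values.
#' @param labels Integer vector of length `n`, class indices starting at 0.
#' @param domain_id Domain identifier string.
#' @param split `"train"` or `"test"`.
#' @param n_classes Number of classes `C`; defaults to `max(labels) + 1`.
#' @return An object of class `latent_dataset`.
#' @export
latent_dataset <- function(features, labels, domain_id = "domain",
                           split = c("train", "test"), n_classes = NULL) {
  split <- match.arg(split)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  abort_if(nrow(features) != length(labels),
           "features has ", nrow(features), " rows but there are ",
           length(labels), " labels")
  abort_if(any(!is.finite(features)), "features must be finite")
  abort_if(length(labels) > 0 && any(labels < 0L), "labels must be >= 0")
  if (is.null(n_classes)) n_classes <- if (length(labels)) max(labels) + 1L else 0L
  abort_if(length(labels) > 0 && any(labels >= n_classes),
           "label index out of range: all labels must be < ", n_classes)
  structure(list(domain_id = domain_id, split = split,
                 features = features, labels = labels,
                 n_classes = as.integer(n_classes)),
            class = "latent_dataset")
}

#' @export
print.latent_dataset <- function(x, ...) {
  cat(sprintf("<latent_dataset> domain=%s split=%s n=%d d=%d C=%d\n",
              x$domain_id, x$split, nrow(x$features), ncol(x$features),
              x$n_classes))
  invisible(x)
}

#' @export
print.domain_spec <- function(x, ...) {
  cat(sprintf(
    "<domain_spec> %s: C=%d d=%d train=%d/class test=%d/class |shift|=%.3g rot=%.3g seed=%d\n",
    x$domain_id, nrow(x$class_means), ncol(x$class_means),
    x$n_train_per_class, x$n_test_per_class,
    sqrt(sum(x$shift_vector^2)), x$rotation_angle, x$seed))
  invisible(x)
}

# Rotation by `angle` in latent coordinates 1 and 2, identity elsewhere.
rotate12 <- function(x, angle) {
  if (angle == 0) return(x)
  co <- cos(angle); si <- sin(angle)
  x1 <- x[, 1L] * co - x[, 2L] * si
  x2 <- x[, 1L] * si + x[, 2L] * co
  x[, 1L] <- x1; x[, 2L] <- x2
  x
}

draw_split <- function(spec, n_per_class, split) {
  C <- nrow(spec$class_means); d <- ncol(spec$class_means)
  n <- n_per_class * C
  feats <- with_seed(derive_seed(spec$seed, paste0(spec$domain_id, "/", split)), {
    z <- matrix(stats::rnorm(n * d), nrow = n, ncol = d)
    for (c in seq_len(C)) {
      rows <- ((c - 1L) * n_per_class + 1L):(c * n_per_class)
      center <- spec$class_means[c, ] + spec$shift_vector
      z[rows, ] <- sweep(z[rows, , drop = FALSE] * spec$class_scales[c],
                         2L, center, "+")
    }
    rotate12(z, spec$rotation_angle)
  })
  colnames(feats) <- paste0("f", seq_len(d) - 1L)
  latent_dataset(feats, rep(seq_len(C) - 1L, each = n_per_class),
                 domain_id = spec$domain_id, split = split, n_classes = C)
}

#' Generate train and test splits for one domain
#'
#' Draws exactly `n_train_per_class` and `n_test_per_class` rows per class
#' from the class-conditional Gaussian model described by the spec. Fully
#' reproducible: the same spec (including seed) yields bitwise-identical
#' matrices; train and test use independent random streams.
#'
#' @param spec A [domain_spec()].
#' @return A list with elements `train` and `test`, each a
#'   [latent_dataset()].
#' @examples
#' sp <- domain_spec("d1", 20, 10, class_means = rbind(c(0, 0), c(3, 3)),
#'                   class_scales = c(1, 1), seed = 1)
#' dom <- make_domain(sp)
#' nrow(dom$test$features)  # 20 = 2 classes x 10
#' @export
make_domain <- function(spec) {
  abort_if(!inherits(spec, "domain_spec"), "spec must be a domain_spec")
  list(train = draw_split(spec, spec$n_train_per_class, "train"),
       test = draw_split(spec, spec$n_test_per_class, "test"))
}

#' Generate an ordered domain-incremental task sequence
#'
#' Element `t` of the result corresponds to task `t` (1-based in reports).
#' All specs must share the same class count and latent dimension: the
#' domain-incremental contract is that the label set is fixed while the
#' input distribution shifts.
#'
#' @param specs List of [domain_spec()] objects, in task order.
#' @return A named list of `list(train =, test =)` pairs, names taken from
#'   the domain ids.
#' @export
make_sequence <- function(specs) {
  abort_if(!is.list(specs) || length(specs) < 1L, "at least one spec is required")
  abort_if(!all(vapply(specs, inherits, logical(1), "domain_spec")),
           "all elements must be domain_spec objects")
  Cs <- vapply(specs, function(s) nrow(s$class_means), integer(1))
  ds <- vapply(specs, function(s) ncol(s$class_means), integer(1))
  abort_if(length(unique(Cs)) != 1L,
           "all domains must share one class set (got C = ",
           paste(unique(Cs), collapse = ", "), ")")
  abort_if(length(unique(ds)) != 1L,
           "all domains must share one latent dimension (got d = ",
           paste(unique(ds), collapse = ", "), ")")
  out <- lapply(specs, make_domain)
  names(out) <- vapply(specs, `[[`, character(1), "domain_id")
  out
}

#' Write / read a latent dataset as delimited text
#'
#' The on-disk format is a delimited table with a header row naming the
#' feature columns `f0..f{d-1}` plus a final `label` column. TSV is the
#' default; `.csv` paths are written/read comma-separated. Round-trips are
#' exact at the written precision (17 significant digits).
#'
#' @param ds A [latent_dataset()].
#' @param path File path; extension `.csv` selects comma separation.
#' @return `write_dataset` invisibly returns `path`; `read_dataset` returns
#'   a [latent_dataset()].
#' @export
write_dataset <- function(ds, path) {
  abort_if(!inherits(ds, "latent_dataset"), "ds must be a latent_dataset")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- ncol(ds$features)
  df <- as.data.frame(ds$features)
  names(df) <- paste0("f", seq_len(d) - 1L)
  df$label <- ds$labels
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = sep), con)
  body <- do.call(paste, c(lapply(df[seq_len(d)], formatC,
                                  digits = 17, format = "g"),
                           list(df$label), sep = sep))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_dataset
#' @param domain_id,split Metadata attached to the dataset read from `path`
#'   (the file itself stores only features and labels).
#' @param n_classes Optional class count; defaults to `max(label) + 1`.
#' @export
read_dataset <- function(path, domain_id = NULL, split = "train",
                         n_classes = NULL) {
  abort_if(!file.exists(path), "no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  abort_if(length(header) < 2L || header[length(header)] != "label",
           "malformed header in ", path,
           ": expected feature columns followed by a final 'label' column")
  d <- length(header) - 1L
  abort_if(!identical(header[seq_len(d)], paste0("f", seq_len(d) - 1L)),
           "malformed header in ", path, ": feature columns must be f0..f",
           d - 1L)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE)
  feats <- matrix(NA_real_, nrow(tab), d,
                  dimnames = list(NULL, header[seq_len(d)]))
  for (j in seq_len(d)) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    bad <- which(!is.finite(v))
    abort_if(length(bad) > 0, "non-numeric feature cell in ", path,
             " at row ", bad[1], ", column ", header[j])
    feats[, j] <- v
  }
  lab <- suppressWarnings(as.integer(tab[["label"]]))
  bad <- which(is.na(lab) | lab < 0L)
  abort_if(length(bad) > 0, "unknown label in ", path, " at row ", bad[1],
           ", column label")
  if (is.null(domain_id))
    domain_id <- sub("\\.(tsv|csv)$", "", basename(path), ignore.case = TRUE)
  latent_dataset(feats, lab, domain_id = domain_id, split = split,
                 n_classes = n_classes)
}

#' Write / read a task sequence directory
#'
#' Layout: one subdirectory per domain holding `train.tsv` and `test.tsv`,
#' plus a `sequence.yaml` manifest listing the domain order.
#'
#' @param sequence A list of `list(train =, test =)` pairs as produced by
#'   [make_sequence()].
#' @param dir Target directory (created if missing).
#' @return `write_sequence` invisibly returns `dir`; `read_sequence`
#'   returns the sequence list in manifest order.
#' @export
write_sequence <- function(sequence, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(sequence, function(p) p$train$domain_id, character(1))
  for (p in sequence) {
    sub <- file.path(dir, p$train$domain_id)
    dir.create(sub, showWarnings = FALSE)
    write_dataset(p$train, file.path(sub, "train.tsv"))
    write_dataset(p$test, file.path(sub, "test.tsv"))
  }
  yaml::write_yaml(list(domains = as.list(ids)), file.path(dir, "sequence.yaml"))
  invisible(dir)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(dir) {
  manifest <- file.path(dir, "sequence.yaml")
  abort_if(!file.exists(manifest), "no sequence.yaml manifest in ", dir)
  ids <- unlist(yaml::read_yaml(manifest)$domains)
  abort_if(length(ids) < 1L, "sequence.yaml lists no domains")
  out <- lapply(ids, function(id) {
    tr <- read_dataset(file.path(dir, id, "train.tsv"), domain_id = id,
                       split = "train")
    te <- read_dataset(file.path(dir, id, "test.tsv"), domain_id = id,
                       split = "test")
    C <- max(tr$n_classes, te$n_classes)
    tr$n_classes <- C; te$n_classes <- C
    list(train = tr, test = te)
  })
  names(out) <- ids
  out
}

#' Default synthetic 4-domain benchmark
#'
#' Defines the study conditions every strategy is evaluated under: T = 4
#' domains over a fixed 3-class label set in a d = 16 latent space, with
#' strong heterogeneous shifts between domains (translations of magnitude
#' ~8 in changing directions, rotations up to ~0.9 rad in the first two
#' coordinates, mild scale changes). Test splits hold 50 rows per class;
#' train splits 100 per class.
#'
#' @param seed Base seed; each domain derives its own stream from it.
#' @param n_train_per_class,n_test_per_class Per-class split sizes.
#' @param d Latent dimension.
#' @return A list of 4 [domain_spec()] objects.
#' @export
default_benchmark_specs <- function(seed = 20260101, n_train_per_class = 100,
                                    n_test_per_class = 50, d = 16) {
  abort_if(d < 6, "the default benchmark needs d >= 6")
  base <- matrix(0, 3, d)
  base[1, 1] <- 0
  base[2, 1] <- 4; base[2, 3] <- 2
  base[3, 2] <- 4; base[3, 4] <- -2
  unit <- function(ix, s) { v <- numeric(d); v[ix] <- s; v }
  shifts <- list(numeric(d),
                 unit(c(3, 5), c(8, -4)),
                 unit(c(1, 6), c(-8, 6)),
                 unit(c(2, 5, 6), c(7, 6, -5)))
  angles <- c(0, 0.3, 0.6, 0.9)
  scales <- list(c(1, 1, 1), c(1.2, 1, 0.9), c(1, 1.3, 1), c(0.9, 1, 1.2))
  lapply(1:4, function(t) {
    domain_spec(paste0("D", t), n_train_per_class, n_test_per_class,
                class_means = base, class_scales = scales[[t]],
                shift_vector = shifts[[t]], rotation_angle = angles[t],
                seed = derive_seed(seed, paste0("domain", t)))
  })
}
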