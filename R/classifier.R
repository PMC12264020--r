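#' Specify the fully-connected classifier head
#'
#' The trainable head appended to a frozen feature extractor: a stack of
#' fully-connected layers (default widths 512, 256, 128, 64, 32) with ReLU
#' activations, followed by a linear layer to `n_classes` logits.
#'
#' @param input_dim Latent dimension `d` of the incoming features.
#' @param n_classes Number of classes `C` (>= 2).
#' @param hidden_widths Ordered positive integers, one per hidden layer.
#' @param activation Hidden activation; only `"relu"` is implemented.
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `head_spec`.
#' @export
head_spec <- function(input_dim, n_classes,
                      hidden_widths = c(512L, 256L, 128L, 64L, 32L),
                      activation = "relu", seed = 0L) {
  abort_if(!is_count(input_dim) || input_dim < 1, "input_dim must be positive")
  abort_if(!is_count(n_classes) || n_classes < 2,
           "n_classes must be an integer >= 2")
  abort_if(length(hidden_widths) < 1L || any(hidden_widths < 1) ||
             any(hidden_widths != as.integer(hidden_widths)),
           "hidden_widths must be positive integers")
  abort_if(!identical(activation, "relu"), "only 'relu' is supported")
  structure(list(input_dim = as.integer(input_dim),
                 n_classes = as.integer(n_classes),
                 hidden_widths = as.integer(hidden_widths),
                 activation = activation, seed = as.integer(seed)),
            class = "head_spec")
}

#' Initialise a classifier head
#'
#' He-normal weight initialisation (`sd = sqrt(2 / fan_in)`), zero biases;
#' deterministic given the spec's seed.
#'
#' @param spec A [head_spec()].
#' @return An object of class `latent_mlp` with fields `spec`, `W` (list of
#'   weight matrices) and `b` (list of bias vectors).
#' @export
init_head <- function(spec) {
  abort_if(!inherits(spec, "head_spec"), "spec must be a head_spec")
  widths <- c(spec$input_dim, spec$hidden_widths, spec$n_classes)
  L <- length(widths) - 1L
  with_seed(derive_seed(spec$seed, "init"), {
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      fan_in <- widths[l]
      W[[l]] <- matrix(stats::rnorm(fan_in * widths[l + 1L],
                                    sd = sqrt(2 / fan_in)),
                       fan_in, widths[l + 1L])
      b[[l]] <- numeric(widths[l + 1L])
    }
    structure(list(spec = spec, W = W, b = b), class = "latent_mlp")
  })
}

#' @export
print.latent_mlp <- function(x, ...) {
  widths <- c(x$spec$input_dim, x$spec$hidden_widths, x$spec$n_classes)
  cat("<latent_mlp> ", paste(widths, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

# Forward pass; keeps per-layer activations when `keep = TRUE` for backprop.
mlp_forward <- function(model, x, keep = FALSE) {
  L <- length(model$W)
  acts <- if (keep) vector("list", L) else NULL
  a <- x
  for (l in seq_len(L)) {
    if (keep) acts[[l]] <- a
    a <- sweep(a %*% model$W[[l]], 2L, model$b[[l]], "+")
    if (l < L) a <- pmax(a, 0)  # ReLU on hidden layers, final layer linear
  }
  if (keep) list(logits = a, acts = acts) else a
}

#' Compute logits for a batch of latents
#'
#' @param model A `latent_mlp`.
#' @param x Numeric `n x d` matrix.
#' @return `n x C` matrix of finite logits.
#' @export
predict_logits <- function(model, x) {
  abort_if(!inherits(model, "latent_mlp"), "model must be a latent_mlp")
  x <- as.matrix(x)
  abort_if(ncol(x) != model$spec$input_dim,
           "latents have d = ", ncol(x), " but the model expects ",
           model$spec$input_dim)
  mlp_forward(model, x)
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

log_softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  z - log(rowSums(exp(z)))
}

#' Loss configuration for teacher-student training
#'
#' @param alpha Balancing factor in `[0, 1]`: the training loss is
#'   `(1 - alpha) * CE + alpha * KLD`, where CE is cross-entropy against
#'   the batch labels and KLD the Kullback-Leibler divergence from the
#'   frozen teacher's output distribution to the student's.
#' @param kd_temperature Softmax temperature for the distillation term.
#' @param kld_scope `"all"` applies the KLD term to every row of a hybrid
#'   batch; `"current_only"` restricts it (and CE) to current-task rows,
#'   which is the distillation-only ablation's reading.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0, kd_temperature = 1,
                        kld_scope = c("all", "current_only")) {
  abort_if(!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
             alpha < 0 || alpha > 1, "alpha must lie in [0, 1]")
  abort_if(!is.numeric(kd_temperature) || kd_temperature <= 0,
           "kd_temperature must be positive")
  structure(list(alpha = as.numeric(alpha),
                 kd_temperature = as.numeric(kd_temperature),
                 kld_scope = match.arg(kld_scope)),
            class = "loss_config")
}

#' Combined cross-entropy / distillation loss
#'
#' Implements `loss = (1 - alpha) * loss_CE + alpha * loss_KLD` with
#' `loss_CE` the batch-mean cross-entropy of the student logits against the
#' ground-truth (or pseudo-) labels, and `loss_KLD` the batch-mean
#' `KL(softmax(teacher / T) || softmax(student / T))`. With `alpha = 0`
#' the result is exactly the cross-entropy term; identical teacher and
#' student logits zero the KLD term.
#'
#' @param student_logits,teacher_logits `n x C` matrices
#'   (`teacher_logits` may be `NULL` when `alpha = 0`).
#' @param labels Length-`n` integer class indices in `0..C-1`.
#' @param cfg A [loss_config()].
#' @return Scalar loss with attributes `"ce"` and `"kld"` holding the two
#'   components.
#' @export
combined_loss <- function(student_logits, teacher_logits = NULL, labels, cfg) {
  abort_if(!inherits(cfg, "loss_config"), "cfg must be a loss_config")
  student_logits <- as.matrix(student_logits)
  n <- nrow(student_logits); C <- ncol(student_logits)
  labels <- as.integer(labels)
  abort_if(length(labels) != n, "labels length must match the batch")
  abort_if(any(labels < 0L | labels >= C), "labels must lie in 0..C-1")
  abort_if(cfg$alpha > 0 && is.null(teacher_logits),
           "alpha > 0 requires teacher logits")
  ls <- log_softmax_rows(student_logits)
  ce <- -mean(ls[cbind(seq_len(n), labels + 1L)])
  kld <- 0
  if (!is.null(teacher_logits)) {
    teacher_logits <- as.matrix(teacher_logits)
    abort_if(!identical(dim(teacher_logits), dim(student_logits)),
             "teacher and student logit shapes must agree")
    Tt <- cfg$kd_temperature
    pt <- softmax_rows(teacher_logits / Tt)
    lst <- log_softmax_rows(teacher_logits / Tt)
    lss <- log_softmax_rows(student_logits / Tt)
    kld <- mean(rowSums(pt * (lst - lss)))
    kld <- max(kld, 0)  # clip tiny negative rounding
  }
  structure((1 - cfg$alpha) * ce + cfg$alpha * kld, ce = ce, kld = kld)
}

#' Teacher pseudo-labels for unlabeled latents
#'
#' The frozen previous-session model assigns a hard label to each synthetic
#' latent by the argmax of its logits; ties break toward the lowest class
#' index. Pseudo-labels are invariant to adding a constant to all logits.
#'
#' @param teacher A `latent_mlp`.
#' @param latents `n x d` matrix.
#' @return Integer vector of class indices in `0..C-1`.
#' @export
pseudo_label <- function(teacher, latents) {
  logits <- predict_logits(teacher, latents)
  max.col(logits, ties.method = "first") - 1L
}

#' Build one epoch of hybrid replay mini-batches
#'
#' Every batch is an equal split: half current-task rows carrying their
#' ground-truth labels, half synthetic rows drawn fresh from the generator
#' and labeled by the teacher. Current-task rows are an epoch-wise shuffle
#' without replacement; when the current data does not divide evenly, the
#' final batch shrinks symmetrically to `r` current + `r` replay rows so
#' the 50/50 composition holds in every batch.
#'
#' @param current A [latent_dataset()] (train split of the current task).
#' @param gen A non-empty `generator_state` representing all past tasks.
#' @param teacher The frozen previous-session `latent_mlp`.
#' @param batch_size Even positive integer (the study setting is 64, i.e.
#'   32 current + 32 replay rows).
#' @param seed Integer seed controlling the shuffle and the replay draws.
#' @return List of batches, each `list(features, labels, is_replay)` with
#'   `sum(is_replay) == nrow(features) / 2`.
#' @export
make_hybrid_batches <- function(current, gen, teacher, batch_size = 64L,
                                seed = 0L) {
  abort_if(!inherits(current, "latent_dataset"), "current must be a latent_dataset")
  abort_if(!is_count(batch_size) || batch_size < 2 || batch_size %% 2 != 0,
           "batch_size must be a positive even integer")
  abort_if(!inherits(gen, "generator_state") || n_support(gen) == 0L,
           "a non-empty generator is required for hybrid batches")
  abort_if(!inherits(teacher, "latent_mlp"), "a teacher model is required")
  n <- nrow(current$features)
  half <- batch_size %/% 2L
  perm <- with_seed(derive_seed(seed, "shuffle"), sample.int(n))
  starts <- seq(1L, n, by = half)
  lapply(seq_along(starts), function(bi) {
    idx <- perm[starts[bi]:min(starts[bi] + half - 1L, n)]
    r <- length(idx)
    cur_x <- current$features[idx, , drop = FALSE]
    rep_x <- sample_generator(gen, r, seed = derive_seed(seed, paste0("replay", bi)))
    list(features = rbind(cur_x, rep_x),
         labels = c(current$labels[idx], pseudo_label(teacher, rep_x)),
         is_replay = rep(c(FALSE, TRUE), each = r))
  })
}

# One epoch of plain (no replay) mini-batches over the current task.
make_plain_batches <- function(current, batch_size, seed) {
  n <- nrow(current$features)
  perm <- with_seed(derive_seed(seed, "shuffle"), sample.int(n))
  starts <- seq(1L, n, by = batch_size)
  lapply(starts, function(s) {
    idx <- perm[s:min(s + batch_size - 1L, n)]
    list(features = current$features[idx, , drop = FALSE],
         labels = current$labels[idx],
         is_replay = rep(FALSE, length(idx)))
  })
}

#' Optimiser configuration
#'
#' @param learning_rate Adam step size.
#' @param epochs Training epochs per session.
#' @param batch_size Mini-batch size (even when replay is active).
#' @param beta1,beta2,eps Adam moment decay rates and stabiliser.
#' @return An object of class `opt_config`.
#' @export
opt_config <- function(learning_rate = 1e-3, epochs = 20L, batch_size = 64L,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  abort_if(learning_rate <= 0, "learning_rate must be positive")
  abort_if(!is_count(epochs) || epochs < 0, "epochs must be a non-negative integer")
  abort_if(!is_count(batch_size) || batch_size < 1, "batch_size must be positive")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), beta1 = beta1,
                 beta2 = beta2, eps = eps), class = "opt_config")
}

# Gradient of the combined loss with respect to the student logits.
# CE (batch mean): (softmax(s) - onehot) / n on rows in CE scope.
# KLD at temperature T: (softmax(s/T) - softmax(t/T)) / (n_scope * T) on
# rows in KLD scope (batch-mean KL of teacher || student).
loss_logit_grad <- function(student_logits, teacher_logits, labels, cfg,
                            ce_rows, kld_rows) {
  n <- nrow(student_logits); C <- ncol(student_logits)
  grad <- matrix(0, n, C)
  if (cfg$alpha < 1 && length(ce_rows)) {
    ps <- softmax_rows(student_logits[ce_rows, , drop = FALSE])
    onehot <- matrix(0, length(ce_rows), C)
    onehot[cbind(seq_along(ce_rows), labels[ce_rows] + 1L)] <- 1
    grad[ce_rows, ] <- grad[ce_rows, ] +
      (1 - cfg$alpha) * (ps - onehot) / length(ce_rows)
  }
  if (cfg$alpha > 0 && length(kld_rows)) {
    Tt <- cfg$kd_temperature
    ps <- softmax_rows(student_logits[kld_rows, , drop = FALSE] / Tt)
    pt <- softmax_rows(teacher_logits[kld_rows, , drop = FALSE] / Tt)
    grad[kld_rows, ] <- grad[kld_rows, ] +
      cfg$alpha * (ps - pt) / (length(kld_rows) * Tt)
  }
  grad
}

# Backpropagate a logit-space gradient through the MLP; returns per-layer
# weight/bias gradients.
mlp_backward <- function(model, fwd, grad_logits) {
  L <- length(model$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- grad_logits
  for (l in rev(seq_len(L))) {
    a <- fwd$acts[[l]]
    gW[[l]] <- crossprod(a, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(model$W[[l]])
      pre <- sweep(fwd$acts[[l - 1L]] %*% model$W[[l - 1L]], 2L,
                   model$b[[l - 1L]], "+")
      delta <- delta * (pre > 0)
    }
  }
  list(W = gW, b = gb)
}

adam_state_init <- function(model) {
  list(mW = lapply(model$W, function(w) w * 0),
       vW = lapply(model$W, function(w) w * 0),
       mb = lapply(model$b, function(b) b * 0),
       vb = lapply(model$b, function(b) b * 0),
       t = 0L)
}

adam_step <- function(model, grads, st, opt) {
  st$t <- st$t + 1L
  lr_t <- opt$learning_rate * sqrt(1 - opt$beta2^st$t) / (1 - opt$beta1^st$t)
  for (l in seq_along(model$W)) {
    st$mW[[l]] <- opt$beta1 * st$mW[[l]] + (1 - opt$beta1) * grads$W[[l]]
    st$vW[[l]] <- opt$beta2 * st$vW[[l]] + (1 - opt$beta2) * grads$W[[l]]^2
    model$W[[l]] <- model$W[[l]] -
      lr_t * st$mW[[l]] / (sqrt(st$vW[[l]]) + opt$eps)
    st$mb[[l]] <- opt$beta1 * st$mb[[l]] + (1 - opt$beta1) * grads$b[[l]]
    st$vb[[l]] <- opt$beta2 * st$vb[[l]] + (1 - opt$beta2) * grads$b[[l]]^2
    model$b[[l]] <- model$b[[l]] -
      lr_t * st$mb[[l]] / (sqrt(st$vb[[l]]) + opt$eps)
  }
  list(model = model, state = st)
}

#' Run one training session
#'
#' Trains the student head for `opt$epochs` epochs of mini-batch Adam steps
#' minimising the combined loss. With a teacher and generator present the
#' batches are hybrid 50/50 replay batches; on the first task (no teacher,
#' no generator) training is plain cross-entropy on the current data. The
#' teacher's parameters are never touched.
#'
#' @param student A `latent_mlp` (modified copy returned; R value semantics
#'   leave the input untouched).
#' @param teacher A frozen `latent_mlp`, or `NULL` on the first task.
#' @param current Train-split [latent_dataset()] of the current task.
#' @param gen A `generator_state` for all past tasks, or `NULL`.
#' @param cfg A [loss_config()].
#' @param opt An [opt_config()].
#' @param seed Session seed; shuffles and replay draws derive from it.
#' @return The trained `latent_mlp`, with the per-step loss trace attached
#'   as attribute `"loss_trace"` (data frame: epoch, step, loss_ce,
#'   loss_kld, loss_total).
#' @export
train_session <- function(student, teacher = NULL, current, gen = NULL,
                          cfg = loss_config(), opt = opt_config(), seed = 0L) {
  abort_if(!inherits(student, "latent_mlp"), "student must be a latent_mlp")
  abort_if(!inherits(current, "latent_dataset"), "current must be a latent_dataset")
  if (is.null(teacher)) {
    abort_if(!is.null(gen), "replay without a teacher is not defined")
    cfg <- loss_config(alpha = 0, kd_temperature = cfg$kd_temperature,
                       kld_scope = cfg$kld_scope)
  }
  use_replay <- !is.null(gen)
  st <- adam_state_init(student)
  trace <- vector("list", 0L)
  for (epoch in seq_len(opt$epochs)) {
    ep_seed <- derive_seed(seed, paste0("epoch", epoch))
    batches <- if (use_replay)
      make_hybrid_batches(current, gen, teacher, opt$batch_size, ep_seed)
    else
      make_plain_batches(current, opt$batch_size, ep_seed)
    for (bi in seq_along(batches)) {
      batch <- batches[[bi]]
      fwd <- mlp_forward(student, batch$features, keep = TRUE)
      tl <- if (!is.null(teacher)) predict_logits(teacher, batch$features)
      n_rows <- nrow(batch$features)
      ce_rows <- if (cfg$kld_scope == "current_only")
        which(!batch$is_replay) else seq_len(n_rows)
      kld_rows <- if (cfg$kld_scope == "current_only")
        which(!batch$is_replay) else seq_len(n_rows)
      loss <- combined_loss(fwd$logits[ce_rows, , drop = FALSE],
                            if (!is.null(tl) && cfg$alpha > 0)
                              tl[ce_rows, , drop = FALSE],
                            batch$labels[ce_rows], cfg)
      abort_if(!is.finite(loss), "non-finite loss at epoch ", epoch,
               ", step ", bi, "; lower the learning rate")
      grad <- loss_logit_grad(fwd$logits, tl, batch$labels, cfg,
                              ce_rows, kld_rows)
      upd <- adam_step(student, mlp_backward(student, fwd, grad), st, opt)
      student <- upd$model; st <- upd$state
      trace[[length(trace) + 1L]] <-
        data.frame(epoch = epoch, step = bi,
                   loss_ce = attr(loss, "ce"), loss_kld = attr(loss, "kld"),
                   loss_total = as.numeric(loss))
    }
  }
  attr(student, "loss_trace") <- if (length(trace))
    do.call(rbind, trace) else
    data.frame(epoch = integer(0), step = integer(0), loss_ce = numeric(0),
               loss_kld = numeric(0), loss_total = numeric(0))
  student
}
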