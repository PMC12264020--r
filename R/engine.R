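#' Test-set accuracy (percent)
#'
#' 100 times the fraction of rows whose argmax logit matches the label;
#' argmax ties break toward the lowest class index.
#'
#' @param model A `latent_mlp`.
#' @param test A non-empty [latent_dataset()].
#' @return Accuracy on the 0-100 scale.
#' @export
evaluate_accuracy <- function(model, test) {
  abort_if(!inherits(test, "latent_dataset"), "test must be a latent_dataset")
  abort_if(nrow(test$features) == 0L, "cannot evaluate on an empty test set")
  pred <- pseudo_label(model, test$features)
  100 * mean(pred == test$labels)
}

strategy_names <- c("naive", "joint", "proposed", "dst_only", "glr_only",
                    "gmm_replay")

#' Run configuration for a continual-learning experiment
#'
#' Collects every tunable of a run: the strategy, the distillation weight
#' `alpha` (the study's grid is {0.01, 0.1, 0.2, 0.3, 0.4, 0.5}), the
#' per-task cluster count `K` (or `"auto"` for BIC selection over
#' `k_candidates`), batch size, optimiser settings, the repeat count and
#' the base seed.
#'
#' @param strategy One of `"naive"`, `"joint"`, `"proposed"`,
#'   `"dst_only"`, `"glr_only"`, `"gmm_replay"`.
#' @param alpha Distillation weight in `[0, 1]` (ignored by strategies
#'   that carry no distillation term).
#' @param K Cluster centers retained per task, or `"auto"`.
#' @param k_candidates Candidate cluster counts when `K = "auto"`.
#' @param batch_size,epochs,learning_rate Optimiser settings.
#' @param n_repeats Independent repetitions (the study reports mean and
#'   standard deviation over 5).
#' @param base_seed Seed of repeat 0; repeat `r` uses `base_seed + r`.
#' @param hidden_widths Head widths, outermost first.
#' @param gmm_components Components per task for the GMM generator.
#' @return An object of class `run_config`.
#' @export
run_config <- function(strategy = "proposed", alpha = 0.2, K = 10L,
                       k_candidates = 1:15, batch_size = 64L, epochs = 20L,
                       learning_rate = 1e-3, n_repeats = 5L,
                       base_seed = 0L,
                       hidden_widths = c(512L, 256L, 128L, 64L, 32L),
                       gmm_components = 10L) {
  abort_if(!strategy %in% strategy_names,
           "unknown strategy '", strategy, "'; expected one of ",
           paste(strategy_names, collapse = ", "))
  abort_if(!identical(K, "auto") && (!is_count(K) || K < 1),
           "K must be a positive integer or \"auto\"")
  abort_if(!is_count(n_repeats) || n_repeats < 1, "n_repeats must be >= 1")
  structure(list(strategy = strategy, alpha = alpha, K = K,
                 k_candidates = as.integer(k_candidates),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 n_repeats = as.integer(n_repeats),
                 base_seed = as.integer(base_seed),
                 hidden_widths = as.integer(hidden_widths),
                 gmm_components = as.integer(gmm_components)),
            class = "run_config")
}

strategy_traits <- function(strategy) {
  switch(strategy,
    naive = list(replay = FALSE, distill = FALSE, scope = "all"),
    joint = list(replay = FALSE, distill = FALSE, scope = "all"),
    proposed = list(replay = TRUE, distill = TRUE, scope = "all"),
    dst_only = list(replay = FALSE, distill = TRUE, scope = "current_only"),
    glr_only = list(replay = TRUE, distill = FALSE, scope = "all"),
    gmm_replay = list(replay = TRUE, distill = TRUE, scope = "all"))
}

task_k <- function(cfg, latents, seed) {
  if (identical(cfg$K, "auto")) {
    cands <- cfg$k_candidates[cfg$k_candidates <= nrow(latents)]
    abort_if(length(cands) == 0L, "no feasible K candidate for this task")
    as.integer(select_k_bic(latents, cands, seed = seed))
  } else min(cfg$K, nrow(latents))
}

#' Run one strategy over a task sequence
#'
#' Sequential protocol: `T` training sessions, one per task in order.
#' After session `i`, row `i` of the train-test matrix `P` is filled by
#' evaluating the current model on every task's test split, so cell
#' `p[i, j]` is the accuracy on task `j` after training on task `i`. For
#' the replay strategies the generator is updated *after* session `t`
#' (session `t` replays the state built from tasks `1..t-1`) and the
#' trained model is snapshotted as the next session's teacher. The first
#' task is trained with plain cross-entropy: there is no teacher or past
#' generator yet. The `joint` strategy instead trains once on the pooled
#' training data and yields a `1 x T` matrix.
#'
#' @param sequence Task sequence from [make_sequence()] / [read_sequence()].
#' @param cfg A [run_config()].
#' @param repeat_seed Seed of this repetition.
#' @return List with `P` (accuracy matrix, percent), `models` is omitted
#'   for size but the final model is returned as `model`, `generator`
#'   (final state or `NULL`), and `loss_traces` per session.
#' @export
run_strategy <- function(sequence, cfg, repeat_seed = 0L) {
  abort_if(!inherits(cfg, "run_config"), "cfg must be a run_config")
  T_ <- length(sequence)
  abort_if(T_ < 1L, "empty sequence")
  d <- ncol(sequence[[1]]$train$features)
  C <- sequence[[1]]$train$n_classes
  task_names <- names(sequence)
  if (is.null(task_names)) task_names <- paste0("task", seq_len(T_))
  traits <- strategy_traits(cfg$strategy)
  hspec <- head_spec(d, C, hidden_widths = cfg$hidden_widths,
                     seed = derive_seed(repeat_seed, "head-init"))
  opt <- opt_config(learning_rate = cfg$learning_rate, epochs = cfg$epochs,
                    batch_size = cfg$batch_size)

  if (cfg$strategy == "joint") {
    pooled <- latent_dataset(
      do.call(rbind, lapply(sequence, function(p) p$train$features)),
      unlist(lapply(sequence, function(p) p$train$labels)),
      domain_id = "joint", split = "train", n_classes = C)
    model <- train_session(init_head(hspec), NULL, pooled, NULL,
                           loss_config(alpha = 0), opt,
                           seed = derive_seed(repeat_seed, "joint"))
    P <- matrix(vapply(sequence, function(p)
      evaluate_accuracy(model, p$test), numeric(1)), nrow = 1L)
    dimnames(P) <- list("joint", task_names)
    return(list(P = P, model = model, generator = NULL,
                loss_traces = list(joint = attr(model, "loss_trace"))))
  }

  P <- matrix(NA_real_, T_, T_, dimnames = list(task_names, task_names))
  model <- init_head(hspec)
  teacher <- NULL
  gen <- if (traits$replay && cfg$strategy != "gmm_replay")
    generator_state("kde") else NULL
  seen_latents <- list()  # gmm_replay refits per-task mixtures as tasks accrue
  traces <- list()
  for (t in seq_len(T_)) {
    current <- sequence[[t]]$train
    sseed <- derive_seed(repeat_seed, paste0("session", t))
    first <- is.null(teacher)
    cfg_t <- loss_config(
      alpha = if (traits$distill && !first) cfg$alpha else 0,
      kld_scope = traits$scope)
    gen_t <- if (!first && traits$replay) {
      if (cfg$strategy == "gmm_replay")
        fit_gmm_generator(seen_latents, cfg$gmm_components,
                          seed = derive_seed(repeat_seed, paste0("gmm", t)))
      else gen
    } else NULL
    use_teacher <- !first && (traits$distill || traits$replay)
    model <- train_session(model, if (use_teacher) teacher else NULL,
                           current, gen_t, cfg_t, opt, seed = sseed)
    traces[[task_names[t]]] <- attr(model, "loss_trace")
    P[t, ] <- vapply(sequence, function(p)
      evaluate_accuracy(model, p$test), numeric(1))
    # update the generator AFTER training on task t
    if (traits$replay || traits$distill) {
      if (cfg$strategy == "gmm_replay") {
        seen_latents[[t]] <- current$features
      } else if (traits$replay) {
        K_t <- task_k(cfg, current$features, seed = sseed)
        centers <- fit_kmeans(current$features, K_t,
                              seed = derive_seed(repeat_seed, paste0("km", t)))
        gen <- update_generator(gen, centers)
      }
      teacher <- model  # frozen snapshot (copy-on-write value semantics)
    }
  }
  list(P = P, model = model,
       generator = if (cfg$strategy == "gmm_replay" && length(seen_latents))
         fit_gmm_generator(seen_latents, cfg$gmm_components,
                           seed = derive_seed(repeat_seed, "gmm-final"))
       else gen,
       loss_traces = traces)
}

#' Repeat a strategy and aggregate the CL metrics
#'
#' Runs [run_strategy()] with seeds `base_seed + r` for
#' `r = 0..n_repeats-1` and reports the mean and sample standard deviation
#' of ACC, BWT and ILM across repeats. The `joint` strategy has no
#' train-test dynamics, so its BWT and ILM are `NA` and only ACC is
#' aggregated.
#'
#' @param sequence Task sequence.
#' @param cfg A [run_config()].
#' @return List with `per_repeat` (list of [run_strategy()] results),
#'   `metrics` (per-repeat data frame) and `summary` (mean/sd per metric).
#' @export
run_experiment <- function(sequence, cfg) {
  runs <- lapply(seq_len(cfg$n_repeats) - 1L, function(r)
    run_strategy(sequence, cfg, repeat_seed = cfg$base_seed + r))
  per <- do.call(rbind, lapply(seq_along(runs), function(i) {
    P <- runs[[i]]$P
    if (cfg$strategy == "joint") {
      data.frame(repeat_index = i - 1L, acc = mean(P[1L, ]),
                 bwt = NA_real_, ilm = NA_real_)
    } else {
      data.frame(repeat_index = i - 1L, acc = cl_acc(P),
                 bwt = if (nrow(P) >= 2L) cl_bwt(P) else NA_real_,
                 ilm = cl_ilm(P))
    }
  }))
  summarise <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(mean = NA_real_, sd = NA_real_))
    c(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0)
  }
  list(per_repeat = runs, metrics = per,
       summary = list(strategy = cfg$strategy,
                      n_repeats = cfg$n_repeats,
                      acc = summarise(per$acc),
                      bwt = summarise(per$bwt),
                      ilm = summarise(per$ilm)))
}
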