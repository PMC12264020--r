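test_that("head initialisation builds the configured layer stack deterministically", {
  spec <- head_spec(16, 3, seed = 1)
  m <- init_head(spec)
  widths <- vapply(m$W, ncol, integer(1))
  expect_equal(widths, c(512L, 256L, 128L, 64L, 32L, 3L))
  expect_equal(vapply(m$W, nrow, integer(1)),
               c(16L, 512L, 256L, 128L, 64L, 32L))

  m2 <- init_head(spec)
  expect_identical(m$W, m2$W)
  expect_false(identical(m$W, init_head(head_spec(16, 3, seed = 2))$W))

  logits <- predict_logits(m, matrix(0, 5, 16))
  expect_equal(dim(logits), c(5L, 3L))
  expect_true(all(is.finite(logits)))
  # all-zero inputs are indistinguishable, so all rows agree
  expect_equal(logits, logits[rep(1, 5), ], ignore_attr = TRUE)

  expect_error(head_spec(16, 1), "n_classes")
  expect_error(predict_logits(m, matrix(0, 2, 7)), "expects 16")
})

test_that("the combined loss obeys its limiting identities", {
  cfg0 <- loss_config(alpha = 0)
  # hand-computed: 2 classes, logits (0,0), label 0 -> CE = ln 2
  expect_equal(as.numeric(combined_loss(matrix(0, 1, 2), NULL, 0L, cfg0)),
               log(2), tolerance = 1e-12)

  set.seed(2)
  s <- matrix(rnorm(30), 10, 3)
  t_ <- matrix(rnorm(30), 10, 3)
  y <- sample(0:2, 10, replace = TRUE)

  # alpha = 0 reduces to pure CE even with a teacher present
  l0 <- combined_loss(s, t_, y, cfg0)
  expect_equal(as.numeric(l0), attr(l0, "ce"))

  # identical teacher/student logits zero the KLD term
  cfg5 <- loss_config(alpha = 0.5)
  lsame <- combined_loss(s, s, y, cfg5)
  expect_equal(attr(lsame, "kld"), 0, tolerance = 1e-12)
  expect_equal(as.numeric(lsame), 0.5 * attr(lsame, "ce"), tolerance = 1e-12)

  # KL non-negativity for arbitrary pairs, equality iff equal distributions
  lmix <- combined_loss(s, t_, y, cfg5)
  expect_gt(attr(lmix, "kld"), 0)
  # shift invariance: softmax ignores a constant added to all logits
  lshift <- combined_loss(s, t_ + 3, y, cfg5)
  expect_equal(attr(lshift, "kld"), attr(lmix, "kld"), tolerance = 1e-10)

  expect_error(combined_loss(s, NULL, y, cfg5), "teacher")
  expect_error(loss_config(alpha = 1.2), "\\[0, 1\\]")
})

test_that("the KLD gradient matches a numerical derivative", {
  set.seed(3)
  s <- matrix(rnorm(12), 4, 3)
  t_ <- matrix(rnorm(12), 4, 3)
  y <- c(0L, 1L, 2L, 0L)
  cfg <- loss_config(alpha = 0.3, kd_temperature = 2)
  g <- latentreplay:::loss_logit_grad(s, t_, y, cfg, 1:4, 1:4)
  num <- matrix(0, 4, 3)
  eps <- 1e-6
  for (i in 1:4) for (j in 1:3) {
    sp <- s; sp[i, j] <- sp[i, j] + eps
    sm <- s; sm[i, j] <- sm[i, j] - eps
    num[i, j] <- (as.numeric(combined_loss(sp, t_, y, cfg)) -
                    as.numeric(combined_loss(sm, t_, y, cfg))) / (2 * eps)
  }
  expect_equal(g, num, tolerance = 1e-6)
})

test_that("pseudo-labels follow the argmax with low-index tie-breaking", {
  spec <- head_spec(4, 3, hidden_widths = 4L, seed = 1)
  teacher <- init_head(spec)
  # identical logits per class (zero weights): everything labels as class 0
  teacher$W <- lapply(teacher$W, function(w) w * 0)
  x <- matrix(rnorm(20), 5, 4)
  expect_equal(pseudo_label(teacher, x), rep(0L, 5))

  # hand-set linear rule on the last layer: sign of x1 decides class
  lin <- init_head(head_spec(2, 2, hidden_widths = 2L, seed = 1))
  lin$W[[1]] <- rbind(c(1, -1), c(0, 0))  # h = (relu(x1), relu(-x1))
  lin$b[[1]] <- c(0, 0)
  lin$W[[2]] <- rbind(c(1, 0), c(0, 1))
  lin$b[[2]] <- c(0, 0)
  pts <- rbind(c(2, 9), c(-3, -9), c(0.5, 0), c(-0.5, 0))
  expect_equal(pseudo_label(lin, pts), c(0L, 1L, 0L, 1L))

  # invariance to constant logit shifts
  shifted <- lin; shifted$b[[2]] <- shifted$b[[2]] + 7
  expect_equal(pseudo_label(shifted, pts), pseudo_label(lin, pts))
})

test_that("hybrid batches are exact 50/50 splits covering the current epoch once", {
  sq <- make_sequence(tiny_specs())
  current <- sq$A$train  # 60 rows
  set.seed(1)
  gen <- update_generator(generator_state(), matrix(rnorm(20), 10, 4))
  teacher <- init_head(head_spec(4, 2, hidden_widths = c(8L, 4L), seed = 2))

  batches <- make_hybrid_batches(current, gen, teacher, batch_size = 16,
                                 seed = 5)
  expect_length(batches, ceiling(60 / 8))
  for (b in batches) {
    expect_equal(sum(b$is_replay), nrow(b$features) / 2)
    expect_equal(sum(!b$is_replay), sum(b$is_replay))
  }
  full <- batches[-length(batches)]
  expect_true(all(vapply(full, function(b) nrow(b$features), numeric(1)) == 16))
  # remainder batch shrinks symmetrically: 60 = 7*8 + 4 current rows
  last <- batches[[length(batches)]]
  expect_equal(nrow(last$features), 8)

  # current rows over the epoch are the training set, each exactly once
  cur_rows <- do.call(rbind, lapply(batches, function(b)
    b$features[!b$is_replay, , drop = FALSE]))
  expect_equal(cur_rows[order(cur_rows[, 1]), ],
               current$features[order(current$features[, 1]), ],
               ignore_attr = TRUE)
  # replay rows carry teacher pseudo-labels
  b1 <- batches[[1]]
  rep_rows <- b1$features[b1$is_replay, , drop = FALSE]
  expect_equal(b1$labels[b1$is_replay], pseudo_label(teacher, rep_rows))

  expect_error(make_hybrid_batches(current, gen, teacher, batch_size = 15),
               "even")
  expect_error(make_hybrid_batches(current, generator_state(), teacher, 16),
               "non-empty")
})

test_that("training sessions learn, freeze the teacher, and respect their limits", {
  sq <- make_sequence(tiny_specs(n_train = 40))
  current <- sq$A$train
  spec <- head_spec(4, 2, hidden_widths = c(16L, 8L), seed = 3)
  student <- init_head(spec)

  # zero epochs: parameters unchanged
  out0 <- train_session(student, NULL, current, NULL,
                        opt = opt_config(epochs = 0), seed = 1)
  expect_identical(out0$W, student$W)

  # the tiny domains are linearly separable: confirm with a direct linear
  # fit first, then training must reach >= 99% train accuracy
  lin <- stats::lm.fit(cbind(1, current$features),
                       2 * current$labels - 1)
  expect_gte(mean(sign(lin$fitted.values) == 2 * current$labels - 1), 0.99)
  trained <- train_session(student, NULL, current, NULL,
                           opt = opt_config(epochs = 60, batch_size = 16),
                           seed = 1)
  acc <- 100 * mean(pseudo_label(trained, current$features) == current$labels)
  expect_gte(acc, 99)
  trace <- attr(trained, "loss_trace")
  expect_true(all(c("epoch", "step", "loss_ce", "loss_kld", "loss_total")
                  %in% names(trace)))
  expect_lt(mean(tail(trace$loss_total, 5)), mean(head(trace$loss_total, 5)))

  # alpha = 0: identical trajectories with and without a teacher
  teacher <- init_head(head_spec(4, 2, hidden_widths = c(16L, 8L), seed = 9))
  with_t <- train_session(student, teacher, current, NULL,
                          cfg = loss_config(alpha = 0),
                          opt = opt_config(epochs = 3, batch_size = 16),
                          seed = 7)
  without_t <- train_session(student, NULL, current, NULL,
                             cfg = loss_config(alpha = 0),
                             opt = opt_config(epochs = 3, batch_size = 16),
                             seed = 7)
  expect_equal(with_t$W, without_t$W, tolerance = 1e-12)

  # teacher immutability through a distilling session with replay
  set.seed(11)
  gen <- update_generator(generator_state(), matrix(rnorm(20), 10, 4))
  teacher_before <- unlist(teacher$W)
  st <- train_session(student, teacher, current, gen,
                      cfg = loss_config(alpha = 0.3),
                      opt = opt_config(epochs = 2, batch_size = 16), seed = 2)
  expect_identical(unlist(teacher$W), teacher_before)
  expect_true(all(is.finite(unlist(st$W))))
})

test_that("trained teachers give consistent pseudo-labels near their support points", {
  # property: once a teacher is trained on two well-separated classes,
  # >= 90% of generator samples inherit the class of their nearest center
  means <- rbind(c(0, 0, 0, 0), c(6, 6, 0, 0))
  sp <- domain_spec("sep", 100, 10, means, c(0.5, 0.5), seed = 42)
  tr <- make_domain(sp)$train
  teacher <- train_session(init_head(head_spec(4, 2, hidden_widths = c(16L, 8L),
                                               seed = 5)),
                           NULL, tr, NULL,
                           opt = opt_config(epochs = 40, batch_size = 16),
                           seed = 3)
  centers <- fit_kmeans(tr$features, 20, seed = 1)
  gen <- update_generator(generator_state(), centers)
  s <- sample_generator(gen, 500, seed = 6)
  labs <- pseudo_label(teacher, s)
  nearest <- latentreplay:::nearest_support(s, centers)
  center_class <- pseudo_label(teacher, centers)
  expect_gte(mean(labs == center_class[nearest]), 0.9)
})
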