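# one moderately sized fixture dataset shared across classifier tests
fixture_ds <- motif_fixture_dataset(n_per_class = 400, side = 9, seed = 11)

test_that("the classifier separates planted-motif fixtures", {
  model <- train_classifier(fixture_ds, arch_spec(2, 64),
                            train_config(epochs = 40, seed = 1))
  expect_gte(model$metrics$accuracy, 0.95)
  expect_gte(model$metrics$auc, 0.95)
  # glance/tidy accessors
  g <- glance(model)
  expect_equal(g$hidden_layers, 2L)
  expect_equal(g$accuracy, model$metrics$accuracy)
  expect_true(all(c("epoch", "train_loss", "val_loss") %in% names(tidy(model))))
})

test_that("shuffled labels drop accuracy to chance", {
  ds <- fixture_ds
  ds$y <- local({ set.seed(99); sample(ds$y) })
  ds$data$label <- ifelse(ds$y == 1, "discriminative", "indiscriminate")
  model <- train_classifier(ds, arch_spec(1, 32),
                            train_config(epochs = 15, seed = 2))
  expect_lt(abs(model$metrics$accuracy - 0.5), 0.1)
})

test_that("evaluation metrics satisfy their exact identities", {
  # perfect predictor
  perfect <- structure(list(), class = "const_pred")
  y <- rep(c(1L, 0L), each = 20)
  p_perfect <- ifelse(y == 1, 0.99, 0.01)
  m <- local({
    # evaluate via a stub model whose predictions are fixed
    stub <- structure(list(p = p_perfect), class = "stub_model")
    assign("predict.stub_model", function(object, newdata, ...) object$p,
           envir = globalenv())
    on.exit(rm("predict.stub_model", envir = globalenv()))
    evaluate_classifier(stub, matrix(0, 40, 1), y)
  })
  expect_equal(m$accuracy, 1)
  expect_equal(m$auc, 1)
  expect_equal(sum(m$confusion), 40)
  expect_equal(m$confusion["indiscriminate", "discriminative"], 0L,
               ignore_attr = TRUE)
  # confusion total equals test size and accuracy = trace/sum on a real model
  model <- train_classifier(fixture_ds, arch_spec(0, 1),
                            train_config(epochs = 5, seed = 3))
  cm <- model$metrics$confusion
  expect_equal(sum(cm), model$metrics$n)
  expect_equal(model$metrics$accuracy, sum(diag(cm)) / sum(cm))
  # balanced split: accuracy = (sensitivity + specificity) / 2
  yb <- model$metrics
  n_pos <- sum(fixture_ds$y[fixture_ds$data$split == "test"] == 1)
  n_neg <- sum(fixture_ds$y[fixture_ds$data$split == "test"] == 0)
  if (n_pos == n_neg)
    expect_equal(yb$accuracy, (yb$sensitivity + yb$specificity) / 2)
  expect_error(evaluate_classifier(model, fixture_ds$X[1:5, ], rep(1L, 5)),
               "single-class")
})

test_that("AUC matches brute-force pair counting", {
  stub <- structure(list(p = c(0.9, 0.6, 0.3, 0.7)), class = "stub_model")
  assign("predict.stub_model", function(object, newdata, ...) object$p,
         envir = globalenv())
  on.exit(rm("predict.stub_model", envir = globalenv()))
  y <- c(1L, 1L, 0L, 0L)
  m <- evaluate_classifier(stub, matrix(0, 4, 1), y)
  # exhaustive pairs: (0.9,0.3) (0.9,0.7) (0.6,0.3) each win, (0.6,0.7)
  # loses -> 3/4 -> AUC 0.75
  expect_equal(m$auc, 0.75)
  # constant score -> AUC 0.5 (all ties)
  stub2 <- structure(list(p = rep(0.5, 4)), class = "stub_model")
  assign("predict.stub_model", function(object, newdata, ...) object$p,
         envir = globalenv())
  expect_equal(evaluate_classifier(stub2, matrix(0, 4, 1), y)$auc, 0.5)
  # independent cross-check on random scores
  skip_if_not_installed("pROC")
  set.seed(5)
  ys <- rep(0:1, each = 30)
  ps <- runif(60)
  stub3 <- structure(list(p = ps), class = "stub_model")
  assign("predict.stub_model", function(object, newdata, ...) object$p,
         envir = globalenv())
  got <- evaluate_classifier(stub3, matrix(0, 60, 1), ys)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(ys, ps, quiet = TRUE,
                                      direction = "<", levels = c(0, 1))))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("training is reproducible under a fixed seed", {
  m1 <- train_classifier(fixture_ds, arch_spec(1, 16),
                         train_config(epochs = 8, seed = 7))
  m2 <- train_classifier(fixture_ds, arch_spec(1, 16),
                         train_config(epochs = 8, seed = 7))
  expect_identical(m1$metrics$confusion, m2$metrics$confusion)
  expect_identical(m1$net$W, m2$net$W)
  m3 <- train_classifier(fixture_ds, arch_spec(1, 16),
                         train_config(epochs = 8, seed = 8))
  expect_false(identical(m1$net$W, m3$net$W))
})

test_that("saliency is the exact input gradient", {
  model <- train_classifier(fixture_ds, arch_spec(1, 16),
                            train_config(epochs = 3, seed = 1))
  # zero first-layer weights give an all-zero map
  z <- model
  z$net$W[[1]][] <- 0
  sal0 <- saliency(z, fixture_ds$data$mask[[1]])
  expect_true(all(sal0 == 0))
  # shape follows the input for every admissible size
  for (side in c(5L, 9L, 13L)) {
    ds <- motif_fixture_dataset(n_per_class = 40, side = side, seed = side)
    m <- train_classifier(ds, arch_spec(0, 1), train_config(epochs = 2, seed = 1))
    sal <- saliency(m, ds$data$mask[[1]])
    expect_equal(dim(sal), c(side, side))
    expect_true(all(sal >= 0))
    # a linear (no hidden layer) model's saliency is its absolute weights
    expect_equal(as.vector(sal), abs(as.vector(m$net$W[[1]])),
                 tolerance = 1e-12)
  }
})

test_that("deeper networks do not underperform linear ones on the fixtures", {
  accs <- vapply(1:3, function(s) {
    m0 <- train_classifier(fixture_ds, arch_spec(0, 1),
                           train_config(epochs = 12, seed = s))
    m2 <- train_classifier(fixture_ds, arch_spec(2, 32),
                           train_config(epochs = 12, seed = s))
    c(m0$metrics$accuracy, m2$metrics$accuracy)
  }, numeric(2))
  expect_gte(mean(accs[2, ]), mean(accs[1, ]) - 1e-9)
})
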