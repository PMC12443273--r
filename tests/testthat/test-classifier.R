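toy_labeled <- function(n_share = 40, n_inq = 30, n_non = 30) {
  labeled_comments(
    text = c(sprintf("I was diagnosed with cancer in year %d and recovered", seq_len(n_share)),
             sprintf("What are the symptoms of diabetes number %d exactly", seq_len(n_inq)),
             sprintf("thank you for this lovely post number %d today", seq_len(n_non))),
    label = rep(c("sharing_experience", "inquiring", "non_informative"),
                c(n_share, n_inq, n_non)))
}

test_that("stratified split reproduces itself and preserves class proportions", {
  lab <- toy_labeled(40, 30, 30)
  cfg <- train_config(test_fraction = 0.30, seed = 21)
  sp1 <- split_data(lab, cfg)
  sp2 <- split_data(lab, cfg)
  expect_identical(sp1, sp2)
  expect_equal(nrow(sp1$train), 70)
  expect_equal(nrow(sp1$test), 30)
  expect_equal(length(intersect(sp1$train$text, sp1$test$text)), 0)
  # per-class proportions preserved within one item
  for (lb in unique(lab$label)) {
    n_class <- sum(lab$label == lb)
    n_test <- sum(sp1$test$label == lb)
    expect_lte(abs(n_test - 0.30 * n_class), 1)
  }
  # fraction 0.5 on a 2-item class puts one on each side
  tiny <- labeled_comments(
    c(sprintf("sharing text %d", 1:6), sprintf("inquiry text %d", 1:2),
      sprintf("noise text %d", 1:2)),
    rep(c("sharing_experience", "inquiring", "non_informative"), c(6, 2, 2)))
  sp <- split_data(tiny, train_config(test_fraction = 0.5, seed = 3))
  expect_equal(sum(sp$test$label == "inquiring"), 1)
  expect_equal(sum(sp$train$label == "inquiring"), 1)
  expect_error(split_data(lab[1:5, ], cfg), "at least 10")
  one <- labeled_comments(c(sprintf("a b c %d", 1:9), "single inquiring item"),
                          c(rep("sharing_experience", 9), "inquiring"))
  expect_error(split_data(one, cfg), "at least 2 instances")
})

test_that("oversampling equalizes class counts using only existing texts", {
  lab <- toy_labeled(50, 10, 40)
  bal <- oversample(lab, seed = 7)
  expect_equal(unname(table(bal$label)[class_labels]),
               rep(50L, 3), ignore_attr = TRUE)
  expect_true(all(bal$text %in% lab$text))
  balanced <- toy_labeled(20, 20, 20)
  expect_equal(nrow(oversample(balanced, seed = 1)), 60)
  expect_error(oversample(lab[0, ]), "non-empty")
})

test_that("oversampling never leaks into the held-out test partition", {
  lab <- toy_labeled(40, 12, 28)
  sp <- split_data(lab, train_config(seed = 9))
  bal <- oversample(sp$train, seed = 9)
  expect_equal(length(intersect(bal$text, sp$test$text)), 0)
})

test_that("rule-based classification is total, deterministic, and follows the cue order", {
  m <- train_classifier(backend = "rule_based")
  expect_equal(classify(m, "What are the symptoms of diabetes?"), "inquiring")
  expect_equal(classify(m, "Does anyone know a good clinic"), "inquiring")
  expect_equal(classify(m, "เบาหวานรักษาหายไหม"), "inquiring")
  expect_equal(classify(m, "I was diagnosed with diabetes last year and changed my diet"),
               "sharing_experience")
  expect_equal(classify(m, "ผมเป็นเบาหวานมาสองปี"), "sharing_experience")
  expect_equal(classify(m, ""), "non_informative")
  expect_equal(classify(m, "good luck everyone"), "non_informative")
  texts <- c("random words here", NA, "ok?", "ผมเคยเป็น")
  p1 <- classify(m, texts)
  expect_identical(p1, classify(m, texts))
  expect_true(all(p1 %in% class_labels))
})

test_that("linear bag-of-words backend recovers planted labels on a separable corpus", {
  out <- generate_corpus(corpus_spec(n_comments = 300, duplicate_rate = 0,
                                     short_rate = 0, seed = 31))
  lab <- labeled_comments(out$records$text, out$ground_truth$label,
                          out$records$language)
  cfg <- train_config(seed = 31)
  sp <- split_data(lab, cfg)
  model <- train_classifier(sp$train, cfg, backend = "linear_bow")
  pred <- classify(model, sp$test$text, sp$test$language)
  expect_gte(mean(pred == sp$test$label), 0.9)
  # same seed, same predictions
  model2 <- train_classifier(sp$train, cfg, backend = "linear_bow")
  expect_identical(pred, classify(model2, sp$test$text, sp$test$language))
})

test_that("the transformer backend is an explicit extension point", {
  lab <- toy_labeled(10, 5, 5)
  expect_error(train_classifier(lab, backend = "transformer"), "fit_fun")
  # a user-supplied fitting function receives train/valid partitions and config
  seen <- NULL
  m <- train_classifier(lab, train_config(seed = 2), backend = "transformer",
                        fit_fun = function(train, valid, config) {
                          seen <<- list(train = train, valid = valid, config = config)
                          list(classify = function(text) "non_informative")
                        })
  expect_equal(classify(m, "anything"), "non_informative")
  expect_equal(seen$config$max_sequence_length, 200L)
  expect_equal(seen$config$learning_rate, 2e-5)
  expect_gte(nrow(seen$valid), 1)
})

test_that("evaluation reproduces hand-computed confusion-matrix metrics", {
  # perfect predictions
  gold <- rep(class_labels, each = 4)
  ev <- evaluate_classifier(gold, gold)
  expect_equal(ev$accuracy, 1)
  expect_true(all(ev$metrics$precision == 1 & ev$metrics$recall == 1 &
                    ev$metrics$f1 == 1))
  # one class with TP=8, FP=2, FN=2 -> P=R=F1=0.8
  gold2 <- c(rep("sharing_experience", 10), rep("inquiring", 10))
  pred2 <- c(rep("sharing_experience", 8), rep("inquiring", 2),
             rep("inquiring", 8), rep("sharing_experience", 2))
  ev2 <- evaluate_classifier(pred2, gold2)
  row <- ev2$metrics[ev2$metrics$class == "sharing_experience", ]
  expect_equal(row$precision, 0.8)
  expect_equal(row$recall, 0.8)
  expect_equal(row$f1, 0.8)
  # all-one-class predictor on balanced gold of 30 -> accuracy 1/3
  gold3 <- rep(class_labels, each = 10)
  ev3 <- evaluate_classifier(rep("inquiring", 30), gold3)
  expect_equal(ev3$accuracy, 1 / 3)
  expect_error(evaluate_classifier("a", character(0)), "same length")
})

test_that("metric identities hold against a counting oracle on random prediction pairs", {
  withr::with_seed(123, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      gold <- sample(class_labels, n, replace = TRUE)
      pred <- sample(class_labels, n, replace = TRUE)
      ev <- evaluate_classifier(pred, gold)
      expect_equal(sum(ev$confusion), n)
      expect_equal(ev$accuracy, mean(pred == gold))
      for (k in seq_along(class_labels)) {
        lb <- class_labels[k]
        tp <- sum(pred == lb & gold == lb)
        fp <- sum(pred == lb & gold != lb)
        fn <- sum(pred != lb & gold == lb)
        row <- ev$metrics[k, ]
        expect_equal(row$precision, if (tp + fp > 0) tp / (tp + fp) else 0)
        expect_equal(row$recall, if (tp + fn > 0) tp / (tp + fn) else 0)
        pr <- row$precision + row$recall
        expect_equal(row$f1,
                     if (pr > 0) 2 * row$precision * row$recall / pr else 0)
      }
    }
  })
})
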