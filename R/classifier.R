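# Three-category comment classification (sharing_experience / inquiring /
# non_informative): stratified splitting, minority-class oversampling,
# pluggable training backends, and confusion-matrix metrics.

class_labels <- c("sharing_experience", "inquiring", "non_informative")

#' Training configuration
#'
#' Bundles the training-recipe knobs: held-out test fraction (default 0.30),
#' maximum sequence length 200 and learning rate 2e-5 (honored by the
#' transformer backend), early-stopping patience, whether to oversample the
#' training set, and the RNG seed.
#'
#' @param test_fraction Held-out fraction in (0, 1).
#' @param max_sequence_length Truncation length for sequence backends.
#' @param learning_rate Positive learning rate for gradient backends.
#' @param early_stopping_patience Epochs without validation improvement
#'   before stopping.
#' @param oversample Balance training classes by duplication?
#' @param seed Integer seed driving every random step.
#' @return A `train_config` list.
#' @export
train_config <- function(test_fraction = 0.30, max_sequence_length = 200L,
                         learning_rate = 2e-5, early_stopping_patience = 3L,
                         oversample = TRUE, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1, learning_rate > 0,
            max_sequence_length >= 1, early_stopping_patience >= 1)
  structure(list(test_fraction = test_fraction,
                 max_sequence_length = as.integer(max_sequence_length),
                 learning_rate = learning_rate,
                 early_stopping_patience = as.integer(early_stopping_patience),
                 oversample = isTRUE(oversample), seed = as.integer(seed)),
            class = "train_config")
}

#' Build a labeled-comment table
#'
#' @param text Character vector of comments.
#' @param label One of the three category labels per comment.
#' @param language Optional language tags (detected when absent).
#' @return Tibble with columns `text`, `language`, `label`.
#' @export
labeled_comments <- function(text, label, language = NULL) {
  label <- as.character(label)
  bad <- setdiff(unique(label), class_labels)
  if (length(bad))
    stop("labels must be one of ", paste(class_labels, collapse = ", "),
         "; got: ", paste(bad, collapse = ", "))
  if (is.null(language)) language <- detect_language(text)
  tibble::tibble(text = as.character(text), language = language, label = label)
}

#' Stratified train/test split
#'
#' Splits labeled comments into train and held-out test sets at
#' `config$test_fraction`, stratified by label and reproducible from
#' `config$seed`. Per-class test counts are `round(n_class * fraction)`
#' (each class keeps at least one item on each side).
#'
#' @param labeled A [labeled_comments()] table with at least 10 rows and at
#'   least 2 instances per class.
#' @param config A [train_config()].
#' @return List with elements `train` and `test` (disjoint tables).
#' @export
split_data <- function(labeled, config = train_config()) {
  if (nrow(labeled) < 10) stop("need at least 10 labeled comments to split")
  counts <- table(labeled$label)
  if (any(counts < 2))
    stop("every class needs at least 2 instances; short: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  test_idx <- withr::with_seed(config$seed, {
    unlist(lapply(names(counts), function(lb) {
      idx <- which(labeled$label == lb)
      n_test <- min(max(1L, round(length(idx) * config$test_fraction)),
                    length(idx) - 1L)
      sample(idx, n_test)
    }))
  })
  test_idx <- sort(test_idx)
  list(train = labeled[-test_idx, ], test = labeled[test_idx, ])
}

#' Oversample minority classes
#'
#' Upsamples every minority class by seeded random duplication of its own
#' items until all class counts equal the majority count. Applied to the
#' training partition only; the test set is never touched.
#'
#' @param train Labeled-comment table.
#' @param seed Integer seed.
#' @return The balanced training table (original rows first, duplicates
#'   appended).
#' @export
oversample <- function(train, seed = 1L) {
  counts <- table(train$label)
  if (length(counts) == 0 || any(counts == 0)) stop("every class must be non-empty")
  target <- max(counts)
  extra <- withr::with_seed(seed, {
    lapply(names(counts), function(lb) {
      need <- target - counts[[lb]]
      if (need == 0) return(NULL)
      idx <- which(train$label == lb)
      train[sample(idx, need, replace = TRUE), ]
    })
  })
  dplyr::bind_rows(c(list(train), extra))
}

#' Train a comment classifier
#'
#' Backends:
#' \describe{
#'   \item{`rule_based`}{No training: interrogative cues (question marks,
#'     wh-words, Thai question particles) mean `inquiring`; otherwise
#'     first-person experience cues mean `sharing_experience`; otherwise
#'     `non_informative`.}
#'   \item{`linear_bow`}{Bag-of-words multinomial ridge regression
#'     (glmnet) over normalized tokens; deterministic given `config$seed`.}
#'   \item{`transformer`}{The fine-tuning recipe (sequence truncation at
#'     `max_sequence_length`, `learning_rate`, early stopping on a
#'     stratified 10% validation carve-out with `early_stopping_patience`)
#'     delegated to a user-supplied `fit_fun(train, valid, config)`;
#'     nothing is downloaded.}
#' }
#' When `config$oversample` is set, training data is balanced with
#' [oversample()] first (never the validation carve-out or test data).
#'
#' @param labeled Labeled-comment table (ignored by `rule_based`).
#' @param config A [train_config()].
#' @param backend `"rule_based"`, `"linear_bow"`, or `"transformer"`.
#' @param fit_fun Required for the `transformer` backend: a function
#'   implementing the fine-tuning step, returning an object with a
#'   `classify(text)` method.
#' @return A `ncdl_classifier` object usable with [classify()].
#' @export
train_classifier <- function(labeled = NULL, config = train_config(),
                             backend = c("rule_based", "linear_bow", "transformer"),
                             fit_fun = NULL) {
  backend <- match.arg(backend)
  model <- switch(backend,
    rule_based = list(),
    linear_bow = fit_linear_bow(labeled, config),
    transformer = {
      if (is.null(fit_fun))
        stop("the transformer backend needs a user-supplied `fit_fun`; ",
             "no pretrained model is bundled or downloaded")
      carve <- validation_carve(labeled, config)
      train_part <- if (config$oversample) oversample(carve$train, config$seed) else carve$train
      fit_fun(train_part, carve$valid, config)
    })
  structure(list(backend = backend, model = model, config = config),
            class = "ncdl_classifier")
}

# stratified 10% validation carve-out for early stopping
validation_carve <- function(labeled, config) {
  sp <- split_data(labeled, train_config(test_fraction = 0.10, seed = config$seed))
  list(train = sp$train, valid = sp$test)
}

bow_features <- function(texts, languages, vocab = NULL) {
  token_lists <- lapply(seq_along(texts), function(i) {
    toks <- normalize_tokens(tokenize(texts[i], languages[i]), languages[i])
    if (languages[i] != "unknown") toks <- remove_stopwords(toks, languages[i])
    toks
  })
  if (is.null(vocab)) vocab <- sort(unique(unlist(token_lists)))
  ij <- do.call(rbind, lapply(seq_along(token_lists), function(i) {
    j <- match(token_lists[[i]], vocab)
    j <- j[!is.na(j)]
    if (length(j) == 0) return(NULL)
    cbind(i = i, j = j)
  }))
  if (is.null(ij)) ij <- cbind(i = integer(0), j = integer(0))
  m <- Matrix::sparseMatrix(i = ij[, "i"], j = ij[, "j"], x = 1,
                            dims = c(length(texts), length(vocab)))
  list(x = m, vocab = vocab)
}

fit_linear_bow <- function(labeled, config) {
  if (is.null(labeled) || nrow(labeled) == 0)
    stop("the linear_bow backend needs labeled training data")
  if (config$oversample) labeled <- oversample(labeled, config$seed)
  feats <- bow_features(labeled$text, labeled$language)
  fit <- withr::with_seed(config$seed,
    glmnet::glmnet(feats$x, factor(labeled$label, levels = class_labels),
                   family = "multinomial", alpha = 0,
                   lambda = 0.01, standardize = FALSE))
  list(fit = fit, vocab = feats$vocab)
}

inquiring_regex <- paste0(
  "\\?|^(what|why|how|when|where|who|which|can|could|do|does|did|is|are|should)\\b",
  "|\\b(anyone know|any advice|please advise)\\b",
  "|(ไหม|มั้ย|หรือเปล่า|หรือยัง|อะไร|ทำไม|ยังไง|อย่างไร|ที่ไหน|กี่|ใครรู้)")
sharing_regex <- paste0(
  "\\b(i|my|me|we|our|mine)\\b",
  "|(ผมเป็น|ฉันเป็น|ดิฉันเป็น|เราเป็น|ผมเคย|ฉันเคย|ของผม|ของฉัน|แม่ผม|แม่ฉัน|พ่อผม|พ่อฉัน|ตัวเอง)")

rule_based_label <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return("non_informative")
  low <- stringi::stri_trans_tolower(text)
  if (stringi::stri_detect_regex(low, inquiring_regex)) return("inquiring")
  if (stringi::stri_detect_regex(low, sharing_regex)) return("sharing_experience")
  "non_informative"
}

#' Classify comments
#'
#' Total function: always returns exactly one of the three category labels
#' per input text.
#'
#' @param model A [train_classifier()] object.
#' @param text Character vector of comments.
#' @param language Optional language tags (detected when absent).
#' @return Character vector of labels.
#' @export
classify <- function(model, text, language = NULL) {
  stopifnot(inherits(model, "ncdl_classifier"))
  if (length(text) == 0) return(character(0))
  if (is.null(language)) language <- detect_language(text)
  switch(model$backend,
    rule_based = vapply(text, rule_based_label, character(1), USE.NAMES = FALSE),
    linear_bow = {
      feats <- bow_features(text, language, vocab = model$model$vocab)
      as.character(predict(model$model$fit, feats$x, type = "class",
                           s = model$model$fit$lambda[1]))
    },
    transformer = vapply(text, function(t) model$model$classify(t),
                         character(1), USE.NAMES = FALSE))
}

#' Evaluate predictions against gold labels
#'
#' Builds the 3x3 confusion matrix (rows = gold, columns = predicted) and
#' the usual one-vs-rest metrics: per-class precision, recall and F1
#' (`F1 = 2PR/(P+R)`, 0 when `P+R = 0`) plus overall accuracy
#' (`trace/total`).
#'
#' @param predictions,gold Equal-length label vectors.
#' @return List with `confusion` (3x3 integer matrix) and `metrics` (tibble
#'   of class, precision, recall, f1) plus `accuracy`.
#' @export
evaluate_classifier <- function(predictions, gold) {
  if (length(predictions) != length(gold) || length(gold) == 0)
    stop("predictions and gold must be non-empty and the same length")
  p <- factor(predictions, levels = class_labels)
  g <- factor(gold, levels = class_labels)
  cm <- table(gold = g, predicted = p)
  cm <- matrix(as.integer(cm), 3, 3, dimnames = dimnames(cm))
  per_class <- lapply(seq_along(class_labels), function(k) {
    tp <- cm[k, k]
    fp <- sum(cm[-k, k])
    fn <- sum(cm[k, -k])
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(class = class_labels[k], precision = prec,
                   recall = rec, f1 = f1)
  })
  list(confusion = cm,
       metrics = dplyr::bind_rows(per_class),
       accuracy = sum(diag(cm)) / sum(cm))
}
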