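# Lexicon-driven knowledge extraction: populate the dashboard variables
# (gender, opinion source, mentioned diseases/symptoms/treatments/behaviors,
# word frequency) for each comment, and the user-driven include/exclude
# data-adjustment step.

lexicon_categories <- c("disease", "symptom", "treatment", "behavior_cause",
                        "gender_cue", "source_cue")
# cue categories are matched on full normalized tokens (pronouns and
# particles are the cues, so stopword removal must not apply to them)
cue_categories <- c("gender_cue", "source_cue")

#' Load a lexicon file
#'
#' Lexicon format: YAML mapping category name (one of `disease`, `symptom`,
#' `treatment`, `behavior_cause`, `gender_cue`, `source_cue`) to a list of
#' entries `{label, en: [terms], th: [terms]}`. Canonical labels must be
#' unique within a category; every entry needs at least one term. English
#' terms are pre-tokenized and normalized at load time so matching uses the
#' same pipeline as comment text.
#'
#' @param path YAML lexicon file; defaults to the starter lexicon shipped
#'   with the package.
#' @return A `lexicon` object: named list of category tibbles with columns
#'   `label`, `en` (list of token vectors), `th` (list of strings).
#' @export
load_lexicon <- function(path = ncdl_resource("lexicon.yaml")) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), lexicon_categories)
  if (length(bad))
    stop("unknown lexicon categor", if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "))
  out <- lapply(names(raw), function(cat) {
    entries <- raw[[cat]]
    if (length(entries) == 0)
      stop("lexicon category '", cat, "' is empty")
    labels <- vapply(entries, function(e) as.character(e$label %||% NA), character(1))
    if (anyNA(labels)) stop("lexicon category '", cat, "': entry without a label")
    dup <- labels[duplicated(labels)]
    if (length(dup))
      stop("lexicon category '", cat, "': duplicate label(s) ",
           paste(unique(dup), collapse = ", "))
    drop_stop <- !(cat %in% cue_categories)
    en <- lapply(entries, function(e) {
      terms <- as.character(unlist(e$en))
      lapply(terms, function(t) normalize_term_en(t, drop_stop))
    })
    th <- lapply(entries, function(e) as.character(unlist(e$th)))
    n_terms <- mapply(function(a, b) length(a) + length(b), en, th)
    if (any(n_terms == 0))
      stop("lexicon category '", cat, "': entry '",
           labels[which(n_terms == 0)[1]], "' has an empty term list")
    tibble::tibble(label = labels, en = en, th = th)
  })
  names(out) <- names(raw)
  structure(out, class = "lexicon")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tokenize + normalize an English lexicon term with the comment pipeline so
# term tokens and comment tokens live in the same space
normalize_term_en <- function(term, drop_stopwords = TRUE) {
  toks <- normalize_tokens(tokenize(term, "english"), "english")
  if (drop_stopwords) {
    dropped <- remove_stopwords(toks, "english")
    if (length(dropped)) toks <- dropped  # a pure-stopword cue stays intact
  }
  toks
}

# first start position of `sub` as a contiguous subsequence of `tokens`, or 0
subseq_position <- function(tokens, sub) {
  k <- length(sub)
  n <- length(tokens)
  if (k == 0 || n < k) return(0L)
  for (i in seq_len(n - k + 1)) {
    if (all(tokens[i:(i + k - 1)] == sub)) return(i)
  }
  0L
}

#' Match one lexicon category against a tokenized comment
#'
#' A canonical label is returned iff at least one of its terms occurs in the
#' comment: English terms as contiguous subsequences of the normalized token
#' stream (stopword-removed for content categories, full for the cue
#' categories), Thai terms as substrings of the raw, unsegmented text.
#' Labels are deduplicated and ordered by first occurrence.
#'
#' @param tokenized One row of [tokenize_comments()] output (or a list with
#'   `tokens`, `normalized_tokens`, `text`, `language`).
#' @param lexicon A [load_lexicon()] object.
#' @param category Lexicon category name.
#' @return Character vector of matched canonical labels.
#' @export
match_category <- function(tokenized, lexicon, category) {
  stopifnot(inherits(lexicon, "lexicon"))
  category <- match.arg(category, lexicon_categories)
  entries <- lexicon[[category]]
  if (is.null(entries)) return(character(0))
  text <- one_of(tokenized, "text")
  lang <- one_of(tokenized, "language")
  if (category %in% cue_categories) {
    toks <- normalize_tokens(unlist(one_of(tokenized, "tokens")), lang)
  } else {
    toks <- unlist(one_of(tokenized, "normalized_tokens"))
  }
  hits <- lapply(seq_len(nrow(entries)), function(i) {
    pos <- Inf
    for (term in entries$en[[i]]) {
      p <- subseq_position(toks, term)
      if (p > 0) pos <- min(pos, p)
    }
    for (term in entries$th[[i]]) {
      p <- stringi::stri_locate_first_fixed(text, term)[1, 1]
      if (!is.na(p)) pos <- min(pos, p + length(toks))  # after token hits
    }
    pos
  })
  pos <- unlist(hits)
  matched <- which(is.finite(pos))
  entries$label[matched[order(pos[matched], matched)]]
}

one_of <- function(x, field) {
  v <- x[[field]]
  if (is.data.frame(x) && nrow(x) != 1) stop("expected a single tokenized comment")
  v
}

#' Extract the dashboard variables for one comment
#'
#' Fills the per-comment knowledge record: mentioned diseases, symptoms,
#' treatments and behaviors from lexicon matching; patient gender from
#' gender-cue words (cues for both genders present means `unknown`); opinion
#' source from source cues, first matched cue winning and `general` as the
#' default. The comment category is left unset — it is filled by the
#' classifier stage.
#'
#' @inheritParams match_category
#' @return A one-row tibble: `seq`, `gender`, `source`, `category` (`NA`),
#'   and list-columns `diseases`, `symptoms`, `treatments`, `behaviors`.
#' @export
extract_variables <- function(tokenized, lexicon) {
  g <- match_category(tokenized, lexicon, "gender_cue")
  gender <- if (length(g) == 0 || all(c("male", "female") %in% g)) "unknown" else g[1]
  s <- match_category(tokenized, lexicon, "source_cue")
  source <- if (length(s) == 0) "general" else s[1]
  tibble::tibble(
    seq = as.integer(one_of(tokenized, "seq")),
    gender = gender, source = source, category = NA_character_,
    diseases = list(match_category(tokenized, lexicon, "disease")),
    symptoms = list(match_category(tokenized, lexicon, "symptom")),
    treatments = list(match_category(tokenized, lexicon, "treatment")),
    behaviors = list(match_category(tokenized, lexicon, "behavior_cause")))
}

#' Extract knowledge for a whole corpus
#'
#' @param tokenized Output of [tokenize_comments()].
#' @param lexicon A [load_lexicon()] object.
#' @return A knowledge table: one [extract_variables()] row per comment.
#' @export
extract_knowledge <- function(tokenized, lexicon) {
  if (nrow(tokenized) == 0)
    return(tibble::tibble(seq = integer(0), gender = character(0),
                          source = character(0), category = character(0),
                          diseases = list(), symptoms = list(),
                          treatments = list(), behaviors = list()))
  rows <- lapply(seq_len(nrow(tokenized)), function(i)
    extract_variables(tokenized[i, ], lexicon))
  dplyr::bind_rows(rows)
}

#' Corpus word frequencies
#'
#' Token counts over the normalized, stopword-removed token streams,
#' descending by count with ties broken lexicographically.
#'
#' @param tokenized Output of [tokenize_comments()].
#' @param top_k Maximum number of (token, count) rows returned; `Inf` for
#'   all.
#' @return Tibble with columns `token`, `count`.
#' @export
word_frequency <- function(tokenized, top_k = 20) {
  stopifnot(top_k >= 1)
  toks <- unlist(tokenized$normalized_tokens)
  if (length(toks) == 0)
    return(tibble::tibble(token = character(0), count = integer(0)))
  tab <- table(toks)
  out <- tibble::tibble(token = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$token), ]
  head(out, if (is.finite(top_k)) top_k else nrow(out))
}

knowledge_mentions <- function(knowledge) {
  lapply(seq_len(nrow(knowledge)), function(i)
    unique(c(knowledge$diseases[[i]], knowledge$symptoms[[i]])))
}

#' Apply the user's include/exclude disease and symptom filters
#'
#' A comment survives iff (the include set is empty OR the comment mentions
#' at least one included disease/symptom label) AND it mentions no excluded
#' label. Surviving records are returned unchanged; the operation is
#' idempotent and its output is always a subset of its input.
#'
#' @param knowledge Knowledge table from [extract_knowledge()].
#' @param include,exclude Character vectors of canonical disease/symptom
#'   labels; must not overlap.
#' @return The filtered knowledge table.
#' @export
adjust_selection <- function(knowledge, include = character(0),
                             exclude = character(0)) {
  overlap <- intersect(include, exclude)
  if (length(overlap))
    stop("labels cannot be both included and excluded: ",
         paste(overlap, collapse = ", "))
  if (nrow(knowledge) == 0) return(knowledge)
  mentions <- knowledge_mentions(knowledge)
  keep <- vapply(mentions, function(m) {
    (length(include) == 0 || any(m %in% include)) && !any(m %in% exclude)
  }, logical(1))
  knowledge[keep, ]
}
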