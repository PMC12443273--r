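# Bilingual (Thai/English) text normalization: language detection,
# tokenization, stopword removal, and normalization. All operations are
# pure functions of (text, language, resource files).

#' Detect the dominant script of a comment
#'
#' Classifies text as `"thai"`, `"english"`, or `"unknown"` by the share of
#' Thai-block codepoints among alphabetic characters. Mixed-script comments
#' get the majority script; text with no alphabetic characters is
#' `"unknown"`.
#'
#' @param text Character vector.
#' @param thai_threshold Fraction of alphabetic characters that must fall in
#'   the Thai Unicode block (U+0E00--U+0E7F) for a `"thai"` call. Default 0.5.
#' @return Character vector of `"thai"`, `"english"`, `"unknown"`.
#' @examples
#' detect_language(c("my mother had lung cancer", "1234 !!"))
#' @export
detect_language <- function(text, thai_threshold = 0.5) {
  vapply(text, function(x) {
    if (is.na(x)) return("unknown")
    chars <- stringi::stri_split_boundaries(x, type = "character")[[1]]
    alpha <- chars[stringi::stri_detect_charclass(chars, "[\\p{L}\\p{M}]")]
    if (length(alpha) == 0) return("unknown")
    thai <- mean(stringi::stri_detect_regex(alpha, "[\\x{0E00}-\\x{0E7F}]"))
    latin <- mean(stringi::stri_detect_regex(alpha, "[\\p{Latin}]"))
    if (thai > thai_threshold) "thai"
    else if (latin > thai_threshold) "english"
    else "unknown"
  }, character(1), USE.NAMES = FALSE)
}

# URLs and emoji pollute keyword matching; strip them before tokenization.
clean_text <- function(text) {
  text <- stringi::stri_replace_all_regex(text, "(https?://|www\\.)\\S+", " ")
  text <- stringi::stri_replace_all_regex(
    text, "[\\x{1F000}-\\x{1FAFF}\\x{2600}-\\x{27BF}\\x{FE0F}\\x{200D}]", " ")
  text
}

thai_dictionary <- function() {
  if (is.null(the$thai_dict)) {
    words <- read_wordlist(ncdl_resource("thai_dictionary.txt"))
    the$thai_dict <- list(words = unique(words),
                          max_len = max(stringi::stri_length(words)))
  }
  the$thai_dict
}

# Longest-match (maximal matching) dictionary segmentation. Runs left to
# right; at each position the longest dictionary word matching the prefix is
# taken. Characters not starting any dictionary word accumulate into a
# single unknown token until the next dictionary hit.
segment_thai <- function(text, dictionary = thai_dictionary()) {
  chars <- stringi::stri_split_boundaries(text, type = "character")[[1]]
  n <- length(chars)
  if (n == 0) return(character(0))
  words <- dictionary$words
  out <- character(0)
  pending <- character(0)  # unknown-character run
  i <- 1
  while (i <= n) {
    if (stringi::stri_detect_regex(chars[i], "^\\s$")) {
      if (length(pending)) { out <- c(out, paste(pending, collapse = "")); pending <- character(0) }
      i <- i + 1
      next
    }
    hit <- 0L
    for (len in seq(min(dictionary$max_len, n - i + 1), 1)) {
      cand <- paste(chars[i:(i + len - 1)], collapse = "")
      if (cand %in% words) { hit <- len; break }
    }
    if (hit > 0L) {
      if (length(pending)) { out <- c(out, paste(pending, collapse = "")); pending <- character(0) }
      out <- c(out, paste(chars[i:(i + hit - 1)], collapse = ""))
      i <- i + hit
    } else {
      pending <- c(pending, chars[i])
      i <- i + 1
    }
  }
  if (length(pending)) out <- c(out, paste(pending, collapse = ""))
  out
}

#' Tokenize a comment
#'
#' Thai text is segmented with a longest-match dictionary segmenter; English
#' and unknown text is lowercased, stripped of punctuation, and split on
#' whitespace. URLs and emoji are removed first. Deterministic.
#'
#' @param text Single string.
#' @param language `"thai"`, `"english"`, or `"unknown"` (see
#'   [detect_language()]).
#' @return Character vector of tokens (possibly empty).
#' @examples
#' tokenize("She was diagnosed, sadly.", "english")
#' @export
tokenize <- function(text, language = detect_language(text)) {
  stopifnot(length(text) == 1)
  language <- match.arg(language, c("thai", "english", "unknown"))
  if (is.na(text)) return(character(0))
  text <- clean_text(text)
  if (language == "thai") {
    toks <- unlist(lapply(
      stringi::stri_split_regex(text, "\\s+")[[1]],
      segment_thai), use.names = FALSE)
    # drop pure punctuation/digit fragments left between Thai words
    toks[stringi::stri_detect_charclass(toks, "[\\p{L}\\p{M}\\p{N}]")]
  } else {
    text <- stringi::stri_trans_tolower(text)
    text <- stringi::stri_replace_all_regex(text, "[^\\p{L}\\p{N}']+", " ")
    text <- stringi::stri_replace_all_regex(text, "(^|\\s)'+|'+(\\s|$)", " ")
    toks <- stringi::stri_split_regex(stringi::stri_trim_both(text), "\\s+")[[1]]
    toks[nzchar(toks)]
  }
}

stopword_set <- function(language) {
  key <- paste0("stopwords_", language)
  if (is.null(the[[key]])) {
    file <- switch(language, english = "stopwords_en.txt", thai = "stopwords_th.txt")
    the[[key]] <- read_wordlist(ncdl_resource(file))
  }
  the[[key]]
}

#' Remove stopwords
#'
#' Order-preserving removal of the language's stopword set. Stopword lists
#' ship as plain-text resources (one token per line) and can be overridden
#' via `stopwords`.
#'
#' @param tokens Character vector of tokens.
#' @param language `"thai"` or `"english"`; `"unknown"` is a no-op with a
#'   warning.
#' @param stopwords Optional custom stopword vector replacing the shipped
#'   list.
#' @return Filtered token vector.
#' @export
remove_stopwords <- function(tokens, language, stopwords = NULL) {
  language <- match.arg(language, c("thai", "english", "unknown"))
  if (language == "unknown" && is.null(stopwords)) {
    warning("no stopword list for language 'unknown'; returning tokens unchanged")
    return(tokens)
  }
  if (is.null(stopwords)) stopwords <- stopword_set(language)
  tokens[!tokens %in% stopwords]
}

lemma_exceptions <- function() {
  if (is.null(the$lemma_exc)) {
    tab <- read.delim(ncdl_resource("lemma_exceptions_en.tsv"),
                      stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    the$lemma_exc <- setNames(tab$lemma, tab$form)
  }
  the$lemma_exc
}

# Rule-and-exception English lemmatizer: irregular forms come from a shipped
# table; regular inflection is handled by light suffix stripping
# (plural -s/-es/-ies, past -ed/-ied, progressive -ing with doubled-consonant
# repair). Unknown forms pass through unchanged.
lemmatize_en <- function(tokens) {
  exc <- lemma_exceptions()
  vapply(tokens, function(w) {
    if (!is.na(exc[w])) return(unname(exc[w]))
    n <- stringi::stri_length(w)
    if (n > 4 && endsWith(w, "ies")) return(paste0(substr(w, 1, n - 3), "y"))
    if (endsWith(w, "sses")) return(substr(w, 1, n - 2))
    if (n > 4 && stringi::stri_detect_regex(w, "(sh|ch|x|z)es$"))
      return(substr(w, 1, n - 2))
    if (n > 3 && endsWith(w, "s") &&
        !stringi::stri_detect_regex(w, "(ss|us|is)$"))
      return(substr(w, 1, n - 1))
    if (n > 4 && endsWith(w, "ied")) return(paste0(substr(w, 1, n - 3), "y"))
    base <- NULL
    if (n > 4 && endsWith(w, "ed")) base <- substr(w, 1, n - 2)
    if (n > 5 && endsWith(w, "ing")) base <- substr(w, 1, n - 3)
    if (!is.null(base)) {
      if (stringi::stri_detect_regex(base, "([bdfgmnprt])\\1$"))
        base <- substr(base, 1, stringi::stri_length(base) - 1)
      return(base)
    }
    w
  }, character(1), USE.NAMES = FALSE)
}

# Thai orthographic normalization: Unicode NFC plus collapsing accidentally
# repeated tone/vowel combining marks (a common typing artifact).
normalize_th <- function(tokens) {
  tokens <- stringi::stri_trans_nfc(tokens)
  stringi::stri_replace_all_regex(tokens, "([\\x{0E31}\\x{0E33}-\\x{0E3A}\\x{0E47}-\\x{0E4E}])\\1+", "$1")
}

#' Normalize tokens
#'
#' English tokens are lemmatized to lowercase base forms; Thai tokens get
#' character-level normalization (NFC, duplicate tone/vowel-mark cleanup).
#' Idempotent and deterministic.
#'
#' @param tokens Character vector of tokens.
#' @param language `"thai"`, `"english"`, or `"unknown"` (left unchanged).
#' @return Character vector, same length as `tokens`.
#' @export
normalize_tokens <- function(tokens, language) {
  language <- match.arg(language, c("thai", "english", "unknown"))
  if (length(tokens) == 0) return(character(0))
  switch(language,
         english = lemmatize_en(stringi::stri_trans_tolower(tokens)),
         thai = normalize_th(tokens),
         unknown = tokens)
}

#' Tokenize a comment table
#'
#' Runs [detect_language()], [tokenize()], [remove_stopwords()] and
#' [normalize_tokens()] over each row of a comment table, producing one
#' tokenized record per comment.
#'
#' @param records Comment table (see [read_comment_table()]).
#' @return A tibble with columns `seq`, `language`, `tokens` (list),
#'   `normalized_tokens` (list: normalized, stopword-removed), `text`
#'   (raw text, kept for substring matching of Thai lexicon terms).
#' @export
tokenize_comments <- function(records) {
  records <- as_comment_table(records)
  lang <- records$language
  toks <- lapply(seq_len(nrow(records)), function(i)
    tokenize(records$text[i], lang[i]))
  norm <- lapply(seq_len(nrow(records)), function(i) {
    tk <- normalize_tokens(toks[[i]], lang[i])
    if (lang[i] == "unknown") tk
    else remove_stopwords(tk, lang[i])
  })
  tibble::tibble(seq = records$seq, language = lang,
                 tokens = toks, normalized_tokens = norm,
                 text = records$text)
}
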