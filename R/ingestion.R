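# Turning saved comment-section HTML or CSV exports into a clean,
# anonymized comment table: parse, deduplicate, drop very short comments,
# replace names with Name(n).

comment_cols <- c("seq", "alias", "text", "likes", "replies", "language")

#' Build a comment table
#'
#' The package's central container: one row per scraped comment with columns
#' `seq` (1-based comment number), `alias`, `text`, `likes`, `replies` and
#' `language`. `seq` is assigned once at scrape/read time and never
#' renumbered, so the anonymized `Name(n)` always refers to the original
#' comment number.
#'
#' @param alias,text Character vectors.
#' @param likes,replies Non-negative integer vectors (recycled from 0).
#' @param seq Positive integers, unique; defaults to document order.
#' @param language Optional language tags; detected from `text` when absent.
#' @return A tibble with the six comment columns.
#' @export
comment_table <- function(alias, text, likes = 0L, replies = 0L,
                          seq = seq_along(text), language = NULL) {
  n <- length(text)
  likes <- rep_len(as.integer(likes), n)
  replies <- rep_len(as.integer(replies), n)
  seq <- as.integer(seq)
  if (anyDuplicated(seq)) stop("comment `seq` numbers must be unique")
  if (any(seq < 1L)) stop("comment `seq` numbers must be positive")
  if (any(likes < 0L, na.rm = TRUE) || any(replies < 0L, na.rm = TRUE))
    stop("`likes` and `replies` must be non-negative")
  if (is.null(language)) language <- detect_language(text)
  tibble::tibble(seq = seq, alias = as.character(rep_len(alias, n)),
                 text = as.character(text), likes = likes,
                 replies = replies, language = language)
}

as_comment_table <- function(x) {
  if (!is.data.frame(x) || !all(comment_cols %in% names(x)))
    stop("expected a comment table with columns ",
         paste(comment_cols, collapse = ", "))
  tibble::as_tibble(x)[, comment_cols]
}

#' Selector configuration for saved comment-section HTML
#'
#' Describes, for one platform, the CSS selector of the repeated comment
#' container element and the selectors (inside each container) of the four
#' scraped fields: name, comment, likes, replies.
#'
#' @param platform Platform identifier (e.g. `"facebook"`).
#' @param comment_container_selector CSS selector matching one element per
#'   comment.
#' @param field_selectors Named list/character vector with entries `name`,
#'   `comment`, `likes`, `replies`; each a non-empty CSS selector.
#' @return A `selector_config` object.
#' @export
selector_config <- function(platform, comment_container_selector, field_selectors) {
  required <- c("name", "comment", "likes", "replies")
  field_selectors <- as.list(field_selectors)
  missing <- setdiff(required, names(field_selectors))
  if (length(missing))
    stop("field_selectors missing entries: ", paste(missing, collapse = ", "))
  sels <- c(comment_container_selector, unlist(field_selectors[required]))
  if (any(!nzchar(trimws(sels))) || any(is.na(sels)))
    stop("selectors must be non-empty strings")
  structure(list(platform = platform,
                 comment_container_selector = comment_container_selector,
                 field_selectors = field_selectors[required]),
            class = "selector_config")
}

#' Load a per-platform selector configuration from YAML
#'
#' @param path YAML file with one block per platform (see the shipped
#'   `selectors.yaml` for the schema). Defaults to the packaged file.
#' @param platform Which platform block to load.
#' @return A [selector_config()].
#' @export
load_selector_config <- function(platform, path = ncdl_resource("selectors.yaml")) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg[[platform]]))
    stop("no selector block for platform '", platform, "' in ", path)
  block <- cfg[[platform]]
  selector_config(platform, block$comment_container_selector, block$field_selectors)
}

# "1.2K" -> 1200, "3M" -> 3e6; platforms render counts this way.
parse_count <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(0L)
    v <- trimws(v)
    if (!nzchar(v)) return(0L)
    m <- stringi::stri_match_first_regex(v, "^([0-9]+(?:[.][0-9]+)?)\\s*([KkMm]?)$")
    if (is.na(m[1, 1])) stop("cannot parse count '", v, "'")
    mult <- switch(tolower(m[1, 3]), k = 1e3, m = 1e6, 1)
    as.integer(round(as.numeric(m[1, 2]) * mult))
  }, integer(1), USE.NAMES = FALSE)
}

#' Parse comments out of saved HTML
#'
#' Extracts one comment record per container element matched by
#' `config$comment_container_selector`, populating the four fields through
#' the per-field selectors. A missing likes/replies element defaults to 0;
#' `seq` follows document order starting at 1. Zero matched containers is a
#' warning (empty table), not an error.
#'
#' @param html HTML document as a string (or an `xml_document`).
#' @param config A [selector_config()].
#' @return A comment table (see [comment_table()]).
#' @export
parse_comments_html <- function(html, config) {
  stopifnot(inherits(config, "selector_config"))
  doc <- tryCatch(
    if (inherits(html, "xml_document")) html else xml2::read_html(html),
    error = function(e) stop("unparseable HTML document: ", conditionMessage(e)))
  containers <- tryCatch(
    rvest::html_elements(doc, css = config$comment_container_selector),
    error = function(e) stop("invalid comment container selector '",
                             config$comment_container_selector, "'"))
  if (length(containers) == 0) {
    warning("selector '", config$comment_container_selector,
            "' matched no comment containers")
    return(comment_table(character(0), character(0)))
  }
  field <- function(node, sel, what) {
    el <- tryCatch(rvest::html_elements(node, css = sel),
                   error = function(e) stop("invalid selector for field '",
                                            what, "': '", sel, "'"))
    if (length(el) == 0) NA_character_
    else trimws(rvest::html_text2(el[[1]]))
  }
  fs <- config$field_selectors
  rows <- lapply(containers, function(node) {
    list(alias = field(node, fs$name, "name"),
         text = field(node, fs$comment, "comment"),
         likes = field(node, fs$likes, "likes"),
         replies = field(node, fs$replies, "replies"))
  })
  comment_table(
    alias = vapply(rows, `[[`, character(1), "alias"),
    text = vapply(rows, function(r) ifelse(is.na(r$text), "", r$text), character(1)),
    likes = parse_count(vapply(rows, `[[`, character(1), "likes")),
    replies = parse_count(vapply(rows, `[[`, character(1), "replies")))
}

#' Read / write a four-column comment CSV
#'
#' The interchange format is UTF-8 CSV with header
#' `name,comments,likes,replies` (columns matched by name, not position).
#' `read_comment_table()` assigns `seq` in file order and detects each
#' comment's language; `write_comment_table()` emits the same four columns,
#' so write-then-read reproduces the records field for field.
#'
#' @param path CSV file path.
#' @param records A comment table.
#' @return `read_comment_table()`: a comment table. `write_comment_table()`:
#'   `path`, invisibly.
#' @export
read_comment_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("name", "comments", "likes", "replies")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("comment CSV is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("likes", "replies")) {
    bad <- which(!stringi::stri_detect_regex(
      trimws(raw[[col]]), "^[0-9]+(?:[.][0-9]+)?\\s*[KkMm]?$") &
        !is.na(raw[[col]]) & nzchar(trimws(raw[[col]])))
    if (length(bad))
      stop("malformed integer in column '", col, "' at data row ", bad[1],
           ": '", raw[[col]][bad[1]], "'")
  }
  comment_table(alias = raw$name, text = raw$comments,
                likes = parse_count(raw$likes), replies = parse_count(raw$replies))
}

#' @rdname read_comment_table
#' @export
write_comment_table <- function(records, path) {
  records <- as_comment_table(records)
  out <- tibble::tibble(name = records$alias, comments = records$text,
                        likes = records$likes, replies = records$replies)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# Duplicate = identical text after trimming outer whitespace and collapsing
# internal whitespace runs (case-sensitive).
normalize_for_dedup <- function(text) {
  stringi::stri_replace_all_regex(stringi::stri_trim_both(text), "\\s+", " ")
}

#' Remove duplicate comments
#'
#' Keeps the first occurrence of each normalized text (outer whitespace
#' trimmed, internal runs collapsed; case-sensitive) and drops later copies,
#' preserving order. Idempotent.
#'
#' @param records A comment table.
#' @return The deduplicated comment table (a subsequence of the input).
#' @export
deduplicate <- function(records) {
  records <- as_comment_table(records)
  records[!duplicated(normalize_for_dedup(records$text)), ]
}

#' Drop very short comments
#'
#' Removes comments whose token count is at most `max_tokens` (default 5,
#' i.e. comments of five words or fewer go; six or more stay). Thai
#' comments are counted in dictionary-segmentation tokens, English in
#' whitespace tokens; unknown-language comments use the English rule with a
#' warning.
#'
#' @param records A comment table.
#' @param max_tokens Comments with `<= max_tokens` tokens are removed.
#' @param tokenizer Function `(text, language) -> tokens`; defaults to
#'   [tokenize()].
#' @return The filtered comment table.
#' @export
filter_short <- function(records, max_tokens = 5L, tokenizer = tokenize) {
  records <- as_comment_table(records)
  if (nrow(records) == 0) return(records)
  if (any(records$language == "unknown"))
    warning("unknown-language comments counted with whitespace tokens")
  counts <- vapply(seq_len(nrow(records)), function(i)
    length(tokenizer(records$text[i], records$language[i])), integer(1))
  records[counts > max_tokens, ]
}

#' Anonymize commenter names
#'
#' Replaces every alias with the literal token `Name(n)` where `n` is the
#' comment's original sequence number. Idempotent; after this step no
#' original alias string remains in the table.
#'
#' @param records A comment table.
#' @return The comment table with anonymized aliases.
#' @export
anonymize <- function(records) {
  records <- as_comment_table(records)
  records$alias <- sprintf("Name(%d)", records$seq)
  records
}

#' Full preprocessing pipeline
#'
#' Composes the three cleaning rules in order: [deduplicate()], then
#' [filter_short()], then [anonymize()], logging the number of records
#' removed at each stage. `seq` is not renumbered.
#'
#' @inheritParams filter_short
#' @param quiet Suppress the per-stage log line.
#' @return The cleaned comment table.
#' @export
preprocess_pipeline <- function(records, max_tokens = 5L, tokenizer = tokenize,
                                quiet = FALSE) {
  records <- as_comment_table(records)
  n0 <- nrow(records)
  deduped <- deduplicate(records)
  kept <- suppressWarnings(filter_short(deduped, max_tokens, tokenizer))
  out <- anonymize(kept)
  if (!quiet)
    message(sprintf("preprocess: %d comments in, %d duplicates removed, %d short removed, %d out",
                    n0, n0 - nrow(deduped), nrow(deduped) - nrow(kept), nrow(out)))
  out
}
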