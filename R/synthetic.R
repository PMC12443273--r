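# Seeded generators for every input the pipeline consumes: bilingual
# comment corpora with recorded ground truth (class labels, planted lexicon
# mentions, duplicates, short comments), fixture comment-section HTML, and
# ordinal survey responses. Every generator is a pure function of its
# spec + seed.

#' Corpus generation specification
#'
#' Defaults describe a plausible NCD comment thread: a roughly even
#' Thai/English mix, comments dominated by experience sharing with a small
#' inquiring minority, most substantive comments naming a disease, and
#' modest duplicate and very-short-comment contamination.
#'
#' @param n_comments Total comments to generate (including duplicates and
#'   shorts).
#' @param language_mix Probability a comment is Thai (rest English).
#' @param class_mixture Named 3-simplex over
#'   `sharing_experience`/`inquiring`/`non_informative`.
#' @param lexicon Lexicon whose terms are planted.
#' @param planted_mentions Named rates in [0, 1]: probability a
#'   sharing/inquiring comment carries a term of each content category
#'   (non-informative comments never carry lexicon terms).
#' @param duplicate_rate,short_rate Fractions of `n_comments` that are
#'   exact duplicates of earlier comments / at most five tokens long.
#' @param seed Integer seed.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(n_comments = 100L, language_mix = 0.5,
                        class_mixture = c(sharing_experience = 0.55,
                                          inquiring = 0.15,
                                          non_informative = 0.30),
                        lexicon = load_lexicon(),
                        planted_mentions = c(disease = 0.8, symptom = 0.5,
                                             treatment = 0.4,
                                             behavior_cause = 0.3),
                        duplicate_rate = 0.05, short_rate = 0.10,
                        seed = 1L) {
  stopifnot(n_comments >= 1, language_mix >= 0, language_mix <= 1,
            all(planted_mentions >= 0), all(planted_mentions <= 1),
            duplicate_rate >= 0, duplicate_rate < 1,
            short_rate >= 0, short_rate < 1)
  if (abs(sum(class_mixture) - 1) > 1e-8 || any(class_mixture < 0) ||
      !setequal(names(class_mixture), class_labels))
    stop("class_mixture must be a named non-negative 3-simplex over the class labels")
  structure(list(n_comments = as.integer(n_comments),
                 language_mix = language_mix,
                 class_mixture = class_mixture[class_labels],
                 lexicon = lexicon, planted_mentions = planted_mentions,
                 duplicate_rate = duplicate_rate, short_rate = short_rate,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

alias_bank <- c("somchai", "malee", "anong", "prasert", "john", "mary",
                "peter", "nok", "lek", "dave")

short_banks <- list(
  english = c("thanks", "so sad", "take care", "oh no", "get well soon"),
  thai = c("สู้ๆนะ",          # su-su na
           "เสียใจด้วย",  # sia jai duai
           "ขอบคุณ"))          # khop khun

#' Generate a synthetic bilingual comment corpus with ground truth
#'
#' Comments are built from class-specific templates: inquiring templates
#' carry interrogative cues, sharing templates carry first-person or kin
#' perspective cues plus planted lexicon terms, and non-informative
#' templates carry neither cues nor lexicon terms. Exact duplicates of
#' earlier comments and at-most-five-token comments are injected at the
#' spec's rates. The returned ground truth records, for every comment, the
#' planted class label, mentions, expected gender/source, duplicate links
#' and short flags, so each pipeline stage is checkable offline.
#'
#' @param spec A [corpus_spec()].
#' @return List with `records` (a comment table) and `ground_truth` (tibble
#'   with columns `seq`, `language`, `label`, `gender`, `source`,
#'   `diseases`, `symptoms`, `treatments`, `behaviors` (list-columns),
#'   `is_short`, `duplicate_of`).
#' @export
generate_corpus <- function(spec = corpus_spec()) {
  stopifnot(inherits(spec, "corpus_spec"))
  withr::with_seed(spec$seed, generate_corpus_impl(spec))
}

generate_corpus_impl <- function(spec) {
  n <- spec$n_comments
  n_dup <- round(spec$duplicate_rate * n)
  n_short <- round(spec$short_rate * n)
  n_base <- n - n_dup - n_short
  if (n_base < 1) stop("duplicate_rate + short_rate leave no base comments")

  lex <- spec$lexicon
  term_of <- function(category, language) {
    entries <- lex[[category]]
    i <- sample.int(nrow(entries), 1)
    th <- entries$th[[i]]
    en_toks <- entries$en[[i]]
    if (language == "thai" && length(th)) {
      list(label = entries$label[i], term = th[[sample.int(length(th), 1)]])
    } else {
      toks <- en_toks[[sample.int(length(en_toks), 1)]]
      list(label = entries$label[i], term = paste(toks, collapse = " "))
    }
  }

  seen <- character(0)
  rows <- vector("list", n)
  truth <- vector("list", n)
  classes <- sample(class_labels, n_base, replace = TRUE,
                    prob = spec$class_mixture)
  langs <- ifelse(runif(n_base) < spec$language_mix, "thai", "english")

  make_base <- function(i) {
    label <- classes[i]; language <- langs[i]
    planted <- list(disease = NULL, symptom = NULL, treatment = NULL,
                    behavior_cause = NULL)
    gender <- "unknown"; source <- "general"
    if (label != "non_informative") {
      for (cat in names(spec$planted_mentions)) {
        if (runif(1) < spec$planted_mentions[[cat]])
          planted[[cat]] <- term_of(cat, language)
      }
    }
    if (label == "inquiring") {
      # questions about a disease/treatment; no symptom/behavior clauses
      planted$symptom <- NULL; planted$behavior_cause <- NULL
      text <- inquiring_text(language, planted)
    } else if (label == "sharing_experience") {
      persp <- sample(c("self", "family"), 1, prob = c(0.6, 0.4))
      out <- sharing_text(language, planted, persp)
      text <- out$text; gender <- out$gender; source <- out$source
    } else {
      text <- non_informative_text(language)
    }
    list(text = text, label = label, language = language, gender = gender,
         source = source, planted = planted)
  }

  label_of <- function(x) if (is.null(x)) character(0) else x$label
  for (i in seq_len(n_base)) {
    b <- make_base(i)
    # guarantee distinct raw text so planted duplicate counts stay exact
    while (b$text %in% seen)
      b$text <- paste0(b$text, if (b$language == "thai") "นะ" else " indeed")
    seen <- c(seen, b$text)
    rows[[i]] <- list(text = b$text, language = b$language)
    truth[[i]] <- tibble::tibble(
      seq = i, language = b$language, label = b$label, gender = b$gender,
      source = b$source,
      diseases = list(label_of(b$planted$disease)),
      symptoms = list(label_of(b$planted$symptom)),
      treatments = list(label_of(b$planted$treatment)),
      behaviors = list(label_of(b$planted$behavior_cause)),
      is_short = FALSE, duplicate_of = NA_integer_)
  }
  for (j in seq_len(n_short)) {
    i <- n_base + j
    language <- if (runif(1) < spec$language_mix) "thai" else "english"
    base <- sample(short_banks[[language]], 1)
    text <- paste(base, j)  # unique, still <= 5 tokens
    rows[[i]] <- list(text = text, language = language)
    truth[[i]] <- tibble::tibble(
      seq = i, language = language, label = "non_informative",
      gender = "unknown", source = "general",
      diseases = list(character(0)), symptoms = list(character(0)),
      treatments = list(character(0)), behaviors = list(character(0)),
      is_short = TRUE, duplicate_of = NA_integer_)
  }
  for (j in seq_len(n_dup)) {
    i <- n_base + n_short + j
    src <- sample.int(n_base, 1)
    t0 <- truth[[src]]
    rows[[i]] <- rows[[src]]
    truth[[i]] <- tibble::tibble(
      seq = i, language = t0$language, label = t0$label, gender = t0$gender,
      source = t0$source, diseases = t0$diseases, symptoms = t0$symptoms,
      treatments = t0$treatments, behaviors = t0$behaviors,
      is_short = FALSE, duplicate_of = src)
  }
  ord <- sample.int(n)  # shuffle, then renumber in document order
  rows <- rows[ord]
  truth <- dplyr::bind_rows(truth[ord])
  truth$seq <- seq_len(n)
  # recompute duplicate links in document order: within each group of
  # identical texts, the first occurrence is the original
  texts <- vapply(rows, `[[`, character(1), "text")
  first_pos <- match(texts, texts)
  truth$duplicate_of <- ifelse(first_pos < seq_len(n), first_pos, NA_integer_)
  records <- comment_table(
    alias = paste0(sample(alias_bank, n, replace = TRUE), seq_len(n)),
    text = vapply(rows, `[[`, character(1), "text"),
    likes = sample(0:50, n, replace = TRUE),
    replies = sample(0:10, n, replace = TRUE),
    language = vapply(rows, `[[`, character(1), "language"))
  list(records = records, ground_truth = truth)
}

sharing_text <- function(language, planted, perspective) {
  d <- planted$disease; s <- planted$symptom
  tr <- planted$treatment; b <- planted$behavior_cause
  if (language == "english") {
    if (perspective == "family") {
      kin <- sample(c(male = "husband", female = "wife"), 1)
      gender <- names(kin); source <- "family_member"
      subject <- paste0("My ", kin)
    } else {
      gender <- "unknown"; source <- "self"
      subject <- "I"
    }
    text <- if (is.null(d))
      paste(subject, "dealt with this illness for a very long time")
    else paste(subject, "was diagnosed with", d$term, "a few years ago")
    if (!is.null(s)) text <- paste(text, "and the", s$term, "kept getting worse")
    if (!is.null(tr)) text <- paste(text, "so the doctor started", tr$term, "soon after")
    if (!is.null(b)) text <- paste(text, "probably because of all those", b$term, "habits")
  } else {
    if (perspective == "family") {
      kin <- sample(c(male = "สามี",      # husband
                      female = "ภรรยา"), 1)  # wife
      gender <- names(kin); source <- "family_member"
      subject <- kin[[1]]
    } else {
      pron <- sample(c(male = "ผม",                  # phom
                       female = "ดิฉัน"), 1)  # dichan
      gender <- names(pron); source <- "self"
      subject <- pron[[1]]
    }
    text <- if (is.null(d))
      paste0(subject, "เป็นโรคนี้มานานแล้ว")      # pen rok nee ma nan laew
    else paste0(subject, "เป็น", d$term,
                "มาสองปีแล้ว")             # ma song pee laew
    if (!is.null(s)) text <- paste0(text, "รู้สึก", s$term,
                                    "ทุกวัน")                       # rusuek ... thuk wan
    if (!is.null(tr)) text <- paste0(text, "หมอให้", tr$term)      # mo hai ...
    if (!is.null(b)) text <- paste0(text, "เพราะ", b$term,
                                    "มานาน")                             # phro ... ma nan
  }
  list(text = text, gender = gender, source = source)
}

inquiring_text <- function(language, planted) {
  d <- planted$disease; tr <- planted$treatment
  if (language == "english") {
    if (!is.null(d) && !is.null(tr))
      paste("Does anyone know whether", tr$term, "works well against", d$term, "these days")
    else if (!is.null(d))
      paste("What are the early warning signs of", d$term, "that people usually notice first")
    else if (!is.null(tr))
      paste("How long does it usually take to recover after", tr$term, "treatment")
    else "What should someone ask the doctor about during a first checkup visit"
  } else {
    th <- function(x) x$term
    if (!is.null(d) && !is.null(tr))
      paste0("อยากทราบว่า", th(tr),
             "รักษา", th(d), "ได้ไหม")    # yak sap wa ... raksa ... dai mai
    else if (!is.null(d))
      paste0(th(d), "มีอาการอะไร",
             "ต้องตรวจอะไร")          # mee akan arai tong truat arai
    else if (!is.null(tr))
      paste0("อยากทราบว่า", th(tr),
             "ต้องรอนานไหม")          # tong ro nan mai
    else paste0("ใครรู้บ้างว่า",
                "ต้องถามหมออะไร") # krai ru bang wa tong tham mo arai
  }
}

non_informative_banks <- list(
  english = c("thank you for this really useful post today",
              "good luck to everyone out there reading along",
              "such an informative page keep it up please",
              "wishing all of you strength and patience always"),
  thai = c("ขอบคุณมากนะที่เล่าให้ฟัง",  # khop khun mak na thi lao hai fang
           "เป็นข้อมูลที่ดีมากเลยขอบคุณนะ",  # pen khomun thi dee mak loei khop khun na
           "ขอให้ทุกคนดูแลสุขภาพกันด้วยนะ")) # kho hai thuk khon du lae sukkhaphap kan duai na

non_informative_text <- function(language) {
  sample(non_informative_banks[[language]], 1)
}

escape_html <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# ".class" or "tag.class" -> c(tag, class); only the simple selector forms
# the shipped configs use can be inverted into fixture markup
invert_selector <- function(sel, default_tag = "div") {
  m <- stringi::stri_match_first_regex(trimws(sel), "^([a-zA-Z0-9]*)\\.([A-Za-z0-9_-]+)$")
  if (is.na(m[1, 1]))
    stop("cannot build fixture markup for selector '", sel,
         "'; use '.class' or 'tag.class'")
  tag <- if (nzchar(m[1, 2])) m[1, 2] else default_tag
  c(tag = tag, class = m[1, 3])
}

#' Generate fixture comment-section HTML
#'
#' Builds an HTML page whose structure matches a [selector_config()] with
#' simple `tag.class` selectors, such that
#' `parse_comments_html(html, config)` reproduces the records'
#' alias/text/likes/replies. Useful as a stand-in for saved platform
#' snapshots.
#'
#' @param records A comment table.
#' @param config A [selector_config()] with `.class`/`tag.class` selectors.
#' @param drop_fields Optional character vector of field names (e.g.
#'   `"likes"`) whose elements are omitted from every comment block, to
#'   exercise the parser's defaults.
#' @return A single HTML string.
#' @export
generate_fixture_html <- function(records, config = load_selector_config("facebook"),
                                  drop_fields = character(0)) {
  records <- as_comment_table(records)
  cont <- invert_selector(config$comment_container_selector)
  fields <- lapply(config$field_selectors, invert_selector, default_tag = "span")
  block <- function(i) {
    vals <- c(name = records$alias[i], comment = records$text[i],
              likes = as.character(records$likes[i]),
              replies = as.character(records$replies[i]))
    inner <- vapply(setdiff(names(fields), drop_fields), function(f) {
      sprintf('    <%s class="%s">%s</%s>', fields[[f]]["tag"],
              fields[[f]]["class"], escape_html(vals[[f]]), fields[[f]]["tag"])
    }, character(1))
    sprintf('  <%s class="%s">\n%s\n  </%s>', cont["tag"], cont["class"],
            paste(inner, collapse = "\n"), cont["tag"])
  }
  blocks <- if (nrow(records)) vapply(seq_len(nrow(records)), block, character(1))
            else character(0)
  paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"></head><body>\n",
         "<div class=\"comment-section\">\n",
         paste(blocks, collapse = "\n"),
         "\n</div>\n</body></html>\n")
}

#' Generate two ordinal Likert samples
#'
#' Draws two seeded 1-5 ordinal samples from a discretized logistic latent
#' scale. Group 2's latent location is shifted down by `shift`, so group 2
#' is stochastically dominated by group 1; at `shift = 0` the groups are
#' exchangeable.
#'
#' @param n_per_group Sample size per group.
#' @param shift Non-negative latent location shift.
#' @param seed Integer seed.
#' @param location,scale Latent logistic parameters for group 1.
#' @return List with integer vectors `group1`, `group2`.
#' @export
generate_likert_responses <- function(n_per_group, shift = 0, seed = 1L,
                                      location = 3.5, scale = 0.9) {
  stopifnot(shift >= 0, n_per_group >= 1)
  withr::with_seed(seed, {
    draw <- function(loc) {
      x <- round(stats::rlogis(n_per_group, location = loc, scale = scale))
      as.integer(pmin(pmax(x, 1L), 5L))
    }
    list(group1 = draw(location), group2 = draw(location - shift))
  })
}
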