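test_that("the starter lexicon ships the four NCD disease groups and validates", {
  lex <- load_lexicon()
  expect_true(all(c("cancer", "heart_disease", "diabetes",
                    "chronic_respiratory_disease") %in% lex$disease$label))
  expect_gte(nrow(lex$disease), 4)
})

test_that("malformed lexicon files are rejected with named errors", {
  dup <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("disease:",
               "  - {label: cancer, en: [cancer]}",
               "  - {label: cancer, en: [tumor]}"), dup)
  expect_error(load_lexicon(dup), "duplicate label.*cancer")
  emptycat <- withr::local_tempfile(fileext = ".yaml")
  writeLines("disease: []", emptycat)
  expect_error(load_lexicon(emptycat), "empty")
  emptyterms <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("disease:", "  - {label: cancer, en: [], th: []}"), emptyterms)
  expect_error(load_lexicon(emptyterms), "empty term list")
  badcat <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("colour:", "  - {label: x, en: [y]}"), badcat)
  expect_error(load_lexicon(badcat), "unknown lexicon categor")
})

test_that("category matching finds terms as token subsequences / Thai substrings", {
  lex <- tiny_lexicon()
  tk <- tokenize_comments(make_comments(c(
    "my mother survived lung cancer last year",
    "nothing medical in this sentence at all",
    "the tumor was found early but the diabetes persisted",
    "แม่เป็นมะเร็งมานานแล้ว")))
  expect_equal(match_category(tk[1, ], lex, "disease"), "cancer")
  expect_equal(match_category(tk[2, ], lex, "disease"), character(0))
  # two entries matched, occurrence order
  expect_equal(match_category(tk[3, ], lex, "disease"), c("cancer", "diabetes"))
  expect_equal(match_category(tk[4, ], lex, "disease"), "cancer")
})

test_that("multi-word English terms match as contiguous subsequences only", {
  lex <- load_lexicon()
  tk <- tokenize_comments(make_comments(c(
    "grandpa was treated for heart disease recently",
    "a disease of the heart worries him greatly")))  # reversed order
  expect_true("heart_disease" %in% match_category(tk[1, ], lex, "disease"))
  expect_false("heart_disease" %in% match_category(tk[2, ], lex, "disease"))
})

test_that("matching agrees with a brute-force term-scan oracle on synthetic corpora", {
  lex <- load_lexicon()
  out <- generate_corpus(corpus_spec(n_comments = 120, seed = 17))
  tk <- tokenize_comments(out$records)
  for (i in seq_len(nrow(tk))) {
    for (cat in c("disease", "symptom", "treatment", "behavior_cause",
                  "gender_cue", "source_cue")) {
      expect_equal(sort(match_category(tk[i, ], lex, cat)),
                   oracle_match_category(tk[i, ], lex, cat),
                   info = paste("seq", tk$seq[i], cat))
    }
  }
})

test_that("lexicon monotonicity: adding a term never shrinks the matched set", {
  base <- tiny_lexicon()
  grown <- base
  grown$disease$en[[2]] <- c(grown$disease$en[[2]], list("sugar"))
  tk <- tokenize_comments(make_comments(c(
    "the doctor mentioned sugar and tumor problems",
    "completely unrelated sentence with no terms")))
  for (i in 1:2) {
    m0 <- match_category(tk[i, ], base, "disease")
    m1 <- match_category(tk[i, ], grown, "disease")
    expect_true(all(m0 %in% m1))
  }
})

test_that("variable extraction applies the cue precedence and conflict rules", {
  lex <- load_lexicon()
  tk <- tokenize_comments(make_comments(c(
    "my mother survived cancer and recovered fully",       # kin cue
    "plain sentence without any cues at all",
    "his wife said she felt tired after chemo",            # male + female cues
    "I was diagnosed with diabetes last year")))           # self cue
  k1 <- extract_variables(tk[1, ], lex)
  expect_equal(k1$source, "family_member")
  k2 <- extract_variables(tk[2, ], lex)
  expect_equal(k2$gender, "unknown")
  expect_equal(k2$source, "general")
  expect_equal(k2$diseases[[1]], character(0))
  k3 <- extract_variables(tk[3, ], lex)
  expect_equal(k3$gender, "unknown")    # conflicting cues
  k4 <- extract_variables(tk[4, ], lex)
  expect_equal(k4$source, "self")
  expect_equal(k4$diseases[[1]], "diabetes")
  expect_true(is.na(k4$category))       # left unset until classification
})

test_that("word frequencies count normalized stopword-free tokens with lexicographic ties", {
  tk <- tokenize_comments(make_comments(c(
    "cancer stories cancer support cancer",
    "cancer and hope", "quiet zebra")))
  wf <- word_frequency(tk, top_k = Inf)
  expect_equal(wf$count[wf$token == "cancer"], 4L)
  expect_equal(wf$count[wf$token == "hope"], 1L)
  singles <- wf$token[wf$count == 1]
  expect_equal(singles, sort(singles))  # ties broken lexicographically
  # conservation: counts sum to the total retained token count
  expect_equal(sum(wf$count), length(unlist(tk$normalized_tokens)))
  expect_equal(nrow(word_frequency(tk, top_k = 2)), 2)
  empty <- tokenize_comments(make_comments(character(0)))
  expect_equal(nrow(word_frequency(empty, 5)), 0)
})

test_that("include/exclude selection follows the survival rule and stays a subset", {
  lex <- tiny_lexicon()
  tk <- tokenize_comments(make_comments(c(
    "cancer mentioned here today", "diabetes mentioned here today",
    "both cancer and diabetes appear", "no disease at all here",
    "feeling tired all the time")))
  kn <- extract_knowledge(tk, lex)
  expect_equal(adjust_selection(kn)$seq, kn$seq)  # no-op filters
  inc <- adjust_selection(kn, include = "diabetes")
  expect_equal(inc$seq, c(2L, 3L))
  exc <- adjust_selection(kn, exclude = "cancer")
  expect_equal(exc$seq, c(2L, 4L, 5L))
  both <- adjust_selection(kn, include = "fatigue", exclude = "cancer")
  expect_equal(both$seq, 5L)
  expect_error(adjust_selection(kn, include = "cancer", exclude = "cancer"),
               "both included and excluded")
  # idempotence and subset property
  expect_equal(adjust_selection(inc, include = "diabetes"), inc)
  expect_true(all(exc$seq %in% kn$seq))
})
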