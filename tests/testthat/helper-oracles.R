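# Independent oracles used across test files. Each deliberately takes a
# different computational route from the implementation it checks.

# U statistic by direct pairwise counting: #(x > y) + 0.5 * #(x == y)
oracle_u_pairwise <- function(g1, g2) {
  u <- 0
  for (x in g1) for (y in g2) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# Exact two-sided Mann-Whitney p by bitmask enumeration of every subset of
# the pooled positions of size n1 (the implementation uses combn instead).
oracle_mwu_exact <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2); N <- n1 + n2
  r <- rank(c(g1, g2))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  u_all <- numeric(0)
  for (mask in 0:(2^N - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(N - 1))) > 0)
    if (length(idx) != n1) next
    u_all <- c(u_all, sum(r[idx]) - n1 * (n1 + 1) / 2)
  }
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Brute-force lexicon scan: for every entry and every term, test occurrence
# directly (token window scan for English terms, substring for Thai).
oracle_match_category <- function(tokenized_row, lexicon, category) {
  entries <- lexicon[[category]]
  toks <- if (category %in% c("gender_cue", "source_cue")) {
    normalize_tokens(unlist(tokenized_row$tokens), tokenized_row$language)
  } else unlist(tokenized_row$normalized_tokens)
  hit <- logical(nrow(entries))
  for (i in seq_len(nrow(entries))) {
    for (term in entries$en[[i]]) {
      k <- length(term)
      if (k >= 1 && length(toks) >= k) {
        for (s in 1:(length(toks) - k + 1)) {
          if (identical(toks[s:(s + k - 1)], term)) hit[i] <- TRUE
        }
      }
    }
    for (term in entries$th[[i]]) {
      if (grepl(term, tokenized_row$text, fixed = TRUE)) hit[i] <- TRUE
    }
  }
  sort(entries$label[hit])
}

# Exhaustive cosine ranking, plainly coded
oracle_cosine_ranking <- function(vectors, query, source_seq) {
  sims <- numeric(nrow(vectors))
  for (i in seq_len(nrow(vectors))) {
    v <- vectors[i, ]
    d <- sqrt(sum(v^2)) * sqrt(sum(query^2))
    sims[i] <- if (d > 0) sum(v * query) / d else 0
  }
  source_seq[order(-sims, source_seq)]
}

make_comments <- function(texts, ...) {
  comment_table(alias = paste0("user", seq_along(texts)), text = texts, ...)
}

# tiny two-category lexicon written to a temp YAML file
tiny_lexicon <- function() {
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  writeLines(c(
    "disease:",
    "  - label: cancer",
    "    en: [cancer, tumor]",
    "    th: [มะเร็ง]",
    "  - label: diabetes",
    "    en: [diabetes]",
    "    th: [เบาหวาน]",
    "symptom:",
    "  - label: fatigue",
    "    en: [tired, fatigue]",
    "    th: [เหนื่อย]"), path)
  load_lexicon(path)
}
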