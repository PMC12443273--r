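# Retrieval-augmented summarization: embed retained comments into a vector
# index, retrieve the most similar comments to the approach's question, and
# render one of the two fixed prompt templates for a pluggable
# text-generation backend. Tests run against deterministic offline
# backends; no network access is ever required.

summary_questions <- c(
  general = "Can you summarize the comments? What are the characteristics of the comments?",
  medical_focus = paste("Can you summarize the comments? What are the diseases?",
                        "What are the symptoms of the disease?",
                        "And other interesting information?"))

# deterministic polynomial rolling hash over UTF-8 bytes; stays well below
# 2^53 so double arithmetic is exact on every platform
str_hash <- function(s, mod, salt = 0) {
  bytes <- as.integer(charToRaw(s))
  h <- salt
  for (b in bytes) h <- (h * 131 + b) %% mod
  h
}

#' Embedding backends
#'
#' `hash_embed_backend()` is the default offline embedder: each comment's
#' normalized tokens are feature-hashed into a `dim`-dimensional vector
#' (signed hashing, two independent hash streams derived from `seed`) and
#' L2-normalized. Identical texts always map to identical vectors.
#' `external` embedding services plug in as any function
#' `(texts) -> numeric matrix`; none is bundled.
#'
#' @param dim Embedding dimension (default 256).
#' @param seed Integer salt for the hash streams.
#' @return A function `(texts) -> matrix` with one row per text.
#' @export
hash_embed_backend <- function(dim = 256L, seed = 1L) {
  dim <- as.integer(dim)
  force(seed)
  function(texts) {
    out <- matrix(0, nrow = length(texts), ncol = dim)
    for (i in seq_along(texts)) {
      lang <- detect_language(texts[i])
      toks <- normalize_tokens(tokenize(texts[i], lang), lang)
      for (tk in toks) {
        j <- str_hash(tk, 268435399, salt = seed) %% dim + 1
        sgn <- if (str_hash(tk, 536870909, salt = seed + 1) %% 2 == 0) 1 else -1
        out[i, j] <- out[i, j] + sgn
      }
      nrm <- sqrt(sum(out[i, ]^2))
      if (nrm > 0) out[i, ] <- out[i, ] / nrm
    }
    out
  }
}

#' Embed comment texts
#'
#' @param texts Character vector.
#' @param backend An embedding backend function (see
#'   [hash_embed_backend()]).
#' @return Numeric matrix, one row per text; all rows share one dimension
#'   and contain only finite values.
#' @export
embed_texts <- function(texts, backend = hash_embed_backend()) {
  m <- backend(texts)
  if (!is.matrix(m) || nrow(m) != length(texts))
    stop("embedding backend must return one row per text")
  if (any(!is.finite(m))) stop("embedding backend produced non-finite values")
  m
}

#' Build a vector index over comments
#'
#' @param records A comment table (the retained comments).
#' @param backend Embedding backend.
#' @return A `vector_index`: embedding matrix plus the source `seq` of each
#'   row and the stored texts.
#' @export
build_index <- function(records, backend = hash_embed_backend()) {
  records <- as_comment_table(records)
  if (anyDuplicated(records$seq)) stop("source_seq must be unique in an index")
  vectors <- embed_texts(records$text, backend)
  structure(list(vectors = vectors, source_seq = records$seq,
                 texts = records$text, dimension = ncol(vectors)),
            class = "vector_index")
}

cosine_to_query <- function(vectors, query) {
  qn <- sqrt(sum(query^2))
  vn <- sqrt(rowSums(vectors^2))
  num <- as.numeric(vectors %*% query)
  denom <- vn * qn
  sim <- ifelse(denom > 0, num / denom, 0)
  sim
}

#' Retrieve the k nearest comments
#'
#' Ranks indexed comments by cosine similarity to the query vector,
#' descending, ties broken by lower source `seq`. Asking for more items
#' than the index holds returns all of them.
#'
#' @param index A [build_index()] object.
#' @param query_vector Numeric vector of the index dimension.
#' @param k Number of items to return (>= 1).
#' @return Integer vector of source `seq` values, best first.
#' @export
retrieve <- function(index, query_vector, k = 20L) {
  stopifnot(inherits(index, "vector_index"), k >= 1)
  if (length(index$source_seq) == 0) stop("cannot retrieve from an empty index")
  if (length(query_vector) != ncol(index$vectors))
    stop("query vector dimension ", length(query_vector),
         " does not match index dimension ", ncol(index$vectors))
  sim <- cosine_to_query(index$vectors, query_vector)
  ord <- order(-sim, index$source_seq)
  index$source_seq[head(ord, min(k, length(ord)))]
}

#' Render a summarization prompt
#'
#' Renders one of the two fixed prompt templates around the retrieved
#' comments. The question text of each approach is fixed verbatim;
#' the framing instructs the generator to answer in English using only the
#' supplied context. An empty retrieved set renders an explicit
#' `[no context retrieved]` marker rather than silently truncating.
#'
#' @param approach `"general"` or `"medical_focus"`.
#' @param retrieved_texts Character vector of retrieved comment texts.
#' @return The prompt string.
#' @export
render_prompt <- function(approach = c("general", "medical_focus"),
                          retrieved_texts = character(0)) {
  approach <- match.arg(approach)
  context <- if (length(retrieved_texts) == 0) "[no context retrieved]"
             else paste(sprintf("- %s", retrieved_texts), collapse = "\n")
  paste0("You are summarizing public social-media comments about ",
         "non-communicable diseases. Answer in English, using only the ",
         "comments provided as context.\n\n",
         "Question: ", summary_questions[[approach]], "\n\n",
         "Comments:\n", context, "\n")
}

#' Deterministic mock text-generation backend
#'
#' Stands in for a remote LLM in tests and offline runs: instead of free
#' text it emits a reproducible digest of its context — the number of
#' context comments and the sorted canonical disease labels matched in
#' them — so pipeline behavior is assertable.
#'
#' @param lexicon Lexicon used to scan the context for disease mentions.
#' @return A function `(prompt) -> text`.
#' @export
mock_llm_backend <- function(lexicon = load_lexicon()) {
  function(prompt) {
    lines <- strsplit(prompt, "\n", fixed = TRUE)[[1]]
    ctx <- sub("^- ", "", lines[startsWith(lines, "- ")])
    labels <- character(0)
    for (x in ctx) {
      rec <- comment_table(alias = "a", text = x)
      tk <- tokenize_comments(rec)
      labels <- c(labels, match_category(tk[1, ], lexicon, "disease"))
    }
    labels <- sort(unique(labels))
    paste0("[mock summary] comments: ", length(ctx),
           "; diseases: ",
           if (length(labels)) paste(labels, collapse = ", ") else "none")
  }
}

#' Retrieval-augmented comment summarization
#'
#' Embeds the comments, indexes them, retrieves the `k` comments most
#' similar to the approach's question, renders the prompt, and calls the
#' text-generation backend on it.
#'
#' @param records Non-empty comment table of retained comments.
#' @param approach `"general"` or `"medical_focus"`.
#' @param k Retrieval depth (default 20).
#' @param llm_backend Function `(prompt) -> text`; default
#'   [mock_llm_backend()].
#' @param embed_backend Embedding backend; default [hash_embed_backend()].
#' @return The generated summary text, with the rendered prompt attached as
#'   attribute `"prompt"`.
#' @export
summarize_comments <- function(records, approach = c("general", "medical_focus"),
                               k = 20L, llm_backend = mock_llm_backend(),
                               embed_backend = hash_embed_backend()) {
  approach <- match.arg(approach)
  records <- as_comment_table(records)
  if (nrow(records) == 0) stop("cannot summarize an empty comment set")
  index <- build_index(records, embed_backend)
  query <- embed_texts(summary_questions[[approach]], embed_backend)[1, ]
  hits <- retrieve(index, query, k)
  retrieved <- index$texts[match(hits, index$source_seq)]
  prompt <- render_prompt(approach, retrieved)
  out <- llm_backend(prompt)
  attr(out, "prompt") <- prompt
  out
}
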