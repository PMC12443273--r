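# Dashboard data model: aggregate extracted knowledge into the eight chart
# specifications with the user-validated visibility defaults, apply dynamic
# include/exclude filters, and export tables/reports.

# The eight dashboard variables with chart type and default visibility.
# Visibility follows the user-assessment rule: variables whose mean
# importance score reached at least 4.21 are shown by default (gender pie;
# disease/symptom/treatment/behavior bars); the rest stay hidden but remain
# retrievable.
dashboard_variables <- tibble::tibble(
  variable = c("gender", "source", "categorized_comments", "diseases",
               "symptoms", "treatments", "behaviors", "word_frequency"),
  chart_type = c("pie", "pie", "pie", "bar", "bar", "bar", "bar", "bar"),
  visible_by_default = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))

count_labels <- function(values) {
  if (length(values) == 0)
    return(tibble::tibble(label = character(0), count = integer(0)))
  tab <- table(values)
  out <- tibble::tibble(label = names(tab), count = as.integer(tab))
  out[order(-out$count, out$label), ]
}

#' Aggregate knowledge into the eight dashboard charts
#'
#' Produces one chart spec per dashboard variable: patient gender (pie,
#' visible; comments with unknown gender are excluded from the pie but stay
#' in the table), opinion source and categorized comments (pies, hidden),
#' the four mention bars (visible; each comment counts once per mentioned
#' label), and the top-`top_k` word-frequency bar (hidden). Bar and pie
#' categories are ordered by descending count, ties lexicographic.
#'
#' @param knowledge Knowledge table from [extract_knowledge()].
#' @param tokenized Optional [tokenize_comments()] output for the
#'   word-frequency chart (empty chart when absent).
#' @param top_k Word-frequency depth, default 20.
#' @return Tibble of chart specs: `variable`, `chart_type`,
#'   `visible_by_default`, `data` (list of label/count tibbles).
#' @export
aggregate_charts <- function(knowledge, tokenized = NULL, top_k = 20) {
  chart_data <- list(
    gender = count_labels(knowledge$gender[knowledge$gender != "unknown"]),
    source = count_labels(knowledge$source),
    categorized_comments = count_labels(knowledge$category[!is.na(knowledge$category)]),
    diseases = count_labels(unlist(knowledge$diseases)),
    symptoms = count_labels(unlist(knowledge$symptoms)),
    treatments = count_labels(unlist(knowledge$treatments)),
    behaviors = count_labels(unlist(knowledge$behaviors)),
    word_frequency = if (is.null(tokenized)) {
      tibble::tibble(label = character(0), count = integer(0))
    } else {
      wf <- word_frequency(tokenized[tokenized$seq %in% knowledge$seq, ], top_k)
      tibble::tibble(label = wf$token, count = wf$count)
    })
  out <- dashboard_variables
  out$data <- unname(chart_data[out$variable])
  out
}

#' Assemble a dashboard state
#'
#' Runs the full back-end path for one post: tokenize, extract knowledge,
#' classify (attaching the category variable), aggregate charts, and
#' summarize via the retrieval-augmented layer.
#'
#' @param records Cleaned comment table (see [preprocess_pipeline()]).
#' @param lexicon A [load_lexicon()] object.
#' @param classifier A [train_classifier()] model (default rule-based).
#' @param include,exclude Disease/symptom label filters (see
#'   [adjust_selection()]).
#' @param summarize Logical: generate `summary_text` via
#'   [summarize_comments()] with the mock backend? Off by default.
#' @param top_k Word-frequency depth.
#' @return A `dashboard_state`: `charts`, `filters`, `summary_text`,
#'   `table` (comments joined with knowledge), plus cached `knowledge`,
#'   `tokenized` and `records` for refiltering.
#' @export
dashboard_state <- function(records, lexicon = load_lexicon(),
                            classifier = train_classifier(backend = "rule_based"),
                            include = character(0), exclude = character(0),
                            summarize = FALSE, top_k = 20) {
  records <- as_comment_table(records)
  tokenized <- tokenize_comments(records)
  knowledge <- extract_knowledge(tokenized, lexicon)
  if (nrow(knowledge))
    knowledge$category <- classify(classifier, records$text, records$language)
  state <- structure(list(records = records, tokenized = tokenized,
                          knowledge_full = knowledge, lexicon = lexicon,
                          top_k = top_k),
                     class = "dashboard_state")
  state <- refilter(state, include, exclude)
  if (summarize && nrow(state$table)) {
    state$summary_text <- summarize_comments(
      state$records[state$records$seq %in% state$table$seq, ],
      llm_backend = mock_llm_backend(lexicon))
    state$summary_stale <- FALSE
  }
  state
}

#' Re-apply include/exclude filters to a dashboard state
#'
#' Delegates to [adjust_selection()] and re-aggregates every chart from the
#' surviving comments. Any existing summary text is kept but marked stale
#' until the state is re-summarized.
#'
#' @param state A [dashboard_state()].
#' @param include,exclude Disease/symptom label sets (disjoint).
#' @return The updated `dashboard_state`.
#' @export
refilter <- function(state, include = character(0), exclude = character(0)) {
  stopifnot(inherits(state, "dashboard_state"))
  knowledge <- adjust_selection(state$knowledge_full, include, exclude)
  state$filters <- list(include = include, exclude = exclude)
  state$knowledge <- knowledge
  state$charts <- aggregate_charts(knowledge, state$tokenized, state$top_k)
  kept <- state$records[state$records$seq %in% knowledge$seq, ]
  state$table <- dplyr::left_join(kept, knowledge, by = "seq")
  if (!is.null(state$summary_text)) state$summary_stale <- TRUE
  state
}

#' Export the retained comment table as CSV
#'
#' Writes the four-column comment CSV of the currently retained comments;
#' the file round-trips through [read_comment_table()].
#'
#' @param state A [dashboard_state()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_table <- function(state, path) {
  stopifnot(inherits(state, "dashboard_state"))
  write_comment_table(state$table[, comment_cols], path)
}

#' Build a structured dashboard report
#'
#' Serializable report document holding every chart's data (including
#' hidden charts), the active filters, and the summary text.
#'
#' @param state A [dashboard_state()].
#' @return A list ready for [jsonlite::write_json()]; also writable with
#'   [write_report()].
#' @export
build_report <- function(state) {
  stopifnot(inherits(state, "dashboard_state"))
  charts <- lapply(seq_len(nrow(state$charts)), function(i) {
    list(variable = state$charts$variable[i],
         chart_type = state$charts$chart_type[i],
         visible_by_default = state$charts$visible_by_default[i],
         data = as.data.frame(state$charts$data[[i]]))
  })
  list(n_comments = nrow(state$table),
       filters = list(include = as.character(state$filters$include),
                      exclude = as.character(state$filters$exclude)),
       summary_text = if (is.null(state$summary_text)) "" else as.character(state$summary_text),
       summary_stale = isTRUE(state$summary_stale),
       charts = charts)
}

#' @rdname build_report
#' @param path Output JSON path.
#' @export
write_report <- function(state, path) {
  jsonlite::write_json(build_report(state), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
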