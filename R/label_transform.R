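#' Disease label frequencies in a multi-labeled DPD graph
#'
#' Counts, for every disease, the number of drug-protein edges whose label set
#' contains it.
#'
#' @param graph a [multilabel_dpd()].
#' @return named integer vector (disease -> count), class
#'   `label_frequency_table`.
#' @export
count_label_frequencies <- function(graph) {
  if (!inherits(graph, "multilabel_dpd")) drh_stop("expected a multilabel_dpd graph")
  if (length(graph) == 0L) drh_stop("cannot count label frequencies of an empty graph")
  tab <- table(unlist(graph$labels))
  counts <- setNames(as.integer(tab), names(tab))
  structure(counts, class = c("label_frequency_table", class(counts)))
}

#' Representative disease of one label set
#'
#' The disease with the least appearance in the whole network (global frequency
#' argmin over the set); ties broken by lexicographically smallest identifier.
#' The criterion is deliberately frequency-only; a secondary ranking score can
#' be supplied through `score` (lower wins before the lexicographic tie-break).
#'
#' @param label_set non-empty character vector of disease ids.
#' @param freq a [count_label_frequencies()] table covering `label_set`.
#' @param score optional named numeric secondary key.
#' @return single disease id.
#' @export
select_representative <- function(label_set, freq, score = NULL) {
  label_set <- as.character(label_set)
  if (!length(label_set)) drh_stop("empty label set")
  missing <- setdiff(label_set, names(freq))
  if (length(missing))
    drh_stop("label(s) not in frequency table: %s", paste(missing, collapse = ", "))
  f <- unclass(freq)[label_set]
  cand <- sort(label_set[f == min(f)])
  if (!is.null(score) && length(cand) > 1L) {
    s <- score[cand]
    cand <- sort(cand[s == min(s)])
  }
  cand[1L]
}

#' Multi-label to single-label transformation
#'
#' Replaces every edge's label set by its representative disease
#' ([select_representative()]), turning the multi-label edge classification
#' task into a single-label multi-class one. No edges are dropped; the label
#' vocabulary is the sorted set of distinct representatives.
#'
#' @param graph a [multilabel_dpd()].
#' @return a [dpd_graph()] with attribute `label_vocabulary`; the label
#'   histogram is logged.
#' @export
transform_labels <- function(graph) {
  freq <- count_label_frequencies(graph)
  reps <- vapply(graph$labels, select_representative, character(1), freq = freq)
  vocab <- sort(unique(reps))
  out <- dpd_graph(graph$drug, graph$protein, reps, label_vocabulary = vocab)
  hist <- table(reps)
  drh_msg("label transform: %d edges, %d representative diseases (max class %d, min class %d)",
          nrow(out), length(vocab), max(hist), min(hist))
  out
}
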