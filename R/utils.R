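#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows distinct n row_number desc across pull rename count
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_int map_dbl map_lgl map2 pmap imap
#' @importFrom Matrix sparseMatrix rowSums colSums t Diagonal
#' @importFrom stats predict rpois runif setNames quantile
NULL

# Sentinel for documents whose publication year is unknown; sorts below all
# real 4-digit years when the date enters a descending sort key.
YEAR_UNKNOWN <- 0L

CTYPE_LEVELS <- c("melanoma", "head_and_neck", "colorectal",
                  "general_cancer", "none")

#' Empty entity-mention table
#'
#' Mentions are stored per document as a tibble with one row per typed span.
#' Offsets are 0-based, half-open, into the annotated text
#' (title, a single space, then the abstract).
#'
#' @return A zero-row tibble with columns `etype`, `start`, `end`,
#'   `surface`, `norm_id`.
#' @export
empty_mentions <- function() {
  tibble(etype = character(), start = integer(), end = integer(),
         surface = character(), norm_id = character())
}

#' Annotated text of a document
#'
#' The text all mention offsets refer to: title and abstract joined by a
#' single space (title alone when the abstract is empty).
#'
#' @param title,abstract Character vectors of equal length.
#' @return Character vector of annotated texts.
#' @export
annotated_text <- function(title, abstract) {
  ifelse(is.na(abstract) | abstract == "", title, paste(title, abstract))
}

#' Build a document tibble
#'
#' Convenience constructor that fills defaults and validates the invariants
#' shared by every corpus in the package: non-empty unique `doc_id`, integer
#' `pub_year` (0 = unknown), and per-document mention tables whose spans lie
#' inside the annotated text.
#'
#' @param doc_id Character ids, unique and non-empty.
#' @param title,abstract Character; `abstract` defaults to `""`.
#' @param pub_year Integer year (4-digit) or 0 when unknown.
#' @param journal Character, may be empty.
#' @param mentions List of mention tibbles (see [empty_mentions()]).
#' @param ctype_label Optional cancer-type tag, filled by classification.
#' @return A tibble with one row per document.
#' @export
document_tibble <- function(doc_id, title, abstract = "", pub_year = YEAR_UNKNOWN,
                            journal = "", mentions = NULL, ctype_label = NA_character_) {
  n <- length(doc_id)
  docs <- tibble(
    doc_id = as.character(doc_id),
    title = as.character(title),
    abstract = rep_len(as.character(abstract), n),
    pub_year = rep_len(as.integer(pub_year), n),
    journal = rep_len(as.character(journal), n),
    mentions = mentions %||% rep(list(empty_mentions()), n),
    ctype_label = rep_len(as.character(ctype_label), n)
  )
  validate_documents(docs)
  docs
}

validate_documents <- function(docs) {
  stopifnot(is.data.frame(docs))
  need <- c("doc_id", "title", "abstract", "pub_year", "mentions")
  miss <- setdiff(need, names(docs))
  if (length(miss) > 0) {
    abort(paste0("document tibble lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(docs$doc_id == "" | is.na(docs$doc_id))) abort("doc_id must be non-empty")
  if (anyDuplicated(docs$doc_id)) {
    abort(paste0("duplicate doc_id: ",
                 paste(unique(docs$doc_id[duplicated(docs$doc_id)]), collapse = ", ")))
  }
  bad_year <- !(docs$pub_year == YEAR_UNKNOWN |
                  (docs$pub_year >= 1000 & docs$pub_year <= 9999))
  if (any(bad_year, na.rm = TRUE)) abort("pub_year must be a 4-digit year or 0 (unknown)")
  txt <- annotated_text(docs$title, docs$abstract)
  ok <- map2(docs$mentions, txt, function(m, tx) {
    if (is.null(m) || nrow(m) == 0) return(TRUE)
    all(m$start >= 0 & m$start < m$end & m$end <= nchar(tx)) &&
      all(substring(tx, m$start + 1L, m$end) == m$surface)
  })
  if (!all(unlist(ok))) abort("mention spans must slice the annotated text exactly")
  invisible(docs)
}

# substring by 0-based half-open offsets (vectorized over offsets)
slice_text <- function(text, start, end) substring(text, start + 1L, end)

#' Min-max normalization to the unit interval
#'
#' Rescales raw scores over an indexed corpus to \[0, 1\] by
#' `(x - min) / (max - min)`. When all scores are equal the corpus carries no
#' ordering information and every document receives 1.0.
#'
#' @param x Numeric vector of raw scores (non-empty, finite).
#' @return Numeric vector in \[0, 1\].
#' @export
normalize_scores <- function(x) {
  if (length(x) == 0) abort("cannot normalize an empty score vector")
  if (any(!is.finite(x))) abort("raw scores must be finite")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(1, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

# precision/recall/F1 from counts; F1 = 0 when both P and R are 0
prf <- function(tp, fp, fn) {
  p <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  r <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f <- if (is.na(p) || is.na(r) || (p + r) == 0) {
    if (is.na(p) || is.na(r)) NA_real_ else 0
  } else {
    2 * p * r / (p + r)
  }
  c(precision = p, recall = r, f1 = f)
}
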