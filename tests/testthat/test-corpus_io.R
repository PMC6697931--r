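test_that("PubMed XML parsing maps fields, concatenates sections, defaults missing parts", {
  path <- write_pubmed_xml(c(
    pubmed_article_xml("123", "T", "A", "2018"),
    pubmed_article_xml("124", "Two part", c("X.", "Y."), "2015"),
    pubmed_article_xml("125", "No abstract", character(), "2012")
  ))
  docs <- read_pubmed_xml(path)
  expect_equal(docs$doc_id, c("123", "124", "125"))
  expect_equal(docs$title[1], "T")
  expect_equal(docs$abstract[1], "A")
  expect_equal(docs$pub_year, c(2018L, 2015L, 2012L))
  expect_equal(docs$abstract[2], "X. Y.")
  expect_equal(docs$abstract[3], "")
  expect_equal(docs$journal[1], "J Test")
})

test_that("PubMed XML articles without PMID are skipped with a warning; bad XML errors", {
  path <- write_pubmed_xml(c(pubmed_article_xml("", "No id", "A"),
                             pubmed_article_xml("200", "Good", "B")))
  expect_warning(docs <- read_pubmed_xml(path), "skipped")
  expect_equal(docs$doc_id, "200")

  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<PubmedArticleSet><PubmedArticle>", bad)
  expect_error(read_pubmed_xml(bad), "malformed XML")
})

test_that("a PubMed article with no usable year gets the unknown sentinel", {
  art <- paste0("<PubmedArticle><MedlineCitation><PMID>9</PMID>",
                "<Article><ArticleTitle>T</ArticleTitle></Article>",
                "</MedlineCitation></PubmedArticle>")
  docs <- read_pubmed_xml(write_pubmed_xml(art))
  expect_equal(docs$pub_year, 0L)
})

test_that("JSONL round trip is lossless, including mention offsets", {
  m <- tibble::tibble(etype = "gene", start = 0L, end = 5L,
                      surface = "GENE1", norm_id = "G1")
  docs <- document_tibble(c("d1", "d2", "d3"),
                          title = c("GENE1 title", "Second", "Third"),
                          abstract = c("body text", "", "abc"),
                          pub_year = c(2018L, 0L, 1999L),
                          journal = c("J", "", "K"),
                          mentions = list(m, empty_mentions(), empty_mentions()),
                          ctype_label = c("melanoma", NA, NA))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_documents_jsonl(docs, path)
  back <- read_documents_jsonl(path)
  expect_equal(as.data.frame(back), as.data.frame(docs))
})

test_that("JSONL reader defaults missing mentions, handles empty files, names bad lines", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"doc_id":"x","title":"T","abstract":"A","pub_year":2001,"journal":""}', path)
  docs <- read_documents_jsonl(path)
  expect_equal(nrow(docs$mentions[[1]]), 0)

  empty <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(), empty)
  expect_equal(nrow(read_documents_jsonl(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"doc_id":"x","title":"T"}', '{"title":"no id"}'), bad)
  expect_error(read_documents_jsonl(bad), "line 2")
})

test_that("judgments TSV yields one set per query and rejects bad labels and conflicts", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("query_id\tdoc_id\tlabel",
               "q1\td1\trelevant",
               "q1\td2\tirrelevant"), path)
  j <- read_judgments_tsv(path)
  expect_equal(nrow(j), 2)
  expect_equal(sum(j$relevant), 1)

  many <- withr::local_tempfile(fileext = ".tsv")
  rows <- paste0("q", 1:14, "\td", 1:14, "\trelevant")
  writeLines(c("query_id\tdoc_id\tlabel", rows), many)
  expect_equal(length(unique(read_judgments_tsv(many)$query_id)), 14)

  badlab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("query_id\tdoc_id\tlabel", "q1\td1\tmaybe"), badlab)
  expect_error(read_judgments_tsv(badlab), "row 1")

  confl <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("query_id\tdoc_id\tlabel",
               "q1\td1\trelevant", "q1\td1\tirrelevant"), confl)
  expect_error(read_judgments_tsv(confl), "conflicting")
})

test_that("assessment consolidation removes contested pairs, majority-votes, discards ties", {
  raw <- tibble::tibble(
    query_id = "q1",
    doc_id = rep(c("contested", "majority", "tie"), c(4, 3, 2)),
    rater_id = c("r1", "r2", "r3", "r4", "r1", "r2", "r3", "r1", "r2"),
    score = c(5L, 1L, 3L, 3L, 4L, 4L, 2L, 4L, 2L)
  )
  full <- consolidate_assessments(raw, keep_all = TRUE)
  expect_equal(full$status[full$doc_id == "contested"], "removed")
  expect_equal(full$status[full$doc_id == "majority"], "relevant")
  expect_equal(full$status[full$doc_id == "tie"], "tie")

  out <- consolidate_assessments(raw)
  expect_equal(out$doc_id, "majority")
  expect_true(out$relevant)

  expect_equal(nrow(consolidate_assessments(raw[0, ])), 0)
})

test_that("consolidation statuses partition the distinct (query, doc) pairs", {
  withr::with_seed(11, {
    raw <- tibble::tibble(
      query_id = sample(paste0("q", 1:3), 60, TRUE),
      doc_id = sample(paste0("d", 1:10), 60, TRUE),
      rater_id = sample(paste0("r", 1:4), 60, TRUE),
      score = sample(1:5, 60, TRUE)
    ) |> dplyr::distinct(query_id, doc_id, rater_id, .keep_all = TRUE)
  })
  full <- consolidate_assessments(raw, keep_all = TRUE)
  n_pairs <- nrow(dplyr::distinct(raw, query_id, doc_id))
  expect_equal(nrow(full), n_pairs)
  expect_true(all(full$status %in% c("relevant", "irrelevant", "removed", "tie")))
})

test_that("lexicon TSV loading enforces synonym uniqueness and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("673\tBRAF\tBRAF|B-RAF1", "3845\tKRAS\tKRAS"), path)
  lex <- read_lexicon_tsv(path, "gene")
  expect_setequal(lex$synonym[lex$id == "673"], c("BRAF", "B-RAF1"))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon_tsv(lex, out)
  back <- dplyr::arrange(as.data.frame(read_lexicon_tsv(out, "gene")), id, synonym)
  expect_equal(back, dplyr::arrange(as.data.frame(lex), id, synonym))

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\tX1\tABC", "2\tY1\tABC"), dup)
  expect_error(read_lexicon_tsv(dup, "gene"), "ABC")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_equal(nrow(read_lexicon_tsv(empty, "gene")), 0)
})

test_that("document validation catches duplicate ids and out-of-range spans", {
  expect_error(document_tibble(c("a", "a"), c("t", "t")), "duplicate")
  m <- tibble::tibble(etype = "gene", start = 0L, end = 99L,
                      surface = "nope", norm_id = "G1")
  expect_error(document_tibble("a", "short", mentions = list(m)), "span")
})
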