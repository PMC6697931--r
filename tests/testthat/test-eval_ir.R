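test_that("average precision, reciprocal rank and nDCG match their closed forms", {
  expect_equal(average_precision(c("r1", "n1", "r2"), c("r1", "r2")),
               (1 / 1 + 2 / 3) / 2)
  expect_equal(average_precision(c("r1", "r2", "n1"), c("r1", "r2")), 1)
  expect_equal(average_precision(c("n1", "n2"), c("r1", "r2", "r3")), 0)
  expect_true(is.na(average_precision(c("n1"), character())))

  expect_equal(reciprocal_rank(c("r1", "n1"), "r1"), 1)
  expect_equal(reciprocal_rank(c("n1", "n2", "n3", "r1"), "r1"), 0.25)
  expect_equal(reciprocal_rank(c("n1", "n2"), "r1"), 0)

  expect_equal(ndcg(c("r1", "r2"), c("r1", "r2")), 1)
  expect_equal(ndcg(c("n1", "r1"), "r1"), (1 / log2(3)) / 1, tolerance = 1e-9)
  expect_equal(ndcg(c("n1", "n2"), "r1"), 0)
})

test_that("the mean-rank ratio matches worked values and conventions", {
  expect_equal(rel_vs_irrel(c(1, 5, 10), c(3, 6, 12)), (16 / 3) / 7)
  expect_equal(rel_vs_irrel(1, 2), 0.5)
  expect_true(is.na(rel_vs_irrel(c(1, 2), integer())))
  fx <- generate_ranked_fixture(pattern = "positions",
                                rel_positions = c(55, 103, 116),
                                irrel_positions = c(44, 201, 240))
  rel <- fx$judgments$doc_id[fx$judgments$relevant]
  irr <- fx$judgments$doc_id[!fx$judgments$relevant]
  expect_equal(rel_vs_irrel_ranking(fx$ranking$doc_id, rel, irr),
               (274 / 3) / (485 / 3))
})

test_that("restricted precision/recall ignores unjudged documents entirely", {
  ranked <- c("r1", "u1", "n1", "u2", "r2", "n2")
  out <- restricted_pr_at_k(ranked, c("r1", "r2"), c("n1", "n2"), k = 1:4)
  expect_equal(out$precision, c(1, 1 / 2, 2 / 3, 2 / 4))
  expect_equal(out$recall, c(1 / 2, 1 / 2, 1, 1))
  # k beyond the restricted length is undefined
  expect_true(is.na(restricted_pr_at_k(ranked, c("r1", "r2"), c("n1", "n2"),
                                       k = 5)$precision))
  # 1000 unjudged documents change nothing
  long <- c(ranked, sprintf("pad%04d", 1:1000))
  out2 <- restricted_pr_at_k(long, c("r1", "r2"), c("n1", "n2"), k = 1:4)
  expect_equal(out2, out)
  all_rel <- restricted_pr_at_k(c("r1", "r2"), c("r1", "r2"), character())
  expect_equal(all_rel$precision, c(1, 1))
  expect_error(restricted_pr_at_k(ranked, c("x"), c("x")), "disjoint")
})

test_that("metrics match brute-force oracles on every judged sequence up to length 6", {
  for (len in 1:6) {
    for (mask in 0:(2^len - 1)) {
      flags <- as.logical(bitwAnd(mask, 2^(0:(len - 1))))
      ids <- sprintf("d%02d", 1:len)
      rel <- ids[flags]
      irr <- ids[!flags]
      n_rel <- length(rel)
      expect_equal(average_precision(ids, rel), oracle_ap(flags, n_rel))
      if (n_rel > 0) {
        expect_equal(reciprocal_rank(ids, rel), oracle_rr(flags))
        expect_equal(ndcg(ids, rel), oracle_ndcg(flags, n_rel))
        expect_equal(ndcg(ids, rel, cutoff = 3), oracle_ndcg(flags, n_rel, 3))
        for (k in seq_len(len)) {
          pr <- restricted_pr_at_k(ids, rel, irr, k = k)
          expect_equal(pr$precision, oracle_p_at_k(flags, k))
          expect_equal(pr$recall, oracle_r_at_k(flags, k, n_rel))
        }
      }
    }
  }
})

test_that("metrics are invariant to unjudged padding and reward upward swaps", {
  ids <- c("r1", "n1", "r2", "n2")
  rel <- c("r1", "r2")
  padded <- c(ids, sprintf("u%03d", 1:50))
  expect_equal(average_precision(padded, rel), average_precision(ids, rel))
  expect_equal(reciprocal_rank(padded, rel), reciprocal_rank(ids, rel))
  expect_equal(ndcg(padded, rel), ndcg(ids, rel))
  # swapping a relevant document above an irrelevant one strictly lowers the ratio
  before <- rel_vs_irrel_ranking(c("n1", "r1"), "r1", "n1")
  after <- rel_vs_irrel_ranking(c("r1", "n1"), "r1", "n1")
  expect_lt(after, before)
})

test_that("fully interleaved equal sets drive the mean-rank ratio to 1", {
  fx <- generate_ranked_fixture(50, 50, pattern = "alternating")
  rel <- fx$judgments$doc_id[fx$judgments$relevant]
  irr <- fx$judgments$doc_id[!fx$judgments$relevant]
  ratio <- rel_vs_irrel_ranking(fx$ranking$doc_id, rel, irr)
  expect_lt(abs(ratio - 1), 0.05)
})

test_that("per-query evaluation and the ranker comparison table are consistent", {
  judgments <- tibble::tibble(
    query_id = rep(c("q1", "q2", "q3"), each = 2),
    doc_id = c("a", "b", "c", "d", "e", "f"),
    relevant = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  )
  good <- tibble::tibble(
    ranker = "good",
    query_id = rep(c("q1", "q2", "q3"), each = 2),
    doc_id = c("a", "b", "c", "d", "e", "f"),
    rank = rep(1:2, 3)
  )
  bad <- good
  bad$ranker <- "bad"
  bad$doc_id <- c("b", "a", "d", "c", "f", "e")
  cmp <- compare_rankers(dplyr::bind_rows(good, bad), judgments)
  expect_equal(cmp$map[cmp$ranker == "good"], 1)
  expect_equal(cmp$n_best_rel_vs_irrel[cmp$ranker == "good"], 3L)
  expect_equal(cmp$n_best_rel_vs_irrel[cmp$ranker == "bad"], 0L)
  # identical rankers share the best count on every query
  twin <- good
  twin$ranker <- "twin"
  cmp2 <- compare_rankers(dplyr::bind_rows(good, twin), judgments)
  expect_equal(cmp2$n_best_rel_vs_irrel, c(3L, 3L))
  per_q <- evaluate_rankings(good, judgments)
  expect_equal(per_q$ap, rep(1, 3))
  expect_equal(per_q$rel_vs_irrel, rep(0.5, 3))
})

test_that("per-gene gold evaluation scores gold documents as the relevant set", {
  b <- generate_corpus(generator_config(n_docs = 200, overlap = 0, seed = 17))
  docs <- b$documents
  # construct scores so gold (clinical_cancer) documents are exactly the top
  docs$cancer_score <- ifelse(docs$class == "non_cancer", 0.1, 0.9)
  docs$clinical_score <- ifelse(docs$class == "clinical_cancer", 0.9, 0.1)
  docs$rank_score <- docs$cancer_score * docs$clinical_score
  docs$pub_year_int <- docs$pub_year
  rep_keys <- per_gene_gold_eval(docs, b$gold, b$lexicon,
                                 sort_keys = c("rank_score", "cancer_score"))
  expect_equal(rep_keys$map[rep_keys$sort_key == "rank_score"], 1)
  expect_equal(rep_keys$recall[rep_keys$sort_key == "rank_score"], 1)
  # identical scores under two keys give identical reports
  docs2 <- docs
  docs2$cancer_score <- docs2$rank_score
  rep2 <- per_gene_gold_eval(docs2, b$gold, b$lexicon,
                             sort_keys = c("rank_score", "cancer_score"))
  expect_equal(rep2$map[1], rep2$map[2])
  expect_equal(rep2$ndcg[1], rep2$ndcg[2])
  # a gene absent from every document yields a counted empty query
  gold_plus <- dplyr::bind_rows(b$gold, tibble::tibble(gene = "ZZZ99", doc_id = "S00001"))
  rep3 <- per_gene_gold_eval(docs, gold_plus, b$lexicon, sort_keys = "rank_score")
  expect_equal(rep3$n_empty, 1L)
})
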