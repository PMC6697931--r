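# Seeded synthetic corpora with the statistical structure the classifiers
# and rankers assume: class-conditional vocabularies with a controllable
# shared fraction, injected gene/variant/drug mentions with ground-truth
# spans, a matching lexicon, per-gene gold document sets and per-query
# relevance judgments.

#' Generator configuration
#'
#' @param n_docs Number of documents.
#' @param class_mixture Named proportions over `clinical_cancer`,
#'   `basic_cancer`, `non_cancer` (must sum to 1).
#' @param ctype_mixture Named proportions over the four cancer-type labels,
#'   used within the two cancer classes.
#' @param vocab_size Words per class-specific vocabulary (the shared pool has
#'   the same size).
#' @param overlap Probability that a token is drawn from the shared pool
#'   instead of the class-specific one; 0 gives disjoint class vocabularies
#'   (maximal separability), 1 makes classes indistinguishable.
#' @param doc_length Mean document length in tokens (Poisson, floor 10).
#' @param gene_injection_rate,variant_injection_rate,drug_injection_rate
#'   Per-document probability of injecting one mention of that entity type.
#' @param n_genes_in_lexicon,n_drugs_in_lexicon Entities in the emitted
#'   lexicons.
#' @param year_range Integer range publication years are drawn from.
#' @param seed Integer seed; the whole bundle is a deterministic function of
#'   the configuration.
#' @return A `clinrank_generator_config` list.
#' @export
generator_config <- function(n_docs = 1000,
                             class_mixture = c(clinical_cancer = 0.4,
                                               basic_cancer = 0.3,
                                               non_cancer = 0.3),
                             ctype_mixture = c(melanoma = 0.3,
                                               head_and_neck = 0.2,
                                               colorectal = 0.2,
                                               general_cancer = 0.3),
                             vocab_size = 120, overlap = 0.2, doc_length = 60,
                             gene_injection_rate = 0.8,
                             variant_injection_rate = 0.3,
                             drug_injection_rate = 0.3,
                             n_genes_in_lexicon = 30, n_drugs_in_lexicon = 10,
                             year_range = c(2000, 2020), seed = 1L) {
  stopifnot(n_docs >= 1, vocab_size >= 2, doc_length >= 10,
            overlap >= 0, overlap <= 1,
            gene_injection_rate >= 0, gene_injection_rate <= 1,
            variant_injection_rate >= 0, variant_injection_rate <= 1,
            drug_injection_rate >= 0, drug_injection_rate <= 1,
            n_genes_in_lexicon >= 1, n_drugs_in_lexicon >= 1,
            length(year_range) == 2, year_range[1] <= year_range[2])
  if (abs(sum(class_mixture) - 1) > 1e-8) abort("class_mixture must sum to 1")
  if (abs(sum(ctype_mixture) - 1) > 1e-8) abort("ctype_mixture must sum to 1")
  stopifnot(setequal(names(class_mixture),
                     c("clinical_cancer", "basic_cancer", "non_cancer")),
            setequal(names(ctype_mixture), setdiff(CTYPE_LEVELS, "none")))
  structure(list(n_docs = as.integer(n_docs), class_mixture = class_mixture,
                 ctype_mixture = ctype_mixture,
                 vocab_size = as.integer(vocab_size), overlap = overlap,
                 doc_length = doc_length,
                 gene_injection_rate = gene_injection_rate,
                 variant_injection_rate = variant_injection_rate,
                 drug_injection_rate = drug_injection_rate,
                 n_genes_in_lexicon = as.integer(n_genes_in_lexicon),
                 n_drugs_in_lexicon = as.integer(n_drugs_in_lexicon),
                 year_range = as.integer(year_range), seed = as.integer(seed)),
            class = "clinrank_generator_config")
}

# n unique random lowercase words of the given length
make_words <- function(n, len = 7L) {
  words <- character(0)
  while (length(words) < n) {
    batch <- vapply(seq_len(n), function(i) {
      paste(sample(letters, len, replace = TRUE), collapse = "")
    }, "")
    words <- unique(c(words, batch))
  }
  words[seq_len(n)]
}

make_gene_lexicon <- function(n) {
  symbols <- character(0)
  while (length(symbols) < n) {
    batch <- vapply(seq_len(n), function(i) {
      paste0(paste(sample(LETTERS, 3, replace = TRUE), collapse = ""),
             sample(10:99, 1))
    }, "")
    symbols <- unique(c(symbols, batch))
  }
  symbols <- symbols[seq_len(n)]
  ids <- sprintf("G%04d", seq_len(n))
  syns <- lapply(symbols, function(s) {
    extra <- if (runif(1) < 0.7) paste0(s, "-", sample(1:9, 1)) else character(0)
    c(s, extra)
  })
  lexicon_tibble(ids, symbols, syns, kind = "gene")
}

make_drug_lexicon <- function(n) {
  stems <- make_words(n, len = 6L)
  names <- paste0(stems, "nib")
  lexicon_tibble(sprintf("D%03d", seq_len(n)), names,
                 as.list(names), kind = "drug")
}

make_variant_surface <- function() {
  kind <- sample(c("short", "coding", "rsid"), 1, prob = c(0.6, 0.25, 0.15))
  if (kind == "short") {
    paste0(sample(unname(AA3[AA3 != "*"]), 1), sample(100:999, 1),
           sample(unname(AA3[AA3 != "*"]), 1))
  } else if (kind == "coding") {
    paste0("c.", sample(10:9999, 1), sample(c("A", "C", "G", "T"), 1), ">",
           sample(c("A", "C", "G", "T"), 1))
  } else {
    paste0("rs", sample(1000:999999, 1))
  }
}

#' Generate a synthetic corpus bundle
#'
#' Draws each document's class from the class mixture, its tokens from the
#' class unigram distribution (a Zipf-weighted class-specific vocabulary,
#' with each token coming from a shared pool with probability `overlap`),
#' injects gene / variant / drug mentions at token boundaries with the
#' configured per-document rates, and records the ground-truth spans. The
#' first six tokens form the title, the rest the abstract. Documents of the
#' clinically-relevant-cancer class form the relevant pool: per-gene gold
#' sets are the clinical-cancer documents carrying that gene, and judgment
#' sets take, for each query gene, those documents as relevant and documents
#' of the other classes carrying the gene as irrelevant.
#'
#' @param cfg A [generator_config()].
#' @return A `clinrank_bundle` list: `documents` (with ground-truth mentions
#'   and `label_cancer` / `label_clinical` / `label_ctype` / `class`
#'   columns), `lexicon`, `drug_lexicon`, `gold` (`gene`, `doc_id`),
#'   `judgments` (`query_id`, `doc_id`, `relevant`) and `config`.
#' @export
generate_corpus <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "clinrank_generator_config"))
  withr::with_seed(cfg$seed, {
    classes <- names(cfg$class_mixture)
    shared <- make_words(cfg$vocab_size)
    class_vocab <- list()
    pool <- make_words(cfg$vocab_size * length(classes))
    for (i in seq_along(classes)) {
      class_vocab[[classes[i]]] <-
        pool[((i - 1) * cfg$vocab_size + 1):(i * cfg$vocab_size)]
    }
    zipf <- 1 / seq_len(cfg$vocab_size)
    zipf <- zipf / sum(zipf)

    lex <- make_gene_lexicon(cfg$n_genes_in_lexicon)
    drug_lex <- make_drug_lexicon(cfg$n_drugs_in_lexicon)
    gene_ids <- unique(lex$id)

    doc_class <- sample(classes, cfg$n_docs, replace = TRUE,
                        prob = cfg$class_mixture)
    missing <- classes[cfg$class_mixture > 0 & !classes %in% doc_class]
    if (length(missing) > 0) {
      abort(paste0("stratum '", missing[1], "' is empty at n_docs = ", cfg$n_docs))
    }
    ctypes <- names(cfg$ctype_mixture)

    rows <- vector("list", cfg$n_docs)
    truth_gene <- vector("list", cfg$n_docs)
    for (d in seq_len(cfg$n_docs)) {
      cl <- doc_class[d]
      len <- max(10L, rpois(1, cfg$doc_length))
      from_shared <- runif(len) < cfg$overlap
      toks <- character(len)
      n_sh <- sum(from_shared)
      if (n_sh > 0) toks[from_shared] <- sample(shared, n_sh, TRUE, prob = zipf)
      if (n_sh < len) toks[!from_shared] <-
          sample(class_vocab[[cl]], len - n_sh, TRUE, prob = zipf)

      inj <- list()
      if (runif(1) < cfg$gene_injection_rate) {
        gid <- sample(gene_ids, 1)
        surf <- sample(lex$synonym[lex$id == gid], 1)
        inj[[length(inj) + 1]] <- list(etype = "gene", surface = surf, norm = gid)
      }
      if (runif(1) < cfg$variant_injection_rate) {
        surf <- make_variant_surface()
        inj[[length(inj) + 1]] <- list(etype = "variant", surface = surf,
                                       norm = canonical_variant(surf))
      }
      if (runif(1) < cfg$drug_injection_rate) {
        did <- sample(unique(drug_lex$id), 1)
        surf <- sample(drug_lex$synonym[drug_lex$id == did], 1)
        inj[[length(inj) + 1]] <- list(etype = "drug", surface = surf, norm = did)
      }
      inj_at <- integer(0)
      if (length(inj) > 0) {
        # insert each entity as its own token, after the title block
        for (e in inj) {
          pos <- sample(7:(length(toks) + 1), 1)
          toks <- append(toks, e$surface, after = pos - 1)
          inj_at <- vapply(inj_at, function(p) if (p >= pos) p + 1L else p, 1L)
          inj_at <- c(inj_at, pos)
        }
      }
      starts <- cumsum(c(0L, nchar(toks) + 1L))[seq_along(toks)]
      ment <- if (length(inj) == 0) empty_mentions() else {
        m <- tibble(
          etype = map_chr(inj, "etype"),
          start = as.integer(starts[inj_at]),
          end = as.integer(starts[inj_at] + nchar(map_chr(inj, "surface"))),
          surface = map_chr(inj, "surface"),
          norm_id = map_chr(inj, "norm")
        )
        m[order(m$start), ]
      }
      rows[[d]] <- tibble(
        doc_id = sprintf("S%05d", d),
        title = paste(toks[1:6], collapse = " "),
        abstract = paste(toks[-(1:6)], collapse = " "),
        pub_year = sample(cfg$year_range[1]:cfg$year_range[2], 1),
        journal = "Synthetic J", mentions = list(ment),
        ctype_label = NA_character_, class = cl
      )
      g <- ment$norm_id[ment$etype == "gene"]
      truth_gene[[d]] <- if (length(g) > 0) g else NA_character_
    }
    docs <- bind_rows(rows) |>
      mutate(
        label_cancer = .data$class != "non_cancer",
        label_clinical = .data$class == "clinical_cancer",
        label_ctype = factor(
          ifelse(.data$class == "non_cancer", "none",
                 sample(ctypes, cfg$n_docs, TRUE, prob = cfg$ctype_mixture)),
          levels = CTYPE_LEVELS)
      )
    validate_documents(docs)

    doc_gene <- tibble(doc_id = docs$doc_id, gene_id = unlist(truth_gene),
                       class = docs$class) |>
      filter(!is.na(.data$gene_id))
    sym <- lex |> distinct(.data$id, .data$canonical)
    gold <- doc_gene |>
      filter(.data$class == "clinical_cancer") |>
      left_join(sym, by = c(gene_id = "id")) |>
      select(gene = "canonical", "doc_id")
    if (nrow(gold) == 0) {
      abort("every per-gene gold set is empty; raise gene_injection_rate")
    }
    judgments <- doc_gene |>
      left_join(sym, by = c(gene_id = "id")) |>
      mutate(relevant = .data$class == "clinical_cancer") |>
      group_by(.data$canonical) |>
      filter(any(.data$relevant) & any(!.data$relevant)) |>
      ungroup() |>
      select(query_id = "canonical", "doc_id", "relevant") |>
      arrange(.data$query_id, .data$doc_id)

    structure(list(documents = docs, lexicon = lex, drug_lexicon = drug_lex,
                   gold = gold, judgments = judgments, config = cfg),
              class = "clinrank_bundle")
  })
}

#' @export
print.clinrank_bundle <- function(x, ...) {
  cat("<clinrank_bundle>", nrow(x$documents), "documents,",
      dplyr::n_distinct(x$lexicon$id), "genes,",
      dplyr::n_distinct(x$judgments$query_id), "judged queries\n")
  invisible(x)
}

#' Generate a ranked-list fixture with known judged positions
#'
#' Builds a ranking with relevant and irrelevant documents placed according
#' to a pattern — relevant block on top, on the bottom, alternating, at
#' random (seeded), or at explicitly given positions with unjudged filler
#' documents elsewhere. Feeds the metric oracle tests and worked examples.
#'
#' @param n_rel,n_irrel Judged document counts (ignored when `pattern =
#'   "positions"`).
#' @param pattern Placement pattern.
#' @param rel_positions,irrel_positions 1-based ranks for
#'   `pattern = "positions"`; remaining ranks up to the maximum are filled
#'   with unjudged documents.
#' @param seed Seed for `pattern = "random"`.
#' @return List with `ranking` (tibble `rank`, `doc_id`) and `judgments`
#'   (tibble `doc_id`, `relevant`, judged documents only).
#' @export
generate_ranked_fixture <- function(n_rel = 3, n_irrel = 3,
                                    pattern = c("top_block", "bottom_block",
                                                "alternating", "random",
                                                "positions"),
                                    rel_positions = NULL, irrel_positions = NULL,
                                    seed = 1L) {
  pattern <- match.arg(pattern)
  if (pattern == "positions") {
    stopifnot(!is.null(rel_positions), !is.null(irrel_positions),
              length(intersect(rel_positions, irrel_positions)) == 0)
    total <- max(rel_positions, irrel_positions)
    ids <- sprintf("fill%03d", seq_len(total))
    ids[rel_positions] <- sprintf("rel%03d", seq_along(rel_positions))
    ids[irrel_positions] <- sprintf("irr%03d", seq_along(irrel_positions))
    judged <- tibble(
      doc_id = c(ids[rel_positions], ids[irrel_positions]),
      relevant = rep(c(TRUE, FALSE), c(length(rel_positions), length(irrel_positions))))
    return(list(ranking = tibble(rank = seq_len(total), doc_id = ids),
                judgments = judged))
  }
  stopifnot(n_rel >= 1, n_irrel >= 1)
  rel_ids <- sprintf("rel%03d", seq_len(n_rel))
  irr_ids <- sprintf("irr%03d", seq_len(n_irrel))
  ids <- switch(pattern,
    top_block = c(rel_ids, irr_ids),
    bottom_block = c(irr_ids, rel_ids),
    alternating = {
      out <- character(n_rel + n_irrel)
      ri <- 1L; ii <- 1L
      for (k in seq_along(out)) {
        take_rel <- (k %% 2 == 1 && ri <= n_rel) || ii > n_irrel
        if (take_rel) { out[k] <- rel_ids[ri]; ri <- ri + 1L }
        else { out[k] <- irr_ids[ii]; ii <- ii + 1L }
      }
      out
    },
    random = withr::with_seed(seed, sample(c(rel_ids, irr_ids)))
  )
  list(ranking = tibble(rank = seq_along(ids), doc_id = ids),
       judgments = tibble(doc_id = c(rel_ids, irr_ids),
                          relevant = rep(c(TRUE, FALSE), c(n_rel, n_irrel))))
}
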