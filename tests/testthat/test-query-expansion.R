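test_that("bigram score follows the discounted collocation formula", {
  # "memory loss" 50x plus 60 sentences of background vocabulary: the score
  # (count_ab - delta) * |V| / (count_a * count_b) is hand-computable
  set.seed(1)
  bg <- lapply(1:60, function(i) sample(paste0("w", 1:80), 5))
  corpus <- c(lapply(1:50, function(i) c("patient", "has", "memory", "loss")),
              bg)
  vsize <- length(unique(unlist(corpus)))
  bgr <- detect_bigrams(corpus, min_count = 5, threshold = 1, delta = 0)
  row <- bgr$phrases[bgr$phrases$phrase == "memory_loss", ]
  expect_equal(row$count, 50)
  expect_equal(row$score, 50 * vsize / (50 * 50))
  expect_true("memory_loss" %in% bgr$corpus[[1]])
  expect_false(any(c("memory", "loss") %in% bgr$corpus[[1]]))
})

test_that("an infinite threshold merges nothing", {
  corpus <- lapply(1:20, function(i) c("memory", "loss", "noted"))
  bgr <- detect_bigrams(corpus, min_count = 1, threshold = Inf, delta = 0)
  expect_identical(bgr$corpus, corpus)
  expect_equal(nrow(bgr$phrases), 0)
})

test_that("the bigram score increases with pair count at fixed marginals", {
  set.seed(2)
  score_of <- function(nab, na, nb, V, delta) (nab - delta) * V / (na * nb)
  for (i in 1:20) {
    na <- sample(50:100, 1); nb <- sample(50:100, 1)
    V <- sample(100:1000, 1); delta <- runif(1, 0, 5)
    nab <- sort(sample(5:min(na, nb), 2))
    expect_lt(score_of(nab[1], na, nb, V, delta), score_of(nab[2], na, nb, V, delta))
  }
})

test_that("empty corpora and invalid dimensions are rejected", {
  expect_error(detect_bigrams(list()), "empty")
  expect_error(train_embeddings(list()), "empty")
  expect_error(train_embeddings(list(c("a", "b")), dim = 0), "positive")
})

planted_corpus <- function() {
  # two interchangeable terms share contexts; distractor topic is disjoint
  set.seed(31)
  ctx <- list(c("patient", "reports"), c("complains", "of"),
              c("daughter", "notes"), c("chart", "documents"))
  c(lapply(1:400, function(i)
      c(ctx[[sample(4, 1)]], sample(c("memory_loss", "forgetfulness"), 1),
        "for", "two", "years")),
    lapply(1:150, function(i)
      c("blood", "pressure", sample(c("stable", "elevated"), 1), "on",
        sample(c("lisinopril", "amlodipine"), 1))))
}

test_that("planted distributional synonyms rank first in expansion", {
  emb <- train_embeddings(planted_corpus(), dim = 30, epochs = 8, seed = 13)
  expect_equal(unname(cosine_similarity(emb, "memory_loss", "memory_loss")), 1,
               tolerance = 1e-12)
  cand <- expand_terms(emb, "memory_loss", k = 10, min_sim = -1)
  expect_equal(cand$term[1], "forgetfulness")
  expect_gt(cand$similarity[1],
            cosine_similarity(emb, "memory_loss", "lisinopril"))
})

test_that("embedding training and expansion are deterministic under a seed", {
  corpus <- planted_corpus()
  e1 <- train_embeddings(corpus, dim = 20, epochs = 3, seed = 13)
  e2 <- train_embeddings(corpus, dim = 20, epochs = 3, seed = 13)
  expect_identical(e1$vectors, e2$vectors)
  expect_identical(expand_terms(e1, "memory_loss", k = 5, min_sim = 0),
                   expand_terms(e2, "memory_loss", k = 5, min_sim = 0))
})

test_that("expansion guards its arguments", {
  emb <- train_embeddings(planted_corpus(), dim = 10, epochs = 1, seed = 1)
  expect_error(expand_terms(emb, "memory_loss", k = 0), "k must be")
  expect_equal(nrow(expand_terms(emb, "memory_loss", k = 5, min_sim = 1.01)), 0)
  expect_warning(expand_terms(emb, c("memory_loss", "unseen_term"), k = 3),
                 "absent from vocabulary")
})

test_that("query matching is word-boundary anchored and case insensitive", {
  m <- match_query("Patient reports Memory Loss.", "memory loss")
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 16)
  expect_equal(m$end, 27)
  expect_equal(nrow(match_query("memorandum", "memory")), 0)
  expect_equal(nrow(match_query("short-term memory  loss", "memory loss")), 1)
  expect_error(match_query("text", character()), "empty")
})

test_that("matching is idempotent and order-independent over lexicon terms", {
  text <- "Forgetfulness and memory loss, also confusion."
  lex <- c("memory loss", "confusion", "forgetfulness")
  a <- match_query(text, lex)
  b <- match_query(text, rev(lex))
  expect_equal(a, b)
  expect_equal(match_query(text, c(lex, lex)), a)
})

test_that("every generated complaint note is retrieved by the symptom lexicon", {
  lex <- names(load_lexicons()$symptom)
  notes <- notes_small()
  has_sx <- vapply(notes, function(n) any(n$entities$label == "SX"), logical(1))
  retrieved <- retrieve_notes(notes[has_sx], lex)
  expect_true(all(retrieved))
})
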