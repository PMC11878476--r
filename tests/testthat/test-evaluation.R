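mk <- function(labels, starts, ends, doc = "d") {
  data.frame(doc_id = doc, label = labels, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

test_that("identical gold and prediction score perfectly", {
  g <- mk(c("SX", "DX", "RX"), c(0, 10, 20), c(5, 15, 25))
  rep <- metrics(match_entities(g, g))
  expect_equal(rep$precision, rep(1, nrow(rep)))
  expect_equal(rep$recall, rep(1, nrow(rep)))
  expect_equal(rep$f1, rep(1, nrow(rep)))
})

test_that("span shift distinguishes exact from overlap mode", {
  g <- mk(c("SX", "DX", "RX"), c(0, 10, 20), c(5, 15, 25))
  p <- mk(c("SX", "DX", "RX"), c(1, 11, 21), c(6, 16, 26))
  exact <- match_entities(g, p, mode = "exact")
  expect_equal(sum(exact$tp), 0)
  overlap <- match_entities(g, p, mode = "overlap")
  expect_equal(sum(overlap$tp), 3)
})

test_that("precision, recall and F1 follow the stated formulas", {
  # tp=9021, fp=279, fn=679 gives precision 0.97 and recall 0.93 exactly
  counts <- structure(data.frame(label = "SX", tp = 9021L, fp = 279L, fn = 679L),
                      class = c("confusion_counts", "data.frame"))
  rep <- metrics(counts)
  m <- rep[rep$label == "micro", ]
  expect_equal(m$precision, 0.97)
  expect_equal(m$recall, 0.93)
  expect_equal(m$f1, 2 * 0.97 * 0.93 / (0.97 + 0.93))
  expect_equal(round(m$f1, 2), 0.95)
  # tp=2, fp=1, fn=1 -> P=R=F1=2/3
  counts2 <- structure(data.frame(label = "SX", tp = 2L, fp = 1L, fn = 1L),
                       class = c("confusion_counts", "data.frame"))
  rep2 <- metrics(counts2)
  expect_equal(rep2$f1[1], 2 / 3)
})

test_that("empty denominators yield zero by convention", {
  counts <- structure(data.frame(label = "SX", tp = 0L, fp = 0L, fn = 0L),
                      class = c("confusion_counts", "data.frame"))
  rep <- metrics(counts)
  expect_equal(rep$precision, c(0, 0))
  expect_equal(rep$recall, c(0, 0))
  expect_equal(rep$f1, c(0, 0))
})

test_that("F1 lies between min and max of precision and recall", {
  set.seed(42)
  for (i in 1:50) {
    counts <- structure(data.frame(label = "X", tp = sample(0:20, 1),
                                   fp = sample(0:20, 1), fn = sample(0:20, 1)),
                        class = c("confusion_counts", "data.frame"))
    r <- metrics(counts)[1, ]
    expect_gte(r$f1, min(r$precision, r$recall) - 1e-12)
    expect_lte(r$f1, max(r$precision, r$recall) + 1e-12)
    expect_lte(r$f1, (r$precision + r$recall) / 2 + 1e-12)
  }
})

test_that("swapping gold and prediction swaps precision and recall", {
  set.seed(7)
  g <- mk(sample(c("SX", "DX"), 6, TRUE), seq(0, 50, 10), seq(4, 54, 10))
  p <- mk(sample(c("SX", "DX"), 5, TRUE), c(0, 10, 25, 30, 41), c(4, 14, 29, 34, 45))
  p <- p[!duplicated(paste(p$label, p$start)), ]
  a <- metrics(match_entities(g, p))
  b <- metrics(match_entities(p, g))
  am <- a[a$label == "micro", ]; bm <- b[b$label == "micro", ]
  expect_equal(am$precision, bm$recall)
  expect_equal(am$recall, bm$precision)
})

test_that("micro counts equal the sum of per-label counts", {
  g <- mk(c("SX", "SX", "DX", "RX"), c(0, 10, 20, 30), c(5, 15, 25, 35))
  p <- mk(c("SX", "DX", "DX"), c(0, 20, 40), c(5, 25, 45))
  rep <- metrics(match_entities(g, p))
  micro <- rep[rep$label == "micro", ]
  per <- rep[rep$label != "micro", ]
  expect_equal(micro$tp, sum(per$tp))
  expect_equal(micro$fp, sum(per$fp))
  expect_equal(micro$fn, sum(per$fn))
  # tp+fn = gold size, tp+fp = pred size
  expect_equal(micro$tp + micro$fn, nrow(g))
  expect_equal(micro$tp + micro$fp, nrow(p))
})

test_that("greedy matching equals brute-force optimal 1:1 matching in exact mode", {
  # in exact mode with unique gold spans, greedy is optimal; verify against
  # exhaustive assignment on small random documents
  set.seed(11)
  for (trial in 1:30) {
    ng <- sample(1:6, 1); np <- sample(1:6, 1)
    g <- mk(sample(c("A", "B"), ng, TRUE), starts <- sample(seq(0, 70, 10), ng),
            starts + 4)
    p <- mk(sample(c("A", "B"), np, TRUE), ps <- sample(seq(0, 70, 10), np), ps + 4)
    counts <- match_entities(g, p)
    tp_greedy <- sum(counts$tp)
    # brute force: maximum bipartite matching where pred i matches gold j iff
    # identical (label, span); equals count of multiset intersection
    gk <- paste(g$label, g$start, g$end)
    pk <- paste(p$label, p$start, p$end)
    tp_opt <- sum(pmin(table(factor(gk, unique(c(gk, pk)))),
                       table(factor(pk, unique(c(gk, pk))))))
    expect_equal(tp_greedy, tp_opt)
  }
})

test_that("duplicate identical gold spans are rejected", {
  g <- mk(c("SX", "SX"), c(0, 0), c(5, 5))
  p <- mk("SX", 0, 5)
  expect_error(match_entities(g, p), "duplicate")
})
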