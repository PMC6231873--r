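test_that("recommendation on a single-profile table is the trivial vote", {
  tab <- association_table("p1", "EMR", "D1", list(c("a", "b")))
  m <- cf_model(tab, "tani", "knn", k = 1)
  r <- recommend(c("a", "b"), m)
  expect_equal(as.data.frame(r), data.frame(disease_id = "D1", score = 1),
               ignore_attr = TRUE)
  # any overlapping query still returns the sole disease
  expect_equal(predict_top1("a", m), "D1")
  expect_error(recommend(character(), m), "empty")
})

test_that("equidistant neighbors split the vote and tie-break by disease id", {
  tab <- association_table(c("p1", "p2"), "EMR", c("D2", "D1"),
                           list(c("a", "b"), c("a", "c")))
  m <- cf_model(tab, "tani", "knn", k = 2)
  r <- recommend("a", m)
  expect_equal(r$disease_id, c("D1", "D2"))
  expect_equal(r$score, c(0.5, 0.5))
})

test_that("ranking matches a brute-force aggregation oracle on a toy table", {
  tab <- association_table(
    c("p1", "p2", "p3", "p4"), "EMR", c("D1", "D1", "D2", "D3"),
    list(c("a", "b", "c"), c("a", "b"), c("b", "c", "d"), c("e", "f"))
  )
  q <- c("a", "b", "d")
  for (k in 1:4) {
    m <- cf_model(tab, "tani", "knn", k = k)
    r <- recommend(q, m)
    # oracle: enumerate all similarities, take top k, weighted vote
    sims <- vapply(tab$phenotypes, function(p) oracle_similarity("tani", q, p),
                   numeric(1))
    ord <- order(-sims, tab$entity_id)[seq_len(k)]
    w <- pmax(sims[ord], 0)
    if (sum(w) == 0) w <- rep(1, length(w))
    agg <- tapply(w / sum(w), tab$disease_id[ord], sum)
    agg <- agg[order(-agg, names(agg), method = "radix")]
    expect_equal(r$disease_id, names(agg))
    expect_equal(r$score, as.numeric(agg))
  }
})

test_that("recommendation scores form a probability-like vector", {
  set.seed(21)
  for (i in 1:25) {
    tab <- random_assoc_table(sample(3:12, 1))
    q <- random_set(sprintf("h%02d", 1:12), max_size = 5)
    measure <- sample(c("tani", "ll", "ol", "fmg"), 1)
    m <- if (runif(1) < 0.5) cf_model(tab, measure, "knn", k = sample(1:6, 1))
         else cf_model(tab, measure, "tpn", t = runif(1, -0.2, 0.8))
    r <- recommend(q, m)
    expect_true(all(r$score >= 0))
    expect_lte(sum(r$score), 1 + 1e-12)
    expect_true(all(diff(r$score) <= 1e-12))
    expect_false(anyDuplicated(r$disease_id) > 0)
    if (nrow(r) > 0) expect_equal(sum(r$score), 1)
  }
})

test_that("recommendation is invariant to training-table storage order", {
  set.seed(31)
  tab <- random_assoc_table(10)
  perm <- sample(nrow(tab))
  tab2 <- association_table(tab$entity_id[perm], tab$source[perm],
                            tab$disease_id[perm], tab$phenotypes[perm])
  q <- c("h01", "h03", "h05")
  for (measure in c("tani", "ll")) {
    r1 <- recommend(q, cf_model(tab, measure, "knn", k = 4))
    r2 <- recommend(q, cf_model(tab2, measure, "knn", k = 4))
    expect_equal(as.data.frame(r1), as.data.frame(r2))
  }
})

test_that("an unreachable threshold yields an empty recommendation", {
  tab <- association_table(c("p1", "p2"), "EMR", c("D1", "D2"),
                           list("a", "b"))
  m <- cf_model(tab, "tani", "tpn", t = 2)
  expect_equal(nrow(recommend("a", m)), 0L)
  expect_true(is.na(predict_top1("a", m)))
})

test_that("model construction enforces the rule/parameter pairing", {
  tab <- association_table("p1", "EMR", "D1", list("a"))
  expect_error(cf_model(tab, "tani", "knn"), "k")
  expect_error(cf_model(tab, "tani", "tpn", k = 3), "t")
  expect_error(cf_model(tab, "tani", "knn", k = 3, t = 0.5), "k")
})

test_that("rmse is zero for a perfect predictor and matches hand arithmetic", {
  # two patients with disjoint signatures: scores are exactly 1 on truth,
  # 0 on the negative, so every rated cell has zero error
  tab <- association_table(c("p1", "p2", "p3", "p4"), "EMR",
                           c("D1", "D1", "D2", "D2"),
                           list(c("a", "b"), c("a", "b"), c("c", "d"),
                                c("c", "d")))
  m <- cf_model(tab, "tani", "knn", k = 1)
  pairs <- eval_pairs_from(tab)
  expect_equal(cf_rmse(m, pairs, negatives_per_positive = 1, seed = 2), 0)
  expect_error(cf_rmse(m, pairs, negatives_per_positive = -1), ">= 0")
})

test_that("rmse of a half-confident vote follows the closed form", {
  # every D1 query sees 2 D1 and 2 D2 neighbors of equal similarity, so
  # the predictor is a constant 0.5 on truth and on the sole negative:
  # RMSE = sqrt(mean(0.5^2)) = 0.5 exactly
  tab <- association_table(c("p1", "p2", "p3", "p4", "p5"), "EMR",
                           c("D1", "D1", "D1", "D2", "D2"),
                           list("a", "a", "a", "a", "a"))
  m <- cf_model(tab, "tani", "knn", k = 4)
  pairs <- eval_pairs_from(tab)
  pairs <- pairs[pairs$truth == "D1", ]
  expect_equal(cf_rmse(m, pairs, negatives_per_positive = 1, seed = 3), 0.5)
})

test_that("rmse equals a direct arithmetic oracle on a toy fixture", {
  tab <- association_table(c("p1", "p2", "p3"), "EMR", c("D1", "D2", "D1"),
                           list(c("a", "b"), c("b", "c"), c("a", "c")))
  m <- cf_model(tab, "tani", "knn", k = 2)
  pairs <- eval_pairs_from(tab)
  got <- cf_rmse(m, pairs, negatives_per_positive = 0, seed = 1)
  sq <- numeric(0)
  for (i in seq_len(nrow(pairs))) {
    r <- recommend(pairs$phenotypes[[i]], m, query_id = pairs$query_id[[i]])
    s <- r$score[r$disease_id == pairs$truth[[i]]]
    if (length(s) == 0) s <- 0
    sq <- c(sq, (1 - s)^2)
  }
  expect_equal(got, sqrt(mean(sq)))
})

test_that("tuning selects the grid argmin deterministically", {
  tab <- association_table(c("p1", "p2", "p3", "p4"), "EMR",
                           c("D1", "D1", "D2", "D2"),
                           list(c("a", "b"), c("a", "b"), c("b", "c"),
                                c("b", "c")))
  pairs <- eval_pairs_from(tab)
  tn <- tune_neighborhood(tab, "tani", "knn", pairs, grid = 3L, seed = 9)
  expect_equal(tn$optimal, 3L)
  # k = 1 reconstructs ratings exactly (rmse 0) and must win over k = 3
  tn2 <- tune_neighborhood(tab, "tani", "knn", pairs, grid = c(3L, 1L),
                           seed = 9)
  expect_equal(tn2$optimal, 1L)
  expect_equal(min(tn2$grid$rmse), 0)
  expect_error(tune_neighborhood(tab, "tani", "knn", pairs,
                                 grid = numeric(0)), "empty")
  # grid rmse agrees with cf_rmse at the same seed, point by point
  m3 <- cf_model(tab, "tani", "knn", k = 3)
  expect_equal(tn2$grid$rmse[tn2$grid$value == 3],
               cf_rmse(m3, pairs, seed = 9))
})

test_that("tuning curves are bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_diseases = 4, signature_size = 5,
                    patients_per_disease = 5, phenotype_dropout = 0.2,
                    noise_phenotypes_per_patient = 1, seed = 17)
  corpus <- build_corpus(cfg)
  pairs <- eval_pairs_from(corpus$emr, n = 10, seed = 2)
  t1 <- tune_neighborhood(corpus$emr, "tani", "knn", pairs, grid = 1:10,
                          seed = 5)
  t2 <- tune_neighborhood(corpus$emr, "tani", "knn", pairs, grid = 1:10,
                          seed = 5)
  expect_identical(t1$grid, t2$grid)
  expect_equal(t1$optimal, t1$grid$value[[which.min(t1$grid$rmse)]])
})

test_that("signature-true literature never hurts noise-free accuracy", {
  cfg <- sim_config(n_diseases = 6, signature_size = 6,
                    patients_per_disease = 6, phenotype_dropout = 0,
                    noise_phenotypes_per_patient = 0, n_lit_docs = 100,
                    lit_fidelity = 1, seed = 23)
  corpus <- build_corpus(cfg)
  queries <- eval_pairs_from(corpus$emr, n = 12, seed = 3)
  acc <- function(tab) {
    m <- cf_model(tab, "tani", "knn", k = 5)
    mean(vapply(seq_len(nrow(queries)), function(i) {
      identical(predict_top1(queries$phenotypes[[i]], m,
                             query_id = queries$query_id[[i]]),
                queries$truth[[i]])
    }, logical(1)))
  }
  a_emr <- acc(corpus$emr)
  a_pl <- acc(fuse_emr_pl(corpus$emr, corpus$lit, seed = 1))
  expect_equal(a_emr, 1)
  expect_gte(a_pl, a_emr)
})
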