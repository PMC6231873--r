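ranked_from_fix <- function(fix) {
  rows <- lapply(seq_along(fix), function(q) {
    nr <- length(fix[[q]]$rel)
    truth <- sprintf("T%d", q)
    dis <- ifelse(fix[[q]]$rel, truth, sprintf("N%d_%d", q, seq_len(nr)))
    tibble::tibble(query_id = sprintf("q%02d", q), truth = truth,
                   rank = seq_len(nr), disease_id = dis,
                   score = fix[[q]]$score)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ranked_results", class(out))
  out
}

test_that("perfect rankings give MAP and PRAUC of exactly 1", {
  fix <- lapply(1:5, function(q) list(rel = c(TRUE, FALSE, FALSE),
                                      score = c(1, 0.4, 0.2)))
  ranked <- ranked_from_fix(fix)
  mc <- string_criterion(unique(c(ranked$disease_id, ranked$truth)))
  expect_equal(mean_average_precision(ranked, mc), 1)
  expect_equal(pr_curve(ranked, mc)$prauc, 1)
})

test_that("a single query with the relevant item last matches hand enumeration", {
  fix <- list(list(rel = c(FALSE, FALSE, FALSE, TRUE),
                   score = c(0.9, 0.7, 0.5, 0.3)))
  ranked <- ranked_from_fix(fix)
  mc <- string_criterion(unique(c(ranked$disease_id, ranked$truth)))
  pr <- pr_curve(ranked, mc)
  # thresholds 0.9, 0.7, 0.5, 0.3: precision 0/1, 0/2, 0/3, 1/4; recall
  # 0, 0, 0, 1
  expect_equal(pr$points$precision, c(0, 0, 0, 0.25))
  expect_equal(pr$points$recall, c(0, 0, 0, 1))
  expect_equal(pr$prauc, oracle_prauc(fix))
  expect_equal(mean_average_precision(ranked, mc), 0.25)
})

test_that("MAP follows the average-precision arithmetic", {
  fix <- list(list(rel = c(TRUE, FALSE), score = c(0.8, 0.6)),
              list(rel = c(FALSE, TRUE), score = c(0.9, 0.5)))
  ranked <- ranked_from_fix(fix)
  mc <- string_criterion(unique(c(ranked$disease_id, ranked$truth)))
  expect_equal(mean_average_precision(ranked, mc), (1 + 0.5) / 2)
  # a query with nothing relevant retrieved contributes AP 0
  fix3 <- c(fix, list(list(rel = c(FALSE, FALSE), score = c(0.7, 0.6))))
  expect_equal(mean_average_precision(ranked_from_fix(fix3),
                                      string_criterion(c(
                                        unique(c(ranked$disease_id, ranked$truth)),
                                        "T3", "N3_1", "N3_2"))),
               (1 + 0.5 + 0) / 3)
  # n_queries accounts for queries with empty recommendations
  expect_equal(mean_average_precision(ranked, mc, n_queries = 3), 0.5)
})

test_that("MAP and PRAUC match brute-force oracles on random fixtures", {
  set.seed(11)
  for (i in 1:100) {
    rf <- random_ranked_fixture()
    mc <- match_criterion("string", rf$vocab)
    expect_equal(mean_average_precision(rf$ranked, mc), oracle_map(rf$fix),
                 tolerance = 1e-9)
    if (any(unlist(lapply(rf$fix, `[[`, "rel")))) {
      expect_equal(pr_curve(rf$ranked, mc)$prauc, oracle_prauc(rf$fix),
                   tolerance = 1e-9)
    } else {
      expect_error(pr_curve(rf$ranked, mc), "undefined")
    }
  }
})

test_that("PRAUC is invariant to duplicating every query", {
  set.seed(19)
  for (i in 1:10) {
    rf <- random_ranked_fixture(max_queries = 5)
    if (!any(unlist(lapply(rf$fix, `[[`, "rel")))) next
    mc <- match_criterion("string", rf$vocab)
    doubled <- rf$ranked
    doubled$query_id <- paste0(doubled$query_id, "_copy")
    both <- rbind(rf$ranked, doubled)
    class(both) <- class(rf$ranked)
    expect_equal(pr_curve(both, mc)$prauc, pr_curve(rf$ranked, mc)$prauc,
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant to query order", {
  rf <- random_ranked_fixture()
  mc <- match_criterion("string", rf$vocab)
  perm <- rf$ranked[sample(nrow(rf$ranked)), ]
  class(perm) <- class(rf$ranked)
  expect_equal(mean_average_precision(perm, mc),
               mean_average_precision(rf$ranked, mc))
  if (any(unlist(lapply(rf$fix, `[[`, "rel")))) {
    expect_equal(pr_curve(perm, mc)$prauc, pr_curve(rf$ranked, mc)$prauc)
  }
})

test_that("per-disease precision/recall/F follows the confusion counts", {
  ids <- c("D1", "D2")
  mc <- string_criterion(ids)
  preds <- tibble::tibble(query_id = c("q1", "q2", "q3"),
                          predicted = c("D1", "D1", "D2"),
                          truth = c("D1", "D1", "D1"))
  prf <- disease_prf(preds, mc, min_patients = 3)
  d1 <- prf$per_disease[prf$per_disease$disease_id == "D1", ]
  expect_equal(d1$recall, 2 / 3)
  expect_equal(d1$precision, 1)
  expect_equal(d1$f, 0.8)
  expect_equal(prf$macro_f, 0.8)  # only D1 has >= 3 affected patients

  all_right <- tibble::tibble(query_id = c("a", "b", "c", "d", "e", "f"),
                              predicted = rep(c("D1", "D2"), each = 3),
                              truth = rep(c("D1", "D2"), each = 3))
  prf2 <- disease_prf(all_right, mc, min_patients = 3)
  expect_true(all(prf2$per_disease$f == 1))
  expect_equal(prf2$macro_f, 1)
})

test_that("category matching turns same-category predictions into TPs", {
  vocab <- nested_disease_vocab()
  preds <- tibble::tibble(query_id = c("q1", "q2", "q3"),
                          predicted = c("D5", "D5", "D1"),
                          truth = c("D1", "D1", "D1"))
  str_f <- disease_prf(preds, match_criterion("string", vocab),
                       min_patients = 3)$macro_f
  cat_f <- disease_prf(preds, match_criterion("category", vocab),
                       min_patients = 3)$macro_f
  expect_equal(str_f, 2 * (1 * 1/3) / (1 + 1/3))  # only the exact hit counts
  expect_equal(cat_f, 1)                          # D5 shares D1's category
  expect_gte(cat_f, str_f)
})

test_that("relaxing the criterion never lowers MAP, PRAUC or macro-F", {
  # nested fixture: concept twins share a category, so match sets nest
  cfg <- sim_config(n_diseases = 8, signature_size = 6,
                    patients_per_disease = 8, phenotype_dropout = 0.25,
                    noise_phenotypes_per_patient = 2,
                    concept_twin_fraction = 1, n_categories = 2, seed = 29)
  corpus <- build_corpus(cfg)
  m <- cf_model(corpus$emr, "tani", "knn", k = 5)
  queries <- eval_pairs_from(corpus$emr, n = 20, seed = 4)
  rep <- evaluate_model(m, queries, corpus$vocabs$diseases,
                        min_patients = 1)
  maps <- vapply(rep$criteria, `[[`, numeric(1), "map")
  fs <- vapply(rep$criteria, `[[`, numeric(1), "macro_f")
  expect_true(all(diff(maps) >= -1e-12))
  expect_true(all(diff(fs) >= -1e-12))
  # pooled PRAUC is only approximately monotone: relaxation also grows the
  # recall denominator, so it may dip by a vanishing amount
  praucs <- vapply(rep$criteria, `[[`, numeric(1), "prauc")
  expect_true(all(diff(praucs) >= -0.01))
})
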