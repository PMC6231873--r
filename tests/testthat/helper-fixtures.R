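# Shared fixture builders and independent brute-force oracles. Oracles are
# deliberately written as plain loops over explicit enumerations so they
# share no code path with the package implementation.

random_set <- function(universe, min_size = 1L, max_size = length(universe)) {
  n <- sample(min_size:max_size, 1L)
  sample(universe, n)
}

random_assoc_table <- function(n_entities, universe = sprintf("h%02d", 1:12),
                               diseases = sprintf("D%d", 1:4),
                               source = "EMR", prefix = "e") {
  if (n_entities == 0) return(association_table())
  association_table(
    entity_id = sprintf("%s%03d", prefix, seq_len(n_entities)),
    source = source,
    disease_id = sample(diseases, n_entities, replace = TRUE),
    phenotypes = replicate(n_entities, random_set(universe, max_size = 6L),
                           simplify = FALSE)
  )
}

# --- similarity oracle: explicit 2x2 contingency matrix ---------------------

oracle_similarity <- function(measure, a, b, N = NULL) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0) return(0)
  k11 <- 0
  for (x in a) if (x %in% b) k11 <- k11 + 1
  k12 <- length(a) - k11
  k21 <- length(b) - k11
  if (measure == "tani") return(k11 / (k11 + k12 + k21))
  if (measure == "ol") return(k11 / min(length(a), length(b)))
  if (measure == "fmg") {
    return(k11 / sqrt(length(a) * length(b)) -
             1 / (2 * sqrt(max(length(a), length(b)))))
  }
  if (measure == "ll") {
    k22 <- N - (k11 + k12 + k21)
    tab <- matrix(c(k11, k12, k21, k22), nrow = 2, byrow = TRUE)
    g2 <- 0
    for (i in 1:2) for (j in 1:2) {
      k <- tab[i, j]
      if (k > 0) g2 <- g2 + 2 * k * log(k * N / (sum(tab[i, ]) * sum(tab[, j])))
    }
    if (g2 < 0) g2 <- 0
    return(1 - 1 / (1 + g2))
  }
  stop("unknown measure in oracle")
}

# --- retrieval-metric oracles -----------------------------------------------

# `fix`: list of queries, each list(rel = logical vector in rank order,
# score = numeric vector, descending within the query).
oracle_map <- function(fix) {
  aps <- numeric(length(fix))
  for (q in seq_along(fix)) {
    rel <- fix[[q]]$rel
    precs <- c()
    hits <- 0
    for (r in seq_along(rel)) {
      if (rel[r]) {
        hits <- hits + 1
        precs <- c(precs, hits / r)
      }
    }
    aps[q] <- if (length(precs) == 0) 0 else mean(precs)
  }
  mean(aps)
}

# Pooled PR sweep over distinct score thresholds; trapezoid anchored flat
# at (0, first precision).
oracle_prauc <- function(fix) {
  score <- unlist(lapply(fix, `[[`, "score"))
  rel <- unlist(lapply(fix, `[[`, "rel"))
  total_rel <- sum(rel)
  thresholds <- sort(unique(score), decreasing = TRUE)
  recall <- precision <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    retrieved <- score >= thresholds[i]
    tp <- sum(rel & retrieved)
    precision[i] <- tp / sum(retrieved)
    recall[i] <- tp / total_rel
  }
  xs <- c(0, recall)
  ys <- c(precision[1], precision)
  auc <- 0
  for (i in seq_along(recall)) {
    auc <- auc + (xs[i + 1] - xs[i]) * (ys[i + 1] + ys[i]) / 2
  }
  auc
}

# Random ranked fixture + the equivalent ranked_results table. Scores are
# drawn on a coarse grid so cross-query ties occur.
random_ranked_fixture <- function(max_queries = 10L, max_ranks = 8L) {
  nq <- sample(1:max_queries, 1L)
  fix <- list()
  rows <- list()
  dis_pool <- sprintf("D%d", 1:(max_ranks + 2L))
  for (q in seq_len(nq)) {
    nr <- sample(1:max_ranks, 1L)
    score <- sort(sample(seq(0.05, 1, by = 0.05), nr), decreasing = TRUE)
    truth <- sprintf("T%d", q)
    cand <- sample(c(dis_pool, truth))[seq_len(nr)]
    fix[[q]] <- list(rel = cand == truth, score = score)
    rows[[q]] <- tibble::tibble(query_id = sprintf("q%02d", q), truth = truth,
                                rank = seq_len(nr), disease_id = cand,
                                score = score)
  }
  ranked <- do.call(rbind, rows)
  class(ranked) <- c("ranked_results", class(ranked))
  list(fix = fix, ranked = ranked,
       vocab = vocabulary(unique(c(ranked$disease_id, ranked$truth)),
                          unique(c(ranked$disease_id, ranked$truth))))
}

# Identity criterion over whatever diseases a fixture mentions.
string_criterion <- function(ids) {
  match_criterion("string", vocabulary(ids, ids))
}

# Small nested-structure vocabulary: D1/D2 synonyms (string match), D3
# shares D1's concept, D5 shares D1's category only.
nested_disease_vocab <- function() {
  vocabulary(
    term_id = c("D1", "D2", "D3", "D4", "D5"),
    name = c("alpha syndrome", "alpha disease", "beta syndrome",
             "gamma disease", "delta disease"),
    synonyms = list("alpha disease", "alpha syndrome", character(),
                    character(), character()),
    concept_key = c("C1", "C1", "C1", "C2", NA),
    categories = list("cat1", c("cat1", "cat2"), "cat1", "cat2", "cat1")
  )
}
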