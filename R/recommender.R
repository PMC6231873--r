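#' Build a collaborative-filtering recommender model
#'
#' Binds a (fused) association table to a similarity measure and a
#' neighborhood rule. The log-likelihood universe size `N` — the number of
#' distinct phenotypes in the table — is fixed here, at model build.
#'
#' @param table An `assoc_table` of training profiles.
#' @param measure One of `"tani"`, `"ll"`, `"ol"`, `"fmg"`.
#' @param neighborhood `"knn"` or `"tpn"`.
#' @param k Neighbor count (required iff `neighborhood = "knn"`).
#' @param t Similarity threshold (required iff `neighborhood = "tpn"`).
#' @return A list of class `cf_model`.
#' @examples
#' tab <- association_table(c("p1", "p2"), "EMR", c("D1", "D2"),
#'                          list(c("h1", "h2"), c("h2", "h3")))
#' m <- cf_model(tab, "tani", "knn", k = 1)
#' recommend(c("h1", "h2"), m)
#' @export
cf_model <- function(table, measure = SIM_MEASURES,
                     neighborhood = c("knn", "tpn"), k = NULL, t = NULL) {
  measure <- match.arg(measure)
  neighborhood <- match.arg(neighborhood)
  if (nrow(table) == 0) stop("training table is empty", call. = FALSE)
  if (neighborhood == "knn" && (is.null(k) || !is.null(t))) {
    stop("knn needs `k` (and no `t`)", call. = FALSE)
  }
  if (neighborhood == "tpn" && (is.null(t) || !is.null(k))) {
    stop("tpn needs `t` (and no `k`)", call. = FALSE)
  }
  structure(list(
    table = table,
    measure = measure,
    neighborhood = neighborhood,
    parameter = if (neighborhood == "knn") k else t,
    N = length(unique(unlist(table$phenotypes, use.names = FALSE))),
    disease_of = setNames(table$disease_id, table$entity_id)
  ), class = "cf_model")
}

#' @export
print.cf_model <- function(x, ...) {
  cat("<cf_model> ", x$measure, " + ", x$neighborhood,
      "(", if (x$neighborhood == "knn") "k=" else "t=", x$parameter, "), ",
      nrow(x$table), " profiles, ", x$N, " phenotypes\n", sep = "")
  invisible(x)
}

select_neighbors <- function(s, model) {
  if (model$neighborhood == "knn") knn_neighbors(s, model$parameter)
  else tpn_neighbors(s, model$parameter)
}

# Similarity-weighted vote over a neighbor list. Negative similarities
# carry no vote; an all-zero neighborhood falls back to a uniform vote so
# selected neighbors still count. Returns a ranked tibble(disease_id, score)
# with scores summing to 1 (or an empty tibble for an empty neighborhood).
aggregate_neighbors <- function(neighbors, disease_of, top_n = Inf) {
  if (nrow(neighbors) == 0) {
    out <- tibble::tibble(disease_id = character(), score = numeric())
    attr(out, "provenance") <- list()
    return(out)
  }
  w <- pmax(neighbors$score, 0)
  if (sum(w) == 0) w <- rep(1, length(w))
  w <- w / sum(w)
  dis <- unname(disease_of[neighbors$neighbor_id])
  score <- vapply(split(w, dis), sum, numeric(1))
  ord <- radix_order(-score, names(score))
  out <- tibble::tibble(disease_id = names(score)[ord],
                        score = unname(score)[ord])
  prov <- split(neighbors$neighbor_id, dis)[out$disease_id]
  out <- out[seq_len(min(top_n, nrow(out))), ]
  attr(out, "provenance") <- prov[out$disease_id]
  out
}

#' Rank candidate diseases for a query phenotype set
#'
#' Scores the query against every training profile, selects neighbors with
#' the model's rule, and turns neighbor diagnosis labels into disease
#' scores by a normalized similarity-weighted vote:
#' `score(d) = sum of similarities of neighbors labeled d / sum over all
#' selected neighbors`. Diseases are ranked by score, ties broken by
#' ascending disease id.
#'
#' @param query Non-empty character vector of phenotype ids.
#' @param model A `cf_model`.
#' @param top_n Maximum number of diseases returned.
#' @param query_id Optional entity id excluded from the neighborhood (use
#'   when the query is itself a training profile).
#' @return A `tbl_df` with columns `disease_id`, `score` (non-increasing,
#'   summing to at most 1), and a `provenance` attribute listing the
#'   contributing neighbor ids per disease. Empty when the neighborhood is
#'   empty.
#' @export
recommend <- function(query, model, top_n = Inf, query_id = NULL) {
  query <- unique(as.character(query))
  if (length(query) == 0) stop("query phenotype set is empty", call. = FALSE)
  s <- score_all(query, model$table, model$measure, N = model$N,
                 query_id = query_id)
  aggregate_neighbors(select_neighbors(s, model), model$disease_of, top_n)
}

#' Top-1 disease prediction for a query
#'
#' @inheritParams recommend
#' @return The highest-scoring disease id, or `NA_character_` when the
#'   neighborhood is empty.
#' @export
predict_top1 <- function(query, model, query_id = NULL) {
  r <- recommend(query, model, top_n = 1L, query_id = query_id)
  if (nrow(r) == 0) NA_character_ else r$disease_id[[1L]]
}

# Seeded negative sampling shared by cf_rmse and tune_neighborhood: for
# each eval pair, up to `npp` diseases other than the truth.
sample_negatives <- function(diseases, truths, npp, seed) {
  with_seed(seed, lapply(truths, function(tr) {
    pool <- setdiff(diseases, tr)
    pool[sample.int(length(pool), min(npp, length(pool)))]
  }))
}

rmse_from_recs <- function(recs, truths, negatives) {
  sq <- unlist(lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    sc <- setNames(r$score, r$disease_id)
    pick <- function(d) { v <- sc[d]; v[is.na(v)] <- 0; unname(v) }
    c((1 - pick(truths[[i]]))^2, pick(negatives[[i]])^2)
  }), use.names = FALSE)
  sqrt(mean(sq))
}

#' Root-mean-square error of rating reconstruction
#'
#' Leave-one-out protocol: each evaluation patient is scored against the
#' model with itself excluded; the predicted rating for its true diagnosis
#' (target 1) is the recommendation score, and for `negatives_per_positive`
#' sampled other diseases (target 0) likewise. RMSE is taken over all rated
#' cells. Binary diagnosis data has no explicit 0-ratings, hence the seeded
#' negative sampling.
#'
#' @param model A `cf_model`.
#' @param eval_pairs A data frame with columns `query_id`, `phenotypes`
#'   (list column), `truth` (disease id); see [eval_pairs_from()].
#' @param negatives_per_positive Sampled absent diseases per patient.
#' @param seed Seed for negative sampling.
#' @return RMSE, a non-negative scalar.
#' @export
cf_rmse <- function(model, eval_pairs, negatives_per_positive = 4L, seed = 1L) {
  if (nrow(eval_pairs) == 0) stop("eval_pairs is empty", call. = FALSE)
  if (negatives_per_positive < 0) {
    stop("negatives_per_positive must be >= 0", call. = FALSE)
  }
  negs <- sample_negatives(unique(model$table$disease_id), eval_pairs$truth,
                           negatives_per_positive, seed)
  recs <- lapply(seq_len(nrow(eval_pairs)), function(i) {
    recommend(eval_pairs$phenotypes[[i]], model,
              query_id = eval_pairs$query_id[[i]])
  })
  rmse_from_recs(recs, eval_pairs$truth, negs)
}

#' Evaluation pairs from a table's EMR profiles
#'
#' @param table An `assoc_table`.
#' @param n Optional subsample size (seeded).
#' @param seed Seed for the subsample.
#' @return A `tbl_df` with columns `query_id`, `phenotypes`, `truth`.
#' @export
eval_pairs_from <- function(table, n = NULL, seed = 1L) {
  emr <- table[table$source == "EMR", ]
  idx <- seq_len(nrow(emr))
  if (!is.null(n) && n < length(idx)) {
    idx <- sort(with_seed(seed, sample(idx, n)))
  }
  tibble::tibble(query_id = emr$entity_id[idx],
                 phenotypes = emr$phenotypes[idx],
                 truth = emr$disease_id[idx])
}

#' Default parameter grids for neighborhood tuning
#'
#' `k` from 1 to 15 for KNN; thresholds 0.05 to 0.95 in steps of 0.05 for
#' TPN.
#'
#' @param neighborhood `"knn"` or `"tpn"`.
#' @return Numeric vector of grid values.
#' @export
default_grid <- function(neighborhood = c("knn", "tpn")) {
  switch(match.arg(neighborhood), knn = 1:15, tpn = seq(0.05, 0.95, by = 0.05))
}

#' Tune the neighborhood parameter by RMSE
#'
#' Evaluates [cf_rmse()] at every grid value with an identical evaluation
#' split and identical sampled negatives (same seed), and picks the argmin
#' (first occurrence on ties). Similarity score maps are computed once and
#' reused across the grid.
#'
#' @param table Training `assoc_table`.
#' @param measure Similarity measure token.
#' @param neighborhood `"knn"` or `"tpn"`.
#' @param eval_pairs As in [cf_rmse()].
#' @param grid Candidate parameter values; default [default_grid()].
#' @param negatives_per_positive,seed As in [cf_rmse()].
#' @return A list of class `cf_tuning`: `grid` (a `tbl_df` of `value`,
#'   `rmse`), `optimal`, `neighborhood`, `measure`, and the
#'   `negatives_per_positive`/`seed` needed to regenerate the curve.
#' @export
tune_neighborhood <- function(table, measure, neighborhood, eval_pairs,
                              grid = default_grid(neighborhood),
                              negatives_per_positive = 4L, seed = 1L) {
  if (length(grid) == 0) stop("empty tuning grid", call. = FALSE)
  neighborhood <- match.arg(neighborhood, c("knn", "tpn"))
  N <- length(unique(unlist(table$phenotypes, use.names = FALSE)))
  disease_of <- setNames(table$disease_id, table$entity_id)
  maps <- lapply(seq_len(nrow(eval_pairs)), function(i) {
    score_all(eval_pairs$phenotypes[[i]], table, measure, N = N,
              query_id = eval_pairs$query_id[[i]])
  })
  negs <- sample_negatives(unique(table$disease_id), eval_pairs$truth,
                           negatives_per_positive, seed)
  rmse <- vapply(grid, function(v) {
    recs <- lapply(maps, function(s) {
      nb <- if (neighborhood == "knn") knn_neighbors(s, v) else tpn_neighbors(s, v)
      aggregate_neighbors(nb, disease_of)
    })
    rmse_from_recs(recs, eval_pairs$truth, negs)
  }, numeric(1))
  structure(list(
    grid = tibble::tibble(value = grid, rmse = rmse),
    optimal = grid[[which.min(rmse)]],
    neighborhood = neighborhood,
    measure = measure,
    negatives_per_positive = negatives_per_positive,
    seed = seed
  ), class = "cf_tuning")
}

#' @export
print.cf_tuning <- function(x, ...) {
  cat("<cf_tuning> ", x$measure, " + ", x$neighborhood, ": optimal ",
      if (x$neighborhood == "knn") "k = " else "t = ", x$optimal,
      " (rmse ", format(min(x$grid$rmse), digits = 4), ")\n", sep = "")
  invisible(x)
}
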