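#' Ranked recommendations for a set of evaluation queries
#'
#' Runs [recommend()] for every query (excluding the query's own profile
#' from the neighborhood) and returns the pooled long-format ranking used
#' by the retrieval metrics.
#'
#' @param model A `cf_model`.
#' @param queries A data frame with columns `query_id`, `phenotypes`
#'   (list column), `truth`; see [eval_pairs_from()].
#' @param top_n Ranks retained per query.
#' @return A `tbl_df` of class `ranked_results` with columns `query_id`,
#'   `truth`, `rank`, `disease_id`, `score`.
#' @export
rank_results <- function(model, queries, top_n = 10L) {
  parts <- lapply(seq_len(nrow(queries)), function(i) {
    r <- recommend(queries$phenotypes[[i]], model, top_n = top_n,
                   query_id = queries$query_id[[i]])
    if (nrow(r) == 0) return(NULL)
    tibble::tibble(query_id = queries$query_id[[i]],
                   truth = queries$truth[[i]],
                   rank = seq_len(nrow(r)),
                   disease_id = r$disease_id, score = r$score)
  })
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- tibble::tibble(query_id = character(), truth = character(),
                          rank = integer(), disease_id = character(),
                          score = numeric())
  }
  class(out) <- c("ranked_results", class(out))
  out
}

relevance_flags <- function(ranked, criterion) {
  diseases_match(ranked$disease_id, ranked$truth, criterion)
}

#' Pooled precision-recall curve and its area
#'
#' All (query, candidate) pairs are pooled and swept by descending score
#' threshold; at each distinct score, precision is TP/retrieved and recall
#' TP/(total relevant in the pool). The area is the trapezoid over the
#' achieved recall points, anchored flat at recall 0 with the first
#' point's precision (so a perfect ranking integrates to exactly 1).
#'
#' @param ranked A `ranked_results` table.
#' @param criterion A `match_criterion` deciding relevance of a candidate
#'   against the query's true diagnosis.
#' @return A list: `points` (`tbl_df` of `threshold`, `recall`,
#'   `precision`) and `prauc`.
#' @export
pr_curve <- function(ranked, criterion) {
  rel <- relevance_flags(ranked, criterion)
  total_rel <- sum(rel)
  if (total_rel == 0) {
    stop("no relevant items in the pooled ranking; PR metrics undefined",
         call. = FALSE)
  }
  ord <- radix_order(-ranked$score, ranked$query_id, ranked$disease_id)
  sc <- ranked$score[ord]; rel <- rel[ord]
  cum_tp <- cumsum(rel)
  at <- cumsum(rle(sc)$lengths)  # last index of each distinct threshold
  precision <- cum_tp[at] / at
  recall <- cum_tp[at] / total_rel
  prauc <- sum(diff(c(0, recall)) *
                 (c(precision[1L], head(precision, -1L)) + precision) / 2)
  list(points = tibble::tibble(threshold = sc[at], recall = recall,
                               precision = precision),
       prauc = prauc)
}

#' Mean average precision over queries
#'
#' Average precision of one query is the mean of precision-at-rank over
#' the ranks where a relevant disease appears (0 when no relevant disease
#' is retrieved); MAP averages over all queries, including those
#' contributing 0.
#'
#' @inheritParams pr_curve
#' @param n_queries Total number of evaluated queries; defaults to the
#'   number of distinct `query_id`s in `ranked`. Supply it when some
#'   queries produced empty recommendations (they count as AP 0).
#' @return MAP in `[0, 1]`.
#' @export
mean_average_precision <- function(ranked, criterion, n_queries = NULL) {
  if (nrow(ranked) == 0 && is.null(n_queries)) {
    stop("empty ranking", call. = FALSE)
  }
  rel <- relevance_flags(ranked, criterion)
  ap <- vapply(split(seq_len(nrow(ranked)), ranked$query_id), function(idx) {
    idx <- idx[order(ranked$rank[idx])]
    r <- rel[idx]
    hits <- which(r)
    if (length(hits) == 0) return(0)
    mean(cumsum(r)[hits] / hits)
  }, numeric(1))
  if (is.null(n_queries)) n_queries <- length(ap)
  if (n_queries < length(ap)) {
    stop("n_queries smaller than the number of queries in `ranked`",
         call. = FALSE)
  }
  sum(ap) / n_queries
}

#' Per-disease precision, recall and F-measure of top-1 predictions
#'
#' For each evaluated disease `d` (a truth label with at least
#' `min_patients` affected patients): TP are patients of `d` whose
#' prediction matches their truth under the criterion, FN are patients of
#' `d` predicted wrongly, and FP are predictions of `d` (by id) that do
#' not match the patient's truth. Zero-denominator cells score 0. The
#' macro F-measure is the unweighted mean F over evaluated diseases.
#' Because the criterion only ever converts errors into hits, every cell
#' improves monotonically as the criterion relaxes on vocabularies whose
#' match sets nest (string within concept within category).
#'
#' @param predictions A data frame with columns `query_id`, `predicted`
#'   (disease id or `NA`), `truth`.
#' @param criterion A `match_criterion`.
#' @param min_patients Minimum affected patients for a disease to be
#'   evaluated.
#' @return A list: `per_disease` (`tbl_df` of `disease_id`, `n_affected`,
#'   `precision`, `recall`, `f`) and `macro_f`.
#' @export
disease_prf <- function(predictions, criterion, min_patients = 3L) {
  truth <- predictions$truth
  pred <- predictions$predicted
  correct <- !is.na(pred) & diseases_match(pred, truth, criterion)
  n_aff <- vapply(unique(truth), function(d) sum(truth == d), integer(1))
  eval_dis <- sort(names(n_aff)[n_aff >= min_patients])
  rows <- lapply(eval_dis, function(d) {
    of_d <- truth == d
    tp <- sum(of_d & correct)
    fn <- sum(of_d & !correct)
    fp <- sum(!is.na(pred) & pred == d & !correct)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    tibble::tibble(disease_id = d, n_affected = sum(of_d),
                   precision = p, recall = r, f = f)
  })
  per_disease <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(per_disease)) {
    per_disease <- tibble::tibble(disease_id = character(),
                                  n_affected = integer(),
                                  precision = numeric(), recall = numeric(),
                                  f = numeric())
  }
  list(per_disease = per_disease,
       macro_f = if (nrow(per_disease) > 0) mean(per_disease$f) else NA_real_)
}

#' Full evaluation report for a model on held-out queries
#'
#' Computes, per matching criterion: the pooled PR curve and PRAUC, MAP,
#' and the per-disease precision/recall/F table with macro F.
#'
#' @param model A `cf_model`.
#' @param queries Evaluation queries as in [rank_results()].
#' @param disease_vocab `rarecf_vocab` backing the matching criteria.
#' @param criteria Subset of `c("string", "concept", "category")`.
#' @param top_n Ranks retained per query.
#' @param min_patients Passed to [disease_prf()].
#' @return A list of class `cf_report`: `ranked`, plus one entry per
#'   criterion with `map`, `prauc`, `pr_points`, `per_disease`, `macro_f`.
#' @export
evaluate_model <- function(model, queries, disease_vocab,
                           criteria = c("string", "concept", "category"),
                           top_n = 10L, min_patients = 3L) {
  ranked <- rank_results(model, queries, top_n = top_n)
  preds <- tibble::tibble(
    query_id = queries$query_id,
    predicted = ranked$disease_id[match(paste(queries$query_id, 1L),
                                        paste(ranked$query_id, ranked$rank))],
    truth = queries$truth
  )
  per_crit <- lapply(criteria, function(cr) {
    mc <- match_criterion(cr, disease_vocab)
    pr <- tryCatch(pr_curve(ranked, mc), error = function(e) NULL)
    prf <- disease_prf(preds, mc, min_patients = min_patients)
    list(criterion = cr,
         map = mean_average_precision(ranked, mc, n_queries = nrow(queries)),
         prauc = if (is.null(pr)) NA_real_ else pr$prauc,
         pr_points = if (is.null(pr)) NULL else pr$points,
         per_disease = prf$per_disease,
         macro_f = prf$macro_f)
  })
  structure(list(ranked = ranked, predictions = preds,
                 criteria = setNames(per_crit, criteria)),
            class = "cf_report")
}

#' @export
print.cf_report <- function(x, ...) {
  cat("<cf_report> ", length(unique(x$ranked$query_id)), " queries\n", sep = "")
  for (cr in x$criteria) {
    cat(sprintf("  %-9s MAP %.3f  PRAUC %s  macro-F %s\n", cr$criterion,
                cr$map,
                ifelse(is.na(cr$prauc), "NA", sprintf("%.3f", cr$prauc)),
                ifelse(is.na(cr$macro_f), "NA", sprintf("%.3f", cr$macro_f))))
  }
  invisible(x)
}
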