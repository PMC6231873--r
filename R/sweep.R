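FUSION_STRATEGIES <- c("emr", "emr_l", "emr_pl")

#' Fuse a corpus under one strategy
#'
#' @param corpus A `cf_corpus` (or any list with `emr` and `lit`
#'   `assoc_table`s).
#' @param strategy `"emr"` (EMR only), `"emr_l"` (raw mix with merged
#'   literature) or `"emr_pl"` (mix with EMR-pruned literature).
#' @param seed Permutation seed for the mixed strategies.
#' @return A fused `assoc_table`.
#' @export
fuse_corpus <- function(corpus, strategy = FUSION_STRATEGIES, seed = 1L) {
  strategy <- match.arg(strategy)
  switch(strategy,
         emr = corpus$emr,
         emr_l = fuse_emr_l(corpus$emr, corpus$lit, seed),
         emr_pl = fuse_emr_pl(corpus$emr, corpus$lit, seed))
}

#' Run one evaluation group end to end
#'
#' One group = one (strategy, measure, neighborhood) cell of the
#' experiment grid: fuse, apply the minimum-support filter, hold out a
#' fraction of EMR patients, tune the neighborhood parameter by RMSE on a
#' subsample of the training patients, then evaluate ranked
#' recommendations and top-1 predictions on the held-out patients under
#' the requested matching criteria. Identical inputs and seed give an
#' identical report.
#'
#' @param corpus A `cf_corpus`.
#' @param strategy,measure,neighborhood Group coordinates.
#' @param seed Master seed for the group (drives the fusion permutation,
#'   the held-out split, tuning subsample and negative sampling).
#' @param grid Tuning grid; default [default_grid()].
#' @param criteria Matching criteria to evaluate.
#' @param min_patients Minimum EMR patients per disease (support filter
#'   and per-disease F table).
#' @param test_fraction Fraction of EMR patients held out.
#' @param n_tune Tuning subsample size (training patients).
#' @param top_n Ranks retained per query.
#' @param negatives_per_positive Negative samples per patient in RMSE.
#' @return A list of class `cf_group_report`: group coordinates, dataset
#'   stats, `tuning`, `optimal`, `metrics` (a `tbl_df` with one row per
#'   criterion: `map`, `prauc`, `macro_f`), and the full `report`.
#' @export
run_group <- function(corpus, strategy = FUSION_STRATEGIES,
                      measure = SIM_MEASURES,
                      neighborhood = c("knn", "tpn"), seed = 1L,
                      grid = NULL,
                      criteria = c("string", "concept", "category"),
                      min_patients = 2L, test_fraction = 0.2,
                      n_tune = 50L, top_n = 10L,
                      negatives_per_positive = 4L) {
  strategy <- match.arg(strategy)
  measure <- match.arg(measure)
  neighborhood <- match.arg(neighborhood)
  if (strategy != "emr" && (is.null(corpus$lit) || nrow(corpus$lit) == 0)) {
    stop("strategy '", strategy, "' needs literature profiles in the corpus",
         call. = FALSE)
  }
  if (is.null(grid)) grid <- default_grid(neighborhood)
  fused <- fuse_corpus(corpus, strategy, seed)
  fused <- min_support_filter(fused, min_patients)
  emr_ids <- fused$entity_id[fused$source == "EMR"]
  n_test <- max(1L, round(test_fraction * length(emr_ids)))
  test_ids <- with_seed(seed + 1L, sort(sample(emr_ids, n_test)))
  train <- as_assoc_table(as.data.frame(fused)[!fused$entity_id %in% test_ids, ,
                                               drop = FALSE])
  test_tab <- fused[match(test_ids, fused$entity_id), ]
  queries <- tibble::tibble(query_id = test_tab$entity_id,
                            phenotypes = test_tab$phenotypes,
                            truth = test_tab$disease_id)
  tune_pairs <- eval_pairs_from(train, n = n_tune, seed = seed + 2L)
  tuning <- tune_neighborhood(train, measure, neighborhood, tune_pairs,
                              grid = grid,
                              negatives_per_positive = negatives_per_positive,
                              seed = seed + 3L)
  model <- if (neighborhood == "knn") {
    cf_model(train, measure, "knn", k = tuning$optimal)
  } else {
    cf_model(train, measure, "tpn", t = tuning$optimal)
  }
  report <- evaluate_model(model, queries, corpus$vocabs$diseases,
                           criteria = criteria, top_n = top_n,
                           min_patients = min_patients)
  metrics <- tibble::tibble(
    criterion = criteria,
    map = vapply(report$criteria, `[[`, numeric(1), "map"),
    prauc = vapply(report$criteria, `[[`, numeric(1), "prauc"),
    macro_f = vapply(report$criteria, `[[`, numeric(1), "macro_f")
  )
  structure(list(
    strategy = strategy, measure = measure, neighborhood = neighborhood,
    seed = seed,
    stats = table_stats(fused, corpus$vocabs$diseases),
    n_train = nrow(train), n_test = nrow(queries),
    tuning = tuning, optimal = tuning$optimal,
    metrics = metrics, report = report
  ), class = "cf_group_report")
}

#' @export
print.cf_group_report <- function(x, ...) {
  cat("<cf_group_report> ", x$measure, "+", x$neighborhood, " on ",
      x$strategy, " (optimal ",
      if (x$neighborhood == "knn") "k=" else "t=", x$optimal, ")\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' Enumerate the full evaluation grid
#'
#' The cross of 4 similarity measures, 2 neighborhood rules and 3 fusion
#' strategies: 24 groups.
#'
#' @return A `tbl_df` with columns `measure`, `neighborhood`, `strategy`.
#' @export
sweep_groups <- function() {
  g <- expand.grid(strategy = FUSION_STRATEGIES,
                   neighborhood = c("knn", "tpn"),
                   measure = SIM_MEASURES,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tibble::as_tibble(g[, c("measure", "neighborhood", "strategy")])
}

#' Run the full 24-group sweep
#'
#' Calls [run_group()] on every cell of [sweep_groups()] with a shared
#' seed. Groups are independent; running them in any order yields the
#' same per-group results.
#'
#' @param corpus A `cf_corpus`.
#' @param seed Master seed applied to every group.
#' @param ... Passed on to [run_group()].
#' @return A list of class `cf_sweep`: `summary` (one row per group with
#'   the optimal parameter and per-criterion MAP/PRAUC/macro-F) and
#'   `reports` (named list of `cf_group_report`s).
#' @export
run_sweep <- function(corpus, seed = 1L, ...) {
  groups <- sweep_groups()
  reports <- lapply(seq_len(nrow(groups)), function(i) {
    run_group(corpus, strategy = groups$strategy[[i]],
              measure = groups$measure[[i]],
              neighborhood = groups$neighborhood[[i]], seed = seed, ...)
  })
  names(reports) <- paste(groups$measure, groups$neighborhood,
                          groups$strategy, sep = "_")
  summary <- do.call(rbind, lapply(reports, function(r) {
    m <- r$metrics
    tibble::tibble(
      measure = r$measure, neighborhood = r$neighborhood,
      strategy = r$strategy, optimal = r$optimal,
      map_string = m$map[m$criterion == "string"],
      map_concept = m$map[m$criterion == "concept"],
      map_category = m$map[m$criterion == "category"],
      prauc_category = m$prauc[m$criterion == "category"],
      macro_f_category = m$macro_f[m$criterion == "category"]
    )
  }))
  rownames(summary) <- NULL
  structure(list(summary = tibble::as_tibble(summary), reports = reports,
                 seed = seed),
            class = "cf_sweep")
}

#' @export
print.cf_sweep <- function(x, ...) {
  cat("<cf_sweep> ", nrow(x$summary), " groups, seed ", x$seed, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Serialize a sweep or group report to JSON
#'
#' Deterministic serialization: the same report always produces the same
#' bytes, so reports can be diffed across runs.
#'
#' @param x A `cf_sweep` or `cf_group_report`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(report_payload(x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

report_payload <- function(x) {
  if (inherits(x, "cf_sweep")) {
    return(list(seed = x$seed,
                summary = as.data.frame(x$summary),
                groups = lapply(x$reports, report_payload)))
  }
  if (inherits(x, "cf_group_report")) {
    return(list(
      strategy = x$strategy, measure = x$measure,
      neighborhood = x$neighborhood, seed = x$seed,
      stats = x$stats, n_train = x$n_train, n_test = x$n_test,
      optimal = x$optimal,
      tuning = as.data.frame(x$tuning$grid),
      metrics = as.data.frame(x$metrics),
      per_disease = lapply(x$report$criteria, function(cr) {
        as.data.frame(cr$per_disease)
      })
    ))
  }
  stop("unsupported report object", call. = FALSE)
}
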