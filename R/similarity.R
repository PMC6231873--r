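#' @section Similarity measures:
#' Four measures over binary phenotype sets, selected by the tokens
#' `"tani"`, `"ol"`, `"fmg"`, `"ll"`. Writing `c = |A` \eqn{\cap} `B|`,
#' `a = |A|`, `b = |B|`:
#' \itemize{
#'   \item Tanimoto: `c / (a + b - c)`, in `[0, 1]`.
#'   \item Overlap coefficient: `c / min(a, b)`, in `[0, 1]`.
#'   \item Fager-McGowan: `c / sqrt(a * b) - 1 / (2 * sqrt(max(a, b)))`,
#'     in `[-0.5, 1)`.
#'   \item Log-likelihood-ratio similarity: `1 - 1/(1 + G2)` where `G2` is
#'     Dunning's likelihood-ratio statistic of the 2x2 contingency table
#'     `(c, a - c, b - c, N - a - b + c)` over a phenotype universe of size
#'     `N`; in `[0, 1)`.
#' }
#' Any measure with an empty operand returns 0 (profiles are guaranteed
#' non-empty at ingest, so this is a total-function convention, not a
#' modeling statement).
#' @name similarity-measures
NULL

SIM_MEASURES <- c("tani", "ll", "ol", "fmg")

# Vectorized similarity from 2x2 contingency counts. `cc` = intersection
# size, `na`/`nb` = set sizes, `N` = phenotype universe (LL only; scalar).
sim_from_counts <- function(measure, cc, na_, nb, N = NULL) {
  empty <- na_ == 0L | nb == 0L
  out <- switch(measure,
    tani = {
      den <- na_ + nb - cc
      ifelse(den > 0, cc / den, 0)
    },
    ol = ifelse(empty, 0, cc / pmin(na_, nb)),
    fmg = ifelse(empty, 0,
                 cc / sqrt(as.numeric(na_) * nb) - 1 / (2 * sqrt(pmax(na_, nb)))),
    ll = {
      if (is.null(N)) stop("log-likelihood similarity needs a universe size N",
                           call. = FALSE)
      if (any(!empty & N < na_ + nb - cc)) {
        stop("universe size N (", N, ") smaller than a profile union",
             call. = FALSE)
      }
      k11 <- cc; k12 <- na_ - cc; k21 <- nb - cc; k22 <- N - na_ - nb + cc
      term <- function(k, rs, cs) {
        t <- numeric(length(k))
        pos <- k > 0
        t[pos] <- k[pos] * log(k[pos] * N / (rs[pos] * cs[pos]))
        t
      }
      r1 <- rep_len(as.numeric(na_), length(cc)); r2 <- N - r1
      c1 <- rep_len(as.numeric(nb), length(cc)); c2 <- N - c1
      g2 <- 2 * (term(k11, r1, c1) + term(k12, r1, c2) +
                 term(k21, r2, c1) + term(k22, r2, c2))
      g2 <- pmax(g2, 0)  # G2 >= 0 analytically; guard rounding
      ifelse(empty, 0, 1 - 1 / (1 + g2))
    },
    stop("unknown similarity measure '", measure, "'; use one of ",
         paste(SIM_MEASURES, collapse = ", "), call. = FALSE)
  )
  out[empty & measure != "ll"] <- 0
  out
}

set_counts <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  list(cc = sum(a %in% b), na_ = length(a), nb = length(b))
}

#' Tanimoto coefficient of two phenotype sets
#' @param a,b Character vectors treated as sets.
#' @return Similarity in `[0, 1]`; 1 iff the sets are equal, 0 if disjoint
#'   or either is empty.
#' @seealso [similarity-measures]
#' @export
tanimoto <- function(a, b) {
  k <- set_counts(a, b)
  sim_from_counts("tani", k$cc, k$na_, k$nb)
}

#' Overlap coefficient of two phenotype sets
#' @inheritParams tanimoto
#' @return Similarity in `[0, 1]`; 1 whenever one set contains the other.
#' @export
overlap_coefficient <- function(a, b) {
  k <- set_counts(a, b)
  sim_from_counts("ol", k$cc, k$na_, k$nb)
}

#' Fager-McGowan coefficient of two phenotype sets
#'
#' The chance-corrected overlap `c/sqrt(|a||b|) - 1/(2 sqrt(max(|a|,|b|)))`;
#' negative for weakly overlapping small sets.
#'
#' @inheritParams tanimoto
#' @return Similarity in `[-0.5, 1)`; 0 if either set is empty.
#' @export
fager_mcgowan <- function(a, b) {
  k <- set_counts(a, b)
  sim_from_counts("fmg", k$cc, k$na_, k$nb)
}

#' Log-likelihood-ratio similarity of two phenotype sets
#'
#' Builds the 2x2 contingency table of the two binary profiles over a
#' phenotype universe of `N` terms, computes Dunning's `G2` statistic
#' (zero-count cells contribute nothing) and maps it to `[0, 1)` via
#' `1 - 1/(1 + G2)`. `G2 = 0` — exact independence — gives similarity 0.
#'
#' @inheritParams tanimoto
#' @param N Universe size; must be at least `|a` \eqn{\cup} `b|`.
#' @return Similarity in `[0, 1)`.
#' @export
log_likelihood_similarity <- function(a, b, N) {
  k <- set_counts(a, b)
  if (k$na_ > 0 && k$nb > 0 && N < k$na_ + k$nb - k$cc) {
    stop("universe size N (", N, ") smaller than |union| (",
         k$na_ + k$nb - k$cc, ")", call. = FALSE)
  }
  sim_from_counts("ll", k$cc, k$na_, k$nb, N)
}

#' Score a query against every profile in a table
#'
#' Produces the sorted similarity score map consumed by the neighborhood
#' rules: one `(neighbor_id, score)` row per profile, sorted by descending
#' score with ties broken by ascending entity id. When `query_id` names a
#' profile in the table, that profile is excluded (leave-one-out hygiene).
#'
#' For the log-likelihood measure the universe `N` defaults to the number
#' of distinct phenotypes in `table`; query phenotypes unseen in the table
#' enlarge the universe for this call so the contingency table stays valid.
#'
#' @param query Character vector: the query phenotype set (non-empty).
#' @param table An `assoc_table`.
#' @param measure One of `"tani"`, `"ll"`, `"ol"`, `"fmg"`.
#' @param N Universe size for `"ll"`; default derived from `table`.
#' @param query_id Optional entity id to exclude from the map.
#' @return A `tbl_df` of class `score_map` with columns `neighbor_id`,
#'   `score`, plus a `query_id` attribute.
#' @export
score_all <- function(query, table, measure = SIM_MEASURES, N = NULL,
                      query_id = NULL) {
  measure <- match.arg(measure)
  query <- unique(as.character(query))
  if (length(query) == 0) stop("query phenotype set is empty", call. = FALSE)
  rows <- table
  if (!is.null(query_id)) rows <- rows[rows$entity_id != query_id, ]
  universe <- unique(unlist(rows$phenotypes, use.names = FALSE))
  if (measure == "ll") {
    if (is.null(N)) N <- length(universe)
    N <- N + sum(!query %in% universe)
  }
  cc <- vapply(rows$phenotypes, function(p) sum(p %in% query), integer(1))
  na_ <- lengths(rows$phenotypes)
  score <- sim_from_counts(measure, cc, na_, length(query), N)
  ord <- radix_order(-score, rows$entity_id)
  out <- tibble::tibble(neighbor_id = rows$entity_id[ord], score = score[ord])
  attr(out, "query_id") <- query_id
  class(out) <- c("score_map", class(out))
  out
}
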