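#' Build a disease-matching criterion
#'
#' Three increasingly relaxed notions of "the predicted disease counts as
#' the true one":
#' \describe{
#'   \item{string}{normalized display names equal, or either name appears
#'     among the other's synonyms.}
#'   \item{concept}{both diseases carry the same non-missing semantic
#'     equivalence key (a flat stand-in for ontology-level synonymy, e.g.
#'     "linear scleroderma" = "morphea"); a disease without a key matches
#'     only itself.}
#'   \item{category}{the diseases' system-category sets intersect (e.g.
#'     two distinct rare cancers).}
#' }
#' Identical disease ids match under every criterion.
#'
#' @param criterion `"string"`, `"concept"` or `"category"`.
#' @param disease_vocab A `rarecf_vocab` for all diseases that will be
#'   compared; must carry a `concept_key`/`categories` column when the
#'   corresponding criterion is chosen.
#' @return A list of class `match_criterion`.
#' @export
match_criterion <- function(criterion = c("string", "concept", "category"),
                            disease_vocab) {
  criterion <- match.arg(criterion)
  if (criterion == "concept" && is.null(disease_vocab[["concept_key"]])) {
    stop("concept matching needs a concept_key map in the disease vocabulary",
         call. = FALSE)
  }
  if (criterion == "category" && is.null(disease_vocab[["categories"]])) {
    stop("category matching needs a categories map in the disease vocabulary",
         call. = FALSE)
  }
  structure(list(
    criterion = criterion,
    ids = disease_vocab$term_id,
    name = setNames(normalize_term(disease_vocab$name), disease_vocab$term_id),
    synonyms = setNames(lapply(disease_vocab$synonyms, normalize_term),
                        disease_vocab$term_id),
    concept_key = setNames(disease_vocab$concept_key, disease_vocab$term_id),
    categories = setNames(disease_vocab$categories, disease_vocab$term_id)
  ), class = "match_criterion")
}

#' Test whether two diseases match under a criterion
#'
#' Vectorized over pairs: `d1` and `d2` are equal-length (or length-1
#' recycled) vectors of disease ids. `NA` ids never match.
#'
#' @param d1,d2 Disease id vectors.
#' @param criterion A `match_criterion`.
#' @return Logical vector.
#' @export
diseases_match <- function(d1, d2, criterion) {
  stopifnot(inherits(criterion, "match_criterion"))
  n <- max(length(d1), length(d2))
  d1 <- rep_len(as.character(d1), n)
  d2 <- rep_len(as.character(d2), n)
  ok <- !is.na(d1) & !is.na(d2)
  unknown <- unique(c(d1[ok], d2[ok]))
  unknown <- unknown[!unknown %in% criterion$ids]
  if (length(unknown) > 0) {
    stop("disease ids absent from the matching vocabulary: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  out <- rep(FALSE, n)
  same <- ok & d1 == d2
  out[same] <- TRUE
  todo <- which(ok & !same)
  if (length(todo) == 0) return(out)
  out[todo] <- switch(criterion$criterion,
    string = vapply(todo, function(i) {
      n1 <- criterion$name[[d1[[i]]]]; n2 <- criterion$name[[d2[[i]]]]
      n1 == n2 || n1 %in% criterion$synonyms[[d2[[i]]]] ||
        n2 %in% criterion$synonyms[[d1[[i]]]]
    }, logical(1)),
    concept = {
      k1 <- unname(criterion$concept_key[d1[todo]])
      k2 <- unname(criterion$concept_key[d2[todo]])
      !is.na(k1) & !is.na(k2) & k1 == k2
    },
    category = vapply(todo, function(i) {
      length(intersect(criterion$categories[[d1[[i]]]],
                       criterion$categories[[d2[[i]]]])) > 0
    }, logical(1))
  )
  out
}
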