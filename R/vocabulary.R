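#' Construct a term vocabulary
#'
#' A vocabulary maps opaque term identifiers to display names, synonyms and
#' (for diseases) the keys used by the concept and category matching
#' relaxations. Phenotype vocabularies typically leave `concept_key` and
#' `categories` empty.
#'
#' @param term_id Character vector of unique, non-empty identifiers.
#' @param name Character vector of non-empty display names.
#' @param synonyms List of character vectors (one per term), or `NULL`.
#' @param concept_key Character vector of semantic-equivalence keys
#'   (`NA` = the term only matches itself under concept matching), or `NULL`.
#' @param categories List of character vectors of system categories (may be
#'   empty per term), or `NULL`.
#' @return A `tbl_df` of class `rarecf_vocab` with one row per term.
#' @examples
#' vocabulary(c("RD:1", "RD:2"), c("morphea", "linear scleroderma"),
#'            concept_key = c("C1", "C1"))
#' @export
vocabulary <- function(term_id, name, synonyms = NULL, concept_key = NULL,
                       categories = NULL) {
  term_id <- as.character(term_id)
  name <- as.character(name)
  n <- length(term_id)
  if (length(name) != n) stop("term_id and name lengths differ", call. = FALSE)
  if (n > 0 && (anyNA(term_id) || any(!nzchar(term_id)))) {
    stop("term_id entries must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(term_id)) {
    stop("duplicate term_id in vocabulary: ",
         paste(unique(term_id[duplicated(term_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (n > 0 && (anyNA(name) || any(!nzchar(name)))) {
    stop("name entries must be non-empty", call. = FALSE)
  }
  norm_list <- function(x) {
    if (is.null(x)) x <- vector("list", n)
    if (!is.list(x)) stop("synonyms/categories must be a list", call. = FALSE)
    lapply(x, function(el) {
      el <- as.character(el)
      sort(unique(el[nzchar(el)]))
    })
  }
  if (is.null(concept_key)) concept_key <- rep(NA_character_, n)
  concept_key <- as.character(concept_key)
  concept_key[!is.na(concept_key) & !nzchar(concept_key)] <- NA_character_
  out <- tibble::tibble(
    term_id = term_id,
    name = name,
    synonyms = norm_list(synonyms),
    concept_key = concept_key,
    categories = norm_list(categories)
  )
  class(out) <- c("rarecf_vocab", class(out))
  out
}

#' Read a vocabulary table from TSV
#'
#' Expected columns: `term_id`, `name`, `synonyms`, `concept_key`,
#' `categories`, with synonyms and categories `|`-separated and an empty
#' `concept_key` meaning "no equivalence class".
#'
#' @param path Path to a UTF-8 TSV file with header.
#' @return A `rarecf_vocab`.
#' @export
read_vocabulary <- function(path) {
  fields <- read_tsv_fields(path, c("term_id", "name", "synonyms",
                                    "concept_key", "categories"))
  if (length(fields) == 0) return(vocabulary(character(), character()))
  vocabulary(
    term_id = vapply(fields, `[[`, "", 1L),
    name = vapply(fields, `[[`, "", 2L),
    synonyms = lapply(fields, function(f) split_bar(f[[3L]])),
    concept_key = vapply(fields, `[[`, "", 4L),
    categories = lapply(fields, function(f) split_bar(f[[5L]]))
  )
}

#' Write a vocabulary table to TSV
#'
#' Inverse of [read_vocabulary()]; `write_vocabulary` then `read_vocabulary`
#' round-trips exactly.
#'
#' @param vocab A `rarecf_vocab`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  lines <- c(
    paste(c("term_id", "name", "synonyms", "concept_key", "categories"),
          collapse = "\t"),
    vapply(seq_len(nrow(vocab)), function(i) {
      paste(c(vocab$term_id[[i]], vocab$name[[i]],
              paste(vocab$synonyms[[i]], collapse = "|"),
              if (is.na(vocab$concept_key[[i]])) "" else vocab$concept_key[[i]],
              paste(vocab$categories[[i]], collapse = "|")),
            collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

split_bar <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, "|", fixed = TRUE)[[1L]]
}

# Strict line-oriented TSV reader: returns a list of character vectors (one
# per data row) and errors with the 1-based file line number on a malformed
# row. Header must match `cols` exactly. A zero-byte file reads as empty.
read_tsv_fields <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (length(lines) == 0) return(list())
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, cols)) {
    stop("unexpected header in ", path, ": expected '",
         paste(cols, collapse = "\t"), "'", call. = FALSE)
  }
  if (length(lines) == 1L) return(list())
  out <- vector("list", length(lines) - 1L)
  for (i in seq_along(out)) {
    f <- strsplit(paste0(lines[[i + 1L]], "\t\x01"), "\t", fixed = TRUE)[[1L]]
    f <- f[-length(f)]  # sentinel keeps trailing empty fields
    if (length(f) != length(cols)) {
      stop("parse error in ", path, " at line ", i + 1L, ": expected ",
           length(cols), " tab-separated fields, found ", length(f),
           call. = FALSE)
    }
    out[[i]] <- f
  }
  out
}

# Normalized (name or synonym) -> term_id lookup for a vocabulary.
# Ambiguous strings (mapping to >1 term) resolve to the first term by id
# order; exact duplicates within a term are harmless.
vocab_lookup <- function(vocab) {
  keys <- c(normalize_term(vocab$name),
            normalize_term(unlist(vocab$synonyms, use.names = FALSE)))
  ids <- c(vocab$term_id,
           rep(vocab$term_id, lengths(vocab$synonyms)))
  ord <- radix_order(keys, ids)
  keys <- keys[ord]; ids <- ids[ord]
  keep <- !duplicated(keys)
  setNames(ids[keep], keys[keep])
}
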