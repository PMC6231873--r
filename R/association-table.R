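#' Construct an association table of phenotype profiles
#'
#' The central container: one row per entity (a patient or a merged
#' literature document), holding a binary phenotype set and a single
#' disease label. Phenotype sets are stored sorted and de-duplicated.
#'
#' @param entity_id Character vector of unique entity identifiers.
#' @param source Character vector, each `"EMR"` or `"LIT"` (recycled if
#'   length 1).
#' @param disease_id Character vector of disease labels, one per entity.
#' @param phenotypes List of non-empty character vectors of phenotype ids.
#' @return A `tbl_df` of class `assoc_table`.
#' @examples
#' association_table(c("patA", "patB"), "EMR", c("D1", "D2"),
#'                   list(c("h1", "h2"), "h2"))
#' @export
association_table <- function(entity_id = character(), source = character(),
                              disease_id = character(), phenotypes = list()) {
  entity_id <- unname(as.character(entity_id))
  n <- length(entity_id)
  if (n > 0 && length(source) == 1L) source <- rep(source, n)
  source <- unname(as.character(source))
  disease_id <- unname(as.character(disease_id))
  phenotypes <- unname(as.list(phenotypes))
  if (length(source) != n || length(disease_id) != n || length(phenotypes) != n) {
    stop("entity_id, source, disease_id and phenotypes lengths differ",
         call. = FALSE)
  }
  if (anyDuplicated(entity_id)) {
    stop("duplicate entity_id: ",
         paste(unique(entity_id[duplicated(entity_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (n > 0) {
    if (anyNA(entity_id) || any(!nzchar(entity_id))) {
      stop("entity_id entries must be non-empty", call. = FALSE)
    }
    bad <- !source %in% c("EMR", "LIT")
    if (any(bad)) {
      stop("source must be 'EMR' or 'LIT' (entity ",
           entity_id[which(bad)[1L]], ")", call. = FALSE)
    }
    if (anyNA(disease_id) || any(!nzchar(disease_id))) {
      stop("every profile needs exactly one non-empty disease label",
           call. = FALSE)
    }
  }
  phenotypes <- lapply(phenotypes, function(p) {
    p <- as.character(p)
    sort(unique(p[!is.na(p) & nzchar(p)]))
  })
  if (any(lengths(phenotypes) == 0L) && n > 0) {
    stop("profile with empty phenotype set: ",
         entity_id[which(lengths(phenotypes) == 0L)[1L]], call. = FALSE)
  }
  out <- tibble::tibble(entity_id = entity_id, source = source,
                        disease_id = disease_id, phenotypes = phenotypes)
  class(out) <- c("assoc_table", class(out))
  out
}

as_assoc_table <- function(df) {
  association_table(df$entity_id, df$source, df$disease_id, df$phenotypes)
}

#' Distinct (phenotype, disease) pairs of a table
#'
#' @param table An `assoc_table`.
#' @return A `tbl_df` with columns `phenotype_id`, `disease_id`, one row per
#'   distinct pair, sorted.
#' @export
pair_set <- function(table) {
  ph <- as.character(unlist(table$phenotypes, use.names = FALSE))
  dis <- rep(table$disease_id, lengths(table$phenotypes))
  key <- paste(ph, dis, sep = "\r")
  keep <- !duplicated(key)
  ph <- ph[keep]; dis <- dis[keep]
  ord <- radix_order(ph, dis)
  tibble::tibble(phenotype_id = ph[ord], disease_id = dis[ord])
}

#' Summary counts for an association table
#'
#' The dataset-statistics block: entities, distinct phenotypes, distinct
#' labeled diseases, distinct phenotype-disease associations, and (when a
#' disease vocabulary is supplied) the number of system categories covered
#' by the labeled diseases.
#'
#' @param table An `assoc_table`.
#' @param disease_vocab Optional `rarecf_vocab` with `categories` filled in.
#' @return A list with elements `entities`, `phenotypes`, `diseases`,
#'   `associations`, `categories_covered` (`NA` without a vocabulary).
#' @export
table_stats <- function(table, disease_vocab = NULL) {
  cats <- NA_integer_
  if (!is.null(disease_vocab)) {
    idx <- match(unique(table$disease_id), disease_vocab$term_id)
    cats <- length(unique(unlist(disease_vocab$categories[idx[!is.na(idx)]],
                                 use.names = FALSE)))
  }
  list(
    entities = nrow(table),
    phenotypes = length(unique(unlist(table$phenotypes, use.names = FALSE))),
    diseases = length(unique(table$disease_id)),
    associations = nrow(pair_set(table)),
    categories_covered = cats
  )
}

#' Read phenotype profiles from TSV or JSONL
#'
#' TSV layout: header `entity_id  source  disease_id  phenotypes` with the
#' phenotype set `|`-separated. Files named `*.jsonl` are read as one JSON
#' object per line with the same field names (`phenotypes` an array).
#' Duplicate rows for one entity are merged by set union when their disease
#' labels agree and rejected otherwise.
#'
#' @param path Input file.
#' @param source Optional `"EMR"`/`"LIT"` override applied to every record
#'   (otherwise the file's `source` field is used).
#' @return An `assoc_table`.
#' @export
read_profiles <- function(path, source = NULL) {
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) {
    recs <- read_profiles_jsonl(path)
  } else {
    fields <- read_tsv_fields(path, c("entity_id", "source", "disease_id",
                                      "phenotypes"))
    recs <- lapply(fields, function(f) {
      list(entity_id = f[[1L]], source = f[[2L]], disease_id = f[[3L]],
           phenotypes = split_bar(f[[4L]]))
    })
  }
  if (!is.null(source)) recs <- lapply(recs, function(r) { r$source <- source; r })
  if (length(recs) == 0) return(association_table())
  ids <- vapply(recs, `[[`, "", "entity_id")
  merged <- list()
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    prev <- merged[[r$entity_id]]
    if (is.null(prev)) {
      merged[[r$entity_id]] <- r
    } else {
      if (!identical(prev$disease_id, r$disease_id)) {
        stop("conflicting disease labels for entity '", r$entity_id, "': '",
             prev$disease_id, "' vs '", r$disease_id, "'", call. = FALSE)
      }
      prev$phenotypes <- union(prev$phenotypes, r$phenotypes)
      merged[[r$entity_id]] <- prev
    }
  }
  association_table(
    entity_id = vapply(merged, `[[`, "", "entity_id"),
    source = vapply(merged, `[[`, "", "source"),
    disease_id = vapply(merged, `[[`, "", "disease_id"),
    phenotypes = lapply(merged, `[[`, "phenotypes")
  )
}

read_profiles_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    r <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                  error = function(e) stop("parse error in ", path,
                                           " at line ", i, ": ",
                                           conditionMessage(e), call. = FALSE))
    for (f in c("entity_id", "source", "disease_id", "phenotypes")) {
      if (is.null(r[[f]])) stop("parse error in ", path, " at line ", i,
                                ": missing field '", f, "'", call. = FALSE)
    }
    list(entity_id = as.character(r$entity_id),
         source = as.character(r$source),
         disease_id = as.character(r$disease_id),
         phenotypes = as.character(r$phenotypes))
  })
}

#' Write phenotype profiles to TSV
#'
#' Inverse of [read_profiles()]: `read_profiles(write_profiles(t))` equals
#' `t` up to phenotype-set ordering (sets are stored sorted).
#'
#' @param table An `assoc_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(table, path) {
  lines <- c(
    "entity_id\tsource\tdisease_id\tphenotypes",
    vapply(seq_len(nrow(table)), function(i) {
      paste(c(table$entity_id[[i]], table$source[[i]], table$disease_id[[i]],
              paste(table$phenotypes[[i]], collapse = "|")),
            collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read predication triples from TSV
#'
#' Columns: `doc_id  subject  predicate  object`, all non-empty.
#'
#' @param path Input file.
#' @return A `tbl_df` with those four character columns.
#' @export
read_predications <- function(path) {
  fields <- read_tsv_fields(path, c("doc_id", "subject", "predicate", "object"))
  out <- tibble::tibble(
    doc_id = vapply(fields, `[[`, "", 1L),
    subject = vapply(fields, `[[`, "", 2L),
    predicate = vapply(fields, `[[`, "", 3L),
    object = vapply(fields, `[[`, "", 4L)
  )
  if (nrow(out) > 0 && any(!nzchar(as.matrix(out)))) {
    stop("predication with empty field in ", path, call. = FALSE)
  }
  out
}

#' Write predication triples to TSV
#' @param preds A data frame with columns `doc_id`, `subject`, `predicate`,
#'   `object`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predications <- function(preds, path) {
  lines <- c("doc_id\tsubject\tpredicate\tobject",
             paste(preds$doc_id, preds$subject, preds$predicate, preds$object,
                   sep = "\t"))
  writeLines(lines[seq_len(nrow(preds) + 1L)], path, useBytes = TRUE)
  invisible(path)
}
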