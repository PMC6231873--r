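#' Filter predication triples down to phenotype-disease associations
#'
#' A predication is kept iff exactly one of subject/object maps (by
#' normalized name or synonym) into the phenotype vocabulary and the other
#' maps into the disease vocabulary. Same-vocabulary pairs
#' (disease-disease, phenotype-phenotype), unmapped terms, and ambiguous
#' assignments are dropped; drop counts are attached as the `"counts"`
#' attribute and reported with [message()].
#'
#' @param preds Data frame of predications (`doc_id`, `subject`,
#'   `predicate`, `object`).
#' @param pheno_vocab,disease_vocab `rarecf_vocab` tables.
#' @param quiet Suppress the summary message.
#' @return A `tbl_df` with columns `doc_id`, `phenotype_id`, `disease_id`.
#' @export
filter_predications <- function(preds, pheno_vocab, disease_vocab,
                                quiet = FALSE) {
  ph <- vocab_lookup(pheno_vocab)
  di <- vocab_lookup(disease_vocab)
  s <- normalize_term(preds$subject)
  o <- normalize_term(preds$object)
  sp <- ph[s]; op <- ph[o]   # phenotype ids (NA when unmapped)
  sd <- di[s]; od <- di[o]   # disease ids
  fwd <- !is.na(sp) & !is.na(od)   # subject=phenotype, object=disease
  rev_ <- !is.na(sd) & !is.na(op)  # subject=disease, object=phenotype
  same <- (!is.na(sp) & !is.na(op)) | (!is.na(sd) & !is.na(od))
  keep_fwd <- fwd & !rev_ & !same
  keep_rev <- rev_ & !fwd & !same
  kept <- keep_fwd | keep_rev
  counts <- c(
    kept = sum(kept),
    dropped_same_vocab = sum(!kept & same),
    dropped_unmapped = sum(!kept & !same &
                             ((is.na(sp) & is.na(sd)) | (is.na(op) & is.na(od)))),
    dropped_ambiguous = sum(!kept & !same & fwd & rev_)
  )
  if (!quiet) {
    message("filter_predications: kept ", counts[["kept"]], " of ",
            nrow(preds), " (", counts[["dropped_unmapped"]], " unmapped, ",
            counts[["dropped_same_vocab"]], " same-vocabulary, ",
            counts[["dropped_ambiguous"]], " ambiguous)")
  }
  out <- tibble::tibble(
    doc_id = c(preds$doc_id[keep_fwd], preds$doc_id[keep_rev]),
    phenotype_id = unname(c(sp[keep_fwd], op[keep_rev])),
    disease_id = unname(c(od[keep_fwd], sd[keep_rev]))
  )
  out <- out[radix_order(out$doc_id, out$phenotype_id, out$disease_id), ]
  attr(out, "counts") <- counts
  out
}

#' Merge literature triples into per-disease documents
#'
#' Individual publications typically assert a single phenotype-disease
#' pair, so all documents mentioning the same disease are merged into one
#' large literature profile: id `LIT::<disease_id>`, phenotype set the
#' union over contributing documents.
#'
#' @param triples Output of [filter_predications()].
#' @return An `assoc_table` with `source = "LIT"`, one profile per disease.
#' @export
merge_literature <- function(triples) {
  if (nrow(triples) == 0) return(association_table())
  by_dis <- split(triples$phenotype_id, triples$disease_id)
  dis <- sort(names(by_dis))
  association_table(
    entity_id = paste0("LIT::", dis),
    source = "LIT",
    disease_id = dis,
    phenotypes = lapply(by_dis[dis], unique)
  )
}

check_disjoint_ids <- function(emr, lit) {
  clash <- intersect(emr$entity_id, lit$entity_id)
  if (length(clash) > 0) {
    stop("entity ids occur in both tables: ",
         paste(head(clash, 5), collapse = ", "), call. = FALSE)
  }
}

#' Fuse EMR and literature profiles by raw mixing
#'
#' Concatenates the two tables and randomly permutes the storage order
#' under `seed`. The permutation affects serialization order only; every
#' downstream computation is order-invariant.
#'
#' @param emr,lit `assoc_table`s with disjoint entity-id spaces.
#' @param seed Integer seed for the permutation.
#' @return A fused `assoc_table`.
#' @export
fuse_emr_l <- function(emr, lit, seed = 1L) {
  check_disjoint_ids(emr, lit)
  both <- rbind(as.data.frame(emr), as.data.frame(lit))
  perm <- with_seed(seed, sample.int(nrow(both)))
  as_assoc_table(both[perm, , drop = FALSE])
}

#' Fuse EMR and pruned literature profiles
#'
#' Before mixing, every literature (phenotype, disease) pair absent from
#' the EMR pair set is removed; literature profiles left empty are dropped
#' entirely. Consequently the fused pair set equals the EMR pair set — the
#' literature adds evidence weight, never new associations.
#'
#' @inheritParams fuse_emr_l
#' @return A fused `assoc_table` with `pair_set()` equal to the EMR's.
#' @export
fuse_emr_pl <- function(emr, lit, seed = 1L) {
  fuse_emr_l(emr, prune_literature(lit, emr), seed)
}

#' Prune literature pairs missing from the EMR
#'
#' @param lit Literature `assoc_table`.
#' @param emr EMR `assoc_table` supplying the reference pair set.
#' @return `lit` with off-EMR pairs removed and emptied profiles dropped.
#'   Idempotent: pruning twice equals pruning once.
#' @export
prune_literature <- function(lit, emr) {
  ps <- pair_set(emr)
  allowed <- paste(ps$phenotype_id, ps$disease_id, sep = "\r")
  kept <- lapply(seq_len(nrow(lit)), function(i) {
    p <- lit$phenotypes[[i]]
    p[paste(p, lit$disease_id[[i]], sep = "\r") %in% allowed]
  })
  keep <- lengths(kept) > 0
  association_table(lit$entity_id[keep], lit$source[keep],
                    lit$disease_id[keep], kept[keep])
}

#' Drop diseases with too few affected patients
#'
#' Removes every profile (EMR and literature alike) whose disease label is
#' carried by fewer than `min_patients` EMR-source profiles. Used with
#' `min_patients = 2` to eliminate single-patient diseases and
#' `min_patients = 3` for the prediction cohort.
#'
#' @param table An `assoc_table`.
#' @param min_patients Minimum number of EMR profiles per disease (>= 1).
#' @return The filtered `assoc_table`.
#' @export
min_support_filter <- function(table, min_patients) {
  if (length(min_patients) != 1L || is.na(min_patients) || min_patients < 1) {
    stop("min_patients must be a single integer >= 1", call. = FALSE)
  }
  emr_labels <- table$disease_id[table$source == "EMR"]
  n_emr <- vapply(unique(table$disease_id),
                  function(d) sum(emr_labels == d), integer(1))
  ok <- names(n_emr)[n_emr >= min_patients]
  as_assoc_table(as.data.frame(table)[table$disease_id %in% ok, , drop = FALSE])
}
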