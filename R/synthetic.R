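#' Configuration for the synthetic benchmark generator
#'
#' The generator plants a phenotype signature per disease, draws noisy
#' patient profiles from the signatures, emits sparse literature
#' predications at controlled fidelity, and wires the vocabularies so all
#' three matching relaxations have structure to exercise.
#'
#' @param n_diseases Number of diseases.
#' @param signature_size Phenotypes per disease signature.
#' @param signature_overlap Fraction in `[0, 1]` of a signature shared
#'   with the next disease's (0 = disjoint signatures).
#' @param patients_per_disease Patients drawn per disease.
#' @param phenotype_dropout Probability a signature phenotype is missing
#'   from a patient's record.
#' @param noise_phenotypes_per_patient Off-signature phenotypes added per
#'   patient.
#' @param n_lit_docs Literature documents; each asserts one predication.
#' @param lit_fidelity Probability a literature predication uses a true
#'   signature phenotype (else a random phenotype).
#' @param decoy_fraction Fraction of documents emitting a same-vocabulary
#'   decoy (phenotype-phenotype or disease-disease) instead.
#' @param n_categories Number of system categories.
#' @param synonym_rate Probability a term gets a synonym.
#' @param concept_twin_fraction Fraction of diseases paired into shared
#'   concept-key twins (twins also share a category, so concept matches
#'   are nested inside category matches).
#' @param n_noise_phenotypes Off-signature phenotype pool size.
#' @param seed Master seed; fixed seed gives byte-identical outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_diseases = 10L, signature_size = 8L,
                       signature_overlap = 0, patients_per_disease = 20L,
                       phenotype_dropout = 0.1,
                       noise_phenotypes_per_patient = 1L,
                       n_lit_docs = 200L, lit_fidelity = 1,
                       decoy_fraction = 0, n_categories = 4L,
                       synonym_rate = 0.2, concept_twin_fraction = 0.4,
                       n_noise_phenotypes = 20L, seed = 1L) {
  cfg <- list(n_diseases = as.integer(n_diseases),
              signature_size = as.integer(signature_size),
              signature_overlap = signature_overlap,
              patients_per_disease = as.integer(patients_per_disease),
              phenotype_dropout = phenotype_dropout,
              noise_phenotypes_per_patient =
                as.integer(noise_phenotypes_per_patient),
              n_lit_docs = as.integer(n_lit_docs),
              lit_fidelity = lit_fidelity,
              decoy_fraction = decoy_fraction,
              n_categories = as.integer(n_categories),
              synonym_rate = synonym_rate,
              concept_twin_fraction = concept_twin_fraction,
              n_noise_phenotypes = as.integer(n_noise_phenotypes),
              seed = as.integer(seed))
  rates <- c("signature_overlap", "phenotype_dropout", "lit_fidelity",
             "decoy_fraction", "synonym_rate", "concept_twin_fraction")
  for (r in rates) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop(r, " must be in [0, 1]", call. = FALSE)
  }
  counts <- c("n_diseases", "signature_size", "patients_per_disease",
              "n_lit_docs", "n_categories", "n_noise_phenotypes",
              "noise_phenotypes_per_patient")
  for (cn in counts) {
    if (is.na(cfg[[cn]]) || cfg[[cn]] < 0) stop(cn, " must be >= 0", call. = FALSE)
  }
  if (cfg$n_diseases < 1 || cfg$signature_size < 1) {
    stop("need at least one disease and a non-empty signature", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Signature layout: stride = ceil(signature_size * (1 - overlap)) positions
# between consecutive signatures over a shared phenotype axis, so overlap 0
# partitions the axis and overlap > 0 shares a sliding window.
signature_positions <- function(cfg) {
  stride <- max(1L, as.integer(ceiling(cfg$signature_size *
                                         (1 - cfg$signature_overlap))))
  lapply(seq_len(cfg$n_diseases) - 1L, function(i) {
    i * stride + seq_len(cfg$signature_size)
  })
}

#' Generate phenotype and disease vocabularies with planted structure
#'
#' Diseases get 1-2 categories; a `concept_twin_fraction` of them are
#' paired so each pair shares a concept key, a synonymized alias and its
#' first category. Determinism: the same config yields identical tables.
#'
#' @param cfg A `sim_config`.
#' @return A list: `phenotypes` and `diseases` (`rarecf_vocab`s) and
#'   `signatures` (named list of phenotype-id vectors per disease).
#' @export
generate_vocabularies <- function(cfg) {
  pos <- signature_positions(cfg)
  n_phen <- max(unlist(pos)) + cfg$n_noise_phenotypes
  ph_ids <- sprintf("HP:%04d", seq_len(n_phen))
  dis_ids <- sprintf("RD:%03d", seq_len(cfg$n_diseases))
  with_seed(cfg$seed, {
    ph_syn <- lapply(seq_len(n_phen), function(i) {
      if (runif(1) < cfg$synonym_rate) sprintf("phenotype %04d alias", i)
      else character()
    })
    n_twin_pairs <- floor(cfg$concept_twin_fraction * cfg$n_diseases / 2)
    concept <- sprintf("CUI:%03d", seq_len(cfg$n_diseases))
    # Categories are assigned in contiguous blocks over the disease axis:
    # diseases with adjacent (hence overlapping) signatures fall in the
    # same system category, emulating real category systems where
    # phenotypically similar diseases share a category. A second, random
    # category is added occasionally so multi-category diseases exist.
    block <- ceiling(cfg$n_diseases / cfg$n_categories)
    categories <- lapply(seq_len(cfg$n_diseases), function(i) {
      primary <- sprintf("category %02d", ceiling(i / block))
      if (cfg$n_categories > 1 && runif(1) < 0.3) {
        sort(unique(c(primary,
                      sprintf("category %02d", sample.int(cfg$n_categories, 1)))))
      } else primary
    })
    dis_syn <- lapply(seq_len(cfg$n_diseases), function(i) {
      if (runif(1) < cfg$synonym_rate) sprintf("disease %03d alias", i)
      else character()
    })
    if (n_twin_pairs > 0) {
      for (p in seq_len(n_twin_pairs)) {
        a <- 2L * p - 1L; b <- 2L * p
        concept[b] <- concept[a]
        categories[[b]] <- sort(unique(c(categories[[b]], categories[[a]][1L])))
      }
    }
    list(
      phenotypes = vocabulary(ph_ids, sprintf("phenotype %04d", seq_len(n_phen)),
                              synonyms = ph_syn),
      diseases = vocabulary(dis_ids, sprintf("disease %03d", seq_len(cfg$n_diseases)),
                            synonyms = dis_syn, concept_key = concept,
                            categories = categories),
      signatures = setNames(lapply(pos, function(p) ph_ids[p]), dis_ids)
    )
  })
}

#' Generate a synthetic EMR patient cohort
#'
#' Each patient takes its disease's signature, loses each phenotype
#' independently with probability `phenotype_dropout`, gains
#' `noise_phenotypes_per_patient` random off-signature phenotypes, and is
#' resampled if the profile comes out empty.
#'
#' @param cfg A `sim_config`.
#' @param vocabs Output of [generate_vocabularies()].
#' @return An `assoc_table` with `source = "EMR"` and
#'   `n_diseases * patients_per_disease` profiles.
#' @export
generate_patients <- function(cfg, vocabs) {
  all_ph <- vocabs$phenotypes$term_id
  dis_ids <- names(vocabs$signatures)
  with_seed(cfg$seed + 1L, {
    n <- cfg$n_diseases * cfg$patients_per_disease
    disease <- rep(dis_ids, each = cfg$patients_per_disease)
    phen <- vector("list", n)
    for (i in seq_len(n)) {
      sig <- vocabs$signatures[[disease[[i]]]]
      pool <- setdiff(all_ph, sig)
      repeat {
        keep <- sig[runif(length(sig)) >= cfg$phenotype_dropout]
        noise <- if (cfg$noise_phenotypes_per_patient > 0) {
          pool[sample.int(length(pool),
                          min(cfg$noise_phenotypes_per_patient, length(pool)))]
        } else character()
        prof <- union(keep, noise)
        if (length(prof) > 0) break
      }
      phen[[i]] <- prof
    }
    association_table(sprintf("P%05d", seq_len(n)), "EMR", disease, phen)
  })
}

#' Generate synthetic literature predications
#'
#' Each document asserts one subject-predicate-object triple. With
#' probability `decoy_fraction` the triple is a same-vocabulary decoy
#' (phenotype-phenotype or disease-disease, to exercise
#' [filter_predications()]); otherwise it links a uniformly drawn disease
#' to a signature phenotype with probability `lit_fidelity` and to a
#' random phenotype otherwise. Subject/object orientation is randomized.
#'
#' @inheritParams generate_patients
#' @return A `tbl_df` of predications (`doc_id`, `subject`, `predicate`,
#'   `object`).
#' @export
generate_literature <- function(cfg, vocabs) {
  ph_name <- setNames(vocabs$phenotypes$name, vocabs$phenotypes$term_id)
  dis_name <- setNames(vocabs$diseases$name, vocabs$diseases$term_id)
  all_ph <- vocabs$phenotypes$term_id
  dis_ids <- names(vocabs$signatures)
  if (cfg$n_lit_docs == 0) {
    return(tibble::tibble(doc_id = character(), subject = character(),
                          predicate = character(), object = character()))
  }
  with_seed(cfg$seed + 2L, {
    rows <- lapply(seq_len(cfg$n_lit_docs), function(i) {
      doc <- sprintf("PMID:%06d", i)
      if (runif(1) < cfg$decoy_fraction) {
        if (runif(1) < 0.5) {
          pair <- sample(all_ph, 2L)
          c(doc, ph_name[[pair[1L]]], "COEXISTS_WITH", ph_name[[pair[2L]]])
        } else {
          pair <- dis_ids[sample.int(length(dis_ids), min(2L, length(dis_ids)))]
          pair <- rep_len(pair, 2L)
          c(doc, dis_name[[pair[1L]]], "COEXISTS_WITH", dis_name[[pair[2L]]])
        }
      } else {
        d <- sample(dis_ids, 1L)
        p <- if (runif(1) < cfg$lit_fidelity) {
          sample(vocabs$signatures[[d]], 1L)
        } else sample(all_ph, 1L)
        if (runif(1) < 0.5) {
          c(doc, ph_name[[p]], "ASSOCIATED_WITH", dis_name[[d]])
        } else {
          c(doc, dis_name[[d]], "AFFECTS", ph_name[[p]])
        }
      }
    })
    m <- do.call(rbind, rows)
    tibble::tibble(doc_id = m[, 1L], subject = m[, 2L],
                   predicate = m[, 3L], object = m[, 4L])
  })
}

#' Generate a full synthetic corpus in memory
#'
#' Vocabularies, EMR cohort, literature predications, and the merged
#' literature table (predications filtered against the vocabularies and
#' merged per disease).
#'
#' @param cfg A `sim_config`.
#' @return A list of class `cf_corpus`: `config`, `vocabs`, `emr`,
#'   `predications`, `triples`, `lit`.
#' @export
build_corpus <- function(cfg) {
  vocabs <- generate_vocabularies(cfg)
  emr <- generate_patients(cfg, vocabs)
  preds <- generate_literature(cfg, vocabs)
  triples <- filter_predications(preds, vocabs$phenotypes, vocabs$diseases,
                                 quiet = TRUE)
  structure(list(config = cfg, vocabs = vocabs, emr = emr,
                 predications = preds, triples = triples,
                 lit = merge_literature(triples)),
            class = "cf_corpus")
}

#' Write a synthetic corpus to a directory
#'
#' Emits `profiles.tsv`, `phenotypes.tsv`, `diseases.tsv`,
#' `predications.tsv` and a `manifest.json` echoing the configuration and
#' seed, so any corpus can be regenerated exactly.
#'
#' @param corpus A `cf_corpus` from [build_corpus()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_profiles(corpus$emr, file.path(dir, "profiles.tsv"))
  write_vocabulary(corpus$vocabs$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_vocabulary(corpus$vocabs$diseases, file.path(dir, "diseases.tsv"))
  write_predications(corpus$predications, file.path(dir, "predications.tsv"))
  jsonlite::write_json(unclass(corpus$config),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
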