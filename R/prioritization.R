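# The recessive-disease filtering funnel and prioritization scheme.

#' Build a filtering-cascade configuration
#'
#' Defaults follow the diagnostic thresholds of the motivating panel: a
#' variant must be supported by at least 31% of covering reads (12% when a
#' mosaic-sensitive run is requested), population/in-house alleles above 2%
#' frequency are excluded, and a nonsynonymous change needs damaging verdicts
#' from at least `predictor_quorum` of the external predictors to count as a
#' pathogenic clue.
#'
#' @param panel_genes Genes on the capture panel.
#' @param disease_genes Subset of `panel_genes` that cause the recessive
#'   disease (defaults to all panel genes).
#' @param min_allele_fraction Minimum allele fraction (default 0.31).
#' @param mosaic_min_allele_fraction Mosaic-mode minimum (default 0.12).
#' @param max_population_frequency Frequency cutoff (default 0.02).
#' @param predictor_quorum Damaging verdicts required for a missense clue
#'   (default 2; set 1 to let any single predictor count).
#' @return A `ps_cascade_config` list.
#' @export
cascade_config <- function(panel_genes, disease_genes = panel_genes,
                           min_allele_fraction = 0.31,
                           mosaic_min_allele_fraction = 0.12,
                           max_population_frequency = 0.02,
                           predictor_quorum = 2L) {
  if (!(mosaic_min_allele_fraction > 0 &&
        mosaic_min_allele_fraction <= min_allele_fraction &&
        min_allele_fraction <= 1)) {
    abort("need 0 < mosaic_min_allele_fraction <= min_allele_fraction <= 1")
  }
  if (max_population_frequency < 0 || max_population_frequency > 1) {
    abort("max_population_frequency must be in [0, 1]")
  }
  if (!all(disease_genes %in% panel_genes)) {
    abort("disease_genes must be a subset of panel_genes")
  }
  structure(
    list(
      panel_genes = panel_genes,
      disease_genes = disease_genes,
      min_allele_fraction = min_allele_fraction,
      mosaic_min_allele_fraction = mosaic_min_allele_fraction,
      max_population_frequency = max_population_frequency,
      predictor_quorum = as.integer(predictor_quorum)
    ),
    class = "ps_cascade_config"
  )
}

#' Filter variants on allele fraction
#'
#' Keeps variants whose allele fraction reaches the detection threshold
#' (31% by default; 12% in mosaic mode, where the aberration may be carried
#' by only a fraction of cells). Pseudogene-flagged variants bypass the
#' filter: their fraction is expected to be diluted by reads from the
#' homologous copies.
#'
#' @param variants Variant tibble with `allele_fraction` (and optionally
#'   `pseudogene_flag`).
#' @param config A [cascade_config()].
#' @param mosaic_mode Use the mosaic threshold.
#' @return The surviving variants.
#' @export
af_filter <- function(variants, config, mosaic_mode = FALSE) {
  thr <- if (mosaic_mode) config$mosaic_min_allele_fraction
         else config$min_allele_fraction
  pg <- if ("pseudogene_flag" %in% names(variants)) variants$pseudogene_flag
        else rep(FALSE, nrow(variants))
  variants[variants$allele_fraction >= thr | pg, , drop = FALSE]
}

#' Score variants for a pathogenic clue
#'
#' Truncating classes (frameshift, stopgain) and canonical splice-site
#' variants are considered pathogenic outright. A nonsynonymous change is a
#' clue when at least `quorum` external predictors call it damaging. All
#' other classes carry no clue.
#'
#' @param variants Annotated variant tibble.
#' @param quorum Damaging verdicts required for a missense clue.
#' @return The variants with logical `clue` and character `clue_reason`
#'   columns appended.
#' @export
clue_score <- function(variants, quorum = 2L) {
  n_dam <- if ("n_damaging" %in% names(variants)) variants$n_damaging
           else rep(0L, nrow(variants))
  truncating <- variants$effect_class %in% c("frameshift", "stopgain")
  splice <- variants$effect_class == "canonical_splice"
  missense_hit <- variants$effect_class == "nonsynonymous" & n_dam >= quorum
  variants$clue <- truncating | splice | missense_hit
  variants$clue_reason <- dplyr::case_when(
    truncating ~ "truncating",
    splice ~ "canonical splice",
    missense_hit ~ sprintf("predicted damaging (%d predictors)", n_dam),
    .default = NA_character_
  )
  variants
}

stage_labels <- c(
  total = "Variants (total)",
  on_target_genes = "Variants (target genes)",
  ns_ss = "NS/SS",
  not_in_dbsnp = "Not in dbSNP",
  disease_genes = "FA genes",
  pathogenic_clue = "Pathogenic clue"
)

#' Run the variant filtering funnel
#'
#' Applies the six funnel stages in order to one sample's annotated
#' variants: (1) all variants; (2) on panel genes; (3) protein-affecting or
#' splice classes (nonsynonymous, stopgain, frameshift, in-frame indel,
#' canonical splice); (4) absent from, or at most `max_population_frequency`
#' in, both the population and the in-house databases; (5) in the disease
#' genes; (6) carrying a pathogenic clue ([clue_score()]). Stage counts are
#' non-increasing by construction.
#'
#' @param variants One sample's annotated variant tibble.
#' @param config A [cascade_config()].
#' @return A `ps_cascade` object: `stages` (tibble of stage, label, n),
#'   `survivors` (list of tibbles per stage) and the `config`.
#' @export
run_cascade <- function(variants, config) {
  v1 <- variants
  v2 <- v1[!is.na(v1$gene) & v1$gene %in% config$panel_genes, , drop = FALSE]
  keep_cls <- c("nonsynonymous", "stopgain", "frameshift",
                "inframe_indel", "canonical_splice")
  v3 <- v2[v2$effect_class %in% keep_cls, , drop = FALSE]
  fmax <- config$max_population_frequency
  ok_freq <- function(x) is.na(x) | x <= fmax
  v4 <- v3[ok_freq(v3$dbsnp_frequency) & ok_freq(v3$inhouse_frequency), ,
           drop = FALSE]
  v5 <- v4[v4$gene %in% config$disease_genes, , drop = FALSE]
  v5 <- clue_score(v5, quorum = config$predictor_quorum)
  v6 <- v5[v5$clue, , drop = FALSE]
  survivors <- list(
    total = v1, on_target_genes = v2, ns_ss = v3,
    not_in_dbsnp = v4, disease_genes = v5, pathogenic_clue = v6
  )
  stages <- tibble::tibble(
    stage = names(survivors),
    label = unname(stage_labels[names(survivors)]),
    n = unname(purrr::map_int(survivors, nrow))
  )
  structure(
    list(stages = stages, survivors = survivors, config = config),
    class = "ps_cascade"
  )
}

#' @export
print.ps_cascade <- function(x, ...) {
  cat("<ps_cascade> filtering funnel\n")
  print(x$stages)
  invisible(x)
}

#' Write the funnel counts as a one-row TSV
#'
#' Column names follow the standard funnel table (`Variants (total)`,
#' `Variants (target genes)`, `NS/SS`, `Not in dbSNP`, `FA genes`,
#' `Pathogenic clue`).
#'
#' @param cascade A `ps_cascade`.
#' @param path Output path.
#' @param sample_id Optional leading `Sample` column value.
#' @return `path`, invisibly.
#' @export
write_funnel_tsv <- function(cascade, path, sample_id = NULL) {
  row <- as.list(setNames(cascade$stages$n, cascade$stages$label))
  if (!is.null(sample_id)) row <- c(list(Sample = sample_id), row)
  readr::write_tsv(tibble::as_tibble(row), path)
  invisible(path)
}

describe_variant <- function(v) {
  sprintf("%s:%d %s>%s [%s%s]", v$chrom, v$pos, v$ref, v$alt,
          v$effect_class,
          ifelse(is.na(v$hgvs_c), "", paste0(", ", v$hgvs_c)))
}

describe_deletion <- function(d) {
  sprintf("%s exon %d-%d deletion [%s, M=%.2f]",
          d$gene, d$first_exon, d$last_exon, d$zygosity_class, d$mean_M)
}

#' Prioritize gene findings under a recessive model
#'
#' Integrates the funnel's surviving clue variants with read-depth deletion
#' calls, per disease gene, under recessive inheritance: a homozygous clue
#' variant (allele fraction >= `hom_af`) is biallelic on its own; two
#' heterozygous clue variants form a (phase-unknown) compound heterozygote;
#' one heterozygous clue variant plus a deletion call in the same gene is
#' biallelic; a homozygous-class deletion alone is biallelic. A single
#' heterozygous clue variant — or a heterozygous deletion — without a second
#' allele yields status `one_allele` with the escalation flag set: the
#' gene's intronic and UTR variants absent from both frequency databases are
#' listed as candidates for the second allele (deep-intronic mutations are
#' invisible to the coding-centric funnel).
#'
#' @param cascade A `ps_cascade` from [run_cascade()].
#' @param deletion_calls This sample's deletion-call tibble (may be `NULL`).
#' @param all_annotated The sample's full annotated variant table, used to
#'   list escalation candidates (may be `NULL`).
#' @param hom_af Allele fraction at or above which a variant is taken as
#'   homozygous (default 0.7).
#' @return Tibble with one row per disease gene: `gene`, `status`
#'   (`biallelic`/`one_allele`/`none`), `allele1`, `allele2`, `escalation`,
#'   and list-column `escalation_candidates`.
#' @export
recessive_prioritize <- function(cascade, deletion_calls = NULL,
                                 all_annotated = NULL, hom_af = 0.7) {
  config <- cascade$config
  clues <- cascade$survivors$pathogenic_clue
  findings <- purrr::map(config$disease_genes, function(g) {
    gv <- clues[clues$gene == g, , drop = FALSE]
    gv <- dplyr::arrange(gv, .data$pos)
    gd <- if (!is.null(deletion_calls) && nrow(deletion_calls) > 0) {
      deletion_calls[deletion_calls$gene == g, , drop = FALSE]
    } else {
      tibble::tibble(gene = character(), first_exon = integer(),
                     last_exon = integer(), mean_M = double(),
                     zygosity_class = character(), mosaic_fraction = double())
    }
    hom <- if (nrow(gv) > 0) which(gv$allele_fraction >= hom_af) else integer(0)
    hom_del <- if (!is.null(gd) && nrow(gd) > 0) {
      which(gd$zygosity_class == "hom")
    } else {
      integer(0)
    }
    a1 <- NA_character_; a2 <- NA_character_
    status <- "none"; note <- NA_character_
    if (length(hom) > 0) {
      status <- "biallelic"
      a1 <- a2 <- describe_variant(gv[hom[[1]], ])
      note <- "homozygous variant"
    } else if (nrow(gv) >= 2) {
      status <- "biallelic"
      a1 <- describe_variant(gv[1, ]); a2 <- describe_variant(gv[2, ])
      note <- "compound heterozygous (phase unknown)"
    } else if (nrow(gv) == 1 && !is.null(gd) && nrow(gd) > 0) {
      status <- "biallelic"
      a1 <- describe_variant(gv[1, ]); a2 <- describe_deletion(gd[1, ])
      note <- "heterozygous variant + deletion"
    } else if (length(hom_del) > 0) {
      status <- "biallelic"
      a1 <- a2 <- describe_deletion(gd[hom_del[[1]], ])
      note <- "homozygous deletion"
    } else if (nrow(gv) == 1) {
      status <- "one_allele"
      a1 <- describe_variant(gv[1, ])
      note <- "single heterozygous clue; inspect intronic/UTR variants"
    } else if (!is.null(gd) && nrow(gd) > 0) {
      status <- "one_allele"
      a1 <- describe_deletion(gd[1, ])
      note <- "heterozygous deletion; inspect intronic/UTR variants"
    }
    escalation <- status == "one_allele"
    cand <- if (escalation && !is.null(all_annotated)) {
      cc <- all_annotated[
        all_annotated$gene %in% g &
          all_annotated$effect_class %in% c("intronic", "utr5", "utr3") &
          is.na(all_annotated$dbsnp_frequency) &
          is.na(all_annotated$inhouse_frequency), , drop = FALSE]
      dplyr::arrange(cc, .data$pos)
    } else {
      NULL
    }
    tibble::tibble(
      gene = g, status = status, allele1 = a1, allele2 = a2,
      note = note, escalation = escalation,
      escalation_candidates = list(cand)
    )
  })
  dplyr::bind_rows(findings) |> dplyr::arrange(.data$gene)
}

#' Assemble the per-sample report
#'
#' Bundles the funnel counts, deletion calls and gene findings into a
#' deterministic report (ordered by gene, then position) and optionally
#' writes the machine-readable JSON and the funnel TSV.
#'
#' @param findings Tibble from [recessive_prioritize()].
#' @param cascade The `ps_cascade` the findings came from.
#' @param deletion_calls This sample's deletion calls (may be `NULL`).
#' @param sample_id Sample identifier recorded in the report.
#' @param dir Optional output directory; when given,
#'   `<sample_id>_report.json` and `<sample_id>_funnel.tsv` are written.
#' @return A `ps_report` list with `sample_id`, `funnel`, `deletion_calls`,
#'   `findings`.
#' @export
report_sample <- function(findings, cascade, deletion_calls = NULL,
                          sample_id = "sample", dir = NULL) {
  calls <- if (is.null(deletion_calls)) {
    tibble::tibble(gene = character(), first_exon = integer(),
                   last_exon = integer(), mean_M = double(),
                   zygosity_class = character(), mosaic_fraction = double())
  } else {
    dplyr::arrange(deletion_calls, .data$gene, .data$first_exon)
  }
  rep <- structure(
    list(
      sample_id = sample_id,
      funnel = cascade$stages,
      deletion_calls = calls,
      findings = dplyr::arrange(findings, .data$gene)
    ),
    class = "ps_report"
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    jl <- list(
      sample_id = sample_id,
      funnel = setNames(as.list(cascade$stages$n), cascade$stages$stage),
      deletion_calls = calls[, setdiff(names(calls), "sample_id")],
      findings = rep$findings[, c("gene", "status", "allele1", "allele2",
                                  "note", "escalation")]
    )
    jsonlite::write_json(
      jl, file.path(dir, paste0(sample_id, "_report.json")),
      auto_unbox = TRUE, digits = NA, na = "null"
    )
    write_funnel_tsv(cascade, file.path(dir, paste0(sample_id, "_funnel.tsv")),
                     sample_id = sample_id)
  }
  rep
}

#' @export
print.ps_report <- function(x, ...) {
  cat("<ps_report>", x$sample_id, "\n")
  cat("Funnel:", paste(x$funnel$n, collapse = " > "), "\n")
  if (nrow(x$deletion_calls) > 0) {
    cat("Deletion calls:\n"); print(x$deletion_calls)
  }
  hits <- x$findings[x$findings$status != "none", , drop = FALSE]
  if (nrow(hits) > 0) {
    cat("Findings:\n")
    print(hits[, c("gene", "status", "allele1", "allele2", "note")])
  } else {
    cat("No gene findings.\n")
  }
  invisible(x)
}
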