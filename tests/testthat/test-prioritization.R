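fa_config <- function(...) {
  cascade_config(
    panel_genes = c("FANCA", "FANCC", "FANCI", "BRCA1X"),
    disease_genes = c("FANCA", "FANCC", "FANCI"),
    ...
  )
}

test_that("allele-fraction filter applies 31%/12% thresholds with pseudogene bypass", {
  cfg <- fa_config()
  v <- dplyr::bind_rows(
    av("FANCA", "nonsynonymous", af = 0.35),
    av("FANCA", "nonsynonymous", af = 0.25),
    av("FANCA", "nonsynonymous", af = 0.20, pgflag = TRUE),
    av("FANCA", "nonsynonymous", af = 0.10)
  )
  expect_equal(af_filter(v, cfg)$allele_fraction, c(0.35, 0.20))
  expect_equal(af_filter(v, cfg, mosaic_mode = TRUE)$allele_fraction,
               c(0.35, 0.25, 0.20))
})

test_that("pathogenic clues are truncating, splice, or quorum-damaging missense", {
  v <- dplyr::bind_rows(
    av("FANCA", "frameshift"),
    av("FANCA", "stopgain"),
    av("FANCA", "canonical_splice"),
    av("FANCA", "nonsynonymous", n_damaging = 3L),
    av("FANCA", "nonsynonymous", n_damaging = 1L),
    av("FANCA", "synonymous")
  )
  s <- clue_score(v, quorum = 2L)
  expect_equal(s$clue, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(s$clue_reason[1], "truncating")
  expect_equal(s$clue_reason[3], "canonical splice")
  s1 <- clue_score(v, quorum = 1L)
  expect_true(s1$clue[5])
})

test_that("the hand-built 10-variant set funnels 10 > 8 > 5 > 3 > 2 > 1", {
  cfg <- fa_config()
  toy <- dplyr::bind_rows(
    av("OFFT1", "nonsynonymous", pos = 1),           # off panel
    av("OFFT2", "stopgain", pos = 2),                # off panel
    av("FANCA", "synonymous", pos = 3),
    av("FANCC", "intronic", pos = 4),
    av("FANCI", "utr3", pos = 5),
    av("FANCA", "nonsynonymous", dbsnp = 0.05, pos = 6),
    av("FANCC", "canonical_splice", inhouse = 0.10, pos = 7),
    av("BRCA1X", "nonsynonymous", pos = 8),          # panel but not disease
    av("FANCI", "nonsynonymous", n_damaging = 1L, pos = 9),  # below quorum
    av("FANCA", "frameshift", pos = 10)
  )
  cascade <- run_cascade(toy, cfg)
  expect_equal(cascade$stages$n, c(10L, 8L, 5L, 3L, 2L, 1L))
  expect_equal(cascade$survivors$pathogenic_clue$effect_class, "frameshift")
  expect_equal(glance(cascade)$pathogenic_clue, 1L)
  expect_equal(tidy(cascade)$label[1], "Variants (total)")

  empty <- run_cascade(toy[0, ], cfg)
  expect_equal(empty$stages$n, rep(0L, 6))
})

test_that("funnel counts are non-increasing for random variant tables", {
  withr::local_seed(53)
  cfg <- fa_config()
  genes <- c("FANCA", "FANCC", "FANCI", "BRCA1X", "OFF1", "OFF2")
  classes <- c("nonsynonymous", "synonymous", "stopgain", "frameshift",
               "inframe_indel", "canonical_splice", "intronic", "utr5",
               "utr3", "intergenic")
  for (i in 1:100) {
    n <- sample.int(60, 1)
    v <- dplyr::bind_rows(purrr::map(seq_len(n), function(j) {
      av(sample(genes, 1), sample(classes, 1),
         af = runif(1),
         dbsnp = ifelse(runif(1) < 0.4, runif(1, 0, 0.2), NA),
         inhouse = ifelse(runif(1) < 0.2, runif(1, 0, 0.2), NA),
         n_damaging = sample(0:3, 1), pos = j)
    }))
    counts <- run_cascade(v, cfg)$stages$n
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("recessive prioritization classifies biallelic configurations", {
  cfg <- fa_config()
  del_het <- tibble::tibble(gene = "FANCI", first_exon = 38L, last_exon = 38L,
                            mean_M = -0.95, zygosity_class = "het",
                            mosaic_fraction = 0.97)
  del_hom <- tibble::tibble(gene = "FANCC", first_exon = 2L, last_exon = 4L,
                            mean_M = -4.8, zygosity_class = "hom",
                            mosaic_fraction = NA_real_)

  # homozygous damaging missense
  hom <- run_cascade(av("FANCA", "nonsynonymous", af = 0.98, n_damaging = 3L), cfg)
  f <- recessive_prioritize(hom)
  expect_equal(f$status[f$gene == "FANCA"], "biallelic")
  expect_equal(f$allele1[f$gene == "FANCA"], f$allele2[f$gene == "FANCA"])

  # compound heterozygote, phase unknown
  comp <- run_cascade(dplyr::bind_rows(
    av("FANCC", "frameshift", af = 0.45, pos = 10),
    av("FANCC", "canonical_splice", af = 0.52, pos = 400)
  ), cfg)
  f2 <- recessive_prioritize(comp)
  expect_equal(f2$status[f2$gene == "FANCC"], "biallelic")
  expect_match(f2$note[f2$gene == "FANCC"], "compound")

  # het truncating + overlapping deletion call
  hetv <- run_cascade(av("FANCI", "stopgain", af = 0.48), cfg)
  f3 <- recessive_prioritize(hetv, deletion_calls = del_het)
  expect_equal(f3$status[f3$gene == "FANCI"], "biallelic")
  expect_match(f3$allele2[f3$gene == "FANCI"], "deletion")

  # homozygous deletion alone
  f4 <- recessive_prioritize(run_cascade(av("X", "intronic")[0, ], cfg),
                             deletion_calls = del_hom)
  expect_equal(f4$status[f4$gene == "FANCC"], "biallelic")

  # single het clue escalates to intronic/UTR inspection
  others <- dplyr::bind_rows(
    av("FANCI", "intronic", af = 0.45, pos = 900),                 # novel
    av("FANCI", "intronic", af = 0.45, pos = 950, dbsnp = 0.3),    # known
    av("FANCA", "intronic", af = 0.45, pos = 999)                  # other gene
  )
  f5 <- recessive_prioritize(hetv, all_annotated = others)
  row <- f5[f5$gene == "FANCI", ]
  expect_equal(row$status, "one_allele")
  expect_true(row$escalation)
  expect_equal(row$escalation_candidates[[1]]$pos, 900L)

  # het deletion alone is also a single-allele finding
  f6 <- recessive_prioritize(run_cascade(av("X", "intronic")[0, ], cfg),
                             deletion_calls = del_het)
  expect_equal(f6$status[f6$gene == "FANCI"], "one_allele")
  expect_equal(f6$status[f6$gene == "FANCA"], "none")
})

test_that("raising the allele-fraction threshold never creates new biallelic calls", {
  withr::local_seed(59)
  genes <- c("FANCA", "FANCC", "FANCI")
  for (i in 1:30) {
    n <- sample.int(8, 1)
    v <- dplyr::bind_rows(purrr::map(seq_len(n), function(j) {
      av(sample(genes, 1), sample(c("stopgain", "frameshift", "nonsynonymous"), 1),
         af = runif(1, 0.1, 1), n_damaging = 3L, pos = j * 7L)
    }))
    status_at <- function(min_af) {
      cfg <- fa_config(min_allele_fraction = min_af)
      recessive_prioritize(run_cascade(af_filter(v, cfg), cfg))$status
    }
    lo <- status_at(0.12)
    hi <- status_at(0.45)
    upgraded <- lo == "none" & hi == "biallelic"
    expect_false(any(upgraded))
  }
})

test_that("reports are deterministic under input shuffling and serialize findings", {
  withr::local_seed(61)
  cfg <- fa_config()
  v <- dplyr::bind_rows(
    av("FANCC", "frameshift", af = 0.45, pos = 10),
    av("FANCC", "canonical_splice", af = 0.52, pos = 400),
    av("FANCA", "stopgain", af = 0.97, pos = 77)
  )
  mk_report <- function(vv) {
    cascade <- run_cascade(vv, cfg)
    report_sample(recessive_prioritize(cascade), cascade, sample_id = "S")
  }
  r1 <- mk_report(v)
  r2 <- mk_report(v[sample.int(3), ])
  expect_equal(r1$findings, r2$findings)
  expect_equal(r1$funnel, r2$funnel)

  dir <- withr::local_tempdir()
  cascade <- run_cascade(v, cfg)
  report_sample(recessive_prioritize(cascade), cascade, sample_id = "S",
                dir = dir)
  j <- jsonlite::read_json(file.path(dir, "S_report.json"))
  statuses <- vapply(j$findings, function(x) x$status, character(1))
  expect_equal(sum(statuses == "biallelic"), 2)
  expect_true(file.exists(file.path(dir, "S_funnel.tsv")))
  funnel <- readr::read_tsv(file.path(dir, "S_funnel.tsv"), show_col_types = FALSE)
  expect_true(all(c("Variants (total)", "NS/SS", "Pathogenic clue")
                  %in% names(funnel)))
})
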