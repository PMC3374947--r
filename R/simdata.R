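# Deterministic synthetic capture-cohort generator: panel, per-base depth
# with spiked deletions and mixtures, and variant tables with ground truth.

# derived stream seeds stay within 32-bit integer range for any master seed
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) + 7919 * salt) %% 2147483647)
}

SENSE_CODONS <- setdiff(names(GENETIC_CODE_DNA), c("TAA", "TAG", "TGA"))
STOP_CODONS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")

#' Specify a synthetic capture cohort
#'
#' The specification pins every study condition: cohort size (11 samples,
#' mirroring a pooled flow-cell lane), per-base depth (Poisson, mean 100),
#' panel shape (15 disease genes, one 43-exon and one 38-exon gene included),
#' bait-driven per-target capture efficiency (lognormal, sigma 0.3, shared
#' across samples — which is what lets a pooled reference cancel it), the
#' planted copy-number events, and the planted pathogenic variants. All
#' randomness derives from `seed`; identical specs give byte-identical
#' cohorts.
#'
#' @param seed Integer master seed.
#' @param n_samples Number of samples (ids `S01`, `S02`, ...).
#' @param mean_depth Mean per-base depth of a diploid region.
#' @param n_genes Panel size; gene 1 gets 43 exons and gene 2 (when present)
#'   38 exons, the remainder draw from `exons_per_gene`.
#' @param exons_per_gene Inclusive range of exon counts for the other genes.
#' @param exon_size,intron_size Inclusive bp ranges for exon/intron lengths.
#' @param utr5,utr3 UTR lengths within the first/last exon (bp).
#' @param target_flank Exon flank captured on each side (bp).
#' @param efficiency_sd Lognormal sigma of per-target capture efficiency.
#' @param background_pool Number of panel-wide population alleles; each
#'   sample carries each allele under Hardy-Weinberg at its frequency.
#' @param events Tibble of planted copy-number events: `sample`, `gene`,
#'   `first_exon`, `last_exon` (transcript order, 1-based inclusive),
#'   `genotype` (`het_del`/`hom_del`), optional `mosaic_fraction` (fraction
#'   of genomes carrying a het deletion; `NA` = constitutional).
#' @param variants Tibble of planted variants: `sample`, `gene`, `class`
#'   (`stopgain`, `frameshift`, `missense_damaging`, `missense_benign`,
#'   `synonymous`, `canonical_splice`, `intronic`, `utr5`, `utr3`),
#'   `zygosity` (`het`/`hom`), `population_frequency` (`NA` = novel).
#' @return A `ps_cohort_spec` list.
#' @export
cohort_spec <- function(seed = 1L, n_samples = 11L, mean_depth = 100,
                        n_genes = 15L, exons_per_gene = c(2L, 20L),
                        exon_size = c(90L, 240L), intron_size = c(250L, 600L),
                        utr5 = 30L, utr3 = 30L, target_flank = 50L,
                        efficiency_sd = 0.3, background_pool = 600L,
                        events = NULL, variants = NULL) {
  if (mean_depth <= 0) abort("mean_depth must be positive")
  if (n_genes < 1) abort("n_genes must be >= 1")
  spec <- structure(
    list(
      seed = as.integer(seed), n_samples = as.integer(n_samples),
      sample_ids = sprintf("S%02d", seq_len(n_samples)),
      mean_depth = mean_depth, n_genes = as.integer(n_genes),
      exons_per_gene = as.integer(exons_per_gene),
      exon_size = as.integer(exon_size), intron_size = as.integer(intron_size),
      utr5 = as.integer(utr5), utr3 = as.integer(utr3),
      target_flank = as.integer(target_flank),
      efficiency_sd = efficiency_sd,
      background_pool = as.integer(background_pool),
      events = events, variants = variants
    ),
    class = "ps_cohort_spec"
  )
  spec
}

#' Generate the synthetic panel: gene models, targets, CDS sequences
#'
#' Genes sit on one chromosome each (`chr1`, `chr2`, ...), strands drawn at
#' random. Each gene gets an ATG-initiated CDS ending in a stop codon, with
#' short UTRs inside the terminal exons. Capture targets are the exons plus
#' `target_flank` bp on each side (introns are wide enough that targets
#' never merge), with a per-target capture efficiency shared by all samples.
#'
#' @param spec A [cohort_spec()].
#' @return List with `models` (refFlat-shaped tibble), `targets` (BED-shaped
#'   tibble + `efficiency`, `gene`, `exon` columns) and `cds_seqs` (named
#'   character vector).
#' @export
make_panel <- function(spec) {
  withr::with_seed(derive_seed(spec$seed, 0), {
    models <- list(); targets <- list(); cds_seqs <- character(0)
    for (g in seq_len(spec$n_genes)) {
      n_ex <- if (g == 1) 43L else if (g == 2) 38L else
        sample(seq(spec$exons_per_gene[1], spec$exons_per_gene[2]), 1)
      gene <- sprintf("FAG%02d", g)
      chrom <- paste0("chr", g)
      strand <- sample(c("+", "-"), 1)
      ex_sizes <- sample(seq(spec$exon_size[1], spec$exon_size[2]),
                         n_ex, replace = TRUE)
      in_sizes <- if (n_ex > 1) {
        sample(seq(spec$intron_size[1], spec$intron_size[2]),
               n_ex - 1, replace = TRUE)
      } else integer(0)
      starts <- integer(n_ex); ends <- integer(n_ex)
      cur <- 1000L
      for (j in seq_len(n_ex)) {
        starts[j] <- cur
        ends[j] <- cur + ex_sizes[j]
        cur <- ends[j] + if (j < n_ex) in_sizes[j] else 0L
      }
      # UTRs live inside the terminal exons, in transcript orientation
      if (strand == "+") {
        cds_start <- starts[1] + spec$utr5
        cds_end <- ends[n_ex] - spec$utr3
      } else {
        cds_start <- starts[1] + spec$utr3
        cds_end <- ends[n_ex] - spec$utr5
      }
      coding_len <- coding_length(starts, ends, cds_start, cds_end)
      # trim the transcript-3' end so the CDS is a whole number of codons
      trim <- coding_len %% 3L
      if (strand == "+") cds_end <- cds_end - trim else cds_start <- cds_start + trim
      coding_len <- coding_len - trim
      n_codons <- coding_len %/% 3L
      cds <- paste0(
        "ATG",
        paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE), collapse = ""),
        sample(STOP_CODONS, 1)
      )
      models[[g]] <- tibble::tibble(
        gene = gene, transcript = paste0(gene, ".t1"), chrom = chrom,
        strand = strand, tx_start = starts[1], tx_end = ends[n_ex],
        cds_start = cds_start, cds_end = cds_end, n_exons = n_ex,
        exon_starts = list(starts), exon_ends = list(ends)
      )
      tx_num <- if (strand == "-") rev(seq_len(n_ex)) else seq_len(n_ex)
      targets[[g]] <- tibble::tibble(
        chrom = chrom,
        start = pmax(starts - spec$target_flank, 0L),
        end = ends + spec$target_flank,
        label = sprintf("%s_ex%d", gene, tx_num),
        gene = gene, exon = tx_num
      )
      cds_seqs[[gene]] <- cds
    }
    targets <- dplyr::bind_rows(targets)
    targets$efficiency <- exp(rnorm(nrow(targets), 0, spec$efficiency_sd))
    list(
      models = dplyr::bind_rows(models),
      targets = targets,
      cds_seqs = cds_seqs
    )
  })
}

coding_length <- function(starts, ends, cds_start, cds_end) {
  sum(pmax(0L, pmin(ends, cds_end) - pmax(starts, cds_start)))
}

# Genomic span [start0, end0) of a transcript-order exon range, extended to
# the exons' capture targets.
event_span <- function(model, first_exon, last_exon, flank) {
  n <- model$n_exons
  tx <- first_exon:last_exon
  gidx <- if (model$strand == "-") n - tx + 1L else tx
  starts <- model$exon_starts[[1]][gidx]
  ends <- model$exon_ends[[1]][gidx]
  c(max(min(starts) - flank, 0L), max(ends) + flank)
}

#' Simulate one sample's per-base depth over the panel
#'
#' Per-base depth at each targeted position is Poisson with mean
#' `mean_depth x efficiency x cn/2`, where the capture efficiency is the
#' target's (shared across samples) and cn is the planted copy number: 2
#' normally, 1 in a constitutional heterozygous deletion, 0 in a homozygous
#' deletion, and 2 - f for a heterozygous deletion carried by a fraction f
#' of genomes. Planted deletions span the whole capture targets of their
#' exon range (breakpoints beyond the flanks).
#'
#' @param spec A [cohort_spec()].
#' @param panel The [make_panel()] output for `spec`.
#' @param sample_id One of `spec$sample_ids`.
#' @return Per-base depth tibble: `chrom`, `pos` (1-based), `depth`,
#'   `sample_id`.
#' @export
simulate_depth <- function(spec, panel, sample_id) {
  idx <- match(sample_id, spec$sample_ids)
  if (is.na(idx)) abort(paste0("unknown sample id: ", sample_id))
  tg <- panel$targets
  pos_list <- purrr::map(seq_len(nrow(tg)), function(i) {
    seq.int(tg$start[[i]] + 1L, tg$end[[i]])
  })
  n_per <- lengths(pos_list)
  chrom <- rep(tg$chrom, n_per)
  pos <- unlist(pos_list)
  eff <- rep(tg$efficiency, n_per)
  cn <- rep(2, length(pos))
  ev <- spec$events
  if (!is.null(ev) && nrow(ev) > 0) {
    ev_s <- ev[ev$sample == sample_id, , drop = FALSE]
    for (k in seq_len(nrow(ev_s))) {
      model <- panel$models[panel$models$gene == ev_s$gene[[k]], ]
      if (nrow(model) == 0) abort(paste0("event in unknown gene: ", ev_s$gene[[k]]))
      span <- event_span(model, ev_s$first_exon[[k]], ev_s$last_exon[[k]],
                         spec$target_flank)
      f <- if ("mosaic_fraction" %in% names(ev_s)) ev_s$mosaic_fraction[[k]] else NA
      val <- switch(ev_s$genotype[[k]],
        hom_del = 0,
        het_del = if (!is.na(f)) 2 - f else 1,
        abort(paste0("unknown event genotype: ", ev_s$genotype[[k]]))
      )
      hit <- chrom == model$chrom & pos > span[1] & pos <= span[2]
      cn[hit] <- val
    }
  }
  depth <- withr::with_seed(derive_seed(spec$seed, idx), {
    rpois(length(pos), spec$mean_depth * eff * cn / 2)
  })
  tibble::tibble(chrom = chrom, pos = pos, depth = depth,
                 sample_id = sample_id)
}

#' Pool two samples into one, emulating a mosaic condition
#'
#' Mixes two samples' depth (and optionally their variant tables) in
#' proportion `p` : `1 - p`, as when two DNA samples are pooled before
#' library preparation. Depth is the rounded weighted sum per position;
#' variant allele fractions are re-derived from the weighted allele depths,
#' with a variant absent from one sample contributing that sample's
#' reference-only coverage to the pooled total.
#'
#' @param a,b Per-base depth tibbles over the same panel positions.
#' @param p Proportion of sample `a` (0 < p < 1).
#' @param sample_id Id for the pooled sample.
#' @param variants_a,variants_b Optional variant tibbles of the two samples.
#' @return List with `depth` and (when variants were given) `variants`.
#' @export
mix_samples <- function(a, b, p = 0.5, sample_id = "mix",
                        variants_a = NULL, variants_b = NULL) {
  if (p <= 0 || p >= 1) abort("p must be in (0, 1)")
  a <- dplyr::arrange(a, .data$chrom, .data$pos)
  b <- dplyr::arrange(b, .data$chrom, .data$pos)
  if (nrow(a) != nrow(b) ||
      !all(a$chrom == b$chrom) || !all(a$pos == b$pos)) {
    abort("samples cover different panels; cannot mix")
  }
  depth <- tibble::tibble(
    chrom = a$chrom, pos = a$pos,
    depth = as.integer(round(p * a$depth + (1 - p) * b$depth)),
    sample_id = sample_id
  )
  out <- list(depth = depth)
  if (!is.null(variants_a) || !is.null(variants_b)) {
    va <- variants_a %||% variants_a_template()
    vb <- variants_b %||% variants_a_template()
    key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt)
    keys <- union(key(va), key(vb))
    depth_at <- function(d, chrom, pos) {
      hit <- d$depth[d$chrom == chrom & d$pos == pos]
      if (length(hit) == 0) 0L else hit[[1]]
    }
    rows <- purrr::map(keys, function(k) {
      ia <- match(k, key(va)); ib <- match(k, key(vb))
      src <- if (!is.na(ia)) va[ia, ] else vb[ib, ]
      tot_a <- if (!is.na(ia)) va$total_depth[[ia]] else depth_at(a, src$chrom, src$pos)
      tot_b <- if (!is.na(ib)) vb$total_depth[[ib]] else depth_at(b, src$chrom, src$pos)
      alt_a <- if (!is.na(ia)) va$alt_depth[[ia]] else 0L
      alt_b <- if (!is.na(ib)) vb$alt_depth[[ib]] else 0L
      tot <- as.integer(round(p * tot_a + (1 - p) * tot_b))
      alt_n <- as.integer(round(p * alt_a + (1 - p) * alt_b))
      tibble::tibble(
        chrom = src$chrom, pos = src$pos, ref = src$ref, alt = src$alt,
        total_depth = tot, alt_depth = alt_n,
        allele_fraction = if (tot > 0) alt_n / tot else 0,
        sample_id = sample_id
      )
    })
    out$variants <- dplyr::bind_rows(rows) |>
      dplyr::arrange(.data$chrom, .data$pos, .data$alt)
  }
  out
}

variants_a_template <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    total_depth = integer(), alt_depth = integer(),
    allele_fraction = double(), sample_id = character()
  )
}

# Panel-wide lookup of every targeted position's gene, coding index and
# (for coding positions) genomic-strand reference base.
panel_position_table <- function(panel) {
  rows <- purrr::map(seq_len(nrow(panel$models)), function(gi) {
    model <- panel$models[gi, ]
    tg <- panel$targets[panel$targets$gene == model$gene, , drop = FALSE]
    pos <- unlist(purrr::map2(tg$start, tg$end, ~ seq.int(.x + 1L, .y)))
    pos <- sort(unique(pos))
    map <- tx_map(model)
    tidx <- match(pos, map$g)
    ci <- ifelse(!is.na(tidx) & tidx >= map$ci1 & tidx <= map$ci2,
                 tidx - map$ci1 + 1L, NA_integer_)
    cds <- panel$cds_seqs[[model$gene]]
    tx_base <- ifelse(is.na(ci), NA_character_,
                      substring(cds, ci, ci))
    gref <- ifelse(is.na(ci), NA_character_,
                   if (model$strand == "-") chartr("ACGT", "TGCA", tx_base) else tx_base)
    tibble::tibble(chrom = model$chrom, pos = pos, gene = model$gene,
                   coding_index = ci, genomic_ref = gref)
  })
  dplyr::bind_rows(rows)
}

#' Draw the panel-wide pool of background population alleles
#'
#' A fixed (seed-determined) set of alleles over the targeted positions,
#' each with a population frequency: mostly common alleles (3-50%), a
#' minority rare (0.1-2%), and a subset also present in the in-house
#' database. Samples carry pool alleles under Hardy-Weinberg.
#'
#' @param spec A [cohort_spec()].
#' @param panel The matching [make_panel()] output.
#' @return Tibble of alleles with `dbsnp_frequency`, `inhouse_frequency`.
#' @export
make_variant_pool <- function(spec, panel) {
  ptab <- panel_position_table(panel)
  withr::with_seed(derive_seed(spec$seed, 5000), {
    n <- min(spec$background_pool, nrow(ptab))
    pick <- sort(sample.int(nrow(ptab), n))
    pool <- ptab[pick, ]
    ref <- ifelse(is.na(pool$genomic_ref),
                  sample(BASES, n, replace = TRUE), pool$genomic_ref)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1),
                  USE.NAMES = FALSE)
    common <- runif(n) < 0.8
    freq <- ifelse(common, runif(n, 0.03, 0.5), runif(n, 0.001, 0.02))
    inhouse <- ifelse(runif(n) < 0.4,
                      pmin(1, pmax(0, freq + runif(n, -0.01, 0.01))),
                      NA_real_)
    tibble::tibble(
      chrom = pool$chrom, pos = pool$pos, ref = ref, alt = alt,
      gene = pool$gene, coding_index = pool$coding_index,
      dbsnp_frequency = freq, inhouse_frequency = inhouse
    )
  })
}

# Pick a planted variant's genomic position and alleles for a given class.
# Operates in transcript space, then converts to genomic-strand alleles.
place_planted_variant <- function(class, model, cds) {
  n_codons <- nchar(cds) %/% 3L
  map <- tx_map(model)
  minus <- model$strand == "-"
  to_genomic <- function(b) if (minus) chartr("ACGT", "TGCA", b) else b
  g_of_ci <- function(ci) map$g[map$ci1 + ci - 1L]
  codon_at <- function(i) substring(cds, (i - 1L) * 3L + 1L, i * 3L)
  if (class %in% c("stopgain", "missense_damaging", "missense_benign",
                   "synonymous")) {
    for (try in 1:500) {
      ci <- sample.int(nchar(cds) - 6L, 1) + 3L  # skip start & stop codons
      codon_i <- (ci - 1L) %/% 3L + 1L
      within <- (ci - 1L) %% 3L + 1L
      codon <- codon_at(codon_i)
      tx_ref <- substring(codon, within, within)
      for (tx_alt in sample(setdiff(BASES, tx_ref))) {
        alt_codon <- codon
        substring(alt_codon, within, within) <- tx_alt
        aa_ref <- GENETIC_CODE_DNA[[codon]]
        aa_alt <- GENETIC_CODE_DNA[[alt_codon]]
        ok <- switch(class,
          stopgain = aa_alt == "*" && aa_ref != "*",
          synonymous = aa_alt == aa_ref,
          aa_alt != aa_ref && aa_alt != "*" && aa_ref != "*"
        )
        if (ok) {
          return(list(pos = g_of_ci(ci), ref = to_genomic(tx_ref),
                      alt = to_genomic(tx_alt)))
        }
      }
    }
    abort(paste0("could not place a ", class, " variant in ", model$gene))
  }
  if (class == "frameshift") {
    ci <- sample.int(nchar(cds) - 6L, 1) + 3L
    tx_ref <- substring(cds, ci, ci)
    g <- g_of_ci(ci)
    gref <- to_genomic(tx_ref)
    return(list(pos = g, ref = gref, alt = paste0(gref, "AT")))
  }
  if (class == "canonical_splice") {
    if (model$n_exons < 2) abort("canonical_splice needs a multi-exon gene")
    j <- sample.int(model$n_exons - 1L, 1)  # genomic intron index
    pos <- model$exon_ends[[1]][j] + 1L     # first intronic base, either strand
    ref <- sample(BASES, 1)
    return(list(pos = pos, ref = ref, alt = sample(setdiff(BASES, ref), 1)))
  }
  if (class == "intronic") {
    if (model$n_exons < 2) abort("intronic variant needs a multi-exon gene")
    j <- sample.int(model$n_exons - 1L, 1)
    lo <- model$exon_ends[[1]][j] + 10L
    hi <- model$exon_starts[[1]][j + 1L] - 10L
    pos <- sample(seq.int(lo, hi), 1)
    ref <- sample(BASES, 1)
    return(list(pos = pos, ref = ref, alt = sample(setdiff(BASES, ref), 1)))
  }
  if (class %in% c("utr5", "utr3")) {
    tidx <- if (class == "utr5") {
      sample.int(map$ci1 - 1L, 1)
    } else {
      map$ci2 + sample.int(length(map$g) - map$ci2, 1)
    }
    pos <- map$g[tidx]
    ref <- sample(BASES, 1)
    return(list(pos = pos, ref = ref, alt = sample(setdiff(BASES, ref), 1)))
  }
  abort(paste0("unknown planted variant class: ", class))
}

#' Simulate one sample's variant call set
#'
#' Background alleles are the sample's Hardy-Weinberg draw from the
#' panel-wide pool ([make_variant_pool()]); planted pathogenic variants get
#' class-appropriate alleles (stop-creating substitution, 2-bp frameshift
#' insertion, damaging missense with three damaging predictor verdicts,
#' benign missense with one, splice/intronic/UTR substitutions). Allele
#' depths are binomial(site depth, allele fraction) with fraction 0.5 (het)
#' or 1 (hom).
#'
#' @param spec A [cohort_spec()].
#' @param panel The matching [make_panel()] output.
#' @param sample_id One of `spec$sample_ids`.
#' @param pool Pool from [make_variant_pool()] (rebuilt if omitted).
#' @param depth Optional per-base depth tibble; site depths fall back to
#'   Poisson(`mean_depth`) where (or when) no track is given.
#' @return List with `variants` (VCF-shaped tibble), `predictors`,
#'   `truth` (planted-variant records incl. class and zygosity).
#' @export
simulate_variants <- function(spec, panel, sample_id,
                              pool = make_variant_pool(spec, panel),
                              depth = NULL) {
  idx <- match(sample_id, spec$sample_ids)
  if (is.na(idx)) abort(paste0("unknown sample id: ", sample_id))
  lookup <- if (!is.null(depth)) {
    setNames(depth$depth, paste(depth$chrom, depth$pos))
  }
  depth_at <- function(chrom, pos) {
    if (!is.null(lookup)) {
      hit <- lookup[paste(chrom, pos)]
      if (!is.na(hit)) return(unname(hit))
    }
    rpois(1, spec$mean_depth)
  }
  withr::with_seed(derive_seed(spec$seed, 10000 + idx), {
    # background: Hardy-Weinberg carriage of pool alleles
    f <- pool$dbsnp_frequency
    u <- runif(nrow(pool))
    genotype <- ifelse(u < f^2, "hom", ifelse(u < f^2 + 2 * f * (1 - f),
                                              "het", "none"))
    carried <- pool[genotype != "none", , drop = FALSE]
    carried_af <- ifelse(genotype[genotype != "none"] == "hom", 1, 0.5)
    bg <- list()
    if (nrow(carried) > 0) {
      tot <- if (!is.null(lookup)) {
        v <- unname(lookup[paste(carried$chrom, carried$pos)])
        miss <- is.na(v)
        v[miss] <- rpois(sum(miss), spec$mean_depth)
        v
      } else {
        rpois(nrow(carried), spec$mean_depth)
      }
      alt_n <- ifelse(carried_af >= 1, tot,
                      rbinom(nrow(carried), tot, carried_af))
      bg <- list(tibble::tibble(
        chrom = carried$chrom, pos = carried$pos,
        ref = carried$ref, alt = carried$alt,
        total_depth = as.integer(tot), alt_depth = as.integer(alt_n),
        allele_fraction = ifelse(tot > 0, alt_n / tot, 0),
        sample_id = sample_id
      ))
    }
    planted <- list(); predictors <- list(); truth <- list()
    pv <- spec$variants
    if (!is.null(pv) && nrow(pv) > 0) {
      pv_s <- pv[pv$sample == sample_id, , drop = FALSE]
      for (k in seq_len(nrow(pv_s))) {
        gene <- pv_s$gene[[k]]
        model <- panel$models[panel$models$gene == gene, ]
        if (nrow(model) == 0) abort(paste0("planted variant in unknown gene: ", gene))
        pl <- place_planted_variant(pv_s$class[[k]], model,
                                    panel$cds_seqs[[gene]])
        af <- if (pv_s$zygosity[[k]] == "hom") 1 else 0.5
        tot <- depth_at(model$chrom, pl$pos)
        alt_n <- if (af >= 1) tot else rbinom(1, tot, af)
        planted[[k]] <- tibble::tibble(
          chrom = model$chrom, pos = pl$pos, ref = pl$ref, alt = pl$alt,
          total_depth = as.integer(tot), alt_depth = as.integer(alt_n),
          allele_fraction = if (tot > 0) alt_n / tot else 0,
          sample_id = sample_id
        )
        if (pv_s$class[[k]] == "missense_damaging") {
          predictors[[k]] <- tibble::tibble(
            chrom = model$chrom, pos = pl$pos, ref = pl$ref, alt = pl$alt,
            predictor = c("SIFT", "PolyPhen-2", "Align-GVGD"),
            verdict = rep("damaging", 3)
          )
        } else if (pv_s$class[[k]] == "missense_benign") {
          predictors[[k]] <- tibble::tibble(
            chrom = model$chrom, pos = pl$pos, ref = pl$ref, alt = pl$alt,
            predictor = c("SIFT", "PolyPhen-2", "Align-GVGD"),
            verdict = c("damaging", "benign", "benign")
          )
        }
        truth[[k]] <- tibble::tibble(
          sample = sample_id, gene = gene, class = pv_s$class[[k]],
          zygosity = pv_s$zygosity[[k]],
          population_frequency = pv_s$population_frequency[[k]],
          chrom = model$chrom, pos = pl$pos, ref = pl$ref, alt = pl$alt
        )
      }
    }
    list(
      variants = dplyr::bind_rows(c(bg, planted)) |>
        dplyr::arrange(.data$chrom, .data$pos, .data$alt),
      predictors = if (length(predictors) > 0) dplyr::bind_rows(predictors)
                   else tibble::tibble(
                     chrom = character(), pos = integer(), ref = character(),
                     alt = character(), predictor = character(),
                     verdict = character()
                   ),
      truth = if (length(truth) > 0) dplyr::bind_rows(truth)
              else tibble::tibble(
                sample = character(), gene = character(), class = character(),
                zygosity = character(), population_frequency = double(),
                chrom = character(), pos = integer(), ref = character(),
                alt = character()
              )
    )
  })
}

#' Simulate the full cohort
#'
#' Panel, per-sample depth tracks, per-sample variant sets, the cohort
#' frequency table (pool alleles plus planted variants with a declared
#' population frequency) and predictor verdicts, together with the truth
#' set.
#'
#' @param spec A [cohort_spec()].
#' @return A `ps_cohort` list: `spec`, `panel`, `depth` (long, all samples),
#'   `variants` (long), `frequencies`, `predictors`, `truth` (list with
#'   `deletions` and `variants` tibbles).
#' @export
simulate_cohort <- function(spec) {
  panel <- make_panel(spec)
  pool <- make_variant_pool(spec, panel)
  depth <- purrr::map(spec$sample_ids, ~ simulate_depth(spec, panel, .x))
  names(depth) <- spec$sample_ids
  vsets <- purrr::map(spec$sample_ids, function(s) {
    simulate_variants(spec, panel, s, pool = pool, depth = depth[[s]])
  })
  freq <- pool[, c("chrom", "pos", "ref", "alt",
                   "dbsnp_frequency", "inhouse_frequency")]
  planted_truth <- dplyr::bind_rows(purrr::map(vsets, "truth"))
  if (nrow(planted_truth) > 0) {
    extra <- planted_truth[!is.na(planted_truth$population_frequency), ,
                           drop = FALSE]
    if (nrow(extra) > 0) {
      freq <- dplyr::bind_rows(
        freq,
        tibble::tibble(
          chrom = extra$chrom, pos = extra$pos, ref = extra$ref,
          alt = extra$alt, dbsnp_frequency = extra$population_frequency,
          inhouse_frequency = NA_real_
        )
      )
    }
  }
  structure(
    list(
      spec = spec,
      panel = panel,
      depth = dplyr::bind_rows(depth),
      variants = dplyr::bind_rows(purrr::map(vsets, "variants")),
      frequencies = dplyr::distinct(freq, .data$chrom, .data$pos, .data$ref,
                                    .data$alt, .keep_all = TRUE),
      predictors = dplyr::bind_rows(purrr::map(vsets, "predictors")),
      truth = list(
        deletions = spec$events %||%
          tibble::tibble(sample = character(), gene = character(),
                         first_exon = integer(), last_exon = integer(),
                         genotype = character(), mosaic_fraction = double()),
        variants = planted_truth
      )
    ),
    class = "ps_cohort"
  )
}

#' Write a simulated cohort to plain-text files
#'
#' Emits `targets.bed`, `genes.refflat`, `cds.tsv` (gene, CDS sequence),
#' per-sample `<id>_depth.tsv` and `<id>.vcf`, `frequencies.tsv`,
#' `predictors.tsv` and `truth.json`.
#'
#' @param cohort A `ps_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(cohort$panel$targets, file.path(dir, "targets.bed"))
  write_refflat(cohort$panel$models, file.path(dir, "genes.refflat"))
  readr::write_tsv(
    tibble::tibble(gene = names(cohort$panel$cds_seqs),
                   cds = unname(cohort$panel$cds_seqs)),
    file.path(dir, "cds.tsv")
  )
  for (s in unique(cohort$depth$sample_id)) {
    write_depth_table(cohort$depth[cohort$depth$sample_id == s, ],
                      file.path(dir, paste0(s, "_depth.tsv")))
  }
  for (s in unique(cohort$variants$sample_id)) {
    write_vcf(cohort$variants[cohort$variants$sample_id == s, ],
              file.path(dir, paste0(s, ".vcf")))
  }
  write_frequency_table(cohort$frequencies, file.path(dir, "frequencies.tsv"))
  write_predictor_table(cohort$predictors, file.path(dir, "predictors.tsv"))
  jsonlite::write_json(
    list(deletions = cohort$truth$deletions, variants = cohort$truth$variants),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(dir)
}

#' Read a CDS sequence table written by [write_cohort()]
#' @param path Path to `cds.tsv`.
#' @return Named character vector of CDS sequences.
#' @export
read_cds_table <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), cds = readr::col_character()
  ), progress = FALSE)
  setNames(d$cds, d$gene)
}
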