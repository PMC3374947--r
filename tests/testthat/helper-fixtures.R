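# Shared fixture builders. Everything is generated in code under fixed
# seeds; no fixture files.

# One-row gene-model tibble with explicit coordinates (0-based half-open).
toy_model <- function(gene = "TOY", chrom = "chr1", strand = "+",
                      exon_starts, exon_ends,
                      cds_start = exon_starts[1],
                      cds_end = exon_ends[length(exon_ends)]) {
  tibble::tibble(
    gene = gene, transcript = paste0(gene, ".t1"), chrom = chrom,
    strand = strand,
    tx_start = exon_starts[1], tx_end = exon_ends[length(exon_ends)],
    cds_start = cds_start, cds_end = cds_end,
    n_exons = length(exon_starts),
    exon_starts = list(as.integer(exon_starts)),
    exon_ends = list(as.integer(exon_ends))
  )
}

# Random multi-exon transcript with a coherent CDS sequence; returns
# list(model, cds, genome) where genome is a named vector of the plus-strand
# base at every transcript-span position (introns included).
random_transcript <- function(gene = "RND", chrom = "chrZ") {
  n_ex <- sample(1:6, 1)
  strand <- sample(c("+", "-"), 1)
  ex_sizes <- sample(30:90, n_ex, replace = TRUE)
  in_sizes <- if (n_ex > 1) sample(20:80, n_ex - 1, replace = TRUE) else integer(0)
  starts <- integer(n_ex); ends <- integer(n_ex)
  cur <- 500L
  for (j in seq_len(n_ex)) {
    starts[j] <- cur; ends[j] <- cur + ex_sizes[j]
    cur <- ends[j] + if (j < n_ex) in_sizes[j] else 0L
  }
  u5 <- sample(0:10, 1); u3 <- sample(0:10, 1)
  cds_start <- starts[1] + (if (strand == "+") u5 else u3)
  cds_end <- ends[n_ex] - (if (strand == "+") u3 else u5)
  clen <- sum(pmax(0L, pmin(ends, cds_end) - pmax(starts, cds_start)))
  trim <- clen %% 3L
  if (strand == "+") cds_end <- cds_end - trim else cds_start <- cds_start + trim
  clen <- clen - trim
  if (clen < 9) return(random_transcript(gene, chrom))  # resample degenerate
  sense <- setdiff(names(panelscreen:::GENETIC_CODE_DNA), c("TAA", "TAG", "TGA"))
  cds <- paste0(
    "ATG",
    paste(sample(sense, clen %/% 3L - 2L, replace = TRUE), collapse = ""),
    sample(c("TAA", "TAG", "TGA"), 1)
  )
  model <- toy_model(gene, chrom, strand, starts, ends, cds_start, cds_end)
  # lay the CDS bases onto the genome (plus-strand), random bases elsewhere
  span <- (starts[1] + 1L):ends[n_ex]
  genome <- setNames(sample(c("A", "C", "G", "T"), length(span), replace = TRUE),
                     span)
  map <- panelscreen:::tx_map(model)
  cds_bases <- strsplit(cds, "")[[1]]
  g_cds <- map$g[map$ci1:map$ci2]
  genome[as.character(g_cds)] <-
    if (strand == "-") chartr("ACGT", "TGCA", cds_bases) else cds_bases
  list(model = model, cds = cds, genome = genome)
}

# Brute-force consequence oracle for coding SNVs: rebuild the entire CDS
# from the genome, apply the substitution, translate both alleles fully
# with Biostrings, and compare the proteins.
oracle_classify_snv <- function(pos, alt, tx) {
  model <- tx$model
  map <- panelscreen:::tx_map(model)
  g_cds <- map$g[map$ci1:map$ci2]
  ref_seq <- tx$genome
  alt_seq <- ref_seq
  alt_seq[as.character(pos)] <- alt
  fetch <- function(genome) {
    b <- genome[as.character(g_cds)]
    s <- paste(b, collapse = "")
    if (model$strand == "-") {
      # bases were collected in transcript order already; complement only
      s <- as.character(Biostrings::complement(Biostrings::DNAString(s)))
    }
    s
  }
  p_ref <- as.character(Biostrings::translate(
    Biostrings::DNAString(fetch(ref_seq)), no.init.codon = TRUE
  ))
  p_alt <- as.character(Biostrings::translate(
    Biostrings::DNAString(fetch(alt_seq)), no.init.codon = TRUE
  ))
  diff <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
  if (length(diff) == 0) return("synonymous")
  aa_alt <- substr(p_alt, diff[1], diff[1])
  aa_ref <- substr(p_ref, diff[1], diff[1])
  if (aa_alt == "*" && aa_ref != "*") "stopgain" else "nonsynonymous"
}

# Minimal annotated-variant row builder.
av <- function(gene, effect, af = 0.5, dbsnp = NA_real_, inhouse = NA_real_,
               n_damaging = 0L, pos = 1L, pgflag = FALSE, chrom = "chr1") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = "A", alt = "T",
    total_depth = 100L, alt_depth = as.integer(af * 100),
    allele_fraction = af, sample_id = "S",
    gene = gene, transcript = paste0(gene, ".t1"),
    effect_class = effect, protein_change = NA_character_,
    hgvs_c = NA_character_,
    dbsnp_frequency = dbsnp, inhouse_frequency = inhouse,
    predictor_verdicts = list(character(0)),
    n_damaging = as.integer(n_damaging), n_predictors = 3L,
    pseudogene_flag = pgflag, expected_af = NA_real_
  )
}

# Deletion-screen scenario used across CNV tests: n diploid samples plus one
# carrier; optionally the carrier is an equimolar pool with a diploid sample.
sim_deletion_screen <- function(seed, gene = "FAG01", first_exon = 15L,
                                last_exon = 23L, mix = FALSE,
                                mosaic_mode = FALSE, n_genes = 15L) {
  n_samples <- if (mix) 12L else 11L
  carrier <- sprintf("S%02d", n_samples)
  ev <- tibble::tibble(
    sample = carrier, gene = gene,
    first_exon = first_exon, last_exon = last_exon,
    genotype = "het_del", mosaic_fraction = NA_real_
  )
  spec <- cohort_spec(seed = seed, n_samples = n_samples, events = ev,
                      n_genes = n_genes)
  panel <- make_panel(spec)
  background <- spec$sample_ids[1:10]
  depth <- dplyr::bind_rows(
    lapply(background, function(s) simulate_depth(spec, panel, s))
  )
  if (mix) {
    a <- simulate_depth(spec, panel, "S11")
    b <- simulate_depth(spec, panel, carrier)
    test_id <- "MIX"
    depth <- dplyr::bind_rows(depth,
                              mix_samples(a, b, 0.5, sample_id = test_id)$depth)
  } else {
    test_id <- carrier
    depth <- dplyr::bind_rows(depth, simulate_depth(spec, panel, carrier))
  }
  screen <- cnv_screen(depth, panel$targets, panel$models,
                       mosaic_mode = mosaic_mode)
  list(spec = spec, panel = panel, screen = screen, test_id = test_id)
}

# Mean normalized M over the deleted exons of the test sample.
deleted_exon_mean_M <- function(scn, gene = "FAG01", exons = 15:23) {
  sm <- scn$screen$summaries
  sm <- sm[sm$sample_id == scn$test_id & sm$gene == gene & sm$exon %in% exons, ]
  sum(sm$mean_M * sm$n_windows) / sum(sm$n_windows)
}
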