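# Transcript-aware consequence annotation with HGVS c. positions.
#
# Coordinate conventions: gene models are 0-based half-open (refFlat);
# variant positions are 1-based (VCF). All mapping happens through an
# explicit exonic-base table in transcript order, so plus and minus strands
# share one code path.

# Standard genetic code, DNA alphabet.
GENETIC_CODE_DNA <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Exonic-base table of a transcript: 1-based genomic positions of every
# exonic base in transcript (5'->3') order, plus the transcript indices of
# the first and last coding base.
tx_map <- function(model) {
  starts <- model$exon_starts[[1]]
  ends <- model$exon_ends[[1]]
  g <- unlist(purrr::map2(starts, ends, ~ seq.int(.x + 1L, .y)))
  if (model$strand == "-") g <- rev(g)
  has_cds <- model$cds_start < model$cds_end
  if (has_cds) {
    cds_g <- g >= model$cds_start + 1L & g <= model$cds_end
    ci <- range(which(cds_g))
  } else {
    ci <- c(NA_integer_, NA_integer_)
  }
  list(g = g, ci1 = ci[1], ci2 = ci[2], has_cds = has_cds)
}

# Coding-coordinate label of a transcript index: "N" inside the CDS,
# "-k" in the 5' UTR, "*k" in the 3' UTR.
coding_label <- function(tidx, map) {
  ifelse(
    tidx < map$ci1, paste0("-", map$ci1 - tidx),
    ifelse(tidx > map$ci2, paste0("*", tidx - map$ci2),
           as.character(tidx - map$ci1 + 1L))
  )
}

#' Convert a genomic position to an HGVS c. position
#'
#' Coding positions are numbered from the A of the ATG (c.1). Intronic
#' positions are written as an offset from the nearest exon edge: `c.N+k`
#' counting into the intron from the preceding exon's last base, `c.M-k`
#' counting back from the following exon's first base, choosing whichever
#' offset k is smaller (ties go to `+`). 5'/3' UTR exonic positions are
#' `c.-k` / `c.*k`. Strand-aware.
#'
#' @param pos 1-based genomic position(s) within the transcript span.
#' @param model One-row gene-model tibble.
#' @return Character vector of HGVS c. position strings (e.g. `"c.893+920"`).
#' @export
genomic_to_cdna <- function(pos, model) {
  stopifnot(nrow(model) == 1)
  map <- tx_map(model)
  if (!map$has_cds) abort("model has no CDS; c. positions are undefined")
  span_lo <- model$tx_start + 1L
  span_hi <- model$tx_end
  vapply(pos, function(p) {
    if (p < span_lo || p > span_hi) {
      abort(paste0("position ", p, " is outside the transcript span"))
    }
    tidx <- match(p, map$g)
    if (!is.na(tidx)) {
      return(paste0("c.", coding_label(tidx, map)))
    }
    # intronic: exon edges on either genomic side
    up_g <- max(map$g[map$g < p])   # genomically previous exonic base
    dn_g <- min(map$g[map$g > p])   # genomically next exonic base
    if (model$strand == "+") {
      prev_g <- up_g; next_g <- dn_g
    } else {
      prev_g <- dn_g; next_g <- up_g  # transcript order reversed
    }
    k_prev <- abs(p - prev_g)
    k_next <- abs(next_g - p)
    if (k_prev <= k_next) {
      paste0("c.", coding_label(match(prev_g, map$g), map), "+", k_prev)
    } else {
      paste0("c.", coding_label(match(next_g, map$g), map), "-", k_next)
    }
  }, character(1))
}

#' Convert an HGVS c. position back to a genomic position
#'
#' Inverse of [genomic_to_cdna()] for simple positions (`c.N`, `c.-k`,
#' `c.*k`, and intronic `c.N+k` / `c.N-k` forms).
#'
#' @param hgvs Character vector of c. position strings.
#' @param model One-row gene-model tibble.
#' @return Integer vector of 1-based genomic positions.
#' @export
cdna_to_genomic <- function(hgvs, model) {
  stopifnot(nrow(model) == 1)
  map <- tx_map(model)
  if (!map$has_cds) abort("model has no CDS; c. positions are undefined")
  vapply(hgvs, function(h) {
    m <- regmatches(h, regexec("^c\\.(\\*?)(-?\\d+)([+-]\\d+)?$", h))[[1]]
    if (length(m) == 0) abort(paste0("cannot parse c. position: ", h))
    anchor_num <- as.integer(m[3])
    tidx <- if (m[2] == "*") {
      map$ci2 + anchor_num
    } else if (anchor_num < 0) {
      map$ci1 + anchor_num  # c.-k
    } else {
      map$ci1 + anchor_num - 1L
    }
    if (tidx < 1 || tidx > length(map$g)) {
      abort(paste0("c. position outside transcript: ", h))
    }
    g <- map$g[tidx]
    if (m[4] == "") return(as.integer(g))
    off <- as.integer(m[4])  # +k: into intron downstream of anchor base
    dir <- if (model$strand == "+") 1L else -1L
    as.integer(g + dir * off)
  }, integer(1), USE.NAMES = FALSE)
}

#' Classify the consequence of a variant on a transcript
#'
#' Deterministic rules in priority order: an indel overlapping the CDS is a
#' `frameshift` when its length change is not a multiple of 3, else an
#' `inframe_indel`; a coding SNV creating a stop is `stopgain`, changing the
#' amino acid `nonsynonymous`, preserving it `synonymous`; a position within
#' 2 bp of an exon-intron junction on the intron side is `canonical_splice`
#' (the GT/AG dinucleotides); remaining positions are `intronic`, `utr5`,
#' `utr3` or `intergenic` by location. For coding SNVs the simple protein
#' change (`p.A2T` style) is also returned. The variant's ref allele must
#' agree with the transcript's CDS sequence at coding positions.
#'
#' @param chrom,pos,ref,alt The variant (genomic, 1-based, plus-strand
#'   alleles).
#' @param model One-row gene-model tibble.
#' @param cds_seq The transcript's spliced CDS sequence (c.1 .. stop), on the
#'   transcript strand.
#' @return List with `effect_class` and `protein_change` (`NA` unless a
#'   coding SNV).
#' @export
classify_consequence <- function(chrom, pos, ref, alt, model, cds_seq) {
  stopifnot(nrow(model) == 1)
  out <- function(cls, prot = NA_character_) {
    list(effect_class = cls, protein_change = prot)
  }
  if (chrom != model$chrom || pos < model$tx_start + 1L || pos > model$tx_end) {
    return(out("intergenic"))
  }
  map <- tx_map(model)
  if (!map$has_cds) abort("model has no CDS; cannot classify consequences")
  is_snv <- nchar(ref) == 1 && nchar(alt) == 1
  if (!is_snv) {
    # indel: does its genomic footprint touch a coding base?
    span <- pos:(pos + max(nchar(ref), 1L) - 1L)
    tidx <- match(span, map$g)
    in_cds <- !is.na(tidx) & tidx >= map$ci1 & tidx <= map$ci2
    if (any(in_cds)) {
      shift <- nchar(alt) - nchar(ref)
      return(out(if (shift %% 3 != 0) "frameshift" else "inframe_indel"))
    }
    # non-coding indel: classify by anchor position below
  }
  tidx <- match(pos, map$g)
  if (!is.na(tidx)) {
    if (tidx >= map$ci1 && tidx <= map$ci2 && is_snv) {
      ci <- tidx - map$ci1 + 1L
      tx_ref <- if (model$strand == "-") revcomp(ref) else ref
      tx_alt <- if (model$strand == "-") revcomp(alt) else alt
      have <- substr(cds_seq, ci, ci)
      if (!identical(have, tx_ref)) {
        abort(paste0(
          "reference allele mismatch at ", chrom, ":", pos,
          " (variant ref ", ref, ", transcript has ", have, ")"
        ))
      }
      codon_i <- (ci - 1L) %/% 3L
      within <- (ci - 1L) %% 3L
      codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
      alt_codon <- codon
      substr(alt_codon, within + 1L, within + 1L) <- tx_alt
      aa_ref <- unname(GENETIC_CODE_DNA[toupper(codon)])
      aa_alt <- unname(GENETIC_CODE_DNA[toupper(alt_codon)])
      prot <- paste0("p.", aa_ref, codon_i + 1L, aa_alt)
      if (aa_alt == "*" && aa_ref != "*") return(out("stopgain", prot))
      if (aa_alt != aa_ref) return(out("nonsynonymous", prot))
      return(out("synonymous", prot))
    }
    # transcript order makes UTR sides strand-independent
    if (tidx < map$ci1) return(out("utr5"))
    return(out("utr3"))
  }
  # intronic side: distance to the nearest exon edge
  up_g <- max(map$g[map$g < pos])
  dn_g <- min(map$g[map$g > pos])
  k <- min(pos - up_g, dn_g - pos)
  if (k <= 2) return(out("canonical_splice"))
  out("intronic")
}

#' Annotate variants with transcript, consequence, frequencies and verdicts
#'
#' Each variant is joined to the transcript overlapping its position (the
#' nearest gene on the chromosome when none overlaps, with effect class
#' `intergenic`); consequence and HGVS c. position are computed from the
#' gene model and its CDS sequence; population/in-house frequencies and
#' external predictor verdicts are attached where present (absent frequency
#' = novel allele). `pseudogene_flag` is initialized `FALSE`; see
#' [flag_pseudogene()].
#'
#' @param variants Variant tibble ([read_vcf()] shape).
#' @param models Gene-model tibble ([read_refflat()] shape).
#' @param cds_seqs Named character vector of CDS sequences, names = gene.
#' @param freq Optional wide frequency tibble ([read_frequency_table()]).
#' @param predictors Optional predictor tibble ([read_predictor_table()]).
#' @return The variants with columns `gene`, `transcript`, `effect_class`,
#'   `protein_change`, `hgvs_c`, `dbsnp_frequency`, `inhouse_frequency`,
#'   `n_damaging`, `n_predictors`, `predictor_verdicts` (list-column) and
#'   `pseudogene_flag` appended.
#' @export
annotate_variants <- function(variants, models, cds_seqs,
                              freq = NULL, predictors = NULL) {
  n <- nrow(variants)
  gene <- character(n); transcript <- character(n)
  effect <- character(n); prot <- character(n); hgvs <- character(n)
  for (i in seq_len(n)) {
    chrom <- variants$chrom[[i]]; pos <- variants$pos[[i]]
    hit <- which(models$chrom == chrom &
                   models$tx_start < pos & pos <= models$tx_end)
    if (length(hit) == 0) {
      near <- which(models$chrom == chrom)
      if (length(near) == 0) {
        gene[i] <- NA_character_; transcript[i] <- NA_character_
      } else {
        dist <- pmax(models$tx_start[near] + 1L - pos, pos - models$tx_end[near], 0L)
        j <- near[which.min(dist)]
        gene[i] <- models$gene[[j]]; transcript[i] <- models$transcript[[j]]
      }
      effect[i] <- "intergenic"; prot[i] <- NA_character_; hgvs[i] <- NA_character_
      next
    }
    j <- hit[[1]]
    model <- models[j, ]
    gene[i] <- model$gene; transcript[i] <- model$transcript
    cls <- classify_consequence(
      chrom, pos, variants$ref[[i]], variants$alt[[i]],
      model, cds_seqs[[model$gene]]
    )
    effect[i] <- cls$effect_class
    prot[i] <- cls$protein_change
    hgvs[i] <- genomic_to_cdna(pos, model)
  }
  out <- variants
  out$gene <- gene
  out$transcript <- transcript
  out$effect_class <- effect
  out$protein_change <- prot
  out$hgvs_c <- hgvs
  if (!is.null(freq) && nrow(freq) > 0) {
    out <- dplyr::left_join(
      out, freq[, c("chrom", "pos", "ref", "alt",
                    "dbsnp_frequency", "inhouse_frequency")],
      by = c("chrom", "pos", "ref", "alt")
    )
  } else {
    out$dbsnp_frequency <- NA_real_
    out$inhouse_frequency <- NA_real_
  }
  if (!is.null(predictors) && nrow(predictors) > 0) {
    key_v <- paste(out$chrom, out$pos, out$ref, out$alt)
    key_p <- paste(predictors$chrom, predictors$pos, predictors$ref, predictors$alt)
    out$predictor_verdicts <- purrr::map(key_v, function(k) {
      hit <- predictors[key_p == k, , drop = FALSE]
      setNames(hit$verdict, hit$predictor)
    })
  } else {
    out$predictor_verdicts <- purrr::map(seq_len(nrow(out)), ~ character(0))
  }
  out$n_damaging <- purrr::map_int(out$predictor_verdicts,
                                   ~ sum(.x == "damaging"))
  out$n_predictors <- purrr::map_int(out$predictor_verdicts, length)
  out$pseudogene_flag <- FALSE
  out$expected_af <- NA_real_
  out
}

#' Flag variants in pseudogene-shadowed regions by depressed allele fraction
#'
#' Reads from highly similar pseudogene copies map over the functional locus
#' and dilute the apparent allele fraction of real variants there. A variant
#' is flagged iff it lies inside a declared region and its allele fraction
#' sits in `[af_floor, flag_af_below)` — low enough to look diluted, high
#' enough not to be sequencing noise. Flagged variants carry the expected
#' diluted heterozygous fraction 0.5 / copy_factor and bypass the
#' allele-fraction filter downstream.
#'
#' @param variants Annotated variant tibble.
#' @param regions Pseudogene-region tibble ([read_pseudogene_bed()] shape).
#' @param flag_af_below Flag only fractions strictly below this (default 0.35).
#' @param af_floor Flag only fractions at or above this (default 0.05).
#' @return The variants with `pseudogene_flag` and `expected_af` updated.
#' @export
flag_pseudogene <- function(variants, regions, flag_af_below = 0.35,
                            af_floor = 0.05) {
  if (!"pseudogene_flag" %in% names(variants)) variants$pseudogene_flag <- FALSE
  if (!"expected_af" %in% names(variants)) variants$expected_af <- NA_real_
  if (is.null(regions) || nrow(regions) == 0) return(variants)
  for (i in seq_len(nrow(variants))) {
    pos <- variants$pos[[i]]
    hit <- which(regions$chrom == variants$chrom[[i]] &
                   regions$start < pos & pos <= regions$end)
    if (length(hit) == 0) next
    af <- variants$allele_fraction[[i]]
    if (af >= af_floor && af < flag_af_below) {
      variants$pseudogene_flag[[i]] <- TRUE
      variants$expected_af[[i]] <- 0.5 / regions$copy_factor[[hit[[1]]]]
    }
  }
  variants
}

#' Write annotated variants as VCF (with INFO annotations) and TSV twin
#'
#' The VCF carries INFO keys `EFFECT`, `HGVSC`, `DBSNP_AF`, `INHOUSE_AF`,
#' `PGFLAG`; the TSV twin holds the full annotation table.
#'
#' @param annotated Annotated variant tibble (single sample).
#' @param vcf_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_annotated <- function(annotated, vcf_path = NULL, tsv_path = NULL) {
  written <- character(0)
  if (!is.null(tsv_path)) {
    flat <- annotated
    flat$predictor_verdicts <- purrr::map_chr(
      flat$predictor_verdicts,
      ~ paste(paste0(names(.x), "=", .x), collapse = ";")
    )
    readr::write_tsv(flat, tsv_path)
    written <- c(written, tsv_path)
  }
  if (!is.null(vcf_path)) {
    sid <- unique(annotated$sample_id)
    if (length(sid) != 1) abort("write_annotated() writes one sample per VCF")
    v <- dplyr::arrange(annotated, .data$chrom, .data$pos, .data$alt)
    info <- sprintf(
      "EFFECT=%s;HGVSC=%s;DBSNP_AF=%s;INHOUSE_AF=%s;PGFLAG=%d",
      v$effect_class,
      ifelse(is.na(v$hgvs_c), ".", v$hgvs_c),
      ifelse(is.na(v$dbsnp_frequency), ".", format(v$dbsnp_frequency)),
      ifelse(is.na(v$inhouse_frequency), ".", format(v$inhouse_frequency)),
      as.integer(v$pseudogene_flag)
    )
    gt <- ifelse(v$allele_fraction >= 0.9, "1/1",
                 ifelse(v$allele_fraction > 0, "0/1", "0/0"))
    header <- c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Consequence class\">",
      "##INFO=<ID=HGVSC,Number=1,Type=String,Description=\"HGVS c. position\">",
      "##INFO=<ID=DBSNP_AF,Number=1,Type=Float,Description=\"dbSNP frequency\">",
      "##INFO=<ID=INHOUSE_AF,Number=1,Type=Float,Description=\"In-house frequency\">",
      "##INFO=<ID=PGFLAG,Number=1,Type=Integer,Description=\"Pseudogene-region low-AF flag\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sid, sep = "\t")
    )
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT:AD:DP\t%s:%d,%d:%d",
      v$chrom, v$pos, v$ref, v$alt, info, gt,
      v$total_depth - v$alt_depth, v$alt_depth, v$total_depth
    )
    writeLines(c(header, body), vcf_path)
    written <- c(written, vcf_path)
  }
  invisible(written)
}
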