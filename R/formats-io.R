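#' Read capture target regions from a BED file
#'
#' Parses a 3+ column BED file into a tibble of capture targets. BED uses
#' 0-based half-open coordinates; they are kept as such (conversion to the
#' 1-based conventions of VCF/depth tables happens only where those formats
#' are read or written). `track`/`browser` lines, comment lines starting with
#' `#`, and blank lines are skipped. File order is preserved.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start` (0-based inclusive),
#'   `end` (0-based exclusive) and `label` (4th column, `NA` when absent).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr16\t100\t200\tFANCA_ex1", bed)
#' read_bed(bed)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) &
    !startsWith(lines, "#") &
    !startsWith(lines, "track") &
    !startsWith(lines, "browser")
  rows <- purrr::map(which(keep), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(paste0("BED parse error at line ", i, ": fewer than 3 columns"))
    }
    start <- suppressWarnings(as.integer(f[[2]]))
    end <- suppressWarnings(as.integer(f[[3]]))
    if (is.na(start) || is.na(end)) {
      abort(paste0("BED parse error at line ", i, ": non-integer coordinates"))
    }
    if (end <= start) {
      abort(paste0("BED parse error at line ", i, ": end <= start"))
    }
    if (!nzchar(f[[1]])) {
      abort(paste0("BED parse error at line ", i, ": empty chromosome"))
    }
    tibble::tibble(
      chrom = f[[1]], start = start, end = end,
      label = if (length(f) >= 4) f[[4]] else NA_character_
    )
  })
  if (length(rows) == 0) {
    return(tibble::tibble(
      chrom = character(), start = integer(),
      end = integer(), label = character()
    ))
  }
  dplyr::bind_rows(rows)
}

#' Write target regions to a BED file
#'
#' @param targets Tibble with `chrom`, `start`, `end` and optionally `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(targets, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(targets)))
  lab <- if ("label" %in% names(targets)) targets$label else rep(NA, nrow(targets))
  lines <- ifelse(
    is.na(lab),
    sprintf("%s\t%d\t%d", targets$chrom, targets$start, targets$end),
    sprintf("%s\t%d\t%d\t%s", targets$chrom, targets$start, targets$end, lab)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read transcript models from a refFlat file
#'
#' Parses the UCSC refFlat dialect (geneName, name, chrom, strand, txStart,
#' txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds; exon lists
#' comma-separated, 0-based half-open). The declared exonCount must match
#' both exon lists; exons must be sorted and non-overlapping.
#'
#' @param path Path to a refFlat TSV.
#' @return A tibble with one row per transcript: `gene`, `transcript`,
#'   `chrom`, `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end`,
#'   `n_exons`, and list-columns `exon_starts`, `exon_ends` (integer vectors).
#' @export
read_refflat <- function(path) {
  if (!file.exists(path)) abort(paste0("refFlat file not found: ", path))
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*$", lines) & !startsWith(lines, "#"))
  rows <- purrr::map(keep, function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) {
      abort(paste0("refFlat parse error at line ", i, ": fewer than 11 columns"))
    }
    n_exons <- suppressWarnings(as.integer(f[[9]]))
    starts <- suppressWarnings(as.integer(strsplit(f[[10]], ",", fixed = TRUE)[[1]]))
    ends <- suppressWarnings(as.integer(strsplit(f[[11]], ",", fixed = TRUE)[[1]]))
    if (anyNA(n_exons) || anyNA(starts) || anyNA(ends)) {
      abort(paste0("refFlat parse error at line ", i, ": non-integer exon fields"))
    }
    if (length(starts) != n_exons || length(ends) != n_exons) {
      abort(paste0(
        "refFlat parse error at line ", i,
        ": exonCount (", n_exons, ") does not match exon list lengths (",
        length(starts), ", ", length(ends), ")"
      ))
    }
    model <- tibble::tibble(
      gene = f[[1]], transcript = f[[2]], chrom = f[[3]], strand = f[[4]],
      tx_start = as.integer(f[[5]]), tx_end = as.integer(f[[6]]),
      cds_start = as.integer(f[[7]]), cds_end = as.integer(f[[8]]),
      n_exons = n_exons,
      exon_starts = list(starts), exon_ends = list(ends)
    )
    validate_gene_model(model, context = paste0("line ", i))
    model
  })
  if (length(rows) == 0) {
    return(tibble::tibble(
      gene = character(), transcript = character(), chrom = character(),
      strand = character(), tx_start = integer(), tx_end = integer(),
      cds_start = integer(), cds_end = integer(), n_exons = integer(),
      exon_starts = list(), exon_ends = list()
    ))
  }
  dplyr::bind_rows(rows)
}

validate_gene_model <- function(model, context = model$gene) {
  starts <- model$exon_starts[[1]]
  ends <- model$exon_ends[[1]]
  if (any(ends <= starts)) {
    abort(paste0("invalid gene model (", context, "): exon end <= start"))
  }
  if (length(starts) > 1 && any(starts[-1] < ends[-length(ends)])) {
    abort(paste0("invalid gene model (", context, "): exons unsorted or overlapping"))
  }
  if (!model$strand %in% c("+", "-")) {
    abort(paste0("invalid gene model (", context, "): strand must be + or -"))
  }
  if (model$cds_start < model$cds_end &&
      (model$cds_start < starts[1] || model$cds_end > ends[length(ends)])) {
    abort(paste0("invalid gene model (", context, "): CDS outside exon span"))
  }
  invisible(model)
}

#' Write transcript models to a refFlat file
#'
#' @param models Tibble as returned by [read_refflat()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_refflat <- function(models, path) {
  lines <- purrr::map_chr(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    paste(
      m$gene, m$transcript, m$chrom, m$strand, m$tx_start, m$tx_end,
      m$cds_start, m$cds_end, m$n_exons,
      paste0(paste(m$exon_starts[[1]], collapse = ","), ","),
      paste0(paste(m$exon_ends[[1]], collapse = ","), ","),
      sep = "\t"
    )
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read called variants from a VCF file
#'
#' Reads a VCF 4.x file through \pkg{vcfR} and extracts one row per sample
#' per alternate allele, with allele depths taken from the per-sample `AD`
#' field. Multi-allelic records are split into one row per alternate allele.
#' Records whose samples lack usable `AD` are skipped with a warning.
#'
#' @param path Path to a VCF file.
#' @return A tibble with `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `total_depth`, `alt_depth`, `allele_fraction`, `sample_id`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  empty <- tibble::tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    total_depth = integer(), alt_depth = integer(),
    allele_fraction = double(), sample_id = character()
  )
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) return(empty)
  fix <- tibble::as_tibble(as.data.frame(v@fix[, 1:5, drop = FALSE],
                                         stringsAsFactors = FALSE))
  names(fix) <- c("chrom", "pos", "id", "ref", "alt")
  fix$pos <- as.integer(fix$pos)
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(ad)
  out <- purrr::map(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$alt[[i]], ",", fixed = TRUE)[[1]]
    purrr::map(samples, function(s) {
      ad_str <- ad[i, s]
      if (is.na(ad_str) || !nzchar(ad_str)) {
        warn(paste0(
          "VCF record ", fix$chrom[[i]], ":", fix$pos[[i]],
          " sample ", s, ": missing AD field; record skipped"
        ))
        return(NULL)
      }
      depths <- suppressWarnings(as.integer(strsplit(ad_str, ",", fixed = TRUE)[[1]]))
      if (anyNA(depths) || length(depths) < length(alts) + 1) {
        warn(paste0(
          "VCF record ", fix$chrom[[i]], ":", fix$pos[[i]],
          " sample ", s, ": unusable AD field; record skipped"
        ))
        return(NULL)
      }
      total <- sum(depths)
      tibble::tibble(
        chrom = fix$chrom[[i]], pos = fix$pos[[i]], ref = fix$ref[[i]],
        alt = alts,
        total_depth = total,
        alt_depth = depths[seq_along(alts) + 1L],
        allele_fraction = ifelse(total > 0, depths[seq_along(alts) + 1L] / total, 0),
        sample_id = s
      )
    })
  })
  res <- dplyr::bind_rows(purrr::flatten(out))
  if (nrow(res) == 0) empty else res
}

#' Write a single-sample variant table to a minimal VCF file
#'
#' Emits a VCF 4.2 file with `GT:AD:DP` genotype fields reconstructed from
#' the table's allele depths. The table must contain a single `sample_id`.
#'
#' @param variants Tibble in the shape returned by [read_vcf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  sid <- unique(variants$sample_id)
  if (length(sid) > 1) abort("write_vcf() writes one sample per file")
  if (length(sid) == 0) sid <- "sample"
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sid, sep = "\t")
  )
  v <- dplyr::arrange(variants, .data$chrom, .data$pos, .data$alt)
  gt <- ifelse(v$allele_fraction >= 0.9, "1/1",
               ifelse(v$allele_fraction > 0, "0/1", "0/0"))
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:DP\t%s:%d,%d:%d",
    v$chrom, v$pos, v$ref, v$alt, gt,
    v$total_depth - v$alt_depth, v$alt_depth, v$total_depth
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a per-base depth table
#'
#' Reads a samtools-depth-style TSV (`chrom`, 1-based `pos`, `depth`; no
#' header). Positions absent from the file are treated as depth 0 by all
#' downstream binning. Duplicate positions and negative depths are parse
#' errors.
#'
#' @param path Path to the depth TSV.
#' @param sample_id Sample identifier to attach to the track.
#' @return A tibble with `chrom`, `pos`, `depth`, `sample_id`.
#' @export
read_depth_table <- function(path, sample_id = basename(path)) {
  if (!file.exists(path)) abort(paste0("depth table not found: ", path))
  d <- readr::read_tsv(
    path,
    col_names = c("chrom", "pos", "depth"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      depth = readr::col_integer()
    ),
    progress = FALSE
  )
  if (nrow(d) > 0) {
    if (anyNA(d$pos) || anyNA(d$depth)) {
      abort("depth table parse error: non-integer position or depth")
    }
    if (any(d$depth < 0)) abort("depth table parse error: negative depth")
    if (anyDuplicated(paste(d$chrom, d$pos))) {
      abort("depth table parse error: duplicate position")
    }
  }
  d$sample_id <- sample_id
  d
}

#' Write a per-base depth table
#'
#' @param track Tibble with `chrom`, `pos`, `depth` (single sample).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "pos", "depth")], path, col_names = FALSE)
  invisible(path)
}

#' Read a population/in-house frequency table
#'
#' Long TSV with header `chrom, pos, ref, alt, source, frequency` where
#' `source` is `dbsnp` or `inhouse`; returned wide with one row per allele
#' and columns `dbsnp_frequency` / `inhouse_frequency` (`NA` = absent from
#' that database, i.e. a novel allele).
#'
#' @param path Path to the TSV.
#' @return A wide tibble keyed by (`chrom`, `pos`, `ref`, `alt`).
#' @export
read_frequency_table <- function(path) {
  d <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer(),
      ref = readr::col_character(), alt = readr::col_character(),
      source = readr::col_character(), frequency = readr::col_double()
    ),
    progress = FALSE
  )
  if (nrow(d) == 0) {
    return(tibble::tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), dbsnp_frequency = double(), inhouse_frequency = double()
    ))
  }
  if (any(d$frequency < 0 | d$frequency > 1)) {
    abort("frequency table parse error: frequency outside [0, 1]")
  }
  if (!all(d$source %in% c("dbsnp", "inhouse"))) {
    abort("frequency table parse error: source must be 'dbsnp' or 'inhouse'")
  }
  tidyr::pivot_wider(
    d,
    names_from = "source", values_from = "frequency",
    names_glue = "{source}_frequency",
    values_fn = max
  ) |>
    add_missing_cols(c("dbsnp_frequency", "inhouse_frequency"))
}

add_missing_cols <- function(d, cols) {
  for (cl in setdiff(cols, names(d))) d[[cl]] <- NA_real_
  d
}

#' Write a frequency table
#'
#' @param freq Wide tibble as returned by [read_frequency_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(freq, path) {
  long <- tidyr::pivot_longer(
    freq,
    cols = dplyr::ends_with("_frequency"),
    names_to = "source", values_to = "frequency"
  ) |>
    dplyr::filter(!is.na(.data$frequency)) |>
    dplyr::mutate(source = sub("_frequency$", "", .data$source))
  readr::write_tsv(
    long[, c("chrom", "pos", "ref", "alt", "source", "frequency")], path
  )
  invisible(path)
}

#' Read external predictor verdicts
#'
#' TSV with header `chrom, pos, ref, alt, predictor, verdict`; verdicts must
#' be `damaging` or `benign`. Predictor algorithms themselves (SIFT,
#' PolyPhen-2, Align-GVGD, ...) are external: their verdicts are consumed,
#' never computed.
#'
#' @param path Path to the TSV.
#' @return A tibble with one row per (allele, predictor).
#' @export
read_predictor_table <- function(path) {
  d <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer(),
      ref = readr::col_character(), alt = readr::col_character(),
      predictor = readr::col_character(), verdict = readr::col_character()
    ),
    progress = FALSE
  )
  if (nrow(d) > 0 && !all(d$verdict %in% c("damaging", "benign"))) {
    abort("predictor table parse error: verdict must be 'damaging' or 'benign'")
  }
  d
}

#' Write a predictor verdict table
#' @param predictors Tibble as returned by [read_predictor_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictor_table <- function(predictors, path) {
  readr::write_tsv(
    predictors[, c("chrom", "pos", "ref", "alt", "predictor", "verdict")], path
  )
  invisible(path)
}

#' Read pseudogene regions from a 5-column BED file
#'
#' Column 4 is a free-text name and column 5 the copy factor: the number of
#' highly similar genomic copies (functional locus included) across which
#' reads are diluted. Copy factor must be at least 2.
#'
#' @param path Path to the BED file.
#' @return Tibble with `chrom`, `start`, `end`, `name`, `copy_factor`.
#' @export
read_pseudogene_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("pseudogene BED not found: ", path))
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*$", lines) & !startsWith(lines, "#") &
                  !startsWith(lines, "track"))
  rows <- purrr::map(keep, function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5) {
      abort(paste0("pseudogene BED parse error at line ", i, ": need 5 columns"))
    }
    cf <- suppressWarnings(as.integer(f[[5]]))
    if (is.na(cf) || cf < 2) {
      abort(paste0("pseudogene BED parse error at line ", i, ": copy_factor must be >= 2"))
    }
    tibble::tibble(
      chrom = f[[1]], start = as.integer(f[[2]]), end = as.integer(f[[3]]),
      name = f[[4]], copy_factor = cf
    )
  })
  if (length(rows) == 0) {
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), copy_factor = integer()
    ))
  }
  dplyr::bind_rows(rows)
}
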