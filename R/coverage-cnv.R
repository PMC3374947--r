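#' Tile capture targets with depth windows
#'
#' Windows tile each target from its start in `step` increments; the final
#' window of a target is truncated at the target end, and windows never span
#' two targets. With `step == size` (the default) windows are non-overlapping
#' and binning conserves total depth exactly; `step < size` gives a sliding
#' (overlapping) window. Targets may arrive unsorted; windows are returned
#' ordered by (chrom, start) and numbered by an `index` ordinal over the
#' whole panel.
#'
#' @param targets Tibble of capture targets ([read_bed()] shape).
#' @param size Window width in bp (>= 20).
#' @param step Step between window starts in bp (1 <= step <= size).
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open), `index`.
#' @export
make_windows <- function(targets, size = 100, step = 100) {
  if (size < 20) abort("window size must be >= 20 bp")
  if (step < 1 || step > size) {
    abort("step must satisfy 1 <= step <= size (step > size would drop signal)")
  }
  if (nrow(targets) == 0) {
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer(), index = integer()
    ))
  }
  win <- purrr::map(seq_len(nrow(targets)), function(i) {
    s <- targets$start[[i]]
    e <- targets$end[[i]]
    starts <- seq.int(s, e - 1L, by = step)
    tibble::tibble(
      chrom = targets$chrom[[i]],
      start = as.integer(starts),
      end = as.integer(pmin(starts + size, e))
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$chrom, .data$start)
  win$index <- seq_len(nrow(win))
  win
}

#' Bin per-base depth into window means
#'
#' For every window, the mean per-base depth over the window: the sum of
#' recorded depths at 1-based positions p with start < p <= end, divided by
#' the window width. Positions absent from the track count as depth 0, so an
#' all-zero (or empty) track is legal and yields zeros.
#'
#' @param depth Per-base depth tibble (`chrom`, `pos`, `depth`, optionally
#'   `sample_id`; multiple samples allowed).
#' @param windows Window tibble from [make_windows()].
#' @return Tibble with one row per (sample, window): `sample_id`, `index`,
#'   `chrom`, `start`, `end`, `depth` (mean per-base depth).
#' @export
bin_depth <- function(depth, windows) {
  if (!"sample_id" %in% names(depth)) depth$sample_id <- "sample"
  samples <- unique(depth$sample_id)
  if (length(samples) == 0) samples <- "sample"
  out <- purrr::map(samples, function(s) {
    d <- depth[depth$sample_id == s, , drop = FALSE]
    sums <- window_sums(d, windows)
    tibble::tibble(
      sample_id = s,
      index = windows$index,
      chrom = windows$chrom,
      start = windows$start,
      end = windows$end,
      depth = sums / (windows$end - windows$start)
    )
  })
  dplyr::bind_rows(out)
}

# Sum of per-base depth inside each 0-based half-open window, via per-chrom
# cumulative sums over the sorted recorded positions.
window_sums <- function(depth, windows) {
  sums <- numeric(nrow(windows))
  if (nrow(depth) == 0 || nrow(windows) == 0) return(sums)
  for (chr in unique(windows$chrom)) {
    wi <- which(windows$chrom == chr)
    d <- depth[depth$chrom == chr, , drop = FALSE]
    if (nrow(d) == 0) next
    o <- order(d$pos)
    pos <- d$pos[o]
    csum <- cumsum(as.numeric(d$depth[o]))
    cum_at <- function(x) {
      i <- findInterval(x, pos)
      ifelse(i == 0, 0, csum[pmax(i, 1)])
    }
    # window [s, e) holds 1-based positions s+1 .. e
    sums[wi] <- cum_at(windows$end[wi]) - cum_at(windows$start[wi])
  }
  sums
}

#' Library-size normalize a window count table
#'
#' Rescales each sample's window means so that its total over all windows
#' equals the cohort median total, making samples sequenced to different
#' depths comparable before ratio computation. The per-sample scaling
#' factors are recorded in the `library_factors` attribute.
#'
#' @param counts Long tibble from [bin_depth()] (>= 1 sample).
#' @return The rescaled tibble, with attribute `library_factors` (named
#'   numeric vector).
#' @export
library_size_normalize <- function(counts) {
  totals <- tapply(counts$depth, counts$sample_id, sum)
  if (any(totals == 0)) {
    abort(paste0(
      "sample(s) with all-zero counts cannot be library-size normalized: ",
      paste(names(totals)[totals == 0], collapse = ", ")
    ))
  }
  med <- median(totals)
  factors <- setNames(as.numeric(med / totals), names(totals))
  counts$depth <- counts$depth * unname(factors[counts$sample_id])
  attr(counts, "library_factors") <- factors
  counts
}

#' Build the pooled per-window reference depth
#'
#' The reference local depth at each window is the median across the included
#' samples of their (library-size normalized) window means. By default all
#' samples are pooled, the test sample included; `exclude_self = TRUE` drops
#' `test_sample` from the pool (requires >= 2 samples). The median makes the
#' reference robust to a deletion carrier in the cohort.
#'
#' @param counts Library-size normalized long count tibble.
#' @param exclude_self Drop `test_sample` from the pool?
#' @param test_sample Sample id to drop when `exclude_self`.
#' @return Tibble with `index`, `chrom`, `start`, `end`, `reference`.
#' @export
build_reference <- function(counts, exclude_self = FALSE, test_sample = NULL) {
  samples <- unique(counts$sample_id)
  if (exclude_self) {
    if (is.null(test_sample)) abort("exclude_self requires test_sample")
    if (length(samples) < 2) {
      abort("exclude_self requires at least 2 samples")
    }
    counts <- counts[counts$sample_id != test_sample, , drop = FALSE]
  }
  counts |>
    dplyr::group_by(.data$index, .data$chrom, .data$start, .data$end) |>
    dplyr::summarise(reference = median(.data$depth), .groups = "drop") |>
    dplyr::arrange(.data$index)
}

#' Per-window log2 depth ratio of a sample against the reference
#'
#' M = log2((count + pseudocount) / (reference + pseudocount)), clamped to
#' \[-5, +5\]. The pseudocount keeps zero-count windows finite while leaving
#' homozygous deletions clearly separated from heterozygous ones; it cancels
#' exactly when a sample is compared against itself. The returned track is
#' unnormalized (`normalized` attribute `FALSE`); apply
#' [mean_shift_normalize()] before exon aggregation.
#'
#' @param counts Long count tibble (normalized), or a single sample's rows.
#' @param reference Reference tibble from [build_reference()].
#' @param sample Sample id to extract when `counts` holds several samples.
#' @param pseudocount Positive depth offset (default 0.5).
#' @return Ratio-track tibble: `sample_id`, `index`, `chrom`, `start`,
#'   `end`, `M`; attribute `normalized = FALSE`.
#' @export
log2_ratio_track <- function(counts, reference, sample = NULL, pseudocount = 0.5) {
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  if (!is.null(sample)) counts <- counts[counts$sample_id == sample, , drop = FALSE]
  if (length(unique(counts$sample_id)) > 1) {
    abort("log2_ratio_track() works on one sample; pass `sample =`")
  }
  counts <- dplyr::arrange(counts, .data$index)
  if (nrow(counts) != nrow(reference) ||
      !all(counts$index == reference$index)) {
    abort("counts and reference cover different windows (length mismatch)")
  }
  m <- log2((counts$depth + pseudocount) / (reference$reference + pseudocount))
  track <- tibble::tibble(
    sample_id = counts$sample_id,
    index = counts$index,
    chrom = counts$chrom,
    start = counts$start,
    end = counts$end,
    M = pmin(pmax(m, -5), 5)
  )
  attr(track, "normalized") <- FALSE
  track
}

#' Mean-shift normalize a log2 ratio track
#'
#' Subtracts the track-wide mean so that mean(M) = 0 (to 1e-9), centring the
#' diploid baseline on zero regardless of residual library-size differences.
#'
#' @param track Ratio track from [log2_ratio_track()].
#' @return The normalized track (`normalized` attribute `TRUE`).
#' @export
mean_shift_normalize <- function(track) {
  if (nrow(track) == 0) abort("cannot normalize an empty ratio track")
  track$M <- track$M - mean(track$M)
  attr(track, "normalized") <- TRUE
  track
}

is_normalized <- function(track) isTRUE(attr(track, "normalized"))

#' Aggregate a ratio track on the exon scale
#'
#' A window is assigned to an exon iff it overlaps the exon by at least 1 bp.
#' Per exon the mean, 25th and 75th percentile (linear interpolation between
#' order statistics, i.e. `quantile(type = 7)`) of the assigned windows' M
#' values are reported. Exons overlapped by no window are reported with
#' `n_windows = 0` and `NA` summaries.
#'
#' @param track Normalized ratio track.
#' @param model One-row gene-model tibble ([read_refflat()] shape).
#' @return Tibble with `gene`, `exon` (1-based, transcript order), `mean_M`,
#'   `q25_M`, `q75_M`, `n_windows`.
#' @export
aggregate_exons <- function(track, model) {
  if (!is_normalized(track)) {
    abort("aggregate_exons() expects a mean-shift normalized track")
  }
  stopifnot(nrow(model) == 1)
  starts <- model$exon_starts[[1]]
  ends <- model$exon_ends[[1]]
  n <- length(starts)
  # exon numbering follows transcript order: reversed on the minus strand
  genomic_exon <- if (model$strand == "-") rev(seq_len(n)) else seq_len(n)
  tr <- track[track$chrom == model$chrom, c("start", "end", "M")]
  stats <- vapply(seq_len(n), function(j) {
    m <- tr$M[tr$start < ends[j] & tr$end > starts[j]]
    if (length(m) == 0) {
      c(NA_real_, NA_real_, NA_real_, 0)
    } else {
      c(mean(m), unname(quantile(m, c(0.25, 0.75), type = 7)), length(m))
    }
  }, numeric(4))
  tibble::tibble(
    gene = model$gene, exon = genomic_exon,
    mean_M = stats[1, ], q25_M = stats[2, ], q75_M = stats[3, ],
    n_windows = as.integer(stats[4, ])
  ) |>
    dplyr::arrange(.data$exon)
}

#' Call exon-scale deletions from per-exon summaries
#'
#' An exon is flagged as deleted when its mean M falls at or below the active
#' threshold (`mosaic_M` when `mosaic_mode`, else `het_M`) and its 75th
#' percentile stays at or below `q75_guard` (guarding against a single
#' outlier window dragging the mean down). Maximal runs of consecutive
#' flagged exons are merged into one call; single-exon calls are permitted.
#' A run is classed `hom` when its mean M is at or below `hom_M`; otherwise
#' `mosaic` when `mosaic_mode` is on and the run mean is above -0.8 (shallower
#' than a constitutional heterozygous deletion); otherwise `het`. For het and
#' mosaic calls the mosaic fraction f is estimated with
#' [estimate_mosaic_fraction()].
#'
#' @param summaries Exon summaries for one gene, from [aggregate_exons()].
#' @param het_M,hom_M,mosaic_M,q75_guard Calling thresholds (log2 ratio).
#' @param mosaic_mode Lower the flag threshold to `mosaic_M` for mosaic
#'   sensitivity.
#' @return Tibble of calls: `gene`, `first_exon`, `last_exon`, `mean_M`,
#'   `zygosity_class`, `mosaic_fraction`.
#' @export
call_deletions <- function(summaries, het_M = -0.65, hom_M = -3.0,
                           mosaic_M = -0.2, q75_guard = -0.2,
                           mosaic_mode = FALSE) {
  empty <- tibble::tibble(
    gene = character(), first_exon = integer(), last_exon = integer(),
    mean_M = double(), zygosity_class = character(), mosaic_fraction = double()
  )
  if (nrow(summaries) == 0) return(empty)
  if (length(unique(summaries$gene)) > 1) {
    abort("call_deletions() expects summaries from a single gene")
  }
  s <- dplyr::arrange(summaries, .data$exon)
  active <- if (mosaic_mode) mosaic_M else het_M
  flag <- !is.na(s$mean_M) & s$n_windows > 0 &
    s$mean_M <= active & s$q75_M <= q75_guard
  if (!any(flag)) return(empty)
  r <- rle(flag)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  calls <- purrr::map(which(r$values), function(k) {
    idx <- run_start[k]:run_end[k]
    w <- s$n_windows[idx]
    run_mean <- sum(s$mean_M[idx] * w) / sum(w)
    cls <- if (run_mean <= hom_M) {
      "hom"
    } else if (mosaic_mode && run_mean > -0.8) {
      "mosaic"
    } else {
      "het"
    }
    tibble::tibble(
      gene = s$gene[[1]],
      first_exon = s$exon[idx[1]],
      last_exon = s$exon[idx[length(idx)]],
      mean_M = run_mean,
      zygosity_class = cls,
      mosaic_fraction = if (cls == "hom") NA_real_ else
        estimate_mosaic_fraction(min(run_mean, 0))
    )
  })
  dplyr::bind_rows(calls)
}

#' Estimate the mosaic fraction from a deletion's log2 ratio
#'
#' Under the heterozygous-deletion mosaic model, a fraction f of genomes
#' carry a one-allele loss diluted by normal diploid cells, so the expected
#' depth ratio is 1 - f/2 and M = log2(1 - f/2). Inverting,
#' f = 2 (1 - 2^M), clamped to \[0, 1\]. f = 1 is a constitutional
#' heterozygous deletion (M = -1); M = log2(3/4) of the equimolar two-sample
#' pool gives f = 0.5, the one-allele-in-four-copies case.
#'
#' @param M Run-mean log2 ratio(s), <= 0.
#' @return Estimated fraction(s) f in \[0, 1\].
#' @export
estimate_mosaic_fraction <- function(M) {
  if (any(M > 0)) abort("M > 0 is a gain, not a deletion; cannot estimate f")
  pmin(1, pmax(0, 2 * (1 - 2^M)))
}

#' Project a ratio track on the ORF and exon scales
#'
#' Produces the two plot-ready series of the standard deletion plot: the ORF
#' scale (every window's M, labeled exonic when it overlaps an exon by >= 1
#' bp, intronic otherwise) and the exon scale (per-exon mean with 25th/75th
#' percentile bars). Use [write_orf_projection()] to emit TSVs and
#' [ggplot2::autoplot()] to draw.
#'
#' @param track Normalized ratio track.
#' @param summaries Exon summaries for the gene, from [aggregate_exons()].
#' @param model One-row gene-model tibble.
#' @return An object of class `ps_orf_projection`: list with tibbles `orf`
#'   (window series + `exonic` flag) and `exon` (the summaries), plus `gene`.
#' @export
project_orf <- function(track, summaries, model) {
  if (!is_normalized(track)) {
    abort("project_orf() expects a mean-shift normalized track")
  }
  stopifnot(nrow(model) == 1)
  starts <- model$exon_starts[[1]]
  ends <- model$exon_ends[[1]]
  exonic <- purrr::map_lgl(seq_len(nrow(track)), function(i) {
    track$chrom[[i]] == model$chrom &&
      any(track$start[[i]] < ends & track$end[[i]] > starts)
  })
  orf <- track
  orf$exonic <- exonic
  structure(
    list(orf = orf, exon = summaries, gene = model$gene),
    class = "ps_orf_projection"
  )
}

#' Write an ORF/exon projection to TSV files
#'
#' @param projection A `ps_orf_projection` from [project_orf()].
#' @param dir Output directory (created if needed).
#' @return The two paths written, invisibly.
#' @export
write_orf_projection <- function(projection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(projection$gene, "_orf.tsv"))
  p2 <- file.path(dir, paste0(projection$gene, "_exon.tsv"))
  readr::write_tsv(projection$orf, p1)
  readr::write_tsv(projection$exon, p2)
  invisible(c(p1, p2))
}

#' Run the whole read-depth deletion screen over a cohort
#'
#' Convenience pipeline: window the targets, bin every sample's depth,
#' library-size normalize, build the pooled median reference (all samples by
#' default), compute each sample's mean-shift normalized log2 ratio track,
#' aggregate per gene on the exon scale, and call deletions.
#'
#' @param depth Long per-base depth tibble for all samples (`chrom`, `pos`,
#'   `depth`, `sample_id`).
#' @param targets Capture targets ([read_bed()] shape).
#' @param models Gene models ([read_refflat()] shape).
#' @param window,step Window size and step in bp.
#' @param exclude_self Build each sample's reference without itself.
#' @param pseudocount Depth pseudocount for the ratio.
#' @param ... Calling thresholds passed to [call_deletions()].
#' @return `ps_cnv_screen` object: list with `windows`, `counts` (normalized),
#'   `tracks` (all samples, normalized), `summaries` (sample x gene exon
#'   summaries) and `calls` tibbles.
#' @export
cnv_screen <- function(depth, targets, models, window = 100, step = 100,
                       exclude_self = FALSE, pseudocount = 0.5, ...) {
  windows <- make_windows(targets, size = window, step = step)
  counts <- bin_depth(depth, windows) |> library_size_normalize()
  samples <- unique(counts$sample_id)
  if (length(samples) < 2) {
    abort("cnv_screen() needs >= 2 samples to build a pooled reference")
  }
  shared_ref <- if (!exclude_self) build_reference(counts)
  per_sample <- purrr::map(samples, function(s) {
    ref <- shared_ref %||%
      build_reference(counts, exclude_self = TRUE, test_sample = s)
    track <- log2_ratio_track(counts, ref, sample = s,
                              pseudocount = pseudocount) |>
      mean_shift_normalize()
    summaries <- purrr::map(seq_len(nrow(models)), function(g) {
      aggregate_exons(track, models[g, ]) |>
        dplyr::mutate(sample_id = s, .before = 1)
    }) |>
      dplyr::bind_rows()
    dots <- rlang::list2(...)
    calls <- summaries |>
      dplyr::group_by(.data$gene) |>
      dplyr::group_map(function(d, key) {
        do.call(call_deletions,
                c(list(dplyr::mutate(d, gene = key$gene)), dots))
      }) |>
      dplyr::bind_rows()
    if (nrow(calls) > 0) calls <- dplyr::mutate(calls, sample_id = s, .before = 1)
    list(track = track, summaries = summaries, calls = calls)
  })
  calls <- dplyr::bind_rows(purrr::map(per_sample, "calls"))
  if (nrow(calls) == 0) {
    calls <- tibble::tibble(
      sample_id = character(), gene = character(), first_exon = integer(),
      last_exon = integer(), mean_M = double(), zygosity_class = character(),
      mosaic_fraction = double()
    )
  }
  structure(
    list(
      windows = windows,
      counts = counts,
      tracks = dplyr::bind_rows(purrr::map(per_sample, "track")),
      summaries = dplyr::bind_rows(purrr::map(per_sample, "summaries")),
      calls = calls
    ),
    class = "ps_cnv_screen"
  )
}

#' @export
print.ps_cnv_screen <- function(x, ...) {
  cat("<ps_cnv_screen>\n")
  cat("  samples:", length(unique(x$counts$sample_id)),
      " windows:", nrow(x$windows), "\n")
  cat("  deletion calls:", nrow(x$calls), "\n")
  if (nrow(x$calls) > 0) print(x$calls)
  invisible(x)
}
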