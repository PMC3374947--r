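targets1 <- function(end = 300L) {
  tibble::tibble(chrom = "chr1", start = 0L, end = end, label = "t")
}

test_that("windows tile targets, truncate at target ends, never span targets", {
  w <- make_windows(targets1(300L), size = 100, step = 100)
  expect_equal(w$start, c(0L, 100L, 200L))
  expect_equal(w$end, c(100L, 200L, 300L))

  w2 <- make_windows(targets1(250L), size = 100, step = 50)
  expect_equal(w2$start, c(0L, 50L, 100L, 150L, 200L))
  expect_equal(w2$end, c(100L, 150L, 200L, 250L, 250L))

  two <- tibble::tibble(chrom = "chr1", start = c(0L, 1000L),
                        end = c(150L, 1100L), label = c("a", "b"))
  w3 <- make_windows(two, size = 100, step = 100)
  expect_true(all(w3$end <= 150 | w3$start >= 1000))
  expect_equal(w3$index, seq_len(nrow(w3)))

  expect_equal(nrow(make_windows(targets1()[0, ])), 0)
  expect_error(make_windows(targets1(), size = 100, step = 150), "step")
  expect_error(make_windows(targets1(), size = 10, step = 10), "size")
})

test_that("binning averages per-base depth with absent positions as zero", {
  w <- make_windows(targets1(300L))
  d <- tibble::tibble(chrom = "chr1", pos = 1:100, depth = 100L,
                      sample_id = "s")
  b <- bin_depth(d, w)
  expect_equal(b$depth, c(100, 0, 0))

  d2 <- tibble::tibble(chrom = "chr1", pos = 1:50, depth = 100L,
                       sample_id = "s")
  expect_equal(bin_depth(d2, w)$depth[1], 50)

  empty <- d[0, ]
  expect_equal(bin_depth(empty, w)$depth, c(0, 0, 0))
})

test_that("non-overlapping binning conserves total depth exactly", {
  withr::local_seed(21)
  for (i in 1:20) {
    tg <- tibble::tibble(
      chrom = sample(c("chrA", "chrB"), 3, replace = TRUE),
      start = c(0L, 500L, 1200L),
      end = c(0L, 500L, 1200L) + sample(c(130L, 250L, 370L))
    )
    tg$label <- letters[1:3]
    w <- make_windows(tg, size = 100, step = 100)
    pos_all <- dplyr::bind_rows(purrr::map(1:3, function(j) {
      tibble::tibble(chrom = tg$chrom[j], pos = (tg$start[j] + 1):tg$end[j])
    })) |> dplyr::distinct(chrom, pos)
    pos_all$depth <- sample.int(200, nrow(pos_all), replace = TRUE)
    pos_all$sample_id <- "s"
    b <- bin_depth(pos_all, w)
    expect_equal(sum(b$depth * (b$end - b$start)), sum(pos_all$depth))
  }
})

test_that("library-size normalization equalizes totals to the cohort median", {
  w <- make_windows(targets1(300L))
  base <- tibble::tibble(chrom = "chr1", pos = 1:300, depth = 100L)
  d <- dplyr::bind_rows(
    dplyr::mutate(base, sample_id = "a"),
    dplyr::mutate(base, sample_id = "b"),
    dplyr::mutate(base, depth = 200L, sample_id = "c")
  )
  n <- library_size_normalize(bin_depth(d, w))
  f <- attr(n, "library_factors")
  expect_equal(unname(f[c("a", "b", "c")]), c(1, 1, 0.5))
  expect_true(all(abs(tapply(n$depth, n$sample_id, sum) - 300) < 1e-9))

  single <- library_size_normalize(bin_depth(dplyr::mutate(base, sample_id = "x"), w))
  expect_equal(unname(attr(single, "library_factors")), 1)

  zero <- dplyr::bind_rows(
    dplyr::mutate(base, sample_id = "a"),
    dplyr::mutate(base, depth = 0L, sample_id = "z")
  )
  expect_error(library_size_normalize(bin_depth(zero, w)), "z")
})

test_that("pooled reference is the per-window median, optionally excluding self", {
  w <- make_windows(targets1(100L))
  counts <- tibble::tibble(
    sample_id = c("a", "b", "c"), index = 1L, chrom = "chr1",
    start = 0L, end = 100L, depth = c(100, 100, 50)
  )
  expect_equal(build_reference(counts)$reference, 100)
  expect_equal(
    build_reference(counts[1:2, ], exclude_self = TRUE, test_sample = "a")$reference,
    100
  )
  expect_error(build_reference(counts[1, ], exclude_self = TRUE,
                               test_sample = "a"), "2 samples")
})

test_that("log2 ratios use the pseudocount and are clamped to [-5, 5]", {
  ref <- tibble::tibble(index = 1:3, chrom = "chr1",
                        start = c(0L, 100L, 200L), end = c(100L, 200L, 300L),
                        reference = c(100, 100, 200))
  counts <- tibble::tibble(sample_id = "s", index = 1:3, chrom = "chr1",
                           start = ref$start, end = ref$end,
                           depth = c(100, 50, 0))
  tr <- log2_ratio_track(counts, ref, pseudocount = 0.5)
  expect_equal(tr$M[1], 0)
  expect_equal(tr$M[2], log2(50.5 / 100.5))
  expect_equal(tr$M[3], -5)  # log2(0.5/200.5) ~ -8.65, clamped
  expect_false(isTRUE(attr(tr, "normalized")))
  expect_error(log2_ratio_track(counts[1:2, ], ref), "mismatch")
})

test_that("mean-shift normalization zeroes the mean exactly", {
  mk <- function(m) {
    tr <- tibble::tibble(sample_id = "s", index = seq_along(m), chrom = "c",
                         start = 0L, end = 1L, M = m)
    attr(tr, "normalized") <- FALSE
    tr
  }
  expect_equal(mean_shift_normalize(mk(c(0, 0, 0)))$M, c(0, 0, 0))
  expect_equal(mean_shift_normalize(mk(c(1, 1, 1)))$M, c(0, 0, 0))
  expect_equal(mean_shift_normalize(mk(c(0, -1)))$M, c(0.5, -0.5))
  expect_error(mean_shift_normalize(mk(numeric(0))), "empty")
  withr::local_seed(5)
  for (i in 1:50) {
    tr <- mean_shift_normalize(mk(rnorm(sample.int(200, 1), sd = 3)))
    expect_lt(abs(mean(tr$M)), 1e-9)
    expect_true(isTRUE(attr(tr, "normalized")))
  }
})

test_that("exon aggregation uses >=1 bp overlap and type-7 quantiles", {
  model <- toy_model("G", "chr1", "+", exon_starts = c(0L, 300L),
                     exon_ends = c(200L, 400L))
  mk_track <- function(starts, ends, m) {
    tr <- tibble::tibble(sample_id = "s", index = seq_along(m), chrom = "chr1",
                         start = starts, end = ends, M = m)
    attr(tr, "normalized") <- TRUE
    tr
  }
  tr <- mk_track(c(0L, 100L, 250L, 300L), c(100L, 200L, 300L, 400L),
                 c(-1, -1, 7, -0.4))
  s <- aggregate_exons(tr, model)
  expect_equal(s$n_windows, c(2L, 1L))
  expect_equal(s$mean_M, c(-1, -0.4))
  expect_equal(s$q25_M, c(-1, -0.4))
  expect_equal(s$q75_M, c(-1, -0.4))

  tr2 <- mk_track(c(0L, 100L), c(100L, 200L), c(0, -2))
  s2 <- aggregate_exons(tr2, model)
  expect_equal(s2$mean_M[1], -1)
  expect_equal(s2$q25_M[1], -1.5)
  expect_equal(s2$q75_M[1], -0.5)
  expect_equal(s2$n_windows[2], 0L)
  expect_true(is.na(s2$mean_M[2]))
})

test_that("deletion calling merges flagged exon runs and classes them", {
  mk <- function(mean_M, q75 = mean_M, gene = "G") {
    tibble::tibble(gene = gene, exon = seq_along(mean_M), mean_M = mean_M,
                   q25_M = mean_M, q75_M = q75,
                   n_windows = rep(3L, length(mean_M)))
  }
  m <- rep(0, 43); m[15:23] <- -1
  calls <- call_deletions(mk(m, q75 = m + 0.2))
  expect_equal(nrow(calls), 1)
  expect_equal(c(calls$first_exon, calls$last_exon), c(15L, 23L))
  expect_equal(calls$zygosity_class, "het")
  expect_equal(calls$mosaic_fraction, 1)

  single <- rep(0, 38); single[38] <- -0.95
  c2 <- call_deletions(mk(single))
  expect_equal(c(c2$first_exon, c2$last_exon), c(38L, 38L))

  expect_equal(nrow(call_deletions(mk(rnorm(43, 0, 0.02)))), 0)

  hom <- rep(0, 10); hom[3:5] <- -4.5
  expect_equal(call_deletions(mk(hom))$zygosity_class, "hom")

  shallow <- rep(0, 10); shallow[4:6] <- -0.4
  expect_equal(nrow(call_deletions(mk(shallow))), 0)  # above het threshold
  c3 <- call_deletions(mk(shallow), mosaic_mode = TRUE)
  expect_equal(c3$zygosity_class, "mosaic")

  mixed <- dplyr::bind_rows(mk(rep(0, 3)), mk(rep(0, 3), gene = "H"))
  expect_error(call_deletions(mixed), "single gene")
})

test_that("mosaic fraction inverts the depth-dilution model", {
  expect_equal(estimate_mosaic_fraction(0), 0)
  expect_equal(estimate_mosaic_fraction(-1), 1)
  expect_equal(estimate_mosaic_fraction(log2(3 / 4)), 0.5)
  for (f in seq(0, 1, by = 0.1)) {
    expect_lt(abs(estimate_mosaic_fraction(log2(1 - f / 2)) - f), 1e-9)
  }
  expect_error(estimate_mosaic_fraction(0.3), "gain")
})

test_that("ORF projection labels windows exonic by >=1 bp overlap", {
  model <- toy_model("G", "chr1", "+", exon_starts = c(100L, 400L),
                     exon_ends = c(200L, 500L))
  tr <- tibble::tibble(
    sample_id = "s", index = 1:5, chrom = "chr1",
    start = c(0L, 100L, 200L, 300L, 400L),
    end = c(100L, 200L, 300L, 400L, 500L),
    M = rnorm(5)
  )
  attr(tr, "normalized") <- TRUE
  s <- aggregate_exons(tr, model)
  proj <- project_orf(tr, s, model)
  expect_equal(nrow(proj$orf), 5)
  expect_equal(sum(proj$orf$exonic), 2)
  expect_equal(nrow(proj$exon), 2)

  intr <- dplyr::mutate(tr, start = start + 1000L, end = end + 1000L)
  attr(intr, "normalized") <- TRUE
  expect_false(any(project_orf(intr, s, model)$orf$exonic))

  paths <- write_orf_projection(proj, withr::local_tempdir())
  expect_true(all(file.exists(paths)))
  expect_s3_class(autoplot(proj), "patchwork")
})

test_that("a sample against a reference of itself gives M identically zero", {
  withr::local_seed(33)
  w <- make_windows(targets1(1000L))
  d <- tibble::tibble(chrom = "chr1", pos = 1:1000,
                      depth = rpois(1000, 80), sample_id = "a")
  counts <- dplyr::bind_rows(
    bin_depth(d, w),
    bin_depth(dplyr::mutate(d, sample_id = "b"), w),
    bin_depth(dplyr::mutate(d, sample_id = "c"), w)
  ) |> library_size_normalize()
  ref <- build_reference(counts)
  tr <- mean_shift_normalize(log2_ratio_track(counts, ref, sample = "a"))
  expect_lt(max(abs(tr$M)), 1e-9)
})
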