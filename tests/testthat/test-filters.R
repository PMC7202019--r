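manifest2 <- list(P1 = c("s1", "s2", "s3"), P2 = c("s4", "s5"))

test_that("index-hop remediation zeroes strictly-below-threshold samples", {
  peaks <- make_peak_table(
    40, data.frame(s1 = c(1000L, 500L, 20L), s2 = c(59L, 0L, 20L),
                   s3 = c(60L, 0L, 20L), s4 = c(0L, 7L, 0L),
                   s5 = c(2L, 100L, 0L)))
  out <- index_hop_filter(peaks, manifest2, 0.06)
  # pool P1, max 1000: 59 < 60 zeroed; 60 kept (not strictly below)
  expect_equal(out$s2[1], 0L)
  expect_equal(out$s3[1], 60L)
  # pools are independent: s5's 2 vs P2 max 2 -> kept
  expect_equal(out$s5[1], 2L)
  # a single carrying sample is its own maximum
  expect_equal(out$s1[2], 500L)
  expect_equal(out$s4[2], 7L)   # 7 >= 0.06 * 100
  # equal counts all survive
  expect_equal(unlist(out[3, c("s1", "s2", "s3")], use.names = FALSE),
               c(20L, 20L, 20L))
  # totals recomputed
  expect_equal(out$n_reads_total, as.integer(rowSums(
    out[, peak_samples(out)])))
})

test_that("samples missing from the manifest are an error, by name", {
  peaks <- make_peak_table(40, data.frame(s1 = 5L, zz = 3L))
  expect_error(index_hop_filter(peaks, manifest2, 0.06), "zz")
})

test_that("peaks emptied by remediation are dropped and counted", {
  peaks <- make_peak_table(40, data.frame(s1 = c(1000L, 300L),
                                          s2 = c(3L, 300L),
                                          s3 = c(0L, 0L)))
  peaks$s2[1] <- 3L
  peaks[1, c("s1", "s2", "s3")] <- c(0L, 0L, 0L)
  peaks$n_reads_total <- as.integer(rowSums(peaks[, c("s1", "s2", "s3")]))
  expect_message(out <- index_hop_filter(peaks, manifest2, 0.06),
                 "dropped")
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "n_dropped"), 1L)
})

test_that("index-hop remediation is idempotent on random peak tables", {
  set.seed(19)
  samples <- sprintf("s%d", 1:5)
  for (i in 1:25) {
    cnt <- matrix(rpois(6 * 5, lambda = sample(c(2, 30, 300), 1)),
                  nrow = 6, dimnames = list(NULL, samples))
    peaks <- make_peak_table(runif(6, 20, 60), as.data.frame(cnt))
    once <- suppressMessages(index_hop_filter(peaks, manifest2, 0.06))
    twice <- suppressMessages(index_hop_filter(once, manifest2, 0.06))
    expect_equal(twice, once)
  }
})

test_that("average reads per carrier divides total by positive samples", {
  peaks <- make_peak_table(40, data.frame(A = c(300L, 100L, 99L),
                                          B = c(0L, 0L, 0L),
                                          C = c(200L, 0L, 0L)))
  expect_equal(avg_reads_per_person(peaks), c(250, 100, 99))
  zero <- make_peak_table(40, data.frame(A = 0L, B = 0L))
  expect_error(avg_reads_per_person(zero), "zero carriers")
})

test_that("the MapQ cutoff is mean minus multiples of the sample SD", {
  expect_equal(mapq_cutoff_from_stats(38.82, 4.10, 2), 30.62)
  # identical peaks: SD 0, cutoff equals the common value
  peaks <- make_peak_table(rep(44.4, 3), data.frame(A = c(5L, 5L, 5L)))
  expect_equal(derive_mapq_cutoff(peaks), 44.4)
  expect_equal(derive_mapq_cutoff(peaks, sd_mult = 0), 44.4)
  # sample (n-1) standard deviation
  peaks <- make_peak_table(c(30, 50), data.frame(A = c(5L, 5L)))
  expect_equal(derive_mapq_cutoff(peaks, 1), 40 - sd(c(30, 50)))
  expect_error(derive_mapq_cutoff(peaks[1, ]), "at least 2")
  # only reference-class rows inform the cutoff
  mix <- rbind(make_peak_table(c(40, 40), data.frame(A = c(5L, 5L)),
                               class = "reference"),
               make_peak_table(c(10, 10), data.frame(A = c(5L, 5L)),
                               class = "novel_nonref"))
  expect_equal(derive_mapq_cutoff(mix, 2), 40)
})

test_that("cutoffs apply sequentially and report retention per class", {
  peaks <- rbind(
    make_peak_table(c(40, 40, 31, 25), data.frame(S1 = c(500L, 50L, 200L, 900L)),
                    class = "reference"),
    make_peak_table(c(35, 29), data.frame(S1 = c(150L, 150L)),
                    class = "novel_nonref"))
  res <- apply_cutoffs(peaks, mapq_cutoff = 30.62, min_avg_reads = 100)
  rep <- res$report
  expect_equal(rep$n_input[rep$class == "reference"], 4L)
  expect_equal(rep$n_after_mapq[rep$class == "reference"], 3L)
  expect_equal(rep$n_retained[rep$class == "reference"], 2L)
  expect_equal(rep$pct_retained[rep$class == "reference"], 50)
  expect_equal(rep$n_retained[rep$class == "novel_nonref"], 1L)
  expect_equal(nrow(res$peaks), 3L)
  expect_true(all(res$peaks$mean_mapq >= 30.62 &
                    res$peaks$avg_reads_per_person >= 100))
  # zero cutoffs retain everything
  all_in <- apply_cutoffs(peaks, 0, 0)
  expect_equal(nrow(all_in$peaks), nrow(peaks))
  expect_equal(all_in$report$pct_retained[1], 100)
})

test_that("raising either cutoff can only shrink the retained set", {
  set.seed(73)
  for (i in 1:15) {
    peaks <- make_peak_table(runif(40, 20, 60),
                             data.frame(A = rpois(40, 200),
                                        B = rpois(40, 20)),
                             class = sample(c("reference", "known_nonref",
                                              "novel_nonref"), 40,
                                            replace = TRUE))
    key <- function(p) paste(p$chrom, p$start)
    prev <- NULL
    for (cut in list(c(0, 0), c(25, 50), c(30.62, 100), c(45, 400))) {
      got <- key(apply_cutoffs(peaks, cut[1], cut[2])$peaks)
      if (!is.null(prev)) expect_true(all(got %in% prev))
      prev <- got
    }
    rep <- apply_cutoffs(peaks, 30.62, 100)$report
    ok <- !is.na(rep$pct_retained)
    expect_true(all(rep$pct_retained[ok] >= 0 & rep$pct_retained[ok] <= 100))
    expect_equal(rep$pct_retained[ok],
                 floor(100 * rep$n_retained[ok] / rep$n_input[ok] * 100
                       + 0.5) / 100)
  }
})
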