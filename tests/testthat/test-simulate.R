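quiet_cfg <- function(...) {
  sim_config(seed = 424, n_ref = 8, n_known = 4, n_novel = 4,
             reads_per_carrier = 30, polyt_rate = 0, hop_rate = 0,
             mapq_mean = 60, mapq_sd = 0, ...)
}

test_that("truth sets are deterministic and correctly cataloged", {
  cfg <- quiet_cfg()
  t1 <- make_truth(cfg)
  t2 <- make_truth(cfg)
  expect_identical(t1, t2)
  expect_equal(nrow(t1$truth), 16L)
  expect_equal(sum(t1$truth$class == "reference"), 8L)
  expect_equal(nrow(t1$ref_features), 8L)
  expect_equal(nrow(t1$known_features), 4L)
  # novel insertions appear in no catalog
  expect_false(any(t1$truth$insertion_id[t1$truth$class == "novel_nonref"]
                   %in% c(t1$ref_features$name, t1$known_features$name)))
  # junction separation respects the configured minimum
  by_chrom <- split(t1$truth$junction, t1$truth$chrom)
  expect_true(all(unlist(lapply(by_chrom, function(j)
    diff(sort(j)) >= cfg$min_separation))))
  # reference insertions are carried by the whole cohort
  ref_car <- t1$truth$carriers[t1$truth$class == "reference"]
  expect_true(all(ref_car == paste(sprintf("S%02d", 1:12), collapse = ",")))
  # elements sit on the strand opposite the peak
  expect_true(all(t1$truth$peak_strand != t1$truth$element_strand))
  # a genome too small for the request is refused
  expect_error(make_truth(sim_config(n_ref = 500, n_known = 0,
                                     n_novel = 0, n_chroms = 1,
                                     chrom_length = 1e5)),
               "too small")
})

test_that("read simulation is seed-deterministic with sane depth", {
  cfg <- quiet_cfg()
  truth <- make_truth(cfg)
  s1 <- simulate_reads(truth, cfg)
  s2 <- simulate_reads(truth, cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$polyt), 0L)   # polyt_rate 0 -> empty FASTQ
  # with one insertion and one carrier, depth is Poisson(mean)
  one <- sim_config(seed = 5, n_ref = 0, n_known = 0, n_novel = 1,
                    n_samples = 1, reads_per_carrier = 50,
                    polyt_rate = 0, hop_rate = 0)
  n <- nrow(simulate_reads(make_truth(one), one)$reads)
  expect_true(n >= qpois(5e-4, 50) && n <= qpois(1 - 5e-4, 50))
  # hop_rate 0, single carrier: every read keeps its sample label
  expect_equal(unique(simulate_reads(make_truth(one), one)$reads$sample),
               "S01")
})

test_that("poly(T) diversion matches the configured rate and trims back", {
  cfg <- sim_config(seed = 77, n_ref = 0, n_known = 6, n_novel = 6,
                    reads_per_carrier = 60, polyt_rate = 0.10,
                    hop_rate = 0, mapq_mean = 60, mapq_sd = 0)
  sim <- simulate_dataset(cfg)
  n_total <- nrow(sim$reads) + nrow(sim$polyt)
  frac <- nrow(sim$polyt) / n_total
  # all reads support non-reference insertions here; fraction within
  # 3 binomial SDs of the configured rate
  tol <- 3 * sqrt(0.1 * 0.9 / n_total)
  expect_lt(abs(frac - 0.10), tol)

  # every diverted read carries a trimmable poly(T) suffix
  trimmed <- trim_polyt(sim$polyt, polyt_config())
  expect_equal(nrow(trimmed$rejected), 0L)
  expect_equal(trimmed$summary$n_trimmed, nrow(sim$polyt))

  # trimmed reads, realigned at their true positions, land in the same
  # peaks as their aligned siblings: one peak per insertion either way
  aligned_plus <- rbind(sim$reads,
                        sim$polyt_truth[, colnames(sim$reads)])
  p_all <- call_peaks(aligned_plus, window = 150)
  expect_equal(nrow(p_all), nrow(sim$truth))
  expect_equal(sum(p_all$n_reads_total), nrow(aligned_plus))
})

test_that("noise-free simulation is recovered exactly end to end", {
  cfg <- quiet_cfg()
  sim <- simulate_dataset(cfg)
  reads <- filter_mapq(sim$reads, 30)
  expect_equal(nrow(reads), nrow(sim$reads))   # MapQ 60 everywhere
  peaks <- call_peaks(reads, window = 150)
  peaks <- annotate_peaks(peaks, sim$ref_features, sim$known_features)
  expect_equal(nrow(peaks), nrow(sim$truth))   # recall 1, no spurious
  truth <- sim$truth[order(sim$truth$chrom, sim$truth$junction), ]
  ord <- order(peaks$chrom, ifelse(peaks$strand == "+", peaks$start,
                                   peaks$end))
  peaks <- peaks[ord, ]
  expect_equal(peaks$strand, truth$peak_strand)
  expect_equal(peaks$annotation_class, truth$class)
  # annotated names point back at the generating insertion
  named <- peaks$annotation_class != "novel_nonref"
  expect_equal(peaks$annotation_name[named], truth$insertion_id[named])
  # carriers match the planted genotypes
  samples <- peak_samples(peaks)
  for (i in which(truth$class != "reference")) {
    got <- samples[unlist(peaks[i, samples]) > 0]
    expect_setequal(got, strsplit(truth$carriers[i], ",")[[1]])
  }
})

test_that("a written simulation reloads through the format layer", {
  cfg <- quiet_cfg()
  sim <- simulate_dataset(cfg)
  dir <- tempfile()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  reads <- read_sam(paths[["sam"]])
  expect_equal(nrow(reads), nrow(sim$reads))
  got <- reads[order(reads$read_id), c("chrom", "start", "end", "strand",
                                       "mapq", "sample")]
  want <- sim$reads[order(sim$reads$read_id),
                    c("chrom", "start", "end", "strand", "mapq", "sample")]
  expect_equal(got, want, ignore_attr = TRUE)
  ref <- read_bed(paths[["ref_bed"]], "repeatmasker_l1hs")
  expect_equal(ref[, c("chrom", "start", "end", "name", "strand")],
               sim$ref_features[, c("chrom", "start", "end", "name",
                                    "strand")], ignore_attr = TRUE)
  expect_equal(read_pool_manifest(paths[["pools"]]), sim$manifest)
})
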