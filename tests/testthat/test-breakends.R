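# Breakend catalogs: insert stats, truth-derived junctions, the VCF BND
# round trip, and the caller emulator

test_that("insert-size stats are the median and unscaled MAD", {
  s <- compute_insert_stats(c(300, 300, 300))
  expect_equal(s$median, 300)
  expect_equal(s$mad, 0)
  s <- compute_insert_stats(c(100, 200, 300, 400, 500))
  expect_equal(s$median, 300)
  expect_equal(s$mad, 100)
  s <- compute_insert_stats(250)
  expect_equal(unclass(s)[c("median", "mad")], list(median = 250, mad = 0))
  expect_error(compute_insert_stats(numeric(0)), "no fragment")
})

test_that("truth sets decompose into junctions with the right orientations", {
  truth <- sv_set(data.frame(
    id = c("d", "t", "v", "x", "n"),
    type = c("deletion", "tandem_duplication", "inversion", "translocation",
             "insertion"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1"),
    start = c(1000L, 5000L, 9000L, 15000L, 20000L),
    end = c(2000L, 6000L, 9500L, NA, 20300L),
    chrom2 = c(NA, NA, NA, "chr2", "chr2"),
    start2 = c(NA, NA, NA, 4000L, 8000L),
    copy = c(NA, NA, NA, NA, TRUE),
    inverted = c(NA, NA, NA, FALSE, NA)))
  bps <- truth_breakpoints(truth)
  expect_equal(nrow(bps), 1 + 1 + 2 + 2 + 2)
  expect_equal(bps$type_hint[bps$sv_id == "d"], "DEL-like")
  expect_equal(bps$type_hint[bps$sv_id == "t"], "TAN-like")
  expect_equal(bps$type_hint[bps$sv_id == "v"], c("INV-like", "INV-like"))
  expect_true(all(bps$type_hint[bps$sv_id %in% c("x", "n")] ==
                    "interchromosomal"))
  expect_equal(bps$length[bps$sv_id == "d"], 1000)
})

test_that("breakend VCF bracket notation decodes deletion geometry", {
  # hand-written pair: deletion-like junction chr1:1000-2000 (0-based)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    paste("chr1", "1000", "j_1", "N", "N[chr1:2001[", "900", "PASS",
          "SVTYPE=BND;MATEID=j_2;FRAGS=12", sep = "\t"),
    paste("chr1", "2001", "j_2", "N", "]chr1:1000]N", "900", "PASS",
          "SVTYPE=BND;MATEID=j_1;FRAGS=12", sep = "\t")), vcf)
  bps <- parse_breakend_vcf(vcf)
  expect_equal(nrow(bps), 1)
  expect_equal(bps$type_hint, "DEL-like")
  expect_equal(bps$pos_1, 1000)
  expect_equal(bps$pos_2, 2000)
  expect_equal(bps$orient_1, "right")
  expect_equal(bps$orient_2, "left")
  expect_equal(bps$nfrag_1, 12L)
  expect_equal(bps$qual_1, 900)
})

test_that("header-only VCF parses to an empty catalog; unpaired mates drop;
           malformed ALT errors", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t")), vcf)
  expect_equal(nrow(parse_breakend_vcf(vcf)), 0)

  writeLines(c("##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    paste("chr1", "100", "a_1", "N", "N[chr1:500[", "10", "PASS",
          "SVTYPE=BND;MATEID=a_2", sep = "\t")), vcf)
  expect_message(got <- parse_breakend_vcf(vcf), "unpaired")
  expect_equal(nrow(got), 0)
  expect_equal(attr(got, "dropped"), 1)

  writeLines(c("##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    paste("chr1", "100", "bad_1", "N", "N[chr1:500", "10", "PASS",
          "SVTYPE=BND;MATEID=bad_2", sep = "\t")), vcf)
  expect_error(parse_breakend_vcf(vcf), "bad_1")
})

test_that("an emulated catalog round trips through the VCF dialect", {
  g <- make_genome(c(chr1 = 60000, chr2 = 50000), seed = 21)
  truth <- suppressWarnings(simulate_svs(g, n = 4, seed = 1))
  istats <- compute_insert_stats(c(250, 300, 350))
  bps <- emulate_caller(truth, g, 30, istats, noise_model(), seed = 2)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_breakend_vcf(bps, vcf,
                     chrom_lengths = setNames(Biostrings::width(g), names(g)))
  back <- parse_breakend_vcf(vcf)
  expect_equal(nrow(back), nrow(bps))
  o1 <- bps[order(bps$bp_id), ]
  o2 <- back[order(back$bp_id), ]
  for (cl in c("chrom_1", "pos_1", "orient_1", "chrom_2", "pos_2",
               "orient_2", "nfrag_1", "nfrag_2", "microhom_1", "ins_seq_1",
               "ins_seq_2", "tags_1", "tags_2", "has_rp_1", "has_sr_2"))
    expect_equal(o2[[cl]], o1[[cl]], label = cl)
  expect_equal(o2$qual_1, o1$qual_1, tolerance = 1e-4)
  expect_equal(o2$vaf_small_2, o1$vaf_small_2, tolerance = 1e-4)
  expect_equal(o2$type_hint, o1$type_hint)
})

test_that("a catalog round trips through its TSV dump", {
  g <- make_genome(c(chr1 = 60000, chr2 = 50000), seed = 26)
  truth <- suppressWarnings(simulate_svs(g, n = 3, seed = 9))
  bps <- emulate_caller(truth, g, 30, NULL, noise_model(), seed = 10)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_breakpoint_table(bps, p)
  back <- read_breakpoint_table(p)
  expect_equal(nrow(back), nrow(bps))
  for (cl in c("chrom_1", "pos_1", "orient_1", "pos_2", "nfrag_1", "tags_2",
               "ins_seq_1", "type_hint"))
    expect_equal(back[[cl]], bps[[cl]], label = cl)
})

test_that("the emitted VCF is readable by an independent VCF parser", {
  skip_if_not_installed("VariantAnnotation")
  g <- make_genome(c(chr1 = 60000, chr2 = 50000), seed = 22)
  truth <- suppressWarnings(simulate_svs(g, n = 3, seed = 3))
  bps <- emulate_caller(truth, g, 30, NULL, noise_model(), seed = 4)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_breakend_vcf(bps, vcf,
                     chrom_lengths = setNames(Biostrings::width(g), names(g)))
  v <- VariantAnnotation::readVcf(vcf)
  expect_equal(length(v), 2 * nrow(bps))
  info <- VariantAnnotation::info(v)
  expect_true(all(info$SVTYPE == "BND"))
  # mate ids pair up both ways
  m <- setNames(unlist(info$MATEID), rownames(info))
  expect_true(all(m[m[names(m)]] == names(m)))
  # positions agree with the catalog's 1-based emission rule
  rr <- SummarizedExperiment::rowRanges(v)
  pos1 <- setNames(BiocGenerics::start(rr), names(rr))[
    paste0(bps$bp_id, "_1")]
  expect_equal(unname(pos1),
               ifelse(bps$orient_1 == "right", bps$pos_1, bps$pos_1 + 1L))
})

test_that("the noiseless emulator reproduces truth junctions exactly and is
           deterministic under a fixed seed", {
  g <- make_genome(c(chr1 = 60000, chr2 = 50000, chr3 = 40000), seed = 23)
  truth <- suppressWarnings(simulate_svs(g, n = 5, seed = 5))
  bps <- emulate_caller(truth, g, 30, NULL, noiseless_noise_model(),
                        seed = 6)
  tb <- truth_breakpoints(truth)
  expect_equal(nrow(bps), nrow(tb))
  key <- function(b) sort(paste(b$chrom_1, b$pos_1, b$orient_1, b$chrom_2,
                                b$pos_2, b$orient_2))
  expect_equal(key(bps), key(tb))

  again <- emulate_caller(truth, g, 30, NULL, noiseless_noise_model(),
                          seed = 6)
  expect_identical(as.data.frame(bps), as.data.frame(again))

  none <- emulate_caller(truth, g, 30, NULL,
                         noise_model(detection_prob = 0, fp_rate_per_mb = 40),
                         seed = 7)
  expect_true(all(is.na(none$sv_id)))
})

test_that("truth-junction detection is binomial at the configured rate", {
  g <- make_genome(c(chr1 = 50000, chr2 = 40000), seed = 24)
  truth <- suppressWarnings(simulate_svs(g, n = 4, seed = 8))
  n_junc <- nrow(truth_breakpoints(truth))
  p <- 0.7
  nm <- noise_model(detection_prob = p, fp_rate_per_mb = 0, jitter_sd = 0)
  detected <- vapply(1:200, function(s)
    nrow(emulate_caller(truth, g, 30, NULL, nm, seed = s)), 1L)
  rate <- mean(detected) / n_junc
  se <- sqrt(p * (1 - p) / (200 * n_junc))
  expect_lt(abs(rate - p), 3 * se)
})

test_that("synthetic coverage reflects copy-number changes and normalizes to
           median 1", {
  g <- make_genome(c(chr1 = 30000), seed = 25)
  truth <- sv_set(data.frame(
    id = c("d", "t"), type = c("deletion", "tandem_duplication"),
    chrom = "chr1", start = c(5000L, 20000L), end = c(7000L, 22000L)))
  covt <- simulate_coverage(g, truth, "haploid", window = 100, noise_sd = 0)
  expect_equal(median(covt$rel_coverage), 1)
  expect_equal(coverage_of_interval(covt, "chr1", 5000, 7000), 0)
  expect_equal(coverage_of_interval(covt, "chr1", 20000, 22000), 2)
  expect_equal(coverage_of_interval(covt, "chr1", 10000, 12000), 1)
  het <- simulate_coverage(g, truth, "diploid_hetero", window = 100,
                           noise_sd = 0)
  expect_equal(coverage_of_interval(het, "chr1", 5000, 7000), 0.5)
  expect_equal(coverage_of_interval(het, "chr1", 20000, 22000), 1.5)
})
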