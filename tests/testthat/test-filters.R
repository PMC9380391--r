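# The breakend filter model, typing, coverage classification and call_svs

istats300 <- compute_insert_stats(c(250, 300, 350)) # median 300, MAD 50

test_that("printed defaults act as behavioral boundaries of the rules", {
  p <- filter_params()
  pass1 <- function(bp) breakend_passes(bp, 1, p, istats300)$pass

  expect_false(pass1(make_bp(nfrag = 4)))        # min_Nfragments 5
  expect_true(pass1(make_bp(nfrag = 5)))
  expect_false(pass1(make_bp(tags = "NO_ASSEMBLY")))
  expect_true(pass1(make_bp()))                  # nominal breakend passes

  # VAF switch: 2 kb event is "large" (length > median + MAD = 350)
  expect_false(pass1(make_bp(pos_2 = 12000, vaf_large = 0.2, vaf_small = 1)))
  expect_true(pass1(make_bp(pos_2 = 12000, vaf_large = 0.3, vaf_small = 0)))
  # a 300 bp event is small: vaf_small is read
  expect_false(pass1(make_bp(pos_2 = 10300, vaf_small = 0.2, vaf_large = 1,
                             orient_1 = "left", orient_2 = "left")))
  # min_af_EitherSmallOrLargeEvent rejects only when both are low
  expect_false(pass1(make_bp(vaf_small = 0.2, vaf_large = 0.2,
                             orient_1 = "left", orient_2 = "left")))
  expect_true(pass1(make_bp(vaf_small = 0.3, vaf_large = 0.2,
                            orient_1 = "left", orient_2 = "left",
                            pos_2 = 10300)))

  # microhomology bound is inclusive at 50
  expect_true(pass1(make_bp(microhom = 50)))
  expect_false(pass1(make_bp(microhom = 51)))
  # inexact homology applies to non-small events only
  expect_false(pass1(make_bp(inexact_hom = 51)))           # 2 kb, non-small
  expect_true(pass1(make_bp(pos_2 = 10300, inexact_hom = 51,
                            orient_1 = "left", orient_2 = "left")))
  # strand bias applies to small events only
  expect_false(pass1(make_bp(pos_2 = 10300, strand_bias = 0.995,
                             orient_1 = "left", orient_2 = "left")))
  expect_true(pass1(make_bp(strand_bias = 0.995)))         # 2 kb, non-small
  # poly-G/C insert: runs > 15 bp are dropped, 15 bp is kept
  expect_false(pass1(make_bp(ins_seq = strrep("G", 16), orient_1 = "left",
                             orient_2 = "left", pos_2 = 10300)))
  expect_false(pass1(make_bp(ins_seq = strrep("C", 16))))
  expect_true(pass1(make_bp(ins_seq = strrep("G", 15))))
  # inversion length bound: 39 bp INV-like is dropped, 40 kept
  expect_false(pass1(make_bp(pos_2 = 10039, orient_2 = "right")))
  expect_true(pass1(make_bp(pos_2 = 10040, orient_2 = "right")))
  # QUAL default 0 is inert
  expect_true(pass1(make_bp(qual = 0)))
})

test_that("DEL-like range and insert-length rules follow their definitions", {
  p <- filter_params(range_filt_DEL_breakpoints = c(500, 1000))
  pass1 <- function(bp, prm = p) breakend_passes(bp, 1, prm, istats300)$pass
  # DEL-like, 700 bp, inexact homology > 5 -> dropped inside the range
  expect_false(pass1(make_bp(pos_2 = 10700, inexact_hom = 6)))
  expect_true(pass1(make_bp(pos_2 = 10700, inexact_hom = 5)))
  expect_true(pass1(make_bp(pos_2 = 11100, inexact_hom = 6))) # outside range
  # TAN-like is untouched by the DEL range rule
  expect_true(pass1(make_bp(pos_2 = 10700, inexact_hom = 6,
                            orient_1 = "left", orient_2 = "right")))

  # insert-vs-deletion margin: small DEL-like with
  # len(insert) > len(event) - 5 is dropped
  d <- filter_params()
  expect_false(pass1(make_bp(pos_2 = 10020, ins_seq = strrep("A", 16)), d))
  expect_true(pass1(make_bp(pos_2 = 10020, ins_seq = strrep("A", 15)), d))
})

test_that("support-type filters apply to the right event-size classes", {
  p <- filter_params(filter_noReadPairs = TRUE, filter_noSplitReads = TRUE)
  pass1 <- function(bp) breakend_passes(bp, 1, p, istats300)$pass
  # large event without read pairs -> dropped; small unaffected
  expect_false(pass1(make_bp(has_rp = FALSE)))
  expect_true(pass1(make_bp(pos_2 = 10300, has_rp = FALSE, has_sr = TRUE,
                            orient_1 = "left", orient_2 = "left")))
  # small event without split reads -> dropped; large unaffected
  expect_false(pass1(make_bp(pos_2 = 10300, has_sr = FALSE,
                             orient_1 = "left", orient_2 = "left")))
  expect_true(pass1(make_bp(has_sr = FALSE)))
  # interchromosomal breakpoints are never small
  expect_false(pass1(make_bp(chrom_2 = "chr2", pos_2 = 500, has_rp = FALSE)))
})

test_that("missing fragment counts error only when the rule can fire", {
  bp <- make_bp(nfrag = NA)
  expect_error(breakend_passes(bp, 1, filter_params(), istats300), "nfrag")
  expect_true(breakend_passes(bp, 1, filter_params(min_Nfragments = 0),
                              istats300)$pass)
})

test_that("a breakpoint is discarded when either breakend fails", {
  bp <- make_bp(nfrag_1 = 30, nfrag_2 = 2)
  pass <- breakpoint_passes(bp, filter_params(), istats300)
  expect_false(pass[1])
  expect_equal(attr(pass, "reasons")[[1]], "min_Nfragments")
  expect_true(breakpoint_passes(make_bp(), filter_params(), istats300)[1])
  both <- make_bp(nfrag = 2, microhom = 60)
  r <- attr(breakpoint_passes(both, filter_params(), istats300), "reasons")
  expect_setequal(r[[1]], c("min_Nfragments", "maximum_microhomology"))
})

test_that("orientation typing follows the junction geometry truth table", {
  expect_equal(make_bp(orient_1 = "right", orient_2 = "left")$type_hint,
               "DEL-like")
  expect_equal(make_bp(orient_1 = "left", orient_2 = "right")$type_hint,
               "TAN-like")
  expect_equal(make_bp(orient_1 = "left", orient_2 = "left")$type_hint,
               "INV-like")
  expect_equal(make_bp(chrom_2 = "chr2")$type_hint, "interchromosomal")
  # canonical ordering makes typing invariant to the input breakend order
  flipped <- make_bp(chrom_1 = "chr1", pos_1 = 12000, orient_1 = "left",
                     chrom_2 = "chr1", pos_2 = 10000, orient_2 = "right")
  expect_equal(flipped$type_hint, "DEL-like")
  expect_equal(flipped$pos_1, 10000)
})

test_that("the filter engine agrees with a straight-line oracle on 10,000
           random breakends", {
  bps <- random_catalog(5000, seed = 31)
  param_sets <- list(
    filter_params(),
    unconservative_filter_params(),
    filter_params(min_Nfragments = 10, min_af = 0.4, min_QUAL = 600,
                  maximum_microhomology = 20, filter_noReadPairs = TRUE,
                  filter_noSplitReads = TRUE, maximum_strand_bias = 0.8,
                  range_filt_DEL_breakpoints = c(100, 5000),
                  dif_between_insert_and_del = 10,
                  wrong_FILTERtags = c("NO_ASSEMBLY", "LOW_QUAL"),
                  filter_overlappingRepeats = TRUE,
                  min_length_inversions = 1000,
                  maximum_lenght_inexactHomology = 10,
                  min_af_EitherSmallOrLargeEvent = 0.5))
  for (p in param_sets) {
    for (side in 1:2) {
      got <- breakend_passes(bps, side, p, istats300)$pass
      want <- vapply(seq_len(nrow(bps)), function(i)
        oracle_breakend_pass(bps, i, side, p, istats300), TRUE)
      expect_equal(got, want)
    }
  }
})

test_that("tightening any single threshold never grows the passing set", {
  bps <- random_catalog(800, seed = 32)
  base <- unconservative_filter_params()
  tighter <- list(
    list("min_Nfragments", c(5, 10, 20)),
    list("min_af", c(0.1, 0.3)),
    list("min_af_EitherSmallOrLargeEvent", c(0.25, 0.6)),
    list("min_QUAL", c(100, 1000)),
    list("min_length_inversions", c(40, 5000)),
    list("maximum_lenght_inexactHomology", c(60, 20)),
    list("maximum_microhomology", c(60, 20)),
    list("maximum_strand_bias", c(0.95, 0.7)),
    list("filter_noReadPairs", TRUE),
    list("filter_noSplitReads", TRUE),
    list("filter_overlappingRepeats", TRUE),
    list("filter_polyGC", TRUE),
    list("wrong_FILTERtags", list("NO_ASSEMBLY",
                                  c("NO_ASSEMBLY", "LOW_QUAL"))))
  prev_all <- breakpoint_passes(bps, base, istats300)
  for (tw in tighter) {
    prev <- prev_all
    vals <- if (is.list(tw[[2]])) tw[[2]] else as.list(tw[[2]])
    for (v in vals) {
      p <- base
      p[[tw[[1]]]] <- v
      cur <- breakpoint_passes(bps, p, istats300)
      expect_true(all(which(cur) %in% which(prev)),
                  label = paste("monotone in", tw[[1]]))
      prev <- cur
    }
  }
})

test_that("the unconservative set passes every syntactically valid breakend", {
  bps <- random_catalog(2000, seed = 33)
  expect_true(all(breakpoint_passes(bps, unconservative_filter_params(),
                                    istats300)))
})

test_that("coverage classification uses strict thresholds and partitions", {
  covt <- data.frame(chrom = "chr1", start = seq(0, 49900, by = 100),
                     end = seq(100, 50000, by = 100), rel_coverage = 1)
  mkcov <- function(lo, hi, value) {
    covt$rel_coverage[covt$start >= lo & covt$end <= hi] <- value
    class(covt) <- c("sv_coverage", "data.frame")
    covt
  }
  del_bp <- make_bp(pos_1 = 10000, pos_2 = 12000)
  tan_bp <- make_bp(pos_1 = 20000, pos_2 = 22000, orient_1 = "left",
                    orient_2 = "right")
  p <- filter_params()
  cls <- classify_del_tan(del_bp, mkcov(10000, 12000, 0.05), p)
  expect_equal(nrow(cls$deletions), 1)
  cls <- classify_del_tan(del_bp, mkcov(10000, 12000, 0.5), p)
  expect_equal(nrow(cls$deletions), 0)
  expect_equal(nrow(cls$remaining), 1)
  cls <- classify_del_tan(tan_bp, mkcov(20000, 22000, 2.0), p)
  expect_equal(nrow(cls$tandem_duplications), 1)
  cls <- classify_del_tan(tan_bp, mkcov(20000, 22000, 1.8), p) # strict >
  expect_equal(nrow(cls$tandem_duplications), 0)

  bps <- random_catalog(300, seed = 34)
  covall <- data.frame(chrom = rep(c("chr1", "chr2"), each = 6000),
                       start = rep(seq(0, 599900, by = 100), 2),
                       end = rep(seq(100, 600000, by = 100), 2),
                       rel_coverage = 1)
  class(covall) <- c("sv_coverage", "data.frame")
  cls <- classify_del_tan(bps, covall, p)
  expect_equal(nrow(cls$deletions) + nrow(cls$tandem_duplications) +
                 nrow(cls$remaining), nrow(bps))
})

test_that("call_svs recovers a noiseless truth set exactly (F = 1) and
           handles empty and repeat-masked catalogs", {
  g <- make_genome(c(chr1 = 60000, chr2 = 50000, chr3 = 40000), seed = 35)
  truth <- suppressWarnings(simulate_svs(g, n = 2, seed = 10))
  covt <- simulate_coverage(g, truth, "haploid", noise_sd = 0)
  bps <- emulate_caller(truth, g, 30, istats300, noiseless_noise_model(),
                        seed = 11)
  calls <- call_svs(bps, unconservative_filter_params(), covt, istats300)
  acc <- compare_sv_sets(calls$svs, truth)
  expect_equal(acc$fvalue[acc$type == "integrated"], 1)

  empty <- call_svs(bps[0, ], filter_params(), covt, istats300)
  expect_equal(nrow(empty$svs), 0)

  repeats <- data.frame(chrom = names(g),
                        start = 0L,
                        end = Biostrings::width(g))
  masked <- call_svs(bps, filter_params(filter_overlappingRepeats = TRUE),
                     covt, istats300, repeats = repeats)
  expect_equal(nrow(masked$svs), 0)
  expect_equal(masked$n_filtered, nrow(bps))
})
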