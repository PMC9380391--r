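# Grid construction, pruning, per-simulation argmax and final selection

istats300 <- compute_insert_stats(c(250, 300, 350))

flat_cov <- function(chroms = c("chr1", "chr2"), len = 6e5) {
  d <- do.call(rbind, lapply(chroms, function(ch)
    data.frame(chrom = ch, start = seq(0, len - 100, by = 100),
               end = seq(100, len, by = 100), rel_coverage = 1)))
  class(d) <- c("sv_coverage", "data.frame")
  d
}

test_that("grids contain the unconservative extreme and the default", {
  un <- unconservative_filter_params()
  de <- filter_params()
  for (preset in c("small", "medium", "large")) {
    g <- filter_grid(preset)
    for (nm in names(g)) {
      has <- function(val) any(vapply(g[[nm]], function(v)
        isTRUE(all.equal(as.vector(v), as.vector(val))), TRUE))
      expect_true(has(un[[nm]]), label = paste(preset, nm, "unconservative"))
      expect_true(has(de[[nm]]), label = paste(preset, nm, "default"))
    }
    expect_gt(grid_size(g), 1)
  }
})

test_that("pruning collapses values that cannot change filtering", {
  # every breakend far above every fragment threshold -> all candidates
  # collapse onto the unconservative value
  bps <- make_bp(nfrag = 35)
  for (i in 2:30) bps <- sv_breakpoints(rbind(as.data.frame(bps),
                                              as.data.frame(make_bp(
                                                pos_1 = 10000 + i * 500,
                                                pos_2 = 12000 + i * 500,
                                                nfrag = 35))))
  pruned <- prune_grid(filter_grid(), bps, istats300, flat_cov())
  expect_length(pruned$min_Nfragments, 1)
  expect_equal(pruned$min_Nfragments[[1]], 0)

  # empty catalog: everything collapses, grid size 1
  pruned0 <- prune_grid(filter_grid(), bps[0, ], istats300, flat_cov())
  expect_equal(grid_size(pruned0), 1)

  # NO_ASSEMBLY on half the breakends: the tag filter stays explorable
  half <- bps
  half$tags_1[seq(1, nrow(half), by = 2)] <- "NO_ASSEMBLY"
  prunedh <- prune_grid(filter_grid(), half, istats300, flat_cov())
  expect_length(prunedh$wrong_FILTERtags, 2)
})

test_that("the grid argmax equals a brute-force argmax on a toy grid", {
  g <- make_genome(c(chr1 = 60000, chr2 = 50000, chr3 = 40000), seed = 51)
  truth <- suppressWarnings(simulate_svs(g, n = 5, seed = 20))
  covt <- simulate_coverage(g, truth, "haploid", noise_sd = 0)
  nm <- noise_model(detection_prob = 0.85, fp_rate_per_mb = 60,
                    jitter_sd = 0)
  bps <- emulate_caller(truth, g, 30, istats300, nm, seed = 21)

  toy <- filter_grid()
  for (p in names(toy)) toy[[p]] <- toy[[p]][1]
  toy$min_Nfragments <- as.list(c(0, 5, 10))
  toy$min_QUAL <- as.list(c(0, 100, 500))
  class(toy) <- "sv_filter_grid"

  got <- optimize_for_simulation(bps, truth, covt, istats300, toy)

  brute <- expand.grid(nf = c(0, 5, 10), q = c(0, 100, 500))
  fmat <- vapply(seq_len(nrow(brute)), function(i) {
    p <- unconservative_filter_params()
    p$min_Nfragments <- brute$nf[i]
    p$min_QUAL <- brute$q[i]
    acc <- compare_sv_sets(call_svs(bps, p, covt, istats300)$svs, truth)
    setNames(acc$fvalue[acc$type != "integrated"],
             acc$type[acc$type != "integrated"])
  }, setNames(numeric(5), svtune:::SV_TYPES))
  for (t in svtune:::SV_TYPES) {
    expect_equal(got$per_type[[t]]$fvalue, max(fmat[t, ]),
                 label = paste("argmax F for", t))
  }
})

test_that("when truth junctions all carry NO_ASSEMBLY, the optimizer drops
           the default tag filter", {
  g <- make_genome(c(chr1 = 60000, chr2 = 50000, chr3 = 40000), seed = 52)
  truth <- suppressWarnings(simulate_svs(g, n = 5, seed = 22))
  covt <- simulate_coverage(g, truth, "haploid", noise_sd = 0)
  nm <- noise_model(detection_prob = 1, fp_rate_per_mb = 10, jitter_sd = 0,
                    true_annot = list(no_assembly_prob = 1),
                    false_annot = list(no_assembly_prob = 0))
  bps <- emulate_caller(truth, g, 30, istats300, nm, seed = 23)
  opt <- optimize_for_simulation(bps, truth, covt, istats300, filter_grid())
  for (t in c("deletion", "inversion", "tandem_duplication")) {
    expect_length(opt$per_type[[t]]$params$wrong_FILTERtags, 0)
  }
  # the default (which requires assembly support) scores worse
  def_acc <- compare_sv_sets(
    call_svs(bps, filter_params(), covt, istats300)$svs, truth)
  expect_lt(def_acc$fvalue[def_acc$type == "deletion"],
            opt$per_type$deletion$fvalue)
})

test_that("an oversized pruned grid errors, suggesting a smaller preset", {
  bps <- random_catalog(400, seed = 53)
  covall <- flat_cov()
  expect_error(
    optimize_for_simulation(bps, random_sv_set(10, seed = 1), covall,
                            istats300, filter_grid("large"),
                            max_combinations = 10),
    "smaller grid preset")
})

test_that("final selection maximizes the minimum F with deterministic
           tie-breaks", {
  g <- make_genome(c(chr1 = 60000, chr2 = 50000, chr3 = 40000), seed = 54)
  truth <- suppressWarnings(simulate_svs(g, n = 4, seed = 24))
  covt <- simulate_coverage(g, truth, "haploid", noise_sd = 0)
  # instance 1: clean catalog (permissive params win)
  bps1 <- emulate_caller(truth, g, 30, istats300, noiseless_noise_model(),
                         seed = 25)
  # instance 2: low-fragment false junctions (needs min_Nfragments)
  nm2 <- noise_model(detection_prob = 1, fp_rate_per_mb = 150, jitter_sd = 0,
                     true_annot = list(no_assembly_prob = 0, polygc_prob = 0,
                                       inexact_hom_mean = 0,
                                       microhom_mean = 0),
                     false_annot = list(nfrag_lambda = 2,
                                        no_assembly_prob = 0))
  bps2 <- emulate_caller(truth, g, 30, istats300, nm2, seed = 26)
  instances <- list(
    list(bps = bps1, truth = truth, coverage = covt,
         insert_stats = istats300, sim = 1, ploidy = "haploid"),
    list(bps = bps2, truth = truth, coverage = covt,
         insert_stats = istats300, sim = 2, ploidy = "haploid"))
  winners <- lapply(instances, function(i)
    optimize_for_simulation(i$bps, i$truth, i$coverage, i$insert_stats,
                            filter_grid()))
  fin <- select_final_parameters(winners, instances)
  # the winner's min F must dominate both the default and the
  # unconservative extreme re-scored on the same instances
  rescore <- function(p) min(vapply(instances, function(i) {
    a <- compare_sv_sets(call_svs(i$bps, p, i$coverage, i$insert_stats)$svs,
                         i$truth)
    min(a$fvalue[a$type != "integrated"])
  }, 1))
  expect_gte(min(tapply(fin$report$fvalue, fin$report$sim, min)),
             rescore(filter_params()) - 1e-9)
  expect_gte(min(fin$report$fvalue), rescore(unconservative_filter_params()))
  expect_equal(nrow(fin$report), 2 * 5)
})

test_that("the fitted parameters dominate the defaults on every training
           instance and the fit is reproducible", {
  g <- make_genome(c(chr1 = 50000, chr2 = 40000, chr3 = 40000), seed = 55)
  fit <- suppressWarnings(
    optimize_sv_filters(g, nsimulations = 2, ploidies = "haploid",
                        nvars = 5, coverage = 30, seed = 7))
  expect_s3_class(fit, "sv_filter_fit")
  expect_equal(nrow(fit$report), 2 * 5)
  # per-instance, per-type argmax dominates the default parameter set
  for (k in seq_along(fit$instances)) {
    inst <- fit$instances[[k]]
    def <- compare_sv_sets(
      call_svs(inst$bps, filter_params(), inst$coverage,
               inst$insert_stats)$svs, inst$truth)
    for (t in svtune:::SV_TYPES) {
      expect_gte(fit$winners[[k]]$per_type[[t]]$fvalue,
                 def$fvalue[def$type == t])
    }
  }
  fit2 <- suppressWarnings(
    optimize_sv_filters(g, nsimulations = 2, ploidies = "haploid",
                        nvars = 5, coverage = 30, seed = 7))
  expect_identical(fit$final_params, fit2$final_params)
  expect_identical(fit$report, fit2$report)
  # coef returns the final parameter object; predict applies it
  expect_identical(coef(fit), fit$final_params)
  inst <- fit$instances[[1]]
  pred <- predict(fit, inst$bps, inst$coverage, inst$insert_stats)
  expect_s3_class(pred, "sv_calls")
})

test_that("a planted fragment-count rule is recovered by the grid search", {
  g <- make_genome(c(chr1 = 40000, chr2 = 30000), seed = 56)
  for (seed in 1:3) {
    truth <- suppressWarnings(simulate_svs(g, n = 4, seed = seed))
    covt <- simulate_coverage(g, truth, "haploid", noise_sd = 0)
    nm <- noise_model(
      detection_prob = 1, fp_rate_per_mb = 200, jitter_sd = 0,
      true_annot = list(nfrag_per_cov = 1, no_assembly_prob = 0.3,
                        inexact_hom_mean = 30, microhom_mean = 30),
      false_annot = list(nfrag_lambda = 3, no_assembly_prob = 0.3,
                         inexact_hom_mean = 30, microhom_mean = 30,
                         vaf_shape1 = 5, vaf_shape2 = 5))
    bps <- emulate_caller(truth, g, 30, istats300, nm, "haploid", seed)
    opt <- optimize_for_simulation(bps, truth, covt, istats300,
                                   filter_grid())
    f <- vapply(opt$per_type, `[[`, 1, "fvalue")
    expect_gte(min(f[c("deletion", "inversion", "tandem_duplication")]),
               0.95)
    nf <- opt$per_type$deletion$params$min_Nfragments
    expect_gt(nf, 0)
    expect_lte(nf, 30)
  }
})
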