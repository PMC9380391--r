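## Parameter-grid construction, outcome-equivalence pruning, per-simulation
## grid search maximizing the F-value, cross-simulation final selection, and
## the top-level fitting function with its S3 methods.

#' Candidate-value grids for the filter parameters
#'
#' Each parameter gets an ordered list of candidate values, most permissive
#' first; every list contains the unconservative extreme and the default.
#' Presets control list sizes (`small` is the default and enumerates on the
#' order of 10^3-10^4 combinations after pruning; `medium` and `large` add
#' values and are intended to be used with pruning on real catalogs).
#'
#' @param preset One of `"small"`, `"medium"`, `"large"`.
#' @return A named list of candidate-value lists, class `sv_filter_grid`.
#' @export
filter_grid <- function(preset = c("small", "medium", "large")) {
  preset <- match.arg(preset)
  g <- list(
    min_Nfragments = c(0, 5, 10, 15),
    min_af = c(0, 0.25),
    min_af_EitherSmallOrLargeEvent = c(0, 0.25),
    min_QUAL = c(0, 500),
    max_to_be_considered_small_event = 1000,
    min_length_inversions = c(0, 40),
    maximum_lenght_inexactHomology = c(.INERT_HI, 50),
    maximum_microhomology = c(.INERT_HI, 50),
    maximum_strand_bias = c(1, 0.99),
    filter_noReadPairs = FALSE,
    filter_noSplitReads = FALSE,
    filter_overlappingRepeats = c(FALSE, TRUE),
    filter_polyGC = c(FALSE, TRUE),
    wrong_FILTERtags = list(character(0), "NO_ASSEMBLY"),
    range_filt_DEL_breakpoints = list(c(.INERT_LO, .INERT_LO), c(0, 1)),
    dif_between_insert_and_del = c(.INERT_LO, 5),
    max_rel_coverage_to_consider_del = c(.INERT_HI, 1, 0.6, 0.1),
    min_rel_coverage_to_consider_dup = c(0, 1.5, 1.8))
  if (preset %in% c("medium", "large")) {
    g$min_Nfragments <- c(0, 2, 5, 8, 10, 15, 20, 30)
    g$min_af <- c(0, 0.05, 0.1, 0.25, 0.5)
    g$min_af_EitherSmallOrLargeEvent <- c(0, 0.1, 0.25)
    g$min_QUAL <- c(0, 100, 500, 1000)
    g$maximum_lenght_inexactHomology <- c(.INERT_HI, 50, 20)
    g$maximum_microhomology <- c(.INERT_HI, 50, 10)
    g$maximum_strand_bias <- c(1, 0.99, 0.95)
    g$filter_noReadPairs <- c(FALSE, TRUE)
    g$filter_noSplitReads <- c(FALSE, TRUE)
    g$range_filt_DEL_breakpoints <- list(c(.INERT_LO, .INERT_LO), c(0, 1),
                                         c(200, 700), c(500, 1000))
    g$dif_between_insert_and_del <- c(.INERT_LO, 0, 5, 10)
    g$max_rel_coverage_to_consider_del <- c(.INERT_HI, 1, 0.8, 0.6, 0.4,
                                            0.25, 0.1)
    g$min_rel_coverage_to_consider_dup <- c(0, 1.1, 1.2, 1.4, 1.5, 1.8, 2)
  }
  if (preset == "large") {
    g$min_Nfragments <- c(0:10, 12, 15, 20, 25, 30, 40)
    g$min_af <- seq(0, 0.5, by = 0.05)
    g$min_QUAL <- c(0, 25, 50, 100, 200, 300, 500, 750, 1000)
    g$max_to_be_considered_small_event <- c(1000, 500, 1500)
  }
  ## columns as lists so heterogeneous values (ranges, tag sets) are uniform
  g <- lapply(g, function(v) if (is.list(v)) v else as.list(v))
  structure(g, class = "sv_filter_grid", preset = preset)
}

#' Number of parameter combinations in a grid
#' @param grid An `sv_filter_grid`.
#' @return A double (grids can exceed integer range).
#' @export
grid_size <- function(grid) prod(vapply(grid, length, 1L))

#' @export
print.sv_filter_grid <- function(x, ...) {
  cat("Filter grid (preset ", attr(x, "preset") %||% "?", "): ",
      format(grid_size(x), big.mark = ","), " combinations\n", sep = "")
  for (nm in names(x)) cat(sprintf("  %-34s %d values\n", nm, length(x[[nm]])))
  invisible(x)
}

.COVERAGE_PARAMS <- c("max_rel_coverage_to_consider_del",
                      "min_rel_coverage_to_consider_dup")

## coverage values that any classification / copy-cut decision compares
## against a threshold on this catalog
.decision_coverages <- function(bps, coverage) {
  covs <- .spanned_coverage(bps, coverage)
  rem <- bps[!(bps$type_hint %in% c("DEL-like", "TAN-like")), , drop = FALSE]
  org <- c()
  n <- nrow(rem)
  if (n >= 2) {
    ends <- function(i, flip = FALSE) {
      idx <- if (flip) c(2L, 1L) else c(1L, 2L)
      list(chrom = c(rem$chrom_1[i], rem$chrom_2[i])[idx],
           pos = c(rem$pos_1[i], rem$pos_2[i])[idx],
           orient = c(rem$orient_1[i], rem$orient_2[i])[idx])
    }
    for (i in 1:(n - 1)) for (j in (i + 1):n) for (flip in c(FALSE, TRUE)) {
      cand <- .eval_junction_pair(ends(i), ends(j, flip), 1000, 40)
      if (!is.null(cand) && cand$kind == "insertion") {
        cv <- tryCatch(coverage_of_interval(coverage, cand$chrom_origin,
                                            cand$start, cand$end),
                       error = function(e) NA_real_)
        org <- c(org, cv)
        break
      }
    }
  }
  c(covs[!is.na(covs)], org[!is.na(org)])
}

#' Prune grid values that cannot change filtering outcomes
#'
#' For each breakend-level parameter, a candidate value is kept only when
#' toggling it alone (all other parameters at their unconservative extremes)
#' changes which breakpoints pass on the given catalog; candidates with
#' identical single-toggle outcomes collapse onto the most permissive of
#' them, and the unconservative extreme is always retained. Coverage
#' thresholds collapse when they order identically against every relative
#' coverage the classification and copy/cut decisions inspect.
#'
#' @param grid An [filter_grid()].
#' @param bps The breakpoint catalog to prune against.
#' @param insert_stats Insert-size stats used by size-dependent rules.
#' @param coverage Coverage table (needed to prune the coverage thresholds;
#'   when `NULL` they are kept as-is).
#' @return The pruned `sv_filter_grid`.
#' @export
prune_grid <- function(grid, bps, insert_stats = NULL, coverage = NULL) {
  un <- unconservative_filter_params()
  out <- grid
  ms_values <- grid$max_to_be_considered_small_event
  for (pname in names(grid)) {
    vals <- grid[[pname]]
    if (length(vals) <= 1) next
    if (pname %in% .COVERAGE_PARAMS) {
      if (is.null(coverage)) next
      C <- .decision_coverages(bps, coverage)
      sig <- vapply(vals, function(v)
        paste(c(C < v, C <= v), collapse = ""), "")
    } else if (pname == "max_to_be_considered_small_event") {
      ## smallness only matters through the size-dependent rules; a value is
      ## kept if any such rule, at any of its candidate values, responds to it
      dep <- c("maximum_lenght_inexactHomology", "maximum_strand_bias",
               "filter_noReadPairs", "filter_noSplitReads",
               "dif_between_insert_and_del")
      sig <- vapply(vals, function(ms) {
        base <- un
        base$max_to_be_considered_small_event <- ms
        masks <- unlist(lapply(dep, function(d)
          lapply(grid[[d]], function(v)
            .bp_rule_reject(bps, d, v, base, insert_stats))))
        paste(as.integer(masks), collapse = "")
      }, "")
    } else {
      sig <- vapply(vals, function(v) {
        masks <- vapply(ms_values, function(ms) {
          base <- un
          base$max_to_be_considered_small_event <- ms
          paste(as.integer(.bp_rule_reject(bps, pname, v, base,
                                           insert_stats)), collapse = "")
        }, "")
        paste(masks, collapse = "|")
      }, "")
    }
    keep <- !duplicated(sig)
    keep[1] <- TRUE
    out[[pname]] <- vals[keep]
  }
  attr(out, "preset") <- attr(grid, "preset")
  class(out) <- "sv_filter_grid"
  out
}

.params_from_indices <- function(grid, idx) {
  vals <- lapply(names(grid), function(nm) grid[[nm]][[idx[[nm]]]])
  names(vals) <- names(grid)
  do.call(filter_params, vals)
}

## score a call set against truth; returns the accuracy rows keyed by type
.score_calls <- function(svs, truth, cfg) {
  acc <- compare_sv_sets(svs, truth, cfg)
  setNames(acc$fvalue, acc$type)
}

#' Grid-search the filter parameters on one simulation
#'
#' Prunes the grid against the catalog, exhaustively enumerates the pruned
#' Cartesian product, scores every combination by running the full
#' classification pipeline against the known truth set, and returns the
#' argmax-F parameters per SV type. Ties keep the earliest combination in
#' enumeration order, which prefers more permissive values (candidate lists
#' are ordered permissive-first and earlier parameters vary fastest).
#'
#' @param bps Breakpoint catalog for this simulation.
#' @param truth The known [sv_set()] behind the catalog.
#' @param coverage `sv_coverage` table.
#' @param insert_stats A [compute_insert_stats()] result.
#' @param grid An [filter_grid()] (pruned internally).
#' @param cfg A [match_config()].
#' @param max_combinations Enumeration budget (default 200000); a pruned grid larger than
#'   this is an error suggesting a smaller preset.
#' @return List with `per_type` (per SV type: `params`, `precision`,
#'   `recall`, `fvalue`), `n_combinations`, and the pruned `grid`.
#' @export
optimize_for_simulation <- function(bps, truth, coverage, insert_stats,
                                    grid = filter_grid(),
                                    cfg = match_config(),
                                    max_combinations = 200000) {
  grid <- prune_grid(grid, bps, insert_stats, coverage)
  n_comb <- grid_size(grid)
  if (n_comb > max_combinations)
    stop("pruned grid has ", format(n_comb, big.mark = ","),
         " combinations (budget ", max_combinations,
         "); use a smaller grid preset")
  pnames <- names(grid)
  be_params <- setdiff(pnames, .COVERAGE_PARAMS)
  un <- unconservative_filter_params()

  ## per-(max_small, param, value) breakpoint reject masks
  ms_vals <- grid$max_to_be_considered_small_event
  masks <- lapply(seq_along(ms_vals), function(mi) {
    base <- un
    base$max_to_be_considered_small_event <- ms_vals[[mi]]
    m <- lapply(be_params, function(pn) {
      if (pn == "max_to_be_considered_small_event") return(NULL)
      lapply(grid[[pn]], function(v)
        .bp_rule_reject(bps, pn, v, base, insert_stats))
    })
    names(m) <- be_params
    m
  })

  covs_all <- .spanned_coverage(bps, coverage)

  ## stage 1: enumerate the breakend-filter combinations (coverage
  ## thresholds excluded) and collapse them onto distinct passing sets; the
  ## first combination reaching a passing set is remembered, which preserves
  ## the permissive-first tie-break
  be_idx <- do.call(expand.grid, c(lapply(grid[be_params], seq_along),
                                   list(KEEP.OUT.ATTRS = FALSE)))
  nonzero <- lapply(masks, function(mm) lapply(mm, function(vm)
    if (is.null(vm)) NULL else vapply(vm, any, TRUE)))
  groups <- new.env(parent = emptyenv())
  group_order <- character(0)
  n_bp <- nrow(bps)
  ms_be_col <- be_idx$max_to_be_considered_small_event
  for (r in seq_len(nrow(be_idx))) {
    mi <- ms_be_col[r]
    rej <- rep(FALSE, n_bp)
    for (pn in be_params) {
      if (pn == "max_to_be_considered_small_event") next
      vi <- be_idx[[pn]][r]
      if (vi > 1L || nonzero[[mi]][[pn]][1L])
        rej <- rej | masks[[mi]][[pn]][[vi]]
    }
    key <- paste0("k", paste(which(rej), collapse = ","))
    if (is.null(groups[[key]])) {
      groups[[key]] <- list(pass = !rej, row = r)
      group_order <- c(group_order, key)
    }
  }

  ## stage 2: score each distinct passing set under every coverage-threshold
  ## pair; enumeration order (filters fastest, then the deletion threshold,
  ## then the duplication threshold) defines the deterministic tie-break
  types <- SV_TYPES
  best <- setNames(vector("list", length(types)), types)
  for (t in types) best[[t]] <- list(f = -1)
  del_vals <- grid$max_rel_coverage_to_consider_del
  dup_vals <- grid$min_rel_coverage_to_consider_dup
  for (ui in seq_along(dup_vals)) for (di in seq_along(del_vals)) {
    pcov <- list(max_rel_coverage_to_consider_del = del_vals[[di]],
                 min_rel_coverage_to_consider_dup = dup_vals[[ui]])
    for (key in group_order) {
      gr <- groups[[key]]
      res <- .call_svs_core(bps[gr$pass, , drop = FALSE], covs_all[gr$pass],
                            pcov, coverage)
      f <- .score_calls(res$svs, truth, cfg)
      for (t in types) {
        if (f[[t]] > best[[t]]$f)
          best[[t]] <- list(f = f[[t]], row = gr$row, di = di, ui = ui)
      }
    }
  }

  per_type <- lapply(types, function(t) {
    b <- best[[t]]
    idx <- as.list(be_idx[b$row, , drop = FALSE])
    idx$max_rel_coverage_to_consider_del <- b$di
    idx$min_rel_coverage_to_consider_dup <- b$ui
    params <- .params_from_indices(grid, idx)
    acc <- compare_sv_sets(
      call_svs(bps, params, coverage, insert_stats)$svs, truth, cfg)
    row <- acc[acc$type == t, ]
    list(params = params, precision = row$precision, recall = row$recall,
         fvalue = row$fvalue)
  })
  names(per_type) <- types
  list(per_type = per_type, n_combinations = n_comb,
       n_distinct_filters = length(group_order), grid = grid)
}

#' Select final parameters across simulations
#'
#' The candidate pool is the union of every per-(simulation, ploidy, type)
#' winner plus the default parameter set. Each candidate is re-scored on
#' every (simulation, SV type) instance; the winner maximizes the minimum F
#' across instances, tie-broken by mean F, then by fewer active filters.
#'
#' @param winners List of per-simulation results from
#'   [optimize_for_simulation()].
#' @param instances List of simulation instances, each a list with `bps`,
#'   `truth`, `coverage`, `insert_stats`, `sim`, `ploidy`.
#' @param cfg A [match_config()].
#' @return List with `params` (the winner), `report` (data.frame of the
#'   winner's precision/recall/F per simulation, ploidy and type) and
#'   `candidate_scores`.
#' @export
select_final_parameters <- function(winners, instances, cfg = match_config()) {
  cands <- list(default = filter_params())
  for (w in winners) for (t in names(w$per_type)) {
    p <- w$per_type[[t]]$params
    key <- paste(vapply(p, function(v) paste(format(v, digits = 12),
                                             collapse = ","), ""),
                 collapse = ";")
    if (!key %in% names(cands)) cands[[key]] <- p
  }
  score_one <- function(params, inst) {
    calls <- call_svs(inst$bps, params, inst$coverage, inst$insert_stats)
    compare_sv_sets(calls$svs, inst$truth, cfg)
  }
  accs <- lapply(cands, function(p) lapply(instances, function(i)
    score_one(p, i)))
  ## only (instance, type) cells with at least one known record inform the
  ## selection; a type absent from a simulation carries no signal
  present <- unlist(lapply(instances, function(i)
    vapply(SV_TYPES, function(t) any(i$truth$type == t), TRUE)))
  fmat <- vapply(accs, function(per_inst)
    unlist(lapply(per_inst, function(a)
      a$fvalue[a$type != "integrated"])),
    numeric(length(instances) * length(SV_TYPES)))
  fmat <- fmat[present, , drop = FALSE]
  min_f <- apply(fmat, 2, min)
  mean_f <- apply(fmat, 2, mean)
  n_active <- vapply(cands, active_filter_count, 1L)
  ord <- order(-min_f, -mean_f, n_active)
  win <- ord[1]
  report <- do.call(rbind, lapply(seq_along(instances), function(k) {
    a <- accs[[win]][[k]]
    a <- a[a$type != "integrated", ]
    data.frame(sim = instances[[k]]$sim, ploidy = instances[[k]]$ploidy,
               type = a$type, n_known = vapply(a$type, function(t)
                 sum(instances[[k]]$truth$type == t), 1L),
               precision = a$precision, recall = a$recall,
               fvalue = a$fvalue)
  }))
  rownames(report) <- NULL
  list(params = cands[[win]], report = report,
       candidate_scores = data.frame(candidate = names(cands),
                                     min_f = min_f, mean_f = mean_f,
                                     n_active = n_active))
}

#' Fit sample-adaptive SV filter parameters on simulated genomes
#'
#' The top-level fitting function: simulates `nsimulations` template genomes
#' each carrying up to `nvars` SVs of each of five types, derives the
#' rearranged sequence, draws insert-size fragments, synthesizes the
#' coverage profile, emulates an annotated breakend caller at every
#' requested ploidy/zygosity, grid-searches the filter parameters per
#' simulation and SV type, and selects a final parameter set that works well
#' for all simulations (max-min F, then mean F, then fewest active filters).
#'
#' @param genome Named [Biostrings::DNAStringSet] or FASTA path.
#' @param nsimulations Number of template genomes (default 2, so the
#'   final selection can see between-simulation variability).
#' @param ploidies Character vector of ploidy specs; each simulation is
#'   emulated once per ploidy.
#' @param nvars Requested SV count per type and simulation.
#' @param regions Optional BEDPE data.frame constraining SV placement.
#' @param chromosomes Optional character vector restricting simulation to a
#'   subset of chromosomes.
#' @param grid An [filter_grid()] or preset name.
#' @param coverage Emulated sequencing depth.
#' @param read_params A [read_sim_params()] object (read length and insert
#'   distribution; its ploidy field is ignored in favor of `ploidies`).
#' @param noise An [noise_model()].
#' @param cov_noise_sd Multiplicative noise SD of the synthetic coverage.
#' @param cfg A [match_config()].
#' @param max_combinations Per-simulation enumeration budget.
#' @param seed Integer seed; fixed seed gives an identical fit.
#' @return An object of class `sv_filter_fit` with components
#'   `final_params`, `report`, `winners`, `instances`, `truths` and `call`.
#'   Methods: `print`, `summary`, `coef` (the final [filter_params()]),
#'   `plot` (F per instance and type), `predict` (apply the fitted
#'   parameters to a new catalog).
#' @export
optimize_sv_filters <- function(genome, nsimulations = 2,
                                ploidies = "haploid", nvars = 50,
                                regions = NULL, chromosomes = NULL,
                                grid = filter_grid("small"), coverage = 30,
                                read_params = read_sim_params(coverage = coverage),
                                noise = noise_model(), cov_noise_sd = 0.05,
                                cfg = match_config(),
                                max_combinations = 200000, seed = 1) {
  cl <- match.call()
  if (is.character(grid)) grid <- filter_grid(grid)
  if (is.character(genome)) genome <- read_fasta(genome)
  if (!is.null(chromosomes)) {
    missing_ch <- setdiff(chromosomes, names(genome))
    if (length(missing_ch)) stop("chromosome not in genome: ", missing_ch[1])
    genome <- genome[chromosomes]
  }
  instances <- list()
  winners <- list()
  truths <- list()
  for (s in seq_len(nsimulations)) {
    truth <- simulate_svs(genome, nvars, regions,
                          seed = derive_seed(seed, paste0("svs", s)))
    truths[[s]] <- truth
    for (pl in ploidies) {
      sfx <- paste0("s", s, "_", pl)
      set.seed(derive_seed(seed, paste0("frag", sfx)))
      frags <- round(rnorm(5000, read_params$insert_median,
                           read_params$insert_mad * 1.4826))
      istats <- compute_insert_stats(frags)
      covt <- simulate_coverage(genome, truth, pl, window = 100,
                                noise_sd = cov_noise_sd,
                                seed = derive_seed(seed, paste0("cov", sfx)))
      bps <- emulate_caller(truth, genome, coverage, istats, noise, pl,
                            seed = derive_seed(seed, paste0("emu", sfx)))
      opt <- optimize_for_simulation(bps, truth, covt, istats, grid, cfg,
                                     max_combinations)
      k <- length(instances) + 1L
      instances[[k]] <- list(bps = bps, truth = truth, coverage = covt,
                             insert_stats = istats, sim = s, ploidy = pl)
      winners[[k]] <- opt
    }
  }
  fin <- select_final_parameters(winners, instances, cfg)
  structure(list(final_params = fin$params, report = fin$report,
                 candidate_scores = fin$candidate_scores, winners = winners,
                 instances = instances, truths = truths, grid = grid,
                 cfg = cfg, seed = seed, call = cl),
            class = "sv_filter_fit")
}

#' @export
print.sv_filter_fit <- function(x, ...) {
  cat("Optimized SV filter parameters\n")
  cat("  simulations x ploidies:", length(x$instances), "instances\n")
  cat("  final F-value: min", round(min(x$report$fvalue), 3),
      "| mean", round(mean(x$report$fvalue), 3), "\n")
  cat("  active filters:", active_filter_count(x$final_params), "\n")
  invisible(x)
}

#' @export
summary.sv_filter_fit <- function(object, ...) {
  cat("Final parameters:\n")
  print(object$final_params)
  cat("\nAccuracy of the final parameters per simulation and SV type:\n")
  print(transform(object$report,
                  precision = round(precision, 3),
                  recall = round(recall, 3),
                  fvalue = round(fvalue, 3)))
  invisible(object$report)
}

#' @export
coef.sv_filter_fit <- function(object, ...) object$final_params

#' @export
plot.sv_filter_fit <- function(x, ...) {
  rep <- x$report
  types <- unique(rep$type)
  inst <- interaction(rep$sim, rep$ploidy, drop = TRUE)
  fm <- tapply(rep$fvalue, list(inst, rep$type), mean)
  graphics::matplot(seq_len(nrow(fm)), fm, type = "b", pch = 19, lty = 1,
                    ylim = c(0, 1), xaxt = "n",
                    xlab = "simulation instance", ylab = "F-value", ...)
  graphics::axis(1, at = seq_len(nrow(fm)), labels = rownames(fm))
  graphics::legend("bottomleft", legend = colnames(fm), col = seq_len(ncol(fm)),
                   pch = 19, cex = 0.8)
  invisible(fm)
}

#' @export
predict.sv_filter_fit <- function(object, bps, coverage = NULL,
                                  insert_stats = NULL, repeats = NULL, ...) {
  call_svs(bps, object$final_params, coverage, insert_stats, repeats)
}
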