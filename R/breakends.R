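## Breakend/breakpoint catalogs in the gridss dialect: construction, VCF 4.2
## BND round trip, a caller emulator driven by a truth set plus a noise
## model, insert-size statistics and synthetic coverage tables.
##
## A catalog is a data.frame (class "sv_breakpoints") with one row per
## breakpoint and two annotated breakends per row (suffix _1/_2). Breakend 1
## is the one with the lexicographically smaller (chrom, pos). Positions are
## 0-based boundary coordinates; orientation is the side on which the
## reference continues, encoded so that a deletion-geometry junction has
## "right" at the lower and "left" at the higher breakend.

BE_FIELDS <- c("qual", "nfrag", "vaf_small", "vaf_large", "inexact_hom",
               "microhom", "strand_bias", "has_rp", "has_sr", "ins_seq",
               "tags", "repeat_ovl")

.be_defaults <- list(qual = 1000, nfrag = NA_integer_, vaf_small = 1,
                     vaf_large = 1, inexact_hom = 0, microhom = 0,
                     strand_bias = 0.5, has_rp = TRUE, has_sr = TRUE,
                     ins_seq = "", tags = "", repeat_ovl = FALSE)

#' Construct a breakpoint catalog
#'
#' Completes a data.frame of paired breakends into an `sv_breakpoints`
#' catalog: missing annotation columns are filled with documented defaults
#' (`qual` 1000, `vaf_*` 1, homology lengths 0, `strand_bias` 0.5, both
#' support flags `TRUE`, empty inserted sequence and FILTER tags, no repeat
#' overlap; `nfrag` defaults to `NA` and the fragment-count filter refuses to
#' run on it), breakends are put in canonical order, and the derived
#' breakpoint columns (`same_chrom`, `length`, `type_hint`) are recomputed.
#'
#' @param df data.frame with at least `chrom_1, pos_1, orient_1, chrom_2,
#'   pos_2, orient_2`; per-breakend annotations use the `_1`/`_2` suffixes
#'   (`qual, nfrag, vaf_small, vaf_large, inexact_hom, microhom, strand_bias,
#'   has_rp, has_sr, ins_seq, tags, repeat_ovl`); `tags` is a comma-joined
#'   FILTER tag string.
#' @return The completed data.frame with class `sv_breakpoints`.
#' @export
sv_breakpoints <- function(df = NULL) {
  base <- c("chrom_1", "pos_1", "orient_1", "chrom_2", "pos_2", "orient_2")
  if (is.null(df) || nrow(df) == 0) {
    df <- data.frame(bp_id = character(), chrom_1 = character(),
                     pos_1 = integer(), orient_1 = character(),
                     chrom_2 = character(), pos_2 = integer(),
                     orient_2 = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(base %in% names(df)) || nrow(df) == 0)
  if (!"bp_id" %in% names(df)) df$bp_id <- sprintf("bp_%d", seq_len(nrow(df)))
  if (!"sv_id" %in% names(df)) df$sv_id <- rep(NA_character_, nrow(df))
  for (f in BE_FIELDS) for (s in c("_1", "_2")) {
    cl <- paste0(f, s)
    if (!cl %in% names(df)) df[[cl]] <- rep(.be_defaults[[f]], nrow(df))
  }
  if (nrow(df)) {
    stopifnot(all(df$orient_1 %in% c("left", "right")),
              all(df$orient_2 %in% c("left", "right")))
    ## canonical breakend order
    swap <- df$chrom_2 < df$chrom_1 |
      (df$chrom_2 == df$chrom_1 & df$pos_2 < df$pos_1)
    if (any(swap)) {
      for (f in c("chrom", "pos", "orient", BE_FIELDS)) {
        a <- paste0(f, "_1"); b <- paste0(f, "_2")
        tmp <- df[[a]][swap]
        df[[a]][swap] <- df[[b]][swap]
        df[[b]][swap] <- tmp
      }
    }
  }
  df$same_chrom <- df$chrom_1 == df$chrom_2
  df$length <- ifelse(df$same_chrom, abs(df$pos_2 - df$pos_1), NA_integer_)
  df$type_hint <- type_breakpoint(df)
  rownames(df) <- NULL
  class(df) <- c("sv_breakpoints", "data.frame")
  df
}

#' @export
print.sv_breakpoints <- function(x, ...) {
  cat("Breakpoint catalog:", nrow(x), "breakpoints")
  if (nrow(x))
    cat(" (", paste(names(table(x$type_hint)), table(x$type_hint),
                    sep = ":", collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Derive the defining breakpoints of a truth set
#'
#' Each SV contributes its minimal junction set: one DEL-like junction per
#' deletion, one TAN-like per tandem duplication, two same-orientation
#' junctions per inversion, two balanced junctions per translocation, and the
#' two destination junctions per insertion.
#'
#' @param truth An [sv_set()].
#' @return An [sv_breakpoints()] catalog without caller annotations (`sv_id`
#'   links each junction to its source record).
#' @export
truth_breakpoints <- function(truth) {
  rows <- list()
  jx <- function(sv_id, c1, p1, o1, c2, p2, o2)
    data.frame(sv_id = sv_id, chrom_1 = c1, pos_1 = as.integer(p1),
               orient_1 = o1, chrom_2 = c2, pos_2 = as.integer(p2),
               orient_2 = o2, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    rows[[length(rows) + 1L]] <- switch(r$type,
      deletion = jx(r$id, r$chrom, r$start, "right", r$chrom, r$end, "left"),
      tandem_duplication = jx(r$id, r$chrom, r$start, "left",
                              r$chrom, r$end, "right"),
      inversion = rbind(
        jx(r$id, r$chrom, r$start, "right", r$chrom, r$end, "right"),
        jx(r$id, r$chrom, r$start, "left", r$chrom, r$end, "left")),
      translocation = if (isTRUE(r$inverted)) rbind(
        jx(r$id, r$chrom, r$start, "right", r$chrom2, r$start2, "right"),
        jx(r$id, r$chrom, r$start, "left", r$chrom2, r$start2, "left"))
      else rbind(
        jx(r$id, r$chrom, r$start, "right", r$chrom2, r$start2, "left"),
        jx(r$id, r$chrom, r$start, "left", r$chrom2, r$start2, "right")),
      insertion = rbind(
        jx(r$id, r$chrom2, r$start2, "right", r$chrom, r$start, "left"),
        jx(r$id, r$chrom, r$end, "right", r$chrom2, r$start2, "left")))
  }
  df <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(df)) df$bp_id <- sprintf("tbp_%d", seq_len(nrow(df)))
  sv_breakpoints(df)
}

## ---- insert-size statistics ------------------------------------------------

#' Median and (unscaled) MAD of fragment lengths
#'
#' The MAD is the raw median absolute deviation from the median, without the
#' 1.4826 consistency factor: the small/large-event VAF switch uses
#' `median + MAD` as its length threshold.
#'
#' @param fragments Numeric vector of fragment (insert) lengths.
#' @return List of class `insert_stats` with `median` and `mad`.
#' @export
compute_insert_stats <- function(fragments) {
  if (length(fragments) == 0) stop("no fragment lengths supplied")
  med <- median(fragments)
  structure(list(median = med, mad = median(abs(fragments - med))),
            class = "insert_stats")
}

#' @export
print.insert_stats <- function(x, ...) {
  cat("Insert size: median", x$median, "MAD", x$mad, "\n")
  invisible(x)
}

## ---- noise model + emulator ------------------------------------------------

#' Noise model for the breakend-caller emulator
#'
#' The emulator stands in for a short-read breakend caller so the whole
#' optimization loop runs in-process. True junctions from the truth set are
#' detected with probability `detection_prob` and jittered by a normal
#' positional error; false junctions are added at `fp_rate_per_mb` per
#' megabase. Per-breakend annotations (qual, supporting fragments, VAFs,
#' homology lengths, strand bias, FILTER tags, support flags, inserted
#' sequence) are drawn from separate distributions for true and false
#' breakends, creating a separable but imperfect filtering problem.
#'
#' @param detection_prob Probability that a true junction is reported.
#' @param fp_rate_per_mb Expected false junctions per Mb of genome.
#' @param jitter_sd SD (bp) of the positional error on reported breakends.
#' @param true_annot,false_annot Named lists overriding individual annotation
#'   settings (see defaults in the function definition): `qual_meanlog`,
#'   `qual_sdlog`, `nfrag_per_cov` / `nfrag_lambda`, `vaf_sd` /
#'   `vaf_shape1`+`vaf_shape2`, `inexact_hom_mean`, `microhom_mean`,
#'   `strand_bias_shape`, `no_assembly_prob`, `rp_prob`, `sr_prob`,
#'   `polygc_prob`, `ins_prob`, `ins_maxlen`.
#' @return A list of class `emulator_noise`.
#' @export
noise_model <- function(detection_prob = 0.9, fp_rate_per_mb = 20,
                        jitter_sd = 3, true_annot = list(),
                        false_annot = list()) {
  stopifnot(detection_prob >= 0, detection_prob <= 1,
            fp_rate_per_mb >= 0, jitter_sd >= 0)
  tr <- list(qual_meanlog = log(1000), qual_sdlog = 0.3, nfrag_per_cov = 0.5,
             vaf_sd = 0.05, inexact_hom_mean = 5, microhom_mean = 3,
             strand_bias_shape = 20, no_assembly_prob = 0.1, rp_prob = 0.95,
             sr_prob = 0.95, polygc_prob = 0.02, ins_prob = 0.2,
             ins_maxlen = 8)
  fa <- list(qual_meanlog = log(60), qual_sdlog = 0.6, nfrag_lambda = 2,
             vaf_shape1 = 1, vaf_shape2 = 8, inexact_hom_mean = 30,
             microhom_mean = 20, strand_bias_shape = 0.7,
             no_assembly_prob = 0.6, rp_prob = 0.5, sr_prob = 0.5,
             polygc_prob = 0.15, ins_prob = 0.4, ins_maxlen = 30)
  tr[names(true_annot)] <- true_annot
  fa[names(false_annot)] <- false_annot
  structure(list(detection_prob = detection_prob,
                 fp_rate_per_mb = fp_rate_per_mb, jitter_sd = jitter_sd,
                 true_annot = tr, false_annot = fa),
            class = "emulator_noise")
}

#' @rdname noise_model
#' @details `noiseless_noise_model()` is the exactly-invertible limit:
#'   detection probability 1, no false junctions, no jitter, and clean
#'   annotations that carry no rejection evidence.
#' @export
noiseless_noise_model <- function() {
  noise_model(detection_prob = 1, fp_rate_per_mb = 0, jitter_sd = 0,
              true_annot = list(qual_sdlog = 0, vaf_sd = 0,
                                inexact_hom_mean = 0, microhom_mean = 0,
                                strand_bias_shape = 1e6, no_assembly_prob = 0,
                                rp_prob = 1, sr_prob = 1, polygc_prob = 0,
                                ins_prob = 0))
}

#' @rdname noise_model
#' @param path YAML file whose top-level keys are `noise_model` arguments.
#' @export
noise_model_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read noise-model configs")
  do.call(noise_model, yaml::read_yaml(path))
}

.draw_annotations <- function(n, ann, coverage, vaf_expected, true_side) {
  if (n == 0) return(NULL)
  gc_run <- function() strrep(sample(c("G", "C"), 1), sample(16:30, 1))
  rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")
  ins <- character(n)
  pg <- runif(n) < ann$polygc_prob
  ins[pg] <- vapply(which(pg), function(i) gc_run(), "")
  other <- !pg & runif(n) < ann$ins_prob
  ins[other] <- vapply(which(other), function(i)
    rand_seq(sample.int(max(1, ann$ins_maxlen), 1)), "")
  if (true_side) {
    nfrag <- rpois(n, pmax(1, coverage * vaf_expected * ann$nfrag_per_cov)) + 1L
    vaf <- pmin(1, pmax(0.01, rnorm(n, vaf_expected, ann$vaf_sd)))
  } else {
    nfrag <- rpois(n, ann$nfrag_lambda)
    vaf <- rbeta(n, ann$vaf_shape1, ann$vaf_shape2)
  }
  data.frame(
    qual = rlnorm(n, ann$qual_meanlog, ann$qual_sdlog),
    nfrag = nfrag,
    vaf_small = vaf,
    vaf_large = pmin(1, pmax(0, vaf + rnorm(n, 0, 0.02))),
    inexact_hom = rpois(n, ann$inexact_hom_mean),
    microhom = rpois(n, ann$microhom_mean),
    strand_bias = rbeta(n, ann$strand_bias_shape, ann$strand_bias_shape),
    has_rp = runif(n) < ann$rp_prob,
    has_sr = runif(n) < ann$sr_prob,
    ins_seq = ins,
    tags = ifelse(runif(n) < ann$no_assembly_prob, "NO_ASSEMBLY", ""),
    repeat_ovl = FALSE,
    stringsAsFactors = FALSE)
}

#' Emulate an annotated breakend caller on a truth set
#'
#' @param truth An [sv_set()] truth set.
#' @param genome_lengths Named chromosome lengths (or a DNAStringSet).
#' @param coverage Sequencing depth the emulated caller saw.
#' @param insert_stats An [compute_insert_stats()] result (carried through to
#'   filtering; not used for drawing).
#' @param noise An [noise_model()].
#' @param ploidy Ploidy spec; sets the expected VAF of true breakends.
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @return An [sv_breakpoints()] catalog; truth-derived rows carry their
#'   source `sv_id`, false rows have `sv_id = NA`.
#' @export
emulate_caller <- function(truth, genome_lengths, coverage = 30,
                           insert_stats = NULL, noise = noise_model(),
                           ploidy = "haploid", seed = 1) {
  if (methods::is(genome_lengths, "DNAStringSet"))
    genome_lengths <- setNames(Biostrings::width(genome_lengths),
                               names(genome_lengths))
  set.seed(derive_seed(seed, "emulate_caller"))
  vf <- ploidy_variant_fraction(ploidy)
  tb <- truth_breakpoints(truth)
  detected <- runif(nrow(tb)) < noise$detection_prob
  tb <- tb[detected, , drop = FALSE]

  jit <- function(pos, chrom) {
    if (noise$jitter_sd == 0 || length(pos) == 0) return(pos)
    p <- pos + as.integer(round(rnorm(length(pos), 0, noise$jitter_sd)))
    pmax(1L, pmin(p, as.integer(genome_lengths[chrom]) - 1L))
  }
  tb$pos_1 <- jit(tb$pos_1, tb$chrom_1)
  tb$pos_2 <- jit(tb$pos_2, tb$chrom_2)

  n_fp <- rpois(1, noise$fp_rate_per_mb * sum(genome_lengths) / 1e6)
  fp <- NULL
  if (n_fp > 0) {
    chroms <- names(genome_lengths)
    c1 <- sample(chroms, n_fp, replace = TRUE, prob = genome_lengths)
    intra <- runif(n_fp) < 0.7 & genome_lengths[c1] > 6000
    p1 <- vapply(c1, function(ch)
      sample.int(genome_lengths[[ch]] - 1L, 1), 1L)
    c2 <- ifelse(intra, c1, sample(chroms, n_fp, replace = TRUE,
                                   prob = genome_lengths))
    p2 <- integer(n_fp)
    p2[intra] <- pmin(genome_lengths[c1[intra]] - 1L,
                      p1[intra] + sample(50:5000, sum(intra), replace = TRUE))
    if (any(!intra))
      p2[!intra] <- vapply(c2[!intra], function(ch)
        sample.int(genome_lengths[[ch]] - 1L, 1), 1L)
    fp <- data.frame(sv_id = NA_character_, chrom_1 = c1, pos_1 = p1,
                     orient_1 = sample(c("left", "right"), n_fp, TRUE),
                     chrom_2 = c2, pos_2 = p2,
                     orient_2 = sample(c("left", "right"), n_fp, TRUE),
                     stringsAsFactors = FALSE)
  }

  ann_t1 <- .draw_annotations(nrow(tb), noise$true_annot, coverage, vf, TRUE)
  ann_t2 <- .draw_annotations(nrow(tb), noise$true_annot, coverage, vf, TRUE)
  ann_f1 <- .draw_annotations(if (is.null(fp)) 0 else nrow(fp),
                              noise$false_annot, coverage, vf, FALSE)
  ann_f2 <- .draw_annotations(if (is.null(fp)) 0 else nrow(fp),
                              noise$false_annot, coverage, vf, FALSE)
  bind_side <- function(core, a1, a2) {
    if (is.null(a1)) return(NULL)
    names(a1) <- paste0(names(a1), "_1")
    names(a2) <- paste0(names(a2), "_2")
    cbind(core, a1, a2)
  }
  parts <- list(bind_side(tb[, c("sv_id", "chrom_1", "pos_1", "orient_1",
                                 "chrom_2", "pos_2", "orient_2")],
                          ann_t1, ann_t2),
                bind_side(fp, ann_f1, ann_f2))
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts)) return(sv_breakpoints())
  df <- do.call(rbind, parts)
  df$bp_id <- sprintf("bp_%d", seq_len(nrow(df)))
  out <- sv_breakpoints(df)
  attr(out, "insert_stats") <- insert_stats
  out
}

## ---- synthetic coverage ----------------------------------------------------

#' Synthesize a relative-coverage table implied by a truth set
#'
#' Windows the genome and sets each window's relative coverage to the local
#' expected copy number under the given ploidy: deletions subtract, tandem
#' duplications and copy-insert origins add, cut-insert origins subtract (the
#' emulator treats the moved copy's depth as assigned to its new locus), all
#' scaled by the variant-fragment fraction, with optional multiplicative
#' log-normal noise. The genome-wide median is normalized to 1.
#'
#' @param genome_lengths Named chromosome lengths (or a DNAStringSet).
#' @param truth An [sv_set()].
#' @param ploidy Ploidy spec string.
#' @param window Window size (bp).
#' @param noise_sd SD of log-normal multiplicative noise (0 = exact).
#' @param seed Integer seed.
#' @return Data.frame of class `sv_coverage` with `chrom, start, end,
#'   rel_coverage`.
#' @export
simulate_coverage <- function(genome_lengths, truth, ploidy = "haploid",
                              window = 100, noise_sd = 0, seed = 1) {
  if (methods::is(genome_lengths, "DNAStringSet"))
    genome_lengths <- setNames(Biostrings::width(genome_lengths),
                               names(genome_lengths))
  set.seed(derive_seed(seed, "simulate_coverage"))
  vf <- ploidy_variant_fraction(ploidy)
  wins <- do.call(rbind, lapply(names(genome_lengths), function(ch) {
    s <- seq(0L, max(0L, genome_lengths[[ch]] - 1L), by = window)
    data.frame(chrom = ch, start = s,
               end = pmin(s + window, genome_lengths[[ch]]))
  }))
  delta <- rep(0, nrow(wins))
  add <- function(chrom, s, e, d) {
    i <- wins$chrom == chrom & wins$start < e & wins$end > s
    if (!any(i)) return()
    ov <- (pmin(wins$end[i], e) - pmax(wins$start[i], s)) /
      (wins$end[i] - wins$start[i])
    delta[i] <<- delta[i] + d * ov
  }
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    if (r$type == "deletion") add(r$chrom, r$start, r$end, -1)
    if (r$type == "tandem_duplication") add(r$chrom, r$start, r$end, +1)
    if (r$type == "insertion")
      add(r$chrom, r$start, r$end, if (isTRUE(r$copy)) +1 else -1)
  }
  rel <- pmax(0, 1 + vf * delta)
  if (noise_sd > 0) rel <- rel * exp(rnorm(length(rel), 0, noise_sd))
  med <- median(rel)
  if (med > 0) rel <- rel / med
  wins$rel_coverage <- rel
  class(wins) <- c("sv_coverage", "data.frame")
  wins
}

#' Relative coverage of an interval from a coverage table
#'
#' Length-weighted mean over the windows overlapping the interval.
#'
#' @param coverage An `sv_coverage` data.frame.
#' @param chrom,start,end Interval (0-based half-open).
#' @return Numeric relative coverage.
#' @export
coverage_of_interval <- function(coverage, chrom, start, end) {
  i <- coverage$chrom == chrom & coverage$start < end & coverage$end > start
  if (!any(i)) stop("no coverage windows for ", chrom, ":", start, "-", end)
  w <- pmin(coverage$end[i], end) - pmax(coverage$start[i], start)
  sum(coverage$rel_coverage[i] * w) / sum(w)
}

## ---- VCF 4.2 BND round trip ------------------------------------------------

.vcf_pos <- function(pos, orient) ifelse(orient == "right", pos, pos + 1L)

.vcf_alt <- function(this_orient, partner_orient, partner_chrom, partner_pos,
                     ref_base, ins_seq) {
  t <- paste0(ref_base, ifelse(is.na(ins_seq), "", ins_seq))
  br <- ifelse(partner_orient == "left",
               paste0("[", partner_chrom, ":", partner_pos, "["),
               paste0("]", partner_chrom, ":", partner_pos, "]"))
  ifelse(this_orient == "right", paste0(t, br), paste0(br, t))
}

#' Write a breakpoint catalog as a VCF 4.2 breakend (BND) file
#'
#' Each breakpoint becomes two paired BND records linked by `MATEID`. QUAL
#' goes to the QUAL column, FILTER tags to the FILTER column (`PASS` when
#' empty), all other annotations to typed INFO keys (`FRAGS, VAF_SMALL,
#' VAF_LARGE, IHOMLEN, HOMLEN, SB, RP, SR, REPEAT`); the inserted sequence is
#' carried inside the ALT allele. POS is 1-based.
#'
#' @param bps An [sv_breakpoints()] catalog.
#' @param path Output path.
#' @param chrom_lengths Optional named lengths for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_breakend_vcf <- function(bps, path, chrom_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
    "##source=svtune",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=MATEID,Number=1,Type=String,Description="ID of mate breakend">',
    '##INFO=<ID=FRAGS,Number=1,Type=Integer,Description="Supporting fragments">',
    '##INFO=<ID=VAF_SMALL,Number=1,Type=Float,Description="VAF assuming a small event">',
    '##INFO=<ID=VAF_LARGE,Number=1,Type=Float,Description="VAF assuming a large event">',
    '##INFO=<ID=IHOMLEN,Number=1,Type=Integer,Description="Inexact homology length">',
    '##INFO=<ID=HOMLEN,Number=1,Type=Integer,Description="Microhomology length">',
    '##INFO=<ID=SB,Number=1,Type=Float,Description="Strand bias">',
    '##INFO=<ID=RP,Number=1,Type=Integer,Description="Has read-pair support">',
    '##INFO=<ID=SR,Number=1,Type=Integer,Description="Has split-read support">',
    '##INFO=<ID=REPEAT,Number=1,Type=Integer,Description="Overlaps a repeat">',
    '##FILTER=<ID=NO_ASSEMBLY,Description="No assembly support">')
  if (!is.null(chrom_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_lengths), chrom_lengths))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", sep = "\t"))
  lines <- character(0)
  for (i in seq_len(nrow(bps))) {
    r <- bps[i, ]
    ids <- paste0(r$bp_id, c("_1", "_2"))
    for (side in 1:2) {
      o <- r[[paste0("orient_", side)]]
      po <- r[[paste0("orient_", 3 - side)]]
      pos <- .vcf_pos(r[[paste0("pos_", side)]], o)
      ppos <- .vcf_pos(r[[paste0("pos_", 3 - side)]], po)
      alt <- .vcf_alt(o, po, r[[paste0("chrom_", 3 - side)]], ppos, "N",
                      r[[paste0("ins_seq_", side)]])
      tags <- r[[paste0("tags_", side)]]
      filt <- if (is.na(tags) || tags == "") "PASS" else gsub(",", ";", tags)
      info <- sprintf(
        "SVTYPE=BND;MATEID=%s;FRAGS=%s;VAF_SMALL=%.6g;VAF_LARGE=%.6g;IHOMLEN=%d;HOMLEN=%d;SB=%.6g;RP=%d;SR=%d;REPEAT=%d",
        ids[3 - side], r[[paste0("nfrag_", side)]],
        r[[paste0("vaf_small_", side)]], r[[paste0("vaf_large_", side)]],
        as.integer(r[[paste0("inexact_hom_", side)]]),
        as.integer(r[[paste0("microhom_", side)]]),
        r[[paste0("strand_bias_", side)]],
        as.integer(r[[paste0("has_rp_", side)]]),
        as.integer(r[[paste0("has_sr_", side)]]),
        as.integer(r[[paste0("repeat_ovl_", side)]]))
      lines <- c(lines, paste(r[[paste0("chrom_", side)]], pos, ids[side], "N",
                              alt, sprintf("%.6g", r[[paste0("qual_", side)]]),
                              filt, info, sep = "\t"))
    }
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

.parse_info <- function(info) {
  kv <- strsplit(strsplit(info, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else "", "")
  names(vals) <- vapply(kv, `[`, "", 1)
  vals
}

#' Parse a breakend (BND) VCF into a breakpoint catalog
#'
#' Decodes bracketed BND ALT alleles, pairs records via `MATEID` and maps the
#' dialect's INFO keys onto breakend annotations. Records whose mate is
#' missing are dropped (counted in the `"dropped"` attribute); a malformed
#' BND ALT is an error naming the record.
#'
#' @param path VCF path.
#' @return An [sv_breakpoints()] catalog.
#' @export
parse_breakend_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(sv_breakpoints())
  f <- strsplit(lines, "\t", fixed = TRUE)
  recs <- list()
  for (x in f) {
    id <- x[3]
    alt <- x[5]
    m <- regmatches(alt,
      regexec("^([A-Za-z]*)([\\[\\]])([^:]+):([0-9]+)([\\[\\]])([A-Za-z]*)$",
              alt, perl = TRUE))[[1]]
    if (length(m) == 0 || m[3] != m[6])
      stop("malformed BND ALT in record '", id, "': ", alt)
    t_prefix <- nzchar(m[2])
    orient <- if (t_prefix) "right" else "left"
    partner_orient <- if (m[3] == "[") "left" else "right"
    tseq <- if (t_prefix) m[2] else m[7]
    info <- .parse_info(x[8])
    filt <- x[7]
    recs[[id]] <- list(
      chrom = x[1], vcf_pos = as.integer(x[2]), orient = orient,
      partner_chrom = m[4], partner_vcf_pos = as.integer(m[5]),
      partner_orient = partner_orient,
      mate = unname(info["MATEID"]), qual = as.numeric(x[6]),
      tags = if (filt %in% c("PASS", ".")) "" else gsub(";", ",", filt),
      nfrag = as.integer(info["FRAGS"] %0% NA),
      vaf_small = as.numeric(info["VAF_SMALL"] %0% 1),
      vaf_large = as.numeric(info["VAF_LARGE"] %0% 1),
      inexact_hom = as.integer(info["IHOMLEN"] %0% 0),
      microhom = as.integer(info["HOMLEN"] %0% 0),
      strand_bias = as.numeric(info["SB"] %0% 0.5),
      has_rp = (info["RP"] %0% "1") == "1",
      has_sr = (info["SR"] %0% "1") == "1",
      repeat_ovl = (info["REPEAT"] %0% "0") == "1",
      ins_seq = substr(tseq, 2, nchar(tseq)))
  }
  ids <- names(recs)
  paired <- vapply(ids, function(id) {
    m <- recs[[id]]$mate
    !is.na(m) && m %in% ids && identical(recs[[m]]$mate, id)
  }, TRUE)
  dropped <- sum(!paired)
  if (dropped) message(dropped, " unpaired breakend record(s) dropped")
  ids <- ids[paired]
  done <- character(0)
  rows <- list()
  for (id in ids) {
    if (id %in% done) next
    mate <- recs[[id]]$mate
    done <- c(done, id, mate)
    a <- recs[[id]]; b <- recs[[mate]]
    to_boundary <- function(r) if (r$orient == "right") r$vcf_pos else r$vcf_pos - 1L
    row <- data.frame(
      bp_id = sub("_[12]$", "", id),
      chrom_1 = a$chrom, pos_1 = to_boundary(a), orient_1 = a$orient,
      chrom_2 = b$chrom, pos_2 = to_boundary(b), orient_2 = b$orient,
      stringsAsFactors = FALSE)
    for (fd in BE_FIELDS) {
      row[[paste0(fd, "_1")]] <- a[[fd]]
      row[[paste0(fd, "_2")]] <- b[[fd]]
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- sv_breakpoints(do.call(rbind, rows))
  attr(out, "dropped") <- dropped
  out
}

`%0%` <- function(a, b) if (is.na(a)) b else a

#' Dump/restore a breakpoint catalog as TSV
#' @param bps An [sv_breakpoints()] catalog.
#' @param path File path.
#' @return The catalog (reader) or the path, invisibly (writer).
#' @export
write_breakpoint_table <- function(bps, path) {
  write.table(as.data.frame(bps), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_breakpoint_table
#' @export
read_breakpoint_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  for (s in c("_1", "_2")) {
    cl <- paste0("ins_seq", s)
    if (cl %in% names(df)) df[[cl]][is.na(df[[cl]])] <- ""
    tg <- paste0("tags", s)
    if (tg %in% names(df)) df[[tg]][is.na(df[[tg]])] <- ""
  }
  sv_breakpoints(df)
}
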