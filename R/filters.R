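## The breakend/breakpoint filter model, orientation-based breakpoint typing,
## coverage classification of DEL-like/TAN-like junctions, junction grouping
## into translocations/insertions, and the full call_svs pipeline.

## numeric sentinels used for "rule never fires" extremes (kept finite so the
## parameter sets serialize cleanly to JSON)
.INERT_HI <- 1e9
.INERT_LO <- -1e9

#' Filter-parameter sets for breakend calls
#'
#' `filter_params()` returns the default parameter set; every threshold can
#' be overridden by name. `unconservative_filter_params()` is the fully
#' permissive extreme: every boolean filter off, every numeric threshold at
#' the value where its rule never fires, and no forbidden FILTER tags — the
#' baseline against which grid values are pruned.
#'
#' Rule semantics (a breakpoint is discarded when at least one of its two
#' breakends fails any enabled rule; "small" events are intrachromosomal
#' breakpoints shorter than `max_to_be_considered_small_event`,
#' interchromosomal breakpoints are never small):
#' \describe{
#'   \item{min_Nfragments}{minimum supporting fragments (default 5).}
#'   \item{min_af}{minimum VAF (0.25), read from `vaf_large` when the event
#'     length exceeds insert median + MAD, else `vaf_small`;
#'     interchromosomal breakends use `vaf_large`.}
#'   \item{min_af_EitherSmallOrLargeEvent}{rejects only when both VAFs fall
#'     below the threshold (0.25).}
#'   \item{min_QUAL}{minimum QUAL (0; inert at default).}
#'   \item{max_to_be_considered_small_event}{small-event length bound
#'     (1000 bp); a rule-applicability modifier, not itself a rule.}
#'   \item{min_length_inversions}{minimum INV-like event length (40).}
#'   \item{maximum_lenght_inexactHomology}{maximum inexact-homology length
#'     (50); non-small events only.}
#'   \item{maximum_microhomology}{maximum microhomology length (50).}
#'   \item{maximum_strand_bias}{maximum strand bias (0.99); small events
#'     only.}
#'   \item{filter_noReadPairs}{drop breakends without read-pair support
#'     (FALSE); non-small events only.}
#'   \item{filter_noSplitReads}{drop breakends without split-read support
#'     (FALSE); small events only.}
#'   \item{filter_overlappingRepeats}{drop breakends inside provided repeat
#'     annotation (FALSE).}
#'   \item{filter_polyGC}{drop breakends whose inserted sequence contains a
#'     G or C homopolymer run longer than 15 bp (TRUE).}
#'   \item{wrong_FILTERtags}{FILTER tags that discard a breakend
#'     (`"NO_ASSEMBLY"`).}
#'   \item{range_filt_DEL_breakpoints}{DEL-like breakends whose event length
#'     lies inside this inclusive range and whose inexact homology exceeds
#'     5 bp are discarded (`c(0, 1)`).}
#'   \item{dif_between_insert_and_del}{small DEL-like breakends whose
#'     inserted sequence is longer than event length minus this margin are
#'     discarded (5).}
#'   \item{max_rel_coverage_to_consider_del}{maximum spanned relative
#'     coverage for a DEL-like breakpoint to be called a deletion (0.1).}
#'   \item{min_rel_coverage_to_consider_dup}{minimum spanned relative
#'     coverage for a TAN-like breakpoint to be called a tandem duplication
#'     (1.8).}
#' }
#'
#' @param ... Named overrides of individual parameters.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(...) {
  p <- list(
    min_Nfragments = 5,
    min_af = 0.25,
    min_af_EitherSmallOrLargeEvent = 0.25,
    min_QUAL = 0,
    max_to_be_considered_small_event = 1000,
    min_length_inversions = 40,
    maximum_lenght_inexactHomology = 50,
    maximum_microhomology = 50,
    maximum_strand_bias = 0.99,
    filter_noReadPairs = FALSE,
    filter_noSplitReads = FALSE,
    filter_overlappingRepeats = FALSE,
    filter_polyGC = TRUE,
    wrong_FILTERtags = "NO_ASSEMBLY",
    range_filt_DEL_breakpoints = c(0, 1),
    dif_between_insert_and_del = 5,
    max_rel_coverage_to_consider_del = 0.1,
    min_rel_coverage_to_consider_dup = 1.8)
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown filter parameter: ", bad[1])
  p[names(dots)] <- dots
  validate_filter_params(p)
  structure(p, class = "filter_params")
}

#' @rdname filter_params
#' @export
unconservative_filter_params <- function() {
  filter_params(
    min_Nfragments = 0, min_af = 0, min_af_EitherSmallOrLargeEvent = 0,
    min_QUAL = 0, min_length_inversions = 0,
    maximum_lenght_inexactHomology = .INERT_HI,
    maximum_microhomology = .INERT_HI, maximum_strand_bias = 1,
    filter_noReadPairs = FALSE, filter_noSplitReads = FALSE,
    filter_overlappingRepeats = FALSE, filter_polyGC = FALSE,
    wrong_FILTERtags = character(0),
    range_filt_DEL_breakpoints = c(.INERT_LO, .INERT_LO),
    dif_between_insert_and_del = .INERT_LO,
    max_rel_coverage_to_consider_del = .INERT_HI,
    min_rel_coverage_to_consider_dup = 0)
}

validate_filter_params <- function(p) {
  num <- c("min_Nfragments", "min_af", "min_af_EitherSmallOrLargeEvent",
           "min_QUAL", "max_to_be_considered_small_event",
           "min_length_inversions", "maximum_lenght_inexactHomology",
           "maximum_microhomology", "maximum_strand_bias",
           "max_rel_coverage_to_consider_del",
           "min_rel_coverage_to_consider_dup")
  for (f in num) if (!is.numeric(p[[f]]) || length(p[[f]]) != 1)
    stop("filter parameter '", f, "' must be a single number")
  if (p$min_af > 1 || p$maximum_strand_bias > 1)
    stop("VAF and strand-bias thresholds must be <= 1")
  r <- p$range_filt_DEL_breakpoints
  if (length(r) != 2 || r[1] > r[2])
    stop("range_filt_DEL_breakpoints must be an ordered length-2 range")
  invisible(TRUE)
}

#' @export
print.filter_params <- function(x, ...) {
  cat("Breakend filter parameters (", active_filter_count(x),
      " active):\n", sep = "")
  for (nm in names(x)) {
    v <- x[[nm]]
    v <- if (length(v) == 0) "{}" else paste(format(v, digits = 4), collapse = ",")
    cat(sprintf("  %-34s %s\n", nm, v))
  }
  invisible(x)
}

#' Number of parameters differing from the unconservative extreme
#' @param params A `filter_params` object.
#' @return Integer count of active (non-permissive) filters.
#' @export
active_filter_count <- function(params) {
  un <- unconservative_filter_params()
  sum(vapply(names(un), function(nm)
    !identical(as.vector(params[[nm]]), as.vector(un[[nm]])) &&
      nm != "max_to_be_considered_small_event", TRUE))
}

#' Read/write filter parameters as JSON
#' @param params A `filter_params` object.
#' @param path JSON path.
#' @export
write_filter_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filter_params
#' @export
read_filter_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$wrong_FILTERtags <- as.character(p$wrong_FILTERtags)
  do.call(filter_params, p)
}

## ---- breakpoint typing -----------------------------------------------------

#' Orientation-based breakpoint typing
#'
#' Intrachromosomal junctions whose lower breakend continues right and whose
#' higher breakend continues left have deletion geometry (`DEL-like`); the
#' converse is `TAN-like`; equal orientations are `INV-like`; junctions
#' joining two chromosomes are `interchromosomal`.
#'
#' @param bps An [sv_breakpoints()] catalog (breakends in canonical order).
#' @return Character vector of type hints.
#' @export
type_breakpoint <- function(bps) {
  if (nrow(bps) == 0) return(character())
  same <- bps$chrom_1 == bps$chrom_2
  ifelse(!same, "interchromosomal",
  ifelse(bps$orient_1 == bps$orient_2, "INV-like",
  ifelse(bps$orient_1 == "right", "DEL-like", "TAN-like")))
}

## per-breakend evaluation frame for one side of every breakpoint
.be_side_frame <- function(bps, side, params, insert_stats) {
  s <- paste0("_", side)
  small <- bps$same_chrom &
    bps$length < params$max_to_be_considered_small_event
  thr <- if (is.null(insert_stats)) 0 else insert_stats$median + insert_stats$mad
  use_large <- !bps$same_chrom | (!is.na(bps$length) & bps$length > thr)
  list(qual = bps[[paste0("qual", s)]],
       nfrag = bps[[paste0("nfrag", s)]],
       vaf_small = bps[[paste0("vaf_small", s)]],
       vaf_large = bps[[paste0("vaf_large", s)]],
       inexact_hom = bps[[paste0("inexact_hom", s)]],
       microhom = bps[[paste0("microhom", s)]],
       strand_bias = bps[[paste0("strand_bias", s)]],
       has_rp = bps[[paste0("has_rp", s)]],
       has_sr = bps[[paste0("has_sr", s)]],
       ins_seq = bps[[paste0("ins_seq", s)]],
       tags = bps[[paste0("tags", s)]],
       repeat_ovl = bps[[paste0("repeat_ovl", s)]],
       small = small, use_large = use_large,
       type_hint = bps$type_hint, length = bps$length)
}

BREAKEND_RULES <- c("min_Nfragments", "min_af",
                    "min_af_EitherSmallOrLargeEvent", "min_QUAL",
                    "min_length_inversions", "maximum_lenght_inexactHomology",
                    "maximum_microhomology", "maximum_strand_bias",
                    "filter_noReadPairs", "filter_noSplitReads",
                    "filter_overlappingRepeats", "filter_polyGC",
                    "wrong_FILTERtags", "range_filt_DEL_breakpoints",
                    "dif_between_insert_and_del")

## reject mask of one rule on one side frame; NA annotations error out only
## when the rule can actually fire
.be_rule_reject <- function(sf, rule, params) {
  n <- length(sf$qual)
  if (n == 0) return(logical(0))
  p <- params[[rule]]
  len0 <- ifelse(is.na(sf$length), 0L, sf$length)
  m <- switch(rule,
    min_Nfragments = {
      if (p > 0 && anyNA(sf$nfrag))
        stop("missing annotation 'nfrag' needed by min_Nfragments")
      if (p <= 0) rep(FALSE, n) else sf$nfrag < p
    },
    min_af = ifelse(sf$use_large, sf$vaf_large, sf$vaf_small) < p,
    min_af_EitherSmallOrLargeEvent = sf$vaf_small < p & sf$vaf_large < p,
    min_QUAL = sf$qual < p,
    min_length_inversions = sf$type_hint == "INV-like" & len0 < p,
    maximum_lenght_inexactHomology = !sf$small & sf$inexact_hom > p,
    maximum_microhomology = sf$microhom > p,
    maximum_strand_bias = sf$small & sf$strand_bias > p,
    filter_noReadPairs = if (!p) rep(FALSE, n) else !sf$small & !sf$has_rp,
    filter_noSplitReads = if (!p) rep(FALSE, n) else sf$small & !sf$has_sr,
    filter_overlappingRepeats = if (!p) rep(FALSE, n) else sf$repeat_ovl,
    filter_polyGC = if (!p) rep(FALSE, n) else
      grepl("G{16,}|C{16,}", sf$ins_seq),
    wrong_FILTERtags = if (length(p) == 0) rep(FALSE, n) else
      vapply(strsplit(ifelse(is.na(sf$tags), "", sf$tags), ","),
             function(tg) any(tg %in% p), TRUE),
    range_filt_DEL_breakpoints = sf$type_hint == "DEL-like" &
      len0 >= p[1] & len0 <= p[2] & sf$inexact_hom > 5,
    dif_between_insert_and_del = sf$small & sf$type_hint == "DEL-like" &
      nchar(ifelse(is.na(sf$ins_seq), "", sf$ins_seq)) > (len0 - p),
    stop("unknown rule: ", rule))
  m[is.na(m)] <- FALSE
  m
}

#' Evaluate the filter rules on individual breakends
#'
#' @param bps An [sv_breakpoints()] catalog.
#' @param side Which breakend of each breakpoint (1 or 2).
#' @param params A [filter_params()] object.
#' @param insert_stats A [compute_insert_stats()] result (sets the
#'   small/large VAF switch; `NULL` means every intrachromosomal event uses
#'   `vaf_large`).
#' @return List with `pass` (logical per breakpoint row) and `reasons` (list
#'   of character vectors naming the rules that fired).
#' @export
breakend_passes <- function(bps, side = 1, params = filter_params(),
                            insert_stats = NULL) {
  sf <- .be_side_frame(bps, side, params, insert_stats)
  rejects <- lapply(BREAKEND_RULES, function(r) .be_rule_reject(sf, r, params))
  names(rejects) <- BREAKEND_RULES
  any_rej <- Reduce(`|`, rejects, rep(FALSE, nrow(bps)))
  reasons <- lapply(seq_len(nrow(bps)), function(i)
    BREAKEND_RULES[vapply(rejects, `[`, TRUE, i)])
  list(pass = !any_rej, reasons = reasons)
}

#' Breakpoint-level filtering: both breakends must pass
#'
#' @inheritParams breakend_passes
#' @return Logical vector (one per breakpoint) with a `reasons` attribute
#'   (per breakpoint, the union of the two breakends' firing rules).
#' @export
breakpoint_passes <- function(bps, params = filter_params(),
                              insert_stats = NULL) {
  a <- breakend_passes(bps, 1, params, insert_stats)
  b <- breakend_passes(bps, 2, params, insert_stats)
  pass <- a$pass & b$pass
  attr(pass, "reasons") <- Map(function(x, y) union(x, y), a$reasons, b$reasons)
  pass
}

## breakpoint-level reject mask for a single (rule, value) toggle; used by
## pruning and by the grid-search evaluator
.bp_rule_reject <- function(bps, rule, value, params_base, insert_stats) {
  params <- params_base
  params[[rule]] <- value
  r1 <- .be_rule_reject(.be_side_frame(bps, 1, params, insert_stats), rule, params)
  r2 <- .be_rule_reject(.be_side_frame(bps, 2, params, insert_stats), rule, params)
  r1 | r2
}

## ---- coverage classification ----------------------------------------------

.spanned_coverage <- function(bps, coverage) {
  if (is.null(coverage)) {
    if (any(bps$same_chrom & bps$pos_2 > bps$pos_1))
      stop("a coverage table is required to classify intrachromosomal breakpoints")
    return(rep(NA_real_, nrow(bps)))
  }
  vapply(seq_len(nrow(bps)), function(i) {
    if (!bps$same_chrom[i]) return(NA_real_)
    if (bps$pos_2[i] <= bps$pos_1[i]) return(1)
    coverage_of_interval(coverage, bps$chrom_1[i], bps$pos_1[i], bps$pos_2[i])
  }, 1)
}

#' Classify DEL-like and TAN-like breakpoints by spanned relative coverage
#'
#' DEL-like breakpoints whose spanned relative coverage is strictly below
#' `max_rel_coverage_to_consider_del` become deletions; TAN-like breakpoints
#' strictly above `min_rel_coverage_to_consider_dup` become tandem
#' duplications; everything else (including INV-like and interchromosomal
#' breakpoints) is returned as `remaining`.
#'
#' @param bps An [sv_breakpoints()] catalog.
#' @param coverage An `sv_coverage` table covering every spanned interval.
#' @param params A [filter_params()] object.
#' @return List of three catalogs: `deletions`, `tandem_duplications`,
#'   `remaining` (a partition of the input rows).
#' @export
classify_del_tan <- function(bps, coverage, params = filter_params()) {
  cov <- .spanned_coverage(bps, coverage)
  is_del <- bps$type_hint == "DEL-like" & !is.na(cov) &
    cov < params$max_rel_coverage_to_consider_del
  is_tan <- bps$type_hint == "TAN-like" & !is.na(cov) &
    cov > params$min_rel_coverage_to_consider_dup
  list(deletions = bps[is_del, , drop = FALSE],
       tandem_duplications = bps[is_tan, , drop = FALSE],
       remaining = bps[!is_del & !is_tan, , drop = FALSE])
}

## ---- junction grouping (translocations / insertions) -----------------------

## Candidate evaluation for a pair of junctions under one endpoint matching.
## Sides: A = (endpoint ai of i, endpoint aj of j), B likewise.
.eval_junction_pair <- function(ei, ej, pair_tol, trans_tol) {
  if (ei$chrom[1] != ej$chrom[1] || ei$chrom[2] != ej$chrom[2]) return(NULL)
  dA <- abs(ei$pos[1] - ej$pos[1])
  dB <- abs(ei$pos[2] - ej$pos[2])
  compl_A <- length(unique(c(ei$orient[1], ej$orient[1]))) == 2
  compl_B <- length(unique(c(ei$orient[2], ej$orient[2]))) == 2
  if (!compl_A || !compl_B) return(NULL)
  within_equal <- ei$orient[1] == ei$orient[2]
  if (dA <= trans_tol && dB <= trans_tol &&
      within_equal == (ej$orient[1] == ej$orient[2])) {
    return(list(kind = "translocation", score = dA + dB,
                chromA = ei$chrom[1], posA = round((ei$pos[1] + ej$pos[1]) / 2),
                chromB = ei$chrom[2], posB = round((ei$pos[2] + ej$pos[2]) / 2),
                inverted = within_equal))
  }
  ## insertion: one shared side (the destination), the other side spans the
  ## origin with "left" at its start and "right" at its end
  for (shared in 1:2) {
    org <- 3 - shared
    d_sh <- if (shared == 1) dA else dB
    d_or <- if (shared == 1) dB else dA
    if (d_sh > pair_tol || d_or <= trans_tol) next
    ps <- c(ei$pos[org], ej$pos[org])
    os <- c(ei$orient[org], ej$orient[org])
    s_idx <- which.min(ps); e_idx <- which.max(ps)
    if (os[s_idx] != "left" || os[e_idx] != "right") next
    return(list(kind = "insertion", score = d_sh,
                chrom_origin = ei$chrom[org], start = ps[s_idx], end = ps[e_idx],
                chrom_dest = ei$chrom[shared],
                pos_dest = round((ei$pos[shared] + ej$pos[shared]) / 2)))
  }
  NULL
}

#' Group leftover junctions into translocations and insertions
#'
#' Implements a deterministic surrogate for graph-based breakpoint
#' summarizing: pairs of junctions whose endpoints agree within `trans_tol`
#' on both sides (with complementary orientations) form balanced
#' translocations; pairs sharing one endpoint (within `pair_tol`) whose
#' other endpoints span an origin interval form insertions, with the origin's
#' relative coverage deciding copy-and-paste (at or above
#' `min_rel_coverage_to_consider_dup`) versus cut-and-paste (at or below
#' `max_rel_coverage_to_consider_del`); when both thresholds are degenerate
#' enough to agree, coverage at or above 1 means copy. A surviving
#' interchromosomal junction left unpaired is still typed as a translocation
#' (its balanced mate may simply have gone undetected), with the inverted
#' flag read off its orientation pattern; unpaired intrachromosomal and
#' undecided junctions are returned as unclassified.
#'
#' @param bps Catalog of junctions not classified as DEL/TAN/INV.
#' @param coverage An `sv_coverage` table.
#' @param params A [filter_params()] object.
#' @param pair_tol Maximum distance (bp) between shared destination
#'   endpoints.
#' @param trans_tol Maximum endpoint distance (bp) for the balanced
#'   translocation pattern.
#' @return List with `translocations` and `insertions` ([sv_set()]s) and
#'   `unclassified` (catalog rows).
#' @export
group_junctions <- function(bps, coverage, params = filter_params(),
                            pair_tol = 1000, trans_tol = 40) {
  n <- nrow(bps)
  empty <- list(translocations = sv_set(), insertions = sv_set(),
                unclassified = bps[0, , drop = FALSE])
  if (n == 0) return(empty)
  ends <- function(i, flip = FALSE) {
    idx <- if (flip) c(2L, 1L) else c(1L, 2L)
    list(chrom = c(bps$chrom_1[i], bps$chrom_2[i])[idx],
         pos = c(bps$pos_1[i], bps$pos_2[i])[idx],
         orient = c(bps$orient_1[i], bps$orient_2[i])[idx])
  }
  cands <- list()
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    for (flip in c(FALSE, TRUE)) {
      cand <- .eval_junction_pair(ends(i), ends(j, flip), pair_tol, trans_tol)
      if (!is.null(cand)) {
        cand$i <- i; cand$j <- j
        cands[[length(cands) + 1L]] <- cand
        break
      }
    }
  }
  used <- rep(FALSE, n)
  trans <- list(); ins <- list()
  if (length(cands)) {
    prio <- vapply(cands, function(c)
      (c$kind != "translocation") * 1e6 + c$score, 1)
    for (k in order(prio)) {
      cand <- cands[[k]]
      if (used[cand$i] || used[cand$j]) next
      if (cand$kind == "translocation") {
        used[c(cand$i, cand$j)] <- TRUE
        trans[[length(trans) + 1L]] <- data.frame(
          id = NA, type = "translocation", chrom = cand$chromA,
          start = cand$posA, end = NA, chrom2 = cand$chromB,
          start2 = cand$posB, copy = NA, inverted = cand$inverted)
      } else {
        cov <- tryCatch(
          coverage_of_interval(coverage, cand$chrom_origin, cand$start, cand$end),
          error = function(e) NA_real_)
        if (is.na(cov)) next
        is_copy <- cov >= params$min_rel_coverage_to_consider_dup
        is_cut <- cov <= params$max_rel_coverage_to_consider_del
        if (is_copy && is_cut) { is_copy <- cov >= 1; is_cut <- !is_copy }
        if (!is_copy && !is_cut) next # undecided -> unclassified
        used[c(cand$i, cand$j)] <- TRUE
        ins[[length(ins) + 1L]] <- data.frame(
          id = NA, type = "insertion", chrom = cand$chrom_origin,
          start = cand$start, end = cand$end, chrom2 = cand$chrom_dest,
          start2 = cand$pos_dest, copy = is_copy, inverted = NA)
      }
    }
  }
  ## a surviving interchromosomal junction with no partner is still a
  ## translocation signature (the balanced mate may simply be undetected);
  ## its inverted status follows from the orientation pattern
  for (i in which(!used)) {
    if (bps$same_chrom[i]) next
    used[i] <- TRUE
    trans[[length(trans) + 1L]] <- data.frame(
      id = NA, type = "translocation", chrom = bps$chrom_1[i],
      start = bps$pos_1[i], end = NA, chrom2 = bps$chrom_2[i],
      start2 = bps$pos_2[i], copy = NA,
      inverted = bps$orient_1[i] == bps$orient_2[i])
  }
  list(
    translocations = if (length(trans)) sv_set(do.call(rbind, trans)) else sv_set(),
    insertions = if (length(ins)) sv_set(do.call(rbind, ins)) else sv_set(),
    unclassified = bps[!used, , drop = FALSE])
}

## cluster kept INV-like junctions into inversion records (the two junctions
## of one inversion share both boundary coordinates up to `tol`)
.inversions_from_breakpoints <- function(bps, tol = 50) {
  if (nrow(bps) == 0) return(sv_set())
  o <- order(bps$chrom_1, bps$pos_1)
  bps <- bps[o, , drop = FALSE]
  recs <- list()
  taken <- rep(FALSE, nrow(bps))
  for (i in seq_len(nrow(bps))) {
    if (taken[i]) next
    grp <- i
    for (j in seq_len(nrow(bps))) {
      if (j == i || taken[j]) next
      if (bps$chrom_1[j] == bps$chrom_1[i] &&
          abs(bps$pos_1[j] - bps$pos_1[i]) <= tol &&
          abs(bps$pos_2[j] - bps$pos_2[i]) <= tol) grp <- c(grp, j)
    }
    taken[grp] <- TRUE
    recs[[length(recs) + 1L]] <- data.frame(
      id = NA, type = "inversion", chrom = bps$chrom_1[i],
      start = round(mean(bps$pos_1[grp])), end = round(mean(bps$pos_2[grp])),
      chrom2 = NA, start2 = NA, copy = NA, inverted = NA)
  }
  sv_set(do.call(rbind, recs))
}

#' Annotate breakends with repeat overlap
#'
#' @param bps An [sv_breakpoints()] catalog.
#' @param repeats data.frame with `chrom`, `start`, `end` (e.g. from
#'   [read_bed()]).
#' @return The catalog with `repeat_ovl_1/_2` set.
#' @export
annotate_repeat_overlap <- function(bps, repeats) {
  hit <- function(chrom, pos) {
    vapply(seq_along(chrom), function(i)
      any(repeats$chrom == chrom[i] & repeats$start <= pos[i] &
            repeats$end > pos[i]), TRUE)
  }
  bps$repeat_ovl_1 <- hit(bps$chrom_1, bps$pos_1)
  bps$repeat_ovl_2 <- hit(bps$chrom_2, bps$pos_2)
  bps
}

#' Call structural variants from a breakend catalog
#'
#' Runs the full classification pipeline: breakend/breakpoint filtering,
#' orientation typing, coverage-based deletion/tandem-duplication
#' classification, inversion pairing, and junction grouping into
#' translocations and insertions. Junctions that survive filtering but fit
#' no pattern land in the unclassified table.
#'
#' @param bps An [sv_breakpoints()] catalog.
#' @param params A [filter_params()] object.
#' @param coverage An `sv_coverage` table.
#' @param insert_stats A [compute_insert_stats()] result.
#' @param repeats Optional repeat annotation (data.frame chrom/start/end);
#'   when given, breakend repeat-overlap flags are recomputed from it.
#' @return A list of class `sv_calls`: `svs` (one [sv_set()] with all typed
#'   calls), `unclassified` (leftover junctions) and `n_filtered` (junctions
#'   removed by the filters).
#' @export
call_svs <- function(bps, params = filter_params(), coverage = NULL,
                     insert_stats = NULL, repeats = NULL) {
  if (!is.null(repeats)) bps <- annotate_repeat_overlap(bps, repeats)
  pass <- breakpoint_passes(bps, params, insert_stats)
  kept <- bps[pass, , drop = FALSE]
  covs <- .spanned_coverage(kept, coverage)
  res <- .call_svs_core(kept, covs, params, coverage)
  structure(c(res, list(n_filtered = sum(!pass))), class = "sv_calls")
}

## classification + grouping on an already-filtered catalog with precomputed
## spanned coverages (the grid search calls this directly)
.call_svs_core <- function(kept, covs, params, coverage,
                           pair_tol = 1000, trans_tol = 40) {
  is_del <- kept$type_hint == "DEL-like" & !is.na(covs) &
    covs < params$max_rel_coverage_to_consider_del
  is_tan <- kept$type_hint == "TAN-like" & !is.na(covs) &
    covs > params$min_rel_coverage_to_consider_dup
  mk <- function(b, type) {
    if (nrow(b) == 0) return(sv_set())
    sv_set(data.frame(id = NA, type = type, chrom = b$chrom_1, start = b$pos_1,
                      end = b$pos_2, chrom2 = NA, start2 = NA, copy = NA,
                      inverted = NA))
  }
  dels <- mk(kept[is_del, , drop = FALSE], "deletion")
  tans <- mk(kept[is_tan, , drop = FALSE], "tandem_duplication")
  rem <- kept[!is_del & !is_tan, , drop = FALSE]
  inv_rows <- rem$type_hint == "INV-like"
  invs <- .inversions_from_breakpoints(rem[inv_rows, , drop = FALSE])
  grp <- group_junctions(rem[!inv_rows, , drop = FALSE], coverage, params,
                         pair_tol, trans_tol)
  svs <- sv_set(do.call(rbind, lapply(
    list(dels, invs, tans, grp$translocations, grp$insertions),
    as.data.frame)))
  if (nrow(svs)) svs$id <- sprintf("call_%d", seq_len(nrow(svs)))
  list(svs = svs, unclassified = grp$unclassified)
}

#' @export
print.sv_calls <- function(x, ...) {
  cat("SV calls:", nrow(x$svs), "typed,", nrow(x$unclassified),
      "unclassified,", x$n_filtered, "junctions filtered out\n")
  if (nrow(x$svs)) print(table(x$svs$type))
  invisible(x)
}
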