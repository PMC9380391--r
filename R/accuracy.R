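## Scoring called SV sets against known (truth) sets: type-specific matching
## rules, and precision / recall / F-value per type and integrated.

#' Matching configuration for SV set comparison
#'
#' @param overlap_fraction Required overlap of the altered regions (default
#'   0.75, inclusive).
#' @param breakend_dist Breakends must be strictly closer than this (bp).
#' @param insertion_site_dist Maximum distance (strict) between insertion
#'   destination sites.
#' @param reciprocal If `TRUE` (default) the overlap fraction must hold
#'   relative to both regions; if `FALSE`, only relative to the first
#'   (called) record.
#' @return A list of class `match_config`.
#' @export
match_config <- function(overlap_fraction = 0.75, breakend_dist = 50,
                         insertion_site_dist = 50, reciprocal = TRUE) {
  stopifnot(overlap_fraction > 0, overlap_fraction <= 1,
            breakend_dist >= 0, insertion_site_dist >= 0)
  structure(list(overlap_fraction = overlap_fraction,
                 breakend_dist = breakend_dist,
                 insertion_site_dist = insertion_site_dist,
                 reciprocal = reciprocal),
            class = "match_config")
}

.interval_match <- function(s1, e1, s2, e2, cfg) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  ok_ov <- if (cfg$reciprocal) {
    inter >= cfg$overlap_fraction * (e1 - s1) &&
      inter >= cfg$overlap_fraction * (e2 - s2)
  } else inter >= cfg$overlap_fraction * (e1 - s1)
  ok_ov && abs(s1 - s2) < cfg$breakend_dist && abs(e1 - e2) < cfg$breakend_dist
}

.canonical_pair <- function(r) {
  ## orient translocation chromosome pairs consistently before comparing
  if (!is.na(r$chrom2) && r$chrom2 < r$chrom) {
    tmp <- r$chrom; r$chrom <- r$chrom2; r$chrom2 <- tmp
    tmp <- r$start; r$start <- r$start2; r$start2 <- tmp
  }
  r
}

#' Do two SV records of the same type match?
#'
#' Deletions, inversions and tandem duplications match when they lie on the
#' same chromosome, their altered regions overlap by at least the configured
#' fraction and their breakends are closer than the configured distance.
#' Insertions additionally require identical origin and destination
#' chromosomes, the same copy/cut mode, matching origin regions and nearby
#' destination sites. Translocations require the same chromosome pair, the
#' same inverted status, and breakpoint positions closer than the distance.
#'
#' @param a,b Single-row [sv_set()] records of the same type.
#' @param cfg A [match_config()].
#' @return Logical.
#' @export
svs_match <- function(a, b, cfg = match_config()) {
  if (a$type != b$type)
    stop("cannot match SVs of different types: ", a$type, " vs ", b$type)
  switch(a$type,
    deletion = ,
    inversion = ,
    tandem_duplication =
      a$chrom == b$chrom && .interval_match(a$start, a$end, b$start, b$end, cfg),
    insertion =
      a$chrom == b$chrom && a$chrom2 == b$chrom2 &&
      identical(as.logical(a$copy), as.logical(b$copy)) &&
      .interval_match(a$start, a$end, b$start, b$end, cfg) &&
      abs(a$start2 - b$start2) < cfg$insertion_site_dist,
    translocation = {
      a <- .canonical_pair(a); b <- .canonical_pair(b)
      a$chrom == b$chrom && a$chrom2 == b$chrom2 &&
        identical(isTRUE(a$inverted), isTRUE(b$inverted)) &&
        abs(a$start - b$start) < cfg$breakend_dist &&
        abs(a$start2 - b$start2) < cfg$breakend_dist
    })
}

.prf <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  fvalue <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, fvalue = fvalue)
}

## vectorized all-pairs match matrix for one SV type (rows = called A,
## columns = known B); same rules as svs_match
.match_matrix <- function(A, B, type, cfg) {
  o <- function(x, y, f) outer(x, y, f)
  iv <- function(sA, eA, sB, eB) {
    inter <- pmax(0, o(eA, eB, pmin) - o(sA, sB, pmax))
    ok <- if (cfg$reciprocal) {
      inter >= cfg$overlap_fraction * (eA - sA) &
        inter >= cfg$overlap_fraction * rep(eB - sB, each = length(sA))
    } else inter >= cfg$overlap_fraction * (eA - sA)
    ok & abs(o(sA, sB, `-`)) < cfg$breakend_dist &
      abs(o(eA, eB, `-`)) < cfg$breakend_dist
  }
  if (type %in% c("deletion", "inversion", "tandem_duplication")) {
    o(A$chrom, B$chrom, `==`) & iv(A$start, A$end, B$start, B$end)
  } else if (type == "insertion") {
    o(A$chrom, B$chrom, `==`) & o(A$chrom2, B$chrom2, `==`) &
      o(as.logical(A$copy), as.logical(B$copy), `==`) &
      iv(A$start, A$end, B$start, B$end) &
      abs(o(A$start2, B$start2, `-`)) < cfg$insertion_site_dist
  } else { # translocation
    cA <- do.call(rbind, lapply(seq_len(nrow(A)), function(i)
      .canonical_pair(A[i, ])))
    cB <- do.call(rbind, lapply(seq_len(nrow(B)), function(i)
      .canonical_pair(B[i, ])))
    o(cA$chrom, cB$chrom, `==`) & o(cA$chrom2, cB$chrom2, `==`) &
      o(isTRUE_vec(cA$inverted), isTRUE_vec(cB$inverted), `==`) &
      abs(o(cA$start, cB$start, `-`)) < cfg$breakend_dist &
      abs(o(cA$start2, cB$start2, `-`)) < cfg$breakend_dist
  }
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Compare a called SV set against a known SV set
#'
#' True positives are called records matching at least one known record of
#' the same type; false positives match none; false negatives are known
#' records matched by no call. A known record may satisfy several calls (no
#' one-to-one assignment). Zero-denominator conventions: precision is 0 when
#' there are no calls, recall is 0 when there are no knowns, F is 0 when
#' precision + recall is 0.
#'
#' @param called,known [sv_set()]s.
#' @param cfg A [match_config()].
#' @return Data.frame of class `sv_accuracy`: one row per SV type plus an
#'   `integrated` row (all types merged), with TP, FP, FN, precision,
#'   recall, fvalue.
#' @export
compare_sv_sets <- function(called, known, cfg = match_config()) {
  rows <- list()
  for (type in SV_TYPES) {
    A <- called[called$type == type, , drop = FALSE]
    B <- known[known$type == type, , drop = FALSE]
    called_hit <- rep(FALSE, nrow(A))
    known_hit <- rep(FALSE, nrow(B))
    if (nrow(A) && nrow(B)) {
      m <- .match_matrix(A, B, type, cfg)
      called_hit <- apply(m, 1, any)
      known_hit <- apply(m, 2, any)
    }
    tp <- sum(called_hit); fp <- nrow(A) - tp; fn <- sum(!known_hit)
    rows[[type]] <- data.frame(type = type, TP = tp, FP = fp, FN = fn,
                               t(.prf(tp, fp, fn)))
  }
  df <- do.call(rbind, rows)
  tot <- colSums(df[, c("TP", "FP", "FN")])
  df <- rbind(df, data.frame(type = "integrated", TP = tot[["TP"]],
                             FP = tot[["FP"]], FN = tot[["FN"]],
                             t(.prf(tot[["TP"]], tot[["FP"]], tot[["FN"]]))))
  rownames(df) <- NULL
  class(df) <- c("sv_accuracy", "data.frame")
  df
}

#' @export
print.sv_accuracy <- function(x, ...) {
  y <- as.data.frame(x)
  y$precision <- round(y$precision, 3)
  y$recall <- round(y$recall, 3)
  y$fvalue <- round(y$fvalue, 3)
  print(y)
  invisible(x)
}

#' Write an accuracy report as TSV
#' @param report An `sv_accuracy` data.frame.
#' @param path Output path.
#' @export
write_accuracy_report <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
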