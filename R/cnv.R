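## Read-depth CNV support: coverage windows with GC / mappability / telomere
## predictors, sequential lowess bias correction, a simple threshold
## segmenter, conservative cross-caller consensus, redundancy removal
## against SV-derived CNVs, and unified VCF export.

#' Build coverage windows with bias predictors
#'
#' Tiles the genome and computes, per window, the GC fraction, a mappability
#' value (from a supplied track, or a built-in exact k-mer-uniqueness
#' fallback) and the distance to the nearest chromosome end (used as the
#' telomere distance when no telomere annotation is available).
#'
#' @param genome Named [Biostrings::DNAStringSet] or FASTA path.
#' @param window Window size (bp).
#' @param mappability Optional data.frame `chrom,start,end,mappability` on
#'   the same binning; `NULL` computes the k-mer uniqueness fallback.
#' @param k K-mer length for the uniqueness fallback (think read length at
#'   desk scale).
#' @return Data.frame `chrom,start,end,gc,mappability,telomere_dist`.
#' @export
coverage_windows <- function(genome, window = 100, mappability = NULL,
                             k = 50) {
  if (is.character(genome)) genome <- read_fasta(genome)
  lens <- setNames(Biostrings::width(genome), names(genome))
  wins <- do.call(rbind, lapply(names(lens), function(ch) {
    s <- seq(0L, max(0L, lens[[ch]] - 1L), by = window)
    data.frame(chrom = ch, start = s, end = pmin(s + window, lens[[ch]]))
  }))
  gc <- numeric(nrow(wins))
  for (ch in names(lens)) {
    i <- which(wins$chrom == ch)
    v <- Biostrings::Views(genome[[ch]],
                           start = wins$start[i] + 1L, end = wins$end[i])
    n_gc <- Biostrings::letterFrequency(v, "GC")[, 1]
    n_at <- Biostrings::letterFrequency(v, "AT")[, 1]
    gc[i] <- ifelse(n_gc + n_at > 0, n_gc / (n_gc + n_at), 0)
  }
  wins$gc <- gc
  if (is.null(mappability)) {
    km_all <- unlist(lapply(names(lens), function(ch) {
      s <- as.character(genome[[ch]])
      n <- nchar(s) - k + 1L
      if (n < 1) character() else substring(s, 1:n, k:(k + n - 1L))
    }))
    counts <- table(km_all)
    mp <- numeric(nrow(wins))
    pos <- 0L
    for (ch in names(lens)) {
      s <- as.character(genome[[ch]])
      n <- nchar(s) - k + 1L
      uniq <- if (n < 1) logical() else
        as.vector(counts[substring(s, 1:n, k:(k + n - 1L))] == 1)
      i <- which(wins$chrom == ch)
      mp[i] <- vapply(i, function(w) {
        a <- wins$start[w] + 1L
        b <- min(wins$end[w], n)
        if (b < a) return(1)
        mean(uniq[a:b])
      }, 1)
    }
    wins$mappability <- mp
  } else {
    key <- paste(wins$chrom, wins$start)
    mkey <- paste(mappability$chrom, mappability$start)
    wins$mappability <- mappability$mappability[match(key, mkey)]
  }
  wins$telomere_dist <- pmin(wins$start, lens[wins$chrom] - wins$end)
  wins
}

#' Correct relative coverage for GC, mappability and telomere distance
#'
#' Sequential nonparametric correction: the relative coverage is regressed
#' (lowess) on each predictor in turn (GC content, then mappability, then
#' telomere distance), dividing by the fitted trend at each step, and the
#' result is renormalized to genome-wide median 1. With fewer than 30
#' windows no trend is fittable and the input is returned with a warning.
#'
#' @param windows Data.frame with `rel_coverage` and any of the predictor
#'   columns `gc`, `mappability`, `telomere_dist`.
#' @param span Lowess span (fraction of points; default 0.3).
#' @param predictors Correction order.
#' @return `windows` with a `corrected_rel_coverage` column.
#' @export
correct_coverage <- function(windows, span = 0.3,
                             predictors = c("gc", "mappability",
                                            "telomere_dist")) {
  cur <- windows$rel_coverage
  if (nrow(windows) < 30) {
    warning("fewer than 30 windows; coverage correction skipped")
    windows$corrected_rel_coverage <- cur
    return(windows)
  }
  for (p in intersect(predictors, names(windows))) {
    x <- windows[[p]]
    if (length(unique(x)) < 2) next
    fit <- lowess(x, cur, f = span)
    trend <- approx(fit$x, fit$y, xout = x, rule = 2, ties = mean)$y
    trend <- pmax(trend, 1e-8)
    cur <- cur / trend
  }
  med <- median(cur)
  if (med > 0) cur <- cur / med
  windows$corrected_rel_coverage <- cur
  windows
}

#' Simple threshold segmentation of corrected coverage into CNV calls
#'
#' Rounds each window's corrected relative coverage to the nearest multiple
#' of 1/ploidy and merges consecutive windows with equal copy number;
#' segments whose relative copy number differs from 1 are reported.
#'
#' @param windows Data.frame with `corrected_rel_coverage` (falls back to
#'   `rel_coverage`).
#' @param ploidy Integer ploidy of the sample.
#' @param min_windows Minimum run length (windows) for a reported segment.
#' @return Data.frame `chrom,start,end,cn,source` (relative copy number;
#'   1 = neutral).
#' @export
segment_cnvs <- function(windows, ploidy = 1, min_windows = 1) {
  cov <- windows$corrected_rel_coverage %||% windows$rel_coverage
  cn <- round(cov * ploidy) / ploidy
  out <- list()
  for (ch in unique(windows$chrom)) {
    i <- which(windows$chrom == ch)
    r <- rle(cn[i])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in seq_along(r$values)) {
      if (r$values[j] == 1 || r$lengths[j] < min_windows) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = windows$start[i[starts[j]]],
        end = windows$end[i[ends[j]]], cn = r$values[j], source = "depth")
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), cn = numeric(), source = character()))
  do.call(rbind, out)
}

#' Conservative consensus of per-program CNV tracks
#'
#' All tracks must share one binning (`chrom,start,end` identical). For each
#' bin the most conservative copy number is kept: the one closest to 1; on
#' ties, 1 if any program reports 1, otherwise the smaller copy number. The
#' result does not depend on track order.
#'
#' @param tracks List of data.frames `chrom,start,end,cn`.
#' @return Data.frame with the consensus `cn` per bin.
#' @export
consensus_cnv <- function(tracks) {
  if (!length(tracks)) stop("need at least one CNV track")
  ref <- tracks[[1]][, c("chrom", "start", "end")]
  for (t in tracks[-1]) {
    if (nrow(t) != nrow(ref) ||
        !all(t$chrom == ref$chrom & t$start == ref$start & t$end == ref$end))
      stop("CNV tracks are not on a common binning")
  }
  cns <- vapply(tracks, function(t) t$cn, numeric(nrow(ref)))
  cns <- matrix(cns, nrow = nrow(ref))
  ref$cn <- apply(cns, 1, function(v) {
    d <- abs(v - 1)
    cand <- v[d == min(d)]
    if (any(cand == 1)) 1 else min(cand)
  })
  ref
}

.reciprocal_overlap <- function(s1, e1, s2, e2) {
  inter <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(inter / (e1 - s1), inter / (e2 - s2))
}

#' Drop coverage CNVs redundant with SV-derived CNVs
#'
#' A coverage-derived CNV is removed when it overlaps any SV-derived CNV
#' (deletion, tandem duplication, insertion-origin gain/loss) reciprocally
#' by at least `min_reciprocal` of each region.
#'
#' @param cnvs Coverage CNV calls (`chrom,start,end,...`).
#' @param sv_cnvs SV-derived CNV intervals (`chrom,start,end`), e.g. from
#'   [sv_derived_cnvs()].
#' @param min_reciprocal Inclusive reciprocal-overlap threshold (0.8).
#' @return The filtered `cnvs`.
#' @export
remove_redundant_cnvs <- function(cnvs, sv_cnvs, min_reciprocal = 0.8) {
  if (!nrow(cnvs) || !nrow(sv_cnvs)) return(cnvs)
  drop <- vapply(seq_len(nrow(cnvs)), function(i) {
    j <- sv_cnvs$chrom == cnvs$chrom[i]
    if (!any(j)) return(FALSE)
    any(.reciprocal_overlap(cnvs$start[i], cnvs$end[i],
                            sv_cnvs$start[j], sv_cnvs$end[j]) >=
          min_reciprocal)
  }, TRUE)
  cnvs[!drop, , drop = FALSE]
}

#' Copy-number-relevant intervals implied by an SV call set
#'
#' @param svs An [sv_set()].
#' @return Data.frame `chrom,start,end,cn,source` (deletions 0, tandem
#'   duplications 2, copy-insert origins 2, cut-insert origins 0).
#' @export
sv_derived_cnvs <- function(svs) {
  rows <- list()
  for (i in seq_len(nrow(svs))) {
    r <- svs[i, ]
    if (r$type == "deletion")
      rows[[length(rows) + 1L]] <- data.frame(chrom = r$chrom, start = r$start,
                                              end = r$end, cn = 0, source = "sv")
    if (r$type == "tandem_duplication")
      rows[[length(rows) + 1L]] <- data.frame(chrom = r$chrom, start = r$start,
                                              end = r$end, cn = 2, source = "sv")
    if (r$type == "insertion")
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = r$chrom, start = r$start, end = r$end,
        cn = if (isTRUE(r$copy)) 2 else 0, source = "sv")
  }
  if (!length(rows))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), cn = numeric(), source = character()))
  do.call(rbind, rows)
}

## ---- unified VCF -----------------------------------------------------------

.overlaps_repeats <- function(chrom, start, end, repeats) {
  if (is.null(repeats)) return(rep(NA, length(chrom)))
  vapply(seq_along(chrom), function(i)
    any(repeats$chrom == chrom[i] & repeats$start < end[i] &
          repeats$end > start[i]), TRUE)
}

#' Export SV and CNV calls as a unified, annotation-ready VCF
#'
#' Decomposes every variant into rows describing how it affects genomic
#' regions: deletions become DEL rows, tandem duplications TDUP, coverage
#' CNV gains DUP (losses DEL), inversions two BND rows (one per end),
#' translocations one BND row per breakpoint end, insertions a DUP (copy)
#' or DEL (cut) row at the origin plus a BND at the destination, and
#' non-template inserted sequences insertionBND rows. All rows of one SV
#' share a `variantID` INFO field; every row has a unique ID; when a repeat
#' annotation is provided each row carries an `overlaps_repeats` flag.
#'
#' @param svs An [sv_set()] of typed calls.
#' @param cnvs Optional coverage CNV calls (`chrom,start,end,cn`).
#' @param repeats Optional repeat annotation (`chrom,start,end`).
#' @param path Output VCF path.
#' @param inserts Optional data.frame `sv_id,chrom,pos,seq` of non-template
#'   insertions around breakends.
#' @return Invisibly, the data.frame of exported rows.
#' @export
export_unified_vcf <- function(svs, cnvs = NULL, repeats = NULL, path,
                               inserts = NULL) {
  rows <- list()
  add <- function(chrom, pos, end, svtype, vid)
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, end = end, svtype = svtype, vid = vid,
      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(svs))) {
    r <- svs[i, ]
    vid <- if (is.na(r$id)) sprintf("sv_%d", i) else r$id
    switch(r$type,
      deletion = add(r$chrom, r$start, r$end, "DEL", vid),
      tandem_duplication = add(r$chrom, r$start, r$end, "TDUP", vid),
      inversion = {
        add(r$chrom, r$start, r$start + 1L, "BND", vid)
        add(r$chrom, r$end, r$end + 1L, "BND", vid)
      },
      translocation = {
        add(r$chrom, r$start, r$start + 1L, "BND", vid)
        add(r$chrom2, r$start2, r$start2 + 1L, "BND", vid)
      },
      insertion = {
        add(r$chrom, r$start, r$end, if (isTRUE(r$copy)) "DUP" else "DEL", vid)
        add(r$chrom2, r$start2, r$start2 + 1L, "BND", vid)
      })
  }
  for (i in seq_len(NROW(cnvs))) {
    add(cnvs$chrom[i], cnvs$start[i], cnvs$end[i],
        if (cnvs$cn[i] > 1) "DUP" else "DEL", sprintf("cnv_%d", i))
  }
  for (i in seq_len(NROW(inserts))) {
    add(inserts$chrom[i], inserts$pos[i], inserts$pos[i] + 1L,
        "insertionBND", inserts$sv_id[i])
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), end = integer(),
               svtype = character(), vid = character())
  df$row_id <- sprintf("%s_r%d", df$vid, stats::ave(
    seq_len(nrow(df)), df$vid, FUN = seq_along))
  rep_flag <- .overlaps_repeats(df$chrom, df$pos, df$end, repeats)
  hdr <- c("##fileformat=VCFv4.2", "##source=svtune",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Row event type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End of the affected region (1-based inclusive)">',
    '##INFO=<ID=variantID,Number=1,Type=String,Description="Identifier shared by all rows of one SV">',
    '##INFO=<ID=overlaps_repeats,Number=1,Type=Integer,Description="Row region overlaps the provided repeat annotation">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  body <- vapply(seq_len(nrow(df)), function(i) {
    info <- sprintf("SVTYPE=%s;END=%d;variantID=%s", df$svtype[i], df$end[i],
                    df$vid[i])
    if (!is.na(rep_flag[i]))
      info <- paste0(info, ";overlaps_repeats=", as.integer(rep_flag[i]))
    paste(df$chrom[i], df$pos[i] + 1L, df$row_id[i], "N",
          paste0("<", sub("insertionBND", "BND", df$svtype[i]), ">"), ".",
          "PASS", info, sep = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(df)
}

#' Parse a unified VCF written by [export_unified_vcf()]
#'
#' @param path VCF path.
#' @return Data.frame with `chrom, pos, end` (0-based half-open), `svtype`,
#'   `variant_id`, `row_id`, `overlaps_repeats`.
#' @export
parse_unified_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), pos = integer(), end = integer(),
                      svtype = character(), variant_id = character(),
                      row_id = character(), overlaps_repeats = logical()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  parse1 <- function(x) {
    info <- .parse_info(x[8])
    data.frame(chrom = x[1], pos = as.integer(x[2]) - 1L,
               end = as.integer(info["END"]),
               svtype = unname(info["SVTYPE"]),
               variant_id = unname(info["variantID"]), row_id = x[3],
               overlaps_repeats = if (is.na(info["overlaps_repeats"])) NA
                 else info["overlaps_repeats"] == "1",
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(f, parse1))
  rownames(out) <- NULL
  out
}
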