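## Inference of BEDPE region pairs for realistic simulations: homologous
## region pairs by windowed self-comparison of the genome, and +/-100 bp
## regions around the breakends of previously called SVs.

.kadane_segment <- function(score) {
  ## best-scoring contiguous segment; returns c(score, start, end) (1-based)
  best <- 0; bs <- 0L; be <- -1L
  cur <- 0; cs <- 1L
  for (i in seq_along(score)) {
    if (cur <= 0) { cur <- 0; cs <- i }
    cur <- cur + score[i]
    if (cur > best) { best <- cur; bs <- cs; be <- i }
  }
  c(best, bs, be)
}

#' Find pairs of homologous regions by windowed genome self-comparison
#'
#' Tiles the genome into non-overlapping windows and aligns each window
#' against the whole genome (both strands) with an internal seed-and-extend
#' aligner: exact k-mer seeds, ungapped extension along each seed diagonal
#' (match +1 / mismatch -2, best segment by maximum subarray), and a
#' Karlin-Altschul e-value `E = K m n exp(-lambda S)`. Hits with an e-value
#' strictly below the threshold whose aligned segment covers strictly more
#' than `min_query_coverage` of the window are reported; a window's exact
#' self-hit is excluded. Chromosomes shorter than one window are skipped
#' with a warning. Precomputed tabular alignments can be supplied instead
#' via [homologous_regions_from_alignments()].
#'
#' @param genome Named [Biostrings::DNAStringSet] or FASTA path.
#' @param window Query window size (bp, default 500).
#' @param evalue_threshold Keep hits with e-value strictly below this.
#' @param min_query_coverage Aligned fraction of the window required
#'   (strict).
#' @param k Seed k-mer length.
#' @param karlin_k,karlin_lambda Karlin-Altschul parameters for the +1/-2
#'   scoring scheme.
#' @return BEDPE-style data.frame (`chrom1,start1,end1,chrom2,start2,end2,
#'   name,score,evalue,strand2`); query intervals are whole windows.
#' @export
find_homologous_regions <- function(genome, window = 500,
                                    evalue_threshold = 1e-5,
                                    min_query_coverage = 0.5, k = 11,
                                    karlin_k = 0.41, karlin_lambda = 1.28) {
  if (is.character(genome)) genome <- read_fasta(genome)
  lens <- setNames(Biostrings::width(genome), names(genome))
  short <- lens < window
  if (any(short))
    warning("skipping chromosome(s) shorter than one window: ",
            paste(names(lens)[short], collapse = ", "))
  n_total <- 2 * sum(lens) # both strands
  seqs <- setNames(as.character(genome), names(genome))
  targets <- list()
  for (ch in names(seqs)) {
    targets[[paste0(ch, "+")]] <- list(chrom = ch, strand = "+",
                                       seq = seqs[[ch]])
    targets[[paste0(ch, "-")]] <- list(
      chrom = ch, strand = "-",
      seq = as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seqs[[ch]]))))
  }
  kmers <- function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1) return(character())
    substring(s, 1:n, k:(k + n - 1L))
  }
  target_kmers <- lapply(targets, function(t) kmers(t$seq))
  target_raw <- lapply(targets, function(t) charToRaw(t$seq))

  out <- list()
  hid <- 0L
  for (ch in names(seqs)[!short]) {
    starts <- seq(0L, lens[[ch]] - window, by = window)
    for (ws in starts) {
      wseq <- substr(seqs[[ch]], ws + 1L, ws + window)
      wk <- kmers(wseq)
      wraw <- charToRaw(wseq)
      win_hits <- list()
      for (tn in names(targets)) {
        tk <- target_kmers[[tn]]
        hits <- which(tk %in% wk)
        if (!length(hits)) next
        wpos <- match(tk[hits], wk) # first offset of the seed in the window
        diags <- unique(hits - wpos) # target offset minus window offset
        tinfo <- targets[[tn]]
        tlen <- nchar(tinfo$seq)
        for (d in diags) {
          if (tinfo$chrom == ch && tinfo$strand == "+" && d == ws) next
          qoff <- max(0L, -d)                 # 0-based window offset
          toff <- max(0L, d)                  # 0-based target offset
          L <- min(window - qoff, tlen - toff)
          if (L < k) next
          m <- target_raw[[tn]][(toff + 1L):(toff + L)] ==
            wraw[(qoff + 1L):(qoff + L)]
          seg <- .kadane_segment(ifelse(m, 1, -2))
          S <- seg[1]
          if (S <= 0) next
          E <- karlin_k * window * n_total * exp(-karlin_lambda * S)
          seglen <- seg[3] - seg[2] + 1
          if (E >= evalue_threshold || seglen <= min_query_coverage * window)
            next
          t0 <- toff + seg[2] - 1L # 0-based target segment start
          t1 <- toff + seg[3]      # exclusive end
          if (tinfo$strand == "+") {
            sstart <- t0; send <- t1
          } else {
            sstart <- tlen - t1; send <- tlen - t0
          }
          win_hits[[length(win_hits) + 1L]] <- data.frame(
            chrom2 = tinfo$chrom, sstart = sstart, send = send,
            score = S, evalue = E, strand2 = tinfo$strand)
        }
      }
      if (!length(win_hits)) next
      h <- do.call(rbind, win_hits)
      h <- h[order(-h$score), , drop = FALSE]
      keep <- rep(TRUE, nrow(h))
      for (i in seq_len(nrow(h))) {
        if (!keep[i]) next
        if (i < nrow(h)) for (j in (i + 1):nrow(h)) {
          if (keep[j] && h$chrom2[j] == h$chrom2[i] &&
              h$sstart[j] < h$send[i] && h$send[j] > h$sstart[i])
            keep[j] <- FALSE
        }
      }
      h <- h[keep, , drop = FALSE]
      for (i in seq_len(nrow(h))) {
        hid <- hid + 1L
        out[[hid]] <- data.frame(
          chrom1 = ch, start1 = ws, end1 = ws + window,
          chrom2 = h$chrom2[i], start2 = h$sstart[i], end2 = h$send[i],
          name = sprintf("hom_%d", hid), score = h$score[i],
          evalue = h$evalue[i], strand2 = h$strand2[i])
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom1 = character(), start1 = integer(),
                      end1 = integer(), chrom2 = character(),
                      start2 = integer(), end2 = integer(),
                      name = character(), score = numeric(),
                      evalue = numeric(), strand2 = character()))
  do.call(rbind, out)
}

#' Homologous-region pairs from precomputed tabular alignments
#'
#' Adapter for outfmt-6-style alignment tables of whole-genome windows
#' (qseqid encoded as `chrom:start-end`, 0-based half-open): applies the
#' same e-value, query-coverage and self-hit rules as
#' [find_homologous_regions()].
#'
#' @param aln data.frame with columns `qseqid, sseqid, qstart, qend, sstart,
#'   send, evalue` (1-based inclusive alignment coordinates as emitted by
#'   blastn).
#' @inheritParams find_homologous_regions
#' @return BEDPE-style data.frame as in [find_homologous_regions()].
#' @export
homologous_regions_from_alignments <- function(aln, window = 500,
                                               evalue_threshold = 1e-5,
                                               min_query_coverage = 0.5) {
  m <- regmatches(aln$qseqid, regexec("^(.+):([0-9]+)-([0-9]+)$", aln$qseqid))
  qchrom <- vapply(m, `[`, "", 2)
  qstart <- as.integer(vapply(m, `[`, "", 3))
  qend <- as.integer(vapply(m, `[`, "", 4))
  cov <- (abs(aln$qend - aln$qstart) + 1) / window
  sstart <- pmin(aln$sstart, aln$send) - 1L
  send <- pmax(aln$sstart, aln$send)
  self <- aln$sseqid == qchrom & sstart == qstart + aln$qstart - 1L &
    aln$sstart <= aln$send
  keep <- aln$evalue < evalue_threshold & cov > min_query_coverage & !self
  out <- data.frame(chrom1 = qchrom[keep], start1 = qstart[keep],
                    end1 = qend[keep], chrom2 = aln$sseqid[keep],
                    start2 = sstart[keep], end2 = send[keep],
                    name = sprintf("hom_%d", seq_len(sum(keep))),
                    score = aln$evalue[keep])
  rownames(out) <- NULL
  out
}

#' BEDPE regions around the breakends of known SVs
#'
#' Emits, for every junction of every SV, the pair of +/-`pad` bp intervals
#' around its two breakends, clipped to chromosome bounds when lengths are
#' provided.
#'
#' @param svs An [sv_set()] (e.g. read with [read_sv_tables()]).
#' @param chrom_lengths Optional named chromosome lengths for clipping.
#' @param pad Half-width (bp) of the emitted regions (default 100).
#' @return BEDPE-style data.frame, one row per junction.
#' @export
find_known_sv_regions <- function(svs, chrom_lengths = NULL, pad = 100) {
  bps <- truth_breakpoints(svs)
  clip <- function(x, chrom) {
    x <- pmax(0L, x)
    if (!is.null(chrom_lengths))
      x <- pmin(x, as.integer(chrom_lengths[chrom]))
    x
  }
  if (nrow(bps) == 0)
    return(data.frame(chrom1 = character(), start1 = integer(),
                      end1 = integer(), chrom2 = character(),
                      start2 = integer(), end2 = integer(),
                      name = character()))
  data.frame(
    chrom1 = bps$chrom_1,
    start1 = clip(bps$pos_1 - pad, bps$chrom_1),
    end1 = clip(bps$pos_1 + pad, bps$chrom_1),
    chrom2 = bps$chrom_2,
    start2 = clip(bps$pos_2 - pad, bps$chrom_2),
    end2 = clip(bps$pos_2 + pad, bps$chrom_2),
    name = paste0(bps$sv_id, "_", seq_len(nrow(bps))))
}
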