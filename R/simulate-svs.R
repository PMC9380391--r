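## SV truth sets: construction, random/region-constrained simulation on a
## reference genome, and derivation of the rearranged (template) sequence.

SV_TYPES <- c("deletion", "inversion", "tandem_duplication",
              "translocation", "insertion")

#' Construct an SV truth/call set
#'
#' An `sv_set` is a data.frame with one row per structural variant and a fixed
#' column layout shared by truth sets and call sets:
#' \describe{
#'   \item{id, type}{record id and one of `deletion`, `inversion`,
#'     `tandem_duplication`, `translocation`, `insertion`.}
#'   \item{chrom, start, end}{the affected interval (0-based half-open); for
#'     insertions the *origin* interval; for translocations `start` is the
#'     breakpoint position on `chrom` and `end` is `NA`.}
#'   \item{chrom2, start2}{second locus: insertion destination chromosome and
#'     position, or translocation partner chromosome and breakpoint.}
#'   \item{copy}{insertions only: `TRUE` copy-and-paste, `FALSE`
#'     cut-and-paste.}
#'   \item{inverted}{translocations only: whether one swapped segment is
#'     reverse-complemented.}
#' }
#'
#' @param df data.frame with at least id, type, chrom, start; missing optional
#'   columns are added as `NA`.
#' @return The data.frame with class `sv_set`.
#' @export
sv_set <- function(df = NULL) {
  cols <- c("id", "type", "chrom", "start", "end", "chrom2", "start2",
            "copy", "inverted")
  if (is.null(df) || nrow(df) == 0) {
    df <- data.frame(id = character(), type = character(), chrom = character(),
                     start = integer(), end = integer(), chrom2 = character(),
                     start2 = integer(), copy = logical(), inverted = logical(),
                     stringsAsFactors = FALSE)
  } else {
    for (cl in setdiff(cols, names(df))) df[[cl]] <- NA
    df <- df[, cols]
    bad <- !(df$type %in% SV_TYPES)
    if (any(bad)) stop("unknown SV type: ", df$type[which(bad)[1]])
  }
  rownames(df) <- NULL
  class(df) <- c("sv_set", "data.frame")
  df
}

#' @export
print.sv_set <- function(x, ...) {
  cat("SV set:", nrow(x), "records (",
      paste(names(table(x$type)), table(x$type), sep = ":", collapse = ", "),
      ")\n", sep = " ")
  if (nrow(x)) print(as.data.frame(head(x, 10)))
  invisible(x)
}

sv_interval_edits <- function(truth) {
  ## every interval a record edits (used for conflict checks), incl. point
  ## loci (insertion destinations, translocation breakpoints) as 1 bp
  out <- list()
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    out[[length(out) + 1L]] <- switch(
      r$type,
      deletion = ,
      inversion = ,
      tandem_duplication = data.frame(chrom = r$chrom, start = r$start,
                                      end = r$end, id = r$id),
      insertion = rbind(
        data.frame(chrom = r$chrom, start = r$start, end = r$end, id = r$id),
        data.frame(chrom = r$chrom2, start = r$start2, end = r$start2 + 1L,
                   id = r$id)),
      translocation = rbind(
        data.frame(chrom = r$chrom, start = r$start, end = r$start + 1L,
                   id = r$id),
        data.frame(chrom = r$chrom2, start = r$start2, end = r$start2 + 1L,
                   id = r$id)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

check_sv_conflicts <- function(truth) {
  ed <- sv_interval_edits(truth)
  if (is.null(ed) || nrow(ed) < 2) return(invisible(TRUE))
  for (ch in unique(ed$chrom)) {
    e <- ed[ed$chrom == ch, ]
    e <- e[order(e$start), ]
    if (nrow(e) < 2) next
    ov <- which(e$start[-1] < e$end[-nrow(e)])
    if (length(ov)) {
      i <- ov[1]
      if (e$id[i] != e$id[i + 1])
        stop("conflicting edits on ", ch, ": ", e$id[i], " and ", e$id[i + 1])
    }
  }
  invisible(TRUE)
}

## rejection-sampling placement bookkeeping
.overlaps_any <- function(occ, start, end) {
  if (is.null(occ) || nrow(occ) == 0) return(FALSE)
  any(start < occ$end & end > occ$start)
}

#' Simulate structural variants on a reference genome
#'
#' Places up to `n` SVs of each of five types (deletions, inversions, tandem
#' duplications, translocations, insertions) on the genome, either uniformly
#' at random or constrained so that every breakend falls inside user-provided
#' BEDPE region pairs (e.g. homologous or known-SV regions). Placement uses
#' rejection sampling; records that cannot be placed within `max_attempts`
#' draws are dropped (with a warning summary), so per-type emitted counts may
#' be lower than requested. Variant sizes are drawn uniformly from
#' `size_range * total genome length` with a floor of `min_size`, so larger
#' genomes receive proportionally larger variants.
#'
#' @param genome Named [Biostrings::DNAStringSet] (or path to FASTA).
#' @param n Either a single count applied to every type or a named vector
#'   over a subset of types (default 50 of each).
#' @param regions Optional BEDPE data.frame (see [read_bedpe()]) restricting
#'   breakend placement.
#' @param seed Integer seed.
#' @param size_range Fraction of total genome length bounding variant sizes.
#' @param min_size Minimum variant size (bp).
#' @param max_attempts Placement attempts per record before giving up.
#' @return An [sv_set()] truth set.
#' @export
simulate_svs <- function(genome, n = 50, regions = NULL, seed = 1,
                         size_range = c(1e-4, 1.5e-3), min_size = 50,
                         max_attempts = 1000) {
  if (is.character(genome)) genome <- read_fasta(genome)
  counts <- setNames(rep(0L, 5L), SV_TYPES)
  if (is.null(names(n))) counts[] <- as.integer(n) else {
    bad <- setdiff(names(n), SV_TYPES)
    if (length(bad)) stop("unknown SV type in n: ", bad[1])
    counts[names(n)] <- as.integer(n)
  }
  if (any(counts < 0)) stop("counts must be >= 0")
  lens <- setNames(Biostrings::width(genome), names(genome))
  G <- sum(lens)
  buffer <- max(60L, min_size)
  occ <- list()            # per-chromosome occupied intervals
  trans_used <- character() # chromosomes already carrying a translocation
  res <- list()
  dropped <- setNames(rep(0L, 5L), SV_TYPES)

  set.seed(derive_seed(seed, "simulate_svs"))
  draw_len <- function() {
    max(min_size, round(runif(1, size_range[1] * G, size_range[2] * G)))
  }
  pick_chrom <- function(minlen = 1) {
    ok <- lens >= minlen
    if (!any(ok)) return(NA_character_)
    sample(names(lens)[ok], 1, prob = lens[ok])
  }
  claim <- function(chrom, start, end) {
    occ[[chrom]] <<- rbind(occ[[chrom]],
                           data.frame(start = start - buffer, end = end + buffer))
  }
  free <- function(chrom, start, end) {
    !.overlaps_any(occ[[chrom]], start - buffer, end + buffer) &&
      start >= 0 && end <= lens[chrom]
  }
  pick_in_region <- function(r, i) {
    ## uniform position inside interval i (1 or 2) of BEDPE row r
    s <- r[[paste0("start", i)]]; e <- r[[paste0("end", i)]]
    s + sample.int(max(1L, e - s), 1) - 1L
  }

  kid <- 0L
  for (type in SV_TYPES) {
    for (k in seq_len(counts[type])) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        if (type %in% c("deletion", "inversion", "tandem_duplication")) {
          if (is.null(regions)) {
            len <- draw_len()
            ch <- pick_chrom(len + 2 * buffer)
            if (is.na(ch)) break
            s <- sample.int(lens[ch] - len - 2 * buffer, 1) + buffer
            e <- s + len
          } else {
            r <- regions[sample.int(nrow(regions), 1), ]
            if (r$chrom1 != r$chrom2) next
            ch <- r$chrom1
            s <- pick_in_region(r, 1); e <- pick_in_region(r, 2)
            if (s > e) { tmp <- s; s <- e; e <- tmp }
            if (e - s < min_size) next
          }
          if (!free(ch, s, e)) next
          claim(ch, s, e)
          rec <- data.frame(id = NA, type = type, chrom = ch, start = s, end = e,
                            chrom2 = NA, start2 = NA, copy = NA, inverted = NA)
        } else if (type == "insertion") {
          if (is.null(regions)) {
            len <- draw_len()
            ch <- pick_chrom(len + 2 * buffer)
            if (is.na(ch)) break
            s <- sample.int(lens[ch] - len - 2 * buffer, 1) + buffer
            e <- s + len
            others <- setdiff(names(lens)[lens > 2 * buffer + 2], ch)
            ch2 <- if (length(others)) sample(others, 1, prob = lens[others]) else ch
            d <- sample.int(lens[ch2] - 2 * buffer - 1, 1) + buffer
          } else {
            r <- regions[sample.int(nrow(regions), 1), ]
            ch <- r$chrom1
            s <- pick_in_region(r, 1); e <- pick_in_region(r, 1)
            if (s > e) { tmp <- s; s <- e; e <- tmp }
            if (e - s < min_size) next
            ch2 <- r$chrom2
            d <- pick_in_region(r, 2)
          }
          if (!free(ch, s, e)) next
          if (ch2 == ch && s - buffer < d + 1 + buffer && d - buffer < e + buffer) next
          if (!free(ch2, d, d + 1L)) next
          claim(ch, s, e); claim(ch2, d, d + 1L)
          rec <- data.frame(id = NA, type = type, chrom = ch, start = s, end = e,
                            chrom2 = ch2, start2 = d,
                            copy = runif(1) < 0.5, inverted = NA)
        } else { # translocation
          avail <- setdiff(names(lens)[lens > 10 * buffer], trans_used)
          if (length(avail) < 2) break
          if (is.null(regions)) {
            chs <- sample(avail, 2, prob = lens[avail])
            ## breakpoint uniform in the central 80% of each chromosome
            x <- round(lens[chs[1]] * runif(1, 0.1, 0.9))
            y <- round(lens[chs[2]] * runif(1, 0.1, 0.9))
          } else {
            r <- regions[sample.int(nrow(regions), 1), ]
            chs <- c(r$chrom1, r$chrom2)
            if (chs[1] == chs[2] || !all(chs %in% avail)) next
            x <- pick_in_region(r, 1); y <- pick_in_region(r, 2)
          }
          if (!free(chs[1], x, x + 1L) || !free(chs[2], y, y + 1L)) next
          claim(chs[1], x, x + 1L); claim(chs[2], y, y + 1L)
          trans_used <- c(trans_used, chs)
          rec <- data.frame(id = NA, type = type, chrom = chs[1], start = x,
                            end = NA, chrom2 = chs[2], start2 = y,
                            copy = NA, inverted = runif(1) < 0.5)
        }
        kid <- kid + 1L
        rec$id <- sprintf("%s_%d", type, kid)
        res[[length(res) + 1L]] <- rec
        placed <- TRUE
        break
      }
      if (!placed) dropped[type] <- dropped[type] + 1L
    }
  }
  if (any(dropped > 0))
    warning("could not place ", sum(dropped), " record(s): ",
            paste(names(dropped)[dropped > 0], dropped[dropped > 0],
                  sep = "=", collapse = ", "))
  out <- if (length(res)) sv_set(do.call(rbind, res)) else sv_set()
  attr(out, "genome_lengths") <- lens
  out
}

## net length change caused by edits located strictly before position x
.edit_shift <- function(edits, x) {
  if (is.null(edits) || nrow(edits) == 0) return(0L)
  before <- edits$start < x
  sum(edits$delta[before])
}

#' Apply a truth set to a genome, producing the rearranged sequence
#'
#' Deletions remove their interval, inversions reverse-complement it in
#' place, tandem duplications insert a second copy directly after the
#' original, insertions copy (or cut) the origin segment into the destination
#' position, and translocations swap the terminal segments of two chromosomes
#' (reverse-complementing one side when `inverted`). Edits never overlap
#' (checked; conflicting pairs are reported by id).
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param truth An [sv_set()].
#' @return A [Biostrings::DNAStringSet] with the rearranged chromosomes.
#' @export
apply_svs <- function(genome, truth) {
  if (is.character(genome)) genome <- read_fasta(genome)
  check_sv_conflicts(truth)
  lens <- setNames(Biostrings::width(genome), names(genome))
  validate_intervals(truth$chrom,
                     truth$start,
                     ifelse(is.na(truth$end), truth$start + 1L, truth$end),
                     lens)
  seqs <- setNames(as.character(genome), names(genome))

  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

  ## gather linear edits per chromosome (everything except translocations)
  edits <- list()
  add_edit <- function(chrom, start, end, kind, payload = NA_character_) {
    edits[[length(edits) + 1L]] <<-
      data.frame(chrom = chrom, start = start, end = end, kind = kind,
                 payload = payload, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    switch(r$type,
      deletion = add_edit(r$chrom, r$start, r$end, "del"),
      inversion = add_edit(r$chrom, r$start, r$end, "inv"),
      tandem_duplication = add_edit(r$chrom, r$start, r$end, "tan"),
      insertion = {
        seg <- substr(seqs[[r$chrom]], r$start + 1L, r$end)
        add_edit(r$chrom2, r$start2, r$start2, "ins", seg)
        if (!isTRUE(r$copy)) add_edit(r$chrom, r$start, r$end, "del")
      },
      translocation = NULL)
  }
  edits <- if (length(edits)) do.call(rbind, edits) else NULL

  if (!is.null(edits)) {
    edits$delta <- ifelse(edits$kind == "del", -(edits$end - edits$start),
                   ifelse(edits$kind == "tan", edits$end - edits$start,
                   ifelse(edits$kind == "ins", nchar(edits$payload), 0L)))
    for (ch in unique(edits$chrom)) {
      e <- edits[edits$chrom == ch, ]
      e <- e[order(e$start, decreasing = TRUE), ]
      s <- seqs[[ch]]
      for (j in seq_len(nrow(e))) {
        a <- e$start[j]; b <- e$end[j]
        left <- substr(s, 1L, a)
        mid <- if (b > a) substr(s, a + 1L, b) else ""
        right <- if (b < nchar(s)) substr(s, b + 1L, nchar(s)) else ""
        s <- switch(e$kind[j],
          del = paste0(left, right),
          inv = paste0(left, rc(mid), right),
          tan = paste0(left, mid, mid, right),
          ins = paste0(left, e$payload[j], right))
      }
      seqs[[ch]] <- s
    }
  }

  ## translocations operate on the edited sequences; breakpoints given in
  ## reference coordinates are shifted by the net length change upstream
  tr <- truth[truth$type == "translocation", , drop = FALSE]
  for (i in seq_len(nrow(tr))) {
    r <- tr[i, ]
    ea <- if (is.null(edits)) NULL else edits[edits$chrom == r$chrom, ]
    eb <- if (is.null(edits)) NULL else edits[edits$chrom == r$chrom2, ]
    xa <- r$start + .edit_shift(ea, r$start)
    xb <- r$start2 + .edit_shift(eb, r$start2)
    A <- seqs[[r$chrom]]; B <- seqs[[r$chrom2]]
    A_l <- substr(A, 1L, xa); A_r <- substr(A, xa + 1L, nchar(A))
    B_l <- substr(B, 1L, xb); B_r <- substr(B, xb + 1L, nchar(B))
    if (isTRUE(r$inverted)) {
      seqs[[r$chrom]] <- paste0(A_l, rc(B_l))
      seqs[[r$chrom2]] <- paste0(rc(A_r), B_r)
    } else {
      seqs[[r$chrom]] <- paste0(A_l, B_r)
      seqs[[r$chrom2]] <- paste0(B_l, A_r)
    }
  }

  Biostrings::DNAStringSet(seqs)
}

## ---- truth tables on disk --------------------------------------------------

#' Write/read per-type SV tables
#'
#' One TSV per SV type present (`deletions.tab`, `inversions.tab`,
#' `tandem_duplications.tab`, `translocations.tab`, `insertions.tab`), with
#' headers and 0-based half-open coordinates.
#'
#' @param svs An [sv_set()].
#' @param dir Output directory (created if needed).
#' @return `write_sv_tables`: the directory, invisibly. `read_sv_tables`: an
#'   [sv_set()].
#' @export
write_sv_tables <- function(svs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fname <- c(deletion = "deletions.tab", inversion = "inversions.tab",
             tandem_duplication = "tandem_duplications.tab",
             translocation = "translocations.tab", insertion = "insertions.tab")
  keep <- list(
    deletion = c("id", "chrom", "start", "end"),
    inversion = c("id", "chrom", "start", "end"),
    tandem_duplication = c("id", "chrom", "start", "end"),
    translocation = c("id", "chrom", "start", "chrom2", "start2", "inverted"),
    insertion = c("id", "chrom", "start", "end", "chrom2", "start2", "copy"))
  for (type in SV_TYPES) {
    sub <- svs[svs$type == type, keep[[type]], drop = FALSE]
    write.table(sub, file.path(dir, fname[[type]]), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_sv_tables
#' @export
read_sv_tables <- function(dir) {
  fname <- c(deletion = "deletions.tab", inversion = "inversions.tab",
             tandem_duplication = "tandem_duplications.tab",
             translocation = "translocations.tab", insertion = "insertions.tab")
  out <- list()
  for (type in names(fname)) {
    p <- file.path(dir, fname[[type]])
    if (!file.exists(p)) next
    df <- read.table(p, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    if (!nrow(df)) next
    df$type <- type
    out[[type]] <- df
  }
  if (!length(out)) return(sv_set())
  all <- Reduce(function(a, b) merge(a, b, all = TRUE, sort = FALSE), out)
  sv_set(all)
}
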