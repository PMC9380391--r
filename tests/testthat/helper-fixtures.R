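# Fixtures are generated in code: random genomes, hand-placed truth sets,
# random annotated breakpoint catalogs, and independent straight-line oracles
# for the filter rules and the matching rules.

make_genome <- function(lens, seed = 42) {
  set.seed(seed)
  Biostrings::DNAStringSet(setNames(vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    ""), names(lens)))
}

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# single annotated breakpoint with overridable fields; both breakends share
# the annotations unless a *_2 override is given
make_bp <- function(chrom_1 = "chr1", pos_1 = 10000, orient_1 = "right",
                    chrom_2 = "chr1", pos_2 = 12000, orient_2 = "left", ...) {
  over <- list(...)
  df <- data.frame(chrom_1 = chrom_1, pos_1 = pos_1, orient_1 = orient_1,
                   chrom_2 = chrom_2, pos_2 = pos_2, orient_2 = orient_2,
                   stringsAsFactors = FALSE)
  for (f in svtune:::BE_FIELDS) {
    v <- if (f %in% names(over)) over[[f]] else
      switch(f, qual = 1000, nfrag = 30, vaf_small = 1, vaf_large = 1,
             inexact_hom = 0, microhom = 0, strand_bias = 0.5, has_rp = TRUE,
             has_sr = TRUE, ins_seq = "", tags = "", repeat_ovl = FALSE)
    df[[paste0(f, "_1")]] <- if (paste0(f, "_1") %in% names(over))
      over[[paste0(f, "_1")]] else v
    df[[paste0(f, "_2")]] <- if (paste0(f, "_2") %in% names(over))
      over[[paste0(f, "_2")]] else v
  }
  sv_breakpoints(df)
}

# random annotated catalog covering small/large, intra/inter, all hints
random_catalog <- function(n, seed = 1) {
  set.seed(seed)
  same <- runif(n) < 0.75
  chrom_1 <- sample(c("chr1", "chr2"), n, replace = TRUE)
  chrom_2 <- ifelse(same, chrom_1,
                    ifelse(chrom_1 == "chr1", "chr2", "chr1"))
  pos_1 <- sample.int(5e5, n)
  len <- sample(c(sample(50:900, n, TRUE), sample(1000:50000, n, TRUE)), n)
  pos_2 <- ifelse(same, pos_1 + len, sample.int(5e5, n))
  orient_1 <- sample(c("left", "right"), n, TRUE)
  orient_2 <- sample(c("left", "right"), n, TRUE)
  ann <- function() list(
    qual = runif(n, 0, 2000),
    nfrag = sample(0:40, n, TRUE),
    vaf_small = runif(n),
    vaf_large = runif(n),
    inexact_hom = sample(0:80, n, TRUE),
    microhom = sample(0:80, n, TRUE),
    strand_bias = runif(n),
    has_rp = runif(n) < 0.8,
    has_sr = runif(n) < 0.8,
    ins_seq = replicate(n, switch(sample(4, 1),
      "", strrep("G", sample(10:25, 1)), strrep("C", sample(10:25, 1)),
      paste(sample(c("A", "C", "G", "T"), sample(1:30, 1), TRUE),
            collapse = ""))),
    tags = sample(c("", "NO_ASSEMBLY", "LOW_QUAL", "NO_ASSEMBLY,LOW_QUAL"),
                  n, TRUE, prob = c(0.5, 0.3, 0.1, 0.1)),
    repeat_ovl = runif(n) < 0.3)
  a1 <- ann(); a2 <- ann()
  df <- data.frame(chrom_1, pos_1, orient_1, chrom_2, pos_2, orient_2,
                   stringsAsFactors = FALSE)
  for (f in names(a1)) {
    df[[paste0(f, "_1")]] <- a1[[f]]
    df[[paste0(f, "_2")]] <- a2[[f]]
  }
  sv_breakpoints(df)
}

# independent straight-line reimplementation of the breakend rules, written
# directly from the rule descriptions (scalar, one breakend at a time)
oracle_breakend_pass <- function(bps, i, side, params, istats) {
  g <- function(f) bps[[paste0(f, "_", side)]][i]
  len <- bps$length[i]
  same <- bps$same_chrom[i]
  hint <- bps$type_hint[i]
  small <- isTRUE(same) && !is.na(len) &&
    len < params$max_to_be_considered_small_event
  if (g("nfrag") < params$min_Nfragments) return(FALSE)
  big_event <- !same || len > (istats$median + istats$mad)
  vaf <- if (big_event) g("vaf_large") else g("vaf_small")
  if (vaf < params$min_af) return(FALSE)
  if (g("vaf_small") < params$min_af_EitherSmallOrLargeEvent &&
      g("vaf_large") < params$min_af_EitherSmallOrLargeEvent) return(FALSE)
  if (g("qual") < params$min_QUAL) return(FALSE)
  if (hint == "INV-like" && len < params$min_length_inversions) return(FALSE)
  if (!small && g("inexact_hom") > params$maximum_lenght_inexactHomology)
    return(FALSE)
  if (g("microhom") > params$maximum_microhomology) return(FALSE)
  if (small && g("strand_bias") > params$maximum_strand_bias) return(FALSE)
  if (params$filter_noReadPairs && !small && !g("has_rp")) return(FALSE)
  if (params$filter_noSplitReads && small && !g("has_sr")) return(FALSE)
  if (params$filter_overlappingRepeats && g("repeat_ovl")) return(FALSE)
  if (params$filter_polyGC) {
    runs <- gregexpr("G+|C+", g("ins_seq"))[[1]]
    if (runs[1] != -1 && max(attr(runs, "match.length")) > 15) return(FALSE)
  }
  tags <- strsplit(g("tags"), ",")[[1]]
  if (length(intersect(tags, params$wrong_FILTERtags)) > 0) return(FALSE)
  r <- params$range_filt_DEL_breakpoints
  if (hint == "DEL-like" && len >= r[1] && len <= r[2] &&
      g("inexact_hom") > 5) return(FALSE)
  if (small && hint == "DEL-like" &&
      nchar(g("ins_seq")) > (len - params$dif_between_insert_and_del))
    return(FALSE)
  TRUE
}

# independent all-pairs matcher oracle, written from the matching rules
oracle_match <- function(a, b, cfg) {
  if (a$type != b$type) return(FALSE)
  ro_ok <- function(s1, e1, s2, e2) {
    inter <- max(0, min(e1, e2) - max(s1, s2))
    inter >= cfg$overlap_fraction * (e1 - s1) &&
      inter >= cfg$overlap_fraction * (e2 - s2)
  }
  if (a$type %in% c("deletion", "inversion", "tandem_duplication")) {
    return(a$chrom == b$chrom && ro_ok(a$start, a$end, b$start, b$end) &&
             abs(a$start - b$start) < cfg$breakend_dist &&
             abs(a$end - b$end) < cfg$breakend_dist)
  }
  if (a$type == "insertion") {
    return(a$chrom == b$chrom && a$chrom2 == b$chrom2 &&
             isTRUE(a$copy) == isTRUE(b$copy) &&
             ro_ok(a$start, a$end, b$start, b$end) &&
             abs(a$start - b$start) < cfg$breakend_dist &&
             abs(a$end - b$end) < cfg$breakend_dist &&
             abs(a$start2 - b$start2) < cfg$insertion_site_dist)
  }
  # translocation
  ach <- c(a$chrom, a$chrom2); bch <- c(b$chrom, b$chrom2)
  apos <- c(a$start, a$start2); bpos <- c(b$start, b$start2)
  oa <- order(ach); ob <- order(bch)
  identical(ach[oa], bch[ob]) &&
    isTRUE(a$inverted) == isTRUE(b$inverted) &&
    all(abs(apos[oa] - bpos[ob]) < cfg$breakend_dist)
}

oracle_compare <- function(called, known, cfg) {
  per <- lapply(svtune:::SV_TYPES, function(type) {
    A <- called[called$type == type, , drop = FALSE]
    B <- known[known$type == type, , drop = FALSE]
    ch <- rep(FALSE, nrow(A)); kh <- rep(FALSE, nrow(B))
    if (nrow(A) && nrow(B))
      for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
        if (oracle_match(A[i, ], B[j, ], cfg)) { ch[i] <- TRUE; kh[j] <- TRUE }
    c(TP = sum(ch), FP = nrow(A) - sum(ch), FN = sum(!kh))
  })
  do.call(rbind, per)
}

# random SV call/truth sets for matcher property tests
random_sv_set <- function(n, seed = 1, jitter = 0) {
  set.seed(seed)
  types <- sample(svtune:::SV_TYPES, n, replace = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    type <- types[i]
    chrom <- sample(c("chr1", "chr2", "chr3"), 1)
    s <- sample.int(1e6, 1)
    len <- sample(100:5000, 1)
    j <- function() sample((-jitter):jitter, 1)
    if (type %in% c("deletion", "inversion", "tandem_duplication")) {
      data.frame(id = paste0("r", i), type = type, chrom = chrom,
                 start = s + (if (jitter) j() else 0), end = s + len +
                   (if (jitter) j() else 0), chrom2 = NA, start2 = NA,
                 copy = NA, inverted = NA)
    } else if (type == "insertion") {
      data.frame(id = paste0("r", i), type = type, chrom = chrom, start = s,
                 end = s + len, chrom2 = sample(c("chr4", "chr5"), 1),
                 start2 = sample.int(1e6, 1), copy = runif(1) < 0.5,
                 inverted = NA)
    } else {
      data.frame(id = paste0("r", i), type = type, chrom = chrom, start = s,
                 end = NA, chrom2 = sample(c("chr4", "chr5"), 1),
                 start2 = sample.int(1e6, 1), copy = NA,
                 inverted = runif(1) < 0.5)
    }
  })
  sv_set(do.call(rbind, rows))
}

# expected +/-50 bp junction sequences implied by a breakpoint, built from
# the reference; used to check simulator/emulator coordinate agreement
junction_candidates <- function(genome, bp_row, flank = 50) {
  seqs <- setNames(as.character(genome), names(genome))
  side_seq <- function(chrom, pos, orient, role) {
    s <- seqs[[chrom]]
    if (role == "left") {
      if (orient == "right") substr(s, pos - flank + 1, pos)
      else revcomp_chr(substr(s, pos + 1, pos + flank))
    } else {
      if (orient == "left") substr(s, pos + 1, pos + flank)
      else revcomp_chr(substr(s, pos - flank + 1, pos))
    }
  }
  r <- bp_row
  c(paste0(side_seq(r$chrom_1, r$pos_1, r$orient_1, "left"),
           side_seq(r$chrom_2, r$pos_2, r$orient_2, "right")),
    paste0(side_seq(r$chrom_2, r$pos_2, r$orient_2, "left"),
           side_seq(r$chrom_1, r$pos_1, r$orient_1, "right")))
}

genome_contains <- function(genome, pattern) {
  any(vapply(seq_along(genome), function(i) {
    s <- genome[[i]]
    Biostrings::countPattern(pattern, s) > 0 ||
      Biostrings::countPattern(pattern,
                               Biostrings::reverseComplement(s)) > 0
  }, TRUE))
}
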