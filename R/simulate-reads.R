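## Paired-end read simulation from a reference/variant genome pair at a given
## ploidy/zygosity, plus downsampling. The ploidy specification controls the
## mixing ratio between fragments drawn from the reference and from the
## variant (rearranged) genome:
##   haploid, diploid_homo  -> all fragments from the variant genome
##   diploid_hetero         -> reference : variant mixed 1:1
##   ref:<n>_var:<m>        -> mixed n:m (e.g. ref:3_var:1 for one variant
##                             copy in a tetraploid)

#' Parse a ploidy specification into the variant-fragment fraction
#'
#' @param ploidy One of `"haploid"`, `"diploid_homo"`, `"diploid_hetero"` or
#'   `"ref:<nref>_var:<nvar>"`.
#' @return Fraction of fragments drawn from the variant genome.
#' @export
ploidy_variant_fraction <- function(ploidy) {
  if (ploidy %in% c("haploid", "diploid_homo")) return(1)
  if (ploidy == "diploid_hetero") return(0.5)
  m <- regmatches(ploidy, regexec("^ref:([0-9]+)_var:([0-9]+)$", ploidy))[[1]]
  if (length(m) != 3) stop("bad ploidy spec: ", ploidy)
  nref <- as.integer(m[2]); nvar <- as.integer(m[3])
  if (nref < 1 || nvar < 1) stop("ref/var copy numbers must be positive: ", ploidy)
  nvar / (nref + nvar)
}

#' Read-simulation parameters
#'
#' @param read_length Read length (bp); must be below the insert median.
#' @param insert_median,insert_mad Median and median absolute deviation (bp)
#'   of the fragment (insert) size distribution.
#' @param coverage Target sequencing depth (x).
#' @param ploidy Ploidy specification string (see
#'   [ploidy_variant_fraction()]).
#' @param error_rate Per-base substitution error rate.
#' @return A list of class `read_sim_params`.
#' @export
read_sim_params <- function(read_length = 100, insert_median = 300,
                            insert_mad = 50, coverage = 30,
                            ploidy = "haploid", error_rate = 0.001) {
  if (read_length >= insert_median)
    stop("read_length must be smaller than insert_median")
  if (coverage <= 0) stop("coverage must be > 0")
  ploidy_variant_fraction(ploidy) # validates the spec
  structure(list(read_length = as.integer(read_length),
                 insert_median = as.integer(insert_median),
                 insert_mad = as.integer(insert_mad),
                 coverage = coverage, ploidy = ploidy,
                 error_rate = error_rate),
            class = "read_sim_params")
}

.sample_fragments <- function(genome, n, params) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  usable <- lens >= params$insert_median
  if (!any(usable)) return(NULL)
  if (any(!usable))
    warning("skipping chromosome(s) shorter than the insert size: ",
            paste(names(genome)[!usable], collapse = ", "))
  lens <- lens[usable]
  chrom_idx <- sample.int(length(lens), n, replace = TRUE, prob = lens)
  frag <- as.integer(round(rnorm(n, params$insert_median,
                                 params$insert_mad * 1.4826)))
  frag <- pmax(frag, params$read_length)
  frag <- pmin(frag, lens[chrom_idx])
  start <- floor(runif(n) * (lens[chrom_idx] - frag)) + 1L # 1-based
  data.frame(chrom = names(lens)[chrom_idx], start = start, frag = frag)
}

.inject_errors <- function(reads, rate) {
  n_bases <- sum(Biostrings::width(reads))
  n_err <- rbinom(1, n_bases, rate)
  if (n_err == 0) return(reads)
  chars <- as.character(reads)
  ridx <- sample.int(length(chars), n_err, replace = TRUE)
  for (k in seq_len(n_err)) {
    i <- ridx[k]
    p <- sample.int(nchar(chars[i]), 1)
    orig <- substr(chars[i], p, p)
    substr(chars[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), orig), 1)
  }
  Biostrings::DNAStringSet(chars)
}

#' Simulate paired-end reads at a given ploidy/zygosity
#'
#' Fragments are drawn from the reference and variant genomes at the ratio
#' implied by the ploidy spec; the expected number of pairs is
#' `coverage * genome_length / (2 * read_length)`. Fragment lengths follow a
#' normal distribution with the configured median and MAD; read 2 is the
#' reverse complement of the fragment end.
#'
#' @param ref_genome,var_genome Named [Biostrings::DNAStringSet]s; the
#'   reference and the rearranged (variant) genome. `var_genome` may be the
#'   same object as `ref_genome`.
#' @param params A [read_sim_params()] object.
#' @param seed Integer seed.
#' @return A list of class `sv_reads` with elements `read1`, `read2`
#'   (DNAStringSets), `origin` (`"ref"`/`"var"` per pair), `fragments`
#'   (fragment lengths) and `params`.
#' @export
simulate_reads <- function(ref_genome, var_genome, params = read_sim_params(),
                           seed = 1) {
  set.seed(derive_seed(seed, "simulate_reads"))
  G <- sum(Biostrings::width(ref_genome))
  n_pairs <- round(params$coverage * G / (2 * params$read_length))
  fv <- ploidy_variant_fraction(params$ploidy)
  n_var <- rbinom(1, n_pairs, fv)
  pools <- list(ref = n_pairs - n_var, var = n_var)
  genomes <- list(ref = ref_genome, var = var_genome)
  r1 <- list(); r2 <- list(); origin <- character(); fragments <- integer()
  for (src in c("ref", "var")) {
    n <- pools[[src]]
    if (n == 0) next
    fr <- .sample_fragments(genomes[[src]], n, params)
    if (is.null(fr)) next
    gr <- genomes[[src]]
    L <- params$read_length
    at1 <- IRanges::IRanges(fr$start, width = L)
    at2 <- IRanges::IRanges(fr$start + fr$frag - L, width = L)
    by_chrom <- split(seq_len(nrow(fr)), fr$chrom)
    a_parts <- list(); b_parts <- list()
    for (ch in names(by_chrom)) {
      ii <- by_chrom[[ch]]
      a_parts[[ch]] <- Biostrings::extractAt(gr[[ch]], at1[ii])
      b_parts[[ch]] <- Biostrings::extractAt(gr[[ch]], at2[ii])
    }
    ord <- order(unlist(by_chrom, use.names = FALSE))
    a <- do.call(c, unname(a_parts))[ord]
    b <- do.call(c, unname(b_parts))[ord]
    b <- Biostrings::reverseComplement(b)
    if (params$error_rate > 0) {
      a <- .inject_errors(a, params$error_rate)
      b <- .inject_errors(b, params$error_rate)
    }
    r1[[src]] <- a; r2[[src]] <- b
    origin <- c(origin, rep(src, nrow(fr)))
    fragments <- c(fragments, fr$frag)
  }
  read1 <- do.call(c, unname(r1))
  read2 <- do.call(c, unname(r2))
  ids <- sprintf("pair_%d", seq_along(origin))
  names(read1) <- paste0(ids, "/1"); names(read2) <- paste0(ids, "/2")
  structure(list(read1 = read1, read2 = read2, origin = origin,
                 fragments = fragments, params = params),
            class = "sv_reads")
}

#' @export
print.sv_reads <- function(x, ...) {
  cat("Paired reads:", length(x$read1), "pairs,",
      x$params$read_length, "bp,", "ploidy", x$params$ploidy, "\n")
  invisible(x)
}

#' Write a simulated read pair as gzipped FASTQ files
#'
#' @param reads An `sv_reads` object from [simulate_reads()].
#' @param prefix Output prefix; writes `<prefix>_1.fastq.gz` and
#'   `<prefix>_2.fastq.gz`.
#' @return The two paths, invisibly.
#' @export
write_fastq_pair <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq.gz", "_2.fastq.gz"))
  qual <- function(x) Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(reads$read1, paths[1], format = "fastq",
                              compress = TRUE, qualities = qual(reads$read1))
  Biostrings::writeXStringSet(reads$read2, paths[2], format = "fastq",
                              compress = TRUE, qualities = qual(reads$read2))
  invisible(paths)
}

#' Randomly downsample a read pair to a target coverage
#'
#' Keeps each pair independently with probability `target / current`,
#' preserving pairing.
#'
#' @param reads An `sv_reads` object.
#' @param target_coverage Desired coverage; must not exceed the current one.
#' @param seed Integer seed.
#' @return A downsampled `sv_reads` object.
#' @export
downsample_reads <- function(reads, target_coverage, seed = 1) {
  current <- reads$params$coverage
  if (target_coverage > current)
    stop("target coverage (", target_coverage,
         ") exceeds current coverage (", current, ")")
  if (target_coverage == current) return(reads)
  set.seed(derive_seed(seed, "downsample_reads"))
  keep <- runif(length(reads$read1)) < target_coverage / current
  out <- reads
  out$read1 <- reads$read1[keep]
  out$read2 <- reads$read2[keep]
  out$origin <- reads$origin[keep]
  out$fragments <- reads$fragments[keep]
  out$params$coverage <- target_coverage
  out
}
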