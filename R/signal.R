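# Coverage tracks are GRanges step functions (score = RPM); queries convert
# them once to a per-chromosome Rle and read means off Views.

.track_rle <- function(track) {
  stopifnot(methods::is(track, "GRanges"), !is.null(track$score))
  if (any(is.na(GenomeInfoDb::seqlengths(track))))
    stop("coverage track must carry chromosome lengths (seqinfo)")
  GenomicRanges::coverage(track, weight = "score")
}

#' Mean coverage of a track over regions
#'
#' Computes, for each region, the average of the step-function track over
#' the region's bases: sum(value x covered bp) / width.  Bases not covered
#' by any track record contribute 0.
#'
#' @param track Coverage `GRanges` with a `score` column and seqlengths.
#' @param regions `GRanges` of query regions, each within its chromosome.
#' @return Numeric vector, one mean (RPM) per region, in input order.
#' @examples
#' gn <- genome_from_lengths(c(chrT = 200))
#' tr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(c(1, 101), c(100, 200)),
#'                              score = c(2, 4), seqinfo = gn)
#' mean_coverage(tr, GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 200),
#'                                          seqinfo = gn))  # 3
#' @export
mean_coverage <- function(track, regions) {
  stopifnot(methods::is(regions, "GRanges"))
  rl <- .track_rle(track)
  out <- numeric(length(regions))
  if (length(regions) == 0) return(out)
  sl <- GenomeInfoDb::seqlengths(track)
  chr <- as.character(GenomeInfoDb::seqnames(regions))
  if (any(!chr %in% names(rl)))
    stop("region chromosome absent from track genome: ",
         chr[!chr %in% names(rl)][1])
  if (any(BiocGenerics::start(regions) < 1) ||
      any(BiocGenerics::end(regions) > sl[chr]))
    stop("region outside chromosome bounds")
  for (ch in unique(chr)) {
    i <- which(chr == ch)
    v <- IRanges::Views(rl[[ch]],
                        start = BiocGenerics::start(regions)[i],
                        end = BiocGenerics::end(regions)[i])
    out[i] <- IRanges::viewMeans(v)
  }
  out
}

#' Genome-wide mean of a coverage track
#'
#' Total signal mass divided by total genome length (implicit zeros
#' included).  Used as the default threshold separating active from primed
#' enhancers on the H3K27ac track.
#'
#' @param track Coverage `GRanges` with `score` and seqlengths.
#' @return A single RPM value.
#' @export
genome_mean_coverage <- function(track) {
  sl <- GenomeInfoDb::seqlengths(track)
  if (any(is.na(sl))) stop("track must carry chromosome lengths")
  sum(as.numeric(track$score) * BiocGenerics::width(track)) / sum(as.numeric(sl))
}

#' 1x-depth (RPGC) scale factor
#'
#' Reads-per-genomic-content normalization scales raw extended-read
#' coverage so that the genome-wide mean depth is 1x.  Sequencing depth is
#' mapped reads x fragment length / effective genome size, so the scale
#' factor is its reciprocal.
#'
#' @param n_mapped Total mapped reads (> 0).
#' @param fragment_length Fragment length in bp (> 0) to which reads are
#'   extended.
#' @param egs Effective genome size in bp (> 0); see
#'   [effective_genome_size()].
#' @return The multiplicative factor `egs / (n_mapped * fragment_length)`.
#' @examples
#' rpgc_scale_factor(1000, 100, 100000)  # exactly 1x depth -> 1
#' @export
rpgc_scale_factor <- function(n_mapped, fragment_length, egs) {
  if (!all(is.finite(c(n_mapped, fragment_length, egs))) ||
      n_mapped <= 0 || fragment_length <= 0 || egs <= 0)
    stop("n_mapped, fragment_length and egs must all be positive")
  egs / (n_mapped * fragment_length)
}

#' Effective genome size
#'
#' The portion of the genome usable for coverage normalization, computed as
#' the count of non-N bases in the genome FASTA.  When no FASTA is
#' available the sum of chromosome lengths is used instead; the value can
#' always be overridden downstream.
#'
#' @param fasta Optional genome FASTA path.
#' @param genome Optional `Seqinfo` fallback.
#' @return Effective genome size in bp.
#' @export
effective_genome_size <- function(fasta = NULL, genome = NULL) {
  if (!is.null(fasta)) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    if (length(seqs) == 0) stop("FASTA contains no sequences: ", fasta)
    af <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
    return(sum(af[, c("A", "C", "G", "T")]))
  }
  if (!is.null(genome)) {
    stopifnot(methods::is(genome, "Seqinfo"))
    return(sum(as.numeric(GenomeInfoDb::seqlengths(genome))))
  }
  stop("supply a FASTA path or a genome")
}

.positions_by_chrom <- function(x, what) {
  if (is.numeric(x)) x <- list(`.` = x)
  if (!is.list(x) || length(x) == 0 || sum(lengths(x)) == 0)
    stop("cannot estimate fragment length: no ", what, " reads")
  lapply(x, as.numeric)
}

#' Estimate fragment length by strand cross-correlation
#'
#' The classic cross-coverage construction: plus-strand 5' read-start
#' density and minus-strand 5' read-end density are binned, the minus
#' density is shifted left by each candidate shift, and the Pearson
#' correlation between the two densities is recorded.  The fragment length
#' is the shift maximizing the correlation.  Shifts within
#' `read_length +/- 10` bp are excluded from the argmax (the "phantom
#' peak" at the read length, an artifact of mappability, would otherwise
#' shadow the true fragment-length peak).
#'
#' @param plus_starts Plus-strand 5' read positions: a numeric vector (one
#'   chromosome) or a named list of vectors per chromosome.
#' @param minus_ends Minus-strand 5' read-end positions (fragment ends),
#'   same structure.
#' @param max_shift Largest shift searched, bp (default 400).
#' @param read_length Read length in bp, used for the phantom-peak guard.
#' @param bin Bin width in bp for the density vectors (default 10; the
#'   estimate has this resolution).
#' @param exclude_read_length Apply the phantom-peak guard (default TRUE).
#' @return A list of class `fragment_length_estimate` with `best_shift`
#'   (bp), `profile` (data.frame of shift and correlation score over the
#'   full search range) and `read_length`.
#' @export
estimate_fragment_length <- function(plus_starts, minus_ends,
                                     max_shift = 400L, read_length = 36L,
                                     bin = 10L, exclude_read_length = TRUE) {
  stopifnot(max_shift >= read_length, bin >= 1)
  plus <- .positions_by_chrom(plus_starts, "plus-strand")
  minus <- .positions_by_chrom(minus_ends, "minus-strand")
  chroms <- union(names(plus), names(minus))

  shifts <- seq(0L, as.integer(max_shift), by = as.integer(bin))
  kmax <- length(shifts) - 1L
  pv <- list(); mv <- list()
  for (ch in chroms) {
    p <- plus[[ch]]; m <- minus[[ch]]
    hi <- max(c(p, m, 0)) + max_shift + bin
    nbin <- ceiling(hi / bin)
    pv[[ch]] <- tabulate(pmin(nbin, floor(c(p) / bin) + 1L), nbins = nbin)
    mv[[ch]] <- tabulate(pmin(nbin, floor(c(m) / bin) + 1L), nbins = nbin)
  }
  score <- vapply(seq_along(shifts), function(si) {
    k <- si - 1L
    a <- numeric(0); b <- numeric(0)
    for (ch in chroms) {
      n <- length(pv[[ch]])
      a <- c(a, pv[[ch]][seq_len(n - kmax)])
      b <- c(b, mv[[ch]][seq_len(n - kmax) + k])
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }, numeric(1))

  profile <- data.frame(shift = shifts, score = score)
  candidate <- rep(TRUE, length(shifts))
  if (exclude_read_length)
    candidate <- abs(shifts - read_length) > 10
  if (!any(candidate)) stop("phantom-peak guard excluded every shift")
  best <- shifts[candidate][which.max(score[candidate])]
  structure(list(best_shift = best, profile = profile,
                 read_length = as.integer(read_length)),
            class = "fragment_length_estimate")
}

#' @export
print.fragment_length_estimate <- function(x, ...) {
  cat("Fragment-length estimate:", x$best_shift, "bp",
      "(cross-correlation over shifts 0..",
      max(x$profile$shift), "bp, read length ", x$read_length, "bp)\n")
  invisible(x)
}

#' Read strand-split read-start positions from TSV
#'
#' Accepts the 3-column (chrom, position, strand) convention: plus-strand
#' rows carry the 5' read start, minus-strand rows the 5' read end
#' (fragment end), both 0-based.
#'
#' @param path TSV path.
#' @return A list with `plus` and `minus`, each a named list of numeric
#'   position vectors per chromosome.
#' @export
read_read_starts <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("chrom", "pos", "strand"),
                           colClasses = c("character", "numeric", "character"))
  if (any(!tab$strand %in% c("+", "-")))
    stop("strand column must be '+' or '-'")
  list(plus = split(tab$pos[tab$strand == "+"], tab$chrom[tab$strand == "+"]),
       minus = split(tab$pos[tab$strand == "-"], tab$chrom[tab$strand == "-"]))
}

#' Write strand-split read positions as TSV
#'
#' @param reads A list with `plus`/`minus` per-chromosome position lists,
#'   as produced by [simulate_reads_for_fraglen()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_read_starts <- function(reads, path) {
  rows <- list()
  for (st in c("plus", "minus")) {
    sym <- if (st == "plus") "+" else "-"
    for (ch in names(reads[[st]])) {
      p <- reads[[st]][[ch]]
      if (length(p))
        rows[[length(rows) + 1L]] <- data.frame(chrom = ch, pos = p,
                                                strand = sym)
    }
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
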