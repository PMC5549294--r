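#' Read a chromosome-sizes table
#'
#' Parses the standard two-column (name, length) TSV emitted by genome
#' tooling (e.g. `samtools faidx` + cut, or UCSC `fetchChromSizes`) into a
#' [GenomeInfoDb::Seqinfo] object.  The `Seqinfo` is the coordinate universe
#' for every interval collection in this package: chromosome order in the
#' file defines genome order, and all windows, calls and tracks are sorted
#' by it.
#'
#' @param path Path to a chrom.sizes file (two whitespace-separated columns:
#'   chromosome name, length in bp).
#' @return A `Seqinfo` with the file's chromosomes in file order.
#' @examples
#' f <- tempfile()
#' writeLines(c("chrA\t1000", "chrB\t500"), f)
#' read_chrom_sizes(f)
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"),
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab$chrom))
    stop("duplicate chromosome name in ", path, ": ",
         tab$chrom[duplicated(tab$chrom)][1])
  if (any(!is.finite(tab$length)) || any(tab$length <= 0))
    stop("chromosome lengths must be positive integers in ", path)
  GenomeInfoDb::Seqinfo(seqnames = tab$chrom, seqlengths = as.integer(tab$length))
}

#' Construct a genome from named chromosome lengths
#'
#' Convenience constructor used throughout the examples and the simulator.
#'
#' @param lengths Named numeric vector of chromosome lengths (bp); names are
#'   chromosome names, order defines genome order.
#' @return A [GenomeInfoDb::Seqinfo].
#' @export
genome_from_lengths <- function(lengths) {
  stopifnot(!is.null(names(lengths)), all(lengths > 0))
  GenomeInfoDb::Seqinfo(seqnames = names(lengths),
                        seqlengths = as.integer(lengths))
}

#' Tile a genome into fixed-width scan windows
#'
#' Splits every chromosome into consecutive windows of `window_size` bp,
#' the unit at which the enhancer classifier scores the genome.  The last
#' window of each chromosome is truncated to the chromosome end, so the
#' windows tile each chromosome exactly: no gaps, no overlaps.
#'
#' @param genome A `Seqinfo` (see [read_chrom_sizes()]).
#' @param window_size Window width in bp (default 200, the scan resolution
#'   used for enhancer prediction).
#' @return A `GRanges` of windows in genome order, with an `index` metadata
#'   column giving the ordinal of each window along the scan.
#' @examples
#' gn <- genome_from_lengths(c(chrT = 500))
#' make_windows(gn, 200)   # [1,200], [201,400], [401,500]
#' @export
make_windows <- function(genome, window_size = 200L) {
  stopifnot(methods::is(genome, "Seqinfo"), window_size >= 1)
  if (length(genome) == 0)
    return(GenomicRanges::GRanges(seqinfo = genome, index = integer(0)))
  w <- GenomicRanges::tileGenome(GenomeInfoDb::seqlengths(genome),
                                 tilewidth = as.integer(window_size),
                                 cut.last.tile.in.chrom = TRUE)
  GenomeInfoDb::seqinfo(w) <- genome
  w$index <- seq_along(w)
  w
}

#' Merge intervals that are within a maximum gap of each other
#'
#' Merges intervals separated by at most `max_gap` uncovered bases into
#' single continuous regions.  With the default `max_gap = 1`, adjacent
#' windows (gap 0) and windows separated by a single base both merge --
#' the rule used to join consecutive enhancer-classified windows into
#' enhancer elements.
#'
#' @param x A `GRanges`.
#' @param max_gap Maximum gap (bp) closed by the merge (default 1).
#' @return A sorted `GRanges`; any two output intervals are separated by a
#'   gap strictly greater than `max_gap`.  Idempotent and order-insensitive.
#' @export
merge_intervals <- function(x, max_gap = 1L) {
  stopifnot(methods::is(x, "GRanges"), max_gap >= 0)
  GenomicRanges::reduce(x, min.gapwidth = as.integer(max_gap) + 1L,
                        ignore.strand = TRUE)
}

#' Pairwise overlap in base pairs
#'
#' @param a,b `GRanges` of equal length; overlap is computed element-wise.
#' @return Integer vector of shared bases; 0 for pairs on different
#'   chromosomes or with no overlap.
#' @export
overlap_bp <- function(a, b) {
  stopifnot(methods::is(a, "GRanges"), methods::is(b, "GRanges"),
            length(a) == length(b))
  ov <- pmin(BiocGenerics::end(a), BiocGenerics::end(b)) -
    pmax(BiocGenerics::start(a), BiocGenerics::start(b)) + 1L
  same <- as.character(GenomeInfoDb::seqnames(a)) ==
    as.character(GenomeInfoDb::seqnames(b))
  as.integer(pmax(0L, ov) * same)
}

#' Nearest feature to each query interval
#'
#' For each query, finds the feature (e.g. gene) minimizing the edge-to-edge
#' gap distance on the same chromosome; overlapping pairs have distance 0.
#' Distances are unstranded and signed: negative when the feature lies 5'
#' (lower coordinates) of the query on the forward axis.  Ties are broken
#' deterministically by (lower feature start, then lexicographic id).
#' Queries with no feature on their chromosome are flagged `unassigned`
#' rather than raising an error.
#'
#' @param query `GRanges` of query intervals (e.g. peaks).
#' @param features Non-empty `GRanges` of features (e.g. genes).
#' @param ids Character vector of feature identifiers; defaults to
#'   `names(features)`, then a `gene_id` metadata column, then ordinals.
#' @return A `data.frame` with one row per query: `feature_id`, signed
#'   `distance` (bp), and logical `unassigned`.
#' @export
nearest_feature <- function(query, features, ids = NULL) {
  stopifnot(methods::is(query, "GRanges"), methods::is(features, "GRanges"))
  if (length(features) == 0) stop("'features' must be non-empty")
  if (is.null(ids)) {
    ids <- names(features)
    if (is.null(ids) && !is.null(features$gene_id)) ids <- features$gene_id
    if (is.null(ids)) ids <- as.character(seq_along(features))
  }
  stopifnot(length(ids) == length(features))

  out <- data.frame(feature_id = rep(NA_character_, length(query)),
                    distance = rep(NA_real_, length(query)),
                    unassigned = rep(TRUE, length(query)),
                    stringsAsFactors = FALSE)
  if (length(query) == 0) return(out)

  fchr <- as.character(GenomeInfoDb::seqnames(features))
  fstart <- BiocGenerics::start(features)
  fend <- BiocGenerics::end(features)
  qchr <- as.character(GenomeInfoDb::seqnames(query))
  qstart <- BiocGenerics::start(query)
  qend <- BiocGenerics::end(query)
  by_chrom <- split(seq_along(features), fchr)

  for (qi in seq_along(query)) {
    fi <- by_chrom[[qchr[qi]]]
    if (is.null(fi)) next
    # edge-to-edge gap; overlapping or book-ended pairs have distance 0.
    # distanceToNearest(select = "all") does not enumerate equal-distance
    # ties on both sides, so distances are computed directly here.
    gap <- pmax(0L, pmax(fstart[fi] - qend[qi], qstart[qi] - fend[fi]) - 1L)
    best <- min(gap)
    cand <- fi[gap == best]
    pick <- cand[order(fstart[cand], ids[cand])][1]
    dist <- best
    if (dist > 0 && fend[pick] < qstart[qi]) dist <- -dist
    out$feature_id[qi] <- ids[pick]
    out$distance[qi] <- dist
    out$unassigned[qi] <- FALSE
  }
  out
}

#' Scan configuration
#'
#' Collects the tunable parameters of the enhancer-prediction pipeline with
#' their defaults: 200-bp scan windows, merging of enhancer windows within
#' 1 bp of each other, DHS validation at q < 0.01 requiring at least 1 bp of
#' overlap, promoter negatives at TSS +/- 1 kb, a 1/3 held-out test split,
#' +/- 3 kb metagene flanks, and the -250/+1000 bp promoter-proximal window.
#'
#' @param window_size Scan window width, bp.
#' @param merge_gap Maximum gap closed when merging enhancer windows, bp.
#' @param dhs_q_max Maximum q-value (FDR) for a DHS peak to count as
#'   validating evidence.
#' @param min_dhs_overlap Minimum overlap (bp) between a call and a DHS peak.
#' @param promoter_flank Half-width of the promoter negatives around the
#'   TSS, bp.
#' @param test_fraction Fraction of the training set held out for testing.
#' @param metagene_flank Half-width of metagene/heatmap matrices around the
#'   element midpoint, bp.
#' @param promoter_upstream,promoter_downstream Promoter-proximal window
#'   relative to the TSS (strand-aware), bp.
#' @param h3k27ac_active_threshold RPM threshold separating active from
#'   primed enhancers; `NULL` (default) uses the genome-wide mean of the
#'   supplied H3K27ac track.
#' @param prob_threshold Classifier probability above which a window is
#'   classed as enhancer.
#' @param flank Symmetric flank (bp) added to each element before computing
#'   its mean-coverage features; 0 means the element body alone.
#' @param n_trees Number of trees in the random forest.
#' @return A named list of class `scan_config`.
#' @export
scan_config <- function(window_size = 200L, merge_gap = 1L,
                        dhs_q_max = 0.01, min_dhs_overlap = 1L,
                        promoter_flank = 1000L, test_fraction = 1 / 3,
                        metagene_flank = 3000L,
                        promoter_upstream = 250L, promoter_downstream = 1000L,
                        h3k27ac_active_threshold = NULL,
                        prob_threshold = 0.5, flank = 0L, n_trees = 500L) {
  stopifnot(window_size >= 1, merge_gap >= 0,
            dhs_q_max > 0, dhs_q_max < 1, min_dhs_overlap >= 1,
            promoter_flank >= 1, test_fraction > 0, test_fraction < 1,
            metagene_flank >= 1, promoter_upstream >= 0,
            promoter_downstream >= 0, prob_threshold >= 0,
            prob_threshold <= 1, flank >= 0, n_trees >= 1)
  structure(list(window_size = as.integer(window_size),
                 merge_gap = as.integer(merge_gap),
                 dhs_q_max = dhs_q_max,
                 min_dhs_overlap = as.integer(min_dhs_overlap),
                 promoter_flank = as.integer(promoter_flank),
                 test_fraction = test_fraction,
                 metagene_flank = as.integer(metagene_flank),
                 promoter_upstream = as.integer(promoter_upstream),
                 promoter_downstream = as.integer(promoter_downstream),
                 h3k27ac_active_threshold = h3k27ac_active_threshold,
                 prob_threshold = prob_threshold,
                 flank = as.integer(flank),
                 n_trees = as.integer(n_trees)),
            class = "scan_config")
}
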