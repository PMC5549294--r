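# Brute-force oracles, deliberately independent of the package internals:
# everything here works on plain data frames in 0-based half-open
# coordinates and enumerates bases or pairs directly.

# -- conversions ------------------------------------------------------------

df_to_granges <- function(df, genome) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1, df$end),
                         seqinfo = genome)
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}

toy_genome <- function(lengths = c(chrA = 1000L, chrB = 700L)) {
  genome_from_lengths(lengths)
}

# -- interval oracles -------------------------------------------------------

# assign every base of every chromosome to a window ordinal, then recover
# the window list from the assignment
oracle_windows <- function(lengths, w) {
  out <- list()
  for (ch in names(lengths)) {
    assign <- (seq_len(lengths[[ch]]) - 1L) %/% w  # 0-based base -> ordinal
    for (k in unique(assign)) {
      bases <- which(assign == k) - 1L
      out[[length(out) + 1L]] <- data.frame(chrom = ch,
                                            start = min(bases),
                                            end = max(bases) + 1L)
    }
  }
  do.call(rbind, out)
}

# per-base occupancy, then close gaps <= max_gap by scanning runs
oracle_merge <- function(df, max_gap, lengths) {
  out <- list()
  for (ch in names(lengths)) {
    occ <- rep(FALSE, lengths[[ch]])
    sub <- df[df$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) occ[(sub$start[i] + 1):sub$end[i]] <- TRUE
    if (!any(occ)) next
    covered <- which(occ)
    grp <- cumsum(c(1, diff(covered) - 1 > max_gap))
    for (g in unique(grp)) {
      b <- covered[grp == g]
      out[[length(out) + 1L]] <- data.frame(chrom = ch,
                                            start = min(b) - 1L,
                                            end = max(b))
    }
  }
  if (!length(out)) return(data.frame(chrom = character(0),
                                      start = integer(0), end = integer(0)))
  do.call(rbind, out)
}

oracle_overlap_bp <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  length(intersect(seq(a$start, a$end - 1L), seq(b$start, b$end - 1L)))
}

# exhaustive pairwise scan with the documented tie-break
oracle_nearest <- function(q, feats, ids) {
  same <- which(feats$chrom == q$chrom)
  if (!length(same)) return(list(id = NA_character_, dist = NA_real_))
  gap <- pmax(0, pmax(feats$start[same] - q$end, q$start - feats$end[same]))
  best <- min(gap)
  cand <- same[gap == best]
  cand <- cand[order(feats$start[cand], ids[cand])]
  pick <- cand[1]
  d <- best
  if (d > 0 && feats$end[pick] <= q$start) d <- -d
  list(id = ids[pick], dist = d)
}

# per-base expansion of a step-function track, then plain mean
oracle_mean_coverage <- function(segments, region, lengths) {
  base_vals <- rep(0, lengths[[region$chrom]])
  sub <- segments[segments$chrom == region$chrom, , drop = FALSE]
  for (i in seq_len(nrow(sub)))
    base_vals[(sub$start[i] + 1):sub$end[i]] <- sub$value[i]
  mean(base_vals[(region$start + 1):region$end])
}

# -- random instance generators --------------------------------------------

random_segments <- function(n, lengths, max_width = 50) {
  rows <- list()
  for (ch in names(lengths)) {
    len <- lengths[[ch]]
    k <- max(1L, round(n / length(lengths)))
    starts <- sort(sample(0:(len - max_width - 1), k))
    ends <- pmin(len, starts + sample(1:max_width, k, replace = TRUE))
    keep <- logical(k)  # greedy non-overlapping selection
    last_end <- -1L
    for (i in seq_len(k)) {
      if (starts[i] >= last_end) {
        keep[i] <- TRUE
        last_end <- ends[i]
      }
    }
    rows[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                             end = ends[keep],
                             value = round(stats::runif(sum(keep), 0, 10), 4))
  }
  do.call(rbind, rows)
}

random_intervals <- function(n, lengths, max_width = 300) {
  ch <- sample(names(lengths), n, replace = TRUE)
  len <- unlist(lengths)[ch]
  width <- sample(1:max_width, n, replace = TRUE)
  start <- floor(stats::runif(n) * (len - width))
  data.frame(chrom = ch, start = start, end = start + width,
             stringsAsFactors = FALSE, row.names = NULL)
}

segments_to_track <- function(segments, genome) {
  gr <- df_to_granges(segments, genome)
  gr$score <- segments$value
  BiocGenerics::sort(gr)
}

# small simulated benchmark shared by caller/model tests (cheaper than the
# full default simulator)
small_benchmark <- function(seed = 1) {
  truth <- simulate_truth(n_enhancers = 12L, n_genes = 40L,
                          genome = genome_from_lengths(c(chrS1 = 4e5)),
                          seed = seed)
  tracks <- simulate_tracks(truth, seed = seed)
  list(truth = truth, tracks = tracks,
       marks = tracks[c("DNase", "H3K4me1", "H3K27ac", "H3K4me3")])
}
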