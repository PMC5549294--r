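#' Score every genome window with the enhancer model
#'
#' Tiles the genome into `config$window_size` windows, extracts each
#' window's mean marker coverages with the model's stored flank, and
#' scores every window with the random forest.  A window is classed
#' "enhancer" when its probability reaches `config$prob_threshold`.
#'
#' @param model An `enhancer_model`.
#' @param genome `Seqinfo`.
#' @param tracks Named list of marker coverage tracks matching the model's
#'   markers.
#' @param config A [scan_config()].
#' @return The window `GRanges` with metadata columns `index`,
#'   `probability` and `enhancer` (logical).
#' @export
scan_genome <- function(model, genome, tracks, config = scan_config()) {
  stopifnot(methods::is(genome, "Seqinfo"))
  windows <- make_windows(genome, config$window_size)
  feats <- extract_features(windows, tracks, flank = model$flank)
  windows$probability <- predict_enhancer_prob(model, feats)
  windows$enhancer <- windows$probability >= config$prob_threshold
  windows
}

#' Merge enhancer windows into candidate enhancer calls
#'
#' Windows classed as enhancer that lie within `config$merge_gap` bp of
#' each other are merged into single continuous elements (adjacent
#' windows have gap 0, so consecutive enhancer windows always merge).  A
#' call's probability is the maximum over its member windows, preserving
#' the strongest evidence through the merge.
#'
#' @param scored Window `GRanges` from [scan_genome()].
#' @param config A [scan_config()].
#' @return A `GRanges` of candidate calls with `probability` and
#'   `n_windows` metadata, named `enh_1`, `enh_2`, ... in genome order.
#' @export
call_enhancers <- function(scored, config = scan_config()) {
  stopifnot(methods::is(scored, "GRanges"), !is.null(scored$enhancer))
  hits <- scored[scored$enhancer]
  if (length(hits) == 0) {
    out <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(scored))
    out$probability <- numeric(0)
    out$n_windows <- integer(0)
    return(out)
  }
  merged <- GenomicRanges::reduce(hits, min.gapwidth = config$merge_gap + 1L,
                                  ignore.strand = TRUE, with.revmap = TRUE)
  merged$probability <- vapply(merged$revmap,
                               function(i) max(hits$probability[i]), numeric(1))
  merged$n_windows <- lengths(merged$revmap)
  merged$revmap <- NULL
  names(merged) <- paste0("enh_", seq_along(merged))
  merged
}

#' Validate candidate calls against DNase hypersensitive sites
#'
#' A candidate becomes a validated enhancer only if a retained DHS peak
#' (q-filtered at read time, see [read_narrowpeak()]) overlaps it by at
#' least `config$min_dhs_overlap` bp -- the strict false-positive guard.
#'
#' @param calls Candidate `GRanges` from [call_enhancers()].
#' @param dhs Peak `GRanges` (already q-filtered).
#' @param config A [scan_config()].
#' @return The validated subset, with `validated = TRUE`; renamed in
#'   genome order.
#' @export
validate_with_dhs <- function(calls, dhs, config = scan_config()) {
  stopifnot(methods::is(calls, "GRanges"), methods::is(dhs, "GRanges"))
  if (length(dhs) == 0) {
    warning("empty DHS peak set: no call can be validated")
    out <- calls[integer(0)]
    out$validated <- logical(0)
    return(out)
  }
  keep <- IRanges::overlapsAny(calls, dhs,
                               minoverlap = config$min_dhs_overlap,
                               ignore.strand = TRUE)
  if (any(!keep))
    message("validate_with_dhs: discarded ", sum(!keep),
            " call(s) without DHS support")
  out <- calls[keep]
  out$validated <- rep(TRUE, length(out))
  if (length(out)) names(out) <- paste0("enh_", seq_along(out))
  out
}

#' Stratify validated enhancers into active and primed states
#'
#' Active enhancers carry H3K27ac; primed enhancers carry the H3K4me1 /
#' open-chromatin signature without it.  A call is classed active when its
#' mean H3K27ac coverage reaches the threshold, else primed.  By default
#' the threshold is the genome-wide mean of the H3K27ac track -- "above
#' background" -- and is recorded on the result.
#'
#' @param calls Validated call `GRanges`.
#' @param h3k27ac H3K27ac coverage track.
#' @param threshold RPM threshold; `NULL` uses the genome-wide track mean.
#' @return `calls` with metadata columns `h3k27ac` (mean RPM) and `state`
#'   (factor active/primed), and attribute-like metadata
#'   `S4Vectors::metadata(calls)$h3k27ac_threshold`.
#' @export
classify_states <- function(calls, h3k27ac, threshold = NULL) {
  stopifnot(methods::is(calls, "GRanges"))
  if (is.null(threshold)) threshold <- genome_mean_coverage(h3k27ac)
  m <- mean_coverage(h3k27ac, calls)
  calls$h3k27ac <- m
  calls$state <- factor(ifelse(m >= threshold, "active", "primed"),
                        levels = c("active", "primed"))
  S4Vectors::metadata(calls)$h3k27ac_threshold <- threshold
  calls
}

#' Attach sense / antisense eRNA coverage to calls
#'
#' Active enhancers are transcribed divergently; their eRNA shows up as
#' bidirectional GRO-seq signal.  For each call this records the mean
#' plus-strand coverage as `erna_sense` and mean minus-strand coverage as
#' `erna_antisense`.
#'
#' @param calls Call `GRanges`.
#' @param gro_plus,gro_minus Strand coverage tracks; a missing track
#'   leaves its field `NA` with a warning.
#' @return `calls` with `erna_sense` and `erna_antisense` columns (RPM).
#' @export
erna_coverage <- function(calls, gro_plus = NULL, gro_minus = NULL) {
  stopifnot(methods::is(calls, "GRanges"))
  if (is.null(gro_plus)) {
    warning("no plus-strand GRO track: erna_sense left NA")
    calls$erna_sense <- rep(NA_real_, length(calls))
  } else {
    calls$erna_sense <- mean_coverage(gro_plus, calls)
  }
  if (is.null(gro_minus)) {
    warning("no minus-strand GRO track: erna_antisense left NA")
    calls$erna_antisense <- rep(NA_real_, length(calls))
  } else {
    calls$erna_antisense <- mean_coverage(gro_minus, calls)
  }
  calls
}

#' Metagene / heatmap matrix around element midpoints
#'
#' Builds the element x bin matrix behind enhancer heatmaps and metagene
#' profiles: each row covers an element's midpoint +/- `flank`, split into
#' `bin_size` bins, each cell the track's mean coverage over that bin.
#' Rows are ranked by decreasing `rank_values` (by default the track's own
#' mean over each call, i.e. heatmaps ranked by signal); ties fall back to
#' genome order.  Bins clipped at a chromosome edge contribute the mean of
#' the clipped part, and a fully out-of-bounds bin is 0.
#'
#' @param calls Element `GRanges` (non-empty).
#' @param track Coverage track to profile.
#' @param flank Half-window in bp (default 3000).
#' @param bin_size Bin width in bp; must divide `2 * flank`.
#' @param rank_values Optional numeric vector (one per call) to rank rows
#'   by, e.g. mean DNase for accessibility-ranked heatmaps.
#' @return A numeric matrix (rows: ranked elements; columns: bins labelled
#'   by their start offset from the midpoint).
#' @export
metagene_matrix <- function(calls, track, flank = 3000L, bin_size = 50L,
                            rank_values = NULL) {
  stopifnot(methods::is(calls, "GRanges"), length(calls) > 0,
            (2L * flank) %% bin_size == 0)
  n_bins <- as.integer(2L * flank / bin_size)
  offsets <- seq(-flank, flank - bin_size, by = bin_size)

  # midpoint in 0-based coordinates: start0 + floor(width / 2)
  mid0 <- (BiocGenerics::start(calls) - 1L) +
    BiocGenerics::width(calls) %/% 2L
  chr <- rep(as.character(GenomeInfoDb::seqnames(calls)), each = n_bins)
  bin_start0 <- rep(mid0, each = n_bins) + rep(offsets, length(calls))
  bin_end0 <- bin_start0 + bin_size
  sl <- GenomeInfoDb::seqlengths(track)[chr]
  cs <- pmax(0, bin_start0)
  ce <- pmin(sl, bin_end0)
  vals <- numeric(length(cs))
  ok <- ce > cs
  if (any(ok)) {
    regions <- GenomicRanges::GRanges(chr[ok],
                                      IRanges::IRanges(cs[ok] + 1, ce[ok]),
                                      seqinfo = GenomeInfoDb::seqinfo(track))
    vals[ok] <- mean_coverage(track, regions)
  }
  mat <- matrix(vals, nrow = length(calls), ncol = n_bins, byrow = TRUE)
  colnames(mat) <- offsets
  rn <- names(calls)
  if (is.null(rn)) rn <- paste0("el_", seq_along(calls))
  rownames(mat) <- rn

  if (is.null(rank_values)) rank_values <- mean_coverage(track, calls)
  stopifnot(length(rank_values) == length(calls))
  ord <- order(-rank_values, seq_along(calls))
  mat[ord, , drop = FALSE]
}

#' Write a metagene matrix as TSV
#'
#' @param mat Matrix from [metagene_matrix()]; the header row carries bin
#'   offsets.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_metagene <- function(mat, path) {
  df <- data.frame(element = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full enhancer-prediction pipeline
#'
#' scan -> merge -> DHS-validate, then annotate every validated call with
#' its per-marker mean coverages; optionally stratify states against the
#' H3K27ac track and attach eRNA strand coverage.  The composition is
#' deterministic given (model, tracks, config).
#'
#' @param model An `enhancer_model`.
#' @param genome `Seqinfo`.
#' @param tracks Named marker tracks matching the model.
#' @param dhs q-filtered DHS peak `GRanges`.
#' @param config A [scan_config()].
#' @param gro_plus,gro_minus Optional GRO-seq strand tracks.
#' @return Validated call `GRanges` with probability, per-marker means,
#'   state (when H3K27ac is among the markers) and eRNA columns (when GRO
#'   tracks are given).
#' @export
predict_enhancers <- function(model, genome, tracks, dhs,
                              config = scan_config(),
                              gro_plus = NULL, gro_minus = NULL) {
  scored <- scan_genome(model, genome, tracks, config)
  calls <- call_enhancers(scored, config)
  calls <- validate_with_dhs(calls, dhs, config)
  if (length(calls)) {
    marks <- extract_features(calls, tracks, flank = 0L)
    for (mk in colnames(marks))
      S4Vectors::mcols(calls)[[paste0("mean_", mk)]] <- marks[, mk]
    if ("H3K27ac" %in% names(tracks))
      calls <- classify_states(calls, tracks$H3K27ac,
                               threshold = config$h3k27ac_active_threshold)
    if (!is.null(gro_plus) && !is.null(gro_minus))
      calls <- erna_coverage(calls, gro_plus, gro_minus)
  }
  calls
}

#' Write enhancer calls as an extended TSV
#'
#' BED-style coordinates plus probability, state, per-marker means and
#' eRNA columns -- whatever annotation the calls carry.
#'
#' @param calls Call `GRanges`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_calls_tsv <- function(calls, path) {
  stopifnot(methods::is(calls, "GRanges"))
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(calls)),
                   start = BiocGenerics::start(calls) - 1L,
                   end = BiocGenerics::end(calls),
                   name = if (is.null(names(calls)))
                     paste0("enh_", seq_along(calls)) else names(calls))
  mc <- as.data.frame(S4Vectors::mcols(calls))
  if (ncol(mc)) df <- cbind(df, mc)
  thr <- S4Vectors::metadata(calls)$h3k27ac_threshold
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(thr))
    writeLines(paste0("# h3k27ac_active_threshold=",
                      format(thr, digits = 10)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
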