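#' FPKM and TPM from gene counts
#'
#' FPKM_g = count_g x 1e9 / (exonic length_g x library total);
#' TPM_g = (count_g / length_g) x 1e6 / sum_j(count_j / length_j).
#' TPM sums to one million whenever any count is positive; with all-zero
#' counts both columns are zero.
#'
#' @param counts Named numeric vector of per-gene read counts.
#' @param lengths Named numeric vector of exonic lengths (bp); must cover
#'   every gene in `counts`.
#' @param library_total Library size; defaults to `sum(counts)`.
#' @return A `data.frame` (gene_id, count, length, fpkm, tpm) with the
#'   library total as attribute `library_total`.
#' @examples
#' compute_expression(c(g1 = 100), c(g1 = 1000), library_total = 1e6)
#' @export
compute_expression <- function(counts, lengths, library_total = NULL) {
  stopifnot(!is.null(names(counts)), !is.null(names(lengths)),
            all(counts >= 0), all(lengths > 0))
  missing <- setdiff(names(counts), names(lengths))
  if (length(missing))
    stop("gene(s) missing a length: ", paste(missing, collapse = ", "))
  lengths <- lengths[names(counts)]
  if (is.null(library_total)) library_total <- sum(counts)
  fpkm <- if (library_total > 0)
    counts * 1e9 / (lengths * library_total) else counts * 0
  rpk <- counts / lengths
  tpm <- if (sum(rpk) > 0) rpk * 1e6 / sum(rpk) else rpk * 0
  out <- data.frame(gene_id = names(counts), count = as.numeric(counts),
                    length = as.numeric(lengths), fpkm = as.numeric(fpkm),
                    tpm = as.numeric(tpm), stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "library_total") <- library_total
  out
}

#' Annotate peaks with their nearest gene's expression
#'
#' For every peak, finds the nearest gene (edge-to-edge, unstranded, ties
#' broken deterministically -- see [nearest_feature()]) and merges in that
#' gene's FPKM and TPM.  Peaks with no gene on their chromosome are
#' flagged `unassigned` rather than dropped.
#'
#' @param peaks `GRanges` of peaks (or enhancer calls).
#' @param genes Gene annotation `GRanges`.
#' @param expr Expression table from [compute_expression()].
#' @return A `data.frame`: one row per peak with coordinates, nearest
#'   `gene_id`, signed `distance` (bp), `fpkm`, `tpm`, `unassigned`.
#' @export
gene_expression_near_peaks <- function(peaks, genes, expr) {
  stopifnot(methods::is(peaks, "GRanges"))
  if (length(genes) == 0) stop("empty gene list")
  nf <- nearest_feature(peaks, genes, ids = genes$gene_id)
  idx <- match(nf$feature_id, expr$gene_id)
  nm <- names(peaks)
  if (is.null(nm)) nm <- paste0("peak_", seq_along(peaks))
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(peaks)),
             start = BiocGenerics::start(peaks) - 1L,
             end = BiocGenerics::end(peaks),
             name = nm,
             gene_id = nf$feature_id,
             distance = nf$distance,
             fpkm = expr$fpkm[idx],
             tpm = expr$tpm[idx],
             unassigned = nf$unassigned,
             stringsAsFactors = FALSE)
}

#' Promoter-proximal co-occupancy across peak sets
#'
#' Builds the strand-aware promoter-proximal window of each gene --
#' `upstream` bp 5' of the TSS through `downstream` bp 3' of it (for a
#' minus-strand gene, upstream extends to larger coordinates) -- and
#' flags the gene as co-occupied when *every* supplied peak set overlaps
#' the window by at least 1 bp.  This is the multi-factor promoter
#' co-occupancy analysis (e.g. Pol II + several cofactors) with the
#' conventional -250/+1000 window as default.
#'
#' @param genes Gene annotation `GRanges`.
#' @param peak_sets Named list of peak `GRanges`.
#' @param upstream,downstream Window extent relative to the TSS, bp.
#' @return A list: `flags` (data.frame with gene_id, one logical column
#'   per peak set, and `co_occupied`), `n_cooccupied` (count of genes
#'   where every set is present), and `windows` (the promoter-proximal
#'   `GRanges`).
#' @export
promoter_cooccupancy <- function(genes, peak_sets,
                                 upstream = 250L, downstream = 1000L) {
  stopifnot(methods::is(genes, "GRanges"), is.list(peak_sets),
            length(peak_sets) >= 1, upstream >= 0, downstream >= 0,
            upstream + downstream >= 1)
  if (is.null(names(peak_sets)))
    names(peak_sets) <- paste0("set", seq_along(peak_sets))
  chr <- as.character(GenomeInfoDb::seqnames(genes))
  tss <- genes$tss
  plus <- as.character(BiocGenerics::strand(genes)) == "+"
  # 1-based inclusive window covering [TSS - upstream, TSS + downstream)
  # on the gene's own orientation
  st <- ifelse(plus, tss - upstream, tss - downstream + 1L)
  en <- ifelse(plus, tss + downstream - 1L, tss + upstream)
  sl <- GenomeInfoDb::seqlengths(genes)[chr]
  windows <- GenomicRanges::GRanges(chr,
                                    IRanges::IRanges(pmax(1, st), pmin(sl, en)),
                                    seqinfo = GenomeInfoDb::seqinfo(genes))
  names(windows) <- genes$gene_id
  flags <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  for (nm in names(peak_sets))
    flags[[nm]] <- IRanges::overlapsAny(windows, peak_sets[[nm]],
                                        ignore.strand = TRUE)
  flags$co_occupied <- Reduce(`&`, flags[names(peak_sets)])
  list(flags = flags, n_cooccupied = sum(flags$co_occupied),
       windows = windows)
}
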