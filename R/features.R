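#' Extract the elements x markers feature matrix
#'
#' The classifier's feature for element `e` and marker `m` is the mean
#' coverage of marker `m`'s track over `e`, optionally expanded by a
#' symmetric `flank` on each side.  Elements extending past chromosome
#' ends after flanking are clipped, and the mean uses the clipped width
#' (no phantom zero-padding).  Marker (column) order follows the order of
#' `tracks` and is fixed at training time: prediction against a model with
#' different markers is an error.
#'
#' @param elements `GRanges` of genomic elements (windows, enhancers,
#'   promoters).
#' @param tracks Named list of coverage `GRanges` (marker name -> track),
#'   all on the same genome.
#' @param flank Symmetric expansion in bp before computing means
#'   (default 0: the element body alone).
#' @return A numeric matrix (rows: elements, in input order; columns:
#'   markers) with attributes `flank` and `markers`.
#' @export
extract_features <- function(elements, tracks, flank = 0L) {
  stopifnot(methods::is(elements, "GRanges"), is.list(tracks),
            length(tracks) > 0, !is.null(names(tracks)),
            length(flank) == 1, flank >= 0)
  sl <- GenomeInfoDb::seqlengths(tracks[[1]])
  chr <- as.character(GenomeInfoDb::seqnames(elements))
  st <- pmax(1L, BiocGenerics::start(elements) - as.integer(flank))
  en <- pmin(sl[chr], BiocGenerics::end(elements) + as.integer(flank))
  regions <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, en),
                                    seqinfo = GenomeInfoDb::seqinfo(tracks[[1]]))
  mat <- vapply(tracks, function(tr) mean_coverage(tr, regions),
                numeric(length(elements)))
  if (length(elements) == 1) mat <- matrix(mat, nrow = 1)
  if (length(elements) == 0)
    mat <- matrix(numeric(0), nrow = 0, ncol = length(tracks))
  colnames(mat) <- names(tracks)
  rn <- names(elements)
  if (is.null(rn)) rn <- paste0("el_", seq_along(elements))
  rownames(mat) <- rn
  attr(mat, "flank") <- as.integer(flank)
  attr(mat, "markers") <- names(tracks)
  mat
}

#' Write a feature matrix with coordinates for audit
#'
#' @param features Matrix from [extract_features()].
#' @param elements The `GRanges` the rows were computed from.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_feature_matrix <- function(features, elements, path) {
  stopifnot(nrow(features) == length(elements))
  df <- data.frame(element = rownames(features),
                   chrom = as.character(GenomeInfoDb::seqnames(elements)),
                   start = BiocGenerics::start(elements) - 1L,
                   end = BiocGenerics::end(elements))
  df <- cbind(df, as.data.frame(features))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
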