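#' Read an RPM-normalized bedGraph coverage track
#'
#' Parses a 4-column bedGraph (chrom, start, end, value; 0-based half-open)
#' into a sorted `GRanges` with a numeric `score` column -- the step-function
#' coverage representation used by every signal operation.  Bases not
#' covered by any record have implicit value 0.  `track`/`browser`/comment
#' header lines are skipped.  Records on chromosomes absent from `genome`
#' are dropped with a message; malformed records (non-numeric value,
#' start >= end, negative or out-of-bounds coordinates, overlapping
#' records) raise an error carrying the offending line number.
#'
#' @param path bedGraph file path.
#' @param genome `Seqinfo` governing the track.
#' @param rescale_rpm If `TRUE`, rescale raw values to reads per million
#'   (value x 1e6 / sum of values); by default values are taken as already
#'   RPM-normalized.
#' @return A sorted `GRanges` with `score` metadata and `genome` as seqinfo.
#' @export
read_bedgraph <- function(path, genome, rescale_rpm = FALSE) {
  stopifnot(file.exists(path), methods::is(genome, "Seqinfo"))
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(track|browser|#)", lines)
  if (!any(keep)) {
    return(GenomicRanges::GRanges(seqinfo = genome, score = numeric(0)))
  }
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4))
    stop("bedGraph line ", lineno[which(nf != 4)[1]],
         ": expected 4 columns, found ", nf[which(nf != 4)[1]])
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  start0 <- suppressWarnings(as.numeric(m[, 2]))
  end0 <- suppressWarnings(as.numeric(m[, 3]))
  value <- suppressWarnings(as.numeric(m[, 4]))
  for (col in list(list(start0, "start"), list(end0, "end"), list(value, "value"))) {
    bad <- which(!is.finite(col[[1]]))
    if (length(bad))
      stop("bedGraph line ", lineno[bad[1]], ": non-numeric ", col[[2]])
  }
  if (any(start0 < 0))
    stop("bedGraph line ", lineno[which(start0 < 0)[1]], ": negative start")
  if (any(start0 >= end0))
    stop("bedGraph line ", lineno[which(start0 >= end0)[1]], ": start >= end")
  chrom <- m[, 1]
  known <- chrom %in% GenomeInfoDb::seqnames(genome)
  if (any(!known)) {
    message("read_bedgraph: dropped ", sum(!known),
            " record(s) on chromosomes absent from the genome")
    chrom <- chrom[known]; start0 <- start0[known]; end0 <- end0[known]
    value <- value[known]; lineno <- lineno[known]
  }
  sl <- GenomeInfoDb::seqlengths(genome)[chrom]
  if (any(end0 > sl))
    stop("bedGraph line ", lineno[which(end0 > sl)[1]],
         ": interval extends past chromosome end")
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1, end0),
                               seqinfo = genome)
  gr$score <- value
  gr$.line <- lineno
  gr <- BiocGenerics::sort(gr)
  # overlap check on the sorted track
  if (length(gr) > 1) {
    same <- as.character(GenomeInfoDb::seqnames(gr))[-length(gr)] ==
      as.character(GenomeInfoDb::seqnames(gr))[-1]
    ov <- same & (BiocGenerics::start(gr)[-1] <= BiocGenerics::end(gr)[-length(gr)])
    if (any(ov)) {
      i <- which(ov)[1]
      stop("bedGraph records overlap (lines ", gr$.line[i], " and ",
           gr$.line[i + 1], ")")
    }
  }
  gr$.line <- NULL
  if (rescale_rpm) {
    total <- sum(gr$score * BiocGenerics::width(gr))
    if (total > 0) gr$score <- gr$score * 1e6 / total
  }
  gr
}

#' Read an ENCODE narrowPeak file, filtering on q-value
#'
#' Parses the 10-column narrowPeak (BED6+4) format and retains peaks whose
#' -log10 q-value column meets `-log10(q_max)`; the count of discarded
#' peaks is reported.  Peaks carrying the missing-value sentinel (-1) fail
#' the filter: validation evidence must be conservative.
#'
#' @param path narrowPeak file path.
#' @param genome `Seqinfo`.
#' @param q_max Maximum q-value (FDR) retained, default 0.01.
#' @return A sorted `GRanges` with metadata columns `name`, `score`,
#'   `signalValue`, `pValue`, `qValue` (-log10 scale) and `peak` (summit
#'   offset).
#' @export
read_narrowpeak <- function(path, genome, q_max = 0.01) {
  stopifnot(file.exists(path), methods::is(genome, "Seqinfo"),
            q_max > 0, q_max < 1)
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(track|browser|#)", lines)
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signalValue", "pValue", "qValue", "peak")
  if (!any(keep)) {
    gr <- GenomicRanges::GRanges(seqinfo = genome)
    gr$name <- character(0)
    for (cn in cols[c(5, 7:9)]) S4Vectors::mcols(gr)[[cn]] <- numeric(0)
    gr$peak <- integer(0)
    return(gr)
  }
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 10))
    stop("narrowPeak line ", lineno[which(nf != 10)[1]],
         ": expected 10 columns, found ", nf[which(nf != 10)[1]])
  m <- matrix(unlist(fields), ncol = 10, byrow = TRUE)
  start0 <- as.numeric(m[, 2]); end0 <- as.numeric(m[, 3])
  if (any(!is.finite(start0)) || any(!is.finite(end0)) || any(start0 < 0))
    stop("narrowPeak line ",
         lineno[which(!is.finite(start0) | !is.finite(end0) | start0 < 0)[1]],
         ": bad coordinates")
  chrom <- m[, 1]
  known <- chrom %in% GenomeInfoDb::seqnames(genome)
  if (any(!known)) {
    message("read_narrowpeak: dropped ", sum(!known),
            " peak(s) on chromosomes absent from the genome")
  }
  gr <- GenomicRanges::GRanges(chrom[known],
                               IRanges::IRanges(start0[known] + 1, end0[known]),
                               seqinfo = genome)
  gr$name <- m[known, 4]
  gr$score <- as.numeric(m[known, 5])
  gr$signalValue <- as.numeric(m[known, 7])
  gr$pValue <- as.numeric(m[known, 8])
  gr$qValue <- as.numeric(m[known, 9])
  gr$peak <- as.integer(m[known, 10])
  q_threshold <- -log10(q_max)
  pass <- gr$qValue >= q_threshold
  if (any(!pass))
    message("read_narrowpeak: discarded ", sum(!pass),
            " peak(s) with q-value above ", q_max)
  BiocGenerics::sort(gr[pass])
}

#' Read gene annotations from GTF or BED6
#'
#' Builds the per-gene table used for promoter construction, nearest-gene
#' annotation and expression normalization: one record per `gene_id` with
#' its genomic extent, strand, TSS (start of a `+` gene, last base of a `-`
#' gene) and total exonic length (union of its exons).  GTF coordinates
#' (1-based inclusive) are read natively; a 6-column BED file is accepted
#' as a fallback, in which case the exonic length is the gene width.
#'
#' @param path GTF (`.gtf`/`.gff`) or BED6 file.
#' @param genome `Seqinfo`; genes on unknown chromosomes are skipped with a
#'   message.
#' @return A `GRanges` (one range per gene, stranded) with metadata columns
#'   `gene_id`, `symbol`, `tss` (1-based position) and `exon_length` (bp).
#' @export
read_gene_annotation <- function(path, genome) {
  stopifnot(file.exists(path), methods::is(genome, "Seqinfo"))
  if (grepl("\\.(gtf|gff[0-9]?)$", path, ignore.case = TRUE)) {
    gx <- rtracklayer::import(path, format = "gtf")
    if (is.null(gx$gene_id)) stop("GTF has no gene_id attribute")
    known <- as.character(GenomeInfoDb::seqnames(gx)) %in%
      GenomeInfoDb::seqnames(genome)
    if (any(!known))
      message("read_gene_annotation: skipped ", sum(!known),
              " record(s) on chromosomes absent from the genome")
    gx <- gx[known]
    genes <- gx[gx$type == "gene"]
    exons <- gx[gx$type == "exon"]
    if (length(genes) == 0) {
      # derive gene extents from exons
      ex_by_gene <- S4Vectors::split(exons, exons$gene_id)
      genes <- unlist(range(ex_by_gene))
      genes$gene_id <- names(genes)
      genes$gene_name <- genes$gene_id
    }
    if (any(as.character(BiocGenerics::strand(genes)) == "*"))
      stop("gene without strand: ",
           genes$gene_id[as.character(BiocGenerics::strand(genes)) == "*"][1])
    symbol <- if (!is.null(genes$gene_name)) genes$gene_name else genes$gene_id
    symbol[is.na(symbol)] <- genes$gene_id[is.na(symbol)]
    exon_length <- rep(NA_real_, length(genes))
    if (length(exons) > 0) {
      ex_union <- sum(BiocGenerics::width(GenomicRanges::reduce(
        S4Vectors::split(exons, exons$gene_id))))
      exon_length <- as.numeric(ex_union[genes$gene_id])
    }
    no_exon <- is.na(exon_length)
    if (any(no_exon)) {
      message("read_gene_annotation: ", sum(no_exon),
              " gene(s) without exon records; using the gene span")
      exon_length[no_exon] <- BiocGenerics::width(genes)[no_exon]
    }
    out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                                  IRanges::ranges(genes),
                                  strand = BiocGenerics::strand(genes),
                                  seqinfo = genome)
    out$gene_id <- genes$gene_id
    out$symbol <- symbol
    out$exon_length <- exon_length
  } else {
    tab <- utils::read.table(path, header = FALSE, sep = "",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 6) stop("BED gene annotation requires 6 columns")
    if (any(!tab[[6]] %in% c("+", "-")))
      stop("gene without strand: ", tab[[4]][!tab[[6]] %in% c("+", "-")][1])
    known <- tab[[1]] %in% GenomeInfoDb::seqnames(genome)
    if (any(!known))
      message("read_gene_annotation: skipped ", sum(!known),
              " record(s) on chromosomes absent from the genome")
    tab <- tab[known, ]
    out <- GenomicRanges::GRanges(tab[[1]],
                                  IRanges::IRanges(tab[[2]] + 1, tab[[3]]),
                                  strand = tab[[6]], seqinfo = genome)
    out$gene_id <- as.character(tab[[4]])
    out$symbol <- as.character(tab[[4]])
    out$exon_length <- as.numeric(BiocGenerics::width(out))
  }
  if (anyDuplicated(out$gene_id)) {
    message("read_gene_annotation: keeping the first record of ",
            sum(duplicated(out$gene_id)), " duplicated gene id(s)")
    out <- out[!duplicated(out$gene_id)]
  }
  out <- BiocGenerics::sort(out, ignore.strand = TRUE)
  out$tss <- ifelse(as.character(BiocGenerics::strand(out)) == "+",
                    BiocGenerics::start(out), BiocGenerics::end(out))
  names(out) <- out$gene_id
  out
}

#' Write genomic elements as BED
#'
#' Emits BED6 in genome order (0-based half-open).  If the elements carry a
#' `probability` metadata column, the BED score is the classifier
#' probability scaled to 0--1000 (integer-clamped); element names default
#' to `enh_1`, `enh_2`, ...
#'
#' @param elements `GRanges`.
#' @param path Output path.
#' @param name_prefix Prefix for auto-generated element names.
#' @return Invisibly, the path.
#' @export
write_bed <- function(elements, path, name_prefix = "enh") {
  stopifnot(methods::is(elements, "GRanges"))
  x <- BiocGenerics::sort(elements, ignore.strand = TRUE)
  nm <- names(x)
  if (is.null(nm)) nm <- paste0(name_prefix, "_", seq_along(x))
  score <- rep(0L, length(x))
  if (!is.null(x$probability))
    score <- pmax(0L, pmin(1000L, as.integer(round(x$probability * 1000))))
  st <- as.character(BiocGenerics::strand(x))
  st[st == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(x)),
                   start = BiocGenerics::start(x) - 1L,
                   end = BiocGenerics::end(x),
                   name = nm, score = score, strand = st)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' Emits 4-column bedGraph in genome order; adjacent runs of equal value
#' are merged into single records so the output is canonical.
#'
#' @param track Coverage `GRanges` with a `score` column.
#' @param path Output path.
#' @param digits Significant digits used to print values.
#' @return Invisibly, the path.
#' @export
write_bedgraph <- function(track, path, digits = 10) {
  stopifnot(methods::is(track, "GRanges"), !is.null(track$score))
  x <- BiocGenerics::sort(track, ignore.strand = TRUE)
  if (length(x) > 1) {
    chrom <- as.character(GenomeInfoDb::seqnames(x))
    adjacent <- c(FALSE,
                  chrom[-1] == chrom[-length(x)] &
                    BiocGenerics::start(x)[-1] ==
                      BiocGenerics::end(x)[-length(x)] + 1L &
                    x$score[-1] == x$score[-length(x)])
    grp <- cumsum(!adjacent)
    st <- tapply(BiocGenerics::start(x), grp, min)
    en <- tapply(BiocGenerics::end(x), grp, max)
    first <- !duplicated(grp)
    df <- data.frame(chrom = chrom[first], start = as.integer(st) - 1L,
                     end = as.integer(en), value = x$score[first])
  } else {
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(x)),
                     start = BiocGenerics::start(x) - 1L,
                     end = BiocGenerics::end(x), value = x$score)
  }
  df$value <- vapply(df$value, function(v)
    format(v, digits = digits, scientific = FALSE, trim = TRUE), character(1))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a peak set as narrowPeak
#'
#' @param peaks `GRanges` with narrowPeak metadata columns (as produced by
#'   [read_narrowpeak()] or the simulator).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_narrowpeak <- function(peaks, path) {
  stopifnot(methods::is(peaks, "GRanges"))
  x <- BiocGenerics::sort(peaks, ignore.strand = TRUE)
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(x)),
                   start = BiocGenerics::start(x) - 1L,
                   end = BiocGenerics::end(x),
                   name = if (is.null(x$name)) paste0("peak_", seq_along(x)) else x$name,
                   score = if (is.null(x$score)) 0L else as.integer(x$score),
                   strand = ".",
                   signalValue = if (is.null(x$signalValue)) 0 else x$signalValue,
                   pValue = if (is.null(x$pValue)) -1 else x$pValue,
                   qValue = if (is.null(x$qValue)) -1 else x$qValue,
                   peak = if (is.null(x$peak)) -1L else x$peak)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a chromosome-sizes table
#'
#' @param genome `Seqinfo`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_chrom_sizes <- function(genome, path) {
  stopifnot(methods::is(genome, "Seqinfo"))
  df <- data.frame(chrom = GenomeInfoDb::seqnames(genome),
                   length = GenomeInfoDb::seqlengths(genome))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
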