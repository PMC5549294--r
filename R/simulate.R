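# Deterministic simulator: a toy multi-chromosome genome with planted
# enhancers (peak-valley-peak H3K4me1/H3K27ac, central DNase, divergent
# GRO-seq) and promoters (H3K4me3-high), the test bed for every stage.
# All signal lives on a 10-bp grid; background noise is exponential with
# mean 0.05 x peak amplitude / snr.

.sim_grid <- 10L

.sim_amps <- list(dnase = 4, h3k4me1 = 3, h3k27ac = 3, h3k4me3 = 4,
                  prom_dnase = 3, prom_h3k4me1 = 0.5,
                  gro_active_sense = 6, gro_active_anti = 5,
                  gro_primed = 1)

#' Simulate a ground-truth genome layout
#'
#' Places `n_enhancers` enhancer elements (500 bp) and `n_genes` genes
#' (1--3 kb, stranded, two exons) uniformly at random on the toy genome,
#' rejecting placements closer than `spacing` bp to any accepted element,
#' so planted signals never blend.  `round(n_enhancers * frac_active)`
#' enhancers are assigned the active state (H3K27ac-positive, strong
#' eRNA), the rest primed.  Every gene gets a planted mean expression
#' level (log-normal; a tenth of genes are silent).  Everything is a pure
#' function of (parameters, seed).
#'
#' @param n_enhancers Number of planted enhancers (default 50).
#' @param frac_active Fraction assigned the active state (default 0.6).
#' @param n_genes Number of genes (default 150).
#' @param genome A `Seqinfo`; default two 1-Mb chromosomes.
#' @param spacing Minimum gap between planted elements, bp (default 2000).
#' @param seed Integer seed.
#' @return A list of class `synthetic_truth`: `genome`, `enhancers`
#'   (`GRanges` with `state`), `genes` (annotation `GRanges` with
#'   `planted_mean`), `seed` and the parameters.
#' @export
simulate_truth <- function(n_enhancers = 50L, frac_active = 0.6,
                           n_genes = 150L, genome = NULL,
                           spacing = 2000L, seed = 1L) {
  if (is.null(genome))
    genome <- genome_from_lengths(c(chrS1 = 1e6, chrS2 = 1e6))
  stopifnot(n_enhancers >= 1, n_genes >= 1,
            frac_active >= 0, frac_active <= 1)
  set.seed(seed)
  sl <- GenomeInfoDb::seqlengths(genome)
  chroms <- GenomeInfoDb::seqnames(genome)

  enh_width <- 500L
  gene_widths <- sample(1000:3000, n_genes, replace = TRUE)
  widths <- c(rep(enh_width, n_enhancers), gene_widths)
  kinds <- rep(c("enhancer", "gene"), c(n_enhancers, n_genes))

  margin <- 4000L  # keep flanking signal and promoters inside the chromosome
  if (all(sl - 2 * margin - max(widths) <= 0))
    stop("genome too small for planted elements with the required margin")
  acc_chr <- character(0); acc_st <- integer(0); acc_en <- integer(0)
  max_attempts_each <- 1000L
  for (i in seq_along(widths)) {
    w <- widths[i]
    placed <- FALSE
    for (attempt in seq_len(max_attempts_each)) {
      ch <- sample(chroms, 1, prob = sl / sum(sl))
      lo <- margin
      hi <- sl[[ch]] - margin - w
      if (hi <= lo) next
      st <- lo + floor(stats::runif(1) * (hi - lo + 1))
      en <- st + w - 1L
      same <- acc_chr == ch
      if (!any(same) ||
          all(pmax(0L, pmax(acc_st[same] - en, st - acc_en[same]) - 1L) >= spacing)) {
        acc_chr <- c(acc_chr, ch); acc_st <- c(acc_st, as.integer(st))
        acc_en <- c(acc_en, as.integer(en))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("cannot place ", length(widths), " elements with ", spacing,
           "-bp spacing on this genome (density infeasible)")
  }

  is_enh <- kinds == "enhancer"
  enhancers <- GenomicRanges::GRanges(acc_chr[is_enh],
                                      IRanges::IRanges(acc_st[is_enh],
                                                       acc_en[is_enh]),
                                      seqinfo = genome)
  n_active <- round(n_enhancers * frac_active)
  state <- rep("primed", n_enhancers)
  state[sample(n_enhancers, n_active)] <- "active"
  ord <- order(match(acc_chr[is_enh], chroms), acc_st[is_enh])
  enhancers <- enhancers[ord]
  enhancers$state <- factor(state[ord], levels = c("active", "primed"))
  names(enhancers) <- paste0("truth_enh_", seq_along(enhancers))

  genes <- GenomicRanges::GRanges(acc_chr[!is_enh],
                                  IRanges::IRanges(acc_st[!is_enh],
                                                   acc_en[!is_enh]),
                                  strand = sample(c("+", "-"), n_genes,
                                                  replace = TRUE),
                                  seqinfo = genome)
  gord <- order(match(acc_chr[!is_enh], chroms), acc_st[!is_enh])
  genes <- genes[gord]
  genes$gene_id <- paste0("g", seq_along(genes))
  genes$symbol <- genes$gene_id
  # two exons covering the first and last 40% of the gene body
  gw <- BiocGenerics::width(genes)
  ex1 <- pmax(1L, as.integer(gw * 0.4))
  genes$exon_length <- as.numeric(2L * ex1)
  genes$exon1_width <- ex1
  genes$tss <- ifelse(as.character(BiocGenerics::strand(genes)) == "+",
                      BiocGenerics::start(genes), BiocGenerics::end(genes))
  mean_expr <- stats::rlnorm(n_genes, meanlog = log(200), sdlog = 1)
  silent <- sample(n_genes, max(1L, round(n_genes * 0.1)))
  mean_expr[silent] <- 0
  genes$planted_mean <- mean_expr
  names(genes) <- genes$gene_id

  structure(list(genome = genome, enhancers = enhancers, genes = genes,
                 seed = as.integer(seed),
                 params = list(n_enhancers = n_enhancers,
                               frac_active = frac_active,
                               n_genes = n_genes, spacing = spacing,
                               enh_width = enh_width)),
            class = "synthetic_truth")
}

.grid_to_track <- function(vals, chrom, chrom_len, genome) {
  grid <- .sim_grid
  n <- length(vals)
  st <- (seq_len(n) - 1L) * grid + 1L
  en <- pmin(chrom_len, seq_len(n) * grid)
  r <- rle(vals)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(st[idx_start], en[idx_end]),
                               seqinfo = genome)
  gr$score <- r$values
  gr
}

.add_bump <- function(vals, center, amp, sd) {
  grid <- .sim_grid
  n <- length(vals)
  lo <- max(1L, floor((center - 4 * sd) / grid))
  hi <- min(n, ceiling((center + 4 * sd) / grid))
  if (hi < lo) return(vals)
  x <- (lo:hi - 0.5) * grid
  vals[lo:hi] <- vals[lo:hi] + amp * exp(-(x - center)^2 / (2 * sd^2))
  vals
}

#' Simulate marker coverage tracks from a planted truth
#'
#' Emits six RPM-like step-function tracks.  At each enhancer (center c):
#' DNase is a central bump (the nucleosome-free region); H3K4me1 -- and,
#' for active enhancers, H3K27ac -- are two flanking bumps at c +/- 250
#' with a central dip (the peak-valley-peak signature of the flanking
#' nucleosomes); GRO-seq plus/minus are divergent bumps at c +/- 150, with
#' a 6:1 (sense) and 5:1 (antisense) active:primed amplitude contrast.
#' At each promoter: H3K4me3 high, DNase moderate, H3K4me1 low.
#' Exponential background noise with mean `0.05 * peak_amplitude / snr`
#' is added everywhere; `snr = Inf` turns noise off.  Values are rounded
#' to 4 decimals so tracks round-trip exactly through bedGraph.
#'
#' @param truth A `synthetic_truth`.
#' @param snr Signal-to-noise ratio (default 5).
#' @param seed Integer seed for the noise.
#' @return Named list of coverage `GRanges`: `DNase`, `H3K4me1`,
#'   `H3K27ac`, `H3K4me3`, `GRO_plus`, `GRO_minus`.
#' @export
simulate_tracks <- function(truth, snr = 5, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), snr > 0)
  set.seed(seed)
  genome <- truth$genome
  sl <- GenomeInfoDb::seqlengths(genome)
  A <- .sim_amps
  marker_names <- c("DNase", "H3K4me1", "H3K27ac", "H3K4me3",
                    "GRO_plus", "GRO_minus")
  tracks <- stats::setNames(vector("list", length(marker_names)),
                            marker_names)
  parts <- lapply(tracks, function(x) list())

  for (ch in GenomeInfoDb::seqnames(genome)) {
    ncell <- ceiling(sl[[ch]] / .sim_grid)
    vals <- lapply(marker_names, function(x) numeric(ncell))
    names(vals) <- marker_names

    enh <- truth$enhancers[as.character(
      GenomeInfoDb::seqnames(truth$enhancers)) == ch]
    for (i in seq_along(enh)) {
      c0 <- BiocGenerics::start(enh)[i] +
        BiocGenerics::width(enh)[i] %/% 2L
      active <- enh$state[i] == "active"
      vals$DNase <- .add_bump(vals$DNase, c0, A$dnase, 80)
      vals$H3K4me1 <- .add_bump(vals$H3K4me1, c0 - 250, A$h3k4me1, 120)
      vals$H3K4me1 <- .add_bump(vals$H3K4me1, c0 + 250, A$h3k4me1, 120)
      if (active) {
        vals$H3K27ac <- .add_bump(vals$H3K27ac, c0 - 250, A$h3k27ac, 120)
        vals$H3K27ac <- .add_bump(vals$H3K27ac, c0 + 250, A$h3k27ac, 120)
      }
      amp_s <- if (active) A$gro_active_sense else A$gro_primed
      amp_a <- if (active) A$gro_active_anti else A$gro_primed
      vals$GRO_plus <- .add_bump(vals$GRO_plus, c0 + 150, amp_s, 100)
      vals$GRO_minus <- .add_bump(vals$GRO_minus, c0 - 150, amp_a, 100)
    }

    gen <- truth$genes[as.character(
      GenomeInfoDb::seqnames(truth$genes)) == ch]
    for (i in seq_along(gen)) {
      t0 <- gen$tss[i]
      vals$H3K4me3 <- .add_bump(vals$H3K4me3, t0, A$h3k4me3, 150)
      vals$DNase <- .add_bump(vals$DNase, t0, A$prom_dnase, 80)
      vals$H3K4me1 <- .add_bump(vals$H3K4me1, t0, A$prom_h3k4me1, 150)
    }

    for (mk in marker_names) {
      if (is.finite(snr)) {
        noise_mean <- 0.05 * A$dnase / snr
        vals[[mk]] <- vals[[mk]] +
          stats::rexp(ncell, rate = 1 / noise_mean)
      }
      v <- round(vals[[mk]], 4)
      parts[[mk]][[ch]] <- .grid_to_track(v, ch, sl[[ch]], genome)
    }
  }
  for (mk in marker_names)
    tracks[[mk]] <- BiocGenerics::sort(do.call(c, unname(parts[[mk]])))
  tracks
}

#' Simulate DHS narrowPeak calls for a planted truth
#'
#' One q-passing peak (-log10 q >= 2, i.e. q < 0.01) is placed over every
#' planted enhancer's center, plus `n_decoys` decoy peaks at random
#' background sites with -log10 q < 2 -- these decoys must all be removed
#' by the q-filter on read.
#'
#' @param truth A `synthetic_truth`.
#' @param n_decoys Number of failing decoy peaks (default 30).
#' @param seed Integer seed.
#' @return An unfiltered peak `GRanges` with narrowPeak metadata columns.
#' @export
simulate_dhs_peaks <- function(truth, n_decoys = 30L, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  genome <- truth$genome
  sl <- GenomeInfoDb::seqlengths(genome)
  enh <- truth$enhancers
  width <- 300L
  c0 <- BiocGenerics::start(enh) + BiocGenerics::width(enh) %/% 2L
  jitter <- as.integer(round(stats::runif(length(enh), -50, 50)))
  st <- c0 + jitter - width %/% 2L
  real <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(enh),
                                 IRanges::IRanges(st, st + width - 1L),
                                 seqinfo = genome)
  real$name <- paste0("dhs_", seq_along(real))
  real$score <- 0L
  real$signalValue <- round(stats::runif(length(real), 5, 50), 3)
  real$qValue <- round(2 + stats::rexp(length(real), 1 / 15), 3)
  real$pValue <- real$qValue + 1
  real$peak <- width %/% 2L

  decoys <- GenomicRanges::GRanges(seqinfo = genome)
  if (n_decoys > 0) {
    chroms <- GenomeInfoDb::seqnames(genome)
    dc <- character(0); ds <- integer(0)
    while (length(ds) < n_decoys) {
      ch <- sample(chroms, 1, prob = sl / sum(sl))
      s <- 1L + floor(stats::runif(1) * (sl[[ch]] - width))
      cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(s, s + width - 1L),
                                     seqinfo = genome)
      if (!any(IRanges::overlapsAny(cand, enh))) {
        dc <- c(dc, ch); ds <- c(ds, as.integer(s))
      }
    }
    decoys <- GenomicRanges::GRanges(dc, IRanges::IRanges(ds, ds + width - 1L),
                                     seqinfo = genome)
    decoys$name <- paste0("decoy_", seq_along(decoys))
    decoys$score <- 0L
    decoys$signalValue <- round(stats::runif(length(decoys), 0.1, 2), 3)
    decoys$qValue <- round(stats::runif(length(decoys), 0, 1.9), 3)
    decoys$pValue <- decoys$qValue + 0.5
    decoys$peak <- width %/% 2L
  }
  BiocGenerics::sort(c(real, decoys))
}

#' Simulate strand-split reads for fragment-length estimation
#'
#' Places `n_fragments` fragments of the given length uniformly on a
#' single test chromosome; the plus-strand read 5' start is the fragment
#' start, the minus-strand read 5' end is the fragment end (both
#' 0-based).
#'
#' @param fragment_length Planted fragment length, bp.
#' @param n_fragments Number of fragments (default 2000).
#' @param read_length Sequenced read length, bp (metadata only).
#' @param chrom_length Length of the test chromosome (default 100 kb).
#' @param seed Integer seed.
#' @return A list with `plus`/`minus` per-chromosome position lists and
#'   `read_length`.
#' @export
simulate_reads_for_fraglen <- function(fragment_length = 150L,
                                       n_fragments = 2000L,
                                       read_length = 36L,
                                       chrom_length = 100000L, seed = 1L) {
  stopifnot(fragment_length >= 1, n_fragments >= 1,
            chrom_length > fragment_length)
  set.seed(seed)
  s <- sort(floor(stats::runif(n_fragments) *
                    (chrom_length - fragment_length)))
  list(plus = list(chrF = s),
       minus = list(chrF = s + fragment_length),
       read_length = as.integer(read_length))
}

#' Simulate a gene-count table from planted expression means
#'
#' Counts are overdispersed non-negative integers (negative binomial,
#' size 10) around each gene's planted mean; a planted mean of zero
#' always yields a zero count.  The reported library total is the sum of
#' the counts.
#'
#' @param truth A `synthetic_truth`.
#' @param seed Integer seed.
#' @param dispersion Negative-binomial size parameter (default 10).
#' @return A list: `counts` (named vector), `lengths` (named exonic
#'   lengths) and `library_total`.
#' @export
simulate_expression <- function(truth, seed = 1L, dispersion = 10) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  mu <- truth$genes$planted_mean
  counts <- stats::rnbinom(length(mu), mu = mu, size = dispersion)
  counts[mu == 0] <- 0L
  names(counts) <- truth$genes$gene_id
  lengths <- stats::setNames(truth$genes$exon_length, truth$genes$gene_id)
  list(counts = counts, lengths = lengths, library_total = sum(counts))
}

.write_gtf <- function(genes, path) {
  rows <- character(0)
  for (i in seq_along(genes)) {
    ch <- as.character(GenomeInfoDb::seqnames(genes))[i]
    st <- BiocGenerics::start(genes)[i]
    en <- BiocGenerics::end(genes)[i]
    sd <- as.character(BiocGenerics::strand(genes))[i]
    gid <- genes$gene_id[i]
    attrs <- sprintf('gene_id "%s"; gene_name "%s";', gid, genes$symbol[i])
    rows <- c(rows, paste(ch, "sim", "gene", st, en, ".", sd, ".", attrs,
                          sep = "\t"))
    e1 <- genes$exon1_width[i]
    rows <- c(rows,
              paste(ch, "sim", "exon", st, st + e1 - 1L, ".", sd, ".",
                    attrs, sep = "\t"),
              paste(ch, "sim", "exon", en - e1 + 1L, en, ".", sd, ".",
                    attrs, sep = "\t"))
  }
  writeLines(rows, path)
  invisible(path)
}

.write_fasta <- function(genome, path, seed, n_run_frac = 0.01) {
  set.seed(seed)
  sl <- GenomeInfoDb::seqlengths(genome)
  seqs <- Biostrings::DNAStringSet(vapply(names(sl), function(ch) {
    len <- sl[[ch]]
    x <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    # plant a few N runs so the effective genome size differs from the
    # nominal length
    n_run <- max(1L, as.integer(len * n_run_frac / 500))
    for (k in seq_len(n_run)) {
      s <- 1L + floor(stats::runif(1) * (len - 500))
      x[s:(s + 499L)] <- "N"
    }
    paste(x, collapse = "")
  }, character(1)))
  names(seqs) <- names(sl)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a complete synthetic bundle to disk
#'
#' Emits every file the pipeline consumes: chrom.sizes, genome FASTA
#' (random sequence with planted N runs), six bedGraph tracks, DHS
#' narrowPeak, GTF gene annotation, gene-count TSV and a truth BED with
#' the planted state in the name column.  All files are valid inputs to
#' the package's readers.
#'
#' @param outdir Output directory (created if needed).
#' @param n_enhancers,frac_active,n_genes,snr,seed Simulator parameters;
#'   see [simulate_truth()] and [simulate_tracks()].
#' @param fasta Also write the genome FASTA (default TRUE; the slowest
#'   artifact).
#' @return Invisibly, a named list of the written paths plus the `truth`
#'   object.
#' @export
simulate_bundle <- function(outdir, n_enhancers = 50L, frac_active = 0.6,
                            n_genes = 150L, snr = 5, seed = 1L,
                            fasta = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_truth(n_enhancers = n_enhancers,
                          frac_active = frac_active,
                          n_genes = n_genes, seed = seed)
  tracks <- simulate_tracks(truth, snr = snr, seed = seed)
  dhs <- simulate_dhs_peaks(truth, seed = seed)
  expr <- simulate_expression(truth, seed = seed)

  paths <- list(truth = truth)
  p <- function(f) file.path(outdir, f)
  paths$chrom_sizes <- write_chrom_sizes(truth$genome, p("genome.chrom.sizes"))
  for (mk in names(tracks))
    paths[[mk]] <- write_bedgraph(tracks[[mk]],
                                  p(paste0(tolower(mk), ".bedgraph")))
  paths$dhs <- write_narrowpeak(dhs, p("dhs.narrowPeak"))
  paths$gtf <- .write_gtf(truth$genes, p("genes.gtf"))
  utils::write.table(data.frame(gene_id = names(expr$counts),
                                count = as.integer(expr$counts)),
                     p("counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths$counts <- p("counts.tsv")
  tb <- truth$enhancers
  names(tb) <- paste0(names(tb), "_", as.character(tb$state))
  paths$truth_bed <- write_bed(tb, p("truth_enhancers.bed"))
  if (fasta)
    paths$fasta <- .write_fasta(truth$genome, p("genome.fa"), seed)
  invisible(paths)
}
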