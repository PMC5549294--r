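#' Build a balanced enhancer / promoter training set
#'
#' The positive class is the supplied set of known enhancer elements; the
#' negative class is an equal number of promoter regions (TSS +/-
#' `promoter_flank`) for a seed-deterministic uniform sample of genes.  A
#' sampled promoter overlapping any enhancer is resampled (and the event
#' reported), so the two classes never share bases.  Features are mean
#' marker coverages (see [extract_features()]).
#'
#' @param enhancers `GRanges` of known enhancer elements.
#' @param genes Gene annotation `GRanges` from [read_gene_annotation()];
#'   must contain at least as many genes as there are enhancers.
#' @param tracks Named list of marker coverage tracks.
#' @param config A [scan_config()]; uses `promoter_flank` and `flank`.
#' @param seed Integer seed making the gene sample reproducible.
#' @return A list of class `training_set`: `features` (matrix), `labels`
#'   (factor, levels enhancer / non_enhancer), `elements` (`GRanges`) and
#'   `origin` (data.frame of per-row provenance).
#' @export
build_training_set <- function(enhancers, genes, tracks,
                               config = scan_config(), seed = 1L) {
  stopifnot(methods::is(enhancers, "GRanges"), methods::is(genes, "GRanges"))
  n <- length(enhancers)
  if (length(genes) < n)
    stop("need at least as many genes (", length(genes),
         ") as enhancers (", n, ") to sample promoter negatives")
  sl <- GenomeInfoDb::seqlengths(genes)

  promoter_of <- function(g) {
    tss <- g$tss
    chr <- as.character(GenomeInfoDb::seqnames(g))
    st <- pmax(1L, tss - config$promoter_flank)
    en <- pmin(sl[chr], tss + config$promoter_flank - 1L)
    GenomicRanges::GRanges(chr, IRanges::IRanges(st, en),
                           seqinfo = GenomeInfoDb::seqinfo(genes))
  }

  set.seed(seed)
  picked <- sample(length(genes), n)
  prom <- promoter_of(genes[picked])
  resampled <- 0L
  pool <- setdiff(seq_along(genes), picked)
  repeat {
    bad <- which(IRanges::overlapsAny(prom, enhancers, ignore.strand = TRUE))
    if (length(bad) == 0 || length(pool) == 0) break
    take <- pool[seq_len(min(length(bad), length(pool)))]
    pool <- setdiff(pool, take)
    replace_idx <- bad[seq_along(take)]
    picked[replace_idx] <- take
    prom[replace_idx] <- promoter_of(genes[take])
    resampled <- resampled + length(take)
  }
  if (resampled > 0)
    message("build_training_set: resampled ", resampled,
            " promoter(s) overlapping an enhancer")
  if (any(IRanges::overlapsAny(prom, enhancers, ignore.strand = TRUE)))
    stop("could not sample enhancer-free promoters: gene pool exhausted")

  pos <- GenomicRanges::granges(enhancers)
  names(pos) <- paste0("enh_", seq_len(n))
  names(prom) <- paste0("prom_", genes$gene_id[picked])
  elements <- c(pos, prom)
  features <- extract_features(elements, tracks, flank = config$flank)
  labels <- factor(rep(c("enhancer", "non_enhancer"), each = n),
                   levels = c("enhancer", "non_enhancer"))
  origin <- data.frame(row = rownames(features),
                       class_source = rep(c("enhancer", "promoter"), each = n),
                       gene_id = c(rep(NA_character_, n), genes$gene_id[picked]),
                       stringsAsFactors = FALSE)
  structure(list(features = features, labels = labels,
                 elements = elements, origin = origin),
            class = "training_set")
}

#' Stratified train/test split
#'
#' Per class, `round(n x test_fraction)` rows go to the test partition
#' (seed-deterministic); the partitions are disjoint and together cover
#' the input.
#'
#' @param ts A `training_set`.
#' @param test_fraction Fraction held out (default 1/3).
#' @param seed Integer seed.
#' @return A list with `train` and `test`, both `training_set` objects.
#' @export
split_train_test <- function(ts, test_fraction = 1 / 3, seed = 1L) {
  stopifnot(inherits(ts, "training_set"),
            test_fraction > 0, test_fraction < 1)
  counts <- table(ts$labels)
  if (any(counts < 2))
    stop("each class needs at least 2 rows to split")
  set.seed(seed)
  test_idx <- integer(0)
  for (cl in levels(ts$labels)) {
    rows <- which(ts$labels == cl)
    n_test <- round(length(rows) * test_fraction)
    test_idx <- c(test_idx, sample(rows, n_test))
  }
  test_idx <- sort(test_idx)
  subset_ts <- function(i) {
    f <- ts$features[i, , drop = FALSE]
    attr(f, "flank") <- attr(ts$features, "flank")
    attr(f, "markers") <- attr(ts$features, "markers")
    structure(list(features = f,
                   labels = droplevels_keep(ts$labels[i]),
                   elements = ts$elements[i],
                   origin = ts$origin[i, , drop = FALSE]),
              class = "training_set")
  }
  list(train = subset_ts(setdiff(seq_along(ts$labels), test_idx)),
       test = subset_ts(test_idx))
}

# keep both class levels even if a partition ends up one-sided
droplevels_keep <- function(f) factor(f, levels = c("enhancer", "non_enhancer"))

#' Train the enhancer random forest
#'
#' Fits a bagged ensemble of binary classification trees: each tree is
#' grown on a bootstrap sample of the training rows with a random subset
#' of `floor(sqrt(p))` markers considered at every split (the classical
#' random-forest construction).  The model records the marker order and
#' feature flank it was trained with and enforces both at prediction time.
#'
#' @param train A `training_set` containing both classes.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed for the bootstrap / feature sampling.
#' @return A list of class `enhancer_model`: `forest`, `markers`, `flank`,
#'   `n_trees`, `seed`, and `held_out` (NULL until [evaluate_model()] is
#'   stored into it).
#' @export
train_classifier <- function(train, n_trees = 500L, seed = 1L) {
  stopifnot(inherits(train, "training_set"))
  if (length(unique(train$labels)) < 2)
    stop("training set must contain both classes")
  const <- apply(train$features, 2, function(x) length(unique(x)) == 1)
  if (any(const))
    warning("constant feature(s) across all training rows: ",
            paste(colnames(train$features)[const], collapse = ", "))
  p <- ncol(train$features)
  set.seed(seed)
  forest <- randomForest::randomForest(
    x = train$features, y = train$labels,
    ntree = as.integer(n_trees), mtry = max(1L, floor(sqrt(p))))
  structure(list(forest = forest,
                 markers = colnames(train$features),
                 flank = attr(train$features, "flank"),
                 n_trees = as.integer(n_trees),
                 seed = as.integer(seed),
                 held_out = NULL),
            class = "enhancer_model")
}

#' Enhancer-class probability for a feature matrix
#'
#' @param model An `enhancer_model` (or, for diagnostic use, a function
#'   mapping a feature matrix to probabilities).
#' @param features Matrix with the model's marker columns.
#' @return Numeric vector of P(enhancer), one per row.
#' @export
predict_enhancer_prob <- function(model, features) {
  if (is.function(model)) return(model(features))
  stopifnot(inherits(model, "enhancer_model"))
  have <- colnames(features)
  missing <- setdiff(model$markers, have)
  extra <- setdiff(have, model$markers)
  if (length(missing) || length(extra))
    stop("marker mismatch with model: missing [",
         paste(missing, collapse = ", "), "], extra [",
         paste(extra, collapse = ", "), "]")
  features <- features[, model$markers, drop = FALSE]
  stats::predict(model$forest, features, type = "prob")[, "enhancer"]
}

#' Evaluate a model on a held-out set
#'
#' Classifies every test row at the probability threshold and tabulates
#' the confusion matrix with "enhancer" as the positive class.
#'
#' @param model An `enhancer_model` or a probability function (see
#'   [predict_enhancer_prob()]).
#' @param test A `training_set` with the model's markers.
#' @param prob_threshold Probability at or above which a row is classed
#'   enhancer (default 0.5).
#' @return A list of class `confusion_matrix`: `TP`, `FP`, `TN`, `FN`,
#'   `accuracy`.
#' @export
evaluate_model <- function(model, test, prob_threshold = 0.5) {
  stopifnot(inherits(test, "training_set"))
  prob <- predict_enhancer_prob(model, test$features)
  pred <- ifelse(prob >= prob_threshold, "enhancer", "non_enhancer")
  truth <- as.character(test$labels)
  cm <- list(TP = sum(pred == "enhancer" & truth == "enhancer"),
             FP = sum(pred == "enhancer" & truth == "non_enhancer"),
             TN = sum(pred == "non_enhancer" & truth == "non_enhancer"),
             FN = sum(pred == "non_enhancer" & truth == "enhancer"))
  cm$accuracy <- (cm$TP + cm$TN) / length(truth)
  structure(cm, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (positive class: enhancer)\n")
  cat(sprintf("  TP %d  FP %d\n  FN %d  TN %d\n", x$TP, x$FP, x$FN, x$TN))
  cat(sprintf("  accuracy %.4f\n", x$accuracy))
  invisible(x)
}

#' @export
print.enhancer_model <- function(x, ...) {
  cat("Enhancer random-forest model:", x$n_trees, "trees, markers [",
      paste(x$markers, collapse = ", "), "], feature flank", x$flank, "bp\n")
  if (!is.null(x$held_out))
    cat(sprintf("  held-out accuracy %.4f\n", x$held_out$accuracy))
  invisible(x)
}

.model_format_version <- 1L

#' Save / load a trained enhancer model
#'
#' The model is serialized to a single file with a format-version header,
#' the marker order, feature flank, training seed and held-out confusion
#' matrix embedded; loading refuses a file with a different format
#' version.
#'
#' @param model An `enhancer_model`.
#' @param path File path.
#' @return `save_enhancer_model` returns the path invisibly;
#'   `load_enhancer_model` returns the model.
#' @export
save_enhancer_model <- function(model, path) {
  stopifnot(inherits(model, "enhancer_model"))
  payload <- list(format_version = .model_format_version,
                  package = "enhancerscan",
                  markers = model$markers, flank = model$flank,
                  n_trees = model$n_trees, seed = model$seed,
                  held_out = model$held_out, forest = model$forest)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_enhancer_model
#' @export
load_enhancer_model <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format_version, .model_format_version))
    stop("model file format version ", payload$format_version,
         " not supported (expected ", .model_format_version, ")")
  structure(list(forest = payload$forest, markers = payload$markers,
                 flank = payload$flank, n_trees = payload$n_trees,
                 seed = payload$seed, held_out = payload$held_out),
            class = "enhancer_model")
}
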