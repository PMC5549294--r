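# deterministic separable features for classifier sanity checks: enhancers
# high H3K4me1 / low H3K4me3, promoters reversed
separable_training_set <- function(n_per_class = 60, seed = 1) {
  set.seed(seed)
  enh <- cbind(DNase = stats::runif(n_per_class, 2, 4),
               H3K4me1 = stats::runif(n_per_class, 2, 4),
               H3K27ac = stats::runif(n_per_class, 0, 3),
               H3K4me3 = stats::runif(n_per_class, 0, 0.3))
  prom <- cbind(DNase = stats::runif(n_per_class, 2, 4),
                H3K4me1 = stats::runif(n_per_class, 0, 0.3),
                H3K27ac = stats::runif(n_per_class, 0, 1),
                H3K4me3 = stats::runif(n_per_class, 2, 4))
  feats <- rbind(enh, prom)
  rownames(feats) <- c(paste0("enh_", seq_len(n_per_class)),
                       paste0("prom_", seq_len(n_per_class)))
  attr(feats, "flank") <- 0L
  attr(feats, "markers") <- colnames(feats)
  gn <- genome_from_lengths(c(chrA = 1e6))
  els <- GenomicRanges::GRanges("chrA",
                                IRanges::IRanges(seq_len(2 * n_per_class) * 1000,
                                                 width = 200),
                                seqinfo = gn)
  names(els) <- rownames(feats)
  structure(list(features = feats,
                 labels = factor(rep(c("enhancer", "non_enhancer"),
                                     each = n_per_class),
                                 levels = c("enhancer", "non_enhancer")),
                 elements = els,
                 origin = data.frame(row = rownames(feats))),
            class = "training_set")
}

test_that("build_training_set balances classes and resamples clashing promoters", {
  bm <- small_benchmark(seed = 4)
  cfg <- scan_config()
  ts <- build_training_set(bm$truth$enhancers, bm$truth$genes, bm$marks,
                           cfg, seed = 1)
  n <- length(bm$truth$enhancers)
  expect_equal(as.vector(table(ts$labels)), c(n, n))
  expect_equal(nrow(ts$features), 2 * n)
  # promoter windows are TSS +/- 1 kb and never overlap an enhancer
  prom <- ts$elements[ts$labels == "non_enhancer"]
  expect_true(all(BiocGenerics::width(prom) == 2 * cfg$promoter_flank))
  expect_false(any(IRanges::overlapsAny(prom, bm$truth$enhancers)))

  # same seed -> identical sample; different seed -> different, same size
  ts2 <- build_training_set(bm$truth$enhancers, bm$truth$genes, bm$marks,
                            cfg, seed = 1)
  expect_identical(ts$origin$gene_id, ts2$origin$gene_id)
  ts3 <- build_training_set(bm$truth$enhancers, bm$truth$genes, bm$marks,
                            cfg, seed = 2)
  expect_false(identical(ts$origin$gene_id, ts3$origin$gene_id))
  expect_equal(nrow(ts3$features), 2 * n)

  # too few genes is an error
  expect_error(build_training_set(bm$truth$enhancers, bm$truth$genes[1:3],
                                  bm$marks, cfg, seed = 1),
               "at least as many genes")
})

test_that("split_train_test is a stratified, seed-deterministic disjoint cover", {
  ts <- separable_training_set(150)
  parts <- split_train_test(ts, 1 / 3, seed = 1)
  expect_equal(as.vector(table(parts$test$labels)), c(50, 50))
  expect_equal(as.vector(table(parts$train$labels)), c(100, 100))
  expect_length(intersect(rownames(parts$train$features),
                          rownames(parts$test$features)), 0)
  expect_setequal(c(rownames(parts$train$features),
                    rownames(parts$test$features)), rownames(ts$features))

  # round(4/3) = 1 per class
  small <- separable_training_set(4)
  p4 <- split_train_test(small, 1 / 3, seed = 1)
  expect_equal(as.vector(table(p4$test$labels)), c(1, 1))

  # determinism
  again <- split_train_test(ts, 1 / 3, seed = 1)
  expect_identical(rownames(again$test$features),
                   rownames(parts$test$features))

  tiny <- separable_training_set(4)
  tiny$features <- tiny$features[c(1, 5), ]
  tiny$labels <- tiny$labels[c(1, 5)]
  expect_error(split_train_test(tiny, 1 / 3), "at least 2 rows")
})

test_that("the forest separates separable classes and is at chance on shuffled labels", {
  ts <- separable_training_set(60, seed = 2)
  parts <- split_train_test(ts, 1 / 3, seed = 2)
  model <- train_classifier(parts$train, n_trees = 200, seed = 2)
  expect_equal(evaluate_model(model, parts$train)$accuracy, 1.0)
  expect_equal(evaluate_model(model, parts$test)$accuracy, 1.0)

  # label shuffling destroys the signal: held-out accuracy ~ 0.5
  accs <- numeric(10)
  for (r in 1:10) {
    shuffled <- separable_training_set(60, seed = 7)
    set.seed(7 + r)
    shuffled$labels <- sample(shuffled$labels)
    sp <- split_train_test(shuffled, 1 / 3, seed = r)
    m <- train_classifier(sp$train, n_trees = 100, seed = r)
    accs[r] <- evaluate_model(m, sp$test)$accuracy
  }
  expect_true(abs(mean(accs) - 0.5) <= 0.1)
})

test_that("prediction is deterministic and enforces the marker contract", {
  ts <- separable_training_set(40, seed = 3)
  model <- train_classifier(ts, n_trees = 100, seed = 3)
  p1 <- predict_enhancer_prob(model, ts$features)
  p2 <- predict_enhancer_prob(model, ts$features)
  expect_identical(p1, p2)

  bad <- ts$features[, c("DNase", "H3K4me1", "H3K27ac")]
  expect_error(predict_enhancer_prob(model, bad), "marker mismatch.*H3K4me3")
  worse <- cbind(ts$features, Extra = 1)
  expect_error(predict_enhancer_prob(model, worse), "extra \\[Extra\\]")
  # column order does not matter: reordered features give identical output
  reord <- ts$features[, c(4, 3, 2, 1)]
  expect_identical(predict_enhancer_prob(model, reord), p1)
})

test_that("evaluate_model tabulates the confusion matrix by hand-checkable rules", {
  # stump model: enhancer iff H3K4me1 > 1, on an enumerated 8-row table
  stump <- function(features) as.numeric(features[, "H3K4me1"] > 1)
  feats <- cbind(DNase = rep(1, 8),
                 H3K4me1 = c(2, 2, 0.5, 0.5, 2, 0.5, 2, 0.5),
                 H3K27ac = rep(0, 8), H3K4me3 = rep(0, 8))
  rownames(feats) <- paste0("r", 1:8)
  labels <- factor(c("enhancer", "enhancer", "enhancer", "enhancer",
                     "non_enhancer", "non_enhancer", "non_enhancer",
                     "non_enhancer"),
                   levels = c("enhancer", "non_enhancer"))
  test_ts <- structure(list(features = feats, labels = labels,
                            elements = NULL, origin = NULL),
                       class = "training_set")
  cm <- evaluate_model(stump, test_ts)
  # hand enumeration: rows 1,2 TP; 3,4 FN; 5,7 FP; 6,8 TN
  expect_equal(cm$TP, 2); expect_equal(cm$FN, 2)
  expect_equal(cm$FP, 2); expect_equal(cm$TN, 2)
  expect_equal(cm$accuracy, 0.5)

  # all correct / all inverted
  perfect <- function(features) as.numeric(grepl("^r[1-4]$", rownames(features)))
  expect_equal(evaluate_model(perfect, test_ts)$accuracy, 1.0)
  inverted <- function(features) 1 - perfect(features)
  expect_equal(evaluate_model(inverted, test_ts)$accuracy, 0.0)
})

test_that("models persist with metadata and refuse other format versions", {
  ts <- separable_training_set(30, seed = 5)
  model <- train_classifier(ts, n_trees = 50, seed = 5)
  model$held_out <- evaluate_model(model, ts)
  f <- withr::local_tempfile(fileext = ".rds")
  save_enhancer_model(model, f)
  back <- load_enhancer_model(f)
  expect_equal(back$markers, model$markers)
  expect_equal(back$flank, model$flank)
  expect_equal(back$held_out$accuracy, model$held_out$accuracy)
  expect_identical(predict_enhancer_prob(back, ts$features),
                   predict_enhancer_prob(model, ts$features))

  payload <- readRDS(f)
  payload$format_version <- 99L
  saveRDS(payload, f)
  expect_error(load_enhancer_model(f), "format version")
})
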