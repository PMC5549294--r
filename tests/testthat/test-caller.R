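# a trained model plus its simulated world, shared across caller tests
caller_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bm <- small_benchmark(seed = 1)
      cfg <- scan_config()
      ts <- build_training_set(bm$truth$enhancers, bm$truth$genes, bm$marks,
                               cfg, seed = 1)
      parts <- split_train_test(ts, cfg$test_fraction, seed = 1)
      model <- train_classifier(parts$train, n_trees = 200, seed = 1)
      cache <<- list(bm = bm, cfg = cfg, model = model, parts = parts)
    }
    cache
  }
})

test_that("scan_genome scores every window and flags planted enhancer windows", {
  fx <- caller_fixture()
  scored <- scan_genome(fx$model, fx$bm$truth$genome, fx$bm$marks, fx$cfg)
  expect_equal(length(scored),
               sum(ceiling(GenomeInfoDb::seqlengths(fx$bm$truth$genome) / 200)))
  expect_true(all(scored$probability >= 0 & scored$probability <= 1))
  # windows over planted enhancer centers must be classed enhancer
  centers <- GenomicRanges::resize(fx$bm$truth$enhancers, 1, fix = "center")
  hit <- scored[IRanges::overlapsAny(scored, centers)]
  expect_true(all(hit$enhancer))
})

test_that("an all-zero genome yields zero enhancer windows for this model", {
  fx <- caller_fixture()
  gn <- fx$bm$truth$genome
  zero <- GenomicRanges::GRanges(seqinfo = gn)
  zero$score <- numeric(0)
  zeros <- list(DNase = zero, H3K4me1 = zero, H3K27ac = zero, H3K4me3 = zero)
  # the model's zero-vector prediction is non-enhancer (no H3K4me1/DNase)
  feat0 <- matrix(0, 1, 4, dimnames = list("z", names(zeros)))
  if (predict_enhancer_prob(fx$model, feat0) < 0.5) {
    scored <- scan_genome(fx$model, gn, zeros, fx$cfg)
    expect_equal(sum(scored$enhancer), 0L)
  } else {
    succeed("zero-vector prediction is not non-enhancer for this forest")
  }
})

test_that("call_enhancers merges enhancer windows like the per-base oracle", {
  gn <- toy_genome(c(chrA = 10000L))
  win <- make_windows(gn, 200)
  set.seed(14)
  for (rep in 1:20) {
    win$enhancer <- stats::runif(length(win)) < 0.3
    win$probability <- round(stats::runif(length(win)), 3)
    calls <- call_enhancers(win, scan_config())
    df <- granges_to_df(win[win$enhancer])
    want <- oracle_merge(df, 1L, c(chrA = 10000L))
    expect_equal(granges_to_df(calls), want, ignore_attr = TRUE)
    # probability is the max over member windows
    for (i in seq_along(calls)) {
      members <- win$enhancer &
        IRanges::overlapsAny(win, calls[i])
      expect_equal(calls$probability[i], max(win$probability[members]))
    }
  }
  # adjacency and isolation
  win$enhancer <- FALSE
  win$enhancer[11:12] <- TRUE  # windows [2000,2200) and [2200,2400)
  one <- call_enhancers(win, scan_config())
  expect_equal(granges_to_df(one),
               data.frame(chrom = "chrA", start = 2000L, end = 2400L))
  win$enhancer <- FALSE
  win$enhancer[5] <- TRUE
  expect_equal(BiocGenerics::width(call_enhancers(win, scan_config())), 200L)
})

test_that("DHS validation applies the single-bp overlap rule and is monotone", {
  gn <- toy_genome(c(chrA = 10000L))
  cfg <- scan_config()
  call <- df_to_granges(data.frame(chrom = "chrA", start = 0, end = 400), gn)
  call$probability <- 0.9
  touching <- df_to_granges(data.frame(chrom = "chrA", start = 399, end = 500), gn)
  beyond <- df_to_granges(data.frame(chrom = "chrA", start = 400, end = 500), gn)
  expect_length(validate_with_dhs(call, touching, cfg), 1L)
  expect_length(suppressMessages(validate_with_dhs(call, beyond, cfg)), 0L)
  expect_warning(validate_with_dhs(call, beyond[0], cfg), "empty DHS")

  set.seed(15)
  for (rep in 1:10) {
    calls <- df_to_granges(random_intervals(30, c(chrA = 10000L)), gn)
    calls$probability <- stats::runif(30)
    peaks <- df_to_granges(random_intervals(15, c(chrA = 10000L)), gn)
    got <- suppressMessages(validate_with_dhs(calls, peaks, cfg))
    want <- vapply(seq_along(calls), function(i)
      any(vapply(seq_along(peaks), function(j)
        oracle_overlap_bp(granges_to_df(calls[i]),
                          granges_to_df(peaks[j])) >= 1, logical(1))),
      logical(1))
    expect_equal(granges_to_df(got), granges_to_df(calls[want]),
                 ignore_attr = TRUE)
    # adding peaks never shrinks the validated set
    more <- c(peaks, df_to_granges(random_intervals(10, c(chrA = 10000L)), gn))
    got2 <- suppressMessages(validate_with_dhs(calls, more, cfg))
    expect_true(all(granges_to_df(got)$start %in% granges_to_df(got2)$start))
  }
})

test_that("state classification partitions calls at the H3K27ac threshold", {
  gn <- toy_genome(c(chrA = 10000L))
  k27 <- segments_to_track(data.frame(chrom = "chrA", start = 1000,
                                      end = 2000, value = 2), gn)
  calls <- df_to_granges(data.frame(chrom = "chrA",
                                    start = c(1200, 5000),
                                    end = c(1800, 5400)), gn)
  out <- classify_states(calls, k27, threshold = 0.5)
  expect_equal(as.character(out$state), c("active", "primed"))
  expect_equal(S4Vectors::metadata(out)$h3k27ac_threshold, 0.5)
  # zero coverage is primed under any positive threshold ("lack thereof")
  expect_equal(as.character(out$state[out$h3k27ac == 0]), "primed")
  # threshold above every mean -> all primed; partition is exact
  all_primed <- classify_states(calls, k27, threshold = 10)
  expect_true(all(all_primed$state == "primed"))
  expect_equal(sum(out$state == "active") + sum(out$state == "primed"),
               length(calls))
})

test_that("planted states are recovered on the simulated benchmark", {
  for (seed in 1:3) {
    bm <- small_benchmark(seed = seed)
    dhs <- simulate_dhs_peaks(bm$truth, seed = seed)
    dhs <- dhs[dhs$qValue >= 2]
    cfg <- scan_config()
    ts <- build_training_set(bm$truth$enhancers, bm$truth$genes, bm$marks,
                             cfg, seed = seed)
    parts <- split_train_test(ts, cfg$test_fraction, seed = seed)
    model <- train_classifier(parts$train, n_trees = 200, seed = seed)
    calls <- suppressMessages(
      predict_enhancers(model, bm$truth$genome, bm$marks, dhs, cfg))
    m <- IRanges::findOverlaps(calls, bm$truth$enhancers, select = "first")
    agree <- as.character(calls$state) ==
      as.character(bm$truth$enhancers$state[m])
    expect_gte(mean(agree, na.rm = TRUE), 0.9)
  }
})

test_that("eRNA coverage reports strand means and tolerates missing tracks", {
  gn <- toy_genome(c(chrA = 10000L))
  call <- df_to_granges(data.frame(chrom = "chrA", start = 1000, end = 1500), gn)
  plus <- segments_to_track(data.frame(chrom = "chrA", start = 1000,
                                       end = 1500, value = 6), gn)
  minus <- segments_to_track(data.frame(chrom = "chrA", start = 1000,
                                        end = 1500, value = 5), gn)
  out <- erna_coverage(call, plus, minus)
  expect_equal(out$erna_sense, 6.0)
  expect_equal(out$erna_antisense, 5.0)

  empty <- GenomicRanges::GRanges(seqinfo = gn); empty$score <- numeric(0)
  zz <- erna_coverage(call, empty, empty)
  expect_equal(zz$erna_sense, 0); expect_equal(zz$erna_antisense, 0)

  expect_warning(na_out <- erna_coverage(call, plus, NULL), "minus")
  expect_true(is.na(na_out$erna_antisense))
})

test_that("metagene matrices have the stated geometry and signal shape", {
  gn <- toy_genome(c(chrA = 100000L))
  uniform <- segments_to_track(data.frame(chrom = "chrA", start = 0,
                                          end = 100000, value = 1), gn)
  calls <- df_to_granges(data.frame(chrom = "chrA",
                                    start = c(20000, 50000, 80000),
                                    end = c(20400, 50500, 80300)), gn)
  m <- metagene_matrix(calls, uniform, flank = 3000, bin_size = 50)
  expect_equal(dim(m), c(3L, 120L))
  expect_true(all(m == 1))
  expect_equal(colnames(m)[1], "-3000")

  # peak-valley-peak: flanking H3K4me1 bins exceed the central dip
  bm <- small_benchmark(seed = 2)
  noise_free <- simulate_tracks(bm$truth, snr = Inf, seed = 2)
  mm <- metagene_matrix(bm$truth$enhancers, noise_free$H3K4me1,
                        flank = 1000, bin_size = 50,
                        rank_values = seq_along(bm$truth$enhancers))
  center_bins <- which(abs(as.numeric(colnames(mm))) <= 50)
  flank_bins <- which(abs(as.numeric(colnames(mm)) + 25 - (-250)) <= 50 |
                        abs(as.numeric(colnames(mm)) + 25 - 250) <= 50)
  expect_true(all(rowMeans(mm[, flank_bins]) > rowMeans(mm[, center_bins])))

  # rows ranked by decreasing rank value, ties by genome order
  calls$v <- c(3, 1, 3)
  mr <- metagene_matrix(calls, uniform, flank = 1000, bin_size = 100,
                        rank_values = calls$v)
  expect_equal(rownames(mr), c("el_1", "el_3", "el_2"))

  # bins clipped at the chromosome edge: zero-width parts contribute 0
  edge <- df_to_granges(data.frame(chrom = "chrA", start = 0, end = 200), gn)
  me <- metagene_matrix(edge, uniform, flank = 3000, bin_size = 50)
  expect_equal(unname(me[1, "-3000"]), 0)
  expect_equal(unname(me[1, "0"]), 1)
})
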