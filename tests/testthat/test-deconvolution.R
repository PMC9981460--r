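# DIA report filtering, pairing, normalisation, testing and gene calls.

make_report_row <- function(seq, quality = 0.9, label = "H", qty = 100,
                            run = "run01", proteotypic = 1L,
                            gene = "G1", charge = 2L) {
  data.frame(Run = run, Stripped.Sequence = seq,
             Precursor.Charge = charge, Label = label,
             Precursor.Quantity = qty, Quantity.Quality = quality,
             Protein.Group = paste0(gene, "_PG"), Genes = gene,
             Proteotypic = proteotypic, stringsAsFactors = FALSE)
}

test_that("report filtering applies the composition and quality rules", {
  rep <- rbind(make_report_row("AAVLK", 0.9),    # kept
               make_report_row("AKVLR", 0.9),    # internal K
               make_report_row("AAVLK", 0.7),    # quality not strict >
               make_report_row("AAVKK", 0.9),    # two lysines
               make_report_row("AAVLR", 0.9),    # no lysine
               make_report_row("AAVLK", 0.9, proteotypic = 0L))
  kept <- load_and_filter(rep)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$Quantity.Quality, 0.9)
  # Data.File accepted as an alias for Run
  rep2 <- rep; names(rep2)[names(rep2) == "Run"] <- "Data.File"
  expect_identical(nrow(load_and_filter(rep2)), 1L)
  expect_error(load_and_filter(rep[, -4]), "Label")
})

test_that("pair matching requires exactly one record per side", {
  rep <- rbind(make_report_row("AAVLK", label = "H", qty = 120),
               make_report_row("AAVLK", label = "L", qty = 60),
               make_report_row("GAVLK", label = "H"),           # unmatched
               make_report_row("TAVLK", label = "H", qty = 10), # duplicate H
               make_report_row("TAVLK", label = "H", qty = 20),
               make_report_row("TAVLK", label = "L"))
  mp <- match_pairs(load_and_filter(rep))
  expect_identical(unname(mp$counts),
                   c(1L, 1L, 1L))
  expect_identical(mp$pairs$Stripped.Sequence, "AAVLK")
  expect_equal(mp$pairs$ratio, 2)
})

test_that("sample QC excludes low-ID and ratio-outlier runs", {
  set.seed(4)
  runs <- sprintf("run%02d", 1:8)
  pairs <- do.call(rbind, lapply(runs, function(r)
    data.frame(Run = r, Stripped.Sequence = sprintf("PEP%03dK", 1:40),
               Precursor.Charge = 2L, Genes = "G1", Protein.Group = "P",
               heavy = 100, light = 100,
               ratio = exp(rnorm(40, 0, 0.1)))))
  # run08: only 4 pairs (10% of the cohort median)
  pairs <- pairs[!(pairs$Run == "run08" &
                     pairs$Stripped.Sequence > "PEP004K"), ]
  # run07: median ratio shifted by 2^2
  pairs$ratio[pairs$Run == "run07"] <-
    pairs$ratio[pairs$Run == "run07"] * 4
  qc <- qc_samples(pairs)
  expect_setequal(qc$excluded, c("run07", "run08"))
  expect_length(qc$kept, 6L)
  # identical samples: none excluded
  qc2 <- qc_samples(pairs[pairs$Run %in% c("run01", "run02"), ])
  expect_length(qc2$excluded, 0L)
  # deviation exactly at the threshold is kept (strict inequality)
  p3 <- rbind(
    data.frame(Run = "a", Stripped.Sequence = sprintf("P%dK", 1:5),
               Precursor.Charge = 2L, Genes = "G", Protein.Group = "P",
               heavy = 1, light = 1, ratio = 1),
    data.frame(Run = "b", Stripped.Sequence = sprintf("P%dK", 1:5),
               Precursor.Charge = 2L, Genes = "G", Protein.Group = "P",
               heavy = 4, light = 1, ratio = 4))
  # log2 medians are 0 and 2, both exactly 1 from the cohort median
  expect_length(qc_samples(p3)$excluded, 0L)
})

test_that("normalisation centres each run's log2 ratios at zero", {
  pairs <- data.frame(Run = "r1",
                      Stripped.Sequence = c("AK", "BK", "CK"),
                      Precursor.Charge = 2L, Genes = "G",
                      Protein.Group = "P", heavy = c(0.5, 1, 2),
                      light = 1, ratio = c(0.5, 1, 2))
  norm <- normalize_pairs(pairs)
  expect_equal(norm$log2_ratio, c(-1, 0, 1))
  expect_equal(median(norm$log2_ratio), 0)
  one <- normalize_pairs(pairs[1, ])
  expect_equal(one$log2_ratio, 0)
  same <- pairs; same$ratio <- 3
  expect_equal(normalize_pairs(same)$log2_ratio, c(0, 0, 0))
})

test_that("the pipeline is invariant to row order and per-run scaling", {
  cfg <- sim_config(seed = 31, sigma = 0.2, replicates = 6)
  rep <- write_dia_report(cfg)$report
  res1 <- deconvolute(rep)
  set.seed(2)
  res2 <- deconvolute(rep[sample(nrow(rep)), ])
  expect_equal(res1$genes, res2$genes)
  scaled <- rep
  for (r in unique(scaled$Run)) {
    idx <- scaled$Run == r
    scaled$Precursor.Quantity[idx] <-
      scaled$Precursor.Quantity[idx] * runif(1, 0.5, 2)
  }
  res3 <- deconvolute(scaled)
  # scaling a run multiplies H and L alike: ratios are untouched
  expect_equal(res1$precursors, res3$precursors)
})

test_that("one-sample t statistics match a hand computation", {
  pairs <- data.frame(Run = c("r1", "r2", "r3"),
                      Stripped.Sequence = "AAVLK",
                      Precursor.Charge = 2L, Genes = "G1",
                      log2_ratio = c(0.8, 1.0, 1.2))
  st <- precursor_tests(pairs)
  expect_equal(st$t, 1.0 / (0.2 / sqrt(3)), tolerance = 1e-9)
  expect_equal(st$t, 8.6603, tolerance = 1e-4)
  expect_equal(st$p, 2 * pt(-abs(st$t), df = 2), tolerance = 1e-12)
  zero <- pairs; zero$log2_ratio <- 0
  st0 <- precursor_tests(zero)
  expect_equal(st0$t, 0); expect_equal(st0$p, 1)
  const <- pairs; const$log2_ratio <- 0.5
  stc <- precursor_tests(const)
  expect_equal(stc$p, 0)
  expect_true(stc$degenerate_variance)
  # fewer than min_samples observations: descriptive only
  st2 <- precursor_tests(pairs[1:2, ])
  expect_true(is.na(st2$p))
  expect_equal(st2$n, 2L)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"),
               c(0.03, 0.03, 0.04))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
    adj <- p.adjust(p, "BH")
    expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in rank
  }
})

test_that("gene-level hit calling follows the three rules", {
  st <- data.frame(
    Stripped.Sequence = sprintf("P%dK", 1:6),
    Precursor.Charge = 2L,
    Genes = rep(c("G1", "G2", "G3"), each = 2),
    n = 3L, mean_log2 = 0,
    median_log2 = c(1.0, 0.8,   # G1: hit
                    1.0, -0.2,  # G2: discordant
                    0.6, 0.5),  # G3: mean 0.55 below threshold
    t = 1, p = 0.01,
    p_adj = c(0.01, 0.2, 0.01, 0.2, 0.01, 0.2),
    significant = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    degenerate_variance = FALSE)
  g <- aggregate_genes(st)
  expect_identical(g$hit[match(c("G1", "G2", "G3"), g$Genes)],
                   c(TRUE, FALSE, FALSE))
  expect_equal(g$mean_log2_fc[g$Genes == "G1"], 0.9)
})
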