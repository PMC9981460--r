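# Deconvolution of producer vs consumer proteomes from bulk DIA report
# tables: record filtering, per-sample QC, heavy/light precursor pairing,
# median normalisation, one-sample t-tests with Benjamini-Hochberg
# correction, and gene-level hit calling.
#
# Report dialect (TSV), column names following DIA-NN reports:
#   Run (or Data.File), Stripped.Sequence, Precursor.Charge, Label
#   (H = target-site heavy = producer-derived, L = light = consumer),
#   Precursor.Quantity, Quantity.Quality, Protein.Group, Genes,
#   Proteotypic (0/1).

dia_columns <- c("Run", "Stripped.Sequence", "Precursor.Charge", "Label",
                 "Precursor.Quantity", "Quantity.Quality",
                 "Protein.Group", "Genes", "Proteotypic")

#' Read and filter a DIA precursor report
#'
#' Keeps proteotypic precursors whose stripped sequence contains exactly
#' one target residue located at the C terminus (so that every y ion is
#' state-specific) and whose quantification quality score strictly exceeds
#' the threshold.
#'
#' @param report Path to a TSV file or a data.frame.
#' @param scheme A [label_scheme()].
#' @param quality_threshold Minimum `Quantity.Quality`, strict (default
#'   0.7).
#' @param col_map Named character vector mapping canonical column names to
#'   those used in the file (e.g. `c(Run = "Data.File")`).
#' @return data.frame of retained records with canonical columns.
#' @export
load_and_filter <- function(report, scheme = label_scheme("K"),
                            quality_threshold = 0.7,
                            col_map = character(0)) {
  df <- if (is.character(report))
    utils::read.delim(report, check.names = FALSE,
                      stringsAsFactors = FALSE)
  else as.data.frame(report)
  for (canon in names(col_map))
    names(df)[names(df) == col_map[[canon]]] <- canon
  if (!"Run" %in% names(df) && "Data.File" %in% names(df))
    names(df)[names(df) == "Data.File"] <- "Run"
  check_columns(df, dia_columns, "DIA report")
  tgt <- scheme$target_residue
  n_target <- vapply(strsplit(df$Stripped.Sequence, ""), function(res)
    sum(res == tgt), integer(1))
  c_terminal <- substring(df$Stripped.Sequence,
                          nchar(df$Stripped.Sequence)) == tgt
  keep <- as.logical(df$Proteotypic) & n_target == 1L & c_terminal &
    df$Quantity.Quality > quality_threshold
  df[keep & !is.na(keep), dia_columns]
}

#' Match heavy/light precursor pairs
#'
#' Pairs are identified by (Run, Stripped.Sequence, Precursor.Charge).
#' A key with exactly one heavy and exactly one light record forms a
#' pair; keys with a missing side or duplicated records are dropped and
#' counted.
#'
#' @param records Filtered records from [load_and_filter()].
#' @return List with `pairs` (data.frame `Run`, `Stripped.Sequence`,
#'   `Precursor.Charge`, `Genes`, `Protein.Group`, `heavy`, `light`,
#'   `ratio` = heavy/light) and `counts` (`paired`, `unmatched`,
#'   `ambiguous`).
#' @export
match_pairs <- function(records) {
  dt <- data.table::as.data.table(records)
  key <- c("Run", "Stripped.Sequence", "Precursor.Charge")
  wide <- dt[, list(n_heavy = sum(Label == "H"),
                    n_light = sum(Label == "L"),
                    heavy = sum(Precursor.Quantity[Label == "H"]),
                    light = sum(Precursor.Quantity[Label == "L"]),
                    Genes = Genes[1], Protein.Group = Protein.Group[1]),
            by = key]
  ambiguous <- wide[n_heavy > 1L | n_light > 1L]
  unmatched <- wide[(n_heavy == 0L) != (n_light == 0L)]
  pairs <- wide[n_heavy == 1L & n_light == 1L]
  pairs[, ratio := heavy / light]
  cols <- c(key, "Genes", "Protein.Group", "heavy", "light", "ratio")
  list(pairs = as.data.frame(pairs[, ..cols]),
       counts = c(paired = nrow(pairs), unmatched = nrow(unmatched),
                  ambiguous = nrow(ambiguous)))
}

#' Per-sample quality control on precursor pairs
#'
#' Excludes samples with an abnormally low number of pairs (fewer than
#' `min_id_fraction` times the cohort median) or with a median
#' heavy/light ratio far from the cohort (absolute deviation of the log2
#' median ratio from the cohort median of log2 median ratios strictly
#' greater than `max_median_ratio_deviation`).
#'
#' @param pairs data.frame from [match_pairs()].
#' @param min_id_fraction Default 0.5.
#' @param max_median_ratio_deviation In log2 units, default 1.
#' @return List with `kept`, `excluded`, `report` (per-sample table with
#'   the applied rules) and `pairs` (the retained pairs).
#' @export
qc_samples <- function(pairs, min_id_fraction = 0.5,
                       max_median_ratio_deviation = 1) {
  dt <- data.table::as.data.table(pairs)
  if (length(unique(dt$Run)) < 2L)
    stop("QC needs at least two samples", call. = FALSE)
  per <- dt[is.finite(ratio) & ratio > 0,
            list(n_pairs = .N,
                 log2_median_ratio = log2(stats::median(ratio))),
            by = "Run"]
  med_n <- stats::median(per$n_pairs)
  med_r <- stats::median(per$log2_median_ratio)
  per[, low_ids := n_pairs < min_id_fraction * med_n]
  per[, ratio_outlier := abs(log2_median_ratio - med_r) >
        max_median_ratio_deviation]
  per[, excluded := low_ids | ratio_outlier]
  if (all(per$excluded))
    stop("sample QC excluded every sample", call. = FALSE)
  kept <- per$Run[!per$excluded]
  list(kept = kept, excluded = per$Run[per$excluded],
       report = as.data.frame(per),
       pairs = as.data.frame(dt[Run %in% kept]))
}

#' Median-normalise heavy/light ratios per sample
#'
#' Within each run, ratios are divided by the run median and log2
#' transformed, so the run median of the normalised log2 ratios is 0.
#' Pairs with a nonpositive side are excluded beforehand.
#'
#' @param pairs data.frame from [match_pairs()] (or [qc_samples()]).
#' @return The pairs with columns `norm_ratio` and `log2_ratio` added.
#' @export
normalize_pairs <- function(pairs) {
  dt <- data.table::as.data.table(pairs)
  dt <- dt[is.finite(ratio) & ratio > 0]
  if (nrow(dt) == 0L) stop("no valid ratios to normalise", call. = FALSE)
  dt[, norm_ratio := ratio / stats::median(ratio), by = "Run"]
  dt[, log2_ratio := log2(norm_ratio)]
  as.data.frame(dt)
}

#' Per-precursor one-sample t-tests with BH correction
#'
#' For every precursor (sequence, charge) observed in at least
#' `min_samples` runs, tests whether the mean normalised log2 ratio
#' differs from 0 (two-sided one-sample t-test); p-values are adjusted
#' by the Benjamini-Hochberg step-up procedure over the tested set.
#' Precursors with fewer observations are retained descriptively with
#' `NA` statistics.
#'
#' @param pairs Normalised pairs from [normalize_pairs()].
#' @param min_samples Minimum runs per precursor for testing (default 3).
#' @param alpha Adjusted-p significance cut-off (default 0.05).
#' @return data.frame with one row per precursor: `Stripped.Sequence`,
#'   `Precursor.Charge`, `Genes`, `n`, `mean_log2`, `median_log2`, `t`,
#'   `p`, `p_adj`, `significant`, `degenerate_variance`.
#' @export
precursor_tests <- function(pairs, min_samples = 3L, alpha = 0.05) {
  dt <- data.table::as.data.table(pairs)
  check_columns(dt, c("Stripped.Sequence", "Precursor.Charge", "Genes",
                      "log2_ratio"), "normalised pairs")
  stats_dt <- dt[, {
    x <- log2_ratio
    n <- length(x)
    mean_x <- mean(x)
    med_x <- stats::median(x)
    if (n >= min_samples) {
      s <- stats::sd(x)
      if (s == 0) {
        degen <- TRUE
        tt <- if (mean_x == 0) 0 else Inf * sign(mean_x)
        p <- if (mean_x == 0) 1 else 0
      } else {
        degen <- FALSE
        tt <- mean_x / (s / sqrt(n))
        p <- 2 * stats::pt(abs(tt), df = n - 1, lower.tail = FALSE)
      }
    } else {
      degen <- NA; tt <- NA_real_; p <- NA_real_
    }
    list(Genes = Genes[1], n = n, mean_log2 = mean_x, median_log2 = med_x,
         t = tt, p = p, degenerate_variance = degen)
  }, by = c("Stripped.Sequence", "Precursor.Charge")]
  tested <- !is.na(stats_dt$p)
  stats_dt[, p_adj := NA_real_]
  stats_dt$p_adj[tested] <- stats::p.adjust(stats_dt$p[tested],
                                            method = "BH")
  stats_dt[, significant := !is.na(p_adj) & p_adj < alpha]
  as.data.frame(stats_dt)
}

#' Gene-level aggregation and hit calling
#'
#' A gene is a hit if (1) at least one of its tested precursors is
#' significant, (2) the absolute mean of the per-precursor median log2
#' fold changes exceeds `fc_threshold`, and (3) all precursors agree in
#' sign.
#'
#' @param stats data.frame from [precursor_tests()]; only precursors with
#'   `n >= min_samples` (non-`NA` `p`) enter the aggregation.
#' @param fc_threshold Absolute mean log2 FC required for a hit, strict
#'   (default 0.75).
#' @return data.frame with one row per gene: `Genes`, `n_precursors`,
#'   `mean_log2_fc` (mean of per-precursor medians), `any_significant`,
#'   `sign_concordant`, `hit`.
#' @export
aggregate_genes <- function(stats, fc_threshold = 0.75) {
  dt <- data.table::as.data.table(stats)
  dt <- dt[!is.na(p)]
  gene <- dt[, list(n_precursors = .N,
                    mean_log2_fc = mean(median_log2),
                    any_significant = any(significant),
                    sign_concordant = all(median_log2 > 0) ||
                      all(median_log2 < 0)),
             by = "Genes"]
  gene[, hit := any_significant & abs(mean_log2_fc) > fc_threshold &
         sign_concordant]
  data.table::setorder(gene, -hit, Genes)
  as.data.frame(gene)
}

#' Full producer/consumer deconvolution pipeline
#'
#' Chains [load_and_filter()], [match_pairs()], optional [qc_samples()],
#' [normalize_pairs()], [precursor_tests()] and [aggregate_genes()].
#'
#' @param report Path to a DIA report TSV or a data.frame.
#' @param scheme A [label_scheme()].
#' @param quality_threshold Passed to [load_and_filter()].
#' @param run_qc Apply per-sample QC (default TRUE; requires >= 2 runs).
#' @param min_samples,alpha Passed to [precursor_tests()].
#' @param fc_threshold Passed to [aggregate_genes()].
#' @param col_map Passed to [load_and_filter()].
#' @return List with `records`, `pair_counts`, `qc`, `pairs` (normalised),
#'   `precursors`, `genes` and `summary` (n tested precursors, n
#'   significant, n genes, n hits, per-run median raw heavy/light ratio).
#' @export
deconvolute <- function(report, scheme = label_scheme("K"),
                        quality_threshold = 0.7, run_qc = TRUE,
                        min_samples = 3L, alpha = 0.05,
                        fc_threshold = 0.75, col_map = character(0)) {
  records <- load_and_filter(report, scheme, quality_threshold, col_map)
  mp <- match_pairs(records)
  qc <- NULL
  pairs <- mp$pairs
  if (run_qc) {
    qc <- qc_samples(pairs)
    pairs <- qc$pairs
  }
  pairs <- normalize_pairs(pairs)
  prec <- precursor_tests(pairs, min_samples = min_samples, alpha = alpha)
  genes <- aggregate_genes(prec, fc_threshold = fc_threshold)
  pdt <- data.table::as.data.table(pairs)
  med <- pdt[, list(median_hl_ratio = stats::median(ratio)), by = "Run"]
  tested <- sum(!is.na(prec$p))
  list(records = records, pair_counts = mp$counts, qc = qc, pairs = pairs,
       precursors = prec, genes = genes,
       summary = list(n_tested_precursors = tested,
                      n_significant = sum(prec$significant, na.rm = TRUE),
                      n_genes = nrow(genes),
                      n_hits = sum(genes$hit),
                      median_ratio_per_run = as.data.frame(med)))
}
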