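# Seeded population simulator: ground-truthed mixtures of producer and
# consumer cells, labelling-state sampling, and writers that emit the
# same transition-report (CSV) and DIA-report (TSV) dialects the analysis
# modules read, so the whole pipeline is testable without instrument
# data.

#' Simulation configuration
#'
#' Describes a cell population and the measurement noise. Three population
#' models are supported: `"two_point"` (a producer subpopulation with
#' per-site import probability 0 and a consumer subpopulation with import
#' probability 1 — the cross-feeding scenario), `"homogeneous"` (every
#' cell imports each residue with the same probability `p`), and `"beta"`
#' (cells draw their import probability from a mixture of Beta
#' components, for gradual heterogeneity). Synthesis-rate multipliers
#' scale how much protein a subpopulation contributes per cell, which
#' biases bulk signal shares away from cell-number shares.
#'
#' @param model `"two_point"`, `"homogeneous"` or `"beta"`.
#' @param f_producer Producer cell fraction for `"two_point"` (default
#'   0.375, reproducing an overall imported-residue fraction of 0.625
#'   at equal rates).
#' @param p Import probability for `"homogeneous"`.
#' @param beta_components data.frame with columns `shape1`, `shape2`,
#'   `weight`, `rate` for `"beta"`.
#' @param rate_producer,rate_consumer Synthesis-rate multipliers of the
#'   two-point subpopulations (default 1).
#' @param n_cells Cells per simulated sample (default 10000).
#' @param molecules_per_cell Peptide molecules contributed by a
#'   rate-1 cell (default 100).
#' @param sigma Log-normal noise s.d. (natural-log scale) applied to
#'   areas/quantities (default 0.2).
#' @param replicates Biological replicates per condition (default 2).
#' @param seed Integer seed fixing all randomness.
#' @return Object of class `dilac_sim_config`.
#' @export
sim_config <- function(model = c("two_point", "homogeneous", "beta"),
                       f_producer = 0.375, p = 0.5,
                       beta_components = NULL,
                       rate_producer = 1, rate_consumer = 1,
                       n_cells = 10000L, molecules_per_cell = 100L,
                       sigma = 0.2, replicates = 2L, seed = 1L) {
  model <- match.arg(model)
  stopifnot(f_producer >= 0, f_producer <= 1, p >= 0, p <= 1,
            rate_producer > 0, rate_consumer > 0, sigma >= 0,
            n_cells >= 1, replicates >= 1)
  if (model == "beta") {
    stopifnot(is.data.frame(beta_components),
              all(c("shape1", "shape2", "weight", "rate") %in%
                    names(beta_components)))
    if (abs(sum(beta_components$weight) - 1) > 1e-9)
      stop("beta component weights must sum to 1", call. = FALSE)
  }
  structure(list(model = model, f_producer = f_producer, p = p,
                 beta_components = beta_components,
                 rate_producer = rate_producer,
                 rate_consumer = rate_consumer,
                 n_cells = as.integer(n_cells),
                 molecules_per_cell = as.integer(molecules_per_cell),
                 sigma = sigma, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "dilac_sim_config")
}

# Mixture components as (p | shape1/shape2), weight (cell fraction) and
# rate multiplier.
mixture_components <- function(config) {
  switch(config$model,
         two_point = data.frame(
           p = c(0, 1), shape1 = NA, shape2 = NA,
           weight = c(config$f_producer, 1 - config$f_producer),
           rate = c(config$rate_producer, config$rate_consumer)),
         homogeneous = data.frame(p = config$p, shape1 = NA, shape2 = NA,
                                  weight = 1, rate = 1),
         beta = data.frame(p = NA, config$beta_components))
}

# E[p^a (1-p)^b] for one component.
component_moment <- function(comp, a, b) {
  if (!is.na(comp$p)) comp$p^a * (1 - comp$p)^b
  else beta(comp$shape1 + a, comp$shape2 + b) /
    beta(comp$shape1, comp$shape2)
}

#' Ground truth implied by a simulation configuration
#'
#' Deterministic (pre-noise) expectations: signal weights are cell
#' fractions times synthesis-rate multipliers, so the k-of-n state
#' fractions are rate-weighted mixture moments of the binomial kernel.
#'
#' @param config A [sim_config()].
#' @param n_sites Number of target sites per peptide (default 2).
#' @return List with `P` (overall imported-residue fraction of the bulk
#'   signal), `fractions` (`k = 0..n` imported-site state fractions),
#'   `pattern_fractions` (per site-resolved H/L pattern) and
#'   `producer_signal_share` (two-point model only).
#' @export
ground_truth <- function(config, n_sites = 2L) {
  comps <- mixture_components(config)
  w <- comps$weight * comps$rate
  w <- w / sum(w)
  frac <- vapply(0:n_sites, function(k)
    sum(w * vapply(seq_len(nrow(comps)), function(i)
      choose(n_sites, k) *
        component_moment(comps[i, ], k, n_sites - k), 0)), 0)
  pats <- enumerate_states(paste(rep("K", n_sites), collapse = ""),
                           empty_scheme("K"))
  pat_names <- vapply(pats, function(x)
    paste(ifelse(x, "H", "L"), collapse = ""), "")
  pat_frac <- vapply(pats, function(x) {
    j <- sum(!x)  # light (imported) sites
    sum(w * vapply(seq_len(nrow(comps)), function(i)
      component_moment(comps[i, ], j, n_sites - j), 0))
  }, 0)
  share <- if (config$model == "two_point") {
    wp <- config$f_producer * config$rate_producer
    wc <- (1 - config$f_producer) * config$rate_consumer
    wp / (wp + wc)
  } else NA_real_
  list(P = sum((0:n_sites) * frac) / n_sites,
       fractions = stats::setNames(frac, 0:n_sites),
       pattern_fractions = stats::setNames(pat_frac, pat_names),
       producer_signal_share = share)
}

# Draw per-cell import probabilities and rate multipliers.
sample_cells <- function(config) {
  comps <- mixture_components(config)
  idx <- sample.int(nrow(comps), config$n_cells, replace = TRUE,
                    prob = comps$weight)
  p <- comps$p[idx]
  if (config$model == "beta")
    p <- stats::rbeta(config$n_cells, comps$shape1[idx], comps$shape2[idx])
  list(p = p, rate = comps$rate[idx])
}

# Multinomial sampling of pattern counts, vectorised over cells via
# conditional binomials.
sample_pattern_counts <- function(p_cells, m_cells, pattern_light) {
  n_cells <- length(p_cells)
  n_pat <- length(pattern_light)
  n_sites <- nchar(names(pattern_light)[1])
  probs <- vapply(pattern_light, function(j)
    p_cells^j * (1 - p_cells)^(n_sites - j), numeric(n_cells))
  counts <- matrix(0L, n_cells, n_pat,
                   dimnames = list(NULL, names(pattern_light)))
  remaining <- m_cells
  rem_prob <- rep(1, n_cells)
  for (j in seq_len(n_pat - 1L)) {
    pr <- ifelse(rem_prob > 0, pmin(probs[, j] / rem_prob, 1), 0)
    counts[, j] <- stats::rbinom(n_cells, remaining, pr)
    remaining <- remaining - counts[, j]
    rem_prob <- rem_prob - probs[, j]
  }
  counts[, n_pat] <- remaining
  counts
}

#' Simulate labelling-state fractions for one population sample
#'
#' Each cell draws an import probability from the configured mixture;
#' each of its peptide molecules labels each target site independently
#' with that probability; per-cell molecule counts scale with the
#' synthesis-rate multiplier. Aggregate pattern fractions are returned
#' with and without multiplicative log-normal noise.
#'
#' @param config A [sim_config()].
#' @param n_sites Target sites per peptide (default 2).
#' @param seed Overrides `config$seed` when given.
#' @return List with `expected` ([ground_truth()] fractions),
#'   `pattern_fractions` (sampled, noise-free), `fractions` (sampled
#'   k-of-n, noise-free), `noisy_fractions` (after log-normal noise and
#'   renormalisation), and `counts`.
#' @export
simulate_states <- function(config, n_sites = 2L, seed = NULL) {
  set.seed(if (is.null(seed)) config$seed else seed)
  truth <- ground_truth(config, n_sites)
  cells <- sample_cells(config)
  m <- pmax(1L, as.integer(round(config$molecules_per_cell * cells$rate)))
  pattern_light <- stats::setNames(
    vapply(strsplit(names(truth$pattern_fractions), ""),
           function(ch) sum(ch == "L"), integer(1)),
    names(truth$pattern_fractions))
  counts <- colSums(sample_pattern_counts(cells$p, m, pattern_light))
  pat_frac <- counts / sum(counts)
  k <- pattern_light
  frac <- vapply(0:n_sites, function(kk) sum(pat_frac[k == kk]), 0)
  names(frac) <- 0:n_sites
  noisy <- pat_frac * exp(stats::rnorm(length(pat_frac), 0, config$sigma))
  noisy <- noisy / sum(noisy)
  noisy_k <- vapply(0:n_sites, function(kk) sum(noisy[k == kk]), 0)
  names(noisy_k) <- 0:n_sites
  list(expected = truth$fractions, pattern_fractions = pat_frac,
       fractions = frac, noisy_fractions = noisy_k, counts = counts)
}

random_peptides <- function(n, n_target = 2L, target = "K",
                            length_range = c(9L, 14L),
                            alphabet = setdiff(standard_residues(),
                                               c("K", "R", "C", "M"))) {
  out <- character(0)
  while (length(out) < n) {
    len <- sample(length_range[1]:length_range[2], 1L)
    body <- sample(alphabet, len - n_target, replace = TRUE)
    # one target site at the C terminus; remaining sites separated by at
    # least two residues (mirrors the far-apart selection criterion, and
    # guarantees diagnostic single-site fragments exist)
    repeat {
      pos <- sort(sample(seq_len(max(1L, len - 3L)), n_target - 1L))
      if (all(diff(c(pos, len)) >= 3L)) break
    }
    res <- character(len)
    res[len] <- target
    free <- setdiff(seq_len(len - 1L), pos)
    res[pos] <- target
    res[free] <- body[seq_along(free)]
    pep <- paste(res, collapse = "")
    if (!pep %in% out) out <- c(out, pep)
  }
  out
}

#' Write a simulated transition report
#'
#' Emits a CSV in the dialect of [read_transition_report()]: every y/b
#' fragment from ordinal 3 to length − 2 of every peptide, for every
#' labelling state, with areas proportional to state abundance times a
#' per-fragment response factor (log-normal, s.d. 0.5, drawn once per
#' fragment) times log-normal measurement noise. Both diagnostic and
#' non-diagnostic fragments are present so the quantifier's specificity
#' filter is exercised.
#'
#' @param config A [sim_config()].
#' @param peptides Character vector of peptide sequences (default: five
#'   generated two-lysine peptides).
#' @param path Output CSV path, or `NULL` to return the data.frame only.
#' @param scheme A [label_scheme()].
#' @param condition Condition label written to the report.
#' @param base_intensity Total area scale per peptide.
#' @return Invisibly, a list with `report` (data.frame) and `truth`
#'   (per-replicate sampled pattern fractions and the [ground_truth()]).
#' @export
write_transition_report <- function(config, peptides = NULL, path = NULL,
                                    scheme = label_scheme("K"),
                                    condition = "sim",
                                    base_intensity = 1e6) {
  set.seed(config$seed)
  if (is.null(peptides))
    peptides <- random_peptides(5L, n_target = 2L,
                                target = scheme$target_residue)
  n_sites_pep <- vapply(peptides, function(p)
    length(target_sites(p, scheme)), integer(1))
  if (length(unique(n_sites_pep)) != 1L)
    stop("peptides must share the target-residue count", call. = FALSE)
  n_sites <- n_sites_pep[[1]]

  # fragment response factors, one draw per (peptide, fragment)
  frag_tab <- do.call(rbind, lapply(peptides, function(pep) {
    len <- nchar(pep)
    ords <- 3:(len - 2L)
    data.frame(peptide = pep,
               fragment = c(paste0("y", ords), paste0("b", ords)),
               stringsAsFactors = FALSE)
  }))
  frag_tab$response <- stats::rlnorm(nrow(frag_tab), 0, 0.5)

  truth <- ground_truth(config, n_sites)
  rows <- list()
  rep_truth <- list()
  for (r in seq_len(config$replicates)) {
    sim <- simulate_states(config, n_sites,
                           seed = config$seed + 1000L * r)
    rep_truth[[r]] <- sim$pattern_fractions
    states <- names(sim$pattern_fractions)
    for (i in seq_len(nrow(frag_tab))) {
      noise <- exp(stats::rnorm(length(states), 0, config$sigma))
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sprintf("%s_rep%d", condition, r),
        condition = condition, replicate = r,
        peptide = frag_tab$peptide[i], state = states,
        fragment = frag_tab$fragment[i],
        area = base_intensity * sim$pattern_fractions *
          frag_tab$response[i] * noise,
        stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(path))
    utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(list(report = report,
                 truth = list(expected = truth,
                              sampled = rep_truth)))
}

#' Write a simulated DIA precursor report
#'
#' Emits a TSV in the dialect of [load_and_filter()]: per gene, peptide,
#' charge and run, one heavy (producer-derived) and one light
#' (consumer-derived) quantity, with expected quantities proportional to
#' baseline × subpopulation signal share × `2^(±log2fc/2)` and log-normal
#' noise. Decoy rows (non-proteotypic peptides, internal-target-residue
#' peptides, low quality scores) are included to exercise the filters.
#'
#' @param config A [sim_config()] (two-point model; its rates and
#'   `f_producer` set the signal shares, `sigma` the noise, `replicates`
#'   the run count).
#' @param genes data.frame with columns `gene` and `log2fc`
#'   (producer-over-consumer expression log2 fold change); default: 20
#'   null genes plus 5 up- and 5 down-regulated at |log2 FC| = 1.5.
#' @param path Output TSV path, or `NULL` to return the data.frame only.
#' @param peptides_per_gene Precursor sequences per gene (default 3).
#' @param charges Precursor charges emitted per peptide (default 2).
#' @param low_quality_fraction Fraction of rows given a quality score
#'   below 0.7 (default 0.05).
#' @param dropout Probability that any single row is missing (default
#'   0.05), creating unmatched pairs.
#' @param scheme A [label_scheme()].
#' @return Invisibly, a list with `report` (data.frame) and `truth`
#'   (the gene table with signal shares).
#' @export
write_dia_report <- function(config, genes = NULL, path = NULL,
                             peptides_per_gene = 3L, charges = 2L,
                             low_quality_fraction = 0.05, dropout = 0.05,
                             scheme = label_scheme("K")) {
  set.seed(config$seed + 1L)
  if (is.null(genes))
    genes <- data.frame(
      gene = sprintf("GENE%03d", 1:30),
      log2fc = c(rep(0, 20), rep(1.5, 5), rep(-1.5, 5)))
  stopifnot(all(c("gene", "log2fc") %in% names(genes)))
  tgt <- scheme$target_residue
  share_p <- ground_truth(config, 1L)$producer_signal_share
  if (is.na(share_p))
    stop("DIA simulation uses the two-point population model",
         call. = FALSE)
  share_c <- 1 - share_p

  n_pep <- nrow(genes) * peptides_per_gene
  pep_pool <- random_peptides(n_pep, n_target = 1L, target = tgt,
                              length_range = c(8L, 14L))
  pep_tab <- data.frame(gene = rep(genes$gene, each = peptides_per_gene),
                        log2fc = rep(genes$log2fc,
                                     each = peptides_per_gene),
                        peptide = pep_pool, stringsAsFactors = FALSE)
  pep_tab$baseline <- stats::rlnorm(n_pep, log(1e5), 0.5)

  runs <- sprintf("run%02d", seq_len(config$replicates))
  grid <- expand.grid(i = seq_len(n_pep), Run = runs,
                      Precursor.Charge = charges, Label = c("H", "L"),
                      stringsAsFactors = FALSE)
  g <- pep_tab[grid$i, ]
  expected <- ifelse(grid$Label == "H",
                     g$baseline * share_p * 2^(g$log2fc / 2),
                     g$baseline * share_c * 2^(-g$log2fc / 2))
  qty <- expected * exp(stats::rnorm(nrow(grid), 0, config$sigma))
  quality <- ifelse(stats::runif(nrow(grid)) < low_quality_fraction,
                    stats::runif(nrow(grid), 0, 0.7),
                    stats::runif(nrow(grid), 0.701, 1))
  report <- data.frame(
    Run = grid$Run,
    Stripped.Sequence = g$peptide,
    Precursor.Charge = grid$Precursor.Charge,
    Label = grid$Label,
    Precursor.Quantity = qty,
    Quantity.Quality = quality,
    Protein.Group = paste0(g$gene, "_PG"),
    Genes = g$gene,
    Proteotypic = 1L,
    stringsAsFactors = FALSE)
  report <- report[stats::runif(nrow(report)) >= dropout, ]

  # decoys: non-proteotypic and internal-target-residue peptides
  decoy1 <- report[seq_len(min(10L, nrow(report))), ]
  decoy1$Stripped.Sequence <- paste0("A", decoy1$Stripped.Sequence)
  decoy1$Proteotypic <- 0L
  decoy1$Genes <- "DECOY_NONPROTEO"
  decoy2 <- report[seq_len(min(10L, nrow(report))), ]
  decoy2$Stripped.Sequence <-
    paste0(substr(decoy2$Stripped.Sequence, 1, 3), tgt, "AVLDR")
  decoy2$Genes <- "DECOY_INTERNAL"
  report <- rbind(report, decoy1, decoy2)
  rownames(report) <- NULL
  if (!is.null(path))
    utils::write.table(report, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  truth <- genes
  truth$producer_signal_share <- share_p
  invisible(list(report = report, truth = truth))
}
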