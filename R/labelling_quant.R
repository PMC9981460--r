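# Quantification of producer/mixed/consumer labelling-state abundances
# from fragment-level transition reports: fragment specificity, top-3
# ranking by mean abundance rank across samples, and nested unweighted
# averaging of state fractions (fragments -> peptides -> replicates).
#
# Transition report dialect (CSV): one row per (sample, peptide, precursor
# labelling state, fragment) with columns
#   sample, condition, replicate, peptide, state, fragment, area
# `state` encodes the precursor labelling pattern over the peptide's
# target sites as a string of H (heavy, synthesised) / L (light,
# imported), e.g. "HH", "HL", "LH", "LL" for a two-lysine peptide.
# `fragment` is a series+ordinal token such as "y5" or "b3".

transition_columns <- c("sample", "condition", "replicate", "peptide",
                        "state", "fragment", "area")

check_columns <- function(df, required, what = "table") {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("missing column(s) in ", what, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Read a transition report
#'
#' @param path CSV file in the dialect described above.
#' @param col_map Named character vector mapping the canonical column
#'   names to the names used in the file, e.g.
#'   `c(sample = "Replicate Name", peptide = "Peptide Sequence")`; columns
#'   not mentioned keep their canonical names.
#' @return data.frame with canonical column names.
#' @export
read_transition_report <- function(path, col_map = character(0)) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  for (canon in names(col_map))
    names(df)[names(df) == col_map[[canon]]] <- canon
  check_columns(df, transition_columns, "transition report")
  df[transition_columns]
}

# Parse a fragment token like "y5" into list(series, ordinal).
parse_fragment <- function(fragment) {
  m <- regmatches(fragment, regexec("^([yb])([0-9]+)$", fragment))[[1]]
  if (length(m) != 3L)
    stop("cannot parse fragment token '", fragment,
         "' (expected e.g. y5 or b3)", call. = FALSE)
  list(series = m[2], ordinal = as.integer(m[3]))
}

# Number of imported (light) sites encoded by a state string.
state_k_light <- function(state) {
  vapply(strsplit(state, ""), function(ch) {
    if (!all(ch %in% c("H", "L")))
      stop("state strings must use H/L per target site", call. = FALSE)
    sum(ch == "L")
  }, integer(1))
}

state_class_label <- function(k, n_sites) {
  ifelse(k == 0L, "producer", ifelse(k == n_sites, "consumer", "mixed"))
}

#' Which labelling states can a fragment discriminate?
#'
#' A fragment covering exactly one target site has a mass unique to the
#' labelling state of that site, so it resolves the mixed states that
#' share a precursor mass. Fragments covering zero sites are
#' pattern-independent; fragments covering two or more sites only report
#' the total label count within the fragment. Only single-site fragments
#' are used for quantification.
#'
#' @param peptide Stripped peptide sequence.
#' @param fragment Fragment token, e.g. `"y5"`.
#' @param scheme A [label_scheme()].
#' @return List with `diagnostic` (logical), `n_sites_covered`, and
#'   `sites_covered` (1-based positions in the peptide).
#' @export
fragment_specificity <- function(peptide, fragment,
                                 scheme = label_scheme("K")) {
  f <- parse_fragment(fragment)
  len <- nchar(peptide)
  if (!(f$ordinal >= 1L && f$ordinal <= len - 1L))
    stop("fragment ", fragment, " invalid for a peptide of length ", len,
         call. = FALSE)
  sites <- target_sites(peptide, scheme)
  idx <- if (f$series == "y") (len - f$ordinal + 1L):len else 1L:f$ordinal
  covered <- sites[sites %in% idx]
  list(diagnostic = length(covered) == 1L,
       n_sites_covered = length(covered),
       sites_covered = covered)
}

#' Rank fragments by mean abundance rank across samples
#'
#' Within each sample, fragments are ranked by their total area (1 = most
#' abundant, ties get average ranks); fragments are then ordered by the
#' mean of these ranks across all samples in which they occur, with
#' lexicographic fragment name as tie-break, and the top `k` returned.
#'
#' @param records Transition records for one peptide (data.frame with at
#'   least `sample`, `fragment`, `area`).
#' @param top_k Number of fragments to retain (default 3).
#' @return List with `ranking` (data.frame `fragment`, `mean_rank`) and
#'   `top` (character vector of retained fragment tokens).
#' @export
rank_fragments <- function(records, top_k = 3L) {
  dt <- data.table::as.data.table(records)
  if (nrow(dt) == 0L)
    stop("no fragment records to rank; peptide unquantifiable",
         call. = FALSE)
  tot <- dt[, list(area = sum(area)), by = c("sample", "fragment")]
  tot[, rank := rank(-area, ties.method = "average"), by = "sample"]
  ranking <- tot[, list(mean_rank = mean(rank)), by = "fragment"]
  data.table::setorder(ranking, mean_rank, fragment)
  list(ranking = as.data.frame(ranking),
       top = utils::head(ranking$fragment, top_k))
}

# Per-fragment state fractions with missing states handled per `missing`.
fragment_fractions <- function(dt, states_all, missing = c("zero", "drop")) {
  missing <- match.arg(missing)
  # complete the state set within each (sample, peptide, fragment)
  key <- c("sample", "condition", "replicate", "peptide", "fragment")
  full <- dt[, {
    miss <- setdiff(states_all[[peptide[1]]], state)
    if (length(miss) > 0L && missing == "zero")
      rbind(.SD, data.table::data.table(state = miss, area = 0))
    else .SD
  }, by = key, .SDcols = c("state", "area")]
  full[, total := sum(area), by = key]
  dropped <- full[total <= 0]
  full <- full[total > 0]
  full[, fraction := area / total]
  list(fractions = full, dropped = unique(dropped[, ..key]))
}

#' Labelling-state profile from a transition report
#'
#' Implements the fragment-level quantification scheme: only fragments
#' covering exactly one target site are used; the top 3 fragments by mean
#' abundance rank across all samples are retained per peptide; state
#' fractions are computed per fragment first and then averaged, unweighted,
#' across fragments, peptides and replicates. The standard deviation is
#' reported at the final (across-replicate) level.
#'
#' @param records Transition report data.frame (see
#'   [read_transition_report()]).
#' @param scheme A [label_scheme()].
#' @param top_k Fragments retained per peptide (default 3).
#' @param missing_state `"zero"` (default) treats a state absent from a
#'   fragment's rows as area 0 with a warning; `"drop"` drops the fragment.
#' @return Object of class `dilac_profile`: a list with
#'   `profile` (data.frame `condition`, `k` imported sites, `state_class`,
#'   `fraction`, `sd`), `by_replicate`, `by_peptide`,
#'   `site_resolved` (fractions per full pattern string) and
#'   `unquantifiable` (peptides with no usable diagnostic fragment).
#' @export
state_fractions <- function(records, scheme = label_scheme("K"),
                            top_k = 3L,
                            missing_state = c("zero", "drop")) {
  missing_state <- match.arg(missing_state)
  check_columns(records, transition_columns, "transition report")
  dt <- data.table::as.data.table(records)
  if (any(dt$area < 0)) stop("negative areas in report", call. = FALSE)

  peptides <- unique(dt$peptide)
  n_sites <- vapply(peptides, function(p)
    length(target_sites(p, scheme)), integer(1))
  # diagnostic fragments per peptide
  diag_ok <- mapply(function(p, f)
    fragment_specificity(p, f, scheme)$diagnostic,
    dt$peptide, dt$fragment)
  dtd <- dt[diag_ok]
  unquantifiable <- setdiff(peptides, unique(dtd$peptide))
  if (nrow(dtd) == 0L)
    stop("no diagnostic fragments in report; nothing to quantify",
         call. = FALSE)

  # top-k fragments per peptide (mean rank across all samples)
  top <- dtd[, {
    r <- rank_fragments(.SD, top_k = top_k)
    list(fragment = r$top)
  }, by = "peptide", .SDcols = c("sample", "fragment", "area")]
  dtt <- merge(dtd, top, by = c("peptide", "fragment"))

  states_all <- lapply(peptides, function(p) {
    pats <- enumerate_states(p, scheme)
    vapply(pats, function(x)
      paste(ifelse(x, "H", "L"), collapse = ""), "")
  })
  names(states_all) <- peptides
  expected_rows <- sum(vapply(unique(dtt$peptide), function(p)
    length(states_all[[p]]), integer(1)) *
      vapply(unique(dtt$peptide), function(p)
        nrow(unique(dtt[peptide == p, c("sample", "fragment")])),
        integer(1)))
  if (missing_state == "zero" && nrow(dtt) < expected_rows)
    warning("absent labelling-state rows treated as area 0",
            call. = FALSE)

  ff <- fragment_fractions(dtt, states_all, missing = missing_state)
  fr <- ff$fractions
  if (nrow(fr) == 0L)
    stop("all fragments had zero total area; nothing to quantify",
         call. = FALSE)

  fr[, k := state_k_light(state)]
  # fragments -> peptide (site-resolved states kept)
  by_pep_state <- fr[, list(fraction = mean(fraction)),
                     by = c("condition", "replicate", "peptide", "state",
                            "k")]
  # merge the site-resolved mixed components into label-count classes
  by_pep <- by_pep_state[, list(fraction = sum(fraction)),
                         by = c("condition", "replicate", "peptide", "k")]
  # peptides -> replicate
  by_rep <- by_pep[, list(fraction = mean(fraction)),
                   by = c("condition", "replicate", "k")]
  # replicates -> condition, s.d. at this level
  prof <- by_rep[, list(fraction = mean(fraction), sd = stats::sd(fraction)),
                 by = c("condition", "k")]
  nmax <- max(n_sites)
  prof[, state_class := state_class_label(k, nmax)]
  data.table::setorder(prof, condition, k)
  structure(list(profile = as.data.frame(prof[, c("condition", "k",
                                                  "state_class",
                                                  "fraction", "sd")]),
                 by_replicate = as.data.frame(by_rep),
                 by_peptide = as.data.frame(by_pep),
                 site_resolved = as.data.frame(by_pep_state),
                 n_sites = nmax,
                 unquantifiable = unquantifiable),
            class = "dilac_profile")
}

#' @export
print.dilac_profile <- function(x, ...) {
  cat("Labelling-state profile (", x$n_sites, " target sites)\n", sep = "")
  print(x$profile, row.names = FALSE)
  if (length(x$unquantifiable) > 0L)
    cat("unquantifiable peptides:",
        paste(x$unquantifiable, collapse = ", "), "\n")
  invisible(x)
}

#' Fraction vector of one condition from a profile
#'
#' @param x A `dilac_profile` or a data.frame with columns `k`, `fraction`.
#' @param condition Condition to extract (default: the only one present).
#' @return Named numeric vector `f_0..f_n` over imported-site counts.
#' @export
profile_fractions <- function(x, condition = NULL) {
  df <- if (inherits(x, "dilac_profile")) x$profile else x
  if (!is.null(condition)) df <- df[df$condition == condition, ]
  if (length(unique(df$condition)) > 1L)
    stop("profile has several conditions; pick one", call. = FALSE)
  df <- df[order(df$k), ]
  stats::setNames(df$fraction, df$k)
}

#' Precursor-level (MS1) labelling-state fractions
#'
#' At the precursor level the two single-site mixed states share a mass
#' and are inherently merged: records carry the total imported-site count
#' `k` instead of a site-resolved pattern. The same normalise-then-average
#' cascade as [state_fractions()] is applied over the `n + 1` mass states.
#'
#' @param records data.frame with columns `sample`, `condition`,
#'   `replicate`, `peptide`, `k`, `area`.
#' @param n_sites Number of target sites (default: inferred as `max(k)`).
#' @return A `dilac_profile` (without site-resolved components).
#' @export
precursor_level_fractions <- function(records, n_sites = NULL) {
  check_columns(records, c("sample", "condition", "replicate", "peptide",
                           "k", "area"), "precursor report")
  dt <- data.table::as.data.table(records)
  if (is.null(n_sites)) n_sites <- max(dt$k)
  key <- c("sample", "condition", "replicate", "peptide")
  full <- dt[, {
    miss <- setdiff(0:n_sites, k)
    if (length(miss) > 0L)
      rbind(.SD, data.table::data.table(k = miss, area = 0))
    else .SD
  }, by = key, .SDcols = c("k", "area")]
  full[, total := sum(area), by = key]
  full <- full[total > 0]
  if (nrow(full) == 0L)
    stop("all precursor areas zero; nothing to quantify", call. = FALSE)
  full[, fraction := area / total]
  by_pep <- full[, list(fraction = mean(fraction)),
                 by = c("condition", "replicate", "peptide", "k")]
  by_rep <- by_pep[, list(fraction = mean(fraction)),
                   by = c("condition", "replicate", "k")]
  prof <- by_rep[, list(fraction = mean(fraction), sd = stats::sd(fraction)),
                 by = c("condition", "k")]
  prof[, state_class := state_class_label(k, n_sites)]
  data.table::setorder(prof, condition, k)
  structure(list(profile = as.data.frame(prof[, c("condition", "k",
                                                  "state_class",
                                                  "fraction", "sd")]),
                 by_replicate = as.data.frame(by_rep),
                 by_peptide = as.data.frame(by_pep),
                 site_resolved = NULL,
                 n_sites = n_sites,
                 unquantifiable = character(0)),
            class = "dilac_profile")
}
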