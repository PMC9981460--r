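# In-silico digestion and selection of peptides suitable for
# labelling-state analysis (the required number of target residues, no
# interfering residues, proteotypic in the proteome).

#' Read a proteome from FASTA
#'
#' @param path Path to an amino-acid FASTA file.
#' @return Named character vector of protein sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)
  seqs
}

cleavage_sites <- function(res, protease, cut_after, not_before_proline) {
  sites <- which(res %in% cut_after)
  sites <- sites[sites < length(res)]
  if (not_before_proline)
    sites <- sites[res[sites + 1L] != "P"]
  sites
}

#' In-silico proteolytic digestion
#'
#' Cleaves a protein sequence with trypsin (after K or R) or gluC (after
#' E; optionally after E and D) and returns all peptides with up to
#' `max_missed_cleavages` retained internal cleavage sites. At zero missed
#' cleavages the peptides partition the protein exactly.
#'
#' @param sequence Protein sequence (standard one-letter codes).
#' @param protease `"trypsin"` or `"gluc"`.
#' @param max_missed_cleavages Maximum internal cleavage sites retained.
#' @param not_before_proline Suppress cleavage before proline (off by
#'   default).
#' @param gluc_cuts_d For gluC, also cleave after aspartate.
#' @param protein_id Optional identifier copied into the result.
#' @return data.frame with columns `protein`, `peptide`, `start`, `end`
#'   (1-based inclusive) and `missed_cleavages`.
#' @examples
#' digest("KYSLAPVAKEAAE", "gluc")$peptide
#' @export
digest <- function(sequence, protease = c("trypsin", "gluc"),
                   max_missed_cleavages = 0L, not_before_proline = FALSE,
                   gluc_cuts_d = FALSE, protein_id = NA_character_) {
  protease <- match.arg(protease)
  res <- check_sequence(sequence)
  cut_after <- switch(protease,
                      trypsin = c("K", "R"),
                      gluc = if (gluc_cuts_d) c("E", "D") else "E")
  sites <- cleavage_sites(res, protease, cut_after, not_before_proline)
  bounds <- c(0L, sites, length(res))   # peptide i spans bounds[i]+1..bounds[i+1]
  n_pep <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(n_pep)) {
    for (mc in 0:min(max_missed_cleavages, n_pep - i)) {
      start <- bounds[i] + 1L
      end <- bounds[i + 1L + mc]
      out[[length(out) + 1L]] <- data.frame(
        protein = protein_id,
        peptide = paste(res[start:end], collapse = ""),
        start = start, end = end, missed_cleavages = mc,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Digest every protein of a proteome
#'
#' @param proteome Named character vector (see [read_proteome()]).
#' @param ... Passed to [digest()].
#' @return data.frame as for [digest()], with `protein` filled in.
#' @export
digest_proteome <- function(proteome, ...) {
  stopifnot(length(proteome) > 0L, !is.null(names(proteome)))
  do.call(rbind, lapply(names(proteome), function(id)
    digest(proteome[[id]], protein_id = id, ...)))
}

count_proteins_containing <- function(peptide, proteome) {
  sum(vapply(proteome, function(p)
    grepl(peptide, p, fixed = TRUE), logical(1)))
}

#' Geometry score of a candidate peptide
#'
#' Candidates are better when the two target residues are far apart and the
#' last one sits close to the C terminus (so that many fragments cover
#' exactly one site). The score is
#' `separation/(L-1) + 1 - dist_last_to_Cterm/(L-1)`, each term in
#' \[0, 1\]; only the ordering of scores is meaningful.
#'
#' @param peptide Stripped peptide sequence.
#' @param scheme A [label_scheme()].
#' @return Numeric score in \[0, 2\].
#' @export
score_candidate <- function(peptide, scheme = label_scheme("K")) {
  sites <- target_sites(peptide, scheme)
  if (length(sites) < 2L)
    stop("candidate scoring needs at least two target sites",
         call. = FALSE)
  len <- nchar(peptide)
  separation <- max(sites) - min(sites)
  dist_last <- len - max(sites)
  separation / (len - 1) + 1 - dist_last / (len - 1)
}

#' Select peptides suitable for labelling-state analysis
#'
#' Keeps peptides with exactly `n_target` target residues and none of the
#' `forbidden` residues, marks each as proteotypic if its sequence occurs
#' as a substring of exactly one protein of the proteome, and attaches the
#' geometry score of [score_candidate()].
#'
#' @param peptides data.frame from [digest()] / [digest_proteome()], or a
#'   character vector of sequences.
#' @param scheme A [label_scheme()].
#' @param n_target Required number of target residues (default 2).
#' @param forbidden Residues that disqualify a peptide (default C and M,
#'   whose oxidation/alkylation chemistry disturbs quantification).
#' @param proteome Named character vector for the proteotypic check; if
#'   `NULL` the `proteotypic` column is `NA`.
#' @param require_proteotypic Drop non-proteotypic candidates (default
#'   `TRUE` when a proteome is given).
#' @return data.frame of candidates with columns of the input plus
#'   `sites` (slash-separated 1-based positions), `n_sites`, `proteotypic`
#'   and `score`, ordered by decreasing score.
#' @export
select_candidates <- function(peptides, scheme = label_scheme("K"),
                              n_target = 2L, forbidden = c("C", "M"),
                              proteome = NULL,
                              require_proteotypic = !is.null(proteome)) {
  if (is.character(peptides))
    peptides <- data.frame(protein = NA_character_, peptide = peptides,
                           start = NA_integer_, end = NA_integer_,
                           missed_cleavages = NA_integer_,
                           stringsAsFactors = FALSE)
  keep <- vapply(peptides$peptide, function(p) {
    res <- strsplit(p, "")[[1]]
    sum(res == scheme$target_residue) == n_target &&
      !any(res %in% forbidden)
  }, logical(1))
  cand <- peptides[keep, , drop = FALSE]
  if (nrow(cand) == 0L) {
    cand$sites <- character(0); cand$n_sites <- integer(0)
    cand$proteotypic <- logical(0); cand$score <- numeric(0)
    return(cand)
  }
  site_list <- lapply(cand$peptide, target_sites, scheme = scheme)
  cand$sites <- vapply(site_list, paste, "", collapse = "/")
  cand$n_sites <- lengths(site_list)
  cand$proteotypic <- if (is.null(proteome)) NA else
    vapply(cand$peptide, count_proteins_containing, 0L,
           proteome = proteome) == 1L
  if (require_proteotypic && !is.null(proteome))
    cand <- cand[cand$proteotypic, , drop = FALSE]
  cand$score <- if (n_target >= 2L)
    vapply(cand$peptide, score_candidate, 0, scheme = scheme)
  else NA_real_
  cand[order(-cand$score, cand$peptide), , drop = FALSE]
}
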