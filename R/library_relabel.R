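# In-silico relabelling of a spectral library to the differential
# labelling state: fixed 13C labels on all residues except the target,
# the target residue expanded into its heavy/light variants, fragment
# usability flags, and precursor filtering.
#
# Library dialect: tab-separated long format, one row per fragment, with
# columns PeptideSequence, ModifiedPeptideSequence, PrecursorCharge,
# PrecursorMz, FragmentType (y/b), FragmentSeriesNumber, FragmentCharge,
# ProductMz, ExcludeFromAssay, plus annotation and retention-time columns
# that are passed through unchanged.

library_columns <- c("PeptideSequence", "PrecursorCharge", "PrecursorMz",
                     "FragmentType", "FragmentSeriesNumber",
                     "FragmentCharge", "ProductMz")

# Modified-sequence string with mass-delta bracket notation, e.g.
# "AC[+2.0067]K[+6.0201]" (four decimals, bit-stable).
modified_sequence <- function(sequence, pattern, scheme) {
  res <- check_sequence(sequence)
  sites <- target_sites(sequence, scheme)
  shift <- vapply(res, function(r) {
    if (r %in% scheme$fixed_labelled_residues)
      residue_carbon_count(r) * scheme$shift else 0
  }, 0)
  if (length(sites) > 0L)
    shift[sites[pattern]] <- shift[sites[pattern]] +
      residue_carbon_count(scheme$target_residue) * scheme$shift
  paste0(res, ifelse(shift > 0, sprintf("[+%.4f]", shift), ""),
         collapse = "")
}

#' Fragment usability flag under a labelling scheme
#'
#' A fragment is usable for state-specific quantification only if it
#' covers exactly one target site; all others are flagged for exclusion.
#' For tryptic peptides with a single C-terminal target residue this
#' reduces to "exclude all b ions, keep all y ions".
#'
#' @param peptide Stripped peptide sequence.
#' @param series `"y"` or `"b"` (vectorised with `ordinal`).
#' @param ordinal Fragment ordinal(s).
#' @param scheme A [label_scheme()].
#' @return Logical vector: `TRUE` = exclude from assay.
#' @export
flag_fragments <- function(peptide, series, ordinal,
                           scheme = label_scheme("K")) {
  if (length(target_sites(peptide, scheme)) == 0L)
    warning("peptide ", peptide, " has no target residue; ",
            "all fragments excluded", call. = FALSE)
  mapply(function(s, o)
    !fragment_specificity(peptide, paste0(s, o), scheme)$diagnostic,
    series, ordinal, USE.NAMES = FALSE)
}

#' Relabel a spectral library in silico
#'
#' Applies the labelling scheme to every library entry: precursors
#' outside the allowed charge and length ranges are dropped; each
#' retained precursor is expanded into the full set of heavy/light
#' variants of its target sites (two variants for the usual single-site
#' peptides); precursor and fragment m/z are recomputed from the isotope
#' mass model; the `ExcludeFromAssay` flag is set by [flag_fragments()];
#' retention-time and annotation columns pass through unchanged.
#'
#' @param library Path to a TSV file or a data.frame in the dialect
#'   above.
#' @param scheme A [label_scheme()].
#' @param charges Allowed precursor charges (default `c(2, 3)`).
#' @param length_range Allowed peptide lengths, inclusive (default
#'   `c(7, 30)`).
#' @param col_map Named character vector mapping canonical column names
#'   to those used in the file.
#' @return data.frame: the relabelled library with `ModifiedPeptideSequence`,
#'   `LabelState` (H/L string over target sites), recomputed `PrecursorMz`
#'   and `ProductMz`, and `ExcludeFromAssay` set.
#' @export
relabel_library <- function(library, scheme = label_scheme("K"),
                            charges = c(2L, 3L),
                            length_range = c(7L, 30L),
                            col_map = character(0)) {
  df <- if (is.character(library))
    utils::read.delim(library, check.names = FALSE,
                      stringsAsFactors = FALSE)
  else as.data.frame(library)
  for (canon in names(col_map))
    names(df)[names(df) == col_map[[canon]]] <- canon
  check_columns(df, library_columns, "spectral library")
  len <- nchar(df$PeptideSequence)
  df <- df[df$PrecursorCharge %in% charges &
             len >= length_range[1] & len <= length_range[2], ,
           drop = FALSE]
  ok <- vapply(df$PeptideSequence, function(s)
    all(strsplit(s, "")[[1]] %in% standard_residues()), logical(1))
  if (any(!ok))
    warning(sum(!ok), " entr(y/ies) with non-standard residues dropped",
            call. = FALSE)
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0L) return(df)

  out <- lapply(unique(df$PeptideSequence), function(pep) {
    rows <- df[df$PeptideSequence == pep, , drop = FALSE]
    states <- enumerate_states(pep, scheme)
    do.call(rbind, lapply(states, function(pat) {
      v <- rows
      v$LabelState <- paste(ifelse(pat, "H", "L"), collapse = "")
      v$ModifiedPeptideSequence <- modified_sequence(pep, pat, scheme)
      v$PrecursorMz <- mz_from_mass(species_mass(pep, pat, scheme),
                                    v$PrecursorCharge)
      v$ProductMz <- mapply(function(s, o, z)
        fragment_species(pep, s, o, pat, scheme, charge = z)$mz,
        v$FragmentType, v$FragmentSeriesNumber, v$FragmentCharge)
      v$ExcludeFromAssay <- flag_fragments(pep, v$FragmentType,
                                           v$FragmentSeriesNumber,
                                           scheme)
      v
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a relabelled library to TSV
#'
#' @param library data.frame from [relabel_library()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_library <- function(library, path) {
  utils::write.table(library, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
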