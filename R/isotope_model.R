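# Isotope mass model: monoisotopic masses and m/z of peptides, free amino
# acids and y/b fragments under arbitrary per-residue 13C labelling, plus
# full enumeration of the labelling states of a peptide's target residues.
#
# Labelling convention: a "fixed-labelled" residue carries 13C on every
# carbon wherever it occurs; the target residue is labelled per site
# according to a LabellingPattern (TRUE = heavy/13C at that site).

#' Define a carbon-13 labelling scheme
#'
#' A scheme names the variable (diagnostic) target residue and the set of
#' residues that carry fixed \eqn{{}^{13}}C labels on all their carbons.
#' The default models growth on fully labelled glucose with unlabelled
#' target amino acid supplied in the medium: every residue except the
#' target is heavy, and the target residue is heavy only when synthesised
#' by the cell (producer) rather than imported (consumer).
#'
#' @param target_residue One-letter code of the diagnostic residue
#'   (default `"K"`, lysine).
#' @param fixed_labelled_residues Residues carrying fixed \eqn{{}^{13}}C
#'   labels; defaults to all standard residues except the target.
#' @param shift Mass difference \eqn{{}^{13}\mathrm{C}-{}^{12}\mathrm{C}}
#'   in Da per carbon.
#' @return An object of class `dilac_scheme`.
#' @examples
#' sch <- label_scheme("K")
#' sch$target_residue
#' @export
label_scheme <- function(target_residue = "K",
                         fixed_labelled_residues =
                           setdiff(standard_residues(), target_residue),
                         shift = dilac_constants[["c13_shift"]]) {
  stopifnot(is.character(target_residue), length(target_residue) == 1L,
            target_residue %in% standard_residues())
  fixed_labelled_residues <- as.character(fixed_labelled_residues)
  if (target_residue %in% fixed_labelled_residues)
    stop("target residue must not be in the fixed-labelled set",
         call. = FALSE)
  if (!all(fixed_labelled_residues %in% standard_residues()))
    stop("unknown residue code in fixed-labelled set", call. = FALSE)
  if (!(is.numeric(shift) && shift > 0))
    stop("label mass shift must be positive", call. = FALSE)
  structure(list(target_residue = target_residue,
                 fixed_labelled_residues = fixed_labelled_residues,
                 shift = shift),
            class = "dilac_scheme")
}

#' An unlabelled (identity) scheme
#'
#' Convenience scheme with no fixed labels; used for round-trip checks and
#' for computing unlabelled masses with the same code path.
#'
#' @param target_residue One-letter code of the target residue.
#' @return A `dilac_scheme` with an empty fixed-labelled set.
#' @export
empty_scheme <- function(target_residue = "K") {
  label_scheme(target_residue, fixed_labelled_residues = character(0))
}

#' Number of carbon atoms in a residue
#'
#' @param residue One-letter amino-acid code (vectorised).
#' @return Integer vector of carbon counts of the residue formula
#'   (peptide-bond form; the count is the same for the free amino acid).
#' @examples
#' residue_carbon_count("K")  # 6
#' @export
residue_carbon_count <- function(residue) {
  tab <- residue_table()
  bad <- setdiff(residue, rownames(tab))
  if (length(bad) > 0L)
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  as.integer(tab[residue, "C"])
}

# 1-based positions of the scheme's target residue in a sequence.
target_sites <- function(sequence, scheme) {
  res <- check_sequence(sequence)
  which(res == scheme$target_residue)
}

#' Enumerate all labelling states of a peptide's target residues
#'
#' Generates all \eqn{2^n} heavy/light patterns over the `n` target-residue
#' sites of a peptide, in lexicographic order over the logical vector
#' (`FALSE` < `TRUE`, leftmost site most significant).
#'
#' @param sequence Stripped peptide sequence.
#' @param scheme A [label_scheme()].
#' @return List of logical vectors (each of length `n`); for a peptide with
#'   no target residues, a list holding one zero-length pattern.
#' @examples
#' length(enumerate_states("KYSLAPVAKE", label_scheme("K")))  # 4
#' @export
enumerate_states <- function(sequence, scheme) {
  n <- length(target_sites(sequence, scheme))
  if (n == 0L) return(list(logical(0)))
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))[, n:1, drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) as.logical(unlist(grid[i, ])))
}

# Monoisotopic mass of a bare residue chain (no termini) under a labelling
# pattern restricted to `sites` (positions of target residues in `res`).
chain_mass <- function(res, sites, pattern, scheme) {
  tab <- residue_table()
  el <- colSums(tab[res, , drop = FALSE])
  base <- sum(el * dilac_constants[c("C", "H", "N", "O", "S")])
  fixed_idx <- res %in% scheme$fixed_labelled_residues
  heavy_c <- sum(tab[res[fixed_idx], "C"])
  if (length(sites) > 0L && any(pattern))
    heavy_c <- heavy_c + sum(tab[res[sites[pattern]], "C"])
  base + heavy_c * scheme$shift
}

#' Monoisotopic mass of a labelled peptide or free amino acid
#'
#' Mass of the neutral molecule: residue chain plus one water, with every
#' fixed-labelled residue fully \eqn{{}^{13}}C and target sites heavy where
#' the pattern is `TRUE`.
#'
#' @param sequence Stripped sequence (a single residue for a free amino
#'   acid).
#' @param pattern Logical labelling pattern over the target sites
#'   (length must equal the number of target residues).
#' @param scheme A [label_scheme()].
#' @param as_free_amino_acid Kept for clarity of intent at call sites; a
#'   free amino acid is the single-residue chain plus water, which is the
#'   same formula the peptide branch uses at length one.
#' @return Monoisotopic mass in Da.
#' @examples
#' species_mass("K", TRUE, empty_scheme("K"))  # heavy free lysine
#' @export
species_mass <- function(sequence, pattern = logical(0), scheme,
                         as_free_amino_acid = FALSE) {
  res <- check_sequence(sequence)
  if (as_free_amino_acid && length(res) != 1L)
    stop("a free amino acid is a single residue", call. = FALSE)
  sites <- target_sites(sequence, scheme)
  if (length(pattern) != length(sites))
    stop("pattern length (", length(pattern),
         ") does not match target-residue count (", length(sites), ")",
         call. = FALSE)
  chain_mass(res, sites, pattern, scheme) + dilac_constants[["water"]]
}

#' m/z of a positive ion of given mass and charge
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param charge Positive integer charge (number of added protons).
#' @return m/z in Th.
#' @export
mz_from_mass <- function(mass, charge = 1L) {
  stopifnot(charge >= 1L)
  (mass + charge * dilac_constants[["proton"]]) / charge
}

#' Nominal (integer) m/z
#'
#' Round half away from zero, the convention used for quoting MRM-style
#' transitions.
#'
#' @param mz m/z value(s).
#' @return Integer nominal m/z.
#' @export
nominal_mz <- function(mz) as.integer(sign(mz) * floor(abs(mz) + 0.5))

#' A labelled species: sequence, pattern, charge, mass and m/z
#'
#' @param sequence Stripped sequence.
#' @param pattern Logical labelling pattern over target sites.
#' @param scheme A [label_scheme()].
#' @param charge Positive integer charge.
#' @param as_free_amino_acid See [species_mass()].
#' @return A `dilac_species` list with fields `sequence`, `charge`,
#'   `pattern`, `mass` and `mz`.
#' @export
labelled_species <- function(sequence, pattern = logical(0), scheme,
                             charge = 1L, as_free_amino_acid = FALSE) {
  mass <- species_mass(sequence, pattern, scheme, as_free_amino_acid)
  structure(list(sequence = sequence, charge = as.integer(charge),
                 pattern = pattern, mass = mass,
                 mz = mz_from_mass(mass, charge)),
            class = "dilac_species")
}

#' Fragment-ion species under a labelling pattern
#'
#' Computes a singly- or multiply-protonated y- or b-ion of a labelled
#' peptide. y ordinals count residues from the C terminus, b ordinals from
#' the N terminus, both 1-based. Conventions: the neutral y fragment is the
#' C-terminal residue chain plus one water (it retains the peptide C
#' terminus and gains the amide proton); the neutral b fragment is the bare
#' N-terminal residue chain (acylium convention). In both cases the singly
#' charged ion is neutral + one proton.
#'
#' @param sequence Stripped peptide sequence.
#' @param ion_series `"y"` or `"b"`.
#' @param ordinal Fragment length, `1 <= ordinal <= nchar(sequence) - 1`.
#' @param pattern Labelling pattern of the whole peptide (over all target
#'   sites); the fragment inherits its restriction to sites inside the
#'   fragment.
#' @param scheme A [label_scheme()].
#' @param charge Fragment charge (default 1).
#' @return A `dilac_fragment` list with fields `sequence` (the fragment
#'   subsequence), `series`, `ordinal`, `charge`, `n_target_sites`,
#'   `pattern` (restricted), `mass` (neutral) and `mz`.
#' @examples
#' sch <- label_scheme("K")
#' frag <- fragment_species("KYSLAPVAKE", "y", 5, c(FALSE, TRUE), sch)
#' frag$sequence  # "PVAKE"
#' @export
fragment_species <- function(sequence, ion_series = c("y", "b"), ordinal,
                             pattern, scheme, charge = 1L) {
  ion_series <- match.arg(ion_series)
  res <- check_sequence(sequence)
  len <- length(res)
  if (!(ordinal >= 1L && ordinal <= len - 1L))
    stop("fragment ordinal out of range 1..", len - 1L, call. = FALSE)
  sites <- target_sites(sequence, scheme)
  if (length(pattern) != length(sites))
    stop("pattern length does not match target-residue count",
         call. = FALSE)
  idx <- if (ion_series == "y") (len - ordinal + 1L):len else 1L:ordinal
  in_frag <- sites %in% idx
  sub_sites <- match(sites[in_frag], idx)
  sub_pattern <- pattern[in_frag]
  neutral <- chain_mass(res[idx], sub_sites, sub_pattern, scheme) +
    if (ion_series == "y") dilac_constants[["water"]] else 0
  structure(list(sequence = paste(res[idx], collapse = ""),
                 series = ion_series, ordinal = as.integer(ordinal),
                 charge = as.integer(charge),
                 n_target_sites = sum(in_frag),
                 pattern = sub_pattern, mass = neutral,
                 mz = mz_from_mass(neutral, charge)),
            class = "dilac_fragment")
}

#' MRM transitions of free target amino acid, unlabelled vs labelled
#'
#' For free lysine the quantifier transition is the protonated molecule to
#' its C5 iminium-derived product ion (loss of formic acid equivalents,
#' composition \eqn{C_5H_9N} + proton). Under full \eqn{{}^{13}}C labelling
#' the precursor shifts by six carbons and the product by five.
#'
#' @param scheme A [label_scheme()] whose target is lysine.
#' @return A data.frame with columns `species` (`"unlabelled"`,
#'   `"labelled"`), `precursor_mz`, `product_mz` and their nominal values.
#' @export
free_lysine_transitions <- function(scheme = label_scheme("K")) {
  if (scheme$target_residue != "K")
    stop("transition table is defined for lysine", call. = FALSE)
  const <- dilac_constants
  # product ion C5H9N (+ proton): the lysine fragment quoted nominally as 84
  prod_light <- 5 * const[["C"]] + 9 * const[["H"]] + const[["N"]]
  prec_light <- species_mass("K", FALSE, empty_scheme("K"),
                             as_free_amino_acid = TRUE)
  prec <- c(prec_light, prec_light + 6 * scheme$shift)
  prod <- c(prod_light, prod_light + 5 * scheme$shift)
  data.frame(species = c("unlabelled", "labelled"),
             precursor_mz = mz_from_mass(prec, 1L),
             product_mz = mz_from_mass(prod, 1L),
             precursor_nominal = nominal_mz(mz_from_mass(prec, 1L)),
             product_nominal = nominal_mz(mz_from_mass(prod, 1L)),
             stringsAsFactors = FALSE)
}
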