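# Physical constants (CODATA) and the residue composition table.

#' Physical constants used by the isotope mass model
#'
#' Monoisotopic element masses, the proton mass and the
#' \eqn{{}^{13}\mathrm{C}-{}^{12}\mathrm{C}} mass difference, all in Da.
#'
#' @format A named numeric vector with elements `C`, `H`, `N`, `O`, `S`,
#'   `proton`, `water` and `c13_shift`.
#' @export
dilac_constants <- c(
  C         = 12.0,
  H         = 1.00782503207,
  N         = 14.0030740048,
  O         = 15.9949146196,
  S         = 31.97207100,
  proton    = 1.007276466879,
  water     = 2 * 1.00782503207 + 15.9949146196,
  c13_shift = 1.0033548378
)

.dilac_env <- new.env(parent = emptyenv())

# Residue elemental compositions, read once from the shipped table.
# Returns a data.frame with rownames = one-letter codes, columns C,H,N,O,S.
residue_table <- function() {
  if (is.null(.dilac_env$residues)) {
    path <- system.file("extdata", "residue_composition.tsv",
                        package = "dilac", mustWork = TRUE)
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    rownames(tab) <- tab$residue
    .dilac_env$residues <- tab[, c("C", "H", "N", "O", "S")]
  }
  .dilac_env$residues
}

#' Standard amino-acid one-letter codes
#'
#' @return Character vector of the 20 standard residues.
#' @export
standard_residues <- function() rownames(residue_table())

check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nzchar(sequence))
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, standard_residues())
  if (length(bad) > 0L)
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  res
}
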