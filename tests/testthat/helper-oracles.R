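# Independent oracles and fixture builders. Everything here is computed
# from first principles (hand-typed element masses and residue formulas),
# deliberately not via the package's own mass model.

oracle_elements <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                     O = 15.9949146196, S = 31.97207100)
oracle_proton <- 1.007276466879
oracle_shift <- 1.0033548378

# residue formulas (peptide-bond form), hand-typed from the standard table
oracle_formulas <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0))

# neutral monoisotopic mass of a peptide; heavy_positions get all their
# carbons as 13C
oracle_peptide_mass <- function(sequence, heavy_positions = integer(0)) {
  res <- strsplit(sequence, "")[[1]]
  total <- sum(oracle_elements[c("H", "O")] * c(2, 1))  # water
  for (i in seq_along(res)) {
    f <- oracle_formulas[[res[i]]]
    total <- total + sum(f * oracle_elements[names(f)])
    if (i %in% heavy_positions)
      total <- total + f[["C"]] * oracle_shift
  }
  total
}

oracle_mz <- function(mass, charge) (mass + charge * oracle_proton) / charge

# brute-force Benjamini-Hochberg step-up: find the largest k with
# p_(k) <= k/m * q; adjusted p by the standard cumulative-minimum form,
# written out directly from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (rank in seq_len(m)) {
    candidates <- vapply(rank:m, function(j) p[o[j]] * m / j, 0)
    adj[o[rank]] <- min(1, min(candidates))
  }
  adj
}

write_fasta_fixture <- function(seqs, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(lapply(names(seqs), function(id)
    c(paste0(">", id), seqs[[id]])))
  writeLines(lines, path)
  path
}

# spectral-library fixture in the long TSV dialect; m/z computed by the
# oracle for unlabelled peptides
make_library_fixture <- function(peptides, charge = 2L) {
  rows <- lapply(peptides, function(pep) {
    len <- nchar(pep)
    ords <- 3:(len - 2L)
    frag <- data.frame(FragmentType = rep(c("y", "b"), each = length(ords)),
                       FragmentSeriesNumber = rep(ords, 2L),
                       stringsAsFactors = FALSE)
    frag$ProductMz <- mapply(function(s, o) {
      res <- strsplit(pep, "")[[1]]
      idx <- if (s == "y") (len - o + 1L):len else 1L:o
      mass <- sum(vapply(res[idx], function(r)
        sum(oracle_formulas[[r]] *
              oracle_elements[names(oracle_formulas[[r]])]), 0)) +
        if (s == "y") sum(oracle_elements[c("H", "O")] * c(2, 1)) else 0
      oracle_mz(mass, 1L)
    }, frag$FragmentType, frag$FragmentSeriesNumber)
    frag$FragmentCharge <- 1L
    frag$PeptideSequence <- pep
    frag$ModifiedPeptideSequence <- pep
    frag$PrecursorCharge <- charge
    frag$PrecursorMz <- oracle_mz(oracle_peptide_mass(pep), charge)
    frag$NormalizedRetentionTime <- 42.5
    frag$ProteinId <- "P1"
    frag
  })
  do.call(rbind, rows)
}

# minimal transition report builder: one peptide, explicit areas
make_transition_records <- function(peptide, fragments, states, areas,
                                    sample = "s1", condition = "c1",
                                    replicate = 1L) {
  grid <- expand.grid(fragment = fragments, state = states,
                      stringsAsFactors = FALSE)
  data.frame(sample = sample, condition = condition,
             replicate = replicate, peptide = peptide,
             state = grid$state, fragment = grid$fragment,
             area = areas, stringsAsFactors = FALSE)
}
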