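#' Nominal residue mass table for peptaibol ion arithmetic
#'
#' Nominal (integer) residue masses in daltons for the three-letter codes
#' found in peptaibol sequences, including the non-proteinogenic residues
#' Aib (alpha-aminoisobutyric acid) and the C-terminal amino alcohols.
#' Residue masses are the mass of the residue as incorporated in the chain
#' (monomer minus water); amino-alcohol codes (\code{Pheol}, \code{Leuol},
#' \code{Valol}) carry the full molecular nominal mass of the free amino
#' alcohol, because in the y-ion convention the C-terminal alcohol is counted
#' as a whole molecule.
#'
#' The ambiguity codes \code{Lxx} (Leu/Ile) and \code{Vxx} (Val/Iva) are not
#' in this table: they are resolved to Leu and Val at parse time (see
#' \code{\link{parse_sequence}}).
#'
#' @return Named integer vector of nominal residue masses (Da).
#' @examples
#' residue_masses()[c("Gly", "Aib", "Pheol")]
#' @export
residue_masses <- function() {
  c(
    Gly =  57L, Ala =  71L, Ser =  87L, Pro =  97L, Val =  99L,
    Thr = 101L, Cys = 103L, Leu = 113L, Ile = 113L, Asn = 114L,
    Asp = 115L, Gln = 128L, Lys = 128L, Glu = 129L, Met = 131L,
    His = 137L, Phe = 147L, Arg = 156L, Tyr = 163L, Trp = 186L,
    # non-proteinogenic residues common in peptaibols
    Aib =  85L,  # alpha-aminoisobutyric acid
    Iva =  99L,  # isovaline (isobaric with Val)
    Hyp = 113L,  # 4-hydroxyproline
    # C-terminal amino alcohols: full molecular nominal mass
    Pheol = 151L,  # phenylalaninol
    Leuol = 117L,  # leucinol
    Valol = 103L   # valinol
  )
}

# mass constants of the nominal ion convention
.MASS_ACETYL_B <- 43L  # acetyl cap contribution to the b (acylium) ion
.MASS_PROTON   <- 1L
.MASS_WATER    <- 18L

.AMINO_ALCOHOLS <- c("Pheol", "Leuol", "Valol")
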