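#' Structural grouping of organophosphate adducts
#'
#' Assigns each adduct to one of the structural groups that organize the
#' reactivation behaviour of the studied series, based on its O-alkyl
#' substituent R1 and second substituent R2 (controlled substituent
#' vocabulary, not general SMILES):
#'
#' * `group_I` - massive R2 carrying an electronegative atom (N or O), e.g.
#'   `N-(CH3)2` or `O-C2H5`; these leave the least room for water around the
#'   fluoride and are the easiest to reactivate.
#' * `group_II` - branched R1 of the general form `CH(X)-X'` (the first carbon
#'   of R1 is a CH group with two substituents, including the cyclohexyl
#'   case); hardest to reactivate, difficulty grows with branching.
#' * `group_III` - less branched R1 of the general form `O-CH2-Y` (first
#'   carbon is a CH2 group) with R2 = CH3.
#' * `transitional` - R2 = C2H5, intermediate between groups I and III.
#' * `special` - aromatic R1 and R2 (the benzodioxaphosphorin-derived adduct),
#'   which fits none of the groups.
#'
#' @param r1,r2 Substituent strings (vectorized), drawn from the controlled
#'   vocabulary (e.g. `"C2H5"`, `"nC4H9"`, `"cC6H11"`, `"CH(CH3)2"`,
#'   `"CH2-CH(CH3)2"`, `"C*H(CH3)-C(CH3)3"`, `"CH3"`, `"N-(CH3)2"`,
#'   `"O-C2H5"`, `"C6H4-CH3"`, `"O-CH2-C6H4-OH"`).
#' @return Character vector with levels `group_I`, `group_II`, `group_III`,
#'   `transitional`, `special`. Unknown substituent tokens are an error.
#' @export
#' @examples
#' classify_adduct("C2H5", "N-(CH3)2")    # group_I
#' classify_adduct("CH(CH3)2", "CH3")     # group_II
#' classify_adduct("CH2-CH(CH3)2", "CH3") # group_III
classify_adduct <- function(r1, r2) {
  stopifnot(length(r1) == length(r2))
  mapply(classify_one, trimws(r1), trimws(r2), USE.NAMES = FALSE)
}

.r1_vocab <- c(
  "C2H5", "nC4H9", "cC6H11", "CH(CH3)2", "CH2-CH(CH3)2",
  "C*H(CH3)-C(CH3)3", "C6H4-CH3"
)
.r2_vocab <- c(
  "CH3", "C2H5", "N-(CH3)2", "O-C2H5", "O-CH2-C6H4-OH"
)

classify_one <- function(r1, r2) {
  if (!r1 %in% .r1_vocab) {
    abort(paste0("unknown R1 substituent token: '", r1, "'"))
  }
  if (!r2 %in% .r2_vocab) {
    abort(paste0("unknown R2 substituent token: '", r2, "'"))
  }
  aromatic <- function(s) grepl("C6H4", s, fixed = TRUE)
  if (aromatic(r1) && aromatic(r2)) return("special")
  # R2 attached through / carrying a heteroatom: amide or ester-type substituent
  if (grepl("^[NO]-", r2)) return("group_I")
  if (r2 == "C2H5") return("transitional")
  # remaining vocabulary has R2 = CH3; split on the branching of R1
  if (grepl("^C\\*?H\\(", r1) || grepl("^cC", r1)) return("group_II")
  if (r1 == "C2H5" || r1 == "nC4H9" || grepl("^CH2-", r1)) return("group_III")
  abort(paste0("substituent pair ('", r1, "', '", r2, "') matches no group"))
}
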