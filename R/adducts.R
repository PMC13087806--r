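# Ion adduct table and adduct m/z calculation.

#' Supported ESI ion adducts
#'
#' The mass delta of each adduct includes the electron-mass correction
#' (electron removed for cations, added for anions), using the 5-decimal
#' electron mass consistent with the precision at which calculated
#' high-resolution m/z values are reported.
#'
#' @return data.frame with columns `name`, `mass_delta` (Da) and `charge`.
#' @export
adduct_table <- function() {
  iso <- isotope_masses()
  e <- .ELECTRON_MASS
  data.frame(
    name = c("[M+H]+", "[M-H]-", "[M+Na]+", "[M+Cl]-"),
    mass_delta = c(iso[["H"]] - e, -(iso[["H"]] - e),
                   iso[["Na"]] - e, iso[["Cl"]] + e),
    charge = c(1L, -1L, 1L, -1L),
    stringsAsFactors = FALSE
  )
}

#' Calculated adduct m/z
#'
#' Computes the theoretical monoisotopic m/z of an ion adduct of a neutral
#' molecule: monoisotopic mass plus the adduct mass delta (which carries the
#' electron-mass correction). This is the quantity reported as the
#' "calculated" value in high-resolution mass spectrometry characterization.
#'
#' @param mol An `nah_mol` (neutral species) or a named element-count vector.
#' @param adduct Adduct name, one of `"[M+H]+"`, `"[M-H]-"`, `"[M+Na]+"`,
#'   `"[M+Cl]-"`. Aliases with unicode minus are accepted.
#' @param digits Decimals used for the reported value (default 5, the
#'   conventional HRMS precision). Use `NA` to skip rounding.
#' @return m/z in Da (numeric scalar).
#' @examples
#' m <- mol_parse("O=C(CCc1c[nH]c2ccccc12)NN=Cc1c[nH]c2ncccc12")
#' adduct_mz(m, "[M+H]+")
#' @export
adduct_mz <- function(mol, adduct, digits = 5) {
  tab <- adduct_table()
  key <- gsub("−", "-", adduct)
  row <- match(key, tab$name)
  if (is.na(row)) {
    stop(sprintf("unsupported adduct '%s'; supported: %s", adduct,
                 paste(tab$name, collapse = ", ")), call. = FALSE)
  }
  if (inherits(mol, "nah_mol") && any(mol$atoms$charge != 0) &&
      sum(mol$atoms$charge) != 0) {
    stop("adduct m/z is defined for neutral molecules", call. = FALSE)
  }
  mz <- monoisotopic_mass(mol) + tab$mass_delta[row]
  if (!is.na(digits)) mz <- round(mz, digits) else mz
  mz
}
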