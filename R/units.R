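# Fixed CODATA-2018 conversion factors. Energies are stored per mole of
# adsorbate; the canonical internal unit is kJ/mol.
.KJMOL_PER_HARTREE <- 2625.4996394799
.KJMOL_PER_EV <- 96.48533212331

.ENERGY_UNITS <- c("hartree", "kJ/mol", "eV")

# Accept a few spellings users actually type.
.normalize_unit <- function(unit) {
  u <- tolower(trimws(unit))
  u <- sub("·", ".", u, fixed = TRUE)
  if (u %in% c("hartree", "ha", "au", "a.u.")) return("hartree")
  if (u %in% c("kj/mol", "kj.mol-1", "kjmol", "kj mol-1", "kj_mol")) {
    return("kJ/mol")
  }
  if (u %in% c("ev", "electronvolt")) return("eV")
  stop("unknown energy unit: '", unit, "' (expected one of ",
       paste(.ENERGY_UNITS, collapse = ", "), ")", call. = FALSE)
}

.to_kjmol_factor <- function(unit) {
  switch(.normalize_unit(unit),
         "hartree" = .KJMOL_PER_HARTREE,
         "kJ/mol"  = 1,
         "eV"      = .KJMOL_PER_EV)
}

#' Convert energies between hartree, kJ/mol and eV
#'
#' Exact conversion through fixed CODATA-2018 factors
#' (1 hartree = 2625.4996394799 kJ/mol, 1 eV = 96.48533212331 kJ/mol).
#'
#' @param x Numeric vector of energies.
#' @param from,to Unit names; one of `"hartree"`, `"kJ/mol"`, `"eV"`
#'   (a few common spellings such as `"Ha"` or `"kJ.mol-1"` are accepted).
#' @return Numeric vector in the target unit.
#' @examples
#' convert_energy(1, "hartree", "kJ/mol")
#' @export
convert_energy <- function(x, from, to) {
  stopifnot(is.numeric(x))
  x * .to_kjmol_factor(from) / .to_kjmol_factor(to)
}
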