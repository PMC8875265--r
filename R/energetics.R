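# Counterpoise interaction-energy bookkeeping for a periodic
# surface–adsorbate complex. The seven (eight with the isolated deformed
# molecule) total energies are named by the E(X//Y) convention: X is the
# system whose energy is computed, Y the geometry at which it is computed,
# square brackets mark ghost basis functions of the deleted partner.

# canonical ledger symbols <-> internal field names
.LEDGER_FIELDS <- c(
  e_complex                    = "E(SN//SN)",
  e_surface_relaxed            = "E(S//S)",
  e_molecule_relaxed           = "E_M(N//N)",
  e_surface_deformed           = "E(S//SN)",
  e_molecule_deformed_periodic = "E(N//SN)",
  e_molecule_deformed_isolated = "E_M(N//SN)",
  e_surface_ghosted            = "E(S[N]//SN)",
  e_molecule_ghosted           = "E([S]N//SN)"
)

#' Construct an energy ledger for counterpoise decomposition
#'
#' Bundles the total electronic energies of a surface--adsorbate complex and
#' its fragments, as produced by periodic DFT runs, under the `E(X//Y)`
#' naming convention (`X` = system, `Y` = geometry; brackets = ghost basis
#' functions of the deleted partner).
#'
#' @param e_complex `E(SN//SN)`, the relaxed complex.
#' @param e_surface_relaxed `E(S//S)`, the relaxed bare surface.
#' @param e_molecule_relaxed `E_M(N//N)`, the relaxed isolated molecule.
#' @param e_surface_deformed `E(S//SN)`, the surface frozen at the adsorption
#'   geometry.
#' @param e_molecule_deformed_periodic `E(N//SN)`, the periodic replica array
#'   of the molecule frozen at the adsorption geometry.
#' @param e_molecule_deformed_isolated `E_M(N//SN)`, a single molecule frozen
#'   at the adsorption geometry.
#' @param e_surface_ghosted `E(S[N]//SN)`, the deformed surface plus the
#'   molecule's ghost functions. Optional; when absent the BSSE terms of the
#'   decomposition are reported as `NA`.
#' @param e_molecule_ghosted `E([S]N//SN)`, the deformed periodic molecule
#'   plus the surface's ghost functions. Optional, as above.
#' @param unit Unit of every entry: `"hartree"`, `"kJ/mol"` or `"eV"`.
#' @return An object of class `energy_ledger`.
#' @seealso [decompose_ledger()], [read_energy_ledger()]
#' @examples
#' led <- energy_ledger(
#'   e_complex = -100, e_surface_relaxed = -40, e_molecule_relaxed = -30,
#'   e_surface_deformed = -38, e_molecule_deformed_periodic = -27,
#'   e_molecule_deformed_isolated = -28, e_surface_ghosted = -41,
#'   e_molecule_ghosted = -29, unit = "kJ/mol")
#' decompose_ledger(led)
#' @export
energy_ledger <- function(e_complex,
                          e_surface_relaxed,
                          e_molecule_relaxed,
                          e_surface_deformed,
                          e_molecule_deformed_periodic,
                          e_molecule_deformed_isolated,
                          e_surface_ghosted = NA_real_,
                          e_molecule_ghosted = NA_real_,
                          unit = "hartree") {
  unit <- .normalize_unit(unit)
  vals <- list(
    e_complex = e_complex,
    e_surface_relaxed = e_surface_relaxed,
    e_molecule_relaxed = e_molecule_relaxed,
    e_surface_deformed = e_surface_deformed,
    e_molecule_deformed_periodic = e_molecule_deformed_periodic,
    e_molecule_deformed_isolated = e_molecule_deformed_isolated,
    e_surface_ghosted = e_surface_ghosted,
    e_molecule_ghosted = e_molecule_ghosted
  )
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L) {
      stop("ledger entry ", .LEDGER_FIELDS[[nm]],
           " must be a single numeric value", call. = FALSE)
    }
    if (!is.na(v) && !is.finite(v)) {
      stop("ledger entry ", .LEDGER_FIELDS[[nm]], " is not finite",
           call. = FALSE)
    }
  }
  required <- setdiff(names(vals),
                      c("e_surface_ghosted", "e_molecule_ghosted"))
  miss <- required[vapply(vals[required], is.na, logical(1))]
  if (length(miss) > 0L) {
    stop("missing required ledger entry: ",
         paste(.LEDGER_FIELDS[miss], collapse = ", "), call. = FALSE)
  }
  # Adding ghost functions can only lower a variational energy.
  if (!is.na(vals$e_surface_ghosted) &&
      vals$e_surface_ghosted > vals$e_surface_deformed + 1e-12) {
    warning("E(S[N]//SN) above E(S//SN): ghost functions should lower ",
            "the surface energy", call. = FALSE)
  }
  if (!is.na(vals$e_molecule_ghosted) &&
      vals$e_molecule_ghosted > vals$e_molecule_deformed_periodic + 1e-12) {
    warning("E([S]N//SN) above E(N//SN): ghost functions should lower ",
            "the molecule energy", call. = FALSE)
  }
  structure(c(vals, list(unit = unit)), class = "energy_ledger")
}

#' @export
print.energy_ledger <- function(x, ...) {
  cat("Energy ledger [", x$unit, "]\n", sep = "")
  for (nm in names(.LEDGER_FIELDS)) {
    cat(sprintf("  %-12s %s\n", .LEDGER_FIELDS[[nm]],
                format(x[[nm]], digits = 12)))
  }
  invisible(x)
}

#' Convert an energy ledger to another unit
#'
#' @param ledger An [energy_ledger()].
#' @param unit Target unit.
#' @return A new `energy_ledger` in the target unit.
#' @export
convert_ledger <- function(ledger, unit) {
  stopifnot(inherits(ledger, "energy_ledger"))
  unit <- .normalize_unit(unit)
  out <- ledger
  for (nm in names(.LEDGER_FIELDS)) {
    out[[nm]] <- convert_energy(ledger[[nm]], ledger$unit, unit)
  }
  out$unit <- unit
  out
}

#' Counterpoise decomposition of an adsorption interaction energy
#'
#' Splits the raw interaction energy dE of a periodic surface--adsorbate
#' complex into a deformation-free term, surface and molecular deformation
#' energies, and the lateral interaction between periodic adsorbate
#' replicas, and applies the counterpoise (ghost-function) correction for
#' the basis set superposition error:
#' \deqn{\Delta E = E(SN//SN) - [E_M(N//N) + E(S//S)]}
#' \deqn{\Delta E = \Delta E^* + \delta E_S + \delta E_N, \qquad
#'       \delta E_N = \Delta E_N + \Delta E_L}
#' \deqn{\Delta E^C = \Delta E^{*C} + \delta E_S + \Delta E_N + \Delta E_L,
#'       \qquad \mathrm{BSSE} = \Delta E^C - \Delta E}
#' with \eqn{\Delta E_N = E_M(N//SN) - E_M(N//N)} (pure molecular
#' deformation) and \eqn{\Delta E_L = E(N//SN) - E_M(N//SN)} (lateral
#' replica--replica interaction), so that all three identities close
#' exactly.
#'
#' @param ledger An [energy_ledger()]. If the ghost-function entries are
#'   absent the BSSE-corrected terms are `NA`.
#' @return An object of class `energy_decomposition`: a list with fields
#'   `dE`, `dE_star`, `delta_S`, `delta_N`, `dE_N`, `dE_L`, `dE_star_C`,
#'   `dE_C`, `bsse`, all in kJ/mol, plus `unit = "kJ/mol"`.
#' @examples
#' led <- generate_energy_ledger(dE_star = -35, delta_S = 2, dE_N = 2,
#'                               dE_L = 1, bsse = 5, seed = 1)
#' decompose_ledger(led)
#' @export
decompose_ledger <- function(ledger) {
  stopifnot(inherits(ledger, "energy_ledger"))
  l <- convert_ledger(ledger, "kJ/mol")

  dE      <- l$e_complex - (l$e_molecule_relaxed + l$e_surface_relaxed)
  delta_S <- l$e_surface_deformed - l$e_surface_relaxed
  delta_N <- l$e_molecule_deformed_periodic - l$e_molecule_relaxed
  dE_N    <- l$e_molecule_deformed_isolated - l$e_molecule_relaxed
  dE_L    <- l$e_molecule_deformed_periodic - l$e_molecule_deformed_isolated
  dE_star <- l$e_complex -
    (l$e_molecule_deformed_periodic + l$e_surface_deformed)

  if (!is.na(l$e_surface_ghosted) && !is.na(l$e_molecule_ghosted)) {
    dE_star_C <- l$e_complex - (l$e_surface_ghosted + l$e_molecule_ghosted)
    dE_C <- dE_star_C + delta_S + dE_N + dE_L
    bsse <- dE_C - dE
  } else {
    dE_star_C <- NA_real_
    dE_C <- NA_real_
    bsse <- NA_real_
  }

  structure(
    list(dE = dE, dE_star = dE_star, delta_S = delta_S, delta_N = delta_N,
         dE_N = dE_N, dE_L = dE_L, dE_star_C = dE_star_C, dE_C = dE_C,
         bsse = bsse, unit = "kJ/mol"),
    class = "energy_decomposition"
  )
}

#' @export
print.energy_decomposition <- function(x, digits = 4, ...) {
  lbl <- c(dE = "dE", dE_star = "dE*", delta_S = "delta_S",
           delta_N = "delta_N", dE_N = "dE_N", dE_L = "dE_L",
           dE_star_C = "dE*^C", dE_C = "dE^C", bsse = "BSSE")
  cat("Counterpoise interaction-energy decomposition [kJ/mol]\n")
  for (nm in names(lbl)) {
    v <- x[[nm]]
    cat(sprintf("  %-8s %s\n", lbl[[nm]],
                if (is.na(v)) "(ghost energies absent)"
                else format(round(v, digits), nsmall = digits)))
  }
  invisible(x)
}

#' Dispersion contribution to an interaction energy
#'
#' The empirical-dispersion contribution isolated as the difference between
#' interaction energies computed with and without the dispersion correction.
#'
#' @param dE_plain Interaction energy without dispersion, kJ/mol.
#' @param dE_disp Interaction energy with dispersion, kJ/mol.
#' @return `dE_disp - dE_plain` in kJ/mol (negative for attractive
#'   dispersion).
#' @examples
#' dispersion_contribution(-10.1, -104.9)  # -94.8
#' @export
dispersion_contribution <- function(dE_plain, dE_disp) {
  stopifnot(is.numeric(dE_plain), is.numeric(dE_disp))
  dE_disp - dE_plain
}

#' Dispersion split of an interaction energy
#'
#' @param dE_plain,dE_disp Interaction energies without / with the
#'   dispersion correction, kJ/mol.
#' @return Object of class `dispersion_split` with fields `dE_plain`,
#'   `dE_disp`, `disp` and, when the dispersion-corrected system is bound
#'   (`dE_disp < 0`), `fraction` = `disp / dE_disp`.
#' @examples
#' s <- dispersion_split(-28.2, -131.9)
#' dispersion_fraction(s)  # 0.786..., i.e. 79%
#' @export
dispersion_split <- function(dE_plain, dE_disp) {
  disp <- dispersion_contribution(dE_plain, dE_disp)
  fraction <- if (dE_disp < 0) disp / dE_disp else NA_real_
  structure(list(dE_plain = dE_plain, dE_disp = dE_disp,
                 disp = disp, fraction = fraction, unit = "kJ/mol"),
            class = "dispersion_split")
}

#' @export
print.dispersion_split <- function(x, ...) {
  cat("Dispersion split [kJ/mol]\n")
  cat(sprintf("  dE (no disp.)   %8.2f\n", x$dE_plain))
  cat(sprintf("  dE^D (disp.)    %8.2f\n", x$dE_disp))
  cat(sprintf("  dispersion      %8.2f\n", x$disp))
  if (!is.na(x$fraction)) {
    cat(sprintf("  fraction of dE^D  %5.1f%%\n", 100 * x$fraction))
  }
  invisible(x)
}

#' Fraction of the interaction energy due to dispersion
#'
#' @param split A [dispersion_split()].
#' @return `disp / dE_disp`, in (0, 1] for a bound, dispersion-dominated
#'   system. Errors if the dispersion-corrected energy is not negative
#'   (unbound system: the fraction is undefined).
#' @export
dispersion_fraction <- function(split) {
  stopifnot(inherits(split, "dispersion_split"))
  if (!(split$dE_disp < 0)) {
    stop("dispersion fraction undefined: dE_disp must be negative ",
         "(bound system)", call. = FALSE)
  }
  split$disp / split$dE_disp
}

#' Read an energy ledger from JSON or CSV
#'
#' JSON ledgers are flat objects keyed by the literal symbols
#' `"E(SN//SN)"`, `"E(S//S)"`, `"E_M(N//N)"`, `"E(S//SN)"`, `"E(N//SN)"`,
#' `"E_M(N//SN)"`, `"E(S[N]//SN)"`, `"E([S]N//SN)"` plus a `"unit"` field.
#' CSV ledgers have columns `symbol,energy` (plus an optional `unit`
#' column, constant).
#'
#' @param path File path; format inferred from the extension.
#' @param unit Unit override when the file carries none.
#' @return An [energy_ledger()].
#' @export
read_energy_ledger <- function(path, unit = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    file_unit <- raw[["unit"]]
    sym <- setdiff(names(raw), "unit")
    vals <- unlist(raw[sym])
  } else {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    if (!all(c("symbol", "energy") %in% names(df))) {
      stop("ledger CSV must have columns 'symbol' and 'energy'",
           call. = FALSE)
    }
    vals <- stats::setNames(as.numeric(df$energy), df$symbol)
    file_unit <- if ("unit" %in% names(df)) unique(df$unit) else NULL
    if (length(file_unit) > 1L) {
      stop("mixed units in ledger file: ",
           paste(file_unit, collapse = ", "), call. = FALSE)
    }
  }
  use_unit <- if (!is.null(unit)) unit else file_unit
  if (is.null(use_unit)) {
    stop("no unit in ledger file and none supplied", call. = FALSE)
  }

  unknown <- setdiff(names(vals), .LEDGER_FIELDS)
  if (length(unknown) > 0L) {
    stop("unknown ledger symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- as.list(rep(NA_real_, length(.LEDGER_FIELDS)))
  names(args) <- names(.LEDGER_FIELDS)
  for (nm in names(.LEDGER_FIELDS)) {
    sym <- .LEDGER_FIELDS[[nm]]
    if (sym %in% names(vals)) args[[nm]] <- vals[[sym]]
  }
  args$unit <- use_unit
  do.call(energy_ledger, args)
}

#' Write an energy ledger as flat JSON
#'
#' @param ledger An [energy_ledger()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_energy_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "energy_ledger"))
  out <- list()
  for (nm in names(.LEDGER_FIELDS)) {
    v <- ledger[[nm]]
    if (!is.na(v)) out[[.LEDGER_FIELDS[[nm]]]] <- v
  }
  out$unit <- ledger$unit
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Format interaction energies as an aligned text table
#'
#' One row per system, columns `dE` (no dispersion), `dE^D` (with
#' dispersion) and `Disp.` (their difference), all kJ/mol.
#'
#' @param systems Character vector of row labels.
#' @param dE,dE_disp Numeric vectors, kJ/mol (`NA` allowed for `dE_disp`).
#' @return Character vector of table lines (printed if not assigned).
#' @export
format_energy_table <- function(systems, dE, dE_disp) {
  stopifnot(length(systems) == length(dE), length(dE) == length(dE_disp))
  disp <- ifelse(is.na(dE_disp), NA_real_, dE_disp - dE)
  num <- function(v) ifelse(is.na(v), "-", sprintf("%.1f", v))
  w <- max(nchar(systems), nchar("system"))
  lines <- c(
    sprintf("%-*s %8s %8s %8s", w, "system", "dE", "dE^D", "Disp."),
    sprintf("%-*s %8s %8s %8s", w, systems, num(dE), num(dE_disp),
            num(disp))
  )
  structure(lines, class = "energy_table")
}

#' @export
print.energy_table <- function(x, ...) {
  cat(x, sep = "\n")
  invisible(x)
}
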