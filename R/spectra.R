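# Broadened IR spectra from harmonic mode tables and gas -> adsorbed
# band-shift matching. Frequencies in 1/cm, intensities in km/mol
# (arbitrary units accepted: spectra are peak-normalized for display).

#' Construct a table of harmonic normal modes
#'
#' @param frequency Mode frequencies, 1/cm, strictly positive (imaginary
#'   modes must be filtered before building the table).
#' @param intensity IR intensities, km/mol, nonnegative.
#' @param label Free-text label (e.g. `"gas"`, `"4.5 OH/nm2"`).
#' @return Object of class `mode_table`: a data frame with columns
#'   `frequency` and `intensity`, sorted ascending in frequency, with a
#'   `label` attribute.
#' @export
mode_table <- function(frequency, intensity, label = "") {
  stopifnot(length(frequency) == length(intensity))
  if (any(!is.finite(frequency)) || any(frequency <= 0)) {
    bad <- which(!is.finite(frequency) | frequency <= 0)[1]
    stop("non-positive frequency at row ", bad,
         ": imaginary/zero modes must be pre-filtered", call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("intensities must be finite and nonnegative", call. = FALSE)
  }
  ord <- order(frequency)
  structure(data.frame(frequency = frequency[ord],
                       intensity = intensity[ord]),
            label = label,
            class = c("mode_table", "data.frame"))
}

#' Read a mode table from CSV or JSON
#'
#' CSV needs columns `freq_cm1` and `intensity` (the names `frequency` /
#' `freq` are also accepted); JSON is an array of `{frequency, intensity}`
#' records or an object with those two arrays.
#'
#' @param path Input path; format inferred from the extension.
#' @param label Label attached to the table (defaults to the file name).
#' @return A [mode_table()], sorted ascending by frequency.
#' @export
read_mode_table <- function(path, label = basename(path)) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(raw)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  fcol <- intersect(c("freq_cm1", "frequency", "freq"), names(df))[1]
  icol <- intersect(c("intensity", "int"), names(df))[1]
  if (is.na(fcol) || is.na(icol)) {
    stop("mode table needs frequency (freq_cm1) and intensity columns",
         call. = FALSE)
  }
  mode_table(as.numeric(df[[fcol]]), as.numeric(df[[icol]]), label = label)
}

#' Write a mode table as CSV
#'
#' Columns `freq_cm1`, `intensity`.
#'
#' @param modes A [mode_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mode_table <- function(modes, path) {
  stopifnot(inherits(modes, "mode_table"))
  utils::write.csv(data.frame(freq_cm1 = modes$frequency,
                              intensity = modes$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

.lorentzian <- function(x, x0, fwhm) {
  hw <- fwhm / 2
  (hw / pi) / ((x - x0)^2 + hw^2)
}

.gaussian_line <- function(x, x0, fwhm) {
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  exp(-(x - x0)^2 / (2 * sig^2)) / (sig * sqrt(2 * pi))
}

#' Broaden a mode table into a continuous IR spectrum
#'
#' Sum of unit-area lineshapes centred at each mode frequency, weighted by
#' the mode intensity, then normalized so the highest peak is 1 (the usual
#' presentation of simulated IR spectra).
#'
#' @param modes A [mode_table()].
#' @param lineshape `"lorentzian"` (default) or `"gaussian"`.
#' @param fwhm Full width at half maximum, 1/cm. Default 10.
#' @param from,to,by Wavenumber grid, 1/cm. Defaults 0 to 4000 step 0.5.
#' @return Object of class `ir_spectrum`: list with `wavenumber`,
#'   `absorbance` (peak-normalized), `raw` (pre-normalization sum),
#'   `lineshape`, `fwhm`, `label`.
#' @examples
#' sp <- broaden(mode_table(1607, 100, "gas"))
#' sp$wavenumber[which.max(sp$absorbance)]  # 1607
#' @export
broaden <- function(modes, lineshape = c("lorentzian", "gaussian"),
                    fwhm = 10, from = 0, to = 4000, by = 0.5) {
  stopifnot(inherits(modes, "mode_table"), fwhm > 0, by > 0, to > from)
  lineshape <- match.arg(lineshape)
  grid <- seq(from, to, by = by)
  if (nrow(modes) == 0L) {
    warning("empty mode table: flat zero spectrum", call. = FALSE)
    raw <- numeric(length(grid))
  } else {
    if (any(modes$frequency < from | modes$frequency > to)) {
      stop("grid [", from, ", ", to, "] does not cover all mode ",
           "frequencies", call. = FALSE)
    }
    shape <- if (lineshape == "lorentzian") .lorentzian else .gaussian_line
    raw <- numeric(length(grid))
    for (m in seq_len(nrow(modes))) {
      raw <- raw + modes$intensity[m] *
        shape(grid, modes$frequency[m], fwhm)
    }
  }
  peak <- max(raw)
  structure(list(wavenumber = grid,
                 absorbance = if (peak > 0) raw / peak else raw,
                 raw = raw, lineshape = lineshape, fwhm = fwhm,
                 label = attr(modes, "label")),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat("IR spectrum", if (nzchar(x$label %||% "")) paste0(" [", x$label, "]"),
      ": ", length(x$wavenumber), " points, ", x$lineshape,
      " fwhm ", x$fwhm, " 1/cm\n", sep = "")
  if (max(x$raw) > 0) {
    cat(sprintf("  highest peak at %.1f 1/cm\n",
                x$wavenumber[which.max(x$absorbance)]))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a spectrum as CSV
#'
#' Columns `wavenumber_cm1`, `absorbance` (peak-normalized).
#'
#' @param spectrum An [broaden()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  utils::write.csv(data.frame(wavenumber_cm1 = spectrum$wavenumber,
                              absorbance = spectrum$absorbance),
                   path, row.names = FALSE)
  invisible(path)
}

#' Match gas and adsorbed modes and report band shifts
#'
#' Greedy nearest-frequency matching: pairs are formed in order of
#' increasing frequency gap until no pair within the window remains; ties
#' are broken toward the higher-intensity adsorbed candidate. Shift =
#' adsorbed - gas frequency, so a red shift is negative.
#'
#' @param gas,adsorbed [mode_table()]s for the free and adsorbed species.
#' @param window Maximum frequency gap for a match, 1/cm. Default 50.
#' @return Object of class `band_shift_report`: list with `pairs` (data
#'   frame `gas_cm1`, `adsorbed_cm1`, `shift_cm1`, `gas_intensity`,
#'   `adsorbed_intensity`), `unmatched_gas`, `unmatched_adsorbed`.
#' @examples
#' g <- mode_table(c(1607, 3478), c(50, 80), "gas")
#' a <- mode_table(c(1610, 3453), c(55, 70), "adsorbed")
#' band_shift(g, a)$pairs$shift_cm1  # +3, -25
#' @export
band_shift <- function(gas, adsorbed, window = 50) {
  stopifnot(inherits(gas, "mode_table"), inherits(adsorbed, "mode_table"),
            window > 0)
  ng <- nrow(gas); na <- nrow(adsorbed)
  pairs <- data.frame(gas_cm1 = numeric(0), adsorbed_cm1 = numeric(0),
                      shift_cm1 = numeric(0), gas_intensity = numeric(0),
                      adsorbed_intensity = numeric(0))
  if (ng > 0L && na > 0L) {
    gap <- abs(outer(gas$frequency, adsorbed$frequency, "-"))
    free_g <- rep(TRUE, ng); free_a <- rep(TRUE, na)
    repeat {
      g2 <- gap
      g2[!free_g, ] <- Inf
      g2[, !free_a] <- Inf
      best <- min(g2)
      if (!is.finite(best) || best > window) break
      cand <- which(g2 == best, arr.ind = TRUE)
      if (nrow(cand) > 1L) {  # tie: prefer the stronger adsorbed band
        cand <- cand[order(-adsorbed$intensity[cand[, 2]]), , drop = FALSE]
      }
      i <- cand[1, 1]; j <- cand[1, 2]
      pairs <- rbind(pairs, data.frame(
        gas_cm1 = gas$frequency[i], adsorbed_cm1 = adsorbed$frequency[j],
        shift_cm1 = adsorbed$frequency[j] - gas$frequency[i],
        gas_intensity = gas$intensity[i],
        adsorbed_intensity = adsorbed$intensity[j]))
      free_g[i] <- FALSE; free_a[j] <- FALSE
    }
    pairs <- pairs[order(pairs$gas_cm1), , drop = FALSE]
    rownames(pairs) <- NULL
    unmatched_gas <- gas$frequency[free_g]
    unmatched_adsorbed <- adsorbed$frequency[free_a]
  } else {
    unmatched_gas <- gas$frequency
    unmatched_adsorbed <- adsorbed$frequency
  }
  structure(list(pairs = pairs, window = window,
                 unmatched_gas = unmatched_gas,
                 unmatched_adsorbed = unmatched_adsorbed),
            class = "band_shift_report")
}

#' @export
print.band_shift_report <- function(x, ...) {
  cat("Band shifts (adsorbed - gas), window ", x$window, " 1/cm\n",
      sep = "")
  if (nrow(x$pairs) == 0L) {
    cat("  no matched pairs\n")
  } else {
    for (r in seq_len(nrow(x$pairs))) {
      cat(sprintf("  %8.1f -> %8.1f   shift %+6.1f 1/cm\n",
                  x$pairs$gas_cm1[r], x$pairs$adsorbed_cm1[r],
                  x$pairs$shift_cm1[r]))
    }
  }
  if (length(x$unmatched_gas)) {
    cat("  unmatched gas bands:", paste(round(x$unmatched_gas, 1),
                                        collapse = ", "), "\n")
  }
  if (length(x$unmatched_adsorbed)) {
    cat("  unmatched adsorbed bands:",
        paste(round(x$unmatched_adsorbed, 1), collapse = ", "), "\n")
  }
  invisible(x)
}
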