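# Structural observables along an MD trajectory: RMSD against a reference
# frame, atom-pair distance time series (with minimum-image convention for
# periodic cells), and H-bond length histograms with Gaussian fits.

# Kabsch optimal rotation: rotate mobile (n x 3, centred) onto
# reference (n x 3, centred).
.kabsch <- function(mobile, reference) {
  h <- crossprod(mobile, reference)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

.resolve_selection <- function(traj, selection) {
  n <- length(traj$symbols)
  if (is.null(selection)) return(seq_len(n))
  if (is.character(selection)) {
    sel <- which(traj$symbols %in% selection)
  } else {
    sel <- as.integer(selection)
    if (any(sel < 1L | sel > n)) {
      stop("atom selection out of range 1..", n, call. = FALSE)
    }
  }
  if (length(sel) == 0L) stop("empty atom selection", call. = FALSE)
  sel
}

#' RMSD time series against a reference frame
#'
#' Unweighted root-mean-square deviation of atomic positions,
#' \deqn{\mathrm{RMSD} = \sqrt{\frac{1}{N}\sum_{i=1}^{N}\delta_i^2},}
#' where \eqn{\delta_i} is the displacement of atom i between the frame and
#' the reference. By default no superposition is applied: deviations are
#' measured in the fixed frame of the (static) surface, so that adsorbate
#' translation over the surface registers as RMSD. Set `align = TRUE` for
#' an optimal rigid-body (Kabsch) superposition of the selection before the
#' deviation is taken.
#'
#' @param traj A [trajectory()].
#' @param reference Index of the reference frame (default 1, the starting
#'   geometry).
#' @param selection Atom indices, or a character vector of element symbols,
#'   to include; `NULL` (default) selects all atoms.
#' @param align Superpose each frame's selection onto the reference before
#'   measuring deviations. Default `FALSE`.
#' @return A data frame with columns `time_ps` and `rmsd` (angstrom).
#' @export
rmsd_series <- function(traj, reference = 1L, selection = NULL,
                        align = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (reference < 1L || reference > nf) {
    stop("reference frame index out of range 1..", nf, call. = FALSE)
  }
  sel <- .resolve_selection(traj, selection)
  ref <- traj$coords[[reference]][sel, , drop = FALSE]
  ref_c <- sweep(ref, 2, colMeans(ref))
  rmsd <- vapply(seq_len(nf), function(f) {
    cur <- traj$coords[[f]][sel, , drop = FALSE]
    if (align) {
      cur_c <- sweep(cur, 2, colMeans(cur))
      cur <- cur_c %*% .kabsch(cur_c, ref_c)
      d <- cur - ref_c
    } else {
      d <- cur - ref
    }
    sqrt(sum(d * d) / nrow(d))
  }, numeric(1))
  data.frame(time_ps = frame_times_ps(traj), rmsd = rmsd)
}

# Minimum-image displacement: fractional-coordinate wrap, then a search
# over the 27 neighbouring images (the wrap alone is exact only for
# orthorhombic cells; skewed triclinic cells need the neighbour search).
.mic_shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))

.mic_displacement <- function(d, cell) {
  frac <- solve(t(cell), d)
  frac <- frac - round(frac)
  cand <- (.mic_shifts + rep(frac, each = 27L)) %*% cell
  best <- which.min(rowSums(cand * cand))
  as.numeric(cand[best, ])
}

#' Atom-pair distance time series
#'
#' Euclidean distance between two atoms in every frame. With
#' `minimum_image = TRUE` and a periodic cell, the distance to the nearest
#' periodic image is used (fractional-coordinate wrapping).
#'
#' @param traj A [trajectory()].
#' @param i,j Distinct 1-based atom indices.
#' @param minimum_image Apply the minimum-image convention (requires a
#'   cell). Default `FALSE`.
#' @return A data frame with columns `time_ps` and `distance` (angstrom).
#' @export
pair_distance_series <- function(traj, i, j, minimum_image = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  n <- length(traj$symbols)
  i <- as.integer(i); j <- as.integer(j)
  if (i < 1L || i > n || j < 1L || j > n) {
    stop("atom index out of range 1..", n, call. = FALSE)
  }
  if (i == j) stop("atom indices must be distinct", call. = FALSE)
  if (minimum_image && is.null(traj$cell)) {
    stop("minimum_image requires a periodic cell", call. = FALSE)
  }
  dist <- vapply(traj$coords, function(m) {
    d <- m[j, ] - m[i, ]
    if (minimum_image) d <- .mic_displacement(d, traj$cell)
    sqrt(sum(d * d))
  }, numeric(1))
  data.frame(time_ps = frame_times_ps(traj), distance = dist)
}

#' Histogram of H-bond lengths with a Gaussian fit
#'
#' Bins a distance series and, when requested, fits a Gaussian
#' `A * exp(-(x - mu)^2 / (2 sigma^2))` to the bin counts by
#' Levenberg--Marquardt least squares, initialised from the sample mean and
#' standard deviation. This fits a curve to the histogram (the usual
#' presentation of H-bond length distributions), not a maximum-likelihood
#' normal model.
#'
#' @param series Numeric vector of distances (angstrom), or a data frame
#'   with a `distance` column as returned by [pair_distance_series()].
#' @param bins Number of bins, or `"FD"` (default) for the
#'   Freedman--Diaconis rule.
#' @param fit Fit a Gaussian to the bin counts. Default `TRUE`.
#' @return Object of class `hbond_distribution`: list with `bin_centers`,
#'   `counts`, `breaks`, `n_samples`, and (when fitted) `fit_mean`,
#'   `fit_sigma`, `fit_amplitude`.
#' @export
hbond_histogram <- function(series, bins = "FD", fit = TRUE) {
  if (is.data.frame(series)) series <- series$distance
  x <- as.numeric(series)
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)

  if (identical(bins, "FD")) {
    nb <- max(1L, grDevices::nclass.FD(x))
  } else {
    nb <- max(1L, as.integer(bins))
  }
  rng <- range(x)
  if (rng[1] == rng[2]) {
    # degenerate constant series: one bin, no spread to fit
    breaks <- rng[1] + c(-0.5, 0.5)
    h <- list(mids = rng[1], counts = length(x), breaks = breaks)
    warning("constant series: degenerate histogram, fit skipped",
            call. = FALSE)
    fit <- FALSE
  } else {
    breaks <- seq(rng[1], rng[2], length.out = nb + 1L)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE)
  }

  out <- list(bin_centers = h$mids, counts = h$counts, breaks = h$breaks,
              n_samples = length(x),
              fit_mean = NA_real_, fit_sigma = NA_real_,
              fit_amplitude = NA_real_)

  if (fit) {
    if (length(x) < max(10L, nb)) {
      warning("fewer samples than needed for a stable fit; fit skipped",
              call. = FALSE)
    } else {
      df <- data.frame(mid = h$mids, count = h$counts)
      # two starts -- sample moments and the tallest bin -- keeping the
      # lower-SSE solution: on multimodal histograms the moment start can
      # settle in a broad local minimum. Centre and width are constrained
      # to the data support.
      span <- diff(rng)
      starts <- list(
        list(A = max(h$counts), mu = mean(x), sig = stats::sd(x)),
        list(A = max(h$counts), mu = h$mids[which.max(h$counts)],
             sig = span / 10))
      one_fit <- function(start) tryCatch(
        minpack.lm::nlsLM(
          count ~ A * exp(-(mid - mu)^2 / (2 * sig^2)),
          data = df, start = start,
          lower = c(A = 0, mu = rng[1], sig = 1e-12),
          upper = c(A = Inf, mu = rng[2], sig = 2 * span),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      fits <- Filter(Negate(is.null), lapply(starts, one_fit))
      if (length(fits) == 0L) {
        fitres <- NULL
      } else {
        sse <- vapply(fits, function(f) sum(stats::residuals(f)^2),
                      numeric(1))
        fitres <- fits[[which.min(sse)]]
      }
      if (is.null(fitres)) {
        warning("Gaussian fit did not converge; fit skipped",
                call. = FALSE)
      } else {
        cf <- stats::coef(fitres)
        out$fit_amplitude <- unname(cf["A"])
        out$fit_mean <- unname(cf["mu"])
        out$fit_sigma <- abs(unname(cf["sig"]))
      }
    }
  }
  structure(out, class = "hbond_distribution")
}

#' @export
print.hbond_distribution <- function(x, ...) {
  cat("H-bond length distribution: ", x$n_samples, " samples, ",
      length(x$counts), " bins\n", sep = "")
  if (!is.na(x$fit_mean)) {
    cat(sprintf("  Gaussian fit: mean %.3f A, sigma %.3f A\n",
                x$fit_mean, x$fit_sigma))
  } else {
    cat("  no Gaussian fit\n")
  }
  invisible(x)
}

#' Write a time series to CSV
#'
#' Two columns, `time_ps` and `value`, as used by the distance/RMSD tools.
#'
#' @param series Data frame whose first column is `time_ps`; the second
#'   column is written as `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(is.data.frame(series), names(series)[1] == "time_ps")
  out <- data.frame(time_ps = series[[1]], value = series[[2]])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
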