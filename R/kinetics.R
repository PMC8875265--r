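# Proton-transfer kinetics from a donor-H...acceptor distance pair.
# Frames are classified into two states -- "bound" (H covalently on the
# silanol O, H-bonded to the drug N) and "transferred" (H on the drug N) --
# by a comparative-distance criterion with hysteresis, and forward event
# statistics are converted to a characteristic time, a rate constant and an
# Eyring free-energy barrier.

# CODATA 2018
.KB <- 1.380649e-23        # J/K
.PLANCK <- 6.62607015e-34  # J*s
.RGAS <- 8.31446           # J/(mol*K)

#' Classify proton-transfer states from N-H and O-H distances
#'
#' A frame is labelled `"transferred"` when the proton sits on the acceptor
#' nitrogen (`d_NH < d_OH - hysteresis` and `d_NH < threshold`) and
#' `"bound"` when it sits on the donor oxygen (`d_OH < d_NH - hysteresis`);
#' otherwise the previous label persists (debouncing, to suppress
#' recrossing chatter near the separatrix). The default threshold of 1.3
#' angstrom sits between a covalent N-H (~1.0-1.1 A) and an N...H hydrogen
#' bond (~1.6-1.9 A). The first frame, if ambiguous, takes the label of the
#' smaller distance.
#'
#' @param d_NH,d_OH Numeric vectors of N-H and O-H distances (angstrom),
#'   aligned in time.
#' @param threshold Maximum N-H distance for the transferred state,
#'   angstrom. Default 1.3.
#' @param hysteresis Dead band around the crossing, angstrom. Default 0.15.
#' @param times_ps Optional frame times in ps (same length).
#' @return Object of class `state_series`: list with `states` (factor with
#'   levels `bound`, `transferred`) and `times_ps`.
#' @export
classify_states <- function(d_NH, d_OH, threshold = 1.3, hysteresis = 0.15,
                            times_ps = NULL) {
  if (length(d_NH) != length(d_OH)) {
    stop("d_NH and d_OH must have the same length", call. = FALSE)
  }
  stopifnot(threshold > 0, hysteresis >= 0)
  n <- length(d_NH)
  if (n == 0L) stop("empty distance series", call. = FALSE)
  if (!is.null(times_ps) && length(times_ps) != n) {
    stop("times_ps length differs from the distance series", call. = FALSE)
  }

  to_transferred <- (d_NH < d_OH - hysteresis) & (d_NH < threshold)
  to_bound <- d_OH < d_NH - hysteresis

  states <- character(n)
  cur <- if (to_transferred[1]) "transferred"
         else if (to_bound[1]) "bound"
         else if (d_NH[1] < d_OH[1]) "transferred" else "bound"
  states[1] <- cur
  for (t in seq_len(n)[-1]) {
    if (to_transferred[t]) cur <- "transferred"
    else if (to_bound[t]) cur <- "bound"
    states[t] <- cur
  }
  structure(list(states = factor(states,
                                 levels = c("bound", "transferred")),
                 times_ps = times_ps),
            class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  tab <- table(x$states)
  cat("Proton-transfer state series: ", length(x$states), " frames (",
      tab[["bound"]], " bound, ", tab[["transferred"]],
      " transferred), ", count_transfer_events(x),
      " forward events\n", sep = "")
  invisible(x)
}

#' Count forward proton-transfer events
#'
#' Number of bound -> transferred transitions in a state series.
#'
#' @param states A `state_series` from [classify_states()], or a character/
#'   factor vector of `bound`/`transferred` labels.
#' @return Integer event count.
#' @export
count_transfer_events <- function(states) {
  s <- if (inherits(states, "state_series")) states$states else states
  s <- as.character(s)
  sum(s[-1] == "transferred" & s[-length(s)] == "bound")
}

# mean residence time (ps) of completed visits to `state`; NA when no
# completed visit exists
.mean_residence_ps <- function(states, dt_ps, state = "bound") {
  s <- as.character(states)
  r <- rle(s)
  idx <- which(r$values == state)
  # an ongoing first/last visit is censored; drop it
  if (length(idx) > 0L && idx[1] == 1L) idx <- idx[-1]
  if (length(idx) > 0L && idx[length(idx)] == length(r$values)) {
    idx <- idx[-length(idx)]
  }
  if (length(idx) == 0L) return(NA_real_)
  mean(r$lengths[idx]) * dt_ps
}

#' Characteristic time of the proton transfer
#'
#' Rough estimate: total simulated time divided by the number of forward
#' (bound -> transferred) events.
#'
#' @param states A `state_series` or label vector (see
#'   [count_transfer_events()]).
#' @param total_time_ps Total simulated time, ps.
#' @return `total_time_ps / n_events` in ps, or `NA` (with attribute
#'   `no_event = TRUE`) when no event occurred.
#' @export
characteristic_time <- function(states, total_time_ps) {
  stopifnot(total_time_ps > 0)
  n_ev <- count_transfer_events(states)
  if (n_ev == 0L) {
    return(structure(NA_real_, no_event = TRUE))
  }
  total_time_ps / n_ev
}

#' Rate constant from a characteristic time
#'
#' @param tau_ps Characteristic time in ps.
#' @return `1 / tau` in 1/s.
#' @examples
#' rate_constant(2)  # 5e11
#' @export
rate_constant <- function(tau_ps) {
  if (!is.numeric(tau_ps) || any(tau_ps <= 0)) {
    stop("tau must be a positive time in ps", call. = FALSE)
  }
  1 / (tau_ps * 1e-12)
}

#' Eyring free-energy barrier from an observed rate
#'
#' Inverts the Eyring equation `k = (k_B T / h) exp(-dG / RT)` (transmission
#' coefficient 1):
#' \deqn{\Delta G^\ddagger = R T \ln\!\frac{k_B T}{h\,k}.}
#'
#' @param k Rate constant, 1/s.
#' @param temperature Temperature, K. Default 300.
#' @return Barrier in kJ/mol. Negative (with a warning) when `k` exceeds
#'   the `k_B T / h` prefactor.
#' @examples
#' eyring_barrier(5e11, 300)  # ~6.30 kJ/mol
#' @export
eyring_barrier <- function(k, temperature = 300) {
  stopifnot(is.numeric(k), is.numeric(temperature))
  if (any(k <= 0)) stop("rate constant must be positive", call. = FALSE)
  if (any(temperature <= 0)) {
    stop("temperature must be positive", call. = FALSE)
  }
  prefactor <- .KB * temperature / .PLANCK
  dG <- .RGAS * temperature * log(prefactor / k) / 1000
  if (any(dG < 0)) {
    warning("rate exceeds the k_B*T/h prefactor: negative barrier",
            call. = FALSE)
  }
  dG
}

#' Eyring rate from a free-energy barrier
#'
#' Companion of [eyring_barrier()]: `k = (k_B T / h) exp(-dG / RT)`.
#'
#' @param dG Barrier, kJ/mol.
#' @param temperature Temperature, K. Default 300.
#' @return Rate constant, 1/s.
#' @export
eyring_rate <- function(dG, temperature = 300) {
  stopifnot(is.numeric(dG), temperature > 0)
  (.KB * temperature / .PLANCK) *
    exp(-dG * 1000 / (.RGAS * temperature))
}

#' Proton-transfer kinetics from distance series
#'
#' End-to-end wrapper: classifies states, counts forward events, and
#' reports two characteristic-time estimators -- the total-time-per-event
#' "rough" estimate and the mean bound-state residence time -- with the
#' corresponding rate constants and the Eyring barrier for the total-time
#' estimate. The residence-time estimator is the consistent estimator of
#' the elementary bound -> transferred hop rate; the total-time estimator
#' matches the conventional rough estimate but converges to the hop rate
#' scaled by the equilibrium bound-state population.
#'
#' @param d_NH,d_OH N-H and O-H distance series, angstrom.
#' @param dt_fs Time between consecutive samples, fs.
#' @param threshold,hysteresis Classification parameters, angstrom; see
#'   [classify_states()].
#' @param temperature Temperature, K. Default 300.
#' @return Object of class `kinetics_result`: list with `n_events`,
#'   `total_time_ps`, `tau_ps`, `k` (1/s), `tau_residence_ps`,
#'   `k_residence` (1/s), `dG_kJmol`, `temperature_K`, and the
#'   `state_series`.
#' @export
proton_transfer_kinetics <- function(d_NH, d_OH, dt_fs,
                                     threshold = 1.3, hysteresis = 0.15,
                                     temperature = 300) {
  stopifnot(dt_fs > 0)
  dt_ps <- dt_fs / 1000
  total_time_ps <- (length(d_NH) - 1L) * dt_ps
  ss <- classify_states(d_NH, d_OH, threshold = threshold,
                        hysteresis = hysteresis,
                        times_ps = (seq_along(d_NH) - 1L) * dt_ps)
  n_ev <- count_transfer_events(ss)
  tau <- if (n_ev > 0L) total_time_ps / n_ev else NA_real_
  k <- if (n_ev > 0L) rate_constant(tau) else NA_real_
  tau_res <- .mean_residence_ps(ss$states, dt_ps, "bound")
  k_res <- if (!is.na(tau_res) && tau_res > 0) rate_constant(tau_res)
           else NA_real_
  dG <- if (!is.na(k)) eyring_barrier(k, temperature) else NA_real_
  structure(
    list(n_events = n_ev, total_time_ps = total_time_ps,
         tau_ps = tau, k = k,
         tau_residence_ps = tau_res, k_residence = k_res,
         dG_kJmol = dG, temperature_K = temperature,
         state_series = ss),
    class = "kinetics_result"
  )
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat("Proton-transfer kinetics @ ", x$temperature_K, " K\n", sep = "")
  cat(sprintf("  forward events    %d in %.2f ps\n",
              x$n_events, x$total_time_ps))
  if (x$n_events == 0L) {
    cat("  no transfer event observed: tau/k/dG undefined\n")
    return(invisible(x))
  }
  cat(sprintf("  tau (total/events)   %.3f ps  -> k = %.3e 1/s\n",
              x$tau_ps, x$k))
  if (!is.na(x$tau_residence_ps)) {
    cat(sprintf("  tau (bound residence) %.3f ps -> k = %.3e 1/s\n",
                x$tau_residence_ps, x$k_residence))
  }
  cat(sprintf("  Eyring barrier    %.2f kJ/mol\n", x$dG_kJmol))
  invisible(x)
}
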