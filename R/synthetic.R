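# Seeded synthetic fixtures: a two-state proton-transfer trajectory whose
# hop rates are known by construction, energy ledgers that decompose to
# prescribed terms, and random mode tables. Everything downstream of an
# electronic-structure code can be exercised against these ground truths.

#' Parameters of the two-state proton-transfer generator
#'
#' Defaults emulate the loosely bound N...H-O triad of a drug adsorbed on a
#' hydroxylated silica surface at 300 K: hops from the H-bonded ("bound")
#' state to the protonated-drug ("transferred") state at `k_hop`, back at
#' `k_return`, with the N-H distance relaxing around state-dependent means
#' (1.75 angstrom H-bond, 1.05 angstrom covalent N-H) as a discretized
#' mean-reverting (Ornstein--Uhlenbeck) process.
#'
#' @param k_hop Bound -> transferred hop rate, 1/s. Default 5e11.
#' @param k_return Transferred -> bound rate, 1/s. Default 1e12.
#' @param mean_bound_NH Mean N-H distance in the bound state, angstrom.
#'   Default 1.75.
#' @param mean_transferred_NH Mean N-H distance in the transferred state,
#'   angstrom. Default 1.05.
#' @param ou_relax Distance relaxation time, fs. Default 20.
#' @param ou_sigma Stationary noise (standard deviation) per state,
#'   angstrom: length-2 vector `(bound, transferred)` or a single value for
#'   both. Defaults 0.09 (loose H-bond) and 0.05 (tight covalent bond).
#' @param dt Sampling time step, fs. Default 0.5.
#' @param duration Simulated time, ps. Default 12.
#' @param seed Integer seed; all randomness flows from it.
#' @return Object of class `two_state_params`.
#' @export
two_state_params <- function(k_hop = 5e11, k_return = 1e12,
                             mean_bound_NH = 1.75,
                             mean_transferred_NH = 1.05,
                             ou_relax = 20, ou_sigma = c(0.09, 0.05),
                             dt = 0.5, duration = 12, seed = 1L) {
  if (length(ou_sigma) == 1L) ou_sigma <- rep(ou_sigma, 2L)
  stopifnot(k_hop > 0, k_return > 0, ou_relax > 0, all(ou_sigma > 0),
            dt > 0, duration > 0)
  if (abs(mean_bound_NH - mean_transferred_NH) <= 4 * max(ou_sigma)) {
    stop("state means must differ by more than 4 * ou_sigma for the ",
         "states to be separable", call. = FALSE)
  }
  structure(list(k_hop = k_hop, k_return = k_return,
                 mean_bound_NH = mean_bound_NH,
                 mean_transferred_NH = mean_transferred_NH,
                 ou_relax = ou_relax, ou_sigma = ou_sigma,
                 dt = dt, duration = duration, seed = as.integer(seed)),
            class = "two_state_params")
}

#' Generate a synthetic two-state proton-transfer trajectory
#'
#' Samples a continuous-time two-state Markov chain on the generator's time
#' grid (per-step switch probability `1 - exp(-k dt)`), lets the N-H
#' distance follow a mean-reverting noisy path around the current state
#' mean (exact discrete-time Ornstein--Uhlenbeck update, so the stationary
#' standard deviation equals `ou_sigma`), and embeds the result as a
#' 3-atom collinear O, H, N trajectory with O and N fixed 2.8 angstrom
#' apart; the proton sits on the O-N axis at the sampled N-H distance from
#' N, so d(O-H) = 2.8 - d(N-H). Fully reproducible from the seed.
#'
#' @param params A [two_state_params()].
#' @return List with `trajectory` (a [trajectory()]), `states` (ground-truth
#'   `state_series`), `d_NH` (sampled distances, angstrom), `n_true_events`
#'   (ground-truth forward transitions) and `params`.
#' @export
generate_two_state_trajectory <- function(params = two_state_params()) {
  stopifnot(inherits(params, "two_state_params"))
  set.seed(params$seed)

  dt_s <- params$dt * 1e-15
  n <- as.integer(round(params$duration * 1000 / params$dt)) + 1L
  p_hop <- 1 - exp(-params$k_hop * dt_s)
  p_ret <- 1 - exp(-params$k_return * dt_s)
  pi_bound <- params$k_return / (params$k_hop + params$k_return)
  if (params$k_hop * params$duration * 1e-12 * pi_bound < 1) {
    warning("duration too short for one expected transfer event",
            call. = FALSE)
  }

  # state path: 1 = bound, 2 = transferred
  u <- stats::runif(n)
  state <- integer(n)
  state[1] <- 1L
  for (t in 2:n) {
    s <- state[t - 1L]
    flip <- if (s == 1L) u[t] < p_hop else u[t] < p_ret
    state[t] <- if (flip) 3L - s else s
  }

  # exact discrete OU around the current state mean
  a <- exp(-params$dt / params$ou_relax)
  noise_scale <- sqrt(1 - a^2)
  mu <- ifelse(state == 1L, params$mean_bound_NH,
               params$mean_transferred_NH)
  sig <- params$ou_sigma[state]
  z <- stats::rnorm(n)
  d <- numeric(n)
  d[1] <- mu[1] + sig[1] * z[1]
  for (t in 2:n) {
    d[t] <- mu[t] + (d[t - 1L] - mu[t]) * a +
      sig[t] * noise_scale * z[t]
  }
  d <- pmin(pmax(d, 0.6), 2.4)  # keep the proton between the heavy atoms

  on_axis <- 2.8 - d
  coords <- lapply(seq_len(n), function(t) {
    matrix(c(0, 0, 0,
             0, 0, on_axis[t],
             0, 0, 2.8), ncol = 3, byrow = TRUE)
  })
  traj <- trajectory(c("O", "H", "N"), coords, dt = params$dt)

  labels <- c("bound", "transferred")[state]
  ss <- structure(list(states = factor(labels,
                                       levels = c("bound", "transferred")),
                       times_ps = (seq_len(n) - 1L) * params$dt / 1000),
                  class = "state_series")
  list(trajectory = traj, states = ss, d_NH = d,
       n_true_events = count_transfer_events(ss), params = params)
}

#' Generate an energy ledger with a known decomposition
#'
#' Draws plausible random fragment base energies, then constructs the
#' complex, deformed and ghosted entries so that [decompose_ledger()]
#' recovers exactly the prescribed terms: `dE = dE_star + delta_S + dE_N +
#' dE_L`, `dE_C = dE + bsse`. The BSSE lowering is split randomly between
#' the two ghosted fragments.
#'
#' @param dE_star Deformation-free interaction energy, kJ/mol.
#' @param delta_S Surface deformation energy, kJ/mol.
#' @param dE_N Molecular deformation energy, kJ/mol.
#' @param dE_L Lateral replica--replica interaction energy, kJ/mol.
#' @param bsse Basis set superposition error, kJ/mol, nonnegative.
#' @param seed Integer seed.
#' @return An [energy_ledger()] in kJ/mol.
#' @export
generate_energy_ledger <- function(dE_star, delta_S, dE_N, dE_L,
                                   bsse = 0, seed = 1L) {
  stopifnot(is.numeric(bsse), bsse >= 0)
  set.seed(as.integer(seed))
  e_surface_relaxed <- stats::runif(1, -2e5, -1e5)
  e_molecule_relaxed <- stats::runif(1, -5e4, -1e4)

  e_surface_deformed <- e_surface_relaxed + delta_S
  e_molecule_deformed_isolated <- e_molecule_relaxed + dE_N
  e_molecule_deformed_periodic <- e_molecule_deformed_isolated + dE_L
  e_complex <- dE_star + e_molecule_deformed_periodic + e_surface_deformed

  frac <- stats::runif(1)
  e_surface_ghosted <- e_surface_deformed - frac * bsse
  e_molecule_ghosted <- e_molecule_deformed_periodic - (1 - frac) * bsse

  energy_ledger(
    e_complex = e_complex,
    e_surface_relaxed = e_surface_relaxed,
    e_molecule_relaxed = e_molecule_relaxed,
    e_surface_deformed = e_surface_deformed,
    e_molecule_deformed_periodic = e_molecule_deformed_periodic,
    e_molecule_deformed_isolated = e_molecule_deformed_isolated,
    e_surface_ghosted = e_surface_ghosted,
    e_molecule_ghosted = e_molecule_ghosted,
    unit = "kJ/mol"
  )
}

#' Generate a random harmonic mode table
#'
#' Reproducible random frequencies (uniform over the range, sorted) and
#' intensities (exponential, mean 50 km/mol). Optionally seeds the table
#' with fixed reference bands -- the azomethine C=N stretch near 1607 1/cm
#' and the amide N-H stretch near 3478 1/cm -- for band-shift exercises.
#'
#' @param n_modes Number of random modes (>= 1). A 32-atom molecule has
#'   3N - 6 = 90 modes.
#' @param frequency_range Length-2 range in 1/cm. Default `c(100, 4000)`.
#' @param seed Integer seed.
#' @param reference_bands Optional numeric vector of frequencies appended
#'   with intensity 100 km/mol (e.g. `c(1607, 3478)`).
#' @param label Table label.
#' @return A [mode_table()].
#' @export
generate_mode_table <- function(n_modes, frequency_range = c(100, 4000),
                                seed = 1L, reference_bands = NULL,
                                label = "synthetic") {
  stopifnot(n_modes >= 1, length(frequency_range) == 2L,
            frequency_range[1] > 0,
            frequency_range[2] > frequency_range[1])
  set.seed(as.integer(seed))
  freq <- sort(stats::runif(n_modes, frequency_range[1],
                            frequency_range[2]))
  intensity <- stats::rexp(n_modes, rate = 1 / 50)
  if (!is.null(reference_bands)) {
    freq <- c(freq, reference_bands)
    intensity <- c(intensity, rep(100, length(reference_bands)))
  }
  mode_table(freq, intensity, label = label)
}
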