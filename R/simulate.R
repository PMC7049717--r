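#' Three-state kinetic scheme for a DNA-binding protein
#'
#' A tracked molecule switches between three diffusion states: freely
#' diffusing in the cytoplasm (FD), nonspecifically bound to and moving on
#' the chromosome (NB), and tightly bound to the chromosome (TB). Transitions
#' follow a continuous-time Markov chain; binding steps are modeled as
#' pseudo-first-order, so all rates are in s^-1.
#'
#' @param D_FD,D_NB,D_TB Effective diffusion constants (um^2/s) with
#'   `D_FD > D_NB > D_TB >= 0`.
#' @param k1_on Effective FD -> TB binding rate (s^-1).
#' @param k_minus1 TB -> FD unbinding rate (s^-1); concentration-dependent
#'   unbinding is injected by varying this rate between simulations.
#' @param k2_on Effective FD -> NB binding rate (s^-1).
#' @param k_minus2 NB -> FD unbinding rate (s^-1).
#' @param k3 NB -> TB interconversion rate on DNA (s^-1; default 0).
#' @param k_minus3 TB -> NB interconversion rate (s^-1; default 0).
#' @return An object of class `kinetic_scheme`.
#' @examples
#' kinetic_scheme(D_FD = 6.7, D_NB = 0.82, D_TB = 0.033,
#'                k1_on = 2, k_minus1 = 10, k2_on = 5, k_minus2 = 4)
#' @export
kinetic_scheme <- function(D_FD, D_NB, D_TB,
                           k1_on = 0, k_minus1 = 0,
                           k2_on = 0, k_minus2 = 0,
                           k3 = 0, k_minus3 = 0) {
  rates <- c(k1_on = k1_on, k_minus1 = k_minus1, k2_on = k2_on,
             k_minus2 = k_minus2, k3 = k3, k_minus3 = k_minus3)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all transition rates must be finite and >= 0", call. = FALSE)
  D <- c(FD = D_FD, NB = D_NB, TB = D_TB)
  if (any(!is.finite(D)) || D_TB < 0 || !(D_FD > D_NB && D_NB > D_TB))
    stop("diffusion constants must satisfy D_FD > D_NB > D_TB >= 0",
         call. = FALSE)
  structure(c(list(D = D), as.list(rates)), class = "kinetic_scheme")
}

# 3x3 generator matrix of the FD/NB/TB chain (rows = from, cols = to)
scheme_generator <- function(scheme) {
  Q <- matrix(0, 3, 3, dimnames = list(c("FD", "NB", "TB"),
                                       c("FD", "NB", "TB")))
  Q["FD", "NB"] <- scheme$k2_on
  Q["FD", "TB"] <- scheme$k1_on
  Q["NB", "FD"] <- scheme$k_minus2
  Q["NB", "TB"] <- scheme$k3
  Q["TB", "FD"] <- scheme$k_minus1
  Q["TB", "NB"] <- scheme$k_minus3
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary state occupancy of the three-state chain
#'
#' Solves `pi Q = 0` with `sum(pi) = 1` for the FD/NB/TB generator. When the
#' chain is reducible (some states unreachable) the distribution is restricted
#' to the communicating states reachable from FD.
#'
#' @param scheme A [kinetic_scheme()].
#' @return Named numeric vector `c(FD=, NB=, TB=)` summing to 1.
#' @export
stationary_distribution <- function(scheme) {
  Q <- scheme_generator(scheme)
  if (all(Q == 0)) return(c(FD = 1, NB = 0, TB = 0))
  A <- rbind(t(Q), rep(1, 3))
  b <- c(0, 0, 0, 1)
  pi_hat <- qr.solve(A, b)
  pi_hat <- pmax(pi_hat, 0)
  pi_hat <- pi_hat / sum(pi_hat)
  names(pi_hat) <- c("FD", "NB", "TB")
  pi_hat
}

#' Stroboscopic time-lapse imaging model
#'
#' Short excitation pulses separated by a longer time lapse let mobile
#' molecules appear as diffraction-limited spots; positions are read at the
#' pulse midpoint and blurred by the localization precision. Photobleaching
#' and blinking are pooled into a single effective track-termination rate on
#' the lapse-time axis, which is exactly what the fluorescence on-time
#' distribution of the tracks measures.
#'
#' @param t_lapse Time lapse between frames in s (default 0.040).
#' @param t_exposure Excitation pulse length in s (default 0.004).
#' @param sigma_loc Localization precision in um (default 0.020).
#' @param k_bleach Effective photobleach/blink termination rate in s^-1 on
#'   the lapse-time axis (default 0 = no bleaching).
#' @param frames_per_cycle Frames per photoconversion/imaging cycle
#'   (default 30); tracks cannot outlive a cycle.
#' @return An object of class `imaging_model`.
#' @export
imaging_model <- function(t_lapse = 0.040, t_exposure = 0.004,
                          sigma_loc = 0.020, k_bleach = 0,
                          frames_per_cycle = 30L) {
  if (!(t_exposure > 0 && t_exposure <= t_lapse))
    stop("need 0 < t_exposure <= t_lapse", call. = FALSE)
  if (sigma_loc < 0 || k_bleach < 0)
    stop("sigma_loc and k_bleach must be >= 0", call. = FALSE)
  if (frames_per_cycle < 1)
    stop("frames_per_cycle must be >= 1", call. = FALSE)
  structure(list(t_lapse = t_lapse, t_exposure = t_exposure,
                 sigma_loc = sigma_loc, k_bleach = k_bleach,
                 frames_per_cycle = as.integer(frames_per_cycle)),
            class = "imaging_model")
}

#' Simulate single-molecule tracks in a spherocylindrical cell
#'
#' Each molecule follows the continuous-time Markov chain of the
#' [kinetic_scheme()] (exact exponential waiting times), performs 3D
#' Brownian motion with the current state's diffusion constant (mirror
#' reflection at the membrane, 1 ms propagation step), and is observed in
#' 2D at each frame's pulse midpoint with isotropic Gaussian localization
#' noise. Tracks terminate at the first photobleach/blink event (exponential
#' with rate `imaging$k_bleach`) or at the end of the imaging cycle.
#'
#' @param geom A [cell_geometry()].
#' @param scheme A [kinetic_scheme()].
#' @param imaging An [imaging_model()].
#' @param n_molecules Number of molecules (tracks) to simulate.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param cell_id Cell identifier stored in the output.
#' @param start_state `"stationary"` (default) samples the initial state from
#'   the chain's stationary distribution; or one of `"FD"`, `"NB"`, `"TB"`.
#' @param dt Propagation time step in s (default 0.001).
#' @return A `data.table` with columns `cell_id`, `track_id`, `frame`,
#'   `x_um`, `y_um` and the hidden `state` label (simulation ground truth;
#'   drop it to emulate real data).
#' @export
simulate_tracks <- function(geom, scheme, imaging, n_molecules, seed,
                            cell_id = 1L, start_state = "stationary",
                            dt = 0.001) {
  stopifnot(inherits(geom, "cell_geometry"),
            inherits(scheme, "kinetic_scheme"),
            inherits(imaging, "imaging_model"),
            n_molecules >= 1)
  if (!missing(seed) && !is.null(seed)) set.seed(seed)
  M <- as.integer(n_molecules)
  states <- c("FD", "NB", "TB")
  Q <- scheme_generator(scheme)
  exit_rate <- -diag(Q)
  D <- scheme$D

  # observed track lengths in frames: geometric bleaching, capped by cycle
  nf_max <- imaging$frames_per_cycle
  if (imaging$k_bleach > 0) {
    p_bleach <- 1 - exp(-imaging$k_bleach * imaging$t_lapse)
    n_frames <- pmin(rgeom(M, p_bleach) + 1L, nf_max)
  } else {
    n_frames <- rep(nf_max, M)
  }
  max_f <- max(n_frames)

  # initial positions and states
  pos <- sample_points(geom, M, seed = NULL)
  if (identical(start_state, "stationary")) {
    pi0 <- stationary_distribution(scheme)
    st <- sample.int(3L, M, replace = TRUE, prob = pi0)
  } else {
    st <- rep(match(match.arg(start_state, states), states), M)
  }
  draw_wait <- function(idx, now) {
    er <- exit_rate[st[idx]]
    w <- ifelse(er > 0, rexp(length(idx), pmax(er, .Machine$double.xmin)), Inf)
    now + w
  }
  t_next <- draw_wait(seq_len(M), 0)

  n_sub <- max(1L, round(imaging$t_lapse / dt))
  mid_sub <- max(1L, round((imaging$t_exposure / 2) / dt))
  obs_x <- matrix(NA_real_, M, max_f)
  obs_y <- matrix(NA_real_, M, max_f)
  obs_s <- matrix(NA_integer_, M, max_f)

  t_now <- 0
  for (f in seq_len(max_f)) {
    for (s_idx in seq_len(n_sub)) {
      t_now <- t_now + dt
      # state switches whose waiting time elapsed within this step
      repeat {
        due <- which(t_next <= t_now)
        if (length(due) == 0L) break
        for (m in due) {
          rates_to <- Q[st[m], ]
          rates_to[st[m]] <- 0
          st[m] <- sample.int(3L, 1L, prob = rates_to)
        }
        t_next[due] <- draw_wait(due, t_now)
      }
      step_sd <- sqrt(2 * D[st] * dt)
      pos <- pos + matrix(rnorm(3L * M, sd = rep(step_sd, 3L)), M, 3L)
      pos <- reflect_into_cell(geom, pos)
      if (s_idx == mid_sub) {
        obs_x[, f] <- pos[, 1] + rnorm(M, sd = imaging$sigma_loc)
        obs_y[, f] <- pos[, 2] + rnorm(M, sd = imaging$sigma_loc)
        obs_s[, f] <- st
      }
    }
  }

  keep <- sequence(n_frames)
  mol <- rep(seq_len(M), n_frames)
  idx <- cbind(mol, keep)
  data.table::data.table(
    cell_id = cell_id,
    track_id = mol,
    frame = keep,
    x_um = obs_x[idx],
    y_um = obs_y[idx],
    state = states[obs_s[idx]]
  )
}
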