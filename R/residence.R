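#' Thresholded residence times from displacement trajectories
#'
#' A residence event is a maximal run of consecutive per-lapse displacements
#' below the threshold `r0`; its residence time is the run length times the
#' time lapse. Runs cut short by the end of the track (photobleaching,
#' blinking, or end of the imaging cycle) are flagged as censored and enter
#' the dwell-model likelihood through survival terms.
#'
#' @param disp Output of [displacements()] (columns `cell_id`, `track_id`,
#'   `r_um`), or a bare numeric vector of displacements from one track.
#' @param r0 Displacement threshold in um (e.g. 0.2).
#' @param t_lapse Time lapse in s.
#' @return A `data.table` with one row per residence event: `cell_id`,
#'   `track_id`, `n_disp` (run length in displacements), `tau` (s),
#'   `censored` (ended by track end rather than a threshold crossing).
#' @examples
#' extract_tau(c(0.5, 0.1, 0.1, 0.1, 0.6), r0 = 0.2, t_lapse = 0.04)
#' @export
extract_tau <- function(disp, r0, t_lapse) {
  stopifnot(r0 > 0, t_lapse > 0)
  if (is.numeric(disp)) {
    disp <- data.table::data.table(cell_id = 1L, track_id = 1L,
                                   frame = seq_along(disp), r_um = disp)
  } else {
    disp <- data.table::as.data.table(disp)
    data.table::setorder(disp, cell_id, track_id, frame)
  }
  empty <- data.table::data.table(cell_id = integer(), track_id = integer(),
                                  n_disp = integer(), tau = numeric(),
                                  censored = logical())
  if (nrow(disp) == 0L) return(empty)
  runs <- disp[, {
    rl <- rle(r_um < r0)
    below <- which(rl$values)
    if (length(below) == 0L) {
      list(n_disp = integer(), censored = logical())
    } else {
      list(n_disp = rl$lengths[below],
           censored = below == length(rl$lengths))
    }
  }, by = c("cell_id", "track_id")]
  if (nrow(runs) == 0L) return(empty)
  runs[, tau := n_disp * t_lapse]
  data.table::setcolorder(runs, c("cell_id", "track_id", "n_disp", "tau",
                                  "censored"))
  runs[]
}

#' Photobleach/blink rate from fluorescence on-times
#'
#' Exponential maximum-likelihood fit of the track on-time distribution
#' (track length in frames times the time lapse): the rate is the inverse
#' mean on-time, on the lapse-time axis — the same axis on which the dwell
#' model applies its bleaching correction.
#'
#' @param n_frames Integer vector of track lengths in frames.
#' @param t_lapse Time lapse in s.
#' @param n_boot Bootstrap replicates for the standard deviation
#'   (default 200).
#' @param seed Integer seed for the bootstrap.
#' @return List with `k_bleach` (s^-1), `sd`, and `n_tracks`.
#' @export
fit_on_times <- function(n_frames, t_lapse, n_boot = 200L, seed = 1L) {
  n_frames <- as.numeric(n_frames)
  if (length(n_frames) < 2L)
    stop("need at least 2 tracks to fit the on-time distribution",
         call. = FALSE)
  if (any(n_frames < 1)) stop("track lengths must be >= 1 frame",
                              call. = FALSE)
  if (length(n_frames) < 100L)
    warning("fewer than 100 tracks: on-time fit may be unreliable",
            call. = FALSE)
  if (stats::sd(n_frames) == 0)
    stop("all tracks have the same length: on-time distribution is ",
         "degenerate, cannot fit a rate", call. = FALSE)
  on_times <- n_frames * t_lapse
  k_hat <- 1 / mean(on_times)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    1 / mean(sample(on_times, length(on_times), replace = TRUE))
  }, numeric(1))
  list(k_bleach = k_hat, sd = stats::sd(boot),
       n_tracks = length(n_frames))
}

# per-event log-likelihood matrix of the discrete dwell model.
# s: per-frame probability that the run continues below threshold for each
# state (TB's depends on k_minus1); b: per-frame bleach survival.  Per
# frame the run continues with prob s*b, ends with an observed
# above-threshold displacement with prob (1-s)*b, or is censored by track
# termination with prob (1-b); the constant censoring factor log(1-b) is
# dropped (it carries no kinetic information and is 0-probability under
# pure cycle-end censoring).
dwell_loglik <- function(m, censored, s, b) {
  s <- pmin(pmax(s, 1e-12), 1 - 1e-12)
  ll <- matrix(NA_real_, length(m), length(s))
  for (i in seq_along(s)) {
    ll[, i] <- (m - 1) * (log(s[i]) + log(b)) +
      ifelse(censored, 0, log(1 - s[i]) + log(b))
  }
  ll
}

#' Fit the residence-time distribution with the three-state dwell model
#'
#' The residence-time distribution is modeled as a mixture over the three
#' diffusion states. A molecule in the TB state continues a sub-threshold
#' run each frame with probability
#' `exp(-(k_minus1) * t_lapse) * p_TB`, where `p_TB` is the probability that
#' a TB displacement falls below `r0` ([brownian_cdf()]); FD and NB
#' molecules contribute apparent runs that continue with probability `p_FD`
#' and `p_NB` — this deconvolutes their contribution from genuine unbinding.
#' Photobleaching/blinking attenuates every continuation by
#' `exp(-k_bleach * t_lapse)`; censored runs enter via survival terms. The
#' discrete (geometric) form is used throughout, so no binning bias arises
#' at small residence times.
#'
#' Component weights are tied to the diffusion-state fit
#' (`w_i` proportional to `f_i * p_i`, the rate at which each state produces
#' sub-threshold runs) by default; `weights = "float"` frees them.
#'
#' @param tau_set Output of [extract_tau()], or a data.frame with columns
#'   `tau` (s) and `censored` (logical).
#' @param D Named diffusion constants `c(FD=, NB=, TB=)` in um^2/s (e.g.
#'   `fit$D` from [fit_mixture()]).
#' @param fractions Fractional populations `c(FD=, NB=, TB=)` of the group
#'   being fitted (a row of `fit$f`).
#' @param k_bleach Photobleach/blink rate (s^-1), from [fit_on_times()];
#'   held fixed.
#' @param r0 Displacement threshold (um).
#' @param t_lapse Time lapse (s).
#' @param sigma_loc Localization precision (um).
#' @param weights `"tied"` (default) or `"float"`.
#' @param n_boot Bootstrap replicates for the s.d. of `k_minus1`
#'   (0 = skip; resampling unit is the cell when `cell_id` is present,
#'   otherwise the residence event).
#' @param seed Seed for the bootstrap.
#' @return An object of class `dwell_fit`: `k_minus1` (s^-1), `sd`,
#'   `k_bleach`, `weights` (FD/NB/TB), `p_below` (per-state sub-threshold
#'   probabilities), `loglik`, `naive_rate` (inverse mean uncensored tau,
#'   uncorrected), `boundary` flag, `n_events`, `n_censored`.
#' @export
fit_dwell_distribution <- function(tau_set, D, fractions, k_bleach,
                                   r0, t_lapse, sigma_loc = 0,
                                   weights = c("tied", "float"),
                                   n_boot = 0L, seed = 1L) {
  weights <- match.arg(weights)
  stopifnot(k_bleach >= 0, r0 > 0, t_lapse > 0, length(D) == length(fractions))
  tau_set <- data.table::as.data.table(tau_set)
  if (!all(c("tau", "censored") %in% names(tau_set)))
    stop("tau_set needs columns 'tau' and 'censored'", call. = FALSE)
  m <- as.integer(round(tau_set$tau / t_lapse))
  if (any(m < 1L)) stop("residence times must be >= one time lapse",
                        call. = FALSE)
  cens <- tau_set$censored
  if (sum(!cens) < 100L)
    warning("fewer than 100 uncensored residence times: k_minus1 may be ",
            "poorly determined", call. = FALSE)

  p_below <- brownian_cdf(r0, D, t_lapse, sigma_loc)
  b <- exp(-k_bleach * t_lapse)
  tb <- length(D)  # slowest state is last when D is sorted decreasing
  if (sum(fractions * p_below) <= 0)
    stop("all component weights are zero", call. = FALSE)

  # tied mixing proportions are event rates: runs per displacement from
  # state i is f_i * p_i * (1 - c_i) (each run lasts 1/(1-c_i) frames),
  # with c_i the per-frame continuation; TB's depends on k_minus1
  tied_w <- function(k) {
    s <- p_below
    s[tb] <- p_below[tb] * exp(-k * t_lapse)
    w <- fractions * p_below * (1 - s * b)
    w / sum(w)
  }
  nll <- function(k, w = NULL) {
    if (is.null(w)) w <- tied_w(k)
    s <- p_below
    s[tb] <- p_below[tb] * exp(-k * t_lapse)
    -sum(log(pmax(rowSums(exp(dwell_loglik(m, cens, s, b)) *
                            rep(w, each = length(m))), 1e-300)))
  }
  k_hi <- 10 / t_lapse
  k_lo <- 1e-4
  if (weights == "tied") {
    opt <- stats::optimize(nll, c(k_lo, k_hi), tol = 1e-8)
    k_hat <- opt$minimum
    w_hat <- tied_w(k_hat)
    ll <- -opt$objective
  } else {
    w0 <- fractions * p_below
    w0 <- w0 / sum(w0)
    K <- length(D)
    par0 <- c(log(1), log(w0[-K] / w0[K]))
    obj <- function(p) {
      w <- c(exp(p[-1]), 1)
      w <- w / sum(w)
      nll(exp(p[1]), w)
    }
    op <- stats::optim(par0, obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-10))
    k_hat <- exp(op$par[1])
    w_hat <- c(exp(op$par[-1]), 1)
    w_hat <- w_hat / sum(w_hat)
    ll <- -op$value
  }
  boundary <- k_hat <= k_lo * 1.01 || k_hat >= k_hi * 0.99
  if (boundary)
    warning("k_minus1 estimate pinned at a bound: non-identifiable",
            call. = FALSE)

  sd_hat <- NA_real_
  if (n_boot > 0L) {
    unit <- if ("cell_id" %in% names(tau_set) &&
                length(unique(tau_set$cell_id)) >= 2L) "cell_id" else NULL
    dat <- data.table::data.table(m = m, censored = cens)
    if (!is.null(unit)) dat$cell_id <- tau_set$cell_id
    refit <- function(d) {
      mm <- d$m; cc <- d$censored
      f <- function(k) {
        s <- p_below
        s[tb] <- p_below[tb] * exp(-k * t_lapse)
        -sum(log(pmax(rowSums(exp(dwell_loglik(mm, cc, s, b)) *
                                rep(w_hat, each = length(mm))), 1e-300)))
      }
      c(k_minus1 = stats::optimize(f, c(k_lo, k_hi), tol = 1e-8)$minimum)
    }
    if (is.null(unit)) {
      set.seed(seed)
      reps <- vapply(seq_len(n_boot), function(i)
        refit(dat[sample.int(nrow(dat), nrow(dat), replace = TRUE)]),
        numeric(1))
      sd_hat <- stats::sd(reps)
    } else {
      sd_hat <- unname(bootstrap_sd(dat, refit, unit = unit,
                                    n_boot = n_boot, seed = seed)$sd)
    }
  }

  mean_unc <- mean(tau_set$tau[!cens])
  structure(list(k_minus1 = k_hat, sd = sd_hat, k_bleach = k_bleach,
                 weights = stats::setNames(w_hat, names(D)),
                 p_below = stats::setNames(p_below, names(D)),
                 loglik = ll, naive_rate = 1 / mean_unc,
                 boundary = boundary, n_events = length(m),
                 n_censored = sum(cens), r0 = r0, t_lapse = t_lapse),
            class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("dwell fit: k_minus1 = %.3g s^-1 (sd %.3g), k_bleach = %.3g s^-1\n",
              x$k_minus1, x$sd, x$k_bleach))
  cat(sprintf("  %d events (%d censored); naive inverse-mean rate %.3g s^-1\n",
              x$n_events, x$n_censored, x$naive_rate))
  cat("  weights:", paste(sprintf("%s = %.3f", names(x$weights), x$weights),
                          collapse = ", "), "\n")
  invisible(x)
}
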