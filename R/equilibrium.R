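#' Equilibrium site-binding model for the state populations
#'
#' Mass-action competitive binding of free dimers to two pools of chromosome
#' sites with depletion: tight-binding (TB) sites of capacity `D0_TB_no`
#' (the site concentration times the oligomer occupancy, so in dimer-nM)
#' with dissociation constant `K_d1`, and nonspecific (NB) sites of capacity
#' `D0_NB` with dissociation constant `K_d2`. `K_d3` is the NB/TB partition
#' ratio carried as a derived diagnostic only, not a free parameter of the
#' isotherm.
#'
#' @param K_d1 TB-site dissociation constant (nM).
#' @param K_d2 NB-site dissociation constant (nM).
#' @param D0_NB Nonspecific site capacity (nM).
#' @param D0_TB_no TB capacity including oligomer slots (nM).
#' @param K_d3 Optional NB/TB interconversion ratio (dimensionless).
#' @return Object of class `equilibrium_model`.
#' @export
equilibrium_model <- function(K_d1, K_d2, D0_NB, D0_TB_no, K_d3 = NA) {
  vals <- c(K_d1 = K_d1, K_d2 = K_d2, D0_NB = D0_NB, D0_TB_no = D0_TB_no)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("K_d's and capacities must be positive", call. = FALSE)
  structure(as.list(c(vals, K_d3 = K_d3)), class = "equilibrium_model")
}

#' Solve the binding equilibrium at a given total concentration
#'
#' Solves the conservation relation
#' `P_total = P_FD + D0_TB_no * P_FD/(K_d1 + P_FD) + D0_NB * P_FD/(K_d2 + P_FD)`
#' for the free concentration `P_FD` by bisection (the left side is strictly
#' increasing in `P_FD`, so the root in `(0, P_total]` is unique), and
#' returns the fractional populations of the three states.
#'
#' @param P_total Total dimer concentration(s) in nM (vectorized).
#' @param model An [equilibrium_model()].
#' @return `data.table` with columns `P_total`, `P_FD`, `f_FD`, `f_NB`,
#'   `f_TB` (fractions sum to 1).
#' @export
solve_equilibrium <- function(P_total, model) {
  stopifnot(inherits(model, "equilibrium_model"))
  if (any(P_total <= 0)) stop("P_total must be > 0", call. = FALSE)
  one <- function(pt) {
    g <- function(p) p + model$D0_TB_no * p / (model$K_d1 + p) +
      model$D0_NB * p / (model$K_d2 + p) - pt
    root <- stats::uniroot(g, lower = pt * 1e-12, upper = pt,
                           tol = .Machine$double.eps^0.6)$root
    root
  }
  p_fd <- vapply(P_total, one, numeric(1))
  b_tb <- model$D0_TB_no * p_fd / (model$K_d1 + p_fd)
  b_nb <- model$D0_NB * p_fd / (model$K_d2 + p_fd)
  tot <- p_fd + b_tb + b_nb
  data.table::data.table(P_total = P_total, P_FD = p_fd,
                         f_FD = p_fd / tot, f_NB = b_nb / tot,
                         f_TB = b_tb / tot)
}

#' Fit the equilibrium model to state fractions versus concentration
#'
#' Weighted least squares of the [solve_equilibrium()] predictions to
#' observed per-group fractions, over the four log-parameterized model
#' parameters; standard deviations by group-level bootstrap.
#'
#' @param fractions Data.frame with columns `P_total` (nM), `f_FD`, `f_NB`,
#'   `f_TB`; optional `sd_FD`, `sd_NB`, `sd_TB` weights (1/sd^2).
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Seed for the bootstrap.
#' @return List of class `equilibrium_fit`: `model` (the fitted
#'   [equilibrium_model()]), `sd` (named), `rss`, `converged`, `fitted`.
#' @export
fit_population_model <- function(fractions, n_boot = 200L, seed = 1L) {
  df <- as.data.frame(fractions)
  need <- c("P_total", "f_FD", "f_NB", "f_TB")
  if (!all(need %in% names(df)))
    stop("fractions need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(df) < 4L)
    stop("need at least 4 concentration groups", call. = FALSE)
  if (diff(range(log10(df$P_total))) < 1)
    warning("concentration span below one decade: capacities and K_d's ",
            "may be degenerate", call. = FALSE)
  wcols <- c("sd_FD", "sd_NB", "sd_TB")
  W <- if (all(wcols %in% names(df)) &&
           all(is.finite(unlist(df[wcols]))) && all(unlist(df[wcols]) > 0))
    1 / as.matrix(df[wcols])^2 else matrix(1, nrow(df), 3)

  obs <- as.matrix(df[c("f_FD", "f_NB", "f_TB")])
  fit_once <- function(df, W, obs) {
    rss <- function(lp) {
      m <- equilibrium_model(exp(lp[1]), exp(lp[2]), exp(lp[3]), exp(lp[4]))
      pred <- solve_equilibrium(df$P_total, m)
      sum(W * (as.matrix(pred[, c("f_FD", "f_NB", "f_TB")]) - obs)^2)
    }
    # starts: K_d1 ~ low end of P, K_d2 ~ high end, capacities from the
    # bound fractions at the extremes
    p_lo <- min(df$P_total); p_hi <- max(df$P_total)
    lp0 <- log(c(max(p_lo / 3, 1e-2), p_hi,
                 max(p_hi * mean(df$f_NB), 1),
                 max(p_lo * mean(df$f_TB) * 2, 1)))
    op <- stats::optim(lp0, rss, method = "Nelder-Mead",
                       control = list(maxit = 4000, reltol = 1e-12))
    op2 <- stats::optim(op$par, rss, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    if (op2$value <= op$value) op <- op2
    op
  }
  op <- fit_once(df, W, obs)
  est <- exp(op$par)
  names(est) <- c("K_d1", "K_d2", "D0_NB", "D0_TB_no")
  model <- equilibrium_model(est[1], est[2], est[3], est[4])

  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, 4, dimnames = list(NULL, names(est)))
  for (b in seq_len(n_boot)) {
    i <- sample.int(nrow(df), nrow(df), replace = TRUE)
    if (length(unique(df$P_total[i])) < 4L) next
    ob <- tryCatch(fit_once(df[i, ], W[i, , drop = FALSE],
                            obs[i, , drop = FALSE]),
                   error = function(e) NULL)
    if (!is.null(ob)) reps[b, ] <- exp(ob$par)
  }
  structure(list(model = model,
                 sd = apply(reps, 2, stats::sd, na.rm = TRUE),
                 rss = op$value, converged = op$convergence == 0,
                 fitted = solve_equilibrium(df$P_total, model),
                 replicates = reps),
            class = "equilibrium_fit")
}

#' @export
print.equilibrium_fit <- function(x, ...) {
  m <- x$model
  cat(sprintf(
    "equilibrium fit: K_d1 = %.3g +/- %.2g nM, K_d2 = %.3g +/- %.2g nM,\n",
    m$K_d1, x$sd["K_d1"], m$K_d2, x$sd["K_d2"]))
  cat(sprintf("  D0_NB = %.3g +/- %.2g nM, D0_TB*n_o = %.3g +/- %.2g nM (rss %.3g)\n",
              m$D0_NB, x$sd["D0_NB"], m$D0_TB_no, x$sd["D0_TB_no"], x$rss))
  invisible(x)
}
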