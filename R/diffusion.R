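#' Per-lapse displacement lengths from tracks
#'
#' One displacement per pair of adjacent localizations within a track; pairs
#' spanning a frame gap are excluded (tracks are built without gap closing,
#' so frames should already advance in unit steps).
#'
#' @param tracks A data.frame/data.table with columns `cell_id`, `track_id`,
#'   `frame`, `x_um`, `y_um` (extra columns are ignored).
#' @return A `data.table` with columns `cell_id`, `track_id`, `frame`
#'   (first frame of the pair) and `r_um`.
#' @examples
#' tr <- data.frame(cell_id = 1, track_id = 1, frame = 1:2,
#'                  x_um = c(0, 0.3), y_um = c(0, 0.4))
#' displacements(tr)$r_um  # 0.5
#' @export
displacements <- function(tracks) {
  cols <- c("cell_id", "track_id", "frame", "x_um", "y_um")
  if (!all(cols %in% names(tracks)))
    stop("tracks need columns: ", paste(cols, collapse = ", "), call. = FALSE)
  dt <- data.table::as.data.table(tracks)[, cols, with = FALSE]
  if (nrow(dt) == 0L)
    return(data.table::data.table(cell_id = integer(), track_id = integer(),
                                  frame = integer(), r_um = numeric()))
  data.table::setorder(dt, cell_id, track_id, frame)
  dt[, `:=`(dx = c(diff(x_um), NA_real_),
            dy = c(diff(y_um), NA_real_),
            df = c(diff(frame), NA_integer_)),
     by = c("cell_id", "track_id")]
  out <- dt[!is.na(df) & df == 1L,
            list(cell_id, track_id, frame, r_um = sqrt(dx^2 + dy^2))]
  out[]
}

#' 2D Brownian displacement CDF with localization-error broadening
#'
#' Probability that a single-lapse displacement of a 2D Brownian motion with
#' diffusion constant `D` is below `r0`, including the static broadening from
#' localization noise in both localizations:
#' \eqn{F(r_0) = 1 - \exp(-r_0^2 / (4 D t + 4\sigma^2))}.
#'
#' @param r0 Displacement threshold (um).
#' @param D Diffusion constant (um^2/s).
#' @param t_lapse Time lapse (s).
#' @param sigma_loc Localization precision (um), default 0.
#' @return Probability in `[0, 1]`. With `D = sigma_loc = 0` the motion is
#'   degenerate at 0, so any `r0 > 0` gives 1.
#' @export
brownian_cdf <- function(r0, D, t_lapse, sigma_loc = 0) {
  stopifnot(all(r0 >= 0), all(D >= 0), t_lapse > 0, all(sigma_loc >= 0))
  v <- 4 * D * t_lapse + 4 * sigma_loc^2
  ifelse(v == 0, as.numeric(r0 > 0), -expm1(-r0^2 / v))
}

# exponential-mixture EM on squared displacements.
# x2: pooled r^2 values; grp: integer group index; mu floor keeps D >= 0.
em_exp_mixture <- function(x2, grp, K, mu0, w0 = NULL, floor_mu = 0,
                           max_iter = 500L, tol = 1e-9) {
  G <- max(grp)
  n_g <- tabulate(grp, G)
  w <- if (is.null(w0)) matrix(1 / K, G, K) else w0
  mu <- mu0
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K),
                   function(k) exp(-x2 / mu[k]) / mu[k], numeric(length(x2)))
    wd <- dens * w[grp, , drop = FALSE]
    tot <- rowSums(wd)
    tot[tot <= 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    resp <- wd / tot
    mu <- pmax(colSums(resp * x2) / pmax(colSums(resp), 1e-300),
               floor_mu + 1e-12)
    w <- rowsum(resp, grp) / n_g
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, w = w, loglik = ll, iterations = it,
       converged = it < max_iter)
}

#' Resolve Brownian diffusion states from displacement statistics
#'
#' Fits the squared per-lapse displacements with a mixture of exponentials
#' (the 2D Brownian form: `r^2 ~ Exp(mean = 4 D t_lapse + 4 sigma_loc^2)`),
#' globally across concentration groups: the diffusion constants are shared
#' by all groups while the fractional populations are free per group. The
#' default objective is the maximum likelihood on `r^2` (EM algorithm); a
#' least-squares fit to the empirical CDF is available as a cross-check via
#' `method = "cdf-ls"`.
#'
#' @param r Displacement lengths in um (pooled over groups), or the `r_um`
#'   column of [displacements()].
#' @param t_lapse Time lapse in s.
#' @param sigma_loc Localization precision in um, treated as a fixed
#'   variance inflation `+4 sigma_loc^2` (not fitted).
#' @param n_states Number of diffusion states (default 3: FD/NB/TB).
#' @param group Optional factor of the same length as `r` assigning each
#'   displacement to a concentration group; `NULL` = one group.
#' @param method `"mle"` (default) or `"cdf-ls"`.
#' @param min_per_group Warn when a group has fewer displacements.
#' @return An object of class `diffusion_fit`: `D` (um^2/s, sorted
#'   decreasing, named FD/NB/TB when `n_states == 3`), `f` (groups x states
#'   matrix of fractions, rows sum to 1), `loglik`, `n_per_group`,
#'   `duplicate_states` flag (two fitted D within 15% of each other),
#'   `D_merged`/`f_merged` (view with duplicate components pooled, since
#'   the weight split between duplicates is arbitrary),
#'   `converged`, and the inputs `t_lapse`, `sigma_loc`.
#' @export
fit_mixture <- function(r, t_lapse, sigma_loc = 0, n_states = 3L,
                        group = NULL, method = c("mle", "cdf-ls"),
                        min_per_group = 500L) {
  method <- match.arg(method)
  if (n_states < 1L) stop("n_states must be >= 1", call. = FALSE)
  r <- as.numeric(r)
  if (any(!is.finite(r)) || any(r < 0))
    stop("displacements must be finite and >= 0", call. = FALSE)
  if (is.null(group)) group <- factor(rep("all", length(r)))
  group <- droplevels(as.factor(group))
  stopifnot(length(group) == length(r))
  grp <- as.integer(group)
  n_g <- tabulate(grp, nlevels(group))
  if (any(n_g < min_per_group))
    warning("group(s) with fewer than ", min_per_group,
            " displacements: fit may be unstable", call. = FALSE)
  x2 <- r^2
  K <- as.integer(n_states)
  floor_mu <- 4 * sigma_loc^2

  # deterministic initializations: equal-count chunks of sorted r^2,
  # and log-spaced means between robust extremes
  xs <- sort(x2[x2 > 0])
  init1 <- if (K == 1L) mean(xs) else
    pmax(vapply(split(xs, cut(seq_along(xs), K, labels = FALSE)), mean, 0),
         floor_mu + 1e-10)
  lo <- stats::quantile(xs, 0.05)
  hi <- stats::quantile(xs, 0.98)
  init2 <- pmax(exp(seq(log(lo), log(max(hi, lo * 2)), length.out = K)),
                floor_mu + 1e-10)
  fits <- lapply(list(init1, init2, sqrt(init1 * init2)), function(mu0)
    em_exp_mixture(x2, grp, K, mu0 = sort(mu0), floor_mu = floor_mu))
  best <- fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]

  if (method == "cdf-ls") best <- cdf_ls_refit(x2, grp, K, best, floor_mu)

  ord <- order(best$mu, decreasing = TRUE)
  D <- (best$mu[ord] - floor_mu) / (4 * t_lapse)
  D <- pmax(D, 0)
  f <- best$w[, ord, drop = FALSE]
  f <- f / rowSums(f)
  state_names <- if (K == 3L) c("FD", "NB", "TB") else paste0("S", seq_len(K))
  names(D) <- state_names
  dimnames(f) <- list(levels(group), state_names)
  dup <- K > 1L && any(D[-K] / pmax(D[-1], .Machine$double.eps) < 1.15)
  # duplicate components describe one state with an arbitrary weight split;
  # the merged view pools them (fraction-weighted D, summed fractions)
  merge_id <- seq_len(K)
  if (K > 1L) for (k in 2:K)
    if (D[k - 1] / max(D[k], .Machine$double.eps) < 1.15)
      merge_id[k] <- merge_id[k - 1]
  f_tot <- colSums(f)
  D_merged <- vapply(unique(merge_id), function(g)
    sum(D[merge_id == g] * f_tot[merge_id == g]) /
      sum(f_tot[merge_id == g]), numeric(1))
  f_merged <- t(apply(f, 1, function(fr)
    vapply(unique(merge_id), function(g) sum(fr[merge_id == g]),
           numeric(1))))
  if (length(unique(merge_id)) == 1L) f_merged <- matrix(rowSums(f))
  rownames(f_merged) <- levels(group)
  structure(list(D = D, f = f, loglik = best$loglik,
                 D_merged = D_merged, f_merged = f_merged,
                 n_per_group = stats::setNames(n_g, levels(group)),
                 duplicate_states = dup, converged = best$converged,
                 method = method, t_lapse = t_lapse, sigma_loc = sigma_loc),
            class = "diffusion_fit")
}

# least-squares on the empirical CDF of r^2 per group, started from the EM
# solution; cross-check mode only.
cdf_ls_refit <- function(x2, grp, K, em_fit, floor_mu) {
  G <- max(grp)
  par0 <- c(log(em_fit$mu - floor_mu + 1e-12),
            as.vector(log(pmax(em_fit$w[, -K, drop = FALSE], 1e-6) /
                            pmax(em_fit$w[, K], 1e-6))))
  split_x <- split(x2, grp)
  grids <- lapply(split_x, function(x) {
    xs <- sort(x)
    list(x = xs, F = seq_along(xs) / length(xs))
  })
  obj <- function(p) {
    mu <- exp(p[seq_len(K)]) + floor_mu
    a <- matrix(p[-seq_len(K)], G, K - 1)
    w <- cbind(exp(a), 1)
    w <- w / rowSums(w)
    s <- 0
    for (g in seq_len(G)) {
      Fm <- rowSums(vapply(seq_len(K),
                           function(k) w[g, k] * (1 - exp(-grids[[g]]$x / mu[k])),
                           numeric(length(grids[[g]]$x))))
      s <- s + mean((Fm - grids[[g]]$F)^2)
    }
    s
  }
  op <- stats::optim(par0, obj, method = "BFGS",
                     control = list(maxit = 300, reltol = 1e-10))
  mu <- exp(op$par[seq_len(K)]) + floor_mu
  a <- matrix(op$par[-seq_len(K)], G, K - 1)
  w <- cbind(exp(a), 1)
  w <- w / rowSums(w)
  list(mu = mu, w = w, loglik = em_fit$loglik, iterations = op$counts[1],
       converged = op$convergence == 0)
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("%d-state Brownian mixture (%s), logLik = %.2f\n",
              length(x$D), x$method, x$loglik))
  cat("D (um^2/s): ", paste(sprintf("%s = %.4g", names(x$D), x$D),
                            collapse = ", "), "\n")
  cat("fractions per group:\n")
  print(round(x$f, 4))
  if (x$duplicate_states)
    cat("note: two states have nearly identical D (possible over-fitting)\n")
  invisible(x)
}

#' Cell-level bootstrap standard deviations for a fit
#'
#' Resamples the sampling units (cells, by default) with replacement,
#' re-runs the fit on each replicate and reports per-parameter standard
#' deviations. The resampling unit is the cell, not the displacement,
#' because localizations within a cell are correlated.
#'
#' @param data A data.frame/data.table containing the observations.
#' @param fit_fun Function taking a resampled data subset and returning a
#'   named numeric vector of parameter estimates.
#' @param unit Column name identifying the resampling unit
#'   (default `"cell_id"`).
#' @param n_boot Number of bootstrap replicates (must be >= 1; fewer than 50
#'   triggers a warning).
#' @param seed Integer seed.
#' @return A list with `sd` (named numeric vector), `replicates` (matrix,
#'   one row per successful replicate) and `n_failed`.
#' @export
bootstrap_sd <- function(data, fit_fun, unit = "cell_id", n_boot = 200L,
                         seed = 1L) {
  if (n_boot < 1L) stop("n_boot must be >= 1", call. = FALSE)
  if (n_boot < 50L)
    warning("n_boot < 50 gives unreliable standard deviations",
            call. = FALSE)
  dt <- data.table::as.data.table(data)
  if (!unit %in% names(dt))
    stop("resampling unit column '", unit, "' not found", call. = FALSE)
  ids <- unique(dt[[unit]])
  if (length(ids) < 2L)
    stop("need at least 2 resampling units for the bootstrap", call. = FALSE)
  set.seed(seed)
  reps <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    take <- sample(ids, length(ids), replace = TRUE)
    # duplicated cells get distinct unit ids so downstream grouping treats
    # them as independent draws
    pieces <- lapply(seq_along(take), function(i) {
      d <- dt[dt[[unit]] == take[i]]
      data.table::set(d, j = unit, value = i)
      d
    })
    boot_data <- data.table::rbindlist(pieces)
    reps[[b]] <- tryCatch(fit_fun(boot_data), error = function(e) NULL)
  }
  ok <- !vapply(reps, is.null, TRUE)
  if (!any(ok)) stop("all bootstrap replicates failed", call. = FALSE)
  mat <- do.call(rbind, reps[ok])
  list(sd = apply(mat, 2, stats::sd), replicates = mat,
       n_failed = sum(!ok))
}
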