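#' Residence sites from thresholded trajectories
#'
#' One site per residence event: the same maximal sub-threshold runs as in
#' [extract_tau()], located at the mean of the run's localizations (a run of
#' `m` sub-threshold displacements spans `m + 1` localizations).
#'
#' @param tracks Track table (`cell_id`, `track_id`, `frame`, `x_um`,
#'   `y_um`).
#' @param r0 Displacement threshold (um).
#' @return `data.table` with one row per residence event: `cell_id`,
#'   `track_id`, `x_um`, `y_um`, `n_disp`.
#' @export
residence_sites <- function(tracks, r0) {
  stopifnot(r0 > 0)
  dt <- data.table::as.data.table(tracks)
  data.table::setorder(dt, cell_id, track_id, frame)
  empty <- data.table::data.table(cell_id = integer(), track_id = integer(),
                                  x_um = numeric(), y_um = numeric(),
                                  n_disp = integer())
  if (nrow(dt) == 0L) return(empty)
  out <- dt[, {
    if (.N < 2L) {
      list(x_um = numeric(), y_um = numeric(), n_disp = integer())
    } else {
      r <- sqrt(diff(x_um)^2 + diff(y_um)^2)
      rl <- rle(r < r0)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      below <- which(rl$values)
      if (length(below) == 0L) {
        list(x_um = numeric(), y_um = numeric(), n_disp = integer())
      } else {
        # displacements a..b involve localizations a..(b+1)
        list(x_um = vapply(below, function(j)
               mean(x_um[starts[j]:(ends[j] + 1L)]), numeric(1)),
             y_um = vapply(below, function(j)
               mean(y_um[starts[j]:(ends[j] + 1L)]), numeric(1)),
             n_disp = rl$lengths[below])
      }
    }
  }, by = c("cell_id", "track_id")]
  out[]
}

# all within-cell pairwise distances, pooled across cells (never across
# cells); cells with < 2 sites are skipped
site_pair_dists <- function(sites) {
  dt <- data.table::as.data.table(sites)
  if (nrow(dt) == 0L) return(numeric(0))
  unlist(lapply(split(dt, by = "cell_id"), function(d) {
    if (nrow(d) < 2L) return(numeric(0))
    as.numeric(stats::dist(cbind(d$x_um, d$y_um)))
  }), use.names = FALSE)
}

#' Normalized pair-wise distance distribution (PWDD) of residence sites
#'
#' Histogram of all within-cell pairwise distances, pooled across the cells
#' of a group and normalized to unit sum.
#'
#' @param sites Site table ([residence_sites()] or [random_reference()]).
#' @param bin_width Bin width in um (default 0.05).
#' @param max_dist Upper edge of the histogram (default: data maximum).
#' @return `data.table` with `bin_mid` (um) and `p` (probability per bin,
#'   summing to 1), plus attribute `n_pairs`.
#' @export
pwdd <- function(sites, bin_width = 0.05, max_dist = NULL) {
  d <- site_pair_dists(sites)
  if (length(d) < 1L)
    stop("need at least 2 sites in at least one cell", call. = FALSE)
  if (is.null(max_dist)) max_dist <- max(d)
  breaks <- seq(0, max_dist + bin_width, by = bin_width)
  h <- graphics::hist(d[d <= max(breaks)], breaks = breaks, plot = FALSE)
  out <- data.table::data.table(bin_mid = h$mids, p = h$counts / sum(h$counts))
  data.table::setattr(out, "n_pairs", length(d))
  out
}

#' Matched random-site reference in the cell geometry
#'
#' The spatial null for clustering: the same number of sites per cell as
#' observed, uniformly distributed in the same cell. The default draws
#' 3D-uniform points in the spherocylinder and projects to the imaging
#' (x, y) plane; `mode = "2d"` draws uniform points in the projected
#' footprint (the stadium shape) instead.
#'
#' @param cells Data.frame with `cell_id`, `length_um`, `radius_um`.
#' @param n_sites Named count per cell (names = cell_id) or a single count
#'   applied to every cell.
#' @param seed Integer seed.
#' @param mode `"3d"` (default, project) or `"2d"` (footprint-uniform).
#' @return `data.table` with `cell_id`, `x_um`, `y_um`.
#' @export
random_reference <- function(cells, n_sites, seed, mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  cells <- data.table::as.data.table(cells)
  stopifnot(all(c("cell_id", "length_um", "radius_um") %in% names(cells)))
  if (is.null(names(n_sites)) && length(n_sites) == 1L)
    n_sites <- stats::setNames(rep(n_sites, nrow(cells)),
                               as.character(cells$cell_id))
  set.seed(seed)
  pieces <- lapply(seq_len(nrow(cells)), function(i) {
    id <- cells$cell_id[i]
    n <- n_sites[[as.character(id)]]
    if (is.null(n) || is.na(n) || n == 0L)
      return(data.table::data.table(cell_id = id[0], x_um = numeric(),
                                    y_um = numeric()))
    geom <- cell_geometry(cells$length_um[i], cells$radius_um[i])
    if (mode == "3d") {
      pts <- sample_points(geom, n, seed = NULL)
      data.table::data.table(cell_id = id, x_um = pts[, 1], y_um = pts[, 2])
    } else {
      # rejection sampling in the 2D stadium footprint
      got <- matrix(numeric(0), 0, 2)
      while (nrow(got) < n) {
        m <- max(32L, 2L * (n - nrow(got)))
        x <- runif(m, -geom$total_length / 2, geom$total_length / 2)
        y <- runif(m, -geom$radius, geom$radius)
        keep <- in_cell(geom, x, y, 0)
        got <- rbind(got, cbind(x[keep], y[keep]))
      }
      data.table::data.table(cell_id = id, x_um = got[seq_len(n), 1],
                             y_um = got[seq_len(n), 2])
    }
  })
  data.table::rbindlist(pieces)
}

#' Fraction of site pairs (or sites) within a radius threshold
#'
#' Default (`type = "pairs"`): the fraction of within-cell pairwise
#' distances at or below `R`, pooled across cells. `type = "nn"`: the
#' fraction of sites whose within-cell nearest neighbour lies within `R`.
#'
#' @param sites Site table.
#' @param R Radius threshold(s) in um (vectorized).
#' @param type `"pairs"` (default) or `"nn"`.
#' @return Numeric vector of fractions (NA where no pairs exist).
#' @export
fraction_within <- function(sites, R, type = c("pairs", "nn")) {
  type <- match.arg(type)
  stopifnot(all(R > 0))
  if (type == "pairs") {
    d <- site_pair_dists(sites)
  } else {
    dt <- data.table::as.data.table(sites)
    d <- unlist(lapply(split(dt, by = "cell_id"), function(x) {
      if (nrow(x) < 2L) return(numeric(0))
      dm <- as.matrix(stats::dist(cbind(x$x_um, x$y_um)))
      diag(dm) <- Inf
      apply(dm, 1, min)
    }), use.names = FALSE)
  }
  if (length(d) == 0L) return(rep(NA_real_, length(R)))
  vapply(R, function(r) mean(d <= r), numeric(1))
}

#' Clustering ratio versus radius threshold
#'
#' For each concentration group, the ratio of the observed
#' [fraction_within()] to that of the matched random reference; the curve
#' reports the mean and s.d. of this ratio across groups at each `R`.
#' Values of `R` where the reference fraction is zero are undefined and
#' reported as `NA`. A flat curve at 1 is the uniform-null calibration; a
#' rise above 1 toward small `R` is the clustering signature.
#'
#' @param observed,reference Site tables; a `group` column splits them into
#'   concentration groups (absent = one group).
#' @param R_grid Radius thresholds in um.
#' @param type Passed to [fraction_within()].
#' @return `data.table` with `R`, `ratio_mean`, `ratio_sd`, `n_groups`.
#' @export
ratio_curve <- function(observed, reference, R_grid, type = "pairs") {
  obs <- data.table::as.data.table(observed)
  ref <- data.table::as.data.table(reference)
  if (!"group" %in% names(obs)) obs$group <- 1L
  if (!"group" %in% names(ref)) ref$group <- 1L
  groups <- sort(unique(obs$group))
  ratios <- vapply(groups, function(g) {
    fo <- fraction_within(obs[obs$group == g], R_grid, type)
    fr <- fraction_within(ref[ref$group == g], R_grid, type)
    r <- fo / fr
    r[!is.finite(r)] <- NA_real_
    r
  }, numeric(length(R_grid)))
  ratios <- matrix(ratios, nrow = length(R_grid))
  data.table::data.table(
    R = R_grid,
    ratio_mean = rowMeans(ratios, na.rm = TRUE),
    ratio_sd = apply(ratios, 1, stats::sd, na.rm = TRUE),
    n_groups = rowSums(!is.na(ratios))
  )
}

#' PWDD of observed versus reference sites with bootstrap bounds
#'
#' Shared-bin PWDDs for observed and reference sites, their difference, and
#' 95% cell-level bootstrap confidence bounds on the difference.
#'
#' @param observed,reference Site tables.
#' @param bin_width Bin width (um).
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Seed.
#' @return `data.table` with `bin_mid`, `observed`, `reference`,
#'   `difference`, `lo95`, `hi95`.
#' @export
pwdd_compare <- function(observed, reference, bin_width = 0.05,
                         n_boot = 200L, seed = 1L) {
  d_obs <- site_pair_dists(observed)
  d_ref <- site_pair_dists(reference)
  max_d <- max(c(d_obs, d_ref))
  breaks <- seq(0, max_d + bin_width, by = bin_width)
  hist_p <- function(d) {
    h <- graphics::hist(d, breaks = breaks, plot = FALSE)
    h$counts / sum(h$counts)
  }
  p_obs <- hist_p(d_obs)
  p_ref <- hist_p(d_ref)
  obs <- data.table::as.data.table(observed)
  ids <- unique(obs$cell_id)
  set.seed(seed)
  diffs <- matrix(NA_real_, n_boot, length(p_obs))
  for (b in seq_len(n_boot)) {
    take <- sample(ids, length(ids), replace = TRUE)
    d_b <- unlist(lapply(seq_along(take), function(i) {
      d <- obs[obs$cell_id == take[i]]
      if (nrow(d) < 2L) return(numeric(0))
      as.numeric(stats::dist(cbind(d$x_um, d$y_um)))
    }), use.names = FALSE)
    if (length(d_b) > 0L) diffs[b, ] <- hist_p(d_b) - p_ref
  }
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  data.table::data.table(
    bin_mid = mids, observed = p_obs, reference = p_ref,
    difference = p_obs - p_ref,
    lo95 = apply(diffs, 2, stats::quantile, 0.025, na.rm = TRUE),
    hi95 = apply(diffs, 2, stats::quantile, 0.975, na.rm = TRUE)
  )
}
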