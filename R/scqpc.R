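AVOGADRO <- 6.02214076e23

#' Per-cell protein concentration from tracking and residual fluorescence
#'
#' Converts the number of molecules tracked during SMT plus the residual
#' photoconverted fluorescence (everything that had not yet been
#' photoconverted and tracked) into the total dimer concentration of the
#' cell: monomer count
#' `N = (n_tracked + residual / f_single) / eta_pc`, dimers `N / 2`, and
#' concentration `N/2 / (N_A * V)`. With the default `eta_pc = 1` and a
#' typical 1.66 fL cell, one dimer corresponds to ~1 nM.
#'
#' @param n_tracked Molecules tracked during SMT (count).
#' @param residual Residual photoconverted fluorescence (a.u.).
#' @param f_single Mean fluorescence of a single fluorophore (a.u., > 0),
#'   measured from the SMT spots.
#' @param volume_fL Cell volume in fL (from [cell_volume()]).
#' @param eta_pc Photoconversion efficiency in (0, 1]; default 1.
#' @param monomers_per_dimer Tagged monomers per counted unit (default 2 for
#'   a homodimer with one tag per monomer).
#' @return Dimer concentration in nM (vectorized).
#' @export
cell_concentration <- function(n_tracked, residual, f_single, volume_fL,
                               eta_pc = 1, monomers_per_dimer = 2) {
  if (any(f_single <= 0)) stop("f_single must be > 0", call. = FALSE)
  if (any(eta_pc <= 0 | eta_pc > 1))
    stop("eta_pc must be in (0, 1]", call. = FALSE)
  if (any(volume_fL <= 0)) stop("cell volume must be > 0", call. = FALSE)
  if (any(n_tracked < 0) || any(residual < 0))
    stop("counts and fluorescence must be >= 0", call. = FALSE)
  monomers <- (n_tracked + residual / f_single) / eta_pc
  dimers <- monomers / monomers_per_dimer
  # nM = mol / L * 1e9 ; V[L] = volume_fL * 1e-15
  dimers / (AVOGADRO * volume_fL * 1e-15) * 1e9
}

#' Quantify concentrations for a table of cell records
#'
#' Applies the spherocylinder volume model and [cell_concentration()] to a
#' per-cell table, appending `volume_fL` and `concentration_nM`.
#'
#' @param cells Data.frame with columns `cell_id`, `length_um`, `radius_um`,
#'   `n_tracked`, `residual_fluorescence`.
#' @param f_single Single-fluorophore intensity (a.u.).
#' @param eta_pc Photoconversion efficiency.
#' @return The input as a `data.table` with the two appended columns.
#' @export
quantify_cells <- function(cells, f_single, eta_pc = 1) {
  need <- c("cell_id", "length_um", "radius_um", "n_tracked",
            "residual_fluorescence")
  if (!all(need %in% names(cells)))
    stop("cells need columns: ", paste(need, collapse = ", "), call. = FALSE)
  dt <- data.table::as.data.table(cells)
  dt[, volume_fL := mapply(function(L, r) cell_volume(cell_geometry(L, r)),
                           length_um, radius_um)]
  dt[, concentration_nM := cell_concentration(
    n_tracked, residual_fluorescence, f_single, volume_fL, eta_pc)]
  dt[]
}

#' Sort cells into equal-count concentration groups
#'
#' Cells are sorted by concentration (stable, so ties keep input order) and
#' split into `n_groups` bins of as-equal-as-possible size; each group
#' reports its mean and s.d. concentration, which labels the group on
#' concentration-dependence plots.
#'
#' @param cells Data.frame with `cell_id` and `concentration_nM` (e.g. from
#'   [quantify_cells()]).
#' @param n_groups Number of groups (1 <= n_groups <= number of cells).
#' @return List with `cells` (input plus integer `group`, ordered by
#'   concentration) and `summary` (`group`, `n_cells`, `mean_nM`, `sd_nM`).
#' @export
group_cells <- function(cells, n_groups) {
  dt <- data.table::as.data.table(cells)
  if (!"concentration_nM" %in% names(dt))
    stop("cells need a concentration_nM column", call. = FALSE)
  n <- nrow(dt)
  if (n_groups < 1L || n_groups > n)
    stop("need 1 <= n_groups <= number of cells", call. = FALSE)
  ord <- order(dt$concentration_nM)  # stable
  dt <- dt[ord]
  dt[, group := ceiling(seq_len(n) * n_groups / n)]
  summ <- dt[, list(n_cells = .N,
                    mean_nM = mean(concentration_nM),
                    sd_nM = ifelse(.N > 1, stats::sd(concentration_nM), 0)),
             by = "group"]
  list(cells = dt[], summary = summ[])
}
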