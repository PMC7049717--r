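# shared forward generators used as independent oracles; these sample from
# the closed-form distributions directly and never call the fitting code

# displacement lengths from a K-component 2D Brownian mixture
gen_mixture_r <- function(n, D, f, t_lapse, sigma_loc = 0, seed = NULL,
                          cell_ids = NULL) {
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(length(D), n, replace = TRUE, prob = f)
  r <- sqrt(stats::rexp(n, rate = 1 / (4 * D[comp] * t_lapse +
                                         4 * sigma_loc^2)))
  if (is.null(cell_ids)) r else data.frame(cell_id = cell_ids, r_um = r)
}

# residence events from the per-frame competing-risk process: each frame the
# run continues w.p. s*b, ends with an observed crossing w.p. (1-s)*b, or is
# censored by bleaching w.p. (1-b), with s = exp(-k t) and b = exp(-kb t)
gen_dwell <- function(n, k_minus1, k_bleach, t_lapse, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- exp(-k_minus1 * t_lapse)
  b <- exp(-k_bleach * t_lapse)
  cont <- s * b
  m <- stats::rgeom(n, 1 - cont) + 1L
  p_cens <- (1 - b) / (1 - cont)
  cens <- stats::runif(n) < p_cens
  data.frame(tau = m * t_lapse, censored = cens)
}

# uniform table of identical spherocylindrical cells
make_cells <- function(n, length_um = 3, radius_um = 0.5) {
  data.frame(cell_id = seq_len(n), length_um = length_um,
             radius_um = radius_um)
}

# clustered 2D sites: n_clusters Gaussian clusters (sd sigma) per cell
gen_clustered_sites <- function(cell_ids, n_sites, n_clusters = 5,
                                sigma = 0.03, length_um = 3,
                                radius_um = 0.5, seed = 1) {
  set.seed(seed)
  g <- cell_geometry(length_um, radius_um)
  data.table::rbindlist(lapply(cell_ids, function(cid) {
    ctr <- sample_points(g, n_clusters, seed = NULL)
    j <- sample.int(n_clusters, n_sites, replace = TRUE)
    data.table::data.table(cell_id = cid,
                           x_um = ctr[j, 1] + stats::rnorm(n_sites, 0, sigma),
                           y_um = ctr[j, 2] + stats::rnorm(n_sites, 0, sigma))
  }))
}

# reference three-state parameter set (repressor-form in-vivo regime):
# effective D's in um^2/s and fractional populations
three_state_D <- c(6.7, 0.82, 0.033)
three_state_f <- c(0.181, 0.472, 0.347)
t_lapse_default <- 0.04
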