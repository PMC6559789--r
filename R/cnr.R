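#' Contrast-to-noise scenario for beam-energy selection
#'
#' The classic circular-phantom model: a small contrasting detail (the stain,
#' e.g. tungsten from PTA at concentration `rho_c`) of path length `d_c` sits
#' at the centre of an absorbing background (soft tissue / water) of path
#' length `d_bg`. The linear attenuation of the background is
#' `mu1(E) = mu_bg(E)`; with the detail present it is
#' `mu2(E) = mu_bg(E) + mu_c(E)` where `mu_c(E) = rho_c * (mu/rho)_c(E)`.
#' The reconstruction noise variance at the centre is inversely proportional
#' to the transmitted intensity, `var{mu_i(E)} = k / I_i(E)`; the
#' proportionality constant `k` is arbitrary, so all derived CNR values are
#' RELATIVE and meaningful only for comparisons across energy or geometry.
#'
#' @param background an [attenuation_table()] for the background material
#'   (used with its own density).
#' @param d_bg_cm background path length, cm.
#' @param detail an [attenuation_table()] for the contrast element.
#' @param d_c_cm detail path length, cm (`d_bg_cm >= d_c_cm >= 0`).
#' @param rho_c stain concentration, g/cm^3 (>= 0); scales the detail's
#'   mass-attenuation coefficient in place of its bulk density.
#' @param I0 incident intensity: a positive scalar or a function of energy
#'   (keV) returning photons.
#' @param k variance proportionality constant (dimensionless, default 1).
#' @return object of class `cnr_scenario`.
#' @export
cnr_scenario <- function(background, d_bg_cm, detail, d_c_cm, rho_c,
                         I0 = 1, k = 1) {
  stopifnot(inherits(background, "attenuation_table"),
            inherits(detail, "attenuation_table"))
  if (!(d_bg_cm >= d_c_cm && d_c_cm >= 0))
    stop("need d_bg_cm >= d_c_cm >= 0")
  if (rho_c < 0) stop("rho_c must be >= 0")
  if (is.numeric(I0) && I0 <= 0) stop("I0 must be positive")
  if (k <= 0) stop("k must be positive")
  structure(list(background = background, d_bg_cm = d_bg_cm, detail = detail,
                 d_c_cm = d_c_cm, rho_c = rho_c, I0 = I0, k = k),
            class = "cnr_scenario")
}

incident_intensity <- function(s, E_keV) {
  if (is.function(s$I0)) vapply(E_keV, s$I0, numeric(1))
  else rep(s$I0, length(E_keV))
}

#' Transmitted intensity through the scenario
#'
#' Beer-Lambert transmission: `I1 = I0 exp(-mu_bg d_bg)` without the detail
#' and `I2 = I0 exp(-(mu_bg d_bg + mu_c d_c))` with it.
#'
#' @param s a [cnr_scenario()].
#' @param E_keV energy (keV), within both tables' range.
#' @param with_detail include the contrast detail in the path.
#' @return transmitted intensity (photons), `0 < I <= I0`.
#' @export
transmitted_intensity <- function(s, E_keV, with_detail = FALSE) {
  stopifnot(inherits(s, "cnr_scenario"))
  mu_bg <- linear_attenuation(s$background, E_keV)
  expo <- mu_bg * s$d_bg_cm
  if (with_detail) {
    mu_c <- linear_attenuation(s$detail, E_keV, density = s$rho_c)
    expo <- expo + mu_c * s$d_c_cm
  }
  incident_intensity(s, E_keV) * exp(-expo)
}

#' Reconstruction noise variance at the image centre
#'
#' `var = k / I` with `I` the transmitted intensity: strictly decreasing in
#' the transmitted flux, so the variance with the detail present is never
#' smaller than without it.
#'
#' @inheritParams transmitted_intensity
#' @return noise variance (arbitrary units set by `k`).
#' @export
reconstruction_variance <- function(s, E_keV, with_detail = FALSE) {
  I <- transmitted_intensity(s, E_keV, with_detail)
  if (any(I <= 0) || any(!is.finite(s$k / I)))
    stop("transmitted intensity underflowed to zero; variance undefined")
  s$k / I
}

#' Relative contrast-to-noise ratio at an energy
#'
#' `CNR(E) = |mu1 - mu2| / sqrt(var1 + var2) = mu_c / sqrt(var1 + var2)`.
#' Because the variance constant `k` is arbitrary the value is relative: it
#' supports comparisons across energies and geometries, not absolute
#' photon-count predictions.
#'
#' @inheritParams transmitted_intensity
#' @return relative CNR (dimensionless), vectorised over `E_keV`.
#' @export
cnr <- function(s, E_keV) {
  stopifnot(inherits(s, "cnr_scenario"))
  mu_c <- linear_attenuation(s$detail, E_keV, density = s$rho_c)
  v1 <- reconstruction_variance(s, E_keV, with_detail = FALSE)
  v2 <- reconstruction_variance(s, E_keV, with_detail = TRUE)
  mu_c / sqrt(v1 + v2)
}

#' CNR curve over an energy grid, with the optimal energy
#'
#' Evaluates [cnr()] pointwise over `E_grid` (sorted ascending; a duplicated
#' edge energy evaluates on the post-edge branch) and reports the argmax,
#' breaking ties towards the smallest energy. On tables with absorption
#' edges the curve is discontinuous exactly at the tabulated edge energies.
#'
#' @param s a [cnr_scenario()].
#' @param E_grid numeric vector of energies (keV) within table range.
#' @return data.frame with columns `E_keV`, `cnr`; attributes `E_opt` and
#'   `cnr_opt` hold the maximising energy and value.
#' @export
cnr_curve <- function(s, E_grid) {
  if (length(E_grid) == 0) stop("empty energy grid")
  E_grid <- sort(as.numeric(E_grid))
  val <- cnr(s, E_grid)
  out <- data.frame(E_keV = E_grid, cnr = val)
  i <- which.max(val)            # first max = smallest-E tie-break
  attr(out, "E_opt") <- E_grid[i]
  attr(out, "cnr_opt") <- val[i]
  out
}

#' Default energy grid over a table's range, refined at absorption edges
#'
#' @param table an [attenuation_table()].
#' @param by grid spacing, keV.
#' @param eps half-width of the extra pre/post edge samples, keV.
#' @return sorted energies including each edge energy and a sample just
#'   below it.
#' @export
energy_grid <- function(table, by = 0.05, eps = 1e-6) {
  stopifnot(inherits(table, "attenuation_table"))
  E <- table$E_keV
  edges <- unique(E[duplicated(E)])
  sort(unique(c(seq(min(E), max(E), by = by), max(E), edges, edges - eps)))
}

#' Throughput parameters for a screening campaign
#'
#' @param setup_min set-up minutes charged once per multiplexed batch.
#' @param scans_per_fish segmental acquisitions per specimen.
#' @param scan_min minutes per acquisition.
#' @param multiplex specimens mounted and scanned together per batch.
#' @param replicates biological replicates per condition.
#' @param conditions number of screened conditions (e.g. mutants).
#' @param scan_days_per_year beamline availability, days/year.
#' @param hours_per_day scanning hours per scanning day.
#' @return object of class `throughput_params`.
#' @export
throughput_params <- function(setup_min = 5, scans_per_fish = 3, scan_min = 20,
                              multiplex = 5, replicates = 10,
                              conditions = 20000, scan_days_per_year = 100,
                              hours_per_day = 10) {
  p <- list(setup_min = setup_min, scans_per_fish = scans_per_fish,
            scan_min = scan_min, multiplex = multiplex,
            replicates = replicates, conditions = conditions,
            scan_days_per_year = scan_days_per_year,
            hours_per_day = hours_per_day)
  if (any(unlist(p) <= 0)) stop("all throughput parameters must be positive")
  structure(p, class = "throughput_params")
}

#' Estimated beamline years for a screening campaign
#'
#' `specimens = conditions x replicates`; specimens are scanned in
#' `ceiling(specimens / multiplex)` batches, each charged one set-up period
#' plus `scans_per_fish x scan_min` of acquisition (multiplexing does not
#' lengthen a scan). Total time is converted to years of beamline
#' availability. Set-up is charged per batch, not per specimen within a
#' batch; both choices are defensible and all assumptions are parameters.
#'
#' @param p a [throughput_params()].
#' @return list with `specimens`, `batches`, `total_hours` and `years`.
#' @export
estimate_throughput <- function(p) {
  stopifnot(inherits(p, "throughput_params"))
  specimens <- p$conditions * p$replicates
  batches <- ceiling(specimens / p$multiplex)
  minutes <- batches * (p$setup_min + p$scans_per_fish * p$scan_min)
  hours <- minutes / 60
  list(specimens = specimens, batches = batches, total_hours = hours,
       years = hours / (p$scan_days_per_year * p$hours_per_day))
}
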