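#' Tabulated mass-attenuation coefficients for a material
#'
#' Rows of `(E keV, mu/rho cm^2/g)` with strictly non-decreasing energy.
#' An absorption edge is represented by a duplicated energy: the earlier row
#' holds the pre-edge (below-edge) value and the later row the post-edge
#' value, exactly as in standard photon cross-section tabulations.
#'
#' @param material material name.
#' @param density bulk density rho in g/cm^3.
#' @param E_keV photon energies, keV, non-decreasing; at most two rows may
#'   share an energy (an edge).
#' @param mu_over_rho mass-attenuation coefficients, cm^2/g, all positive.
#' @return object of class `attenuation_table`.
#' @export
attenuation_table <- function(material, density, E_keV, mu_over_rho) {
  E_keV <- as.numeric(E_keV); mu_over_rho <- as.numeric(mu_over_rho)
  if (length(E_keV) != length(mu_over_rho) || length(E_keV) < 2L)
    stop("need matching E and mu/rho vectors with at least 2 rows")
  if (any(diff(E_keV) < 0)) stop("energies must be non-decreasing")
  if (any(mu_over_rho <= 0)) stop("mu/rho must be positive")
  if (any(table(E_keV) > 2)) stop("an energy may appear at most twice (edge)")
  if (density <= 0) stop("density must be positive")
  structure(list(material = material, density = density,
                 E_keV = E_keV, mu_over_rho = mu_over_rho),
            class = "attenuation_table")
}

#' @export
print.attenuation_table <- function(x, ...) {
  ed <- unique(x$E_keV[duplicated(x$E_keV)])
  cat(sprintf("<attenuation_table> %s (rho = %g g/cm^3), %d rows, %.4g-%.4g keV",
              x$material, x$density, length(x$E_keV), min(x$E_keV), max(x$E_keV)))
  if (length(ed)) cat(", edges at", paste(signif(ed, 6), collapse = ", "), "keV")
  cat("\n")
  invisible(x)
}

#' Read an attenuation table from CSV
#'
#' Expects columns `E_keV` and `mu_over_rho_cm2_g`.
#' @param file CSV path.
#' @param material material name.
#' @param density g/cm^3.
#' @return an [attenuation_table()].
#' @export
read_attenuation_table <- function(file, material, density) {
  d <- read.csv(file)
  attenuation_table(material, density, d$E_keV, d$mu_over_rho_cm2_g)
}

#' Bundled attenuation tables (water background, tungsten stain)
#'
#' Desk-scale mass-attenuation tables spanning 8-30 keV condensed from
#' standard reference tabulations of photon cross sections: liquid water
#' (soft-tissue surrogate, rho = 1 g/cm^3) and tungsten, whose L3
#' (10.2068 keV) and L1 (12.0998 keV) absorption edges (and the L2 edge at
#' 11.544 keV) appear as duplicated-energy rows. Tungsten is the attenuating
#' element of the PTA (phosphotungstic acid) stain.
#'
#' @param material `"water"` or `"tungsten"`.
#' @return an [attenuation_table()].
#' @export
zf_attenuation <- function(material = c("water", "tungsten")) {
  material <- match.arg(material)
  f <- system.file("extdata",
                   if (material == "water") "mu_water.csv" else "mu_tungsten.csv",
                   package = "histotomo", mustWork = TRUE)
  read_attenuation_table(f, material,
                         density = if (material == "water") 1.0 else 19.3)
}

#' Linear attenuation coefficient at an energy
#'
#' `mu(E) = rho * interp(mu/rho, E)` with log-log interpolation between
#' tabulated samples (the standard convention for photon cross sections).
#' At a duplicated-energy absorption edge, querying the edge energy itself
#' returns the post-edge value while energies approaching from below follow
#' the pre-edge branch. Energies outside the tabulated range raise an error;
#' no extrapolation is performed.
#'
#' @param table an [attenuation_table()].
#' @param E_keV energy or energies, keV.
#' @param density override the table's density (g/cm^3), e.g. to use a
#'   stain's concentration rather than the element's bulk density.
#' @return linear attenuation coefficient(s), 1/cm.
#' @export
linear_attenuation <- function(table, E_keV, density = table$density) {
  stopifnot(inherits(table, "attenuation_table"))
  Ev <- table$E_keV; mu <- table$mu_over_rho
  if (any(E_keV < Ev[1] | E_keV > Ev[length(Ev)]))
    stop("energy out of tabulated range [", Ev[1], ", ", Ev[length(Ev)],
         "] keV; no extrapolation")
  vapply(E_keV, function(e) {
    hit <- which(Ev == e)
    if (length(hit)) return(density * mu[hit[length(hit)]])  # post-edge at edge
    i <- findInterval(e, Ev)       # last row with Ev <= e (post-edge side)
    lo <- i; hi <- i + 1L          # hi is the first (pre-edge) row above
    w <- (log(e) - log(Ev[lo])) / (log(Ev[hi]) - log(Ev[lo]))
    density * exp((1 - w) * log(mu[lo]) + w * log(mu[hi]))
  }, numeric(1))
}
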