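#' Förster rate-law parameters
#'
#' Parameters of the point-dipole Förster rate
#' \eqn{k_{FRET} = C \kappa^2 / (n^4 r^6)} between two chlorophylls, with
#' \eqn{r} the Mg–Mg distance. With the default nanometre convention
#' (`distance_unit = "nm"`, i.e. \eqn{r = R[\text{Å}]/10}) and
#' \eqn{C = 32.26}, \eqn{n = 1.55}, the rate comes out in \eqn{ps^{-1}}
#' for chlorophyll a -> chlorophyll a transfer. `C` absorbs the
#' donor–acceptor spectral overlap and is treated as an opaque constant;
#' supply a different value for other pigment pairings.
#'
#' @param C overlap-integral factor; default 32.26 (Chl a -> Chl a).
#' @param n refractive index of the protein medium; default 1.55.
#' @param cutoff Mg–Mg pair cutoff in Å (strict `<`); default 30.
#' @param distance_unit unit in which the Mg–Mg distance enters the
#'   \eqn{r^6} denominator: `"nm"` (default) or `"angstrom"`. Only the nm
#'   convention yields physically admissible orientation factors with the
#'   default `C` (see the package vignette).
#' @return object of class `fret_params`.
#' @export
fret_params <- function(C = 32.26, n = 1.55, cutoff = 30,
                        distance_unit = c("nm", "angstrom")) {
  assert_scalar_number(C, "C", positive = TRUE)
  assert_scalar_number(n, "n")
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  assert_scalar_number(cutoff, "cutoff", positive = TRUE)
  structure(
    list(C = C, n = n, cutoff = cutoff,
         distance_unit = match.arg(distance_unit)),
    class = "fret_params"
  )
}

#' @export
print.fret_params <- function(x, ...) {
  cat(sprintf("<fret_params> C=%g n=%g cutoff=%g A (unit: %s)\n",
              x$C, x$n, x$cutoff, x$distance_unit))
  invisible(x)
}

#' Qy transition dipole of a chlorophyll site
#'
#' The Qy transition dipole is approximated by the NB -> ND ring-nitrogen
#' axis, anchored at the central Mg. The direction is the unit vector from
#' the NB atom to the ND atom; the sign choice is immaterial downstream
#' because the orientation factor is quadratic in each dipole.
#'
#' @param site a chlorophyll `pigment_site` carrying Mg, NB and ND atoms.
#' @return object of class `transition_dipole`: list with `site_id`,
#'   `origin` (Mg position, Å) and `direction` (unit 3-vector).
#' @export
qy_dipole <- function(site) {
  stopifnot(inherits(site, "pigment_site"))
  if (!site$kind %in% CHL_KINDS)
    stop("ligand-geometry error: site ", site$site_id,
         " is not a chlorophyll", call. = FALSE)
  a <- site$atoms
  nb <- which(a$name == "NB")[1L]
  nd <- which(a$name == "ND")[1L]
  if (is.null(site$mg_position) || is.na(nb) || is.na(nd))
    stop("ligand-geometry error: site ", site$site_id,
         " lacks Mg/NB/ND atoms", call. = FALSE)
  structure(
    list(
      site_id = site$site_id,
      origin = site$mg_position,
      direction = unit_vector(as.numeric(a[nd, c("x", "y", "z")]) -
                              as.numeric(a[nb, c("x", "y", "z")]))
    ),
    class = "transition_dipole"
  )
}

#' Dipole orientation factor kappa-squared
#'
#' Standard Förster orientation factor
#' \eqn{\kappa = \hat u_D \cdot \hat u_A -
#'   3 (\hat u_D \cdot \hat R)(\hat u_A \cdot \hat R)},
#' with \eqn{\hat R} the unit vector from donor Mg to acceptor Mg. Returns
#' \eqn{\kappa^2 \in [0, 4]}; invariant under flipping the sign of either
#' dipole and under swapping donor and acceptor.
#'
#' @param d_donor,d_acceptor `transition_dipole` objects with distinct
#'   origins.
#' @return \eqn{\kappa^2}, dimensionless.
#' @export
orientation_factor <- function(d_donor, d_acceptor) {
  r <- d_acceptor$origin - d_donor$origin
  if (vnorm(r) < 1e-9)
    stop("geometry error: coincident dipole origins", call. = FALSE)
  rhat <- r / vnorm(r)
  ud <- d_donor$direction
  ua <- d_acceptor$direction
  kappa <- sum(ud * ua) - 3 * sum(ud * rhat) * sum(ua * rhat)
  kappa^2
}

#' Förster transfer rate between two chlorophyll dipoles
#'
#' Evaluates \eqn{k = C \kappa^2 / (n^4 r^6)} from the two dipoles and the
#' Mg–Mg distance. Symmetric under donor/acceptor exchange (for a single
#' `C`).
#'
#' @inheritParams orientation_factor
#' @param params a [fret_params()] object.
#' @return rate in \eqn{ps^{-1}} (for the default parameterisation).
#' @examples
#' d1 <- structure(list(site_id = "d", origin = c(0, 0, 0),
#'                      direction = c(0, 0, 1)), class = "transition_dipole")
#' d2 <- structure(list(site_id = "a", origin = c(10, 0, 0),
#'                      direction = c(0, 0, 1)), class = "transition_dipole")
#' fret_rate(d1, d2)  # 32.26 / 1.55^4 ~= 5.589 ps^-1
#' @export
fret_rate <- function(d_donor, d_acceptor, params = fret_params()) {
  R <- vnorm(d_acceptor$origin - d_donor$origin)
  if (R < 1e-9)
    stop("geometry error: zero Mg-Mg distance", call. = FALSE)
  k2 <- orientation_factor(d_donor, d_acceptor)
  r <- if (params$distance_unit == "nm") R / 10 else R
  params$C * k2 / (params$n^4 * r^6)
}
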