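# Parametric vibronic lineshapes over wavenumber, mirror-image emission, and
# donor-emission / acceptor-absorption overlap integrals.
#
# A lineshape is a sum of Gaussian vibronic components, each an offset
# (>= 0, cm^-1) from the 0-0 energy e00, a relative weight and a width sigma.
# Absorption components sit at e00 + offset, emission components at
# e00 - offset. Evaluated profiles are normalized to unit trapezoidal area,
# so values have units of cm (density per cm^-1).

#' Construct a vibronic lineshape
#'
#' @param kind `"ABSORPTION"` or `"EMISSION"`.
#' @param e00 0-0 transition energy, cm^-1.
#' @param components Data.frame with columns `offset` (cm^-1, >= 0 from
#'   `e00`), `weight` (> 0) and `sigma` (cm^-1, > 0), one row per Gaussian
#'   vibronic term. Default: a single component at the 0-0 energy with
#'   `sigma = 100`.
#' @param grid Length-3 numeric `c(min, max, step)` evaluation window in
#'   cm^-1; `NULL` auto-spans every component center +/- 6 sigma at 1 cm^-1
#'   steps.
#' @return Object of class `lineshape`.
#' @export
lineshape <- function(kind = c("ABSORPTION", "EMISSION"), e00,
                      components = data.frame(offset = 0, weight = 1,
                                              sigma = 100),
                      grid = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(e00), length(e00) == 1, e00 > 0)
  stopifnot(all(c("offset", "weight", "sigma") %in% names(components)))
  if (any(components$offset < 0)) stop("component offsets must be >= 0")
  if (any(components$weight <= 0)) stop("component weights must be > 0")
  if (any(components$sigma <= 0)) stop("component widths must be > 0")
  centers <- if (kind == "ABSORPTION") e00 + components$offset
             else e00 - components$offset
  if (is.null(grid)) {
    lo <- floor(min(centers - 6 * components$sigma))
    hi <- ceiling(max(centers + 6 * components$sigma))
    grid <- c(lo, hi, 1)
  }
  stopifnot(length(grid) == 3, grid[1] < grid[2], grid[3] > 0)
  need_lo <- centers - 5 * components$sigma
  need_hi <- centers + 5 * components$sigma
  if (grid[1] > min(need_lo) || grid[2] < max(need_hi))
    stop(sprintf(paste0("grid [%g, %g] too narrow: must span +/- 5 sigma of ",
                        "every component, i.e. at least [%g, %g] cm^-1"),
                 grid[1], grid[2], min(need_lo), max(need_hi)))
  structure(list(kind = kind, e00 = e00, components = components,
                 grid = grid),
            class = "lineshape")
}

# Unnormalized Gaussian mixture of `shape` at wavenumbers nu.
.lineshape_raw <- function(shape, nu) {
  sgn <- if (shape$kind == "ABSORPTION") 1 else -1
  out <- numeric(length(nu))
  for (k in seq_len(nrow(shape$components))) {
    cm <- shape$components[k, ]
    out <- out + cm$weight * stats::dnorm(nu, shape$e00 + sgn * cm$offset,
                                          cm$sigma)
  }
  out
}

.lineshape_nu <- function(shape) seq(shape$grid[1], shape$grid[2],
                                     by = shape$grid[3])

# Trapezoidal integral of y over x.
.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Evaluate a lineshape on its wavenumber grid
#'
#' @param shape A [lineshape()].
#' @return List with `nu` (cm^-1 grid) and `density` (cm; non-negative,
#'   trapezoidal area 1 within 1e-6).
#' @export
evaluate <- function(shape) {
  stopifnot(inherits(shape, "lineshape"))
  nu <- .lineshape_nu(shape)
  y <- .lineshape_raw(shape, nu)
  area <- .trapz(nu, y)
  if (area <= 0) stop("lineshape has zero area on its grid")
  list(nu = nu, density = y / area)
}

#' Mirror-image emission from an absorption lineshape
#'
#' Keeps the 0-0 energy, component offsets and widths, flips the kind to
#' EMISSION so every vibronic component is reflected about the 0-0 line, and
#' renormalizes. This is the standard mirror-image construction used when an
#' emission (or absorption) profile is unavailable.
#'
#' @param absorption A `lineshape` of kind ABSORPTION.
#' @return A `lineshape` of kind EMISSION.
#' @export
mirror_emission <- function(absorption) {
  stopifnot(inherits(absorption, "lineshape"))
  if (absorption$kind != "ABSORPTION")
    stop("mirror_emission expects an ABSORPTION lineshape, got ",
         absorption$kind)
  centers <- absorption$e00 - absorption$components$offset
  lo <- floor(min(centers - 6 * absorption$components$sigma))
  hi <- ceiling(max(centers + 6 * absorption$components$sigma))
  lineshape("EMISSION", absorption$e00, absorption$components,
            grid = c(lo, hi, absorption$grid[3]))
}

#' Spectral overlap integral of donor emission and acceptor absorption
#'
#' J = integral of f_D(nu) a_A(nu) d nu over the common grid, by the
#' trapezoidal rule, with both profiles normalized to unit area on their own
#' grids. Units: cm (both densities are per cm^-1).
#'
#' @param donor_emission `lineshape` of kind EMISSION.
#' @param acceptor_absorption `lineshape` of kind ABSORPTION.
#' @return Overlap integral J >= 0, cm.
#' @export
spectral_overlap <- function(donor_emission, acceptor_absorption) {
  stopifnot(inherits(donor_emission, "lineshape"),
            inherits(acceptor_absorption, "lineshape"))
  if (donor_emission$kind != "EMISSION")
    stop("donor lineshape must be EMISSION, got ", donor_emission$kind)
  if (acceptor_absorption$kind != "ABSORPTION")
    stop("acceptor lineshape must be ABSORPTION, got ",
         acceptor_absorption$kind)
  lo <- max(donor_emission$grid[1], acceptor_absorption$grid[1])
  hi <- min(donor_emission$grid[2], acceptor_absorption$grid[2])
  if (lo >= hi)
    stop("disjoint grids: donor emission spans [", donor_emission$grid[1],
         ", ", donor_emission$grid[2], "] and acceptor absorption [",
         acceptor_absorption$grid[1], ", ", acceptor_absorption$grid[2],
         "] cm^-1")
  step <- min(donor_emission$grid[3], acceptor_absorption$grid[3])
  nu <- seq(lo, hi, by = step)
  fd <- .lineshape_raw(donor_emission, nu) /
    .trapz(.lineshape_nu(donor_emission),
           .lineshape_raw(donor_emission, .lineshape_nu(donor_emission)))
  aa <- .lineshape_raw(acceptor_absorption, nu) /
    .trapz(.lineshape_nu(acceptor_absorption),
           .lineshape_raw(acceptor_absorption,
                          .lineshape_nu(acceptor_absorption)))
  .trapz(nu, fd * aa)
}

#' Default lineshape library
#'
#' Absorption templates (0-0 energy set per pigment at rate-matrix build
#' time):
#' \describe{
#'   \item{pcb}{Bilin absorption: 0-0 band plus one vibronic satellite at
#'     +1300 cm^-1 (weights 1.0/0.5), sigma 500 cm^-1.}
#'   \item{can_s1}{Surrogate carotenoid S0->S1 band: 0-0 plus two vibronic
#'     satellites at +1400 and +2800 cm^-1 (weights 1.0/0.7/0.3), sigma
#'     600 cm^-1. A parametric stand-in for the empirical keto-carotenoid
#'     emission shape used in the source models, which is not tabulated
#'     anywhere accessible; see the vignette.}
#' }
#' Each entry is a list of component data.frames; realize one with
#' [realize_lineshape()].
#'
#' @return Named list of component tables.
#' @export
default_lineshape_library <- function() {
  list(
    pcb = data.frame(offset = c(0, 1300), weight = c(1, 0.5),
                     sigma = c(500, 500)),
    can_s1 = data.frame(offset = c(0, 1400, 2800), weight = c(1, 0.7, 0.3),
                        sigma = c(600, 600, 600))
  )
}

#' Realize a lineshape template at a 0-0 energy
#'
#' @param components Component table (as stored in a lineshape library).
#' @param e00 0-0 energy, cm^-1.
#' @param kind `"ABSORPTION"` or `"EMISSION"`.
#' @return A [lineshape()].
#' @export
realize_lineshape <- function(components, e00,
                              kind = c("ABSORPTION", "EMISSION")) {
  lineshape(match.arg(kind), e00, components)
}

#' Import a tabulated spectrum as an empirical lineshape surrogate
#'
#' Reads a two-column text table (wavenumber cm^-1, intensity), normalizes it
#' to unit area, and returns it as a function-backed profile on its native
#' grid together with the grid. Intended for users who have a measured band
#' shape; parametric lineshapes remain the default.
#'
#' @param path Two-column whitespace/comma-separated text file.
#' @return List with `nu` and `density` (unit trapezoidal area).
#' @export
read_tabulated_spectrum <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          comment.char = "#")
  if (ncol(df) < 2) stop("expected two columns: wavenumber, intensity")
  nu <- df[[1]]; y <- df[[2]]
  o <- order(nu); nu <- nu[o]; y <- y[o]
  if (any(y < 0)) stop("negative intensities in tabulated spectrum")
  area <- .trapz(nu, y)
  if (area <= 0) stop("tabulated spectrum has zero area")
  list(nu = nu, density = y / area)
}
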