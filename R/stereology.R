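#' Stereology inputs for vesicle counting
#'
#' Bundles the per-genotype measurements needed to compute total,
#' membrane-proximal and docked LDCV numbers per cell. Units are fixed to
#' micrometres and picofarads; convert nanometre diameters before use.
#'
#' @param delta_v 2D cytoplasm density of vesicle profiles, vesicles/um^2.
#' @param d_v vesicle diameter from 3D tomography, um.
#' @param h ultrathin section thickness, um (default 0.060).
#' @param c_rest resting membrane capacitance, pF.
#' @param spec_cap specific membrane capacitance, fF/um^2 (default 10,
#'   i.e. 1 uF/cm^2).
#' @param f nucleus-to-cell radius ratio, in (0,1) (default 0.5).
#' @param n_l membrane-proximal vesicles per um membrane length (vesicles
#'   with centres within 40 nm of the plasma membrane).
#' @param docked_fraction fraction of membrane-proximal vesicles that are
#'   physically attached to the membrane, in \[0,1\].
#' @return An object of class `stereology_input`.
#' @export
stereology_input <- function(delta_v, d_v, h = 0.060, c_rest,
                             spec_cap = 10, f = 0.5,
                             n_l = 0, docked_fraction = 0) {
  stopifnot(delta_v > 0, d_v > 0, h > 0, c_rest > 0, spec_cap > 0,
            f > 0, f < 1, n_l >= 0,
            docked_fraction >= 0, docked_fraction <= 1)
  structure(list(delta_v = delta_v, d_v = d_v, h = h, c_rest = c_rest,
                 spec_cap = spec_cap, f = f, n_l = n_l,
                 docked_fraction = docked_fraction),
            class = "stereology_input")
}

#' Corrected cytoplasmic volume fraction of vesicles
#'
#' A vesicle profile seen in a section of thickness `h` is first treated as
#' a cylinder of the vesicle's diameter and the section's height, giving the
#' uncorrected volume fraction `delta_v * cyl_vol / h`. Because vesicles are
#' spheres and are still recognised when the section cuts them tangentially
#' (down to half the section thickness), the fraction is multiplied by the
#' ratio of the sphere volume to a circumscribed cylinder whose height is
#' the vesicle diameter plus `h`.
#'
#' @inheritParams stereology_input
#' @return List with `cyl_vol` (um^3), `frac_uncorrected`, `ves_vol` (um^3),
#'   `circ_cyl_vol` (um^3), `correction`, `frac_corrected`.
#' @export
volume_fraction_chain <- function(delta_v, d_v, h = 0.060) {
  stopifnot(delta_v >= 0, d_v > 0, h > 0)
  r <- d_v / 2
  cyl_vol <- pi * r^2 * h
  frac_uncorrected <- delta_v * cyl_vol / h
  ves_vol <- 4 / 3 * pi * r^3
  circ_cyl_vol <- pi * r^2 * (d_v + h)
  correction <- ves_vol / circ_cyl_vol
  list(cyl_vol = cyl_vol, frac_uncorrected = frac_uncorrected,
       ves_vol = ves_vol, circ_cyl_vol = circ_cyl_vol,
       correction = correction,
       frac_corrected = frac_uncorrected * correction)
}

#' Cell geometry from resting capacitance
#'
#' Membrane area follows from the specific capacitance; the cell is treated
#' as a sphere and the nucleus as a concentric sphere of radius `f * r_cell`.
#'
#' @inheritParams stereology_input
#' @return List with `pm_area` (um^2), `r_cell` (um), `cytoplasm_vol` (um^3).
#' @export
cell_geometry <- function(c_rest, spec_cap = 10, f = 0.5) {
  stopifnot(c_rest > 0, spec_cap > 0, f >= 0, f < 1)
  pm_area <- c_rest * 1000 / spec_cap       # pF -> fF, / (fF/um^2)
  r_cell <- sqrt(pm_area / (4 * pi))
  cytoplasm_vol <- 4 / 3 * pi * r_cell^3 * (1 - f^3)
  list(pm_area = pm_area, r_cell = r_cell, cytoplasm_vol = cytoplasm_vol)
}

#' Total number of vesicles per cell
#'
#' Single-equation form of the full stereology chain:
#' \deqn{N_v = \frac{4\,\delta_v\, \pi\, r_{cell}^3 (1 - f^3)}
#'                 {3\,(2 r_{ves} + h)}}
#' which is algebraically identical to
#' `frac_corrected * cytoplasm_vol / ves_vol` from
#' [volume_fraction_chain()] and [cell_geometry()].
#'
#' @param inp a [stereology_input()].
#' @return Total vesicle count per cell (not rounded).
#' @export
total_vesicles <- function(inp) {
  stopifnot(inherits(inp, "stereology_input"))
  geo <- cell_geometry(inp$c_rest, inp$spec_cap, inp$f)
  4 * inp$delta_v * pi * geo$r_cell^3 * (1 - inp$f^3) /
    (3 * (inp$d_v + inp$h))
}

#' Membrane-proximal and docked vesicle counts
#'
#' Converts the linear density of membrane-proximal vesicles (per um of
#' membrane in a section) to a surface density with
#' `n_a = n_l / (d_v + 0.06)`, where the 0.06 um denominator term is the
#' 40-nm proximity shell plus section geometry, then scales by the plasma
#' membrane area and the tomographically determined docked fraction.
#'
#' @param n_l membrane-proximal vesicles per um membrane length.
#' @param d_v vesicle diameter, um.
#' @param pm_area plasma membrane area, um^2.
#' @param docked_fraction fraction of proximal vesicles that are docked.
#' @return List with `n_a` (vesicles/um^2), `n_proximal`, `n_docked`.
#' @export
docked_vesicles <- function(n_l, d_v, pm_area, docked_fraction) {
  stopifnot(n_l >= 0, d_v > 0, pm_area >= 0,
            docked_fraction >= 0, docked_fraction <= 1)
  n_a <- n_l / (d_v + 0.06)
  n_proximal <- n_a * pm_area
  list(n_a = n_a, n_proximal = n_proximal,
       n_docked = n_proximal * docked_fraction)
}

#' Full stereology chain
#'
#' Runs [volume_fraction_chain()], [cell_geometry()], [total_vesicles()] and
#' [docked_vesicles()] on one input set. `rounding = "printed"` additionally
#' reports each intermediate rounded to the precision conventionally printed
#' in worked examples (3 significant figures for volumes and fractions,
#' 0.01 um for the cell radius); the vesicle counts themselves are always
#' computed from the unrounded single-equation form, since chaining rounded
#' intermediates accumulates error of order 0.1%.
#'
#' @param inp a [stereology_input()].
#' @param rounding `"full"` (default) or `"printed"`.
#' @return An object of class `stereology_result` with all intermediate and
#'   final quantities (see field list in the package vignette).
#' @export
stereology_chain <- function(inp, rounding = c("full", "printed")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(inp, "stereology_input"))
  vf <- volume_fraction_chain(inp$delta_v, inp$d_v, inp$h)
  geo <- cell_geometry(inp$c_rest, inp$spec_cap, inp$f)
  n_total <- total_vesicles(inp)
  dk <- docked_vesicles(inp$n_l, inp$d_v, geo$pm_area, inp$docked_fraction)
  res <- c(vf, geo, list(n_total = n_total), dk)
  if (rounding == "printed") {
    res$cyl_vol <- signif(res$cyl_vol, 3)
    res$frac_uncorrected <- signif(res$frac_uncorrected, 3)
    res$ves_vol <- signif(res$ves_vol, 4)
    res$circ_cyl_vol <- signif(res$circ_cyl_vol, 3)
    res$correction <- signif(res$correction, 3)
    res$frac_corrected <- signif(res$frac_uncorrected * res$correction, 3)
    res$r_cell <- round(res$r_cell, 2)
    res$pm_area <- signif(res$pm_area, 3)
    res$cytoplasm_vol <- round(4 / 3 * pi * res$r_cell^3, 1) -
      round(4 / 3 * pi * (inp$f * res$r_cell)^3, 1)
    res$n_total <- round(res$n_total)
    res$n_a <- round(res$n_a, 2)
    res$n_proximal <- round(res$n_proximal)
    res$n_docked <- round(res$n_docked)
  }
  structure(res, class = "stereology_result", rounding = rounding)
}

#' @export
print.stereology_result <- function(x, ...) {
  cat("<stereology_result>", paste0("(", attr(x, "rounding"), " precision)"), "\n")
  cat(sprintf("  corrected volume fraction: %.4g\n", x$frac_corrected))
  cat(sprintf("  cell radius %.3g um, PM area %.4g um^2, cytoplasm %.4g um^3\n",
              x$r_cell, x$pm_area, x$cytoplasm_vol))
  cat(sprintf("  total vesicles: %.0f\n", x$n_total))
  cat(sprintf("  n_a %.3g /um^2, proximal %.0f, docked %.0f\n",
              x$n_a, x$n_proximal, x$n_docked))
  invisible(x)
}
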