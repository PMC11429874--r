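#' Copy-number and density arithmetic for membrane signaling molecules
#'
#' Small helpers for the back-of-envelope bookkeeping that connects
#' single-molecule densities measured in TIRF footprints to whole-cell
#' copy numbers and concentrations: lipid pool sizes, molecules per cell,
#' ploidy scaling, fractions of a total pool, diffraction-limit densities
#' and molar concentrations.
#'
#' @name copy_numbers
NULL

#' @describeIn copy_numbers Copies of a product lipid from a substrate
#'   pool and a conversion fraction (e.g. the PIP3 pool from the
#'   plasma-membrane PI(4,5)P2 pool at a few percent conversion).
#' @param substrate_copies Substrate pool size, molecules per cell.
#' @param conversion_fraction Fraction converted, in `[0, 1]`.
#' @export
converted_pool <- function(substrate_copies, conversion_fraction) {
  stopifnot(substrate_copies >= 0, conversion_fraction >= 0,
            conversion_fraction <= 1)
  substrate_copies * conversion_fraction
}

#' @describeIn copy_numbers Whole-cell molecule count from a membrane
#'   density per 100 um^2 and the cell surface area.
#' @param density_per_100um2 Molecules per 100 um^2 of membrane.
#' @param cell_area_um2 Membrane area per cell, um^2.
#' @export
molecules_per_cell <- function(density_per_100um2, cell_area_um2) {
  stopifnot(density_per_100um2 >= 0, cell_area_um2 >= 0)
  density_per_100um2 * cell_area_um2 / 100
}

#' @describeIn copy_numbers Scale a per-allele count by ploidy (e.g. a
#'   single tagged allele in a pseudotriploid line).
#' @param per_allele_copies Copies attributable to one allele.
#' @param ploidy Number of alleles.
#' @export
allele_scaled_copies <- function(per_allele_copies, ploidy) {
  stopifnot(per_allele_copies >= 0, ploidy >= 1)
  per_allele_copies * ploidy
}

#' @describeIn copy_numbers Percentage a subpool represents of a total
#'   pool.
#' @param copies Subpool size.
#' @param total_copies Total pool size (> 0).
#' @export
percent_of_pool <- function(copies, total_copies) {
  stopifnot(total_copies > 0, copies >= 0)
  100 * copies / total_copies
}

#' @describeIn copy_numbers Area of an Airy disc from its diameter.
#' @param diameter_um Airy-disc diameter, um.
#' @export
airy_disc_area <- function(diameter_um) {
  stopifnot(diameter_um > 0)
  pi * (diameter_um / 2)^2
}

#' @describeIn copy_numbers Density (per `ref_area_um2`, default
#'   100 um^2) at which diffraction-limited spots tile the membrane and
#'   fuse into unresolvable, continuous fluorescence: one molecule per
#'   Airy-disc area.
#' @param airy_area_um2 Airy-disc area, um^2.
#' @param ref_area_um2 Reference area for the density. Default 100.
#' @export
convolution_density_limit <- function(airy_area_um2, ref_area_um2 = 100) {
  stopifnot(airy_area_um2 > 0, ref_area_um2 > 0)
  ref_area_um2 / airy_area_um2
}

#' @describeIn copy_numbers Volume of a spherical cell in picoliters
#'   (1 um^3 = 1e-3 pL).
#' @export
sphere_volume_pL <- function(diameter_um) {
  stopifnot(diameter_um > 0)
  4 / 3 * pi * (diameter_um / 2)^3 * 1e-3
}

#' @describeIn copy_numbers Molar concentration in nanomolar of `copies`
#'   molecules in a cell volume given in picoliters.
#' @param volume_pL Cell volume, pL.
#' @export
concentration_nM <- function(copies, volume_pL) {
  stopifnot(copies >= 0, volume_pL > 0)
  copies / (6.02214076e23 * volume_pL * 1e-12) * 1e9
}
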