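# Physical constants and unit conversions shared across the package.

#' Physical constants used throughout the package
#'
#' @format A named list:
#' \describe{
#'   \item{k_e}{Coulomb constant, 332.0636 kcal mol^-1 A e^-2 (biomolecular
#'     convention).}
#'   \item{N_A}{Avogadro's number, 6.02214e23 mol^-1.}
#' }
#' @export
ak_constants <- list(
  k_e = 332.0636,
  N_A = 6.02214e23
)

#' Molar masses of common crowding agents
#'
#' Built-in molar masses (g/mol) for the crowders used in actin crowding
#' studies: PEG 8000, BSA, and sucrose. `sucrose_md_model` and
#' `peg_md_model` are the masses of the small molecular-model compounds used
#' in all-atom simulations; use the plain entries for solution (stock)
#' arithmetic.
#'
#' @format Named numeric vector, g/mol.
#' @export
crowder_molar_masses <- c(
  PEG8000          = 8000,
  BSA              = 66540.3,
  sucrose          = 342.30,
  sucrose_md_model = 389.52,
  peg_md_model     = 385.25
)

# diffusion unit scale factors to um^2/s
.diff_unit_scale <- c("A2/ns" = 10, "um2/s" = 1, "nm2/us" = 1)

.normalize_diff_unit <- function(u) {
  u0 <- gsub("µ", "u", u)
  u0 <- gsub("Å|Å", "A", u0)
  key <- switch(tolower(gsub("[²\\^ ]", "", u0)),
    "a2/ns" = "A2/ns",
    "um2/s" = "um2/s",
    "nm2/us" = "nm2/us",
    stop("unknown diffusion unit: '", u, "' (use A2/ns, um2/s or nm2/us)",
      call. = FALSE
    )
  )
  key
}

#' Convert a diffusion coefficient between unit systems
#'
#' Exact unit algebra between the Angstrom/nanosecond scale of molecular
#' trajectories and the micrometre/second scale of cell-biological tables:
#' 1 A^2/ns = 10 um^2/s = 10 nm^2/us.
#'
#' @param value Numeric diffusion coefficient(s).
#' @param from,to Unit labels: `"A2/ns"`, `"um2/s"` or `"nm2/us"`
#'   (unicode spellings with Angstrom and micro signs are accepted).
#' @return `value` expressed in `to` units.
#' @examples
#' convert_diffusion_units(1, "A2/ns", "um2/s") # 10
#' @export
convert_diffusion_units <- function(value, from, to) {
  stopifnot(is.numeric(value))
  value * .diff_unit_scale[[.normalize_diff_unit(from)]] /
    .diff_unit_scale[[.normalize_diff_unit(to)]]
}

#' Crowding-agent stock concentration from percent weight/weight
#'
#' Converts a stock composition given as % w/w to molarity, assuming a
#' solution density (default 1.00 g/mL, appropriate for the dilute-to-
#' moderate stocks used in crowding buffers):
#' c (mM) = percent/100 * density * 1e6 / molar_mass.
#'
#' @param percent_ww Percent weight/weight, in `[0, 100)`.
#' @param molar_mass Crowder molar mass, g/mol (see [crowder_molar_masses]).
#' @param density Solution density, g/mL.
#' @return Concentration in mM.
#' @examples
#' percent_ww_to_molar(15, crowder_molar_masses[["PEG8000"]]) # ~18.8 mM
#' @export
percent_ww_to_molar <- function(percent_ww, molar_mass, density = 1.0) {
  stopifnot(
    is.numeric(percent_ww), all(percent_ww >= 0), all(percent_ww < 100),
    is.numeric(density), all(density > 0)
  )
  if (!is.numeric(molar_mass) || any(molar_mass <= 0)) {
    stop("molar_mass must be positive (g/mol)", call. = FALSE)
  }
  percent_ww / 100 * density * 1000 / molar_mass * 1000
}

#' @rdname percent_ww_to_molar
#' @param concentration_mM Concentration in mM.
#' @return `molar_to_percent_ww`: percent w/w (exact inverse of
#'   [percent_ww_to_molar]).
#' @export
molar_to_percent_ww <- function(concentration_mM, molar_mass, density = 1.0) {
  stopifnot(is.numeric(concentration_mM), all(concentration_mM >= 0))
  if (!is.numeric(molar_mass) || any(molar_mass <= 0)) {
    stop("molar_mass must be positive (g/mol)", call. = FALSE)
  }
  stopifnot(all(density > 0))
  concentration_mM * molar_mass / (density * 1000 * 1000) * 100
}

#' Molecule counts and concentrations in a simulation box
#'
#' Converts between a number of molecules in a box of given volume and the
#' corresponding molar concentration: c = n / (N_A * V).
#'
#' @param n_molecules Molecule count (positive).
#' @param box_volume_nm3 Box volume in nm^3 (positive).
#' @return Concentration in mM.
#' @examples
#' count_to_concentration(15, 3834) # ~6.5 mM
#' @export
count_to_concentration <- function(n_molecules, box_volume_nm3) {
  stopifnot(is.numeric(n_molecules), all(n_molecules > 0))
  if (!is.numeric(box_volume_nm3) || any(box_volume_nm3 <= 0)) {
    stop("box_volume_nm3 must be positive", call. = FALSE)
  }
  # n / (N_A * V[L]) in M; V[L] = V_nm3 * 1e-24; result to mM
  n_molecules / (ak_constants$N_A * box_volume_nm3 * 1e-24) * 1000
}

#' @rdname count_to_concentration
#' @param concentration_mM Concentration in mM (positive).
#' @return `concentration_to_count`: molecule count, rounded to the nearest
#'   integer.
#' @export
concentration_to_count <- function(concentration_mM, box_volume_nm3) {
  stopifnot(is.numeric(concentration_mM), all(concentration_mM > 0))
  if (!is.numeric(box_volume_nm3) || any(box_volume_nm3 <= 0)) {
    stop("box_volume_nm3 must be positive", call. = FALSE)
  }
  round(concentration_mM / 1000 * ak_constants$N_A * box_volume_nm3 * 1e-24)
}

#' @rdname count_to_concentration
#' @return `box_volume_for_concentration`: box volume in nm^3 holding
#'   `n_molecules` at `concentration_mM`.
#' @export
box_volume_for_concentration <- function(n_molecules, concentration_mM) {
  stopifnot(all(n_molecules > 0), all(concentration_mM > 0))
  n_molecules / (ak_constants$N_A * concentration_mM / 1000) * 1e24
}

#' Filament elongation rate in subunits per second
#'
#' Converts a linear elongation rate (nm/s) to a subunit addition rate using
#' the axial rise contributed per added subunit. The canonical actin value is
#' 2.7 nm per subunit (half the 5.4 nm crossover-independent monomer spacing
#' of the double helix); 2.626 nm is an alternative in circulation.
#'
#' @param rate_nm_s Elongation rate, nm/s.
#' @param rise_per_subunit_nm Axial rise per subunit, nm (> 0).
#' @return Subunit addition rate, subunits/s.
#' @examples
#' rate_to_subunits(35.9, 2.626) # ~13.67 subunits/s
#' @export
rate_to_subunits <- function(rate_nm_s, rise_per_subunit_nm = 2.7) {
  stopifnot(is.numeric(rate_nm_s))
  if (!is.numeric(rise_per_subunit_nm) || any(rise_per_subunit_nm <= 0)) {
    stop("rise_per_subunit_nm must be positive", call. = FALSE)
  }
  rate_nm_s / rise_per_subunit_nm
}

#' Fold change of a rate relative to a control
#'
#' @param rate Rate (any units).
#' @param control_rate Control rate, same units, strictly positive.
#' @return Dimensionless ratio `rate / control_rate`.
#' @examples
#' fold_change(61.3, 35.9) # ~1.7
#' @export
fold_change <- function(rate, control_rate) {
  stopifnot(is.numeric(rate))
  if (!is.numeric(control_rate) || any(control_rate <= 0)) {
    stop("control_rate must be strictly positive", call. = FALSE)
  }
  rate / control_rate
}
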