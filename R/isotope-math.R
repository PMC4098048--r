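# Isotopologue arithmetic for 12C / U-13C paired metabolomes.
#
# All mass constants follow the 5-decimal convention of the 1.00335 u
# 13C-12C mass difference; only carbon is modelled (no S/Cl isotope
# corrections), because pattern verification in this workflow checks the
# M+1 and M'-1 carbon isotopologues only.

#' Isotope and adduct constants
#'
#' Fixed physical constants used throughout the package: the
#' \eqn{^{13}C-^{12}C} mass difference (1.00335 u), the proton mass
#' (1.00728 u), the natural \eqn{^{13}C} incorporation probability
#' (0.0111, i.e. 98.8 % \eqn{^{12}C} / 1.1 % \eqn{^{13}C}), and the
#' default ESI adduct table.
#'
#' @param p_natural Natural per-atom \eqn{^{13}C} probability. Must lie in
#'   (0, 0.05).
#' @param adducts Adduct table, a `data.frame` with columns `name`,
#'   `mass_shift` (total m/z shift times charge, in u) and `charge`.
#'   Defaults to `default_adducts()`.
#' @return A list with elements `delta_c`, `proton_mass`, `p_natural`,
#'   `adducts`.
#' @examples
#' isotope_constants()$delta_c   # 1.00335
#' @export
isotope_constants <- function(p_natural = 0.0111, adducts = default_adducts()) {
  stopifnot(p_natural > 0, p_natural < 0.05)
  list(
    delta_c = 1.00335,
    proton_mass = 1.00728,
    p_natural = p_natural,
    adducts = adducts
  )
}

#' Default ESI(+) adduct table
#'
#' The ion species handled by default: protonated molecule, sodium adduct,
#' water loss from the protonated molecule, and a doubly protonated
#' representative. `mass_shift` is the total mass added to the neutral
#' molecule to form the ion (so that `mz = (M + mass_shift) / charge`).
#'
#' @return `data.frame` with columns `name`, `mass_shift`, `charge`.
#' @export
default_adducts <- function() {
  # Na+ = 22.98977 (Na) - 0.00055 (electron); H2O = 18.01056
  data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M+H-H2O]+", "[M+2H]2+"),
    mass_shift = c(1.00728, 22.98922, 1.00728 - 18.01056, 2 * 1.00728),
    charge = c(1L, 1L, 1L, 2L),
    stringsAsFactors = FALSE
  )
}

#' Deduce the carbon count of an ion from its M / M' pair
#'
#' A native monoisotopic ion M and its uniformly \eqn{^{13}C}-labelled
#' partner M' are separated by `n_c * 1.00335 / z` on the m/z axis, so the
#' carbon count follows directly from the measured spacing. The rounded
#' count is accepted only when the residual spacing error, expressed on
#' the m/z scale at M', stays within `ppm`.
#'
#' @param mz_m,mz_mprime m/z of the monoisotopic native ion and of the
#'   fully labelled ion (u); `mz_mprime > mz_m`.
#' @param z Charge state (>= 1).
#' @param ppm Tolerance for the residual, in parts per million of
#'   `mz_mprime`.
#' @return Integer carbon count, or `NA_integer_` when the spacing is not
#'   an acceptable multiple of 1.00335/z (or rounds to n < 1).
#' @examples
#' carbon_count(625.38998, 655.49048, 1)  # 30
#' @export
carbon_count <- function(mz_m, mz_mprime, z, ppm = 2.5) {
  stopifnot(mz_mprime > mz_m, z >= 1)
  delta <- (mz_mprime - mz_m)
  n <- round(delta * z / 1.00335)
  if (n < 1) return(NA_integer_)
  residual <- abs(delta - n * 1.00335 / z)
  if (residual > ppm * 1e-6 * mz_mprime) return(NA_integer_)
  as.integer(n)
}

#' Expected M+1 / M intensity ratio of a native ion
#'
#' First-order binomial ratio of the first heavy isotopologue to the
#' monoisotopic signal for an ion with `n_c` carbon atoms at natural
#' (or any) \eqn{^{13}C} abundance `p_nat`:
#' \eqn{n_C \, p / (1 - p)}.
#'
#' @param n_c Carbon count (>= 1).
#' @param p_nat Per-atom \eqn{^{13}C} probability.
#' @return Expected intensity ratio M+1 / M.
#' @export
expected_m1_ratio <- function(n_c, p_nat = 0.0111) {
  stopifnot(all(n_c >= 1))
  n_c * p_nat / (1 - p_nat)
}

#' Expected M'-1 / M' intensity ratio of a labelled ion
#'
#' Binomial ratio of the one-residual-\eqn{^{12}C} isotopologue to the
#' fully labelled ion at enrichment `p_enr`:
#' \eqn{n_C (1 - p) / p}.
#'
#' @param n_c Carbon count (>= 1).
#' @param p_enr Per-atom \eqn{^{13}C} enrichment, in (0, 1].
#' @return Expected intensity ratio M'-1 / M'.
#' @export
expected_mprime_minus1_ratio <- function(n_c, p_enr) {
  stopifnot(all(n_c >= 1), all(p_enr > 0), all(p_enr <= 1))
  n_c * (1 - p_enr) / p_enr
}

#' Estimate the 13C enrichment from an observed M'-1 / M' ratio
#'
#' Exact algebraic inverse of [expected_mprime_minus1_ratio()]:
#' \eqn{p = n_C / (n_C + r)}.
#'
#' @param ratio Observed intensity ratio M'-1 / M' (>= 0).
#' @param n_c Carbon count deduced for the ion.
#' @return Estimated per-atom enrichment probability.
#' @examples
#' estimate_enrichment(expected_mprime_minus1_ratio(30, 0.995), 30)  # 0.995
#' @export
estimate_enrichment <- function(ratio, n_c) {
  stopifnot(all(ratio >= 0), all(n_c >= 1))
  n_c / (n_c + ratio)
}

#' Largest carbon count with unambiguous direct assignment
#'
#' At enrichment `p_enr` the residual M'-1 signal grows linearly with the
#' carbon count; once it reaches the fully labelled M' signal the
#' monoisotopic/fully-labelled anchors are no longer unambiguous. This
#' returns the largest `n` whose expected M'-1 / M' ratio does not exceed
#' 1, i.e. `floor(p / (1 - p))` (parity counts; a small epsilon guards
#' floating-point representation of the bound).
#'
#' @param p_enr Enrichment in (0.5, 1).
#' @return Integer carbon count bound.
#' @examples
#' max_direct_carbon(0.98)  # 49
#' @export
max_direct_carbon <- function(p_enr) {
  stopifnot(p_enr > 0.5, p_enr < 1)
  max(1L, as.integer(floor(p_enr / (1 - p_enr) + 1e-9)))
}

#' Reconstruct the neutral monoisotopic mass of an ion
#'
#' @param mz Measured m/z of the monoisotopic ion (u).
#' @param z Charge state.
#' @param adduct Adduct name, looked up in `constants$adducts`.
#' @param constants See [isotope_constants()].
#' @return Neutral monoisotopic mass in u.
#' @examples
#' neutral_mass(625.38998, 1, "[M+H]+")  # 624.3827
#' @export
neutral_mass <- function(mz, z, adduct, constants = isotope_constants()) {
  tab <- constants$adducts
  i <- match(adduct, tab$name)
  if (is.na(i)) {
    stop("unknown adduct '", adduct, "'; known: ",
         paste(tab$name, collapse = ", "))
  }
  if (tab$charge[i] != z) {
    stop("adduct '", adduct, "' implies charge ", tab$charge[i],
         ", got z = ", z)
  }
  mz * z - tab$mass_shift[i]
}

#' m/z of an adduct ion of a neutral molecule
#'
#' Inverse of [neutral_mass()]; used by the simulator.
#'
#' @inheritParams neutral_mass
#' @param mass Neutral monoisotopic mass (u).
#' @return m/z of the monoisotopic adduct ion.
#' @export
adduct_mz <- function(mass, adduct, constants = isotope_constants()) {
  tab <- constants$adducts
  i <- match(adduct, tab$name)
  if (is.na(i)) {
    stop("unknown adduct '", adduct, "'; known: ",
         paste(tab$name, collapse = ", "))
  }
  (mass + tab$mass_shift[i]) / tab$charge[i]
}

#' Enrichment model of a labelled metabolome
#'
#' @param p_enriched Per-atom \eqn{^{13}C} probability of the labelled
#'   metabolome (e.g. 0.995 for a 99.5 % enriched culture).
#' @param p_natural Natural \eqn{^{13}C} probability of the native
#'   metabolome.
#' @return A list with class `sil_enrichment`.
#' @export
enrichment_model <- function(p_enriched = 0.995, p_natural = 0.0111) {
  stopifnot(p_enriched > 0.5, p_enriched <= 1, p_natural < 0.5)
  structure(list(p_enriched = p_enriched, p_natural = p_natural),
            class = "sil_enrichment")
}
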