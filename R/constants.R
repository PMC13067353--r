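#' Physical constants (CODATA 2018)
#'
#' Named list of the physical constants used for rate estimation and unit
#' conversion, pinned to CODATA 2018 so results are bit-reproducible:
#' `kB` (J/K), `h` (J s), `NA` (1/mol), `R_kcal` (kcal/(mol K)),
#' `eV_kcal` (kcal/mol per eV), `kcal_kJ` (kJ per kcal, thermochemical).
#'
#' @format Named list of numeric scalars.
#' @export
pt_constants <- list(
  kB      = 1.380649e-23,        # J/K (exact)
  h       = 6.62607015e-34,      # J s (exact)
  NA_     = 6.02214076e23,       # 1/mol (exact)
  kcal_kJ = 4.184,               # thermochemical calorie (exact)
  # R = NA * kB = 8.31446261815324 J/(mol K) -> kcal/(mol K)
  R_kcal  = 8.31446261815324 / 4184,
  # 1 eV = NA * e / 4184 kcal/mol = 23.060548 kcal/mol
  eV_kcal = 6.02214076e23 * 1.602176634e-19 / 4184
)

#' Thermal energy in kcal/mol
#'
#' @param temperature Temperature in K.
#' @return k_B T in kcal/mol.
#' @export
kT_kcal <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  pt_constants$R_kcal * temperature
}

#' Convert energies between common units
#'
#' Exact linear conversion between `meV`, `eV`, `kcal/mol`, `kJ/mol` and
#' `kBT` (thermal units at a stated temperature), via CODATA factors.
#'
#' @param value Numeric energy value(s).
#' @param from,to Unit names, one of `"meV"`, `"eV"`, `"kcal/mol"`,
#'   `"kJ/mol"`, `"kBT"`.
#' @param temperature Temperature in K, required only when either unit is
#'   `"kBT"` (default 310).
#' @return Converted numeric value(s).
#' @examples
#' convert_energy(800, "meV", "kcal/mol")  # 18.45
#' @export
convert_energy <- function(value, from, to, temperature = 310) {
  to_kcal <- function(unit) {
    switch(unit,
      "meV"      = pt_constants$eV_kcal / 1000,
      "eV"       = pt_constants$eV_kcal,
      "kcal/mol" = 1,
      "kJ/mol"   = 1 / pt_constants$kcal_kJ,
      "kBT"      = kT_kcal(temperature),
      stop("unknown energy unit: ", unit)
    )
  }
  stopifnot(is.numeric(value))
  value * to_kcal(from) / to_kcal(to)
}
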