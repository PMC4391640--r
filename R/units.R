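#' Physical constants and unit conversions
#'
#' All internal computation uses Hartree atomic units (hbar = 1, energies in
#' hartree, time in atomic time units, lengths in bohr). User-facing
#' boundaries use eV, fs, cm^-1 and Angstrom. Every conversion constant is
#' pinned here and nowhere else.
#'
#' @format A named list with elements
#' \describe{
#'   \item{hartree_ev}{1 hartree in eV (27.211386...)}
#'   \item{hartree_cm1}{1 hartree in cm^-1 (219474.63...)}
#'   \item{au_fs}{1 atomic time unit in fs}
#'   \item{fs_au}{1 fs in atomic time units}
#'   \item{bohr_angstrom}{1 bohr in Angstrom}
#' }
#' @export
#' @examples
#' units_au$hartree_ev
units_au <- list(
  hartree_ev    = 27.211386245988,
  hartree_cm1   = 219474.6313632,
  au_fs         = 0.024188843265857,
  fs_au         = 1 / 0.024188843265857,
  bohr_angstrom = 0.529177210903
)

#' Convert between eV/hartree and cm^-1/hartree
#'
#' Small helpers used throughout the package.
#' @param x numeric values to convert.
#' @return converted numeric values.
#' @export
#' @rdname unit-helpers
ev_to_hartree <- function(x) x / units_au$hartree_ev

#' @export
#' @rdname unit-helpers
hartree_to_ev <- function(x) x * units_au$hartree_ev

#' @export
#' @rdname unit-helpers
cm1_to_hartree <- function(x) x / units_au$hartree_cm1

#' @export
#' @rdname unit-helpers
hartree_to_cm1 <- function(x) x * units_au$hartree_cm1
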