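## Ion species and stopping materials.

# Elemental data used for Bragg additivity: charge, atomic mass, mean
# excitation energy (eV).  Covers the GCR design range (Z <= 28) plus the
# constituents of the shipped materials.
ELEMENTS <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
             "Ti", "Cr", "Mn", "Fe", "Ni"),
  Z = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10,
        11, 12, 13, 14, 15, 16, 17, 18, 19, 20,
        22, 24, 25, 26, 28),
  A = c(1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999, 18.998,
        20.180, 22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45,
        39.948, 39.098, 40.078, 47.867, 51.996, 54.938, 55.845, 58.693),
  I_eV = c(19.2, 41.8, 40, 63.7, 76, 78, 82, 95, 115, 137,
           149, 156, 166, 173, 173, 180, 174, 188, 190, 191,
           233, 257, 272, 286, 311),
  stringsAsFactors = FALSE
)

# nucleon rest mass used to turn MeV/u into velocity; the proton gets its
# physical mass, heavier ions the atomic mass unit (sub-0.1% difference)
AMU_MEV <- 931.494
PROTON_MEV <- 938.272

#' Define an ion species
#'
#' Parses a nuclide label such as `"16O"`, `"4He"` or `"p"` (or takes
#' explicit charge and mass numbers) and returns the species record used by
#' the physics routines.
#'
#' @param label Nuclide label: mass number followed by element symbol
#'   (`"56Fe"`), or `"p"` for protons.
#' @param Z,A Optional explicit charge and mass numbers; override the label.
#' @return A list of class `gcr_ion` with elements `label`, `Z`, `A`.
#' @examples
#' ion("16O")
#' ion("p")
#' @export
ion <- function(label, Z = NULL, A = NULL) {
  if (is.null(Z) || is.null(A)) {
    if (identical(label, "p") || identical(label, "1H")) {
      Z <- 1L; A <- 1L
    } else {
      m <- regmatches(label, regexec("^([0-9]+)([A-Za-z]+)$", label))[[1]]
      if (length(m) != 3) {
        abort(paste0("cannot parse ion label '", label, "'"))
      }
      A <- as.integer(m[2])
      idx <- match(m[3], ELEMENTS$symbol)
      if (is.na(idx)) abort(paste0("unknown element symbol '", m[3], "'"))
      Z <- ELEMENTS$Z[idx]
    }
  }
  Z <- as.integer(Z); A <- as.integer(A)
  if (Z < 1 || Z > 28) abort("charge number Z must be in 1..28")
  if (A < 1 || A < Z) abort("mass number A must satisfy A >= Z and A >= 1")
  structure(list(label = label, Z = Z, A = A), class = "gcr_ion")
}

#' @export
print.gcr_ion <- function(x, ...) {
  cat("<ion ", x$label, ": Z=", x$Z, " A=", x$A, ">\n", sep = "")
  invisible(x)
}

as_ion <- function(x) {
  if (inherits(x, "gcr_ion")) x else ion(x)
}

# per-nucleon rest mass in MeV
nucleon_mass <- function(ion) {
  if (ion$Z == 1L && ion$A == 1L) PROTON_MEV else AMU_MEV
}

#' Define a stopping material
#'
#' Materials carry a density, an elemental composition by mass fraction and
#' a mean excitation energy I.  When `I_eV` is not given it is derived from
#' the composition by Bragg additivity (`ln I = sum w_i (Z/A)_i ln I_i /
#' sum w_i (Z/A)_i`).
#'
#' @param name Material name.
#' @param density Bulk density, g/cm^3.
#' @param composition Named numeric vector of element mass fractions
#'   (must sum to 1).
#' @param I_eV Mean excitation energy in eV; `NULL` to derive it.
#' @return A list of class `gcr_material` with `name`, `density`, `za`
#'   (electrons per nucleon, sum of w_i Z_i/A_i) and `I_eV`.
#' @examples
#' material("polyethylene", 0.97, c(C = 0.8563, H = 0.1437))
#' @export
material <- function(name, density, composition, I_eV = NULL) {
  composition <- unlist(composition)
  if (density <= 0) abort("density must be positive")
  if (abs(sum(composition) - 1) > 1e-9) {
    abort("composition mass fractions must sum to 1")
  }
  idx <- match(names(composition), ELEMENTS$symbol)
  if (anyNA(idx)) {
    abort(paste0("unknown element(s): ",
                 paste(names(composition)[is.na(idx)], collapse = ", ")))
  }
  wza <- composition * ELEMENTS$Z[idx] / ELEMENTS$A[idx]
  za <- sum(wza)
  if (is.null(I_eV)) {
    I_eV <- exp(sum(wza * log(ELEMENTS$I_eV[idx])) / za)
  }
  if (I_eV <= 0) abort("mean excitation energy must be positive")
  structure(list(name = name, density = density,
                 composition = composition, za = za, I_eV = I_eV),
            class = "gcr_material")
}

#' @export
print.gcr_material <- function(x, ...) {
  cat("<material ", x$name, ": rho=", x$density, " g/cm^3, Z/A=",
      signif(x$za, 5), ", I=", signif(x$I_eV, 4), " eV>\n", sep = "")
  invisible(x)
}

#' Load a packaged material definition
#'
#' Reads the material config shipped with the package (`materials.yaml`)
#' and builds the requested [material()].  `"tissue"` is unit-density water
#' with I = 75 eV; `"polyethylene"` is (CH2)n at 0.97 g/cm^3.
#'
#' @param name One of the names in the config; see `list_materials()`.
#' @param config Path to an alternative YAML config.
#' @return A `gcr_material`.
#' @examples
#' gcr_material("tissue")
#' @export
gcr_material <- function(name,
                         config = system.file("extdata", "materials.yaml",
                                              package = "gcrsim")) {
  defs <- yaml::read_yaml(config)
  if (!name %in% names(defs)) {
    abort(paste0("material '", name, "' not in config (have: ",
                 paste(names(defs), collapse = ", "), ")"))
  }
  d <- defs[[name]]
  material(name, d$density, d$composition, d$I_eV)
}

#' @rdname gcr_material
#' @export
list_materials <- function(config = system.file("extdata", "materials.yaml",
                                                package = "gcrsim")) {
  names(yaml::read_yaml(config))
}
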