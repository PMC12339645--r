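#' Elemental reference data
#'
#' Atomic numbers and IUPAC standard (conventional) atomic weights for the
#' elements that occur in tissue-equivalent materials and reference tissues.
#'
#' @return A tibble with columns `element` (symbol), `z` (atomic number) and
#'   `atomic_weight` (g/mol).
#' @examples
#' ct_elements()
#' @export
ct_elements <- function() {
  path <- system.file("extdata", "atomic_weights.csv", package = "ctcal")
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    element = readr::col_character(),
                    z = readr::col_integer(),
                    atomic_weight = readr::col_double()
                  ))
}

# cached copy so hot loops do not re-read the CSV
the <- new.env(parent = emptyenv())

element_table <- function() {
  if (is.null(the$elements)) the$elements <- ct_elements()
  the$elements
}

#' Construct a material
#'
#' A material couples a mass density with an elemental composition given as
#' percent-by-weight mass fractions. The composition is validated against the
#' packaged element reference table.
#'
#' @param composition A data frame with columns `element` and
#'   `mass_fraction_percent` (percent by weight).
#' @param name Material label.
#' @param mass_density Mass density in g/cm^3; must be positive.
#' @param normalize If `TRUE` (default), rescale the mass fractions to sum to
#'   exactly 100 (see [normalize_mass_fractions()]).
#'
#' @return A tibble of class `ct_material` with columns `element` and
#'   `mass_fraction_percent`, carrying `material_name` and `mass_density`
#'   attributes.
#' @examples
#' ct_material(data.frame(element = c("H", "O"),
#'                        mass_fraction_percent = c(11.19, 88.81)),
#'             name = "water", mass_density = 1)
#' @export
ct_material <- function(composition, name, mass_density, normalize = TRUE) {
  comp <- validate_composition(composition)
  if (!is.numeric(mass_density) || length(mass_density) != 1 ||
      is.na(mass_density) || mass_density <= 0) {
    stop_validation("`mass_density` must be a single positive number.")
  }
  if (normalize) comp <- normalize_mass_fractions(comp)
  structure(
    as_tibble(comp),
    material_name = as.character(name),
    mass_density = as.numeric(mass_density),
    class = c("ct_material", class(as_tibble(comp)))
  )
}

validate_composition <- function(composition) {
  if (!is.data.frame(composition)) {
    stop_validation("A composition must be a data frame.")
  }
  req <- c("element", "mass_fraction_percent")
  if (!all(req %in% names(composition))) {
    stop_validation(
      "A composition needs columns `element` and `mass_fraction_percent`.")
  }
  comp <- as_tibble(composition)[req]
  if (nrow(comp) == 0) {
    stop_validation("Composition is empty.")
  }
  if (anyNA(comp$mass_fraction_percent) || any(comp$mass_fraction_percent < 0)) {
    stop_validation("Mass fractions must be non-negative and non-missing.")
  }
  if (anyDuplicated(comp$element)) {
    stop_validation("Duplicated element symbols in composition.")
  }
  unknown <- setdiff(comp$element, element_table()$element)
  if (length(unknown) > 0) {
    stop_validation(paste0("Unknown element symbol(s): ",
                           paste(unknown, collapse = ", "), "."))
  }
  comp
}

#' Rescale mass fractions to sum to 100
#'
#' Printed composition tables often sum to slightly less than 100 percent
#' because of rounding; this rescales all fractions by a common factor so the
#' sum is exactly 100, preserving relative proportions. Raw sums far from 100
#' are treated as transcription errors.
#'
#' @param composition Data frame with columns `element` and
#'   `mass_fraction_percent`; raw sum must lie in \[90, 110\].
#' @return A tibble with the same elements and rescaled fractions.
#' @examples
#' normalize_mass_fractions(
#'   data.frame(element = c("H", "O"), mass_fraction_percent = c(10, 89.9)))
#' @export
normalize_mass_fractions <- function(composition) {
  comp <- validate_composition(composition)
  total <- sum(comp$mass_fraction_percent)
  if (total < 90 || total > 110) {
    stop_validation(sprintf(
      "Mass fractions sum to %.4g; expected within [90, 110]. Likely a transcription mistake.",
      total))
  }
  mutate(comp, mass_fraction_percent = .data$mass_fraction_percent * 100 / total)
}

material_name <- function(material) attr(material, "material_name")

#' Mass density of a material
#'
#' @param material A `ct_material`.
#' @return Mass density in g/cm^3.
#' @examples
#' mass_density(water_material())
#' @export
mass_density <- function(material) {
  md <- attr(material, "mass_density")
  if (is.null(md)) stop_validation("Not a `ct_material`: no mass density attribute.")
  md
}

#' @export
print.ct_material <- function(x, ...) {
  cat(sprintf("<ct_material> %s (mass density %.4g g/cm^3)\n",
              material_name(x), mass_density(x)))
  NextMethod()
  invisible(x)
}

# composition joined to Z and A, with electron-density weights w*Z/A
composition_weights <- function(material) {
  comp <- validate_composition(material)
  left_join(comp, element_table(), by = "element") %>%
    mutate(wza = .data$mass_fraction_percent * .data$z / .data$atomic_weight)
}

#' Read / write a material file
#'
#' Material files are plain CSV with two `key,value` header rows (`name` and
#' `mass_density_g_cm3`) followed by an `element,mass_fraction_percent` block.
#' Lines starting with `#` are comments.
#'
#' @param path File path.
#' @param normalize Passed to [ct_material()].
#' @return `read_material()` returns a `ct_material`; `write_material()`
#'   returns `path` invisibly.
#' @examples
#' bdp <- read_material(system.file("extdata", "material_bdp.csv", package = "ctcal"))
#' mass_density(bdp)
#' @export
read_material <- function(path, normalize = TRUE) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hdr_idx <- grep("^element\\s*,", lines)
  if (length(hdr_idx) != 1) {
    stop_format("Material file must contain one `element,mass_fraction_percent` header.")
  }
  meta <- strsplit(lines[seq_len(hdr_idx - 1)], ",")
  meta <- setNames(
    vapply(meta, function(kv) trimws(paste(kv[-1], collapse = ",")), character(1)),
    vapply(meta, function(kv) trimws(kv[1]), character(1)))
  if (!all(c("name", "mass_density_g_cm3") %in% names(meta))) {
    stop_format("Material file must declare `name` and `mass_density_g_cm3`.")
  }
  md <- suppressWarnings(as.numeric(meta[["mass_density_g_cm3"]]))
  if (is.na(md)) stop_format("`mass_density_g_cm3` is not numeric.")
  comp <- suppressWarnings(
    readr::read_csv(I(lines[hdr_idx:length(lines)]), show_col_types = FALSE,
                    col_types = readr::cols(
                      element = readr::col_character(),
                      mass_fraction_percent = readr::col_double())))
  if (anyNA(comp$mass_fraction_percent)) stop_format("Non-numeric mass fraction.")
  ct_material(comp, name = meta[["name"]], mass_density = md,
              normalize = normalize)
}

#' @param material A `ct_material`.
#' @rdname read_material
#' @export
write_material <- function(material, path) {
  comp <- validate_composition(material)
  lines <- c(
    paste0("name,", material_name(material)),
    paste0("mass_density_g_cm3,", format(mass_density(material), digits = 15)),
    "element,mass_fraction_percent",
    paste0(comp$element, ",", vapply(comp$mass_fraction_percent,
                                     format, character(1), digits = 15)))
  readr::write_lines(lines, path)
  invisible(path)
}

fixture_material <- function(file) {
  read_material(system.file("extdata", file, package = "ctcal"))
}

#' Packaged reference materials
#'
#' `bdp_material()` is the Gammex Brain SR-2 brain-tissue-equivalent density
#' plug as characterised by elemental analysis; `icrp110_brain_material()` is
#' the ICRP Publication 110 reference adult whole brain;
#' `water_material()` and `air_material()` are stoichiometric water and dry
#' air. Compositions are percent by weight, normalized to sum to 100.
#'
#' @return A `ct_material`.
#' @examples
#' effective_atomic_number(icrp110_brain_material())
#' @export
bdp_material <- function() fixture_material("material_bdp.csv")

#' @rdname bdp_material
#' @export
icrp110_brain_material <- function() fixture_material("material_icrp110_brain.csv")

#' @rdname bdp_material
#' @export
water_material <- function() fixture_material("material_water.csv")

#' @rdname bdp_material
#' @export
air_material <- function() fixture_material("material_air.csv")

#' Add trace elements to a material
#'
#' Elements detected only qualitatively (e.g. reported as "< 0.01 percent")
#' are excluded from the packaged compositions. This helper adds
#' user-specified trace mass fractions and renormalizes, for sensitivity
#' analyses of how traces move the effective atomic number or predicted CT
#' number.
#'
#' @param material A `ct_material`.
#' @param traces Named numeric vector of percent-by-weight fractions, e.g.
#'   `c(Ti = 0.05, Ba = 0.02)`.
#' @return A new `ct_material` with the traces merged in and fractions
#'   renormalized to 100.
#' @export
with_trace_elements <- function(material, traces) {
  if (is.null(names(traces)) || any(!nzchar(names(traces))) || any(traces < 0)) {
    stop_validation("`traces` must be a named vector of non-negative percents.")
  }
  comp <- validate_composition(material)
  extra <- tibble(element = names(traces),
                  mass_fraction_percent = as.numeric(traces))
  merged <- bind_rows(comp, extra) %>%
    group_by(.data$element) %>%
    summarise(mass_fraction_percent = sum(.data$mass_fraction_percent),
              .groups = "drop")
  ct_material(merged, name = material_name(material),
              mass_density = mass_density(material), normalize = TRUE)
}

#' Relative electron density
#'
#' Electrons per unit volume relative to water:
#' \deqn{\rho_e = \frac{\rho \sum_i \omega_i Z_i / A_i}
#'                     {\rho_w \sum_i \omega_i Z_i / A_i |_{water}}}
#' where \eqn{\omega_i} are mass fractions, \eqn{Z_i} atomic numbers and
#' \eqn{A_i} atomic weights. Linear in mass density at fixed composition.
#'
#' @param material,water `ct_material` objects; `water` defaults to the
#'   packaged stoichiometric water.
#' @return A single positive number (1 for water against itself).
#' @examples
#' relative_electron_density(bdp_material())
#' @export
relative_electron_density <- function(material, water = water_material()) {
  zw <- composition_weights(material)
  ww <- composition_weights(water)
  num <- mass_density(material) *
    sum(zw$wza) / sum(zw$mass_fraction_percent)
  den <- mass_density(water) *
    sum(ww$wza) / sum(ww$mass_fraction_percent)
  num / den
}

#' Effective atomic number (power-law)
#'
#' The power-law effective atomic number of a mixture,
#' \deqn{Z_{eff} = \left(\frac{\sum_i (\omega_i Z_i / A_i)\, Z_i^m}
#'                            {\sum_i \omega_i Z_i / A_i}\right)^{1/m},}
#' an electron-fraction-weighted mean atomic number. The default exponent
#' `m = 3.3` balances Compton scattering against the photoelectric effect in
#' the 50-60 keV effective-energy range of diagnostic CT. Invariant under
#' rescaling of all mass fractions, so normalization does not matter.
#'
#' @param composition A `ct_material` or any data frame with columns
#'   `element` and `mass_fraction_percent`.
#' @param m Positive power-law exponent.
#' @return A single number between the smallest and largest Z present.
#' @examples
#' effective_atomic_number(bdp_material())
#' effective_atomic_number(water_material())
#' @export
effective_atomic_number <- function(composition, m = 3.3) {
  if (!is.numeric(m) || length(m) != 1 || is.na(m) || m <= 0) {
    stop_validation("`m` must be a single positive number.")
  }
  w <- composition_weights(composition)
  (sum(w$wza * w$z^m) / sum(w$wza))^(1 / m)
}

#' Effective atomic numbers for a set of materials
#'
#' Tidy wrapper over [effective_atomic_number()].
#'
#' @param materials A list of `ct_material` objects (optionally named).
#' @param m Power-law exponent, see [effective_atomic_number()].
#' @return A tibble with columns `material`, `mass_density`, `z_eff`.
#' @examples
#' ean_table(list(bdp_material(), icrp110_brain_material(), water_material()))
#' @export
ean_table <- function(materials, m = 3.3) {
  materials <- as_material_list(materials)
  tibble(
    material = vapply(materials, material_name, character(1)),
    mass_density = vapply(materials, mass_density, numeric(1)),
    z_eff = vapply(materials, effective_atomic_number, numeric(1), m = m)
  )
}

as_material_list <- function(materials) {
  if (inherits(materials, "ct_material")) materials <- list(materials)
  if (!is.list(materials) ||
      !all(vapply(materials, inherits, logical(1), "ct_material"))) {
    stop_validation("`materials` must be a ct_material or a list of them.")
  }
  materials
}
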