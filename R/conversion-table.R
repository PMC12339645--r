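#' CT-RED/MD conversion table
#'
#' A treatment planning system converts CT numbers to relative electron
#' density (RED) and mass density (MD) through a piecewise-linear table of
#' knots. This constructor validates knot ordering: CT numbers must be
#' strictly increasing (ties are an error), and non-monotone RED or MD
#' columns raise a warning only, since clinical tables occasionally contain
#' them around near-water materials.
#'
#' @param knots Data frame with numeric columns `hu`, `red`, `md` and an
#'   optional character `material` annotation column.
#' @param variant One of `"original"`, `"bdp_excluded"`, `"icrp110_brain"`.
#' @return A tibble of class `ct_conversion_table` with a `variant`
#'   attribute, sorted by `hu`.
#' @examples
#' conversion_table(data.frame(hu = c(-1000, 0, 1000),
#'                             red = c(0.001, 1, 1.6),
#'                             md = c(0.001, 1, 1.7)))
#' @export
conversion_table <- function(knots,
                             variant = c("original", "bdp_excluded",
                                         "icrp110_brain")) {
  variant <- match.arg(variant)
  if (!is.data.frame(knots) || !all(c("hu", "red", "md") %in% names(knots))) {
    stop_validation("`knots` needs columns hu, red, md.")
  }
  k <- as_tibble(knots)
  if (!"material" %in% names(k)) k$material <- NA_character_
  k <- k[c("hu", "red", "md", "material")]
  if (nrow(k) < 2) stop_validation("A conversion table needs at least 2 knots.")
  if (anyNA(k$hu) || anyNA(k$red) || anyNA(k$md)) {
    stop_validation("Knot values must be numeric and non-missing.")
  }
  if (any(k$red <= 0) || any(k$md <= 0)) {
    stop_validation("RED and MD must be positive at every knot.")
  }
  if (any(k$hu < -1000)) stop_validation("Knot CT numbers below -1000 HU.")
  k <- arrange(k, .data$hu)
  if (anyDuplicated(k$hu)) {
    stop_validation("Tied CT numbers: knots must be strictly increasing in hu.")
  }
  if (is.unsorted(k$red) || is.unsorted(k$md)) {
    warn("RED/MD not non-decreasing in hu; check the table.",
         class = "ctcal_table_monotonicity")
  }
  structure(k, variant = variant,
            class = c("ct_conversion_table", class(k)))
}

table_variant <- function(table) attr(table, "variant")

#' @export
print.ct_conversion_table <- function(x, ...) {
  cat(sprintf("<ct_conversion_table> variant: %s, %d knots\n",
              table_variant(x), nrow(x)))
  NextMethod()
  invisible(x)
}

#' Read / write a conversion table
#'
#' Plain CSV with header `hu,red,md,material`, one knot per line; a leading
#' `# variant=` comment records the table variant and other `#` lines are
#' free comments. `write_conversion_table()` emits a canonical form whose
#' write-read-write round trip is byte-identical.
#'
#' @param path File path; `read_conversion_table()` defaults to the packaged
#'   clinical table.
#' @return A `ct_conversion_table`; the writer returns `path` invisibly.
#' @examples
#' tbl <- read_conversion_table()
#' head(tbl, 3)
#' @export
read_conversion_table <- function(path = system.file(
    "extdata", "conversion_table_original.csv", package = "ctcal")) {
  lines <- readr::read_lines(path)
  variant <- "original"
  vl <- grep("^#\\s*variant=", lines, value = TRUE)
  if (length(vl) > 0) variant <- trimws(sub("^#\\s*variant=", "", vl[1]))
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  # non-numeric cells surface as NA and are reported as a format error below
  df <- suppressWarnings(readr::read_csv(I(body), show_col_types = FALSE,
                        col_types = readr::cols(
                          hu = readr::col_double(),
                          red = readr::col_double(),
                          md = readr::col_double(),
                          material = readr::col_character())))
  if (anyNA(df$hu) || anyNA(df$red) || anyNA(df$md)) {
    stop_format("Non-numeric cell in conversion table.")
  }
  if (anyDuplicated(df$hu)) stop_format("Duplicate hu knot in conversion table.")
  conversion_table(df, variant = variant)
}

#' @param table A `ct_conversion_table`.
#' @rdname read_conversion_table
#' @export
write_conversion_table <- function(table, path) {
  stopifnot(inherits(table, "ct_conversion_table"))
  num <- function(v) vapply(v, format, character(1), digits = 15)
  mat <- ifelse(is.na(table$material), "", table$material)
  readr::write_lines(c(
    paste0("# variant=", table_variant(table)),
    "hu,red,md,material",
    paste0(num(table$hu), ",", num(table$red), ",", num(table$md), ",", mat)
  ), path)
  invisible(path)
}

#' Interpolating table lookup
#'
#' Piecewise-linear interpolation of RED and MD at arbitrary CT numbers,
#' exact at the knots. Outside the tabulated range the terminal knot values
#' are held constant (clamping), so extreme image artifacts can never map to
#' negative densities.
#'
#' @param table A `ct_conversion_table`.
#' @param hu Numeric vector of CT numbers.
#' @return A tibble with columns `hu`, `red`, `md`, one row per input.
#' @examples
#' hu_lookup(read_conversion_table(), c(-72, 0, 5000))
#' @export
hu_lookup <- function(table, hu) {
  stopifnot(inherits(table, "ct_conversion_table"), is.numeric(hu))
  tibble(
    hu = as.numeric(hu),
    red = approx(table$hu, table$red, xout = hu, method = "linear",
                 rule = 2)$y,
    md = approx(table$hu, table$md, xout = hu, method = "linear",
                rule = 2)$y
  )
}

find_bdp_knot <- function(table, red = NULL, md = NULL) {
  idx <- which(!is.na(table$material) &
                 grepl("bdp", table$material, ignore.case = TRUE))
  if (length(idx) == 0 && !is.null(red) && !is.null(md)) {
    idx <- which(abs(table$red - red) < 1e-9 & abs(table$md - md) < 1e-9)
  }
  if (length(idx) != 1) {
    abort("BDP knot not found (or ambiguous) in conversion table.",
          class = "ctcal_lookup_error")
  }
  idx
}

#' Derive a modified conversion table
#'
#' Builds the two modified table variants compared against the clinical
#' original: `"bdp_excluded"` drops the brain-plug knot entirely, so lookups
#' in its neighbourhood interpolate between its former neighbours;
#' `"icrp110_brain"` keeps the knot's RED/MD but moves its CT number to
#' `brain_hu`, typically the stoichiometric prediction for ICRP 110 brain
#' tissue. The result is revalidated, so a replacement CT number that breaks
#' the strict knot ordering is an error.
#'
#' @param table A `ct_conversion_table` containing a knot annotated as the
#'   BDP (matched case-insensitively on `"bdp"` in `material`, or by exact
#'   `red`/`md` if supplied).
#' @param variant `"bdp_excluded"` or `"icrp110_brain"`.
#' @param brain_hu Replacement CT number (required for `"icrp110_brain"`).
#' @param red,md Optional RED/MD used to identify the BDP knot when no
#'   material annotation is present.
#' @return A new `ct_conversion_table` of the requested variant.
#' @examples
#' orig <- read_conversion_table()
#' modify_table(orig, "bdp_excluded")
#' modify_table(orig, "icrp110_brain", brain_hu = 45.8)
#' @export
modify_table <- function(table, variant = c("bdp_excluded", "icrp110_brain"),
                         brain_hu = NULL, red = NULL, md = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(table, "ct_conversion_table"))
  idx <- find_bdp_knot(table, red = red, md = md)
  k <- as_tibble(table)
  if (variant == "bdp_excluded") {
    k <- k[-idx, ]
  } else {
    if (is.null(brain_hu) || !is.numeric(brain_hu) || length(brain_hu) != 1) {
      stop_validation("`brain_hu` must be supplied for the icrp110_brain variant.")
    }
    lo <- if (idx > 1) k$hu[idx - 1] else -Inf
    hi <- if (idx < nrow(k)) k$hu[idx + 1] else Inf
    if (brain_hu <= lo || brain_hu >= hi) {
      stop_validation(sprintf(
        "Replacement CT number %.4g leaves the BDP knot's (%.4g, %.4g) interval: hu ordering would break.",
        brain_hu, lo, hi))
    }
    k$hu[idx] <- brain_hu
  }
  out <- try(conversion_table(k, variant = variant), silent = TRUE)
  if (inherits(out, "try-error")) {
    stop_validation(
      "Modification breaks the strict hu ordering of the table knots.")
  }
  out
}
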