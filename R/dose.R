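#' Cumulative dose-volume histogram
#'
#' For each dose level d on a regular axis, the percentage of the structure's
#' voxels receiving at least d:
#' \deqn{V(d) = 100 \cdot \#\{v \in mask : D_v \ge d\} / \#mask.}
#' The curve starts at 100 percent, is non-increasing, and reaches 0 one bin
#' beyond the maximum dose.
#'
#' @param dose Numeric array of voxel doses (Gy, non-negative), or a
#'   `dose_grid` from [generate_dose_grid()] (in which case `mask` defaults
#'   to its structure mask).
#' @param mask Logical array matching `dose`; the structure.
#' @param bin_width Dose-axis step in Gy. The default 0.01 Gy keeps
#'   discretization error far below the 0.1 percent differences of interest.
#' @return A tibble of class `dvh_curve` with columns `dose` and
#'   `volume_pct`.
#' @examples
#' g <- generate_dose_grid(c(10, 10, 10), "uniform", list(dose = 30))
#' dvh <- cumulative_dvh(g)
#' dose_at_volume(dvh, c(2, 50, 98))
#' @export
cumulative_dvh <- function(dose, mask = NULL, bin_width = 0.01) {
  if (inherits(dose, "dose_grid")) {
    if (is.null(mask)) mask <- dose$mask
    dose <- dose$dose
  }
  if (is.null(mask)) stop_validation("A structure `mask` is required.")
  if (!identical(dim(dose), dim(mask)) || !is.logical(mask)) {
    stop_validation("`mask` must be a logical array matching `dose`.")
  }
  d <- dose[mask]
  if (length(d) == 0) stop_validation("Empty structure mask.")
  if (any(d < 0)) stop_validation("Negative doses.")
  if (bin_width <= 0) stop_validation("`bin_width` must be positive.")
  axis <- seq(0, max(d) + bin_width, by = bin_width)
  # vectorized count of doses >= each axis value
  counts <- length(d) - findInterval(axis - bin_width * 1e-9, sort(d))
  out <- tibble(dose = axis, volume_pct = 100 * counts / length(d))
  class(out) <- c("dvh_curve", class(out))
  out
}

#' Dose received by the hottest x percent of a structure
#'
#' Reads Dx% off a cumulative DVH: the dose at which the volume curve
#' crosses x percent, linearly interpolated between adjacent dose bins.
#' Quantile monotonicity holds by construction: D98% <= D50% <= D2%.
#'
#' @param curve A `dvh_curve` from [cumulative_dvh()].
#' @param x Volume percentage(s), each strictly between 0 and 100.
#' @return Numeric vector of doses in Gy, one per `x`.
#' @export
dose_at_volume <- function(curve, x) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 100)) {
    stop_validation("`x` must lie strictly between 0 and 100 percent.")
  }
  vol <- curve$volume_pct
  dos <- curve$dose
  vapply(x, function(xi) {
    i <- which(vol <= xi)[1]          # first bin at or below the target volume
    if (is.na(i)) return(dos[length(dos)])
    if (i == 1) return(dos[1])
    if (vol[i] == vol[i - 1]) return(dos[i])
    dos[i - 1] + (vol[i - 1] - xi) / (vol[i - 1] - vol[i]) *
      (dos[i] - dos[i - 1])
  }, numeric(1))
}

#' Relative dose difference
#'
#' The percentage change of a dose metric under a modified conversion table
#' against the clinical reference:
#' \deqn{\Delta D = (D_{mod} - D_{ref}) / D_{ref} \times 100.}
#'
#' @param d_ref Reference dose(s) in Gy; must be positive.
#' @param d_mod Modified-table dose(s) in Gy.
#' @return Relative difference(s) in percent.
#' @examples
#' relative_dose_difference(100, 100.6)
#' @export
relative_dose_difference <- function(d_ref, d_mod) {
  if (any(!is.finite(d_ref)) || any(d_ref <= 0)) {
    stop_validation("`d_ref` must be positive.")
  }
  (d_mod - d_ref) / d_ref * 100
}

#' Per-metric summary of dose differences across cases
#'
#' Summarises case-level relative dose differences in the shape of a
#' multi-case audit table: for every DVH metric (and any additional grouping
#' columns such as algorithm or table variant), the mean and sample SD
#' (n - 1) of the relative difference across cases.
#'
#' @param cases Data frame with columns `case`, `metric`, and either
#'   `delta_pct` or the pair `d_ref`, `d_mod` (from which `delta_pct` is
#'   computed). Any further columns (e.g. `algorithm`, `table_variant`) are
#'   treated as grouping variables. Every case must report the same metric
#'   set within each group.
#' @return A tibble with the grouping columns, `metric`, `n_cases`,
#'   `mean_delta_pct`, `sd_delta_pct`.
#' @examples
#' comparison_report(data.frame(case = rep(1:3, each = 2),
#'                              metric = rep(c("D98%", "D50%"), 3),
#'                              d_ref = 30, d_mod = c(30.1, 30, 29.9,
#'                                                    30, 30.2, 30.1)))
#' @export
comparison_report <- function(cases) {
  if (!is.data.frame(cases) || !all(c("case", "metric") %in% names(cases))) {
    stop_validation("`cases` needs `case` and `metric` columns.")
  }
  cases <- as_tibble(cases)
  if (!"delta_pct" %in% names(cases)) {
    if (!all(c("d_ref", "d_mod") %in% names(cases))) {
      stop_validation("Provide either `delta_pct` or both `d_ref` and `d_mod`.")
    }
    cases <- mutate(cases,
                    delta_pct = relative_dose_difference(.data$d_ref,
                                                         .data$d_mod))
  }
  if (nrow(cases) == 0) stop_validation("Empty comparison set.")
  grouping <- setdiff(names(cases),
                      c("case", "d_ref", "d_mod", "delta_pct"))
  # each case must carry an identical metric set within its group
  extra <- setdiff(grouping, "metric")
  sets <- cases %>%
    group_by(across(all_of(c(extra, "case")))) %>%
    summarise(key = paste(sort(.data$metric), collapse = "|"),
              .groups = "drop")
  per_group <- if (length(extra) > 0) {
    sets %>% group_by(across(all_of(extra))) %>%
      summarise(nkey = length(unique(.data$key)), .groups = "drop")
  } else {
    summarise(sets, nkey = length(unique(.data$key)))
  }
  if (any(per_group$nkey > 1)) {
    stop_validation("Inconsistent metric sets across cases.")
  }
  cases %>%
    group_by(across(all_of(grouping))) %>%
    summarise(n_cases = dplyr::n(),
              mean_delta_pct = mean(.data$delta_pct),
              sd_delta_pct = if (dplyr::n() > 1) sd(.data$delta_pct) else 0,
              .groups = "drop")
}

#' Dose-metric comparison of two conversion tables on a synthetic plan
#'
#' End-to-end synthetic analogue of a table-swap audit: generates a dose
#' grid, perturbs the voxel doses by the ratio of mass densities the two
#' conversion tables assign to a brain-like CT-number region, and extracts
#' D2%, D50% and D98% under both, returning the per-metric relative
#' differences. The perturbation is a deliberately simple first-order density
#' scaling — a stand-in for a dose engine, not a model of one.
#'
#' @param reference,modified `ct_conversion_table` objects.
#' @param tissue_hu CT number representative of the structure (HU).
#' @param grid A `dose_grid`; default is a spherical-falloff plan.
#' @param bin_width DVH bin width in Gy.
#' @return A tibble with columns `metric`, `d_ref`, `d_mod`, `delta_pct`.
#' @examples
#' orig <- read_conversion_table()
#' compare_tables_dose(orig, modify_table(orig, "bdp_excluded"))
#' @export
compare_tables_dose <- function(reference, modified, tissue_hu = 37.3,
                                grid = generate_dose_grid(
                                  c(40, 40, 40), "spherical_falloff",
                                  list(center_dose = 60), seed = 1),
                                bin_width = 0.01) {
  stopifnot(inherits(reference, "ct_conversion_table"),
            inherits(modified, "ct_conversion_table"))
  md_ref <- hu_lookup(reference, tissue_hu)$md
  md_mod <- hu_lookup(modified, tissue_hu)$md
  dvh_ref <- cumulative_dvh(grid, bin_width = bin_width)
  scaled <- grid
  scaled$dose <- grid$dose * (md_ref / md_mod)
  dvh_mod <- cumulative_dvh(scaled, bin_width = bin_width)
  metrics <- c("D2%" = 2, "D50%" = 50, "D98%" = 98)
  d_ref <- dose_at_volume(dvh_ref, unname(metrics))
  d_mod <- dose_at_volume(dvh_mod, unname(metrics))
  tibble(metric = names(metrics), d_ref = d_ref, d_mod = d_mod,
         delta_pct = relative_dose_difference(d_ref, d_mod))
}
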