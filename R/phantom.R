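#' Phantom slice layout
#'
#' Geometry of a synthetic calibration-phantom CT slice: a pixel grid with a
#' homogeneous background and circular plug inserts, each with its own mean
#' CT number and Gaussian pixel-noise SD. Coordinates are in cm with the
#' origin at the image corner; pixel (i, j) has its center at
#' ((j - 0.5) * spacing, (i - 0.5) * spacing).
#'
#' @param shape Integer vector `c(rows, cols)`.
#' @param spacing Pixel spacing in cm/pixel.
#' @param plugs Data frame with columns `x_cm`, `y_cm` (center), `radius_cm`,
#'   `material`, `mean_hu`, `sd_hu`. Plugs must lie inside the image and must
#'   not overlap.
#' @param background_mean,background_sd Background CT-number mean and noise
#'   SD in HU.
#' @return A list of class `phantom_layout`.
#' @examples
#' phantom_layout(c(128, 128), spacing = 0.1,
#'                plugs = data.frame(x_cm = 6.4, y_cm = 6.4, radius_cm = 1.4,
#'                                   material = "BDP", mean_hu = 23.3,
#'                                   sd_hu = 15))
#' @export
phantom_layout <- function(shape, spacing, plugs,
                           background_mean = 0, background_sd = 0) {
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 1)) {
    stop_validation("`shape` must be two positive integers (rows, cols).")
  }
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0) {
    stop_validation("`spacing` must be a single positive number (cm/pixel).")
  }
  req <- c("x_cm", "y_cm", "radius_cm", "material", "mean_hu", "sd_hu")
  if (!is.data.frame(plugs) || !all(req %in% names(plugs))) {
    stop_validation(paste("`plugs` needs columns", paste(req, collapse = ", ")))
  }
  plugs <- as_tibble(plugs)[req]
  if (any(plugs$radius_cm <= 0)) stop_validation("Plug radii must be positive.")
  if (any(plugs$sd_hu < 0)) stop_validation("Plug noise SDs must be non-negative.")
  w <- shape[2] * spacing; h <- shape[1] * spacing
  inside <- plugs$x_cm - plugs$radius_cm >= 0 & plugs$x_cm + plugs$radius_cm <= w &
    plugs$y_cm - plugs$radius_cm >= 0 & plugs$y_cm + plugs$radius_cm <= h
  if (!all(inside)) stop_validation("All plugs must lie inside the image.")
  if (nrow(plugs) > 1) {
    for (a in seq_len(nrow(plugs) - 1)) {
      for (b in seq(a + 1, nrow(plugs))) {
        d <- sqrt((plugs$x_cm[a] - plugs$x_cm[b])^2 +
                    (plugs$y_cm[a] - plugs$y_cm[b])^2)
        if (d < plugs$radius_cm[a] + plugs$radius_cm[b]) {
          stop_validation(sprintf("Plugs %d and %d overlap.", a, b))
        }
      }
    }
  }
  structure(list(shape = shape, spacing = spacing, plugs = plugs,
                 background_mean = background_mean,
                 background_sd = background_sd),
            class = "phantom_layout")
}

pixel_centers <- function(shape, spacing) {
  list(x = ((seq_len(shape[2])) - 0.5) * spacing,
       y = ((seq_len(shape[1])) - 0.5) * spacing)
}

#' Generate a synthetic phantom CT slice
#'
#' Draws every pixel independently from a Gaussian with its region's mean and
#' SD (a plug if the pixel center falls inside one, otherwise the
#' background). With `sd_hu = 0` the image is exactly piecewise-constant.
#' Reproducible: the same seed always yields the same image, without
#' touching the global RNG state.
#'
#' @param layout A [phantom_layout()].
#' @param seed Integer seed.
#' @return A numeric matrix of CT numbers (HU) of dimension `layout$shape`.
#' @examples
#' lay <- phantom_layout(c(64, 64), 0.1,
#'                       data.frame(x_cm = 3.2, y_cm = 3.2, radius_cm = 1,
#'                                  material = "BDP", mean_hu = 23.3, sd_hu = 0))
#' img <- generate_phantom_image(lay, seed = 1)
#' @export
generate_phantom_image <- function(layout, seed) {
  stopifnot(inherits(layout, "phantom_layout"))
  ctr <- pixel_centers(layout$shape, layout$spacing)
  mean_img <- matrix(layout$background_mean, layout$shape[1], layout$shape[2])
  sd_img <- matrix(layout$background_sd, layout$shape[1], layout$shape[2])
  xg <- matrix(ctr$x, layout$shape[1], layout$shape[2], byrow = TRUE)
  yg <- matrix(ctr$y, layout$shape[1], layout$shape[2])
  for (i in seq_len(nrow(layout$plugs))) {
    p <- layout$plugs[i, ]
    inside <- (xg - p$x_cm)^2 + (yg - p$y_cm)^2 <= p$radius_cm^2
    mean_img[inside] <- p$mean_hu
    sd_img[inside] <- p$sd_hu
  }
  withr::with_seed(as.integer(seed), {
    matrix(rnorm(length(mean_img), mean = mean_img, sd = sd_img),
           layout$shape[1], layout$shape[2])
  })
}

#' Circular region-of-interest mask
#'
#' Boolean mask of the pixels whose centers fall inside a circle, the
#' convention used when reading mean CT numbers off a homogeneous plug. The
#' default diameter of 1.53 cm matches a routine plug-measurement ROI.
#'
#' @param shape Image dimensions `c(rows, cols)`.
#' @param center Circle center `c(x_cm, y_cm)`.
#' @param spacing Pixel spacing in cm/pixel.
#' @param diameter ROI diameter in cm.
#' @return A logical matrix of dimension `shape`.
#' @examples
#' m <- circular_roi_mask(c(200, 200), center = c(1, 1), spacing = 0.01)
#' sum(m)  # ~ pi * 0.765^2 / 0.01^2
#' @export
circular_roi_mask <- function(shape, center, spacing, diameter = 1.53) {
  shape <- as.integer(shape)
  if (diameter <= 0 || spacing <= 0) {
    stop_validation("`diameter` and `spacing` must be positive.")
  }
  r <- diameter / 2
  w <- shape[2] * spacing; h <- shape[1] * spacing
  if (center[1] - r < 0 || center[1] + r > w ||
      center[2] - r < 0 || center[2] + r > h) {
    stop_validation("ROI circle extends outside the image.")
  }
  ctr <- pixel_centers(shape, spacing)
  xg <- matrix(ctr$x, shape[1], shape[2], byrow = TRUE)
  yg <- matrix(ctr$y, shape[1], shape[2])
  (xg - center[1])^2 + (yg - center[2])^2 <= r^2
}

#' ROI statistics and histogram
#'
#' Mean, population SD (divide by n) and a fixed-width histogram of the CT
#' numbers inside a mask — the summary reported for a plug or tissue ROI.
#' Histogram bins are aligned to multiples of `bin_width` and cover the
#' observed range, so counts always sum to the pixel count.
#'
#' @param image Numeric matrix of CT numbers.
#' @param mask Logical matrix of the same dimension; must select at least one
#'   pixel.
#' @param bin_width Histogram bin width in HU.
#' @return A list of class `roi_statistics`: `mean_hu`, `sd_hu`, `n`, and a
#'   `histogram` tibble (`bin_left`, `bin_right`, `count`).
#' @examples
#' img <- matrix(c(10, 20, 30, 40), 2)
#' roi_statistics(img, matrix(TRUE, 2, 2))
#' @export
roi_statistics <- function(image, mask, bin_width = 5) {
  if (!is.logical(mask) || !identical(dim(image), dim(mask))) {
    stop_validation("`mask` must be a logical matrix matching `image`.")
  }
  vals <- image[mask]
  if (length(vals) == 0) stop_validation("Empty ROI mask.")
  if (bin_width <= 0) stop_validation("`bin_width` must be positive.")
  n <- length(vals)
  mu <- mean(vals)
  sigma <- sqrt(sum((vals - mu)^2) / n)
  lo <- floor(min(vals) / bin_width) * bin_width
  hi <- ceiling(max(vals) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  counts <- tabulate(pmin(findInterval(vals, edges,
                                       rightmost.closed = TRUE),
                          length(edges) - 1),
                     nbins = length(edges) - 1)
  structure(
    list(mean_hu = mu, sd_hu = sigma, n = n,
         histogram = tibble(bin_left = edges[-length(edges)],
                            bin_right = edges[-1],
                            count = as.integer(counts))),
    class = "roi_statistics")
}

#' @export
print.roi_statistics <- function(x, ...) {
  cat(sprintf("<roi_statistics> mean %.2f HU, SD %.2f HU over %d pixels (%d bins)\n",
              x$mean_hu, x$sd_hu, x$n, nrow(x$histogram)))
  invisible(x)
}

#' @rdname roi_statistics
#' @param x An `roi_statistics` object.
#' @param ... Unused.
#' @method tidy roi_statistics
#' @export
tidy.roi_statistics <- function(x, ...) {
  tibble(mean_hu = x$mean_hu, sd_hu = x$sd_hu, n = x$n)
}

#' Cohort summary of per-case CT-number statistics
#'
#' Aggregates per-case ROI summaries the way multi-patient CT-number audits
#' report them: the overall mean is the arithmetic mean of the case means and
#' the overall SD is the arithmetic mean of the case SDs (not a pooled SD).
#'
#' @param cases Data frame with numeric columns `mean_hu` and `sd_hu`, one
#'   row per case.
#' @return A one-row tibble: `n_cases`, `mean_hu`, `sd_hu`.
#' @examples
#' summarize_cohort(data.frame(mean_hu = c(33.8, 33.9), sd_hu = c(16.1, 13.0)))
#' @export
summarize_cohort <- function(cases) {
  if (!is.data.frame(cases) || !all(c("mean_hu", "sd_hu") %in% names(cases))) {
    stop_validation("`cases` needs columns mean_hu and sd_hu.")
  }
  if (nrow(cases) == 0) stop_validation("Empty case list.")
  if (anyNA(cases$mean_hu) || anyNA(cases$sd_hu)) {
    stop_validation("Missing values in case summaries.")
  }
  tibble(n_cases = nrow(cases),
         mean_hu = mean(cases$mean_hu),
         sd_hu = mean(cases$sd_hu))
}

#' Generate a synthetic dose grid with a structure mask
#'
#' Produces a 3-D dose distribution and a structure mask for exercising
#' DVH machinery, standing in for planning-system dose exports. Patterns:
#' `"uniform"` (constant dose inside the mask), `"linear_ramp"` (dose varies
#' linearly along the first axis from `low` to `high` across the mask, so
#' its DVH is analytically linear), and `"spherical_falloff"` (dose
#' `center_dose * (1 - (r/R)^2)` around the grid center). Optional Gaussian
#' noise of SD `noise_sd` is added inside the mask; generation is
#' seed-reproducible.
#'
#' @param shape Integer vector `c(nx, ny, nz)` of grid dimensions.
#' @param pattern One of `"uniform"`, `"linear_ramp"`, `"spherical_falloff"`.
#' @param params Named list of pattern parameters: `dose` (uniform, default
#'   30), `low`/`high` (ramp, default 0/100), `center_dose`/`radius_frac`
#'   (falloff, default 60/0.45), `noise_sd` (all, default 0). Doses in Gy.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return A list of class `dose_grid`: `dose` (numeric array), `mask`
#'   (logical array), `pattern`.
#' @examples
#' g <- generate_dose_grid(c(20, 20, 20), "linear_ramp",
#'                         list(low = 0, high = 100), seed = 1)
#' range(g$dose[g$mask])
#' @export
generate_dose_grid <- function(shape, pattern = c("uniform", "linear_ramp",
                                                  "spherical_falloff"),
                               params = list(), seed = 1) {
  if (is.character(pattern) && length(pattern) == 1 &&
      !pattern %in% c("uniform", "linear_ramp", "spherical_falloff")) {
    stop_validation(sprintf("Unknown dose pattern '%s'.", pattern))
  }
  pattern <- match.arg(pattern)
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1)) {
    stop_validation("`shape` must be three positive integers.")
  }
  noise_sd <- params$noise_sd %||% 0
  ix <- slice.index(array(0, shape), 1)
  dose <- array(0, shape)
  if (pattern == "spherical_falloff") {
    ctr <- (shape + 1) / 2
    rad <- (params$radius_frac %||% 0.45) * min(shape)
    cd <- params$center_dose %||% 60
    iy <- slice.index(dose, 2); iz <- slice.index(dose, 3)
    r2 <- ((ix - ctr[1])^2 + (iy - ctr[2])^2 + (iz - ctr[3])^2) / rad^2
    mask <- r2 <= 1
    dose[mask] <- cd * (1 - r2[mask])
  } else {
    # central box structure spanning the middle half of each axis
    lo <- pmax(1L, floor(shape / 4) + 1L)
    hi <- pmin(shape, ceiling(3 * shape / 4))
    mask <- array(FALSE, shape)
    mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    if (pattern == "uniform") {
      dose[mask] <- params$dose %||% 30
    } else {
      low <- params$low %||% 0; high <- params$high %||% 100
      frac <- (ix - lo[1]) / max(1L, hi[1] - lo[1])
      dose[mask] <- low + (high - low) * frac[mask]
    }
  }
  if (noise_sd > 0) {
    dose <- withr::with_seed(as.integer(seed), {
      dose + array(rnorm(length(dose), 0, noise_sd), shape) * mask
    })
  }
  structure(list(dose = dose, mask = mask, pattern = pattern),
            class = "dose_grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
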