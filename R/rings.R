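#' Annular ring grid around trapping sites
#'
#' Defines the concentric distance rings over which land-cover proportions
#' are extracted around a site.  The default grid uses 100 rings of 0.1 km
#' width from 0 to 10 km, the resolution at which the distance-weighted
#' covariate and its scale of effect are computed.
#'
#' @param max_km outer radius of the largest ring, in km.
#' @param width_km ring width, in km.  Must divide `max_km` evenly.
#' @param cell_counts optional integer vector (one per ring) of raster-cell
#'   counts used as the area weight of each ring.  When `NULL`, ideal
#'   annulus areas (proportional to the ring midpoint for a constant-width
#'   grid) are used.
#' @return An object of class `ring_grid` with elements `edges`
#'   (length `n + 1`, starting at 0), `midpoints` (length `n`), `width`,
#'   and `cell_counts`.
#' @examples
#' g <- ring_grid()
#' length(g$midpoints)  # 100
#' @export
ring_grid <- function(max_km = 10, width_km = 0.1, cell_counts = NULL) {
  stopifnot(max_km > 0, width_km > 0)
  n <- round(max_km / width_km)
  if (abs(n * width_km - max_km) > 1e-9)
    stop("'width_km' must divide 'max_km' evenly")
  edges <- seq(0, max_km, length.out = n + 1)
  mids <- (edges[-1] + edges[-(n + 1)]) / 2
  if (is.null(cell_counts)) {
    ## ideal annulus areas pi*(e_i^2 - e_{i-1}^2); only relative size matters
    cell_counts <- pi * (edges[-1]^2 - edges[-(n + 1)]^2)
  }
  if (length(cell_counts) != n || any(cell_counts < 0))
    stop("'cell_counts' must be a nonnegative vector with one entry per ring")
  structure(list(edges = edges, midpoints = mids, width = width_km,
                 cell_counts = cell_counts),
            class = "ring_grid")
}

#' @export
print.ring_grid <- function(x, ...) {
  cat(sprintf("Ring grid: %d rings of %.3g km from 0 to %.3g km\n",
              length(x$midpoints), x$width, max(x$edges)))
  invisible(x)
}

#' Extract ring-wise land-cover proportions around trap points
#'
#' For each ring, computes the proportion of raster cells whose center lies
#' within that distance band of the *nearest* trap point that are classified
#' as the focal cover (value 1).  Rings are half-open intervals, lower-open
#' and upper-closed, except that a cell-center distance of exactly zero is
#' assigned to ring 1.
#'
#' @param raster numeric matrix of 0/1 values (rows = northing, columns =
#'   easting); any other value is rejected.  `NA` cells are ignored.
#' @param trap_xy two-column matrix or data frame of planar trap coordinates
#'   in the same units as `cellsize`.
#' @param cellsize raster cell size in meters.
#' @param origin coordinates `c(x, y)` of the lower-left corner of the
#'   raster, in meters.  Defaults to `c(0, 0)`.
#' @param grid a [ring_grid()].
#' @param partial what to do when the raster does not extend to the outer
#'   ring everywhere: `"error"` stops; `"flag"` leaves uncovered rings as
#'   flagged-missing (`NA`) values.  Rings containing no cell centers are
#'   always returned as `NA` and listed in the `empty_rings` attribute,
#'   never as zero.
#' @return numeric vector of ring proportions in `[0, 1]` (length equal to
#'   the number of rings) with attributes `cell_counts` (cells per ring) and
#'   `empty_rings` (integer indices of rings with no cells).
#' @export
extract_ring_proportions <- function(raster, trap_xy, cellsize,
                                     origin = c(0, 0), grid = ring_grid(),
                                     partial = c("error", "flag")) {
  partial <- match.arg(partial)
  raster <- as.matrix(raster)
  vals <- raster[!is.na(raster)]
  if (length(vals) == 0L) stop("raster has no non-missing cells")
  if (!all(vals %in% c(0, 1))) stop("raster is not binary: values must be 0 or 1")
  trap_xy <- as.matrix(trap_xy)[, 1:2, drop = FALSE]
  if (nrow(trap_xy) < 1L) stop("at least one trap point is required")

  nr <- nrow(raster); nc <- ncol(raster)
  ## cell centers; row 1 = top of the grid (northernmost), like image rasters
  cx <- origin[1] + (seq_len(nc) - 0.5) * cellsize
  cy <- origin[2] + (nr - seq_len(nr) + 0.5) * cellsize

  max_m <- max(grid$edges) * 1000
  covered <- all(
    apply(trap_xy, 1L, function(p) {
      p[1] - max_m >= origin[1] && p[1] + max_m <= origin[1] + nc * cellsize &&
      p[2] - max_m >= origin[2] && p[2] + max_m <= origin[2] + nr * cellsize
    })
  )
  if (!covered && partial == "error")
    stop("raster does not extend ", max(grid$edges),
         " km beyond every trap point; use partial = \"flag\" to allow")

  ## distance (km) from each cell center to the nearest trap
  d2 <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(trap_xy))) {
    dx2 <- (cx - trap_xy[k, 1])^2
    dy2 <- (cy - trap_xy[k, 2])^2
    d2 <- pmin(d2, outer(dy2, dx2, "+"))
  }
  d_km <- sqrt(d2) / 1000

  keep <- !is.na(raster)
  ring <- cut(d_km[keep], breaks = grid$edges, labels = FALSE,
              include.lowest = TRUE)   # (lo, hi], d = 0 goes to ring 1
  ok <- !is.na(ring)
  nrings <- length(grid$midpoints)
  counts <- tabulate(ring[ok], nbins = nrings)
  rice <- vapply(seq_len(nrings), function(i) {
    sum(raster[keep][ok][ring[ok] == i])
  }, numeric(1))

  prop <- ifelse(counts > 0, rice / pmax(counts, 1), NA_real_)
  empty <- which(counts == 0L)
  structure(prop, cell_counts = counts, empty_rings = empty)
}

#' Standardize ring proportions to a common scale
#'
#' Centers and scales all raw ring proportions with a single global mean and
#' SD across every site, year, and ring, so one unit of the standardized
#' covariate means the same amount of cover everywhere.  The sample SD
#' (divisor `n - 1`, the [stats::sd()] convention) is used and recorded so
#' the transformation is exactly invertible.
#'
#' Flagged-missing rings (`NA`) are imputed at the global mean (standardized
#' value 0) with a warning rather than treated as zero cover.
#'
#' @param raw numeric array of proportions in `[0, 1]`, typically
#'   site x year x ring.
#' @return A list with `standardized` (same shape as `raw`), and `scaling`
#'   (`mean`, `sd`, `sd_type = "sample"`).
#' @seealso [unstandardize_rings()]
#' @export
standardize_rings <- function(raw) {
  v <- as.vector(raw)
  if (any(!is.na(v) & (v < 0 | v > 1)))
    stop("raw ring proportions must lie in [0, 1]")
  if (sum(!is.na(v)) < 2L) stop("need at least 2 non-missing values")
  m <- mean(v, na.rm = TRUE)
  s <- stats::sd(v, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("ring proportions are constant; SD is 0")
  z <- (raw - m) / s
  if (anyNA(v)) {
    warning(sum(is.na(v)), " flagged-missing ring value(s) imputed at the ",
            "global mean (standardized value 0)")
    z[is.na(z)] <- 0
  }
  list(standardized = z, scaling = list(mean = m, sd = s, sd_type = "sample"))
}

#' Invert ring standardization
#'
#' @param standardized array produced by [standardize_rings()].
#' @param scaling the `scaling` element returned by [standardize_rings()].
#' @return array of raw proportions.
#' @export
unstandardize_rings <- function(standardized, scaling) {
  standardized * scaling$sd + scaling$mean
}

#' Distance-weight kernel over rings
#'
#' Gaussian per-unit-area decay: the weight of ring *i* is proportional to
#' `A_i * exp(-m_i^2 / (2 * sigma^2))` where `m_i` is the ring midpoint and
#' `A_i` its cell count (area), normalized to sum to one.  With the kernel
#' scale `sigma` estimated in the demographic model, this yields the
#' distance-weighted landscape covariate and its derived scale of effect.
#'
#' @param sigma kernel scale in km; must be positive.
#' @param grid a [ring_grid()].
#' @return numeric weight vector summing to 1, one entry per ring.
#' @export
kernel_weights <- function(sigma, grid = ring_grid()) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("'sigma' must be a single positive number")
  w <- grid$cell_counts * exp(-grid$midpoints^2 / (2 * sigma^2))
  if (sum(w) <= 0) stop("all kernel weights are zero; check the ring grid")
  w / sum(w)
}

#' Distance-weighted landscape covariate for one site-year
#'
#' The scalar covariate is the weighted sum of standardized ring values,
#' `R_w = sum_i w_i x_i`.
#'
#' @param w normalized weight vector from [kernel_weights()].
#' @param x standardized ring vector for one site-year.
#' @return scalar covariate value.
#' @export
weighted_covariate <- function(w, x) {
  if (length(w) != length(x)) stop("'w' and 'x' lengths differ")
  if (abs(sum(w) - 1) > 1e-8) stop("'w' must be normalized to sum to 1")
  sum(w * x)
}

#' Scale of effect of a distance-weighted covariate
#'
#' Summarizes a kernel by (1) `scale_max`, the midpoint of the ring with
#' maximal weight, and (2) `scale_90`, the smallest ring outer edge at which
#' cumulative weight reaches 90%.  When applied to posterior draws of
#' `sigma`, compute these per draw and summarize the draws.
#'
#' @inheritParams kernel_weights
#' @return list with `sigma`, `scale_max`, and `scale_90`, in km.
#' @export
effect_scales <- function(sigma, grid = ring_grid()) {
  w <- kernel_weights(sigma, grid)
  i_max <- which.max(w)
  cum <- cumsum(w)
  i_90 <- which(cum >= 0.90)[1]
  list(sigma = sigma,
       scale_max = grid$midpoints[i_max],
       scale_90 = grid$edges[i_90 + 1L])
}

#' Build a ring covariate set from a site x year x ring array
#'
#' Bundles raw proportions, their standardized version, the scaling record,
#' and the ring grid into the container consumed by [fit_growth()] and
#' [fit_cmr()].
#'
#' @param raw 3-d array (site x year x ring) of proportions in `[0, 1]`,
#'   with dimnames giving site and year labels.
#' @param grid a [ring_grid()] whose ring count matches `dim(raw)[3]`.
#' @return object of class `ring_covariates` with elements `raw`,
#'   `standardized`, `scaling`, `grid`, `sites`, `years`.
#' @export
ring_covariates <- function(raw, grid = ring_grid()) {
  stopifnot(length(dim(raw)) == 3L)
  if (dim(raw)[3] != length(grid$midpoints))
    stop("third dimension of 'raw' must match the number of rings")
  std <- standardize_rings(raw)
  sites <- dimnames(raw)[[1]]
  years <- dimnames(raw)[[2]]
  if (is.null(sites)) sites <- as.character(seq_len(dim(raw)[1]))
  if (is.null(years)) years <- as.character(seq_len(dim(raw)[2]))
  structure(list(raw = raw, standardized = std$standardized,
                 scaling = std$scaling, grid = grid,
                 sites = sites, years = years),
            class = "ring_covariates")
}

#' @export
print.ring_covariates <- function(x, ...) {
  cat(sprintf("Ring covariates: %d sites x %d years x %d rings\n",
              dim(x$raw)[1], dim(x$raw)[2], dim(x$raw)[3]))
  cat(sprintf("  scaling: mean %.4f, %s SD %.4f\n", x$scaling$mean,
              x$scaling$sd_type, x$scaling$sd))
  invisible(x)
}

#' Read / write a ring proportion table
#'
#' Long CSV with columns `site`, `year`, `ring_index` and `proportion`;
#' every site-year must carry the full set of rings.
#'
#' @param path CSV file path.
#' @param grid a [ring_grid()].
#' @return for the reader, a [ring_covariates()] object.
#' @export
read_rings <- function(path, grid = ring_grid()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "year", "ring_index", "proportion")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ring CSV is missing column(s): ",
                         paste(miss, collapse = ", "))
  nrings <- length(grid$midpoints)
  sites <- sort(unique(as.character(df$site)))
  years <- sort(unique(df$year))
  raw <- array(NA_real_, c(length(sites), length(years), nrings),
               dimnames = list(sites, years, NULL))
  idx <- cbind(match(as.character(df$site), sites),
               match(df$year, years), df$ring_index)
  raw[idx] <- df$proportion
  if (anyNA(raw))
    stop("ring CSV does not cover every site x year x ring combination")
  ring_covariates(raw, grid)
}

#' @rdname read_rings
#' @param rings a [ring_covariates()] object to write.
#' @export
write_rings <- function(rings, path) {
  d <- dim(rings$raw)
  df <- expand.grid(site = rings$sites, year = rings$years,
                    ring_index = seq_len(d[3]), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  df$proportion <- as.vector(rings$raw)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a plain-text or TIFF binary land-cover raster
#'
#' Plain-text rasters use the ESRI ASCII grid header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, optional `NODATA_value`) followed by
#' rows of 0/1 values, northernmost row first.  Single-band TIFF files are
#' read through the 'tiff' package when available; because plain TIFF carries
#' no georeferencing, `cellsize` and `origin` must then be supplied to
#' [extract_ring_proportions()] by the caller.
#'
#' @param path raster file path.
#' @return list with `values` (matrix), `cellsize` (m), `origin` (x, y of the
#'   lower-left corner; `NA` for TIFF input).
#' @export
read_landcover_raster <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF rasters requires the 'tiff' package")
    m <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    return(list(values = m, cellsize = NA_real_, origin = c(NA_real_, NA_real_)))
  }
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header must contain ncols, nrows and cellsize")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid has ", length(vals), " values; expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  origin <- c(hdr$xllcorner %||% 0, hdr$yllcorner %||% 0)
  list(values = m, cellsize = hdr$cellsize, origin = origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
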