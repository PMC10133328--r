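#' Land-cover raster
#'
#' Lightweight container for one unit's categorical land-cover grid.
#' The grid is an integer matrix in row-major visual orientation (row 1
#' is the top of the map), with class codes from [lc_legend()].
#'
#' @param grid Integer matrix of legend codes.
#' @param pixel_size Pixel edge length in metres (> 0).
#' @param origin Numeric length-2, (x, y) of the lower-left corner in
#'   projected metres.
#' @return An object of class `lc_raster`: a list with elements `grid`,
#'   `pixel_size`, `origin`.
#' @export
#' @examples
#' r <- lc_raster(matrix(c(1, 2, 3, 3), 2, 2), pixel_size = 25)
#' class_area(r, 3)
lc_raster <- function(grid, pixel_size = 25, origin = c(0, 0)) {
  if (!is.matrix(grid)) stop("grid must be a matrix")
  storage.mode(grid) <- "integer"
  bad <- setdiff(unique(as.vector(grid)), unname(lc_legend()))
  if (length(bad) > 0) {
    stop("unknown land-cover class code(s): ", paste(bad, collapse = ", "))
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    stop("pixel_size must be a single positive number")
  }
  if (length(origin) != 2 || !is.numeric(origin)) {
    stop("origin must be numeric of length 2")
  }
  structure(list(grid = grid, pixel_size = as.numeric(pixel_size),
                 origin = as.numeric(origin)),
            class = "lc_raster")
}

#' @export
print.lc_raster <- function(x, ...) {
  tab <- table(factor(as.vector(x$grid), levels = unname(lc_legend()),
                      labels = names(lc_legend())))
  cat(sprintf("<lc_raster> %d x %d pixels @ %g m\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size))
  print(tab)
  invisible(x)
}

#' Read / write a land-cover raster as an Esri ASCII grid
#'
#' Plain-text raster exchange format: a six-line header (NCOLS, NROWS,
#' XLLCORNER, YLLCORNER, CELLSIZE, NODATA_VALUE) followed by rows of
#' cell values, top row first. Nodata is stored as code 0, so the
#' round trip `write_raster()` then `read_raster()` reproduces the grid
#' exactly.
#'
#' @param path File path.
#' @return `read_raster()` returns an [lc_raster()]; `write_raster()`
#'   returns `path` invisibly.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[toupper(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER", "CELLSIZE",
            "NODATA_VALUE")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path)
  }
  nc <- hdr$NCOLS; nr <- hdr$NROWS
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop("grid body has ", length(vals), " values, expected ", nr * nc)
  }
  vals[vals == hdr$NODATA_VALUE] <- 0
  grid <- matrix(as.integer(vals), nrow = nr, ncol = nc, byrow = TRUE)
  lc_raster(grid, pixel_size = hdr$CELLSIZE,
            origin = c(hdr$XLLCORNER, hdr$YLLCORNER))
}

#' @rdname read_raster
#' @param raster An [lc_raster()].
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "lc_raster"))
  g <- raster$grid
  hdr <- c(sprintf("NCOLS %d", ncol(g)),
           sprintf("NROWS %d", nrow(g)),
           sprintf("XLLCORNER %.6g", raster$origin[1]),
           sprintf("YLLCORNER %.6g", raster$origin[2]),
           sprintf("CELLSIZE %.10g", raster$pixel_size),
           "NODATA_VALUE 0")
  body <- apply(g, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Area covered by one land-cover class
#'
#' @param raster An [lc_raster()].
#' @param class_code Legend code (see [lc_legend()]).
#' @return Area in square metres: pixel count times pixel_size^2.
#' @export
class_area <- function(raster, class_code) {
  stopifnot(inherits(raster, "lc_raster"))
  if (!class_code %in% lc_legend()) {
    stop("class code not in legend: ", class_code)
  }
  sum(raster$grid == class_code) * raster$pixel_size^2
}

# matrix shifted by (dr, dc), padding with `fill`
shift_matrix <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Label patches of one class
#'
#' Connected-component labeling of all pixels of a class, under 4- or
#' 8-connectivity, together with per-patch pixel and exposed-edge
#' counts. An edge is exposed when its neighbour across the edge is a
#' different class, nodata, or the grid boundary; the embankment of a
#' unit therefore counts as patch perimeter.
#'
#' @param raster An [lc_raster()].
#' @param class_code Legend code of the class to label.
#' @param connectivity 4 (default) or 8.
#' @return An object of class `patch_set`: list with `labels` (integer
#'   matrix, 0 = not this class), `patches` (data.frame with columns
#'   `patch_id`, `n_pixels`, `n_edges`), `class_code`, `pixel_size`,
#'   `connectivity`.
#' @export
label_patches <- function(raster, class_code, connectivity = 4) {
  stopifnot(inherits(raster, "lc_raster"))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  if (!class_code %in% lc_legend()) {
    stop("class code not in legend: ", class_code)
  }
  mask <- raster$grid == class_code
  labels <- cpp_label_components(mask, as.integer(connectivity))
  np <- max(labels)
  if (np == 0) {
    patches <- data.frame(patch_id = integer(), n_pixels = integer(),
                          n_edges = integer())
  } else {
    n_pixels <- tabulate(labels[labels > 0], nbins = np)
    n_edges <- integer(np)
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      nbr <- shift_matrix(mask, d[1], d[2], fill = FALSE)
      exposed <- mask & !nbr
      n_edges <- n_edges + tabulate(labels[exposed], nbins = np)
    }
    patches <- data.frame(patch_id = seq_len(np), n_pixels = n_pixels,
                          n_edges = n_edges)
  }
  structure(list(labels = labels, patches = patches,
                 class_code = class_code, pixel_size = raster$pixel_size,
                 connectivity = connectivity),
            class = "patch_set")
}

#' Patch perimeter
#'
#' Exposed-edge count of one patch times the pixel size.
#'
#' @param patchset A `patch_set` from [label_patches()].
#' @param patch_id Patch id.
#' @return Perimeter in metres.
#' @export
patch_perimeter <- function(patchset, patch_id) {
  stopifnot(inherits(patchset, "patch_set"))
  row <- patchset$patches[patchset$patches$patch_id == patch_id, ]
  if (nrow(row) != 1) stop("unknown patch id: ", patch_id)
  row$n_edges * patchset$pixel_size
}

#' Normalised difference vegetation index
#'
#' Per-pixel (NIR - Red) / (NIR + Red). Pixels where both bands are
#' zero are returned as NA (nodata).
#'
#' @param red_band,nir_band Non-negative numeric matrices of equal
#'   dimension (reflectances).
#' @return Numeric matrix in \[-1, 1\] (NA where undefined).
#' @export
ndvi <- function(red_band, nir_band) {
  if (!is.matrix(red_band) || !is.matrix(nir_band) ||
      !identical(dim(red_band), dim(nir_band))) {
    stop("red and NIR bands must be matrices of identical dimension")
  }
  if (any(red_band < 0, na.rm = TRUE) || any(nir_band < 0, na.rm = TRUE)) {
    stop("reflectances must be non-negative")
  }
  denom <- nir_band + red_band
  out <- (nir_band - red_band) / denom
  out[denom == 0] <- NA_real_
  out
}

#' Detect vegetation patches from an annual NDVI stack
#'
#' Flags pixels whose across-years mean NDVI falls inside a closed
#' interval. Used to locate halophyte (Salicornia) patches from a
#' multi-year NDVI series.
#'
#' @param annual_ndvi_stack List of >= 1 NDVI matrices (same dims).
#' @param ndvi_range Numeric length 2, `c(lo, hi)` with lo <= hi; the
#'   interval is closed on both ends.
#' @return Logical matrix; NA-mean pixels are FALSE.
#' @export
detect_vegetation_patches <- function(annual_ndvi_stack, ndvi_range) {
  if (!is.list(annual_ndvi_stack) || length(annual_ndvi_stack) == 0) {
    stop("annual NDVI stack must be a non-empty list of matrices")
  }
  if (length(ndvi_range) != 2 || ndvi_range[1] > ndvi_range[2]) {
    stop("ndvi_range must be c(lo, hi) with lo <= hi")
  }
  dims <- lapply(annual_ndvi_stack, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("all NDVI layers must share the same dimension")
  }
  mean_ndvi <- Reduce(`+`, annual_ndvi_stack) / length(annual_ndvi_stack)
  mask <- mean_ndvi >= ndvi_range[1] & mean_ndvi <= ndvi_range[2]
  mask[is.na(mask)] <- FALSE
  mask
}
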