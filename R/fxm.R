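# Fluorescence-exclusion volume measurement (FXm): a cell in a chamber of
# known height excludes dye, so the intensity deficit under the cell
# integrates to its volume. Microchannel volumes come from cell length times
# the channel cross-section.

#' Fluorescence-exclusion chamber image
#'
#' @param pixels Numeric matrix of intensities (a.u.), >= 0. Row-major grid,
#'   origin top-left; volumes use pixel centers.
#' @param pixel_size Pixel edge in um.
#' @param h_max Chamber roof height in um.
#' @return An object of class `"fxm_image"`.
#' @export
fxm_image <- function(pixels, pixel_size, h_max) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (any(pixels < 0)) stop("intensities must be >= 0")
  if (pixel_size <= 0 || h_max <= 0) stop("pixel_size and h_max must be > 0")
  structure(list(pixels = pixels, pixel_size = pixel_size, h_max = h_max),
            class = "fxm_image")
}

check_mask <- function(mask, dim_img, what) {
  if (!is.matrix(mask) || !identical(dim(mask), dim_img))
    stop(what, " must be a logical matrix matching the image dimensions")
  storage.mode(mask) <- "logical"
  mask
}

#' Calibrate an exclusion image
#'
#' The intensity-to-height factor is `alpha_cal = (I_max - I_min) / h_max`,
#' with `I_max` the mean intensity under the empty roof (no object) and
#' `I_min` the mean under a full-height pillar.
#'
#' @param image An [fxm_image()].
#' @param roof_mask,pillar_mask Logical matrices selecting empty-roof and
#'   pillar pixels; non-empty and disjoint.
#' @return A list of class `"fxm_calibration"` with `I_max`, `I_min`,
#'   `alpha_cal` (units/um).
#' @export
#' @examples
#' px <- matrix(2000, 4, 4); px[1:2, 1:2] <- 1000
#' img <- fxm_image(px, pixel_size = 1, h_max = 20)
#' pil <- roof <- matrix(FALSE, 4, 4); pil[1:2, 1:2] <- TRUE
#' roof[3:4, 3:4] <- TRUE
#' fxm_calibrate(img, roof, pil)$alpha_cal # 50 units/um
fxm_calibrate <- function(image, roof_mask, pillar_mask) {
  stopifnot(inherits(image, "fxm_image"))
  roof_mask <- check_mask(roof_mask, dim(image$pixels), "roof_mask")
  pillar_mask <- check_mask(pillar_mask, dim(image$pixels), "pillar_mask")
  if (!any(roof_mask) || !any(pillar_mask))
    stop("roof and pillar masks must be non-empty")
  if (any(roof_mask & pillar_mask))
    stop("roof and pillar masks must be disjoint")
  I_max <- mean(image$pixels[roof_mask])
  I_min <- mean(image$pixels[pillar_mask])
  if (I_max <= I_min)
    stop("calibration failure: I_max <= I_min (inverted chamber or ",
         "saturation)")
  structure(list(I_max = I_max, I_min = I_min,
                 alpha_cal = (I_max - I_min) / image$h_max),
            class = "fxm_calibration")
}

#' Integrate a cell volume from an exclusion image
#'
#' Sums the per-pixel height `(I_max - I) / alpha_cal` over the cell mask and
#' multiplies by the pixel area. Pixels brighter than the background (negative
#' heights, from noise) are clipped to zero and counted; more than 1% clipped
#' pixels triggers a warning.
#'
#' @param image An [fxm_image()].
#' @param cell_mask Logical matrix selecting the cell (plus surroundings).
#' @param cal An `"fxm_calibration"`.
#' @param pillar_mask Optional; overlap between cell and pillar masks is
#'   rejected.
#' @return Volume in um^3, with attribute `clipped_px`.
#' @export
fxm_volume <- function(image, cell_mask, cal, pillar_mask = NULL) {
  stopifnot(inherits(image, "fxm_image"), inherits(cal, "fxm_calibration"))
  cell_mask <- check_mask(cell_mask, dim(image$pixels), "cell_mask")
  if (!is.null(pillar_mask)) {
    pillar_mask <- check_mask(pillar_mask, dim(image$pixels), "pillar_mask")
    if (any(cell_mask & pillar_mask))
      stop("cell mask overlaps the pillar mask")
  }
  if (!any(cell_mask)) {
    out <- 0
    attr(out, "clipped_px") <- 0L
    return(out)
  }
  h <- (cal$I_max - image$pixels[cell_mask]) / cal$alpha_cal
  clipped <- sum(h < 0)
  h[h < 0] <- 0
  if (clipped > 0.01 * length(h))
    warning(sprintf("%d of %d mask pixels clipped at zero height",
                    clipped, length(h)))
  out <- sum(h) * image$pixel_size^2
  attr(out, "clipped_px") <- as.integer(clipped)
  out
}

#' Microchannel geometry
#'
#' @param width,height Channel width and height in um.
#' @return A list with `width`, `height` and the cross-section `CS` (um^2).
#' @export
#' @examples
#' microchannel_geometry(13, 8)$CS # 104 um^2
microchannel_geometry <- function(width = 13, height = 8) {
  if (width <= 0 || height <= 0) stop("width and height must be > 0")
  structure(list(width = width, height = height, CS = width * height),
            class = "microchannel_geometry")
}

#' Cell volume from its length in a microchannel
#'
#' A cell confined in a microchannel occupies the whole cross-section and is
#' approximately cylindrical, so `V = length * CS`.
#'
#' @param length Cell length in um, > 0.
#' @param geom A [microchannel_geometry()]. Default 13 x 8 um (CS 104 um^2).
#' @return Volume in um^3.
#' @export
microchannel_volume <- function(length, geom = microchannel_geometry()) {
  stopifnot(inherits(geom, "microchannel_geometry"))
  if (any(!is.finite(length)) || any(length <= 0))
    stop("length must be finite and > 0")
  length * geom$CS
}

#' Render a synthetic exclusion-chamber image
#'
#' Test fixture generator: builds the intensity image
#' `I = I_max - alpha_cal * h` from a list of cell height maps placed on the
#' canvas, renders full-height pillars, optionally applies multiplicative
#' Gaussian noise, and returns the masks plus exact ground-truth volumes
#' (summed height map times pixel area).
#'
#' @param cells List of cell descriptors: each a list with `row`, `col`
#'   (top-left placement, 1-based) and `height` (a matrix of heights in um,
#'   all <= `h_max`).
#' @param nrow,ncol Canvas size in pixels.
#' @param pixel_size Pixel edge, um. Default 1.
#' @param h_max Chamber height, um. Default 20.
#' @param I_max Background intensity (a.u.). Default 2000.
#' @param alpha_cal Intensity per um. Default 50.
#' @param pillar Pillar square: list with `row`, `col`, `size` (pixels), or
#'   `NULL` for the default 8 x 8 square at (2, 2).
#' @param noise_cv Multiplicative Gaussian noise CV. Default 0.
#' @param seed Optional seed.
#' @return A list with `image` (an [fxm_image()]), `roof_mask`,
#'   `pillar_mask`, `cell_masks` (list), `volumes` (ground truth, um^3), and
#'   the true `I_max`, `I_min`, `alpha_cal`.
#' @export
render_synthetic_chamber <- function(cells = list(), nrow = 64, ncol = 64,
                                     pixel_size = 1, h_max = 20,
                                     I_max = 2000, alpha_cal = 50,
                                     pillar = NULL, noise_cv = 0,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  height <- matrix(0, nrow, ncol)
  cell_masks <- list()
  volumes <- numeric(length(cells))
  for (i in seq_along(cells)) {
    cc <- cells[[i]]
    hm <- cc$height
    if (any(hm > h_max)) stop("cell ", i, " is taller than the chamber")
    if (any(hm < 0)) stop("cell heights must be >= 0")
    r <- cc$row + seq_len(nrow(hm)) - 1L
    k <- cc$col + seq_len(ncol(hm)) - 1L
    if (max(r) > nrow || max(k) > ncol || min(r) < 1 || min(k) < 1)
      stop("cell ", i, " does not fit on the canvas")
    height[r, k] <- height[r, k] + hm
    m <- matrix(FALSE, nrow, ncol)
    m[r, k] <- hm > 0
    cell_masks[[i]] <- m
    volumes[i] <- sum(hm) * pixel_size^2
  }
  if (is.null(pillar)) pillar <- list(row = 2L, col = 2L, size = 8L)
  pillar_mask <- matrix(FALSE, nrow, ncol)
  pr <- pillar$row + seq_len(pillar$size) - 1L
  pc <- pillar$col + seq_len(pillar$size) - 1L
  pillar_mask[pr, pc] <- TRUE
  if (any(height[pillar_mask] > 0)) stop("a cell overlaps the pillar")
  height[pillar_mask] <- h_max

  I <- I_max - alpha_cal * height
  if (noise_cv > 0) I <- I * (1 + stats::rnorm(length(I), 0, noise_cv))
  I[I < 0] <- 0

  occupied <- pillar_mask | Reduce(`|`, cell_masks,
                                   matrix(FALSE, nrow, ncol))
  roof_mask <- !occupied

  list(image = fxm_image(I, pixel_size, h_max),
       roof_mask = roof_mask, pillar_mask = pillar_mask,
       cell_masks = cell_masks, volumes = volumes,
       I_max = I_max, I_min = I_max - alpha_cal * h_max,
       alpha_cal = alpha_cal)
}

#' Hemispherical cap height map
#'
#' Convenience builder for synthetic cells: height
#' `h(x, y) = sqrt(R^2 - d^2)` within radius `R` of the center, evaluated at
#' pixel centers.
#'
#' @param radius Sphere radius in um.
#' @param pixel_size Pixel edge in um. Default 1.
#' @return A square height matrix (um).
#' @export
hemisphere_height_map <- function(radius, pixel_size = 1) {
  npx <- ceiling(2 * radius / pixel_size)
  ctr <- (npx + 1) / 2
  xy <- (seq_len(npx) - ctr) * pixel_size
  d2 <- outer(xy^2, xy^2, `+`)
  sqrt(pmax(radius^2 - d2, 0)) # pmax keeps the dim of its first argument
}
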