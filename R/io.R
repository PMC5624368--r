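#' Read an RGB image with the package byte convention
#'
#' Reads a PNG or JPEG image and maps stored integer levels to the open unit
#' interval: an 8-bit level v becomes `(v + 0.5)/256` (16-bit analogously
#' `/65536`), so 0 maps to 1/512 and 255 to 511/512 and the endpoints 0 and
#' 1 -- which the inverse logistic map cannot handle -- can never occur.
#' Grayscale images are promoted by channel replication (with a warning);
#' an alpha channel is dropped. No color management or gamma handling is
#' applied: monotone display transforms leave the statistics of interest
#' essentially intact.
#'
#' @param path path to a `.png`, `.jpg` or `.jpeg` file.
#' @return H x W x 3 array of values strictly inside (0, 1).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                jpg = ,
                jpeg = jpeg::readJPEG(path),
                stop(sprintf("unsupported image format '%s'", ext), call. = FALSE))
  if (length(dim(img)) == 2L) {
    warning(sprintf("'%s' is grayscale; replicating channels", basename(path)))
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  if (dim(img)[3] == 2L) {  # gray + alpha
    warning(sprintf("'%s' is grayscale; replicating channels", basename(path)))
    img <- array(rep(img[, , 1L], 3L), dim = c(dim(img)[1:2], 3L))
  }
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  # readers return v/255 (8 bit) or v/65535 (16 bit); recover the levels
  v255 <- img * 255
  if (max(abs(v255 - round(v255))) < 1e-9) {
    out <- (round(v255) + 0.5) / 256
  } else {
    out <- (round(img * 65535) + 0.5) / 65536
  }
  out
}

#' Specification of an image corpus to iterate
#'
#' @param paths image files, or a single directory (scanned for PNG/JPEG,
#'   sorted).
#' @param crop_top_fraction,crop_bottom_fraction optional row bands in
#'   `[0, 0.5]` analyzed separately (e.g. 0.25 to take the upper quarter of
#'   the rows as a "sky" band), in addition to the full frame.
#' @param max_pixels_per_image subsampling cap per region (>= 1000).
#' @param seed seed controlling the (deterministic) pixel subsampling.
#' @export
corpus_spec <- function(paths, crop_top_fraction = 0, crop_bottom_fraction = 0,
                        max_pixels_per_image = 1e5, seed = 1L) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                        full.names = TRUE)
  if (length(paths) < 1L) stop("empty corpus", call. = FALSE)
  fr <- c(crop_top_fraction, crop_bottom_fraction)
  if (any(fr < 0 | fr > 0.5))
    stop("crop fractions must lie in [0, 0.5]", call. = FALSE)
  if (max_pixels_per_image < 1000)
    stop("max_pixels_per_image must be at least 1000", call. = FALSE)
  structure(list(paths = sort(paths),
                 crop_top_fraction = crop_top_fraction,
                 crop_bottom_fraction = crop_bottom_fraction,
                 max_pixels_per_image = max_pixels_per_image,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Iterate an image corpus, yielding per-region pixel samples
#'
#' Reads each image of the corpus in sorted-path order and yields the full
#' frame plus, when crop fractions are set, "top" and "bottom" row bands.
#' Each region is uniformly subsampled to at most `max_pixels_per_image`
#' pixels; the subsampling is deterministic given the corpus seed.
#'
#' @param spec a [corpus_spec()].
#' @return A list of entries, each with `id` (file name), `region`
#'   (`"full"`, `"top"` or `"bottom"`) and `samples` (an n x 3 matrix).
#' @export
iterate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  out <- list()
  for (i in seq_along(spec$paths)) {
    path <- spec$paths[i]
    img <- read_image(path)
    H <- dim(img)[1]
    regions <- list(full = img)
    if (spec$crop_top_fraction > 0)
      regions$top <- img[seq_len(floor(H * spec$crop_top_fraction)), , , drop = FALSE]
    if (spec$crop_bottom_fraction > 0)
      regions$bottom <- img[(H - floor(H * spec$crop_bottom_fraction) + 1L):H, , ,
                            drop = FALSE]
    for (rg in names(regions)) {
      flat <- matrix(regions[[rg]], ncol = 3L)
      if (nrow(flat) > spec$max_pixels_per_image) {
        local_seed(spec$seed + i)
        keep <- sample.int(nrow(flat), spec$max_pixels_per_image)
        flat <- flat[sort(keep), , drop = FALSE]
      }
      out[[length(out) + 1L]] <- list(id = basename(path), region = rg,
                                      samples = flat)
    }
  }
  out
}

#' Specification of a synthetic image fixture set
#'
#' Describes a set of images to generate from gamut signatures: either a
#' single signature per image, or a two-region "landscape" layout stacking
#' a sky band (its own signature) over a ground band. Serves as an on-disk
#' stand-in for natural-image corpora with known, controllable statistics.
#'
#' @param n_images number of images (>= 1).
#' @param width,height image dimensions in pixels (>= 16).
#' @param signature a [gamut_params()], or a list
#'   `list(ground = ..., sky = ...)` of two for the landscape layout.
#' @param sky_fraction height fraction of the sky band (landscape layout).
#' @param spatial_smoothing Gaussian blur sigma in pixels, applied in the
#'   physical domain before the sigmoid (0 = none).
#' @param seed integer seed; together with the manifest it regenerates the
#'   images bit-identically.
#' @export
fixture_spec <- function(n_images, width, height, signature,
                         sky_fraction = 0.25, spatial_smoothing = 0,
                         seed = 1L) {
  if (n_images < 1L) stop("n_images must be at least 1", call. = FALSE)
  if (width < 16L || height < 16L)
    stop("image dimensions must be at least 16", call. = FALSE)
  two <- is.list(signature) && !inherits(signature, "gamut_params") &&
    all(c("ground", "sky") %in% names(signature))
  if (!two && !inherits(signature, c("gamut_params", "gamut_signature")))
    stop("signature must be gamut_params or list(ground=, sky=)", call. = FALSE)
  structure(list(n_images = as.integer(n_images), width = as.integer(width),
                 height = as.integer(height), signature = signature,
                 two_region = two, sky_fraction = sky_fraction,
                 spatial_smoothing = spatial_smoothing, seed = as.integer(seed)),
            class = "fixture_spec")
}

# separable Gaussian blur with edge replication, one channel
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(m) {  # blur along rows of m
    padded <- m[c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r)), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * padded[j:(j + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(x))))
}

# physical-domain field for one region: opponent normal deviates -> T^-1
physical_field <- function(params, npix) {
  opp <- cbind(stats::rnorm(npix, params$mu_lambda, params$sigma_lambda),
               stats::rnorm(npix, params$mu_theta, params$sigma_theta),
               stats::rnorm(npix, params$mu_xi, params$sigma_xi))
  opponent_inverse(opp)
}

#' Generate a synthetic image fixture set on disk
#'
#' Fills each image with gamut samples under the given signature(s),
#' optionally blurs in the physical domain (preserving the marginal
#' families approximately), squashes through the logistic map, quantizes to
#' 8 bits and writes PNGs plus a JSON manifest recording every parameter
#' and per-image seed.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
make_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  H <- spec$height; W <- spec$width
  files <- character(spec$n_images)
  for (i in seq_len(spec$n_images)) {
    local_seed(spec$seed + i)
    phys <- array(NA_real_, dim = c(H, W, 3L))
    if (spec$two_region) {
      hs <- floor(H * spec$sky_fraction)
      sky <- physical_field(spec$signature$sky, hs * W)
      ground <- physical_field(spec$signature$ground, (H - hs) * W)
      for (ch in 1:3) {
        phys[seq_len(hs), , ch] <- matrix(sky[, ch], hs, W)
        phys[(hs + 1L):H, , ch] <- matrix(ground[, ch], H - hs, W)
      }
    } else {
      field <- physical_field(spec$signature, H * W)
      for (ch in 1:3) phys[, , ch] <- matrix(field[, ch], H, W)
    }
    if (spec$spatial_smoothing > 0)
      for (ch in 1:3) phys[, , ch] <- gaussian_blur(phys[, , ch],
                                                    spec$spatial_smoothing)
    rgb <- omega(phys)
    bytes <- pmin(pmax(round(256 * rgb - 0.5), 0), 255)
    files[i] <- sprintf("fixture_%03d.png", i)
    png::writePNG(bytes / 255, target = file.path(dir, files[i]))
  }
  manifest <- list(n_images = spec$n_images, width = W, height = H,
                   two_region = spec$two_region,
                   sky_fraction = if (spec$two_region) spec$sky_fraction else NULL,
                   signature = if (spec$two_region)
                     lapply(spec$signature, unclass) else unclass(spec$signature),
                   spatial_smoothing = spec$spatial_smoothing,
                   seed = spec$seed, per_image_seeds = spec$seed + seq_len(spec$n_images),
                   files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
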