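# Synthetic two-channel puncta fields with known ground truth.

#' Parameters for the two-channel puncta field simulator
#'
#' Describes one simulated optical section: field geometry, the number of
#' presynaptic (channel A) and postsynaptic (channel B) puncta, the fraction
#' of B puncta planted concentrically on an A punctum (the ground-truth
#' synapses), spot shape, background plane and shot noise. A stack is simply a
#' list of sections simulated with different seeds.
#'
#' @param width_px,height_px Field size in pixels.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param optical_thickness_um Optical-section thickness in micrometres
#'   (z-step of the acquisition).
#' @param n_puncta_a,n_puncta_b Planted puncta per channel.
#' @param coloc_fraction Fraction of B puncta centered (within 1 px) on an A
#'   punctum; the planted synapse count is `round(coloc_fraction * n_puncta_b)`.
#' @param spot_sigma_px Gaussian spot sigma in pixels; length 1 or 2
#'   (channel A, channel B).
#' @param amp_range Per-punctum peak amplitude range (uniform draw).
#' @param background_level,background_gradient Constant background plus a
#'   left-to-right linear ramp of the given total amplitude.
#' @param min_separation_px Minimum center-to-center distance enforced among
#'   all planted puncta of both channels (colocalized pairs excepted, they
#'   coincide by construction).
#' @param shot_noise Apply Poisson shot noise (`counts ~ Pois(photons * I) /
#'   photons`).
#' @param photons Photon scale of the shot noise.
#' @param seed Integer seed.
#' @return An object of class `sim_image_params`.
#' @export
sim_image_params <- function(width_px = 256, height_px = 256,
                             pixel_size_um = 0.082, optical_thickness_um = 0.46,
                             n_puncta_a = 100, n_puncta_b = 100,
                             coloc_fraction = 0.25, spot_sigma_px = 2,
                             amp_range = c(0.5, 1),
                             background_level = 0.04, background_gradient = 0.04,
                             min_separation_px = 8, shot_noise = TRUE,
                             photons = 200, seed = 1L) {
  stopifnot_scalar(coloc_fraction, "coloc_fraction", 0, 1)
  stopifnot_scalar(min_separation_px, "min_separation_px", lower = 1e-9)
  if (n_puncta_a < 0 || n_puncta_b < 0) stop("puncta counts must be non-negative")
  if (length(spot_sigma_px) == 1) spot_sigma_px <- rep(spot_sigma_px, 2)
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         pixel_size_um = pixel_size_um,
         optical_thickness_um = optical_thickness_um,
         n_puncta_a = as.integer(n_puncta_a), n_puncta_b = as.integer(n_puncta_b),
         coloc_fraction = coloc_fraction, spot_sigma_px = spot_sigma_px,
         amp_range = amp_range, background_level = background_level,
         background_gradient = background_gradient,
         min_separation_px = min_separation_px,
         shot_noise = isTRUE(shot_noise), photons = photons,
         seed = as.integer(seed)),
    class = "sim_image_params")
}

# Rejection-sample n points with pairwise (and vs. `existing`) min separation.
# Coordinates are 0-based pixel centers. Budget: 100 attempts per requested
# point; exceeded -> error (infeasible packing is reported, not silently
# densified).
place_puncta <- function(n, width, height, min_sep, margin, existing = NULL,
                         budget_factor = 100) {
  if (n == 0) return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  pts <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
  all_pts <- existing
  placed <- 0L
  tries <- 0L
  budget <- budget_factor * n
  min_sep2 <- min_sep^2
  while (placed < n) {
    tries <- tries + 1L
    if (tries > budget)
      stop(sprintf("could not place %d puncta with min separation %.1f px in a %dx%d field (retry budget %d exhausted)",
                   n, min_sep, width, height, budget))
    p <- c(stats::runif(1, margin, width - 1 - margin),
           stats::runif(1, margin, height - 1 - margin))
    if (!is.null(all_pts) && nrow(all_pts) > 0) {
      d2 <- (all_pts[, 1] - p[1])^2 + (all_pts[, 2] - p[2])^2
      if (min(d2) < min_sep2) next
    }
    placed <- placed + 1L
    pts[placed, ] <- p
    all_pts <- rbind(all_pts, p)
  }
  pts
}

# Render isotropic Gaussian spots onto an h x w matrix (0-based centers).
render_spots <- function(width, height, centers, amps, sigma) {
  img <- matrix(0, height, width)
  if (nrow(centers) == 0) return(img)
  r <- ceiling(4 * sigma)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    xs <- max(1, floor(cx + 1 - r)):min(width, ceiling(cx + 1 + r))
    ys <- max(1, floor(cy + 1 - r)):min(height, ceiling(cy + 1 + r))
    gx <- exp(-((xs - 1 - cx)^2) / (2 * sigma^2))
    gy <- exp(-((ys - 1 - cy)^2) / (2 * sigma^2))
    img[ys, xs] <- img[ys, xs] + amps[i] * outer(gy, gx)
  }
  img
}

#' Simulate a two-channel puncta field
#'
#' Places channel-A puncta, plants `round(coloc_fraction * n_puncta_b)`
#' channel-B puncta concentric with the first A puncta (sub-pixel jitter,
#' centers within 1 px), places the remaining B puncta away from everything,
#' renders each punctum as an isotropic Gaussian spot, adds a background plane
#' and optional Poisson shot noise. Identical parameters and seed give an
#' identical field. Packing is rejection-sampled with a bounded retry budget;
#' an infeasible request errors.
#'
#' @param params A [sim_image_params()].
#' @param field_id Identifier carried to quantification tables.
#' @return An object of class `puncta_field`: `channels` (list of `pre` and
#'   `post` image matrices), geometry metadata, and `truth` (0-based planted
#'   centers per channel, colocalized pair indices, `n_coloc`
#'   (= planted synapse count), and per-channel noiseless area fraction at
#'   half the minimum spot amplitude).
#' @examples
#' fld <- simulate_puncta_field(sim_image_params(n_puncta_a = 20, n_puncta_b = 20,
#'                                               coloc_fraction = 0.5, seed = 2))
#' fld$truth$n_coloc  # 10
#' @export
simulate_puncta_field <- function(params, field_id = "field") {
  if (!inherits(params, "sim_image_params")) stop("'params' must be sim_image_params")
  set.seed(params$seed)
  w <- params$width_px; h <- params$height_px
  sig <- params$spot_sigma_px
  margin <- ceiling(3 * max(sig))
  n_coloc <- as.integer(round(params$coloc_fraction * params$n_puncta_b))
  if (n_coloc > params$n_puncta_a)
    stop("coloc_fraction requires more colocalized B puncta than there are A puncta")

  ca <- place_puncta(params$n_puncta_a, w, h, params$min_separation_px, margin)
  cb_coloc <- if (n_coloc > 0) {
    ca[seq_len(n_coloc), , drop = FALSE] +
      matrix(stats::runif(2 * n_coloc, -0.5, 0.5), ncol = 2)
  } else matrix(numeric(0), ncol = 2)
  cb_free <- place_puncta(params$n_puncta_b - n_coloc, w, h,
                          params$min_separation_px, margin,
                          existing = rbind(ca, cb_coloc))
  cb <- rbind(cb_coloc, cb_free)
  colnames(cb) <- c("x", "y")

  amp_a <- stats::runif(params$n_puncta_a, params$amp_range[1], params$amp_range[2])
  amp_b <- stats::runif(params$n_puncta_b, params$amp_range[1], params$amp_range[2])
  spots_a <- render_spots(w, h, ca, amp_a, sig[1])
  spots_b <- render_spots(w, h, cb, amp_b, sig[2])

  ramp <- matrix(rep((0:(w - 1)) / max(1, w - 1), each = h), h, w)
  bg <- params$background_level + params$background_gradient * ramp
  img_a <- spots_a + bg
  img_b <- spots_b + bg
  if (params$shot_noise) {
    img_a <- matrix(stats::rpois(length(img_a), img_a * params$photons) / params$photons, h, w)
    img_b <- matrix(stats::rpois(length(img_b), img_b * params$photons) / params$photons, h, w)
  }

  thr <- 0.5 * params$amp_range[1]
  truth <- list(
    centers_a = ca, centers_b = cb,
    coloc_pairs = if (n_coloc > 0) cbind(a = seq_len(n_coloc), b = seq_len(n_coloc))
                  else cbind(a = integer(0), b = integer(0)),
    n_coloc = n_coloc,
    area_fraction_a = 100 * mean(spots_a > thr),
    area_fraction_b = 100 * mean(spots_b > thr))

  structure(
    list(channels = list(pre = img_a, post = img_b),
         width_px = w, height_px = h,
         pixel_size_um = params$pixel_size_um,
         optical_thickness_um = params$optical_thickness_um,
         field_id = field_id, truth = truth),
    class = "puncta_field")
}

#' @export
print.puncta_field <- function(x, ...) {
  cat(sprintf("Puncta field '%s': %dx%d px (%.1f um/px, section %.2f um)\n",
              x$field_id, x$width_px, x$height_px, x$pixel_size_um,
              x$optical_thickness_um))
  if (!is.null(x$truth))
    cat(sprintf("  truth: %d pre, %d post, %d colocalized\n",
                nrow(x$truth$centers_a), nrow(x$truth$centers_b), x$truth$n_coloc))
  invisible(x)
}

#' Write / read a puncta field as multi-channel TIFF with YAML sidecar
#'
#' The two channels are written as a two-directory 32-bit float TIFF (values
#' scaled into \[0, 1\]; the scale factor is recorded in the sidecar).
#' Geometry metadata (pixel size, optical-section thickness, channel roles)
#' goes into `<prefix>.yaml`; ground truth, when present, into
#' `<prefix>_truth.json`.
#'
#' @param field A `puncta_field`.
#' @param prefix Path prefix (files `<prefix>.tiff`, `<prefix>.yaml`,
#'   `<prefix>_truth.json`).
#' @return `write_puncta_field` returns the TIFF path invisibly;
#'   `read_puncta_field` a `puncta_field` (without truth unless the JSON file
#'   is present).
#' @export
write_puncta_field <- function(field, prefix) {
  scale <- max(unlist(field$channels), 1)
  tiff::writeTIFF(lapply(field$channels, function(ch) ch / scale),
                  paste0(prefix, ".tiff"), bits.per.sample = 32L)
  yaml::write_yaml(
    list(pixel_size_um = field$pixel_size_um,
         optical_thickness_um = field$optical_thickness_um,
         channels = names(field$channels),
         value_scale = scale,
         field_id = field$field_id),
    paste0(prefix, ".yaml"))
  if (!is.null(field$truth)) {
    tr <- field$truth
    jsonlite::write_json(
      list(centers_a = unname(as.data.frame(tr$centers_a)),
           centers_b = unname(as.data.frame(tr$centers_b)),
           n_coloc = tr$n_coloc,
           area_fraction_a = tr$area_fraction_a,
           area_fraction_b = tr$area_fraction_b),
      paste0(prefix, "_truth.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(paste0(prefix, ".tiff"))
}

#' @rdname write_puncta_field
#' @export
read_puncta_field <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  planes <- tiff::readTIFF(paste0(prefix, ".tiff"), all = TRUE)
  channels <- lapply(planes, function(p) p * meta$value_scale)
  names(channels) <- meta$channels
  truth <- NULL
  tj <- paste0(prefix, "_truth.json")
  if (file.exists(tj)) {
    tr <- jsonlite::read_json(tj, simplifyVector = TRUE)
    truth <- list(centers_a = as.matrix(tr$centers_a),
                  centers_b = as.matrix(tr$centers_b),
                  n_coloc = tr$n_coloc,
                  area_fraction_a = tr$area_fraction_a,
                  area_fraction_b = tr$area_fraction_b)
  }
  structure(
    list(channels = channels,
         width_px = ncol(channels[[1]]), height_px = nrow(channels[[1]]),
         pixel_size_um = meta$pixel_size_um,
         optical_thickness_um = meta$optical_thickness_um,
         field_id = meta$field_id, truth = truth),
    class = "puncta_field")
}
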