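# Immunopuncta segmentation, counting and object-based colocalization.

#' Preprocess one fluorescence channel
#'
#' Rolling-ball-style background correction followed by median noise removal:
#' the background is estimated by grayscale morphological opening with a disk
#' of `background_radius_px` (which must exceed the spot radius so puncta are
#' removed from the estimate) and subtracted; the result is clamped at zero
#' and median-filtered.
#'
#' @param channel Numeric image matrix.
#' @param background_radius_px Radius of the background structuring disk in
#'   pixels (default 8).
#' @param median_size_px Median filter window size in pixels; odd (default 3).
#' @return Non-negative image matrix of the same size.
#' @export
preprocess_channel <- function(channel, background_radius_px = 8,
                               median_size_px = 3) {
  if (median_size_px %% 2 != 1) stop("'median_size_px' must be odd")
  r <- as.integer(background_radius_px)
  brush_size <- 2L * r + 1L
  if (brush_size > min(dim(channel)) || median_size_px > min(dim(channel)))
    stop("filter kernel larger than the image")
  # edge-replicated padding so the opening has no zero-padding border artifact
  ri <- pmin(pmax(seq_len(nrow(channel) + 2L * r) - r, 1L), nrow(channel))
  ci <- pmin(pmax(seq_len(ncol(channel) + 2L * r) - r, 1L), ncol(channel))
  padded <- channel[ri, ci]
  # EBImage grayscale morphology works on [0, 1]; rescale around it
  scale <- max(padded, 1e-12)
  bg <- EBImage::opening(padded / scale, EBImage::makeBrush(brush_size, "disc")) * scale
  bg <- bg[r + seq_len(nrow(channel)), r + seq_len(ncol(channel))]
  out <- pmax(channel - bg, 0)
  mx <- max(out)
  if (mx > 0) {
    out <- EBImage::medianFilter(out / mx, (median_size_px - 1L) / 2L,
                                 cacheSize = 4096) * mx
  }
  matrix(as.numeric(out), nrow(channel), ncol(channel))
}

# Label centroids and areas (0-based centroids, row-major pixel convention).
label_table <- function(labels) {
  lab <- as.integer(labels)
  keep <- lab > 0L
  if (!any(keep))
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area = integer(0)))
  idx <- which(keep)
  rr <- (idx - 1L) %% nrow(labels)        # 0-based row (y)
  cc <- (idx - 1L) %/% nrow(labels)       # 0-based col (x)
  l <- lab[keep]
  data.frame(label = sort(unique(l)),
             x = as.numeric(tapply(cc, l, mean)),
             y = as.numeric(tapply(rr, l, mean)),
             area = as.integer(tapply(l, l, length)))
}

#' Segment immunopuncta in a preprocessed channel
#'
#' Thresholds the image (Otsu by default, or a fixed value), optionally
#' separates touching puncta with a distance-transform watershed, labels
#' connected components and removes components outside
#' `[min_area_px, max_area_px]`. An empty mask is a valid result (count 0);
#' a flat saturated image yields a warning flag.
#'
#' @param image Preprocessed image matrix (see [preprocess_channel()]).
#' @param threshold `"otsu"` or `"fixed"`.
#' @param threshold_value Threshold for `threshold = "fixed"`.
#' @param min_area_px,max_area_px Component size filter in pixels
#'   (defaults 4 and `Inf`; sub-4 px specks are treated as noise).
#' @param split_touching Apply the watershed split (default `TRUE`).
#' @return An object of class `puncta_set`: binary `mask` (size-filtered),
#'   integer `labels`, `puncta` table (label, 0-based centroid, area px^2),
#'   `count`, `area_fraction` (percent of field covered) and a `saturated`
#'   flag.
#' @examples
#' img <- matrix(0, 100, 100); img[20:29, 20:29] <- 1
#' segment_puncta(img, threshold = "fixed", threshold_value = 0.5)$area_fraction
#' @export
segment_puncta <- function(image, threshold = c("otsu", "fixed"),
                           threshold_value = NULL, min_area_px = 4,
                           max_area_px = Inf, split_touching = TRUE) {
  threshold <- match.arg(threshold)
  mx <- max(image)
  saturated <- mx > 0 && min(image) == mx
  thr <- if (threshold == "fixed") {
    if (is.null(threshold_value)) stop("'threshold_value' required for fixed threshold")
    threshold_value
  } else {
    if (mx <= 0) Inf else EBImage::otsu(EBImage::Image(image / mx)) * mx
  }
  mask <- image > thr
  if (any(mask)) {
    labels <- if (split_touching) {
      EBImage::watershed(EBImage::distmap(EBImage::Image(mask * 1)), tolerance = 1)
    } else {
      EBImage::bwlabel(EBImage::Image(mask * 1))
    }
    labels <- matrix(as.integer(labels), nrow(image), ncol(image))
  } else {
    labels <- matrix(0L, nrow(image), ncol(image))
  }
  tab <- label_table(labels)
  drop <- tab$label[tab$area < min_area_px | tab$area > max_area_px]
  if (length(drop)) {
    labels[labels %in% drop] <- 0L
    tab <- tab[!tab$label %in% drop, , drop = FALSE]
  }
  structure(
    list(mask = labels > 0L, labels = labels, puncta = tab,
         count = nrow(tab),
         area_fraction = 100 * sum(labels > 0L) / length(image),
         saturated = saturated),
    class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("Puncta set: %d puncta, area fraction %.2f%%%s\n", x$count,
              x$area_fraction, if (x$saturated) " [saturated image]" else ""))
  invisible(x)
}

#' Object-based colocalization of two puncta sets (AND mask)
#'
#' Conjoins the two binary masks pixelwise (the "AND" operation) and counts
#' the connected components of the intersection with area at least
#' `min_overlap_px`. Co-labeled components proxy excitatory synapses when the
#' inputs are a presynaptic and a postsynaptic marker.
#'
#' @param pre,post [segment_puncta()] results of identical dimensions.
#' @param min_overlap_px Minimum overlap component area in pixels (default 1,
#'   i.e. any overlap counts).
#' @return An object of class `coloc_result`: `and_mask`, `co_labeled_count`,
#'   and the component table `overlaps`.
#' @export
colocalize <- function(pre, post, min_overlap_px = 1) {
  if (!identical(dim(pre$mask), dim(post$mask)))
    stop("mask dimensions differ")
  and_mask <- pre$mask & post$mask
  if (any(and_mask)) {
    labels <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(and_mask * 1))),
                     nrow(and_mask), ncol(and_mask))
    tab <- label_table(labels)
    tab <- tab[tab$area >= min_overlap_px, , drop = FALSE]
  } else {
    tab <- label_table(matrix(0L, 1, 1))
  }
  structure(list(and_mask = and_mask, co_labeled_count = nrow(tab),
                 overlaps = tab),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization: %d co-labeled puncta\n", x$co_labeled_count))
  invisible(x)
}

#' Convert a co-labeled count to synapse density
#'
#' Density is the count divided by the sampled tissue volume: field area
#' (pixels times pixel size squared) times the optical-section thickness.
#'
#' @param co_labeled_count Number of co-labeled puncta.
#' @param dim_px Field size `c(width, height)` in pixels, or a `puncta_field`.
#' @param pixel_size_um,optical_thickness_um Geometry; taken from the field
#'   when one is supplied.
#' @return Synapses per cubic micrometre.
#' @examples
#' synapse_density(5, c(500, 500), 0.1, 0.46)  # 5 / 1150
#' @export
synapse_density <- function(co_labeled_count, dim_px, pixel_size_um = NULL,
                            optical_thickness_um = NULL) {
  if (inherits(dim_px, "puncta_field")) {
    pixel_size_um <- dim_px$pixel_size_um
    optical_thickness_um <- dim_px$optical_thickness_um
    dim_px <- c(dim_px$width_px, dim_px$height_px)
  }
  if (is.null(pixel_size_um) || is.null(optical_thickness_um) ||
      is.na(pixel_size_um) || is.na(optical_thickness_um))
    stop("pixel size and optical-section thickness are required")
  volume_um3 <- prod(dim_px) * pixel_size_um^2 * optical_thickness_um
  co_labeled_count / volume_um3
}

#' Percent participation of a marker in co-labeled synapses
#'
#' The share of one channel's puncta that belong to co-labeled (synaptic)
#' sites: `100 * co_labeled_count / channel_count`. Undefined (returned as
#' `NA` with a warning) when the channel has no puncta.
#'
#' @param co_labeled_count Co-labeled puncta count.
#' @param channel_count Puncta count of the channel.
#' @return Percent, or `NA` when `channel_count` is zero.
#' @examples
#' percent_participation(35, 50)  # 70
#' @export
percent_participation <- function(co_labeled_count, channel_count) {
  if (channel_count == 0) {
    warning("channel has no puncta; participation undefined")
    return(NA_real_)
  }
  if (co_labeled_count > channel_count)
    stop("co-labeled count exceeds the channel count")
  100 * co_labeled_count / channel_count
}

#' Quantify one two-channel field
#'
#' Runs the full per-field chain on both channels: preprocessing,
#' segmentation, AND colocalization, synapse density and percent
#' participation.
#'
#' @param field A `puncta_field` (simulated or read from disk).
#' @param background_radius_px,median_size_px See [preprocess_channel()].
#' @param threshold,threshold_value,min_area_px,max_area_px,split_touching
#'   See [segment_puncta()].
#' @param min_overlap_px See [colocalize()].
#' @return A one-row `data.frame`: `field_id`, per-channel `count_pre`,
#'   `count_post`, `area_fraction_pre_pct`, `area_fraction_post_pct`,
#'   `co_labeled_count`, `density_per_um3`, `participation_pre_pct`,
#'   `participation_post_pct`, `saturated`.
#' @export
quantify_field <- function(field, background_radius_px = 8, median_size_px = 3,
                           threshold = "otsu", threshold_value = NULL,
                           min_area_px = 4, max_area_px = Inf,
                           split_touching = TRUE, min_overlap_px = 1) {
  seg <- lapply(field$channels[c("pre", "post")], function(ch) {
    segment_puncta(preprocess_channel(ch, background_radius_px, median_size_px),
                   threshold = threshold, threshold_value = threshold_value,
                   min_area_px = min_area_px, max_area_px = max_area_px,
                   split_touching = split_touching)
  })
  cl <- colocalize(seg$pre, seg$post, min_overlap_px)
  dens <- synapse_density(cl$co_labeled_count, field)
  data.frame(
    field_id = field$field_id,
    count_pre = seg$pre$count, count_post = seg$post$count,
    area_fraction_pre_pct = seg$pre$area_fraction,
    area_fraction_post_pct = seg$post$area_fraction,
    co_labeled_count = cl$co_labeled_count,
    density_per_um3 = dens,
    participation_pre_pct = if (seg$pre$count > 0)
      100 * cl$co_labeled_count / seg$pre$count else NA_real_,
    participation_post_pct = if (seg$post$count > 0)
      100 * cl$co_labeled_count / seg$post$count else NA_real_,
    saturated = seg$pre$saturated || seg$post$saturated,
    stringsAsFactors = FALSE)
}
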