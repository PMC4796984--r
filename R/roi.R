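#' Region-of-interest specification
#'
#' Circular ROIs mirror the two regions used in zinc-spark image analysis:
#' the `interior` disk covering the whole cell and the extracellular
#' `ring`, an annulus hugging the cell perimeter. Coordinates are 0-based
#' with x increasing rightwards (columns) and y downwards (rows). A pixel
#' `(x, y)` belongs to a region when its center satisfies the half-open
#' radial inequality `r_inner <= d < r_outer`, which makes the interior
#' disk and its ring exactly disjoint.
#'
#' @param kind `"interior"` or `"ring"`.
#' @param center Numeric `(x, y)` center in pixels.
#' @param radius Disk radius (interior) or inner radius (ring), pixels.
#' @param ring_thickness Ring width in pixels (ring only); by convention it
#'   is held identical across all eggs of one analysis run.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(kind = c("interior", "ring"), center, radius,
                     ring_thickness = NULL) {
  kind <- match.arg(kind)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (kind == "ring") {
    if (is.null(ring_thickness) || ring_thickness <= 0) {
      stop("ring_thickness must be positive for ring ROIs", call. = FALSE)
    }
  } else {
    ring_thickness <- NULL
  }
  structure(
    list(kind = kind, center = as.numeric(center), radius = radius,
         ring_thickness = ring_thickness),
    class = "roi_spec"
  )
}

#' Build the perimeter ring ROI from an interior ROI
#'
#' The annulus runs from the interior radius outward by `thickness`
#' pixels, sharing the interior's center, so its inner edge coincides with
#' the segmented cell boundary.
#'
#' @param interior An interior [roi_spec()].
#' @param thickness Ring thickness in pixels (> 0); default 5.
#' @return A ring [roi_spec()].
#' @export
make_ring <- function(interior, thickness = 5) {
  stopifnot(inherits(interior, "roi_spec"))
  if (interior$kind != "interior") stop("expected an interior ROI", call. = FALSE)
  if (thickness <= 0) stop("ring thickness must be > 0", call. = FALSE)
  roi_spec("ring", interior$center, interior$radius, ring_thickness = thickness)
}

#' Logical pixel mask of an ROI
#'
#' @param roi An [roi_spec()].
#' @param width,height Frame dimensions in pixels.
#' @return Logical matrix `(height, width)`; `TRUE` where the pixel center
#'   lies in the region.
#' @export
roi_mask <- function(roi, width, height) {
  stopifnot(inherits(roi, "roi_spec"))
  xs <- matrix(rep(0:(width - 1), each = height), nrow = height)
  ys <- matrix(rep(0:(height - 1), times = width), nrow = height)
  d <- sqrt((xs - roi$center[1])^2 + (ys - roi$center[2])^2)
  if (roi$kind == "interior") {
    d < roi$radius
  } else {
    d >= roi$radius & d < roi$radius + roi$ring_thickness
  }
}

#' Locate the egg in a time-lapse stack
#'
#' Automates the manual ROI-drawing step: the temporal-mean frame is
#' thresholded at its between-class-optimal (Otsu) level, the class not
#' touching the image border is taken as the egg, and the largest
#' connected component yields the ROI. In the extracellular-dye channel
#' the cell interior excludes dye and appears dark against a bright
#' background; the border rule makes the segmentation agnostic to that
#' polarity.
#'
#' @param stack An [image_stack()].
#' @param min_area_frac Minimum egg area as a fraction of the frame
#'   (default 0.01); smaller largest components raise a segmentation
#'   failure.
#' @return An interior [roi_spec()] with the component centroid and its
#'   equivalent-area radius (`sqrt(area/pi)`).
#' @export
segment_egg <- function(stack, min_area_frac = 0.01) {
  stopifnot(inherits(stack, "image_stack"))
  m <- apply(stack$data, c(1, 2), mean)
  rng <- range(m)
  if (diff(rng) == 0) {
    stop("segmentation failure: temporal-mean frame is constant", call. = FALSE)
  }
  m01 <- (m - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(m01), range = c(0, 1))
  bright <- m01 > th
  border <- c(bright[1, ], bright[nrow(bright), ], bright[, 1], bright[, ncol(bright)])
  fg <- if (mean(border) > 0.5) !bright else bright
  if (!any(fg)) stop("segmentation failure: no foreground pixels", call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  sizes <- tabulate(as.integer(lab[lab > 0]))
  biggest <- which.max(sizes)
  if (sizes[biggest] < min_area_frac * length(m)) {
    stop("segmentation failure: largest component covers < ",
         100 * min_area_frac, "% of the frame", call. = FALSE)
  }
  idx <- which(as.integer(lab) == biggest)
  # array index -> 0-based (x, y): rows are y, columns are x
  ys <- (idx - 1) %% nrow(m)
  xs <- (idx - 1) %/% nrow(m)
  roi_spec("interior", center = c(mean(xs), mean(ys)),
           radius = sqrt(sizes[biggest] / pi))
}

#' Extract a mean-intensity trace from a stack
#'
#' Per-frame arithmetic mean of the pixels whose centers fall inside the
#' ROI, with the time axis taken from the stack metadata.
#'
#' @param stack An [image_stack()].
#' @param roi An [roi_spec()].
#' @param egg_id Identifier for the returned trace.
#' @return A raw [fluorescence_trace()].
#' @export
extract_trace <- function(stack, roi, egg_id = "egg_1") {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "roi_spec"))
  mask <- roi_mask(roi, stack$meta$width, stack$meta$height)
  if (!any(mask)) stop("ROI lies fully outside the frame", call. = FALSE)
  vals <- vapply(seq_len(stack$meta$n_frames),
                 function(t) mean(stack$data[, , t][mask]), numeric(1))
  fluorescence_trace(egg_id,
                     (seq_len(stack$meta$n_frames) - 1L) * stack$meta$frame_interval_s,
                     vals, channel = stack$meta$channel)
}

#' Export ROI definitions to CSV
#'
#' Columns: `egg_id, kind, cx, cy, r, thickness` (thickness empty for
#' interior ROIs). This mirrors a hand-drawn ROI workflow: masks drawn
#' elsewhere can be imported with [read_rois_csv()].
#'
#' @param rois Named list of [roi_spec()] (names are egg ids).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rois_csv <- function(rois, path) {
  df <- do.call(rbind, lapply(names(rois), function(id) {
    r <- rois[[id]]
    data.frame(egg_id = id, kind = r$kind, cx = r$center[1], cy = r$center[2],
               r = r$radius,
               thickness = if (is.null(r$ring_thickness)) NA_real_ else r$ring_thickness)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Import ROI definitions from CSV
#'
#' @param path CSV with columns `egg_id, kind, cx, cy, r, thickness`.
#' @return Named list of [roi_spec()].
#' @export
read_rois_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("egg_id", "kind", "cx", "cy", "r")
  if (!all(need %in% names(df))) {
    stop("ROI CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    roi_spec(df$kind[i], c(df$cx[i], df$cy[i]), df$r[i],
             ring_thickness = if (df$kind[i] == "ring") df$thickness[i] else NULL)
  })
  names(out) <- df$egg_id
  out
}
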