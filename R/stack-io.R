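#' Image-stack metadata
#'
#' @param n_frames Number of frames (pages) in the stack; at least 6 so the
#'   five-frame F0 window is satisfiable.
#' @param frame_interval_s Seconds between frames.
#' @param width,height Frame dimensions in pixels.
#' @param bit_depth Bits per sample (stacks are written 16-bit unsigned).
#' @param channel Channel label, `"zinc_extracellular"` or
#'   `"calcium_intracellular"`.
#' @return An object of class `image_stack_meta`.
#' @export
image_stack_meta <- function(n_frames, frame_interval_s = 4,
                             width = NA_integer_, height = NA_integer_,
                             bit_depth = 16L,
                             channel = c("zinc_extracellular",
                                         "calcium_intracellular")) {
  channel <- match.arg(channel)
  if (n_frames < 6L) stop("n_frames must be >= 6 (F0 window unsatisfiable)",
                          call. = FALSE)
  if (frame_interval_s <= 0) stop("frame_interval_s must be positive", call. = FALSE)
  structure(
    list(n_frames = as.integer(n_frames), frame_interval_s = frame_interval_s,
         width = as.integer(width), height = as.integer(height),
         bit_depth = as.integer(bit_depth), channel = channel),
    class = "image_stack_meta"
  )
}

#' Construct an in-memory image stack
#'
#' @param data Numeric array with dim `(height, width, n_frames)`; one
#'   matrix per frame. Intensities are counts in `[0, 65535]`.
#' @param meta An [image_stack_meta()]; dimensions are filled in from
#'   `data`.
#' @return An object of class `image_stack` (list with `$data`, `$meta`).
#' @export
image_stack <- function(data, meta) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            inherits(meta, "image_stack_meta"))
  if (dim(data)[3] != meta$n_frames) {
    stop("meta$n_frames (", meta$n_frames, ") does not match stack depth (",
         dim(data)[3], ")", call. = FALSE)
  }
  meta$height <- dim(data)[1]
  meta$width <- dim(data)[2]
  structure(list(data = data, meta = meta), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d frames of %dx%d px @ %.3g s | %s\n",
              x$meta$n_frames, x$meta$width, x$meta$height,
              x$meta$frame_interval_s, x$meta$channel))
  invisible(x)
}

#' Write an image stack as multi-page 16-bit TIFF
#'
#' Intensities are rounded and clamped to `[0, 65535]`. A plain-text YAML
#' sidecar (`<path>.meta.yaml`) records the frame interval and channel so
#' [read_stack()] can recover acquisition metadata absent from TIFF tags.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @param sidecar Write the metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(seq_len(stack$meta$n_frames), function(t) {
    m <- round(stack$data[, , t])
    m[m < 0] <- 0
    m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (sidecar) {
    yaml::write_yaml(
      list(frame_interval_s = stack$meta$frame_interval_s,
           channel = stack$meta$channel),
      paste0(path, ".meta.yaml")
    )
  }
  invisible(path)
}

#' Read a single-channel multi-page TIFF stack
#'
#' @param path TIFF path.
#' @param frame_interval_s Frame interval override; when `NULL` it is taken
#'   from the `<path>.meta.yaml` sidecar, and defaults to 4 s if neither is
#'   available.
#' @param channel Channel label override (sidecar consulted as above).
#' @return An [image_stack()].
#' @export
read_stack <- function(path, frame_interval_s = NULL, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1)))) {
    stop("unsupported format: multi-channel or RGB TIFF; expected one ",
         "grayscale channel per page", call. = FALSE)
  }
  if (length(pages) < 6L) {
    stop("stack has ", length(pages),
         " frames; at least 6 required (F0 window unsatisfiable)",
         call. = FALSE)
  }
  side <- paste0(path, ".meta.yaml")
  sc <- if (file.exists(side)) yaml::read_yaml(side) else list()
  if (is.null(frame_interval_s)) frame_interval_s <- sc$frame_interval_s %||% 4
  if (is.null(channel)) channel <- sc$channel %||% "zinc_extracellular"
  data <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) data[, , t] <- pages[[t]]
  meta <- image_stack_meta(length(pages), frame_interval_s,
                           width = ncol(pages[[1]]), height = nrow(pages[[1]]),
                           channel = channel)
  image_stack(data, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
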