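#' Construct an image stack
#'
#' A single-channel multi-frame grayscale movie stored as a
#' height x width x frames array of non-negative intensities.
#'
#' @param frames A 3-D numeric array (`h x w x n`), or a list of equally
#'   sized matrices.
#' @param frame_interval_s Frame interval in seconds.
#' @param channel Channel label (`"nuclear"` or `"cytosolic"`).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_interval_s,
                        channel = c("nuclear", "cytosolic")) {
  channel <- match.arg(channel)
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stop("all frames must share dimensions",
                                 call. = FALSE)
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            frame_interval_s > 0)
  if (any(frames < 0)) stop("pixel values must be non-negative",
                            call. = FALSE)
  structure(list(frames = frames, frame_interval_s = frame_interval_s,
                 channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %s channel, %d x %d px, %d frame(s) every %g s\n",
              x$channel, d[1], d[2], d[3], x$frame_interval_s))
  invisible(x)
}

#' Subtract background from an image stack
#'
#' Constant mode subtracts a fixed level from every pixel; percentile mode
#' subtracts the per-frame p-th percentile. Results are clipped at zero.
#'
#' @param stack An [image_stack].
#' @param mode `"constant"` or `"percentile"`.
#' @param value Background level (constant mode) or percentile in
#'   `[0, 100]` (percentile mode).
#' @return A background-subtracted [image_stack].
#' @export
subtract_background <- function(stack, mode = c("constant", "percentile"),
                                value) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "image_stack"))
  fr <- stack$frames
  if (mode == "constant") {
    fr <- pmax(fr - value, 0)
  } else {
    if (value < 0 || value > 100) {
      stop("percentile must lie in [0, 100]", call. = FALSE)
    }
    for (k in seq_len(dim(fr)[3])) {
      bg <- stats::quantile(fr[, , k], probs = value / 100, names = FALSE)
      fr[, , k] <- pmax(fr[, , k] - bg, 0)
    }
  }
  image_stack(fr, stack$frame_interval_s, stack$channel)
}

check_roi_bounds <- function(rois, h, w) {
  bad <- rois$x_px - rois$radius_px < 1 | rois$x_px + rois$radius_px > w |
    rois$y_px - rois$radius_px < 1 | rois$y_px + rois$radius_px > h |
    rois$radius_px <= 0
  if (any(bad)) {
    stop(sprintf("ROI(s) out of frame bounds or degenerate: %s",
                 paste(rois$cell_id[bad], collapse = ", ")), call. = FALSE)
  }
}

#' Extract per-ROI mean-intensity traces from an image stack
#'
#' For each circular ROI, the trace value at each frame is the mean of all
#' pixels whose centre lies within the ROI radius. Extraction is linear in
#' the pixel values.
#'
#' @param stack An [image_stack].
#' @param rois Data frame with columns `cell_id`, `x_px`, `y_px`,
#'   `radius_px` and optionally `position_um`.
#' @param plant_id Plant label attached to the extracted traces.
#' @return A list of [fluorescence_trace] objects, one per ROI.
#' @export
extract_roi_traces <- function(stack, rois, plant_id = "p1") {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  check_roi_bounds(rois, d[1], d[2])
  times <- (seq_len(d[3]) - 1L) * stack$frame_interval_s
  xs <- matrix(rep(seq_len(d[2]), each = d[1]), nrow = d[1])
  ys <- matrix(rep(seq_len(d[1]), times = d[2]), nrow = d[1])
  lapply(seq_len(nrow(rois)), function(i) {
    mask <- (xs - rois$x_px[i])^2 + (ys - rois$y_px[i])^2 <=
      rois$radius_px[i]^2
    vals <- vapply(seq_len(d[3]), function(k)
      mean(stack$frames[, , k][mask]), numeric(1))
    fluorescence_trace(
      plant_id = plant_id, cell_id = as.character(rois$cell_id[i]),
      channel = stack$channel, times = times, intensities = vals,
      frame_interval = stack$frame_interval_s,
      position_um = if ("position_um" %in% names(rois))
        rois$position_um[i] else NA_real_)
  })
}

#' Simulate a two-channel nucleus movie
#'
#' Renders each nucleus as a Gaussian blob whose peak brightness follows a
#' simulated fluorescence trace (one spiking event per nucleus, cytosolic
#' channel lagging per the configuration). Pixel values are rounded to
#' integer counts so TIFF round trips are exact. Intended for end-to-end
#' testing of the ROI front end: extracting the ROIs and running the
#' detector recovers the injected spikes.
#'
#' @param config A [sim_config]; pixel noise comes from `noise_sigma`
#'   scaled down by `pixel_noise_scale`.
#' @param nuclei Data frame with `cell_id`, `x_px`, `y_px`, `radius_px`
#'   and optionally `position_um`.
#' @param dim_px Frame height and width in pixels (default `c(48, 48)`).
#' @param background Constant background level added to every pixel
#'   (default 10).
#' @param pixel_noise_scale Multiplier applied to `noise_sigma` for
#'   per-pixel noise (default 0.1).
#' @param seed Seed applied for this call (default `config$seed`).
#' @return A list with `nuclear` and `cytosolic` [image_stack]s, the
#'   underlying `traces` (per nucleus and channel) and the spike `truth`
#'   table.
#' @export
simulate_stack <- function(config, nuclei, dim_px = c(48, 48),
                           background = 10, pixel_noise_scale = 0.1,
                           seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  check_roi_bounds(nuclei, dim_px[1], dim_px[2])
  run <- function() {
    n_frames <- length(seq(0, config$duration_s,
                           by = config$frame_interval_s))
    xs <- matrix(rep(seq_len(dim_px[2]), each = dim_px[1]),
                 nrow = dim_px[1])
    ys <- matrix(rep(seq_len(dim_px[1]), times = dim_px[2]),
                 nrow = dim_px[1])
    stacks <- list()
    traces <- list()
    truth <- list()
    for (ch in c("nuclear", "cytosolic")) {
      fr <- array(background, dim = c(dim_px[1], dim_px[2], n_frames))
      for (i in seq_len(nrow(nuclei))) {
        pair_seedless <- simulate_cell_pair(
          config, plant_id = "p1",
          cell_id = as.character(nuclei$cell_id[i]),
          position_um = if ("position_um" %in% names(nuclei))
            nuclei$position_um[i] else NA_real_,
          seed = NULL)
        tr <- pair_seedless[[ch]]
        traces[[paste(ch, nuclei$cell_id[i], sep = "|")]] <- tr
        truth[[paste(ch, nuclei$cell_id[i], sep = "|")]] <-
          pair_seedless$truth[pair_seedless$truth$channel == ch, ,
                              drop = FALSE]
        sgm <- nuclei$radius_px[i] / 2
        blob <- exp(-((xs - nuclei$x_px[i])^2 + (ys - nuclei$y_px[i])^2) /
                      (2 * sgm^2))
        for (k in seq_len(n_frames)) {
          fr[, , k] <- fr[, , k] + tr$intensities[k] * blob
        }
      }
      fr <- fr + stats::rnorm(length(fr), 0,
                              config$noise_sigma * pixel_noise_scale)
      fr <- round(pmax(fr, 0))
      stacks[[ch]] <- image_stack(fr, config$frame_interval_s, ch)
    }
    list(nuclear = stacks$nuclear, cytosolic = stacks$cytosolic,
         traces = traces,
         truth = do.call(rbind, c(unname(truth),
                                  list(make.row.names = FALSE))))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Write an image stack to a multi-page 16-bit grayscale TIFF
#'
#' Pixel values are stored as 16-bit counts (0--65535); fractional values
#' are rounded. Frame order is time order.
#'
#' @param stack An [image_stack] with values below 65536.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  fr <- round(stack$frames)
  if (any(fr > 65535)) stop("pixel values exceed 16-bit range",
                            call. = FALSE)
  pages <- lapply(seq_len(dim(fr)[3]), function(k) fr[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page grayscale TIFF written by [write_stack_tiff()]
#'
#' @param path TIFF file path.
#' @param frame_interval_s Frame interval in seconds.
#' @param channel Channel label.
#' @return An [image_stack] with integer count values.
#' @export
read_stack_tiff <- function(path, frame_interval_s,
                            channel = c("nuclear", "cytosolic")) {
  channel <- match.arg(channel)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  fr <- array(unlist(lapply(pages, function(p) round(p * 65535))),
              dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                      length(pages)))
  image_stack(fr, frame_interval_s, channel)
}
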