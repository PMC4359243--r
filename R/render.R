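#' Image-rendering parameters
#'
#' Geometry and noise settings for the synthetic microscope. Defaults give a
#' 256x256 field with ~10-pixel nucleus radii and a 0.5-pixel Gaussian
#' point-spread blur — the scale of a high-content imager after binning
#' (roughly 10 um nuclei at 0.5 um/pixel), where mean-over-mask
#' quantification loses only a few percent of a nucleus' signal to edge
#' blur — plus a camera offset of 10 counts and Gaussian read noise of 2.
#'
#' @param width,height Image size in pixels.
#' @param psf_sigma Gaussian blur SD in pixels (0 disables blurring).
#' @param read_noise_sd SD of additive Gaussian read noise (0 disables).
#' @param offset Constant camera offset added to both channels.
#' @param radius_mean,radius_sd Nucleus radius distribution (pixels).
#' @return Named list of rendering parameters.
#' @export
image_params <- function(width = 256, height = 256, psf_sigma = 0.5,
                         read_noise_sd = 2, offset = 10,
                         radius_mean = 10, radius_sd = 1) {
  list(width = width, height = height, psf_sigma = psf_sigma,
       read_noise_sd = read_noise_sd, offset = offset,
       radius_mean = radius_mean, radius_sd = radius_sd)
}

#' Render a cell population as a two-channel image pair
#'
#' Draws each cell as a filled disc — at its `hoechst_level` in the nuclear
#' channel and its `signal_level` in the signal channel — convolves both
#' channels with a Gaussian blur of `psf_sigma`, adds the camera offset and
#' Gaussian read noise, and clips at zero. Overlapping discs take the
#' pixelwise maximum (nuclei do not sum their stain).
#'
#' @param pop Cell population tibble from [simulate_well_cells()] with
#'   positions (`center_x`, `center_y`, `radius` must be non-`NA`).
#' @param image_params Rendering parameters from [image_params()].
#' @param seed Seed for the read-noise draw; a fixed seed gives identical
#'   images.
#'
#' @return An object of class `image_pair`: list with numeric matrices
#'   `hoechst` and `signal` (rows = y, columns = x), all values >= 0.
#' @export
render_images <- function(pop, image_params = hcscreen::image_params(),
                          seed = 1) {
  w <- image_params$width
  h <- image_params$height
  if (nrow(pop) > 0) {
    if (anyNA(pop$center_x) || anyNA(pop$center_y) || anyNA(pop$radius)) {
      stop_hcs("Population has no positions; simulate with positions = TRUE.",
               "render_error")
    }
    out_of_bounds <- pop$center_x - pop$radius < 0 |
      pop$center_x + pop$radius > w - 1 |
      pop$center_y - pop$radius < 0 |
      pop$center_y + pop$radius > h - 1
    if (any(out_of_bounds)) {
      stop_hcs(sprintf("%d cell(s) extend outside the %dx%d field.",
                       sum(out_of_bounds), w, h), "render_error")
    }
  }

  hoechst <- matrix(0, nrow = h, ncol = w)
  signal <- matrix(0, nrow = h, ncol = w)
  for (i in seq_len(nrow(pop))) {
    cx <- pop$center_x[i]; cy <- pop$center_y[i]; r <- pop$radius[i]
    rows <- max(1, floor(cy - r) + 1):min(h, ceiling(cy + r) + 1)
    cols <- max(1, floor(cx - r) + 1):min(w, ceiling(cx + r) + 1)
    # 0-based pixel coordinates of the candidate box
    dy <- (rows - 1) - cy
    dx <- (cols - 1) - cx
    inside <- outer(dy^2, dx^2, "+") <= r^2
    sub_h <- hoechst[rows, cols, drop = FALSE]
    sub_s <- signal[rows, cols, drop = FALSE]
    sub_h[inside] <- pmax(sub_h[inside], pop$hoechst_level[i])
    sub_s[inside] <- pmax(sub_s[inside], pop$signal_level[i])
    hoechst[rows, cols] <- sub_h
    signal[rows, cols] <- sub_s
  }

  if (image_params$psf_sigma > 0) {
    hoechst <- as.matrix(imageData(gblur(Image(hoechst),
                                         sigma = image_params$psf_sigma)))
    signal <- as.matrix(imageData(gblur(Image(signal),
                                        sigma = image_params$psf_sigma)))
  }
  hoechst <- hoechst + image_params$offset
  signal <- signal + image_params$offset
  if (image_params$read_noise_sd > 0) {
    set.seed(seed)
    hoechst <- hoechst + rnorm(length(hoechst), 0, image_params$read_noise_sd)
    signal <- signal + rnorm(length(signal), 0, image_params$read_noise_sd)
  }
  hoechst[hoechst < 0] <- 0
  signal[signal < 0] <- 0

  structure(list(hoechst = hoechst, signal = signal,
                 plate_id = attr(pop, "plate_id"),
                 well_id = attr(pop, "well_id")),
            class = "image_pair")
}
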