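#' Segmentation parameters
#'
#' @param threshold_method `"otsu"` (parameter-free, default) or `"fixed"`.
#' @param threshold Intensity cutoff when `threshold_method = "fixed"`.
#' @param min_area,max_area Nucleus area limits in pixels (defaults 40 and
#'   5000 at the default render scale); components outside are discarded.
#' @param connectivity Pixel connectivity, 8 (default) or 4.
#' @param exclude_border Drop nuclei touching the image border (default
#'   `TRUE`): their area and mean intensity are truncated.
#' @return Named list of segmentation parameters.
#' @export
segment_params <- function(threshold_method = c("otsu", "fixed"),
                           threshold = NULL, min_area = 40, max_area = 5000,
                           connectivity = 8, exclude_border = TRUE) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && is.null(threshold)) {
    stop_hcs("Fixed thresholding needs a `threshold` value.",
             "parameter_error")
  }
  if (!connectivity %in% c(4, 8)) {
    stop_hcs("`connectivity` must be 4 or 8.", "parameter_error")
  }
  list(threshold_method = threshold_method, threshold = threshold,
       min_area = min_area, max_area = max_area,
       connectivity = connectivity, exclude_border = exclude_border)
}

#' Identify nuclei in the nuclear-stain channel
#'
#' Thresholds the Hoechst image (Otsu by default), labels connected
#' foreground components, and filters them by area and border contact.
#' Touching or strongly overlapping nuclei merge into a single component —
#' a documented limitation of threshold-plus-components segmentation (no
#' watershed splitting).
#'
#' A constant (blank) image yields zero nuclei rather than an error.
#'
#' @param hoechst Numeric matrix (rows = y, columns = x), all values finite
#'   and >= 0, at least 16x16.
#' @param params Segmentation parameters from [segment_params()].
#'
#' @return An object of class `nucleus_masks`: list with `labels` (integer
#'   matrix, 0 = background, nuclei labelled consecutively from 1 in
#'   row-major scan order) and `features` (tibble `label`, `area`,
#'   `centroid_x`, `centroid_y` in 0-based pixel coordinates).
#' @export
segment_nuclei <- function(hoechst, params = segment_params()) {
  if (!is.matrix(hoechst) || nrow(hoechst) < 16 || ncol(hoechst) < 16) {
    stop_hcs("Image must be a numeric matrix of at least 16x16 pixels.",
             "parameter_error")
  }
  if (any(!is.finite(hoechst)) || any(hoechst < 0)) {
    stop_hcs("Image pixels must be finite and >= 0.", "data_error")
  }

  rng <- range(hoechst)
  if (params$threshold_method == "fixed") {
    thr <- params$threshold
  } else {
    if (diff(rng) == 0) return(empty_masks(hoechst))  # blank image
    scaled <- (hoechst - rng[1]) / diff(rng)
    thr <- rng[1] + otsu(Image(scaled), range = c(0, 1)) * diff(rng)
  }
  fg <- hoechst > thr
  if (!any(fg)) return(empty_masks(hoechst))

  labels <- imageData(bwlabel(fg))  # 4-connected components
  if (params$connectivity == 8) {
    labels <- merge_diagonal_labels(labels)
  }
  labels <- matrix(as.integer(labels), nrow = nrow(hoechst))

  area <- tabulate(labels[labels > 0])
  keep <- which(area >= params$min_area & area <= params$max_area)
  if (params$exclude_border) {
    border <- unique(c(labels[1, ], labels[nrow(labels), ],
                       labels[, 1], labels[, ncol(labels)]))
    keep <- setdiff(keep, border)
  }
  if (length(keep) == 0) return(empty_masks(hoechst))

  # relabel consecutively from 1 in row-major scan order
  idx <- which(labels %in% keep)
  rr <- (idx - 1) %% nrow(labels) + 1
  cc <- (idx - 1) %/% nrow(labels) + 1
  old <- labels[idx]
  first_seen <- vapply(keep, function(k) {
    sel <- old == k
    min((rr[sel] - 1) * ncol(labels) + cc[sel])  # row-major rank
  }, numeric(1))
  new_id <- match(keep, keep[order(first_seen)])
  relabelled <- matrix(0L, nrow(labels), ncol(labels))
  relabelled[idx] <- new_id[match(old, keep)]

  grp <- relabelled[idx]
  lab <- sort(unique(grp))
  cx <- tapply(cc - 1, grp, mean)
  cy <- tapply(rr - 1, grp, mean)
  feats <- tibble(
    label = lab,
    area = as.integer(tabulate(grp)[lab]),
    centroid_x = as.numeric(cx[as.character(lab)]),
    centroid_y = as.numeric(cy[as.character(lab)])
  )
  structure(list(labels = relabelled, features = feats),
            class = "nucleus_masks")
}

empty_masks <- function(img) {
  structure(list(labels = matrix(0L, nrow(img), ncol(img)),
                 features = tibble(label = integer(), area = integer(),
                                   centroid_x = numeric(),
                                   centroid_y = numeric())),
            class = "nucleus_masks")
}

# Merge 4-connected labels that touch diagonally (-> 8-connectivity) with a
# small union-find over label pairs.
merge_diagonal_labels <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  a1 <- labels[-nr, -nc]; b1 <- labels[-1, -1]    # down-right diagonal
  a2 <- labels[-nr, -1]; b2 <- labels[-1, -nc]    # down-left diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs) == 0) return(labels)
  n <- max(labels)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- labels
  out[out > 0] <- root[out[out > 0]]
  out
}

#' Per-nucleus mean signal intensity
#'
#' For each nucleus mask, the arithmetic mean of the signal-channel pixels
#' over the mask's pixel set — the per-cell readout of the screen.
#'
#' @param signal Numeric matrix, same dimensions as the segmented Hoechst
#'   image.
#' @param masks A `nucleus_masks` object from [segment_nuclei()].
#' @return Numeric vector of per-nucleus means, ordered by mask label
#'   (empty masks give an empty vector).
#' @export
quantify_nuclei <- function(signal, masks) {
  stopifnot(inherits(masks, "nucleus_masks"))
  if (!all(dim(signal) == dim(masks$labels))) {
    stop_hcs("Signal image and masks have different dimensions.",
             "data_error")
  }
  if (nrow(masks$features) == 0) return(numeric(0))
  sel <- masks$labels > 0
  means <- tapply(signal[sel], masks$labels[sel], mean)
  as.numeric(means[as.character(masks$features$label)])
}

#' Aggregate per-nucleus values to a well measurement
#'
#' The well readout is the mean over nuclei of the per-nucleus mean signal.
#' Wells with fewer nuclei than `min_nuclei` are flagged invalid (their mean
#' is too unstable to enter plate normalization) but not dropped; wells with
#' zero nuclei have an undefined `raw_value`.
#'
#' @param per_nucleus Numeric vector of per-nucleus mean intensities.
#' @param min_nuclei Minimum nucleus count for a valid well (default 50).
#' @return One-row tibble: `n_nuclei`, `raw_value`, `valid`.
#' @export
aggregate_well <- function(per_nucleus, min_nuclei = 50) {
  n <- length(per_nucleus)
  tibble(n_nuclei = n,
         raw_value = if (n >= 1) mean(per_nucleus) else NA_real_,
         valid = n >= min_nuclei)
}

#' Quantify one well from its image pair
#'
#' Convenience wrapper: segment the Hoechst channel, measure per-nucleus
#' signal means, aggregate to the well level.
#'
#' @param pair An `image_pair` (or list with `hoechst` and `signal`
#'   matrices).
#' @param params Segmentation parameters.
#' @param min_nuclei Minimum nucleus count for a valid well.
#' @return One-row tibble: `plate_id`, `well_id` (if carried by the pair),
#'   `n_nuclei`, `raw_value`, `valid`.
#' @export
quantify_well <- function(pair, params = segment_params(), min_nuclei = 50) {
  masks <- segment_nuclei(pair$hoechst, params)
  vals <- quantify_nuclei(pair$signal, masks)
  out <- aggregate_well(vals, min_nuclei)
  tibble(plate_id = pair$plate_id %||% NA_character_,
         well_id = pair$well_id %||% NA_character_, out)
}

#' Subtract background-well signal
#'
#' Subtracts the mean raw value of the background wells (stained without the
#' primary antibody) from every sample and control well, per plate by
#' default. Background wells themselves get no corrected value and are
#' excluded from downstream normalization. Negative corrected values are
#' retained — clamping would bias the plate statistics — and reported via a
#' warning.
#'
#' @param wells Well-measurement tibble with `plate_id`, `well_id`,
#'   `raw_value`, `valid` and (directly or via `layout`) a `content` column.
#' @param layout Optional `plate_layout` supplying `content` (and `gene_id`)
#'   when `wells` lacks them.
#' @param scope `"per_plate"` (default; background wells of each plate
#'   correct that plate) or `"global"` (one background mean for the screen).
#' @return `wells` with columns `content`, `background_mean` and
#'   `corrected_value` added (`NA` for background and empty wells).
#' @export
subtract_background <- function(wells, layout = NULL,
                                scope = c("per_plate", "global")) {
  scope <- match.arg(scope)
  if (!"content" %in% names(wells)) {
    if (is.null(layout)) {
      stop_hcs("`wells` has no `content` column and no layout was given.",
               "data_error")
    }
    keep <- c("plate_id", "well_id", "content",
              intersect("gene_id", names(layout)))
    wells <- left_join(wells, layout[, keep], by = c("plate_id", "well_id"))
  }
  bg <- wells$content == "background" & wells$valid & !is.na(wells$raw_value)
  if (scope == "global") {
    if (!any(bg)) {
      stop_hcs("No valid background wells in the screen.",
               "missing_background")
    }
    wells$background_mean <- mean(wells$raw_value[bg])
  } else {
    bg_means <- tapply(wells$raw_value[bg], wells$plate_id[bg], mean)
    missing <- setdiff(unique(wells$plate_id), names(bg_means))
    if (length(missing) > 0) {
      stop_hcs(paste0("No valid background wells on plate(s): ",
                      paste(missing, collapse = ", ")),
               "missing_background")
    }
    wells$background_mean <- as.numeric(bg_means[wells$plate_id])
  }
  wells$corrected_value <- wells$raw_value - wells$background_mean
  drop <- wells$content %in% c("background", "empty")
  wells$corrected_value[drop] <- NA_real_
  n_neg <- sum(wells$corrected_value < 0, na.rm = TRUE)
  if (n_neg > 0) {
    rlang::warn(sprintf(
      "%d well(s) have negative background-corrected values (retained).",
      n_neg), class = "hcs_negative_corrected")
  }
  wells
}
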