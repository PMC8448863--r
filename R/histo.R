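# Adipocyte histomorphometry: neighbourhood median/sd/product features,
# luminance+texture thresholding, watershed separation of clustered
# vacuoles, area/form-factor shape filtering and per-biopsy morphometry.

#' Segmentation parameters
#'
#' @param window_radius_px neighbourhood radius for the median/sd filters
#'   (window is `(2r+1) x (2r+1)`).
#' @param luminance_threshold `"auto"` (Otsu split of the median-luminance
#'   histogram inside the ROI, upper class kept) or a fixed value in \[0,1\].
#' @param texture_threshold `"auto"` (Otsu split of the moving-sd histogram,
#'   lower class kept) or a fixed value.
#' @param min_area_um2,max_area_um2 object area bounds in um^2.
#' @param min_form_factor minimum compactness `4*pi*A/P^2` (circle = 1).
#' @param separation_enabled split clustered vacuoles by watershed.
#' @param min_seed_separation_um minimum distance between watershed seeds.
#' @param exclude_border drop objects touching the ROI/image border.
#' @return validated list of class `segmentation_params`.
#' @export
segmentation_params <- function(window_radius_px = 3,
                                luminance_threshold = "auto",
                                texture_threshold = "auto",
                                min_area_um2 = 200, max_area_um2 = 15000,
                                min_form_factor = 0.5,
                                separation_enabled = TRUE,
                                min_seed_separation_um = 15,
                                exclude_border = FALSE) {
  stop_if_not_count(window_radius_px, "window_radius_px", lower = 1)
  for (th in list(luminance_threshold, texture_threshold)) {
    if (!(identical(th, "auto") || (is.numeric(th) && length(th) == 1 && is.finite(th))))
      stop("thresholds must be \"auto\" or a single finite number", call. = FALSE)
  }
  stop_if_not_scalar_number(min_area_um2, "min_area_um2", lower = 1e-12)
  stop_if_not_scalar_number(max_area_um2, "max_area_um2", lower = min_area_um2)
  if (min_area_um2 >= max_area_um2)
    stop("need min_area_um2 < max_area_um2", call. = FALSE)
  stop_if_not_scalar_number(min_form_factor, "min_form_factor", lower = 0, upper = 1)
  stop_if_not_scalar_number(min_seed_separation_um, "min_seed_separation_um", lower = 0)
  structure(list(window_radius_px = as.integer(window_radius_px),
                 luminance_threshold = luminance_threshold,
                 texture_threshold = texture_threshold,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 min_form_factor = min_form_factor,
                 separation_enabled = isTRUE(separation_enabled),
                 min_seed_separation_um = min_seed_separation_um,
                 exclude_border = isTRUE(exclude_border)),
            class = "segmentation_params")
}

reflect_pad <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc) stop("radius too large for image", call. = FALSE)
  ri <- c(r:1, 1:nr, nr:(nr - r + 1))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1))
  m[ri, ci]
}

#' Neighbourhood median / standard deviation / product features
#'
#' Converts the image to scalar luminance and computes, over a square
#' `(2r+1) x (2r+1)` window with reflected borders: the moving median, the
#' moving standard deviation, and their elementwise product.
#'
#' @param image an Image2D list (`data`, `pixel_size_um`), an RGB array or a
#'   luminance matrix with values in \[0, 1\].
#' @param radius window radius in pixels (>= 1).
#' @return list of class `feature_image` with matrices `median`, `sd`,
#'   `product` and the `pixel_size_um` carried over (if available).
#' @export
neighborhood_features <- function(image, radius = 3) {
  px <- if (is.list(image)) image$pixel_size_um else NA_real_
  dat <- if (is.list(image)) image$data else image
  lum <- luminance(dat)
  radius <- stop_if_not_count(radius, "radius", lower = 1)
  if (radius > min(dim(lum)) / 2)
    stop("radius larger than half the smaller image dimension", call. = FALSE)
  pad <- reflect_pad(lum, radius)
  med <- EBImage::medianFilter(pad, radius)
  box <- matrix(1 / (2 * radius + 1)^2, 2 * radius + 1, 2 * radius + 1)
  m1 <- EBImage::filter2(pad, box)
  m2 <- EBImage::filter2(pad^2, box)
  sdv <- sqrt(pmax(m2 - m1^2, 0))
  nr <- nrow(lum); nc <- ncol(lum)
  crop <- function(x) as.matrix(x)[radius + seq_len(nr), radius + seq_len(nc)]
  med <- crop(med); sdv <- crop(sdv)
  structure(list(median = med, sd = sdv, product = med * sdv,
                 pixel_size_um = px), class = "feature_image")
}

# Otsu threshold on a numeric sample (256-bin histogram); maximises
# between-class variance. Degenerate (single-bin) input -> error.
otsu_threshold <- function(x, what) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) < 1e-12)
    stop(sprintf(
      "cannot auto-threshold the %s channel: histogram is degenerate (constant); supply a fixed threshold",
      what), call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = 256)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[256]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Threshold adipocyte vacuoles from neighbourhood features
#'
#' Candidate vacuole pixels are bright (`median >= luminance_threshold`) and
#' inside the ROI; the low-texture condition (`sd <= texture_threshold`)
#' seeds true vacuoles (their interiors are smooth, whereas textured-bright
#' artefacts are not). The mask is the union of bright connected components
#' containing at least one seed pixel (morphological reconstruction), with
#' interior holes filled. `"auto"` thresholds use an Otsu histogram split
#' inside the ROI.
#'
#' @param features a [neighborhood_features()] result.
#' @param roi ROI mask: list(`mask`, `pixel_size_um`) or a logical matrix.
#' @param params a [segmentation_params()] object.
#' @return logical matrix.
#' @export
threshold_adipocytes <- function(features, roi, params = segmentation_params()) {
  stopifnot(inherits(features, "feature_image"))
  roi_m <- if (is.list(roi)) roi$mask else roi
  if (!all(dim(roi_m) == dim(features$median)))
    stop("ROI shape does not match feature image", call. = FALSE)
  if (!any(roi_m)) stop("ROI is empty", call. = FALSE)
  L <- params$luminance_threshold
  if (identical(L, "auto")) L <- otsu_threshold(features$median[roi_m], "median-luminance")
  Tt <- params$texture_threshold
  if (identical(Tt, "auto")) Tt <- otsu_threshold(features$sd[roi_m], "texture (sd)")
  extent <- features$median >= L & roi_m
  core <- extent & features$sd <= Tt
  if (!any(core)) return(matrix(FALSE, nrow(extent), ncol(extent)))
  comp <- EBImage::bwlabel(extent)
  keep <- unique(comp[core])
  keep <- keep[keep > 0]
  mask <- matrix(as.matrix(comp) %in% keep, nrow(extent), ncol(extent))
  as.matrix(EBImage::fillHull(mask)) > 0
}

#' Separate clustered vacuoles by watershed on the distance transform
#'
#' Connected blobs holding two or more distance-transform maxima at least
#' `min_seed_separation_um` apart are split along watershed lines of the
#' negated distance transform; ridge pixels are assigned to a neighbouring
#' object, so the total labelled area equals the input mask area exactly.
#'
#' @param mask logical or 0/1 matrix.
#' @param pixel_size_um physical pixel size.
#' @param min_seed_separation_um minimum seed separation (um); maxima closer
#'   than this are merged into one object.
#' @return integer label matrix (0 = background).
#' @export
separate_clusters <- function(mask, pixel_size_um, min_seed_separation_um = 15) {
  stop_if_not_scalar_number(pixel_size_um, "pixel_size_um", lower = 1e-12)
  m <- (mask > 0) * 1
  if (!any(m > 0)) return(matrix(0L, nrow(m), ncol(m)))
  sep_px <- min_seed_separation_um / pixel_size_um
  dm <- EBImage::distmap(m)
  ws <- EBImage::watershed(dm, tolerance = 1, ext = max(1L, as.integer(round(sep_px / 2))))
  out <- matrix(as.integer(as.matrix(ws)), nrow(m), ncol(m))
  out
}

# Perimeter of a binary object by a corner-weighted crack-boundary
# estimator: P = a * (# unit crack edges) + b * (# boundary corner turns),
# a = 1.010, b = -0.3725, calibrated on rasterised disks (r = 10..60 px) and
# axis-aligned rectangles so both are near-unbiased. A floor at the
# equal-area circle perimeter / sqrt(1 + eps) guards degenerate tiny objects
# so the form factor never exceeds 1 + eps (eps = 0.05).
perimeter_crack <- function(m) {
  p <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
  p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- (m > 0) * 1L
  n_edges <- sum(p[-1, ] != p[-nrow(p), ]) + sum(p[, -1] != p[, -ncol(p)])
  a <- p[-nrow(p), -ncol(p)]; b <- p[-nrow(p), -1]
  c_ <- p[-1, -ncol(p)]; d <- p[-1, -1]
  s <- a + b + c_ + d
  diagx <- (a == d) & (b == c_) & (a != b)
  n_corner <- sum(s == 1L | s == 3L) + 2L * sum(diagx)
  pe <- 1.010 * n_edges - 0.3725 * n_corner
  area <- sum(p)
  max(pe, 2 * sqrt(pi * area / 1.05))
}

#' Filter labelled objects by area and form factor
#'
#' Computes per-object geometry in physical units and keeps objects with
#' `min_area_um2 <= area <= max_area_um2` and form factor
#' `4*pi*A/P^2 >= min_form_factor`. Perimeter uses a corner-weighted
#' crack-boundary estimator (see the methods vignette) to reduce
#' rasterisation bias.
#'
#' @param labels integer label matrix.
#' @param pixel_size_um physical pixel size (> 0).
#' @param params a [segmentation_params()] object.
#' @return data.frame with columns `label`, `area_um2`, `perimeter_um`,
#'   `form_factor`, `centroid_row`, `centroid_col`, `bbox_r0`, `bbox_r1`,
#'   `bbox_c0`, `bbox_c1` (0-based row/col origin at top-left).
#' @export
shape_filter <- function(labels, pixel_size_um, params = segmentation_params()) {
  stop_if_not_scalar_number(pixel_size_um, "pixel_size_um", lower = 1e-12)
  if (any(labels < 0)) stop("labels must be non-negative integers", call. = FALSE)
  labs <- sort(unique(labels[labels > 0]))
  nr <- nrow(labels)
  empty <- data.frame(label = integer(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), form_factor = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      bbox_r0 = integer(0), bbox_r1 = integer(0),
                      bbox_c0 = integer(0), bbox_c1 = integer(0))
  if (length(labs) == 0) return(empty)
  rows <- lapply(labs, function(l) {
    idx <- which(labels == l)
    r <- (idx - 1L) %% nr + 1L
    cc <- (idx - 1L) %/% nr + 1L
    r0 <- min(r); r1 <- max(r); c0 <- min(cc); c1 <- max(cc)
    sub <- matrix(FALSE, r1 - r0 + 1, c1 - c0 + 1)
    sub[cbind(r - r0 + 1L, cc - c0 + 1L)] <- TRUE
    area_px <- length(idx)
    per_px <- perimeter_crack(sub)
    area <- area_px * pixel_size_um^2
    per <- per_px * pixel_size_um
    data.frame(label = l, area_um2 = area, perimeter_um = per,
               form_factor = 4 * pi * area / per^2,
               centroid_row = mean(r) - 1, centroid_col = mean(cc) - 1,
               bbox_r0 = r0 - 1L, bbox_r1 = r1 - 1L,
               bbox_c0 = c0 - 1L, bbox_c1 = c1 - 1L)
  })
  out <- do.call(rbind, rows)
  keep <- out$area_um2 >= params$min_area_um2 &
    out$area_um2 <= params$max_area_um2 &
    out$form_factor >= params$min_form_factor
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-biopsy morphometry summary
#'
#' @param objects data.frame from [shape_filter()].
#' @param roi ROI mask list (`mask`, `pixel_size_um`) or logical matrix plus
#'   `pixel_size_um` argument.
#' @param pixel_size_um required if `roi` is a bare matrix.
#' @return list with `n_adipocytes`, `roi_area_mm2`, `density_per_mm2`,
#'   `sizes_um2`, `mean_size_um2`, `median_size_um2`.
#' @export
morphometry <- function(objects, roi, pixel_size_um = NULL) {
  if (is.list(roi) && !is.matrix(roi)) {
    mask <- roi$mask; px <- roi$pixel_size_um
  } else {
    mask <- roi; px <- pixel_size_um
  }
  stop_if_not_scalar_number(px, "pixel_size_um", lower = 1e-12)
  roi_area_mm2 <- sum(mask) * px^2 * 1e-6
  if (roi_area_mm2 <= 0) stop("ROI area is zero", call. = FALSE)
  n <- nrow(objects)
  sizes <- objects$area_um2
  list(n_adipocytes = n, roi_area_mm2 = roi_area_mm2,
       density_per_mm2 = n / roi_area_mm2, sizes_um2 = sizes,
       mean_size_um2 = if (n > 0) mean(sizes) else NA_real_,
       median_size_um2 = if (n > 0) median(sizes) else NA_real_)
}

#' Full adipocyte segmentation pipeline on one image
#'
#' Chains [neighborhood_features()], [threshold_adipocytes()],
#' [separate_clusters()] (or plain connected-component labelling when
#' separation is disabled), [shape_filter()] and [morphometry()].
#'
#' @param image Image2D list (`data`, `pixel_size_um`).
#' @param roi ROI mask list (`mask`, `pixel_size_um`).
#' @param params a [segmentation_params()] object.
#' @return list with `objects`, `labels`, `mask`, `summary`, `params`.
#' @export
segment_adipocytes <- function(image, roi, params = segmentation_params()) {
  px <- image$pixel_size_um
  feats <- neighborhood_features(image, params$window_radius_px)
  mask <- threshold_adipocytes(feats, roi, params)
  labels <- if (params$separation_enabled) {
    separate_clusters(mask, px, params$min_seed_separation_um)
  } else {
    matrix(as.integer(as.matrix(EBImage::bwlabel(mask * 1))), nrow(mask), ncol(mask))
  }
  objects <- shape_filter(labels, px, params)
  if (params$exclude_border && nrow(objects) > 0) {
    roi_m <- if (is.list(roi)) roi$mask else roi
    er <- as.matrix(EBImage::erode(roi_m * 1, EBImage::makeBrush(3, "box"))) > 0
    border_labs <- unique(labels[labels > 0 & !er])
    objects <- objects[!(objects$label %in% border_labs), , drop = FALSE]
  }
  keep_ids <- objects$label
  labels_kept <- labels
  labels_kept[!(labels %in% keep_ids)] <- 0L
  list(objects = objects, labels = labels_kept, mask = mask,
       summary = morphometry(objects, roi), params = params)
}
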