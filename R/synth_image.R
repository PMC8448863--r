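# Synthetic H&E-style bone-marrow images with known adipocyte ground truth.
#
# Adipocyte "ghosts" (lipid dissolved during processing) appear as bright,
# low-texture elliptical vacuoles on an eosin-pink, noisy marrow background,
# optionally with a thin darker rim just outside each vacuole. Dark artifact
# blobs (tears / bone bands) can be planted outside the ROI.

#' Parameters for the synthetic marrow image generator
#'
#' @param width_px,height_px image size in pixels.
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @param n_adipocytes number of vacuoles to plant.
#' @param median_diameter_um,sigma_log lognormal size distribution of the
#'   equivalent-circle diameter (median in um, log-sd).
#' @param cluster_fraction fraction of adipocytes placed as touching pairs
#'   (overlapping by 10-30 percent of the smaller radius) in \[0, 1\].
#' @param background_noise_sd Gaussian intensity noise sd (on the \[0, 1\]
#'   scale) added to non-vacuole pixels.
#' @param n_artifacts number of dark artifact blobs planted outside the ROI.
#' @param rim logical; draw a thin darker rim just outside each vacuole.
#' @param seed RNG seed (explicit; no global state is consumed).
#' @return validated parameter list of class `marrow_image_params`.
#' @export
marrow_image_params <- function(width_px = 1024, height_px = 1024,
                                pixel_size_um = 1, n_adipocytes = 50,
                                median_diameter_um = 55, sigma_log = 0.25,
                                cluster_fraction = 0, background_noise_sd = 0.03,
                                n_artifacts = 0, rim = TRUE, seed = 1) {
  stop_if_not_count(width_px, "width_px", lower = 1)
  stop_if_not_count(height_px, "height_px", lower = 1)
  stop_if_not_scalar_number(pixel_size_um, "pixel_size_um", lower = 1e-9)
  stop_if_not_count(n_adipocytes, "n_adipocytes", lower = 0)
  stop_if_not_scalar_number(median_diameter_um, "median_diameter_um", lower = 1e-9)
  stop_if_not_scalar_number(sigma_log, "sigma_log", lower = 0)
  stop_if_not_scalar_number(cluster_fraction, "cluster_fraction", lower = 0, upper = 1)
  stop_if_not_scalar_number(background_noise_sd, "background_noise_sd", lower = 0)
  stop_if_not_count(n_artifacts, "n_artifacts", lower = 0)
  structure(list(width_px = as.integer(width_px), height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um, n_adipocytes = as.integer(n_adipocytes),
                 median_diameter_um = median_diameter_um, sigma_log = sigma_log,
                 cluster_fraction = cluster_fraction,
                 background_noise_sd = background_noise_sd,
                 n_artifacts = as.integer(n_artifacts), rim = isTRUE(rim),
                 seed = as.integer(seed)),
            class = "marrow_image_params")
}

# Logical mask of an ellipse on an nr x nc grid (pixel centres inside).
ellipse_mask <- function(nr, nc, cy, cx, a_row, a_col, theta, bbox_pad = 2) {
  rmax <- max(a_row, a_col) + bbox_pad
  r0 <- max(1L, floor(cy - rmax)); r1 <- min(nr, ceiling(cy + rmax))
  c0 <- max(1L, floor(cx - rmax)); c1 <- min(nc, ceiling(cx + rmax))
  if (r0 > r1 || c0 > c1) return(NULL)
  rr <- r0:r1; cc <- c0:c1
  y <- outer(rr - cy, rep(1, length(cc)))
  x <- outer(rep(1, length(rr)), cc - cx)
  u <- y * cos(theta) + x * sin(theta)
  v <- -y * sin(theta) + x * cos(theta)
  inside <- (u / a_row)^2 + (v / a_col)^2 <= 1
  list(rows = rr, cols = cc, inside = inside)
}

paint <- function(canvas, em, value) {
  sub <- canvas[em$rows, em$cols]
  sub[em$inside] <- value
  canvas[em$rows, em$cols] <- sub
  canvas
}

#' Generate a synthetic marrow image with adipocyte ground truth
#'
#' @param params a [marrow_image_params()] object.
#' @return list with elements `image` (list: `data` rows x cols x 3 array in
#'   \[0,1\], `pixel_size_um`), `roi` (list: `mask` logical matrix,
#'   `pixel_size_um`), and `truth` (list: `true_count`, `objects` data.frame
#'   with per-object `label`, `area_um2`, `centroid_row`, `centroid_col`,
#'   `is_pair_member`, and `label_map` integer matrix).
#' @export
gen_marrow_image <- function(params) {
  stopifnot(inherits(params, "marrow_image_params"))
  p <- params
  nr <- p$height_px; nc <- p$width_px
  if (nr < 8 || nc < 8) stop("image too small to carry any content", call. = FALSE)
  with_seed(p$seed, {
    label_map <- matrix(0L, nr, nc)
    roi <- matrix(TRUE, nr, nc)
    artifact <- matrix(FALSE, nr, nc)

    # Artifacts first; ROI excludes them with a safety margin.
    if (p$n_artifacts > 0) {
      for (i in seq_len(p$n_artifacts)) {
        a <- runif(1, 15, 40) / p$pixel_size_um
        em <- ellipse_mask(nr, nc, runif(1, 1, nr), runif(1, 1, nc),
                           a * runif(1, 1, 2), a, runif(1, 0, pi))
        if (!is.null(em)) artifact <- paint(artifact, em, TRUE)
      }
      margin <- max(3, round(15 / p$pixel_size_um))
      roi <- !(EBImage::dilate(artifact, EBImage::makeBrush(
        2L * as.integer(margin %/% 2) + 1L, "disc")) > 0)
    }

    # Sample sizes/orientations, then place: pairs first (they need room).
    n <- p$n_adipocytes
    n_pairs <- floor(round(p$cluster_fraction * n) / 2)
    n_single <- n - 2L * n_pairs
    placed <- data.frame(cy = numeric(0), cx = numeric(0), r = numeric(0))
    gap_px <- max(6, round(8 / p$pixel_size_um))
    max_attempts <- 400L * max(1L, n)
    attempts <- 0L
    next_label <- 1L

    radius_px <- function() {
      d <- exp(rnorm(1, log(p$median_diameter_um), p$sigma_log))
      (d / 2) / p$pixel_size_um
    }
    fits <- function(cy, cx, r) {
      if (cy - r < 2 || cy + r > nr - 1 || cx - r < 2 || cx + r > nc - 1) return(FALSE)
      em <- ellipse_mask(nr, nc, cy, cx, r + 2, r + 2, 0)
      if (any(!roi[em$rows, em$cols][em$inside])) return(FALSE)
      if (nrow(placed) > 0 &&
          any(sqrt((placed$cy - cy)^2 + (placed$cx - cx)^2) < placed$r + r + gap_px))
        return(FALSE)
      TRUE
    }
    add_object <- function(cy, cx, a_row, a_col, theta, pair) {
      em <- ellipse_mask(nr, nc, cy, cx, a_row, a_col, theta)
      sub <- label_map[em$rows, em$cols]
      sub[em$inside] <- next_label
      label_map[em$rows, em$cols] <<- sub
      placed[nrow(placed) + 1L, ] <<- list(cy, cx, max(a_row, a_col))
      pair_flag[next_label] <<- pair
      next_label <<- next_label + 1L
    }
    pair_flag <- logical(0)

    for (i in seq_len(n_pairs)) {
      repeat {
        attempts <- attempts + 1L
        if (attempts > max_attempts)
          stop(sprintf(
            "could not place %d adipocytes in a %dx%d image without exceeding the packing limit (placed %d)",
            n, nc, nr, nrow(placed)), call. = FALSE)
        r1 <- radius_px(); r2 <- radius_px()
        ov <- runif(1, 0.1, 0.3)
        dist <- r1 + r2 - ov * min(r1, r2)
        cy1 <- runif(1, 1, nr); cx1 <- runif(1, 1, nc)
        ang <- runif(1, 0, 2 * pi)
        cy2 <- cy1 + dist * sin(ang); cx2 <- cx1 + dist * cos(ang)
        # the pair occupies one bounding disc for collision purposes
        ccy <- (cy1 + cy2) / 2; ccx <- (cx1 + cx2) / 2
        rr <- dist / 2 + max(r1, r2)
        if (fits(ccy, ccx, rr)) {
          # assign overlap pixels to the nearer centre: draw both, then fix
          add_object(cy1, cx1, r1, r1, 0, TRUE)
          em2 <- ellipse_mask(nr, nc, cy2, cx2, r2, r2, 0)
          sub <- label_map[em2$rows, em2$cols]
          lab1 <- next_label - 1L
          both <- em2$inside & sub == lab1
          if (any(both)) {
            y <- outer(em2$rows - cy1, rep(1, length(em2$cols)))
            x <- outer(rep(1, length(em2$rows)), em2$cols - cx1)
            d1 <- sqrt(y^2 + x^2)
            y2 <- outer(em2$rows - cy2, rep(1, length(em2$cols)))
            x2 <- outer(rep(1, length(em2$rows)), em2$cols - cx2)
            d2 <- sqrt(y2^2 + x2^2)
            take <- em2$inside & (sub != lab1 | d2 < d1)
          } else take <- em2$inside
          sub[take] <- next_label
          label_map[em2$rows, em2$cols] <- sub
          placed[nrow(placed) + 1L, ] <- list(cy2, cx2, r2)
          pair_flag[next_label] <- TRUE
          next_label <- next_label + 1L
          break
        }
      }
    }

    for (i in seq_len(n_single)) {
      repeat {
        attempts <- attempts + 1L
        if (attempts > max_attempts)
          stop(sprintf(
            "could not place %d adipocytes in a %dx%d image without exceeding the packing limit (placed %d)",
            n, nc, nr, nrow(placed)), call. = FALSE)
        r <- radius_px()
        q <- runif(1, 1, 1.6)              # axis ratio; keeps form factor high
        a_row <- r * sqrt(q); a_col <- r / sqrt(q)
        theta <- runif(1, 0, pi)
        cy <- runif(1, 1, nr); cx <- runif(1, 1, nc)
        if (fits(cy, cx, max(a_row, a_col))) {
          add_object(cy, cx, a_row, a_col, theta, FALSE)
          break
        }
      }
    }

    # Render. Eosin-pink marrow, bright smooth vacuoles, optional dark rim.
    vac <- label_map > 0
    bg_rgb <- c(0.90, 0.62, 0.70)
    vac_rgb <- c(0.96, 0.94, 0.96)
    rim_rgb <- c(0.55, 0.35, 0.45)
    art_rgb <- c(0.30, 0.22, 0.28)
    rim_mask <- matrix(FALSE, nr, nc)
    if (p$rim && any(vac)) {
      rim_mask <- (EBImage::dilate(vac, EBImage::makeBrush(3, "box")) > 0) & !vac
    }
    img <- array(0, dim = c(nr, nc, 3))
    for (ch in 1:3) {
      plane <- matrix(bg_rgb[ch], nr, nc)
      if (p$background_noise_sd > 0)
        plane <- plane + matrix(rnorm(nr * nc, 0, p$background_noise_sd), nr, nc)
      plane[rim_mask] <- rim_rgb[ch] +
        if (p$background_noise_sd > 0) rnorm(sum(rim_mask), 0, p$background_noise_sd) else 0
      plane[vac] <- vac_rgb[ch]
      plane[artifact] <- art_rgb[ch]
      img[, , ch] <- pmin(1, pmax(0, plane))
    }

    labs <- sort(unique(label_map[label_map > 0]))
    objects <- if (length(labs) == 0) {
      data.frame(label = integer(0), area_um2 = numeric(0),
                 centroid_row = numeric(0), centroid_col = numeric(0),
                 is_pair_member = logical(0))
    } else {
      idx <- which(label_map > 0)
      lab <- label_map[idx]
      rows <- (idx - 1L) %% nr + 1L
      cols <- (idx - 1L) %/% nr + 1L
      cnt <- tabulate(lab, nbins = max(labs))
      data.frame(label = labs,
                 area_um2 = cnt[labs] * p$pixel_size_um^2,
                 centroid_row = tapply(rows, lab, mean)[as.character(labs)],
                 centroid_col = tapply(cols, lab, mean)[as.character(labs)],
                 is_pair_member = pair_flag[labs],
                 row.names = NULL)
    }
    list(image = list(data = img, pixel_size_um = p$pixel_size_um),
         roi = list(mask = roi, pixel_size_um = p$pixel_size_um),
         truth = list(true_count = length(labs), objects = objects,
                      label_map = label_map))
  })
}
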