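#' Simulate ground-truth geometry for one microscope field
#'
#' Places non-touching lymphocyte nuclei at random positions in a field,
#' assigns each a Poisson number of gamma-H2AX foci at well-separated
#' positions inside the nucleus, distributes foci over the optical planes,
#' and marks a configurable fraction of nuclei apoptotic. Apoptotic nuclei
#' are rendered as a ring of small DAPI fragments (and carry no foci; dying
#' cells show pan-nuclear rather than punctate staining).
#'
#' Geometry defaults mirror the acquisition the assay uses: five optical
#' planes 0.75 um apart and a pixel size such that a 5-10 um lymphocyte
#' nucleus spans roughly 25-40 px.
#'
#' @param n_nuclei Number of nuclei to place.
#' @param image_size `c(rows, cols)` of each plane, pixels.
#' @param pixel_size Pixel size, um.
#' @param n_planes Number of optical planes.
#' @param plane_spacing Axial distance between planes, um.
#' @param mean_foci Mean foci per (non-apoptotic) nucleus.
#' @param nucleus_radius_um Range of nucleus radii, um.
#' @param apoptotic_fraction Fraction of nuclei rendered as fragmented.
#' @param foci_min_separation Minimum in-plane distance between two foci of
#'   one nucleus, px.
#' @param foci_max_radial_frac Foci are placed within this fraction of the
#'   nucleus radius.
#' @param background,noise_sd Additive background level and Gaussian noise SD
#'   (camera counts).
#' @param dapi_intensity Range of nucleus fill intensities (counts).
#' @param focus_amplitude Peak amplitude of one focus above background
#'   (counts).
#' @param focus_sigma Lateral PSF sigma of a focus, px.
#' @param focus_sigma_z Axial PSF sigma of a focus, um.
#' @param bit_depth Integer bit depth of the rendered stack.
#' @param seed Integer seed (geometry and rendering noise).
#' @return An object of class `image_truth`: list with `nuclei` (data frame
#'   `nucleus_id`, `cy`, `cx`, `radius_px`, `intensity`, `apoptotic`,
#'   `n_foci`), `foci` (`nucleus_id`, `y`, `x`, `plane`), `fragments`
#'   (fragment geometry of apoptotic nuclei), `geometry` and `optics` lists,
#'   and `seed`.
#' @seealso [generate_zstack()]
#' @export
simulate_image_truth <- function(n_nuclei = 25,
                                 image_size = c(512, 512),
                                 pixel_size = 0.2,
                                 n_planes = 5,
                                 plane_spacing = 0.75,
                                 mean_foci = 2,
                                 nucleus_radius_um = c(2.7, 3.7),
                                 apoptotic_fraction = 0,
                                 foci_min_separation = 5,
                                 foci_max_radial_frac = 0.7,
                                 background = 200,
                                 noise_sd = 8,
                                 dapi_intensity = c(1500, 2500),
                                 focus_amplitude = 4000,
                                 focus_sigma = 1.5,
                                 focus_sigma_z = 0.6,
                                 bit_depth = 16,
                                 seed = NULL) {
  stopifnot(n_planes >= 1, plane_spacing > 0, pixel_size > 0,
            length(image_size) == 2, all(image_size >= 64),
            apoptotic_fraction >= 0, apoptotic_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  h <- image_size[1]; w <- image_size[2]
  r_px <- runif(n_nuclei, nucleus_radius_um[1], nucleus_radius_um[2]) / pixel_size
  # apoptotic fragment rings spread past the nominal radius; leave room
  spread <- if (apoptotic_fraction > 0) 1.5 else 1
  margin <- spread * max(r_px) + 8
  gap <- if (apoptotic_fraction > 0) 2 + (spread - 1) * 2 * max(r_px) + 10 else 12

  cy <- numeric(0); cx <- numeric(0)
  for (i in seq_len(n_nuclei)) {
    placed <- FALSE
    for (try in seq_len(2000)) {
      y <- runif(1, margin, h - margin)
      x <- runif(1, margin, w - margin)
      if (i == 1 ||
          all(sqrt((cy - y)^2 + (cx - x)^2) > r_px[i] + r_px[seq_len(i - 1)] + gap)) {
        cy <- c(cy, y); cx <- c(cx, x); placed <- TRUE; break
      }
    }
    if (!placed) stop("could not place ", n_nuclei, " non-touching nuclei; ",
                      "reduce n_nuclei or enlarge the field", call. = FALSE)
  }

  apoptotic <- runif(n_nuclei) < apoptotic_fraction
  intensity <- runif(n_nuclei, dapi_intensity[1], dapi_intensity[2])

  foci <- list()
  n_foci <- integer(n_nuclei)
  for (i in seq_len(n_nuclei)) {
    if (apoptotic[i]) next
    k <- rpois(1, mean_foci)
    if (k == 0) next
    fy <- numeric(0); fx <- numeric(0)
    rmax <- foci_max_radial_frac * r_px[i]
    for (j in seq_len(k)) {
      for (try in seq_len(200)) {
        ang <- runif(1, 0, 2 * pi)
        rad <- rmax * sqrt(runif(1))
        y <- cy[i] + rad * sin(ang); x <- cx[i] + rad * cos(ang)
        if (length(fy) == 0 ||
            all(sqrt((fy - y)^2 + (fx - x)^2) >= foci_min_separation)) {
          fy <- c(fy, y); fx <- c(fx, x); break
        }
      }
    }
    n_foci[i] <- length(fy)  # truth records what was actually placed
    if (n_foci[i] > 0) {
      foci[[length(foci) + 1]] <- data.frame(
        nucleus_id = i, y = fy, x = fx,
        plane = sample.int(n_planes, n_foci[i], replace = TRUE)
      )
    }
  }
  foci <- if (length(foci)) do.call(rbind, foci) else
    data.frame(nucleus_id = integer(0), y = numeric(0), x = numeric(0),
               plane = integer(0))

  # Apoptotic nuclei break into 3-4 fragments on a ring. Fragment radius
  # 0.58 r keeps the summed fragment area close to the intact nucleus area
  # (so the merged object still passes nucleus-sized area bounds) and the
  # ring radius is chosen to leave a ~4 px gap between neighbouring
  # fragments: separate objects, but close enough to be recognised as one
  # fragmented nucleus.
  fragments <- list()
  for (i in which(apoptotic)) {
    nf <- sample(3:4, 1)
    ang0 <- runif(1, 0, 2 * pi)
    ang <- ang0 + 2 * pi * seq_len(nf) / nf
    fr <- 0.58 * r_px[i]
    off <- (2 * fr + 4) / (2 * sin(pi / nf))
    fragments[[length(fragments) + 1]] <- data.frame(
      nucleus_id = i,
      y = cy[i] + off * sin(ang),
      x = cx[i] + off * cos(ang),
      radius_px = fr
    )
  }
  fragments <- if (length(fragments)) do.call(rbind, fragments) else
    data.frame(nucleus_id = integer(0), y = numeric(0), x = numeric(0),
               radius_px = numeric(0))

  structure(list(
    nuclei = data.frame(nucleus_id = seq_len(n_nuclei), cy = cy, cx = cx,
                        radius_px = r_px, intensity = intensity,
                        apoptotic = apoptotic, n_foci = n_foci),
    foci = foci,
    fragments = fragments,
    geometry = list(image_size = c(h, w), pixel_size = pixel_size,
                    n_planes = n_planes, plane_spacing = plane_spacing,
                    field_area_mm2 = h * w * pixel_size^2 / 1e6),
    optics = list(background = background, noise_sd = noise_sd,
                  focus_amplitude = focus_amplitude,
                  focus_sigma = focus_sigma, focus_sigma_z = focus_sigma_z,
                  bit_depth = bit_depth),
    seed = seed
  ), class = "image_truth")
}

# add a soft-edged disk to a matrix patchwise; edge ~1.5 px linear ramp
add_disk <- function(img, cy, cx, r, amp) {
  h <- nrow(img); w <- ncol(img)
  rr <- max(1L, floor(cy - r - 3)):min(h, ceiling(cy + r + 3))
  cc <- max(1L, floor(cx - r - 3)):min(w, ceiling(cx + r + 3))
  d <- sqrt(outer((rr - cy)^2, (cc - cx)^2, "+"))
  img[rr, cc] <- img[rr, cc] + amp * pmin(1, pmax(0, (r - d) / 1.5 + 0.5))
  img
}

add_gaussian_spot <- function(img, cy, cx, sigma, amp) {
  h <- nrow(img); w <- ncol(img)
  ext <- ceiling(4 * sigma)
  rr <- max(1L, floor(cy - ext)):min(h, ceiling(cy + ext))
  cc <- max(1L, floor(cx - ext)):min(w, ceiling(cx + ext))
  d2 <- outer((rr - cy)^2, (cc - cx)^2, "+")
  img[rr, cc] <- img[rr, cc] + amp * exp(-d2 / (2 * sigma^2))
  img
}

#' Render a two-channel z-stack from ground truth
#'
#' The DAPI channel renders each nucleus as a smooth bright disk (apoptotic
#' nuclei as their fragment disks); the gamma-H2AX channel renders each focus
#' as a lateral Gaussian spot centred on its home plane and attenuated on
#' neighbouring planes by an axial Gaussian. Background level plus Gaussian
#' read noise is added to every plane and the result is rounded and clamped
#' to the declared integer range. Rendering is deterministic given the
#' truth's seed.
#'
#' @param truth An [simulate_image_truth()] object.
#' @return An object of class `zstack`: list with `nucleus` and `foci`
#'   (row x col x plane arrays), `n_planes`, `plane_spacing`, `pixel_size`,
#'   `bit_depth` and `seed`.
#' @export
generate_zstack <- function(truth) {
  stopifnot(inherits(truth, "image_truth"))
  g <- truth$geometry; o <- truth$optics
  h <- g$image_size[1]; w <- g$image_size[2]; P <- g$n_planes
  if (nrow(truth$foci) > 0) {
    f <- truth$foci
    if (any(f$y < 1 | f$y > h | f$x < 1 | f$x > w)) {
      stop("focus outside image bounds", call. = FALSE)
    }
    nuc <- truth$nuclei[f$nucleus_id, ]
    if (any(sqrt((f$y - nuc$cy)^2 + (f$x - nuc$cx)^2) > nuc$radius_px)) {
      stop("focus outside its nucleus", call. = FALSE)
    }
    if (any(f$plane < 1 | f$plane > P)) stop("focus plane out of range",
                                             call. = FALSE)
  }
  if (!is.null(truth$seed)) set.seed(truth$seed + 1L)

  mid <- (P + 1) / 2
  nuc_arr <- array(0, c(h, w, P))
  foc_arr <- array(0, c(h, w, P))
  for (p in seq_len(P)) {
    plane_nuc <- matrix(0, h, w)
    zfac <- 1 - 0.05 * abs(p - mid)  # mild axial falloff of the DAPI signal
    for (i in seq_len(nrow(truth$nuclei))) {
      ni <- truth$nuclei[i, ]
      if (ni$apoptotic) next
      plane_nuc <- add_disk(plane_nuc, ni$cy, ni$cx, ni$radius_px,
                            ni$intensity * zfac)
    }
    if (nrow(truth$fragments) > 0) {
      for (i in seq_len(nrow(truth$fragments))) {
        fr <- truth$fragments[i, ]
        amp <- truth$nuclei$intensity[fr$nucleus_id] * zfac
        plane_nuc <- add_disk(plane_nuc, fr$y, fr$x, fr$radius_px, amp)
      }
    }
    plane_foc <- matrix(0, h, w)
    if (nrow(truth$foci) > 0) {
      dz <- (truth$foci$plane - p) * g$plane_spacing
      zatt <- exp(-dz^2 / (2 * o$focus_sigma_z^2))
      for (i in seq_len(nrow(truth$foci))) {
        if (zatt[i] < 1e-3) next
        plane_foc <- add_gaussian_spot(plane_foc, truth$foci$y[i],
                                       truth$foci$x[i], o$focus_sigma,
                                       o$focus_amplitude * zatt[i])
      }
    }
    nuc_arr[, , p] <- plane_nuc
    foc_arr[, , p] <- plane_foc
  }
  maxval <- 2^o$bit_depth - 1
  n <- length(nuc_arr)
  nuc_arr <- nuc_arr + o$background + rnorm(n, 0, o$noise_sd)
  foc_arr <- foc_arr + o$background + rnorm(n, 0, o$noise_sd)
  nuc_arr[] <- pmin(maxval, pmax(0, round(nuc_arr)))
  foc_arr[] <- pmin(maxval, pmax(0, round(foc_arr)))

  structure(list(
    nucleus = nuc_arr, foci = foc_arr,
    n_planes = P, plane_spacing = g$plane_spacing,
    pixel_size = g$pixel_size, bit_depth = o$bit_depth, seed = truth$seed
  ), class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  cat(sprintf(
    "zstack: %d x %d px, %d planes (%.2f um spacing), 2 channels, %d-bit\n",
    dim(x$nucleus)[1], dim(x$nucleus)[2], x$n_planes, x$plane_spacing,
    x$bit_depth))
  invisible(x)
}

#' Write / read a z-stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are stored plane-major (for each plane: nucleus channel page, then
#' foci channel page); the sidecar `<prefix>.json` records the geometry,
#' channel layout, bit depth and seed needed to reconstruct the object.
#'
#' @param stack A `zstack` object.
#' @param prefix Path prefix; `<prefix>.tif` and `<prefix>.json` are written.
#' @return `write_zstack()` returns the prefix invisibly; `read_zstack()`
#'   returns a `zstack`.
#' @export
write_zstack <- function(stack, prefix) {
  stopifnot(inherits(stack, "zstack"))
  maxval <- 2^stack$bit_depth - 1
  pages <- vector("list", 2 * stack$n_planes)
  k <- 1
  for (p in seq_len(stack$n_planes)) {
    pages[[k]] <- stack$nucleus[, , p] / maxval; k <- k + 1
    pages[[k]] <- stack$foci[, , p] / maxval; k <- k + 1
  }
  tiff::writeTIFF(pages, paste0(prefix, ".tif"), bits.per.sample = 16L,
                  compression = "LZW")
  meta <- list(
    n_planes = stack$n_planes, plane_spacing = stack$plane_spacing,
    pixel_size = stack$pixel_size, bit_depth = stack$bit_depth,
    channels = c("nucleus", "foci"), page_order = "plane-major",
    image_size = dim(stack$nucleus)[1:2], seed = stack$seed
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_zstack
#' @export
read_zstack <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE, as.is = TRUE)
  P <- meta$n_planes
  stopifnot(length(pages) == 2 * P)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  nuc <- array(0, c(h, w, P)); foc <- array(0, c(h, w, P))
  for (p in seq_len(P)) {
    nuc[, , p] <- pages[[2 * p - 1]]
    foc[, , p] <- pages[[2 * p]]
  }
  structure(list(
    nucleus = nuc, foci = foc, n_planes = P,
    plane_spacing = meta$plane_spacing, pixel_size = meta$pixel_size,
    bit_depth = meta$bit_depth,
    seed = if (is.null(meta$seed)) NULL else meta$seed
  ), class = "zstack")
}

#' Write an image ground-truth table
#'
#' Flattens the per-nucleus truth (position, radius, apoptotic flag, planted
#' focus count) to a CSV named `<prefix>.truth.csv`.
#'
#' @param truth An `image_truth` object.
#' @param prefix Path prefix.
#' @export
write_image_truth <- function(truth, prefix) {
  stopifnot(inherits(truth, "image_truth"))
  write.csv(truth$nuclei, paste0(prefix, ".truth.csv"), row.names = FALSE)
  invisible(prefix)
}
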