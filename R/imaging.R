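#' Configuration of nucleus segmentation and focus detection
#'
#' Bundles the tunable parameters of the image-quantification stage. Nucleus
#' area bounds are derived from the pixel size and a 5-10 um lymphocyte
#' nucleus diameter unless given explicitly.
#'
#' @param pixel_size Pixel size, um.
#' @param spot_sigma_range Lateral sigma range of the Laplacian-of-Gaussian
#'   blob detector, px (`sigma_min < sigma_max`).
#' @param n_sigma Number of LoG scales spanned across the range.
#' @param min_spot_separation Minimum distance between two counted foci, px;
#'   closer detections are merged into one.
#' @param prominence Detection threshold in units of the background SD of the
#'   LoG response (robustly estimated per nucleus).
#' @param nucleus_diameter_um Admissible nucleus diameter range, um; sets the
#'   area bounds.
#' @param nucleus_area_px Optional explicit area bounds `c(min, max)`, px;
#'   overrides `nucleus_diameter_um`.
#' @param solidity_threshold Nuclei with solidity below this are flagged
#'   apoptotic (`low_solidity`).
#' @param fragment_threshold Merged DAPI objects resolving into at least this
#'   many fragments are flagged apoptotic (`fragmented`).
#' @param merge_radius Dilation radius used to group fragmented DAPI objects,
#'   px.
#' @param min_component_px Components smaller than this are discarded as
#'   noise specks before grouping, px.
#' @param split_touching Split touching nuclei by distance-transform
#'   watershed (`TRUE`, default) instead of keeping them merged.
#' @param watershed_tolerance Minimum distance-map depth between two watershed
#'   seeds, px.
#' @return An object of class `foci_config`.
#' @export
foci_config <- function(pixel_size = 0.2,
                        spot_sigma_range = c(1, 2.5),
                        n_sigma = 3,
                        min_spot_separation = 3,
                        prominence = 5,
                        nucleus_diameter_um = c(5, 10),
                        nucleus_area_px = NULL,
                        solidity_threshold = 0.8,
                        fragment_threshold = 3,
                        merge_radius = 3,
                        min_component_px = 25,
                        split_touching = TRUE,
                        watershed_tolerance = 2) {
  stopifnot(pixel_size > 0,
            length(spot_sigma_range) == 2,
            spot_sigma_range[1] > 0,
            spot_sigma_range[1] < spot_sigma_range[2],
            min_spot_separation > 0, prominence > 0,
            solidity_threshold > 0, solidity_threshold <= 1,
            fragment_threshold >= 2, merge_radius >= 1,
            min_component_px >= 1)
  if (is.null(nucleus_area_px)) {
    nucleus_area_px <- pi * (nucleus_diameter_um / 2 / pixel_size)^2
  }
  stopifnot(length(nucleus_area_px) == 2, nucleus_area_px[1] > 0,
            nucleus_area_px[1] < nucleus_area_px[2])
  structure(list(
    pixel_size = pixel_size, spot_sigma_range = spot_sigma_range,
    n_sigma = n_sigma, min_spot_separation = min_spot_separation,
    prominence = prominence, nucleus_area_px = nucleus_area_px,
    solidity_threshold = solidity_threshold,
    fragment_threshold = fragment_threshold, merge_radius = merge_radius,
    min_component_px = min_component_px,
    split_touching = split_touching,
    watershed_tolerance = watershed_tolerance
  ), class = "foci_config")
}

#' Maximum-intensity projection of a z-stack channel
#'
#' Combines the optical planes into one extended-focus image: each output
#' pixel is the maximum of that pixel across all planes.
#'
#' @param stack A `zstack` object or a `rows x cols x planes` numeric array.
#' @param channel For a `zstack`, which channel to project (`"nucleus"` or
#'   `"foci"`); ignored for arrays.
#' @return A matrix with the dimensions of one plane.
#' @examples
#' a <- array(1:24, c(2, 3, 4))
#' max_intensity_projection(a)
#' @export
max_intensity_projection <- function(stack, channel = c("nucleus", "foci")) {
  if (inherits(stack, "zstack")) {
    channel <- match.arg(channel)
    stack <- stack[[channel]]
  }
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3 || dim(stack)[3] < 1) {
    stop("stack must contain at least one plane", call. = FALSE)
  }
  out <- stack[, , 1]
  for (p in seq_len(dim(stack)[3])[-1]) out <- pmax(out, stack[, , p])
  out
}

# solidity = pixel count / lattice points inside the convex hull of the
# pixel centres (half-plane test per hull edge)
region_solidity <- function(rows, cols) {
  n <- length(rows)
  if (n < 4) return(1)
  pts <- unique(cbind(cols, rows))
  if (nrow(pts) < 3) return(1)
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  if (nrow(hull) < 3) return(1)
  gr <- expand.grid(x = min(cols):max(cols), y = min(rows):max(rows))
  inside <- rep(TRUE, nrow(gr))
  nh <- nrow(hull)
  for (i in seq_len(nh)) {
    a <- hull[i, ]; b <- hull[if (i == nh) 1 else i + 1, ]
    # chull() returns vertices clockwise in (x, y): interior has cross <= 0
    cr <- (b[1] - a[1]) * (gr$y - a[2]) - (b[2] - a[2]) * (gr$x - a[1])
    inside <- inside & (cr <= 1e-9)
    if (!any(inside)) break
  }
  convex_area <- sum(inside)
  if (convex_area <= 0) return(1)
  min(1, n / convex_area)
}

new_nucleus_mask <- function(pixels, dim, id, fragment_count = 1L) {
  rc <- arrayInd(pixels, dim)
  structure(list(
    id = id, pixels = pixels, dim = dim,
    area = length(pixels),
    centroid = c(row = mean(rc[, 1]), col = mean(rc[, 2])),
    solidity = region_solidity(rc[, 1], rc[, 2]),
    fragment_count = as.integer(fragment_count),
    apoptotic = FALSE, qc_reason = NA_character_
  ), class = "nucleus_mask")
}

#' Segment nuclei in a projected DAPI image
#'
#' Otsu threshold on the projected DAPI channel, connected components,
#' grouping of fragmented objects (components whose supports touch after a
#' small dilation; groups of at least `fragment_threshold` members are kept
#' as one merged mask with the member count recorded, so the apoptotic rule
#' can act on them), optional watershed splitting of touching nuclei, and
#' area filtering. A blank image yields an empty list, not an error.
#'
#' @param dapi Projected DAPI image (matrix).
#' @param config A [foci_config()].
#' @return List of `nucleus_mask` objects (disjoint pixel sets, each with
#'   area inside the configured bounds, centroid, solidity and fragment
#'   count).
#' @export
segment_nuclei <- function(dapi, config = foci_config()) {
  stopifnot(is.matrix(dapi), length(dapi) > 0)
  rng <- range(dapi)
  if (!all(is.finite(rng))) stop("non-finite pixel values", call. = FALSE)
  if (rng[2] <= rng[1]) return(list())
  x <- (dapi - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  bw <- x > thr
  if (!any(bw)) return(list())
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw)))
  # despeckle: sub-fragment-sized components are noise, not nuclei
  sizes <- tabulate(lab[lab > 0])
  speck <- which(sizes < config$min_component_px)
  if (length(speck) > 0) {
    bw[lab %in% speck] <- FALSE
    lab[lab %in% speck] <- 0L
    if (!any(bw)) return(list())
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw)))
  }
  ncomp <- max(lab)
  dimg <- dim(dapi)

  # group components that merge under dilation (candidate fragment clusters)
  brush <- EBImage::makeBrush(2 * config$merge_radius + 1, shape = "disc")
  dil <- EBImage::imageData(EBImage::bwlabel(
    EBImage::dilate(EBImage::Image(bw), brush)))
  fg <- which(lab > 0)
  comp_pix <- split(fg, factor(lab[fg], levels = seq_len(ncomp)))
  comp_group <- vapply(comp_pix, function(px) dil[px[1]], numeric(1))

  masks <- list()
  next_id <- 1L
  for (grp in unique(comp_group)) {
    members <- which(comp_group == grp)
    if (length(members) >= config$fragment_threshold) {
      px <- sort(unlist(comp_pix[members], use.names = FALSE))
      masks[[length(masks) + 1]] <-
        new_nucleus_mask(px, dimg, next_id, fragment_count = length(members))
      next_id <- next_id + 1L
      next
    }
    for (m in members) {
      px <- comp_pix[[m]]
      pieces <- list(px)
      if (config$split_touching && length(px) > 4) {
        pieces <- split_component(px, dimg, config$watershed_tolerance)
      }
      for (piece in pieces) {
        masks[[length(masks) + 1]] <- new_nucleus_mask(piece, dimg, next_id)
        next_id <- next_id + 1L
      }
    }
  }
  ab <- config$nucleus_area_px
  Filter(function(m) m$area >= ab[1] && m$area <= ab[2], masks)
}

# watershed on the distance map of one component's patch; returns a list of
# pixel-index vectors (length 1 if no split)
split_component <- function(pixels, dimg, tolerance) {
  rc <- arrayInd(pixels, dimg)
  r0 <- min(rc[, 1]); c0 <- min(rc[, 2])
  patch <- matrix(FALSE, max(rc[, 1]) - r0 + 3, max(rc[, 2]) - c0 + 3)
  patch[cbind(rc[, 1] - r0 + 2, rc[, 2] - c0 + 2)] <- TRUE
  dm <- EBImage::distmap(EBImage::Image(patch))
  ws <- EBImage::imageData(EBImage::watershed(dm, tolerance = tolerance))
  k <- max(ws)
  if (k <= 1) return(list(pixels))
  out <- vector("list", k)
  idx <- cbind(rc[, 1] - r0 + 2, rc[, 2] - c0 + 2)
  labv <- ws[idx]
  for (j in seq_len(k)) out[[j]] <- pixels[labv == j]
  out[lengths(out) > 0]
}

#' Exclude apoptotic nuclei
#'
#' A nucleus is flagged apoptotic when its DAPI object resolved into at
#' least `fragment_threshold` fragments within a merged region
#' (`qc_reason = "fragmented"`) or when its solidity falls below the
#' threshold (`qc_reason = "low_solidity"`); dying lymphocytes show
#' fragmented or collapsed nuclear morphology that confounds foci counting.
#'
#' @param masks List of `nucleus_mask` from [segment_nuclei()].
#' @param dapi Projected DAPI image (unused by the default rules, accepted
#'   for signature stability).
#' @param config A [foci_config()].
#' @return List with `kept` and `excluded` mask lists; excluded masks carry
#'   `apoptotic = TRUE` and a `qc_reason`.
#' @export
exclude_apoptotic <- function(masks, dapi = NULL, config = foci_config()) {
  kept <- list(); excluded <- list()
  for (m in masks) {
    if (m$fragment_count >= config$fragment_threshold) {
      m$apoptotic <- TRUE; m$qc_reason <- "fragmented"
    } else if (m$solidity < config$solidity_threshold) {
      m$apoptotic <- TRUE; m$qc_reason <- "low_solidity"
    }
    if (m$apoptotic) excluded[[length(excluded) + 1]] <- m
    else kept[[length(kept) + 1]] <- m
  }
  list(kept = kept, excluded = excluded)
}

# scale-normalised LoG kernel (negated so blobs give positive response);
# forced to zero sum so constant offsets contribute exactly nothing
log_kernel <- function(sigma) {
  ext <- ceiling(3.5 * sigma)
  g <- seq(-ext, ext)
  d2 <- outer(g^2, g^2, "+")
  k <- -((d2 - 2 * sigma^2) / sigma^4) * exp(-d2 / (2 * sigma^2))
  k <- k * sigma^2
  k - mean(k)
}

# pooled LoG response, each scale z-normalised by its own robust noise SD
# (MAD over `ref` pixels) so thresholds are in background-SD units; scales
# whose response is numerically flat contribute nothing
log_response <- function(img, sigmas, ref = NULL) {
  if (is.null(ref)) ref <- rep(TRUE, length(img))
  flat_tol <- 1e-8 * (max(abs(img)) + 1)
  resp <- NULL
  for (s in sigmas) {
    r <- EBImage::imageData(EBImage::filter2(
      EBImage::Image(img), log_kernel(s), boundary = "replicate"))
    noise <- mad(r[ref])
    r <- if (noise > flat_tol) r / noise else r * 0
    resp <- if (is.null(resp)) r else pmax(resp, r)
  }
  resp
}

local_maxima <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  p <- matrix(-Inf, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- x
  res <- matrix(TRUE, nr, nc)
  ri <- 2:(nr + 1); ci <- 2:(nc + 1)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    res <- res & (x >= p[ri + dr, ci + dc])
  }
  res
}

#' Count gamma-H2AX foci inside one nucleus
#'
#' Band-pass blob detection restricted to the nucleus: the patch around the
#' mask (pixels outside the mask replaced by the in-mask median, which makes
#' the count strictly mask-local and offset-invariant) is filtered with
#' scale-normalised Laplacian-of-Gaussian kernels over the configured sigma
#' range, each scale z-normalised by its robust (MAD) background SD inside
#' the mask; local maxima of the pooled response inside the mask count as
#' foci when they exceed `prominence` background-SD units and are at least
#' `min_spot_separation` apart (closer maxima are merged, strongest wins).
#'
#' @param foci_image Projected gamma-H2AX channel (matrix).
#' @param mask A `nucleus_mask`.
#' @param config A [foci_config()].
#' @return Integer focus count, with detected peak coordinates in attribute
#'   `"peaks"`.
#' @export
count_foci <- function(foci_image, mask, config = foci_config()) {
  stopifnot(is.matrix(foci_image), inherits(mask, "nucleus_mask"))
  if (mask$area == 0) stop("degenerate mask (area 0)", call. = FALSE)
  if (!all(mask$dim == dim(foci_image))) {
    stop("mask and image dimensions differ", call. = FALSE)
  }
  rc <- arrayInd(mask$pixels, mask$dim)
  pad <- ceiling(3.5 * config$spot_sigma_range[2]) + 1
  r1 <- max(1L, min(rc[, 1]) - pad); r2 <- min(nrow(foci_image), max(rc[, 1]) + pad)
  c1 <- max(1L, min(rc[, 2]) - pad); c2 <- min(ncol(foci_image), max(rc[, 2]) + pad)

  inmask <- matrix(FALSE, r2 - r1 + 1, c2 - c1 + 1)
  inmask[cbind(rc[, 1] - r1 + 1, rc[, 2] - c1 + 1)] <- TRUE
  vals <- foci_image[cbind(rc[, 1], rc[, 2])]
  patch <- matrix(median(vals), r2 - r1 + 1, c2 - c1 + 1)
  patch[inmask] <- vals

  sigmas <- seq(config$spot_sigma_range[1], config$spot_sigma_range[2],
                length.out = config$n_sigma)
  resp <- log_response(patch, sigmas, ref = inmask)
  thr <- config$prominence

  cand <- local_maxima(resp) & inmask & (resp > thr)
  if (!any(cand)) {
    return(structure(0L, peaks = data.frame(row = integer(0),
                                            col = integer(0),
                                            response = numeric(0))))
  }
  idx <- which(cand, arr.ind = TRUE)
  v <- resp[cand]
  ord <- order(v, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]; v <- v[ord]
  keep <- integer(0)
  for (i in seq_len(nrow(idx))) {
    if (length(keep) == 0 ||
        all((idx[keep, 1] - idx[i, 1])^2 + (idx[keep, 2] - idx[i, 2])^2 >=
            config$min_spot_separation^2)) {
      keep <- c(keep, i)
    }
  }
  peaks <- data.frame(row = idx[keep, 1] + r1 - 1L,
                      col = idx[keep, 2] + c1 - 1L,
                      response = v[keep])
  structure(length(keep), peaks = peaks)
}

#' Quantify one microscope field
#'
#' Full composition of the image stage: project both channels, segment the
#' DAPI projection, exclude apoptotic objects, and count foci in every kept
#' nucleus. Records carry a sequential `cell_index` in segmentation order.
#'
#' @param stack A `zstack` object.
#' @param config A [foci_config()].
#' @param individual_id,group,condition Metadata copied into the records so
#'   the output matches the shared per-cell count-table schema.
#' @return List with
#'   \describe{
#'     \item{records}{data frame `individual_id`, `group`, `condition`,
#'       `cell_index`, `foci_count`, plus centroid and area.}
#'     \item{qc}{per-nucleus QC table (area, solidity, fragment count,
#'       apoptotic flag, reason) covering kept and excluded objects.}
#'     \item{masks}{the kept `nucleus_mask` list, in record order.}
#'   }
#' @export
quantify_field <- function(stack, config = foci_config(),
                           individual_id = "field", group = NA_character_,
                           condition = NA_character_) {
  stopifnot(inherits(stack, "zstack"))
  dapi <- max_intensity_projection(stack, "nucleus")
  foci <- max_intensity_projection(stack, "foci")
  masks <- segment_nuclei(dapi, config)
  spl <- exclude_apoptotic(masks, dapi, config)
  kept <- spl$kept

  counts <- integer(length(kept))
  for (i in seq_along(kept)) counts[i] <- count_foci(foci, kept[[i]], config)
  records <- data.frame(
    individual_id = rep_len(individual_id, length(kept)),
    group = rep_len(group, length(kept)),
    condition = rep_len(condition, length(kept)),
    cell_index = seq_along(kept),
    foci_count = counts,
    centroid_row = vapply(kept, function(m) m$centroid[["row"]], numeric(1)),
    centroid_col = vapply(kept, function(m) m$centroid[["col"]], numeric(1)),
    area_px = vapply(kept, function(m) m$area, numeric(1)),
    stringsAsFactors = FALSE
  )
  allm <- c(kept, spl$excluded)
  qc <- data.frame(
    mask_id = vapply(allm, function(m) m$id, numeric(1)),
    area_px = vapply(allm, function(m) m$area, numeric(1)),
    solidity = vapply(allm, function(m) m$solidity, numeric(1)),
    fragment_count = vapply(allm, function(m) m$fragment_count, integer(1)),
    apoptotic = vapply(allm, function(m) m$apoptotic, logical(1)),
    qc_reason = vapply(allm, function(m) m$qc_reason, character(1)),
    stringsAsFactors = FALSE
  )
  list(records = records, qc = qc, masks = kept)
}
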