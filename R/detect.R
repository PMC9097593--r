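# Per-frame object detection: thresholded cell-shape centroids and
# sub-pixel vacuole spot detection.

#' Detect cells by global thresholding
#'
#' Applies Otsu's global threshold to a preprocessed frame (cells bright on
#' a flat background), labels 8-connected foreground components, discards
#' components smaller than `min_area`, and reports each remaining
#' component's centre of mass. By default this is the centre of mass of the
#' thresholded shape (uniform weight over the component, the quantity
#' tracked in the original protocol); `weighted = TRUE` instead weights by
#' the intensity in excess of the threshold, which pulls the centroid
#' toward bright interior features such as the contractile vacuole.
#'
#' @param img a preprocessed frame (matrix), e.g. a [cell_preprocess()] output.
#' @param min_area minimum component area in px^2 (default 20).
#' @param weighted use intensity-above-threshold weights instead of the
#'   binary shape.
#' @return a data.frame with columns `x`, `y` (0-based px) and `area`
#'   (px^2), ordered by (`y`, `x`); empty when nothing is found.
#' @export
threshold_cells <- function(img, min_area = 20, weighted = FALSE) {
  empty <- data.frame(x = numeric(), y = numeric(), area = numeric())
  if (diff(range(img)) == 0) return(empty)
  thr <- EBImage::otsu(EBImage::Image(img), range = range(img))
  mask <- img > thr
  idx <- which(mask)
  if (!length(idx)) return(empty)
  H <- nrow(img); W <- ncol(img)
  pos <- arrayInd(idx, dim(img))          # row, col (1-based)
  id_of <- integer(H * W)
  id_of[idx] <- seq_along(idx)
  edges <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    nr <- pos[, 1] + off[1]; nc <- pos[, 2] + off[2]
    ok <- nr >= 1 & nr <= H & nc >= 1 & nc <= W
    if (!any(ok)) next
    nb <- id_of[(nc[ok] - 1L) * H + nr[ok]]
    from <- which(ok)[nb > 0]
    nb <- nb[nb > 0]
    if (length(nb)) edges[[length(edges) + 1]] <- rbind(from, nb)
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, as.integer(unlist(edges)))
  comp <- igraph::components(g)$membership
  w <- if (weighted) img[idx] - thr else rep(1, length(idx))
  out <- do.call(rbind, lapply(split(seq_along(idx), comp), function(members) {
    if (length(members) < min_area) return(NULL)
    ww <- w[members]
    sw <- sum(ww)
    data.frame(x = sum(ww * (pos[members, 2] - 1)) / sw,
               y = sum(ww * (pos[members, 1] - 1)) / sw,
               area = length(members))
  }))
  if (is.null(out)) return(empty)
  out <- out[order(out$y, out$x), ]
  rownames(out) <- NULL
  out
}

#' Spot detection parameters
#'
#' Defaults are the Particle Tracker settings used for contractile-vacuole
#' tracking: Radius = 7, Cutoff = 0, Percentile = 0.4. `percentile` is the
#' fraction (in percent) of the brightest pixels admitted as candidate
#' particle pixels — top 0.4% by default, the convention of that tracker.
#'
#' @param radius detection disk radius, px (>= 1).
#' @param cutoff non-particle discrimination score cutoff; 0 disables removal.
#' @param percentile percent of brightest pixels taken as candidates (0, 100].
#' @export
spot_params <- function(radius = 7, cutoff = 0, percentile = 0.4) {
  if (radius < 1) stop("radius must be >= 1")
  if (percentile <= 0 || percentile > 100) stop("percentile must be in (0, 100]")
  if (cutoff < 0) stop("cutoff must be >= 0")
  structure(list(radius = radius, cutoff = cutoff, percentile = percentile),
            class = "spot_params")
}

flat_disk_se <- function(radius) {
  q <- -floor(radius):floor(radius)
  d2 <- outer(q^2, q^2, "+")
  se <- matrix(NA_real_, length(q), length(q))
  se[d2 <= radius^2] <- 0
  se
}

# Intensity-weighted centroid refinement over a disk, iterated to
# convergence (<= 10 iterations or shift < 0.1 px). `baseline` is
# subtracted from intensities and negatives clamped to zero.
refine_spot <- function(img, x0, y0, radius, baseline) {
  H <- nrow(img); W <- ncol(img)
  x <- x0; y <- y0
  m0 <- 0; m2 <- 0
  for (iter in 1:10) {
    r0 <- max(1, floor(y - radius) + 1); r1 <- min(H, ceiling(y + radius) + 1)
    c0 <- max(1, floor(x - radius) + 1); c1 <- min(W, ceiling(x + radius) + 1)
    rows <- r0:r1; cols <- c0:c1
    dy <- (rows - 1) - y; dx <- (cols - 1) - x
    d2 <- outer(dy^2, dx^2, "+")
    wmat <- pmax(img[rows, cols, drop = FALSE] - baseline, 0)
    wmat[d2 > radius^2] <- 0
    m0 <- sum(wmat)
    if (m0 <= 0) break
    nx <- sum(t(wmat) * (cols - 1)) / m0
    ny <- sum(wmat * (rows - 1)) / m0
    shift <- sqrt((nx - x)^2 + (ny - y)^2)
    x <- nx; y <- ny
    m2 <- sum(wmat * d2) / (m0 * radius^2)
    if (shift < 0.1) break
  }
  list(x = x, y = y, m0 = m0, m2 = m2)
}

#' Detect sub-pixel spots in a preprocessed frame
#'
#' Candidate pixels are local maxima within a disk of the given radius whose
#' intensity lies in the brightest `percentile` percent of the frame. Each
#' candidate is refined to the intensity-weighted centroid over the disk
#' (iterated to convergence), candidates closer than `radius` are merged
#' keeping the brighter, and spots whose discrimination score (`m0`) falls
#' below `cutoff` are removed (`cutoff = 0` disables removal; the score is
#' still reported).
#'
#' @param img a preprocessed frame (matrix), e.g. a [spot_preprocess()] output.
#' @param p a [spot_params()] object.
#' @return a data.frame with columns `x`, `y` (0-based px, sub-pixel
#'   refined), `m0` (total excess intensity in the disk) and `m2`
#'   (radius-normalized second moment), ordered by (`y`, `x`).
#' @export
detect_spots <- function(img, p = spot_params()) {
  empty <- data.frame(x = numeric(), y = numeric(), m0 = numeric(), m2 = numeric())
  if (diff(range(img)) == 0) return(empty)
  thr <- as.numeric(quantile(img, 1 - p$percentile / 100, names = FALSE))
  dil <- grey_morph(img, flat_disk_se(p$radius), TRUE)
  cand <- which(img >= thr & img >= dil)
  if (!length(cand)) return(empty)
  pos <- arrayInd(cand, dim(img))
  ord <- order(-img[cand], pos[, 1], pos[, 2])
  spots <- lapply(ord, function(i) {
    refine_spot(img, pos[i, 2] - 1, pos[i, 1] - 1, p$radius, thr)
  })
  spots <- Filter(function(s) s$m0 > 0, spots)
  if (!length(spots)) return(empty)
  # merge: brightest first, drop refined centres within `radius` of a keeper
  keep <- list()
  for (s in spots[order(-vapply(spots, `[[`, 0, "m0"))]) {
    close <- any(vapply(keep, function(k)
      (k$x - s$x)^2 + (k$y - s$y)^2 < p$radius^2, logical(1)))
    if (!close) keep[[length(keep) + 1]] <- s
  }
  out <- do.call(rbind, lapply(keep, function(s)
    data.frame(x = s$x, y = s$y, m0 = s$m0, m2 = s$m2)))
  out <- out[out$m0 >= p$cutoff, , drop = FALSE]
  out <- out[order(out$y, out$x), ]
  rownames(out) <- NULL
  out
}

#' Detect cells across all frames of a stack
#' @param stack a preprocessed [image_stack()].
#' @param min_area minimum component area, px^2.
#' @return detections data.frame with `frame` (0-based), `x`, `y`, `area`.
#' @export
detect_cells_stack <- function(stack, min_area = 20) {
  out <- lapply(seq_len(n_frames(stack)), function(i) {
    d <- threshold_cells(stack$frames[[i]], min_area = min_area)
    if (nrow(d)) cbind(frame = i - 1L, d) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(frame = integer(), x = numeric(),
                               y = numeric(), area = numeric()) else out
}

#' Detect spots across all frames of a stack
#' @param stack a preprocessed [image_stack()].
#' @param p a [spot_params()] object.
#' @return detections data.frame with `frame` (0-based), `x`, `y`, `m0`, `m2`.
#' @export
detect_spots_stack <- function(stack, p = spot_params()) {
  out <- lapply(seq_len(n_frames(stack)), function(i) {
    d <- detect_spots(stack$frames[[i]], p = p)
    if (nrow(d)) cbind(frame = i - 1L, d) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(frame = integer(), x = numeric(), y = numeric(),
                               m0 = numeric(), m2 = numeric()) else out
}
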