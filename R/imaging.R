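#' Frame rendering specification
#'
#' Greyscale rendering parameters for synthetic arena frames. Grey values are
#' in \[0, 1\] with 0 black; the aphid is the darkest object so a
#' grey-threshold tracker can segment it against both the leaf disc and the
#' agar background.
#'
#' @param image_size image side length in px (square frames).
#' @param background,disc,aphid grey levels of agar, leaf disc and subject.
#' @param aphid_axes semi-axes of the subject ellipse in mm (a 1.7 mm
#'   *M. persicae* body is roughly 1.7 x 0.8 mm).
#' @param pixel_scale px per mm.
#' @param frame_rate frames per s.
#' @param supersample sub-pixel sampling factor for area-coverage
#'   anti-aliasing.
#' @return object of class `frame_spec`.
#' @export
frame_spec <- function(image_size = 128, background = 0.80, disc = 0.55,
                       aphid = 0.10, aphid_axes = c(0.85, 0.40),
                       pixel_scale = 16.6, frame_rate = 25, supersample = 4) {
  if (length(unique(c(background, disc, aphid))) != 3)
    stop("grey levels must be distinct")
  structure(list(image_size = as.integer(image_size), background = background,
                 disc = disc, aphid = aphid, aphid_axes = aphid_axes,
                 pixel_scale = pixel_scale, frame_rate = frame_rate,
                 supersample = as.integer(supersample)),
            class = "frame_spec")
}

# mm -> px mapping of a frame stack: image centred on the arena centre,
# x along columns, y along rows (top-left origin, y downward)
mm_to_px <- function(x, y, arena, spec) {
  half <- spec$image_size / 2
  list(col = (x - arena$centre[1]) * spec$pixel_scale + half + 0.5,
       row = (y - arena$centre[2]) * spec$pixel_scale + half + 0.5)
}
px_to_mm <- function(col, row, arena, spec) {
  half <- spec$image_size / 2
  list(x = (col - half - 0.5) / spec$pixel_scale + arena$centre[1],
       y = (row - half - 0.5) / spec$pixel_scale + arena$centre[2])
}

# area-coverage of an ellipse over a pixel grid patch, by supersampling
ellipse_coverage <- function(rows, cols, c_row, c_col, a_px, b_px, theta, ss) {
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  cov <- matrix(0, length(rows), length(cols))
  ct <- cos(theta); st <- sin(theta)
  for (dr in off) for (dc in off) {
    rr <- outer(rows + dr - c_row, rep(1, length(cols)))
    cc <- outer(rep(1, length(rows)), cols + dc - c_col)
    u <- (cc * ct + rr * st) / a_px
    v <- (-cc * st + rr * ct) / b_px
    cov <- cov + (u * u + v * v <= 1)
  }
  cov / (ss * ss)
}

#' Render greyscale frames from a trajectory
#'
#' One greyscale matrix per trajectory sample: uniform agar background, the
#' leaf disc as a darker circle, and the subject as the darkest ellipse at
#' the sample position, oriented along the direction of motion. Edges are
#' anti-aliased by sub-pixel area coverage so that recovered centroids are
#' meaningful below one pixel. Undetected samples render without a subject.
#'
#' @param traj an [trajectory()] object (positions in mm).
#' @param spec a [frame_spec()].
#' @param arena an [arena_geometry()].
#' @return object of class `frame_stack`: list of `image_size` x
#'   `image_size` matrices with attributes `spec` and `arena`.
#' @export
render_frames <- function(traj, spec, arena) {
  stopifnot(inherits(traj, "aphid_trajectory"), inherits(spec, "frame_spec"),
            inherits(arena, "arena_geometry"))
  sz <- spec$image_size
  ctr <- mm_to_px(arena$centre[1], arena$centre[2], arena, spec)
  disc_cov <- ellipse_coverage(seq_len(sz), seq_len(sz), ctr$row, ctr$col,
                               arena$disc_radius * spec$pixel_scale,
                               arena$disc_radius * spec$pixel_scale, 0,
                               spec$supersample)
  base <- spec$background * (1 - disc_cov) + spec$disc * disc_cov

  a_px <- spec$aphid_axes[1] * spec$pixel_scale
  b_px <- spec$aphid_axes[2] * spec$pixel_scale
  margin <- ceiling(max(a_px, b_px)) + 2L

  dx <- c(0, diff(traj$x)); dy <- c(0, diff(traj$y))
  heading <- atan2(dy, dx)
  mov <- sqrt(dx^2 + dy^2) > 1e-9
  last <- 0
  for (i in seq_along(heading)) {           # hold heading while still
    if (mov[i] && is.finite(heading[i])) last <- heading[i]
    heading[i] <- last
  }

  frames <- vector("list", nrow(traj))
  for (i in seq_len(nrow(traj))) {
    img <- base
    if (traj$detected[i]) {
      p <- mm_to_px(traj$x[i], traj$y[i], arena, spec)
      if (p$row < 1 + margin / 2 || p$row > sz - margin / 2 ||
          p$col < 1 + margin / 2 || p$col > sz - margin / 2)
        stop(sprintf("subject outside image at frame %d", i))
      rows <- max(1L, floor(p$row - margin)):min(sz, ceiling(p$row + margin))
      cols <- max(1L, floor(p$col - margin)):min(sz, ceiling(p$col + margin))
      cov <- ellipse_coverage(rows, cols, p$row, p$col, a_px, b_px,
                              heading[i], spec$supersample)
      img[rows, cols] <- img[rows, cols] * (1 - cov) + spec$aphid * cov
    }
    frames[[i]] <- img
  }
  structure(frames, spec = spec, arena = arena,
            frame_rate = attr(traj, "frame_rate"), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  s <- attr(x, "spec")
  cat(sprintf("Frame stack: %d frames of %dx%d px at %g fps\n",
              length(x), s$image_size, s$image_size, attr(x, "frame_rate")))
  invisible(x)
}

# 8-connected component labelling by iterative minimum-label propagation
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(nr * nc)[mask]       # unique positional labels
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  labf <- matrix(Inf, nr, nc); labf[mask] <- lab[mask]
  repeat {
    new <- labf
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                   c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
      new <- pmin(new, shift(labf, d[1], d[2]))
    new[!mask] <- Inf
    if (identical(new, labf)) break
    labf <- new
  }
  lab <- matrix(0L, nr, nc)
  if (any(mask)) lab[mask] <- as.integer(factor(labf[mask]))
  lab
}

#' Track the subject in a greyscale frame stack
#'
#' A minimal grey-threshold blob tracker: per frame, pixels darker than the
#' threshold of their zone (the leaf disc and the agar need different
#' thresholds) are foreground; the largest 8-connected component becomes the
#' subject and its pixel centroid the sample position. Ties between equal
#' sized components are broken by darker mean grey, then by the more
#' top-left component. Frames without any foreground yield
#' `detected = FALSE`.
#'
#' @param stack a [render_frames()] stack, or any list of grey matrices with
#'   the same geometry.
#' @param arena an [arena_geometry()].
#' @param thresholds named list `zone1`, `zone2` of grey cut-offs; pixels
#'   with values strictly below the cut-off of their zone are foreground.
#' @param spec the [frame_spec()] (defaults to the stack's own).
#' @return an [trajectory()] object (positions in mm).
#' @export
track_frames <- function(stack, arena, thresholds = list(zone1 = 0.3, zone2 = 0.3),
                         spec = attr(stack, "spec")) {
  stopifnot(inherits(arena, "arena_geometry"), !is.null(spec))
  sz <- spec$image_size
  fr <- attr(stack, "frame_rate")
  if (is.null(fr)) fr <- spec$frame_rate
  pix <- px_to_mm(outer(rep(1, sz), seq_len(sz)), outer(seq_len(sz), rep(1, sz)),
                  arena, spec)
  pdist <- sqrt((pix$x - arena$centre[1])^2 + (pix$y - arena$centre[2])^2)
  thr <- matrix(thresholds$zone2, sz, sz)
  thr[pdist <= arena$disc_radius] <- thresholds$zone1

  n <- length(stack)
  x <- rep(NA_real_, n); y <- rep(NA_real_, n); det <- rep(FALSE, n)
  for (i in seq_len(n)) {
    img <- stack[[i]]
    mask_full <- img < thr
    if (!any(mask_full)) next
    # label only the foreground bounding box
    wf <- which(mask_full, arr.ind = TRUE)
    r0 <- min(wf[, 1]); r1 <- max(wf[, 1])
    c0 <- min(wf[, 2]); c1 <- max(wf[, 2])
    mask <- mask_full[r0:r1, c0:c1, drop = FALSE]
    img <- img[r0:r1, c0:c1, drop = FALSE]
    lab <- label_components(mask)
    sizes <- tabulate(lab[mask])
    best <- which(sizes == max(sizes))
    if (length(best) > 1) {
      mg <- vapply(best, function(l) mean(img[lab == l]), numeric(1))
      best <- best[mg == min(mg)]
      if (length(best) > 1) {
        tl <- vapply(best, function(l) {
          w <- which(lab == l, arr.ind = TRUE)
          min(w[, 1]) * (sz + 1) + min(w[, 2])
        }, numeric(1))
        best <- best[which.min(tl)]
      }
    }
    w <- which(lab == best[1], arr.ind = TRUE)
    mm <- px_to_mm(mean(w[, 2]) + c0 - 1, mean(w[, 1]) + r0 - 1, arena, spec)
    x[i] <- mm$x; y[i] <- mm$y; det[i] <- TRUE
  }
  trajectory(t = (seq_len(n) - 1) / fr, x = x, y = y, detected = det,
             frame_rate = fr, pixel_scale = spec$pixel_scale,
             arena_id = "tracked")
}

#' Write / read a frame stack as PNG files
#'
#' @param stack a [render_frames()] stack.
#' @param dir output directory (created if missing); frames are written as
#'   `frame_000001.png` etc.
#' @return [write_frames()]: the directory; [read_frames()]: a list of grey
#'   matrices.
#' @export
write_frames <- function(stack, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write frames")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stack))
    png::writePNG(stack[[i]], file.path(dir, sprintf("frame_%06d.png", i)))
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to read frames")
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
}
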