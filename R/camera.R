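#' Pinhole camera model with ground-frame extrinsics
#'
#' Constructs the camera description used throughout the pipeline: pinhole
#' intrinsics plus the two extrinsic quantities that matter for height
#' measurement from a row-following platform -- the mount height above the
#' ground and the downward pitch of the optical axis.
#'
#' Axis convention: camera x right, y down (image down), z forward along the
#' optical axis. `pitch` rotates the camera about its x-axis so the optical
#' axis points `pitch` radians below horizontal. Pixel coordinates are
#' 0-based with pixel centers at integer coordinates.
#'
#' @param fx,fy Focal lengths in pixels (> 0).
#' @param cx,cy Principal point in pixels.
#' @param mount_height Camera height above ground in meters (> 0).
#' @param pitch_deg Downward tilt from horizontal in degrees, in [0, 90).
#' @param depth_scale Depth-map units per meter (1000 for millimeter maps).
#' @param width,height Image size in pixels.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model(fx = 200, fy = 200, cx = 159.5, cy = 119.5,
#'                     mount_height = 1.8, pitch_deg = 45)
#' backproject_pixel(159.5, 119.5, 2000, cam)
#' @export
camera_model <- function(fx, fy, cx, cy,
                         mount_height = 1.8, pitch_deg = 45,
                         depth_scale = 1000, width = 320L, height = 240L) {
  stopifnot(fx > 0, fy > 0, depth_scale > 0, mount_height > 0,
            pitch_deg >= 0, pitch_deg < 90)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 mount_height = mount_height,
                 pitch = pitch_deg * pi / 180,
                 depth_scale = depth_scale,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "<camera_model> %dx%d px, fx=%.1f fy=%.1f cx=%.1f cy=%.1f\n",
    x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  cat(sprintf("  mount %.2f m, pitch %.1f deg, depth scale %g/m\n",
              x$mount_height, x$pitch * 180 / pi, x$depth_scale))
  invisible(x)
}

#' Read / write a camera configuration file
#'
#' YAML with keys `fx, fy, cx, cy, mount_height_m, pitch_deg, depth_scale,
#' width, height`.
#'
#' @param path File path.
#' @return `read_camera_config` returns a [camera_model()].
#' @export
read_camera_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("fx", "fy", "cx", "cy", "mount_height_m", "pitch_deg", "depth_scale")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("camera config missing keys: ", paste(miss, collapse = ", "))
  camera_model(fx = cfg$fx, fy = cfg$fy, cx = cfg$cx, cy = cfg$cy,
               mount_height = cfg$mount_height_m, pitch_deg = cfg$pitch_deg,
               depth_scale = cfg$depth_scale,
               width = cfg$width %||% 320L, height = cfg$height %||% 240L)
}

#' @rdname read_camera_config
#' @param cam A [camera_model()].
#' @export
write_camera_config <- function(cam, path) {
  yaml::write_yaml(list(fx = cam$fx, fy = cam$fy, cx = cam$cx, cy = cam$cy,
                        mount_height_m = cam$mount_height,
                        pitch_deg = cam$pitch * 180 / pi,
                        depth_scale = cam$depth_scale,
                        width = cam$width, height = cam$height), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Back-project a pixel with depth to a camera-frame point
#'
#' Inverse pinhole mapping: `z = depth / depth_scale`,
#' `x = (u - cx) z / fx`, `y = (v - cy) z / fy` (meters).
#'
#' @param u,v Pixel column / row (0-based, vectorized).
#' @param depth Raw depth values in depth-map units; 0 or NA is invalid.
#' @param cam A [camera_model()].
#' @return A 3-column matrix (x, y, z) in meters; one row per input pixel.
#'   Invalid depths raise an error.
#' @export
backproject_pixel <- function(u, v, depth, cam) {
  bad <- !is.finite(depth) | depth <= 0
  if (any(bad)) stop("no valid depth at ", sum(bad), " pixel(s)")
  z <- depth / cam$depth_scale
  cbind(x = (u - cam$cx) * z / cam$fx,
        y = (v - cam$cy) * z / cam$fy,
        z = z)
}

#' Back-project all valid depth pixels inside a box
#'
#' @param depth A [depth_frame()].
#' @param box Pixel rectangle `c(x1, y1, x2, y2)` (0-based, half-open in x2/y2
#'   when rasterized).
#' @param cam A [camera_model()].
#' @return A list with `points` (n x 3 matrix, meters) and `n_skipped`
#'   (invalid pixels inside the clipped box). A box with no valid pixels
#'   raises an "empty point cloud" error.
#' @export
backproject_box <- function(depth, box, cam) {
  px <- box_pixels(depth, box)
  if (length(px$u) == 0L) stop("box outside image or empty")
  d <- depth$data[cbind(px$v + 1L, px$u + 1L)]
  ok <- is.finite(d) & d > 0
  if (!any(ok)) stop("empty point cloud: no valid depth pixels in box")
  pts <- backproject_pixel(px$u[ok], px$v[ok], d[ok], cam)
  list(points = pts, n_skipped = sum(!ok))
}

# integer pixel grid inside a box clipped to the image; 0-based coordinates
box_pixels <- function(depth, box) {
  x1 <- max(0L, as.integer(ceiling(box[1])))
  y1 <- max(0L, as.integer(ceiling(box[2])))
  x2 <- min(ncol(depth$data), as.integer(floor(box[3])))
  y2 <- min(nrow(depth$data), as.integer(floor(box[4])))
  if (x2 <= x1 || y2 <= y1) return(list(u = integer(0), v = integer(0)))
  u <- rep(x1:(x2 - 1L), each = y2 - y1)
  v <- rep(y1:(y2 - 1L), times = x2 - x1)
  list(u = u, v = v)
}

#' Height above ground of camera-frame points
#'
#' For a camera mounted `mount_height` above the ground and pitched down by
#' `pitch` about its x-axis, a camera-frame point (x, y, z) sits
#' `y cos(pitch) + z sin(pitch)` below the camera, so its height above
#' ground is `mount_height - (y cos(pitch) + z sin(pitch))`.
#'
#' @param points n x 3 matrix of camera-frame points (meters).
#' @param cam A [camera_model()].
#' @return Numeric vector of per-point heights above ground (meters).
#' @export
ground_height <- function(points, cam) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (nrow(points) == 0L) stop("empty point set")
  drop <- points[, 2] * cos(cam$pitch) + points[, 3] * sin(cam$pitch)
  cam$mount_height - drop
}

#' Horizontal ground-plane range of camera-frame points
#'
#' The forward distance from the camera measured along the ground (the
#' component of the point's offset in the horizontal direction of view):
#' `z cos(pitch) - y sin(pitch)`. For a level camera this is exactly the
#' depth `z`.
#'
#' @inheritParams ground_height
#' @return Numeric vector of horizontal ranges (meters).
#' @export
ground_range <- function(points, cam) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points[, 3] * cos(cam$pitch) - points[, 2] * sin(cam$pitch)
}

#' Project a world point into the image of a camera at a given station
#'
#' The camera travels along the world x-axis at lateral position 0 and
#' height `mount_height`, viewing in +y (lateral) pitched down. World frame:
#' x along the row (travel direction), y lateral toward the rows, z up.
#'
#' @param p World point `c(x, y, z)` in meters (vectorized: n x 3 matrix).
#' @param cam A [camera_model()].
#' @param station Camera position along the row (meters).
#' @return A data.frame with columns `u`, `v`, `depth` (raw units), `z_m`.
#'   Points at or behind the camera plane get `NA` with `visible = FALSE`.
#' @export
project_point <- function(p, cam, station = 0) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  dx <- p[, 1] - station
  dy <- p[, 2]
  dz <- p[, 3] - cam$mount_height
  sa <- sin(cam$pitch); ca <- cos(cam$pitch)
  # camera axes in world coords: x=(1,0,0), y=(0,-sa,-ca), z=(0,ca,-sa)
  xc <- dx
  yc <- -dy * sa - dz * ca
  zc <- dy * ca - dz * sa
  vis <- zc > 1e-9
  u <- ifelse(vis, cam$cx + cam$fx * xc / zc, NA_real_)
  v <- ifelse(vis, cam$cy + cam$fy * yc / zc, NA_real_)
  data.frame(u = u, v = v, depth = ifelse(vis, zc * cam$depth_scale, NA_real_),
             z_m = ifelse(vis, zc, NA_real_), visible = vis)
}

#' Depth frame container
#'
#' A per-pixel range image. Values are raw integer depth units
#' (`cam$depth_scale` units per meter); 0 marks an invalid pixel
#' (RealSense convention), NA is also treated as invalid.
#'
#' @param data Numeric matrix, rows = image rows (v), cols = image columns (u).
#' @return An object of class `depth_frame`.
#' @export
depth_frame <- function(data) {
  stopifnot(is.matrix(data))
  structure(list(data = data, width = ncol(data), height = nrow(data)),
            class = "depth_frame")
}

#' @export
print.depth_frame <- function(x, ...) {
  ok <- is.finite(x$data) & x$data > 0
  cat(sprintf("<depth_frame> %dx%d px, %.1f%% valid\n",
              x$width, x$height, 100 * mean(ok)))
  invisible(x)
}

#' Read / write a 16-bit depth image
#'
#' Depth frames are stored as single-channel 16-bit grayscale images in raw
#' integer depth units. Writing uses 16-bit TIFF (lossless for the full
#' 0..65535 range); reading accepts 16-bit TIFF or 16-bit PNG.
#'
#' @param path Image path (`.tif`/`.tiff` or `.png`).
#' @return `read_depth` returns a [depth_frame()].
#' @export
read_depth <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (!is.null(bits) && bits != 16L)
      stop("depth image must be 16-bit, got ", bits, "-bit: ", path)
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 16L)
      stop("depth image must be 16-bit, got ", info$bit.depth, "-bit: ", path)
  } else stop("unsupported depth image format: ", path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L) stop("depth image must be single-channel: ", path)
    img <- img[, , 1]
  }
  depth_frame(matrix(round(img * 65535), nrow(img), ncol(img)))
}

#' @rdname read_depth
#' @param frame A [depth_frame()].
#' @export
write_depth <- function(frame, path) {
  d <- frame$data
  d[!is.finite(d)] <- 0
  d <- pmin(pmax(round(d), 0), 65535)
  tiff::writeTIFF(d / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
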