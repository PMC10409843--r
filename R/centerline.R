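#' Vessel centreline
#'
#' An ordered 3D polyline (in mm) with cumulative arc length. Centrelines are
#' the kinematic backbone of the package: artery surfaces are extruded along
#' them and the bending displacement field is the pointwise difference between
#' the diastolic and systolic centrelines.
#'
#' @param points Numeric matrix (n x 3) of ordered coordinates in mm, n >= 3.
#' @return Object of class \code{centerline} with elements \code{points}
#'   (n x 3 matrix) and \code{arc_length} (cumulative arc length, mm,
#'   starting at 0 and strictly increasing).
#' @examples
#' cl <- centerline(cbind(0:10, 0, 0))
#' cl$arc_length
#' @export
centerline <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("centerline points must be n x 3", call. = FALSE)
  if (nrow(points) < 3L) stop("a centerline needs at least 3 points", call. = FALSE)
  storage.mode(points) <- "double"
  seg <- row_norms(diff(points))
  if (any(seg <= 0))
    stop("invalid centerline: arc length not strictly increasing (repeated points)",
         call. = FALSE)
  structure(list(points = points, arc_length = c(0, cumsum(seg))),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.3f mm\n",
              nrow(x$points), total_length(x)))
  invisible(x)
}

#' Total arc length of a centreline
#' @param c A \code{centerline}.
#' @return Length in mm.
#' @export
total_length <- function(c) c$arc_length[length(c$arc_length)]

#' Resample a centreline at equal normalised arc length
#'
#' Places \code{n} points equally spaced in normalised arc length by linear
#' interpolation along the polyline; the endpoints are preserved exactly.
#' Used to co-register diastolic and systolic centrelines before computing
#' bending vectors.
#'
#' @param c A \code{centerline}.
#' @param n Number of output points (>= 3).
#' @return A \code{centerline} with \code{n} points.
#' @export
resample_centerline <- function(c, n) {
  if (n < 3L) stop("n must be >= 3", call. = FALSE)
  L <- total_length(c)
  if (L <= 0) stop("degenerate (zero-length) centerline", call. = FALSE)
  s_new <- seq(0, L, length.out = n)
  pts <- sapply(1:3, function(k)
    stats::approx(c$arc_length, c$points[, k], xout = s_new)$y)
  pts[1, ] <- c$points[1, ]
  pts[n, ] <- c$points[nrow(c$points), ]
  centerline(pts)
}

# Unit tangents by central differences (one-sided at the ends).
centerline_tangents <- function(c) {
  p <- c$points
  n <- nrow(p)
  t <- matrix(0, n, 3)
  t[1, ] <- p[2, ] - p[1, ]
  t[n, ] <- p[n, ] - p[n - 1, ]
  if (n > 2) t[2:(n - 1), ] <- p[3:n, ] - p[1:(n - 2), ]
  normalize_rows(t)
}

#' Curvature vectors of a centreline
#'
#' Discrete curvature vector dT/ds (1/mm) at each point, pointing towards the
#' local centre of curvature (the concave, inner-curvature side). Used to
#' anchor the circumferential origin and the inner-curvature bending patch.
#'
#' @param c A \code{centerline}.
#' @return n x 3 matrix of curvature vectors (1/mm); rows are zero where the
#'   polyline is locally straight.
#' @export
centerline_curvature <- function(c) {
  t <- centerline_tangents(c)
  s <- c$arc_length
  n <- nrow(t)
  k <- matrix(0, n, 3)
  if (n > 2)
    k[2:(n - 1), ] <- (t[3:n, ] - t[1:(n - 2), ]) / (s[3:n] - s[1:(n - 2)])
  k[1, ] <- k[2, ]
  k[n, ] <- k[n - 1, ]
  # remove any tangential component so k is purely normal
  k - t * rowSums(k * t)
}

#' Read a centreline from CSV
#'
#' Expects columns x, y, z (mm), one point per row; extra columns ignored.
#'
#' @param path CSV file path.
#' @return A \code{centerline}.
#' @export
read_centerline_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("x", "y", "z")
  if (!all(need %in% names(d)))
    stop("centerline CSV needs columns x,y,z", call. = FALSE)
  centerline(as.matrix(d[, need]))
}

#' Write a centreline to CSV
#' @param c A \code{centerline}.
#' @param path Output path.
#' @export
write_centerline_csv <- function(c, path) {
  d <- data.frame(x = c$points[, 1], y = c$points[, 2], z = c$points[, 3])
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a centreline from a legacy-ASCII VTK polyline file
#'
#' Minimal reader for legacy VTK POLYDATA files holding a single polyline
#' (POINTS section, coordinates in mm).
#'
#' @param path VTK file path.
#' @return A \code{centerline}.
#' @export
read_centerline_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)
  if (length(ip) != 1L) stop("not a VTK POLYDATA polyline file", call. = FALSE)
  n <- as.integer(strsplit(trimws(lines[ip]), "\\s+")[[1]][2])
  nums <- numeric(0)
  i <- ip + 1L
  while (length(nums) < 3L * n && i <= length(lines)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (anyNA(v)) break
    nums <- c(nums, v)
    i <- i + 1L
  }
  if (length(nums) < 3L * n) stop("truncated VTK POINTS section", call. = FALSE)
  centerline(matrix(nums[seq_len(3L * n)], ncol = 3, byrow = TRUE))
}
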