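#' Metric map container
#'
#' A scalar field on the structured (axial station x circumferential) lumen
#' grid with its summary statistics.
#'
#' @param values Numeric matrix (n_axial x n_circ).
#' @param metric_name One of "TAWSS", "tSS", "OSI", "strain_axial",
#'   "strain_circ", "strain_radial" (or any label).
#' @param units Unit string ("Pa", "\%", "").
#' @return Object of class \code{metric_map} with \code{values},
#'   \code{metric_name}, \code{units} and \code{summary}.
#' @export
metric_map <- function(values, metric_name, units = "") {
  values <- as.matrix(values)
  structure(list(values = values, metric_name = metric_name, units = units,
                 summary = summarize_field(values)),
            class = "metric_map")
}

#' @export
print.metric_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<metric_map> %s [%s]: median %.4g [Q1 %.4g, Q3 %.4g], range [%.4g, %.4g]\n",
              x$metric_name, x$units, s$median, s$q1, s$q3, s$min, s$max))
  invisible(x)
}

summarize_field <- function(v) {
  v <- as.vector(v)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], min = min(v), max = max(v))
}

#' Summary statistics of a metric map
#'
#' Median, quartiles (linear-interpolation, type-7 rule), minimum and
#' maximum over all grid nodes (the inlet extension is already excluded
#' from every metric grid).
#'
#' @param map A \code{metric_map} (or plain matrix).
#' @return List with \code{median}, \code{q1}, \code{q3}, \code{min},
#'   \code{max}.
#' @export
summarize <- function(map) {
  if (inherits(map, "metric_map")) map$summary else summarize_field(map)
}

wss_component <- function(wss, k) {
  x <- wss$tau[, , , k, drop = FALSE]
  dim(x) <- dim(wss$tau)[1:3]
  x
}

wss_magnitude <- function(wss) {
  sqrt(wss_component(wss, 1)^2 + wss_component(wss, 2)^2 +
         wss_component(wss, 3)^2)
}

wss_time_mean_vec <- function(wss) {
  # mean WSS vector per node over the periodic cycle: n_ax x n_circ x 3
  d <- dim(wss$tau)
  out <- array(0, c(d[1], d[2], 3))
  for (k in 1:3) out[, , k] <- apply(wss_component(wss, k), c(1, 2), mean)
  out
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' Cycle average of the wall-shear-stress vector magnitude per lumen node,
#' by the trapezoidal rule on the uniform periodic time grid.
#'
#' @param wss A \code{wss_field} covering exactly one cycle.
#' @return A \code{metric_map} in Pa.
#' @export
tawss <- function(wss) {
  metric_map(apply(wss_magnitude(wss), c(1, 2), mean), "TAWSS", "Pa")
}

#' Oscillatory shear index (OSI)
#'
#' OSI = 1/2 (1 - |integral tau dt| / integral |tau| dt) per node: 0 for
#' unidirectional shear, 0.5 for fully reversing shear. Nodes where the
#' shear vanishes over the whole cycle are assigned 0.
#'
#' @param wss A \code{wss_field}.
#' @return A \code{metric_map}, dimensionless, values in [0, 0.5].
#' @export
osi <- function(wss) {
  mv <- wss_time_mean_vec(wss)
  num <- sqrt(mv[, , 1]^2 + mv[, , 2]^2 + mv[, , 3]^2)
  den <- apply(wss_magnitude(wss), c(1, 2), mean)
  v <- ifelse(den > 0, 0.5 * (1 - num / den), 0)
  v <- pmin(pmax(v, 0), 0.5)
  metric_map(v, "OSI", "")
}

#' Transverse wall shear stress (tSS / transWSS)
#'
#' Cycle average of the unsigned wall-shear component perpendicular to the
#' cycle-mean WSS direction within the tangent plane: a multidirectionality
#' metric. Nodes with a vanishing mean WSS vector are assigned 0.
#'
#' @param wss A \code{wss_field}.
#' @return A \code{metric_map} in Pa.
#' @export
tss <- function(wss) {
  d <- dim(wss$tau)
  mv <- wss_time_mean_vec(wss)
  g <- wss$geometry
  ct <- cos(wss$theta); st <- sin(wss$theta)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      m <- mv[i, j, ]
      nm <- vec_norm(m)
      if (nm == 0) next
      n_hat <- ct[j] * g$frame$normal[i, ] + st[j] * g$frame$binormal[i, ]
      q <- cross3(n_hat, m / nm)
      nq <- vec_norm(q)
      if (nq == 0) next
      q <- q / nq
      out[i, j] <- mean(abs(wss$tau[i, j, , ] %*% q))
    }
  }
  metric_map(out, "tSS", "Pa")
}

#' Opened-and-flattened metric map
#'
#' Re-indexes the structured metric grid into the display layout used for
#' opened-and-flattened vessel maps: rows are the circumferential index
#' starting at the theta = 0 (inner-curvature) cut line, columns run
#' proximal (left) to distal (right). The re-indexing is lossless; rows 1
#' and n_circ are circumferential neighbours across the cut.
#'
#' @param map A \code{metric_map}.
#' @return Matrix (n_circ x n_axial) with axis attributes \code{axial}
#'   (station index) and \code{theta} (radians).
#' @export
flatten_map <- function(map) {
  m <- t(map$values)
  attr(m, "axial") <- seq_len(ncol(m))
  attr(m, "theta") <- 2 * pi * (seq_len(nrow(m)) - 1) / nrow(m)
  m
}

#' Compare metric distributions between simulation arms
#'
#' Unpaired comparisons use the Kruskal-Wallis test across all groups plus
#' pairwise Wilcoxon rank-sum tests; paired comparisons (strain fields on
#' identical grids) use Wilcoxon signed-rank tests. All p-values are
#' Bonferroni-multiplied by the number of pairwise comparisons and capped
#' at 1.
#'
#' @param maps Named list of >= 2 \code{metric_map} objects (or matrices).
#' @param paired Use paired signed-rank tests (grids must match).
#' @return List with \code{kruskal} (H statistic and corrected p; unpaired
#'   only) and \code{pairwise}, a data frame of pairwise corrected
#'   p-values.
#' @export
compare_distributions <- function(maps, paired = FALSE) {
  if (length(maps) < 2) stop("need at least 2 groups", call. = FALSE)
  vals <- lapply(maps, function(m)
    as.vector(if (inherits(m, "metric_map")) m$values else m))
  if (is.null(names(vals)))
    names(vals) <- paste0("group", seq_along(vals))
  pairs <- utils::combn(length(vals), 2)
  n_comp <- ncol(pairs)
  kr <- NULL
  if (!paired) {
    k <- stats::kruskal.test(vals)
    kr <- list(H = unname(k$statistic), p = min(1, k$p.value * n_comp),
               p_raw = k$p.value)
  }
  pw <- data.frame(group1 = character(0), group2 = character(0),
                   p = numeric(0), p_raw = numeric(0))
  for (c_i in seq_len(n_comp)) {
    a <- pairs[1, c_i]; b <- pairs[2, c_i]
    if (paired && length(vals[[a]]) != length(vals[[b]]))
      stop("paired tests require equal grids", call. = FALSE)
    diffs_equal <- paired && all(vals[[a]] == vals[[b]])
    p_raw <- if (diffs_equal) 1 else
      suppressWarnings(stats::wilcox.test(vals[[a]], vals[[b]],
                                          paired = paired)$p.value)
    pw <- rbind(pw, data.frame(group1 = names(vals)[a],
                               group2 = names(vals)[b],
                               p = min(1, p_raw * n_comp), p_raw = p_raw))
  }
  list(kruskal = kr, pairwise = pw, n_comparisons = n_comp)
}

#' Export a metric map as CSV
#'
#' Flat CSV with columns station, theta_index, value.
#'
#' @param map A \code{metric_map}.
#' @param path Output path.
#' @export
write_metric_csv <- function(map, path) {
  v <- map$values
  d <- data.frame(station = rep(seq_len(nrow(v)), ncol(v)) - 1L,
                  theta_index = rep(seq_len(ncol(v)), each = nrow(v)) - 1L,
                  value = as.vector(v))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
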