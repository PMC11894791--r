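#' Synthetic high-density sensor layout
#'
#' Builds a quasi-uniform arrangement of EEG sensors on the upper unit
#' hemisphere (a Fibonacci lattice), labels them, and attaches a
#' distance-based neighbor graph plus named region-of-interest (ROI) masks.
#' The geometry stands in for a proprietary 129-channel geodesic montage;
#' every analysis in the package takes the layout as an argument, so a real
#' montage (ids, positions, edges, ROIs) can be substituted via
#' [read_layout()].
#'
#' Axes follow the usual head convention: +y is anterior (front), -y
#' posterior, +z up. The `posterior` and `anterior` ROIs are the sensors
#' with y below/above +-0.15; they are conventional masks, not a
#' reconstruction of any published montage.
#'
#' @param n_sensors number of sensors (default 129).
#' @param adjacency_degree target median neighbor count for the
#'   distance-threshold adjacency (default 6, typical for high-density EEG
#'   neighbor definitions).
#' @return An object of class `sensor_layout`: a list with `ids` (character),
#'   `positions` (n x 3 matrix, unit sphere), `edges` (two-column integer
#'   matrix, i < j), `neighbors` (list of integer vectors), and `rois`
#'   (named list of sensor-id character vectors).
#' @export
#' @examples
#' lay <- sensor_layout(32)
#' length(lay$ids)
sensor_layout <- function(n_sensors = 129, adjacency_degree = 6) {
  stopifnot(n_sensors >= 4)
  # Fibonacci lattice on the upper hemisphere: deterministic, quasi-uniform
  i <- seq_len(n_sensors) - 0.5
  z <- i / n_sensors            # in (0, 1): heights above the equator
  phi <- pi * (1 + sqrt(5)) * i # golden-angle azimuths
  r <- sqrt(1 - z^2)
  pos <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  ids <- sprintf("E%03d", seq_len(n_sensors))
  rownames(pos) <- ids

  thr <- .adjacency_threshold(pos, adjacency_degree)
  edges <- neighbors_from_distance(pos, thr)

  rois <- list(
    posterior = ids[pos[, "y"] <= -0.15],
    anterior  = ids[pos[, "y"] >= 0.15]
  )
  structure(
    list(
      ids = ids, positions = pos, edges = edges,
      neighbors = edges_to_neighbors(edges, n_sensors),
      rois = rois, adjacency_threshold = thr
    ),
    class = "sensor_layout"
  )
}

#' @export
print.sensor_layout <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf(
    "<sensor_layout> %d sensors, %d edges (median degree %g)\nROIs: %s\n",
    length(x$ids), nrow(x$edges), stats::median(deg),
    paste(sprintf("%s (%d)", names(x$rois), lengths(x$rois)), collapse = ", ")
  ))
  invisible(x)
}

# smallest threshold whose adjacency has the target median degree
.adjacency_threshold <- function(pos, target_degree) {
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  cand <- sort(unique(signif(d[upper.tri(d)], 6)))
  for (thr in cand) {
    deg <- rowSums(d <= thr)
    if (stats::median(deg) >= target_degree) return(thr)
  }
  max(cand)
}

#' Distance-threshold sensor adjacency
#'
#' Connects two sensors whenever their Euclidean distance is at most
#' `threshold`. The edge set is symmetric and irreflexive; it is returned in
#' canonical form (each undirected edge once, `i < j`). A warning is issued
#' if the resulting graph does not connect all sensors, since cluster
#' formation then cannot bridge the components.
#'
#' @param positions n x 3 numeric matrix of sensor positions.
#' @param threshold positive distance cutoff (same units as `positions`).
#' @return two-column integer matrix of edges (`i`, `j`), `i < j`.
#' @export
neighbors_from_distance <- function(positions, threshold) {
  stopifnot(is.matrix(positions), ncol(positions) == 3, threshold > 0)
  d <- as.matrix(stats::dist(positions))
  keep <- d <= threshold & upper.tri(d)
  idx <- which(keep, arr.ind = TRUE)
  edges <- cbind(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  if (!.is_connected(edges, nrow(positions))) {
    warning("adjacency graph is not connected at threshold ", threshold)
  }
  edges
}

# adjacency list from a canonical edge matrix
edges_to_neighbors <- function(edges, n) {
  nb <- vector("list", n)
  for (k in seq_len(n)) nb[[k]] <- integer(0)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  lapply(nb, sort)
}

.is_connected <- function(edges, n) {
  if (n <= 1) return(TRUE)
  nb <- edges_to_neighbors(edges, n)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in nb[[v]]) if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
  }
  all(seen)
}

#' Subset a layout to an ROI
#'
#' Restricts a layout to one of its named ROI masks (or an explicit id set),
#' rebuilding the neighbor structure over the kept sensors. Values are never
#' touched: ROI selection only changes the sensor index set.
#'
#' @param layout a [sensor_layout()].
#' @param roi ROI name (e.g. `"posterior"`) or character vector of sensor ids.
#' @return a `sensor_layout` over the selected sensors.
#' @export
layout_roi <- function(layout, roi) {
  ids <- if (length(roi) == 1 && roi %in% names(layout$rois)) {
    layout$rois[[roi]]
  } else {
    roi
  }
  stopifnot(all(ids %in% layout$ids))
  keep <- match(ids, layout$ids)
  edges <- layout$edges
  edges <- edges[edges[, 1] %in% keep & edges[, 2] %in% keep, , drop = FALSE]
  remap <- match(seq_along(layout$ids), keep)
  edges <- cbind(i = remap[edges[, 1]], j = remap[edges[, 2]])
  structure(
    list(
      ids = layout$ids[keep],
      positions = layout$positions[keep, , drop = FALSE],
      edges = edges,
      neighbors = edges_to_neighbors(edges, length(keep)),
      rois = lapply(layout$rois, function(r) intersect(r, layout$ids[keep])),
      adjacency_threshold = layout$adjacency_threshold
    ),
    class = "sensor_layout"
  )
}

#' Read / write a sensor layout as JSON
#'
#' The JSON schema carries sensor ids, xyz positions, the explicit edge list
#' and the ROI name -> id mapping, so externally defined montages can be used
#' everywhere a packaged layout can.
#'
#' @param layout a `sensor_layout`.
#' @param path file path.
#' @return `read_layout` returns a `sensor_layout`; `write_layout` its path,
#'   invisibly.
#' @export
write_layout <- function(layout, path) {
  obj <- list(
    ids = layout$ids,
    positions = apply(layout$positions, 1, function(p) as.list(p), simplify = FALSE),
    edges = apply(layout$edges, 1, function(e) as.integer(e), simplify = FALSE),
    rois = layout$rois
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  ids <- vapply(obj$ids, identity, character(1))
  pos <- t(vapply(obj$positions, function(p) unlist(p, use.names = FALSE), numeric(3)))
  colnames(pos) <- c("x", "y", "z")
  rownames(pos) <- ids
  edges <- if (length(obj$edges)) {
    t(vapply(obj$edges, function(e) as.integer(unlist(e)), integer(2)))
  } else {
    matrix(integer(0), 0, 2)
  }
  colnames(edges) <- c("i", "j")
  structure(
    list(
      ids = ids, positions = pos, edges = edges,
      neighbors = edges_to_neighbors(edges, length(ids)),
      rois = lapply(obj$rois, function(r) vapply(r, identity, character(1))),
      adjacency_threshold = NA_real_
    ),
    class = "sensor_layout"
  )
}
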