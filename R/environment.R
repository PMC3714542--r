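#' Maze environments
#'
#' An environment is a navigable 2-D region bounded by polygon walls: an outer
#' ring plus optional hole rings (obstacles). Coordinates are metres, origin at
#' the lower left, y up. Built-in shapes:
#'
#' * `"open"`: square arena of side `side`.
#' * `"T"`: T-shaped corridor (one junction, three arm endpoints).
#' * `"A"`: triangular loop corridor, one hole (two routes between most pairs
#'   of points).
#' * `"inf"`: figure-of-eight corridor, two holes.
#'
#' A custom environment is given as a list of rings, each an `k x 2` vertex
#' matrix, the first ring being the outer boundary.
#'
#' @param shape `"open"`, `"T"`, `"A"`, `"inf"`, or a list of ring matrices
#' @param side scale of the built-in shapes (metres)
#' @return an object of class `wn_env`
#' @examples
#' env <- make_environment("T")
#' env_contains(env, cbind(0.5, 0.9))
#' @export
make_environment <- function(shape = "open", side = 1) {
  if (is.character(shape)) {
    rings <- switch(shape,
      open = list(side * rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))),
      "T" = list(side * rbind(
        c(0.35, 0), c(0.65, 0), c(0.65, 0.7), c(1, 0.7),
        c(1, 1), c(0, 1), c(0, 0.7), c(0.35, 0.7))),
      A = list(
        side * rbind(c(0, 0), c(1, 0), c(0.5, 1.1)),
        side * rbind(c(0.3, 0.22), c(0.7, 0.22), c(0.5, 0.66))),
      inf = list(
        side * rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1)),
        side * rbind(c(0.3, 0.3), c(0.8, 0.3), c(0.8, 0.7), c(0.3, 0.7)),
        side * rbind(c(1.2, 0.3), c(1.7, 0.3), c(1.7, 0.7), c(1.2, 0.7))),
      stop("unknown built-in shape: ", shape)
    )
    name <- shape
  } else {
    rings <- lapply(shape, function(r) {
      r <- as.matrix(r)
      stopifnot(ncol(r) == 2, nrow(r) >= 3)
      storage.mode(r) <- "double"
      r
    })
    if (ring_self_intersects(rings[[1L]]))
      stop("outer ring is self-intersecting")
    name <- "custom"
  }
  bbox <- apply(do.call(rbind, rings), 2, range)
  env <- structure(
    list(name = name, rings = rings, bbox = bbox,
         area = abs(shoelace(rings[[1L]])) -
           sum(vapply(rings[-1L], function(r) abs(shoelace(r)), 0)),
         side = side),
    class = "wn_env")
  if (!region_connected(env))
    stop("navigable region is disconnected")
  env
}

shoelace <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  i2 <- c(seq_len(nrow(ring))[-1L], 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

ring_self_intersects <- function(ring) {
  k <- nrow(ring)
  idx <- cbind(seq_len(k), c(seq_len(k)[-1L], 1L))
  for (a in seq_len(k - 2L)) {
    for (b in (a + 2L):k) {
      if (a == 1L && b == k) next
      s <- rbind(c(ring[idx[a, 1], ], ring[idx[a, 2], ]))
      e <- list(rbind(ring[idx[b, 1], ], ring[idx[b, 2], ]))
      if (seg_cross_cpp(s, e)) return(TRUE)
    }
  }
  FALSE
}

# connectivity of the navigable region, checked on a coarse raster
region_connected <- function(env, res = 40) {
  gx <- seq(env$bbox[1, 1], env$bbox[2, 1], length.out = res)
  gy <- seq(env$bbox[1, 2], env$bbox[2, 2], length.out = res)
  pts <- as.matrix(expand.grid(x = gx, y = gy))
  inside <- matrix(pip_cpp(pts, env$rings), res, res)
  idx <- which(inside, arr.ind = TRUE)
  if (nrow(idx) == 0) return(FALSE)
  comp <- matrix(0L, res, res)
  queue <- idx[1, , drop = FALSE]
  comp[idx[1, 1], idx[1, 2]] <- 1L
  while (nrow(queue) > 0) {
    cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nb <- cur + d
      if (all(nb >= 1) && all(nb <= res) && inside[nb[1], nb[2]] &&
          comp[nb[1], nb[2]] == 0L) {
        comp[nb[1], nb[2]] <- 1L
        queue <- rbind(queue, nb)
      }
    }
  }
  sum(comp) == nrow(idx)
}

#' Point containment test
#'
#' @param env a [make_environment()] object
#' @param pts `k x 2` matrix of positions (metres)
#' @return logical vector, `TRUE` for points inside the navigable region
#' @export
env_contains <- function(env, pts) {
  pts <- matrix(as.double(pts), ncol = 2)
  pip_cpp(pts, env$rings)
}

#' Wall-crossing test for straight segments
#'
#' @param env environment
#' @param segs `k x 4` matrix `(x1, y1, x2, y2)`
#' @return logical vector, `TRUE` where the segment crosses a wall
#' @export
env_blocked <- function(env, segs) {
  segs <- matrix(as.double(segs), ncol = 4)
  seg_cross_cpp(segs, env$rings)
}

#' Distance from points to the nearest wall
#'
#' Used to select interior cells (e.g. at least 2 sigma from any wall) for
#' vector-field diagnostics.
#'
#' @param env environment
#' @param pts `k x 2` matrix
#' @return numeric vector of distances (metres)
#' @export
env_wall_distance <- function(env, pts) {
  pts <- matrix(as.double(pts), ncol = 2)
  d <- rep(Inf, nrow(pts))
  for (ring in env$rings) {
    k <- nrow(ring)
    for (a in seq_len(k)) {
      b <- if (a == k) 1L else a + 1L
      d <- pmin(d, point_seg_dist(pts, ring[a, ], ring[b, ]))
    }
  }
  d
}

point_seg_dist <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
  sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
}

#' Read an environment from a JSON spec
#'
#' The file holds `{"rings": [[[x, y], ...], ...]}` with the outer ring first;
#' origin lower-left, y up, metres.
#'
#' @param path JSON file path
#' @return a `wn_env`
#' @export
read_environment <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(spec$shape))
    return(make_environment(spec$shape[[1]],
                            if (is.null(spec$side)) 1 else spec$side[[1]]))
  rings <- lapply(spec$rings, function(r)
    matrix(unlist(r), ncol = 2, byrow = TRUE))
  make_environment(rings)
}

#' @export
print.wn_env <- function(x, ...) {
  cat(sprintf("<wn_env '%s': %d ring(s), area %.3f m^2, bbox [%g, %g] x [%g, %g]>\n",
              x$name, length(x$rings), x$area,
              x$bbox[1, 1], x$bbox[2, 1], x$bbox[1, 2], x$bbox[2, 2]))
  invisible(x)
}
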