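#' Assign place-field centers in one or more environments
#'
#' Centers are laid on a regular grid restricted to the navigable region, with
#' isotropic Gaussian jitter, and assigned to neurons by a uniformly random
#' permutation per environment, so the neuron-to-center pairing in different
#' environments is statistically independent.
#'
#' The receptive-field width `sigma` is derived from the grid pitch so that
#' the field footprint (cells within `2 * sigma` of a center) covers the
#' configured number of neighbouring cells; the regime of interest is 25-50
#' cells in a ~2000-cell network.
#'
#' @param envs a `wn_env` or list of `wn_env` (one place field per neuron per
#'   environment)
#' @param n_cells number of neurons; `NULL` uses the capacity of the first
#'   environment's grid
#' @param grid_pitch grid spacing in metres; `NULL` chooses the pitch so the
#'   grid capacity of the smallest environment is close to `n_cells`
#' @param jitter_sd Gaussian jitter of each center (metres); default
#'   `0.15 * grid_pitch`
#' @param footprint target number of cells within `2 * sigma` of a center
#' @param amplitude peak sensory current (nA)
#' @param seed integer seed (assignment is deterministic given the seed)
#' @return an object of class `wn_map` with fields `centers` (list of `n x 2`
#'   matrices, one per environment), `sigma`, `amplitude`, `pitch`, `n`,
#'   `n_envs`
#' @export
assign_place_fields <- function(envs, n_cells = NULL, grid_pitch = NULL,
                                jitter_sd = NULL, footprint = 35,
                                amplitude = 1.2, seed = 1) {
  if (inherits(envs, "wn_env")) envs <- list(envs)
  set.seed(derive_seed(seed, "place_fields"))

  n_envs <- length(envs)
  auto_pitch <- is.null(grid_pitch)
  if (auto_pitch) {
    if (is.null(n_cells)) stop("give n_cells or grid_pitch")
    # each environment gets its own pitch so the n cells tile its own area
    grid_pitch <- vapply(envs, function(e) sqrt(e$area / n_cells), 0)
  } else {
    grid_pitch <- rep_len(grid_pitch, n_envs)
  }
  grids <- vector("list", n_envs)
  for (e in seq_len(n_envs)) {
    grids[[e]] <- grid_points(envs[[e]], grid_pitch[e])
    while (auto_pitch && nrow(grids[[e]]) < n_cells &&
           grid_pitch[e] > 0.8 * sqrt(envs[[e]]$area / n_cells)) {
      grid_pitch[e] <- 0.98 * grid_pitch[e]  # derived pitch: shrink to fit
      grids[[e]] <- grid_points(envs[[e]], grid_pitch[e])
    }
  }
  cap <- vapply(grids, nrow, 0L)
  if (is.null(n_cells)) n_cells <- min(cap)
  if (any(cap < n_cells))
    stop(sprintf("grid does not fit region: requested %d cells, achieved %d",
                 n_cells, min(cap)))
  jitter_sd <- rep_len(jitter_sd %||% (0.15 * grid_pitch), n_envs)
  if (n_cells < 10 * footprint)
    warning(sprintf("with %d cells the %d-cell footprint regime cannot be reached",
                    n_cells, footprint))

  centers <- vector("list", n_envs)
  for (e in seq_len(n_envs)) {
    g <- grids[[e]]
    keep <- if (nrow(g) > n_cells) sort(sample.int(nrow(g), n_cells)) else seq_len(nrow(g))
    g <- g[keep, , drop = FALSE]
    if (jitter_sd[e] > 0) {
      for (tries in 1:25) {
        jit <- g + matrix(stats::rnorm(2 * n_cells, 0, jitter_sd[e]), ncol = 2)
        ok <- pip_cpp(jit, envs[[e]]$rings)
        g[ok, ] <- jit[ok, ]   # re-draw jitter for points pushed outside
        if (all(ok)) break
      }
    }
    perm <- sample.int(n_cells)          # neuron -> center pairing
    centers[[e]] <- g[perm, , drop = FALSE]
  }

  sigma <- grid_pitch * sqrt(footprint / pi) / 2
  structure(
    list(centers = centers, sigma = sigma, amplitude = amplitude,
         pitch = grid_pitch, n = n_cells, n_envs = n_envs,
         envs = envs, seed = seed),
    class = "wn_map")
}

grid_points <- function(env, pitch) {
  gx <- seq(env$bbox[1, 1] + pitch / 2, env$bbox[2, 1], by = pitch)
  gy <- seq(env$bbox[1, 2] + pitch / 2, env$bbox[2, 2], by = pitch)
  pts <- as.matrix(expand.grid(x = gx, y = gy))
  pts[pip_cpp(pts, env$rings), , drop = FALSE]
}

#' Location-dependent sensory drive
#'
#' Each cell receives an isotropic Gaussian current
#' `amplitude * exp(-|pos - center|^2 / (2 sigma^2))` around its field center,
#' identical width and strength for every neuron. Values below
#' `floor * amplitude` are clamped to zero.
#'
#' @param map a [assign_place_fields()] object
#' @param env_index which environment's centers to use
#' @param pos agent position, length-2 (metres)
#' @param floor relative clamp threshold
#' @return per-neuron current (nA)
#' @export
sensory_current <- function(map, env_index, pos, floor = 1e-4) {
  ctr <- map$centers[[env_index]]
  d2 <- (ctr[, 1] - pos[1])^2 + (ctr[, 2] - pos[2])^2
  i <- map$amplitude * exp(-d2 / (2 * map$sigma[env_index]^2))
  i[i < floor * map$amplitude] <- 0
  i
}

#' Cells within a radius of a point
#' @keywords internal
cells_near <- function(map, env_index, pos, radius) {
  ctr <- map$centers[[env_index]]
  which((ctr[, 1] - pos[1])^2 + (ctr[, 2] - pos[2])^2 <= radius^2)
}

#' Export place-field centers as CSV (neuron_id, env_id, x, y)
#' @param map a `wn_map`
#' @param path output file
#' @export
write_place_fields <- function(map, path) {
  df <- do.call(rbind, lapply(seq_len(map$n_envs), function(e)
    data.frame(neuron_id = seq_len(map$n), env_id = e,
               x = map$centers[[e]][, 1], y = map$centers[[e]][, 2])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @export
print.wn_map <- function(x, ...) {
  cat(sprintf(
    "<wn_map: %d cells x %d env(s), pitch %s m, sigma %s m (footprint ~%d)>\n",
    x$n, x$n_envs, paste(round(x$pitch, 4), collapse = "/"),
    paste(round(x$sigma, 4), collapse = "/"),
    round(pi * (2 * x$sigma[1] / x$pitch[1])^2)))
  invisible(x)
}
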