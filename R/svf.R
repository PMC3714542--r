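#' Compute the synaptic vector field
#'
#' For each neuron `i`, the field vector runs from its place-field center to
#' the weight-weighted centroid of the cells it projects onto:
#' `r_i = sum_j w_ji (x_j - x_i) / sum_j w_ji` over the outgoing synapses of
#' `i`. Neurons with zero total outflow get the zero vector. Because the
#' expression is a weighted mean of neighbour offsets, `|r_i|` can never
#' exceed the largest offset, and scaling all weights by a constant leaves
#' every `r_i` unchanged.
#'
#' @param weights a `wn_weights`
#' @param map a `wn_map`
#' @param env_index environment whose coordinates anchor the vectors
#' @param local_radius only projections within this distance (in the
#'   rendering environment) enter the sum; default three sigma
#' @param mode `"delta"` (default) applies the weighted-centroid formula to
#'   the wavefront-induced weight change `max(w - w_baseline, 0)`, so the
#'   field is exactly zero at baseline (and after [reset_synapses()]) and is
#'   not biased by the geometry of the baseline neighbourhoods; `"direct"`
#'   uses the raw weights
#' @return a `wn_svf`: data.frame `(neuron_id, x, y, dx, dy)`
#' @export
compute_svf <- function(weights, map, env_index = 1,
                        mode = c("delta", "direct"), local_radius = NULL) {
  mode <- match.arg(mode)
  W <- weights$W
  x <- W@x
  if (mode == "delta") x <- pmax(x - weights$baseline, 0)
  n <- weights$n
  ctr <- map$centers[[env_index]]
  pre <- rep(seq_len(n), diff(W@p))
  post <- W@i + 1L
  # the SVF is a local field: only projections within the receptive-field
  # footprint of the rendering environment contribute (with several maps
  # stored, a cell's partners from the other map sit at arbitrary positions
  # in these coordinates and are not part of this environment's field)
  local_radius <- local_radius %||% (3 * map$sigma[env_index])
  off2 <- (ctr[post, 1] - ctr[pre, 1])^2 + (ctr[post, 2] - ctr[pre, 2])^2
  x[off2 > local_radius^2] <- 0
  wsum <- as.numeric(tapply(x, factor(pre, levels = seq_len(n)), sum))
  wsum[is.na(wsum)] <- 0
  dxs <- x * (ctr[post, 1] - ctr[pre, 1])
  dys <- x * (ctr[post, 2] - ctr[pre, 2])
  dx <- as.numeric(tapply(dxs, factor(pre, levels = seq_len(n)), sum))
  dy <- as.numeric(tapply(dys, factor(pre, levels = seq_len(n)), sum))
  dx[is.na(dx)] <- 0; dy[is.na(dy)] <- 0
  ok <- wsum > 0
  dx[ok] <- dx[ok] / wsum[ok]; dy[ok] <- dy[ok] / wsum[ok]
  dx[!ok] <- 0; dy[!ok] <- 0
  out <- data.frame(neuron_id = seq_len(n), x = ctr[, 1], y = ctr[, 2],
                    dx = dx, dy = dy)
  attr(out, "env_index") <- env_index
  attr(out, "outflow") <- wsum
  inflow <- as.numeric(tapply(x, factor(post, levels = seq_len(n)), sum))
  inflow[is.na(inflow)] <- 0
  attr(out, "inflow") <- inflow
  # rectified wavefront-induced deltas and raw local outgoing weight, both
  # used by the attractor localizer in svf_diagnostics()
  xd <- pmax(W@x - weights$baseline, 0)
  xd[off2 > local_radius^2] <- 0
  xr <- W@x
  xr[off2 > local_radius^2] <- 0
  dsum <- function(v, fac) {
    z <- as.numeric(tapply(v, fac, sum)); z[is.na(z)] <- 0; z
  }
  fpre <- factor(pre, levels = seq_len(n))
  fpost <- factor(post, levels = seq_len(n))
  attr(out, "outflow_delta") <- dsum(xd, fpre)
  attr(out, "inflow_delta") <- dsum(xd, fpost)
  attr(out, "outflow_raw") <- dsum(xr, fpre)
  attr(out, "outdegree") <- tabulate(pre, n)
  class(out) <- c("wn_svf", "data.frame")
  out
}

#' Vector-field diagnostics
#'
#' Quantifies how well a synaptic vector field encodes flow toward a target:
#'
#' * `alignment`: median cosine between each interior cell's vector and the
#'   oracle descent direction (the direction of the graph neighbour closest
#'   to the target); `NA` (flagged) for a zero field.
#' * `attractor`: the cell with the smallest mean outgoing weight -- the
#'   wavefront source weakens outgoing synapses around itself, so the summed
#'   outflow is minimal at the target.
#' * `mrl`: global mean resultant length of the vector directions.
#' * `local_mrl`: mean resultant length computed within spatial blocks of
#'   side `block` and averaged (weighted by block population). A coherent
#'   converging field scores near 1; spatially random directions score near
#'   `1/sqrt(block population)`.
#'
#' @param field a [compute_svf()] result
#' @param oracle optional [geodesic_distances()] output (fields `dist`,
#'   `descent`) for the alignment score
#' @param map the `wn_map` (for wall distances)
#' @param interior_min_sigma interior cells are at least this many sigma from
#'   the nearest wall
#' @param block block side for the local statistic; default `6 * sigma`
#' @return list of diagnostics
#' @export
svf_diagnostics <- function(field, oracle = NULL, map = NULL,
                            interior_min_sigma = 2, block = NULL) {
  v <- cbind(field$dx, field$dy)
  len <- vec_norm(v)
  nz <- len > 0
  out <- list()
  if (!any(nz)) {
    return(list(alignment = NA_real_, attractor = NA_integer_, mrl = 0,
                local_mrl = 0, zero_field = TRUE))
  }
  theta <- atan2(v[nz, 2], v[nz, 1])
  out$mrl <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  out$zero_field <- FALSE

  env_index <- attr(field, "env_index")
  if (!is.null(oracle)) {
    ok <- nz & is.finite(oracle$dist) & vec_norm(oracle$descent) > 0
    if (!is.null(map)) {
      wd <- env_wall_distance(map$envs[[env_index]], cbind(field$x, field$y))
      ok <- ok & wd >= interior_min_sigma * map$sigma[env_index]
    }
    cosang <- rowSums(v * oracle$descent) /
      (vec_norm(v) * vec_norm(oracle$descent))
    out$alignment <- stats::median(cosang[ok])
    out$n_interior <- sum(ok)
  }

  # Attractor localization: the wavefront source weakens its outgoing
  # synapses (raw outgoing weight minimal there) and strengthens its incoming
  # ones (delta outflow/total-flow ratio minimal there). Both scores are
  # smoothed over the field footprint and their depth-weighted minima
  # averaged; each alone is noisy at the grid-pitch scale.
  raw <- attr(field, "outflow_raw") / pmax(attr(field, "outdegree"), 1L)
  od <- attr(field, "outflow_delta"); idl <- attr(field, "inflow_delta")
  ratio <- ifelse(od + idl > 0, od / (od + idl), NA)
  if (!is.null(map)) {
    est <- function(s0) {
      r2 <- (2 * map$sigma[env_index])^2
      sc <- vapply(seq_along(s0), function(i) {
        nb <- (field$x - field$x[i])^2 + (field$y - field$y[i])^2 <= r2
        mean(s0[nb], na.rm = TRUE)
      }, 0)
      am <- which.min(sc)
      nb0 <- (field$x - field$x[am])^2 + (field$y - field$y[am])^2 <= r2
      dep <- (max(sc[nb0], na.rm = TRUE) - sc[nb0])^2
      dep[!is.finite(dep)] <- 0
      pos <- if (sum(dep) > 0)
        c(sum(field$x[nb0] * dep), sum(field$y[nb0] * dep)) / sum(dep)
      else c(field$x[am], field$y[am])
      list(am = am, pos = pos)
    }
    e1 <- est(raw); e2 <- est(ratio)
    out$attractor <- e1$am
    out$attractor_pos <- (e1$pos + e2$pos) / 2
  } else {
    out$attractor <- which.min(raw)
    out$attractor_pos <- c(field$x[out$attractor], field$y[out$attractor])
  }

  if (!is.null(map)) {
    out$local_mrl <- svf_local_mrl(field, map, block)
  }
  out
}

#' Neighbourhood coherence of field directions
#'
#' For every nonzero vector, the mean resultant length of the directions of
#' its nearest nonzero neighbours (up to eight, within a radius), averaged
#' over cells. A smooth converging field scores near one; spatially random
#' directions score near the resultant of a handful of uniform angles. Works
#' at any field density, including the sparse fields a partially covered
#' foreign map produces.
#'
#' @param field a `wn_svf`
#' @param map the `wn_map`
#' @param block neighbourhood radius (metres); default six sigma
#' @return mean local resultant length
#' @export
svf_local_mrl <- function(field, map, block = NULL) {
  env_index <- attr(field, "env_index")
  nz <- which(field$dx != 0 | field$dy != 0)
  if (length(nz) < 8) return(0)
  rad <- block %||% (6 * map$sigma[env_index])
  th <- atan2(field$dy[nz], field$dx[nz])
  xs <- field$x[nz]; ys <- field$y[nz]
  vals <- vapply(seq_along(nz), function(i) {
    d2 <- (xs - xs[i])^2 + (ys - ys[i])^2
    nb <- which(d2 <= rad^2)
    if (length(nb) < 5) return(NA_real_)
    nb <- nb[order(d2[nb])][seq_len(min(9, length(nb)))]
    sqrt(mean(cos(th[nb]))^2 + mean(sin(th[nb]))^2)
  }, 0)
  if (all(is.na(vals))) return(0)
  mean(vals, na.rm = TRUE)
}

#' Permutation null for the local direction coherence
#'
#' Re-assigns the field vectors to random cells (shuffling the neuron-to-
#' position pairing) and recomputes the block-local mean resultant length.
#' Used to test whether a field rendered in a foreign environment's
#' coordinates is directionally structured or random.
#'
#' @param field a `wn_svf`
#' @param map the `wn_map`
#' @param n_perm permutations
#' @param seed integer seed
#' @return vector of `local_mrl` values under the null
#' @export
svf_coherence_null <- function(field, map, n_perm = 99, seed = 1) {
  set.seed(derive_seed(seed, "svf_null"))
  vapply(seq_len(n_perm), function(p) {
    perm <- sample.int(nrow(field))
    f2 <- field
    f2$dx <- field$dx[perm]; f2$dy <- field$dy[perm]
    svf_local_mrl(f2, map)
  }, 0)
}

#' Export a vector field as CSV (neuron_id, x, y, dx, dy, env_id)
#' @param field a `wn_svf`
#' @param path output file
#' @param arrow_scale single normalization constant recorded in the header
#'   comment so fields from different environments share one arrow scale
#' @export
write_svf <- function(field, path, arrow_scale = 1) {
  df <- as.data.frame(field)
  df$env_id <- attr(field, "env_index")
  con <- file(path, "w")
  writeLines(sprintf("# arrow_scale=%g", arrow_scale), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(df)
}
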