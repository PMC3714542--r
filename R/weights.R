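#' Sparse synaptic weight matrix
#'
#' Weights are stored as a `dgCMatrix` with rows = postsynaptic and columns =
#' presynaptic, so `W[j, i]` is the strength of the synapse from neuron `i`
#' onto neuron `j`. The object carries the post-exploration baseline snapshot
#' (for [reset_synapses()]) and the transpose index map used by the online
#' plasticity kernel.
#'
#' @name wn_weights
NULL

make_weights <- function(pre, post, w0, n) {
  W <- Matrix::sparseMatrix(i = post, j = pre, x = rep(w0, length(pre)),
                            dims = c(n, n))
  weights_from_matrix(W)
}

weights_from_matrix <- function(W) {
  W <- methods::as(methods::as(W, "generalMatrix"), "CsparseMatrix")
  n <- nrow(W)
  stopifnot(ncol(W) == n)
  if (any(W@x < 0)) stop("negative synaptic weights")
  diag_idx <- which(rep(seq_len(n), diff(W@p)) == W@i + 1L)
  if (length(diag_idx) && any(W@x[diag_idx] != 0)) stop("nonzero diagonal (self-synapse)")
  Wt <- Matrix::t(W)
  colW <- rep(seq_len(n), diff(W@p))             # pre per entry of W
  keyW <- (W@i + 1L) + as.double(n) * (colW - 1L)
  colT <- rep(seq_len(n), diff(Wt@p))            # post per entry of Wt
  keyT <- colT + as.double(n) * Wt@i
  structure(
    list(W = W, n = n, baseline = W@x,
         Ti = Wt@i, Tp = Wt@p, Tmap = match(keyT, keyW) - 1L),
    class = "wn_weights")
}

#' Reset all synapses to the post-exploration baseline
#'
#' Whenever a new planning process is needed, the synapses return to the
#' baseline state; the synaptic vector field computed immediately afterwards
#' is identically zero (up to the geometric asymmetry of the baseline
#' neighbourhoods), and new wavefronts can be seeded from new targets.
#'
#' @param weights a `wn_weights`
#' @return the weights with `W@x` restored to the stored baseline
#' @export
reset_synapses <- function(weights) {
  if (is.null(weights$baseline)) stop("no baseline snapshot stored")
  weights$W@x <- weights$baseline
  weights
}

#' @export
print.wn_weights <- function(x, ...) {
  cat(sprintf("<wn_weights: %d neurons, %d synapses, mean w %.3f>\n",
              x$n, length(x$W@x), mean(x$W@x)))
  invisible(x)
}

#' Incoming neighbour sets
#' @param weights a `wn_weights`
#' @return list of presynaptic index vectors, one per postsynaptic cell
#' @export
incoming_sets <- function(weights) {
  W <- weights$W
  pre <- rep(seq_len(weights$n), diff(W@p))
  post <- W@i + 1L
  split(pre, factor(post, levels = seq_len(weights$n)))
}

#' Export weights as a coordinate-list text file (pre_id, post_id, weight)
#' @param weights a `wn_weights`
#' @param path output file
#' @export
write_weights <- function(weights, path) {
  W <- weights$W
  df <- data.frame(pre_id = rep(seq_len(weights$n), diff(W@p)),
                   post_id = W@i + 1L, weight = W@x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read weights from a coordinate-list file written by [write_weights()]
#' @param path input file
#' @param n number of neurons
#' @export
read_weights <- function(path, n) {
  df <- utils::read.csv(path)
  weights_from_matrix(Matrix::sparseMatrix(i = df$post_id, j = df$pre_id,
                                           x = df$weight, dims = c(n, n)))
}
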