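#' Configuration for the HOG-PSSM descriptor
#'
#' The normalized PSSM is treated as an L x 20 gray-scale image: the
#' 20-residue axis is cut into `n_cell_rows` contiguous blocks and the
#' sequence axis into `n_cell_cols` contiguous blocks, and each resulting
#' cell contributes a magnitude-weighted orientation histogram with `n_bins`
#' equal bins over (-pi, pi]. The output dimension is
#' `n_cell_rows * n_cell_cols * n_bins` — 4 x 4 x 16 = 256 by default.
#'
#' @param n_cell_rows cells along the 20-residue axis (default 4, blocks of 5).
#' @param n_cell_cols cells along the sequence axis (default 4).
#' @param n_bins orientation bins per cell (default 16).
#' @param epsilon per-cell L2 normalization floor; cells whose histogram norm
#'   does not exceed it stay all-zero.
#' @return A `hog_config` list.
#' @export
hog_config <- function(n_cell_rows = 4L, n_cell_cols = 4L, n_bins = 16L,
                       epsilon = 1e-12) {
  stopifnot(n_cell_rows >= 1, n_cell_cols >= 1, n_bins >= 1, epsilon >= 0,
            20 %% n_cell_rows == 0)
  structure(list(n_cell_rows = as.integer(n_cell_rows),
                 n_cell_cols = as.integer(n_cell_cols),
                 n_bins = as.integer(n_bins), epsilon = epsilon),
            class = "hog_config")
}

#' Gradient field of a normalized PSSM
#'
#' Central differences in the interior and one-sided differences with an
#' implicit zero beyond the boundary: along the residue axis (index i over
#' the 20 columns) the first column's gradient is `P[, 2] - 0` and the last
#' is `0 - P[, 19]`; the sequence axis (index j over the L rows) is treated
#' the same way. Magnitude is the Euclidean norm of the two components;
#' direction is the two-argument arctangent of (residue-axis, sequence-axis)
#' components, well-defined even where the sequence-axis component is zero.
#'
#' @param P numeric L x 20 matrix (normalized PSSM), L >= 2.
#' @return A `gradient_field` list with L x 20 matrices `Gx` (residue axis),
#'   `Gy` (sequence axis), `G` (magnitude) and `Theta` (direction, radians
#'   in (-pi, pi]).
#' @export
compute_gradients <- function(P) {
  P <- as.matrix(P)
  L <- nrow(P)
  if (L < 2L) stop("need at least 2 sequence positions")
  if (ncol(P) != 20L) stop("PSSM must have 20 columns")
  nc <- 20L
  Gx <- matrix(0, L, nc)
  Gx[, 1] <- P[, 2]
  Gx[, nc] <- -P[, nc - 1]
  if (nc > 2L) Gx[, 2:(nc - 1)] <- P[, 3:nc] - P[, 1:(nc - 2)]
  Gy <- matrix(0, L, nc)
  Gy[1, ] <- P[2, ]
  Gy[L, ] <- -P[L - 1, ]
  if (L > 2L) Gy[2:(L - 1), ] <- P[3:L, ] - P[1:(L - 2), ]
  G <- sqrt(Gx^2 + Gy^2)
  Theta <- atan2(Gx, Gy)
  structure(list(Gx = Gx, Gy = Gy, G = G, Theta = Theta),
            class = "gradient_field")
}

# Contiguous index blocks: n_blocks blocks of floor(n/n_blocks), the last
# absorbing any remainder.
split_blocks <- function(n, n_blocks) {
  base <- n %/% n_blocks
  starts <- (seq_len(n_blocks) - 1L) * base + 1L
  ends <- c(starts[-1L] - 1L, n)
  Map(seq, starts, ends)
}

#' Partition a gradient field into HOG cells
#'
#' The 20 residue columns split into `n_cell_rows` equal contiguous blocks;
#' the L sequence positions split into `n_cell_cols` contiguous blocks of
#' `floor(L / n_cell_cols)` with the final block absorbing the remainder.
#' Cells tile the matrix with no overlap and no omission.
#'
#' @param field a `gradient_field`.
#' @param cfg a [hog_config()].
#' @return List of cells in row-major order (residue blocks outer, sequence
#'   blocks inner); each cell holds sub-matrices `G`, `Theta` and its block
#'   indices `aa_block`, `seq_block`.
#' @export
partition_cells <- function(field, cfg = hog_config()) {
  L <- nrow(field$G)
  if (L < 2L * cfg$n_cell_cols) {
    stop("sequence too short for the cell grid: need L >= ",
         2L * cfg$n_cell_cols)
  }
  aa_blocks <- split_blocks(20L, cfg$n_cell_rows)
  seq_blocks <- split_blocks(L, cfg$n_cell_cols)
  cells <- list()
  for (m in seq_along(aa_blocks)) {
    for (n in seq_along(seq_blocks)) {
      cells[[length(cells) + 1L]] <-
        list(G = field$G[seq_blocks[[n]], aa_blocks[[m]], drop = FALSE],
             Theta = field$Theta[seq_blocks[[n]], aa_blocks[[m]], drop = FALSE],
             aa_block = m, seq_block = n)
    }
  }
  cells
}

# Magnitude-weighted orientation histogram over n_bins equal bins of
# (-pi, pi], L2-normalized unless the cell carries no gradient.
cell_histogram <- function(G, Theta, n_bins, epsilon) {
  width <- 2 * pi / n_bins
  bin <- floor((as.numeric(Theta) + pi) / width) + 1L
  bin[bin > n_bins] <- n_bins   # Theta == pi lands in the top bin
  bin[bin < 1L] <- 1L
  h <- vapply(seq_len(n_bins),
              function(b) sum(as.numeric(G)[bin == b]), numeric(1))
  nrm <- sqrt(sum(h^2))
  if (nrm > epsilon) h / nrm else rep(0, n_bins)
}

#' Encode a PSSM as a HOG descriptor
#'
#' Computes the gradient field of the normalized profile, partitions it into
#' cells, builds one magnitude-weighted orientation histogram per cell and
#' concatenates the per-cell histograms in row-major cell order. With the
#' default 4 x 4 grid and 16 bins the descriptor has 256 dimensions.
#'
#' @param x a `pssm` object or a normalized L x 20 matrix.
#' @param cfg a [hog_config()].
#' @return A 256-D (by default) [feature_vector()] tagged `"HOG-PSSM"`.
#' @export
encode_hog <- function(x, cfg = hog_config()) {
  if (inherits(x, "pssm")) {
    P <- x$normalized; id <- x$record_id
  } else {
    P <- as.matrix(x); id <- NA_character_
  }
  field <- compute_gradients(P)
  cells <- partition_cells(field, cfg)
  out <- unlist(lapply(cells, function(cl)
    cell_histogram(cl$G, cl$Theta, cfg$n_bins, cfg$epsilon)))
  blocks <- setNames(rep(cfg$n_bins, length(cells)),
                     vapply(cells, function(cl)
                       sprintf("cell_m%d_n%d", cl$aa_block, cl$seq_block), ""))
  feature_vector(out, "HOG-PSSM", id, blocks)
}
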