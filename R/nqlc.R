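#' Load the three-group physicochemical property tables
#'
#' Each of the seven properties (hydrophobicity, normalized van der Waals
#' volume, polarity, polarizability, charge, secondary-structure preference,
#' solvent accessibility) partitions the 20 canonical residues into three
#' disjoint groups labeled 1/2/3. The shipped defaults are the standard
#' Dubchak-style CTD tables; users may point `path` at their own TSV
#' (columns `property`, `residue`, `group`) to substitute other assignments.
#'
#' @param path TSV path; defaults to the table shipped with the package.
#' @return Named list (one entry per property, in a fixed order) of named
#'   integer vectors mapping residue to group.
#' @export
ctd_groupings <- function(path = system.file("extdata", "ctd_groups.tsv",
                                             package = "dpforest")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("property", "residue", "group") %in% names(tab)))
  order <- c("hydrophobicity", "vdw_volume", "polarity", "polarizability",
             "charge", "secondary_structure", "solvent_accessibility")
  props <- if (all(order %in% tab$property)) order else unique(tab$property)
  out <- lapply(props, function(p) {
    sub <- tab[tab$property == p, ]
    g <- setNames(as.integer(sub$group), sub$residue)
    if (!setequal(names(g), AA_CANONICAL) || anyDuplicated(names(g)))
      stop("property '", p, "' is not a partition of the 20 residues")
    if (!all(sort(unique(g)) == 1:3))
      stop("property '", p, "' must use groups 1, 2, 3")
    g
  })
  names(out) <- props
  out
}

#' Map a sequence onto three-group labels for one property
#'
#' @param sequence canonical amino-acid string.
#' @param grouping named integer vector residue -> group (one element of
#'   [ctd_groupings()]).
#' @return Integer vector of group labels (1/2/3), one per residue.
#' @export
map_to_groups <- function(sequence, grouping) {
  chars <- strsplit(sequence, "")[[1]]
  g <- grouping[chars]
  if (anyNA(g)) {
    stop("residue '", chars[which(is.na(g))[1]], "' absent from grouping table")
  }
  unname(g)
}

#' Composition, transition and distribution indices of a group string
#'
#' For a sequence mapped to labels 1/2/3:
#' * composition `C_g` is the fraction of residues in group g (3 values,
#'   summing to 1);
#' * transition `T_gh` is the count of adjacent unordered pairs \{g, h\},
#'   g != h, divided by the L - 1 adjacent pairs (pairs \{1,2\}, \{1,3\},
#'   \{2,3\});
#' * distribution gives, per group, the sequence positions (as percent of L)
#'   at which the first occurrence and 25%, 50%, 75%, 100% of that group's
#'   residues are reached (5 landmarks x 3 groups = 15 values); a group
#'   absent from the sequence contributes five zeros.
#'
#' @param groups integer vector of labels in \{1, 2, 3\}, length >= 2.
#' @return List with components `C` (3), `T` (3) and `D` (15).
#' @export
ctd_indices <- function(groups) {
  L <- length(groups)
  if (L < 2L) stop("need at least 2 residues")
  C <- vapply(1:3, function(g) sum(groups == g) / L, numeric(1))
  a <- groups[-L]; b <- groups[-1L]
  pairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  Tr <- vapply(1:3, function(k) {
    g <- pairs[k, 1]; h <- pairs[k, 2]
    sum((a == g & b == h) | (a == h & b == g)) / (L - 1L)
  }, numeric(1))
  D <- unlist(lapply(1:3, function(g) {
    pos <- which(groups == g)
    k <- length(pos)
    if (k == 0L) return(rep(0, 5))
    marks <- c(pos[1],
               pos[ceiling(0.25 * k)], pos[ceiling(0.50 * k)],
               pos[ceiling(0.75 * k)], pos[k])
    100 * marks / L
  }))
  list(C = C, T = Tr, D = D)
}

#' Encode a sequence as the 147-D CTD physicochemical descriptor
#'
#' For each of the seven three-group properties the sequence is mapped to
#' group labels and the composition (3), transition (3) and distribution
#' (15) indices are concatenated, giving 7 x 21 = 147 dimensions. Two
#' sequences whose residues fall in the same groups under all seven
#' properties receive identical vectors.
#'
#' @param record a `protein_record` (length >= 2).
#' @param groupings output of [ctd_groupings()].
#' @return A 147-D [feature_vector()] tagged `"NQLC"`.
#' @export
encode_nqlc <- function(record, groupings = ctd_groupings()) {
  stopifnot(inherits(record, "protein_record"))
  parts <- lapply(groupings, function(g) {
    idx <- ctd_indices(map_to_groups(record$sequence, g))
    c(idx$C, idx$T, idx$D)
  })
  blocks <- setNames(rep(21L, length(groupings)), names(groupings))
  feature_vector(unlist(parts), "NQLC", record$id, blocks)
}

#' Fit per-feature standardization parameters
#'
#' Computes the mean and sample standard deviation (denominator n - 1) of
#' every column. Constant columns (sd below `tol`) are flagged; applying the
#' parameters zeroes them with a warning. Fit on training data only and
#' re-apply to held-out data to avoid leakage.
#'
#' @param X numeric matrix, >= 2 rows.
#' @param tol threshold below which a column counts as constant.
#' @return A `standardization_params` list with `mean`, `sd` and `constant`.
#' @export
fit_standardizer <- function(X, tol = 1e-12) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples to fit standardization")
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  structure(list(mean = mu, sd = sdv, constant = sdv <= tol),
            class = "standardization_params")
}

#' Apply z-score standardization
#'
#' `y = (x - mean) / sd` per feature, using parameters fitted by
#' [fit_standardizer()]. Columns flagged constant are set to 0.
#'
#' @param X numeric matrix with the same columns as the fitted matrix.
#' @param params a `standardization_params` object.
#' @return Standardized matrix of the same shape.
#' @export
apply_standardizer <- function(X, params) {
  X <- as.matrix(X)
  if (ncol(X) != length(params$mean)) stop("column count mismatch")
  if (any(params$constant)) {
    warning(sum(params$constant), " constant feature(s) set to 0")
  }
  sdv <- ifelse(params$constant, 1, params$sd)
  Y <- sweep(sweep(X, 2, params$mean), 2, sdv, "/")
  Y[, params$constant] <- 0
  Y
}

#' Standardize a feature matrix (fit + apply in one step)
#'
#' Convenience wrapper: fits on `X` and returns the transformed matrix with
#' the parameters attached as attribute `"params"`. An optional min-max
#' `[0, 1]` mode is provided for users who prefer range scaling.
#'
#' @param X numeric matrix.
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return Transformed matrix with attribute `params`.
#' @export
standardize <- function(X, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (method == "zscore") {
    params <- fit_standardizer(X)
    Y <- apply_standardizer(X, params)
  } else {
    lo <- apply(X, 2, min); hi <- apply(X, 2, max)
    rng <- ifelse(hi - lo <= 1e-12, 1, hi - lo)
    Y <- sweep(sweep(X, 2, lo), 2, rng, "/")
    Y[, hi - lo <= 1e-12] <- 0
    params <- list(min = lo, max = hi)
  }
  attr(Y, "params") <- params
  Y
}
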