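#' Construct a tagged, schema-carrying feature vector
#'
#' All encoders return their output through this constructor so downstream
#' code can verify dimensions and recover block provenance after fusion.
#'
#' @param values numeric vector.
#' @param encoder_tag one of `"CPSR"`, `"NQLC"`, `"HOG-PSSM"`, `"Hybrid1"`,
#'   `"Hybrid2"`, `"Hybrid3"`.
#' @param record_id identifier of the encoded sequence.
#' @param blocks named integer vector of block lengths, in order; must sum to
#'   `length(values)`.
#' @return A numeric vector of class `feature_vector` with attributes
#'   `encoder_tag`, `record_id` and `schema` (a data.frame of block name,
#'   offset and length).
#' @export
feature_vector <- function(values, encoder_tag, record_id, blocks) {
  stopifnot(is.numeric(values), sum(blocks) == length(values))
  schema <- data.frame(block = names(blocks),
                       offset = cumsum(c(0L, unname(blocks)))[seq_along(blocks)],
                       length = unname(blocks), stringsAsFactors = FALSE)
  structure(as.numeric(values), class = "feature_vector",
            encoder_tag = encoder_tag, record_id = record_id, schema = schema)
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s  %s  %d-D  blocks: %s\n",
              attr(x, "encoder_tag"), attr(x, "record_id"), length(x),
              paste(attr(x, "schema")$block, collapse = ", ")))
  invisible(x)
}

#' Extract one schema block from a feature vector or matrix
#'
#' @param x a `feature_vector`, or a feature matrix with a `schema` attribute.
#' @param block block name as recorded in the schema.
#' @return The sub-vector (or sub-matrix column range) of that block.
#' @export
feature_block <- function(x, block) {
  schema <- attr(x, "schema")
  row <- schema[schema$block == block, ]
  if (nrow(row) != 1L) stop("unknown block: ", block)
  idx <- seq(row$offset + 1L, row$offset + row$length)
  if (is.matrix(x)) x[, idx, drop = FALSE] else as.numeric(x)[idx]
}
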