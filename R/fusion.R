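#' Serial fusion of feature vectors
#'
#' Concatenates encoder outputs for one record in the given order, recording
#' block provenance in the schema. The canonical hybrids are
#' Hybrid1 = CPSR + HOG-PSSM (327-D), Hybrid2 = NQLC + HOG-PSSM (403-D) and
#' Hybrid3 = CPSR + NQLC + HOG-PSSM (474-D).
#'
#' @param parts ordered list of [feature_vector()]s from the same record.
#' @param tag optional tag for the fused vector; inferred from the part tags
#'   when omitted.
#' @return A fused `feature_vector` whose schema blocks are named
#'   `<encoder_tag>.<block>`.
#' @export
hybridize <- function(parts, tag = NULL) {
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, inherits, TRUE, "feature_vector")))
  ids <- unique(vapply(parts, attr, "", "record_id"))
  ids <- ids[!is.na(ids)]
  if (length(ids) > 1L)
    stop("parts come from different records: ", paste(ids, collapse = ", "))
  tags <- vapply(parts, attr, "", "encoder_tag")
  if (is.null(tag)) {
    key <- paste(sort(tags), collapse = "+")
    tag <- switch(key,
                  "CPSR+HOG-PSSM" = "Hybrid1",
                  "HOG-PSSM+NQLC" = "Hybrid2",
                  "CPSR+HOG-PSSM+NQLC" = "Hybrid3",
                  paste(tags, collapse = "+"))
  }
  blocks <- unlist(lapply(parts, function(p) {
    s <- attr(p, "schema")
    setNames(s$length, paste(attr(p, "encoder_tag"), s$block, sep = "."))
  }))
  feature_vector(unlist(lapply(parts, as.numeric)), tag,
                 if (length(ids)) ids else NA_character_, blocks)
}

#' Expected dimension of each encoder tag
#' @param tag encoder tag string.
#' @return Integer dimension under default configurations.
#' @export
encoder_dimension <- function(tag) {
  switch(tag,
         "CPSR" = 71L, "NQLC" = 147L, "HOG-PSSM" = 256L,
         "Hybrid1" = 327L, "Hybrid2" = 403L, "Hybrid3" = 474L,
         stop("unknown encoder tag: ", tag))
}

#' Encode one record under a named encoder
#'
#' @param record a `protein_record`.
#' @param encoder one of `"cpsr"`, `"nqlc"`, `"hog"`, `"hybrid1"`,
#'   `"hybrid2"`, `"hybrid3"`.
#' @param pssm the record's [pssm_matrix()] (required for encoders that use
#'   the evolutionary profile).
#' @param hog_cfg a [hog_config()].
#' @param groupings CTD groupings, see [ctd_groupings()].
#' @param tables CPSR tables, see [cpsr_tables()].
#' @return A [feature_vector()].
#' @export
encode_record <- function(record,
                          encoder = c("hybrid3", "cpsr", "nqlc", "hog",
                                      "hybrid1", "hybrid2"),
                          pssm = NULL, hog_cfg = hog_config(),
                          groupings = ctd_groupings(),
                          tables = cpsr_tables()) {
  encoder <- match.arg(encoder)
  needs_pssm <- encoder %in% c("hog", "hybrid1", "hybrid2", "hybrid3")
  if (needs_pssm && is.null(pssm))
    stop("encoder '", encoder, "' requires a PSSM for record ", record$id)
  switch(encoder,
         cpsr = encode_cpsr(record, tables),
         nqlc = encode_nqlc(record, groupings),
         hog = encode_hog(pssm, hog_cfg),
         hybrid1 = hybridize(list(encode_cpsr(record, tables),
                                  encode_hog(pssm, hog_cfg))),
         hybrid2 = hybridize(list(encode_nqlc(record, groupings),
                                  encode_hog(pssm, hog_cfg))),
         hybrid3 = hybridize(list(encode_cpsr(record, tables),
                                  encode_nqlc(record, groupings),
                                  encode_hog(pssm, hog_cfg))))
}

#' Assemble the feature matrix of a labeled dataset
#'
#' Encodes every record in dataset order under a common encoder and stacks
#' the vectors into an n x d matrix carrying the shared schema, the encoder
#' tag and the aligned label vector as attributes. Optionally standardizes:
#' `standardize_mode = "fit"` fits z-score parameters on this matrix
#' (training mode, parameters attached as attribute `"standardization"`);
#' passing a `standardization_params` object applies stored parameters
#' (inference mode, no refitting).
#'
#' @param dataset a `labeled_dataset`.
#' @param pssms named list of `pssm` objects keyed by record id (required
#'   for PSSM-based encoders).
#' @param encoder encoder name, see [encode_record()].
#' @param standardize_mode `"none"` (default), `"fit"`, or a
#'   `standardization_params` object.
#' @param ... passed to [encode_record()].
#' @return Numeric matrix with attributes `schema`, `encoder_tag`, `labels`
#'   and (when standardized) `standardization`.
#' @export
build_feature_matrix <- function(dataset, pssms = NULL,
                                 encoder = "hybrid3",
                                 standardize_mode = "none", ...) {
  ids <- vapply(dataset$records, `[[`, "", "id")
  needs_pssm <- encoder %in% c("hog", "hybrid1", "hybrid2", "hybrid3")
  if (needs_pssm) {
    missing <- setdiff(ids, names(pssms))
    if (length(missing))
      stop("missing PSSM for record(s): ", paste(missing, collapse = ", "))
  }
  dots <- list(...)
  # load shared tables once, not per record
  if (is.null(dots$groupings)) dots$groupings <- ctd_groupings()
  if (is.null(dots$tables)) dots$tables <- cpsr_tables()
  rows <- lapply(dataset$records, function(r) {
    do.call(encode_record,
            c(list(record = r, encoder = encoder,
                   pssm = if (needs_pssm) pssms[[r$id]]), dots))
  })
  dims <- vapply(rows, length, integer(1))
  if (length(unique(dims)) != 1L)
    stop("row dimension mismatch: ", paste(unique(dims), collapse = ", "))
  X <- do.call(rbind, lapply(rows, as.numeric))
  rownames(X) <- ids
  schema <- attr(rows[[1]], "schema")
  colnames(X) <- unlist(lapply(seq_len(nrow(schema)), function(k)
    paste(schema$block[k], seq_len(schema$length[k]), sep = ".")))
  if (inherits(standardize_mode, "standardization_params")) {
    X <- apply_standardizer(X, standardize_mode)
    attr(X, "standardization") <- standardize_mode
  } else if (identical(standardize_mode, "fit")) {
    params <- fit_standardizer(X)
    X <- suppressWarnings(apply_standardizer(X, params))
    attr(X, "standardization") <- params
  } else if (!identical(standardize_mode, "none")) {
    stop("standardize_mode must be 'none', 'fit' or stored parameters")
  }
  attr(X, "schema") <- schema
  attr(X, "encoder_tag") <- attr(rows[[1]], "encoder_tag")
  attr(X, "labels") <- dataset_labels(dataset)
  X
}
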