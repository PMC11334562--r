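#' Construct a PSSM object
#'
#' An L x 20 evolutionary profile. `raw` holds the PSI-BLAST log-odds scores;
#' `normalized` holds the element-wise logistic transform
#' `f(a) = 1 / (1 + exp(-a))`, which maps every score into (0, 1).
#' Columns follow [PSSM_COLUMNS] (PSI-BLAST order).
#'
#' @param record_id identifier of the underlying sequence.
#' @param raw numeric L x 20 matrix of log-odds scores.
#' @param residues optional character vector of length L (the per-row
#'   residues of the query sequence), kept for cross-checking.
#' @return An object of class `pssm` with fields `record_id`, `raw`,
#'   `normalized`, `residues` and `column_order`.
#' @export
pssm_matrix <- function(record_id, raw, residues = NULL) {
  raw <- as.matrix(raw)
  if (ncol(raw) != 20L) stop("PSSM must have 20 columns")
  if (!all(is.finite(raw))) stop("PSSM contains non-finite entries")
  if (!is.null(residues) && length(residues) != nrow(raw))
    stop("residue annotation length differs from row count")
  colnames(raw) <- PSSM_COLUMNS
  structure(list(record_id = record_id, raw = raw,
                 normalized = normalize_pssm(raw),
                 residues = residues, column_order = PSSM_COLUMNS),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> %s  %d x 20\n", x$record_id, nrow(x$raw)))
  invisible(x)
}

#' Logistic normalization of PSSM scores
#'
#' Applies `f(a) = 1 / (1 + exp(-a))` element-wise. The transform is strictly
#' increasing and maps any finite score into the open interval (0, 1), so
#' profiles from sequences of very different conservation become comparable.
#'
#' @param raw numeric matrix (or vector) of finite log-odds scores.
#' @return Matrix of the same shape with entries in (0, 1).
#' @examples
#' normalize_pssm(matrix(c(0, 1, -1), 1))  # 0.5, 0.731..., 0.268...
#' @export
normalize_pssm <- function(raw) {
  if (!all(is.finite(raw))) stop("non-finite PSSM entry")
  1 / (1 + exp(-raw))
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the `-out_ascii_pssm` dialect: header lines, one row per sequence
#' position carrying the position, the query residue and 20 log-odds columns
#' (followed, in files produced by PSI-BLAST, by 20 weighted-percentage
#' columns and per-row statistics), and trailing K/Lambda statistics. Only
#' the log-odds block is retained: it is what the logistic normalization
#' targets.
#'
#' @param path path to the ASCII PSSM file.
#' @param sequence optional sequence string; when given, the file's residue
#'   column is validated against it.
#' @param record_id identifier for the returned object; defaults to the file
#'   name without extension.
#' @return A [pssm_matrix()] object.
#' @export
parse_ascii_pssm <- function(path, sequence = NULL, record_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(record_id))
    record_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  rows <- list(); residues <- character(0); expected_pos <- 1L
  for (ln in seq_along(lines)) {
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 2L) next
    if (!grepl("^[0-9]+$", tok[1]) || !grepl("^[A-Za-z]$", tok[2])) next
    if (as.integer(tok[1]) != expected_pos) {
      stop("line ", ln, ": position ", tok[1], " out of order (expected ",
           expected_pos, ")")
    }
    num <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (anyNA(num) || length(num) < 40L) {
      stop("line ", ln, ": expected 40 numeric fields after position and ",
           "residue, found ", sum(!is.na(num)))
    }
    rows[[expected_pos]] <- num[1:20]
    residues[expected_pos] <- toupper(tok[2])
    expected_pos <- expected_pos + 1L
  }
  if (length(rows) == 0L) stop("no PSSM rows found in ", path,
                               " (truncated or not an ASCII PSSM?)")
  raw <- do.call(rbind, rows)
  if (!is.null(sequence)) {
    want <- strsplit(toupper(sequence), "")[[1]]
    if (length(want) != length(residues) || any(want != residues)) {
      bad <- if (length(want) == length(residues)) which(want != residues)[1]
             else NA_integer_
      stop("PSSM residue column disagrees with supplied sequence",
           if (!is.na(bad)) paste0(" at position ", bad) else
             " (length mismatch)")
    }
  }
  pssm_matrix(record_id, raw, residues = residues)
}

#' Write a PSSM as a PSI-BLAST-style ASCII file
#'
#' Emits a minimal header, the per-row numeric table (log-odds block plus a
#' zero-filled percentage block so the layout matches the PSI-BLAST dialect),
#' and a short footer. `parse_ascii_pssm(write_ascii_pssm(p))` recovers the
#' raw matrix exactly for integer scores.
#'
#' @param pssm a `pssm` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ascii_pssm <- function(pssm, path) {
  raw <- pssm$raw
  res <- pssm$residues
  if (is.null(res)) res <- rep("X", nrow(raw))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
               paste0("           ",
                      paste(sprintf("%3s", c(PSSM_COLUMNS, PSSM_COLUMNS)),
                            collapse = " "))), con)
  for (j in seq_len(nrow(raw))) {
    writeLines(paste0(sprintf("%5d %s ", j, res[j]),
                      paste(sprintf("%3.0f", raw[j, ]), collapse = " "), " ",
                      paste(sprintf("%3d", rep(0L, 20)), collapse = " ")),
               con)
  }
  writeLines(c("", "                      K         Lambda"), con)
  invisible(path)
}

#' Synthesize a sequence-consistent PSSM
#'
#' Stands in for running PSI-BLAST against a reference database. Row `j`
#' receives an elevated score `+sharpness` in the column of the residue at
#' position `j`, plus zero-mean integer Gaussian noise, so the profile's
#' dominant signal reflects the sequence itself — the property real profiles
#' of well-conserved sequences share. Deterministic under `seed`.
#'
#' @param record a `protein_record`.
#' @param sharpness non-negative score added on the diagonal-residue column.
#' @param noise_sd standard deviation of the rounded Gaussian noise; 0
#'   disables noise.
#' @param seed integer seed.
#' @return A [pssm_matrix()] object.
#' @export
synthesize_pssm <- function(record, sharpness = 8, noise_sd = 1, seed = 1L) {
  stopifnot(inherits(record, "protein_record"), sharpness >= 0, noise_sd >= 0)
  L <- record$length
  chars <- strsplit(record$sequence, "")[[1]]
  raw <- with_local_seed(seed, {
    m <- if (noise_sd > 0) matrix(round(rnorm(L * 20, 0, noise_sd)), L, 20)
         else matrix(0, L, 20)
    idx <- match(chars, PSSM_COLUMNS)
    m[cbind(seq_len(L), idx)] <- m[cbind(seq_len(L), idx)] + sharpness
    m
  })
  pssm_matrix(record$id, raw, residues = chars)
}

#' Synthesize PSSMs for every record of a dataset
#'
#' @param dataset a `labeled_dataset`.
#' @param sharpness,noise_sd passed to [synthesize_pssm()].
#' @param seed master seed; each record gets a sub-seed via [derive_seed()].
#' @return Named list of `pssm` objects, keyed by record id.
#' @export
synthesize_pssm_set <- function(dataset, sharpness = 8, noise_sd = 1,
                                seed = 1L) {
  out <- lapply(seq_along(dataset$records), function(k) {
    synthesize_pssm(dataset$records[[k]], sharpness, noise_sd,
                    seed = derive_seed(seed, estimator = k))
  })
  names(out) <- vapply(dataset$records, `[[`, "", "id")
  out
}
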