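#' Construct a validated protein record
#'
#' A protein record couples an identifier with an amino-acid sequence over
#' the 20 canonical residues and an optional binary druggability label
#' (1 = druggable, 0 = non-druggable).
#'
#' @param id character identifier.
#' @param sequence character scalar over `ACDEFGHIKLMNPQRSTVWY`.
#' @param label optional label, `NA`, 0 or 1.
#' @return An object of class `protein_record` with fields `id`, `sequence`,
#'   `length` and `label`.
#' @examples
#' protein_record("p1", "MKVACDE")
#' @export
protein_record <- function(id, sequence, label = NA) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("record '", id, "': empty sequence")
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% AA_CANONICAL)
  if (length(bad)) {
    stop("record '", id, "': non-canonical residue '", chars[bad[1]],
         "' at position ", bad[1])
  }
  if (!is.na(label) && !label %in% c(0, 1)) stop("label must be NA, 0 or 1")
  structure(list(id = id, sequence = sequence, length = nchar(sequence),
                 label = if (is.na(label)) NA_integer_ else as.integer(label)),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s  L=%d  label=%s\n", x$id, x$length,
              ifelse(is.na(x$label), "NA", x$label)))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Parses a (multi-line) FASTA file into a list of [protein_record()]s.
#' By default the reader is strict: any residue outside the 20 canonical
#' amino acids (including X, B, Z, U, O) is an error naming the record and
#' position, because every downstream property table is defined only for the
#' canonical alphabet. With `sanitize = TRUE` sequences are uppercased and
#' non-canonical letters removed with a warning.
#'
#' @param path path to a FASTA file.
#' @param sanitize logical; repair non-canonical residues instead of erroring.
#' @return A list of `protein_record` objects in file order.
#' @export
read_fasta <- function(path, sanitize = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  records <- vector("list", length(set))
  for (k in seq_along(seqs)) {
    s <- seqs[[k]]
    if (!nzchar(s)) stop("record '", ids[k], "': empty sequence")
    if (sanitize) {
      chars <- strsplit(s, "")[[1]]
      keep <- chars %in% AA_CANONICAL
      if (!all(keep)) {
        warning("record '", ids[k], "': removed ", sum(!keep),
                " non-canonical residue(s)")
        s <- paste(chars[keep], collapse = "")
        if (!nzchar(s)) stop("record '", ids[k],
                             "': no canonical residues left after sanitizing")
      }
    }
    records[[k]] <- protein_record(ids[k], s)
  }
  records
}

#' Write protein records to a FASTA file
#'
#' @param records list of `protein_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(vapply(records, `[[`, "", "sequence"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Bundle labeled records into a dataset
#'
#' @param records list of `protein_record`, all labeled.
#' @return A `labeled_dataset` with fields `records`, `n_pos`, `n_neg`.
#' @export
labeled_dataset <- function(records) {
  labels <- vapply(records, `[[`, integer(1), "label")
  if (anyNA(labels)) stop("all records must carry a 0/1 label")
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(records = records,
                 n_pos = sum(labels == 1L), n_neg = sum(labels == 0L)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d records (%d druggable, %d non-druggable)\n",
              length(x$records), x$n_pos, x$n_neg))
  invisible(x)
}

#' Labels of a dataset, in record order
#' @param dataset a `labeled_dataset`.
#' @return Integer vector of 0/1 labels.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$records, `[[`, integer(1), "label")
}

#' Load a two-class dataset from paired FASTA files
#'
#' Positives (druggable) are labeled 1, negatives 0, matching the convention
#' that true positives are correctly predicted druggable proteins.
#'
#' @param pos_path FASTA of druggable sequences.
#' @param neg_path FASTA of non-druggable sequences.
#' @param sanitize passed to [read_fasta()].
#' @return A `labeled_dataset`.
#' @export
load_labeled_dataset <- function(pos_path, neg_path, sanitize = FALSE) {
  pos <- read_fasta(pos_path, sanitize = sanitize)
  neg <- read_fasta(neg_path, sanitize = sanitize)
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be non-empty")
  pos <- lapply(pos, function(r) { r$label <- 1L; r })
  neg <- lapply(neg, function(r) { r$label <- 0L; r })
  labeled_dataset(c(pos, neg))
}

#' Default residue profiles for the synthetic two-class generator
#'
#' The positive (druggable-like) class is enriched about two-fold in
#' hydrophobic residues (C, F, I, L, M, V, W, Y), mimicking the elevated
#' hydrophobic content of drug-binding pockets; the negative class is uniform
#' over the 20 canonical residues. Both profiles sum to 1.
#'
#' @return A list with components `pos` and `neg`, each a named
#'   20-probability vector in [AA_CANONICAL] order.
#' @export
default_class_profiles <- function() {
  hydrophobic <- c("C", "F", "I", "L", "M", "V", "W", "Y")
  w <- setNames(rep(1, 20), AA_CANONICAL)
  w[hydrophobic] <- 2
  list(pos = w / sum(w),
       neg = setNames(rep(1 / 20, 20), AA_CANONICAL))
}

#' Generate a synthetic two-class sequence dataset
#'
#' Draws residues i.i.d. from a per-class residue probability profile and
#' lengths uniformly from `length_range`. Deterministic for a fixed seed.
#' Serves as the test-bed stand-in for curated druggable / non-druggable
#' sequence collections.
#'
#' @param n_pos,n_neg number of positive / negative sequences.
#' @param length_range integer `c(min, max)` sequence lengths; `min >= 8`
#'   (shortest length every encoder accepts).
#' @param class_profiles list with `pos` and `neg` 20-probability vectors in
#'   [AA_CANONICAL] order; defaults to [default_class_profiles()].
#' @param seed integer seed.
#' @return A `labeled_dataset` (or an empty one when both counts are 0).
#' @export
generate_synthetic_dataset <- function(n_pos, n_neg,
                                       length_range = c(50L, 300L),
                                       class_profiles = default_class_profiles(),
                                       seed = 1L) {
  stopifnot(n_pos >= 0, n_neg >= 0, length(length_range) == 2L)
  if (length_range[1] < 8) stop("minimum synthetic length is 8")
  if (length_range[2] < length_range[1]) stop("invalid length range")
  for (cls in c("pos", "neg")) {
    p <- class_profiles[[cls]]
    if (length(p) != 20L || abs(sum(p) - 1) > 1e-9)
      stop("class profile '", cls, "' must be 20 probabilities summing to 1")
  }
  if (n_pos + n_neg == 0L) {
    return(structure(list(records = list(), n_pos = 0L, n_neg = 0L),
                     class = "labeled_dataset"))
  }
  with_local_seed(seed, {
    make <- function(n, prefix, profile, label) {
      lapply(seq_len(n), function(k) {
        L <- sample(seq(length_range[1], length_range[2]), 1L)
        s <- paste(sample(AA_CANONICAL, L, replace = TRUE, prob = profile),
                   collapse = "")
        protein_record(sprintf("%s%04d", prefix, k), s, label)
      })
    }
    recs <- c(make(n_pos, "pos", class_profiles$pos, 1L),
              make(n_neg, "neg", class_profiles$neg, 0L))
    labeled_dataset(recs)
  })
}
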