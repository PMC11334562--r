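#' Load the residue property tables for the composite descriptor
#'
#' Three residue partitions and three per-residue numeric scales:
#' * `exchange`: six Dayhoff-derived exchange groups \{HRK\}, \{DENQ\},
#'   \{C\}, \{STPAG\}, \{MILV\}, \{FYW\} reflecting evolutionary
#'   substitutability;
#' * `electron`: six electron donor/acceptor classes;
#' * `r_group`: the five standard side-chain families (nonpolar aliphatic,
#'   aromatic, polar uncharged, positively charged, negatively charged);
#' * `scales`: per-residue rigidity, flexibility and irreplaceability values.
#'   Flexibility is the Bhaskaran-Ponnuswamy average flexibility index; the
#'   rigidity and irreplaceability columns are package-default synthetic
#'   scales (file `cpsr_scales_synthetic.tsv`) that order residues by
#'   side-chain conformational stiffness and by evolutionary
#'   substitution tolerance respectively — replace them via `scales_path`
#'   to use a preferred literature scale.
#'
#' @param groups_path TSV (`scheme`, `residue`, `class`) of the partitions.
#' @param scales_path TSV (`residue`, `rigidity`, `flexibility`,
#'   `irreplaceability`).
#' @return A `cpsr_tables` list with `exchange`, `electron`, `r_group`
#'   (named character vectors residue -> class; class levels stored as
#'   attribute `"levels"`) and `scales` (data.frame keyed by residue).
#' @export
cpsr_tables <- function(groups_path = system.file("extdata",
                                                  "cpsr_groups.tsv",
                                                  package = "dpforest"),
                        scales_path = system.file("extdata",
                                                  "cpsr_scales_synthetic.tsv",
                                                  package = "dpforest")) {
  grp <- read.delim(groups_path, stringsAsFactors = FALSE)
  stopifnot(all(c("scheme", "residue", "class") %in% names(grp)))
  pick <- function(scheme, n_classes) {
    sub <- grp[grp$scheme == scheme, ]
    m <- setNames(sub$class, sub$residue)
    if (!setequal(names(m), AA_CANONICAL) || anyDuplicated(names(m)))
      stop("scheme '", scheme, "' is not a partition of the 20 residues")
    lev <- unique(sub$class)
    if (length(lev) != n_classes)
      stop("scheme '", scheme, "' must have ", n_classes, " classes")
    attr(m, "levels") <- lev
    m
  }
  sc <- read.delim(scales_path, stringsAsFactors = FALSE)
  stopifnot(all(c("residue", "rigidity", "flexibility", "irreplaceability")
                %in% names(sc)))
  if (!setequal(sc$residue, AA_CANONICAL))
    stop("scales must cover exactly the 20 canonical residues")
  rownames(sc) <- sc$residue
  structure(list(exchange = pick("exchange", 6L),
                 electron = pick("electron", 6L),
                 r_group = pick("r_group", 5L),
                 scales = sc),
            class = "cpsr_tables")
}

#' Amino-acid composition
#'
#' Frequency of each of the 20 canonical residues (count / L), in
#' [AA_CANONICAL] order. Sums to 1.
#'
#' @param record a `protein_record`.
#' @return Named numeric vector of length 20.
#' @export
aac <- function(record) {
  chars <- strsplit(record$sequence, "")[[1]]
  counts <- table(factor(chars, levels = AA_CANONICAL))
  setNames(as.numeric(counts) / record$length, AA_CANONICAL)
}

#' Ordered bigram frequencies over the 6-letter exchange alphabet
#'
#' The sequence is mapped to its 6-class exchange-group string; all L - 1
#' overlapping ordered bigrams are counted and divided by L - 1, giving
#' 36 frequencies in row-major class order (e1e1, e1e2, ..., e6e6) that sum
#' to 1.
#'
#' @param record a `protein_record` with L >= 2.
#' @param tables a [cpsr_tables()] object.
#' @return Named numeric vector of length 36.
#' @export
exchange_bigram_frequencies <- function(record, tables = cpsr_tables()) {
  if (record$length < 2L) stop("need at least 2 residues for bigrams")
  lev <- attr(tables$exchange, "levels")
  g <- unname(tables$exchange[strsplit(record$sequence, "")[[1]]])
  first <- factor(g[-length(g)], levels = lev)
  second <- factor(g[-1L], levels = lev)
  counts <- table(first, second)
  freq <- as.numeric(t(counts)) / (record$length - 1L)
  # t() so the vector runs e1e1, e1e2, ... (first index outer)
  names(freq) <- as.vector(t(outer(lev, lev, function(a, b) paste0(a, ".", b))))
  freq
}

# Per-class frequency over a residue partition, in stored class order.
class_frequencies <- function(record, mapping) {
  lev <- attr(mapping, "levels")
  g <- unname(mapping[strsplit(record$sequence, "")[[1]]])
  counts <- table(factor(g, levels = lev))
  setNames(as.numeric(counts) / record$length, lev)
}

#' Length-normalized physicochemical scalar indices
#'
#' Each index is the sum of a per-residue scale over the sequence divided by
#' its length — i.e. the mean scale value. Satisfies the weighted-mean
#' identity under concatenation.
#'
#' @param record a `protein_record`.
#' @param tables a [cpsr_tables()] object.
#' @return Named numeric vector `c(rigidity, flexibility, irreplaceability)`.
#' @export
scalar_indices <- function(record, tables = cpsr_tables()) {
  chars <- strsplit(record$sequence, "")[[1]]
  sc <- tables$scales[chars, ]
  c(rigidity = sum(sc$rigidity) / record$length,
    flexibility = sum(sc$flexibility) / record$length,
    irreplaceability = sum(sc$irreplaceability) / record$length)
}

#' Encode a sequence as the 71-D composite physicochemical descriptor
#'
#' Concatenates, in order: amino-acid composition (20), sequence length (1),
#' ordered exchange-group bigram frequencies (36), electron-group
#' frequencies (6), rigidity (1), flexibility (1), irreplaceability (1) and
#' R-group frequencies (5). Group blocks are length-normalized frequencies
#' so features stay comparable across sequence lengths (`count_mode =
#' "count"` switches the electron and R-group blocks to raw counts). The
#' length feature is left on its natural scale; standardize the assembled
#' matrix for learners that need it.
#'
#' @param record a `protein_record` with L >= 2.
#' @param tables a [cpsr_tables()] object.
#' @param count_mode `"frequency"` (default) or `"count"`.
#' @return A 71-D [feature_vector()] tagged `"CPSR"`.
#' @export
encode_cpsr <- function(record, tables = cpsr_tables(),
                        count_mode = c("frequency", "count")) {
  count_mode <- match.arg(count_mode)
  stopifnot(inherits(record, "protein_record"))
  if (record$length < 2L) stop("need at least 2 residues")
  electron <- class_frequencies(record, tables$electron)
  rgrp <- class_frequencies(record, tables$r_group)
  if (count_mode == "count") {
    electron <- electron * record$length
    rgrp <- rgrp * record$length
  }
  values <- c(aac(record), length = record$length,
              exchange_bigram_frequencies(record, tables),
              electron, scalar_indices(record, tables), rgrp)
  blocks <- c(aac = 20L, length = 1L, exchange_bigrams = 36L,
              electron = 6L, rigidity = 1L, flexibility = 1L,
              irreplaceability = 1L, r_group = 5L)
  feature_vector(values, "CPSR", record$id, blocks)
}
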