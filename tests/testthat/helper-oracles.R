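# Independent brute-force reimplementations used as oracles. Deliberately
# naive (scalar loops, no shared code with the package internals).

naive_gradients <- function(P) {
  L <- nrow(P); nc <- ncol(P)
  Gx <- matrix(0, L, nc); Gy <- matrix(0, L, nc)
  for (j in seq_len(L)) {
    for (i in seq_len(nc)) {
      Gx[j, i] <- if (i == 1) P[j, 2] else if (i == nc) -P[j, nc - 1]
                  else P[j, i + 1] - P[j, i - 1]
      Gy[j, i] <- if (j == 1) P[2, i] else if (j == L) -P[L - 1, i]
                  else P[j + 1, i] - P[j - 1, i]
    }
  }
  list(Gx = Gx, Gy = Gy, G = sqrt(Gx^2 + Gy^2), Theta = atan2(Gx, Gy))
}

naive_hog <- function(P, n_cell_rows = 4, n_cell_cols = 4, n_bins = 16,
                      epsilon = 1e-12) {
  f <- naive_gradients(P)
  L <- nrow(P)
  aa_w <- 20 %/% n_cell_rows
  seq_w <- L %/% n_cell_cols
  out <- c()
  for (m in seq_len(n_cell_rows)) {
    cols <- ((m - 1) * aa_w + 1):(m * aa_w)
    for (n in seq_len(n_cell_cols)) {
      rows <- ((n - 1) * seq_w + 1):(if (n == n_cell_cols) L else n * seq_w)
      h <- rep(0, n_bins)
      for (j in rows) for (i in cols) {
        b <- floor((f$Theta[j, i] + pi) / (2 * pi / n_bins)) + 1
        b <- min(max(b, 1), n_bins)
        h[b] <- h[b] + f$G[j, i]
      }
      nrm <- sqrt(sum(h^2))
      out <- c(out, if (nrm > epsilon) h / nrm else rep(0, n_bins))
    }
  }
  out
}

naive_ctd <- function(sequence, groupings) {
  out <- c()
  for (g in groupings) {
    lab <- unname(g[strsplit(sequence, "")[[1]]])
    L <- length(lab)
    C <- sapply(1:3, function(k) sum(lab == k) / L)
    Tr <- c()
    for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
      cnt <- 0
      for (j in 1:(L - 1)) {
        if ((lab[j] == p[1] && lab[j + 1] == p[2]) ||
            (lab[j] == p[2] && lab[j + 1] == p[1])) cnt <- cnt + 1
      }
      Tr <- c(Tr, cnt / (L - 1))
    }
    D <- c()
    for (k in 1:3) {
      pos <- which(lab == k)
      if (!length(pos)) { D <- c(D, rep(0, 5)); next }
      nk <- length(pos)
      D <- c(D, 100 * c(pos[1], pos[ceiling(0.25 * nk)],
                        pos[ceiling(0.5 * nk)], pos[ceiling(0.75 * nk)],
                        pos[nk]) / L)
    }
    out <- c(out, C, Tr, D)
  }
  out
}

naive_cpsr <- function(record, tables) {
  chars <- strsplit(record$sequence, "")[[1]]
  L <- length(chars)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  comp <- sapply(aa, function(a) sum(chars == a) / L)
  ex_lev <- attr(tables$exchange, "levels")
  ex <- unname(tables$exchange[chars])
  big <- c()
  for (a in ex_lev) for (b in ex_lev) {
    cnt <- 0
    for (j in 1:(L - 1)) if (ex[j] == a && ex[j + 1] == b) cnt <- cnt + 1
    big <- c(big, cnt / (L - 1))
  }
  el_lev <- attr(tables$electron, "levels")
  el <- sapply(el_lev, function(cl)
    sum(unname(tables$electron[chars]) == cl) / L)
  rg_lev <- attr(tables$r_group, "levels")
  rg <- sapply(rg_lev, function(cl)
    sum(unname(tables$r_group[chars]) == cl) / L)
  sc <- tables$scales
  unname(c(comp, L, big, el,
           sum(sc[chars, "rigidity"]) / L,
           sum(sc[chars, "flexibility"]) / L,
           sum(sc[chars, "irreplaceability"]) / L, rg))
}

# record with a fixed short sequence for hand checks
toy_record <- function(seq = "ACDEFGHIKL", id = "toy", label = NA) {
  protein_record(id, seq, label)
}

write_tmp_fasta <- function(entries) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(entries), function(id)
    c(paste0(">", id), entries[[id]]))), path)
  path
}
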