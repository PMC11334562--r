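test_that("group mapping is total and faithful for all seven properties", {
  gr <- ctd_groupings()
  expect_length(gr, 7)
  for (g in gr) {
    expect_setequal(names(g), AA_CANONICAL)
    expect_setequal(unique(g), 1:3)
    # total: any sequence maps without error
    expect_length(map_to_groups("ACDEFGHIKLMNPQRSTVWY", g), 20)
  }
  # homopolymer maps to a constant string, alternation alternates
  hyd <- gr$hydrophobicity
  g1_res <- names(hyd)[hyd == 1][1]
  g2_res <- names(hyd)[hyd == 2][1]
  expect_equal(map_to_groups(strrep(g1_res, 6), hyd), rep(1L, 6))
  expect_equal(map_to_groups(paste(rep(c(g1_res, g2_res), 4), collapse = ""),
                             hyd), rep(c(1L, 2L), 4))
  expect_error(map_to_groups("ACD", hyd[-1]), "absent")
})

test_that("C/T/D indices reproduce hand-computed toy values", {
  idx <- ctd_indices(rep(1:3, each = 4))      # "111122223333", L = 12
  expect_equal(idx$C, rep(4 / 12, 3))
  expect_equal(idx$T, c(1 / 11, 0, 1 / 11))
  # homopolymer: no transitions; landmarks at 25/25/50/75/100 percent
  h <- ctd_indices(rep(1L, 4))
  expect_equal(h$T, rep(0, 3))
  expect_equal(h$D[1:5], c(25, 25, 50, 75, 100))
  expect_equal(h$D[6:15], rep(0, 10))        # absent groups
  expect_equal(h$C, c(1, 0, 0))
  expect_error(ctd_indices(1L), "at least 2")
})

test_that("C sums to 1, T bounded, D monotone and bounded on random strings", {
  set.seed(19)
  for (rep in 1:50) {
    g <- sample(1:3, sample(10:80, 1), replace = TRUE)
    idx <- ctd_indices(g)
    expect_equal(sum(idx$C), 1, tolerance = 1e-12)
    expect_true(all(idx$T >= 0) && sum(idx$T) <= 1)
    for (k in 1:3) {
      lm <- idx$D[((k - 1) * 5 + 2):(k * 5)]  # the 25..100% landmarks
      expect_true(all(diff(lm) >= -1e-12))
      expect_true(all(idx$D >= 0 & idx$D <= 100))
    }
  }
})

test_that("147-D descriptor matches the naive oracle exactly", {
  gr <- ctd_groupings()
  expect_length(encode_nqlc(toy_record()), 147)
  ds <- generate_synthetic_dataset(50, 50, c(10, 120), seed = 23)
  for (rec in ds$records) {
    expect_equal(as.numeric(encode_nqlc(rec, gr)),
                 naive_ctd(rec$sequence, gr), tolerance = 1e-14)
  }
  # group-substitution invariance: swap residues within the same groups
  gr_all <- do.call(rbind, lapply(gr, function(g) g[AA_CANONICAL]))
  sig <- apply(gr_all, 2, paste, collapse = "")
  twins <- split(AA_CANONICAL, sig)
  twins <- twins[lengths(twins) >= 2][[1]]
  s1 <- paste(rep(twins[1], 10), collapse = "")
  s2 <- paste(rep(twins[2], 10), collapse = "")
  expect_equal(as.numeric(encode_nqlc(protein_record("a", s1), gr)),
               as.numeric(encode_nqlc(protein_record("b", s2), gr)))
})

test_that("z-score standardization matches Eq-style hand values", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  params <- fit_standardizer(X)
  expect_equal(unname(params$mean), c(2, 5))
  expect_equal(unname(params$sd[1]), 1)     # sample sd, denominator n-1
  expect_warning(Y <- apply_standardizer(X, params), "constant")
  expect_equal(unname(Y[, 1]), c(-1, 0, 1))
  expect_equal(unname(Y[, 2]), c(0, 0, 0))
  # idempotence: standardizing an already standardized matrix changes nothing
  Z <- matrix(rnorm(40), 10)
  S1 <- standardize(Z)
  S2 <- standardize(S1)
  expect_equal(unclass(S2)[, ], unclass(S1)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # train-fit / test-apply round trip
  p <- fit_standardizer(Z)
  expect_equal(apply_standardizer(Z, p), attr(S1, "params") |>
                 (\(q) apply_standardizer(Z, q))())
  expect_error(fit_standardizer(Z[1, , drop = FALSE]), "2 samples")
  # minmax mode stays in [0, 1]
  M <- standardize(Z, method = "minmax")
  expect_true(all(M >= 0 & M <= 1))
})
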