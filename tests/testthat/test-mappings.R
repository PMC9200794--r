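# The 11-base worked example used throughout: its five encodings are pinned
# to the published arrays, spectra to a direct-sum DFT oracle, descriptors to
# formula-by-formula recomputation.
EX <- "TGACCGAGAGA"

test_that("integer, real and eiip encodings reproduce the worked example", {
  expect_equal(as.vector(encode_sequence(EX, "integer")$channels),
               c(0, 3, 2, 1, 1, 3, 2, 3, 2, 3, 2))
  expect_equal(as.vector(encode_sequence(EX, "real")$channels),
               c(1.5, -0.5, -1.5, 0.5, 0.5, -0.5, -1.5, -0.5, -1.5, -0.5,
                 -1.5))
  expect_equal(as.vector(encode_sequence(EX, "eiip")$channels),
               c(0.1335, 0.0806, 0.1260, 0.1340, 0.1340, 0.0806, 0.1260,
                 0.0806, 0.1260, 0.0806, 0.1260))
})

test_that("binary encoding gives the published indicator rows", {
  ch <- encode_sequence(EX, "binary")$channels
  expect_equal(unname(ch[, "A"]), c(0, 0, 1, 0, 0, 0, 1, 0, 1, 0, 1))
  expect_equal(unname(ch[, "C"]), c(0, 0, 0, 1, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(ch[, "G"]), c(0, 1, 0, 0, 0, 1, 0, 1, 0, 1, 0))
  expect_equal(unname(ch[, "T"]), c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  # indicator completeness at every position
  expect_equal(unname(rowSums(ch)), rep(1, 11))
})

test_that("Z-curve coordinates match the published x/z and the count oracle y", {
  ch <- encode_sequence(EX, "zcurve")$channels
  expect_equal(unname(ch[, "x"]), c(-1, 0, 1, 0, -1, 0, 1, 2, 3, 4, 5))
  expect_equal(unname(ch[, "z"]), c(1, 0, 1, 0, -1, -2, -1, -2, -1, -2, -1))
  # the printed y has an elided entry; recompute from cumulative base counts
  s <- strsplit(EX, "")[[1]]
  y_oracle <- cumsum(s %in% c("A", "C")) - cumsum(s %in% c("G", "T"))
  expect_equal(unname(ch[, "y"]), y_oracle)
  expect_equal(y_oracle, c(-1, -2, -1, 0, 1, 0, 1, 0, 1, 0, 1))
})

test_that("Z-curve bookkeeping invariants hold on random sequences", {
  set.seed(11)
  for (rep in 1:20) {
    s <- random_dna(sample(5:80, 1))
    ch <- encode_sequence(s, "zcurve")$channels
    l <- seq_len(nrow(ch))
    v <- strsplit(s, "")[[1]]
    counts <- cbind(A = cumsum(v == "A"), C = cumsum(v == "C"),
                    G = cumsum(v == "G"), T = cumsum(v == "T"))
    expect_equal(unname(rowSums(counts)), l)
    expect_equal(unname(counts[, "A"] - counts[, "T"]),
                 unname((ch[, "x"] + ch[, "y"]) / 2))
    # consecutive coordinates move by exactly 1 per channel
    expect_true(all(abs(diff(ch)) == 1 | nrow(ch) == 1))
    expect_true(all(abs(ch) <= l))
  }
  expect_equal(unname(encode_sequence("AAAA", "zcurve")$channels),
               cbind(1:4, 1:4, 1:4))
})

test_that("power spectra: constant, impulse, and the direct-sum DFT oracle", {
  const <- structure(list(scheme = "integer",
                          channels = matrix(3, 8, 1)),
                     class = "numeric_signal")
  P <- power_spectrum(const)
  expect_equal(P[1], (8 * 3)^2)
  expect_equal(P[-1], rep(0, 7))

  imp <- structure(list(scheme = "integer",
                        channels = matrix(c(1, 0, 0, 0), 4, 1)),
                   class = "numeric_signal")
  expect_equal(power_spectrum(imp), rep(1, 4))

  set.seed(3)
  for (scheme in c("binary", "integer", "real", "zcurve", "eiip")) {
    s <- random_dna(32)
    sig <- encode_sequence(s, scheme)
    P <- power_spectrum(sig)
    expect_true(all(P >= 0))
    expect_equal(P, dft_power_oracle(sig$channels), tolerance = 1e-9)
    # Parseval: time-domain energy equals mean spectral power
    expect_equal(sum(sig$channels^2), mean(P), tolerance = 1e-9)
  }
})

test_that("spectra depend on residues only (bit-identical across records)", {
  a <- power_spectrum(encode_sequence("ACGTACGGT", "zcurve"))
  b <- power_spectrum(encode_sequence("ACGTACGGT", "zcurve"))
  expect_identical(a, b)
})

test_that("descriptor vector matches a formula-by-formula recomputation", {
  set.seed(21)
  P <- power_spectrum(encode_sequence(random_dna(50), "eiip"))
  d <- spectral_descriptors(P)
  expect_named(d, c("papr", "snr", "min", "max", "median", "sd_pop",
                    "sd_samp", "p15", "p25", "p50", "p75", "var", "cv",
                    "amplitude", "semi_iqr", "iqr", "skewness", "kurtosis"))
  L <- length(P); mu <- mean(P)
  m2 <- mean((P - mu)^2); m3 <- mean((P - mu)^3); m4 <- mean((P - mu)^4)
  expect_equal(d[["papr"]], max(P) / mu)
  expect_equal(d[["snr"]], P[round(L / 3) + 1] / mu)
  expect_equal(d[["min"]], min(P))
  expect_equal(d[["max"]], max(P))
  expect_equal(d[["median"]], unname(quantile(P, 0.5)))
  expect_equal(d[["sd_pop"]], sqrt(m2))
  expect_equal(d[["sd_samp"]], sd(P))
  expect_equal(unname(d[c("p15", "p25", "p50", "p75")]),
               unname(quantile(P, c(0.15, 0.25, 0.5, 0.75))))
  expect_equal(d[["var"]], var(P))
  expect_equal(d[["cv"]], sqrt(m2) / mu)
  expect_equal(d[["amplitude"]], max(P) - min(P))
  expect_equal(d[["iqr"]], 2 * d[["semi_iqr"]])
  expect_equal(d[["skewness"]], m3 / m2^1.5)
  expect_equal(d[["kurtosis"]], m4 / m2^2)
  # order invariants
  expect_true(d[["min"]] <= d[["p15"]] && d[["p15"]] <= d[["p25"]] &&
              d[["p25"]] <= d[["median"]] && d[["median"]] <= d[["p75"]] &&
              d[["p75"]] <= d[["max"]])
  expect_equal(d[["median"]], d[["p50"]])
})

test_that("descriptor degenerate cases", {
  d <- spectral_descriptors(c(4, 4, 4, 4))
  expect_equal(d[["papr"]], 1)
  expect_equal(d[["var"]], 0)
  expect_equal(d[["amplitude"]], 0)
  expect_equal(d[["iqr"]], 0)
  d2 <- spectral_descriptors(c(0, 0, 0, 8))
  expect_equal(d2[["papr"]], 4)
  expect_equal(d2[["amplitude"]], 8)
  expect_error(spectral_descriptors(c(0, 0, 0)), "degenerate")
  expect_error(spectral_descriptors(5), "too short")
})

test_that("rff vector: 90 named features, deterministic, scheme-block layout", {
  v <- rff_vector(EX)
  expect_length(v, 90)
  expect_equal(names(v)[1:2], c("binary_papr", "binary_snr"))
  expect_equal(sum(startsWith(names(v), "eiip_")), 18)
  expect_identical(v, rff_vector(EX))
  # first block equals descriptors of the binary spectrum
  expect_equal(unname(v[1:18]),
               unname(spectral_descriptors(
                 dft_power_oracle(encode_sequence(EX, "binary")$channels))))
  m <- rff_features(fasta_dataset(id = c("a", "b"),
                                  residues = c(EX, "ACGTAC")))
  expect_equal(dim(m), c(2, 90))
  expect_equal(rownames(m), c("a", "b"))
})

test_that("encoding input validation", {
  expect_error(encode_sequence("", "integer"), "empty")
  expect_error(encode_sequence("ACGT", "bogus"))
  expect_error(encode_sequence("ACNT", "integer"), "non-ACGT")
})
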