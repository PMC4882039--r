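test_that("Voss mapping matches the worked indicator-track example", {
  tr <- voss_mapping("ATCTCACTGGT")
  expect_equal(unname(tr["T", ]), c(0, 1, 0, 1, 0, 0, 0, 1, 0, 0, 1))
  expect_equal(unname(tr["A", ]), c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0))
  expect_equal(unname(tr["C", ]), c(0, 0, 1, 0, 1, 0, 1, 0, 0, 0, 0))
  expect_equal(unname(tr["G", ]), c(0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 0))
})

test_that("Voss tracks partition the sequence and reject bad characters", {
  expect_equal(unname(voss_mapping("AAAA")["A", ]), rep(1, 4))
  set.seed(42)
  for (i in 1:20) {
    s <- random_seq(sample(1:80, 1))
    expect_equal(unname(colSums(voss_mapping(s))), rep(1, nchar(s)))
  }
  expect_error(voss_mapping("ACGN"), "position 4")
})

test_that("power spectrum matches closed forms and the direct DFT oracle", {
  # constant track: all mass at k = 0
  P <- power_spectrum(voss_mapping(strrep("A", 300)))
  expect_equal(P[1], 90000)
  expect_equal(max(abs(P[-1])), 0, tolerance = 1e-6)
  # one of each base: flat spectrum of height N
  expect_equal(power_spectrum(voss_mapping("ACGT")), rep(4, 4),
               tolerance = 1e-9)
  set.seed(7)
  for (i in 1:10) {
    s <- random_seq(sample(20:200, 1))
    expect_equal(power_spectrum(voss_mapping(s)), oracle_power_spectrum(s),
                 tolerance = 1e-8)
  }
})

test_that("spectrum sums to N^2 (Parseval), so the mean power is N", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(10:600, 1)
    s <- random_seq(n, prob = stats::runif(4) + 0.05)
    P <- power_spectrum(voss_mapping(s))
    expect_equal(sum(P), n^2, tolerance = 1e-6 * n^2)
  }
})

test_that("SNR matches analytic values and the nearest-bin rule", {
  expect_equal(snr(strrep("A", 300)), 0, tolerance = 1e-9)
  expect_equal(snr(strrep("ACG", 100)), 100, tolerance = 1e-8)
  expect_equal(snr("ACGT"), 1, tolerance = 1e-9)
  # N not divisible by 3: bin round(N/3) — cross-checked against the oracle
  set.seed(13)
  for (n in c(50, 101, 250, 397)) {
    s <- random_seq(n)
    expect_equal(snr(s), oracle_snr(s), tolerance = 1e-8)
  }
  expect_error(snr("AC"), ">= 3")
})

test_that("max_orf matches the stated conventions", {
  expect_equal(max_orf("ATGTAA"), 6)
  expect_equal(max_orf("AATGAAATAGC"), 9)
  expect_equal(max_orf("CCCCCC"), 0)
  # ATG with no in-frame stop: no ORF unless require_stop = FALSE
  expect_equal(max_orf("ATGAAAAAA"), 0)
  expect_equal(max_orf("ATGAAAAAA", require_stop = FALSE), 9)
  # reverse-complement frames are not scanned: CAT..TTA is revcomp ATG..TAA
  expect_equal(max_orf("CCATTTACC"), 0)
})

test_that("max_orf agrees with the exhaustive scan oracle", {
  set.seed(17)
  for (i in 1:80) {
    s <- random_seq(sample(30:400, 1),
                    prob = c(0.35, 0.15, 0.15, 0.35))  # AT-rich: many stops
    m <- max_orf(s)
    expect_identical(m, as.integer(oracle_max_orf(s)))
    expect_true(m == 0 || (m >= 6 && m %% 3 == 0))
  }
})

test_that("rmax_orf is the ORF fraction with validated domain", {
  expect_equal(rmax_orf(6, 6), 1.0)
  expect_equal(rmax_orf(0, 500), 0.0)
  expect_equal(rmax_orf(9, 11), 0.8182, tolerance = 1e-4)
  expect_error(rmax_orf(6, 0), "positive")
  expect_error(rmax_orf(12, 6), "\\[0, length\\]")
})

test_that("k-mer frequencies use overlapping windows and sum to 1", {
  expect_equal(unname(kmer_frequencies("ACGT", 1)), rep(0.25, 4))
  f2 <- kmer_frequencies("AAAA", 2)
  expect_equal(unname(f2["AA"]), 1.0)
  expect_equal(sum(f2), 1)
  f <- kmer_frequencies("ACGA", 2)
  expect_equal(unname(f[c("AC", "CG", "GA")]), rep(1 / 3, 3))
  expect_equal(sum(f != 0), 3)
  expect_error(kmer_frequencies("AC", 3), "shorter")
  set.seed(19)
  for (k in 1:3) {
    s <- random_seq(100)
    expect_equal(sum(kmer_frequencies(s, k)), 1, tolerance = 1e-9)
  }
})

test_that("extract_features emits 89 consistent named entries", {
  s <- paste0("ATGTAA", strrep("GATC", 80))
  fv <- extract_features(s)
  expect_length(fv, 89L)
  expect_identical(names(fv), feature_names())
  expect_equal(unname(fv["MaxORF"]), max_orf(s))
  expect_equal(unname(fv["SNR"]), snr(s))
  expect_equal(unname(fv["Length"]), nchar(s))
  expect_equal(unname(fv["RMaxORF"]), max_orf(s) / nchar(s))

  g <- extract_features(strrep("G", 300))
  expect_equal(unname(g["(G+C)%"]), 1.0)
  expect_equal(unname(g["SNR"]), 0, tolerance = 1e-9)
})

test_that("batch feature extraction is deterministic and order-independent", {
  set.seed(23)
  tx <- data.frame(id = paste0("t", 1:6),
                   seq = replicate(6, random_seq(sample(200:400, 1))))
  fm1 <- feature_matrix(tx)
  fm2 <- feature_matrix(tx[6:1, ])
  expect_identical(fm1, feature_matrix(tx))
  reordered <- fm2[match(fm1$id, fm2$id), ]
  rownames(reordered) <- NULL
  expect_equal(fm1, reordered)
  expect_identical(colnames(fm1), c("id", feature_names()))
})
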