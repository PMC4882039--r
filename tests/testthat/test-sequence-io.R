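test_that("read_fasta parses multi-line, multi-record files in order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">t1 some description", "ACGT", "ACGT", ">t2", "GGGC"), f)
  tx <- read_fasta(f)
  expect_equal(tx$id, c("t1", "t2"))
  expect_equal(tx$seq, c("ACGTACGT", "GGGC"))
  expect_equal(tx$label, c("UNKNOWN", "UNKNOWN"))
})

test_that("read_fasta handles empty files and flags empty records", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), f)
  expect_equal(nrow(read_fasta(f)), 0L)

  writeLines(c(">bad", ">ok", "ACGT"), f)
  expect_error(read_fasta(f), "bad")
  expect_error(read_fasta(file.path(tempdir(), "no-such-file.fa")),
               "not found")
})

test_that("read_fasta preserves case until normalization", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">t", "acgU"), f)
  expect_equal(read_fasta(f)$seq, "acgU")
})

test_that("cleaning normalizes U/u to T and uppercases", {
  tx <- data.frame(id = "r1", seq = strrep("acgu", 75))
  out <- clean_transcripts(tx)
  expect_equal(out$transcripts$seq, strrep("ACGT", 75))
  expect_equal(out$report$kept, 1L)
})

test_that("cleaning rejects disallowed alphabets, bad lengths and duplicates", {
  tx <- data.frame(
    id = paste0("r", 1:5),
    seq = c(paste0("ACGUN", strrep("A", 295)),  # N -> alphabet
            strrep("ACGT", 75),                  # kept
            strrep("ACGT", 75),                  # duplicate of r2
            strrep("AC", 75),                    # length 150 -> too short
            strrep("G", 20000)))                 # length 20000 -> at cap
  out <- clean_transcripts(tx)
  expect_equal(out$report$rejected_alphabet, 1L)
  expect_equal(out$report$rejected_length, 2L)
  expect_equal(out$report$rejected_duplicate, 1L)
  expect_equal(out$report$kept, 1L)
  expect_setequal(out$rejects$id, c("r1", "r3", "r4", "r5"))
  expect_equal(sort(unique(out$rejects$reason)),
               c("alphabet", "duplicate", "length"))
})

test_that("length window is half-open: 200 kept, 20000 rejected", {
  tx <- data.frame(id = c("lo", "hi"),
                   seq = c(strrep("A", 200), strrep("A", 19999)))
  out <- clean_transcripts(tx, drop_duplicates = FALSE)
  expect_equal(out$report$kept, 2L)
})

test_that("cleaning report counts always reconcile and cleaning is idempotent", {
  set.seed(1)
  tx <- data.frame(
    id = paste0("r", 1:40),
    seq = replicate(40, {
      n <- sample(c(50, 300, 500, 25000), 1)
      paste(sample(c("A", "C", "G", "T", "N", "u"), n, replace = TRUE,
                   prob = c(rep(0.24, 4), 0.02, 0.02)), collapse = "")
    }))
  out1 <- clean_transcripts(tx)
  r <- out1$report
  expect_equal(r$kept + r$rejected_alphabet + r$rejected_length +
                 r$rejected_duplicate, nrow(tx))
  out2 <- clean_transcripts(out1$transcripts)
  expect_identical(out2$transcripts, out1$transcripts)
  expect_equal(out2$report$kept, r$kept)
  expect_equal(out2$report$rejected_alphabet + out2$report$rejected_length +
                 out2$report$rejected_duplicate, 0L)
})

test_that("prediction-mode cleaning flags rather than drops short records", {
  tx <- data.frame(id = c("short", "ok"),
                   seq = c(strrep("ACGT", 20), strrep("ACGT", 100)))
  out <- clean_transcripts(tx, enforce_length = FALSE,
                           drop_duplicates = FALSE)
  expect_equal(nrow(out$transcripts), 2L)
  expect_equal(out$transcripts$length_flag, c(TRUE, FALSE))
})

test_that("min_len > max_len is a configuration error", {
  tx <- data.frame(id = "a", seq = strrep("A", 300))
  expect_error(clean_transcripts(tx, min_len = 500, max_len = 400),
               "min_len")
})

test_that("write_report emits a TSV with fixed leading columns", {
  preds <- data.frame(id = c("x", "y", "z"),
                      noncoding_score = c(0.87, 0.1, 1),
                      predicted_class = c("NONCODING", "CODING", "NONCODING"),
                      shortcut_applied = c(FALSE, FALSE, TRUE),
                      `SNR` = c(1.2, 8.1, 0.4),
                      check.names = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report(preds, f)
  lines <- readLines(f)
  expect_length(lines, 4L)
  expect_equal(lines[1],
               "id\tnoncoding_score\tpredicted_class\tshortcut_applied\tSNR")
  expect_match(lines[2], "^x\t0\\.87\t")

  write_report(preds[0, ], f)
  expect_length(readLines(f), 1L)
})
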