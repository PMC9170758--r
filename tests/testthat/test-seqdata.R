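test_that("load_sites keeps thymine-mapped sites and discards the rest", {
  ref <- c(tx = "AAGTCCATGA")        # T at 0-based 3 and 7; A at 0, 1, 6, 9
  df <- data.frame(sequence_id = "tx",
                   position = c(3L, 4L, 6L, 7L),
                   strand = c("+", "+", "-", "+"))
  expect_message(s <- load_sites(df, ref), "discarded")
  # + on T retained; + on C discarded; - on A retained (revcomp T); + on T kept
  expect_equal(s$position, c(3L, 6L, 7L))
  expect_equal(attr(s, "n_discarded"), 1L)
})

test_that("load_sites hard-errors on unknown ids and malformed records", {
  ref <- c(tx = "AAGTCCATGA")
  expect_error(load_sites(data.frame(sequence_id = "nope", position = 1L,
                                     strand = "+"), ref),
               "nope")
  expect_error(load_sites(data.frame(sequence_id = "tx", position = 99L,
                                     strand = "+"), ref),
               "line 1")
  expect_error(load_sites(data.frame(sequence_id = "tx", position = 3L,
                                     strand = "x"), ref),
               "strand")
})

test_that("load_sites reads BED input as 0-based half-open", {
  ref <- c(tx = "AAGTCCATGA")
  bed <- tempfile(fileext = ".bed")
  writeLines(c("tx\t3\t4\tsite1\t0\t+", "tx\t6\t7\tsite2\t0\t-"), bed)
  s <- load_sites(bed, ref)
  expect_equal(s$position, c(3L, 6L))
  expect_equal(s$strand, c("+", "-"))
})

test_that("positive windows are centered, padded, and strand-resolved", {
  set.seed(11)
  ref <- c(tx = paste(c(sample(c("A", "C", "G"), 3, TRUE), "T",
                        sample(c("A", "C", "G", "T"), 196, TRUE)),
                      collapse = ""))
  # interior site: full window, no padding
  tin <- which(strsplit(ref[["tx"]], "")[[1]] == "T")
  tin <- tin[tin > 60 & tin < 140][1] - 1L
  s <- load_sites(data.frame(sequence_id = "tx", position = tin,
                             strand = "+"), ref)
  p <- build_positive_samples(s, ref)
  expect_equal(nchar(p$sequence), 101L)
  expect_false(grepl("N", p$sequence))
  expect_equal(substr(p$sequence, 51, 51), "T")
  expect_equal(p$sequence,
               substr(ref[["tx"]], tin - 50 + 1, tin + 50 + 1))

  # edge site at position 3: 47 left 'N's, center still T
  s3 <- load_sites(data.frame(sequence_id = "tx", position = 3L,
                              strand = "+"), ref)
  p3 <- build_positive_samples(s3, ref)
  expect_equal(substr(p3$sequence, 1, 47), strrep("N", 47))
  expect_equal(substr(p3$sequence, 51, 51), "T")
})

test_that("minus-strand samples equal the reverse complement of the plus slice", {
  set.seed(12)
  ref <- c(tx = paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""))
  apos <- which(strsplit(ref[["tx"]], "")[[1]] == "A")
  apos <- apos[apos > 60 & apos < 140][1] - 1L
  s <- load_sites(data.frame(sequence_id = "tx", position = apos,
                             strand = "-"), ref)
  p <- build_positive_samples(s, ref)
  plus_slice <- substr(ref[["tx"]], apos - 50 + 1, apos + 50 + 1)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(plus_slice)))
  expect_identical(p$sequence, rc)
  expect_equal(substr(p$sequence, 51, 51), "T")
})

test_that("negative sampling matches the brute-force oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    ref <- c(tx = paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = ""))
    tpos <- which(strsplit(ref[["tx"]], "")[[1]] == "T") - 1L
    centers <- tpos[tpos > 55 & tpos < 345]
    if (length(centers) < 1) next
    center <- centers[sample.int(length(centers), 1)]
    s <- load_sites(data.frame(sequence_id = "tx", position = center,
                               strand = "+"), ref)
    p <- build_positive_samples(s, ref)
    expected <- negative_oracle(ref[["tx"]], center, center)
    if (is.na(expected)) {
      expect_warning(n <- build_negative_samples(p, ref), "no eligible")
      expect_equal(nrow(n), 0L)
    } else {
      n <- build_negative_samples(p, ref)
      expect_equal(n$window_start + 50L, expected)
      expect_equal(nchar(n$sequence), 101L)
      expect_equal(substr(n$sequence, 51, 51), "T")
    }
  }
})

test_that("equidistant negative candidates resolve downstream", {
  # symmetric construction: T at center +/- 120 exactly, nothing else
  chars <- rep("A", 400)
  chars[201] <- "T"                 # positive center, 0-based 200
  chars[201 - 120] <- "T"           # upstream candidate, 0-based 80
  chars[201 + 120] <- "T"           # downstream candidate, 0-based 320
  ref <- c(tx = paste(chars, collapse = ""))
  s <- load_sites(data.frame(sequence_id = "tx", position = 200L,
                             strand = "+"), ref)
  p <- build_positive_samples(s, ref)
  n <- build_negative_samples(p, ref)
  expect_equal(n$window_start + 50L, 320L)
})

test_that("no negative window overlaps any positive window", {
  set.seed(33)
  ref <- c(tx = paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = ""))
  tpos <- which(strsplit(ref[["tx"]], "")[[1]] == "T") - 1L
  centers <- sort(sample(tpos[tpos > 55 & tpos < 1945], 5))
  s <- load_sites(data.frame(sequence_id = "tx", position = centers,
                             strand = "+"), ref)
  p <- build_positive_samples(s, ref)
  n <- suppressWarnings(build_negative_samples(p, ref, ratio_n = 3L))
  for (i in seq_len(nrow(n))) {
    nc <- n$window_start[i] + 50L
    for (c0 in centers) {
      expect_true((nc + 50) < (c0 - 50) || (nc - 50) > (c0 + 50))
    }
  }
  expect_lte(nrow(n), 3L * nrow(p))
  # duplicates removed
  expect_false(any(duplicated(paste(n$sequence_id, n$window_start, n$strand))))
})

test_that("one-hot encoding follows the A,C,G,T channel convention", {
  m <- one_hot_encode("ACGT")
  expect_equal(unname(m), rbind(c(1, 0, 0, 0), c(0, 1, 0, 0),
                                c(0, 0, 1, 0), c(0, 0, 0, 1)))
  expect_equal(unname(one_hot_encode("N")), matrix(0, 1, 4))
  expect_equal(one_hot_encode("u"), one_hot_encode("T"))
  expect_error(one_hot_encode("ACXG"), "illegal character 'X' at position 3")
})

test_that("encode/decode round-trips over random sequences", {
  set.seed(99)
  for (s in random_dna(200, 101)) {
    expect_identical(one_hot_decode(one_hot_encode(s)), s)
  }
  # N maps to the zero row and survives the round trip
  s <- "ANCGTNNA"
  expect_identical(one_hot_decode(one_hot_encode(s)), s)
  expect_equal(rowSums(one_hot_encode(s)), c(1, 0, 1, 1, 1, 0, 0, 1))
})

test_that("fold assignment partitions samples with near-equal sizes", {
  fa <- make_folds(100, 10, seed = 5)
  expect_equal(as.integer(table(fa$fold)), rep(10L, 10))
  fa2 <- make_folds(101, 10, seed = 5)
  expect_equal(sort(as.integer(table(fa2$fold))), c(rep(10L, 9), 11L))
  expect_equal(length(fa2$fold), 101L)
  # determinism
  expect_identical(make_folds(57, 7, seed = 3), make_folds(57, 7, seed = 3))
  expect_error(make_folds(5, 10, seed = 1), "exceeds")
  expect_error(make_folds(5, 1, seed = 1), "at least 2")
})

test_that("sample tables survive a TSV round trip", {
  ds <- generate_dataset(synthetic_config(n_pos = 5L, n_neg = 5L, seed = 2L))
  f <- tempfile(fileext = ".tsv")
  write_samples(ds, f)
  back <- read_samples(f)
  expect_equal(back, ds)
})
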