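test_that("transcript scanning scores exactly the thymines, with N padding", {
  fit <- fixture_model()
  # no thymine, no scores
  expect_equal(nrow(scan_transcript(fit, "x", strrep("A", 40))), 0L)

  # thymine at offset 2 of a 30-nt transcript: 48 left-pad N's
  s <- paste0("GGTAAAAAAA", strrep("C", 20))
  sc <- scan_transcript(fit, "x", s)
  expect_equal(sc$position, 2L)
  # reconstruct the window the scanner must have used
  win <- paste0(strrep("N", 48), s, strrep("N", 101 - 48 - 30))
  win <- substr(win, 1, 101)
  expect_equal(substr(win, 51, 51), "T")

  # |output| equals the thymine count on random transcripts
  set.seed(61)
  for (i in 1:20) {
    tx <- paste(sample(c("A", "C", "G", "T"), sample(50:300, 1), TRUE),
                collapse = "")
    sc <- scan_transcript(fit, "tx", tx)
    expect_equal(nrow(sc), lengths(regmatches(tx, gregexpr("T", tx))))
    if (nrow(sc)) {
      expect_true(all(substring(tx, sc$position + 1, sc$position + 1) == "T"))
    }
  }
})

test_that("scanner scores equal manual window extraction bit-for-bit", {
  fit <- fixture_model()
  set.seed(62)
  tx <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  sc <- scan_transcript(fit, "tx", tx)
  padded <- paste0(strrep("N", 50), tx, strrep("N", 50))
  for (i in sample(nrow(sc), min(10, nrow(sc)))) {
    win <- substr(padded, sc$position[i] + 1, sc$position[i] + 101)
    expect_equal(sc$lpps[i], predict(fit, win), tolerance = 1e-12)
  }
})

test_that("site calling is a strict-threshold partition", {
  scores <- data.frame(sequence_id = "x", position = 0:4,
                       lpps = c(0.5, 0.51, 0.49, 1, 0))
  parts <- call_sites(scores)
  expect_equal(parts$psi$position, c(1L, 3L))          # 0.5 exactly -> non_psi
  expect_equal(nrow(parts$psi) + nrow(parts$non_psi), nrow(scores))
  # threshold monotonicity
  hi <- call_sites(scores, 0.6)$psi$position
  lo <- call_sites(scores, 0.4)$psi$position
  expect_true(all(hi %in% lo))
})

test_that("tPPS reproduces the defining formula and flags degeneracies", {
  sc <- data.frame(sequence_id = "x", position = 0:3,
                   lpps = c(0.9, 0.8, 0.3, 0.2))
  t1 <- tpps(sc, L = 10)
  expect_equal(t1$K, 4L); expect_equal(t1$num_psi, 2L)
  expect_equal(t1$num_u, 2L)
  expect_equal(t1$tpps, 2.5)
  expect_true(t1$defined)

  # all below threshold: defined zero
  t0 <- tpps(transform(sc, lpps = c(0.1, 0.2, 0.3, 0.4)), L = 10)
  expect_equal(t0$tpps, 0)
  # all above: undefined (num_u = 0)
  tu <- tpps(transform(sc, lpps = c(0.9, 0.9, 0.9, 0.9)), L = 10)
  expect_false(tu$defined)
  expect_true(is.na(tu$tpps))
  # no thymines at all: undefined
  te <- tpps(sc[0, ], L = 10)
  expect_false(te$defined)
  # positions outside the transcript are a hard error
  expect_error(tpps(sc, L = 3), "outside")
})

test_that("tPPS matches a direct formula transcription on random vectors", {
  set.seed(63)
  for (i in 1:200) {
    K <- sample(1:50, 1)
    lpps <- runif(K)
    L <- K + sample(1:100, 1)
    sc <- data.frame(sequence_id = "x", position = seq_len(K) - 1, lpps = lpps)
    t <- tpps(sc, L)
    expected <- tpps_oracle(lpps, L)
    if (is.na(expected)) {
      expect_false(t$defined)
    } else {
      expect_equal(t$tpps, expected)
    }
  }
})

test_that("AFCP is antisymmetric under allele swap and checks the reference", {
  fit <- fixture_model()
  set.seed(64)
  ref <- c(tx = paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""))
  pos <- sample(60:440, 20)
  vars <- data.frame(variant_id = paste0("v", seq_along(pos)),
                     sequence_id = "tx", position = pos,
                     major_allele = substring(ref[["tx"]], pos + 1, pos + 1),
                     minor_allele = NA_character_,
                     stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  vars$minor_allele <- vapply(vars$major_allele, function(b)
    sample(setdiff(bases, b), 1), character(1))

  fwd <- afcp(fit, vars, ref)
  # swapped alleles against the minor-substituted reference negate exactly
  for (i in seq_len(nrow(vars))) {
    if (nzchar(fwd$skip_reason[i])) next
    ref2 <- ref
    substr(ref2[["tx"]], vars$position[i] + 1, vars$position[i] + 1) <-
      vars$minor_allele[i]
    sw <- vars[i, ]
    sw$major_allele <- vars$minor_allele[i]
    sw$minor_allele <- vars$major_allele[i]
    rev <- afcp(fit, sw, ref2)
    expect_identical(rev$afcp, -fwd$afcp[i])
    expect_identical(rev$target_position, fwd$target_position[i])
  }

  # reference mismatch is a hard error naming both bases
  bad <- vars[1, ]
  bad$major_allele <- setdiff(bases, c(bad$major_allele, bad$minor_allele))[1]
  expect_error(afcp(fit, bad, ref), "does not match the major allele")
})

test_that("AFCP is exactly zero under a base-identity-blind model", {
  # make the first convolution channel-symmetric: every window position
  # contributes the same weight whichever base occupies it, so substituting
  # one base for another cannot change any activation
  cfg <- tiny_config()
  m <- build_model(cfg)
  K1 <- cfg$conv1_len
  for (j in seq_len(K1)) {
    rows <- (0:3) * K1 + j
    m$params$W1[rows, ] <- rep(m$params$W1[rows[1], ], each = 4)
  }
  set.seed(65)
  ref <- c(tx = paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""))
  pos <- 150L
  v <- data.frame(variant_id = "v1", sequence_id = "tx", position = pos,
                  major_allele = substring(ref[["tx"]], pos + 1, pos + 1),
                  minor_allele = "A", stringsAsFactors = FALSE)
  if (v$major_allele == "A") v$minor_allele <- "C"
  res <- afcp(m, v, ref)
  expect_identical(res$afcp, 0)
})

test_that("AFCP skips variants with no shared thymine and reports why", {
  fit <- fixture_model()
  # a transcript of pure G around the variant: no T anywhere within 50 nt
  ref <- c(tx = paste0(strrep("G", 200)))
  v <- data.frame(variant_id = "v1", sequence_id = "tx", position = 100L,
                  major_allele = "G", minor_allele = "C",
                  stringsAsFactors = FALSE)
  res <- afcp(fit, v, ref)
  expect_true(is.na(res$afcp))
  expect_match(res$skip_reason, "no thymine")

  # if the variant position itself is T in both alleles it is its own target
  ref2 <- c(tx = paste0(strrep("G", 100), "T", strrep("G", 99)))
  # both alleles T is impossible for the variant base itself (alleles differ),
  # so place the variant adjacent to the lone T
  v2 <- data.frame(variant_id = "v2", sequence_id = "tx", position = 101L,
                   major_allele = "G", minor_allele = "A",
                   stringsAsFactors = FALSE)
  res2 <- afcp(fit, v2, ref2)
  expect_equal(res2$target_position, 100L)
})

test_that("variant tables read from TSV and VCF agree", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tsequence_id\tposition\tmajor_allele\tminor_allele",
               "rs1\ttx1\t41\tT\tC",
               "rs2\ttx2\t10\tG\tA"), tsv)
  a <- read_variants(tsv)
  expect_equal(a$position, c(41L, 10L))

  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "tx1\t42\trs1\tT\tC\t.\tPASS\t.",
               "tx2\t11\trs2\tG\tA\t.\tPASS\t.",
               "tx3\t5\trs3\tGT\tG\t.\tPASS\t."), vcf)
  expect_message(b <- read_variants(vcf), "non-SNV")
  expect_equal(nrow(b), 2L)
  expect_equal(b$position, a$position)        # VCF POS is 1-based
  expect_equal(b$major_allele, a$major_allele)
  expect_equal(b$minor_allele, a$minor_allele)
})
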