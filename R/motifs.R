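# Sequence-motif extraction from trained first-layer convolution filters.
#
# A first-layer filter is slid over the positive training windows; every
# 8-mer whose raw activation (cross-correlation plus filter bias, before
# batch normalization, PReLU, and pooling, in inference mode) strictly
# exceeds half the filter's global maximum activation is collected, and the
# collected 8-mers are stacked into a position frequency/weight matrix.

#' Scan a first-layer filter over positive samples
#'
#' Computes the filter's raw activation (convolution + bias) at every valid
#' offset of every sample and returns the segments whose activation strictly
#' exceeds half of the per-filter global maximum over all samples and
#' offsets. With an all-zero filter (or any filter whose maximum is not
#' positive) no segment can strictly exceed the half-max, so the result is
#' empty.
#'
#' @param model A trained `psicnn_model`.
#' @param positives data.frame of positive samples (`sequence` column) or a
#'   character vector of sequences of the model's input length.
#' @param filter_id Filter index in `1..conv1_filters`.
#' @return data.frame: `sample_index`, `offset` (0-based window start within
#'   the sample), `subsequence` (the k-mer), `activation`.
#' @export
scan_filter_activations <- function(model, positives, filter_id) {
  stopifnot(inherits(model, "psicnn_model"))
  if (filter_id < 1L || filter_id > model$config$conv1_filters) {
    stop("filter_id ", filter_id, " out of range 1..",
         model$config$conv1_filters)
  }
  acts <- .filter_activations(model, positives)
  .threshold_segments(acts$A[, filter_id], acts$seqs, acts$n, acts$L1,
                      model$config$conv1_len)
}

# activation matrix for all filters at once: (N * L1) x F1, rows ordered
# sample-fastest within offset
.filter_activations <- function(model, positives) {
  seqs <- if (is.data.frame(positives)) positives$sequence else positives
  stopifnot(all(nchar(seqs) == model$config$input_len))
  X <- .encode_batch(seqs)
  d <- model$config$dims
  n <- length(seqs)
  M1 <- X[, model$cache$idx1, drop = FALSE]
  dim(M1) <- c(n * d$conv1, 4L * model$config$conv1_len)
  A <- .addcol(M1 %*% model$params$W1, model$params$b1)
  list(A = A, seqs = seqs, n = n, L1 = d$conv1)
}

.threshold_segments <- function(a, seqs, n, L1, klen) {
  thr <- max(a) / 2
  keep <- which(a > thr)                      # strict
  if (!length(keep)) {
    return(data.frame(sample_index = integer(), offset = integer(),
                      subsequence = character(), activation = numeric(),
                      stringsAsFactors = FALSE))
  }
  sample_index <- ((keep - 1L) %% n) + 1L
  offset <- ((keep - 1L) %/% n)               # 0-based
  data.frame(sample_index = sample_index,
             offset = offset,
             subsequence = substr(seqs[sample_index], offset + 1L,
                                  offset + klen),
             activation = a[keep],
             stringsAsFactors = FALSE)
}

#' Build a position weight matrix from activation segments
#'
#' Column `j` holds the frequency of each base at position `j` across the
#' segments. 'N' characters contribute to no channel; each column is
#' renormalized over the bases actually observed (a column with no observed
#' base falls back to the uniform distribution). An optional pseudocount can
#' be added for logo rendering; the default is raw frequencies.
#'
#' @param segments data.frame from [scan_filter_activations()].
#' @param pseudocount Added to every cell of the count matrix (default 0).
#' @return Object of class `filter_motif`: `pwm` (k x 4, columns summing to
#'   1), `n_segments`, `coverage` (distinct contributing samples),
#'   `filter_id` (NA unless set by the caller).
#' @export
build_pwm <- function(segments, pseudocount = 0) {
  if (nrow(segments) == 0L) stop("cannot build a PWM from zero segments")
  klen <- nchar(segments$subsequence[1])
  ch <- matrix(unlist(strsplit(segments$subsequence, "", fixed = TRUE),
                      use.names = FALSE),
               nrow = nrow(segments), byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  counts <- sapply(bases, function(b) colSums(ch == b)) + pseudocount
  counts <- matrix(counts, nrow = klen, dimnames = list(NULL, bases))
  tot <- rowSums(counts)
  pwm <- counts / ifelse(tot == 0, 1, tot)
  pwm[tot == 0, ] <- 0.25
  structure(list(filter_id = NA_integer_, pwm = pwm,
                 n_segments = nrow(segments),
                 coverage = length(unique(segments$sample_index))),
            class = "filter_motif")
}

#' @export
print.filter_motif <- function(x, ...) {
  cat("filter_motif", if (!is.na(x$filter_id)) paste0("#", x$filter_id), ":",
      consensus_string(x$pwm), "(", x$n_segments, "segments,",
      x$coverage, "samples )\n")
  invisible(x)
}

#' Consensus string of a PWM
#'
#' Majority base per column; columns with maximum probability below
#' `ambiguous_below` print as 'N'.
#' @param pwm A k x 4 probability matrix (A,C,G,T columns).
#' @param ambiguous_below Threshold below which a column is called 'N'.
#' @return Character string of length k.
#' @export
consensus_string <- function(pwm, ambiguous_below = 0.5) {
  bases <- c("A", "C", "G", "T")
  paste(apply(pwm, 1, function(p) {
    if (max(p) < ambiguous_below) "N" else bases[which.max(p)]
  }), collapse = "")
}

#' Extract the high-confidence motifs of a trained model
#'
#' Runs the activation scan and PWM conversion for every first-layer filter
#' and keeps motifs whose coverage (number of distinct positive samples
#' contributing at least one segment) exceeds `min_coverage_fraction` of the
#' positive set — the published workflow keeps motifs covering more than 1%
#' of the positives.
#'
#' @param model A trained `psicnn_model`.
#' @param positives Positive samples (data.frame or character vector).
#' @param min_coverage_fraction Coverage cutoff as a fraction of
#'   `length(positives)` (default 0.01).
#' @return List of `filter_motif` objects (possibly empty), each with its
#'   `filter_id` set.
#' @export
high_confidence_motifs <- function(model, positives,
                                   min_coverage_fraction = 0.01) {
  acts <- .filter_activations(model, positives)
  cutoff <- min_coverage_fraction * acts$n
  out <- list()
  for (f in seq_len(model$config$conv1_filters)) {
    seg <- .threshold_segments(acts$A[, f], acts$seqs, acts$n, acts$L1,
                               model$config$conv1_len)
    if (nrow(seg) == 0L) next
    cov <- length(unique(seg$sample_index))
    if (cov <= cutoff) next
    motif <- build_pwm(seg)
    motif$filter_id <- f
    out[[length(out) + 1L]] <- motif
  }
  out
}

#' Best ungapped alignment of a PWM to a consensus string
#'
#' Slides the consensus along the PWM (all offsets at which it fits
#' entirely) and computes, at each offset, the mean per-column Pearson
#' correlation between the PWM column and the one-hot encoding of the
#' consensus base; 'N' consensus positions are skipped. Columns with zero
#' variance on either side contribute 0. Used to quantify recovery of a
#' planted motif.
#'
#' @param pwm A k x 4 probability matrix.
#' @param consensus Consensus string over `{A,C,G,T,N,U}` with
#'   `nchar(consensus) <= k`.
#' @return List: `score` (best mean column correlation), `offset` (0-based
#'   PWM offset of the best alignment).
#' @export
pwm_match_consensus <- function(pwm, consensus) {
  consensus <- gsub("U", "T", toupper(consensus), fixed = TRUE)
  cc <- strsplit(consensus, "", fixed = TRUE)[[1]]
  k <- nrow(pwm); w <- length(cc)
  if (w > k) stop("consensus is longer than the PWM")
  bases <- c("A", "C", "G", "T")
  best <- -Inf; best_off <- 0L
  for (off in 0:(k - w)) {
    rs <- numeric(0)
    for (j in seq_len(w)) {
      if (cc[j] == "N") next
      target <- as.numeric(bases == cc[j])
      col <- pwm[off + j, ]
      r <- if (stats::sd(col) == 0) 0 else stats::cor(col, target)
      rs <- c(rs, r)
    }
    sc <- mean(rs)
    if (sc > best) { best <- sc; best_off <- off }
  }
  list(score = best, offset = best_off)
}

# ---- MEME minimal format ----------------------------------------------------

#' Write motifs in MEME minimal format
#'
#' One `letter-probability matrix` record per motif, alphabet ACGT, uniform
#' background, `nsites` set to the segment count. A zero-motif list yields a
#' valid header-only file.
#'
#' @param motifs List of `filter_motif` objects.
#' @param path Output file.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               "ALPHABET= ACGT", "",
               "strands: +", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (m in motifs) {
    id <- if (is.na(m$filter_id)) "motif" else paste0("filter_", m$filter_id)
    writeLines(sprintf("MOTIF %s", id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      nrow(m$pwm), m$n_segments), con)
    writeLines(apply(m$pwm, 1, function(r) paste(sprintf("%.6f", r),
                                                 collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a MEME minimal motif file written by [write_meme()]
#'
#' @param path MEME minimal file.
#' @return List of `filter_motif` objects (PWMs to the file's printed
#'   precision; `coverage` is not stored in the format and returns NA).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("^MEME version", lines))) {
    stop("not a MEME minimal file: missing version line")
  }
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF ", lines[i])) {
      id <- sub("^MOTIF\\s+", "", lines[i])
      i <- i + 1L
      hdr <- lines[i]
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
      nsites <- as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr))
      rows <- lines[(i + 1L):(i + w)]
      pwm <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
      colnames(pwm) <- c("A", "C", "G", "T")
      fid <- suppressWarnings(as.integer(sub("^filter_", "", id)))
      out[[length(out) + 1L]] <- structure(
        list(filter_id = fid, pwm = pwm, n_segments = nsites,
             coverage = NA_integer_),
        class = "filter_motif")
      i <- i + w + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Write activation segments as TSV
#' @param segments data.frame from [scan_filter_activations()].
#' @param path Output file.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
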