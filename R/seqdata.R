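# ---- reference handling -----------------------------------------------------

#' Normalize a reference to a named DNAStringSet
#'
#' Accepts a FASTA path, a `Biostrings::DNAStringSet`, or a named character
#' vector of sequences. 'U' is tolerated and treated as 'T' downstream.
#' @noRd
.as_reference <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) return(reference)
  if (is.character(reference) && length(reference) == 1L && file.exists(reference)) {
    return(Biostrings::readDNAStringSet(reference))
  }
  if (is.character(reference) && !is.null(names(reference))) {
    return(Biostrings::DNAStringSet(toupper(gsub("U", "T", reference, fixed = TRUE))))
  }
  stop("`reference` must be a FASTA path, a DNAStringSet, or a named character vector")
}

.ref_seq <- function(reference, id) {
  if (!(id %in% names(reference))) {
    stop("sequence id '", id, "' not found in the reference", call. = FALSE)
  }
  as.character(reference[[id]])
}

.revcomp <- function(s) {
  # N-preserving reverse complement on a plain character string
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Extract a width-long window starting at 0-based `start0`, padding with 'N'
# where the window runs off either end of the sequence.
.extract_window <- function(seqchar, start0, width) {
  len <- nchar(seqchar)
  left_pad <- max(0L, -start0)
  from <- max(0L, start0) + 1L                     # 1-based
  to <- min(len, start0 + width)                   # 1-based inclusive
  core <- if (from <= to) substr(seqchar, from, to) else ""
  right_pad <- width - left_pad - nchar(core)
  paste0(strrep("N", left_pad), core, strrep("N", right_pad))
}

# ---- site loading -----------------------------------------------------------

#' Load candidate pseudouridine sites and keep only those on a thymine
#'
#' Reads a BED-like table of genomic/transcriptomic sites and retains the
#' records whose strand-resolved reference base is a thymine (i.e. a uridine
#' in the transcript). All other records are discarded with a message; the
#' discard count is attached as attribute `n_discarded`.
#'
#' Coordinates are 0-based internally. BED input (`*.bed`) is read with
#' \pkg{rtracklayer} and interpreted as standard 0-based half-open intervals;
#' the site position is the interval start. TSV input must have columns
#' `sequence_id`, `position` (0-based), `strand`, and optionally `source`.
#'
#' @param records Path to a `.bed` or `.tsv` file, or a data.frame with
#'   columns `sequence_id`, `position`, `strand` (and optionally `source`).
#' @param reference FASTA path, `DNAStringSet`, or named character vector.
#' @return data.frame with columns `sequence_id`, `position`, `strand`,
#'   `source`; attribute `n_discarded` counts rejected non-thymine records.
#' @export
load_sites <- function(records, reference) {
  reference <- .as_reference(reference)
  df <- .read_site_table(records)

  # hard errors: unknown sequence, malformed coordinates
  for (id in unique(df$sequence_id)) .ref_seq(reference, id)
  lens <- vapply(reference, length, integer(1))[df$sequence_id]
  bad <- which(is.na(df$position) | df$position < 0 | df$position >= lens)
  if (length(bad)) {
    stop("malformed site record at line ", bad[1],
         ": position ", df$position[bad[1]], " outside sequence '",
         df$sequence_id[bad[1]], "'", call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-"))) {
    bad <- which(!(df$strand %in% c("+", "-")))[1]
    stop("malformed site record at line ", bad, ": strand must be '+' or '-'",
         call. = FALSE)
  }

  # strand-resolved base: 'T' on '+', 'A' on '-' (reverse complement of T)
  base <- character(nrow(df))
  for (id in unique(df$sequence_id)) {
    i <- which(df$sequence_id == id)
    s <- .ref_seq(reference, id)
    base[i] <- substring(s, df$position[i] + 1L, df$position[i] + 1L)
  }
  keep <- ifelse(df$strand == "+", base == "T", base == "A")
  n_discarded <- sum(!keep)
  if (n_discarded > 0) {
    message(n_discarded, " of ", nrow(df),
            " site(s) could not be mapped to a thymine and were discarded")
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_discarded") <- n_discarded
  out
}

#' @noRd
.read_site_table <- function(records) {
  if (is.data.frame(records)) {
    df <- records
    if (!all(c("sequence_id", "position", "strand") %in% names(df))) {
      stop("site data.frame needs columns sequence_id, position, strand")
    }
    if (is.null(df$source)) df$source <- ""
    return(data.frame(sequence_id = as.character(df$sequence_id),
                      position = as.integer(df$position),
                      strand = as.character(df$strand),
                      source = as.character(df$source),
                      stringsAsFactors = FALSE))
  }
  if (!is.character(records) || length(records) != 1L || !file.exists(records)) {
    stop("`records` must be a data.frame or an existing file path")
  }
  if (grepl("\\.bed$", records, ignore.case = TRUE)) {
    gr <- rtracklayer::import(records, format = "BED")
    strand <- as.character(BiocGenerics::strand(gr))
    strand[strand == "*"] <- "+"
    return(data.frame(
      sequence_id = as.character(GenomicRanges::seqnames(gr)),
      position = BiocGenerics::start(gr) - 1L,   # back to 0-based
      strand = strand,
      source = if (!is.null(gr$name)) as.character(gr$name) else "",
      stringsAsFactors = FALSE))
  }
  df <- utils::read.delim(records, header = TRUE, stringsAsFactors = FALSE)
  .read_site_table(df)
}

# ---- sample construction ----------------------------------------------------

#' Build positive training samples around validated sites
#'
#' Each site becomes one 101-nt window (`2 * flank + 1`) centered on the
#' candidate uridine, padded with 'N' where the window runs off the sequence.
#' Minus-strand windows are reverse-complemented so every sample reads 5'->3'
#' with the modified base at index `flank` (0-based).
#'
#' `window_start` is the (possibly negative, unclipped) 0-based start of the
#' window on the reference sequence, so the window center is always
#' `window_start + flank` in reference coordinates regardless of strand.
#'
#' @param sites data.frame from [load_sites()].
#' @param reference FASTA path, `DNAStringSet`, or named character vector.
#' @param flank Flanking width on each side (default 50).
#' @return data.frame: `sequence_id`, `window_start`, `strand`, `label` (1),
#'   `sequence`.
#' @export
build_positive_samples <- function(sites, reference, flank = 50L) {
  reference <- .as_reference(reference)
  n <- nrow(sites)
  seqs <- character(n)
  for (id in unique(sites$sequence_id)) {
    i <- which(sites$sequence_id == id)
    s <- .ref_seq(reference, id)
    for (j in i) {
      w <- .extract_window(s, sites$position[j] - flank, 2L * flank + 1L)
      if (sites$strand[j] == "-") w <- .revcomp(w)
      seqs[j] <- w
    }
  }
  center <- substring(seqs, flank + 1L, flank + 1L)
  stopifnot(all(center == "T"))
  data.frame(sequence_id = sites$sequence_id,
             window_start = sites$position - flank,
             strand = sites$strand,
             label = 1L,
             sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Build negative samples from nearest non-overlapping thymines
#'
#' For every positive sample, the `ratio_n` nearest thymines on the same
#' sequence and strand whose own 101-nt windows share no base position with
#' any positive window are selected and labeled 0. Equidistant
#' upstream/downstream candidates resolve to the larger coordinate.
#' Duplicate negatives (same sequence, center, strand) arising from different
#' positives are removed. Positives with fewer than `ratio_n` eligible
#' thymines trigger a warning and contribute what is available.
#'
#' Negative windows may overlap each other; only overlap with positive
#' windows is forbidden.
#'
#' @param positives data.frame from [build_positive_samples()].
#' @param reference FASTA path, `DNAStringSet`, or named character vector.
#' @param ratio_n Negatives requested per positive (PNR 1:`ratio_n`).
#' @return data.frame with the same columns as the positives, `label` 0.
#' @export
build_negative_samples <- function(positives, reference, ratio_n = 1L) {
  reference <- .as_reference(reference)
  flank <- (nchar(positives$sequence[1]) - 1L) %/% 2L
  width <- 2L * flank + 1L
  out <- vector("list", nrow(positives))
  n_short <- 0L

  for (id in unique(positives$sequence_id)) {
    s <- .ref_seq(reference, id)
    pos_here <- positives[positives$sequence_id == id, , drop = FALSE]
    centers <- pos_here$window_start + flank
    # positive windows as closed intervals in 0-based coordinates
    pw <- IRanges::IRanges(start = centers - flank + 1L, end = centers + flank + 1L)

    for (strand in unique(pos_here$strand)) {
      want <- if (strand == "+") "T" else "A"
      tpos <- as.integer(gregexpr(want, s, fixed = TRUE)[[1]])
      tpos <- tpos[tpos > 0] - 1L                   # 0-based thymine positions
      if (!length(tpos)) next
      cand <- IRanges::IRanges(start = tpos - flank + 1L, end = tpos + flank + 1L)
      eligible <- tpos[!IRanges::overlapsAny(cand, pw)]

      rows <- which(positives$sequence_id == id & positives$strand == strand)
      for (r in rows) {
        c0 <- positives$window_start[r] + flank
        if (!length(eligible)) {
          warning("no eligible negative thymine for positive at ", id, ":", c0,
                  " (", strand, ")", call. = FALSE)
          n_short <- n_short + 1L
          next
        }
        ord <- order(abs(eligible - c0), -eligible)   # ties -> downstream
        take <- eligible[ord[seq_len(min(ratio_n, length(eligible)))]]
        if (length(take) < ratio_n) {
          warning("only ", length(take), " of ", ratio_n,
                  " eligible negatives for positive at ", id, ":", c0, call. = FALSE)
        }
        seqs <- vapply(take, function(tp) {
          w <- .extract_window(s, tp - flank, width)
          if (strand == "-") .revcomp(w) else w
        }, character(1))
        out[[r]] <- data.frame(sequence_id = id,
                               window_start = take - flank,
                               strand = strand,
                               label = 0L,
                               sequence = seqs,
                               stringsAsFactors = FALSE)
      }
    }
  }
  neg <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(neg)) {
    return(data.frame(sequence_id = character(), window_start = integer(),
                      strand = character(), label = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  key <- paste(neg$sequence_id, neg$window_start, neg$strand)
  neg <- neg[!duplicated(key), , drop = FALSE]
  rownames(neg) <- NULL
  neg
}

# ---- one-hot encoding -------------------------------------------------------

#' One-hot encode a nucleotide sequence
#'
#' Channels are ordered A, C, G, T. 'N' encodes to an all-zero row; 'U' is
#' normalized to 'T'; lowercase is accepted. Any other character is a hard
#' error naming the offending position.
#'
#' @param sequence A single string over `{A,C,G,T,U,N}` (case-insensitive).
#' @return An `nchar(sequence) x 4` binary matrix with colnames A,C,G,T.
#' @export
one_hot_encode <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- gsub("U", "T", toupper(sequence), fixed = TRUE)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!(ch %in% c("A", "C", "G", "T", "N")))
  if (length(bad)) {
    stop("illegal character '", ch[bad[1]], "' at position ", bad[1],
         " of the input sequence", call. = FALSE)
  }
  m <- cbind(A = ch == "A", C = ch == "C", G = ch == "G", T = ch == "T") * 1
  m
}

#' Decode a one-hot matrix back to a sequence string
#'
#' All-zero rows decode to 'N'.
#' @param m An `L x 4` binary matrix in A,C,G,T channel order.
#' @return Character string of length `L`.
#' @export
one_hot_decode <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 4L)
  bases <- c("A", "C", "G", "T")
  paste(apply(m, 1, function(r) if (sum(r) == 0) "N" else bases[which.max(r)]),
        collapse = "")
}

# Fast batch encoding used internally by the network: N x (4 * L) matrix whose
# columns are the column-major flattening of the L x 4 one-hot matrix
# (positions fastest within each channel).
.encode_batch <- function(sequences) {
  sequences <- gsub("U", "T", toupper(sequences), fixed = TRUE)
  L <- nchar(sequences[1])
  stopifnot(all(nchar(sequences) == L))
  ch <- matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
               nrow = length(sequences), byrow = TRUE)
  bad <- !(ch %in% c("A", "C", "G", "T", "N"))
  if (any(bad)) {
    w <- which(bad)[1]
    stop("illegal character '", ch[w], "' in input sequences", call. = FALSE)
  }
  cbind((ch == "A") * 1, (ch == "C") * 1, (ch == "G") * 1, (ch == "T") * 1)
}

# ---- cross-validation folds -------------------------------------------------

#' Randomly assign samples to k folds of near-equal size
#'
#' Deterministic for a fixed seed; folds partition the samples and sizes
#' differ by at most one.
#'
#' @param n Number of samples (or a data.frame, whose rows are counted).
#' @param k Fold count (default 10).
#' @param seed Integer RNG seed.
#' @return Object of class `fold_assignment`: list with `fold` (integer in
#'   `1..k` per sample), `k`, `n`, `seed`.
#' @export
make_folds <- function(n, k = 10L, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold <- integer(n)
  fold[sample.int(n)] <- rep(seq_len(k), times = sizes)
  structure(list(fold = fold, k = k, n = n, seed = as.integer(seed)),
            class = "fold_assignment")
}

# Preserve the caller's RNG state so seeded package internals do not
# side-effect user code.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# ---- sample table I/O -------------------------------------------------------

#' Write a sample table as TSV
#' @param samples data.frame with columns `sequence_id`, `window_start`,
#'   `strand`, `label`, `sequence`.
#' @param path Output file.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample table written by [write_samples()]
#' @param path TSV file.
#' @return data.frame of labeled samples.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence_id", "window_start", "strand", "label", "sequence")
  if (!all(need %in% names(df))) {
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  }
  df
}
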