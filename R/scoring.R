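# Transcriptome-wide application of a trained model: per-uridine lPPS,
# per-transcript tPPS, and per-variant AFCP.

#' Score every thymine of a transcript (lPPS)
#'
#' Extracts the 101-nt window around each thymine ('N'-padded where the
#' window runs off the transcript) and predicts its local pseudouridylation
#' potential score. The given strand is scored as-is: supply sequences in
#' transcript orientation.
#'
#' @param model A trained `psicnn_model`.
#' @param sequence_id Identifier recorded in the output.
#' @param sequence Transcript sequence (string, `DNAString`, or anything
#'   coercible by `as.character`); 'U' is normalized to 'T'.
#' @return data.frame: `sequence_id`, `position` (0-based thymine offset),
#'   `lpps`. Empty for sequences without thymines.
#' @export
scan_transcript <- function(model, sequence_id, sequence) {
  stopifnot(inherits(model, "psicnn_model"))
  s <- gsub("U", "T", toupper(as.character(sequence)), fixed = TRUE)
  flank <- (model$config$input_len - 1L) %/% 2L
  tpos <- as.integer(gregexpr("T", s, fixed = TRUE)[[1]])
  tpos <- tpos[tpos > 0] - 1L                     # 0-based
  if (!length(tpos) || !nzchar(s)) {
    return(data.frame(sequence_id = character(), position = integer(),
                      lpps = numeric(), stringsAsFactors = FALSE))
  }
  padded <- paste0(strrep("N", flank), s, strrep("N", flank))
  windows <- substring(padded, tpos + 1L, tpos + 2L * flank + 1L)
  data.frame(sequence_id = sequence_id, position = tpos,
             lpps = predict(model, windows), stringsAsFactors = FALSE)
}

#' Score every transcript of a FASTA or DNAStringSet
#'
#' @param model A trained `psicnn_model`.
#' @param sequences FASTA path, `DNAStringSet`, or named character vector.
#' @return Combined [scan_transcript()] data.frame over all records.
#' @export
scan_transcripts <- function(model, sequences) {
  ref <- .as_reference(sequences)
  do.call(rbind, lapply(names(ref), function(id) {
    scan_transcript(model, id, ref[[id]])
  }))
}

#' Partition site scores into called and uncalled sites
#'
#' A site is called pseudouridylated when `lpps > threshold` (strict, so a
#' score exactly at the threshold is not called).
#'
#' @param scores data.frame from [scan_transcript()].
#' @param threshold Call threshold (default 0.5, matching the tPPS
#'   indicator).
#' @return List with data.frames `psi` and `non_psi`; together they
#'   partition the input.
#' @export
call_sites <- function(scores, threshold = 0.5) {
  is_psi <- scores$lpps > threshold
  list(psi = scores[is_psi, , drop = FALSE],
       non_psi = scores[!is_psi, , drop = FALSE])
}

#' Transcript pseudouridylation potential score (tPPS)
#'
#' For a transcript of length `L` with `K` thymines of which `num_psi` score
#' above 0.5 and `num_u` do not,
#' `tPPS = (num_psi / num_u) / (K / L)`:
#' the predicted-to-unmodified uridine ratio, normalized by the transcript's
#' overall thymine density so uridine-rich transcripts are not favored.
#' Undefined (flagged) when the transcript has no thymines or when every
#' thymine is called (num_u = 0); zero when no thymine is called.
#'
#' @param scores data.frame from [scan_transcript()] for one transcript.
#' @param L Transcript length (>= 1); every score position must be < `L`.
#' @param threshold Indicator threshold (default 0.5).
#' @return Object of class `transcript_score`: `sequence_id`, `tpps`,
#'   `defined`, `K`, `num_psi`, `num_u`, `L`.
#' @export
tpps <- function(scores, L, threshold = 0.5) {
  stopifnot(L >= 1)
  if (nrow(scores) && any(scores$position >= L)) {
    stop("score position ", max(scores$position),
         " is outside a transcript of length ", L)
  }
  K <- nrow(scores)
  num_psi <- sum(scores$lpps > threshold)
  num_u <- K - num_psi
  defined <- K > 0L && num_u > 0L
  val <- if (defined) (num_psi / num_u) / (K / L) else NA_real_
  structure(list(sequence_id = if (K) scores$sequence_id[1] else NA_character_,
                 tpps = val, defined = defined,
                 K = K, num_psi = num_psi, num_u = num_u, L = as.integer(L)),
            class = "transcript_score")
}

#' @export
print.transcript_score <- function(x, ...) {
  cat(sprintf("tPPS[%s] = %s  (K=%d, num_psi=%d, num_u=%d, L=%d%s)\n",
              x$sequence_id,
              ifelse(x$defined, sprintf("%.4f", x$tpps), "undefined"),
              x$K, x$num_psi, x$num_u, x$L,
              ifelse(x$defined, "", "; flagged")))
  invisible(x)
}

#' tPPS for every transcript of a reference
#'
#' @param model A trained `psicnn_model`.
#' @param sequences FASTA path, `DNAStringSet`, or named character vector.
#' @param threshold Indicator threshold.
#' @return data.frame: `sequence_id`, `K`, `num_psi`, `num_u`, `L`, `tpps`,
#'   `defined`.
#' @export
tpps_table <- function(model, sequences, threshold = 0.5) {
  ref <- .as_reference(sequences)
  rows <- lapply(names(ref), function(id) {
    sc <- scan_transcript(model, id, ref[[id]])
    t <- tpps(sc, length(ref[[id]]), threshold)
    data.frame(sequence_id = id, K = t$K, num_psi = t$num_psi,
               num_u = t$num_u, L = t$L, tpps = t$tpps, defined = t$defined,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- variants ---------------------------------------------------------------

#' Read a variant table (TSV or VCF)
#'
#' TSV input needs columns `variant_id`, `sequence_id`, `position` (0-based),
#' `major_allele`, `minor_allele`, and optionally `maf`. VCF input (`*.vcf`)
#' is parsed with \pkg{vcfR}: REF is the major allele, the first ALT the
#' minor allele, POS is converted to 0-based; non-SNV records are dropped
#' with a message.
#'
#' @param path Variant file.
#' @return data.frame of variant records.
#' @export
read_variants <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    alt1 <- sub(",.*$", "", fix$ALT)
    snv <- nchar(fix$REF) == 1L & nchar(alt1) == 1L
    if (any(!snv)) message(sum(!snv), " non-SNV record(s) dropped")
    fix <- fix[snv, , drop = FALSE]
    id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                 paste0(fix$CHROM, ":", fix$POS), fix$ID)
    return(data.frame(variant_id = id,
                      sequence_id = fix$CHROM,
                      position = as.integer(fix$POS) - 1L,
                      major_allele = fix$REF,
                      minor_allele = alt1[snv],
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "sequence_id", "position", "major_allele",
            "minor_allele")
  if (!all(need %in% names(df))) {
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Allele fold change of pseudouridylation potential (AFCP)
#'
#' For each SNV, builds the major-allele sequence (which must equal the
#' reference — a mismatch is a hard error naming both bases) and the
#' minor-allele sequence, picks the target uridine as the thymine nearest to
#' the variant position (ties broken downstream, i.e. larger coordinate)
#' that is 'T' in BOTH allele sequences and within `flank` nt of the
#' variant, scores the 101-nt windows centered on it under both alleles, and
#' reports `afcp = log2((lpps_major + eps) / (lpps_minor + eps))`. Swapping
#' the alleles negates the score exactly. Variants with no eligible thymine
#' are kept in the output with an explicit `skip_reason` and NA scores.
#'
#' A positive AFCP means the minor allele lowers the pseudouridylation
#' potential of its nearest uridine.
#'
#' @param model A trained `psicnn_model`.
#' @param variants data.frame from [read_variants()] (or of the same shape).
#' @param reference FASTA path, `DNAStringSet`, or named character vector.
#' @param eps Stabilizer inside the log ratio (default 1e-6).
#' @param flank Maximum distance from the variant to the target uridine and
#'   window flank (default 50).
#' @return data.frame: `variant_id`, `sequence_id`, `position`,
#'   `target_position`, `lpps_major`, `lpps_minor`, `afcp`, `skip_reason`.
#' @export
afcp <- function(model, variants, reference, eps = 1e-6, flank = 50L) {
  stopifnot(inherits(model, "psicnn_model"))
  reference <- .as_reference(reference)
  n <- nrow(variants)
  out <- data.frame(variant_id = variants$variant_id,
                    sequence_id = variants$sequence_id,
                    position = variants$position,
                    target_position = NA_integer_,
                    lpps_major = NA_real_, lpps_minor = NA_real_,
                    afcp = NA_real_, skip_reason = "",
                    stringsAsFactors = FALSE)
  width <- 2L * flank + 1L

  for (i in seq_len(n)) {
    v <- variants[i, ]
    stopifnot(v$major_allele %in% c("A", "C", "G", "T"),
              v$minor_allele %in% c("A", "C", "G", "T"),
              v$major_allele != v$minor_allele)
    s <- .ref_seq(reference, v$sequence_id)
    ref_base <- substring(s, v$position + 1L, v$position + 1L)
    if (ref_base != v$major_allele) {
      stop("variant ", v$variant_id, ": reference base '", ref_base,
           "' does not match the major allele '", v$major_allele, "'",
           call. = FALSE)
    }
    minor_s <- s
    substr(minor_s, v$position + 1L, v$position + 1L) <- v$minor_allele

    lo <- max(0L, v$position - flank)
    hi <- min(nchar(s) - 1L, v$position + flank)
    span <- lo:hi
    both_t <- substring(s, span + 1L, span + 1L) == "T" &
      substring(minor_s, span + 1L, span + 1L) == "T"
    cand <- span[both_t]
    if (!length(cand)) {
      out$skip_reason[i] <- "no thymine shared by both alleles within flank"
      next
    }
    target <- cand[order(abs(cand - v$position), -cand)][1]  # ties downstream
    w_major <- .extract_window(s, target - flank, width)
    w_minor <- .extract_window(minor_s, target - flank, width)
    p <- predict(model, c(w_major, w_minor))
    out$target_position[i] <- target
    out$lpps_major[i] <- p[1]
    out$lpps_minor[i] <- p[2]
    # written as a difference of logs so allele swap negates bit-exactly
    out$afcp[i] <- log2(p[1] + eps) - log2(p[2] + eps)
  }
  out
}
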