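# Seeded synthetic data with planted pseudouridylation contexts, so every
# other module is testable end-to-end without any external download. The
# default planted consensi are the DNA renderings of the PUS4 and PUS7
# recognition contexts: GT[T]CNA and TG[T]AG, each with the modified uridine
# (marked index, 0-based) at position 2.

#' Configuration for the synthetic planted-motif generator
#'
#' @param n_pos,n_neg Positive/negative sample counts (1000/1000).
#' @param motifs List of planted motifs, each `list(consensus =, psi_index =)`
#'   with a 0-based `psi_index` pointing at a 'T' of the consensus ('N' is
#'   the IUPAC any-base wildcard). Defaults to the PUS4 context `GTTCNA`
#'   (psi_index 2) and the PUS7 context `TGTAG` (psi_index 2).
#' @param embed_prob Probability that a positive actually carries a planted
#'   motif (1 gives noise-free labels).
#' @param jitter Maximum absolute offset of the motif's psi position from the
#'   window center, in `[0, 40]` (default 0). Offsets that would overwrite
#'   the mandatory center thymine with a non-T consensus base are excluded
#'   from the draw, so labels stay noise-free.
#' @param gc_content Background GC fraction (default 0.5, i.e. uniform).
#' @param seed Integer seed; identical configurations generate byte-identical
#'   data.
#' @param window Sample window length (101).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pos = 1000L, n_neg = 1000L,
                             motifs = list(
                               list(consensus = "GTTCNA", psi_index = 2L),
                               list(consensus = "TGTAG", psi_index = 2L)),
                             embed_prob = 1.0, jitter = 0L,
                             gc_content = 0.5, seed = 1L, window = 101L) {
  stopifnot(n_pos >= 1L, n_neg >= 0L, embed_prob >= 0, embed_prob <= 1,
            jitter >= 0L, jitter <= 40L, gc_content > 0, gc_content < 1)
  for (m in motifs) {
    cc <- strsplit(toupper(m$consensus), "")[[1]]
    if (any(!(cc %in% c("A", "C", "G", "T", "N")))) {
      stop("motif consensus must be over {A,C,G,T,N}: ", m$consensus)
    }
    if (length(cc) > window) stop("motif longer than the sample window")
    if (cc[m$psi_index + 1L] != "T") {
      stop("psi_index ", m$psi_index, " of '", m$consensus,
           "' does not point at a 'T'")
    }
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 motifs = motifs, embed_prob = embed_prob,
                 jitter = as.integer(jitter), gc_content = gc_content,
                 seed = as.integer(seed), window = as.integer(window)),
            class = "synthetic_config")
}

.bg_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                            T = (1 - gc) / 2)

# random background sequences as an n x L character matrix
.bg_chars <- function(n, L, gc) {
  matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE,
                prob = .bg_probs(gc)), nrow = n)
}

# jitter offsets compatible with the center-T invariant for one motif:
# offset d places the motif's psi at center + d; if the motif then covers the
# center, the consensus base landing there must be 'T' or 'N'
.valid_jitter <- function(motif, jitter) {
  cc <- strsplit(toupper(motif$consensus), "")[[1]]
  pi <- motif$psi_index
  ok <- logical(2L * jitter + 1L)
  ds <- -jitter:jitter
  for (i in seq_along(ds)) {
    d <- ds[i]
    covers <- (pi - d) >= 0 && (pi - d) <= (length(cc) - 1L)
    ok[i] <- !covers || cc[pi - d + 1L] %in% c("T", "N")
  }
  ds[ok]
}

# regexes matching any instantiation of the configured consensi
.motif_patterns <- function(config) {
  vapply(config$motifs, function(m) {
    gsub("N", "[ACGT]", toupper(m$consensus), fixed = TRUE)
  }, character(1))
}

#' Generate a labeled synthetic dataset with planted motifs
#'
#' Positives are background windows with the center forced to 'T' and (with
#' probability `embed_prob`) one planted motif whose psi position lands at
#' the center plus a jitter offset; consensus 'N' positions are instantiated
#' uniformly. Negatives are background windows with a center 'T',
#' rejection-sampled until no instantiation of any configured consensus
#' occurs anywhere in the window. Fully deterministic per seed.
#'
#' @param config A [synthetic_config()].
#' @return data.frame of labeled samples (`sequence_id`, `window_start`,
#'   `strand`, `label`, `sequence`) with positives first.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  L <- config$window
  center <- L %/% 2L + 1L                       # 1-based center (0-based 50)
  patterns <- .motif_patterns(config)
  valid_d <- lapply(config$motifs, .valid_jitter, jitter = config$jitter)

  # positives
  ch <- .bg_chars(config$n_pos, L, config$gc_content)
  ch[, center] <- "T"
  embed <- stats::runif(config$n_pos) < config$embed_prob
  which_motif <- sample.int(length(config$motifs), config$n_pos, replace = TRUE)
  for (i in which(embed)) {
    m <- config$motifs[[which_motif[i]]]
    cc <- strsplit(toupper(m$consensus), "")[[1]]
    dset <- valid_d[[which_motif[i]]]
    d <- if (length(dset) == 1L) dset else sample(dset, 1L)
    start <- center + d - m$psi_index           # 1-based motif start
    inst <- cc
    inst[inst == "N"] <- sample(c("A", "C", "G", "T"), sum(inst == "N"),
                                replace = TRUE)
    ch[i, start:(start + length(cc) - 1L)] <- inst
    ch[i, center] <- "T"                        # psi or compatible overlap
  }
  pos_seq <- apply(ch, 1, paste, collapse = "")

  # negatives: motif-free by rejection sampling
  neg_seq <- character(config$n_neg)
  filled <- 0L
  while (filled < config$n_neg) {
    want <- config$n_neg - filled
    chn <- .bg_chars(want, L, config$gc_content)
    chn[, center] <- "T"
    cand <- apply(chn, 1, paste, collapse = "")
    hit <- Reduce(`|`, lapply(patterns, function(p) grepl(p, cand)))
    keep <- cand[!hit]
    if (length(keep)) {
      neg_seq[(filled + 1L):(filled + length(keep))] <- keep
      filled <- filled + length(keep)
    }
  }

  data.frame(
    sequence_id = c(sprintf("synthetic_pos_%d", seq_len(config$n_pos)),
                    sprintf("synthetic_neg_%d", seq_len(config$n_neg))),
    window_start = 0L,
    strand = "+",
    label = rep(c(1L, 0L), c(config$n_pos, config$n_neg)),
    sequence = c(pos_seq, neg_seq),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic transcriptome with planted sites
#'
#' Random background transcripts in which pseudouridylation contexts are
#' planted at known positions (kept at least one window apart so planted
#' windows do not interact). The returned truth table drives scanner-recall
#' checks and the negative-sampling and tPPS workflows.
#'
#' @param n_transcripts Number of transcripts.
#' @param length_range Two-element integer range of transcript lengths.
#' @param planted_site_rate Expected planted sites per nucleotide (sites per
#'   transcript are `rbinom(L, rate)` thinned to non-overlapping positions);
#'   0 plants nothing.
#' @param config A [synthetic_config()] supplying motifs, background
#'   composition, and the seed.
#' @return List: `sequences` (named character vector), `sites` (data.frame
#'   `sequence_id`, `position`, `strand`, `source` — every position is a 'T').
#' @export
generate_transcriptome <- function(n_transcripts, length_range,
                                   planted_site_rate, config) {
  stopifnot(inherits(config, "synthetic_config"),
            length(length_range) == 2L, length_range[1] <= length_range[2],
            planted_site_rate >= 0, planted_site_rate < 0.01)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed + 7L)
  flank <- (config$window - 1L) %/% 2L
  seqs <- character(n_transcripts)
  names(seqs) <- sprintf("synthetic_tx_%d", seq_len(n_transcripts))
  sites <- list()

  for (t in seq_len(n_transcripts)) {
    L <- sample(length_range[1]:length_range[2], 1L)
    ch <- as.vector(.bg_chars(1L, L, config$gc_content))
    n_sites <- stats::rbinom(1L, L, planted_site_rate)
    placed <- integer(); placed_motif <- integer()
    if (n_sites > 0L) {
      # psi positions must leave room for the motif; keep them a full window
      # apart so each planted context sits in otherwise-background sequence
      pop <- seq(flank + 1L, max(flank + 1L, L - flank))
      cand <- sample(pop, min(n_sites * 4L, length(pop)))
      for (p in cand) {
        if (length(placed) >= n_sites) break
        if (length(placed) && min(abs(placed - p)) <= config$window) next
        mi <- sample.int(length(config$motifs), 1L)
        m <- config$motifs[[mi]]
        cc <- strsplit(toupper(m$consensus), "")[[1]]
        start <- p - m$psi_index
        if (start < 1L || start + length(cc) - 1L > L) next
        inst <- cc
        inst[inst == "N"] <- sample(c("A", "C", "G", "T"), sum(inst == "N"),
                                    replace = TRUE)
        ch[start:(start + length(cc) - 1L)] <- inst
        placed <- c(placed, p); placed_motif <- c(placed_motif, mi)
      }
    }
    seqs[t] <- paste(ch, collapse = "")
    if (length(placed)) {
      ord <- order(placed)
      sites[[length(sites) + 1L]] <- data.frame(
        sequence_id = names(seqs)[t], position = placed[ord] - 1L,
        strand = "+", source = "planted", motif = placed_motif[ord],
        stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(sequence_id = character(), position = integer(),
               strand = character(), source = character(),
               motif = integer(), stringsAsFactors = FALSE)
  list(sequences = seqs, sites = sites)
}

#' Generate synthetic variants over a planted transcriptome
#'
#' A stated fraction of variants fall inside planted motif instances and
#' destroy a consensus base (expected large |AFCP|); the rest fall in
#' background at least one window away from any planted site (expected small
#' |AFCP|). The major allele always matches the reference base.
#'
#' @param transcriptome Result of [generate_transcriptome()].
#' @param n_variants Number of variants to draw.
#' @param motif_hit_fraction Fraction placed inside planted motifs.
#' @param seed Integer seed.
#' @param config The [synthetic_config()] used for the transcriptome
#'   (supplies the motif definitions).
#' @return data.frame: `variant_id`, `sequence_id`, `position`,
#'   `major_allele`, `minor_allele`, `in_motif` (truth label).
#' @export
generate_variants <- function(transcriptome, n_variants, motif_hit_fraction,
                              seed, config) {
  stopifnot(motif_hit_fraction >= 0, motif_hit_fraction <= 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  seqs <- transcriptome$sequences
  sites <- transcriptome$sites
  n_hit <- round(n_variants * motif_hit_fraction)
  if (n_hit > 0L && nrow(sites) == 0L) {
    stop("cannot place motif-hitting variants: the transcriptome has no planted sites")
  }
  bases <- c("A", "C", "G", "T")
  rows <- list()

  # variants destroying a planted consensus base (never the psi T itself)
  if (n_hit > 0L) {
    pick <- sites[sample.int(nrow(sites), n_hit, replace = TRUE), , drop = FALSE]
    for (i in seq_len(n_hit)) {
      m <- config$motifs[[pick$motif[i]]]
      cc <- strsplit(toupper(m$consensus), "")[[1]]
      off <- sample(setdiff(which(cc != "N"), m$psi_index + 1L), 1L)
      pos <- pick$position[i] - m$psi_index + off - 1L
      ref <- substring(seqs[[pick$sequence_id[i]]], pos + 1L, pos + 1L)
      alt <- sample(setdiff(bases, ref), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence_id = pick$sequence_id[i], position = pos,
        major_allele = ref, minor_allele = alt, in_motif = TRUE,
        stringsAsFactors = FALSE)
    }
  }

  # background variants, kept a window away from every planted site
  flank <- (config$window - 1L) %/% 2L
  n_bg <- n_variants - n_hit
  tries <- 0L
  while (n_bg > 0L && tries < 10000L) {
    tries <- tries + 1L
    tx <- sample(names(seqs), 1L)
    L <- nchar(seqs[[tx]])
    pos <- sample.int(L, 1L) - 1L
    near <- sites[sites$sequence_id == tx, "position"]
    if (length(near) && min(abs(near - pos)) <= config$window) next
    ref <- substring(seqs[[tx]], pos + 1L, pos + 1L)
    alt <- sample(setdiff(bases, ref), 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      sequence_id = tx, position = pos, major_allele = ref,
      minor_allele = alt, in_motif = FALSE, stringsAsFactors = FALSE)
    n_bg <- n_bg - 1L
  }
  out <- do.call(rbind, rows)
  out <- cbind(variant_id = sprintf("synthvar_%d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  out
}

#' Write a named character vector of sequences as FASTA
#' @param sequences Named character vector.
#' @param path Output FASTA path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Write a site table as 6-column BED
#'
#' 0-based half-open single-base intervals; `source` goes in the name column.
#' @param sites data.frame with `sequence_id`, `position`, `strand` and
#'   optionally `source`.
#' @param path Output BED path.
#' @export
write_bed <- function(sites, path) {
  name <- if (!is.null(sites$source) && any(nzchar(sites$source)))
    sites$source else "."
  df <- data.frame(sites$sequence_id, sites$position, sites$position + 1L,
                   name, 0L, sites$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
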