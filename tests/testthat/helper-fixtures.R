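# Shared fixtures and independent oracles. Everything is generated in code;
# expensive fixtures are memoized for the session.

.fixture_env <- new.env(parent = emptyenv())

random_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# A small trained model on a single planted motif, shared by the motif and
# scoring tests (16 + 8 filters, 6 epochs: enough to separate planted
# positives from background cleanly).
fixture_model <- function() {
  if (!is.null(.fixture_env$model)) return(.fixture_env$model)
  sc <- synthetic_config(n_pos = 300L, n_neg = 300L, embed_prob = 1,
                         jitter = 0L, seed = 3L,
                         motifs = list(list(consensus = "GTTCNA",
                                            psi_index = 2L)))
  ds <- generate_dataset(sc)
  cfg <- model_config(conv1_filters = 16L, conv2_filters = 8L,
                      fc_units = c(16L, 16L), max_epochs = 6L, seed = 2L)
  .fixture_env$synth_config <- sc
  .fixture_env$dataset <- ds
  .fixture_env$model <- train_model(cfg, ds)
  .fixture_env$model
}
fixture_dataset <- function() { fixture_model(); .fixture_env$dataset }
fixture_synth_config <- function() { fixture_model(); .fixture_env$synth_config }

# A tiny config whose training runs in a couple of seconds; any model_config
# field can be overridden.
tiny_config <- function(...) {
  args <- list(conv1_filters = 8L, conv2_filters = 4L, fc_units = c(8L, 8L),
               max_epochs = 2L, seed = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}

# ---- independent oracles ----------------------------------------------------

# AUC by exhaustive pair counting (ties get half credit).
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Direct transcription of the tPPS formula.
tpps_oracle <- function(lpps, L) {
  K <- length(lpps)
  num_psi <- sum(lpps > 0.5)
  num_u <- sum(lpps <= 0.5)
  if (K == 0 || num_u == 0) return(NA_real_)
  (num_psi / num_u) / (K / L)
}

# Brute-force nearest-non-overlapping-thymine negative search for a single
# positive center on one sequence (plus strand), against all positive windows.
negative_oracle <- function(seqchar, pos_centers, center, flank = 50L) {
  tpos <- which(strsplit(seqchar, "")[[1]] == "T") - 1L
  ok <- vapply(tpos, function(t) {
    all(vapply(pos_centers, function(c0) {
      (t + flank) < (c0 - flank) || (t - flank) > (c0 + flank)
    }, logical(1)))
  }, logical(1))
  elig <- tpos[ok]
  if (!length(elig)) return(NA_integer_)
  elig[order(abs(elig - center), -elig)][1]
}
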