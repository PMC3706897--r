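# Independent oracles and small fixture builders used across the suite.

# Smith-Waterman with affine gaps (Gotoh), brute-force quadratic DP.
# Gap of length L costs gap_open + gap_ext * L, matching align_pair().
sw_score_oracle <- function(a, b, match = 1, mismatch = -1, gap_open = 10,
                            gap_ext = 0.5) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (consuming b)
  F_ <- matrix(-Inf, n + 1, m + 1) # gap in b (consuming a)
  best <- 0L
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - gap_ext, H[i, j - 1] - gap_open - gap_ext)
      F_[i, j] <- max(F_[i - 1, j] - gap_ext, H[i - 1, j] - gap_open - gap_ext)
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F_[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Exhaustive microhomology search over all k in [0, max_len].
mh_oracle <- function(deleted, left, right, max_len = 40) {
  best <- 0L
  for (k in seq_len(min(max_len, nchar(deleted)))) {
    if (k <= nchar(right) && substr(deleted, 1, k) == substr(right, 1, k))
      best <- max(best, k)
    if (k <= nchar(left) &&
        substr(deleted, nchar(deleted) - k + 1, nchar(deleted)) ==
        substr(left, nchar(left) - k + 1, nchar(left)))
      best <- max(best, k)
  }
  best
}

# Brute-force substring occurrence count (both strands) of `word` in a set
# of sequences.
count_occurrences <- function(word, seqs) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(word)))
  sum(vapply(seqs, function(s) {
    f <- gregexpr(word, s, fixed = TRUE)[[1]]
    r <- gregexpr(rc, s, fixed = TRUE)[[1]]
    sum(f > 0) + sum(r > 0)
  }, numeric(1)))
}

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A small designed genome + array shared by several tests.
small_design <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- generate_reference(n_contigs = 6, contig_length = 20000, seed = 3)
      d <- design_array(ref)
      cache <<- list(ref = ref, design = d)
    }
    cache
  }
})

# A fragment-scale PAV/duplication panel on the small design.
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sd <- small_design()
      fr <- sd$design$fragments
      set.seed(10)
      sel <- fr[sample(nrow(fr), 8), ]
      specs <- data.frame(contig = sel$contig,
                          position = pmax(0, sel$start - 50),
                          type = c(rep("deletion", 6), rep("duplication", 2)),
                          size = (sel$end - sel$start) + 100,
                          mechanism = "none", genotypes = "g1")
      panel <- spike_variants(sd$ref, specs, seed = 5)
      cache <<- list(panel = panel, design = sd$design,
                     pav_fragments = sel$fragment_id[1:6],
                     dup_fragments = sel$fragment_id[7:8])
    }
    cache
  }
})
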