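# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific random seed from a global seed
#'
#' A stable 32-bit hash of `label` is combined with `seed` so that every
#' stochastic stage of a run draws from its own reproducible stream while the
#' whole pipeline is controlled by a single integer.
#'
#' @param seed Integer global seed.
#' @param label Character scalar naming the stream (e.g. a stage name).
#' @return An integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L, is.numeric(seed))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483629
  as.integer((h + as.numeric(seed)) %% 2147483629)
}

# Uniform random DNA string of length n with the given GC fraction.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Reverse complement for a character vector of DNA strings.
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Longest shared prefix of two strings, optionally capped.
common_prefix_length <- function(a, b, cap = Inf) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  n <- min(length(ra), length(rb), cap)
  if (n == 0L) return(0L)
  neq <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (!length(neq)) as.integer(n) else neq[1L] - 1L
}

# Longest shared suffix of two strings, optionally capped.
common_suffix_length <- function(a, b, cap = Inf) {
  ra <- rev(charToRaw(a))
  rb <- rev(charToRaw(b))
  n <- min(length(ra), length(rb), cap)
  if (n == 0L) return(0L)
  neq <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (!length(neq)) as.integer(n) else neq[1L] - 1L
}

assert_dna <- function(seqs, what = "sequence") {
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T} (first offender: %s)",
                 what, names(seqs)[bad][1] %||% which(bad)[1]), call. = FALSE)
  }
  invisible(TRUE)
}

# 0-based half-open interval overlap length.
interval_overlap <- function(a1, a2, b1, b2) {
  pmax(0, pmin(a2, b2) - pmax(a1, b1))
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "")
}
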