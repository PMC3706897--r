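# Breakpoint-signature classification of insertions/deletions.
#
# Deletions arising from double-strand-break repair leave diagnostic
# sequence signatures at the junction: single-strand annealing (SSA) leaves a
# short motif bordering the breakpoint that is repeated at the other end
# inside the deleted region; synthesis-dependent strand annealing (SDSA) can
# copy non-homologous "filler" sequence into the junction; replication
# slippage produces 1-6 bp indels whose sequence is duplicated in the
# immediate flank.

#' Microhomology length at a deletion junction
#'
#' Returns the length of the longest motif (capped at `max_len`) that borders
#' the breakpoint and is repeated at the other end inside the deleted
#' sequence: the maximum of (a) the longest prefix of the deleted sequence
#' that is also a prefix of the right flank and (b) the longest suffix of the
#' deleted sequence that is also a suffix of the left flank.
#'
#' @param deleted_seq Deleted (or inserted) sequence, length >= 1.
#' @param left_flank,right_flank Flanking sequences immediately outside the
#'   indel.
#' @param max_len Cap on the reported motif length.
#' @return Integer in `[0, max_len]`.
#' @export
microhomology_length <- function(deleted_seq, left_flank, right_flank,
                                 max_len = 40) {
  if (!nzchar(deleted_seq)) stop("deleted_seq must be non-empty")
  k_left <- common_prefix_length(deleted_seq, right_flank, cap = max_len)
  k_right <- common_suffix_length(deleted_seq, left_flank, cap = max_len)
  max(k_left, k_right)
}

#' Detect a template-slippage signature
#'
#' True when the indel is 1-6 bp and its complete sequence is repeated
#' perfectly in the immediately adjacent flank (left or right).
#'
#' @param seq Indel sequence.
#' @param left_flank,right_flank Immediate flanks.
#' @param max_size Maximum slippage size (default 6 bp).
#' @return List with `slippage` (logical) and `unit` (the repeated unit, or
#'   `""`).
#' @export
detect_template_slippage <- function(seq, left_flank, right_flank,
                                     max_size = 6) {
  n <- nchar(seq)
  if (n < 1 || n > max_size) return(list(slippage = FALSE, unit = ""))
  right_ok <- nchar(right_flank) >= n && substr(right_flank, 1L, n) == seq
  ln <- nchar(left_flank)
  left_ok <- ln >= n && substr(left_flank, ln - n + 1L, ln) == seq
  list(slippage = right_ok || left_ok, unit = if (right_ok || left_ok) seq else "")
}

#' Detect non-homologous filler sequence in a replacement
#'
#' A replacement record carries both a reference-only (deleted) and a
#' query-only (inserted) segment. The inserted segment is called filler when
#' it is at least `min_filler` bp and cannot be aligned to the local
#' reference context (deleted segment plus both flanks): its best local
#' alignment covers at most `max_identity` percent of its bases.
#'
#' @param seq_ins Query-only (inserted) sequence; `""` for pure deletions.
#' @param seq_del Reference-only (deleted) sequence.
#' @param left_flank,right_flank Reference flanks.
#' @param min_filler Minimum filler length (bp).
#' @param max_identity Maximum percent of filler bases matched in the best
#'   local alignment against the context for the segment to still count as
#'   non-homologous.
#' @return List with `filler` (logical) and `filler_length`.
#' @export
detect_filler <- function(seq_ins, seq_del, left_flank, right_flank,
                          min_filler = 5, max_identity = 60) {
  if (!nzchar(seq_ins) || !nzchar(seq_del))  # not a replacement
    return(list(filler = FALSE, filler_length = 0L))
  if (nchar(seq_ins) < min_filler)
    return(list(filler = FALSE, filler_length = 0L))
  context <- paste0(left_flank, seq_del, right_flank)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(seq_ins),
                                       Biostrings::DNAString(context),
                                       type = "local", substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 2)
  pct <- 100 * Biostrings::nmatch(aln) / nchar(seq_ins)
  list(filler = pct <= max_identity,
       filler_length = if (pct <= max_identity) nchar(seq_ins) else 0L)
}

classify_one <- function(side, seq_del, seq_ins, left, right,
                         min_filler = 5, max_identity = 60, max_len = 40,
                         slippage_max = 6) {
  own_seq <- if (side == "insertion") seq_ins else seq_del
  mh <- microhomology_length(own_seq, left, right, max_len = max_len)
  slip <- if (side == "replacement") list(slippage = FALSE, unit = "") else
    detect_template_slippage(own_seq, left, right, max_size = slippage_max)
  if (slip$slippage) {
    return(list(class = "slippage", signature_length = 0L, filler_length = 0L,
                slippage_unit = slip$unit, microhomology = mh))
  }
  fil <- detect_filler(seq_ins, seq_del, left, right,
                       min_filler = min_filler, max_identity = max_identity)
  if (fil$filler) {
    return(list(class = "SDSA", signature_length = 0L,
                filler_length = fil$filler_length, slippage_unit = "",
                microhomology = mh))
  }
  if (mh >= 2 && mh <= max_len) {
    return(list(class = "SSA", signature_length = mh, filler_length = 0L,
                slippage_unit = "", microhomology = mh))
  }
  list(class = "unknown", signature_length = 0L, filler_length = 0L,
       slippage_unit = "", microhomology = mh)
}

#' Classify the formation mechanism of indels
#'
#' Applies the signature detectors with fixed precedence: template slippage,
#' then SDSA (filler), then SSA (2-40 bp breakpoint microhomology), else
#' unknown. Classification is a pure function of the record.
#'
#' @param indels Indel table as produced by [extract_indels()] or
#'   [truth_indel_records()]: columns `indel_id`, `side`, `seq_del`,
#'   `seq_ins`, `flank_left`, `flank_right`.
#' @param min_filler,max_identity Passed to [detect_filler()].
#' @param max_len Microhomology cap, passed to [microhomology_length()].
#' @param slippage_max Maximum slippage size.
#' @return `data.frame` with `indel_id`, `class` (`SSA`, `SDSA`, `slippage`,
#'   `unknown`), `signature_length`, `filler_length`, `slippage_unit` and
#'   `microhomology`.
#' @export
classify_mechanism <- function(indels, min_filler = 5, max_identity = 60,
                               max_len = 40, slippage_max = 6) {
  stopifnot(all(c("side", "seq_del", "seq_ins", "flank_left", "flank_right")
                %in% names(indels)))
  rows <- lapply(seq_len(nrow(indels)), function(i) {
    classify_one(indels$side[i], indels$seq_del[i], indels$seq_ins[i],
                 indels$flank_left[i], indels$flank_right[i],
                 min_filler = min_filler, max_identity = max_identity,
                 max_len = max_len, slippage_max = slippage_max)
  })
  data.frame(indel_id = indels$indel_id %||% seq_len(nrow(indels)),
             class = vapply(rows, `[[`, character(1), "class"),
             signature_length = vapply(rows, `[[`, integer(1), "signature_length"),
             filler_length = vapply(rows, function(r) as.integer(r$filler_length), integer(1)),
             slippage_unit = vapply(rows, `[[`, character(1), "slippage_unit"),
             microhomology = vapply(rows, function(r) as.integer(r$microhomology), integer(1)),
             stringsAsFactors = FALSE)
}

# Vectorized longest-common-prefix length of two string vectors (monotone
# binary search; cap <= 64).
vec_prefix_len <- function(a, b, cap) {
  lo <- integer(length(a))
  hi <- rep.int(as.integer(cap), length(a))
  while (any(lo < hi)) {
    mid <- (lo + hi + 1L) %/% 2L
    ok <- substr(a, 1L, mid) == substr(b, 1L, mid)
    lo[ok] <- mid[ok]
    hi[!ok] <- mid[!ok] - 1L
  }
  lo
}

str_rev <- function(x) {
  as.character(Biostrings::reverse(Biostrings::DNAStringSet(x)))
}

#' Random-breakpoint null distribution of microhomology signatures
#'
#' Places the observed indel sizes at uniform random positions in the given
#' genome and records, per simulation, how many junctions carry 0, 1-2 or >2
#' bp of breakpoint microhomology. This is the chance expectation against
#' which observed SSA-like signatures are tested.
#'
#' @param genome A `cgh_genome` or named character vector of contig
#'   sequences.
#' @param sizes Integer vector of observed indel sizes (one simulated indel
#'   per size per simulation).
#' @param n_sim Number of simulations (>= 1000 recommended for inference).
#' @param seed Integer seed.
#' @param max_len Microhomology cap.
#' @return Object of class `indel_null`: list with `n_sim`, `sizes`,
#'   `class_counts` (`n_sim` x 3 matrix, columns `mh0`, `mh1_2`, `mh_gt2`),
#'   `sig_hist` (aggregate histogram over 0..`max_len`) and `seed`.
#' @export
random_indel_null <- function(genome, sizes, n_sim, seed, max_len = 40) {
  contigs <- if (inherits(genome, "cgh_genome")) genome$contigs else genome
  sizes <- as.integer(sizes)
  if (any(sizes < 1)) stop("indel sizes must be >= 1")
  lens <- nchar(contigs)
  if (max(sizes) + 2 * max_len + 2 > max(lens))
    stop("an indel size (plus flanks) exceeds every contig length")
  set.seed(derive_seed(seed, "indel-null"))

  n_per <- length(sizes)
  counts <- matrix(0L, nrow = n_sim, ncol = 3,
                   dimnames = list(NULL, c("mh0", "mh1_2", "mh_gt2")))
  hist_acc <- integer(max_len + 1L)

  chunk <- max(1L, min(n_sim, as.integer(ceiling(2e5 / n_per))))
  done <- 0L
  while (done < n_sim) {
    nb <- min(chunk, n_sim - done)
    N <- nb * n_per
    sz <- rep.int(sizes, nb)
    ci <- integer(N)
    # sample contig weighted by eligible length, per size class
    for (s in unique(sz)) {
      idx <- which(sz == s)
      w <- pmax(lens - s - 2L * max_len, 0)
      if (all(w == 0)) stop(sprintf("size %d does not fit in any contig", s))
      ci[idx] <- sample.int(length(contigs), length(idx), replace = TRUE, prob = w)
    }
    # 1-based start of the deleted segment, leaving max_len of flank each side
    p <- max_len + 1L +
      floor(runif(N) * pmax(lens[ci] - sz - 2L * max_len + 1L, 1L))
    seqv <- contigs[ci]
    del_pref <- substr(seqv, p, p + pmin(sz, max_len) - 1L)
    right <- substr(seqv, p + sz, p + sz + max_len - 1L)
    del_suf_r <- str_rev(substr(seqv, p + pmax(sz - max_len, 0L), p + sz - 1L))
    left_r <- str_rev(substr(seqv, p - max_len, p - 1L))
    mh <- pmax(vec_prefix_len(del_pref, right, max_len),
               vec_prefix_len(del_suf_r, left_r, max_len))
    mh <- matrix(mh, nrow = n_per, ncol = nb)
    counts[done + seq_len(nb), "mh0"] <- colSums(mh == 0L)
    counts[done + seq_len(nb), "mh1_2"] <- colSums(mh == 1L | mh == 2L)
    counts[done + seq_len(nb), "mh_gt2"] <- colSums(mh > 2L)
    hist_acc <- hist_acc + tabulate(as.vector(mh) + 1L, nbins = max_len + 1L)
    done <- done + nb
  }
  structure(list(n_sim = n_sim, sizes = sizes, class_counts = counts,
                 sig_hist = stats::setNames(hist_acc, 0:max_len), seed = seed),
            class = "indel_null")
}

#' @export
print.indel_null <- function(x, ...) {
  cat(sprintf("indel_null: %d simulations of %d indels; mean counts mh0=%.1f, mh1-2=%.1f, mh>2=%.1f\n",
              x$n_sim, length(x$sizes), mean(x$class_counts[, 1]),
              mean(x$class_counts[, 2]), mean(x$class_counts[, 3])))
  invisible(x)
}

#' Observed microhomology class counts
#'
#' Tabulates classified indels into the signature classes used by the
#' enrichment test: no microhomology, 1-2 bp, and >2 bp.
#'
#' @param mechanism Output of [classify_mechanism()] (uses its
#'   `microhomology` column).
#' @return Named integer vector `mh0`, `mh1_2`, `mh_gt2`.
#' @export
observed_signature_counts <- function(mechanism) {
  mh <- mechanism$microhomology
  c(mh0 = sum(mh == 0L), mh1_2 = sum(mh %in% 1:2), mh_gt2 = sum(mh > 2L))
}

#' Monte-Carlo enrichment test of breakpoint signatures
#'
#' Compares observed signature class counts with the random-breakpoint null:
#' `mh_gt2` is tested for over-representation (upper tail), `mh0` and
#' `mh1_2` for under-representation (lower tail), with add-one Monte-Carlo
#' p-values `(1 + #{more extreme simulations}) / (1 + n_sim)`.
#'
#' @param observed Named counts as from [observed_signature_counts()].
#' @param null An `indel_null`.
#' @return `data.frame` with `class`, `observed`, `null_mean`, `direction`
#'   and `p_value`.
#' @export
signature_enrichment_test <- function(observed, null) {
  stopifnot(inherits(null, "indel_null"))
  classes <- c("mh0", "mh1_2", "mh_gt2")
  if (!all(classes %in% names(observed)))
    stop("observed counts must be named mh0, mh1_2, mh_gt2")
  n <- null$n_sim
  p <- vapply(classes, function(cl) {
    sim <- null$class_counts[, cl]
    if (cl == "mh_gt2") (1 + sum(sim >= observed[[cl]])) / (1 + n)
    else (1 + sum(sim <= observed[[cl]])) / (1 + n)
  }, numeric(1))
  data.frame(class = classes,
             observed = as.integer(observed[classes]),
             null_mean = colMeans(null$class_counts)[classes],
             direction = c("under", "under", "over"),
             p_value = as.numeric(p),
             row.names = NULL, stringsAsFactors = FALSE)
}
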