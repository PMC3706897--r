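# Sequence-level CNV confirmation: ortholog search, supercontig
# construction, Smith-Waterman alignment, indel extraction and fragment
# coverage binning.

#' Contigs eligible for sequence-level confirmation
#'
#' A contig is analyzable when it carries at least three fragments and at
#' least one called fragment whose immediate neighbors on both sides are not
#' called: the uncalled flanks anchor the alignment across the variant.
#'
#' @param calls Call table for the genotype under study.
#' @param fragments Fragment table.
#' @return Character vector of contig ids.
#' @export
select_analyzable_contigs <- function(calls, fragments) {
  called <- fragments$fragment_id %in% calls$fragment_id
  keep <- character(0)
  for (ctg in unique(fragments$contig)) {
    i <- which(fragments$contig == ctg)
    i <- i[order(fragments$start[i])]
    if (length(i) < 3) next
    st <- called[i]
    internal <- 2:(length(i) - 1)
    if (any(st[internal] & !st[internal - 1] & !st[internal + 1]))
      keep <- c(keep, ctg)
  }
  keep
}

# Substitution matrix over A,C,G,T,N; N never aligns favorably, so local
# alignments do not cross supercontig spacers.
aln_submat <- function(match = 1, mismatch = -1) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", ] <- m[, "N"] <- 2 * mismatch
  m
}

#' Find orthologous query contigs for a reference contig
#'
#' Best local alignment per query contig (both orientations), retaining hits
#' with identity above `min_identity` percent and at least `min_hit_length`
#' aligned columns, chained along the reference best-identity-first with
#' overlapping reference intervals trimmed.
#'
#' Candidate contigs are pre-screened with exact seed words sampled from the
#' reference, which keeps the search linear in assembly size at the high
#' identity demanded here.
#'
#' @param ref_seq Reference contig sequence (character scalar).
#' @param query_assembly Named character vector of query contigs.
#' @param min_identity Minimum percent identity (strict `>`).
#' @param min_hit_length Minimum alignment length in columns.
#' @param seed_k,seed_every Seed word size and sampling stride of the
#'   candidate pre-screen.
#' @return Object of class `ortholog_match`: `data.frame` (`query_id`,
#'   `orientation`, `ref_start`, `ref_end`, `identity`, `score`), ordered
#'   along the reference; zero rows when no hit qualifies.
#' @export
find_orthologs <- function(ref_seq, query_assembly, min_identity = 95,
                           min_hit_length = 100, seed_k = 21,
                           seed_every = 200) {
  L <- nchar(ref_seq)
  starts <- unique(pmin(seq(1L, max(1L, L - seed_k + 1L), by = seed_every),
                        max(1L, L - seed_k + 1L)))
  seeds <- unique(substring(ref_seq, starts, starts + seed_k - 1L))
  seeds <- c(seeds, revcomp(seeds))
  cand <- names(query_assembly)[vapply(query_assembly, function(q) {
    any(vapply(seeds, grepl, logical(1), x = q, fixed = TRUE))
  }, logical(1))]
  mat <- aln_submat()
  hits <- list()
  for (qid in cand) {
    best <- NULL
    for (ori in c("+", "-")) {
      qs <- if (ori == "+") query_assembly[[qid]] else revcomp(query_assembly[[qid]])
      a <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(qs), Biostrings::DNAString(ref_seq),
        type = "local", substitutionMatrix = mat,
        gapOpening = 10, gapExtension = 0.5)
      if (is.null(best) || BiocGenerics::score(a) > best$score)
        best <- list(aln = a, ori = ori, score = BiocGenerics::score(a))
    }
    a <- best$aln
    ncols <- nchar(as.character(Biostrings::alignedPattern(a)))
    # identity over aligned (non-gap) columns: an indel between orthologs
    # must not disqualify the hit
    naln <- Biostrings::nmatch(a) + Biostrings::nmismatch(a)
    ident <- if (naln > 0) 100 * Biostrings::nmatch(a) / naln else 0
    if (ncols >= min_hit_length && ident > min_identity) {
      sr <- Biostrings::subject(a)
      hits[[length(hits) + 1L]] <- data.frame(
        query_id = qid, orientation = best$ori,
        ref_start = BiocGenerics::start(sr) - 1L,
        ref_end = BiocGenerics::end(sr),
        identity = ident, score = best$score, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(hits)) do.call(rbind, hits) else
    data.frame(query_id = character(0), orientation = character(0),
               ref_start = integer(0), ref_end = integer(0),
               identity = numeric(0), score = numeric(0),
               stringsAsFactors = FALSE)
  if (!nrow(res)) {
    message("no qualifying ortholog hit")
    return(structure(res, class = c("ortholog_match", "data.frame")))
  }
  # chain along the reference, best identity first, trimming overlaps
  res <- res[order(-res$identity, -res$score), , drop = FALSE]
  acc <- res[0, , drop = FALSE]
  for (i in seq_len(nrow(res))) {
    h <- res[i, , drop = FALSE]
    if (nrow(acc)) {
      ov <- interval_overlap(h$ref_start, h$ref_end, acc$ref_start, acc$ref_end)
      if (any(ov > 0.5 * (h$ref_end - h$ref_start))) next
      for (j in which(ov > 0)) {  # trim the new hit's recorded interval
        if (h$ref_start < acc$ref_end[j] && h$ref_end > acc$ref_end[j])
          h$ref_start <- acc$ref_end[j]
        if (h$ref_end > acc$ref_start[j] && h$ref_start < acc$ref_start[j])
          h$ref_end <- acc$ref_start[j]
      }
      if (h$ref_end <= h$ref_start) next
    }
    acc <- rbind(acc, h)
  }
  acc <- acc[order(acc$ref_start), , drop = FALSE]
  rownames(acc) <- NULL
  structure(acc, class = c("ortholog_match", "data.frame"))
}

#' Concatenate chained query contigs into a supercontig
#'
#' Query contigs are oriented and concatenated in reference order, joined by
#' a run of 50 `N`s; alignments never cross the spacer because `N` scores as
#' a strong mismatch.
#'
#' @param match An `ortholog_match`.
#' @param query_assembly Named character vector of query contigs.
#' @param spacer Spacer length (bp).
#' @return List with `seq` (the supercontig) and `map` (`data.frame` of
#'   `query_id`, `orientation`, `super_start`, `super_end`, 0-based
#'   half-open).
#' @export
build_supercontig <- function(match, query_assembly, spacer = 50) {
  if (!nrow(match)) stop("empty ortholog match")
  seqs <- vapply(seq_len(nrow(match)), function(i) {
    s <- query_assembly[[match$query_id[i]]]
    if (match$orientation[i] == "-") revcomp(s) else s
  }, character(1))
  lens <- nchar(seqs)
  super_start <- cumsum(c(0L, head(lens + spacer, -1L)))
  list(seq = paste(seqs, collapse = strrep("N", spacer)),
       map = data.frame(query_id = match$query_id,
                        orientation = match$orientation,
                        super_start = super_start,
                        super_end = super_start + lens,
                        stringsAsFactors = FALSE))
}

#' Optimal local alignment of a reference contig and a query (super)contig
#'
#' Smith-Waterman alignment under affine gap scoring (defaults: match +1,
#' mismatch -1, gap opening 10, gap extension 0.5 per position).
#'
#' @param ref_seq,query_seq Sequences (A/C/G/T/N only).
#' @param match,mismatch,gap_open,gap_ext Scoring parameters.
#' @return Object of class `pairwise_aln`: aligned strings (with `-` gaps),
#'   1-based alignment start positions on each sequence, score, identity,
#'   and the full input sequences (for flank extraction).
#' @export
align_pair <- function(ref_seq, query_seq, match = 1, mismatch = -1,
                       gap_open = 10, gap_ext = 0.5) {
  if (!nzchar(ref_seq) || !nzchar(query_seq)) stop("sequences must be non-empty")
  if (grepl("[^ACGTN]", ref_seq) || grepl("[^ACGTN]", query_seq))
    stop("sequences must contain only A, C, G, T, N")
  a <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ref_seq), Biostrings::DNAString(query_seq),
    type = "local", substitutionMatrix = aln_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_ext)
  ar <- as.character(Biostrings::alignedPattern(a))
  aq <- as.character(Biostrings::alignedSubject(a))
  structure(list(aligned_ref = ar, aligned_query = aq,
                 ref_start = BiocGenerics::start(Biostrings::pattern(a)),
                 query_start = BiocGenerics::start(Biostrings::subject(a)),
                 score = BiocGenerics::score(a),
                 identity = 100 * Biostrings::nmatch(a) / nchar(ar),
                 ref_seq = ref_seq, query_seq = query_seq),
            class = "pairwise_aln")
}

#' @export
print.pairwise_aln <- function(x, ...) {
  cat(sprintf("pairwise_aln: %d columns, score %.1f, identity %.1f%% (ref from %d, query from %d)\n",
              nchar(x$aligned_ref), x$score, x$identity, x$ref_start,
              x$query_start))
  invisible(x)
}

# Per-column bookkeeping of an alignment: ref/query positions (0-based of
# the base at each column, NA in gaps) and gap state.
aln_columns <- function(aln) {
  rch <- strsplit(aln$aligned_ref, "")[[1]]
  qch <- strsplit(aln$aligned_query, "")[[1]]
  rgap <- rch == "-"
  qgap <- qch == "-"
  rpos <- cumsum(!rgap) + (aln$ref_start - 1L)  # 1-based pos of ref base
  qpos <- cumsum(!qgap) + (aln$query_start - 1L)
  list(rch = rch, qch = qch, rgap = rgap, qgap = qgap,
       rpos = ifelse(rgap, NA_integer_, rpos),
       qpos = ifelse(qgap, NA_integer_, qpos),
       aligned = !rgap & !qgap, match = !rgap & !qgap & rch == qch)
}

#' Extract indel records from a pairwise alignment
#'
#' Every gap run becomes a record: a gap in the query string is a deletion
#' in the query (the reference bases are absent), a gap in the reference
#' string is an insertion in the query. A deletion and an insertion
#' separated by fewer than `merge_within` aligned columns merge into one
#' replacement record. Indels inside microhomology tracts are normalized to
#' their leftmost equivalent position so that signature detection is
#' deterministic. Runs within `min_anchor` aligned columns of the alignment
#' edge, and runs whose sequence contains `N` (supercontig spacers), are
#' dropped.
#'
#' @param aln A `pairwise_aln`.
#' @param min_flank Flanks shorter than this are flagged as truncated.
#' @param flank Flank length to record (bp).
#' @param merge_within Maximum aligned columns between opposite-side gap
#'   runs merged into a replacement.
#' @param min_anchor Minimum aligned columns required on both sides of a
#'   run.
#' @return `data.frame` with `indel_id`, `ref_start`, `ref_end`,
#'   `query_start`, `query_end` (0-based half-open), `side`
#'   (`deletion`/`insertion`/`replacement`, in-query perspective), `size`,
#'   `seq_del`, `seq_ins`, `flank_left`, `flank_right`, `flank_truncated`.
#' @export
extract_indels <- function(aln, min_flank = 20, flank = 60, merge_within = 5,
                           min_anchor = 10) {
  cols <- aln_columns(aln)
  state <- ifelse(cols$qgap, 1L, ifelse(cols$rgap, 2L, 0L))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cum_aligned <- cumsum(cols$aligned)
  total_aligned <- cum_aligned[length(cum_aligned)]
  runs <- list()
  for (i in which(r$values != 0L)) {
    s <- starts[i]
    e <- ends[i]
    before <- if (s > 1L) cum_aligned[s - 1L] else 0L
    after <- total_aligned - cum_aligned[e]
    if (before < min_anchor || after < min_anchor) next
    # 0-based coordinates of the gap on both sequences
    rs <- if (r$values[i] == 1L) cols$rpos[s] - 1L else
      (if (s > 1L) max(cols$rpos[seq_len(s - 1L)], na.rm = TRUE) else aln$ref_start - 1L)
    re <- if (r$values[i] == 1L) cols$rpos[e] else rs
    qs <- if (r$values[i] == 2L) cols$qpos[s] - 1L else
      (if (s > 1L) max(cols$qpos[seq_len(s - 1L)], na.rm = TRUE) else aln$query_start - 1L)
    qe <- if (r$values[i] == 2L) cols$qpos[e] else qs
    runs[[length(runs) + 1L]] <- list(
      type = if (r$values[i] == 1L) "deletion" else "insertion",
      col_start = s, col_end = e,
      ref_start = rs, ref_end = re, query_start = qs, query_end = qe)
  }
  # merge opposite-side runs separated by < merge_within aligned columns
  merged <- list()
  i <- 1L
  while (i <= length(runs)) {
    cur <- runs[[i]]
    if (i < length(runs)) {
      nxt <- runs[[i + 1L]]
      between <- cum_aligned[nxt$col_start - 1L] - cum_aligned[cur$col_end]
      if (nxt$type != cur$type && between < merge_within) {
        cur <- list(type = "replacement",
                    col_start = cur$col_start, col_end = nxt$col_end,
                    ref_start = min(cur$ref_start, nxt$ref_start),
                    ref_end = max(cur$ref_end, nxt$ref_end),
                    query_start = min(cur$query_start, nxt$query_start),
                    query_end = max(cur$query_end, nxt$query_end))
        i <- i + 1L
      }
    }
    merged[[length(merged) + 1L]] <- cur
    i <- i + 1L
  }
  out <- list()
  for (run in merged) {
    rs <- run$ref_start; re <- run$ref_end
    qs <- run$query_start; qe <- run$query_end
    # leftmost-normalize pure indels within repeat/microhomology tracts
    if (run$type == "deletion") {
      while (rs > 0 &&
             substr(aln$ref_seq, rs, rs) == substr(aln$ref_seq, re, re)) {
        rs <- rs - 1L; re <- re - 1L; qs <- qs - 1L; qe <- qs
      }
    } else if (run$type == "insertion") {
      while (qs > 0 &&
             substr(aln$query_seq, qs, qs) == substr(aln$query_seq, qe, qe)) {
        qs <- qs - 1L; qe <- qe - 1L; rs <- rs - 1L; re <- rs
      }
    }
    seq_del <- if (re > rs) substr(aln$ref_seq, rs + 1L, re) else ""
    seq_ins <- if (qe > qs) substr(aln$query_seq, qs + 1L, qe) else ""
    if (grepl("N", seq_del, fixed = TRUE) || grepl("N", seq_ins, fixed = TRUE))
      next  # spacer-join artifact, not a genuine indel
    fl <- substr(aln$ref_seq, max(1L, rs - flank + 1L), rs)
    fr <- substr(aln$ref_seq, re + 1L, min(nchar(aln$ref_seq), re + flank))
    out[[length(out) + 1L]] <- data.frame(
      indel_id = NA_character_, ref_start = rs, ref_end = re,
      query_start = qs, query_end = qe, side = run$type,
      size = max(re - rs, qe - qs),
      seq_del = seq_del, seq_ins = seq_ins,
      flank_left = fl, flank_right = fr,
      flank_truncated = nchar(fl) < min_flank | nchar(fr) < min_flank,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(indel_id = character(0), ref_start = integer(0),
               ref_end = integer(0), query_start = integer(0),
               query_end = integer(0), side = character(0), size = integer(0),
               seq_del = character(0), seq_ins = character(0),
               flank_left = character(0), flank_right = character(0),
               flank_truncated = logical(0), stringsAsFactors = FALSE)
  if (nrow(res)) res$indel_id <- sprintf("indel_%03d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

COVERAGE_BINS <- c("0", "0-24", "25-49", "50-74", "75-99", "100")

coverage_bin <- function(percent) {
  ifelse(percent == 0, "0",
  ifelse(percent < 25, "0-24",
  ifelse(percent < 50, "25-49",
  ifelse(percent < 75, "50-74",
  ifelse(percent < 100, "75-99", "100")))))
}

#' Fragment coverage category in the query
#'
#' Percent of fragment bases aligned (non-gap on both sides) in the query,
#' binned as 0 / 0-24 / 25-49 / 50-74 / 75-99 / 100. A fully covered
#' fragment with identity at least 95 percent and no indel longer than 1 bp
#' inside it is flagged as a false-positive call.
#'
#' @param aln A `pairwise_aln` on the fragment's contig.
#' @param fragment One-row fragment table (uses `start`, `end`, contig
#'   coordinates).
#' @param indels Optional indel table from [extract_indels()] on the same
#'   alignment (used for the >1 bp indel check).
#' @return One-row `data.frame` (`fragment_id`, `percent`, `bin`,
#'   `identity`, `false_positive`).
#' @export
fragment_coverage <- function(aln, fragment, indels = NULL) {
  cols <- aln_columns(aln)
  fs <- fragment$start
  fe <- fragment$end
  inside <- !is.na(cols$rpos) & cols$rpos > fs & cols$rpos <= fe
  aligned <- sum(cols$aligned[inside])
  percent <- 100 * aligned / (fe - fs)
  ident <- if (aligned > 0) 100 * sum(cols$match[inside]) / aligned else NA_real_
  big_indel <- FALSE
  if (!is.null(indels) && nrow(indels)) {
    del_hit <- indels$size > 1 &
      ((indels$side != "insertion" &
          interval_overlap(indels$ref_start, indels$ref_end, fs, fe) > 0) |
       (indels$side == "insertion" &
          indels$ref_start > fs & indels$ref_start < fe))
    big_indel <- any(del_hit)
  }
  bin <- coverage_bin(percent)
  data.frame(fragment_id = fragment$fragment_id, percent = percent,
             bin = bin, identity = ident,
             false_positive = bin == "100" && !is.na(ident) &&
               ident >= 95 && !big_indel,
             stringsAsFactors = FALSE)
}

#' Sequence-level confirmation of CNV calls for one genotype
#'
#' Runs the full chain for every analyzable contig: ortholog search against
#' the query assembly, supercontig construction, local alignment, indel
#' extraction and per-fragment coverage binning.
#'
#' @param ref A `cgh_genome`.
#' @param query_assembly Named character vector of query contigs.
#' @param calls Call table for the query genotype.
#' @param fragments Fragment table.
#' @param min_identity Ortholog identity threshold.
#' @return List with `indels` (all records, with a `contig` column),
#'   `coverage` (per-fragment table with call class) and `contigs` (the
#'   analyzable contig ids).
#' @export
confirm_cnv_sequence <- function(ref, query_assembly, calls, fragments,
                                 min_identity = 95) {
  ctgs <- select_analyzable_contigs(calls, fragments)
  indels <- list()
  coverage <- list()
  for (ctg in ctgs) {
    m <- find_orthologs(ref$contigs[[ctg]], query_assembly,
                        min_identity = min_identity)
    if (!nrow(m)) next
    sc <- build_supercontig(m, query_assembly)
    aln <- align_pair(ref$contigs[[ctg]], sc$seq)
    ind <- extract_indels(aln)
    if (nrow(ind)) {
      ind$contig <- ctg
      indels[[ctg]] <- ind
    }
    fr <- fragments[fragments$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(fr))) {
      cv <- fragment_coverage(aln, fr[i, ], ind)
      cv$contig <- ctg
      cv$class <- if (fr$fragment_id[i] %in% calls$fragment_id)
        calls$class[match(fr$fragment_id[i], calls$fragment_id)] else "NoCNV"
      coverage[[length(coverage) + 1L]] <- cv
    }
  }
  list(indels = if (length(indels)) do.call(rbind, c(indels, make.row.names = FALSE)) else NULL,
       coverage = if (length(coverage)) do.call(rbind, c(coverage, make.row.names = FALSE)) else NULL,
       contigs = ctgs)
}
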