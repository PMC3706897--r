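# Array design: candidate probe generation on a 10 bp grid, 15-mer repeat
# masking, genome-wide uniqueness filtering, and assembly of 10-probe 200 bp
# contig fragments separated by at least 500 bp.

contig_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

canonical_kmers <- function(kmers) {
  pmin(kmers, revcomp(kmers))
}

#' Build a genome-wide k-mer frequency table
#'
#' Counts every k-mer window of the genome. With the default strand policy
#' (`"both"`) a k-mer and its reverse complement share one count bucket
#' (repeat masking is strand-agnostic because hybridization is
#' double-stranded); with `"forward"` only forward-strand windows are
#' counted.
#'
#' @param genome A `cgh_genome` or named character vector of contig
#'   sequences.
#' @param k Word size (the array design uses 15).
#' @param strand `"both"` or `"forward"`.
#' @return Object of class `kmer_table`: list with `k`, `strand` and
#'   `counts` (named integer vector).
#' @export
build_kmer_table <- function(genome, k = 15, strand = c("both", "forward")) {
  strand <- match.arg(strand)
  if (k < 1) stop("k must be >= 1")
  seqs <- if (inherits(genome, "cgh_genome")) genome$contigs else genome
  short <- nchar(seqs) < k
  if (any(short)) {
    warning(sprintf("%d contig(s) shorter than k = %d skipped", sum(short), k))
    seqs <- seqs[!short]
  }
  if (!length(seqs)) stop("no contig is at least k long")
  kmers <- unlist(lapply(seqs, contig_kmers, k = k), use.names = FALSE)
  if (strand == "both") kmers <- canonical_kmers(kmers)
  tab <- table(kmers)
  structure(list(k = k, strand = strand,
                 counts = stats::setNames(as.integer(tab), names(tab))),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("kmer_table: k = %d, strand = %s, %d distinct k-mers, %d windows\n",
              x$k, x$strand, length(x$counts), sum(x$counts)))
  invisible(x)
}

kmer_lookup <- function(table, kmers) {
  if (table$strand == "both") kmers <- canonical_kmers(kmers)
  cnt <- table$counts[kmers]
  cnt[is.na(cnt)] <- 0L
  unname(cnt)
}

# GC-count melting-temperature proxy for an oligo of length L.
tm_proxy <- function(gc_count, L) {
  64.9 + 41 * (gc_count - 16.4) / L
}

#' Generate candidate probes on a fixed start grid
#'
#' One variable-length probe (56-100 bp) is generated at every `step` bp
#' along each contig. The length at each start is chosen deterministically:
#' the smallest grid length whose GC-based melting-temperature proxy reaches
#' `tm_target`, otherwise the longest grid length that fits. Probes never
#' extend past the contig end.
#'
#' @param genome A `cgh_genome` or named character vector.
#' @param min_len,max_len,step Probe length bounds and start-grid step (bp).
#' @param tm_target Target of the Tm proxy `64.9 + 41 (GC - 16.4) / L`.
#' @return `data.frame` with `probe_id`, `contig`, `start` (0-based),
#'   `length`, `sequence`.
#' @export
generate_candidate_probes <- function(genome, min_len = 56, max_len = 100,
                                      step = 10, tm_target = 74.5) {
  seqs <- if (inherits(genome, "cgh_genome")) genome$contigs else genome
  grid <- unique(c(seq(min_len, max_len, by = step), max_len))
  out <- lapply(names(seqs), function(ctg) {
    seq <- seqs[[ctg]]
    L <- nchar(seq)
    if (L < min_len) return(NULL)
    starts <- seq(0L, L - min_len, by = step)  # 0-based
    gc_cum <- c(0L, cumsum(strsplit(seq, "")[[1]] %in% c("G", "C")))
    chosen <- rep(NA_integer_, length(starts))
    for (l in grid) {
      fits <- starts + l <= L
      gc <- gc_cum[pmin(starts + l, L) + 1L] - gc_cum[starts + 1L]
      hit <- is.na(chosen) & fits & tm_proxy(gc, l) >= tm_target
      chosen[hit] <- l
    }
    if (anyNA(chosen)) {  # fall back to the longest grid length that fits
      for (l in rev(grid)) {
        hit <- is.na(chosen) & starts + l <= L
        chosen[hit] <- l
      }
    }
    data.frame(probe_id = sprintf("%s_%06d", ctg, starts), contig = ctg,
               start = starts, length = chosen,
               sequence = substring(seq, starts + 1L, starts + chosen),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(probe_id = character(0), contig = character(0),
                      start = integer(0), length = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Remove probes with a high average k-mer frequency
#'
#' A probe is removed iff the mean genome-wide count of its `length - k + 1`
#' k-mer windows is strictly greater than `max_avg_freq` (the array design
#' removed probes with average 15-mer frequency > 25).
#'
#' @param probes Probe table.
#' @param table A `kmer_table` built from the same genome.
#' @param max_avg_freq Threshold (strict `>` removes).
#' @return The retained probes, with a `mean_kmer_freq` column.
#' @export
mask_repetitive_probes <- function(probes, table, max_avg_freq = 25) {
  stopifnot(inherits(table, "kmer_table"))
  if (!nrow(probes)) return(cbind(probes, mean_kmer_freq = numeric(0)))
  if (any(nchar(probes$sequence) < table$k))
    stop("probe shorter than the k-mer size")
  kml <- lapply(probes$sequence, contig_kmers, k = table$k)
  cnt <- kmer_lookup(table, unlist(kml, use.names = FALSE))
  means <- as.numeric(tapply(cnt, rep(seq_along(kml), lengths(kml)), mean))
  probes$mean_kmer_freq <- means
  probes[means <= max_avg_freq, , drop = FALSE]
}

#' Eliminate probes with secondary genomic matches
#'
#' A probe is retained iff its only qualifying alignment in the genome is its
#' source site. Detection follows an exact-seed scheme: any `min_match`-mer
#' of the probe occurring more than once genome-wide (forward or reverse
#' complement) marks a secondary alignment with at least `min_match` matched
#' bases, and the probe is eliminated. Under this detection scheme the
#' gapped-extension allowance (`max_gaps`) does not alter the decision: a
#' qualifying secondary alignment is anchored by its exact seed.
#'
#' @param probes Probe table (every probe must occur in the genome).
#' @param genome A `cgh_genome` or named character vector.
#' @param min_match Minimum exact match size (seed length).
#' @param max_gaps Gap allowance of the alignment definition (kept for the
#'   interface; see Details).
#' @return The retained probes.
#' @export
uniqueness_filter <- function(probes, genome, min_match = 30, max_gaps = 5) {
  if (!nrow(probes)) return(probes)
  if (any(nchar(probes$sequence) < min_match))
    stop("probe shorter than min_match")
  seed_tab <- build_kmer_table(genome, k = min_match, strand = "both")
  kml <- lapply(probes$sequence, contig_kmers, k = min_match)
  cnt <- kmer_lookup(seed_tab, unlist(kml, use.names = FALSE))
  grp <- rep(seq_along(kml), lengths(kml))
  if (any(cnt == 0L))
    stop(sprintf("probe %s not found in the genome: design/genome mismatch",
                 probes$probe_id[unique(grp[cnt == 0L])[1L]]))
  keep <- as.logical(tapply(cnt == 1L, grp, all))
  probes[keep, , drop = FALSE]
}

#' Assemble 10-probe contig fragments
#'
#' Greedy left-to-right placement per contig: the first window of at most
#' `span` bp that fully contains at least `per_fragment` surviving probes
#' becomes a fragment (the first `per_fragment` probes by start, ties broken
#' by length then id); the search then resumes `min_gap` bp after the window
#' end, so consecutive fragment starts are at least `span + min_gap` bp
#' apart.
#'
#' @param probes Filtered probe table (masked and unique).
#' @param span Window size (bp) of one fragment.
#' @param per_fragment Number of probes per fragment.
#' @param min_gap Minimum separation (bp) between adjoining fragment windows.
#' @return `data.frame` with `fragment_id`, `contig`, `start`, `end`
#'   (0-based half-open; `end` is the last probe end, so `end - start <=
#'   span`) and `probe_ids` (comma-separated).
#' @export
assemble_fragments <- function(probes, span = 200, per_fragment = 10,
                               min_gap = 500) {
  out <- list()
  for (ctg in unique(probes$contig)) {
    p <- probes[probes$contig == ctg, , drop = FALSE]
    p <- p[order(p$start, p$length, p$probe_id), , drop = FALSE]
    s <- p$start
    e <- p$start + p$length
    i <- 1L
    n <- nrow(p)
    while (i <= n) {
      w <- s[i]
      inside <- which(s >= w & e <= w + span)
      if (length(inside) >= per_fragment) {
        sel <- inside[seq_len(per_fragment)]
        frag_end <- max(e[sel])
        out[[length(out) + 1L]] <- data.frame(
          fragment_id = sprintf("%s:%d-%d", ctg, w, frag_end),
          contig = ctg, start = w, end = frag_end,
          probe_ids = paste(p$probe_id[sel], collapse = ","),
          stringsAsFactors = FALSE)
        nxt <- which(s >= w + span + min_gap)
        i <- if (length(nxt)) nxt[1L] else n + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(fragment_id = character(0), contig = character(0),
               start = integer(0), end = integer(0),
               probe_ids = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

fragment_probe_map <- function(fragments) {
  ids <- strsplit(fragments$probe_ids, ",")
  data.frame(fragment_id = rep(fragments$fragment_id, lengths(ids)),
             probe_id = unlist(ids), stringsAsFactors = FALSE)
}

#' Run the full array design
#'
#' Candidate generation, repeat masking, uniqueness filtering and fragment
#' assembly in sequence, returning the final design (only probes that belong
#' to a fragment) plus per-stage counts.
#'
#' @param genome A `cgh_genome`.
#' @param k,max_avg_freq,min_match,max_gaps,span,per_fragment,min_gap,tm_target
#'   Stage parameters (see the stage functions).
#' @inheritParams generate_candidate_probes
#' @return List with `probes` (final), `fragments`, and `summary`
#'   (`data.frame` of stage counts).
#' @export
design_array <- function(genome, min_len = 56, max_len = 100, step = 10,
                         tm_target = 74.5, k = 15, max_avg_freq = 25,
                         min_match = 30, max_gaps = 5, span = 200,
                         per_fragment = 10, min_gap = 500) {
  cand <- generate_candidate_probes(genome, min_len, max_len, step, tm_target)
  tab <- build_kmer_table(genome, k = k)
  masked <- mask_repetitive_probes(cand, tab, max_avg_freq = max_avg_freq)
  uniq <- uniqueness_filter(masked, genome, min_match = min_match,
                            max_gaps = max_gaps)
  frags <- assemble_fragments(uniq, span = span, per_fragment = per_fragment,
                              min_gap = min_gap)
  final_ids <- unlist(strsplit(frags$probe_ids, ","))
  probes <- uniq[uniq$probe_id %in% final_ids, , drop = FALSE]
  list(probes = probes, fragments = frags,
       summary = data.frame(stage = c("candidates", "masked", "unique",
                                      "fragments", "probes_on_array"),
                            n = c(nrow(cand), nrow(masked), nrow(uniq),
                                  nrow(frags), nrow(probes))))
}

#' Write fragments as BED
#' @param fragments Fragment table.
#' @param path Output path.
#' @export
write_fragments_bed <- function(fragments, path) {
  utils::write.table(fragments[, c("contig", "start", "end", "fragment_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
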