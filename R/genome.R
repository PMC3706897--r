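#' Generate a synthetic multi-contig reference genome
#'
#' Emulates the input of an array-CGH design: a fragmented whole-genome
#' shotgun assembly whose contigs are anchored to chromosomes, plus a genetic
#' map. Interspersed repeat families can be embedded at requested copy
#' numbers, and the genetic map can be made telomere-enriched (higher cM/Mb
#' towards chromosome ends), the pattern typical of large cereal genomes.
#'
#' @param n_contigs Number of contigs to simulate.
#' @param contig_length Contig length(s) in bp (recycled); must be >= 1000.
#' @param chromosomes Chromosome labels; contigs are assigned in consecutive
#'   blocks.
#' @param gc GC fraction of the background sequence.
#' @param repeat_families Optional `data.frame` with columns `motif` (DNA
#'   string) and `copies` (integer): each motif is embedded at exactly that
#'   many non-overlapping positions.
#' @param telomere_enriched Logical; if `TRUE` the recombination rate used to
#'   build the genetic map increases towards chromosome ends.
#' @param map_points Number of genetic-map anchor points per chromosome.
#' @param contig_gap Physical gap (bp) assumed between consecutive contigs on
#'   a chromosome.
#' @param seed Integer seed; the result is deterministic given `seed` and the
#'   configuration.
#' @return An object of class `cgh_genome`: a list with `contigs` (named
#'   character vector), `contig_meta` (`contig`, `length`, `chrom`,
#'   `chrom_start`), `genetic_map` (`chrom`, `pos`, `cM`) and
#'   `repeat_families`. All coordinates are 0-based half-open.
#' @export
generate_reference <- function(n_contigs = 14, contig_length = 10000,
                               chromosomes = paste0(1:7, "H"), gc = 0.45,
                               repeat_families = NULL,
                               telomere_enriched = TRUE, map_points = 25,
                               contig_gap = 500, seed) {
  if (missing(seed)) stop("a seed is required")
  if (n_contigs < 1) stop("n_contigs must be >= 1")
  lens <- rep_len(as.integer(contig_length), n_contigs)
  if (any(lens < 1000)) stop("contig lengths must be >= 1 kb")
  if (!is.null(repeat_families)) {
    repeat_families <- as.data.frame(repeat_families)
    stopifnot(all(c("motif", "copies") %in% names(repeat_families)))
    assert_dna(repeat_families$motif, "repeat motif")
    if (any(nchar(repeat_families$motif) > max(lens)))
      stop("repeat motif longer than the longest contig")
  }
  set.seed(derive_seed(seed, "reference"))

  ids <- sprintf("contig_%04d", seq_len(n_contigs))
  seqs <- vapply(lens, random_dna, character(1), gc = gc)
  names(seqs) <- ids

  # consecutive blocks of contigs per chromosome
  chrom_of <- chromosomes[ceiling(seq_len(n_contigs) / (n_contigs / length(chromosomes)))]
  chrom_of <- chrom_of[seq_len(n_contigs)]
  chrom_start <- integer(n_contigs)
  for (chr in unique(chrom_of)) {
    i <- which(chrom_of == chr)
    chrom_start[i] <- cumsum(c(0L, head(lens[i] + contig_gap, -1L)))
  }
  meta <- data.frame(contig = ids, length = lens, chrom = chrom_of,
                     chrom_start = chrom_start, stringsAsFactors = FALSE)

  # embed repeat families at non-overlapping positions
  if (!is.null(repeat_families) && nrow(repeat_families)) {
    occupied <- lapply(ids, function(i) matrix(numeric(0), ncol = 2))
    names(occupied) <- ids
    for (r in seq_len(nrow(repeat_families))) {
      motif <- repeat_families$motif[r]
      m <- nchar(motif)
      placed <- 0L
      tries <- 0L
      while (placed < repeat_families$copies[r]) {
        tries <- tries + 1L
        if (tries > 10000L) stop("could not place repeat copies without overlap")
        ci <- sample.int(n_contigs, 1, prob = lens)
        if (lens[ci] < m + 2) next
        p <- sample.int(lens[ci] - m + 1L, 1)  # 1-based start
        occ <- occupied[[ci]]
        if (nrow(occ) && any(interval_overlap(p, p + m, occ[, 1], occ[, 2]) > 0)) next
        substr(seqs[ci], p, p + m - 1L) <- motif
        occupied[[ci]] <- rbind(occ, c(p, p + m))
        placed <- placed + 1L
      }
    }
  }

  gmap <- do.call(rbind, lapply(unique(chrom_of), function(chr) {
    i <- which(chrom_of == chr)
    L <- max(chrom_start[i] + lens[i])
    pos <- round(seq(0, L, length.out = max(3, map_points)))
    mid <- (head(pos, -1) + tail(pos, -1)) / 2
    rate <- if (telomere_enriched) {
      d <- pmin(mid, L - mid) / (L / 2)  # 0 at ends, 1 at centre
      0.3 + 3.0 * (1 - d)^2
    } else rep(1.5, length(mid))
    cm <- c(0, cumsum(rate * diff(pos) / 1e6))
    data.frame(chrom = chr, pos = pos, cM = cm, stringsAsFactors = FALSE)
  }))
  rownames(gmap) <- NULL

  structure(list(contigs = seqs, contig_meta = meta, genetic_map = gmap,
                 repeat_families = repeat_families),
            class = "cgh_genome")
}

#' @export
print.cgh_genome <- function(x, ...) {
  cat(sprintf("cgh_genome: %d contigs, %s bp total, %d chromosome(s)\n",
              length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","),
              length(unique(x$contig_meta$chrom))))
  invisible(x)
}

#' Genome-wide physical coordinates of contig fragments
#'
#' Maps fragment intervals (contig coordinates) onto chromosome coordinates
#' using the contig anchoring of the genome, and labels chromosome arms by
#' the midpoint relative to the chromosome centre.
#'
#' @param genome A `cgh_genome`.
#' @param fragments Fragment table from [assemble_fragments()].
#' @return `data.frame` with `fragment_id`, `contig`, `chrom`, `start`,
#'   `end` (chromosome bp, 0-based half-open) and `arm` (`"S"`/`"L"`).
#' @export
fragment_positions <- function(genome, fragments) {
  meta <- genome$contig_meta
  i <- match(fragments$contig, meta$contig)
  if (anyNA(i)) stop("fragments reference contigs absent from the genome")
  start <- meta$chrom_start[i] + fragments$start
  end <- meta$chrom_start[i] + fragments$end
  chrom <- meta$chrom[i]
  chrom_len <- tapply(meta$chrom_start + meta$length, meta$chrom, max)
  mid <- (start + end) / 2
  arm <- ifelse(mid < chrom_len[chrom] / 2, "S", "L")
  data.frame(fragment_id = fragments$fragment_id, contig = fragments$contig,
             chrom = chrom, start = start, end = end, arm = as.character(arm),
             stringsAsFactors = FALSE)
}

#' Write a genome to FASTA
#' @param genome A `cgh_genome` or named character vector of sequences.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- if (inherits(genome, "cgh_genome")) genome$contigs else genome
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a plain contig set
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
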