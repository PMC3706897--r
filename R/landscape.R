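# Genome-wide CNV landscape summaries over a fragment x genotype variant
# matrix: sharing spectrum, chromosome rates, sliding-window densities,
# wild-vs-cultivated contrasts, recombination correlation, exon overlap.

#' Build a fragment-by-genotype variant matrix
#'
#' @param calls Call table from [call_cnvs()] / [call_cnv_panel()].
#' @param fragment_ids All tested fragment ids (rows).
#' @param genotypes All genotypes (columns).
#' @param groups Optional `data.frame` (`genotype`, `group` in
#'   `wild`/`cultivated`).
#' @return Character matrix (`Up`/`Down`/`none`) of class `variant_matrix`
#'   with a `groups` attribute.
#' @export
variant_matrix <- function(calls, fragment_ids, genotypes, groups = NULL) {
  m <- matrix("none", nrow = length(fragment_ids), ncol = length(genotypes),
              dimnames = list(fragment_ids, genotypes))
  if (nrow(calls)) {
    cls <- ifelse(calls$class == "UpCNV", "Up", "Down")
    keep <- calls$fragment_id %in% fragment_ids & calls$genotype %in% genotypes
    m[cbind(calls$fragment_id[keep], calls$genotype[keep])] <- cls[keep]
  }
  if (!is.null(groups)) {
    stopifnot(all(genotypes %in% groups$genotype))
    groups <- stats::setNames(groups$group, groups$genotype)[genotypes]
  }
  structure(m, class = c("variant_matrix", "matrix"), groups = groups)
}

is_variant_fragment <- function(vm) rowSums(unclass(vm) != "none") > 0

#' CNV frequency spectrum
#'
#' Distribution of variant fragments by the number of genotypes sharing them
#' (singletons are private to one genotype).
#'
#' @param vm A `variant_matrix`.
#' @return List with `counts` (named vector over 1..n genotypes),
#'   `singleton_fraction` and `n_variant_fragments`.
#' @export
frequency_spectrum <- function(vm) {
  share <- rowSums(unclass(vm) != "none")
  share <- share[share > 0]
  counts <- tabulate(share, nbins = ncol(vm))
  names(counts) <- seq_len(ncol(vm))
  list(counts = counts,
       singleton_fraction = if (length(share)) counts[[1]] / length(share) else NA_real_,
       n_variant_fragments = length(share))
}

#' Per-window CNV proportions
#'
#' Tiles each chromosome with fixed windows and reports, per window, the
#' proportion of fragments that are variant in at least one genotype.
#' Fragments are assigned to windows by their start coordinate (half-open
#' windows, no double counting); empty windows get an `NA` proportion.
#'
#' @param vm A `variant_matrix`.
#' @param positions Fragment positions from [fragment_positions()].
#' @param window_bp Window size (bp).
#' @return `data.frame` (`chrom`, `win_start`, `win_end`, `n_fragments`,
#'   `n_variant`, `proportion`).
#' @export
window_proportions <- function(vm, positions, window_bp = 1500000) {
  var_frag <- is_variant_fragment(vm)
  pos <- positions[match(rownames(vm), positions$fragment_id), , drop = FALSE]
  out <- list()
  for (chr in unique(pos$chrom)) {
    i <- which(pos$chrom == chr)
    win <- floor(pos$start[i] / window_bp)
    n_win <- max(win) + 1L
    tot <- tabulate(win + 1L, nbins = n_win)
    nv <- tabulate((win + 1L)[var_frag[i]], nbins = n_win)
    out[[chr]] <- data.frame(chrom = chr,
                             win_start = (seq_len(n_win) - 1L) * window_bp,
                             win_end = seq_len(n_win) * window_bp,
                             n_fragments = tot, n_variant = nv,
                             proportion = ifelse(tot > 0, nv / tot, NA_real_),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-chromosome CNV rates with a one-vs-rest test
#'
#' The chromosome proportion is (variant fragments)/(fragments); the test
#' contrasts the chromosome's window-level proportions against all other
#' chromosomes' windows with a two-sample t-test (skipped, with `NA`, for
#' chromosomes with fewer than two non-empty windows).
#'
#' @inheritParams window_proportions
#' @return `data.frame` (`chrom`, `n_fragments`, `n_variant`, `proportion`,
#'   `p_value`).
#' @export
chromosome_rates <- function(vm, positions, window_bp = 1500000) {
  var_frag <- is_variant_fragment(vm)
  pos <- positions[match(rownames(vm), positions$fragment_id), , drop = FALSE]
  wins <- window_proportions(vm, positions, window_bp)
  wins <- wins[!is.na(wins$proportion), , drop = FALSE]
  out <- lapply(unique(pos$chrom), function(chr) {
    i <- pos$chrom == chr
    pw <- wins$proportion[wins$chrom == chr]
    rest <- wins$proportion[wins$chrom != chr]
    p <- if (length(pw) >= 2 && length(rest) >= 2 &&
             (stats::sd(pw) > 0 || stats::sd(rest) > 0))
      stats::t.test(pw, rest)$p.value else NA_real_
    data.frame(chrom = chr, n_fragments = sum(i), n_variant = sum(var_frag[i]),
               proportion = if (sum(i)) sum(var_frag[i]) / sum(i) else NA_real_,
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Wild-minus-cultivated variant difference per window
#'
#' Per window, the number of fragments variant in at least one wild genotype
#' minus the number variant in at least one cultivated genotype.
#'
#' @inheritParams window_proportions
#' @return `data.frame` with per-window counts and `difference`; attribute
#'   `summary` holds the positive/negative window counts.
#' @export
group_difference_profile <- function(vm, positions, window_bp = 1500000) {
  groups <- attr(vm, "groups")
  if (is.null(groups)) stop("variant matrix carries no group labels")
  if (!all(c("wild", "cultivated") %in% groups))
    stop("both groups (wild, cultivated) must be non-empty")
  m <- unclass(vm)
  wildv <- rowSums(m[, groups == "wild", drop = FALSE] != "none") > 0
  cultv <- rowSums(m[, groups == "cultivated", drop = FALSE] != "none") > 0
  pos <- positions[match(rownames(vm), positions$fragment_id), , drop = FALSE]
  out <- list()
  for (chr in unique(pos$chrom)) {
    i <- which(pos$chrom == chr)
    win <- floor(pos$start[i] / window_bp)
    n_win <- max(win) + 1L
    nw <- tabulate((win + 1L)[wildv[i]], nbins = n_win)
    nc <- tabulate((win + 1L)[cultv[i]], nbins = n_win)
    out[[chr]] <- data.frame(chrom = chr,
                             win_start = (seq_len(n_win) - 1L) * window_bp,
                             win_end = seq_len(n_win) * window_bp,
                             n_wild = nw, n_cultivated = nc,
                             difference = nw - nc, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "summary") <- c(n_positive = sum(res$difference > 0),
                            n_negative = sum(res$difference < 0))
  res
}

#' Correlation between recombination rate and CNV frequency
#'
#' Bins all chromosomes into fixed physical windows (default 10 Mb),
#' computes cM/Mb per bin by linear interpolation of the genetic map at the
#' bin edges, the CNV proportion per bin, and Spearman's rho over all bins
#' of all chromosomes combined.
#'
#' @inheritParams window_proportions
#' @param genetic_map `data.frame` (`chrom`, `pos`, `cM`).
#' @param bin_bp Bin size (bp).
#' @return List with `rho`, `p_value` and `bins`.
#' @export
recombination_cnv_correlation <- function(vm, positions, genetic_map,
                                          bin_bp = 10000000) {
  var_frag <- is_variant_fragment(vm)
  pos <- positions[match(rownames(vm), positions$fragment_id), , drop = FALSE]
  if (anyNA(pos$start))
    stop("positions missing for some fragments of the variant matrix")
  out <- list()
  for (chr in unique(pos$chrom)) {
    i <- which(pos$chrom == chr)
    gm <- genetic_map[genetic_map$chrom == chr, , drop = FALSE]
    if (nrow(gm) < 2) next
    win <- floor(pos$start[i] / bin_bp)
    n_win <- max(win) + 1L
    tot <- tabulate(win + 1L, nbins = n_win)
    nv <- tabulate((win + 1L)[var_frag[i]], nbins = n_win)
    lo <- (seq_len(n_win) - 1L) * bin_bp
    hi <- pmin(seq_len(n_win) * bin_bp, max(gm$pos, pos$start[i] + 1))
    cm <- stats::approx(gm$pos, gm$cM, xout = c(lo, hi), rule = 2)$y
    cmmb <- (cm[n_win + seq_len(n_win)] - cm[seq_len(n_win)]) /
      pmax((hi - lo) / 1e6, 1e-9)
    keep <- tot > 0
    if (!any(keep)) next
    out[[chr]] <- data.frame(chrom = chr, bin_start = lo[keep],
                             bin_end = hi[keep], cM_per_Mb = cmmb[keep],
                             n_fragments = tot[keep],
                             proportion = nv[keep] / tot[keep],
                             stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, out)
  if (is.null(bins) || nrow(bins) < 3)
    stop("fewer than 3 populated bins: correlation undefined")
  rownames(bins) <- NULL
  ct <- suppressWarnings(stats::cor.test(bins$cM_per_Mb, bins$proportion,
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, bins = bins)
}

#' Exon overlap of Up and Down calls
#'
#' Fraction of UpCNV calls whose fragment overlaps an annotated exon by at
#' least 1 bp (half-open intervals), and the same for DownCNV/PAV calls.
#'
#' @param calls Call table.
#' @param positions Fragment positions from [fragment_positions()].
#' @param annotation `data.frame` of exon intervals (`chrom`, `start`,
#'   `end`), 0-based half-open, chromosome coordinates.
#' @return List with `up_proportion`, `down_proportion`, `n_up`, `n_down`.
#' @export
exon_overlap_summary <- function(calls, positions, annotation) {
  n_up <- sum(calls$class == "UpCNV")
  n_down <- sum(calls$class == "DownCNV/PAV")
  if (is.null(annotation) || !nrow(annotation)) {
    warning("empty annotation: overlap proportions are 0")
    return(list(up_proportion = 0, down_proportion = 0,
                n_up = n_up, n_down = n_down))
  }
  hit <- logical(nrow(positions))
  for (chr in unique(positions$chrom)) {
    i <- which(positions$chrom == chr)
    a <- annotation[annotation$chrom == chr, , drop = FALSE]
    if (!nrow(a)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(positions$start[i] + 1L, positions$end[i]),
      IRanges::IRanges(a$start + 1L, a$end))
    hit[i[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  frag_hit <- stats::setNames(hit, positions$fragment_id)
  up <- calls$class == "UpCNV"
  down <- calls$class == "DownCNV/PAV"
  list(up_proportion = if (n_up) mean(frag_hit[calls$fragment_id[up]]) else NA_real_,
       down_proportion = if (n_down) mean(frag_hit[calls$fragment_id[down]]) else NA_real_,
       n_up = n_up, n_down = n_down)
}
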