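# Two-channel normalization and fragment-level aggregation.
#
# The normalization contract is variance flatness and monotonicity rather
# than a particular calibration: each array (genotype x replicate) gets a
# per-channel generalized-log transform g(x) = log2(x + sqrt(x^2 + a^2)),
# with the offset a estimated as a low quantile of that channel (a robust
# proxy for additive background). Ratios are then re-anchored so that their
# median equals the median raw log2(sample/reference) ratio: this removes the
# additive constant introduced by the transform without erasing genuine
# global dosage, and leaves the null mode at 0 when most probes are
# unchanged. For noise-free proportional channels the output equals the raw
# log2 ratio exactly, and multiplying both channels by a constant leaves the
# output unchanged.

glog2 <- function(x, a) log2(x + sqrt(x^2 + a^2))

#' Normalize raw two-channel intensities to probe log2 ratios
#'
#' @param raw Intensity table (`probe_id`, `genotype`, `replicate`,
#'   `ch_sample`, `ch_ref`), one row per probe per array.
#' @param glog_quantile Quantile of each channel used as the generalized-log
#'   offset.
#' @return `data.frame` (`probe_id`, `genotype`, `replicate`, `log2_ratio`).
#' @export
normalize_intensities <- function(raw, glog_quantile = 0.05) {
  need <- c("probe_id", "genotype", "replicate", "ch_sample", "ch_ref")
  if (!all(need %in% names(raw))) stop("missing channel or id columns")
  if (anyNA(raw$ch_sample) || anyNA(raw$ch_ref)) stop("missing channel values")
  if (any(raw$ch_sample < 0) || any(raw$ch_ref < 0))
    stop("negative intensities")
  arr <- interaction(raw$genotype, raw$replicate, drop = TRUE)
  out <- raw[, c("probe_id", "genotype", "replicate")]
  out$log2_ratio <- NA_real_
  for (g in levels(arr)) {
    i <- which(arr == g)
    s <- raw$ch_sample[i]
    r <- raw$ch_ref[i]
    a_s <- max(stats::quantile(s, glog_quantile, names = FALSE), 1e-8)
    a_r <- max(stats::quantile(r, glog_quantile, names = FALSE), 1e-8)
    v <- glog2(s, a_s) - glog2(r, a_r)
    pos <- s > 0 & r > 0
    anchor <- if (any(pos)) stats::median(log2(s[pos] / r[pos])) else 0
    out$log2_ratio[i] <- v - stats::median(v) + anchor
  }
  out
}

#' Average probe log2 ratios into fragment signals
#'
#' Probe values are first averaged across replicates, then across each
#' fragment's probes (replicate averaging precedes fragment averaging). A
#' fragment missing any probe value for a genotype is excluded with a
#' warning.
#'
#' @param ratios Probe log2 ratio table from [normalize_intensities()].
#' @param fragments Fragment table from [assemble_fragments()].
#' @return `data.frame` (`fragment_id`, `genotype`, `signal`), attribute
#'   `excluded` listing dropped fragment x genotype pairs.
#' @export
aggregate_fragment_signal <- function(ratios, fragments) {
  if (anyNA(ratios$log2_ratio) || any(!is.finite(ratios$log2_ratio)))
    stop("ratios must be finite")
  # replicate averaging first
  agg <- aggregate(list(value = ratios$log2_ratio),
                   by = list(probe_id = ratios$probe_id,
                             genotype = ratios$genotype), FUN = mean)
  map <- fragment_probe_map(fragments)
  m <- merge(map, agg, by = "probe_id")
  n_probes <- lengths(strsplit(fragments$probe_ids, ","))
  names(n_probes) <- fragments$fragment_id
  res <- aggregate(list(signal = m$value, n = rep(1, nrow(m))),
                   by = list(fragment_id = m$fragment_id,
                             genotype = m$genotype),
                   FUN = sum)
  res$signal <- res$signal / res$n
  full <- n_probes[res$fragment_id]
  bad <- res$n < full
  if (any(bad)) {
    warning(sprintf("%d fragment x genotype pair(s) missing probe values; excluded",
                    sum(bad)))
  }
  excluded <- res[bad, c("fragment_id", "genotype")]
  res <- res[!bad, c("fragment_id", "genotype", "signal")]
  res <- res[order(res$genotype, res$fragment_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

#' Per-chromosome-arm mean fragment signal
#'
#' The dosage profile used to validate an array against a known aneuploid
#' sample (e.g. a chromosome-arm addition line): an arm present in an extra
#' copy should show a shifted mean log2 ratio while all other arms stay at 0.
#'
#' @param signals Fragment signal table.
#' @param labels `data.frame` mapping `fragment_id` to a chromosome/arm
#'   `label`.
#' @return `data.frame` (`genotype`, `label`, `n`, `mean`, `sd`, `se`).
#' @export
chromosome_dosage_profile <- function(signals, labels) {
  m <- merge(signals, labels[, c("fragment_id", "label")], by = "fragment_id")
  dropped <- nrow(signals) - nrow(m)
  if (dropped > 0) message(sprintf("%d unlabeled fragment signal(s) excluded", dropped))
  res <- aggregate(list(mean = m$signal), by = list(genotype = m$genotype,
                                                    label = m$label), FUN = mean)
  res$sd <- aggregate(list(sd = m$signal),
                      by = list(genotype = m$genotype, label = m$label),
                      FUN = sd)$sd
  res$n <- aggregate(list(n = m$signal),
                     by = list(genotype = m$genotype, label = m$label),
                     FUN = length)$n
  res$se <- res$sd / sqrt(res$n)
  res[order(res$genotype, res$label), c("genotype", "label", "n", "mean", "sd", "se")]
}
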