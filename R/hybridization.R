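# Two-channel hybridization simulation.
#
# Expected per-probe log2 ratio follows copy number: log2((c + eps)/(1 + eps))
# with a pseudo-copy eps bounding the ratio for absent sequence (arrays report
# background, not -Inf). A probe whose target is interrupted by a breakpoint
# hybridizes only through its longest contiguous matching stretch m; the
# retained signal fraction is max(0, (m - m0)/(L - m0)) with m0 = 0.75 * L,
# i.e. a duplex shorter than three quarters of the probe yields background.
# Short query-side insertions (<= loopout_max bp) are looped out and do not
# interrupt the duplex.

duplex_fraction <- function(m, L, duplex_min_frac) {
  m0 <- duplex_min_frac * L
  pmax(0, (m - m0) / (L - m0))
}

# Effective relative copy number of each probe target in one genotype.
probe_copy_effect <- function(probes, truth_gt, duplex_min_frac, loopout_max) {
  cc <- rep(1, nrow(probes))
  if (!nrow(truth_gt)) return(cc)
  for (j in seq_len(nrow(truth_gt))) {
    v <- truth_gt[j, ]
    idx <- which(probes$contig == v$contig &
                   probes$start < v$ref_end + (v$type == "insertion") &
                   probes$start + probes$length > v$ref_start)
    if (!length(idx)) next
    a <- probes$start[idx]
    b <- a + probes$length[idx]
    L <- probes$length[idx]
    p <- v$ref_start
    q <- v$ref_end
    eff <- switch(v$type,
      deletion = {
        inside <- a >= p & b <= q
        left <- pmax(0, p - a)
        right <- pmax(0, b - q)
        # a deletion fully inside the probe joins both flanks in the query,
        # but the probe's own deleted middle must loop out
        m <- ifelse(a < p & q < b & v$size <= loopout_max, L,
                    pmax(left, right))
        ifelse(inside, 0, ifelse(m >= L, 1, duplex_fraction(m, L, duplex_min_frac)))
      },
      duplication = {
        inside <- a >= p & b <= q
        ifelse(inside, 2, 1)
      },
      insertion = {
        covers <- a < p & p < b
        ins <- nchar(v$ins_seq)
        m <- pmax(p - a, b - p)
        ifelse(!covers | ins <= loopout_max, 1,
               duplex_fraction(m, L, duplex_min_frac))
      },
      replacement = {
        inside <- a >= p & b <= q
        m <- pmax(pmax(0, p - a), pmax(0, b - q))
        ifelse(inside, 0, duplex_fraction(m, L, duplex_min_frac))
      })
    # variant placement guarantees >= 2 x margin between variants, so no
    # probe is touched by more than one variant
    cc[idx] <- eff
  }
  cc
}

#' Simulate two-channel probe intensities for a spiked panel
#'
#' Each probe's expected log2(sample/reference) ratio is determined by its
#' target's copy number in the derived genome (with breakpoint-overlapping
#' probes attenuated through the duplex model described above), then realized
#' as a pair of channel intensities with log-scale ratio noise, per-probe
#' multiplicative brightness noise and an additive background component, to
#' exercise the normalization.
#'
#' @param panel A `cgh_panel` from [spike_variants()] /
#'   [generate_population()].
#' @param probes Probe table designed on `panel$ref` (see
#'   [generate_candidate_probes()]).
#' @param noise List with `sigma_log2` (sd of Gaussian noise on the log2
#'   ratio), `additive` (mean of the exponential additive background, in
#'   intensity units) and `multiplicative` (sd, in log2 units, of per-probe
#'   per-channel brightness noise). All must be >= 0.
#' @param n_replicates Replicate arrays per genotype.
#' @param eps Pseudo-copy number bounding the ratio for absent targets.
#' @param intensity_log2_mean,intensity_log2_sd Log2-normal distribution of
#'   per-probe baseline brightness.
#' @param duplex_min_frac Fraction of the probe length below which a duplex
#'   yields background signal.
#' @param loopout_max Largest query-side insertion (bp) tolerated by loop-out
#'   without interrupting the duplex.
#' @param seed Integer seed.
#' @return `data.frame` (`probe_id`, `genotype`, `replicate`, `ch_sample`,
#'   `ch_ref`) with an attribute `expected_log2` giving the noise-free
#'   per-probe expected ratio per genotype.
#' @export
simulate_hybridization <- function(panel, probes,
                                   noise = list(sigma_log2 = 0.2,
                                                additive = 100,
                                                multiplicative = 0.1),
                                   n_replicates = 2, eps = 0.01,
                                   intensity_log2_mean = 10,
                                   intensity_log2_sd = 1,
                                   duplex_min_frac = 0.75, loopout_max = 21,
                                   seed) {
  stopifnot(inherits(panel, "cgh_panel"))
  noise <- utils::modifyList(list(sigma_log2 = 0.2, additive = 100,
                                  multiplicative = 0.1), as.list(noise))
  if (any(unlist(noise) < 0)) stop("noise parameters must be >= 0")
  if (!all(probes$contig %in% names(panel$ref$contigs)))
    stop("unknown probe contig: probes must be designed on the panel's reference")
  set.seed(derive_seed(seed, "hybridization"))

  genotypes <- names(panel$genomes)
  np <- nrow(probes)
  B <- 2^rnorm(np, intensity_log2_mean, intensity_log2_sd)

  expected <- matrix(0, nrow = np, ncol = length(genotypes),
                     dimnames = list(probes$probe_id, genotypes))
  out <- vector("list", length(genotypes) * n_replicates)
  k <- 0L
  for (gt in genotypes) {
    cc <- probe_copy_effect(probes, panel$truth[panel$truth$genotype == gt, , drop = FALSE],
                            duplex_min_frac, loopout_max)
    r <- log2((cc + eps) / (1 + eps))
    expected[, gt] <- r
    for (rep_i in seq_len(n_replicates)) {
      e <- if (noise$sigma_log2 > 0) rnorm(np, 0, noise$sigma_log2) else 0
      ms <- if (noise$multiplicative > 0) 2^rnorm(np, 0, noise$multiplicative) else 1
      mr <- if (noise$multiplicative > 0) 2^rnorm(np, 0, noise$multiplicative) else 1
      as_ <- if (noise$additive > 0) rexp(np, 1 / noise$additive) else 0
      ar <- if (noise$additive > 0) rexp(np, 1 / noise$additive) else 0
      k <- k + 1L
      out[[k]] <- data.frame(probe_id = probes$probe_id, genotype = gt,
                             replicate = rep_i,
                             ch_sample = B * 2^(r + e) * ms + as_,
                             ch_ref = B * mr + ar,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "expected_log2") <- expected
  res
}
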