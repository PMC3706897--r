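# Landscape summaries over synthetic variant matrices.

mk_calls <- function(ids, genotype = "g1", class = "DownCNV/PAV") {
  data.frame(fragment_id = ids, genotype = rep_len(genotype, length(ids)),
             class = rep_len(class, length(ids)),
             log2 = rep_len(-2, length(ids)),
             posterior = rep_len(0.99, length(ids)), stringsAsFactors = FALSE)
}

mk_positions <- function(n_per_chrom = 150, chroms = paste0(1:7, "H"),
                         spacing = 50000) {
  do.call(rbind, lapply(chroms, function(chr) {
    data.frame(fragment_id = sprintf("%s_f%04d", chr, seq_len(n_per_chrom)),
               contig = chr, chrom = chr,
               start = (seq_len(n_per_chrom) - 1) * spacing,
               end = (seq_len(n_per_chrom) - 1) * spacing + 200,
               arm = "S", stringsAsFactors = FALSE)
  }))
}

test_that("the frequency spectrum partitions variant fragments", {
  vm <- variant_matrix(rbind(mk_calls("f1", "g1"), mk_calls("f1", "g2"),
                             mk_calls("f2", "g3")),
                       sprintf("f%d", 1:10), sprintf("g%d", 1:3))
  spec <- frequency_spectrum(vm)
  expect_equal(sum(spec$counts), spec$n_variant_fragments)
  expect_equal(unname(spec$counts), c(1, 1, 0))
  expect_equal(spec$singleton_fraction, 0.5)
  # all singletons
  vm1 <- variant_matrix(mk_calls(c("f1", "f2"), "g1"),
                        sprintf("f%d", 1:10), sprintf("g%d", 1:3))
  expect_equal(frequency_spectrum(vm1)$singleton_fraction, 1)
  # one fragment shared by everyone occupies the top bin
  vm2 <- variant_matrix(do.call(rbind, lapply(sprintf("g%d", 1:3), mk_calls,
                                              ids = "f1")),
                        sprintf("f%d", 1:10), sprintf("g%d", 1:3))
  expect_equal(unname(frequency_spectrum(vm2)$counts[3]), 1)
})

test_that("window proportions use half-open start-based assignment", {
  pos <- mk_positions(n_per_chrom = 40, chroms = "1H", spacing = 100000)
  # a fragment exactly on a window boundary belongs to the right-hand window
  pos$start[16] <- 1500000
  vm <- variant_matrix(mk_calls(pos$fragment_id[16]), pos$fragment_id, "g1")
  w <- window_proportions(vm, pos)
  expect_equal(w$n_variant[w$win_start == 1500000], 1)
  expect_equal(w$n_variant[w$win_start == 0], 0)
  # fully-variant window reaches 1
  vm2 <- variant_matrix(mk_calls(pos$fragment_id[pos$start < 1500000]),
                        pos$fragment_id, "g1")
  w2 <- window_proportions(vm2, pos)
  expect_equal(w2$proportion[1], 1)
  # zero variants -> all proportions 0
  vm0 <- variant_matrix(mk_calls(character(0)), pos$fragment_id, "g1")
  expect_true(all(window_proportions(vm0, pos)$proportion == 0))
})

test_that("chromosome-rate tests detect a depleted chromosome and not noise", {
  pos <- mk_positions()
  detected <- 0L
  false_hits <- 0L
  n_seeds <- 5
  for (seed in seq_len(n_seeds)) {
    set.seed(seed)
    # equal rates everywhere
    v_eq <- pos$fragment_id[runif(nrow(pos)) < 0.3]
    r_eq <- chromosome_rates(variant_matrix(mk_calls(v_eq), pos$fragment_id, "g1"),
                             pos)
    false_hits <- false_hits + sum(r_eq$p_value < 0.05, na.rm = TRUE)
    # chromosome 4H at half the rate
    p <- ifelse(pos$chrom == "4H", 0.15, 0.3)
    v_dep <- pos$fragment_id[runif(nrow(pos)) < p]
    r_dep <- chromosome_rates(variant_matrix(mk_calls(v_dep), pos$fragment_id, "g1"),
                              pos)
    detected <- detected + (r_dep$p_value[r_dep$chrom == "4H"] < 0.05)
  }
  expect_gte(detected, n_seeds - 1)
  expect_lte(false_hits / (7 * n_seeds), 0.15)
  # zero variants: proportions 0, no spurious tests
  r0 <- chromosome_rates(variant_matrix(mk_calls(character(0)),
                                        pos$fragment_id, "g1"), pos)
  expect_true(all(r0$proportion == 0))
})

test_that("group difference profiles follow the configured rate imbalance", {
  pos <- mk_positions(n_per_chrom = 100, chroms = c("1H", "2H"))
  gts <- c("wild_1", "wild_2", "cv_1", "cv_2")
  groups <- data.frame(genotype = gts,
                       group = c("wild", "wild", "cultivated", "cultivated"))
  set.seed(3)
  calls <- do.call(rbind, lapply(gts, function(g) {
    rate <- if (grepl("wild", g)) 0.3 else 0.15
    mk_calls(pos$fragment_id[runif(nrow(pos)) < rate], g)
  }))
  vm <- variant_matrix(calls, pos$fragment_id, gts, groups)
  prof <- group_difference_profile(vm, pos)
  s <- attr(prof, "summary")
  expect_gt(s[["n_positive"]], s[["n_negative"]])
  # wild-only variants make every non-zero window positive
  vmw <- variant_matrix(mk_calls(pos$fragment_id[1:30], "wild_1"),
                        pos$fragment_id, gts, groups)
  profw <- group_difference_profile(vmw, pos)
  expect_true(all(profw$difference >= 0))
  expect_error(group_difference_profile(
    variant_matrix(calls, pos$fragment_id, gts), pos), "group")
})

test_that("recombination correlation recovers the placement regime", {
  ref <- generate_reference(n_contigs = 21, contig_length = 50000,
                            chromosomes = c("1H", "2H", "3H"),
                            telomere_enriched = TRUE, seed = 61)
  # one pseudo-fragment every 5 kb
  meta <- ref$contig_meta
  pos <- do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
    st <- seq(0, meta$length[i] - 200, by = 2500)
    data.frame(fragment_id = sprintf("%s_f%04d", meta$contig[i], st),
               contig = meta$contig[i], chrom = meta$chrom[i],
               start = meta$chrom_start[i] + st,
               end = meta$chrom_start[i] + st + 200, arm = "S",
               stringsAsFactors = FALSE)
  }))
  gm <- ref$genetic_map
  rate_of <- numeric(nrow(pos))
  for (chr in unique(pos$chrom)) {
    g <- gm[gm$chrom == chr, ]
    i <- which(pos$chrom == chr)
    x <- pos$start[i]
    rate_of[i] <- pmax(
      stats::approx(g$pos, g$cM, xout = pmin(x + 2.5e4, max(g$pos)))$y -
        stats::approx(g$pos, g$cM, xout = pmax(x - 2.5e4, 0))$y, 1e-6)
  }
  bin_bp <- 20000
  set.seed(62)
  v_prop <- pos$fragment_id[runif(nrow(pos)) < 0.6 * rate_of / max(rate_of)]
  vmp <- variant_matrix(mk_calls(v_prop), pos$fragment_id, "g1")
  res <- recombination_cnv_correlation(vmp, pos, gm, bin_bp = bin_bp)
  expect_gt(res$rho, 0.4)
  # independent placement: |rho| small in most seeds
  small <- 0L
  for (seed in 1:5) {
    set.seed(100 + seed)
    v_ind <- pos$fragment_id[runif(nrow(pos)) < 0.3]
    vmi <- variant_matrix(mk_calls(v_ind), pos$fragment_id, "g1")
    ri <- recombination_cnv_correlation(vmi, pos, gm, bin_bp = bin_bp)
    small <- small + (abs(ri$rho) < 0.3)
  }
  expect_gte(small, 4L)
  # a map covering only one chromosome leaves fewer than 3 populated bins
  expect_error(recombination_cnv_correlation(vmp, pos, gm[gm$chrom == "1H", ],
                                             bin_bp = 1e9), "bins")
})

test_that("exon overlap proportions are recovered exactly by construction", {
  pos <- mk_positions(n_per_chrom = 100, chroms = "1H")
  ann_all <- data.frame(chrom = "1H", start = 0, end = max(pos$end))
  calls <- rbind(mk_calls(pos$fragment_id[1:50], class = "UpCNV"),
                 mk_calls(pos$fragment_id[51:100], class = "DownCNV/PAV"))
  full <- exon_overlap_summary(calls, pos, ann_all)
  expect_equal(full$up_proportion, 1)
  expect_equal(full$down_proportion, 1)
  expect_warning(empty <- exon_overlap_summary(calls, pos, ann_all[0, ]),
                 "empty")
  expect_equal(empty$up_proportion, 0)
  # 30% of Up calls on exons
  exon_frags <- pos[1:15, ]
  ann <- data.frame(chrom = "1H", start = exon_frags$start,
                    end = exon_frags$end)
  part <- exon_overlap_summary(calls, pos, ann)
  expect_equal(part$up_proportion, 0.30)
  expect_equal(part$down_proportion, 0)
})
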