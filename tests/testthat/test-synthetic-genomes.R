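# Reference generation, variant spiking and hybridization simulation.

test_that("reference generation is deterministic and validates inputs", {
  r1 <- generate_reference(n_contigs = 2, contig_length = 10000, seed = 1)
  r2 <- generate_reference(n_contigs = 2, contig_length = 10000, seed = 1)
  expect_identical(r1$contigs, r2$contigs)
  expect_identical(r1$genetic_map, r2$genetic_map)
  expect_false(identical(
    r1$contigs,
    generate_reference(n_contigs = 2, contig_length = 10000, seed = 2)$contigs))
  expect_true(all(grepl("^[ACGT]+$", r1$contigs)))
  expect_error(generate_reference(contig_length = 500, seed = 1), "1 kb")
  expect_error(generate_reference(contig_length = -1, seed = 1), "1 kb")
})

test_that("requested repeat families are embedded at exact copy numbers", {
  motif <- rand_dna(300, seed = 7)
  ref <- generate_reference(n_contigs = 3, contig_length = 12000,
                            repeat_families = data.frame(motif = motif,
                                                         copies = 30),
                            seed = 2)
  expect_equal(sum(vapply(ref$contigs, function(s) {
    hits <- gregexpr(motif, s, fixed = TRUE)[[1]]
    sum(hits > 0)
  }, numeric(1))), 30)
})

test_that("telomere-enriched maps recombine faster near chromosome ends", {
  ref <- generate_reference(n_contigs = 8, contig_length = 10000,
                            chromosomes = c("1H", "2H"), seed = 3)
  gm <- ref$genetic_map
  for (chr in unique(gm$chrom)) {
    g <- gm[gm$chrom == chr, ]
    expect_true(all(diff(g$cM) >= 0))  # cM non-decreasing with bp
    rate <- diff(g$cM) / (diff(g$pos) / 1e6)
    mid <- (head(g$pos, -1) + tail(g$pos, -1)) / 2
    d <- pmin(mid, max(g$pos) - mid)
    expect_lt(cor(d, rate, method = "spearman"), 0)
  }
})

test_that("spiked variants carry exactly their intended signature", {
  ref <- generate_reference(n_contigs = 4, contig_length = 20000, seed = 3)
  specs <- data.frame(type = c("deletion", "deletion", "replacement", "deletion"),
                      size = c(100, 3, 80, 50),
                      mechanism = c("SSA", "slippage", "SDSA", "none"),
                      motif_length = c(5, NA, NA, NA),
                      genotypes = "g1")
  panel <- spike_variants(ref, specs, seed = 4)
  rec <- truth_indel_records(panel)
  mc <- classify_mechanism(rec)
  expect_equal(mc$class, c("SSA", "slippage", "SDSA", "unknown"))
  # the SSA detector at truth coordinates returns the implanted motif length
  expect_equal(mc$signature_length[1], 5L)
  expect_equal(microhomology_length(rec$seq_del[1], rec$flank_left[1],
                                    rec$flank_right[1]), 5L)
  # the slippage deletion has a perfect adjacent copy by construction
  v <- panel$truth[2, ]
  seq <- panel$ref$contigs[[v$contig]]
  expect_identical(substr(seq, v$ref_start + 1, v$ref_end),
                   substr(seq, v$ref_end + 1, v$ref_end + v$size))
})

test_that("an empty spec list leaves the derived genome identical to the reference", {
  ref <- generate_reference(n_contigs = 2, contig_length = 10000, seed = 5)
  panel <- spike_variants(ref, data.frame(), seed = 6, genotypes = "g1")
  expect_identical(panel$genomes$g1, ref$contigs)
  expect_equal(nrow(panel$truth), 0L)
})

test_that("impossible signatures and overlapping specs are rejected", {
  ref <- generate_reference(n_contigs = 2, contig_length = 10000, seed = 5)
  expect_error(spike_variants(ref, data.frame(type = "deletion", size = 20,
                                              mechanism = "SSA",
                                              motif_length = 25),
                              seed = 1), "impossible signature")
  expect_error(spike_variants(ref, data.frame(type = "deletion", size = 8,
                                              mechanism = "slippage"),
                              seed = 1), "slippage")
  specs <- data.frame(contig = "contig_0001", position = c(5000, 5020),
                      type = "deletion", size = 100, mechanism = "none",
                      genotypes = "g1")
  expect_error(spike_variants(ref, specs, seed = 1), "overlap")
})

test_that("zero-noise hybridization follows the copy-number ratio formula", {
  sp <- small_panel()
  probes <- sp$design$probes
  raw <- simulate_hybridization(sp$panel, probes,
                                noise = list(sigma_log2 = 0, additive = 0,
                                             multiplicative = 0),
                                n_replicates = 1, seed = 7)
  ex <- attr(raw, "expected_log2")
  eps <- 0.01
  map <- fragment_probe_map <- strsplit(sp$design$fragments$probe_ids, ",")
  names(map) <- sp$design$fragments$fragment_id
  # duplication: log2((2 + eps)/(1 + eps)); deletion: log2(eps/(1 + eps))
  dup_probes <- unlist(map[sp$dup_fragments])
  expect_true(all(abs(ex[dup_probes, "g1"] - log2((2 + eps) / (1 + eps))) < 1e-12))
  pav_probes <- unlist(map[sp$pav_fragments])
  expect_true(all(abs(ex[pav_probes, "g1"] - log2(eps / (1 + eps))) < 1e-12))
  # raw channel ratio equals the expected ratio exactly under zero noise
  ratio <- log2(raw$ch_sample / raw$ch_ref)
  expect_equal(ratio, unname(ex[raw$probe_id, "g1"]), tolerance = 1e-12)
  # unaffected fragments sit exactly at 0
  affected <- unlist(map[c(sp$pav_fragments, sp$dup_fragments)])
  expect_true(all(ex[setdiff(rownames(ex), affected), "g1"] == 0))
})

test_that("a mid-fragment insertion reproduces the DownCNV artifact", {
  sd <- small_design()
  fr <- sd$design$fragments
  target <- fr[10, ]
  for (ins_size in c(22, 50)) {
    specs <- data.frame(contig = target$contig,
                        position = round((target$start + target$end) / 2),
                        type = "insertion", size = ins_size,
                        mechanism = "none", genotypes = "g1")
    panel <- spike_variants(sd$ref, specs, seed = 9)
    raw <- simulate_hybridization(panel, sd$design$probes,
                                  noise = list(sigma_log2 = 0, additive = 0,
                                               multiplicative = 0),
                                  n_replicates = 1, seed = 11)
    sig <- aggregate_fragment_signal(normalize_intensities(raw), fr)
    expect_lt(sig$signal[match(target$fragment_id, sig$fragment_id)], -0.9)
  }
})

test_that("population panels honor rates and sharing configuration", {
  ref <- generate_reference(n_contigs = 10, contig_length = 30000, seed = 12)
  # rate 0: derived genome equals the reference
  p0 <- generate_population(ref, n_wild = 0, n_cultivated = 1, n_variants = 0,
                            seed = 13)
  expect_identical(p0$genomes$cv_1, ref$contigs)
  # singleton fraction recovered within 3 multinomial SEs
  p1 <- generate_population(ref, n_wild = 3, n_cultivated = 3,
                            n_variants = 150, singleton_fraction = 0.4,
                            size_range = c(60, 200), seed = 14)
  per_variant <- table(p1$truth$variant_id)
  frac <- mean(per_variant == 1)
  se <- sqrt(0.4 * 0.6 / 150)
  expect_lt(abs(frac - 0.4), 3 * se)
  # wild genotypes carry ~2x the variants when configured (pure singletons)
  p2 <- generate_population(ref, n_wild = 4, n_cultivated = 4,
                            n_variants = 200, singleton_fraction = 1,
                            wild_rate_multiplier = 2,
                            size_range = c(60, 120), seed = 15)
  counts <- table(p2$truth$genotype)
  wild_mean <- mean(counts[grep("^wild", names(counts))])
  cv_mean <- mean(counts[grep("^cv", names(counts))])
  expect_gt(wild_mean / cv_mean, 1.4)
  expect_lt(wild_mean / cv_mean, 2.8)
  expect_error(generate_population(ref, 0, 0, seed = 1), "at least one")
})
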