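# Ortholog search, supercontigs, alignment, indel extraction, coverage.

test_that("analyzable contigs need an internally flanked call", {
  frags <- data.frame(fragment_id = sprintf("%s_f%d", rep(c("c1", "c2", "c3"),
                                                          each = 3), 1:3),
                      contig = rep(c("c1", "c2", "c3"), each = 3),
                      start = rep(c(0, 700, 1400), 3), end = rep(c(200, 900, 1600), 3),
                      probe_ids = "x", stringsAsFactors = FALSE)
  calls <- data.frame(fragment_id = c("c1_f2", "c2_f1"), genotype = "g1",
                      class = "DownCNV/PAV", stringsAsFactors = FALSE)
  # c1: [none, Down, none] -> retained; c2: call at the edge -> rejected;
  # c3: no call -> rejected
  expect_equal(select_analyzable_contigs(calls, frags), "c1")
  two <- frags[frags$contig == "c1", ][1:2, ]
  expect_equal(length(select_analyzable_contigs(calls, two)), 0L)
})

test_that("ortholog search finds exact and split copies but not diverged ones", {
  set.seed(71)
  ref <- rand_dna(4000)
  # exact copy -> one full-identity hit
  m1 <- find_orthologs(ref, c(q1 = ref))
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$identity, 100)
  expect_equal(m1$orientation, "+")
  # 10% diverged copy -> below the 95% threshold, no hit
  div <- strsplit(ref, "")[[1]]
  idx <- sample(length(div), 400)
  div[idx] <- vapply(div[idx], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  expect_message(m2 <- find_orthologs(paste(div, collapse = ""), c(q1 = ref)),
                 "no qualifying")
  expect_equal(nrow(m2), 0L)
  # reference spanned by two query contigs -> two chained, non-overlapping hits
  m3 <- find_orthologs(ref, c(qa = substr(ref, 1, 2000),
                              qb = substr(ref, 2001, 4000)))
  expect_equal(nrow(m3), 2L)
  expect_true(all(diff(m3$ref_start) > 0))
  ov <- min(m3$ref_end[1], m3$ref_end[2]) - max(m3$ref_start[2], m3$ref_start[1])
  expect_lte(m3$ref_end[1], m3$ref_start[2])
  # reverse-complement contig is flagged and reoriented
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref)))
  m4 <- find_orthologs(ref, c(q1 = rc))
  expect_equal(m4$orientation, "-")
  sc4 <- build_supercontig(m4, c(q1 = rc))
  expect_identical(sc4$seq, ref)
})

test_that("supercontigs concatenate oriented contigs with a 50 N spacer", {
  set.seed(72)
  ref <- rand_dna(3000)
  qa <- substr(ref, 1, 1500)
  qb <- substr(ref, 1501, 3000)
  m <- find_orthologs(ref, c(qa = qa, qb = qb))
  sc <- build_supercontig(m, c(qa = qa, qb = qb))
  expect_equal(nchar(sc$seq), 3000 + 50)
  expect_equal(sc$map$super_start, c(0, 1550))
  single <- build_supercontig(m[1, ], c(qa = qa, qb = qb))
  expect_identical(single$seq, qa)
  expect_error(build_supercontig(m[0, ], c(qa = qa)), "empty")
})

test_that("alignment scores match a quadratic affine-gap DP oracle", {
  set.seed(73)
  a <- rand_dna(300)
  expect_equal(align_pair(a, a)$score, 300)
  expect_equal(align_pair(a, a)$identity, 100)
  cases <- list(
    del = list(ref = a, query = paste0(substr(a, 1, 150), substr(a, 201, 300))),
    unrelated = list(ref = rand_dna(200), query = rand_dna(200)),
    mut = local({
      x <- strsplit(a, "")[[1]]
      x[seq(10, 290, by = 25)] <- "A"
      list(ref = a, query = paste(x, collapse = ""))
    }))
  for (cs in cases) {
    aln <- align_pair(cs$ref, cs$query)
    expect_equal(aln$score, sw_score_oracle(cs$ref, cs$query))
  }
  expect_error(align_pair("ACGTX", "ACGT"), "A, C, G, T, N")
  expect_error(align_pair("", "ACGT"), "non-empty")
})

test_that("indel extraction recovers gap runs, merges replacements, normalizes left", {
  set.seed(74)
  ref <- rand_dna(800)
  # single 100 bp deletion
  q <- paste0(substr(ref, 1, 400), substr(ref, 501, 800))
  ind <- extract_indels(align_pair(ref, q))
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$side, "deletion")
  expect_equal(ind$size, 100L)
  expect_equal(ind$seq_del, substr(ref, ind$ref_start + 1, ind$ref_end))
  # 3 bp deletion
  q3 <- paste0(substr(ref, 1, 200), substr(ref, 204, 800))
  i3 <- extract_indels(align_pair(ref, q3))
  expect_equal(i3$size, 3L)
  # no gaps -> empty
  expect_equal(nrow(extract_indels(align_pair(ref, ref))), 0L)
  # a 40 bp ref-side gap run immediately followed by a 25 bp query-side gap
  # run merges into one replacement record (alignment constructed directly)
  r1 <- rand_dna(100)
  r2 <- rand_dna(100)
  del40 <- rand_dna(40)
  ins25 <- rand_dna(25)
  constructed <- structure(list(
    aligned_ref = paste0(r1, del40, strrep("-", 25), r2),
    aligned_query = paste0(r1, strrep("-", 40), ins25, r2),
    ref_start = 1L, query_start = 1L, score = NA_real_, identity = NA_real_,
    ref_seq = paste0(r1, del40, r2), query_seq = paste0(r1, ins25, r2)),
    class = "pairwise_aln")
  ir <- extract_indels(constructed)
  expect_equal(ir$side, "replacement")
  expect_equal(nchar(ir$seq_del), 40L)
  expect_equal(nchar(ir$seq_ins), 25L)
  expect_equal(ir$seq_del, del40)
  expect_equal(ir$seq_ins, ins25)
  # a deletion inside a homopolymer run is reported at its leftmost placement
  hp <- paste0(rand_dna(200), strrep("T", 12), rand_dna(200))
  qh <- paste0(substr(hp, 1, 203), substr(hp, 208, 412))  # drop 4 of the Ts
  ih <- extract_indels(align_pair(hp, qh))
  chars <- strsplit(hp, "")[[1]]
  run_start <- max(which(chars[1:201] != "T"))  # 0-based leftmost T of the run
  expect_equal(ih$ref_start, run_start)
  expect_equal(ih$seq_del, "TTTT")
})

test_that("fragment coverage bins follow the published categories", {
  set.seed(75)
  ref <- rand_dna(1200)
  frag <- data.frame(fragment_id = "f1", contig = "c1", start = 500L,
                     end = 700L, stringsAsFactors = FALSE)
  # half the fragment absent -> 50%, bin 50-74
  q <- paste0(substr(ref, 1, 500), substr(ref, 601, 1200))
  aln <- align_pair(ref, q)
  cov <- fragment_coverage(aln, frag, extract_indels(aln))
  expect_equal(cov$percent, 50)
  expect_equal(cov$bin, "50-74")
  expect_false(cov$false_positive)
  # fully aligned with only a 1 bp indel -> bin 100 and false positive
  q1 <- paste0(substr(ref, 1, 600), substr(ref, 602, 1200))
  aln1 <- align_pair(ref, q1)
  cov1 <- fragment_coverage(aln1, frag, extract_indels(aln1))
  expect_equal(cov1$bin, "75-99")  # the 1 bp gap leaves 199/200 aligned
  covc <- fragment_coverage(align_pair(ref, ref), frag, NULL)
  expect_equal(covc$bin, "100")
  expect_true(covc$false_positive)
  # fragment wholly outside the alignment span -> bin 0
  off <- data.frame(fragment_id = "f2", contig = "c1", start = 900L,
                    end = 1100L, stringsAsFactors = FALSE)
  qcut <- substr(ref, 1, 800)
  cov0 <- fragment_coverage(align_pair(ref, qcut), off, NULL)
  expect_equal(cov0$bin, "0")
  # bins partition [0, 100]
  pct <- c(0, 0.5, 24.9, 25, 49.9, 50, 74.9, 75, 99.5, 100)
  bins <- cghcnv:::coverage_bin(pct)
  expect_equal(bins, c("0", "0-24", "0-24", "25-49", "25-49", "50-74",
                       "50-74", "75-99", "75-99", "100"))
})

test_that("a spiked deletion round-trips through the alignment chain", {
  ref <- generate_reference(n_contigs = 3, contig_length = 8000, seed = 21)
  specs <- data.frame(contig = "contig_0002", position = 4000,
                      type = "deletion", size = 120, mechanism = "SSA",
                      motif_length = 8, genotypes = "q")
  panel <- spike_variants(ref, specs, seed = 22)
  m <- find_orthologs(panel$ref$contigs[["contig_0002"]], panel$genomes$q)
  sc <- build_supercontig(m, panel$genomes$q)
  aln <- align_pair(panel$ref$contigs[["contig_0002"]], sc$seq)
  ind <- extract_indels(aln)
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$size, 120L)
  expect_lte(abs(ind$ref_start - panel$truth$ref_start), 2L)
  mc <- classify_mechanism(ind)
  expect_equal(mc$class, "SSA")
  expect_equal(mc$signature_length, 8L)
})
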