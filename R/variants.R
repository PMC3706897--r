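# Spiking mechanism-tagged structural variants into a reference genome and
# deriving per-genotype genomes with a ground-truth table.

VARIANT_TYPES <- c("deletion", "duplication", "insertion", "replacement")
MECHANISMS <- c("SSA", "SDSA", "slippage", "none")

normalize_specs <- function(specs) {
  specs <- as.data.frame(specs, stringsAsFactors = FALSE)
  if (!nrow(specs)) return(specs)
  if (is.null(specs$variant_id)) specs$variant_id <- sprintf("v%04d", seq_len(nrow(specs)))
  if (is.null(specs$contig)) specs$contig <- NA_character_
  if (is.null(specs$position)) specs$position <- NA_integer_
  if (is.null(specs$mechanism)) specs$mechanism <- "none"
  if (is.null(specs$motif_length)) specs$motif_length <- NA_integer_
  if (is.null(specs$ins_size)) specs$ins_size <- NA_integer_
  if (is.null(specs$genotypes)) specs$genotypes <- "g1"
  stopifnot(all(specs$type %in% VARIANT_TYPES),
            all(specs$mechanism %in% MECHANISMS),
            all(specs$size >= 1))
  if (any(specs$mechanism == "slippage" & specs$size > 6))
    stop("slippage variants must have size in [1, 6]")
  if (any(specs$mechanism == "SSA" & specs$type != "deletion"))
    stop("SSA signatures apply to deletions")
  if (any(specs$mechanism == "SDSA" & specs$type != "replacement"))
    stop("SDSA (filler) signatures apply to replacements")
  ssa <- specs$mechanism == "SSA" & !is.na(specs$motif_length)
  if (any(ssa & (specs$motif_length >= specs$size | specs$motif_length < 2 |
                 specs$motif_length > 40)))
    stop("impossible signature: SSA motif must have length in [2, 40] and be shorter than the deletion")
  specs
}

#' Spike structural variants with diagnostic breakpoint signatures
#'
#' Realizes a list of variant specifications on a reference genome: SSA
#' deletions get a border motif implanted at the breakpoint and repeated at
#' the other end inside the deleted region, slippage indels get a perfect
#' adjacent copy of the indel sequence, SDSA replacements get a
#' non-homologous filler segment, and "none" variants are rejection-sampled
#' until they carry no signature (microhomology <= 1 bp, no adjacent perfect
#' repeat, no filler). Each realized variant is verified by re-running the
#' mechanism detectors at the truth coordinates; a variant that cannot be
#' realized with exactly its intended signature is resampled and eventually
#' errors.
#'
#' Signature motifs are ancestral sequence features, so they are written into
#' a copy of the reference, which is returned alongside the derived genomes.
#' Variants must not overlap (sharing across genotypes is expressed through
#' the `genotypes` field of one spec row).
#'
#' @param ref A `cgh_genome`.
#' @param specs `data.frame` of variant specifications with columns `type`
#'   (deletion/duplication/insertion/replacement), `size` (bp) and optionally
#'   `variant_id`, `contig`, `position` (0-based; `NA` = sample), `mechanism`
#'   (`SSA`, `SDSA`, `slippage`, `none`), `motif_length` (SSA), `ins_size`
#'   (replacement filler length) and `genotypes` (comma-separated genotype
#'   ids carrying the variant).
#' @param seed Integer seed.
#' @param genotypes Optional character vector of genotype ids; genotypes not
#'   named by any spec receive an unmodified copy of the reference.
#' @param flank Flank length (bp) used for signature verification.
#' @param max_tries Rejection-sampling budget per variant.
#' @return Object of class `cgh_panel`: list with `ref` (the possibly edited
#'   reference `cgh_genome`), `genomes` (named list of per-genotype contig
#'   sets) and `truth` (one row per variant x genotype with 0-based half-open
#'   `ref_start`/`ref_end`, `query_start`/`query_end`, `type`, `size`,
#'   `mechanism`, `signature_length`, `slippage_unit`, `filler_length`,
#'   `ins_seq`).
#' @export
spike_variants <- function(ref, specs, seed, genotypes = NULL, flank = 60,
                           max_tries = 200) {
  stopifnot(inherits(ref, "cgh_genome"))
  specs <- normalize_specs(specs)
  set.seed(derive_seed(seed, "spike"))
  seqs <- ref$contigs
  lens <- nchar(seqs)
  margin <- flank + 45L
  occupied <- lapply(seqs, function(s) matrix(numeric(0), ncol = 2))

  all_gt <- unique(c(genotypes,
                     unlist(strsplit(specs$genotypes %||% character(0), ","))))
  all_gt <- trimws(all_gt[nzchar(all_gt)])
  if (!length(all_gt)) all_gt <- "g1"

  truth0 <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    size <- as.integer(sp$size)
    fixed_pos <- !is.na(sp$position)
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ctg <- if (!is.na(sp$contig)) sp$contig else
        names(seqs)[sample.int(length(seqs), 1, prob = lens)]
      L <- lens[[ctg]]
      lo <- margin
      hi <- L - size - margin
      if (hi < lo) {
        if (!is.na(sp$contig)) stop(sprintf("variant %s does not fit on contig %s",
                                            sp$variant_id, ctg))
        next
      }
      pos <- if (fixed_pos) as.integer(sp$position) else
        lo + sample.int(hi - lo + 1L, 1) - 1L   # 0-based start
      if (fixed_pos && (pos < 0 || pos + size > L))
        stop(sprintf("variant %s has invalid coordinates", sp$variant_id))
      occ <- occupied[[ctg]]
      if (nrow(occ) &&
          any(interval_overlap(pos - margin, pos + size + margin,
                               occ[, 1], occ[, 2]) > 0)) {
        if (fixed_pos) stop(sprintf("variant %s overlaps another variant", sp$variant_id))
        next
      }
      p1 <- pos + 1L  # 1-based
      save_lo <- max(1L, p1 - flank)
      save_hi <- min(L, p1 + size + margin)
      saved <- substr(seqs[[ctg]], save_lo, save_hi)

      mech <- sp$mechanism
      sig_len <- 0L
      unit <- ""
      ins_seq <- ""
      filler_len <- 0L
      if (mech == "SSA") {
        m <- if (!is.na(sp$motif_length)) as.integer(sp$motif_length) else
          sample(2:max(2L, min(40L, size - 2L)), 1)
        if (m >= size) stop("impossible signature: SSA motif longer than deletion")
        motif <- random_dna(m)
        substr(seqs[[ctg]], p1, p1 + m - 1L) <- motif
        substr(seqs[[ctg]], p1 + size, p1 + size + m - 1L) <- motif
        # block extension of the border motif beyond m
        inside <- substr(seqs[[ctg]], p1 + m, p1 + m)
        alt <- setdiff(c("A", "C", "G", "T"), inside)
        substr(seqs[[ctg]], p1 + size + m, p1 + size + m) <- sample(alt, 1)
        # block left-junction homology
        left_last <- substr(seqs[[ctg]], p1 - 1L, p1 - 1L)
        del_last <- substr(seqs[[ctg]], p1 + size - 1L, p1 + size - 1L)
        if (left_last == del_last) {
          substr(seqs[[ctg]], p1 + size - 1L, p1 + size - 1L) <-
            sample(setdiff(c("A", "C", "G", "T"), left_last), 1)
        }
        sig_len <- m
      } else if (mech == "slippage") {
        unit <- random_dna(size)
        if (sp$type == "deletion") {
          substr(seqs[[ctg]], p1, p1 + size - 1L) <- unit
          substr(seqs[[ctg]], p1 + size, p1 + 2L * size - 1L) <- unit
        } else if (sp$type == "insertion") {
          # insert a copy of the sequence immediately right of the breakpoint
          unit <- substr(seqs[[ctg]], p1, p1 + size - 1L)
          ins_seq <- unit
        } else stop("slippage applies to deletions and insertions")
      } else if (mech == "SDSA") {
        fl <- if (!is.na(sp$ins_size)) as.integer(sp$ins_size) else sample(10:60, 1)
        ins_seq <- random_dna(fl)
        filler_len <- fl
      } else {  # none: actively remove junction homology so no signature remains
        bases <- c("A", "C", "G", "T")
        if (sp$type %in% c("deletion", "replacement")) {
          rf1 <- substr(seqs[[ctg]], p1 + size, p1 + size)
          lfl <- substr(seqs[[ctg]], p1 - 1L, p1 - 1L)
          d1 <- substr(seqs[[ctg]], p1, p1)
          forbid_first <- if (size == 1L) c(rf1, lfl) else rf1
          if (d1 %in% forbid_first)
            substr(seqs[[ctg]], p1, p1) <- sample(setdiff(bases, forbid_first), 1)
          if (size > 1L) {
            dl <- substr(seqs[[ctg]], p1 + size - 1L, p1 + size - 1L)
            if (dl == lfl)
              substr(seqs[[ctg]], p1 + size - 1L, p1 + size - 1L) <-
                sample(setdiff(bases, lfl), 1)
          }
        }
        if (sp$type %in% c("insertion", "replacement")) {
          fl <- if (!is.na(sp$ins_size)) as.integer(sp$ins_size) else size
          ins_seq <- if (sp$type == "replacement")
            substr(seqs[[ctg]], max(1L, p1 - fl), p1 - 1L)  # alignable copy of the left flank
          else random_dna(fl)
          if (sp$type == "insertion" && nchar(ins_seq)) {
            rf1 <- substr(seqs[[ctg]], p1, p1)
            lfl <- substr(seqs[[ctg]], p1 - 1L, p1 - 1L)
            forbid <- if (nchar(ins_seq) == 1L) c(rf1, lfl) else rf1
            if (substr(ins_seq, 1L, 1L) %in% forbid)
              substr(ins_seq, 1L, 1L) <- sample(setdiff(bases, forbid), 1)
            n_i <- nchar(ins_seq)
            if (n_i > 1L && substr(ins_seq, n_i, n_i) == lfl)
              substr(ins_seq, n_i, n_i) <- sample(setdiff(bases, lfl), 1)
          }
        }
      }

      # verify the realized signature with the detectors themselves
      verdict <- TRUE
      if (sp$type != "duplication") {
        left <- substr(seqs[[ctg]], p1 - flank, p1 - 1L)
        right <- substr(seqs[[ctg]], p1 + size, p1 + size + flank - 1L)
        if (sp$type == "insertion") right <- substr(seqs[[ctg]], p1, p1 + flank - 1L)
        seq_del <- if (sp$type == "insertion") "" else
          substr(seqs[[ctg]], p1, p1 + size - 1L)
        side <- switch(sp$type, deletion = "deletion", insertion = "insertion",
                       replacement = "replacement")
        cls <- classify_one(side, seq_del, ins_seq, left, right)
        verdict <- switch(mech,
          SSA = cls$class == "SSA" && cls$signature_length == sig_len,
          slippage = cls$class == "slippage" && cls$slippage_unit == unit,
          SDSA = cls$class == "SDSA",
          none = cls$class == "unknown" && cls$microhomology <= 1L)
      }
      if (!verdict) {
        substr(seqs[[ctg]], save_lo, save_hi) <- saved
        if (fixed_pos && try >= 5L)
          stop(sprintf("variant %s: could not realize its signature at the fixed position",
                       sp$variant_id))
        next
      }
      occupied[[ctg]] <- rbind(occupied[[ctg]], c(pos - margin, pos + size + margin))
      gts <- trimws(strsplit(sp$genotypes, ",")[[1]])
      re <- if (sp$type == "insertion") pos else pos + size
      truth0[[i]] <- data.frame(
        variant_id = sp$variant_id, genotype = gts, contig = ctg,
        ref_start = pos, ref_end = re, type = sp$type, size = size,
        mechanism = mech, signature_length = sig_len, slippage_unit = unit,
        filler_length = filler_len, ins_seq = ins_seq,
        stringsAsFactors = FALSE)
      ok <- TRUE
      break
    }
    if (!ok) stop(sprintf("variant %s: rejection sampling failed after %d tries",
                          specs$variant_id[i], max_tries))
  }
  truth <- if (length(truth0)) do.call(rbind, truth0) else
    data.frame(variant_id = character(0), genotype = character(0),
               contig = character(0), ref_start = integer(0),
               ref_end = integer(0), type = character(0), size = integer(0),
               mechanism = character(0), signature_length = integer(0),
               slippage_unit = character(0), filler_length = integer(0),
               ins_seq = character(0), stringsAsFactors = FALSE)

  ref$contigs <- seqs
  genomes <- lapply(all_gt, function(gt) derive_genome(seqs, truth[truth$genotype == gt, , drop = FALSE]))
  names(genomes) <- all_gt
  # collect query coordinates back into the truth table
  truth$query_start <- rep(NA_integer_, nrow(truth))
  truth$query_end <- rep(NA_integer_, nrow(truth))
  for (gt in all_gt) {
    qc <- attr(genomes[[gt]], "query_coords")
    attr(genomes[[gt]], "query_coords") <- NULL
    idx <- which(truth$genotype == gt)
    if (!length(idx)) next
    key <- paste(truth$variant_id[idx], truth$contig[idx])
    m <- match(key, paste(qc$variant_id, qc$contig))
    truth$query_start[idx] <- qc$query_start[m]
    truth$query_end[idx] <- qc$query_end[m]
  }
  structure(list(ref = ref, genomes = genomes, truth = truth),
            class = "cgh_panel")
}

# Apply one genotype's edits to the (edited) reference contigs, returning the
# derived contig set with per-variant query coordinates as an attribute.
derive_genome <- function(seqs, truth_gt) {
  out <- seqs
  qc <- data.frame(variant_id = character(0), contig = character(0),
                   query_start = integer(0), query_end = integer(0),
                   stringsAsFactors = FALSE)
  for (ctg in unique(truth_gt$contig)) {
    ed <- truth_gt[truth_gt$contig == ctg, , drop = FALSE]
    ed <- ed[order(ed$ref_start), , drop = FALSE]
    seq <- seqs[[ctg]]
    parts <- character(0)
    cur <- 0L
    out_len <- 0L
    qs <- qe <- integer(nrow(ed))
    for (j in seq_len(nrow(ed))) {
      s <- ed$ref_start[j]
      e <- ed$ref_end[j]
      content <- switch(ed$type[j],
        deletion = "",
        duplication = paste0(substr(seq, s + 1L, e), substr(seq, s + 1L, e)),
        insertion = ed$ins_seq[j],
        replacement = ed$ins_seq[j])
      pre <- substr(seq, cur + 1L, s)
      parts <- c(parts, pre, content)
      out_len <- out_len + nchar(pre)
      qs[j] <- out_len
      qe[j] <- out_len + nchar(content)
      out_len <- qe[j]
      cur <- e
    }
    parts <- c(parts, substr(seq, cur + 1L, nchar(seq)))
    out[[ctg]] <- paste(parts, collapse = "")
    qc <- rbind(qc, data.frame(variant_id = ed$variant_id, contig = ctg,
                               query_start = qs, query_end = qe,
                               stringsAsFactors = FALSE))
  }
  attr(out, "query_coords") <- qc
  out
}

#' Indel records at ground-truth coordinates
#'
#' Builds the same record structure as [extract_indels()] directly from the
#' truth table of a spiked panel, with flanks sliced from the (edited)
#' reference. Duplications are skipped (they are copy-number, not indel,
#' events).
#'
#' @param panel A `cgh_panel` from [spike_variants()].
#' @param flank Flank length (bp).
#' @return Indel `data.frame` (see [extract_indels()]) with an extra
#'   `truth_mechanism` column.
#' @export
truth_indel_records <- function(panel, flank = 60) {
  stopifnot(inherits(panel, "cgh_panel"))
  truth <- panel$truth[panel$truth$type != "duplication", , drop = FALSE]
  seqs <- panel$ref$contigs
  n <- nrow(truth)
  rec <- data.frame(
    indel_id = paste(truth$genotype, truth$variant_id, sep = ":"),
    contig = truth$contig, ref_start = truth$ref_start,
    ref_end = truth$ref_end, query_start = truth$query_start,
    query_end = truth$query_end,
    side = ifelse(truth$type == "insertion", "insertion",
                  ifelse(truth$type == "replacement", "replacement", "deletion")),
    size = truth$size, seq_del = character(n), seq_ins = truth$ins_seq,
    flank_left = character(n), flank_right = character(n),
    flank_truncated = logical(n), truth_mechanism = truth$mechanism,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    seq <- seqs[[truth$contig[i]]]
    s <- truth$ref_start[i]
    e <- truth$ref_end[i]
    rec$seq_del[i] <- if (truth$type[i] == "insertion") "" else
      substr(seq, s + 1L, e)
    rec$flank_left[i] <- substr(seq, max(1L, s - flank + 1L), s)
    rec$flank_right[i] <- substr(seq, e + 1L, min(nchar(seq), e + flank))
    rec$flank_truncated[i] <- s - flank < 0 || e + flank > nchar(seq)
  }
  rec
}

#' Generate a genotype panel with shared and private variants
#'
#' Emulates a diversity panel of inbred genotypes (wild and cultivated
#' groups) hybridized against one reference: variants are placed at random
#' non-overlapping positions and assigned to genotypes so that a configurable
#' fraction are singletons (private to one genotype), with wild genotypes
#' receiving variants at `wild_rate_multiplier` times the cultivated rate.
#'
#' @param ref A `cgh_genome`.
#' @param n_wild,n_cultivated Panel sizes (genotype ids `wild_*` / `cv_*`).
#' @param n_variants Total number of distinct variants.
#' @param singleton_fraction Fraction of variants private to one genotype.
#' @param wild_rate_multiplier Relative per-genotype variant rate of the wild
#'   group.
#' @param mechanism_probs Mechanism mixture; the mechanism determines the
#'   variant type (SSA/slippage -> deletion, SDSA -> replacement, none ->
#'   sampled from `type_probs`).
#' @param type_probs Type mixture for mechanism-less variants.
#' @param size_range Size range (bp) for non-slippage variants.
#' @param seed Integer seed.
#' @return A `cgh_panel` (see [spike_variants()]) with an extra `groups`
#'   element (`data.frame` of `genotype`, `group`).
#' @export
generate_population <- function(ref, n_wild, n_cultivated, n_variants = 50,
                                singleton_fraction = 0.391,
                                wild_rate_multiplier = 1.5,
                                mechanism_probs = c(SSA = 0, SDSA = 0,
                                                    slippage = 0, none = 1),
                                type_probs = c(deletion = 0.7, duplication = 0.3),
                                size_range = c(200, 2000), seed) {
  if (n_wild + n_cultivated < 1) stop("the panel must contain at least one genotype")
  set.seed(derive_seed(seed, "population"))
  wild <- if (n_wild) paste0("wild_", seq_len(n_wild)) else character(0)
  cult <- if (n_cultivated) paste0("cv_", seq_len(n_cultivated)) else character(0)
  panel_gt <- c(wild, cult)
  w <- c(rep(wild_rate_multiplier, n_wild), rep(1, n_cultivated))

  specs <- NULL
  if (n_variants > 0) {
    mech <- sample(names(mechanism_probs), n_variants, replace = TRUE,
                   prob = mechanism_probs)
    type <- ifelse(mech %in% c("SSA", "slippage"), "deletion",
                   ifelse(mech == "SDSA", "replacement",
                          sample(names(type_probs), n_variants, replace = TRUE,
                                 prob = type_probs)))
    size <- ifelse(mech == "slippage", sample(1:6, n_variants, replace = TRUE),
                   round(runif(n_variants, size_range[1], size_range[2])))
    carriers <- vapply(seq_len(n_variants), function(i) {
      k <- if (runif(1) < singleton_fraction) 1L else
        min(length(panel_gt), 2L + stats::rpois(1, 1))
      paste(sample(panel_gt, k, prob = w), collapse = ",")
    }, character(1))
    specs <- data.frame(type = type, size = as.integer(size), mechanism = mech,
                        genotypes = carriers, stringsAsFactors = FALSE)
  }
  panel <- spike_variants(ref, specs %||% data.frame(), seed = derive_seed(seed, "population-spike"),
                          genotypes = panel_gt)
  panel$groups <- data.frame(genotype = panel_gt,
                             group = c(rep("wild", n_wild),
                                       rep("cultivated", n_cultivated)),
                             stringsAsFactors = FALSE)
  panel
}

#' Synthetic deletion set with a prescribed mechanism mixture
#'
#' Convenience wrapper: spikes `n` indels whose mechanism classes follow the
#' given proportions (largest-remainder rounding to exact counts) into a
#' fresh synthetic genome, and returns the indel records at truth
#' coordinates. Used to exercise the mechanism classifier and the
#' random-breakpoint enrichment test at a realistic scale.
#'
#' @param n Number of indels.
#' @param proportions Named proportions over SSA, SDSA, slippage, none.
#' @param seed Integer seed.
#' @param n_contigs,contig_length Genome size knobs.
#' @return List with `panel` (a `cgh_panel`), `records` (indel records) and
#'   `counts` (intended class counts).
#' @export
simulate_mechanism_panel <- function(n = 299,
                                     proportions = c(SSA = 0.411, SDSA = 0.127,
                                                     slippage = 0.157, none = 0.304),
                                     seed, n_contigs = 10, contig_length = 60000) {
  proportions <- proportions / sum(proportions)
  counts <- floor(n * proportions)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * proportions - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  set.seed(derive_seed(seed, "mechanism-panel-sizes"))
  mk <- function(mech, k) {
    if (!k) return(NULL)
    switch(mech,
      SSA = data.frame(type = "deletion", mechanism = "SSA",
                       size = sample(20:200, k, replace = TRUE)),
      SDSA = data.frame(type = "replacement", mechanism = "SDSA",
                        size = sample(30:200, k, replace = TRUE),
                        ins_size = sample(10:60, k, replace = TRUE)),
      slippage = data.frame(type = "deletion", mechanism = "slippage",
                            size = sample(1:6, k, replace = TRUE)),
      none = data.frame(type = "deletion", mechanism = "none",
                        size = sample(7:200, k, replace = TRUE)))
  }
  specs <- do.call(rbind, c(lapply(names(counts), function(m) {
    s <- mk(m, counts[[m]])
    if (!is.null(s) && is.null(s$ins_size)) s$ins_size <- NA_integer_
    s
  })))
  specs$genotypes <- "query"
  ref <- generate_reference(n_contigs = n_contigs,
                            contig_length = contig_length,
                            seed = derive_seed(seed, "mechanism-panel-genome"))
  panel <- spike_variants(ref, specs, seed = derive_seed(seed, "mechanism-panel-spike"))
  list(panel = panel, records = truth_indel_records(panel), counts = counts)
}
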