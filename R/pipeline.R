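# Orchestration: one YAML config, deterministic per-stage seeds, fixed
# output file names under a run directory, and a manifest with checksums.

config_defaults <- function() {
  list(
    seed = 1L,
    outdir = "cghcnv_run",
    genome = list(n_contigs = 14L, contig_length = 10000L, gc = 0.45,
                  telomere_enriched = TRUE, map_points = 25L),
    panel = list(n_wild = 2L, n_cultivated = 2L, n_variants = 40L,
                 singleton_fraction = 0.391, wild_rate_multiplier = 1.5),
    design = list(min_len = 56L, max_len = 100L, step = 10L, tm_target = 74.5,
                  k = 15L, max_avg_freq = 25, min_match = 30L, max_gaps = 5L,
                  span = 200L, per_fragment = 10L, min_gap = 500L),
    hybridization = list(sigma_log2 = 0.2, additive = 100, multiplicative = 0.1,
                         n_replicates = 2L, eps = 0.01),
    calling = list(p_min = 0.95, min_abs_log2 = 0.9, tol = 1e-8,
                   max_iter = 500L),
    landscape = list(window_bp = 1500000, bin_bp = 10000000),
    orthologs = list(genotype = NA_character_, min_identity = 95),
    mechanism = list(n_sim = 1000L, min_filler = 5L, max_identity = 60)
  )
}

check_config_value <- function(cfg, violations) {
  chk <- function(cond, msg) if (!cond) c(violations, msg) else violations
  violations <- chk(cfg$calling$min_abs_log2 > 0,
                    "calling.min_abs_log2 must be > 0")
  violations <- chk(cfg$calling$p_min > 0 && cfg$calling$p_min < 1,
                    "calling.p_min must be in (0, 1)")
  violations <- chk(cfg$design$min_len <= cfg$design$max_len,
                    "design.min_len must be <= design.max_len")
  violations <- chk(cfg$hybridization$sigma_log2 >= 0,
                    "hybridization.sigma_log2 must be >= 0")
  violations <- chk(cfg$panel$n_wild + cfg$panel$n_cultivated >= 1,
                    "panel must contain at least one genotype")
  violations <- chk(cfg$mechanism$n_sim >= 1, "mechanism.n_sim must be >= 1")
  violations
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), rejects unknown keys, fills in all
#' defaults, and checks value constraints; all violations are reported
#' together.
#'
#' @param config Path to a YAML file or a named list.
#' @return The fully-defaulted configuration (class `cgh_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config) %||% list()
  }
  stopifnot(is.list(config))
  defaults <- config_defaults()
  violations <- character(0)
  for (key in names(config)) {
    if (!key %in% names(defaults)) {
      violations <- c(violations, sprintf("unknown key: %s", key))
      next
    }
    if (is.list(defaults[[key]])) {
      bad <- setdiff(names(config[[key]]), names(defaults[[key]]))
      if (length(bad))
        violations <- c(violations,
                        sprintf("unknown key: %s.%s", key, bad))
    }
  }
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (!length(violations)) violations <- check_config_value(cfg, character(0))
  if (length(violations))
    stop(paste(c("invalid configuration:", violations), collapse = "\n  "))
  structure(cfg, class = "cgh_config")
}

stage_order <- function() {
  c("simulate", "design", "normalize", "call", "landscape", "orthologs", "mech")
}

#' Run the CNV pipeline
#'
#' Executes the stages in dependency order — simulate (synthetic genomes,
#' panel, intensities), design (probes and fragments), normalize, call,
#' landscape, orthologs (sequence-level confirmation of one genotype) and
#' mech (mechanism classification plus enrichment test) — writing fixed-name
#' TSV/BED/FASTA/JSON outputs under the run directory. A subset of stages
#' can be run when the upstream outputs already exist in the directory.
#'
#' @param config A `cgh_config`, path to a YAML file, or list.
#' @param stages Character vector of stages to run.
#' @param outdir Output directory (overrides the config's).
#' @return The run manifest (list with config hash, per-stage timings and
#'   output checksums), also written to `manifest.json`.
#' @export
run_pipeline <- function(config, stages = stage_order(), outdir = NULL) {
  cfg <- if (inherits(config, "cgh_config")) config else validate_config(config)
  stages <- match.arg(stages, stage_order(), several.ok = TRUE)
  stages <- stage_order()[stage_order() %in% stages]
  outdir <- outdir %||% cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)
  yaml::write_yaml(unclass(cfg), pth("config.yaml"))
  need <- function(f, stage) {
    if (!file.exists(pth(f)))
      stop(sprintf("stage '%s' requires missing upstream output %s", stage, f))
    pth(f)
  }
  manifest <- list(config_hash = unname(tools::md5sum(pth("config.yaml"))),
                   version = as.character(utils::packageVersion("cghcnv")),
                   seed = cfg$seed, stages = list())
  state <- new.env(parent = emptyenv())

  timings <- c()
  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    files <- switch(stage,
      simulate = {
        ref <- generate_reference(n_contigs = cfg$genome$n_contigs,
                                  contig_length = cfg$genome$contig_length,
                                  gc = cfg$genome$gc,
                                  telomere_enriched = cfg$genome$telomere_enriched,
                                  map_points = cfg$genome$map_points,
                                  seed = derive_seed(cfg$seed, "genome"))
        panel <- generate_population(ref, cfg$panel$n_wild, cfg$panel$n_cultivated,
                                     n_variants = cfg$panel$n_variants,
                                     singleton_fraction = cfg$panel$singleton_fraction,
                                     wild_rate_multiplier = cfg$panel$wild_rate_multiplier,
                                     seed = derive_seed(cfg$seed, "panel"))
        state$panel <- panel
        write_genome_fasta(panel$ref, pth("reference.fasta"))
        for (gt in names(panel$genomes))
          write_genome_fasta(panel$genomes[[gt]], pth(sprintf("genome_%s.fasta", gt)))
        write_tsv_file(panel$truth, pth("truth.tsv"))
        write_tsv_file(panel$groups, pth("groups.tsv"))
        write_tsv_file(panel$ref$genetic_map, pth("genetic_map.tsv"))
        write_tsv_file(panel$ref$contig_meta, pth("contig_meta.tsv"))
        c("reference.fasta", "truth.tsv", "groups.tsv", "genetic_map.tsv",
          "contig_meta.tsv")
      },
      design = {
        if (is.null(state$panel)) stop("stage 'design' requires stage 'simulate' in the same run")
        d <- design_array(state$panel$ref,
                          min_len = cfg$design$min_len, max_len = cfg$design$max_len,
                          step = cfg$design$step, tm_target = cfg$design$tm_target,
                          k = cfg$design$k, max_avg_freq = cfg$design$max_avg_freq,
                          min_match = cfg$design$min_match, max_gaps = cfg$design$max_gaps,
                          span = cfg$design$span, per_fragment = cfg$design$per_fragment,
                          min_gap = cfg$design$min_gap)
        state$design <- d
        write_tsv_file(d$probes[, c("probe_id", "contig", "start", "length", "sequence")],
                       pth("probes.tsv"))
        write_tsv_file(d$fragments, pth("fragments.tsv"))
        write_fragments_bed(d$fragments, pth("fragments.bed"))
        jsonlite::write_json(d$summary, pth("design_summary.json"))
        c("probes.tsv", "fragments.tsv", "fragments.bed", "design_summary.json")
      },
      normalize = {
        if (is.null(state$panel) || is.null(state$design))
          stop("stage 'normalize' requires stages 'simulate' and 'design' in the same run")
        raw <- simulate_hybridization(
          state$panel, state$design$probes,
          noise = cfg$hybridization[c("sigma_log2", "additive", "multiplicative")],
          n_replicates = cfg$hybridization$n_replicates,
          eps = cfg$hybridization$eps,
          seed = derive_seed(cfg$seed, "hybridization"))
        write_tsv_file(raw, pth("intensities.tsv"))
        ratios <- normalize_intensities(raw)
        signals <- aggregate_fragment_signal(ratios, state$design$fragments)
        state$signals <- signals
        write_tsv_file(ratios, pth("probe_ratios.tsv"))
        write_tsv_file(signals, pth("fragment_signals.tsv"))
        c("intensities.tsv", "probe_ratios.tsv", "fragment_signals.tsv")
      },
      call = {
        if (is.null(state$signals)) {
          f <- need("fragment_signals.tsv", "call")
          state$signals <- read_tsv_file(f)
          state$design <- list(fragments = read_tsv_file(need("fragments.tsv", "call")))
        }
        res <- call_cnv_panel(state$signals, p_min = cfg$calling$p_min,
                              min_abs_log2 = cfg$calling$min_abs_log2,
                              tol = cfg$calling$tol, max_iter = cfg$calling$max_iter)
        state$calls <- res$calls
        events <- merge_consecutive_events(res$calls, state$design$fragments)
        write_tsv_file(res$calls, pth("cnv_calls.tsv"))
        write_tsv_file(events, pth("cnv_events.tsv"))
        c("cnv_calls.tsv", "cnv_events.tsv")
      },
      landscape = {
        if (is.null(state$calls)) {
          state$calls <- read_tsv_file(need("cnv_calls.tsv", "landscape"))
          state$design <- list(fragments = read_tsv_file(need("fragments.tsv", "landscape")))
        }
        if (is.null(state$panel)) stop("stage 'landscape' requires stage 'simulate' in the same run")
        frags <- state$design$fragments
        pos <- fragment_positions(state$panel$ref, frags)
        vm <- variant_matrix(state$calls, frags$fragment_id,
                             names(state$panel$genomes), state$panel$groups)
        spec <- frequency_spectrum(vm)
        rates <- chromosome_rates(vm, pos, window_bp = cfg$landscape$window_bp)
        wins <- window_proportions(vm, pos, window_bp = cfg$landscape$window_bp)
        write_tsv_file(rates, pth("chromosome_rates.tsv"))
        write_tsv_file(wins, pth("window_proportions.tsv"))
        jsonlite::write_json(
          list(spectrum = as.list(spec$counts),
               singleton_fraction = spec$singleton_fraction,
               n_variant_fragments = spec$n_variant_fragments),
          pth("frequency_spectrum.json"), auto_unbox = TRUE)
        c("chromosome_rates.tsv", "window_proportions.tsv",
          "frequency_spectrum.json")
      },
      orthologs = {
        if (is.null(state$panel) || is.null(state$calls) || is.null(state$design))
          stop("stage 'orthologs' requires stages 'simulate' and 'call' in the same run")
        gt <- cfg$orthologs$genotype
        if (is.na(gt)) gt <- names(state$panel$genomes)[1]
        conf <- confirm_cnv_sequence(state$panel$ref, state$panel$genomes[[gt]],
                                     state$calls[state$calls$genotype == gt, ],
                                     state$design$fragments,
                                     min_identity = cfg$orthologs$min_identity)
        state$indels <- conf$indels %||% data.frame(
          indel_id = character(0), ref_start = integer(0),
          ref_end = integer(0), query_start = integer(0),
          query_end = integer(0), side = character(0), size = integer(0),
          seq_del = character(0), seq_ins = character(0),
          flank_left = character(0), flank_right = character(0),
          flank_truncated = logical(0), stringsAsFactors = FALSE)
        write_tsv_file(state$indels, pth("indels.tsv"))
        if (!is.null(conf$coverage)) write_tsv_file(conf$coverage, pth("fragment_coverage.tsv"))
        intersect(c("indels.tsv", "fragment_coverage.tsv"), list.files(outdir))
      },
      mech = {
        if (is.null(state$indels)) {
          f <- need("indels.tsv", "mech")
          state$indels <- read_tsv_file(f)
        }
        if (is.null(state$panel)) stop("stage 'mech' requires stage 'simulate' in the same run")
        ind <- state$indels
        mech <- classify_mechanism(ind, min_filler = cfg$mechanism$min_filler,
                                   max_identity = cfg$mechanism$max_identity)
        write_tsv_file(mech, pth("mechanisms.tsv"))
        files <- "mechanisms.tsv"
        if (nrow(ind)) {
          null <- random_indel_null(state$panel$ref, pmax(ind$size, 1),
                                    n_sim = cfg$mechanism$n_sim,
                                    seed = derive_seed(cfg$seed, "null"))
          enr <- signature_enrichment_test(observed_signature_counts(mech), null)
          jsonlite::write_json(enr, pth("enrichment.json"), digits = NA)
          files <- c(files, "enrichment.json")
        }
        files
      })
    manifest$stages[[stage]] <- list(
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = as.list(tools::md5sum(file.path(outdir, files))))
    timings <- c(timings, stage)
  }
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
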