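# Configuration, orchestration and provenance for the five analysis stages:
# simulate -> call -> score -> qc -> cluster. Each stage reads and writes
# plain-text files under the configured output directory, so any stage can
# be re-run or resumed; a JSON manifest records parameters, per-stage seeds
# and output checksums.

pipeline_defaults <- function() {
  list(
    outdir = "codonscan_run",
    seed = 1L,
    read_level = TRUE,
    simulate = list(
      n_variants = 25L, n_conditions = 14L, depth = 10000L,
      n_replicates = 3L, wt_fraction = 0.1, noise_sd = 0.3,
      error_rate = 0.001, template_switch_rate = 0.02,
      switch_suppression = 2.5, spike_in_fraction = 0.01
    ),
    scheme = list(codon_match = 1L, codon_mismatch = -1L, indel = -2L),
    flank_len = 15L,
    band = 9L,
    filters = list(min_pool_reads = 200L, min_condition_reads = 50L,
                   pool_condition_name = "SC-Leu", rule = "both"),
    score = list(pseudocount = 0.5, log_base = 2),
    cluster = list(linkage = "average", k_min = 2L, k_max = 8L)
  )
}

merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    if (!key %in% names(defaults))
      stop("unknown configuration key: ",
           paste(c(path, key), collapse = "."))
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key ", paste(c(path, key), collapse = "."),
             " must be a block")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, rejects unknown keys
#' and invalid parameter values, and returns the completed configuration.
#'
#' @param config path to a YAML file, or a list of overrides (possibly
#'   empty for all-defaults).
#' @return A validated list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  if (inherits(config, "pipeline_config")) config <- unclass(config)
  cfg <- merge_config(pipeline_defaults(), config)
  errs <- character()
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  sim <- cfg$simulate
  chk(sim$depth > 0, "simulate.depth must be positive")
  chk(sim$n_variants >= 8, "simulate.n_variants must be >= 8")
  chk(sim$n_replicates >= 1, "simulate.n_replicates must be >= 1")
  chk(sim$n_conditions >= 2 && sim$n_conditions <= length(default_conditions()),
      "simulate.n_conditions must lie in [2, 14]")
  chk(sim$wt_fraction > 0 && sim$wt_fraction < 1,
      "simulate.wt_fraction must lie in (0,1)")
  chk(sim$error_rate >= 0 && sim$error_rate <= 1,
      "simulate.error_rate must lie in [0,1]")
  chk(sim$template_switch_rate >= 0 && sim$template_switch_rate <= 1,
      "simulate.template_switch_rate must lie in [0,1]")
  chk(sim$noise_sd >= 0, "simulate.noise_sd must be >= 0")
  chk(cfg$scheme$codon_match > 0, "scheme.codon_match must be positive")
  chk(cfg$scheme$codon_mismatch < 0, "scheme.codon_mismatch must be negative")
  chk(cfg$scheme$indel < 0, "scheme.indel must be negative")
  chk(cfg$filters$min_pool_reads >= 0, "filters.min_pool_reads must be >= 0")
  chk(cfg$filters$min_condition_reads >= 0,
      "filters.min_condition_reads must be >= 0")
  chk(cfg$filters$rule %in% c("both", "either"),
      "filters.rule must be 'both' or 'either'")
  chk(cfg$score$pseudocount >= 0, "score.pseudocount must be >= 0")
  chk(cfg$score$log_base > 1, "score.log_base must be > 1")
  chk(cfg$cluster$linkage %in% c("average", "complete", "single"),
      "cluster.linkage must be average, complete or single")
  chk(cfg$cluster$k_min >= 2 && cfg$cluster$k_max >= cfg$cluster$k_min,
      "cluster.k_min/k_max must satisfy 2 <= k_min <= k_max")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  structure(cfg, class = "pipeline_config")
}

#' Serialize a validated configuration back to YAML
#' @param cfg a `pipeline_config`.
#' @param path output YAML file.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Fill missing variant x sample combinations with zero counts so that
# downstream joins see a complete table.
complete_counts <- function(counts) {
  samples <- unique(counts[c("sample", "condition", "replicate", "role")])
  ids <- unique(counts$variant_id)
  full <- merge(samples, data.frame(variant_id = ids))
  out <- merge(full, counts, all.x = TRUE,
               by = c("sample", "condition", "replicate", "role", "variant_id"))
  out$count[is.na(out$count)] <- 0L
  out[order(out$sample, out$variant_id), ]
}

stage_simulate <- function(cfg, dirs) {
  sim <- cfg$simulate
  ref <- make_reference()
  evs <- make_variant_set(ref, spike_in_fraction = sim$spike_in_fraction)
  conds <- default_conditions()[seq_len(sim$n_conditions)]
  ls <- simulate_landscape_screen(
    n_variants = sim$n_variants,
    config = class_profile_config(conditions = conds,
                                  class_effects = default_class_effects(conds),
                                  noise_sd = sim$noise_sd,
                                  seed = derive_seed(cfg$seed, "classcfg")),
    depth = sim$depth, n_replicates = sim$n_replicates,
    wt_fraction = sim$wt_fraction, seed = derive_seed(cfg$seed, "simulate"),
    ref = ref, evs = evs)
  write_reference_fasta(ref, file.path(dirs$out, "reference.fasta"))
  write_whitelist(evs, file.path(dirs$out, "whitelist.tsv"))
  eff <- ls$effects
  truth <- data.frame(variant_id = rep(rownames(eff), ncol(eff)),
                      condition = rep(colnames(eff), each = nrow(eff)),
                      true_effect = as.vector(eff))
  write_tsv_plain(truth, file.path(dirs$out, "truth_effects.tsv"))
  write_tsv_plain(data.frame(variant_id = names(ls$classes),
                             class = ls$classes),
                  file.path(dirs$out, "truth_classes.tsv"))

  if (!cfg$read_level) {
    # molecule-level template switching on each sample, then counts out
    rows <- split(ls$counts, ls$counts$sample)
    out <- lapply(rows, function(df) {
      cv <- stats::setNames(df$count, df$variant_id)
      cv <- apply_template_switching(
        cv, evs, sim$template_switch_rate, "emulsion",
        sim$switch_suppression,
        seed = derive_seed(cfg$seed, paste0("switch_", df$sample[1])))
      data.frame(sample = df$sample[1], condition = df$condition[1],
                 replicate = df$replicate[1], role = df$role[1],
                 variant_id = names(cv), count = as.integer(cv))
    })
    counts <- do.call(rbind, out)
    rownames(counts) <- NULL
    write_tsv_plain(counts, file.path(dirs$out, "counts.tsv"))
    return(c("reference.fasta", "whitelist.tsv", "truth_effects.tsv",
             "truth_classes.tsv", "counts.tsv"))
  }

  fq_dir <- file.path(dirs$out, "fastq")
  dir.create(fq_dir, showWarnings = FALSE)
  sheets <- list()
  for (s in unique(ls$counts$sample)) {
    df <- ls$counts[ls$counts$sample == s, ]
    cv <- stats::setNames(df$count, df$variant_id)
    r1 <- file.path("fastq", paste0(s, "_R1.fastq"))
    r2 <- file.path("fastq", paste0(s, "_R2.fastq"))
    simulate_reads(cv, ref, evs, file.path(dirs$out, r1),
                   file.path(dirs$out, r2), error_rate = sim$error_rate,
                   template_switch_rate = sim$template_switch_rate,
                   pcr_mode = "emulsion",
                   switch_suppression = sim$switch_suppression,
                   seed = derive_seed(cfg$seed, paste0("reads_", s)),
                   sample_id = s)
    sheets[[s]] <- data.frame(sample = s, condition = df$condition[1],
                              replicate = df$replicate[1], role = df$role[1],
                              fastq1 = r1, fastq2 = r2)
  }
  write_sample_sheet(do.call(rbind, sheets),
                     file.path(dirs$out, "sample_sheet.tsv"))

  # the pool of replicate 1 rendered under regular PCR as the template-
  # switching comparison library
  pool1 <- ls$counts[ls$counts$role == "unselected" & ls$counts$replicate == 1, ]
  cv <- stats::setNames(pool1$count, pool1$variant_id)
  qf1 <- file.path("fastq", "QC_regular_R1.fastq")
  qf2 <- file.path("fastq", "QC_regular_R2.fastq")
  simulate_reads(cv, ref, evs, file.path(dirs$out, qf1),
                 file.path(dirs$out, qf2), error_rate = sim$error_rate,
                 template_switch_rate = sim$template_switch_rate,
                 pcr_mode = "regular",
                 switch_suppression = sim$switch_suppression,
                 seed = derive_seed(cfg$seed, "reads_QC_regular"),
                 sample_id = "QC_regular")
  write_tsv_plain(data.frame(sample = c(pool1$sample[1], "QC_regular"),
                             mode = c("emulsion", "regular"),
                             fastq1 = c(sheets[[pool1$sample[1]]]$fastq1, qf1),
                             fastq2 = c(sheets[[pool1$sample[1]]]$fastq2, qf2)),
                  file.path(dirs$out, "qc_sheet.tsv"))
  c("reference.fasta", "whitelist.tsv", "truth_effects.tsv",
    "truth_classes.tsv", "sample_sheet.tsv", "qc_sheet.tsv")
}

stage_call <- function(cfg, dirs) {
  ref <- read_reference_fasta(file.path(dirs$out, "reference.fasta"))
  evs <- read_whitelist(file.path(dirs$out, "whitelist.tsv"), ref)
  scheme <- scoring_scheme(cfg$scheme$codon_match, cfg$scheme$codon_mismatch,
                           cfg$scheme$indel)
  if (!cfg$read_level) return(c("counts.tsv"))
  sheet <- read_sample_sheet(file.path(dirs$out, "sample_sheet.tsv"))
  abs_path <- function(p) ifelse(substr(p, 1, 1) == "/", p,
                                 file.path(dirs$out, p))
  counts <- list(); rejects <- list()
  for (k in seq_len(nrow(sheet))) {
    ac <- call_fastq(abs_path(sheet$fastq1[k]), abs_path(sheet$fastq2[k]),
                     ref, evs, scheme,
                     flank_len = cfg$flank_len, band = cfg$band,
                     sample = sheet$sample[k], condition = sheet$condition[k],
                     replicate = sheet$replicate[k], role = sheet$role[k])
    counts[[k]] <- ac$counts
    rejects[[k]] <- data.frame(sample = sheet$sample[k],
                               reason = names(ac$rejected),
                               count = as.integer(ac$rejected))
  }
  counts <- complete_counts(do.call(rbind, counts))
  write_tsv_plain(counts, file.path(dirs$out, "counts.tsv"))
  write_tsv_plain(do.call(rbind, rejects), file.path(dirs$out, "rejects.tsv"))

  qsheet <- read_tsv_plain(file.path(dirs$out, "qc_sheet.tsv"))
  qcounts <- lapply(seq_len(nrow(qsheet)), function(k) {
    ac <- call_fastq(abs_path(qsheet$fastq1[k]), abs_path(qsheet$fastq2[k]),
                     ref, evs, scheme,
                     flank_len = cfg$flank_len, band = cfg$band,
                     sample = qsheet$sample[k], condition = "pool",
                     replicate = 1L, role = "qc")
    cbind(ac$counts, mode = qsheet$mode[k])
  })
  write_tsv_plain(do.call(rbind, qcounts), file.path(dirs$out, "qc_counts.tsv"))
  c("counts.tsv", "rejects.tsv", "qc_counts.tsv")
}

stage_score <- function(cfg, dirs) {
  counts <- read_tsv_plain(file.path(dirs$out, "counts.tsv"))
  fcfg <- filter_config(cfg$filters$min_pool_reads,
                        cfg$filters$min_condition_reads,
                        cfg$filters$pool_condition_name, cfg$filters$rule)
  rs <- score_screen(counts, fcfg, pseudocount = cfg$score$pseudocount,
                     log_base = cfg$score$log_base)
  sm <- aggregate_replicates(rs)
  write_tsv_plain(as.data.frame(rs), file.path(dirs$out, "replicate_scores.tsv"))
  write_score_matrix(sm, file.path(dirs$out, "score_matrix.tsv"))
  flt <- apply_filters(counts, fcfg)
  write_tsv_plain(flt, file.path(dirs$out, "filter_report.tsv"))
  c("replicate_scores.tsv", "score_matrix.tsv", "filter_report.tsv")
}

stage_qc <- function(cfg, dirs) {
  counts <- read_tsv_plain(file.path(dirs$out, "counts.tsv"))
  ref <- read_reference_fasta(file.path(dirs$out, "reference.fasta"))
  spike_ids <- names(spike_in_classes())
  p <- parse_variant_id(spike_ids)
  spikes <- data.frame(variant_id = spike_ids,
                       residue = p$residue[match(spike_ids, p$id)])
  pool <- counts[counts$role == "unselected", ]
  fr <- allele_frequencies(pool)
  mat <- tapply(fr$freq, list(fr$variant_id, fr$sample), sum)
  mat[is.na(mat)] <- 0
  rep_cor <- replicate_correlation(mat)

  out <- list(replicate_correlation = rep_cor)
  qc_path <- file.path(dirs$out, "qc_counts.tsv")
  if (file.exists(qc_path)) {
    qc <- read_tsv_plain(qc_path)
    reports <- lapply(split(qc, qc$mode), function(df) {
      template_switch_ratio(allele_frequencies(df), spikes)
    })
    out$mean_ratio <- lapply(reports, function(r) r$mean_ratio)
    if (all(c("regular", "emulsion") %in% names(reports))) {
      cmp <- compare_pcr_modes(reports$regular, reports$emulsion)
      out$fold_suppression <- cmp$fold_suppression
      write_tsv_plain(reports$regular$per_pair,
                      file.path(dirs$out, "qc_pairs_regular.tsv"))
    }
  }
  jsonlite::write_json(out, file.path(dirs$out, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA)
  c("qc_report.json")
}

stage_cluster <- function(cfg, dirs) {
  sm <- read_tsv_plain(file.path(dirs$out, "score_matrix.tsv"),
                       check.names = FALSE)
  m <- as.matrix(sm[, -1, drop = FALSE])
  rownames(m) <- sm$variant_id
  hc <- hier_cluster(m, linkage = cfg$cluster$linkage)
  ca <- assign_classes(hc, k_range = cfg$cluster$k_min:cfg$cluster$k_max)
  write_tsv_plain(data.frame(variant_id = names(ca$labels), class = ca$labels),
                  file.path(dirs$out, "classes.tsv"))
  write_tsv_plain(data.frame(k = as.integer(names(ca$silhouette)),
                             mean_silhouette = ca$silhouette),
                  file.path(dirs$out, "silhouette.tsv"))
  write_dendrogram_newick(hc, file.path(dirs$out, "dendrogram.nwk"))
  c("classes.tsv", "silhouette.tsv", "dendrogram.nwk")
}

#' Run the analysis pipeline end to end (or resume part of it)
#'
#' Executes the requested stages in order `simulate`, `call`, `score`,
#' `qc`, `cluster`, each reading its inputs from and writing its outputs to
#' `cfg$outdir`, and writes `manifest.json` recording the configuration,
#' per-stage output files and their MD5 checksums. Identical configuration
#' and seed reproduce identical checksums.
#'
#' @param config a `pipeline_config`, a YAML path, or a list of overrides.
#' @param stages character vector of stages to run (default: all five).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "call", "score", "qc",
                                    "cluster")) {
  cfg <- validate_config(config)
  order_all <- c("simulate", "call", "score", "qc", "cluster")
  stages <- order_all[order_all %in% stages]
  if (length(stages) == 0L) stop("no recognized stage requested")
  dirs <- list(out = cfg$outdir)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  runners <- list(simulate = stage_simulate, call = stage_call,
                  score = stage_score, qc = stage_qc, cluster = stage_cluster)
  manifest <- list(config = unclass(cfg), stages = list())
  for (st in stages) {
    files <- tryCatch(runners[[st]](cfg, dirs), error = function(e)
      stop("stage '", st, "' failed: ", conditionMessage(e), call. = FALSE))
    paths <- file.path(cfg$outdir, files)
    manifest$stages[[st]] <- list(
      outputs = files,
      md5 = as.list(stats::setNames(unname(tools::md5sum(paths)), files)),
      seed = derive_seed(cfg$seed, st))
  }
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
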