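#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or a YAML file parsed into one)
#' selecting pipeline stages and their inputs. Recognized stages:
#' `consensus` (degenerate-consensus genome scan), `info` (information
#' model build + weight-matrix rescan), `chip` (bound-region calling and
#' sequence export), `expression` (gene scores and regulation calls),
#' `classify` (GRS/CAS labeling of the consensus hits or of a supplied
#' operator table). All referenced files must exist and all parameters
#' are range-checked before any stage runs.
#'
#' @param config Named list or path to a YAML file.
#' @return The normalized configuration list, invisibly on success;
#'   errors name the offending field.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  stages <- config$stages
  if (is.null(stages) || length(stages) == 0L)
    stop("config error: 'stages' must list at least one stage")
  known <- c("consensus", "info", "chip", "expression", "classify")
  bad <- setdiff(stages, known)
  if (length(bad) > 0L)
    stop("config error: unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(config$out_dir)) stop("config error: 'out_dir' is required")
  need_file <- function(field) {
    path <- config[[field]]
    if (is.null(path)) stop("config error: '", field, "' is required for the selected stages")
    if (!file.exists(path)) stop("config error: ", field, " file not found: ", path)
    path
  }
  if (any(stages %in% c("consensus", "info"))) need_file("genome_fasta")
  if ("info" %in% stages) need_file("operators_tsv")
  if ("chip" %in% stages) {
    need_file("probes_tsv")
    if (is.null(config$chip_threshold) || !is.numeric(config$chip_threshold))
      stop("config error: 'chip_threshold' (numeric) is required for the chip stage")
    need_file("genome_fasta")
  }
  if ("expression" %in% stages) {
    need_file("wt_tsv"); need_file("mut_tsv"); need_file("annotation_tsv")
  }
  if ("classify" %in% stages) {
    need_file("tss_tsv")
    if (is.null(config$operators_tsv) && !("consensus" %in% stages))
      stop("config error: classify stage needs 'operators_tsv' or the consensus stage")
    if (!is.null(config$operators_tsv)) need_file("operators_tsv")
  }
  if (!is.null(config$expression_cutoff) && config$expression_cutoff <= 1)
    stop("config error: 'expression_cutoff' must be > 1")
  if (!is.null(config$info_threshold) && !is.numeric(config$info_threshold))
    stop("config error: 'info_threshold' must be numeric")
  invisible(config)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline from a single declarative configuration
#'
#' Stages run in dependency order (`consensus`, `info`, `chip`,
#' `expression`, `classify`); any failure aborts with a stage-named
#' error. Outputs are written to a staging directory and moved into
#' `out_dir` only when every stage succeeds, so partial results are
#' never mixed with a complete manifest. The manifest (JSON) echoes
#' every parameter and lists each output file with its MD5 checksum;
#' rerunning an identical configuration on identical inputs reproduces
#' byte-identical outputs.
#'
#' @param config Named list or YAML path, see [validate_config()].
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  stages <- config$stages
  out_dir <- config$out_dir
  staging <- file.path(out_dir, ".staging")
  dir.create(staging, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  genome <- NULL
  if (!is.null(config$genome_fasta))
    genome <- read_fasta(config$genome_fasta)[[1L]]

  hits <- NULL
  if ("consensus" %in% stages) {
    run_stage("consensus", function() {
      motif <- consensus_motif(
        pattern = config$consensus_pattern %||% "GTGNAANCGNTTNCAC",
        fixed = config$consensus_fixed %||% c(3L, 5L, 9L, 15L),
        max_mismatches = config$consensus_max_mismatches %||% 2L)
      hits <<- scan_consensus(genome, motif)
      outputs <<- c(outputs, write_tsv(hits, file.path(staging, "consensus_hits.tsv")))
    })
  }

  if ("info" %in% stages) {
    run_stage("info", function() {
      ops <- read_operator_table(config$operators_tsv)
      left <- config$info_left %||% 20L
      right <- config$info_right %||% 21L
      sites <- aligned_sites(genome, ops, left, right,
                             symmetrize = isTRUE(config$info_symmetrize))
      freq <- freq_matrix(sites)
      corr <- small_sample_correction(freq$n)
      info <- information_summary(freq, corr)
      riw <- build_riw(freq, corr,
                       pseudocount = config$info_pseudocount %||% "none")
      outputs <<- c(outputs,
                    write_info_model(freq, corr,
                                     file.path(staging, "info_model.json"),
                                     left, right))
      outputs <<- c(outputs,
                    write_tsv(logo_table(freq, info, left_offset = left),
                              file.path(staging, "logo_table.tsv")))
      thr <- config$info_threshold %||% 9.4
      ri_sites <- scan_riw(genome, riw, thr)
      outputs <<- c(outputs,
                    write_tsv(ri_sites, file.path(staging, "sites_ri.tsv")))
    })
  }

  regions <- NULL
  if ("chip" %in% stages) {
    run_stage("chip", function() {
      probes <- read_probe_track(config$probes_tsv)
      probes <- filter_probes(probes, config$min_pixels %||% 100L)
      regions <<- call_regions(probes, config$chip_threshold,
                               mode = config$boundary_mode %||% "corrected")
      outputs <<- c(outputs,
                    write_region_table(regions, file.path(staging, "chip_regions.tsv")))
      fa <- file.path(staging, "chip_regions.fa")
      export_region_sequences(regions, genome, fa)
      outputs <<- c(outputs, fa)
    })
  }

  if ("expression" %in% stages) {
    run_stage("expression", function() {
      ann <- read_gene_annotation(config$annotation_tsv)
      wt <- gene_scores(read_probe_scores(config$wt_tsv), ann)
      mut <- gene_scores(read_probe_scores(config$mut_tsv), ann)
      calls <- regulation_calls(wt, mut,
                                cutoff = config$expression_cutoff %||% 3)
      roll <- rollup_transcripts(calls)
      outputs <<- c(outputs,
                    write_tsv(calls, file.path(staging, "regulation_calls.tsv")),
                    write_tsv(roll$transcripts,
                              file.path(staging, "transcript_summary.tsv")))
    })
  }

  if ("classify" %in% stages) {
    run_stage("classify", function() {
      ops <- if (!is.null(config$operators_tsv))
        read_operator_table(config$operators_tsv) else hits
      tss <- read_tss_table(config$tss_tsv)
      win <- config$classify_window %||% c(-200, 400)
      labeled <- classify_operators(ops, tss, window = win)
      outputs <<- c(outputs,
                    write_tsv(labeled, file.path(staging, "labeled_operators.tsv")))
    })
  }

  # promote staged outputs, then write the manifest
  final <- file.path(out_dir, basename(outputs))
  ok <- file.rename(outputs, final)
  if (!all(ok)) stop("pipeline: failed to promote staged outputs")
  unlink(staging, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("galregulon")),
    config = config[setdiff(names(config), "out_dir")],
    outputs = lapply(seq_along(final), function(i) {
      list(file = basename(final[i]),
           md5 = unname(tools::md5sum(final[i])))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# probe score tables for the expression stage use ln_score, not S
read_probe_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("seq_id", "U", "D", "ln_score"), names(df))
  if (length(miss) > 0L)
    stop("probe score table is missing columns: ", paste(miss, collapse = ", "))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
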