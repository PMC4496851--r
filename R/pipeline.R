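# End-to-end pipeline driver: fragmentation -> (projected) alignment ->
# graph creation -> clustering sweep -> evaluation summaries, with a
# reproducible run manifest.

#' Pipeline run configuration
#'
#' @param output_dir Directory for all outputs (created if missing).
#' @param fasta Optional FASTA path of a labelled sequence database
#'   (`organism|group|serial` ids). Ignored when `synthetic` is given.
#' @param hit_table Optional path to an externally produced 14-column hit
#'   table for the intact database (the real-BLAST path). When absent,
#'   hits come from the synthetic generator.
#' @param synthetic Optional [synthetic_config()]; when given, the
#'   database and hit table are simulated.
#' @param scheme_codes Character vector of fragmentation scheme codes;
#'   `"1"` means no fragmentation. Each code is run in the configured
#'   `label_mode` x `breakpoint_mode` variant.
#' @param label_mode,breakpoint_mode Passed to [fragmentation_scheme()].
#' @param metrics Metrics to export and cluster (default all four).
#' @param normalization `"raw"`, `"inter_organism"`, or `"both"` (default):
#'   which graph variants to produce.
#' @param inflations Inflation grid (default [inflation_grid()], 50 values).
#' @param evalue_cutoff E-value cutoff (default 1e-5).
#' @param seed Seed for fragmentation randomness.
#' @return List of class `run_config`.
#' @export
run_config <- function(output_dir,
                       fasta = NULL, hit_table = NULL, synthetic = NULL,
                       scheme_codes = "1",
                       label_mode = "ordered", breakpoint_mode = "even",
                       metrics = metric_names(),
                       normalization = c("both", "raw", "inter_organism"),
                       inflations = inflation_grid(),
                       evalue_cutoff = 1e-5, seed = 1L) {
  stopifnot(length(metrics) >= 1, all(metrics %in% metric_names()),
            length(inflations) >= 1)
  if (is.null(synthetic) && is.null(fasta)) {
    stopf("supply either a FASTA database or a synthetic_config")
  }
  structure(list(output_dir = output_dir, fasta = fasta,
                 hit_table = hit_table, synthetic = synthetic,
                 scheme_codes = as.character(scheme_codes),
                 label_mode = label_mode, breakpoint_mode = breakpoint_mode,
                 metrics = metrics, normalization = match.arg(normalization),
                 inflations = inflations, evalue_cutoff = evalue_cutoff,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Stages, per fragmentation scheme: 1) sequence fragmentation, 2) hit
#' generation (projection of intact-database best hits onto fragments, or
#' a user-supplied table), 3) graph creation (selected metrics, raw and/or
#' inter-organism normalized, exported as ABC + TSV), 4) Markov clustering
#' across the inflation grid, 5) evaluation summaries (sensitivity,
#' specificity, perfect-reconstruction counts, weight distributions). A
#' JSON manifest records the config hash, seeds and every file written.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage log lines.
#' @return The manifest, invisibly (list with `files`, `counts`, ...).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  note <- function(path) { files <<- c(files, path); path }
  log_line <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  mcfg <- metric_config(evalue_cutoff = config$evalue_cutoff)

  # --- input database + intact hit table -------------------------------
  if (!is.null(config$synthetic)) {
    bench <- generate_benchmark(config$synthetic)
    db <- bench$db
    reference <- bench$reference
    parent_hits <- bench$hits
  } else {
    db <- read_fasta_db(config$fasta)
    reference <- setNames(db$group, db$id)
    if (is.null(config$hit_table)) {
      stopf("a FASTA database needs an accompanying hit table")
    }
    parent_hits <- parse_blast_table(config$hit_table)
  }
  stats <- database_stats(db)
  parent_self <- extract_self_scores(parent_hits)
  parent_best <- best_hits(parent_hits)
  parent_best <- parent_best[parent_best$evalue <= config$evalue_cutoff, ,
                             drop = FALSE]
  log_line("input: %d sequences, %d groups, %d best hits",
           nrow(db), length(unique(reference)), nrow(parent_best))

  cfg_json <- file.path(config$output_dir, "run_config.json")
  jsonlite::write_json(config[setdiff(names(config), "synthetic")],
                       cfg_json, auto_unbox = TRUE, null = "null")
  note(cfg_json)

  counts <- list(sequences = nrow(db), groups = length(unique(reference)),
                 best_hits = nrow(parent_best), graphs = 0L, clusterings = 0L)

  norm_states <- switch(config$normalization,
                        both = c("raw", "inter_organism"),
                        raw = "raw",
                        inter_organism = "inter_organism")

  for (code in config$scheme_codes) {
    tag <- paste0("scheme", code)
    # --- stage 1: fragmentation ---------------------------------------
    if (identical(code, "1")) {
      frag <- NULL
      hits <- parent_hits
      ref <- reference
      node_info <- db
    } else {
      scheme <- fragmentation_scheme(code, config$label_mode,
                                     config$breakpoint_mode,
                                     seed = config$seed)
      fr <- fragment_database(db, scheme)
      frag <- fr$fragments
      node_info <- fr$db
      note(write_fragment_map(frag, file.path(config$output_dir,
                                              paste0(tag, "_fragments.tsv"))))
      if (!is.null(db$seq)) {
        note(write_fasta_db(fr$db, file.path(config$output_dir,
                                             paste0(tag, ".fasta"))))
      }
      # --- stage 2: projected alignment -------------------------------
      hits <- project_hits(parent_best, parent_self, frag, stats,
                           cutoff = config$evalue_cutoff)
      ref <- fragment_reference(reference, frag)
      log_line("%s: %d fragments, %d projected hits", tag, nrow(frag),
               nrow(hits))
    }
    self_scores <- extract_self_scores(hits)
    best <- best_hits(hits)
    best <- best[best$evalue <= config$evalue_cutoff, , drop = FALSE]

    # --- stage 3: graph creation --------------------------------------
    raw_graph <- build_graph(best, self_scores, stats, node_info = node_info,
                             config = mcfg)
    graphs <- list()
    for (ns in norm_states) {
      graphs[[ns]] <- if (ns == "raw") raw_graph else
        normalize_inter_organism(raw_graph, metrics = config$metrics)
    }
    log_line("%s: graph %d nodes / %d edges", tag, nrow(raw_graph$nodes),
             nrow(raw_graph$edges))

    comp <- connected_components(raw_graph)
    eval_rows <- list()
    for (ns in names(graphs)) {
      g <- graphs[[ns]]
      note(write_graph_tsv(g, file.path(config$output_dir,
                                        sprintf("%s_%s_edges.tsv", tag, ns))))
      for (m in config$metrics) {
        counts$graphs <- counts$graphs + 1L
        note(write_abc(g, m, file.path(config$output_dir,
                                       sprintf("%s_%s_%s.abc", tag, ns, m))))
        # --- stage 4: clustering sweep --------------------------------
        sweep <- inflation_sweep(g, m, inflations = config$inflations)
        counts$clusterings <- counts$clusterings + length(sweep)
        long <- do.call(rbind, lapply(sweep, clusters_long))
        note(write_eval_tsv(long, file.path(config$output_dir,
                                            sprintf("%s_%s_%s_clusters.tsv",
                                                    tag, ns, m))))
        # --- stage 5: evaluation --------------------------------------
        for (I in names(sweep)) {
          cl <- sweep[[I]]
          sens <- sensitivity_counts(cl, ref)
          spec <- specificity_counts(cl, ref)
          eval_rows[[length(eval_rows) + 1L]] <- data.frame(
            scheme = code, normalization = ns, metric = m,
            inflation = as.numeric(I),
            n_clusters = length(cl$clusters),
            perfect = perfect_cluster_count(cl, ref),
            split_groups = sum(sens$n_clusters > 1L),
            lost_groups = sum(!sens$surviving),
            mixed_clusters = sum(spec$n_groups > 1L),
            stringsAsFactors = FALSE
          )
        }
      }
      dist <- edge_weight_distributions(g, ref)
      note(write_eval_tsv(dist$summary,
                          file.path(config$output_dir,
                                    sprintf("%s_%s_distributions.tsv", tag, ns))))
    }
    evaluation <- do.call(rbind, eval_rows)
    note(write_eval_tsv(evaluation,
                        file.path(config$output_dir,
                                  sprintf("%s_evaluation.tsv", tag))))
    comp_eval <- data.frame(
      scheme = code,
      n_components = length(comp$clusters),
      perfect_components = perfect_cluster_count(comp, ref),
      stringsAsFactors = FALSE
    )
    note(write_eval_tsv(comp_eval,
                        file.path(config$output_dir,
                                  sprintf("%s_components.tsv", tag))))
    log_line("%s: %d clusterings evaluated", tag, counts$clusterings)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("bgmcl")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_json)),
    counts = counts,
    files = files
  )
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  manifest$files <- c(manifest$files, manifest_path)
  invisible(manifest)
}
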