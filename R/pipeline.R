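# End-to-end pipeline orchestration: filters -> event catalog -> PSI ->
# differential splicing -> differential expression -> homoeolog pairing /
# bias / transitions -> integration and enrichment. Reports are plain TSV
# plus a JSON manifest (input hashes, thresholds, seed, versions); reruns
# on identical inputs are byte-identical.

#' Pipeline configuration
#'
#' @param gtf,abundance,counts,event_counts,support,hits,term_map Paths to
#'   the input files (GTF annotation; transcript TPM TSV; gene count TSV;
#'   event read-count TSV; transcript support TSV; BLAST tabular hit
#'   table; gene-to-term TSV). `support`, `hits` and `term_map` may be
#'   `NULL` to skip the corresponding stages.
#' @param outdir Output directory for report tables.
#' @param contrasts List of `c(treatment, control)` label pairs; defaults
#'   to CG/BG vs their controls.
#' @param min_reads Support-filter threshold (transcripts and events).
#' @param dpsi_min,alpha,psi_low,psi_high Differential-splicing thresholds
#'   (see [dse_thresholds()]).
#' @param lfc_min,q_cut DEG thresholds.
#' @param min_identity RBH identity threshold (percent).
#' @param log2_cut,floor,pseudocount Bias-classification parameters.
#' @param fdr_cut Enrichment significance threshold.
#' @param seed Integer seed recorded in the manifest.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(gtf, abundance, counts, event_counts,
                            support = NULL, hits = NULL, term_map = NULL,
                            outdir = "splicebias_out",
                            contrasts = list(c("CG", "AG"), c("CG", "BG"),
                                             c("BG", "AG")),
                            min_reads = 3, dpsi_min = 0.20, alpha = 0.05,
                            psi_low = 0.05, psi_high = 0.95, lfc_min = 2,
                            q_cut = 0.05, min_identity = 90, log2_cut = 1,
                            floor = 1, pseudocount = 1, fdr_cut = 0.05,
                            seed = 1L) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  for (f in c("gtf", "abundance", "counts", "event_counts", "support",
              "hits", "term_map")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p)) {
      stop("input file for '", f, "' not found: ", p, call. = FALSE)
    }
  }
  stopifnot(cfg$dpsi_min > 0, cfg$alpha > 0, cfg$alpha < 1,
            cfg$psi_low > 0, cfg$psi_low < cfg$psi_high, cfg$psi_high < 1,
            cfg$lfc_min >= 0, cfg$min_reads >= 0)
  cfg
}

write_report <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order and writes the report tables
#' and a `manifest.json` under `config$outdir`.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage record-count messages.
#' @return List of in-memory results (catalog, PSI matrix, DSE/DEG tables,
#'   bias calls, transitions, integration summaries) with the report paths
#'   in `$paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[splicebias] ", ...)
  paths <- character()

  say("reading annotation: ", config$gtf)
  genes <- read_gtf_models(config$gtf)
  abundance <- read_matrix_tsv(config$abundance)
  counts <- read_matrix_tsv(config$counts)
  event_counts <- read_event_counts_tsv(config$event_counts)
  support <- if (!is.null(config$support)) {
    read_matrix_tsv(config$support)
  }

  # stage: support filters
  if (!is.null(support)) {
    kept_tx <- filter_transcripts_by_support(support, config$min_reads)
    say("transcript filter: ", length(kept_tx), "/", nrow(support),
        " retained")
  } else {
    kept_tx <- rownames(abundance)
  }

  # stage: event catalog
  catalog <- enumerate_events(genes)
  catalog <- prune_catalog(catalog, kept_tx)
  kept_ev <- filter_events_by_support(event_counts, config$min_reads)
  catalog <- catalog[catalog$event_id %in% kept_ev, , drop = FALSE]
  say("event catalog: ", nrow(catalog), " events after filters")
  paths["catalog"] <- write_report(catalog, config$outdir, "event_catalog")

  # stage: PSI
  psi <- compute_psi(catalog, abundance)
  groups <- sample_groups(colnames(psi))
  mask <- active_event_mask(psi)
  tally <- tally_active_events(psi)
  freq <- summarize_event_frequencies(catalog, mask)
  paths["psi"] <- write_report(
    data.frame(event_id = rownames(psi), psi, check.names = FALSE),
    config$outdir, "psi_matrix")
  paths["event_frequencies"] <- write_report(freq, config$outdir,
                                             "event_type_frequencies")
  paths["psi_correlation"] <- write_report(
    as.data.frame(psi_correlation(psi)), config$outdir, "psi_correlation")

  # stage: differential splicing and expression per contrast
  thresholds <- dse_thresholds(config$dpsi_min, config$alpha,
                               config$psi_low, config$psi_high)
  sf <- size_factors(counts)
  dse_all <- list()
  deg_all <- list()
  for (ct in config$contrasts) {
    dse <- test_dse(psi, event_counts, ct[1], ct[2],
                    thresholds = thresholds)
    idx <- match(dse$event_id, catalog$event_id)
    dse$etype <- catalog$etype[idx]
    dse$gene_id <- catalog$gene_id[idx]
    deg <- test_de(counts, ct[1], ct[2], lfc_min = config$lfc_min,
                   alpha = config$q_cut, sf = sf)
    say("contrast ", ct[1], "vs", ct[2], ": ",
        sum(dse$category != "ns"), " significant events, ",
        sum(deg$status != "ns"), " DEGs")
    dse_all[[paste0(ct[1], "vs", ct[2])]] <- dse
    deg_all[[paste0(ct[1], "vs", ct[2])]] <- deg
  }
  dse_tab <- do.call(rbind, c(dse_all, list(make.row.names = FALSE)))
  deg_tab <- do.call(rbind, c(deg_all, list(make.row.names = FALSE)))
  paths["dse"] <- write_report(dse_tab, config$outdir, "differential_splicing")
  paths["deg"] <- write_report(deg_tab, config$outdir,
                               "differential_expression")
  comp <- do.call(rbind, lapply(names(dse_all), function(nm) {
    s <- summarize_dse_composition(dse_all[[nm]])
    if (nrow(s) > 0) data.frame(contrast = nm, s, stringsAsFactors = FALSE)
  }))
  paths["dse_composition"] <- write_report(
    comp %||% data.frame(), config$outdir, "dse_composition")

  # stage: homoeolog pairs, bias, transitions
  bias_block <- NULL
  if (!is.null(config$hits)) {
    hits <- read_blast_tab(config$hits)
    subg <- stats::setNames(
      subgenome_of(vapply(genes, `[[`, "", "chrom")),
      vapply(genes, `[[`, "", "gene_id"))
    pairs <- reciprocal_best_hits(hits, config$min_identity, subg)
    say("homoeolog pairs: ", nrow(pairs))
    norm <- sweep(counts, 2, sf, "/")
    expr_means <- vapply(unique(groups), function(g) {
      rowMeans(norm[, groups == g, drop = FALSE])
    }, numeric(nrow(norm)))
    calls <- classify_bias(expr_means, pairs, config$log2_cut,
                           config$floor, config$pseudocount)
    transitions <- list()
    for (ct in config$contrasts) {
      deg_ids <- deg_all[[paste0(ct[1], "vs", ct[2])]]
      deg_ids <- deg_ids$gene_id[deg_ids$status != "ns"]
      sub_pairs <- pairs$pair_id[pairs$gene_a %in% deg_ids |
                                 pairs$gene_b %in% deg_ids]
      tt <- transition_table(calls, ct[2], ct[1], subset = sub_pairs)
      if (nrow(tt$table) > 0) {
        transitions[[length(transitions) + 1L]] <- data.frame(
          contrast = paste0(ct[1], "vs", ct[2]), tt$table,
          total = tt$total, stringsAsFactors = FALSE)
      }
    }
    transitions <- do.call(rbind, transitions)
    paths["pairs"] <- write_report(pairs, config$outdir, "homoeolog_pairs")
    paths["bias"] <- write_report(calls, config$outdir, "bias_calls")
    paths["transitions"] <- write_report(
      transitions %||% data.frame(), config$outdir, "bias_transitions")
    chisq_tab <- do.call(rbind, lapply(names(deg_all), function(nm) {
      ds <- deg_summary_by_subgenome(deg_all[[nm]], counts, subg, sf = sf)
      cs <- tryCatch(
        chisq_2x2(ds$deg[1], ds$expressed[1], ds$deg[2], ds$expressed[2]),
        error = function(e) list(chi2 = NA_real_, dof = NA, p = NA_real_))
      data.frame(contrast = nm, deg_a = ds$deg[1],
                 expressed_a = ds$expressed[1], deg_b = ds$deg[2],
                 expressed_b = ds$expressed[2], chi2 = cs$chi2, p = cs$p,
                 stringsAsFactors = FALSE)
    }))
    paths["subgenome_chisq"] <- write_report(chisq_tab, config$outdir,
                                             "subgenome_deg_chisq")
    bias_block <- list(pairs = pairs, calls = calls,
                       transitions = transitions, chisq = chisq_tab)
  }

  # stage: integration
  first <- paste0(config$contrasts[[1]][1], "vs", config$contrasts[[1]][2])
  corr <- correlate_dpsi_expression(dse_all[[first]], deg_all[[first]])
  paths["dpsi_expression_correlation"] <- write_report(
    corr, config$outdir, "dpsi_expression_correlation")
  deg_sets <- lapply(deg_all, function(d) d$gene_id[d$status != "ns"])
  dag_sets <- lapply(dse_all, function(d) {
    unique(d$gene_id[d$category != "ns"])
  })
  sets <- c(stats::setNames(deg_sets[seq_len(min(2, length(deg_sets)))],
                            paste0("DEG_", names(deg_sets)[
                              seq_len(min(2, length(deg_sets)))])),
            stats::setNames(dag_sets[seq_len(min(2, length(dag_sets)))],
                            paste0("DAG_", names(dag_sets)[
                              seq_len(min(2, length(dag_sets)))])))
  overlaps <- overlap_sets(sets)
  paths["overlaps"] <- write_report(overlaps$regions, config$outdir,
                                    "deg_dag_overlaps")
  enrich <- NULL
  if (!is.null(config$term_map)) {
    term_map <- read_term_map(config$term_map)
    background <- rownames(counts)
    glist <- intersect(deg_sets[[first]], background)
    if (length(glist) > 0) {
      enrich <- hypergeom_enrich(glist, background, term_map,
                                 fdr_cut = config$fdr_cut)
      paths["enrichment"] <- write_report(enrich, config$outdir,
                                          "term_enrichment")
    }
  }

  # manifest: input hashes, thresholds, seed, versions (no timestamps so
  # reruns are byte-identical)
  inputs <- Filter(Negate(is.null),
                   config[c("gtf", "abundance", "counts", "event_counts",
                            "support", "hits", "term_map")])
  manifest <- list(
    package = "splicebias",
    version = as.character(utils::packageVersion("splicebias")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    thresholds = config[c("min_reads", "dpsi_min", "alpha", "psi_low",
                          "psi_high", "lfc_min", "q_cut", "min_identity",
                          "log2_cut", "floor", "pseudocount", "fdr_cut")],
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }))
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths["manifest"] <- manifest_path

  list(catalog = catalog, psi = psi, mask = mask, tally = tally,
       event_frequencies = freq, dse = dse_all, deg = deg_all,
       bias = bias_block, dpsi_expression = corr, overlaps = overlaps,
       enrichment = enrich, paths = paths)
}
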