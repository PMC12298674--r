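# Configuration for the synthetic allotetraploid generator.

#' Synthetic-data generator configuration
#'
#' Parameterizes a miniature two-subgenome (A/B) transcriptome with three
#' condition groups and planted splicing, expression and subgenome-bias
#' effects. Defaults define the package's standard study conditions: three
#' groups (healthy AG, lesion-adjacent BG, lesion-core CG) x three
#' replicates, planted differential-splicing events at |delta PSI| 0.4 with
#' event coverage around 60 reads, planted DEGs at |log2FC| 3, and bias
#' transitions dominated by gains of B-subgenome bias.
#'
#' @param n_genes_per_subgenome Genes in subgenome B; subgenome A receives
#'   `a_surplus` more, mirroring the A > B event-count asymmetry of
#'   allotetraploid annotations.
#' @param n_chromosomes_per_subgenome Chromosomes per subgenome
#'   (`chr01A..`, `chr01B..`).
#' @param groups Ordered condition labels; the last group is the lesion
#'   core whose planted effects differ from the first two.
#' @param replicates_per_group Replicates per condition.
#' @param planted_event_counts Named list `gain`/`lost`/`das`/`stable`,
#'   each a named integer vector over event types `IR`, `ES`, `A5`, `A3`.
#' @param planted_deg_count Genes planted as DEGs (last group shifted).
#' @param planted_bias_shift_counts Named counts of homoeolog-pair bias
#'   transitions `"<from>><to>"` over classes `balanced`, `A-bias`,
#'   `B-bias`; `from` applies to the first two groups, `to` to the last.
#' @param nb_dispersion Shared negative-binomial dispersion of gene counts.
#' @param library_size Expected total reads per sample.
#' @param deg_log2fc Planted |log2 fold change| of DEGs (>= 2).
#' @param das_delta_psi Planted |delta PSI| of DAS events, in (0.2, 0.9].
#' @param event_depth Expected inclusion+exclusion reads per event per
#'   sample.
#' @param a_surplus Fractional surplus of subgenome-A genes, default 0.1.
#' @param n_terms Random annotation terms for the gene-to-term map (one
#'   further term is planted to be enriched among DEGs).
#' @param noise_free Replace all random draws by their deterministic means
#'   (exact classifier round-trips).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return Validated config list of class `sim_config`.
#' @export
sim_config <- function(n_genes_per_subgenome = 120,
                       n_chromosomes_per_subgenome = 3,
                       groups = c("AG", "BG", "CG"),
                       replicates_per_group = 3,
                       planted_event_counts = list(
                         gain = c(IR = 5, ES = 5, A5 = 5, A3 = 5),
                         lost = c(IR = 5, ES = 5, A5 = 5, A3 = 5),
                         das = c(IR = 8, ES = 8, A5 = 8, A3 = 8),
                         stable = c(IR = 5, ES = 5, A5 = 5, A3 = 5)),
                       planted_deg_count = 40,
                       planted_bias_shift_counts = c(
                         "balanced>B-bias" = 8, "balanced>A-bias" = 5,
                         "A-bias>B-bias" = 4, "A-bias>A-bias" = 3,
                         "B-bias>B-bias" = 3),
                       nb_dispersion = 0.05,
                       library_size = 5e5,
                       deg_log2fc = 3,
                       das_delta_psi = 0.4,
                       event_depth = 60,
                       a_surplus = 0.1,
                       n_terms = 15,
                       noise_free = FALSE,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  err <- function(field, why) {
    stop("invalid sim_config: ", field, " ", why, call. = FALSE)
  }
  if (cfg$n_genes_per_subgenome < 1) err("n_genes_per_subgenome", "< 1")
  if (cfg$n_chromosomes_per_subgenome < 1) {
    err("n_chromosomes_per_subgenome", "< 1")
  }
  if (length(cfg$groups) < 2) err("groups", "needs >= 2 labels")
  if (cfg$replicates_per_group < 1) err("replicates_per_group", "< 1")
  if (cfg$nb_dispersion <= 0) err("nb_dispersion", "must be > 0")
  if (cfg$library_size < 1) err("library_size", "< 1")
  if (cfg$deg_log2fc < 2) err("deg_log2fc", "must be >= 2")
  if (cfg$das_delta_psi <= 0.2 || cfg$das_delta_psi > 0.9) {
    err("das_delta_psi", "must lie in (0.2, 0.9]")
  }
  ev <- cfg$planted_event_counts
  if (!all(names(ev) %in% c("gain", "lost", "das", "stable"))) {
    err("planted_event_counts", "has unknown category")
  }
  for (cat in names(ev)) {
    if (!all(names(ev[[cat]]) %in% EVENT_TYPES) || any(ev[[cat]] < 0)) {
      err("planted_event_counts", paste0("category '", cat, "' malformed"))
    }
  }
  if (cfg$planted_deg_count < 0) err("planted_deg_count", "< 0")
  bias <- cfg$planted_bias_shift_counts
  if (length(bias) > 0) {
    parts <- strsplit(names(bias), ">", fixed = TRUE)
    ok <- vapply(parts, function(p) {
      length(p) == 2 && all(p %in% c("balanced", "A-bias", "B-bias"))
    }, TRUE)
    if (!all(ok) || any(bias < 0)) {
      err("planted_bias_shift_counts", "has malformed transition label")
    }
  }
  # capacity: bias transitions consume homoeolog pairs; event and DEG genes
  # come from the remaining gene pool
  n_b <- cfg$n_genes_per_subgenome
  n_a <- round(n_b * (1 + cfg$a_surplus))
  n_bias <- sum(cfg$planted_bias_shift_counts)
  if (n_bias > n_b) {
    err("planted_bias_shift_counts",
        sprintf("requests %d pairs but only %d exist", n_bias, n_b))
  }
  n_free <- (n_b - n_bias) * 2 + (n_a - n_b)
  n_event <- sum(unlist(cfg$planted_event_counts))
  if (n_event + cfg$planted_deg_count > n_free) {
    err("planted_event_counts/planted_deg_count",
        sprintf("request %d genes but only %d are free",
                n_event + cfg$planted_deg_count, n_free))
  }
  invisible(cfg)
}
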