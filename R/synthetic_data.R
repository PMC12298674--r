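# Synthetic allotetraploid transcriptome generator.
#
# Emits a miniature two-subgenome annotation with homoeolog pairs, planted
# local splice events of the four types, grouped NB count matrices with
# planted DEGs and bias transitions, event read counts consistent in
# expectation with the abundance-implied PSI, and a truth ledger (SimTruth)
# for recovery tests.

# -- exon-chain templates ---------------------------------------------------

# Each template returns inclusion/exclusion exon chains (0-based, relative)
# and the event anchor. `alt_left`/`alt_right` are boundary-variant
# templates; which of A5/A3 they realize depends on strand.
event_templates <- list(
  ES = function() list(
    inc = rbind(c(0, 100), c(200, 300), c(400, 500)),
    exc = rbind(c(0, 100), c(400, 500)),
    anchor = c(100, 200, 300, 400)),
  IR = function() list(
    inc = rbind(c(0, 300)),
    exc = rbind(c(0, 100), c(200, 300)),
    anchor = c(0, 100, 200, 300)),
  alt_left = function() list(   # A5 on "+", A3 on "-"
    inc = rbind(c(0, 150), c(200, 300)),
    exc = rbind(c(0, 100), c(200, 300)),
    anchor = c(100, 150, 200, 200)),
  alt_right = function() list(  # A3 on "+", A5 on "-"
    inc = rbind(c(0, 100), c(150, 300)),
    exc = rbind(c(0, 100), c(200, 300)),
    anchor = c(100, 100, 150, 200)))

event_gene_structure <- function(etype, strand) {
  tpl_name <- switch(etype,
    ES = "ES", IR = "IR",
    A5 = if (strand == "+") "alt_left" else "alt_right",
    A3 = if (strand == "+") "alt_right" else "alt_left")
  event_templates[[tpl_name]]()
}

# Random single-isoform exon chain for a background gene.
background_structure <- function() {
  n_ex <- sample(1:3, 1)
  widths <- sample(100:300, n_ex, replace = TRUE)
  gaps <- if (n_ex > 1) sample(80:150, n_ex - 1, replace = TRUE) else integer()
  starts <- cumsum(c(0, widths[-n_ex] + gaps))
  cbind(starts, starts + widths)
}

# -- annotation -------------------------------------------------------------

#' Generate a synthetic allotetraploid annotation with planted events
#'
#' Places genes on chromosomes `chr01A..` / `chr01B..`, establishes 1:1
#' homoeolog pairs across subgenomes (with a configurable subgenome-A gene
#' surplus), gives every planted-event gene two transcripts whose exon
#' chains realize exactly the planted event type, assigns bias transitions
#' to pairs and DEG status to genes, and builds the protein-similarity hit
#' table and gene-to-term map. Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return List with `genes` (named list of [gene_model()]s), `pairs`
#'   (homoeolog pair truth), `hits` (BLAST-tabular `data.frame`),
#'   `term_map`, and `truth` (SimTruth skeleton: `events`, `genes`,
#'   `pairs` ledgers).
#' @export
generate_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_b <- config$n_genes_per_subgenome
  n_a <- round(n_b * (1 + config$a_surplus))
  n_chr <- config$n_chromosomes_per_subgenome

  gene_table <- do.call(rbind, lapply(list(c("A", n_a), c("B", n_b)),
    function(sg) {
      n <- as.integer(sg[2])
      idx <- seq_len(n)
      data.frame(
        gene_id = sprintf("Pg%s%04d", sg[1], idx),
        chrom = sprintf("chr%02d%s", ((idx - 1) %% n_chr) + 1, sg[1]),
        offset = ((idx - 1) %/% n_chr) * 20000 + 1000,
        strand = sample(c("+", "-"), n, replace = TRUE),
        subgenome = sg[1], stringsAsFactors = FALSE)
    }))

  pairs <- data.frame(
    pair_id = sprintf("HP%04d", seq_len(n_b)),
    gene_a = sprintf("PgA%04d", seq_len(n_b)),
    gene_b = sprintf("PgB%04d", seq_len(n_b)),
    stringsAsFactors = FALSE)

  # allocate pairs to bias transitions, then genes to events and DEGs
  bias_counts <- config$planted_bias_shift_counts
  pair_order <- sample(n_b)
  n_bias <- sum(bias_counts)
  bias_pairs <- pair_order[seq_len(n_bias)]
  pair_transition <- rep(names(bias_counts), bias_counts)
  free_pairs <- if (n_bias > 0) pair_order[-seq_len(n_bias)] else pair_order
  free_genes <- c(pairs$gene_a[free_pairs], pairs$gene_b[free_pairs],
                  if (n_a > n_b) sprintf("PgA%04d", (n_b + 1):n_a))
  free_genes <- sample(free_genes)

  ev_cfg <- config$planted_event_counts
  ev_cat <- rep(names(ev_cfg), vapply(ev_cfg, sum, 0))
  ev_type <- unlist(lapply(ev_cfg, function(v) rep(names(v), v)),
                    use.names = FALSE)
  n_event <- length(ev_cat)
  event_genes <- free_genes[seq_len(n_event)]
  deg_genes <- if (config$planted_deg_count > 0) {
    free_genes[n_event + seq_len(config$planted_deg_count)]
  } else character()

  # planted group-mean PSI per event
  d <- config$das_delta_psi
  flip <- sample(c(TRUE, FALSE), n_event, replace = TRUE)
  psi_of <- function(cat, fl) {
    ctrl_trt <- switch(cat,
      gain = c(if (fl) 0.98 else 0.02, 0.5),
      lost = c(0.5, if (fl) 0.98 else 0.02),
      das = if (fl) c((1 - d) / 2, (1 + d) / 2) else
                    c((1 + d) / 2, (1 - d) / 2),
      stable = c(0.5, 0.5))
    ctrl_trt
  }
  psi_planted <- t(vapply(seq_len(n_event),
                          function(i) psi_of(ev_cat[i], flip[i]),
                          numeric(2)))

  # build gene models
  genes <- vector("list", nrow(gene_table))
  names(genes) <- gene_table$gene_id
  truth_event_rows <- list()
  for (r in seq_len(nrow(gene_table))) {
    gid <- gene_table$gene_id[r]
    chrom <- gene_table$chrom[r]
    strand <- gene_table$strand[r]
    off <- gene_table$offset[r]
    ei <- match(gid, event_genes)
    if (!is.na(ei)) {
      tpl <- event_gene_structure(ev_type[ei], strand)
      inc_tx <- transcript_model(paste0(gid, ".t1"), gid, chrom, strand,
                                 tpl$inc + off)
      exc_tx <- transcript_model(paste0(gid, ".t2"), gid, chrom, strand,
                                 tpl$exc + off)
      genes[[gid]] <- gene_model(gid, chrom, strand, list(inc_tx, exc_tx))
      eid <- event_id_string(gid, ev_type[ei], chrom, tpl$anchor + off,
                             strand)
      truth_event_rows[[ei]] <- data.frame(
        event_id = eid, gene_id = gid, etype = ev_type[ei],
        category = ev_cat[ei],
        inclusion_tx = paste0(gid, ".t1"),
        exclusion_tx = paste0(gid, ".t2"),
        psi_control = psi_planted[ei, 1], psi_treatment = psi_planted[ei, 2],
        delta_psi = psi_planted[ei, 2] - psi_planted[ei, 1],
        stringsAsFactors = FALSE)
    } else {
      tx <- transcript_model(paste0(gid, ".t1"), gid, chrom, strand,
                             background_structure() + off)
      genes[[gid]] <- gene_model(gid, chrom, strand, list(tx))
    }
  }
  truth_events <- do.call(rbind, truth_event_rows) %||%
    data.frame(event_id = character(), gene_id = character(),
               etype = character(), category = character(),
               stringsAsFactors = FALSE)

  # gene ledger: planted DEG sign and magnitude (last group shifted)
  deg_sign <- sample(c(1, -1), length(deg_genes), replace = TRUE)
  truth_genes <- data.frame(
    gene_id = gene_table$gene_id,
    subgenome = gene_table$subgenome,
    is_deg = gene_table$gene_id %in% deg_genes,
    planted_log2fc = 0, stringsAsFactors = FALSE)
  truth_genes$planted_log2fc[match(deg_genes, truth_genes$gene_id)] <-
    deg_sign * config$deg_log2fc

  # pair ledger: class per group from the transition label
  from_to <- strsplit(pair_transition, ">", fixed = TRUE)
  n_grp <- length(config$groups)
  class_mat <- matrix("balanced", nrow = n_b, ncol = n_grp,
                      dimnames = list(pairs$pair_id, config$groups))
  for (i in seq_along(bias_pairs)) {
    class_mat[bias_pairs[i], ] <- c(rep(from_to[[i]][1], n_grp - 1),
                                    from_to[[i]][2])
  }
  truth_pairs <- data.frame(pairs, identity_pct = NA_real_,
                            class_mat, check.names = FALSE,
                            stringsAsFactors = FALSE)
  truth_pairs$transition <- paste(class_mat[, 1], class_mat[, n_grp],
                                  sep = ">")

  # similarity hit table: reciprocal rows for true pairs, plus decoys
  ident <- if (config$noise_free) rep(95, n_b) else
    round(stats::runif(n_b, 92, 99.5), 1)
  truth_pairs$identity_pct <- ident
  hit_row <- function(q, s, pid, score) {
    len <- 400L
    data.frame(qseqid = q, sseqid = s, pident = pid, length = len,
               mismatch = as.integer(round(len * (100 - pid) / 100)),
               gapopen = 0L, qstart = 1L, qend = len, sstart = 1L,
               send = len, evalue = 1e-50, bitscore = score,
               stringsAsFactors = FALSE)
  }
  score <- if (config$noise_free) rep(600, n_b) else
    round(stats::runif(n_b, 500, 900))
  hits <- rbind(
    do.call(rbind, lapply(seq_len(n_b), function(i) {
      hit_row(pairs$gene_a[i], pairs$gene_b[i], ident[i], score[i])
    })),
    do.call(rbind, lapply(seq_len(n_b), function(i) {
      hit_row(pairs$gene_b[i], pairs$gene_a[i], ident[i], score[i])
    })))
  n_decoy <- max(1L, n_b %/% 5L)
  decoy_q <- sample(pairs$gene_a, n_decoy)
  decoy_s <- sample(pairs$gene_b, n_decoy)
  decoys <- do.call(rbind, lapply(seq_len(n_decoy), function(i) {
    hit_row(decoy_q[i], decoy_s[i],
            round(stats::runif(1, 60, 85), 1),
            round(stats::runif(1, 100, 300)))
  }))
  decoys <- decoys[decoys$qseqid != decoys$sseqid, , drop = FALSE]
  # unpaired surplus A genes: one-directional (non-reciprocal) hits
  if (n_a > n_b) {
    surplus <- sprintf("PgA%04d", (n_b + 1):n_a)
    hits <- rbind(hits, do.call(rbind, lapply(surplus, function(g) {
      hit_row(g, sample(pairs$gene_b, 1), round(stats::runif(1, 91, 97), 1),
              round(stats::runif(1, 350, 450)))
    })))
  }
  hits <- rbind(hits, decoys)

  # gene-to-term map; the last term is planted enriched among DEGs
  term_rows <- list()
  for (t in seq_len(config$n_terms)) {
    lo <- min(5L, nrow(gene_table))
    hi <- min(30L, nrow(gene_table))
    members <- sample(gene_table$gene_id,
                      seq(lo, hi)[sample.int(hi - lo + 1, 1)])
    term_rows[[t]] <- data.frame(gene_id = members,
                                 term_id = sprintf("T%03d", t),
                                 stringsAsFactors = FALSE)
  }
  if (length(deg_genes) >= 3) {
    planted_members <- c(deg_genes[seq_len(ceiling(length(deg_genes) * 0.6))],
                         sample(setdiff(gene_table$gene_id, deg_genes), 3))
    term_rows[[length(term_rows) + 1L]] <- data.frame(
      gene_id = planted_members, term_id = "T_PLANTED",
      stringsAsFactors = FALSE)
  }
  term_map <- do.call(rbind, term_rows)

  list(genes = genes, pairs = truth_pairs, hits = hits,
       term_map = term_map,
       truth = list(events = truth_events, genes = truth_genes,
                    pairs = truth_pairs))
}

# -- expression -------------------------------------------------------------

#' Generate grouped expression, count and event-read-count matrices
#'
#' Draws per-sample gene counts from a negative binomial around group means
#' that realize the planted DEG and bias effects, realizes per-event PSI by
#' binomial draws of inclusion reads at the planted event depth, and splits
#' gene abundance over isoforms so that abundance-implied PSI matches the
#' realized read-count PSI. In noise-free mode all draws are replaced by
#' their means.
#'
#' @param annotation Result of [generate_annotation()].
#' @param config The same [sim_config()].
#' @return List with `abundance` (transcript TPM matrix), `counts` (gene
#'   count matrix), `event_counts` (list of `inclusion`/`exclusion`
#'   matrices), `support` (transcript read-support matrix), `samples`,
#'   and the completed `truth` ledger.
#' @export
generate_expression <- function(annotation, config) {
  set.seed(config$seed + 1000L)
  truth <- annotation$truth
  gene_ids <- truth$genes$gene_id
  n_genes <- length(gene_ids)
  groups <- config$groups
  reps <- config$replicates_per_group
  samples <- as.vector(vapply(groups, function(g) {
    paste0(g, "_rep", seq_len(reps))
  }, character(reps)))
  sample_grp <- sample_groups(samples)
  n_grp <- length(groups)
  last <- groups[n_grp]

  # group means: lognormal baseline, bias-pair splitting, DEG shifts
  base <- stats::rlnorm(n_genes, log(300), 1)
  names(base) <- gene_ids
  mu <- matrix(rep(base, n_grp), ncol = n_grp,
               dimnames = list(gene_ids, groups))
  split_of <- c("balanced" = 0.5, "A-bias" = 0.8, "B-bias" = 0.2)
  tp <- truth$pairs
  for (i in seq_len(nrow(tp))) {
    tot <- base[tp$gene_a[i]] + base[tp$gene_b[i]]
    for (g in groups) {
      fr <- split_of[[tp[[g]][i]]]
      mu[tp$gene_a[i], g] <- tot * fr
      mu[tp$gene_b[i], g] <- tot * (1 - fr)
    }
  }
  deg <- truth$genes[truth$genes$is_deg, , drop = FALSE]
  mu[deg$gene_id, last] <- mu[deg$gene_id, last] * 2^deg$planted_log2fc

  # per-sample expected counts scaled to the library size
  mu_s <- mu[, sample_grp, drop = FALSE]
  colnames(mu_s) <- samples
  mu_s <- sweep(mu_s, 2, colSums(mu_s), "/") * config$library_size

  # refresh the pair-ledger classes from the realized group means: DEG
  # planting can move an unplanted (balanced) pair into a biased class in
  # the shifted group, and the ledger must stay truthful to the emitted
  # means (classes computed with the default classifier parameters)
  grp_mu <- vapply(groups, function(g) {
    rowMeans(mu_s[, sample_grp == g, drop = FALSE])
  }, numeric(n_genes))
  class_of <- function(ma, mb) {
    lr <- log2((ma + 1) / (mb + 1))
    ifelse(ma < 1 & mb < 1, "low-expression",
    ifelse(lr >= 1, "A-bias", ifelse(lr <= -1, "B-bias", "balanced")))
  }
  for (g in groups) {
    truth$pairs[[g]] <- class_of(grp_mu[truth$pairs$gene_a, g],
                                 grp_mu[truth$pairs$gene_b, g])
  }
  truth$pairs$transition <- paste(truth$pairs[[groups[1]]],
                                  truth$pairs[[last]], sep = ">")
  counts <- if (config$noise_free) round(mu_s) else {
    matrix(stats::rnbinom(length(mu_s), mu = mu_s,
                          size = 1 / config$nb_dispersion),
           nrow = n_genes, dimnames = dimnames(mu_s))
  }
  tpm <- sweep(counts, 2, pmax(colSums(counts), 1), "/") * 1e6

  # event read counts and realized PSI
  te <- truth$events
  n_ev <- nrow(te)
  inc_mat <- exc_mat <- matrix(0L, nrow = n_ev, ncol = length(samples),
                               dimnames = list(te$event_id, samples))
  psi_real <- matrix(NA_real_, nrow = n_ev, ncol = length(samples),
                     dimnames = list(te$event_id, samples))
  if (n_ev > 0) {
    for (j in seq_along(samples)) {
      g <- sample_grp[j]
      psi_g <- if (g == last) te$psi_treatment else te$psi_control
      depth <- if (config$noise_free) rep(config$event_depth, n_ev) else {
        pmax(stats::rpois(n_ev, config$event_depth), 1L)
      }
      inc <- if (config$noise_free) round(depth * psi_g) else {
        stats::rbinom(n_ev, depth, psi_g)
      }
      inc_mat[, j] <- as.integer(inc)
      exc_mat[, j] <- as.integer(depth - inc)
      psi_real[, j] <- inc / depth
    }
  }

  # transcript abundance and read support, consistent with realized PSI
  tx2gene <- transcript_index(annotation$genes)
  tx_ids <- tx2gene$transcript_id
  abundance <- matrix(0, nrow = length(tx_ids), ncol = length(samples),
                      dimnames = list(tx_ids, samples))
  support <- abundance
  gene_of <- stats::setNames(tx2gene$gene_id, tx_ids)
  ev_of_gene <- match(gene_of, te$gene_id)
  inc_tx <- te$inclusion_tx[ev_of_gene]
  frac <- matrix(1, nrow = length(tx_ids), ncol = length(samples))
  has_ev <- !is.na(ev_of_gene)
  frac[has_ev, ] <- ifelse(
    matrix(tx_ids[has_ev] == inc_tx[has_ev], nrow = sum(has_ev),
           ncol = length(samples)),
    psi_real[ev_of_gene[has_ev], , drop = FALSE],
    1 - psi_real[ev_of_gene[has_ev], , drop = FALSE])
  abundance <- tpm[gene_of, , drop = FALSE] * frac
  support <- round(counts[gene_of, , drop = FALSE] * frac)
  dimnames(abundance) <- dimnames(support) <- list(tx_ids, samples)

  list(abundance = abundance, counts = counts,
       event_counts = list(inclusion = inc_mat, exclusion = exc_mat),
       support = support, samples = samples, truth = truth,
       tx2gene = tx2gene)
}

# -- fixture bundle I/O -----------------------------------------------------

write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV matrix written by the fixture bundle
#'
#' @param path File path; first column holds row ids.
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write event read counts as a long TSV
#'
#' @param event_counts List of `inclusion`/`exclusion` matrices.
#' @param path Output path.
#' @export
write_event_counts_tsv <- function(event_counts, path) {
  inc <- event_counts$inclusion
  long <- data.frame(
    event_id = rep(rownames(inc), ncol(inc)),
    sample = rep(colnames(inc), each = nrow(inc)),
    inclusion_reads = as.integer(inc),
    exclusion_reads = as.integer(event_counts$exclusion),
    stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read event read counts written by [write_event_counts_tsv()]
#'
#' @param path File path.
#' @return List of `inclusion`/`exclusion` matrices.
#' @export
read_event_counts_tsv <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  events <- unique(long$event_id)
  samples <- unique(long$sample)
  shape <- function(col) {
    m <- matrix(long[[col]][order(match(long$sample, samples),
                                  match(long$event_id, events))],
                nrow = length(events),
                dimnames = list(events, samples))
    m
  }
  list(inclusion = shape("inclusion_reads"),
       exclusion = shape("exclusion_reads"))
}

#' Write the complete synthetic fixture bundle
#'
#' Emits the GTF annotation, abundance/count/support matrices, event read
#' counts, similarity hit table (BLAST tabular), gene-to-term map, the
#' truth ledgers, and the config as YAML. All files are plain text and
#' round-trip losslessly through the package readers.
#'
#' @param annotation Result of [generate_annotation()].
#' @param expression Result of [generate_expression()].
#' @param dir Output directory (created if needed).
#' @param config The [sim_config()] used.
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture_bundle <- function(annotation, expression, dir, config) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) {
      stop("cannot create output directory ", dir, call. = FALSE)
    }
  }
  paths <- c(
    gtf = file.path(dir, "annotation.gtf"),
    abundance = file.path(dir, "abundance_tpm.tsv"),
    counts = file.path(dir, "gene_counts.tsv"),
    support = file.path(dir, "transcript_support.tsv"),
    event_counts = file.path(dir, "event_read_counts.tsv"),
    hits = file.path(dir, "homology_hits.tsv"),
    term_map = file.path(dir, "gene_terms.tsv"),
    truth_events = file.path(dir, "truth_events.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_pairs = file.path(dir, "truth_pairs.tsv"),
    config = file.path(dir, "sim_config.yaml"))
  write_gtf_models(annotation$genes, paths["gtf"])
  write_matrix_tsv(expression$abundance, paths["abundance"], "transcript_id")
  write_matrix_tsv(expression$counts, paths["counts"], "gene_id")
  write_matrix_tsv(expression$support, paths["support"], "transcript_id")
  write_event_counts_tsv(expression$event_counts, paths["event_counts"])
  write_blast_tab(annotation$hits, paths["hits"])
  utils::write.table(annotation$term_map, paths["term_map"], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (nm in c("events", "genes", "pairs")) {
    utils::write.table(expression$truth[[nm]],
                       paths[paste0("truth_", nm)], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  cfg <- unclass(config)
  cfg$planted_event_counts <- lapply(cfg$planted_event_counts, as.list)
  cfg$planted_bias_shift_counts <- as.list(cfg$planted_bias_shift_counts)
  yaml::write_yaml(cfg, paths["config"])
  invisible(paths)
}

#' Read a gene-to-term annotation map
#'
#' @param path Two-column headerless TSV (`gene_id`, `term_id`).
#' @return `data.frame` with `gene_id`, `term_id`.
#' @export
read_term_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("gene_id", "term_id")
  df
}

#' Simulate and write a complete fixture bundle
#'
#' Convenience wrapper: [generate_annotation()] then
#' [generate_expression()] then [write_fixture_bundle()].
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return List with `annotation`, `expression` and `paths`.
#' @export
simulate_bundle <- function(config = sim_config(), dir) {
  ann <- generate_annotation(config)
  expr <- generate_expression(ann, config)
  paths <- write_fixture_bundle(ann, expr, dir, config)
  list(annotation = ann, expression = expr, paths = paths)
}
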