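tiny_cfg <- function(...) {
  sim_config(n_genes_per_subgenome = 30,
             planted_event_counts = list(
               gain = c(IR = 1, ES = 1, A5 = 1, A3 = 1),
               lost = c(IR = 1, ES = 1, A5 = 1, A3 = 1),
               das = c(IR = 2, ES = 2, A5 = 2, A3 = 2),
               stable = c(IR = 1, ES = 1, A5 = 1, A3 = 1)),
             planted_deg_count = 8,
             planted_bias_shift_counts = c("balanced>B-bias" = 3,
                                           "balanced>A-bias" = 2,
                                           "A-bias>B-bias" = 2),
             ...)
}

test_that("configuration errors name the offending count", {
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(das_delta_psi = 0.1), "das_delta_psi")
  expect_error(sim_config(deg_log2fc = 1), "deg_log2fc")
  expect_error(
    sim_config(n_genes_per_subgenome = 4,
               planted_bias_shift_counts = c("balanced>B-bias" = 10)),
    "planted_bias_shift_counts")
  expect_error(
    sim_config(n_genes_per_subgenome = 5, planted_deg_count = 100,
               planted_bias_shift_counts = c("balanced>B-bias" = 0)),
    "planted_deg_count")
})

test_that("a single planted ES gene realizes the minimal skipping structure", {
  cfg <- sim_config(n_genes_per_subgenome = 2,
                    planted_event_counts = list(gain = c(ES = 1)),
                    planted_deg_count = 0,
                    planted_bias_shift_counts = c("balanced>B-bias" = 0),
                    seed = 2)
  ann <- generate_annotation(cfg)
  ev_gene <- ann$truth$events$gene_id[1]
  g <- ann$genes[[ev_gene]]
  expect_length(g$transcripts, 2)
  rel <- lapply(g$transcripts, function(tx) {
    sweep(tx$exons, 2, min(tx$exons))
  })
  shapes <- vapply(rel, function(m) paste(t(m), collapse = ","), "")
  expect_setequal(shapes, c("0,100,200,300,400,500", "0,100,400,500"))
})

test_that("same seed and config give a byte-identical bundle", {
  cfg <- tiny_cfg(seed = 12)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_bundle(cfg, d1)
  s2 <- simulate_bundle(cfg, d2)
  for (f in names(s1$paths)) {
    expect_identical(
      readBin(s1$paths[[f]], "raw", file.size(s1$paths[[f]])),
      readBin(s2$paths[[f]], "raw", file.size(s2$paths[[f]])),
      label = paste("bytes of", f))
  }
  # a different seed changes the truth ledger
  s3 <- simulate_bundle(tiny_cfg(seed = 13), withr::local_tempdir())
  expect_false(identical(s1$expression$truth$events$event_id,
                         s3$expression$truth$events$event_id))
})

test_that("planted events are recovered exactly by enumeration", {
  cfg <- tiny_cfg(seed = 14)
  ann <- generate_annotation(cfg)
  cat_ <- enumerate_events(ann$genes)
  expect_setequal(cat_$event_id, ann$truth$events$event_id)
  got_types <- cat_$etype[match(ann$truth$events$event_id, cat_$event_id)]
  expect_equal(got_types, ann$truth$events$etype)
})

test_that("noise-free gain events have extreme control and intermediate treatment PSI", {
  cfg <- tiny_cfg(noise_free = TRUE, seed = 15)
  ann <- generate_annotation(cfg)
  ex <- generate_expression(ann, cfg)
  cat_ <- enumerate_events(ann$genes)
  psi <- compute_psi(cat_, ex$abundance)
  gains <- ann$truth$events$event_id[ann$truth$events$category == "gain"]
  grp <- sample_groups(colnames(psi))
  ctrl <- psi[gains, grp == "AG", drop = FALSE]
  trt <- psi[gains, grp == "CG", drop = FALSE]
  expect_true(all(ctrl >= 0.96 | ctrl <= 0.04))
  expect_true(all(trt >= 0.05 & trt <= 0.95))
})

test_that("planted DEG fold changes land inside the tolerance band", {
  cfg <- sim_config(n_genes_per_subgenome = 100,
                    planted_event_counts = list(gain = c(IR = 0)),
                    planted_bias_shift_counts = c("balanced>B-bias" = 0),
                    planted_deg_count = 60, deg_log2fc = 3,
                    library_size = 1e6, seed = 16)
  ann <- generate_annotation(cfg)
  ex <- generate_expression(ann, cfg)
  # library scaling is compositional (up-DEGs squeeze the other genes in
  # CG), so the empirical ratio is taken on size-factor-normalized counts
  norm <- sweep(ex$counts, 2, size_factors(ex$counts), "/")
  grp <- sample_groups(colnames(norm))
  m_ag <- rowMeans(norm[, grp == "AG"])
  m_cg <- rowMeans(norm[, grp == "CG"])
  tg <- ex$truth$genes[ex$truth$genes$is_deg, ]
  emp <- log2((m_cg[tg$gene_id] + 0.5) / (m_ag[tg$gene_id] + 0.5))
  in_band <- abs(emp - tg$planted_log2fc) <= 0.5
  expect_gte(mean(in_band), 0.9)
})

test_that("noise-free bias transitions round-trip through classify_bias", {
  cfg <- tiny_cfg(noise_free = TRUE, seed = 17)
  ann <- generate_annotation(cfg)
  ex <- generate_expression(ann, cfg)
  sf <- size_factors(ex$counts)
  norm <- sweep(ex$counts, 2, sf, "/")
  grp <- sample_groups(colnames(norm))
  em <- vapply(unique(grp), function(g) {
    rowMeans(norm[, grp == g, drop = FALSE])
  }, numeric(nrow(norm)))
  subg <- stats::setNames(ex$truth$genes$subgenome,
                          ex$truth$genes$gene_id)
  pairs <- reciprocal_best_hits(ann$hits, 90, subg)
  calls <- classify_bias(em, pairs)
  tp <- ex$truth$pairs
  truth_by_gene <- function(g) stats::setNames(tp[[g]], tp$gene_a)
  for (g in c("AG", "BG", "CG")) {
    cc <- calls[calls$condition == g, ]
    ga <- pairs$gene_a[match(cc$pair_id, pairs$pair_id)]
    expect_equal(cc$klass, unname(truth_by_gene(g)[ga]))
  }
})

test_that("per-sample totals stay near the configured library size", {
  cfg <- tiny_cfg(seed = 18)
  ann <- generate_annotation(cfg)
  totals <- unlist(lapply(1:20, function(s) {
    cfg$seed <- 100 + s
    colSums(generate_expression(ann, cfg)$counts)
  }))
  se <- stats::sd(totals) / sqrt(length(totals))
  expect_lte(abs(mean(totals) - cfg$library_size), 3 * se)
})

test_that("fixture files are internally consistent and round-trip", {
  cfg <- tiny_cfg(seed = 19)
  dir <- withr::local_tempdir()
  sim <- simulate_bundle(cfg, dir)
  # hit rows for planted pairs carry identity >= 90
  hits <- read_blast_tab(sim$paths[["hits"]])
  tp <- sim$annotation$pairs
  planted_rows <- hits[paste(hits$qseqid, hits$sseqid) %in%
                       paste(tp$gene_a, tp$gene_b), ]
  expect_true(all(planted_rows$pident >= 90))
  # every term's genes are emitted genes
  tm <- read_term_map(sim$paths[["term_map"]])
  expect_true(all(tm$gene_id %in% names(sim$annotation$genes)))
  # matrices round-trip
  ab <- read_matrix_tsv(sim$paths[["abundance"]])
  expect_equal(ab, sim$expression$abundance[rownames(ab), colnames(ab)],
               tolerance = 1e-8)
  cm <- read_matrix_tsv(sim$paths[["counts"]])
  expect_equal(cm, sim$expression$counts[rownames(cm), colnames(cm)])
  ec <- read_event_counts_tsv(sim$paths[["event_counts"]])
  ref <- sim$expression$event_counts
  expect_equal(ec$inclusion[rownames(ref$inclusion), colnames(ref$inclusion)],
               ref$inclusion, ignore_attr = FALSE)
  # unwritable directory errors
  expect_error(
    write_fixture_bundle(sim$annotation, sim$expression,
                         file.path("/proc/no_such_place", "x"), cfg),
    "directory")
})
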