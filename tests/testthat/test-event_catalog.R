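test_that("minimal exon-skipping gene yields exactly one ES event", {
  g <- gene_model("g1", "chr01A", "+", list(
    transcript_model("T1", "g1", "chr01A", "+",
                     rbind(c(0, 100), c(200, 300), c(400, 500))),
    transcript_model("T2", "g1", "chr01A", "+",
                     rbind(c(0, 100), c(400, 500)))))
  cat_ <- enumerate_events(list(g1 = g))
  expect_equal(nrow(cat_), 1)
  expect_equal(cat_$etype, "ES")
  expect_equal(unlist(cat_[, c("a1", "a2", "a3", "a4")], use.names = FALSE),
               c(100, 200, 300, 400))
  expect_equal(cat_$inclusion, "T1")
  expect_equal(cat_$exclusion, "T2")
  # the cassette exon must NOT also fire alternative-boundary events
  expect_false(any(cat_$etype %in% c("A5", "A3")))
})

test_that("minimal intron-retention gene yields one IR event, retaining form as inclusion", {
  g <- gene_model("g2", "chr01A", "+", list(
    transcript_model("T1", "g2", "chr01A", "+",
                     rbind(c(0, 100), c(200, 300))),
    transcript_model("T2", "g2", "chr01A", "+", rbind(c(0, 300)))))
  cat_ <- enumerate_events(list(g2 = g))
  expect_equal(nrow(cat_), 1)
  expect_equal(cat_$etype, "IR")
  expect_equal(unlist(cat_[, c("a1", "a2", "a3", "a4")], use.names = FALSE),
               c(0, 100, 200, 300))
  expect_equal(cat_$inclusion, "T2")
  expect_equal(cat_$exclusion, "T1")
})

test_that("alternative boundary events resolve donor/acceptor by strand", {
  mk <- function(strand) {
    gene_model("g3", "chr01A", strand, list(
      transcript_model("T1", "g3", "chr01A", strand,
                       rbind(c(0, 150), c(200, 300))),
      transcript_model("T2", "g3", "chr01A", strand,
                       rbind(c(0, 100), c(200, 300)))))
  }
  plus <- enumerate_events(list(g3 = mk("+")))
  minus <- enumerate_events(list(g3 = mk("-")))
  expect_equal(plus$etype, "A5")   # left boundary is the donor on "+"
  expect_equal(minus$etype, "A3")  # and the acceptor on "-"
  # shorter intron (more exon retained) is the inclusion form
  expect_equal(plus$inclusion, "T1")
  expect_equal(plus$exclusion, "T2")
})

test_that("overlapping exons raise a validation error naming the transcript", {
  expect_error(
    transcript_model("Tbad", "g", "chr01A", "+",
                     rbind(c(0, 100), c(50, 200))),
    "Tbad")
})

test_that("enumeration matches the brute-force pairwise oracle on random genes", {
  set.seed(101)
  for (i in seq_len(300)) {
    g <- random_gene(sprintf("rg%03d", i))
    got <- catalog_triples(enumerate_events(stats::setNames(list(g),
                                                            g$gene_id)))
    expect_identical(got, oracle_event_triples(g))
  }
})

test_that("coordinate reflection behaves coherently under strand handling", {
  # Reflecting coordinates while KEEPING the strand label swaps donor and
  # acceptor roles (A5 <-> A3); reflecting AND flipping the strand is an
  # isometry of the annotation and preserves every event type. IR/ES are
  # invariant either way.
  set.seed(202)
  swap <- c(IR = "IR", ES = "ES", A5 = "A3", A3 = "A5")
  keep <- c(IR = "IR", ES = "ES", A5 = "A5", A3 = "A3")
  for (i in seq_len(80)) {
    g <- random_gene(sprintf("sg%03d", i))
    span <- max(vapply(g$transcripts, function(tx) max(tx$exons), 0)) + 17
    gr_flip <- reflect_gene(g, span)
    gr_keep <- gene_model(g$gene_id, g$chrom, g$strand,
                          lapply(gr_flip$transcripts, function(tx) {
                            transcript_model(tx$transcript_id, tx$gene_id,
                                             tx$chrom, g$strand, tx$exons)
                          }))
    cat_f <- enumerate_events(stats::setNames(list(g), g$gene_id))
    mapped <- function(tab) {
      if (nrow(cat_f) == 0) return(character())
      sort(paste(cat_f$gene_id, unname(tab[cat_f$etype]),
                 paste(span - cat_f$a4, span - cat_f$a3, span - cat_f$a2,
                       span - cat_f$a1, sep = ":"), sep = "|"))
    }
    expect_identical(
      catalog_triples(enumerate_events(list(g = gr_flip))), mapped(keep))
    expect_identical(
      catalog_triples(enumerate_events(list(g = gr_keep))), mapped(swap))
  }
})

test_that("adding a transcript never removes an existing event", {
  set.seed(303)
  for (i in seq_len(60)) {
    g <- random_gene(sprintf("mg%03d", i))
    before <- catalog_triples(enumerate_events(stats::setNames(list(g),
                                                               g$gene_id)))
    extra <- random_gene("tmp", chrom = g$chrom, strand = g$strand)
    tx <- extra$transcripts[[1]]
    tx2 <- transcript_model(paste0(g$gene_id, ".extra"), g$gene_id,
                            g$chrom, g$strand, tx$exons)
    g2 <- gene_model(g$gene_id, g$chrom, g$strand,
                     c(g$transcripts, list(tx2)))
    after <- catalog_triples(enumerate_events(stats::setNames(list(g2),
                                                              g$gene_id)))
    expect_true(all(before %in% after))
  }
})

test_that("event-type frequencies sum to 100 and handle degenerate groups", {
  cat_ <- make_catalog(c("IR", "ES", "A5", "A3"))
  freq <- summarize_event_frequencies(cat_)
  expect_equal(freq$pct, rep(25, 4))
  expect_equal(sum(freq$count), 4)
  # group with no active events: zero counts, pct flagged missing
  mask <- matrix(c(rep(TRUE, 4), rep(FALSE, 4)), ncol = 2,
                 dimnames = list(cat_$event_id, c("AG", "CG")))
  freq2 <- summarize_event_frequencies(cat_, mask)
  expect_equal(sum(freq2$count[freq2$group == "CG"]), 0)
  expect_true(all(is.na(freq2$pct[freq2$group == "CG"])))
  expect_equal(sum(freq2$pct[freq2$group == "AG"]), 100, tolerance = 1e-9)
})

test_that("planted composition is recovered exactly", {
  etypes <- rep(c("IR", "A3", "A5", "ES"), c(40, 30, 20, 10))
  cat_ <- make_catalog(etypes)
  freq <- summarize_event_frequencies(cat_)
  got <- stats::setNames(freq$pct, freq$etype)
  expect_equal(got[c("IR", "A3", "A5", "ES")],
               c(IR = 40, A3 = 30, A5 = 20, ES = 10))
})

test_that("events-per-gene histogram matches a direct recount", {
  cat_ <- make_catalog(c("IR", "IR", rep("A3", 7), "ES"),
                       genes = c("gA", "gA", rep("gB", 7), "gC"))
  hist <- events_per_gene_distribution(cat_)
  all_bins <- hist[hist$etype == "all", ]
  expect_equal(all_bins$n_genes[all_bins$bin == "1"], 1)   # gC
  expect_equal(all_bins$n_genes[all_bins$bin == "2"], 1)   # gA
  expect_equal(all_bins$n_genes[all_bins$bin == ">5"], 1)  # gB
  a3 <- hist[hist$etype == "A3", ]
  expect_equal(a3$n_genes[a3$bin == ">5"], 1)
  # mass equals number of active genes, overall and per type
  expect_equal(sum(all_bins$n_genes), 3)
  # random catalog vs recount oracle
  set.seed(11)
  etypes <- sample(c("IR", "ES", "A5", "A3"), 200, replace = TRUE)
  genes <- sample(sprintf("g%02d", 1:40), 200, replace = TRUE)
  rc <- make_catalog(etypes, genes = genes)
  rc <- rc[!duplicated(rc$event_id), ]
  h <- events_per_gene_distribution(rc)
  oracle <- table(table(rc$gene_id))
  got_all <- stats::setNames(h$n_genes[h$etype == "all"],
                             h$bin[h$etype == "all"])
  for (nm in names(oracle)) {
    bin <- if (as.integer(nm) > 5) ">5" else nm
    expect_equal(sum(got_all[bin]),
                 sum(oracle[as.integer(names(oracle)) > 5 & bin == ">5"],
                     oracle[nm][bin != ">5"], na.rm = TRUE))
  }
})

test_that("aggregation by subgenome and bin is consistent", {
  cat_ <- make_catalog(rep("IR", 5), chrom = "chr01A")
  cat_$chrom[4:5] <- "chr01B"
  agg <- aggregate_events(cat_, bin_size = 1e9)
  sg <- agg$by_subgenome
  expect_equal(sg$count[sg$subgenome == "A"], 3)
  expect_equal(sg$count[sg$subgenome == "B"], 2)
  # bin larger than chromosome -> single bin per chromosome
  expect_equal(nrow(agg$by_bin), 2)
  expect_equal(sum(agg$by_bin$count), sum(agg$by_chromosome$count))
  # unlabeled chromosome errors
  bad <- make_catalog("IR", chrom = "scaffold7")
  expect_error(aggregate_events(bad), "subgenome suffix")
})

test_that("per-bin counts match a direct recount on random placements", {
  set.seed(21)
  n <- 150
  cat_ <- make_catalog(sample(c("IR", "ES", "A5", "A3"), n, replace = TRUE))
  cat_$a1 <- sample.int(1e6, n)
  cat_$chrom <- sample(c("chr01A", "chr02A", "chr01B"), n, replace = TRUE)
  bin_size <- 1e5
  agg <- aggregate_events(cat_, bin_size = bin_size)
  oracle <- table(paste(cat_$chrom, floor(cat_$a1 / bin_size), sep = ":"))
  got <- tapply(agg$by_bin$count, agg$by_bin$bin, sum)
  expect_equal(sort(names(got)), sort(names(oracle)))
  expect_equal(as.integer(got[names(oracle)]), as.integer(oracle))
  # subgenome totals equal the sum of member chromosomes
  chr_tot <- tapply(agg$by_chromosome$count,
                    subgenome_of(agg$by_chromosome$chrom), sum)
  sg_tot <- tapply(agg$by_subgenome$count, agg$by_subgenome$subgenome, sum)
  expect_equal(as.integer(sg_tot[names(chr_tot)]), as.integer(chr_tot))
})
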