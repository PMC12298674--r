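hit_rows <- function(q, s, pident, bitscore) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = 400,
             mismatch = 0, gapopen = 0, qstart = 1, qend = 400, sstart = 1,
             send = 400, evalue = 1e-50, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

test_that("reciprocal best hits keep mutual top-scoring pairs above identity", {
  hits <- rbind(
    hit_rows("A1", "B1", 95, 800), hit_rows("B1", "A1", 95, 800),
    # A2's best is B2 but B2 prefers A3: no pair for either
    hit_rows("A2", "B2", 96, 700), hit_rows("B2", "A3", 97, 750),
    hit_rows("A3", "B3", 92, 600), hit_rows("B3", "A3", 92, 600),
    # mutual but below the identity bar
    hit_rows("A4", "B4", 80, 900), hit_rows("B4", "A4", 80, 900))
  pairs <- reciprocal_best_hits(hits)
  expect_setequal(pairs$gene_a, c("A1", "A3"))
  expect_false("B2" %in% c(pairs$gene_a, pairs$gene_b))
  expect_false("A4" %in% pairs$gene_a)
  expect_true(all(pairs$identity_pct >= 90))
  expect_equal(nrow(reciprocal_best_hits(hits[0, ])), 0)
})

test_that("RBH matches a brute-force mutual-argmax oracle and is role-symmetric", {
  set.seed(61)
  a <- sprintf("A%02d", 1:15)
  b <- sprintf("B%02d", 1:15)
  grid <- expand.grid(qseqid = a, sseqid = b, stringsAsFactors = FALSE)
  keep <- sample(nrow(grid), 120)
  hits <- hit_rows(grid$qseqid[keep], grid$sseqid[keep],
                   round(runif(120, 85, 100), 2),
                   round(runif(120, 100, 1000), 2))
  both <- rbind(hits, stats::setNames(
    hits[, c(2, 1, 3:12)], names(hits)))
  pairs <- reciprocal_best_hits(both, min_identity = 90)
  # oracle: mutual argmax by bitscore over the directed score table
  best_of <- function(g) {
    h <- both[both$qseqid == g, ]
    h <- h[order(-h$bitscore, -h$pident, h$sseqid), ]
    h[1, ]
  }
  oracle <- character()
  for (g in a) {
    if (!g %in% both$qseqid) next
    h1 <- best_of(g)
    if (!h1$sseqid %in% both$qseqid) next
    h2 <- best_of(h1$sseqid)
    if (h2$sseqid == g && h1$pident >= 90 && h2$pident >= 90) {
      oracle <- c(oracle, paste(g, h1$sseqid))
    }
  }
  expect_setequal(paste(pairs$gene_a, pairs$gene_b), oracle)
  # swapping query/subject roles leaves the pair set unchanged
  swapped <- stats::setNames(both[, c(2, 1, 3:12)], names(both))
  pairs_sw <- reciprocal_best_hits(swapped, min_identity = 90)
  expect_setequal(pairs$pair_id, pairs_sw$pair_id)
})

test_that("hit-table reader enforces the 12-column dialect", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_blast_tab(hit_rows("A1", "B1", 95, 800), tmp)
  back <- read_blast_tab(tmp)
  expect_equal(back$pident, 95)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("A1\tB1\t95", bad)
  expect_error(read_blast_tab(bad), "12")
})

test_that("bias classes follow the log2-ratio rule with floor and pseudocount", {
  em <- matrix(c(100, 100, 10, 100, 0.2, 0.5), ncol = 1,
               dimnames = list(c("A1", "B1", "A2", "B2", "A3", "B3"), "AG"))
  pairs <- data.frame(pair_id = c("p1", "p2", "p3"),
                      gene_a = c("A1", "A2", "A3"),
                      gene_b = c("B1", "B2", "B3"))
  calls <- classify_bias(em, pairs)
  expect_equal(calls$klass, c("balanced", "B-bias", "low-expression"))
  expect_equal(calls$log2_ratio[2], log2(11 / 101))
  # A-bias threshold is inclusive at +/- log2_cut
  em2 <- matrix(c(39, 19), ncol = 1, dimnames = list(c("A1", "B1"), "AG"))
  expect_equal(classify_bias(em2, pairs[1, ])$klass, "A-bias")
  expect_error(classify_bias(em[1:3, , drop = FALSE], pairs), "missing")
})

test_that("swapping subgenome labels mirrors A-bias and B-bias", {
  set.seed(62)
  n <- 50
  em <- matrix(rexp(2 * n, 1 / 100), ncol = 1,
               dimnames = list(c(sprintf("A%02d", 1:n),
                                 sprintf("B%02d", 1:n)), "AG"))
  pairs <- data.frame(pair_id = sprintf("p%02d", 1:n),
                      gene_a = sprintf("A%02d", 1:n),
                      gene_b = sprintf("B%02d", 1:n))
  fwd <- classify_bias(em, pairs)
  mirrored <- pairs
  mirrored$gene_a <- pairs$gene_b
  mirrored$gene_b <- pairs$gene_a
  rev <- classify_bias(em, mirrored)
  swap <- c("A-bias" = "B-bias", "B-bias" = "A-bias",
            balanced = "balanced", "low-expression" = "low-expression")
  expect_equal(unname(swap[fwd$klass]), rev$klass)
})

test_that("transition tables reproduce printed-count percentages and marginals", {
  # 6043 DEG-linked pairs of which 1003 move balanced -> B-bias
  klass_from <- rep("balanced", 6043)
  klass_to <- rep(c("B-bias", "balanced"), c(1003, 5040))
  calls <- rbind(
    data.frame(pair_id = sprintf("p%04d", 1:6043), condition = "AG",
               klass = klass_from),
    data.frame(pair_id = sprintf("p%04d", 1:6043), condition = "CG",
               klass = klass_to))
  tt <- transition_table(calls, "AG", "CG")
  cell <- tt$table[tt$table$class_from == "balanced" &
                   tt$table$class_to == "B-bias", ]
  expect_equal(round(cell$pct, 2), 16.60)
  expect_equal(tt$total, 6043)
  # all balanced in both conditions -> diagonal cell 100%
  calls2 <- calls
  calls2$klass <- "balanced"
  tt2 <- transition_table(calls2, "AG", "CG")
  expect_equal(max(tt2$table$pct), 100)
  # random labels: recount oracle and marginal conservation
  set.seed(63)
  cls <- c("A-bias", "balanced", "B-bias")
  kf <- sample(cls, 300, replace = TRUE)
  kt <- sample(cls, 300, replace = TRUE)
  calls3 <- rbind(
    data.frame(pair_id = sprintf("q%03d", 1:300), condition = "AG",
               klass = kf),
    data.frame(pair_id = sprintf("q%03d", 1:300), condition = "CG",
               klass = kt))
  tt3 <- transition_table(calls3, "AG", "CG")
  oracle <- table(factor(kf, cls), factor(kt, cls))
  for (i in seq_len(nrow(tt3$table))) {
    expect_equal(tt3$table$count[i],
                 unname(oracle[tt3$table$class_from[i],
                               tt3$table$class_to[i]]))
  }
  row_marg <- tapply(tt3$table$count, tt3$table$class_from, sum)
  expect_equal(as.integer(row_marg[cls]), as.integer(table(factor(kf, cls))))
  # low-expression pairs are excluded and reported
  calls4 <- calls3
  calls4$klass[calls4$pair_id == "q001" & calls4$condition == "AG"] <-
    "low-expression"
  tt4 <- transition_table(calls4, "AG", "CG")
  expect_equal(tt4$excluded_low, "q001")
  expect_equal(tt4$total, 299)
})

test_that("2x2 chi-square uses the continuity correction correctly", {
  # equal proportions: zero statistic without correction
  expect_equal(chisq_2x2(10, 100, 10, 100, yates = FALSE)$chi2, 0)
  # Yates value against the closed-form shortcut formula
  a <- 30; b <- 70; c_ <- 45; d <- 55
  n <- a + b + c_ + d
  shortcut <- n * (abs(a * d - b * c_) - n / 2)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  expect_equal(chisq_2x2(30, 100, 45, 100)$chi2, shortcut,
               tolerance = 1e-12)
  expect_error(chisq_2x2(0, 10, 0, 10), "marginal")
})

test_that("Mann-Whitney matches exact enumeration and the large-sample oracle", {
  res <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_gte(res$p, 0.99)
  sep <- mann_whitney(1:10, 21:30)
  expect_equal(sep$U, 0)
  # exact p against brute-force enumeration over all 70 assignments
  set.seed(64)
  for (i in 1:10) {
    x <- round(runif(4, 0, 10), 2)
    y <- round(runif(4, 0, 10), 2)
    got <- mann_whitney(x, y)
    r <- rank(c(x, y))
    combs <- utils::combn(8, 4)
    us <- colSums(matrix(r[combs], nrow = 4)) - 10
    brute <- min(1, 2 * min(mean(us <= got$U + 1e-9),
                            mean(us >= got$U - 1e-9)))
    expect_equal(got$p, brute, tolerance = 1e-12)
    # tie-free cases also agree with the distribution-based oracle
    if (!any(duplicated(c(x, y)))) {
      expect_equal(got$p,
                   stats::wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  }
  # normal approximation path agrees with the standard implementation
  set.seed(65)
  x <- rnorm(25); y <- rnorm(30, 0.5)
  got <- mann_whitney(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})
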