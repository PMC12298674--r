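# Homoeolog pairing and subgenome expression bias.
#
# Homoeologs are paired by reciprocal best hits (RBH) on a BLAST tabular
# similarity table; per-condition bias is classified from the log2 ratio of
# the two copies' mean expression; transitions between conditions are
# cross-tabulated with percentages over the examined gene subset.

BLAST6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore")

#' Read a 12-column BLAST tabular (outfmt 6) hit table
#'
#' @param path File path.
#' @return `data.frame` with the standard outfmt-6 column names.
#' @export
read_blast_tab <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse hit table ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(df) != 12) {
    stop("hit table ", path, " has ", ncol(df),
         " columns; expected 12 (outfmt 6)", call. = FALSE)
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(df[[3]]))))
  if (length(bad) > 0) {
    stop("malformed pident at line ", bad[1], " of ", path, call. = FALSE)
  }
  names(df) <- BLAST6_COLS
  df
}

#' Write a hit table in BLAST outfmt-6 layout
#'
#' @param hits `data.frame` with the outfmt-6 columns.
#' @param path Output path.
#' @export
write_blast_tab <- function(hits, path) {
  utils::write.table(hits[, BLAST6_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Best hit per query: highest bitscore, ties by higher pident, then
# lexicographically smaller subject id.
best_hits <- function(hits) {
  ord <- order(hits$qseqid, -hits$bitscore, -hits$pident, hits$sseqid)
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h$qseqid), , drop = FALSE]
}

#' Pair homoeologs by reciprocal best hits
#'
#' For each gene the best cross-subgenome hit is chosen by bitscore (ties:
#' higher percent identity, then lexicographically smaller subject id). A
#' pair is kept iff the best hits are mutual and the percent identity is at
#' least `min_identity` in both directions. The resulting pairing is 1:1.
#'
#' @param hits BLAST tabular `data.frame` (see [read_blast_tab()]) holding
#'   hits in both directions.
#' @param min_identity Identity threshold in percent, default 90.
#' @param subgenomes Optional named vector gene_id -> `"A"`/`"B"`; when
#'   given, same-subgenome hit rows are dropped and pairs are reported with
#'   `gene_a` from subgenome A. Without it, pairs are reported with the
#'   lexicographically smaller member first.
#' @return `data.frame` of homoeolog pairs: `pair_id`, `gene_a`, `gene_b`,
#'   `identity_pct` (minimum of the two directions).
#' @export
reciprocal_best_hits <- function(hits, min_identity = 90,
                                 subgenomes = NULL) {
  empty <- data.frame(pair_id = character(), gene_a = character(),
                      gene_b = character(), identity_pct = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  if (!is.null(subgenomes)) {
    cross <- subgenomes[hits$qseqid] != subgenomes[hits$sseqid]
    hits <- hits[!is.na(cross) & cross, , drop = FALSE]
  }
  if (nrow(hits) == 0) return(empty)
  bh <- best_hits(hits)
  partner <- stats::setNames(bh$sseqid, bh$qseqid)
  mutual <- !is.na(partner[bh$sseqid]) & partner[bh$sseqid] == bh$qseqid
  bh <- bh[mutual, , drop = FALSE]
  if (nrow(bh) == 0) return(empty)
  # one row per unordered pair; identity must clear the bar both ways
  a <- pmin(bh$qseqid, bh$sseqid)
  b <- pmax(bh$qseqid, bh$sseqid)
  key <- paste(a, b)
  ident <- vapply(split(bh$pident, key), min, 0)
  n_dir <- vapply(split(bh$pident, key), length, 0L)
  first <- !duplicated(key)
  keep <- n_dir[key[first]] == 2 & ident[key[first]] >= min_identity
  a <- a[first][keep]; b <- b[first][keep]
  ident <- unname(ident[key[first]][keep])
  if (!is.null(subgenomes)) {
    swap <- subgenomes[a] == "B"
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  }
  ord <- order(a)
  data.frame(pair_id = paste(a, b, sep = "|")[ord],
             gene_a = a[ord], gene_b = b[ord],
             identity_pct = ident[ord], stringsAsFactors = FALSE)
}

#' Classify per-condition subgenome bias of homoeolog pairs
#'
#' The bias class is determined solely by the log2 expression ratio
#' `log2((mean_a + pseudocount) / (mean_b + pseudocount))` and the
#' expression floor: `low-expression` when both copies fall below `floor`,
#' otherwise `A-bias` / `B-bias` when the ratio is at least `log2_cut` away
#' from zero, else `balanced`.
#'
#' @param expr_means Numeric matrix of mean normalized expression, genes x
#'   conditions.
#' @param pairs Homoeolog pairs from [reciprocal_best_hits()].
#' @param log2_cut Bias threshold on |log2 ratio|, default 1.
#' @param floor Low-expression floor on group means, default 1.
#' @param pseudocount Added to both means in the ratio, default 1.
#' @return `data.frame` of bias calls: `pair_id`, `condition`, `mean_a`,
#'   `mean_b`, `log2_ratio`, `klass`.
#' @export
classify_bias <- function(expr_means, pairs, log2_cut = 1, floor = 1,
                          pseudocount = 1) {
  missing <- setdiff(c(pairs$gene_a, pairs$gene_b), rownames(expr_means))
  if (length(missing) > 0) {
    stop("pair member(s) missing from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (cond in colnames(expr_means)) {
    ma <- expr_means[pairs$gene_a, cond]
    mb <- expr_means[pairs$gene_b, cond]
    lr <- log2((ma + pseudocount) / (mb + pseudocount))
    klass <- ifelse(ma < floor & mb < floor, "low-expression",
             ifelse(lr >= log2_cut, "A-bias",
             ifelse(lr <= -log2_cut, "B-bias", "balanced")))
    out[[cond]] <- data.frame(pair_id = pairs$pair_id, condition = cond,
                              mean_a = unname(ma), mean_b = unname(mb),
                              log2_ratio = unname(lr), klass = klass,
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-tabulate bias transitions between two conditions
#'
#' @param calls Bias calls from [classify_bias()].
#' @param cond_from,cond_to Condition labels.
#' @param subset Optional vector of `pair_id`s to restrict to (e.g. pairs
#'   with a DEG member in the matching contrast).
#' @param drop_low Exclude pairs classified `low-expression` in either
#'   condition (default); the excluded pairs are reported.
#' @return List with `table` (`data.frame` `class_from`, `class_to`,
#'   `count`, `pct` over the subset total), `total`, and `excluded_low`
#'   (pair ids).
#' @export
transition_table <- function(calls, cond_from, cond_to, subset = NULL,
                             drop_low = TRUE) {
  from <- calls[calls$condition == cond_from, , drop = FALSE]
  to <- calls[calls$condition == cond_to, , drop = FALSE]
  ids <- intersect(from$pair_id, to$pair_id)
  if (!is.null(subset)) ids <- intersect(ids, subset)
  kf <- stats::setNames(from$klass, from$pair_id)[ids]
  kt <- stats::setNames(to$klass, to$pair_id)[ids]
  excluded <- character()
  if (drop_low) {
    low <- kf == "low-expression" | kt == "low-expression"
    excluded <- ids[low]
    ids <- ids[!low]; kf <- kf[!low]; kt <- kt[!low]
  }
  if (length(ids) == 0) {
    return(list(table = data.frame(class_from = character(),
                                   class_to = character(),
                                   count = integer(), pct = numeric(),
                                   stringsAsFactors = FALSE),
                total = 0L, excluded_low = excluded))
  }
  classes <- c("A-bias", "balanced", "B-bias")
  tab <- as.data.frame(table(class_from = factor(kf, classes),
                             class_to = factor(kt, classes)),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tab$pct <- 100 * tab$count / length(ids)
  list(table = tab, total = length(ids), excluded_low = excluded)
}

#' Yates-corrected 2x2 chi-square test of DEG proportions
#'
#' Tests the (DEG vs non-DEG) x (subgenome A vs B) contingency table built
#' from DEG and expressed-gene totals.
#'
#' @param deg_a,expressed_a DEG count and expressed-gene total, subgenome A.
#' @param deg_b,expressed_b Same for subgenome B.
#' @param yates Apply the continuity correction (default `TRUE`).
#' @return List with `chi2`, `dof`, `p`, `yates`.
#' @export
chisq_2x2 <- function(deg_a, expressed_a, deg_b, expressed_b, yates = TRUE) {
  stopifnot(deg_a >= 0, deg_b >= 0, deg_a <= expressed_a,
            deg_b <= expressed_b)
  m <- matrix(c(deg_a, expressed_a - deg_a,
                deg_b, expressed_b - deg_b), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero marginal in 2x2 table; chi-square undefined", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = yates))
  list(chi2 = unname(ct$statistic), dof = unname(ct$parameter),
       p = ct$p.value, yates = yates)
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums with average ranks on ties. For
#' `n1 + n2 <= 20` the two-sided p-value is obtained by exact enumeration
#' over all assignments of the pooled observations (valid under ties);
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. p is `2 * min(P(U <= u), P(U >= u))`, capped at 1.
#'
#' @param x,y Numeric samples.
#' @param exact_max Total size at or below which exact enumeration is used.
#' @return List with `U` (statistic for `x`), `p`, `sides = 2`.
#' @export
mann_whitney <- function(x, y, exact_max = 20) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("empty input sample", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exact_max) {
    combs <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(us <= u + eps), mean(us >= u - eps))
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term))
    z <- (u - mu - sign(u - mu) * 0.5) / sigma
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = u, p = min(1, p), sides = 2)
}
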