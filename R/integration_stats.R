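# Integration of the splicing and expression layers: rank correlations,
# set overlaps, and hypergeometric term enrichment.

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks on ties; `p` from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `method`, `r`, `p`, `n`. `r` is `NA` (flagged
#'   `degenerate`) when either variable has zero rank variance.
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) return(list(method = "spearman", r = NA_real_, p = NA_real_,
                         n = n, degenerate = TRUE))
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(method = "spearman", r = NA_real_, p = NA_real_, n = n,
                degenerate = TRUE))
  }
  r <- stats::cor(rx, ry)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(method = "spearman", r = r, p = p, n = n, degenerate = FALSE)
}

#' Correlate delta PSI with expression fold change, per event type
#'
#' Joins each DSE record to its gene's log2 fold change in the same
#' contrast and computes a Spearman correlation per event type.
#'
#' @param dse DSE records from [test_dse()], with an `etype` column (join
#'   the catalog's `etype`/`gene_id` in beforehand or pass `catalog`).
#' @param degs DEG records from [test_de()].
#' @param catalog Optional event catalog supplying `etype` and `gene_id`
#'   when `dse` lacks them.
#' @param min_n Minimum pairs per event type, default 10; smaller types are
#'   flagged `insufficient`.
#' @return `data.frame` with `etype`, `n`, `r`, `p`, `insufficient`.
#' @export
correlate_dpsi_expression <- function(dse, degs, catalog = NULL,
                                      min_n = 10) {
  if (!all(c("etype", "gene_id") %in% names(dse))) {
    if (is.null(catalog)) {
      stop("dse records lack etype/gene_id; supply the event catalog",
           call. = FALSE)
    }
    idx <- match(dse$event_id, catalog$event_id)
    dse$etype <- catalog$etype[idx]
    dse$gene_id <- catalog$gene_id[idx]
  }
  lfc <- stats::setNames(degs$log2fc, degs$gene_id)
  dse$log2fc <- lfc[dse$gene_id]
  do.call(rbind, lapply(EVENT_TYPES, function(ty) {
    sub <- dse[dse$etype == ty & !is.na(dse$log2fc), , drop = FALSE]
    if (nrow(sub) < min_n) {
      return(data.frame(etype = ty, n = nrow(sub), r = NA_real_,
                        p = NA_real_, insufficient = TRUE,
                        stringsAsFactors = FALSE))
    }
    sc <- spearman_cor(sub$delta_psi, sub$log2fc)
    data.frame(etype = ty, n = sc$n, r = sc$r, p = sc$p,
               insufficient = FALSE, stringsAsFactors = FALSE)
  }))
}

#' Overlap report for up to four named gene sets
#'
#' Reports set sizes, every intersection cardinality over the nonempty
#' subsets of sets, and the exclusive (Venn-region) cardinalities.
#'
#' @param sets Named list of up to 4 character vectors.
#' @return List with `sizes`, `regions` (`data.frame` of `members`,
#'   `intersection`, `exclusive`), and `union_size`.
#' @export
overlap_sets <- function(sets) {
  stopifnot(length(sets) >= 1, length(sets) <= 4, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  nm <- names(sets)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  combos <- unlist(lapply(seq_along(nm), function(k) {
    utils::combn(nm, k, simplify = FALSE)
  }), recursive = FALSE)
  regions <- do.call(rbind, lapply(combos, function(co) {
    inside <- rowSums(membership[, co, drop = FALSE]) == length(co)
    exact <- inside & rowSums(membership[, setdiff(nm, co),
                                         drop = FALSE]) == 0
    data.frame(members = paste(co, collapse = "&"),
               intersection = sum(inside), exclusive = sum(exact),
               stringsAsFactors = FALSE)
  }))
  list(sizes = lengths(sets), regions = regions,
       union_size = length(universe))
}

#' Hypergeometric term over-representation test
#'
#' For each term with `M` background genes annotated and `k` of the `n`
#' query genes annotated, tests `P(X >= k)` for a hypergeometric draw of
#' `n` from a background of `N` with `M` successes. FDR by
#' Benjamini-Hochberg across tested terms; terms with `M < min_m` or
#' `k = 0` are excluded from testing (reported with `tested = FALSE`).
#' `gene_ratio` is `k / M`.
#'
#' @param gene_list Character vector of query genes (subset of
#'   `background`).
#' @param background Character vector of background genes.
#' @param term_map `data.frame` with columns `gene_id`, `term_id`.
#' @param fdr_cut Significance threshold on FDR, default 0.05.
#' @param min_m Minimum background annotation count for testing, default 3.
#' @return `data.frame` of enrichment records: `term_id`, `k`, `M`, `n`,
#'   `N`, `gene_ratio`, `p`, `fdr`, `tested`, `significant`.
#' @export
hypergeom_enrich <- function(gene_list, background, term_map,
                             fdr_cut = 0.05, min_m = 3) {
  gene_list <- unique(gene_list)
  background <- unique(background)
  offenders <- setdiff(gene_list, background)
  if (length(offenders) > 0) {
    stop("gene(s) absent from background: ",
         paste(utils::head(offenders, 10), collapse = ", "), call. = FALSE)
  }
  term_map <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  term_map <- unique(term_map[, c("gene_id", "term_id")])
  N <- length(background)
  n <- length(gene_list)
  terms <- split(term_map$gene_id, term_map$term_id)
  rec <- do.call(rbind, lapply(names(terms), function(t) {
    M <- length(terms[[t]])
    k <- length(intersect(terms[[t]], gene_list))
    data.frame(term_id = t, k = k, M = M, n = n, N = N,
               gene_ratio = k / M,
               p = stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rec)) {
    return(data.frame(term_id = character(), k = integer(), M = integer(),
                      n = integer(), N = integer(), gene_ratio = numeric(),
                      p = numeric(), fdr = numeric(), tested = logical(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  rec$tested <- rec$M >= min_m & rec$k > 0
  rec$fdr <- NA_real_
  rec$fdr[rec$tested] <- stats::p.adjust(rec$p[rec$tested], method = "BH")
  rec$significant <- !is.na(rec$fdr) & rec$fdr < fdr_cut
  rec[order(rec$p), , drop = FALSE]
}

#' Correlate per-gene event counts with expressed-isoform counts
#'
#' Spearman correlation, within one sample group, between the number of
#' active splice events of each gene and its number of expressed isoforms.
#'
#' @param catalog Event catalog.
#' @param active Logical event x group mask (see [active_event_mask()]).
#' @param isoform_counts Named integer vector gene_id -> expressed-isoform
#'   count in the group.
#' @param group Group label (column of `active`).
#' @return A [spearman_cor()] result list (with `degenerate = TRUE` when a
#'   variable is constant).
#' @export
event_isoform_correlation <- function(catalog, active, isoform_counts,
                                      group) {
  on <- rownames(active)[active[, group]]
  ev_gene <- catalog$gene_id[match(on, catalog$event_id)]
  ev_counts <- table(ev_gene)
  genes <- names(ev_counts)
  iso <- isoform_counts[genes]
  spearman_cor(as.numeric(ev_counts), as.numeric(iso))
}
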