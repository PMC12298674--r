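# Differential splicing: delta-PSI, exact binomial test, gained/lost/DAS
# classification.
#
# An event passing |delta PSI| > dpsi_min and p < alpha is
#   gain  when the control PSI is near 0 or 1 (outside [psi_low, psi_high])
#         while the treatment PSI is intermediate,
#   lost  mirrored (treatment near 0/1, control intermediate),
#   DAS   otherwise (a quantitative shift between intermediate levels).

#' Differential-splicing thresholds
#'
#' @param dpsi_min Minimum |delta PSI| for significance, default 0.20.
#' @param alpha p-value threshold, default 0.05.
#' @param psi_low,psi_high Boundaries of the "intermediate" PSI band used by
#'   the gained/lost classification, defaults 0.05 / 0.95.
#' @return List of thresholds.
#' @export
dse_thresholds <- function(dpsi_min = 0.20, alpha = 0.05,
                           psi_low = 0.05, psi_high = 0.95) {
  stopifnot(psi_low > 0, psi_low < psi_high, psi_high < 1)
  list(dpsi_min = dpsi_min, alpha = alpha,
       psi_low = psi_low, psi_high = psi_high)
}

#' Per-event delta PSI for a contrast
#'
#' Group PSI values are replicate means; events with fewer than `min_reps`
#' defined replicate PSIs in either group are skipped for the contrast.
#'
#' @param psi PSI matrix (events x samples).
#' @param treatment,control Group labels; delta is treatment minus control.
#' @param groups Optional group label per sample column.
#' @param min_reps Minimum defined replicates per group, default 2.
#' @return `data.frame` with `event_id`, `psi_control`, `psi_treatment`,
#'   `delta_psi`.
#' @export
delta_psi <- function(psi, treatment, control, groups = NULL, min_reps = 2) {
  groups <- groups %||% sample_groups(colnames(psi))
  if (!all(c(treatment, control) %in% groups)) {
    stop("unknown contrast label(s): ",
         paste(setdiff(c(treatment, control), groups), collapse = ", "),
         call. = FALSE)
  }
  gm <- group_mean_psi(psi, groups, min_reps = min_reps)
  ok <- !is.na(gm[, treatment]) & !is.na(gm[, control])
  data.frame(event_id = rownames(gm)[ok],
             psi_control = unname(gm[ok, control]),
             psi_treatment = unname(gm[ok, treatment]),
             delta_psi = unname(gm[ok, treatment] - gm[ok, control]),
             stringsAsFactors = FALSE)
}

#' Exact two-sided binomial test for an event
#'
#' Tests the pooled treatment inclusion count `k` out of `n = inc + exc`
#' reads against the null inclusion proportion given by the pooled control
#' PSI (clipped to `[0.01, 0.99]`). Two-sided by summing the probabilities
#' of all outcomes at most as likely as the observed one (with the usual
#' `1 + 1e-7` relative guard against floating-point ties).
#'
#' @param inc_treat,exc_treat Pooled treatment inclusion/exclusion reads.
#' @param psi_control_pooled Null inclusion proportion.
#' @return Two-sided p-value; `NA` when `n = 0`.
#' @export
binomial_test_event <- function(inc_treat, exc_treat, psi_control_pooled) {
  n <- inc_treat + exc_treat
  if (n == 0) return(NA_real_)
  p0 <- min(max(psi_control_pooled, 0.01), 0.99)
  d <- stats::dbinom(0:n, n, p0)
  min(1, sum(d[d <= d[inc_treat + 1] * (1 + 1e-7)]))
}

#' Classify differential-splicing events
#'
#' Vectorised three-way classification of significant events into gained,
#' lost or DAS; non-significant events are `"ns"`.
#'
#' @param psi_control,psi_treatment Group-mean PSI values.
#' @param delta_psi Treatment-minus-control PSI differences.
#' @param p Per-event p-values.
#' @param thresholds See [dse_thresholds()].
#' @return Character vector of categories in
#'   `c("gain", "lost", "DAS", "ns")`.
#' @export
classify_dse <- function(psi_control, psi_treatment, delta_psi, p,
                         thresholds = dse_thresholds()) {
  th <- thresholds
  sig <- abs(delta_psi) > th$dpsi_min & p < th$alpha & !is.na(p)
  extreme_c <- psi_control > th$psi_high | psi_control < th$psi_low
  extreme_t <- psi_treatment > th$psi_high | psi_treatment < th$psi_low
  mid_c <- !extreme_c
  mid_t <- !extreme_t
  out <- rep("ns", length(delta_psi))
  out[sig] <- "DAS"
  out[sig & extreme_c & mid_t] <- "gain"
  out[sig & extreme_t & mid_c] <- "lost"  # disjoint from gain by construction
  out
}

#' Full differential-splicing test for one contrast
#'
#' Combines [delta_psi()] (abundance-based group PSI), the pooled binomial
#' test on inclusion/exclusion read counts and [classify_dse()].
#'
#' @param psi PSI matrix.
#' @param event_counts Event read counts (list of `inclusion`/`exclusion`
#'   matrices).
#' @param treatment,control Group labels.
#' @param groups Optional group label per sample column.
#' @param thresholds See [dse_thresholds()].
#' @param adjust Apply Benjamini-Hochberg correction to the event p-values
#'   before thresholding (off by default; the classification then uses raw
#'   p, matching a raw-p significance rule).
#' @return `data.frame` of DSE records: `event_id`, `contrast`,
#'   `psi_control`, `psi_treatment`, `delta_psi`, `p`, `category`.
#' @export
test_dse <- function(psi, event_counts, treatment, control, groups = NULL,
                     thresholds = dse_thresholds(), adjust = FALSE) {
  dp <- delta_psi(psi, treatment, control, groups)
  groups_ec <- sample_groups(colnames(event_counts$inclusion))
  t_cols <- groups_ec == treatment
  c_cols <- groups_ec == control
  idx <- match(dp$event_id, rownames(event_counts$inclusion))
  if (anyNA(idx)) {
    stop("event counts missing for ", sum(is.na(idx)), " event(s)",
         call. = FALSE)
  }
  inc_t <- rowSums(event_counts$inclusion[idx, t_cols, drop = FALSE])
  exc_t <- rowSums(event_counts$exclusion[idx, t_cols, drop = FALSE])
  inc_c <- rowSums(event_counts$inclusion[idx, c_cols, drop = FALSE])
  exc_c <- rowSums(event_counts$exclusion[idx, c_cols, drop = FALSE])
  p0 <- ifelse(inc_c + exc_c > 0, inc_c / (inc_c + exc_c), NA_real_)
  p <- mapply(function(i, e, q) {
    if (is.na(q)) NA_real_ else binomial_test_event(i, e, q)
  }, inc_t, exc_t, p0)
  if (adjust) p <- stats::p.adjust(p, method = "BH")
  keep <- !is.na(p)
  data.frame(event_id = dp$event_id[keep],
             contrast = paste0(treatment, "vs", control),
             psi_control = dp$psi_control[keep],
             psi_treatment = dp$psi_treatment[keep],
             delta_psi = dp$delta_psi[keep],
             p = unname(p[keep]),
             category = classify_dse(dp$psi_control[keep],
                                     dp$psi_treatment[keep],
                                     dp$delta_psi[keep], p[keep],
                                     thresholds),
             stringsAsFactors = FALSE)
}

#' Composition of significant differential-splicing events
#'
#' @param records DSE records from [test_dse()].
#' @return `data.frame` with `category` (DAS/gain/lost), `count`, `pct`;
#'   percentages sum to 100. Zero rows when no event is significant.
#' @export
summarize_dse_composition <- function(records) {
  sig <- records[records$category != "ns", , drop = FALSE]
  if (nrow(sig) == 0) {
    return(data.frame(category = character(), count = integer(),
                      pct = numeric(), stringsAsFactors = FALSE))
  }
  counts <- table(factor(sig$category, levels = c("DAS", "gain", "lost")))
  data.frame(category = names(counts), count = as.integer(counts),
             pct = 100 * as.integer(counts) / nrow(sig),
             stringsAsFactors = FALSE)
}

#' Count novel isoforms per gene between two groups
#'
#' A transcript is novel in the target group iff it passes the support rule
#' there (at least `min_reads` reads in every target replicate) while every
#' baseline replicate stays below `min_reads`.
#'
#' @param support Transcript support matrix (transcripts x samples).
#' @param tx2gene `data.frame` with `transcript_id`, `gene_id`.
#' @param baseline,target Group labels.
#' @param min_reads Support threshold, default 3.
#' @return List with `novel_transcripts` (ids) and `per_gene_bins`
#'   (`data.frame` of gene counts over bins 1..5, >5).
#' @export
count_novel_isoforms <- function(support, tx2gene, baseline, target,
                                 min_reads = 3) {
  b_cols <- group_columns(support, baseline)
  t_cols <- group_columns(support, target)
  pass_t <- apply(support[, t_cols, drop = FALSE] >= min_reads, 1, all)
  fail_b <- apply(support[, b_cols, drop = FALSE] < min_reads, 1, all)
  novel <- rownames(support)[pass_t & fail_b]
  genes <- tx2gene$gene_id[match(novel, tx2gene$transcript_id)]
  per_gene <- table(genes)
  bins <- if (length(per_gene) == 0) {
    table(factor(character(), levels = COUNT_BINS))
  } else {
    table(factor(bin_counts(as.integer(per_gene)), levels = COUNT_BINS))
  }
  list(novel_transcripts = novel,
       per_gene_bins = data.frame(bin = COUNT_BINS,
                                  n_genes = as.integer(bins),
                                  stringsAsFactors = FALSE))
}
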