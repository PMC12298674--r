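# Differential gene expression with a transparent negative-binomial test:
# median-of-ratios size factors, method-of-moments dispersion, and a Wald
# test on the log2 fold change of normalized group means.

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median ratio of each
#' sample's counts to the per-gene geometric-mean reference, over genes
#' expressed in every sample.
#'
#' @param counts Integer matrix of raw gene counts (genes x samples).
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos)) {
    stop("no gene has nonzero counts in every sample; cannot derive ",
         "size factors", call. = FALSE)
  }
  geo <- exp(rowMeans(log(counts[all_pos, , drop = FALSE])))
  sf <- apply(counts[all_pos, , drop = FALSE], 2, function(col) {
    stats::median(col / geo)
  })
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("degenerate size factors", call. = FALSE)
  }
  sf
}

#' Negative-binomial Wald test for differential expression
#'
#' For each gene the log2 fold change of normalized group means (with
#' pseudocount) is tested against zero with a Wald statistic whose variance
#' comes from the NB mean-variance relation `var = mu + alpha * mu^2`, the
#' dispersion `alpha` estimated per gene by method of moments across groups
#' (floored at 1e-8). p-values are BH-adjusted across tested genes; status
#' is assigned by the fold-change and q-value thresholds.
#'
#' @param counts Raw gene count matrix (genes x samples,
#'   `GROUP_rep<i>` columns).
#' @param treatment,control Group labels; log2FC is treatment over control.
#' @param lfc_min Minimum |log2FC| for a call, default 2.
#' @param alpha q-value threshold, default 0.05.
#' @param pseudocount Stabilizing pseudocount on group means, default 0.5.
#' @param sf Optional precomputed size factors.
#' @return `data.frame` of DEG records: `gene_id`, `contrast`, `base_mean`,
#'   `log2fc`, `p`, `q`, `status` (`up`/`down`/`ns`).
#' @export
test_de <- function(counts, treatment, control, lfc_min = 2, alpha = 0.05,
                    pseudocount = 0.5, sf = NULL) {
  grp <- sample_groups(colnames(counts))
  t_cols <- grp == treatment
  c_cols <- grp == control
  if (sum(t_cols) < 2 || sum(c_cols) < 2) {
    stop("contrast ", treatment, " vs ", control,
         " needs >= 2 replicates per side", call. = FALSE)
  }
  sf <- sf %||% size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  nt <- sum(t_cols); nc <- sum(c_cols)
  m_t <- rowMeans(norm[, t_cols, drop = FALSE])
  m_c <- rowMeans(norm[, c_cols, drop = FALSE])
  v_t <- apply(norm[, t_cols, drop = FALSE], 1, stats::var)
  v_c <- apply(norm[, c_cols, drop = FALSE], 1, stats::var)

  # method-of-moments dispersion, averaged over groups where defined
  disp_of <- function(m, v) ifelse(m > 0, (v - m) / m^2, NA_real_)
  a_t <- disp_of(m_t, v_t)
  a_c <- disp_of(m_c, v_c)
  disp <- rowMeans(cbind(a_t, a_c), na.rm = TRUE)
  disp[is.nan(disp)] <- 0
  disp <- pmin(pmax(disp, 1e-8), 10)

  log2fc <- log2((m_t + pseudocount) / (m_c + pseudocount))
  # delta-method variance of log2 mean under var = mu + alpha mu^2
  se2 <- ((m_t + disp * m_t^2) / nt / (m_t + pseudocount)^2 +
          (m_c + disp * m_c^2) / nc / (m_c + pseudocount)^2) / log(2)^2
  z <- ifelse(se2 > 0, log2fc / sqrt(se2), 0)
  p <- 2 * stats::pnorm(-abs(z))
  p[m_t == 0 & m_c == 0] <- 1
  q <- stats::p.adjust(p, method = "BH")
  status <- rep("ns", nrow(counts))
  status[abs(log2fc) >= lfc_min & q < alpha & log2fc > 0] <- "up"
  status[abs(log2fc) >= lfc_min & q < alpha & log2fc < 0] <- "down"
  data.frame(gene_id = rownames(counts),
             contrast = paste0(treatment, "vs", control),
             base_mean = rowMeans(norm), log2fc = log2fc, p = p, q = q,
             status = status, row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-subgenome DEG and expressed-gene totals
#'
#' Tabulates, for each subgenome, the number of DEGs and of expressed genes
#' (mean normalized count at least `expr_min` across all samples). The
#' resulting 2x2 counts feed [chisq_2x2()].
#'
#' @param degs DEG records from [test_de()].
#' @param counts Raw count matrix used for the test.
#' @param subgenomes Named character vector gene_id -> `"A"`/`"B"`.
#' @param expr_min Expressed-gene threshold on mean normalized counts,
#'   default 1.
#' @param sf Optional precomputed size factors.
#' @return `data.frame` with `subgenome`, `deg`, `expressed`.
#' @export
deg_summary_by_subgenome <- function(degs, counts, subgenomes,
                                     expr_min = 1, sf = NULL) {
  sg <- subgenomes[rownames(counts)]
  if (anyNA(sg)) {
    stop("gene(s) without subgenome label: ",
         paste(utils::head(rownames(counts)[is.na(sg)], 5), collapse = ", "),
         call. = FALSE)
  }
  sf <- sf %||% size_factors(counts)
  norm_mean <- rowMeans(sweep(counts, 2, sf, "/"))
  expressed <- norm_mean >= expr_min
  is_deg <- rownames(counts) %in% degs$gene_id[degs$status != "ns"]
  do.call(rbind, lapply(c("A", "B"), function(s) {
    data.frame(subgenome = s,
               deg = sum(is_deg & expressed & sg == s),
               expressed = sum(expressed & sg == s),
               stringsAsFactors = FALSE)
  }))
}
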