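# PSI quantification and support filters.
#
# PSI for an event is the abundance share of its inclusion isoforms:
#   psi = sum TPM(inclusion) / (sum TPM(inclusion) + sum TPM(exclusion)),
# undefined (NA) when the denominator falls below a small floor. A
# count-based path psi = inc / (inc + exc) backs the binomial test.

PSI_TPM_FLOOR <- 1e-9

#' Filter transcripts by read support
#'
#' A transcript is retained iff it has at least `min_reads` supporting reads
#' in every replicate of at least one sample group (`scope = "any_group"`,
#' the default), or of every group (`scope = "all_groups"`).
#'
#' @param support Numeric matrix of supporting read counts, transcripts x
#'   samples; column names follow `GROUP_rep<i>`.
#' @param min_reads Support threshold (reads), default 3.
#' @param groups Optional group label per column; derived from column names
#'   when `NULL`. Unknown labels error.
#' @param scope `"any_group"` or `"all_groups"`.
#' @return Character vector of retained transcript ids.
#' @export
filter_transcripts_by_support <- function(support, min_reads = 3,
                                          groups = NULL,
                                          scope = c("any_group",
                                                    "all_groups")) {
  scope <- match.arg(scope)
  stopifnot(all(support >= 0))
  groups <- groups %||% sample_groups(colnames(support))
  if (anyNA(groups) || any(!nzchar(groups))) {
    stop("unknown sample labels in support matrix", call. = FALSE)
  }
  pass <- vapply(unique(groups), function(g) {
    apply(support[, groups == g, drop = FALSE] >= min_reads, 1, all)
  }, logical(nrow(support)))
  keep <- if (scope == "any_group") apply(pass, 1, any) else apply(pass, 1, all)
  rownames(support)[keep]
}

#' Restrict an event catalog to a set of retained transcripts
#'
#' Removal cascades: transcripts absent from `keep_tx` are dropped from the
#' inclusion/exclusion sets, and events whose inclusion or exclusion set
#' becomes empty are dropped from the catalog (genes losing all events
#' disappear with them).
#'
#' @param catalog Event catalog.
#' @param keep_tx Character vector of retained transcript ids.
#' @return Pruned event catalog.
#' @export
prune_catalog <- function(catalog, keep_tx) {
  if (nrow(catalog) == 0) return(catalog)
  inc <- lapply(split_ids(catalog$inclusion), intersect, y = keep_tx)
  exc <- lapply(split_ids(catalog$exclusion), intersect, y = keep_tx)
  keep <- lengths(inc) > 0 & lengths(exc) > 0
  out <- catalog[keep, , drop = FALSE]
  out$inclusion <- vapply(inc[keep], paste, "", collapse = ",")
  out$exclusion <- vapply(exc[keep], paste, "", collapse = ",")
  rownames(out) <- NULL
  out
}

#' Filter events by read support
#'
#' An event is discarded iff there exists a sample group in which every
#' replicate has at most `min_reads` total (inclusion + exclusion) reads.
#'
#' @param event_counts Event read counts: list with numeric matrices
#'   `inclusion` and `exclusion` (events x samples, identical dimnames).
#' @param min_reads Support threshold, default 3 (events with exactly 3
#'   reads in every replicate of some group are discarded; 4 retains).
#' @param groups Optional group label per sample column.
#' @return Character vector of retained event ids.
#' @export
filter_events_by_support <- function(event_counts, min_reads = 3,
                                     groups = NULL) {
  tot <- event_counts$inclusion + event_counts$exclusion
  groups <- groups %||% sample_groups(colnames(tot))
  weak <- vapply(unique(groups), function(g) {
    apply(tot[, groups == g, drop = FALSE] <= min_reads, 1, all)
  }, logical(nrow(tot)))
  rownames(tot)[!apply(weak, 1, any)]
}

#' Compute the PSI matrix from isoform abundances
#'
#' @param catalog Event catalog.
#' @param abundance Numeric matrix of isoform abundances (TPM), transcripts
#'   x samples; must cover every transcript referenced by the catalog.
#' @return Numeric matrix events x samples of PSI values in `[0, 1]`, `NA`
#'   where the event's total abundance is below the floor.
#' @export
compute_psi <- function(catalog, abundance) {
  stopifnot(all(abundance >= 0, na.rm = TRUE))
  inc <- split_ids(catalog$inclusion)
  exc <- split_ids(catalog$exclusion)
  missing <- setdiff(unique(unlist(c(inc, exc))), rownames(abundance))
  if (length(missing) > 0) {
    stop("event catalog references unknown transcript(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  psi <- matrix(NA_real_, nrow = nrow(catalog), ncol = ncol(abundance),
                dimnames = list(catalog$event_id, colnames(abundance)))
  for (i in seq_len(nrow(catalog))) {
    inc_sum <- colSums(abundance[inc[[i]], , drop = FALSE])
    exc_sum <- colSums(abundance[exc[[i]], , drop = FALSE])
    tot <- inc_sum + exc_sum
    p <- ifelse(tot < PSI_TPM_FLOOR, NA_real_, inc_sum / tot)
    psi[i, ] <- p
  }
  psi
}

#' Count-based PSI
#'
#' @param event_counts Event read counts (see [filter_events_by_support()]).
#' @return Matrix of `inc / (inc + exc)`, `NA` where no reads.
#' @export
compute_psi_from_counts <- function(event_counts) {
  tot <- event_counts$inclusion + event_counts$exclusion
  out <- event_counts$inclusion / tot
  out[tot == 0] <- NA_real_
  out
}

# Group-mean PSI per event: events x groups matrix (NA-aware means).
group_mean_psi <- function(psi, groups = NULL, min_reps = 1) {
  groups <- groups %||% sample_groups(colnames(psi))
  out <- vapply(unique(groups), function(g) {
    sub <- psi[, groups == g, drop = FALSE]
    m <- rowMeans(sub, na.rm = TRUE)
    m[rowSums(!is.na(sub)) < min_reps] <- NA_real_
    m
  }, numeric(nrow(psi)))
  rownames(out) <- rownames(psi)
  out
}

#' Tally events with intermediate PSI
#'
#' Counts events whose PSI lies strictly between 0 and 1 -- per sample, and
#' per group using the group-mean PSI.
#'
#' @param psi PSI matrix from [compute_psi()].
#' @param groups Optional group label per sample column.
#' @return List with `per_sample` and `per_group` named integer vectors.
#' @export
tally_active_events <- function(psi, groups = NULL) {
  groups <- groups %||% sample_groups(colnames(psi))
  per_sample <- colSums(psi > 0 & psi < 1, na.rm = TRUE)
  gm <- group_mean_psi(psi, groups)
  per_group <- colSums(gm > 0 & gm < 1, na.rm = TRUE)
  list(per_sample = per_sample, per_group = per_group)
}

#' Active-event mask per sample group
#'
#' An event is active in a group when its group-mean PSI lies strictly in
#' `(0, 1)`.
#'
#' @inheritParams tally_active_events
#' @return Logical matrix events x groups.
#' @export
active_event_mask <- function(psi, groups = NULL) {
  gm <- group_mean_psi(psi, groups)
  mask <- gm > 0 & gm < 1
  mask[is.na(mask)] <- FALSE
  mask
}

#' Sample-by-sample PSI correlation
#'
#' Correlation over pairwise-complete PSI values; cells with fewer than
#' `min_complete` complete event pairs are `NA`.
#'
#' @param psi PSI matrix.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_complete Minimum pairwise-complete observations, default 3.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
psi_correlation <- function(psi, method = c("pearson", "spearman"),
                            min_complete = 3) {
  method <- match.arg(method)
  if (ncol(psi) < 2) stop("need at least 2 samples", call. = FALSE)
  n <- ncol(psi)
  out <- diag(1, n)
  dimnames(out) <- list(colnames(psi), colnames(psi))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(psi[, i]) & !is.na(psi[, j])
      r <- if (sum(ok) < min_complete) NA_real_ else {
        stats::cor(psi[ok, i], psi[ok, j], method = method)
      }
      out[i, j] <- out[j, i] <- r
    }
  }
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of group PSI distributions
#'
#' Compares the per-event group-mean PSI distributions of two groups.
#'
#' @param psi PSI matrix.
#' @param group_x,group_y Group labels to compare.
#' @param groups Optional group label per sample column.
#' @param min_n Minimum defined PSI values per group, default 10.
#' @return List with `D` (statistic in `[0, 1]`) and `p` (asymptotic).
#' @export
ks_compare_psi <- function(psi, group_x, group_y, groups = NULL,
                           min_n = 10) {
  gm <- group_mean_psi(psi, groups)
  if (!all(c(group_x, group_y) %in% colnames(gm))) {
    stop("unknown group label", call. = FALSE)
  }
  x <- gm[!is.na(gm[, group_x]), group_x]
  y <- gm[!is.na(gm[, group_y]), group_y]
  if (length(x) < min_n || length(y) < min_n) {
    stop("fewer than ", min_n, " defined PSI values in a group",
         call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(x, y))
  list(D = unname(kt$statistic), p = kt$p.value)
}
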