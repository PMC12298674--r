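#' @keywords internal
"_PACKAGE"

#' Derive group labels from sample names
#'
#' Sample columns follow the `GROUP_rep<i>` convention (e.g. `AG_rep1`);
#' the group label is everything before the final `_rep<i>` suffix.
#'
#' @param samples Character vector of sample names.
#' @return Character vector of group labels, same length as `samples`.
#' @export
sample_groups <- function(samples) {
  sub("_rep[0-9]+$", "", samples)
}

# Columns of `x` belonging to `group`; errors on unknown labels.
group_columns <- function(x, group) {
  grp <- sample_groups(colnames(x))
  if (!group %in% grp) {
    stop("unknown sample group: ", group, call. = FALSE)
  }
  which(grp == group)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared bin labels for per-gene event / isoform count histograms.
COUNT_BINS <- c("1", "2", "3", "4", "5", ">5")

bin_counts <- function(n) {
  stopifnot(all(n >= 1))
  ifelse(n > 5, ">5", as.character(n))
}

EVENT_TYPES <- c("IR", "ES", "A5", "A3")
BIAS_CLASSES <- c("A-bias", "B-bias", "balanced", "low-expression")
DSE_CATEGORIES <- c("gain", "lost", "DAS", "ns")
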