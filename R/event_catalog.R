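# Local alternative-splicing event enumeration.
#
# Four event types are recognised from pairs of isoform structures within a
# gene, in the ioe/SUPPA-like local-event idiom:
#
#   ES  exon skipping          anchor (c1e, as, ae, c2s): a cassette exon
#                              (as, ae) flanked by junctions c1e->as and
#                              ae->c2s versus the direct junction c1e->c2s.
#   IR  intron retention       anchor (x1, c1e, c2s, y2): a retained exon
#                              spanning exactly (x1, y2) versus the spliced
#                              exon pair (x1, c1e), (c2s, y2).
#   A5  alternative donor      two introns sharing the acceptor boundary but
#                              differing at the donor (transcription-proximal)
#                              boundary.
#   A3  alternative acceptor   mirrored at the acceptor boundary.
#
# For A5/A3 the region between the two alternative boundaries must be
# exonic in the inclusion (shorter-intron) transcript: the exon adjacent to
# the shorter intron at the variant side must reach the longer intron's
# boundary. Without this constraint every cassette exon would also fire a
# spurious donor and acceptor event (its skip junction shares one boundary
# with each flanking intron).
#
# For A5/A3 the inclusion form is the shorter intron (more exonic sequence
# retained); for IR the retaining form is the inclusion form. Donor/acceptor
# roles are resolved by strand: on "+" the donor is the intron's left (start)
# boundary, on "-" its right (end) boundary.

event_id_string <- function(gene_id, etype, chrom, anchor, strand) {
  sprintf("%s;%s:%s:%d-%d:%d-%d:%s", gene_id, etype, chrom,
          anchor[1], anchor[2], anchor[3], anchor[4], strand)
}

# Intron matrix (start, end) of an exon chain; 0 rows for single-exon chains.
tx_introns <- function(exons) {
  n <- nrow(exons)
  if (n < 2) return(matrix(numeric(0), ncol = 2))
  cbind(exons[-n, 2], exons[-1, 1])
}

#' Enumerate local alternative-splicing events
#'
#' Scans each gene's transcript structures for intron-retention (IR),
#' exon-skipping (ES), alternative-donor (A5) and alternative-acceptor (A3)
#' events. Events are deduplicated by `(gene, type, anchor)`; the inclusion
#' and exclusion transcript sets contain every transcript of the gene
#' exhibiting the respective structure. Structurally identical transcripts
#' are collapsed for enumeration but all their identifiers are reported.
#'
#' @param genes Named list of [gene_model()] objects.
#' @param strict_ir Require the retained exon to span exactly the outer
#'   boundaries of the two flanking exons (default). With `FALSE`, any exon
#'   covering the intron and both flank boundaries qualifies, anchored at
#'   the spliced form's outer boundaries.
#' @return An event catalog `data.frame` with columns `event_id`, `gene_id`,
#'   `etype`, `chrom`, `strand`, anchor coordinates `a1..a4` (genomic,
#'   0-based half-open, ascending) and comma-joined `inclusion` /
#'   `exclusion` transcript sets.
#' @export
enumerate_events <- function(genes, strict_ir = TRUE) {
  rows <- lapply(genes, enumerate_gene_events, strict_ir = strict_ir)
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(empty_catalog())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene_id, out$etype, out$a1, out$a2, out$a3, out$a4), ,
      drop = FALSE]
}

empty_catalog <- function() {
  data.frame(event_id = character(), gene_id = character(),
             etype = character(), chrom = character(), strand = character(),
             a1 = numeric(), a2 = numeric(), a3 = numeric(), a4 = numeric(),
             inclusion = character(), exclusion = character(),
             stringsAsFactors = FALSE)
}

enumerate_gene_events <- function(gene, strict_ir = TRUE) {
  txs <- gene$transcripts
  for (tx in txs) validate_transcript(tx)
  if (length(txs) < 2) return(NULL)
  tx_ids <- vapply(txs, `[[`, "", "transcript_id")
  exon_lists <- lapply(txs, `[[`, "exons")

  # Collapse structurally identical transcripts: one representative per
  # structure, but remember every member id.
  struct_key <- vapply(exon_lists, function(ex) paste(t(ex), collapse = ","),
                       "")
  reps <- !duplicated(struct_key)
  members <- split(tx_ids, struct_key)  # structure key -> all member ids
  r_exons <- exon_lists[reps]
  r_keys <- struct_key[reps]
  nr <- length(r_exons)
  if (nr < 2) return(NULL)

  # Per-representative structural feature keys.
  intron_map <- new.env(parent = emptyenv())   # "s:e" -> rep indices
  intron_ext <- new.env(parent = emptyenv())   # "s:e" -> (rep, lstart, rend)
  exon_map <- new.env(parent = emptyenv())
  es_ctx_map <- new.env(parent = emptyenv())   # internal-exon context
  ir_ctx_map <- new.env(parent = emptyenv())   # adjacent-exon-pair context
  add <- function(map, key, i) assign(key, c(map[[key]], i), envir = map)
  for (i in seq_len(nr)) {
    ex <- r_exons[[i]]
    n <- nrow(ex)
    for (j in seq_len(n)) add(exon_map, paste(ex[j, ], collapse = ":"), i)
    if (n >= 2) {
      for (j in seq_len(n - 1)) {
        ikey <- paste(ex[j, 2], ex[j + 1, 1], sep = ":")
        add(intron_map, ikey, i)
        assign(ikey, rbind(intron_ext[[ikey]],
                           c(i, ex[j, 1], ex[j + 1, 2])),
               envir = intron_ext)
        add(ir_ctx_map,
            paste(ex[j, 1], ex[j, 2], ex[j + 1, 1], ex[j + 1, 2], sep = ":"),
            i)
      }
    }
    if (n >= 3) {
      for (j in 2:(n - 1)) {
        add(es_ctx_map,
            paste(ex[j - 1, 2], ex[j, 1], ex[j, 2], ex[j + 1, 1], sep = ":"),
            i)
      }
    }
  }
  get0e <- function(map, key) map[[key]] %||% integer(0)
  ids_of <- function(rep_idx) {
    sort(unique(unlist(members[r_keys[rep_idx]], use.names = FALSE)))
  }

  events <- new.env(parent = emptyenv())
  emit <- function(etype, anchor, inc_reps, exc_reps) {
    inc <- ids_of(inc_reps)
    exc <- ids_of(exc_reps)
    if (length(inc) == 0 || length(exc) == 0) return(invisible())
    key <- paste(etype, paste(anchor, collapse = ":"), sep = "|")
    events[[key]] <- list(etype = etype, anchor = anchor,
                          inclusion = inc, exclusion = exc)
    invisible()
  }

  for (i in seq_len(nr)) {
    ex <- r_exons[[i]]
    n <- nrow(ex)
    # ES: internal exon of i skipped by a direct junction elsewhere.
    if (n >= 3) {
      for (j in 2:(n - 1)) {
        c1e <- ex[j - 1, 2]; as_ <- ex[j, 1]; ae <- ex[j, 2]
        c2s <- ex[j + 1, 1]
        skip <- get0e(intron_map, paste(c1e, c2s, sep = ":"))
        if (length(skip) > 0) {
          ctx <- get0e(es_ctx_map, paste(c1e, as_, ae, c2s, sep = ":"))
          emit("ES", c(c1e, as_, ae, c2s), ctx, skip)
        }
      }
    }
    # IR: intron of i retained by a single exon elsewhere.
    if (n >= 2) {
      for (j in seq_len(n - 1)) {
        x1 <- ex[j, 1]; c1e <- ex[j, 2]; c2s <- ex[j + 1, 1]; y2 <- ex[j + 1, 2]
        if (strict_ir) {
          ret <- get0e(exon_map, paste(x1, y2, sep = ":"))
        } else {
          ret <- which(vapply(seq_len(nr), function(k) {
            eo <- r_exons[[k]]
            any(eo[, 1] <= x1 & eo[, 2] >= y2)
          }, TRUE))
        }
        if (length(ret) > 0) {
          spl <- get0e(ir_ctx_map, paste(x1, c1e, c2s, y2, sep = ":"))
          emit("IR", c(x1, c1e, c2s, y2), ret, spl)
        }
      }
    }
  }

  # A5/A3: pairs of distinct introns sharing exactly one boundary, where
  # the variant region is exonic in the shorter-intron transcript.
  intron_keys <- ls(intron_map)
  if (length(intron_keys) >= 2) {
    im <- do.call(rbind, lapply(strsplit(intron_keys, ":"), as.numeric))
    for (u in seq_len(nrow(im) - 1)) {
      for (v in (u + 1):nrow(im)) {
        same_start <- im[u, 1] == im[v, 1]
        same_end <- im[u, 2] == im[v, 2]
        if (same_start == same_end) next  # zero or two shared boundaries
        len_u <- im[u, 2] - im[u, 1]
        len_v <- im[v, 2] - im[v, 1]
        shorter <- if (len_u <= len_v) u else v
        longer <- if (len_u <= len_v) v else u
        ext <- intron_ext[[intron_keys[shorter]]]
        if (same_end) {
          # alternative left boundary; inclusion exon must reach back to
          # the longer intron's start
          etype <- if (gene$strand == "+") "A5" else "A3"
          anchor <- c(im[longer, 1], im[shorter, 1], im[u, 2], im[v, 2])
          inc_reps <- ext[ext[, 2] <= im[longer, 1], 1]
        } else {
          # alternative right boundary; inclusion exon must reach forward
          # to the longer intron's end
          etype <- if (gene$strand == "+") "A3" else "A5"
          anchor <- c(im[u, 1], im[v, 1], im[shorter, 2], im[longer, 2])
          inc_reps <- ext[ext[, 3] >= im[longer, 2], 1]
        }
        if (length(inc_reps) == 0) next
        emit(etype, anchor, inc_reps,
             get0e(intron_map, intron_keys[longer]))
      }
    }
  }

  keys <- ls(events)
  if (length(keys) == 0) return(NULL)
  do.call(rbind, lapply(keys, function(k) {
    ev <- events[[k]]
    data.frame(
      event_id = event_id_string(gene$gene_id, ev$etype, gene$chrom,
                                 ev$anchor, gene$strand),
      gene_id = gene$gene_id, etype = ev$etype, chrom = gene$chrom,
      strand = gene$strand,
      a1 = ev$anchor[1], a2 = ev$anchor[2], a3 = ev$anchor[3],
      a4 = ev$anchor[4],
      inclusion = paste(ev$inclusion, collapse = ","),
      exclusion = paste(ev$exclusion, collapse = ","),
      stringsAsFactors = FALSE)
  }))
}

split_ids <- function(x) strsplit(x, ",", fixed = TRUE)

#' Per-group event-type frequency summary
#'
#' @param catalog Event catalog from [enumerate_events()].
#' @param active Logical matrix (events x groups, rownames = `event_id`)
#'   flagging which events are active in each group; see
#'   [active_event_mask()]. `NULL` counts every event once under group
#'   `"all"`.
#' @return `data.frame` with `group`, `etype`, `count`, `pct`. Percentages
#'   are `NA` for groups with zero active events.
#' @export
summarize_event_frequencies <- function(catalog, active = NULL) {
  if (nrow(catalog) == 0) {
    return(data.frame(group = character(), etype = character(),
                      count = integer(), pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(active)) {
    active <- matrix(TRUE, nrow = nrow(catalog), ncol = 1,
                     dimnames = list(catalog$event_id, "all"))
  }
  stopifnot(setequal(rownames(active), catalog$event_id))
  etype <- catalog$etype[match(rownames(active), catalog$event_id)]
  out <- do.call(rbind, lapply(colnames(active), function(g) {
    counts <- vapply(EVENT_TYPES, function(ty) {
      sum(active[etype == ty, g])
    }, 0L)
    tot <- sum(counts)
    data.frame(group = g, etype = EVENT_TYPES, count = as.integer(counts),
               pct = if (tot > 0) 100 * counts / tot else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Events-per-gene histogram
#'
#' Counts, per group and per event type (plus the overall `"all"` class),
#' how many active genes carry 1, 2, 3, 4, 5 or more than 5 active events.
#'
#' @inheritParams summarize_event_frequencies
#' @return `data.frame` with `group`, `etype`, `bin`, `n_genes`.
#' @export
events_per_gene_distribution <- function(catalog, active = NULL) {
  if (nrow(catalog) == 0) {
    return(data.frame(group = character(), etype = character(),
                      bin = character(), n_genes = integer(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(active)) {
    active <- matrix(TRUE, nrow = nrow(catalog), ncol = 1,
                     dimnames = list(catalog$event_id, "all"))
  }
  idx <- match(rownames(active), catalog$event_id)
  gene <- catalog$gene_id[idx]
  etype <- catalog$etype[idx]
  out <- list()
  for (g in colnames(active)) {
    on <- active[, g]
    for (ty in c("all", EVENT_TYPES)) {
      sel <- on & (ty == "all" | etype == ty)
      if (!any(sel)) next
      per_gene <- table(gene[sel])
      bins <- table(factor(bin_counts(as.integer(per_gene)),
                           levels = COUNT_BINS))
      out[[length(out) + 1L]] <- data.frame(
        group = g, etype = ty, bin = COUNT_BINS,
        n_genes = as.integer(bins), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Aggregate events by chromosome, subgenome and genomic bin
#'
#' @inheritParams summarize_event_frequencies
#' @param bin_size Genomic bin width in bases; events are binned by their
#'   leftmost anchor coordinate.
#' @return List with elements `by_chromosome`, `by_subgenome` and `by_bin`
#'   (`data.frame`s of per-etype counts; `by_*` include per-group rows when
#'   a mask is supplied).
#' @export
aggregate_events <- function(catalog, active = NULL, bin_size = 1e6) {
  stopifnot(bin_size > 0)
  if (nrow(catalog) == 0) {
    empty <- data.frame(group = character(), etype = character(),
                        stringsAsFactors = FALSE)
    return(list(by_chromosome = empty, by_subgenome = empty, by_bin = empty))
  }
  subgenome_of(catalog$chrom)  # errors on unlabelled chromosomes
  if (is.null(active)) {
    active <- matrix(TRUE, nrow = nrow(catalog), ncol = 1,
                     dimnames = list(catalog$event_id, "all"))
  }
  idx <- match(rownames(active), catalog$event_id)
  chrom <- catalog$chrom[idx]
  etype <- catalog$etype[idx]
  sg <- subgenome_of(chrom)
  bin <- floor(catalog$a1[idx] / bin_size)

  tab <- function(keys, keyname) {
    out <- list()
    for (g in colnames(active)) {
      on <- active[, g]
      if (!any(on)) next
      t2 <- as.data.frame(table(key = keys[on], etype = etype[on]),
                          stringsAsFactors = FALSE)
      t2 <- t2[t2$Freq > 0, , drop = FALSE]
      t2 <- data.frame(group = g, t2, stringsAsFactors = FALSE)
      names(t2) <- c("group", keyname, "etype", "count")
      out[[length(out) + 1L]] <- t2
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  }
  list(by_chromosome = tab(chrom, "chrom"),
       by_subgenome = tab(sg, "subgenome"),
       by_bin = tab(paste(chrom, bin, sep = ":"), "bin"))
}

#' Write an event catalog as an ioe-like TSV
#'
#' @param catalog Event catalog.
#' @param path Output path.
#' @export
write_catalog_tsv <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an event catalog TSV written by [write_catalog_tsv()]
#'
#' @param path Input path.
#' @export
read_catalog_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
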