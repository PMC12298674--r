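# Independent brute-force oracles and random-structure generators used
# across the suite. The event oracle tests every ordered transcript pair
# against the textual event definitions, independently of the catalog
# implementation's index-based scan.

`%||%` <- function(a, b) if (is.null(a)) b else a

# unique (gene, type, anchor) triples from an event catalog data.frame
catalog_triples <- function(catalog) {
  if (nrow(catalog) == 0) return(character())
  sort(unique(paste(catalog$gene_id, catalog$etype,
                    paste(catalog$a1, catalog$a2, catalog$a3, catalog$a4,
                          sep = ":"), sep = "|")))
}

# brute-force pairwise enumeration of (gene, type, anchor) triples
oracle_event_triples <- function(gene) {
  txs <- gene$transcripts
  out <- character()
  emit <- function(etype, anchor) {
    out <<- c(out, paste(gene$gene_id, etype,
                         paste(anchor, collapse = ":"), sep = "|"))
  }
  for (t1 in txs) {
    for (t2 in txs) {
      if (t1$transcript_id == t2$transcript_id) next
      e1 <- t1$exons; e2 <- t2$exons
      # ES: t1 carries the cassette exon, t2 the direct skip junction
      if (nrow(e1) >= 3 && nrow(e2) >= 2) {
        for (j in 2:(nrow(e1) - 1)) {
          c1e <- e1[j - 1, 2]; as_ <- e1[j, 1]
          ae <- e1[j, 2]; c2s <- e1[j + 1, 1]
          for (k in seq_len(nrow(e2) - 1)) {
            if (e2[k, 2] == c1e && e2[k + 1, 1] == c2s) {
              emit("ES", c(c1e, as_, ae, c2s))
            }
          }
        }
      }
      # IR: t1 retains (single exon spanning exactly), t2 splices
      if (nrow(e2) >= 2) {
        for (k in seq_len(nrow(e2) - 1)) {
          x1 <- e2[k, 1]; c1e <- e2[k, 2]
          c2s <- e2[k + 1, 1]; y2 <- e2[k + 1, 2]
          if (any(e1[, 1] == x1 & e1[, 2] == y2)) {
            emit("IR", c(x1, c1e, c2s, y2))
          }
        }
      }
      # A5/A3: t1 holds the shorter intron; its adjacent exon must be
      # exonic across the variant region
      if (nrow(e1) >= 2 && nrow(e2) >= 2) {
        for (a in seq_len(nrow(e1) - 1)) {
          for (b in seq_len(nrow(e2) - 1)) {
            s1 <- e1[a, 2]; en1 <- e1[a + 1, 1]
            s2 <- e2[b, 2]; en2 <- e2[b + 1, 1]
            if (s1 == s2 && en1 == en2) next
            if ((en1 - s1) >= (en2 - s2)) next  # t1 must be shorter
            if (en1 == en2) {
              # variant left boundary
              if (e1[a, 1] <= s2) {
                emit(if (gene$strand == "+") "A5" else "A3",
                     c(min(s1, s2), max(s1, s2), en1, en2))
              }
            } else if (s1 == s2) {
              # variant right boundary
              if (e1[a + 1, 2] >= en2) {
                emit(if (gene$strand == "+") "A3" else "A5",
                     c(s1, s2, min(en1, en2), max(en1, en2)))
              }
            }
          }
        }
      }
    }
  }
  sort(unique(out))
}

int_between <- function(lo, hi) {
  if (hi < lo) return(NULL)
  seq(lo, hi)[sample.int(hi - lo + 1, 1)]
}

# random multi-isoform gene: a base exon chain perturbed per transcript by
# exon skips, intron retentions and alternative boundary shifts
random_gene <- function(gid, chrom = NULL, strand = NULL) {
  chrom <- chrom %||% sample(c("chr01A", "chr02B"), 1)
  strand <- strand %||% sample(c("+", "-"), 1)
  n_ex <- sample(2:8, 1)
  width <- sample(50:200, n_ex, replace = TRUE)
  gap <- sample(50:150, max(n_ex - 1, 1), replace = TRUE)
  starts <- cumsum(c(0, (width[-n_ex] + gap[seq_len(n_ex - 1)])))
  base <- cbind(starts, starts + width)
  n_tx <- sample(2:5, 1)
  txs <- vector("list", n_tx)
  for (t in seq_len(n_tx)) {
    ex <- base
    for (i in seq_len(sample(0:3, 1))) {
      n <- nrow(ex)
      op <- sample(c("skip", "retain", "alt_end", "alt_start", "none"), 1)
      if (op == "skip" && n >= 3) {
        ex <- ex[-sample(2:(n - 1), 1), , drop = FALSE]
      } else if (op == "retain" && n >= 2) {
        j <- if (n == 2) 1 else sample(seq_len(n - 1), 1)
        ex[j, 2] <- ex[j + 1, 2]
        ex <- ex[-(j + 1), , drop = FALSE]
      } else if (op == "alt_end" && n >= 2) {
        j <- if (n == 2) 1 else sample(seq_len(n - 1), 1)
        v <- int_between(ex[j, 1] + 1, ex[j + 1, 1] - 1)
        if (!is.null(v)) ex[j, 2] <- v
      } else if (op == "alt_start" && n >= 2) {
        j <- if (n == 2) 1 else sample(seq_len(n - 1), 1)
        v <- int_between(ex[j, 2] + 1, ex[j + 1, 2] - 1)
        if (!is.null(v)) ex[j + 1, 1] <- v
      }
    }
    txs[[t]] <- transcript_model(paste0(gid, ".t", t), gid, chrom, strand,
                                 ex)
  }
  gene_model(gid, chrom, strand, txs)
}

# reflect a gene's coordinates (x -> span - x) and flip its strand
reflect_gene <- function(gene, span) {
  txs <- lapply(gene$transcripts, function(tx) {
    ex <- cbind(span - tx$exons[, 2], span - tx$exons[, 1])
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    transcript_model(tx$transcript_id, tx$gene_id, tx$chrom,
                     if (tx$strand == "+") "-" else "+", ex)
  })
  gene_model(gene$gene_id, gene$chrom,
             if (gene$strand == "+") "-" else "+", txs)
}

# all permutations of 1..n as a matrix (rows are permutations)
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# sample matrix with GROUP_rep<i> columns
named_sample_matrix <- function(values, groups, reps, rownames_) {
  samples <- as.vector(vapply(groups, function(g) {
    paste0(g, "_rep", seq_len(reps))
  }, character(reps)))
  matrix(values, nrow = length(rownames_), ncol = length(samples),
         dimnames = list(rownames_, samples))
}

# synthetic catalog data.frame built directly (no gene models needed)
make_catalog <- function(etypes, genes = NULL, chrom = "chr01A") {
  n <- length(etypes)
  genes <- genes %||% sprintf("g%03d", seq_len(n))
  a1 <- seq_len(n) * 1000
  data.frame(
    event_id = sprintf("%s;%s:%s:%d-%d:%d-%d:+", genes, etypes, chrom,
                       a1, a1 + 100, a1 + 200, a1 + 300),
    gene_id = genes, etype = etypes, chrom = chrom, strand = "+",
    a1 = a1, a2 = a1 + 100, a3 = a1 + 200, a4 = a1 + 300,
    inclusion = paste0(genes, ".t1"), exclusion = paste0(genes, ".t2"),
    stringsAsFactors = FALSE)
}
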