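# Independent brute-force oracles used across the suite.
#
# The per-base-pair attribution oracle re-derives segment ownership literally
# (one base pair at a time) from the raw element spans, and the oracle
# classifier rebuilds every read's hit sets from those per-bp maps and
# re-states the category decision table.  Both are deliberately naive and
# share no code with the streaming implementation.

library(data.table)

# winner among elements covering one bp: most deeply nested span, then
# earlier start, then longer, then lexicographically smaller id
.oracle_winner <- function(el, covering) {
  if (length(covering) == 0L) return(NA_integer_)
  if (length(covering) == 1L) return(covering)
  s <- el$start[covering]; e <- el$end[covering]; id <- el$element_id[covering]
  depth <- vapply(seq_along(covering), function(i)
    sum(s <= s[i] & e[i] <= e & !(s == s[i] & e == e[i])), 0L)
  covering[order(-depth, s, -(e - s), id)][1L]
}

# per-bp element owner (row index into el, NA when unowned) after exon
# masking, one vector per chromosome
oracle_owner_maps <- function(el, exons, chrom_lens) {
  maps <- lapply(names(chrom_lens), function(ch) {
    len <- chrom_lens[[ch]]
    own <- rep(NA_integer_, len)
    rows <- which(el$chrom == ch)
    if (length(rows)) {
      cov <- matrix(FALSE, length(rows), len)
      for (k in seq_along(rows))
        cov[k, el$start[rows[k]]:el$end[rows[k]]] <- TRUE
      for (bp in seq_len(len)) {
        hit <- rows[cov[, bp]]
        if (length(hit)) own[bp] <- .oracle_winner(el, hit)
      }
    }
    erows <- which(exons$chrom == ch)
    for (k in erows) own[exons$start[k]:exons$end[k]] <- NA_integer_
    own
  })
  names(maps) <- names(chrom_lens)
  maps
}

# per-bp gene ids per chromosome (list of character vectors is overkill;
# genes rarely overlap in the random generator, but handle it anyway)
oracle_gene_hits <- function(exons, ch, bps) {
  unique(unlist(lapply(bps, function(bp)
    exons$gene_id[exons$chrom == ch & exons$start <= bp & exons$end >= bp])))
}

# literal re-statement of the category decision table
oracle_decide <- function(n_hits, genes, elements, families) {
  ng <- length(genes); nf <- length(families)
  if (ng == 0L && nf == 0L) return("unassigned")
  if (nf > 1L) return("unassigned")
  if (n_hits == 1L) {
    if (nf == 0L) return(if (ng == 1L) "gene_unique" else "unassigned")
    if (ng == 0L) return("u_te.fam")
    return("u_te.g")
  }
  if (nf == 0L) return("unassigned")     # multi-mapper, genes only
  if (ng == 0L) return("m_te.fam")
  "m_te.g"
}

# classify a block table (read_id, chrom, start, end, n_hits) per-bp
oracle_classify <- function(blocks, el, exons, chrom_lens) {
  own <- oracle_owner_maps(el, exons, chrom_lens)
  out <- blocks[, {
    gset <- character(0); eset <- integer(0)
    for (k in seq_len(.N)) {
      bps <- start[k]:end[k]
      gset <- union(gset, oracle_gene_hits(exons, chrom[k], bps))
      o <- own[[chrom[k]]][bps]
      eset <- union(eset, o[!is.na(o)])
    }
    fams <- unique(el$family[eset])
    cat <- oracle_decide(n_hits[1L], gset, eset, fams)
    tgt <- if (cat == "gene_unique") gset
           else if (cat %in% c("u_te.fam", "m_te.fam", "u_te.g", "m_te.g"))
             fams else NA_character_
    .(category = cat, target = tgt[1L])
  }, by = read_id]
  setorder(out, read_id)
  out
}

# random annotation sets exercising nesting and partial overlap
random_annotation <- function(seed, chrom_len = 800L, n_elements = 10L,
                              n_genes = 2L, n_chroms = 1L) {
  set.seed(seed)
  chroms <- setNames(rep(chrom_len, n_chroms), paste0("chr", seq_len(n_chroms)))
  fams <- c("RLC00001", "RLG00002", "DTA00003", "DHH00004")
  n_el <- sample.int(n_elements, 1L)
  el <- data.table(
    element_id = sprintf("E%02d", seq_len(n_el)),
    family = sample(fams, n_el, replace = TRUE),
    chrom = sample(names(chroms), n_el, replace = TRUE),
    start = 0L, end = 0L, strand = "+")
  for (i in seq_len(n_el)) {
    len <- sample(20:200, 1L)
    if (i > 1L && runif(1) < 0.4) {           # nest inside an earlier element
      host <- el[sample.int(i - 1L, 1L)]
      hl <- host$end - host$start + 1L
      if (hl > len + 2L) {
        el$chrom[i] <- host$chrom
        el$start[i] <- host$start + sample.int(hl - len - 1L, 1L)
        el$end[i] <- el$start[i] + len - 1L
        next
      }
    }
    el$start[i] <- sample.int(chrom_len - len, 1L)
    el$end[i] <- el$start[i] + len - 1L
  }
  el[, te_order := te_order(family)]
  setcolorder(el, c("element_id", "family", "te_order", "chrom", "start",
                    "end", "strand"))
  ng <- sample.int(n_genes + 1L, 1L) - 1L
  if (ng > 0L) {
    g <- data.table(gene_id = sprintf("G%02d", seq_len(ng)),
                    chrom = sample(names(chroms), ng, replace = TRUE),
                    start = 0L, end = 0L, strand = "+")
    ex <- vector("list", ng)
    for (i in seq_len(ng)) {
      len <- sample(80:250, 1L)
      g$start[i] <- sample.int(chrom_len - len, 1L)
      g$end[i] <- g$start[i] + len - 1L
      mid <- (g$start[i] + g$end[i]) %/% 2L
      ex[[i]] <- data.table(gene_id = g$gene_id[i], chrom = g$chrom[i],
                            start = c(g$start[i], mid + 10L),
                            end = c(mid - 10L, g$end[i]))
      ex[[i]] <- ex[[i]][end >= start]
    }
    genes <- list(genes = g, exons = rbindlist(ex))
  } else {
    genes <- list(genes = data.table(gene_id = character(), chrom = character(),
                                     start = integer(), end = integer(),
                                     strand = character()),
                  exons = data.table(gene_id = character(), chrom = character(),
                                     start = integer(), end = integer()))
  }
  list(elements = el, genes = genes, chrom_lens = chroms)
}

# random alignment block tables (not truth-guided: blocks land anywhere)
random_blocks <- function(ann, n_reads, seed) {
  set.seed(seed)
  rows <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    k <- sample(c(1L, 1L, 2L, 3L), 1L)
    ch <- sample(names(ann$chrom_lens), k, replace = TRUE)
    len <- sample(15:50, 1L)
    st <- vapply(ch, function(c2)
      sample.int(ann$chrom_lens[[c2]] - len, 1L), 0L)
    rows[[i]] <- data.table(read_id = sprintf("q%05d", i), chrom = ch,
                            start = as.integer(st),
                            end = as.integer(st + len - 1L),
                            aln = seq_len(k), n_hits = k)
  }
  rbindlist(rows)
}

# write a block table as a SAM file (NH tags, secondary flags)
blocks_to_sam <- function(blocks, chrom_lens, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(chrom_lens), "\tLN:",
                  unname(chrom_lens) + 10L))
  b <- copy(blocks)
  b[, flag := fifelse(aln == 1L, 0L, 256L)]
  body <- b[, paste(read_id, flag, chrom, start, 255L,
                    paste0(end - start + 1L, "M"), "*", 0L, 0L, "*", "*",
                    paste0("NH:i:", n_hits), sep = "\t")]
  writeLines(c(hdr, body), path)
  path
}

# literal BH step-up oracle
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  padj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[o[j]] / j, 0)
    padj[o[i]] <- min(1, min(vals))
  }
  padj
}

# a tiny handcrafted index used by several classification tests:
#   chr1: gene g1 with exons 1001-1200 and 1501-1700
#         TE tIn (RLC00010) at 1601-1900: overlaps exon 2, segment 1701-1900
#         TE tIn2 (RLC00010) at 6001-6200: second member of the in-gene family
#         TE tA1/tA2 (RLG00020) at 3001-3200 / 4001-4200
#         TE tB1 (DTA00030) at 5001-5200
#   chr2: TE tC1 (RLC00040) at 101-300
tiny_index <- function() {
  el <- data.table(
    element_id = c("tIn", "tIn2", "tA1", "tA2", "tB1", "tC1"),
    family = c("RLC00010", "RLC00010", "RLG00020", "RLG00020", "DTA00030",
               "RLC00040"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(1601L, 6001L, 3001L, 4001L, 5001L, 101L),
    end = c(1900L, 6200L, 3200L, 4200L, 5200L, 300L),
    strand = "+")
  el[, te_order := te_order(family)]
  genes <- list(
    genes = data.table(gene_id = "g1", chrom = "chr1", start = 1001L,
                       end = 1700L, strand = "+"),
    exons = data.table(gene_id = "g1", chrom = "chr1",
                       start = c(1001L, 1501L), end = c(1200L, 1700L)))
  seg <- subtract_exons(disjoin_te_annotations(el), genes$exons)
  build_annotation_index(seg, el, genes, c("chr1", "chr2"))
}

# block-table constructor for readable classification tests
mk_read <- function(read_id, chrom, start, end) {
  data.table(read_id = read_id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), aln = seq_along(start),
             n_hits = length(start))
}
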