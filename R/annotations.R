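# Annotation layer: parse TE / gene GFF3, disjoin nested TE spans, mask exons,
# and build the merged interval index that read classification queries.
#
# All coordinates are GFF3-style: 1-based, fully closed intervals.  SAM input
# (also 1-based) needs no shifting; converters live at the alignment boundary.

TE_ORDER_PREFIX <- c(RL = "LTR", DT = "TIR", DH = "Helitron",
                     RI = "LINE", RS = "SINE")

#' Decode TE order from a family code
#'
#' Family codes carry a three-letter order/superfamily prefix
#' (e.g. `RLG00001` is an LTR Gypsy family, `DTA...` a TIR hAT family,
#' `DHH...` a Helitron).  The order is a deterministic function of the first
#' two letters: `RL` = LTR, `DT` = TIR, `DH` = Helitron, `RI` = LINE,
#' `RS` = SINE.
#'
#' @param family Character vector of family codes.
#' @return Character vector of orders; `"Unknown"` (with a warning) for
#'   prefixes outside the table.
#' @examples
#' te_order(c("RLG00001", "DTA00123", "DHH00042"))
#' @export
te_order <- function(family) {
  pref <- substr(family, 1L, 2L)
  ord <- unname(TE_ORDER_PREFIX[pref])
  bad <- is.na(ord) & !is.na(family)
  if (any(bad)) {
    warning("unknown TE order prefix for famil",
            if (sum(bad) > 1L) "ies: " else "y: ",
            paste(unique(family[bad]), collapse = ", "))
    ord[bad] <- "Unknown"
  }
  ord
}

# Light structural validation so malformed lines fail with a line number;
# rtracklayer does the real parsing afterwards.
validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L)
      stop("GFF3 parse error at line ", i, ": expected 9 tab-separated fields, got ",
           length(f), call. = FALSE)
    s <- suppressWarnings(as.integer(f[4L])); e <- suppressWarnings(as.integer(f[5L]))
    if (is.na(s) || is.na(e) || s < 1L || e < s)
      stop("GFF3 parse error at line ", i, ": invalid coordinates '",
           f[4L], "'..'", f[5L], "'", call. = FALSE)
  }
  invisible(length(body))
}

#' Parse a structural TE annotation (GFF3)
#'
#' Each record must carry an element identifier (`ID` attribute) and a family
#' code, looked up first in `family_attribute` and, failing that, parsed from
#' the leading family-code prefix of the element ID (e.g.
#' `RLG00001B73v400001` belongs to family `RLG00001`).
#'
#' @param path Path to a GFF3 file of TE spans (1-based inclusive).
#' @param family_attribute GFF3 attribute holding the family code
#'   (default `"Name"`).
#' @return A `data.table` with columns `element_id`, `family`, `te_order`,
#'   `chrom`, `start`, `end`, `strand` — one row per element.
#' @export
parse_te_gff <- function(path, family_attribute = "Name") {
  validate_gff3_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L)
    return(data.table(element_id = character(), family = character(),
                      te_order = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character()))
  md <- mcols(gr)
  id <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  if (anyNA(id) || any(!nzchar(id)))
    stop("TE records without an ID attribute at GFF3 record(s): ",
         paste(head(which(is.na(id) | !nzchar(id)), 5L), collapse = ", "))
  fam <- if (family_attribute %in% names(md)) as.character(md[[family_attribute]])
         else rep(NA_character_, length(gr))
  need <- is.na(fam) | !nzchar(fam)
  if (any(need)) {
    from_id <- regmatches(id[need], regexpr("^[A-Z]{3}[0-9]{5}", id[need]))
    got <- attr(regexpr("^[A-Z]{3}[0-9]{5}", id[need]), "match.length") > 0
    if (!all(got))
      stop("missing family code for element(s): ",
           paste(head(id[need][!got], 5L), collapse = ", "))
    fam[need] <- from_id
  }
  out <- data.table(
    element_id = id, family = fam, te_order = te_order(fam),
    chrom = as.character(seqnames(gr)),
    start = start(gr), end = end(gr),
    strand = as.character(strand(gr)))
  if (anyDuplicated(out$element_id))
    stop("duplicated element IDs: ",
         paste(head(unique(out$element_id[duplicated(out$element_id)]), 5L),
               collapse = ", "))
  out[]
}

#' Parse a gene model annotation (GFF3)
#'
#' Keeps gene spans and their exons; exons are merged (reduced) per gene so
#' the exon list is sorted and non-overlapping.  Exons are attached to genes
#' through the `Parent` chain (exon -> mRNA -> gene) or directly when exons
#' name the gene as parent.
#'
#' @param path Path to a GFF3 gene annotation.
#' @return A list with `genes` (data.table: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`) and `exons` (data.table: `gene_id`, `chrom`, `start`,
#'   `end`, merged per gene).
#' @export
parse_gene_gff <- function(path) {
  validate_gff3_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  gmask <- typ == "gene"
  genes <- data.table(
    gene_id = as.character(mcols(gr)$ID[gmask]),
    chrom = as.character(seqnames(gr))[gmask],
    start = start(gr)[gmask], end = end(gr)[gmask],
    strand = as.character(strand(gr))[gmask])
  # map transcript IDs up to genes
  tmask <- typ %in% c("mRNA", "transcript")
  tx2gene <- if (any(tmask)) {
    par <- vapply(mcols(gr)$Parent[tmask], function(p) as.character(p)[1L], "")
    setNames(par, as.character(mcols(gr)$ID[tmask]))
  } else character()
  emask <- typ == "exon"
  if (any(emask)) {
    par <- vapply(mcols(gr)$Parent[emask], function(p) as.character(p)[1L], "")
    gid <- ifelse(par %in% names(tx2gene), unname(tx2gene[par]), par)
    ex <- data.table(gene_id = gid,
                     chrom = as.character(seqnames(gr))[emask],
                     start = start(gr)[emask], end = end(gr)[emask])
    ex <- merge_exons(ex)
  } else {
    ex <- data.table(gene_id = character(), chrom = character(),
                     start = integer(), end = integer())
  }
  if (nrow(genes) == 0L && nrow(ex) > 0L)
    genes <- ex[, .(chrom = chrom[1L], start = min(start), end = max(end),
                    strand = "."), by = gene_id]
  list(genes = genes[], exons = ex[])
}

# reduce exons within each gene (sorted, non-overlapping)
merge_exons <- function(exons) {
  if (nrow(exons) == 0L) return(exons)
  gr <- GRanges(exons$chrom, IRanges(exons$start, exons$end))
  grl <- GenomicRanges::split(gr, exons$gene_id)
  red <- reduce(grl)
  ul <- unlist(red, use.names = TRUE)
  out <- data.table(gene_id = names(ul),
                    chrom = as.character(seqnames(ul)),
                    start = start(ul), end = end(ul))
  setorder(out, gene_id, chrom, start)
  out[]
}

# Priority of covering elements for one disjoint piece: most deeply nested
# (span contained in most other covering spans) wins; then earlier start,
# then longer span, then lexicographically smaller ID.  Returns the index
# (into the covering set) of the winner.
.piece_winner <- function(start, end, id) {
  n <- length(start)
  if (n == 1L) return(1L)
  depth <- integer(n)
  for (i in seq_len(n)) {
    inside <- start <= start[i] & end[i] <= end &
      !(start == start[i] & end == end[i])
    depth[i] <- sum(inside)
  }
  ord <- order(-depth, start, -(end - start), id)
  ord[1L]
}

#' Disjoin overlapping / nested TE elements
#'
#' Resolves the structural TE annotation so that every covered base pair is
#' attributed to exactly one element.  A fully nested element claims its own
#' span and punches a hole in its container's segments (recursively for
#' deeper nests).  Partially overlapping, non-nested elements are resolved
#' deterministically: the element with the earlier start keeps the shared
#' base pairs; remaining ties go to the longer span, then to the
#' lexicographically smaller element ID (a warning reports such overlaps).
#'
#' @param elements `data.table` from [parse_te_gff()].
#' @return `data.table` of segments (`element_id`, `family`, `chrom`,
#'   `start`, `end`), pairwise non-overlapping, each within its element span.
#'   Total covered bp is conserved.
#' @export
disjoin_te_annotations <- function(elements) {
  empty <- data.table(element_id = character(), family = character(),
                      chrom = character(), start = integer(), end = integer())
  if (nrow(elements) == 0L) return(empty)
  gr <- GRanges(elements$chrom, IRanges(elements$start, elements$end))
  dj <- disjoin(gr)
  ov <- findOverlaps(dj, gr)
  dt <- data.table(piece = queryHits(ov), elem = subjectHits(ov))
  # warn on genuine partial (non-nested) overlaps
  self <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(self)) {
    qs <- queryHits(self); ss <- subjectHits(self)
    nested <- (elements$start[qs] <= elements$start[ss] &
                 elements$end[ss] <= elements$end[qs]) |
              (elements$start[ss] <= elements$start[qs] &
                 elements$end[qs] <= elements$end[ss])
    if (any(!nested))
      warning(sum(!nested), " partially overlapping non-nested TE pair(s) ",
              "resolved by the earlier-start/longer/ID tie-break")
  }
  win <- dt[, .(elem = elem[.piece_winner(elements$start[elem],
                                          elements$end[elem],
                                          elements$element_id[elem])]),
            by = piece]
  seg <- data.table(
    element_id = elements$element_id[win$elem],
    family = elements$family[win$elem],
    chrom = as.character(seqnames(dj))[win$piece],
    start = start(dj)[win$piece],
    end = end(dj)[win$piece])
  # merge adjacent pieces attributed to the same element
  setorder(seg, element_id, chrom, start)
  seg <- seg[, {
    gap <- c(FALSE, start[-1L] > end[-.N] + 1L) | c(FALSE, chrom[-1L] != chrom[-.N])
    run <- cumsum(gap)
    .(chrom = chrom[!duplicated(run)],
      start = tapply(start, run, min), end = tapply(end, run, max))
  }, by = .(element_id, family)]
  seg[, `:=`(start = as.integer(start), end = as.integer(end))]
  setorder(seg, chrom, start, element_id)
  seg[]
}

#' Mask exonic base pairs out of disjoined TE segments
#'
#' Removes every TE segment base pair that overlaps a (merged) exon; segments
#' may split around internal exons.  Elements whose assignable footprint
#' vanishes are dropped from the segment table but remain in the family
#' registry; the masking report (attribute `"mask_report"`) lists per-element
#' bp before and after.
#'
#' @param segments `data.table` from [disjoin_te_annotations()].
#' @param exons `data.table` of merged exons (`gene_id`, `chrom`, `start`,
#'   `end`); an empty table is a no-op.
#' @return Masked segment `data.table` with a `"mask_report"` attribute.
#' @export
subtract_exons <- function(segments, exons) {
  if (nrow(segments) == 0L || nrow(exons) == 0L) {
    rep0 <- segments[, .(bp_before = sum(end - start + 1L)), by = element_id]
    rep0[, bp_after := bp_before]
    setattr(segments, "mask_report", rep0[])
    return(segments)
  }
  seg_gr <- GRanges(segments$chrom, IRanges(segments$start, segments$end))
  ex_gr <- reduce(GRanges(exons$chrom, IRanges(exons$start, exons$end)))
  kept <- GenomicRanges::subtract(seg_gr, ex_gr, ignore.strand = TRUE)
  lens <- lengths(kept)
  ul <- unlist(kept)
  out <- data.table(
    element_id = rep(segments$element_id, lens),
    family = rep(segments$family, lens),
    chrom = as.character(seqnames(ul)),
    start = start(ul), end = end(ul))
  before <- segments[, .(bp_before = sum(end - start + 1L)), by = element_id]
  after <- out[, .(bp_after = sum(end - start + 1L)), by = element_id]
  rep <- merge(before, after, by = "element_id", all.x = TRUE)
  rep[is.na(bp_after), bp_after := 0L]
  setorder(out, chrom, start, element_id)
  setattr(out, "mask_report", rep[])
  out[]
}

#' Build the merged gene/TE annotation index
#'
#' Combines exon-masked TE segments and merged gene exons into one
#' per-chromosome interval index used by the read classifier.  Features on
#' sequences outside `chrom_allowlist` (e.g. unplaced contigs) are dropped.
#'
#' @param segments Exon-masked TE segments ([subtract_exons()]).
#' @param elements Full TE element table ([parse_te_gff()]); defines the
#'   family registry (elements with no assignable bp still count as members).
#' @param genes List from [parse_gene_gff()].
#' @param chrom_allowlist Character vector of sequence names to retain.
#' @return An object of class `annotation_index`.
#' @export
build_annotation_index <- function(segments, elements, genes,
                                   chrom_allowlist = NULL) {
  if (is.null(chrom_allowlist))
    chrom_allowlist <- sort(unique(c(segments$chrom, genes$exons$chrom)))
  if (length(chrom_allowlist) == 0L)
    stop("empty chromosome allowlist: nothing to index")
  seg <- segments[chrom %in% chrom_allowlist]
  ex <- genes$exons[chrom %in% chrom_allowlist]
  feat <- rbind(
    data.table(feature_id = seg$element_id, family = seg$family,
               feature_type = "te", chrom = seg$chrom,
               start = seg$start, end = seg$end),
    data.table(feature_id = ex$gene_id, family = NA_character_,
               feature_type = "gene", chrom = ex$chrom,
               start = ex$start, end = ex$end))
  gr <- GRanges(feat$chrom, IRanges(feat$start, feat$end))
  mcols(gr)$feature_id <- feat$feature_id
  mcols(gr)$family <- feat$family
  mcols(gr)$feature_type <- feat$feature_type
  # invariants: TE segments disjoint, and no TE bp under an exon
  te_gr <- gr[feat$feature_type == "te"]
  if (length(findOverlaps(te_gr, drop.self = TRUE)) > 0L)
    stop("TE segments are not disjoint; run disjoin_te_annotations() first")
  ex_gr <- gr[feat$feature_type == "gene"]
  if (length(findOverlaps(te_gr, ex_gr)) > 0L)
    stop("TE segments overlap exons; run subtract_exons() first")
  fams <- elements[, .(member_count = .N, te_order = te_order[1L]), by = family]
  setorder(fams, family)
  structure(list(features = gr,
                 elements = elements,
                 families = fams[],
                 genes = genes$genes,
                 chrom_allowlist = chrom_allowlist),
            class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  nte <- sum(mcols(x$features)$feature_type == "te")
  nex <- sum(mcols(x$features)$feature_type == "gene")
  cat("annotation_index:", nte, "TE segments (",
      nrow(x$families), "families,", nrow(x$elements), "elements ),",
      nex, "exon intervals,", length(x$chrom_allowlist), "sequences\n")
  invisible(x)
}

#' Query an annotation index with genomic intervals
#'
#' @param index An `annotation_index`.
#' @param chrom,start,end Parallel vectors describing 1-based closed query
#'   intervals.
#' @return `data.table` with one row per (query, feature) overlap of at least
#'   1 bp: columns `query`, `feature_id`, `family`, `feature_type`.
#' @export
query_index <- function(index, chrom, start, end) {
  q <- GRanges(chrom, IRanges(start, end))
  ov <- findOverlaps(q, index$features)
  md <- mcols(index$features)
  data.table(query = queryHits(ov),
             feature_id = md$feature_id[subjectHits(ov)],
             family = md$family[subjectHits(ov)],
             feature_type = md$feature_type[subjectHits(ov)])
}

#' Write the merged annotation as GFF3
#'
#' Emits exon-masked TE segments (type `transposable_element`, with `ID`,
#' `Name` = family and `Order` attributes) and gene exons (type `exon`,
#' `Parent` = gene) in deterministic coordinate order.
#'
#' @param index An `annotation_index`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotation_gff <- function(index, path) {
  md <- mcols(index$features)
  dt <- data.table(chrom = as.character(seqnames(index$features)),
                   start = start(index$features), end = end(index$features),
                   feature_id = md$feature_id, family = md$family,
                   feature_type = md$feature_type)
  ords <- setNames(index$families$te_order, index$families$family)
  attrs <- ifelse(dt$feature_type == "te",
                  paste0("ID=", dt$feature_id, ";Name=", dt$family,
                         ";Order=", ords[dt$family]),
                  paste0("Parent=", dt$feature_id))
  lines <- paste(dt$chrom, "tefamquant",
                 ifelse(dt$feature_type == "te", "transposable_element", "exon"),
                 dt$start, dt$end, ".", ".", ".", attrs, sep = "\t")
  ord <- order(dt$chrom, dt$start, dt$end, dt$feature_id)
  writeLines(c("##gff-version 3", lines[ord]), path)
  invisible(path)
}

#' One-call annotation build from GFF3 inputs
#'
#' Convenience wrapper: parse TE and gene GFF3s, disjoin, mask exons, and
#' build the index.
#'
#' @inheritParams parse_te_gff
#' @param te_gff,gene_gff Input GFF3 paths.
#' @param chrom_allowlist Sequences to retain (default: all observed).
#' @return An `annotation_index`.
#' @export
build_annotation <- function(te_gff, gene_gff, chrom_allowlist = NULL,
                             family_attribute = "Name") {
  elements <- parse_te_gff(te_gff, family_attribute)
  genes <- parse_gene_gff(gene_gff)
  seg <- disjoin_te_annotations(elements)
  seg <- subtract_exons(seg, genes$exons)
  build_annotation_index(seg, elements, genes, chrom_allowlist)
}
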