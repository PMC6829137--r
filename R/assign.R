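# Read classification: group alignment records by read name, intersect every
# alignment block with the annotation index (>= 1 bp overlap), and resolve
# each read to exactly one category:
#
#   gene_unique  unique mapper, gene exon(s) only, a single gene
#   u_te.fam     unique mapper, TE hit(s) within one family, no gene
#                (when a single element is hit, the element table is also
#                credited: element-unique)
#   m_te.fam     multi mapper, all annotated hits in one TE family, no gene
#   u_te.g       unique mapper hitting both one TE family and a gene
#   m_te.g       multi mapper hitting both one TE family and a gene
#   unassigned   everything else: no feature, several families, several
#                genes, or a multi mapper whose annotated hits are genes only
#
# Alignments that overlap no feature never disqualify a multi-mapper whose
# annotated hits are single-family: the single-family rule constrains the
# hit set, not unannotated positions.

CATEGORY_LEVELS <- c("gene_unique", "te_element_unique", "u_te.fam",
                     "m_te.fam", "u_te.g", "m_te.g", "unassigned")

#' Read and group an alignment file into per-read records
#'
#' Accepts SAM (converted in-memory via [Rsamtools::asBam()]) or BAM.  All
#' mapped records — including secondary alignments — are kept; unmapped
#' records are skipped.  Spliced alignments contribute one interval per
#' aligned block.  The per-read alignment count is taken from the observed
#' records; when an NH tag is present and disagrees, a warning is issued and
#' the observed count wins.
#'
#' @param path SAM or BAM file.
#' @return `data.table` with one row per aligned block: `read_id`, `chrom`,
#'   `start`, `end`, `aln` (alignment ordinal within the read) and `n_hits`
#'   (alignments observed for the read).
#' @export
read_alignments <- function(path) {
  ext <- tolower(file_ext(path))
  bam <- path
  if (ext == "sam") {
    bam <- asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  }
  param <- ScanBamParam(what = c("qname", "flag"), tag = "NH",
                        flag = scanBamFlag(isUnmappedQuery = FALSE))
  ga <- readGAlignments(bam, param = param)
  if (length(ga) == 0L)
    return(data.table(read_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      aln = integer(), n_hits = integer()))
  nh <- mcols(ga)$NH
  qname <- mcols(ga)$qname
  blocks <- grglist(ga)          # spliced blocks, one GRangesList slot per record
  nb <- lengths(blocks)
  ul <- unlist(blocks, use.names = FALSE)
  dt <- data.table(read_id = rep(qname, nb),
                   record = rep(seq_along(ga), nb),
                   chrom = as.character(seqnames(ul)),
                   start = start(ul), end = end(ul),
                   nh = rep(if (is.null(nh)) NA_integer_ else nh, nb))
  dt[, aln := match(record, unique(record)), by = read_id]
  dt[, n_hits := max(aln), by = read_id]
  bad_nh <- dt[!is.na(nh) & nh != n_hits, unique(read_id)]
  if (length(bad_nh))
    warning("NH tag disagrees with observed alignment count for ",
            length(bad_nh), " read(s); observed count used")
  dt[, c("record", "nh") := NULL]
  dt[]
}

# Decision table on per-read hit summaries.  Vectorised over reads.
.classify <- function(n_hits, n_genes, n_elements, n_families) {
  unique_ <- n_hits == 1L
  fcase(
    n_genes == 0L & n_families == 0L, "unassigned",
    n_families > 1L, "unassigned",
    unique_ & n_genes == 1L & n_families == 0L, "gene_unique",
    unique_ & n_genes == 0L & n_families == 1L, "u_te.fam",
    !unique_ & n_genes == 0L & n_families == 1L, "m_te.fam",
    unique_ & n_genes >= 1L & n_families == 1L, "u_te.g",
    !unique_ & n_genes >= 1L & n_families == 1L, "m_te.g",
    default = "unassigned"   # multi gene-only, several genes, ...
  )
}

#' Classify every read of a library against an annotation index
#'
#' @param alignments Block table from [read_alignments()].
#' @param index An `annotation_index`.
#' @return `data.table` with one row per read: `read_id`, `n_hits`,
#'   `category`, `target` (gene ID, family code, or `NA`), and `element`
#'   (element ID when exactly one element is hit, else `NA`).
#' @export
classify_reads <- function(alignments, index) {
  reads <- unique(alignments[, .(read_id, n_hits)])
  if (nrow(reads) == 0L)
    return(data.table(read_id = character(), n_hits = integer(),
                      category = character(), target = character(),
                      element = character()))
  hits <- query_index(index, alignments$chrom, alignments$start, alignments$end)
  hits <- unique(data.table(read_id = alignments$read_id[hits$query],
                            feature_id = hits$feature_id,
                            family = hits$family,
                            feature_type = hits$feature_type))
  # hits rows are unique (read, feature), so .N counts distinct features
  gh <- hits[feature_type == "gene",
             .(n_genes = .N, gene = feature_id[1L]), by = read_id]
  th <- hits[feature_type == "te",
             .(n_elements = .N, n_families = uniqueN(family),
               element = feature_id[1L], family = family[1L]), by = read_id]
  out <- merge(reads, gh, by = "read_id", all.x = TRUE)
  out <- merge(out, th, by = "read_id", all.x = TRUE)
  for (cn in c("n_genes", "n_elements", "n_families"))
    out[is.na(get(cn)), (cn) := 0L]
  out[n_genes != 1L, gene := NA_character_]
  out[n_elements != 1L, element := NA_character_]
  out[n_families != 1L, family := NA_character_]
  out[, category := .classify(n_hits, n_genes, n_elements, n_families)]
  out[, target := fcase(
    category == "gene_unique", gene,
    category %chin% c("u_te.fam", "m_te.fam", "u_te.g", "m_te.g"), family,
    default = NA_character_)]
  out[!(category == "u_te.fam" & n_elements == 1L), element := NA_character_]
  setorder(out, read_id)
  out[, .(read_id, n_hits, category, target, element)]
}

#' Count one library in the family / element / summary categories
#'
#' Produces the two per-library tables plus the one-line summary:
#' a family table with the four count columns (`u_te.fam`, `u_te.g`,
#' `m_te.fam`, `m_te.g`), and an element/gene table with `unique` and `te.g`
#' columns (unique reads hitting a single TE element credit both the family
#' and the element table; unique ambiguous reads hitting a single element
#' credit that element's `te.g`).
#'
#' @param alignments Block table from [read_alignments()], or a SAM/BAM path.
#' @param index An `annotation_index`.
#' @param library_id Library name recorded in the summary line.
#' @return Object of class `library_counts`: list with `family` and
#'   `element` count tables, `summary` (single-row data.table), and the
#'   per-read `assignments` table.
#' @export
count_library <- function(alignments, index, library_id = "library") {
  if (is.character(alignments) && length(alignments) == 1L)
    alignments <- read_alignments(alignments)
  asg <- classify_reads(alignments, index)
  # family table over the full registry (zero-filled)
  fam <- data.table(family = index$families$family)
  tally <- function(cat) {
    t <- asg[category == cat, .N, by = target]
    setNames(t$N, t$target)
  }
  for (cn in c("u_te.fam", "u_te.g", "m_te.fam", "m_te.g")) {
    v <- tally(cn)
    fam[, (cn) := fifelse(family %chin% names(v), as.integer(v[family]), 0L)]
    fam[is.na(get(cn)), (cn) := 0L]
  }
  # element/gene table: unique + te.g (te.g only for single-element u_te.g)
  g_u <- asg[category == "gene_unique", .N, by = .(feature = target)]
  e_u <- asg[category == "u_te.fam" & !is.na(element), .N, by = .(feature = element)]
  # single-element ambiguous unique reads
  e_g <- asg[category == "u_te.g", .(read_id)]
  if (nrow(e_g)) {
    hits1 <- classify_reads_element_hits(alignments, index, e_g$read_id)
    one <- hits1[, if (uniqueN(feature_id) == 1L) .(feature = feature_id[1L]),
                 by = read_id]
    e_g <- if (nrow(one)) one[, .N, by = feature]
           else data.table(feature = character(), N = integer())
  } else e_g <- data.table(feature = character(), N = integer())
  el <- rbind(
    data.table(feature = index$genes$gene_id, type = "gene"),
    data.table(feature = index$elements$element_id, type = "te"))
  el[, `:=`(unique = 0L, te.g = 0L)]
  el[g_u, on = "feature", unique := i.N]
  el[e_u, on = "feature", unique := i.N]
  el[e_g, on = "feature", te.g := i.N]
  summary <- data.table(
    library_id = library_id,
    total_reads = nrow(asg),
    gene_unique = sum(asg$category == "gene_unique"),
    u_te.fam = sum(asg$category == "u_te.fam"),
    m_te.fam = sum(asg$category == "m_te.fam"),
    u_te.g = sum(asg$category == "u_te.g"),
    m_te.g = sum(asg$category == "m_te.g"),
    unassigned = sum(asg$category == "unassigned"))
  structure(list(library_id = library_id, family = fam[], element = el[],
                 summary = summary, assignments = asg),
            class = "library_counts")
}

# element hits for a subset of reads (used for element-level te.g credit)
classify_reads_element_hits <- function(alignments, index, read_ids) {
  sub <- alignments[read_id %chin% read_ids]
  hits <- query_index(index, sub$chrom, sub$start, sub$end)
  hits <- hits[feature_type == "te"]
  unique(data.table(read_id = sub$read_id[hits$query],
                    feature_id = hits$feature_id))
}

#' @export
print.library_counts <- function(x, ...) {
  cat("library_counts for '", x$library_id, "':\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write per-library count files
#'
#' Emits `<prefix>_family_counts.txt` (family, u_te.fam, u_te.g, m_te.fam,
#' m_te.g), `<prefix>_element_counts.txt` (feature, type, unique, te.g) and
#' appends one line to `te_mapping_summary.txt` in `dir`.
#'
#' @param counts A `library_counts` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_library_counts <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(counts$family,
         file.path(dir, paste0(counts$library_id, "_family_counts.txt")),
         sep = "\t")
  fwrite(counts$element,
         file.path(dir, paste0(counts$library_id, "_element_counts.txt")),
         sep = "\t")
  sfile <- file.path(dir, "te_mapping_summary.txt")
  fwrite(counts$summary, sfile, sep = "\t", append = file.exists(sfile))
  invisible(dir)
}
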