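# Synthetic-data generator: annotations and alignment files with exact
# ground truth, emulating the repetitive-genome structure the classifier
# addresses — TE families from one to many members, nested insertions, TEs
# overlapping gene exons (the source of ambiguous reads), and reads mapping
# uniquely or to several members of one family.
#
# No nucleotide sequences are simulated: alignments are placed directly
# (CIGAR = full-length match) inside the assignable segments of expressed
# elements, so the intended category of every read is exact by construction
# and the classifier's output can be compared read-for-read with the truth.

#' Simulation configuration
#'
#' @param n_chromosomes Number of chromosomes (default 2).
#' @param chrom_length Chromosome length in bp (default 100000).
#' @param families `data.table` with columns `family`, `member_count`,
#'   `member_length`, `nesting_prob` (probability a member is inserted
#'   inside a previously placed TE), `frac_in_gene` (probability a member is
#'   placed straddling an exon boundary, creating ambiguous-read sites).
#'   The default set spans 1 to 20 members across LTR, TIR and Helitron
#'   orders.
#' @param n_genes,exons_per_gene,exon_length,intron_length Gene model shape.
#' @param seed Integer seed used by [simulate_annotation()] by default.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 2L, chrom_length = 100000L,
                       families = NULL, n_genes = 12L, exons_per_gene = 3L,
                       exon_length = 200L, intron_length = 150L, seed = 1L) {
  if (is.null(families))
    families <- data.table(
      family = c("RLC00001", "RLG00002", "DTA00003", "DHH00004",
                 "RLC00005", "RIT00006"),
      member_count = c(20L, 8L, 5L, 3L, 1L, 1L),
      member_length = c(400L, 300L, 200L, 250L, 500L, 350L),
      nesting_prob = c(0, 0.3, 0.3, 0.2, 0, 0),
      frac_in_gene = c(0.1, 0.1, 0.2, 0, 0, 1))
  stopifnot(all(families$member_count >= 1L), chrom_length > 0L)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 families = families, n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_length = as.integer(exon_length),
                 intron_length = as.integer(intron_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a TE + gene annotation with known structure
#'
#' Genes are laid out at regular offsets; TE members are placed by rejection
#' sampling, nested inside an earlier TE with probability `nesting_prob`, or
#' straddling a gene exon's 3' boundary with probability `frac_in_gene`
#' (which, after exon masking, leaves a TE segment abutting the exon — the
#' site class that generates ambiguous reads).  Deterministic for a seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (default `config$seed`).
#' @return A `sim_annotation` list: `elements`, `genes` (as
#'   [parse_gene_gff()]), `chromosomes` (named lengths), `config`, `seed`.
#' @export
simulate_annotation <- function(config = sim_config(), seed = config$seed) {
  withr_seed(seed, {
    chroms <- setNames(rep(config$chrom_length, config$n_chromosomes),
                       paste0("chr", seq_len(config$n_chromosomes)))
    # genes on a regular grid with jitter
    gene_span <- config$exons_per_gene * config$exon_length +
      (config$exons_per_gene - 1L) * config$intron_length
    genes <- vector("list", config$n_genes)
    exons <- vector("list", config$n_genes)
    per_chrom <- ceiling(config$n_genes / config$n_chromosomes)
    spacing <- config$chrom_length %/% (per_chrom + 1L)
    if (spacing <= gene_span + 100L)
      stop("features exceeding chromosome length: reduce gene count or size")
    for (i in seq_len(config$n_genes)) {
      ci <- ((i - 1L) %% config$n_chromosomes) + 1L
      slot <- (i - 1L) %/% config$n_chromosomes
      start <- slot * spacing + spacing %/% 2L +
        sample.int(max(1L, spacing %/% 10L), 1L)
      gid <- sprintf("gene%03d", i)
      ex_starts <- start + (seq_len(config$exons_per_gene) - 1L) *
        (config$exon_length + config$intron_length)
      genes[[i]] <- data.table(gene_id = gid, chrom = names(chroms)[ci],
                               start = start,
                               end = start + gene_span - 1L, strand = "+")
      exons[[i]] <- data.table(gene_id = gid, chrom = names(chroms)[ci],
                               start = ex_starts,
                               end = ex_starts + config$exon_length - 1L)
    }
    genes <- rbindlist(genes); exons <- rbindlist(exons)
    if (any(genes$end > config$chrom_length))
      stop("features exceeding chromosome length")
    # TE placement
    placed <- data.table(element_id = character(), family = character(),
                         chrom = character(), start = integer(),
                         end = integer())
    occ <- rbind(genes[, .(chrom, start, end)])  # plain TEs avoid genes/TEs
    overlaps_any <- function(tab, ch, s, e)
      nrow(tab[chrom == ch & start <= e & end >= s]) > 0L
    fams <- config$families
    for (fi in seq_len(nrow(fams))) {
      fam <- fams$family[fi]; mlen <- fams$member_length[fi]
      for (mi in seq_len(fams$member_count[fi])) {
        eid <- sprintf("%sm%04d", fam, mi)
        r <- runif(1)
        ok <- FALSE
        if (r < fams$nesting_prob[fi]) {
          hosts <- placed[end - start + 1L >= mlen + 2L]
          if (nrow(hosts)) {
            for (try in seq_len(20L)) {
              h <- hosts[sample.int(nrow(hosts), 1L)]
              s <- h$start + 1L + sample.int(h$end - h$start - mlen, 1L) - 1L
              en <- s + mlen - 1L
              # keep nesting clean: the candidate must contain or be
              # contained in (or miss) every previously placed element
              ovl <- placed[chrom == h$chrom & start <= en & end >= s]
              if (all(ovl$start <= s & en <= ovl$end |
                      s <= ovl$start & ovl$end <= en)) {
                placed <- rbind(placed,
                                data.table(element_id = eid, family = fam,
                                           chrom = h$chrom, start = s,
                                           end = en))
                ok <- TRUE
                break
              }
            }
          }
        }
        if (!ok && r < fams$nesting_prob[fi] + fams$frac_in_gene[fi] &&
            nrow(exons)) {
          for (try in seq_len(50L)) {
            e <- exons[sample.int(nrow(exons), 1L)]
            ov <- min(mlen %/% 2L, e$end - e$start)   # bp inside the exon
            s <- e$end - ov + 1L
            en <- s + mlen - 1L
            if (en <= chroms[[e$chrom]] &&
                !overlaps_any(placed, e$chrom, s, en)) {
              placed <- rbind(placed, data.table(element_id = eid,
                                                 family = fam, chrom = e$chrom,
                                                 start = s, end = en))
              ok <- TRUE
              break
            }
          }
        }
        if (!ok) {
          for (try in seq_len(200L)) {
            ch <- names(chroms)[sample.int(length(chroms), 1L)]
            s <- sample.int(chroms[[ch]] - mlen, 1L)
            en <- s + mlen - 1L
            if (!overlaps_any(occ, ch, s, en) &&
                !overlaps_any(placed, ch, s, en)) {
              placed <- rbind(placed, data.table(element_id = eid,
                                                 family = fam, chrom = ch,
                                                 start = s, end = en))
              ok <- TRUE
              break
            }
          }
        }
        if (!ok) stop("could not place ", eid,
                      ": features exceeding chromosome length")
      }
    }
    elements <- data.table(element_id = placed$element_id,
                           family = placed$family,
                           te_order = te_order(placed$family),
                           chrom = placed$chrom, start = placed$start,
                           end = placed$end, strand = "+")
    setorder(elements, chrom, start, element_id)
    structure(list(elements = elements,
                   genes = list(genes = genes, exons = exons),
                   chromosomes = chroms, config = config, seed = seed),
              class = "sim_annotation")
  })
}

#' Write a simulated annotation as GFF3 files
#'
#' @param sim A `sim_annotation`.
#' @param dir Output directory; writes `te.gff3` and `genes.gff3`.
#' @return Named paths, invisibly.
#' @export
write_sim_annotation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  te_path <- file.path(dir, "te.gff3")
  el <- sim$elements
  writeLines(c("##gff-version 3",
               paste(el$chrom, "sim", "transposable_element", el$start, el$end,
                     ".", el$strand, ".",
                     paste0("ID=", el$element_id, ";Name=", el$family),
                     sep = "\t")), te_path)
  gene_path <- file.path(dir, "genes.gff3")
  g <- sim$genes$genes; ex <- sim$genes$exons
  glines <- paste(g$chrom, "sim", "gene", g$start, g$end, ".", g$strand, ".",
                  paste0("ID=", g$gene_id), sep = "\t")
  elines <- paste(ex$chrom, "sim", "exon", ex$start, ex$end, ".", "+", ".",
                  paste0("Parent=", ex$gene_id), sep = "\t")
  writeLines(c("##gff-version 3", glines, elines), gene_path)
  invisible(c(te = te_path, genes = gene_path))
}

#' Build the annotation index of a simulated annotation
#'
#' @param sim A `sim_annotation`.
#' @return An `annotation_index` (disjoined, exon-masked).
#' @export
sim_annotation_index <- function(sim) {
  seg <- disjoin_te_annotations(sim$elements)
  seg <- subtract_exons(seg, sim$genes$exons)
  build_annotation_index(seg, sim$elements, sim$genes,
                         names(sim$chromosomes))
}

#' Library specification for the read simulator
#'
#' @param library_id Library name.
#' @param tissue,genotype,replicate,dataset Metadata fields.
#' @param total_reads Reads to draw (default 20000).
#' @param gene_weight Fraction of reads originating from gene exons
#'   (default 0.85), split uniformly across genes.
#' @param family_weights Named numeric vector of per-family expression
#'   weights (need not be normalized); default: equal weight on every
#'   simulated family summing to `1 - gene_weight`.
#' @param expressed_member_mode `"single_member"` (all family reads from one
#'   designated member), `"uniform"` (each read from a random member), or a
#'   named list of element IDs per family (explicit expressed-member sets).
#' @param multimap_rate Fraction of family reads emitted as multi-mappers
#'   with alignments in several members (downgraded to unique, with a
#'   message, for effectively single-member families).
#' @param ambiguous_rate Fraction of family reads placed straddling an
#'   exon/TE-segment boundary (requires such a site; downgraded otherwise).
#' @param read_length Read length in bp (default 60; shrunk to fit short
#'   segments).
#' @return A `library_spec` list.
#' @export
library_spec <- function(library_id, tissue = "leaf", genotype = "B73",
                         replicate = 1L, dataset = "sim",
                         total_reads = 20000L, gene_weight = 0.85,
                         family_weights = NULL,
                         expressed_member_mode = "uniform",
                         multimap_rate = 0.3, ambiguous_rate = 0.05,
                         read_length = 60L) {
  stopifnot(total_reads > 0L, gene_weight >= 0, gene_weight <= 1)
  if (!is.null(family_weights) && any(family_weights < 0))
    stop("family weights must be non-negative")
  structure(list(library_id = library_id, tissue = tissue,
                 genotype = genotype, replicate = as.integer(replicate),
                 dataset = dataset, total_reads = as.integer(total_reads),
                 gene_weight = gene_weight, family_weights = family_weights,
                 expressed_member_mode = expressed_member_mode,
                 multimap_rate = multimap_rate,
                 ambiguous_rate = ambiguous_rate,
                 read_length = as.integer(read_length)),
            class = "library_spec")
}

# assignable pieces per element, plus ambiguous-capable pieces (those whose
# start abuts an exon end, left behind by exon masking)
.sim_pieces <- function(index) {
  md <- mcols(index$features)
  te <- md$feature_type == "te"
  pieces <- data.table(element_id = md$feature_id[te],
                       family = md$family[te],
                       chrom = as.character(seqnames(index$features))[te],
                       start = start(index$features)[te],
                       end = end(index$features)[te])
  ex <- data.table(chrom = as.character(seqnames(index$features))[!te],
                   start = start(index$features)[!te],
                   end = end(index$features)[!te])
  pieces[, len := end - start + 1L]
  amb <- merge(pieces, ex[, .(chrom, exon_start = start, exon_end = end)],
               by = "chrom", allow.cartesian = TRUE)
  amb <- amb[start == exon_end + 1L]
  list(pieces = pieces, ambig = amb)
}

#' Simulate one RNA-seq library as direct alignments with exact truth
#'
#' Reads are multinomially apportioned to genes and TE families by weight.
#' Family reads become multi-mappers (alignments placed at congruent
#' positions in several members' assignable segments) at `multimap_rate`
#' and boundary-straddling ambiguous reads at `ambiguous_rate`; everything
#' else is placed wholly inside one assignable segment, so the intended
#' category of every read is exact.
#'
#' @param index An `annotation_index` (typically [sim_annotation_index()]).
#' @param spec A [library_spec()].
#' @param seed Integer seed.
#' @return A `sim_library` list: `sam` (character vector of SAM lines),
#'   `truth` (per-read `data.table`: `read_id`, `category`, `target`,
#'   `element`, `n_hits`), `summary` (per-category totals),
#'   `family_truth` (per family x category counts), `spec`, `seed`.
#' @export
simulate_library <- function(index, spec, seed = 1L) {
  withr_seed(seed, {
    ps <- .sim_pieces(index)
    pieces <- ps$pieces
    fams <- sort(unique(pieces$family))
    genes_dt <- data.table(
      gene_id = mcols(index$features)$feature_id[
        mcols(index$features)$feature_type == "gene"],
      chrom = as.character(seqnames(index$features))[
        mcols(index$features)$feature_type == "gene"],
      start = start(index$features)[
        mcols(index$features)$feature_type == "gene"],
      end = end(index$features)[
        mcols(index$features)$feature_type == "gene"])
    gene_ids <- unique(genes_dt$gene_id)
    fw <- spec$family_weights
    if (is.null(fw))
      fw <- setNames(rep((1 - spec$gene_weight) / length(fams), length(fams)),
                     fams)
    fw <- fw[names(fw) %in% fams & fw > 0]
    targets <- c(setNames(rep(spec$gene_weight / max(1, length(gene_ids)),
                              length(gene_ids)), gene_ids), fw)
    targets <- targets / sum(targets)
    ns <- as.vector(rmultinom(1L, spec$total_reads, targets))
    names(ns) <- names(targets)

    sam_parts <- vector("list", length(ns))
    truth <- vector("list", length(ns))
    ridx <- 0L
    rl <- spec$read_length
    for (ti in seq_along(ns)) {
      tgt <- names(ns)[ti]; n <- ns[ti]
      if (n == 0L) next
      if (tgt %in% gene_ids) {
        ex <- genes_dt[gene_id == tgt]
        rid <- sprintf("r%07d", ridx + seq_len(n)); ridx <- ridx + n
        ei <- sample.int(nrow(ex), n, replace = TRUE)
        len <- pmin(rl, ex$end[ei] - ex$start[ei] + 1L)
        pos <- ex$start[ei] +
          as.integer(floor(runif(n) * (ex$end[ei] - ex$start[ei] + 2L - len)))
        sam_parts[[ti]] <- paste(rid, 0L, ex$chrom[ei], pos, 255L,
                                 paste0(len, "M"), "*", 0L, 0L, "*", "*",
                                 "NH:i:1", sep = "\t")
        truth[[ti]] <- data.table(read_id = rid, category = "gene_unique",
                                  target = tgt, element = NA_character_,
                                  n_hits = 1L)
      } else {
        fp <- pieces[family == tgt]
        memb <- unique(fp$element_id)
        mode <- spec$expressed_member_mode
        if (is.list(mode)) {
          memb_use <- intersect(mode[[tgt]], memb)
          if (length(memb_use) == 0L) { ns[ti] <- 0L; next }
        } else if (identical(mode, "single_member")) {
          memb_use <- memb[1L]
        } else memb_use <- memb
        fp_use <- fp[element_id %chin% memb_use]
        amb_sites <- ps$ambig[family == tgt & element_id %chin% memb_use]
        n_memb <- length(unique(fp_use$element_id))
        r <- runif(n)
        # disjoint draw intervals; incapable draws downgrade to unique
        is_amb <- r < spec$ambiguous_rate & nrow(amb_sites) > 0L
        is_mm <- r >= spec$ambiguous_rate &
          r < spec$ambiguous_rate + spec$multimap_rate & n_memb >= 2L
        rid <- sprintf("r%07d", ridx + seq_len(n)); ridx <- ridx + n
        lines <- vector("list", n)
        rows <- vector("list", n)
        # unique single-segment reads (vectorized)
        iu <- which(!is_amb & !is_mm)
        if (length(iu)) {
          pi <- sample.int(nrow(fp_use), length(iu), replace = TRUE,
                           prob = fp_use$len)
          len <- pmin(rl, fp_use$len[pi])
          pos <- fp_use$start[pi] +
            as.integer(floor(runif(length(iu)) * (fp_use$len[pi] - len + 1L)))
          lines[iu] <- paste(rid[iu], 0L, fp_use$chrom[pi], pos, 255L,
                             paste0(len, "M"), "*", 0L, 0L, "*", "*",
                             "NH:i:1", sep = "\t")
          rows[[n + 1L]] <- data.table(read_id = rid[iu],
                                       category = "u_te.fam", target = tgt,
                                       element = fp_use$element_id[pi],
                                       n_hits = 1L)
        }
        # ambiguous boundary reads
        for (j in which(is_amb)) {
          a <- amb_sites[sample.int(nrow(amb_sites), 1L)]
          h <- min(rl %/% 2L, a$exon_end - a$exon_start + 1L)  # bp in exon
          k <- min(rl - h, a$len)                              # bp in TE
          lines[[j]] <- paste(rid[j], 0L, a$chrom, a$start - h, 255L,
                              paste0(h + k, "M"), "*", 0L, 0L, "*", "*",
                              "NH:i:1", sep = "\t")
          rows[[j]] <- data.table(read_id = rid[j], category = "u_te.g",
                                  target = tgt, element = a$element_id,
                                  n_hits = 1L)
        }
        # multi-mappers across members of the family
        mm_pieces <- split(seq_len(nrow(fp_use)), fp_use$element_id)
        for (j in which(is_mm)) {
          k_el <- sample(names(mm_pieces), min(sample(2:4, 1L),
                                               length(mm_pieces)))
          pi <- vapply(mm_pieces[k_el], function(rows_)
            rows_[sample.int(length(rows_), 1L)], 0L)
          len <- min(rl, min(fp_use$len[pi]))
          pos <- fp_use$start[pi] +
            as.integer(floor(runif(length(pi)) * (fp_use$len[pi] - len + 1L)))
          lines[[j]] <- paste(rid[j], c(0L, rep(256L, length(pi) - 1L)),
                              fp_use$chrom[pi], pos, 255L, paste0(len, "M"),
                              "*", 0L, 0L, "*", "*",
                              paste0("NH:i:", length(pi)), sep = "\t")
          rows[[j]] <- data.table(read_id = rid[j], category = "m_te.fam",
                                  target = tgt, element = NA_character_,
                                  n_hits = length(pi))
        }
        sam_parts[[ti]] <- unlist(lines)
        truth[[ti]] <- rbindlist(rows)
      }
    }
    sam <- unlist(sam_parts)
    truth <- rbindlist(truth)
    setorder(truth, read_id)
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                paste0("@SQ\tSN:", names(index2chroms(index)),
                       "\tLN:", index2chroms(index)))
    summary <- data.table(
      library_id = spec$library_id,
      total_reads = nrow(truth),
      gene_unique = sum(truth$category == "gene_unique"),
      u_te.fam = sum(truth$category == "u_te.fam"),
      m_te.fam = sum(truth$category == "m_te.fam"),
      u_te.g = sum(truth$category == "u_te.g"),
      m_te.g = sum(truth$category == "m_te.g"),
      unassigned = sum(truth$category == "unassigned"))
    fam_truth <- dcast(truth[category %chin% c("u_te.fam", "m_te.fam",
                                               "u_te.g", "m_te.g")],
                       target ~ category, fun.aggregate = length,
                       value.var = "read_id")
    structure(list(sam = c(header, sam), truth = truth, summary = summary,
                   family_truth = fam_truth, spec = spec, seed = seed),
              class = "sim_library")
  })
}

# chromosome lengths visible to an index (upper bounds for SAM @SQ)
index2chroms <- function(index) {
  dt <- data.table(chrom = as.character(seqnames(index$features)),
                   end = end(index$features))
  mx <- dt[, .(len = max(end) + 1000L), by = chrom]
  out <- setNames(mx$len, mx$chrom)
  out[sort(names(out))]
}

#' Write a simulated library to a SAM file
#'
#' @param lib A `sim_library`.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sim_library <- function(lib, path) {
  writeLines(lib$sam, path)
  invisible(path)
}

#' Simulate expression segregation across a RIL panel
#'
#' Each expressed element carries a parent-of-origin tag; every RIL inherits
#' each non-shared element independently with probability 0.5 (`"shared"`
#' elements are present in all lines).  Per-library family expression is
#' drawn by multinomial sampling of reads over a gene background plus the
#' carried elements, with per-element gamma noise (`noise_cv`) emulating
#' biological variability; RPM uses the assigned-read denominator.  With
#' `emit = "counts"` (default) the panel is returned as count/RPM matrices;
#' `emit = "sam"` additionally generates per-RIL alignment files via
#' [simulate_library()] (slower; intended for small panels).
#'
#' @param index An `annotation_index`.
#' @param expressed `data.table` with columns `element_id`, `origin`
#'   (`"p1"`, `"p2"` or `"shared"`) and `weight` (expected share of the
#'   library's reads when carried).
#' @param n_rils Number of RILs (>= 2).
#' @param reads_per_ril Library size (default 200000).
#' @param noise_cv Coefficient of variation of per-element gamma noise
#'   (default 0.4).
#' @param seed Integer seed.
#' @param emit `"counts"` or `"sam"`.
#' @return A `sim_ril_panel` list: `rpm` (families x RILs), `counts`,
#'   `genotype` (elements x RILs logical truth), `expressed`, and `sams`
#'   (named list of SAM line vectors when `emit = "sam"`).
#' @export
simulate_ril_panel <- function(index, expressed, n_rils = 100L,
                               reads_per_ril = 200000L, noise_cv = 0.4,
                               seed = 1L, emit = c("counts", "sam")) {
  emit <- match.arg(emit)
  if (n_rils < 2L) stop("need at least 2 RILs")
  stopifnot(all(expressed$origin %in% c("p1", "p2", "shared")))
  el2fam <- setNames(index$elements$family, index$elements$element_id)
  if (anyNA(el2fam[expressed$element_id]))
    stop("expressed element(s) not in the annotation: ",
         paste(setdiff(expressed$element_id, names(el2fam)), collapse = ", "))
  withr_seed(seed, {
    ne <- nrow(expressed)
    geno <- matrix(TRUE, ne, n_rils,
                   dimnames = list(expressed$element_id,
                                   sprintf("RIL%03d", seq_len(n_rils))))
    seg <- expressed$origin != "shared"
    geno[seg, ] <- matrix(runif(sum(seg) * n_rils) < 0.5, sum(seg), n_rils)
    fams <- sort(unique(el2fam[expressed$element_id]))
    gene_w <- 1 - sum(expressed$weight)
    if (gene_w <= 0) stop("expressed element weights must sum to < 1")
    counts <- matrix(0L, length(fams), n_rils,
                     dimnames = list(fams, colnames(geno)))
    denom <- numeric(n_rils)
    shp <- 1 / noise_cv^2
    sams <- if (emit == "sam") vector("list", n_rils) else NULL
    for (r in seq_len(n_rils)) {
      w_el <- expressed$weight * geno[, r] *
        (if (noise_cv > 0) rgamma(ne, shape = shp, rate = shp) else 1)
      w <- c(gene = gene_w, setNames(w_el, expressed$element_id))
      n <- as.vector(rmultinom(1L, reads_per_ril, w / sum(w)))
      el_n <- n[-1L]
      fam_n <- tapply(el_n, el2fam[expressed$element_id], sum)
      counts[names(fam_n), r] <- as.integer(fam_n)
      denom[r] <- sum(n)   # genes + family reads, all unambiguous
      if (emit == "sam") {
        carried <- expressed$element_id[geno[, r] & el_n > 0]
        fw <- tapply(el_n, el2fam[expressed$element_id], sum) / sum(n)
        fw <- fw[fw > 0]
        spec <- library_spec(colnames(geno)[r], tissue = "shoot_apex",
                             genotype = colnames(geno)[r],
                             total_reads = reads_per_ril,
                             gene_weight = gene_w,
                             family_weights = fw,
                             expressed_member_mode =
                               split(carried, unname(el2fam[carried])),
                             multimap_rate = 0, ambiguous_rate = 0)
        lib <- simulate_library(index, spec, seed = seed + r)
        sams[[r]] <- lib$sam
        # counts must describe the emitted library, not a separate draw
        fam_obs <- lib$truth[category == "u_te.fam", .N, by = target]
        counts[, r] <- 0L
        counts[fam_obs$target, r] <- fam_obs$N
        denom[r] <- nrow(lib$truth)   # all reads unambiguous by construction
      }
    }
    rpm <- sweep(counts, 2L, denom, "/") * 1e6
    if (emit == "sam") names(sams) <- colnames(geno)
    structure(list(rpm = rpm, counts = counts, genotype = geno,
                   expressed = expressed, denominators = denom,
                   sams = sams, seed = seed),
              class = "sim_ril_panel")
  })
}
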