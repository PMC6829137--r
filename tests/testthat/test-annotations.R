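test_that("TE order decoding is total and deterministic over the prefix table", {
  expect_identical(te_order(c("RLG00001", "RLC11137", "DTA00123",
                              "DHH00123", "RIT00001", "RST00002")),
                   c("LTR", "LTR", "TIR", "Helitron", "LINE", "SINE"))
  expect_warning(ord <- te_order("XXY00001"), "unknown TE order prefix")
  expect_identical(ord, "Unknown")
})

test_that("parse_te_gff reads records, decodes orders, and falls back to ID prefixes", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\ttransposable_element\t100\t400\t.\t+\t.\tID=RLG00001m1;Name=RLG00001",
    "chr1\tsrc\ttransposable_element\t900\t1200\t.\t-\t.\tID=DHH00123m1;Name=DHH00123",
    "chr2\tsrc\ttransposable_element\t50\t80\t.\t+\t.\tID=DTA00042ZmB73v4"),
    gff)
  el <- parse_te_gff(gff)
  expect_equal(nrow(el), 3L)
  expect_identical(el$te_order, c("LTR", "Helitron", "TIR"))
  expect_identical(el$family[3L], "DTA00042")   # parsed from the ID prefix
  expect_identical(el$start, c(100L, 900L, 50L))
  expect_identical(el$strand, c("+", "-", "+"))
})

test_that("parse_te_gff handles empty and malformed input", {
  gff <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", gff)
  expect_identical(nrow(parse_te_gff(gff)), 0L)

  writeLines(c("##gff-version 3",
               "chr1\tsrc\tte\t100\t400\t.\t+\t.\tID=RLG00001m1",
               "chr1\tsrc\tte\tnot_a_number\t400"), gff)
  expect_error(parse_te_gff(gff), "line 3")

  writeLines(c("##gff-version 3",
               "chr1\tsrc\tte\t500\t400\t.\t+\t.\tID=RLG00001m1"), gff)
  expect_error(parse_te_gff(gff), "line 2")

  # no Name attribute and no family-code prefix in the ID
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tte\t100\t400\t.\t+\t.\tID=myweird.te.7"), gff)
  expect_error(parse_te_gff(gff), "myweird.te.7")
})

test_that("parse_gene_gff merges exons through the transcript chain", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1000\t2000\t.\t+\t.\tID=g1_T001;Parent=g1",
    "chr1\tsrc\texon\t1000\t1300\t.\t+\t.\tParent=g1_T001",
    "chr1\tsrc\texon\t1250\t1400\t.\t+\t.\tParent=g1_T001",
    "chr1\tsrc\texon\t1800\t2000\t.\t+\t.\tParent=g1_T001"), gff)
  g <- parse_gene_gff(gff)
  expect_identical(g$genes$gene_id, "g1")
  expect_identical(g$exons$start, c(1000L, 1800L))   # first two merged
  expect_identical(g$exons$end, c(1400L, 2000L))
})

el_tab <- function(ids, fams, starts, ends, chrom = "chr1") {
  data.table::data.table(element_id = ids, family = fams,
                         te_order = te_order(fams), chrom = chrom,
                         start = as.integer(starts), end = as.integer(ends),
                         strand = "+")
}

test_that("disjoin: nesting punches holes; disjoint elements are untouched", {
  el <- el_tab(c("outer", "inner"), c("RLC00001", "RLG00002"),
               c(1, 400), c(1000, 600))
  seg <- disjoin_te_annotations(el)
  expect_identical(seg[element_id == "outer", .(start, end)],
                   data.table::data.table(start = c(1L, 601L),
                                          end = c(399L, 1000L)))
  expect_identical(seg[element_id == "inner", .(start, end)],
                   data.table::data.table(start = 400L, end = 600L))

  el2 <- el_tab(c("a", "b"), c("RLC00001", "RLC00001"), c(1, 500), c(100, 700))
  seg2 <- disjoin_te_annotations(el2)
  expect_identical(seg2$start, c(1L, 500L))
  expect_identical(seg2$end, c(100L, 700L))
})

test_that("disjoin: three-deep nesting matches the per-bp brute-force oracle", {
  el <- el_tab(c("L1", "L2", "L3"),
               c("RLC00001", "RLG00002", "DTA00003"),
               c(1, 200, 300), c(1000, 600, 400))
  seg <- disjoin_te_annotations(el)
  # innermost wins its span; middle keeps span minus innermost; outer the rest
  expect_identical(seg[element_id == "L3", .(start, end)],
                   data.table::data.table(start = 300L, end = 400L))
  expect_identical(seg[element_id == "L2", .(start, end)],
                   data.table::data.table(start = c(200L, 401L),
                                          end = c(299L, 600L)))
  # brute-force per-bp attribution agrees everywhere
  own <- oracle_owner_maps(el, data.table::data.table(
    gene_id = character(), chrom = character(), start = integer(),
    end = integer()), c(chr1 = 1100L))$chr1
  got <- rep(NA_integer_, 1100L)
  for (i in seq_len(nrow(seg)))
    got[seg$start[i]:seg$end[i]] <- match(seg$element_id[i], el$element_id)
  expect_identical(got, own)
})

test_that("disjoin warns on partial overlaps and the earlier start wins", {
  el <- el_tab(c("p1", "p2"), c("RLC00001", "RLG00002"),
               c(100, 300), c(500, 800))
  expect_warning(seg <- disjoin_te_annotations(el), "partially overlapping")
  expect_identical(seg[element_id == "p1", end], 500L)   # keeps shared bp
  expect_identical(seg[element_id == "p2", start], 501L)
})

test_that("subtract_exons removes exonic bp, splits segments, reports losses", {
  el <- el_tab("t1", "RLC00001", 100, 200)
  seg <- disjoin_te_annotations(el)
  ex <- data.table::data.table(gene_id = "g1", chrom = "chr1",
                               start = 150L, end = 160L)
  out <- subtract_exons(seg, ex)
  expect_identical(out$start, c(100L, 161L))
  expect_identical(out$end, c(149L, 200L))

  # TE entirely inside an exon vanishes but is reported
  ex2 <- data.table::data.table(gene_id = "g1", chrom = "chr1",
                                start = 50L, end = 400L)
  out2 <- subtract_exons(seg, ex2)
  expect_identical(nrow(out2), 0L)
  rep2 <- attr(out2, "mask_report")
  expect_identical(rep2[element_id == "t1", bp_after], 0L)

  # empty exon list is a no-op
  out3 <- subtract_exons(seg, ex[0L])
  expect_identical(out3$start, seg$start)
  expect_identical(out3$end, seg$end)
})

test_that("annotation index honors 1 bp overlap, masking, and the allowlist", {
  idx <- tiny_index()
  # exactly one bp inside the tIn segment (1701-1900)
  h <- query_index(idx, "chr1", 1701, 1701)
  expect_identical(h$feature_id, "tIn")
  # query in the masked (exonic) stretch of tIn returns the gene only
  h2 <- query_index(idx, "chr1", 1650, 1660)
  expect_identical(h2$feature_type, "gene")
  # sequence outside the allowlist
  expect_identical(nrow(suppressWarnings(query_index(idx, "chr9", 1, 100))),
                   0L)
  # masked elements still count toward family membership
  expect_identical(idx$families[family == "RLG00020", member_count], 2L)
  expect_error(build_annotation_index(
    data.table::data.table(element_id = character(), family = character(),
                           chrom = character(), start = integer(),
                           end = integer()),
    idx$elements, list(genes = idx$genes,
                       exons = data.table::data.table(
                         gene_id = character(), chrom = character(),
                         start = integer(), end = integer())),
    character(0)), "allowlist")
})

test_that("round-trip: simulated annotation -> GFF3 -> parse -> identical index", {
  sim <- simulate_annotation(sim_config(), seed = 11)
  dir <- tempfile(); paths <- write_sim_annotation(sim, dir)
  el <- parse_te_gff(paths[["te"]])
  expect_equal(nrow(el), nrow(sim$elements))
  expect_setequal(el$element_id, sim$elements$element_id)
  g <- parse_gene_gff(paths[["genes"]])
  expect_setequal(g$genes$gene_id, sim$genes$genes$gene_id)
  idx1 <- sim_annotation_index(sim)
  idx2 <- build_annotation(paths[["te"]], paths[["genes"]],
                           names(sim$chromosomes))
  expect_identical(
    as.character(GenomicRanges::granges(idx1$features)),
    as.character(GenomicRanges::granges(idx2$features)))
})

test_that("disjoin + mask equal the brute-force per-bp oracle on random sets", {
  for (seed in 1:60) {
    ann <- random_annotation(seed)
    seg <- suppressWarnings(disjoin_te_annotations(ann$elements))
    seg <- subtract_exons(seg, ann$genes$exons)
    own <- oracle_owner_maps(ann$elements, ann$genes$exons, ann$chrom_lens)
    for (ch in names(ann$chrom_lens)) {
      got <- rep(NA_integer_, ann$chrom_lens[[ch]])
      s <- seg[chrom == ch]
      for (i in seq_len(nrow(s)))
        got[s$start[i]:s$end[i]] <- match(s$element_id[i],
                                          ann$elements$element_id)
      expect_identical(got, own[[ch]])
    }
    # conservation: covered bp = input TE bp minus exon bp
    expect_identical(sum(!is.na(unlist(own))),
                     sum(seg$end - seg$start + 1L))
  }
})
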