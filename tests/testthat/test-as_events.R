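two_tx <- function(starts1, ends1, starts2, ends2, strand = "+") {
  genome_annotation(data.frame(
    gene_id = "g", tx_id = c(rep("g.t1", length(starts1)),
                             rep("g.t2", length(starts2))),
    chrom = "c", strand = strand,
    start = c(starts1, starts2), end = c(ends1, ends2)))
}

test_that("exon clusters merge exons and collect junctions", {
  # single transcript, no observed junctions: identity case
  ann <- genome_annotation(data.frame(
    gene_id = "g", tx_id = "t", chrom = "c", strand = "+",
    start = c(0, 200), end = c(100, 300)))
  cl <- build_exon_clusters(ann)[["g"]]
  expect_equal(as.data.frame(cl$members),
               data.frame(start = c(0L, 200L), end = c(100L, 300L)))
  expect_equal(as.data.frame(cl$junctions),
               data.frame(donor = 100L, acceptor = 200L))
  # cassette pair: three junctions, cassette exon among the members
  ann <- two_tx(c(0, 200, 400), c(100, 300, 500), c(0, 400), c(100, 500))
  cl <- build_exon_clusters(ann)[["g"]]
  expect_equal(nrow(cl$junctions), 3L)
  expect_true(any(cl$members$start == 200 & cl$members$end == 300))
})

test_that("observed junctions reannotate clusters by splitting exons", {
  ann <- genome_annotation(data.frame(
    gene_id = "g", tx_id = "t", chrom = "c", strand = "+",
    start = 0, end = 1000))
  f <- tempfile()
  # junction (400, 600) wholly inside the exon, well supported in both groups
  recs <- do.call(rbind, lapply(0:4, function(i) data.frame(
    qname = sprintf("r%d", i), pos1 = 301L + i,
    cigar = sprintf("%dM200N60M", 100L - i))))
  write_fixture_sam(recs, f, chrom = "c")
  reads <- pool_reads(read_sam(f, "CK", 1), read_sam(f, "S", 1))
  jf <- filter_junctions(extract_junctions(reads), 4)
  expect_equal(nrow(jf$junctions), 1L)
  cl <- build_exon_clusters(ann, jf)[["g"]]
  expect_true(any(cl$members$start == 0 & cl$members$end == 400))
  expect_true(any(cl$members$start == 600 & cl$members$end == 1000))
  # the junction is novel RI evidence: intron inside the annotated exon
  ev <- enumerate_events(cl)
  expect_equal(ev$type, "RI")
  expect_equal(c(ev$alt_start, ev$alt_end), c(400L, 600L))
})

test_that("junctions not contained in a gene span are skipped with a message", {
  ann <- genome_annotation(data.frame(
    gene_id = c("g1", "g2"), tx_id = c("t1", "t2"), chrom = "c", strand = "+",
    start = c(0, 5000), end = c(1000, 6000)))
  f <- tempfile()
  recs <- do.call(rbind, lapply(0:4, function(i) data.frame(
    qname = sprintf("r%d", i), pos1 = 801L + i,
    cigar = sprintf("%dM4200N60M", 100L - i))))
  write_fixture_sam(recs, f, chrom = "c")
  reads <- pool_reads(read_sam(f, "CK", 1), read_sam(f, "S", 1))
  jf <- filter_junctions(extract_junctions(reads), 4)
  expect_message(build_exon_clusters(ann, jf), "not contained in any gene span")
})

test_that("event enumeration identifies the canonical configurations", {
  # cassette exon -> exactly one SE event
  ann <- two_tx(c(0, 200, 400), c(100, 300, 500), c(0, 400), c(100, 500))
  ev <- enumerate_events(build_exon_clusters(ann)[["g"]])
  expect_equal(ev$type, "SE")
  expect_equal(c(ev$alt_start, ev$alt_end), c(200L, 300L))
  expect_equal(sort(strsplit(ev$incl_j, ",")[[1]]), c("100-200", "300-400"))
  expect_equal(ev$excl_j, "100-400")

  # shared donor, distinct acceptors on + strand -> A3SS
  ann <- two_tx(c(0, 200), c(100, 300), c(0, 230), c(100, 300))
  ev <- enumerate_events(build_exon_clusters(ann)[["g"]])
  expect_equal(ev$type, "A3SS")
  expect_equal(c(ev$alt_start, ev$alt_end), c(200L, 230L))
  # same shape on - strand -> A5SS
  ann <- two_tx(c(0, 200), c(100, 300), c(0, 230), c(100, 300), strand = "-")
  expect_equal(enumerate_events(build_exon_clusters(ann)[["g"]])$type, "A5SS")

  # shared acceptor, distinct donors on + strand -> A5SS
  ann <- two_tx(c(0, 200), c(100, 300), c(0, 200), c(70, 300))
  ev <- enumerate_events(build_exon_clusters(ann)[["g"]])
  expect_equal(ev$type, "A5SS")
  expect_equal(c(ev$alt_start, ev$alt_end), c(70L, 100L))

  # retained intron
  ann <- two_tx(0, 500, c(0, 300), c(200, 500))
  ev <- enumerate_events(build_exon_clusters(ann)[["g"]])
  expect_equal(ev$type, "RI")
  expect_equal(c(ev$alt_start, ev$alt_end), c(200L, 300L))

  # mutually exclusive exons -> one MXE, no spurious alt-site calls
  ann <- two_tx(c(0, 200, 600), c(100, 300, 700),
                c(0, 400, 600), c(100, 500, 700))
  ev <- enumerate_events(build_exon_clusters(ann)[["g"]])
  expect_equal(ev$type, "MXE")

  # single transcript -> nothing alternative
  ann <- genome_annotation(data.frame(
    gene_id = "g", tx_id = "t", chrom = "c", strand = "+",
    start = c(0, 200), end = c(100, 300)))
  expect_equal(nrow(enumerate_events(build_exon_clusters(ann)[["g"]])), 0L)
})

test_that("enumeration equals the transcript-pair structural oracle", {
  set.seed(41)
  types <- c("SE", "A5SS", "A3SS", "RI", "MXE")
  for (i in 1:150) {
    ann <- random_two_tx_gene(sample(types, 1))
    got <- enumerate_events(build_exon_clusters(ann)[["gX"]])
    want <- oracle_events_two_tx(ann)
    expect_equal(as.data.frame(got[order(type, alt_start, alt_end),
                                   .(type, alt_start, alt_end)]),
                 as.data.frame(want), info = paste("case", i))
  }
})

test_that("isoform support counting fills the documented tables", {
  # cassette gene, reads built by hand: inclusion junctions supported by
  # CK-heavy counts, skip junction S-heavy
  ann <- two_tx(c(0, 200, 400), c(100, 300, 500), c(0, 400), c(100, 500))
  f1 <- tempfile(); f2 <- tempfile()
  incl1 <- data.frame(qname = sprintf("i%d", 1:10), pos1 = 51L + 0:9,
                      cigar = sprintf("%dM100N30M", 50:41))
  incl2 <- data.frame(qname = sprintf("j%d", 1:10), pos1 = 251L + 0:9,
                      cigar = sprintf("%dM100N30M", 50:41))
  skip <- data.frame(qname = sprintf("k%d", 1:5), pos1 = 51L + 0:4,
                     cigar = sprintf("%dM300N30M", 50:46))
  write_fixture_sam(rbind(incl1, incl2, skip), f1, chrom = "c")
  write_fixture_sam(rbind(incl1[1:5, ], incl2[1:5, ], skip), f2, chrom = "c")
  reads <- pool_reads(read_sam(f1, "CK", 1), read_sam(f2, "S", 1))
  jf <- filter_junctions(extract_junctions(reads), 4)
  ev <- enumerate_events(build_exon_clusters(ann, jf)[["g"]])
  ev <- count_isoform_support(ev[type == "SE"], jf, reads, ann)
  expect_equal(ev$incl_CK, 20L)
  expect_equal(ev$excl_CK, 5L)
  expect_equal(ev$incl_S, 10L)
  expect_equal(ev$excl_S, 5L)
  # alt coverage counts reads overlapping the cassette exon: both
  # inclusion-side read sets touch [200, 300)
  expect_equal(ev$alt_CK, 20L)
  expect_gt(ev$gene_CK, ev$alt_CK)

  # zero-read group yields all-zero counts
  reads_ck <- read_sam(f1, "CK", 1)
  jt2 <- extract_junctions(reads_ck)
  ev2 <- enumerate_events(build_exon_clusters(ann, jt2)[["g"]])
  ev2 <- count_isoform_support(ev2[type == "SE"], jt2, reads_ck, ann)
  expect_equal(ev2$incl_S + ev2$excl_S + ev2$alt_S + ev2$gene_S, 0L)
})

test_that("junction and coverage tests follow the 2x2 construction", {
  ev <- data.table::data.table(
    event_id = c("e1", "e2", "e3"), incl_CK = c(20L, 10L, 0L),
    excl_CK = c(5L, 10L, 0L), incl_S = c(5L, 10L, 0L), excl_S = c(20L, 10L, 0L),
    alt_CK = c(30L, 10L, 0L), alt_S = c(10L, 20L, 0L),
    gene_CK = c(100L, 100L, 0L), gene_S = c(100L, 200L, 0L))
  out <- junction_test(ev)
  expect_equal(out$p1[1], oracle_fisher(20, 5, 5, 20))
  expect_equal(out$p1[2], 1)
  expect_equal(out$p1[3], 1)
  out <- coverage_test(ev)
  expect_equal(out$p2[1], oracle_fisher(30, 70, 10, 90))
  expect_equal(out$p2[2], oracle_fisher(10, 90, 20, 180))
  expect_equal(out$p2[3], 1)
})

test_that("call_events combines, adjusts, gates and sorts", {
  ev <- data.table::data.table(event_id = "e", gene_id = "g", type = "SE",
                               p1 = 0.02, p2 = 0.04)
  res <- call_events(ev)
  expect_equal(res$events$p_combined, 0.03)
  expect_equal(res$events$q, 0.03)
  expect_true(res$events$significant)

  ev <- data.table::data.table(event_id = c("a", "b"), gene_id = "g",
                               type = c("SE", "RI"), p1 = 1, p2 = 1)
  res <- call_events(ev)
  expect_false(any(res$events$significant))

  # MXE reporting is off by default and excluded from the BH family
  ev <- data.table::data.table(event_id = c("a", "b"), gene_id = "g",
                               type = c("SE", "MXE"), p1 = c(0.04, 0.001),
                               p2 = c(0.04, 0.001))
  res <- call_events(ev)
  expect_equal(res$events$event_id, "a")
  expect_equal(res$events$q, 0.04)
  res <- call_events(ev, report_mxe = TRUE)
  expect_equal(nrow(res$events), 2L)
  # empty event collection is fine
  expect_equal(nrow(call_events(ev[0])$events), 0L)
})

test_that("swapping CK and S labels leaves all p-values unchanged", {
  cfg <- simulation_config(seed = 43, n_genes = 25, depth_per_condition = 3e4)
  ann <- simulate_annotation(cfg)
  tr <- truth_table(ann, cfg)
  reads <- simulate_all_reads(ann, tr, cfg)
  res1 <- detect_as_events(ann, reads)
  swapped <- data.table::copy(data.table::as.data.table(reads))
  swapped[, group := ifelse(group == "CK", "S", "CK")]
  reads2 <- junctionAS:::.aligned_reads(swapped, attr(reads, "n_records"))
  res2 <- detect_as_events(ann, reads2)
  expect_equal(res1$events[order(event_id), .(event_id, p1, p2, p_combined, q)],
               res2$events[order(event_id), .(event_id, p1, p2, p_combined, q)])
})

test_that("stronger planted PSI shifts never weaken the combined evidence", {
  med_logp <- sapply(c(0.1, 0.25, 0.4), function(dpsi) {
    cfg <- simulation_config(seed = 44, n_genes = 40, depth_per_condition = 1e5,
                             frac_as_genes = 1, psi_ck = 0.5 - dpsi / 2,
                             psi_s = 0.5 + dpsi / 2, frac_de_genes = 0)
    ann <- simulate_annotation(cfg)
    tr <- truth_table(ann, cfg)
    res <- detect_as_events(ann, simulate_all_reads(ann, tr, cfg))
    stats::median(-log10(pmax(res$events$p_combined, 1e-300)))
  })
  expect_true(all(diff(med_logp) >= 0))
})
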