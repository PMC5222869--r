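# Independent oracles and fixture builders shared across the test files.
# Each oracle recomputes a quantity from first principles, deliberately
# avoiding the code path it checks.

# Brute-force two-sided Fisher: enumerate all tables with the observed
# margins, probabilities from binomial coefficients directly.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (n == 0) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- exp(lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1))
  p_obs <- pr[ks == a]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

# Naive step-up BH straight from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[o[i]] <- min(1, min(p[o[js]] * m / js))
  }
  q
}

# ---- random two-transcript gene generator + structural oracle ----------

# Builds one gene with two transcripts realizing a random AS structure.
# Coordinate scales are independent of the package simulator.
random_two_tx_gene <- function(type = c("SE", "A5SS", "A3SS", "RI", "MXE"),
                               strand = sample(c("+", "-"), 1L)) {
  type <- match.arg(type)
  el <- function(k) sample(50:150, k, replace = TRUE)
  il <- function(k) sample(30:100, k, replace = TRUE)
  off <- sample(12:40, 1L)
  g <- "gX"
  mk <- function(starts1, ends1, starts2, ends2) {
    genome_annotation(data.table::data.table(
      gene_id = g,
      tx_id = c(rep("gX.t1", length(starts1)), rep("gX.t2", length(starts2))),
      chrom = "chrT", strand = strand,
      start = c(starts1, starts2), end = c(ends1, ends2)))
  }
  if (type == "SE") {
    e <- el(3); i <- il(2)
    s1 <- 100; e1 <- s1 + e[1]; s2 <- e1 + i[1]; e2 <- s2 + e[2]
    s3 <- e2 + i[2]; e3 <- s3 + e[3]
    ann <- mk(c(s1, s2, s3), c(e1, e2, e3), c(s1, s3), c(e1, e3))
  } else if (type == "RI") {
    e <- el(2); i <- il(1)
    s1 <- 100; e1 <- s1 + e[1]; s2 <- e1 + i[1]; e2 <- s2 + e[2]
    ann <- mk(s1, e2, c(s1, s2), c(e1, e2))
  } else if (type == "MXE") {
    e <- el(4); i <- il(3)
    s1 <- 100; e1 <- s1 + e[1]
    sA <- e1 + i[1]; eA <- sA + e[2]
    sB <- eA + i[2]; eB <- sB + e[3]
    s4 <- eB + i[3]; e4 <- s4 + e[4]
    ann <- mk(c(s1, sA, s4), c(e1, eA, e4), c(s1, sB, s4), c(e1, eB, e4))
  } else {
    # A5SS / A3SS: which genomic side varies follows the strand
    varies_left <- (type == "A5SS") == (strand == "+")
    e <- el(2); i <- il(1)
    if (varies_left) {
      s1 <- 100; dS <- s1 + e[1]; dL <- dS + off
      s2 <- dL + i[1]; e2 <- s2 + e[2]
      ann <- mk(c(s1, s2), c(dL, e2), c(s1, s2), c(dS, e2))
    } else {
      s1 <- 100; e1 <- s1 + e[1]
      aL <- e1 + i[1]; aS <- aL + off
      e2 <- aS + e[2]
      ann <- mk(c(s1, aL), c(e1, e2), c(s1, aS), c(e1, e2))
    }
  }
  ann
}

# Events implied by direct structural comparison of the two transcripts of
# a gene (no exon clustering, no junction table).  Returns a data.table of
# (type, alt_start, alt_end) rows.
oracle_events_two_tx <- function(annotation) {
  x <- data.table::as.data.table(annotation)
  strand <- x$strand[1L]
  txs <- split(x[, .(start, end)], x$tx_id)
  stopifnot(length(txs) == 2L)
  juncs <- lapply(txs, function(e) {
    e <- e[order(start)]
    if (nrow(e) < 2L) data.table::data.table(d = integer(), a = integer())
    else data.table::data.table(d = e$end[-nrow(e)], a = e$start[-1L])
  })
  res <- list()
  add <- function(type, s, e) res[[length(res) + 1L]] <<-
    data.table::data.table(type = type, alt_start = s, alt_end = e)
  for (ord in list(1:2, 2:1)) {
    A <- txs[[ord[1]]][order(start)]; B <- txs[[ord[2]]][order(start)]
    JA <- juncs[[ord[1]]]; JB <- juncs[[ord[2]]]
    has <- function(J, d, a) any(J$d == d & J$a == a)
    # SE: internal exon of A, skipped by a junction of B
    if (nrow(A) >= 3L) for (k in 2:(nrow(A) - 1L)) {
      s <- A$start[k]; e <- A$end[k]
      L <- JA$d[JA$a == s]; R <- JA$a[JA$d == e]
      for (l in L) for (r in R) if (has(JB, l, r)) add("SE", s, e)
    }
    # RI: junction of A inside an exon of B
    for (k in seq_len(nrow(JA)))
      if (any(B$start < JA$d[k] & B$end > JA$a[k])) add("RI", JA$d[k], JA$a[k])
    # MXE: exon of A and exon of B, mutually exclusive, shared neighbours;
    # recorded once with the left exon as the alternative region
    for (k1 in seq_len(nrow(A))) for (k2 in seq_len(nrow(B))) {
      s1 <- A$start[k1]; e1 <- A$end[k1]; s2 <- B$start[k2]; e2 <- B$end[k2]
      if (e1 > s2 && e2 > s1) next        # overlapping
      if (any(B$start == s1 & B$end == e1)) next  # shared exon
      if (any(A$start == s2 & A$end == e2)) next
      Ls <- intersect(JA$d[JA$a == s1], JB$d[JB$a == s2])
      Rs <- intersect(JA$a[JA$d == e1], JB$a[JB$d == e2])
      if (length(Ls) && length(Rs) && s1 < s2) add("MXE", s1, e1)
    }
    # alternative splice sites: a junction of A and a junction of B sharing
    # exactly one intron end, not explained by an SE or MXE configuration
    for (k1 in seq_len(nrow(JA))) for (k2 in seq_len(nrow(JB))) {
      d1 <- JA$d[k1]; a1 <- JA$a[k1]; d2 <- JB$d[k2]; a2 <- JB$a[k2]
      if (d1 == d2 && a1 < a2) {
        # SE: A carries exon [a1, e) spliced onward to a2
        eA <- A$end[A$start == a1]
        if (any(vapply(eA, function(x) has(JA, x, a2), TRUE))) next
        # MXE: exons at a1 (in A) and a2 (in B) joined to a common acceptor
        eB <- B$end[B$start == a2]
        rA <- JA$a[JA$d %in% eA]; rB <- JB$a[JB$d %in% eB]
        if (length(intersect(rA, rB))) next
        add(if (strand == "+") "A3SS" else "A5SS", a1, a2)
      }
      if (a1 == a2 && d1 < d2) {
        # SE: B carries exon [s, d2) spliced from d1
        sB <- B$start[B$end == d2]
        if (any(vapply(sB, function(x) has(JB, d1, x), TRUE))) next
        # MXE mirror: exons ending at d1 (in A) and d2 (in B) sharing a donor
        sA <- A$start[A$end == d1]
        lA <- JA$d[JA$a %in% sA]; lB <- JB$d[JB$a %in% sB]
        if (length(intersect(lA, lB))) next
        add(if (strand == "+") "A5SS" else "A3SS", d1, d2)
      }
    }
  }
  if (!length(res))
    return(data.table::data.table(type = character(), alt_start = integer(),
                                  alt_end = integer()))
  unique(data.table::rbindlist(res))[order(type, alt_start, alt_end)]
}

# ---- SAM fixture builder -----------------------------------------------

# records: data.frame(qname, pos1, cigar); minimal valid SAM text.
write_fixture_sam <- function(records, path, chrom = "chrT", len = 100000L,
                              flag = 0L) {
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, len),
             sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                     records$qname,
                     if (length(flag) == 1L) rep(flag, nrow(records)) else flag,
                     chrom, records$pos1, records$cigar))
  writeLines(lines, path)
  path
}

# Pool simulated reads for both groups and all replicates of a config.
simulate_all_reads <- function(ann, tr, cfg) {
  pool_reads(unlist(lapply(c("CK", "S"), function(g)
    lapply(seq_len(cfg$n_replicates_per_condition), function(r)
      simulate_reads(ann, tr, cfg, g, r))), recursive = FALSE))
}
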