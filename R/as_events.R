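# Exon-cluster reconstruction and alternative-splicing event detection.
#
# Per gene, exons are unioned across transcripts into a cluster, the gene's
# annotation-derived junctions are merged with observed (filtered) junctions,
# and observed junction boundaries falling inside merged exons split them
# ("reannotation").  Events are enumerated from the cluster's junction set:
#   SE    internal exon E with junctions L->E, E->R and the skip L->R;
#   A5SS/ two junctions sharing one intron end; the label depends on which
#   A3SS  side varies and on the strand;
#   RI    a junction whose intron lies inside an exon of some transcript;
#   MXE   two exons never joined to each other, sharing outer neighbours.
# Each event is scored with two Fisher tests -- CK-vs-S junction counts
# (p1) and alternative-region vs gene coverage (p2) -- combined by a
# weighted arithmetic mean and BH-adjusted across the reported family.

.jkey <- function(donor, acceptor) paste0(donor, "-", acceptor)

#' Build per-gene exon clusters
#'
#' Unions each gene's exons across transcripts (merging overlaps), attaches
#' the gene's annotation-implied junctions plus any observed junctions
#' contained in the gene span, and splits member exons at observed junction
#' boundaries that fall inside them.  Observed junctions not contained in
#' any single gene span (e.g. spanning two genes) are reported via
#' `message()` and skipped.
#'
#' @param annotation a [genome_annotation()].
#' @param junctions optional filtered `junction_table` of observed
#'   junctions; `NULL` uses annotation junctions only.
#' @return named list of `exon_cluster` objects (one per gene), each a list
#'   with `gene_id`, `chrom`, `strand`, `members` (split merged exons),
#'   `junctions` (donor/acceptor table), `tx_exons` (the gene's annotated
#'   exons) and the gene span.
#' @export
build_exon_clusters <- function(annotation, junctions = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  spans <- .gene_spans(annotation)
  annj <- .annotation_junctions(annotation)
  obs <- if (is.null(junctions)) {
    data.table(chrom = character(), donor = integer(), acceptor = integer())
  } else {
    stopifnot(inherits(junctions, "junction_table"))
    junctions$junctions[, .(chrom, donor, acceptor)]
  }
  if (nrow(obs)) {
    hit <- spans[obs, on = .(chrom, gstart <= donor, gend >= acceptor),
                 .(chrom = i.chrom, donor = i.donor, acceptor = i.acceptor,
                   gene_id = x.gene_id), allow.cartesian = TRUE]
    unassigned <- hit[is.na(gene_id), .(chrom, donor, acceptor)]
    obs_assigned <- hit[!is.na(gene_id)]
    if (nrow(unassigned))
      message(nrow(unique(unassigned)),
              " observed junction(s) not contained in any gene span; skipped")
  } else {
    obs_assigned <- data.table(chrom = character(), donor = integer(),
                               acceptor = integer(), gene_id = character())
  }
  ann <- as.data.table(annotation)
  clusters <- vector("list", nrow(spans))
  names(clusters) <- spans$gene_id
  for (i in seq_len(nrow(spans))) {
    g <- spans$gene_id[i]
    tx_exons <- ann[gene_id == g, .(tx_id, start, end)]
    merged <- .merge_intervals(tx_exons$start, tx_exons$end)
    j <- unique(rbind(annj[gene_id == g, .(donor, acceptor)],
                      obs_assigned[gene_id == g, .(donor, acceptor)]))
    setorder(j, donor, acceptor)
    # reannotation: split merged exons at interior junction boundaries
    bounds <- sort(unique(c(j$donor, j$acceptor)))
    members <- merged[, {
      cuts <- bounds[bounds > start & bounds < end]
      s <- c(start, cuts); e <- c(cuts, end)
      .(start = s, end = e)
    }, by = .(.id = seq_len(nrow(merged)))][, .(start, end)]
    clusters[[i]] <- structure(
      list(gene_id = g, chrom = spans$chrom[i], strand = spans$strand[i],
           members = members, junctions = j, tx_exons = tx_exons,
           gstart = spans$gstart[i], gend = spans$gend[i]),
      class = "exon_cluster")
  }
  clusters
}

#' Enumerate candidate alternative-splicing events in one exon cluster
#'
#' Applies the structural definitions of SE, A5SS, A3SS, RI and MXE to the
#' cluster's junction set (see the package vignette for the exact rules,
#' including the suppression of alternative-splice-site calls that are
#' fully explained by an SE or MXE configuration).  Counts are left
#' unfilled.
#'
#' @param cluster an `exon_cluster` from [build_exon_clusters()].
#' @return data.table of candidate events (possibly empty): `event_id`,
#'   `gene_id`, `type`, `chrom`, `strand`, `alt_start`, `alt_end`,
#'   `incl_j`, `excl_j` (comma-separated `donor-acceptor` keys).
#' @export
enumerate_events <- function(cluster) {
  stopifnot(inherits(cluster, "exon_cluster"))
  j <- cluster$junctions
  mem <- cluster$members
  ev <- list()
  jset <- .jkey(j$donor, j$acceptor)
  has_j <- function(d, a) .jkey(d, a) %in% jset

  # SE: exon [s,e) with incoming L->s, outgoing e->R and skip L->R
  if (nrow(j) >= 3L && nrow(mem)) {
    for (k in seq_len(nrow(mem))) {
      s <- mem$start[k]; e <- mem$end[k]
      lefts <- j[acceptor == s, donor]
      rights <- j[donor == e, acceptor]
      if (!length(lefts) || !length(rights)) next
      for (L in lefts) for (R in rights) if (has_j(L, R)) {
        ev[[length(ev) + 1L]] <- data.table(
          type = "SE", alt_start = s, alt_end = e,
          incl_j = paste(.jkey(L, s), .jkey(e, R), sep = ","),
          excl_j = .jkey(L, R))
      }
    }
  }

  # MXE: exons E1, E2 (disjoint, unlinked) sharing a common donor L and a
  # common acceptor R
  if (nrow(mem) >= 2L && nrow(j) >= 4L) {
    for (k1 in seq_len(nrow(mem) - 1L)) for (k2 in (k1 + 1L):nrow(mem)) {
      s1 <- mem$start[k1]; e1 <- mem$end[k1]
      s2 <- mem$start[k2]; e2 <- mem$end[k2]
      if (s2 < e1) next                       # overlapping
      if (has_j(e1, s2)) next                 # linked -> not mutually exclusive
      Ls <- intersect(j[acceptor == s1, donor], j[acceptor == s2, donor])
      Rs <- intersect(j[donor == e1, acceptor], j[donor == e2, acceptor])
      if (length(Ls) && length(Rs)) {
        L <- min(Ls); R <- max(Rs)
        ev[[length(ev) + 1L]] <- data.table(
          type = "MXE", alt_start = s1, alt_end = e1,
          incl_j = paste(.jkey(L, s1), .jkey(e1, R), sep = ","),
          excl_j = paste(.jkey(L, s2), .jkey(e2, R), sep = ","))
      }
    }
  }

  # RI: junction whose intron is contained in an exon of some transcript
  if (nrow(j)) {
    tx <- cluster$tx_exons
    for (k in seq_len(nrow(j))) {
      d <- j$donor[k]; a <- j$acceptor[k]
      if (any(tx$start < d & tx$end > a)) {
        ev[[length(ev) + 1L]] <- data.table(
          type = "RI", alt_start = d, alt_end = a,
          incl_j = "", excl_j = .jkey(d, a))
      }
    }
  }

  # Alternative splice sites.  Donor-shared pair (d,a1),(d,a2), a1 < a2:
  # the acceptor varies (genomic right) -> A3SS on '+', A5SS on '-'.
  # Suppressed when explained by SE (exon [a1,x) with junction x->a2) or
  # by MXE (exons at a1 and a2 both linked to a common downstream acceptor,
  # unlinked to each other).
  if (nrow(j) >= 2L) {
    for (d in unique(j[duplicated(donor), donor])) {
      acc <- sort(j[donor == d, acceptor])
      for (i1 in seq_len(length(acc) - 1L)) for (i2 in (i1 + 1L):length(acc)) {
        a1 <- acc[i1]; a2 <- acc[i2]
        e1s <- mem[start == a1, end]
        se_like <- any(vapply(e1s, function(x) has_j(x, a2), TRUE))
        mxe_like <- FALSE
        e2s <- mem[start == a2, end]
        if (length(e1s) && length(e2s)) {
          r1 <- j[donor %in% e1s, acceptor]
          r2 <- j[donor %in% e2s, acceptor]
          linked <- any(vapply(e1s, function(x) has_j(x, a2), TRUE))
          mxe_like <- !linked && length(intersect(r1, r2)) > 0L
        }
        if (se_like || mxe_like) next
        lab <- if (cluster$strand == "+") "A3SS" else "A5SS"
        ev[[length(ev) + 1L]] <- data.table(
          type = lab, alt_start = a1, alt_end = a2,
          incl_j = .jkey(d, a1), excl_j = .jkey(d, a2))
      }
    }
    # Acceptor-shared pair (d1,a),(d2,a), d1 < d2: donor varies (genomic
    # left) -> A5SS on '+', A3SS on '-'; suppression mirrored.
    for (a in unique(j[duplicated(acceptor), acceptor])) {
      don <- sort(j[acceptor == a, donor])
      for (i1 in seq_len(length(don) - 1L)) for (i2 in (i1 + 1L):length(don)) {
        d1 <- don[i1]; d2 <- don[i2]
        e2s <- mem[end == d2, start]
        se_like <- any(vapply(e2s, function(x) has_j(d1, x), TRUE))
        mxe_like <- FALSE
        e1s <- mem[end == d1, start]
        if (length(e1s) && length(e2s)) {
          l1 <- j[acceptor %in% e1s, donor]
          l2 <- j[acceptor %in% e2s, donor]
          linked <- any(vapply(e2s, function(x) has_j(d1, x), TRUE))
          mxe_like <- !linked && length(intersect(l1, l2)) > 0L
        }
        if (se_like || mxe_like) next
        lab <- if (cluster$strand == "+") "A5SS" else "A3SS"
        ev[[length(ev) + 1L]] <- data.table(
          type = lab, alt_start = d1, alt_end = d2,
          incl_j = .jkey(d2, a), excl_j = .jkey(d1, a))
      }
    }
  }

  if (!length(ev))
    return(data.table(event_id = character(), gene_id = character(),
                      type = character(), chrom = character(),
                      strand = character(), alt_start = integer(),
                      alt_end = integer(), incl_j = character(),
                      excl_j = character()))
  out <- rbindlist(ev)
  out[, `:=`(gene_id = cluster$gene_id, chrom = cluster$chrom,
             strand = cluster$strand)]
  out <- unique(out, by = c("type", "alt_start", "alt_end", "incl_j", "excl_j"))
  out[, event_id := sprintf("%s|%s|%s:%d-%d|%s", gene_id, type, chrom,
                            alt_start, alt_end, excl_j)]
  setcolorder(out, c("event_id", "gene_id", "type", "chrom", "strand",
                     "alt_start", "alt_end", "incl_j", "excl_j"))
  setorder(out, event_id)
  out[]
}

# Expand "d1-a1,d2-a2" strings into one row per junction key.
.expand_jkeys <- function(events, col) {
  x <- events[, .(event_id, keys = get(col), chrom)]
  x <- x[nzchar(keys)]
  if (!nrow(x)) return(data.table(event_id = character(), chrom = character(),
                                  donor = integer(), acceptor = integer()))
  x <- x[, .(key = strsplit(keys, ",", fixed = TRUE)[[1L]]), by = .(event_id, chrom)]
  parts <- tstrsplit(x$key, "-", fixed = TRUE)
  x[, `:=`(donor = as.integer(parts[[1L]]), acceptor = as.integer(parts[[2L]]),
           key = NULL)]
  x
}

#' Fill inclusion/exclusion and coverage counts for enumerated events
#'
#' Per sample group (replicates pooled): the inclusion count sums the
#' non-redundant junction-read counts over the event's inclusion junctions
#' (for RI, reads overlapping the retained intron interior by at least
#' `min_anchor` bases); the exclusion count does the same over the
#' exclusion junctions.  Also fills the alternative-region read coverage
#' and the gene exonic-union read coverage used by the second Fisher test.
#'
#' @param events event table from [enumerate_events()] (rows from several
#'   clusters may be concatenated).
#' @param junctions the filtered `junction_table` used for enumeration.
#' @param reads pooled `aligned_reads` of both groups.
#' @param annotation the [genome_annotation()].
#' @param min_anchor minimum intron-interior overlap for RI inclusion
#'   evidence (same scale as the junction anchor filter).
#' @return the event table with count columns `incl_CK`, `excl_CK`,
#'   `incl_S`, `excl_S`, `alt_CK`, `alt_S`, `gene_CK`, `gene_S` added.
#' @export
count_isoform_support <- function(events, junctions, reads, annotation,
                                  min_anchor = 7L) {
  stopifnot(inherits(junctions, "junction_table"),
            inherits(reads, "aligned_reads"),
            inherits(annotation, "genome_annotation"))
  events <- copy(as.data.table(events))
  zero <- function() integer(nrow(events))
  events[, `:=`(incl_CK = zero(), excl_CK = zero(), incl_S = zero(),
                excl_S = zero(), alt_CK = zero(), alt_S = zero(),
                gene_CK = zero(), gene_S = zero())]
  if (!nrow(events)) return(events[])

  jsum <- junctions$junctions
  for (col in c("incl_j", "excl_j")) {
    keys <- .expand_jkeys(events, col)
    if (nrow(keys)) {
      # annotation-derived junctions may carry no surviving read support;
      # they count zero rather than erroring
      agg <- jsum[keys, on = c("chrom", "donor", "acceptor")][
        , .(CK = sum(nr_CK, na.rm = TRUE), S = sum(nr_S, na.rm = TRUE)),
        by = event_id]
      tgt <- if (col == "incl_j") c("incl_CK", "incl_S") else c("excl_CK", "excl_S")
      events[agg, on = "event_id", (tgt) := .(i.CK, i.S)]
    }
  }

  b <- copy(as.data.table(reads))  # setkey below must not reorder the input
  if (nrow(b)) {
    setkey(b, chrom, bstart, bend)
    # alternative-region coverage (>= 1 bp overlap; RI inclusion needs
    # >= min_anchor bp inside the intron interior)
    reg <- events[, .(event_id, type, chrom, rstart = alt_start, rend = alt_end)]
    ov <- foverlaps(reg, b,
                    by.x = c("chrom", "rstart", "rend"),
                    by.y = c("chrom", "bstart", "bend"), nomatch = NULL)
    if (nrow(ov)) {
      ov[, olap := pmin(rend, bend) - pmax(rstart, bstart)]
      ov <- ov[olap > 0L]
      altc <- ov[, .(n = uniqueN(read_id)), by = .(event_id, group)]
      events[altc[group == "CK"], on = "event_id", alt_CK := i.n]
      events[altc[group == "S"], on = "event_id", alt_S := i.n]
      ric <- ov[type == "RI" & olap >= min_anchor,
                .(n = uniqueN(read_id)), by = .(event_id, group)]
      events[ric[group == "CK"], on = "event_id", incl_CK := i.n]
      events[ric[group == "S"], on = "event_id", incl_S := i.n]
    }
    # gene exonic-union coverage
    uni <- .exonic_union(annotation)
    genes_needed <- unique(events$gene_id)
    uni <- uni[gene_id %in% genes_needed]
    ovg <- foverlaps(uni, b,
                     by.x = c("chrom", "ustart", "uend"),
                     by.y = c("chrom", "bstart", "bend"), nomatch = NULL)
    if (nrow(ovg)) {
      ovg <- ovg[pmin(uend, bend) - pmax(ustart, bstart) > 0L]
      gc <- ovg[, .(n = uniqueN(read_id)), by = .(gene_id, group)]
      events[gc[group == "CK"], on = "gene_id", gene_CK := i.n]
      events[gc[group == "S"], on = "gene_id", gene_S := i.n]
    }
  }
  events[]
}

#' Junction-count Fisher test (first P-value)
#'
#' `p1 = fisher_exact_2x2([[incl_CK, excl_CK], [incl_S, excl_S]])`; an
#' all-zero table carries no evidence and yields 1.
#'
#' @param events counted event table from [count_isoform_support()].
#' @return the table with a `p1` column.
#' @export
junction_test <- function(events) {
  events <- copy(as.data.table(events))
  events[, p1 := vapply(seq_len(.N), function(i)
    fisher_exact_2x2(c(incl_CK[i], excl_CK[i], incl_S[i], excl_S[i])), 0)]
  events[]
}

#' Coverage Fisher test (second P-value)
#'
#' `p2 = fisher_exact_2x2([[alt_CK, gene_CK - alt_CK], [alt_S, gene_S -
#' alt_S]])` with the gene-minus-alt cells floored at zero; zero gene
#' coverage in both groups yields 1.
#'
#' @param events counted event table.
#' @return the table with a `p2` column.
#' @export
coverage_test <- function(events) {
  events <- copy(as.data.table(events))
  events[, p2 := vapply(seq_len(.N), function(i)
    fisher_exact_2x2(c(alt_CK[i], max(gene_CK[i] - alt_CK[i], 0L),
                       alt_S[i], max(gene_S[i] - alt_S[i], 0L))), 0)]
  events[]
}

#' Combine, adjust and gate event P-values
#'
#' Combines `p1` and `p2` by the weighted arithmetic mean, BH-adjusts the
#' combined P-values over the reported family (MXE rows are dropped first
#' unless `report_mxe = TRUE`), flags events with `q < fdr_threshold` and
#' sorts by `q` then `event_id`.
#'
#' @param events tested event table (columns `p1`, `p2`).
#' @param w1,w2 combination weights.
#' @param fdr_threshold FDR gate (default 0.05).
#' @param report_mxe include mutually-exclusive-exon events in the
#'   reported (and adjusted) family?
#' @return an `as_result`: list with `events` (with `p_combined`, `q`,
#'   `significant`), `thresholds`, and `counts_by_type` over significant
#'   events.
#' @export
call_events <- function(events, w1 = 0.5, w2 = 0.5, fdr_threshold = 0.05,
                        report_mxe = FALSE) {
  events <- copy(as.data.table(events))
  if (!report_mxe && nrow(events)) events <- events[type != "MXE"]
  if (nrow(events)) {
    events[, p_combined := combine_pvalues(p1, p2, w1, w2)]
    events[, q := bh_fdr(p_combined)]
    events[, significant := q < fdr_threshold]
    setorder(events, q, event_id)
  } else {
    events[, `:=`(p_combined = numeric(0), q = numeric(0),
                  significant = logical(0))]
  }
  sig <- events[significant == TRUE]
  structure(list(events = events[],
                 thresholds = list(w1 = w1, w2 = w2,
                                   fdr_threshold = fdr_threshold,
                                   report_mxe = report_mxe),
                 counts_by_type = if (nrow(sig)) table(sig$type) else table(character())),
            class = "as_result")
}

#' @export
print.as_result <- function(x, ...) {
  cat(sprintf("as_result: %d events tested, %d significant (FDR < %g)\n",
              nrow(x$events), sum(x$events$significant),
              x$thresholds$fdr_threshold))
  if (length(x$counts_by_type)) print(x$counts_by_type)
  invisible(x)
}

#' Run the full alternative-splicing detector
#'
#' Convenience wrapper: junction extraction and filtering, exon-cluster
#' reconstruction, event enumeration, counting, both Fisher tests,
#' P-value combination and FDR gating.
#'
#' @param annotation a [genome_annotation()].
#' @param reads pooled `aligned_reads` covering both CK and S groups.
#' @param min_anchor junction anchor threshold (bp).
#' @param min_nonredundant per-group non-redundant support threshold.
#' @param w1,w2 P-value combination weights.
#' @param fdr_threshold FDR gate.
#' @param report_mxe report MXE events?
#' @return an `as_result` with an extra `stats` element of pipeline stage
#'   counts.
#' @export
detect_as_events <- function(annotation, reads, min_anchor = 7L,
                             min_nonredundant = 4L, w1 = 0.5, w2 = 0.5,
                             fdr_threshold = 0.05, report_mxe = FALSE) {
  jt <- extract_junctions(reads, min_anchor = min_anchor)
  jf <- filter_junctions(jt, min_nonredundant = min_nonredundant)
  clusters <- build_exon_clusters(annotation, jf)
  events <- rbindlist(lapply(clusters, enumerate_events))
  events <- count_isoform_support(events, jf, reads, annotation,
                                  min_anchor = min_anchor)
  events <- coverage_test(junction_test(events))
  res <- call_events(events, w1 = w1, w2 = w2, fdr_threshold = fdr_threshold,
                     report_mxe = report_mxe)
  res$stats <- list(
    reads = uniqueN(as.data.table(reads)$read_id),
    records_parsed = attr(reads, "n_records"),
    junction_observations = jt$n_observations_raw,
    anchor_failed = jt$n_observations_anchor_fail,
    junctions_unfiltered = nrow(jt$junctions),
    junctions_retained = nrow(jf$junctions),
    clusters = length(clusters),
    events_enumerated = nrow(events),
    events_significant = sum(res$events$significant))
  res
}

#' Write an AS result to tab-separated text
#'
#' @param result an `as_result`.
#' @param path output path.
#' @param extra named character vector folded into the commented header.
#' @export
write_as_result <- function(result, path, extra = c()) {
  stopifnot(inherits(result, "as_result"))
  th <- result$thresholds
  hdr <- c("# junctionAS events table",
           sprintf("# version: %s", as.character(packageVersion("junctionAS"))),
           sprintf("# weights: %g,%g", th$w1, th$w2),
           sprintf("# fdr_threshold: %g", th$fdr_threshold),
           if (length(extra)) sprintf("# %s: %s", names(extra), extra))
  writeLines(hdr, path)
  fwrite(result$events, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(NULL)
}
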