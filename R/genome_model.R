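# Gene/transcript/exon data model.
#
# Internally every interval is 0-based half-open [start, end); the GFF3
# boundary converts to and from the 1-based closed convention of the format.
# An annotation is a data.table of exon rows (gene_id, tx_id, chrom, strand,
# start, end) wrapped in the "genome_annotation" class; all higher stages
# (simulation, clustering, counting) work off this one table.

#' Construct a genome annotation from an exon table
#'
#' @param exons a data.frame with columns `gene_id`, `tx_id`, `chrom`,
#'   `strand`, `start`, `end`; coordinates 0-based half-open.
#' @return a `genome_annotation` object (a keyed data.table).
#' @export
genome_annotation <- function(exons) {
  req <- c("gene_id", "tx_id", "chrom", "strand", "start", "end")
  if (!all(req %in% names(exons)))
    stop("exon table must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  dt <- as.data.table(exons)[, .(
    gene_id = as.character(gene_id), tx_id = as.character(tx_id),
    chrom = as.character(chrom), strand = as.character(strand),
    start = as.integer(start), end = as.integer(end))]
  if (nrow(dt)) {
    if (any(!dt$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'", call. = FALSE)
    if (any(dt$start < 0L) || any(dt$end <= dt$start))
      stop("exon coordinates must satisfy 0 <= start < end", call. = FALSE)
    setorder(dt, gene_id, tx_id, start)
    # one chrom/strand per gene; tx ids unique genome-wide
    g <- dt[, .(nc = uniqueN(chrom), ns = uniqueN(strand)), by = gene_id]
    if (any(g$nc > 1L) || any(g$ns > 1L))
      stop("all exons of a gene must share chrom and strand", call. = FALSE)
    t2g <- unique(dt[, .(tx_id, gene_id)])
    if (anyDuplicated(t2g$tx_id))
      stop("transcript ids must be unique genome-wide", call. = FALSE)
    gap <- dt[, .(bad = any(start[-1L] < end[-.N] + 1L)), by = tx_id]
    if (any(gap$bad))
      stop("exons within a transcript must be separated by >= 1 intronic base",
           call. = FALSE)
  }
  setattr(dt, "class", c("genome_annotation", class(data.table())))
  dt[]
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes, %d transcripts, %d exon rows\n",
              uniqueN(x$gene_id), uniqueN(x$tx_id), nrow(x)))
  invisible(x)
}

#' Read a GFF3 file into a genome annotation
#'
#' Accepts gene / mRNA / exon features linked through `ID`/`Parent`
#' attributes.  1-based closed GFF3 coordinates are converted to the
#' internal 0-based half-open convention.  Exons whose `Parent` chain
#' cannot be resolved to a gene are an error.
#'
#' @param path path to a GFF3 file.
#' @return a [genome_annotation()] object.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lns <- which(keep)
  if (!length(lns))
    return(genome_annotation(data.table(gene_id = character(), tx_id = character(),
                                        chrom = character(), strand = character(),
                                        start = integer(), end = integer())))
  fields <- strsplit(lines[lns], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated columns, got %d",
                 lns[which(nf != 9L)[1L]], nf[nf != 9L][1L]), call. = FALSE)
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  type <- m[, 3L]
  start1 <- suppressWarnings(as.integer(m[, 4L]))
  end1 <- suppressWarnings(as.integer(m[, 5L]))
  bad <- is.na(start1) | is.na(end1)
  if (any(bad))
    stop(sprintf("malformed GFF3 line %d: non-numeric coordinates", lns[which(bad)[1L]]),
         call. = FALSE)
  if (any(end1 < start1))
    stop(sprintf("invalid GFF3 line %d: end < start", lns[which(end1 < start1)[1L]]),
         call. = FALSE)
  attr_field <- m[, 9L]
  get_attr <- function(key) {
    re <- paste0("(?:^|;)", key, "=([^;]+)")
    mm <- regmatches(attr_field, regexec(re, attr_field))
    vapply(mm, function(z) if (length(z) == 2L) z[2L] else NA_character_, "")
  }
  id <- get_attr("ID")
  parent <- get_attr("Parent")

  is_gene <- type == "gene"
  is_mrna <- type %in% c("mRNA", "transcript")
  is_exon <- type == "exon"
  if (any(is_gene & is.na(id)) || any(is_mrna & is.na(id)))
    stop("gene/mRNA feature without an ID attribute", call. = FALSE)
  tx2gene <- setNames(parent[is_mrna], id[is_mrna])
  gene_ids <- id[is_gene]
  if (any(is.na(tx2gene)) || !all(tx2gene %in% gene_ids)) {
    off <- id[is_mrna][is.na(tx2gene) | !tx2gene %in% gene_ids][1L]
    stop("mRNA with unresolvable Parent: ", off, call. = FALSE)
  }
  ep <- parent[is_exon]
  orphan <- is.na(ep) | !ep %in% names(tx2gene)
  if (any(orphan)) {
    off <- ep[orphan][1L]
    if (is.na(off)) off <- id[is_exon][orphan][1L]
    stop("exon with unresolvable Parent: ", off, call. = FALSE)
  }
  genome_annotation(data.table(
    gene_id = unname(tx2gene[ep]), tx_id = ep,
    chrom = m[is_exon, 1L], strand = m[is_exon, 7L],
    start = start1[is_exon] - 1L, end = end1[is_exon]))
}

#' Write a genome annotation to GFF3
#'
#' Emits gene, mRNA and exon rows with `ID`/`Parent` attributes;
#' `read_gff3(write_gff3(x))` reproduces `x` exactly.
#'
#' @param annotation a [genome_annotation()].
#' @param path output path.
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path, call. = FALSE))
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  x <- as.data.table(annotation)
  if (!nrow(x)) return(invisible(NULL))
  setorder(x, chrom, gene_id, tx_id, start)
  genes <- x[, .(chrom = chrom[1L], strand = strand[1L],
                 start = min(start), end = max(end)), by = gene_id]
  txs <- x[, .(gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
               start = min(start), end = max(end)), by = tx_id]
  out <- character(0)
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi]
    out <- c(out, sprintf("%s\tjunctionAS\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                          g$chrom, g$start + 1L, g$end, g$strand, g$gene_id))
    gtx <- txs[gene_id == g$gene_id]
    for (ti in seq_len(nrow(gtx))) {
      t <- gtx[ti]
      out <- c(out, sprintf("%s\tjunctionAS\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                            t$chrom, t$start + 1L, t$end, t$strand, t$tx_id, g$gene_id))
      ex <- x[tx_id == t$tx_id]
      out <- c(out, sprintf("%s\tjunctionAS\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                            ex$chrom, ex$start + 1L, ex$end, ex$strand,
                            t$tx_id, seq_len(nrow(ex)), t$tx_id))
    }
  }
  writeLines(out, con)
  invisible(NULL)
}

# Merge a set of [start,end) intervals (assumed on one sequence).
.merge_intervals <- function(start, end) {
  o <- order(start, end)
  s <- start[o]; e <- end[o]
  if (!length(s)) return(data.table(start = integer(), end = integer()))
  grp <- cumsum(c(1L, as.integer(s[-1L] > cummax(e[-length(e)]))))
  data.table(start = s, end = e)[, .(start = min(start), end = max(end)), by = grp][
    , .(start, end)]
}

#' Exonic union length of a gene
#'
#' Length in bp of the union of all exon intervals across all transcripts
#' of a gene; the gene-length denominator of RPKM.
#'
#' @param annotation a [genome_annotation()].
#' @param gene_id single gene identifier; if `NULL`, all genes.
#' @return named integer vector of union lengths.
#' @export
exonic_union_length <- function(annotation, gene_id = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  x <- as.data.table(annotation)
  if (!is.null(gene_id)) {
    gid <- as.character(gene_id)
    x <- x[x[["gene_id"]] %chin% gid]
    if (!nrow(x)) stop("unknown gene_id", call. = FALSE)
  }
  res <- x[, {
    mi <- .merge_intervals(start, end); .(len = sum(mi$end - mi$start))
  }, by = "gene_id"]
  setNames(as.integer(res$len), res$gene_id)
}

# Exonic-union intervals per gene (used by clustering and read counting).
.exonic_union <- function(annotation) {
  as.data.table(annotation)[, {
    mi <- .merge_intervals(start, end)
    .(chrom = chrom[1L], strand = strand[1L], ustart = mi$start, uend = mi$end)
  }, by = "gene_id"]
}

# Gene spans [min start, max end).
.gene_spans <- function(annotation) {
  as.data.table(annotation)[, .(chrom = chrom[1L], strand = strand[1L],
                                gstart = min(start), gend = max(end)),
                            by = "gene_id"]
}

# Annotation-derived junctions: consecutive exon pairs within transcripts.
.annotation_junctions <- function(annotation) {
  x <- as.data.table(annotation)
  setorder(x, tx_id, start)
  j <- x[, if (.N > 1L) .(chrom = chrom[1L], gene_id = gene_id[1L],
                          donor = end[-.N], acceptor = start[-1L]), by = tx_id]
  if (!nrow(j)) return(data.table(chrom = character(), gene_id = character(),
                                  donor = integer(), acceptor = integer()))
  unique(j[, .(chrom, gene_id, donor, acceptor)])
}
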