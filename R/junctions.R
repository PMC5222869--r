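# Junction evidence extraction and the two junction-read filters:
#   (i)  each flanking anchor of a splice gap must be longer than 6 nt
#        (default min_anchor = 7);
#   (ii) a junction is kept only with > 3 non-redundant supporting reads
#        (default min_nonredundant = 4) in BOTH the CK and the S group,
#        replicates pooled within a group.
# "Non-redundant" collapses supporting reads by alignment start position.

.SAM_SKIP_FLAGS <- bitwOr(bitwOr(0x4, 0x100), 0x800)  # unmapped/secondary/suppl.

.aligned_reads <- function(blocks, n_records) {
  setattr(blocks, "class", c("aligned_reads", class(data.table())))
  setattr(blocks, "n_records", as.integer(n_records))
  blocks[]
}

#' @export
print.aligned_reads <- function(x, ...) {
  cat(sprintf("aligned_reads: %d reads (%d blocks) from %d parsed records\n",
              uniqueN(x$read_id), nrow(x), attr(x, "n_records")))
  invisible(x)
}

#' Read a SAM file into an aligned-reads block table
#'
#' Decodes CIGAR strings (`M`, `I`, `D`, `N`, `S`, `=`, `X`) into 0-based
#' half-open reference blocks; `N` separates blocks, `D` extends the
#' current block, `I`/`S` consume no reference.  Unmapped, secondary and
#' supplementary records are skipped but counted.
#'
#' @param path SAM file path.
#' @param sample_group group label, `"CK"` or `"S"`.
#' @param replicate replicate index.
#' @return an `aligned_reads` object: a data.table with one row per
#'   aligned block (`read_id`, `qname`, `chrom`, `group`, `replicate`,
#'   `bidx`, `bstart`, `bend`) and attribute `n_records` (records parsed,
#'   including skipped ones).
#' @export
read_sam <- function(path, sample_group = c("CK", "S"), replicate = 1L) {
  sample_group <- match.arg(sample_group)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  empty <- data.table(read_id = integer(), qname = character(),
                      chrom = character(), group = character(),
                      replicate = integer(), bidx = integer(),
                      bstart = integer(), bend = integer())
  if (!length(lines)) return(.aligned_reads(empty, 0L))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 11L))
    stop("malformed SAM record: fewer than 11 fields", call. = FALSE)
  qname <- vapply(f, `[[`, "", 1L)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  cigar <- vapply(f, `[[`, "", 6L)
  keep <- bitwAnd(flag, .SAM_SKIP_FLAGS) == 0L & rname != "*" & cigar != "*"
  n_rec <- length(lines)
  if (!any(keep)) return(.aligned_reads(empty, n_rec))
  qname <- qname[keep]; rname <- rname[keep]; pos <- pos[keep]; cigar <- cigar[keep]

  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Za-z=]", cigar))
  ntok <- lengths(toks)
  tok <- unlist(toks)
  op <- substr(tok, nchar(tok), nchar(tok))
  oplen <- as.integer(substr(tok, 1L, nchar(tok) - 1L))
  bad <- !op %in% c("M", "I", "D", "N", "S", "=", "X")
  if (any(bad)) {
    rec <- rep.int(seq_along(ntok), ntok)[which(bad)[1L]]
    stop("unsupported CIGAR operation '", op[which(bad)[1L]],
         "' in record ", qname[rec], call. = FALSE)
  }
  dt <- data.table(rid = rep.int(seq_along(ntok), ntok), op = op, len = oplen)
  dt[, reflen := fifelse(op %chin% c("M", "=", "X", "D", "N"), len, 0L)]
  dt[, off := cumsum(shift(reflen, fill = 0L)), by = rid]       # ref offset of op
  dt[, reflen := fifelse(op == "N", 0L, reflen)]                 # N spans no block
  dt[, nprev := cumsum(op == "N"), by = rid]                     # block index
  seg <- dt[op %chin% c("M", "=", "X", "D")]
  blocks <- seg[, .(bstart0 = min(off), bend0 = max(off + reflen)),
                by = .(rid, nprev)]
  setorder(blocks, rid, bstart0)
  blocks[, bidx := seq_len(.N), by = rid]
  out <- blocks[, .(read_id = rid,
                    qname = qname[rid], chrom = rname[rid],
                    group = sample_group, replicate = as.integer(replicate),
                    bidx,
                    bstart = pos[rid] - 1L + bstart0,
                    bend = pos[rid] - 1L + bend0)]
  out[, read_id := as.integer(factor(read_id, levels = unique(read_id)))]
  .aligned_reads(out[, .(read_id, qname, chrom, group, replicate, bidx,
                         bstart, bend)], n_rec)
}

#' Pool several aligned-reads objects
#'
#' @param ... `aligned_reads` objects (e.g. both conditions, all
#'   replicates).
#' @return one `aligned_reads` object with globally unique read ids.
#' @export
pool_reads <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1L]]) && !inherits(xs[[1L]], "aligned_reads"))
    xs <- xs[[1L]]
  stopifnot(all(vapply(xs, inherits, TRUE, "aligned_reads")))
  offs <- 0L
  n_rec <- 0L
  parts <- vector("list", length(xs))
  for (i in seq_along(xs)) {
    b <- copy(as.data.table(xs[[i]]))
    if (nrow(b)) b[, read_id := read_id + offs]
    offs <- offs + (if (nrow(b)) max(b$read_id) - min(b$read_id) + 1L else 0L)
    n_rec <- n_rec + attr(xs[[i]], "n_records")
    parts[[i]] <- b
  }
  .aligned_reads(rbindlist(parts), n_rec)
}

#' Extract junction observations from aligned reads
#'
#' Every adjacent block pair of a read is one junction observation; the
#' anchors are the lengths of the two blocks flanking the gap.
#' Observations with either anchor shorter than `min_anchor` are
#' discarded (the "more than 6 nt perfect flanking match" criterion).
#'
#' @param reads an `aligned_reads` object.
#' @param min_anchor minimum anchor length in bp (default 7).
#' @return a `junction_table`: list with `support` (one row per retained
#'   observation) and `junctions` (per-junction summary with raw and
#'   non-redundant counts per group), plus filter provenance fields.
#' @export
extract_junctions <- function(reads, min_anchor = 7L) {
  stopifnot(inherits(reads, "aligned_reads"), min_anchor >= 1L)
  b <- copy(as.data.table(reads))  # defensive: keep the caller's object intact
  setorder(b, read_id, bidx)
  b[, astart := bstart[1L], by = read_id]
  nb <- b[, .N, by = read_id]
  multi <- b[read_id %in% nb[N > 1L]$read_id]
  n_obs_raw <- 0L
  if (nrow(multi)) {
    multi[, `:=`(nxt_start = shift(bstart, -1L), nxt_end = shift(bend, -1L)),
          by = read_id]
    obs <- multi[!is.na(nxt_start),
                 .(chrom, donor = bend, acceptor = nxt_start,
                   left_anchor = bend - bstart, right_anchor = nxt_end - nxt_start,
                   group, replicate, astart, read_id)]
    n_obs_raw <- nrow(obs)
    obs <- obs[left_anchor >= min_anchor & right_anchor >= min_anchor]
  } else {
    obs <- data.table(chrom = character(), donor = integer(), acceptor = integer(),
                      left_anchor = integer(), right_anchor = integer(),
                      group = character(), replicate = integer(),
                      astart = integer(), read_id = integer())
  }
  structure(list(support = obs,
                 junctions = .summarize_junctions(obs),
                 min_anchor = as.integer(min_anchor),
                 n_observations_raw = n_obs_raw,
                 n_observations_anchor_fail = n_obs_raw - nrow(obs),
                 filtered = FALSE, min_nonredundant = NA_integer_),
            class = "junction_table")
}

.summarize_junctions <- function(obs) {
  if (!nrow(obs))
    return(data.table(chrom = character(), donor = integer(), acceptor = integer(),
                      raw_CK = integer(), raw_S = integer(),
                      nr_CK = integer(), nr_S = integer(),
                      max_left_anchor = integer(), max_right_anchor = integer()))
  obs[, .(raw_CK = sum(group == "CK"), raw_S = sum(group == "S"),
          nr_CK = uniqueN(astart[group == "CK"]),
          nr_S = uniqueN(astart[group == "S"]),
          max_left_anchor = max(left_anchor),
          max_right_anchor = max(right_anchor)),
      by = .(chrom, donor, acceptor)][order(chrom, donor, acceptor)]
}

#' @export
print.junction_table <- function(x, ...) {
  cat(sprintf("junction_table: %d junctions, %d supporting observations%s\n",
              nrow(x$junctions), nrow(x$support),
              if (isTRUE(x$filtered))
                sprintf(" (filtered at NR >= %d in both groups)", x$min_nonredundant)
              else ""))
  invisible(x)
}

#' Non-redundant read count of one junction in one group
#'
#' Supporting reads of a junction collapse to their distinct alignment
#' start positions; replicates within the group are pooled.
#'
#' @param table a `junction_table`.
#' @param chrom,donor,acceptor junction key (0-based half-open intron
#'   `[donor, acceptor)`).
#' @param sample_group `"CK"` or `"S"`.
#' @return integer count (0 if the junction is unsupported).
#' @export
nonredundant_count <- function(table, chrom, donor, acceptor,
                               sample_group = c("CK", "S")) {
  sample_group <- match.arg(sample_group)
  stopifnot(inherits(table, "junction_table"))
  s <- table$support
  sel <- s[s$chrom == chrom & s$donor == donor & s$acceptor == acceptor &
             s$group == sample_group]
  uniqueN(sel$astart)
}

#' Apply the non-redundant support filter to a junction table
#'
#' Retains junctions with at least `min_nonredundant` non-redundant
#' supporting reads in the CK group AND in the S group (default 4,
#' i.e. "more than 3").
#'
#' @param table a `junction_table` from [extract_junctions()].
#' @param min_nonredundant minimum per-group non-redundant read count.
#' @return the filtered `junction_table`.
#' @export
filter_junctions <- function(table, min_nonredundant = 4L) {
  stopifnot(inherits(table, "junction_table"), min_nonredundant >= 0L)
  keep <- table$junctions[nr_CK >= min_nonredundant & nr_S >= min_nonredundant,
                          .(chrom, donor, acceptor)]
  table$support <- table$support[keep, on = c("chrom", "donor", "acceptor"),
                                 nomatch = NULL]
  table$junctions <- .summarize_junctions(table$support)
  table$filtered <- TRUE
  table$min_nonredundant <- as.integer(min_nonredundant)
  table
}

#' Export a junction table as tab-separated text
#'
#' @param table a `junction_table`.
#' @param path output path.
#' @export
write_junction_table <- function(table, path) {
  stopifnot(inherits(table, "junction_table"))
  hdr <- c("# junctionAS junction table",
           sprintf("# min_anchor: %d", table$min_anchor),
           sprintf("# min_nonredundant: %s",
                   ifelse(is.na(table$min_nonredundant), "unfiltered",
                          table$min_nonredundant)))
  writeLines(hdr, path)
  fwrite(table$junctions, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(NULL)
}
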