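# Synthetic two-condition spliced-read simulator.
#
# The generator states a small, explicit world: toy gene models on one
# chromosome, log-normal relative abundances shared between conditions,
# Poisson sampling of read counts per replicate, Bernoulli isoform choice
# for AS-designated genes, error-free single-end uniquely mapped reads of
# fixed length.  Differential expression enters only through a planted fold
# change, differential splicing only through a planted inclusion-proportion
# (PSI) shift.  Everything is deterministic given the seed.

.EVENT_TYPES <- c("SE", "A5SS", "A3SS", "RI")

#' Simulation configuration
#'
#' Collects and validates the parameters of the synthetic world.  Defaults
#' describe a two-replicate-per-condition heat-stress-style design: 200
#' genes, 75 bp reads, 100,000 expected reads per condition, 20% of genes
#' differentially expressed at 4-fold, 30% of genes carrying one planted
#' splicing event with inclusion shifting from PSI 0.3 (control, CK) to
#' 0.7 (stress, S).
#'
#' @param seed integer seed; the sole source of randomness.
#' @param n_genes number of genes.
#' @param read_length read length in bp.
#' @param depth_per_condition expected total read count per condition,
#'   split evenly across its replicates.
#' @param frac_de_genes,de_fold_change fraction of genes with planted
#'   differential expression and the (>1) fold change applied in condition
#'   S (half up, half down).
#' @param frac_as_genes fraction of genes carrying one planted splicing
#'   event.
#' @param psi_ck,psi_s inclusion-isoform probability in each condition.
#' @param event_type_mix named proportions over SE, A5SS, A3SS, RI.
#' @param expression_meanlog,expression_sdlog log-normal parameters of the
#'   relative gene abundances (shared across conditions and replicates).
#' @param n_replicates_per_condition biological replicates per condition.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_genes = 200L, read_length = 75L,
                              depth_per_condition = 1e5,
                              frac_de_genes = 0.2, de_fold_change = 4,
                              frac_as_genes = 0.3, psi_ck = 0.3, psi_s = 0.7,
                              event_type_mix = c(SE = 0.4, A5SS = 0.2,
                                                 A3SS = 0.2, RI = 0.2),
                              expression_meanlog = 0, expression_sdlog = 1,
                              n_replicates_per_condition = 2L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              read_length = as.integer(read_length),
              depth_per_condition = as.numeric(depth_per_condition),
              frac_de_genes = frac_de_genes, de_fold_change = de_fold_change,
              frac_as_genes = frac_as_genes, psi_ck = psi_ck, psi_s = psi_s,
              event_type_mix = event_type_mix,
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog,
              n_replicates_per_condition = as.integer(n_replicates_per_condition))
  props <- c(cfg$frac_de_genes, cfg$frac_as_genes, cfg$psi_ck, cfg$psi_s)
  if (anyNA(props) || any(props < 0) || any(props > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  if (cfg$read_length < 1L) stop("read_length must be >= 1", call. = FALSE)
  if (cfg$depth_per_condition < 0) stop("depth must be >= 0", call. = FALSE)
  if (cfg$de_fold_change <= 1) stop("de_fold_change must be > 1", call. = FALSE)
  if (is.null(names(cfg$event_type_mix)) ||
      !all(names(cfg$event_type_mix) %in% .EVENT_TYPES) ||
      any(cfg$event_type_mix < 0) ||
      abs(sum(cfg$event_type_mix) - 1) > 1e-8)
    stop("event_type_mix must be named proportions over SE/A5SS/A3SS/RI summing to 1",
         call. = FALSE)
  if (cfg$n_replicates_per_condition < 1L)
    stop("need >= 1 replicate per condition", call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

# Deterministic sub-seed: keeps per-(condition, replicate) draws independent
# of each other while sharing the gene-level design.  Stays below 2^31.
.derive_seed <- function(seed, i, j = 0L) {
  as.integer((abs(as.numeric(seed)) %% 1e6) * 2049 + i * 8191 + j * 131) %% 2147483629L
}

# Build the whole gene-level design (structures, lambdas, truth) from the
# config seed.  Called by simulate_annotation() and truth_table() so that
# the two always agree.
.simulate_design <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  rl <- config$read_length
  gene_id <- sprintf("g%05d", seq_len(n))
  strand <- sample(c("+", "-"), n, replace = TRUE)

  n_as <- round(config$frac_as_genes * n)
  n_de <- round(config$frac_de_genes * n)
  as_idx <- sort(sample.int(n, n_as))
  de_idx <- sort(sample.int(n, n_de))
  etype <- rep(NA_character_, n)
  if (n_as > 0)
    etype[as_idx] <- sample(names(config$event_type_mix), n_as, replace = TRUE,
                            prob = config$event_type_mix)
  de_dir <- rep(NA_character_, n)
  if (n_de > 0) de_dir[de_idx] <- rep_len(c("up", "down"), n_de)
  lambda <- rlnorm(n, config$expression_meanlog, config$expression_sdlog)

  elen <- function(k) 2L * rl + sample.int(150L, k, replace = TRUE)
  ilen <- function(k) 79L + sample.int(120L, k, replace = TRUE)
  offset <- 30L  # alt 5'/3' splice-site shift (>= 12 bp, anchor-resolvable)

  exon_list <- vector("list", n)
  event_list <- vector("list", n)
  cursor <- 1000L
  for (i in seq_len(n)) {
    gi <- gene_id[i]
    if (is.na(etype[i])) {
      k <- sample(2:3, 1L)
      el <- elen(k); il <- ilen(k - 1L)
      st <- cursor + c(0L, cumsum(el[-k] + il))
      exon_list[[i]] <- data.table(gene_id = gi, tx_id = paste0(gi, ".t1"),
                                   start = st, end = st + el)
      gend <- st[k] + el[k]
    } else if (etype[i] == "SE") {
      el <- elen(3L); il <- ilen(2L)
      s1 <- cursor; e1 <- s1 + el[1L]
      s2 <- e1 + il[1L]; e2 <- s2 + el[2L]
      s3 <- e2 + il[2L]; e3 <- s3 + el[3L]
      exon_list[[i]] <- rbind(
        data.table(gene_id = gi, tx_id = paste0(gi, ".t1"),
                   start = c(s1, s2, s3), end = c(e1, e2, e3)),
        data.table(gene_id = gi, tx_id = paste0(gi, ".t2"),
                   start = c(s1, s3), end = c(e1, e3)))
      event_list[[i]] <- data.table(gene_id = gi, type = "SE",
                                    alt_start = s2, alt_end = e2)
      gend <- e3
    } else if (etype[i] == "RI") {
      el <- elen(2L); il <- ilen(1L)
      s1 <- cursor; e1 <- s1 + el[1L]
      s2 <- e1 + il[1L]; e2 <- s2 + el[2L]
      exon_list[[i]] <- rbind(
        data.table(gene_id = gi, tx_id = paste0(gi, ".t1"),
                   start = s1, end = e2),          # intron retained
        data.table(gene_id = gi, tx_id = paste0(gi, ".t2"),
                   start = c(s1, s2), end = c(e1, e2)))
      event_list[[i]] <- data.table(gene_id = gi, type = "RI",
                                    alt_start = e1, alt_end = s2)
      gend <- e2
    } else {  # A5SS / A3SS: which genomic side varies depends on strand
      el <- elen(2L); il <- ilen(1L)
      varies_left <- (etype[i] == "A5SS") == (strand[i] == "+")
      if (varies_left) {
        s1 <- cursor; d_short <- s1 + el[1L]; d_long <- d_short + offset
        s2 <- d_long + il[1L]; e2 <- s2 + el[2L]
        exon_list[[i]] <- rbind(
          data.table(gene_id = gi, tx_id = paste0(gi, ".t1"),
                     start = c(s1, s2), end = c(d_long, e2)),   # inclusion
          data.table(gene_id = gi, tx_id = paste0(gi, ".t2"),
                     start = c(s1, s2), end = c(d_short, e2)))
        event_list[[i]] <- data.table(gene_id = gi, type = etype[i],
                                      alt_start = d_short, alt_end = d_long)
      } else {
        s1 <- cursor; e1 <- s1 + el[1L]
        a_long <- e1 + il[1L]; a_short <- a_long + offset
        e2 <- a_short + el[2L]
        exon_list[[i]] <- rbind(
          data.table(gene_id = gi, tx_id = paste0(gi, ".t1"),
                     start = c(s1, a_long), end = c(e1, e2)),   # inclusion
          data.table(gene_id = gi, tx_id = paste0(gi, ".t2"),
                     start = c(s1, a_short), end = c(e1, e2)))
        event_list[[i]] <- data.table(gene_id = gi, type = etype[i],
                                      alt_start = a_long, alt_end = a_short)
      }
      gend <- max(exon_list[[i]]$end)
    }
    cursor <- gend + 500L
  }
  exons <- rbindlist(exon_list)
  smap <- setNames(strand, gene_id)
  exons[, chrom := "chr1"]
  exons[, strand := smap[gene_id]]

  genes <- data.table(gene_id = gene_id, strand = strand, lambda = lambda,
                      is_de = !is.na(de_dir), de_direction = de_dir,
                      is_as = !is.na(etype), event_type = etype)
  events <- if (length(event_list) && any(!vapply(event_list, is.null, TRUE))) {
    ev <- rbindlist(event_list)
    ev[, chrom := "chr1"]
    ev[, strand := smap[gene_id]]
    ev[, `:=`(psi_ck = config$psi_ck, psi_s = config$psi_s,
              inclusion_tx = paste0(gene_id, ".t1"),
              exclusion_tx = paste0(gene_id, ".t2"))]
    ev[]
  } else data.table(gene_id = character(), type = character(),
                    alt_start = integer(), alt_end = integer(),
                    chrom = character(), strand = character(),
                    psi_ck = numeric(), psi_s = numeric(),
                    inclusion_tx = character(), exclusion_tx = character())
  list(annotation = genome_annotation(exons), genes = genes, events = events)
}

#' Simulate a toy genome annotation
#'
#' Emits gene models realizing the configured mix of splicing structures:
#' AS-designated genes get an inclusion and an exclusion transcript
#' (cassette exon, alternative 5'/3' splice site with a 30 bp shift, or
#' retained intron), all other genes a single transcript.  Exon lengths are
#' at least twice the read length so every junction can carry compliant
#' anchors.  Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return a [genome_annotation()].
#' @export
simulate_annotation <- function(config) .simulate_design(config)$annotation

#' Ground-truth tables for a simulated annotation
#'
#' @param annotation the annotation produced by [simulate_annotation()]
#'   with the same config (consistency is checked).
#' @param config the [simulation_config()] used.
#' @return a list of class `truth_table` with elements `genes` (per-gene
#'   lambda, DE flag/direction, AS flag/type) and `events` (planted event
#'   type, coordinates, PSI per condition, isoform ids).
#' @export
truth_table <- function(annotation, config) {
  d <- .simulate_design(config)
  if (!is.null(annotation)) {
    stopifnot(inherits(annotation, "genome_annotation"))
    if (!identical(sort(unique(annotation$gene_id)), sort(d$genes$gene_id)))
      stop("annotation does not match this config's design", call. = FALSE)
  }
  structure(list(genes = d$genes, events = d$events), class = "truth_table")
}

#' Simulate aligned spliced reads for one sample
#'
#' Per gene g, the replicate's read count is Poisson with mean
#' `depth_per_replicate * lambda_g / sum(lambda)`, multiplied by the
#' planted fold change (or its reciprocal) in condition S for
#' DE-designated genes.  Reads from AS genes choose the inclusion isoform
#' with probability `psi_ck` or `psi_s`; read starts are uniform on the
#' transcript; transcript-to-genome projection produces the match/skip
#' block structure.  Condition and replicate perturb only the Poisson /
#' isoform / start draws; gene abundances are shared.
#'
#' @param annotation a [genome_annotation()] from [simulate_annotation()].
#' @param truth the matching [truth_table()].
#' @param config the [simulation_config()].
#' @param condition `"CK"` (control) or `"S"` (stressed).
#' @param replicate replicate index (1-based).
#' @return an `aligned_reads` object (see [read_sam()]), coordinate-sorted.
#' @export
simulate_reads <- function(annotation, truth, config, condition = c("CK", "S"),
                           replicate = 1L) {
  condition <- match.arg(condition)
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(truth, "truth_table"),
            inherits(config, "simulation_config"))
  rl <- config$read_length
  ann <- as.data.table(annotation)
  txlen <- ann[, .(len = sum(end - start), gene_id = gene_id[1L]), by = tx_id]
  if (any(txlen$len < rl))
    stop("read_length exceeds the shortest transcript (",
         txlen$tx_id[which.min(txlen$len)], ")", call. = FALSE)

  genes <- copy(truth$genes)
  lam <- genes$lambda
  mult <- rep(1, nrow(genes))
  if (condition == "S" && any(genes$is_de)) {
    up <- genes$is_de & genes$de_direction == "up"
    dn <- genes$is_de & genes$de_direction == "down"
    mult[up] <- config$de_fold_change
    mult[dn] <- 1 / config$de_fold_change
  }
  depth_rep <- config$depth_per_condition / config$n_replicates_per_condition
  mu <- depth_rep * lam * mult / sum(lam)

  set.seed(.derive_seed(config$seed, if (condition == "CK") 1L else 2L, replicate))
  n_reads <- rpois(nrow(genes), mu)

  psi <- if (condition == "CK") config$psi_ck else config$psi_s
  incl_tx <- paste0(genes$gene_id, ".t1")
  excl_tx <- paste0(genes$gene_id, ".t2")
  tx_of_read <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    if (n_reads[i] == 0L) next
    tx_of_read[[i]] <- if (genes$is_as[i]) {
      ifelse(runif(n_reads[i]) < psi, incl_tx[i], excl_tx[i])
    } else rep(paste0(genes$gene_id[i], ".t1"), n_reads[i])
  }
  txv <- unlist(tx_of_read)
  if (is.null(txv) || !length(txv)) {
    return(.aligned_reads(data.table(read_id = integer(), qname = character(),
                                     chrom = character(), group = character(),
                                     replicate = integer(), bidx = integer(),
                                     bstart = integer(), bend = integer()),
                          n_records = 0L))
  }
  len_of <- setNames(txlen$len, txlen$tx_id)
  s <- floor(runif(length(txv)) * (len_of[txv] - rl + 1))

  # project transcript interval [s, s + rl) to genome blocks
  ex <- copy(ann)
  setorder(ex, tx_id, start)
  ex[, cend := cumsum(end - start), by = tx_id]
  ex[, cstart := cend - (end - start)]
  reads <- data.table(rid = seq_along(txv), tx_id = txv, s = as.integer(s))
  pieces <- ex[reads, on = "tx_id", allow.cartesian = TRUE]
  pieces <- pieces[cend > s & cstart < s + rl]
  pieces[, `:=`(bstart = start + pmax(s - cstart, 0L),
                bend = start + pmin(s + rl - cstart, end - start))]
  setorder(pieces, rid, bstart)
  pieces[, bidx := seq_len(.N), by = rid]

  blocks <- pieces[, .(rid, chrom, bstart = as.integer(bstart),
                       bend = as.integer(bend), bidx)]
  # coordinate sort: order reads by (chrom, alignment start)
  first <- blocks[bidx == 1L, .(rid, chrom, astart = bstart)]
  setorder(first, chrom, astart, rid)
  first[, new_id := seq_len(.N)]
  blocks <- first[, .(rid, new_id)][blocks, on = "rid"]
  setorder(blocks, new_id, bidx)
  out <- blocks[, .(read_id = new_id,
                    qname = sprintf("sim_%s_r%d_%06d", condition, as.integer(replicate), new_id),
                    chrom, group = condition, replicate = as.integer(replicate),
                    bidx, bstart, bend)]
  .aligned_reads(out, n_records = length(txv))
}

#' Write aligned reads as a SAM file
#'
#' Emits a coordinate-sorted SAM with `@HD`/`@SQ` headers (reference
#' lengths taken from the annotation span plus margin), flag 0, MAPQ 60,
#' and `M`/`N` CIGARs reconstructed from the block structure; sequence and
#' quality are `*` (the simulator is error-free and sequence-agnostic).
#'
#' @param reads an `aligned_reads` object.
#' @param annotation the [genome_annotation()] defining reference sequences.
#' @param path output path.
#' @export
write_sam <- function(reads, annotation, path) {
  stopifnot(inherits(reads, "aligned_reads"))
  spans <- .gene_spans(annotation)
  sq <- spans[, .(len = max(gend) + 1000L), by = chrom]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", sq$chrom, sq$len))
  b <- as.data.table(reads)
  if (!nrow(b)) { writeLines(hdr, path); return(invisible(NULL)) }
  recs <- b[, .(qname = qname[1L], chrom = chrom[1L], pos = bstart[1L] + 1L,
                cigar = paste(ifelse(seq_len(.N) == 1L, "",
                                     paste0(bstart - shift(bend), "N")),
                              bend - bstart, "M", sep = "", collapse = "")),
            by = read_id]
  writeLines(c(hdr, sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                            recs$qname, recs$chrom, recs$pos, recs$cigar)),
             path)
  invisible(NULL)
}
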