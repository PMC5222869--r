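# Gene-level expression: read counting, RPKM, threshold-based DEG calling,
# direction-aware multi-group overlap, and term enrichment.

#' Count reads per gene and sample
#'
#' A read is assigned to gene g when at least 50% of its aligned bases fall
#' within g's exonic union; reads satisfying this for more than one gene
#' are discarded as ambiguous.  Samples are (group, replicate) pairs.
#'
#' @param reads pooled `aligned_reads` carrying sample metadata.
#' @param annotation a [genome_annotation()].
#' @return a `count_table`: list with `counts` (gene x sample integer
#'   matrix over all annotated genes), `samples` (data.table: sample,
#'   group, replicate, total_reads = all parsed reads incl. intergenic,
#'   assigned_reads), and bookkeeping (`ambiguous`, `intergenic`).
#' @export
count_gene_reads <- function(reads, annotation) {
  stopifnot(inherits(reads, "aligned_reads"),
            inherits(annotation, "genome_annotation"))
  b <- copy(as.data.table(reads))  # setkey/:= below must not alias the input
  uni <- .exonic_union(annotation)
  gene_ids <- sort(unique(as.data.table(annotation)$gene_id))

  if (nrow(b)) {
    b[, sample := paste0(group, replicate)]
    rinfo <- b[, .(alen = sum(bend - bstart), sample = sample[1L],
                   group = group[1L], replicate = replicate[1L]), by = read_id]
    setkey(b, chrom, bstart, bend)
    ov <- foverlaps(uni, b, by.x = c("chrom", "ustart", "uend"),
                    by.y = c("chrom", "bstart", "bend"), nomatch = NULL)
    ov[, olap := pmin(uend, bend) - pmax(ustart, bstart)]
    ov <- ov[olap > 0L]
    pg <- ov[, .(olap = sum(olap)), by = .(read_id, gene_id)]
    pg <- pg[rinfo, on = "read_id", nomatch = NULL][olap * 2L >= alen]
    ng <- pg[, .(ngenes = .N), by = read_id]
    ambiguous <- ng[ngenes > 1L, read_id]
    assigned <- pg[!read_id %in% ambiguous]
  } else {
    rinfo <- data.table(read_id = integer(), alen = integer(),
                        sample = character(), group = character(),
                        replicate = integer())
    assigned <- data.table(read_id = integer(), gene_id = character(),
                           olap = integer(), alen = integer(),
                           sample = character(), group = character(),
                           replicate = integer())
    ambiguous <- integer(0)
  }
  samples <- unique(rinfo[, .(sample, group, replicate)])
  setorder(samples, group, replicate)
  cnt <- matrix(0L, nrow = length(gene_ids), ncol = nrow(samples),
                dimnames = list(gene_ids, samples$sample))
  if (nrow(assigned)) {
    tab <- assigned[, .N, by = .(gene_id, sample)]
    cnt[cbind(match(tab$gene_id, gene_ids), match(tab$sample, samples$sample))] <-
      tab$N
  }
  totals <- rinfo[, .(total_reads = .N), by = sample]
  samples <- totals[samples, on = "sample"]
  samples[is.na(total_reads), total_reads := 0L]
  samples[, assigned_reads := colSums(cnt)[sample]]
  setcolorder(samples, c("sample", "group", "replicate", "total_reads",
                         "assigned_reads"))
  structure(list(counts = cnt, samples = samples[],
                 ambiguous = length(ambiguous),
                 intergenic = nrow(rinfo) - length(ambiguous) - uniqueN(assigned$read_id)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d genes x %d samples (%d ambiguous, %d intergenic reads)\n",
              nrow(x$counts), ncol(x$counts), x$ambiguous, x$intergenic))
  invisible(x)
}

#' RPKM normalization
#'
#' Reads per kilobase of exonic-union gene model per million gene-assigned
#' reads: `RPKM(g, s) = count(g, s) / (length_kb(g) * assigned_millions(s))`.
#'
#' @param counts a `count_table`.
#' @param annotation the matching [genome_annotation()] (gene lengths).
#' @return an `rpkm_table`: list with `rpkm` (gene x sample matrix) and
#'   `gene_lengths`.
#' @export
rpkm <- function(counts, annotation) {
  stopifnot(inherits(counts, "count_table"))
  lens <- exonic_union_length(annotation)[rownames(counts$counts)]
  tot <- colSums(counts$counts)
  if (any(tot == 0))
    stop("sample with zero assigned reads cannot be normalized: ",
         paste(colnames(counts$counts)[tot == 0], collapse = ", "), call. = FALSE)
  r <- sweep(counts$counts / (lens / 1e3), 2L, tot / 1e6, "/")
  structure(list(rpkm = r, gene_lengths = lens), class = "rpkm_table")
}

#' Call differentially expressed genes between two groups
#'
#' Replicates are pooled within each group.  Per gene, the P-value is the
#' two-sided Fisher exact test on `[[k_CK, T_CK - k_CK], [k_S, T_S -
#' k_S]]` (gene count vs remaining assigned reads), q-values are BH over
#' all genes, and the log2 fold change (S over CK) is computed on
#' counts-per-million with a pseudocount.  A gene is a DEG when
#' `|log2fc| > fc_threshold` strictly AND `q < fdr_threshold`.
#'
#' @param counts a `count_table` containing both groups.
#' @param group_a,group_b the control and treatment group labels.
#' @param fc_threshold log2 fold-change threshold (default 1).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @param pseudocount pseudocount on the CPM scale (default 1).
#' @return data.table of DEG records: `gene_id`, `cpm_CK`, `cpm_S`,
#'   `log2fc`, `p`, `q`, `direction` (`up`/`down`/`none`), `is_deg`.
#' @export
call_degs <- function(counts, group_a = "CK", group_b = "S",
                      fc_threshold = 1.0, fdr_threshold = 0.05,
                      pseudocount = 1) {
  stopifnot(inherits(counts, "count_table"))
  sa <- counts$samples[group == group_a, sample]
  sb <- counts$samples[group == group_b, sample]
  if (!length(sa) || !length(sb))
    stop("both groups need at least one sample", call. = FALSE)
  ka <- rowSums(counts$counts[, sa, drop = FALSE])
  kb <- rowSums(counts$counts[, sb, drop = FALSE])
  Ta <- sum(ka); Tb <- sum(kb)
  if (Ta == 0 || Tb == 0)
    stop("a group has zero assigned reads; cannot normalize", call. = FALSE)
  p <- vapply(seq_along(ka), function(i)
    fisher_exact_2x2(c(ka[i], Ta - ka[i], kb[i], Tb - kb[i])), 0)
  q <- bh_fdr(p)
  cpm_a <- ka / Ta * 1e6
  cpm_b <- kb / Tb * 1e6
  lfc <- log2_fold_change(cpm_b, cpm_a, pseudocount)
  out <- data.table(gene_id = names(ka), cpm_CK = cpm_a, cpm_S = cpm_b,
                    log2fc = lfc, p = p, q = q)
  out[, is_deg := abs(log2fc) > fc_threshold & q < fdr_threshold]
  out[, direction := fifelse(is_deg & log2fc > 0, "up",
                             fifelse(is_deg & log2fc < 0, "down", "none"))]
  setorder(out, gene_id)
  out[]
}

#' Direction-aware overlap of three DEG sets
#'
#' The all-groups overlap counts genes that are DEGs in every set
#' regardless of direction; the up (down) overlap counts genes called up
#' (down) in all three.  A gene changing direction between groups belongs
#' to the all-groups overlap but to neither directional overlap, which is
#' how the total can exceed up + down.
#'
#' @param deg_sets list of three DEG tables from [call_degs()] over a
#'   shared gene universe.
#' @return list with `all_overlap`, `up_overlap`, `down_overlap` (counts)
#'   and the corresponding gene-id vectors.
#' @export
overlap_groups <- function(deg_sets) {
  stopifnot(is.list(deg_sets), length(deg_sets) == 3L)
  degs <- lapply(deg_sets, function(d) d[d$is_deg == TRUE])
  all_ids <- Reduce(intersect, lapply(degs, `[[`, "gene_id"))
  dir_of <- function(d) setNames(d$direction, d$gene_id)
  dirs <- lapply(degs, dir_of)
  up_ids <- all_ids[vapply(all_ids, function(g)
    all(vapply(dirs, function(dd) dd[[g]] == "up", TRUE)), TRUE)]
  down_ids <- all_ids[vapply(all_ids, function(g)
    all(vapply(dirs, function(dd) dd[[g]] == "down", TRUE)), TRUE)]
  list(all_overlap = length(all_ids), up_overlap = length(up_ids),
       down_overlap = length(down_ids), all_genes = all_ids,
       up_genes = up_ids, down_genes = down_ids)
}

#' Read a gene-to-term annotation map
#'
#' Two-column tab-separated text: gene_id, term_id (no header, `#`
#' comments allowed).
#'
#' @param path file path.
#' @return data.table with columns `gene_id`, `term_id`.
#' @export
read_term_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- fread(path, header = FALSE, sep = "\t", col.names = c("gene_id", "term_id"),
              colClasses = "character")
  unique(dt)
}

#' Term over-representation analysis
#'
#' For each term with at least one annotated background gene, tests the
#' 2x2 table `[[k, n - k], [K - k, N - n - (K - k)]]` (DEG hits in term,
#' other DEGs, non-DEG term genes, rest) with the Fisher exact test
#' (two-sided, matching the package-wide convention) or the chi-squared
#' test; degenerate chi-squared tables fall back to Fisher with a message.
#' Q-values are BH over all tested terms.
#'
#' @param deg_genes character vector of significant genes.
#' @param background character vector of background genes (superset of
#'   `deg_genes`).
#' @param term_map data.table/data.frame with columns `gene_id`,
#'   `term_id`.
#' @param test `"fisher"` or `"chisq"`.
#' @param fdr_threshold significance gate on q.
#' @return data.table of enrichment records sorted by q: `term_id`, `k`,
#'   `K`, `n`, `N`, `fold_enrichment`, `p`, `q`, `significant`.
#' @export
term_enrichment <- function(deg_genes, background, term_map,
                            test = c("fisher", "chisq"),
                            fdr_threshold = 0.05) {
  test <- match.arg(test)
  background <- unique(as.character(background))
  deg_genes <- unique(as.character(deg_genes))
  if (!length(background)) stop("empty background", call. = FALSE)
  if (!all(deg_genes %in% background))
    stop("deg_genes must be a subset of the background", call. = FALSE)
  tm <- unique(as.data.table(term_map)[, .(gene_id = as.character(gene_id),
                                           term_id = as.character(term_id))])
  tm <- tm[gene_id %in% background]
  N <- length(background)
  n <- length(deg_genes)
  terms <- tm[, .(K = .N, k = sum(gene_id %in% deg_genes)), by = term_id]
  terms <- terms[K >= 1L]
  if (!nrow(terms))
    return(data.table(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), fold_enrichment = numeric(),
                      p = numeric(), q = numeric(), significant = logical()))
  pvec <- vapply(seq_len(nrow(terms)), function(i) {
    k <- terms$k[i]; K <- terms$K[i]
    tab <- c(k, n - k, K - k, N - n - (K - k))
    if (test == "fisher") return(fisher_exact_2x2(tab))
    tryCatch(chisq_2x2(tab)$p.value, error = function(e) {
      message("chi-squared degenerate for term ", terms$term_id[i],
              "; falling back to Fisher")
      fisher_exact_2x2(tab)
    })
  }, 0)
  out <- terms[, .(term_id, k, K, n = n, N = N,
                   fold_enrichment = fifelse(n > 0 & K > 0, (k / n) / (K / N), 0),
                   p = pvec)]
  out[, q := bh_fdr(p)]
  out[, significant := q < fdr_threshold]
  setorder(out, q, term_id)
  out[]
}
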