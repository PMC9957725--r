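# CTSS ingestion and promoter architecture: tags-per-million normalisation,
# distance clustering, quantile promoter width with the sharp/broad cut,
# per-gene TSS profiles, TOPscore and PRTE score against a genome.

#' Construct a CTSS table
#'
#' A CTSS table holds per-position capped 5'-end tag counts for one sample
#' (library). Positions are 1-based genome coordinates of the +1 base.
#'
#' @param records data.frame with columns `chrom` (character), `pos`
#'   (1-based integer), `strand` (`"+"`/`"-"`), `count` (non-negative
#'   integer). `(chrom, pos, strand)` must be unique.
#' @param sample_id Sample identifier.
#' @param condition Optional condition label (e.g. `"WT"`, `"SCC"`).
#' @param fraction Optional polysome fraction label (`"total"`, `"LP"`,
#'   `"HP"`).
#' @return Object of class `ctss_table`: the records plus `library_size`
#'   (total tag count) and the labels, as attributes.
#' @export
ctss_table <- function(records, sample_id = "sample", condition = NA_character_,
                       fraction = NA_character_) {
  stopifnot(is.data.frame(records),
            all(c("chrom", "pos", "strand", "count") %in% names(records)))
  if (nrow(records) > 0) {
    if (any(records$count < 0)) stop("negative tag counts")
    if (!all(records$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    key <- paste(records$chrom, records$pos, records$strand)
    if (anyDuplicated(key)) stop("(chrom, pos, strand) not unique")
    records <- records[order(records$chrom, records$strand, records$pos), ,
                       drop = FALSE]
    rownames(records) <- NULL
  }
  structure(records,
            class = c("ctss_table", "data.frame"),
            sample_id = sample_id, condition = condition, fraction = fraction,
            library_size = sum(records$count))
}

#' @export
print.ctss_table <- function(x, ...) {
  cat(sprintf("ctss_table '%s' (condition %s, fraction %s): %d positions, %d tags\n",
              attr(x, "sample_id"), attr(x, "condition"), attr(x, "fraction"),
              nrow(x), attr(x, "library_size")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

library_size <- function(table) {
  ls <- attr(table, "library_size")
  if (is.null(ls)) sum(table$count) else ls
}

#' Normalise CTSS tag counts to tags per million
#'
#' `tpm_i = count_i / library_size * 1e6`; the tpm column sums to 1e6.
#'
#' @param table A [ctss_table()] with at least one tag.
#' @return The table with a `tpm` column added.
#' @export
normalize_tpm <- function(table) {
  ls <- library_size(table)
  if (nrow(table) == 0L || ls <= 0) stop("empty CTSS table: cannot normalise")
  table$tpm <- table$count / ls * 1e6
  table
}

#' Cluster CTSS positions by distance
#'
#' Greedy distance clustering ("distclu"): two positions on the same
#' chromosome and strand belong to one tag cluster iff they are connected by
#' a chain of gaps each `<= maxdist` base pairs; clusters are maximal.
#'
#' @param records data.frame (or [ctss_table()]) with `chrom`, `pos`,
#'   `strand`, `count`.
#' @param maxdist Maximum gap in bp joining two positions (default 20).
#' @return List of class `tag_clusters` with `members` (records plus a
#'   `cluster_id` column) and `clusters` (one row per cluster: `cluster_id`,
#'   `chrom`, `strand`, `start`, `end`, `n_pos`, `total_tags`,
#'   `dominant_pos`).
#' @export
cluster_ctss <- function(records, maxdist = 20L) {
  df <- as.data.frame(records)[, c("chrom", "pos", "strand", "count")]
  df <- df[order(df$chrom, df$strand, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  n <- nrow(df)
  if (n == 0L) {
    return(structure(list(members = cbind(df, cluster_id = integer(0)),
                          clusters = data.frame()),
                     class = "tag_clusters"))
  }
  new_grp <- c(TRUE, df$chrom[-1] != df$chrom[-n] |
                     df$strand[-1] != df$strand[-n] |
                     (df$pos[-1] - df$pos[-n]) > maxdist)
  df$cluster_id <- cumsum(new_grp)
  cl <- do.call(rbind, lapply(split(df, df$cluster_id), function(g) {
    data.frame(cluster_id = g$cluster_id[1], chrom = g$chrom[1],
               strand = g$strand[1], start = min(g$pos), end = max(g$pos),
               n_pos = nrow(g), total_tags = sum(g$count),
               dominant_pos = g$pos[which.max(g$count)],
               stringsAsFactors = FALSE)
  }))
  rownames(cl) <- NULL
  structure(list(members = df, clusters = cl), class = "tag_clusters")
}

#' @export
print.tag_clusters <- function(x, ...) {
  cat(sprintf("tag_clusters: %d clusters over %d CTSS positions\n",
              nrow(x$clusters), nrow(x$members)))
  print(utils::head(x$clusters), ...)
  invisible(x)
}

#' Quantile promoter width of a tag cluster
#'
#' Accumulates tag fractions in transcription direction (ascending genome
#' coordinate on `+`, descending on `-`). The low/high quantile positions
#' are the first positions whose cumulative fraction reaches `q_low` /
#' `q_high`; width is the inclusive distance between them. Promoters with
#' width `< sharp_cut` are sharp, else broad.
#'
#' @param positions Integer genome positions of the cluster members.
#' @param counts Tag counts per position (same length, total > 0).
#' @param strand `"+"` or `"-"`.
#' @param q_low,q_high Quantiles (defaults 0.1 and 0.9).
#' @param sharp_cut Width cut separating sharp from broad (default 10 bp).
#' @return List of class `promoter_width`: `q_low_pos`, `q_high_pos`,
#'   `width`, `shape` (`"sharp"`/`"broad"`).
#' @export
quantile_width <- function(positions, counts, strand = "+",
                           q_low = 0.1, q_high = 0.9, sharp_cut = 10L) {
  if (length(positions) == 0L || sum(counts) <= 0)
    stop("empty cluster: cannot compute quantile width")
  ord <- order(positions, decreasing = (strand == "-"))
  pos <- positions[ord]
  cum <- cumsum(counts[ord]) / sum(counts)
  q_low_pos <- pos[which(cum >= q_low - 1e-12)[1]]
  q_high_pos <- pos[which(cum >= q_high - 1e-12)[1]]
  width <- as.integer(abs(q_high_pos - q_low_pos)) + 1L
  structure(list(q_low_pos = q_low_pos, q_high_pos = q_high_pos,
                 width = width,
                 shape = if (width < sharp_cut) "sharp" else "broad"),
            class = "promoter_width")
}

#' Quantile widths for every cluster in a tag_clusters object
#'
#' @param tc A [cluster_ctss()] result.
#' @inheritParams quantile_width
#' @return data.frame: one row per cluster with the [quantile_width()]
#'   fields appended.
#' @export
cluster_widths <- function(tc, q_low = 0.1, q_high = 0.9, sharp_cut = 10L) {
  stopifnot(inherits(tc, "tag_clusters"))
  res <- lapply(split(tc$members, tc$members$cluster_id), function(g) {
    w <- quantile_width(g$pos, g$count, g$strand[1],
                        q_low = q_low, q_high = q_high, sharp_cut = sharp_cut)
    data.frame(cluster_id = g$cluster_id[1],
               q_low_pos = w$q_low_pos, q_high_pos = w$q_high_pos,
               width = w$width, shape = w$shape, stringsAsFactors = FALSE)
  })
  out <- merge(tc$clusters, do.call(rbind, res), by = "cluster_id")
  out[order(out$cluster_id), , drop = FALSE]
}

#' Extract transcript-strand genomic sequence from a 5' end
#'
#' Returns up to `len` nucleotides in transcription direction starting at
#' `pos` (the +1 base): downstream on `+`, reverse-complemented upstream on
#' `-`. Clipped at chromosome bounds.
#'
#' @param genome A `Biostrings::DNAStringSet` keyed by chromosome name.
#' @param chrom,pos,strand Location of the 5' end (1-based).
#' @param len Number of nucleotides requested.
#' @return Character string (possibly shorter than `len` near a boundary).
#' @export
tss_sequence <- function(genome, chrom, pos, strand, len) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  chr <- genome[[chrom]]
  n <- length(chr)
  if (pos < 1L || pos > n) stop("position ", pos, " outside ", chrom)
  if (strand == "+") {
    as.character(Biostrings::subseq(chr, pos, min(n, pos + len - 1L)))
  } else {
    s <- Biostrings::subseq(chr, max(1L, pos - len + 1L), pos)
    as.character(Biostrings::reverseComplement(s))
  }
}

#' Build a per-gene TSS profile
#'
#' Collects a gene's CTSS positions with tag fractions `f_i` (summing to 1)
#' and the pyrimidine run length `L_i` of the genomic sequence read from
#' each position in transcription direction (run must start at the +1 base;
#' purine start gives `L_i = 0`).
#'
#' @param positions,counts CTSS positions and tag counts for one gene.
#' @param strand,chrom Gene strand and chromosome.
#' @param genome `DNAStringSet` genome.
#' @param gene_id Identifier carried through.
#' @param cap Maximum run length extracted (default 16).
#' @return List of class `gene_tss_profile`: `gene_id`, `strand`, `pos`,
#'   `count`, `f`, `L`.
#' @export
gene_tss_profile <- function(positions, counts, strand, chrom, genome,
                             gene_id = NA_character_, cap = 16L) {
  if (length(positions) == 0L || sum(counts) <= 0)
    stop("profile with zero tags")
  f <- counts / sum(counts)
  L <- vapply(positions, function(p) {
    s <- tss_sequence(genome, chrom, p, strand, cap + 1L)
    pyrimidine_run_length(s, 1L, cap = cap)
  }, integer(1))
  structure(list(gene_id = gene_id, strand = strand, pos = positions,
                 count = counts, f = f, L = L),
            class = "gene_tss_profile")
}

#' TOPscore of a gene TSS profile
#'
#' `topscore = sum_i f_i * min(L_i, cap)`: tag fraction at each observed TSS
#' weighted by the (capped) pyrimidine run length starting at that 5' end.
#' A transform `g(L)` may be supplied to change the per-position score.
#'
#' @param profile A [gene_tss_profile()].
#' @param cap Run-length cap (default 16).
#' @param transform Optional function applied to the capped run lengths in
#'   place of the identity.
#' @return List: `gene_id`, `topscore`, `is_top_gt2` (`topscore > 2`).
#' @export
topscore <- function(profile, cap = 16L, transform = identity) {
  stopifnot(inherits(profile, "gene_tss_profile"))
  if (sum(profile$count) <= 0) stop("profile with zero tags")
  sc <- sum(profile$f * transform(pmin(profile$L, cap)))
  list(gene_id = profile$gene_id, topscore = sc, is_top_gt2 = sc > 2)
}

# Assign each CTSS record to a gene by span + strand overlap; NA when no gene
# matches. `genes` needs gene_id, chrom, strand and either start/end or
# gene_start/gene_end columns.
assign_genes <- function(records, genes) {
  st <- genes$start %||% genes$gene_start
  en <- genes$end %||% genes$gene_end
  if (is.null(st) || is.null(en))
    stop("gene annotation needs start/end (or gene_start/gene_end) columns")
  gid <- rep(NA_character_, nrow(records))
  for (k in seq_len(nrow(genes))) {
    hit <- records$chrom == genes$chrom[k] &
      records$strand == genes$strand[k] &
      records$pos >= st[k] & records$pos <= en[k]
    gid[hit] <- genes$gene_id[k]
  }
  gid
}

#' Per-gene TOPscores from a CTSS table
#'
#' Assigns CTSS records to genes by span and strand, builds a TSS profile per
#' gene and scores it.
#'
#' @param table A [ctss_table()].
#' @param genome `DNAStringSet`.
#' @param genes Annotation data.frame: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`.
#' @param cap Run-length cap.
#' @return data.frame: `gene_id`, `topscore`, `total_tags`, `is_top_gt2`.
#' @export
gene_topscores <- function(table, genome, genes, cap = 16L) {
  gid <- assign_genes(table, genes)
  keep <- !is.na(gid)
  df <- as.data.frame(table)[keep, , drop = FALSE]
  df$gene_id <- gid[keep]
  res <- lapply(split(df, df$gene_id), function(g) {
    pr <- gene_tss_profile(g$pos, g$count, g$strand[1], g$chrom[1], genome,
                           gene_id = g$gene_id[1], cap = cap)
    ts <- topscore(pr, cap = cap)
    data.frame(gene_id = ts$gene_id, topscore = ts$topscore,
               total_tags = sum(g$count), is_top_gt2 = ts$is_top_gt2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Filter genes by mean read count across samples
#'
#' Keeps genes whose arithmetic mean tag count across the given samples is
#' strictly greater than `min_avg` (default 500).
#'
#' @param counts Numeric matrix, genes x samples, rownames = gene ids.
#' @param min_avg Strict lower bound on the mean (default 500).
#' @return Character vector of gene ids passing the filter.
#' @export
filter_min_avg_reads <- function(counts, min_avg = 500) {
  counts <- as.matrix(counts)
  rownames(counts)[rowMeans(counts) > min_avg]
}

#' Per-gene PRTE scores from a CTSS table
#'
#' Each tag is modelled as a `read_len`-nt transcript-strand genomic read
#' starting at its 5' end; a tag contributes its count to its gene's PRTE
#' count when the read contains at least one PRTE motif. Counts are
#' normalised to counts per million mapped reads; genes with score
#' `> threshold` are flagged PRTE-containing.
#'
#' @param table A [ctss_table()].
#' @param genome `DNAStringSet`.
#' @param genes Annotation data.frame (`gene_id`, `chrom`, `strand`,
#'   `start`, `end`).
#' @param read_len Modelled read length in nt (default 75).
#' @param threshold Strict flag threshold on the CPM score (default 10).
#' @return data.frame: `gene_id`, `prte_count`, `prte_score`, `prte_flag`.
#'   CTSS records outside any gene are skipped with a message.
#' @export
gene_prte_scores <- function(table, genome, genes, read_len = 75L,
                             threshold = 10) {
  ls <- library_size(table)
  if (ls <= 0) stop("empty CTSS table")
  gid <- assign_genes(table, genes)
  if (anyNA(gid)) {
    n_skip <- sum(table$count[is.na(gid)])
    message(sum(is.na(gid)), " CTSS positions (", n_skip,
            " tags) outside any gene: skipped")
  }
  keep <- !is.na(gid)
  df <- as.data.frame(table)[keep, , drop = FALSE]
  df$gene_id <- gid[keep]
  has_prte <- vapply(seq_len(nrow(df)), function(i) {
    s <- tss_sequence(genome, df$chrom[i], df$pos[i], df$strand[i], read_len)
    nrow(scan_prte(s)) > 0L
  }, logical(1))
  cnt <- tapply(df$count * has_prte, df$gene_id, sum)
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  out$prte_count <- as.numeric(cnt[out$gene_id])
  out$prte_count[is.na(out$prte_count)] <- 0
  out$prte_score <- out$prte_count / ls * 1e6
  out$prte_flag <- out$prte_score > threshold
  out
}

#' Read fractions across TSS windows
#'
#' For each gene, the fraction of its tags falling in each of its windows,
#' relative to the total over all of that gene's windows. Genes with zero
#' tags in every window get `NA` fractions.
#'
#' @param table A [ctss_table()].
#' @param windows data.frame: `chrom`, `start`, `end` (1-based inclusive),
#'   `strand`, `gene_id`, `window` (index or label). Windows of one gene
#'   must not overlap and must share the gene's strand.
#' @return data.frame: `gene_id`, `window`, `tags`, `fraction`.
#' @export
window_read_fractions <- function(table, windows) {
  stopifnot(all(c("chrom", "start", "end", "strand", "gene_id", "window")
                %in% names(windows)))
  tags <- vapply(seq_len(nrow(windows)), function(k) {
    hit <- table$chrom == windows$chrom[k] &
      table$strand == windows$strand[k] &
      table$pos >= windows$start[k] & table$pos <= windows$end[k]
    sum(table$count[hit])
  }, numeric(1))
  out <- data.frame(gene_id = windows$gene_id, window = windows$window,
                    tags = tags, stringsAsFactors = FALSE)
  tot <- tapply(out$tags, out$gene_id, sum)
  denom <- as.numeric(tot[out$gene_id])
  out$fraction <- ifelse(denom > 0, out$tags / denom, NA_real_)
  out
}
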