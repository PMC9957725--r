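# Polysome heavy/light translational-efficiency readouts, gene-level TE,
# two-sample KS comparison, differential tag-cluster usage with BH
# correction, and the mTORC1-dependency reporter statistic.

#' Classify an HP/LP ratio into a TE class
#'
#' low: ratio < 1; middle: 1 <= ratio <= 3; high: ratio > 3.
#'
#' @param ratio Numeric vector of heavy/light ratios.
#' @return Character vector of classes; `NA` input stays `NA`.
#' @export
te_class <- function(ratio) {
  ifelse(is.na(ratio), NA_character_,
         ifelse(ratio < 1, "low", ifelse(ratio > 3, "high", "middle")))
}

# Sum tpm-normalised tags over a region for one ctss_table.
region_tpm <- function(table, region) {
  table <- normalize_tpm(table)
  hit <- table$chrom == region$chrom & table$strand == region$strand &
    table$pos >= region$start & table$pos <= region$end
  sum(table$tpm[hit])
}

#' Heavy/light polysome ratio per region
#'
#' Normalises each replicate library to tags per million, averages replicate
#' tpm within the heavy and light fractions per region, and reports the
#' HP/LP ratio with its TE class (low < 1, middle 1-3, high > 3) as a proxy
#' for translational efficiency. Regions with zero light-fraction signal get
#' an `NA` ratio (undefined); regions absent from both fractions are skipped
#' with a message.
#'
#' @param hp,lp A [ctss_table()] or list of replicate tables for the heavy
#'   and light polysome fractions.
#' @param regions data.frame: `region_id`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @return data.frame: `region_id`, `hp_norm`, `lp_norm`, `ratio`,
#'   `te_class`.
#' @export
hp_lp_ratio <- function(hp, lp, regions) {
  as_list <- function(x) if (inherits(x, "ctss_table")) list(x) else x
  hp <- as_list(hp); lp <- as_list(lp)
  res <- lapply(seq_len(nrow(regions)), function(k) {
    reg <- regions[k, ]
    hpv <- mean(vapply(hp, region_tpm, numeric(1), region = reg))
    lpv <- mean(vapply(lp, region_tpm, numeric(1), region = reg))
    if (hpv == 0 && lpv == 0) {
      message("region ", reg$region_id, " absent from both fractions: skipped")
      return(NULL)
    }
    ratio <- if (lpv > 0) hpv / lpv else NA_real_
    data.frame(region_id = reg$region_id, hp_norm = hpv, lp_norm = lpv,
               ratio = ratio, te_class = te_class(ratio),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(region_id = character(0),
                                      hp_norm = numeric(0), lp_norm = numeric(0),
                                      ratio = numeric(0), te_class = character(0))
  rownames(out) <- NULL
  out
}

#' Reads per kilobase per million mapped reads
#'
#' @param counts Count matrix (genes x samples) or vector.
#' @param lengths Feature lengths in nt.
#' @param lib_sizes Library sizes (per sample); defaults to column sums.
#' @return Matrix/vector of RPKM values.
#' @export
rpkm <- function(counts, lengths, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  sweep(counts / (lengths / 1e3), 2, lib_sizes / 1e6, "/")
}

#' Gene-level translational efficiency
#'
#' TE = ribosome-profiling RPKM / RNA-seq RPKM per gene, per condition
#' (replicate RPKM averaged within condition). Genes must pass RNA
#' `rpkm > 1` in both conditions; the optional `base_mean` filter
#' additionally requires a mean raw RNA count `> 25`. The log2 fold change
#' is computed between the two conditions on mean TE.
#'
#' @param ribo_counts,rna_counts Count matrices (genes x samples) with
#'   identical rownames; columns grouped by `conditions`.
#' @param lengths Gene lengths in nt (named or in row order).
#' @param conditions Factor/character of length ncol giving the condition of
#'   each column (exactly two levels for `log2fc`).
#' @param lib_sizes_ribo,lib_sizes_rna Optional library sizes.
#' @param min_rna_rpkm RNA RPKM filter (strict, default 1).
#' @param base_mean_filter If `TRUE`, additionally require mean raw RNA
#'   count > `min_base_mean` across all samples (default off).
#' @param min_base_mean Base-mean cut (default 25).
#' @return data.frame: `gene_id`, `te_<cond>` per condition, `log2fc`
#'   (second level vs first), `passes_filters`.
#' @export
gene_te <- function(ribo_counts, rna_counts, lengths, conditions,
                    lib_sizes_ribo = NULL, lib_sizes_rna = NULL,
                    min_rna_rpkm = 1, base_mean_filter = FALSE,
                    min_base_mean = 25) {
  ribo_counts <- as.matrix(ribo_counts); rna_counts <- as.matrix(rna_counts)
  stopifnot(identical(rownames(ribo_counts), rownames(rna_counts)),
            length(conditions) == ncol(ribo_counts))
  conditions <- factor(conditions, levels = unique(conditions))
  levs <- levels(conditions)
  r_ribo <- rpkm(ribo_counts, lengths, lib_sizes_ribo)
  r_rna <- rpkm(rna_counts, lengths, lib_sizes_rna)
  per_lev <- function(f) {
    matrix(unlist(lapply(levs, f)), ncol = length(levs),
           dimnames = list(rownames(ribo_counts), levs))
  }
  te <- per_lev(function(lv) {
    cols <- conditions == lv
    rowMeans(r_ribo[, cols, drop = FALSE]) /
      rowMeans(r_rna[, cols, drop = FALSE])
  })
  rna_ok <- per_lev(function(lv) {
    rowMeans(r_rna[, conditions == lv, drop = FALSE]) > min_rna_rpkm
  })
  passes <- apply(rna_ok, 1, all)
  if (base_mean_filter) passes <- passes & rowMeans(rna_counts) > min_base_mean
  out <- data.frame(gene_id = rownames(ribo_counts), stringsAsFactors = FALSE)
  for (lv in levs) out[[paste0("te_", lv)]] <- te[, lv]
  if (length(levs) == 2L) out$log2fc <- log2(te[, levs[2L]] / te[, levs[1L]])
  out$passes_filters <- passes
  rownames(out) <- NULL
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|`; p-value from the asymptotic Kolmogorov
#' distribution with effective sample size `n = nx*ny/(nx+ny)`.
#'
#' @param x,y Non-empty numeric samples.
#' @return List of class `ks_result`: `D` in `[0,1]`, `p`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  nx <- length(x); ny <- length(y)
  pts <- sort(unique(c(x, y)))
  ex <- vapply(pts, function(t) mean(x <= t), numeric(1))
  ey <- vapply(pts, function(t) mean(y <= t), numeric(1))
  D <- max(abs(ex - ey))
  ne <- nx * ny / (nx + ny)
  lambda <- sqrt(ne) * D
  # two-sided asymptotic Kolmogorov tail: 2 * sum (-1)^(k-1) exp(-2 k^2 l^2)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  structure(list(D = D, p = min(max(p, 0), 1)), class = "ks_result")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control: `padj_(i) = min_{j >= i} (m/j) p_(j)` clipped at 1
#' and mapped back to the input order.
#'
#' @param pvalues Numeric vector in `[0, 1]` (NA allowed, propagated).
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  m <- length(p)
  if (m > 0L) {
    ord <- order(p)
    adj <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
    res <- numeric(m)
    res[ord] <- adj
    out[!is.na(pvalues)] <- res
  }
  out
}

#' Differential tag-cluster usage between two conditions
#'
#' For each cluster, a 2x2 table (cluster tags vs remaining library tags,
#' condition A vs B; replicates summed beforehand) is tested with Fisher's
#' exact test (two-sided); the log2 fold change is computed on tags per
#' million with a pseudocount, and p-values are Benjamini-Hochberg adjusted.
#' This is a deliberately self-contained substitute for a negative-binomial
#' count model (see the methods vignette).
#'
#' @param counts_a,counts_b Summed tag counts per cluster in conditions A/B
#'   (same length/order, rownames or `cluster_ids` give the ids).
#' @param lib_a,lib_b Total library tag counts per condition (>= the column
#'   sums; both > 0).
#' @param cluster_ids Optional cluster identifiers.
#' @param pseudocount Added to tpm before the log2 ratio (default 0.5).
#' @return data.frame: `cluster_id`, `log2fc` (B vs A), `p`, `padj`.
#' @export
differential_cluster_usage <- function(counts_a, counts_b, lib_a = sum(counts_a),
                                       lib_b = sum(counts_b),
                                       cluster_ids = NULL, pseudocount = 0.5) {
  stopifnot(length(counts_a) == length(counts_b))
  if (lib_a <= 0 || lib_b <= 0) stop("zero total tags in a condition")
  if (is.null(cluster_ids))
    cluster_ids <- names(counts_a) %||% seq_along(counts_a)
  p <- vapply(seq_along(counts_a), function(i) {
    tab <- matrix(c(counts_a[i], lib_a - counts_a[i],
                    counts_b[i], lib_b - counts_b[i]), nrow = 2)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  tpm_a <- counts_a / lib_a * 1e6
  tpm_b <- counts_b / lib_b * 1e6
  data.frame(cluster_id = cluster_ids,
             log2fc = log2((tpm_b + pseudocount) / (tpm_a + pseudocount)),
             p = p, padj = bh_adjust(p), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' mTORC1 dependency of a reporter
#'
#' `(SCC no Torin - SCC Torin) / (SCC no Torin - WT Torin)`: the
#' Torin-1-induced drop in the tumour cells normalised to the drop relative
#' to the Torin-treated wild-type baseline. 1 means the full effect, 0 none.
#'
#' @param scc_ctrl,scc_torin,wt_torin Reporter TE values (untreated SCC,
#'   Torin-treated SCC, Torin-treated WT).
#' @param tol Relative tolerance on the denominator: an error is raised when
#'   `|scc_ctrl - wt_torin| < tol * |scc_ctrl|`.
#' @return Dimensionless score.
#' @export
mtorc1_dependency <- function(scc_ctrl, scc_torin, wt_torin, tol = 1e-9) {
  den <- scc_ctrl - wt_torin
  if (abs(den) < tol * abs(scc_ctrl))
    stop("mTORC1 dependency undefined: SCC control and WT+Torin TE coincide (denominator ",
         format(den), ")")
  (scc_ctrl - scc_torin) / den
}

#' Reporter translational efficiency from dual-luciferase data
#'
#' `te = (firefly / renilla) / mrna_level`, optionally normalised so a
#' designated reference measurement is 100%.
#'
#' @param firefly,renilla Luciferase activities (renilla > 0).
#' @param mrna_level Reporter mRNA level from qPCR (> 0).
#' @param reference Index of the reference measurement for 100%-scaling, or
#'   `NULL` for raw values.
#' @return Numeric vector of TE values (percent when `reference` given).
#' @export
reporter_te <- function(firefly, renilla, mrna_level, reference = NULL) {
  if (any(renilla <= 0) || any(mrna_level <= 0) || any(firefly <= 0))
    stop("firefly, renilla and mrna_level must be positive")
  te <- (firefly / renilla) / mrna_level
  if (!is.null(reference)) te <- te / te[reference] * 100
  te
}
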