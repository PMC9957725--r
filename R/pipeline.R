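# Pipeline orchestration: a resolved parameter set whose defaults are the
# published cutoffs, and a run_pipeline() sequencing clustering, widths,
# TOPscore/PRTE, window fractions, HP/LP ratios, 5'UTR features and the
# optional survival stage over a dataset directory.

#' Pipeline parameter set
#'
#' All analysis thresholds in one place; the defaults are the published
#' cutoffs (clustering distance 20 bp, 0.1-0.9 quantile width with the
#' 10-bp sharp/broad cut, TOPscore cap 16, >500-read average filter, 75-nt
#' PRTE reads with the >10 CPM flag, TE class cuts at ratios 1 and 3).
#'
#' @param maxdist CTSS clustering distance (bp).
#' @param q_low,q_high Promoter width quantiles.
#' @param sharp_cut Sharp/broad width cut (bp).
#' @param topscore_cap Pyrimidine-run cap for the TOPscore.
#' @param min_avg_reads Strict mean-read filter for TOPscore reporting.
#' @param prte_read_len Modelled CAGE read length (nt).
#' @param prte_threshold Strict PRTE-score flag threshold (CPM).
#' @param te_cuts Low/middle/high HP-LP ratio cuts.
#' @param seed Seed recorded with the run.
#' @return List of class `pipeline_params`.
#' @export
pipeline_params <- function(maxdist = 20L, q_low = 0.1, q_high = 0.9,
                            sharp_cut = 10L, topscore_cap = 16L,
                            min_avg_reads = 500, prte_read_len = 75L,
                            prte_threshold = 10, te_cuts = c(1, 3),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_params")
}

# Sum replicate ctss_tables into one pooled table.
pool_ctss <- function(tables, sample_id = "pooled") {
  df <- do.call(rbind, lapply(tables, function(t)
    as.data.frame(t)[, c("chrom", "pos", "strand", "count")]))
  agg <- stats::aggregate(count ~ chrom + pos + strand, df, sum)
  ctss_table(agg, sample_id = sample_id,
             condition = attr(tables[[1]], "condition"),
             fraction = attr(tables[[1]], "fraction"))
}

#' Run the full 5'UTR landscape pipeline on a dataset directory
#'
#' Expects the layout written by [write_simulation()]: `genome.fa`,
#' `genes.gtf`, per-sample `ctss_<cond>_<rep>_<fraction>.tsv`, optionally
#' `windows.bed`, `ribo_counts.tsv`/`rna_counts.tsv`, `survival.tsv` and
#' `transcript_tpm.tsv`. Stages: distance clustering and promoter widths
#' per condition; per-gene TOPscore and PRTE score; TSS-window read
#' fractions; HP/LP TE ratios over windows (when polysome fractions exist);
#' 5'UTR features from the annotation; PSI survival stratification (when
#' survival inputs exist). Any stage failure aborts with a stage-tagged
#' error; completed stage tables are retained in the error condition.
#'
#' @param dir Dataset directory.
#' @param params A [pipeline_params()].
#' @param out_dir Optional directory for TSV/JSON outputs.
#' @return List of class `run_report`: per-stage tables plus the resolved
#'   parameters.
#' @export
run_pipeline <- function(dir, params = pipeline_params(), out_dir = NULL) {
  if (!file.exists(file.path(dir, "genome.fa")))
    stop("configuration error: genome.fa not found in ", dir)
  report <- list(params = params)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  genome <- stage("input", read_genome(file.path(dir, "genome.fa")))
  ann <- stage("input", read_gtf(file.path(dir, "genes.gtf")))
  genes <- ann$genes
  ctss_files <- list.files(dir, "^ctss_.*\\.tsv$", full.names = TRUE)
  meta <- do.call(rbind, lapply(ctss_files, function(f) {
    p <- strsplit(sub("\\.tsv$", "", basename(f)), "_")[[1]]
    data.frame(path = f, condition = p[2], rep = p[3], fraction = p[4],
               stringsAsFactors = FALSE)
  }))
  tabs <- lapply(seq_len(nrow(meta)), function(i)
    read_ctss(meta$path[i], sample_id = basename(meta$path[i]),
              condition = meta$condition[i], fraction = meta$fraction[i]))

  # clustering + promoter widths on pooled total tags per condition
  report$widths <- stage("width", {
    do.call(rbind, lapply(unique(meta$condition), function(cond) {
      sel <- meta$condition == cond & meta$fraction == "total"
      if (!any(sel)) return(NULL)
      pooled <- pool_ctss(tabs[sel])
      tc <- cluster_ctss(pooled, maxdist = params$maxdist)
      w <- cluster_widths(tc, q_low = params$q_low, q_high = params$q_high,
                          sharp_cut = params$sharp_cut)
      cbind(condition = cond, w)
    }))
  })

  # TOPscore and PRTE per gene, pooled per condition, with the read filter
  report$topscore <- stage("topscore", {
    do.call(rbind, lapply(unique(meta$condition), function(cond) {
      sel <- meta$condition == cond & meta$fraction == "total"
      if (!any(sel)) return(NULL)
      pooled <- pool_ctss(tabs[sel])
      ts <- gene_topscores(pooled, genome, genes, cap = params$topscore_cap)
      per_sample <- sapply(which(sel), function(i) {
        gid <- assign_genes(tabs[[i]], genes)
        v <- tapply(tabs[[i]]$count, gid, sum)
        as.numeric(v[ts$gene_id])
      })
      per_sample[is.na(per_sample)] <- 0
      ts$avg_reads <- rowMeans(as.matrix(per_sample))
      ts$passes_read_filter <- ts$avg_reads > params$min_avg_reads
      cbind(condition = cond, ts)
    }))
  })
  report$prte <- stage("prte", {
    do.call(rbind, lapply(unique(meta$condition), function(cond) {
      sel <- meta$condition == cond & meta$fraction == "total"
      if (!any(sel)) return(NULL)
      pooled <- pool_ctss(tabs[sel])
      cbind(condition = cond,
            gene_prte_scores(pooled, genome, genes,
                             read_len = params$prte_read_len,
                             threshold = params$prte_threshold))
    }))
  })

  wfile <- file.path(dir, "windows.bed")
  if (file.exists(wfile)) {
    windows <- read_bed_windows(wfile)
    report$window_fractions <- stage("windows", {
      do.call(rbind, lapply(unique(meta$condition), function(cond) {
        sel <- meta$condition == cond & meta$fraction == "total"
        if (!any(sel)) return(NULL)
        cbind(condition = cond,
              window_read_fractions(pool_ctss(tabs[sel]), windows))
      }))
    })
    if (all(c("LP", "HP") %in% meta$fraction)) {
      report$hp_lp <- stage("hp_lp", {
        regions <- data.frame(region_id = paste0(windows$gene_id, ":",
                                                 windows$window),
                              windows[, c("chrom", "start", "end", "strand")],
                              stringsAsFactors = FALSE)
        do.call(rbind, lapply(unique(meta$condition), function(cond) {
          hp <- tabs[meta$condition == cond & meta$fraction == "HP"]
          lp <- tabs[meta$condition == cond & meta$fraction == "LP"]
          if (!length(hp) || !length(lp)) return(NULL)
          cbind(condition = cond, hp_lp_ratio(hp, lp, regions))
        }))
      })
    }
  }

  if (nrow(ann$utrs) > 0) {
    report$utr_features <- stage("features", {
      do.call(rbind, lapply(seq_len(nrow(ann$utrs)), function(i) {
        u <- ann$utrs[i, ]
        tss <- if (u$strand == "+") u$start else u$end
        s <- tss_sequence(genome, u$chrom, tss, u$strand,
                          u$end - u$start + 1L)
        cbind(gene_id = u$gene_id, utr_features(s))
      }))
    })
  }

  sfile <- file.path(dir, "survival.tsv")
  tfile <- file.path(dir, "transcript_tpm.tsv")
  if (file.exists(sfile) && file.exists(tfile)) {
    report$survival <- stage("survival", {
      surv <- read_survival_tsv(sfile)
      tp <- read_tpm_tsv(tfile)
      psi <- psi_per_isoform(tp$tpm, tp$gene_map)
      res <- lapply(rownames(psi), function(tx) {
        st <- stratify_survival(psi[tx, ], surv)
        data.frame(transcript_id = tx, n_low = length(st$groups$low_group),
                   n_high = length(st$groups$high_group),
                   median_low = st$km_low$median_survival,
                   median_high = st$km_high$median_survival,
                   logrank_chisq = st$logrank$chi_square,
                   logrank_p = st$logrank$p, cox_hr = st$cox$hr,
                   cox_p = st$cox$p, stringsAsFactors = FALSE)
      })
      do.call(rbind, res)
    })
  }
  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in setdiff(names(report), "params")) {
      utils::write.table(report[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      list(params = unclass(params),
           stages = setdiff(names(report), "params"),
           n_rows = lapply(report[setdiff(names(report), "params")], nrow)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report with stages:",
      paste(setdiff(names(x), "params"), collapse = ", "), "\n")
  invisible(x)
}
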