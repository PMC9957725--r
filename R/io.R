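# Readers and writers for the plain-text formats the pipeline exchanges:
# FASTA genomes, GTF annotation, CTSS TSV tables, BED6 TSS windows, count
# and survival TSVs. CTSS files carry 1-based positions (the internal
# convention); BED is 0-based half-open and converted at the boundary.

#' Read a CTSS table from TSV
#'
#' Four tab-separated columns: chrom, pos (1-based), strand, count. Lines
#' starting with `#` are ignored.
#'
#' @param path File path.
#' @param sample_id,condition,fraction Labels attached to the table.
#' @return A [ctss_table()].
#' @export
read_ctss <- function(path, sample_id = basename(path),
                      condition = NA_character_, fraction = NA_character_) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("chrom", "pos", "strand", "count"),
                          colClasses = c("character", "integer", "character",
                                         "integer"))
  bad <- which(!df$strand %in% c("+", "-") | df$count < 0 | is.na(df$pos))
  if (length(bad))
    stop("malformed CTSS record in ", path, " (data line ", bad[1], ")")
  ctss_table(df, sample_id = sample_id, condition = condition,
             fraction = fraction)
}

#' Write a CTSS table to TSV
#' @param table A [ctss_table()].
#' @param path Output path.
#' @export
write_ctss <- function(table, path) {
  df <- as.data.frame(table)[, c("chrom", "pos", "strand", "count")]
  df <- df[order(df$chrom, df$pos, df$strand), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA file.
#' @return `Biostrings::DNAStringSet` with names truncated at whitespace.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read gene annotation from GTF
#'
#' Extracts `gene` features (gene_id, span, strand) and, when present,
#' `five_prime_utr` features, using rtracklayer.
#'
#' @param path GTF file.
#' @return List: `genes` (data.frame `gene_id`, `chrom`, `strand`, `start`,
#'   `end`) and `utrs` (same shape; zero rows when absent).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr),
                   end = BiocGenerics::end(gr),
                   strand = as.character(BiocGenerics::strand(gr)),
                   type = as.character(gr$type),
                   gene_id = gr$gene_id, stringsAsFactors = FALSE)
  pick <- function(ty) {
    out <- df[df$type == ty, c("gene_id", "chrom", "strand", "start", "end")]
    rownames(out) <- NULL
    out
  }
  list(genes = pick("gene"), utrs = pick("five_prime_utr"))
}

write_gtf_lines <- function(genes, path) {
  att <- function(id, cls) sprintf('gene_id "%s"; gene_class "%s";', id, cls)
  gene_lines <- sprintf("%s\tutrscape_sim\tgene\t%d\t%d\t.\t%s\t.\t%s",
                        genes$chrom, genes$gene_start, genes$gene_end,
                        genes$strand, att(genes$gene_id, genes$class))
  utr_lines <- sprintf("%s\tutrscape_sim\tfive_prime_utr\t%d\t%d\t.\t%s\t.\t%s",
                       genes$chrom, genes$utr_start, genes$utr_end,
                       genes$strand, att(genes$gene_id, genes$class))
  writeLines(c(gene_lines, utr_lines), path)
  invisible(path)
}

#' Read TSS windows from BED6
#'
#' BED is 0-based half-open; converted to the internal 1-based inclusive
#' convention. The name field must be `gene_id:window_index`; strand `"."`
#' is rejected (fractions need a transcription direction).
#'
#' @param path BED6 file.
#' @return data.frame: `chrom`, `start`, `end`, `strand`, `gene_id`,
#'   `window`.
#' @export
read_bed_windows <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"))
  if (any(df$strand == "."))
    stop("BED windows require an explicit strand ('.' found in ", path, ")")
  parts <- strsplit(as.character(df$name), ":", fixed = TRUE)
  data.frame(chrom = as.character(df$chrom),
             start = df$start + 1L, end = df$end,
             strand = as.character(df$strand),
             gene_id = vapply(parts, `[`, character(1), 1L),
             window = vapply(parts, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

write_bed_windows <- function(windows, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s:%s\t0\t%s", windows$chrom,
                     windows$start - 1L, windows$end,
                     windows$gene_id, windows$window, windows$strand),
             path)
  invisible(path)
}

#' Read a gene count table (TSV with header: gene_id, length, samples...)
#' @param path TSV file.
#' @return List: `counts` (matrix genes x samples), `lengths` (named).
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(counts) <- df$gene_id
  list(counts = counts, lengths = stats::setNames(df$length, df$gene_id))
}

#' Read a survival table (TSV: patient_id, time, event)
#' @param path TSV file.
#' @return data.frame with validated `time > 0` and `event` in {0, 1}.
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.delim(path)
  stopifnot(all(c("patient_id", "time", "event") %in% names(df)))
  if (any(df$time <= 0) || !all(df$event %in% c(0, 1)))
    stop("invalid survival record in ", path)
  df
}

#' Read a transcript TPM matrix (TSV: transcript_id, gene_id, patients...)
#' @param path TSV file.
#' @return List: `tpm` (matrix), `gene_map` (named character).
#' @export
read_tpm_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  tpm <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(tpm) <- df$transcript_id
  list(tpm = tpm, gene_map = stats::setNames(df$gene_id, df$transcript_id))
}

#' Write a complete simulated dataset to a directory
#'
#' Emits genome.fa, genes.gtf, windows.bed, per-sample CTSS TSVs (total and,
#' when polysome splits are given, LP/HP), ribo/rna count TSVs, survival and
#' transcript-TPM TSVs, and the planted truth as JSON.
#'
#' @param world [make_genome()] result.
#' @param dir Output directory (created).
#' @param tables Optional [simulate_ctss()] output.
#' @param polysome Optional [simulate_polysome_split()] output.
#' @param counts Optional [simulate_ribo_rna()] output.
#' @param cohort Optional [simulate_survival()] output.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(world, dir, tables = NULL, polysome = NULL,
                             counts = NULL, cohort = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(world$genome, file.path(dir, "genome.fa"))
  write_gtf_lines(world$genes, file.path(dir, "genes.gtf"))
  if (!is.null(world$windows))
    write_bed_windows(world$windows, file.path(dir, "windows.bed"))
  for (cond in names(tables)) {
    for (r in names(tables[[cond]])) {
      write_ctss(tables[[cond]][[r]],
                 file.path(dir, sprintf("ctss_%s_%s_total.tsv", cond, r)))
    }
  }
  for (cond in names(polysome)) {
    for (r in names(polysome[[cond]])) {
      for (fr in c("LP", "HP"))
        write_ctss(polysome[[cond]][[r]][[fr]],
                   file.path(dir, sprintf("ctss_%s_%s_%s.tsv", cond, r, fr)))
    }
  }
  if (!is.null(counts)) {
    for (what in c("ribo", "rna")) {
      df <- data.frame(gene_id = rownames(counts[[what]]),
                       length = counts$lengths[rownames(counts[[what]])],
                       counts[[what]], check.names = FALSE)
      utils::write.table(df, file.path(dir, paste0(what, "_counts.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(cohort)) {
    utils::write.table(cohort$survival, file.path(dir, "survival.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    df <- data.frame(transcript_id = rownames(cohort$tpm),
                     gene_id = cohort$gene_map[rownames(cohort$tpm)],
                     cohort$tpm, check.names = FALSE)
    utils::write.table(df, file.path(dir, "transcript_tpm.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- world$genes
  truth$utr_seq <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"), dataframe = "rows")
  invisible(dir)
}
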