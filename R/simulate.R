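# Synthetic-data generator: a toy genome with planted promoter classes and
# motifs, CTSS tables per condition/replicate, polysome heavy/light splits,
# negative-binomial ribo/RNA counts, and survival cohorts tied to isoform
# PSI. Every dataset carries its planted truth.

#' Simulation configuration
#'
#' Bundles the generator's stated world. Defaults: four promoter classes of
#' 25 genes each; 5'UTR lengths 30-300 nt (mammalian range); library depth
#' 1e6 tags; 2 replicates (matching the two independent polysome CAGE
#' experiments the readouts average over); heavy-polysome odds with a 3-fold
#' TOP effect (`beta_top = log(3)`); 519 patients (the HNSCC cohort size)
#' with ~50% censoring and a baseline median survival of 60 months.
#'
#' @param n_genes Named integer vector: genes per promoter class
#'   (`sharp_top`, `broad_mixed`, `sharp_nontop`, `prte_plus`).
#' @param utr_len_range 5'UTR length range in nt.
#' @param tract_range Range of the planted TOP tract (pyrimidines following
#'   the +1 C), within the 4-16 motif definition.
#' @param depth Tags per CTSS library.
#' @param replicates Replicate libraries per condition.
#' @param conditions Condition labels; the second condition carries the
#'   planted TSS-window switch.
#' @param switch_fraction Fraction of `broad_mixed` genes with a planted
#'   window switch between conditions.
#' @param beta0,beta_top,beta_prte,beta_len,beta_gc Heavy-polysome
#'   log-odds: intercept and effects of TOP flag, PRTE flag, standardised
#'   UTR length and GC.
#' @param expr_sdlog Log-normal sd of gene expression.
#' @param nb_dispersion Negative-binomial dispersion of count simulation.
#' @param n_patients,beta_s,baseline_hazard,censor_frac Survival cohort
#'   size, log hazard ratio per unit covariate, baseline exponential hazard
#'   (per month), target censoring fraction.
#' @param seed Integer seed; fixes all downstream randomness (each stage
#'   draws from a stream keyed by seed + stage offset).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = c(sharp_top = 25L, broad_mixed = 25L,
                                   sharp_nontop = 25L, prte_plus = 25L),
                       utr_len_range = c(30L, 300L),
                       tract_range = c(4L, 16L),
                       depth = 1e6, replicates = 2L,
                       conditions = c("WT", "SCC"),
                       switch_fraction = 0.5,
                       beta0 = 0, beta_top = log(3), beta_prte = log(2),
                       beta_len = -0.3, beta_gc = -0.2,
                       expr_sdlog = 1, nb_dispersion = 0.1,
                       n_patients = 519L, beta_s = log(2),
                       baseline_hazard = log(2) / 60, censor_frac = 0.5,
                       seed = 1L) {
  stopifnot(depth > 0, replicates >= 1, length(conditions) == 2,
            all(n_genes >= 0))
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

stage_seed <- function(config, stage) {
  offs <- c(genome = 1L, ctss = 2L, polysome = 3L, riborna = 4L,
            survival = 5L)
  (as.integer(config$seed) * 7L + offs[[stage]]) %% 2147483647L
}

rand_dna <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# Write `s` (transcript orientation, character vector) into the chromosome
# char vector starting at the 5' end `tss`, respecting strand.
plant_seq <- function(chr, tss, strand, s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(s)
  if (strand == "+") {
    chr[tss:(tss + n - 1L)] <- s
  } else {
    chr[tss:(tss - n + 1L)] <- comp[s]
  }
  chr
}

#' Build a synthetic genome with planted promoter classes
#'
#' Lays out genes (~50 per chromosome, alternating strands) over i.i.d.
#' uniform background sequence. Per class, the modal TSS is planted as:
#' `sharp_top` - C at +1 followed by a 4-16 pyrimidine tract (then a
#' purine); `sharp_nontop` - purine at +1; `prte_plus` - purine at +1 and a
#' valid PRTE 9-mer inside the 5'UTR (within 75-nt read reach of the TSS);
#' `broad_mixed` - three TSS components 15 bp apart (component 1 TOP-planted,
#' component 3 purine-start) with condition-dependent mixture weights for
#' switch genes.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_world`: `genome` (`DNAStringSet`), `genes`
#'   (annotation + planted truth), `windows` (TSS windows of broad genes),
#'   `config`.
#' @export
make_genome <- function(config = sim_config()) {
  set.seed(stage_seed(config, "genome"))
  classes <- rep(names(config$n_genes), config$n_genes)
  n <- length(classes)
  if (n == 0L) stop("no genes configured")
  ids <- sprintf("g%03d", seq_len(n))
  per_chrom <- 50L
  genes <- data.frame(
    gene_id = ids, class = classes,
    chrom = sprintf("chrS%d", (seq_len(n) - 1L) %/% per_chrom + 1L),
    strand = rep(c("+", "-"), length.out = n),
    utr_len = sample(seq(config$utr_len_range[1], config$utr_len_range[2]),
                     n, replace = TRUE),
    tract_length = sample(seq(config$tract_range[1], config$tract_range[2]),
                          n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  genes$tss_sd <- ifelse(genes$class == "broad_mixed", 2, 0.5)
  genes$is_top <- genes$class == "sharp_top"
  genes$is_prte <- genes$class == "prte_plus"
  sw <- genes$class == "broad_mixed" &
    seq_len(n) %in% which(genes$class == "broad_mixed")[
      seq_len(round(sum(genes$class == "broad_mixed") * config$switch_fraction))]
  genes$switch <- sw
  # layout: per gene a slot of flank + promoter + UTR + CDS stub + flank
  slot <- 200L + max(genes$utr_len) + 200L
  idx_in_chrom <- (seq_len(n) - 1L) %% per_chrom
  genes$anchor <- 150L + idx_in_chrom * slot    # 5'-most genomic pos of slot use
  chrom_len <- per_chrom * slot + 400L
  chroms <- unique(genes$chrom)
  seqs <- lapply(chroms, function(ch) rand_dna(chrom_len))
  names(seqs) <- chroms
  pyr <- c("C", "T"); pur <- c("A", "G")
  genes$tss <- NA_integer_; genes$utr_start <- NA_integer_
  genes$utr_end <- NA_integer_; genes$gene_start <- NA_integer_
  genes$gene_end <- NA_integer_
  windows <- NULL
  for (i in seq_len(n)) {
    g <- genes[i, ]
    chr <- seqs[[g$chrom]]
    dirn <- if (g$strand == "+") 1L else -1L
    tss <- if (g$strand == "+") g$anchor else g$anchor + g$utr_len + 150L
    span <- sort(c(tss - dirn * 60L, tss + dirn * (g$utr_len + 120L)))
    genes$tss[i] <- tss
    genes$gene_start[i] <- span[1]; genes$gene_end[i] <- span[2]
    genes$utr_start[i] <- min(tss, tss + dirn * (g$utr_len - 1L))
    genes$utr_end[i] <- max(tss, tss + dirn * (g$utr_len - 1L))
    if (g$class == "sharp_top") {
      tract <- c("C", sample(pyr, g$tract_length, replace = TRUE),
                 sample(pur, 1L))
      chr <- plant_seq(chr, tss, g$strand, tract)
    } else if (g$class == "sharp_nontop") {
      chr <- plant_seq(chr, tss, g$strand, sample(pur, 2L, replace = TRUE))
    } else if (g$class == "prte_plus") {
      chr <- plant_seq(chr, tss, g$strand, sample(pur, 2L, replace = TRUE))
      prte <- sample(pyr, 9L, replace = TRUE); prte[6L] <- "T"
      # fully inside the UTR and within reach of 75-nt reads from the TSS
      off <- sample(10:min(40L, g$utr_len - 9L), 1L)
      chr <- plant_seq(chr, tss + dirn * off, g$strand, prte)
    } else {  # broad_mixed: components at +0, +15, +30 (transcript direction)
      comp_pos <- tss + dirn * c(0L, 15L, 30L)
      chr <- plant_seq(chr, comp_pos[1], g$strand,
                       c("C", sample(pyr, 6L, replace = TRUE), sample(pur, 1L)))
      chr <- plant_seq(chr, comp_pos[3], g$strand,
                       sample(pur, 2L, replace = TRUE))
      windows <- rbind(windows, data.frame(
        chrom = g$chrom,
        start = pmin(comp_pos - 7L, comp_pos + 7L),
        end = pmax(comp_pos - 7L, comp_pos + 7L),
        strand = g$strand, gene_id = g$gene_id, window = 1:3,
        stringsAsFactors = FALSE))
    }
    seqs[[g$chrom]] <- chr
  }
  genes$anchor <- NULL
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                            collapse = ""))
  names(genome) <- chroms
  # realised UTR covariates for the polysome odds
  genes$utr_seq <- vapply(seq_len(n), function(i) {
    tss_sequence(genome, genes$chrom[i], genes$tss[i], genes$strand[i],
                 genes$utr_len[i])
  }, character(1))
  genes$gc <- vapply(genes$utr_seq, gc_content, numeric(1))
  structure(list(genome = genome, genes = genes, windows = windows,
                 config = config),
            class = "sim_world")
}

#' @export
print.sim_world <- function(x, ...) {
  cat(sprintf("sim_world: %d genes on %d chromosomes (%s)\n",
              nrow(x$genes), length(x$genome),
              paste(names(table(x$genes$class)), table(x$genes$class),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# Mixture weights over broad components; the switch moves weight from
# window 3 to window 1 in the second condition (0.7 -> 0.2).
broad_weights <- function(switch, second_condition) {
  if (!switch) c(0.4, 0.3, 0.3)
  else if (!second_condition) c(0.2, 0.1, 0.7)
  else c(0.55, 0.25, 0.2)
}

# Discretised, truncated Gaussian over integer offsets.
offset_weights <- function(sd, halfspan) {
  off <- seq(-halfspan, halfspan)
  w <- exp(-off^2 / (2 * sd^2))
  list(off = off, w = w / sum(w))
}

#' Simulate CTSS libraries
#'
#' Gene expression is log-normal (drawn once, shared across conditions and
#' replicates); each library's `depth` tags are multinomially distributed
#' over (gene, TSS position) cells. Sharp genes scatter tags around the
#' modal TSS with sd `tss_sd`; broad genes mix three components whose
#' weights shift between conditions for switch genes.
#'
#' @param world A [make_genome()] result.
#' @param config Defaults to `world$config`.
#' @return Nested list `tables[[condition]][[replicate]]` of
#'   [ctss_table()]s; attribute `expression` holds the per-gene expression
#'   weights.
#' @export
simulate_ctss <- function(world, config = world$config) {
  set.seed(stage_seed(config, "ctss"))
  genes <- world$genes
  expr <- exp(rnorm(nrow(genes), 0, config$expr_sdlog))
  names(expr) <- genes$gene_id
  cells <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    dirn <- if (g$strand == "+") 1L else -1L
    if (g$class == "broad_mixed") {
      comp <- lapply(1:3, function(k) {
        ow <- offset_weights(2, 5L)
        data.frame(pos = g$tss + dirn * (15L * (k - 1L) + ow$off),
                   comp = k, w0 = ow$w)
      })
      do.call(rbind, comp)
    } else {
      ow <- offset_weights(g$tss_sd, 2L)
      data.frame(pos = g$tss + dirn * ow$off, comp = 1L, w0 = ow$w)
    }
  }))
  cells$gene <- rep(genes$gene_id,
                    ifelse(genes$class == "broad_mixed", 33L, 5L))
  cells$chrom <- genes$chrom[match(cells$gene, genes$gene_id)]
  cells$strand <- genes$strand[match(cells$gene, genes$gene_id)]
  tables <- list()
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    w <- cells$w0
    for (i in which(genes$class == "broad_mixed")) {
      bw <- broad_weights(genes$switch[i], ci == 2L)
      sel <- cells$gene == genes$gene_id[i]
      w[sel] <- cells$w0[sel] * bw[cells$comp[sel]]
    }
    p <- w * expr[cells$gene]
    p <- p / sum(p)
    reps <- lapply(seq_len(config$replicates), function(r) {
      cnt <- as.vector(rmultinom(1, config$depth, p))
      df <- data.frame(chrom = cells$chrom, pos = cells$pos,
                       strand = cells$strand, count = cnt,
                       stringsAsFactors = FALSE)
      df <- df[df$count > 0, , drop = FALSE]
      ctss_table(df, sample_id = sprintf("%s_rep%d", cond, r),
                 condition = cond, fraction = "total")
    })
    names(reps) <- sprintf("rep%d", seq_len(config$replicates))
    tables[[cond]] <- reps
  }
  attr(tables, "expression") <- expr
  tables
}

#' Split CTSS libraries into light and heavy polysome fractions
#'
#' Each tag goes to the heavy fraction with probability
#' `logistic(beta0 + beta_top*TOP + beta_prte*PRTE + beta_len*z(len) +
#' beta_gc*z(GC))` of its gene; the light fraction receives the remainder,
#' so LP + HP counts equal the input per position.
#'
#' @param tables Output of [simulate_ctss()] (or a single nested list of
#'   [ctss_table()]s).
#' @param world The [make_genome()] world.
#' @param config Defaults to `world$config`.
#' @return List with the structure of `tables`, each element a list
#'   `LP`/`HP` of [ctss_table()]s; attribute `hp_prob` gives the per-gene
#'   heavy probability (the planted truth).
#' @export
simulate_polysome_split <- function(tables, world, config = world$config) {
  set.seed(stage_seed(config, "polysome"))
  genes <- world$genes
  z <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  eta <- config$beta0 + config$beta_top * genes$is_top +
    config$beta_prte * genes$is_prte +
    config$beta_len * z(genes$utr_len) + config$beta_gc * z(genes$gc)
  p_hp <- stats::setNames(plogis(eta), genes$gene_id)
  split_one <- function(tab) {
    gid <- assign_genes(tab, genes)
    pr <- p_hp[gid]
    pr[is.na(pr)] <- plogis(config$beta0)
    hp <- rbinom(nrow(tab), tab$count, pr)
    mk <- function(cnt, frac) {
      df <- data.frame(chrom = tab$chrom, pos = tab$pos, strand = tab$strand,
                       count = cnt, stringsAsFactors = FALSE)
      df <- df[df$count > 0, , drop = FALSE]
      ctss_table(df, sample_id = paste0(attr(tab, "sample_id"), "_", frac),
                 condition = attr(tab, "condition"), fraction = frac)
    }
    list(LP = mk(tab$count - hp, "LP"), HP = mk(hp, "HP"))
  }
  out <- lapply(tables, function(reps) lapply(reps, split_one))
  attr(out, "hp_prob") <- p_hp
  out
}

#' Simulate ribosome-profiling and RNA-seq count tables
#'
#' RNA counts are negative-binomial with mean proportional to expression x
#' length; ribosome-profiling counts use the same mean times the gene's
#' translational efficiency `TE_g = exp(eta_g)` (the polysome linear
#' predictor). In the second condition, `shift_genes` have their TE
#' multiplied by `te_fold` (planted shift).
#'
#' @param world The [make_genome()] world.
#' @param config Defaults to `world$config`.
#' @param shift_genes Gene ids with a planted TE shift (default: the
#'   `sharp_nontop` class, a neutral background set).
#' @param te_fold Fold change of the planted shift (default 2).
#' @param lib_size Target library size per sample (default 1e6).
#' @return List: `ribo`, `rna` (count matrices genes x samples),
#'   `conditions`, `lengths`, `lib_ribo`/`lib_rna` (the known normalisation
#'   constants, to be passed to [gene_te()]), `te_true` (per-gene baseline
#'   TE), `shift_genes`.
#' @export
simulate_ribo_rna <- function(world, config = world$config,
                              shift_genes = NULL, te_fold = 2,
                              lib_size = 1e6) {
  set.seed(stage_seed(config, "riborna"))
  genes <- world$genes
  if (is.null(shift_genes))
    shift_genes <- genes$gene_id[genes$class == "sharp_nontop"]
  expr <- exp(rnorm(nrow(genes), 0, config$expr_sdlog))
  z <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  te <- exp(config$beta_top * genes$is_top + config$beta_prte * genes$is_prte +
            config$beta_len * z(genes$utr_len) + config$beta_gc * z(genes$gc))
  len <- genes$utr_len + 500L        # UTR + CDS stub
  size <- 1 / config$nb_dispersion
  samples <- expand.grid(rep = seq_len(config$replicates),
                         cond = config$conditions,
                         stringsAsFactors = FALSE)
  draw <- function(mu) as.integer(rnbinom(length(mu), mu = mu, size = size))
  sample_ids <- sprintf("%s_rep%d", samples$cond, samples$rep)
  rna <- ribo <- matrix(0L, nrow(genes), nrow(samples),
                        dimnames = list(genes$gene_id, sample_ids))
  for (j in seq_len(nrow(samples))) {
    te_j <- te
    if (samples$cond[j] == config$conditions[2])
      te_j[genes$gene_id %in% shift_genes] <-
        te_j[genes$gene_id %in% shift_genes] * te_fold
    mu_rna <- expr * len
    mu_rna <- mu_rna / sum(mu_rna) * lib_size
    mu_ribo <- expr * len * te_j
    mu_ribo <- mu_ribo / sum(expr * len) * lib_size  # common scaling: TE preserved
    rna[, j] <- draw(mu_rna)
    ribo[, j] <- draw(mu_ribo)
  }
  # lib_ribo/lib_rna are the simulation's known normalisation constants
  # (both equal lib_size by construction): using them instead of observed
  # column sums keeps TE estimates free of the composition bias a planted
  # shift induces in the realised totals
  lib <- stats::setNames(rep(lib_size, nrow(samples)), sample_ids)
  list(ribo = ribo, rna = rna,
       conditions = samples$cond, lengths = stats::setNames(len, genes$gene_id),
       lib_ribo = lib, lib_rna = lib,
       te_true = stats::setNames(te, genes$gene_id), shift_genes = shift_genes)
}

#' Simulate an isoform PSI survival cohort
#'
#' One three-isoform gene: the designated risk isoform's PSI varies across
#' patients (Beta(2,2), or a binary 0.2/0.8 split); survival times are
#' exponential with hazard `h0 * exp(beta_s * covariate)` where the
#' covariate is the standardised PSI (continuous) or the high-PSI indicator
#' (binary). Censoring is independent uniform on `(0, b)` with `b` solved so
#' the expected censored fraction at baseline matches `censor_frac`.
#'
#' @param config A [sim_config()].
#' @param psi_dist `"beta"` (default) or `"binary"`.
#' @return List: `tpm` (3 x n matrix), `gene_map`, `psi` (risk-isoform PSI),
#'   `covariate` (the true hazard covariate), `survival` (data.frame
#'   `patient_id`, `time`, `event`).
#' @export
simulate_survival <- function(config = sim_config(), psi_dist = c("beta",
                                                                  "binary")) {
  psi_dist <- match.arg(psi_dist)
  set.seed(stage_seed(config, "survival"))
  n <- config$n_patients
  pid <- sprintf("P%04d", seq_len(n))
  psi <- if (psi_dist == "beta") stats::rbeta(n, 2, 2)
         else sample(c(0.2, 0.8), n, replace = TRUE)
  covariate <- if (psi_dist == "binary") as.numeric(psi > 0.5)
               else (psi - mean(psi)) / stats::sd(psi)
  total <- exp(rnorm(n, 3, 1))
  rest <- runif(n, 0.3, 0.7)
  tpm <- rbind(tx_risk = total * psi,
               tx_alt1 = total * (1 - psi) * rest,
               tx_alt2 = total * (1 - psi) * (1 - rest))
  colnames(tpm) <- pid
  h0 <- config$baseline_hazard
  hz <- h0 * exp(config$beta_s * covariate)
  t_event <- rexp(n, hz)
  # b: E[censored | T ~ Exp(h0), C ~ U(0,b)] = censor_frac
  cf <- config$censor_frac
  b <- stats::uniroot(function(b) {
    1 - (1 - exp(-h0 * b)) / (h0 * b) - (1 - cf)
  }, c(1e-6, 1e6))$root
  c_time <- runif(n, 0, b)
  time <- pmin(t_event, c_time)
  event <- as.integer(t_event <= c_time)
  time <- pmax(time, 1e-6)
  list(tpm = tpm,
       gene_map = c(tx_risk = "RISKG", tx_alt1 = "RISKG", tx_alt2 = "RISKG"),
       psi = stats::setNames(psi, pid),
       covariate = stats::setNames(covariate, pid),
       survival = data.frame(patient_id = pid, time = time, event = event,
                             stringsAsFactors = FALSE))
}
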