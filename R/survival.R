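# Isoform-level PSI, splice-event ratios, quartile stratification,
# Kaplan-Meier estimation, log-rank testing and univariate Cox regression.

#' Relative transcript abundance (PSI) per isoform
#'
#' `psi_t = tpm_t / sum(tpm over the transcript's gene)`, per patient.
#' Missing (`NA`) when the gene's total TPM is 0 for that patient.
#'
#' @param transcript_tpm Numeric matrix, transcripts x patients, rownames =
#'   transcript ids.
#' @param gene_map Named character vector mapping transcript id -> gene id;
#'   every transcript must be mapped.
#' @return Matrix of PSI values in `[0, 1]` with attribute `gene_map`.
#' @export
psi_per_isoform <- function(transcript_tpm, gene_map) {
  transcript_tpm <- as.matrix(transcript_tpm)
  tx <- rownames(transcript_tpm)
  if (is.null(tx)) stop("transcript_tpm needs rownames (transcript ids)")
  if (!all(tx %in% names(gene_map)))
    stop("transcripts without gene mapping: ",
         paste(utils::head(setdiff(tx, names(gene_map))), collapse = ", "))
  genes <- gene_map[tx]
  gene_tot <- rowsum(transcript_tpm, genes)          # genes x patients
  denom <- gene_tot[genes, , drop = FALSE]
  psi <- transcript_tpm / denom
  psi[denom == 0] <- NA_real_
  rownames(psi) <- tx
  attr(psi, "gene_map") <- genes
  psi
}

#' Ratio between alternative splice events
#'
#' Per patient: `(sum PSI over numerator transcripts + pseudocount) /
#' (sum PSI over denominator transcripts + pseudocount)`. All named
#' transcripts must belong to one gene. A zero denominator with
#' pseudocount 0 yields `NA`.
#'
#' @param psi PSI matrix from [psi_per_isoform()].
#' @param numerator,denominator Transcript ids.
#' @param pseudocount Default 0.
#' @return Named numeric vector, one ratio per patient.
#' @export
splice_event_ratio <- function(psi, numerator, denominator, pseudocount = 0) {
  gm <- attr(psi, "gene_map")
  ids <- c(numerator, denominator)
  if (!all(ids %in% rownames(psi))) stop("unknown transcript id")
  if (!is.null(gm) && length(unique(gm[ids])) != 1L)
    stop("numerator and denominator transcripts must share one gene")
  num <- colSums(psi[numerator, , drop = FALSE]) + pseudocount
  den <- colSums(psi[denominator, , drop = FALSE]) + pseudocount
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Quartile patient stratification
#'
#' Nearest-rank bottom and top quartiles: with `n` non-missing patients,
#' `k = floor(n/4)` patients go into each group, ties broken by stable
#' patient-id order. Requires at least 8 non-missing values.
#'
#' @param values Named numeric vector (names = patient ids; NA dropped).
#' @return List of class `stratified_groups`: `low_group`, `high_group`
#'   (patient id vectors), `k`, `degenerate` (TRUE when all values equal).
#' @export
quartile_stratify <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 8L) stop("need >= 8 patients with non-missing values")
  if (is.null(names(v))) names(v) <- as.character(seq_along(v))
  ord <- order(v, names(v))     # stable tie-break by patient id
  k <- floor(length(v) / 4)
  structure(list(low_group = names(v)[ord[seq_len(k)]],
                 high_group = names(v)[ord[seq(length(v) - k + 1L, length(v))]],
                 k = k, degenerate = length(unique(v)) == 1L),
            class = "stratified_groups")
}

#' Kaplan-Meier product-limit estimator
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times.
#' Median survival is the first event time at which `S <= 0.5` (`NA` when
#' never reached).
#'
#' @param time Survival/censoring times (> 0).
#' @param event 1 = event observed, 0 = censored.
#' @return List of class `km_curve`: data.frame `curve` (`time`, `n_risk`,
#'   `n_event`, `surv`) over distinct event times, and `median_survival`.
#' @export
km_estimator <- function(time, event) {
  stopifnot(length(time) == length(event), all(time > 0),
            all(event %in% c(0, 1)))
  if (length(time) == 0L) stop("empty group")
  et <- sort(unique(time[event == 1]))
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  med <- if (any(surv <= 0.5)) et[which(surv <= 0.5)[1]] else NA_real_
  structure(list(curve = data.frame(time = et, n_risk = n_risk,
                                    n_event = n_event, surv = surv),
                 median_survival = med),
            class = "km_curve")
}

#' Two-group log-rank test
#'
#' At each distinct event time, observed events in group A are compared with
#' their hypergeometric expectation given the pooled risk set;
#' `chi_square = (sum(O_A - E_A))^2 / sum(V)` referred to a chi-square
#' distribution with 1 df.
#'
#' @param time_a,event_a,time_b,event_b Survival data of the two groups.
#' @return List of class `logrank_result`: `chi_square`, `p`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0L || length(time_b) == 0L) stop("empty group")
  if (sum(event_a) + sum(event_b) == 0) stop("no events in either group")
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(0L, 1L), c(length(time_a), length(time_b)))
  et <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & grp == 0L)
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & grp == 0L)
    e_a <- d * n_a / n
    o_minus_e <- o_minus_e + (d_a - e_a)
    if (n > 1)
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  chi <- if (v > 0) o_minus_e^2 / v else 0
  structure(list(chi_square = chi,
                 p = stats::pchisq(chi, df = 1, lower.tail = FALSE)),
            class = "logrank_result")
}

#' Univariate Cox proportional-hazards regression
#'
#' Maximises the Cox partial likelihood for a single covariate by
#' Newton-Raphson (gradient tolerance 1e-8, at most `max_iter` iterations)
#' with Breslow handling of tied event times (Efron available). Standard
#' error from the observed information; Wald p-value.
#'
#' @param x Covariate per patient (non-constant).
#' @param time,event Survival data (time > 0; event 0/1, >= 1 event).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param max_iter Newton iteration cap (default 100).
#' @param tol Convergence tolerance on the score (default 1e-8).
#' @return List of class `cox_result`: `beta`, `hr = exp(beta)`, `se`, `p`.
#' @export
cox_univariate <- function(x, time, event, ties = c("breslow", "efron"),
                           max_iter = 100L, tol = 1e-8) {
  ties <- match.arg(ties)
  stopifnot(length(x) == length(time), length(time) == length(event))
  if (sum(event) == 0) stop("no events")
  if (stats::sd(x) == 0) stop("constant covariate")
  xc <- x - mean(x)      # centring: beta invariant, numerically safer
  et <- sort(unique(time[event == 1]))
  deriv <- function(beta) {
    w <- exp(beta * xc)
    U <- 0; I <- 0
    for (t in et) {
      risk <- time >= t
      s0 <- sum(w[risk]); s1 <- sum(w[risk] * xc[risk])
      s2 <- sum(w[risk] * xc[risk]^2)
      dead <- time == t & event == 1
      d <- sum(dead)
      sx <- sum(xc[dead])
      if (ties == "breslow" || d == 1L) {
        U <- U + sx - d * s1 / s0
        I <- I + d * (s2 / s0 - (s1 / s0)^2)
      } else {           # Efron
        w_d <- sum(w[dead]); s1_d <- sum(w[dead] * xc[dead])
        s2_d <- sum(w[dead] * xc[dead]^2)
        for (l in seq_len(d) - 1L) {
          f <- l / d
          den <- s0 - f * w_d
          num1 <- s1 - f * s1_d
          num2 <- s2 - f * s2_d
          U <- U - num1 / den
          I <- I + num2 / den - (num1 / den)^2
        }
        U <- U + sx
      }
    }
    list(U = U, I = I)
  }
  beta <- 0
  for (it in seq_len(max_iter)) {
    d <- deriv(beta)
    if (abs(d$U) < tol) break
    if (d$I <= 0) stop("non-positive information: cannot iterate")
    beta <- beta + d$U / d$I
    if (it == max_iter) stop("Newton-Raphson did not converge in ",
                             max_iter, " iterations")
  }
  info <- deriv(beta)$I
  se <- 1 / sqrt(info)
  z <- beta / se
  structure(list(beta = beta, hr = exp(beta), se = se,
                 p = 2 * stats::pnorm(-abs(z))),
            class = "cox_result")
}

#' Survival stratification of one isoform feature
#'
#' Convenience wrapper: quartile-stratifies patients by a per-patient value
#' (e.g. a transcript's PSI or a splice-event ratio), runs Kaplan-Meier in
#' each group, the log-rank test between them, and a univariate Cox model on
#' the continuous value.
#'
#' @param values Named per-patient values (names matching `survival$patient_id`).
#' @param survival data.frame: `patient_id`, `time`, `event`.
#' @return List: `groups`, `km_low`, `km_high`, `logrank`, `cox`.
#' @export
stratify_survival <- function(values, survival) {
  stopifnot(all(c("patient_id", "time", "event") %in% names(survival)))
  values <- values[names(values) %in% survival$patient_id]
  g <- quartile_stratify(values)
  lo <- survival[match(g$low_group, survival$patient_id), ]
  hi <- survival[match(g$high_group, survival$patient_id), ]
  keep <- survival$patient_id %in% names(values)[!is.na(values)]
  sv_all <- survival[keep, ]
  list(groups = g,
       km_low = km_estimator(lo$time, lo$event),
       km_high = km_estimator(hi$time, hi$event),
       logrank = logrank_test(lo$time, lo$event, hi$time, hi$event),
       cox = cox_univariate(values[sv_all$patient_id], sv_all$time,
                            sv_all$event))
}
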