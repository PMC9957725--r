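# Independent brute-force oracles. Each deliberately takes a different route
# than the implementation it checks.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# PRTE: plain substring check, no cumulative-sum machinery.
oracle_prte_count <- function(seq) {
  s <- toupper(chartr("Uu", "Tt", seq))
  n <- nchar(s)
  if (n < 9) return(0L)
  hits <- 0L
  for (i in 1:(n - 8)) {
    w <- substr(s, i, i + 8)
    ch <- strsplit(w, "")[[1]]
    if (all(ch %in% c("C", "T")) && ch[6] == "T") hits <- hits + 1L
  }
  hits
}

# NUG: substring enumeration.
oracle_nug_count <- function(seq) {
  s <- toupper(chartr("Uu", "Tt", seq))
  n <- nchar(s)
  if (n < 3) return(0L)
  sum(vapply(1:(n - 2), function(i)
    substr(s, i, i + 2) %in% c("ATG", "CTG", "GTG", "TTG"), logical(1)))
}

# Strict uORFs: six-frame-style scan restricted to NUG starts.
oracle_uorf_strict <- function(seq) {
  s <- toupper(chartr("Uu", "Tt", seq))
  n <- nchar(s)
  cnt <- 0L
  for (i in seq_len(max(0, n - 2))) {
    if (!substr(s, i, i + 2) %in% c("ATG", "CTG", "GTG", "TTG")) next
    j <- i + 3
    while (j + 2 <= n) {
      if (substr(s, j, j + 2) %in% c("TAA", "TAG", "TGA")) {
        cnt <- cnt + 1L
        break
      }
      j <- j + 3
    }
  }
  cnt
}

# Maximum nested pairing by explicit recursion over all pairings of the
# first position (enumerates the full matching space; exponential, tiny n).
oracle_fold_pairs <- function(seq, min_loop = 3) {
  ch <- strsplit(toupper(chartr("Uu", "Tt", seq)), "")[[1]]
  ok <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  rec <- function(i, j) {
    if (i >= j) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + 1L):j) {
      if (k - i > min_loop && ok(ch[i], ch[k]))
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  if (length(ch) < 2) 0L else rec(1L, length(ch))
}

# Clustering by transitive closure over the full pairwise adjacency matrix.
oracle_cluster <- function(df, maxdist) {
  n <- nrow(df)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    df$chrom[i] == df$chrom[j] & df$strand[i] == df$strand[j] &
      abs(df$pos[i] - df$pos[j]) <= maxdist
  })
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  # canonical partition label: smallest member index of each component
  apply(reach, 1, function(r) min(which(r)))
}

# Promoter quantile positions by explicit cumulative enumeration.
oracle_quantile_width <- function(pos, counts, strand, q_low, q_high) {
  ord <- if (strand == "+") order(pos) else order(-pos)
  pos <- pos[ord]; counts <- counts[ord]
  tot <- sum(counts)
  cum <- 0
  qlp <- qhp <- NA
  for (i in seq_along(pos)) {
    cum <- cum + counts[i]
    if (is.na(qlp) && cum / tot >= q_low - 1e-12) qlp <- pos[i]
    if (is.na(qhp) && cum / tot >= q_high - 1e-12) qhp <- pos[i]
  }
  abs(qhp - qlp) + 1
}

# Two-sample KS D by direct double loop over every sample point.
oracle_ks_D <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# Two-sided Fisher p for a 2x2 table by hypergeometric tail sum.
oracle_fisher_p <- function(a, b, c, d) {
  # margins: row1 = a+b, col1 = a+c, total = a+b+c+d
  m <- a + c; nn <- b + d; k <- a + b
  supp <- max(0, k - nn):min(k, m)
  dens <- dhyper(supp, m, nn, k)
  p0 <- dhyper(a, m, nn, k)
  sum(dens[dens <= p0 * (1 + 1e-7)])
}

# Cox partial log-likelihood (Breslow) and 1-D grid-search maximiser.
oracle_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    risk <- time >= t
    dead <- time == t & event == 1
    ll <- ll + sum(beta * x[dead]) -
      sum(dead) * log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_cox_grid <- function(x, time, event, lo = -5, hi = 5, step = 1e-3) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), x = x, time = time,
               event = event)
  grid[which.max(ll)]
}

# Kaplan-Meier by hand over a small worked table.
oracle_km <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(et))
  for (i in seq_along(et)) {
    n_i <- sum(time >= et[i])
    d_i <- sum(time == et[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    out[i] <- s
  }
  data.frame(time = et, surv = out)
}

# Small default world used by several files.
small_world <- function(seed = 7, depth = 1e5,
                        n = c(sharp_top = 5L, broad_mixed = 5L,
                              sharp_nontop = 5L, prte_plus = 5L), ...) {
  make_genome(sim_config(n_genes = n, depth = depth, seed = seed, ...))
}
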