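# Sequence-level 5' end and 5'UTR feature extraction: pyrimidine runs,
# TOP / TOP-like status, PRTE scanning, NUG / uORF counting, GC content,
# and a maximum-pairing folding proxy.

PYRIMIDINES <- c("C", "T")
NUG_CODONS <- c("ATG", "CTG", "GTG", "TTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Normalise a nucleotide sequence
#'
#' Upper-cases and maps U to T so that RNA and DNA spellings are equivalent.
#' Only A, C, G, T, U and N are accepted; anything else is an error.
#'
#' @param seq A single character string, 5' to 3'.
#' @return Upper-case DNA-alphabet string.
#' @keywords internal
normalize_seq <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("`seq` must be a single non-NA character string")
  s <- toupper(chartr("Uu", "Tt", seq))
  if (grepl("[^ACGTN]", s))
    stop("sequence contains characters outside {A,C,G,T,U,N}")
  s
}

seq_chars <- function(seq) strsplit(normalize_seq(seq), "", fixed = TRUE)[[1L]]

#' Length of the pyrimidine run starting at a position
#'
#' Returns the length of the maximal contiguous C/U(T) run beginning exactly
#' at `start`, truncated at `cap`. A purine or N at `start` gives 0; N never
#' counts as a pyrimidine and breaks runs.
#'
#' @param seq Nucleotide sequence (string; T and U equivalent).
#' @param start 1-based position at which the run must begin.
#' @param cap Maximum reported run length (default 16, the upper bound of the
#'   TOP motif definition, treated as a scoring cap rather than an exclusion).
#' @return Integer run length in `[0, cap]`.
#' @examples
#' pyrimidine_run_length("CTTTC", 1)  # 5
#' pyrimidine_run_length("ATTTC", 1)  # 0
#' @export
pyrimidine_run_length <- function(seq, start = 1L, cap = 16L) {
  ch <- seq_chars(seq)
  n <- length(ch)
  if (n == 0L) stop("empty sequence")
  if (start < 1L || start > n) stop("`start` out of range [1, ", n, "]")
  run <- 0L
  i <- start
  while (i <= n && run < cap && ch[i] %in% PYRIMIDINES) {
    run <- run + 1L
    i <- i + 1L
  }
  run
}

#' Classify a 5' end as TOP, TOP-like or non-TOP
#'
#' A 5' terminal oligopyrimidine (TOP) motif is a C at the +1 (cap-adjacent)
#' position followed by an unbroken series of at least 4 pyrimidines.
#' TOP-like (not formally defined in the literature; rule documented in the
#' methods vignette) is a C start followed by 1-3 pyrimidines, or a U start
#' followed by >= 4 pyrimidines. Everything else is non-TOP.
#'
#' @param five_prime_seq Sequence starting at the transcript 5' end
#'   (position 1 is the +1 base).
#' @param cap Cap applied to the reported run length (default 16).
#' @return A list of class `top_status` with elements `label` (one of
#'   `"TOP"`, `"TOP_LIKE"`, `"NON_TOP"`) and `run_length` (capped
#'   pyrimidine run including the +1 base).
#' @examples
#' classify_top_status("CUUUUGGA")$label  # "TOP"
#' classify_top_status("GUUUUUUU")$label  # "NON_TOP"
#' @export
classify_top_status <- function(five_prime_seq, cap = 16L) {
  ch <- seq_chars(five_prime_seq)
  if (length(ch) == 0L) stop("empty sequence")
  run <- pyrimidine_run_length(five_prime_seq, 1L, cap = .Machine$integer.max)
  first <- ch[1L]
  following <- if (run > 0L) run - 1L else 0L
  label <- if (first == "C" && following >= 4L) {
    "TOP"
  } else if (first == "C" && following >= 1L) {
    "TOP_LIKE"
  } else if (first == "T" && following >= 4L) {
    "TOP_LIKE"
  } else {
    "NON_TOP"
  }
  structure(list(label = label, run_length = min(run, as.integer(cap))),
            class = "top_status")
}

#' Scan a sequence for PRTE motifs
#'
#' A pyrimidine-rich translational element (PRTE) is a stretch of 9
#' consecutive pyrimidines with an invariant uridine (T) at position 6 of
#' the 9-mer. All (possibly overlapping) hits are reported.
#'
#' @param seq Nucleotide sequence.
#' @return A data.frame with columns `offset` (1-based start of the 9-mer),
#'   `kind` (`"PRTE"`) and `matched` (the 9-mer); zero rows when no hit.
#' @examples
#' scan_prte("CCTTCTTCC")  # one hit at offset 1
#' @export
scan_prte <- function(seq) {
  ch <- seq_chars(seq)
  n <- length(ch)
  hits <- integer(0)
  if (n >= 9L) {
    pyr <- ch %in% PYRIMIDINES
    cum <- cumsum(pyr)
    for (i in seq_len(n - 8L)) {
      n_pyr <- cum[i + 8L] - if (i > 1L) cum[i - 1L] else 0L
      if (n_pyr == 9L && ch[i + 5L] == "T") hits <- c(hits, i)
    }
  }
  data.frame(
    offset = hits,
    kind = rep("PRTE", length(hits)),
    matched = vapply(hits, function(i) paste(ch[i:(i + 8L)], collapse = ""),
                     character(1)),
    stringsAsFactors = FALSE
  )
}

#' Find NUG codons (potential uORF initiation sites) in a 5'UTR
#'
#' NUG = AUG, CUG, GUG or UUG; these approximate upstream open reading frame
#' start sites. All 1-based offsets are reported.
#'
#' @param utr 5'UTR sequence.
#' @return data.frame with columns `offset`, `kind` (`"NUG"`), `matched`.
#' @export
nug_sites <- function(utr) {
  ch <- seq_chars(utr)
  n <- length(ch)
  hits <- integer(0)
  mats <- character(0)
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) {
      tri <- paste(ch[i:(i + 2L)], collapse = "")
      if (tri %in% NUG_CODONS) {
        hits <- c(hits, i)
        mats <- c(mats, tri)
      }
    }
  }
  data.frame(offset = hits, kind = rep("NUG", length(hits)),
             matched = mats, stringsAsFactors = FALSE)
}

#' Count strictly-defined uORFs in a 5'UTR
#'
#' Counts NUG start sites that have an in-frame stop codon (UAA/UAG/UGA)
#' strictly downstream and fully contained inside the UTR. This is the
#' stop-verified refinement of the NUG-count uORF proxy.
#'
#' @param utr 5'UTR sequence.
#' @return Integer count.
#' @examples
#' count_uorfs_strict("AUGAAAUAA")  # 1
#' count_uorfs_strict("AUGAAAA")    # 0
#' @export
count_uorfs_strict <- function(utr) {
  ch <- seq_chars(utr)
  n <- length(ch)
  starts <- nug_sites(utr)$offset
  n_uorf <- 0L
  for (s in starts) {
    i <- s + 3L
    while (i + 2L <= n) {
      cod <- paste(ch[i:(i + 2L)], collapse = "")
      if (cod %in% STOP_CODONS) {
        n_uorf <- n_uorf + 1L
        break
      }
      i <- i + 3L
    }
  }
  n_uorf
}

#' GC content of a sequence
#'
#' (#G + #C) / length; N counts in the denominator but never the numerator.
#'
#' @param seq Non-empty nucleotide sequence.
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  ch <- seq_chars(seq)
  if (length(ch) == 0L) stop("empty sequence")
  sum(ch %in% c("G", "C")) / length(ch)
}

#' Folding-energy proxy by maximum nested base pairing
#'
#' Dimensionless pseudo-energy: -1 per base pair in the maximum set of
#' non-crossing Watson-Crick + G.U pairs with hairpin loops of at least
#' `min_loop` unpaired bases (Nussinov dynamic programme). When an external
#' thermodynamic folding engine is supplied it is called instead and its
#' minimum free energy (kcal/mol) returned, flagged by the `"origin"`
#' attribute.
#'
#' @param seq Nucleotide sequence (length >= 1).
#' @param min_loop Minimum hairpin loop size (default 3).
#' @param engine Optional function `function(seq) -> numeric` returning an
#'   engine-computed MFE; `NULL` (default) uses the internal proxy.
#' @return Numeric <= 0 with attribute `origin` = `"proxy"` or `"engine"`.
#' @examples
#' fold_proxy("GGGAAACCC")  # -3
#' @export
fold_proxy <- function(seq, min_loop = 3L, engine = NULL) {
  s <- normalize_seq(seq)
  if (nchar(s) == 0L) stop("empty sequence")
  if (!is.null(engine)) {
    v <- as.numeric(engine(seq))
    attr(v, "origin") <- "engine"
    return(v)
  }
  v <- -as.numeric(nussinov_pairs(s, as.integer(min_loop)))
  attr(v, "origin") <- "proxy"
  v
}

#' Assemble the 5'UTR feature vector
#'
#' One row per UTR: length, GC content, NUG count and per-nt density, strict
#' uORF count, folding proxy and its per-nt value.
#'
#' @param utr Non-empty 5'UTR sequence.
#' @param min_loop Hairpin loop constraint passed to [fold_proxy()].
#' @param engine Optional external folding engine (see [fold_proxy()]).
#' @return One-row data.frame with columns `length`, `gc`, `nug_count`,
#'   `nug_density`, `uorf_strict_count`, `mfe_proxy`, `mfe_per_nt`,
#'   `mfe_origin`.
#' @export
utr_features <- function(utr, min_loop = 3L, engine = NULL) {
  s <- normalize_seq(utr)
  len <- nchar(s)
  if (len == 0L) stop("empty sequence")
  nug <- nrow(nug_sites(s))
  mfe <- fold_proxy(s, min_loop = min_loop, engine = engine)
  data.frame(
    length = len,
    gc = gc_content(s),
    nug_count = nug,
    nug_density = nug / len,
    uorf_strict_count = count_uorfs_strict(s),
    mfe_proxy = as.numeric(mfe),
    mfe_per_nt = as.numeric(mfe) / len,
    mfe_origin = attr(mfe, "origin"),
    stringsAsFactors = FALSE
  )
}
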