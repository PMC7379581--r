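# Independent oracles used to cross-check the implementation. These are
# deliberately written from the definitions (set lookups, exhaustive
# enumeration, plain matrix DP) rather than sharing code with the package.

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_bases <- function(code, mode = "as_N") {
  if (code == "I") {
    if (mode == "as_N") return(c("A", "C", "G", "T"))
    return(c("A", "C", "T"))
  }
  ORACLE_SETS[[code]]
}

oracle_mismatches <- function(primer, window, mode = "as_N") {
  p <- strsplit(primer, "")[[1]]
  w <- strsplit(window, "")[[1]]
  sum(vapply(seq_along(p),
             function(i) !(w[i] %in% oracle_bases(p[i], mode)),
             logical(1)))
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Naive in-silico PCR: enumerate every (forward-site, reverse-site) window
# pair on both strands of the (doubled, if circular) template. The reverse
# primer is matched against the reverse complement of its template window.
naive_amplify <- function(seq, circular, fwd, rev, expected,
                          max_mm = 0, anchor = 2, mode = "as_N",
                          window = 0.10) {
  Lf <- nchar(fwd); Lr <- nchar(rev)
  lo <- max(1, ceiling(expected * (1 - window)))
  hi <- floor(expected * (1 + window))
  n <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    scan <- if (circular) paste0(s, s) else s
    N <- nchar(scan)
    for (i in seq_len(min(n, N - Lf + 1))) {
      wf <- substr(scan, i, i + Lf - 1)
      if (oracle_mismatches(fwd, wf, mode) > max_mm) next
      if (anchor > 0 &&
          oracle_mismatches(substr(fwd, Lf - anchor + 1, Lf),
                            substr(wf, Lf - anchor + 1, Lf), mode) > 0) next
      for (ins in lo:hi) {
        j <- i + Lf + ins          # reverse window start
        if (j + Lr - 1 > N) next
        plen <- Lf + ins + Lr
        if (circular && plen > n) next
        wr <- oracle_revcomp(substr(scan, j, j + Lr - 1))
        if (oracle_mismatches(rev, wr, mode) > max_mm) next
        if (anchor > 0 &&
            oracle_mismatches(substr(rev, Lr - anchor + 1, Lr),
                              substr(wr, Lr - anchor + 1, Lr), mode) > 0) next
        start0 <- if (strand == "+") i - 1 else (n - (i - 1 + plen)) %% n
        out[[length(out) + 1]] <- data.frame(
          strand = strand, product_start = start0,
          insert_seq = substr(scan, i + Lf, j - 1),
          insert_len = ins,
          fwd_mismatches = oracle_mismatches(fwd, wf, mode),
          rev_mismatches = oracle_mismatches(rev, wr, mode)
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(strand = character(0), product_start = integer(0),
                      insert_seq = character(0), insert_len = integer(0),
                      fwd_mismatches = integer(0),
                      rev_mismatches = integer(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$strand, df$product_start, df$insert_len), , drop = FALSE]
}

canon_hits <- function(df) {
  df <- as.data.frame(df)
  attr(df, "pair") <- NULL
  df <- df[, c("strand", "product_start", "insert_seq", "insert_len",
               "fwd_mismatches", "rev_mismatches")]
  df <- df[order(df$strand, df$product_start, df$insert_len,
                 df$insert_seq), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# ---- alignment identity oracles ------------------------------------------
# Tuple order: maximal global score (match +1 / mismatch -1 / gap -2, end
# gaps penalized), then maximal matches, then minimal span, where span is
# the number of columns between the first and last aligned pair.

tup_better <- function(a, b) {
  if (a[1] != b[1]) return(a[1] > b[1])
  if (a[2] != b[2]) return(a[2] > b[2])
  a[3] < b[3]
}

# plain-matrix two-layer DP (for sequences up to ~100 bases)
dp_align_tuple <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  best <- c(-2 * (n + m), 0, 0)
  S <- matrix(-Inf, n + 1, m + 1); M <- matrix(0, n + 1, m + 1)
  P <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      eq <- A[i] == B[j]
      sub <- if (eq) 1 else -1
      cand <- c(-2 * (i - 1 + j - 1) + sub, as.integer(eq), 1)
      if (is.finite(S[i, j])) {
        t <- c(S[i, j] + sub, M[i, j] + eq, P[i, j] + 1)
        if (tup_better(t, cand)) cand <- t
      }
      if (is.finite(S[i, j + 1])) {
        t <- c(S[i, j + 1] - 2, M[i, j + 1], P[i, j + 1] + 1)
        if (tup_better(t, cand)) cand <- t
      }
      if (is.finite(S[i + 1, j])) {
        t <- c(S[i + 1, j] - 2, M[i + 1, j], P[i + 1, j] + 1)
        if (tup_better(t, cand)) cand <- t
      }
      S[i + 1, j + 1] <- cand[1]; M[i + 1, j + 1] <- cand[2]
      P[i + 1, j + 1] <- cand[3]
      closed <- c(cand[1] - 2 * ((n - i) + (m - j)), cand[2], cand[3])
      if (tup_better(closed, best)) best <- closed
    }
  }
  best
}

dp_identity <- function(a, b) {
  t <- dp_align_tuple(a, b)
  if (t[3] == 0) 0 else t[2] / t[3]
}

# exhaustive enumeration of every global alignment (short sequences only)
enum_align_tuple <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  best <- c(-2 * (n + m), 0, 0)
  recurse <- function(i, j, moves) {
    if (i == n && j == m) {
      if (any(moves == 1L)) {
        score <- 0; matches <- 0
        ii <- 0; jj <- 0
        diag_cols <- integer(0)
        for (k in seq_along(moves)) {
          if (moves[k] == 1L) {
            ii <- ii + 1; jj <- jj + 1
            eq <- A[ii] == B[jj]
            score <- score + if (eq) 1 else -1
            matches <- matches + eq
            diag_cols <- c(diag_cols, k)
          } else {
            if (moves[k] == 2L) ii <- ii + 1 else jj <- jj + 1
            score <- score - 2
          }
        }
        span <- max(diag_cols) - min(diag_cols) + 1
        t <- c(score, matches, span)
        if (tup_better(t, best)) best <<- t
      }
      return(invisible())
    }
    if (i < n && j < m) recurse(i + 1, j + 1, c(moves, 1L))
    if (i < n) recurse(i + 1, j, c(moves, 2L))
    if (j < m) recurse(i, j + 1, c(moves, 3L))
    invisible()
  }
  recurse(0, 0, integer(0))
  best
}

# exhaustive optimal degenerate-consensus search: every IUPAC primer built
# from subsets of the bases observed in each column, degeneracy <= cap
exhaustive_best_coverage <- function(window, cap) {
  M <- do.call(rbind, strsplit(window, ""))
  L <- ncol(M)
  col_opts <- lapply(seq_len(L), function(j) {
    present <- sort(unique(M[, j]))
    subsets <- unlist(lapply(seq_along(present), function(k) {
      combn(present, k, simplify = FALSE)
    }), recursive = FALSE)
    subsets
  })
  best <- 0
  n <- nrow(M)
  search <- function(j, deg, chosen) {
    if (j > L) {
      ok <- rep(TRUE, n)
      for (k in seq_len(L)) ok <- ok & (M[, k] %in% chosen[[k]])
      best <<- max(best, sum(ok) / n)
      return(invisible())
    }
    for (s in col_opts[[j]]) {
      d <- deg * length(s)
      if (d > cap) next
      search(j + 1, d, c(chosen, list(s)))
    }
    invisible()
  }
  search(1, 1, list())
  best
}
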