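# Independent oracles used to freeze and cross-check expected values.
# These deliberately share no code with the implementation paths they test.

# Brute-force Benjamini-Hochberg step-up from the definition:
# padj_i = min over ranks k >= rank(i) of m * p_(k) / k, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  padj <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(ord == i)
    vals <- vapply(r:m, function(k) m * p[ord[k]] / k, numeric(1))
    padj[i] <- min(c(vals, 1))
  }
  padj
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins.
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  a_range <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- dhyper(a_range, c1, N - c1, r1)
  p_obs <- dhyper(tab[1, 1], c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force hairpin enumeration: every anti-diagonal D, every column
# window [p1, p2]; a candidate must satisfy the stem/mismatch/loop/span
# bounds, be trimmed to terminal matches, be maximal (inextensible on the
# diagonal without exceeding the mismatch budget), and not be dominated.
# Independent of the two-pointer sweep in the implementation.
oracle_scan_hairpins <- function(seq, min_stem = 25L, max_mismatch = 10L,
                                 min_loop = 3L, max_span = NULL,
                                 wobble = TRUE) {
  base <- strsplit(chartr("U", "T", toupper(seq)), "", fixed = TRUE)[[1]]
  n <- length(base)
  pairs <- c("AT", "TA", "CG", "GC")
  if (wobble) pairs <- c(pairs, "GT", "TG")
  if (is.null(max_span)) max_span <- n
  cands <- list(); ci <- 0L
  for (D in 1:(2L * n - 3L)) {
    p_lo <- max(0L, D - (n - 1L))
    p_hi <- (D - min_loop - 1L) %/% 2L
    p_lo <- max(p_lo, as.integer(ceiling((D + 1L - max_span) / 2)))
    if (p_hi - p_lo + 1L < 1L) next
    ps <- p_lo:p_hi
    is_match <- paste0(base[ps + 1L], base[D - ps + 1L]) %in% pairs
    cum <- c(0L, cumsum(!is_match))
    m <- length(ps)
    # enumerate every window (i, j) on the diagonal
    i <- rep(seq_len(m), times = m); j <- rep(seq_len(m), each = m)
    ok <- j >= i
    i <- i[ok]; j <- j[ok]
    mmw <- cum[j + 1L] - cum[i]
    ok <- mmw <= max_mismatch
    # maximal: cannot extend either side within the diagonal
    ok <- ok & !(i > 1L & (cum[j + 1L] - cum[pmax(i - 1L, 1L)]) <=
                   max_mismatch)
    ok <- ok & !(j < m & (cum[pmin(j + 2L, m + 1L)] - cum[i]) <=
                   max_mismatch)
    if (!any(ok)) next
    i <- i[ok]; j <- j[ok]
    # trim to terminal matches: next match at/after i, last match at/before j
    fwd <- seq_len(m); fwd[!is_match] <- m + 1L
    next_match <- rev(cummin(rev(fwd)))
    bwd <- seq_len(m); bwd[!is_match] <- 0L
    prev_match <- cummax(bwd)
    ii <- next_match[i]; jj <- prev_match[j]
    ok <- ii <= jj & (jj - ii + 1L) >= min_stem
    if (!any(ok)) next
    ii <- ii[ok]; jj <- jj[ok]
    p1 <- ps[ii]; p2 <- ps[jj]
    ci <- ci + 1L
    cands[[ci]] <- cbind(left_start = p1 + 1L, left_end = p2 + 1L,
                         right_start = D - p2 + 1L, right_end = D - p1 + 1L,
                         stem = jj - ii + 1L,
                         mismatches = cum[jj + 1L] - cum[ii],
                         loop = D - 2L * p2 - 1L)
  }
  if (ci == 0L)
    return(data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      stem = integer(), mismatches = integer(),
                      loop = integer()))
  out <- unique(as.data.frame(do.call(rbind, cands)))
  # dominance: drop candidates contained in another's arms with <= mismatches
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i == j) next
      same <- all(out[j, 1:4] == out[i, 1:4]) &&
        out$mismatches[j] == out$mismatches[i]
      if (same) next
      if (out$left_start[j] <= out$left_start[i] &&
          out$left_end[j] >= out$left_end[i] &&
          out$right_start[j] <= out$right_start[i] &&
          out$right_end[j] >= out$right_end[i] &&
          out$mismatches[j] <= out$mismatches[i]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$left_start, out$right_start, out$stem), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Build a hairpin string: arm + loop + reverse complement of arm with
# substitutions at the given arm columns (columns counted from the stem's
# outer end; substituted bases can pair with nothing, wobble included).
make_hairpin_seq <- function(arm, loop, sub_cols = integer(0)) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(arm)))
  rs <- strsplit(rc, "", fixed = TRUE)[[1]]
  stem <- nchar(arm)
  for (cc in sub_cols) {
    partner <- substr(arm, cc, cc)
    # base that neither Watson-Crick nor wobble pairs with `partner`
    rs[stem - cc + 1L] <- switch(partner, A = "G", C = "A", G = "G", T = "C")
  }
  paste0(arm, loop, paste(rs, collapse = ""))
}
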