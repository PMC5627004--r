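# Independent dynamic-programming oracle for the end-gap-free affine
# aligner: full query, free reference end gaps, gap of length L costs
# gap_open + L * gap_ext, deterministic tie-breaks (match state preferred,
# earliest reference end wins). Coded separately from the package's C++
# implementation; rows are vectorised for speed, the within-row
# reference-gap scan is a scalar loop. Traceback needs only the pointer
# matrices plus the final row of scores.

oracle_glocal <- function(q, r, match = 1, mismatch = -1,
                          gap_open = 2, gap_ext = 1) {
  qc <- strsplit(toupper(q), "", fixed = TRUE)[[1]]
  rc <- strsplit(toupper(r), "", fixed = TRUE)[[1]]
  m <- length(qc); n <- length(rc)
  gapo <- gap_open + gap_ext; gape <- gap_ext
  NEG <- -1e30
  acgt <- c("A", "C", "G", "T")
  rbase <- rc %in% acgt

  Mrow <- rep(NEG, n + 1); Irow <- rep(NEG, n + 1); Drow <- rep(NEG, n + 1)
  # pointer codes: 1 = from M, 2 = from D, 3 = from I, 4 = start
  pM <- matrix(0L, m, n + 1); pI <- matrix(0L, m, n + 1); pD <- matrix(0L, m, n + 1)

  for (i in seq_len(m)) {
    s <- ifelse(rc == qc[i] & rbase & qc[i] %in% acgt, match, mismatch)
    Mprev <- Mrow; Iprev <- Irow; Dprev <- Drow
    if (i == 1) {
      Irow <- rep(-gapo, n + 1); pI[i, ] <- 4L
      Mrow <- c(NEG, s);         pM[i, 2:(n + 1)] <- 4L
    } else {
      # I state: predecessor preference M > I > D at the same j
      best <- Mprev - gapo; ptr <- rep(1L, n + 1)
      cand <- Iprev - gape; sel <- cand > best; best[sel] <- cand[sel]; ptr[sel] <- 3L
      cand <- Dprev - gapo; sel <- cand > best; best[sel] <- cand[sel]; ptr[sel] <- 2L
      Irow <- best; pI[i, ] <- ptr
      # M state: predecessor preference M > D > I at (i-1, j-1)
      best <- Mprev[1:n]; ptr <- rep(1L, n)
      cand <- Dprev[1:n]; sel <- cand > best; best[sel] <- cand[sel]; ptr[sel] <- 2L
      cand <- Iprev[1:n]; sel <- cand > best; best[sel] <- cand[sel]; ptr[sel] <- 3L
      Mrow <- c(NEG, s + best); pM[i, 2:(n + 1)] <- ptr
    }
    # D state: within-row scan, predecessor preference M > D > I at (i, j-1)
    Drow <- rep(NEG, n + 1)
    for (j in 2:(n + 1)) {
      b <- Mrow[j - 1] - gapo; p <- 1L
      cd <- Drow[j - 1] - gape
      if (cd > b) { b <- cd; p <- 2L }
      ci <- Irow[j - 1] - gapo
      if (ci > b) { b <- ci; p <- 3L }
      Drow[j] <- b; pD[i, j] <- p
    }
  }

  # end: scan j left to right, M preferred over I, strict improvement only
  best <- NEG; endj <- 0L; endstate <- 3L # 1 = M, 3 = I
  for (j in 0:n) {
    if (j >= 1 && Mrow[j + 1] > best) { best <- Mrow[j + 1]; endj <- j; endstate <- 1L }
    if (Irow[j + 1] > best) { best <- Irow[j + 1]; endj <- j; endstate <- 3L }
  }

  i <- m; j <- endj; state <- endstate
  matches <- 0L; cols <- 0L
  repeat {
    if (state == 1L) {
      cols <- cols + 1L
      if (qc[i] == rc[j] && qc[i] %in% acgt) matches <- matches + 1L
      p <- pM[i, j + 1]; i <- i - 1L; j <- j - 1L
    } else if (state == 3L) {
      cols <- cols + 1L
      p <- pI[i, j + 1]; i <- i - 1L
    } else {
      cols <- cols + 1L
      p <- pD[i, j + 1]; j <- j - 1L
    }
    if (p == 4L) break
    state <- p
  }
  list(score = best, matches = matches, aligned_cols = cols,
       identity = matches / cols)
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# best hit over both strands; plus strand wins ties
oracle_align <- function(q, r, ...) {
  plus <- oracle_glocal(q, r, ...)
  minus <- oracle_glocal(oracle_revcomp(q), r, ...)
  if (minus$score > plus$score) c(minus, strand = "-") else c(plus, strand = "+")
}

# best hit over a set of references (first record wins score ties), and the
# recruitment decision at the given thresholds
oracle_recruit <- function(q, refs, min_identity = 0.50, min_len = 75) {
  best <- NULL
  for (r in refs) {
    h <- oracle_align(q, r)
    if (is.null(best) || h$score > best$score) best <- h
  }
  best$recruited <- best$identity >= min_identity && best$aligned_cols >= min_len
  best
}
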