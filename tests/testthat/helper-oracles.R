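# Independent oracles and shared fixture builders. The oracles are
# deliberately naive (explicit loops, hand-written degeneracy sets) so they
# share no code path with the implementation they check.

TEST_SEED <- 1729L

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Position-by-position membership check, one window at a time.
oracle_iupac_match <- function(motif, window) {
  m <- strsplit(motif, "")[[1L]]
  w <- strsplit(window, "")[[1L]]
  if (length(m) != length(w)) stop("length mismatch")
  for (i in seq_along(m)) {
    if (!w[i] %in% ORACLE_SETS[[m[i]]]) {
      return(FALSE)
    }
  }
  TRUE
}

oracle_revcomp <- function(s) {
  lut <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(lut[strsplit(s, "")[[1L]]])), collapse = "")
}

# Exhaustive per-offset scan of one strand frame for motif matches whose
# protospacer fits; returns 0-based PAM starts.
oracle_scan_frame <- function(frame, motif, lo = 20L,
                              hi = nchar(frame) - nchar(motif)) {
  hits <- integer(0)
  mlen <- nchar(motif)
  lo <- max(0L, lo)
  hi <- min(nchar(frame) - mlen, hi)
  if (lo > hi) return(hits)
  for (s0 in seq.int(lo, hi)) {
    win <- substr(frame, s0 + 1L, s0 + mlen)
    if (oracle_iupac_match(motif, win)) hits <- c(hits, s0)
  }
  hits
}

# Brute-force equivalent of scan_pams: both strands, window anchored at the
# edit's 3' end in each strand's own frame.
oracle_scan_pams <- function(edited) {
  L <- nchar(edited$sequence)
  res <- list()
  for (strand in c("+", "-")) {
    fr <- if (strand == "+") edited$sequence else oracle_revcomp(edited$sequence)
    a0 <- edited$alt_start0
    a1 <- edited$alt_end0
    if (strand == "-") {
      t <- L - a1
      a1 <- L - a0
      a0 <- t
    }
    anchor <- if (a1 > a0) a1 - 1L else a0
    starts <- oracle_scan_frame(fr, "NGG", max(20L, anchor - 100L),
      anchor + 6L)
    if (length(starts) > 0L) {
      res[[strand]] <- data.frame(strand = strand, pam_start0 = starts)
    }
  }
  do.call(rbind, unname(res))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Canonical manual PE fixture on a CA-repeat background (NGG-free on both
# strands). A TGG PAM sits at 1-based 134-136, so the nick bond is at
# 0-based 130 and nick-relative position k corresponds to 1-based sense
# position 130 + k. `overwrite` is a named character vector of 1-based
# position -> base patches.
ca_fixture <- function(len = 260L, overwrite = NULL) {
  chars <- rep(c("C", "A"), length.out = len)
  chars[134:136] <- c("T", "G", "G")
  if (!is.null(overwrite)) {
    for (p in names(overwrite)) {
      chars[as.integer(p)] <- overwrite[[p]]
    }
  }
  paste(chars, collapse = "")
}

# Substitution at nick-relative position k of the ca_fixture (1-based sense
# position 130 + k), changing the background base to `alt`.
ca_edit_at <- function(seq, k, alt = "G") {
  pos <- 130L + k
  edit_substitution(pos, substr(seq, pos, pos), alt)
}
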