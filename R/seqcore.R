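# Nucleotide-sequence primitives: validation, reverse complement, IUPAC
# motif matching, and edit application with coordinate mapping.
#
# Coordinates are 0-based half-open internally; every user-facing surface
# (constructors, CLI, output tables) is 1-based inclusive.

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Validate and normalise a DNA sequence
#'
#' Upper-cases the input and checks that every character is A, C, G or T
#' (N is additionally permitted for genome-derived input, never in designed
#' output). RNA input (U) is rejected: this package works on DNA only.
#'
#' @param x A character scalar.
#' @param allow_n Permit the ambiguity code N (default `FALSE`).
#' @param what Label used in error messages.
#' @return The validated upper-case sequence (character scalar).
#' @export
#' @examples
#' as_dna("acgt")
as_dna <- function(x, allow_n = FALSE, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  x <- toupper(x)
  if (nchar(x) < 1L) stop(what, " must have length >= 1", call. = FALSE)
  alphabet <- if (allow_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% alphabet)
  if (length(bad) > 0L) {
    stop(
      what, " contains invalid character '", chars[bad[1L]],
      "' at position ", bad[1L],
      if (chars[bad[1L]] == "U") " (RNA input is not supported; use T)" else "",
      call. = FALSE
    )
  }
  x
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick complement, reversed. IUPAC ambiguity codes are complemented
#' to their partner codes (N stays N). Vectorised over `x`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")  # "ACGT"
#' revcomp("AAA")   # "TTT"
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(
    strsplit(comp, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1L)
  )
}

#' Match a window against an IUPAC motif
#'
#' `TRUE` iff every position of `window` lies in the degeneracy set of the
#' corresponding motif character (N = \{ACGT\}, R = \{AG\}, Y = \{CT\}, ...).
#' Vectorised over `window`; every window must have the motif's length.
#'
#' @param motif IUPAC motif string, e.g. "NGG" or "NNGRRT".
#' @param window Character vector of windows, each `nchar(motif)` long.
#' @return Logical vector.
#' @export
#' @examples
#' iupac_match("NGG", c("TGG", "TGA"))
iupac_match <- function(motif, window) {
  motif <- toupper(motif)
  mchars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  if (!all(mchars %in% names(IUPAC_CODES))) {
    stop("motif contains a non-IUPAC character", call. = FALSE)
  }
  window <- toupper(window)
  if (any(nchar(window) != length(mchars))) {
    stop(
      "window length must equal motif length (", length(mchars), ")",
      call. = FALSE
    )
  }
  sets <- IUPAC_CODES[mchars]
  vapply(strsplit(window, "", fixed = TRUE), function(wc) {
    all(mapply(function(w, s) w %in% s, wc, sets))
  }, logical(1L))
}

# Regex character-class equivalent of an IUPAC motif; used by the fast PAM
# scanner (a lookahead keeps overlapping matches).
iupac_to_regex <- function(motif) {
  mchars <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
  paste(vapply(mchars, function(m) {
    set <- IUPAC_CODES[[m]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1L)), collapse = "")
}

# All start positions (0-based) where `motif` matches `seq`, overlapping
# matches included.
motif_starts0 <- function(motif, seq) {
  rx <- paste0("(?=", iupac_to_regex(motif), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

# ---- Edits ------------------------------------------------------------------

new_edit <- function(kind, pos0, ref, alt) {
  structure(
    list(kind = kind, pos0 = as.integer(pos0), ref = ref, alt = alt),
    class = "pegbe_edit"
  )
}

#' Describe a sequence edit
#'
#' Constructors for the three edit kinds, using 1-based positions on the
#' working (sense) sequence. Indels use a minimal left-aligned representation
#' with no anchor base: an insertion has an empty `ref`, a deletion an empty
#' `alt`.
#'
#' @param pos 1-based position: for a substitution/deletion, the first
#'   affected base; for an insertion, the base *before* which `alt` is
#'   inserted.
#' @param ref Reference allele (substitution/deletion).
#' @param alt Alternate allele (substitution/insertion).
#' @return A `pegbe_edit` object.
#' @export
#' @examples
#' edit_substitution(30, "A", "G")
#' edit_insertion(12, "CC")
#' edit_deletion(5, "ACG")
edit_substitution <- function(pos, ref, alt) {
  ref <- as_dna(ref, what = "ref")
  alt <- as_dna(alt, what = "alt")
  if (nchar(ref) != nchar(alt)) {
    stop("substitution requires ref and alt of equal length", call. = FALSE)
  }
  new_edit("substitution", pos - 1L, ref, alt)
}

#' @rdname edit_substitution
#' @export
edit_insertion <- function(pos, alt) {
  alt <- as_dna(alt, what = "alt")
  new_edit("insertion", pos - 1L, "", alt)
}

#' @rdname edit_substitution
#' @export
edit_deletion <- function(pos, ref) {
  ref <- as_dna(ref, what = "ref")
  new_edit("deletion", pos - 1L, ref, "")
}

#' Parse compact edit syntax
#'
#' `"POS:REF>ALT"` (substitution), `"POS:ins:SEQ"` (insertion before POS),
#' `"POS:del:SEQ"` (deletion starting at POS); positions 1-based.
#'
#' @param x Character scalar.
#' @return A `pegbe_edit`.
#' @export
#' @examples
#' parse_edit("30:A>G")
#' parse_edit("12:ins:CTT")
parse_edit <- function(x) {
  if (grepl("^[0-9]+:[ACGTacgt]+>[ACGTacgt]+$", x)) {
    parts <- strsplit(x, "[:>]")[[1L]]
    return(edit_substitution(as.integer(parts[1L]), parts[2L], parts[3L]))
  }
  if (grepl("^[0-9]+:ins:[ACGTacgt]+$", x)) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1L]]
    return(edit_insertion(as.integer(parts[1L]), parts[3L]))
  }
  if (grepl("^[0-9]+:del:[ACGTacgt]+$", x)) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1L]]
    return(edit_deletion(as.integer(parts[1L]), parts[3L]))
  }
  stop(
    "cannot parse edit '", x,
    "'; use POS:REF>ALT, POS:ins:SEQ or POS:del:SEQ (1-based)",
    call. = FALSE
  )
}

#' @export
print.pegbe_edit <- function(x, ...) {
  desc <- switch(x$kind,
    substitution = paste0(x$pos0 + 1L, ":", x$ref, ">", x$alt),
    insertion = paste0(x$pos0 + 1L, ":ins:", x$alt),
    deletion = paste0(x$pos0 + 1L, ":del:", x$ref)
  )
  cat("<edit ", desc, ">\n", sep = "")
  invisible(x)
}

#' Invert an edit
#'
#' The edit that undoes `x` when applied to the edited sequence: substitutions
#' swap ref/alt, insertions become deletions of the inserted bases and vice
#' versa. Used by revert-mode design.
#'
#' @param x A `pegbe_edit`.
#' @return A `pegbe_edit`.
#' @export
invert_edit <- function(x) {
  stopifnot(inherits(x, "pegbe_edit"))
  switch(x$kind,
    substitution = new_edit("substitution", x$pos0, x$alt, x$ref),
    insertion = new_edit("deletion", x$pos0, x$alt, ""),
    deletion = new_edit("insertion", x$pos0, "", x$ref)
  )
}

#' Apply an edit to a sequence
#'
#' Returns the edited sequence together with the monotone coordinate map
#' from original to edited positions and the location of the alternate
#' allele on the edited sequence. The `ref` allele must match the working
#' sequence at the edit position; a mismatch is rejected naming the expected
#' and observed bases.
#'
#' @param seq Working sense sequence (character scalar; N allowed).
#' @param edit A `pegbe_edit`.
#' @return An object of class `edited_seq`: a list with elements
#'   `sequence` (edited string), `original`, `edit`, `delta`
#'   (`nchar(alt) - nchar(ref)`), `alt_start0`/`alt_end0` (0-based half-open
#'   interval of the alt allele on the edited sequence; empty interval at the
#'   junction for deletions) and `map` (vectorised function taking 1-based
#'   original positions to 1-based edited positions, `NA` for deleted bases).
#' @export
#' @examples
#' e <- apply_edit("AAAAA", edit_substitution(3, "A", "G"))
#' e$sequence  # "AAGAA"
apply_edit <- function(seq, edit) {
  seq <- as_dna(seq, allow_n = TRUE)
  stopifnot(inherits(edit, "pegbe_edit"))
  n <- nchar(seq)
  p0 <- edit$pos0
  rlen <- nchar(edit$ref)
  alen <- nchar(edit$alt)
  if (p0 < 0L || p0 > n - max(rlen, 1L) + (edit$kind == "insertion")) {
    stop("edit position ", p0 + 1L, " out of range for sequence of length ",
      n, call. = FALSE)
  }
  if (rlen > 0L) {
    observed <- substr(seq, p0 + 1L, p0 + rlen)
    if (observed != edit$ref) {
      stop(
        "ref mismatch at position ", p0 + 1L, ": expected '", edit$ref,
        "', observed '", observed, "'",
        call. = FALSE
      )
    }
  }
  left <- substr(seq, 1L, p0)
  right <- substr(seq, p0 + rlen + 1L, n)
  edited <- paste0(left, edit$alt, right)
  delta <- alen - rlen
  map <- function(pos) {
    pos <- as.integer(pos)
    out <- pos
    if (edit$kind == "insertion") {
      out[pos > p0] <- pos[pos > p0] + delta
    } else if (edit$kind == "deletion") {
      out[pos > p0 & pos <= p0 + rlen] <- NA_integer_
      out[pos > p0 + rlen] <- pos[pos > p0 + rlen] + delta
    }
    out
  }
  structure(
    list(
      sequence = edited, original = seq, edit = edit, delta = delta,
      alt_start0 = p0, alt_end0 = p0 + alen, map = map
    ),
    class = "edited_seq"
  )
}

#' @export
print.edited_seq <- function(x, ...) {
  cat("<edited_seq ", nchar(x$sequence), " nt, ", x$edit$kind,
    " at ", x$alt_start0 + 1L, ">\n",
    sep = ""
  )
  invisible(x)
}
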