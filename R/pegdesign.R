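# PE2 pegRNA candidate generation and penalty scoring.
#
# Geometry, all on the edited sequence. Each PAM hit lives in the frame of
# its own strand (the sense sequence for "+", its reverse complement for
# "-"). In that frame, with the PAM's 5'-most base at 0-based `pam_start0`:
#   protospacer   = [pam_start0 - 20, pam_start0)
#   nick          = bond at coordinate nick0 = pam_start0 - 3, i.e. between
#                   protospacer positions 17 and 18 (3 nt 5' of the PAM)
#   PBS region    = [nick0 - pbs_len, nick0)          (5' of the nick)
#   RTT region    = [nick0, nick0 + rtt_len)          (3' of the nick)
# The pegRNA 3' extension is the reverse complement of the edited PAM-strand
# segment [nick0 - pbs_len, nick0 + rtt_len), written RTT-then-PBS 5'->3'.

PROTO_LEN <- 20L
NICK_OFFSET <- 3L          # nick is 3 nt 5' of the PAM
PBS_MAX <- 17L             # nick-to-protospacer-5'-end span
SCAN_5P <- 100L            # PAM scan extent 5' of the edit
SCAN_3P <- 6L              # PAM scan extent 3' of the edit

# Alt-allele interval and edit anchor in a strand frame.
# Returns list(alt_start0, alt_end0, anchor3p) where anchor3p is the frame
# coordinate of the edit's 3' end used to anchor the PAM scan window
# (last alt base for non-empty alt; the junction for deletions).
frame_alt_interval <- function(edited, strand) {
  L <- nchar(edited$sequence)
  a0 <- edited$alt_start0
  a1 <- edited$alt_end0
  if (strand == "-") {
    tmp <- L - a1
    a1 <- L - a0
    a0 <- tmp
  }
  anchor <- if (a1 > a0) a1 - 1L else a0
  list(alt_start0 = a0, alt_end0 = a1, anchor3p = anchor)
}

frame_seq <- function(edited, strand) {
  if (strand == "+") edited$sequence else revcomp(edited$sequence)
}

#' Scan for candidate NGG PAM sites around an edit
#'
#' Finds every 5'-NGG-3' PAM on both strands of the *edited* sequence whose
#' 5'-most base lies in the window from 6 nt 3' of the edit's 3' end to
#' 100 nt 5' of it, each strand evaluated in its own 5'->3' frame. Only
#' placements whose full 20-nt protospacer and PAM fit inside the sequence
#' are returned; the window is clipped at the sequence ends, so short flanks
#' yield fewer hits rather than an error. Downstream RTT-coverage filtering
#' removes geometrically unusable hits.
#'
#' @param edited An `edited_seq` from [apply_edit()].
#' @param motif PAM motif (fixed to NGG for prime editing).
#' @return A tibble with one row per PAM hit: `strand`, frame coordinates
#'   `pam_start0` and `nick0` (0-based; `nick0` is the bond coordinate),
#'   `nick_sense0` (the same bond in sense-frame coordinates, for distance
#'   arithmetic), `pam_seq`, `protospacer`. Rows are ordered by ascending
#'   sense coordinate of the PAM, "+" before "-".
#' @export
scan_pams <- function(edited, motif = "NGG") {
  stopifnot(inherits(edited, "edited_seq"))
  L <- nchar(edited$sequence)
  mlen <- nchar(motif)
  if (L < PROTO_LEN + mlen) {
    stop(
      "insufficient context: at least ", PROTO_LEN + mlen,
      " nt are required to place a protospacer and PAM (got ", L, " nt); ",
      ">= 120 nt of flank on each side of the edit is recommended",
      call. = FALSE
    )
  }
  hits <- purrr::map_dfr(c("+", "-"), function(strand) {
    fr <- frame_seq(edited, strand)
    iv <- frame_alt_interval(edited, strand)
    lo <- max(PROTO_LEN, iv$anchor3p - SCAN_5P)
    hi <- min(L - mlen, iv$anchor3p + SCAN_3P)
    if (lo > hi) {
      return(tibble::tibble())
    }
    starts <- motif_starts0(motif, fr)
    starts <- starts[starts >= lo & starts <= hi]
    if (length(starts) == 0L) {
      return(tibble::tibble())
    }
    nick0 <- starts - NICK_OFFSET
    nick_sense0 <- if (strand == "+") nick0 else L - nick0
    tibble::tibble(
      strand = strand,
      pam_start0 = starts,
      nick0 = nick0,
      nick_sense0 = nick_sense0,
      pam_seq = substring(fr, starts + 1L, starts + mlen),
      protospacer = substring(fr, starts - PROTO_LEN + 1L, starts)
    )
  })
  if (nrow(hits) == 0L) {
    return(tibble::tibble(
      strand = character(), pam_start0 = integer(), nick0 = integer(),
      nick_sense0 = integer(), pam_seq = character(),
      protospacer = character()
    ))
  }
  sense_pos <- ifelse(hits$strand == "+", hits$pam_start0,
    L - hits$pam_start0 - mlen)
  hits[order(sense_pos, hits$strand), , drop = FALSE]
}

#' Nick-relative edit position for a PAM hit
#'
#' 1-based distance from the nick to the edit's nick-proximal end on the
#' edited PAM strand: position 1 is the first nucleotide 3' of the nick
#' (protospacer position 18), so positions 1-3 fall in the residual
#' protospacer and 4-6 in the PAM. Returns `NA` when the edit lies (even
#' partially) 5' of the nick, which disqualifies the candidate.
#'
#' @param hit One row of the tibble returned by [scan_pams()].
#' @param edited The `edited_seq` the hit was found on.
#' @return Integer position, or `NA_integer_`.
#' @export
compute_edit_position <- function(hit, edited) {
  iv <- frame_alt_interval(edited, hit$strand)
  if (iv$alt_start0 < hit$nick0) {
    return(NA_integer_)
  }
  iv$alt_start0 - hit$nick0 + 1L
}

#' Build a pegRNA candidate for one PAM hit
#'
#' Returns a candidate iff the entire alternate allele lies within the RTT
#' window `[nick, nick + rtt_len)` on the edited PAM strand (for deletions,
#' the junction must lie in the window with at least one templated
#' nucleotide 3' of it). PBS and RTT are reverse complements of the edited
#' PAM-strand segments flanking the nick, and the 3' extension is RTT
#' followed by PBS.
#'
#' @param hit One row from [scan_pams()].
#' @param edited The `edited_seq`.
#' @param pbs_len Primer-binding-site length in nt (1-17; default 13).
#' @param rtt_len Reverse-transcriptase-template length in nt (default 13).
#' @return A one-row tibble candidate, or `NULL` if the edit is not covered.
#' @export
build_pegrna <- function(hit, edited, pbs_len = 13L, rtt_len = 13L) {
  pbs_len <- as.integer(pbs_len)
  rtt_len <- as.integer(rtt_len)
  if (pbs_len < 1L || pbs_len > PBS_MAX) {
    stop("pbs_len must be between 1 and ", PBS_MAX,
      " (the nick-to-protospacer-5'-end span)", call. = FALSE)
  }
  if (rtt_len < 1L) stop("rtt_len must be >= 1", call. = FALSE)
  L <- nchar(edited$sequence)
  fr <- frame_seq(edited, hit$strand)
  iv <- frame_alt_interval(edited, hit$strand)
  n0 <- hit$nick0
  is_del <- iv$alt_end0 == iv$alt_start0
  covered <- if (is_del) {
    iv$alt_start0 >= n0 && (iv$alt_start0 - n0) <= rtt_len - 1L
  } else {
    iv$alt_start0 >= n0 && (iv$alt_end0 - n0) <= rtt_len
  }
  if (!covered) {
    return(NULL)
  }
  if (n0 + rtt_len > L || n0 - pbs_len < 0L) {
    return(NULL)
  }
  edit_position <- iv$alt_start0 - n0 + 1L
  homology <- rtt_len - (iv$alt_end0 - n0)
  pbs <- revcomp(substring(fr, n0 - pbs_len + 1L, n0))
  rtt <- revcomp(substring(fr, n0 + 1L, n0 + rtt_len))
  tibble::tibble(
    strand = hit$strand,
    protospacer = hit$protospacer,
    pam_seq = hit$pam_seq,
    pbs = pbs,
    rtt = rtt,
    extension_3p = paste0(rtt, pbs),
    edit_position = edit_position,
    pbs_len = pbs_len,
    rtt_len = rtt_len,
    homology_after_edit = homology,
    pam_start0 = hit$pam_start0,
    nick0 = hit$nick0,
    nick_sense0 = hit$nick_sense0
  )
}

#' Score pegRNA candidates
#'
#' Heuristic penalty score flagging design features known to impair pegRNA
#' function; larger negative totals indicate worse designs. Components:
#' \describe{
#'   \item{first_base_C}{-28 if the 3' extension starts with C (can pair
#'     with G81 of Cas9 and disrupt the guide scaffold).}
#'   \item{poly_T}{-50 if the extension contains a run of more than 4
#'     consecutive T (Pol III transcription terminator).}
#'   \item{short_homology}{-6 if fewer than 5 homologous nt follow the edit
#'     in the RTT.}
#'   \item{edit_distance}{-1 per nick-relative edit position (position 1
#'     scores -1).}
#' }
#' The score is the sum of the components, so it is always at most -1.
#'
#' @param cands Candidate tibble from [build_pegrna()] (any number of rows).
#' @return `cands` with columns `penalty_first_base_c`, `penalty_poly_t`,
#'   `penalty_short_homology`, `penalty_edit_distance` and `score` appended.
#' @export
score_pegrna <- function(cands) {
  if (nrow(cands) == 0L) {
    return(dplyr::mutate(cands,
      penalty_first_base_c = integer(), penalty_poly_t = integer(),
      penalty_short_homology = integer(), penalty_edit_distance = integer(),
      score = integer()
    ))
  }
  dplyr::mutate(cands,
    penalty_first_base_c =
      ifelse(substr(.data$extension_3p, 1L, 1L) == "C", -28L, 0L),
    penalty_poly_t =
      ifelse(grepl("TTTTT", .data$extension_3p, fixed = TRUE), -50L, 0L),
    penalty_short_homology =
      ifelse(.data$homology_after_edit < 5L, -6L, 0L),
    penalty_edit_distance = -.data$edit_position,
    score = .data$penalty_first_base_c + .data$penalty_poly_t +
      .data$penalty_short_homology + .data$penalty_edit_distance
  )
}
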