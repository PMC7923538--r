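# PE3 / PE3b secondary nicking-guide design.
#
# Both operate on the edited sequence, on the strand opposite the pegRNA's
# PAM strand, so PE3b protospacers anneal to the edited strand by
# construction.

opposite_strand <- function(strand) if (strand == "+") "-" else "+"

# All NGG protospacer placements on one strand of the edited sequence
# (no window restriction), with sense-frame nick bond and footprint.
scan_strand_all <- function(edited, strand, motif = "NGG") {
  L <- nchar(edited$sequence)
  mlen <- nchar(motif)
  fr <- frame_seq(edited, strand)
  starts <- motif_starts0(motif, fr)
  starts <- starts[starts >= PROTO_LEN & starts <= L - mlen]
  if (length(starts) == 0L) {
    return(tibble::tibble(
      strand = character(), pam_start0 = integer(), nick0 = integer(),
      nick_sense0 = integer(), pam_seq = character(),
      protospacer = character(), fp_start0 = integer(), fp_end0 = integer()
    ))
  }
  nick0 <- starts - NICK_OFFSET
  # footprint = protospacer + PAM, as a sense-frame half-open interval
  fs <- starts - PROTO_LEN
  fe <- starts + mlen
  if (strand == "-") {
    tmp <- L - fe
    fe <- L - fs
    fs <- tmp
  }
  nick_sense0 <- if (strand == "+") nick0 else L - nick0
  tibble::tibble(
    strand = strand,
    pam_start0 = starts,
    nick0 = nick0,
    nick_sense0 = nick_sense0,
    pam_seq = substring(fr, starts + 1L, starts + mlen),
    protospacer = substring(fr, starts - PROTO_LEN + 1L, starts),
    fp_start0 = fs,
    fp_end0 = fe
  )
}

peg_footprint <- function(peg, L) {
  fs <- peg$pam_start0 - PROTO_LEN
  fe <- peg$pam_start0 + 3L
  if (peg$strand == "-") {
    tmp <- L - fe
    fe <- L - fs
    fs <- tmp
  }
  c(fs, fe)
}

empty_nicks <- function() {
  tibble::tibble(
    system = character(), strand = character(), protospacer = character(),
    pam_seq = character(), nick_distance = integer(), overlap_nt = integer()
  )
}

#' Design PE3 nicking guides
#'
#' All NGG protospacers on the strand opposite the pegRNA's PAM strand whose
#' nick lies 40-100 nt (inclusive, either direction) from the pegRNA nick.
#' Nicking the non-edited strand biases repair toward the edited strand.
#'
#' @param edited The `edited_seq` the pegRNA was designed on.
#' @param peg A one-row pegRNA candidate (from [build_pegrna()] or a row of
#'   a [design_pegrnas()] result).
#' @param min_dist,max_dist Inclusive nick-to-nick distance bounds in nt.
#' @return A tibble of nicking guides sorted by `nick_distance`:
#'   `system` ("PE3"), `strand`, `protospacer`, `pam_seq`, `nick_distance`,
#'   `overlap_nt` (`NA` for PE3).
#' @export
design_pe3_nicks <- function(edited, peg, min_dist = 40L, max_dist = 100L) {
  hits <- scan_strand_all(edited, opposite_strand(peg$strand))
  if (nrow(hits) == 0L) {
    return(empty_nicks())
  }
  hits$nick_distance <- abs(hits$nick_sense0 - peg$nick_sense0)
  hits <- hits[hits$nick_distance >= min_dist & hits$nick_distance <= max_dist, ]
  hits <- hits[order(hits$nick_distance, hits$pam_start0), ]
  tibble::tibble(
    system = rep("PE3", nrow(hits)),
    strand = hits$strand,
    protospacer = hits$protospacer,
    pam_seq = hits$pam_seq,
    nick_distance = hits$nick_distance,
    overlap_nt = NA_integer_
  )
}

#' Design PE3b nicking guides
#'
#' All NGG protospacer+PAM footprints on the opposite strand of the *edited*
#' sequence that overlap the pegRNA's protospacer+PAM footprint by at least
#' one nucleotide. Because the guides are taken from the edited strand, a
#' PE3b guide whose seed spans the edit only binds after successful editing,
#' delaying the second nick until the edit is installed.
#'
#' @inheritParams design_pe3_nicks
#' @return A tibble like [design_pe3_nicks()] with `system` "PE3b" and
#'   `overlap_nt` filled in (`nick_distance` is `NA`), sorted by decreasing
#'   overlap.
#' @export
design_pe3b_nicks <- function(edited, peg) {
  L <- nchar(edited$sequence)
  hits <- scan_strand_all(edited, opposite_strand(peg$strand))
  if (nrow(hits) == 0L) {
    return(empty_nicks())
  }
  fp <- peg_footprint(peg, L)
  ov <- pmin(hits$fp_end0, fp[2L]) - pmax(hits$fp_start0, fp[1L])
  keep <- ov >= 1L
  hits <- hits[keep, ]
  ov <- ov[keep]
  o <- order(-ov, hits$fp_start0)
  hits <- hits[o, ]
  ov <- ov[o]
  tibble::tibble(
    system = rep("PE3b", nrow(hits)),
    strand = hits$strand,
    protospacer = hits$protospacer,
    pam_seq = hits$pam_seq,
    nick_distance = NA_integer_,
    overlap_nt = as.integer(ov)
  )
}
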