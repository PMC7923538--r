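# Orchestration: single-variant and batch pegRNA design.

untargetable_row <- function(variant_name, reason, pbs_len, rtt_len) {
  tibble::tibble(
    variant_name = variant_name,
    status = "untargetable",
    reason = reason,
    score = NA_integer_,
    protospacer = NA_character_,
    edit_position = NA_integer_,
    pam_seq = NA_character_,
    strand = NA_character_,
    extension_3p = NA_character_,
    pbs = NA_character_,
    rtt = NA_character_,
    pbs_len = as.integer(pbs_len),
    rtt_len = as.integer(rtt_len),
    homology_after_edit = NA_integer_,
    penalty_first_base_c = NA_integer_,
    penalty_poly_t = NA_integer_,
    penalty_short_homology = NA_integer_,
    penalty_edit_distance = NA_integer_
  )
}

peg_columns <- c(
  "variant_name", "status", "reason", "score", "protospacer",
  "edit_position", "pam_seq", "strand", "extension_3p", "pbs", "rtt",
  "pbs_len", "rtt_len", "homology_after_edit", "penalty_first_base_c",
  "penalty_poly_t", "penalty_short_homology", "penalty_edit_distance"
)

new_peg_design <- function(x, job = list()) {
  structure(x, job = job, class = c("peg_design", class(x)))
}

#' Design and rank pegRNAs for one variant
#'
#' End-to-end PE2 design: scan the edited sequence for candidate NGG PAMs on
#' both strands, build a pegRNA for every PAM whose RTT covers the edit,
#' score the candidates, and rank them (score descending; ties broken by
#' smaller edit position, then "+" strand, then lower coordinate). In
#' `"revert"` mode the supplied sequence must carry the `ref` allele: the
#' edit is first applied to obtain the variant sequence, and the design then
#' installs the inverse edit, restoring the reference.
#'
#' A variant with no workable candidate yields a single `"untargetable"` row
#' whose `reason` distinguishes "no PAM in scan window" from "edit not
#' covered by RTT".
#'
#' @param sequence Working sense sequence containing `edit$ref`.
#' @param edit A `pegbe_edit` (see [edit_substitution()] and friends).
#' @param mode `"install"` (default) or `"revert"`.
#' @param pbs_len,rtt_len PBS/RTT lengths in nt; the defaults of 13 nt are
#'   the suggested starting values.
#' @param show_all Return every candidate (`TRUE`) or only the top-scoring
#'   one (`FALSE`, default).
#' @param variant_name Label carried into the output.
#' @param nicking `"none"` (PE2), `"PE3"` or `"PE3b"`; when not "none", each
#'   returned candidate carries its nicking guides in the `nicking_guides`
#'   list-column.
#' @return A `peg_design` tibble, one row per candidate (or one
#'   untargetable row), with penalty breakdown columns.
#' @export
#' @examples
#' seq <- make_sequence(240, plant = data.frame(strand = "+", pos = 131,
#'   seq = "TGG"), seed = 1)
#' design_pegrnas(seq, edit_substitution(130, substr(seq, 130, 130), "G"))
design_pegrnas <- function(sequence, edit, mode = c("install", "revert"),
                           pbs_len = 13L, rtt_len = 13L, show_all = FALSE,
                           variant_name = "variant",
                           nicking = c("none", "PE3", "PE3b")) {
  mode <- match.arg(mode)
  nicking <- match.arg(nicking)
  sequence <- as_dna(sequence, allow_n = TRUE)
  job <- list(
    mode = mode, pbs_len = pbs_len, rtt_len = rtt_len,
    show_all = show_all, nicking = nicking
  )
  if (mode == "revert") {
    variant_seq <- apply_edit(sequence, edit)$sequence
    sequence <- variant_seq
    edit <- invert_edit(edit)
  }
  edited <- apply_edit(sequence, edit)
  hits <- scan_pams(edited)
  if (nrow(hits) == 0L) {
    return(new_peg_design(
      untargetable_row(variant_name, "no PAM in scan window",
        pbs_len, rtt_len),
      job
    ))
  }
  cands <- purrr::map_dfr(seq_len(nrow(hits)), function(i) {
    b <- build_pegrna(hits[i, ], edited, pbs_len = pbs_len,
      rtt_len = rtt_len)
    if (is.null(b)) tibble::tibble() else b
  })
  if (nrow(cands) == 0L) {
    return(new_peg_design(
      untargetable_row(variant_name, "edit not covered by RTT",
        pbs_len, rtt_len),
      job
    ))
  }
  cands <- score_pegrna(cands)
  sense_pos <- ifelse(cands$strand == "+", cands$pam_start0,
    nchar(edited$sequence) - cands$pam_start0 - 3L)
  cands <- cands[order(-cands$score, cands$edit_position,
    cands$strand != "+", sense_pos), ]
  if (!show_all) cands <- cands[1L, ]
  cands$variant_name <- variant_name
  cands$status <- "targetable"
  cands$reason <- NA_character_
  if (nicking != "none") {
    design_fn <- if (nicking == "PE3") design_pe3_nicks else design_pe3b_nicks
    cands$nicking_guides <- purrr::map(seq_len(nrow(cands)), function(i) {
      design_fn(edited, cands[i, ])
    })
    out <- cands[, c(peg_columns, "nicking_guides")]
  } else {
    out <- cands[, peg_columns]
  }
  new_peg_design(out, job)
}

#' Design pegRNAs for a batch of variant jobs
#'
#' Runs [design_pegrnas()] over a jobs table (from [read_pe_batch()],
#' [read_clinvar_variant_summary()], or built by hand). Genomic-coordinate
#' jobs have their window fetched from `genome`; raw-sequence jobs need no
#' genome. Invalid jobs (flagged by the readers, or with a `ref` mismatch
#' against the genome) surface as `"invalid"` rows rather than aborting the
#' batch, so the output always conserves one-or-more rows per input job.
#'
#' @param jobs Tibble with columns `name`, `sequence` or
#'   `contig`/`position`, `edit_type`, `ref`, `alt`, and optionally
#'   `position` (1-based position in `sequence` for raw jobs), `mode`,
#'   `pbs_len`, `rtt_len`, `valid`, `reason`.
#' @param genome Path to a FASTA file (indexed on first use) for
#'   genomic-coordinate jobs.
#' @param show_all Keep all candidates per variant, or only the best.
#' @param flank Nucleotides of genomic context fetched on each side of a
#'   variant (default 150).
#' @param nicking Nicking system, as in [design_pegrnas()].
#' @return A `peg_design` tibble over all jobs.
#' @export
design_pegrna_batch <- function(jobs, genome = NULL, show_all = FALSE,
                                flank = 150L,
                                nicking = c("none", "PE3", "PE3b")) {
  nicking <- match.arg(nicking)
  rows <- purrr::map_dfr(seq_len(nrow(jobs)), function(i) {
    job <- jobs[i, ]
    pbs_len <- jfield(job, "pbs_len", 13L)
    rtt_len <- jfield(job, "rtt_len", 13L)
    if (isFALSE(jfield(job, "valid", TRUE))) {
      r <- untargetable_row(job$name, jfield(job, "reason", "invalid row"),
        pbs_len, rtt_len)
      r$status <- "invalid"
      return(r)
    }
    res <- tryCatch(
      {
        raw_seq <- jfield(job, "sequence", NA_character_)
        if (!is.na(raw_seq) && nzchar(raw_seq)) {
          seq <- raw_seq
          pos <- jfield(job, "position", NA_integer_)
        } else {
          win <- fetch_genomic_window(genome, job$contig, job$position, flank)
          seq <- win$sequence
          pos <- win$position_in_window
        }
        edit <- make_job_edit(job$edit_type, pos, job$ref, job$alt)
        design_pegrnas(seq, edit,
          mode = jfield(job, "mode", "install"),
          pbs_len = pbs_len, rtt_len = rtt_len,
          show_all = show_all, variant_name = job$name, nicking = nicking
        )
      },
      error = function(e) {
        r <- untargetable_row(job$name, conditionMessage(e),
          pbs_len, rtt_len)
        r$status <- "invalid"
        r
      }
    )
    res
  })
  new_peg_design(rows, list(show_all = show_all, nicking = nicking))
}

# Build a pegbe_edit from batch-table fields (1-based position).
make_job_edit <- function(edit_type, position, ref, alt) {
  ref <- if (is.na(ref) || ref == "-" ) "" else ref
  alt <- if (is.na(alt) || alt == "-" ) "" else alt
  switch(tolower(edit_type),
    substitution = ,
    snv = edit_substitution(position, ref, alt),
    insertion = edit_insertion(position, alt),
    deletion = edit_deletion(position, ref),
    stop("unknown edit_type '", edit_type, "'", call. = FALSE)
  )
}

# Field from a one-row jobs tibble, with a default when the column is
# absent or NA.
jfield <- function(job, name, default) {
  if (!name %in% names(job)) return(default)
  v <- job[[name]]
  if (length(v) != 1L || is.na(v)) default else v
}
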