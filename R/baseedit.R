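# Base-editor guide design: editor registry, strand resolution for SNVs,
# window scanning on both strands, bystander detection and editor ranking.
#
# Protospacer positions are numbered 1-20 from the PAM-distal (5') end;
# an editor's window (start, end) is in those coordinates.

#' Built-in base-editor registry
#'
#' The default set of deaminase-Cas9 fusions the designer searches with.
#' Cytosine base editors (CBEs; C->T) are engineered low-off-target BE3
#' variants plus Target-AID, all recognising 5'-NGG-3' PAMs. Adenine base
#' editors (ABEs; A->G) cover seven distinct PAM motifs across SpCas9 and
#' SaCas9 variants: NGG, NGA, NGCG, NNGRRT, NNNRRT, NGN and the near-PAMless
#' SpRY NRN. ABEmax's editing window is protospacer positions 5-7 (base 1
#' PAM-distal); windows for the other editors are registry defaults taken
#' from the editor literature and can be overridden via
#' [read_editor_registry()]. BE3(R33A/K34A) carries a hard sequence
#' constraint: it requires a T immediately 5' of the target C. SpRY carries
#' a lower-efficiency note that is propagated to the output and used in
#' ranking.
#'
#' @param spry_nyn Also accept NYN PAMs for SpRY (edited less efficiently
#'   than NRN; off by default, keeping the distinct ABE PAM count at 7).
#' @return A tibble with columns `name`, `class` ("ABE"/"CBE"), `pam`,
#'   `window_start`, `window_end`, `constraint`, `efficiency_note`.
#' @export
builtin_editors <- function(spry_nyn = FALSE) {
  ed <- tibble::tribble(
    ~name, ~class, ~pam, ~window_start, ~window_end, ~constraint,
    ~efficiency_note,
    "ABEmax-SpCas9", "ABE", "NGG", 5L, 7L, NA_character_, NA_character_,
    "ABE-SpCas9-VRQR", "ABE", "NGA", 5L, 7L, NA_character_, NA_character_,
    "ABE-SpCas9-NG", "ABE", "NGCG", 5L, 7L, NA_character_, NA_character_,
    "ABE-SaCas9", "ABE", "NNGRRT", 5L, 7L, NA_character_, NA_character_,
    "ABE-SaCas9-KKH", "ABE", "NNNRRT", 5L, 7L, NA_character_, NA_character_,
    "ABE-SpG", "ABE", "NGN", 5L, 7L, NA_character_, NA_character_,
    "ABE-SpRY", "ABE", "NRN", 5L, 7L, NA_character_,
    "lower overall efficiency than other implemented editors",
    "BE3(R33A)", "CBE", "NGG", 4L, 8L, NA_character_, NA_character_,
    "BE3(R33A/K34A)", "CBE", "NGG", 4L, 8L, "5prime_T", NA_character_,
    "BE3-hA3A(R128A)", "CBE", "NGG", 4L, 8L, NA_character_, NA_character_,
    "Target-AID", "CBE", "NGG", 2L, 4L, NA_character_, NA_character_
  )
  if (spry_nyn) {
    ed <- dplyr::bind_rows(ed, tibble::tibble(
      name = "ABE-SpRY (NYN)", class = "ABE", pam = "NYN",
      window_start = 5L, window_end = 7L, constraint = NA_character_,
      efficiency_note = "NYN PAMs are edited less efficiently than NRN"
    ))
  }
  validate_editors(ed)
}

validate_editors <- function(ed) {
  required <- c(
    "name", "class", "pam", "window_start", "window_end",
    "constraint", "efficiency_note"
  )
  missing <- setdiff(required, names(ed))
  if (length(missing) > 0L) {
    stop("editor registry is missing field(s): ",
      paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(ed$class %in% c("ABE", "CBE"))) {
    stop("editor registry field 'class' must be ABE or CBE", call. = FALSE)
  }
  bad_pam <- !vapply(ed$pam, function(p) {
    nchar(p) >= 3L && nchar(p) <= 6L &&
      all(strsplit(p, "")[[1L]] %in% names(IUPAC_CODES))
  }, logical(1L))
  if (any(bad_pam)) {
    stop("editor registry field 'pam' invalid for: ",
      paste(ed$name[bad_pam], collapse = ", "), call. = FALSE)
  }
  if (any(ed$window_start < 1L | ed$window_end > 20L |
    ed$window_start > ed$window_end)) {
    stop("editor registry fields 'window_start'/'window_end' must satisfy ",
      "1 <= start <= end <= 20", call. = FALSE)
  }
  known <- c(NA_character_, "5prime_T")
  if (!all(ed$constraint %in% known)) {
    stop("editor registry field 'constraint' must be empty or '5prime_T'",
      call. = FALSE)
  }
  ed$registry_index <- seq_len(nrow(ed))
  ed
}

#' Resolve which deaminase acts on which strand for a single-base change
#'
#' Base editors perform transitions only: ABEs convert A->G on the strand
#' they act on, CBEs convert C->T. A genomic change is therefore reachable
#' on exactly one strand: A->G by an ABE on the sense strand, T->C by an ABE
#' acting on the antisense A, C->T by a CBE on the sense strand, and G->A by
#' a CBE acting on the antisense C. In `"revert"` mode the change to perform
#' is alt->ref (the variant base is present and must be converted back);
#' `"install"` performs ref->alt. With gene `orientation` "-", `ref`/`alt`
#' are interpreted on the minus strand and complemented first.
#'
#' @param ref,alt Single reference/alternate bases of the SNV.
#' @param mode `"install"` or `"revert"`.
#' @param orientation Strand on which `ref`/`alt` are reported ("+"/"-").
#' @return A tibble of tasks: `class` (ABE/CBE), `strand` (strand the
#'   deaminase acts on, relative to the working sense sequence),
#'   `source_base` (the base edited in that strand's frame), `change`
#'   (sense-strand change label). Zero rows with attribute `reason` when the
#'   change is a transversion (not base-editable).
#' @export
#' @examples
#' resolve_strand_tasks("C", "T", mode = "revert")  # ABE on antisense
resolve_strand_tasks <- function(ref, alt, mode = c("install", "revert"),
                                 orientation = "+") {
  mode <- match.arg(mode)
  ref <- as_dna(ref, what = "ref")
  alt <- as_dna(alt, what = "alt")
  if (nchar(ref) != 1L || nchar(alt) != 1L) {
    stop("base editing addresses single-base substitutions only",
      call. = FALSE)
  }
  if (orientation == "-") {
    ref <- revcomp(ref)
    alt <- revcomp(alt)
  }
  from <- if (mode == "install") ref else alt
  to <- if (mode == "install") alt else ref
  change <- paste0(from, ">", to)
  task <- switch(change,
    "A>G" = tibble::tibble(class = "ABE", strand = "+", source_base = "A"),
    "T>C" = tibble::tibble(class = "ABE", strand = "-", source_base = "A"),
    "C>T" = tibble::tibble(class = "CBE", strand = "+", source_base = "C"),
    "G>A" = tibble::tibble(class = "CBE", strand = "-", source_base = "C"),
    NULL
  )
  if (is.null(task)) {
    out <- tibble::tibble(
      class = character(), strand = character(), source_base = character(),
      change = character()
    )
    attr(out, "reason") <- paste0(
      "not base-editable: ", change,
      " is a transversion (base editors perform A>G / C>T transitions)"
    )
    return(out)
  }
  task$change <- change
  task
}

#' Bystander bases in an editing window
#'
#' Protospacer positions inside the editor's window, other than the target
#' position, that hold the same editable base (A for ABEs, C for CBEs) on
#' the protospacer strand — bases the deaminase could also modify.
#'
#' @param protospacer 20-nt protospacer string.
#' @param window_start,window_end Editing window in protospacer coordinates.
#' @param edit_position Protospacer position of the intended target.
#' @param base Editable base ("A" or "C").
#' @return Integer vector of bystander positions (possibly empty).
#' @export
find_bystanders <- function(protospacer, window_start, window_end,
                            edit_position, base) {
  pos <- window_start:window_end
  chars <- substring(protospacer, pos, pos)
  pos[chars == base & pos != edit_position]
}

#' Design base-editor guide RNAs for an SNV
#'
#' For every registry editor and every strand task, enumerates each
#' placement where a motif-matching PAM puts the target base inside the
#' editor's window, applying any sequence constraint (e.g. the
#' BE3(R33A/K34A) requirement for a T immediately 5' of the target C).
#' Guides target the variant-carrying sequence: in `"revert"` mode the SNV
#' is first written into the supplied (reference) sequence.
#'
#' @param sequence Working sense sequence carrying `ref` at `position`.
#' @param position 1-based position of the SNV in `sequence`.
#' @param ref,alt SNV alleles (on `orientation` strand).
#' @param mode `"install"` or `"revert"`.
#' @param orientation Strand of `ref`/`alt` ("+"/"-").
#' @param editors Editor registry tibble (default [builtin_editors()]).
#' @param ranked Rank candidates with [rank_editors()] (default `TRUE`).
#' @return A `be_design` tibble: `editor`, `class`, `pam`, `protospacer`
#'   (targeting the variant sequence), `pam_seq`, `strand`, `edit_position`,
#'   `bystanders` (list-column), `n_bystanders`, `note`, `status`, `reason`.
#'   A non-editable change yields one `"not_base_editable"` row.
#' @export
design_be_guides <- function(sequence, position, ref, alt,
                             mode = c("install", "revert"),
                             orientation = "+",
                             editors = builtin_editors(), ranked = TRUE) {
  mode <- match.arg(mode)
  sequence <- as_dna(sequence, allow_n = TRUE)
  editors <- validate_editors(editors)
  # sense-frame alleles
  sref <- if (orientation == "-") revcomp(ref) else toupper(ref)
  salt <- if (orientation == "-") revcomp(alt) else toupper(alt)
  observed <- substr(sequence, position, position)
  if (nchar(sref) == 1L && observed != sref) {
    stop("ref mismatch at position ", position, ": expected '", sref,
      "', observed '", observed, "'", call. = FALSE)
  }
  tasks <- resolve_strand_tasks(ref, alt, mode = mode,
    orientation = orientation)
  if (nrow(tasks) == 0L) {
    out <- tibble::tibble(
      editor = NA_character_, class = NA_character_, pam = NA_character_,
      protospacer = NA_character_, pam_seq = NA_character_,
      strand = NA_character_, edit_position = NA_integer_,
      bystanders = list(integer(0)), n_bystanders = NA_integer_,
      note = NA_character_, status = "not_base_editable",
      reason = attr(tasks, "reason")
    )
    return(structure(out, class = c("be_design", class(out))))
  }
  # working sequence carries the base to be converted
  working <- if (mode == "revert") {
    apply_edit(sequence, edit_substitution(position, sref, salt))$sequence
  } else {
    sequence
  }
  L <- nchar(working)
  cands <- purrr::map_dfr(seq_len(nrow(tasks)), function(ti) {
    task <- tasks[ti, ]
    fr <- if (task$strand == "+") working else revcomp(working)
    tpos0 <- if (task$strand == "+") position - 1L else L - position
    stopifnot(substr(fr, tpos0 + 1L, tpos0 + 1L) == task$source_base)
    eds <- editors[editors$class == task$class, ]
    purrr::map_dfr(seq_len(nrow(eds)), function(ei) {
      ed <- eds[ei, ]
      plen <- nchar(ed$pam)
      purrr::map_dfr(ed$window_start:ed$window_end, function(w) {
        start0 <- tpos0 - (w - 1L)
        if (start0 < 0L || start0 + PROTO_LEN + plen > L) {
          return(tibble::tibble())
        }
        pam_seq <- substr(fr, start0 + PROTO_LEN + 1L, start0 + PROTO_LEN + plen)
        if (!iupac_match(ed$pam, pam_seq)) {
          return(tibble::tibble())
        }
        if (!is.na(ed$constraint) && ed$constraint == "5prime_T") {
          if (tpos0 < 1L || substr(fr, tpos0, tpos0) != "T") {
            return(tibble::tibble())
          }
        }
        proto <- substr(fr, start0 + 1L, start0 + PROTO_LEN)
        bys <- find_bystanders(proto, ed$window_start, ed$window_end, w,
          task$source_base)
        tibble::tibble(
          editor = ed$name, class = ed$class, pam = ed$pam,
          protospacer = proto, pam_seq = pam_seq, strand = task$strand,
          edit_position = w, bystanders = list(bys),
          n_bystanders = length(bys), note = ed$efficiency_note,
          registry_index = ed$registry_index,
          status = "targetable", reason = NA_character_
        )
      })
    })
  })
  if (nrow(cands) == 0L) {
    out <- tibble::tibble(
      editor = NA_character_, class = NA_character_, pam = NA_character_,
      protospacer = NA_character_, pam_seq = NA_character_,
      strand = NA_character_, edit_position = NA_integer_,
      bystanders = list(integer(0)), n_bystanders = NA_integer_,
      note = NA_character_, status = "untargetable",
      reason = "no PAM places the target base inside an editing window"
    )
    return(structure(out, class = c("be_design", class(out))))
  }
  if (ranked) cands <- rank_editors(cands)
  cands$registry_index <- NULL
  structure(cands, class = c("be_design", class(cands)))
}

#' Rank base-editor guide candidates
#'
#' Candidates with fewer bystander bases come first (cleaner editing); ties
#' prefer editors without an efficiency caveat (e.g. SpRY's lower overall
#' efficiency) and then registry order, edit position, strand and sequence
#' for a deterministic result.
#'
#' @param cands Candidate tibble from [design_be_guides()].
#' @return The same tibble, reordered.
#' @export
rank_editors <- function(cands) {
  if (nrow(cands) == 0L) {
    return(cands)
  }
  idx <- if ("registry_index" %in% names(cands)) {
    cands$registry_index
  } else {
    seq_len(nrow(cands))
  }
  o <- order(
    cands$n_bystanders,
    !is.na(cands$note),
    idx,
    cands$edit_position,
    cands$strand != "+",
    cands$protospacer
  )
  cands[o, ]
}
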