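# Readers and writers: batch CSV templates, ClinVar-style variant_summary
# tables, genomic FASTA windows, and result tables.
#
# All readers are total over malformed rows: a bad row never aborts a
# batch; it is flagged (valid = FALSE, reason) and surfaces in the design
# output as an "invalid" row, so row conservation holds end to end.

PE_BATCH_MANDATORY <- c("name", "position", "edit_type", "ref", "alt")

#' Read a prime-editing batch CSV
#'
#' The batch dialect has one variant per row with columns `name`,
#' `sequence` *or* `contig` (exactly one per row), `position` (1-based; in
#' the raw sequence, or genomic), `orientation` (+/-, default +),
#' `edit_type` (substitution/insertion/deletion), `ref`, `alt` ("-" or
#' empty for the absent allele of an indel), and optional `pbs_len`,
#' `rtt_len` (default 13 nt) and `mode` (install/revert, default install).
#' A template is shipped at
#' `system.file("extdata", "pe_template.csv", package = "pegbe")`.
#'
#' @param path CSV path.
#' @return A jobs tibble, one row per input row, with `valid` and `reason`
#'   columns; invalid rows are retained (flagged) so batch output conserves
#'   the input row count.
#' @export
read_pe_batch <- function(path) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  missing <- setdiff(PE_BATCH_MANDATORY, names(raw))
  if (length(missing) > 0L) {
    stop("batch file is missing mandatory column(s): ",
      paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!any(c("sequence", "contig") %in% names(raw))) {
    stop("batch file is missing mandatory column(s): sequence or contig",
      call. = FALSE)
  }
  get <- function(col, default = "") {
    if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  num_or <- function(x, default) {
    x <- suppressWarnings(as.integer(x))
    ifelse(is.na(x), default, x)
  }
  jobs <- tibble::tibble(
    name = get("name"),
    sequence = toupper(get("sequence")),
    contig = get("contig"),
    position = suppressWarnings(as.integer(get("position"))),
    orientation = ifelse(get("orientation", "+") == "", "+",
      get("orientation", "+")),
    edit_type = tolower(get("edit_type")),
    ref = toupper(get("ref")),
    alt = toupper(get("alt")),
    pbs_len = num_or(get("pbs_len"), 13L),
    rtt_len = num_or(get("rtt_len"), 13L),
    mode = ifelse(get("mode", "install") == "", "install",
      get("mode", "install"))
  )
  jobs <- dplyr::mutate(jobs, valid = TRUE, reason = NA_character_)
  flag <- function(jobs, bad, why) {
    dplyr::mutate(jobs,
      reason = ifelse(bad & .data$valid, why, .data$reason),
      valid = .data$valid & !bad
    )
  }
  jobs <- flag(jobs, jobs$name == "", "missing name")
  jobs <- flag(jobs, is.na(jobs$position) | jobs$position < 1L,
    "missing or invalid position")
  jobs <- flag(jobs, !(nzchar(jobs$sequence) | nzchar(jobs$contig)),
    "neither sequence nor contig given")
  jobs <- flag(jobs, nzchar(jobs$sequence) & nzchar(jobs$contig),
    "both sequence and contig given")
  jobs <- flag(jobs,
    !jobs$edit_type %in% c("substitution", "snv", "insertion", "deletion"),
    "unknown edit_type")
  jobs <- flag(jobs, !jobs$mode %in% c("install", "revert"), "unknown mode")
  jobs <- flag(jobs,
    !grepl("^[ACGTN]*$", jobs$sequence) |
      !grepl("^[ACGT-]*$", jobs$ref) | !grepl("^[ACGT-]*$", jobs$alt),
    "invalid characters in sequence/ref/alt")
  jobs <- flag(jobs, jobs$pbs_len < 1L | jobs$pbs_len > 17L,
    "pbs_len out of range 1-17")
  jobs
}

CLINVAR_MANDATORY <- c(
  "Name", "Type", "ClinicalSignificance", "Chromosome", "Start",
  "ReferenceAllele", "AlternateAllele"
)

#' Read a ClinVar-style variant_summary table
#'
#' Reads the tab-delimited variant_summary dialect by column *name*
#' (tolerant to column order and extra columns), keeping rows whose clinical
#' significance is Pathogenic or Likely pathogenic, whose type is one of the
#' four prime-editable classes (single nucleotide variant, deletion,
#' duplication, insertion) and whose contig is nuclear (not MT).
#' Duplications are mapped to insertion edits whose alt equals the
#' duplicated segment, placed immediately after it. Alleles use the minimal
#' representation ("-" or empty for the absent allele).
#'
#' @param path Tab-delimited file path.
#' @return A revert-mode jobs tibble (columns as in [read_pe_batch()]);
#'   excluded rows are recorded in the `"skipped"` attribute with reasons.
#' @export
read_clinvar_variant_summary <- function(path) {
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  missing <- setdiff(CLINVAR_MANDATORY, names(raw))
  if (length(missing) > 0L) {
    stop("variant_summary file is missing column(s): ",
      paste(missing, collapse = ", "), call. = FALSE)
  }
  sig_keep <- c("Pathogenic", "Likely pathogenic")
  type_map <- c(
    "single nucleotide variant" = "substitution",
    "deletion" = "deletion",
    "duplication" = "duplication",
    "insertion" = "insertion"
  )
  keep <- raw$ClinicalSignificance %in% sig_keep &
    raw$Type %in% names(type_map) &
    !raw$Chromosome %in% c("MT", "chrM", "chrMT")
  skipped <- tibble::tibble(
    row = which(!keep),
    name = raw$Name[!keep],
    reason = dplyr::case_when(
      !raw$ClinicalSignificance[!keep] %in% sig_keep ~
        "not pathogenic/likely pathogenic",
      !raw$Type[!keep] %in% names(type_map) ~ "type not designable",
      TRUE ~ "mitochondrial contig"
    )
  )
  kept <- raw[keep, ]
  norm <- function(x) ifelse(x %in% c("-", "na", "NA"), "", toupper(x))
  ref <- norm(kept$ReferenceAllele)
  alt <- norm(kept$AlternateAllele)
  pos <- suppressWarnings(as.integer(kept$Start))
  type <- unname(type_map[kept$Type])
  # duplication of segment [pos, pos + nchar(ref)): insert a second copy
  # immediately 3' of the original
  is_dup <- type == "duplication"
  alt[is_dup] <- ref[is_dup]
  pos[is_dup] <- pos[is_dup] + nchar(ref[is_dup])
  ref[is_dup] <- ""
  type[is_dup] <- "insertion"
  jobs <- tibble::tibble(
    name = kept$Name,
    sequence = "",
    contig = kept$Chromosome,
    position = pos,
    orientation = "+",
    edit_type = type,
    ref = ref,
    alt = alt,
    pbs_len = 13L,
    rtt_len = 13L,
    mode = "revert",
    valid = TRUE,
    reason = NA_character_
  )
  bad <- is.na(jobs$position)
  jobs$valid[bad] <- FALSE
  jobs$reason[bad] <- "unparseable position"
  attr(jobs, "skipped") <- skipped
  jobs
}

#' Fetch a genomic sequence window from an indexed FASTA
#'
#' Retrieves `[position - flank, position + flank]` (1-based, clipped to the
#' contig with a warning) from a FASTA file, indexing it first if no `.fai`
#' exists.
#'
#' @param fasta Path to the FASTA file.
#' @param contig Contig name.
#' @param position 1-based genomic position of interest.
#' @param flank Nucleotides of context on each side.
#' @return A list: `sequence` (upper-case window), `start` (genomic
#'   coordinate of the window's first base), `position_in_window` (1-based
#'   position of `position` inside the window).
#' @export
fetch_genomic_window <- function(fasta, contig, position, flank = 150L) {
  if (is.null(fasta)) {
    stop("a genome FASTA is required for genomic-coordinate jobs",
      call. = FALSE)
  }
  if (!file.exists(paste0(fasta, ".fai"))) {
    Rsamtools::indexFa(fasta)
  }
  fa <- Rsamtools::FaFile(fasta)
  info <- Rsamtools::seqinfo(fa)
  contigs <- GenomeInfoDb::seqnames(info)
  if (!contig %in% contigs) {
    stop("contig '", contig, "' not found in ", fasta, "; available: ",
      paste(contigs, collapse = ", "), call. = FALSE)
  }
  clen <- GenomeInfoDb::seqlengths(info)[[contig]]
  if (position < 1L || position > clen) {
    stop("position ", position, " outside contig '", contig, "' (1-",
      clen, ")", call. = FALSE)
  }
  start <- max(1L, position - as.integer(flank))
  end <- min(clen, position + as.integer(flank))
  if (start > position - flank || end < position + flank) {
    warning("window truncated at contig boundary", call. = FALSE)
  }
  rng <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, end))
  seq <- as.character(Rsamtools::scanFa(fa, rng)[[1L]])
  list(
    sequence = toupper(seq),
    start = start,
    position_in_window = position - start + 1L
  )
}

#' Materialise genomic windows into raw-sequence jobs
#'
#' Fetches each genomic-coordinate job's window once and rewrites the job
#' as a raw-sequence job (with `position` relocated into the window).
#' Useful before repeated re-design of the same batch, e.g. an RTT-length
#' sweep, so the FASTA is only read once per variant.
#'
#' @param jobs Jobs tibble (see [design_pegrna_batch()]).
#' @param genome FASTA path.
#' @param flank Context per side in nt.
#' @return The jobs tibble with `sequence` filled and `contig` cleared;
#'   jobs whose window cannot be fetched are flagged invalid.
#' @export
materialize_windows <- function(jobs, genome, flank = 150L) {
  purrr::map_dfr(seq_len(nrow(jobs)), function(i) {
    job <- jobs[i, ]
    if (isFALSE(job$valid) || !nzchar(job$contig %||0% "")) {
      return(job)
    }
    tryCatch(
      {
        win <- fetch_genomic_window(genome, job$contig, job$position, flank)
        job$sequence <- win$sequence
        job$position <- win$position_in_window
        job$contig <- ""
        job
      },
      error = function(e) {
        job$valid <- FALSE
        job$reason <- conditionMessage(e)
        job
      }
    )
  })
}

#' Write a result table
#'
#' Writes PE or BE design results as TSV/CSV with a fixed, deterministic
#' column order. PE tables carry variant name, pegRNA score, protospacer,
#' edit position, PAM sequence and strand, and the 3' extension, followed by
#' the penalty breakdown and homology; untargetable variants appear as rows
#' with a `reason`. List-columns (bystanders, nicking guides) are flattened
#' to comma-separated strings.
#'
#' @param records A `peg_design` or `be_design` tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  out <- tibble::as_tibble(records)
  if ("bystanders" %in% names(out)) {
    out$bystanders <- vapply(out$bystanders, function(b) {
      paste(b, collapse = ",")
    }, character(1L))
  }
  if ("nicking_guides" %in% names(out)) {
    out$nicking_guides <- vapply(out$nicking_guides, function(g) {
      if (is.null(g) || nrow(g) == 0L) "" else
        paste(paste0(g$protospacer, "|", g$pam_seq), collapse = ",")
    }, character(1L))
  }
  writer <- if (format == "tsv") readr::write_tsv else readr::write_csv
  writer(out, path, na = "")
  invisible(path)
}
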