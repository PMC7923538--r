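# Seeded synthetic-data generators. Every design path is testable without
# downloads: sequences with planted PAMs on controlled backgrounds, and
# desk-scale ClinVar-dialect variant tables with a synthetic genome and an
# exact ground-truth ledger. All generators are pure functions of their
# arguments and seed.

#' Generate a sequence with planted motifs on a controlled background
#'
#' Draws a background sequence from `alphabet` and overwrites planted
#' realizations at the requested positions ("-" strand plantings are
#' written as their reverse complement on the sense strand). When `forbid`
#' is given, the generated sequence is verified to contain no match of that
#' motif on either strand outside the planted windows; a background able to
#' produce accidental matches is rejected as infeasible rather than
#' silently patched.
#'
#' @param length Sequence length in nt.
#' @param plant Optional data frame with columns `strand` ("+"/"-"), `pos`
#'   (1-based sense position of the realization's 5'-most sense base) and
#'   `seq` (the realization, in its own strand's orientation).
#' @param alphabet Background letters (default `c("A","T")`, which cannot
#'   form an NGG PAM).
#' @param forbid Optional IUPAC motif that must not occur outside plantings.
#' @param seed RNG seed (default 1729, the suite's documented seed).
#' @return A character scalar sequence.
#' @export
#' @examples
#' make_sequence(60, plant = data.frame(strand = "+", pos = 30, seq = "TGG"))
make_sequence <- function(length, plant = NULL, alphabet = c("A", "T"),
                          forbid = "NGG", seed = 1729L) {
  stopifnot(length >= 1L)
  chars <- withr::with_seed(seed, {
    sample(alphabet, length, replace = TRUE)
  })
  planted_iv <- list()
  if (!is.null(plant) && nrow(plant) > 0L) {
    plant <- tibble::as_tibble(plant)
    plant$sense_seq <- ifelse(plant$strand == "-", revcomp(plant$seq),
      toupper(plant$seq))
    iv <- cbind(plant$pos, plant$pos + nchar(plant$sense_seq) - 1L)
    if (any(iv[, 1L] < 1L | iv[, 2L] > length)) {
      stop("planting outside sequence bounds", call. = FALSE)
    }
    o <- order(iv[, 1L])
    if (nrow(iv) > 1L && any(iv[o, 1L][-1L] <= iv[o, 2L][-nrow(iv)])) {
      stop("plantings overlap", call. = FALSE)
    }
    for (i in seq_len(nrow(plant))) {
      s <- strsplit(plant$sense_seq[i], "")[[1L]]
      chars[iv[i, 1L]:iv[i, 2L]] <- s
    }
    planted_iv <- lapply(seq_len(nrow(plant)), function(i) iv[i, ])
  }
  seq <- paste(chars, collapse = "")
  if (!is.null(forbid)) {
    verify_no_accidental(seq, forbid, planted_iv)
  }
  seq
}

# Error if `motif` matches either strand of `seq` outside the planted
# sense-coordinate intervals.
verify_no_accidental <- function(seq, motif, planted_iv) {
  L <- nchar(seq)
  mlen <- nchar(motif)
  allowed <- function(s, e) {
    any(vapply(planted_iv, function(iv) s >= iv[1L] && e <= iv[2L],
      logical(1L)))
  }
  plus <- motif_starts0(motif, seq) + 1L
  for (s in plus) {
    if (!allowed(s, s + mlen - 1L)) {
      stop("infeasible fixture spec: accidental ", motif, " at sense ",
        s, call. = FALSE)
    }
  }
  minus <- motif_starts0(motif, revcomp(seq)) + 1L
  for (q in minus) {
    s <- L - (q + mlen - 1L) + 1L
    if (!allowed(s, s + mlen - 1L)) {
      stop("infeasible fixture spec: accidental ", motif,
        " on antisense at sense ", s, call. = FALSE)
    }
  }
  invisible(seq)
}

#' Generate a synthetic genome and ClinVar-dialect variant table
#'
#' Emulates, at desk scale, a pathogenic-variant table over the four
#' prime-editable classes (SNV, deletion, duplication, insertion): writes a
#' random synthetic contig as FASTA plus a tab-delimited variant_summary
#' dialect file, with a configurable fraction of Benign rows and
#' mitochondrial rows that the reader must exclude. Returns the exact
#' ground truth (expected post-filter jobs and per-class counts), so reader
#' round-trips can be asserted verbatim.
#'
#' @param n Number of pathogenic nuclear variant rows.
#' @param mix Named class proportions over `c("snv","del","dup","ins")`,
#'   summing to 1; the default mirrors a pathogenic-variant class mixture
#'   dominated by SNVs.
#' @param benign_frac Fraction of additional Benign rows (excluded by the
#'   reader).
#' @param mito_frac Fraction of additional MT-contig rows (excluded).
#' @param dir Output directory (created if needed).
#' @param contig_spacing Genomic spacing between variants (default 250 nt,
#'   ample design context).
#' @param seed RNG seed.
#' @return A list: `fasta` (path), `variants` (path), `truth` (expected
#'   jobs tibble, as [read_clinvar_variant_summary()] should return it),
#'   `counts` (per-class counts), `n_excluded`.
#' @export
make_variant_table <- function(n, mix = c(snv = 0.65, del = 0.22,
                                 dup = 0.10, ins = 0.03),
                               benign_frac = 0.1, mito_frac = 0.05,
                               dir = tempfile("varsim"),
                               contig_spacing = 250L, seed = 1729L) {
  stopifnot(n >= 1L, abs(sum(mix) - 1) < 1e-8)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(seed, {
    contig_len <- 200L + n * contig_spacing + 200L
    genome <- paste(
      sample(c("A", "C", "G", "T"), contig_len, replace = TRUE),
      collapse = ""
    )
    classes <- sample(names(mix), n, replace = TRUE, prob = mix)
    positions <- 200L + (seq_len(n) - 1L) * contig_spacing
    base_at <- function(p, k = 1L) substr(genome, p, p + k - 1L)
    rows <- purrr::map_dfr(seq_len(n), function(i) {
      p <- positions[i]
      cls <- classes[i]
      if (cls == "snv") {
        ref <- base_at(p)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        tibble::tibble(
          Name = sprintf("VAR%04d", i), Type = "single nucleotide variant",
          ClinicalSignificance = "Pathogenic", Chromosome = "chr1",
          Start = as.character(p), ReferenceAllele = ref,
          AlternateAllele = alt
        )
      } else if (cls == "del") {
        k <- sample(1:5, 1L)
        tibble::tibble(
          Name = sprintf("VAR%04d", i), Type = "deletion",
          ClinicalSignificance = "Likely pathogenic", Chromosome = "chr1",
          Start = as.character(p), ReferenceAllele = base_at(p, k),
          AlternateAllele = "-"
        )
      } else if (cls == "dup") {
        k <- sample(1:4, 1L)
        tibble::tibble(
          Name = sprintf("VAR%04d", i), Type = "duplication",
          ClinicalSignificance = "Pathogenic", Chromosome = "chr1",
          Start = as.character(p), ReferenceAllele = base_at(p, k),
          AlternateAllele = "-"
        )
      } else {
        k <- sample(1:6, 1L)
        tibble::tibble(
          Name = sprintf("VAR%04d", i), Type = "insertion",
          ClinicalSignificance = "Likely pathogenic", Chromosome = "chr1",
          Start = as.character(p), ReferenceAllele = "-",
          AlternateAllele = paste(
            sample(c("A", "C", "G", "T"), k, replace = TRUE),
            collapse = ""
          )
        )
      }
    })
    n_benign <- round(n * benign_frac)
    n_mito <- round(n * mito_frac)
    extra <- tibble::tibble()
    if (n_benign > 0L) {
      p <- sample(positions, n_benign, replace = TRUE) + 50L
      extra <- dplyr::bind_rows(extra, tibble::tibble(
        Name = sprintf("BEN%04d", seq_len(n_benign)),
        Type = "single nucleotide variant",
        ClinicalSignificance = "Benign", Chromosome = "chr1",
        Start = as.character(p),
        ReferenceAllele = vapply(p, base_at, character(1L)),
        AlternateAllele = "A"
      ))
    }
    if (n_mito > 0L) {
      extra <- dplyr::bind_rows(extra, tibble::tibble(
        Name = sprintf("MT%04d", seq_len(n_mito)),
        Type = "single nucleotide variant",
        ClinicalSignificance = "Pathogenic", Chromosome = "MT",
        Start = as.character(sample(100:1000, n_mito, replace = TRUE)),
        ReferenceAllele = "A", AlternateAllele = "G"
      ))
    }
    all_rows <- dplyr::bind_rows(rows, extra)
    all_rows <- all_rows[sample(nrow(all_rows)), ]
    fasta <- file.path(dir, "genome.fa")
    writeLines(c(">chr1", chunk_fasta(genome)), fasta)
    variants <- file.path(dir, "variant_summary.tsv")
    readr::write_tsv(all_rows, variants, na = "")
    # expected post-filter jobs, in file order
    truth <- build_clinvar_truth(all_rows)
    counts <- table(factor(classes, levels = names(mix)))
    list(
      fasta = fasta, variants = variants, truth = truth,
      counts = as.list(counts), n_excluded = nrow(all_rows) - nrow(truth)
    )
  })
}

chunk_fasta <- function(seq, width = 70L) {
  starts <- seq(1L, nchar(seq), by = width)
  substring(seq, starts, pmin(starts + width - 1L, nchar(seq)))
}

# The reader's contract, restated independently for ground truth.
build_clinvar_truth <- function(rows) {
  keep <- rows$ClinicalSignificance %in% c("Pathogenic", "Likely pathogenic") &
    rows$Chromosome != "MT" &
    rows$Type %in% c(
      "single nucleotide variant", "deletion", "duplication", "insertion"
    )
  kept <- rows[keep, ]
  type <- c(
    "single nucleotide variant" = "substitution", "deletion" = "deletion",
    "duplication" = "duplication", "insertion" = "insertion"
  )[kept$Type]
  ref <- ifelse(kept$ReferenceAllele == "-", "", kept$ReferenceAllele)
  alt <- ifelse(kept$AlternateAllele == "-", "", kept$AlternateAllele)
  pos <- as.integer(kept$Start)
  is_dup <- type == "duplication"
  alt[is_dup] <- ref[is_dup]
  pos[is_dup] <- pos[is_dup] + nchar(ref[is_dup])
  ref[is_dup] <- ""
  type[is_dup] <- "insertion"
  tibble::tibble(
    name = kept$Name, sequence = "", contig = kept$Chromosome,
    position = pos, orientation = "+", edit_type = unname(type),
    ref = ref, alt = alt, pbs_len = 13L, rtt_len = 13L, mode = "revert",
    valid = TRUE, reason = NA_character_
  )
}
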