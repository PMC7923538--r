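# Golden-Gate oligo export for selected pegRNA candidates.

#' Default Golden-Gate adapter configuration
#'
#' Reads the shipped adapter config (`inst/extdata/oligo_adapters.yml`):
#' per-part 5'/3' adapter overhangs plus the invariant sgRNA scaffold
#' payload. Adapters are configuration, not constants — supply your own
#' file to match a different acceptor vector's sticky ends.
#'
#' @param path Optional path to a YAML adapter config.
#' @return A nested list: parts `spacer`, `scaffold`, `extension`,
#'   `nicking`, each with `top5`, `top3`, `bottom5`, `bottom3` (and
#'   `payload` for the scaffold).
#' @export
default_adapters <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "oligo_adapters.yml", package = "pegbe")
  }
  yaml::read_yaml(path)
}

oligo_pair <- function(variant, part, payload, ad) {
  tibble::tibble(
    variant_name = variant,
    part = part,
    oligo = c("top", "bottom"),
    sequence = c(
      paste0(ad$top5 %||0% "", payload, ad$top3 %||0% ""),
      paste0(ad$bottom5 %||0% "", revcomp(payload), ad$bottom3 %||0% "")
    )
  )
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

#' Export cloning oligos for selected pegRNAs
#'
#' For each candidate row, emits three oligo pairs — spacer (payload: the
#' protospacer), scaffold (invariant payload from the config) and 3'
#' extension (payload: RTT + PBS) — each pair being
#' `adapter5 + payload + adapter3` on top and
#' `adapter5 + revcomp(payload) + adapter3` on the bottom, ready for
#' Golden-Gate assembly into a BsmBI-digested acceptor. Nicking guides
#' attached in a `nicking_guides` list-column are exported as plain spacer
#' pairs.
#'
#' @param cands A `peg_design` tibble (targetable rows are exported;
#'   untargetable rows are skipped).
#' @param path Output TSV path, or `NULL` to just return the tibble.
#' @param adapters Adapter configuration (default [default_adapters()]).
#' @return A tibble of oligo records: `variant_name`, `part`, `oligo`
#'   (top/bottom), `sequence`.
#' @export
export_oligos <- function(cands, path = NULL, adapters = default_adapters()) {
  cands <- tibble::as_tibble(cands)
  keep <- !is.na(cands$protospacer)
  cands <- cands[keep, ]
  out <- purrr::map_dfr(seq_len(nrow(cands)), function(i) {
    row <- cands[i, ]
    recs <- dplyr::bind_rows(
      oligo_pair(row$variant_name, "spacer", row$protospacer,
        adapters$spacer),
      oligo_pair(row$variant_name, "scaffold", adapters$scaffold$payload,
        adapters$scaffold),
      oligo_pair(row$variant_name, "extension", row$extension_3p,
        adapters$extension)
    )
    if ("nicking_guides" %in% names(row)) {
      ng <- row$nicking_guides[[1L]]
      if (!is.null(ng) && nrow(ng) > 0L) {
        recs <- dplyr::bind_rows(recs, purrr::map_dfr(
          seq_len(nrow(ng)),
          function(j) {
            oligo_pair(
              paste0(row$variant_name, "_nick", j),
              paste0("nicking_", ng$system[j]),
              ng$protospacer[j], adapters$nicking
            )
          }
        ))
      }
    }
    recs
  })
  if (!is.null(path)) {
    readr::write_tsv(out, path, na = "")
  }
  out
}
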