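# Base-editor registry, strand resolution, window logic, bystanders.

# Frame sequence with a chosen protospacer + NGG PAM embedded in a pure-C
# background (C cannot form NGG on either strand except where G is placed).
be_fixture <- function(protospacer, pam = "TGG", pad5 = 30L, pad3 = 30L) {
  paste0(strrep("C", pad5), protospacer, pam, strrep("C", pad3))
}

test_that("the built-in registry matches the advertised editor set", {
  ed <- builtin_editors()
  expect_equal(sum(ed$class == "CBE"), 4L)
  expect_true(all(ed$pam[ed$class == "CBE"] == "NGG"))
  expect_equal(length(unique(ed$pam[ed$class == "ABE"])), 7L)
  abemax <- ed[ed$name == "ABEmax-SpCas9", ]
  expect_equal(c(abemax$window_start, abemax$window_end), c(5L, 7L))
  expect_equal(ed$constraint[ed$name == "BE3(R33A/K34A)"], "5prime_T")
  expect_false(is.na(ed$efficiency_note[ed$name == "ABE-SpRY"]))
  # optional NYN acceptance adds an eighth motif only when asked
  expect_equal(
    length(unique(builtin_editors(spry_nyn = TRUE)$pam)), 8L
  )
})

test_that("the registry round-trips through its config file bit-exactly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ed <- builtin_editors()
  write_editor_registry(ed, path)
  back <- read_editor_registry(path)
  cols <- c("name", "class", "pam", "window_start", "window_end",
    "constraint", "efficiency_note")
  expect_identical(
    as.data.frame(ed[, cols]), as.data.frame(back[, cols])
  )
  # malformed override is rejected naming the field
  bad <- ed
  bad$window_end[1] <- 25L
  expect_error(write_editor_registry(bad, path), "window_start.*window_end")
})

test_that("strand resolution maps transitions to the correct deaminase", {
  # reverting a genomic C>T variant: the variant T must become C, which is
  # A>G on the antisense strand - an ABE task
  t1 <- resolve_strand_tasks("C", "T", mode = "revert")
  expect_equal(t1$class, "ABE")
  expect_equal(t1$strand, "-")
  # installing A>G acts directly on the sense strand
  t2 <- resolve_strand_tasks("A", "G", mode = "install")
  expect_equal(t2$class, "ABE")
  expect_equal(t2$strand, "+")
  # reverting G>A: the variant A becomes G, an ABE task on the sense strand
  t3 <- resolve_strand_tasks("G", "A", mode = "revert")
  expect_equal(t3$class, "ABE")
  expect_equal(t3$strand, "+")
  # CBE tasks: install C>T on sense, install G>A via the antisense C
  expect_equal(resolve_strand_tasks("C", "T")$class, "CBE")
  expect_equal(resolve_strand_tasks("G", "A")$strand, "-")
  # transversions are structurally not base-editable
  t4 <- resolve_strand_tasks("A", "C", mode = "revert")
  expect_equal(nrow(t4), 0L)
  expect_match(attr(t4, "reason"), "transversion")
  # minus-strand gene orientation complements the alleles first
  t5 <- resolve_strand_tasks("T", "C", mode = "install", orientation = "-")
  expect_equal(t5$class, "ABE")
  expect_equal(t5$strand, "+")
})

test_that("guides require the target base inside the editor window", {
  # A at protospacer position 6 with an NGG PAM: ABEmax candidate at 6
  proto <- paste0("CCCCC", "A", strrep("C", 14))
  s <- be_fixture(proto)
  res <- design_be_guides(s, 36L, "A", "G", mode = "install")
  abemax <- res[!is.na(res$editor) & res$editor == "ABEmax-SpCas9", ]
  expect_equal(nrow(abemax), 1L)
  expect_equal(abemax$edit_position, 6L)
  expect_equal(abemax$protospacer, proto)
  expect_equal(abemax$pam_seq, "TGG")
  expect_equal(abemax$n_bystanders, 0L)

  # the same A at position 9 is outside ABEmax's 5-7 window
  proto9 <- paste0(strrep("C", 8), "A", strrep("C", 11))
  s9 <- be_fixture(proto9)
  res9 <- design_be_guides(s9, 39L, "A", "G", mode = "install")
  expect_false(any(stats::na.omit(res9$editor) == "ABEmax-SpCas9"))
})

test_that("the 5'-T rule excludes BE3(R33A/K34A) and only it", {
  # target C at protospacer position 4 preceded by A: all NGG CBEs with a
  # window containing 4 hit, except the 5'-T-requiring variant
  protoA <- paste0("GTA", "C", strrep("T", 16))
  sA <- be_fixture(protoA)
  resA <- design_be_guides(sA, 34L, "C", "T", mode = "install")
  hitsA <- unique(resA$editor[resA$class == "CBE" & !is.na(resA$editor)])
  expect_true(all(
    c("BE3(R33A)", "BE3-hA3A(R128A)", "Target-AID") %in% hitsA
  ))
  expect_false("BE3(R33A/K34A)" %in% hitsA)

  # with a T at the 5' neighbour the constrained editor joins the set
  protoT <- paste0("GTT", "C", strrep("T", 16))
  sT <- be_fixture(protoT)
  resT <- design_be_guides(sT, 34L, "C", "T", mode = "install")
  hitsT <- unique(resT$editor[resT$class == "CBE" & !is.na(resT$editor)])
  expect_true("BE3(R33A/K34A)" %in% hitsT)
})

test_that("bystanders equal a brute-force window enumeration", {
  expect_equal(find_bystanders("CCCCACC" , 5, 7, 5, "A"), integer(0))
  expect_equal(
    find_bystanders(paste0("CCCC", "ACA", strrep("C", 13)), 5, 7, 5, "A"),
    7L
  )
  withr::with_seed(TEST_SEED, {
    for (i in 1:50) {
      proto <- random_dna(20)
      ws <- sample(1:15, 1L)
      we <- ws + sample(0:5, 1L)
      base <- sample(c("A", "C"), 1L)
      chars <- strsplit(proto, "")[[1L]]
      in_win <- which(chars == base)
      in_win <- in_win[in_win >= ws & in_win <= we]
      if (length(in_win) == 0L) next
      target <- sample(in_win, 1L)
      got <- find_bystanders(proto, ws, we, target, base)
      expect_equal(sort(got), sort(setdiff(in_win, target)))
    }
  })
})

test_that("every emitted candidate places its target inside the window", {
  ed <- builtin_editors()
  withr::with_seed(TEST_SEED, {
    for (i in 1:15) {
      s <- random_dna(160)
      pos <- sample(60:100, 1L)
      ref <- substr(s, pos, pos)
      alt <- switch(ref, A = "G", G = "A", C = "T", T = "C")
      res <- design_be_guides(s, pos, ref, alt, mode = "install")
      ok <- !is.na(res$editor)
      if (!any(ok)) next
      for (j in which(ok)) {
        row <- res[j, ]
        e <- ed[ed$name == row$editor, ]
        expect_gte(row$edit_position, e$window_start)
        expect_lte(row$edit_position, e$window_end)
        base <- if (e$class == "ABE") "A" else "C"
        expect_equal(
          substr(row$protospacer, row$edit_position, row$edit_position),
          base
        )
        expect_true(iupac_match(e$pam, row$pam_seq))
      }
    }
  })
})

test_that("ranking prefers fewer bystanders, then editors without caveats", {
  # A target with a bystander-free SpRY hit must still rank NGG editors
  # first when bystander counts tie
  proto <- paste0("CCCCC", "A", strrep("C", 14))
  s <- be_fixture(proto)
  res <- design_be_guides(s, 36L, "A", "G", mode = "install")
  eq <- res[res$n_bystanders == 0L & !is.na(res$editor), ]
  spry_idx <- which(eq$editor == "ABE-SpRY")
  nggmax_idx <- which(eq$editor == "ABEmax-SpCas9")
  if (length(spry_idx) > 0L && length(nggmax_idx) > 0L) {
    expect_lt(min(nggmax_idx), min(spry_idx))
  }
  expect_equal(rank_editors(res[0, ]), res[0, ])
})

test_that("mirror symmetry: complementary change on the reverse complement", {
  # designing T>C on the reverse-complemented sequence yields the same
  # guides as A>G on the original, with strands swapped
  withr::with_seed(TEST_SEED, {
    s <- random_dna(140)
    pos <- 70L
    ref <- substr(s, pos, pos)
    alt <- switch(ref, A = "G", G = "A", C = "T", T = "C")
    res_fwd <- design_be_guides(s, pos, ref, alt, mode = "install")
    s_rc <- oracle_revcomp(s)
    pos_rc <- nchar(s) - pos + 1L
    res_rc <- design_be_guides(s_rc, pos_rc, oracle_revcomp(ref),
      oracle_revcomp(alt), mode = "install")
    ok_f <- res_fwd[!is.na(res_fwd$editor), ]
    ok_r <- res_rc[!is.na(res_rc$editor), ]
    key_f <- sort(paste(ok_f$editor, ok_f$protospacer, ok_f$edit_position))
    key_r <- sort(paste(ok_r$editor, ok_r$protospacer, ok_r$edit_position))
    expect_equal(key_f, key_r)
    expect_equal(sum(ok_f$strand == "+"), sum(ok_r$strand == "-"))
    expect_equal(sum(ok_f$strand == "-"), sum(ok_r$strand == "+"))
  })
})

test_that("a lone SpRY hit is returned with its efficiency note", {
  # NAA PAM: matched by NRN (SpRY) but by no other ABE motif
  proto <- paste0("CCCC", "A", strrep("C", 15))
  s <- be_fixture(proto, pam = "CAA")
  res <- design_be_guides(s, 35L, "A", "G", mode = "install")
  ok <- res[!is.na(res$editor), ]
  expect_true(all(ok$editor == "ABE-SpRY"))
  expect_gte(nrow(ok), 1L)
  expect_match(ok$note[1], "lower overall efficiency")
})
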