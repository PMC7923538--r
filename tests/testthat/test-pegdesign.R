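# PE2 design: PAM scanning, candidate geometry, scoring.

test_that("scan finds a single planted plus-strand PAM", {
  s <- make_sequence(240,
    plant = data.frame(strand = "+", pos = 121, seq = "TGG"),
    seed = TEST_SEED
  )
  edited <- apply_edit(s, edit_substitution(131, substr(s, 131, 131), "G"))
  hits <- scan_pams(edited)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$pam_seq, "TGG")
  oracle <- oracle_scan_pams(edited)
  expect_equal(nrow(oracle), 1L)
  expect_equal(hits$pam_start0, oracle$pam_start0)
})

test_that("a sequence without G or C yields no PAM hits", {
  s <- paste(rep(c("A", "T"), 120), collapse = "")
  edited <- apply_edit(s, edit_substitution(120, substr(s, 120, 120), "A"))
  expect_equal(nrow(scan_pams(edited)), 0L)
})

test_that("a planted antisense PAM is reported on the minus strand", {
  # CCA on the sense strand is TGG on the antisense strand
  s <- make_sequence(240,
    plant = data.frame(strand = "-", pos = 100, seq = "TGG"),
    seed = TEST_SEED
  )
  edited <- apply_edit(s, edit_substitution(95, substr(s, 95, 95), "G"))
  hits <- scan_pams(edited)
  expect_equal(hits$strand, "-")
  expect_equal(hits$pam_seq, "TGG")
  # nick bond in the antisense frame is 3 nt 5' of the PAM
  expect_equal(hits$nick0, hits$pam_start0 - 3L)
  expect_equal(substr(s, 100, 102), "CCA")
})

test_that("scan_pams equals the brute-force oracle on random fixtures", {
  withr::with_seed(TEST_SEED, {
    for (i in 1:30) {
      s <- random_dna(300)
      pos <- sample(120:180, 1L)
      e <- edit_substitution(pos, substr(s, pos, pos),
        sample(setdiff(c("A", "C", "G", "T"), substr(s, pos, pos)), 1L))
      edited <- apply_edit(s, e)
      got <- scan_pams(edited)
      want <- oracle_scan_pams(edited)
      got_key <- sort(paste(got$strand, got$pam_start0))
      want_key <- if (is.null(want)) character(0) else
        sort(paste(want$strand, want$pam_start0))
      expect_equal(got_key, want_key)
    }
  })
})

test_that("scan rejects sequences too short to hold a protospacer and PAM", {
  s <- "ACGTACGTACGTACGTACGT"  # 20 nt
  edited <- apply_edit(s, edit_substitution(10, substr(s, 10, 10), "C"))
  expect_error(scan_pams(edited), "insufficient context")
})

test_that("edit position is nick-relative with position 1 just 3' of the nick", {
  s <- ca_fixture()
  # protospacer position 18 is the first base 3' of the nick; nick-relative
  # position 4 is the PAM's first (N) base, edited here without breaking NGG
  cases <- list(
    list(k = 1L, want = 1L, alt = "G"),
    list(k = 4L, want = 4L, alt = "A"),
    list(k = 10L, want = 10L, alt = "G")
  )
  for (case in cases) {
    edited <- apply_edit(s, ca_edit_at(s, case$k, alt = case$alt))
    hits <- scan_pams(edited)
    expect_equal(nrow(hits), 1L)
    expect_equal(compute_edit_position(hits[1, ], edited), case$want)
  }
})

test_that("edits 5' of the nick disqualify the candidate", {
  s <- ca_fixture()
  pos <- 129L  # 0-based 128, 5' of the nick bond at 0-based 130
  edited <- apply_edit(s, edit_substitution(pos, substr(s, pos, pos), "G"))
  hits <- scan_pams(edited)
  expect_equal(nrow(hits), 1L)
  expect_true(is.na(compute_edit_position(hits[1, ], edited)))
  expect_null(build_pegrna(hits[1, ], edited))
})

test_that("candidate geometry: defaults, RTT coverage bound, PBS cap", {
  s <- ca_fixture()
  edited <- apply_edit(s, ca_edit_at(s, 1L))
  hits <- scan_pams(edited)
  cand <- build_pegrna(hits[1, ], edited)
  expect_equal(cand$pbs_len, 13L)
  expect_equal(cand$rtt_len, 13L)
  expect_equal(nchar(cand$pbs), 13L)
  expect_equal(nchar(cand$rtt), 13L)
  expect_equal(cand$extension_3p, paste0(cand$rtt, cand$pbs))
  expect_error(build_pegrna(hits[1, ], edited, pbs_len = 18L), "pbs_len")

  # edit at nick-relative position 14 is not covered by a 13 nt RTT
  edited14 <- apply_edit(s, ca_edit_at(s, 14L))
  hits14 <- scan_pams(edited14)
  expect_null(build_pegrna(hits14[1, ], edited14, rtt_len = 13L))
  expect_false(is.null(build_pegrna(hits14[1, ], edited14, rtt_len = 14L)))
})

test_that("extension reconstruction holds against a slice-and-revcomp oracle", {
  withr::with_seed(TEST_SEED, {
    n_checked <- 0L
    for (i in 1:60) {
      s <- random_dna(300)
      pos <- sample(130:170, 1L)
      kind <- sample(c("substitution", "insertion", "deletion"), 1L)
      e <- switch(kind,
        substitution = edit_substitution(pos, substr(s, pos, pos),
          sample(setdiff(c("A", "C", "G", "T"), substr(s, pos, pos)), 1L)),
        insertion = edit_insertion(pos, random_dna(sample(1:5, 1L))),
        deletion = edit_deletion(pos, substr(s, pos, pos + sample(0:4, 1L)))
      )
      edited <- apply_edit(s, e)
      hits <- scan_pams(edited)
      for (h in seq_len(nrow(hits))) {
        cand <- build_pegrna(hits[h, ], edited)
        if (is.null(cand)) next
        frame <- if (cand$strand == "+") edited$sequence else
          oracle_revcomp(edited$sequence)
        span <- substr(frame, cand$nick0 - cand$pbs_len + 1L,
          cand$nick0 + cand$rtt_len)
        expect_equal(cand$extension_3p, oracle_revcomp(span))
        # the full alt allele lies inside the RTT window
        expect_gte(cand$edit_position, 1L)
        expect_lte(cand$edit_position + nchar(edited$edit$alt) - 1L,
          cand$rtt_len)
        n_checked <- n_checked + 1L
      }
    }
    expect_gt(n_checked, 50L)
  })
})

test_that("penalty components are independent and sum to the score", {
  s_base <- ca_fixture()                       # extension starts with G
  s_c <- ca_fixture(overwrite = c("143" = "G")) # extension starts with C
  s_t <- ca_fixture(overwrite = c(
    "137" = "A", "138" = "A", "139" = "A", "140" = "A", "141" = "A"
  ))                                           # AAAAA -> TTTTT in extension
  design1 <- function(s, k = 1L, rtt = 13L) {
    r <- design_pegrnas(s, ca_edit_at(s, k), rtt_len = rtt, show_all = TRUE)
    r[1, ]
  }
  base <- design1(s_base)
  expect_equal(base$score, -1L)
  expect_equal(base$penalty_first_base_c, 0L)

  first_c <- design1(s_c)
  expect_equal(substr(first_c$extension_3p, 1, 1), "C")
  expect_equal(first_c$score - base$score, -28L)
  expect_equal(first_c$score, -29L)

  poly_t <- design1(s_t)
  expect_true(grepl("TTTTT", poly_t$extension_3p))
  expect_equal(poly_t$score - base$score, -50L)

  pos2 <- design1(s_base, k = 2L)
  expect_equal(pos2$score - base$score, -1L)

  pos3 <- design1(s_base, k = 3L)
  expect_equal(pos3$score, -3L)

  # homology < 5 triggers -6: same edit, RTT one nt shorter
  hom4 <- design1(s_base, k = 10L, rtt = 14L)
  hom5 <- design1(s_base, k = 10L, rtt = 15L)
  expect_equal(hom4$homology_after_edit, 4L)
  expect_equal(hom5$homology_after_edit, 5L)
  expect_equal(hom4$score - hom5$score, -6L)

  for (cand in list(base, first_c, poly_t, pos2, pos3, hom4, hom5)) {
    expect_equal(
      cand$score,
      cand$penalty_first_base_c + cand$penalty_poly_t +
        cand$penalty_short_homology + cand$penalty_edit_distance
    )
    expect_lte(cand$score, -1L)
  }
})

test_that("a 4-T run is tolerated but 5 consecutive T are penalized", {
  cand4 <- tibble::tibble(
    extension_3p = "GTTTTAGTTTTAGTTTTA", edit_position = 1L,
    homology_after_edit = 10L
  )
  cand5 <- tibble::tibble(
    extension_3p = "GTTTTTAGAGCAGAGCAA", edit_position = 1L,
    homology_after_edit = 10L
  )
  expect_equal(score_pegrna(cand4)$penalty_poly_t, 0L)
  expect_equal(score_pegrna(cand5)$penalty_poly_t, -50L)
})
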