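make_protein <- function(id = "syn", n = 140, seed = 1) {
  set.seed(seed)
  peptide(id, paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = ""))
}

test_that("window_fragments counts and spans follow the sliding rule", {
  p <- make_protein(n = 140)
  fs <- window_fragments(p, width = 20, step = 1)
  expect_equal(nrow(fs$fragments), 121L)  # 140 - 20 + 1
  expect_equal(fs$fragments$start[1], 1L)
  expect_equal(fs$fragments$end[121], 140L)
  fs10 <- window_fragments(p, width = 20, step = 10)
  expect_equal(nrow(fs10$fragments), 13L)  # floor(120/10) + 1
  p20 <- make_protein(n = 20)
  expect_equal(nrow(window_fragments(p20, 20, 5)$fragments), 1L)
  expect_error(window_fragments(make_protein(n = 19), 20), "shorter")
  expect_error(window_fragments(p, width = 13), "threadable minimum")
  expect_error(window_fragments(p, width = 20, step = 0), "step")
  # Fragment sequences are exact parent subsequences.
  expect_true(all(fs$fragments$seq ==
                    substring(p$seq, fs$fragments$start, fs$fragments$end)))
})

test_that("explicit_fragments names repeats R1..Rn and validates bounds", {
  p <- make_protein(n = 100)
  b <- rbind(c(1, 20), c(25, 44), c(50, 69), c(72, 91), c(92, 100))
  fs <- explicit_fragments(p, b)
  expect_equal(fs$fragments$name, paste0("R", 1:5))
  expect_equal(fs$scheme, "explicit")
  expect_true(all(fs$fragments$seq ==
                    substring(p$seq, fs$fragments$start, fs$fragments$end)))
  expect_error(explicit_fragments(p, rbind(c(1, 20), c(15, 40))),
               "non-overlapping")
  expect_error(explicit_fragments(p, rbind(c(1, 20), c(30, 25))),
               "end < start")
  expect_error(explicit_fragments(p, rbind(c(90, 110))), "outside")
})

test_that("scan_pair fills every cell deterministically", {
  tpl <- make_template()
  pot <- make_potential("hydrophobic", seed = 3)
  pa <- make_protein("pa", 56, seed = 2)
  pb <- make_protein("pb", 60, seed = 3)
  fa <- window_fragments(pa, 20, 18)           # starts 1, 19, 37 -> 3 rows
  fb <- explicit_fragments(pb, rbind(c(1, 20), c(25, 44)))
  r <- scan_pair(fa, fb, tpl, pot, threshold = -2, n_models = 2, seed = 5)
  expect_equal(dim(r$scores), c(3L, 2L))
  expect_false(anyNA(r$scores))
  expect_equal(nrow(r$best), 6L)
  expect_true(all(diff(r$best$ndope) >= 0))
  expect_equal(r$best$ndope[1], min(r$scores))
  expect_identical(r$calls, matrix(as.integer(r$scores <= -2), 3, 2,
                                   dimnames = dimnames(r$scores)))
  r2 <- scan_pair(fa, fb, tpl, pot, threshold = -2, n_models = 2, seed = 5)
  expect_identical(r$scores, r2$scores)
  r3 <- scan_pair(fa, fb, tpl, pot, threshold = -2, n_models = 2, seed = 6)
  expect_false(identical(r$scores, r3$scores))
})

test_that("identical row fragments give identical matrix rows at sigma 0", {
  tpl <- make_template()
  pot <- make_potential("hydrophobic", seed = 3)
  rep_seq <- paste(rep("QNAVLIFMWYQNAVLIFMWY", 2), collapse = "")
  pa <- peptide("rep", rep_seq)                 # period 20
  fa <- window_fragments(pa, 20, 20)            # two identical fragments
  expect_equal(fa$fragments$seq[1], fa$fragments$seq[2])
  fb <- explicit_fragments(make_protein("pb", 40, 4), rbind(c(1, 20)))
  r <- scan_pair(fa, fb, tpl, pot, threshold = 0, n_models = 1, seed = 1,
                 sigma = 0)
  expect_equal(r$scores[1, ], r$scores[2, ])
})

test_that("scan matrix transposes under swapping the two proteins", {
  tpl <- make_template()
  pot <- make_potential("hydrophobic", seed = 3)
  fa <- window_fragments(make_protein("pa", 40, 5), 20, 20)
  fb <- window_fragments(make_protein("pb", 40, 6), 20, 10)
  rab <- scan_pair(fa, fb, tpl, pot, threshold = 0, n_models = 1, seed = 1,
                   sigma = 0)
  rba <- scan_pair(fb, fa, tpl, pot, threshold = 0, n_models = 1, seed = 1,
                   sigma = 0)
  expect_equal(unname(rab$scores), unname(t(rba$scores)), tolerance = 1e-9)
})

test_that("best_regions merges runs of consecutive called windows", {
  p <- make_protein("pa", 80, 7)
  fa <- window_fragments(p, 20, 1)
  fb <- explicit_fragments(make_protein("pb", 30, 8), rbind(c(1, 20)))
  nr <- nrow(fa$fragments)
  scores <- matrix(0, nr, 1, dimnames = list(fa$fragments$name, "R1"))
  scores[c(30, 31, 32, 50), 1] <- -10
  calls <- matrix(as.integer(scores <= -5), nr, 1,
                  dimnames = dimnames(scores))
  ord <- order(scores)
  cells <- arrayInd(ord, dim(scores))
  fake <- structure(
    list(rows = fa, cols = fb, scores = scores, calls = calls,
         best = data.frame(
           row = fa$fragments$name[cells[, 1]], col = "R1",
           row_span = sprintf("%d-%d", fa$fragments$start[cells[, 1]],
                              fa$fragments$end[cells[, 1]]),
           col_span = "1-20", ndope = scores[ord]
         ),
         threshold = -5, n_models = 1, seed = 1, sigma = 0),
    class = "scan_result"
  )
  reg <- best_regions(fake, k = 4)
  expect_equal(nrow(reg$top), 4L)
  # Windows starting 30, 31, 32 (width 20) merge into 30..51; 50 stands
  # alone as 50..69.
  expect_equal(reg$regions_a$start, c(30L, 50L))
  expect_equal(reg$regions_a$end, c(51L, 69L))
  expect_warning(big <- best_regions(fake, k = 1000), "truncat")
  expect_equal(nrow(big$top), nr)
  # No calls -> empty merged regions, top-k still reported.
  fake$calls[] <- 0L
  reg0 <- best_regions(fake, k = 3)
  expect_equal(nrow(reg0$regions_a), 0L)
  expect_equal(nrow(reg0$top), 3L)
})

test_that("potential deepened on a fragment-specific residue is local", {
  tpl <- make_template()
  pot <- make_potential("hydrophobic", seed = 3)
  # Deepen the hetero pair (W, C): W occurs only in row fragment 1, C only
  # in the column protein, so only cell (1, 1) can contain a (W, C) contact.
  deeper <- pot
  iw <- aa_index("W")
  ic <- aa_index("C")
  deeper$energies[iw, ic, ] <- deeper$energies[iw, ic, ] - 1
  deeper$energies[ic, iw, ] <- deeper$energies[ic, iw, ] - 1
  pa <- peptide("pa", paste0(strrep("WA", 10), strrep("LA", 10)))
  fa <- window_fragments(pa, 20, 20)  # fragment 1 has W, fragment 2 none
  fb <- explicit_fragments(peptide("pb", strrep("CQ", 10)), rbind(c(1, 20)))
  r0 <- scan_pair(fa, fb, tpl, pot, threshold = 0, n_models = 1, seed = 1,
                  sigma = 0)
  r1 <- scan_pair(fa, fb, tpl, deeper, threshold = 0, n_models = 1, seed = 1,
                  sigma = 0)
  expect_lt(r1$scores[1, 1], r0$scores[1, 1])
  expect_equal(r1$scores[2, 1], r0$scores[2, 1])
})
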