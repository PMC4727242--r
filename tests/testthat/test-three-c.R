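# 3C: digestion, restriction-efficiency QC, BAC normalization, relative
# profiles, peak calling.

test_that("single-site digestion cuts after the first C of CCATGG", {
  fm <- digest_sequence("AAACCATGGTTT")
  expect_equal(fm$fragments$end - fm$fragments$start, c(4, 8))
  expect_equal(fm$fragments$start, c(0, 4))
  expect_equal(fm$fragments$midpoint, c(2, 8))
})

test_that("motif-free and ambiguous sequences produce no cuts", {
  fm <- digest_sequence("ACGTACGTACGT")
  expect_identical(nrow(fm$fragments), 1L)
  expect_equal(fm$fragments$end, 12)
  # N inside a candidate site is a strict mismatch
  fmN <- digest_sequence("AAACCATNGTTT")
  expect_identical(nrow(fmN$fragments), 1L)
})

test_that("digestion matches a naive scan and tiles the sequence exactly", {
  set.seed(14)
  for (rep in 1:5) {
    len <- sample(2000:10000, 1)
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    # guarantee at least a few sites
    s <- paste0(s, "CCATGG", substr(s, 1, 500), "CCATGG")
    fm <- digest_sequence(s)
    cuts <- naive_cut_positions(s)
    expect_equal(fm$fragments$start, c(0L, cuts))
    # fragment count = site count + 1; concatenation reconstructs input
    expect_identical(nrow(fm$fragments), length(cuts) + 1L)
    pieces <- substring(s, fm$fragments$start + 1, fm$fragments$end)
    expect_identical(paste(pieces, collapse = ""), s)
  }
  # doubling a sequence at least doubles its site count (the junction can
  # add at most a handful of new spanning sites)
  base <- make_locus_sequence(5000, 4, seed = 3)
  k <- nrow(digest_sequence(base)$fragments) - 1L
  k2 <- nrow(digest_sequence(paste0(base, base))$fragments) - 1L
  expect_gte(k2, 2L * k)
  expect_lte(k2, 2L * k + 5L)
})

test_that("restriction efficiency arithmetic matches the reported band", {
  expect_equal(restriction_efficiency(c(s1 = 0), 10), c(s1 = 1))
  expect_equal(restriction_efficiency(c(s1 = 10), 10), c(s1 = 0))
  eff <- restriction_efficiency(c(s1 = 0.35 * 8), 8)
  expect_equal(unname(eff), 0.65)
  expect_true(eff >= 0.6 && eff <= 0.7)
  expect_warning(e2 <- restriction_efficiency(c(s1 = 12), 10), "clipped")
  expect_equal(unname(e2), 0)
})

test_that("BAC normalization cancels arbitrary primer bias exactly when noise-free", {
  fm <- digest_sequence(make_locus_sequence(20000, 13, seed = 42))
  ids <- fm$fragments$id
  set.seed(15)
  bias <- stats::setNames(runif(length(ids), 0.2, 5), ids)
  sc_plain <- make_3c_fixture(ct_sd = 0, seed = 1)
  sc_bias <- three_c_scenario(fm, sc_plain$anchor, background_alpha = 1,
                              primer_bias = bias,
                              noise = qpcr_noise_model(ct_sd = 0), seed = 1)
  p_plain <- profile_3c_scenario(sc_plain)
  p_bias <- profile_3c_scenario(sc_bias)
  expect_equal(p_bias$profile$relative, p_plain$profile$relative,
               tolerance = 1e-6)
})

test_that("sample identical to the BAC template gives a flat normalized profile", {
  sc <- make_3c_fixture(ct_sd = 0)
  tabs <- make_3c_tables(sc)
  nz <- normalize_junctions(tabs$bac_plate, tabs$bac_plate, tabs$dilutions)
  expect_equal(nz$normalized, rep(1, nrow(nz)), tolerance = 1e-6)
})

test_that("relative profile references the first 3' fragment and is scale-invariant", {
  sc <- make_3c_fixture(ct_sd = 0)
  tabs <- make_3c_tables(sc)
  nz <- normalize_junctions(tabs$sample_plate, tabs$bac_plate,
                            tabs$dilutions)
  prof <- relative_profile(nz, sc$fragment_map, sc$anchor)
  ref_row <- prof$profile[prof$profile$fragment == prof$reference, ]
  expect_equal(ref_row$relative, 1, tolerance = 1e-12)
  # reference is the closest 3' fragment
  three_prime <- prof$profile[prof$profile$distance > 0, ]
  expect_identical(prof$reference,
                   three_prime$fragment[which.min(three_prime$distance)])
  # scaling all normalized frequencies changes nothing
  nz2 <- nz; nz2$normalized <- nz2$normalized * 137
  prof2 <- relative_profile(nz2, sc$fragment_map, sc$anchor)
  expect_equal(prof2$profile$relative, prof$profile$relative,
               tolerance = 1e-12)
  # uniform frequencies: all relative values are 1
  nz3 <- nz; nz3$normalized <- 1
  prof3 <- relative_profile(nz3, sc$fragment_map, sc$anchor)
  expect_true(all(prof3$profile$relative == 1))
  # anchor at the 3'-most fragment has no reference
  last <- sc$fragment_map$fragments$id[nrow(sc$fragment_map$fragments)]
  expect_error(relative_profile(nz[nz$fragment != last, ],
                                sc$fragment_map, last),
               "3'-most")
})

test_that("pure decay is monotone non-increasing with distance on each side", {
  prof <- profile_3c_scenario(make_3c_fixture(ct_sd = 0))$profile
  up <- prof[prof$distance < 0, ]     # 5' side, farthest first
  down <- prof[prof$distance > 0, ]
  expect_true(all(diff(down$relative) <= 1e-9))
  expect_true(all(diff(up$relative) >= -1e-9))
})

test_that("peak calling recovers loop partners and stays silent without loops", {
  sc0 <- make_3c_fixture(ct_sd = 0)
  fr <- sc0$fragment_map$fragments
  anchor_i <- match(sc0$anchor, fr$id)
  partner <- fr$id[anchor_i - 4L]
  loops <- data.frame(anchor = sc0$anchor, partner = partner, fold = 5)
  prof <- profile_3c_scenario(make_3c_fixture(ct_sd = 0, loops = loops))
  peaks <- detect_interaction_peaks(prof)
  expect_identical(peaks$fragment, partner)
  # noise-free, no loop: nothing called
  expect_identical(nrow(detect_interaction_peaks(
    profile_3c_scenario(sc0))), 0L)
  # two disjoint loops give two called regions
  partner2 <- fr$id[anchor_i + 5L]
  loops2 <- rbind(loops, data.frame(anchor = sc0$anchor,
                                    partner = partner2, fold = 5))
  prof2 <- profile_3c_scenario(make_3c_fixture(ct_sd = 0, loops = loops2))
  peaks2 <- detect_interaction_peaks(prof2)
  expect_identical(sort(peaks2$fragment), sort(c(partner, partner2)))
  expect_identical(length(unique(peaks2$region)), 2L)
})

test_that("noisy no-loop profiles rarely produce false-positive calls", {
  n_called <- sum(vapply(1:60, function(s) {
    prof <- profile_3c_scenario(make_3c_fixture(ct_sd = 0.2, seed = s))
    nrow(detect_interaction_peaks(prof)) > 0
  }, logical(1)))
  expect_lte(n_called / 60, 0.05)
})

test_that("3C tables are reproducible under a fixed seed", {
  a <- make_3c_tables(make_3c_fixture(ct_sd = 0.3, seed = 9))
  b <- make_3c_tables(make_3c_fixture(ct_sd = 0.3, seed = 9))
  expect_identical(a$sample_plate, b$sample_plate)
  expect_identical(a$bac_plate, b$bac_plate)
})

test_that("scenario validation rejects missing fragments and weak loops", {
  fm <- digest_sequence(make_locus_sequence(8000, 5, seed = 2))
  expect_error(three_c_scenario(fm, "nope"), "anchor")
  expect_error(three_c_scenario(
    fm, fm$fragments$id[2],
    loops = data.frame(anchor = fm$fragments$id[2], partner = "ghost",
                       fold = 5)), "not in map")
  expect_error(three_c_scenario(
    fm, fm$fragments$id[2],
    loops = data.frame(anchor = fm$fragments$id[2],
                       partner = fm$fragments$id[4], fold = 1)),
    "> 1")
})
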