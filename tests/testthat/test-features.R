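# Feature encoders: compositions, entropies, physicochemical descriptors,
# and the assembled feature vector, checked against independent oracles.

test_that("AAC counts residues over the full window length, X inert", {
  a <- aac_vector("GGGGGRGGGGG")
  expect_equal(a[["AAC_G"]], 10 / 11)
  expect_equal(a[["AAC_R"]], 1 / 11)
  expect_equal(sum(a), 1)

  ap <- aac_vector("XXXXXRGGGGX")
  expect_equal(ap[["AAC_R"]], 1 / 11)
  expect_equal(ap[["AAC_G"]], 4 / 11)
  expect_equal(sum(ap), 5 / 11)  # non-pad count / l
})

test_that("DPC counts adjacent pairs over l, skipping pad pairs", {
  d <- dpc_vector("GGGGGRGGGGG")
  expect_equal(d[["DPC_GG"]], 8 / 11)
  expect_equal(d[["DPC_GR"]], 1 / 11)
  expect_equal(d[["DPC_RG"]], 1 / 11)
  expect_equal(sum(d), 10 / 11)  # (l - 1) / l for a pad-free window

  dp <- dpc_vector("XXXXXRGGGGX")
  expect_equal(dp[["DPC_RG"]], 1 / 11)
  expect_equal(dp[["DPC_GG"]], 3 / 11)
  expect_equal(sum(dp), 4 / 11)

  # optional conventional denominator
  expect_equal(sum(dpc_vector("GGGGGRGGGGG", denominator = "l-1")), 1)
})

test_that("entropy block reproduces the analytic values", {
  # degenerate distribution: all four entropies vanish
  hom <- entropy_block(c(1, rep(0, 19)))
  expect_equal(hom$SE, 0)
  expect_equal(hom$HE, 0)
  expect_equal(hom$RE, 0)
  expect_equal(hom$AE, 0)

  # uniform profile
  u <- entropy_block(rep(1 / 20, 20), alpha = 2)
  expect_equal(u$SE, log2(20))
  expect_equal(u$relative_SE, 0)
  expect_equal(u$RE, log2(20))
  expect_equal(u$HE, 1.9)   # (2^-1 - 1)^-1 (20 * (1/20)^2 - 1)
  expect_equal(u$AE, 19)    # (2^1 - 1)^-1 ((20 * sqrt(1/20))^2 - 1)
  # RE at uniform equals log2(20) for any valid alpha
  for (al in c(0.5, 3, 7.7)) {
    expect_equal(entropy_block(rep(1 / 20, 20), alpha = al)$RE, log2(20))
  }

  # two-letter profile evaluated straight from the definition
  p <- c(10 / 11, 1 / 11)
  expect_equal(entropy_block(c(p, rep(0, 18)))$SE, -sum(p * log2(p)))
  expect_equal(entropy_block(c(p, rep(0, 18)))$SE, 0.43949698692,
               tolerance = 1e-10)

  expect_error(entropy_block(rep(1 / 20, 20), alpha = 1), "alpha")
  expect_error(entropy_block(rep(1 / 20, 20), alpha = -2), "alpha")
})

test_that("RE, HE and AE are continuous in alpha at the Shannon limit", {
  withr::with_seed(5, {
    for (i in 1:20) {
      w <- random_windows(1, pad_frac = 0, seed = i)
      p <- composition_profile(w)$probabilities
      se <- entropy_block(p, alpha = 2)$SE
      for (al in c(1 - 1e-4, 1 + 1e-4)) {
        eb <- entropy_block(p, alpha = al)
        expect_lt(abs(eb$RE - se), 1e-3)
        expect_lt(abs(eb$HE - se), 1e-3)
        expect_lt(abs(eb$AE - se), 1e-3)
      }
    }
  })
})

test_that("composition-only features are permutation invariant, DPC is not", {
  w <- "ACDEFRGHIKL"
  perm <- "LKIHGRFEDCA"  # same multiset, center still R
  expect_equal(itb_features(w), itb_features(perm))
  expect_equal(aac_vector(w), aac_vector(perm))
  expect_false(isTRUE(all.equal(dpc_vector(w), dpc_vector(perm))))
  # homopolymer window: all four entropies zero
  expect_equal(unname(itb_features("AAAAAAAAAAA")), rep(0, 4))
})

test_that("extinction coefficient follows the three-term assay formula", {
  expect_equal(extinction_coefficient("GGGGGRGGGGG", oxidized = FALSE), 0)
  expect_equal(extinction_coefficient("GGGGGRGGGGG", oxidized = TRUE), 0)
  # 1 W, 1 Y, 2 C, oxidized: 5500 + 1490 + 125
  expect_equal(extinction_coefficient("WYCCGRGGGGG", oxidized = TRUE), 7115)
  expect_equal(extinction_coefficient("WYCCGRGGGGG", oxidized = FALSE), 6990)
  # reduced <= oxidized always
  for (w in random_windows(50, seed = 9)) {
    expect_lte(extinction_coefficient(w, FALSE),
               extinction_coefficient(w, TRUE))
  }
})

test_that("instability index matches the weighted-dipeptide definition", {
  # stubbed table where every weight is w: value = (10 / L) * (L - 1) * w
  stub <- matrix(2.5, 20, 20, dimnames = list(amino_acids(), amino_acids()))
  expect_equal(as.numeric(instability_index("GGGGGRGGGGG", diwv = stub)),
               10 / 11 * 10 * 2.5)
  # bundled-table value against the independent lookup-and-sum oracle
  for (w in random_windows(25, seed = 4)) {
    expect_equal(as.numeric(instability_index(w)),
                 unname(oracle_pp(w)[["PP_II"]]), tolerance = 1e-9)
  }
  # stability flag threshold at 40: "AARAA" has 4 pairs, value = 2 * sum
  stub40 <- matrix(5, 20, 20, dimnames = list(amino_acids(), amino_acids()))
  v <- instability_index("AARAA", diwv = stub40)  # exactly 40
  expect_equal(as.numeric(v), 40)
  expect_false(attr(v, "unstable"))
  stub40h <- matrix(5.00001, 20, 20,
                    dimnames = list(amino_acids(), amino_acids()))
  expect_true(attr(instability_index("AARAA", diwv = stub40h), "unstable"))
  expect_error(instability_index("XXXXXRXXXXX"), "at least 2")
})

test_that("GRAVY is the mean Kyte-Doolittle hydropathy of non-pad residues", {
  expect_equal(gravy("AAAAAAAAAAA"), 1.8)
  expect_equal(gravy("GGGGGRGGGGG"), (10 * -0.4 + -4.5) / 11)
  # appending a residue at the current mean leaves the mean unchanged
  expect_equal(gravy("AAAAAAAAAAA"), gravy(paste0("AAAAAAAAAAA", "A")))
})

test_that("physicochemical block has the documented layout and values", {
  v <- pp_features("GGGGGRGGGGG")
  expect_length(v, 10)
  expect_named(v, paste0("PP_", c("pI", "MW", "AROM", "II", "GRAVY",
                                  "EX_RED", "EX_OX", "HELIX", "TURN", "SHEET")))
  expect_equal(v[["PP_AROM"]], 0)
  expect_equal(pp_features("FGGGGRGGGGG")[["PP_AROM"]], 1 / 11)
  tabs <- constant_tables()
  expect_equal(v[["PP_MW"]],
               10 * tabs$mass[["G"]] + tabs$mass[["R"]] + tabs$mass_water)
  expect_equal(v[["PP_TURN"]], 10 / 11)
  expect_error(pp_features("XXXXXRXXXXX"), "at least 2")
})

test_that("encode_window assembles 434 features in the stable layout", {
  v <- encode_window("GGGGGRGGGGG")
  expect_length(v, 434)
  nms <- names(v)
  expect_equal(nms[1], "AAC_A")
  expect_equal(nms[21], "DPC_AA")
  expect_equal(nms[421], "ITB_SE")
  expect_equal(nms[425], "PP_pI")
  expect_identical(nms, feature_names())
  # determinism on identical strings
  expect_identical(encode_window("ACDEFRGHIKL"), encode_window("ACDEFRGHIKL"))
  # block subsetting widths
  expect_length(encode_window("ACDEFRGHIKL", blocks = "AAC"), 20)
  expect_length(encode_window("ACDEFRGHIKL", blocks = c("AAC", "DPC")), 420)
})

test_that("every feature matches the equation oracle on random windows", {
  wins <- random_windows(200, seed = 77)
  for (w in wins) {
    expect_equal(encode_window(w), oracle_encode(w), tolerance = 1e-9)
  }
})

test_that("encoded vectors are finite for all windows, including padded", {
  wins <- c(random_windows(60, pad_frac = 0.6, seed = 12),
            "XXXXARAXXXX", "XXXXXRAXXXX")
  for (w in wins) {
    expect_true(all(is.finite(encode_window(w))))
  }
})

test_that("encode_windows returns a tidy feature table with extensions", {
  win <- generate_windows(synthetic_config(n_positive = 4, n_negative = 4,
                                           seed = 6))
  f <- encode_windows(win)
  expect_equal(dim(f), c(8, 436))
  expect_equal(names(f)[1:2], c("window_id", "label"))
  fx <- encode_windows(win, itb_extended = TRUE)
  expect_equal(ncol(fx), 441)
  expect_true(all(c("ITB_REL_SE", "ITB_IG") %in% names(fx)))
  # information gain identity on the extended block
  p <- composition_profile(win$residues[1])$probabilities
  eb <- entropy_block(p)
  expect_equal(fx$ITB_IG[1], eb$SE - eb$relative_SE)
})
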