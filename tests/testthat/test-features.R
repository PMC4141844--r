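# The 2,924-feature encoder: registry arithmetic, worked examples per
# block, and brute-force formula oracles on random sequences.

test_that("registry arithmetic matches the fixed layout", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 2924L)
  sizes <- table(reg$block)
  expect_equal(unname(sizes[c("aaindex_seq", "aaindex_exposed",
                              "aaindex_buried")]), rep(544L, 3),
               ignore_attr = TRUE)
  expect_equal(sum(sizes[c("dipeptide", "nmbroto", "moran", "geary",
                           "ctd_c", "ctd_t", "ctd_d", "qso", "apaac",
                           "taap")]), 1060L)
  expect_equal(unname(sizes["dipeptide"]), 400L, ignore_attr = TRUE)
  expect_equal(unname(sizes["qso"]), 160L, ignore_attr = TRUE)
  expect_equal(unname(sizes["apaac"]), 80L, ignore_attr = TRUE)
  # removing the AAindex blocks leaves the 1,292 remainder
  expect_equal(2924L - 3L * 544L, 1292L)
  expect_equal(sum(!reg$block %in% c("aaindex_seq", "aaindex_exposed",
                                     "aaindex_buried")), 1292L)
  expect_false(anyDuplicated(reg$feature_id) > 0)
})

test_that("class partitions cover the 20 amino acids exactly once", {
  for (p in ctd_partitions()) {
    expect_equal(sort(names(p)), sort(AA_ALPHABET))
    expect_true(all(p %in% 1:3))
  }
  expect_equal(sort(names(five_class_alphabet())), sort(AA_ALPHABET))
  expect_equal(sort(names(three_class_alphabet())), sort(AA_ALPHABET))
  expect_equal(sort(names(functional_group_alphabet())), sort(AA_ALPHABET))
  expect_equal(length(unique(functional_group_alphabet())), 10L)
})

test_that("composition blocks count correctly and normalize", {
  v <- encode_compositions("ACDC")
  expect_equal(v[["comp_A"]], 0.25)
  expect_equal(v[["comp_C"]], 0.5)
  expect_equal(v[["comp_D"]], 0.25)
  expect_equal(sum(v[startsWith(names(v), "comp_")]), 1)

  # all-hydrophobic homopolymer: single grouped tripeptide cell
  v2 <- encode_compositions("AAAA")
  tri <- v2[startsWith(names(v2), "gtripep_")]
  expect_equal(unname(tri[["gtripep_111"]]), 1)
  expect_equal(sum(tri), 1)

  # K (positive) followed by D (negative) in the five-class alphabet
  v3 <- encode_compositions("KD")
  di <- v3[startsWith(names(v3), "gdipep_")]
  expect_equal(unname(di[["gdipep_45"]]), 1)
  expect_equal(sum(di), 1)
  # too short for tripeptides: block all zero
  expect_equal(sum(v3[startsWith(names(v3), "gtripep_")]), 0)
})

test_that("AAindex blocks average per exposure class with fallback", {
  aai <- aaindex_table()
  v <- encode_aaindex_blocks("AAAA", "EEBB", aai)
  # constant sequence: every seq mean equals the A value of the index
  a_vals <- unlist(aai[, "A"])
  expect_equal(unname(v[paste0("aaseq_", aai$index_id)]), unname(a_vals))

  v2 <- encode_aaindex_blocks("AC", "EB", aai)
  expect_equal(unname(v2[paste0("aaexp_", aai$index_id)]),
               unname(unlist(aai[, "A"])))
  expect_equal(unname(v2[paste0("aabur_", aai$index_id)]),
               unname(unlist(aai[, "C"])))

  # empty buried class falls back to the whole-sequence mean
  v3 <- encode_aaindex_blocks("ACDE", "EEEE", aai)
  expect_equal(unname(v3[paste0("aabur_", aai$index_id)]),
               unname(v3[paste0("aaseq_", aai$index_id)]))
  expect_error(encode_aaindex_blocks("AC", NA), "exposure")
})

test_that("dipeptide composition matches direct counting", {
  v <- encode_dipeptide("ACAC")
  expect_equal(v[["dipep_AC"]], 2 / 3)
  expect_equal(v[["dipep_CA"]], 1 / 3)
  expect_equal(sum(v), 1)
  expect_equal(length(v), 400L)
  v2 <- encode_dipeptide("AA")
  expect_equal(v2[["dipep_AA"]], 1)
  expect_warning(v3 <- encode_dipeptide("A"), "shorter")
  expect_equal(sum(v3), 0)
})

test_that("autocorrelation conventions hold on constructed sequences", {
  aai <- aaindex_table()
  prm <- autocorr_params()
  # homopolymer: Moreau-Broto equals the squared standardized value at all
  # lags; Moran and Geary are 0 by the zero-variance convention
  v <- encode_autocorrelation("AAAAAAAA", prm, aai)
  P <- aaindex_P(aai)
  for (i in seq_along(prm$properties)) {
    scale <- P[, prm$properties[[i]]]
    pa <- ((scale - mean(scale)) / sd(scale))[["A"]]
    nm <- paste0("nmb_", names(prm$properties)[i], "_d", 1:7)
    expect_equal(unname(v[nm]), rep(pa^2, 7))
  }
  expect_true(all(v[startsWith(names(v), "moran_")] == 0))
  expect_true(all(v[startsWith(names(v), "geary_")] == 0))

  # strict period-2 alternation has Moran(2) = 1
  v2 <- encode_autocorrelation(strrep("AR", 20), prm, aai)
  expect_equal(unname(v2[paste0("moran_", names(prm$properties), "_d2")]),
               rep(1, 3))
})

test_that("autocorrelation encoders match the brute-force formulas", {
  aai <- aaindex_table()
  prm <- autocorr_params()
  P <- aaindex_P(aai)
  for (s in 1:20) {
    chars <- strsplit(random_seq(sample(20:80, 1), seed = 100 + s), "")[[1]]
    v <- encode_autocorrelation(paste(chars, collapse = ""), prm, aai)
    for (i in seq_along(prm$properties)) {
      o <- oracle_autocorr(chars, P[, prm$properties[[i]]])
      tag <- paste0(names(prm$properties)[i], "_d", 1:30)
      expect_equal(unname(v[paste0("nmb_", tag)]), o$nmb, tolerance = 1e-10)
      expect_equal(unname(v[paste0("moran_", tag)]), o$moran,
                   tolerance = 1e-10)
      expect_equal(unname(v[paste0("geary_", tag)]), o$geary,
                   tolerance = 1e-10)
    }
  }
})

test_that("CTD blocks follow the stated conventions", {
  v <- encode_ctd("AAAA")
  # A is in exactly one class of each partition; its distribution is
  # (25, 25, 50, 75, 100) and every transition is 0
  parts <- ctd_partitions()
  for (pn in names(parts)) {
    g <- parts[[pn]][["A"]]
    expect_equal(unname(v[paste0("ctdd_", pn, "_g", g, "_",
                                 c("first", "q25", "q50", "q75", "q100"))]),
                 c(25, 25, 50, 75, 100))
    expect_equal(sum(v[paste0("ctdt_", pn, "_", c("g12", "g13", "g23"))]), 0)
    expect_equal(sum(v[paste0("ctdc_", pn, "_g", 1:3)]), 1)
  }
  # distribution oracle on random sequences
  for (s in 1:5) {
    chars <- strsplit(random_seq(40, seed = 200 + s), "")[[1]]
    v2 <- encode_ctd(paste(chars, collapse = ""))
    for (pn in names(parts)) {
      expect_equal(unname(v2[grep(paste0("ctdd_", pn, "_"), names(v2))]),
                   oracle_ctd_distribution(chars, parts[[pn]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("QSO descriptors normalize and match the coupling oracle", {
  v <- encode_qso(strrep("A", 40))
  # zero-diagonal distances: all couplings vanish, X_A = 1
  expect_true(all(v[grepl("_tau", names(v))] == 0))
  expect_equal(unname(v[["qso_pd_xA"]]), 1)
  expect_equal(unname(v[["qso_gr_xA"]]), 1)
  expect_equal(length(v), 160L)

  prm <- qso_params()
  for (s in 1:10) {
    chars <- strsplit(random_seq(sample(31:70, 1), seed = 300 + s), "")[[1]]
    v2 <- encode_qso(paste(chars, collapse = ""), prm)
    for (m in names(prm$matrices)) {
      tau <- oracle_qso_tau(chars, prm$matrices[[m]])
      expect_equal(unname(v2[paste0("qso_", m, "_tau", 1:30)]), tau,
                   tolerance = 1e-10)
      # the 50 descriptors of each matrix sum to 1
      expect_equal(sum(v2[grep(paste0("qso_", m, "_x"), names(v2))]), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("APAAC matches the independent formula evaluation", {
  prm <- apaac_params()
  v <- encode_apaac("AAAAAAAAAA", prm)
  h1a <- ((prm$hydrophobicity - mean(prm$hydrophobicity)) /
            sd(prm$hydrophobicity))[["A"]]
  h2a <- ((prm$hydrophilicity - mean(prm$hydrophilicity)) /
            sd(prm$hydrophilicity))[["A"]]
  # homopolymer: every tier is the squared standardized scale value
  denom <- 1 + prm$weight * 30 * (h1a^2 + abs(h2a^2))
  expect_equal(unname(v[["apaac_tau1"]]) / unname(v[["apaac_tau3"]]), 1)
  expect_equal(length(v), 80L)

  for (s in 1:10) {
    chars <- strsplit(random_seq(sample(31:60, 1), seed = 400 + s), "")[[1]]
    got <- encode_apaac(paste(chars, collapse = ""), prm)
    want <- oracle_apaac(chars, prm$hydrophobicity, prm$hydrophilicity)
    expect_equal(unname(got), want, tolerance = 1e-10)
  }
})

test_that("total amino-acid properties are per-residue means", {
  aai <- aaindex_table()
  prm <- autocorr_params()
  P <- aaindex_P(aai)
  v <- encode_taap("CCCC", prm, aai)
  expect_equal(unname(v), unname(P["C", prm$properties]))
  # concatenation invariance
  expect_equal(encode_taap("ARND", prm, aai),
               encode_taap("ARNDARND", prm, aai))
  expect_equal(length(v), 3L)
})

test_that("isoelectric point satisfies the root contract", {
  for (s in c("ACDEFGHIK", "MKLVVNAG", "DDKKRRHH")) {
    pi_val <- compute_pi(s)
    counts <- table(factor(strsplit(s, "")[[1]], levels = AA_ALPHABET))
    q <- xtalprop:::net_charge_at(pi_val, as.numeric(counts) |>
                                    stats::setNames(AA_ALPHABET))
    expect_lt(abs(q), 1e-3)
    expect_equal(pi_val, oracle_pi_grid(s), tolerance = 2e-3)
  }
  expect_lt(compute_pi("DDDD"), 7)
  expect_gt(compute_pi("KKKK"), 7)
})

test_that("structure blocks count runs and overlaps as specified", {
  v <- encode_structure_blocks("MMMMM", ss = "CCHHH", disorder = "OOOOO",
                               exposure = "EEBBE")
  expect_equal(v[["exp_frac"]], 0.6)
  expect_equal(v[["erun_ge1"]], 2 / 5)
  expect_equal(v[["erun_max"]], 2)
  expect_equal(v[["erun_mean"]], 1.5)
  # "CCHHH": one coil and one helix segment
  expect_equal(v[["ss_total_segs"]], 2 / 5)
  expect_equal(v[["ss_C_maxseg"]], 2)
  # all-Met coil: sulfur frequency within coil is 1
  expect_equal(v[["ss_C_sulfur"]], 1)
  expect_equal(v[["ss_H_sulfur"]], 1)
  expect_equal(length(v), 145L)

  # exposed-His frequency
  v2 <- encode_structure_blocks("HHAA", ss = "CCCC", disorder = "DDOO",
                                exposure = "EEBB")
  expect_equal(v2[["exp_his"]], 0.5)
  expect_equal(v2[["dis_exp"]], 0.5)
  expect_equal(v2[["dis_frac"]], 0.5)
  expect_error(encode_structure_blocks("AA", ss = NA, disorder = "OO",
                                       exposure = "EB"), "track")
})

test_that("encode_features yields the full deterministic vector", {
  pr <- annotate_baseline(simulate_sequences(3, c(40, 80), seed = 11))
  ft <- encode_features(pr)
  expect_equal(ncol(ft), 2925L) # id + 2,924 features
  expect_equal(names(ft)[-1], feature_registry()$feature_id)
  expect_true(all(is.finite(as.matrix(ft[-1]))))
  # bit-identical on repetition
  expect_identical(encode_features(pr), ft)
})

test_that("composition is shuffle-invariant but dipeptides are not", {
  s <- "ARNDCEQGHILKMFPSTWYVAAAA"
  set.seed(5)
  shuffled <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(encode_compositions(s)[1:20],
               encode_compositions(shuffled)[1:20])
  # counterexample: dipeptide composition depends on order
  expect_false(isTRUE(all.equal(encode_dipeptide("ACAC"),
                                encode_dipeptide("AACC"))))
})
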