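sig5 <- gene_signature("sig5", paste0("g", 1:5))

test_that("Ts% averages log2 differences in log space", {
  t_ref <- stats::setNames(rep(10, 5), paste0("g", 1:5))
  # a sample identical to the purified-T-cell reference scores exactly 100
  expect_equal(ts_percent(t_ref, sig5, t_ref), 100)
  # uniform 5-log2 deficit
  expect_equal(ts_percent(t_ref - 5, sig5, t_ref), 100 * 2^-5)
  # differences (-4, -6) average to -5 in log space, not to 2^-4/2 + 2^-6/2
  t2 <- stats::setNames(c(10, 10), c("g1", "g2"))
  s2 <- stats::setNames(c(6, 4), c("g1", "g2"))
  expect_equal(ts_percent(s2, c("g1", "g2"), t2), 3.125)
  expect_error(ts_percent(stats::setNames(1, "other"), sig5, t_ref),
               "no signature genes")
})

test_that("Ts% is shift-invariant per gene and strictly increasing", {
  set.seed(9)
  t_ref <- stats::setNames(runif(5, 8, 12), paste0("g", 1:5))
  s <- t_ref - runif(5, 2, 6)
  shift <- stats::setNames(rnorm(5), paste0("g", 1:5))
  expect_equal(ts_percent(s + shift, sig5, t_ref + shift),
               ts_percent(s, sig5, t_ref))
  base <- ts_percent(s, sig5, t_ref)
  for (g in names(s)) {
    bumped <- s; bumped[g] <- bumped[g] + 0.1
    expect_gt(ts_percent(bumped, sig5, t_ref), base)
  }
})

test_that("Tav is the arithmetic mean of signature-gene log2 values", {
  v <- stats::setNames(c(2, 4, 6), paste0("g", 1:3))
  expect_equal(as.numeric(tav(v, paste0("g", 1:3))), 4)
  expect_equal(as.numeric(tav(v, "g2")), 4)
  expect_identical(attr(tav(v, "g2", platform = "RNAseq"), "platform"), "RNAseq")
  set.seed(2)
  m <- matrix(rnorm(15 * 4, 7), 15, 4,
              dimnames = list(sprintf("g%02d", 1:15), paste0("s", 1:4)))
  expect_equal(as.numeric(tav(m, rownames(m))), colMeans(m), ignore_attr = TRUE)
})

test_that("Ts-l2 measures the log2 difference to matched healthy tissue", {
  ht <- stats::setNames(rep(5, 5), paste0("g", 1:5))
  expect_equal(ts_l2(ht, ht, sig5), 0)
  expect_equal(ts_l2(ht + 0.5, ht, sig5), 0.5)
  expect_error(ts_l2(ht, NULL, sig5), "healthy-tissue reference")
  # identity with Ts% under a shared T-cell reference
  set.seed(3)
  t_ref <- stats::setNames(runif(5, 9, 11), paste0("g", 1:5))
  tumor <- t_ref - runif(5, 1, 6)
  expect_equal(ts_l2(tumor, ht, sig5),
               log2(ts_percent(tumor, sig5, t_ref) / ts_percent(ht, sig5, t_ref)))
})

test_that("band classification reproduces the 80-125% similar window", {
  cfg <- band_config(reference_ts = 3.0)
  expect_identical(as.character(classify_band(3.0, cfg)), "similar")
  expect_identical(as.character(classify_band(2.4, cfg)), "similar")   # 0.8 x 3.0
  expect_identical(as.character(classify_band(3.75, cfg)), "similar")  # 1.25 x 3.0
  expect_identical(as.character(classify_band(3.76, cfg)), "moderate")
  expect_identical(as.character(classify_band(7.5, cfg)), "moderate")  # 2.5 x 3.0
  expect_identical(as.character(classify_band(7.6, cfg)), "high")
  expect_identical(as.character(classify_band(1.2, cfg)), "very_low")  # 0.4 x 3.0
  expect_identical(as.character(classify_band(1.1, cfg)), "extremely_low")
  expect_error(classify_band(0, cfg), "positive")
  expect_error(band_config(extremely_low_frac = 0.9), "band fractions")
})

test_that("infiltration calls use mean + 1 sample SD with a strict inequality", {
  expect_true(call_infiltrated(1.01, c(1, 1, 1)))    # SD 0
  expect_false(call_infiltrated(3.0, c(1, 2, 3)))    # threshold exactly 3
  expect_true(call_infiltrated(3.1, c(1, 2, 3)))
  expect_false(call_infiltrated(1.5, c(1, 2, 3)))    # below the HT mean
  expect_error(call_infiltrated(2, 1), "two healthy-tissue")
})

test_that("platform adaptation drops missing genes and renames by count", {
  sig <- signature_h()
  platform8 <- c("CD2", "CD247", "CD28", "CD3D", "CD3G", "CD6", "ITK", "TRAT1",
                 "GAPDH", "ACTB")
  expect_warning(h8 <- adapt_signature(sig, platform8), "absent from platform")
  expect_length(h8$genes, 8)
  expect_identical(h8$name, "signature-H8")
  platform14 <- c(setdiff(sig$genes, "TRBC1"), "GAPDH")
  expect_warning(h14 <- adapt_signature(sig, platform14), "TRBC1")
  expect_length(h14$genes, 14)
  expect_identical(h14$name, "signature-H14")
  all_there <- adapt_signature(sig, sig$genes)
  expect_identical(all_there$genes, sig$genes)
  expect_identical(all_there$name, "signature-H")
  expect_error(adapt_signature(sig, sig$genes[1:5]), "min 8")
})

test_that("quartile concordance ranks descending with stable ties", {
  ids <- paste0("p", 1:8)
  s <- stats::setNames(8:1, ids)
  expect_equal(quartile_concordance(s, s)$q1_overlap_pct, 100)
  expect_equal(quartile_concordance(s, s)$q4_overlap_pct, 100)
  rev <- stats::setNames(1:8, ids)
  expect_equal(quartile_concordance(s, rev)$q1_overlap_pct, 0)
  expect_equal(quartile_concordance(s, rev)$q4_overlap_pct, 0)
  # swap one pair across the Q1 boundary: overlap drops to 1/2
  other <- s; other[c("p2", "p3")] <- other[c("p3", "p2")]
  expect_equal(quartile_concordance(s, other)$q1_overlap_pct, 50)
  expect_equal(quartile_concordance(s, other)$q4_overlap_pct, 100)
  expect_error(quartile_concordance(s, rev[1:7]), "differ")
  expect_error(quartile_concordance(s[1:3], rev[1:3]), "at least 4")
})

test_that("score_infiltration assembles per-sample scores consistently", {
  co <- generate_corpus(corpus_spec(seed = 21,
    tumor_fractions = c(colon_tumor = 0.15)))
  gm <- group_means(co$matrix, co$annotation)
  ann <- co$annotation
  ht_cols <- ann$sample_id[ann$group == "colon"]
  tumor_cols <- ann$sample_id[ann$class == "TUMOR"]
  ht_means <- rowMeans(co$matrix[, ht_cols])
  ht_tavs <- as.numeric(tav(co$matrix[, ht_cols], co$planted))
  sc <- score_infiltration(co$matrix[, tumor_cols, drop = FALSE], co$planted,
                           gm$t_ref, ht_gene_means = ht_means,
                           ht_specimen_tavs = ht_tavs)
  expect_s3_class(sc, "infiltration_scores")
  expect_setequal(colnames(sc),
                  c("sample_id", "ts_percent", "tav", "band", "ts_l2", "infiltrated"))
  # tumor fraction 0.15 vs healthy colon 0.06: clearly more infiltrated
  expect_true(all(sc$ts_l2 > 0.32))
  expect_true(all(sc$infiltrated))
  expect_equal(sc$ts_percent,
               unname(ts_percent(co$matrix[, tumor_cols], co$planted, gm$t_ref)))
})
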