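make_gm <- function(t_ref, imm = NULL, tis = NULL) {
  genes <- names(t_ref)
  means <- cbind(imm, tis)
  structure(list(
    means = means,
    group_class = stats::setNames(
      rep(c("IMMUNE_NON_T", "TISSUE"),
          c(if (is.null(imm)) 0 else ncol(imm), if (is.null(tis)) 0 else ncol(tis))),
      colnames(means)),
    n_samples = stats::setNames(rep(1L, ncol(means)), colnames(means)),
    t_ref = t_ref, pooling = "pooled_samples"), class = "group_mean_table")
}

test_that("round 1 excludes on the limiting immune-subset margin, boundary kept", {
  t_ref <- c(clear = 10, tight = 10, edge = 10)
  imm <- rbind(clear = c(4, 5, 3, 6),     # min margin 4 -> kept
               tight = c(4, 5, 3, 7),     # margin vs monocytes 3 -> excluded
               edge = c(4, 5, 3, 6.68))   # margin exactly 3.32 -> kept
  colnames(imm) <- c("Bcell", "DC", "granulocyte", "monocyte")
  gm <- make_gm(t_ref, imm = imm)
  r <- round1_immune_filter(gm)
  expect_setequal(r$kept, c("clear", "edge"))
  expect_identical(r$excluded, "tight")
  # pooled mode compares against the unweighted mean of subset means
  rp <- round1_immune_filter(gm, selection_config(immune_compare_mode = "pooled"))
  expect_setequal(rp$kept, c("clear", "tight", "edge"))  # mean margins all >= 3.32
  expect_error(round1_immune_filter(make_gm(t_ref, tis = imm)), "IMMUNE_NON_T")
})

test_that("round 2 compares against the mean of tissue means by default", {
  t_ref <- c(a = 10, b = 10)
  tis <- rbind(a = c(4, 5, 6),    # aggregate 5, margin 5 -> kept
               b = c(4, 9, NA))
  tis["b", 3] <- 6.5              # aggregate 6.5, margin 3.5 -> kept by default
  colnames(tis) <- paste0("t", 1:3)
  gm <- make_gm(t_ref, tis = tis)
  r <- round2_tissue_filter(gm)
  expect_setequal(r$kept, c("a", "b"))
  # per-tissue mode: margin vs t2 for gene b is 1 -> excluded
  rp <- round2_tissue_filter(gm, selection_config(tissue_compare_mode = "per_tissue"))
  expect_identical(rp$excluded, "b")
  expect_error(round2_tissue_filter(make_gm(t_ref, tis = tis[, 1, drop = FALSE])),
               "two TISSUE")
})

test_that("round 3 keeps ranges inside the inclusive 2.5-8.5 window", {
  t_ref <- c(ok = 10, wide = 10, edge = 10, flat = 10)
  tis <- rbind(ok = c(4, 8), wide = c(4, 13), edge = c(4, 6.5), flat = c(4, 5))
  colnames(tis) <- c("t1", "t2")
  r <- round3_range_filter(make_gm(t_ref, tis = tis))
  expect_setequal(r$kept, c("ok", "edge"))      # range 4; range exactly 2.5
  expect_setequal(r$excluded, c("wide", "flat")) # 9 > 8.5; 1 < 2.5
})

test_that("outlier passes use cohort statistics frozen at pass entry", {
  # nl/Tc rows: g1 = (-5,-5), g2 = (-5,-5), g3 = (-5, 0)
  t_ref <- c(g1 = 10, g2 = 10, g3 = 10)
  tis <- rbind(g1 = c(5, 5), g2 = c(5, 5), g3 = c(5, 10))
  colnames(tis) <- c("t1", "t2")
  r <- round45_outlier_filter(make_gm(t_ref, tis = tis))
  # M = (-5, -10/3); g3 deviation at t2 = 10/3 = 3.333 > 3.32
  expect_identical(r$pass_excluded[[1]], "g3")
  expect_setequal(r$kept, c("g1", "g2"))
  d <- r$diagnostics[r$diagnostics$pass == 1 & r$diagnostics$gene == "g3", ]
  expect_equal(d$max_deviation, 10 / 3, tolerance = 1e-12)

  # identical profiles: zero deviations, nothing excluded in either pass
  tis2 <- rbind(g1 = c(5, 6), g2 = c(5, 6), g3 = c(5, 6))
  colnames(tis2) <- c("t1", "t2")
  r2 <- round45_outlier_filter(make_gm(t_ref, tis = tis2))
  expect_length(r2$excluded, 0)

  # single gene entering: pass skipped with a warning
  expect_warning(
    r3 <- round45_outlier_filter(make_gm(t_ref["g1"],
                                         tis = tis["g1", , drop = FALSE])),
    "fewer than 2")
  expect_identical(r3$kept, "g1")
})

test_that("a second outlier pass can exclude genes shielded in the first", {
  # g3 grossly constitutive in t2 inflates M(t2); g4 mildly constitutive
  # survives pass 1 only because of that shield, and falls in pass 2.
  t_ref <- c(g1 = 10, g2 = 10, g3 = 10, g4 = 10)
  # pass 1: M(t2) = (-5-5+4+0)/4 = -1.5, g3 deviation 5.5 -> out, g4 only 1.5
  # pass 2: M(t2) recomputed from g1/g2/g4 = -10/3, g4 deviation 10/3 > 3.32
  tis <- rbind(g1 = c(5, 5), g2 = c(5, 5), g3 = c(5, 14), g4 = c(5, 10))
  colnames(tis) <- c("t1", "t2")
  cfg <- selection_config()
  r1pass <- round45_outlier_filter(make_gm(t_ref, tis = tis), cfg, passes = 1)
  expect_identical(r1pass$excluded, "g3")
  r2pass <- round45_outlier_filter(make_gm(t_ref, tis = tis), cfg, passes = 2)
  expect_setequal(r2pass$excluded, c("g3", "g4"))
  expect_identical(r2pass$pass_excluded[[2]], "g4")
  # matches the brute-force oracle
  expect_setequal(r2pass$kept, bf_round45(tis, t_ref, 3.32, passes = 2))
})

test_that("round 6 counts distinct parenchymal sources among violating lines", {
  lines <- list(means = rbind(two_src = c(9, 3, 9, 3, 3),
                              one_src = c(9, 9, 3, 3, 3),
                              immune = c(3, 3, 3, 3, 9),
                              clean = c(3, 3, 3, 3, 3)),
                source = stats::setNames(
                  c("lung", "lung", "colon", "breast", "immune"),
                  c("lu1", "lu2", "co1", "br1", "B1")))
  colnames(lines$means) <- names(lines$source)
  t_ref <- c(two_src = 10, one_src = 10, immune = 10, clean = 10)
  r <- round6_cellline_filter(lines, t_ref)
  expect_setequal(r$excluded, c("two_src", "immune"))  # 2 sources; immune line
  expect_setequal(r$kept, c("one_src", "clean"))       # 2 lung lines = 1 source
  expect_setequal(r$kept, bf_round6(lines$means, lines$source, t_ref, 3.32))
})

test_that("each round agrees with an independent brute-force re-implementation", {
  for (seed in 1:5) {
    fx <- random_group_table(n_genes = 30, seed = seed)
    cfg <- selection_config()
    expect_setequal(round1_immune_filter(fx$gm, cfg)$kept,
                    bf_round1(fx$imm, fx$t_ref, cfg$log2_min_overexpr))
    expect_setequal(round2_tissue_filter(fx$gm, cfg)$kept,
                    bf_round2(fx$tis, fx$t_ref, cfg$log2_min_overexpr))
    expect_setequal(round3_range_filter(fx$gm, cfg)$kept,
                    bf_round3(fx$tis, cfg$range_min, cfg$range_max))
    expect_setequal(round45_outlier_filter(fx$gm, cfg)$kept,
                    bf_round45(fx$tis, fx$t_ref, cfg$deviation_threshold))
  }
})

test_that("selection report satisfies the exclusion-count invariant", {
  co <- generate_corpus(corpus_spec(seed = 3))
  rep <- run_selection(co$matrix, co$annotation, rownames(co$matrix))
  expect_equal(sum(rep$excluded_counts) + length(rep$signature$genes),
               rep$n_candidates)
  expect_true(all(rep$signature$genes %in% rownames(co$matrix)))
  # candidates already T-restricted: nothing excluded
  rep2 <- run_selection(co$matrix, co$annotation, co$planted)
  expect_identical(rep2$signature$genes, co$planted$genes)
  expect_equal(sum(rep2$excluded_counts), 0)
})

test_that("missing candidates are dropped with a warning, empty survival warns", {
  co <- generate_corpus(corpus_spec(seed = 4))
  expect_warning(
    rep <- run_selection(co$matrix, co$annotation,
                         c(co$planted$genes, "NOT_A_GENE")),
    "NOT_A_GENE")
  expect_identical(rep$signature$genes, co$planted$genes)
  # impossible threshold: everything dies at round 2, empty signature + warning
  cfg <- selection_config(log2_min_overexpr = 20)
  expect_warning(
    rep0 <- run_selection(co$matrix, co$annotation, co$planted, cfg),
    "no genes survived")
  expect_length(rep0$signature$genes, 0)
  expect_equal(sum(rep0$excluded_counts) + 0, rep0$n_candidates)
})

test_that("raising the over-expression threshold never grows the survivor set", {
  # per-round monotonicity on random fixtures
  for (seed in 1:5) {
    fx <- random_group_table(seed = seed)
    thresholds <- c(1, 2, 3.32, 5)
    k1 <- lapply(thresholds, function(th)
      round1_immune_filter(fx$gm, selection_config(log2_min_overexpr = th))$kept)
    k2 <- lapply(thresholds, function(th)
      round2_tissue_filter(fx$gm, selection_config(log2_min_overexpr = th))$kept)
    for (i in seq_along(thresholds)[-1]) {
      expect_true(all(k1[[i]] %in% k1[[i - 1]]))
      expect_true(all(k2[[i]] %in% k2[[i - 1]]))
    }
  }
  # whole-pipeline monotonicity across a threshold grid on a generated corpus
  co <- generate_corpus(corpus_spec(seed = 11))
  sizes <- sapply(c(2, 3.32, 4.5, 6), function(th) {
    cfg <- selection_config(log2_min_overexpr = th)
    length(suppressWarnings(
      run_selection(co$matrix, co$annotation, rownames(co$matrix), cfg))$signature$genes)
  })
  expect_true(all(diff(sizes) <= 0))
})

test_that("planted genes are recovered exactly across seeds", {
  hits <- 0
  for (s in 1:100) {
    co <- generate_corpus(corpus_spec(seed = s))
    rep <- suppressWarnings(
      run_selection(co$matrix, co$annotation, rownames(co$matrix)))
    if (setequal(rep$signature$genes, co$planted$genes)) hits <- hits + 1
  }
  expect_gte(hits, 99)
})
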