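# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# product-limit estimator by direct counting
bf_km <- function(time, event) {
  event <- as.integer(event)
  tt <- sort(unique(time[event == 1]))
  surv <- numeric(length(tt))
  s <- 1
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    deaths <- sum(time == tt[i] & event == 1)
    s <- s * (1 - deaths / at_risk)
    surv[i] <- s
  }
  list(time = tt, surv = surv)
}

# two-group Mantel-Cox: O/E by hypergeometric counting at each event time
bf_logrank2 <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  stopifnot(nlevels(group) == 2)
  g1 <- levels(group)[1]
  event <- as.integer(event)
  tt <- sort(unique(time[event == 1]))
  O1 <- sum(event == 1 & group == g1)
  E1 <- 0; V <- 0
  for (t in tt) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g1)
    d <- sum(time == t & event == 1)
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  O <- c(O1, sum(event == 1) - O1)
  E <- c(E1, sum(event == 1) - E1)
  names(O) <- names(E) <- levels(group)
  list(chi2 = (O1 - E1)^2 / V, observed = O, expected = E)
}

# Pearson chi-square on a 2x2 table, closed form, no correction
bf_chi2_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# brute-force re-implementations of the selection rounds (loops, no reuse)
bf_round1 <- function(imm_means, t_ref, thr, mode = "per_group") {
  kept <- character(0)
  for (g in rownames(imm_means)) {
    margins <- t_ref[g] - imm_means[g, ]
    m <- if (mode == "per_group") min(margins) else t_ref[g] - mean(imm_means[g, ])
    if (!(m < thr)) kept <- c(kept, g)
  }
  kept
}

bf_round2 <- function(tis_means, t_ref, thr, mode = "mean_of_tissue_means") {
  kept <- character(0)
  for (g in rownames(tis_means)) {
    m <- if (mode == "mean_of_tissue_means") t_ref[g] - mean(tis_means[g, ])
    else min(t_ref[g] - tis_means[g, ])
    if (!(m < thr)) kept <- c(kept, g)
  }
  kept
}

bf_round3 <- function(tis_means, lo, hi) {
  kept <- character(0)
  for (g in rownames(tis_means)) {
    r <- max(tis_means[g, ]) - min(tis_means[g, ])
    if (r >= lo && r <= hi) kept <- c(kept, g)
  }
  kept
}

bf_round45 <- function(tis_means, t_ref, thr, passes = 2) {
  entering <- rownames(tis_means)
  for (p in seq_len(passes)) {
    if (length(entering) < 2) break
    M <- sapply(colnames(tis_means), function(t)
      mean(tis_means[entering, t] - t_ref[entering]))
    out <- character(0)
    for (g in entering) {
      dev <- (tis_means[g, ] - t_ref[g]) - M
      if (max(dev) > thr) out <- c(out, g)
    }
    entering <- setdiff(entering, out)
  }
  entering
}

bf_round6 <- function(line_means, source, t_ref, thr, min_sources = 2) {
  kept <- character(0)
  for (g in rownames(line_means)) {
    viol <- colnames(line_means)[t_ref[g] - line_means[g, ] < thr]
    src <- source[viol]
    if (!(length(unique(src[src != "immune"])) >= min_sources ||
          any(src == "immune")))
      kept <- c(kept, g)
  }
  kept
}

# random group-mean fixture for round-level property tests
random_group_table <- function(n_genes = 30, n_imm = 4, n_tis = 5, seed = 1) {
  set.seed(seed)
  genes <- sprintf("G%02d", seq_len(n_genes))
  t_ref <- stats::setNames(runif(n_genes, 8, 12), genes)
  imm <- matrix(runif(n_genes * n_imm, 2, 11), n_genes,
                dimnames = list(genes, paste0("imm", seq_len(n_imm))))
  tis <- matrix(runif(n_genes * n_tis, 2, 11), n_genes,
                dimnames = list(genes, paste0("tis", seq_len(n_tis))))
  means <- cbind(imm, tis)
  gm <- structure(list(
    means = means,
    group_class = stats::setNames(rep(c("IMMUNE_NON_T", "TISSUE"), c(n_imm, n_tis)),
                                  colnames(means)),
    n_samples = stats::setNames(rep(1L, ncol(means)), colnames(means)),
    t_ref = t_ref, pooling = "pooled_samples"), class = "group_mean_table")
  list(gm = gm, imm = imm, tis = tis, t_ref = t_ref)
}
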