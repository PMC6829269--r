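#' Specification of a synthetic selection corpus
#'
#' Defines a self-contained expression corpus with the statistical structure
#' the scoring model assumes: bulk tissue expression is a linear-scale
#' mixture of a T-cell profile (fraction `f`) and a parenchymal background
#' (fraction `1 - f`), log2-transformed, with lognormal (post-log Gaussian)
#' noise. Planted T-restricted genes clear every selection round by a wide
#' margin; six confounder classes are each designed to be caught at one
#' specific round under the ordered procedure: over-expression by one immune
#' subset (round 1), constitutive expression across tissues (round 2), a
#' too-flat or too-wide tissue range (round 3), constitutive expression in a
#' single tissue (rounds 4-5) and over-expression by cell lines from two
#' parenchymal sources or an immune-derived line (round 6).
#'
#' @param n_true Number of planted T-restricted genes, default 10.
#' @param confounders Named integer vector of per-class confounder counts
#'   (`r1`, `r2`, `r3_flat`, `r3_wide`, `r45`, `r6`), default 10/10/5/5/10/10.
#' @param t_cell_mean Mean log2 expression of every candidate gene in T
#'   cells, default 10.
#' @param margin Log2 gap between T cells and the quiet compartments (immune
#'   subsets, cell lines) for planted genes, default 7. Must be at least the
#'   selection threshold (3.32) plus six noise SDs for guaranteed recovery.
#' @param noise_sd Post-log Gaussian noise SD (log2), default 0.25.
#' @param tissue_fractions Named T-cell fractions per healthy tissue,
#'   defaults spanning 0.006-0.06 over six tissues.
#' @param tumor_fractions Optional named T-cell fractions for tumor groups.
#' @param n_per_group Samples per T/immune/tissue group, default 6.
#' @param n_per_line Arrays per cell line, default 3.
#' @param bg_log2 Baseline parenchymal background (log2) for quiet genes;
#'   `-Inf` means zero linear background, default 0.
#' @param floor_log2 Floor applied when the mixture underflows (all-zero
#'   linear signal), default 0.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   corpora.
#' @return A list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_true = 10,
                        confounders = c(r1 = 10, r2 = 10, r3_flat = 5,
                                        r3_wide = 5, r45 = 10, r6 = 10),
                        t_cell_mean = 10, margin = 7, noise_sd = 0.25,
                        tissue_fractions = c(brain = 0.006, cerebellum = 0.009,
                                             breast = 0.015, kidney = 0.024,
                                             lung = 0.04, colon = 0.06),
                        tumor_fractions = NULL,
                        n_per_group = 6, n_per_line = 3,
                        bg_log2 = 0, floor_log2 = 0, seed = NULL) {
  full <- c(r1 = 0, r2 = 0, r3_flat = 0, r3_wide = 0, r45 = 0, r6 = 0)
  bad <- setdiff(names(confounders), names(full))
  if (length(bad)) stop("unknown confounder class(es): ", paste(bad, collapse = ", "))
  full[names(confounders)] <- confounders
  if (margin < 3.32 + 6 * noise_sd)
    stop("infeasible spec: margin must be at least 3.32 + 6 * noise_sd for ",
         "guaranteed planted recovery")
  fr <- c(tissue_fractions, tumor_fractions)
  if (any(fr <= 0 | fr >= 1)) stop("all fractions must lie in (0, 1)")
  if (length(tissue_fractions) < 2) stop("at least two tissues are required")
  if (is.null(names(tissue_fractions))) stop("tissue_fractions must be named")
  structure(list(n_true = n_true, confounders = full,
                 t_cell_mean = t_cell_mean, margin = margin,
                 noise_sd = noise_sd,
                 tissue_fractions = tissue_fractions,
                 tumor_fractions = tumor_fractions,
                 n_per_group = n_per_group, n_per_line = n_per_line,
                 bg_log2 = bg_log2, floor_log2 = floor_log2, seed = seed),
            class = "corpus_spec")
}

# log2 of the linear mixture f * 2^mu_t + (1 - f) * 2^bg, floored
mix_log2 <- function(f, mu_t, bg, floor_log2) {
  lin <- f * 2^mu_t + (1 - f) * ifelse(is.finite(bg), 2^bg, 0)
  ifelse(lin > 0, log2(lin), floor_log2)
}

#' Generate a synthetic selection corpus
#'
#' Builds the expression matrix, sample annotation and planted signature
#' described by a [corpus_spec()]. Compartments: three purified T-cell
#' subsets, four non-T immune subsets, the specified healthy tissues (and
#' optional tumors) generated from the mixture model, and six cell lines
#' (two lung, two colon, one breast, one immune-derived).
#'
#' @param spec A [corpus_spec()].
#' @return List with `matrix` ([expr_matrix()]), `annotation` (data.frame),
#'   `planted` ([gene_signature()]) and `spec`.
#' @export
generate_corpus <- function(spec = corpus_spec()) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  cf <- spec$confounders
  mu_t <- spec$t_cell_mean
  quiet <- mu_t - spec$margin            # immune/cell-line level of restricted genes
  hot <- mu_t - 1                        # confounder over-expression level

  genes <- c(
    if (spec$n_true) sprintf("TRG%02d", seq_len(spec$n_true)),
    if (cf["r1"]) sprintf("CFIM%02d", seq_len(cf["r1"])),
    if (cf["r2"]) sprintf("CFTI%02d", seq_len(cf["r2"])),
    if (cf["r3_flat"]) sprintf("CFFL%02d", seq_len(cf["r3_flat"])),
    if (cf["r3_wide"]) sprintf("CFWD%02d", seq_len(cf["r3_wide"])),
    if (cf["r45"]) sprintf("CFOU%02d", seq_len(cf["r45"])),
    if (cf["r6"]) sprintf("CFCL%02d", seq_len(cf["r6"])))
  klass <- rep(c("true", "r1", "r2", "r3_flat", "r3_wide", "r45", "r6"),
               c(spec$n_true, cf))
  ng <- length(genes)
  if (!ng) stop("empty corpus: no genes specified")

  t_groups <- c("Tcell_CD4", "Tcell_CD8", "Tcell_memory")
  imm_groups <- c("Bcell", "DC", "granulocyte", "monocyte")
  tissues <- names(spec$tissue_fractions)
  lines <- data.frame(
    line = c("line_lung_1", "line_lung_2", "line_colon_1", "line_colon_2",
             "line_breast_1", "line_B_1"),
    source = c("lung", "lung", "colon", "colon", "breast", "immune"),
    stringsAsFactors = FALSE)

  # immune-subset means: quiet except the cycled hot subset of r1 confounders
  imm_mean <- matrix(quiet, ng, length(imm_groups),
                     dimnames = list(genes, imm_groups))
  i_r1 <- which(klass == "r1")
  if (length(i_r1))
    imm_mean[cbind(i_r1, 1 + (seq_along(i_r1) - 1) %% length(imm_groups))] <- hot

  # parenchymal background per gene and tissue
  nt <- length(tissues)
  bg <- matrix(spec$bg_log2, ng, nt, dimnames = list(genes, tissues))
  ord <- order(spec$tissue_fractions)     # ascending T-cell fraction
  bg[klass == "r2", ] <- rep(mu_t - seq(3.6, 2.6, length.out = nt)[order(ord)],
                             each = sum(klass == "r2"))
  bg[klass == "r3_flat", ] <- mu_t - 4.7
  bg[klass == "r3_wide", tissues[ord[1]]] <- mu_t + 2.45
  i_r45 <- which(klass == "r45")
  if (length(i_r45))
    bg[cbind(i_r45, 1 + (seq_along(i_r45) - 1) %% nt)] <- mu_t + 0.5

  # cell-line means: quiet except designed round-6 violations
  line_mean <- matrix(quiet, ng, nrow(lines), dimnames = list(genes, lines$line))
  i_r6 <- which(klass == "r6")
  for (j in seq_along(i_r6)) {
    if (j %% 2 == 1) {                   # two distinct parenchymal sources
      line_mean[i_r6[j], c("line_lung_1", "line_colon_1")] <- hot
    } else {                             # immune-derived line
      line_mean[i_r6[j], "line_B_1"] <- hot
    }
  }

  cols <- list(); ann <- list()
  add_group <- function(means, group, class, n, source = NA_character_) {
    vals <- matrix(rnorm(ng * n, mean = means, sd = spec$noise_sd), ng, n)
    ids <- sprintf("%s_s%02d", group, seq_len(n))
    colnames(vals) <- ids
    cols[[length(cols) + 1]] <<- vals
    ann[[length(ann) + 1]] <<- data.frame(
      sample_id = ids, class = class, group = group,
      source_lineage = source, stringsAsFactors = FALSE)
  }

  for (g in t_groups)
    add_group(rep(mu_t, ng), g, "T_CELL", spec$n_per_group)
  for (g in imm_groups)
    add_group(imm_mean[, g], g, "IMMUNE_NON_T", spec$n_per_group)
  for (tt in tissues)
    add_group(mix_log2(spec$tissue_fractions[[tt]], mu_t, bg[, tt], spec$floor_log2),
              tt, "TISSUE", spec$n_per_group)
  if (!is.null(spec$tumor_fractions))
    for (tt in names(spec$tumor_fractions))
      add_group(mix_log2(spec$tumor_fractions[[tt]], mu_t, spec$bg_log2,
                         spec$floor_log2),
                tt, "TUMOR", spec$n_per_group)
  for (j in seq_len(nrow(lines)))
    add_group(line_mean[, lines$line[j]], lines$line[j], "CELL_LINE",
              spec$n_per_line, source = lines$source[j])

  values <- do.call(cbind, cols)
  rownames(values) <- genes
  planted <- if (spec$n_true)
    gene_signature("planted", genes[klass == "true"],
                   provenance = "synthetic T-restricted genes")
  else NULL
  list(matrix = expr_matrix(values), annotation = do.call(rbind, ann),
       planted = planted, gene_class = stats::setNames(klass, genes),
       spec = spec)
}

#' Generate a survival cohort with bin-dependent hazards
#'
#' Draws exponential event times whose hazard depends on the Tav bin of each
#' patient, with independent uniform censoring: censoring times are
#' `Unif(0, cmax)` with the horizon `cmax` solved numerically so that the
#' expected censored fraction equals `censor_frac`. Independence of the
#' censoring from the event times keeps the designed hazard ratios
#' undistorted. Tav values are drawn uniformly within each bin's range, so
#' the true bin is known.
#'
#' @param n_per_bin Patients per bin (scalar or per-bin vector).
#' @param hazards Positive hazard rate per bin (events per time unit),
#'   ordered as the bins of `binning`.
#' @param censor_frac Fraction of patients censored, default 0.2.
#' @param binning A [tav_bins()] object or numeric edges.
#' @param seed Optional seed.
#' @return data.frame with `patient_id`, `time`, `event`, `tav`, `true_bin`.
#' @export
generate_survival_cohort <- function(n_per_bin, hazards, censor_frac = 0.2,
                                     binning = tav_bins(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(binning)) binning <- tav_bins(binning)
  if (any(hazards <= 0)) stop("hazards must be positive")
  e <- binning$edges
  nb <- length(e) + 1L
  if (length(hazards) != nb)
    stop("need one hazard per bin (", nb, " bins)")
  n_per_bin <- rep_len(n_per_bin, nb)
  lo <- c(0, e)
  hi <- c(e, 3 * e[length(e)])
  recs <- lapply(seq_len(nb), function(b) {
    n <- n_per_bin[b]
    tav <- runif(n, lo[b], hi[b])
    t_event <- rexp(n, rate = hazards[b])
    data.frame(tav = tav, time = t_event, event = TRUE,
               true_bin = binning$labels[b], stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, recs)
  n <- nrow(d)
  if (censor_frac > 0) {
    if (censor_frac >= 1) {
      d$time <- runif(n, 0, d$time)
      d$event <- FALSE
    } else {
      # P(T > C) for C ~ Unif(0, cmax), averaged over the bin mixture
      w <- n_per_bin / n
      p_censor <- function(cmax)
        sum(w * (1 - exp(-hazards * cmax)) / (hazards * cmax))
      cmax <- stats::uniroot(function(x) p_censor(x) - censor_frac,
                             lower = 1e-6 / max(hazards),
                             upper = 1e6 / min(hazards))$root
      cens <- runif(n, 0, cmax)
      d$event <- d$time <= cens
      d$time <- pmin(d$time, cens)
    }
  }
  data.frame(patient_id = sprintf("P%04d", seq_len(n)), d,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic checkpoint-profile cohort
#'
#' Builds anti-PD-1-treated melanoma-like profiles: a `frac_good` fraction
#' satisfies all three response-rule criteria by construction; the rest
#' violate exactly one criterion, chosen uniformly (ligand/receptor ratio
#' out of window, Tav-RNAseq at or below the minimum, or PD-1/Tav at or
#' below its minimum). Responses are Bernoulli with probability
#' `p_good_respond` for rule-satisfying and `p_bad_respond` for violating
#' profiles (responders split between CR and PR, others PD), and survival
#' is linked to response (responders have a much lower death hazard), with
#' administrative censoring at three years.
#'
#' @param n Cohort size, default 200.
#' @param p_good_respond,p_bad_respond Response probabilities, defaults 0.85
#'   and 0.25.
#' @param frac_good Fraction of rule-satisfying profiles, default 0.5.
#' @param rules A [rule_config()].
#' @param seed Optional seed.
#' @return data.frame with `patient_id`, `pd1`, `pdl1`, `pdl2`,
#'   `tav_rnaseq`, `satisfies_rule`, `response`, `time`, `event`.
#' @export
generate_melanoma_cohort <- function(n = 200, p_good_respond = 0.85,
                                     p_bad_respond = 0.25, frac_good = 0.5,
                                     rules = rule_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(c(p_good_respond, p_bad_respond) < 0) ||
      any(c(p_good_respond, p_bad_respond) > 1))
    stop("response probabilities must lie in [0, 1]")
  n_good <- round(frac_good * n)
  satisfies <- sample(rep(c(TRUE, FALSE), c(n_good, n - n_good)))

  tav <- runif(n, 1.2, 3)
  pd1 <- tav * runif(n, 0.8, 2.5)        # PD-1/Tav comfortably above 0.5
  pdl1 <- pd1 * runif(n, 1, 9)           # ratios comfortably inside (0.5, 10)
  pdl2 <- pd1 * runif(n, 1, 9)

  mode <- sample.int(3, n, replace = TRUE)  # which criterion a violator breaks
  for (i in which(!satisfies)) {
    if (mode[i] == 1) {
      pdl1[i] <- pd1[i] * if (runif(1) < 0.5) runif(1, 0.05, 0.4) else runif(1, 11, 25)
    } else if (mode[i] == 2) {
      tav[i] <- runif(1, 0.05, 0.9)
      pd1[i] <- runif(1, 1, 3)            # keep PD-1/Tav and ratios valid
      pdl1[i] <- pd1[i] * runif(1, 1, 9)
      pdl2[i] <- pd1[i] * runif(1, 1, 9)
    } else {
      pd1[i] <- tav[i] * runif(1, 0.05, 0.45)
      pdl1[i] <- pd1[i] * runif(1, 1, 9)
      pdl2[i] <- pd1[i] * runif(1, 1, 9)
    }
  }

  p <- ifelse(satisfies, p_good_respond, p_bad_respond)
  responds <- rbinom(n, 1, p) == 1
  response <- ifelse(responds,
                     ifelse(runif(n) < 0.3, "CR", "PR"),
                     "PD")
  t_event <- rexp(n, rate = ifelse(responds, 1 / 1200, 1 / 250))
  horizon <- 1095
  data.frame(patient_id = sprintf("M%03d", seq_len(n)),
             pd1 = pd1, pdl1 = pdl1, pdl2 = pdl2, tav_rnaseq = tav,
             satisfies_rule = satisfies, response = response,
             time = pmin(t_event, horizon), event = t_event <= horizon,
             stringsAsFactors = FALSE)
}
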