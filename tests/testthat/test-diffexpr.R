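test_that("degenerate equal groups give log2fc 0, t 0, p 1", {
  ft <- make_ft(matrix(1, 1, 6), conds = rep(c("A", "B"), each = 3))
  r <- moderated_ttest(ft, "A", "B", moderation = "off")
  expect_equal(r$log2fc, 0)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
})

test_that("moderation off reproduces the classical pooled t exactly", {
  set.seed(101)
  v <- matrix(rnorm(1000 * 8), 1000, 8)
  ft <- make_ft(v)
  r <- moderated_ttest(ft, "A", "B", moderation = "off")
  oracle <- sapply(seq_len(1000), function(i)
    stats::t.test(v[i, 5:8], v[i, 1:4], var.equal = TRUE)$statistic)
  expect_lt(max(abs(r$t - oracle)), 1e-10)
  expect_error(moderated_ttest(ft, "A", "Z"), "absent")
})

test_that("BH adjustment: worked example, permutation invariance, edge cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.5)),
               c(0.04, 0.04, 0.16 / 3, 0.5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(1)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significance calling uses strict FDR and inclusive log2FC cuts", {
  r <- data.frame(fdr = c(0.04, 0.04, 0.05, 0.049),
                  log2fc = c(1.2, 0.9, 2.0, 1.0))
  out <- call_significant(r)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("multiplicity reconciliation removes only significantly discordant sites", {
  r <- data.frame(
    site_id = c("P1:S1", "P1:S1", "P2:S2", "P2:S2", "P3:S3"),
    multiplicity = c(1L, 2L, 1L, 2L, 1L),
    log2fc = c(2, -2, 2, -0.3, 1.5),
    significant = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  out <- reconcile_multiplicity(r)
  expect_false(any(out$site_id == "P1:S1"))      # both directions significant
  expect_equal(sum(out$site_id == "P2:S2"), 2)   # discordant but one n.s.
  expect_true("P3:S3" %in% out$site_id)
})

test_that("PTM adjustment reproduces the hand-evaluated pooled-SE example", {
  ph <- data.frame(feature_id = "s1", site_id = "P1:S1", protein_id = "P1",
                   log2fc = 2.0, se = 0.3, df = 6)
  pr <- data.frame(feature_id = "P1", log2fc = 0.5, se = 0.4, df = 6)
  a <- adjust_ptm(ph, pr)
  expect_equal(a$sp^2, 0.125)
  expect_equal(a$se, sqrt(0.125) * sqrt(2 / 6), tolerance = 1e-12)
  expect_equal(a$t_adj, 1.5 / (sqrt(0.125) * sqrt(2 / 6)),
               tolerance = 1e-12)
  expect_equal(round(a$t_adj, 2), 7.35)
  # equal fold changes force t to zero
  ph0 <- ph; ph0$log2fc <- 0.5
  expect_equal(adjust_ptm(ph0, pr)$t_adj, 0)
})

test_that("PTM adjustment matches an independent formula oracle on random inputs", {
  set.seed(202)
  n <- 1000
  ph <- data.frame(feature_id = paste0("s", 1:n),
                   site_id = paste0("P", 1:n, ":S1"),
                   protein_id = paste0("P", 1:n),
                   log2fc = rnorm(n), se = runif(n, 0.05, 1),
                   df = sample(2:30, n, TRUE))
  pr <- data.frame(feature_id = paste0("P", 1:n), log2fc = rnorm(n),
                   se = runif(n, 0.05, 1), df = sample(2:30, n, TRUE))
  a <- adjust_ptm(ph, pr)
  # oracle: literal re-evaluation, scalar arithmetic
  t_or <- vapply(1:n, function(i) {
    sp2 <- (pr$se[i]^2 * (pr$df[i] - 1) + ph$se[i]^2 * (ph$df[i] - 1)) /
      (pr$df[i] + ph$df[i] - 2)
    (ph$log2fc[i] - pr$log2fc[i]) /
      (sqrt(sp2) * sqrt(1 / pr$df[i] + 1 / ph$df[i]))
  }, 0)
  expect_lt(max(abs(a$t_adj - t_or)), 1e-10)
  expect_true(all(a$fdr_adj >= a$p_adj - 1e-12))
})

test_that("sites without protein evidence pass through flagged", {
  ph <- data.frame(feature_id = c("s1", "s2"),
                   site_id = c("P1:S1", "P9:S9"),
                   protein_id = c("P1", "P9"),
                   log2fc = c(2, 2), se = c(0.3, 0.3), df = c(6, 6))
  pr <- data.frame(feature_id = "P1", log2fc = 0.5, se = 0.4, df = 6)
  a <- adjust_ptm(ph, pr)
  expect_equal(a$no_protein_evidence, c(FALSE, TRUE))
  expect_true(a$phospho_driven[2])
  expect_true(is.na(a$fdr_adj[2]))
})

test_that("keep rule retains all raw-significant sites of driven proteins", {
  adj <- data.frame(
    feature_id = paste0("f", 1:4),
    site_id = c("P1:S1", "P1:S2", "Q1:S3", "Q1:S4"),
    protein_id = c("P1", "P1", "Q1", "Q1"),
    phospho_driven = c(TRUE, FALSE, FALSE, FALSE),
    no_protein_evidence = FALSE)
  out <- apply_keep_rule(adj, c("P1:S1", "P1:S2", "Q1:S3"))
  expect_equal(out$kept, c(TRUE, TRUE, FALSE, FALSE))
  expect_setequal(attr(out, "kept_sites"), c("P1:S1", "P1:S2"))
  empty <- apply_keep_rule(adj[0, ], character())
  expect_length(attr(empty, "kept_sites"), 0)
})

test_that("planted phospho-driven effects are recovered; protein-driven t is centered", {
  tp <- c(); tprot <- c()
  for (s in 1:5) {
    x <- gen_phosphoproteome(n_proteins = 250, sites_per_protein = 2,
                             n_kinases = 5, n_active = 2,
                             n_substrates = 15, n_protein_de = 20,
                             effect_log2 = 2, noise_sd = 0.3,
                             missing_params = NULL, seed = s)
    pp <- prep_chain(x, seed = s)
    pr <- moderated_ttest(pp$prot, "M1", "M2a")
    pr$fdr <- bh_adjust(pr$p)
    pm <- moderated_ttest(pp$phos, "M1", "M2a")
    pm$fdr <- bh_adjust(pm$p)
    adj <- adjust_ptm(pm, pr)
    planted <- intersect(x$truth$phospho_driven_sites, adj$site_id)
    tp <- c(tp, mean(planted %in% adj$site_id[adj$phospho_driven]))
    prot_sites <- adj$protein_id %in% names(x$truth$de_proteins)
    tprot <- c(tprot, adj$t_adj[prot_sites])
  }
  expect_gte(mean(tp), 0.95)
  # protein-abundance-driven sites: adjusted statistic centered at zero
  # (pooled across seeds; individual t values are noisy by construction)
  expect_lt(abs(stats::median(tprot, na.rm = TRUE)), 0.5)
})
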