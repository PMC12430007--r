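mk_ksmap <- function(kinase, sites) {
  parts <- strsplit(sites, ":", fixed = TRUE)
  data.frame(kinase = kinase,
             protein = vapply(parts, `[[`, "", 1),
             residue = vapply(parts, `[[`, "", 2),
             source = "curated", stringsAsFactors = FALSE)
}

test_that("curated enrichment: worked 2x2 value and exclusion of unseen kinases", {
  measured <- c("A:S1", "B:S2", "C:S3", "D:S4")
  up <- c("A:S1", "B:S2")
  ks <- rbind(mk_ksmap("K1", c("A:S1", "B:S2")),
              mk_ksmap("K2", c("X:S9", "Y:S8")))
  out <- enrich_curated_substrates(up, measured, ks)
  # table [[2,0],[0,2]] at N=4: two-sided point-probability p = 1/3
  expect_equal(out$p[out$kinase == "K1"], 1 / 3, tolerance = 1e-12)
  expect_equal(out$a[out$kinase == "K1"], 2)
  expect_equal(attr(out, "excluded"), "K2")
  expect_error(enrich_curated_substrates(c("Z:S1"), measured, ks),
               "subset")
})

test_that("kinase recognizing no upregulated site trends to odds ratio <= 1", {
  measured <- paste0("P", 1:40, ":S1")
  up <- measured[1:10]
  ks <- mk_ksmap("K1", measured[31:40])  # all recognized sites non-up
  out <- enrich_curated_substrates(up, measured, ks)
  expect_lte(out$odds_ratio, 1)
  expect_false(out$significant)
})

test_that("removing a kinase's substrates from the up set cannot lower p", {
  measured <- paste0("P", 1:60, ":S1")
  ks <- mk_ksmap("K1", measured[1:12])
  up_full <- measured[c(1:8, 41:50)]
  up_less <- measured[c(1:4, 41:50)]
  p_full <- enrich_curated_substrates(up_full, measured, ks)$p
  p_less <- enrich_curated_substrates(up_less, measured, ks)$p
  expect_gte(p_less, p_full)
})

test_that("site-prediction filter: posterior cut, prior rule, top-3 with ties", {
  preds <- data.frame(
    protein = "P1", residue = c("S1", "S1", "S1", "S1", "S1", "S2", "S3"),
    kinase_family = c("F1", "F2", "F3", "F4", "F5", "F6", "F7"),
    posterior = c(0.5, 0.4, 0.3, 0.3, 0.2, 0.05, 0.05),
    prior = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.06))
  out <- filter_site_predictions(preds)
  s1 <- out[out$residue == "S1", ]
  # top three by posterior, ties at rank 3 all kept
  expect_setequal(s1$kinase_family, c("F1", "F2", "F3", "F4"))
  expect_true("F6" %in% out$kinase_family)       # 0.05 > 0.035, > prior
  expect_false("F7" %in% out$kinase_family)      # posterior below prior
  low <- data.frame(protein = "P", residue = "S1", kinase_family = "F",
                    posterior = 0.03, prior = 0.001)
  expect_equal(nrow(filter_site_predictions(low)), 0)
})

test_that("family enrichment requires >= 10 upregulated substrates AND fdr", {
  measured <- paste0("P", 1:200, ":S1")
  up <- measured[1:30]
  # family A: 9 of the up sites (strong enrichment but below count rule)
  # family B: 15 up sites (passes both)
  preds <- data.frame(
    protein = paste0("P", c(1:9, 16:30, 101:140)), residue = "S1",
    kinase_family = c(rep("FA", 9), rep("FB", 55)),
    posterior = 0.2, prior = 0.01)
  out <- enrich_predicted_families(preds, up, measured)
  fa <- out[out$family == "FA", ]; fb <- out[out$family == "FB", ]
  expect_equal(fa$a, 9); expect_false(fa$significant)
  expect_equal(fb$a, 15)
  expect_lt(fb$fdr, 0.05); expect_true(fb$significant)
  empty <- enrich_predicted_families(preds, character(), measured)
  expect_equal(nrow(empty), 0)
})

test_that("planted-active kinases are recovered from synthetic data", {
  hits <- 0; total <- 0; fps <- c()
  for (s in 1:5) {
    x <- gen_phosphoproteome(n_proteins = 400, sites_per_protein = 2,
                             n_kinases = 8, n_active = 2,
                             n_substrates = 25, n_protein_de = 20,
                             effect_log2 = 2, noise_sd = 0.5, seed = s)
    pp <- prep_chain(x, seed = s)
    pm <- moderated_ttest(pp$phos, "M1", "M2a")
    pm$fdr <- bh_adjust(pm$p)
    pm <- call_significant(pm)
    in_motif <- pm$feature_id %in% pp$motif$feature_id
    measured <- unique(pm$site_id[in_motif])
    up <- unique(pm$site_id[in_motif & pm$significant & pm$log2fc > 0])
    en <- enrich_curated_substrates(up, measured, x$ksmap)
    sig <- en$kinase[en$significant]
    hits <- hits + sum(x$truth$active_kinases %in% sig)
    total <- total + length(x$truth$active_kinases)
    fps <- c(fps, length(setdiff(sig, x$truth$active_kinases)))
  }
  expect_equal(hits, total)
  expect_lte(stats::median(fps), 1)
})

test_that("signaling network obeys the edge and node inclusion rules", {
  # K1 upregulated, recognizes up site on kinase K3 (measured)
  # K2 unmeasured, bridges K1 -> K2 -> K3
  # K4 measured, not upregulated, connects only one upregulated kinase
  ks <- rbind(mk_ksmap("K1", c("K3:S1", "K2:S5")),
              mk_ksmap("K2", "K3:S2"),
              mk_ksmap("K4", "K1:S3"),
              mk_ksmap("K1", "TF1:S4"))
  up_sites <- c("K3:S1", "K3:S2", "K2:S5", "K1:S3", "TF1:S4")
  g <- build_signaling_network(
    upregulated_kinases = "K1",
    measured_kinases = c("K1", "K3", "K4"),
    ksmap = ks, upregulated_sites = up_sites, tf_list = "TF1",
    mode = "focused")
  nm <- igraph::V(g)$name
  expect_true(all(c("K1", "K3", "K2", "TF1") %in% nm))
  el <- igraph::as_edgelist(g)
  expect_true(any(el[, 1] == "K1" & el[, 2] == "K3"))
  expect_true(igraph::V(g)$bridging[match("K2", nm)])
  expect_true(igraph::V(g)$is_tf[match("TF1", nm)])
  # edge only when the exact site is upregulated
  g2 <- build_signaling_network("K1", c("K1", "K3", "K4"), ks,
                                upregulated_sites = c("K2:S5"),
                                tf_list = "TF1", mode = "focused")
  el2 <- igraph::as_edgelist(g2)
  expect_false(any(el2[, 2] == "K3"))
  # large mode: K4 connects only one upregulated kinase -> excluded
  gl <- build_signaling_network("K1", c("K1", "K3", "K4"), ks,
                                upregulated_sites = up_sites,
                                tf_list = "TF1", mode = "large")
  expect_false("K4" %in% igraph::V(gl)$name)
})
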