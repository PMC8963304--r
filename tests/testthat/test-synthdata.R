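test_that("noise-free Ct generation gives exactly zero treated-control differences", {
  cfg <- ct_sim_config(n_mirnas = 20, baseline_sd_between_mirnas = 0,
                       replicate_sd = 0, plate_shift_sd = 0, seed = 3)
  ctm <- gen_ct_matrix(cfg)
  tr <- ctm$ct[, ctm$samples$role == "treated"]
  co <- ctm$ct[, ctm$samples$role == "control"]
  expect_identical(tr - co, tr * 0)
  # and downstream fold changes are exactly 1
  norm <- mean_center_normalize(cap_detection_limit(ctm))
  expect_equal(unname(fold_change(norm, "treatment")), rep(1, 20))
})

test_that("a spike lowers treated Ct by exactly its log2 effect under zero noise", {
  spikes <- data.frame(mirna_index = 5L, treatment = "treatment",
                       log2_effect = 2)
  cfg <- ct_sim_config(n_mirnas = 10, baseline_sd_between_mirnas = 0,
                       replicate_sd = 0, plate_shift_sd = 0,
                       spikes = spikes, seed = 1)
  ctm <- gen_ct_matrix(cfg)
  tr <- ctm$ct[5, ctm$samples$role == "treated"]
  co <- ctm$ct[5, ctm$samples$role == "control"]
  expect_equal(unname(co - tr), rep(2, 3))
})

test_that("spike indices out of range are rejected with the offending index", {
  expect_error(
    ct_sim_config(n_mirnas = 10,
                  spikes = data.frame(mirna_index = 11L,
                                      treatment = "treatment",
                                      log2_effect = 1)),
    "11")
})

test_that("generators are pure functions of their config", {
  cfg <- ct_sim_config(n_mirnas = 30, seed = 17)
  expect_identical(gen_ct_matrix(cfg)$ct, gen_ct_matrix(cfg)$ct)
  ocfg <- ontology_sim_config(n_genes = 200, n_mirnas = 20, seed = 17)
  expect_identical(gen_target_network(ocfg)$edges,
                   gen_target_network(ocfg)$edges)
  g1 <- gen_interaction_graph(30, 0.1, seed = 17)
  g2 <- gen_interaction_graph(30, 0.1, seed = 17)
  expect_identical(g1, g2)
})

test_that("flat Hill curves with zero noise give exactly 100 everywhere", {
  ch <- data.frame(chemical = "X", endpoint = "ATP", top = 100, bottom = 100,
                   ec50 = 1, slope = 1)
  cfg <- apical_sim_config(ch, well_cv = 0, plate_scale_sd = 0, seed = 1)
  ap <- gen_apical(cfg)
  expect_equal(ap$value, rep(100, nrow(ap)))
})

test_that("the Hill midpoint sits at exactly half the span", {
  ch <- data.frame(chemical = "X", endpoint = "ATP", top = 100, bottom = 0,
                   ec50 = 1, slope = 1)
  cfg <- apical_sim_config(ch, concentrations = c(0.1, 1, 10),
                           well_cv = 0, plate_scale_sd = 0, seed = 1)
  ap <- gen_apical(cfg)
  expect_equal(unique(ap$value[ap$concentration_uM == 1]), 50)
  expect_equal(hill_response(1, 100, 0, 1, 1), 50)
})

test_that("apical sample means stay near the Hill mean under well noise", {
  ch <- data.frame(chemical = "X", endpoint = "ATP", top = 100, bottom = 20,
                   ec50 = 1, slope = 1.5)
  hits <- vapply(1:200, function(s) {
    cfg <- apical_sim_config(ch, concentrations = c(1), wells_per_group = 6L,
                             well_cv = 0.1, n_plates = 1L,
                             plate_scale_sd = 0, seed = s)
    ap <- gen_apical(cfg)
    v <- ap$value[ap$concentration_uM == 1]
    mu <- hill_response(1, 100, 20, 1, 1.5)
    abs(mean(v) - mu) <= 3 * (0.1 * mu) / sqrt(6)
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("invalid apical configs are rejected", {
  ch <- data.frame(chemical = "X", endpoint = "ATP", top = 100, bottom = 0,
                   ec50 = -1, slope = 1)
  expect_error(apical_sim_config(ch), "ec50")
  ch$ec50 <- 1
  expect_error(apical_sim_config(ch, concentrations = c(1, 0.1)), "sorted")
  expect_error(apical_sim_config(ch, wells_per_group = 1), "wells_per_group")
})

test_that("degenerate degree range gives every miRNA exactly that many targets", {
  cfg <- ontology_sim_config(n_genes = 100, n_mirnas = 25,
                             degree_distribution = c(3, 3, 2),
                             pathway_size_range = c(5, 20), seed = 5)
  net <- gen_target_network(cfg)
  expect_true(all(table(net$edges$mirna) == 3))
  expect_error(ontology_sim_config(n_genes = 5, n_mirnas = 3,
                                   degree_distribution = c(10, 12, 2),
                                   pathway_size_range = c(2, 4)),
               "min_targets")
})

test_that("power-law out-degrees show the expected CCDF slope", {
  cfg <- ontology_sim_config(n_genes = 2000, n_mirnas = 10000,
                             degree_distribution = c(1, 100, 2), seed = 42)
  net <- gen_target_network(cfg)
  deg <- as.integer(table(net$edges$mirna))
  d <- sort(unique(deg))
  ccdf <- vapply(d, function(x) mean(deg >= x), numeric(1))
  keep <- d <= 50 & ccdf > 0   # stable region of the empirical tail
  fit <- stats::lm(log(ccdf[keep]) ~ log(d[keep]))
  expect_lt(abs(unname(stats::coef(fit)[2]) - (-1)), 0.3)
})

test_that("planted pathway honours the configured spiked-target overlap", {
  base <- ontology_sim_config(n_genes = 300, n_mirnas = 30,
                              degree_distribution = c(3, 8, 2),
                              pathway_size_range = c(10, 60),
                              n_pathways = 5, seed = 9)
  net <- gen_target_network(base)
  spiked <- net$mirnas[1:5]
  u <- secretomir:::targets_of(net, spiked)

  cfg0 <- ontology_sim_config(n_genes = 300, n_mirnas = 30,
                              degree_distribution = c(3, 8, 2),
                              pathway_size_range = c(10, 60),
                              n_pathways = 5,
                              planted_pathway_overlap = 0, seed = 9)
  ont0 <- gen_pathway_ontology(cfg0, spiked, net)
  sz <- length(ont0$sets[[ont0$planted]])
  expect_true(sz >= 10 && sz <= 60)

  cfg1 <- ontology_sim_config(n_genes = 300, n_mirnas = 30,
                              degree_distribution = c(3, 8, 2),
                              pathway_size_range = c(10, 300),
                              n_pathways = 5,
                              planted_pathway_overlap = 1, seed = 9)
  ont1 <- gen_pathway_ontology(cfg1, spiked, net)
  expect_true(all(u %in% ont1$sets[[ont1$planted]]))

  cfg_bad <- ontology_sim_config(n_genes = 300, n_mirnas = 30,
                                 degree_distribution = c(3, 8, 2),
                                 pathway_size_range = c(2, 3),
                                 n_pathways = 5,
                                 planted_pathway_overlap = 1, seed = 9)
  expect_error(gen_pathway_ontology(cfg_bad, spiked, net), "pathway size")
})

test_that("interaction graphs hit requested density and sign fractions", {
  empty <- gen_interaction_graph(50, 1e-9, seed = 1)
  expect_identical(nrow(empty), 0L)
  g <- gen_interaction_graph(150, 10000 / (150 * 149),
                             sign_fractions = c(activating = 0.5,
                                                inhibiting = 0.3,
                                                unknown = 0.2), seed = 11)
  expect_equal(nrow(g), 10000)
  expect_false(any(g$source == g$target))
  expect_false(anyDuplicated(paste(g$source, g$target)) > 0)
  frac <- table(g$sign) / nrow(g)
  expect_lt(abs(frac[["activating"]] - 0.5), 0.02)
  expect_lt(abs(frac[["inhibiting"]] - 0.3), 0.02)
  expect_lt(abs(frac[["unknown"]] - 0.2), 0.02)
})
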