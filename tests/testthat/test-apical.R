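make_wells <- function(chemical, endpoint, plate, conc, values) {
  data.frame(chemical = chemical, concentration_uM = conc, plate = plate,
             well = paste0("w", seq_along(values)), endpoint = endpoint,
             value = values, stringsAsFactors = FALSE)
}

test_that("percent-of-control normalization maps vehicle mean to 100 per plate", {
  df <- rbind(make_wells("X", "ATP", 1, c(0, 0, 10), c(10, 10, 5)))
  norm <- normalize_percent_of_control(df)
  expect_equal(norm$value, c(100, 100, 50))
  # all wells identical -> all 100
  df2 <- make_wells("X", "ATP", 1, c(0, 0, 1, 10), rep(7, 4))
  expect_equal(normalize_percent_of_control(df2)$value, rep(100, 4))
})

test_that("plates with different raw scales pool identically after normalization", {
  p1 <- make_wells("X", "ATP", 1, c(0, 0, 10, 10), c(10, 10, 5, 5))
  p2 <- make_wells("X", "ATP", 2, c(0, 0, 10, 10), 2 * c(10, 10, 5, 5))
  norm <- normalize_percent_of_control(rbind(p1, p2))
  expect_equal(norm$value[norm$plate == 1], norm$value[norm$plate == 2])
  # idempotence
  expect_equal(normalize_percent_of_control(norm)$value, norm$value)
})

test_that("missing vehicle wells abort with the plate and endpoint named", {
  df <- make_wells("X", "neurite_length", 3, c(0, 1, 10), c(9, 5, 2))
  expect_error(normalize_percent_of_control(df), "plate 3.*neurite_length")
})

test_that("Dunnett with one treated group reduces to the pooled two-sample t", {
  set.seed(21)
  x <- rnorm(6, 100, 5); y <- rnorm(6, 90, 5)
  d <- dunnett_test(c(x, y), rep(c("0", "10"), each = 6))
  tt <- t.test(y, x, var.equal = TRUE)
  expect_equal(d$t, unname(tt$statistic), tolerance = 1e-8)
  expect_equal(d$p_adj, tt$p.value, tolerance = 1e-10)
  expect_equal(d$df, unname(tt$parameter))
})

test_that("Dunnett adjusted p is exactly 1 for a zero contrast and errors on zero variance", {
  vals <- c(10, 12, 14, 10, 12, 14, 9, 13, 14, 8, 12, 16)
  g <- rep(c("0", "1", "2", "3"), each = 3)
  # group 2 mean equals control mean exactly
  d <- dunnett_test(vals, g)
  expect_equal(d$p_adj[d$comparison == "1"], 1, tolerance = 1e-6)
  expect_true(all(d$p_adj > 0 & d$p_adj <= 1))
  expect_error(dunnett_test(rep(5, 8), rep(c("0", "1"), each = 4)),
               "zero pooled variance")
})

test_that("Dunnett adjusted p agrees with the multivariate-t computation", {
  skip_if_not_installed("mvtnorm")
  set.seed(5)
  k <- 3; n <- 6
  vals <- rnorm((k + 1) * n, mean = rep(c(0, 0.5, 1, 1.5), each = n))
  g <- rep(as.character(0:k), each = n)
  d <- dunnett_test(vals, g)
  df <- (k + 1) * (n - 1)
  corr <- matrix(0.5, k, k); diag(corr) <- 1
  p_ref <- vapply(abs(d$t), function(a) {
    1 - mvtnorm::pmvt(lower = rep(-a, k), upper = rep(a, k), df = df,
                      corr = corr, algorithm = mvtnorm::GenzBretz(abseps = 1e-5))[1]
  }, numeric(1))
  expect_equal(d$p_adj, p_ref, tolerance = 0.005)
})

test_that("lowest effect concentration picks the smallest significant dose", {
  dn <- data.frame(chemical = "X", endpoint = "neurite_length",
                   concentration_uM = c(0.1, 1, 10),
                   estimate = 0, t = 0, df = 10,
                   p_adj = c(0.2, 0.03, 0.001), stringsAsFactors = FALSE)
  expect_equal(lowest_effect_concentration(dn)$lowest_effect_concentration, 1)
  dn$p_adj <- c(0.2, 0.3, 0.4)
  expect_true(is.na(
    lowest_effect_concentration(dn)$lowest_effect_concentration))
})

test_that("steep morphology decline is detected at the lowest tested dose", {
  ch <- secretomir:::default_apical_chemicals()
  ap <- gen_apical(apical_sim_config(ch[ch$chemical == "COL", ], seed = 2))
  dn <- apical_dunnett(normalize_percent_of_control(ap))
  lec <- lowest_effect_concentration(dn)
  expect_equal(
    lec$lowest_effect_concentration[lec$endpoint == "neurite_length"], 0.1)
  expect_equal(
    lec$lowest_effect_concentration[lec$endpoint == "neurite_count"], 0.1)
})

test_that("endpoint correlation recovers exact linear relations", {
  conds <- expand.grid(chemical = paste0("c", 1:5),
                       concentration_uM = c(1, 10))
  x <- seq(-1, 0.8, length.out = nrow(conds))
  mk <- function(ep, lfc) {
    data.frame(chemical = conds$chemical,
               concentration_uM = conds$concentration_uM, plate = 1,
               well = paste0(ep, seq_len(nrow(conds))), endpoint = ep,
               value = 100 * 2^lfc, stringsAsFactors = FALSE)
  }
  r <- correlate_endpoints(rbind(mk("ATP", x), mk("neurite_length", 2 * x)))
  expect_equal(r$r, 1)
  expect_lte(r$p, 1e-100)
  r2 <- correlate_endpoints(rbind(mk("ATP", x), mk("neurite_length", -x)))
  expect_equal(r2$r, -1)
  expect_error(
    correlate_endpoints(rbind(mk("ATP", x), mk("neurite_length", 0 * x))),
    "zero variance")
})

test_that("sample correlations are close to the population value on average", {
  rs <- vapply(1:300, function(s) {
    set.seed(s)
    x <- rnorm(30); y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(30)
    conds <- data.frame(chemical = paste0("c", 1:30), concentration_uM = 1)
    mk <- function(ep, lfc) {
      data.frame(chemical = conds$chemical, concentration_uM = 1, plate = 1,
                 well = paste0(ep, 1:30), endpoint = ep, value = 100 * 2^lfc,
                 stringsAsFactors = FALSE)
    }
    correlate_endpoints(rbind(mk("a", x), mk("b", y)))$r
  }, numeric(1))
  # E[r] ~ rho (1 - (1 - rho^2)/(2n)) ~ 0.79 at rho = 0.8, n = 30
  expect_lt(abs(mean(rs) - 0.79), 0.02)
})

test_that("concentration selection implements the low/high screening rules", {
  mk_norm <- function(mean_tbl) {
    # mean_tbl: endpoint x concentration pooled means (as percent of control)
    do.call(rbind, lapply(rownames(mean_tbl), function(ep) {
      do.call(rbind, lapply(colnames(mean_tbl), function(cc) {
        data.frame(chemical = "X", concentration_uM = as.numeric(cc),
                   plate = 1, well = "w", endpoint = ep,
                   value = mean_tbl[ep, cc], stringsAsFactors = FALSE)
      }))
    }))
  }
  mk_dunnett <- function(p_tbl) {
    do.call(rbind, lapply(rownames(p_tbl), function(ep) {
      data.frame(chemical = "X", endpoint = ep,
                 concentration_uM = as.numeric(colnames(p_tbl)),
                 estimate = 0, t = 0, df = 10, p_adj = p_tbl[ep, ],
                 stringsAsFactors = FALSE)
    }))
  }
  conc <- c("0.1", "1", "10", "30", "100")
  eps <- c("ATP", "neurite_length")

  # ATP never drops, neurites drop 40% from 0.1 uM -> low 0.1, high 100
  m1 <- rbind(ATP = rep(98, 5), neurite_length = rep(60, 5))
  dimnames(m1) <- list(eps, conc)
  p1 <- rbind(ATP = rep(0.9, 5), neurite_length = rep(1e-4, 5))
  dimnames(p1) <- list(eps, conc)
  out1 <- select_concentrations(mk_norm(m1), mk_dunnett(p1))
  expect_equal(out1$low, 0.1)
  expect_equal(out1$high, 100)
  expect_match(out1$high_rationale, "maximum tested")

  # negative control: no effects anywhere -> no qualifying pair
  m2 <- rbind(ATP = rep(100, 5), neurite_length = rep(99, 5))
  dimnames(m2) <- list(eps, conc)
  p2 <- rbind(ATP = rep(0.8, 5), neurite_length = rep(0.7, 5))
  dimnames(p2) <- list(eps, conc)
  out2 <- select_concentrations(mk_norm(m2), mk_dunnett(p2))
  expect_true(is.na(out2$low) && is.na(out2$high))
  expect_match(out2$low_rationale, "no qualifying low")

  # ATP -50% and neurites -60% at 10 uM, clean below -> low from the <=10
  # tier meeting the rule, high = 10
  m3 <- rbind(ATP = c(100, 95, 50, 45, 40),
              neurite_length = c(95, 70, 40, 35, 30))
  dimnames(m3) <- list(eps, conc)
  p3 <- rbind(ATP = c(0.9, 0.2, 1e-4, 1e-4, 1e-4),
              neurite_length = c(0.6, 1e-3, 1e-5, 1e-5, 1e-5))
  dimnames(p3) <- list(eps, conc)
  out3 <- select_concentrations(mk_norm(m3), mk_dunnett(p3))
  expect_equal(out3$low, 1)
  expect_equal(out3$high, 10)
})

test_that("concentration selection is invariant to well ordering", {
  ch <- secretomir:::default_apical_chemicals()
  ap <- gen_apical(apical_sim_config(ch, seed = 4))
  norm <- normalize_percent_of_control(ap)
  dn <- apical_dunnett(norm)
  base <- select_concentrations(norm, dn)
  set.seed(1)
  perm <- sample(nrow(norm))
  shuffled <- select_concentrations(norm[perm, ], dn[sample(nrow(dn)), ])
  expect_equal(base, shuffled)
})
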