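test_that("peptide areas aggregate by sum and preserve missingness", {
  ev <- make_evidence(
    list(ds = "D1", ch = "sample", prot = "P1", pep = "AAAK", area = 100),
    list(ds = "D1", ch = "sample", prot = "P2", pep = "CCCK", area = 100),
    list(ds = "D1", ch = "sample", prot = "P2", pep = "DDDK", area = 250),
    list(ds = "D1", ch = "sample", prot = "P2", pep = "EEEK", area = 50),
    list(ds = "D1", ch = "control", prot = "P1", pep = "AAAK", area = 30))
  m <- aggregate_protein_intensity(ev, "D1")
  expect_equal(m$sample["P1", "1"], 100)
  expect_equal(m$sample["P2", "1"], 400)
  # P2 absent from the control replicate: missing, never zero
  expect_true(is.na(m$control["P2", "1"]))
  expect_equal(m$control["P1", "1"], 30)
  # mean rule
  mm <- aggregate_protein_intensity(ev, "D1", rule = "mean")
  expect_equal(mm$sample["P2", "1"], mean(c(100, 250, 50)))
  ev$peak_area[1] <- -5
  expect_error(aggregate_protein_intensity(ev, "D1"), "negative")
})

test_that("variance prior: degenerate and hand-solved cases", {
  # identical variances: no excess dispersion, infinite prior df
  fit <- fit_moderated_model(c(1, 1), c(2, 2))
  expect_identical(fit$d0, Inf)
  expect_equal(fit$s0_sq, 1)
  fit2 <- fit_moderated_model(rep(2.5, 10), rep(4, 10))
  expect_identical(fit2$d0, Inf)
  expect_equal(fit2$s0_sq, 2.5)
  expect_error(fit_moderated_model(1, 2), "at least 2")
})

test_that("variance prior recovers known hyperparameters and matches limma", {
  set.seed(101)
  d0_true <- 4; s0_true <- 2; dg <- 4; n <- 2000
  s2 <- s0_true * d0_true / rchisq(n, d0_true) * rchisq(n, dg) / dg
  fit <- fit_moderated_model(s2, dg)
  expect_lt(abs(fit$d0 - d0_true) / d0_true, 0.20)
  expect_lt(abs(fit$s0_sq - s0_true) / s0_true, 0.10)
  # independent cross-check against limma's empirical-Bayes fit
  lf <- limma::fitFDist(s2, df1 = dg)
  expect_equal(fit$d0, lf$df2, tolerance = 1e-6)
  expect_equal(fit$s0_sq, lf$scale, tolerance = 1e-6)
})

make_matrix <- function(sample, control, dataset_id = "D1") {
  structure(list(dataset_id = dataset_id, sample = sample,
                 control = control),
            class = "protein_intensity_matrix")
}

test_that("d0 = 0 reduces the moderated t to the ordinary pooled t", {
  set.seed(7)
  ns <- 4; nprot <- 20
  s <- matrix(2^rnorm(nprot * ns, 18), nprot,
              dimnames = list(sprintf("P%02d", 1:nprot), 1:ns))
  c0 <- matrix(2^rnorm(nprot * ns, 16), nprot,
               dimnames = list(sprintf("P%02d", 1:nprot), 1:ns))
  m <- make_matrix(s, c0)
  res <- test_dataset(m, model = list(d0 = 0, s0_sq = 1))
  for (i in 1:nprot) {
    tt <- t.test(log2(s[i, ]), log2(c0[i, ]), var.equal = TRUE)
    expect_equal(res$t_moderated[res$protein_id == rownames(s)[i]],
                 unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_value[res$protein_id == rownames(s)[i]],
                 tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t matches an independent oracle on random matrices", {
  set.seed(11)
  for (rep in 1:50) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1); np <- sample(3:8, 1)
    s <- matrix(2^rnorm(np * n1, 18, 1), np,
                dimnames = list(sprintf("P%d", 1:np), 1:n1))
    c0 <- matrix(2^rnorm(np * n2, 17, 1), np,
                 dimnames = list(sprintf("P%d", 1:np), 1:n2))
    d0 <- sample(c(1, 3, 10, Inf), 1); s0 <- runif(1, 0.2, 2)
    res <- test_dataset(make_matrix(s, c0), model = list(d0 = d0, s0_sq = s0))
    i <- sample(np, 1)
    o <- oracle_moderated_t(log2(s[i, ]), log2(c0[i, ]), d0, s0)
    expect_equal(res$t_moderated[i], o$t, tolerance = 1e-10)
    expect_equal(res$p_value[i], o$p, tolerance = 1e-10)
    expect_equal(res$delta_log2[i], o$delta, tolerance = 1e-10)
    # shrinkage bounds: posterior variance between s_g^2 and s0^2
    if (is.finite(d0)) {
      spost <- (d0 * s0 + res$d_g[i] * res$s_g_sq[i]) / (d0 + res$d_g[i])
      expect_gte(spost, min(res$s_g_sq[i], s0) - 1e-12)
      expect_lte(spost, max(res$s_g_sq[i], s0) + 1e-12)
    }
  }
})

test_that("null protein gives t = 0, p = 1; thresholds are >= 5 and < 0.01", {
  s <- matrix(2^c(18, 18, 18), 1, dimnames = list("P1", 1:3))
  m <- make_matrix(s, s)
  res <- test_dataset(m, model = list(d0 = 3, s0_sq = 0.5))
  expect_equal(res$t_moderated, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)

  # threshold semantics: FC exactly 5 with p = 0.009 passes,
  # FC 4.9 with tiny p does not
  res_pass <- data.frame(fold_change = 5.0, p_value = 0.009, testable = TRUE)
  res_fail <- data.frame(fold_change = 4.9, p_value = 1e-4, testable = TRUE)
  cfg <- filter_config()
  expect_true(with(res_pass, testable & fold_change >= cfg$fc_min &
                     p_value < cfg$p_max))
  expect_false(with(res_fail, testable & fold_change >= cfg$fc_min &
                      p_value < cfg$p_max))
  # and through the real code path: plant exact fold changes
  s2 <- matrix(rep(1000 * 5, 3), 1, dimnames = list("P1", 1:3))
  c2 <- matrix(rep(1000, 3), 1, dimnames = list("P1", 1:3))
  r2 <- test_dataset(make_matrix(s2, c2), model = list(d0 = Inf, s0_sq = 1e-4))
  expect_equal(r2$fold_change, 5)
  expect_true(r2$significant)
  s3 <- matrix(rep(1000 * 4.9, 3), 1, dimnames = list("P1", 1:3))
  r3 <- test_dataset(make_matrix(s3, c2), model = list(d0 = Inf, s0_sq = 1e-4))
  expect_false(r3$significant)
})

test_that("|t| is monotone in |delta| at fixed variance", {
  c0 <- matrix(2^rep(15, 3), 1, dimnames = list("P1", 1:3))
  deltas <- c(0.5, 1, 2, 4)
  ts <- vapply(deltas, function(d) {
    s <- matrix(2^rep(15 + d, 3), 1, dimnames = list("P1", 1:3))
    test_dataset(make_matrix(s, c0),
                 model = list(d0 = 2, s0_sq = 0.3))$t_moderated
  }, 1)
  expect_true(all(diff(abs(ts)) > 0))
})

test_that("proteins without 2 observations per channel are untestable", {
  s <- matrix(c(2^18, NA, 2^18.2, 2^19, 2^19, 2^19), 2, byrow = TRUE,
              dimnames = list(c("P1", "P2"), 1:3))
  c0 <- matrix(c(2^16, NA, NA, 2^16, 2^16, 2^16), 2, byrow = TRUE,
               dimnames = list(c("P1", "P2"), 1:3))
  res <- test_dataset(make_matrix(s, c0), model = list(d0 = Inf, s0_sq = 1))
  expect_false(res$testable[res$protein_id == "P1"])
  expect_false(res$significant[res$protein_id == "P1"])
  expect_true(res$testable[res$protein_id == "P2"])
})
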