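test_that("standardization gives mean 0, sample variance 1", {
  df <- data.frame(a = c(1, 2, 3), b = c(2, 4, 9))
  z <- standardize(df, c("a", "b"))
  expect_equal(unname(z$z[, "a"]), c(-1, 0, 1))
  expect_equal(unname(z$z[, "b"]), c(-0.8321, -0.2774, 1.1094),
               tolerance = 1e-4)
  for (s in 1:10) {
    set.seed(s)
    d <- as.data.frame(matrix(rlnorm(60), 20))
    z <- standardize(d, names(d))
    expect_lt(max(abs(colMeans(z$z))), 1e-9)
    expect_lt(max(abs(apply(z$z, 2, var) - 1)), 1e-9)
  }
  expect_error(standardize(data.frame(a = c(1, 1, 1)), "a"), "zero-variance")
})

test_that("selection differentials: slope and doubled quadratic term", {
  z <- matrix(c(-1, 0, 1), dimnames = list(NULL, "t"))
  d <- selection_differentials(z, c(0.5, 1, 1.5))
  expect_equal(d$S, 0.5, tolerance = 1e-12)
  d0 <- selection_differentials(z, c(1, 1, 1))
  expect_equal(d0$S, 0); expect_equal(d0$C_ii, 0)
  ## exact parabola through (−1,1), (0,0), (1,1): raw quadratic coef 1
  dq <- selection_differentials(z, c(1, 0, 1))
  expect_equal(dq$C_ii, 2, tolerance = 1e-12)
  expect_equal(selection_differentials(z, c(1, 0, 1), double_C = FALSE)$C_ii,
               1, tolerance = 1e-12)
})

test_that("S equals the covariance of w with the standardized trait", {
  set.seed(42)
  for (rep in 1:20) {
    df <- as.data.frame(matrix(rlnorm(25 * 3), 25))
    z <- standardize(df, names(df))
    w <- relative_fitness(rgamma(25, 2, 2))
    d <- selection_differentials(z, w)
    for (j in 1:3)
      expect_equal(d$S[j], cov(w, z$z[, j]), tolerance = 1e-9)
  }
})

test_that("gradients on constructed surfaces are exact", {
  Z <- orthogonal_traits(40, 2, seed = 1)
  ## pure linear surface: beta recovers the slope, gamma terms vanish
  w <- 1 + 0.3 * Z[, 1]
  g <- selection_gradients(Z, w)
  expect_equal(unname(g$beta), c(0.3, 0), tolerance = 1e-9)
  expect_equal(unname(g$gamma_ii), c(0, 0), tolerance = 1e-9)
  ## pure interaction surface on a 3-level factorial: gamma_12 = 1 exactly
  grid <- expand.grid(z1 = c(-1, 0, 1), z2 = c(-1, 0, 1))
  Zf <- as.matrix(grid)
  gf <- selection_gradients(Zf, 1 + Zf[, 1] * Zf[, 2])
  expect_equal(gf$gamma_ij$estimate, 1, tolerance = 1e-9)
  expect_equal(unname(gf$beta), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(gf$gamma_ii), c(0, 0), tolerance = 1e-9)
  ## 2-level factorial aliases the quadratic columns: named rank error
  Z2 <- as.matrix(expand.grid(z1 = c(-1, 1), z2 = c(-1, 1)))
  expect_error(selection_gradients(rbind(Z2, Z2), c(0, 2, 2, 0, 0, 2, 2, 0)),
               "aliased")
  ## single trait: beta coincides with S
  z1 <- Z[, 1, drop = FALSE]
  expect_equal(unname(selection_gradients(z1, w)$beta),
               selection_differentials(z1, w)$S, tolerance = 1e-12)
})

test_that("with orthogonal traits beta_j equals S_j", {
  Z <- orthogonal_traits(50, 4, seed = 2)
  set.seed(3)
  w <- relative_fitness(rgamma(50, 2, 2))
  expect_equal(unname(selection_gradients(Z, w)$beta),
               selection_differentials(Z, w)$S, tolerance = 1e-9)
})

test_that("gamma_ii doubling is exactly a factor of two", {
  sim <- small_study()
  z <- standardize(sim$plants)
  w <- relative_fitness(sim$plants$total_seeds)
  g2 <- selection_gradients(z, w, double_gamma = TRUE)
  g1 <- selection_gradients(z, w, double_gamma = FALSE)
  expect_equal(g2$gamma_ii, 2 * g1$gamma_ii, tolerance = 1e-12)
  expect_equal(g2$gamma_ij, g1$gamma_ij)   # cross products never doubled
})

test_that("log-model p-values match an independent lm refit", {
  sim <- small_study(n = 50, seed = 4)
  z <- standardize(sim$plants)
  w <- relative_fitness(sim$plants$total_seeds)
  off <- if (any(w == 0)) 1 else 0
  p <- pvalues_log_model(z, w, offset = off)
  df <- data.frame(y = log(w + off), z$z)
  ## oracle: summary.lm on the multiple linear model
  o_beta <- lm_pvalues_oracle(df, y ~ stems_per_plant + racemes_per_stem +
                                flowers_per_raceme + hue + chroma + reflectivity)
  got <- p$p_value[match(paste0("beta.", names(o_beta)), p$coefficient)]
  expect_equal(got, unname(o_beta), tolerance = 1e-8)
  ## oracle: single-trait quadratic model
  o_q <- lm_pvalues_oracle(df, y ~ chroma + I(chroma^2))
  expect_equal(p$p_value[p$coefficient == "S.chroma"],
               lm_pvalues_oracle(df, y ~ chroma)[[1]], tolerance = 1e-8)
  expect_equal(p$p_value[p$coefficient == "C_ii.chroma"], unname(o_q[2]),
               tolerance = 1e-8)
  ## zero fitness with zero offset is a domain error
  w0 <- w; w0[1] <- 0
  expect_error(pvalues_log_model(z, w0, offset = 0), "offset")
  expect_true(all(is.finite(pvalues_log_model(z, w0, offset = 1)$p_value)))
})

test_that("bootstrap CIs are deterministic and collapse on degenerate data", {
  sim <- small_study(n = 40, seed = 5)
  dat <- sim$plants
  dat$.w <- relative_fitness(dat$total_seeds)
  est <- function(d) {
    z <- standardize(d, c("stems_per_plant", "chroma"))
    zc <- selection_coefficients(z, relative_fitness(d$total_seeds))
    zc[c("S.stems_per_plant", "beta.chroma")]
  }
  s <- bootstrap_settings(B = 60, seed = 7)
  ci1 <- bootstrap_cis(dat, est, s)
  ci2 <- bootstrap_cis(dat, est, s)
  expect_identical(ci1, ci2)
  expect_true(all(ci1$ci_lower <= ci1$ci_upper))
  ## identical rows replicated: every replicate yields the same estimate
  one <- dat[rep(1, 40), ]
  est_id <- function(d) c(m = mean(d$total_seeds))
  ci3 <- bootstrap_cis(one, est_id, bootstrap_settings(B = 30, seed = 1))
  expect_equal(ci3$ci_lower, ci3$ci_upper)
  ## an estimator that always fails exhausts retries
  expect_error(
    bootstrap_cis(dat, function(d) if (nrow(d) == nrow(dat) &&
                                       all(d$plant_id == dat$plant_id))
      c(x = 1) else stop("boom"),
      bootstrap_settings(B = 2, seed = 1, max_retries = 3)),
    "redraws")
})

test_that("selection_report is tidy, complete and offset-invariant", {
  sim <- small_study(n = 80, seed = 6)
  s <- bootstrap_settings(B = 25, seed = 2)
  rep1 <- selection_report(sim$plants, sim$visits, default_rates, settings = s)
  blocks <- unique(paste(rep1$species, rep1$basis))
  expect_length(blocks, 7)   # 3 species x 2 bases + all-bee total
  kinds <- table(rep1$coefficient_kind) / 7
  expect_equal(kinds[["S"]], 6); expect_equal(kinds[["beta"]], 6)
  expect_equal(kinds[["C_ii"]], 6); expect_equal(kinds[["gamma_ii"]], 6)
  expect_equal(kinds[["gamma_ij"]], 15)
  expect_false(any(duplicated(
    rep1[, c("species", "basis", "coefficient_kind", "trait_1", "trait_2")])))
  ## estimates do not depend on the log offset (p-values may)
  rep2 <- selection_report(sim$plants, sim$visits, default_rates,
                           settings = s, log_offset = 5)
  expect_equal(rep1$estimate, rep2$estimate, tolerance = 1e-12)
  ## disabling the log model for a species leaves NA p-values there only
  rep3 <- selection_report(sim$plants, sim$visits, default_rates,
                           settings = s, log_model = c("bumble", "all"))
  expect_true(all(is.na(rep3$p_log_model[rep3$species == "honey"])))
  expect_true(all(!is.na(rep3$p_log_model[rep3$species == "bumble"])))
})

test_that("listwise deletion drops incomplete plants with a message", {
  sim <- small_study(n = 50, seed = 8)
  sim$plants$chroma[3] <- NA
  sim$plants$total_seeds[7] <- NA
  expect_message(
    rep <- selection_report(sim$plants, sim$visits, default_rates,
                            settings = bootstrap_settings(B = 5, seed = 1),
                            bases = "total"),
    "listwise deletion dropped 2")
  expect_length(unique(rep$species), 1)
})

test_that("noise-free linear surface is recovered through the whole pipeline", {
  plants <- generate_plants(trait_model(), 100, seed = 12)
  z <- standardize(plants)
  plants$total_seeds <- 500 * (1 + 0.3 * z$z[, "stems_per_plant"])
  w <- relative_fitness(plants$total_seeds)
  g <- selection_gradients(standardize(plants), w)
  expect_equal(unname(g$beta["stems_per_plant"]), 0.3, tolerance = 1e-6)
  expect_lt(max(abs(g$beta[names(g$beta) != "stems_per_plant"])), 1e-6)
})
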