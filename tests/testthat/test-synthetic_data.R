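test_that("trait model validates its configuration", {
  expect_error(trait_model(sds = c(stems_per_plant = 0, racemes_per_stem = 3.41,
                                   flowers_per_raceme = 2.44, hue = 0.476,
                                   chroma = 0.76, reflectivity = 1.11)),
               "sds must be")
  badR <- diag(6); badR[1, 2] <- 0.5        # asymmetric
  expect_error(trait_model(correlation = badR), "symmetric")
  notpsd <- matrix(0.99, 6, 6) * (1 - diag(6)) + diag(6)
  notpsd[1, 2] <- notpsd[2, 1] <- -0.99     # wildly inconsistent signs
  expect_error(trait_model(correlation = notpsd), "semi-definite")
})

test_that("generated plants honour bounds, types and determinism", {
  tm <- trait_model()
  p1 <- generate_plants(tm, 500, seed = 5)
  p2 <- generate_plants(tm, 500, seed = 5)
  expect_identical(p1, p2)
  expect_true(all(p1$stems_per_plant >= 1))
  expect_true(all(p1$stems_per_plant == round(p1$stems_per_plant)))
  expect_true(all(p1$chroma > 0))
  expect_true(all(p1$racemes_per_stem > 0))
  expect_error(generate_plants(tm, 1, seed = 1), "n_plants")
})

test_that("moment calibration: marginals match the field means and SDs", {
  p <- generate_plants(trait_model(), 10000, seed = 1)
  targets <- list(
    racemes_per_stem = c(4.93, 3.41), stems_per_plant = c(30.65, 16.4),
    flowers_per_raceme = c(7.53, 2.44), hue = c(-0.012, 0.476),
    chroma = c(1.29, 0.76), reflectivity = c(3.76, 1.11))
  for (tr in names(targets)) {
    m <- targets[[tr]][1]; s <- targets[[tr]][2]
    expect_lt(abs(mean(p[[tr]]) - m), 2 * s / sqrt(10000))
    expect_lt(abs(sd(p[[tr]]) - s), 0.05 * s)
  }
})

test_that("identity correlation yields uncorrelated traits at large n", {
  p <- generate_plants(trait_model(), 50000, seed = 2)
  C <- cor(p[, trait_names()])
  expect_lt(max(abs(C[upper.tri(C)])), 3.5 / sqrt(50000) + 0.005)
})

test_that("a requested trait correlation is induced", {
  R <- diag(6); R[2, 3] <- R[3, 2] <- 0.6
  p <- generate_plants(trait_model(correlation = R), 20000, seed = 3)
  expect_lt(abs(cor(p$racemes_per_stem, p$flowers_per_raceme) - 0.6), 0.03)
})

test_that("visits: no preference means exchangeable counts; intercepts set the mix", {
  plants <- generate_plants(trait_model(), 2000, seed = 4)
  v <- generate_visits(plants, preference_model(), seed = 4)
  expect_true(all(v$flowers_visited >= 0))
  expect_true(all(v$flowers_visited == round(v$flowers_visited)))
  tot <- tapply(v$flowers_visited, v$species, sum)
  shares <- tot / sum(tot)
  expect_lt(abs(shares[["bumble"]] - 0.523), 0.02)
  expect_lt(abs(shares[["honey"]] - 0.450), 0.02)
  expect_lt(abs(shares[["leafcutting"]] - 0.027), 0.01)
  expect_lt(abs(sum(tot) - 8727), 4 * sqrt(8727))   # Poisson total
  ## per-plant means equal across plants up to Monte-Carlo error: regressing
  ## counts on any trait finds nothing
  vb <- v[v$species == "bumble", ]
  expect_gt(cor.test(plants$stems_per_plant, vb$flowers_visited)$p.value, 1e-3)
})

test_that("a positive stem preference induces a positive visit correlation", {
  plants <- generate_plants(trait_model(), 5000, seed = 6)
  pm <- preference_model(linear = list(bumble = c(stems_per_plant = 0.5)))
  v <- generate_visits(plants, pm, seed = 6)
  vb <- v[v$species == "bumble", ]
  expect_gt(cor(plants$stems_per_plant, vb$flowers_visited), 0.1)
  ## other species unaffected in sign beyond noise
  vh <- v[v$species == "honey", ]
  expect_lt(abs(cor(plants$stems_per_plant, vh$flowers_visited)), 0.05)
})

test_that("seed generation follows the tripping arithmetic", {
  plants <- tiny_plants()[1, ]
  visits <- data.frame(plant_id = 1,
                       species = c("bumble", "honey", "leafcutting"),
                       flowers_visited = c(10, 10, 5))
  ym <- yield_model(kappa = 2, noise = FALSE)
  gen <- generate_seeds(plants, visits, ym)
  expect_equal(gen$seeds$total_seeds, 2 * (5.5 + 2.5 + 4.0))   # = 24
  expect_equal(gen$truth$expected_tripped, c(5.5, 2.5, 4.0))
  ## zero visits everywhere -> zero seeds
  visits0 <- visits; visits0$flowers_visited <- 0L
  expect_equal(generate_seeds(plants, visits0, ym)$seeds$total_seeds, 0)
  ## misalignment is an error
  bad <- visits; bad$plant_id <- 99
  expect_error(generate_seeds(plants, bad, ym), "misaligned")
})

test_that("with noise on, mean seed set matches the truth expectation", {
  sim <- simulate_study(n_plants = 10000, seed = 8)
  mu <- tapply(sim$truth$expected_seeds, sim$truth$plant_id, sum)
  mu <- as.numeric(mu[as.character(sim$plants$plant_id)])
  se <- sd(sim$plants$total_seeds) / sqrt(length(mu))
  expect_lt(abs(mean(sim$plants$total_seeds) - mean(mu)), 2 * se)
})

test_that("noise-off chain conserves species contributions exactly", {
  tm <- trait_model()
  plants <- generate_plants(tm, 40, seed = 9)
  visits <- generate_visits(plants, preference_model(), seed = 9)
  gen <- generate_seeds(plants, visits, yield_model(noise = FALSE))
  plants$total_seeds <- gen$seeds$total_seeds
  ft <- fitness_table(plants, visits, default_rates, bases = "tripped")
  truth <- gen$truth[order(gen$truth$species, gen$truth$plant_id), ]
  ft <- ft[order(ft$species, ft$plant_id), ]
  expect_equal(ft$attributed_seeds, truth$expected_seeds, tolerance = 1e-9)
})

test_that("calibration fixture (N = 153) reproduces printed trait means within 2 SE", {
  sim <- simulate_study(n_plants = 153, seed = 10)
  targets <- list(
    racemes_per_stem = c(4.93, 3.41), stems_per_plant = c(30.65, 16.4),
    flowers_per_raceme = c(7.53, 2.44), hue = c(-0.012, 0.476),
    chroma = c(1.29, 0.76), reflectivity = c(3.76, 1.11))
  for (tr in names(targets))
    expect_lt(abs(mean(sim$plants[[tr]]) - targets[[tr]][1]),
              2 * targets[[tr]][2] / sqrt(153))
})
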