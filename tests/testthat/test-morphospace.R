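test_that("achievable octave range reproduces the worked morphospace points", {
  # frozen from log2((1/x) * exp(0.5 * B * 0.7 * (x - 1)))
  expect_equal(achievable_octaves(10, 1.5), 1.93975382083453, tolerance = 1e-12)
  expect_equal(achievable_octaves(10, 2), 4.049432643111372, tolerance = 1e-12)
  expect_equal(achievable_octaves(7, 2.5), 3.979976180379578, tolerance = 1e-12)
  # no stress gain: doubling length halves frequency
  expect_equal(achievable_octaves(0, 2), -1)
  expect_equal(achievable_octaves(5, 1), 0)
  expect_error(achievable_octaves(-1, 2), class = "vocalrange_domain_error")
  expect_error(achievable_octaves(10, 0.9), class = "vocalrange_domain_error")
})

test_that("required_B closed form matches its derivation and flags infeasibility", {
  # human male: ratio 5 (100-500 Hz) at L2/L1 = 1.7
  expect_equal(required_B(1.7, 5), 2 * log(5 * 1.7) / (0.7 * 0.7))
  expect_equal(required_B(1.7, 5), 8.734963932637841, tolerance = 1e-12)
  # four octaves at L2/L1 = 2: 2*ln(32)/0.7
  expect_equal(required_B(2, 16), 2 * log(32) / 0.7, tolerance = 1e-12)
  # B = 0 limit: target equal to the inverse length ratio
  expect_equal(required_B(2, 0.5), 0)
  # below that, no fibrous gain is needed at all
  b <- required_B(2, 0.3)
  expect_lt(b, 0)
  expect_true(isTRUE(attr(b, "infeasible_for_fibrous_gain")))
  expect_error(required_B(1, 5), class = "vocalrange_domain_error")
})

test_that("required_length_ratio solves the printed species inversions", {
  # male rhesus monkey: B = 16.2, four octaves -> ratio ~1.6
  expect_equal(round(required_length_ratio(16.2, 16), 1), 1.6)
  expect_equal(required_length_ratio(16.2, 16), 1.5683635785, tolerance = 1e-6)
  # tiger: B = 8.5, four octaves -> ratio ~2.2
  expect_equal(round(required_length_ratio(8.5, 16), 1), 2.2)
  expect_equal(required_length_ratio(8.5, 16), 2.1964469810, tolerance = 1e-6)
})

test_that("inversions refuse outside their domain of uniqueness", {
  # at or below B = 2/l1_fraction the surface is non-monotone
  expect_error(required_length_ratio(2.8, 16), "monoton",
               class = "vocalrange_domain_error")
  expect_error(required_length_ratio(2 / 0.5, 16, l1_fraction = 0.5),
               class = "vocalrange_domain_error")
  # a target beyond the reach of the [1, 10] bracket
  expect_error(required_length_ratio(3, 1e6), class = "vocalrange_infeasible_error")
  expect_error(required_length_ratio(16.2, 0.5), class = "vocalrange_domain_error")
})

test_that("required_B and required_length_ratio invert achievable_octaves", {
  set.seed(202)
  for (i in 1:25) {
    l1f <- runif(1, 0.5, 1)
    x <- runif(1, 1.05, 3)
    target <- runif(1, 1.5, 30)
    b <- required_B(x, target, l1f)
    if (b >= 0) {
      expect_equal(achievable_octaves(b, x, l1f), log2(target), tolerance = 1e-9)
    }
    b2 <- runif(1, 2 / l1f * 1.2, 18)
    target2 <- runif(1, 1.5, min(30, 2^achievable_octaves(b2, 9.9, l1f)))
    if (target2 > 1) {
      x2 <- required_length_ratio(b2, target2, l1f)
      expect_equal(achievable_octaves(b2, x2, l1f), log2(target2),
                   tolerance = 1e-6)
    }
  }
})

test_that("the octave surface grid is consistent and monotone in B", {
  grid <- morphospace_grid(b_values = seq(2, 16, by = 1),
                           ratio_values = seq(1, 2.5, by = 0.25))
  expect_s3_class(grid, "morphospace_grid")
  expect_equal(dim(grid$octave_surface), c(15, 7))
  # cells agree with the scalar operation
  expect_equal(grid$octave_surface["10", "2"], achievable_octaves(10, 2))
  # ratio = 1 column: no elongation, no range
  expect_true(all(grid$octave_surface[, "1"] == 0))
  # non-decreasing along the B axis at every fixed ratio
  expect_true(all(apply(grid$octave_surface, 2, function(col) all(diff(col) >= 0))))
  # strictly increasing wherever there is real elongation
  expect_true(all(apply(grid$octave_surface[, -1], 2,
                        function(col) all(diff(col) > 0))))
})

test_that("degenerate and unsorted grid axes are rejected", {
  expect_error(morphospace_grid(numeric(0), c(1, 2)),
               class = "vocalrange_domain_error")
  expect_error(morphospace_grid(c(5, 3), c(1, 2)), "ascending",
               class = "vocalrange_domain_error")
  expect_error(morphospace_grid(c(3, 5), c(2, 1)), "ascending",
               class = "vocalrange_domain_error")
  one <- morphospace_grid(10, 2)
  expect_equal(as.numeric(one$octave_surface), 4.049432643111372,
               tolerance = 1e-12)
})

test_that("grid CSV export carries both axes and the surface", {
  grid <- morphospace_grid(c(5, 10), c(1.5, 2, 2.5))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_grid_csv(grid, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(names(back), c("B", "1.5", "2", "2.5"))
  expect_equal(back$B, c(5, 10))
  expect_equal(back[["2"]], as.numeric(grid$octave_surface[, "2"]),
               tolerance = 1e-6)
})

test_that("species placement finds the elongation each B value needs", {
  tab <- load_species_table()
  placed <- place_species(tab, target_octaves = 4)
  expect_equal(nrow(placed), 11)  # records with a measured stress law
  rhesus_m <- placed[placed$species == "Rhesus monkey" & placed$sex == "male", ]
  expect_equal(round(rhesus_m$required_ratio, 1), 1.6)
  # higher B always needs less elongation for the same target
  expect_true(all(diff(placed$required_ratio[order(placed$stress_B)]) < 0))
})
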