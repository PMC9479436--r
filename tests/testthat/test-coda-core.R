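# Simplex geometry: closure, zero replacement, perturbation,
# compositional means, balances and ternary constructs.

test_that("closure rescales, is idempotent and rejects degenerate input", {
  x <- c(sleep = 478, sed = 672, lpa = 239, mvpa = 50)
  cl <- close_composition(x, 1)
  expect_equal(unname(cl), unname(x / 1439))
  expect_equal(sum(cl), 1)
  expect_equal(close_composition(c(1, 1, 1, 1), 1440), rep(360, 4))
  expect_equal(close_composition(cl, 1), cl)  # idempotent
  m <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40), 2, byrow = TRUE)
  expect_equal(rowSums(close_composition(m, 1440)), c(1440, 1440))
  expect_error(close_composition(c(0, 0, 0, 0)), "all-zero")
  expect_error(close_composition(c(-1, 2, 3, 4)), "nonnegative")
})

test_that("multiplicative zero replacement matches the hand formula and preserves totals", {
  x <- c(500, 700, 240, 0)
  out <- replace_zeros(x, detection_limit = 1)
  scale <- (1440 - 0.65) / 1440
  expect_equal(out, c(500 * scale, 700 * scale, 240 * scale, 0.65))
  expect_equal(sum(out), 1440)
  # identity on zero-free input
  y <- c(480, 660, 250, 50)
  expect_identical(replace_zeros(y), y)
  # totals preserved row-wise on a matrix with several zero patterns
  m <- rbind(c(500, 700, 240, 0), c(700, 0, 740, 0), c(480, 660, 250, 50))
  rep_m <- replace_zeros(m)
  expect_equal(rowSums(rep_m), rowSums(m))
  expect_true(all(rep_m > 0))
  expect_error(replace_zeros(c(0, 0, 0, 0)), "entirely zero")
})

test_that("perturbation difference reproduces the published change composition", {
  post <- c(515, 667, 217, 42)
  pre <- c(478, 672, 239, 50)
  d <- perturb_diff(post, pre)
  expect_equal(unname(d), c(0.2822, 0.2600, 0.2378, 0.2200), tolerance = 1e-4)
  # identity and group property
  expect_equal(unname(perturb_diff(pre, pre)), rep(0.25, 4))
  expect_equal(perturb(pre, d, 1), close_composition(post, 1), tolerance = 1e-12)
})

test_that("perturbation satisfies the group laws on random compositions", {
  xs <- random_compositions(20, seed = 42)
  neutral <- rep(0.25, 4)
  for (i in seq_len(10)) {
    x <- xs[2 * i - 1, ]; y <- xs[2 * i, ]
    expect_equal(perturb(x, neutral, 1), close_composition(x, 1), tolerance = 1e-12)
    expect_equal(unname(perturb(x, perturb_inverse(x), 1)), neutral, tolerance = 1e-12)
    expect_equal(perturb(perturb(x, y, 1), neutral, 1),
                 perturb(x, perturb(y, neutral, 1), 1), tolerance = 1e-12)
  }
})

test_that("compositional mean is the closed geometric mean and commutes with perturbation", {
  m <- rbind(c(400, 700, 290, 50), c(500, 700, 190, 50))
  got <- compositional_mean(m, kappa = 1440)
  hand <- c(sqrt(400 * 500), 700, sqrt(290 * 190), 50)
  expect_equal(unname(got), hand / sum(hand) * 1440, tolerance = 1e-12)
  # permutation invariance, single observation, n copies
  expect_equal(compositional_mean(m[2:1, ]), got)
  one <- c(480, 660, 250, 50)
  expect_equal(unname(compositional_mean(rbind(one))), one, tolerance = 1e-12)
  expect_equal(unname(compositional_mean(rbind(one, one, one))), one, tolerance = 1e-12)
  # mean(p (+) x_i) = p (+) mean(x_i)
  xs <- random_compositions(12, seed = 7)
  p <- c(1.2, 0.8, 1.5, 0.6)
  lhs <- compositional_mean(perturb(xs, p, 1), kappa = 1)
  rhs <- perturb(compositional_mean(xs, kappa = 1), p, 1)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(compositional_mean(matrix(0, 0, 4)), "empty")
})

test_that("the default partition is valid and non-nested sign tables are rejected", {
  s <- default_sbp()
  expect_identical(dim(unclass(s)), c(3L, 4L))
  expect_identical(rownames(s),
                   c("active_vs_passive", "lpa_vs_mvpa", "sed_vs_sleep"))
  # row 2 splits {lpa, mvpa}: both positive in row 1; row 3 splits the negatives
  expect_error(sbp(rbind(c(-1, -1, 1, 1), c(1, 0, -1, 0), c(-1, 1, 0, 0))),
               "not nested")
  expect_error(sbp(rbind(c(1, 1, 1, 1), c(0, 0, 1, -1), c(-1, 1, 0, 0))),
               "positive and one negative")
})

test_that("balance coordinates match the published worked example and basic symmetries", {
  z <- ilr_transform(c(478, 672, 239, 50))
  expect_equal(unname(z[1]), sqrt(1) * log(sqrt(239 * 50) / sqrt(478 * 672)),
               tolerance = 1e-12)
  expect_equal(unname(z), c(-1.646, 1.106, 0.241), tolerance = 1e-3)
  expect_equal(unname(ilr_transform(rep(360, 4))), c(0, 0, 0))
  # scale invariance
  x <- c(478, 672, 239, 50)
  expect_equal(ilr_transform(x), ilr_transform(close_composition(x, 1)),
               tolerance = 1e-12)
  expect_error(ilr_transform(c(1, 0, 1, 1)), "replace_zeros")
})

test_that("balance transform agrees with an independent basis-matrix oracle", {
  s <- default_sbp()
  xs <- random_compositions(100, seed = 11)
  for (i in seq_len(nrow(xs))) {
    expect_equal(unname(ilr_transform(xs[i, ], s)),
                 unname(oracle_ilr(xs[i, ], unclass(s))), tolerance = 1e-10)
  }
})

test_that("ilr inverse is exact and maps the origin to equal parts", {
  expect_equal(unname(ilr_inverse(c(0, 0, 0), kappa = 1440)), rep(360, 4))
  xs <- random_compositions(25, seed = 3)
  for (i in seq_len(nrow(xs))) {
    x <- xs[i, ]
    expect_equal(unname(ilr_inverse(ilr_transform(x), kappa = 1)),
                 unname(close_composition(x, 1)), tolerance = 1e-10)
  }
  z <- ilr_transform(c(478, 672, 239, 50))
  expect_equal(unname(ilr_inverse(z, kappa = 1440)),
               unname(close_composition(c(478, 672, 239, 50), 1440)),
               tolerance = 1e-10)
})

test_that("sub-compositions enumerate closed leave-one-out triples coherently", {
  x <- c(sleep = 400, sed = 600, lpa = 300, mvpa = 140)
  subs <- subcompositions(x)
  expect_length(subs, 4)
  expect_named(subs, c("sed_lpa_mvpa", "sleep_lpa_mvpa", "sleep_sed_mvpa",
                       "sleep_sed_lpa"))
  for (s in subs) expect_equal(sum(s), 1)
  # subcompositional coherence: within-triple ratios equal parent ratios
  tri <- subs[["sleep_sed_lpa"]]
  expect_equal(tri[["sleep"]] / tri[["sed"]], 400 / 600, tolerance = 1e-12)
  expect_equal(tri[["sed"]] / tri[["lpa"]], 600 / 300, tolerance = 1e-12)
})

test_that("ternary coordinates map vertices, centroid, and ignore scale", {
  expect_equal(unname(ternary_coords(c(1, 0, 0))), c(0, 0))
  expect_equal(unname(ternary_coords(c(0, 1, 0))), c(1, 0))
  expect_equal(unname(ternary_coords(c(0, 0, 1))), c(0.5, sqrt(3) / 2))
  expect_equal(unname(ternary_coords(c(1, 1, 1) / 3)), c(0.5, sqrt(3) / 6))
  x <- c(0.2, 0.5, 0.3)
  expect_equal(ternary_coords(x * 1440), ternary_coords(x), tolerance = 1e-12)
})

test_that("confidence regions collapse for identical samples and are seed-stable", {
  same <- matrix(rep(c(0.3, 0.5, 0.2), 10), ncol = 3, byrow = TRUE)
  reg <- confidence_region(same, seed = 4)
  expect_true(reg$degenerate)
  expect_equal(unname(reg$center), c(0.3, 0.5, 0.2), tolerance = 1e-10)
  expect_true(region_contains(reg, c(0.3, 0.5, 0.2)))

  set.seed(21)
  x <- ilr_inverse(cbind(rnorm(40, 0, 0.3), rnorm(40, 0, 0.2)),
                   triple_sbp <- sbp(rbind(c(1, -1, -1), c(0, 1, -1))), kappa = 1)
  r1 <- confidence_region(x, n_boot = 300, seed = 9)
  r2 <- confidence_region(x, n_boot = 300, seed = 9)
  expect_identical(r1$boundary, r2$boundary)
  # doubling n_boot leaves the centre within tolerance
  r3 <- confidence_region(x, n_boot = 600, seed = 9)
  expect_equal(r1$center, r3$center, tolerance = 0.02)
  # boundary closes to a loop and the centre is inside
  expect_equal(r1$boundary[1, ], r1$boundary[nrow(r1$boundary), ])
  expect_true(region_contains(r1, r1$center))
})

test_that("log-contrast outlier screen flags a planted aberrant change only", {
  set.seed(6)
  n <- 40
  mu <- ilr_transform(c(478, 672, 239, 50))
  pre <- ilr_inverse(matrix(rnorm(n * 3, 0, 0.2), n, 3) +
                       matrix(rep(mu, each = n), n, 3), kappa = 1440)
  # each participant drifts by a common change plus individual variation
  post_z <- ilr_transform(pre) +
    matrix(rep(c(-0.1, 0.05, -0.05), each = n), n, 3) +
    matrix(rnorm(n * 3, 0, 0.1), n, 3)
  post <- ilr_inverse(post_z, kappa = 1440)
  # no-change cohort: nothing flagged
  expect_false(any(flag_outliers(pre, pre)))
  # plant one participant whose post SED/sleep ratio blows up 20-fold
  post[7, "sed"] <- post[7, "sed"] * 20
  flags <- flag_outliers(pre, post)
  expect_true(flags[7])
  expect_equal(sum(flags), 1)
  # invariance to the closure constant
  flags_scaled <- flag_outliers(close_composition(pre, 1), close_composition(post, 1))
  expect_identical(as.vector(flags), as.vector(flags_scaled))
  # small cohorts disable screening with a warning
  expect_warning(small <- flag_outliers(pre[1:5, ], post[1:5, ]), "disabled")
  expect_false(any(small))
})
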