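test_that("energy-weighted closure matches hand arithmetic and stays on the simplex", {
  x <- energy_shares(c(80, 250, 20, 25, 15))
  # kcal (320, 1000, 180, 225, 135), total 1860
  expect_equal(unname(x),
               c(320, 1000, 180, 225, 135) / 1860, tolerance = 1e-12)
  expect_equal(sum(x), 1, tolerance = 1e-12)

  # equal energies -> uniform composition
  u <- energy_shares(c(9, 9, 4, 4, 4) * 5)
  expect_equal(unname(u), rep(0.2, 5), tolerance = 1e-12)

  expect_error(energy_shares(c(0, 250, 20, 25, 15)), "positive")
  expect_error(energy_shares(c(80, 250, 20, 25)), "5-part")
})

test_that("closure is scale invariant and idempotent", {
  expect_equal(closure(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  v <- c(1.2, 0.4, 3.3, 0.1)
  expect_equal(closure(17 * v), closure(v), tolerance = 1e-14)
  expect_equal(closure(closure(v)), closure(v), tolerance = 1e-14)
  expect_equal(closure(rep(1, 5)), rep(0.2, 5))
  expect_error(closure(c(1, -1, 2)))
})

test_that("alr matches hand logs and round-trips", {
  expect_equal(alr(rep(0.2, 5)), rep(0, 4))
  expect_equal(alr(c(0.4, 0.2, 0.2, 0.1, 0.1)),
               c(log(4), log(2), log(2), 0), tolerance = 1e-12)
  comps <- random_compositions(1000, 5, seed = 1)
  for (i in seq_len(nrow(comps))) {
    expect_equal(alr_inv(alr(comps[i, ])), comps[i, ], tolerance = 1e-10)
  }
})

test_that("balance bases are orthonormal with zero row sums and the right pivot", {
  for (focal in c("default", macro_parts())) {
    B <- make_basis(5, focal)
    expect_equal(B %*% t(B), diag(4), tolerance = 1e-10)
    expect_equal(rowSums(B), rep(0, 4), tolerance = 1e-12)
  }
  expect_equal(unname(make_basis(2)[1, ]), c(sqrt(0.5), -sqrt(0.5)))
  # focal pivot formula oracle: z1 = sqrt(4/5) log(x_f / gmean(rest))
  x <- c(0.18, 0.54, 0.10, 0.12, 0.06)
  z <- ilr(x, make_basis(5, "protein"))
  expect_equal(z[1], 0.2220978483, tolerance = 1e-8)
  expect_error(make_basis(5, 9), "focal")
  expect_error(make_basis(1), "integer")
})

test_that("ilr round-trips and is an isometry across bases", {
  B1 <- make_basis(5, "default")
  comps <- random_compositions(1000, 5, seed = 2)
  for (i in seq_len(nrow(comps))) {
    expect_equal(ilr_inv(ilr(comps[i, ], B1), B1), comps[i, ], tolerance = 1e-10)
  }
  expect_equal(ilr(rep(0.2, 5), B1), rep(0, 4), tolerance = 1e-12)
  B2 <- make_basis(5, "polyunsaturated")
  set.seed(3)
  for (k in 1:25) {
    xy <- random_compositions(2, 5)
    d1 <- sqrt(sum((ilr(xy[1, ], B1) - ilr(xy[2, ], B1))^2))
    d2 <- sqrt(sum((ilr(xy[1, ], B2) - ilr(xy[2, ], B2))^2))
    expect_equal(d1, d2, tolerance = 1e-10)
  }
})

test_that("variation matrix matches a brute-force pair loop and its limits", {
  comps <- rbind(c(0.2, 0.3, 0.5), c(0.1, 0.4, 0.5), c(0.25, 0.25, 0.5))
  T <- variation_matrix(comps)
  # frozen from an independent pairwise-variance loop
  expect_equal(T[1, 2], 0.50804000552, tolerance = 1e-9)
  expect_equal(T[1, 3], 0.22830579395, tolerance = 1e-9)
  expect_equal(T[2, 3], 0.05615092273, tolerance = 1e-9)
  expect_equal(T, t(T))
  expect_equal(diag(T), rep(0, 3))
  # perfectly proportional parts -> zero entry
  prop <- random_compositions(20, 4, seed = 4)
  prop[, 1] <- 2 * prop[, 2]
  prop <- prop / rowSums(prop)
  expect_equal(variation_matrix(prop)[1, 2], 0, tolerance = 1e-12)
  expect_error(variation_matrix(comps[1, , drop = FALSE]), "2 samples")
})

test_that("compositional mean: dual-route oracle, permutation and perturbation equivariance", {
  comps <- random_compositions(2, 5, seed = 5)
  m1 <- compositional_mean(comps)
  # independent route 1: closure of sqrt(x * y)
  expect_equal(unname(m1), unname(closure(sqrt(comps[1, ] * comps[2, ]))),
               tolerance = 1e-12)
  # independent route 2: ilr_inv of the mean ilr coordinate (any basis)
  B <- make_basis(5, "saturated")
  m2 <- ilr_inv(colMeans(ilr(comps, B)), B)
  expect_equal(unname(m1), unname(m2), tolerance = 1e-10)

  many <- random_compositions(30, 5, seed = 6)
  expect_equal(compositional_mean(many), compositional_mean(many[30:1, ]))
  expect_equal(unname(compositional_mean(many[c(1, 1, 1), ])), unname(closure(many[1, ])),
               tolerance = 1e-12)
  # perturbing every row by a fixed composition perturbs the mean likewise
  p <- c(0.4, 0.1, 0.2, 0.2, 0.1)
  pert <- t(apply(many, 1, function(r) closure(r * p)))
  expect_equal(unname(compositional_mean(pert)),
               unname(closure(compositional_mean(many) * p)), tolerance = 1e-10)
})

test_that("proportional reallocation matches hand arithmetic and conserves closure", {
  x <- c(0.18, 0.54, 0.10, 0.12, 0.06)
  names(x) <- macro_parts()
  up <- reallocate(x, realloc_spec("protein", 0.06, "add"))
  expect_equal(unname(up), c(0.24, 0.5004878, 0.0926829, 0.1112195, 0.0556098),
               tolerance = 1e-6)
  dn <- reallocate(x, realloc_spec("protein", 0.06, "take"))
  expect_equal(unname(dn), c(0.12, 0.5795122, 0.1073171, 0.1287805, 0.0643902),
               tolerance = 1e-6)
  expect_equal(sum(up), 1, tolerance = 1e-12)
  expect_equal(sum(dn), 1, tolerance = 1e-12)
  expect_equal(reallocate(x, realloc_spec("protein", 0, "add")), x)
  # same-focal add-then-take inverts exactly (reciprocal scale factors) ...
  back <- reallocate(up, realloc_spec("protein", 0.06, "take"))
  expect_equal(back, x, tolerance = 1e-12)
  # ... but interleaved reallocations across different focal parts do not
  mixed <- reallocate(reallocate(reallocate(reallocate(x,
    realloc_spec("protein", 0.05, "add")),
    realloc_spec("carbohydrate", 0.05, "add")),
    realloc_spec("protein", 0.05, "take")),
    realloc_spec("carbohydrate", 0.05, "take"))
  expect_gt(max(abs(mixed - x)), 1e-6)
  expect_error(reallocate(x, realloc_spec("polyunsaturated", 0.07, "take")), "cap")
})

test_that("pairwise substitution moves exactly delta and leaves others untouched", {
  x <- c(0.18, 0.54, 0.10, 0.115, 0.065)
  names(x) <- macro_parts()
  y <- substitute_pairwise(x, "polyunsaturated", "protein", 0.06)
  expect_equal(unname(y), c(0.24, 0.54, 0.10, 0.115, 0.005), tolerance = 1e-12)
  expect_identical(y[2:4], x[2:4])
  expect_equal(sum(y), 1, tolerance = 1e-15)
  expect_equal(substitute_pairwise(x, "protein", "carbohydrate", 0), x)
  expect_equal(substitute_pairwise(x, "protein", "protein", 0.05), x)
  expect_error(substitute_pairwise(x, "polyunsaturated", "protein", 0.066), "donor")
})
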