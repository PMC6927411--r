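test_that("symmetrized features are exactly permutation invariant", {
  bs <- basis_spec(2)
  d <- sample_dimer_set(1, c(3.0, 3.5), seed = 81)[[1]]
  f0 <- build_basis(d, bs)
  swap_mol <- configuration(d$coords[c(4:6, 1:3), ], validate = FALSE)
  expect_lt(max(abs(build_basis(swap_mol, bs) - f0)), 1e-14)
  swap_h <- configuration(d$coords[c(1, 3, 2, 4, 5, 6), ], validate = FALSE)
  expect_lt(max(abs(build_basis(swap_h, bs) - f0)), 1e-14)

  bs3 <- basis_spec(3)
  tr <- sample_trimer_set(1, c(2.8, 4.0), seed = 82)[[1]]
  f3 <- build_basis(tr, bs3)
  perm <- configuration(tr$coords[c(7:9, 1:3, 4:6), ], validate = FALSE)
  expect_lt(max(abs(build_basis(perm, bs3) - f3)), 1e-14)
})

test_that("features vanish beyond the outer switching radius", {
  bs <- basis_spec(2)
  far <- sample_dimer_set(1, c(bs$sw_out + 0.5, bs$sw_out + 1), seed = 83)[[1]]
  expect_equal(max(abs(build_basis(far, bs))), 0)
  expect_error(build_basis(random_cluster(3, seed = 1), bs), "molecules")
})

test_that("feature count equals the Burnside orbit-count oracle", {
  # independent enumeration: count orbits of degree<=d monomials under the
  # pair-permutation group via Burnside's lemma on the explicit group
  burnside_orbits <- function(order, degree) {
    pg <- mbwater:::.pair_group(order)
    mons <- mbwater:::.monomials(length(pg[[1]]), degree)
    fixed <- vapply(pg, function(p) {
      img <- mons
      img[, p] <- mons                       # exponent vector under g
      sum(rowSums(img != mons) == 0L)
    }, numeric(1))
    sum(fixed) / length(pg)
  }
  expect_equal(length(mbwater:::.pip_structure(2, 3)$orbit_size),
               burnside_orbits(2, 3))
  expect_equal(length(mbwater:::.pip_structure(3, 2)$orbit_size),
               burnside_orbits(3, 2))
})

test_that("in-basis targets are recovered to numerical precision", {
  bs <- basis_spec(2)
  dimers <- sample_dimer_set(200, c(2.5, 7.0), seed = 84)
  # labels from a synthetic coefficient vector inside the basis
  nfeat <- length(build_basis(dimers[[1]], bs))
  set.seed(9)
  beta <- rnorm(nfeat, 0, 0.3)
  X <- t(vapply(dimers, build_basis, numeric(nfeat), spec = bs))
  lab <- structure(list(configs = dimers, energies = as.vector(X %*% beta),
                        order = 2L, level_tag = "synthetic",
                        noise_sigma = 0),
                   class = "mbw_labeled_set")
  ft <- fit_term(lab, bs, ridge = 1e-12)
  expect_lt(ft$training_stats$rmsd, 1e-8)
})

test_that("noisy labels give residuals near the noise floor", {
  bs <- basis_spec(2, degree = 2)
  dimers <- sample_dimer_set(600, c(2.8, 7.0), seed = 85)
  nfeat <- length(build_basis(dimers[[1]], bs))
  set.seed(10)
  beta <- rnorm(nfeat, 0, 0.3)
  X <- t(vapply(dimers, build_basis, numeric(nfeat), spec = bs))
  sigma <- 0.2
  y <- as.vector(X %*% beta) + rnorm(length(dimers), 0, sigma)
  lab <- structure(list(configs = dimers, energies = y, order = 2L,
                        level_tag = "synthetic", noise_sigma = sigma),
                   class = "mbw_labeled_set")
  ft <- fit_term(lab, bs, ridge = 1e-10)
  expect_lt(ft$training_stats$rmsd, sigma * 1.05)
  expect_gt(ft$training_stats$rmsd, sigma * 0.8)
})

test_that("duplicating the training set leaves the fit unchanged", {
  pot <- truth_pot()
  dimers <- sample_dimer_set(200, c(2.5, 7.0), seed = 86)
  lab <- label_set(dimers, pot, 2, baseline = baseline_only(pot))
  lab2 <- lab
  lab2$configs <- c(lab$configs, lab$configs)
  lab2$energies <- c(lab$energies, lab$energies)
  bs <- basis_spec(2, degree = 2)       # well-conditioned small basis
  f1 <- fit_term(lab, bs, ridge = 0)
  f2 <- fit_term(lab2, bs, ridge = 0)
  expect_lt(max(abs(coef(f1) - coef(f2))) / max(abs(coef(f1))), 1e-6)
  expect_equal(predict(f2, dimers), predict(f1, dimers), tolerance = 1e-9)
})

test_that("degenerate normal equations at zero ridge raise a helpful error", {
  pot <- truth_pot()
  dimers <- sample_dimer_set(5, c(2.5, 7.0), seed = 87)  # n << features
  lab <- label_set(dimers, pot, 2, baseline = baseline_only(pot))
  expect_warning(expect_error(fit_term(lab, basis_spec(2), ridge = 0),
                              "ridge"),
                 "training points")
})

test_that("error statistics match closed forms and hand computation", {
  pot <- truth_pot()
  dimers <- sample_dimer_set(5, c(2.6, 5.0), seed = 88)
  lab <- label_set(dimers, pot, 2)
  perfect <- error_stats(lab$energies, lab)
  expect_equal(perfect$rmsd, 0)
  expect_equal(perfect$pearson_r, 1)
  shifted <- error_stats(lab$energies + 0.7, lab)
  expect_equal(shifted$rmsd, 0.7, tolerance = 1e-12)
  expect_equal(shifted$mae, 0.7, tolerance = 1e-12)
  expect_equal(shifted$pearson_r, 1, tolerance = 1e-12)
  # 5-point hand rmsd
  pred <- lab$energies + c(0.1, -0.2, 0.3, 0, -0.1)
  hand <- sqrt(mean(c(0.1, -0.2, 0.3, 0, -0.1)^2))
  expect_equal(error_stats(pred, lab)$rmsd, hand, tolerance = 1e-12)
  expect_equal(error_stats(pred, lab)$max_abs, 0.3, tolerance = 1e-12)
  expect_error(error_stats(pred, structure(list(configs = list()),
                                           class = "mbw_labeled_set")),
               "empty")
})

test_that("surrogate error vs truth grows monotonically with distortion", {
  truth <- truth_pot()
  dimers <- sample_dimer_set(150, c(2.5, 6.5), seed = 89)
  ref <- label_set(dimers, truth, 2)
  rmsds <- vapply(c(1, 2, 4), function(s) {
    sur <- surrogate_pot(scale = s, label = paste0("x", s))
    error_stats(label_set(dimers, sur, 2)$energies, ref)$rmsd
  }, numeric(1))
  expect_true(all(diff(rmsds) > 0))
})

test_that("out-of-sample error stays near training error for clean targets", {
  bs <- basis_spec(2)
  train_d <- sample_dimer_set(250, c(2.5, 7.0), seed = 90)
  test_d <- sample_dimer_set(100, c(2.5, 7.0), seed = 91)
  nfeat <- length(build_basis(train_d[[1]], bs))
  set.seed(12)
  beta <- rnorm(nfeat, 0, 0.3)
  Xtr <- t(vapply(train_d, build_basis, numeric(nfeat), spec = bs))
  Xte <- t(vapply(test_d, build_basis, numeric(nfeat), spec = bs))
  mk <- function(cfgs, y) structure(
    list(configs = cfgs, energies = y, order = 2L, level_tag = "synthetic",
         noise_sigma = 0), class = "mbw_labeled_set")
  ft <- fit_term(mk(train_d, as.vector(Xtr %*% beta)), bs, ridge = 1e-12)
  oos <- error_stats(ft, mk(test_d, as.vector(Xte %*% beta)))
  # noise-free in-basis target: held-out error within 2x training error,
  # floored at the linear-algebra noise level
  expect_lt(oos$rmsd, max(2 * ft$training_stats$rmsd, 1e-6))
})

test_that("fitted terms serialize and round-trip through text", {
  pot <- truth_pot()
  dimers <- sample_dimer_set(120, c(2.5, 7.0), seed = 92)
  lab <- label_set(dimers, pot, 2, baseline = baseline_only(pot))
  ft <- fit_term(lab, basis_spec(2), ridge = 1e-10)
  path <- withr::local_tempfile(fileext = ".txt")
  write_fitted_term(ft, path)
  back <- read_fitted_term(path)
  expect_equal(coef(back), coef(ft), tolerance = 1e-15)
  d <- sample_dimer_set(3, c(2.8, 6), seed = 93)
  expect_equal(predict(back, d), predict(ft, d), tolerance = 1e-12)
})
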