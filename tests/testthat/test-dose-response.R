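hill_truth <- list(v_max = 1, k_half_uM = 18, h = 2.214)

test_that("noiseless Hill data round-trip exactly", {
  curve <- generate_response_curve(model = "hill", noise_sd = 0,
                                   replicates = 1)
  fit <- fit_hill(curve)
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_equal(est[["v_max"]], 1, tolerance = 1e-6)
  expect_equal(est[["k_half_uM"]], 18, tolerance = 1e-6)
  expect_equal(est[["h"]], 2.214, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("the Hill model nests Michaelis-Menten at h = 1", {
  curve <- generate_response_curve(model = "michaelis_menten", noise_sd = 0,
                                   replicates = 1)
  mm <- fit_michaelis_menten(curve)
  hl <- fit_hill(curve)
  expect_equal(setNames(mm$params$estimate, mm$params$term)[["k_half_uM"]],
               18, tolerance = 1e-6)
  est <- setNames(hl$params$estimate, hl$params$term)
  expect_equal(est[["h"]], 1, tolerance = 1e-5)
  expect_equal(est[["k_half_uM"]], 18, tolerance = 1e-4)
})

test_that("noisy sigmoidal data recover the activation constant", {
  curve <- generate_response_curve(model = "hill", v_max = 1,
                                   k_half_uM = 18, h = 2.214,
                                   noise_sd = 0.02, replicates = 3,
                                   seed = 2024)
  fit <- fit_hill(curve)
  k <- setNames(fit$params$estimate, fit$params$term)[["k_half_uM"]]
  expect_gt(k, 16); expect_lt(k, 20)
  expect_gt(fit$r_squared, 0.97)
})

test_that("biphasic fitting reduces to Hill and recovers basal activity", {
  pure <- generate_response_curve(model = "hill", noise_sd = 0,
                                  replicates = 1)
  bf <- fit_biphasic(pure)
  est <- setNames(bf$params$estimate, bf$params$term)
  expect_lt(est[["basal"]], 1e-4)
  expect_equal(est[["k_half_uM"]], 18, tolerance = 1e-3)

  mut <- generate_response_curve(model = "biphasic", basal = 0.6,
                                 noise_sd = 0.01, replicates = 3, seed = 7)
  mf <- fit_biphasic(mut)
  bm <- setNames(mf$params$estimate, mf$params$term)
  expect_lt(abs(bm[["basal"]] - 0.6) / 0.6, 0.05)

  flat <- tibble::tibble(effector_uM = c(0.1, 1, 10, 100, 1000),
                         rate = rep(0.7, 5))
  fd <- fit_biphasic(flat)
  expect_true(fd$degenerate)
  est <- setNames(fd$params$estimate, fd$params$term)
  expect_equal(est[["basal"]], 0.7)
  expect_equal(est[["v_max"]], 0.7)
})

test_that("r_squared matches hand arithmetic and rejects degeneracy", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  obs <- c(2, 5, 8)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  # frozen hand computation: obs (1,2,4), fitted (1.1, 2.0, 3.8)
  expect_equal(r_squared(c(1, 2, 4), c(1.1, 2, 3.8)), 0.9892857142857143,
               tolerance = 1e-12)
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 1)), "zero variance")
  expect_error(r_squared(1:3, 1:4), "Lengths")
})

test_that("model comparison ranks by AICc as the data dictate", {
  sig <- generate_response_curve(model = "hill", h = 2.214, noise_sd = 0.02,
                                 replicates = 3, seed = 31)
  cmp <- compare_models(sig)
  expect_identical(cmp$model[1], "hill")
  aicc <- setNames(cmp$aicc, cmp$model)
  expect_lt(aicc[["hill"]], aicc[["michaelis_menten"]])

  hyp <- generate_response_curve(model = "michaelis_menten", noise_sd = 0.02,
                                 replicates = 3, seed = 32)
  cmp2 <- compare_models(hyp)
  aicc2 <- setNames(cmp2$aicc, cmp2$model)
  expect_lte(aicc2[["michaelis_menten"]], aicc2[["hill"]])
})

test_that("fits are equivariant under rescaling of the activity axis", {
  curve <- generate_response_curve(model = "biphasic", basal = 0.3,
                                   noise_sd = 0.02, replicates = 3, seed = 5)
  f1 <- fit_biphasic(curve)
  scaled <- dplyr::mutate(curve, rate = rate * 7.3)
  f2 <- fit_biphasic(scaled)
  e1 <- setNames(f1$params$estimate, f1$params$term)
  e2 <- setNames(f2$params$estimate, f2$params$term)
  expect_equal(e2[["v_max"]], 7.3 * e1[["v_max"]], tolerance = 1e-5)
  expect_equal(e2[["basal"]], 7.3 * e1[["basal"]], tolerance = 1e-4)
  expect_equal(e2[["k_half_uM"]], e1[["k_half_uM"]], tolerance = 1e-5)
  expect_equal(e2[["h"]], e1[["h"]], tolerance = 1e-5)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-9)
})

test_that("fitting demands a minimally informative curve", {
  few <- tibble::tibble(effector_uM = c(1, 10, 100), rate = c(0.1, 0.5, 0.9))
  expect_error(fit_hill(few), "5 distinct")
  expect_error(fit_hill(tibble::tibble(effector_uM = -1:3, rate = 0:4)),
               "nonnegative")
})

test_that("estimator calibration holds across seeded repetitions", {
  ks <- hs <- numeric(30)
  for (i in seq_len(30)) {
    curve <- generate_response_curve(model = "hill", noise_sd = 0.02,
                                     replicates = 3, seed = 100 + i)
    fi <- fit_hill(curve)
    est <- setNames(fi$params$estimate, fi$params$term)
    ks[i] <- est[["k_half_uM"]]; hs[i] <- est[["h"]]
  }
  expect_lt(abs(median(ks) - 18) / 18, 0.05)
  expect_lt(abs(median(hs) - 2.214) / 2.214, 0.10)
})

test_that("tidy and glance expose the fit in broom shape", {
  curve <- generate_response_curve(noise_sd = 0.02, seed = 12)
  fit <- fit_hill(curve)
  td <- tidy(fit)
  expect_identical(names(td), c("term", "estimate", "std.error"))
  expect_setequal(td$term, c("v_max", "k_half_uM", "h"))
  gl <- glance(fit)
  expect_identical(gl$model, "hill")
  expect_lte(gl$r_squared, 1)
  pr <- predict(fit, tibble::tibble(effector_uM = c(0, 18)))
  expect_equal(pr[1], 0)
  expect_equal(pr[2] / td$estimate[td$term == "v_max"], 0.5, tolerance = 0.1)
})
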