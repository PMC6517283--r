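test_that("frailty link multipliers follow their defining variants", {
  sp <- bd_spec("inverse")
  expect_equal(re_multiplier(sp, 1, 1, 2, u = 2), 2)
  expect_equal(re_multiplier(sp, 1, 2, 1, u = 2), 0.5)
  expect_equal(re_multiplier(sp, 2, 2, 3, u = 4), 4)
  expect_equal(re_multiplier(sp, 2, 3, 2, u = 4), 0.25)

  # a frailty of 1 is neutral under every variant, process and transition
  for (lk in c("none", "simple", "inverse", "power_inverse", "separate")) {
    spl <- bd_spec(lk)
    for (j in 1:2)
      for (k in seq_len(nrow(spl$transitions)))
        expect_equal(
          re_multiplier(spl, j, spl$transitions[k, 1], spl$transitions[k, 2],
                        u = 1, alpha = 1.221),
          1
        )
  }

  # power-inverse applies the exponent to the second process only
  spp <- bd_spec("power_inverse")
  expect_equal(re_multiplier(spp, 2, 2, 3, u = 2, alpha = 1.221), 2^1.221)
  expect_equal(re_multiplier(spp, 2, 2, 1, u = 2, alpha = 1.221), 2^-1.221)
  expect_equal(re_multiplier(spp, 1, 2, 3, u = 2, alpha = 1.221), 2)

  # simple scales every transition of both processes the same way
  sps <- bd_spec("simple")
  expect_equal(re_multiplier(sps, 1, 2, 1, u = 3), 3)
  expect_equal(re_multiplier(sps, 2, 1, 2, u = 3), 3)

  expect_error(re_multiplier(sp, 1, 1, 3, u = 2), "not allowed")
  expect_error(re_multiplier(sp, 1, 1, 2, u = 0), "positive")
  expect_error(re_multiplier(sp, 1, 1, 2, u = -1), "positive")
})

test_that("power-inverse at alpha = 1 equals the inverse link; multipliers are monotone", {
  spp <- bd_spec("power_inverse")
  spi <- bd_spec("inverse")
  us <- exp(seq(log(0.05), log(20), length.out = 41))
  for (k in seq_len(nrow(spp$transitions))) {
    from <- spp$transitions[k, 1]; to <- spp$transitions[k, 2]
    for (j in 1:2) {
      gp <- re_multiplier(spp, j, from, to, us, alpha = 1)
      gi <- re_multiplier(spi, j, from, to, us)
      expect_identical(gp, gi)
      # strictly monotone: increasing on worsening, decreasing on improving
      expect_true(all(diff(gi) > 0) || all(diff(gi) < 0))
      expect_equal(all(diff(gi) > 0), spi$deterioration[k])
    }
  }
})

test_that("free-parameter count matches the published AIC bookkeeping", {
  expect_identical(n_free_params(bd_spec("none")), 8L)
  expect_identical(n_free_params(bd_spec("simple")), 9L)
  expect_identical(n_free_params(bd_spec("inverse")), 9L)
  expect_identical(n_free_params(bd_spec("power_inverse")), 10L)
  expect_identical(n_free_params(bd_spec("separate")), 10L)

  # published log-likelihood / AIC pairs are consistent with these counts
  expect_equal(cmsm_aic(-2448.96, n_free_params(bd_spec("none"))), 4913.92)
  expect_equal(cmsm_aic(-2367.93, n_free_params(bd_spec("inverse"))), 4753.86)
  expect_equal(cmsm_aic(-2367.46, n_free_params(bd_spec("power_inverse"))), 4754.92)

  # each covariate adds one coefficient per transition of its process
  spc <- bd_spec("inverse", covariates = list(p1 = c("x1", "x2")))
  expect_identical(n_free_params(spc), 17L)
})

test_that("specifications round-trip through YAML", {
  sp <- cmsm_spec(n_states = 4, processes = c("kidney", "urine"),
                  transitions = c("1->2", "2->1", "2->3", "3->2", "3->4", "4->3"),
                  link = "separate",
                  covariates = list(kidney = "age"))
  path <- withr::local_tempfile(fileext = ".yaml")
  cmsm_spec_write(sp, path)
  sp2 <- cmsm_spec_read(path)
  expect_identical(sp2$n_states, sp$n_states)
  expect_identical(sp2$processes, sp$processes)
  expect_identical(sp2$labels, sp$labels)
  expect_identical(sp2$deterioration, sp$deterioration)
  expect_identical(sp2$link, sp$link)
  expect_identical(sp2$covariates$kidney, "age")
})

test_that("malformed specifications and models are rejected", {
  expect_error(cmsm_spec(n_states = 1), "at least 2")
  expect_error(cmsm_spec(transitions = c("1->4")), "1..K")
  expect_error(cmsm_spec(transitions = c("1->1")), "self-transitions")
  expect_error(cmsm_spec(deterioration = c("1->3")), "subset")

  sp <- bd_spec("inverse")
  expect_error(cmsm_model(sp, list(p1 = rep(0.1, 4), p2 = rep(-0.1, 4)),
                          theta = 0.5), "nonnegative")
  expect_error(cmsm_model(sp, list(p1 = rep(0.1, 4), p2 = rep(0.1, 4)),
                          theta = -1), "positive")
  expect_error(cmsm_model(sp, list(p1 = rep(0.1, 4), p2 = rep(0.1, 4))),
               "theta")
  # the separate link needs two variance parameters
  expect_error(cmsm_model(bd_spec("separate"),
                          list(p1 = rep(0.1, 4), p2 = rep(0.1, 4)),
                          theta = 0.5), "2 positive")
})

test_that("parameterised models round-trip through YAML", {
  mod <- kidney_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  cmsm_model_write(mod, path)
  mod2 <- cmsm_model_read(path)
  expect_equal(mod2$intensities, mod$intensities)
  expect_equal(mod2$theta, mod$theta)
  expect_identical(mod2$spec$link, "inverse")
})
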