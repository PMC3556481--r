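test_that("KD = kd/ka in nM, with domain checks", {
  expect_equal(kd_from_rates(7208, 0.003898), 540.8, tolerance = 1e-4)
  expect_equal(kd_from_rates(1.218e4, 0.002851), 234.0, tolerance = 1e-3)
  expect_equal(kd_from_rates(1e5, 0), 0)
  expect_error(kd_from_rates(0, 0.01), class = "glycoforge_validation_error")
  expect_error(kd_from_rates(1e4, -1), class = "glycoforge_validation_error")
})

test_that("packaged SPR table reproduces its printed KD column", {
  tab <- read_spr_table()
  expect_equal(nrow(tab), 6L)
  self_consistent <- abs(tab$KD_computed_nM - tab$KD_printed_nM) < 0.1
  expect_gte(sum(self_consistent), 3L)
  expect_true(all(abs(tab$KD_computed_nM - tab$KD_printed_nM) <= 0.2))
})

test_that("noiseless sensorgrams obey the 1:1 Langmuir closed forms", {
  ka <- 5.6e4; kd <- 0.028; rmax <- 100
  KD <- kd / ka
  # at C = KD the plateau is Rmax/2
  g <- simulate_sensorgram(ka, kd, KD, rmax, t_assoc = 2000, t_total = 2100)
  expect_equal(max(g$response), rmax / 2, tolerance = 1e-6)
  # continuity at t_assoc and decay to zero
  h <- simulate_sensorgram(ka, kd, 1e-6, rmax, t_assoc = 120, t_total = 600,
                           dt = 0.5)
  ia <- which(h$time == 120)
  expect_equal(h$response[ia + 1L], h$response[ia], tolerance = 0.02)
  expect_lt(h$response[length(h$response)], h$response[ia] * 1e-5)
  expect_true(all(diff(h$response[h$time <= 120]) >= 0))  # monotone association
  expect_error(simulate_sensorgram(ka, kd, -1, rmax),
               class = "glycoforge_validation_error")
  expect_error(simulate_sensorgram(ka, kd, 1e-6, rmax, noise_sd = 1),
               class = "glycoforge_validation_error")  # noise without seed
})

test_that("association observed rate equals ka*C + kd (log-slope oracle)", {
  ka <- 5.721e4; kd <- 0.02794; C <- 1e-6; rmax <- 80
  g <- simulate_sensorgram(ka, kd, C, rmax, t_assoc = 60, t_total = 100,
                           dt = 0.25)
  KD <- kd / ka
  req <- rmax * C / (C + KD)
  assoc <- g$time <= 40 & g$time > 0
  slope <- coef(lm(log(req - g$response[assoc]) ~ g$time[assoc]))[[2]]
  expect_equal(-slope, ka * C + kd, tolerance = 1e-6)
})

test_that("Req is monotone in concentration and saturates at Rmax", {
  ka <- 5.6e4; kd <- 0.028; rmax <- 100
  KD <- kd / ka
  plateaus <- vapply(KD * c(0.1, 1, 10, 100, 1e4), function(C) {
    max(simulate_sensorgram(ka, kd, C, rmax, t_assoc = 5000,
                            t_total = 5100, dt = 10)$response)
  }, numeric(1))
  expect_true(all(diff(plateaus) > 0))
  expect_equal(plateaus[5], rmax, tolerance = 1e-3)
})

test_that("global Langmuir fit recovers noiseless parameters to 1e-6 relative error", {
  truth <- fixture_truth()$spr
  grams <- lapply(truth$concs, function(C) {
    simulate_sensorgram(truth$ka, truth$kd, C, truth$rmax)
  })
  fit <- fit_langmuir(grams)
  expect_equal(fit$ka, truth$ka, tolerance = 1e-6)
  expect_equal(fit$kd, truth$kd, tolerance = 1e-6)
  expect_equal(fit$rmax, truth$rmax, tolerance = 1e-6)
  expect_equal(fit$KD_nM, 500, tolerance = 1e-6)
  expect_lt(fit$rms, 1e-6)
})

test_that("a single saturating concentration triggers an identifiability warning", {
  truth <- fixture_truth()$spr
  g <- simulate_sensorgram(truth$ka, truth$kd, 10 * truth$KD_M, truth$rmax)
  expect_warning(fit_langmuir(list(g)), "identifiab")
})

test_that("4PL fit recovers exact parameters and honours the EC50 definition", {
  conc <- 10^seq(-2, 3, length.out = 9)
  y <- 0 + (1 - 0) / (1 + (10 / conc)^1)
  fit <- fit_4pl(conc, y)
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
  expect_equal(fit$top, 1, tolerance = 1e-6)
  expect_equal(fit$ec50, 10, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_lte(fit$bottom, fit$top)
  # y at x = EC50 is midway between bottom and top
  expect_equal(predict(fit, newdata = fit$ec50),
               (fit$bottom + fit$top) / 2, tolerance = 1e-9)
})

test_that("decreasing curves are normalised so bottom <= top", {
  conc <- 10^seq(-2, 3, length.out = 9)
  y <- 2 - 1.5 / (1 + (10 / conc)^1.2)  # decreasing signal
  fit <- fit_4pl(conc, y)
  expect_lte(fit$bottom, fit$top)
  expect_equal(fit$ec50, 10, tolerance = 1e-5)
})

test_that("degenerate ELISA data raise informative fit errors", {
  conc <- 10^seq(-2, 3, length.out = 9)
  expect_error(fit_4pl(conc, rep(1, 9)), class = "glycoforge_computation_error")
  set.seed(5)
  noise_only <- rnorm(9)
  err <- expect_error(fit_4pl(conc, noise_only),
                      class = "glycoforge_computation_error")
  expect_match(conditionMessage(err), "R\\^2")
  expect_error(fit_4pl(conc[1:4], conc[1:4]), class = "glycoforge_validation_error")
  expect_error(fit_4pl(c(-1, conc[1:8]), rep(1, 9)),
               class = "glycoforge_validation_error")
})

test_that("fold differences compare EC50s with domain checks", {
  expect_equal(fold_difference(9.278, 247.3), 26.65, tolerance = 1e-3)
  expect_equal(fold_difference(6.509, 247.3), 38.0, tolerance = 1e-2)
  expect_equal(fold_difference(5, 5), 1)
  expect_error(fold_difference(0, 5), class = "glycoforge_validation_error")
  expect_error(fold_difference(5, -1), class = "glycoforge_validation_error")
})

test_that("positivity counting parses +/- scores strictly", {
  expect_equal(summarize_positivity(), 4L)
  allneg <- data.frame(MUC1_16A = rep("-", 6))
  expect_equal(summarize_positivity(allneg), 0L)
  expect_equal(summarize_positivity(data.frame(MUC1_16A = character())), 0L)
  expect_error(summarize_positivity(data.frame(MUC1_16A = c("+", "?"))),
               class = "glycoforge_validation_error")
  expect_error(summarize_positivity(data.frame(other = "+")),
               class = "glycoforge_validation_error")
})
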