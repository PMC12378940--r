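# Mendelian randomization: instrument rules, clumping, harmonization,
# Steiger filtering, estimators and sensitivity analyses.

test_that("instrument selection enforces p and F rules", {
  ex <- data.frame(snp = c("a", "b", "c"),
                   beta = c(3.17, 3.0, 4.0) * 0.01,
                   se = 0.01,
                   pval = c(1e-6, 1e-6, 2e-5))
  kept <- select_instruments(ex)
  expect_equal(kept$snp, "a")            # F = 10.05 kept; F = 9 and p = 2e-5 dropped
  expect_gt(kept$F, 10)
  expect_error(select_instruments(ex[ex$snp == "b", ]), "no instruments")
})

test_that("LD clumping keeps the lead SNP per correlated pair", {
  cand <- data.frame(snp = c("a", "b"), pval = c(1e-8, 1e-6),
                     position = c(1e6, 1.5e6))
  ld <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(ld_clump(cand, ld)$snp, "a")

  ld_low <- matrix(c(1, sqrt(5e-4), sqrt(5e-4), 1), 2,
                   dimnames = list(c("a", "b"), c("a", "b")))
  expect_setequal(ld_clump(cand, ld_low)$snp, c("a", "b"))

  far <- data.frame(snp = c("a", "b"), pval = c(1e-8, 1e-6),
                    position = c(1e6, 1e6 + 20000 * 1000))
  ld_hi <- matrix(c(1, sqrt(0.9), sqrt(0.9), 1), 2,
                  dimnames = list(c("a", "b"), c("a", "b")))
  expect_setequal(ld_clump(far, ld_hi)$snp, c("a", "b"))  # outside window

  expect_warning(
    ld_clump(cand, matrix(1, 1, 1, dimnames = list("a", "a"))),
    "missing")
})

test_that("clumping recovers one SNP per planted LD block", {
  tr <- gwas_truth(causal_beta = 0, n_instruments = 12,
                   ld_blocks = c(4, 4, 4), ld_rho = 0.95)
  gw <- generate_gwas_pair(12, tr, seed = 21)
  sel <- data.frame(snp = gw$exposure$snp, pval = gw$exposure$pval,
                    position = gw$exposure$position)
  # make positions tight so every pair is within the window
  sel$position <- seq(1e6, by = 1000, length.out = 12)
  kept <- ld_clump(sel, gw$ld, r2_max = 0.5)
  blocks <- rep(1:3, each = 4)[match(kept$snp, gw$exposure$snp)]
  expect_equal(sort(unique(blocks)), 1:3)
  expect_lte(max(table(blocks)), 2)
})

test_that("harmonization aligns, drops ambiguity, and is idempotent", {
  ex <- data.frame(snp = c("s1", "s2", "s3", "s4"),
                   effect_allele = c("A", "A", "A", "G"),
                   other_allele = c("G", "G", "T", "C"),
                   eaf = c(0.3, 0.3, 0.5, 0.2),
                   beta = c(0.1, 0.1, 0.1, 0.1), se = 0.01,
                   pval = 1e-8, n = 8299)
  out <- data.frame(snp = c("s1", "s2", "s3", "s4"),
                    effect_allele = c("A", "G", "A", "C"),
                    other_allele = c("G", "A", "T", "A"),
                    eaf = c(0.3, 0.7, 0.5, 0.2),
                    beta = c(0.02, -0.02, 0.02, 0.02), se = 0.01,
                    pval = 0.5, n = 494164)
  h <- harmonize(ex, out)
  expect_setequal(h$snp, c("s1", "s2"))      # s3 palindromic-ambiguous,
                                             # s4 irreconcilable (G/C vs C/A)
  expect_equal(h$beta_out[h$snp == "s1"], 0.02)
  expect_equal(h$beta_out[h$snp == "s2"], 0.02)   # swapped alleles flipped
  expect_true(any(grepl("palindromic", attr(h, "log"))))
  expect_true(any(grepl("irreconcilable", attr(h, "log"))))

  # idempotence: re-harmonizing the aligned rows changes nothing
  ex2 <- data.frame(snp = h$snp, effect_allele = h$effect_allele,
                    other_allele = h$other_allele, eaf = h$eaf,
                    beta = h$beta_exp, se = h$se_exp, pval = h$p_exp,
                    n = h$n_exp)
  out2 <- data.frame(snp = h$snp, effect_allele = h$effect_allele,
                     other_allele = h$other_allele, eaf = h$eaf_out,
                     beta = h$beta_out, se = h$se_out, pval = h$p_out,
                     n = h$n_out)
  h2 <- harmonize(ex2, out2)
  expect_equal(h2$beta_out, h$beta_out)
  expect_equal(h2$beta_exp, h$beta_exp)
})

test_that("outcome-associated SNPs are excluded at harmonization", {
  ex <- data.frame(snp = c("s1", "s2"), effect_allele = "A",
                   other_allele = "G", eaf = 0.3, beta = 0.1, se = 0.01,
                   pval = 1e-8, n = 8299)
  out <- data.frame(snp = c("s1", "s2"), effect_allele = "A",
                    other_allele = "G", eaf = 0.3, beta = c(0.001, 0.2),
                    se = 0.01, pval = c(0.5, 1e-9), n = 494164)
  h <- harmonize(ex, out)
  expect_equal(h$snp, "s1")
})

test_that("Steiger filtering compares explained variance directionally", {
  strong <- make_rows(bx = 0.11, by = 0.001, sy = 0.0032)  # F=121 vs F~0.1
  st <- steiger_filter(strong)
  expect_true(st$rows$steiger_ok)

  reversed <- make_rows(bx = 0.0032, by = 0.11, sy = 0.01, sx = 0.0032)
  expect_false(steiger_filter(reversed)$rows$steiger_ok)

  equal_r2 <- make_rows(bx = 0.1, by = 0.1, sy = 0.01, sx = 0.01,
                        n_exp = 1000, n_out = 1000)
  expect_false(steiger_filter(equal_r2)$rows$steiger_ok)  # tie drops

  no_n <- make_rows(bx = 0.1, by = 0.01, sy = 0.01)
  no_n$n_exp <- NA
  expect_warning(st2 <- steiger_filter(no_n), "skipped")
  expect_true(all(st2$rows$steiger_ok))
})

test_that("IVW reproduces identical ratios and the WLS oracle", {
  rows <- make_rows(bx = c(0.1, 0.2, 0.5), by = c(0.02, 0.04, 0.10),
                    sy = c(0.01, 0.01, 0.02))
  iv <- mr_ivw(rows)
  expect_equal(iv$beta, 0.2, tolerance = 1e-12)
  expect_equal(iv$cochran_Q, 0, tolerance = 1e-12)

  set.seed(22)
  rnd <- make_rows(bx = runif(10, 0.05, 0.2),
                   by = rnorm(10, 0.02, 0.01), sy = runif(10, 0.005, 0.02))
  iv2 <- mr_ivw(rnd)
  wls <- stats::lm(beta_out ~ 0 + beta_exp, data = rnd,
                   weights = 1 / rnd$se_out^2)
  expect_equal(iv2$beta, unname(stats::coef(wls)), tolerance = 1e-12)
  expect_error(mr_ivw(rnd[1, ]), "Wald")
})

test_that("IVW is invariant to ordering and weight scaling", {
  set.seed(23)
  rows <- make_rows(bx = runif(8, 0.05, 0.2), by = rnorm(8, 0.02, 0.01),
                    sy = runif(8, 0.005, 0.02))
  shuffled <- rows[sample(nrow(rows)), ]
  expect_equal(mr_ivw(rows)$beta, mr_ivw(shuffled)$beta, tolerance = 1e-12)
  scaled <- rows; scaled$se_out <- scaled$se_out * 3
  expect_equal(mr_ivw(rows)$beta, mr_ivw(scaled)$beta, tolerance = 1e-12)
  # multiplicative random-effects se never below fixed when Q > k-1
  ivf <- mr_ivw(rows, model = "fixed")
  ivm <- mr_ivw(rows)
  if (ivm$cochran_Q > nrow(rows) - 1) expect_gte(ivm$se, ivf$se)
})

test_that("Egger slope, intercept and constrained identity behave", {
  rows <- make_rows(bx = c(0.1, 0.2, 0.5), by = c(0.02, 0.04, 0.10),
                    sy = c(0.01, 0.01, 0.02))
  suppressWarnings({
    eg <- mr_egger(rows)
    expect_equal(eg$beta, 0.2, tolerance = 1e-9)
    expect_equal(eg$egger_intercept, 0, tolerance = 1e-9)

    shifted <- rows; shifted$beta_out <- shifted$beta_out + 0.05
    eg2 <- mr_egger(shifted)
    expect_equal(eg2$egger_intercept, 0.05, tolerance = 1e-9)
    expect_equal(eg2$beta, 0.2, tolerance = 1e-9)
  })

  # with the intercept constrained to zero, the slope is the IVW beta
  set.seed(24)
  rnd <- make_rows(bx = runif(10, 0.05, 0.2), by = rnorm(10, 0.02, 0.01),
                   sy = runif(10, 0.005, 0.02))
  constrained <- stats::lm(beta_out ~ 0 + beta_exp, data = rnd,
                           weights = 1 / rnd$se_out^2)
  expect_equal(unname(stats::coef(constrained)), mr_ivw(rnd)$beta,
               tolerance = 1e-12)
  expect_error(mr_egger(rnd[1:2, ]), "3 instruments")
})

test_that("weighted median resists outliers and respects weights", {
  rows <- make_rows(bx = rep(0.1, 3), by = rep(0.02, 3), sy = 0.01)
  expect_equal(mr_weighted_median(rows, n_boot = 50)$beta, 0.2,
               tolerance = 1e-12)

  # 10 valid instruments (ratio 0.3) + 4 outliers (ratio 2.0), equal weight
  bx <- rep(0.1, 14)
  by <- c(rep(0.03, 10), rep(0.2, 4))
  rows2 <- make_rows(bx, by, sy = 0.01)
  wm <- mr_weighted_median(rows2, n_boot = 50)
  expect_equal(wm$beta, 0.3, tolerance = 0.02)
  expect_equal(brute_weighted_median(by / bx, rep(1, 14)), 0.3,
               tolerance = 1e-12)                       # oracle agrees
  plain_mean <- mean(by / bx)
  expect_gt(abs(plain_mean - 0.3), abs(wm$beta - 0.3))  # robust vs mean

  # weight concentrated on one SNP pulls the estimate to its ratio
  rows3 <- make_rows(bx = c(0.01, 1, 0.01), by = c(0.005, 0.5, 0.002),
                     sy = 0.01)
  expect_equal(mr_weighted_median(rows3, n_boot = 50)$beta, 0.5,
               tolerance = 0.01)
  expect_error(mr_weighted_median(rows3[1:2, ]), "3 instruments")
})

test_that("sensitivity suite: Q, LOO, outlier flagging, simple mode", {
  rows <- make_rows(bx = rep(0.1, 5), by = rep(0.02, 5), sy = 0.01)
  s <- mr_sensitivity(rows, n_sim = 200, seed = 1)
  expect_equal(s$cochran_Q$Q, 0, tolerance = 1e-12)
  expect_equal(s$cochran_Q$p, 1, tolerance = 1e-12)
  expect_equal(length(unique(round(s$loo$beta, 12))), 1)

  set.seed(25)
  gw <- generate_gwas_pair(20, gwas_truth(causal_beta = 0.2,
                                          n_instruments = 20), seed = 3)
  h <- harmonize(gw$exposure, gw$outcome, outcome_p_thresh = 0)
  h$beta_out[1] <- h$beta_out[1] + 0.5
  s2 <- mr_sensitivity(h, n_sim = 500, seed = 2)
  expect_lt(s2$presso_global_p, 0.05)
  base <- mr_ivw(h)$beta
  expect_equal(s2$loo$snp[which.max(abs(s2$loo$beta - base))], h$snp[1])

  # Q equals the independent direct-sum oracle
  expect_equal(s2$cochran_Q$Q, brute_cochran_q(h, base), tolerance = 1e-10)

  sm <- mr_simple_mode(h[-1, ], n_boot = 50)
  expect_lt(abs(sm$beta - 0.2), 0.15)
})

test_that("full MR analysis runs end to end on synthetic data", {
  gw <- generate_gwas_pair(60, gwas_truth(causal_beta = 0.25,
                                          n_instruments = 40),
                           n_outcome = 20000, seed = 26)
  res <- mr_analysis(gw$exposure, gw$outcome, gw$ld)
  expect_setequal(res$estimates$method,
                  c("IVW", "Egger", "weighted_median", "simple_mode"))
  ivw <- res$estimates[res$estimates$method == "IVW", ]
  expect_lt(abs(ivw$beta - 0.25), 3 * ivw$se)
  expect_true(all(res$log >= c(selected = 3, clumped = 3, harmonized = 3,
                               steiger = 3)))
})
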