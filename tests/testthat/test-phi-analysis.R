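test_that("kinetic Kd and its propagated SE match closed form and Monte Carlo", {
  kk <- kd_kin(0.078, 1e6)
  expect_equal(kk$value, 7.8e-8, tolerance = 1e-12)
  expect_identical(kk$se, 0)
  # equal 10% relative SEs: relative SE of the ratio is sqrt(2) * 10%
  kk2 <- kd_kin(0.078, 1e6, 0.0078, 1e5)
  expect_equal(kk2$se / kk2$value, sqrt(2) * 0.1, tolerance = 1e-12)
  mc <- mc_se(function(kd, ka) kd / ka, c(0.078, 1e6), c(0.0078, 1e5))
  expect_equal(kk2$se, mc, tolerance = 0.05)
  expect_error(kd_kin(-1, 1e6), "> 0")
})

test_that("ddG uses RT ln of the Kd ratio with the stated gas constant", {
  expect_equal(delta_delta_g(1e-5, 1e-6)$value,
               1.987e-3 * 298.15 * log(10), tolerance = 1e-12)
  expect_equal(delta_delta_g(1e-5, 1e-6)$value, 1.364, tolerance = 1e-3)
  expect_identical(delta_delta_g(1e-6, 1e-6)$value, 0)
  # three orders of magnitude, the most destabilizing realistic case
  expect_equal(delta_delta_g(1e-3, 1e-6)$value, 4.09, tolerance = 1e-2)
  dg <- delta_delta_g(1e-5, 1e-6, kd_mut_se = 1e-6, kd_ref_se = 1e-7)
  mc <- mc_se(function(a, b) 1.987e-3 * 298.15 * log(a / b),
              c(1e-5, 1e-6), c(1e-6, 1e-7))
  expect_equal(dg$se, mc, tolerance = 0.05)
})

test_that("Phi worked cases behave as the definition requires", {
  # association halves, Kd quadruples: Phi = ln2/ln4 = 0.5
  expect_equal(phi_value(20, 10, 4e-6, 1e-6)$value, 0.5,
               tolerance = 1e-12)
  # association unchanged, Kd increases: Phi = 0
  expect_identical(phi_value(20, 20, 4e-6, 1e-6)$value, 0)
  # faster association with destabilization: Phi < 0
  expect_lt(phi_value(20, 25, 4e-6, 1e-6)$value, 0)
  expect_error(phi_value(20, 10, 1e-6, 1e-6), "undefined Phi")
})

test_that("Phi SE matches the stated propagation formula and Monte Carlo", {
  p <- phi_value(20, 10, 4e-6, 1e-6, k_ass_ref_se = 1, k_ass_mut_se = 0.5,
                 kd_mut_se = 2e-7, kd_ref_se = 5e-8)
  A <- log(2); B <- log(4)
  sA <- sqrt((1 / 20)^2 + (0.5 / 10)^2)
  sB <- sqrt((2e-7 / 4e-6)^2 + (5e-8 / 1e-6)^2)
  expect_equal(p$se, abs(p$value) * sqrt((sA / A)^2 + (sB / B)^2),
               tolerance = 1e-12)
  mc <- mc_se(function(kr, km, dm, dr) log(kr / km) / log(dm / dr),
              c(20, 10, 4e-6, 1e-6), c(1, 0.5, 2e-7, 5e-8))
  expect_equal(p$se, mc, tolerance = 0.1)
  # A -> 0 limit: se = sigma_A / |B|
  p0 <- phi_value(20, 20, 4e-6, 1e-6, k_ass_ref_se = 1, k_ass_mut_se = 1)
  expect_equal(p0$se, sqrt(2 * (1 / 20)^2) / log(4), tolerance = 1e-12)
  mc0 <- mc_se(function(kr, km) log(kr / km) / log(4),
               c(20, 20), c(1, 1))
  expect_equal(p0$se, mc0, tolerance = 0.1)
})

test_that("Phi is invariant under common unit rescalings", {
  set.seed(5)
  for (i in 1:10) {
    kr <- runif(1, 1, 100); km <- runif(1, 1, 100)
    dm <- 10^runif(1, -8, -5); dr <- 10^runif(1, -8, -5)
    if (dm == dr) next
    base <- phi_value(kr, km, dm, dr)$value
    s1 <- runif(1, 1e-3, 1e3); s2 <- runif(1, 1e-3, 1e3)
    expect_equal(phi_value(kr * s1, km * s1, dm * s2, dr * s2)$value,
                 base, tolerance = 1e-9)
  }
})

test_that("equilibrium and kinetic Phi agree when the Kd branches agree", {
  p_eq <- phi_value(20, 10, 4e-6, 1e-6)
  p_kin <- phi_value(20, 10, 4e-6, 1e-6)
  expect_identical(p_eq$value, p_kin$value)
  avg <- phi_average(list(value = 0.4, se = 0.06),
                     list(value = 0.3, se = 0.08))
  expect_equal(avg$value, 0.35)
  expect_equal(avg$se, sqrt(0.06^2 + 0.08^2) / 2)
})

test_that("report filter requires both branches and an inclusive boundary", {
  expect_false(apply_report_filter(0.50, 0.30))
  expect_true(apply_report_filter(0.34, 0.34))
  expect_false(apply_report_filter(-1.2, -1.3))  # stabilizing: never
  expect_false(apply_report_filter(NA, 1))
  expect_identical(apply_report_filter(c(0.5, 0.2), c(0.5, 0.5)),
                   c(TRUE, FALSE))
})

test_that("consistency flag trips at 3x the combined SE but not at 0", {
  expect_true(consistency_check(1.0, 1.0, 0.05, 0.05))
  comb <- sqrt(0.05^2 + 0.05^2)
  expect_false(consistency_check(1.0, 1.0 + 3 * comb, 0.05, 0.05))
  expect_true(consistency_check(1.0, 1.0 + 1.5 * comb, 0.05, 0.05))
  # machine-precision disagreement on noiseless data never flags
  expect_true(consistency_check(1.0, 1.0 + 1e-12, 0, 0))
})

test_that("transition-state classification follows the threshold rules", {
  expect_identical(classify_transition_state(-0.15, 0.05),
                   "nonnative_candidate")
  expect_identical(classify_transition_state(0.35, 0.1),
                   "weakly_structured")
  expect_identical(classify_transition_state(-0.05, 0.1), "unstructured")
  expect_identical(classify_transition_state(0.7, 0.1), "structured")
  expect_identical(
    classify_transition_state(c(-0.2, 0.05, 0.3, 0.8), c(0.05, 0.02,
                                                         0.1, 0.1)),
    c("nonnative_candidate", "unstructured", "weakly_structured",
      "structured"))
})

test_that("composite Ala-Gly treatment uses the Ala reference and adds up", {
  temp <- 298.15
  rt <- 1.987e-3 * temp
  wt <- list(k_ass_fast = 4e6, k_ass_fast_se = 0, k_diss = 0.2,
             k_diss_se = 0, kd_equb = 5e-8, kd_equb_se = 0,
             position = 0L)
  # Ala: ddg 0.2 all in dissociation; Gly: further 0.6 with phi 0.3
  kd_a <- 5e-8 * exp(0.2 / rt)
  ala <- list(k_ass_fast = 4e6, k_ass_fast_se = 0,
              k_diss = kd_a * 4e6, k_diss_se = 0, kd_equb = kd_a,
              kd_equb_se = 0, position = 10L)
  kd_g <- kd_a * exp(0.6 / rt)
  kag <- 4e6 * (kd_g / kd_a)^(-0.3)
  gly <- list(k_ass_fast = kag, k_ass_fast_se = 0,
              k_diss = kd_g * kag, k_diss_se = 0, kd_equb = kd_g,
              kd_equb_se = 0, position = 10L)
  res <- composite_ala_gly(ala, gly, temperature = temp)
  expect_equal(res$ddg_equb, 0.6, tolerance = 1e-12)
  expect_equal(res$phi_equb, 0.3, tolerance = 1e-12)
  expect_true(res$reportable)
  # thermodynamic cycle: WT->A plus A->G equals WT->G exactly
  d_wa <- delta_delta_g(ala$kd_equb, wt$kd_equb, temp)$value
  d_ag <- delta_delta_g(gly$kd_equb, ala$kd_equb, temp)$value
  d_wg <- delta_delta_g(gly$kd_equb, wt$kd_equb, temp)$value
  expect_equal(d_wa + d_ag, d_wg, tolerance = 1e-14)
  expect_error(composite_ala_gly(ala, within(gly, position <- 11L)),
               "share a position")
  # identical rates: ddg 0, undefined Phi, not reportable
  same <- composite_ala_gly(ala, ala)
  expect_equal(same$ddg_equb, 0)
  expect_true(is.na(same$phi_equb))
  expect_false(same$reportable)
})

test_that("LFE slopes separate association- and dissociation-dominated panels", {
  rt <- 1.987e-3 * 298.15
  ddg <- seq(0.3, 2.4, length.out = 8)
  kd <- 5e-8 * exp(ddg / rt)
  base <- data.frame(variant_id = sprintf("V%d", seq_along(ddg)),
                     kd_equb = kd)
  # all effect in dissociation
  d1 <- transform(base, k_ass_fast = 4e6, k_diss = kd * 4e6)
  l1 <- lfe_table(d1)
  expect_equal(l1$slope_kdiss, 1, tolerance = 1e-8)
  expect_equal(l1$slope_kass, 0, tolerance = 1e-8)
  # all effect in association
  d2 <- transform(base, k_ass_fast = 4e6 * (kd / 5e-8)^(-1),
                  k_diss = 0.2)
  l2 <- lfe_table(d2)
  expect_equal(l2$slope_kdiss, 0, tolerance = 1e-8)
  expect_equal(l2$slope_kass, -1, tolerance = 1e-8)
  expect_error(lfe_table(d1[1:2, ]), "at least 3")
})

test_that("Kd-agreement table propagates ratio errors and flags coverage", {
  d <- data.frame(variant_id = c("WT", "M1", "M2"),
                  k_ass_fast = c(4e6, 4e6, 4e6),
                  k_ass_fast_se = c(4e4, 4e4, 4e4),
                  k_diss = c(0.2, 0.5, 2),
                  k_diss_se = c(0.004, 0.01, 0.04),
                  kd_equb = c(5e-8, 1.25e-7, 5e-7),
                  kd_equb_se = c(2e-9, 5e-9, 2e-8))
  cmp <- compare_kd(d)
  expect_equal(cmp$table$ratio, rep(1, 3), tolerance = 1e-9)
  expect_identical(cmp$fraction_covering_one, 1)
  d2 <- d
  d2$kd_equb[2] <- 5e-7  # kinetic branch now 4x below equilibrium
  expect_false(compare_kd(d2)$table$covers_one[2])
})
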