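# Statistics pipeline: transforms, outlier screen, mixed models,
# contrasts, PCA, ReliefF. Simulation sizes are scaled down from the full
# study design to keep the suite fast; the acceptance tests run the
# calibration checks at larger rep counts.

## shared fixture: a moderate simulated table with strong planted effects
fix_spec <- table_effect_spec(n_ecotypes = 5, n_reps = 8,
                              descriptors = c("area", "compactness"),
                              eco_offsets = seq(-2, 2, length.out = 5),
                              interaction_slopes = seq(-0.06, 0.06,
                                                       length.out = 5),
                              seed = 101)
fix_tab <- apply_transforms(simulate_descriptor_table(fix_spec))
fix_fit <- fit_lme(fix_tab, "area")

test_that("transform policy log-transforms exactly the flagged columns", {
  tab <- data.frame(plant_id = "p1", ecotype = "E", das = 17,
                    area = 100, compactness = 0.9)
  out <- apply_transforms(tab)
  expect_equal(out$area, log(100))
  expect_equal(out$compactness, 0.9)

  bad <- tab; bad$area <- 0
  expect_error(apply_transforms(bad), "non-positive.*'area'.*row 1")

  flags <- descriptor_log_flags()
  expect_true(all(c("mincirclediam", "minrectarea", "vrectsizey",
                    "vrectsizex", "area", "circumference", "maxdiam",
                    "bdryround", "bdrycount", "conhullcirc",
                    "conhullarea") %in% names(flags)[flags]))
  expect_false(flags[["compactness"]])
  expect_false(flags[["roundness"]])
  expect_equal(sum(flags), 11L)
})

test_that("shapiro screen is calibrated and detects log-normal data", {
  set.seed(42)
  rej <- mean(replicate(400, shapiro_screen(rnorm(100))$p < 0.05))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.08)
  set.seed(43)
  expect_lt(shapiro_screen(exp(rnorm(500, sd = 1.5)))$p, 1e-3)
  expect_error(shapiro_screen(rep(1, 50)), "constant")
  expect_error(shapiro_screen(c(1, 2)), "3 <= n")
})

test_that("Bonferroni outlier test flags a planted 10-sigma point", {
  set.seed(7)
  x <- seq_len(60)
  y <- 2 + 0.5 * x + rnorm(60, sd = 1)
  y[23] <- y[23] + 10
  flagged <- bonferroni_outlier_test(lm(y ~ x))
  expect_equal(flagged$index, 23L)
  expect_true(all(flagged$p_bonferroni <= 1))

  # clean data: typically nothing flagged; removing nothing keeps the table
  set.seed(8)
  y2 <- 2 + 0.5 * x + rnorm(60, sd = 1)
  expect_equal(nrow(bonferroni_outlier_test(lm(y2 ~ x))), 0L)
})

test_that("remove_outliers drops flagged rows from the mixed model", {
  tab <- fix_tab
  tab$area[10] <- tab$area[10] + 8  # gross contamination on log scale
  cleaned <- remove_outliers(tab, "area")
  expect_equal(attr(cleaned, "n_outliers_removed"), 1L)
  expect_equal(nrow(cleaned), nrow(tab) - 1L)
  expect_false(tab$area[10] %in% cleaned$area)

  clean2 <- remove_outliers(fix_tab, "area")
  expect_equal(attr(clean2, "n_outliers_removed"), 0L)
  expect_equal(nrow(clean2), nrow(fix_tab))
})

test_that("fit_lme recovers planted effects and the AR(1) parameter", {
  expect_s3_class(fix_fit, "lme_result")
  eff <- fix_fit$effects
  expect_setequal(eff$effect, c("ecotype", "time", "interaction"))
  expect_true(all(eff$p < 0.05))           # all effects planted
  expect_equal(eff$numDF[eff$effect == "time"], 2L)  # das + das^2
  expect_gt(fix_fit$phi, 0.3)              # true rho = 0.6
  expect_lt(fix_fit$phi, 0.85)
  expect_equal(length(fix_fit$residuals), nrow(fix_tab))

  # NonArea descriptor: no quadratic term
  fitc <- fit_lme(fix_tab, "compactness")
  expect_false("I(das^2)" %in% names(fitc$coefficients))
  expect_equal(fitc$effects$numDF[fitc$effects$effect == "time"], 1L)
})

test_that("iid errors yield a small fitted AR(1) parameter", {
  spec0 <- table_effect_spec(n_ecotypes = 4, n_reps = 10, rho = 0,
                             descriptors = "area", seed = 5)
  fit0 <- fit_lme(apply_transforms(simulate_descriptor_table(spec0)),
                  "area")
  expect_lt(abs(fit0$phi), 0.2)
})

test_that("single-time-point table reduces to a one-way layout", {
  spec1 <- table_effect_spec(n_ecotypes = 3, n_reps = 6, das = 22,
                             descriptors = "compactness", seed = 9)
  tab1 <- simulate_descriptor_table(spec1)
  fit1 <- fit_lme(tab1, "compactness")
  cf <- fit1$coefficients
  mu <- tapply(tab1$compactness, tab1$ecotype, mean)
  expect_equal(unname(cf["(Intercept)"]), unname(mu[1]), tolerance = 1e-6)
  expect_equal(unname(cf["(Intercept)"] + cf["ecotypeE02"]),
               unname(mu[2]), tolerance = 1e-6)
  expect_true(is.na(fit1$phi))
})

test_that("degenerate designs raise informative errors", {
  one_eco <- data.frame(plant_id = rep(c("a", "b"), each = 2),
                        ecotype = "E1", das = rep(c(1, 2), 2),
                        area = rnorm(4))
  expect_error(fit_lme(one_eco, "area"), "2 ecotypes")
  single <- data.frame(plant_id = c("a", "b"), ecotype = c("E1", "E2"),
                       das = 1, area = rnorm(2))
  expect_error(fit_lme(single, "area"), "2 plants")
})

test_that("pairwise contrasts carry Bonferroni adjustment and tiers", {
  pw <- tukey_pairwise(fix_fit, "ecotype")
  expect_equal(nrow(pw), choose(5, 2))
  expect_true(all(pw$p_adjusted >= pw$p_raw - 1e-12))
  expect_true(all(pw$p_adjusted <= 1))
  # monotone in raw p
  expect_false(is.unsorted(pw$p_adjusted[order(pw$p_raw)]))
  # extreme planted pair (offsets -2 vs +2 SD) is in the < 0.01 tier
  expect_equal(as.character(pw$tier[pw$contrast == "E01 - E05"]), "<0.01")

  pd <- tukey_pairwise(fix_fit, "das")
  expect_equal(nrow(pd), choose(5, 2))
  expect_true(all(pd$p_adjusted < 0.05))  # strong planted growth

  # two levels: one contrast, adjustment factor 1
  spec2 <- table_effect_spec(n_ecotypes = 2, n_reps = 5,
                             descriptors = "area", seed = 3)
  fit2 <- fit_lme(apply_transforms(simulate_descriptor_table(spec2)),
                  "area")
  pw2 <- tukey_pairwise(fit2, "ecotype")
  expect_equal(nrow(pw2), 1L)
  expect_equal(pw2$p_adjusted, pw2$p_raw)
})

test_that("19 ecotypes produce 171 pairwise contrasts", {
  spec19 <- table_effect_spec(n_reps = 2, descriptors = "area", seed = 11)
  fit19 <- fit_lme(apply_transforms(simulate_descriptor_table(spec19)),
                   "area")
  expect_equal(nrow(tukey_pairwise(fit19, "ecotype")), 171L)
})

test_that("PCA percent variance behaves on analytic cases", {
  # two perfectly correlated columns -> PC1 carries 100%
  d <- data.frame(plant_id = sprintf("p%d", 1:40), ecotype = "E",
                  das = 17, area = exp(rnorm(40)))
  d$conhullarea <- d$area * 3
  p <- pca_per_timepoint(d, das = 17,
                         descriptors = c("area", "conhullarea"))
  expect_equal(p$percent[1], 100, tolerance = 1e-9)
  expect_equal(sum(p$percent), 100, tolerance = 1e-9)

  # independent standardized columns: each PC near 100/k
  set.seed(21)
  k <- 4
  big <- data.frame(plant_id = sprintf("p%d", 1:4000), ecotype = "E",
                    das = 17, area = exp(rnorm(4000)),
                    compactness = rnorm(4000), roundness = rnorm(4000),
                    paxratio = rnorm(4000))
  pb <- pca_per_timepoint(big, das = 17,
                          descriptors = c("area", "compactness",
                                          "roundness", "paxratio"))
  expect_true(all(abs(pb$percent - 100 / k) < 5))

  # invariance to affine rescaling (standardisation)
  big2 <- big; big2$compactness <- big2$compactness * 1000 + 5
  pb2 <- pca_per_timepoint(big2, das = 17,
                           descriptors = c("area", "compactness",
                                           "roundness", "paxratio"))
  expect_equal(pb$percent, pb2$percent, tolerance = 1e-9)

  # zero-variance column dropped with a warning
  bigz <- big; bigz$roundness <- 1
  expect_warning(pz <- pca_per_timepoint(bigz, das = 17,
                                         descriptors = c("area",
                                                         "compactness",
                                                         "roundness")),
                 "zero-variance")
  expect_equal(length(pz$descriptors), 2L)

  expect_error(pca_per_timepoint(big, das = 17, subset = "nosuch"),
               "not in table")
})

test_that("PCA subset option restricts to the comparison descriptors", {
  tab <- simulate_descriptor_table(
    table_effect_spec(n_ecotypes = 4, n_reps = 6, seed = 2))
  p <- pca_per_timepoint(tab, das = 17,
                         subset = perez_perez_descriptors())
  expect_setequal(p$descriptors, perez_perez_descriptors())
  expect_length(perez_perez_descriptors(), 7L)
  expect_equal(sum(p$percent), 100, tolerance = 1e-9)
})

test_that("ReliefF weights match a brute-force hand oracle (k = 1)", {
  # 6 instances, 2 features, 2 balanced classes
  x <- rbind(c(0.0, 0.1), c(0.1, 0.9), c(0.2, 0.5),
             c(0.8, 0.2), c(0.9, 0.8), c(1.0, 0.5))
  y <- c("a", "a", "a", "b", "b", "b")
  got <- relieff_rank(x, y, k = 1)$weights

  # literal transcription of the definition: normalise to [0,1] range,
  # manhattan nearest hit/miss per instance, prior weight 0.5/(1-0.5)=1
  xs <- apply(x, 2, function(v) (v - min(v)) / diff(range(v)))
  w <- c(0, 0)
  for (i in 1:6) {
    d <- rowSums(abs(xs - matrix(xs[i, ], 6, 2, byrow = TRUE)))
    hits <- which(y == y[i]); hits <- hits[hits != i]
    miss <- which(y != y[i])
    h <- hits[which.min(d[hits])]
    m <- miss[which.min(d[miss])]
    w <- w - abs(xs[h, ] - xs[i, ]) / 6 + abs(xs[m, ] - xs[i, ]) / 6
  }
  expect_equal(unname(got), unname(w), tolerance = 1e-12)
})

test_that("ReliefF separates informative from constant/noise features", {
  # constant feature gets weight exactly 0
  x <- cbind(f1 = rep(c(0, 1), each = 8), f2 = rep(3.7, 16))
  r <- relieff_rank(x, rep(c("a", "b"), each = 8), k = 3)
  expect_equal(unname(r$weights["f2"]), 0)
  expect_gt(r$weights["f1"], 0)
  expect_equal(r$ranking[1], "f1")

  # separating feature beats pure noise across seeded runs
  wins <- 0L
  for (s in 1:50) {
    set.seed(s)
    n <- 30
    cls <- rep(c("a", "b"), each = n / 2)
    xx <- cbind(sep = ifelse(cls == "a", 0, 1) + rnorm(n, sd = 0.15),
                noise = runif(n))
    rr <- relieff_rank(xx, cls, k = 5)
    wins <- wins + (rr$weights["sep"] > rr$weights["noise"])
  }
  expect_gte(wins, 49L)
})

test_that("ReliefF is permutation-equivariant and validates inputs", {
  set.seed(31)
  x <- matrix(runif(60), ncol = 3,
              dimnames = list(NULL, c("u", "v", "w")))
  y <- rep(c("a", "b"), each = 10)
  r1 <- relieff_rank(x, y, k = 4)
  r2 <- relieff_rank(x[, c(3, 1, 2)], y, k = 4)
  expect_equal(r2$weights[c("u", "v", "w")], r1$weights[c("u", "v", "w")])

  expect_error(relieff_rank(x, rep("a", 20), k = 2), "2 classes")
  expect_warning(relieff_rank(x[1:5, ], c("a", "a", "a", "b", "b"), k = 4),
                 "k reduced")
})
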