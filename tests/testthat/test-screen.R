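# Population screening: saturation catalogs, allele-frequency enrichment,
# protective-variant elimination and case/control testing.

law_scorer <- function(law) {
  function(s) vapply(s, function(x) lawProximal(law, x), numeric(1),
                     USE.NAMES = FALSE)
}

test_that("the saturation catalog is complete and internally consistent", {
  law <- defaultLaw()
  pas <- data.frame(id = 1:2,
                    sequence = pasSequences(tiny_bundle(2, seed = 80)))
  cat <- saturationScreen(law_scorer(law), pas, baselines = c(0.4, 0.6))
  expect_equal(nrow(cat), 2L * 3L * 205L)
  expect_equal(as.vector(table(cat$pas)), rep(615L, 2))
  # reference rows are absent: alt always differs from ref
  expect_true(all(cat$ref != cat$alt))
  # delta_use is consistent with its defining transform
  base <- ifelse(cat$pas == 1, 0.4, 0.6)
  expect_equal(cat$delta_use, deltaUsage(cat$lor, base), tolerance = 1e-12)
  expect_error(saturationScreen(law_scorer(law), pas, baselines = 0),
               "baselines")
})

test_that("allele-frequency enrichment ratios are relative to singletons", {
  set.seed(81)
  n <- 2000
  base <- rnorm(n, 0, 0.1)
  cat0 <- data.frame(af_class = sample(c("singleton", "rare", "common"), n,
                                       replace = TRUE),
                     delta_use = base)
  r0 <- afEnrichment(cat0)
  expect_equal(r0$enrichment[r0$af_class != "singleton"], c(1, 1),
               tolerance = 0.35)
  # planted depletion: disruptive variants 2.5-fold rarer among common
  sing <- c(rnorm(800, 0, 0.05), rnorm(200, -0.3, 0.05))  # 20% disruptive
  comm <- c(rnorm(920, 0, 0.05), rnorm(80, -0.3, 0.05))   # 8% disruptive
  cat1 <- data.frame(
    af_class = rep(c("singleton", "common"), c(1000, 1000)),
    delta_use = c(sing, comm))
  r1 <- afEnrichment(cat1)
  expect_equal(r1$enrichment[r1$af_class == "common"], 0.4, tolerance = 0.15)
  expect_lt(r1$p_value[r1$af_class == "common"], 0.01)
  # the threshold is a strict inequality
  catb <- data.frame(af_class = rep("singleton", 4),
                     delta_use = c(-0.15, -0.15, -0.2, 0))
  expect_equal(afEnrichment(catb)$frac_disruptive, 0.25)
  expect_error(afEnrichment(data.frame(af_class = "common", delta_use = 0)),
               "singleton")
})

test_that("protective-variant elimination reproduces hand-worked decisions", {
  an <- 150000
  common <- 20    # AF = 1.33e-4 > 1e-4 cutoff
  rare <- 5       # AF = 3.3e-5 <= cutoff
  cohort <- data.frame(pas = c(1, 2, 3), lor = c(1.0, 1.0, 2.0))
  background <- data.frame(
    pas = c(1, 2, 3),
    lor = c(1.2, 1.2, 1.2),
    allele_count = c(common, rare, common))
  # strictly-larger rule: PAS 1 removed (1.2 > 1.0 and common); PAS 2 kept
  # (background too rare); PAS 3 kept (1.2 < 2.0)
  r <- eliminateProtected(cohort, background, af_cutoff = 1e-4)
  expect_equal(r$cohort$pas, c(2, 3))
  expect_equal(r$audit$pas, 1)
  expect_equal(r$audit$rule, "common_strictly_larger")
  expect_equal(r$audit$trigger, 1.2)
  # 1.5-fold rule: |background| must reach 1.5x the cohort effect
  r15 <- eliminateProtected(data.frame(pas = 1, lor = 1.0), background[1, ],
                            af_cutoff = 1e-4, fold_rule = 1.5)
  expect_equal(nrow(r15$cohort), 1L)   # 1.2 < 1.5, retained
  r15b <- eliminateProtected(data.frame(pas = 1, lor = 0.7), background[1, ],
                             af_cutoff = 1e-4, fold_rule = 1.5)
  expect_equal(nrow(r15b$cohort), 0L)  # 1.2 >= 1.05, removed
  # no background variant above the AF cutoff: cohort unchanged
  r0 <- eliminateProtected(cohort, transform(background, allele_count = 1),
                           af_cutoff = 1e-4)
  expect_equal(nrow(r0$cohort), 3L)
  expect_equal(nrow(r0$audit), 0L)
})

test_that("five-bin aggregation lets rare variants act as one common variant", {
  an <- 150000
  # three rare variants with comparable effects in one PAS: joint allele
  # count 30 crosses the AF cutoff and their bin dominates the cohort variant
  background <- data.frame(pas = 1, lor = c(1.18, 1.20, 1.22, -0.5),
                           allele_count = c(10, 10, 10, 2))
  cohort <- data.frame(pas = 1, lor = 1.0)
  r_none <- eliminateProtected(cohort, background, af_cutoff = 1e-4,
                               binning = "none")
  expect_equal(nrow(r_none$cohort), 1L)  # individually all too rare
  r_bin <- eliminateProtected(cohort, background, af_cutoff = 1e-4,
                              binning = "five_bin")
  expect_equal(nrow(r_bin$cohort), 0L)
  expect_equal(r_bin$audit$trigger, 1.22)
})

test_that("the downstream-neighbour rule and multi-PAS assignment apply", {
  pas_info <- data.frame(id = 1:2, downstream_neighbor_nt = c(150, 400))
  cohort <- data.frame(pas = c(1, 2), lor = c(1, 1))
  r <- eliminateProtected(cohort, data.frame(pas = integer(0), lor = numeric(0),
                                             allele_count = integer(0)),
                          neighbor_rule_nt = 200, pas_info = pas_info)
  expect_equal(r$cohort$pas, 2)
  expect_equal(r$audit$rule, "downstream_neighbor")
  # a variant overlapping two PASs is assigned to the larger predicted effect
  dup <- data.frame(id = c("v1", "v1"), pas = c(1, 2), lor = c(0.5, -1.5))
  r2 <- eliminateProtected(dup, data.frame(pas = integer(0), lor = numeric(0),
                                           allele_count = integer(0)))
  expect_equal(r2$cohort$pas, 2)
  expect_true("multi_pas_assignment" %in% r2$audit$rule)
})

test_that("elimination is monotone in the allele-frequency cutoff", {
  set.seed(82)
  cohort <- data.frame(pas = sample(1:10, 50, replace = TRUE),
                       lor = rnorm(50))
  background <- data.frame(pas = sample(1:10, 200, replace = TRUE),
                           lor = rnorm(200, sd = 1.5),
                           allele_count = rpois(200, 20) + 1L)
  loose <- eliminateProtected(cohort, background, af_cutoff = 1e-5)
  tight <- eliminateProtected(cohort, background, af_cutoff = 1e-3)
  # a higher AF requirement can only remove a subset
  expect_true(all(tight$audit$row %in% loose$audit$row))
})

test_that("case/control comparison behaves at the null and under enrichment", {
  set.seed(83)
  x <- rnorm(200)
  cc0 <- cohortCompare(x, x)
  expect_equal(cc0$fold, 1)
  expect_gt(cc0$fisher_p, 0.99)
  expect_gt(cc0$wilcox_p, 0.99)
  # planted enrichment across seeds: median fold near 3, Fisher mostly small
  folds <- numeric(10)
  ps <- numeric(10)
  for (i in 1:10) {
    co <- generateVariantCohort(300, 300, enrichment = 3, seed = 8000 + i)
    cc <- cohortCompare(co$case$lor_true, co$ctrl$lor_true)
    folds[i] <- cc$fold
    ps[i] <- cc$fisher_p
  }
  expect_gt(median(folds), 2)
  expect_lt(median(folds), 4)
  expect_gte(mean(ps < 0.05), 0.9)
  # no exceeders in either group: fold undefined, reported missing
  ccm <- cohortCompare(rnorm(20, -3), rnorm(20, -3))
  expect_true(is.na(ccm$fold))
})

test_that("label-permuted comparisons yield uniform p-values", {
  set.seed(84)
  pool <- rnorm(120)
  ps <- replicate(200, {
    idx <- sample(120, 60)
    suppressWarnings(cohortCompare(pool[idx], pool[-idx])$wilcox_p)
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
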