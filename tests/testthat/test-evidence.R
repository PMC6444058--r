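gcps <- function(penetrance = 1) {
  disease_model("Greig cephalopolysyndactyly syndrome", "AD",
                omim_id = "175700", prevalence = 1e-6,
                penetrance = penetrance)
}

wilson <- function() {
  disease_model("Wilson disease", "AR", omim_id = "277900",
                prevalence = 1 / 30000, penetrance = 1,
                carrier_frequency = 1 / 90)
}

test_that("maximum credible allele frequency follows the closed form", {
  expect_equal(max_credible_af(gcps()), 1e-6 * 1 * 0.5 / 1)
  # linear in 1/penetrance: halving penetrance doubles the threshold
  expect_equal(max_credible_af(gcps(penetrance = 0.5)),
               2 * max_credible_af(gcps()))
  expect_equal(max_credible_af(gcps(), allelic_heterogeneity = 0.2),
               0.2 * max_credible_af(gcps()))
  # recessive default genotypic contribution is 1
  expect_equal(max_credible_af(wilson()), 1 / 30000)
  d <- disease_model("no prevalence", "AD", penetrance = 1)
  expect_message(thr <- max_credible_af(d), "unavailable")
  expect_true(is.na(thr))
})

test_that("max credible frequency is monotone in prevalence and penetrance", {
  prev <- sort(stats::runif(5, 1e-7, 1e-3))
  thr <- vapply(prev, function(p) {
    max_credible_af(disease_model("d", "AD", prevalence = p,
                                  penetrance = 1))
  }, numeric(1))
  expect_true(all(diff(thr) > 0))
  pen <- sort(stats::runif(5, 0.1, 1))
  thr2 <- vapply(pen, function(q) {
    max_credible_af(disease_model("d", "AD", prevalence = 1e-4,
                                  penetrance = q))
  }, numeric(1))
  expect_true(all(diff(thr2) < 0))
})

test_that("dominant high-frequency variants receive BS1 (not PM2)", {
  obs <- rbind(population_observation("ExAC r0.3", 0.0019,
                                      healthy_adult_observed = TRUE),
               population_observation("gnomAD r2.0", 0.002,
                                      healthy_adult_observed = TRUE))
  ev <- frequency_evidence(obs, gcps())
  expect_true("BS1" %in% ev$code)
  expect_true("BS2" %in% ev$code)
  expect_false("PM2" %in% ev$code)
  expect_false("BA1" %in% ev$code)
  # BS2 arrives at its default strong strength, downgradable
  bs2 <- ev[ev$code == "BS2", ]
  expect_equal(bs2$applied_strength, "STRONG")
})

test_that("recessive rare variants below carrier scale receive PM2", {
  obs <- population_observation("ExAC r0.3", 0.0005, allele_count = 60L,
                                homozygote_count = 0L)
  ev <- frequency_evidence(obs, wilson())
  expect_equal(ev$code, "PM2")
  expect_match(ev$justification, "no homozygote")
  # a reported homozygote suppresses PM2 for recessive disease
  obs_hom <- population_observation("ExAC r0.3", 0.0005,
                                    allele_count = 60L,
                                    homozygote_count = 2L)
  expect_equal(nrow(frequency_evidence(obs_hom, wilson())), 0L)
})

test_that("the stand-alone cutoff fires BA1", {
  obs <- population_observation("gnomAD r2.0", 0.10)
  ev <- frequency_evidence(obs, gcps())
  expect_true("BA1" %in% ev$code)
  expect_false("BS1" %in% ev$code)
})

test_that("no threshold means only BA1/PM2 logic, with a message", {
  d <- disease_model("orphan", "AD", penetrance = 1)
  obs <- population_observation("ExAC r0.3", 0.001)
  expect_message(ev <- frequency_evidence(obs, d), "BA1/PM2")
  expect_false("BS1" %in% ev$code)
})

test_that("BS1 and PM2 are never emitted together", {
  set.seed(47)
  for (rep in 1:40) {
    inh <- sample(c("AD", "AR"), 1)
    d <- disease_model("d", inh,
                       prevalence = 10^stats::runif(1, -7, -2),
                       penetrance = stats::runif(1, 0.3, 1),
                       carrier_frequency = if (inh == "AR")
                         10^stats::runif(1, -3, -1) else NA_real_)
    obs <- population_observation(
      "sim", 10^stats::runif(1, -6, -0.5),
      homozygote_count = sample(0:2, 1) * 5L,
      healthy_adult_observed = sample(c(TRUE, FALSE), 1))
    ev <- suppressMessages(frequency_evidence(obs, d))
    expect_false(all(c("BS1", "PM2") %in% ev$code))
  }
})

test_that("computational consensus needs all three predictors to agree", {
  verdicts <- c("DELETERIOUS", "TOLERATED", "UNKNOWN")
  grid <- expand.grid(p = verdicts, s = verdicts, m = verdicts,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    ev <- computational_consensus(grid$p[i], grid$s[i], grid$m[i])
    if (all(grid[i, ] == "DELETERIOUS")) {
      expect_equal(ev$code, "PP3")
    } else if (all(grid[i, ] == "TOLERATED")) {
      expect_equal(ev$code, "BP4")
    } else {
      expect_null(ev)
    }
  }
  expect_equal(computational_consensus("damaging", "Deleterious",
                                       "deleterious")$code, "PP3")
  expect_error(computational_consensus("maybe", "TOLERATED", "TOLERATED"),
               "verdict")
})

test_that("functional evidence requires a biologically relevant assay", {
  expect_equal(functional_evidence("NO_EFFECT", TRUE)$code, "BS3")
  expect_equal(functional_evidence("DAMAGING", TRUE)$code, "PS3")
  expect_message(ev <- functional_evidence("DAMAGING", FALSE),
                 "disregarded")
  expect_null(ev)
  expect_message(ev2 <- functional_evidence("EQUIVOCAL", TRUE),
                 "disregarded")
  expect_null(ev2)
  expect_error(functional_evidence("BROKEN", TRUE), "effect")
})

test_that("the GLI3-style pipeline reclassifies as likely benign", {
  obs <- rbind(population_observation("ExAC r0.3", 0.0019,
                                      healthy_adult_observed = TRUE),
               population_observation("gnomAD r2.0", 0.002,
                                      healthy_adult_observed = TRUE))
  ev <- frequency_evidence(obs, gcps())
  i <- which(ev$code == "BS2")
  ev[i, ] <- adjust_strength(ev[i, ], "SUPPORTING",
                             "penetrance is not 100%")
  func <- suppressMessages(functional_evidence("DAMAGING", FALSE))
  r <- combine_evidence(rbind(ev, func))
  expect_equal(r$classification, "LIKELY_BENIGN")
  expect_false(r$conflicting)
})

test_that("the ATP7B-style pipeline yields a conflicted VUS", {
  obs <- rbind(population_observation("ExAC r0.3", 0.0005,
                                      homozygote_count = 0L),
               population_observation("gnomAD r2.0", 0.0004,
                                      homozygote_count = 0L))
  freq <- frequency_evidence(obs, wilson())
  expect_equal(freq$code, "PM2")
  pm3 <- evidence_assignment(
    "PM3", justification = "detected in trans with a pathogenic variant")
  bs3 <- functional_evidence("NO_EFFECT", TRUE, source = "copper assays")
  r <- combine_evidence(rbind(freq, pm3, bs3))
  expect_equal(r$classification, "VUS")
  expect_true(r$conflicting)
})
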