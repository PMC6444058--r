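test_that("evidence codes carry polarity and default strength", {
  codes <- acmg_codes()
  expect_equal(nrow(codes), 28L)
  expect_equal(codes$default_strength[codes$code == "PVS1"], "VERY_STRONG")
  expect_equal(codes$polarity[codes$code == "BA1"], "BENIGN")
  expect_equal(codes$default_strength[codes$code == "BA1"], "STAND_ALONE")
  a <- evidence_assignment("PM2")
  expect_equal(a$applied_strength, "MODERATE")
  expect_error(evidence_assignment("PX9"), "unknown")
})

test_that("strength adjustment requires justification, keeps polarity", {
  a <- evidence_assignment("BS2")
  down <- adjust_strength(a, "SUPPORTING", "penetrance is not 100%")
  expect_equal(down$applied_strength, "SUPPORTING")
  expect_equal(down$default_strength, "STRONG")
  expect_equal(down$polarity, "BENIGN")
  expect_error(adjust_strength(a, "SUPPORTING", "  "), "justification")
  expect_error(adjust_strength(a, "SUPPORTING"), "justification")
  expect_error(adjust_strength(evidence_assignment("BS3"), "PATHOGENIC",
                               "flip it"), "immutable")
  expect_error(adjust_strength(evidence_assignment("PM1"), "STAND_ALONE",
                               "why not"), "benign")
  # same strength with a justification: unchanged record with note
  same <- adjust_strength(evidence_assignment("PM2"), "MODERATE",
                          "confirmed default")
  expect_equal(same$applied_strength, "MODERATE")
  expect_equal(same$justification, "confirmed default")
})

test_that("worked evidence combinations reproduce the expected classes", {
  gli3 <- rbind(evidence_assignment("BS1"),
                adjust_strength(evidence_assignment("BS2"), "SUPPORTING",
                                "penetrance is not 100%"))
  r <- combine_evidence(gli3)
  expect_equal(r$classification, "LIKELY_BENIGN")
  expect_false(r$conflicting)

  atp7b <- rbind(evidence_assignment("PM2"), evidence_assignment("PM3"),
                 evidence_assignment("BS3"))
  r2 <- combine_evidence(atp7b)
  expect_equal(r2$classification, "VUS")
  expect_true(r2$conflicting)

  r3 <- combine_evidence(NULL)
  expect_equal(r3$classification, "VUS")
  expect_false(r3$conflicting)

  r4 <- combine_evidence(rbind(evidence_assignment("PVS1"),
                               evidence_assignment("PS1")))
  expect_equal(r4$classification, "PATHOGENIC")

  # simultaneous firing on both sides is a conflict
  r5 <- combine_evidence(rbind(evidence_assignment("PVS1"),
                               evidence_assignment("PS1"),
                               evidence_assignment("BA1")))
  expect_equal(r5$classification, "VUS")
  expect_true(r5$conflicting)
})

test_that("duplicated evidence codes are counted once", {
  dup <- rbind(evidence_assignment("BS1"), evidence_assignment("BS1"),
               evidence_assignment("BS1"))
  expect_message(r <- combine_evidence(dup), "duplicated")
  # one strong benign alone fires nothing
  expect_equal(r$classification, "VUS")
  expect_equal(nrow(r$evidence), 1L)
})

test_that("combine_evidence is invariant under evidence permutation", {
  set.seed(31)
  all_codes <- acmg_codes()$code
  for (rep in 1:20) {
    codes <- sample(all_codes, sample(2:7, 1))
    ev <- do.call(rbind, lapply(codes, evidence_assignment))
    r1 <- combine_evidence(ev)
    r2 <- combine_evidence(ev[sample(nrow(ev)), ])
    expect_equal(r2$classification, r1$classification)
    expect_equal(r2$conflicting, r1$conflicting)
    expect_equal(sort(r2$fired_rules), sort(r1$fired_rules))
  }
})

test_that("count-level engine agrees with the independent rule encoding", {
  grid <- expand.grid(pvs = 0:4, ps = 0:4, pm = 0:4, pp = 0:4,
                      ba = 0:4, bs = 0:4, bp = 0:4)
  got <- classify_evidence_counts(grid$pvs, grid$ps, grid$pm, grid$pp,
                                  grid$ba, grid$bs, grid$bp)
  want <- oracle_classify(grid$pvs, grid$ps, grid$pm, grid$pp,
                          grid$ba, grid$bs, grid$bp)
  expect_equal(got$classification, want$classification)
  expect_equal(got$conflicting, want$conflicting)
})

test_that("evidence-list engine agrees with the count-level engine", {
  set.seed(37)
  for (rep in 1:60) {
    k <- c(pvs = sample(0:1, 1), ps = sample(0:4, 1), pm = sample(0:4, 1),
           pp = sample(0:4, 1), ba = sample(0:1, 1), bs = sample(0:4, 1),
           bp = sample(0:4, 1))
    ev <- evidence_from_counts(k["pvs"], k["ps"], k["pm"], k["pp"],
                               k["ba"], k["bs"], k["bp"])
    r <- combine_evidence(ev)
    want <- oracle_classify(k["pvs"], k["ps"], k["pm"], k["pp"],
                            k["ba"], k["bs"], k["bp"])
    expect_equal(r$classification, want$classification)
    expect_equal(r$conflicting, want$conflicting)
  }
})

test_that("added pathogenic evidence never moves the class toward benign", {
  set.seed(41)
  codes <- acmg_codes()
  for (rep in 1:120) {
    base <- sample(codes$code, sample(0:6, 1))
    ev <- if (length(base)) do.call(rbind, lapply(base,
                                                  evidence_assignment))
    r0 <- combine_evidence(ev)
    pool <- setdiff(codes$code[codes$polarity == "PATHOGENIC"], base)
    add <- sample(pool, 1)
    r1 <- combine_evidence(rbind(ev, evidence_assignment(add)))
    if (!r1$conflicting) {
      expect_gte(acmg_rank[[r1$classification]],
                 acmg_rank[[r0$classification]])
    }
    pool_b <- setdiff(codes$code[codes$polarity == "BENIGN"], base)
    add_b <- sample(pool_b, 1)
    r2 <- combine_evidence(rbind(ev, evidence_assignment(add_b)))
    if (!r2$conflicting) {
      expect_lte(acmg_rank[[r2$classification]],
                 acmg_rank[[r0$classification]])
    }
  }
})

test_that("reports render deterministically and round-trip the class", {
  set.seed(43)
  gli3 <- read_evidence_table(fixture("evidence_gli3.tsv"))
  r <- combine_evidence(gli3)
  report <- render_report(r)
  expect_identical(report, render_report(combine_evidence(gli3)))
  expect_match(report, "BS1")
  expect_match(report, "BS2")
  expect_match(report, "Likely benign")
  expect_match(report, "default=STRONG applied=SUPPORTING")
  back <- parse_report(report)
  expect_equal(back$classification, r$classification)
  expect_equal(back$conflicting, r$conflicting)

  empty <- render_report(combine_evidence(NULL))
  expect_match(empty, "no criteria met")
  expect_match(empty, "Uncertain significance")

  for (rep in 1:10) {
    ev <- do.call(rbind, lapply(sample(acmg_codes()$code, sample(1:6, 1)),
                                evidence_assignment))
    r <- combine_evidence(ev)
    back <- parse_report(render_report(r))
    expect_equal(back$classification, r$classification)
    expect_equal(back$conflicting, r$conflicting)
  }
})

test_that("the shipped rule file is pinned", {
  rules <- acmg_rule_table()
  expect_equal(nrow(rules), 18L)
  expect_equal(sort(unique(rules$class)),
               c("BENIGN", "LIKELY_BENIGN", "LIKELY_PATHOGENIC",
                 "PATHOGENIC"))
  expect_equal(sum(rules$class == "PATHOGENIC"), 8L)
  expect_equal(sum(rules$class == "LIKELY_PATHOGENIC"), 6L)
})
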