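table1 <- function() read_contingency(fixture("table1_interpretations.tsv"))

test_that("five-tier classes harmonize onto the three buckets", {
  expect_equal(harmonize_class(c("PATHOGENIC", "LIKELY_PATHOGENIC", "VUS",
                                 "LIKELY_BENIGN", "BENIGN")),
               c("DISEASE", "DISEASE", "UNCLASSIFIED",
                 "POLYMORPHISM", "POLYMORPHISM"))
  # synonyms and pass-through of bucket tokens
  expect_equal(harmonize_class(c("Likely benign", "DISEASE")),
               c("POLYMORPHISM", "DISEASE"))
})

test_that("contingency construction equals brute-force tallies", {
  pairs <- data.frame(uniprot_class = c("DISEASE", "POLYMORPHISM"),
                      aggregate_class = c("PATHOGENIC", "BENIGN"),
                      gene_symbol = c("A", "B"), hgvs_p = NA,
                      condition = c("a", "b"))
  t <- build_contingency(pairs)
  expect_equal(diag(unclass(t)), c(DISEASE = 1L, POLYMORPHISM = 1L,
                                   UNCLASSIFIED = 0L))
  expect_equal(sum(t) - sum(diag(t)), 0L)

  set.seed(5)
  for (rep in 1:10) {
    n <- 50
    ub <- sample(uniprot_classes(), n, replace = TRUE)
    cc <- sample(acmg_classes(), n, replace = TRUE)
    pairs <- data.frame(uniprot_class = ub, aggregate_class = cc,
                        gene_symbol = "G", hgvs_p = NA, condition = "c")
    expect_equal(unclass(build_contingency(pairs)),
                 brute_contingency(ub, cc), ignore_attr = TRUE)
  }
})

test_that("a pair without a classification is reported by name", {
  pairs <- data.frame(uniprot_class = c("DISEASE", NA),
                      aggregate_class = c("PATHOGENIC", "BENIGN"),
                      gene_symbol = c("A", "BADGENE"), hgvs_p = "p.Ala2Val",
                      condition = c("a", "b"))
  expect_error(build_contingency(pairs), "BADGENE")
})

test_that("per-category concordance uses the union denominator", {
  t1 <- table1()
  expect_equal(category_concordance(t1, "POLYMORPHISM"), 100 * 2328 / 2694)
  expect_equal(round_half_up(category_concordance(t1, "POLYMORPHISM")), 86)
  expect_equal(round_half_up(category_concordance(t1, "DISEASE")), 81)
  expect_equal(round_half_up(category_concordance(t1, "UNCLASSIFIED")), 24)
  ident <- contingency_table(diag(c(5, 3, 2)))
  for (b in uniprot_classes()) {
    expect_equal(category_concordance(ident, b), 100)
  }
  empty_bucket <- contingency_table(diag(c(5, 3, 0)))
  expect_error(category_concordance(empty_bucket, "UNCLASSIFIED"),
               "undefined")
})

test_that("overall concordance is trace over total", {
  rep1 <- overall_concordance(table1())
  expect_equal(rep1$n_total, 4286L)
  expect_equal(rep1$n_agree, 3771L)
  expect_equal(round_half_up(rep1$overall), 88)
  expect_equal(overall_concordance(contingency_table(diag(c(1, 2, 3))))$
                 overall, 100)
  expect_error(overall_concordance(contingency_table(matrix(0, 3, 3))),
               "empty")
  set.seed(9)
  for (rep in 1:20) {
    m <- matrix(sample(0:30, 9, replace = TRUE), 3, 3)
    if (sum(m) == 0) next
    r <- overall_concordance(contingency_table(m))
    expect_equal(r$overall, 100 * sum(diag(m)) / sum(m))
    expect_true(r$n_agree <= r$n_total)
    expect_true(all(stats::na.omit(r$per_category) <= 100))
  }
})

test_that("category concordance is 100 iff off-diagonal marginals vanish", {
  set.seed(13)
  for (rep in 1:30) {
    m <- matrix(sample(0:5, 9, replace = TRUE), 3, 3)
    t <- contingency_table(m)
    for (b in uniprot_classes()) {
      off <- sum(t[b, ]) + sum(t[, b]) - 2 * t[b, b]
      union <- sum(t[b, ]) + sum(t[, b]) - t[b, b]
      if (union == 0) next
      cc <- category_concordance(t, b)
      expect_equal(cc == 100, off == 0)
    }
  }
})

test_that("overall concordance is invariant under bucket permutation", {
  set.seed(17)
  m <- matrix(sample(1:20, 9), 3, 3,
              dimnames = list(uniprot_classes(), uniprot_classes()))
  perm <- c(2, 3, 1)
  t0 <- overall_concordance(contingency_table(m))
  tp <- overall_concordance(contingency_table(m[perm, perm]))
  expect_equal(tp$overall, t0$overall)
  expect_equal(tp$per_category, t0$per_category)
})

test_that("transition tables cross-classify original vs re-curated class", {
  before <- data.frame(variant_id = paste0("v", 1:4),
                       uniprot_class = c("DISEASE", "DISEASE",
                                         "POLYMORPHISM", "UNCLASSIFIED"))
  unchanged <- data.frame(variant_id = paste0("v", 1:4),
                          acmg_class = c("PATHOGENIC", "LIKELY_PATHOGENIC",
                                         "BENIGN", "VUS"))
  t <- build_transition(before, unchanged)
  expect_equal(sum(diag(t)), 4L)
  expect_equal(sum(t) - sum(diag(t)), 0L)

  moved <- unchanged
  moved$acmg_class[2] <- "VUS"
  t2 <- build_transition(before, moved)
  expect_equal(t2["DISEASE", "UNCLASSIFIED"], 4L - 3L)

  expect_error(build_transition(before, unchanged[-1, ]), "unmatched")

  set.seed(23)
  for (rep in 1:10) {
    n <- 20
    b <- sample(uniprot_classes(), n, replace = TRUE)
    a <- sample(acmg_classes(), n, replace = TRUE)
    after <- data.frame(variant_id = sample(seq_len(n)))
    after$acmg_class <- a[after$variant_id]
    tt <- build_transition(
      data.frame(variant_id = seq_len(n), uniprot_class = b), after)
    expect_equal(unclass(tt), brute_contingency(b, a), ignore_attr = TRUE)
  }
})

test_that("the re-curation fixture reproduces its printed counts", {
  t3 <- read_contingency(fixture("table3_recuration_concordant.tsv"))
  expect_equal(diag(unclass(t3)), c(DISEASE = 54L, POLYMORPHISM = 38L,
                                    UNCLASSIFIED = 4L))
  expect_equal(t3["DISEASE", "UNCLASSIFIED"], 4L)
  expect_equal(sum(t3) - sum(diag(t3)), 4L)
  t2 <- read_contingency(fixture("table2_recuration_discordant.tsv"))
  expect_equal(sum(t2), 100L)
  expect_equal(sum(diag(t2)), 15L)
})

test_that("projection combines retention and resolution rates", {
  t1 <- table1()
  expect_equal(project_concordance(t1, 1, 1), 100)
  set.seed(29)
  for (rep in 1:20) {
    rr <- stats::runif(2)
    a <- sum(diag(t1)) / sum(t1)
    expect_equal(project_concordance(t1, rr[1], rr[2]),
                 100 * (a * rr[1] + (1 - a) * rr[2]))
  }
  expect_error(project_concordance(t1, 1.2, 0.5))
})

test_that("expanding a table into pairs and re-tallying recovers it", {
  t1 <- table1()
  pairs <- expand_contingency_pairs(t1)
  expect_equal(nrow(pairs), 4286L)
  expect_equal(unclass(build_contingency(pairs)), unclass(t1))
})

test_that("contingency fixtures survive a write/read cycle", {
  t1 <- table1()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contingency(t1, path)
  expect_equal(unclass(read_contingency(path)), unclass(t1))
})
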