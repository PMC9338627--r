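# Association-rule analytics and Kaplan-Meier survival.

test_that("transactions of the two-patient fixture match the hand sets", {
  tr <- build_transactions(two_patient_bundles())
  expect_identical(tr$n, 2L)
  expect_setequal(tr$transactions$P1,
                  c("EGFR", "TP53", "CHEK2", "osimertinib"))
  expect_setequal(tr$transactions$P2,
                  c("EGFR", "TP53", "DNMT3A", "CDKN2A/B", "RAF1",
                    "pembrolizumab"))
  # a patient with no post-test drugs still counts toward T
  coh <- two_patient_cohort()
  coh$medications <- coh$medications[0, ]
  tr2 <- build_transactions(build_bundles(coh))
  expect_identical(tr2$n, 2L)
  expect_setequal(tr2$transactions$P1, c("EGFR", "TP53", "CHEK2"))
  # empty cohort
  tr0 <- build_transactions(build_bundles(generate_cohort(
    cohort_config(n_patients = 0), seed = 1)))
  expect_identical(tr0$n, 0L)
})

test_that("support and confidence match the two-patient enumeration", {
  tr <- build_transactions(two_patient_bundles())
  expect_identical(support("EGFR", tr), 1)          # both carry EGFR
  expect_identical(support("osimertinib", tr), 0.5)
  expect_identical(support(c("EGFR", "TP53"), tr), 1)
  expect_identical(confidence("EGFR", "osimertinib", tr), 0.5)
  expect_identical(confidence(c("EGFR", "TP53"), "TP53", tr), 1)  # Y in X
  expect_identical(confidence("CHEK2", "pembrolizumab", tr), 0)
  expect_error(confidence("NOTANITEM", "EGFR", tr), "undefined rule")
  tr0 <- structure(list(transactions = list(), n = 0L),
                   class = "transaction_set")
  expect_error(support("EGFR", tr0), "empty transaction set")
})

test_that("support/confidence equal exhaustive counting on small cohorts", {
  coh <- generate_cohort(cohort_config(n_patients = 18), seed = 5)
  tr <- build_transactions(suppressWarnings(build_bundles(coh)))
  items <- unique(unlist(tr$transactions))
  expect_lte(tr$n, 20)
  set.seed(42)
  for (rep in 1:25) {
    X <- sample(items, sample(1:2, 1))
    Y <- sample(items, 1)
    expect_identical(support(X, tr), brute_support(X, tr$transactions))
    sX <- brute_support(X, tr$transactions)
    if (sX > 0) {
      want <- brute_support(unique(c(X, Y)), tr$transactions) / sX
      expect_equal(confidence(X, Y, tr), want, tolerance = 1e-12)
      expect_equal(confidence(X, Y, tr) * support(X, tr),
                   support(unique(c(X, Y)), tr), tolerance = 1e-12)
    }
  }
})

test_that("drug ranking is confidence-sorted with lexicographic ties", {
  trans <- list(A = c("G1", "d_b", "d_a"), B = c("G1", "d_b", "d_a"),
                C = c("G1", "d_c"), D = "d_c")
  tr <- structure(list(transactions = trans, n = 4L),
                  class = "transaction_set")
  out <- rank_drugs_for_gene("G1", tr, k = 10,
                             drug_items = c("d_b", "d_a", "d_c"))
  # d_a and d_b tie at 2/3 -> lexicographic; d_c at 1/3
  expect_identical(out$drug, c("d_a", "d_b", "d_c"))
  expect_equal(out$confidence, c(2/3, 2/3, 1/3), tolerance = 1e-12)
  # k larger than the number of drugs returns the full list
  expect_identical(nrow(rank_drugs_for_gene("G1", tr, k = 99,
                                            drug_items = c("d_a", "d_b"))),
                   2L)
  expect_error(rank_drugs_for_gene("NOGENE", tr, drug_items = "d_a"),
               "no support")
})

test_that("km_curve matches hand product-limit computations", {
  # all censored -> S = 1 everywhere, median undefined
  allc <- km_curve(data.frame(time = c(3, 7, 9), event = 0))
  expect_true(all(allc$surv == 1))
  expect_true(is.na(km_median(allc)))

  # times 1 (event), 2 (censored), 3 (event):
  # S(1) = 1 - 1/3 = 2/3; at t = 3 risk set = 1 -> S = 0
  k <- km_curve(data.frame(time = c(1, 2, 3), event = c(1, 0, 1)))
  expect_equal(k$surv, c(2/3, 2/3, 0), tolerance = 1e-12)
  expect_identical(km_median(k), 3)

  # single record, event at 5: S jumps 1 -> 0 at 5
  k1 <- km_curve(data.frame(time = 5, event = 1))
  expect_identical(k1$surv, 0)
  expect_identical(k1$time, 5)

  expect_error(km_curve(data.frame(time = -1, event = 1)), "non-negative")
})

test_that("km_curve matches the no-censoring closed form and survfit", {
  set.seed(9)
  time <- round(rweibull(60, 1.2, 400))
  k <- km_curve(data.frame(time = time, event = 1))
  # closed form without censoring: S(t) = #survivors past t / n
  for (t in k$time) {
    expect_equal(k$surv[k$time == t], sum(time > t) / length(time),
                 tolerance = 1e-12)
  }
  skip_if_not_installed("survival")
  ev <- rbinom(60, 1, 0.7)
  k2 <- km_curve(data.frame(time = time, event = ev))
  sf <- survival::survfit(survival::Surv(time, ev) ~ 1)
  sm <- summary(sf, times = k2$time)
  expect_equal(k2$surv[match(sm$time, k2$time)], sm$surv,
               tolerance = 1e-10)
})

test_that("TP53 stratification recovers the planted survival penalty", {
  coh <- memo("surv_cohort",
              generate_cohort(cohort_config(n_patients = 800), seed = 3))
  b <- suppressWarnings(build_bundles(coh))
  sv <- stratified_survival(b, "TP53", "lung adenocarcinoma")
  med <- sv$medians
  for (st in c("III", "IV")) {
    mm <- med$median[med$stage == st & med$status == "mutant"]
    mw <- med$median[med$stage == st & med$status == "wild-type"]
    expect_lt(mm, mw)
  }

  # null case: multiplier 1 leaves the stage-IV medians within noise
  sm <- default_survival_model()
  sm$hazard_multiplier <- c(TP53 = 1.0)
  coh0 <- generate_cohort(cohort_config(n_patients = 800,
                                        survival_model = sm), seed = 3)
  sv0 <- stratified_survival(suppressWarnings(build_bundles(coh0)),
                             "TP53", "lung adenocarcinoma")
  m0 <- sv0$medians
  r <- m0$median[m0$stage == "IV" & m0$status == "mutant"] /
    m0$median[m0$stage == "IV" & m0$status == "wild-type"]
  expect_gt(r, 0.6)
  expect_lt(r, 1.67)

  # disease absent from the cohort -> empty result, not a crash
  empty <- stratified_survival(b, "TP53", "mesothelioma")
  expect_identical(length(empty$curves), 0L)

  # degenerate input: everyone censored at day 0
  co <- two_patient_cohort()
  co$patients$death_date <- as.Date(NA)
  co$patients$last_contact_date <- co$patients$diagnosis_date
  svz <- stratified_survival(build_bundles(co), "TP53",
                             "lung adenocarcinoma")
  expect_true(all(is.na(svz$medians$median)))
})

test_that("co-occurrence summary counts patients once per pair", {
  rel <- derive_relations(two_patient_bundles())
  cs <- cooccurrence_summary(rel)
  e <- cs$edges
  lung_egfr <- e[e$from == "lung adenocarcinoma" & e$to == "EGFR", ]
  expect_identical(lung_egfr$weight, 1L)
  # gene-gene edges are never emitted
  expect_false(any(e$from_class == "Gene" & e$to_class == "Gene"))
  # EGFR partners: lung adenocarcinoma + melanoma (disease-gene) and
  # osimertinib (gene-drug) -> degree 3
  expect_identical(cs$nodes$degree[cs$nodes$name == "EGFR"], 3L)
  # duplicated relations from one patient do not inflate weights
  rel2 <- rbind(rel, rel)
  expect_identical(cooccurrence_summary(rel2)$edges, cs$edges)
  empty <- cooccurrence_summary(rel[0, ])
  expect_identical(nrow(empty$edges), 0L)
})
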