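# Record linkage, disease resolution, relation derivation and the
# temporal validity windows.

mk_patients <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}

test_that("linkage precedence: clinic number dominates, then name+dob", {
  pats <- mk_patients(
    patient_id = c("A", "B"),
    clinic_number = c("MC1", "MC2"),
    first_name = c("Jane", "John"), last_name = c("Doe", "Smith"),
    dob = as.Date(c("1960-01-01", "1970-02-02")))
  rep1 <- data.frame(report_id = "R1", clinic_number = "MC1",
                     first_name = "Totally", last_name = "Different",
                     dob = as.Date("1999-09-09"), stringsAsFactors = FALSE)
  out <- link_records(rep1, pats)
  expect_identical(out$linked$patient_id, "A")   # clinic number wins

  rep2 <- data.frame(report_id = "R2", clinic_number = "",
                     first_name = "JOHN ", last_name = "smith",
                     dob = as.Date("1970-02-02"), stringsAsFactors = FALSE)
  out2 <- link_records(rep2, pats)
  expect_identical(out2$linked$patient_id, "B")  # case-folded name + dob

  rep3 <- data.frame(report_id = "R3", clinic_number = "",
                     first_name = "John", last_name = "Smith",
                     dob = as.Date("1970-02-03"), stringsAsFactors = FALSE)
  out3 <- link_records(rep3, pats)
  expect_identical(nrow(out3$linked), 0L)        # dob differs -> unlinked
  expect_identical(out3$unlinked$report_id, "R3")
})

test_that("ambiguous linkage is an error listing candidates", {
  pats <- mk_patients(
    patient_id = c("A", "B"),
    clinic_number = c("MC1", "MC1"),
    first_name = c("Jane", "Janet"), last_name = c("Doe", "Doe"),
    dob = as.Date(c("1960-01-01", "1961-01-01")))
  rep1 <- data.frame(report_id = "R1", clinic_number = "MC1",
                     first_name = "Jane", last_name = "Doe",
                     dob = as.Date("1960-01-01"), stringsAsFactors = FALSE)
  expect_error(link_records(rep1, pats), "ambiguous.*A.*B")
})

test_that("disease resolution keeps the report as gold standard", {
  rep_dx <- data.frame(diagnosis_text = "lung adenocarcinoma",
                       date = as.Date("2019-01-01"), stage = "III",
                       is_primary = TRUE, stringsAsFactors = FALSE)
  wh_dx <- data.frame(diagnosis_text = c("melanoma", "hypertension"),
                      date = as.Date(c("2019-01-05", "2018-01-01")),
                      stage = c("II", ""), is_primary = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  res <- resolve_diseases(rep_dx, wh_dx)
  expect_setequal(res$disease, c("lung adenocarcinoma", "melanoma"))
  expect_false(res$superseded[res$disease == "lung adenocarcinoma"])
  expect_true(res$superseded[res$disease == "melanoma"])
  expect_false("hypertension" %in% res$disease)   # non-cancer filtered

  # concordant sources merge to one entry; warehouse date/stage win
  wh2 <- data.frame(diagnosis_text = "lung adenocarcinoma",
                    date = as.Date("2019-01-10"), stage = "IV",
                    is_primary = TRUE, stringsAsFactors = FALSE)
  res2 <- resolve_diseases(rep_dx, wh2)
  expect_identical(nrow(res2), 1L)
  expect_identical(res2$sources, "report+warehouse")
  expect_identical(res2$date, as.Date("2019-01-10"))
  expect_identical(res2$stage, "IV")
})

test_that("the two-patient worked example yields the expected relations", {
  rel <- derive_relations(two_patient_bundles())
  p1 <- rel[rel$patient_id == "P1", ]
  cnt <- table(p1$predicate)
  expect_identical(as.integer(cnt[["HasMutGene"]]), 3L)
  expect_identical(as.integer(cnt[["HasVariant"]]), 3L)
  expect_identical(as.integer(cnt[["AssociatedWithVariant"]]), 3L)
  expect_identical(as.integer(cnt[["HasDisease"]]), 1L)
  expect_identical(as.integer(cnt[["AssociatedWithGene"]]), 3L)
  expect_identical(as.integer(cnt[["TreatedBy"]]), 1L)
  expect_identical(as.integer(cnt[["MayTreatedBy"]]), 1L)
  expect_identical(
    p1[p1$predicate == "TreatedBy", "object"], "osimertinib")
  mtb <- p1[p1$predicate == "MayTargetedBy", ]
  expect_identical(nrow(mtb), 1L)
  expect_identical(mtb$subject, "EGFR")
  expect_identical(mtb$object, "osimertinib")

  # patient 2: pembrolizumab is not a targeted therapy -> TreatedBy only
  p2 <- rel[rel$patient_id == "P2", ]
  expect_identical(p2[p2$predicate == "TreatedBy", "object"],
                   "pembrolizumab")
  expect_identical(nrow(p2[p2$predicate == "MayTargetedBy", ]), 0L)
  expect_identical(sum(p2$predicate == "HasMutGene"), 5L)
})

test_that("temporal windows exclude out-of-range records", {
  coh <- two_patient_cohort()
  coh$medications$date[1] <- coh$reports$receipt_date[1] + 400
  rel <- derive_relations(build_bundles(coh))
  p1 <- rel[rel$patient_id == "P1", ]
  expect_identical(nrow(p1[p1$predicate %in%
                             c("TreatedBy", "MayTargetedBy"), ]), 0L)
  # ... but the disease-drug association has no upper bound
  expect_identical(p1[p1$predicate == "MayTreatedBy", "object"],
                   "osimertinib")

  # boundary: day +365 is in, +366 is out; dx at -365 in, -366 out
  for (off in c(365, 366)) {
    coh2 <- two_patient_cohort()
    coh2$medications$date[1] <- coh2$reports$receipt_date[1] + off
    r <- derive_relations(build_bundles(coh2))
    expect_identical("TreatedBy" %in%
                       r$predicate[r$patient_id == "P1"], off == 365)
  }
  for (off in c(365, 366)) {
    coh2 <- two_patient_cohort()
    coh2$diagnoses$date[1] <- coh2$reports$receipt_date[1] - off
    coh2$patients$diagnosis_date[1] <- coh2$diagnoses$date[1]
    r <- derive_relations(build_bundles(coh2))
    expect_identical("HasDisease" %in%
                       r$predicate[r$patient_id == "P1"], off == 365)
  }
})

test_that("repeat prescriptions collapse to one disease-drug relation", {
  coh <- two_patient_cohort()
  extra <- coh$medications[1, ]
  extra$date <- extra$date + 60
  coh$medications <- rbind(coh$medications, extra)
  rel <- derive_relations(build_bundles(coh))
  mtb <- rel[rel$patient_id == "P1" & rel$predicate == "MayTreatedBy", ]
  expect_identical(nrow(mtb), 1L)
})

test_that("relations are deduplicated and respect domain/range", {
  rel <- small_relations()
  key <- paste(rel$patient_id, rel$predicate, rel$subject, rel$object)
  # brute-force pairwise comparison on a sample would be O(n^2); the full
  # key comparison is the same check
  expect_identical(anyDuplicated(key), 0L)
  op <- schema_def()$object_properties
  i <- match(rel$predicate, op$predicate)
  expect_false(anyNA(i))
  expect_identical(rel$subject_class, op$domain[i])
  expect_identical(rel$object_class, op$range[i])
})

test_that("windows are monotone in window_days", {
  b <- small_bundles()
  key <- function(r) paste(r$patient_id, r$predicate, r$subject, r$object)
  r300 <- key(derive_relations(b, window_days = 300))
  r365 <- key(derive_relations(b, window_days = 365))
  r500 <- key(derive_relations(b, window_days = 500))
  expect_true(all(r300 %in% r365))
  expect_true(all(r365 %in% r500))
  r0 <- derive_relations(b, window_days = 0)
  expect_identical(
    nrow(r0[r0$predicate %in% c("TreatedBy", "MayTargetedBy"), ]), 0L)
  hd <- r0[r0$predicate == "HasDisease", ]
  if (nrow(hd)) expect_true(all(hd$date1 == hd$date2))  # same-day only
})

test_that("shifting one prescription changes exactly its relations", {
  coh <- two_patient_cohort()
  base <- derive_relations(build_bundles(coh))
  coh$medications$date[2] <- coh$reports$receipt_date[2] + 400  # P2 drug out
  pert <- derive_relations(build_bundles(coh))
  key <- function(r) paste(r$patient_id, r$predicate, r$subject, r$object)
  gone <- setdiff(key(base), key(pert))
  added <- setdiff(key(pert), key(base))
  expect_identical(added, character(0))
  expect_true(all(grepl("pembrolizumab", gone)))
  expect_true(all(grepl("^P2 ", gone)))
  # MayTreatedBy survives the shift (still after diagnosis)
  expect_true("MayTreatedBy" %in% pert$predicate[pert$patient_id == "P2"])
  expect_setequal(gone, "P2 TreatedBy P2 pembrolizumab")
})

test_that("missing dates are skipped with a warning, not an error", {
  coh <- two_patient_cohort()
  coh$medications$date[1] <- NA
  expect_warning(rel <- derive_relations(build_bundles(coh)),
                 "missing date")
  expect_false("TreatedBy" %in% rel$predicate[rel$patient_id == "P1"])
})
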