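make_bal <- function(values, analytes = colnames(values)) {
  proteomic_matrix(values, "bal", "raw")
}

test_that("LOD censoring applies the substitution rules", {
  v <- matrix(c(1, 3, 30,
                2.5, 5, 12,
                3, 4.5, 11), 3, 3, byrow = TRUE,
              dimnames = list(paste0("S", 1:3), c("A", "B", "C")))
  lod <- lod_spec(c("A", "B", "C"), llod = c(2, 4, 10), ulod = c(20, 40, 25))
  # imputation constant: half the lowest LLOD across the panel
  expect_equal(attr(lod, "imputation_constant"), 1.0)
  out <- censor_bal_lod(make_bal(v), lod)
  expect_equal(out$matrix$values["S1", "A"], 1.0)   # below LLOD -> constant
  expect_equal(out$matrix$values["S1", "C"], 25)    # above ULOD -> ULOD
  expect_equal(out$matrix$values["S2", ], c(A = 2.5, B = 5, C = 12))
  expect_equal(out$flags["S1", "A"], "below_llod")
  expect_equal(out$flags["S1", "C"], "above_ulod")
  expect_equal(out$flags["S2", "B"], "ok")
  # strictly-in-range panel passes through unchanged
  v2 <- matrix(c(5, 6, 15, 4, 7, 12), 2, 3, byrow = TRUE,
               dimnames = list(c("S1", "S2"), c("A", "B", "C")))
  expect_equal(censor_bal_lod(make_bal(v2), lod)$matrix$values, v2)
  # censoring is idempotent on its own output
  again <- censor_bal_lod(out$matrix, lod)
  expect_equal(again$matrix$values, out$matrix$values)
  # analyte missing from the spec
  v3 <- v; colnames(v3) <- c("A", "B", "X")
  expect_error(censor_bal_lod(make_bal(v3), lod), "X")
})

test_that("analytes with >= 50% of values below LLOD are removed", {
  d <- small_cohort()
  cens <- censor_bal_lod(d$bal, d$lod)
  filt <- filter_bal_analytes(cens$matrix, cens$flags)
  expect_equal(n_analytes(filt), 48 - 23)
  expect_length(attr(filt, "removed"), 23)
  # survivor order preserved
  expect_equal(colnames(filt$values),
               setdiff(colnames(d$bal$values), attr(filt, "removed")))
  # filtering is idempotent
  filt2 <- filter_bal_analytes(
    filt, cens$flags[, colnames(filt$values), drop = FALSE]
  )
  expect_equal(filt2$values, filt$values)

  # the boundary case: exactly half below is removed (rule is >=)
  v <- matrix(c(1, 9, 1, 9), 4, 1,
              dimnames = list(paste0("S", 1:4), "A"))
  flags <- matrix(c("below_llod", "ok", "below_llod", "ok"), 4, 1,
                  dimnames = dimnames(v))
  expect_warning(res <- filter_bal_analytes(make_bal(v), flags), "all BAL")
  expect_equal(n_analytes(res), 0)
  # nothing below -> everything kept
  flags_ok <- matrix("ok", 4, 1, dimnames = dimnames(v))
  expect_equal(n_analytes(filter_bal_analytes(make_bal(v), flags_ok)), 1)
})

test_that("total-protein normalization and log2 transform", {
  v <- matrix(c(10, 8, 6, 4), 2, 2,
              dimnames = list(c("S1", "S2"), c("A", "B")))
  totals <- c(S1 = 2, S2 = 1)
  out <- normalize_and_log(make_bal(v), totals)
  expect_equal(out$bal$values["S1", "A"], log2(5))
  expect_equal(out$bal$values["S2", "A"], log2(8))
  expect_equal(out$bal$scale, "log")
  # unit totals: normalization is the identity
  out1 <- normalize_and_log(make_bal(v), c(S1 = 1, S2 = 1))
  expect_equal(out1$bal$values, log2(v))
  # doubling one sample's total shifts its log2 values by exactly -1
  out2 <- normalize_and_log(make_bal(v), c(S1 = 4, S2 = 1))
  expect_equal(out2$bal$values["S1", ], out$bal$values["S1", ] - 1)
  expect_equal(out2$bal$values["S2", ], out$bal$values["S2", ])
  expect_error(normalize_and_log(make_bal(v), c(S1 = 0, S2 = 1)), "S1")
  expect_error(normalize_and_log(make_bal(v), c(S1 = 2)), "S2")
})

test_that("sex-association filter removes planted sex analytes and only those", {
  prep <- small_prepared()
  d <- prep$data
  sex_true <- paste0("blood:",
                     d$truth$analyte[d$truth$role == "sex"])
  expect_setequal(prep$sex_removed, sex_true)   # recall 4/4 at 2 SD
  expect_false(any(prep$sex_removed %in% colnames(prep$merged$values)))

  # no sex effect anywhere: BH keeps removals near zero
  cfg <- cohort_config(n_blood = 200, n_bal = 10, n_planted = 0,
                       n_sex_assoc = 0, n_bal_fail_lod = 2, seed = 31)
  dn <- generate_cohort(cfg)
  lv <- proteomic_matrix(log2(dn$blood$values), "blood", "log")
  res <- sex_association_filter(lv, dn$participants$sex)
  expect_lte(length(res$removed), 2)

  expect_error(sex_association_filter(lv, rep("male", 85)), "both sexes")
  expect_error(sex_association_filter(lv, dn$participants$sex, alpha = 1.2),
               "alpha")
})

test_that("compartment merge keeps features distinct and counts additive", {
  bl <- proteomic_matrix(
    matrix(1:4, 2, 2, dimnames = list(c("S1", "S2"), c("X", "Y"))),
    "blood", "log"
  )
  ba <- proteomic_matrix(
    matrix(5:8, 2, 2, dimnames = list(c("S2", "S1"), c("X", "Z"))),
    "bal", "log"
  )
  m <- merge_compartments(bl, ba)
  expect_equal(n_analytes(m), 4)
  expect_setequal(colnames(m$values),
                  c("blood:X", "blood:Y", "bal:X", "bal:Z"))
  # sample order reconciled by id
  expect_equal(m$values["S1", "bal:X"], 6)
  expect_equal(length(m$values), length(bl$values) + length(ba$values))
  # empty BAL: blood unchanged except tags
  ba0 <- proteomic_matrix(
    matrix(numeric(0), 2, 0, dimnames = list(c("S1", "S2"), NULL)),
    character(0), "log"
  )
  m0 <- merge_compartments(bl, ba0)
  expect_equal(unname(m0$values), unname(bl$values))
  # sample mismatch names the discrepancy
  ba2 <- proteomic_matrix(
    matrix(1:2, 1, 2, dimnames = list("S3", c("X", "Z"))), "bal", "log"
  )
  expect_error(merge_compartments(bl, ba2), "S3")
})
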