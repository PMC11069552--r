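test_that("CSV loading flags empty and NA cells as missing and validates values", {
  sch <- tiny_schema()
  csv <- tempfile(fileext = ".csv")
  writeLines(c("age,gender,work,sick",
               "2,F,home,0",
               ",M,field,1",
               "6,na,office,0"), csv)
  tab <- load_table(csv, sch)
  expect_equal(sum(tab$mask), 2)
  expect_true(tab$mask[2, "age"])
  expect_true(tab$mask[3, "gender"])
  expect_equal(tab$values$age[1], 2)

  writeLines(c("age,gender,work,sick", "2,Unknown,home,0"), csv)
  expect_error(load_table(csv, sch), "not a declared level")
  writeLines(c("age,gender,work,sick", "2,F,home,"), csv)
  expect_error(load_table(csv, sch), "label")
  writeLines(c("age,wrong,work,sick", "2,F,home,0"), csv)
  expect_error(load_table(csv, sch), "schema")
})

test_that("write/load round-trips values and mask", {
  sch <- tiny_schema()
  tab <- random_table(sch, 20, missing_rate = 0.3, seed = 4)
  csv <- tempfile(fileext = ".csv")
  write_table(tab, csv)
  back <- load_table(csv, sch)
  expect_equal(back$mask, tab$mask)
  expect_equal(back$values$age[!tab$mask[, "age"]],
               tab$values$age[!tab$mask[, "age"]])
  expect_equal(back$values$work[!tab$mask[, "work"]],
               tab$values$work[!tab$mask[, "work"]])
})

test_that("encoding scales, one-hots and propagates the mask", {
  tab <- tiny_table()
  enc <- encode_table(tab)
  expect_equal(as.vector(enc$X[, "age"]), c(0, 0.5, 1))      # [2,4,6]
  expect_equal(as.vector(enc$X[, "gender"]), c(0, 1, 0))
  work_cols <- paste0("work=", c("home", "office", "field"))
  expect_equal(rowSums(enc$X[, work_cols]), rep(1, 3))
  expect_equal(enc$y, c(0L, 1L, 0L))

  # masked source cell: placeholder 0, mask expanded over one-hot group
  tab$mask[1, "work"] <- TRUE
  tab$mask[2, "age"] <- TRUE
  enc2 <- encode_table(tab)
  expect_true(all(enc2$mask[1, work_cols]))
  expect_equal(unname(enc2$X[1, work_cols]), c(0, 0, 0))
  expect_true(enc2$mask[2, "age"])
  expect_equal(sum(enc2$mask), 4)  # 3 one-hot cells + 1 numeric
})

test_that("constant numeric columns encode to 0.5 with a warning", {
  sch <- tiny_schema()
  tab <- clinical_table(
    data.frame(age = c(3, 3), gender = c("F", "M"), work = c("home", "home"),
               sick = c("0", "1"), stringsAsFactors = FALSE), sch)
  expect_warning(enc <- encode_table(tab), "zero observed range")
  expect_equal(as.vector(enc$X[, "age"]), c(0.5, 0.5))
})

test_that("a frozen encoding map clips test data into [0,1]", {
  tr <- tiny_table()                     # age range [2, 6]
  enc <- encode_table(tr)
  te <- clinical_table(
    data.frame(age = c(1, 10), gender = c("F", "M"), work = c("home", "home"),
               sick = c("0", "0"), stringsAsFactors = FALSE), tiny_schema())
  enc_te <- encode_table(te, map = enc$map)
  expect_equal(as.vector(enc_te$X[, "age"]), c(0, 1))
})

test_that("decoding inverts encoding: arg-max one-hot, inverse scaling", {
  # one-hot row (0.1, 0.7, 0.2) decodes to the middle level
  tab <- tiny_table()
  enc <- encode_table(tab)
  enc$X[1, paste0("work=", c("home", "office", "field"))] <- c(0.1, 0.7, 0.2)
  dec <- decode_matrix(enc)
  expect_equal(dec$values$work[1], "office")
  # scaled 0.5 on a column with min 2 max 6 -> 4
  enc$X[1, "age"] <- 0.5
  expect_equal(decode_matrix(enc)$values$age[1], 4)
  # width mismatch is a structural error
  enc_bad <- enc; enc_bad$X <- enc$X[, -1]
  expect_error(decode_matrix(enc_bad), "structural")
})

test_that("encode/decode round-trip is exact on observed cells over random schemas", {
  for (seed in 1:8) {
    sch <- random_schema(seed)
    tab <- random_table(sch, 30, missing_rate = 0.2, seed = seed)
    enc <- encode_table(tab)
    # observed encoded entries in [0,1]; mask cardinality conserved
    expect_true(all(enc$X[!enc$mask] >= 0 & enc$X[!enc$mask] <= 1))
    src_missing <- sum(tab$mask[, feature_columns(sch)])
    grp_missing <- sum(vapply(enc$map, function(m) sum(enc$mask[, m$cols[1]]),
                              numeric(1)))
    expect_equal(grp_missing, src_missing)
    dec <- decode_matrix(enc)
    for (nm in feature_columns(sch)) {
      obs <- !tab$mask[, nm]
      expect_equal(dec$values[[nm]][obs], tab$values[[nm]][obs],
                   tolerance = 1e-12)
    }
    expect_equal(dec$values[[sch$label_column]],
                 tab$values[[sch$label_column]])
  }
})

test_that("stratified split is exact, disjoint and deterministic", {
  sch <- tiny_schema()
  n <- 100
  set.seed(1)
  vals <- data.frame(age = rnorm(n), gender = sample(c("F", "M"), n, TRUE),
                     work = sample(c("home", "office", "field"), n, TRUE),
                     sick = rep(c("0", "1"), c(90, 10)),
                     stringsAsFactors = FALSE)
  tab <- clinical_table(vals, sch)
  sp <- stratified_split(tab, 0.2, seed = 7)
  expect_length(sp$test, 20)
  expect_length(sp$train, 80)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_len(n))
  # 90/10 classes at fraction 0.2: 18 majority + 2 minority in test
  y <- vals$sick[sp$test]
  expect_equal(sum(y == "0"), 18)
  expect_equal(sum(y == "1"), 2)
  expect_identical(sp, stratified_split(tab, 0.2, seed = 7))
  expect_false(identical(sp$test, stratified_split(tab, 0.2, seed = 8)$test))
  # a class with < 2 members is refused
  vals2 <- vals; vals2$sick <- c("1", rep("0", n - 1))
  expect_error(stratified_split(clinical_table(vals2, sch), 0.2, 1),
               "fewer than 2")
})
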