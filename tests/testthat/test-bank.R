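test_that("parsing preserves entry order and round-trips field-for-field", {
  b <- fixture_bank("minimal6")
  txt <- write_bank(b)
  b2 <- parse_bank(txt)
  expect_length(b2$entries, 6L)
  expect_identical(vapply(b2$entries, `[[`, "", "type_id"),
                   vapply(b$entries, `[[`, "", "type_id"))
  for (k in seq_along(b$entries)) {
    e1 <- b$entries[[k]]; e2 <- b2$entries[[k]]
    expect_equal(e2$central, e1$central)
    expect_equal(e2$symmetry, e1$symmetry)
    expect_equal(names(e2$rules), names(e1$rules))
    expect_equal(e2$frame, e1$frame)
    expect_equal(e2$params$p_val, e1$params$p_val, tolerance = 1e-4)
    expect_equal(unclass(e2$params$plm_mean), unclass(e1$params$plm_mean),
                 tolerance = 1e-4, ignore_attr = TRUE)
    for (lab in names(e1$rules)) {
      expect_equal(e2$rules[[lab]]$elements, e1$rules[[lab]]$elements)
      expect_equal(e2$rules[[lab]]$planar, e1$rules[[lab]]$planar)
      expect_setequal(e2$rules[[lab]]$bonded_to, e1$rules[[lab]]$bonded_to)
    }
  }
})

test_that("write-parse-write is a byte-stable fixpoint", {
  txt <- write_bank(fixture_bank("minimal6"))
  expect_identical(write_bank(parse_bank(txt)), txt)
  # and with quality flags present
  e <- fixture_bank("minimal6")$entries[[1L]]
  e$params$plm_ssd <- plm_set(e$params$plm_ssd, 3, 3, 0.06)
  txt2 <- write_bank(bank(list(e)))
  expect_true(any(grepl("^# QFLAG plm 3 3", txt2)))
  expect_identical(write_bank(parse_bank(txt2)), txt2)
})

test_that("a symmetry-forbidden population is diagnosed on parse", {
  e <- fixture_bank("minimal6")$entries[[5L]]   # water O, mm2
  txt <- write_bank(bank(list(e)))
  # inject a forbidden sine-type quadrupole (2,-1)
  txt <- append(txt, "PLM 2 -1 0.0300 0.0000 5",
                after = grep("^KPRIME", txt)[1L])
  b <- parse_bank(txt)
  d <- bank_diagnostics(b)
  expect_length(d, 1L)
  expect_match(d, "\\(2,-1\\)")
})

test_that("malformed banks are rejected with informative errors", {
  txt <- write_bank(fixture_bank("minimal6"))
  # duplicate id
  dup <- c(txt, txt[grep("^ENTRY Car", txt):grep("^END", txt)[1L]])
  expect_error(parse_bank(dup), "duplicate type_id")
  # unknown point group
  bad <- sub("^SYMMETRY m$", "SYMMETRY qq7", txt)
  expect_error(parse_bank(bad), "line")
  # missing header
  expect_error(parse_bank(txt[-1L]), "MATTSLIKE")
  # unterminated entry
  expect_error(parse_bank(txt[-length(txt)]), "END")
})

test_that("writer refuses entries that violate their invariants", {
  e <- fixture_bank("minimal6")$entries[[5L]]
  e$params$plm_mean <- plm_set(e$params$plm_mean, 2, -1, 0.05)
  expect_error(write_bank(bank(list(e))), "forbidden")
})

test_that("entry-order audit flags general-before-detailed", {
  expect_length(check_entry_order(fixture_bank("ordering")), 0L)
  warn <- check_entry_order(fixture_bank("ordering_bad"))
  expect_length(warn, 1L)
  expect_match(warn, "Cgen4.*more general.*Cme")
  # element-disjoint entries never shadow each other
  b <- fixture_bank("minimal6")
  expect_length(check_entry_order(bank(b$entries[c(5L, 3L)])), 0L)
})

test_that("generality is antisymmetric on the fixture entries", {
  b <- fixture_bank("ordering")
  A <- b$entries[[1L]]; B <- b$entries[[2L]]
  expect_false(taamkit:::.entry_generalizes(A, B))
  expect_true(taamkit:::.entry_generalizes(B, A))
  expect_true(taamkit:::.entry_generalizes(A, A))
})
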