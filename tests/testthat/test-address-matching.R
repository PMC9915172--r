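# Address normalization and fuzzy UPRN matching.

test_that("normalization uppercases, strips punctuation and expands types", {
  t1 <- normalize_address("12, acacia ave.")
  expect_equal(as.character(t1), c("12", "ACACIA", "AVENUE"))
  # canonical input is unchanged and normalization is idempotent
  t2 <- normalize_address("12 ACACIA AVENUE")
  expect_equal(as.character(t2), c("12", "ACACIA", "AVENUE"))
  renorm <- normalize_address(paste(t1, collapse = " "))
  expect_equal(as.character(renorm), as.character(t1))
  # postcode is detected and canonicalized with one internal space
  t3 <- normalize_address("Flat 2, 9 Birch rd,BD13AB")
  expect_equal(attr(t3, "postcode"), "BD1 3AB")
  expect_true(all(c("BD1", "3AB", "ROAD", "BIRCH") %in% t3))
  # blank input matches nothing
  t4 <- normalize_address("   ")
  expect_length(t4, 0)
})

ref_base <- function() {
  data.frame(
    uprn = c(1001L, 1002L, 1003L),
    address = c("12 ACACIA AVENUE BD1 2AB", "14 ACACIA AVENUE BD1 2AB",
                "3 QUARRY LANE BD2 9ZZ"),
    postcode = c("BD1 2AB", "BD1 2AB", "BD2 9ZZ"),
    stringsAsFactors = FALSE
  )
}

test_that("exact, fuzzy and failed matches are classified deterministically", {
  base <- ref_base()
  self <- match_address("12 ACACIA AVENUE BD1 2AB", base)
  expect_equal(self$uprn, 1001L)
  expect_equal(self$score, 1)
  expect_equal(self$method, "exact")
  dirty <- match_address("12, acacia ave. BD1 2AB", base)
  expect_equal(dirty$uprn, 1001L)  # punctuation/case/abbreviation only
  trans <- match_address("ACACIA 12 AVENUE BD1 2AB", base)
  expect_equal(trans$uprn, 1001L)
  expect_equal(trans$method, "fuzzy")
  none <- match_address("THE OLD LIGHTHOUSE XY99 9XY", base)
  expect_equal(none$method, "none")
  expect_true(is.na(none$uprn))
  # determinism
  expect_identical(match_address("12 acacia ave BD1 2AB", base),
                   match_address("12 acacia ave BD1 2AB", base))
})

test_that("postcode disagreement penalizes otherwise-similar addresses", {
  base <- ref_base()
  wrong_pc <- match_address("12 ACACIA AVENUE BD2 9ZZ", base, threshold = 0.95)
  expect_false(identical(wrong_pc$method, "exact"))
  # with the penalty the wrong-postcode candidate drops below threshold
  expect_equal(wrong_pc$method, "none")
})

test_that("ties break by postcode agreement then smaller UPRN", {
  base <- data.frame(uprn = c(9L, 5L),
                     address = c("1 ELM STREET BD1 1AA", "1 ELM STREET BD2 2BB"),
                     stringsAsFactors = FALSE)
  # equally similar apart from postcode -> postcode decides
  m <- match_address("1 elm st BD2 2BB", base)
  expect_equal(m$uprn, 5L)
  # no postcode in the query: the smaller UPRN wins the exact tie
  base2 <- data.frame(uprn = c(9L, 5L),
                      address = c("1 ELM STREET", "1 ELM STREET"),
                      stringsAsFactors = FALSE)
  m2 <- match_address("1 elm st", base2)
  expect_equal(m2$uprn, 5L)
})

test_that("seeded dirty addresses are recovered from the synthetic city", {
  city <- generate_city(42, city_params(n_addresses = 100, p_transpose = 0))
  base <- data.frame(uprn = city$addresses$uprn,
                     address = city$addresses$address,
                     postcode = city$addresses$postcode,
                     stringsAsFactors = FALSE)
  res <- match_addresses(city$dirty_addresses$raw_address, base)
  hit <- res$uprn == city$dirty_addresses$true_uprn
  expect_equal(mean(hit), 1)  # case/punctuation/abbreviation only
  # with transpositions allowed, recovery stays near-perfect
  city2 <- generate_city(43, city_params(n_addresses = 100, p_transpose = 0.5))
  base2 <- data.frame(uprn = city2$addresses$uprn,
                      address = city2$addresses$address,
                      postcode = city2$addresses$postcode,
                      stringsAsFactors = FALSE)
  res2 <- match_addresses(city2$dirty_addresses$raw_address, base2)
  expect_gte(mean(res2$uprn == city2$dirty_addresses$true_uprn, na.rm = TRUE),
             0.95)
})
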