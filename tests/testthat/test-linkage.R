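test_that("composite keys depend only on their level's identifiers", {
  tabs <- toy_pair_tables(4)
  a <- tabs$claims[1, ]; b <- tabs$claims[1, ]
  b$name_key <- "other"
  # same uid, different name: equal DII keys, different III keys
  expect_equal(composite_key(a, "DII"), composite_key(b, "DII"))
  expect_false(composite_key(a, "III") == composite_key(b, "III"))
  # same quasi-identifiers, different uid: equal III keys
  c2 <- tabs$claims[1, ]; c2$uid <- "Z999"
  expect_equal(composite_key(a, "III"), composite_key(c2, "III"))
  # absent uid is unlinkable at DII level, still linkable at III level
  d <- tabs$claims[1, ]; d$uid <- NA
  expect_true(is.na(composite_key(d, "DII")))
  expect_false(is.na(composite_key(d, "III")))
})

test_that("zero error rates leave the claims table untouched", {
  tabs <- simulated_tables(scenario_config(n_per_stratum = c(TC = 300), seed = 2))
  out <- corrupt_identifiers(tabs$claims, error_model(0, 0, 0, seed = 1))
  expect_identical(out$table, tabs$claims)
  expect_equal(nrow(out$log), 0)
})

test_that("an empty claims table is a no-op", {
  tabs <- simulated_tables(scenario_config(n_per_stratum = c(TC = 0), seed = 1))
  out <- corrupt_identifiers(tabs$claims, error_model(0.5, 0.1, 0.1, seed = 1))
  expect_equal(nrow(out$table), 0)
  expect_equal(nrow(out$log), 0)
})

test_that("total corruption breaks every indirect key", {
  tabs <- simulated_tables(scenario_config(n_per_stratum = c(TC = 200), seed = 8))
  out <- corrupt_identifiers(tabs$claims,
                             error_model(miss_rate = 1, collision_rate = 0,
                                         dii_miss_rate = 0, seed = 3))
  orig <- composite_key(tabs$claims, "III")
  corr <- composite_key(out$table, "III")
  expect_true(all(corr != orig))
  # and none of the corrupted keys hits any original key (no accidental
  # false matches from the miss mechanism)
  expect_false(any(corr %in% orig))
  linked <- link_tables(tabs$registry, out$table, "III", tabs$truth)
  expect_equal(nrow(linked), 0)
})

test_that("the realized miss fraction matches the configured rate", {
  tabs <- simulated_tables(scenario_config(n_per_stratum = c(TC = 100000), seed = 11))
  out <- corrupt_identifiers(tabs$claims,
                             error_model(miss_rate = 0.287, collision_rate = 0,
                                         dii_miss_rate = 0, seed = 21))
  frac <- sum(out$log$action == "miss") / nrow(tabs$claims)
  expect_lt(abs(frac - 0.287), 0.005)
})

test_that("informative missingness shifts the per-record miss rate", {
  tabs <- simulated_tables(one_stratum_scenario(n = 20000, hr = 1,
                                                lambda = 0.2, seed = 14))
  em <- error_model(miss_rate = 0.2, collision_rate = 0, dii_miss_rate = 0,
                    informative_coeffs = c("event_indicator=fracture" = 2),
                    seed = 4)
  out <- corrupt_identifiers(tabs$claims, em)
  hit <- tabs$claims$rid[tabs$claims$event_indicator == "fracture"]
  p_hit <- mean(hit %in% out$log$rid[out$log$action == "miss"])
  p_other <- mean(setdiff(tabs$claims$rid, hit) %in%
                    out$log$rid[out$log$action == "miss"])
  expect_lt(abs(p_other - 0.2), 0.02)
  expect_lt(abs(p_hit - stats::plogis(stats::qlogis(0.2) + 2)), 0.03)
})

test_that("a hand-built toy reproduces the expected linkage accounting", {
  tabs <- toy_pair_tables(10)
  claims <- tabs$claims
  # two corrupted records; record 2's corruption is an engineered
  # collision taking record 1's original identifiers
  claims$name_key[1] <- "zz99"
  claims$name_key[2] <- tabs$claims$name_key[1]
  claims$dob[2] <- tabs$claims$dob[1]
  claims$sex[2] <- tabs$claims$sex[1]
  linked <- link_tables(tabs$registry, claims, "III", tabs$truth)
  expect_equal(nrow(linked), 9)
  expect_equal(sum(linked$provenance == "false-match"), 1)
  acct <- account(linked, tabs$truth)
  expect_equal(acct$n_missed, 2)
  expect_equal(acct$n_false, 1)
  expect_equal(acct$n_linked, 9)
  # the false row joins registry 1 with the claims of record 2
  bad <- linked[linked$provenance == "false-match", ]
  expect_equal(bad$uid, "T001")
  expect_equal(bad$rid, "T002")
})

test_that("linkage equals a brute-force all-pairs oracle on small tables", {
  for (seed in 1:5) {
    cfg <- scenario_config(n_per_stratum = c(TC = 15), seed = seed,
                           name_dictionary_size = 5) # force homonyms
    tabs <- simulated_tables(cfg)
    out <- corrupt_identifiers(tabs$claims,
                               error_model(0.3, 0.1, 0.2, seed = seed + 100))
    for (level in c("DII", "III")) {
      linked <- as.data.frame(link_tables(tabs$registry, out$table, level,
                                          tabs$truth))
      got <- linked[order(linked$uid, linked$rid), c("uid", "rid")]
      rownames(got) <- NULL
      want <- brute_force_link(tabs$registry, out$table, level)
      rownames(want) <- NULL
      expect_equal(got, want, label = sprintf("seed %d level %s", seed, level))
    }
  }
})

test_that("accounting conservation holds on every run", {
  for (seed in 1:4) {
    tabs <- simulated_tables(scenario_config(n_per_stratum = c(TC = 400, CC = 100),
                                             seed = seed))
    out <- corrupt_identifiers(tabs$claims,
                               error_model(0.25, 0.01, 0.05, seed = seed))
    for (level in c("DII", "III")) {
      acct <- account(link_tables(tabs$registry, out$table, level, tabs$truth),
                      tabs$truth)
      expect_equal(acct$n_linked, acct$n_total - acct$n_missed + acct$n_false)
      expect_true(all(c(acct$n_linked, acct$n_false, acct$n_missed) >= 0))
      expect_lte(acct$n_missed, acct$n_total)
    }
  }
})

test_that("raising the miss rate never increases the linked count", {
  tabs <- simulated_tables(scenario_config(n_per_stratum = c(TC = 2000), seed = 17))
  n_linked <- vapply(c(0, 0.1, 0.3, 0.6, 1), function(rate) {
    out <- corrupt_identifiers(tabs$claims,
                               error_model(rate, 0, 0, seed = 55))
    nrow(link_tables(tabs$registry, out$table, "III", tabs$truth))
  }, numeric(1))
  expect_true(all(diff(n_linked) <= 0))
})

test_that("direct-identifier linkage with no uid corruption is error-free", {
  tabs <- simulated_tables(scenario_config(n_per_stratum = c(TC = 800), seed = 19))
  out <- corrupt_identifiers(tabs$claims,
                             error_model(0.4, 0.01, dii_miss_rate = 0, seed = 9))
  linked <- link_tables(tabs$registry, out$table, "DII", tabs$truth)
  expect_equal(nrow(linked), 800)
  expect_true(all(linked$provenance == "true-match"))
})

test_that("an empty claims table links to an empty cohort", {
  tabs <- toy_pair_tables(5)
  empty <- tabs$claims[0, ]
  linked <- link_tables(tabs$registry, empty, "III", tabs$truth)
  expect_equal(nrow(linked), 0)
})

test_that("accounting arithmetic validates its invariants", {
  expect_error(linkage_accounting(10, 0, 12), "exceed")
  expect_error(linkage_accounting(10, -1, 2), ">= 0")
  expect_error(linkage_accounting(10, 1, 2, n_linked = 8), "inconsistent")
  a <- linkage_accounting(10, 1, 2)
  expect_equal(a$n_linked, 9)
  expect_equal(a$linkage_rate_vs_reference, NA_real_)
})

test_that("account rejects linked rows missing from the truth map", {
  tabs <- toy_pair_tables(4)
  linked <- link_tables(tabs$registry, tabs$claims, "III", tabs$truth)
  expect_error(account(linked, tabs$truth[-1, ]), "integrity")
})

test_that("error model inputs are validated", {
  expect_error(error_model(miss_rate = 1.2), "\\[0, 1\\]")
  expect_error(error_model(informative_coeffs = c(2)), "named")
})
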