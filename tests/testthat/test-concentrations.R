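test_that("wide CSV round-trips through read_concentrations", {
  tab <- tiny_table()
  path <- tempfile(fileext = ".csv")
  write_concentrations(tab, path)
  back <- read_concentrations(path)
  expect_equal(unclass(back), unclass(tab))
})

test_that("malformed or invalid CSVs are rejected", {
  empty <- write_tmp_csv(character(0))
  expect_error(read_concentrations(empty), "malformed|empty")
  neg <- write_tmp_csv(c("location,Naph,BaP", "L1,1.0,-1.0"))
  expect_error(read_concentrations(neg), "nonnegative")
  unk <- write_tmp_csv(c("location,Naph,FOO,BAR", "L1,1,2,3"))
  err <- tryCatch(read_concentrations(unk), error = conditionMessage)
  expect_match(err, "FOO")
  expect_match(err, "BAR")
  expect_error(read_concentrations(tempfile()), "not found")
})

test_that("non-detect substitution honours the chosen rule", {
  csv <- write_tmp_csv(c("location,Naph,BaP", "L1,0.05,2", "L2,0.30,3"))
  z <- read_concentrations(csv, detection_limit = 0.1)
  expect_equal(unname(z[, "Naph"]), c(0, 0.3))
  h <- read_concentrations(csv, detection_limit = 0.1, nd_action = "half_dl")
  expect_equal(unname(h[, "Naph"]), c(0.05, 0.3))
  d <- read_concentrations(csv, detection_limit = 0.1, nd_action = "dl")
  expect_equal(unname(d[, "Naph"]), c(0.1, 0.3))
})

test_that("summary statistics match direct computation on a small table", {
  tab <- tiny_table()
  s <- summarize_concentrations(tab)
  expect_s3_class(s, "compound_summary")
  expect_equal(s$mean, c(3, 2, 4, 0))
  expect_equal(s$std, c(2, 0, 4, 0))
  expect_equal(s$min, c(1, 2, 0, 0))
  expect_equal(s$max, c(5, 2, 8, 0))
  expect_equal(total_concentration(s), 9)
  expect_equal(s$pct_of_total, 100 * s$mean / 9)
  expect_equal(sum(s$pct_of_total), 100)
  # all-zero column: mean 0, share 0
  expect_equal(s$pct_of_total[s$abbreviation == "BgP"], 0)
  # population-std option
  sp <- summarize_concentrations(tab, std = "population")
  expect_equal(sp$std, c(2, 0, 4, 0) * sqrt(2 / 3))
})

test_that("summaries are invariant to location order and handle NA cells", {
  tab <- tiny_table()
  perm <- concentration_table(unclass(tab)[c(3, 1, 2), ])
  expect_equal(summarize_concentrations(perm)$mean,
               summarize_concentrations(tab)$mean)
  withNA <- unclass(tab)
  withNA[2, "Naph"] <- NA
  sNA <- summarize_concentrations(concentration_table(withNA))
  expect_equal(sNA$mean[sNA$abbreviation == "Naph"], 3) # mean of 1, 5
})

test_that("single-location tables warn and report zero std", {
  one <- concentration_table(matrix(c(1, 2), nrow = 1,
                                    dimnames = list("L1", c("Naph", "BaP"))))
  expect_warning(s <- summarize_concentrations(one), "single")
  expect_equal(s$std, c(0, 0))
  expect_equal(s$mean, c(1, 2))
})

test_that("ring and molecular-weight profiles partition the total", {
  ref <- reference_summary()
  ring <- ring_distribution(ref)
  mw <- mw_distribution(ref)
  expect_equal(sum(ring), 100, tolerance = 1e-9)
  expect_equal(sum(mw), 100, tolerance = 1e-9)
  # class aggregation identities
  expect_equal(unname(mw["MMW"]), unname(ring["4"]))
  expect_equal(unname(mw["LMW"]), unname(ring["2"] + ring["3"]))
  expect_equal(unname(mw["HMW"]), unname(ring["5"] + ring["6"]))
  # the published profile is HMW-dominant with the 5-ring class largest
  expect_equal(names(which.max(ring)), "5")
  expect_equal(names(which.max(mw)), "HMW")
  # 2-ring share is Naph alone
  expect_equal(unname(ring["2"]),
               100 * ref$mean[ref$abbreviation == "Naph"] / sum(ref$mean))
})

test_that("profile partition holds on random tables", {
  set.seed(11)
  for (i in 1:5) {
    tab <- generate_site(default_profile(), pah_registry())
    s <- suppressWarnings(summarize_concentrations(tab))
    expect_equal(sum(ring_distribution(s)), 100, tolerance = 1e-9)
    expect_equal(sum(mw_distribution(s)), 100, tolerance = 1e-9)
    expect_equal(s$pct_of_total, 100 * s$mean / sum(s$mean))
  }
})

test_that("degenerate composition cases behave", {
  reg <- pah_registry()
  single <- concentration_table(matrix(c(2, 3), ncol = 1,
                                       dimnames = list(NULL, "Phe")), reg)
  s <- summarize_concentrations(single)
  expect_equal(unname(ring_distribution(s, reg)), 100)
  expect_equal(unname(mw_distribution(s, reg)), 100)
  expect_equal(names(mw_distribution(s, reg)), "LMW")
})

test_that("carcinogenic aggregate sums the seven flagged compounds", {
  ref <- reference_summary()
  cf <- carcinogenic_fraction(ref)
  carc <- c("BaA", "CHR", "BbF", "BkF", "BaP", "IcP", "DhA")
  expect_equal(cf$sum, sum(ref$mean[ref$abbreviation %in% carc]))
  expect_equal(cf$pct, 100 * cf$sum / sum(ref$mean))
  # zeroing the flagged compounds gives (0, 0)
  zeroed <- ref
  zeroed$mean[zeroed$abbreviation %in% carc] <- 0
  cf0 <- carcinogenic_fraction(zeroed)
  expect_equal(cf0$sum, 0)
  expect_equal(cf0$pct, 0)
})
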