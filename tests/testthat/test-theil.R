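test_that("theil_index matches hand-computed and oracle values", {
  # 0.5*ln(5/9) + 0.5*ln(5), evaluated by hand before the implementation
  sh <- data.frame(p = c(0.5, 0.5), y = c(0.9, 0.1))
  expect_equal(theil_index(sh), 0.5 * log(5 / 9) + 0.5 * log(5))
  expect_equal(round(theil_index(sh), 4), 0.5108)
  expect_equal(theil_index(sh), oracle_theil(sh$p, sh$y))

  # proportional allocation is exactly equitable
  prop <- data.frame(p = c(0.2, 0.3, 0.5), y = c(0.2, 0.3, 0.5))
  expect_equal(theil_index(prop), 0)

  # p_i = 0 terms contribute nothing (continuous limit)
  withp0 <- data.frame(p = c(0, 0.4, 0.6), y = c(0.5, 0.2, 0.3))
  expect_equal(theil_index(withp0),
               oracle_theil(c(0.4, 0.6), c(0.2, 0.3)))
})

test_that("zero resource share is an error unless the epsilon policy is enabled", {
  sh <- data.frame(unit = c("a", "b"), p = c(0.5, 0.5), y = c(1, 0))
  expect_error(theil_index(sh), "b", class = "theilequity_domain_error")

  adj <- theil_index(sh, epsilon = 1e-12)
  expect_true(is.finite(adj))
  expect_true(attr(adj, "adjusted"))
  # untouched inputs are not flagged
  clean <- theil_index(data.frame(p = c(0.5, 0.5), y = c(0.4, 0.6)),
                       epsilon = 1e-12)
  expect_null(attr(clean, "adjusted"))
})

test_that("within-group Theil renormalizes and is denominator-invariant", {
  expect_equal(theil_within(data.frame(unit = "solo", p = 1, y = 1), "solo"), 0)

  sh <- random_shares(10)
  two <- sh[1:2, ]
  two$p <- c(0.09, 0.09)  # renormalizes to (0.5, 0.5)
  two$y <- c(0.27, 0.03)  # renormalizes to (0.9, 0.1)
  sh[1:2, ] <- two
  expect_equal(theil_within(sh, c("u01", "u02")),
               0.5 * log(5 / 9) + 0.5 * log(5))

  # rescaling the parent shares (e.g. a larger reference denominator)
  # leaves every within-group value unchanged
  scaled <- sh
  scaled$p <- scaled$p * 0.97
  expect_equal(theil_within(scaled, c("u01", "u02")),
               theil_within(sh, c("u01", "u02")), tolerance = 1e-12)

  expect_error(theil_within(sh, character(0)),
               class = "theilequity_validation_error")
  expect_error(theil_within(sh, "nope"),
               class = "theilequity_validation_error")
})

test_that("decomposition is exactly additive and matches the brute-force total", {
  withr::with_seed(2024, {
    for (rep in 1:200) {
      n <- sample(3:40, 1)
      k <- sample(1:min(6, n), 1)
      sh <- random_shares(n)
      part <- random_partition(sh$unit, k)
      dec <- theil_decompose(sh, part)
      expect_lt(abs(dec$total - (dec$within + dec$between)), 1e-12)
      expect_gte(dec$total, 0)
      expect_gte(dec$within, 0)
      expect_gte(dec$between, 0)
      expect_equal(dec$total, oracle_theil(sh$p, sh$y), tolerance = 1e-12)
      expect_equal(sum(dec$groups$p_g), 1, tolerance = 1e-9)
      expect_equal(sum(dec$groups$y_g), 1, tolerance = 1e-9)
      if (dec$total > 0) {
        expect_equal(dec$contribution_within + dec$contribution_between, 1,
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("degenerate partitions collapse to one side of the decomposition", {
  sh <- random_shares(8)
  # one group holding everything: all inequality is within
  all_one <- tibble::tibble(unit = sh$unit, region = "all")
  dec1 <- theil_decompose(sh, all_one)
  expect_equal(dec1$between, 0)
  expect_equal(dec1$within, dec1$total)

  # every unit its own group: all inequality is between
  singletons <- tibble::tibble(unit = sh$unit, region = sh$unit)
  dec2 <- theil_decompose(sh, singletons)
  expect_equal(dec2$within, 0)
  expect_equal(dec2$between, dec2$total)
})

test_that("unit order never affects results beyond reporting order", {
  withr::with_seed(7, {
    sh <- random_shares(15)
    part <- random_partition(sh$unit, 3)
    dec <- theil_decompose(sh, part)
    perm <- sample.int(nrow(sh))
    dec_p <- theil_decompose(sh[perm, ], part)
    expect_equal(dec_p$total, dec$total, tolerance = 1e-14)
    expect_equal(dec_p$within, dec$within, tolerance = 1e-14)
    expect_equal(dec_p$between, dec$between, tolerance = 1e-14)
    g <- dec$groups[order(dec$groups$group), ]
    gp <- dec_p$groups[order(dec_p$groups$group), ]
    expect_equal(gp$t_g, g$t_g, tolerance = 1e-14)
  })
})

test_that("merging units with equal per-capita levels leaves the index unchanged", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      sh <- random_shares(12)
      # force units 1 and 2 onto a common per-capita level
      lvl <- sh$y[1] / sh$p[1]
      sh$y[2] <- lvl * sh$p[2]
      sh$y <- sh$y / sum(sh$y)
      merged <- tibble::tibble(
        unit = c("merged", sh$unit[-(1:2)]),
        p = c(sh$p[1] + sh$p[2], sh$p[-(1:2)]),
        y = c(sh$y[1] + sh$y[2], sh$y[-(1:2)]))
      expect_equal(theil_index(merged), theil_index(sh), tolerance = 1e-12)
    }
  })
})

test_that("the index is zero iff allocation is proportional", {
  withr::with_seed(13, {
    for (rep in 1:20) {
      sh <- random_shares(10)
      prop <- sh
      prop$y <- prop$p
      expect_lt(theil_index(prop), 1e-12)
      if (max(abs(sh$y - sh$p)) > 1e-6) expect_gt(theil_index(sh), 0)
    }
  })
})

test_that("tidy and glance expose the decomposition in the documented schema", {
  sh <- resource_shares(china_panel_2013(), "personnel")
  dec <- theil_decompose(sh, china_partition())

  td <- tidy(dec)
  expect_equal(names(td),
               c("group", "p_g", "y_g", "t_g", "weighted_term", "contribution"))
  expect_equal(td$group,
               c("east", "central", "west", "__within__", "__between__", "__total__"))
  expect_equal(td$weighted_term[td$group == "__total__"], dec$total)
  expect_equal(sum(td$contribution[1:3]) +
                 td$contribution[td$group == "__between__"], 1,
               tolerance = 1e-9)

  gl <- glance(dec)
  expect_equal(gl$n_units, 31)
  expect_equal(gl$n_groups, 3)
  expect_equal(gl$total, gl$within + gl$between, tolerance = 1e-12)

  expect_s3_class(autoplot(dec), "ggplot")
})

test_that("contribution rates are undefined sentinels when total is zero", {
  sh <- tibble::tibble(unit = c("a", "b", "c", "d"),
                       p = rep(0.25, 4), y = rep(0.25, 4))
  part <- tibble::tibble(unit = sh$unit, region = c("g1", "g1", "g2", "g2"))
  dec <- theil_decompose(sh, part)
  expect_equal(dec$total, 0)
  expect_true(is.na(dec$contribution_within))
  expect_true(is.na(dec$contribution_between))
  expect_true(all(is.na(dec$groups$contribution)))
})
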