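toy_table <- function() {
  sites <- sprintf("s%02d", 1:20)
  site_annotation(
    universe = sites,
    ppbd = tibble::tibble(site_id = sites[1:5], family = "14-3-3"),
    pk = tibble::tibble(site_id = sites[1:8], family = "AGC"))
}

test_that("doubly regulated sites are exact set intersections", {
  sites <- sprintf("s%02d", 1:20)
  tab <- site_annotation(
    universe = sites,
    ppbd = tibble::tibble(site_id = c(sites[1:4], sites[10:12]),
                          family = rep(c("A", "B"), c(4, 3))),
    pk = tibble::tibble(site_id = c(sites[3:6], sites[15:16]),
                        family = rep(c("K1", "K2"), c(4, 2))))
  expect_setequal(identify_drps(tab, "A", "K1"), sites[3:4])
  expect_length(identify_drps(tab, "B", "K2"), 0)
  # brute-force membership oracle
  oracle <- sites[sites %in% c(sites[1:4]) & sites %in% sites[3:6]]
  expect_setequal(identify_drps(tab, "A", "K1"), oracle)
  expect_error(identify_drps(tab, "Z", "K1"), "unknown")
})

test_that("a domain covering the whole universe gives a null p of one", {
  sites <- sprintf("s%02d", 1:15)
  tab <- site_annotation(
    universe = sites,
    ppbd = tibble::tibble(site_id = sites, family = "ALL"),
    pk = tibble::tibble(site_id = sites[1:6], family = "K"))
  res <- permutation_test(tab, "ALL", "K", rounds = 500, seed = 1)
  expect_equal(res$p_value, 1, tolerance = 1e-3)
  expect_equal(res$null_sd, 0)
})

test_that("the permutation null matches the hypergeometric oracle", {
  res <- permutation_test(toy_table(), "14-3-3", "AGC", rounds = 10000,
                          seed = 11)
  expect_identical(res$x, 5L)
  exact <- 1 - phyper(4, 5, 15, 8)  # = C(15,3)/C(20,8), about 0.00361
  mc_se <- sqrt(exact * (1 - exact) / res$rounds)
  expect_lt(abs(res$p_value - exact), 3 * mc_se + 1 / res$rounds)
  # null moments follow Hypergeometric(T = 20, m = 5, n = 8)
  expect_lt(abs(res$null_mean - 5 * 8 / 20),
            3 * res$null_sd / sqrt(res$rounds))
  expect_identical(res$rounds, 10000L)
})

test_that("empirical p-values are smoothed away from zero", {
  res <- permutation_test(toy_table(), "14-3-3", "AGC", rounds = 200,
                          seed = 2)
  expect_gt(res$p_value, 0)
  expect_gte(res$p_value, 1 / 201)
})

test_that("gaussian and empirical modes agree on a near-normal null", {
  sites <- sprintf("s%03d", 1:200)
  tab <- site_annotation(
    universe = sites,
    ppbd = tibble::tibble(site_id = sites[1:80], family = "A"),
    pk = tibble::tibble(site_id = sites[c(1:45, 100:150)], family = "K"))
  emp <- permutation_test(tab, "A", "K", rounds = 4000, seed = 3)
  gau <- permutation_test(tab, "A", "K", rounds = 4000, seed = 3,
                          mode = "gaussian")
  expect_lt(max(emp$p_value, gau$p_value) /
              min(emp$p_value, gau$p_value), 2)
})

test_that("a skewed null triggers a warning in gaussian mode", {
  sites <- sprintf("s%02d", 1:30)
  tab <- site_annotation(
    universe = sites,
    ppbd = tibble::tibble(site_id = sites[1:2], family = "A"),
    pk = tibble::tibble(site_id = sites[1:2], family = "K"))
  expect_warning(
    permutation_test(tab, "A", "K", rounds = 2000, seed = 4,
                     mode = "gaussian"),
    "non-normal")
})

test_that("p-values are invariant to site relabeling", {
  sites <- sprintf("s%02d", 1:20)
  relab <- setNames(sprintf("x%02d", 20:1), sites)
  tab1 <- toy_table()
  tab2 <- site_annotation(
    universe = unname(relab[sites]),
    ppbd = tibble::tibble(site_id = unname(relab[sites[1:5]]),
                          family = "14-3-3"),
    pk = tibble::tibble(site_id = unname(relab[sites[1:8]]),
                        family = "AGC"))
  r1 <- permutation_test(tab1, "14-3-3", "AGC", rounds = 2000, seed = 5)
  r2 <- permutation_test(tab2, "14-3-3", "AGC", rounds = 2000, seed = 5)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("the family grid applies multiplicity control", {
  sites <- sprintf("s%02d", 1:40)
  tab <- site_annotation(
    universe = sites,
    ppbd = tibble::tibble(site_id = c(sites[1:10], sites[5:20]),
                          family = rep(c("A", "B"), c(10, 16))),
    pk = tibble::tibble(site_id = c(sites[1:12], sites[30:35]),
                        family = rep(c("K1", "K2"), c(12, 6))))
  res <- associate_families(tab, rounds = 500, seed = 6)
  expect_identical(nrow(res), 4L)
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_true(all(res$p_adjusted <= 1))
})

test_that("term enrichment reproduces the exact tail sum", {
  bg <- sprintf("g%03d", 1:100)
  fg <- bg[1:10]
  ann <- tibble::tibble(term = "T1", id = bg[c(1:5, 50:54)])
  res <- hypergeometric_enrichment(fg, bg, ann, alpha = 1)
  oracle <- sum(vapply(5:10, function(k) {
    choose(10, k) * choose(90, 10 - k) / choose(100, 10)
  }, numeric(1)))
  expect_equal(res$p_value, oracle, tolerance = 1e-12)
  expect_identical(res$overlap, 5L)
  expect_equal(res$fold_enrichment, (5 / 10) / (10 / 100))
})

test_that("matched foreground and background fractions show no enrichment", {
  bg <- sprintf("g%03d", 1:100)
  fg <- bg[1:10]
  # term covers 20% of the background and exactly 20% of the foreground
  ann <- tibble::tibble(term = "T1", id = bg[c(1, 2, 11:28)])
  res <- hypergeometric_enrichment(fg, bg, ann, alpha = 1)
  expect_equal(res$fold_enrichment, 1)
  expect_gte(res$p_value, 0.5)
  # and it is filtered out at a conventional alpha
  expect_identical(nrow(hypergeometric_enrichment(fg, bg, ann,
                                                  alpha = 0.05)), 0L)
})

test_that("enrichment validates its sets", {
  bg <- sprintf("g%03d", 1:50)
  ann <- tibble::tibble(term = "T1", id = bg[1:5])
  expect_error(hypergeometric_enrichment(character(0), bg, ann), "empty")
  expect_error(hypergeometric_enrichment(c(bg[1], "zzz"), bg, ann),
               "subset")
  expect_error(
    site_annotation(bg, tibble::tibble(site_id = "zzz", family = "A"),
                    tibble::tibble(site_id = bg[1], family = "K")),
    "universe")
})
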