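test_that("contingency tables count the documented layout", {
  tbl <- score_table(cluster_id = c("A", "A", "B", "B"),
                     delta_g = c(-7, -7, -3, -3))
  tbl$is_virtual_hit <- tbl$delta_g <= -6
  ct <- build_contingency(tbl, "A")
  expect_equal(ct, list(a = 2L, b = 0L, c = 0L, d = 2L, n = 4L))
  expect_error(build_contingency(tbl, ""), "non-empty")
  expect_error(build_contingency(tbl, "Z"), "not present")
  # conservation: a + c equals the cluster size
  set.seed(5)
  big <- score_table(sample(LETTERS[1:4], 60, TRUE), rnorm(60, -5, 2))
  big$is_virtual_hit <- big$delta_g <= -6
  for (cl in unique(big$cluster_id)) {
    ct <- build_contingency(big, cl)
    expect_equal(ct$a + ct$c, sum(big$cluster_id == cl))
    expect_equal(ct$n, nrow(big))
  }
})

test_that("the point probability reproduces direct factorial evaluation", {
  # (1,1,1,1): 2!2!2!2! / 1!1!1!1!4! = 16/24
  expect_equal(fisher_point_probability(1, 1, 1, 1), 16 / 24,
               tolerance = 1e-12)
  expect_equal(fisher_point_probability(3, 1, 1, 3),
               (factorial(4)^4) / (factorial(3)^2 * factorial(8)),
               tolerance = 1e-12)
})

test_that("tail p-values agree with enumeration and with fisher.test", {
  cases <- list(c(3, 1, 1, 3), c(5, 0, 2, 8), c(2, 6, 9, 1), c(0, 4, 4, 0),
                c(10, 2, 3, 11), c(1, 1, 1, 1))
  for (tb in cases) {
    for (alt in c("greater", "two_sided")) {
      mine <- fisher_exact(tb[1], tb[2], tb[3], tb[4], alternative = alt)
      oracle <- fisher_oracle(tb[1], tb[2], tb[3], tb[4], alternative = alt)
      expect_equal(mine, oracle, tolerance = 1e-12)
      ralt <- if (alt == "greater") "greater" else "two.sided"
      ref <- stats::fisher.test(matrix(tb, 2, byrow = TRUE),
                                alternative = ralt)$p.value
      expect_equal(mine, ref, tolerance = 1e-9)
    }
  }
})

test_that("degenerate margins give p = 1 and a = 0 behaves at the boundary", {
  expect_equal(fisher_exact(0, 0, 3, 5), 1)
  expect_equal(fisher_exact(0, 5, 3, 0), 1)
  p <- fisher_exact(0, 4, 4, 8, alternative = "greater")
  expect_gte(p, fisher_point_probability(0, 4, 4, 8))
  # when the observed table is the least extreme, the greater tail is 1
  expect_equal(fisher_exact(0, 4, 4, 4, alternative = "greater"), 1)
})

test_that("no hits means every cluster has p = 1 and nothing is enriched", {
  tbl <- score_table(rep(c("A", "B", "C"), each = 10), rep(-3, 30))
  enr <- enrich_clusters(tbl, dg_cutoff = -6)
  expect_true(all(enr$p_value == 1))
  expect_false(any(enr$enriched))
})

test_that("a planted all-hit cluster is flagged with the smallest p", {
  dg <- c(rep(-7, 10), rep(-3, 90))
  cl <- c(rep("HOT", 10), rep(sprintf("bg%02d", 1:9), each = 10))
  tbl <- score_table(cl, dg)
  enr <- enrich_clusters(tbl, dg_cutoff = -6)
  expect_equal(enr$cluster_id[1], "HOT")
  expect_true(enr$enriched[1])
  expect_equal(sum(enr$enriched), 1)
})

test_that("enriched count is monotone as alpha decreases", {
  set.seed(13)
  tbl <- score_table(sample(sprintf("c%02d", 1:8), 400, TRUE),
                     rnorm(400, -5.5, 1))
  alphas <- c(0.2, 0.1, 0.05, 0.01, 0.001)
  counts <- vapply(alphas, function(a) {
    sum(enrich_clusters(tbl, dg_cutoff = -6, alpha = a)$enriched)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the NO_SCAFFOLD pool is excluded unless requested", {
  tbl <- score_table(c(rep("A", 5), rep("NO_SCAFFOLD", 5)),
                     rep(c(-7, -3), 5))
  enr <- enrich_clusters(tbl)
  expect_false("NO_SCAFFOLD" %in% enr$cluster_id)
  enr2 <- enrich_clusters(tbl, include_no_scaffold = TRUE)
  expect_true("NO_SCAFFOLD" %in% enr2$cluster_id)
})

test_that("scaffold selection takes the best score with id tie-breaks", {
  tbl <- score_table(c("A", "A", "B", "B", "B"),
                     c(-7.0, -6.5, -7.0, -7.0, -5))
  tbl$record_id <- c("a2", "a1", "b2", "b1", "b3")
  enr <- tibble::tibble(cluster_id = c("A", "B"), enriched = c(TRUE, TRUE))
  sel <- select_scaffolds(enr, tbl)
  expect_equal(sel, c("a2", "b1"))  # argmin; tie in B -> lowest id
  # per_cluster larger than the cluster clamps without error
  enr1 <- tibble::tibble(cluster_id = "A", enriched = TRUE)
  expect_equal(length(select_scaffolds(enr1, tbl[1, ], per_cluster = 2)), 1)
})

test_that("the sweep stops at the first cutoff inside the target band", {
  # 250 tight clusters whose full-hit threshold steps down in two tiers:
  # 100 clusters at -6.0 and 150 at -6.1, over a cold background
  hot <- score_table(
    rep(sprintf("h%03d", 1:250), each = 10),
    rep(c(rep(-6.0, 100), rep(-6.15, 150)), each = 10))
  bg <- score_table(rep(sprintf("bg%02d", 1:10), each = 250), rep(0, 2500))
  bg$record_id <- paste0("x", bg$record_id)
  tbl <- dplyr::bind_rows(hot, bg)
  sw <- sweep_cutoff(tbl, start = -6, step = -0.1, target = c(100, 200))
  expect_equal(sw$chosen_cutoff, -6.1, tolerance = 1e-9)
  expect_true(sw$in_target)
  expect_equal(nrow(tidy(sw)), 2)
  expect_equal(tidy(sw)$n_scaffolds, c(250, 150))
  # hit counts are nested (non-increasing) along the trace
  expect_true(all(diff(tidy(sw)$n_hits) <= 0))
})

test_that("an open-ended target accepts the starting cutoff", {
  tbl <- score_table(rep(c("A", "B"), each = 10),
                     rep(c(-7, -3), each = 10))
  sw <- sweep_cutoff(tbl, target = c(0, Inf))
  expect_equal(sw$chosen_cutoff, -6)
})

test_that("a sweep with no scoreable record is flagged and empty", {
  tbl <- score_table(rep("A", 5), rep(0, 5))
  sw <- sweep_cutoff(tbl)
  expect_true(sw$flagged)
  expect_equal(length(sw$scaffolds), 0)
})
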