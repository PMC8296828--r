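make_cohort <- function(deltas, ids = sprintf("A%02d", seq_along(deltas))) {
  tibble::tibble(animal_id = rep(ids, each = 2),
                 day = rep(c(0, 14), length(ids)),
                 body_weight = as.vector(rbind(20, 20 + deltas)))
}

test_that("cohort assignment takes the k largest and smallest gainers", {
  deltas <- c(7.0, 6.5, 6.0, 5.9, 5.8, 3.0, 1.5, 1.4, 1.3, 1.2, 1.0, 0.9)
  cohort <- make_cohort(deltas)
  ass <- assign_cohorts(cohort, k = 5)
  expect_setequal(prone_ids(ass), sprintf("A%02d", 1:5))
  expect_setequal(resistant_ids(ass), sprintf("A%02d", 8:12))
  expect_equal(sort(ass$delta_weight, decreasing = TRUE), sort(deltas, TRUE))
  expect_true(min(ass$delta_weight[ass$cohort == "prone"]) >=
                max(ass$delta_weight[ass$cohort != "prone"]))
})

test_that("boundary ties break by ascending animal id and rows may be shuffled", {
  deltas <- c(5, 4, 3, 3, 3, 2, 1)
  cohort <- make_cohort(deltas) # tie at the k = 3 boundary: A03, A04, A05
  ass <- assign_cohorts(cohort, k = 3)
  # within the tied block the smaller animal id wins on both sides
  expect_setequal(prone_ids(ass), c("A01", "A02", "A03"))
  expect_setequal(resistant_ids(ass), c("A04", "A06", "A07"))
  set.seed(3)
  for (rep in 1:5) {
    shuffled <- cohort[sample(nrow(cohort)), ]
    ass2 <- assign_cohorts(shuffled, k = 3)
    expect_equal(prone_ids(ass2), prone_ids(ass))
    expect_equal(resistant_ids(ass2), resistant_ids(ass))
  }
})

test_that("cohort assignment validates sizes and endpoint days", {
  expect_error(assign_cohorts(make_cohort(c(1, 2, 3)), k = 2), "at least 4")
  broken <- make_cohort(c(1, 2, 3, 4, 5))
  broken <- broken[!(broken$animal_id == "A02" & broken$day == 14), ]
  expect_error(assign_cohorts(broken, k = 2), "A02")
})

test_that("group summaries reproduce the printed intake difference", {
  d <- tibble::tibble(group = rep(c("prone", "resistant"), each = 5),
                      intake = c(3.2, 3.0, 3.1, 3.15, 3.05,
                                 2.55, 2.65, 2.6, 2.7, 2.5))
  gs <- group_summary(d, "intake", "group", reference = "resistant")
  expect_equal(gs$groups$mean, c(3.1, 2.6), tolerance = 1e-12)
  expect_equal(gs$abs_diff, 0.5, tolerance = 1e-12)
  expect_equal(gs$pct_diff, 100 * 0.5 / 2.6, tolerance = 1e-12)
  expect_equal(gs$pct_diff_rounded, 19)

  same <- tibble::tibble(g = rep(c("a", "b"), each = 3), v = rep(2, 6))
  expect_equal(group_summary(same, "v", "g", reference = "b")$pct_diff, 0)
  double <- tibble::tibble(g = rep(c("a", "b"), each = 3),
                           v = rep(c(2, 1), each = 3))
  expect_equal(group_summary(double, "v", "g", reference = "b")$pct_diff, 100)
})

test_that("delta-delta-Ct follows its closed form and normalizes the reference", {
  rec <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 3),
    group = rep(c("prone", "resistant"), each = 3),
    gene = rep(c("Tgt", "Pgk1", "Hprt"), 2),
    ct = c(20, 18, 20,   # prone: dCt = 20 - 19 = 1
           21, 19, 19))  # resistant: dCt = 21 - 19 = 2
  dd <- ddct_relative_expression(rec, reference_group = "resistant")
  s <- dd$samples
  expect_equal(s$dct[s$group == "prone"], 1)
  expect_equal(s$ddct[s$group == "prone"], -1)
  expect_equal(s$rq[s$group == "prone"], 2)
  expect_equal(s$rq[s$group == "resistant"], 1)

  # global shifts of all Ct values leave every RQ unchanged
  dd_shift <- ddct_relative_expression(
    dplyr::mutate(rec, ct = ct + 3.7), reference_group = "resistant")
  expect_equal(dd_shift$samples$rq, s$rq)

  # target Ct equal to the housekeeping mean everywhere: all RQ = 1
  flat <- dplyr::mutate(rec, ct = rep(c(19, 18, 20), 2))
  expect_equal(ddct_relative_expression(flat, reference_group = "resistant")$samples$rq,
               rep(1, 2))
})

test_that("ddCt errors on missing housekeeping measurements", {
  rec <- tibble::tibble(sample_id = c("s1", "s1", "s2", "s2", "s2"),
                        group = c("p", "p", "r", "r", "r"),
                        gene = c("Tgt", "Pgk1", "Tgt", "Pgk1", "Hprt"),
                        ct = c(20, 19, 21, 19, 19))
  expect_error(ddct_relative_expression(rec, reference_group = "r"), "s1")
})

test_that("Welch screen matches the closed-form statistic", {
  d <- tibble::tibble(gene = "g1",
                      group = rep(c("a", "b"), each = 3),
                      value = c(1, 2, 3, 4, 5, 6))
  res <- welch_bky_screen(d, fdr = 0.1)
  hand <- welch_hand(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, hand$t, tolerance = 1e-9)
  expect_equal(round(res$t, 3), -3.674)
  expect_equal(res$df, 4.0, tolerance = 1e-9)
  expect_equal(res$p, hand$p, tolerance = 1e-9)
  expect_equal(round(res$p, 4), 0.0213)

  same <- tibble::tibble(gene = "g1", group = rep(c("a", "b"), each = 3),
                         value = rep(1, 6))
  rs <- welch_bky_screen(same)
  expect_equal(rs$t, 0)
  expect_equal(rs$p, 1)
  expect_false(rs$reject)
  diffc <- tibble::tibble(gene = "g1", group = rep(c("a", "b"), each = 3),
                          value = rep(c(1, 2), each = 3))
  expect_error(welch_bky_screen(diffc), "zero variance")
})

test_that("uniformly extreme p-values are all rejected by the two-stage screen", {
  expect_true(all(bky_reject(rep(1e-6, 20), fdr = 0.10)))
})

test_that("two-stage BKY matches an independent transcription on random vectors", {
  set.seed(17)
  for (rep in 1:60) {
    p <- random_p_vector(sample(2:120, 1))
    for (fdr in c(0.05, 0.10)) {
      expect_equal(bky_reject(p, fdr), bky_literal(p, fdr))
    }
  }
})

test_that("BKY on a classic 15-test example is adaptive beyond plain BH", {
  # multiple-endpoint p-values widely used to illustrate step-up procedures
  p <- c(0.0001, 0.0004, 0.0019, 0.0095, 0.0201, 0.0278, 0.0298, 0.0344,
         0.0459, 0.3240, 0.4262, 0.5719, 0.6528, 0.7590, 1.000)
  expect_equal(sum(bh_fdr(p) <= 0.05), 4)
  expect_equal(sum(bky_reject(p, fdr = 0.05)), 8)

  # faithfulness of the published procedure: when stage one rejects nothing
  # the two-stage procedure stops, even where plain BH would reject — the
  # adaptive procedure is not a uniform superset of BH
  expect_equal(sum(bky_reject(c(0.024, 1), fdr = 0.05)), 0)
  expect_equal(sum(bh_fdr(c(0.024, 1)) <= 0.05), 1)
})

test_that("BKY is a superset of BH whenever stage one rejects enough", {
  # the adaptive stage-two level exceeds the nominal level exactly when
  # r1 >= m * q / (1 + q); on such vectors no BH rejection can be lost
  set.seed(19)
  checked <- 0
  for (rep in 1:200) {
    p <- random_p_vector(sample(5:100, 1), signal_fraction = 0.4)
    fdr <- 0.10
    m <- length(p)
    stage1 <- sum(bh_fdr(p) <= fdr / (1 + fdr))
    if (stage1 >= m * fdr / (1 + fdr)) {
      bh <- bh_fdr(p) <= fdr
      expect_true(all(bky_reject(p, fdr)[bh]))
      checked <- checked + 1
    }
  }
  expect_gt(checked, 20)
})

test_that("a two-group screen separates planted signal from nulls", {
  set.seed(23)
  genes <- paste0("g", 1:30)
  d <- tidyr::expand_grid(gene = genes, group = c("a", "b"),
                          rep = 1:5) |>
    dplyr::mutate(value = rnorm(dplyr::n()) +
                    ifelse(gene %in% genes[1:5] & group == "a", 3, 0))
  res <- welch_bky_screen(d, fdr = 0.10)
  expect_true(all(res$reject[res$gene %in% genes[1:5]]))
  expect_lt(mean(res$reject[!res$gene %in% genes[1:5]]), 0.2)
})
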