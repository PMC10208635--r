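events_df <- function(animal, stage, period, height, phase = "regular") {
  data.frame(animal_id = animal, stage = stage, period = period,
             height = height, phase = phase, stringsAsFactors = FALSE)
}

test_that("height normalization anchors the proestrus-light mean at exactly 1", {
  ev <- events_df("a1",
                  rep(c("proestrus", "metestrus"), each = 4),
                  "light",
                  c(2, 2, 2, 2, 3, 3, 3, 3))
  nh <- normalized_heights(ev, ev$stage == "proestrus" & ev$period == "light")
  gm <- nh$group_means
  expect_equal(gm$mean_norm_height[gm$stage == "proestrus"], 1)
  expect_equal(gm$mean_norm_height[gm$stage == "metestrus"], 1.5)
  # all equal heights: every group is exactly 1
  ev2 <- events_df("a1", rep(c("proestrus", "estrus"), 3), "light", rep(2, 6))
  nh2 <- normalized_heights(ev2, ev2$stage == "proestrus")
  expect_true(all(nh2$group_means$mean_norm_height == 1))
  # an animal without anchor events is dropped with a warning
  ev3 <- rbind(ev, events_df("a2", "metestrus", "light", 5))
  expect_warning(nh3 <- normalized_heights(ev3, ev3$stage == "proestrus" &
                                             ev3$animal_id %in% c("a1", "a2") &
                                             ev3$period == "light"),
                 "a2")
  expect_false("a2" %in% nh3$events$animal_id)
})

test_that("interval CDF comparison is the two-sample Kolmogorov-Smirnov test", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(interval_cdf_compare(x, x)$statistic, 0)
  expect_equal(interval_cdf_compare(x, x)$p_value, 1)
  out <- interval_cdf_compare(1:10, 101:110)
  expect_equal(out$statistic, 1)
  expect_lt(out$p_value, 0.01)
  expect_false(interval_cdf_compare(1, x)$computable)
  # agreement with the reference on ordinary samples
  set.seed(2)
  a <- rgamma(40, 3); b <- rgamma(50, 3)
  out <- interval_cdf_compare(a, b)
  ref <- stats::ks.test(a, b)
  expect_equal(out$statistic, unname(ref$statistic))
  expect_equal(out$p_value, ref$p.value)
})

test_that("height CV is sample sd over mean and scale-invariant", {
  expect_equal(height_cv(c(1, 3)), sqrt(2) / 2)
  expect_equal(height_cv(rep(4, 10)), 0)
  h <- rlnorm(20)
  expect_equal(height_cv(h * 7), height_cv(h))
  expect_true(is.na(height_cv(c(-1, 1))))
  expect_error(height_cv(1), class = "arcpulse_data_error")
})

test_that("aging fold change divides phase means by the reference phase", {
  ev <- rbind(events_df("a1", "diestrus", "light", rep(2, 4), "regular"),
              events_df("a1", "diestrus", "light", rep(1, 4), "acyclic"))
  fc <- aging_fold_change(ev, "regular")
  expect_equal(fc$fold_change[fc$phase == "acyclic"], 0.5)
  expect_equal(fc$fold_change[fc$phase == "regular"], 1.0)
  # doubling all heights changes nothing
  ev2 <- ev; ev2$height <- 2 * ev2$height
  expect_equal(aging_fold_change(ev2, "regular")$fold_change, fc$fold_change)
  # an animal without reference-phase events is excluded
  ev3 <- rbind(ev, events_df("a2", "diestrus", "light", 3, "acyclic"))
  expect_warning(fc3 <- aging_fold_change(ev3, "regular"), "a2")
  expect_false("a2" %in% fc3$animal_id)
})

test_that("the test battery dispatches the matching standard test", {
  set.seed(11)
  # Mann-Whitney on identical groups: maximal p under tie handling
  d <- data.frame(value = rep(1:5, 2), group = rep(c("x", "y"), each = 5))
  mw <- test_battery(d, "mannwhitney")
  expect_gt(mw$omnibus$p_value, 0.99)
  # paired t on a pure shift with zero noise: deterministic rejection
  dp <- data.frame(value = c(1:10, 1:10 + 2),
                   group = rep(c("pre", "post"), each = 10))
  expect_equal(test_battery(dp, "paired_t")$omnibus$p_value, 0)
  expect_equal(test_battery(data.frame(value = rep(1:10, 2),
                                       group = rep(c("a", "b"), each = 10)),
                            "paired_t")$omnibus$p_value, 1)
  # one-way ANOVA + Tukey agrees with the stats primitives
  d3 <- data.frame(value = rnorm(30, rep(c(0, 0, 3), each = 10)),
                   group = rep(c("a", "b", "c"), each = 10))
  bt <- test_battery(d3, "oneway_anova_tukey")
  ref <- summary(stats::aov(value ~ group, data = d3))[[1]]
  expect_equal(bt$omnibus$p_value, ref[1, "Pr(>F)"])
  expect_equal(nrow(bt$pairwise), 3)
  # a and b are indistinguishable and share a letter; c does not
  expect_equal(bt$letters[["a"]], bt$letters[["b"]])
  expect_false(bt$letters[["c"]] == bt$letters[["a"]])
  # Kruskal-Wallis omnibus agrees with the primitive
  kw <- test_battery(d3, "kruskal_mannwhitney")
  expect_equal(kw$omnibus$p_value,
               stats::kruskal.test(value ~ group, data = d3)$p.value)
  # two-way interaction p comes from the aov table
  d4 <- data.frame(value = rnorm(40), group = rep(c("g1", "g2"), each = 20),
                   period = rep(c("light", "dark"), 20))
  tw <- test_battery(d4, "twoway_anova_interaction")
  expect_true(is.finite(tw$omnibus$p_value))
  # KS design
  ks <- test_battery(d, "ks")
  expect_equal(ks$omnibus$statistic, 0)
})

test_that("repeated-measures design uses a random animal intercept with Tukey contrasts", {
  set.seed(21)
  d <- expand.grid(animal_id = paste0("m", 1:6),
                   group = c("P", "E", "M", "D"))
  d$value <- rnorm(nrow(d), ave(rep(0, nrow(d)), d$animal_id,
                                FUN = function(x) rnorm(1))) +
    ifelse(d$group == "M", 3, 0)
  bt <- test_battery(d, "rm_anova_tukey")
  expect_lt(bt$omnibus$p_value, 0.01)
  expect_equal(nrow(bt$pairwise), 6)
  m_contrasts <- grepl("M", bt$pairwise$contrast)
  expect_true(all(bt$pairwise$p_value[m_contrasts] < 0.05))
})

test_that("one-way ANOVA holds its nominal type-I error under the null", {
  set.seed(33)
  rej <- vapply(1:1000, function(i) {
    d <- data.frame(value = rnorm(18), group = rep(c("a", "b", "c"), each = 6))
    test_battery(d, "oneway_anova_tukey")$omnibus$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.015)
})
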