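make_profile <- function(values, pop, sex, components = paste0("c", seq_len(ncol(values)))) {
  rows <- do.call(rbind, lapply(seq_len(nrow(values)), function(i) {
    data.frame(individual = sprintf("i%02d", i), population = pop[i],
               sex = sex[i], component = components,
               area = values[i, ], stringsAsFactors = FALSE)
  }))
  profile_matrix(rows[rows$area > 0, ], components = components)
}

test_that("area normalization is exact and scale-invariant", {
  expect_equal(normalize_areas(c(1, 1, 2)), c(25, 25, 50))
  expect_equal(normalize_areas(5), 100)
  expect_equal(normalize_areas(c(3, 7) * 1e6), normalize_areas(c(3, 7)))
  expect_error(normalize_areas(c(0, 0)), "all peak areas are zero")
  expect_error(normalize_areas(c(-1, 2)), "non-negative")
})

test_that("profile rows sum to 100 and nd components are flagged zeros", {
  v <- rbind(c(10, 0, 30), c(5, 5, 0))
  p <- make_profile(v, c("A", "A"), c("male", "female"))
  expect_equal(unname(rowSums(p$percent)), c(100, 100), tolerance = 1e-9)
  expect_equal(unname(p$percent[1, 2]), 0)
  expect_false(p$detected[1, 2])
  expect_true(all(p$percent >= 0))
})

test_that("group summaries report mean, SE and n per component", {
  set.seed(5)
  v <- matrix(rexp(40) + 1, 8, 5)
  p <- make_profile(v, rep(c("A", "B"), each = 4), rep("male", 8))
  gs <- group_summary(p, "population")
  a1 <- gs[gs$group == "A" & gs$component == "c1", ]
  expect_equal(a1$n, 4L)
  expect_equal(a1$mean, mean(p$percent[1:4, 1]))
  expect_equal(a1$se, sd(p$percent[1:4, 1]) / 2)
})

test_that("class composition sums group means by hydrocarbon class", {
  pm <- population_mean_matrix()
  cc <- class_composition(pm, "ARIM")
  # independent recomputation straight from the long fixture
  long <- population_means()
  arim <- long[long$population == "ARIM", ]
  cls <- vapply(lapply(arim$label, parse_component_name), `[[`, "", "chc_class")
  expect_equal(unname(cc["alkene"]), sum(arim$mean[cls == "alkene"]))
  expect_equal(unname(cc["n_alkane"]), sum(arim$mean[cls == "n_alkane"]))
  expect_equal(sum(cc), sum(arim$mean))
  expect_error(class_composition(pm, "NOPE"), "unknown group")

  # a single-class profile concentrates at 100
  one <- make_profile(rbind(c(40, 60)), "A", "male",
                      components = c("n-C25", "n-C27"))
  expect_equal(unname(class_composition(one, "A")["n_alkane"]), 100)
})

test_that("n-weighted sex means loosely reconstruct the overall class totals", {
  sm <- sex_means()
  cls <- vapply(lapply(sm$label, parse_component_name), `[[`, "", "chc_class")
  pooled <- (30 * sm$male_mean + 28 * sm$female_mean) / 58
  totals <- tapply(pooled, factor(cls, c("n_alkane", "alkene", "monomethyl",
                                         "dimethyl")), sum)
  printed <- c(n_alkane = 42.3, alkene = 25.8, monomethyl = 22.3,
               dimethyl = 9.2)
  expect_true(all(abs(totals - printed) <= 1.5))
})

test_that("fixture integrity: six populations x 30 components with nd cells", {
  long <- population_means()
  expect_equal(length(unique(long$population)), 6L)
  expect_equal(nrow(long), 180L)
  expect_equal(sum(!long$detected), 17L)
  expect_equal(as.numeric(tapply(long$n, long$population, unique)[
    c("MJHL", "WDLN", "GHIM", "YCHL", "EDJL", "ARIM")]),
    c(10, 12, 10, 8, 12, 6))
})

test_that("sex contrasts behave under null, shift and permutation", {
  set.seed(7)
  v <- matrix(rexp(200) + 1, 20, 10)
  p0 <- make_profile(v, rep("A", 20), rep(c("male", "female"), each = 10))
  same <- p0
  same$percent[11:20, ] <- same$percent[1:10, ]
  r0 <- sex_contrast(same, "c1")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$direction, "none")

  # +5-point shift at n=30/28 with unit sd is decisive (closed-form t ~ 19)
  shift <- rbind(matrix(rnorm(30 * 2, c(30, 70)), 30, 2, byrow = TRUE),
                 matrix(rnorm(28 * 2, c(35, 65)), 28, 2, byrow = TRUE))
  ps <- make_profile(shift, rep("A", 58),
                     c(rep("female", 30), rep("male", 28)))
  rs <- sex_contrast(ps, "c1")
  expect_true(rs$significant_01)
  expect_equal(rs$direction, "male")

  # permuting labels under the null gives a uniform p value
  set.seed(11)
  pvals <- replicate(1000, t.test(rnorm(10), rnorm(10),
                                  var.equal = TRUE)$p.value)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.025)
  expect_lt(abs(mean(pvals) - 0.5), 0.04)

  expect_error(sex_contrast(p0, "nope"), "unknown component")
})

test_that("ANOVA + SNK letters separate and merge groups correctly", {
  set.seed(13)
  # all groups from one distribution: a single letter is overwhelmingly likely
  v <- matrix(rexp(180) + 5, 18, 10)
  p_same <- make_profile(v, rep(c("A", "B", "C"), each = 6), rep("male", 18))
  # literally identical groups: zero MSE path returns one shared letter
  p_ident <- p_same
  p_ident$percent[7:12, ] <- p_ident$percent[1:6, ]
  p_ident$percent[13:18, ] <- p_ident$percent[1:6, ]
  r_ident <- population_contrast(p_ident, "c1")
  expect_equal(unname(r_ident$letters), rep("a", 3))

  # 10-sd separated groups get distinct letters
  g1 <- cbind(rnorm(6, 10, 0.5), rnorm(6, 50, 0.5))
  g2 <- cbind(rnorm(6, 25, 0.5), rnorm(6, 35, 0.5))
  g3 <- cbind(rnorm(6, 40, 0.5), rnorm(6, 20, 0.5))
  p_sep <- make_profile(rbind(g1, g2, g3) ,
                        rep(c("A", "B", "C"), each = 6), rep("male", 18))
  r_sep <- population_contrast(p_sep, "c1")
  expect_equal(length(unique(r_sep$letters)), 3L)
  expect_true(r_sep$p_value < 1e-6)

  # letters are invariant under group relabeling
  p_rel <- p_sep
  map <- c(A = "Z", B = "Q", C = "M")
  p_rel$population[] <- map[p_rel$population]
  r_rel <- population_contrast(p_rel, "c1")
  expect_equal(unname(r_rel$letters[map[names(r_sep$letters)]]),
               unname(r_sep$letters))
})
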