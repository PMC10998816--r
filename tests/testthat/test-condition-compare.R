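random_sig_matrix <- function(k) {
  m <- matrix(FALSE, k, k, dimnames = list(letters[1:k], letters[1:k]))
  up <- upper.tri(m)
  m[up] <- runif(sum(up)) < 0.5
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

test_that("one-way ANOVA matches direct sums-of-squares arithmetic", {
  withr::with_seed(31, {
    groups <- list(g1 = rnorm(3, 10), g2 = rnorm(3, 12), g3 = rnorm(3, 9))
  })
  a <- anova_oneway(groups)

  # textbook-formula oracle
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(a$f_stat, f_oracle, tolerance = 1e-10)
  expect_identical(c(a$df_between, a$df_within), c(2L, 6L))
  expect_equal(a$p_value, pf(f_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("ANOVA handles identical groups and clear separation sensibly", {
  same <- anova_oneway(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$f_stat, 0)
  expect_equal(same$p_value, 1)

  sep <- suppressWarnings(   # near-perfect separation trips lm's F-test caveat
    anova_oneway(list(lo = c(0, 1e-9, -1e-9), hi = c(10, 10 + 1e-9, 10 - 1e-9))))
  expect_lt(sep$p_value, 1e-6)

  expect_error(anova_oneway(list(a = 1, b = c(1, 2))), "fewer than 2",
               class = "fermkin_data_error")
  expect_error(anova_oneway(list(a = c(5, 5), b = c(5, 5))), "identical",
               class = "fermkin_degenerate_error")
  expect_error(anova_oneway(list(a = c(5, 5), b = c(7, 7))), "undefined",
               class = "fermkin_degenerate_error")
})

test_that("two-group Tukey is algebraically the pooled t test", {
  withr::with_seed(17, {
    groups <- list(a = rnorm(4, 1), b = rnorm(4, 1.8))
  })
  th <- tukey_hsd(groups, alpha = 0.05)
  tt <- t.test(groups$a, groups$b, var.equal = TRUE)
  expect_equal(th$q["a", "b"], abs(tt$statistic[[1]]) * sqrt(2),
               tolerance = 1e-10)
  # the studentized-range CDF is evaluated by numerical quadrature (~1e-8)
  expect_lt(abs(th$p_value["a", "b"] - tt$p.value), 1e-6)
  expect_identical(th$significant["a", "b"], tt$p.value < 0.05)
})

test_that("Tukey agrees with the reference implementation on many groups", {
  withr::with_seed(23, {
    groups <- lapply(c(10, 11, 11.5, 14, 15), function(m) rnorm(3, m, 0.8))
  })
  names(groups) <- paste0("g", 1:5)
  th <- tukey_hsd(groups)

  df <- data.frame(value = unlist(groups),
                   group = factor(rep(names(groups), each = 3)))
  ref <- TukeyHSD(aov(value ~ group, df))$group
  for (row in rownames(ref)) {
    pair <- strsplit(row, "-")[[1]]
    expect_equal(th$p_value[pair[1], pair[2]], ref[row, "p adj"],
                 tolerance = 1e-6)
  }
})

test_that("Tukey decisions are invariant to relabeling and location shifts", {
  withr::with_seed(29, {
    groups <- list(a = rnorm(3, 5), b = rnorm(3, 6), c = rnorm(3, 9))
  })
  th1 <- tukey_hsd(groups)
  shifted <- lapply(groups, function(g) g + 100)
  th2 <- tukey_hsd(shifted)
  expect_equal(th1$q, th2$q, tolerance = 1e-9)

  relabeled <- groups[c(3, 1, 2)]
  th3 <- tukey_hsd(relabeled)
  expect_equal(th3$q["c", "a"], th1$q["a", "c"], tolerance = 1e-12)
})

test_that("significance is monotone in alpha", {
  withr::with_seed(37, {
    groups <- lapply(c(10, 10.5, 11, 13), function(m) rnorm(3, m, 0.6))
  })
  names(groups) <- paste0("g", 1:4)
  strict <- tukey_hsd(groups, alpha = 0.001)$significant
  loose <- tukey_hsd(groups, alpha = 0.49)$significant
  expect_true(all(loose[strict]))   # strict-significant pairs stay significant
  expect_gte(sum(loose), sum(strict))
})

test_that("compact letters encode exactly the non-significance relation", {
  k4_all_sig <- matrix(TRUE, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(k4_all_sig) <- FALSE
  cl <- compact_letters(k4_all_sig, setNames(c(4, 3, 2, 1), letters[1:4]))
  expect_identical(unname(cl), c("a", "b", "c", "d"))

  none <- matrix(FALSE, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_identical(unname(compact_letters(none, setNames(3:1, letters[1:3]))),
                   rep("a", 3))

  # one non-significant pair among 5 groups
  m <- matrix(TRUE, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(m) <- FALSE
  m["b", "d"] <- m["d", "b"] <- FALSE
  cl5 <- compact_letters(m, setNames(c(9, 7, 5, 6.5, 1), letters[1:5]))
  share <- function(x, y) {
    any(strsplit(cl5[[x]], "")[[1]] %in% strsplit(cl5[[y]], "")[[1]])
  }
  for (x in letters[1:5]) for (y in letters[1:5]) {
    if (x == y) next
    expect_identical(share(x, y), !m[x, y])
  }
})

test_that("letters are ordered by descending means with 'a' on top", {
  m <- matrix(TRUE, 3, 3, dimnames = list(c("lo", "mid", "hi"),
                                          c("lo", "mid", "hi")))
  diag(m) <- FALSE
  cl <- compact_letters(m, c(lo = 1, mid = 5, hi = 9))
  expect_identical(cl[["hi"]], "a")
  expect_identical(cl[["mid"]], "b")
  expect_identical(cl[["lo"]], "c")
})

test_that("letter sharing round-trips random significance patterns", {
  withr::with_seed(41, {
    for (rep in 1:200) {
      k <- sample(3:6, 1)
      m <- random_sig_matrix(k)
      means <- setNames(runif(k, 0, 10), rownames(m))
      cl <- compact_letters(m, means)
      expect_true(all(nchar(cl) >= 1))
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        shared <- any(strsplit(cl[[i]], "")[[1]] %in%
                        strsplit(cl[[j]], "")[[1]])
        expect_identical(shared, !m[i, j])
      }
    }
  })
})

test_that("find_optimum returns the top condition and its co-optimal set", {
  tab <- descriptor_table(generate_study(
    sim_params(t_end = 24, dt_out = 6, noise_cv = 0.02),
    s0_grid = 150, ph_grid = c(4.0, 4.5, 5.0), salinity_grid = "seawater",
    replicates = 3, seed = 13))
  opt <- find_optimum(tab, "e_p")
  expect_identical(opt$best_condition, names(which.max(opt$means)))
  expect_true(opt$best_condition %in% opt$co_optimal)

  expect_error(find_optimum(tab, "nonexistent"), "unknown",
               class = "fermkin_data_error")

  # two statistically indistinguishable top conditions are both co-optimal
  reps <- tab[tab$row_type == "replicate", ]
  reps[[1]] <- rep(c("p1", "p2", "p3"), each = 3)
  reps$e_p <- c(mk_group(104, 0.2), mk_group(104.05, 0.2), mk_group(90, 0.2))
  tab2 <- rbind(reps, tab[tab$row_type == "summary", ])
  opt2 <- find_optimum(tab2, "e_p")
  expect_identical(opt2$best_condition, "p2")
  expect_setequal(opt2$co_optimal, c("p1", "p2"))
})
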