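# Signed differences, SSD/MSD, ICC, Bland-Altman, and the assembled report.

toy_table <- function() {
  # 4 subjects x 2 raters x (orig + 1 sim condition)
  age_estimate_table(data.frame(
    subject = rep(1:4, times = 4),
    rater = rep(rep(c("R1", "R2"), each = 4), times = 2),
    condition = rep(c("orig", "sim_15s"), each = 8),
    age = c(14.0, 15.5, 16.0, 17.5,  14.5, 15.0, 16.5, 17.0,
            14.5, 15.5, 15.5, 18.0,  14.0, 15.5, 16.5, 17.5)))
}

test_that("table validation catches schema and duplicate violations", {
  expect_error(age_estimate_table(data.frame(a = 1)), "columns")
  df <- data.frame(subject = c(1, 1), rater = "R1",
                   condition = "orig", age = c(14, 15))
  expect_error(age_estimate_table(df), "duplicate")
})

test_that("deltas: definition, antisymmetry, and missing-reference error", {
  tab <- toy_table()
  d <- compute_deltas(tab)
  expect_equal(nrow(d), 8)
  expect_true(all(d$condition != "orig"))
  # subject 1, R1: 14.5 - 14.0
  expect_equal(d$delta[d$subject == 1 & d$rater == "R1"], 0.5)
  # identical conditions -> all zero
  t0 <- tab; t0$age[t0$condition == "sim_15s"] <-
    t0$age[t0$condition == "orig"]
  expect_true(all(compute_deltas(t0)$delta == 0))
  # swapping the roles of the conditions negates every delta
  d_rev <- compute_deltas(tab, reference = "sim_15s")
  key <- function(x) paste(x$subject, x$rater)
  expect_equal(d_rev$delta[match(key(d), key(d_rev))], -d$delta)
  # missing reference partner
  bad <- tab[!(tab$subject == 2 & tab$condition == "orig" &
                 tab$rater == "R1"), ]
  expect_error(compute_deltas(age_estimate_table(bad)), "missing")
})

test_that("SSD and MSD match direct formulas", {
  expect_equal(ssd_msd(rep(0.3, 5)), c(SSD = 0, MSD = 0.3))
  d <- c(0.5, -0.5, 0, 0)
  sm <- ssd_msd(d)
  expect_equal(sm[["MSD"]], 0)
  # hand formula: sqrt(sum((d - mean)^2) / (n - 1))
  expect_equal(sm[["SSD"]], sqrt(sum((d - mean(d))^2) / 3))
  expect_true(is.na(ssd_msd(0.2)[["SSD"]]))
})

test_that("MSD shifts with an added constant while SSD is unchanged", {
  set.seed(31)
  d <- rnorm(15, 0, 0.4)
  a <- ssd_msd(d); b <- ssd_msd(d + 0.7)
  expect_equal(b[["MSD"]], a[["MSD"]] + 0.7)
  expect_equal(b[["SSD"]], a[["SSD"]])
})

test_that("ICC: identity, noise degradation, and the ANOVA oracle", {
  x <- c(14, 15, 16, 17, 18)
  expect_equal(icc(x, x, "A"), 1)
  # large independent noise swamps the subject variance
  set.seed(77)
  subj <- rnorm(40, 16, 1)
  noisy <- subj + rnorm(40, 0, 10)
  expect_lt(icc(subj, noisy, "A"), 0.2)
  # 4-subject toy vs mean squares from aov (independent route)
  a <- c(14.0, 15.5, 16.0, 17.5); b <- c(14.5, 15.0, 16.5, 18.0)
  long <- data.frame(y = c(a, b),
                     subj = factor(rep(1:4, 2)),
                     rater = factor(rep(1:2, each = 4)))
  ms <- summary(stats::aov(y ~ subj + rater, data = long))[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  n <- 4; k <- 2
  expect_equal(icc(a, b, "A"),
               (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE)),
               tolerance = 1e-12)
  expect_equal(icc(a, b, "C"), (MSR - MSE) / (MSR + (k - 1) * MSE),
               tolerance = 1e-12)
  expect_true(is.na(icc(rep(1, 4), rep(1, 4))))
  expect_error(icc(1:2, 1:2), "3 complete")
})

test_that("ICC is invariant to a common affine transform", {
  set.seed(5)
  a <- rnorm(12, 15, 2); b <- a + rnorm(12, 0.2, 0.5)
  for (type in c("A", "C"))
    expect_equal(icc(2.5 * a - 3, 2.5 * b - 3, type), icc(a, b, type),
                 tolerance = 1e-10)
})

test_that("Bland-Altman: identity, constant offset, column exchange", {
  x <- c(14, 15, 16, 17)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0); expect_equal(ba0$loa, 0)
  ba <- bland_altman(x, x + 0.3)
  expect_equal(ba$bias, -0.3)   # sign convention: mean(a - b)
  expect_equal(ba$loa, 0)
  set.seed(9)
  b <- x + rnorm(4, 0, 0.3)
  f <- bland_altman(x, b); g <- bland_altman(b, x)
  expect_equal(g$bias, -f$bias)
  expect_equal(g$loa, f$loa)
  expect_equal(f$means, g$means)
  expect_error(bland_altman(1, 1), "2 pairs")
})

test_that("a perfectly echoing table yields ICC 1, SSD/MSD 0, LOA 0", {
  true_age <- c(13.9, 14.8, 15.6, 16.4, 17.2, 18.1)
  tab <- do.call(rbind, lapply(c("orig", "sim_29s", "sim_15s"), function(cd)
    do.call(rbind, lapply(c("R1", "R2", "A"), function(rt)
      data.frame(subject = 1:6, rater = rt, condition = cd,
                 age = true_age)))))
  rep_ <- build_report(age_estimate_table(tab))
  expect_true(all(rep_$per_condition$ICC == 1))
  expect_true(all(rep_$per_condition$SSD == 0))
  expect_true(all(rep_$per_condition$MSD == 0))
  expect_true(all(rep_$inter_rater$LOA == 0))
  expect_true(all(rep_$inter_rater$bias == 0))
})

test_that("pooled SSD concentrates around the injected noise level", {
  # sampling-distribution oracle: 15 subjects x 6 conditions, noise 0.2 y
  n_ok <- 0
  for (rep_i in 1:100) {
    tab <- with_seed_local(1000 + rep_i, {
      base <- runif(15, 13, 18)
      rows <- data.frame(subject = 1:15, rater = "A",
                         condition = "orig", age = base)
      for (cd in paste0("sim_", 1:6)) {
        rows <- rbind(rows, data.frame(
          subject = 1:15, rater = "A", condition = cd,
          age = base + rnorm(15, 0, 0.2)))
      }
      rows
    })
    d <- compute_deltas(age_estimate_table(tab))
    ssd <- ssd_msd(d$delta)[["SSD"]]
    if (abs(ssd - 0.2) <= 0.2 * 0.2) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 90)
})

test_that("report pooling switch restricts inter-rater cells", {
  tab <- toy_table()
  r_all <- build_report(tab, pooling = "all")
  r_sim <- build_report(tab, pooling = "sim")
  expect_gt(r_all$inter_rater$n, r_sim$inter_rater$n)
})
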