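test_that("LLOD threshold is blank mean plus three blank SDs", {
  # blanks {10, 12, 14}: mean 12, SD 2 -> threshold 18; unit slope maps 1:1
  llod <- compute_llod(c(10, 12, 14), calibration = list(slope = 1,
                                                         intercept = 0))
  expect_equal(llod, 18)
  # calibration line is inverted through slope and intercept
  llod2 <- compute_llod(c(10, 12, 14), calibration = list(slope = 2,
                                                          intercept = 6))
  expect_equal(llod2, (18 - 6) / 2)
})

test_that("the zero-blank fallback uses three lowest-spike SDs, no mean term", {
  llod <- compute_llod(c(0, 0, 0), lowest_spike_areas = c(0.8, 1.0, 1.2),
                       calibration = list(slope = 1, intercept = 0))
  expect_equal(llod, 3 * sd(c(0.8, 1.0, 1.2)))
  llod_na <- compute_llod(c(NA, NA, NA), lowest_spike_areas = c(0.8, 1.0, 1.2),
                          calibration = list(slope = 1, intercept = 0))
  expect_equal(llod_na, llod)
})

test_that("LLOD insufficient-data and degenerate-calibration errors", {
  expect_error(compute_llod(c(10, 12), calibration = list(slope = 1)),
               "3 blank")
  expect_error(compute_llod(c(10, 12, 14), calibration = list(slope = 0)),
               "degenerate")
  expect_error(compute_llod(c(0, 0, 0), lowest_spike_areas = c(1),
                            calibration = list(slope = 1)), "fallback")
})

test_that("LLOD is monotone nondecreasing in blank SD at fixed mean", {
  llods <- sapply(seq(0, 5, length.out = 50), function(s) {
    blanks <- 12 + c(-1, 0, 1) * s  # mean 12, SD s * 1
    compute_llod(blanks, calibration = list(slope = 1, intercept = 0))
  })
  expect_true(all(diff(llods) >= 0))
})

test_that("LLOQ is the lowest level below threshold with all higher levels below", {
  mk <- function(level, cv) {
    # three replicates around 1 with the requested sample CV
    x <- c(1 - cv / 100, 1, 1 + cv / 100) / sqrt(1)  # sd = cv/100, mean 1
    data.frame(level = level, value = 1 + (x - 1) / sd(x) * cv / 100)
  }
  series <- rbind(mk(0.5, 35), mk(1, 18), mk(4, 9), mk(10, 5))
  res <- compute_lloq(series)
  expect_equal(res$lloq_fmol, 1)
  expect_equal(unname(res$cv_by_level), c(35, 18, 9, 5), tolerance = 1e-9)
})

test_that("a non-monotone CV dip cannot define the LLOQ", {
  mk <- function(level, cv) data.frame(level = level,
                                       value = c(1 - cv / 100, 1 + cv / 100))
  # 2-replicate CV of c(1-x, 1+x) is sqrt(2) * x * 100; scale accordingly
  mk2 <- function(level, cv) {
    x <- cv / 100 / sqrt(2)
    data.frame(level = level, value = c(1 - x, 1 + x))
  }
  series <- rbind(mk2(0.5, 10), mk2(1, 30), mk2(4, 5), mk2(10, 5))
  expect_equal(compute_lloq(series)$lloq_fmol, 4)
})

test_that("LLOQ is missing when every level is too noisy", {
  mk2 <- function(level, cv) {
    x <- cv / 100 / sqrt(2)
    data.frame(level = level, value = c(1 - x, 1 + x))
  }
  series <- rbind(mk2(1, 30), mk2(10, 25), mk2(100, 22))
  expect_true(is.na(compute_lloq(series)$lloq_fmol))
})

test_that("LLOQ requires at least two replicates per level", {
  series <- rbind(data.frame(level = 1, value = 1),
                  data.frame(level = 10, value = c(1, 1.1)))
  expect_error(compute_lloq(series), "level 1")
})

test_that("linearity on exact points is a perfect fit", {
  series <- data.frame(level = c(1, 10, 100), ratio = c(0.01, 0.1, 1))
  fit <- fit_linearity(series, scope = "peptide")
  expect_equal(fit$slope, 0.01, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_linearity(data.frame(level = c(1, 10), ratio = c(1, 2)),
                             scope = "peptide"),
               "3 distinct levels")
})

test_that("protein-scope linearity averages peptide ratios per level first", {
  series <- rbind(
    data.frame(level = c(1, 10, 100), ratio = c(0.012, 0.12, 1.2),
               peptide = "A"),
    data.frame(level = c(1, 10, 100), ratio = c(0.008, 0.08, 0.8),
               peptide = "B"))
  fit <- fit_linearity(series, scope = "protein")
  expect_equal(fit$slope, 0.01, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("CV components obey the quadrature identity on a 3-4-5 table", {
  # constructed so intra-assay CV = 3% and inter-assay CV = 4% exactly
  grid <- expand.grid(day = 1:2, replicate = 1:2)
  # within-day pairs with CV 3; injection-wise across-day pairs with CV 4
  # values solved by hand: day d, replicate r -> m_d * (1 + s_r * x)
  x <- 0.03 / sqrt(2)              # within-day half-spread
  vals <- c(`1_1` = 1 - x, `1_2` = 1 + x)
  # scale day 2 so each injection's across-day CV is 4%
  f <- function(k) {
    v11 <- 1 - x; v12 <- 1 + x
    v21 <- k * v11; v22 <- k * v12
    cv <- function(a) 100 * sd(a) / mean(a)
    mean(c(cv(c(v11, v21)), cv(c(v12, v22)))) - 4
  }
  k <- uniroot(f, c(1, 2), tol = 1e-12)$root
  tab <- data.frame(day = c(1, 1, 2, 2), replicate = c(1, 2, 1, 2),
                    value = c(1 - x, 1 + x, k * (1 - x), k * (1 + x)))
  comp <- compute_cv_components(tab)
  expect_equal(unname(comp["intra_cv"]), 3, tolerance = 1e-9)
  expect_equal(unname(comp["inter_cv"]), 4, tolerance = 1e-9)
  expect_equal(unname(comp["total_cv"]), 5, tolerance = 1e-9)
})

test_that("identical replicate tables give zero CV everywhere", {
  tab <- expand.grid(day = 1:5, replicate = 1:3)
  tab$value <- 7
  comp <- compute_cv_components(tab)
  expect_equal(unname(comp), c(0, 0, 0))
})

test_that("CV components match a brute-force oracle on random tables", {
  oracle <- function(tab) {
    cv <- function(x) 100 * sd(x) / mean(x)
    intra <- mean(sapply(sort(unique(tab$day)), function(d) {
      cv(tab$value[tab$day == d])
    }))
    inter <- mean(sapply(sort(unique(tab$replicate)), function(r) {
      cv(tab$value[tab$replicate == r])
    }))
    c(intra, inter, sqrt(intra^2 + inter^2))
  }
  set.seed(31)
  for (i in 1:50) {
    tab <- expand.grid(day = 1:5, replicate = 1:3)
    tab$value <- exp(rnorm(15, 2, 0.2))
    comp <- compute_cv_components(tab)
    expect_equal(unname(comp), oracle(tab), tolerance = 1e-12)
    expect_gte(comp[["total_cv"]],
               max(comp[["intra_cv"]], comp[["inter_cv"]]))
  }
})

test_that("CV components need at least a 2x2 usable grid", {
  tab <- data.frame(day = c(1, 1, 1), replicate = 1:3, value = c(1, 2, 3))
  expect_error(compute_cv_components(tab), "2 usable days")
})

test_that("acceptance requires all three CVs below threshold at every level", {
  cv_tab <- data.frame(
    peptide = c("A", "A", "B", "B"), protein = "P1",
    level = c(5, 50, 5, 50),
    intra_cv = c(3, 2, 21, 2), inter_cv = c(4, 3, 4, 3),
    total_cv = c(5, 3.6, 21.4, 3.6))
  res <- accept_peptides(cv_tab, threshold = 20)
  expect_identical(res$accepted, "A")
  # borderline: a total CV of 18.35 with all others lower is accepted
  cv_ok <- data.frame(peptide = "C", protein = "P2", level = 5,
                      intra_cv = 10, inter_cv = 15.4, total_cv = 18.35)
  expect_identical(accept_peptides(cv_ok)$accepted, "C")
  # protein-level CV averages accepted peptides only
  expect_equal(res$protein_cv$total_cv[res$protein_cv$level == 5], 5)
  expect_identical(accept_peptides(cv_tab[0, ])$accepted, character(0))
})

test_that("noise-free synthetic data yields perfect figures of merit", {
  truth <- noise_free_truth()
  cal <- generate_calibration(truth, levels = c(0.5, 1, 4, 10, 50, 100, 500,
                                                1000),
                              n_blanks = 3, seed = 2)
  repd <- generate_replicate_design(truth, seed = 2)
  report <- suppressWarnings(build_assay_report(cal, repd))
  expect_true(all(report$peptides$r_squared > 1 - 1e-12))
  expect_true(all(report$proteins$protein_r_squared > 1 - 1e-12))
  expect_equal(report$peptides$lloq_fmol, rep(0.5, 4))
  cv_cols <- grep("^total_cv", names(report$peptides), value = TRUE)
  expect_true(all(abs(as.matrix(report$peptides[cv_cols])) < 1e-9))
  expect_true(all(report$peptides$accepted))
})
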