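mk_pair_rows <- function(run, pep, fragments, light, heavy, protein = "P1") {
  rbind(
    data.frame(run_id = run, protein = protein, peptide = pep,
               precursor_charge = 2L, fragment = fragments, label = "light",
               rt_min = 30, area = light, stringsAsFactors = FALSE),
    data.frame(run_id = run, protein = protein, peptide = pep,
               precursor_charge = 2L, fragment = fragments, label = "heavy",
               rt_min = 30, area = heavy, stringsAsFactors = FALSE))
}

test_that("a transition deviating beyond the fold tolerance is excluded", {
  tr <- mk_pair_rows("r1", "AAAEEEGGGK", c("y4", "y5", "y6"),
                     light = c(100, 105, 400), heavy = c(100, 100, 100))
  ex <- flag_interference(tr, fold_tolerance = 2)
  expect_equal(nrow(ex), 1L)
  expect_identical(ex$fragment, "y6")
})

test_that("equal transition ratios are never flagged", {
  tr <- mk_pair_rows("r1", "AAAEEEGGGK", c("y4", "y5", "y6"),
                     light = c(10, 20, 30), heavy = c(5, 10, 15))
  expect_equal(nrow(flag_interference(tr)), 0L)
})

test_that("at least one transition always survives screening", {
  tr <- mk_pair_rows("r1", "AAAEEEGGGK", c("y4", "y5"),
                     light = c(1, 100), heavy = c(100, 1))
  ex <- flag_interference(tr, fold_tolerance = 2)
  expect_lt(nrow(ex), 2L)
})

test_that("single-transition peptides are returned unflagged with a warning", {
  tr <- mk_pair_rows("r1", "AAAEEEGGGK", "y4", light = 10, heavy = 20)
  expect_warning(ex <- flag_interference(tr), "single usable")
  expect_equal(nrow(ex), 0L)
})

test_that("injected interference is flagged with few false positives", {
  truth <- noise_free_truth()
  truth$cv_at_level <- c("0.5" = 0.05, "1000" = 0.05)
  n_inject <- 0L; n_hit <- 0L; n_false <- 0L; n_clean <- 0L
  for (seed in 1:10) {
    cal <- generate_calibration(truth, levels = c(10, 50, 100), n_blanks = 3,
                                seed = seed)
    tr <- cal$transitions
    cal_runs <- cal$metadata$run_id[cal$metadata$run_type == "calibration"]
    light_idx <- which(tr$label == "light" & tr$run_id %in% cal_runs &
                         tr$area > 0)
    set.seed(seed + 1000)
    # one co-eluting contaminant per affected (run, peptide): 15% of groups
    # times one of three transitions = 5% of light transitions
    grp_key <- paste(tr$run_id, tr$peptide, sep = "\r")[light_idx]
    hit_groups <- sample(unique(grp_key), round(0.15 * length(unique(grp_key))))
    contaminated <- vapply(hit_groups, function(g) {
      sample(light_idx[grp_key == g], 1)
    }, integer(1))
    tr$area[contaminated] <- tr$area[contaminated] * 8
    ex <- flag_interference(tr, fold_tolerance = 2)
    key <- paste(tr$run_id, tr$peptide, tr$fragment, sep = "\r")
    ex_key <- paste(ex$run_id, ex$peptide, ex$fragment, sep = "\r")
    truth_key <- key[contaminated]
    n_inject <- n_inject + length(truth_key)
    n_hit <- n_hit + sum(truth_key %in% ex_key)
    n_false <- n_false + sum(!(ex_key %in% truth_key))
    n_clean <- n_clean + (length(light_idx) - length(truth_key))
  }
  expect_gt(n_hit / n_inject, 0.95)
  expect_lt(n_false / n_clean, 0.01)
})

test_that("peptide ratios are summed-area quotients", {
  tr <- mk_pair_rows("r1", "AAAEEEGGGK", c("y4", "y5"),
                     light = c(100, 200), heavy = c(50, 100))
  r <- compute_ratios(tr)
  expect_equal(r$ratio, 2)
  expect_equal(r$log2_ratio, 1)
  expect_equal(r$transitions_used, 2L)
  r_inv <- compute_ratios(tr, orientation = "heavy_over_light")
  expect_equal(r_inv$ratio, 0.5)
})

test_that("missing signal produces a missing ratio with a reason code", {
  tr <- mk_pair_rows("r1", "AAAEEEGGGK", c("y4", "y5"),
                     light = c(NA, NA), heavy = c(50, 100))
  r <- compute_ratios(tr)
  expect_true(is.na(r$ratio))
  expect_identical(r$reason, "no_light_signal")
  tr2 <- mk_pair_rows("r1", "AAAEEEGGGK", c("y4", "y5"),
                      light = c(10, 20), heavy = c(0, 0))
  r2 <- compute_ratios(tr2)
  expect_true(is.na(r2$ratio))
  expect_identical(r2$reason, "zero_heavy_signal")
})

test_that("excluded transitions are removed from the ratio sums", {
  tr <- mk_pair_rows("r1", "AAAEEEGGGK", c("y4", "y5", "y6"),
                     light = c(100, 105, 400), heavy = c(100, 100, 100))
  ex <- flag_interference(tr)
  r <- compute_ratios(tr, excluded = ex)
  expect_equal(r$ratio, 205 / 200)
  expect_equal(r$transitions_used, 2L)
  expect_equal(r$transitions_excluded, 1L)
})

test_that("identical runs normalize with zero factors (identity)", {
  values <- expand.grid(sample_id = c("s1", "s2", "s3"),
                        peptide = c("A", "B", "C"),
                        stringsAsFactors = FALSE)
  values$value <- rep(c(1, 2, 3), each = 3)
  heavy <- values
  heavy$heavy_area <- 1000
  heavy$value <- NULL
  out <- normalize_runs(values, heavy)
  expect_equal(out$factors$factor_log2, rep(0, 3))
  expect_identical(out$values$value, values$value)
})

test_that("an injected run offset is removed by heavy-standard normalization", {
  set.seed(5)
  peps <- sprintf("PEP%02d", 1:10)
  runs <- sprintf("s%02d", 1:8)
  grid <- expand.grid(sample_id = runs, peptide = peps,
                      stringsAsFactors = FALSE)
  base_heavy <- setNames(exp(rnorm(10, 10, 0.5)), peps)
  grid$heavy_area <- base_heavy[grid$peptide] * exp(rnorm(nrow(grid), 0, 0.02))
  grid$value <- rnorm(nrow(grid), 5, 0.05)
  # +1 log2 loading offset on run s03 hits both channels
  hit <- grid$sample_id == "s03"
  grid$heavy_area[hit] <- grid$heavy_area[hit] * 2
  grid$value[hit] <- grid$value[hit] + 1
  out <- normalize_runs(grid[c("sample_id", "peptide", "value")],
                        grid[c("sample_id", "peptide", "heavy_area")])
  run_means <- tapply(out$values$value, out$values$sample_id, mean)
  expect_lt(abs(run_means[["s03"]] - mean(run_means[names(run_means) != "s03"])),
            0.05)
})

test_that("median run factors equal the least-squares run effect on symmetric data", {
  # two runs, three peptides, exact two-way structure (no noise)
  peps <- c("A", "B", "C")
  pep_eff <- c(A = 0, B = 1, C = 2)
  run_eff <- c(r1 = 0, r2 = 0.7)
  grid <- expand.grid(sample_id = names(run_eff), peptide = peps,
                      stringsAsFactors = FALSE)
  grid$heavy_area <- 2^(10 + pep_eff[grid$peptide] + run_eff[grid$sample_id])
  grid$value <- 0
  out <- normalize_runs(grid[c("sample_id", "peptide", "value")],
                        grid[c("sample_id", "peptide", "heavy_area")])
  fit <- lm(log2(heavy_area) ~ peptide + sample_id, data = grid)
  ls_gap <- unname(coef(fit)["sample_idr2"])
  fac <- setNames(out$factors$factor_log2, out$factors$sample_id)
  expect_equal(fac[["r2"]] - fac[["r1"]], ls_gap, tolerance = 1e-6)
  # the explicit least-squares method agrees as well
  out_ls <- normalize_runs(grid[c("sample_id", "peptide", "value")],
                           grid[c("sample_id", "peptide", "heavy_area")],
                           method = "least_squares")
  fac_ls <- setNames(out_ls$factors$factor_log2, out_ls$factors$sample_id)
  expect_equal(fac_ls[["r2"]] - fac_ls[["r1"]], ls_gap, tolerance = 1e-6)
})

test_that("runs with too few heavy observations are flagged with factor 0", {
  values <- expand.grid(sample_id = c("s1", "s2"), peptide = c("A", "B", "C"),
                        stringsAsFactors = FALSE)
  values$value <- 1
  heavy <- values
  heavy$value <- NULL
  heavy$heavy_area <- 1000
  heavy <- heavy[!(heavy$sample_id == "s2" & heavy$peptide != "A"), ]
  expect_warning(out <- normalize_runs(values, heavy), "fewer than 3 heavy")
  expect_equal(out$factors$factor_log2[out$factors$sample_id == "s2"], 0)
  expect_true(out$factors$flagged[out$factors$sample_id == "s2"])
})

test_that("equal-weight rollup averages peptides; single peptide is identity", {
  values <- data.frame(sample_id = "s1", protein = "P1",
                       peptide = c("A", "B"), value = c(2, 4),
                       stringsAsFactors = FALSE)
  m <- rollup(values, weights = "equal")
  expect_equal(unname(m["s1", "P1"]), 3)
  single <- data.frame(sample_id = "s1", protein = "P2", peptide = "C",
                       value = 1.5, stringsAsFactors = FALSE)
  expect_equal(unname(rollup(single)["s1", "P2"]), 1.5)
})

test_that("inverse-variance weights match the closed-form optimum", {
  set.seed(17)
  n <- 4000
  values <- rbind(
    data.frame(sample_id = sprintf("s%04d", 1:n), protein = "P1",
               peptide = "A", value = rnorm(n, 5, 0.1)),
    data.frame(sample_id = sprintf("s%04d", 1:n), protein = "P1",
               peptide = "B", value = rnorm(n, 7, 0.2)))
  m <- rollup(values, weights = "inverse_variance")
  w <- attr(m, "provenance")$P1
  w_a <- w$weight[w$peptide == "A"]
  # closed form: w_A = (1/0.01) / (1/0.01 + 1/0.04) = 0.8
  expect_lt(abs(w_a - 0.8), 0.02)
})

test_that("rollup is scale-consistent and never fabricates values", {
  set.seed(23)
  values <- expand.grid(sample_id = sprintf("s%d", 1:6),
                        peptide = c("A", "B", "C"),
                        stringsAsFactors = FALSE)
  values$protein <- "P1"
  values$value <- rnorm(nrow(values))
  m1 <- rollup(values)
  shifted <- values
  shifted$value <- shifted$value + 1.5
  m2 <- rollup(shifted)
  expect_equal(unclass(m2)[, "P1"], unclass(m1)[, "P1"] + 1.5,
               tolerance = 1e-12)
  # a sample with no observed peptides stays missing
  values2 <- values[values$sample_id != "s6", ]
  m3 <- rollup(values2)
  expect_false("s6" %in% rownames(m3))
  values3 <- values
  values3$value[values3$sample_id == "s6"] <- NA
  m4 <- rollup(values3)
  expect_true(is.na(unclass(m4)["s6", "P1"]))
})
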