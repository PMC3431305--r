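test_that("feature-table CSV round-trips through read and write", {
  X <- matrix(c(1.5, 0, 2.25, 10, 0.125, 3), nrow = 2, byrow = TRUE)
  colnames(X) <- c("0.49_104.1077", "7.43_339.2898", "2.34_353.228")
  obs <- data.frame(line_id = c("L1", "L2"), class = c("A", "B"),
                    subclass = c("A1", "B1"), replicate = c(1L, 1L))
  ft <- feature_table(X, observations = obs)
  expect_equal(dim(ft), c(2L, 3L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  ft2 <- read_feature_table(path)
  expect_identical(ft2$observations, ft$observations)
  expect_identical(ft2$features$feature_id, ft$features$feature_id)
  expect_equal(ft2$intensities, ft$intensities)
})

test_that("invalid tables are rejected with informative errors", {
  obs <- data.frame(line_id = c("L1", "L2"), class = "A", replicate = 1:2)
  X <- matrix(1, 2, 2, dimnames = list(NULL, c("1.00_100.5", "1.00_100.5")))
  expect_error(feature_table(X, observations = obs), "1.00_100.5")

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("line_id,class,subclass,replicate,1.00_100.5",
               "L1,A,NA,1,abc"), path)
  expect_error(read_feature_table(path), "non-numeric")

  writeLines(c("line_id,replicate,1.00_100.5", "L1,1,2.0"), path)
  expect_error(read_feature_table(path), "class")

  Xn <- matrix(c(1, NA), 1, 2, dimnames = list(NULL, c("1_1", "1_2")))
  expect_error(
    feature_table(Xn, observations = data.frame(line_id = "L1", class = "A",
                                                replicate = 1)),
    "missing")
})

test_that("feature ids parse back to rt and m/z, tolerating trailing zeros", {
  ions <- wheat_discriminatory_ions()
  ids <- unique(ions$ion_id)
  expect_length(ids, 35L)
  parsed <- parse_feature_ids(ids)
  first <- ions[!duplicated(ions$ion_id), ]
  expect_equal(parsed$rt, first$rt)
  expect_equal(parsed$mz, first$mz)
  expect_equal(parse_feature_ids("0.49_104.1077"),
               data.frame(feature_id = "0.49_104.1077", rt = 0.49,
                          mz = 104.1077))
  # "2.25_365.316" is the trailing-zero variant of mz 365.3160
  expect_equal(parse_feature_ids("2.25_365.316")$mz, 365.316)
  expect_error(parse_feature_ids("garbage"), "rt")
})

test_that("replicate averaging takes arithmetic means per line", {
  X <- matrix(c(0, 3, 3, 5), ncol = 1,
              dimnames = list(NULL, "1.00_200.1"))
  obs <- data.frame(line_id = c("L1", "L1", "L1", "L2"),
                    class = c("A", "A", "A", "B"), replicate = c(1:3, 1L))
  avg <- average_replicates(feature_table(X, observations = obs))
  expect_equal(unname(avg$intensities[, 1]), c(2, 5))
  expect_equal(avg$observations$line_id, c("L1", "L2"))
  expect_equal(avg$observations$class, c("A", "B"))
  # single-replicate line passes through unchanged
  expect_equal(unname(avg$intensities["L2" == avg$observations$line_id, 1]), 5)
  # inconsistent class labels within a line are rejected at construction
  obs$class[2] <- "B"
  expect_error(feature_table(X, observations = obs), "inconsistent class")
})

test_that("presence filter applies the >=80%-within-a-class rule inclusively", {
  n <- c(A = 6, B = 27, C = 12)
  obs <- data.frame(line_id = sprintf("L%02d", 1:45),
                    class = rep(names(n), n), replicate = 1L)
  X <- matrix(0, 45, 3)
  colnames(X) <- c("1.00_100.1", "1.00_100.2", "1.00_100.3")
  X[1:5, 1] <- 7          # 5/6 in A = 0.833 -> retained
  X[7:27, 2] <- 7         # 21/27 in B = 0.778, zero elsewhere -> removed
  X[, 3] <- 7             # present everywhere -> retained at any frac
  ft <- feature_table(X, observations = obs)
  res <- filter_presence(ft, 0.8)
  expect_setequal(res$table$features$feature_id,
                  c("1.00_100.1", "1.00_100.3"))
  expect_equal(res$report$n_before, 3L)
  expect_equal(res$report$n_removed + res$report$n_retained,
               res$report$n_before)
  res1 <- filter_presence(ft, 1)
  expect_equal(res1$table$features$feature_id, "1.00_100.3")
})

test_that("mean-intensity filter pools all classes and is inclusive at the bound", {
  obs <- data.frame(line_id = sprintf("L%02d", 1:45),
                    class = rep(c("A", "B", "C"), c(6, 27, 12)),
                    replicate = 1L)
  X <- cbind("1.00_100.1" = rep(1.0, 45),          # mean exactly 1 -> kept
             "1.00_100.2" = rep(0.5, 45),          # mean 0.5 -> removed
             "1.00_100.3" = c(45, rep(0, 44)))     # mean 1 via one large value
  ft <- feature_table(X, observations = obs)
  res <- filter_mean_intensity(ft, 1.0)
  expect_setequal(res$table$features$feature_id,
                  c("1.00_100.1", "1.00_100.3"))
  expect_equal(res$report$n_removed, 1L)
})

test_that("filter reports chain and conserve counts on a realistic table", {
  sim <- simulate_feature_table(simulation_config(seed = 11, n_features = 800,
                                                  n_noise = 500, n_lowmean = 100))
  avg <- average_replicates(sim$table)
  expect_equal(nrow(avg$intensities), 45L)
  f1 <- filter_presence(avg)
  f2 <- filter_mean_intensity(f1$table)
  expect_equal(f1$report$n_before, 800L)
  expect_equal(f2$report$n_before, f1$report$n_retained)
  expect_equal(f1$report$n_removed + f1$report$n_retained, 800L)
  # composing the filters never retains a feature either filter rejects
  both <- f2$table$features$feature_id
  expect_true(all(both %in% f1$table$features$feature_id))
  lines <- format_filter_report(list(f1$report, f2$report))
  expect_length(lines, 3L)
  expect_match(lines[1], "n_before")
})

test_that("Pareto scaling centers, divides by sqrt(sd), and is equivariant", {
  X <- cbind(a = c(1, 3), b = c(5, 5))
  sc <- pareto_scale(X)
  expect_equal(unname(sc$X[, "a"]), c(-1, 1) / 2^0.25, tolerance = 1e-12)
  expect_equal(round(unname(sc$X[2, "a"]), 4), 0.8409)
  expect_equal(unname(sc$X[, "b"]), c(0, 0))   # sd = 0 convention

  set.seed(3)
  Y <- matrix(rlnorm(60), 10, 6)
  scy <- pareto_scale(Y)
  expect_equal(colSums(scy$X), rep(0, 6), tolerance = 1e-10,
               ignore_attr = TRUE)
  # multiplying a raw column by c > 0 multiplies its scaled column by sqrt(c)
  Y2 <- Y; Y2[, 1] <- 4 * Y[, 1]
  expect_equal(pareto_scale(Y2)$X[, 1], 2 * scy$X[, 1], tolerance = 1e-10)
  # re-centering a scaled column changes nothing
  expect_equal(sweep(scy$X, 2, colMeans(scy$X)), scy$X, tolerance = 1e-12)

  expect_error(pareto_scale(Y[1, , drop = FALSE]), "2 rows")
  # stored parameters project new observations identically
  expect_equal(pareto_apply(scy, Y), scy$X, tolerance = 1e-12)
})
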