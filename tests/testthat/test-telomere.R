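test_that("standard curve recovers slope, efficiency and exact interpolation", {
  concs <- c(109.0, 36.3, 12.1, 4.0, 1.3)
  cq <- -1 / log10(2) * log10(concs) + 30  # ideal doubling assay
  curve <- fit_standard_curve(concs, cq)
  expect_equal(curve$slope, -1 / log10(2), tolerance = 1e-10)
  expect_equal(curve$efficiency, 1, tolerance = 1e-10)
  expect_equal(curve$r_squared, 1, tolerance = 1e-10)
  expect_equal(predict(curve, cq), concs, tolerance = 1e-10)
  # one cycle earlier means twice the concentration at efficiency 1
  expect_equal(predict(curve, cq - 1), 2 * concs, tolerance = 1e-10)
  expect_error(fit_standard_curve(c(10, 1), c(25, 29)), "at least 3")
  expect_error(fit_standard_curve(rep(10, 4), c(25, 25, 25, 25)), "distinct")
})

test_that("identical T and S concentrations give a T/S ratio of exactly 1", {
  concs <- c(s1 = 10, s2 = 25, s3 = 5)
  pl <- rbind(ideal_plate(concs, "T", "T1"), ideal_plate(concs, "S", "S1"))
  ts <- compute_ts(pl, adjust_batch = FALSE)
  expect_equal(ts$ts_ratio, rep(1, 3), tolerance = 1e-10)
  expect_equal(ts$t_conc, unname(concs[ts$sample_id]), tolerance = 1e-10)
})

test_that("interplate normalization rescales by the control and is scale-equivariant", {
  concs <- c(s1 = 12, s2 = 30)
  # control reads 10% high on the T plate: samples there get scaled by 1/1.1
  pl <- rbind(ideal_plate(concs * 1.1, "T", "T1", shift = 1), # wells up 10%
              ideal_plate(concs, "S", "S1"))
  pl$cq[pl$plate_id == "T1" & pl$role == "control"] <-
    -1 / log10(2) * log10(35 * 1.1) + 30
  ts <- compute_ts(pl, adjust_batch = FALSE)
  expect_equal(ts$ts_ratio, rep(1, 2), tolerance = 1e-10)

  # multiplying every well concentration of one plate by a constant
  # (a uniform Cq shift) leaves every T/S ratio unchanged
  concs2 <- c(s3 = 16, s4 = 42)
  base <- rbind(ideal_plate(concs, "T", "T1", batch = "b1"),
                ideal_plate(concs, "S", "S1", batch = "b1"),
                ideal_plate(concs2 * 1.3, "T", "T2", batch = "b2"),
                ideal_plate(concs2, "S", "S2", batch = "b2"))
  scaled <- base
  sel <- scaled$plate_id == "T2" & scaled$role %in% c("sample", "control")
  scaled$cq[sel] <- scaled$cq[sel] + (-1 / log10(2)) * log10(3)
  got <- compute_ts(scaled, adjust_batch = FALSE)
  want <- compute_ts(base, adjust_batch = FALSE)
  expect_equal(got$ts_ratio, want$ts_ratio, tolerance = 1e-10)
  expect_equal(want$ts_ratio[want$sample_id %in% c("s3", "s4")], c(1.3, 1.3),
               tolerance = 1e-10)
})

test_that("Cq doubling propagates to a doubled ratio through the curve arithmetic", {
  concs <- c(s1 = 10)
  pl <- rbind(ideal_plate(concs, "T", "T1"), ideal_plate(concs, "S", "S1"))
  ts0 <- compute_ts(pl, adjust_batch = FALSE)$ts_ratio
  pl2 <- pl
  sel <- pl2$plate_id == "T1" & pl2$role == "sample"
  pl2$cq[sel] <- pl2$cq[sel] - 1
  expect_equal(compute_ts(pl2, adjust_batch = FALSE)$ts_ratio, 2 * ts0,
               tolerance = 1e-10)
})

test_that("triplicate outliers beyond 0.5 Cq are dropped; noisy samples flagged", {
  concs <- c(s1 = 10)
  pl <- rbind(ideal_plate(concs, "T", "T1"), ideal_plate(concs, "S", "S1"))
  sel <- which(pl$plate_id == "T1" & pl$role == "sample")
  pl$cq[sel[1]] <- pl$cq[sel[1]] + 2  # one wild well
  ts <- compute_ts(pl, adjust_batch = FALSE)
  expect_equal(ts$ts_ratio, 1, tolerance = 1e-10)  # outlier removed
  expect_false(ts$flag_repeat)
  pl2 <- rbind(ideal_plate(concs, "T", "T1"), ideal_plate(concs, "S", "S1"))
  pl2$cq[sel] <- pl2$cq[sel] + c(-0.45, 0, 0.45)  # spread but no single outlier
  expect_true(compute_ts(pl2, adjust_batch = FALSE, cv_threshold = 0.05)$flag_repeat)
  pl3 <- pl[!(pl$plate_id == "S1" & pl$role == "control"), ]
  expect_error(compute_ts(pl3), "control sample missing")
})

test_that("batch adjustment removes batch means exactly and preserves the grand mean", {
  v <- c(9, 11, 11.5, 12.5)
  adj <- batch_adjust(v, c("a", "a", "b", "b"))
  expect_equal(as.numeric(tapply(adj, c("a", "a", "b", "b"), mean)),
               c(11, 11), tolerance = 1e-12)
  expect_equal(mean(adj), mean(v), tolerance = 1e-12)

  set.seed(8)
  x <- rnorm(100, 5000, 400)
  batch <- sample(c("r1", "r2", "r3"), 100, TRUE)
  shifted <- x + c(r1 = 0, r2 = 250, r3 = -120)[batch]
  adj2 <- batch_adjust(shifted, batch)
  bm <- tapply(adj2, batch, mean)
  expect_lt(max(bm) - min(bm), 1e-9)
  expect_warning(same <- batch_adjust(x, rep("one", 100)), "single batch")
  expect_identical(same, x)
  expect_error(batch_adjust(1:5, c("a", "a", "a", "a", "b")), "at least 2")
})

test_that("recovered T/S ratios are unbiased under per-well Cq noise", {
  # noise is placed on the quantified sample wells; standards and control are
  # exact so the 200 sample errors are independent and the mean isolates bias
  # in the interpolation/triplicate/normalization/ratio arithmetic (noise on
  # shared wells adds plate-level variance, not bias)
  set.seed(21)
  samp <- data.frame(sample_id = sprintf("s%03d", 1:200),
                     ts = runif(200, 0.6, 1.8),
                     batch = rep(c("b1", "b2"), each = 100))
  pl <- generate_qpcr_plates(samp, seed = 22, cq_sd = 0, plate_shift_sd = 0.05)
  idx <- pl$role == "sample"
  pl$cq[idx] <- pl$cq[idx] + rnorm(sum(idx), 0, 0.1)
  ts <- compute_ts(pl, adjust_batch = FALSE)
  rel_err <- ts$ts_ratio / samp$ts[match(ts$sample_id, samp$sample_id)] - 1
  expect_lt(abs(mean(rel_err)), 0.01)
  expect_gt(sd(rel_err), 0.01)  # noise genuinely present
})
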