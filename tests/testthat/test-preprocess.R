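test_that("negative TGS correction floors or offsets as documented", {
  expect_equal(correct_negative_tgs(c(-3, 0.2, 7)), c(0.5, 0.5, 7))
  expect_equal(correct_negative_tgs(c(-3, 0.2, 7), "offset", offset = 1),
               c(1, 4.2, 11))
  x <- c(0.6, 2, 7)
  expect_equal(correct_negative_tgs(x), x)   # identity above the floor
  expect_error(correct_negative_tgs(c(0, 1), "offset", offset = 0),
               "non-positive")
})

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(c(1, 2, 3), c(4, 5, 6))
  expect_equal(quantile_normalize(m), cbind(c(2.5, 3.5, 4.5),
                                            c(2.5, 3.5, 4.5)))
  # independent hand oracle on shuffled columns: mean of sorted columns,
  # re-distributed by rank
  set.seed(7)
  r <- cbind(sample(c(10, 20, 30, 40)), sample(c(1, 2, 3, 4)))
  qn <- quantile_normalize(r)
  target <- rowMeans(apply(r, 2, sort))
  expect_equal(qn[order(r[, 1]), 1], target)
  expect_equal(qn[order(r[, 2]), 2], target)

  # exact equality of sorted value sets; idempotence; permutation equivariance
  x <- matrix(rnorm(600), 100, 6)
  q <- quantile_normalize(x)
  sorted <- apply(q, 2, sort)
  for (j in 2:6) expect_identical(sorted[, j], sorted[, 1])
  expect_equal(quantile_normalize(q), q)
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(quantile_normalize(x[, perm]), q[, perm])

  expect_identical(quantile_normalize(x[, 1, drop = FALSE]),
                   x[, 1, drop = FALSE])  # single column unchanged
  m2 <- cbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(quantile_normalize(m2), m2) # identical columns: fixed point
})

test_that("scale normalization equalizes column medians", {
  m <- cbind(c(1, 2, 3), c(3, 4, 5))      # medians 2 and 4 -> both 3
  s <- scale_normalize(m)
  expect_equal(apply(s, 2, median), c(3, 3))
  meq <- cbind(c(0, 1, 2), c(1, 1, 1))    # equal medians: unchanged
  expect_equal(scale_normalize(meq), meq)
})

test_that("normexp fit recovers simulated background parameters", {
  set.seed(11)
  x <- rnorm(50000, 100, 10) + rexp(50000, rate = 1 / 500)
  p <- normexp_fit(x)
  expect_gt(p$mu, 90); expect_lt(p$mu, 110)
  expect_gt(p$alpha, 400); expect_lt(p$alpha, 600)
  expect_gt(p$sigma, 0)

  # scale equivariance: all parameters scale by ~c
  p3 <- normexp_fit(3 * x)
  expect_equal(p3$mu / p$mu, 3, tolerance = 0.05)
  expect_equal(p3$sigma / p$sigma, 3, tolerance = 0.05)
  expect_equal(p3$alpha / p$alpha, 3, tolerance = 0.05)

  expect_error(normexp_fit(rep(5, 1000)), "degenerate")
  expect_error(normexp_fit(rnorm(50)), ">= 100")
})

test_that("normexp adjustment matches the conditional-expectation quadrature", {
  pars <- list(mu = 100, sigma = 10, alpha = 500)
  class(pars) <- "normexp_params"
  oracle <- function(x, mu, sigma, alpha) {
    lo <- max(0, x - mu - 15 * sigma)
    hi <- max(0, x - mu) + 15 * sigma + alpha / 100
    f <- function(s) s * stats::dexp(s, 1 / alpha) * stats::dnorm(x - mu - s, 0, sigma)
    g <- function(s) stats::dexp(s, 1 / alpha) * stats::dnorm(x - mu - s, 0, sigma)
    stats::integrate(f, lo, hi, rel.tol = 1e-11)$value /
      stats::integrate(g, lo, hi, rel.tol = 1e-11)$value
  }
  grid <- c(20, 50, 80, 100, 120, 200, 500, 2000, 5000)
  est <- normexp_adjust(grid, pars)
  ref <- vapply(grid, oracle, 0, mu = 100, sigma = 10, alpha = 500)
  expect_equal(est, ref, tolerance = 1e-6)

  # positivity and monotonicity over an extreme range
  wide <- normexp_adjust(seq(-1e6, 1e6, length.out = 4001), pars)
  expect_true(all(wide > 0))
  expect_true(all(diff(wide) > 0))
  # asymptote: x >> mu + sigma^2/alpha
  x <- 1e6
  expect_equal(normexp_adjust(x, pars), x - 100 - 100 / 500,
               tolerance = 1e-12)
})

test_that("replicate-probe medians use the standard conventions", {
  ds <- manual_probes(probe_name = c("p1", "p1", "p1", "p2", "p2", "p3"),
                      gene_name = c(rep("g1", 5), "g2"),
                      control_type = rep(0L, 6),
                      processed = matrix(0, 6, 2),
                      mean_signal = cbind(c(1, 2, 9, 1, 3, 42),
                                          c(5, 5, 5, 0, 10, 7)))
  pm <- median_replicate_probes(ds)
  expect_equal(pm$values["p1", ], c(2, 5), ignore_attr = TRUE)  # odd count
  expect_equal(pm$values["p2", ], c(2, 5), ignore_attr = TRUE)  # even: midpair
  expect_equal(pm$values["p3", ], c(42, 7), ignore_attr = TRUE) # identity
  expect_equal(unname(pm$gene), c("g1", "g1", "g2"))
})

test_that("median polish reconstructs exactly and matches stats::medpolish", {
  # exactly additive matrix: residuals vanish after one sweep
  r <- c(1, 4, -2); cc <- c(0, 2, 5, 7)
  m <- outer(r, cc, `+`) + 3
  mp <- median_polish(m)
  expect_equal(mp$residuals, matrix(0, 3, 4), ignore_attr = TRUE)
  expect_equal(mp$overall + outer(mp$probe, mp$array, `+`) + mp$residuals,
               m, ignore_attr = TRUE)

  # 1 x n boundary: array effects reproduce the data
  m1 <- matrix(c(5, 7, 9), 1, 3)
  mp1 <- median_polish(m1)
  expect_equal(mp1$overall + mp1$array, c(5, 7, 9), ignore_attr = TRUE)
  expect_true(all(mp1$residuals == 0))

  # identical sweep-by-sweep agreement with the independent implementation,
  # including matrices with gross outliers
  set.seed(3)
  for (i in 1:40) {
    x <- matrix(rnorm(24), 4, 6)
    if (i %% 3 == 0) x[1, 1] <- x[1, 1] + 50
    mine <- median_polish(x, tol = 0, max_iter = 10)
    ref <- suppressWarnings(stats::medpolish(x, eps = 0, maxiter = 10,
                                             trace.iter = FALSE))
    expect_lt(max(abs(mine$residuals - ref$residuals)), 1e-12)
    expect_lt(abs(mine$overall - ref$overall), 1e-12)
    expect_lt(max(abs(mine$probe - ref$row)), 1e-12)
    expect_lt(max(abs(mine$array - ref$col)), 1e-12)
    # reconstruction identity and converged residual medians
    expect_equal(mine$overall + outer(mine$probe, mine$array, `+`) +
                   mine$residuals, x, ignore_attr = TRUE)
    # at convergence the last (column) sweep zeroes column medians exactly,
    # and a further row sweep cannot reduce the absolute-residual sum by
    # more than tol (row medians themselves need not vanish with even
    # column counts, where the L1 objective is flat between the central
    # order statistics)
    conv <- median_polish(x, tol = 1e-9, max_iter = 200)
    expect_lt(max(abs(apply(conv$residuals, 2, median))), 1e-12)
    swept <- conv$residuals - apply(conv$residuals, 1, median)
    expect_lt(sum(abs(conv$residuals)) - sum(abs(swept)), 1e-9 + 1e-12)
  }
})

test_that("RMA summarization honors the additive probe model", {
  # identical probe rows: gene value equals that row
  row <- c(4, 6, 8, 5)
  m <- rbind(p1 = row, p2 = row, p3 = row)
  g <- summarize_rma(m, c(p1 = "g", p2 = "g", p3 = "g"))
  expect_equal(g["g", ], row, ignore_attr = TRUE)

  # probes differing only by constants: array differences preserved exactly
  m2 <- rbind(p1 = row, p2 = row + 2, p3 = row - 1)
  g2 <- summarize_rma(m2, c(p1 = "g", p2 = "g", p3 = "g"))
  expect_equal(diff(unname(g2["g", ])), diff(row))

  # random 4-probe gene equals the independent oracle (overall + col effects)
  set.seed(12)
  m3 <- matrix(rnorm(24, 8), 4, 6,
               dimnames = list(paste0("p", 1:4), NULL))
  g3 <- summarize_rma(m3, setNames(rep("g", 4), rownames(m3)),
                      tol = 0, max_iter = 10)
  ref <- suppressWarnings(stats::medpolish(m3, eps = 0, maxiter = 10,
                                           trace.iter = FALSE))
  expect_equal(unname(g3["g", ]), ref$overall + ref$col, tolerance = 1e-12)

  # single-probe genes pass through; unmapped probes error
  m4 <- rbind(p9 = c(1, 2, 3))
  expect_equal(summarize_rma(m4, c(p9 = "solo"))["solo", ], c(1, 2, 3),
               ignore_attr = TRUE)
  expect_error(summarize_rma(m4, c(px = "other")), "not mapped")
})

test_that("TGS protocol collapses, corrects, logs and normalizes in order", {
  # constant TGS of 2 -> after half-correction and log2, all values 1
  ds <- manual_probes(probe_name = rep(c("p1", "p2"), each = 2),
                      gene_name = rep(c("g1", "g2"), each = 2),
                      control_type = rep(0L, 4),
                      processed = matrix(1, 4, 3))
  ds$total_gene_signal <- matrix(2, 4, 3,
                                 dimnames = dimnames(ds$processed_signal))
  ex <- tgs_pipeline(ds, normalization = "quantile")
  expect_true(all(ex$exprs == 1))

  # normalization = none equals log2 of the corrected TGS exactly
  set.seed(14)
  ds2 <- simulate_probe_signals(small_design(), simulation_config(seed = 14))
  exn <- tgs_pipeline(ds2, normalization = "none")
  gene_rows <- ds2$control_type == 0L
  tgs <- do.call(rbind, lapply(split(which(gene_rows),
                                     ds2$gene_name[gene_rows]),
                               function(i) ds2$total_gene_signal[i[1], ]))
  expect_equal(exn$exprs, log2(correct_negative_tgs(tgs)),
               ignore_attr = TRUE, tolerance = 1e-12)

  # quantile: all columns share one sorted value set
  exq <- tgs_pipeline(ds2, normalization = "quantile")
  sorted <- apply(exq$exprs, 2, sort)
  for (j in 2:ncol(sorted)) expect_equal(sorted[, j], sorted[, 1])

  # inconsistent TGS within a gene's spots -> error
  bad <- ds
  bad$total_gene_signal[1, 1] <- 99
  expect_error(tgs_pipeline(bad), "inconsistent")
})

test_that("RMA protocol executes its five stages in order", {
  des <- small_design()
  cfg <- simulation_config(seed = 15, noise_sd = 0.1)
  ds <- simulate_probe_signals(des, cfg)

  # independent stage-by-stage oracle for the background-off path
  gene_rows <- ds$control_type == 0L
  x <- quantile_normalize(ds$mean_signal[gene_rows, ])   # step 2
  lx <- log2(x)                                          # step 3
  idx <- split(seq_len(nrow(lx)), ds$probe_name[gene_rows])
  pm <- t(vapply(idx, function(i)
    apply(lx[i, , drop = FALSE], 2, median), numeric(ncol(lx))))
  gene_of <- vapply(idx, function(i) ds$gene_name[gene_rows][i[1]], "")
  ref <- t(vapply(split(seq_len(nrow(pm)), gene_of), function(rows) {
    sub <- pm[rows, , drop = FALSE]
    if (nrow(sub) == 1) return(sub[1, ])
    fit <- suppressWarnings(stats::medpolish(sub, eps = 0.01, maxiter = 10,
                                             trace.iter = FALSE))
    fit$overall + fit$col
  }, numeric(ncol(pm))))                                  # steps 4-5
  ex <- rma_pipeline(ds)
  # the oracle stops on medpolish's relative criterion, the package on the
  # absolute one; both use tol/eps = 0.01, so agreement is at that scale
  expect_equal(ex$exprs, ref[rownames(ex$exprs), ], ignore_attr = TRUE,
               tolerance = 0.01)

  # background on differs from off only through stage 1
  exbg <- rma_pipeline(ds, background = "on")
  expect_false(identical(ex$exprs, exbg$exprs))
  expect_identical(rownames(exbg$exprs), rownames(ex$exprs))

  # spike-in recovery: estimated group effect within 0.15 of truth.
  # Run at the full array scale: quantile normalization is only
  # near-effect-preserving when spiked genes are a small fraction of the
  # distribution.
  spikes <- data.frame(gene = c("hsa-miR-sim-0005", "hsa-miR-sim-0011"),
                       group = "B", effect = c(1, 2))
  cfg2 <- simulation_config(groups = rep(c("A", "B"), each = 3),
                            subjects = NULL, seed = 16, noise_sd = 0.1,
                            spikes = spikes)
  ds2 <- simulate_probe_signals(make_array_design(), cfg2)
  ex2 <- rma_pipeline(ds2)
  grp <- ds2$targets$Treatment
  for (i in seq_len(nrow(spikes))) {
    est <- mean(ex2$exprs[spikes$gene[i], grp == "B"]) -
      mean(ex2$exprs[spikes$gene[i], grp == "A"])
    expect_lt(abs(est - spikes$effect[i]), 0.15)
  }
})
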