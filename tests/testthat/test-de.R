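test_that("design matrices use group-mean coding with blocking covariates", {
  tf <- read_targets(write_targets_file())
  X <- build_design(tf, c("Treatment", "Subject"))
  expect_equal(dim(X), c(6L, 4L))
  expect_equal(qr(X)$rank, 4L)
  expect_equal(colnames(X)[1:3], c("A", "B", "C"))
  expect_equal(rowSums(X[, 1:3]), rep(1, 6), ignore_attr = TRUE)

  # one-level treatment: single intercept-like column
  tg1 <- tf; tg1$Treatment <- "A"; tg1$GErep <- 1L
  X1 <- build_design(tg1, "Treatment")
  expect_equal(ncol(X1), 1L)
  expect_true(all(X1 == 1))

  # duplicated factor information is confounded -> rank error
  tg2 <- tf; tg2$Copy <- tf$Treatment
  expect_error(build_design(tg2, c("Treatment", "Copy")), "rank deficient")
  expect_error(build_design(tf, "NoSuchColumn"), "NoSuchColumn")
})

test_that("contrast strings become difference columns", {
  tf <- read_targets(write_targets_file())
  X <- build_design(tf)
  C <- make_contrasts(c("B-A", "C-A"), X)
  expect_equal(dim(C), c(3L, 2L))
  expect_equal(C[, "B-A"], c(A = -1, B = 1, C = 0))
  expect_error(make_contrasts("D-A", X), "unknown")
})

test_that("gene-wise least squares matches closed forms and oracles", {
  # intercept-only: coefficient = mean, sigma = sample sd
  set.seed(40)
  e <- matrix(rnorm(5 * 6, 8), 5, 6, dimnames = list(paste0("g", 1:5), NULL))
  X0 <- matrix(1, 6, 1, dimnames = list(NULL, "mu"))
  f0 <- lm_fit(e, X0)
  expect_equal(f0$coefficients[, 1], rowMeans(e))
  expect_equal(f0$sigma, apply(e, 1, sd), ignore_attr = TRUE)
  expect_equal(f0$df_residual, rep(5L, 5), ignore_attr = TRUE)
  expect_equal(f0$Amean, rowMeans(e))

  # data in the design's column space -> sigma = 0
  dg <- two_group_design()
  ec <- rbind(g1 = rep(c(2, 5), each = 3))
  expect_equal(lm_fit(rbind(ec, ec), dg$X)$sigma, c(0, 0),
               ignore_attr = TRUE)

  # random instances vs the normal-equations oracle and limma
  e2 <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(sprintf("g%02d", 1:20),
                                                     NULL))
  fit <- lm_fit(e2, dg$X)
  XtXi <- solve(crossprod(dg$X))
  for (g in 1:20) {
    beta <- XtXi %*% crossprod(dg$X, e2[g, ])
    expect_equal(unname(fit$coefficients[g, ]), as.vector(beta),
                 tolerance = 1e-10)
    rss <- sum((e2[g, ] - dg$X %*% beta)^2)
    expect_equal(unname(fit$sigma[g]), sqrt(rss / 4), tolerance = 1e-10)
  }
  lf <- limma::lmFit(e2, dg$X)
  expect_equal(fit$coefficients, lf$coefficients, ignore_attr = TRUE)
  expect_equal(fit$stdev_unscaled, lf$stdev.unscaled, ignore_attr = TRUE)
  expect_equal(fit$sigma, lf$sigma, ignore_attr = TRUE)

  # no residual degrees of freedom -> error (one array per group)
  expect_error(lm_fit(e2[, c(1, 4)], dg$X[c(1, 4), ]), "residual degrees")
})

test_that("contrast propagation carries the covariance geometry", {
  dg <- two_group_design(n_per_group = 3)
  set.seed(41)
  e <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(paste0("g", 1:10), NULL))
  fit <- lm_fit(e, dg$X)

  # identity contrast leaves the fit unchanged
  id <- diag(2); dimnames(id) <- list(c("A", "B"), c("A", "B"))
  fid <- contrast_fit(fit, id)
  expect_equal(fid$coefficients, fit$coefficients, ignore_attr = TRUE)
  expect_equal(fid$stdev_unscaled, fit$stdev_unscaled, ignore_attr = TRUE)

  # two-sample comparison: unscaled sd = sqrt(2/n)
  cf <- contrast_fit(fit, dg$C)
  expect_equal(unname(cf$stdev_unscaled[1, 1]), sqrt(2 / 3))
  # zero-sum contrast on equal coefficients -> estimate 0
  eq <- rbind(g = rep(4, 6))
  cfe <- contrast_fit(lm_fit(rbind(eq, eq), dg$X), dg$C)
  expect_equal(unname(cfe$coefficients[, 1]), c(0, 0))
  expect_error(contrast_fit(fit, matrix(1, 3, 1)), "match")
})

test_that("variance moderation matches the hierarchical model and limma", {
  dg <- two_group_design()
  # degenerate dispersion: all gene variances identical -> infinite prior df
  base <- c(0, 1, 2, 0, 1, 2)
  e_eq <- t(vapply(1:10, function(g) base + g, numeric(6)))
  rownames(e_eq) <- paste0("g", 1:10)
  mod_eq <- moderate(lm_fit(e_eq, dg$X))
  expect_equal(mod_eq$df_prior, Inf)
  expect_equal(mod_eq$s2_post, rep(mod_eq$s2_prior, 10))
  expect_equal(mod_eq$s2_prior, unname(lm_fit(e_eq, dg$X)$sigma[1])^2,
               tolerance = 1e-9)

  # hierarchical simulation: full agreement with the limma oracle
  set.seed(42)
  G <- 2000
  sigma2 <- 4 * 4 / rchisq(G, 4)
  e <- matrix(rnorm(G * 6, 0, rep(sqrt(sigma2), 6)), G, 6,
              dimnames = list(sprintf("g%04d", 1:G), NULL))
  mod <- moderate(contrast_fit(lm_fit(e, dg$X), dg$C))
  eb <- limma::eBayes(limma::contrasts.fit(limma::lmFit(e, dg$X),
                                           unname(dg$C)))
  expect_equal(mod$df_prior, eb$df.prior, tolerance = 1e-10)
  expect_equal(mod$s2_prior, eb$s2.prior, tolerance = 1e-10)
  expect_equal(unname(mod$t), unname(eb$t), tolerance = 1e-10)
  expect_equal(unname(mod$p_value), unname(eb$p.value), tolerance = 1e-10)
  expect_equal(unname(mod$F), unname(eb$F), tolerance = 1e-10)

  # moderated t lies between the ordinary t and the fully pooled t
  fit <- contrast_fit(lm_fit(e, dg$X), dg$C)
  t_ord <- fit$coefficients[, 1] / (fit$stdev_unscaled[, 1] * fit$sigma)
  t_pool <- fit$coefficients[, 1] /
    (fit$stdev_unscaled[, 1] * sqrt(mod$s2_prior))
  tm <- mod$t[, 1]
  ok <- fit$sigma > 0
  expect_true(all(sign(tm[ok]) == sign(t_ord[ok]) | tm[ok] == 0))
  expect_true(all(abs(tm[ok]) >= pmin(abs(t_ord[ok]), abs(t_pool[ok])) - 1e-12))
  expect_true(all(abs(tm[ok]) <= pmax(abs(t_ord[ok]), abs(t_pool[ok])) + 1e-12))
})

test_that("BH adjustment is exact on hand cases and dominates raw p-values", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(43)
  p <- runif(100)
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(bh_adjust(p) <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significance calling respects method, adjustment and cutoff", {
  dg <- two_group_design()
  set.seed(44)
  e <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(sprintf("g%02d", 1:50),
                                                    NULL))
  e[1:5, 4:6] <- e[1:5, 4:6] + 5
  mod <- moderate(contrast_fit(lm_fit(e, dg$X), dg$C))

  # all p = 1 -> all-zero decision matrix
  null_mod <- mod
  null_mod$p_value[] <- 1
  expect_true(all(decide_tests(null_mod) == 0L))

  # single contrast: separated and nestedF agree
  d_sep <- decide_tests(mod, "separated", "BH", 0.05)
  d_nf <- decide_tests(mod, "nestedF", "BH", 0.05)
  expect_equal(d_sep, d_nf, ignore_attr = TRUE)
  expect_true(all(rownames(d_sep)[d_sep[, 1] == 1] %in% sprintf("g%02d", 1:5)))

  # cutoff 1 with no adjustment marks every gene, signed by the estimate
  d_all <- decide_tests(mod, "separated", "none", cutoff = 1)
  expect_true(all(d_all != 0))
  expect_equal(unname(d_all[, 1]),
               unname(as.integer(sign(mod$coefficients[, 1]))))
  expect_error(decide_tests(mod, "separated", "BH", 0), "cutoff")
})

test_that("result tables carry the exact column contract", {
  ds <- simulate_probe_signals(
    small_design(),
    simulation_config(groups = rep(c("A", "B"), each = 3), subjects = NULL,
                      seed = 45, spikes = data.frame(
                        gene = c("hsa-miR-sim-0001", "hsa-miR-sim-0006",
                                 "vir-miR-sim-001"),
                        group = "B", effect = c(3, -3, 4))))
  ex <- rma_pipeline(ds)
  X <- build_design(ds$targets)
  mod <- moderate(contrast_fit(lm_fit(ex, X), make_contrasts("B-A", X)))
  dec <- decide_tests(mod, "separated", "BH", 0.05)
  tab <- significant_table(mod, dec, ex, "B-A")
  expect_identical(colnames(tab),
                   c("Probe", "Gene", "M", "A", "t", "pval", "adj.pval",
                     "fdr.pval"))
  expect_equal(nrow(tab), nrow(ex$exprs))      # all analyzed genes listed
  expect_identical(tab$adj.pval, tab$fdr.pval) # BH: adj.pval == fdr.pval
  expect_equal(tab$fdr.pval, bh_adjust(tab$pval))
  dec_none <- decide_tests(mod, "separated", "none", 0.05)
  tab_none <- significant_table(mod, dec_none, ex, "B-A")
  expect_identical(tab_none$adj.pval, tab_none$pval)  # none: adj == pval
  # representative probe belongs to the gene
  expect_true(all(startsWith(tab$Probe, tab$Gene)))
})

test_that("reports list significant genes with registry links", {
  dg <- two_group_design()
  set.seed(46)
  e <- matrix(rnorm(30 * 6), 30, 6,
              dimnames = list(sprintf("mir-%02d", 1:30), NULL))
  mod <- moderate(contrast_fit(lm_fit(e, dg$X), dg$C))
  dec <- decide_tests(mod, "separated", "none", 0.05)
  dec[, 1] <- 0L
  dec[c("mir-03", "mir-11", "mir-20"), 1] <- 1L
  tab <- significant_table(mod, dec, e, "B-A")
  dir <- tempfile()
  files <- write_reports(list(`B-A` = tab), dec, dir)
  html <- readLines(file.path(dir, "B-A_significant.html"))
  anchors <- grep('<a href="http://microrna.sanger.ac.uk/', html,
                  fixed = TRUE, value = TRUE)
  expect_length(anchors, 3L)
  full <- read.delim(file.path(dir, "B-A_all.txt"))
  expect_equal(nrow(full), 30L)

  # zero significant genes: valid html, empty list
  dec0 <- dec; dec0[, 1] <- 0L
  write_reports(list(`B-A` = significant_table(mod, dec0, e, "B-A")),
                dec0, dir)
  html0 <- readLines(file.path(dir, "B-A_significant.html"))
  expect_length(grep("<a href=", html0), 0L)
  expect_true(any(grepl("</html>", html0)))
})
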