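test_that("clone trees honor the ordered-gain and CIN controls", {
  # no CIN, no extension: every clone equals the founder
  set.seed(91)
  spec0 <- cohort_spec(cin_rate = 0, p_extend = 0)
  tr0 <- simulate_clone_tree(spec0)
  expect_equal(nrow(unique(tr0$gains)), 1)
  founder <- tr0$gains[1, ]
  expect_equal(unname(founder[c("21", "14", "X", "18", "17")]), rep(1L, 5))
  expect_equal(unname(founder[c("10", "6", "4")]), rep(0L, 3))

  # depth 1, CIN certain on chromosome X only: children are founder +/- X
  spec1 <- cohort_spec(depth = 1, branching = 4, p_extend = 0,
                       cin_rate = c(1, 0, 0, 0, 0, 0, 0, 0),
                       cin_loss_frac = 0.5)
  tr1 <- simulate_clone_tree(spec1)
  kids <- tr1$gains[-1, ]
  expect_true(all(kids[, "X"] %in% c(0L, 2L)))
  expect_equal(unname(kids[, setdiff(colnames(kids), "X")]),
               matrix(rep(founder[setdiff(names(founder), "X")],
                          each = 4), 4))
  expect_equal(tr1$parent, c(NA, 1L, 1L, 1L, 1L))

  expect_error(simulate_clone_tree(cohort_spec(cin_rate = 1, depth = 9)),
               "degenerate")
})

test_that("default clone trees gain chr21 early and chr4/6 late", {
  set.seed(92)
  frac21 <- frac46 <- numeric(20)
  for (i in 1:20) {
    tr <- simulate_clone_tree(cohort_spec())
    g <- unique(tr$gains)
    frac21[i] <- mean(g[, "21"] >= 1)
    frac46[i] <- mean(g[, "4"] >= 1 | g[, "6"] >= 1)
  }
  expect_gte(mean(frac21), 0.95)
  expect_lt(mean(frac46), 0.5)
})

test_that("sampled cells reproduce their source clones when noise-free", {
  set.seed(93)
  gains <- rbind(c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 2L),
                 c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L))
  colnames(gains) <- panel8$label
  cells <- sample_cells(gains, c(0.7, 0.3), 400, sex = "F",
                        false_gain = 0, false_loss = 0, admixture = 0)
  enc <- encode_cells(cells, "F")
  src <- attr(cells, "source")
  codes <- apply(gains, 1, subclone_string)
  expect_equal(enc$code, codes[src])
})

test_that("planted FISH noise rates are recovered within exact binomial CIs", {
  set.seed(94)
  gains0 <- matrix(0L, 1, 8, dimnames = list(NULL, panel8$label))
  n <- 5000
  cells <- sample_cells(gains0, 1, n, sex = "M",
                        false_gain = 0.0037, false_loss = 0.05)
  r <- estimate_error_rates(cells, sex = "M")
  for (dir in c("gain", "loss")) {
    planted <- if (dir == "gain") 0.0037 else 0.05
    for (chr in panel8$label) {
      k <- r$errors[r$chromosome == chr & r$direction == dir]
      # 99.9% CI per test: 16 chromosome/direction checks run jointly
      ci <- stats::binom.test(k, n, conf.level = 0.999)$conf.int
      expect_true(planted >= ci[1] && planted <= ci[2],
                  label = paste(chr, dir))
    }
  }
})

test_that("admixed normal cells are filtered out as no-gain at the planted rate", {
  set.seed(95)
  gains <- matrix(c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 2L), 1,
                  dimnames = list(NULL, panel8$label))
  n <- 2000
  cells <- sample_cells(gains, 1, n, sex = "F", false_gain = 0,
                        false_loss = 0, admixture = 0.3)
  fl <- filter_cells(cells, sex = "F")
  k <- sum(fl$excluded$reason == "no-gain")
  ci <- stats::binom.test(k, n, conf.level = 0.999)$conf.int
  expect_true(0.3 >= ci[1] && 0.3 <= ci[2])
})

test_that("cohort generation is exactly reproducible from the master seed", {
  spec <- cohort_spec(n_favorable = 3, n_unfavorable = 2,
                      cells_per_sample = 100)
  a <- generate_cohort(spec, seed = 17)
  b <- generate_cohort(spec, seed = 17)
  expect_identical(a$cells, b$cells)
  expect_identical(a$clinical, b$clinical)
  c2 <- generate_cohort(spec, seed = 18)
  expect_false(identical(a$cells, c2$cells))
})

test_that("planted per-sample trisomy rates carry through to measured blasts", {
  set.seed(96)
  spec <- cohort_spec(n_favorable = 6, n_unfavorable = 6,
                      cells_per_sample = 500)
  coh <- generate_cohort(spec, seed = 5)
  meas <- truth <- numeric(12)
  for (i in 1:12) {
    fl <- filter_cells(coh$cells[[i]], sex = coh$clinical$sex[i])
    g <- gain_rates(fl$blasts)
    meas[i] <- g$rates$gain_pct[g$rates$chromosome == "18"]
    truth[i] <- coh$truth[[i]]$rate18
  }
  # strong agreement; FISH loss noise attenuates rates slightly
  expect_gt(stats::cor(meas, truth), 0.95)
  expect_lt(mean(abs(meas - truth)), 8)
})

test_that("estimated entropy converges to the true clone entropy with cell count", {
  set.seed(97)
  k <- 10
  freqs <- stats::rgamma(k, 2); freqs <- freqs / sum(freqs)
  gains <- matrix(0L, k, 8, dimnames = list(NULL, panel8$label))
  gains[, "21"] <- 1L                       # all hyperdiploid
  gains[cbind(seq_len(k), ((seq_len(k) - 1) %% 7) + 1)] <- seq_len(k) %% 3
  codes <- apply(gains, 1, subclone_string)
  true_h <- shannon_entropy(rowsum(freqs, codes)[, 1])
  errs <- sapply(c(200, 2000, 20000), function(n) {
    mean(replicate(8, {
      cells <- sample_cells(gains, freqs, n, sex = "F", false_gain = 0,
                            false_loss = 0)
      enc <- encode_cells(cells, "F")
      abs(shannon_entropy(tabulate_clones(enc$code)$counts) - true_h)
    }))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("PMC and entropy anti-correlate across the concentration sweep", {
  set.seed(98)
  pmcs <- ents <- numeric(0)
  for (conc in c(0.1, 0.3, 1, 3)) {
    for (r in 1:5) {
      spec <- cohort_spec(n_favorable = 1, n_unfavorable = 0,
                          cells_per_sample = 300,
                          concentration = c(favorable = conc,
                                            unfavorable = conc))
      coh <- generate_cohort(spec, seed = 1000 * conc + r)
      fl <- filter_cells(coh$cells[[1]], sex = coh$clinical$sex[1])
      d <- tabulate_clones(fl$blasts)
      pmcs <- c(pmcs, d$pmc); ents <- c(ents, d$entropy)
    }
  }
  expect_lt(stats::cor(pmcs, ents, method = "spearman"), -0.5)
})
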