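test_that("identical gain columns merge first at distance zero", {
  m <- cbind(a = c(1, 1, 0, 1), b = c(1, 1, 0, 1), c = c(0, 1, 1, 0))
  tr <- chromosome_linkage(m)
  expect_equal(tr$height[1], 0)
  expect_setequal(tr$labels[-tr$merge[1, ]], c("a", "b"))
  expect_error(chromosome_linkage(m[, 1, drop = FALSE]), "at least 2")
})

test_that("complete-linkage trees equal the exhaustive oracle (<= 6 leaves)", {
  set.seed(77)
  for (rep in 1:100) {
    k <- sample(3:6, 1)
    m <- matrix(stats::rnorm(20 * k), 20, k,
                dimnames = list(NULL, letters[1:k]))
    tr <- chromosome_linkage(m)
    dmat <- as.matrix(stats::dist(t(m)))
    expect_equal(tr$height, complete_linkage_oracle(dmat), tolerance = 1e-10)
  }
})

test_that("cluster heights are invariant to cell (row) order", {
  set.seed(78)
  m <- matrix(sample(0:2, 200 * 8, TRUE), 200,
              dimnames = list(NULL, panel8$label))
  tr1 <- chromosome_linkage(m)
  tr2 <- chromosome_linkage(m[sample(nrow(m)), ])
  expect_equal(tr1$height, tr2$height)
})

test_that("an early-gained chromosome separates at the base of the tree", {
  # chr21 gained (often doubly) in every cell; chr14/X gained in almost all
  # cells; chr4 and chr6 only in a late subclone where they co-occur;
  # remaining chromosomes gained in scattered intermediate clones
  set.seed(79)
  n <- 600
  late <- stats::runif(n) < 0.15
  m <- matrix(0L, n, 8, dimnames = list(NULL, panel8$label))
  m[, "21"] <- 2L
  m[, "14"] <- stats::rbinom(n, 1, 0.95)
  m[, "X"] <- stats::rbinom(n, 1, 0.93)
  m[, "17"] <- stats::rbinom(n, 1, 0.5)
  m[, "18"] <- stats::rbinom(n, 1, 0.5)
  m[, "10"] <- stats::rbinom(n, 1, 0.45)
  m[late, "4"] <- 1L
  m[late, "6"] <- 1L
  tr <- chromosome_linkage(m)
  ord <- gain_order(tr)
  # the universally gained chromosome separates at the base of the tree
  expect_equal(ord$label[ord$rank == 1], "21")
  # chr4 and chr6 merge with each other before joining anything else
  first46 <- which(apply(tr$merge, 1, function(r)
    setequal(tr$labels[-r[r < 0]], c("4", "6")) && all(r < 0)))
  expect_length(first46, 1)
  # the early pair chr14/chr X also cluster directly together
  first14x <- which(apply(tr$merge, 1, function(r)
    all(r < 0) && setequal(tr$labels[-r[r < 0]], c("14", "X"))))
  expect_length(first14x, 1)
})

test_that("gain order peels chains and shares ranks on star trees", {
  # chain: 21 splits last (base), then {14, X}, then the rest
  nm <- c("21", "14", "X", "r1", "r2", "r3")
  coord <- c("21" = 0, "14" = 40, "X" = 41, "r1" = 60, "r2" = 60.5,
             "r3" = 61)
  d <- abs(outer(coord, coord, "-"))
  dimnames(d) <- list(nm, nm)
  tr <- stats::hclust(stats::as.dist(d), method = "complete")
  ord <- gain_order(tr)
  expect_equal(ord$label[ord$rank == 1], "21")
  expect_setequal(ord$label[ord$rank == 2], c("14", "X"))
  expect_true(all(ord$rank[ord$label %in% c("r1", "r2", "r3")] > 2))

  # equal distances everywhere: every leaf shares one rank
  d2 <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d2) <- 0
  tr2 <- stats::hclust(stats::as.dist(d2), method = "complete")
  ord2 <- gain_order(tr2)
  expect_true(all(ord2$rank == 1))
})

test_that("gain order ranks agree with an independent peel from stored heights", {
  peel_oracle <- function(tree) {
    # independent reimplementation walking merges top-down via leaf sets
    leafset <- function(node) if (node < 0) -node else
      c(leafset(tree$merge[node, 1]), leafset(tree$merge[node, 2]))
    sep <- setNames(rep(NA_real_, length(tree$labels)), tree$labels)
    node <- nrow(tree$merge)
    repeat {
      a <- tree$merge[node, 1]; b <- tree$merge[node, 2]
      la <- leafset(a); lb <- leafset(b)
      h <- tree$height[node]
      if (length(la) == length(lb)) {
        sep[tree$labels[c(la, lb)]] <- h; break
      }
      small <- if (length(la) < length(lb)) la else lb
      sep[tree$labels[small]] <- h
      node <- if (length(la) < length(lb)) b else a
      if (node < 0) break
    }
    rk <- match(signif(sep, 12), sort(unique(signif(sep, 12)), TRUE))
    rk
  }
  set.seed(80)
  for (rep in 1:20) {
    m <- matrix(stats::rnorm(30 * 7), 30, 7,
                dimnames = list(NULL, letters[1:7]))
    tr <- chromosome_linkage(m)
    ord <- gain_order(tr)
    expect_equal(ord$rank[match(tr$labels, ord$label)], unname(peel_oracle(tr)))
  }
})

test_that("row z-scores use the population SD and flag constant rows", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 2, 1))
  cc <- clone_clustering(m)
  expect_equal(unname(cc$z["a", ]), c(-1.224745, 0, 1.224745),
               tolerance = 1e-6)
  expect_equal(unname(cc$z["b", ]), c(0, 0, 0))
  expect_equal(cc$constant_rows, "b")
  # non-constant standardized rows: mean 0, population SD 1
  expect_equal(mean(cc$z["c", ]), 0)
  expect_equal(stats::sd(cc$z["c", ]) * sqrt(2 / 3), 1)
  expect_error(clone_clustering(rbind(c(1, 1), c(2, 2))), "constant")
})

test_that("samples with identical clone profiles sit at column distance zero", {
  m <- cbind(S1 = c(0.6, 0.3, 0.1, 0), S2 = c(0.6, 0.3, 0.1, 0),
             S3 = c(0, 0.1, 0.2, 0.7))
  rownames(m) <- paste0("cl", 1:4)
  cc <- clone_clustering(m)
  dm <- as.matrix(stats::dist(t(cc$z)))
  expect_equal(dm["S1", "S2"], 0)
  expect_gt(dm["S1", "S3"], 0)
})

test_that("matched DX-REL columns sharing major clones co-cluster", {
  # three patients, each pair dominated by a private clone; background
  # clones evenly spread (constant rows standardize to zero)
  m <- matrix(0.04, 6, 6,
              dimnames = list(paste0("cl", 1:6),
                              c("P1_DX", "P1_REL", "P2_DX", "P2_REL",
                                "P3_DX", "P3_REL")))
  m[1, 1:2] <- 0.8; m[2, 3:4] <- 0.8; m[3, 5:6] <- 0.8
  cc <- clone_clustering(m)
  mrg <- cc$col_tree$merge
  labs <- cc$col_tree$labels
  pair_first <- vapply(1:3, function(p) {
    cols <- grep(paste0("P", p, "_"), labs)
    any(apply(mrg, 1, function(r) setequal(-r[r < 0], cols) && all(r < 0)))
  }, logical(1))
  expect_true(all(pair_first))
})

test_that("dendrograms export as Newick with additive branch lengths", {
  m <- matrix(stats::rnorm(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  tr <- chromosome_linkage(m)
  nwk <- export_newick(tr)
  expect_match(nwk, "^\\(.*\\);$")
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, letters[1:4])
})
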