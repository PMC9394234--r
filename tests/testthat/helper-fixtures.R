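# shared fixtures and independent oracles, built in code at test time

panel8 <- default_panel()

# cell table from a cells x 8 count matrix
make_cell_table <- function(counts, sample_id = "S1") {
  counts <- matrix(counts, ncol = nrow(panel8),
                   dimnames = list(NULL, panel8$label))
  cbind(data.frame(cell_id = paste0("c", seq_len(nrow(counts))),
                   sample_id = sample_id, stringsAsFactors = FALSE),
        as.data.frame(counts, check.names = FALSE))
}

write_cells_tmp <- function(df) {
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  tf
}

# diploid copy-number row for a given sex
diploid_counts <- function(sex) {
  ifelse(panel8$label == "X", if (sex == "M") 1L else 2L, 2L)
}

# independent exact binomial upper-tail by explicit summation
tail_sum_oracle <- function(k, n, p) {
  if (k > n) return(0)
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j), 0))
}

# independent brute-force cutoff search against the summed tail
cutoff_oracle <- function(p, n, alpha) {
  for (k in 1:(n + 1)) {
    if (k > n) return(NA_integer_)
    if (tail_sum_oracle(k, n, p) < alpha) return(k)
  }
}

# exhaustive complete-linkage agglomeration from the raw distance matrix;
# returns the sequence of merge heights
complete_linkage_oracle <- function(dmat) {
  clusters <- as.list(seq_len(nrow(dmat)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    bh <- Inf; bi <- c(NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- max(dmat[clusters[[i]], clusters[[j]]])
        if (h < bh) { bh <- h; bi <- c(i, j) }
      }
    }
    heights <- c(heights, bh)
    clusters[[bi[1]]] <- c(clusters[[bi[1]]], clusters[[bi[2]]])
    clusters[[bi[2]]] <- NULL
  }
  heights
}

# hand product-limit estimator for small fixtures (right censoring)
km_oracle <- function(time, event, at) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  for (t in tt[tt <= at]) {
    d <- sum(time == t & event == 1)
    r <- sum(time >= t)
    s <- s * (1 - d / r)
  }
  s
}

# cohort of planted-rule labels: true features uniform, label from the
# 40/40 two-step rule on the TRUE values, observed = true + N(0, sd)
planted_rule_cohort <- function(n = 200, t18 = 40, t10 = 40, sd = 5) {
  f18 <- stats::runif(n, 5, 95)
  f10 <- stats::runif(n, 5, 95)
  lab <- ifelse(f18 > t18 & f10 > t10, "CR", "REL")
  feats <- cbind("18" = f18 + stats::rnorm(n, 0, sd),
                 "10" = f10 + stats::rnorm(n, 0, sd),
                 "21" = stats::runif(n, 5, 95),
                 "14" = stats::runif(n, 5, 95))
  feats <- pmin(pmax(feats, 0), 100)
  colnames(feats) <- c("18", "10", "21", "14")
  list(features = feats, labels = lab)
}
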