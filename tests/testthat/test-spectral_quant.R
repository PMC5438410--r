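test_that("unique-peptide filter keeps proteins at or above the cutoff", {
  m <- spectral_count_matrix(
    data.frame(protein_id = c("A", "B", "C"), length_aa = c(10L, 10L, 10L),
               unique_peptides = c(1L, 2L, 3L)),
    matrix(1L, 3, 1, dimnames = list(NULL, "S1")),
    data.frame(sample = "S1", condition = "tumor", pair_id = "p1"))
  expect_equal(filter_by_unique_peptides(m, 2)$proteins$protein_id,
               c("B", "C"))
  expect_equal(filter_by_unique_peptides(m, 0)$proteins$protein_id,
               m$proteins$protein_id)

  spec <- simulation_spec(seed = 2, n_proteins = 100, depth_per_sample = 5e3)
  big <- simulate_spectral_experiment(spec)
  n37 <- sum(big$proteins$unique_peptides >= 2)
  expect_equal(nrow(filter_by_unique_peptides(big, 2)$proteins), n37)
})

test_that("NSAF matches the length-normalized formula by hand", {
  m <- two_protein_matrix()
  pr <- compute_nsaf(m, "T1")  # A: S=4,L=2; B: S=1,L=1
  expect_equal(unname(pr$nsaf), c(2 / 3, 1 / 3))
  expect_equal(sum(pr$nsaf), 1)

  single <- spectral_count_matrix(
    data.frame(protein_id = "A", length_aa = 7L, unique_peptides = 2L),
    matrix(9L, 1, 1, dimnames = list(NULL, "S1")),
    data.frame(sample = "S1", condition = "tumor", pair_id = "p1"))
  expect_equal(unname(compute_nsaf(single, "S1")$nsaf), 1)

  zero <- spectral_count_matrix(
    data.frame(protein_id = c("A", "B", "C"), length_aa = c(5L, 5L, 5L),
               unique_peptides = c(2L, 2L, 2L)),
    matrix(c(0L, 3L, 2L), 3, 1, dimnames = list(NULL, "S1")),
    data.frame(sample = "S1", condition = "tumor", pair_id = "p1"))
  expect_equal(unname(compute_nsaf(zero, "S1")$nsaf[1]), 0)

  allzero <- spectral_count_matrix(
    data.frame(protein_id = "A", length_aa = 5L, unique_peptides = 2L),
    matrix(0L, 1, 1, dimnames = list(NULL, "S1")),
    data.frame(sample = "S1", condition = "tumor", pair_id = "p1"))
  expect_error(compute_nsaf(allzero, "S1"), "degenerate")
})

test_that("NSAF equals direct evaluation of the formula on tiny instances", {
  set.seed(10)
  for (rep in 1:25) {
    np <- sample(1:5, 1)
    s <- rpois(np, 20); s[1] <- s[1] + 1  # at least one nonzero
    len <- sample(50:500, np)
    m <- spectral_count_matrix(
      data.frame(protein_id = paste0("P", seq_len(np)),
                 length_aa = as.integer(len),
                 unique_peptides = rep(2L, np)),
      matrix(as.integer(s), np, 1, dimnames = list(NULL, "S1")),
      data.frame(sample = "S1", condition = "tumor", pair_id = "p1"))
    direct <- (s / len) / sum(s / len)
    expect_equal(unname(compute_nsaf(m, "S1")$nsaf), direct,
                 tolerance = 1e-12)
  }
})

test_that("ppm rescaling sums to one million", {
  m <- two_protein_matrix()
  pr <- compute_nsaf(m, "T1")
  expect_equal(unname(pr$ppm), c(2 / 3, 1 / 3) * 1e6)
  expect_equal(sum(pr$ppm), 1e6, tolerance = 1e-3)
  pr$nsaf <- c(A = 0.25, B = 0.75)
  expect_equal(unname(nsaf_to_ppm(pr)$ppm), c(250000, 750000))
})

test_that("NSAF is invariant to sample-wide count rescaling and monotone in
          counts at equal length", {
  spec <- simulation_spec(seed = 3, n_proteins = 50, depth_per_sample = 2e3)
  m <- simulate_spectral_experiment(spec)
  pr1 <- compute_nsaf(m, "T1")
  m7 <- m
  m7$counts[, "T1"] <- m7$counts[, "T1"] * 7L
  expect_equal(compute_nsaf(m7, "T1")$nsaf, pr1$nsaf, tolerance = 1e-15)

  eq <- spectral_count_matrix(
    data.frame(protein_id = c("A", "B"), length_aa = c(100L, 100L),
               unique_peptides = c(2L, 2L)),
    matrix(c(3L, 9L), 2, 1, dimnames = list(NULL, "S1")),
    data.frame(sample = "S1", condition = "tumor", pair_id = "p1"))
  pr <- compute_nsaf(eq, "S1")
  expect_lt(pr$nsaf["A"], pr$nsaf["B"])
})

test_that("paired differential matches the closed-form paired t-test", {
  # protein X: log2(ppm+1) of 10,11,10,11 (tumor) vs 9,9,9,9 (para)
  ppm <- rbind(X = 2^c(10, 11, 10, 11, 9, 9, 9, 9) - 1,
               Y = rep(100, 8))
  colnames(ppm) <- c(paste0("T", 1:4), paste0("N", 1:4))
  de <- paired_differential(profiles_from_ppm(ppm), paired_sheet(4))
  x <- de[de$protein_id == "X", ]
  # mean paired log2 difference 1.5, t = 5.196 on 3 df
  expect_equal(x$p_value, 2 * pt(-1.5 / (sd(c(1, 2, 1, 2)) / 2), df = 3),
               tolerance = 1e-12)
  expect_equal(round(x$p_value, 4), 0.0138)
  y <- de[de$protein_id == "Y", ]
  expect_equal(y$ratio, 1)
  expect_equal(y$log2fc, 0)
  expect_equal(y$p_value, 1)
})

test_that("single-condition proteins are capped and classed", {
  ppm <- rbind(TO = c(900, 1100, 1000, 950, 0, 0, 0, 0),
               PO = c(0, 0, 0, 0, 500, 450, 600, 520),
               Z = rep(1000, 8))
  colnames(ppm) <- c(paste0("T", 1:4), paste0("N", 1:4))
  de <- paired_differential(profiles_from_ppm(ppm), paired_sheet(4),
                            ratio_cap = 500)
  to <- de[de$protein_id == "TO", ]
  expect_equal(to$ratio, 500)
  expect_true(to$ratio_capped)
  expect_equal(to$regulation, "tumor_only")
  expect_equal(to$log2fc, log2(500))
  po <- de[de$protein_id == "PO", ]
  expect_equal(po$ratio, 1 / 500)
  expect_equal(po$regulation, "para_only")
})

test_that("swapping condition labels negates log2fc and preserves p", {
  spec <- simulation_spec(seed = 6, n_proteins = 200,
                          depth_per_sample = 1e4)
  m <- simulate_spectral_experiment(spec)
  pr <- abundance_profiles(m)
  de <- paired_differential(pr, m$samples)
  swapped <- m$samples
  swapped$condition <- ifelse(swapped$condition == "tumor",
                              "para_tumor", "tumor")
  de2 <- paired_differential(pr, swapped)
  expect_equal(de2$log2fc, -de$log2fc, tolerance = 1e-9)
  expect_equal(de2$p_value, de$p_value, tolerance = 1e-12)
})

test_that("differential calling requires valid pairing", {
  ppm <- rbind(X = rep(10, 2))
  colnames(ppm) <- c("T1", "N1")
  expect_error(paired_differential(profiles_from_ppm(ppm), paired_sheet(1)),
               "insufficient replication")
  sheet <- paired_sheet(2)
  sheet$condition[2] <- "para_tumor"  # pair p2 now lacks its tumor sample
  ppm <- matrix(10, 1, 4, dimnames = list("X", sheet$sample))
  expect_error(paired_differential(profiles_from_ppm(ppm), sheet),
               "pairing error")
})

test_that("regulation classification applies fold and p thresholds", {
  rec <- data.frame(
    protein_id = c("uchl1_like", "flat", "lowp", "downsig"),
    mean_tumor_ppm = 1, mean_para_ppm = 1,
    ratio = c(55.4, 1.0, 3.0, 0.2), ratio_capped = FALSE,
    log2fc = log2(c(55.4, 1, 3, 0.2)),
    p_value = c(0.016, 1.0, 0.2, 0.01),
    neg_log10_p = -log10(c(0.016, 1, 0.2, 0.01)),
    regulation = "unchanged", stringsAsFactors = FALSE)
  cl <- classify_regulation(rec, min_fold = 2, max_p = 0.05)
  expect_equal(cl$records$regulation,
               c("up", "unchanged", "unchanged", "down"))
  expect_equal(cl$summary, list(n_up = 1, n_down = 1, n_unchanged = 2))
  expect_equal(with(cl$summary, n_up + n_down + n_unchanged), nrow(rec))
})
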