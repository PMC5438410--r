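# In-code fixtures shared across test files.

two_protein_matrix <- function() {
  spectral_count_matrix(
    proteins = data.frame(protein_id = c("A", "B"),
                          length_aa = c(2L, 1L),
                          unique_peptides = c(3L, 2L)),
    counts = matrix(c(4L, 1L, 2L, 2L), nrow = 2,
                    dimnames = list(c("A", "B"), c("T1", "N1"))),
    samples = data.frame(sample = c("T1", "N1"),
                         condition = c("tumor", "para_tumor"),
                         pair_id = c("p1", "p1"))
  )
}

# abundance profiles built directly from a ppm matrix (proteins x samples)
profiles_from_ppm <- function(ppm, sample_names = colnames(ppm)) {
  stats::setNames(lapply(seq_len(ncol(ppm)), function(j) {
    structure(list(sample_id = sample_names[j],
                   nsaf = ppm[, j] / 1e6, ppm = ppm[, j]),
              class = "abundance_profile")
  }), sample_names)
}

paired_sheet <- function(k) {
  data.frame(sample = c(sprintf("T%d", 1:k), sprintf("N%d", 1:k)),
             condition = rep(c("tumor", "para_tumor"), each = k),
             pair_id = rep(sprintf("p%d", 1:k), 2),
             stringsAsFactors = FALSE)
}

# minimal subject-record constructor with sensible defaults
make_subjects <- function(n, ...) {
  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    cohort = "I", age = 50, sex = "female", subtype = "insulinoma",
    functional = "functional", grade = "G1", stage = "I", size_cm = 2,
    ki67_class = "<=2%", metastasis = FALSE, location = "head",
    uchl1_percent = 50, inx_percent = 50,
    followup_months = 60, status = "DFS",
    stringsAsFactors = FALSE
  )
  args <- list(...)
  for (nm in names(args)) out[[nm]] <- args[[nm]]
  out
}

# independent brute-force oracle: two-sided Fisher p by direct enumeration
# of hypergeometric point probabilities computed from factorials
fisher_bruteforce_p <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  lo <- max(0, r1 - (n - c1)); hi <- min(r1, c1)
  prob <- function(x) {
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
  }
  p_obs <- prob(a)
  sum(vapply(lo:hi, function(x) {
    p <- prob(x); if (p <= p_obs * (1 + 1e-7)) p else 0
  }, numeric(1)))
}

# independent brute-force oracle: exact two-sided Mann-Whitney p by full
# enumeration of group labelings
mw_enumeration_p <- function(g1, g2) {
  v <- c(g1, g2); n1 <- length(g1); n <- length(v)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(g1, g2)
  center <- n1 * (n - n1) / 2
  idx <- utils::combn(n, n1)
  u_all <- apply(idx, 2, function(i) u_of(v[i], v[-i]))
  mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
}
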