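# fixture builders and brute-force oracles shared across the suite

# small expression matrix from a plain matrix (auto names, half/half groups)
make_em <- function(values, groups = NULL, ...) {
  if (is.null(rownames(values))) rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (is.null(groups)) {
    half <- ncol(values) %/% 2
    groups <- c(rep("case", half), rep("control", ncol(values) - half))
  }
  expression_matrix(values, groups, ...)
}

# exhaustive-enumeration oracle for the overlap tail: distribution of the
# overlap between a random n-subset of 1..N and the set 1..M
enum_overlap_tail <- function(N, M, n, m) {
  if (m == 0) return(1)
  sel <- utils::combn(N, n)
  overlaps <- colSums(sel <= M)
  mean(overlaps >= m)
}

# exhaustive-enumeration oracle for the two-sided rank-sum p-value, matching
# the exact-test two-sided convention (doubled smaller tail, capped at 1)
enum_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U of x
  splits <- utils::combn(n1 + n2, n1)
  w_all <- apply(splits, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  if (w_obs > n1 * n2 / 2) p <- 2 * mean(w_all >= w_obs)
  else p <- 2 * mean(w_all <= w_obs)
  min(1, p)
}

# minimal spec whose matrix contains all classifier genes, with optional
# planted structure
classifier_spec <- function(seed, planted = c(LDHA = 1, LDHB = 1, SLC16A1 = 1,
                                              SLC16A3 = 1, PKM = 1, PDHB = 1),
                            n_case = 50, n_control = 50, n_genes = 100) {
  simulation_spec(n_genes = n_genes, n_case = n_case, n_control = n_control,
                  seed = seed, planted_fc = planted)
}
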