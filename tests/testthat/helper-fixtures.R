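# Shared fixtures and independent oracles, built in code at test time.

# Rasterised disk as a 0/1 label matrix (pixel centres within radius r+0.5,
# matching the usual "all pixels whose centre falls in the disc" rule).
disk_label <- function(r, pad = 5) {
  n <- 2 * r + 2 * pad
  centre <- r + pad + 0.5
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  m <- matrix(0L, n, n)
  m[(g$row - centre)^2 + (g$col - centre)^2 <= (r + 0.5)^2] <- 1L
  m
}

rect_label <- function(h, w, pad = 2) {
  m <- matrix(0L, h + 2 * pad, w + 2 * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- 1L
  m
}

# Hand-built 6-record SILAC table: 1 reverse, 1 contaminant, 1 modified-only,
# 1 with no valid ratio, 2 clean.
silac_fixture <- function() {
  data.frame(
    protein_id = paste0("P", 1:6),
    ratio_hm_t24 = c(0.5, 1.2, 0.9, NA, 0.25, 1.0),
    ratio_hm_t48 = c(0.6, 1.1, 1.0, NA, 0.30, 2.0),
    reverse = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    contaminant = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    only_modified = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

# Exhaustive-enumeration oracle for the upper-tail hypergeometric: walk all
# choose(N, n) draws and count those with >= k marked members.
hyper_tail_enum <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  combs <- utils::combn(N, n)
  hits <- colSums(matrix(combs <= K, nrow = n))
  mean(hits >= k)
}

# Enumeration oracle for the two-sided Fisher point-probability rule: the
# frequency of each table over all choose(N, n1) assignments, then the sum
# of frequencies not exceeding the observed table's.
fisher_enum <- function(a, b, c, d) {
  m1 <- a + b; n1 <- a + c; N <- a + b + c + d
  if (N == 0) return(1)
  if (n1 == 0 || n1 == N) return(1)
  combs <- utils::combn(N, n1)
  as_ <- colSums(matrix(combs <= m1, nrow = n1))
  freq <- table(as_) / ncol(combs)
  pobs <- freq[[as.character(a)]]
  sum(freq[freq <= pobs * (1 + 1e-7)])
}

# Tiny flat-field image for feature tests: values on the [0,1] 8-bit scale.
flat_image <- function(value, n = 16) {
  list(data = array(value, dim = c(n, n, 3)), pixel_size_um = 1)
}
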