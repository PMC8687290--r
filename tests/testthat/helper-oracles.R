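# Brute-force oracle for forced-flux classification: sample several distinct
# points of the affine solution set {u_free : A u_free = rhs} by projecting
# random anchor vectors onto it (KKT system), and call a coordinate forced
# when it is identical across all samples. Independent of the SVD-based
# production path.
forced_oracle <- function(network, condition, n_samples = 6, tol = 1e-7,
                          seed = 99) {
  S <- network$S
  rids <- colnames(S)
  pin <- condition$pinned
  free <- setdiff(rids, names(pin))
  rhs <- -drop(S[, names(pin), drop = FALSE] %*% pin)
  if (length(condition$supply)) {
    sp <- intersect(names(condition$supply), rownames(S))
    rhs[sp] <- rhs[sp] - condition$supply[sp]
  }
  A <- S[, free, drop = FALSE]
  # drop dependent rows so the KKT system is solvable
  qrA <- qr(t(A))
  keep <- qrA$pivot[seq_len(qrA$rank)]
  A2 <- A[keep, , drop = FALSE]
  rhs2 <- rhs[keep]
  n <- ncol(A2); m <- nrow(A2)
  KKT <- rbind(cbind(diag(n), t(A2)), cbind(A2, matrix(0, m, m)))
  withr::with_seed(seed, {
    sols <- sapply(seq_len(n_samples), function(k) {
      r <- stats::rnorm(n)
      solve(KKT, c(r, rhs2))[seq_len(n)]
    })
  })
  spread <- apply(sols, 1, function(v) max(v) - min(v))
  data.frame(id = free,
             forced = spread < tol,
             flux = rowMeans(sols),
             stringsAsFactors = FALSE)
}

# analytic irreversible Michaelis-Menten for cross-checks
mm_rate <- function(VF, K, x) VF * x / (K + x)
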