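## Small shared fixtures, all built in code.

small_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

toy_table <- function() {
  m <- matrix(c(5L, 5L, 0L,
                0L, 10L, 10L), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  community_table(m)
}

## random integer community table with guaranteed positive column sums
random_table <- function(n_otu = 12, n_samp = 6, lambda = 2, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n_otu * n_samp, lambda), n_otu, n_samp,
                dimnames = list(paste0("OTU_", seq_len(n_otu)),
                                paste0("s", seq_len(n_samp))))
    m[1, ] <- m[1, ] + 1L   # no zero-sum sample
    community_table(m)
  })
}

## plain-R beta-MNTD, independent of the C++ path
r_bmntd <- function(W, D) {
  ns <- ncol(W)
  out <- matrix(0, ns, ns, dimnames = list(colnames(W), colnames(W)))
  for (k in seq_len(ns - 1)) {
    for (m in (k + 1):ns) {
      ik <- which(W[, k] > 0); im <- which(W[, m] > 0)
      dk <- apply(D[ik, im, drop = FALSE], 1, min)
      dm <- apply(D[im, ik, drop = FALSE], 1, min)
      v <- 0.5 * (sum(W[ik, k] * dk) / sum(W[ik, k]) +
                  sum(W[im, m] * dm) / sum(W[im, m]))
      out[k, m] <- out[m, k] <- v
    }
  }
  out
}
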