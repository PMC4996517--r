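# Shared fixture builders; everything is generated in code.

# random I x 2 count table with both column totals positive
random_two_class_table <- function(nrow = 4L, max_count = 20L) {
  repeat {
    m <- matrix(sample(0:max_count, nrow * 2L, replace = TRUE), nrow, 2L)
    if (all(colSums(m) > 0) && sum(m) > 0) return(m)
  }
}

# table with exactly proportional columns (independence: n_ij == E_ij)
independence_table <- function(row_weights = c(2, 1, 3), col_weights = c(2, 3)) {
  outer(row_weights, col_weights)
}

# tiny dataset where SNP pair (1, 2) perfectly determines a binary class
# (class 1 on the diagonal cells g1 == g2) while every single SNP's margin is
# exactly 50:50 — diagonal cells carry double weight so each genotype row of a
# one-locus table splits 2:2 per weight unit
perfect_pair_dataset <- function(scale = 3L) {
  cells <- as.matrix(expand.grid(g1 = 0:2, g2 = 0:2))
  reps <- ifelse(cells[, 1] == cells[, 2], 2L, 1L) * scale
  g12 <- cells[rep(seq_len(9), reps), ]
  cls <- ifelse(g12[, 1] == g12[, 2], 1L, 2L)
  set.seed(99)
  g <- cbind(g12, simulate_genotypes(nrow(g12), 2L, 0.5))
  colnames(g) <- paste0("SNP", 1:4)
  list(genotypes = unname(g), classes = cls)
}
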