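# brute-force neighbour oracle: explicit loops and full sorting, no
# shared code with mnn_pairs()
mnn_oracle <- function(a, b, k) {
  na <- ncol(a); nb <- ncol(b)
  d <- matrix(0, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb))
    d[i, j] <- sqrt(sum((a[, i] - b[, j])^2))
  nn_a <- lapply(seq_len(na), function(i)
    order(d[i, ], colnames(b))[seq_len(k)])
  nn_b <- lapply(seq_len(nb), function(j)
    order(d[, j], colnames(a))[seq_len(k)])
  out <- NULL
  for (i in seq_len(na)) for (j in seq_len(nb))
    if (j %in% nn_a[[i]] && i %in% nn_b[[j]])
      out <- rbind(out, data.frame(cell_a = colnames(a)[i],
                                   cell_b = colnames(b)[j],
                                   stringsAsFactors = FALSE))
  out[order(out$cell_a, out$cell_b), , drop = FALSE]
}

rand_mat <- function(nf, nc, prefix, seed) {
  set.seed(seed)
  matrix(rnorm(nf * nc), nf, nc,
         dimnames = list(paste0("f", seq_len(nf)),
                         sprintf("%s%03d", prefix, seq_len(nc))))
}
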