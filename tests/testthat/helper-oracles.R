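# Independent brute-force oracles and small fixture builders.

# Dense between- and within-class scatter matrices by the definitional
# double loop: S_b = sum_i n_i (m_i - m)(m_i - m)', S_w = sum_i sum_j
# (x_ij - m_i)(x_ij - m_i)'. Deliberately naive, independent of the
# factored implementation.
dense_scatter <- function(x, labels) {
  labels <- factor(labels)
  p <- nrow(x)
  m <- rowMeans(x)
  Sb <- matrix(0, p, p)
  Sw <- matrix(0, p, p)
  for (cl in levels(labels)) {
    cols <- which(labels == cl)
    mi <- rowMeans(x[, cols, drop = FALSE])
    Sb <- Sb + length(cols) * tcrossprod(mi - m)
    for (j in cols) Sw <- Sw + tcrossprod(x[, j] - mi)
  }
  list(Sb = Sb, Sw = Sw)
}

dense_st <- function(x, labels, beta, st_form = "diff") {
  sc <- dense_scatter(x, labels)
  if (st_form == "diff") sc$Sb - beta * sc$Sw else sc$Sb + beta * sc$Sw
}

# Grid-search oracle for max a'u s.t. ||u||_2 <= 1, ||u||_1 <= c over the
# soft-threshold path: scans candidate thresholds on a coarse grid, then
# refines around the best feasible candidate. Independent of the binary
# search in the implementation.
l1_unit_oracle <- function(a, c, grid_n = 4000L) {
  scan <- function(deltas) {
    best <- NULL
    best_obj <- -Inf
    best_delta <- NA_real_
    for (delta in deltas) {
      su <- sign(a) * pmax(abs(a) - delta, 0)
      nrm <- sqrt(sum(su^2))
      if (nrm == 0) next
      u <- su / nrm
      if (sum(abs(u)) <= c + 1e-6) {
        obj <- sum(a * u)
        if (obj > best_obj) {
          best_obj <- obj
          best <- u
          best_delta <- delta
        }
      }
    }
    list(u = best, delta = best_delta)
  }
  top <- max(abs(a)) * (1 - 1e-9)
  step <- top / (grid_n - 1)
  coarse <- scan(seq(0, top, length.out = grid_n))
  lo <- max(0, coarse$delta - 2 * step)
  hi <- min(top, coarse$delta + 2 * step)
  scan(seq(lo, hi, length.out = grid_n))$u
}

# Random labeled expression fixture with balanced classes.
rand_labeled <- function(p, n, C = 2L) {
  stopifnot(n %% C == 0L)
  x <- matrix(rnorm(p * n), p, n,
              dimnames = list(paste0("g", seq_len(p)),
                              paste0("s", seq_len(n))))
  labels <- factor(rep(paste0("cl", seq_len(C)), each = n %/% C))
  names(labels) <- colnames(x)
  list(x = x, labels = labels)
}

# Write a small expression TSV for I/O tests.
write_expr_file <- function(x, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_label_file <- function(labels, path = tempfile(fileext = ".tsv"),
                             header = FALSE) {
  lines <- paste(names(labels), as.character(labels), sep = "\t")
  if (header) lines <- c("sample_id\tclass", lines)
  writeLines(lines, path)
  path
}
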