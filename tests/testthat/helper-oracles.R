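# Independent oracles, written as literal transcriptions of the defining
# formulas. They deliberately share no code with the package internals.

# Nadaraya-Watson smoother: explicit double loop over the three equations.
nw_oracle <- function(x, y, b) {
  n <- length(y)
  y_hat <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (k in seq_len(n)) {
      d <- (x[k] - x[i]) / b
      wt <- exp(-0.5 * d^2) / sqrt(2 * pi)
      num <- num + wt * y[k]
      den <- den + wt
    }
    y_hat[i] <- num / den
  }
  y_hat
}

# Brute-force longest strict up/down run scanner.
runs_oracle <- function(y_hat) {
  up <- 0L; down <- 0L; cu <- 0L; cd <- 0L
  for (i in seq_len(length(y_hat) - 1L)) {
    if (y_hat[i + 1L] > y_hat[i]) { cu <- cu + 1L; cd <- 0L }
    else if (y_hat[i + 1L] < y_hat[i]) { cd <- cd + 1L; cu <- 0L }
    else { cu <- 0L; cd <- 0L }
    up <- max(up, cu); down <- max(down, cd)
  }
  c(up = up, down = down)
}

# Independent classification rule checker applying the gates in order.
rule_checker <- function(y_hat, T = 0.3, C = 5, B = 3, E = 0.45) {
  rng <- max(y_hat) - min(y_hat)
  if (rng <= T) return("NR")
  r <- runs_oracle(y_hat)
  slope <- mean(diff(y_hat))          # positions assumed 1..n
  end_diff <- abs(y_hat[length(y_hat)] - y_hat[1])
  if (r[["up"]] >= B && r[["down"]] >= B && end_diff <= E * rng)
    return("biphasic")
  if (slope > 0 && r[["up"]] >= B) return("hyper")
  if (slope < 0 && r[["down"]] >= C) return("hypo")
  "NR"
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of the
# background and count those with >= k set members. Feasible for N <= 12.
hyper_enum_oracle <- function(N, K, n, k) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  draws <- utils::combn(N, n)
  inset <- colSums(draws <= K)        # members 1..K form the set
  mean(inset >= k)
}

# Written fixture helpers -----------------------------------------------

fixture_design <- function(n = 9) {
  dose_design(doses = dose_design()$doses[seq_len(n)])
}

write_site_fixture <- function(rows, design = fixture_design(),
                               path = tempfile(fileext = ".tsv"),
                               drop_cols = character()) {
  df <- data.frame(Protein = rows$protein, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df[["Gene names"]] <- rows$gene %||% rows$protein
  df[["Position"]] <- rows$position %||% 10L
  df[["Amino acid"]] <- rows$residue %||% "S"
  df[["Localization prob"]] <- rows$loc %||% 1
  df[["Replicate"]] <- rows$replicate %||% 1L
  df[["Temperature"]] <- rows$temperature %||% 37
  intens <- rows$intensities
  for (j in seq_along(design$channels)) df[[design$channels[j]]] <- intens[, j]
  df <- df[setdiff(names(df), drop_cols)]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A well-formed 3-site, 2-replicate intensity block (all positive).
demo_intensities <- function(n_rows, n_chan = 9, base = 1000) {
  matrix(base + seq_len(n_rows * n_chan), nrow = n_rows)
}

small_config <- function(...) run_config(design = fixture_design(), ...)
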