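# Independent oracles and fixture builders shared across test files.

# Brute-force FLS: raw product of likelihood ratios, then one log.
# Recomputes the window fraction inline so it shares no code with the
# sum-of-logs implementation under test.
fls_product_oracle <- function(age, affected, a = 0.50, b = 0.134,
                               cc = 65, d = 5) {
  u <- (age - d) / (cc - d)
  u[u < 0] <- 0; u[u > 1] <- 1
  lr <- ifelse(affected, a / b, (1 - a * u) / (1 - b * u))
  log10(prod(lr))
}

# Brute-force Benjamini-Hochberg step-up: literal definition.
bh_brute_force <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k <- which(p[o] <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  reject
}

# Random family of relatives with resolved statuses.
random_family <- function(n = NULL) {
  if (is.null(n)) n <- sample(0:10, 1L)
  data.frame(
    proband_id = rep("P1", n),
    relation = sample(c("parent", "sibling"), n, replace = TRUE),
    age_years = round(runif(n, 0, 100), 1),
    affected = runif(n) < 0.35,
    stringsAsFactors = FALSE)
}

# Minimal relative-level CSV on disk; returns its path.
write_family_csv <- function(df, dir = withr::local_tempdir(.local_envir =
                                                              parent.frame())) {
  path <- file.path(dir, "relatives.csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
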