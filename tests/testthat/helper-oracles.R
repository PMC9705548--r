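## Independent oracles: deliberately naive implementations used only to
## cross-check the package's code paths.

## all-offsets brute force: first offset whose k-window is all T
brute_scan_oracle <- function(flank, k) {
  n <- nchar(flank)
  if (n < k) return(NA_integer_)
  d <- 0:(n - k)
  hits <- substring(flank, d + 1, d + k) == strrep("T", k)
  if (any(hits)) d[which(hits)[1]] else NA_integer_
}

## regex-free suffix classifier: rightmost bait occurrence by position scan,
## then character-by-character suffix inspection
brute_tail_oracle <- function(read, bait) {
  nb <- nchar(bait); nr <- nchar(read)
  pos <- NA_integer_
  for (s in seq_len(nr - nb + 1)) {
    if (substring(read, s, s + nb - 1) == bait) pos <- s
  }
  if (is.na(pos)) return(NA_character_)
  suffix <- substring(read, pos + nb)
  ch <- strsplit(suffix, "", fixed = TRUE)[[1]]
  if (identical(ch, c("C", "C", "A"))) return("CCA")
  if (length(ch) >= 1 && all(ch == "T")) return(paste0("U", min(length(ch), 10)))
  "UNCLASSIFIED"
}

## one-way ANOVA by explicit sums of squares
anova_oracle <- function(groups) {
  y <- unlist(groups); g <- rep(seq_along(groups), lengths(groups))
  grand <- mean(y)
  means <- tapply(y, g, mean)
  ssb <- sum(lengths(groups) * (means - grand)^2)
  ssw <- sum((y - means[as.character(g)])^2)
  df1 <- length(groups) - 1; df2 <- length(y) - length(groups)
  list(F = (ssb / df1) / (ssw / df2), df_between = df1, df_within = df2)
}

## Tukey HSD p-values from first principles via the studentized range
tukey_oracle <- function(groups) {
  y <- unlist(groups); g <- rep(seq_along(groups), lengths(groups))
  means <- tapply(y, g, mean); n <- lengths(groups)
  k <- length(groups); dfw <- length(y) - k
  msw <- sum((y - means[as.character(g)])^2) / dfw
  out <- c()
  for (i in 2:k) for (j in 1:(i - 1)) {
    se <- sqrt(msw / 2 * (1 / n[i] + 1 / n[j]))
    q <- abs(means[i] - means[j]) / se
    out <- c(out, stats::ptukey(q, k, dfw, lower.tail = FALSE))
  }
  out
}

## balanced two-way fixed-effects ANOVA by cell-mean sums of squares
twoway_oracle <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  n_cell <- length(y) / (nlevels(a) * nlevels(b))
  grand <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  ssa <- length(y) / nlevels(a) * sum((ma - grand)^2)
  ssb <- length(y) / nlevels(b) * sum((mb - grand)^2)
  ssab <- n_cell * sum((mab - outer(ma, mb, "+") + grand)^2)
  sse <- sum((y - mab[cbind(as.integer(a), as.integer(b))])^2)
  dfe <- length(y) - nlevels(a) * nlevels(b)
  list(F_a = (ssa / (nlevels(a) - 1)) / (sse / dfe),
       F_b = (ssb / (nlevels(b) - 1)) / (sse / dfe),
       F_ab = (ssab / ((nlevels(a) - 1) * (nlevels(b) - 1))) / (sse / dfe))
}

random_flanks <- function(n, len = 60, t_rich = TRUE) {
  probs <- if (t_rich) c(0.2, 0.2, 0.2, 0.4) else rep(0.25, 4)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
}
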