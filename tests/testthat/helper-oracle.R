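# Independent brute-force inverted-repeat finder used as the oracle for the
# scanner. Enumerates every (start, armLen, spacerLen) triple, checks arm
# complementarity base by base, applies the thresholds, keeps only maximal
# triples (outward extension impossible), and prunes contained intervals by
# direct pairwise comparison. Deliberately shares no code with the package's
# scanner or pruner.
bruteForceIRs <- function(seq, minArm = 5L, maxSpacer = 8L, minTotal = 13L) {
  seq <- toupper(seq)
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pairs_ok <- function(i, j) {
    ci <- comp[ch[i]]
    !is.na(ci) & !is.na(ch[j]) & ci == ch[j]
  }

  cand <- list()
  for (R in minArm:max(minArm, L %/% 2)) {
    for (S in 0:maxSpacer) {
      total <- 2L * R + S
      if (total < minTotal || total > L) next
      starts <- seq_len(L - total + 1L)
      # progressive filtering over arm depth; logically each (start,R,S)
      # triple is tested at every depth
      alive <- starts
      for (k in 0:(R - 1L)) {
        if (!length(alive)) break
        alive <- alive[pairs_ok(alive + k, alive + total - 1L - k)]
      }
      for (st in alive) {
        # maximality: one-base outward extension must be impossible
        if (st > 1L && st + total <= L && pairs_ok(st - 1L, st + total))
          next
        cand[[length(cand) + 1L]] <- c(start = st, end = st + total - 1L,
                                       arm = R, spacer = S)
      }
    }
  }
  if (!length(cand))
    return(data.frame(start = integer(), end = integer(), arm = integer(),
                      spacer = integer()))
  df <- as.data.frame(do.call(rbind, cand))

  # equal intervals: keep max arm, then min spacer
  key <- paste(df$start, df$end)
  keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(i) {
    i <- i[df$arm[i] == max(df$arm[i])]
    i[which.min(df$spacer[i])]
  }), use.names = FALSE)
  df <- df[sort(keep), , drop = FALSE]

  # containment: drop proper sub-intervals (pairwise)
  contained <- vapply(seq_len(nrow(df)), function(i) {
    any(df$start <= df$start[i] & df$end >= df$end[i] &
          (df$start < df$start[i] | df$end > df$end[i]))
  }, logical(1))
  df <- df[!contained, , drop = FALSE]
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# random test sequence with a given AT fraction (may include N's)
randomSeq <- function(len, at = 0.5, nProb = 0) {
  p <- c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)
  chars <- sample(c("A", "T", "G", "C"), len, replace = TRUE, prob = p)
  if (nProb > 0) {
    idx <- runif(len) < nProb
    chars[idx] <- "N"
  }
  paste(chars, collapse = "")
}

# compare scanner output with the oracle on one sequence
expect_matches_oracle <- function(seq, ...) {
  got <- findMaximalIRs(seq, ...)
  want <- bruteForceIRs(seq, ...)
  gdf <- data.frame(start = start(got), end = end(got),
                    arm = armLength(got), spacer = spacerLength(got))
  rownames(gdf) <- NULL
  expect_equal(gdf, want, info = paste("sequence:", seq))
}
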