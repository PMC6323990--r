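# Independent oracles used to cross-check the implementation. These are
# deliberately written as naive, direct procedures sharing no code with
# the package internals.

# Brute-force ORF scan: for every position carrying ATG, walk codon by
# codon to the first stop; report when the protein is long enough.
bruteOrfScan <- function(seq, minCodons = 30L,
                         mode = c("all_starts", "longest_per_stop")) {
  mode <- match.arg(mode)
  seq <- toupper(seq)
  L <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  rows <- list()
  i <- 1L
  while (i + 2L <= L) {
    if (substr(seq, i, i + 2L) == "ATG") {
      j <- i
      repeat {
        if (j + 2L > L) break
        cod <- substr(seq, j, j + 2L)
        if (j > i && cod %in% stops) {
          nAa <- (j - i) %/% 3L
          if (nAa >= minCodons)
            rows[[length(rows) + 1L]] <- data.frame(
              tx_start = i, tx_end = j + 2L, frame = (i - 1L) %% 3L)
          break
        }
        j <- j + 3L
      }
    }
    i <- i + 1L
  }
  if (!length(rows))
    return(data.frame(tx_start = integer(), tx_end = integer(),
                      frame = integer()))
  res <- do.call(rbind, rows)
  if (mode == "longest_per_stop") {
    res <- res[order(res$tx_start), , drop = FALSE]
    res <- res[!duplicated(paste(res$frame, res$tx_end)), , drop = FALSE]
  }
  res <- res[order(res$tx_start, res$tx_end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Quadratic Gotoh local-alignment DP (affine gaps, Biostrings gap
# convention: a gap of length k costs open + k * extend).
gotohLocalScore <- function(a, b, mat, open, extend) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)  # gap in a (consume b)
  F <- matrix(-Inf, n + 1L, m + 1L)  # gap in b (consume a)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - open - extend, E[i, j - 1L] - extend)
      F[i, j] <- max(H[i - 1L, j] - open - extend, F[i - 1L, j] - extend)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + mat[a[i - 1L], b[j - 1L]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Brute-force IUPAC window matcher built on Biostrings' own code map
# (regex character classes), independent of the package's motif logic.
bruteIupacMatch <- function(window, pattern) {
  pattern <- chartr("U", "T", toupper(pattern))
  classes <- Biostrings::IUPAC_CODE_MAP[strsplit(pattern, "")[[1L]]]
  rx <- paste0("^", paste0("[", classes, "]", collapse = ""), "$")
  grepl(rx, window)
}

# Fine-grid scan for the zero crossing of the charge curve.
gridPi <- function(seq, step = 5e-5) {
  grid <- seq(0, 14, by = step)
  ch <- Orfeome::proteinCharge(seq, grid)
  i <- which(ch <= 0)[1L]
  (grid[i - 1L] + grid[i]) / 2
}

randomProtein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n, TRUE),
        collapse = "")
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")
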