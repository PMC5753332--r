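## Brute-force oracles, independent of the package's computation paths:
## exhaustive enumeration over haplotype pairs, explicit gamete counting,
## and a genetic-code table from seqinr.

## mean pairwise Hamming distance over all C(n,2) haplotype pairs
oracle_pi_total <- function(H) {
  n <- nrow(H)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(H[i, ] != H[j, ])
  tot / choose(n, 2)
}

oracle_S <- function(H) {
  cnt <- colSums(H)
  sum(cnt > 0 & cnt < nrow(H))
}

oracle_theta_w <- function(H) {
  oracle_S(H) / sum(1 / seq_len(nrow(H) - 1))
}

oracle_hap_diversity <- function(H) {
  n <- nrow(H)
  f <- table(apply(H, 1, paste, collapse = "|")) / n
  (n / (n - 1)) * (1 - sum(f^2))
}

## r2 by explicit 2x2 gamete counting
oracle_r2 <- function(x, y) {
  n <- length(x)
  f11 <- sum(x == 1 & y == 1) / n
  p1 <- sum(x) / n; p2 <- sum(y) / n
  D <- f11 - p1 * p2
  D^2 / (p1 * (1 - p1) * p2 * (1 - p2))
}

## ZnS by materializing the full pair list
oracle_zns <- function(H) {
  S <- ncol(H)
  vals <- c()
  for (i in seq_len(S - 1)) for (j in (i + 1):S)
    vals <- c(vals, oracle_r2(H[, i], H[, j]))
  mean(vals)
}

oracle_za <- function(H) {
  S <- ncol(H)
  mean(vapply(seq_len(S - 1), function(i) oracle_r2(H[, i], H[, i + 1]), 0))
}

## Wall's B and Q by enumerating two-site haplotypes
oracle_wall_bq <- function(H) {
  S <- ncol(H)
  congruent <- logical(S - 1)
  part <- character(S - 1)
  for (i in seq_len(S - 1)) {
    two <- unique(apply(H[, c(i, i + 1)], 1, paste, collapse = ""))
    congruent[i] <- length(two) == 2
    if (congruent[i]) {
      x <- H[, i]
      if (x[1] == 1) x <- 1 - x
      part[i] <- paste(x, collapse = "")
    }
  }
  list(b = sum(congruent) / (S - 1),
       q = (sum(congruent) + length(unique(part[congruent]))) / S)
}

## degeneracy by exhaustive substitution through seqinr's translator
oracle_degeneracy <- function(codon, position) {
  cb <- strsplit(toupper(codon), "")[[1]]
  if (!all(cb %in% c("A", "C", "G", "T"))) return("excluded")
  aa <- seqinr::translate(cb)
  syn <- 0
  for (b in setdiff(c("A", "C", "G", "T"), cb[position + 1])) {
    alt <- cb; alt[position + 1] <- b
    if (seqinr::translate(alt) == aa) syn <- syn + 1
  }
  if (syn == 3) "fourfold" else if (syn == 0) "zerofold" else "other"
}
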