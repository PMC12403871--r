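# Independent scorer for a complete secondary structure: walks the loop
# decomposition of an explicit pair table and sums the energy terms
# directly from the parameter tables. A third route, separate from both
# the dynamic program and the enumeration search.
score_structure <- function(seq, pairs, temperature = 30) {
  b <- match(strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]],
             c("A", "C", "G", "U"))
  n <- length(b)
  tabs <- fold_energy_tables(temperature, max_len = max(n, 60))
  pt <- function(i, j) {
    key <- paste0(c("A", "C", "G", "U")[b[i]], c("A", "C", "G", "U")[b[j]])
    match(key, c("AU", "UA", "CG", "GC", "GU", "UG"))
  }
  E <- 0
  for (i in seq_len(n)) {
    j <- pairs[i]
    if (j <= i) next
    kids <- list(); k <- i + 1
    while (k < j) {
      if (pairs[k] > k) {
        kids[[length(kids) + 1]] <- c(k, pairs[k]); k <- pairs[k] + 1
      } else k <- k + 1
    }
    nc <- length(kids)
    if (nc == 0) {
      E <- E + tabs$hairpin[j - i]
    } else if (nc == 1) {
      kk <- kids[[1]]; l1 <- kk[1] - i - 1; l2 <- j - kk[2] - 1
      E <- E + if (l1 == 0 && l2 == 0) {
        tabs$stack[pt(i, j), pt(kk[1], kk[2])]
      } else if (l1 == 0 || l2 == 0) {
        tabs$bulge[l1 + l2 + 1]
      } else {
        tabs$internal[l1 + 1, l2 + 1]
      }
    } else {
      unp <- (j - i - 1) - sum(vapply(kids, function(kk) kk[2] - kk[1] + 1, 0))
      E <- E + tabs$ml_a + tabs$ml_b * (nc + 1) + tabs$ml_c * unp
    }
  }
  E
}
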