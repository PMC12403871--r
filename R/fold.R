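# Minimum-free-energy folding of short RNA windows.
#
# The folder scores nested secondary structures (no pseudoknots) with a
# nearest-neighbor model: stacking free energies for adjacent base pairs plus
# additive penalties for hairpin, bulge, internal and multibranch loops.
# Watson-Crick and G:U wobble pairs are allowed; the minimum hairpin loop is
# 3 nt. There are no dangling-end, helix-end or coaxial-stacking terms, and
# helices do not stack across bulges; the model is deliberately small enough
# that an exhaustive structure enumeration (fold_enumerate) can verify it
# exactly. Temperature enters through the parameter table: stack free
# energies are recomputed from embedded enthalpies at the requested
# temperature and loop penalties are treated as purely entropic.

.fold_env <- new.env(parent = emptyenv())

# base encoding A=1 C=2 G=3 U=4; pair types 1:AU 2:UA 3:CG 4:GC 5:GU 6:UG
.PAIR_TYPE <- local({
  m <- matrix(0L, 4, 4)
  m[1, 4] <- 1L; m[4, 1] <- 2L
  m[2, 3] <- 3L; m[3, 2] <- 4L
  m[3, 4] <- 5L; m[4, 3] <- 6L
  m
})

# 5' base of each pair type (A,U,C,G,G,U)
.PAIR_BASE5 <- c(1L, 4L, 2L, 3L, 3L, 4L)

#' Energy parameter tables for the hairpin folder
#'
#' Builds the stacking and loop tables used by [fold_window()] and
#' [fold_enumerate()] at a given temperature. Watson-Crick stack free
#' energies and enthalpies are an embedded nearest-neighbor set (37 degrees C
#' reference); wobble-containing stacks use a simplified class-based
#' parameterization. Loop penalties (all non-negative) are scaled as purely
#' entropic terms.
#'
#' @param temperature folding temperature in degrees Celsius.
#' @param max_len largest window length the tables must cover (nt).
#' @return list with elements `stack` (6x6 pair-type matrix, kcal/mol),
#'   `hairpin`, `bulge` (penalty by loop size, index = size + 1),
#'   `internal` (matrix indexed by side lengths + 1), `ml_a`, `ml_b`,
#'   `ml_c` (multiloop closing/branch/unpaired terms), `stack_min`, and
#'   `min_loop`.
#' @export
fold_energy_tables <- function(temperature = 30, max_len = 120) {
  key <- sprintf("T%.4f_L%d", temperature, max_len)
  cached <- .fold_env[[key]]
  if (!is.null(cached)) return(cached)

  tK <- 273.15 + temperature
  tf <- tK / 310.15

  # WC nearest-neighbor steps, rows = 5' base of outer pair, cols = 5' base
  # of inner pair (A, C, G, U).
  dg37 <- matrix(c(
    -0.93, -2.24, -2.08, -1.10,
    -2.11, -3.26, -2.36, -2.08,
    -2.35, -3.42, -3.26, -2.24,
    -1.33, -2.35, -2.11, -0.93), 4, 4, byrow = TRUE)
  dh <- matrix(c(
    -6.82, -11.40, -10.48, -9.38,
    -10.44, -13.39, -10.64, -10.48,
    -12.44, -14.88, -13.39, -11.40,
    -7.69, -12.44, -10.44, -6.82), 4, 4, byrow = TRUE)

  sg37 <- matrix(NA_real_, 6, 6)
  sh <- matrix(NA_real_, 6, 6)
  wob <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  strong <- c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  for (p in 1:6) for (q in 1:6) {
    if (!wob[p] && !wob[q]) {
      sg37[p, q] <- dg37[.PAIR_BASE5[p], .PAIR_BASE5[q]]
      sh[p, q] <- dh[.PAIR_BASE5[p], .PAIR_BASE5[q]]
    } else if (wob[p] && wob[q]) {
      sg37[p, q] <- -0.4
      sh[p, q] <- -1.2
    } else {
      other_strong <- if (wob[p]) strong[q] else strong[p]
      sg37[p, q] <- if (other_strong) -1.4 else -0.8
      sh[p, q] <- 3 * sg37[p, q]
    }
  }
  stack <- sh - tf * (sh - sg37)

  sizes <- 0:max_len
  hair37 <- rep(Inf, max_len + 1)
  base_h <- c(5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4)
  for (L in 3:max_len) {
    hair37[L + 1] <- if (L <= 9) base_h[L - 2] else 6.4 + 1.08 * log(L / 9)
  }
  bulge37 <- rep(Inf, max_len + 1)
  base_b <- c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4)
  for (L in 1:max_len) {
    bulge37[L + 1] <- if (L <= 6) base_b[L] else 4.4 + 1.08 * log(L / 6)
  }
  int_base <- rep(Inf, max_len + 1)
  base_i <- c(1.2, 1.9, 2.2, 2.5, 2.9)
  for (L in 2:max_len) {
    int_base[L + 1] <- if (L <= 6) base_i[L - 1] else 2.9 + 1.08 * log(L / 6)
  }
  side_max <- max_len
  internal <- matrix(Inf, side_max + 1, side_max + 1)
  for (l1 in 1:side_max) for (l2 in 1:side_max) {
    tot <- l1 + l2
    if (tot <= max_len) {
      internal[l1 + 1, l2 + 1] <- int_base[tot + 1] + min(3.0, 0.5 * abs(l1 - l2))
    }
  }

  tabs <- list(
    stack = stack,
    hairpin = hair37 * tf,
    bulge = bulge37 * tf,
    internal = internal * tf,
    ml_a = 3.4 * tf,
    ml_b = 0.4 * tf,
    ml_c = 0.0,
    stack_min = min(stack),
    min_loop = 3L,
    temperature = temperature
  )
  .fold_env[[key]] <- tabs
  tabs
}

.encode_rna <- function(seq) {
  s <- chartr("Tt", "Uu", toupper(seq))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  code <- match(chars, c("A", "C", "G", "U"))
  if (anyNA(code)) {
    bad <- unique(chars[is.na(code)])
    stop("illegal characters in fold input: ", paste(bad, collapse = ", "))
  }
  code
}

#' Fold a short sequence to its minimum-free-energy structure
#'
#' Zuker-style dynamic program over nested structures under the package's
#' nearest-neighbor energy model (see [fold_energy_tables()]). Intended for
#' the 40-nt windows upstream of transcript 3'-end positions; any length up
#' to `max_len` of the tables is accepted (windows truncated at contig edges
#' are flagged via the `truncated` field by the caller).
#'
#' @param seq character scalar over A/C/G/T/U (T and U are equivalent).
#' @param temperature folding temperature in degrees Celsius (default 30).
#' @return object of class `fold_result`: list with `delta_g` (kcal/mol,
#'   <= 0; 0 means no stabilizing structure), `structure` (dot-bracket,
#'   same length as input), and `hairpin3` (metrics of the 3'-most hairpin:
#'   `stem_length` bp of the continuous helix closing its loop,
#'   `loop_length` nt, `stem_close_pos` 1-based index of the 3'-most paired
#'   base of that helix), or NULL when the structure has no pairs.
#' @examples
#' fold_window(strrep("A", 40))$delta_g # 0
#' fold_window("GGGCGCAAAGCGCCC")$structure
#' @export
fold_window <- function(seq, temperature = 30) {
  stopifnot(is.character(seq), length(seq) == 1L)
  b <- .encode_rna(seq)
  n <- length(b)
  if (n == 0L) stop("empty sequence")
  tabs <- fold_energy_tables(temperature, max_len = max(n, 60L))
  ml <- tabs$min_loop
  if (n < ml + 2L) {
    return(.fold_result(0, strrep(".", n)))
  }

  ptm <- matrix(0L, n, n)
  for (i in seq_len(n - ml - 1L)) {
    js <- (i + ml + 1L):n
    ptm[i, js] <- .PAIR_TYPE[cbind(b[i], b[js])]
  }
  pair_idx <- which(ptm > 0L, arr.ind = TRUE)
  if (nrow(pair_idx) == 0L) {
    return(.fold_result(0, strrep(".", n)))
  }
  PK <- pair_idx[, 1L]
  PL <- pair_idx[, 2L]

  V <- matrix(Inf, n, n)
  WM <- matrix(Inf, n, n)
  WM2 <- matrix(Inf, n, n)
  SG <- tabs$stack
  HP <- tabs$hairpin
  BG <- tabs$bulge
  IL <- tabs$internal
  ml_a <- tabs$ml_a; ml_b <- tabs$ml_b

  for (d in 1:(n - 1L)) {
    for (i in 1:(n - d)) {
      j <- i + d
      p <- ptm[i, j]
      if (p > 0L && d > ml) {
        e <- HP[d]  # hairpin size = d - 1, index size + 1 = d
        sel <- PK > i & PL < j
        if (any(sel)) {
          K <- PK[sel]; L <- PL[sel]
          v <- V[cbind(K, L)]
          ok <- is.finite(v)
          if (any(ok)) {
            K <- K[ok]; L <- L[ok]; v <- v[ok]
            l1 <- K - i - 1L
            l2 <- j - L - 1L
            cost <- numeric(length(K))
            st <- l1 == 0L & l2 == 0L
            bu <- xor(l1 == 0L, l2 == 0L)
            io <- !st & !bu
            if (any(st)) cost[st] <- SG[cbind(p, ptm[cbind(K[st], L[st])])]
            if (any(bu)) cost[bu] <- BG[l1[bu] + l2[bu] + 1L]
            if (any(io)) cost[io] <- IL[cbind(l1[io] + 1L, l2[io] + 1L)]
            e <- min(e, min(v + cost))
          }
        }
        if (d >= 2L && is.finite(WM2[i + 1L, j - 1L])) {
          e <- min(e, ml_a + ml_b + WM2[i + 1L, j - 1L])
        }
        V[i, j] <- e
      }
      # multiloop accumulators: WM = >= 1 branch over [i, j] (unpaired
      # positions free, ml_c = 0), WM2 = >= 2 branches. A branch may start
      # anywhere in [i, j]: the first branch of a collection carries only
      # unpaired positions on its left.
      wm2 <- if (j - 1L >= i) WM2[i, j - 1L] else Inf
      ks <- if (j - 1L >= i + 1L) (i + 1L):j else integer(0)
      if (length(ks)) {
        vk <- V[cbind(ks, j)]
        wk <- WM[cbind(i, ks - 1L)]
        cand <- wk + vk + ml_b
        cand <- cand[is.finite(cand)]
        if (length(cand)) wm2 <- min(wm2, min(cand))
      }
      wm <- if (j - 1L >= i) WM[i, j - 1L] else Inf
      vsingle <- V[cbind(i:j, j)]
      vsingle <- vsingle[is.finite(vsingle)]
      if (length(vsingle)) wm <- min(wm, min(vsingle) + ml_b)
      WM2[i, j] <- wm2
      WM[i, j] <- min(wm, wm2)
    }
  }

  W <- c(0, rep(0, n))  # W[j + 1] = best energy over prefix 1..j
  for (j in 1:n) {
    best <- W[j]  # j unpaired
    ks <- 1:j
    v <- V[cbind(ks, j)]
    ok <- is.finite(v)
    if (any(ok)) best <- min(best, min(W[ks[ok]] + v[ok]))
    W[j + 1L] <- best
  }
  dg <- min(0, W[n + 1L])

  pairs <- integer(n)
  if (dg < 0) {
    eps <- 1e-9
    tb_V <- function(i, j) {
      pairs[i] <<- j; pairs[j] <<- i
      e <- V[i, j]
      if (abs(e - HP[j - i]) < eps) return(invisible())
      sel <- which(PK > i & PL < j)
      for (m in sel) {
        k <- PK[m]; l <- PL[m]
        v <- V[k, l]
        if (!is.finite(v)) next
        l1 <- k - i - 1L; l2 <- j - l - 1L
        cost <- if (l1 == 0L && l2 == 0L) SG[ptm[i, j], ptm[k, l]]
          else if (l1 == 0L || l2 == 0L) BG[l1 + l2 + 1L]
          else IL[l1 + 1L, l2 + 1L]
        if (abs(e - (v + cost)) < eps) { tb_V(k, l); return(invisible()) }
      }
      tb_WM2(i + 1L, j - 1L)
    }
    tb_WM2 <- function(i, j) {
      e <- WM2[i, j]
      if (j - 1L >= i && abs(e - WM2[i, j - 1L]) < eps) { tb_WM2(i, j - 1L); return(invisible()) }
      for (k in (i + 1L):j) {
        if (is.finite(V[k, j]) && is.finite(WM[i, k - 1L]) &&
            abs(e - (WM[i, k - 1L] + V[k, j] + ml_b)) < eps) {
          tb_WM(i, k - 1L); tb_V(k, j); return(invisible())
        }
      }
      stop("fold traceback failed (WM2)")
    }
    tb_WM <- function(i, j) {
      e <- WM[i, j]
      for (k in i:j) {
        if (is.finite(V[k, j]) && abs(e - (V[k, j] + ml_b)) < eps) {
          tb_V(k, j); return(invisible())
        }
      }
      if (j - 1L >= i && abs(e - WM[i, j - 1L]) < eps) { tb_WM(i, j - 1L); return(invisible()) }
      if (abs(e - WM2[i, j]) < eps) { tb_WM2(i, j); return(invisible()) }
      stop("fold traceback failed (WM)")
    }
    j <- n
    while (j >= 1L) {
      if (abs(W[j + 1L] - W[j]) < eps) { j <- j - 1L; next }
      hit <- FALSE
      for (k in 1:j) {
        if (is.finite(V[k, j]) && abs(W[j + 1L] - (W[k] + V[k, j])) < eps) {
          tb_V(k, j); j <- k - 1L; hit <- TRUE; break
        }
      }
      if (!hit) stop("fold traceback failed (external)")
    }
  }

  db <- rep(".", n)
  db[pairs > seq_len(n)] <- "("
  db[pairs != 0L & pairs < seq_len(n)] <- ")"
  .fold_result(dg, paste(db, collapse = ""))
}

.fold_result <- function(dg, structure) {
  structure(list(delta_g = dg, structure = structure,
                 hairpin3 = hairpin3_metrics(structure)),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("fold_result: dG = %.2f kcal/mol\n%s\n", x$delta_g, x$structure))
  if (!is.null(x$hairpin3)) {
    cat(sprintf("3'-most hairpin: stem %d bp, loop %d nt, closes at %d\n",
                x$hairpin3$stem_length, x$hairpin3$loop_length,
                x$hairpin3$stem_close_pos))
  }
  invisible(x)
}

#' Base-pair table of a dot-bracket string
#'
#' @param structure dot-bracket string.
#' @return integer vector; entry i is the partner of position i (0 = unpaired).
#' @export
db_pairs <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  n <- length(ch)
  pairs <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j; pairs[j] <- i
    } else if (ch[i] != ".") stop("illegal dot-bracket character: ", ch[i])
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  pairs
}

#' Metrics of the 3'-most hairpin of a structure
#'
#' Identifies the hairpin loop with the 3'-most closing pair, then measures
#' the continuous helix closing that loop (stacked pairs with no intervening
#' bulge) and the position of its 3'-most paired base. This anchor is where
#' the U-tract of an intrinsic terminator is counted from.
#'
#' @param structure dot-bracket string.
#' @return list(`stem_length`, `loop_length`, `stem_close_pos`) or NULL when
#'   the structure contains no hairpin (i.e. no pairs).
#' @export
hairpin3_metrics <- function(structure) {
  pairs <- db_pairs(structure)
  n <- length(pairs)
  # hairpin loops: pairs (i,j) with no paired position strictly inside
  hp <- NULL
  for (i in seq_len(n)) {
    j <- pairs[i]
    if (j > i) {
      inside <- if (j - i >= 2L) pairs[(i + 1L):(j - 1L)] else integer(0)
      if (all(inside == 0L)) hp <- rbind(hp, c(i, j))
    }
  }
  if (is.null(hp)) return(NULL)
  sel <- which.max(hp[, 1L])  # 3'-most hairpin loop
  i <- hp[sel, 1L]; j <- hp[sel, 2L]
  stem <- 1L
  while (i - 1L >= 1L && j + 1L <= n && pairs[i - 1L] == j + 1L) {
    i <- i - 1L; j <- j + 1L; stem <- stem + 1L
  }
  list(stem_length = stem,
       loop_length = hp[sel, 2L] - hp[sel, 1L] - 1L,
       stem_close_pos = j)
}

#' Exhaustive-enumeration reference folder
#'
#' Depth-first enumeration of every nested structure of the input under the
#' same energy tables as [fold_window()], with sound branch-and-bound
#' pruning (branches are discarded only when a lower bound on any completion
#' already exceeds the best energy found). The returned minimum is therefore
#' exact; this routine is the independent cross-check for the dynamic
#' program and is practical for sequences up to ~40 nt.
#'
#' @inheritParams fold_window
#' @param prune apply branch-and-bound pruning (FALSE walks every structure
#'   unconditionally; only practical below ~28 nt, used to verify that
#'   pruning never changes the minimum).
#' @return list(`delta_g`, `structure` (dot-bracket of the best structure
#'   found)).
#' @export
fold_enumerate <- function(seq, temperature = 30, prune = TRUE) {
  b <- .encode_rna(seq)
  n <- length(b)
  if (n == 0L) stop("empty sequence")
  tabs <- fold_energy_tables(temperature, max_len = max(n, 60L))
  res <- enum_mfe_cpp(b, tabs$stack, tabs$hairpin, tabs$bulge, tabs$internal,
                      tabs$ml_a, tabs$ml_b, tabs$ml_c, tabs$min_loop,
                      isTRUE(prune))
  pairs <- res$pairs + 1L
  pairs[pairs == 0L] <- 0L  # -1 -> 0 (unpaired)
  db <- rep(".", n)
  db[pairs > seq_len(n)] <- "("
  db[pairs != 0L & pairs < seq_len(n)] <- ")"
  list(delta_g = min(0, res$dg),
       structure = if (res$dg < 0) paste(db, collapse = "") else
         strrep(".", n))
}
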