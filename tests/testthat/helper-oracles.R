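# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive (pixel loops, exhaustive enumeration) and share
# no code with the package internals.

# binary dilation with a structuring-element matrix; out-of-bounds pixels are
# background (cannot activate anything)
naive_dilate <- function(mask, se) {
  nr <- nrow(mask); nc <- ncol(mask)
  kr <- (nrow(se) - 1L) / 2L; kc <- (ncol(se) - 1L) / 2L
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    hit <- FALSE
    for (a in -kr:kr) for (b in -kc:kc) {
      if (se[a + kr + 1L, b + kc + 1L] == 0) next
      ii <- i + a; jj <- j + b
      if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc && mask[ii, jj] > 0) {
        hit <- TRUE; break
      }
    }
    if (hit) out[i, j] <- 1L
  }
  out
}

# binary erosion; out-of-bounds pixels count as foreground (border padding
# convention matching the package's closing)
naive_erode <- function(mask, se) {
  nr <- nrow(mask); nc <- ncol(mask)
  kr <- (nrow(se) - 1L) / 2L; kc <- (ncol(se) - 1L) / 2L
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    all_fg <- TRUE
    for (a in -kr:kr) for (b in -kc:kc) {
      if (se[a + kr + 1L, b + kc + 1L] == 0) next
      ii <- i + a; jj <- j + b
      if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc && mask[ii, jj] == 0) {
        all_fg <- FALSE; break
      }
    }
    if (all_fg) out[i, j] <- 1L
  }
  out
}

naive_close <- function(mask, se) naive_erode(naive_dilate(mask, se), se)

# 8-connected labeling by flood fill
naive_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (mask[i0, j0] == 0 || lab[i0, j0] > 0) next
    cur <- cur + 1L
    queue <- list(c(i0, j0)); lab[i0, j0] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (a in -1:1) for (b in -1:1) {
        ii <- p[1] + a; jj <- p[2] + b
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc &&
            mask[ii, jj] > 0 && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# partition equality of two labelings, ignoring label numbering
same_partition <- function(lab1, lab2) {
  if (!identical(lab1 > 0, lab2 > 0)) return(FALSE)
  fg <- which(lab1 > 0)
  if (!length(fg)) return(TRUE)
  key1 <- lab1[fg]; key2 <- lab2[fg]
  length(unique(key1)) == length(unique(key2)) &&
    !anyDuplicated(unique(cbind(key1, key2))[, 1]) &&
    !anyDuplicated(unique(cbind(key1, key2))[, 2])
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# brute-force break-apart FISH oracle: enumerate every maximal red-green
# matching, take the one whose ascending-sorted distance vector is
# lexicographically smallest, then count fused/split copies and call.
oracle_fish <- function(red, green, fusion_distance) {
  nr <- nrow(red); ng <- nrow(green)
  k <- min(nr, ng)
  lex_less <- function(a, b) {
    nz <- which(a != b)
    length(nz) > 0 && a[nz[1]] < b[nz[1]]
  }
  best <- NULL
  if (k > 0L) {
    subsets_r <- utils::combn(seq_len(nr), k, simplify = FALSE)
    subsets_g <- utils::combn(seq_len(ng), k, simplify = FALSE)
    for (sr in subsets_r) for (sg in subsets_g)
      for (pg in all_permutations(sg)) {
        d <- sort(sqrt((red[sr, 1] - green[pg, 1])^2 +
                       (red[sr, 2] - green[pg, 2])^2))
        if (is.null(best) || lex_less(d, best)) best <- d
      }
  } else best <- numeric(0)
  n_fused <- sum(best <= fusion_distance)
  n_split <- sum(best > fusion_distance) + (nr - k) + (ng - k)
  copies <- n_fused + n_split
  call <- if (copies <= 1L) "UNINTERPRETABLE"
    else if (n_split >= 1L) {
      if (copies >= 3L) "POSITIVE_POLYSOMY" else "POSITIVE"
    } else if (copies >= 3L) "NEGATIVE_POLYSOMY" else "NEGATIVE"
  list(call = call, n_fused = n_fused, n_split = n_split)
}

# compact mixed fixture shared by gating and acceptance tests
mixed_fixture_spec <- function(seed = 7L) {
  synthetic_spec(n_cells = 4L, n_debris = 3L, n_small_cells = 3L,
                 frame_shape = c(256L, 376L), seed = seed)
}
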