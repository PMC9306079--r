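# Independent dynamic-programming oracle for the read screen: affine-gap
# semi-global alignment (query end-to-end, subject local) with the same
# scoring as the package aligner (match 2, mismatch -3, gap open 5,
# gap extend 2; a gap of length L costs open + L * extend). Returns the
# optimal score and the identity (matches / alignment columns) of the
# traced-back alignment. Pure R, O(n*m); intended for sequences <= 200 nt.
dp_align <- function(query, subject, match = 2, mismatch = -3,
                     open = 5, ext = 2) {
  q <- strsplit(toupper(query), "")[[1]]
  s <- strsplit(toupper(subject), "")[[1]]
  n <- length(q)
  m <- length(s)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # last column aligned q[i] to s[j]
  X <- matrix(NEG, n + 1, m + 1)   # last column gap in subject
  Y <- matrix(NEG, n + 1, m + 1)   # last column gap in query
  ptrM <- matrix(0L, n + 1, m + 1) # 1 from M, 2 from X, 3 from Y, 4 start
  ptrX <- matrix(0L, n + 1, m + 1)
  ptrY <- matrix(0L, n + 1, m + 1)
  M[1, ] <- 0                      # free leading subject (local subject)
  ptrM[1, ] <- 4L
  for (i in 2:(n + 1)) {
    # query consumed against a gap (no subject yet consumed)
    fromM <- M[i - 1, 1] - (open + ext)
    fromX <- X[i - 1, 1] - ext
    X[i, 1] <- max(fromM, fromX)
    ptrX[i, 1] <- if (fromM >= fromX) 1L else 2L
    for (j in 2:(m + 1)) {
      sc <- if (q[i - 1] == s[j - 1]) match else mismatch
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(cand)
      M[i, j] <- cand[k] + sc
      ptrM[i, j] <- k
      candX <- c(M[i - 1, j] - (open + ext), X[i - 1, j] - ext)
      kx <- which.max(candX)
      X[i, j] <- candX[kx]
      ptrX[i, j] <- c(1L, 2L)[kx]
      candY <- c(M[i, j - 1] - (open + ext), Y[i, j - 1] - ext)
      ky <- which.max(candY)
      Y[i, j] <- candY[ky]
      ptrY[i, j] <- c(1L, 3L)[ky]
    }
  }
  # free trailing subject: end anywhere in j; query must be exhausted
  finals <- pmax(M[n + 1, ], X[n + 1, ])
  j <- which.max(finals)
  state <- if (M[n + 1, j] >= X[n + 1, j]) 1L else 2L
  score <- finals[j]
  # traceback, counting match and total columns
  i <- n + 1
  matches <- 0L
  cols <- 0L
  while (i > 1 || (state == 1L && ptrM[i, j] != 4L)) {
    if (state == 1L) {
      prev <- ptrM[i, j]
      if (prev == 4L) break
      cols <- cols + 1L
      if (q[i - 1] == s[j - 1]) matches <- matches + 1L
      i <- i - 1
      j <- j - 1
      state <- prev
    } else if (state == 2L) {
      prev <- ptrX[i, j]
      cols <- cols + 1L
      i <- i - 1
      state <- prev
    } else {
      prev <- ptrY[i, j]
      cols <- cols + 1L
      j <- j - 1
      state <- prev
    }
    if (i == 1 && state != 1L && state != 2L) break
  }
  list(score = score, identity = matches / cols)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, n_subs) {
  s <- strsplit(seq, "")[[1]]
  pos <- sample(length(s), n_subs)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}
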