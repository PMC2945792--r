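# Independent oracles used across the suite.  Each reimplements the checked
# quantity from its definition, by a different decomposition than the
# package code.

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                              collapse = "")

.o_pair_class <- function(a, b) {
  wc <- c(A = "U", U = "A", C = "G", G = "C")
  if (wc[[a]] == b) return("WC")
  if ((a == "G" && b == "U") || (a == "U" && b == "G")) return("GU")
  "MISMATCH"
}

# Exhaustive optimal gapped local alignment by forward recursion over
# (query index, subject index, previous column type), maximizing over all
# alignments that start and end with a pair.  Affine gaps: first gap of a
# run costs gap_open, later ones gap_extend.
oracle_local_align <- function(query, subject, seed_flags, params) {
  qb <- strsplit(query, "")[[1]]
  sb <- strsplit(subject, "")[[1]]
  nq <- length(qb); ns <- length(sb)
  pscore <- function(i, j) {
    cls <- .o_pair_class(qb[i], sb[j])
    s <- switch(cls, WC = params$match_score, GU = params$wobble_score,
                params$mismatch_score)
    if (seed_flags[i]) s * params$seed_scale else s
  }
  # gap multipliers mirror the seed-weighting convention: a gap consuming a
  # seed query position, or a subject bulge flanked by one, is scaled too
  gx <- function(i) if (seed_flags[i]) params$seed_scale else 1
  gy <- function(i) {
    # bulge between query positions i-1 and i
    if ((i - 1 >= 1 && seed_flags[i - 1]) || (i <= nq && seed_flags[i]))
      params$seed_scale else 1
  }
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, last) {
    # best score obtainable by extending past (i-1, j-1); may stop ( = 0 )
    key <- paste(i, j, last)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    best <- 0
    if (i <= nq && j <= ns)
      best <- max(best, pscore(i, j) + rec(i + 1, j + 1, "M"))
    if (i <= nq)
      best <- max(best,
                  (if (last == "X") params$gap_extend else params$gap_open) *
                    gx(i) + rec(i + 1, j, "X"))
    if (j <= ns)
      best <- max(best,
                  (if (last == "Y") params$gap_extend else params$gap_open) *
                    gy(i) + rec(i, j + 1, "Y"))
    memo[[key]] <- best
    best
  }
  best <- 0
  for (i in seq_len(nq))
    for (j in seq_len(ns))
      best <- max(best, pscore(i, j) + rec(i + 1, j + 1, "M"))
  best
}

# seed flags and reversed-query construction matching the site search
oracle_query <- function(mirna_seq) {
  n <- nchar(mirna_seq)
  b <- strsplit(mirna_seq, "")[[1]]
  q <- rev(b)[3:(n - 1)]
  list(query = paste(q, collapse = ""),
       seed = (n - 1 - seq_len(n - 3)) %in% 2:8)
}

# Independent seed-class rule: explicit decision list over the glossary
# definitions, keyed on the multiset of states.
oracle_seed_class <- function(states27, state8, a1) {
  # states27: states at microRNA positions 2..7; state8 at position 8
  perfect6 <- all(states27 == "WC")
  if (!perfect6) return("non_canonical")
  if (state8 == "WC") {
    if (a1) "8mer" else "7mer_m8"
  } else {
    if (a1) "7mer_A1" else "6mer"
  }
}

# --- secondary-structure oracles --------------------------------------------

.o_weight <- function(a, b, model) {
  w <- 0
  if ((a == "G" && b == "C") || (a == "C" && b == "G"))
    w <- exp(-model$e_gc / model$kT)
  else if ((a == "A" && b == "U") || (a == "U" && b == "A"))
    w <- exp(-model$e_au / model$kT)
  else if ((a == "G" && b == "U") || (a == "U" && b == "G"))
    w <- exp(-model$e_gu / model$kT)
  w
}

# literal enumeration of every nested structure (list of pair matrices);
# exponential -- keep sequences short
enum_structures <- function(seq, model, max_span = Inf) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  gen <- function(i, j) {
    if (j - i < model$min_loop + 1) return(list(matrix(nrow = 0, ncol = 2)))
    out <- gen(i + 1, j)                       # i unpaired
    for (k in (i + model$min_loop + 1):j) {
      if (k - i > max_span) next
      if (.o_weight(b[i], b[k], model) == 0) next
      inner <- gen(i + 1, k - 1)
      outer <- if (k + 1 <= j) gen(k + 1, j) else
        list(matrix(nrow = 0, ncol = 2))
      for (s1 in inner) for (s2 in outer)
        out <- c(out, list(rbind(c(i, k), s1, s2)))
    }
    out
  }
  if (n < model$min_loop + 2) return(list(matrix(nrow = 0, ncol = 2)))
  gen(1, n)
}

struct_weight <- function(pairs, b, model) {
  if (!nrow(pairs)) return(1)
  prod(apply(pairs, 1, function(p) .o_weight(b[p[1]], b[p[2]], model)))
}

# exhaustive Boltzmann sums by memoized recursion decomposed on the pairing
# of the LAST position of each interval (the package kernel decomposes on
# the first); optional blocked positions are excluded from pairing
oracle_partition <- function(seq, model, blocked = integer(0),
                             max_span = Inf) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  blk <- logical(n); blk[blocked] <- TRUE
  memo <- new.env(hash = TRUE)
  Z <- function(i, j) {
    if (j - i < model$min_loop + 1) return(1)
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    tot <- Z(i, j - 1)                         # j unpaired
    if (!blk[j]) {
      for (k in i:(j - model$min_loop - 1)) {
        if (blk[k] || j - k > max_span) next
        w <- .o_weight(b[k], b[j], model)
        if (w == 0) next
        left <- if (k - 1 >= i) Z(i, k - 1) else 1
        mid <- if (k + 1 <= j - 1) Z(k + 1, j - 1) else 1
        tot <- tot + w * left * mid
      }
    }
    memo[[key]] <- tot
    tot
  }
  Z(1, n)
}

oracle_unpaired_prob <- function(seq, u, model, max_span = Inf) {
  n <- nchar(seq)
  Zfull <- oracle_partition(seq, model, max_span = max_span)
  vapply(seq_len(n - u + 1), function(i) {
    oracle_partition(seq, model, blocked = i:(i + u - 1),
                     max_span = max_span) / Zfull
  }, numeric(1))
}
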