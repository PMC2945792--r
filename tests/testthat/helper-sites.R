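# construct a target_site object directly (for feature-level tests)
make_site <- function(mirna_seq, utr_start, utr_end,
                      states = NULL, utr_pair = NULL, a1 = FALSE,
                      mirna_id = "mir", gene_id = "g1") {
  n <- nchar(mirna_seq)
  if (is.null(states)) {
    states <- rep("WC", n)
    states[c(1, n - 1, n)] <- "EXCLUDED"
  }
  names(states) <- paste0("p", seq_len(n))
  if (is.null(utr_pair)) {
    # ungapped: position 2 opposite utr_end - 1, position n-2 opposite utr_start
    utr_pair <- rep(NA_integer_, n)
    utr_pair[2:(n - 2)] <- utr_end - 1 - (0:(n - 4))
  }
  s <- list(mirna_id = mirna_id, gene_id = gene_id, mirna_seq = mirna_seq,
            utr_start = as.integer(utr_start), utr_end = as.integer(utr_end),
            score = 0, pair_states = states, utr_pair = utr_pair,
            a1_anchor = a1)
  s$seed_class <- classify_seed(structure(s, class = "duplex_alignment"))
  s$seed_violations <- seed_violations(s$pair_states)
  structure(s, class = c("target_site", "duplex_alignment"))
}

# reverse complement on the RNA alphabet (independent of package internals)
rc_rna <- function(x) paste(rev(strsplit(chartr("ACGU", "UGCA", x), "")[[1]]),
                            collapse = "")

# the perfectly complementary window for a microRNA's aligned region
perfect_window <- function(mirna_seq) {
  n <- nchar(mirna_seq)
  rc_rna(substr(mirna_seq, 2, n - 2))
}
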