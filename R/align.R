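#' Alignment parameters for seed-weighted target-site search
#'
#' Bundles the scoring scheme of the seed-weighted local alignment used to
#' detect candidate microRNA target sites in 3' UTRs.  Defaults follow the
#' classic miRanda-style search: score cutoff 120, affine gap penalties
#' -9 (open) and -4 (extend), pair scores +5 (Watson-Crick), +1 (G:U),
#' -3 (mismatch), and a 4-fold weight on pair scores at microRNA seed
#' positions 2-8 so that alignments strongly favour 5' pairing.
#'
#' @param score_cutoff minimum alignment score for a reported site.
#' @param gap_open,gap_extend affine gap penalties (negative); a gap run of
#'   length k costs \code{gap_open + (k - 1) * gap_extend}.
#' @param match_score,wobble_score,mismatch_score pair scores for
#'   Watson-Crick, G:U wobble and mismatched opposite bases.
#' @param seed_scale multiplier applied to pair scores at microRNA positions
#'   2-8 (must be >= 1).
#' @param seed_rule \code{"canonical_only"} keeps only sites with a perfect
#'   Watson-Crick 6-mer match at microRNA positions 2-7;
#'   \code{"all_sites"} additionally keeps sites with exactly one G:U wobble
#'   or mismatch (but no gap) in the seed region.
#' @return an object of class \code{"alignment_params"}.
#' @export
alignment_params <- function(score_cutoff = 120, gap_open = -9, gap_extend = -4,
                             match_score = 5, wobble_score = 1,
                             mismatch_score = -3, seed_scale = 4,
                             seed_rule = c("canonical_only", "all_sites")) {
  seed_rule <- match.arg(seed_rule)
  stopifnot(score_cutoff > 0, gap_open < 0, gap_extend < 0, seed_scale >= 1)
  structure(list(score_cutoff = score_cutoff, gap_open = gap_open,
                 gap_extend = gap_extend, match_score = match_score,
                 wobble_score = wobble_score, mismatch_score = mismatch_score,
                 seed_scale = seed_scale, seed_rule = seed_rule),
            class = "alignment_params")
}

#' @export
print.alignment_params <- function(x, ...) {
  cat("Seed-weighted alignment parameters\n")
  cat(sprintf("  cutoff %g | gaps %g/%g | pair %g/%g/%g (WC/GU/MM) | seed x%g | rule %s\n",
              x$score_cutoff, x$gap_open, x$gap_extend, x$match_score,
              x$wobble_score, x$mismatch_score, x$seed_scale, x$seed_rule))
  invisible(x)
}

# --- sequence plumbing -------------------------------------------------------

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Uppercases and converts T to U; any other character is an error.
#'
#' @param x character scalar (DNA or RNA).
#' @return character scalar over A/C/G/U.
#' @export
normalize_rna <- function(x) {
  s <- chartr("t", "u", toupper(x))
  s <- chartr("T", "U", s)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), RNA_BASES)
  if (length(bad))
    stop("non-nucleotide characters in sequence: ", paste(bad, collapse = " "))
  s
}

.encode <- function(x) {
  match(strsplit(x, "")[[1]], RNA_BASES) - 1L
}

.rc <- function(x) {
  # reverse complement on the RNA alphabet
  paste(rev(strsplit(chartr("ACGU", "UGCA", x), "")[[1]]), collapse = "")
}

.as_mirna <- function(mirna, mirna_id) {
  if (is.list(mirna)) {
    if (missing(mirna_id) || is.null(mirna_id)) mirna_id <- mirna$id
    mirna <- mirna$sequence
  }
  seq <- normalize_rna(mirna)
  if (nchar(seq) < 9) stop("microRNA must be at least 9 nt (seed + position 9)")
  list(id = if (is.null(mirna_id)) "mirna" else mirna_id, seq = seq)
}

.state_labels <- c("WC", "GU", "MISMATCH", "GAP", "MISMATCH")

# --- duplex construction -----------------------------------------------------

.build_site <- function(hit, mir, utr_seq, gene_id, offset = 0L) {
  n <- nchar(mir$seq)
  m <- n - 3L                       # aligned region: positions 2 .. n-2
  states <- rep("EXCLUDED", n)
  utr_pair <- rep(NA_integer_, n)
  qstate <- hit$qstate              # query index q <-> miRNA position n-1-q
  qsub <- hit$qsub
  for (q in seq_len(m)) {
    pos <- n - 1L - q
    states[pos] <- .state_labels[qstate[q] + 1L]
    if (qsub[q] >= 0L) utr_pair[pos] <- qsub[q] + offset
  }
  utr_start <- hit$sub_start + offset
  utr_end <- hit$sub_end + offset
  a1 <- utr_end < nchar(utr_seq) &&
    substr(utr_seq, utr_end + 1L, utr_end + 1L) == "A"
  # UTR bulges between the partners of adjacent seed positions break the
  # contiguity of the seed duplex: count them per adjacent pair 2..8
  bulge <- function(p) {
    x <- utr_pair[p]; y <- utr_pair[p + 1L]
    !is.na(x) && !is.na(y) && (x - y != 1L)
  }
  bulges27 <- sum(vapply(2:6, bulge, logical(1)))
  bulge78 <- bulge(7L)
  duplex <- structure(list(
    mirna_id = mir$id, gene_id = gene_id, mirna_seq = mir$seq,
    utr_start = utr_start, utr_end = utr_end, score = hit$score,
    pair_states = stats::setNames(states, paste0("p", seq_len(n))),
    utr_pair = utr_pair, a1_anchor = a1,
    seed_bulges = bulges27, seed_bulge_m8 = bulge78),
    class = "duplex_alignment")
  structure(c(duplex, list(
    seed_class = classify_seed(duplex),
    seed_violations = seed_violations(duplex))),
    class = c("target_site", "duplex_alignment"))
}

#' Locally align a microRNA against a UTR window
#'
#' Computes all score-maximal, mutually non-overlapping local alignments
#' between the reverse of the microRNA (excluding its first 5' base and last
#' two 3' bases, which never enter the alignment) and the window, with pair
#' scores at microRNA positions 2-8 multiplied by \code{seed_scale}.
#' A:U and G:C pairs score \code{match_score}, G:U pairs
#' \code{wobble_score}, anything else \code{mismatch_score}.
#'
#' @param mirna microRNA sequence (character, 5'->3') or a
#'   \code{list(id=, sequence=)} record.
#' @param utr_window UTR sequence window (character, 5'->3'; DNA or RNA).
#' @param params an \code{\link{alignment_params}} object.
#' @param mirna_id,gene_id identifiers attached to the result.
#' @param min_score alignments below this score are not reported; defaults
#'   to \code{params$score_cutoff}.
#' @return list of \code{"target_site"} objects, each carrying 0-based
#'   half-open UTR coordinates of the footprint, the alignment score,
#'   per-microRNA-position pair states (positions 1, n-1, n are always
#'   \code{EXCLUDED}), and the A1 anchor flag (UTR base opposite microRNA
#'   position 1 is an A).
#' @export
align_duplex <- function(mirna, utr_window, params = alignment_params(),
                         mirna_id = NULL, gene_id = "utr",
                         min_score = params$score_cutoff) {
  mir <- .as_mirna(mirna, mirna_id)
  utr_seq <- normalize_rna(utr_window)
  if (nchar(utr_seq) < 6) stop("UTR window shorter than 6 nt")
  n <- nchar(mir$seq)
  query <- rev(.encode(mir$seq))[3:(n - 1L)]   # miRNA 3'->5', positions n-2..2
  seed_pos <- (n - 1L - seq_len(n - 3L)) %in% 2:8
  hits <- .sw_hits(query, .encode(utr_seq), seed_pos,
                   params$match_score, params$wobble_score,
                   params$mismatch_score, params$gap_open, params$gap_extend,
                   params$seed_scale, min_score,
                   max_hits = 2L + nchar(utr_seq) %/% 6L)
  lapply(hits, .build_site, mir = mir, utr_seq = utr_seq, gene_id = gene_id)
}

#' Scan a 3' UTR for candidate microRNA target sites
#'
#' Slides the seed-weighted local alignment over the UTR, keeps alignments
#' with score at or above the cutoff, and then applies the seed rule:
#' under \code{canonical_only} a site must have a perfect Watson-Crick match
#' at microRNA positions 2-7; under \code{all_sites} exactly one G:U wobble
#' or mismatch (never a gap) is tolerated in the seed.  Overlapping
#' candidates are resolved greedily by score (ties toward the 5' end), so
#' reported footprints never share a base.
#'
#' @inheritParams align_duplex
#' @param utr UTR sequence (character) or \code{list(id=, sequence=)}.
#' @return list of \code{"target_site"} objects in UTR coordinate order.
#' @export
scan_utr <- function(mirna, utr, params = alignment_params(),
                     mirna_id = NULL, gene_id = NULL) {
  if (is.list(utr)) {
    if (is.null(gene_id)) gene_id <- utr$id
    utr <- utr$sequence
  }
  if (is.null(gene_id)) gene_id <- "utr"
  if (!nchar(utr)) return(list())
  sites <- align_duplex(mirna, utr, params, mirna_id = mirna_id,
                        gene_id = gene_id)
  keep <- vapply(sites, function(s) {
    if (params$seed_rule == "canonical_only") s$seed_violations == 0L
    else s$seed_violations <= 1L && s$seed_bulges == 0L &&
      !any(s$pair_states[paste0("p", 2:7)] == "GAP")
  }, logical(1))
  sites <- sites[keep]
  sites[order(vapply(sites, `[[`, integer(1), "utr_start"))]
}

# --- seed classification -----------------------------------------------------

#' Classify the seed match of a predicted site
#'
#' Seed classes follow the standard canonical hierarchy: \code{8mer}
#' (Watson-Crick at microRNA positions 2-8 plus an A opposite position 1),
#' \code{7mer_m8} (Watson-Crick at 2-8, no A1), \code{7mer_A1}
#' (Watson-Crick at 2-7 plus A1, position 8 not Watson-Crick), \code{6mer}
#' (Watson-Crick at 2-7 only); anything else is \code{non_canonical}.
#'
#' @param site a \code{"target_site"}/\code{"duplex_alignment"} object, or a
#'   character vector of pair states named \code{p1..pn}.
#' @param a1_anchor used only when \code{site} is a raw state vector.
#' @return character scalar, one of
#'   \code{"8mer"}, \code{"7mer_m8"}, \code{"7mer_A1"}, \code{"6mer"},
#'   \code{"non_canonical"}.
#' @export
classify_seed <- function(site, a1_anchor = FALSE) {
  bulges27 <- 0L
  bulge78 <- FALSE
  if (is.list(site)) {
    states <- site$pair_states
    a1_anchor <- isTRUE(site$a1_anchor)
    bulges27 <- if (is.null(site$seed_bulges)) 0L else site$seed_bulges
    bulge78 <- isTRUE(site$seed_bulge_m8)
  } else states <- site
  wc27 <- all(states[paste0("p", 2:7)] == "WC") && bulges27 == 0L
  wc8 <- states["p8"] == "WC" && !bulge78
  if (wc27 && wc8 && a1_anchor) return("8mer")
  if (wc27 && wc8) return("7mer_m8")
  if (wc27 && a1_anchor) return("7mer_A1")
  if (wc27) return("6mer")
  "non_canonical"
}

#' Count seed violations (non-Watson-Crick states at microRNA positions 2-7)
#'
#' @param site a site object or named pair-state vector.
#' @return integer in 0..6.
#' @export
seed_violations <- function(site) {
  if (is.list(site)) {
    bul <- if (is.null(site$seed_bulges)) 0L else site$seed_bulges
    sum(site$pair_states[paste0("p", 2:7)] != "WC") + bul
  } else sum(site[paste0("p", 2:7)] != "WC")
}

#' @export
print.target_site <- function(x, ...) {
  cat(sprintf("target site %s :: %s [%d, %d) score %.1f  %s (%d seed violation%s)\n",
              x$mirna_id, x$gene_id, x$utr_start, x$utr_end, x$score,
              x$seed_class, x$seed_violations,
              if (x$seed_violations == 1) "" else "s"))
  invisible(x)
}

#' Summarize a list of target sites as a data frame
#'
#' @param sites list of \code{"target_site"} objects.
#' @return data.frame with one row per site (0-based half-open coordinates).
#' @export
sites_table <- function(sites) {
  if (!length(sites))
    return(data.frame(mirna_id = character(), gene_id = character(),
                      utr_start = integer(), utr_end = integer(),
                      score = numeric(), seed_class = character(),
                      seed_violations = integer(),
                      stringsAsFactors = FALSE))
  data.frame(
    mirna_id = vapply(sites, `[[`, character(1), "mirna_id"),
    gene_id = vapply(sites, `[[`, character(1), "gene_id"),
    utr_start = vapply(sites, `[[`, integer(1), "utr_start"),
    utr_end = vapply(sites, `[[`, integer(1), "utr_end"),
    score = vapply(sites, `[[`, numeric(1), "score"),
    seed_class = vapply(sites, `[[`, character(1), "seed_class"),
    seed_violations = vapply(sites, `[[`, integer(1), "seed_violations"),
    stringsAsFactors = FALSE)
}
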