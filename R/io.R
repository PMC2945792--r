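#' Read sequences from a FASTA file
#'
#' Record ids are the first whitespace-delimited token of the header.
#' Sequences are normalized to the uppercase RNA alphabet (T converted to
#' U).  Duplicate ids are an error unless \code{collapse_longest = TRUE},
#' in which case records sharing an id are collapsed to the longest
#' (the standard treatment of alternative UTR isoforms).
#'
#' @param path FASTA file.
#' @param collapse_longest collapse duplicate ids to the longest record.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, collapse_longest = FALSE) {
  recs <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(recs), "[ \t]"), `[[`, character(1), 1)
  seqs <- vapply(as.character(recs), normalize_rna, character(1),
                 USE.NAMES = FALSE)
  if (anyDuplicated(ids)) {
    if (!collapse_longest) {
      dup <- unique(ids[duplicated(ids)])
      stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
    }
    keep <- unlist(lapply(split(seq_along(ids), ids), function(i)
      i[which.max(nchar(seqs[i]))]))
    keep <- sort(keep)
    ids <- ids[keep]; seqs <- seqs[keep]
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a transfection expression table
#'
#' Tab-separated with a header; requires columns \code{gene_id},
#' \code{experiment_id}, \code{mirna_id}, \code{log_change} and either
#' \code{control_intensity} or \code{above_median}.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("gene_id", "experiment_id", "mirna_id", "log_change")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("expression table missing column(s): ", paste(miss, collapse = ", "))
  tab
}

#' Write an expression table
#'
#' @param tab data.frame as produced by \code{\link{generate_expression}}.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-UTR conservation track
#'
#' Accepts either a two-column table (1-based position, score) or a
#' fixed-step wiggle block (\code{fixedStep start=<s> step=1} followed by
#' one value per line).  Positions absent from the file are filled with 0
#' and flagged with a warning.
#'
#' @param path file path.
#' @param utr_length length of the UTR the track belongs to.
#' @return numeric vector of length \code{utr_length}, values in [0, 1].
#' @export
read_conservation <- function(path, utr_length) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  track <- rep(NA_real_, utr_length)
  fs <- grep("^fixedStep", lines)
  if (length(fs)) {
    i <- fs[1]
    m <- regmatches(lines[i], regexec("start=([0-9]+)", lines[i]))[[1]]
    start <- as.integer(m[2])
    vals <- as.numeric(lines[(i + 1):length(lines)])
    idx <- start + seq_along(vals) - 1L
    ok <- idx <= utr_length
    track[idx[ok]] <- vals[ok]
  } else {
    for (i in seq_along(lines)) {
      f <- strsplit(trimws(lines[i]), "[\t ]+")[[1]]
      v <- suppressWarnings(as.numeric(f))
      if (length(v) < 2 || anyNA(v[1:2])) {
        if (i == 1 && length(f) >= 2 && all(is.na(v[1:2]))) next  # header
        stop("malformed conservation row at line ", i, ": ", lines[i])
      }
      if (v[1] >= 1 && v[1] <= utr_length) track[v[1]] <- v[2]
    }
  }
  if (anyNA(track)) {
    warning(sum(is.na(track)), " position(s) missing from track; filled with 0",
            call. = FALSE)
    track[is.na(track)] <- 0
  }
  pmin(pmax(track, 0), 1)
}

#' Write a conservation track as a two-column table
#'
#' @param track numeric vector of per-base values.
#' @param path output TSV (1-based positions).
#' @return \code{path}, invisibly.
#' @export
write_conservation <- function(track, path) {
  utils::write.table(
    data.frame(position = seq_along(track), score = track),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# alignment display strings for a site: miRNA 3'->5', pairing line, UTR 5'->3'
.alignment_strings <- function(site, utr_seq) {
  n <- nchar(site$mirna_seq)
  mb <- strsplit(site$mirna_seq, "")[[1]]
  ub <- strsplit(normalize_rna(utr_seq), "")[[1]]
  mir_line <- utr_line <- pair_line <- character(0)
  sym <- c(WC = "|", GU = ":", MISMATCH = " ", GAP = " ", EXCLUDED = " ")
  next_utr <- site$utr_start
  for (pos in (n - 2):2) {                   # miRNA 3'->5' along the UTR
    st <- site$pair_states[[paste0("p", pos)]]
    tgt <- site$utr_pair[pos]
    if (!is.na(tgt)) {
      while (next_utr < tgt) {               # bulged UTR bases
        mir_line <- c(mir_line, "-")
        pair_line <- c(pair_line, " ")
        utr_line <- c(utr_line, ub[next_utr + 1])
        next_utr <- next_utr + 1
      }
      mir_line <- c(mir_line, mb[pos])
      pair_line <- c(pair_line, sym[[st]])
      utr_line <- c(utr_line, ub[tgt + 1])
      next_utr <- tgt + 1
    } else if (st == "GAP") {
      mir_line <- c(mir_line, mb[pos])
      pair_line <- c(pair_line, " ")
      utr_line <- c(utr_line, "-")
    }
  }
  c(mirna_3to5 = paste(mir_line, collapse = ""),
    pairing = paste(pair_line, collapse = ""),
    utr_5to3 = paste(utr_line, collapse = ""))
}

#' Write predicted sites as a TSV report
#'
#' One row per site with 0-based half-open UTR coordinates, the alignment
#' score, seed class and violation count, and the three alignment strings
#' (miRNA 3'->5', pairing line, UTR 5'->3').
#'
#' @param sites list of \code{"target_site"} objects.
#' @param utrs named character vector of UTR sequences keyed by gene id.
#' @param path output TSV.
#' @param scores optional data.frame with \code{raw_score} and
#'   \code{mirsvr_score} columns (same order as \code{sites}).
#' @return \code{path}, invisibly.
#' @export
write_sites <- function(sites, utrs, path, scores = NULL) {
  tab <- sites_table(sites)
  if (nrow(tab)) {
    aln <- t(vapply(sites, function(s)
      .alignment_strings(s, utrs[[s$gene_id]]), character(3)))
    tab <- cbind(tab, as.data.frame(aln, stringsAsFactors = FALSE))
    if (!is.null(scores))
      tab <- cbind(tab, scores[, intersect(c("raw_score", "mirsvr_score"),
                                           names(scores)), drop = FALSE])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# target sites; coordinates 0-based half-open", con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
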