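#' Canonical feature order of the site feature vector
#'
#' The fixed feature order shared by training and scoring: seed match bits
#' for microRNA positions 2-8, the A1 anchor bit, the position-9 match bit,
#' the 3' binding count (perfect pairs at positions 12-17), the AU context
#' score, 21 accessibility features (site-relative positions -20..+20
#' averaged over 2-base windows), the seed-block conservation, the UTR
#' length and the relative position of the site within the UTR.
#'
#' @return character vector of feature names in canonical order.
#' @export
feature_names <- function() {
  acc <- vapply(seq(-20, 20, by = 2), function(k) {
    if (k < 0) paste0("acc_m", -k) else if (k > 0) paste0("acc_p", k) else "acc_0"
  }, character(1))
  c(paste0("seed_m", 2:8), "a1", "m9", "three_prime", "au_score", acc,
    "conservation", "utr_length", "rel_position")
}

#' 3' binding: perfect pairs at microRNA positions 12-17
#'
#' @param site a \code{"target_site"} object.
#' @return integer in 0..6 (count over existing positions if the microRNA is
#'   shorter than 17 nt, with a warning).
#' @export
three_prime_binding <- function(site) {
  n <- nchar(site$mirna_seq)
  pos <- 12:17
  if (n < 17) {
    warning("microRNA shorter than 17 nt; 3' binding counted over positions 12-",
            n, call. = FALSE)
    pos <- pos[pos <= n]
  }
  sum(site$pair_states[paste0("p", pos)] == "WC")
}

#' AU context score of the sequence flanking a site
#'
#' Distance-weighted A/U content of up to \code{flank} bases on each side of
#' the site footprint: the base at offset i from the site edge carries weight
#' 1/(i + 1), and the score is the weighted fraction of A or U bases over
#' the positions that exist (flanks are truncated at the UTR ends), so it
#' lies in [0, 1].
#'
#' @param utr UTR sequence (character) or \code{list(id=, sequence=)}.
#' @param site a \code{"target_site"} object.
#' @param flank number of flanking bases considered on each side.
#' @return numeric scalar in [0, 1]; 0 with a warning if the site has no
#'   flanking bases at all.
#' @export
au_context_score <- function(utr, site, flank = 30) {
  seq <- normalize_rna(if (is.list(utr)) utr$sequence else utr)
  n <- nchar(seq)
  b <- strsplit(seq, "")[[1]]
  offs <- seq_len(flank)
  idx <- c(site$utr_start - offs + 1L,            # left flank, 1-based
           site$utr_end + offs)                   # right flank, 1-based
  w <- rep(1 / (offs + 1), 2)
  ok <- idx >= 1L & idx <= n
  if (!any(ok)) {
    warning("site has no flanking bases; AU score set to 0", call. = FALSE)
    return(0)
  }
  sum(w[ok] * (b[idx[ok]] %in% c("A", "U"))) / sum(w[ok])
}

#' Global UTR features of a site
#'
#' @inheritParams au_context_score
#' @return named numeric vector \code{c(utr_length=, rel_position=)} where
#'   \code{rel_position} is the distance of the site midpoint to the nearer
#'   UTR end divided by the UTR length (range [0, 0.5]).
#' @export
global_features <- function(utr, site) {
  seq <- if (is.list(utr)) utr$sequence else utr
  len <- nchar(seq)
  mid <- (site$utr_start + site$utr_end) / 2
  c(utr_length = len, rel_position = min(mid, len - mid) / len)
}

#' Conservation of the seed-match block
#'
#' Mean per-base conservation over the UTR positions opposite microRNA
#' positions 2-7.
#'
#' @param site a \code{"target_site"} object.
#' @param track numeric vector of per-base conservation values in [0, 1],
#'   one per UTR position, or \code{NULL}.
#' @return numeric scalar; 0 with a warning when the track is missing.
#' @export
conservation_score <- function(site, track) {
  if (is.null(track)) {
    warning("no conservation track; conservation feature set to 0", call. = FALSE)
    return(0)
  }
  idx <- site$utr_pair[2:7]
  idx <- idx[!is.na(idx)]
  if (!length(idx)) return(0)
  mean(track[idx + 1L])
}

#' Assemble the full feature vector of a target site
#'
#' Deterministically concatenates the duplex and context features in the
#' canonical order of \code{\link{feature_names}}.  When no accessibility
#' profile is supplied one is computed from the UTR itself with the default
#' energy model (see \code{\link{accessibility_profile}}).
#'
#' @inheritParams au_context_score
#' @param track per-base conservation values or \code{NULL} (feature 0).
#' @param access_profile an \code{"accessibility_profile"} covering the
#'   site, or \code{NULL} to compute one.
#' @return named numeric vector following \code{\link{feature_names}}.
#' @export
assemble_features <- function(site, utr, track = NULL, access_profile = NULL,
                              flank = 30) {
  states <- site$pair_states
  seed_bits <- as.numeric(states[paste0("p", 2:8)] == "WC")
  if (is.null(access_profile))
    access_profile <- accessibility_profile(
      utr, site, focus = c(site$utr_start - 20L, site$utr_start + 21L))
  acc <- site_accessibility_features(access_profile, site)
  cons <- if (is.null(track)) 0 else conservation_score(site, track)
  glob <- global_features(utr, site)
  out <- c(seed_bits, as.numeric(isTRUE(site$a1_anchor)),
           as.numeric(states["p9"] == "WC"),
           three_prime_binding(site),
           au_context_score(utr, site, flank),
           acc, cons, glob)
  names(out) <- feature_names()
  out
}

#' Build the feature matrix for a list of sites
#'
#' @param sites list of \code{"target_site"} objects.
#' @param utrs named character vector (or list) of UTR sequences keyed by
#'   gene id.
#' @param tracks optional named list of conservation tracks keyed by gene id.
#' @param profiles optional named list of accessibility profiles keyed by
#'   gene id (one region per gene) or \code{NULL} to compute per site.
#' @return numeric matrix, one row per site, columns
#'   \code{\link{feature_names}}.
#' @export
feature_matrix <- function(sites, utrs, tracks = NULL, profiles = NULL) {
  rows <- lapply(sites, function(s) {
    assemble_features(s, utrs[[s$gene_id]],
                      track = tracks[[s$gene_id]],
                      access_profile = profiles[[s$gene_id]])
  })
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(sites, function(s)
    paste(s$mirna_id, s$gene_id, s$utr_start, sep = ":"), character(1))
  X
}

# --- Z-score scaler ----------------------------------------------------------

#' Fit a Z-score scaler on a training feature matrix
#'
#' Records per-feature mean and standard deviation (population convention,
#' divisor n: a two-point column (0, 2) standardizes to exactly (-1, +1)).
#' Constant features are dropped with a warning and remain dropped when the
#' scaler is applied.
#'
#' @param X numeric matrix (>= 2 rows) with column names.
#' @return object of class \code{"feature_scaler"}.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows to fit a scaler")
  mu <- colMeans(X)
  sd_pop <- sqrt(colMeans(sweep(X, 2, mu)^2))
  keep <- sd_pop > 0
  if (!any(keep)) stop("all features are constant; cannot standardize")
  if (any(!keep))
    warning("dropping constant feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
  structure(list(center = mu[keep], scale = sd_pop[keep],
                 features = colnames(X)[keep]), class = "feature_scaler")
}

#' Apply a fitted Z-score scaler
#'
#' @param scaler a \code{"feature_scaler"}.
#' @param X numeric matrix containing at least the scaler's feature columns.
#' @return standardized matrix restricted to the scaler's features.
#' @export
apply_scaler <- function(scaler, X) {
  X <- as.matrix(X)
  miss <- setdiff(scaler$features, colnames(X))
  if (length(miss))
    stop("feature(s) missing from matrix: ", paste(miss, collapse = ", "))
  Xs <- X[, scaler$features, drop = FALSE]
  sweep(sweep(Xs, 2, scaler$center), 2, scaler$scale, "/")
}

#' @export
print.feature_scaler <- function(x, ...) {
  cat(sprintf("Z-score scaler over %d features (population sd)\n",
              length(x$features)))
  invisible(x)
}
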