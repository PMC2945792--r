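#' Simplified base-pair energy model for local structure prediction
#'
#' A stand-in for full nearest-neighbour thermodynamics: one stabilizing
#' energy per pair type (G:C, A:U, G:U), a minimum hairpin loop length and a
#' Boltzmann temperature factor.  With the defaults (-3/-2/-1 at kT = 1)
#' the three pair types get clearly separated, non-degenerate Boltzmann
#' weights.
#'
#' @param e_gc,e_au,e_gu pair energies (negative, arbitrary units).
#' @param min_loop minimum number of unpaired bases enclosed by a hairpin.
#' @param kT temperature factor dividing energies in the Boltzmann weight.
#' @return object of class \code{"energy_model"}.
#' @export
energy_model <- function(e_gc = -3, e_au = -2, e_gu = -1, min_loop = 3, kT = 1) {
  stopifnot(e_gc < 0, e_au < 0, e_gu < 0, min_loop >= 3, kT > 0)
  structure(list(e_gc = e_gc, e_au = e_au, e_gu = e_gu,
                 min_loop = min_loop, kT = kT), class = "energy_model")
}

#' Per-position probability that a short window is unpaired
#'
#' McCaskill-style partition function over all nested secondary structures
#' of the sequence (pair span capped at \code{L}, minimum hairpin loop from
#' the model), returning for every valid start position the probability
#' that the \code{u}-base window starting there is completely unpaired:
#' the ratio of the pairing-restricted to the unrestricted partition
#' function.
#'
#' @param seq nucleotide sequence (character; T converted to U).
#' @param u unpaired window length.
#' @param L maximum span (distance between paired bases).
#' @param model an \code{\link{energy_model}}.
#' @return numeric vector of length \code{nchar(seq) - u + 1}; element i is
#'   the probability for the window starting at 0-based position i - 1.
#' @export
partition_unpaired <- function(seq, u = 8, L = 40, model = energy_model()) {
  s <- normalize_rna(if (is.list(seq)) seq$sequence else seq)
  if (u > nchar(s)) stop("u exceeds sequence length")
  .pf_unpaired(.encode(s), as.integer(u), as.integer(L),
               as.integer(model$min_loop),
               model$e_gc, model$e_au, model$e_gu, model$kT,
               0L, nchar(s) - as.integer(u))
}

#' Local accessibility profile around a target site
#'
#' Computes the unpaired-window probabilities on a region (default 160
#' bases) centred on the site midpoint, mirroring an RNAplfold-style local
#' fold with parameters u = 8 and L = 40.
#'
#' @param utr UTR sequence (character) or \code{list(id=, sequence=)}.
#' @param site a \code{"target_site"} object, or an integer 0-based centre
#'   position.
#' @param u,L window length and maximum pair span.
#' @param span length of the region folded around the site.
#' @param model an \code{\link{energy_model}}.
#' @param focus optional 0-based UTR position range \code{c(lo, hi)}: only
#'   window starts within it are evaluated (the partition function is still
#'   computed over the whole region).  Used by the feature extractor, which
#'   only reads windows around the site.
#' @return object of class \code{"accessibility_profile"}: list with
#'   \code{start} (0-based UTR position of the first window start),
#'   \code{u}, \code{L} and \code{prob}.
#' @export
accessibility_profile <- function(utr, site, u = 8, L = 40, span = 160,
                                  model = energy_model(), focus = NULL) {
  seq <- normalize_rna(if (is.list(utr)) utr$sequence else utr)
  n <- nchar(seq)
  centre <- if (is.list(site)) floor((site$utr_start + site$utr_end) / 2)
            else as.integer(site)
  start <- max(0L, min(centre - span %/% 2L, n - span))
  end <- min(n, start + span)                      # 0-based half-open region
  region <- substr(seq, start + 1L, end)
  if (nchar(region) < u) stop("region around site shorter than u")
  nr <- nchar(region)
  i0 <- 0L
  i1 <- nr - as.integer(u)
  if (!is.null(focus)) {
    i0 <- max(0L, min(as.integer(focus[1]) - start, i1))
    i1 <- max(i0, min(as.integer(focus[2]) - start, i1))
  }
  prob <- .pf_unpaired(.encode(region), as.integer(u), as.integer(L),
                       as.integer(model$min_loop),
                       model$e_gc, model$e_au, model$e_gu, model$kT, i0, i1)
  structure(list(start = start + i0, u = u, L = L, prob = prob),
            class = "accessibility_profile")
}

#' @export
print.accessibility_profile <- function(x, ...) {
  cat(sprintf("accessibility profile: %d windows (u=%d, L=%d) from position %d\n",
              length(x$prob), x$u, x$L, x$start))
  invisible(x)
}

.profile_at <- function(profile, utr_pos, warn = TRUE) {
  # unpaired probability of the window starting at a 0-based UTR position,
  # clamped to the nearest computed window when outside the profile
  idx <- utr_pos - profile$start + 1L
  clamped <- pmin(pmax(idx, 1L), length(profile$prob))
  if (warn && any(idx != clamped))
    warning("accessibility profile truncated; nearest window value used",
            call. = FALSE)
  profile$prob[clamped]
}

#' Accessibility features of a site
#'
#' Samples the unpaired-window probabilities at site-relative positions
#' -20..+20 (relative to the site 5' end on the UTR), averaging consecutive
#' pairs of positions over a window of two bases, yielding 21 values.
#'
#' @param profile an \code{\link{accessibility_profile}} covering the site.
#' @param site a \code{"target_site"} object.
#' @return numeric vector of 21 probabilities in [0, 1].
#' @export
site_accessibility_features <- function(profile, site) {
  anchor <- site$utr_start
  lo <- anchor - 20L
  hi <- anchor + 21L
  if (lo < profile$start ||
      hi > profile$start + length(profile$prob) - 1L)
    warning("accessibility profile truncated; nearest window value used",
            call. = FALSE)
  vapply(seq(-20, 20, by = 2), function(k) {
    mean(.profile_at(profile, anchor + k + 0:1, warn = FALSE))
  }, numeric(1))
}

#' Read an externally computed accessibility profile
#'
#' Accepts a two-column table (1-based position, probability) as written by
#' \code{\link{write_accessibility}} or extracted from an RNAplfold
#' \code{_lunp} file; comment lines starting with \code{#} may carry
#' \code{u=}, \code{L=} and \code{start=} metadata.  Probabilities outside
#' [0, 1] are clipped with a warning.
#'
#' @param path file path.
#' @return an \code{"accessibility_profile"}.
#' @export
load_accessibility <- function(path) {
  lines <- readLines(path)
  meta <- list(u = 8L, L = 40L)
  hdr <- grep("^#", lines)
  for (h in hdr) {
    for (key in c("u", "L")) {
      m <- regmatches(lines[h], regexec(paste0("\\b", key, "=([0-9]+)"), lines[h]))[[1]]
      if (length(m) == 2) meta[[key]] <- as.integer(m[2])
    }
  }
  body <- setdiff(seq_along(lines), hdr)
  body <- body[nzchar(trimws(lines[body]))]
  pos <- prob <- numeric(length(body))
  for (i in seq_along(body)) {
    f <- strsplit(trimws(lines[body[i]]), "[\t ]+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(v) < 2 || anyNA(v[1:2]))
      stop("malformed accessibility row at line ", body[i], ": ", lines[body[i]])
    pos[i] <- v[1]; prob[i] <- v[2]
  }
  if (any(prob < 0 | prob > 1)) {
    warning("probabilities outside [0,1] clipped", call. = FALSE)
    prob <- pmin(pmax(prob, 0), 1)
  }
  structure(list(start = as.integer(pos[1]) - 1L, u = meta$u, L = meta$L,
                 prob = prob), class = "accessibility_profile")
}

#' Write an accessibility profile as a plain-text table
#'
#' Two tab-separated columns (1-based window start position, probability)
#' with a metadata comment line; round-trips through
#' \code{\link{load_accessibility}}.
#'
#' @param profile an \code{"accessibility_profile"}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_accessibility <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unpaired window probabilities u=%d L=%d",
                     profile$u, profile$L), con)
  writeLines(sprintf("%d\t%.17g",
                     profile$start + seq_along(profile$prob), profile$prob), con)
  invisible(path)
}
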