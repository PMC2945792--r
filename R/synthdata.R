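# Synthetic transfection experiments with known ground truth: microRNAs,
# UTRs with planted sites of chosen seed classes and contexts, conservation
# tracks, and expression tables generated from a known linear-in-features
# downregulation signal passed through a known sigmoid.

.COMP <- c(A = "U", C = "G", G = "C", U = "A")
.WOBBLE <- c(A = NA, C = NA, G = "U", U = "G")

# a base opposite m that is neither its Watson-Crick complement nor its
# wobble partner
.mismatch_base <- function(m) if (m == "G") "A" else "C"

#' Generate random microRNA sequences
#'
#' @param n number of microRNAs.
#' @param length sequence length in nt.
#' @param seed RNG seed (the generator is fully deterministic given the
#'   seed).
#' @return list of records \code{list(id=, sequence=)}.
#' @export
generate_mirnas <- function(n, length = 22, seed = 1) {
  stopifnot(n >= 1, length >= 9)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    list(id = sprintf("syn-mir-%03d", i),
         sequence = paste(sample(RNA_BASES, length, replace = TRUE),
                          collapse = ""))
  })
}

#' Specification of a planted target site
#'
#' @param seed_class one of \code{"8mer"}, \code{"7mer_m8"},
#'   \code{"7mer_A1"}, \code{"6mer"}, \code{"non_canonical"}.
#' @param position 0-based UTR start of the site footprint.
#' @param viol_pos,viol_type for non-canonical sites: the seed position
#'   (2-7) carrying the violation and its type (\code{"MM"} mismatch or
#'   \code{"GU"} wobble; a wobble needs a G or U at that microRNA
#'   position).
#' @param flank_au target A/U fraction of the 30-base flanks (\code{NA}
#'   leaves the background composition).
#' @param three_prime_pairs number of Watson-Crick pairs planted at
#'   microRNA positions 12-17 (0-6).
#' @param conservation conservation level written over the site footprint
#'   in the gene's synthetic track.
#' @return object of class \code{"site_spec"}.
#' @export
site_spec <- function(seed_class = "8mer", position = 100, viol_pos = NA,
                      viol_type = c("MM", "GU"), flank_au = NA,
                      three_prime_pairs = 6, conservation = 1) {
  viol_type <- match.arg(viol_type)
  seed_class <- match.arg(seed_class, c("8mer", "7mer_m8", "7mer_A1",
                                        "6mer", "non_canonical"))
  if (seed_class == "non_canonical" && !(viol_pos %in% 2:7))
    stop("non-canonical spec needs viol_pos in 2..7")
  structure(list(seed_class = seed_class, position = as.integer(position),
                 viol_pos = viol_pos, viol_type = viol_type,
                 flank_au = flank_au,
                 three_prime_pairs = as.integer(three_prime_pairs),
                 conservation = conservation), class = "site_spec")
}

# sequence planted into the UTR for a spec: the site footprint (opposite
# microRNA positions n-2 .. 2, read 5'->3' on the UTR) plus the A1 base
.site_sequence <- function(mirna_seq, spec) {
  mb <- strsplit(mirna_seq, "")[[1]]
  n <- length(mb)
  opp <- .COMP[mb]                      # opposite base per miRNA position
  if (spec$seed_class %in% c("7mer_A1", "6mer"))
    opp[8] <- .mismatch_base(mb[8])
  if (spec$seed_class == "non_canonical") {
    p <- spec$viol_pos
    if (spec$viol_type == "GU") {
      if (is.na(.WOBBLE[mb[p]]))
        stop("G:U violation impossible: microRNA position ", p, " is ", mb[p])
      opp[p] <- .WOBBLE[mb[p]]
    } else opp[p] <- .mismatch_base(mb[p])
  }
  if (n >= 17 && spec$three_prime_pairs < 6) {
    off <- 12:17
    mm <- off[seq_len(6 - spec$three_prime_pairs) + spec$three_prime_pairs]
    opp[mm] <- vapply(mb[mm], .mismatch_base, character(1))
  }
  a1 <- if (spec$seed_class %in% c("8mer", "7mer_A1")) "A" else "C"
  paste(c(rev(opp[2:(n - 2)]), a1), collapse = "")
}

#' Generate a UTR with planted target sites
#'
#' Draws a random background sequence, embeds sites realizing the requested
#' seed classes, violations, 3' pairing and flank AU composition, and (by
#' default) screens the background so that no accidental perfect seed
#' match to the microRNA survives outside the planted footprints — making
#' plant-and-recover tests exact.
#'
#' @param mirna microRNA record (\code{list(id=, sequence=)}) or sequence.
#' @param site_specs list of \code{\link{site_spec}} objects with
#'   non-overlapping footprints.
#' @param length UTR length in nt.
#' @param background_gc G+C fraction of the background.
#' @param seed RNG seed.
#' @param screen remove accidental seed matches from the background.
#' @return list with \code{id}, \code{sequence}, and \code{planted}
#'   (data.frame of 0-based half-open footprints and spec fields).
#' @export
generate_utr <- function(mirna, site_specs = list(), length = 600,
                         background_gc = 0.5, seed = 1, screen = TRUE) {
  mir <- .as_mirna(mirna, NULL)
  n <- nchar(mir$seq)
  m <- n - 3L                                   # footprint length
  set.seed(seed)
  bg_p <- c(A = (1 - background_gc) / 2, C = background_gc / 2,
            G = background_gc / 2, U = (1 - background_gc) / 2)
  probs <- matrix(bg_p, nrow = 4, ncol = length,
                  dimnames = list(names(bg_p), NULL))
  fixed <- logical(length)

  planted <- NULL
  for (spec in site_specs) {
    fs <- spec$position
    fe <- fs + m + 1L                           # footprint + A1 base
    if (fs < 0 || fe > length) stop("planted site does not fit in UTR")
    if (any(fixed[(fs + 1):fe])) stop("planted sites overlap")
    fixed[(fs + 1):fe] <- TRUE
    if (!is.na(spec$flank_au)) {
      au <- spec$flank_au
      fp <- c(A = au / 2, C = (1 - au) / 2, G = (1 - au) / 2, U = au / 2)
      for (j in c((fs - 30):(fs - 1), (fe + 1):(fe + 30)))
        if (j >= 0 && j < length && !fixed[j + 1]) probs[, j + 1] <- fp
    }
    # a mismatch violation at position 2 sits at the very end of the
    # aligned region, so the local alignment trims it: the recovered
    # footprint ends one base earlier
    trim <- as.integer(spec$seed_class == "non_canonical" &&
                         !is.na(spec$viol_pos) && spec$viol_pos == 2 &&
                         spec$viol_type == "MM")
    planted <- rbind(planted, data.frame(
      utr_start = fs, utr_end = fs + m - trim, seed_class = spec$seed_class,
      viol_pos = spec$viol_pos, three_prime_pairs = spec$three_prime_pairs,
      conservation = spec$conservation, stringsAsFactors = FALSE))
  }

  draw <- function(cols) vapply(cols, function(j)
    sample(RNA_BASES, 1, prob = probs[, j]), character(1))
  b <- draw(seq_len(length))
  for (i in seq_along(site_specs)) {
    spec <- site_specs[[i]]
    s <- strsplit(.site_sequence(mir$seq, spec), "")[[1]]
    b[(spec$position + 1):(spec$position + m + 1L)] <- s
  }

  if (screen) {
    motif <- paste(rev(.COMP[strsplit(substr(mir$seq, 2, 7), "")[[1]]]),
                   collapse = "")
    for (round in 1:100) {
      seqstr <- paste(b, collapse = "")
      occ <- gregexpr(motif, seqstr, fixed = TRUE)[[1]]
      occ <- occ[occ > 0]
      occ <- occ[vapply(occ, function(o)
        !any(fixed[o:(o + 5)]), logical(1))]
      if (!length(occ)) break
      for (o in occ) b[o:(o + 5)] <- draw(o:(o + 5))
    }
  }
  list(id = "utr", sequence = paste(b, collapse = ""), planted = planted)
}

#' Ground truth of a synthetic transfection experiment
#'
#' @param w_star named true feature weights (names from
#'   \code{\link{feature_names}} or any feature subset).
#' @param sigmoid true transfer parameters \code{c(a=, b=, c=)}, or
#'   \code{NULL} for a purely linear signal.
#' @param noise_sd Gaussian noise standard deviation on the expression
#'   scale.
#' @return object of class \code{"ground_truth"}.
#' @export
ground_truth <- function(w_star, sigmoid = NULL, noise_sd = 0.3) {
  stopifnot(!is.null(names(w_star)))
  structure(list(w_star = w_star, sigmoid = sigmoid, noise_sd = noise_sd),
            class = "ground_truth")
}

# per-site true contribution on the expression scale
.site_signal <- function(X, truth) {
  keep <- intersect(names(truth$w_star), colnames(X))
  sc <- suppressWarnings(fit_scaler(X))
  Xs <- apply_scaler(sc, X)
  keep <- intersect(keep, colnames(Xs))
  raw <- drop(Xs[, keep, drop = FALSE] %*% truth$w_star[keep])
  if (is.null(truth$sigmoid)) raw
  else sigmoid_transform(raw, truth$sigmoid[["a"]], truth$sigmoid[["b"]],
                         truth$sigmoid[["c"]])
}

#' Generate a transfection-style expression table from site features
#'
#' Per gene, the expected log expression change is the sum of its sites'
#' true contributions (the linear signal \code{<w*, x>} per site, passed
#' through the true sigmoid when one is given); genes without sites have
#' zero expectation.  Gaussian noise is added and an independent
#' log-normal control-intensity column is simulated so the above-median
#' expression filter can be exercised downstream.  Log changes are written
#' untransformed; \code{\link{prepare_training_set}} Z-transforms them per
#' experiment.
#'
#' @param features site feature matrix (one row per site).
#' @param site_gene gene id per feature row.
#' @param genes all gene ids of the experiment (including site-less genes).
#' @param truth a \code{\link{ground_truth}}.
#' @param mirna_id transfected microRNA id.
#' @param experiment_id experiment label.
#' @param seed RNG seed.
#' @return data.frame with \code{gene_id}, \code{experiment_id},
#'   \code{mirna_id}, \code{log_change}, \code{control_intensity};
#'   attribute \code{"signal"} holds the per-gene noise-free expectation.
#' @export
generate_expression <- function(features, site_gene, genes, truth,
                                mirna_id = "mir", experiment_id = "tx1",
                                seed = 1) {
  set.seed(seed)
  signal <- stats::setNames(numeric(length(genes)), genes)
  if (nrow(features)) {
    contrib <- .site_signal(features, truth)
    agg <- tapply(contrib, site_gene, sum)
    signal[names(agg)] <- agg
  }
  out <- data.frame(
    gene_id = genes, experiment_id = experiment_id, mirna_id = mirna_id,
    log_change = signal + stats::rnorm(length(genes), 0, truth$noise_sd),
    control_intensity = stats::rlnorm(length(genes), meanlog = 8, sdlog = 1),
    stringsAsFactors = FALSE)
  attr(out, "signal") <- signal
  rownames(out) <- NULL
  out
}

#' Sample plausible site feature vectors directly
#'
#' Feature-level companion to the sequence-level generator: draws feature
#' vectors with the marginal structure of real sites (a seed-class mix
#' driving the seed bits, binomial 3' pairing, beta-distributed AU,
#' accessibility and conservation, log-normal-ish UTR lengths) without
#' synthesizing sequences.  Used for model-level recovery experiments at
#' sample sizes where folding every site would be wasteful.
#'
#' @param n number of sites.
#' @param seed RNG seed.
#' @return numeric matrix \code{n x length(feature_names())}.
#' @export
generate_site_features <- function(n, seed = 1) {
  set.seed(seed)
  cls <- sample(c("8mer", "7mer_m8", "7mer_A1", "6mer", "non_canonical"),
                n, replace = TRUE, prob = c(0.25, 0.25, 0.15, 0.15, 0.2))
  X <- matrix(0, n, length(feature_names()),
              dimnames = list(NULL, feature_names()))
  for (i in seq_len(n)) {
    bits <- rep(1, 7)
    a1 <- 0
    switch(cls[i],
           "8mer" = { a1 <- 1 },
           "7mer_m8" = { },
           "7mer_A1" = { bits[7] <- 0; a1 <- 1 },
           "6mer" = { bits[7] <- 0 },
           "non_canonical" = { bits[sample(1:6, 1)] <- 0 })
    X[i, paste0("seed_m", 2:8)] <- bits
    X[i, "a1"] <- a1
  }
  X[, "m9"] <- stats::rbinom(n, 1, 0.3)
  X[, "three_prime"] <- stats::rbinom(n, 6, 0.4)
  X[, "au_score"] <- stats::rbeta(n, 2, 2)
  acc_cols <- grep("^acc_", feature_names(), value = TRUE)
  base_acc <- stats::rbeta(n, 2, 3)
  for (ac in acc_cols)
    X[, ac] <- pmin(pmax(base_acc + stats::rnorm(n, 0, 0.08), 0), 1)
  X[, "conservation"] <- stats::rbeta(n, 1.2, 1.2)
  X[, "utr_length"] <- round(exp(stats::rnorm(n, log(900), 0.6)))
  X[, "rel_position"] <- stats::runif(n, 0, 0.5)
  X
}

#' Default true weights of the synthetic downregulation signal
#'
#' Negative weights mean the feature promotes downregulation (more
#' negative observed log change): strong seed pairing, the A1 anchor,
#' 3' supplementary pairing, AU-rich context, accessibility and
#' conservation all do; long UTRs dilute the effect slightly.
#'
#' @return named numeric vector over a subset of
#'   \code{\link{feature_names}}.
#' @export
default_truth_weights <- function() {
  w <- c(stats::setNames(rep(-0.25, 7), paste0("seed_m", 2:8)),
         a1 = -0.3, m9 = -0.05, three_prime = -0.2, au_score = -0.3,
         acc_0 = -0.15, acc_p2 = -0.1, acc_m2 = -0.1,
         conservation = -0.2, utr_length = 0.1, rel_position = 0.1)
  w
}

#' Simulate a complete transfection experiment
#'
#' End-to-end synthetic data: one transfected microRNA, \code{n_genes}
#' UTRs (a mix of site-less, single-site and two-site genes with a mix of
#' seed classes, random 3' pairing, AU context and conservation levels),
#' screened backgrounds, per-gene conservation tracks, recovered sites
#' (via \code{\link{scan_utr}} under the all-sites rule), their assembled
#' features, and an expression table drawn from the known ground truth.
#'
#' @param n_genes number of genes.
#' @param mirna microRNA record, or \code{NULL} to generate one.
#' @param utr_length UTR length in nt.
#' @param noise_sd expression noise standard deviation.
#' @param truth a \code{\link{ground_truth}}, or \code{NULL} for the
#'   default weights with sigmoid \code{(a=-1.2, b=1, c=2.5)}.
#' @param n_site_probs probabilities of a gene carrying 0, 1 or 2 sites.
#' @param class_probs seed-class mix of planted sites.
#' @param seed master RNG seed; all per-gene seeds derive from it.
#' @param experiment_id experiment label.
#' @return list with \code{mirna}, \code{utrs} (named sequences),
#'   \code{tracks} (named conservation vectors), \code{planted}
#'   (data.frame of planted footprints), \code{sites} (recovered
#'   \code{"target_site"} list), \code{features}, \code{expression} and
#'   \code{truth}.
#' @export
simulate_transfection <- function(n_genes = 300, mirna = NULL,
                                  utr_length = 600, noise_sd = 0.3,
                                  truth = NULL,
                                  n_site_probs = c(0.25, 0.6, 0.15),
                                  class_probs = c("8mer" = 0.3,
                                                  "7mer_m8" = 0.2,
                                                  "7mer_A1" = 0.15,
                                                  "6mer" = 0.15,
                                                  "non_canonical" = 0.2),
                                  seed = 1, experiment_id = "tx1") {
  set.seed(seed)
  if (is.null(mirna)) mirna <- generate_mirnas(1, seed = seed)[[1]]
  if (is.null(truth))
    truth <- ground_truth(default_truth_weights(),
                          sigmoid = c(a = -1.2, b = 1, c = 2.5),
                          noise_sd = noise_sd)
  m <- nchar(mirna$sequence) - 3L
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  n_sites <- sample(0:2, n_genes, replace = TRUE, prob = n_site_probs)
  child <- sample.int(.Machine$integer.max - 1L, n_genes)

  # candidate anchor positions keep sites clear of the ends (flank + folding
  # room) and of each other
  slots <- c(80L, utr_length - 80L - m - 40L)
  utrs <- vector("list", n_genes)
  tracks <- vector("list", n_genes)
  planted_all <- NULL
  for (g in seq_len(n_genes)) {
    specs <- list()
    if (n_sites[g] > 0) {
      pos <- sample(slots, n_sites[g])
      for (k in seq_len(n_sites[g])) {
        cl <- sample(names(class_probs), 1, prob = class_probs)
        vp <- NA
        vt <- "MM"
        if (cl == "non_canonical") {
          vp <- sample(2:7, 1)
          mb <- substr(mirna$sequence, vp, vp)
          vt <- if (mb %in% c("G", "U") && stats::runif(1) < 0.5) "GU" else "MM"
        }
        specs[[k]] <- site_spec(cl, position = pos[k] +
                                  sample(0:20, 1), viol_pos = vp,
                                viol_type = vt,
                                flank_au = stats::runif(1, 0.15, 0.85),
                                three_prime_pairs = sample(0:6, 1),
                                conservation = stats::runif(1))
      }
    }
    u <- generate_utr(mirna, specs, length = utr_length, seed = child[g])
    utrs[[g]] <- u$sequence
    set.seed(child[g] %% 1000000L + 7L)
    tr <- stats::runif(utr_length, 0, 0.4)
    if (!is.null(u$planted)) {
      for (r in seq_len(nrow(u$planted)))
        tr[(u$planted$utr_start[r] + 1):(u$planted$utr_end[r])] <-
          u$planted$conservation[r]
      u$planted$gene_id <- gene_ids[g]
      planted_all <- rbind(planted_all, u$planted)
    }
    tracks[[g]] <- tr
  }
  names(utrs) <- names(tracks) <- gene_ids

  params <- alignment_params(seed_rule = "all_sites")
  sites <- list()
  for (g in seq_len(n_genes)) {
    hits <- scan_utr(mirna, list(id = gene_ids[g], sequence = utrs[[g]]),
                     params, mirna_id = mirna$id)
    sites <- c(sites, hits)
  }
  features <- if (length(sites))
    suppressWarnings(feature_matrix(sites, utrs, tracks)) else
    matrix(numeric(), 0, length(feature_names()),
           dimnames = list(NULL, feature_names()))
  site_gene <- vapply(sites, `[[`, character(1), "gene_id")
  expression <- generate_expression(features, site_gene, gene_ids, truth,
                                    mirna_id = mirna$id,
                                    experiment_id = experiment_id,
                                    seed = seed + 101L)
  list(mirna = mirna, utrs = utrs, tracks = tracks, planted = planted_all,
       sites = sites, features = features, site_gene = site_gene,
       expression = expression, truth = truth,
       params = params, seed = seed)
}
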