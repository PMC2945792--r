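test_that("a perfectly complementary window yields one all-WC site with the summed scaled score", {
  set.seed(11)
  for (rep in 1:5) {
    mir <- list(id = "m", sequence = rand_rna(22))
    win <- perfect_window(mir$sequence)
    hits <- align_duplex(mir, win)
    expect_length(hits, 1)
    s <- hits[[1]]
    states <- s$pair_states[paste0("p", 2:20)]
    expect_true(all(states == "WC"))
    expect_identical(unname(s$pair_states[c("p1", "p21", "p22")]),
                     rep("EXCLUDED", 3))
    # 7 seed positions (2-8) at 5*4, 12 remaining aligned positions at 5
    expect_equal(s$score, 7 * 5 * 4 + 12 * 5)
    expect_identical(c(s$utr_start, s$utr_end), c(0L, nchar(win)))
  }
})

test_that("default parameters carry the miRanda-style search configuration", {
  p <- alignment_params()
  expect_equal(c(p$score_cutoff, p$gap_open, p$gap_extend), c(120, -9, -4))
  expect_equal(p$seed_rule, "canonical_only")
})

test_that("alignment score equals the exhaustive-search optimum on random small pairs", {
  set.seed(42)
  p <- alignment_params()
  for (rep in 1:60) {
    mir <- rand_rna(sample(9:12, 1))
    win <- rand_rna(sample(8:12, 1))
    q <- oracle_query(mir)
    expected <- oracle_local_align(q$query, win, q$seed, p)
    hits <- align_duplex(mir, win, p, min_score = 1e-9)
    got <- if (length(hits)) max(vapply(hits, `[[`, numeric(1), "score")) else 0
    expect_equal(got, expected, tolerance = 1e-12,
                 info = paste("miR", mir, "win", win))
  }
})

test_that("reported sites are non-overlapping, above cutoff, and satisfy the seed rule", {
  set.seed(7)
  mir <- generate_mirnas(1, seed = 3)[[1]]
  for (rep in 1:6) {
    specs <- list(site_spec("8mer", position = 60),
                  site_spec("6mer", position = 200),
                  site_spec("non_canonical", position = 330, viol_pos = 4),
                  site_spec("7mer_m8", position = 460))
    u <- generate_utr(mir, specs, length = 560, seed = 100 + rep)
    for (rule in c("canonical_only", "all_sites")) {
      sites <- scan_utr(mir, list(id = "g", sequence = u$sequence),
                        alignment_params(seed_rule = rule))
      tab <- sites_table(sites)
      expect_true(all(tab$score >= 120))
      if (nrow(tab) > 1) {
        ord <- order(tab$utr_start)
        expect_true(all(tab$utr_end[ord][-nrow(tab)] <=
                          tab$utr_start[ord][-1]))
      }
      max_v <- if (rule == "canonical_only") 0 else 1
      expect_true(all(tab$seed_violations <= max_v))
      for (s in sites)
        expect_false(any(s$pair_states[paste0("p", 2:7)] == "GAP"))
    }
  }
})

test_that("raising the cutoff never adds sites and canonical sites are a subset of all sites", {
  mir <- generate_mirnas(1, seed = 5)[[1]]
  u <- generate_utr(mir, list(site_spec("8mer", position = 80),
                              site_spec("non_canonical", position = 240,
                                        viol_pos = 5)),
                    length = 400, seed = 9)
  utr <- list(id = "g", sequence = u$sequence)
  lo <- sites_table(scan_utr(mir, utr, alignment_params(
    score_cutoff = 100, seed_rule = "all_sites")))
  hi <- sites_table(scan_utr(mir, utr, alignment_params(
    score_cutoff = 160, seed_rule = "all_sites")))
  key <- function(t) paste(t$utr_start, t$utr_end)
  expect_true(all(key(hi) %in% key(lo)))
  can <- sites_table(scan_utr(mir, utr, alignment_params(
    seed_rule = "canonical_only")))
  all_s <- sites_table(scan_utr(mir, utr, alignment_params(
    seed_rule = "all_sites")))
  expect_true(all(key(can) %in% key(all_s)))
})

test_that("site coordinates round-trip: consumed UTR bases reproduce the footprint substring", {
  set.seed(13)
  mir <- generate_mirnas(1, seed = 21)[[1]]
  u <- generate_utr(mir, list(site_spec("8mer", position = 100),
                              site_spec("7mer_A1", position = 250)),
                    length = 400, seed = 22)
  sites <- scan_utr(mir, list(id = "g", sequence = u$sequence),
                    alignment_params(seed_rule = "all_sites"))
  expect_gt(length(sites), 0)
  for (s in sites) {
    aln <- mirsvr:::.alignment_strings(s, u$sequence)
    consumed <- gsub("-", "", aln[["utr_5to3"]])
    expect_identical(consumed,
                     substr(u$sequence, s$utr_start + 1, s$utr_end))
  }
})

test_that("overlapping candidates resolve to the higher-scoring site", {
  # a strong perfect site; a weaker overlapping alignment cannot be reported
  mir <- list(id = "m", sequence = "UGAGGUAGUAGGUUGUAUAGUU")
  win <- perfect_window(mir$sequence)
  utr <- paste0(paste(rep("C", 30), collapse = ""), win,
                paste(rep("C", 30), collapse = ""))
  hits <- align_duplex(mir, utr, min_score = 30)
  scores <- vapply(hits, `[[`, numeric(1), "score")
  best <- hits[[which.max(scores)]]
  expect_equal(max(scores), 200)
  expect_identical(c(best$utr_start, best$utr_end), c(30L, 49L))
  starts <- vapply(hits, `[[`, integer(1), "utr_start")
  ends <- vapply(hits, `[[`, integer(1), "utr_end")
  ord <- order(starts)
  expect_true(all(ends[ord][-length(ord)] <= starts[ord][-1]))
})

test_that("a G:U wobble in the seed is kept only under the all-sites rule", {
  mir <- generate_mirnas(1, seed = 77)[[1]]
  # ensure a G or U at a seed position for the wobble
  viol <- which(strsplit(mir$sequence, "")[[1]][2:7] %in% c("G", "U"))[1] + 1
  u <- generate_utr(mir, list(site_spec("non_canonical", position = 120,
                                        viol_pos = viol, viol_type = "GU")),
                    length = 300, seed = 78)
  utr <- list(id = "g", sequence = u$sequence)
  can <- sites_table(scan_utr(mir, utr, alignment_params(
    seed_rule = "canonical_only")))
  all_s <- sites_table(scan_utr(mir, utr, alignment_params(
    seed_rule = "all_sites")))
  expect_false(u$planted$utr_start[1] %in% can$utr_start)
  expect_true(u$planted$utr_start[1] %in% all_s$utr_start)
})

test_that("seed classification matches the independent rule over all state combinations", {
  states <- c("WC", "GU", "MISMATCH")
  grid <- expand.grid(p2 = states, p3 = states, p4 = states, p5 = states,
                      p6 = states, p7 = states, p8 = states,
                      a1 = c(TRUE, FALSE), stringsAsFactors = FALSE)
  full <- rep("WC", 22)
  for (i in seq_len(nrow(grid))) {
    v <- full
    v[2:8] <- unlist(grid[i, 1:7])
    v[c(1, 21, 22)] <- "EXCLUDED"
    names(v) <- paste0("p", 1:22)
    got <- classify_seed(v, a1_anchor = grid$a1[i])
    want <- oracle_seed_class(unlist(grid[i, 1:6]), grid$p8[i], grid$a1[i])
    if (got != want) {
      fail(sprintf("row %d: got %s want %s", i, got, want))
      break
    }
  }
  succeed()
})

test_that("a site abutting the UTR 3' end has no A1 anchor", {
  mir <- list(id = "m", sequence = rand_rna(22))
  win <- perfect_window(mir$sequence)
  hits <- align_duplex(mir, win)        # window IS the footprint, no base after
  expect_false(hits[[1]]$a1_anchor)
  hits2 <- align_duplex(mir, paste0(win, "A"))
  expect_true(hits2[[1]]$a1_anchor)
  expect_equal(hits2[[1]]$seed_class, "8mer")
})

test_that("input validation rejects bad sequences", {
  expect_error(align_duplex("ACGUNACGUACGU", "ACGUACGU"), "non-nucleotide")
  expect_error(align_duplex("ACGUACGU", "ACGUACGUACGU"), "at least 9")
  expect_identical(scan_utr(list(id = "m", sequence = rand_rna(22)),
                            list(id = "g", sequence = "")), list())
})
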